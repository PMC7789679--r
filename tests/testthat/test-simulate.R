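test_that("noise-free, fully observed simulation reproduces true effects in raw means", {
    fc <- matrix(0, 3, 5,
                 dimnames = list(NULL, c("baseline", "healthy", "traumatic",
                                         "degenerative", "IL1b")))
    fc[, "traumatic"] <- c(0, 1.5, -2)
    fc[, "healthy"] <- c(2, 0, 0.5)
    cfg <- simulationConfig(nDonors = 4, nProteins = 3L, trueLog2FC = fc,
                            donorSD = 0, noiseSD = 0, missingMcarRate = 0,
                            missingMnarScale = 0, seed = 11)
    sim <- simulatePeptideTable(cfg)
    l2 <- log2(intensityMatrix(sim$experiment))
    des <- sampleDesign(sim$experiment)
    prot <- proteinGroups(sim$experiment)
    for (cc in c("traumatic", "healthy")) {
        b <- unique(des$batch[des$condition == cc])
        for (i in seq_len(nrow(l2))) {
            mcond <- mean(l2[i, des$condition == cc])
            mbase <- mean(l2[i, des$condition == "baseline" & des$batch == b])
            expect_equal(mcond - mbase,
                         unname(fc[match(prot[i], sprintf("PROT%04d", 1:3)),
                                   cc]),
                         tolerance = 1e-9)
        }
    }
})

test_that("MCAR missingness hits its nominal rate and MNAR dropout is monotone in intensity", {
    cfg <- simulationConfig(nProteins = 60L, missingMcarRate = 0.2,
                            missingMnarScale = 0, seed = 21)
    sim <- simulatePeptideTable(cfg)
    n <- length(sim$truth$missing)
    rate <- mean(sim$truth$missing)
    tol <- 3 * sqrt(0.2 * 0.8 / n)
    expect_gt(rate, 0.2 - tol)
    expect_lt(rate, 0.2 + tol)

    cfg2 <- simulationConfig(nProteins = 80L, missingMcarRate = 0,
                             missingMnarScale = 1.5, seed = 22)
    sim2 <- simulatePeptideTable(cfg2)
    l2 <- sim2$truth$log2complete
    bins <- cut(l2, quantile(l2, seq(0, 1, 0.2)), include.lowest = TRUE)
    frac <- tapply(as.vector(sim2$truth$missing), bins, mean)
    expect_true(all(diff(frac) <= 0.02))  # non-increasing up to binomial noise
    expect_gt(frac[1], frac[5])
})

test_that("the generator is deterministic in its seed", {
    cfg <- simulationConfig(nProteins = 10L, seed = 5)
    a <- simulatePeptideTable(cfg)
    b <- simulatePeptideTable(cfg)
    expect_identical(intensityMatrix(a$experiment),
                     intensityMatrix(b$experiment))
    expect_identical(a$truth, b$truth)
    c2 <- simulatePeptideTable(simulationConfig(nProteins = 10L, seed = 6))
    expect_false(identical(intensityMatrix(a$experiment),
                           intensityMatrix(c2$experiment)))
})

test_that("the default design is 48 + 24 samples with baseline in both batches", {
    sim <- simulatePeptideTable(simulationConfig(nProteins = 2L, seed = 1))
    des <- sampleDesign(sim$experiment)
    expect_equal(sum(des$batch == "batch1"), 48)
    expect_equal(sum(des$batch == "batch2"), 24)
    expect_setequal(unique(des$batch[des$condition == "baseline"]),
                    c("batch1", "batch2"))
    expect_equal(sum(des$condition == "baseline"), 24)
})

test_that("invalid configurations are rejected", {
    expect_error(simulationConfig(nProteins = 0), "positive")
    expect_error(simulationConfig(nDonors = -1), "positive")
    fc <- matrix(1, 3, 1, dimnames = list(NULL, "nosuch"))
    expect_error(simulationConfig(nProteins = 3L, trueLog2FC = fc),
                 "unknown condition")
    fc2 <- matrix(1, 3, 5,
                  dimnames = list(NULL, c("baseline", "healthy", "traumatic",
                                          "degenerative", "IL1b")))
    expect_error(simulatePeptideTable(
        simulationConfig(nProteins = 3L, trueLog2FC = fc2)),
        "reference condition")
})

test_that("gene-set generation plants enrichment and respects size limits", {
    out <- simulateGeneSets(letters, nSets = 0)
    expect_length(out, 0)
    expect_error(simulateGeneSets(letters, 3, setSizeRange = c(2, 40)),
                 "universe")
    expect_error(simulateGeneSets(letters, 3, setSizeRange = c(1, 5)),
                 ">= 2")
    prots <- sprintf("PROT%04d", 1:100)
    fc <- matrix(0, 100, 2, dimnames = list(prots, c("baseline", "stim")))
    fc[1:30, "stim"] <- 2
    sets <- simulateGeneSets(prots, nSets = 10, setSizeRange = c(10, 15),
                             trueLog2FC = fc, nPlanted = 3,
                             plantedCondition = "stim", seed = 4)
    expect_length(sets, 10)
    expect_equal(attr(sets, "planted"), sprintf("planted%02d", 1:3))
    upFrac <- vapply(sets, function(s) mean(s %in% prots[1:30]), 0)
    expect_gt(mean(upFrac[1:3]), mean(upFrac[4:10]))
})

test_that("immunoassay simulation recovers multipliers exactly in the noise-free limit", {
    cfg <- simulationConfig(nDonors = 5, seed = 9)
    sim <- simulateImmunoassay(cfg, analytes = c("IL6", "VEGF"),
                               multipliers = c(baseline = 1, healthy = 2,
                                               traumatic = 1, degenerative = 3,
                                               IL1b = 1),
                               noiseSD = 0, detectionLimit = 0)
    expect_true(all(sim$assay$detected))
    fc <- foldChange(sim$assay, sim$dna)
    expect_equal(unique(round(fc$fc[fc$condition == "healthy"], 10)), 2)
    expect_equal(unique(round(fc$fc[fc$condition == "degenerative"], 10)), 3)
    expect_error(simulateImmunoassay(cfg, analytes = character()),
                 "non-empty")
})
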