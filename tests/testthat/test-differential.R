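.noiseFreeSim <- function(effects = c(0, 1, -1), seed = 31) {
    conds <- c("baseline", "healthy", "traumatic", "degenerative", "IL1b")
    fc <- matrix(0, length(effects), length(conds),
                 dimnames = list(NULL, conds))
    for (cc in setdiff(conds, "baseline")) fc[, cc] <- effects
    simulatePeptideTable(simulationConfig(
        nDonors = 4, nProteins = length(effects), trueLog2FC = fc,
        donorSD = 0, noiseSD = 0, missingMcarRate = 0,
        missingMnarScale = 0, seed = seed))
}

test_that("noise-free effects (0, +1, -1) are recovered exactly", {
    sim <- .noiseFreeSim()
    eff <- as.data.frame(runDifferential(sim$experiment,
                                         assayName = "intensity"))
    truth <- sim$truth$log2fc
    for (i in seq_len(nrow(eff)))
        expect_equal(eff$log2fc[i],
                     truth[eff$protein[i], eff$condition[i]],
                     tolerance = 1e-6)
})

test_that("estimates are invariant to sample order and to the normalization location", {
    sim <- simulatePeptideTable(simulationConfig(nProteins = 6L, seed = 41))
    flt <- applyQuantFilters(sim$experiment)$experiment
    base <- runDifferential(normalizeIntensities(flt))

    perm <- sample(ncol(flt))
    shuffled <- PeptideExperiment(intensityMatrix(flt)[, perm],
                                  peptideSequences(flt), proteinGroups(flt),
                                  design = sampleDesign(flt)[perm, ],
                                  reference = "baseline")
    permEff <- runDifferential(normalizeIntensities(shuffled))
    expect_equal(as.data.frame(base)[, c("protein", "condition", "log2fc", "p")],
                 as.data.frame(permEff)[, c("protein", "condition", "log2fc", "p")],
                 tolerance = 1e-8)

    noLoc <- runDifferential(normalizeIntensities(flt, addLocation = FALSE))
    expect_equal(base$log2fc, noLoc$log2fc, tolerance = 1e-8)
    expect_equal(base$p, noLoc$p, tolerance = 1e-8)
})

test_that("swapping reference and condition labels negates the contrast", {
    design <- toyDesign(nDonors = 6, conditions = c("baseline", "stim"))
    set.seed(7)
    m <- matrix(2^(rnorm(8 * nrow(design), 24, 1) +
                   rep(c(0, 1.2), each = 6)[match(design$condition,
                                                  c("baseline", "stim"))]),
                8, nrow(design), dimnames = list(NULL, design$sample))
    pe <- PeptideExperiment(m, sprintf("PEP%d", 1:8),
                            rep(c("PA", "PB"), each = 4),
                            design = design, reference = "baseline")
    fwd <- runDifferential(normalizeIntensities(pe))
    swapped <- design
    swapped$condition <- ifelse(design$condition == "baseline",
                                "stim", "baseline")
    peRev <- PeptideExperiment(m, sprintf("PEP%d", 1:8),
                               rep(c("PA", "PB"), each = 4),
                               design = swapped, reference = "baseline")
    rev <- runDifferential(normalizeIntensities(peRev))
    expect_equal(fwd$log2fc, -rev$log2fc, tolerance = 1e-8)
})

test_that("zero-variance data returns log2fc 0 and p 1 by convention", {
    design <- toyDesign(nDonors = 3)
    m <- matrix(1024, 2, nrow(design), dimnames = list(NULL, design$sample))
    res <- fitProtein(log2(m), design, "baseline")
    expect_equal(res$log2fc, 0)
    expect_equal(res$p, 1)
    expect_equal(res$fitNote, "degenerate")
})

test_that("a simulated effect of +2 is recovered within its standard error", {
    conds <- c("baseline", "healthy", "traumatic", "degenerative", "IL1b")
    fc <- matrix(0, 1, 5, dimnames = list(NULL, conds))
    fc[, "traumatic"] <- 2
    sim <- simulatePeptideTable(simulationConfig(
        nProteins = 1L, meanPeptides = 6, trueLog2FC = fc, donorSD = 0.3,
        noiseSD = 0.4, missingMcarRate = 0, missingMnarScale = 0,
        seed = 55))
    eff <- as.data.frame(runDifferential(sim$experiment,
                                         assayName = "intensity"))
    tr <- eff[eff$condition == "traumatic", ]
    expect_lt(abs(tr$log2fc - 2), 3 * tr$se)
    expect_lt(tr$p, 0.001)
    expect_true(tr$fitNote %in% c("full", "reduced", "ols_fallback"))
})

test_that("significance selection applies the inclusive boundary and matches a brute-force predicate", {
    eff <- data.frame(
        protein = c("A", "B", "C", "D"),
        condition = "stim",
        log2fc = c(1.5, 1.49, -1.8, 2.4),
        se = 0.1, df = 10,
        p = c(0.049, 0.001, 0.01, 0.2),
        q = c(0.08, 0.004, 0.02, 0.3),
        nPeptides = 2, fitNote = "full")
    sel <- selectSignificant(eff, significanceRule())
    expect_setequal(sel$sets$stim, c("A", "C"))   # 1.5/0.049 in; 1.49 out
    selPos <- selectSignificant(eff, significanceRule(useAbsolute = FALSE))
    expect_setequal(selPos$sets$stim, "A")
    selStrict <- selectSignificant(eff, significanceRule(strict = TRUE))
    expect_setequal(selStrict$sets$stim, "C")

    set.seed(8)
    rnd <- data.frame(protein = sprintf("P%03d", 1:300),
                      condition = sample(c("x", "y"), 300, TRUE),
                      log2fc = rnorm(300, 0, 1.5),
                      p = runif(300), q = runif(300))
    rule <- significanceRule(alpha = 0.07, fcThreshold = 1.2)
    sel2 <- selectSignificant(rnd, rule)
    want <- rnd$protein[rnd$p < 0.07 & abs(rnd$log2fc) >= 1.2 &
                        rnd$condition == "x"]
    expect_setequal(sel2$sets$x, want)
})

test_that("BH adjustment is computed within each contrast", {
    sim <- simulatePeptideTable(simulationConfig(nProteins = 8L, seed = 77))
    eff <- as.data.frame(runDifferential(normalizeIntensities(
        applyQuantFilters(sim$experiment)$experiment)))
    for (cc in unique(eff$condition)) {
        sub <- eff[eff$condition == cc, ]
        expect_equal(sub$q, p.adjust(sub$p, "BH"))
    }
})

test_that("inestimable proteins are reported, not fatal", {
    design <- toyDesign(nDonors = 3)
    m <- matrix(2^rnorm(4 * nrow(design), 24), 4, nrow(design),
                dimnames = list(NULL, design$sample))
    m[3:4, design$condition != "baseline"] <- NA  # PB observed only at baseline
    pe <- PeptideExperiment(m, sprintf("PEP%d", 1:4),
                            rep(c("PA", "PB"), each = 2),
                            design = design, reference = "baseline")
    res <- runDifferential(normalizeIntensities(pe))
    expect_setequal(unique(res$protein), "PA")
    expect_true("PB" %in% names(S4Vectors::metadata(res)$problems))
})
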