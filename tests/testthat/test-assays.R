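test_that("LDH cytotoxicity maps the controls to 0% and 100% and is affine-invariant", {
    expect_equal(ldhCytotoxicity(0.2, neg = 0.2, pos = 1.0), 0)
    expect_equal(ldhCytotoxicity(1.0, neg = 0.2, pos = 1.0), 100)
    expect_equal(ldhCytotoxicity(0.6, neg = 0.2, pos = 1.0), 50)
    expect_equal(ldhCytotoxicity(0.6 + 3, neg = 3.2, pos = 4.0), 50)
    expect_error(ldhCytotoxicity(0.5, neg = 0.3, pos = 0.3), "undefined")
})

test_that("fold changes are DNA-normalized per-donor baseline ratios", {
    assay <- data.frame(
        analyte = "IL6",
        sample = c("d1_base", "d1_stim", "d2_base", "d2_stim"),
        donor = c("d1", "d1", "d2", "d2"),
        condition = c("baseline", "stim", "baseline", "stim"),
        concentration = c(100, 200, 50, 50),
        detected = TRUE)
    dna <- data.frame(sample = assay$sample, dna = 1)
    fc <- foldChange(assay, dna)
    expect_equal(fc$fc, c(2, 1))
    # doubling concentration doubles fc; DNA scale change cancels
    assay2 <- assay; assay2$concentration <- assay$concentration * 7
    expect_equal(foldChange(assay2, dna)$fc, c(2, 1))
    dna2 <- dna; dna2$dna <- 0.25
    expect_equal(foldChange(assay, dna2)$fc, c(2, 1))
    # per-sample DNA enters the ratio
    dna3 <- dna; dna3$dna <- c(1, 2, 1, 1)
    expect_equal(foldChange(assay, dna3)$fc, c(1, 1))
    expect_error(foldChange(assay, data.frame(sample = dna$sample, dna = 0)),
                 "DNA")
})

test_that("undetected values exclude donors and drop saturatedly-missing analytes", {
    assay <- data.frame(
        analyte = rep(c("A", "B"), each = 4),
        sample = rep(c("d1_base", "d1_stim", "d2_base", "d2_stim"), 2),
        donor = rep(c("d1", "d1", "d2", "d2"), 2),
        condition = rep(c("baseline", "stim"), 4),
        concentration = c(10, 30, 10, 20, 1, 1, 1, 1),
        detected = c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE, TRUE))
    dna <- data.frame(sample = unique(assay$sample), dna = 1)
    fc <- foldChange(assay, dna, dropUndetectedFrac = 0.75)
    expect_equal(attr(fc, "droppedAnalytes"), "B")
    expect_equal(attr(fc, "excludedDonors"), "A/d2")
    expect_equal(fc$fc, 3)
})

test_that("the D'Agostino-Pearson omnibus matches reference values", {
    # frozen oracle values from an independent implementation of the
    # K^2 statistic (scipy.stats.normaltest)
    x1 <- c(0.304717, -1.039984, 0.750451, 0.940565, -1.951035, -1.30218,
            0.12784, -0.316243, -0.016801, -0.853044, 0.879398, 0.777792,
            0.066031, 1.127241, 0.467509, -0.859292, 0.368751, -0.958883,
            0.87845, -0.049926, -0.184862, -0.68093, 1.222541, -0.154529,
            -0.428328, -0.352134, 0.532309, 0.365444, 0.412733, 0.430821)
    x2 <- c(8.513453, 0.666034, 0.59915, 0.443183, 1.851469, 3.092477,
            0.892305, 0.431643, 0.438462, 1.916677, 2.102767, 1.721428,
            0.514011, 1.261323, 1.123766, 1.244444, 2.390324, 1.250565,
            1.971734, 1.069915, 1.335251, 1.880031, 0.232898, 0.726388,
            0.624769)
    r1 <- dagostinoTest(x1)
    expect_equal(r1$statistic, 1.9577817476, tolerance = 1e-9)
    expect_equal(r1$p.value, 0.3757275971, tolerance = 1e-8)
    r2 <- dagostinoTest(x2)
    expect_equal(r2$statistic, 45.4410364529, tolerance = 1e-9)
    expect_equal(r2$p.value, 1e-10, tolerance = 1)
    expect_error(dagostinoTest(rnorm(5)), "n >= 8")
})

test_that("the normality gate routes Gaussian data to ANOVA and skewed data to Kruskal-Wallis", {
    set.seed(14)
    g <- rep(c("a", "b", "c"), each = 40)
    gauss <- rnorm(120)
    rg <- gatedTest(gauss, g)
    expect_equal(rg$test, "anova")
    lnorm <- rlnorm(120, 0, 1.5)
    rl <- gatedTest(lnorm, g)
    expect_equal(rl$test, "kruskal")
    expect_true(any(rl$normality$reject))
})

test_that("small groups are skipped and constant data returns p = 1", {
    set.seed(2)
    vals <- c(rnorm(5), rnorm(5), 1, 2)
    grp <- c(rep("a", 5), rep("b", 5), "tiny", "tiny")
    r <- gatedTest(vals, grp)
    expect_named(r$skippedGroups, "tiny")
    expect_error(gatedTest(c(1, 2, 1, 2), c("a", "a", "b", "b")),
                 ">= 2 groups")
    rc <- gatedTest(rep(5, 12), rep(c("a", "b"), each = 6))
    expect_equal(rc$test, "none")
    expect_equal(rc$p.value, 1)
    expect_false(rc$significant)
    expect_true(all(rc$normality$p[!is.na(rc$normality$p)] == 1 |
                    is.na(rc$normality$p)))
})

test_that("per-analyte gated results summarize simulated fold changes", {
    cfg <- simulationConfig(nDonors = 9, seed = 3)
    sim <- simulateImmunoassay(cfg, c("IL6", "MCP1"),
                               multipliers = c(baseline = 1, healthy = 1,
                                               traumatic = 4, degenerative = 4,
                                               IL1b = 8),
                               noiseSD = 0.2)
    fc <- foldChange(sim$assay, sim$dna)
    res <- assayResults(fc)
    expect_setequal(res$analyte, c("IL6", "MCP1"))
    expect_true(all(res$test %in% c("anova", "kruskal")))
    expect_true(all(res$significant))
})
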