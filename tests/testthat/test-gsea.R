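.rankedToy <- function() data.frame(id = paste0("g", 1:6),
                                    score = c(3, 2, 1, -1, -2, -3))

test_that("a set spanning the whole list has ES exactly 1", {
    r <- .rankedToy()
    es <- enrichmentScore(r, r$id)
    expect_equal(es$es, 1)
})

test_that("the hand-executed running sum gives ES 0.75 for {g1, g4}", {
    es <- enrichmentScore(.rankedToy(), c("g1", "g4"))
    expect_equal(es$es, 0.75)
    expect_equal(es$runningSum,
                 c(0.75, 0.5, 0.25, 0.5, 0.25, 0), tolerance = 1e-12)
    expect_equal(es$leadingEdge, "g1")
})

test_that("score negation plus list reversal negates the ES", {
    for (s in 1:20) {
        set.seed(s)
        n <- sample(8:40, 1)
        r <- data.frame(id = sprintf("g%02d", 1:n), score = rnorm(n))
        members <- sample(r$id, sample(2:(n - 1), 1))
        es1 <- enrichmentScore(r, members)$es
        r2 <- data.frame(id = r$id, score = -r$score)
        es2 <- enrichmentScore(r2, members)$es
        expect_equal(abs(es2), abs(es1), tolerance = 1e-12)
        # exact mirror-symmetric ties (max == -min) may resolve to either
        # sign; otherwise the sign must flip
        expect_true(min(abs(es2 + es1), abs(es2 - es1)) < 1e-12)
    }
})

test_that("vectorized ES matches a literal step-by-step walk on random lists", {
    for (s in 1:25) {
        set.seed(100 + s)
        n <- sample(6:50, 1)
        r <- data.frame(id = sprintf("g%02d", 1:n), score = rnorm(n))
        r <- r[order(-r$score, r$id), ]
        members <- sample(r$id, sample(2:5, 1))
        got <- enrichmentScore(r, members)$es
        want <- bruteES(r$score, r$id %in% members)
        expect_equal(got, want, tolerance = 1e-12)
    }
})

test_that("ES agrees with fgsea's statistic on random inputs", {
    for (s in 1:10) {
        set.seed(200 + s)
        n <- 30
        stats <- sort(rnorm(n), decreasing = TRUE)
        names(stats) <- sprintf("g%02d", 1:n)
        r <- data.frame(id = names(stats), score = unname(stats))
        members <- sample(names(stats), 6)
        got <- enrichmentScore(r, members)$es
        want <- fgsea::calcGseaStat(stats, which(names(stats) %in% members),
                                    gseaParam = 1)
        expect_equal(got, want, tolerance = 1e-10)
    }
})

test_that("permutation p matches exact enumeration over all member placements", {
    r <- .rankedToy()
    collection <- list(S = c("g1", "g4"))
    cfg <- gseaConfig(minSetSize = 1, nPerm = 1000, seed = 3)
    res <- gsea(r, collection, cfg)   # C(6,2)=15 <= nPerm: exhaustive
    esObs <- res$es[1]
    expect_equal(res$p[1], brutePermP(r$score, esObs, 2))
})

test_that("the GSEA stage is deterministic given its seed and honours the size filter", {
    set.seed(9)
    n <- 80
    r <- data.frame(id = sprintf("g%02d", 1:n), score = rnorm(n))
    sets <- list(big = sample(r$id, 20), small = sample(r$id, 3),
                 gone = c("zz1", "zz2"))
    cfg <- gseaConfig(minSetSize = 10, nPerm = 200, seed = 42)
    a <- gsea(r, sets, cfg)
    b <- gsea(r, sets, cfg)
    expect_identical(as.data.frame(a), as.data.frame(b))
    expect_equal(a$set, "big")
    skipped <- S4Vectors::metadata(a)$skipped
    expect_match(skipped[["gone"]], "empty intersection")
    expect_match(skipped[["small"]], "size 3")
    expect_true(abs(a$es[1]) <= 1)
    expect_equal(sign(a$nes[1]), sign(a$es[1]))
})

test_that("planted sets score positive NES and outrank uniform sets", {
    hits <- 0
    for (s in 1:15) {
        set.seed(300 + s)
        prots <- sprintf("PROT%03d", 1:150)
        fc <- matrix(0, 150, 2, dimnames = list(prots, c("baseline", "stim")))
        fc[1:40, "stim"] <- 2
        sets <- simulateGeneSets(prots, nSets = 8, setSizeRange = c(10, 20),
                                 trueLog2FC = fc, nPlanted = 2,
                                 plantedCondition = "stim", seed = 300 + s)
        score <- fc[, "stim"] + rnorm(150, 0, 0.5)
        r <- data.frame(id = prots, score = score)
        res <- as.data.frame(gsea(r, sets, gseaConfig(nPerm = 200,
                                                      seed = s)))
        planted <- res$nes[res$set %in% attr(sets, "planted")]
        uniform <- res$nes[!res$set %in% attr(sets, "planted")]
        if (mean(planted) > mean(uniform)) hits <- hits + 1
    }
    expect_gte(hits, 13)
})

test_that("top terms are ordered by NES with deterministic tie-breaks", {
    res <- S4Vectors::DataFrame(
        set = c("a", "b", "c", "d", "e"),
        size = 10L, es = c(0.5, 0.6, 0.6, -0.5, -0.7),
        nes = c(1.5, 2.0, 2.0, -1.4, -2.2),
        p = c(0.001, 0.002, 0.001, 0.003, 0.5),
        fdr = 0.01, leadingEdge = "")
    top <- as.data.frame(topTerms(res, k = 2, pThreshold = 0.01))
    expect_equal(top$set[top$direction == "up"], c("b", "c"))
    expect_equal(top$set[top$direction == "down"], "d")  # e fails p; k trims
    all3 <- as.data.frame(topTerms(res, k = 10, pThreshold = 0.01))
    expect_equal(sum(all3$direction == "up"), 3)  # k larger than available
})

test_that("ranking is by descending fold change with id tie-break", {
    eff <- data.frame(protein = c("B", "A", "C"), condition = "x",
                      log2fc = c(1, 1, -2), p = 0.1, q = 0.1)
    r <- rankProteins(eff, "x")
    expect_equal(r$id, c("A", "B", "C"))
    expect_error(rankProteins(eff, "nope"), "no effects")
})
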