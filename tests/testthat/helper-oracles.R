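# Independent brute-force oracles and small builders shared across tests.

# literal per-peptide re-evaluation of the occupancy rule
bruteOccupancy <- function(obs, condition, minFraction = 0.5) {
    apply(obs, 1, function(r) {
        for (cc in unique(condition)) {
            idx <- condition == cc
            if (sum(r[idx]) > minFraction * sum(idx)) return(TRUE)
        }
        FALSE
    })
}

# literal step-by-step running-sum walk (plain loop, no vectorization);
# near-ties between the extrema resolve positive, like the implementation
bruteES <- function(scores, hit, weight = 1, tol = 1e-9) {
    N <- length(scores)
    k <- sum(hit)
    w <- abs(scores)^weight
    W <- sum(w[hit])
    if (W == 0) { w[hit] <- 1; W <- k }
    rs <- 0; lo <- 0; hi <- 0
    for (i in seq_len(N)) {
        rs <- rs + if (hit[i]) w[i] / W else -1 / (N - k)
        if (rs > hi) hi <- rs
        if (rs < lo) lo <- rs
    }
    if (hi >= -lo - tol) hi else lo
}

# exhaustive permutation p for a set of size k on a fixed score vector;
# ties are counted with a float tolerance (placements yielding the same
# rational ES differ at machine epsilon across summation orders)
brutePermP <- function(scores, esObs, k, weight = 1, tol = 1e-12) {
    N <- length(scores)
    perms <- utils::combn(N, k)
    es <- apply(perms, 2, function(pos) {
        hit <- seq_len(N) %in% pos
        bruteES(scores, hit, weight)
    })
    if (esObs >= 0) sum(es >= esObs - tol) / sum(es >= 0)
    else sum(es <= esObs + tol) / sum(es < 0)
}

# small two-batch repeated-measures design
toyDesign <- function(nDonors = 4,
                      conditions = c("baseline", "stim"),
                      batch = "b1") {
    d <- expand.grid(donor = sprintf("D%02d", seq_len(nDonors)),
                     condition = conditions, stringsAsFactors = FALSE)
    d$batch <- batch
    d$sample <- paste(d$donor, d$condition, sep = "_")
    d[, c("sample", "donor", "condition", "batch")]
}

# random PeptideExperiment over a given design
randomPeptideTable <- function(design, nProteins = 10, pepPerProt = 3,
                               missingRate = 0.3, seed = 1) {
    set.seed(seed)
    np <- nProteins * pepPerProt
    m <- matrix(2^rnorm(np * nrow(design), 24, 1.5), np, nrow(design),
                dimnames = list(NULL, design$sample))
    m[matrix(runif(length(m)) < missingRate, nrow(m))] <- NA
    # keep at least 2 observed distinct values per sample
    for (j in seq_len(ncol(m))) {
        miss <- which(is.na(m[, j]))
        if (length(miss) > nrow(m) - 2)
            m[miss[1:2], j] <- 2^rnorm(2, 24, 1.5)
    }
    PeptideExperiment(
        m, sequence = sprintf("PEP%03d", seq_len(np)),
        proteinGroup = sprintf("PR%02d", rep(seq_len(nProteins),
                                             each = pepPerProt)),
        design = design, reference = design$condition[1])
}
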