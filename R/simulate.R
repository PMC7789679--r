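#' Build a simulation configuration
#'
#' Defaults encode the repeated-measures secretome study design the package
#' targets: 12 donors, five stimulation conditions with `baseline` as the
#' reference, and two acquisition batches. The reference condition is
#' measured in every batch (each donor contributes one baseline sample per
#' batch) so that batch differences are estimable; with the default
#' assignment this yields 48 samples in batch1 (baseline, traumatic,
#' degenerative, IL1b) and 24 in batch2 (baseline, healthy).
#'
#' @param nDonors number of donors (default 12).
#' @param conditions condition labels, reference first.
#' @param reference reference condition (true log2FC identically 0).
#' @param batchAssignment named character mapping every non-reference
#'   condition to one batch id.
#' @param nProteins number of simulated proteins.
#' @param meanPeptides mean peptides per protein; counts are drawn as
#'   `1 + rpois(meanPeptides - 1)` (min 1, mean `meanPeptides`).
#' @param trueLog2FC `nProteins x length(conditions)` matrix of true
#'   condition effects (log2 units); default all zero (a null experiment).
#'   The reference column must be 0.
#' @param donorSD,peptideOffsetSD,noiseSD standard deviations (log2 units)
#'   of the random donor intercepts, peptide ionization offsets, and
#'   residual noise.
#' @param batchShift named numeric, additive log2 shift per batch.
#' @param baseRange protein base log2 abundances drawn uniformly over this
#'   interval (default 22..27, about 5 log2 units of dynamic range so the
#'   occupancy filter sees a realistic intensity spread).
#' @param missingMcarRate per-cell probability of missing-completely-at-random
#'   dropout.
#' @param missingMnarScale logistic slope of intensity-dependent dropout;
#'   0 disables the MNAR mechanism.
#' @param missingMnarMid logistic midpoint on the log2 intensity scale;
#'   `NA` (default) uses the 10th percentile of the simulated intensities.
#' @param seed integer seed; identical config + seed reproduces identical
#'   output, byte for byte.
#' @return A [SimulationConfig-class] object.
#' @export
simulationConfig <- function(nDonors = 12L,
                             conditions = c("baseline", "healthy", "traumatic",
                                            "degenerative", "IL1b"),
                             reference = conditions[1],
                             batchAssignment = c(healthy = "batch2",
                                                 traumatic = "batch1",
                                                 degenerative = "batch1",
                                                 IL1b = "batch1"),
                             nProteins = 50L, meanPeptides = 4,
                             trueLog2FC = NULL,
                             donorSD = 0.3, peptideOffsetSD = 1.0,
                             noiseSD = 0.4,
                             batchShift = c(batch1 = 0, batch2 = 0.5),
                             baseRange = c(22, 27),
                             missingMcarRate = 0.05, missingMnarScale = 0.6,
                             missingMnarMid = NA_real_, seed = 1L) {
    nDonors <- as.integer(nDonors); nProteins <- as.integer(nProteins)
    if (is.na(nDonors) || nDonors < 1L || is.na(nProteins) || nProteins < 1L)
        stop("nDonors and nProteins must be positive integers")
    if (is.null(trueLog2FC))
        trueLog2FC <- matrix(0, nProteins, length(conditions),
                             dimnames = list(NULL, conditions))
    if (is.null(colnames(trueLog2FC)))
        colnames(trueLog2FC) <- conditions
    unknown <- setdiff(colnames(trueLog2FC), conditions)
    if (length(unknown))
        stop("trueLog2FC has unknown condition(s): ",
             paste(unknown, collapse = ", "))
    trueLog2FC <- trueLog2FC[, conditions, drop = FALSE]
    batches <- sort(unique(batchAssignment))
    if (!all(names(batchShift) %in% batches))
        batchShift <- batchShift[intersect(names(batchShift), batches)]
    miss <- setdiff(batches, names(batchShift))
    if (length(miss)) batchShift[miss] <- 0
    new("SimulationConfig", nDonors = nDonors, conditions = conditions,
        reference = reference, batchAssignment = batchAssignment,
        nProteins = nProteins, meanPeptides = meanPeptides,
        trueLog2FC = trueLog2FC, donorSD = donorSD,
        peptideOffsetSD = peptideOffsetSD, noiseSD = noiseSD,
        batchShift = batchShift[batches], baseRange = baseRange,
        missingMcarRate = missingMcarRate,
        missingMnarScale = missingMnarScale,
        missingMnarMid = missingMnarMid, seed = as.integer(seed))
}

.simDesign <- function(config) {
    batches <- sort(unique(config@batchAssignment))
    rows <- list()
    for (b in batches) {
        conds <- c(config@reference,
                   names(config@batchAssignment)[config@batchAssignment == b])
        for (cc in conds)
            rows[[length(rows) + 1L]] <- data.frame(
                donor = sprintf("D%02d", seq_len(config@nDonors)),
                condition = cc, batch = b)
    }
    d <- do.call(rbind, rows)
    d$sample <- sprintf("%s_%s_%s", d$donor, d$condition, d$batch)
    d[, c("sample", "donor", "condition", "batch")]
}

#' Simulate a peptide-level LFQ experiment with known ground truth
#'
#' Generates log2 peptide intensities under the additive model
#' `protein base + peptide offset + donor effect + batch shift +
#' true log2FC(protein, condition) + noise`, exponentiates to the raw
#' scale, then removes cells completely at random (MCAR) and by
#' intensity-dependent logistic dropout (MNAR; dropout probability
#' decreasing in intensity). Donor effects are drawn once per donor and
#' shared across all of that donor's samples, reproducing the
#' repeated-measures structure the downstream mixed model assumes.
#'
#' @param config a [SimulationConfig-class] from [simulationConfig()].
#' @return A list with elements
#'   \describe{
#'     \item{experiment}{a [PeptideExperiment-class] with design attached,}
#'     \item{truth}{ground truth: `log2fc` (protein x condition matrix),
#'       `missing` (logical matrix matching the peptide table),
#'       `donorEffects`, `peptideOffsets`, `base`, `proteinOfPeptide`,}
#'     \item{config}{the input config.}
#'   }
#' @examples
#' sim <- simulatePeptideTable(simulationConfig(nProteins = 5, seed = 3))
#' sim$experiment
#' @export
simulatePeptideTable <- function(config) {
    stopifnot(is(config, "SimulationConfig"))
    validObject(config)
    set.seed(config@seed)
    design <- .simDesign(config)
    ns <- nrow(design)
    npep <- 1L + stats::rpois(config@nProteins, max(config@meanPeptides - 1, 0))
    prot <- sprintf("PROT%04d", seq_len(config@nProteins))
    protOf <- rep(seq_len(config@nProteins), npep)
    pepSeq <- sprintf("PEP%04d_%02d", protOf,
                      unlist(lapply(npep, seq_len), use.names = FALSE))
    base <- stats::runif(config@nProteins, config@baseRange[1], config@baseRange[2])
    off <- stats::rnorm(length(protOf), 0, config@peptideOffsetSD)
    donors <- sprintf("D%02d", seq_len(config@nDonors))
    donorEff <- stats::setNames(stats::rnorm(config@nDonors, 0, config@donorSD),
                                donors)
    sampleEff <- donorEff[design$donor] +
        config@batchShift[design$batch]
    condFC <- config@trueLog2FC[protOf, design$condition, drop = FALSE]
    log2x <- (base[protOf] + off) +
        matrix(sampleEff, length(protOf), ns, byrow = TRUE) + condFC
    if (config@noiseSD > 0)
        log2x <- log2x + matrix(stats::rnorm(length(log2x), 0, config@noiseSD),
                                nrow(log2x), ns)
    missing <- matrix(FALSE, nrow(log2x), ns)
    if (config@missingMcarRate > 0)
        missing <- missing |
            matrix(stats::runif(length(log2x)) < config@missingMcarRate,
                   nrow(log2x), ns)
    if (config@missingMnarScale > 0) {
        mid <- config@missingMnarMid
        if (is.na(mid)) mid <- stats::quantile(log2x, 0.10, names = FALSE)
        pdrop <- stats::plogis(config@missingMnarScale * (mid - log2x))
        missing <- missing |
            matrix(stats::runif(length(log2x)) < pdrop, nrow(log2x), ns)
    }
    intensity <- 2^log2x
    intensity[missing] <- NA_real_
    colnames(intensity) <- design$sample
    pe <- PeptideExperiment(intensity, sequence = pepSeq,
                            proteinGroup = prot[protOf], design = design,
                            reference = config@reference)
    truth <- list(log2fc = `rownames<-`(config@trueLog2FC, prot),
                  log2complete = `colnames<-`(log2x, design$sample),
                  missing = missing, donorEffects = donorEff,
                  peptideOffsets = off, base = stats::setNames(base, prot),
                  proteinOfPeptide = prot[protOf])
    list(experiment = pe, truth = truth, config = config)
}

#' Simulate gene-set collections, optionally with planted enrichment
#'
#' Non-planted sets are drawn uniformly from the protein universe. Planted
#' sets draw their members preferentially (9:1 weighting) from proteins
#' whose true log2 fold change in `plantedCondition` has the requested
#' sign, so that downstream preranked enrichment should recover them.
#'
#' @param proteins character vector of protein ids (the universe).
#' @param nSets number of sets to generate.
#' @param setSizeRange integer length-2, min/max set size (min >= 2).
#' @param trueLog2FC optional protein x condition matrix (rownames =
#'   protein ids); required when `nPlanted > 0`.
#' @param nPlanted number of planted-enriched sets (first `nPlanted` sets).
#' @param plantedCondition condition whose effects drive the planting.
#' @param plantedDirection +1 (enrich among upregulated) or -1.
#' @param seed integer seed.
#' @return Named list of character member vectors; attributes `planted`
#'   (names of planted sets) and `description` (named character).
#' @export
simulateGeneSets <- function(proteins, nSets, setSizeRange = c(10, 30),
                             trueLog2FC = NULL, nPlanted = 0,
                             plantedCondition = NULL, plantedDirection = 1,
                             seed = 1L) {
    if (nSets == 0) {
        out <- stats::setNames(list(), character())
        attr(out, "planted") <- character()
        return(out)
    }
    if (setSizeRange[1] < 2)
        stop("set sizes must be >= 2")
    if (setSizeRange[2] > length(proteins))
        stop("max set size exceeds the protein universe (",
             length(proteins), ")")
    if (nPlanted > 0 && (is.null(trueLog2FC) || is.null(plantedCondition)))
        stop("planting requires trueLog2FC and plantedCondition")
    set.seed(as.integer(seed))
    sizes <- sample(seq(setSizeRange[1], setSizeRange[2]), nSets,
                    replace = TRUE)
    nm <- c(sprintf("planted%02d", seq_len(nPlanted)),
            sprintf("set%03d", seq_len(nSets - nPlanted)))
    sets <- vector("list", nSets)
    for (i in seq_len(nSets)) {
        if (i <= nPlanted) {
            fc <- trueLog2FC[proteins, plantedCondition]
            w <- ifelse(plantedDirection * fc > 0, 9, 1)
            sets[[i]] <- sort(sample(proteins, sizes[i], prob = w))
        } else {
            sets[[i]] <- sort(sample(proteins, sizes[i]))
        }
    }
    names(sets) <- nm
    attr(sets, "planted") <- nm[seq_len(nPlanted)]
    attr(sets, "description") <- stats::setNames(
        ifelse(seq_len(nSets) <= nPlanted, "planted", "uniform"), nm)
    sets
}

#' Simulate an immunoassay plate with per-sample DNA content
#'
#' Per donor and condition, analyte concentrations (pg/mL) are generated as
#' `base concentration x condition multiplier x DNA content x log-normal
#' noise`, so that DNA normalization followed by the per-donor baseline
#' ratio recovers the multiplier exactly in the noise-free limit.
#' Concentrations below `detectionLimit` are flagged undetected.
#'
#' @param config a [SimulationConfig-class] (supplies donors, conditions,
#'   reference and, by default, the seed).
#' @param analytes non-empty character vector of analyte names.
#' @param multipliers analyte x condition matrix of true fold changes vs
#'   the reference (default all 1); a named vector per condition is
#'   recycled across analytes.
#' @param noiseSD sdlog of the multiplicative log-normal noise.
#' @param baseConcRange range of per-analyte baseline concentrations.
#' @param dnaRange range of per-sample DNA content (arbitrary units > 0).
#' @param detectionLimit lower limit of detection (same units as
#'   concentration); 0 means everything is detected.
#' @param seed integer seed.
#' @return list with `assay` (data.frame: analyte, sample, donor,
#'   condition, concentration, detected) and `dna` (sample, dna).
#' @export
simulateImmunoassay <- function(config, analytes, multipliers = NULL,
                                noiseSD = 0.25, baseConcRange = c(50, 5000),
                                dnaRange = c(0.5, 2), detectionLimit = 0,
                                seed = config@seed) {
    stopifnot(is(config, "SimulationConfig"))
    if (length(analytes) == 0) stop("analyte list must be non-empty")
    conds <- config@conditions
    if (is.null(multipliers))
        multipliers <- matrix(1, length(analytes), length(conds),
                              dimnames = list(analytes, conds))
    if (is.null(dim(multipliers)))
        multipliers <- matrix(rep(multipliers[conds], each = length(analytes)),
                              length(analytes), length(conds),
                              dimnames = list(analytes, conds))
    set.seed(as.integer(seed))
    donors <- sprintf("D%02d", seq_len(config@nDonors))
    grid <- expand.grid(donor = donors, condition = conds,
                        stringsAsFactors = FALSE)
    grid$sample <- paste(grid$donor, grid$condition, sep = "_")
    dna <- stats::runif(nrow(grid), dnaRange[1], dnaRange[2])
    names(dna) <- grid$sample
    base <- stats::runif(length(analytes), baseConcRange[1], baseConcRange[2])
    names(base) <- analytes
    rows <- expand.grid(analyte = analytes, i = seq_len(nrow(grid)),
                        stringsAsFactors = FALSE)
    noise <- if (noiseSD > 0)
        stats::rlnorm(nrow(rows), 0, noiseSD) else rep(1, nrow(rows))
    conc <- base[rows$analyte] *
        multipliers[cbind(rows$analyte, grid$condition[rows$i])] *
        dna[grid$sample[rows$i]] * noise
    assay <- data.frame(analyte = rows$analyte,
                        sample = grid$sample[rows$i],
                        donor = grid$donor[rows$i],
                        condition = grid$condition[rows$i],
                        concentration = unname(conc),
                        detected = unname(conc >= detectionLimit))
    list(assay = assay,
         dna = data.frame(sample = grid$sample, dna = unname(dna)))
}
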