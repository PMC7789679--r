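.stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
        stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE))
}

#' Run the full secretome quantification pipeline
#'
#' Fixed stage order: read/validate -> occupancy + two-peptide filters ->
#' rescaled z-score normalization -> per-protein mixed models vs the
#' reference -> significance selection -> preranked GSEA per contrast ->
#' set comparison and category composition -> write results. Re-running
#' with identical inputs and seeds reproduces byte-identical TSVs; every
#' output directory carries a `run_metadata.json` with the configuration
#' hash.
#'
#' @param peptides a [PeptideExperiment-class] or path to a peptide TSV
#'   (see [readPeptideTable()]).
#' @param design data.frame or path (see [readDesign()]); ignored when
#'   `peptides` already carries a design.
#' @param gmt named list of gene sets or GMT path; `NULL` skips GSEA.
#' @param categories named character protein -> category, or TSV path;
#'   `NULL` skips the category split.
#' @param reference reference condition label.
#' @param outDir output directory; `NULL` writes nothing.
#' @param significance a [significanceRule()].
#' @param gseaCfg a [gseaConfig()].
#' @param skipGsea,skipSets stage toggles.
#' @param minFraction,minPeptides,perBatchBaseline filter settings
#'   (see [filterPeptides()], [filterProteins()]).
#' @param addLocation see [normalizeIntensities()].
#' @param randomEffects see [fitProtein()].
#' @param dialect peptide-table dialect when `peptides` is a path.
#' @return list with `experiment`, `filterReport`, `effects`,
#'   `significant`, `gsea` (per-condition list), `partition`,
#'   `categories`, and `files` (paths written), invisibly.
#' @export
runPipeline <- function(peptides, design = NULL, gmt = NULL,
                        categories = NULL, reference = "baseline",
                        outDir = NULL,
                        significance = significanceRule(),
                        gseaCfg = gseaConfig(),
                        skipGsea = FALSE, skipSets = FALSE,
                        minFraction = 0.5, minPeptides = 2L,
                        perBatchBaseline = FALSE, addLocation = TRUE,
                        randomEffects = c("donor", "peptide"),
                        dialect = "maxquant") {
    pe <- .stage("read", {
        if (is.character(design)) design <- readDesign(design, reference)
        if (is.character(peptides))
            readPeptideTable(peptides, dialect, design = design,
                             reference = reference)
        else if (!is.null(design))
            PeptideExperiment(intensityMatrix(peptides),
                              peptideSequences(peptides),
                              proteinGroups(peptides), design = design,
                              reference = reference)
        else peptides
    })
    if (is.character(gmt) && length(gmt) == 1L && is.null(names(gmt)))
        gmt <- .stage("read", readGmt(gmt))
    if (is.character(categories) && length(categories) == 1L &&
        is.null(names(categories)))
        categories <- .stage("read", readCategoryMap(categories))
    flt <- .stage("filter",
        applyQuantFilters(pe, minFraction, minPeptides, perBatchBaseline))
    normed <- .stage("normalize",
        normalizeIntensities(flt$experiment, addLocation))
    effects <- .stage("model",
        runDifferential(normed, randomEffects = randomEffects))
    sig <- .stage("select", selectSignificant(effects, significance))
    gres <- NULL
    if (!skipGsea && !is.null(gmt)) {
        gres <- .stage("gsea", {
            conds <- unique(effects$condition)
            lapply(stats::setNames(conds, conds), function(cc)
                gsea(rankProteins(effects, cc), gmt, gseaCfg))
        })
    }
    part <- cats <- NULL
    if (!skipSets) {
        part <- .stage("sets", buildPartition(sig$sets))
        if (!is.null(categories))
            cats <- .stage("sets", categorize(sig$sets, categories))
    }
    files <- character()
    if (!is.null(outDir)) {
        files <- .stage("write", {
            tabs <- list(
                protein_effects = as.data.frame(effects),
                significant_membership = as.data.frame(sig$membership),
                normalization = normalizationTable(
                    normalizationParams(normed)))
            if (!is.null(cats)) tabs$categories <- cats
            if (!is.null(gres))
                for (cc in names(gres))
                    tabs[[paste0("gsea_", cc)]] <- as.data.frame(gres[[cc]])
            cfg <- list(reference = reference,
                        significance = unclass(significance),
                        gsea = unclass(gseaCfg),
                        minFraction = minFraction,
                        minPeptides = minPeptides,
                        perBatchBaseline = perBatchBaseline,
                        addLocation = addLocation,
                        randomEffects = randomEffects)
            f <- writeResults(tabs, outDir, config = cfg,
                              seed = gseaCfg$seed)
            f <- c(f, writeFilterReport(flt$report, outDir))
            if (!is.null(part)) f <- c(f, writePartition(part, outDir))
            f
        })
    }
    invisible(list(experiment = normed, filterReport = flt$report,
                   effects = effects, significant = sig, gsea = gres,
                   partition = part, categories = cats, files = files))
}

#' Simulation-based calibration and recovery study
#'
#' Runs the generator + pipeline loop the package's own guarantees rest
#' on: (1) a null experiment (all true effects 0) measuring the
#' per-protein type-I error of the mixed-model test; (2) a recovery
#' experiment with known effects measuring bias, RMSE, coverage of
#' +/- 2 SE intervals, and power at each effect size. All randomness
#' derives from `seed`.
#'
#' @param nNull proteins in the null experiment (0 skips it).
#' @param nRecovery proteins in the recovery experiment (0 skips it).
#' @param effects true log2 fold changes cycled over the
#'   protein x condition cells of the recovery experiment.
#' @param alpha significance level under test.
#' @param config base [simulationConfig()]; `nProteins`, `trueLog2FC` and
#'   `seed` are overridden per experiment.
#' @param normalize apply [normalizeIntensities()] before modelling
#'   (default `FALSE`: the generator contains no per-sample loading
#'   differences, so the study measures the estimator itself; the
#'   normalization contract is tested separately).
#' @param seed root seed.
#' @return list with `typeI` (rejection rate under the null; `NA` if
#'   skipped), `nNullTests`, and `recovery` (data.frame: effect, bias,
#'   rmse, coverage, power, n).
#' @export
runSimulationStudy <- function(nNull = 200, nRecovery = 100,
                               effects = c(-2, -1, 0, 1, 2),
                               alpha = 0.05,
                               config = simulationConfig(),
                               normalize = FALSE, seed = 1L) {
    seed <- as.integer(seed)
    typeI <- NA_real_; nNullTests <- 0L
    runOne <- function(n, fc, s) {
        cfg <- simulationConfig(
            nDonors = config@nDonors, conditions = config@conditions,
            reference = config@reference,
            batchAssignment = config@batchAssignment, nProteins = n,
            meanPeptides = config@meanPeptides, trueLog2FC = fc,
            donorSD = config@donorSD,
            peptideOffsetSD = config@peptideOffsetSD,
            noiseSD = config@noiseSD, batchShift = config@batchShift,
            baseRange = config@baseRange,
            missingMcarRate = config@missingMcarRate,
            missingMnarScale = config@missingMnarScale,
            missingMnarMid = config@missingMnarMid, seed = s)
        sim <- simulatePeptideTable(cfg)
        flt <- applyQuantFilters(sim$experiment)
        eff <- if (normalize)
            runDifferential(normalizeIntensities(flt$experiment))
        else runDifferential(flt$experiment, assayName = "intensity")
        list(effects = eff, truth = sim$truth)
    }
    if (nNull > 0) {
        r <- runOne(nNull, NULL, seed)
        typeI <- mean(r$effects$p < alpha, na.rm = TRUE)
        nNullTests <- sum(!is.na(r$effects$p))
    }
    recovery <- NULL
    if (nRecovery > 0) {
        conds <- config@conditions
        nonref <- setdiff(conds, config@reference)
        fc <- matrix(0, nRecovery, length(conds),
                     dimnames = list(NULL, conds))
        fc[, nonref] <- effects[
            (seq_len(nRecovery * length(nonref)) - 1) %% length(effects) + 1]
        r <- runOne(nRecovery, fc, seed + 1L)
        eff <- as.data.frame(r$effects)
        pidx <- match(eff$protein, rownames(r$truth$log2fc))
        eff$true <- r$truth$log2fc[cbind(pidx, match(eff$condition, conds))]
        eff <- eff[!is.na(eff$log2fc) & !is.na(eff$se), ]
        recovery <- do.call(rbind, lapply(sort(unique(eff$true)), function(tv) {
            sub <- eff[eff$true == tv, ]
            data.frame(effect = tv,
                       bias = mean(sub$log2fc - tv),
                       rmse = sqrt(mean((sub$log2fc - tv)^2)),
                       coverage = mean(abs(sub$log2fc - tv) <= 2 * sub$se),
                       power = mean(sub$p < alpha, na.rm = TRUE),
                       n = nrow(sub))
        }))
    }
    list(typeI = typeI, nNullTests = nNullTests, recovery = recovery,
         alpha = alpha, seed = seed)
}
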