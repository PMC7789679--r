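#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames rowData colData assay<-
NULL

#' PeptideExperiment: peptide-level LFQ intensities with sample design
#'
#' The central data container of the package. It extends
#' [SummarizedExperiment::SummarizedExperiment] with peptide rows
#' (`rowData` columns `sequence` and `proteinGroup`) and sample columns
#' (`colData` columns `donor`, `condition`, `batch`). Intensities live in
#' the `"intensity"` assay on the raw (linear) scale; missing measurements
#' are `NA`, never zero (zeros in input files are coerced to `NA` on read,
#' following the MaxQuant convention that an unobserved peptide ion is
#' reported as 0). After [normalizeIntensities()] a second assay
#' `"log2norm"` holds normalized log2 intensities.
#'
#' The reference (baseline) condition used for all fold-change contrasts is
#' stored in `metadata(x)$reference`.
#'
#' @slot .  inherits all slots from `SummarizedExperiment`.
#' @seealso [PeptideExperiment()] for construction,
#'   [filterPeptides()], [normalizeIntensities()], [runDifferential()].
#' @export
setClass("PeptideExperiment", contains = "SummarizedExperiment")

setValidity("PeptideExperiment", function(object) {
    msg <- character()
    rd <- rowData(object)
    if (!all(c("sequence", "proteinGroup") %in% colnames(rd)))
        msg <- c(msg, "rowData must contain 'sequence' and 'proteinGroup'")
    else {
        key <- paste(rd$sequence, rd$proteinGroup, sep = "\r")
        if (anyDuplicated(key))
            msg <- c(msg, sprintf(
                "duplicated (sequence, proteinGroup) pairs: %s",
                paste(unique(rd$sequence[duplicated(key)]), collapse = ", ")))
    }
    if (!"intensity" %in% assayNames(object))
        msg <- c(msg, "an 'intensity' assay is required")
    else {
        x <- assay(object, "intensity")
        if (any(x <= 0, na.rm = TRUE))
            msg <- c(msg, "intensities must be missing (NA) or > 0; coerce zeros to NA")
    }
    ref <- metadata(object)$reference
    if (!is.null(ref) && "condition" %in% colnames(colData(object))) {
        if (!ref %in% colData(object)$condition)
            msg <- c(msg, sprintf("reference condition '%s' absent from design", ref))
    }
    if (length(msg)) msg else TRUE
})

#' Peptide/protein filter report
#'
#' Bookkeeping for the occupancy and two-peptide filters: counts in/out at
#' both levels, a per-peptide pass flag with the condition that qualified
#' it, and a per-protein exclusion reason
#' (`"single_peptide"` or `"no_quantified_peptides"`).
#'
#' @slot nPeptidesIn,nPeptidesOut,nProteinsIn,nProteinsOut integer counts.
#' @slot peptideStatus `DataFrame` with columns `sequence`, `proteinGroup`,
#'   `retained`, `qualifyingCondition`.
#' @slot proteinStatus `DataFrame` with columns `proteinGroup`, `nPeptides`,
#'   `retained`, `reason`.
#' @export
setClass("FilterReport", representation(
    nPeptidesIn = "integer", nPeptidesOut = "integer",
    nProteinsIn = "integer", nProteinsOut = "integer",
    peptideStatus = "DataFrame", proteinStatus = "DataFrame"))

setValidity("FilterReport", function(object) {
    msg <- character()
    if (object@nPeptidesOut > object@nPeptidesIn)
        msg <- c(msg, "nPeptidesOut > nPeptidesIn")
    if (object@nProteinsOut > object@nProteinsIn)
        msg <- c(msg, "nProteinsOut > nProteinsIn")
    bad <- setdiff(object@proteinStatus$reason,
                   c(NA, "single_peptide", "no_quantified_peptides"))
    if (length(bad))
        msg <- c(msg, paste("unknown exclusion reason:", paste(bad, collapse = ", ")))
    if (length(msg)) msg else TRUE
})

#' Rescaled z-score normalization parameters
#'
#' Per-sample mean and SD of observed log2 intensities together with the
#' pooled location (mean of the per-sample means) and pooled scale (mean of
#' the per-sample SDs) used by the rescaled z-score transform.
#'
#' @slot sampleMean,sampleSD named numeric, one entry per sample.
#' @slot pooledMean,pooledSD numeric scalars.
#' @slot addLocation logical; whether the pooled location was re-added
#'   (see [normalizeIntensities()]).
#' @export
setClass("NormalizationParams", representation(
    sampleMean = "numeric", sampleSD = "numeric",
    pooledMean = "numeric", pooledSD = "numeric",
    addLocation = "logical"))

setValidity("NormalizationParams", function(object) {
    if (any(object@sampleSD <= 0))
        return(sprintf("zero/negative SD for sample(s): %s",
                       paste(names(object@sampleSD)[object@sampleSD <= 0],
                             collapse = ", ")))
    if (object@pooledSD <= 0) return("pooled SD must be > 0")
    TRUE
})

#' Simulation configuration for synthetic LFQ data
#'
#' Defines the study design the generator emulates: donors contributing one
#' sample per assigned condition, two acquisition batches with the
#' reference (baseline) condition measured in every batch, and an additive
#' log2 intensity model with protein, peptide, donor, batch and condition
#' effects, plus intensity-independent (MCAR) and intensity-dependent
#' (MNAR, logistic in -intensity) missingness.
#'
#' Create with [simulationConfig()], which supplies the default design:
#' 12 donors; conditions baseline, healthy, traumatic, degenerative, IL1b;
#' batch1 = \{baseline, traumatic, degenerative, IL1b\} (48 samples),
#' batch2 = \{baseline, healthy\} (24 samples).
#'
#' @slot nDonors integer.
#' @slot conditions character, reference first.
#' @slot reference character scalar; has true log2FC identically 0.
#' @slot batchAssignment named character: non-reference condition -> batch.
#' @slot nProteins integer.
#' @slot meanPeptides numeric; peptides per protein ~ 1 + Poisson(meanPeptides - 1).
#' @slot trueLog2FC numeric matrix, protein x condition (reference column 0).
#' @slot donorSD,peptideOffsetSD,noiseSD non-negative reals, log2 units
#'   (noiseSD strictly positive unless explicitly 0 for noise-free checks).
#' @slot batchShift named numeric, one entry per batch, log2 units.
#' @slot baseRange numeric length-2: protein base log2 abundances drawn
#'   log-uniform over this interval.
#' @slot missingMcarRate probability of MCAR dropout per cell.
#' @slot missingMnarScale logistic slope of intensity-dependent dropout
#'   (0 disables MNAR).
#' @slot missingMnarMid logistic midpoint (log2 intensity); `NA` = 10th
#'   percentile of the simulated intensities.
#' @slot seed integer.
#' @export
setClass("SimulationConfig", representation(
    nDonors = "integer", conditions = "character", reference = "character",
    batchAssignment = "character", nProteins = "integer",
    meanPeptides = "numeric", trueLog2FC = "matrix",
    donorSD = "numeric", peptideOffsetSD = "numeric", noiseSD = "numeric",
    batchShift = "numeric", baseRange = "numeric",
    missingMcarRate = "numeric", missingMnarScale = "numeric",
    missingMnarMid = "numeric", seed = "integer"))

setValidity("SimulationConfig", function(object) {
    msg <- character()
    if (object@nDonors < 1L) msg <- c(msg, "nDonors must be >= 1")
    if (object@nProteins < 1L) msg <- c(msg, "nProteins must be >= 1")
    if (!object@reference %in% object@conditions)
        msg <- c(msg, "reference must be one of conditions")
    nonref <- setdiff(object@conditions, object@reference)
    if (!setequal(names(object@batchAssignment), nonref))
        msg <- c(msg, "batchAssignment must map every non-reference condition to exactly one batch")
    if (any(c(object@donorSD, object@peptideOffsetSD, object@noiseSD,
              object@missingMnarScale) < 0))
        msg <- c(msg, "SDs and MNAR scale must be >= 0")
    if (object@missingMcarRate < 0 || object@missingMcarRate > 1)
        msg <- c(msg, "missingMcarRate must be in [0, 1]")
    if (!identical(dim(object@trueLog2FC),
                   c(object@nProteins, length(object@conditions))))
        msg <- c(msg, "trueLog2FC must be nProteins x length(conditions)")
    else if (any(object@trueLog2FC[, object@reference] != 0))
        msg <- c(msg, "reference condition must have true log2FC == 0 for all proteins")
    if (length(msg)) msg else TRUE
})

#' Multi-condition secretome partition
#'
#' Exact set algebra over per-condition sets of (upregulated) protein ids:
#' per-protein membership, all 2^k - 1 disjoint Venn cells, and pairwise
#' intersection counts.
#'
#' @slot sets named list of character vectors (one per condition).
#' @slot membership `DataFrame` (protein, comma-joined conditions), protein
#'   id ascending.
#' @slot vennCells named integer; names are `&`-joined condition subsets.
#' @slot pairwise symmetric integer matrix of intersection sizes.
#' @seealso [buildPartition()]
#' @export
setClass("SecretomePartition", representation(
    sets = "list", membership = "DataFrame",
    vennCells = "integer", pairwise = "matrix"))

setValidity("SecretomePartition", function(object) {
    msg <- character()
    if (sum(object@vennCells) != length(unique(unlist(object@sets))))
        msg <- c(msg, "Venn cells must partition the union of all sets")
    if (length(msg)) msg else TRUE
})

setMethod("show", "PeptideExperiment", function(object) {
    callNextMethod()
    ref <- metadata(object)$reference
    if (!is.null(ref)) cat("reference condition:", ref, "\n")
    if ("condition" %in% colnames(colData(object))) {
        tb <- table(colData(object)$condition)
        cat("samples per condition:",
            paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
    }
})

setMethod("show", "FilterReport", function(object) {
    cat("FilterReport\n")
    cat(sprintf("  peptides: %d -> %d\n", object@nPeptidesIn, object@nPeptidesOut))
    cat(sprintf("  proteins: %d -> %d\n", object@nProteinsIn, object@nProteinsOut))
    rs <- table(object@proteinStatus$reason[!object@proteinStatus$retained])
    if (length(rs))
        cat("  exclusions:",
            paste(sprintf("%s=%d", names(rs), rs), collapse = ", "), "\n")
})

setMethod("show", "NormalizationParams", function(object) {
    cat(sprintf(
        "NormalizationParams: %d samples, pooled mean %.4f, pooled SD %.4f%s\n",
        length(object@sampleMean), object@pooledMean, object@pooledSD,
        if (object@addLocation) "" else " (location not re-added)"))
})

setMethod("show", "SimulationConfig", function(object) {
    cat(sprintf(
        "SimulationConfig: %d donors x %d conditions (ref '%s'), %d proteins, seed %d\n",
        object@nDonors, length(object@conditions), object@reference,
        object@nProteins, object@seed))
    cat("  batches:", paste(sprintf("%s->%s", names(object@batchAssignment),
                                    object@batchAssignment), collapse = ", "), "\n")
})

setMethod("show", "SecretomePartition", function(object) {
    cat(sprintf("SecretomePartition over %d conditions, %d proteins\n",
                length(object@sets), length(unique(unlist(object@sets)))))
    cat("  set sizes:", paste(sprintf("%s=%d", names(object@sets),
                                      lengths(object@sets)), collapse = ", "), "\n")
})
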