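#' Construct a PeptideExperiment
#'
#' @param intensity numeric matrix, peptides x samples, raw (linear) scale.
#'   `NA` marks a missing measurement; zeros are coerced to `NA`
#'   (MaxQuant writes 0 for "not observed", and log2(0) is undefined).
#' @param sequence,proteinGroup character vectors, one entry per row of
#'   `intensity`. Protein groups are atomic identifiers; no razor-peptide
#'   reassignment is attempted.
#' @param design optional `data.frame`/`DataFrame` with columns `sample`,
#'   `donor`, `condition`, `batch`. Must cover exactly the samples in
#'   `colnames(intensity)`.
#' @param reference reference condition label (default `"baseline"`); only
#'   checked when `design` is supplied.
#' @return A [PeptideExperiment-class] object.
#' @examples
#' m <- matrix(c(100, 0, 250, 300), 2,
#'             dimnames = list(NULL, c("s1", "s2")))
#' pe <- PeptideExperiment(m, sequence = c("PEPTIDEA", "PEPTIDEB"),
#'                         proteinGroup = c("P1", "P1"))
#' intensityMatrix(pe)  # the 0 is now NA
#' @export
PeptideExperiment <- function(intensity, sequence, proteinGroup,
                              design = NULL, reference = "baseline") {
    intensity <- as.matrix(intensity)
    if (is.null(colnames(intensity)))
        stop("intensity matrix must have sample ids as colnames")
    storage.mode(intensity) <- "double"
    intensity[!is.na(intensity) & intensity == 0] <- NA_real_
    if (length(proteinGroup) == 1L)
        proteinGroup <- rep(proteinGroup, nrow(intensity))
    if (length(sequence) != nrow(intensity) ||
        length(proteinGroup) != nrow(intensity))
        stop("sequence/proteinGroup length must equal nrow(intensity)")
    rd <- DataFrame(sequence = as.character(sequence),
                    proteinGroup = as.character(proteinGroup))
    rownames(intensity) <- NULL
    md <- list()
    if (!is.null(design)) {
        design <- as.data.frame(design)
        need <- c("sample", "donor", "condition", "batch")
        miss <- setdiff(need, colnames(design))
        if (length(miss))
            stop("design lacks column(s): ", paste(miss, collapse = ", "))
        absent <- setdiff(colnames(intensity), design$sample)
        if (length(absent))
            stop("sample(s) in peptide table absent from design: ",
                 paste(absent, collapse = ", "))
        extra <- setdiff(design$sample, colnames(intensity))
        if (length(extra))
            stop("sample(s) in design absent from peptide table: ",
                 paste(extra, collapse = ", "))
        design <- design[match(colnames(intensity), design$sample), , drop = FALSE]
        cd <- DataFrame(donor = as.character(design$donor),
                        condition = as.character(design$condition),
                        batch = as.character(design$batch),
                        row.names = design$sample)
        if (!reference %in% cd$condition)
            stop("reference condition '", reference, "' not found in the design; ",
                 "pass the correct label via `reference=`")
        md$reference <- reference
        se <- SummarizedExperiment(
            assays = SimpleList(intensity = intensity),
            rowData = rd, colData = cd, metadata = md)
    } else {
        se <- SummarizedExperiment(
            assays = SimpleList(intensity = intensity), rowData = rd)
    }
    new("PeptideExperiment", se)
}

#' @rdname PeptideExperiment
#' @param x a `PeptideExperiment`.
#' @export
setGeneric("peptideSequences", function(x) standardGeneric("peptideSequences"))

#' @rdname PeptideExperiment
#' @export
setMethod("peptideSequences", "PeptideExperiment",
          function(x) rowData(x)$sequence)

#' @rdname PeptideExperiment
#' @export
setGeneric("proteinGroups", function(x) standardGeneric("proteinGroups"))

#' @rdname PeptideExperiment
#' @export
setMethod("proteinGroups", "PeptideExperiment",
          function(x) rowData(x)$proteinGroup)

#' @rdname PeptideExperiment
#' @param assayName which assay to return (`"intensity"` or `"log2norm"`).
#' @export
setGeneric("intensityMatrix",
           function(x, assayName = "intensity") standardGeneric("intensityMatrix"))

#' @rdname PeptideExperiment
#' @export
setMethod("intensityMatrix", "PeptideExperiment",
          function(x, assayName = "intensity") assay(x, assayName))

#' @rdname PeptideExperiment
#' @export
setGeneric("referenceCondition", function(x) standardGeneric("referenceCondition"))

#' @rdname PeptideExperiment
#' @export
setMethod("referenceCondition", "PeptideExperiment",
          function(x) metadata(x)$reference)

#' @rdname PeptideExperiment
#' @export
setGeneric("sampleDesign", function(x) standardGeneric("sampleDesign"))

#' @rdname PeptideExperiment
#' @export
setMethod("sampleDesign", "PeptideExperiment", function(x) {
    cd <- colData(x)
    data.frame(sample = rownames(cd), donor = cd$donor,
               condition = cd$condition, batch = cd$batch,
               row.names = NULL)
})

#' @rdname PeptideExperiment
#' @export
setGeneric("normalizationParams",
           function(x) standardGeneric("normalizationParams"))

#' @rdname PeptideExperiment
#' @export
setMethod("normalizationParams", "PeptideExperiment",
          function(x) metadata(x)$normalization)

.checkDesign <- function(x, need_reference = TRUE) {
    cd <- colData(x)
    if (!all(c("donor", "condition", "batch") %in% colnames(cd)))
        stop("this operation needs a sample design ",
             "(donor/condition/batch); construct the PeptideExperiment ",
             "with a design table")
    tb <- table(cd$condition)
    if (any(tb < 2))
        stop("every condition needs >= 2 samples; violated by: ",
             paste(names(tb)[tb < 2], collapse = ", "))
    if (need_reference && is.null(metadata(x)$reference))
        stop("no reference condition set; pass `reference=` when building ",
             "the PeptideExperiment")
    invisible(TRUE)
}

#' Accessors for FilterReport
#'
#' @param x a [FilterReport-class].
#' @return `peptideStatus()`/`proteinStatus()` return the per-peptide and
#'   per-protein bookkeeping `DataFrame`s; `filterCounts()` a named integer
#'   vector of in/out counts at both levels.
#' @name FilterReport-accessors
NULL

#' @rdname FilterReport-accessors
#' @export
setGeneric("peptideStatus", function(x) standardGeneric("peptideStatus"))

#' @rdname FilterReport-accessors
#' @export
setMethod("peptideStatus", "FilterReport", function(x) x@peptideStatus)

#' @rdname FilterReport-accessors
#' @export
setGeneric("proteinStatus", function(x) standardGeneric("proteinStatus"))

#' @rdname FilterReport-accessors
#' @export
setMethod("proteinStatus", "FilterReport", function(x) x@proteinStatus)

#' @rdname FilterReport-accessors
#' @export
filterCounts <- function(x) {
    stopifnot(is(x, "FilterReport"))
    c(nPeptidesIn = x@nPeptidesIn, nPeptidesOut = x@nPeptidesOut,
      nProteinsIn = x@nProteinsIn, nProteinsOut = x@nProteinsOut)
}
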