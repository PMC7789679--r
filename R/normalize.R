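#' Rescaled z-score normalization of log2 intensities
#'
#' Removes per-sample loading differences: the z-score of the log2
#' intensities is computed per sample over its observed cells and rescaled
#' by the average of the per-sample standard deviations so the original
#' intensity scale is preserved,
#' \deqn{x'_{is} = \frac{\log_2 x_{is} - \mu_s}{\sigma_s}\,\bar\sigma + \bar\mu ,}
#' where \eqn{\bar\sigma} is the mean of the per-sample SDs and
#' \eqn{\bar\mu} the mean of the per-sample means. After the transform
#' every sample has observed-cell mean exactly \eqn{\bar\mu} and SD exactly
#' \eqn{\bar\sigma}. Missing cells stay missing.
#'
#' Re-adding the pooled location \eqn{\bar\mu} keeps the values on the
#' original abundance scale (a plain `z * sigma-bar` would center every
#' sample at 0); the location constant cancels in all baseline-referenced
#' contrasts, so downstream fold changes are invariant to
#' `addLocation` — a property the test suite asserts.
#'
#' @param pe a [PeptideExperiment-class]; every sample needs at least two
#'   observed cells with distinct values.
#' @param addLocation re-add the pooled location (default `TRUE`).
#' @return The `PeptideExperiment` with a new `"log2norm"` assay and the
#'   fitted [NormalizationParams-class] in `metadata(pe)$normalization`
#'   (accessor [normalizationParams()]).
#' @examples
#' m <- 2^cbind(s1 = c(1, 2, 3), s2 = c(11, 12, 13))
#' pe <- PeptideExperiment(m, sequence = paste0("P", 1:3),
#'                         proteinGroup = "A")
#' intensityMatrix(normalizeIntensities(pe), "log2norm")  # both samples 6,7,8
#' @export
normalizeIntensities <- function(pe, addLocation = TRUE) {
    l2 <- log2(intensityMatrix(pe))
    mu <- apply(l2, 2, mean, na.rm = TRUE)
    sd_ <- apply(l2, 2, stats::sd, na.rm = TRUE)
    bad <- colnames(l2)[is.na(sd_) | sd_ == 0]
    if (length(bad))
        stop("zero variance (need >= 2 distinct observed values) in ",
             "sample(s): ", paste(bad, collapse = ", "))
    pooledSD <- mean(sd_)
    pooledMean <- if (addLocation) mean(mu) else 0
    norm <- sweep(sweep(l2, 2, mu, "-"), 2, sd_, "/") * pooledSD + pooledMean
    params <- new("NormalizationParams",
                  sampleMean = mu, sampleSD = sd_,
                  pooledMean = pooledMean, pooledSD = pooledSD,
                  addLocation = addLocation)
    assays(pe)[["log2norm"]] <- norm
    metadata(pe)$normalization <- params
    pe
}

#' @importFrom SummarizedExperiment assays<-
NULL

#' Export normalization parameters as a data.frame (for audit TSVs)
#'
#' @param params a [NormalizationParams-class].
#' @return data.frame with per-sample mean/SD and the pooled values.
#' @export
normalizationTable <- function(params) {
    stopifnot(is(params, "NormalizationParams"))
    data.frame(sample = names(params@sampleMean),
               mean = unname(params@sampleMean),
               sd = unname(params@sampleSD),
               pooledMean = params@pooledMean,
               pooledSD = params@pooledSD)
}
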