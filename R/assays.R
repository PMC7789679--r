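#' DNA-normalized per-donor fold changes for immunoassay data
#'
#' Each concentration is divided by its sample's DNA content, then by the
#' same donor's DNA-normalized baseline value:
#' `fc(donor, condition) = (conc/DNA)(donor, condition) /
#' (conc/DNA)(donor, reference)`. Undetected values are excluded, never
#' zero-imputed; a donor without a detected reference value is excluded
#' for that analyte; an analyte undetected in at least
#' `dropUndetectedFrac` of all samples is dropped entirely.
#'
#' @param assay data.frame with columns `analyte`, `sample`, `donor`,
#'   `condition`, `concentration`, `detected` (see
#'   [simulateImmunoassay()]).
#' @param dna data.frame with columns `sample`, `dna` (all > 0).
#' @param reference reference condition label.
#' @param dropUndetectedFrac drop analytes undetected in at least this
#'   fraction of samples (default 0.9).
#' @return data.frame (`analyte`, `donor`, `condition`, `fc`) for
#'   non-reference conditions; attributes `droppedAnalytes` and
#'   `excludedDonors` record the bookkeeping.
#' @export
foldChange <- function(assay, dna, reference = "baseline",
                       dropUndetectedFrac = 0.9) {
    need <- c("analyte", "sample", "donor", "condition", "concentration",
              "detected")
    stopifnot(all(need %in% colnames(assay)))
    if (any(dna$dna <= 0))
        stop("non-positive DNA content for sample(s): ",
             paste(dna$sample[dna$dna <= 0], collapse = ", "))
    if (!reference %in% assay$condition)
        stop("reference condition '", reference, "' absent from assay table")
    d <- dna$dna[match(assay$sample, dna$sample)]
    if (any(is.na(d)))
        stop("sample(s) missing from the DNA table: ",
             paste(unique(assay$sample[is.na(d)]), collapse = ", "))
    norm <- ifelse(assay$detected, assay$concentration / d, NA_real_)
    undetFrac <- tapply(!assay$detected, assay$analyte, mean)
    dropped <- names(undetFrac)[undetFrac >= dropUndetectedFrac]
    excluded <- character()
    rows <- list()
    for (a in setdiff(unique(assay$analyte), dropped)) {
        ia <- assay$analyte == a
        for (dn in unique(assay$donor[ia])) {
            id <- ia & assay$donor == dn
            baseVals <- norm[id & assay$condition == reference]
            baseVals <- baseVals[!is.na(baseVals)]
            if (!length(baseVals)) {
                excluded <- c(excluded, paste(a, dn, sep = "/"))
                next
            }
            base <- exp(mean(log(baseVals)))
            sel <- id & assay$condition != reference & !is.na(norm)
            if (any(sel))
                rows[[length(rows) + 1L]] <- data.frame(
                    analyte = a, donor = dn,
                    condition = assay$condition[sel],
                    fc = norm[sel] / base)
        }
    }
    out <- if (length(rows)) do.call(rbind, rows) else
        data.frame(analyte = character(), donor = character(),
                   condition = character(), fc = numeric())
    rownames(out) <- NULL
    attr(out, "droppedAnalytes") <- dropped
    attr(out, "excludedDonors") <- excluded
    out
}

#' LDH cytotoxicity percentage
#'
#' `100 * (sample - negative) / (positive - negative)`: the untreated
#' negative control maps to 0% and the lysed positive control to 100%.
#' The result is affine-invariant: adding a constant to all three
#' absorbances leaves it unchanged.
#'
#' @param x sample absorbance(s).
#' @param neg negative-control absorbance.
#' @param pos positive-control absorbance (must differ from `neg`).
#' @return cytotoxicity percent (same length as `x`).
#' @export
ldhCytotoxicity <- function(x, neg, pos) {
    if (any(pos == neg))
        stop("positive and negative controls are equal; cytotoxicity undefined")
    100 * (x - neg) / (pos - neg)
}

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the transformed sample skewness and kurtosis into
#' `K^2 = Z_skew^2 + Z_kurt^2`, chi-squared with 2 df under normality
#' (D'Agostino, Belanger & D'Agostino 1990). Needs n >= 8.
#'
#' @param x numeric vector.
#' @return list (`statistic`, `p.value`, `method`).
#' @export
dagostinoTest <- function(x) {
    x <- x[!is.na(x)]
    n <- length(x)
    if (n < 8) stop("D'Agostino-Pearson omnibus test needs n >= 8")
    m <- mean(x)
    m2 <- mean((x - m)^2)
    if (m2 == 0) return(list(statistic = NA_real_, p.value = 1,
                             method = "D'Agostino-Pearson omnibus (degenerate)"))
    g1 <- mean((x - m)^3) / m2^1.5
    b2 <- mean((x - m)^4) / m2^2
    # skewness: D'Agostino (1970) normalizing transform
    Y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
    beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
        ((n - 2) * (n + 5) * (n + 7) * (n + 9))
    W2 <- -1 + sqrt(2 * (beta2 - 1))
    delta <- 1 / sqrt(log(sqrt(W2)))
    alpha <- sqrt(2 / (W2 - 1))
    Zs <- delta * log(Y / alpha + sqrt((Y / alpha)^2 + 1))
    # kurtosis: Anscombe & Glynn (1983)
    Eb2 <- 3 * (n - 1) / (n + 1)
    Vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
    X <- (b2 - Eb2) / sqrt(Vb2)
    sqrtB1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
        sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
    A <- 6 + 8 / sqrtB1 * (2 / sqrtB1 + sqrt(1 + 4 / sqrtB1^2))
    Zk <- ((1 - 2 / (9 * A)) -
           ((1 - 2 / A) / (1 + X * sqrt(2 / (A - 4))))^(1 / 3)) /
        sqrt(2 / (9 * A))
    K2 <- Zs^2 + Zk^2
    list(statistic = K2,
         p.value = stats::pchisq(K2, df = 2, lower.tail = FALSE),
         method = "D'Agostino-Pearson omnibus")
}

.normalityBattery <- function(x) {
    run <- function(f) tryCatch(f(x)$p.value, error = function(e) NA_real_)
    c(dagostino = if (length(x) >= 8) run(dagostinoTest) else NA_real_,
      shapiro = if (length(x) >= 3 && length(x) <= 5000)
          run(stats::shapiro.test) else NA_real_,
      lilliefors = if (length(x) >= 4) run(nortest::lillie.test)
                   else NA_real_)
}

#' Normality-gated group comparison (ANOVA vs Kruskal-Wallis)
#'
#' Runs three normality tests per group at level `alpha`
#' (D'Agostino-Pearson omnibus, Shapiro-Wilk, Lilliefors-corrected
#' Kolmogorov-Smirnov); if the gate concludes the data are parametric, a
#' one-way ANOVA is used, otherwise Kruskal-Wallis. `gate = "any"` (the
#' strictest rule, the default) goes non-parametric as soon as any test
#' in any group rejects; `gate = "all"` only when, within some group,
#' every computable test rejects. Tests that cannot run on a group (too
#' small, constant values) contribute `NA` and never count as
#' rejections. Groups with fewer than 3 observations are skipped with a
#' reason; completely constant data returns p = 1 by convention.
#'
#' @param values numeric vector of observations (e.g. per-donor fold
#'   changes).
#' @param groups group labels, same length.
#' @param alpha level for the normality gate and reported significance
#'   (default 0.05).
#' @param gate `"any"` or `"all"` (see above).
#' @return list of class `"AssayGatedTest"`: `test`
#'   (`"anova"`/`"kruskal"`/`"none"`), `p.value`, `significant`,
#'   `normality` (data.frame of per-group test p-values and rejections),
#'   `skippedGroups`, `gate`, `alpha`.
#' @export
gatedTest <- function(values, groups, alpha = 0.05,
                      gate = c("any", "all")) {
    gate <- match.arg(gate)
    groups <- as.character(groups)
    ok <- !is.na(values) & !is.na(groups)
    values <- values[ok]; groups <- groups[ok]
    n <- table(groups)
    skipped <- stats::setNames(
        sprintf("n = %d < 3", n[n < 3]), names(n)[n < 3])
    keep <- groups %in% names(n)[n >= 3]
    values <- values[keep]; groups <- factor(groups[keep])
    if (nlevels(groups) < 2)
        stop("need >= 2 groups with n >= 3 after skipping")
    norm <- do.call(rbind, lapply(levels(groups), function(g) {
        p <- .normalityBattery(values[groups == g])
        data.frame(group = g, test = names(p), p = unname(p),
                   reject = !is.na(p) & p < alpha)
    }))
    if (stats::sd(values) == 0) {
        out <- list(test = "none", p.value = 1, significant = FALSE,
                    normality = norm, skippedGroups = skipped,
                    gate = gate, alpha = alpha)
        class(out) <- "AssayGatedTest"
        return(out)
    }
    nonparam <- if (gate == "any") any(norm$reject) else
        any(vapply(split(norm, norm$group), function(d) {
            avail <- !is.na(d$p)
            any(avail) && all(d$reject[avail])
        }, TRUE))
    if (nonparam) {
        p <- stats::kruskal.test(values, groups)$p.value
        test <- "kruskal"
    } else {
        p <- summary(stats::aov(values ~ groups))[[1]][1, "Pr(>F)"]
        test <- "anova"
    }
    out <- list(test = test, p.value = p, significant = p < alpha,
                normality = norm, skippedGroups = skipped, gate = gate,
                alpha = alpha)
    class(out) <- "AssayGatedTest"
    out
}

#' @export
print.AssayGatedTest <- function(x, ...) {
    cat(sprintf("Normality-gated comparison: %s, p = %.4g%s (gate '%s')\n",
                x$test, x$p.value,
                if (x$significant) " *" else "", x$gate))
    invisible(x)
}

#' Per-analyte gated tests over fold-change groups
#'
#' Convenience wrapper: applies [gatedTest()] to the fold changes of each
#' analyte, grouped by condition.
#'
#' @param fc output of [foldChange()].
#' @param alpha,gate passed to [gatedTest()].
#' @return data.frame: `analyte`, `test`, `p`, `significant`.
#' @export
assayResults <- function(fc, alpha = 0.05, gate = "any") {
    rows <- lapply(unique(fc$analyte), function(a) {
        sub <- fc[fc$analyte == a, ]
        r <- tryCatch(gatedTest(sub$fc, sub$condition, alpha, gate),
                      error = function(e) NULL)
        if (is.null(r)) return(NULL)
        data.frame(analyte = a, test = r$test, p = r$p.value,
                   significant = r$significant)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
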