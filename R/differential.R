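#' Significance / fold-change selection rule
#'
#' The selection applied to per-protein effects: raw p below `alpha` and a
#' log2 fold change at least `fcThreshold` (absolute value for
#' "significant" lists; positive-only for "upregulated" lists). The
#' fold-change comparison is inclusive (`>=`) by default; `strict = TRUE`
#' switches to `>`.
#'
#' @param alpha significance level in (0, 1), default 0.05.
#' @param fcThreshold log2 fold-change threshold >= 0, default 1.5.
#' @param useAbsolute if `TRUE` (default) use `|log2fc|`; if `FALSE`,
#'   positive-only (upregulated lists).
#' @param strict use strict `>` instead of `>=` for the fold-change bound.
#' @param useAdjusted gate on BH-adjusted q instead of raw p (default
#'   `FALSE`: the selection rule is raw p < alpha, with q reported
#'   alongside).
#' @return list of class `"SignificanceRule"`.
#' @export
significanceRule <- function(alpha = 0.05, fcThreshold = 1.5,
                             useAbsolute = TRUE, strict = FALSE,
                             useAdjusted = FALSE) {
    if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
    if (fcThreshold < 0) stop("fcThreshold must be >= 0")
    structure(list(alpha = alpha, fcThreshold = fcThreshold,
                   useAbsolute = useAbsolute, strict = strict,
                   useAdjusted = useAdjusted),
              class = "SignificanceRule")
}

.tryFit <- function(expr_fun) {
    conv_warn <- FALSE
    m <- withCallingHandlers(
        tryCatch(suppressMessages(expr_fun()), error = function(e) NULL),
        warning = function(w) {
            if (grepl("converge", conditionMessage(w), ignore.case = TRUE))
                conv_warn <<- TRUE
            invokeRestart("muffleWarning")
        })
    if (is.null(m) || conv_warn) return(NULL)
    if (inherits(m, "merMod") && lme4::isSingular(m, tol = 1e-4)) return(NULL)
    m
}

.fitProteinLong <- function(df, reference, randomEffects = c("donor", "peptide")) {
    conds <- unique(df$condition)
    if (length(conds) < 2 || !reference %in% conds)
        return(structure("fewer than 2 conditions observed (incl. reference)",
                         class = "fitError"))
    other <- setdiff(conds, reference)
    df$condition <- factor(df$condition, levels = c(reference, other))
    df$donor <- factor(df$donor)
    df$peptide <- factor(df$peptide)
    df$batch <- factor(df$batch)
    nPep <- nlevels(df$peptide)
    out_skeleton <- function(est, se, dfree, p, note)
        data.frame(condition = other, log2fc = est, se = se, df = dfree,
                   p = p, nPeptides = nPep, fitNote = note,
                   stringsAsFactors = FALSE)
    if (stats::sd(df$y) == 0)   # zero-variance convention: fc 0, p 1
        return(out_skeleton(0, 0, NA_real_, 1, "degenerate"))
    fixed <- "y ~ condition"
    if (nlevels(df$batch) > 1) fixed <- paste(fixed, "+ batch")
    wantDonor <- "donor" %in% randomEffects && nlevels(df$donor) > 1
    wantPep <- "peptide" %in% randomEffects && nPep > 1
    ladder <- list()
    if (wantDonor && wantPep)
        ladder <- c(ladder, list(list(
            f = paste(fixed, "+ (1|donor) + (1|peptide)"), note = "full")))
    if (wantPep)
        ladder <- c(ladder, list(list(
            f = paste(fixed, "+ (1|peptide)"),
            note = if (wantDonor) "reduced" else "full")))
    else if (wantDonor)
        ladder <- c(ladder, list(list(
            f = paste(fixed, "+ (1|donor)"), note = "full")))
    fit <- NULL; note <- NULL
    for (step in ladder) {
        fit <- .tryFit(function() lmerTest::lmer(
            stats::as.formula(step$f), data = df,
            control = lme4::lmerControl(calc.derivs = FALSE)))
        if (!is.null(fit)) { note <- step$note; break }
    }
    if (is.null(fit)) {   # fixed-effects least squares, peptide as covariate
        f <- if (nPep > 1) paste(fixed, "+ peptide") else fixed
        fit <- stats::lm(stats::as.formula(f), data = df)
        note <- "ols_fallback"
    }
    if (inherits(fit, "merMod")) {
        cf <- stats::coef(summary(fit))
        est <- cf[, "Estimate"]; se <- cf[, "Std. Error"]
        dfree <- cf[, "df"]; p <- cf[, "Pr(>|t|)"]
    } else {
        cf <- stats::coef(summary(fit))
        est <- cf[, "Estimate"]; se <- cf[, "Std. Error"]
        dfree <- rep(stats::df.residual(fit), nrow(cf))
        names(dfree) <- rownames(cf)
        p <- cf[, "Pr(>|t|)"]
    }
    rows <- paste0("condition", other)
    found <- rows %in% rownames(cf)
    res <- out_skeleton(NA_real_, NA_real_, NA_real_, NA_real_, note)
    res$log2fc[found] <- est[rows[found]]
    res$se[found] <- se[rows[found]]
    res$df[found] <- dfree[rows[found]]
    res$p[found] <- p[rows[found]]
    res[!is.na(res$log2fc), , drop = FALSE]   # aliased contrasts dropped
}

#' Fit the per-protein mixed model and extract baseline contrasts
#'
#' Peptide-level log2 intensities of one protein are modelled as
#' `y = condition + batch + (1|donor) + (1|peptide) + error` with the
#' reference condition as the treatment-coding baseline, so each condition
#' coefficient is the protein's log2 fold change vs the reference,
#' adjusted for batch. Random donor intercepts carry the repeated-measures
#' correlation; random peptide intercepts absorb systematic ionization
#' offsets. p-values use the Satterthwaite degree-of-freedom
#' approximation (lmerTest).
#'
#' Singular or non-converged fits walk a fallback ladder: drop the donor
#' intercept (`fitNote "reduced"`), then fall back to fixed-effects least
#' squares with peptide as a fixed covariate (`"ols_fallback"`).
#' Zero-variance data returns log2fc 0 and p 1 by convention
#' (`"degenerate"`).
#'
#' @param mat numeric matrix (peptides x samples) of normalized log2
#'   intensities, `NA` for missing; column names are sample ids.
#' @param design data.frame with `sample`, `donor`, `condition`, `batch`.
#' @param reference reference condition label.
#' @param randomEffects which random intercepts to request, subset of
#'   `c("donor", "peptide")`.
#' @return data.frame with one row per estimable non-reference condition:
#'   `condition`, `log2fc`, `se`, `df`, `p`, `nPeptides`, `fitNote`; or a
#'   `"fitError"` reason string when no contrast is estimable.
#' @export
fitProtein <- function(mat, design, reference,
                       randomEffects = c("donor", "peptide")) {
    mat <- as.matrix(mat)
    idx <- which(!is.na(mat), arr.ind = TRUE)
    if (!nrow(idx))
        return(structure("no observed cells", class = "fitError"))
    s <- match(colnames(mat)[idx[, 2]], design$sample)
    df <- data.frame(y = mat[idx], peptide = idx[, 1],
                     donor = design$donor[s],
                     condition = design$condition[s],
                     batch = design$batch[s])
    .fitProteinLong(df, reference, randomEffects)
}

#' Differential abundance for all proteins against the reference
#'
#' Runs [fitProtein()] for every protein in the filtered, normalized
#' table, assembles one row per protein x non-reference condition, and
#' adds Benjamini-Hochberg adjusted q-values computed within each
#' contrast across proteins. Ordering is deterministic (protein id
#' ascending, condition in design order) and invariant to the sample
#' order of the input. Per-protein failures never abort the run; they are
#' collected in `metadata(result)$problems`.
#'
#' @param pe a filtered [PeptideExperiment-class] carrying a `"log2norm"`
#'   assay (see [normalizeIntensities()]).
#' @param assayName assay to model (default `"log2norm"`); passing
#'   `"intensity"` models the log2 of the raw intensities (ablation runs
#'   without normalization).
#' @param randomEffects passed to [fitProtein()].
#' @return A `DataFrame` with columns `protein`, `condition`, `log2fc`,
#'   `se`, `df`, `p`, `q`, `nPeptides`, `fitNote`.
#' @export
runDifferential <- function(pe, assayName = "log2norm",
                            randomEffects = c("donor", "peptide")) {
    .checkDesign(pe)
    if (!assayName %in% assayNames(pe))
        stop("assay '", assayName, "' not found; run normalizeIntensities() ",
             "first (or pass assayName = \"intensity\" deliberately)")
    ref <- metadata(pe)$reference
    design <- sampleDesign(pe)
    condOrder <- sort(setdiff(unique(design$condition), ref))
    mat <- intensityMatrix(pe, assayName)
    if (assayName == "intensity") mat <- log2(mat)
    prots <- proteinGroups(pe)
    out <- list(); problems <- list()
    for (prot in sort(unique(prots))) {
        sub <- mat[prots == prot, , drop = FALSE]
        res <- fitProtein(sub, design, ref, randomEffects)
        if (inherits(res, "fitError")) {
            problems[[prot]] <- unclass(res)
            next
        }
        res$protein <- prot
        out[[prot]] <- res
    }
    if (!length(out)) {
        res <- DataFrame(protein = character(), condition = character(),
                         log2fc = numeric(), se = numeric(), df = numeric(),
                         p = numeric(), q = numeric(),
                         nPeptides = integer(), fitNote = character())
        metadata(res) <- list(problems = problems, reference = ref)
        return(res)
    }
    tab <- do.call(rbind, out)
    tab <- tab[order(tab$protein,
                     match(tab$condition, condOrder)), , drop = FALSE]
    q <- stats::ave(tab$p, tab$condition,
                    FUN = function(p) stats::p.adjust(p, "BH"))
    res <- DataFrame(protein = tab$protein, condition = tab$condition,
                     log2fc = tab$log2fc, se = tab$se, df = tab$df,
                     p = tab$p, q = q,
                     nPeptides = as.integer(tab$nPeptides),
                     fitNote = tab$fitNote)
    rownames(res) <- NULL
    metadata(res) <- list(problems = problems, reference = ref)
    res
}

#' Select significant proteins per condition
#'
#' Applies a [significanceRule()] to differential results: a protein is
#' selected for a condition when its p-value is below `alpha` and its
#' log2 fold change meets the threshold (absolute or positive-only).
#' Also emits a per-protein membership table (protein -> set of
#' conditions) in the shape of a published overlap listing.
#'
#' @param effects result of [runDifferential()] (or any data.frame with
#'   `protein`, `condition`, `log2fc`, `p`, `q`).
#' @param rule a [significanceRule()].
#' @return list with `sets` (named list of protein ids per condition),
#'   `membership` (`DataFrame`: protein, comma-joined conditions, protein
#'   ascending) and `rule`.
#' @export
selectSignificant <- function(effects, rule = significanceRule()) {
    stopifnot(inherits(rule, "SignificanceRule"))
    effects <- as.data.frame(effects)
    pval <- if (rule$useAdjusted) effects$q else effects$p
    fc <- if (rule$useAbsolute) abs(effects$log2fc) else effects$log2fc
    hit <- !is.na(pval) & pval < rule$alpha &
        (if (rule$strict) fc > rule$fcThreshold else fc >= rule$fcThreshold)
    conds <- unique(effects$condition)
    sets <- lapply(stats::setNames(conds, conds), function(cc)
        sort(effects$protein[hit & effects$condition == cc]))
    sel <- effects[hit, , drop = FALSE]
    prots <- sort(unique(sel$protein))
    membership <- DataFrame(
        protein = prots,
        conditions = vapply(prots, function(p) paste(
            conds[conds %in% sel$condition[sel$protein == p]],
            collapse = ","), ""))
    rownames(membership) <- NULL
    list(sets = sets, membership = membership, rule = rule)
}
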