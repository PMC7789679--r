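#' Configuration for preranked gene-set enrichment
#'
#' @param minSetSize minimum number of ranked proteins a set must contain
#'   to be tested (default 10; set membership outside the ranked list is
#'   ignored).
#' @param nPerm number of gene-label permutations for the null
#'   (default 1000).
#' @param weight exponent on `|score|` in the running-sum hit increments
#'   (default 1, the standard weighted statistic).
#' @param seed integer seed; the whole stage is deterministic given it.
#' @param pThreshold report-listing threshold on the permutation p
#'   (default 0.01, used by [topTerms()]).
#' @param fdrThreshold highlighting threshold (default 0.05).
#' @param exhaustive `"auto"` (default) enumerates all member placements
#'   instead of sampling whenever `choose(N, k) <= nPerm`, making p exact;
#'   `TRUE`/`FALSE` force the choice.
#' @return list of class `"GseaConfig"`.
#' @export
gseaConfig <- function(minSetSize = 10, nPerm = 1000, weight = 1,
                       seed = 1L, pThreshold = 0.01, fdrThreshold = 0.05,
                       exhaustive = "auto") {
    if (nPerm < 1) stop("nPerm must be >= 1")
    if (minSetSize < 1) stop("minSetSize must be >= 1")
    structure(list(minSetSize = minSetSize, nPerm = as.integer(nPerm),
                   weight = weight, seed = as.integer(seed),
                   pThreshold = pThreshold, fdrThreshold = fdrThreshold,
                   exhaustive = exhaustive),
              class = "GseaConfig")
}

#' Build a ranked list from differential results
#'
#' Proteins are ranked by estimated log2 fold change for one contrast,
#' descending; ties break deterministically on protein id ascending.
#'
#' @param effects result of [runDifferential()].
#' @param condition which contrast to rank.
#' @return data.frame with columns `id`, `score`, in rank order.
#' @export
rankProteins <- function(effects, condition) {
    effects <- as.data.frame(effects)
    sub <- effects[effects$condition == condition & !is.na(effects$log2fc), ]
    if (!nrow(sub)) stop("no effects for condition '", condition, "'")
    sub <- sub[order(-sub$log2fc, sub$protein), ]
    data.frame(id = sub$protein, score = sub$log2fc)
}

.sortRanked <- function(ranked) {
    stopifnot(all(c("id", "score") %in% colnames(ranked)))
    if (anyDuplicated(ranked$id)) stop("ranked ids must be unique")
    ranked[order(-ranked$score, ranked$id), c("id", "score")]
}

# ES from sorted hit positions; O(k). The running sum increases only at
# hits, so its maximum sits at a hit and its (negative) minimum just
# before one; both are evaluated from the positions alone.
# Near-ties between the positive and negative extremum (within .esTieTol)
# resolve to the positive one, deterministically across summation orders.
.esTieTol <- 1e-9
.esFromPositions <- function(w, pos, N) {
    k <- length(pos)
    wp <- w[pos]
    W <- sum(wp)
    if (W == 0) { wp <- rep.int(1, k); W <- k }   # all-zero scores: equal weights
    cum <- cumsum(wp)
    missStep <- if (N > k) 1 / (N - k) else 0
    after <- cum / W - (pos - seq_len(k)) * missStep
    before <- after - wp / W
    imax <- which.max(after); imin <- which.min(before)
    if (after[imax] >= -before[imin] - .esTieTol)
        list(es = after[imax], hitIdx = seq_len(imax), extremum = pos[imax])
    else
        list(es = before[imin], hitIdx = imin:k, extremum = pos[imin])
}

#' Weighted running-sum enrichment score
#'
#' Walks the ranked list: members ("hits") add `|score|^weight`
#' normalized by the set total, non-members subtract `1/(N - N_set)`. The
#' enrichment score is the running-sum value of maximal absolute
#' deviation from zero (ties prefer the positive extremum); the leading
#' edge contains the members at or before the extremum (at or after, for
#' negative ES).
#'
#' @param ranked data.frame (`id`, `score`); re-sorted internally by
#'   (score descending, id ascending).
#' @param members character vector of set member ids; members absent from
#'   the ranked list are ignored.
#' @param weight exponent on `|score|`, default 1.
#' @return list with `es`, `runningSum` (length-N numeric), and
#'   `leadingEdge` (character ids).
#' @export
enrichmentScore <- function(ranked, members, weight = 1) {
    ranked <- .sortRanked(ranked)
    N <- nrow(ranked)
    hit <- ranked$id %in% members
    k <- sum(hit)
    if (k == 0) stop("set has empty intersection with the ranked list")
    w <- abs(ranked$score)^weight
    W <- sum(w[hit])
    if (W == 0) { w[hit] <- 1; W <- k }
    inc <- ifelse(hit, w / W, if (N > k) -1 / (N - k) else 0)
    rs <- cumsum(inc)
    esPos <- max(rs); esNeg <- min(rs)
    if (esPos >= -esNeg - .esTieTol) {
        es <- esPos
        ex <- which.max(rs)
        le <- ranked$id[hit & seq_len(N) <= ex]
    } else {
        es <- esNeg
        ex <- which.min(rs) + 1L   # extremum value sits just before this hit
        le <- ranked$id[hit & seq_len(N) >= ex]
    }
    list(es = es, runningSum = rs, leadingEdge = le)
}

.permNull <- function(w, N, sizes, nPerm, exhaustive) {
    out <- list()
    for (k in sizes) {
        exh <- if (identical(exhaustive, "auto"))
            choose(N, k) <= nPerm else isTRUE(exhaustive)
        if (exh && choose(N, k) <= 1e6) {
            cmb <- utils::combn(N, k)
            es <- apply(cmb, 2, function(p) .esFromPositions(w, p, N)$es)
        } else {
            es <- vapply(seq_len(nPerm), function(i)
                .esFromPositions(w, sort(sample.int(N, k)), N)$es, 0)
        }
        out[[as.character(k)]] <- es
    }
    out
}

#' Preranked gene-set enrichment with a gene-label permutation null
#'
#' For every set with at least `minSetSize` members in the ranked list,
#' computes the weighted running-sum enrichment score (ES), a permutation
#' p-value, a normalized enrichment score (NES) and a permutation-based
#' FDR. The null permutes gene labels: for each permutation the set's
#' members are placed at random ranks and the ES recomputed. Because the
#' score vector is fixed, the null depends only on the set size, so one
#' null per distinct size serves all sets of that size. When
#' `choose(N, k) <= nPerm` (and `exhaustive` is not `FALSE`) all
#' placements are enumerated and p is exact.
#'
#' Conventions (standard preranked semantics): p is the one-sided
#' frequency of same-sign permuted ES at least as extreme as the observed
#' ES; NES is ES divided by the mean magnitude of same-sign permuted ES;
#' FDR is the tail-frequency ratio of permuted to observed NES, computed
#' separately for each sign and clipped to [0, 1].
#'
#' @param ranked data.frame (`id`, `score`), see [rankProteins()].
#' @param collection named list of character member vectors (see
#'   [readGmt()] / [simulateGeneSets()]).
#' @param config a [gseaConfig()].
#' @return `DataFrame` with columns `set`, `size`, `es`, `nes`, `p`,
#'   `fdr`, `leadingEdge` (comma-joined ids), ordered by set name;
#'   sets skipped by the size filter are listed in
#'   `metadata(result)$skipped`.
#' @export
gsea <- function(ranked, collection, config = gseaConfig()) {
    stopifnot(inherits(config, "GseaConfig"))
    if (config$nPerm < 10)
        warning("fewer than 10 permutations: p/NES/FDR estimates unstable")
    ranked <- .sortRanked(ranked)
    N <- nrow(ranked)
    w <- abs(ranked$score)^config$weight
    inList <- lapply(collection, function(m) which(ranked$id %in% m))
    sizes <- lengths(inList)
    keep <- sizes >= config$minSetSize
    skipped <- stats::setNames(
        ifelse(sizes[!keep] == 0, "empty intersection",
               sprintf("in-list size %d < %d", sizes[!keep],
                       config$minSetSize)),
        names(collection)[!keep])
    if (!any(keep)) {
        warning("no set passes the size filter (minSetSize = ",
                config$minSetSize, ")")
        res <- DataFrame(set = character(), size = integer(),
                         es = numeric(), nes = numeric(), p = numeric(),
                         fdr = numeric(), leadingEdge = character())
        metadata(res) <- list(skipped = skipped, config = config)
        return(res)
    }
    set.seed(config$seed)
    nms <- sort(names(collection)[keep])
    null <- .permNull(w, N, sort(unique(sizes[nms])), config$nPerm,
                      config$exhaustive)
    es <- nes <- p <- numeric(length(nms))
    le <- character(length(nms))
    permNES <- vector("list", length(nms))
    for (i in seq_along(nms)) {
        pos <- sort(inList[[nms[i]]])
        r <- .esFromPositions(w, pos, N)
        es[i] <- r$es
        le[i] <- paste(ranked$id[pos[r$hitIdx]], collapse = ",")
        perm <- null[[as.character(length(pos))]]
        posPerm <- perm[perm >= 0]; negPerm <- perm[perm < 0]
        if (es[i] >= 0) {
            p[i] <- if (length(posPerm)) mean(posPerm >= es[i]) else 1
            nes[i] <- if (length(posPerm) && mean(posPerm) > 0)
                es[i] / mean(posPerm) else NA_real_
        } else {
            p[i] <- if (length(negPerm)) mean(negPerm <= es[i]) else 1
            nes[i] <- if (length(negPerm)) es[i] / mean(abs(negPerm))
                      else NA_real_
        }
        pn <- rep(NA_real_, length(perm))
        if (length(posPerm) && mean(posPerm) > 0)
            pn[perm >= 0] <- posPerm / mean(posPerm)
        if (length(negPerm))
            pn[perm < 0] <- negPerm / mean(abs(negPerm))
        permNES[[i]] <- pn[!is.na(pn)]
    }
    allPerm <- unlist(permNES)
    fdr <- vapply(seq_along(nms), function(i) {
        if (is.na(nes[i])) return(NA_real_)
        if (nes[i] >= 0) {
            denomP <- sum(allPerm >= 0)
            num <- if (denomP) sum(allPerm >= nes[i]) / denomP else 0
            denO <- sum(nes >= 0, na.rm = TRUE)
            den <- if (denO) sum(nes >= nes[i], na.rm = TRUE) / denO else 1
        } else {
            denomP <- sum(allPerm < 0)
            num <- if (denomP) sum(allPerm <= nes[i]) / denomP else 0
            denO <- sum(nes < 0, na.rm = TRUE)
            den <- if (denO) sum(nes <= nes[i], na.rm = TRUE) / denO else 1
        }
        min(1, num / max(den, .Machine$double.eps))
    }, 0)
    res <- DataFrame(set = nms, size = as.integer(sizes[nms]), es = es,
                     nes = nes, p = p, fdr = fdr, leadingEdge = le)
    rownames(res) <- NULL
    metadata(res) <- list(skipped = skipped, config = config)
    res
}

#' Top enriched terms by NES
#'
#' The top `k` positively and negatively enriched sets (separately) among
#' those with permutation p below the report threshold; ordering is by
#' NES (descending magnitude) with ties broken on set name.
#'
#' @param results output of [gsea()].
#' @param k how many per direction (default 10).
#' @param pThreshold listing threshold on p (default from the run config,
#'   else 0.01).
#' @return `DataFrame` subset of `results` with a `direction` column
#'   (`"up"`/`"down"`).
#' @export
topTerms <- function(results, k = 10, pThreshold = NULL) {
    if (is.null(pThreshold)) {
        cfg <- metadata(results)$config
        pThreshold <- if (!is.null(cfg)) cfg$pThreshold else 0.01
    }
    if (!nrow(results)) stop("empty GSEA results")
    df <- as.data.frame(results)
    df <- df[!is.na(df$nes) & df$p < pThreshold, , drop = FALSE]
    up <- df[df$nes > 0, , drop = FALSE]
    up <- up[order(-up$nes, up$set), , drop = FALSE]
    down <- df[df$nes < 0, , drop = FALSE]
    down <- down[order(down$nes, down$set), , drop = FALSE]
    up <- utils::head(up, k); down <- utils::head(down, k)
    out <- rbind(up, down)
    out$direction <- rep(c("up", "down"), c(nrow(up), nrow(down)))
    res <- DataFrame(out)
    rownames(res) <- NULL
    res
}
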