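#' Occupancy filter: peptide quantified in >50% of samples of a condition
#'
#' A peptide is considered quantified if it is observed in strictly more
#' than `minFraction` (default one half) of the samples within at least one
#' condition; qualifying peptides keep all of their measurements across all
#' samples. The boundary is strict: 7 of 12 qualifies, 6 of 12 does not.
#'
#' Occupancy is evaluated per condition pooled across batches (the
#' reference condition is measured in both batches but modelled as one
#' condition); `perBatchBaseline = TRUE` instead evaluates the reference
#' condition separately within each batch.
#'
#' @param pe a [PeptideExperiment-class] with design attached.
#' @param minFraction occupancy threshold (strict inequality), default 0.5.
#' @param perBatchBaseline evaluate reference occupancy per batch.
#' @return list with `experiment` (the filtered table) and `report`
#'   (a [FilterReport-class]).
#' @export
filterPeptides <- function(pe, minFraction = 0.5, perBatchBaseline = FALSE) {
    .checkDesign(pe, need_reference = perBatchBaseline)
    obs <- !is.na(intensityMatrix(pe))
    cd <- colData(pe)
    group <- as.character(cd$condition)
    if (perBatchBaseline) {
        ref <- metadata(pe)$reference
        isref <- group == ref
        group[isref] <- paste(ref, cd$batch[isref], sep = "/")
    }
    glev <- unique(group)
    nPer <- vapply(glev, function(g) sum(group == g), 0L)
    if (any(nPer == 0)) stop("condition with 0 samples in design")
    cnt <- vapply(glev, function(g)
        rowSums(obs[, group == g, drop = FALSE]), numeric(nrow(pe)))
    cnt <- matrix(cnt, nrow = nrow(pe),
                  dimnames = list(NULL, glev))
    pass <- sweep(cnt, 2, minFraction * nPer, ">")
    keep <- rowSums(pass) > 0
    qual <- apply(pass, 1, function(r) {
        w <- which(r)
        if (length(w)) glev[w[1]] else NA_character_
    })
    protIn <- unique(proteinGroups(pe))
    filtered <- pe[keep, ]
    protOut <- unique(proteinGroups(filtered))
    report <- new("FilterReport",
        nPeptidesIn = nrow(pe), nPeptidesOut = sum(keep),
        nProteinsIn = length(protIn), nProteinsOut = length(protOut),
        peptideStatus = DataFrame(sequence = peptideSequences(pe),
                                  proteinGroup = proteinGroups(pe),
                                  retained = keep,
                                  qualifyingCondition = qual),
        proteinStatus = DataFrame(
            proteinGroup = protIn,
            nPeptides = as.integer(table(
                factor(proteinGroups(filtered), levels = protIn))),
            retained = protIn %in% protOut,
            reason = ifelse(protIn %in% protOut, NA_character_,
                            "no_quantified_peptides")))
    list(experiment = filtered, report = report)
}

#' Two-peptide rule: drop proteins with a single quantified peptide
#'
#' Proteins with at least `minPeptides` (default 2) surviving peptides are
#' retained; proteins with only one quantified peptide are excluded with
#' reason `"single_peptide"`.
#'
#' @param pe a peptide-filtered [PeptideExperiment-class].
#' @param minPeptides minimum peptides per protein, default 2.
#' @return list with `experiment` and `report` ([FilterReport-class]).
#' @export
filterProteins <- function(pe, minPeptides = 2L) {
    prots <- proteinGroups(pe)
    tb <- table(prots)
    keepProt <- names(tb)[tb >= minPeptides]
    keep <- prots %in% keepProt
    protIn <- unique(prots)
    report <- new("FilterReport",
        nPeptidesIn = nrow(pe), nPeptidesOut = sum(keep),
        nProteinsIn = length(protIn), nProteinsOut = length(keepProt),
        peptideStatus = DataFrame(sequence = peptideSequences(pe),
                                  proteinGroup = prots, retained = keep,
                                  qualifyingCondition = NA_character_),
        proteinStatus = DataFrame(
            proteinGroup = protIn,
            nPeptides = as.integer(tb[protIn]),
            retained = protIn %in% keepProt,
            reason = ifelse(protIn %in% keepProt, NA_character_,
                            "single_peptide")))
    list(experiment = pe[keep, ], report = report)
}

#' Apply both quantification filters with a combined report
#'
#' Runs [filterPeptides()] then [filterProteins()]; the combined protein
#' report distinguishes proteins that lost all peptides at the occupancy
#' stage (`"no_quantified_peptides"`) from proteins left with a single
#' peptide (`"single_peptide"`). The filter pair is idempotent.
#'
#' @inheritParams filterPeptides
#' @inheritParams filterProteins
#' @return list with `experiment` and `report`.
#' @export
applyQuantFilters <- function(pe, minFraction = 0.5, minPeptides = 2L,
                              perBatchBaseline = FALSE) {
    s1 <- filterPeptides(pe, minFraction, perBatchBaseline)
    s2 <- filterProteins(s1$experiment, minPeptides)
    protIn <- unique(proteinGroups(pe))
    protFinal <- unique(proteinGroups(s2$experiment))
    lostAll <- s1$report@proteinStatus$proteinGroup[
        !s1$report@proteinStatus$retained]
    reason <- rep(NA_character_, length(protIn))
    reason[protIn %in% lostAll] <- "no_quantified_peptides"
    reason[is.na(reason) & !(protIn %in% protFinal)] <- "single_peptide"
    report <- new("FilterReport",
        nPeptidesIn = nrow(pe), nPeptidesOut = nrow(s2$experiment),
        nProteinsIn = length(protIn), nProteinsOut = length(protFinal),
        peptideStatus = s1$report@peptideStatus,
        proteinStatus = DataFrame(
            proteinGroup = protIn,
            nPeptides = as.integer(table(factor(
                proteinGroups(s2$experiment), levels = protIn))),
            retained = protIn %in% protFinal, reason = reason))
    list(experiment = s2$experiment, report = report)
}

#' Serialize a FilterReport to TSV files
#'
#' @param report a [FilterReport-class].
#' @param outDir directory for `filter_peptides.tsv` / `filter_proteins.tsv`.
#' @return paths, invisibly.
#' @export
writeFilterReport <- function(report, outDir) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    p1 <- file.path(outDir, "filter_peptides.tsv")
    p2 <- file.path(outDir, "filter_proteins.tsv")
    utils::write.table(as.data.frame(report@peptideStatus), p1, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(report@proteinStatus), p2, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    message(sprintf("filters: %d/%d peptides, %d/%d proteins retained",
                    report@nPeptidesOut, report@nPeptidesIn,
                    report@nProteinsOut, report@nProteinsIn))
    invisible(c(p1, p2))
}
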