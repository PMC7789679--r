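#' Read a peptide-level intensity table
#'
#' Three dialects are accepted:
#' \describe{
#'   \item{`"maxquant"`}{a peptides.txt-style TSV with columns `Sequence`,
#'     `Proteins`, and one `Intensity <sample>` column per sample.}
#'   \item{`"long"`}{generic long format with columns
#'     `sequence`, `protein`, `sample`, `intensity`.}
#'   \item{`"evidence"`}{evidence.txt-style TSV with columns `Sequence`,
#'     `Proteins`, `Raw file`, `Intensity`; multiple evidence rows for the
#'     same peptide and sample are aggregated by summing.}
#' }
#' Intensities of 0 are coerced to missing (`NA`): MaxQuant reports 0 for
#' "not observed" and log2(0) is undefined. Duplicate
#' (sequence, protein) rows are rejected, naming the offending sequences.
#'
#' @param path file path.
#' @param dialect one of `"maxquant"`, `"long"`, `"evidence"`.
#' @param design optional design `data.frame` (see [readDesign()]); when
#'   supplied the samples are cross-checked and the reference recorded.
#' @param reference reference condition, used with `design`.
#' @return A [PeptideExperiment-class].
#' @export
readPeptideTable <- function(path, dialect = c("maxquant", "long", "evidence"),
                             design = NULL, reference = "baseline") {
    dialect <- match.arg(dialect)
    tab <- utils::read.delim(path, check.names = FALSE,
                             stringsAsFactors = FALSE)
    if (dialect == "maxquant") {
        for (col in c("Sequence", "Proteins"))
            if (!col %in% colnames(tab))
                stop("peptide table lacks mandatory column '", col, "'")
        icols <- grep("^Intensity ", colnames(tab), value = TRUE)
        if (!length(icols))
            stop("peptide table lacks 'Intensity <sample>' columns")
        m <- as.matrix(tab[, icols, drop = FALSE])
        .checkNumeric(m, icols)
        storage.mode(m) <- "double"
        colnames(m) <- sub("^Intensity ", "", icols)
        seqs <- tab$Sequence; prots <- tab$Proteins
    } else if (dialect == "long") {
        need <- c("sequence", "protein", "sample", "intensity")
        miss <- setdiff(need, colnames(tab))
        if (length(miss))
            stop("peptide table lacks mandatory column '", miss[1], "'")
        if (!is.numeric(tab$intensity)) {
            bad <- which(is.na(suppressWarnings(as.numeric(tab$intensity))) &
                         !is.na(tab$intensity))
            stop("non-numeric intensity at row(s): ",
                 paste(utils::head(bad, 5), collapse = ", "))
        }
        key <- paste(tab$sequence, tab$protein, sep = "\r")
        dupcell <- duplicated(paste(key, tab$sample, sep = "\r"))
        if (any(dupcell))
            stop("duplicated peptide/sample rows for sequence(s): ",
                 paste(unique(tab$sequence[dupcell]), collapse = ", "))
        peps <- unique(tab[, c("sequence", "protein")])
        samples <- unique(tab$sample)
        m <- matrix(NA_real_, nrow(peps), length(samples),
                    dimnames = list(NULL, samples))
        ridx <- match(paste(tab$sequence, tab$protein, sep = "\r"),
                      paste(peps$sequence, peps$protein, sep = "\r"))
        m[cbind(ridx, match(tab$sample, samples))] <- tab$intensity
        seqs <- peps$sequence; prots <- peps$protein
    } else { # evidence
        for (col in c("Sequence", "Proteins", "Raw file", "Intensity"))
            if (!col %in% colnames(tab))
                stop("evidence table lacks mandatory column '", col, "'")
        if (!is.numeric(tab$Intensity))
            stop("non-numeric intensity in evidence table")
        agg <- stats::aggregate(
            Intensity ~ Sequence + Proteins + `Raw file`, data = tab,
            FUN = sum, na.rm = TRUE, na.action = stats::na.pass)
        peps <- unique(agg[, c("Sequence", "Proteins")])
        samples <- unique(agg$`Raw file`)
        m <- matrix(NA_real_, nrow(peps), length(samples),
                    dimnames = list(NULL, samples))
        ridx <- match(paste(agg$Sequence, agg$Proteins, sep = "\r"),
                      paste(peps$Sequence, peps$Proteins, sep = "\r"))
        m[cbind(ridx, match(agg$`Raw file`, samples))] <- agg$Intensity
        m[is.nan(m)] <- NA_real_
        seqs <- peps$Sequence; prots <- peps$Proteins
    }
    key <- paste(seqs, prots, sep = "\r")
    if (anyDuplicated(key))
        stop("duplicated peptide row(s) for sequence(s): ",
             paste(unique(seqs[duplicated(key)]), collapse = ", "))
    PeptideExperiment(m, sequence = seqs, proteinGroup = prots,
                      design = design, reference = reference)
}

.checkNumeric <- function(m, cols) {
    for (j in seq_len(ncol(m))) {
        v <- m[, j]
        if (!is.numeric(v)) {
            bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))
            stop("non-numeric intensity in column '", cols[j],
                 "' at row(s): ", paste(utils::head(bad, 5), collapse = ", "))
        }
    }
}

#' Write a peptide table in the MaxQuant peptides.txt dialect
#'
#' Missing cells are written as 0, so `readPeptideTable(writePeptideTable(x))`
#' round-trips to an identical in-memory object.
#'
#' @param pe a [PeptideExperiment-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writePeptideTable <- function(pe, path) {
    m <- intensityMatrix(pe)
    m[is.na(m)] <- 0
    out <- data.frame(Sequence = peptideSequences(pe),
                      Proteins = proteinGroups(pe), check.names = FALSE)
    out[paste("Intensity", colnames(m))] <- as.data.frame(m)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read / write GMT gene-set files
#'
#' GMT is tab-separated: set name, description, then member ids. Duplicate
#' members within a line are deduplicated with a warning; lines with no
#' members are rejected.
#'
#' @param path file path.
#' @return `readGmt()`: a named list of character member vectors with a
#'   `description` attribute (named character).
#' @export
readGmt <- function(path) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    sets <- list(); desc <- character()
    for (i in seq_along(lines)) {
        f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
        if (length(f) < 3)
            stop("GMT line ", i, " has fewer than 3 fields")
        members <- f[-(1:2)]
        members <- members[nzchar(members)]
        if (!length(members))
            stop("GMT line ", i, " ('", f[1], "') has no members")
        if (anyDuplicated(members)) {
            warning("GMT set '", f[1], "' (line ", i,
                    ") has duplicate members; deduplicated")
            members <- unique(members)
        }
        sets[[f[1]]] <- members
        desc[f[1]] <- f[2]
    }
    attr(sets, "description") <- desc
    sets
}

#' @rdname readGmt
#' @param sets named list of character member vectors; an optional
#'   `description` attribute is carried through.
#' @return `writeGmt()`: `path`, invisibly.
#' @export
writeGmt <- function(sets, path) {
    desc <- attr(sets, "description")
    if (is.null(desc)) desc <- stats::setNames(rep("na", length(sets)),
                                               names(sets))
    lines <- vapply(names(sets), function(nm)
        paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t"), "")
    writeLines(lines, path)
    invisible(path)
}

#' Read a sample design table
#'
#' Expects a TSV with header `sample`, `donor`, `condition`, `batch`.
#'
#' @param path file path.
#' @param reference reference condition label; an error instructs to pass
#'   `reference=` when the label is absent from the condition column.
#' @return data.frame with attribute `reference`.
#' @export
readDesign <- function(path, reference = "baseline") {
    d <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("sample", "donor", "condition", "batch")
    miss <- setdiff(need, colnames(d))
    if (length(miss))
        stop("design lacks column(s): ", paste(miss, collapse = ", "))
    if (anyDuplicated(d$sample))
        stop("duplicated sample id(s): ",
             paste(unique(d$sample[duplicated(d$sample)]), collapse = ", "))
    if (!reference %in% d$condition)
        stop("reference condition '", reference, "' not found in the design; ",
             "pass the correct label via `reference=`")
    attr(d, "reference") <- reference
    d
}

#' Read a protein -> category map
#'
#' Two-column TSV (`protein`, `category`); categories restricted to the six
#' labels ECM, anabolic, catabolic, growth factor, immune system, other.
#'
#' @param path file path.
#' @return named character vector (protein -> category).
#' @export
readCategoryMap <- function(path) {
    d <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (ncol(d) < 2) stop("category map needs two columns: protein, category")
    colnames(d)[1:2] <- c("protein", "category")
    bad <- setdiff(unique(d$category), secretomeCategories())
    if (length(bad))
        stop("unknown categor(ies): ", paste(bad, collapse = ", "),
             "; allowed: ", paste(secretomeCategories(), collapse = ", "))
    stats::setNames(d$category, d$protein)
}

#' The six secretome protein categories
#' @return character vector of the allowed category labels.
#' @export
secretomeCategories <- function()
    c("ECM", "anabolic", "catabolic", "growth factor", "immune system",
      "other")

#' Read a plain per-condition protein list
#'
#' One protein id per line (the format written by [exportForNetwork()] and
#' the shape of deposited per-condition supplementary lists). Blank lines
#' are ignored.
#'
#' @param path file path.
#' @return character vector of ids.
#' @export
readProteinList <- function(path) {
    x <- readLines(path, warn = FALSE)
    x[nzchar(trimws(x))]
}

#' Hash a configuration for provenance
#'
#' Canonical-JSON serialization followed by MD5; the hash written into the
#' run metadata lets a reader confirm which configuration produced a
#' results directory.
#'
#' @param config any jsonlite-serializable list.
#' @return character MD5 hash.
#' @export
configHash <- function(config) {
    f <- tempfile()
    on.exit(unlink(f))
    writeLines(as.character(jsonlite::toJSON(
        config, auto_unbox = TRUE, digits = NA, force = TRUE)), f)
    unname(tools::md5sum(f))
}

#' Write result tables plus run metadata
#'
#' Each table is written as TSV with its given name and stable column
#' order; a `run_metadata.json` records the config hash, seed, and package
#' and R versions.
#'
#' @param tables named list of data.frame-like tables.
#' @param outDir output directory (created if needed).
#' @param config configuration list to hash into the metadata.
#' @param seed the run's root seed (recorded, not used).
#' @return character vector of file paths, invisibly.
#' @export
writeResults <- function(tables, outDir, config = list(), seed = NA_integer_) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    stopifnot(length(names(tables)) == length(tables))
    paths <- character()
    for (nm in names(tables)) {
        p <- file.path(outDir, paste0(nm, ".tsv"))
        utils::write.table(as.data.frame(tables[[nm]]), p, sep = "\t",
                           quote = FALSE, row.names = FALSE)
        paths <- c(paths, p)
    }
    meta <- list(config_hash = configHash(config), seed = seed,
                 r_version = as.character(getRversion()),
                 package_version = as.character(
                     utils::packageVersion("secretoscope")))
    mp <- file.path(outDir, "run_metadata.json")
    jsonlite::write_json(meta, mp, auto_unbox = TRUE, digits = NA)
    invisible(c(paths, mp))
}
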