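#' Read a log2 miRNA expression matrix from TSV
#'
#' The expected layout is a header row of sample ids and a first column of
#' miRNA ids; every remaining cell is a finite numeric log2-scale intensity.
#' The matrix is assumed to be already normalized and log2-transformed;
#' no normalization is performed here.
#'
#' @param path Path to a tab-separated file.
#' @return A numeric matrix, miRNAs in rows (rownames) and samples in
#'   columns (colnames), row and column order as in the file.
#' @export
read_expression_matrix <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("expression file needs a miRNA id column plus at least one sample column")
  mirna_ids <- raw[[1L]]
  sample_ids <- colnames(raw)[-1L]
  if (anyDuplicated(mirna_ids)) {
    dup <- unique(mirna_ids[duplicated(mirna_ids)])
    stop("duplicated miRNA id(s) in expression file: ", paste(dup, collapse = ", "))
  }
  if (anyDuplicated(sample_ids)) {
    dup <- unique(sample_ids[duplicated(sample_ids)])
    stop("duplicated sample id(s) in expression file: ", paste(dup, collapse = ", "))
  }
  vals <- suppressWarnings(vapply(raw[-1L], as.numeric, numeric(nrow(raw))))
  vals <- matrix(vals, nrow = nrow(raw), dimnames = list(mirna_ids, sample_ids))
  bad <- which(!is.finite(vals), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-numeric or missing expression value at miRNA '%s', sample '%s'",
                 mirna_ids[bad[1L, 1L]], sample_ids[bad[1L, 2L]]))
  }
  vals
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression_matrix()].
#'
#' @param expr Numeric matrix with rownames (miRNA ids) and colnames (sample ids).
#' @param path Output path.
#' @export
write_expression_matrix <- function(expr, path) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)), !is.null(colnames(expr)))
  df <- data.frame(mirna_id = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.group_levels <- c("nonsmoker", "smoker_baseline", "quitter")

#' Read and validate the sample metadata table
#'
#' Expects columns `sample_id`, `subject_id`, `group`, `gender`. Groups must
#' be one of `nonsmoker`, `smoker_baseline`, `quitter`; genders `M`/`F`.
#' The cohort is a paired cessation design: every quitter sample must share
#' its subject id with exactly one smoker_baseline sample.
#'
#' @param path Path to a tab-separated file.
#' @return A data.frame with the four validated columns; `group` is a factor
#'   with levels nonsmoker, smoker_baseline, quitter.
#' @export
read_sample_metadata <- function(path) {
  meta <- utils::read.delim(path, header = TRUE, sep = "\t",
                            colClasses = "character", stringsAsFactors = FALSE)
  validate_sample_metadata(meta)
}

#' Validate an in-memory sample metadata table
#'
#' @param meta data.frame with columns sample_id, subject_id, group, gender.
#' @return The validated data.frame with `group` as a factor.
#' @export
validate_sample_metadata <- function(meta) {
  need <- c("sample_id", "subject_id", "group", "gender")
  missing_cols <- setdiff(need, colnames(meta))
  if (length(missing_cols) > 0L)
    stop("metadata is missing column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(meta$sample_id))
    stop("duplicated sample_id in metadata")
  bad_group <- setdiff(unique(as.character(meta$group)), .group_levels)
  if (length(bad_group) > 0L)
    stop("unknown group label(s) ", paste(sQuote(bad_group), collapse = ", "),
         "; allowed: ", paste(.group_levels, collapse = ", "))
  bad_gender <- setdiff(unique(as.character(meta$gender)), c("M", "F"))
  if (length(bad_gender) > 0L)
    stop("unknown gender label(s) ", paste(sQuote(bad_gender), collapse = ", "),
         "; allowed: M, F")
  meta$group <- factor(as.character(meta$group), levels = .group_levels)
  # paired design: each quitter is the re-bronchoscoped baseline smoker
  q <- meta$subject_id[meta$group == "quitter"]
  s <- meta$subject_id[meta$group == "smoker_baseline"]
  unpaired <- setdiff(q, s)
  if (length(unpaired) > 0L)
    stop("quitter subject(s) with no smoker_baseline sample: ",
         paste(unpaired, collapse = ", "))
  multi <- names(which(table(s[s %in% q]) > 1L))
  if (length(multi) > 0L)
    stop("subject(s) with more than one smoker_baseline sample: ",
         paste(multi, collapse = ", "))
  meta[, need]
}

#' Read a GMT gene-set (or miRNA-set) file
#'
#' Standard GMT dialect: one set per line, fields tab-separated —
#' name, description, then members. Duplicate members within a set are
#' removed with a warning. The universe size is either supplied or derived
#' as the size of the union of all members (reported via the
#' `universe_derived` attribute).
#'
#' @param path Path to the GMT file.
#' @param universe_size Optional positive integer; the number of
#'   annotatable entities the sets are drawn from.
#' @return A list with elements `sets` (named list of character vectors) and
#'   `universe_size`; attribute `universe_derived` says whether the universe
#'   was derived from the union of members.
#' @export
read_gene_sets <- function(path, universe_size = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop(sprintf("GMT line %d: set '%s' has no members", i,
                   if (length(f) >= 1L) f[[1L]] else "<unnamed>"))
    members <- f[-(1:2)]
    members <- members[nzchar(members)]
    if (length(members) == 0L)
      stop(sprintf("GMT line %d: set '%s' has no members", i, f[[1L]]))
    if (anyDuplicated(members)) {
      warning(sprintf("GMT set '%s': duplicated member(s) removed", f[[1L]]))
      members <- unique(members)
    }
    sets[[f[[1L]]]] <- members
  }
  derived <- is.null(universe_size)
  if (derived) universe_size <- length(unique(unlist(sets, use.names = FALSE)))
  universe_size <- as.integer(universe_size)
  if (universe_size < 1L) stop("universe_size must be a positive integer")
  too_big <- names(sets)[vapply(sets, length, 1L) > universe_size]
  if (length(too_big) > 0L)
    stop("set(s) larger than the universe (", universe_size, "): ",
         paste(too_big, collapse = ", "))
  structure(list(sets = sets, universe_size = universe_size),
            universe_derived = derived)
}

#' Write a named list of sets as GMT
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @export
write_gene_sets <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
}

#' Read a miRNA-to-target-gene map
#'
#' Two-column TSV (`mirna_id`, `gene_id`), as exported from a target
#' prediction database. Duplicate pairs are collapsed.
#'
#' @param path Path to the TSV file.
#' @param header Does the file carry a header row? Default TRUE.
#' @return data.frame with columns mirna_id, gene_id, deduplicated.
#' @export
read_target_map <- function(path, header = TRUE) {
  lines <- readLines(path, warn = FALSE)
  if (header && length(lines) > 0L) lines <- lines[-1L]
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(data.frame(mirna_id = character(0), gene_id = character(0),
                      stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf != 2L)
  if (length(bad) > 0L)
    stop(sprintf("target map line %d: expected 2 tab-separated columns, found %d",
                 bad[1L] + as.integer(header), nf[bad[1L]]))
  df <- data.frame(mirna_id = vapply(parts, `[[`, "", 1L),
                   gene_id = vapply(parts, `[[`, "", 2L),
                   stringsAsFactors = FALSE)
  unique(df)
}

#' Read a gene RPKM table
#'
#' Two-column TSV (`gene_id`, `rpkm`). RPKM values must be finite and
#' non-negative.
#'
#' @param path Path to the TSV file.
#' @return Named numeric vector of RPKM values keyed by gene id.
#' @export
read_rpkm_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("RPKM table needs columns gene_id, rpkm")
  rpkm <- suppressWarnings(as.numeric(df[[2L]]))
  if (any(!is.finite(rpkm)) || any(rpkm < 0))
    stop("RPKM values must be finite and non-negative")
  if (anyDuplicated(df[[1L]])) stop("duplicated gene_id in RPKM table")
  stats::setNames(rpkm, df[[1L]])
}

#' Load a differential-expression table transcribed from the published study
#'
#' `"table2"` is the 34-miRNA smoking signature (smokers vs nonsmokers,
#' 25 up / 9 down); `"table4"` is the 12-miRNA cessation-persistent subset
#' (quitters vs nonsmokers, 7 up / 5 down). Probe ids keep their Affymetrix
#' `_st` suffixes; fold-changes are signed with magnitude >= 1 as printed
#' (rounded to one decimal).
#'
#' @param name Either `"table2"` or `"table4"`.
#' @return data.frame with columns probeset_id, fold_change, p_value,
#'   direction.
#' @export
load_fixture_table <- function(name) {
  files <- c(table2 = "table2_smoking_mirnas.tsv",
             table4 = "table4_persistent_mirnas.tsv")
  if (!is.character(name) || length(name) != 1L || !name %in% names(files))
    stop("unknown fixture name; valid names: ", paste(names(files), collapse = ", "))
  path <- system.file("extdata", files[[name]], package = "saemir", mustWork = TRUE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  df$fold_change <- as.numeric(df$fold_change)
  df$p_value <- as.numeric(df$p_value)
  df
}

#' Write a results table as TSV
#' @param df data.frame of results.
#' @param path Output path.
#' @export
write_results_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a results table written by [write_results_table()]
#' @param path Path to the TSV file.
#' @return data.frame.
#' @export
read_results_table <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
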