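#' Over-representation of a query set in each annotation category
#'
#' For each set: k = query members in the set, percent = 100 * k / K with
#' K the set size, fold enrichment = (k/m) / (K/N) with m the query size
#' and N the universe size, and the hypergeometric upper-tail p,
#' P[X >= k] — identical to a one-sided Fisher exact test for
#' over-representation. Results are ranked by ascending p.
#'
#' @param query Character vector of miRNA (or gene) ids. Members outside
#'   the universe are dropped with a warning when `universe` is given.
#' @param collection A gene-set collection from [read_gene_sets()] or
#'   [generate_annotation_resources()] (list with `sets`, `universe_size`).
#' @param universe Optional character vector enumerating the universe; when
#'   supplied it defines membership and overrides `universe_size`.
#' @return data.frame: set_name, set_size, count, percent, fold_enrichment,
#'   p_value, ordered by p_value.
#' @export
category_enrichment <- function(query, collection, universe = NULL) {
  sets <- collection$sets
  if (!is.null(universe)) {
    N <- length(unique(universe))
    outside <- setdiff(query, universe)
    if (length(outside) > 0L) {
      warning(length(outside), " query member(s) outside the universe dropped")
      query <- intersect(query, universe)
    }
  } else {
    N <- collection$universe_size
  }
  query <- unique(query)
  m <- length(query)
  if (m == 0L) stop("empty query after universe intersection")
  if (m > N) stop("query larger than the universe")
  res <- do.call(rbind, lapply(names(sets), function(nm) {
    members <- sets[[nm]]
    K <- length(members)
    k <- length(intersect(query, members))
    data.frame(set_name = nm, set_size = K, count = k,
               percent = 100 * k / K,
               fold_enrichment = (k / m) / (K / N),
               p_value = stats::phyper(k - 1L, K, N - K, m, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }))
  res <- res[order(res$p_value), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Filter a target map to genes expressed above an RPKM threshold
#'
#' Keeps (miRNA, gene) pairs whose gene has RPKM strictly greater than
#' `cfg$rpkm_min`; genes absent from the RPKM table are dropped.
#'
#' @param target_map data.frame (mirna_id, gene_id).
#' @param rpkm Named numeric vector of RPKM values.
#' @param cfg A [threshold_config()] (threshold `rpkm_min`, default 0.125).
#' @return The filtered target map.
#' @export
filter_targets_by_expression <- function(target_map, rpkm,
                                         cfg = threshold_config()) {
  stopifnot(inherits(cfg, "threshold_config"))
  v <- rpkm[target_map$gene_id]
  keep <- !is.na(v) & v > cfg$rpkm_min
  out <- target_map[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Target-gene summary and pathway enrichment for persistent miRNAs
#'
#' Counts expression-filtered predicted targets per persistent miRNA, pools
#' them (deduplicated), and tests each pathway for over-representation of
#' the pooled set by the hypergeometric upper tail, reporting the coverage
#' ratio (pooled targets in pathway / pathway size). The default universe
#' is the expressed (filtered) gene list.
#'
#' @param cessation data.frame from [run_cessation()] or
#'   [classify_persistence()] (columns mirna_id, persistent).
#' @param target_map Expression-filtered target map.
#' @param pathways Gene-set collection (list with `sets`, `universe_size`).
#' @param universe Optional character vector of universe genes; defaults to
#'   the distinct genes of `target_map`... see Details.
#' @details When `universe` is NULL the pathway universe is
#'   `pathways$universe_size` and membership is not checked; supply the
#'   expressed gene list to restrict the universe to expressed genes.
#' @return list with `per_mirna` (mirna_id, n_targets), `pooled_targets`
#'   (character), `pathway` (data.frame: set_name, set_size, count,
#'   coverage_ratio, fold_enrichment, p_value, ranked by p).
#' @export
collect_persistent_targets <- function(cessation, target_map, pathways,
                                       universe = NULL) {
  pers <- cessation$mirna_id[cessation$persistent]
  if (length(pers) == 0L) stop("no persistent miRNAs")
  counts <- vapply(pers, function(mi)
    length(unique(target_map$gene_id[target_map$mirna_id == mi])), integer(1L))
  zero <- pers[counts == 0L]
  if (length(zero) > 0L)
    warning("persistent miRNA(s) with zero filtered targets: ",
            paste(zero, collapse = ", "))
  pooled <- unique(target_map$gene_id[target_map$mirna_id %in% pers])
  enr <- category_enrichment(pooled, pathways, universe = universe)
  enr$coverage_ratio <- enr$count / enr$set_size
  enr <- enr[, c("set_name", "set_size", "count", "coverage_ratio",
                 "fold_enrichment", "p_value")]
  list(per_mirna = data.frame(mirna_id = pers, n_targets = counts,
                              stringsAsFactors = FALSE, row.names = NULL),
       pooled_targets = pooled,
       pathway = enr)
}
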