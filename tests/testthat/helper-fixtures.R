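# Shared in-code fixtures for the suite.

# Tiny three-group metadata with paired quitters.
toy_meta <- function(n_ns = 4L, n_sm = 4L, quitters = TRUE) {
  ns <- sprintf("NS%02d", seq_len(n_ns))
  sm <- sprintf("S%02d", seq_len(n_sm))
  ids <- c(ns, paste0(sm, "_b"), if (quitters) paste0(sm, "_q"))
  data.frame(
    sample_id = ids,
    subject_id = c(ns, sm, if (quitters) sm),
    group = c(rep("nonsmoker", n_ns), rep("smoker_baseline", n_sm),
              if (quitters) rep("quitter", n_sm)),
    gender = c(rep_len(c("M", "F"), n_ns), rep_len(c("M", "F"), n_sm),
               if (quitters) rep_len(c("M", "F"), n_sm)),
    stringsAsFactors = FALSE)
}

# Gaussian matrix matched to a metadata table, no planted effects.
toy_matrix <- function(meta, n_mirna = 6L, seed = 1L, sd = 0.5, mean = 7) {
  set.seed(seed)
  m <- matrix(stats::rnorm(n_mirna * nrow(meta), mean, sd), n_mirna,
              dimnames = list(sprintf("mir-%03d", seq_len(n_mirna)),
                              meta$sample_id))
  m
}

# Exact hypergeometric upper tail by exhaustive enumeration of all
# size-m query draws from a universe of size N (feasible for N <= 12).
enum_hyper_upper <- function(k, K, N, m) {
  universe <- seq_len(N)
  inset <- seq_len(K)
  draws <- utils::combn(N, m)
  hits <- apply(draws, 2L, function(d) sum(d %in% inset))
  mean(hits >= k)
}

# Brute-force average-linkage agglomeration: returns the sequence of
# merged cluster member sets, smallest-average-distance pair first.
brute_average_agglomeration <- function(d) {
  d <- as.matrix(d)
  clusters <- lapply(seq_len(nrow(d)), identity)
  merges <- list()
  while (length(clusters) > 1L) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      avg <- mean(d[clusters[[i]], clusters[[j]]])
      if (avg < best_d) { best_d <- avg; best <- c(i, j) }
    }
    merged <- sort(c(clusters[[best[1L]]], clusters[[best[2L]]]))
    merges[[length(merges) + 1L]] <- merged
    clusters <- c(clusters[-best], list(merged))
  }
  merges
}

# Member sets produced by an hclust merge matrix, in merge order.
hclust_merge_sets <- function(hc) {
  sets <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    members <- unlist(lapply(hc$merge[i, ], function(x)
      if (x < 0) -x else sets[[x]]))
    sets[[i]] <- sort(members)
  }
  sets
}
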