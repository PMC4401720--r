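#' Percent change (reversibility) of a smoking-dependent miRNA
#'
#' Quantifies how far expression returned toward the nonsmoker level after
#' cessation, on linear-scale group means:
#' 100 * (smoker mean - quitter mean) / (smoker mean - nonsmoker mean).
#' 100 means full return to the nonsmoker level, 0 no change; values can
#' exceed 100 (overshoot) or be negative (further departure). The statistic
#' is direction-agnostic: negating all three means leaves it unchanged.
#'
#' @param mean_ns,mean_s,mean_q Group mean expression (linear scale) for
#'   nonsmokers, baseline smokers, quitters. Vectorised.
#' @param rel_tol Relative tolerance below which the denominator
#'   (smoker - nonsmoker difference) is treated as degenerate.
#' @return Numeric vector of percent changes; NA where the denominator is
#'   degenerate (flagged, not an error).
#' @export
percent_change <- function(mean_ns, mean_s, mean_q, rel_tol = 1e-9) {
  if (any(!is.finite(c(mean_ns, mean_s, mean_q)))) stop("group means must be finite")
  den <- mean_s - mean_ns
  scale <- pmax(abs(mean_s), abs(mean_ns), 1)
  out <- ifelse(abs(den) < rel_tol * scale, NA_real_,
                100 * (mean_s - mean_q) / den)
  out
}

#' Classify smoking-dependent miRNAs as cessation-persistent or reversible
#'
#' A signature miRNA is cessation-persistent when it still differs between
#' quitters and nonsmokers at p < `persist_p` with |fold-change| >
#' `persist_fc` (strict); otherwise it is reversible. A persistent call
#' whose quitter-contrast direction disagrees with the smoking-signature
#' direction is flagged in `direction_match`.
#'
#' @param signature data.frame of smoking-dependent miRNAs (from
#'   [select_smoking_dependent()]), with columns `mirna_id`-like id,
#'   `direction`.
#' @param quitter_records data.frame from [run_diffexp()] for the
#'   quitter_vs_nonsmoker contrast (all signature miRNAs must be present).
#' @param cfg A [threshold_config()].
#' @param id_col Id column name shared by the two tables.
#' @param printed_decimals As in [select_smoking_dependent()]: widen the
#'   fold-change gate by half an ulp of the printed precision when gating
#'   values transcribed from print.
#' @return data.frame with columns mirna_id, direction, quitter_fc,
#'   quitter_p, persistent, direction_match.
#' @export
classify_persistence <- function(signature, quitter_records,
                                 cfg = threshold_config(), id_col = "mirna_id",
                                 printed_decimals = NULL) {
  stopifnot(inherits(cfg, "threshold_config"))
  ids <- signature[[id_col]]
  m <- match(ids, quitter_records[[id_col]])
  if (anyNA(m))
    stop("signature miRNA(s) absent from quitter records: ",
         paste(ids[is.na(m)], collapse = ", "))
  qfc <- quitter_records$fold_change[m]
  qp <- quitter_records$p_value[m]
  fc_thr <- cfg$persist_fc
  if (!is.null(printed_decimals)) fc_thr <- fc_thr - 0.5 * 10^(-printed_decimals)
  persistent <- (qp < cfg$persist_p) & (abs(qfc) > fc_thr)
  q_dir <- ifelse(qfc >= 0, "up", "down")
  out <- data.frame(mirna_id = ids, direction = signature$direction,
                    quitter_fc = qfc, quitter_p = qp,
                    persistent = persistent,
                    direction_match = !persistent | (q_dir == signature$direction),
                    stringsAsFactors = FALSE)
  if (any(!out$direction_match))
    warning("persistent call(s) with direction opposite to the smoking signature: ",
            paste(out$mirna_id[!out$direction_match], collapse = ", "))
  out
}

#' Full cessation analysis for a three-group cohort
#'
#' Computes the quitter-vs-nonsmoker LSD contrasts from the same
#' three-group + gender ANOVA used for the smoking signature, classifies
#' persistence, and attaches the percent-change reversibility statistic
#' computed from linear-scale (anti-logged) group means.
#'
#' @param expr log2 expression matrix (all miRNAs or the signature subset).
#' @param meta Metadata data.frame aligned with `expr` columns.
#' @param signature Output of [select_smoking_dependent()] over the
#'   smoker_vs_nonsmoker contrast.
#' @param cfg A [threshold_config()].
#' @param include_gender Fit the gender covariate (default TRUE).
#' @return data.frame: mirna_id, direction, quitter_fc, quitter_p,
#'   persistent, direction_match, percent_change, percent_change_defined.
#' @export
run_cessation <- function(expr, meta, signature, cfg = threshold_config(),
                          include_gender = TRUE) {
  quitter <- run_diffexp(expr, meta, "quitter_vs_nonsmoker",
                         include_gender = include_gender)
  out <- classify_persistence(signature, quitter, cfg)
  sub <- expr[out$mirna_id, , drop = FALSE]
  lin <- 2^sub
  grp_mean <- function(g) rowMeans(lin[, meta$group == g, drop = FALSE])
  pc <- percent_change(grp_mean("nonsmoker"), grp_mean("smoker_baseline"),
                       grp_mean("quitter"))
  out$percent_change <- pc
  out$percent_change_defined <- !is.na(pc)
  out
}

#' Fraction of miRNAs reversing less than each cutoff
#'
#' For each cutoff c, the percentage of miRNAs (with a defined percent
#' change) whose percent change is strictly below c — the reversal curve.
#'
#' @param percent_changes Numeric vector (NAs, i.e. undefined records,
#'   are dropped).
#' @param cutoffs Numeric vector of percent cutoffs.
#' @return data.frame with columns cutoff and fraction_below (percent).
#' @export
reversal_fraction_curve <- function(percent_changes, cutoffs = c(25, 50)) {
  pc <- percent_changes[!is.na(percent_changes)]
  if (length(pc) == 0L) stop("no defined percent-change values")
  data.frame(cutoff = cutoffs,
             fraction_below = vapply(cutoffs, function(cc) 100 * mean(pc < cc),
                                     numeric(1L)))
}

#' Nonsmoker expression quartiles per signature miRNA
#'
#' First and third quartiles of nonsmoker expression, interpolated so the
#' k-th of n sorted values sits at probability (k-1)/(n-1) (R quantile
#' type 7).
#'
#' @param expr log2 expression matrix.
#' @param meta Metadata aligned with `expr` columns; needs >= 4 nonsmokers.
#' @param signature_ids miRNA ids to compute thresholds for.
#' @return data.frame with columns mirna_id, q1, q3.
#' @export
nonsmoker_quartiles <- function(expr, meta, signature_ids) {
  ns <- meta$group == "nonsmoker"
  if (sum(ns) < 4L) stop("need at least 4 nonsmoker samples for quartiles")
  missing_ids <- setdiff(signature_ids, rownames(expr))
  if (length(missing_ids) > 0L)
    stop("signature miRNA(s) absent from the matrix: ",
         paste(missing_ids, collapse = ", "))
  sub <- expr[signature_ids, ns, drop = FALSE]
  q <- t(apply(sub, 1L, stats::quantile, probs = c(0.25, 0.75),
               names = FALSE, type = 7))
  data.frame(mirna_id = signature_ids, q1 = q[, 1L], q3 = q[, 2L],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Smoking-dependent miRNA index for one sample
#'
#' Counts signature miRNAs exceeding their nonsmoker quartile threshold in
#' the smoking direction: an up-regulated signature miRNA scores 1 when the
#' sample value is strictly above the nonsmoker third quartile, a
#' down-regulated one when strictly below the first quartile; values
#' exactly at a threshold score 0.
#'
#' @param sample_expr Named numeric vector of log2 values for one sample.
#' @param directions Character vector (up/down) per signature miRNA,
#'   aligned with `thresholds`.
#' @param thresholds data.frame from [nonsmoker_quartiles()].
#' @return Integer index in [0, number of signature miRNAs].
#' @export
subject_index <- function(sample_expr, directions, thresholds) {
  ids <- thresholds$mirna_id
  if (length(directions) != length(ids))
    stop("directions must align with thresholds rows")
  missing_ids <- setdiff(ids, names(sample_expr))
  if (length(missing_ids) > 0L)
    stop("sample is missing signature miRNA(s): ",
         paste(missing_ids, collapse = ", "))
  v <- sample_expr[ids]
  e <- ifelse(directions == "up", v > thresholds$q3, v < thresholds$q1)
  as.integer(sum(e))
}

#' Smoking-dependent miRNA index for every sample in a cohort
#'
#' @param expr log2 expression matrix.
#' @param meta Metadata aligned with `expr` columns.
#' @param signature data.frame with the signature ids (`mirna_id`) and
#'   `direction` column.
#' @param thresholds Optional precomputed [nonsmoker_quartiles()]; computed
#'   from the nonsmokers of this cohort when NULL.
#' @return data.frame with columns sample_id, group, index.
#' @export
compute_index <- function(expr, meta, signature, thresholds = NULL) {
  if (is.null(thresholds))
    thresholds <- nonsmoker_quartiles(expr, meta, signature$mirna_id)
  idx <- vapply(seq_len(ncol(expr)), function(j)
    subject_index(expr[, j], signature$direction, thresholds), integer(1L))
  data.frame(sample_id = meta$sample_id, group = as.character(meta$group),
             index = idx, stringsAsFactors = FALSE)
}

# Dunn's z for groups i, j given pooled mean ranks, total N and tie term.
.dunn_z <- function(rbar_i, rbar_j, n_i, n_j, N, tie_sum) {
  se <- sqrt(((N * (N + 1) / 12) - tie_sum / (12 * (N - 1))) * (1 / n_i + 1 / n_j))
  (rbar_i - rbar_j) / se
}

#' Compare the miRNA index across groups (Kruskal-Wallis + Dunn)
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square p on (groups - 1)
#' degrees of freedom, followed by Dunn's pairwise z tests on the pooled
#' ranks. Dunn p values are two-sided and unadjusted; a Bonferroni-adjusted
#' column is reported alongside.
#'
#' @param indices data.frame from [compute_index()] (columns `group`,
#'   `index`), or any data.frame with those columns.
#' @return list with `H`, `df`, `p` and `pairs` (data.frame: group_a,
#'   group_b, z, p, p_bonferroni).
#' @export
index_group_comparison <- function(indices) {
  g <- factor(indices$group)
  x <- indices$index
  tab <- table(g)
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  if (any(tab < 2L))
    stop("group(s) with fewer than 2 subjects: ",
         paste(names(tab)[tab < 2L], collapse = ", "))
  all_tied <- length(unique(x)) == 1L
  if (all_tied) {
    # a single tie group carries no rank information: H = 0 by convention
    kw <- list(statistic = c(`Kruskal-Wallis chi-squared` = 0),
               parameter = c(df = nlevels(g) - 1L), p.value = 1)
  } else {
    kw <- stats::kruskal.test(x, g)
  }
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  ties <- table(x)
  tie_sum <- sum(ties^3 - ties)
  combos <- utils::combn(levels(g), 2L)
  pairs <- data.frame(group_a = combos[1L, ], group_b = combos[2L, ],
                      stringsAsFactors = FALSE)
  pairs$z <- if (all_tied) rep(0, nrow(pairs)) else mapply(function(a, b)
    .dunn_z(rbar[[a]], rbar[[b]], tab[[a]], tab[[b]], N, tie_sum),
    pairs$group_a, pairs$group_b)
  pairs$p <- 2 * stats::pnorm(abs(pairs$z), lower.tail = FALSE)
  pairs$p_bonferroni <- pmin(1, pairs$p * nrow(pairs))
  list(H = unname(kw$statistic), df = unname(kw$parameter),
       p = kw$p.value, pairs = pairs)
}
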