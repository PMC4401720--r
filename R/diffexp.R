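#' Threshold configuration for the selection and persistence gates
#'
#' Defaults are the published criteria: smoking-dependent selection at
#' p < 0.01 with |fold-change| > 1.5; cessation persistence at p < 0.05
#' with |fold-change| > 1.5; expressed-gene filter at RPKM > 0.125.
#' All inequalities are strict.
#'
#' @param de_p,de_fc Selection gate: p threshold and fold-change threshold.
#' @param persist_p,persist_fc Persistence gate thresholds.
#' @param rpkm_min Expressed-gene RPKM threshold.
#' @return list of class `threshold_config`.
#' @export
threshold_config <- function(de_p = 0.01, de_fc = 1.5,
                             persist_p = 0.05, persist_fc = 1.5,
                             rpkm_min = 0.125) {
  cfg <- list(de_p = de_p, de_fc = de_fc, persist_p = persist_p,
              persist_fc = persist_fc, rpkm_min = rpkm_min)
  if (any(vapply(cfg, function(x) !is.numeric(x) || x <= 0, TRUE)))
    stop("all thresholds must be positive numbers")
  if (de_fc <= 1 || persist_fc <= 1) stop("fold-change thresholds must exceed 1")
  class(cfg) <- "threshold_config"
  cfg
}

# Residual sum of squares for each feature (rows of expr) under a design
# matrix, via QR. Returns a vector across features.
.rss <- function(expr, X) {
  fit <- stats::lm.fit(X, t(expr))
  colSums(as.matrix(fit$residuals)^2)
}

# Vectorised two-factor (group + gender) ANOVA across all features.
# Type II sums of squares for the additive unbalanced design:
#   SS(group | gender) = RSS(~gender) - RSS(~group+gender)
#   SS(gender | group) = RSS(~group)  - RSS(~group+gender)
.anova_stats <- function(expr, meta, include_gender = TRUE) {
  group <- droplevels(factor(meta$group, levels = .group_levels))
  if (nlevels(group) < 2L) stop("need at least 2 groups")
  tab <- table(group)
  if (any(tab < 2L))
    stop("group(s) with fewer than 2 samples: ",
         paste(names(tab)[tab < 2L], collapse = ", "))
  gender <- factor(meta$gender, levels = c("M", "F"))
  if (include_gender && nlevels(droplevels(gender)) < 2L)
    stop("both genders must be present to fit the gender term")

  df_group <- nlevels(group) - 1L
  n <- ncol(expr)
  if (include_gender) {
    X_full <- stats::model.matrix(~ group + gender)
    rss_full <- .rss(expr, X_full)
    rss_no_group <- .rss(expr, stats::model.matrix(~ gender))
    rss_no_gender <- .rss(expr, stats::model.matrix(~ group))
    df_res <- n - 1L - df_group - 1L
    mse <- rss_full / df_res
    gender_f <- (rss_no_gender - rss_full) / 1L / mse
    gender_p <- stats::pf(gender_f, 1L, df_res, lower.tail = FALSE)
  } else {
    rss_full <- .rss(expr, stats::model.matrix(~ group))
    rss_no_group <- .rss(expr, matrix(1, n, 1L))
    df_res <- n - 1L - df_group
    mse <- rss_full / df_res
    gender_f <- gender_p <- rep(NA_real_, nrow(expr))
  }
  if (df_res < 1L) stop("no residual degrees of freedom in this design")
  group_f <- (rss_no_group - rss_full) / df_group / mse
  group_p <- stats::pf(group_f, df_group, df_res, lower.tail = FALSE)

  means <- t(apply(expr, 1L, function(v) tapply(v, group, mean)))
  if (nrow(expr) == 1L) means <- matrix(means, 1L, dimnames = list(rownames(expr), levels(group)))

  list(group_f = group_f, group_p = group_p,
       gender_f = gender_f, gender_p = gender_p,
       mse = mse, df_res = df_res,
       group_means = means, group_n = as.integer(tab),
       groups = levels(group))
}

#' Two-factor ANOVA (group + gender) for a single miRNA
#'
#' Additive model, no interaction, Type II sums of squares so factor order
#' does not matter in the unbalanced design. Keeps the residual mean square
#' and residual degrees of freedom for the Fisher LSD contrasts.
#'
#' @param expr_row Numeric vector of log2 values, one per sample.
#' @param meta Metadata data.frame aligned with `expr_row` (columns
#'   `group`, `gender`).
#' @param include_gender Fit the gender covariate (default TRUE).
#' @return list of class `anova_fit`: per-factor F and p, `mse`, `df_res`,
#'   per-group means and sizes.
#' @export
fit_group_gender_anova <- function(expr_row, meta, include_gender = TRUE) {
  if (!is.numeric(expr_row) || any(!is.finite(expr_row)))
    stop("expr_row must be finite numeric")
  if (length(expr_row) != nrow(meta))
    stop("expr_row length must match the number of metadata rows")
  expr <- matrix(expr_row, nrow = 1L)
  s <- .anova_stats(expr, meta, include_gender = include_gender)
  if (s$mse[1L] <= .Machine$double.eps * mean(expr_row^2 + 1))
    stop("degenerate fit: zero residual variance")
  fit <- list(group_f = s$group_f[1L], group_p = s$group_p[1L],
              gender_f = s$gender_f[1L], gender_p = s$gender_p[1L],
              mse = s$mse[1L], df_res = s$df_res,
              group_means = stats::setNames(as.numeric(s$group_means[1L, ]), s$groups),
              group_n = stats::setNames(s$group_n, s$groups))
  class(fit) <- "anova_fit"
  fit
}

#' Fisher's least-significant-difference contrast between two groups
#'
#' Pairwise t contrast using the pooled residual variance of the full
#' ANOVA: t = (mean_a - mean_b) / sqrt(MSE * (1/n_a + 1/n_b)), two-sided p
#' on the ANOVA residual degrees of freedom. No family-wise adjustment.
#'
#' @param fit An `anova_fit` from [fit_group_gender_anova()].
#' @param group_a,group_b Group labels present in the fit.
#' @return list with `log2_diff` (mean_a - mean_b), `t` and `p`.
#' @export
lsd_contrast <- function(fit, group_a, group_b) {
  stopifnot(inherits(fit, "anova_fit"))
  for (g in c(group_a, group_b))
    if (!g %in% names(fit$group_means))
      stop("unknown group label: ", g)
  d <- fit$group_means[[group_a]] - fit$group_means[[group_b]]
  se <- sqrt(fit$mse * (1 / fit$group_n[[group_a]] + 1 / fit$group_n[[group_b]]))
  tt <- d / se
  list(log2_diff = d, t = tt,
       p = 2 * stats::pt(abs(tt), fit$df_res, lower.tail = FALSE))
}

#' Signed fold-change from a log2 difference
#'
#' Ratio convention with magnitudes >= 1: r = 2^log2_diff; the fold-change
#' is r when r >= 1 and -1/r otherwise, so a halving is written -2.0 and no
#' change is +1.0.
#'
#' @param log2_diff Numeric vector of log2 differences.
#' @return Numeric vector of signed fold-changes.
#' @export
signed_fold_change <- function(log2_diff) {
  if (any(!is.finite(log2_diff))) stop("log2_diff must be finite")
  r <- 2^log2_diff
  ifelse(r >= 1, r, -1 / r)
}

.contrast_pairs <- list(
  smoker_vs_nonsmoker = c("smoker_baseline", "nonsmoker"),
  quitter_vs_nonsmoker = c("quitter", "nonsmoker"),
  smoker_vs_quitter = c("smoker_baseline", "quitter"))

#' Per-miRNA differential expression for one group contrast
#'
#' Fits the additive group + gender ANOVA to every miRNA (all groups present
#' in the metadata enter the model) and extracts the Fisher LSD contrast
#' named by `contrast`. Benjamini-Hochberg q-values are reported as an
#' informational column; the selection gates use raw p.
#'
#' @param expr log2 expression matrix, miRNAs x samples.
#' @param meta Metadata data.frame; rows must match `colnames(expr)`.
#' @param contrast One of `"smoker_vs_nonsmoker"`, `"quitter_vs_nonsmoker"`,
#'   `"smoker_vs_quitter"`.
#' @param include_gender Fit the gender covariate (default TRUE).
#' @return data.frame with columns mirna_id, contrast, log2_diff,
#'   fold_change, p_value, q_value, direction (up/down), anova_group_p,
#'   anova_gender_p.
#' @export
run_diffexp <- function(expr, meta, contrast = "smoker_vs_nonsmoker",
                        include_gender = TRUE) {
  contrast <- match.arg(contrast, names(.contrast_pairs))
  if (ncol(expr) != nrow(meta)) stop("expr columns and metadata rows must align")
  if (!is.null(colnames(expr)) && !identical(colnames(expr), meta$sample_id))
    stop("expr column order must match metadata sample_id order")
  pair <- .contrast_pairs[[contrast]]
  s <- .anova_stats(expr, meta, include_gender = include_gender)
  if (!all(pair %in% s$groups))
    stop("contrast ", contrast, " needs groups ", paste(pair, collapse = " and "))
  zero_var <- which(s$mse <= .Machine$double.eps)
  if (length(zero_var) > 0L)
    stop("degenerate fit (zero residual variance) for miRNA(s): ",
         paste(rownames(expr)[utils::head(zero_var, 5L)], collapse = ", "))
  d <- s$group_means[, pair[1L]] - s$group_means[, pair[2L]]
  n <- stats::setNames(s$group_n, s$groups)
  se <- sqrt(s$mse * (1 / n[[pair[1L]]] + 1 / n[[pair[2L]]]))
  tt <- d / se
  p <- 2 * stats::pt(abs(tt), s$df_res, lower.tail = FALSE)
  data.frame(mirna_id = rownames(expr), contrast = contrast,
             log2_diff = as.numeric(d),
             fold_change = signed_fold_change(as.numeric(d)),
             p_value = as.numeric(p),
             q_value = stats::p.adjust(as.numeric(p), method = "BH"),
             direction = ifelse(d >= 0, "up", "down"),
             anova_group_p = as.numeric(s$group_p),
             anova_gender_p = as.numeric(s$gender_p),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Select smoking-dependent miRNAs
#'
#' Applies the published selection gate — p < `de_p` AND |fold-change| >
#' `de_fc`, strict inequalities — and orders the survivors up-regulated
#' first, by descending |fold-change| within direction (stable sort).
#'
#' For tables transcribed from print, fold-changes are rounded; passing
#' `printed_decimals` widens the fold-change gate by half an ulp of the
#' printed precision so that a printed 1.5 (an underlying value that
#' exceeded 1.5 before rounding) is retained.
#'
#' @param records data.frame with columns `p_value` and `fold_change`
#'   (signed) and a miRNA/probe id column.
#' @param cfg A [threshold_config()].
#' @param p_col,fc_col Column names for p and fold-change.
#' @param printed_decimals Decimals the fold-changes were printed to, or
#'   NULL (default) for exact strict comparison.
#' @return The gated, reordered data.frame with a `direction` column.
#' @export
select_smoking_dependent <- function(records, cfg = threshold_config(),
                                     p_col = "p_value", fc_col = "fold_change",
                                     printed_decimals = NULL) {
  stopifnot(inherits(cfg, "threshold_config"))
  p <- records[[p_col]]
  fc <- records[[fc_col]]
  if (is.null(p) || is.null(fc)) stop("records must carry p and fold-change columns")
  fc_thr <- cfg$de_fc
  if (!is.null(printed_decimals))
    fc_thr <- fc_thr - 0.5 * 10^(-printed_decimals)
  keep <- (p < cfg$de_p) & (abs(fc) > fc_thr)
  out <- records[keep, , drop = FALSE]
  out$direction <- ifelse(out[[fc_col]] >= 0, "up", "down")
  ord <- order(factor(out$direction, levels = c("up", "down")),
               -abs(out[[fc_col]]))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Unsupervised hierarchical clustering of a signature matrix
#'
#' Distance 1 - Pearson correlation, average linkage, for both samples
#' (columns) and miRNAs (rows). `hclust` processes tied merges in input
#' order, so results are deterministic for a given matrix.
#'
#' @param x Numeric matrix (signature miRNAs x samples), >= 2 rows and
#'   columns, every row with positive variance.
#' @return list with `samples` and `mirnas`, each an `hclust` object.
#' @export
cluster_signature <- function(x) {
  if (nrow(x) < 2L || ncol(x) < 2L) stop("need at least 2 rows and 2 columns")
  v <- apply(x, 1L, stats::var)
  if (any(v <= 0)) {
    bad <- rownames(x)[which(v <= 0)[1L]]
    stop("zero-variance row: ", if (is.null(bad)) which(v <= 0)[1L] else bad)
  }
  d_samples <- stats::as.dist(1 - stats::cor(x))
  d_mirnas <- stats::as.dist(1 - stats::cor(t(x)))
  list(samples = stats::hclust(d_samples, method = "average"),
       mirnas = stats::hclust(d_mirnas, method = "average"))
}

#' Comparative-CT relative quantification
#'
#' The delta-delta-Ct method for qPCR: per sample, delta Ct = target Ct -
#' endogenous-control Ct; delta-delta Ct subtracts the mean delta Ct of the
#' reference group; the relative quantity is 2^(-delta-delta Ct).
#'
#' @param ct_target,ct_control Cycle-threshold vectors, one value per sample.
#' @param group Group label per sample.
#' @param reference_group Label of the reference group (its mean relative
#'   quantity is centred at 1 on the log scale).
#' @return data.frame with columns group, dct, ddct, rq.
#' @export
ddct_fold_change <- function(ct_target, ct_control, group, reference_group) {
  if (length(ct_target) != length(ct_control) || length(ct_target) != length(group))
    stop("ct_target, ct_control and group must have equal length")
  if (any(!is.finite(ct_target)) || any(!is.finite(ct_control)))
    stop("CT values must be finite")
  ref <- group == reference_group
  if (!any(ref)) stop("reference group ", sQuote(reference_group), " is empty")
  dct <- ct_target - ct_control
  ddct <- dct - mean(dct[ref])
  data.frame(group = group, dct = dct, ddct = ddct, rq = 2^(-ddct),
             stringsAsFactors = FALSE)
}
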