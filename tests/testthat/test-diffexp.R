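# Independent least-squares oracle: Type II F for each factor via the
# normal equations, comparing residual sums of squares of nested models.
oracle_type2 <- function(y, group, gender) {
  rss <- function(X) {
    beta <- solve(t(X) %*% X, t(X) %*% y)
    sum((y - X %*% beta)^2)
  }
  Xf <- stats::model.matrix(~ group + gender)
  Xg <- stats::model.matrix(~ gender)
  Xs <- stats::model.matrix(~ group)
  df_group <- nlevels(group) - 1L
  df_res <- length(y) - 1L - df_group - 1L
  mse <- rss(Xf) / df_res
  f_group <- (rss(Xg) - rss(Xf)) / df_group / mse
  f_gender <- (rss(Xs) - rss(Xf)) / 1 / mse
  list(group_f = f_group,
       group_p = stats::pf(f_group, df_group, df_res, lower.tail = FALSE),
       gender_f = f_gender,
       gender_p = stats::pf(f_gender, 1, df_res, lower.tail = FALSE),
       mse = mse, df_res = df_res)
}

test_that("two-factor ANOVA matches the normal-equations oracle on an unbalanced design", {
  meta <- toy_meta(n_ns = 5L, n_sm = 4L)  # 5/4/4, mixed genders
  set.seed(21)
  y <- stats::rnorm(nrow(meta), 7, 0.5) +
    ifelse(meta$group == "smoker_baseline", 0.8, 0)
  fit <- fit_group_gender_anova(y, meta)
  orc <- oracle_type2(y, factor(meta$group), factor(meta$gender))
  expect_equal(fit$group_f, orc$group_f, tolerance = 1e-10)
  expect_equal(fit$group_p, orc$group_p, tolerance = 1e-10)
  expect_equal(fit$gender_f, orc$gender_f, tolerance = 1e-10)
  expect_equal(fit$gender_p, orc$gender_p, tolerance = 1e-10)
  expect_equal(fit$mse, orc$mse, tolerance = 1e-10)
  expect_equal(fit$df_res, orc$df_res)
  # cross-check against car's Type II table
  cc <- car::Anova(stats::lm(y ~ group + gender,
                             data = transform(meta, group = factor(group))),
                   type = 2)
  expect_equal(fit$group_p, cc["group", "Pr(>F)"], tolerance = 1e-10)
  expect_equal(fit$gender_p, cc["gender", "Pr(>F)"], tolerance = 1e-10)
})

test_that("balanced two-group toy reduces to one-way ANOVA with an idle gender term", {
  meta <- data.frame(sample_id = paste0("s", 1:6),
                     subject_id = paste0("s", 1:6),
                     group = rep(c("nonsmoker", "smoker_baseline"), each = 3),
                     gender = rep(c("M", "F", "M"), 2),
                     stringsAsFactors = FALSE)
  y <- c(4, 5, 6, 7, 8, 9)
  fit <- fit_group_gender_anova(y, meta, include_gender = FALSE)
  one_way <- summary(stats::aov(y ~ factor(meta$group)))[[1]]
  expect_equal(fit$group_p, one_way[["Pr(>F)"]][1], tolerance = 1e-12)
  fit2 <- fit_group_gender_anova(y, meta, include_gender = TRUE)
  expect_gt(fit2$gender_p, 0.5)
})

test_that("degenerate inputs raise errors", {
  meta <- toy_meta(quitters = FALSE)
  expect_error(fit_group_gender_anova(rep(5, nrow(meta)), meta), "degenerate")
  one_per_group <- toy_meta(n_ns = 1L, n_sm = 4L, quitters = FALSE)
  expect_error(fit_group_gender_anova(stats::rnorm(5), one_per_group),
               "fewer than 2")
})

test_that("LSD contrast equals the pooled two-sample t-test with two groups and no covariate", {
  meta <- toy_meta(n_ns = 5L, n_sm = 6L, quitters = FALSE)
  set.seed(31)
  y <- stats::rnorm(nrow(meta), 7, 1)
  fit <- fit_group_gender_anova(y, meta, include_gender = FALSE)
  con <- lsd_contrast(fit, "smoker_baseline", "nonsmoker")
  tt <- stats::t.test(y[meta$group == "smoker_baseline"],
                      y[meta$group == "nonsmoker"], var.equal = TRUE)
  expect_equal(con$p, tt$p.value, tolerance = 1e-12)
  expect_equal(con$log2_diff, unname(diff(rev(tt$estimate))), tolerance = 1e-12)

  # antisymmetry and the zero-difference identity
  rev_con <- lsd_contrast(fit, "nonsmoker", "smoker_baseline")
  expect_equal(rev_con$p, con$p)
  expect_equal(rev_con$log2_diff, -con$log2_diff)
  fit$group_means[] <- 5
  expect_equal(lsd_contrast(fit, "nonsmoker", "smoker_baseline")$p, 1)
  expect_error(lsd_contrast(fit, "nonsmoker", "exsmoker"), "unknown group")
})

test_that("signed fold-change follows the +/- reciprocal convention", {
  expect_equal(signed_fold_change(c(1, -1, 0)), c(2, -2, 1))
  expect_error(signed_fold_change(NaN), "finite")
  # involution under negation for many magnitudes
  d <- seq(-5, 5, by = 0.25); d <- d[d != 0]
  expect_equal(signed_fold_change(-d), -signed_fold_change(d))
  expect_true(all(abs(signed_fold_change(d)) >= 1))
})

test_that("selection gate applies strict thresholds and orders by |FC| within direction", {
  rec <- data.frame(mirna_id = paste0("m", 1:5),
                    p_value = c(0.009, 0.02, 0.001, 0.005, 0.0005),
                    fold_change = c(1.6, 3.0, -2.5, 1.5, -1.7),
                    stringsAsFactors = FALSE)
  kept <- select_smoking_dependent(rec)
  # m2 fails the p gate, m4 sits exactly at the FC threshold (strict)
  expect_setequal(kept$mirna_id, c("m1", "m3", "m5"))
  expect_equal(kept$direction, c("up", "down", "down"))
  expect_equal(kept$mirna_id, c("m1", "m3", "m5"))  # |FC| descending within direction

  # printed-precision gating retains a rounded 1.5
  kept_printed <- select_smoking_dependent(rec, printed_decimals = 1)
  expect_true("m4" %in% kept_printed$mirna_id)
})

test_that("hierarchical clustering separates blocks and matches brute-force agglomeration", {
  set.seed(41)
  base <- stats::rnorm(20)
  x <- cbind(a1 = base + stats::rnorm(20, 0, 0.05),
             a2 = base + stats::rnorm(20, 0, 0.05),
             b1 = -base + stats::rnorm(20, 0, 0.05),
             b2 = -base + stats::rnorm(20, 0, 0.05))
  rownames(x) <- paste0("mir", 1:20)
  hc <- cluster_signature(x)
  grp <- stats::cutree(hc$samples, 2)
  expect_equal(grp[["a1"]], grp[["a2"]])
  expect_equal(grp[["b1"]], grp[["b2"]])
  expect_false(grp[["a1"]] == grp[["b1"]])

  # 4-point merge sequence equals exhaustive nearest-pair agglomeration
  set.seed(43)
  y <- matrix(stats::rnorm(4 * 10), 10, 4,
              dimnames = list(paste0("mir", 1:10), paste0("s", 1:4)))
  hc2 <- cluster_signature(y)
  d <- stats::as.dist(1 - stats::cor(y))
  expect_identical(hclust_merge_sets(hc2$samples), brute_average_agglomeration(d))

  # duplicated profile merges first at distance zero
  z <- cbind(y, s4dup = y[, 4])
  hc3 <- cluster_signature(z)
  expect_equal(hc3$samples$height[1], 0, tolerance = 1e-12)
  expect_setequal(-hc3$samples$merge[1, ], c(4, 5))

  flat <- y; flat[1, ] <- 3
  expect_error(cluster_signature(flat), "mir1")
})

test_that("comparative-CT arithmetic maps cycle differences to fold-changes", {
  # one reference sample pins the reference mean; ddct -1/0/+1 -> 2/1/0.5
  res <- ddct_fold_change(ct_target = c(20, 19, 20, 21),
                          ct_control = c(15, 15, 15, 15),
                          group = c("ref", "a", "b", "c"),
                          reference_group = "ref")
  expect_equal(res$ddct, c(0, -1, 0, 1))
  expect_equal(res$rq, c(1, 2, 1, 0.5))
  expect_error(ddct_fold_change(1, 1, "a", "ref"), "empty")
})

test_that("run_diffexp agrees with the single-feature fit and flags directions", {
  meta <- toy_meta(n_ns = 5L, n_sm = 5L)
  x <- toy_matrix(meta, n_mirna = 8L, seed = 51)
  x[1, meta$group == "smoker_baseline"] <- x[1, meta$group == "smoker_baseline"] + 2
  de <- run_diffexp(x, meta, "smoker_vs_nonsmoker")
  fit1 <- fit_group_gender_anova(x[3, ], meta)
  con1 <- lsd_contrast(fit1, "smoker_baseline", "nonsmoker")
  expect_equal(de$p_value[3], con1$p, tolerance = 1e-12)
  expect_equal(de$log2_diff[3], con1$log2_diff, tolerance = 1e-12)
  expect_equal(de$direction[1], "up")
  expect_equal(de$q_value, stats::p.adjust(de$p_value, "BH"))
})
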