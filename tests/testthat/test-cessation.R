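test_that("percent change hits the constructed anchors and is direction-agnostic", {
  expect_equal(percent_change(10, 20, 20), 0)
  expect_equal(percent_change(10, 20, 10), 100)
  expect_equal(percent_change(10, 20, 15), 50)
  # negating all means (a down-regulated miRNA) leaves the statistic unchanged
  set.seed(61)
  ns <- stats::runif(50, 1, 10); s <- ns + stats::runif(50, 0.5, 5)
  q <- ns + stats::runif(50, -1, 5)
  expect_equal(percent_change(-ns, -s, -q), percent_change(ns, s, q))
  # degenerate denominator is flagged, not fatal
  expect_true(is.na(percent_change(10, 10 + 1e-12, 12)))
})

test_that("persistence gate follows the p<0.05, |FC|>1.5 rule and checks directions", {
  sig <- data.frame(mirna_id = c("m1", "m2", "m3"),
                    direction = c("up", "up", "down"),
                    stringsAsFactors = FALSE)
  quit <- data.frame(mirna_id = c("m1", "m2", "m3"),
                     fold_change = c(1.8, 1.2, 1.9),
                     p_value = c(0.03, 0.2, 0.01),
                     stringsAsFactors = FALSE)
  expect_warning(res <- classify_persistence(sig, quit), "m3")
  expect_equal(res$persistent, c(TRUE, FALSE, TRUE))
  expect_equal(res$direction_match, c(TRUE, TRUE, FALSE))
  expect_error(classify_persistence(sig, quit[1:2, ]), "m3")
})

test_that("reversal curve counts the fraction strictly below each cutoff", {
  pc <- c(10, 30, 60)
  expect_equal(reversal_fraction_curve(pc, 25)$fraction_below, 100 / 3)
  expect_equal(reversal_fraction_curve(pc, 0)$fraction_below, 0)
  expect_equal(reversal_fraction_curve(pc, Inf)$fraction_below, 100)
  expect_error(reversal_fraction_curve(NA_real_, 25), "no defined")
})

test_that("nonsmoker quartiles use the (k-1)/(n-1) interpolation rule", {
  meta <- data.frame(sample_id = paste0("n", 1:9), subject_id = paste0("n", 1:9),
                     group = "nonsmoker", gender = rep_len(c("M", "F"), 9),
                     stringsAsFactors = FALSE)
  x <- rbind(a = 1:9, b = rep(4, 9))
  colnames(x) <- meta$sample_id
  q <- nonsmoker_quartiles(x, meta, c("a", "b"))
  expect_equal(q$q1, c(3, 4))
  expect_equal(q$q3, c(7, 4))

  meta4 <- meta[1:4, ]
  x4 <- matrix(c(1, 2, 3, 4), 1, dimnames = list("a", meta4$sample_id))
  q4 <- nonsmoker_quartiles(x4, meta4, "a")
  expect_equal(q4$q1, 1.75)
  expect_equal(q4$q3, 3.25)
  expect_error(nonsmoker_quartiles(x4[, 1:3, drop = FALSE], meta4[1:3, ], "a"),
               "at least 4")
})

test_that("subject index scores strict quartile exceedance in the smoking direction", {
  thr <- data.frame(mirna_id = c("u1", "u2", "d1"), q1 = c(2, 2, 2),
                    q3 = c(7, 7, 7), stringsAsFactors = FALSE)
  dirs <- c("up", "up", "down")
  expect_equal(subject_index(c(u1 = 8, u2 = 7, d1 = 3), dirs, thr), 1L)  # boundary scores 0
  expect_equal(subject_index(c(u1 = 8, u2 = 9, d1 = 1), dirs, thr), 3L)  # maximum
  expect_equal(subject_index(c(u1 = 2, u2 = 2, d1 = 2), dirs, thr), 0L)  # q1 boundary scores 0
  expect_error(subject_index(c(u1 = 8, u2 = 9), dirs, thr), "d1")

  # invariance under a joint strictly monotone transform
  set.seed(71)
  v <- stats::setNames(stats::runif(3, 0, 10), thr$mirna_id)
  mono <- function(x) exp(x / 3) + x
  thr2 <- transform(thr, q1 = mono(q1), q3 = mono(q3))
  expect_equal(subject_index(v, dirs, thr), subject_index(mono(v), dirs, thr2))
})

test_that("held-out exceedance of an empirical quartile follows the order-statistic rate", {
  # with n = 9 nonsmokers the type-7 third quartile is the 7th order
  # statistic, so a fresh draw exceeds it with probability (n-7+1)/(n+1) = 0.3
  set.seed(81)
  n <- 9L; reps <- 4000L
  exceed <- replicate(reps, {
    q3 <- stats::quantile(stats::rnorm(n), 0.75, names = FALSE, type = 7)
    stats::rnorm(1) > q3
  })
  expect_lt(abs(mean(exceed) - 0.3), 3 * sqrt(0.3 * 0.7 / reps))
})

test_that("Kruskal-Wallis/Dunn comparison matches hand computation and rank-test oracles", {
  idx <- data.frame(group = rep(c("a", "b", "c"), each = 3),
                    index = 1:9, stringsAsFactors = FALSE)
  res <- index_group_comparison(idx)
  expect_equal(res$H, 7.2, tolerance = 1e-12)   # 12/90 * (36+225+576)/3 - 30
  expect_equal(res$df, 2)
  # hand-computed Dunn z for a vs c: (2 - 8) / sqrt((90/12) * (2/3))
  z_ac <- res$pairs$z[res$pairs$group_a == "a" & res$pairs$group_b == "c"]
  expect_equal(z_ac, -6 / sqrt(5), tolerance = 1e-12)

  # all observations equal: no rank information
  flat <- data.frame(group = rep(c("a", "b"), each = 3), index = rep(2, 6))
  res_flat <- index_group_comparison(flat)
  expect_equal(res_flat$H, 0)
  expect_equal(res_flat$p, 1)
  expect_equal(res_flat$pairs$p, 1)

  # two-group case: KW p equals the two-sided Mann-Whitney normal approximation
  set.seed(91)
  two <- data.frame(group = rep(c("a", "b"), times = c(8, 7)),
                    index = sample.int(20, 15, replace = TRUE))
  res2 <- index_group_comparison(two)
  x <- two$index[two$group == "a"]; y <- two$index[two$group == "b"]
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(two$index)
  U <- sum(r[two$group == "a"]) - n1 * (n1 + 1) / 2
  ties <- table(two$index)
  sd_u <- sqrt(n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1))))
  z <- (U - n1 * n2 / 2) / sd_u
  expect_equal(res2$p, 2 * stats::pnorm(-abs(z)), tolerance = 1e-10)

  expect_error(index_group_comparison(data.frame(group = c("a", "a", "b"),
                                                 index = 1:3)), "fewer than 2")
})

test_that("run_cessation ties the contrasts, gates and percent change together", {
  d <- cohort_design(n_mirna = 120, n_up = 6, n_down = 4,
                     persist_fraction = 0.5, effect_log2 = 2.5, seed = 13)
  co <- generate_cohort(d)
  sig <- select_smoking_dependent(run_diffexp(co$expr, co$meta))
  ces <- run_cessation(co$expr, co$meta, sig)
  expect_equal(nrow(ces), nrow(sig))
  expect_true(all(ces$percent_change_defined == !is.na(ces$percent_change)))
  # persistent truths should reverse far less than reversible truths
  truth <- co$truth[match(ces$mirna_id, co$truth$mirna_id), ]
  m_pers <- mean(ces$percent_change[truth$persistence == "persistent"], na.rm = TRUE)
  m_rev <- mean(ces$percent_change[truth$persistence == "reversible"], na.rm = TRUE)
  expect_lt(m_pers, m_rev)
})
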