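# ROC AUC, bootstrap CIs, multiclass AUC, cutpoints, rank-sum, Pearson.

mini_table <- function(scores, classes, direction = "higher",
                       column = "s") {
  df <- data.frame(case = paste0("c", seq_along(scores)), rank = 1,
                   capri_class = classes, s = scores)
  names(df)[names(df) == "s"] <- column
  score_table(df, directions = stats::setNames(direction, column))
}

test_that("binary AUC handles separation, interleaving and direction", {
  t1 <- mini_table(c(1, 2, 3, 4), c("incorrect", "incorrect", "high", "high"))
  expect_equal(binary_auc(t1, "s", "high", "incorrect")$auc, 1.0)

  # pos {1, 3}, neg {2, 4}: 1 of 4 pairs concordant
  t2 <- mini_table(c(1, 3, 2, 4), c("high", "high", "incorrect", "incorrect"))
  expect_equal(binary_auc(t2, "s", "high", "incorrect")$auc, 0.25)

  t2l <- mini_table(c(1, 3, 2, 4), c("high", "high", "incorrect", "incorrect"),
                    direction = "lower")
  expect_equal(binary_auc(t2l, "s", "high", "incorrect")$auc, 0.75)

  expect_warning(
    const <- binary_auc(mini_table(c(2, 2, 2, 2),
                                   c("high", "high", "incorrect", "incorrect")),
                        "s", "high", "incorrect"),
    "constant")
  expect_equal(const$auc, 0.5)
})

test_that("binary AUC equals exhaustive pair counting on random small
           tables", {
  set.seed(31)
  for (i in 1:30) {
    n <- sample(4:12, 1)
    classes <- sample(c("high", "incorrect"), n, replace = TRUE)
    if (length(unique(classes)) < 2) classes[1:2] <- c("high", "incorrect")
    scores <- sample(1:6, n, replace = TRUE)  # ties likely
    tab <- mini_table(scores, classes)
    expect_equal(binary_auc(tab, "s", "high", "incorrect")$auc,
                 brute_force_auc(scores[classes == "high"],
                                 scores[classes == "incorrect"]))
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(5)
  scores <- rnorm(40)
  classes <- sample(c("medium", "incorrect"), 40, replace = TRUE)
  a0 <- binary_auc(mini_table(scores, classes), "s", "medium",
                   "incorrect")$auc
  a1 <- binary_auc(mini_table(exp(scores), classes), "s", "medium",
                   "incorrect")$auc
  expect_equal(a0, a1)
  # negation with unchanged direction flag flips the AUC
  a2 <- binary_auc(mini_table(-scores, classes), "s", "medium",
                   "incorrect")$auc
  expect_equal(a2, 1 - a0)
})

test_that("ROC curve runs monotonically from (0,0) to (1,1)", {
  set.seed(8)
  tab <- mini_table(rnorm(30), sample(c("high", "incorrect"), 30,
                                      replace = TRUE))
  cv <- binary_auc(tab, "s", "high", "incorrect")$curve
  expect_equal(cv$fpr[1], 0); expect_equal(cv$sensitivity[1], 0)
  expect_equal(cv$fpr[nrow(cv)], 1); expect_equal(cv$sensitivity[nrow(cv)], 1)
  expect_true(all(diff(cv$fpr) >= 0))
  expect_true(all(diff(cv$sensitivity) >= 0))
})

test_that("binary AUC agrees with pROC", {
  skip_if_not_installed("pROC")
  set.seed(17)
  scores <- rnorm(60)
  classes <- sample(c("high", "incorrect"), 60, replace = TRUE)
  got <- binary_auc(mini_table(scores, classes), "s", "high",
                    "incorrect")$auc
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = as.integer(classes == "high"), predictor = scores,
    direction = "<", levels = c(0, 1), quiet = TRUE)))
  expect_equal(got, ref, tolerance = 1e-12)
})

test_that("stratified bootstrap CI is deterministic under a seed,
           contains the point AUC, and collapses for separated groups", {
  set.seed(3)
  scores <- c(rnorm(30, 1), rnorm(30))
  classes <- rep(c("high", "incorrect"), each = 30)
  tab <- mini_table(scores, classes)
  ci1 <- bootstrap_ci(tab, "s", "high", "incorrect", n_boot = 500, seed = 7)
  ci2 <- bootstrap_ci(tab, "s", "high", "incorrect", n_boot = 500, seed = 7)
  expect_identical(ci1, ci2)
  a <- binary_auc(tab, "s", "high", "incorrect")$auc
  expect_lte(ci1$ci_low, a)
  expect_gte(ci1$ci_high, a)

  sep <- mini_table(c(rnorm(200, 10), rnorm(200)),
                    rep(c("high", "incorrect"), each = 200))
  cis <- bootstrap_ci(sep, "s", "high", "incorrect", n_boot = 300, seed = 1)
  expect_lt(cis$ci_high - cis$ci_low, 0.01)
  expect_equal(cis$ci_high, 1)
})

test_that("multiclass AUC reduces sensibly and is near 0.5 under random
           labels", {
  # two classes, direction oriented so the binary AUC is above 0.5
  set.seed(23)
  scores <- c(rnorm(25, 2), rnorm(25))
  classes <- rep(c("high", "incorrect"), each = 25)
  tab <- mini_table(scores, classes)
  mc <- multiclass_auc(tab, "s", n_boot = 0)
  expect_equal(mc$auc, binary_auc(tab, "s", "high", "incorrect")$auc)

  set.seed(29)
  scores <- rnorm(500)
  classes <- sample(c("high", "medium", "acceptable", "incorrect"),
                    500, replace = TRUE)
  null_mc <- multiclass_auc(mini_table(scores, classes), "s", n_boot = 0)
  expect_lt(abs(null_mc$auc - 0.5), 0.05)

  # classes with < 2 members are excluded with a warning
  tab_small <- mini_table(c(1, 2, 3, 4, 10),
                          c("incorrect", "incorrect", "medium", "medium",
                            "high"))
  expect_warning(mc2 <- multiclass_auc(tab_small, "s", n_boot = 0), "fewer")
  expect_setequal(mc2$classes, c("medium", "incorrect"))
})

test_that("multiclass bootstrap CI brackets the estimate for both CI
           types", {
  set.seed(41)
  scores <- c(rnorm(20, 3), rnorm(20, 2), rnorm(20, 1), rnorm(20))
  classes <- rep(c("high", "medium", "acceptable", "incorrect"), each = 20)
  tab <- mini_table(scores, classes)
  for (ct in c("percentile", "bca")) {
    mc <- multiclass_auc(tab, "s", n_boot = 200, seed = 5, ci_type = ct)
    expect_lte(mc$ci_low, mc$auc + 0.02)
    expect_gte(mc$ci_high, mc$auc - 0.02)
  }
})

test_that("optimal cutpoint picks the lowest separating positive and
           degrades when groups interleave", {
  tab <- mini_table(c(5, 6, 7, 1, 2, 3),
                    c(rep("high", 3), rep("incorrect", 3)))
  cp <- optimal_cutpoint(tab, "s", "high", "incorrect")
  expect_equal(cp$threshold, 5)
  expect_equal(cp$sensitivity, 1)
  expect_equal(cp$specificity, 1)
  expect_equal(cp$objective, 2)

  mixed <- mini_table(c(1, 3, 5, 2, 4, 6),
                      c(rep("high", 3), rep("incorrect", 3)))
  expect_lt(optimal_cutpoint(mixed, "s", "high", "incorrect")$objective, 2)
})

test_that("optimal cutpoint recovers a planted threshold", {
  set.seed(53)
  for (i in 1:8) {
    thr <- runif(1, 40, 60)
    pos <- runif(40, thr + 0.5, 100)
    neg <- runif(40, 0, thr - 0.5)
    tab <- mini_table(c(pos, neg),
                      rep(c("medium", "incorrect"), each = 40))
    cp <- optimal_cutpoint(tab, "s", "medium", "incorrect")
    expect_equal(cp$objective, 2)
    expect_equal(cp$threshold, min(pos))  # lowest separating observed value
  }
})

test_that("cutpoints on lower-is-better columns report the original scale", {
  tab <- mini_table(c(1, 2, 3, 8, 9, 10),
                    c(rep("high", 3), rep("incorrect", 3)),
                    direction = "lower")
  cp <- optimal_cutpoint(tab, "s", "high", "incorrect")
  expect_equal(cp$direction, "lower")
  expect_equal(cp$threshold, 3)  # classify positive when score <= 3
  expect_equal(cp$objective, 2)
})

test_that("rank-sum test matches exact enumeration for small samples", {
  expect_equal(rank_sum_test(c(1, 2, 3), c(10, 11, 12)), 0.1)
  set.seed(61)
  for (i in 1:10) {
    n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
    v <- sample(1:100, n1 + n2)  # distinct values: no ties
    x <- v[seq_len(n1)]; y <- v[-seq_len(n1)]
    expect_equal(rank_sum_test(x, y), exact_rank_sum_p(x, y),
                 tolerance = 1e-12)
  }
})

test_that("rank-sum large-sample approximation tracks the exact value", {
  set.seed(67)
  x <- sample(1:1000, 8); y <- sample(1001:2000, 8) - 950
  exact <- exact_rank_sum_p(x, y)
  approx_p <- suppressWarnings(
    stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
  expect_lt(abs(approx_p - exact), 0.01)
  expect_equal(rank_sum_test(x, y), exact, tolerance = 1e-12)
})

test_that("identical samples give p near 1", {
  expect_gt(rank_sum_test(c(1, 2, 3), c(1, 2, 3)), 0.99)
})

test_that("pearson matches the direct formula and flags degenerate input", {
  expect_equal(pearson(1:10, 2 * (1:10) + 1)$r, 1)
  expect_equal(pearson(1:10, -(1:10))$r, -1)
  set.seed(71)
  x <- rnorm(50); y <- 0.4 * x + rnorm(50)
  got <- pearson(x, y)
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(got$r, r_direct, tolerance = 1e-12)
  tstat <- r_direct * sqrt(48 / (1 - r_direct^2))
  expect_equal(got$p_value, 2 * stats::pt(-abs(tstat), df = 48),
               tolerance = 1e-12)
  expect_error(pearson(rep(1, 5), 1:5), "constant")
})

test_that("significance stars follow the published bins", {
  expect_equal(significance_stars(c(0.2, 0.05, 0.04, 0.01, 0.0005, 0.001)),
               c("ns", "*", "*", "**", "***", "***"))
  expect_error(significance_stars(1.5), "p must be")
})

test_that("score_table validates classes, duplicates and directions", {
  df <- data.frame(case = "c1", rank = 1, capri_class = "great", s = 1)
  expect_error(score_table(df), "unknown CAPRI class")
  df2 <- data.frame(case = c("c1", "c1"), rank = c(1, 1),
                    capri_class = "high", s = 1:2)
  expect_error(score_table(df2), "duplicated")
  df3 <- data.frame(case = "c1", rank = 1, capri_class = "high", s = 1)
  expect_error(score_table(df3, directions = c(s = "sideways")),
               "higher")
  # missing scores are excluded from analysis for that column only
  df4 <- data.frame(case = paste0("c", 1:6), rank = 1,
                    capri_class = rep(c("high", "incorrect"), 3),
                    s = c(3, 1, NA, 2, 4, 1))
  roc <- binary_auc(score_table(df4), "s", "high", "incorrect")
  expect_equal(roc$n_pos + roc$n_neg, 5)
})
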