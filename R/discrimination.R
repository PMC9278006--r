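# Score-discrimination statistics: ROC AUC, bootstrap CIs, cutpoints,
# rank-sum tests, correlation.

#' Per-model score table
#'
#' One row per model: the case identifier, the model's rank within its
#' case, its CAPRI accuracy class, and any number of named score columns
#' (pTM, interface pLDDT, interface PAE, externally computed energies, ...).
#' Each score column has a direction: `"higher"` when larger values are
#' expected for better models, `"lower"` otherwise (errors, energies).
#'
#' @param df data.frame with columns `case`, `rank`, `capri_class` plus
#'   score columns.
#' @param directions named character vector mapping score columns to
#'   `"higher"` or `"lower"`; unnamed score columns default to `"higher"`.
#' @return `df` with class `score_table` and a `directions` attribute.
#' @export
score_table <- function(df, directions = character(0)) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  needed <- c("case", "rank", "capri_class")
  if (!all(needed %in% names(df))) {
    stop("score table needs columns: ", paste(needed, collapse = ", "))
  }
  bad <- setdiff(unique(df$capri_class), CAPRI_CLASSES)
  if (length(bad) > 0L) {
    stop("unknown CAPRI class(es): ", paste(bad, collapse = ", "))
  }
  if (anyDuplicated(paste(df$case, df$rank))) {
    stop("duplicated (case, rank) rows")
  }
  score_cols <- setdiff(names(df), needed)
  dirs <- stats::setNames(rep("higher", length(score_cols)), score_cols)
  dirs[names(directions)] <- unname(directions)
  if (!all(dirs %in% c("higher", "lower"))) {
    stop("directions must be 'higher' or 'lower'")
  }
  attr(df, "directions") <- dirs
  class(df) <- c("score_table", "data.frame")
  df
}

score_direction <- function(table, column) {
  dirs <- attr(table, "directions")
  if (!is.null(dirs) && column %in% names(dirs)) dirs[[column]] else "higher"
}

# scores of rows in a class set, oriented so larger = better, NA dropped
oriented_scores <- function(table, column, classes) {
  if (!column %in% names(table)) stop("no such score column: ", column)
  s <- table[[column]][table$capri_class %in% classes]
  s <- s[!is.na(s)]
  if (score_direction(table, column) == "lower") s <- -s
  s
}

# Mann-Whitney AUC with midrank tie handling; pos/neg already oriented
auc_from_scores <- function(pos, neg) {
  r <- rank(c(pos, neg))
  np <- length(pos); nn <- length(neg)
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

roc_curve_points <- function(pos, neg) {
  thr <- sort(unique(c(pos, neg)), decreasing = TRUE)
  sens <- vapply(thr, function(t) mean(pos >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(neg >= t), numeric(1))
  data.frame(fpr = c(0, fpr, 1), sensitivity = c(0, sens, 1))
}

#' Binary ROC AUC of a score for two CAPRI class groups
#'
#' The AUC is computed as the Mann-Whitney probability that a positive
#' outscores a negative (ties counted half), with the column's direction
#' flag applied so that better scores for positives give AUC above 0.5.
#'
#' @param table a [score_table()].
#' @param column score column name.
#' @param positives,negatives character vectors of CAPRI classes forming
#'   the positive and negative group (e.g. `c("medium", "high")` vs
#'   `"incorrect"`).
#' @return Object of class `roc_result`: list with `auc`, `ci_low`,
#'   `ci_high` (`NA` until [bootstrap_ci()] is run), `n_pos`, `n_neg`, and
#'   `curve` (data.frame of `fpr`, `sensitivity`, from (0,0) to (1,1)).
#' @export
binary_auc <- function(table, column, positives, negatives) {
  pos <- oriented_scores(table, column, positives)
  neg <- oriented_scores(table, column, negatives)
  if (length(pos) == 0L || length(neg) == 0L) {
    stop("empty positive or negative group for column ", column)
  }
  if (length(unique(c(pos, neg))) == 1L) {
    warning("constant score column ", column, "; AUC is 0.5")
  }
  structure(list(auc = auc_from_scores(pos, neg),
                 ci_low = NA_real_, ci_high = NA_real_,
                 n_pos = length(pos), n_neg = length(neg),
                 curve = roc_curve_points(pos, neg),
                 column = column),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  ci <- if (is.na(x$ci_low)) "" else
    sprintf(" (95%% CI %.3f-%.3f)", x$ci_low, x$ci_high)
  cat(sprintf("roc_result: AUC %.3f%s [%d pos, %d neg]\n",
              x$auc, ci, x$n_pos, x$n_neg))
  invisible(x)
}

#' Stratified bootstrap confidence interval for a binary AUC
#'
#' Positives and negatives are resampled separately with replacement
#' (group sizes preserved) and the percentile 95% interval of the AUC over
#' `n_boot` replicates is returned.
#'
#' @inheritParams binary_auc
#' @param n_boot number of bootstrap replicates (default 2000).
#' @param seed integer seed for reproducibility.
#' @return list with `ci_low`, `ci_high`.
#' @export
bootstrap_ci <- function(table, column, positives, negatives,
                         n_boot = 2000, seed = NULL) {
  pos <- oriented_scores(table, column, positives)
  neg <- oriented_scores(table, column, negatives)
  if (length(pos) < 2L || length(neg) < 2L) {
    stop("both groups need at least 2 observations")
  }
  if (!is.null(seed)) set.seed(seed)
  reps <- vapply(seq_len(n_boot), function(i) {
    auc_from_scores(sample(pos, replace = TRUE),
                    sample(neg, replace = TRUE))
  }, numeric(1))
  q <- unname(stats::quantile(reps, c(0.025, 0.975)))
  list(ci_low = q[[1]], ci_high = q[[2]])
}

#' Multiclass AUC over the CAPRI classes
#'
#' One-vs-rest AUCs are computed for each class present (classes with
#' fewer than 2 models are excluded with a warning), each oriented so the
#' class is scored as separable from the rest (AUC >= 0.5; with a single
#' ordinal score column the natural orientation of a one-vs-rest contrast
#' differs between the top and the bottom class, so orientation is
#' resolved per class).  The macro average weights classes equally; the
#' micro average weights them by size.  The confidence interval uses a
#' class-stratified bootstrap, percentile by default, with a BCa
#' (bias-corrected accelerated) variant available.
#'
#' @inheritParams binary_auc
#' @param n_boot bootstrap replicates for the CI (0 to skip).
#' @param seed integer seed.
#' @param average `"macro"` or `"micro"`.
#' @param ci_type `"percentile"` or `"bca"`.
#' @return list with `auc`, `ci_low`, `ci_high`, `per_class` (named vector
#'   of one-vs-rest AUCs), `classes`.
#' @export
multiclass_auc <- function(table, column, n_boot = 2000, seed = NULL,
                           average = c("macro", "micro"),
                           ci_type = c("percentile", "bca")) {
  average <- match.arg(average)
  ci_type <- match.arg(ci_type)
  tab <- table[!is.na(table[[column]]), , drop = FALSE]
  counts <- table(tab$capri_class)
  small <- names(counts)[counts < 2]
  if (length(small) > 0L) {
    warning("excluding class(es) with fewer than 2 models: ",
            paste(small, collapse = ", "))
  }
  classes <- intersect(CAPRI_CLASSES, names(counts)[counts >= 2])
  if (length(classes) < 2L) stop("need at least 2 classes with >= 2 models")
  scores <- tab[[column]]
  if (score_direction(tab, column) == "lower") scores <- -scores
  labels <- tab$capri_class
  point <- function(scores, labels) {
    per_class <- vapply(classes, function(cl) {
      a <- auc_from_scores(scores[labels == cl], scores[labels != cl])
      max(a, 1 - a)
    }, numeric(1))
    w <- if (average == "macro") rep(1, length(classes)) else
      as.numeric(table(factor(labels, levels = classes)))
    sum(per_class * w) / sum(w)
  }
  est <- point(scores, labels)
  per_class <- vapply(classes, function(cl) {
    a <- auc_from_scores(scores[labels == cl], scores[labels != cl])
    max(a, 1 - a)
  }, numeric(1))
  ci_low <- NA_real_; ci_high <- NA_real_
  if (n_boot > 0) {
    if (!is.null(seed)) set.seed(seed)
    idx_by_class <- split(seq_along(labels), labels)
    reps <- vapply(seq_len(n_boot), function(i) {
      idx <- unlist(lapply(idx_by_class, function(ii) {
        sample(ii, replace = TRUE)
      }), use.names = FALSE)
      point(scores[idx], labels[idx])
    }, numeric(1))
    if (ci_type == "percentile") {
      q <- unname(stats::quantile(reps, c(0.025, 0.975)))
    } else {
      q <- bca_interval(reps, est, function(drop_i) {
        point(scores[-drop_i], labels[-drop_i])
      }, n = length(labels))
    }
    ci_low <- q[[1]]; ci_high <- q[[2]]
  }
  list(auc = est, ci_low = ci_low, ci_high = ci_high,
       per_class = per_class, classes = classes)
}

# BCa interval from bootstrap replicates + jackknife acceleration
bca_interval <- function(reps, est, jack_fun, n, conf = 0.95) {
  z0 <- stats::qnorm(mean(reps < est) + 0.5 * mean(reps == est))
  jack <- vapply(seq_len(n), jack_fun, numeric(1))
  jm <- mean(jack)
  num <- sum((jm - jack)^3)
  den <- 6 * (sum((jm - jack)^2))^1.5
  a <- if (den == 0) 0 else num / den
  alpha <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
  zal <- stats::qnorm(alpha)
  adj <- stats::pnorm(z0 + (z0 + zal) / (1 - a * (z0 + zal)))
  unname(stats::quantile(reps, adj, na.rm = TRUE))
}

#' Optimal score cutpoint by sensitivity + specificity maximization
#'
#' Scans the observed score values as candidate thresholds and returns the
#' one maximizing sensitivity + specificity for discriminating the
#' positive from the negative class group.  Ties are broken toward the
#' threshold with higher specificity, then toward the more permissive
#' threshold.  The returned threshold is an achieved observed score value,
#' reported on the column's original scale.
#'
#' @inheritParams binary_auc
#' @return Object of class `cutpoint_result`: list with `threshold`,
#'   `sensitivity`, `specificity`, `objective`, `direction`.
#' @export
optimal_cutpoint <- function(table, column, positives, negatives) {
  pos <- oriented_scores(table, column, positives)
  neg <- oriented_scores(table, column, negatives)
  if (length(pos) == 0L || length(neg) == 0L) {
    stop("empty positive or negative group for column ", column)
  }
  cand <- sort(unique(c(pos, neg)))
  sens <- vapply(cand, function(t) mean(pos >= t), numeric(1))
  spec <- vapply(cand, function(t) mean(neg < t), numeric(1))
  obj <- sens + spec
  best <- which(obj >= max(obj) - 1e-12)
  best <- best[order(-spec[best], cand[best])][[1]]
  thr <- cand[[best]]
  dir <- score_direction(table, column)
  structure(list(threshold = if (dir == "lower") -thr else thr,
                 sensitivity = sens[[best]], specificity = spec[[best]],
                 objective = obj[[best]], direction = dir,
                 column = column),
            class = "cutpoint_result")
}

#' @export
print.cutpoint_result <- function(x, ...) {
  cat(sprintf(
    "cutpoint_result: threshold %s %.4g (sens %.3f, spec %.3f, sum %.3f)\n",
    if (x$direction == "higher") ">=" else "<=",
    x$threshold, x$sensitivity, x$specificity, x$objective))
  invisible(x)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact enumeration when both samples have at most 8 observations and no
#' ties are present; otherwise the normal approximation with tie and
#' continuity corrections.
#'
#' @param x,y numeric samples.
#' @return two-sided p-value.
#' @export
rank_sum_test <- function(x, y) {
  if (length(x) < 1L || length(y) < 1L) stop("both samples need >= 1 value")
  exact <- length(x) <= 8 && length(y) <= 8 && !anyDuplicated(c(x, y))
  suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = exact, correct = TRUE)$p.value)
}

#' Pearson correlation with t-based p-value
#'
#' @param x,y numeric vectors of equal length (n >= 3), neither constant.
#' @return list with `r` and `p_value` (from the t transform with n - 2
#'   degrees of freedom).
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant vector")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value)
}

#' Significance stars for a p-value
#'
#' Bins: `ns` for p > .05, `*` for p <= .05, `**` for p <= .01, `***` for
#' p <= .001.
#'
#' @param p p-value(s) in `[0, 1]`.  Vectorized.
#' @return character vector of labels.
#' @export
significance_stars <- function(p) {
  if (any(p < 0 | p > 1)) stop("p must be in [0, 1]")
  out <- rep("ns", length(p))
  out[p <= 0.05] <- "*"
  out[p <= 0.01] <- "**"
  out[p <= 0.001] <- "***"
  out
}
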