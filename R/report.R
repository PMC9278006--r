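# Per-case success-rate aggregation (T1/T5 tables).

class_rank <- function(cl) match(cl, CAPRI_CLASSES)  # 1 = high ... 4 = incorrect

#' Top-N success rates across cases
#'
#' For each case, models are ranked by `ranking_column` (respecting its
#' direction flag; falls back to the stored `rank` column when `NULL` or
#' absent) and the best CAPRI class among the top `n` models is taken.
#' The success rate at an accuracy level is the percentage of cases whose
#' best class reaches that level.
#'
#' @param table a [score_table()].
#' @param top_n vector of model counts to consider (default `c(1, 5)`,
#'   the T1/T5 convention).
#' @param ranking_column score column used to order models within a case
#'   (default `"ptm"` when present).
#' @return data.frame with columns `top_n`, `acceptable_or_better`,
#'   `medium_or_better`, `high` (percentages of cases), and `n_cases`.
#' @export
success_rates <- function(table, top_n = c(1, 5),
                          ranking_column = "ptm") {
  use_col <- !is.null(ranking_column) && ranking_column %in% names(table)
  by_case <- split(as.data.frame(table), table$case)
  out <- lapply(top_n, function(n) {
    best <- vapply(by_case, function(d) {
      if (use_col) {
        s <- d[[ranking_column]]
        if (score_direction(table, ranking_column) == "lower") s <- -s
        d <- d[order(-s), , drop = FALSE]
      } else {
        d <- d[order(d$rank), , drop = FALSE]
      }
      min(class_rank(d$capri_class[seq_len(min(n, nrow(d)))]))
    }, numeric(1))
    data.frame(top_n = n,
               acceptable_or_better = 100 * mean(best <= 3),
               medium_or_better = 100 * mean(best <= 2),
               high = 100 * mean(best <= 1),
               n_cases = length(best))
  })
  do.call(rbind, out)
}
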