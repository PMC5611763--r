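#' Two-sample Student's t test (equal variance)
#'
#' Pooled-variance unpaired t test with `n_a + n_b - 2` degrees of freedom
#' and a two-sided p value, as used for univariate marker confirmation.
#' Computed via [stats::t.test()]; the degenerate zero-pooled-variance case
#' is resolved first: equal means give `t = 0, p = 1` by convention,
#' unequal means with no variance are an error.
#'
#' @param group_a,group_b numeric vectors, each of length >= 2.
#' @return list with `t`, `p`, `df`.
#' @export
t_test <- function(group_a, group_b) {
  na <- length(group_a); nb <- length(group_b)
  if (na < 2L || nb < 2L) stop("each group needs at least 2 observations")
  pooled <- (sum((group_a - mean(group_a))^2) +
             sum((group_b - mean(group_b))^2)) / (na + nb - 2L)
  if (pooled <= 0) {
    if (isTRUE(all.equal(mean(group_a), mean(group_b)))) {
      return(list(t = 0, p = 1, df = na + nb - 2L))
    }
    stop("zero pooled variance with unequal means: t is undefined")
  }
  ht <- stats::t.test(group_a, group_b, var.equal = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter))
}

#' Bonferroni significance threshold
#'
#' Family-wise threshold `alpha / m`, with the full variable count of the
#' refined dataset as the number of independent tests (not just the number
#' of marker candidates actually tested).
#'
#' @param alpha family-wise error rate, in (0, 1).
#' @param m number of tests (>= 1).
#' @return the per-test threshold.
#' @export
#' @examples
#' bonferroni_threshold(0.05, 13250)  # 3.77e-06
bonferroni_threshold <- function(alpha = 0.05, m = 1L) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  if (m < 1) stop("m must be >= 1")
  alpha / m
}

#' Univariate marker statistics
#'
#' For each candidate variable: the organic/conventional peak-area ratio
#' (arithmetic group means of the sum-normalized -- but not Pareto-scaled --
#' intensities), the pooled two-sample t statistic, the uncorrected
#' two-sided p value, and a Bonferroni-significance flag at
#' `alpha / m_total`.
#'
#' @param table sum-normalized [feature_table()].
#' @param meta sample metadata with a `system` column (`organic` /
#'   `conventional`).
#' @param candidates bucket ids to test; must be columns of the table.
#'   `NULL` tests every column.
#' @param m_total number of tests for the Bonferroni family: the full
#'   refined variable count (default `ncol(table)`).
#' @param alpha family-wise error rate (default 0.05).
#' @return a `data.frame` (class `marker_table`) with columns `bucket_id`,
#'   `mean_organic`, `mean_conventional`, `ratio`, `t`, `p`, `significant`.
#'   A conventional group mean of 0 leaves `ratio = NA` (flagged, not an
#'   error).
#' @export
marker_stats <- function(table, meta, candidates = NULL,
                         m_total = NULL, alpha = 0.05) {
  stopifnot(inherits(table, "feature_table"))
  meta <- align_meta(table, meta)
  if (is.null(m_total)) m_total <- ncol(table$values)
  if (is.null(candidates)) candidates <- bucket_ids(table)
  miss <- setdiff(candidates, bucket_ids(table))
  if (length(miss)) stop("candidate(s) not in the table: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  thr <- bonferroni_threshold(alpha, m_total)
  org <- meta$system == "organic"
  conv <- meta$system == "conventional"
  if (!any(org) || !any(conv)) stop("need both organic and conventional samples")
  out <- lapply(candidates, function(b) {
    x <- table$values[, b]
    mo <- mean(x[org]); mc <- mean(x[conv])
    tt <- t_test(x[org], x[conv])
    data.frame(bucket_id = b, mean_organic = mo, mean_conventional = mc,
               ratio = if (mc > 0) mo / mc else NA_real_,
               t = tt$t, p = tt$p, significant = tt$p < thr,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  attr(out, "m_total") <- m_total
  attr(out, "threshold") <- thr
  class(out) <- c("marker_table", "data.frame")
  out
}

#' Write a marker table as delimited text
#'
#' @param markers a `marker_table` from [marker_stats()].
#' @param path output file (comma for `.csv`, tab otherwise).
#' @export
write_markers <- function(markers, path) {
  data.table::fwrite(as.data.frame(markers), path, sep = delim_for(path))
  invisible(path)
}
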