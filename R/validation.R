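#' Build a train/test split
#'
#' External-validation splitting strategies:
#' \describe{
#'   \item{`random_third`}{`floor(n/3)` test samples drawn at random,
#'     stratified over production system x harvest year (largest-remainder
#'     quotas); set `stratify = FALSE` for a simple random draw.}
#'   \item{`leave_year_out`}{every sample of the named harvest `year` goes
#'     to the test set.}
#'   \item{`leave_cultivar_out`}{every sample of the named `cultivar` goes
#'     to the test set.}
#'   \item{`leave_fields_out`}{every sample whose `field_code` is in
#'     `field_codes` goes to the test set (e.g. nearby fields, to probe the
#'     effect of a shared environment).}
#' }
#'
#' @param meta sample metadata `data.frame` (`sample_id`, `year`, `system`,
#'   optionally `cultivar`, `field_code`).
#' @param strategy one of `"random_third"`, `"leave_year_out"`,
#'   `"leave_cultivar_out"`, `"leave_fields_out"`.
#' @param year,cultivar,field_codes the level(s) to hold out, per strategy.
#' @param seed RNG seed (`random_third` only).
#' @param stratify stratify the random third by system x year (default).
#' @return an object of class `split_spec`: list with `train` and `test`
#'   sample ids, `strategy`, `seed`.
#' @export
make_split <- function(meta, strategy = c("random_third", "leave_year_out",
                                          "leave_cultivar_out",
                                          "leave_fields_out"),
                       year = NULL, cultivar = NULL, field_codes = NULL,
                       seed = 1L, stratify = TRUE) {
  strategy <- match.arg(strategy)
  ids <- as.character(meta$sample_id)
  n <- length(ids)
  test <- switch(strategy,
    random_third = {
      target <- n %/% 3L
      set.seed(seed)
      if (stratify) {
        strata <- interaction(meta$system, meta$year, drop = TRUE)
        ns <- table(strata)
        base <- floor(ns / 3)
        rem <- ns / 3 - base
        left <- target - sum(base)
        if (left > 0) {
          bump <- order(rem, decreasing = TRUE)[seq_len(left)]
          base[bump] <- base[bump] + 1
        } else if (left < 0) {
          drop_ <- order(rem)[seq_len(-left)]
          base[drop_] <- pmax(base[drop_] - 1, 0)
        }
        unlist(lapply(names(ns), function(s) {
          pool <- ids[strata == s]
          sample(pool, min(base[[s]], length(pool)))
        }), use.names = FALSE)
      } else {
        sample(ids, target)
      }
    },
    leave_year_out = {
      if (is.null(year)) stop("leave_year_out requires a year")
      if (!year %in% meta$year) stop("year '", year, "' not in the metadata")
      ids[meta$year == year]
    },
    leave_cultivar_out = {
      if (is.null(cultivar)) stop("leave_cultivar_out requires a cultivar")
      if (!cultivar %in% meta$cultivar) {
        stop("cultivar '", cultivar, "' not in the metadata")
      }
      ids[meta$cultivar == cultivar]
    },
    leave_fields_out = {
      if (is.null(field_codes)) stop("leave_fields_out requires field codes")
      miss <- setdiff(field_codes, meta$field_code)
      if (length(miss)) stop("field code(s) not in the metadata: ",
                             paste(miss, collapse = ", "))
      ids[meta$field_code %in% field_codes]
    })
  train <- setdiff(ids, test)
  if (!length(test)) stop("empty test set")
  train_sys <- meta$system[ids %in% train]
  absent <- setdiff(unique(as.character(meta$system)), unique(as.character(train_sys)))
  if (length(absent)) {
    stop("strategy leaves the training set without class '", absent[1], "'")
  }
  structure(list(train = train, test = test, strategy = strategy,
                 seed = if (strategy == "random_third") seed else NULL),
            class = "split_spec")
}

#' Evaluate an OPLS-DA model on an external test set
#'
#' Predicts the test samples and reports the classification rate together
#' with sensitivity (% of conventional samples called conventional -- the
#' positive class) and specificity (% of organic samples called organic,
#' the fraud-relevant rate: a conventional product mislabelled organic is a
#' specificity failure).
#'
#' @param model a binary `opls_model` with frozen scaling.
#' @param test_table sum-normalized [feature_table()] of test samples.
#' @param test_meta metadata for the test samples (`system` column used as
#'   truth).
#' @return an object of class `validation_report`: list with `rate`,
#'   `sensitivity`, `specificity` (all percentages), `n`, and `predictions`
#'   (per-sample data.frame with the continuous response, predicted and true
#'   labels).
#' @export
evaluate <- function(model, test_table, test_meta) {
  stopifnot(inherits(model, "opls_model"), inherits(test_table, "feature_table"))
  test_meta <- align_meta(test_table, test_meta)
  pr <- opls_predict(model, test_table)
  truth <- as.character(test_meta$system)
  pred <- as.character(pr$labels)
  pos <- model$encoding$positive
  neg <- setdiff(model$encoding$classes, pos)
  pct <- function(x) if (length(x)) 100 * mean(x) else NA_real_
  structure(list(
    rate = pct(pred == truth),
    sensitivity = pct(pred[truth == pos] == pos),
    specificity = pct(pred[truth == neg] == neg),
    n = length(truth),
    positive = pos,
    predictions = data.frame(sample_id = test_meta$sample_id,
                             response = drop(pr$response),
                             predicted = pred, truth = truth,
                             stringsAsFactors = FALSE)),
    class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(paste0("external validation (n = %d): rate %.1f%%, ",
                     "sensitivity %.1f%%, specificity %.1f%%\n"),
              x$n, x$rate, x$sensitivity, x$specificity))
  invisible(x)
}

#' Receiver operating characteristic curve and AUC
#'
#' Sweeps the decision threshold over all distinct predicted responses,
#' recording the true- and false-positive rates, and integrates the curve
#' by the trapezoidal rule. With ties handled by grouping equal responses,
#' the trapezoidal AUC equals the normalized Mann-Whitney U statistic
#' (probability that a random positive outranks a random negative, ties
#' counted half).
#'
#' @param response numeric predicted responses (higher = more positive).
#' @param labels true class labels; both classes must be present.
#' @param positive label of the positive class (default `"conventional"`
#'   when present, else the second factor level).
#' @return an object of class `roc_curve`: data.frame-backed list with
#'   `fpr`, `tpr`, `thresholds` and `auc`.
#' @export
roc <- function(response, labels, positive = NULL) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L) {
    stop("both classes must be present to compute a ROC")
  }
  if (is.null(positive)) {
    positive <- if ("conventional" %in% labels) "conventional"
                else levels(factor(labels))[2L]
  }
  is_pos <- labels == positive
  n1 <- sum(is_pos); n0 <- sum(!is_pos)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present to compute a ROC")
  ord <- order(response, decreasing = TRUE)
  r <- response[ord]; pos <- is_pos[ord]
  last <- !duplicated(r, fromLast = TRUE)  # group ties: step after each distinct value
  tp <- cumsum(pos)[last]
  fp <- cumsum(!pos)[last]
  tpr <- c(0, tp / n1)
  fpr <- c(0, fp / n0)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(fpr = fpr, tpr = tpr,
                 thresholds = c(Inf, r[last]), auc = auc,
                 positive = positive),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve (%d thresholds), AUC = %.3f\n",
              length(x$thresholds), x$auc))
  invisible(x)
}

#' Write a validation report (per-sample predictions + summary line)
#'
#' @param report a `validation_report`.
#' @param path delimited output file.
#' @export
write_validation <- function(report, path) {
  sep <- delim_for(path)
  data.table::fwrite(report$predictions, path, sep = sep)
  invisible(path)
}
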