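#' Assign samples to cross-validation folds
#'
#' Deterministic round-robin: samples are ordered by class label (then by
#' their position, or by supplied metadata keys) and dealt into folds in
#' turn, so fold sizes differ by at most one and every fold sees every
#' class whenever counts permit. A seeded shuffled assignment is available
#' via `shuffle`.
#'
#' @param labels class labels, one per sample.
#' @param nfold number of folds (default 7).
#' @param order_keys optional data.frame of metadata columns (e.g. year,
#'   system, sample id) used to fix the within-class ordering.
#' @param shuffle if `TRUE`, shuffle sample order (seeded) instead of the
#'   deterministic ordering.
#' @param seed RNG seed used only when `shuffle = TRUE`.
#' @return integer vector of fold ids in 1..nfold.
#' @export
assign_folds <- function(labels, nfold = 7L, order_keys = NULL,
                         shuffle = FALSE, seed = 1L) {
  n <- length(labels)
  if (nfold < 2L || nfold > n) stop("nfold must be in [2, n]")
  if (shuffle) {
    set.seed(seed)
    ord <- order(as.integer(factor(labels)), sample.int(n))
  } else if (!is.null(order_keys)) {
    ord <- do.call(order, c(list(as.integer(factor(labels))),
                            as.list(as.data.frame(order_keys))))
  } else {
    ord <- order(as.integer(factor(labels)), seq_len(n))
  }
  folds <- integer(n)
  folds[ord] <- rep_len(seq_len(nfold), n)
  folds
}

#' Sevenfold cross-validation of OPLS-DA over orthogonal-component counts
#'
#' For each candidate number of orthogonal components `0..a_orth_max`, fits
#' the model on each fold's training part (refitting the Pareto scaling on
#' that part only), predicts the held-out fold, and accumulates the
#' prediction error sum of squares. The cumulative predictive ability is
#' `Q2(cum) = 1 - PRESS / SS(Y - Ybar)` with the total sum of squares taken
#' over the centred dummy response of all samples. Internal classification
#' rates from the held-out predictions are reported alongside.
#'
#' @param table a sum-normalized [feature_table()] (unscaled; scaling is
#'   refit inside every fold).
#' @param labels class labels aligned to the table rows.
#' @param a_orth_max largest orthogonal-component count to evaluate.
#' @param nfold number of folds (default 7).
#' @param a_pred predictive components; default 1 (binary) or classes - 1.
#' @param order_keys,shuffle,seed passed to [assign_folds()].
#' @param positive binary positive class.
#' @return an object of class `cv_report`: `folds` (assignment), `q2`
#'   (named vector, index = a_orth), `press`, `internal_rate` (% correct
#'   held-out classifications per candidate), `a_pred`.
#' @export
cross_validate <- function(table, labels, a_orth_max = 5L, nfold = 7L,
                           a_pred = NULL, order_keys = NULL, shuffle = FALSE,
                           seed = 1L, positive = NULL) {
  stopifnot(inherits(table, "feature_table"))
  n <- nrow(table$values)
  if (length(labels) != n) stop("labels and table disagree on sample count")
  encoding <- class_encoding(labels, positive = positive)
  Y <- encode_y(labels, encoding)
  if (is.null(a_pred)) {
    a_pred <- if (encoding$type == "binary") 1L else length(encoding$classes) - 1L
  }
  folds <- assign_folds(labels, nfold = nfold, order_keys = order_keys,
                        shuffle = shuffle, seed = seed)
  for (f in seq_len(nfold)) {
    train_lab <- labels[folds != f]
    absent <- setdiff(encoding$classes, unique(as.character(train_lab)))
    if (length(absent)) {
      stop("class '", absent[1], "' absent from the training part of fold ", f,
           "; use stratified folds or fewer folds")
    }
  }
  ss <- sum(sweep(Y, 2L, colMeans(Y))^2)
  cand <- 0:a_orth_max
  press <- numeric(length(cand))
  correct <- numeric(length(cand))
  for (f in seq_len(nfold)) {
    tr <- folds != f; te <- !tr
    tr_tab <- subset_table(table, samples = which(tr))
    sp <- fit_pareto(tr_tab)
    Xtr <- apply_scaling(tr_tab, sp)
    Xte <- apply_scaling(subset_table(table, samples = which(te)), sp)
    for (ci in seq_along(cand)) {
      model <- opls_fit(Xtr, labels[tr], a_orth = cand[ci], a_pred = a_pred,
                        positive = positive)
      pr <- opls_predict(model, Xte)
      press[ci] <- press[ci] + sum((Y[te, , drop = FALSE] - pr$response)^2)
      correct[ci] <- correct[ci] + sum(pr$labels == as.character(labels)[te])
    }
  }
  q2 <- 1 - press / ss
  names(q2) <- names(press) <- paste0("a_orth_", cand)
  structure(list(folds = folds, q2 = q2, press = press,
                 internal_rate = 100 * correct / n,
                 a_pred = a_pred, a_orth_max = a_orth_max,
                 encoding = encoding),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("sevenfold CV report; Q2(cum) by orthogonal components:\n")
  print(round(x$q2, 4))
  invisible(x)
}

#' Select the component counts from a cross-validation report
#'
#' The predictive component count is fixed by the response (1 for binary,
#' classes - 1 for multi-class). Orthogonal components are added greedily:
#' each added component must raise Q2(cum) by more than `increment`
#' (default 0.01); the first failure stops the search.
#'
#' @param report a `cv_report` from [cross_validate()].
#' @param increment minimum Q2(cum) gain to accept one more orthogonal
#'   component.
#' @return list with `a_pred`, `a_orth` and the achieved `q2`.
#' @export
select_components <- function(report, increment = 0.01) {
  stopifnot(inherits(report, "cv_report"))
  q2 <- report$q2
  a_orth <- 0L
  while (a_orth + 1L < length(q2) &&
         q2[a_orth + 2L] - q2[a_orth + 1L] > increment) {
    a_orth <- a_orth + 1L
  }
  if (a_orth == report$a_orth_max && report$a_orth_max > 0L) {
    warning("Q2 still rising at a_orth_max = ", report$a_orth_max,
            "; consider raising the search limit")
  }
  list(a_pred = report$a_pred, a_orth = a_orth,
       q2 = unname(q2[a_orth + 1L]))
}
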