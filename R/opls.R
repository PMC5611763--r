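#' Principal component analysis of a scaled data matrix
#'
#' Unsupervised first look at the dominant variance structure, computed by
#' singular value decomposition of the (already centred, e.g. Pareto-scaled)
#' matrix. Per-component explained variation is
#' `R2X_k = sigma_k^2 / sum(X^2)`.
#'
#' @param X numeric matrix, samples x variables, columns centred.
#' @param n_components number of components to retain; at most `min(n, p)`.
#' @return an object of class `pca_model`: scores `T` (n x k), loadings `P`
#'   (p x k), per-component `r2x` and cumulative `r2x_cum`.
#' @export
pca_fit <- function(X, n_components = 2) {
  X <- as.matrix(X)
  k <- n_components
  if (k < 1 || k > min(dim(X))) {
    stop("n_components must be between 1 and min(n, p) = ", min(dim(X)))
  }
  sv <- svd(X, nu = k, nv = k)
  ssx <- sum(X^2)
  r2 <- sv$d[seq_len(k)]^2 / ssx
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  rownames(scores) <- rownames(X)
  colnames(scores) <- paste0("t", seq_len(k))
  loadings <- sv$v
  rownames(loadings) <- colnames(X)
  colnames(loadings) <- paste0("p", seq_len(k))
  structure(list(T = scores, P = loadings, r2x = r2, r2x_cum = cumsum(r2)),
            class = "pca_model")
}

#' Encode class labels as a dummy response matrix
#'
#' Binary problems collapse to a single 0/1 column with the positive class
#' coded 1 (for organic-vs-conventional data the positive class is
#' `conventional`, matching the sensitivity definition used throughout).
#' Problems with 3 or more classes get one membership column per class.
#'
#' @param labels factor or character vector of class labels (no missing
#'   values; every sample belongs to exactly one class).
#' @param positive for binary problems, the label coded 1. Defaults to
#'   `"conventional"` when that label is present, otherwise the second
#'   factor level.
#' @return an object of class `class_encoding`: list with `classes`,
#'   `type` (`"binary"` or `"multi"`), `positive` (binary only) and the
#'   dummy matrix builder is [encode_y()].
#' @export
class_encoding <- function(labels, positive = NULL) {
  f <- factor(labels)
  if (anyNA(f)) stop("class labels must be non-missing")
  lev <- levels(f)
  if (length(lev) < 2L) stop("need at least 2 classes")
  if (length(lev) == 2L) {
    if (is.null(positive)) {
      positive <- if ("conventional" %in% lev) "conventional" else lev[2L]
    }
    if (!positive %in% lev) stop("positive class '", positive, "' not among labels")
    structure(list(classes = lev, type = "binary", positive = positive),
              class = "class_encoding")
  } else {
    structure(list(classes = lev, type = "multi", positive = NULL),
              class = "class_encoding")
  }
}

#' @rdname class_encoding
#' @param encoding a `class_encoding`.
#' @return `encode_y`: numeric dummy matrix (n x 1 binary, n x m multi).
#' @export
encode_y <- function(labels, encoding) {
  f <- factor(labels, levels = encoding$classes)
  if (anyNA(f)) stop("labels outside the encoding's class set")
  if (encoding$type == "binary") {
    matrix(as.numeric(f == encoding$positive), ncol = 1,
           dimnames = list(NULL, encoding$positive))
  } else {
    Y <- sapply(encoding$classes, function(cl) as.numeric(f == cl))
    dimnames(Y) <- list(NULL, encoding$classes)
    Y
  }
}

# One NIPALS PLS round on the current (deflated) X and Y. For a single-column
# Y this converges immediately to w = X'y / ||X'y||; for multi-column Y it
# iterates to the principal direction of the Y-weight space.
nipals_round <- function(X, Y, tol = 1e-12, max_iter = 500L) {
  u <- Y[, which.max(colSums(Y^2))]
  w <- NULL
  for (it in seq_len(max_iter)) {
    w_new <- drop(crossprod(X, u))
    nw <- sqrt(sum(w_new^2))
    if (nw < 1e-300) stop("degenerate PLS component: X'u vanished")
    w_new <- w_new / nw
    t_ <- drop(X %*% w_new)
    c_ <- drop(crossprod(Y, t_)) / sum(t_^2)
    u <- drop(Y %*% c_) / sum(c_^2)
    if (!is.null(w) && sum((w_new - w)^2) < tol^2) { w <- w_new; break }
    w <- w_new
    if (ncol(Y) == 1L) break
  }
  t_ <- drop(X %*% w)
  list(w = w,
       t = t_,
       c = drop(crossprod(Y, t_)) / sum(t_^2),
       p = drop(crossprod(X, t_)) / sum(t_^2))
}

#' Fit an OPLS(-DA) model
#'
#' Orthogonal projections to latent structures: X-variation is split into a
#' predictive part correlated with the response and `a_orth` orthogonal
#' components uncorrelated with it, following the NIPALS O-PLS recipe. For
#' each orthogonal component the loading of a provisional PLS component is
#' orthogonalized against the Y-predictive weight direction, the resulting
#' orthogonal score is removed from X, and the final predictive
#' component(s) are extracted from the filtered matrix. With `a_orth = 0`
#' and a binary response the model coincides with single-component NIPALS
#' PLS1. Multi-class responses use the principal Y-weight direction for the
#' orthogonalization and `a_pred = (number of classes - 1)` predictive
#' components by default.
#'
#' @param X numeric matrix, samples x variables, columns centred
#'   (Pareto scaling includes centring).
#' @param y class labels (factor/character), or a pre-built numeric response
#'   matrix.
#' @param a_orth number of orthogonal-in-X components.
#' @param a_pred number of predictive components; default 1 for binary,
#'   `classes - 1` otherwise.
#' @param scaling optional `scaling_params` frozen into the model so that
#'   [opls_predict()] can scale raw (normalized, unscaled) new data.
#' @param positive binary positive class, see [class_encoding()].
#' @return an object of class `opls_model` with predictive weights `W`
#'   (p x a_pred, unit columns), loadings `P`, scores `T`, response
#'   loadings `C`; orthogonal `W_o`, `P_o`, `T_o`; `r2y`, `r2x`; the class
#'   `encoding`, response column means `y_means` and the frozen `scaling`.
#' @export
opls_fit <- function(X, y, a_orth = 0, a_pred = NULL, scaling = NULL,
                     positive = NULL) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (is.matrix(y) || is.data.frame(y)) {
    Y <- as.matrix(y)
    encoding <- NULL
    if (is.null(a_pred)) a_pred <- ncol(Y)
  } else {
    encoding <- class_encoding(y, positive = positive)
    Y <- encode_y(y, encoding)
    if (is.null(a_pred)) {
      a_pred <- if (encoding$type == "binary") 1L else length(encoding$classes) - 1L
    }
  }
  if (nrow(Y) != n) stop("X and y disagree on sample count")
  y_means <- colMeans(Y)
  Yc <- sweep(Y, 2L, y_means)
  if (sum(Yc^2) == 0) stop("response has no variation (single class?)")
  if (a_orth + a_pred > min(n - 1L, p)) {
    stop("a_orth = ", a_orth, " too large for the rank of X (n = ", n,
         ", p = ", p, ", a_pred = ", a_pred, ")")
  }

  Xd <- X
  W_o <- matrix(0, p, 0); P_o <- matrix(0, p, 0); T_o <- matrix(0, n, 0)
  if (a_orth > 0) {
    for (k in seq_len(a_orth)) {
      cmp <- nipals_round(Xd, Yc)
      w_o <- cmp$p - sum(cmp$w * cmp$p) * cmp$w
      nwo <- sqrt(sum(w_o^2))
      if (nwo < 1e-10 * sqrt(sum(cmp$p^2))) {
        stop("no orthogonal variation left at component ", k,
             "; reduce a_orth")
      }
      w_o <- w_o / nwo
      t_o <- drop(Xd %*% w_o)
      p_o <- drop(crossprod(Xd, t_o)) / sum(t_o^2)
      Xd <- Xd - tcrossprod(t_o, p_o)
      W_o <- cbind(W_o, w_o); P_o <- cbind(P_o, p_o); T_o <- cbind(T_o, t_o)
    }
  }

  W <- matrix(0, p, 0); P <- matrix(0, p, 0); Tm <- matrix(0, n, 0)
  C <- matrix(0, ncol(Y), 0)
  Yd <- Yc
  for (a in seq_len(a_pred)) {
    cmp <- nipals_round(Xd, Yd)
    Xd <- Xd - tcrossprod(cmp$t, cmp$p)
    Yd <- Yd - tcrossprod(cmp$t, cmp$c)
    W <- cbind(W, cmp$w); P <- cbind(P, cmp$p)
    Tm <- cbind(Tm, cmp$t); C <- cbind(C, cmp$c)
  }
  dimnames(W) <- list(colnames(X), paste0("w", seq_len(a_pred)))
  dimnames(Tm) <- list(rownames(X), paste0("t", seq_len(a_pred)))
  if (ncol(T_o)) {
    dimnames(T_o) <- list(rownames(X), paste0("to", seq_len(a_orth)))
    rownames(W_o) <- rownames(P_o) <- colnames(X)
  }
  r2y <- 1 - sum(Yd^2) / sum(Yc^2)
  r2x <- 1 - sum(Xd^2) / sum(X^2)
  structure(list(W = W, P = P, T = Tm, C = C,
                 W_o = W_o, P_o = P_o, T_o = T_o,
                 a_pred = a_pred, a_orth = a_orth,
                 r2y = r2y, r2x = r2x,
                 y_means = y_means, encoding = encoding,
                 scaling = scaling, variables = colnames(X)),
            class = "opls_model")
}

#' @export
print.opls_model <- function(x, ...) {
  cat(sprintf("OPLS-DA model: %d + %d + 0 components, R2Y = %.3f, R2X = %.3f\n",
              x$a_pred, x$a_orth, x$r2y, x$r2x))
  if (!is.null(x$encoding)) {
    cat("  classes:", paste(x$encoding$classes, collapse = " vs "),
        if (x$encoding$type == "binary")
          sprintf("(positive = %s)", x$encoding$positive) else "", "\n")
  }
  invisible(x)
}

# Orthogonal filtering + predictive projection of an already-scaled matrix.
# Returns the continuous predicted responses (training-mean added back).
opls_project <- function(model, Xs) {
  if (ncol(Xs) != nrow(model$W)) {
    stop("new data has ", ncol(Xs), " variables; model expects ", nrow(model$W))
  }
  Xf <- Xs
  for (k in seq_len(model$a_orth)) {
    t_o <- drop(Xf %*% model$W_o[, k])
    Xf <- Xf - tcrossprod(t_o, model$P_o[, k])
  }
  Yhat <- matrix(0, nrow(Xs), length(model$y_means))
  for (a in seq_len(model$a_pred)) {
    t_ <- drop(Xf %*% model$W[, a])
    Xf <- Xf - tcrossprod(t_, model$P[, a])
    Yhat <- Yhat + tcrossprod(t_, model$C[, a])
  }
  sweep(Yhat, 2L, model$y_means, "+")
}

#' Predict classes for new analyses
#'
#' Applies the model's frozen scaling (when present), removes the orthogonal
#' variation, projects through the predictive component(s) and decodes the
#' class: binary predictions are the positive class iff the predicted
#' response exceeds 0.5 on the 0/1 dummy scale; multi-class predictions take
#' the arg-max class column.
#'
#' @param model an `opls_model`.
#' @param newdata a [feature_table()] or matrix. With a frozen `scaling` in
#'   the model, `newdata` is expected on the normalized (unscaled) intensity
#'   scale; without one it must already be scaled like the training matrix.
#' @param threshold binary decision threshold on the dummy response.
#' @return list with `response` (continuous predicted dummy responses) and
#'   `labels` (character predicted classes, `NULL` for matrix-response fits).
#' @export
opls_predict <- function(model, newdata, threshold = 0.5) {
  x <- if (inherits(newdata, "feature_table")) newdata$values else as.matrix(newdata)
  if (!is.null(model$variables) && !is.null(colnames(x))) {
    miss <- setdiff(model$variables, colnames(x))
    if (length(miss)) {
      stop("new data lacks model variables: ",
           paste(utils::head(miss, 5), collapse = ", "),
           if (length(miss) > 5) sprintf(" (and %d more)", length(miss) - 5))
    }
    x <- x[, model$variables, drop = FALSE]
  }
  Xs <- if (!is.null(model$scaling)) apply_scaling(x, model$scaling) else x
  resp <- opls_project(model, Xs)
  rownames(resp) <- rownames(x)
  labels <- NULL
  if (!is.null(model$encoding)) {
    enc <- model$encoding
    labels <- if (enc$type == "binary") {
      neg <- setdiff(enc$classes, enc$positive)
      ifelse(drop(resp) > threshold, enc$positive, neg)
    } else {
      enc$classes[max.col(resp, ties.method = "first")]
    }
    names(labels) <- rownames(x)
  }
  list(response = resp, labels = labels)
}

#' Convenience trainer: Pareto scaling + OPLS-DA in one step
#'
#' Fits Pareto scaling on the (sum-normalized) training table, freezes the
#' parameters into the model, and fits the OPLS-DA, so that
#' [opls_predict()] can consume normalized test tables directly.
#'
#' @param table a sum-normalized [feature_table()] of training samples.
#' @param labels class labels aligned to the table rows.
#' @inheritParams opls_fit
#' @return an `opls_model` with frozen scaling.
#' @export
opls_train <- function(table, labels, a_orth = 0, a_pred = NULL,
                       positive = NULL) {
  stopifnot(inherits(table, "feature_table"))
  sp <- fit_pareto(table)
  Xs <- apply_scaling(table, sp)
  opls_fit(Xs, labels, a_orth = a_orth, a_pred = a_pred,
           scaling = sp, positive = positive)
}

#' Serialize / restore an OPLS model
#'
#' Writes every matrix, the scaling parameters and the class encoding to a
#' single plain-text archive (RFC-ish key/value + delimited sections, 17
#' significant digits) sufficient for bit-reproducible prediction.
#'
#' @param model an `opls_model`.
#' @param path output file.
#' @export
write_opls <- function(model, path) {
  num <- function(v) paste(sprintf("%.17g", v), collapse = "\t")
  con <- file(path, "wt", encoding = "UTF-8")
  on.exit(close(con))
  wl <- function(...) writeLines(paste0(...), con)
  wl("#opls_model v1")
  wl("a_pred\t", model$a_pred)
  wl("a_orth\t", model$a_orth)
  wl("r2y\t", sprintf("%.17g", model$r2y))
  wl("r2x\t", sprintf("%.17g", model$r2x))
  wl("y_means\t", num(model$y_means))
  if (!is.null(model$encoding)) {
    wl("classes\t", paste(model$encoding$classes, collapse = "\t"))
    wl("type\t", model$encoding$type)
    wl("positive\t", model$encoding$positive %||% "")
  }
  wl("variables\t", paste(model$variables, collapse = "\t"))
  dump_mat <- function(name, m) {
    wl("@", name, "\t", nrow(m), "\t", ncol(m))
    for (j in seq_len(ncol(m))) wl(num(m[, j]))
  }
  dump_mat("W", model$W); dump_mat("P", model$P)
  dump_mat("T", model$T); dump_mat("C", model$C)
  dump_mat("W_o", model$W_o); dump_mat("P_o", model$P_o)
  dump_mat("T_o", model$T_o)
  if (!is.null(model$scaling)) {
    wl("@scaling_mean\t", length(model$scaling$mean), "\t1")
    wl(num(model$scaling$mean))
    wl("@scaling_sd\t", length(model$scaling$sd), "\t1")
    wl(num(model$scaling$sd))
  }
  invisible(path)
}

#' @rdname write_opls
#' @return `read_opls`: an `opls_model`.
#' @export
read_opls <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  stopifnot(lines[1] == "#opls_model v1")
  kv <- list(); mats <- list()
  i <- 2L
  while (i <= length(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (startsWith(parts[1], "@")) {
      name <- sub("^@", "", parts[1])
      nr <- as.integer(parts[2]); nc <- as.integer(parts[3])
      m <- matrix(0, nr, nc)
      for (j in seq_len(nc)) {
        m[, j] <- as.numeric(strsplit(lines[i + j], "\t", fixed = TRUE)[[1]])
      }
      mats[[name]] <- m
      i <- i + nc + 1L
    } else {
      kv[[parts[1]]] <- parts[-1]
      i <- i + 1L
    }
  }
  encoding <- NULL
  if (!is.null(kv$classes)) {
    encoding <- structure(list(classes = kv$classes, type = kv$type,
                               positive = if (nzchar(kv$positive %||% ""))
                                 kv$positive else NULL),
                          class = "class_encoding")
  }
  scaling <- NULL
  if (!is.null(mats$scaling_mean)) {
    scaling <- structure(list(mean = drop(mats$scaling_mean),
                              sd = drop(mats$scaling_sd), kind = "pareto",
                              variables = kv$variables),
                         class = "scaling_params")
  }
  vars <- kv$variables
  W <- mats$W; rownames(W) <- vars
  structure(list(W = W, P = mats$P, T = mats$T, C = mats$C,
                 W_o = mats$W_o, P_o = mats$P_o, T_o = mats$T_o,
                 a_pred = as.integer(kv$a_pred), a_orth = as.integer(kv$a_orth),
                 r2y = as.numeric(kv$r2y), r2x = as.numeric(kv$r2x),
                 y_means = as.numeric(kv$y_means), encoding = encoding,
                 scaling = scaling, variables = vars),
            class = "opls_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
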