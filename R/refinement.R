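#' Variable importance in the projection (VIP)
#'
#' VIP summarizes each variable's contribution to the predictive part of an
#' OPLS(-DA) model:
#' `VIP_j = sqrt( p * sum_a SSY_a * (w_aj / ||w_a||)^2 / sum_a SSY_a )`
#' over the predictive components `a`, where `SSY_a` is the response sum of
#' squares explained by component `a` and `p` the variable count. The
#' squared VIPs average to exactly 1, so VIP > 1 marks variables of
#' above-average importance.
#'
#' @param model an `opls_model`.
#' @return an object of class `vip_result`: list with `vip` (named numeric
#'   vector) and the component shares used.
#' @export
vip_scores <- function(model) {
  stopifnot(inherits(model, "opls_model"))
  p <- nrow(model$W)
  ssy <- vapply(seq_len(model$a_pred), function(a) {
    sum(model$C[, a]^2) * sum(model$T[, a]^2)
  }, numeric(1))
  wn2 <- sapply(seq_len(model$a_pred), function(a) {
    w <- model$W[, a]
    w^2 / sum(w^2)
  })
  wn2 <- matrix(wn2, nrow = p)
  vip <- sqrt(p * drop(wn2 %*% ssy) / sum(ssy))
  names(vip) <- rownames(model$W)
  structure(list(vip = vip, ssy = ssy), class = "vip_result")
}

#' Keep only variables with VIP above a threshold
#'
#' Dataset refinement: variables whose VIP does not exceed the threshold
#' (strict `>`, so ties at exactly 1.0 are dropped) are removed, preserving
#' column order.
#'
#' @param table a [feature_table()] whose columns align with the VIP result.
#' @param vip a `vip_result` from [vip_scores()].
#' @param threshold VIP cut-off (default 1).
#' @return the refined [feature_table()].
#' @export
filter_by_vip <- function(table, vip, threshold = 1.0) {
  stopifnot(inherits(table, "feature_table"), inherits(vip, "vip_result"))
  v <- vip$vip
  if (length(v) != ncol(table$values) ||
      (!is.null(names(v)) && !identical(names(v), bucket_ids(table)))) {
    stop("VIP result is not aligned to the table's columns")
  }
  keep <- which(v > threshold)
  if (!length(keep)) {
    stop("no variable exceeds VIP threshold ", threshold,
         "; lower the threshold")
  }
  subset_table(table, buckets = keep)
}

#' Remove the variables that carry a confounding factor
#'
#' Deconfounding by variable removal: an OPLS-DA model is fit on the
#' confounder (by default the harvest year, with `levels - 1` predictive
#' components), its VIP scores are computed, and every variable with
#' VIP > 1 -- i.e. responsible for classifying the confounder -- is removed
#' from the table. The production-system model is then fit on the reduced
#' table, which can no longer exploit the confounder's signal.
#'
#' @param table a sum-normalized [feature_table()] (typically the training
#'   split).
#' @param meta sample metadata aligned (or alignable) to the table.
#' @param factor metadata column holding the confounder (default
#'   `"year"`), which must have at least 2 levels.
#' @param a_orth orthogonal components for the confounder model (default 2).
#' @param vip_threshold removal threshold (strict `>`, default 1).
#' @return list with `table` (reduced [feature_table()]), `removed`
#'   (bucket ids), `vip` (the confounder model's `vip_result`) and `model`
#'   (the confounder `opls_model`).
#' @export
deconfound_factor <- function(table, meta, factor = "year", a_orth = 2L,
                              vip_threshold = 1.0) {
  stopifnot(inherits(table, "feature_table"))
  meta <- align_meta(table, meta)
  if (!factor %in% names(meta)) stop("metadata has no column '", factor, "'")
  f <- factor(meta[[factor]])
  if (nlevels(f) < 2L) stop("confounder '", factor, "' has fewer than 2 levels")
  if (!is.null(meta$system)) {
    tab <- table(f, meta$system)
    if (all(rowSums(tab > 0) == 1L)) {
      stop("'", factor, "' is confounded 1:1 with the production system; ",
           "removing its variables would erase the class signal")
    }
  }
  model <- opls_train(table, f, a_orth = a_orth)
  vip <- vip_scores(model)
  removed <- bucket_ids(table)[vip$vip > vip_threshold]
  if (length(removed) == ncol(table$values)) {
    stop("deconfounding would remove every variable")
  }
  keep <- setdiff(bucket_ids(table), removed)
  list(table = subset_table(table, buckets = keep),
       removed = removed, vip = vip, model = model)
}

#' S-plot of an OPLS-DA model
#'
#' For each variable, the covariance and the correlation of its (scaled)
#' values with the first predictive score `t`:
#' `p(cov)_j = t' x_j / (n - 1)`, `p(corr)_j = p(cov)_j / (s_t * s_xj)`.
#' Variables in the two tails (large `|p(corr)|` and `|p(cov)|`) contribute
#' most to separating the two groups and are the discriminant-marker
#' candidates. Zero-variance variables get `p(corr) = 0` and are flagged.
#'
#' @param model a binary `opls_model`.
#' @param X_scaled the scaled training matrix the model was fit on.
#' @return an object of class `splot_result`: data.frame with `bucket_id`,
#'   `cov`, `corr`, `flat` (zero-variance flag), ordered as the input
#'   columns.
#' @export
s_plot <- function(model, X_scaled) {
  stopifnot(inherits(model, "opls_model"))
  if (!is.null(model$encoding) && model$encoding$type != "binary") {
    stop("the S-plot is defined for binary models")
  }
  X <- as.matrix(X_scaled)
  t_ <- model$T[, 1L]
  if (nrow(X) != length(t_)) stop("X_scaled does not match the model's samples")
  n <- nrow(X)
  Xc <- sweep(X, 2L, colMeans(X))
  tc <- t_ - mean(t_)
  cov_ <- drop(crossprod(tc, Xc)) / (n - 1)
  s_x <- sqrt(colSums(Xc^2) / (n - 1))
  s_t <- sqrt(sum(tc^2) / (n - 1))
  flat <- s_x <= 0
  corr_ <- numeric(ncol(X))
  corr_[!flat] <- cov_[!flat] / (s_t * s_x[!flat])
  structure(data.frame(bucket_id = colnames(X) %||% paste0("V", seq_len(ncol(X))),
                       cov = cov_, corr = corr_, flat = flat,
                       stringsAsFactors = FALSE),
            class = c("splot_result", "data.frame"))
}

#' Select discriminant-marker candidates
#'
#' Union of the two selection routes used for marker discovery: the
#' `n_top` variables with the largest `|p(corr)|` in the S-plot tails, and
#' the `n_top` variables with the highest VIP (restricted to VIP above
#' `vip_threshold`).
#'
#' @param model a binary `opls_model`.
#' @param X_scaled the scaled training matrix the model was fit on.
#' @param n_top how many variables each route contributes (default 24).
#' @param vip_threshold minimum VIP for the VIP route (default 1).
#' @return character vector of candidate bucket ids.
#' @export
select_candidates <- function(model, X_scaled, n_top = 24L,
                              vip_threshold = 1.0) {
  sp <- s_plot(model, X_scaled)
  tails <- sp$bucket_id[order(-abs(sp$corr))][seq_len(min(n_top, nrow(sp)))]
  v <- vip_scores(model)$vip
  v <- v[v > vip_threshold]
  top_vip <- names(sort(v, decreasing = TRUE))[seq_len(min(n_top, length(v)))]
  union(tails, top_vip)
}

#' Write VIP scores / S-plot values / removal lists for audit
#'
#' @param x a `vip_result`, `splot_result`, or character vector of removed
#'   bucket ids.
#' @param path delimited output file (comma for `.csv`, tab otherwise).
#' @export
write_refinement <- function(x, path) {
  sep <- delim_for(path)
  if (inherits(x, "vip_result")) {
    data.table::fwrite(data.table::data.table(bucket_id = names(x$vip),
                                              vip = x$vip), path, sep = sep)
  } else if (inherits(x, "splot_result")) {
    data.table::fwrite(as.data.frame(x), path, sep = sep)
  } else {
    data.table::fwrite(data.table::data.table(bucket_id = as.character(x)),
                       path, sep = sep)
  }
  invisible(path)
}
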