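#' Per-analysis sum normalization
#'
#' Divides each sample's intensities by its own total so that every row sums
#' to 1. Because an injection-volume or source-efficiency error multiplies a
#' whole analysis by one constant, sum normalization removes it exactly.
#' Applied per acquisition block, before [combine_blocks()], since "one
#' analysis" is one injection of one block.
#'
#' @param table a [feature_table()]; every row must have a positive sum.
#' @return a [feature_table()] with unit row sums.
#' @export
normalize_total <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  rs <- rowSums(table$values)
  bad <- which(rs <= 0)
  if (length(bad)) {
    stop("cannot sum-normalize all-zero sample(s): ",
         paste(rownames(table$values)[bad], collapse = ", "))
  }
  feature_table(table$values / rs, bucket_meta = table$bucket_meta)
}

#' Fit Pareto scaling parameters
#'
#' Pareto scaling mean-centres each variable and divides by the square root
#' of its standard deviation (sample sd, n-1 denominator) -- intermediate
#' between no scaling and unit-variance scaling, damping the dominance of
#' high-intensity buckets without blowing up noise. Parameters are fit on
#' the training data only and frozen for scaling test or external samples.
#'
#' @param table a [feature_table()] or numeric matrix with at least 2 rows.
#' @return an object of class `scaling_params`: list with `mean`, `sd`
#'   (per variable), `kind = "pareto"` and the variable ids.
#' @export
fit_pareto <- function(table) {
  x <- if (inherits(table, "feature_table")) table$values else as.matrix(table)
  if (nrow(x) < 2L) stop("need at least 2 samples to fit scaling")
  mu <- colMeans(x)
  sd_ <- sqrt(colSums(sweep(x, 2L, mu)^2) / (nrow(x) - 1L))
  structure(list(mean = mu, sd = sd_, kind = "pareto",
                 variables = colnames(x)),
            class = "scaling_params")
}

#' Apply frozen scaling parameters
#'
#' @param table a [feature_table()] or matrix whose columns match the
#'   parameters' variable set.
#' @param params a `scaling_params` object from [fit_pareto()].
#' @return a numeric matrix of scaled values: `(x - mean) / sqrt(sd)`, with
#'   zero-variance variables mapped to 0.
#' @export
apply_scaling <- function(table, params) {
  stopifnot(inherits(params, "scaling_params"))
  x <- if (inherits(table, "feature_table")) table$values else as.matrix(table)
  if (ncol(x) != length(params$mean)) {
    stop("scaling params fit for ", length(params$mean),
         " variables, table has ", ncol(x))
  }
  if (!is.null(params$variables) && !is.null(colnames(x)) &&
      !identical(colnames(x), params$variables)) {
    stop("variable ids do not match the scaling parameters")
  }
  den <- sqrt(params$sd)
  zero <- params$sd <= 0
  den[zero] <- 1
  out <- sweep(sweep(x, 2L, params$mean), 2L, den, "/")
  if (any(zero)) out[, zero] <- 0
  out
}

#' Serialize / restore scaling parameters
#'
#' Writes a small delimited sidecar (`variable`, `mean`, `sd`, 17
#' significant digits) so that predictions on new analyses can reproduce the
#' training-time scaling exactly.
#'
#' @param params a `scaling_params` object.
#' @param path sidecar file path (comma for `.csv`, tab otherwise).
#' @export
write_scaling <- function(params, path) {
  stopifnot(inherits(params, "scaling_params"))
  sep <- delim_for(path)
  con <- file(path, "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("variable", "mean", "sd"), collapse = sep), con)
  vars <- if (is.null(params$variables)) {
    paste0("V", seq_along(params$mean))
  } else params$variables
  writeLines(paste(vars, sprintf("%.17g", params$mean),
                   sprintf("%.17g", params$sd), sep = sep), con)
  invisible(path)
}

#' @rdname write_scaling
#' @return `read_scaling`: a `scaling_params` object.
#' @export
read_scaling <- function(path) {
  dt <- data.table::fread(path, sep = delim_for(path), header = TRUE,
                          data.table = FALSE)
  structure(list(mean = dt$mean, sd = dt$sd, kind = "pareto",
                 variables = as.character(dt$variable)),
            class = "scaling_params")
}
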