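#' Configuration for the synthetic paired-field study generator
#'
#' Describes a multi-year organic-vs-conventional field study of the shape
#' the pipeline expects: in each harvest year a number of paired field
#' sites, each pair holding one organically and one conventionally managed
#' field at the same location, with a fixed number of biological replicates
#' per field analysed in several ionization-mode blocks. Effects are
#' additive on the log2 intensity scale (so multiplicative on the raw
#' scale): a dominant year effect on a large fraction of variables, a
#' smaller production-system effect on a handful of marker variables, a
#' shared location intercept per field pair, a per-field intercept, a
#' per-analysis injection-scale multiplier, and multiplicative noise.
#'
#' @param n_years number of harvest years (default 4).
#' @param fields_per_year paired field-pairs per year; a scalar or a vector
#'   of length `n_years` (default 2 -- with 10 replicates this gives
#'   4 x 2 x 2 x 10 = 160 samples; `c(2, 2, 2, 1)` reproduces a
#'   140-sample design).
#' @param replicates_per_field biological replicates per field (default 10).
#' @param n_variables variables (buckets) per ionization block (default 2000).
#' @param n_blocks ionization-mode blocks to column-concatenate (default 3:
#'   ESI+, ESI-, ESI- with acidic mobile phase).
#' @param frac_year_affected fraction of all variables carrying year
#'   effects (default 0.4).
#' @param n_system_markers variables carrying a production-system effect
#'   (default 30); must be fewer than the total variable count.
#' @param system_log2_effect mean absolute log2 organic/conventional
#'   difference on the markers (default 1, i.e. a ratio of 2; individual
#'   markers draw |effect| uniformly in 0.5--1.5 times this, spanning
#'   ratios of about 1.4--2.8).
#' @param year_effect_sd sd of the per-year log2 shifts on year-affected
#'   variables (default 1.5; the year effect is meant to dominate).
#' @param location_sd sd of the log2 location intercept shared by both
#'   fields of a pair (default 0.25).
#' @param field_sd sd of the per-field log2 intercept (default 0.1).
#' @param noise_cv coefficient of variation of the multiplicative
#'   measurement noise (default 0.2).
#' @param injection_scale_range interval of the per-analysis global
#'   intensity multiplier (default `c(0.7, 1.3)`); sum normalization
#'   removes it exactly.
#' @param markers_overlap_year if `TRUE`, system markers may also carry
#'   year effects (the hard case for deconfounding); by default the two
#'   sets are disjoint.
#' @param seed RNG seed; the same seed reproduces the dataset bit for bit.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_years = 4L, fields_per_year = 2L,
                             replicates_per_field = 10L,
                             n_variables = 2000L, n_blocks = 3L,
                             frac_year_affected = 0.4,
                             n_system_markers = 30L,
                             system_log2_effect = 1.0,
                             year_effect_sd = 1.5,
                             location_sd = 0.25, field_sd = 0.1,
                             noise_cv = 0.2,
                             injection_scale_range = c(0.7, 1.3),
                             markers_overlap_year = FALSE,
                             seed = 1L) {
  if (length(fields_per_year) == 1L) {
    fields_per_year <- rep(as.integer(fields_per_year), n_years)
  }
  if (length(fields_per_year) != n_years) {
    stop("fields_per_year must be a scalar or length n_years")
  }
  counts <- c(n_years, fields_per_year, replicates_per_field,
              n_variables, n_blocks)
  if (any(counts < 1)) stop("all design counts must be >= 1")
  if (frac_year_affected < 0 || frac_year_affected > 1) {
    stop("frac_year_affected must be in [0, 1]")
  }
  p_total <- n_variables * n_blocks
  if (n_system_markers >= p_total) {
    stop("n_system_markers (", n_system_markers,
         ") must be smaller than the total variable count (", p_total, ")")
  }
  if (length(injection_scale_range) != 2L ||
      any(injection_scale_range <= 0) ||
      injection_scale_range[1] > injection_scale_range[2]) {
    stop("injection_scale_range must be a positive ordered interval")
  }
  if (noise_cv < 0) stop("noise_cv must be non-negative")
  if (year_effect_sd < 0 || location_sd < 0 || field_sd < 0) {
    stop("effect sds must be non-negative")
  }
  structure(list(n_years = as.integer(n_years),
                 fields_per_year = as.integer(fields_per_year),
                 replicates_per_field = as.integer(replicates_per_field),
                 n_variables = as.integer(n_variables),
                 n_blocks = as.integer(n_blocks),
                 frac_year_affected = frac_year_affected,
                 n_system_markers = as.integer(n_system_markers),
                 system_log2_effect = system_log2_effect,
                 year_effect_sd = year_effect_sd,
                 location_sd = location_sd, field_sd = field_sd,
                 noise_cv = noise_cv,
                 injection_scale_range = injection_scale_range,
                 markers_overlap_year = markers_overlap_year,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a synthetic paired-field metabolomics dataset
#'
#' Draws raw (un-normalized) intensities
#' `baseline * year * system * location * field * injection * noise`,
#' all factors multiplicative (additive in log2), strictly positive,
#' split into per-block feature tables, together with the sample metadata
#' and the planted ground truth. Deterministic given `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @return an object of class `synthetic_dataset`: list with
#'   \describe{
#'     \item{`blocks`}{list of raw [feature_table()] objects, one per
#'       ionization block, ready for [normalize_total()] then
#'       [combine_blocks()].}
#'     \item{`meta`}{sample metadata (`sample_id`, `year`, `system`,
#'       `cultivar`, `field_code`, `location`).}
#'     \item{`truth`}{ground truth: `marker_idx` / `marker_id` and the
#'       signed planted log2 effects (`marker_log2`, organic minus
#'       conventional), `year_idx` / `year_id`, and the per-year log2
#'       shift matrix `year_log2`.}
#'   }
#' @export
generate_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  cfg <- config
  p_block <- cfg$n_variables
  p <- p_block * cfg$n_blocks
  modes <- rep_len(c("ESI+", "ESI-", "ESI-acid"), cfg$n_blocks)

  # design layout: one row per sample
  pair_global <- 0L
  rows <- list()
  for (yi in seq_len(cfg$n_years)) {
    year <- 2004L + yi
    for (pr in seq_len(cfg$fields_per_year[yi])) {
      pair_global <- pair_global + 1L
      cultivar <- if (pr %% 2L == 1L) "Nerac" else "Namur"
      for (sys in c("organic", "conventional")) {
        code <- paste0(pair_global, if (sys == "organic") "a" else "b")
        for (r in seq_len(cfg$replicates_per_field)) {
          rows[[length(rows) + 1L]] <- data.frame(
            year = year, system = sys, cultivar = cultivar,
            field_code = code, location = paste0("loc", pair_global),
            pair = pair_global, stringsAsFactors = FALSE)
        }
      }
    }
  }
  meta <- do.call(rbind, rows)
  n <- nrow(meta)
  meta <- data.frame(sample_id = sprintf("S%03d", seq_len(n)), meta,
                     stringsAsFactors = FALSE)
  n_pairs <- pair_global
  n_fields <- 2L * n_pairs

  # planted effects
  n_year_vars <- round(cfg$frac_year_affected * p)
  year_idx <- sort(sample.int(p, n_year_vars))
  marker_pool <- if (cfg$markers_overlap_year) seq_len(p) else
    setdiff(seq_len(p), year_idx)
  if (length(marker_pool) < cfg$n_system_markers) {
    stop("not enough non-year variables to place the system markers")
  }
  marker_idx <- sort(sample(marker_pool, cfg$n_system_markers))
  marker_log2 <- sample(c(-1, 1), cfg$n_system_markers, replace = TRUE) *
    stats::runif(cfg$n_system_markers, 0.5, 1.5) * cfg$system_log2_effect

  baseline <- stats::runif(p, 10, 20)
  year_log2 <- matrix(0, cfg$n_years, p)
  year_log2[, year_idx] <- stats::rnorm(cfg$n_years * n_year_vars,
                                        sd = cfg$year_effect_sd)
  loc_log2 <- matrix(stats::rnorm(n_pairs * p, sd = cfg$location_sd), n_pairs, p)
  field_log2 <- matrix(stats::rnorm(n_fields * p, sd = cfg$field_sd),
                       n_fields, p)

  field_index <- as.integer(factor(meta$field_code,
                                   levels = unique(meta$field_code)))
  year_index <- as.integer(factor(meta$year))
  sys_sign <- ifelse(meta$system == "organic", +0.5, -0.5)

  log2x <- matrix(rep(baseline, each = n), n, p)
  log2x <- log2x + year_log2[year_index, , drop = FALSE]
  log2x <- log2x + loc_log2[meta$pair, , drop = FALSE]
  log2x <- log2x + field_log2[field_index, , drop = FALSE]
  log2x[, marker_idx] <- log2x[, marker_idx] +
    outer(sys_sign, marker_log2)
  sd_log2_noise <- sqrt(log(1 + cfg$noise_cv^2)) / log(2)
  log2x <- log2x + matrix(stats::rnorm(n * p, sd = sd_log2_noise), n, p)

  inj <- matrix(stats::runif(n * cfg$n_blocks,
                             cfg$injection_scale_range[1],
                             cfg$injection_scale_range[2]),
                n, cfg$n_blocks)

  # plausible grid-cell centres for the bucket metadata
  rt <- round(stats::runif(p, 0.5, 20), 3)
  mz <- round(stats::runif(p, 60.5, 850.5), 4)

  blocks <- vector("list", cfg$n_blocks)
  truth_block <- findInterval(seq_len(p) - 1L, seq(0L, p, by = p_block),
                              rightmost.closed = FALSE)
  all_ids <- character(p)
  for (b in seq_len(cfg$n_blocks)) {
    cols <- ((b - 1L) * p_block + 1L):(b * p_block)
    ids <- make_bucket_id(rt[cols], mz[cols], mode = modes[b], fraction = "MW")
    # grid centres can collide by chance; disambiguate within the block
    dup <- duplicated(ids)
    while (any(dup)) {
      ids[dup] <- paste0(ids[dup], "+")
      dup <- duplicated(ids)
    }
    all_ids[cols] <- ids
    v <- 2^log2x[, cols, drop = FALSE] * inj[, b]
    dimnames(v) <- list(meta$sample_id, ids)
    blocks[[b]] <- feature_table(v, bucket_meta = data.frame(
      bucket_id = ids, rt = rt[cols], mz = mz[cols],
      mode = modes[b], fraction = "MW", stringsAsFactors = FALSE))
  }

  meta$pair <- NULL
  truth <- structure(list(marker_idx = marker_idx,
                          marker_id = all_ids[marker_idx],
                          marker_log2 = marker_log2,
                          year_idx = year_idx,
                          year_id = all_ids[year_idx],
                          year_log2 = year_log2[, year_idx, drop = FALSE],
                          bucket_id = all_ids),
                     class = "ground_truth")
  structure(list(blocks = blocks, meta = meta, truth = truth,
                 config = cfg),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(paste0("synthetic dataset: %d samples, %d blocks x %d variables, ",
                     "%d system markers, %d year-affected variables\n"),
              nrow(x$meta), length(x$blocks), ncol(x$blocks[[1]]$values),
              length(x$truth$marker_idx), length(x$truth$year_idx)))
  invisible(x)
}

#' Expected organic/conventional ratio of a planted marker
#'
#' The generator plants a signed log2 effect `d` on each system marker
#' (organic minus conventional). Because all other factors are shared in
#' expectation between the paired groups, the implied arithmetic-mean
#' peak-area ratio is `2^d`.
#'
#' @param truth the `ground_truth` from [generate_dataset()].
#' @param var_index marker variable, as a column index or bucket id.
#' @return the expected organic/conventional ratio.
#' @export
planted_ratio <- function(truth, var_index) {
  stopifnot(inherits(truth, "ground_truth"))
  pos <- if (is.character(var_index)) {
    match(var_index, truth$marker_id)
  } else {
    match(var_index, truth$marker_idx)
  }
  if (anyNA(pos)) {
    stop("variable '", var_index[which(is.na(pos))[1]],
         "' is not a planted system marker")
  }
  2^truth$marker_log2[pos]
}

#' Write the ground truth as delimited text
#'
#' Two sections are written side by side as a long table: one row per
#' planted effect, with `kind` either `system_marker` (signed log2 effect,
#' implied ratio) or `year_affected`.
#'
#' @param truth the `ground_truth` from [generate_dataset()].
#' @param path output file (comma for `.csv`, tab otherwise).
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  df <- rbind(
    data.frame(kind = "system_marker", bucket_id = truth$marker_id,
               var_index = truth$marker_idx, log2_effect = truth$marker_log2,
               ratio = 2^truth$marker_log2, stringsAsFactors = FALSE),
    data.frame(kind = "year_affected", bucket_id = truth$year_id,
               var_index = truth$year_idx, log2_effect = NA_real_,
               ratio = NA_real_, stringsAsFactors = FALSE))
  data.table::fwrite(df, path, sep = delim_for(path))
  invisible(path)
}

#' Sum-normalize each block and combine into the full feature table
#'
#' Convenience wrapper over the canonical preprocessing order: per-analysis
#' sum normalization inside every ionization block, then column
#' concatenation of the blocks.
#'
#' @param dataset a `synthetic_dataset` (or any list of raw block
#'   [feature_table()]s).
#' @return the combined, sum-normalized [feature_table()].
#' @export
prepare_dataset <- function(dataset) {
  blocks <- if (inherits(dataset, "synthetic_dataset")) dataset$blocks else dataset
  combine_blocks(lapply(blocks, normalize_total))
}
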