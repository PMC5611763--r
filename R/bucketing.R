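#' Bucketing parameters
#'
#' Parameters of the fixed retention-time by m/z grid onto which centroid
#' peaks are aggregated ("advanced bucketing"): half-open cells of width
#' `delta_rt` minutes by `delta_mz` Th, anchored at `(rt_min, mz_min)`,
#' spanning RT 0.5--20 min and m/z 60.5--850.5 by default. The
#' feature-detection settings of the upstream vendor peak picker
#' (signal-to-noise threshold, correlation threshold, minimum compound
#' length, smoothing width) are stored as provenance metadata only; peak
#' detection itself is not performed here, bucketing consumes
#' already-centroided peak lists.
#'
#' @param rt_min,rt_max retention-time range in minutes (peaks at
#'   `rt >= rt_max` are dropped).
#' @param mz_min,mz_max m/z range (half-open on the right).
#' @param delta_rt grid cell width in minutes.
#' @param delta_mz grid cell width in m/z.
#' @param sn_threshold,corr_threshold,min_length,smoothing provenance
#'   metadata describing the upstream feature detector; stored, not executed.
#' @return an object of class `bucketing_params`.
#' @export
bucketing_params <- function(rt_min = 0.5, rt_max = 20,
                             mz_min = 60.5, mz_max = 850.5,
                             delta_rt = 0.3, delta_mz = 0.005,
                             sn_threshold = 2, corr_threshold = 0.7,
                             min_length = 10, smoothing = 2) {
  if (!(rt_max > rt_min)) stop("rt_max must exceed rt_min")
  if (!(mz_max > mz_min)) stop("mz_max must exceed mz_min")
  if (!(delta_rt > 0) || !(delta_mz > 0)) stop("grid deltas must be positive")
  structure(list(rt_min = rt_min, rt_max = rt_max,
                 mz_min = mz_min, mz_max = mz_max,
                 delta_rt = delta_rt, delta_mz = delta_mz,
                 detector = list(sn_threshold = sn_threshold,
                                 corr_threshold = corr_threshold,
                                 min_length = min_length,
                                 smoothing = smoothing)),
            class = "bucketing_params")
}

#' Construct a centroid peak list
#'
#' @param rt,mz,intensity numeric vectors of equal length; one centroid peak
#'   per element. All must be finite and intensities strictly positive.
#' @param mode,fraction acquisition-block tags for the analysis the peaks
#'   came from.
#' @return an object of class `peak_list` (a data.frame with attributes
#'   `mode` and `fraction`).
#' @export
peak_list <- function(rt, mz, intensity, mode = "ESI+", fraction = "MW") {
  if (!(length(rt) == length(mz) && length(mz) == length(intensity))) {
    stop("rt, mz and intensity must have equal length")
  }
  if (length(rt) && (any(!is.finite(rt)) || any(!is.finite(mz)) ||
                     any(!is.finite(intensity)))) {
    stop("peak rt, mz and intensity must be finite")
  }
  if (length(intensity) && any(intensity <= 0)) {
    stop("peak intensities must be strictly positive")
  }
  structure(data.frame(rt = rt, mz = mz, intensity = intensity),
            mode = mode, fraction = fraction, class = c("peak_list", "data.frame"))
}

#' Read a centroid peak list from delimited text
#'
#' Expects columns `rt` (minutes), `mz` and `intensity`.
#'
#' @param path delimited text file (comma for `.csv`, tab otherwise).
#' @inheritParams peak_list
#' @return a [peak_list()].
#' @export
read_peak_list <- function(path, mode = "ESI+", fraction = "MW") {
  dt <- data.table::fread(path, sep = delim_for(path), header = TRUE,
                          data.table = FALSE)
  miss <- setdiff(c("rt", "mz", "intensity"), names(dt))
  if (length(miss)) stop("peak list lacks columns: ", paste(miss, collapse = ", "))
  peak_list(dt$rt, dt$mz, dt$intensity, mode = mode, fraction = fraction)
}

#' Read centroided peaks from an mzML file
#'
#' Thin adapter over the `mzR` parser: every point of every centroided MS1
#' spectrum becomes a peak, with retention time converted to minutes.
#' Profile-mode data are rejected rather than centroided here.
#'
#' @param path mzML file.
#' @inheritParams peak_list
#' @return a [peak_list()].
#' @export
read_peaks_mzml <- function(path, mode = "ESI+", fraction = "MW") {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop("mzML input requires the mzR package")
  }
  h <- mzR::openMSfile(path)
  on.exit(mzR::close(h))
  hdr <- mzR::header(h)
  hdr <- hdr[hdr$msLevel == 1L, , drop = FALSE]
  if (!nrow(hdr)) stop("no MS1 spectra in ", path)
  if (!is.null(hdr$centroided) && any(!hdr$centroided, na.rm = TRUE)) {
    stop("profile-mode spectra in ", path, "; centroid the data upstream")
  }
  pk <- mzR::peaks(h, hdr$seqNum)
  if (is.matrix(pk)) pk <- list(pk)
  rt <- rep(hdr$retentionTime / 60, vapply(pk, nrow, integer(1)))
  m <- do.call(rbind, pk)
  keep <- m[, 2] > 0
  peak_list(rt[keep], m[keep, 1], m[keep, 2], mode = mode, fraction = fraction)
}

# Half-open grid index with edge correction: floor((x-lo)/delta) can land a
# value sitting exactly on a representable edge in the lower cell (e.g.
# 0.8 - 0.5 < 0.3 in doubles); membership is defined against edges computed
# as lo + i*delta, so such values are nudged into the upper cell.
grid_index <- function(x, lo, delta) {
  i <- floor((x - lo) / delta)
  up <- x >= lo + (i + 1) * delta
  i[up] <- i[up] + 1
  dn <- x < lo + i * delta
  i[dn] <- i[dn] - 1
  i
}

#' Aggregate a centroid peak list onto the bucketing grid
#'
#' Peaks outside `[rt_min, rt_max)` or `[mz_min, mz_max)` are dropped;
#' surviving peaks are assigned to half-open grid cells anchored at
#' `(rt_min, mz_min)` and intensities within a cell are summed. The result
#' is a one-sample [feature_table()] whose bucket identifiers encode the
#' cell centres and the analysis' mode/fraction tags.
#'
#' @param peaks a [peak_list()].
#' @param params a [bucketing_params()].
#' @param analysis_id sample identifier for the resulting row.
#' @return a [feature_table()] with one row. If no peak survives the range
#'   filter the table has zero columns and a warning is raised.
#' @export
bucket_peaks <- function(peaks, params = bucketing_params(),
                         analysis_id = "analysis1") {
  stopifnot(inherits(peaks, "peak_list"), inherits(params, "bucketing_params"))
  mode <- attr(peaks, "mode"); fraction <- attr(peaks, "fraction")
  keep <- peaks$rt >= params$rt_min & peaks$rt < params$rt_max &
    peaks$mz >= params$mz_min & peaks$mz < params$mz_max
  p <- peaks[keep, , drop = FALSE]
  if (!nrow(p)) {
    warning("no peaks inside the bucketing range for ", analysis_id)
    v <- matrix(numeric(0), nrow = 1, ncol = 0,
                dimnames = list(analysis_id, character(0)))
    return(feature_table(v, bucket_meta = data.frame(
      bucket_id = character(0), rt = numeric(0), mz = numeric(0),
      mode = character(0), fraction = character(0))))
  }
  i_rt <- grid_index(p$rt, params$rt_min, params$delta_rt)
  i_mz <- grid_index(p$mz, params$mz_min, params$delta_mz)
  cell <- paste(i_rt, i_mz, sep = "_")
  agg <- rowsum(p$intensity, group = cell)
  first <- !duplicated(cell)
  key <- cell[first]
  rt_c <- params$rt_min + (i_rt[first] + 0.5) * params$delta_rt
  mz_c <- params$mz_min + (i_mz[first] + 0.5) * params$delta_mz
  ord <- order(rt_c, mz_c)
  ids <- make_bucket_id(rt_c[ord], mz_c[ord], mode = mode, fraction = fraction)
  v <- matrix(agg[match(key[ord], rownames(agg)), 1], nrow = 1,
              dimnames = list(analysis_id, ids))
  feature_table(v, bucket_meta = data.frame(
    bucket_id = ids, rt = rt_c[ord], mz = mz_c[ord],
    mode = mode, fraction = fraction, stringsAsFactors = FALSE))
}

#' Bucket a batch of analyses into one feature table
#'
#' Each analysis' peaks are bucketed with [bucket_peaks()] and the rows are
#' assembled over the sparse union of occupied grid cells: a bucket present
#' in any analysis is materialized for all, with 0 intensity where absent.
#'
#' @param peak_lists named list of [peak_list()] objects; names are the
#'   sample identifiers.
#' @param params a [bucketing_params()].
#' @return a [feature_table()] with one row per analysis.
#' @export
bucket_analyses <- function(peak_lists, params = bucketing_params()) {
  stopifnot(is.list(peak_lists), length(peak_lists) >= 1L,
            !is.null(names(peak_lists)), all(nzchar(names(peak_lists))))
  rows <- lapply(names(peak_lists), function(id) {
    bucket_peaks(peak_lists[[id]], params, analysis_id = id)
  })
  metas <- do.call(rbind, lapply(rows, `[[`, "bucket_meta"))
  metas <- metas[!duplicated(metas$bucket_id), , drop = FALSE]
  metas <- metas[order(metas$mode, metas$fraction, metas$rt, metas$mz), ,
                 drop = FALSE]
  rownames(metas) <- NULL
  v <- matrix(0, nrow = length(rows), ncol = nrow(metas),
              dimnames = list(names(peak_lists), metas$bucket_id))
  for (k in seq_along(rows)) {
    rv <- rows[[k]]$values
    if (ncol(rv)) v[k, colnames(rv)] <- rv[1, ]
  }
  feature_table(v, bucket_meta = metas)
}
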