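#' Construct a bucketed feature table
#'
#' A feature table holds the intensities of one batch of LC-MS analyses as a
#' samples-by-buckets matrix. Each bucket (column) is one cell of a fixed
#' retention-time by m/z grid, tagged with its ionization mode and extraction
#' fraction so that tables from different acquisition blocks can be
#' concatenated without identifier collisions.
#'
#' @param values numeric matrix (samples x buckets) of non-negative
#'   intensities, with sample identifiers as row names and bucket identifiers
#'   as column names.
#' @param bucket_meta optional `data.frame` with one row per bucket and
#'   columns `bucket_id`, `rt`, `mz`, `mode`, `fraction` describing the grid
#'   cell each column represents. When omitted, an attempt is made to parse
#'   the metadata out of structured bucket identifiers (see
#'   [make_bucket_id()]); unparseable identifiers yield `NA` metadata.
#'
#' @return An object of class `feature_table`: a list with elements `values`
#'   (the matrix) and `bucket_meta`.
#' @export
#' @examples
#' m <- matrix(c(2, 3, 5, 7), nrow = 2,
#'             dimnames = list(c("s1", "s2"), c("b1", "b2")))
#' ft <- feature_table(m)
#' dim(ft)
feature_table <- function(values, bucket_meta = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("feature table values must be numeric")
  if (is.null(rownames(values))) stop("feature table requires sample ids as row names")
  if (is.null(colnames(values)) && ncol(values) > 0L) {
    stop("feature table requires bucket ids as column names")
  }
  dup_s <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_s)) {
    stop("duplicate sample ids: ", paste(dup_s, collapse = ", "))
  }
  dup_b <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_b)) {
    stop("duplicate bucket ids: ", paste(utils::head(dup_b, 5), collapse = ", "))
  }
  if (any(!is.finite(values))) stop("feature table values must be finite")
  if (any(values < 0)) stop("feature table values must be non-negative")
  if (is.null(bucket_meta)) {
    bucket_meta <- parse_bucket_ids(colnames(values))
  } else {
    bucket_meta <- as.data.frame(bucket_meta)
    need <- c("bucket_id", "rt", "mz", "mode", "fraction")
    miss <- setdiff(need, names(bucket_meta))
    if (length(miss)) stop("bucket_meta lacks columns: ", paste(miss, collapse = ", "))
    if (nrow(bucket_meta) != ncol(values) ||
        !identical(as.character(bucket_meta$bucket_id),
                   as.character(colnames(values) %||% character(0)))) {
      stop("bucket_meta rows must match table columns (same ids, same order)")
    }
  }
  structure(list(values = values, bucket_meta = bucket_meta),
            class = "feature_table")
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d samples x %d buckets\n",
              nrow(x$values), ncol(x$values)))
  md <- x$bucket_meta
  if (nrow(md) && !all(is.na(md$mode))) {
    blk <- table(paste(md$mode, md$fraction, sep = "/"))
    cat("  blocks:", paste(sprintf("%s (%d)", names(blk), blk), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @rdname feature_table
#' @param x a `feature_table`.
#' @export
sample_ids <- function(x) rownames(x$values)

#' @rdname feature_table
#' @export
bucket_ids <- function(x) colnames(x$values)

#' Compose / parse structured bucket identifiers
#'
#' Bucket identifiers encode the grid-cell centre and acquisition block as
#' `"<mode>|<fraction>|<rt>|<mz>"`, e.g. `"ESI+|MW|0.950|100.0025"` (RT in
#' minutes, m/z in Thomson). Identifiers of this shape can be parsed back
#' into bucket metadata; anything else is carried through with `NA` metadata.
#'
#' @param rt,mz numeric grid-cell centres.
#' @param mode ionization mode label, e.g. `"ESI+"`, `"ESI-"`, `"ESI-acid"`.
#' @param fraction extraction fraction label, e.g. `"MW"` (methanol/water)
#'   or `"C"` (chloroform).
#' @return `make_bucket_id`: character vector of identifiers.
#' @export
make_bucket_id <- function(rt, mz, mode = "ESI+", fraction = "MW") {
  sprintf("%s|%s|%.3f|%.4f", mode, fraction, rt, mz)
}

#' @rdname make_bucket_id
#' @param ids character vector of bucket identifiers.
#' @return `parse_bucket_ids`: data.frame with columns `bucket_id`, `rt`,
#'   `mz`, `mode`, `fraction`.
#' @export
parse_bucket_ids <- function(ids) {
  parts <- strsplit(ids, "|", fixed = TRUE)
  ok <- lengths(parts) == 4L
  out <- data.frame(bucket_id = ids,
                    rt = NA_real_, mz = NA_real_,
                    mode = NA_character_, fraction = NA_character_,
                    stringsAsFactors = FALSE)
  if (any(ok)) {
    m <- do.call(rbind, parts[ok])
    rt <- suppressWarnings(as.numeric(m[, 3L]))
    mz <- suppressWarnings(as.numeric(m[, 4L]))
    num_ok <- is.finite(rt) & is.finite(mz)
    idx <- which(ok)[num_ok]
    out$mode[idx] <- m[num_ok, 1L]
    out$fraction[idx] <- m[num_ok, 2L]
    out$rt[idx] <- rt[num_ok]
    out$mz[idx] <- mz[num_ok]
  }
  rownames(out) <- NULL
  out
}

delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read / write feature tables as delimited text
#'
#' The on-disk format is plain delimited text (comma for `.csv`, tab
#' otherwise), first column `sample_id`, remaining columns one per bucket
#' with the bucket identifier in the header. `write_feature_table` prints
#' values with 17 significant digits so that `read_feature_table` recovers
#' them bit-exactly.
#'
#' @param path file path; the extension selects the delimiter.
#' @return `read_feature_table`: a [feature_table()].
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  nf <- utils::count.fields(path, sep = delim_for(path), comment.char = "")
  if (length(unique(nf)) > 1L) {
    bad <- which(nf != nf[1])[1]
    stop("malformed feature table '", path, "': ragged row at line ", bad,
         " (", nf[bad], " fields, expected ", nf[1], ")")
  }
  dt <- tryCatch(
    data.table::fread(path, sep = delim_for(path), header = TRUE,
                      fill = FALSE, data.table = TRUE,
                      colClasses = list(character = 1L)),
    error = function(e) stop("malformed feature table '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (ncol(dt) < 2L) stop("feature table '", path, "' has no bucket columns")
  ids <- as.character(dt[[1L]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) stop("duplicate sample ids in '", path, "': ",
                        paste(dup, collapse = ", "))
  hdr <- names(dt)[-1L]
  duph <- unique(hdr[duplicated(hdr)])
  if (length(duph)) stop("duplicate bucket ids in '", path, "': ",
                         paste(duph, collapse = ", "))
  for (j in seq.int(2L, ncol(dt))) {
    bad <- if (!is.numeric(dt[[j]])) {
      which(is.na(suppressWarnings(as.numeric(dt[[j]]))))
    } else {
      which(is.na(dt[[j]]))
    }
    if (!is.numeric(dt[[j]]) || length(bad)) {
      stop(sprintf("non-numeric value in '%s' at row %d, column '%s'",
                   path, if (length(bad)) bad[1L] else 1L, names(dt)[j]))
    }
  }
  values <- as.matrix(dt[, -1L, drop = FALSE])
  rownames(values) <- ids
  feature_table(values)
}

#' @rdname read_feature_table
#' @param table a [feature_table()].
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  sep <- delim_for(path)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("sample_id", colnames(table$values)), collapse = sep), con)
  v <- table$values
  for (i in seq_len(nrow(v))) {
    writeLines(paste(c(rownames(v)[i], sprintf("%.17g", v[i, ])),
                     collapse = sep), con)
  }
  invisible(path)
}

#' Read / write sample metadata
#'
#' Sample metadata carries the design factors of the study: harvest `year`,
#' production `system` (`"organic"` or `"conventional"`), `cultivar`,
#' `field_code` and `location`, keyed by `sample_id`.
#'
#' @param path delimited text file (comma for `.csv`, tab otherwise).
#' @return `read_sample_meta`: a `data.frame` with one row per sample.
#' @export
read_sample_meta <- function(path) {
  dt <- data.table::fread(path, sep = delim_for(path), header = TRUE,
                          data.table = FALSE)
  need <- c("sample_id", "year", "system")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop("sample metadata lacks columns: ",
                         paste(miss, collapse = ", "))
  dt$sample_id <- as.character(dt$sample_id)
  dup <- unique(dt$sample_id[duplicated(dt$sample_id)])
  if (length(dup)) stop("duplicate sample ids in metadata: ",
                        paste(dup, collapse = ", "))
  if (anyNA(dt$year) || anyNA(dt$system)) {
    stop("sample metadata must have non-missing year and system")
  }
  dt
}

#' @rdname read_sample_meta
#' @param meta sample metadata `data.frame`.
#' @export
write_sample_meta <- function(meta, path) {
  data.table::fwrite(meta, path, sep = delim_for(path))
  invisible(path)
}

#' Align sample metadata to a feature table
#'
#' Reorders metadata rows to the table's sample order and errors if the two
#' id sets differ.
#'
#' @param table a [feature_table()].
#' @param meta sample metadata `data.frame` with a `sample_id` column.
#' @return the reordered metadata.
#' @export
align_meta <- function(table, meta) {
  ids <- sample_ids(table)
  missing_m <- setdiff(ids, meta$sample_id)
  extra_m <- setdiff(meta$sample_id, ids)
  if (length(missing_m) || length(extra_m)) {
    stop("sample ids differ between table and metadata; missing from metadata: [",
         paste(missing_m, collapse = ", "), "], absent from table: [",
         paste(extra_m, collapse = ", "), "]")
  }
  out <- meta[match(ids, meta$sample_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Subset a feature table
#'
#' @param table a [feature_table()].
#' @param samples,buckets character ids (or logical/integer index vectors)
#'   selecting rows / columns; `NULL` keeps all.
#' @return a [feature_table()].
#' @export
subset_table <- function(table, samples = NULL, buckets = NULL) {
  v <- table$values
  md <- table$bucket_meta
  if (!is.null(samples)) v <- v[samples, , drop = FALSE]
  if (!is.null(buckets)) {
    v <- v[, buckets, drop = FALSE]
    md <- md[match(colnames(v), md$bucket_id), , drop = FALSE]
    rownames(md) <- NULL
  }
  feature_table(v, bucket_meta = md)
}

#' Column-concatenate feature tables from different acquisition blocks
#'
#' Tables from the individual ionization-mode / fraction blocks are combined
#' into the "All" dataset by aligning rows on sample id and concatenating
#' columns. Bucket identifiers are already namespaced by mode and fraction;
#' should two blocks still collide, the colliding block's ids are prefixed
#' with its position.
#'
#' @param tables list of [feature_table()] objects with identical sample-id
#'   sets (any row order).
#' @return a single [feature_table()].
#' @export
combine_blocks <- function(tables) {
  stopifnot(is.list(tables), length(tables) >= 1L)
  for (t in tables) stopifnot(inherits(t, "feature_table"))
  ref <- sample_ids(tables[[1L]])
  for (k in seq_along(tables)[-1L]) {
    ids <- sample_ids(tables[[k]])
    a <- setdiff(ref, ids); b <- setdiff(ids, ref)
    if (length(a) || length(b)) {
      stop("block ", k, " sample ids differ from block 1; only in block 1: [",
           paste(a, collapse = ", "), "], only in block ", k, ": [",
           paste(b, collapse = ", "), "]")
    }
  }
  seen <- character(0)
  vals <- vector("list", length(tables))
  metas <- vector("list", length(tables))
  for (k in seq_along(tables)) {
    t <- tables[[k]]
    v <- t$values[match(ref, sample_ids(t)), , drop = FALSE]
    md <- t$bucket_meta
    clash <- colnames(v) %in% seen
    if (any(clash)) {
      colnames(v)[clash] <- paste0("b", k, ":", colnames(v)[clash])
      md$bucket_id <- colnames(v)
    }
    seen <- c(seen, colnames(v))
    vals[[k]] <- v
    metas[[k]] <- md
  }
  feature_table(do.call(cbind, vals), bucket_meta = do.call(rbind, metas))
}
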