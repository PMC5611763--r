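#' Declarative configuration for an end-to-end pipeline run
#'
#' Collects everything one model-building recipe needs: the data source
#' (paths to block tables + metadata, or a [synthetic_config()] to
#' simulate), the preprocessing and refinement settings, the split
#' strategy, and the component-search settings. Every run records its seed
#' and a hash of the configuration in the outputs.
#'
#' @param out_dir directory for the run's artifacts (created if absent).
#' @param block_paths character vector of feature-table files (one per
#'   ionization block), or `NULL` to simulate.
#' @param meta_path sample-metadata file (ignored when simulating).
#' @param synthetic a [synthetic_config()] used when `block_paths` is
#'   `NULL`.
#' @param deconfound confounding factor to remove before the system model
#'   (metadata column name, default `"year"`), or `NULL` to skip
#'   deconfounding.
#' @param deconfound_a_orth orthogonal components of the confounder model.
#' @param split list describing the external-validation split: `strategy`
#'   plus its argument (`year`, `cultivar`, or `field_codes`), as in
#'   [make_split()].
#' @param vip_threshold VIP threshold used for deconfounding removal.
#' @param a_orth_max largest orthogonal-component count searched by the
#'   sevenfold cross-validation.
#' @param increment Q2 gain required to accept one more orthogonal
#'   component ([select_components()]).
#' @param n_markers marker candidates contributed by each selection route
#'   ([select_candidates()]).
#' @param alpha family-wise error rate for the Bonferroni flag.
#' @param seed seed for the random split (and the simulation, unless the
#'   synthetic config carries its own).
#' @param label free-text model label written into the summary.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("fieldprint_run_"),
                            block_paths = NULL, meta_path = NULL,
                            synthetic = synthetic_config(),
                            deconfound = "year", deconfound_a_orth = 2L,
                            split = list(strategy = "random_third"),
                            vip_threshold = 1.0, a_orth_max = 5L,
                            increment = 0.01, n_markers = 24L,
                            alpha = 0.05, seed = 1L, label = "model") {
  if (!is.null(block_paths) && is.null(meta_path)) {
    stop("meta_path is required when block_paths is given")
  }
  stopifnot(is.list(split), !is.null(split$strategy))
  structure(list(out_dir = out_dir, block_paths = block_paths,
                 meta_path = meta_path, synthetic = synthetic,
                 deconfound = deconfound,
                 deconfound_a_orth = as.integer(deconfound_a_orth),
                 split = split, vip_threshold = vip_threshold,
                 a_orth_max = as.integer(a_orth_max),
                 increment = increment, n_markers = as.integer(n_markers),
                 alpha = alpha, seed = as.integer(seed), label = label),
            class = "pipeline_config")
}

log_stage <- function(...) message("[fieldprint] ", ...)

#' Run one model-building recipe end to end
#'
#' Executes simulate/load -> per-block sum normalization -> block
#' combination -> external split -> (optional) confounder deconfounding on
#' the training set -> sevenfold cross-validated component selection ->
#' OPLS-DA fit -> external validation -> ROC -> S-plot/VIP marker
#' candidates -> univariate marker statistics, writing each artifact under
#' `config$out_dir`:
#' `config.yaml`, `summary.csv` (one Table-1-style row), `predictions.csv`,
#' `roc.csv`, `vip.csv`, `splot.csv`, `removed.csv`, `markers.csv`,
#' `scaling.tsv`, `model.txt`, plus (for simulated data) `meta.csv` and
#' `ground_truth.csv`.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a list with the `summary` row (data.frame), the
#'   fitted `model`, the `report` ([evaluate()]), the `roc_curve`, the
#'   `markers` table and the `split`.
#' @export
run_recipe <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(config$out_dir, "config.yaml")
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  yaml::write_yaml(strip(config[setdiff(names(config), "out_dir")]), cfg_path)
  cfg_hash <- unname(tools::md5sum(cfg_path))
  log_stage("recipe '", config$label, "' (seed ", config$seed,
            ", config ", substr(cfg_hash, 1, 8), ")")

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  truth <- NULL
  if (is.null(config$block_paths)) {
    ds <- stage("simulate", {
      sc <- config$synthetic
      sc$seed <- config$seed
      generate_dataset(sc)
    })
    blocks <- ds$blocks
    meta <- ds$meta
    truth <- ds$truth
    write_sample_meta(meta, file.path(config$out_dir, "meta.csv"))
    write_ground_truth(truth, file.path(config$out_dir, "ground_truth.csv"))
    log_stage("simulated ", nrow(meta), " samples x ",
              sum(vapply(blocks, function(b) ncol(b$values), integer(1))),
              " variables")
  } else {
    blocks <- stage("load", lapply(config$block_paths, read_feature_table))
    meta <- stage("load", read_sample_meta(config$meta_path))
  }

  table <- stage("normalize+combine", prepare_dataset(blocks))
  meta <- align_meta(table, meta)

  split_args <- config$split
  split <- stage("split", do.call(make_split, c(
    list(meta = meta, strategy = split_args$strategy, seed = config$seed),
    split_args[setdiff(names(split_args), "strategy")])))
  train_tab <- subset_table(table, samples = split$train)
  train_meta <- align_meta(train_tab, meta[meta$sample_id %in% split$train, ])
  log_stage("split '", split$strategy, "': ", length(split$train),
            " train / ", length(split$test), " test")

  removed <- character(0)
  if (!is.null(config$deconfound)) {
    dec <- stage("deconfound", deconfound_factor(
      train_tab, train_meta, factor = config$deconfound,
      a_orth = config$deconfound_a_orth,
      vip_threshold = config$vip_threshold))
    removed <- dec$removed
    train_tab <- dec$table
    write_refinement(removed, file.path(config$out_dir, "removed.csv"))
    log_stage("deconfounded '", config$deconfound, "': removed ",
              length(removed), " variables, ", ncol(train_tab$values),
              " remain")
  }
  test_tab <- subset_table(table, samples = split$test,
                           buckets = bucket_ids(train_tab))
  test_meta <- align_meta(test_tab, meta[meta$sample_id %in% split$test, ])

  cv <- stage("cross-validate", cross_validate(
    train_tab, train_meta$system, a_orth_max = config$a_orth_max,
    order_keys = train_meta[, c("year", "sample_id")]))
  sel <- select_components(cv, increment = config$increment)
  log_stage("selected ", sel$a_pred, " + ", sel$a_orth,
            " + 0 components, Q2(cum) = ", sprintf("%.3f", sel$q2))

  model <- stage("fit", opls_train(train_tab, train_meta$system,
                                   a_orth = sel$a_orth))
  write_opls(model, file.path(config$out_dir, "model.txt"))
  write_scaling(model$scaling, file.path(config$out_dir, "scaling.tsv"))

  report <- stage("evaluate", evaluate(model, test_tab, test_meta))
  write_validation(report, file.path(config$out_dir, "predictions.csv"))
  rc <- stage("roc", roc(report$predictions$response,
                         report$predictions$truth,
                         positive = model$encoding$positive))
  data.table::fwrite(data.table::data.table(threshold = rc$thresholds,
                                            fpr = rc$fpr, tpr = rc$tpr),
                     file.path(config$out_dir, "roc.csv"))

  Xs <- apply_scaling(train_tab, model$scaling)
  vip <- vip_scores(model)
  sp <- s_plot(model, Xs)
  write_refinement(vip, file.path(config$out_dir, "vip.csv"))
  write_refinement(sp, file.path(config$out_dir, "splot.csv"))
  candidates <- select_candidates(model, Xs, n_top = config$n_markers,
                                  vip_threshold = config$vip_threshold)
  markers <- stage("markers", marker_stats(
    subset_table(table, samples = split$train, buckets = bucket_ids(train_tab)),
    train_meta, candidates = candidates,
    m_total = ncol(train_tab$values), alpha = config$alpha))
  write_markers(markers, file.path(config$out_dir, "markers.csv"))

  summary <- data.frame(
    label = config$label,
    classification = "C vs O",
    variables = ncol(train_tab$values),
    components = sprintf("%d + %d + 0", sel$a_pred, sel$a_orth),
    r2y = model$r2y, q2_cum = sel$q2,
    internal_rate = cv$internal_rate[sel$a_orth + 1L],
    validation = split$strategy,
    external_rate = report$rate,
    sensitivity = report$sensitivity,
    specificity = report$specificity,
    auc = rc$auc,
    n_removed = length(removed),
    seed = config$seed,
    config_md5 = cfg_hash,
    stringsAsFactors = FALSE)
  data.table::fwrite(summary, file.path(config$out_dir, "summary.csv"))
  log_stage("external rate ", sprintf("%.1f", report$rate),
            "%, sensitivity ", sprintf("%.1f", report$sensitivity),
            "%, specificity ", sprintf("%.1f", report$specificity),
            "%, AUC ", sprintf("%.3f", rc$auc))

  invisible(list(summary = summary, model = model, report = report,
                 roc = rc, markers = markers, split = split,
                 cv = cv, removed = removed, truth = truth))
}
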