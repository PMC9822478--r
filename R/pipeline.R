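# End-to-end orchestration: dataset (synthetic or CSV of SMILES) ->
# standardization -> features -> ensemble splits -> Mondrian aggregated
# conformal prediction -> metrics report, with an optional output directory
# holding every intermediate file plus a run manifest.

default_experiment_config <- function() {
  list(
    dataset = list(type = "synthetic", regime = "vt", n_train = 5000L,
                   n_eval = 2000L, dimension = 16L, delta = 1.5,
                   label_noise = 0),
    model = list(K = 10L, fractions = c(train = 0.72, dl_val = 0.08, calib = 0.20),
                 smoothing = FALSE, ntree = 500L),
    epsilons = c(0.1, 0.15, 0.2, 0.25, 0.3),
    headline_epsilon = 0.2,
    seed = 1L,
    tags = list(dataset = NULL, method = "rf")
  )
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    base[[nm]] <- if (is.list(user[[nm]]) && is.list(base[[nm]])) {
      merge_config(base[[nm]], user[[nm]])
    } else {
      user[[nm]]
    }
  }
  base
}

#' Run a full conformal-prediction experiment
#'
#' Executes the pipeline stages in order for one configuration: obtain
#' features and labels (synthetic generator, or CSV files of molecules that
#' are standardized and featurized), hold out the evaluation set, build the
#' ensemble splits, fit the Mondrian aggregated conformal predictor, and
#' compute the metrics report at every configured significance level.
#' Idempotent given the seed: rerunning a config reproduces the report
#' byte-for-byte.
#'
#' @param config a nested list (or path to a YAML file) overriding the
#'   defaults: `dataset` (`type = "synthetic"` with `regime`, `n_train`,
#'   `n_eval`, `dimension`, `delta`, `label_noise`; or `type = "csv"` with
#'   `train`, `eval` file paths of `id,smiles,label`), `model` (`K`,
#'   `fractions`, `smoothing`, `ntree`), `epsilons`, `headline_epsilon`,
#'   `seed`, `tags`.
#' @param outdir optional directory; when given, all intermediate files
#'   (features, split manifest, aggregated p-values, prediction sets, report)
#'   and a YAML run manifest are written there.
#' @return list with `report` (one row per significance level), `metrics`
#'   (list of [cp_metrics()] rows), `pvalues`, `sets`, `fit`, `labels_eval`,
#'   `manifest`.
#' @export
run_experiment <- function(config = list(), outdir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(default_experiment_config(), config)
  cfg$model$fractions <- stats::setNames(as.numeric(cfg$model$fractions),
                                         c("train", "dl_val", "calib"))
  seed <- as.integer(cfg$seed)
  counts <- list()

  if (identical(cfg$dataset$type, "synthetic")) {
    ds <- cfg$dataset
    sc <- synth_config(regime = ds$regime %||% "custom",
                       n_total = ds$n_train + ds$n_eval,
                       imbalance = ds$imbalance %||% 11,
                       dimension = ds$dimension %||% 16L,
                       delta = ds$delta %||% 1.5,
                       label_noise = ds$label_noise %||% 0,
                       seed = seed)
    syn <- generate_tabular(sc)
    set.seed(derive_seed(seed, 2L, stream = 4L))
    eval_ids <- sample(rownames(syn$x), ds$n_eval)
    pool_ids <- setdiff(rownames(syn$x), eval_ids)
    x_pool <- syn$x[pool_ids, , drop = FALSE]
    x_eval <- syn$x[eval_ids, , drop = FALSE]
    y_pool <- syn$labels[pool_ids]
    y_eval <- syn$labels[eval_ids]
    dataset_tag <- cfg$tags$dataset %||% paste0("synthetic_", sc$regime)
    counts$generated <- nrow(syn$x)
  } else if (identical(cfg$dataset$type, "csv")) {
    read_side <- function(path) {
      raw <- utils::read.csv(path, stringsAsFactors = FALSE)
      std <- standardize_dataset(raw, std_config())
      feats <- compute_descriptors(std$kept,
                                   cfg$dataset$descriptors %||% default_descriptors())
      keep <- rownames(feats)
      list(x = feats,
           y = stats::setNames(std$kept$label[match(keep, std$kept$id)], keep),
           std = std)
    }
    tr <- read_side(cfg$dataset$train)
    ev <- read_side(cfg$dataset$eval)
    x_pool <- tr$x; y_pool <- tr$y
    x_eval <- ev$x; y_eval <- ev$y
    dataset_tag <- cfg$tags$dataset %||% basename(cfg$dataset$train)
    counts$standardization_train <- as.list(tr$std$report)
    counts$standardization_eval <- as.list(ev$std$report)
  } else {
    stop("dataset$type must be 'synthetic' or 'csv'", call. = FALSE)
  }
  counts$pool <- nrow(x_pool)
  counts$evaluation <- nrow(x_eval)

  splits <- make_splits(rownames(x_pool), y_pool,
                        fractions = cfg$model$fractions,
                        K = cfg$model$K, seed = seed,
                        evaluation_ids = rownames(x_eval))
  fit <- mondrian_acp(x_pool, y_pool, splits = splits,
                      learner = rf_learner(ntree = cfg$model$ntree),
                      smoothing = isTRUE(cfg$model$smoothing), seed = seed)
  p <- stats::predict(fit, x_eval)
  sets_all <- lapply(cfg$epsilons, function(e) predict_set(p, e))
  metrics <- lapply(sets_all, function(s)
    cp_metrics(s, y_eval, dataset = dataset_tag, method = cfg$tags$method))
  report <- report_table(metrics)

  manifest <- list(config = cfg, master_seed = seed,
                   package_version = as.character(utils::packageVersion("macp")),
                   counts = counts,
                   member_seeds = vapply(splits, `[[`, integer(1), "seed"),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(data.frame(id = rownames(x_eval), p, check.names = FALSE),
                     file.path(outdir, "pvalues_agg.csv"), row.names = FALSE)
    utils::write.csv(do.call(rbind, sets_all), file.path(outdir, "sets.csv"),
                     row.names = FALSE)
    utils::write.csv(split_manifest(splits), file.path(outdir, "splits.csv"),
                     row.names = FALSE)
    report_table(metrics, file.path(outdir, "report.csv"))
    yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  }

  list(report = report, metrics = metrics, pvalues = p,
       sets = do.call(rbind, sets_all), fit = fit, labels_eval = y_eval,
       manifest = manifest)
}

#' Ingest a local acute-toxicity benchmark file
#'
#' Maps a locally downloaded benchmark table (the package never downloads) to
#' the pipeline's `id,smiles,label` layout for one binary endpoint, preserving
#' the benchmark's original train/evaluation assignment. Column names vary
#' between benchmark releases, so detection is permissive and overridable via
#' `mapping`.
#'
#' @param path CSV/TSV file.
#' @param endpoint `"vt"` (very-toxic) or `"nt"` (non-toxic); selects the
#'   label column when `mapping$label` is not given. Class 1 is the endpoint
#'   class (the minority for the very-toxic endpoint).
#' @param mapping optional list with entries `id`, `smiles`, `label`, `split`
#'   naming the columns explicitly.
#' @return list with `train` and `evaluation` data.frames (`id,smiles,label`).
#' @export
ingest_catmos <- function(path, endpoint = c("vt", "nt"), mapping = NULL) {
  endpoint <- match.arg(endpoint)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE,
                        check.names = FALSE)
  nms <- names(df)
  pick <- function(key, pattern) {
    if (!is.null(mapping[[key]])) {
      if (!mapping[[key]] %in% nms) {
        stop(sprintf("mapped column '%s' not in file; found: %s",
                     mapping[[key]], paste(nms, collapse = ", ")), call. = FALSE)
      }
      return(mapping[[key]])
    }
    hit <- grep(pattern, nms, ignore.case = TRUE, value = TRUE)
    if (length(hit) == 0L) {
      stop(sprintf("could not locate a '%s' column; found columns: %s",
                   key, paste(nms, collapse = ", ")), call. = FALSE)
    }
    hit[1L]
  }
  id_col <- pick("id", "dtxsid|casrn|^id$|chem.*id|compound")
  smi_col <- pick("smiles", "smiles")
  lab_pattern <- if (endpoint == "vt") "very.?tox|^vt$|vt_|_vt" else "non.?tox|^nt$|nt_|_nt"
  lab_col <- pick("label", lab_pattern)
  split_col <- pick("split", "split|subset|^set$|train")

  lab_raw <- df[[lab_col]]
  label <- if (is.numeric(lab_raw)) {
    as.integer(lab_raw)
  } else {
    as.integer(tolower(trimws(lab_raw)) %in% c("1", "yes", "true", "positive", "active"))
  }
  if (!all(label %in% c(0L, 1L))) {
    stop(sprintf("label column '%s' is not binary", lab_col), call. = FALSE)
  }
  out <- data.frame(id = as.character(df[[id_col]]),
                    smiles = as.character(df[[smi_col]]),
                    label = label, stringsAsFactors = FALSE)
  is_train <- grepl("train", df[[split_col]], ignore.case = TRUE)
  list(train = out[is_train, , drop = FALSE],
       evaluation = out[!is_train, , drop = FALSE])
}
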