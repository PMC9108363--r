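#' Pipeline configuration
#'
#' Collects every stage parameter of the subtyping workflow. A single
#' master seed deterministically derives per-stage seeds (see
#' [derive_seed()]), so the whole run is reproducible and any stage can be
#' rerun in isolation.
#'
#' @param min_mean mean-expression gene filter threshold (raw scale,
#'   default 10).
#' @param keep_fraction fraction of genes kept by mad (default 0.9).
#' @param log_transform apply log2(x + 1) at load time (default `FALSE`;
#'   set `TRUE` for FPKM-like inputs).
#' @param fold_size subsampling `Ns`; `NULL` for the per-dataset default.
#' @param n_folds subsampling `F`; `NULL` for the per-subtype default.
#' @param alpha combined p-value cutoff for edges (default 0.01).
#' @param min_module_size smallest retained module (default 10).
#' @param cut_height dendrogram cut height (default 0.95).
#' @param n_edges specific edges per subtype `E` (default 100).
#' @param n_ref reference network size `P`; `NULL` for the default.
#' @param n_sets reference network sets (default 10).
#' @param test_fraction held-out fraction per subtype (default 0.1).
#' @param classifier an [mlp_config()] (its seed is overridden by the
#'   derived stage seed).
#' @param seed master seed (default 1).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(min_mean = 10, keep_fraction = 0.9,
                            log_transform = FALSE, fold_size = NULL,
                            n_folds = NULL, alpha = 0.01,
                            min_module_size = 10L, cut_height = 0.95,
                            n_edges = 100L, n_ref = NULL, n_sets = 10L,
                            test_fraction = 0.1,
                            classifier = mlp_config(), seed = 1L) {
  structure(list(min_mean = min_mean, keep_fraction = keep_fraction,
                 log_transform = log_transform, fold_size = fold_size,
                 n_folds = n_folds, alpha = alpha,
                 min_module_size = as.integer(min_module_size),
                 cut_height = cut_height, n_edges = as.integer(n_edges),
                 n_ref = n_ref, n_sets = as.integer(n_sets),
                 test_fraction = test_fraction, classifier = classifier,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys map to [pipeline_config()] arguments; a `classifier`
#' block maps to [mlp_config()] arguments. Unknown keys are an error.
#'
#' @param path YAML file path.
#' @param overrides named list applied on top of the file's values.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path, overrides = list()) {
  raw <- yaml::read_yaml(path)
  raw <- utils::modifyList(raw, overrides)
  cls <- raw$classifier
  raw$classifier <- NULL
  unknown <- setdiff(names(raw), names(formals(pipeline_config)))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- do.call(pipeline_config, raw)
  if (!is.null(cls)) cfg$classifier <- do.call(mlp_config, cls)
  cfg
}

write_sidecar <- function(path, stage, params) {
  jsonlite::write_json(c(list(stage = stage), params),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
}

#' Run the full subtyping workflow
#'
#' Executes gene filtering, per-subtype aggregated network construction
#' and pruning, module detection, specific-module and specific-edge
#' identification, the stratified train/test split, reference-set
#' construction, featurization with class balancing, classifier training,
#' vote-based prediction of the held-out samples, and evaluation. When
#' `out_dir` is given every intermediate artifact is written with a JSON
#' provenance sidecar recording its stage parameters and seed, and
#' rerunning with the same configuration reproduces all artifacts. Stage
#' failures are reported with the failing stage's name.
#'
#' @param ds an [expression_dataset()] (already loaded; see
#'   [load_expression()]).
#' @param cfg a [pipeline_config()].
#' @param out_dir directory for artifacts, or `NULL` to keep everything in
#'   memory.
#' @return list with `dataset` (filtered), `networks`, `partitions`,
#'   `specificity`, `split`, `reference_sets`, `train_features`,
#'   `test_features`, `model`, `predictions`, `report`.
#' @export
run_pipeline <- function(ds, cfg = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(ds, "expression_dataset"),
            inherits(cfg, "pipeline_config"))
  if (!is.null(out_dir))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  fds <- stage("preprocess",
               filter_genes(ds, cfg$min_mean, cfg$keep_fraction))
  subs <- subtypes(fds)

  networks <- stage("networks", {
    nets <- lapply(subs, function(s) {
      scheme <- default_scheme(fds, s, fold_size = cfg$fold_size,
                               n_folds = cfg$n_folds,
                               seed = derive_seed(cfg$seed, paste0("net_", s)))
      prune_network(aggregate_network(fds, s, scheme), cfg$alpha)
    })
    names(nets) <- subs
    nets
  })
  partitions <- stage("modules", {
    parts <- lapply(networks, function(net)
      detect_modules(net, min_module_size = cfg$min_module_size,
                     cut_height = cfg$cut_height))
    names(parts) <- subs
    parts
  })
  spec <- stage("specificity",
                specificity_stage(partitions, networks, cfg$n_edges))
  split <- stage("split",
                 split_train_test(fds, cfg$test_fraction,
                                  seed = derive_seed(cfg$seed, "split")))
  refs <- stage("reference_sets",
                build_reference_sets(fds, split$train, spec,
                                     n_ref = cfg$n_ref, n_sets = cfg$n_sets,
                                     seed = derive_seed(cfg$seed, "refs")))
  train_feats <- stage("featurize",
                       featurize_training(fds, split$train, refs,
                                          seed = derive_seed(cfg$seed, "feat")))
  model <- stage("train", {
    mcfg <- cfg$classifier
    mcfg$seed <- derive_seed(cfg$seed, "mlp")
    train_mlp(train_feats$x, train_feats$labels, mcfg)
  })
  test_feats <- NULL; predictions <- NULL; report <- NULL
  if (length(split$test)) {
    test_feats <- stage("featurize_test",
                        featurize_samples(fds, split$test, refs))
    predictions <- stage("predict", predict_vote(model, test_feats))
    report <- stage("evaluate",
                    evaluate_predictions(
                      unname(fds$labels[predictions$sample_id]),
                      predictions$predicted, classes = sort(subs)))
  }

  if (!is.null(out_dir)) {
    for (s in subs) {
      p <- file.path(out_dir, paste0("network_", s, ".tsv"))
      write_network(networks[[s]], p)
      write_partition(partitions[[s]],
                      file.path(out_dir, paste0("modules_", s, ".tsv")))
      ep <- file.path(out_dir, paste0("specific_edges_", s, ".tsv"))
      write_specific_edges(spec[[s]]$edges, ep)
      write_sidecar(ep, "specificity",
                    list(subtype = s, module = spec[[s]]$module,
                         n_edges = cfg$n_edges, seed = cfg$seed))
    }
    write_features(train_feats, file.path(out_dir, "train_features.tsv"))
    write_sidecar(file.path(out_dir, "train_features.tsv"), "featurize",
                  list(n_sets = cfg$n_sets, seed = cfg$seed))
    if (!is.null(predictions)) {
      utils::write.table(predictions, file.path(out_dir, "predictions.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      write_sidecar(file.path(out_dir, "predictions.tsv"), "predict",
                    list(seed = cfg$seed, n_sets = cfg$n_sets))
      jsonlite::write_json(
        list(accuracy = report$accuracy,
             macro_precision = report$macro_precision,
             macro_recall = report$macro_recall,
             macro_f1 = report$macro_f1,
             per_class_recall = as.list(report$per_class_recall)),
        file.path(out_dir, "report.json"), auto_unbox = TRUE, pretty = TRUE)
    }
  }

  list(dataset = fds, networks = networks, partitions = partitions,
       specificity = spec, split = split, reference_sets = refs,
       train_features = train_feats, test_features = test_feats,
       model = model, predictions = predictions, report = report)
}
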