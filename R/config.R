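# YAML run configuration and the workflow commands behind the command-line
# script (inst/cli/qsarstack.R). Each command is a thin wrapper over the
# package functions: it reads its declared inputs, writes its outputs plus
# the resolved configuration and a run log into `output_dir`, and is
# idempotent given identical configuration and seeds.

config_defaults <- function() {
  list(input = list(path = NULL, dialect = "generic_csv"),
       output_dir = "qsarstack_run",
       thresholds = list(active_max_nM = 1000, inactive_min_nM = 10000),
       train_fraction = 0.8,
       algorithms = .ALGORITHMS,
       descriptors = NULL,           # default: whatever is available
       import_paths = NULL,
       grids = NULL,
       selection = list(m_start = 5, m_end = 70, s = 5),
       k = 10, inner_k = 5, seed = 1,
       pf_mode = "concat", cv_scoring = "pooled")
}

#' Read and validate a YAML run configuration
#'
#' Unknown keys are rejected; missing keys take documented defaults.
#'
#' @param path YAML file path.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  user <- yaml::read_yaml(path)
  defaults <- config_defaults()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, user)
  if (!cfg$pf_mode %in% c("concat", "average")) {
    abort("pf_mode must be 'concat' or 'average'")
  }
  if (!cfg$cv_scoring %in% c("pooled", "macro")) {
    abort("cv_scoring must be 'pooled' or 'macro'")
  }
  bad_algo <- setdiff(cfg$algorithms, .ALGORITHMS)
  if (length(bad_algo)) {
    abort(sprintf("unknown algorithm(s) in config: %s",
                  paste(bad_algo, collapse = ", ")))
  }
  structure(cfg, class = "run_config")
}

run_log <- function(dir, stage, event, detail = "") {
  line <- sprintf("%s\t%s\t%s\t%s",
                  format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), stage, event, detail)
  cat(line, "\n", file = file.path(dir, "run.log"), append = TRUE, sep = "")
}

prepare_output <- function(config, stage) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(unclass(config),
                   file.path(config$output_dir, "resolved_config.yaml"))
  run_log(config$output_dir, stage, "start")
}

config_thresholds <- function(config) {
  label_thresholds(config$thresholds$active_max_nM,
                   config$thresholds$inactive_min_nM)
}

config_descriptors <- function(config) {
  config$descriptors %||% available_descriptors(config$import_paths)
}

#' Workflow commands
#'
#' `run_curate()` reads the raw compound table, curates and splits it, and
#' writes `curated.csv`. `run_train()` fits the stacked model on the training
#' split and writes the model bundle (`model.rds`), the per-base-model PF CV
#' summary (`base_cv_mcc.csv`) and the selection curve (`selection.csv`).
#' `run_evaluate()` scores the bundle on the test split
#' (`metrics_independent.csv`). `run_predict()` scores a new compound table
#' (`predictions.csv`), isolating per-record standardization failures.
#' `run_synth()` fabricates a synthetic table plus fingerprint files.
#'
#' @param config A `run_config` from [read_run_config()].
#' @return Each command invisibly returns the path(s) it wrote.
#' @name workflow-commands
NULL

#' @rdname workflow-commands
#' @export
run_curate <- function(config) {
  prepare_output(config, "curate")
  if (is.null(config$input$path)) abort("config lacks input.path")
  curated <- read_compound_table(config$input$path, config$input$dialect) |>
    curate_compounds(config_thresholds(config)) |>
    stratified_split(config$train_fraction, seed = config$seed)
  path <- file.path(config$output_dir, "curated.csv")
  write_curated_csv(curated, path)
  run_log(config$output_dir, "curate", "done",
          sprintf("%d compounds", nrow(curated)))
  invisible(path)
}

load_split_blocks <- function(config, curated, split) {
  rows <- curated[curated$split == split, , drop = FALSE]
  blocks <- compute_fp_blocks(rows, config_descriptors(config),
                              config$import_paths)
  list(data = rows, blocks = blocks)
}

#' @rdname workflow-commands
#' @export
run_train <- function(config) {
  prepare_output(config, "train")
  curated <- read_curated_csv(file.path(config$output_dir, "curated.csv"))
  tr <- load_split_blocks(config, curated, "train")
  model <- fit_stacker(tr$data, tr$blocks,
                       algorithms = config$algorithms,
                       grids = config$grids,
                       sel_grid = selection_grid(config$selection$m_start,
                                                 config$selection$m_end,
                                                 config$selection$s),
                       k = config$k, inner_k = config$inner_k,
                       seed = config$seed, pf_mode = config$pf_mode)
  paths <- file.path(config$output_dir,
                     c("model.rds", "base_cv_mcc.csv", "selection.csv"))
  saveRDS(model, paths[1])
  base_cv <- tibble(
    column = colnames(model$apf$matrix),
    cv_mcc = apply(model$apf$matrix, 2, function(p)
      mcc_from_counts(confusion_counts(model$y, as.integer(p >= 0.5)))))
  readr::write_csv(base_cv, paths[2])
  readr::write_csv(tidy(model$selection), paths[3])
  run_log(config$output_dir, "train", "done",
          sprintf("%d base models, m=%d", length(model$base_models),
                  model$selection$chosen_m))
  invisible(paths)
}

#' @rdname workflow-commands
#' @export
run_evaluate <- function(config) {
  prepare_output(config, "evaluate")
  curated <- read_curated_csv(file.path(config$output_dir, "curated.csv"))
  model <- readRDS(file.path(config$output_dir, "model.rds"))
  te <- load_split_blocks(config, curated, "test")
  report <- evaluate_independent(model, te$data, te$blocks)
  path <- file.path(config$output_dir, "metrics_independent.csv")
  readr::write_csv(report, path)
  run_log(config$output_dir, "evaluate", "done",
          sprintf("MCC=%.3f", report$MCC))
  invisible(path)
}

#' @rdname workflow-commands
#' @param new_table Path to a raw compound table to score (predict only).
#' @export
run_predict <- function(config, new_table) {
  prepare_output(config, "predict")
  model <- readRDS(file.path(config$output_dir, "model.rds"))
  raw <- read_compound_table(new_table, config$input$dialect)
  std <- purrr::map(raw$smiles_raw, function(s)
    tryCatch(list(ok = TRUE, smiles = standardize_structure(s)),
             error = function(e) list(ok = FALSE, msg = conditionMessage(e))))
  ok <- vapply(std, `[[`, logical(1), "ok")
  out <- tibble(id = raw$id, p_active = NA_real_,
                class = NA_character_, error = NA_character_)
  out$error[!ok] <- vapply(std[!ok], `[[`, character(1), "msg")
  if (any(ok)) {
    valid <- raw[ok, , drop = FALSE]
    valid$smiles_canonical <- vapply(std[ok], `[[`, character(1), "smiles")
    blocks <- compute_fp_blocks(valid, config_descriptors(config),
                                config$import_paths)
    pred <- predict(model, blocks = blocks)
    out$p_active[ok] <- pred$p_active
    out$class[ok] <- as.character(pred$class)
  }
  path <- file.path(config$output_dir, "predictions.csv")
  readr::write_csv(out, path)
  run_log(config$output_dir, "predict", "done",
          sprintf("%d scored, %d failed", sum(ok), sum(!ok)))
  invisible(path)
}

#' @rdname workflow-commands
#' @export
run_synth <- function(config) {
  prepare_output(config, "synth")
  spec <- synthetic_spec(seed = config$seed)
  raw <- gen_labeled_smiles(spec)
  path <- file.path(config$output_dir, "synthetic_compounds.csv")
  readr::write_csv(raw, path)
  fams <- setdiff(config_descriptors(config), c("MACCS", "RDK5"))
  fp_paths <- if (length(fams)) {
    gen_imported_fp_files(raw, fams, file.path(config$output_dir, "fp"),
                          seed = config$seed)
  } else character()
  run_log(config$output_dir, "synth", "done",
          sprintf("%d compounds, %d fingerprint files", nrow(raw),
                  length(fp_paths)))
  invisible(c(path, fp_paths))
}
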