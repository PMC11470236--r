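#' Load an experiment configuration
#'
#' One YAML file with optional sections `synthetic`, `model`, `loss`,
#' `train`, `protocol`, `split` and a top-level `master_seed`.  Section keys
#' must match the corresponding constructor arguments ([synthetic_spec()],
#' [model_config()], [loss_config()], [train_config()], [eval_protocol()]);
#' unknown sections or keys are rejected.  Every stochastic stage gets a
#' deterministic sub-seed derived from `master_seed` (simulation,
#' splitting, initialization, training, evaluation protocol), so one master
#' seed reproduces the whole pipeline; a seed given explicitly inside a
#' section wins over the derived one.
#'
#' @param path YAML file path, or `NULL` for an all-defaults configuration.
#' @param master_seed Overrides the file's `master_seed` when not `NULL`.
#' @return An `mgrn_experiment`: list with elements `synthetic`, `model`,
#'   `loss`, `train`, `protocol`, `split_fractions`, `master_seed` and
#'   `seeds`.
#' @export
experiment_config <- function(path = NULL, master_seed = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c("synthetic", "model", "loss", "train", "protocol", "split",
             "master_seed")
  extra <- setdiff(names(raw), known)
  if (length(extra)) stop("unknown config section(s): ", paste(extra, collapse = ", "))
  ms <- master_seed
  if (is.null(ms)) ms <- raw$master_seed
  if (is.null(ms)) ms <- 42L
  ms <- as.integer(ms)
  seeds <- list(simulate = ms, split = ms + 1L, init = ms + 2L,
                train = ms + 3L, protocol = ms + 4L)

  build <- function(section, ctor, seed_field = NULL, seed_value = NULL) {
    args <- raw[[section]]
    if (is.null(args)) args <- list()
    bad <- setdiff(names(args), names(formals(ctor)))
    if (length(bad))
      stop(sprintf("unknown key(s) in section '%s': %s", section,
                   paste(bad, collapse = ", ")))
    if (!is.null(seed_field) && is.null(args[[seed_field]]))
      args[[seed_field]] <- seed_value
    do.call(ctor, args)
  }
  split_frac <- raw$split
  if (is.null(split_frac)) split_frac <- c(2/3, 1/6, 1/6)
  split_frac <- as.numeric(unlist(split_frac))
  if (length(split_frac) != 3L) stop("'split' must give three fractions")

  structure(list(
    synthetic = build("synthetic", synthetic_spec, "seed", seeds$simulate),
    model = build("model", model_config),
    loss = build("loss", loss_config),
    train = build("train", train_config, "seed", seeds$train),
    protocol = build("protocol", eval_protocol, "seed", seeds$protocol),
    split_fractions = split_frac,
    master_seed = ms,
    seeds = seeds
  ), class = "mgrn_experiment")
}

resolved_config_list <- function(exp_cfg) {
  c(lapply(exp_cfg[c("synthetic", "model", "loss", "train", "protocol")],
           unclass),
    list(split_fractions = exp_cfg$split_fractions,
         master_seed = exp_cfg$master_seed, seeds = exp_cfg$seeds))
}

log_resolved_config <- function(exp_cfg, out_dir, command) {
  x <- resolved_config_list(exp_cfg)
  x$command <- command
  jsonlite::write_json(x, file.path(out_dir, "resolved_config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

ensure_outputs <- function(paths, force) {
  existing <- paths[file.exists(paths)]
  if (length(existing) && !force)
    stop("output exists (use force = TRUE to overwrite): ",
         paste(existing, collapse = ", "))
  invisible(paths)
}

#' Simulate a cohort to disk
#'
#' Writes `cohort.jsonl`, `ddi.tsv`, `vocab.json` and `rule.json` (the
#' ground-truth prescribing rule, kept for oracle analyses) into `out_dir`.
#'
#' @param exp_cfg An `mgrn_experiment`.
#' @param out_dir Output directory (created if missing).
#' @param force Overwrite existing outputs.
#' @return Invisibly, the named vector of file paths.
#' @export
cmd_simulate <- function(exp_cfg, out_dir, force = FALSE) {
  validate_synth_spec(exp_cfg$synthetic)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(cohort = file.path(out_dir, "cohort.jsonl"),
             ddi = file.path(out_dir, "ddi.tsv"),
             vocab = file.path(out_dir, "vocab.json"),
             rule = file.path(out_dir, "rule.json"))
  ensure_outputs(paths, force)
  g <- generate_cohort(exp_cfg$synthetic)
  write_cohort_jsonl(g$cohort, paths[["cohort"]])
  write_ddi_edgelist(g$ddi, g$cohort$vocab, paths[["ddi"]])
  write_vocab_json(g$cohort$vocab, paths[["vocab"]])
  jsonlite::write_json(
    list(diag_to_drugs = lapply(g$rule$diag_to_drugs, as.integer),
         persistence_rho = g$rule$persistence_rho,
         noise_eps = g$rule$noise_eps),
    paths[["rule"]], auto_unbox = FALSE, digits = NA)
  log_resolved_config(exp_cfg, out_dir, "simulate")
  invisible(paths)
}

load_experiment_data <- function(exp_cfg, cohort_path, ddi_path,
                                 vocab_path = NULL) {
  vocab <- if (!is.null(vocab_path)) read_vocab_json(vocab_path) else NULL
  cohort <- read_cohort_jsonl(cohort_path, vocab = vocab)
  ddi <- read_ddi_edgelist(ddi_path, cohort$vocab)
  splits <- split_cohort(cohort, exp_cfg$split_fractions,
                         seed = exp_cfg$seeds$split)
  list(cohort = cohort, ddi = ddi, splits = splits)
}

#' Train a model from files
#'
#' Reads the cohort and DDI graph, splits deterministically, trains, and
#' writes `checkpoint.rds` plus `training_log.csv` into `out_dir`.
#'
#' @param exp_cfg An `mgrn_experiment`.
#' @param cohort_path,ddi_path Input files.
#' @param out_dir Output directory.
#' @param vocab_path Optional fixed vocabulary JSON.
#' @param force Overwrite existing outputs.
#' @return Invisibly, the `mgrn_fit`.
#' @export
cmd_train <- function(exp_cfg, cohort_path, ddi_path, out_dir,
                      vocab_path = NULL, force = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(checkpoint = file.path(out_dir, "checkpoint.rds"),
             log = file.path(out_dir, "training_log.csv"))
  ensure_outputs(paths, force)
  dat <- load_experiment_data(exp_cfg, cohort_path, ddi_path, vocab_path)
  params0 <- init_params(exp_cfg$model, dat$cohort$vocab,
                         seed = exp_cfg$seeds$init)
  fit <- train(params0, exp_cfg$model, exp_cfg$loss, exp_cfg$train,
               dat$splits$train, dat$splits$val, dat$ddi)
  save_checkpoint(fit$params, exp_cfg$model, dat$cohort$vocab,
                  paths[["checkpoint"]])
  write_training_log(fit, paths[["log"]])
  log_resolved_config(exp_cfg, out_dir, "train")
  invisible(fit)
}

#' Evaluate a checkpoint on the test split
#'
#' @param exp_cfg An `mgrn_experiment`.
#' @param checkpoint_path Checkpoint written by [cmd_train()].
#' @param cohort_path,ddi_path Input files (split exactly as in training).
#' @param out_dir Output directory for `report.json` / `report.csv`.
#' @param vocab_path Optional fixed vocabulary JSON.
#' @param force Overwrite existing outputs.
#' @return Invisibly, the `mgrn_report`.
#' @export
cmd_evaluate <- function(exp_cfg, checkpoint_path, cohort_path, ddi_path,
                         out_dir, vocab_path = NULL, force = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(json = file.path(out_dir, "report.json"),
             csv = file.path(out_dir, "report.csv"))
  ensure_outputs(paths, force)
  dat <- load_experiment_data(exp_cfg, cohort_path, ddi_path, vocab_path)
  ck <- load_checkpoint(checkpoint_path, dat$cohort$vocab)
  report <- evaluate(ck$params, ck$config, dat$splits$test, dat$ddi,
                     exp_cfg$protocol)
  write_report(report, paths[["json"]], paths[["csv"]])
  log_resolved_config(exp_cfg, out_dir, "evaluate")
  invisible(report)
}

#' Train and evaluate an ablation variant from files
#'
#' @param exp_cfg An `mgrn_experiment`.
#' @param variant Ablation variant name (see [ablation_config()]).
#' @param cohort_path,ddi_path Input files.
#' @param out_dir Output directory; the report files are named after the
#'   variant.
#' @param vocab_path Optional fixed vocabulary JSON.
#' @param force Overwrite existing outputs.
#' @return Invisibly, the variant's `mgrn_report`.
#' @export
cmd_ablate <- function(exp_cfg, variant, cohort_path, ddi_path, out_dir,
                       vocab_path = NULL, force = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(json = file.path(out_dir, sprintf("report_%s.json", variant)),
             csv = file.path(out_dir, sprintf("report_%s.csv", variant)))
  ensure_outputs(paths, force)
  dat <- load_experiment_data(exp_cfg, cohort_path, ddi_path, vocab_path)
  report <- run_ablation(variant, dat$splits, dat$ddi, exp_cfg$model,
                         exp_cfg$loss, exp_cfg$train, exp_cfg$protocol,
                         init_seed = exp_cfg$seeds$init)
  write_report(report, paths[["json"]], paths[["csv"]])
  log_resolved_config(exp_cfg, out_dir, paste0("ablate:", variant))
  invisible(report)
}

#' Run the training-set deletion sweep from files
#'
#' @param exp_cfg An `mgrn_experiment`.
#' @param rates Deletion rates in `[0, 1)`.
#' @param seeds Seeds (one training run per rate-seed pair).
#' @param cohort_path,ddi_path Input files.
#' @param out_dir Output directory for `robustness.csv`.
#' @param vocab_path Optional fixed vocabulary JSON.
#' @param force Overwrite existing outputs.
#' @return Invisibly, the sweep data.frame.
#' @export
cmd_robustness <- function(exp_cfg, rates, seeds, cohort_path, ddi_path,
                           out_dir, vocab_path = NULL, force = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(out_dir, "robustness.csv")
  ensure_outputs(path, force)
  dat <- load_experiment_data(exp_cfg, cohort_path, ddi_path, vocab_path)
  tab <- robustness_sweep(rates, seeds, dat$splits, dat$ddi, exp_cfg$model,
                          exp_cfg$loss, exp_cfg$train, exp_cfg$protocol)
  write.csv(tab, path, row.names = FALSE)
  log_resolved_config(exp_cfg, out_dir, "robustness")
  invisible(tab)
}
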