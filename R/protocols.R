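#' Train and evaluate one ablation variant
#'
#' Applies the variant's ablation flags (see [ablation_config()]), trains
#' from a fresh initialization and evaluates under the same seeds and
#' configurations as every other variant, so reports are directly
#' comparable.
#'
#' @param variant Variant name (see [ablation_config()]).
#' @param splits List with `train`, `val`, `test` cohorts (as returned by
#'   [split_cohort()]).
#' @param ddi DDI matrix.
#' @param config Base `mgrn_config` (flags are overridden by the variant).
#' @param loss_cfg An `mgrn_loss_config`.
#' @param train_cfg An `mgrn_train_config`.
#' @param protocol An `mgrn_protocol`.
#' @param init_seed Seed for parameter initialization.
#' @return The `mgrn_report` for the variant, with the fitted model in
#'   attribute `"fit"`.
#' @export
run_ablation <- function(variant, splits, ddi, config = model_config(),
                         loss_cfg = loss_config(), train_cfg = train_config(),
                         protocol = eval_protocol(), init_seed = 1L) {
  cfg <- ablation_config(config, variant)
  params0 <- init_params(cfg, splits$train$vocab, seed = init_seed)
  fit <- train(params0, cfg, loss_cfg, train_cfg, splits$train, splits$val, ddi)
  report <- evaluate(fit$params, cfg, splits$test, ddi, protocol)
  attr(report, "fit") <- fit
  attr(report, "variant") <- variant
  report
}

#' Training-set deletion sweep
#'
#' The robustness protocol: for each deletion rate and seed, removes that
#' fraction of training patients (whole records), retrains from a fresh
#' initialization, and evaluates on the untouched test set.
#'
#' @param rates Numeric vector of deletion rates in `[0, 1)`.
#' @param seeds Integer vector; each seed drives the deletion draw, the
#'   initialization and the training run.
#' @param splits List with `train`, `val`, `test` cohorts.
#' @param ddi DDI matrix.
#' @param config,loss_cfg,train_cfg,protocol Shared configurations.
#' @param verbose Print progress.
#' @return A long-format data.frame with one row per (rate, seed):
#'   `rate`, `seed`, `n_train`, `jaccard`, `prauc`, `f1`, `ddi_rate`,
#'   `avg_drugs`.
#' @export
robustness_sweep <- function(rates, seeds, splits, ddi,
                             config = model_config(),
                             loss_cfg = loss_config(),
                             train_cfg = train_config(),
                             protocol = eval_protocol(), verbose = FALSE) {
  stopifnot(all(rates >= 0), all(rates < 1))
  rows <- list()
  for (rate in rates) {
    for (seed in seeds) {
      tr <- delete_fraction(splits$train, rate, seed = seed)
      tc <- train_cfg; tc$seed <- as.integer(seed)
      params0 <- init_params(config, splits$train$vocab, seed = seed)
      fit <- train(params0, config, loss_cfg, tc, tr, splits$val, ddi)
      rep <- evaluate(fit$params, config, splits$test, ddi, protocol)
      if (verbose)
        message(sprintf("rate %.2f seed %d: Jaccard %.4f", rate, seed,
                        rep$mean[["jaccard"]]))
      rows[[length(rows) + 1L]] <- data.frame(
        rate = rate, seed = seed, n_train = n_patients(tr),
        jaccard = rep$mean[["jaccard"]], prauc = rep$mean[["prauc"]],
        f1 = rep$mean[["f1"]], ddi_rate = rep$mean[["ddi_rate"]],
        avg_drugs = rep$mean[["avg_drugs"]])
    }
  }
  do.call(rbind, rows)
}
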