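#' Training configuration
#'
#' @param epochs Maximum number of epochs (0 returns the initial
#'   parameters untouched).
#' @param learning_rate Adam step size.
#' @param batch_size Patients per gradient step.
#' @param seed Seed controlling shuffling and dropout.
#' @param early_stop_patience Stop after this many epochs without a new best
#'   validation Jaccard; the best-validation checkpoint is returned.
#' @param gradient_clip_norm Global L2 norm ceiling for each step's
#'   gradient.
#' @param weight_decay Decoupled L2 weight decay applied to all non-bias
#'   parameter matrices at each step (AdamW style).
#' @return An `mgrn_train_config`.
#' @export
train_config <- function(epochs = 30L, learning_rate = 3e-3, batch_size = 16L,
                         seed = 1L, early_stop_patience = 10L,
                         gradient_clip_norm = 5, weight_decay = 0) {
  stopifnot(epochs >= 0L, learning_rate > 0, batch_size >= 1L,
            early_stop_patience >= 1L, gradient_clip_norm > 0,
            weight_decay >= 0)
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 early_stop_patience = as.integer(early_stop_patience),
                 gradient_clip_norm = gradient_clip_norm,
                 weight_decay = weight_decay),
            class = "mgrn_train_config")
}

loss_config_to_engine <- function(lcfg) {
  list(alpha = lcfg$alpha, beta = lcfg$beta, gamma = lcfg$gamma,
       kappa = lcfg$kappa, eps = lcfg$eps)
}

# mean per-visit Jaccard of thresholded predictions over a cohort
mean_jaccard <- function(params, config, cohort, engine_patients = NULL) {
  Nm <- cohort$vocab$n_drug
  if (is.null(engine_patients))
    engine_patients <- lapply(cohort$records, patient_to_engine, n_drug = Nm)
  fwd <- cpp_forward_cohort(engine_patients, plain_params(params),
                            engine_config(config, Nm))
  vals <- unlist(lapply(seq_along(fwd), function(p) {
    O <- fwd[[p]]$o
    vapply(seq_len(ncol(O)), function(t) {
      jaccard_sets(predict_drugs(O[, t], config$phi),
                   cohort$records[[p]]$visits[[t]]$drugs)
    }, numeric(1))
  }))
  mean(vals)
}

#' Train the model
#'
#' Mini-batch Adam on the joint loss (binary cross-entropy + multi-label
#' hinge + adaptive DDI penalty), with global-norm gradient clipping,
#' per-epoch validation Jaccard, early stopping, and best-validation
#' checkpointing.  Deterministic given `train_cfg$seed`.
#'
#' @param params Initial `mgrn_params`.
#' @param config An `mgrn_config`.
#' @param loss_cfg An `mgrn_loss_config`.
#' @param train_cfg An `mgrn_train_config`.
#' @param train_cohort,val_cohort Disjoint `mgrn_cohort`s sharing a
#'   vocabulary.
#' @param ddi An `mgrn_ddi` matrix.
#' @param verbose Print per-epoch progress.
#' @return An `mgrn_fit`: list with `params` (best-validation), `log` (one
#'   row per epoch: epoch, bce, mlh, addi, adaptive_weight, total,
#'   val_jaccard) and `best_epoch`.
#' @export
train <- function(params, config, loss_cfg, train_cfg, train_cohort,
                  val_cohort, ddi, verbose = FALSE) {
  stopifnot(inherits(config, "mgrn_config"), inherits(loss_cfg, "mgrn_loss_config"),
            inherits(train_cfg, "mgrn_train_config"))
  if (length(intersect(
        vapply(train_cohort$records, `[[`, character(1), "patient_id"),
        vapply(val_cohort$records, `[[`, character(1), "patient_id"))))
    stop("train and validation cohorts must be disjoint")
  Nm <- train_cohort$vocab$n_drug
  check_params(params, config, train_cohort$vocab)
  pp <- plain_params(params)
  log_rows <- list()
  if (train_cfg$epochs == 0L) {
    return(structure(list(params = params, log = empty_log(), best_epoch = 0L),
                     class = "mgrn_fit"))
  }
  ec_train <- engine_config(config, Nm, training = TRUE)
  lc <- loss_config_to_engine(loss_cfg)
  eng_train <- lapply(train_cohort$records, patient_to_engine, n_drug = Nm)
  eng_val <- lapply(val_cohort$records, patient_to_engine, n_drug = Nm)
  ddi_m <- unclass(ddi)

  adam_m <- lapply(pp, function(x) array(0, dim(x)))
  adam_v <- lapply(pp, function(x) array(0, dim(x)))
  step <- 0L
  best_val <- -Inf; best_params <- pp; best_epoch <- 0L; stale <- 0L

  withr_seed(train_cfg$seed, {
    for (epoch in seq_len(train_cfg$epochs)) {
      ord <- sample.int(length(eng_train))
      comps <- c(bce = 0, mlh = 0, addi = 0, adaptive_weight = 0, total = 0)
      n_batches <- 0L
      for (start in seq(1L, length(ord), by = train_cfg$batch_size)) {
        idx <- ord[start:min(start + train_cfg$batch_size - 1L, length(ord))]
        bseed <- sample.int(2147483646L, 1L)
        res <- cpp_batch_grad(eng_train[idx], pp, ec_train, lc, ddi_m,
                              bseed, TRUE)
        if (!is.finite(res$total))
          stop(sprintf("training diverged at epoch %d (loss = %g)", epoch,
                       res$total))
        g <- res$grads
        gn <- sqrt(sum(vapply(g, function(x) sum(x * x), numeric(1))))
        scale <- if (gn > train_cfg$gradient_clip_norm)
          train_cfg$gradient_clip_norm / gn else 1
        step <- step + 1L
        b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
        lr_t <- train_cfg$learning_rate *
          sqrt(1 - b2^step) / (1 - b1^step)
        wd <- train_cfg$weight_decay
        for (nm in names(pp)) {
          gi <- g[[nm]] * scale
          adam_m[[nm]] <- b1 * adam_m[[nm]] + (1 - b1) * gi
          adam_v[[nm]] <- b2 * adam_v[[nm]] + (1 - b2) * gi * gi
          upd <- lr_t * adam_m[[nm]] / (sqrt(adam_v[[nm]]) + eps)
          if (wd > 0 && !grepl("_b", nm, fixed = TRUE))
            upd <- upd + train_cfg$learning_rate * wd * pp[[nm]]
          pp[[nm]] <- pp[[nm]] - upd
        }
        comps <- comps + c(res$bce, res$mlh, res$addi, res$adaptive_weight,
                           res$total)
        n_batches <- n_batches + 1L
      }
      comps <- comps / n_batches
      cfg_eval <- config
      val_j <- mean_jaccard(structure(pp, class = "mgrn_params"), cfg_eval,
                            val_cohort, eng_val)
      log_rows[[epoch]] <- data.frame(epoch = epoch, bce = comps[["bce"]],
                                      mlh = comps[["mlh"]],
                                      addi = comps[["addi"]],
                                      adaptive_weight = comps[["adaptive_weight"]],
                                      total = comps[["total"]],
                                      val_jaccard = val_j)
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  val Jaccard %.4f", epoch,
                        comps[["total"]], val_j))
      if (val_j > best_val + 1e-12) {
        best_val <- val_j; best_params <- pp; best_epoch <- epoch; stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale >= train_cfg$early_stop_patience) break
      }
    }
  })
  out_params <- structure(best_params, class = "mgrn_params",
                          vocab_hash = attr(params, "vocab_hash"))
  structure(list(params = out_params, log = do.call(rbind, log_rows),
                 best_epoch = best_epoch),
            class = "mgrn_fit")
}

empty_log <- function() {
  data.frame(epoch = integer(), bce = numeric(), mlh = numeric(),
             addi = numeric(), adaptive_weight = numeric(), total = numeric(),
             val_jaccard = numeric())
}

#' Write a training log to CSV
#'
#' @param fit An `mgrn_fit`.
#' @param path Output CSV path.
#' @export
write_training_log <- function(fit, path) {
  write.csv(fit$log, path, row.names = FALSE)
  invisible(path)
}
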