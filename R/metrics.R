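#' Evaluation protocol
#'
#' Multi-round testing: each round resamples a fraction of the test
#' patients without replacement (round-specific seed), metrics are averaged
#' within rounds, and the report gives mean and standard deviation across
#' rounds.
#'
#' @param n_rounds Number of rounds (default 5).
#' @param round_fraction Fraction of test patients sampled per round.
#' @param seed Protocol seed; round `r` uses `seed + r`.
#' @return An `mgrn_protocol`.
#' @export
eval_protocol <- function(n_rounds = 5L, round_fraction = 0.8, seed = 1L) {
  stopifnot(n_rounds >= 1L, round_fraction > 0, round_fraction <= 1)
  structure(list(n_rounds = as.integer(n_rounds),
                 round_fraction = round_fraction, seed = as.integer(seed)),
            class = "mgrn_protocol")
}

#' Average precision of a drug ranking
#'
#' Area under the precision-recall curve by the average-precision step
#' interpolation: drugs are ranked by decreasing probability (ties broken by
#' index) and `AP = (1/P) * sum over positive ranks k of precision@k`.
#'
#' @param o Probability vector.
#' @param truth Multi-hot 0/1 vector.
#' @export
average_precision <- function(o, truth) {
  stopifnot(length(o) == length(truth))
  P <- sum(truth)
  if (P == 0) return(0)
  ord <- order(-o, seq_along(o))
  y <- truth[ord]
  hits <- cumsum(y)
  sum((hits / seq_along(y))[y > 0.5]) / P
}

#' Per-visit recommendation metrics
#'
#' Set-overlap metrics of a predicted drug set against the ground truth,
#' plus the ranking quality of the probability vector and the DDI rate of
#' the prediction.
#'
#' @param pred_set Integer vector of predicted 0-based drug indices.
#' @param true_set Integer vector of true drug indices (non-empty).
#' @param o Probability vector over the drug vocabulary.
#' @param ddi DDI adjacency matrix.
#' @return An `mgrn_visit_metrics`: list with `jaccard`, `precision`,
#'   `recall`, `f1`, `avg_precision`, `ddi_rate` (fraction of predicted
#'   unordered pairs that interact; 0 when fewer than 2 drugs are
#'   predicted), and `n_pred`.
#' @export
visit_metrics <- function(pred_set, true_set, o, ddi) {
  if (!length(true_set)) stop("true_set must be non-empty")
  pred_set <- as.integer(pred_set); true_set <- as.integer(true_set)
  inter <- length(intersect(pred_set, true_set))
  jac <- jaccard_sets(pred_set, true_set)
  prec <- if (length(pred_set)) inter / length(pred_set) else 0
  rec <- inter / length(true_set)
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  ap <- average_precision(o, multi_hot(true_set, length(o)))
  k <- length(pred_set)
  dr <- 0
  if (k >= 2) {
    sub <- ddi[pred_set + 1L, pred_set + 1L, drop = FALSE]
    dr <- sum(sub[upper.tri(sub)]) / (k * (k - 1) / 2)
  }
  structure(list(jaccard = jac, precision = prec, recall = rec, f1 = f1,
                 avg_precision = ap, ddi_rate = dr, n_pred = k),
            class = "mgrn_visit_metrics")
}

# all visit metrics of a cohort as a data.frame (one row per visit)
cohort_visit_metrics <- function(params, config, cohort, ddi) {
  Nm <- cohort$vocab$n_drug
  eng <- lapply(cohort$records, patient_to_engine, n_drug = Nm)
  fwd <- cpp_forward_cohort(eng, plain_params(params), engine_config(config, Nm))
  rows <- list()
  for (p in seq_along(fwd)) {
    O <- fwd[[p]]$o
    for (t in seq_len(ncol(O))) {
      true_set <- cohort$records[[p]]$visits[[t]]$drugs
      vm <- visit_metrics(predict_drugs(O[, t], config$phi), true_set,
                          O[, t], ddi)
      rows[[length(rows) + 1L]] <- data.frame(
        patient = p, visit = t, jaccard = vm$jaccard, precision = vm$precision,
        recall = vm$recall, f1 = vm$f1, prauc = vm$avg_precision,
        ddi_rate = vm$ddi_rate, n_pred = vm$n_pred)
    }
  }
  do.call(rbind, rows)
}

#' Evaluate a trained model under the multi-round protocol
#'
#' Each round samples `ceiling(round_fraction * n)` test patients without
#' replacement, computes per-visit metrics for every visit of the sampled
#' patients, and averages within the round; the report aggregates mean and
#' standard deviation across rounds.  `avg_drugs` is the mean predicted-set
#' size.
#'
#' @param params Trained `mgrn_params`.
#' @param config An `mgrn_config`.
#' @param cohort Test `mgrn_cohort`.
#' @param ddi DDI matrix.
#' @param protocol An `mgrn_protocol`.
#' @return An `mgrn_report`: list with `rounds` (per-round data.frame),
#'   `mean` and `sd` (named vectors over jaccard, prauc, f1, ddi_rate,
#'   avg_drugs) and `n_patients`.
#' @export
evaluate <- function(params, config, cohort, ddi, protocol = eval_protocol()) {
  stopifnot(inherits(protocol, "mgrn_protocol"))
  if (!n_patients(cohort)) stop("empty test cohort")
  per_visit <- cohort_visit_metrics(params, config, cohort, ddi)
  n <- n_patients(cohort)
  k <- ceiling(protocol$round_fraction * n)
  rounds <- lapply(seq_len(protocol$n_rounds), function(r) {
    pick <- withr_seed(protocol$seed + r, sample.int(n, k))
    sub <- per_visit[per_visit$patient %in% pick, , drop = FALSE]
    data.frame(round = r, jaccard = mean(sub$jaccard), prauc = mean(sub$prauc),
               f1 = mean(sub$f1), ddi_rate = mean(sub$ddi_rate),
               avg_drugs = mean(sub$n_pred))
  })
  rounds <- do.call(rbind, rounds)
  metr <- c("jaccard", "prauc", "f1", "ddi_rate", "avg_drugs")
  agg_mean <- vapply(metr, function(m) mean(rounds[[m]]), numeric(1))
  agg_sd <- vapply(metr, function(m) sd(rounds[[m]]), numeric(1))
  if (protocol$n_rounds == 1L) agg_sd[] <- 0
  structure(list(rounds = rounds, mean = agg_mean, sd = agg_sd,
                 n_patients = n, per_visit = per_visit),
            class = "mgrn_report")
}

#' @export
print.mgrn_report <- function(x, ...) {
  cat(sprintf("<mgrn_report> %d patients, %d rounds\n", x$n_patients,
              nrow(x$rounds)))
  for (m in names(x$mean))
    cat(sprintf("  %-9s %.4f +/- %.4f\n", m, x$mean[[m]], x$sd[[m]]))
  invisible(x)
}

#' Write an evaluation report to JSON and CSV
#'
#' @param report An `mgrn_report`.
#' @param json_path,csv_path Output paths (either may be `NULL`).
#' @export
write_report <- function(report, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(mean = as.list(report$mean), sd = as.list(report$sd),
           rounds = report$rounds, n_patients = report$n_patients),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(csv_path)) write.csv(report$rounds, csv_path, row.names = FALSE)
  invisible(report)
}

#' Metrics stratified by visit position
#'
#' Groups per-visit metrics by visit index `t = 1..5`, pooling later visits
#' into `"5+"`; history-aware components can only help from the second visit
#' onwards, so the gradient of performance across this table shows how much
#' the model exploits the medication history.
#'
#' @param params Trained `mgrn_params`.
#' @param config An `mgrn_config`.
#' @param cohort Test cohort.
#' @param ddi DDI matrix.
#' @param max_index Last unpooled visit index (default 5).
#' @return A data.frame with one row per populated bucket: `visit_index`,
#'   `n_visits`, `jaccard`, `prauc`, `f1`, `ddi_rate`, `avg_drugs`.
#' @export
stratify_by_visit_index <- function(params, config, cohort, ddi,
                                    max_index = 5L) {
  pv <- cohort_visit_metrics(params, config, cohort, ddi)
  bucket <- ifelse(pv$visit <= max_index, as.character(pv$visit),
                   paste0(max_index, "+"))
  levels_order <- c(as.character(seq_len(max_index)), paste0(max_index, "+"))
  out <- lapply(intersect(levels_order, unique(bucket)), function(b) {
    sub <- pv[bucket == b, , drop = FALSE]
    data.frame(visit_index = b, n_visits = nrow(sub),
               jaccard = mean(sub$jaccard), prauc = mean(sub$prauc),
               f1 = mean(sub$f1), ddi_rate = mean(sub$ddi_rate),
               avg_drugs = mean(sub$n_pred))
  })
  do.call(rbind, out)
}
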