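#' Loss configuration
#'
#' The training objective is `L = L_bce + alpha * L_mlh + w * beta * L_addi`,
#' where `L_bce` is binary cross-entropy on the drug probabilities, `L_mlh`
#' the multi-label hinge loss on the pre-sigmoid scores, and `L_addi` the
#' drug-drug interaction penalty.  The DDI term is adaptive: its weight
#' `w = adaptive_weight(batch DDI rate, gamma, kappa)` ramps from 0 to 1 as
#' the model's recommendations become unsafe, so the penalty only acts when
#' the predicted DDI rate exceeds the acceptable level `gamma`.
#'
#' @param alpha Weight of the multi-label hinge term.
#' @param beta Weight of the DDI term.
#' @param gamma Acceptable DDI rate; below it the DDI penalty is off.
#' @param kappa Width of the linear ramp from weight 0 (at `gamma`) to 1
#'   (at `gamma + kappa`).
#' @param eps Numerical floor used when taking logarithms.
#' @return An `mgrn_loss_config`.
#' @export
loss_config <- function(alpha = 0.05, beta = 0.1, gamma = 0.06,
                        kappa = 0.05, eps = 1e-8) {
  stopifnot(alpha >= 0, beta >= 0, gamma >= 0, gamma <= 1, kappa > 0,
            eps > 0, eps <= 1e-3)
  structure(list(alpha = alpha, beta = beta, gamma = gamma, kappa = kappa,
                 eps = eps),
            class = "mgrn_loss_config")
}

#' Binary cross-entropy over drugs
#'
#' Mean over the drug vocabulary of
#' `-(y * log(o) + (1 - y) * log(1 - o))`, with `o` clipped to
#' `[eps, 1 - eps]`.
#'
#' @param o Probability vector.
#' @param target Multi-hot 0/1 vector of the same length.
#' @param eps Clipping floor.
#' @export
bce_loss <- function(o, target, eps = 1e-8) {
  stopifnot(length(o) == length(target))
  oc <- pmin(pmax(o, eps), 1 - eps)
  mean(-(target * log(oc) + (1 - target) * log(1 - oc)))
}

#' Multi-label hinge loss
#'
#' Average over all (positive, negative) drug pairs of
#' `max(0, 1 - (s_pos - s_neg))`, computed on pre-sigmoid scores where the
#' unit margin is scale-meaningful.  Returns 0 when the target has no
#' positive or no negative label.
#'
#' @param scores Pre-sigmoid score vector (`r_g + r_h`).
#' @param target Multi-hot 0/1 vector.
#' @export
multilabel_hinge <- function(scores, target) {
  stopifnot(length(scores) == length(target))
  pos <- which(target > 0.5)
  neg <- which(target < 0.5)
  if (!length(pos) || !length(neg)) return(0)
  diffs <- outer(scores[pos], scores[neg], function(a, b) 1 - (a - b))
  sum(pmax(diffs, 0)) / (length(pos) * length(neg))
}

#' Drug-drug interaction loss
#'
#' Expected pairwise co-prescription mass on interacting drug pairs,
#' normalized by the number of interacting pairs:
#' `sum_{i<j} A_ij * o_i * o_j / max(1, sum_{i<j} A_ij)`.
#'
#' @param o Probability vector of length `Nm`.
#' @param ddi An `Nm x Nm` symmetric 0/1 matrix with zero diagonal.
#' @export
ddi_loss <- function(o, ddi) {
  stopifnot(length(o) == nrow(ddi), nrow(ddi) == ncol(ddi))
  z <- max(1, sum(ddi) / 2)
  0.5 * drop(o %*% ddi %*% o) / z
}

#' Adaptive weight for the DDI penalty
#'
#' Piecewise-linear ramp on the current predicted DDI rate: 0 while the rate
#' is at or below the acceptable level `gamma`, rising linearly to 1 at
#' `gamma + kappa`.  Monotone non-decreasing in the rate.
#'
#' @param current_ddi_rate Scalar rate of interacting pairs among
#'   recommended pairs.
#' @param gamma,kappa Ramp parameters (see [loss_config()]).
#' @export
adaptive_weight <- function(current_ddi_rate, gamma = 0.06, kappa = 0.05) {
  stopifnot(is.finite(current_ddi_rate), kappa > 0)
  if (current_ddi_rate <= gamma) return(0)
  min(1, (current_ddi_rate - gamma) / kappa)
}

#' Joint training loss for one visit
#'
#' @param scores Pre-sigmoid score vector (`r_g + r_h`).
#' @param probs Probability vector (`sigmoid(scores)`).
#' @param target Multi-hot 0/1 vector.
#' @param ddi DDI adjacency matrix.
#' @param batch_ddi_rate Predicted DDI rate of the current batch, used to
#'   set the adaptive DDI weight.
#' @param config An `mgrn_loss_config`.
#' @return An `mgrn_loss_breakdown`: list with `bce`, `mlh`, `addi`,
#'   `adaptive_weight` and `total = bce + alpha*mlh + w*beta*addi`.
#' @export
joint_loss <- function(scores, probs, target, ddi, batch_ddi_rate, config) {
  stopifnot(inherits(config, "mgrn_loss_config"))
  bce <- bce_loss(probs, target, config$eps)
  mlh <- multilabel_hinge(scores, target)
  addi <- ddi_loss(probs, ddi)
  w <- adaptive_weight(batch_ddi_rate, config$gamma, config$kappa)
  structure(list(bce = bce, mlh = mlh, addi = addi, adaptive_weight = w,
                 total = bce + config$alpha * mlh + w * config$beta * addi),
            class = "mgrn_loss_breakdown")
}
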