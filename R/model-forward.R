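sigmoid <- function(x) 1 / (1 + exp(-x))

# numerically stable softplus; output activation of the gating unit
softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

# single-layer GRU over columns of X (in x L); returns h x L hidden states.
# Gate rows of W/U/b are stacked [update; reset; candidate]; the candidate
# bias is added inside the reset-gated recurrent term.
gru_forward_r <- function(X, W, U, b) {
  h <- ncol(U)
  L <- ncol(X)
  H <- matrix(0, h, L)
  hp <- numeric(h)
  if (L == 0L) return(H)
  iz <- seq_len(h); ir <- h + iz; in_ <- 2L * h + iz
  A <- W %*% X
  for (t in seq_len(L)) {
    uh <- U %*% hp
    z <- sigmoid(A[iz, t] + uh[iz] + b[iz, 1])
    r <- sigmoid(A[ir, t] + uh[ir] + b[ir, 1])
    un <- uh[in_] + b[in_, 1]
    n <- tanh(A[in_, t] + r * un)
    hp <- (1 - z) * n + z * hp
    H[, t] <- hp
  }
  H
}

# bidirectional summary: concat(final forward state, final backward state)
bigru_summary_concat <- function(X, Wf, Uf, bf, Wb, Ub, bb) {
  h <- ncol(Uf)
  if (ncol(X) == 0L) return(numeric(2L * h))
  Hf <- gru_forward_r(X, Wf, Uf, bf)
  Hb <- gru_forward_r(X[, rev(seq_len(ncol(X))), drop = FALSE], Wb, Ub, bb)
  c(Hf[, ncol(Hf)], Hb[, ncol(Hb)])
}

# bidirectional summary: elementwise sum of the two directions' final states
bigru_summary_sum <- function(X, Wf, Uf, bf, Wb, Ub, bb) {
  h <- ncol(Uf)
  if (ncol(X) == 0L) return(numeric(h))
  Hf <- gru_forward_r(X, Wf, Uf, bf)
  Hb <- gru_forward_r(X[, rev(seq_len(ncol(X))), drop = FALSE], Wb, Ub, bb)
  Hf[, ncol(Hf)] + Hb[, ncol(Hb)]
}

#' Embed one visit's diagnosis and procedure tokens
#'
#' Looks up the embedding row of each token, in the canonical (sorted-index)
#' token order.  Row `i` of the result is the embedding of the `i`-th token.
#'
#' @param visit An `mgrn_visit`.
#' @param params An `mgrn_params`.
#' @return A list with `De` (`|diag| x d`) and `Pe` (`|proc| x d`).
#' @export
embed_visit <- function(visit, params) {
  if (length(visit$diag) && max(visit$diag) >= nrow(params$Ed))
    stop("diagnosis index out of vocabulary range")
  if (length(visit$proc) && max(visit$proc) >= nrow(params$Ep))
    stop("procedure index out of vocabulary range")
  list(De = params$Ed[visit$diag + 1L, , drop = FALSE],
       Pe = params$Ep[visit$proc + 1L, , drop = FALSE])
}

#' Visit-level view
#'
#' Sums each visit's token embeddings into per-visit feature vectors, runs
#' unidirectional recurrent encoders over the visit sequence (diagnosis and
#' procedure streams separately), concatenates the two hidden states into
#' the visit-level patient representation `C_v^t`, and matches it against
#' the view's drug matrix: `r_v^t = m_v %*% C_v^t`.  `C_v^t` depends only on
#' visits `1..t`.
#'
#' @param visits List of `mgrn_visit` in chronological order.
#' @param params An `mgrn_params`.
#' @return A list with `C_v` (list of `2*h_visit` vectors) and `r_v` (list
#'   of length-`Nm` score vectors), one per visit.
#' @export
visit_level_view <- function(visits, params) {
  stopifnot(length(visits) >= 1L)
  d <- ncol(params$Ed)
  DR <- vapply(visits, function(v) {
    e <- embed_visit(v, params)
    if (nrow(e$De)) colSums(e$De) else numeric(d)
  }, numeric(d))
  PR <- vapply(visits, function(v) {
    e <- embed_visit(v, params)
    if (nrow(e$Pe)) colSums(e$Pe) else numeric(d)
  }, numeric(d))
  DR <- matrix(DR, nrow = d); PR <- matrix(PR, nrow = d)
  Hd <- gru_forward_r(DR, params$vd_W, params$vd_U, params$vd_b)
  Hp <- gru_forward_r(PR, params$vp_W, params$vp_U, params$vp_b)
  C_v <- lapply(seq_along(visits), function(t) c(Hd[, t], Hp[, t]))
  r_v <- lapply(C_v, function(cv) drop(params$m_v %*% cv))
  list(C_v = C_v, r_v = r_v)
}

#' Sequence-level view
#'
#' Encodes the current visit's diagnosis and procedure token sequences with
#' bidirectional recurrent encoders (summary: concatenated final forward and
#' backward states), concatenates the two summaries into `C_s`, and matches
#' against the view's drug matrix: `r_s = m_s %*% C_s`.  A pure function of
#' the single visit.
#'
#' @param visit An `mgrn_visit`.
#' @param params An `mgrn_params`.
#' @return A list with `C_s` (length `4*h_seq`) and `r_s` (length `Nm`).
#' @export
sequence_level_view <- function(visit, params) {
  e <- embed_visit(visit, params)
  Ds <- bigru_summary_concat(t(e$De), params$sdf_W, params$sdf_U, params$sdf_b,
                             params$sdb_W, params$sdb_U, params$sdb_b)
  Ps <- bigru_summary_concat(t(e$Pe), params$spf_W, params$spf_U, params$spf_b,
                             params$spb_W, params$spb_U, params$spb_b)
  C_s <- c(Ds, Ps)
  list(C_s = C_s, r_s = drop(params$m_s %*% C_s))
}

#' Token-level view
#'
#' Matches every individual token embedding against the view's drug matrix
#' (`Rtd = De %*% t(m_t)`, one score row per token), fuses each score-row
#' sequence with a bidirectional recurrent encoder of hidden size `Nm`
#' (summary: elementwise sum of the two directions' final states), and adds
#' the diagnosis and procedure summaries.
#'
#' @param visit An `mgrn_visit`.
#' @param params An `mgrn_params`.
#' @return A list with `r_t` (length `Nm`) and the per-token score matrices
#'   `Rtd` (`|diag| x Nm`) and `Rtp` (`|proc| x Nm`).
#' @export
token_level_view <- function(visit, params) {
  e <- embed_visit(visit, params)
  Rtd <- e$De %*% t(params$m_t)
  Rtp <- e$Pe %*% t(params$m_t)
  sd_ <- bigru_summary_sum(t(Rtd), params$tdf_W, params$tdf_U, params$tdf_b,
                           params$tdb_W, params$tdb_U, params$tdb_b)
  sp_ <- bigru_summary_sum(t(Rtp), params$tpf_W, params$tpf_U, params$tpf_b,
                           params$tpb_W, params$tpb_U, params$tpb_b)
  list(r_t = sd_ + sp_, Rtd = Rtd, Rtp = Rtp)
}

#' Gating drug retrieval
#'
#' For each historical visit `i < t`, concatenates the current patient
#' representation with the historical one into a current-history visit pair
#' (CHVP), passes it through a gating MLP (linear, tanh, linear, softplus;
#' weights shared across history positions) to obtain non-negative per-drug
#' retrieval weights, and sums the gated historical multi-hot drug vectors:
#' `r = sum_i G_i * M_i`.  With no history the result is the zero vector.
#' The softplus output keeps the weights non-negative (gate semantics)
#' while leaving them unbounded above, so a drug seen in a single past
#' visit can still receive an arbitrarily strong retrieval score.
#'
#' @param C_current Patient representation at the current visit.
#' @param C_history List of `t-1` historical representations (same length
#'   as `drug_history`).
#' @param drug_history List of `t-1` multi-hot drug vectors (length `Nm`).
#' @param gate_params List with `W1`, `b1`, `W2`, `b2`.
#' @return A list with `r` (length `Nm`) and `gates` (list of gate vectors).
#' @export
gating_drug_retrieval <- function(C_current, C_history, drug_history, gate_params) {
  stopifnot(length(C_history) == length(drug_history))
  Nm <- nrow(gate_params$W2)
  r <- numeric(Nm)
  gates <- vector("list", length(C_history))
  for (i in seq_along(C_history)) {
    if (length(C_history[[i]]) != length(C_current))
      stop("dimension mismatch between current and historical representations")
    chvp <- c(C_current, C_history[[i]])
    hid <- tanh(drop(gate_params$W1 %*% chvp) + gate_params$b1[, 1])
    g <- softplus(drop(gate_params$W2 %*% hid) + gate_params$b2[, 1])
    gates[[i]] <- g
    r <- r + g * drug_history[[i]]
  }
  list(r = r, gates = gates)
}

#' Aggregate view scores into drug probabilities
#'
#' Computes the historical drug score `r_h` by applying gating drug
#' retrieval under the visit-level and sequence-level representations
#' (separate gating MLPs), the global score `r_g = r_v + r_s + r_t`, and the
#' per-drug usage probabilities `o = sigmoid(r_g + r_h)`.  Views disabled in
#' `config` contribute exactly zero, and `use_gdr = FALSE` forces `r_h = 0`.
#'
#' @param r_v,r_s,r_t Length-`Nm` view scores for the current visit (use
#'   zero vectors for disabled views).
#' @param C_v_list,C_s_list Per-visit representations for visits `1..t`
#'   (the last element is the current visit).
#' @param drug_history List of `t-1` historical multi-hot drug vectors.
#' @param params An `mgrn_params`.
#' @param config An `mgrn_config`.
#' @return A list with `r_h`, `r_g` and `o` (all length `Nm`).
#' @export
aggregate_scores <- function(r_v, r_s, r_t, C_v_list, C_s_list, drug_history,
                             params, config) {
  Nm <- nrow(params$m_t)
  zero <- numeric(Nm)
  if (!config$use_visit_view) r_v <- zero
  if (!config$use_seq_view) r_s <- zero
  if (!config$use_token_view) r_t <- zero
  r_g <- r_v + r_s + r_t
  r_h <- zero
  t_cur <- length(C_v_list)
  if (config$use_gdr && length(drug_history)) {
    hist_idx <- seq_len(t_cur - 1L)
    if (config$use_visit_view) {
      r_h <- r_h + gating_drug_retrieval(
        C_v_list[[t_cur]], C_v_list[hist_idx], drug_history,
        list(W1 = params$gv_W1, b1 = params$gv_b1,
             W2 = params$gv_W2, b2 = params$gv_b2))$r
    }
    if (config$use_seq_view) {
      r_h <- r_h + gating_drug_retrieval(
        C_s_list[[t_cur]], C_s_list[hist_idx], drug_history,
        list(W1 = params$gs_W1, b1 = params$gs_b1,
             W2 = params$gs_W2, b2 = params$gs_b2))$r
    }
  }
  list(r_h = r_h, r_g = r_g, o = sigmoid(r_g + r_h))
}

#' Threshold probabilities into a recommended drug set
#'
#' @param o Probability vector in `(0,1)^Nm`.
#' @param phi Threshold in `(0,1)`; drug `j` is recommended iff `o[j] >= phi`.
#' @return Sorted integer vector of 0-based drug indices.
#' @export
predict_drugs <- function(o, phi = 0.5) {
  stopifnot(phi > 0, phi < 1)
  which(o >= phi) - 1L
}

#' Full forward pass over one patient
#'
#' For each visit `t`, composes the three views and gating drug retrieval
#' using only diagnoses/procedures of visits `1..t` and drugs of visits
#' `1..t-1` (the current visit's drugs are never an input to their own
#' prediction), and thresholds the resulting probabilities.
#'
#' @param patient An `mgrn_patient`.
#' @param params An `mgrn_params`.
#' @param config An `mgrn_config`.
#' @param n_drug Drug vocabulary size.
#' @param engine `"cpp"` (fused engine) or `"r"` (reference composition of
#'   the exported view operations); the two agree to floating-point
#'   tolerance.
#' @return An `mgrn_forward`: list with per-visit lists `o`, `r_v`, `r_s`,
#'   `r_t`, `r_h`, `r_g`, `C_v`, `C_s` and `pred` (0-based drug indices).
#' @export
forward_patient <- function(patient, params, config, n_drug,
                            engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  if (engine == "cpp") {
    raw <- cpp_forward_cohort(list(patient_to_engine(patient, n_drug)),
                              plain_params(params), engine_config(config, n_drug))[[1]]
    T_p <- length(patient$visits)
    out <- list(
      o = mat_cols(raw$o), r_v = mat_cols(raw$rv), r_s = mat_cols(raw$rs),
      r_t = mat_cols(raw$rt), r_h = mat_cols(raw$rh), r_g = mat_cols(raw$rg),
      C_v = mat_cols(raw$Cv), C_s = mat_cols(raw$Cs)
    )
    out$pred <- lapply(out$o, predict_drugs, phi = config$phi)
    class(out) <- "mgrn_forward"
    return(out)
  }
  visits <- patient$visits
  T_p <- length(visits)
  vv <- visit_level_view(visits, params)
  sq <- lapply(visits, sequence_level_view, params = params)
  tk <- lapply(visits, token_level_view, params = params)
  C_s_list <- lapply(sq, `[[`, "C_s")
  drug_hot <- lapply(visits, function(v) multi_hot(v$drugs, n_drug))
  out <- list(o = list(), r_v = list(), r_s = list(), r_t = list(),
              r_h = list(), r_g = list(), C_v = vv$C_v, C_s = C_s_list,
              pred = list())
  for (t in seq_len(T_p)) {
    agg <- aggregate_scores(
      vv$r_v[[t]], sq[[t]]$r_s, tk[[t]]$r_t,
      vv$C_v[seq_len(t)], C_s_list[seq_len(t)],
      if (t > 1L) drug_hot[seq_len(t - 1L)] else list(),
      params, config
    )
    zero <- numeric(n_drug)
    out$r_v[[t]] <- if (config$use_visit_view) vv$r_v[[t]] else zero
    out$r_s[[t]] <- if (config$use_seq_view) sq[[t]]$r_s else zero
    out$r_t[[t]] <- if (config$use_token_view) tk[[t]]$r_t else zero
    out$r_h[[t]] <- agg$r_h
    out$r_g[[t]] <- agg$r_g
    out$o[[t]] <- agg$o
    out$pred[[t]] <- predict_drugs(agg$o, config$phi)
  }
  class(out) <- "mgrn_forward"
  out
}

mat_cols <- function(M) lapply(seq_len(ncol(M)), function(j) M[, j])

# convert a patient to the 0-based list form the C++ engine consumes
patient_to_engine <- function(patient, n_drug) {
  list(
    diag = lapply(patient$visits, function(v) as.integer(v$diag)),
    proc = lapply(patient$visits, function(v) as.integer(v$proc)),
    drugs = lapply(patient$visits, function(v) as.integer(v$drugs))
  )
}

engine_config <- function(config, n_drug, training = FALSE) {
  list(d = config$d, hv = config$h_visit, hs = config$h_seq,
       mlp = config$mlp_hidden, Nm = as.integer(n_drug),
       dropout = if (training) config$dropout else 0,
       phi = config$phi,
       use_vst = config$use_visit_view, use_seq = config$use_seq_view,
       use_tkn = config$use_token_view, use_gdr = config$use_gdr)
}
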