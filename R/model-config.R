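#' Model configuration
#'
#' Hyperparameters of the multi-view gating retrieval network.  The three
#' views match patient representations against independent learned drug
#' matrices: the visit-level view encodes per-visit embedding sums with
#' unidirectional recurrent (GRU) encoders across visits (so visit `t` sees
#' only visits `1..t`); the sequence-level view encodes the current visit's
#' token sequences with bidirectional GRUs; the token-level view matches
#' every token embedding against the drug matrix and fuses the per-token
#' score rows with bidirectional GRUs.  The gating drug retrieval (GDR)
#' module scores every historically prescribed drug for reuse via a gating
#' MLP over current-history visit pairs.
#'
#' @param d Embedding dimension.
#' @param h_visit Hidden size of each visit-level recurrent encoder.
#' @param h_seq Hidden size (per direction) of each sequence-level encoder.
#' @param mlp_hidden Hidden width of the gating MLPs.
#' @param dropout Dropout rate applied to token embeddings during training.
#' @param phi Decision threshold: drug `j` is recommended iff `o[j] >= phi`.
#' @param use_visit_view,use_seq_view,use_token_view,use_gdr Ablation flags;
#'   disabled components contribute exactly zero score and receive no
#'   gradient.  At least one view must stay enabled.
#' @return An `mgrn_config`.
#' @export
model_config <- function(d = 64L, h_visit = 32L, h_seq = 32L,
                         mlp_hidden = 64L, dropout = 0.3, phi = 0.5,
                         use_visit_view = TRUE, use_seq_view = TRUE,
                         use_token_view = TRUE, use_gdr = TRUE) {
  cfg <- list(d = as.integer(d), h_visit = as.integer(h_visit),
              h_seq = as.integer(h_seq), mlp_hidden = as.integer(mlp_hidden),
              dropout = dropout, phi = phi,
              use_visit_view = isTRUE(use_visit_view),
              use_seq_view = isTRUE(use_seq_view),
              use_token_view = isTRUE(use_token_view),
              use_gdr = isTRUE(use_gdr))
  stopifnot(cfg$d >= 1L, cfg$h_visit >= 1L, cfg$h_seq >= 1L,
            cfg$mlp_hidden >= 1L, cfg$phi > 0, cfg$phi < 1,
            cfg$dropout >= 0, cfg$dropout < 1)
  if (!cfg$use_visit_view && !cfg$use_seq_view && !cfg$use_token_view)
    stop("at least one view must be enabled")
  class(cfg) <- "mgrn_config"
  cfg
}

#' Apply an ablation variant to a model configuration
#'
#' @param config An `mgrn_config`.
#' @param variant One of `"full"`, `"wo_vst"`, `"wo_seq"`, `"wo_tkn"`,
#'   `"only_vst"`, `"only_seq"`, `"only_tkn"`, `"wo_gdr"`.  Remove-one
#'   variants drop a single view; keep-one variants drop the other two; GDR
#'   still runs for a keep-one variant only when the kept view supplies its
#'   patient representation (the token-level view does not).
#' @return The modified `mgrn_config`.
#' @export
ablation_config <- function(config, variant) {
  variant <- match.arg(variant, c("full", "wo_vst", "wo_seq", "wo_tkn",
                                  "only_vst", "only_seq", "only_tkn", "wo_gdr"))
  flags <- switch(variant,
    full     = list(TRUE, TRUE, TRUE, TRUE),
    wo_vst   = list(FALSE, TRUE, TRUE, TRUE),
    wo_seq   = list(TRUE, FALSE, TRUE, TRUE),
    wo_tkn   = list(TRUE, TRUE, FALSE, TRUE),
    only_vst = list(TRUE, FALSE, FALSE, TRUE),
    only_seq = list(FALSE, TRUE, FALSE, TRUE),
    only_tkn = list(FALSE, FALSE, TRUE, TRUE),
    wo_gdr   = list(TRUE, TRUE, TRUE, FALSE)
  )
  config$use_visit_view <- flags[[1]]
  config$use_seq_view <- flags[[2]]
  config$use_token_view <- flags[[3]]
  config$use_gdr <- flags[[4]]
  config
}

# shapes of every parameter array, given config + vocabulary sizes.
# GRU weights are stored gate-stacked: rows [z; r; n], W: 3h x in, U: 3h x h,
# b: 3h x 1 (the candidate-gate bias sits inside the reset-gated term).
param_shapes <- function(config, vocab) {
  d <- config$d; hv <- config$h_visit; hs <- config$h_seq
  mh <- config$mlp_hidden
  Nd <- vocab$n_diag; Np <- vocab$n_proc; Nm <- vocab$n_drug
  gru <- function(h, in_) list(W = c(3L * h, in_), U = c(3L * h, h), b = c(3L * h, 1L))
  sh <- list(Ed = c(Nd, d), Ep = c(Np, d))
  for (p in c("vd", "vp")) for (w in c("W", "U", "b"))
    sh[[paste0(p, "_", w)]] <- gru(hv, d)[[w]]
  for (p in c("sdf", "sdb", "spf", "spb")) for (w in c("W", "U", "b"))
    sh[[paste0(p, "_", w)]] <- gru(hs, d)[[w]]
  for (p in c("tdf", "tdb", "tpf", "tpb")) for (w in c("W", "U", "b"))
    sh[[paste0(p, "_", w)]] <- gru(Nm, Nm)[[w]]
  sh$m_v <- c(Nm, 2L * hv)
  sh$m_s <- c(Nm, 4L * hs)
  sh$m_t <- c(Nm, d)
  sh$gv_W1 <- c(mh, 4L * hv); sh$gv_b1 <- c(mh, 1L)
  sh$gv_W2 <- c(Nm, mh);      sh$gv_b2 <- c(Nm, 1L)
  sh$gs_W1 <- c(mh, 8L * hs); sh$gs_b1 <- c(mh, 1L)
  sh$gs_W2 <- c(Nm, mh);      sh$gs_b2 <- c(Nm, 1L)
  sh
}

#' Initialize model parameters
#'
#' Embedding tables and the three drug representation matrices are drawn
#' from `N(0, 0.1^2)` (randomly initialized drug representations); recurrent
#' and MLP weights use Xavier-uniform; biases start at zero.  Deterministic
#' given `seed`.
#'
#' @param config An `mgrn_config`.
#' @param vocab An `mgrn_vocab` (fixes all shapes).
#' @param seed Integer seed.
#' @return An `mgrn_params`: named list of matrices.
#' @export
init_params <- function(config, vocab, seed = 1L) {
  shapes <- param_shapes(config, vocab)
  gaussian <- c("Ed", "Ep", "m_v", "m_s", "m_t")
  params <- withr_seed(seed, {
    lapply(setNames(names(shapes), names(shapes)), function(nm) {
      sh <- shapes[[nm]]
      if (nm %in% gaussian) {
        matrix(rnorm(prod(sh), sd = 0.1), sh[1], sh[2])
      } else if (endsWith(nm, "b") || endsWith(nm, "b1") || endsWith(nm, "b2")) {
        matrix(0, sh[1], sh[2])
      } else {
        lim <- sqrt(6 / (sh[1] + sh[2]))
        matrix(runif(prod(sh), -lim, lim), sh[1], sh[2])
      }
    })
  })
  structure(params, class = "mgrn_params",
            vocab_hash = vocab_hash(vocab))
}

check_params <- function(params, config, vocab) {
  shapes <- param_shapes(config, vocab)
  for (nm in names(shapes)) {
    if (is.null(params[[nm]])) stop("missing parameter: ", nm)
    if (!all(dim(params[[nm]]) == shapes[[nm]]))
      stop(sprintf("parameter %s has shape %dx%d, expected %dx%d", nm,
                   nrow(params[[nm]]), ncol(params[[nm]]),
                   shapes[[nm]][1], shapes[[nm]][2]))
  }
  invisible(params)
}

# strip class/attrs for the C++ engine (plain named list of matrices)
plain_params <- function(params) {
  p <- unclass(params)
  attr(p, "vocab_hash") <- NULL
  p
}
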