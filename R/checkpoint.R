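#' Save a model checkpoint
#'
#' A single-file archive holding the model configuration, all parameter
#' arrays, and a digest of the vocabulary the model was trained against.
#' Loading refuses a mismatched vocabulary, since parameter rows are
#' meaningless under a different code-to-index mapping.
#'
#' @param params An `mgrn_params`.
#' @param config The `mgrn_config` the parameters belong to.
#' @param vocab The `mgrn_vocab` the parameters were built for.
#' @param path Output file path.
#' @export
save_checkpoint <- function(params, config, vocab, path) {
  check_params(params, config, vocab)
  saveRDS(list(format = "mgrn_checkpoint_v1",
               config = unclass(config),
               vocab_hash = vocab_hash(vocab),
               params = plain_params(params)),
          path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path Checkpoint file written by [save_checkpoint()].
#' @param vocab The `mgrn_vocab` of the data the model will be applied to;
#'   must match the checkpoint's vocabulary digest.
#' @return A list with `params` (`mgrn_params`) and `config` (`mgrn_config`).
#' @export
load_checkpoint <- function(path, vocab) {
  x <- readRDS(path)
  if (!identical(x$format, "mgrn_checkpoint_v1"))
    stop("not an mgrn checkpoint: ", path)
  if (!identical(x$vocab_hash, vocab_hash(vocab)))
    stop("checkpoint was trained against a different vocabulary")
  config <- do.call(model_config, x$config[c("d", "h_visit", "h_seq",
                                             "mlp_hidden", "dropout", "phi",
                                             "use_visit_view", "use_seq_view",
                                             "use_token_view", "use_gdr")])
  params <- structure(x$params, class = "mgrn_params",
                      vocab_hash = x$vocab_hash)
  check_params(params, config, vocab)
  list(params = params, config = config)
}
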