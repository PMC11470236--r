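#' Build a vocabulary from raw coded records
#'
#' Collects every diagnosis, procedure and drug code observed in a list of raw
#' patient records and assigns each code a 0-based integer index.  Codes are
#' ordered lexicographically within each of the three namespaces so that
#' repeated builds over the same cohort (in any record order) produce an
#' identical vocabulary.
#'
#' @param raw_records A list of patients, each a list with a `visits` element;
#'   each visit is a list with character vectors `diag`, `proc` and `drugs`.
#' @return An object of class `mgrn_vocab` with elements `diag_codes`,
#'   `proc_codes`, `drug_codes` (sorted character vectors) and the sizes
#'   `n_diag`, `n_proc`, `n_drug`.
#' @export
build_vocabulary <- function(raw_records) {
  if (length(raw_records) == 0L) stop("empty cohort")
  pool <- function(field) {
    codes <- unlist(lapply(raw_records, function(p) {
      unlist(lapply(p$visits, function(v) as.character(v[[field]])))
    }), use.names = FALSE)
    codes <- unique(codes)
    if (any(!nzchar(codes))) stop("codes must be non-empty strings")
    sort(codes, method = "radix")
  }
  new_vocab(pool("diag"), pool("proc"), pool("drugs"))
}

new_vocab <- function(diag_codes, proc_codes, drug_codes) {
  structure(
    list(
      diag_codes = as.character(diag_codes),
      proc_codes = as.character(proc_codes),
      drug_codes = as.character(drug_codes),
      n_diag = length(diag_codes),
      n_proc = length(proc_codes),
      n_drug = length(drug_codes)
    ),
    class = "mgrn_vocab"
  )
}

#' @export
print.mgrn_vocab <- function(x, ...) {
  cat(sprintf("<mgrn_vocab> %d diagnoses, %d procedures, %d drugs\n",
              x$n_diag, x$n_proc, x$n_drug))
  invisible(x)
}

# map code strings to 0-based indices; errors name the offending code
code_to_index <- function(codes, table, space, context = "") {
  idx <- match(as.character(codes), table)
  if (anyNA(idx)) {
    bad <- as.character(codes)[which(is.na(idx))[1L]]
    stop(sprintf("unknown %s code '%s'%s", space, bad,
                 if (nzchar(context)) paste0(" (", context, ")") else ""))
  }
  as.integer(idx - 1L)
}

#' Write a vocabulary to JSON
#'
#' @param vocab An `mgrn_vocab`.
#' @param path Output file path.
#' @export
write_vocab_json <- function(vocab, path) {
  stopifnot(inherits(vocab, "mgrn_vocab"))
  jsonlite::write_json(
    list(diag = vocab$diag_codes, proc = vocab$proc_codes,
         drug = vocab$drug_codes),
    path, auto_unbox = FALSE
  )
  invisible(path)
}

#' Read a vocabulary from JSON
#'
#' @param path JSON file with arrays `diag`, `proc`, `drug`.
#' @return An `mgrn_vocab`.
#' @export
read_vocab_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("diag", "proc", "drug")) {
    if (is.null(x[[f]])) stop(sprintf("vocabulary file missing '%s' array", f))
  }
  new_vocab(x$diag, x$proc, x$drug)
}

# stable digest used to bind checkpoints to a vocabulary
vocab_hash <- function(vocab) {
  s <- paste(c(vocab$diag_codes, "|", vocab$proc_codes, "|", vocab$drug_codes),
             collapse = "\x1f")
  # polynomial rolling hash (mod 2^31 - 1); dependency-free, stable across runs
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
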