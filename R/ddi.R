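#' Read a drug-drug interaction edge list
#'
#' Parses a two-column TSV of drug-code pairs (lines starting with `#` are
#' comments) into a symmetric binary adjacency matrix over the drug
#' vocabulary.  Edges mentioning a code absent from `vocab` are skipped (a
#' message reports how many); self-edges are ignored.
#'
#' @param path TSV file path.
#' @param vocab An `mgrn_vocab` fixing the drug index space.
#' @return An `mgrn_ddi`: an `n_drug x n_drug` 0/1 matrix, symmetric with a
#'   zero diagonal.
#' @export
read_ddi_edgelist <- function(path, vocab) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  A <- matrix(0, vocab$n_drug, vocab$n_drug)
  skipped <- 0L
  for (ln in lines) {
    parts <- strsplit(ln, "[\t ]+")[[1]]
    if (length(parts) < 2L) stop("DDI edge list rows need two drug codes: ", ln)
    i <- match(parts[1], vocab$drug_codes)
    j <- match(parts[2], vocab$drug_codes)
    if (is.na(i) || is.na(j)) { skipped <- skipped + 1L; next }
    if (i == j) next
    A[i, j] <- 1; A[j, i] <- 1
  }
  if (skipped > 0L)
    message(sprintf("read_ddi_edgelist: skipped %d edge(s) with unknown codes", skipped))
  as_ddi(A)
}

as_ddi <- function(A) {
  check_ddi(A)
  structure(A, class = c("mgrn_ddi", "matrix", "array"))
}

check_ddi <- function(A) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  if (!all(A %in% c(0, 1))) stop("DDI matrix entries must be 0/1")
  if (!isTRUE(all.equal(A, t(A)))) stop("DDI matrix must be symmetric")
  if (any(diag(A) != 0)) stop("DDI matrix must have a zero diagonal")
  invisible(A)
}

#' Write a DDI matrix as a TSV edge list
#'
#' @param ddi An `mgrn_ddi` matrix.
#' @param vocab The `mgrn_vocab` supplying drug codes.
#' @param path Output path.
#' @export
write_ddi_edgelist <- function(ddi, vocab, path) {
  check_ddi(unclass(ddi))
  idx <- which(upper.tri(ddi) & ddi == 1, arr.ind = TRUE)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("# drug_a\tdrug_b", con)
  if (nrow(idx)) {
    ord <- order(idx[, 1], idx[, 2])
    writeLines(paste(vocab$drug_codes[idx[ord, 1]],
                     vocab$drug_codes[idx[ord, 2]], sep = "\t"), con)
  }
  invisible(path)
}
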