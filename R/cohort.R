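#' Construct a single visit
#'
#' A visit is the unit record of a longitudinal EHR: the set of diagnosis
#' codes, procedure codes, and prescribed drug codes for one admission.
#' Indices are 0-based into the owning vocabulary and stored sorted, which
#' fixes the canonical token order consumed by the order-sensitive recurrent
#' encoders.
#'
#' @param diag,proc,drugs Integer vectors of 0-based vocabulary indices.
#' @param min_diag,min_drugs Minimum set sizes enforced (default 1 each:
#'   the visit-level embedding sum and the multi-label losses are ill-defined
#'   on empty sets).  Pass 0 to relax.
#' @return A list of class `mgrn_visit` with sorted, de-duplicated `diag`,
#'   `proc`, `drugs`.
#' @export
new_visit <- function(diag, proc = integer(), drugs = integer(),
                      min_diag = 1L, min_drugs = 1L) {
  canon <- function(x) sort(unique(as.integer(x)))
  diag <- canon(diag); proc <- canon(proc); drugs <- canon(drugs)
  if (length(diag) < min_diag) stop("visit has fewer than ", min_diag, " diagnoses")
  if (length(drugs) < min_drugs) stop("visit has fewer than ", min_drugs, " drugs")
  if (length(c(diag, proc, drugs)) && min(c(diag, proc, drugs)) < 0L)
    stop("negative code index")
  structure(list(diag = diag, proc = proc, drugs = drugs), class = "mgrn_visit")
}

#' Construct a patient record
#'
#' @param patient_id Character scalar.
#' @param visits List of `mgrn_visit`, in chronological order.
#' @return An `mgrn_patient`.
#' @export
new_patient <- function(patient_id, visits) {
  stopifnot(is.character(patient_id), length(patient_id) == 1L,
            length(visits) >= 1L)
  structure(list(patient_id = patient_id, visits = visits),
            class = "mgrn_patient")
}

#' Construct a cohort
#'
#' @param records List of `mgrn_patient`.
#' @param vocab The shared `mgrn_vocab`.
#' @return An `mgrn_cohort`.
#' @export
new_cohort <- function(records, vocab) {
  ids <- vapply(records, function(p) p$patient_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate patient_id: ", ids[duplicated(ids)][1L])
  for (p in records) {
    for (v in p$visits) {
      if (length(v$diag) && max(v$diag) >= vocab$n_diag)
        stop("diagnosis index out of vocabulary range for patient ", p$patient_id)
      if (length(v$proc) && max(v$proc) >= vocab$n_proc)
        stop("procedure index out of vocabulary range for patient ", p$patient_id)
      if (length(v$drugs) && max(v$drugs) >= vocab$n_drug)
        stop("drug index out of vocabulary range for patient ", p$patient_id)
    }
  }
  structure(list(records = records, vocab = vocab), class = "mgrn_cohort")
}

#' @export
print.mgrn_cohort <- function(x, ...) {
  tv <- vapply(x$records, function(p) length(p$visits), integer(1))
  cat(sprintf("<mgrn_cohort> %d patients, %d visits (T: %d-%d), vocab %d/%d/%d\n",
              length(x$records), sum(tv),
              if (length(tv)) min(tv) else 0L, if (length(tv)) max(tv) else 0L,
              x$vocab$n_diag, x$vocab$n_proc, x$vocab$n_drug))
  invisible(x)
}

#' Number of patients in a cohort
#' @param cohort An `mgrn_cohort`.
#' @export
n_patients <- function(cohort) length(cohort$records)

#' Read a cohort from JSON Lines
#'
#' One patient object per line:
#' `{"patient_id": "...", "visits": [{"diag": [...], "proc": [...], "drugs": [...]}]}`
#' with codes as strings.  Codes are mapped to 0-based indices under `vocab`;
#' if `vocab` is `NULL` it is built from the file first (lexicographic code
#' order, so rebuilding is deterministic).  Duplicate codes inside one set are
#' de-duplicated with a warning.
#'
#' @param path JSONL file path.
#' @param vocab Optional fixed `mgrn_vocab`; an unknown code under a fixed
#'   vocabulary is an error naming the code and line.
#' @param min_diag,min_drugs Minimum per-visit set sizes (see [new_visit()]).
#' @return An `mgrn_cohort`.
#' @export
read_cohort_jsonl <- function(path, vocab = NULL, min_diag = 1L, min_drugs = 1L) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty cohort")
  raw <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    obj <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE),
                    error = function(e) stop(sprintf(
                      "malformed JSON on line %d: %s", i, conditionMessage(e)),
                      call. = FALSE))
    if (is.null(obj$patient_id) || is.null(obj$visits))
      stop(sprintf("line %d: patient object needs 'patient_id' and 'visits'", i))
    raw[[i]] <- obj
  }
  if (is.null(vocab)) {
    vocab <- build_vocabulary(lapply(raw, function(p) {
      list(visits = lapply(p$visits, function(v)
        list(diag = unlist(v$diag), proc = unlist(v$proc), drugs = unlist(v$drugs))))
    }))
  }
  dup_warned <- FALSE
  records <- vector("list", length(raw))
  for (i in seq_along(raw)) {
    p <- raw[[i]]
    visits <- lapply(p$visits, function(v) {
      d <- as.character(unlist(v$diag)); pr <- as.character(unlist(v$proc))
      m <- as.character(unlist(v$drugs))
      if ((anyDuplicated(d) || anyDuplicated(pr) || anyDuplicated(m)) &&
          !dup_warned) {
        warning(sprintf("duplicate codes within a set (first at line %d); de-duplicated", i))
        dup_warned <<- TRUE
      }
      ctx <- sprintf("line %d", i)
      new_visit(
        code_to_index(unique(d), vocab$diag_codes, "diagnosis", ctx),
        code_to_index(unique(pr), vocab$proc_codes, "procedure", ctx),
        code_to_index(unique(m), vocab$drug_codes, "drug", ctx),
        min_diag = min_diag, min_drugs = min_drugs
      )
    })
    records[[i]] <- new_patient(as.character(p$patient_id), visits)
  }
  new_cohort(records, vocab)
}

#' Write a cohort to JSON Lines
#'
#' Serializes in canonical form: one patient per line, sets written as
#' lexicographically sorted code-string arrays, so output files are stable
#' and diffable and `write` then `read` is the identity.
#'
#' @param cohort An `mgrn_cohort`.
#' @param path Output path.
#' @export
write_cohort_jsonl <- function(cohort, path) {
  stopifnot(inherits(cohort, "mgrn_cohort"))
  v <- cohort$vocab
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (p in cohort$records) {
    visits <- lapply(p$visits, function(vi) list(
      diag = sort(v$diag_codes[vi$diag + 1L]),
      proc = sort(v$proc_codes[vi$proc + 1L]),
      drugs = sort(v$drug_codes[vi$drugs + 1L])
    ))
    line <- jsonlite::toJSON(list(patient_id = p$patient_id, visits = visits),
                             auto_unbox = TRUE, null = "null")
    writeLines(as.character(line), con, useBytes = TRUE)
  }
  invisible(path)
}

#' Split a cohort into train/validation/test
#'
#' Patient-level partition: every patient lands in exactly one split, sizes
#' are the rounded fractions, and the shuffle is deterministic given `seed`.
#'
#' @param cohort An `mgrn_cohort`.
#' @param fractions Numeric length-3 `(train, val, test)`; positive, summing
#'   to 1.  Default `c(2/3, 1/6, 1/6)`.
#' @param seed Integer seed.
#' @return A list with cohorts `train`, `val`, `test`.
#' @export
split_cohort <- function(cohort, fractions = c(2/3, 1/6, 1/6), seed = 1L) {
  stopifnot(length(fractions) == 3L)
  if (any(fractions <= 0)) stop("fractions must be positive")
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  n <- n_patients(cohort)
  perm <- withr_seed(seed, sample.int(n))
  n_train <- round(fractions[1] * n)
  n_val <- round(fractions[2] * n)
  n_val <- min(n_val, n - n_train)
  if (n_train + n_val >= n) stop("split leaves no test patients; use more patients")
  idx <- list(train = perm[seq_len(n_train)],
              val = perm[n_train + seq_len(n_val)],
              test = perm[(n_train + n_val + 1L):n])
  lapply(idx, function(i) new_cohort(cohort$records[sort(i)], cohort$vocab))
}

#' Randomly delete a fraction of patients
#'
#' The robustness protocol: removes `floor(rate * n)` whole patients
#' uniformly at random (whole records, preserving visit-sequence integrity),
#' deterministic given `seed`.
#'
#' @param cohort An `mgrn_cohort`.
#' @param rate Fraction in `[0, 1)`.
#' @param seed Integer seed.
#' @return The surviving `mgrn_cohort`.
#' @export
delete_fraction <- function(cohort, rate, seed = 1L) {
  stopifnot(rate >= 0, rate < 1)
  n <- n_patients(cohort)
  k <- floor(rate * n)
  if (k == 0L) return(cohort)
  drop <- withr_seed(seed, sample.int(n, k))
  new_cohort(cohort$records[-drop], cohort$vocab)
}

#' Multi-hot encoding of a drug set
#'
#' @param drug_set Integer vector of 0-based drug indices.
#' @param n_drug Drug vocabulary size.
#' @return Binary numeric vector `v` of length `n_drug` with `v[j+1] = 1`
#'   iff `j` is in `drug_set`.
#' @export
multi_hot <- function(drug_set, n_drug) {
  drug_set <- as.integer(drug_set)
  if (length(drug_set) && max(drug_set) >= n_drug) stop("drug index out of range")
  v <- numeric(n_drug)
  v[drug_set + 1L] <- 1
  v
}

# run expr under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
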