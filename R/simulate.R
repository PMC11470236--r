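#' Specification for a synthetic longitudinal cohort
#'
#' The simulator emulates the structure that matters for history-aware
#' medication recommendation: multi-visit patients, a stable
#' diagnosis-to-drug prescribing rule, and strong overlap between a visit's
#' drug set and the union of previously prescribed drugs (chronic
#' medication).  Each patient keeps a "chronic core" of half their
#' first-visit diagnoses across all visits; each drug prescribed at visit
#' `t-1` recurs at visit `t` with probability `persistence_rho`; and every
#' drug coordinate is flipped independently with probability `noise_eps`
#' (adding a random drug or removing a present one).
#'
#' Defaults are the package's standard study conditions: a 60/30/40 code
#' vocabulary, 600 patients with 2-5 visits, 2 rule drugs per diagnosis,
#' persistence 0.9, noise 0.05 and DDI density 0.1.
#'
#' @param n_diag,n_proc,n_drug Vocabulary sizes.
#' @param n_patients Number of patients.
#' @param visit_count_range Inclusive `(min, max)` for visits per patient.
#' @param drugs_per_diag Number of rule drugs per diagnosis (`k`).
#' @param persistence_rho Probability each drug at visit `t-1` recurs at `t`.
#' @param noise_eps Per-coordinate flip probability applied to each visit's
#'   drug vector.
#' @param diags_per_visit_range,procs_per_visit_range Inclusive ranges for
#'   per-visit set sizes.
#' @param ddi_density Independent probability each unordered drug pair
#'   interacts.
#' @param seed Master seed; the simulator derives separate sub-streams for
#'   structure (diagnoses/procedures), persistence, noise and DDI edges, so
#'   changing one parameter does not reshuffle the others.
#' @return An `mgrn_synth_spec`.
#' @export
synthetic_spec <- function(n_diag = 60L, n_proc = 30L, n_drug = 40L,
                           n_patients = 600L,
                           visit_count_range = c(2L, 5L),
                           drugs_per_diag = 2L,
                           persistence_rho = 0.9,
                           noise_eps = 0.05,
                           diags_per_visit_range = c(2L, 4L),
                           procs_per_visit_range = c(1L, 3L),
                           ddi_density = 0.1,
                           seed = 42L) {
  spec <- list(
    n_diag = as.integer(n_diag), n_proc = as.integer(n_proc),
    n_drug = as.integer(n_drug), n_patients = as.integer(n_patients),
    visit_count_range = as.integer(visit_count_range),
    drugs_per_diag = as.integer(drugs_per_diag),
    persistence_rho = persistence_rho, noise_eps = noise_eps,
    diags_per_visit_range = as.integer(diags_per_visit_range),
    procs_per_visit_range = as.integer(procs_per_visit_range),
    ddi_density = ddi_density, seed = as.integer(seed)
  )
  class(spec) <- "mgrn_synth_spec"
  validate_synth_spec(spec)
  spec
}

validate_synth_spec <- function(spec) {
  with(spec, {
    stopifnot(n_diag >= 1L, n_proc >= 1L, n_drug >= 1L, n_patients >= 1L)
    if (n_patients >= 10000L) stop("simulator supports at most 9999 patients")
    ok_range <- function(r, lo) length(r) == 2L && r[1] >= lo && r[2] >= r[1]
    if (!ok_range(visit_count_range, 1L)) stop("invalid visit_count_range")
    if (!ok_range(diags_per_visit_range, 1L)) stop("invalid diags_per_visit_range")
    if (!ok_range(procs_per_visit_range, 0L)) stop("invalid procs_per_visit_range")
    if (diags_per_visit_range[2] > n_diag) stop("diags_per_visit_range exceeds n_diag")
    if (procs_per_visit_range[2] > n_proc) stop("procs_per_visit_range exceeds n_proc")
    if (drugs_per_diag < 1L) stop("drugs_per_diag must be >= 1")
    if (n_drug < drugs_per_diag) stop("n_drug must be >= drugs_per_diag")
    for (p in c(persistence_rho, noise_eps, ddi_density))
      if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]")
  })
  invisible(spec)
}

# distinct deterministic sub-seed per (stream, patient); requires n_patients < 10000
stream_seed <- function(seed, stream, patient = 0L) {
  as.integer(((seed %% 10000L) * 100000L + stream * 10000L + patient) %% 2147483647L)
}

#' Draw the ground-truth prescribing rule
#'
#' Assigns each diagnosis a fixed set of `drugs_per_diag` distinct drugs,
#' sampled without replacement; deterministic given the simulator seed.  The rule
#' is retained alongside generated cohorts so that clairvoyant upper-bound
#' predictors and parameter-recovery tests are possible.
#'
#' @param spec An `mgrn_synth_spec`.
#' @return An `mgrn_rule`: list with `diag_to_drugs` (list of 0-based drug
#'   index vectors, one per diagnosis), `persistence_rho`, `noise_eps`.
#' @export
make_rule <- function(spec) {
  validate_synth_spec(spec)
  diag_to_drugs <- withr_seed(stream_seed(spec$seed, 0L), {
    lapply(seq_len(spec$n_diag), function(i)
      sort(sample.int(spec$n_drug, spec$drugs_per_diag) - 1L))
  })
  structure(list(diag_to_drugs = diag_to_drugs,
                 persistence_rho = spec$persistence_rho,
                 noise_eps = spec$noise_eps),
            class = "mgrn_rule")
}

rule_drugs_for <- function(rule, diag_idx) {
  sort(unique(unlist(rule$diag_to_drugs[diag_idx + 1L], use.names = FALSE)))
}

#' Generate a synthetic cohort
#'
#' Per patient, the number of visits is uniform over `visit_count_range`.
#' Diagnoses: the first visit samples uniformly; a chronic core of
#' `ceiling(half)` of the first-visit diagnoses persists across all visits,
#' the remainder are resampled per visit.  Procedures sample uniformly.
#' Drugs at visit `t` are the rule drugs of the current diagnoses, plus each
#' drug of visit `t-1` independently retained with probability
#' `persistence_rho`, after which each drug coordinate flips independently
#' with probability `noise_eps`; a visit emptied by noise gets one rule drug
#' re-added.  The DDI matrix sets each unordered drug pair to 1 with
#' probability `ddi_density`.  Everything is deterministic given the seed.
#'
#' @param spec An `mgrn_synth_spec`.
#' @return A list with `cohort` (`mgrn_cohort`), `rule` (`mgrn_rule`) and
#'   `ddi` (`mgrn_ddi`).
#' @export
generate_cohort <- function(spec) {
  validate_synth_spec(spec)
  rule <- make_rule(spec)
  vocab <- new_vocab(
    sprintf("D%03d", seq_len(spec$n_diag)),
    sprintf("P%03d", seq_len(spec$n_proc)),
    sprintf("M%03d", seq_len(spec$n_drug))
  )
  Nm <- spec$n_drug
  records <- vector("list", spec$n_patients)
  for (p in seq_len(spec$n_patients)) {
    # structure stream: visit count, diagnoses, procedures
    str_draws <- withr_seed(stream_seed(spec$seed, 1L, p), {
      runif_int <- function(n, r) r[1] + sample.int(r[2] - r[1] + 1L, n,
                                                    replace = TRUE) - 1L
      T_p <- runif_int(1L, spec$visit_count_range)
      nd <- runif_int(T_p, spec$diags_per_visit_range)
      np <- runif_int(T_p, spec$procs_per_visit_range)
      first <- sample.int(spec$n_diag, nd[1]) - 1L
      core <- first[seq_len(ceiling(nd[1] / 2))]
      diags <- vector("list", T_p)
      diags[[1]] <- first
      if (T_p > 1L) for (t in 2:T_p) {
        pool <- setdiff(seq_len(spec$n_diag) - 1L, core)
        n_extra <- min(max(nd[t] - length(core), 0L), length(pool))
        extra <- if (n_extra > 0L) pool[sample.int(length(pool), n_extra)] else integer()
        diags[[t]] <- c(core, extra)
      }
      procs <- lapply(np, function(k)
        if (k > 0L) sample.int(spec$n_proc, k) - 1L else integer())
      list(T_p = T_p, diags = diags, procs = procs)
    })
    T_p <- str_draws$T_p
    # fixed-size coin blocks keep stream consumption independent of set sizes
    u_pers <- withr_seed(stream_seed(spec$seed, 2L, p),
                         matrix(runif(T_p * Nm), T_p, Nm))
    u_noise <- withr_seed(stream_seed(spec$seed, 3L, p),
                          matrix(runif(T_p * Nm), T_p, Nm))
    visits <- vector("list", T_p)
    prev <- logical(Nm)
    for (t in seq_len(T_p)) {
      member <- logical(Nm)
      member[rule_drugs_for(rule, str_draws$diags[[t]]) + 1L] <- TRUE
      if (t > 1L) member[prev & (u_pers[t, ] < spec$persistence_rho)] <- TRUE
      flip <- u_noise[t, ] < spec$noise_eps
      member <- xor(member, flip)
      if (!any(member)) {
        rd <- rule_drugs_for(rule, str_draws$diags[[t]])
        member[rd[1] + 1L] <- TRUE
      }
      visits[[t]] <- new_visit(str_draws$diags[[t]], str_draws$procs[[t]],
                               which(member) - 1L, min_diag = 1L, min_drugs = 1L)
      prev <- member
    }
    records[[p]] <- new_patient(sprintf("SYN%04d", p), visits)
  }
  A <- withr_seed(stream_seed(spec$seed, 4L), {
    M <- matrix(0, Nm, Nm)
    if (Nm > 1L) {
      ut <- upper.tri(M)
      M[ut] <- as.numeric(runif(sum(ut)) < spec$ddi_density)
      M <- M + t(M)
    }
    M
  })
  list(cohort = new_cohort(records, vocab), rule = rule, ddi = as_ddi(A))
}

#' Jaccard similarity between two index sets
#'
#' `|A intersect B| / |A union B|`; defined as 1 when both sets are empty.
#'
#' @param a,b Integer vectors (sets).
#' @export
jaccard_sets <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(1)
  length(intersect(a, b)) / u
}

#' Histogram of current-vs-history drug overlap
#'
#' For every visit `t >= 2` of every patient, computes the Jaccard
#' similarity between the visit's drug set and the union of all earlier
#' visits' drug sets, and bins the values over `[0, 1]`.  This is the
#' summary statistic that motivates retrieving drugs from the medication
#' history: under chronic prescribing most current drugs have appeared
#' before.
#'
#' @param cohort An `mgrn_cohort` with at least one patient with `T >= 2`.
#' @param n_bins Number of equal-width bins over `[0, 1]`.
#' @return A list with `counts` (length `n_bins`, summing to the number of
#'   visits with history), `breaks`, `mids` and the raw `values`.
#' @export
history_overlap_histogram <- function(cohort, n_bins = 10L) {
  vals <- unlist(lapply(cohort$records, function(p) {
    if (length(p$visits) < 2L) return(numeric())
    hist_set <- integer()
    out <- numeric(length(p$visits) - 1L)
    for (t in seq_along(p$visits)) {
      if (t >= 2L) out[t - 1L] <- jaccard_sets(p$visits[[t]]$drugs, hist_set)
      hist_set <- union(hist_set, p$visits[[t]]$drugs)
    }
    out
  }), use.names = FALSE)
  if (!length(vals)) stop("cohort has no visits with history (all T = 1)")
  breaks <- seq(0, 1, length.out = n_bins + 1L)
  bin <- pmin(pmax(findInterval(vals, breaks, rightmost.closed = TRUE), 1L), n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  list(counts = counts, breaks = breaks,
       mids = (breaks[-1] + breaks[-length(breaks)]) / 2, values = vals)
}
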