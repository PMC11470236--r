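test_that("the prescribing rule has the requested shape and is deterministic", {
  spec <- tiny_spec(n_diag = 3L, n_drug = 10L, drugs_per_diag = 2L, seed = 0L)
  rule <- make_rule(spec)
  expect_length(rule$diag_to_drugs, 3L)
  for (s in rule$diag_to_drugs) {
    expect_length(s, 2L)
    expect_length(unique(s), 2L)
  }
  expect_identical(make_rule(spec), rule)
  forced <- make_rule(tiny_spec(n_diag = 4L, n_drug = 1L, drugs_per_diag = 1L,
                                diags_per_visit_range = c(1L, 2L)))
  expect_true(all(vapply(forced$diag_to_drugs, identical, logical(1), 0L)))
})

test_that("without persistence or noise, drugs equal the rule image of the diagnoses", {
  spec <- tiny_spec(persistence_rho = 0, noise_eps = 0, n_patients = 20L)
  g <- generate_cohort(spec)
  for (p in g$cohort$records) {
    for (v in p$visits) {
      expected <- sort(unique(unlist(g$rule$diag_to_drugs[v$diag + 1L])))
      expect_equal(v$drugs, expected)
    }
  }
})

test_that("full persistence without noise makes drug sets nested over time", {
  g <- generate_cohort(tiny_spec(persistence_rho = 1, noise_eps = 0,
                                 n_patients = 20L))
  for (p in g$cohort$records) {
    for (t in seq_along(p$visits)[-1]) {
      expect_true(all(p$visits[[t - 1L]]$drugs %in% p$visits[[t]]$drugs))
    }
  }
})

test_that("zero interaction density yields an all-zero DDI matrix", {
  g <- generate_cohort(tiny_spec(ddi_density = 0))
  expect_equal(sum(g$ddi), 0)
})

test_that("identical specs serialize to byte-identical cohorts", {
  spec <- tiny_spec(n_patients = 15L)
  p1 <- withr::local_tempfile(fileext = ".jsonl")
  p2 <- withr::local_tempfile(fileext = ".jsonl")
  write_cohort_jsonl(generate_cohort(spec)$cohort, p1)
  write_cohort_jsonl(generate_cohort(spec)$cohort, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("changing noise does not reshuffle diagnoses (separate streams)", {
  g1 <- generate_cohort(tiny_spec(noise_eps = 0))
  g2 <- generate_cohort(tiny_spec(noise_eps = 0.3))
  d1 <- lapply(g1$cohort$records, function(p) lapply(p$visits, `[[`, "diag"))
  d2 <- lapply(g2$cohort$records, function(p) lapply(p$visits, `[[`, "diag"))
  expect_identical(d1, d2)
  expect_identical(unclass(g1$ddi), unclass(g2$ddi))
})

test_that("history-overlap histogram puts repeated drug sets in the top bin", {
  vocab <- mgrn:::new_vocab(c("D1"), c("P1"), sprintf("M%d", 1:5))
  rec <- lapply(1:4, function(i) new_patient(sprintf("p%d", i), lapply(1:3, function(t)
    new_visit(0L, 0L, c(0L, 2L)))))
  cohort <- new_cohort(rec, vocab)
  h <- history_overlap_histogram(cohort, n_bins = 10L)
  expect_equal(sum(h$counts), 8L)           # 2 history visits x 4 patients
  expect_equal(h$counts[10L], 8L)
  expect_true(all(h$values == 1))
})

test_that("disjoint per-visit drugs give zero overlap mass", {
  vocab <- mgrn:::new_vocab(c("D1"), c("P1"), sprintf("M%d", 1:6))
  rec <- list(new_patient("p1", list(new_visit(0L, 0L, 0:1),
                                     new_visit(0L, 0L, 2:3),
                                     new_visit(0L, 0L, 4:5))))
  h <- history_overlap_histogram(new_cohort(rec, vocab), n_bins = 5L)
  expect_equal(h$counts[1L], 2L)
  expect_true(all(h$values == 0))
})

test_that("mean history overlap increases with drug persistence", {
  means <- vapply(c(0, 0.3, 0.6, 0.9), function(rho) {
    mean(vapply(1:3, function(s) {
      g <- generate_cohort(tiny_spec(persistence_rho = rho, n_patients = 60L,
                                     seed = 100L + s))
      # brute-force recomputation of the mean overlap
      mean(unlist(lapply(g$cohort$records, function(p) {
        hist_set <- integer()
        out <- c()
        for (t in seq_along(p$visits)) {
          if (t >= 2) out <- c(out, jaccard_sets(p$visits[[t]]$drugs, hist_set))
          hist_set <- union(hist_set, p$visits[[t]]$drugs)
        }
        out
      })))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) >= 0))
  # and the histogram agrees with the brute-force values
  g <- generate_cohort(tiny_spec(persistence_rho = 0.9, n_patients = 60L))
  h <- history_overlap_histogram(g$cohort, n_bins = 20L)
  expect_equal(sum(h$counts), length(h$values))
})

test_that("a clairvoyant rule predictor is perfect on noiseless cohorts", {
  for (rho in c(0, 1)) {
    g <- generate_cohort(tiny_spec(persistence_rho = rho, noise_eps = 0,
                                   n_patients = 15L))
    vals <- unlist(lapply(g$cohort$records, function(p) {
      prev <- integer()
      vapply(seq_along(p$visits), function(t) {
        v <- p$visits[[t]]
        pred <- sort(unique(unlist(g$rule$diag_to_drugs[v$diag + 1L])))
        if (rho == 1) pred <- union(pred, prev)
        prev <<- v$drugs
        jaccard_sets(pred, v$drugs)
      }, numeric(1))
    }))
    expect_true(all(vals == 1))
  }
})
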