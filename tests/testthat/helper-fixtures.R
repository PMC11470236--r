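# small in-code fixtures shared across test files

raw_two_patients <- function() {
  list(
    list(patient_id = "a", visits = list(
      list(diag = c("D1", "D2"), proc = "P1", drugs = c("M1", "M2")),
      list(diag = "D1", proc = character(), drugs = "M3")
    )),
    list(patient_id = "b", visits = list(
      list(diag = "D2", proc = "P1", drugs = c("M2", "M3"))
    ))
  )
}

write_jsonl_fixture <- function(raw, path) {
  lines <- vapply(raw, function(p)
    as.character(jsonlite::toJSON(p, auto_unbox = TRUE)), character(1))
  writeLines(lines, path)
  path
}

tiny_spec <- function(...) {
  args <- modifyList(
    list(n_diag = 8L, n_proc = 5L, n_drug = 10L, n_patients = 12L,
         visit_count_range = c(2L, 4L), drugs_per_diag = 2L,
         persistence_rho = 0.5, noise_eps = 0.05,
         diags_per_visit_range = c(1L, 3L), procs_per_visit_range = c(0L, 2L),
         ddi_density = 0.2, seed = 7L),
    list(...))
  do.call(synthetic_spec, args)
}

tiny_model <- function(vocab, seed = 1L, ...) {
  cfg <- model_config(d = 6L, h_visit = 5L, h_seq = 4L, mlp_hidden = 7L,
                      dropout = 0, ...)
  list(config = cfg, params = init_params(cfg, vocab, seed = seed))
}

# independent scalar sigmoid for oracle recomputation
oracle_sigmoid <- function(x) 1 / (1 + exp(-x))
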