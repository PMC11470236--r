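write_tiny_yaml <- function(path, extra = character()) {
  writeLines(c(
    "master_seed: 123",
    "synthetic:",
    "  n_diag: 8",
    "  n_proc: 5",
    "  n_drug: 10",
    "  n_patients: 18",
    "  visit_count_range: [2, 3]",
    "  diags_per_visit_range: [1, 3]",
    "  procs_per_visit_range: [0, 2]",
    "model:",
    "  d: 6",
    "  h_visit: 5",
    "  h_seq: 4",
    "  mlp_hidden: 7",
    "  dropout: 0",
    "train:",
    "  epochs: 2",
    "  batch_size: 8",
    "protocol:",
    "  n_rounds: 2",
    extra), path)
  path
}

test_that("experiment configuration derives sub-seeds from the master seed", {
  path <- withr::local_tempfile(fileext = ".yaml")
  write_tiny_yaml(path)
  cfg <- experiment_config(path)
  expect_equal(cfg$master_seed, 123L)
  expect_equal(cfg$synthetic$seed, 123L)
  expect_equal(cfg$train$seed, 126L)
  expect_equal(cfg$protocol$seed, 127L)
  expect_equal(cfg$synthetic$n_patients, 18L)
  # command-line master seed overrides the file
  cfg2 <- experiment_config(path, master_seed = 7L)
  expect_equal(cfg2$synthetic$seed, 7L)
})

test_that("unknown config sections and keys are rejected", {
  p1 <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("master_seed: 1", "bogus:", "  x: 1"), p1)
  expect_error(experiment_config(p1), "unknown config section")
  p2 <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("model:", "  embedding: 12"), p2)
  expect_error(experiment_config(p2), "unknown key")
})

test_that("simulate writes four files and is reproducible under force", {
  path <- withr::local_tempfile(fileext = ".yaml")
  write_tiny_yaml(path)
  cfg <- experiment_config(path)
  out <- withr::local_tempdir()
  paths <- cmd_simulate(cfg, out)
  expect_true(all(file.exists(paths)))
  expect_setequal(basename(paths), c("cohort.jsonl", "ddi.tsv", "vocab.json",
                                     "rule.json"))
  before <- lapply(paths, readLines)
  expect_error(cmd_simulate(cfg, out), "exists")
  cmd_simulate(cfg, out, force = TRUE)
  expect_identical(lapply(paths, readLines), before)
})

test_that("an invalid simulation spec fails before writing anything", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("synthetic:", "  n_patients: 0"), path)
  out <- file.path(withr::local_tempdir(), "sim")
  expect_error(cmd_simulate(experiment_config(path), out))
  expect_false(file.exists(file.path(out, "cohort.jsonl")))
})

test_that("train and evaluate commands produce their artifacts and round-trip", {
  yml <- withr::local_tempfile(fileext = ".yaml")
  write_tiny_yaml(yml)
  cfg <- experiment_config(yml)
  out <- withr::local_tempdir()
  paths <- cmd_simulate(cfg, out)
  fit <- cmd_train(cfg, paths[["cohort"]], paths[["ddi"]], out,
                   vocab_path = paths[["vocab"]])
  expect_true(file.exists(file.path(out, "checkpoint.rds")))
  log <- read.csv(file.path(out, "training_log.csv"))
  expect_equal(nrow(log), 2L)
  expect_true(file.exists(file.path(out, "resolved_config.json")))
  report <- cmd_evaluate(cfg, file.path(out, "checkpoint.rds"),
                         paths[["cohort"]], paths[["ddi"]], out,
                         vocab_path = paths[["vocab"]], force = TRUE)
  expect_true(file.exists(file.path(out, "report.json")))
  rj <- jsonlite::read_json(file.path(out, "report.json"), simplifyVector = TRUE)
  expect_setequal(names(rj$mean), c("jaccard", "prauc", "f1", "ddi_rate",
                                    "avg_drugs"))
  # checkpoint round trip: reloaded parameters reproduce the report
  vocab <- read_vocab_json(paths[["vocab"]])
  ck <- load_checkpoint(file.path(out, "checkpoint.rds"), vocab)
  expect_equal(mgrn:::plain_params(ck$params), mgrn:::plain_params(fit$params))
  report2 <- cmd_evaluate(cfg, file.path(out, "checkpoint.rds"),
                          paths[["cohort"]], paths[["ddi"]], out,
                          vocab_path = paths[["vocab"]], force = TRUE)
  expect_equal(report2$mean, report$mean, tolerance = 1e-6)
})

test_that("missing input paths give a clear error", {
  cfg <- experiment_config(NULL)
  expect_error(cmd_train(cfg, "nope.jsonl", "nope.tsv", withr::local_tempdir()),
               "no such file")
})

test_that("ablate and robustness commands write comparable reports", {
  yml <- withr::local_tempfile(fileext = ".yaml")
  write_tiny_yaml(yml)
  cfg <- experiment_config(yml)
  out <- withr::local_tempdir()
  paths <- cmd_simulate(cfg, out)
  r_full <- cmd_ablate(cfg, "full", paths[["cohort"]], paths[["ddi"]], out,
                       vocab_path = paths[["vocab"]])
  r_nogdr <- cmd_ablate(cfg, "wo_gdr", paths[["cohort"]], paths[["ddi"]], out,
                        vocab_path = paths[["vocab"]])
  expect_true(file.exists(file.path(out, "report_full.json")))
  expect_true(file.exists(file.path(out, "report_wo_gdr.json")))
  # identical protocol: same rounds sampled for both variants
  expect_equal(r_full$rounds$round, r_nogdr$rounds$round)
  tab <- cmd_robustness(cfg, rates = c(0, 0.3), seeds = 1L,
                        paths[["cohort"]], paths[["ddi"]], out,
                        vocab_path = paths[["vocab"]])
  expect_equal(nrow(tab), 2L)
  expect_true(file.exists(file.path(out, "robustness.csv")))
})
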