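make_fixture <- function(seed = 3L, n_patients = 6L, ...) {
  g <- generate_cohort(tiny_spec(n_patients = n_patients, seed = seed, ...))
  tm <- tiny_model(g$cohort$vocab)
  list(g = g, cfg = tm$config, par = tm$params, Nm = g$cohort$vocab$n_drug)
}

test_that("visit embedding is a row lookup in canonical token order", {
  fx <- make_fixture()
  v <- new_visit(c(4L, 1L, 6L), c(0L, 2L), 0L)
  e <- embed_visit(v, fx$par)
  expect_equal(dim(e$De), c(3L, fx$cfg$d))
  expect_equal(dim(e$Pe), c(2L, fx$cfg$d))
  # canonical order is sorted: rows are embeddings of diag 1, 4, 6
  expect_equal(e$De[1, ], fx$par$Ed[2, ])
  expect_equal(e$De[2, ], fx$par$Ed[5, ])
  # shared codes produce identical rows across visits
  v2 <- new_visit(c(1L, 3L), integer(), 0L)
  e2 <- embed_visit(v2, fx$par)
  expect_equal(e2$De[1, ], e$De[1, ])
  # zeroed table embeds to zeros
  pz <- fx$par; pz$Ed[] <- 0
  expect_true(all(embed_visit(v, pz)$De == 0))
  expect_error(embed_visit(new_visit(99L, integer(), 0L), fx$par),
               "out of vocabulary range")
})

test_that("the visit-level view is token-order invariant and causal", {
  fx <- make_fixture()
  # same diagnosis set given in different orders canonicalizes identically
  va <- new_visit(c(5L, 2L, 0L), 1L, 0L)
  vb <- new_visit(c(0L, 5L, 2L), 1L, 0L)
  ra <- visit_level_view(list(va), fx$par)
  rb <- visit_level_view(list(vb), fx$par)
  expect_equal(ra$r_v[[1]], rb$r_v[[1]])
  # zero drug matrix zeroes the score
  pz <- fx$par; pz$m_v[] <- 0
  expect_true(all(visit_level_view(list(va), pz)$r_v[[1]] == 0))
  # causality: prefix recomputation reproduces the first entries exactly
  pt <- fx$g$cohort$records[[which.max(vapply(fx$g$cohort$records, function(p)
    length(p$visits), integer(1)))]]
  T_p <- length(pt$visits)
  full <- visit_level_view(pt$visits, fx$par)
  pre <- visit_level_view(pt$visits[seq_len(T_p - 1L)], fx$par)
  for (t in seq_len(T_p - 1L)) {
    expect_equal(pre$C_v[[t]], full$C_v[[t]])
    expect_equal(pre$r_v[[t]], full$r_v[[t]])
  }
})

test_that("the sequence-level view is a pure function of the visit", {
  fx <- make_fixture()
  v <- new_visit(c(2L, 4L), 1L, 0L)
  s1 <- sequence_level_view(v, fx$par)
  s2 <- sequence_level_view(new_visit(c(4L, 2L), 1L, 5L), fx$par)  # drugs differ
  expect_equal(s1$C_s, s2$C_s)
  expect_equal(s1$r_s, s2$r_s)
  pz <- fx$par; pz$m_s[] <- 0
  expect_true(all(sequence_level_view(v, pz)$r_s == 0))
  # degenerate single-token sequences are well-defined
  s3 <- sequence_level_view(new_visit(3L, 2L, 0L), fx$par)
  expect_length(s3$r_s, fx$Nm)
  expect_true(all(is.finite(s3$r_s)))
})

test_that("token-level per-token scores equal brute-force dot products", {
  fx <- make_fixture()
  v <- new_visit(c(0L, 3L, 7L), c(1L, 2L), 0L)
  tk <- token_level_view(v, fx$par)
  e <- embed_visit(v, fx$par)
  for (i in 1:3) for (j in seq_len(fx$Nm)) {
    expect_equal(tk$Rtd[i, j], sum(e$De[i, ] * fx$par$m_t[j, ]),
                 tolerance = 1e-12)
  }
  # single-token case is the plain matrix product row
  tk1 <- token_level_view(new_visit(3L, 1L, 0L), fx$par)
  expect_equal(dim(tk1$Rtd), c(1L, fx$Nm))
  expect_equal(drop(tk1$Rtd), drop(fx$par$Ed[4, ] %*% t(fx$par$m_t)))
  # zero drug matrix makes r_t independent of the visit content
  pz <- fx$par; pz$m_t[] <- 0
  ra <- token_level_view(new_visit(c(0L, 3L), 1L, 0L), pz)$r_t
  rb <- token_level_view(new_visit(c(5L, 6L), 2L, 0L), pz)$r_t
  expect_equal(ra, rb)
})

test_that("gating drug retrieval sums gated historical multi-hot vectors", {
  fx <- make_fixture()
  gate <- list(W1 = fx$par$gv_W1, b1 = fx$par$gv_b1,
               W2 = fx$par$gv_W2, b2 = fx$par$gv_b2)
  C <- rnorm(2 * fx$cfg$h_visit)
  # no history: empty sum
  expect_equal(gating_drug_retrieval(C, list(), list(), gate)$r,
               rep(0, fx$Nm))
  # retrieval weights pinned at one reproduce the historical drug vector
  gate_open <- gate; gate_open$W2[] <- 0; gate_open$b2[] <- log(exp(1) - 1)
  M1 <- multi_hot(c(1L, 4L), fx$Nm)
  out <- gating_drug_retrieval(C, list(C * 0.5), list(M1), gate_open)
  expect_equal(out$r, M1, tolerance = 1e-10)
  # two histories with arbitrary gates match an explicit double loop
  oracle_softplus <- function(x) log(1 + exp(x))
  set.seed(4)
  C1 <- rnorm(length(C)); C2 <- rnorm(length(C))
  M2 <- multi_hot(c(0L, 7L), fx$Nm)
  out2 <- gating_drug_retrieval(C, list(C1, C2), list(M1, M2), gate)
  for (j in seq_len(fx$Nm)) {
    g1 <- oracle_softplus(gate$W2[j, ] %*% tanh(gate$W1 %*% c(C, C1) + gate$b1[, 1]) +
                            gate$b2[j, 1])
    g2 <- oracle_softplus(gate$W2[j, ] %*% tanh(gate$W1 %*% c(C, C2) + gate$b1[, 1]) +
                            gate$b2[j, 1])
    expect_equal(out2$r[j], drop(g1) * M1[j] + drop(g2) * M2[j],
                 tolerance = 1e-10)
  }
  expect_error(gating_drug_retrieval(C, list(C1[-1]), list(M1), gate),
               "dimension mismatch")
})

test_that("aggregation applies the elementwise logistic to summed scores", {
  fx <- make_fixture()
  Nm <- fx$Nm
  zero <- numeric(Nm)
  # all-zero scores give probability one half everywhere
  agg0 <- aggregate_scores(zero, zero, zero, list(rnorm(2 * fx$cfg$h_visit)),
                           list(rnorm(4 * fx$cfg$h_seq)), list(),
                           fx$par, fx$cfg)
  pz <- fx$par
  expect_equal(agg0$o, rep(0.5, Nm))
  # gdr off: o = sigmoid(r_g)
  set.seed(12)
  rv <- rnorm(Nm); rs <- rnorm(Nm); rt <- rnorm(Nm)
  cfg_nogdr <- fx$cfg; cfg_nogdr$use_gdr <- FALSE
  agg1 <- aggregate_scores(rv, rs, rt, list(rnorm(2 * fx$cfg$h_visit)),
                           list(rnorm(4 * fx$cfg$h_seq)),
                           list(multi_hot(1L, Nm)), fx$par, cfg_nogdr)
  expect_equal(agg1$r_h, zero)
  expect_equal(agg1$o, oracle_sigmoid(rv + rs + rt))
  # scalar recomputation of the logistic, with history
  Cv <- lapply(1:2, function(i) rnorm(2 * fx$cfg$h_visit))
  Cs <- lapply(1:2, function(i) rnorm(4 * fx$cfg$h_seq))
  dh <- list(multi_hot(c(0L, 2L), Nm))
  agg2 <- aggregate_scores(rv, rs, rt, Cv, Cs, dh, fx$par, fx$cfg)
  expect_equal(agg2$r_g, rv + rs + rt)
  for (j in seq_len(Nm)) {
    expect_equal(agg2$o[j], 1 / (1 + exp(-(agg2$r_g[j] + agg2$r_h[j]))),
                 tolerance = 1e-12)
  }
})

test_that("thresholding selects exactly the probabilities at or above phi", {
  expect_equal(predict_drugs(c(0.9, 0.4, 0.6), 0.5), c(0L, 2L))
  expect_equal(predict_drugs(c(0.1, 0.2), 0.999), integer())
  set.seed(13)
  for (i in 1:100) {
    o <- runif(12)
    phi <- runif(1, 0.05, 0.95)
    expect_equal(length(predict_drugs(o, phi)), sum(o >= phi))
  }
})

test_that("the fused forward matches the composed reference operations", {
  fx <- make_fixture()
  for (variant in c("full", "wo_vst", "only_tkn", "wo_gdr")) {
    cfg <- ablation_config(fx$cfg, variant)
    for (pt in fx$g$cohort$records[1:4]) {
      fr <- forward_patient(pt, fx$par, cfg, fx$Nm, engine = "r")
      fc <- forward_patient(pt, fx$par, cfg, fx$Nm, engine = "cpp")
      for (f in c("o", "r_v", "r_s", "r_t", "r_h", "r_g")) {
        expect_lt(max(mapply(function(a, b) max(abs(a - b)), fr[[f]], fc[[f]])),
                  1e-10)
      }
    }
  }
})

test_that("per-visit probabilities stay in (0,1) and scores are additive", {
  fx <- make_fixture()
  for (pt in fx$g$cohort$records) {
    fw <- forward_patient(pt, fx$par, fx$cfg, fx$Nm)
    for (t in seq_along(fw$o)) {
      expect_true(all(fw$o[[t]] > 0 & fw$o[[t]] < 1))
      expect_equal(fw$r_g[[t]], fw$r_v[[t]] + fw$r_s[[t]] + fw$r_t[[t]],
                   tolerance = 1e-6)
    }
  }
})

test_that("a single-visit patient gets no historical drug score", {
  fx <- make_fixture()
  v <- fx$g$cohort$records[[1]]$visits[[1]]
  pt <- new_patient("solo", list(v))
  fw <- forward_patient(pt, fx$par, fx$cfg, fx$Nm)
  expect_equal(fw$r_h[[1]], rep(0, fx$Nm))
  expect_equal(fw$o[[1]], oracle_sigmoid(fw$r_g[[1]]))
})

test_that("batched and per-patient forwards agree", {
  fx <- make_fixture(n_patients = 8L)
  eng <- lapply(fx$g$cohort$records, mgrn:::patient_to_engine, n_drug = fx$Nm)
  batched <- mgrn:::cpp_forward_cohort(eng, mgrn:::plain_params(fx$par),
                                       mgrn:::engine_config(fx$cfg, fx$Nm))
  for (p in seq_along(eng)) {
    single <- forward_patient(fx$g$cohort$records[[p]], fx$par, fx$cfg, fx$Nm)
    for (t in seq_along(single$o)) {
      expect_lt(max(abs(batched[[p]]$o[, t] - single$o[[t]])), 1e-5)
    }
  }
})

test_that("outputs at visit t ignore current and future drugs (no leakage)", {
  fx <- make_fixture()
  pt <- fx$g$cohort$records[[which.max(vapply(fx$g$cohort$records, function(p)
    length(p$visits), integer(1)))]]
  T_p <- length(pt$visits)
  expect_gte(T_p, 3L)
  base <- forward_patient(pt, fx$par, fx$cfg, fx$Nm)
  t_probe <- T_p - 1L
  # mutate drugs at t_probe and every later visit
  mut <- pt
  for (t in t_probe:T_p) {
    mut$visits[[t]]$drugs <- sort(sample(0:(fx$Nm - 1L),
                                         length(mut$visits[[t]]$drugs)))
  }
  fwd_mut <- forward_patient(mut, fx$par, fx$cfg, fx$Nm)
  for (t in seq_len(t_probe)) {
    expect_equal(fwd_mut$o[[t]], base$o[[t]], tolerance = 1e-12)
  }
  # truncating the record reproduces the prefix exactly
  short <- new_patient(pt$patient_id, pt$visits[1:2])
  fwd_short <- forward_patient(short, fx$par, fx$cfg, fx$Nm)
  for (t in 1:2) expect_equal(fwd_short$o[[t]], base$o[[t]], tolerance = 1e-12)
})

test_that("every parameter receives gradient somewhere with all views on", {
  fx <- make_fixture()
  eng <- lapply(fx$g$cohort$records, mgrn:::patient_to_engine, n_drug = fx$Nm)
  lc <- mgrn:::loss_config_to_engine(loss_config(alpha = 0.2, beta = 0.5,
                                                 gamma = 0))
  res <- mgrn:::cpp_batch_grad(eng, mgrn:::plain_params(fx$par),
                               mgrn:::engine_config(fx$cfg, fx$Nm),
                               lc, unclass(fx$g$ddi), 1L, FALSE)
  for (nm in names(res$grads)) {
    expect_gt(max(abs(res$grads[[nm]])), 0, label = paste("grad of", nm))
  }
})

test_that("disabled views receive exactly zero gradient", {
  fx <- make_fixture()
  eng <- lapply(fx$g$cohort$records, mgrn:::patient_to_engine, n_drug = fx$Nm)
  lc <- mgrn:::loss_config_to_engine(loss_config())
  exclusive <- list(
    wo_vst = c("vd_W", "vd_U", "vd_b", "vp_W", "vp_U", "vp_b", "m_v",
               "gv_W1", "gv_b1", "gv_W2", "gv_b2"),
    wo_seq = c("sdf_W", "sdf_U", "sdf_b", "sdb_W", "sdb_U", "sdb_b",
               "spf_W", "spf_U", "spf_b", "spb_W", "spb_U", "spb_b", "m_s",
               "gs_W1", "gs_b1", "gs_W2", "gs_b2"),
    wo_tkn = c("tdf_W", "tdf_U", "tdf_b", "tdb_W", "tdb_U", "tdb_b",
               "tpf_W", "tpf_U", "tpf_b", "tpb_W", "tpb_U", "tpb_b", "m_t"),
    wo_gdr = c("gv_W1", "gv_b1", "gv_W2", "gv_b2",
               "gs_W1", "gs_b1", "gs_W2", "gs_b2")
  )
  for (variant in names(exclusive)) {
    cfg <- ablation_config(fx$cfg, variant)
    res <- mgrn:::cpp_batch_grad(eng, mgrn:::plain_params(fx$par),
                                 mgrn:::engine_config(cfg, fx$Nm),
                                 lc, unclass(fx$g$ddi), 1L, FALSE)
    for (nm in exclusive[[variant]]) {
      expect_equal(max(abs(res$grads[[nm]])), 0,
                   label = paste(variant, "grad of", nm))
    }
  }
})

test_that("engine gradients match central finite differences", {
  fx <- make_fixture(n_patients = 3L)
  eng <- lapply(fx$g$cohort$records[1:3], mgrn:::patient_to_engine,
                n_drug = fx$Nm)
  ec <- mgrn:::engine_config(fx$cfg, fx$Nm)
  lc <- mgrn:::loss_config_to_engine(loss_config(alpha = 0.3, beta = 0.5,
                                                 gamma = 0))
  ddi <- unclass(fx$g$ddi)
  pp <- mgrn:::plain_params(fx$par)
  res <- mgrn:::cpp_batch_grad(eng, pp, ec, lc, ddi, 1L, FALSE)
  loss_at <- function(p) mgrn:::cpp_batch_grad(eng, p, ec, lc, ddi, 1L, FALSE)$total
  set.seed(17)
  h <- 1e-5
  for (nm in names(pp)) {
    idx <- sample(length(pp[[nm]]), min(3L, length(pp[[nm]])))
    for (i in idx) {
      p1 <- pp; p1[[nm]][i] <- p1[[nm]][i] + h
      p2 <- pp; p2[[nm]][i] <- p2[[nm]][i] - h
      g_num <- (loss_at(p1) - loss_at(p2)) / (2 * h)
      expect_equal(res$grads[[nm]][i], g_num, tolerance = 1e-3,
                   label = sprintf("analytic grad %s[%d]", nm, i))
    }
  }
})

test_that("checkpoints round-trip and refuse mismatched vocabularies", {
  fx <- make_fixture()
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(fx$par, fx$cfg, fx$g$cohort$vocab, path)
  ck <- load_checkpoint(path, fx$g$cohort$vocab)
  expect_equal(mgrn:::plain_params(ck$params), mgrn:::plain_params(fx$par))
  expect_equal(unclass(ck$config), unclass(fx$cfg))
  other <- generate_cohort(tiny_spec(n_diag = 9L))$cohort$vocab
  expect_error(load_checkpoint(path, other), "different vocabulary")
})
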