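# mgrn

Medication recommendation from longitudinal electronic health records with
a multi-view gating retrieval network (MGRN), plus a synthetic-cohort
simulator so the entire pipeline — simulation, training, evaluation,
ablations, robustness sweeps — runs end to end with no access-restricted
clinical data.

## Who this is for

Researchers working on EHR-based drug recommendation: multi-label
prediction of the drug set $M_t$ of a hospital visit from the visit's
diagnosis set $D_t$ and procedure set $P_t$, the earlier visits
$\{D_i,P_i\}_{i<t}$, and the patient's drug history $\{M_i\}_{i<t}$, under
a drug–drug interaction (DDI) safety constraint.

## The model

Diagnosis and procedure tokens are embedded in $\mathbb{R}^d$ and matched
against learned drug representations at three granularities, each giving a
score vector over the $N_m$ drugs for the current visit:

* **visit level** — per-visit embedding sums, encoded causally across the
  visit sequence by GRUs: $r_v^t = m_v\,C_v^t$;
* **sequence level** — the current visit's token sequences, encoded by
  bidirectional GRUs: $r_s^t = m_s\,C_s^t$;
* **token level** — each token matched against the drug matrix first
  ($R_{td}=D_e m_t^\top$), the score rows fused by bidirectional GRUs.

A **gating drug retrieval** module concatenates the current and each
historical patient representation into current–history visit pairs, maps
each pair through a gating MLP to non-negative per-drug retrieval weights
$G_i^t$, and scores the medication history by the gated sum
$r_h^t=\sum_{i<t}G_i^t\odot M_i$.  Drug probabilities are
$o_t=\sigma(r_v^t+r_s^t+r_t^t+r_h^t)$, thresholded at $\phi=0.5$.

Training minimizes $L_{bce}+\alpha L_{mlh}+w\,\beta L_{addi}$: binary
cross-entropy, a multi-label hinge on the pre-sigmoid scores, and a DDI
penalty whose weight $w$ ramps up only while the recommendations' DDI rate
exceeds an acceptable level.  See the methods vignette
(`vignettes/medication-recommendation.Rmd`) for every design decision.

## Worked example

```r
library(mgrn)
spec <- synthetic_spec()          # 60/30/40 codes, 600 patients, 2-5 visits
sim <- generate_cohort(spec)      # cohort + ground-truth rule + DDI graph
h <- history_overlap_histogram(sim$cohort)
mean(h$values)                    # 0.65: most drugs repeat from the history

splits <- split_cohort(sim$cohort, seed = 11)
fit <- train(init_params(model_config(), sim$cohort$vocab, seed = 1),
             model_config(), loss_config(), train_config(seed = 1),
             splits$train, splits$val, sim$ddi)
report <- evaluate(fit$params, model_config(), splits$test, sim$ddi,
                   eval_protocol(seed = 99))
print(report)
```

```
<mgrn_report> 100 patients, 5 rounds
  jaccard   0.7312 +/- 0.0043
  prauc     0.8675 +/- 0.0033
  f1        0.8371 +/- 0.0028
  ddi_rate  0.0863 +/- 0.0030
  avg_drugs 9.3388 +/- 0.1395
```

Jaccard/PRAUC/F1 compare the recommended drug set (and its probability
ranking) against the visit's true prescription, averaged per visit over 5
bootstrap rounds of 80% of test patients; `ddi_rate` is the fraction of
recommended drug pairs that interact (the simulator's ground truth sits
near 0.089 here); `avg_drugs` is the mean recommendation size.  A
clairvoyant predictor that knows the simulator's prescribing rule and
copies the previous visit tops out near 0.79 Jaccard under the default
noise, so 0.73 means the model has learned both the diagnosis-to-drug
mapping and the history-reuse structure.  Stratifying by visit position
(`stratify_by_visit_index()`) shows the history paying off: Jaccard rises
from 0.695 at the first visit (no history) to ~0.75 from the third visit
on.

## Command line

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "mgrn.R", package = "mgrn"))') \
    simulate --config experiment.yaml --out runs/sim
# then: train | evaluate | ablate | robustness  (see --help)
```

Each command logs its fully resolved configuration (with derived seeds) to
the output directory, so any run is reproducible from that log alone.

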