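---
title: "Multi-view gating retrieval for medication recommendation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-view gating retrieval for medication recommendation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A longitudinal electronic health record presents a patient as an ordered
sequence of visits; each visit carries a set of diagnosis codes $D_t$, a set
of procedure codes $P_t$, and the set of drugs $M_t$ prescribed at that
visit.  Medication recommendation is the multi-label prediction of $M_t$
from the current diagnoses and procedures, the earlier visits
$\{D_i, P_i\}_{i<t}$, and — crucially — the earlier prescriptions
$\{M_i\}_{i<t}$.  Two properties of real prescribing drive the design:

* **Chronic reuse.** Many conditions are long-lived and so are their
  treatments; a large fraction of a visit's drugs already appear in the
  patient's history.  A model that only maps diagnoses to drugs ignores
  the single most informative signal available at visit $t \ge 2$.
* **Safety.** Some drug pairs interact adversely.  A recommender should
  trade a little coverage for a recommendation set whose drug-drug
  interaction (DDI) rate stays near what clinicians themselves produce.

`mgrn` implements a multi-view gating retrieval network (MGRN) for this
task, together with a synthetic cohort simulator, so the whole pipeline is
testable without credentialed clinical data.

## The model

Let $N_d$, $N_p$, $N_m$ be the numbers of distinct diagnosis, procedure and
drug codes.  Tokens are embedded in $\mathbb{R}^d$ via two lookup tables.
Three *views* produce drug-matching score vectors in $\mathbb{R}^{N_m}$ for
the current visit, each by matching a patient representation against its
own learned drug representation matrix:

* **Visit level.** Each visit's token embeddings are summed into one
  feature vector per stream ($Dr_t$, $Pr_t$); two unidirectional GRUs run
  across the visit sequence, and their hidden states are concatenated into
  $C_v^t$.  The score is $r_v^t = m_v C_v^t$ with $m_v \in
  \mathbb{R}^{N_m \times 2h_v}$.  Because the encoders are causal, $C_v^t$
  depends only on visits $1..t$.
* **Sequence level.** The current visit's diagnosis and procedure token
  sequences are each encoded by a bidirectional GRU; the concatenated
  final forward/backward states give $C_s^t$, and $r_s^t = m_s C_s^t$.
* **Token level.** Every token embedding is matched against the drug
  matrix first ($R_{td} = D_e m_t^\top$, one score row per token), and the
  row sequences are fused by bidirectional GRUs of hidden size $N_m$; the
  diagnosis and procedure summaries are added to give $r_t^t$.  This
  early interaction preserves per-token drug affinity that the pooled
  views blur.

**Gating drug retrieval (GDR).** For every historical visit $i < t$ the
current and historical patient representations are concatenated into a
current-history visit pair (CHVP).  A two-layer MLP (shared across history
positions) maps each CHVP to a vector of per-drug retrieval weights
$G_i^t$, and the historical score is the gated sum
$r_h^t=\sum_{i<t} G_i^t \odot M_i$ over the historical multi-hot drug
vectors.  GDR is applied under both the visit-level and the
sequence-level representations, with separate MLPs, and the two results
are added.  Scores aggregate as

$$o_t=\sigma\!\left(r_v^t+r_s^t+r_t^t+r_h^t\right),$$

and drug $j$ is recommended iff $o_t[j] \ge \phi$ (default $\phi = 0.5$).

### Why the retrieval weights are softplus, not logistic

The gating unit's output activation is a genuinely open design point: the
formulation only says the weights come from an MLP.  A logistic output
("gate in $(0,1)$") looks natural but has a structural consequence: the
maximal historical boost for a drug seen in one past visit is bounded by
the number of views ($\approx 2$ logits).  A well-calibrated model puts a
never-before-seen drug near the noise base rate — a logit of about $-3$
under the default simulator — so a bounded gate *cannot* lift a
once-prescribed drug above threshold without miscalibrating every
first-visit prediction.  We measured exactly this failure: with logistic
gates the retrieval weights saturated near 1 while recall on
history-only drugs stalled at 0.57.  The package therefore uses a
softplus output: weights stay non-negative (retrieval semantics) but are
unbounded above, and recall on history-only drugs is no longer capped.

### Other resolved design points

* **Recurrent cell.** "RNN" is read as a single-layer GRU everywhere, the
  standard choice in this model family.
* **Causality of the visit-level encoders.** They are unidirectional:
  visit $t$'s representation must not see future visits, otherwise the
  per-visit predictions leak.
* **Bidirectional summaries.** Sequence-level encoders summarize as the
  concatenation of the final forward and backward states.  The
  token-level fusion must output a length-$N_m$ vector without an extra
  projection, so there the two directions' final states are summed
  elementwise.
* **Token order.** Code sets are mathematically unordered; all
  order-sensitive encoders consume tokens in the canonical
  sorted-by-code order, which makes the model a deterministic function
  of its inputs.  The visit-level view is order-invariant by
  construction (it sums embeddings).
* **Threshold direction.** Recommendation is $o \ge \phi$; the branch
  printed ambiguously in the source formulation is resolved in the only
  direction that makes larger probability mean "recommend".

## The objective

Training minimizes, per visit,

$$L = L_{bce} + \alpha\,L_{mlh} + w\,\beta\,L_{addi},$$

* $L_{bce}$: mean binary cross-entropy of $o$ against the multi-hot truth
  (probabilities clipped at $\varepsilon = 10^{-8}$ before logs).
* $L_{mlh}$: multi-label hinge on the *pre-sigmoid* scores, averaged over
  (positive, negative) pairs: $\max(0, 1-(s_{pos}-s_{neg}))$.  Margins are
  scale-meaningful on the score scale, not after squashing.
* $L_{addi}$: expected co-prescription mass on interacting pairs,
  $\sum_{i<j}A_{ij}o_io_j / \max(1, \sum_{i<j}A_{ij})$.
* $w = $ `adaptive_weight(batch DDI rate, gamma, kappa)`: a piecewise
  linear ramp that is 0 while the thresholded recommendations' DDI rate is
  at or below the acceptable level `gamma` (default 0.06) and reaches 1 at
  `gamma + kappa` (default ramp width 0.05).  The exact adaptive mechanism
  of the original is not public; this surrogate reproduces its qualitative
  behaviour — the safety penalty acts only while recommendations are
  unsafe — and is isolated in one function so it can be swapped.

Defaults $\alpha = 0.05$, $\beta = 0.1$ keep the auxiliary terms an order
of magnitude below the cross-entropy, which dominates calibration.

## Training

Mini-batch Adam (learning rate $3\times10^{-3}$, batch 16 patients,
global-norm gradient clipping at 5) with early stopping on validation
Jaccard (patience 10) and best-validation checkpointing; an optional
decoupled weight decay is off by default (it measured as a no-op at this
scale).  Dropout 0.3 is applied to token embeddings during training.  The
learning rate and hidden sizes ($h_v = h_s = 32$, gating MLP width 64,
$d = 64$) were sized once against the default simulator: with ~25
gradient steps per epoch, a smaller learning rate fails to plateau within
the 30-epoch budget, and doubling the hidden sizes only increases the
train/test gap at a 60/30/40-code vocabulary.  Everything — shuffling,
dropout, initialization — is driven by explicit seeds, and the whole
simulate/train/evaluate pipeline is bit-reproducible from one master seed.

The numerical engine (forward pass and analytic backpropagation through
all six GRUs, the gating MLPs and the joint loss) is RcppArmadillo; the
exported R view operations are an independent reference composition, and
the test suite checks the two agree to $10^{-10}$ and that the analytic
gradients match central finite differences.

## The synthetic cohort

`synthetic_spec()` fixes the simulator's conditions; the defaults are the
package's standard study conditions (60 diagnoses, 30 procedures, 40
drugs, 600 patients, 2-5 visits).

* **Prescribing rule.** Each diagnosis maps to a fixed set of
  `drugs_per_diag = 2` drugs — the learnable diagnosis-to-drug signal.
* **Chronic core.** Half of a patient's first-visit diagnoses recur at
  every visit, creating the cross-visit correlation that makes history
  informative.
* **Persistence.** Each drug prescribed at visit $t-1$ recurs at $t$ with
  probability `persistence_rho = 0.9` — the chronic-medication structure
  (most of a visit's drugs have appeared before, matching the high
  current-vs-history Jaccard overlap of real cohorts, here ~0.65).
* **Noise.** Every drug coordinate flips independently with probability
  `noise_eps = 0.05` (symmetric add/remove), keeping label marginals
  controllable by one parameter and bounding attainable accuracy: a
  clairvoyant predictor that knows the rule and copies the previous
  visit's drugs reaches a Jaccard of about 0.79 under the defaults.
* **DDI graph.** Each unordered drug pair interacts independently with
  probability `ddi_density = 0.1`.
* **Streams.** Structure, persistence, noise, and DDI edges draw from
  separate per-patient random streams with fixed-size coin blocks, so
  changing one parameter never reshuffles the others at a fixed seed.

What it does *not* emulate: real code semantics (ICD/ATC hierarchies),
demographic covariates, visit-timing gaps, co-prescription correlations
beyond persistence, or the heavy-tailed code frequencies of hospital
data.  Passing tests on this simulator demonstrates that the
architecture, objective, and protocols behave as designed — not clinical
performance.

## Evaluation

Per visit: Jaccard, precision, recall, F1, average precision of the
probability ranking (PRAUC; step interpolation, per-visit then averaged —
the per-visit convention, not macro-over-drugs), the DDI rate of the
predicted set (0 when fewer than two drugs are predicted), and the
predicted-set size.  `evaluate()` runs the multi-round protocol: 5 rounds,
each resampling 80% of test patients without replacement, reported as
mean ± sd across rounds.  `stratify_by_visit_index()` buckets metrics by
visit position (1..5, later visits pooled as "5+"); history-aware
components can only act from position 2 on.  `run_ablation()` retrains
named variants (drop one view, keep one view, or disable GDR) under
identical seeds; in keep-one variants GDR runs only under the kept view's
representation (the token-level view supplies none).  `robustness_sweep()`
deletes a fraction of *training patients* (whole records, preserving visit
sequences), retrains, and evaluates on the untouched test set.

Test-suite problem sizes: unit tests use 8-12-code vocabularies and a
dozen patients; the end-to-end checks train the default 600-patient
conditions for up to 30 epochs across 3 seeds.

## Limitations

* Single-layer GRU encoders and a 2-layer gating MLP; no drug-structure,
  EHR-graph or language-model components.
* The adaptive DDI weight is a package-designed surrogate, not the
  original's exact formula.
* The retrieval weights score *drugs the patient has already received*;
  cold-start accuracy rests entirely on the diagnosis/procedure views.
* Thresholding at a fixed $\phi$ is global; no per-drug calibration.
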