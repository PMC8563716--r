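---
title: "Simulating rule-plus-exception category learning in a hippocampal-subfield network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating rule-plus-exception category learning in a hippocampal-subfield network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(hipporpe)
```

## The scientific problem

In a rule-plus-exception (RPE) category structure, most stimuli follow a
simple rule while a minority violate it.  The Shepard-Hovland-Jenkins
Type III problem used here has three binary diagnostic feature dimensions,
one binary nondiagnostic dimension, and two categories of five flower
stimuli each: two prototypes (one per value of the nondiagnostic disc
colour), two rule-followers (one diagnostic dimension away from their
prototype) and one exception (two diagnostic dimensions away from its own
prototype and only one away from the *opposite* prototype).  Exceptions
can therefore only be categorized correctly by remembering them as
specific items — the computation classically attributed to the
hippocampus, with pattern separation in the trisynaptic pathway
(EC→DG→CA3→CA1) storing distinct traces and the monosynaptic pathway
(EC↔CA1) extracting shared structure.

The manipulation of interest is *when* the exceptions are introduced.
In the early condition they appear from the first learning block; in the
delayed condition they are withheld until trial 49 of 144.  The question
is whether delaying the exceptions — letting the category rule consolidate
before it is violated — improves exception learning, and whether a
hippocampal circuit model reproduces that benefit and its puzzling
asymmetry between the two exceptions.

## The stimulus space and its asymmetry

`stimulus_set()` builds the canonical Type III assignment
(A = {000 P, 001 R, 010 R, 110 E}; B = {111 P, 101 R, 011 R, 100 E} on
the diagnostic triple).  Stimuli are padded into 10-unit binary vectors,
one one-hot pair per dimension (0 ↦ "10", 1 ↦ "01"), so the category-A
prototype with all-zero features is `1010101010` and every stimulus
activates exactly 5 of 10 input units.

The exact nondiagnostic (d4) assignments of the non-prototype stimuli are
only constrained qualitatively by the source experiment, so the default
map is chosen to realize the asymmetry the behavioural data demand: the
category-A exception (EA) shares its disc colour with its diagnostically
nearest own-category neighbours (RA2 at overall distance 1, plus the
d4-matched prototype), whereas the category-B exception (EB) does not —
its nearest own-category member is two features away.  EA is therefore
"less exceptional" than EB, and the package validates this with an
exhaustive distance check.  The assignment is config-overridable.

## The network

`hc_params()` / `init_network()` define a rate-coded autoencoder with
layers EC_in (10), DG (400, k = 4), CA3 (80, k = 6), CA1 (100, k = 25)
and EC_out (10, k = 5).  The projection graph is fixed: EC_in→DG,
EC_in→CA3, DG→CA3, CA3→CA1 (trisynaptic), EC_in→CA1 and EC_out→CA1
(monosynaptic), CA1→EC_out (output) and EC_out→EC_in (big-loop
recurrence, a fixed one-to-one feedback from the deep to the superficial
entorhinal code).  Within a layer, inhibition is k-winners-take-all: each
cycle the inhibition threshold is set midway between the k-th and
(k+1)-th largest net input and activations follow a logistic of the
suprathreshold drive, with units receiving no positive drive staying
silent.  Net inputs are normalized by the expected activity of the
sending layer so that pathway strengths are comparable.

Tunable parameters that matter, with defaults and rationale:

* **Layer sizes and k** — order-of-magnitude match to published
  hippocampal circuit models; they fix the sparsity gradient
  DG (1%) < CA3 (7.5%) < CA1 (25%), which is validated at construction
  and empirically on every snapshot.
* **Gains** (`gain = 100` hidden, `gain_ec = 8`) — the sparse layers need
  a steep activation function for the winner-count contract (realized
  active counts within ~10% of k); the entorhinal layers use a shallow
  gain so that the category readout stays graded rather than saturating,
  which is what makes the Luce-choice accuracy informative about the
  *strength* of the network's category belief.
* **Learning rates** (`lr_tsp = 0.08` > `lr_out = 0.02` ≥ `lr_msp = 0.03`
  on the feedback/input side; the constructor enforces TSP > MSP
  strictly) — the trisynaptic pathway learns fast (episodic, pattern
  separated), the monosynaptic pathway slowly (statistical). The absolute
  scale was set so that 144 trials produce strong but not saturated
  learning: prototypes ≈ 0.86, rule-followers ≈ 0.82, exceptions ≈ 0.7
  median end-of-learning accuracy, reproducing the qualitative difficulty
  ordering.  Much higher rates memorize everything (all conditions at
  ceiling, no sequence effects); much lower rates prevent the rule from
  consolidating, which inverts the delayed-exception benefit.
* **Phases** — 80 settling cycles per trial, 60 expectation (input
  clamped, output free to predict) + 20 outcome (output also clamped).
  Learning is two-phase contrastive: each projection moves by
  `lr × (outcome coproduct − expectation coproduct)` plus a small
  postsynaptically gated Hebbian term (`hebb = 0.05`), clipped to [0,1].
  This is a documented stand-in for the original simulator's theta-phase
  error-driven rule; it preserves the mechanisms the analyses depend on —
  mismatch-proportional updates, fast sparse TSP storage, slow dense MSP
  generalization — without attempting numerical parity.
* **Test cueing** — at test each stimulus is presented with its 8 feature
  units active and both category units at zero, so EC_out must
  pattern-complete the category.  Whether the source model clamped or
  freed those units is an open question; the default clamps them to zero
  (`test_category_free = FALSE` frees them under big-loop drive instead).
  Clamping was chosen because big-loop amplification otherwise saturates
  the readout and masks the sequence effects.

`run_batches()` runs independently initialized simulations ("batches"):
batch *b* uses seed `base_seed + b` for both the weight draw and the
sequence shuffle, trains through the condition's 144 trials, and probes
all 10 stimuli at the condition's checkpoints (early: 12, 36, 48, 72, 96,
120, 144; delayed: 24, 48, 60, 72, 84, 96, 120, 144 — denser around the
introduction of exceptions).  The reference scale is 500 batches per
condition.

## Readout and analyses

**Accuracy** is the Luce-choice ratio of cosine similarities between the
two category units of EC_out and the one-hot target versus nontarget
codes; for nonnegative readouts this equals `x_t / (x_t + x_nt)`.  A
fully silent readout is an error by default (it usually indicates an
untrained or broken network); probing code opts into 0.5.

**Representational similarity** per subfield is the 10×10 Pearson
correlation matrix of settled activation vectors, with condition
contrasts taken as elementwise early − delayed differences,
cross-category structure summarized by the mean of the 25 intercategory
cells, and each exception's standing summarized by the category
representational difference
`CRD = ((1+ρ_intra) − (1+ρ_inter)) / ((1+ρ_intra) + (1+ρ_inter))`
(ρ_intra excludes the self-correlation; constant activation vectors are
flagged `NA` and excluded from means).  Per-batch scalars feed two-sided
Wilcoxon rank-sum comparisons across conditions; displays use
ensemble-mean matrices.

**Trajectories**: each checkpoint's ensemble-mean similarity matrix is
converted to dissimilarities (`d = 1 − r`, bounded and monotone; the
chord transform was evaluated and embeds worse), Sammon-mapped to 2-D
(classical-scaling initialization, then `MASS::sammon` descent — making
the map deterministic), and Procrustes-aligned (translation, isotropic
scale, rotation, reflection; `vegan::procrustes`) to the end-of-learning
configuration.  Displacements of the exceptions are measured from the
probe taken at the introduction boundary (trial 48 in the delayed
condition) to trial 144: the representational jump caused by an
exception's first appearances happens within a dozen trials, so a later
reference point would miss most of it.

**Mixed models**: end-of-learning accuracies are analysed with linear
mixed models (`lme4::lmer`) — stimulus type × condition (or exception
category × condition) as fixed effects and simulation batch as a random
intercept.  The response is kept on the accuracy scale because the
quantities of interest are accuracy differences; an empirical-logit
sensitivity fit is available behind a flag.  Condition contrasts within
type and the type-difference-by-condition interactions are computed with
`emmeans`.  Behavioural-format tables are analysed with binomial logit
GLMEs (participant random intercept), in base, repetition,
exceptions-by-category and cell-means parameterizations.

**Preprocessing** of behavioural tables excludes participants that (a)
have at least one block in which no stimulus type exceeds 0.75 accuracy
(that clause of the published rule is ambiguous; this reading — "some
block with no type above criterion" — is the implemented one) or (b) have
more than 20% of reaction times outside [0.15 s, 2 s]; remaining
out-of-range trials are dropped, and learning-phase trials beyond the
first 36 repetitions of a type are flagged out of the learning analyses
(flagged rather than deleted so preprocessing is idempotent).

## The synthetic behavioural generator

`generate_participants()` emulates the deposited trial-table layout:
each simulated participant works through their condition's 144-trial
learning sequence plus a 48-trial test block; responses are Bernoulli
with logit = cell intercept (role × condition) + cell slope × repetition
+ participant random intercept; reaction times are truncated log-normal
and exist purely to exercise the exclusion rules (they are never
analysed).  The default ground truth mimics the observed qualitative
pattern (prototype > rule-follower > exception; steeper learning for
delayed exceptions) and is illustrative, not fitted.  What passing the
recovery tests shows is that the preprocessing and fitting stages are
correct for data generated under the model the fits assume; it does not
validate the logistic-linear form against real behaviour, nor does the
generator model lapses, fatigue, RT-accuracy coupling or item-level
(rather than type-level) effects.

The parameter-recovery harness fits the raw generated tables.  The
exclusion rules are deliberately not applied there: with exception cells
near chance, the block-accuracy rule selects on the participant random
intercept and biases the recovered effects — a real property of such
exclusion rules, but not the round-trip being tested.  The rules
themselves are tested exactly with planted violators.

## Numerical choices and degenerate inputs

* Settling uses damped updates (`dt = 0.4`) in Gauss-Seidel order; 80
  cycles reach a fixed point to < 1e-4.  Non-finite activations abort
  with a divergence error.
* Weight updates are clipped to [0,1]; an all-zero learning-rate schedule
  is allowed for null-update diagnostics.
* Zero off-diagonal dissimilarities (identical representations) are
  jittered deterministically or rejected, per configuration; degenerate
  (all-coincident) Procrustes references are rejected; all-tied rank-sum
  samples return p = 1 with a warning; complete separation in a GLME cell
  produces an explicit warning.
* Ensemble statistics always aggregate per-batch scalars; bootstrap
  summaries (median of resampled means, percentile 95% intervals, 10,000
  resamples by default) are seeded.

## Problem sizes used by the test-suite and acceptance script

The packaged checks run 500 batches per condition for reference
quantities and reuse the leading 50 batches (batches are independently
seeded, so a prefix is itself a valid smaller ensemble) for the
directional checks; parameter recovery uses 200 synthetic replicates at
40 participants per condition with `nAGQ = 0` fits.  These sizes were
chosen to keep full runs in the minutes range on a single core while
leaving Monte-Carlo error well below the effect sizes being tested.

## Known limitations

* The learning rule is a documented stand-in.  Directional phenomena
  (the delayed-exception benefit and its EB-specificity, early-condition
  category blurring in CA1, the sparsity gradient, the EB trajectory
  shift) replicate; absolute similarity levels do not — this model's
  codes are more strongly pattern-separated, so CA1 correlations sit near
  zero rather than around 0.6-0.7, and the near-flat similarity
  structure embeds in 2-D with Sammon stress around 0.07 rather than
  under 0.035.  Both are reported honestly by the acceptance checks.
* The paper's *negative* condition effect for EA does not emerge: here
  EA's loss of integration under delay is offset by the recency of the
  denser late exception training, leaving its condition effect at zero
  within batch noise.
* No reaction-time modelling, no recognition-memory task, no lesion
  simulations (the CA3→CA1 and EC_in→CA1 strength scales are exposed but
  untested beyond their intact defaults), no spiking dynamics.
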