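---
title: "Auditing hallucinations in tabular synthetic health data: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing hallucinations in tabular synthetic health data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(sdgaudit)
```

## The problem

Generative models for tabular health data learn the joint distribution of a
training table and sample fully synthetic records from it. A synthetic record
can be *faithful* (close to the training data), *diverse* (unlike the training
data but present in the underlying population), or *hallucinated*: a record
that does not exist in the population at all, whether implausible on its face
or plausible but simply absent. `sdgaudit` operationalizes this factuality
notion at record level and asks two quantitative questions:

1. Does the **hallucination rate** (HR) of a synthesizer grow with the
   structural complexity of its training data?
2. Does a higher HR degrade the **downstream prognostic utility** of the
   synthetic data, measured as train-synthetic-test-real (TSTR) AUROC against
   a fixed real holdout?

Because the individual-level health registries this methodology targets are
access-restricted, the package ships a seeded population simulator that
reproduces their *structure* — categorical-dominant tables with a binary
outcome, a small core variable set, a large adjunct pool including long-tailed
high-cardinality codes, missing values, and class imbalance — so the entire
pipeline is testable end to end.

## Pipeline model

For each simulated reference population `R`:

1. **Variants.** Column subsets `P = core ∪ (sampled adjunct subset) ∪
   outcome` are built; all records are kept, so every variant shares the same
   row multiset. The core-only variant is always included.
2. **Split.** One disjoint train/holdout record split is drawn per population
   and reused by every variant, so utility comparisons across variants are
   not confounded by the split and the holdout never reaches any generator.
3. **Synthesis.** Each generator family is fitted on the variant's training
   rows and sampled `k` times (study convention: `k = 10`, 10,000 rows per
   replicate; replicate `r` uses a sub-seed derived from `(seed, r)`).
4. **Audit.** Hallucinated records are the antijoin `S \ P` of each
   canonicalized synthetic table against the canonicalized variant;
   `HR = |HA| / |S|`, averaged over replicates.
5. **Utility and effects.** TSTR/TRTR AUROC per learner, then two
   random-intercept mixed models: a binomial-logit GLMM of hallucinated
   counts on complexity, and a linear mixed model of TSTR on HR (percentage
   points), both with the population as the random effect.

## Record matching

Exact matching needs a canonical scale, fixed once per variant:

* **Numerics** are discretized into equal-width bins (default `n_bins = 10`)
  whose edges are computed on the variant's full record set and applied
  unchanged to synthetic tables. Bins are left-closed/right-open with the
  last bin closed; values outside the variant's range fall into dedicated
  out-of-range bins. More bins make detection more sensitive; fewer are more
  tolerant — the count is therefore a first-class configuration knob, and
  tests assert that HR is monotone non-decreasing in it.
* **Missing values** map to a sentinel token and match only other missing
  values. This is the convention under which an antijoin is well defined;
  it also means a missing value contributes one extra level to cardinality.
* **All columns of the variant participate**, outcome included: a record is
  a full row.

`hallucinated_records()` implements the antijoin via canonical row keys;
`hamming_oracle()` computes pairwise Hamming distances directly and must
agree exactly (it refuses instances beyond 10^4 x 10^4 comparisons). The
equivalence is tested on batches of random fixtures up to 1,000 x 1,000 rows.

## Complexity

Complexity is `log(sum of per-variable cardinalities)` — dimensionality adds
terms, cardinality sets their size. Cardinality is the number of observed
canonical levels (bins for numerics, plus one for missingness), measured on
the variant's full record set (configurable to training scope). The log base
is natural by default and configurable: the base only rescales the scale of
the fixed effect, leaving monotone relationships, test outcomes, and
mixed-model signs unchanged.

## Generator families

Two families are implemented from scratch; anything else (GAN-, VAE-,
flow-based synthesizers) enters through `register_plugin()` under the same
fit/sample contract and is validated at sampling time.

Both built-ins synthesize on the canonical categorical scale (numerics
binned, missing as a level) and back-transform numeric draws uniformly
within the sampled bin. This aligns generation with the matching convention:
the generators and the auditor see the same alphabet.

**Sequential decision trees.** The first variable in the visit order is
sampled from its empirical marginal; each later variable from a CART
(minimum leaf size 20, no complexity penalty, depth 30) on all previously
visited variables, drawing from the reached leaf's empirical distribution of
donor values. The default visit order puts core variables first with the
outcome last among them — keeping the predictive relationship conditioned on
its features — then adjuncts in schema order. Predictors enter the trees as
frequency-rank integer codes: exhaustive subset search over many-level
categorical predictors is exponential in the level count, while ordinal
frequency encoding keeps fits tractable at the cardinalities the design
requires without affecting the leaf-donor sampling semantics.

**Chow–Liu Bayesian network.** Pairwise mutual information is estimated by
plug-in on the canonical scale; the maximum-MI spanning tree is rooted at
the first visit-order variable; conditional probability tables are smoothed
and sampling is ancestral from the root. Smoothing strength `alpha = 1`
allocates the same total pseudo-mass per parent level as uniform Laplace
smoothing, but shaped by the child's marginal: uniform pseudo-counts flatten
long-tailed code variables noticeably at `n = 10,000`, while
marginal-shaped pseudo-counts preserve marginal fidelity (per-variable total
variation distance ≤ 0.05 against training data in tests) and still leave
every observed level reachable under every parent level, so unseen
combinations retain nonzero probability.

## Variant sampling

The number of adjunct subsets explodes combinatorially (`2^m`; about
1.27 x 10^30 at `m = 100`), so variants are sampled. For `m ≤ 5` the space is
enumerated exhaustively. Otherwise target subset sizes cycle over a
log-spaced grid from 1 to `m` (the core-only plan is always included), and a
uniform random subset of each target size is drawn with duplicate rejection.
This is an explicit design stand-in, not a reconstruction of any particular
weighting scheme; it guarantees coverage of the full complexity range at any
budget, and the scheme is recorded in each plan's provenance.

## Downstream learners

* **Gradient-boosted trees** (`train_gbm()`): leaf-wise (lossguide) growth,
  hyperparameters — learning rate {0.05, 0.1}, leaves {15, 31, 63}, rounds
  {100, 300} — selected by mean AUROC in 5-fold cross-validation and refit
  on all rows. The grid is configurable; small pipeline runs use a single
  configuration.
* **Multilayer perceptron** (`train_mlp()`): dense 16 (ReLU) → dropout 0.2 →
  dense 16 (ReLU) → sigmoid output, Adam (lr 1e-3), batch 256, up to 100
  epochs, 10% validation split with early-stopping patience 10 on binary
  cross-entropy. No architecture search — the guard is against overfitting,
  not for capacity.
* **Encoding:** one-hot for categoricals with an explicit missing category;
  median imputation plus a missingness indicator for numerics
  (standardized for the MLP). Level sets are frozen from the training table,
  so unseen holdout levels encode as all-zero dummies.
* **AUROC** is the rank-based Mann–Whitney statistic with average ranks for
  ties, cross-checked in the test suite against an independent ROC
  implementation.

TSTR trains one classifier per synthetic replicate and averages holdout
AUROC; a replicate whose sampled outcome collapses to one class is recorded
as missing, excluded from the mean, and flagged. TRTR on the fixed split is
the reference; `extra_splits` re-splits the population to quantify split
sensitivity (small on stable simulated populations: spread ≤ 0.02 in tests).
Holdout leakage into any training stage is asserted against at run time.

## Effect estimation

* **Complexity → HR:** binomial-logit GLMM (Laplace approximation) on
  *aggregated counts* — hallucinated records out of `k x |S|` trials per
  trained generator — with a population random intercept. Aggregated counts
  handle HR = 1 observations without ad-hoc boundary corrections, which a
  quasi-likelihood on the averaged rate would need. Effects are reported as
  odds ratios per complexity unit with Wald 95% CIs (chosen over profile
  CIs for speed; the method is recorded in the output).
* **HR → TSTR:** linear mixed model by REML, HR in percentage points so the
  slope reads as AUROC change per HR percentage point. Populations first
  pass a spread filter: only those whose HR P90 − P10 (linear-interpolation
  percentiles) is at least 0.25 carry information about the slope. If a
  single population survives, the model degrades to OLS and the conditional
  R² equals the marginal R².
* **Model fit:** Nakagawa marginal/conditional R² computed from the variance
  of the fixed-effect predictor, the random-intercept variance, and the
  residual variance (π²/3 on the latent scale for the binomial-logit model —
  the theoretical variant).
* **Significance** is α = .05 throughout; per-generator models are reported
  without multiplicity adjustment, matching the unit of interpretation.
* **Sensitivity:** `subset_sensitivity()` refits both models on 50% and 25%
  per-population subsets of the variants; sparse cells are marked missing
  with a logged note rather than failing the run.

Parameter-recovery simulations in the test suite check both models at
realistic effect scales — an odds ratio of 1.10 per complexity unit
(12 populations x 100 observations) and a slope of −0.0002 AUROC per HR
percentage point (3 populations x 600 observations) — with CI coverage
required to fall in 93–97% over 200 runs each.

## What the simulator does and does not emulate

Defaults: mostly categorical variables (≥80%), long-tailed high-cardinality
codes from a truncated Zipf law (exponent 1.2), numeric variables as normal
mixtures discretizable to ~10 bins, MCAR missingness (2% per variable by
default; never in the outcome), outcome from a logistic model on a subset of
core variables with an optional prevalence target (default suite: 25%,
emulating class imbalance). Pool sizes in `default_population_suite()` span
~5 to 120+ adjuncts, echoing the range from small registries to wide
discharge datasets.

It does **not** emulate: informative missingness, event-level (non-individual)
records, real registry-specific dependence structures or code semantics, or
temporal structure. Passing tests therefore demonstrate that the *machinery*
behaves lawfully (matching, monotonicity, recovery of known effects), not
that any specific real dataset would show a particular HR or TSTR value.

## Numerical and scale choices

* Sub-seeds derive deterministically from `(seed, indices)` by integer
  mixing below 2^31, so any stage reproduces in isolation and a full run is
  idempotent given the master seed.
* Degenerate inputs: constant training tables yield a marginal-only
  generator that resamples the observed record; all-missing columns carry
  cardinality 1; empty datasets and invalid specs fail validation with the
  offending field named.
* Test and example runs are scaled to desk size by design — populations of
  thousands to tens of thousands of records, 20 variants x 2 families x 3
  replicates of 2,000 rows for the end-to-end check, 10,000/10,000 splits
  where split-level claims are made — chosen so each suite exercises the same
  code paths as a full study at interactive runtimes.

## Known limitations

* Exact-match hallucination detection is bin-count dependent for numeric
  variables; boundary values can be misclassified. The policy keeps the bin
  count explicit rather than hiding it.
* The variant-sampling scheme covers the complexity range but makes no claim
  of representativeness of the full combinatorial space.
* The GLMM treats replicate draws as independent trials within a trained
  generator; overdispersion between replicates is absorbed by the population
  random effect only.
* The built-in generators deliberately exclude deep architectures; plugins
  carry those families but are validated only at the contract level.
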