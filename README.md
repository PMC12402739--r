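# sdgaudit

Auditing hallucinations in tabular synthetic health data and their impact on
downstream prognostic modelling.

A synthetic record is **hallucinated** when it does not exist in the
population the training data were sampled from — a violation of factuality,
regardless of statistical plausibility. With the synthetic table `S` and the
population variant `P`, the hallucinated set is the exact-row antijoin

    HA = S \ P,        HR = |HA| / |S|

(equivalently, the synthetic rows at record-level Hamming distance > 0 from
every population row), with the hallucination rate `HR` averaged over
replicate synthetic datasets per trained generator. `sdgaudit` implements
the full validation pipeline around this quantity:

* **Population simulator** — seeded, individual-level, categorical-dominant
  reference populations with a binary outcome, core predictors, an adjunct
  pool with long-tailed high-cardinality codes, missingness and class
  imbalance (stand-ins for access-restricted health registries).
* **Variants and splits** — column-subset population variants of graded
  complexity over the adjunct pool; one fixed, disjoint train/holdout record
  split per population shared by all its variants.
* **Complexity** — `log(sum of variable cardinalities)` under the shared
  discretization policy.
* **Generators** — sequential decision trees (CART with leaf-donor sampling)
  and a Chow–Liu Bayesian network (max-MI spanning tree, smoothed CPTs,
  ancestral sampling), plus a plugin contract for external families.
* **Hallucination audit** — canonicalization (fixed bin edges, missing
  sentinel), antijoin, an independent Hamming-distance oracle, per-replicate
  and averaged HR.
* **Downstream utility** — TSTR and TRTR AUROC with a CV-tuned
  gradient-boosted classifier and a 16–dropout–16–1 MLP.
* **Effect models** — binomial-logit GLMM of hallucinated counts on
  complexity and linear mixed model of TSTR on HR (population random
  intercepts, Wald CIs, Nakagawa marginal/conditional R², HR-spread filter,
  50%/25% subset sensitivity), with broom-style `tidy()`/`glance()`.

## Worked example

```r
library(sdgaudit)
library(dplyr)

spec <- population_spec(
  "demo", n_records = 6000,
  core_vars = list(var_spec("age_band", "categorical", 5),
                   var_spec("sex", "categorical", 2, weights = c(0.5, 0.5)),
                   var_spec("comorbidity", "categorical", 3)),
  adjunct_pool = list(
    var_spec("dx_code", "categorical", 120, tail_shape = 1.2),
    var_spec("adj_1", "categorical", 3),
    var_spec("adj_2", "categorical", 4),
    var_spec("lab_1", "numeric")),
  outcome = outcome_spec("outcome", c("age_band", "comorbidity"),
                         c(0.5, 0.7), intercept = -1.2),
  missing_rate = 0.02, seed = 11)

pop     <- generate_population(spec)
variant <- build_variant(pop, c("dx_code", "adj_1"))
split   <- make_split(pop, n_train = 2000, n_holdout = 2000, seed = 11)
train   <- filter(variant$data, record_id %in% split$train_ids) |>
  select(-record_id)

policy <- binning_policy(select(variant$data, -record_id))
complexity(variant$data, policy)
#> <complexity 4.9416 (natural log, sum of 6 cardinalities = 140)>

gen  <- fit_sequential_trees(train, roles = variant$roles, seed = 11)
reps <- sample_replicates(gen, n_per_replicate = 2000, k = 3, seed = 11)
hallucination_rate(reps, variant$data, policy)
#> <hr_report: mean HR 0.3453 over 3 replicates of 2000 records>
```

A third of the synthetic records do not exist anywhere in this variant's
6,000 population records — unsurprising once a 120-level long-tailed code
variable enters the joint alphabet. The core-only variant of the same
population audits at HR 0.002. Downstream, that gap need not cost utility:

```r
task    <- task_spec("outcome", c("age_band", "sex", "comorbidity"))
holdout <- filter(variant$data, record_id %in% split$holdout_ids)
evaluate_tstr(reps, holdout, task, learner = "gbm",
              gbm_grid = tibble::tibble(eta = .1, leaves = 31, nrounds = 60),
              seed = 11)$tstr_mean
#> [1] 0.690769
evaluate_trtr(train, holdout, task, learner = "gbm",
              gbm_grid = tibble::tibble(eta = .1, leaves = 31, nrounds = 60),
              seed = 11)$trtr
#> [1] 0.7190398
```

A classifier trained on the hallucination-laden synthetic replicates loses
about 0.03 AUROC against training on the real records. `run_experiment()` scales this
loop over populations x variants x generator families and fits the two
mixed-effects models; `plot_hr_complexity()` and `plot_tstr_hr()` visualize
the results and `tidy()`/`glance()` extract the effect tables.

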