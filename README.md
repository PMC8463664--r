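# dendrocare

Comparative phylogenetics of aposematism and parental care in poison frogs
(Dendrobatidae) — and, more generally, a toolkit for testing whether two
binary traits evolve in a correlated fashion on a time-calibrated
phylogeny, alongside the trait coding, ancestral reconstruction and
phylogenetic regression machinery such an analysis needs.

## Who this is for

Evolutionary biologists with (1) a rooted ultrametric tree in Newick
format and (2) a species-by-trait table: discrete natural-history fields
(caregiver sex, tadpole deposition site, habitat, cannibalism), continuous
measurements (body sizes, clutch and egg metrics, tadpole counts), a
0–11 coloration conspicuousness score, and skin-alkaloid quantities. The
package codes these into analysis-ready variables using explicit,
literature-standard rules (conspicuous ⇔ score ≥ 6; alkaloids present ⇔
> 10 µg per 100 mg skin; phytotelm vs non-phytotelm deposition; ranges
reduced to midpoints; natural-log transforms; female-size-controlled
residuals), then runs the comparative analyses.

## The models at the core

**Equal-rates Mk and marginal ancestral reconstruction.** Each discrete
character evolves by a continuous-time Markov chain with a single rate *q*
for all ordered state pairs. Likelihoods use Felsenstein pruning with
per-node scaling; marginal reconstructions give each internal node's
posterior state probabilities given all tips.

**Pagel-style correlated evolution.** Two binary traits (an aposematism
component *A* and phytotelm-breeding *B*) form a 4-state chain,
1 = (0,0), 2 = (0,1), 3 = (1,0), 4 = (1,1), with dual transitions
forbidden. Three model classes: *independent* (4 rates, likelihood
factorizes over traits), *dependent* (8 rates), and *constrained
dependent* (q34 = q43 = q12 = q21; 5 rates) in which the asymmetry between
q24 (gaining aposematism while phytotelm-breeding) and q42 / q31
(reversals) is read off directly. Fitting is by bounded multi-start ML or
Metropolis–Hastings on log-rates under uniform(0, 100) rate priors.
Evidence for correlated evolution is the log Bayes factor
logBF = 2 (ln ML_dep − ln ML_ind), with marginal likelihoods from a
stepping-stone sampler (generalized reference path by default; plain
prior path available): logBF < 2 weak, 2–5 positive, 5–10 strong, > 10
very strong.

**Phylogenetic regressions.** Pairwise PGLS under Brownian covariance with
Benjamini–Hochberg FDR across all trait pairs, and Bayesian phylogenetic
logistic regression (latent logit scale, species random effect with
σ² × Brownian covariance, inverse-Gamma(0.001, 0.001) variance prior,
Gelman–Rubin convergence checks).

**Synthetic data.** Exact event-driven CTMC simulation, Yule trees,
Brownian traits, logistic responses, and a 220-species dendrobatid-like
fixture whose state counts match the study system's margins.

## Worked example

```r
library(dendrocare)

fx <- make_dendrobatid_like_fixture(seed = 1)   # 220-species synthetic data
coded <- code_traits(fx$traits, fx$tree)$coded
sum(coded$conspicuous, na.rm = TRUE)            # 69 conspicuous species
sum(coded$phytotelm_breeder, na.rm = TRUE)      # 51 known phytotelm-breeders

A <- setNames(coded$conspicuous, coded$species)
B <- setNames(coded$phytotelm_breeder, coded$species)

ml_fit(fx$tree, A, B, "dependent_constrained")$rates
#> shared    q13    q31    q24    q42
#>   0.62   0.41   3.81  10.96   2.69

ss_c <- stepping_stone_ml(fx$tree, A, B, "dependent_constrained", seed = 1)
ss_i <- stepping_stone_ml(fx$tree, A, B, "independent", seed = 2)
log_bayes_factor(ss_c, ss_i)
#> logBF = 35.1 (very strong evidence for correlated evolution)

mc <- mcmc_sample(fx$tree, A, B, "dependent_constrained",
                  n_iter = 6000, seed = 3)
s <- transition_summary(mc)
s$table[s$table$parameter %in% c("q31", "q24", "q42"), ]
#>  parameter  mean median
#>        q31  4.12   4.11
#>        q24 34.93  29.36
#>        q42 10.51   8.06
s$ratios[["q24/q31"]]
#> 8.5
```

Reading the output: the fixture's traits were generated under a strongly
asymmetric dependent model, and the analysis recovers that — the
constrained dependent model beats the independent one decisively
(logBF ≈ 35, "very strong"), and the posterior puts the transition rate
*into* aposematism on the phytotelm-breeding background (q24) about 8–9×
above the reversal rate (q31), the same direction of asymmetry reported
for real dendrobatids. ML rate estimates sit near the generating values;
posterior means of large, weakly constrained rates run higher than
medians, which is the expected skew under flat rate priors.

The full pipeline (coding → ASR → pairwise PGLS → logistic regressions →
Bayes factors, with CSV/JSON outputs) is one call:

```r
res <- run_all(fx$tree, fx$traits, out_dir = "results", seed = 1)
```

or from a shell via the wrapper in `inst/scripts/run_pipeline.R`.

## Scope notes

The package consumes the phylogeny as input (no tree inference or dating),
scores coloration from human-vision segment indicators (no
spectrophotometric visual modelling), and reports marginal ancestral state
probabilities without imposing an origin-counting rule. See the methods
vignette (`vignettes/methods.Rmd`) for the models, priors, numerical
choices and known limitations.
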