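---
title: "Correlated evolution of aposematism and parental care: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlated evolution of aposematism and parental care: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific question

Poison frogs (Dendrobatidae) combine two striking trait complexes:
aposematism — conspicuous coloration advertising skin-alkaloid defenses —
and unusually elaborate parental care, including the transport of tadpoles
on a parent's back and their deposition in small plant-held water bodies
(phytotelmata). `dendrocare` implements the comparative-phylogenetics
toolkit needed to ask whether these complexes evolve together: does
phytotelm-breeding evolve more readily on an aposematic background, and do
care traits covary with the components of aposematism once shared ancestry
is accounted for?

The package operates on a time-calibrated phylogeny (Newick, branch lengths
required) and a species-by-trait table, and provides four analysis layers:
trait coding, ancestral state reconstruction, phylogenetic regression, and
correlated-evolution tests for trait pairs. A seed-deterministic synthetic
data generator stands in for the compiled empirical dataset so that every
stage is testable end to end.

## Trait coding

Coding rules follow the conventions of the dendrobatid literature:

* **Conspicuousness score.** The body is divided into 11 non-overlapping
  skin segments; each scores 1 when its coloration contrasts with a
  leaf-litter background. The species score is the sum (0–11). Scores of 6
  or more are binarized as *conspicuous*: every species reported to carry
  skin alkaloids scores at least 6, so the threshold separates the
  aposematic phenotype from partial brightness.
* **Chemical defense.** Alkaloids are *present* when the measured quantity
  strictly exceeds 10 µg per 100 mg of skin. A value of exactly 10 codes as
  absent; the boundary convention matters only for species sitting exactly
  on it.
* **Care traits.** The caregiver sex is binarized male/female; species with
  no parental care or with biparental care lacking a clearly dominant sex
  are excluded, each with a machine-readable reason. The
  tadpole-transporting sex follows the observed majority, and an exact tie
  is treated as missing rather than assigned arbitrarily. Deposition sites
  are binarized phytotelm versus non-phytotelm, with species using both
  ponds and streams coded non-phytotelm.
* **Continuous traits.** Values reported only as ranges are reduced to the
  range midpoint. Body-size dimorphism (SSD) is the female/male
  snout–vent-length ratio. Continuous traits are natural-log transformed
  (any fixed base is monotone-equivalent for the regressions). Egg size,
  clutch size and tadpole size can be residualized on female size; the
  residual regression is phylogenetic GLS by default — the consistent choice
  inside a phylogenetic pipeline — with ordinary least squares available for
  sensitivity checks.

Coding is deterministic: the same table always produces byte-identical
coded output.

## Discrete-character models

### Equal-rates Mk and marginal reconstruction

Single characters evolve under a continuous-time Markov chain with one
shared rate `q` for every ordered state pair (the ER model). Likelihoods
use Felsenstein pruning with per-node scaling; missing tip states are
marginalized with all-ones partial vectors, so every character uses the
same tree. The root is weighted by a uniform prior, which equals the ER
stationary distribution, so the choice is innocuous here; it is
configurable. Marginal ancestral reconstructions come from an up–down pass
giving, at each internal node, the posterior state probabilities given all
tips; on every small tree in the test suite these match brute-force
enumeration over internal-node states to 10 decimal places.

### Correlated evolution of two binary traits

Two binary traits are analyzed jointly as a 4-state chain with the fixed
encoding 1 = (0,0), 2 = (0,1), 3 = (1,0), 4 = (1,1), where trait A is an
aposematism component (conspicuous coloration or alkaloid presence) and
trait B is phytotelm-breeding. Dual simultaneous transitions are
structurally zero. Three model classes are supported:

* **independent** (4 rates): each trait's gain/loss rates ignore the other
  trait; its paired likelihood factorizes exactly into the product of the
  two 2-state likelihoods, a property the test suite checks to 1e-9.
* **dependent** (8 rates): every single-step rate free.
* **dependent_constrained** (5 rates): the dependent model with
  q34 = q43 = q12 = q21, i.e. all phytotelm gain/loss rates equal across
  coloration backgrounds, leaving the aposematism transitions (q13, q31 on
  the non-phytotelm background; q24, q42 on the phytotelm background) free.
  This is the parameterization under which "does phytotelm-breeding favor
  gaining aposematism?" is read directly off q24 versus q42 and q31.

Note on nesting: independent and constrained-dependent are *not* nested in
each other (independent permits asymmetric B rates; constrained forces them
equal while freeing the A rates), so only `dependent >= constrained` and
`dependent >= independent` are guaranteed inequalities for maximized
likelihoods. On data with genuinely correlated evolution the constrained
model in practice also beats the independent one.

ML fitting uses bounded multi-start L-BFGS-B on log-rates (rates in
[1e-8, 1e3]); the richer classes additionally start from the mapped optimum
of the simpler class so the fitted likelihoods respect the guaranteed
nesting inequalities numerically. Monomorphic traits drive rates to the
lower bound, which is flagged rather than hidden.

### Bayesian fitting and marginal likelihoods

Rates get independent uniform(0, 100) priors by default (the convention of
the standard correlated-evolution software); an exponential alternative is
available. Posterior sampling is Metropolis–Hastings on log-rates with a
mixed kernel — random-scan componentwise steps with per-coordinate scales,
occasional joint and heavy-tailed moves, and independence proposals — with
scale adaptation confined to the burn-in so the post-burn-in kernel is
fixed and runs are exactly reproducible by seed.

Evidence for correlated evolution is a log Bayes factor,
`logBF = 2 (ln ML_dependent − ln ML_independent)`, with the usual bands:
weak < 2, positive 2–5, strong 5–10, very strong > 10. Marginal
likelihoods come from stepping-stone sampling over a Beta(0.4, 1)-quantile
power ladder. Two path choices are offered:

* `reference = "prior"`: the textbook prior-to-posterior path.
* `reference = "mle"` (default): a generalized stepping stone whose
  reference distribution is a mixture of independent normals centered on
  the ML log-rates (70%) and the prior (30%). The estimand is identical —
  the marginal likelihood under the rate prior — but the path stays
  concentrated, and at desk-scale settings (20 stones × 3000 iterations)
  the seed-to-seed standard deviation of ln ML is about 0.24 (independent
  model) and 0.12 (constrained) on 100-tip data, versus 1–4 for the plain
  prior path at the same number of likelihood evaluations. The mixture
  component bounds the importance weights when some rates are weakly
  identified and their posterior stays prior-wide.

The full 8-rate dependent model remains the hard case: its posterior on
~100-species datasets is diffuse and multimodal, and its desk-scale ln ML
estimates still vary by roughly ±1.5. Two consequences are worth knowing.
First, for headline inference the package compares the *constrained*
dependent model against the independent one — the same workflow as the
study system's analysis, where the constrained variant was the best-fitting
model. Second, the extra four uniform(0, 100) rates of the full dependent
model carry a substantial Occam penalty: on simulated 300-species datasets
with strong (≈ 11×) rate asymmetry, the full-dependent-versus-independent
logBF is often below 10 even when computed at high precision, while the
constrained-versus-independent logBF is typically 20–37. A "weak" band for
the full dependent model therefore does not contradict a "very strong" band
for the constrained one; it mostly reflects prior volume. The published-scale
preset (100 stones × 10 000 iterations) is recommended when the full
dependent model's evidence is itself of interest.

## Phylogenetic regressions

### Pairwise GLS

Pairwise trait relationships use generalized least squares with the
Brownian-motion covariance (shared root-to-MRCA path lengths), implemented
by Cholesky whitening; the tree is rescaled to unit height before
inversion, which leaves slopes invariant and conditions the matrix. On a
star phylogeny the estimates reduce exactly to ordinary least squares, and
the test suite cross-checks slopes and p-values against an independent GLS
implementation. All unordered pairs are fitted and the p-values are
adjusted by Benjamini–Hochberg over the full set, mirroring a
lower-triangular comparison table with significance flags.

### Phylogenetic logistic regression

Binary responses (deposition site, cannibalism, alkaloid presence,
transporting sex, conspicuousness, habitat, caregiver sex) are regressed on
continuous predictors (coloration score, SSD, number of tadpoles
transported, size-controlled tadpole size) with a species-level random
effect whose covariance is σ² times the unit-height Brownian matrix.
Coefficients live on the latent logit scale with residual variance fixed at
1, the usual categorical-response convention, so users can rescale if they
need marginal effects. The variance prior is inverse-Gamma with shape and
scale 0.001; behaviour near σ² → 0 under this prior is surfaced as a
warning rather than silently absorbed.

The sampler combines random-walk Metropolis for the fixed effects (normal
prior, variance 1e8), independence proposals from the conditional prior for
each species effect (their acceptance ratio reduces to a single site's
Bernoulli likelihood), and a conjugate inverse-gamma Gibbs update for σ².
Proposal scales adapt during burn-in only; chains are bit-reproducible by
seed. Defaults are 4 chains × 50 000 iterations (burn-in 5000, thin 10) at
desk scale, with a published-scale preset of 2×10⁷ iterations, burn-in 1000,
thin 500; the pipeline's desk preset shortens this to 4 × 20 000 per
response, which recovers known coefficients within posterior uncertainty in
the suite's simulations. Convergence is monitored by the Gelman–Rubin
statistic computed from between- and within-chain variances; two-sided
posterior tail probabilities (pMCMC) summarize coefficient significance.
Very large posterior means (|β| > 20 on the logit scale) trigger a
separation warning: with small complete-case samples, a predictor can
separate the classes and the latent-scale magnitudes then reflect the prior
more than the data.

## Synthetic data

The generator provides the forward models matching every analysis
assumption: exact event-driven CTMC simulation along branches (no
discretization bias), pure-birth trees grown by exponential waiting times,
Brownian traits by root-to-tip normal increments, and logistic responses
from a latent liability with a Brownian species effect.

`make_dendrobatid_like_fixture()` assembles a 220-species dataset shaped
like a compiled dendrobatid dataset. The paired characters (conspicuous coloration ×
phytotelm-breeding) evolve under a constrained dependent model with strong
asymmetry, truth rates (shared = 0.45, q13 = 0.4, q31 = 2.2, q24 = 17,
q42 = 2.7) on a unit-height tree with a cryptic, non-phytotelm root. These
values were chosen by matching the expected tip marginals, the row of
exp(Q) for the root state, to reported dendrobatid marginal counts (≈ 77/220
conspicuous; ≈ 52 phytotelm-breeders among the ~75% of species with known
deposition); q24 ≫ q42, q31 reproduces the reported direction of
asymmetry. Because phylogenetic correlation makes realized counts
variable, the generator redraws the character history from seed-indexed
substreams until the coded counts fall within ±15% of the target margins —
conditioning on a count window, never relabeling tips, so the generative
model the fits assume is preserved. Remaining fields (caregiver,
transporter, habitat, cannibalism, body sizes, clutch and egg metrics,
alkaloid quantities consistent with the coloration state) are simulated
with missingness fractions that roughly reproduce realistic per-analysis
usable sample sizes; alkaloid data are the sparsest, as in reality.

What the fixture does *not* emulate: literature-compilation biases
(missingness correlated with clade and body size rather than at random),
measurement error in alkaloid quantities, intraspecific variation, and any
trait-dependent diversification. Tests passing on the fixture therefore
demonstrate statistical correctness of the machinery under the assumed
generative models, not robustness to those real-data complications.

## Numerical choices

* Transition probabilities exp(Qt) come from an eigendecomposition of Q
  computed once per likelihood call, with a Padé/scaling–squaring fallback
  when the eigenbasis is ill-conditioned; small negative entries from
  round-off are clamped to zero.
* Pruning uses per-edge renormalization of partial likelihoods with
  accumulated log-scalers, so likelihoods of 500-tip trees with extreme
  rates do not underflow.
* Pruned trees keep the stem above the retained clade's most recent common
  ancestor as a root edge, so root-to-tip depths and pairwise shared-path
  covariances are unchanged by pruning — the property the regression
  modules rely on.
* The ultrametricity check compares each root-to-tip depth with the mean
  depth at a user-visible tolerance (default 1e-6 in branch-length units).
* Ties, boundaries, degenerate inputs: exact transporter ties are missing;
  monomorphic characters flag a boundary rather than erroring; an
  all-missing character is an error; stepping-stone ladders must include
  the β = 0 endpoint (at least two stones).

## Problem sizes used in the checks

The packaged test suite exercises exact oracles on trees of 3–6 tips
(enumeration over internal states), parameter recovery on 100–600 tips,
Bayes-factor power and specificity on 300-tip simulations (10 seeds per
condition), PGLS type-I error on 500 replicates of 200-tip trees, and a
full desk-scale pipeline run on the 220-species fixture. These sizes were
chosen so the whole suite completes in tens of minutes on a single CPU
while each check retains enough replication to be meaningful; the
published-scale presets reproduce the published chain settings when more
precision is wanted.
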