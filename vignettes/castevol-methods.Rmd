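---
title: "Models and methods behind castevol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind castevol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Social insects vary enormously in how strictly reproduction is divided
between queens and workers. In ants, workers range from individuals with
full sexual capacity — able to mate and produce both male and female
offspring — through species whose workers can lay only male (haploid) eggs,
to completely sterile castes; similarly, queens range from the same size as
workers to hundreds of times their volume. The size-complexity hypothesis
predicts that larger colonies favour a greater division of labour. Testing
that prediction is a comparative-phylogenetics problem: species are not
independent data points, and the questions are about the *order* of
evolutionary change (do lineages lose reproductive potential stepwise?), its
*tempo* (how often has sterility evolved?), and its *causal structure* (does
colony size drive the loss, or the reverse?).

`castevol` packages the full analytical toolchain for this class of
question: constrained multistate Markov (Mk) models compared by Bayes
factors, Pagel's correlated-evolution test for binary trait pairs, marginal
ancestral state reconstruction with transition counting, Brownian-motion
estimates of ancestral continuous traits, phylogenetic regressions (GLS and
Bayesian mixed models), and phylogenetic path analysis. Because the
empirical dataset that motivated the design is not redistributable, every
stage is validated against a synthetic-data module with exact ground truth.

## Discrete trait evolution: the constrained Mk model

A k-state trait evolves along the tree as a continuous-time Markov chain
with instantaneous rate matrix $Q$, $q_{ij} \ge 0$ for $i \ne j$ and rows
summing to zero. The likelihood of the tip states is computed by
Felsenstein's pruning algorithm with per-edge transition probabilities
$P(t) = e^{Qt}$. Hypotheses about the order of evolution are encoded as
*constraint maps*: each ordered transition is `free`, `zero`, or `shared`
with a named group. The shipped model family for a four-category
reproductive-potential trait is:

* `FREE` — 12 independent rates (non-ordinal categories);
* `SEQUENTIAL` — only adjacent transitions (1↔2, 2↔3, 3↔4), 6 rates
  (a ladder of states);
* `SEQUENTIAL_PLUS_1to4` — sequential plus a direct loss from full capacity
  to sterility (7 rates);
* `INTERMEDIATE_SHARED` — adjacent rates free, all non-sequential
  transitions pooled into one shared (rare) rate class.

The intermediate model deserves a note: the verbal description "non-
sequential transitions could occur but were rarer" does not pin down a
parameterization, so the package implements one defensible reading — a
single shared rate for every non-sequential cell — and labels it clearly.

### Priors, MCMC, and marginal likelihoods

Rates carry an exponential prior whose mean is itself uniform on
$(0, u)$ with $u = 0.1$ by default. This hyperprior convention pairs with
the convention of rescaling trees to a mean branch length of 0.1 (see
`scale_branch_lengths()`): rescaling changes nothing statistically — the
likelihood is invariant when rates are multiplied by the inverse constant —
but keeps rates in a numerically comfortable range. The MCMC uses log-scale
random-walk proposals on one randomly chosen rate group per sweep, an
independence update of the hyper-mean from its prior, and uniform
tree-index switching when a set of trees is supplied.

Marginal likelihoods come from stepping-stone sampling: power posteriors at
inverse temperatures $\beta_j$ placed at quantiles of a Beta(0.4, 1)
distribution (dense near the prior, where the integrand changes fastest),
with the log marginal likelihood accumulated as the sum over adjacent rungs
of log mean importance ratios. The default schedule is 100 stones of 10,000
iterations. Support is expressed as $BF = 2(\ln ML_1 - \ln ML_0)$ with the
conventional reading: below 2 minimal, 2–6 positive, 6–10 strong, above 10
very strong.

Two design choices here are worth making explicit. First, the
"reversible-jump" machinery of the original software is represented by the
zero/free/shared constraint families compared explicitly via stepping-stone
Bayes factors; full reversible-jump moves across all rate-class partitions
add sampler complexity without changing the pairwise model comparisons
that carry the inference. Second, the samplers refuse
`root_mode = "stationary"`, because the stationary distribution is a
function of the sampled rates; the default is flat root frequencies, with
`observed` and user-supplied distributions available.

## Correlated evolution of binary trait pairs

Pagel's test builds the product chain over two binary traits — states
(00, 01, 10, 11) — with simultaneous double transitions structurally zero.
The *independent* model ties each trait's gain and loss rates across the
other trait's states (4 parameters); the *dependent* model frees all 8
single-change rates. The Bayes factor of dependent over independent, from
stepping-stone marginal likelihoods, measures support for correlated
evolution. Continuous traits enter this machinery through the binarization
rules in `trait_prep`: median (or mean) splits with a central *buffer zone*
— the central `round(b·n)` species by rank distance from the center are
dropped before dichotomizing (b = 5% or 10% in the motivating study) — and
the fixed threshold of two for queen number (polygyny) and effective mating
frequency (polyandry). Ties in the buffer are broken by rank order, and
species exactly at the center score 0; both conventions are deterministic
and documented because the verbal definition of a "buffer zone" does not
fix them.

## Ancestral states and transition counting

Marginal ancestral probabilities come from the standard two-pass algorithm
(post-order "down" partials, pre-order "up" partials; the product,
normalized per node, is the marginal posterior). On trees small enough to
enumerate, the implementation is tested against explicit summation over all
internal-state assignments. Hidden-rate models (observed states × 1–3 rate
classes, ER or ARD within class, a single class-switching rate, ranked by
AIC) marginalize class out of the reported state probabilities.

Transition counts across a tree set are produced two ways, reported side by
side because the literature rarely states which was used:

* **joint** — assign each node its maximum-marginal state and count
  discordant parent→child edges by type (fast, deterministic, directly
  comparable to simulation truth);
* **stochastic** — sample full character histories conditional on the tips
  (node states by conditional sampling, within-edge paths by
  uniformization), and average event counts. Stochastic maps include
  multiple hits and therefore average at least as many events as joint
  counts.

Continuous traits get Brownian-motion GLS ancestral estimates: the root is
the phylogenetic mean, other nodes are conditional expectations given the
tips, with a REML-style rate estimate and standard errors that include the
uncertainty of the estimated mean. The transition-context contrasts then
ask whether a continuous trait (e.g. log colony size) is larger at parent
nodes of transition edges than at other internal nodes
(`origin-vs-nonorigin`), or larger before than after transitions
(`before-vs-after`); "ancestral nodes of lineages that had transitions" is
operationalized as parent nodes of transition edges.

## Regressions and path analysis

`pgls_fit()` is generalized least squares under the Brownian covariance
$C$ (shared root-to-ancestor path lengths), optionally scaled by Pagel's
lambda (fixed or profiled on [0, 1], endpoints included). On a star
phylogeny it reduces exactly to ordinary least squares. `bpmm_fit()` is a
Bayesian phylogenetic mixed model: Gibbs sampling over fixed effects, a
phylogenetic random effect with covariance $\sigma_p^2 C$ (diagonalized
once per tree, so all conditionals are cheap), and residual variance; binary
and ordinal responses use latent-threshold probit augmentation with the
residual variance fixed at 1. `pMCMC` is twice the smaller posterior tail
probability; intervals are 95% highest-density; two or more chains trigger a
Gelman–Rubin check with the conventional 1.1 threshold. The
exponential-family responses of the motivating study (queen number, mating
frequency) are handled as gaussian models of log-transformed values — a
faithful latent-threshold family is testable, whereas an
exponential-response GLMM would add little inferential content here.

Path analysis follows the d-separation recipe: each candidate DAG implies a
basis set of conditional independencies — here, every non-adjacent pair
conditioned on the parents of the later node in topological order (the
convention matters for Fisher's C and is therefore fixed and documented) —
each claim is tested by PGLS, and
$C = -2\sum \ln p_i \sim \chi^2_{2k}$ under the model. Models are ranked by
$CICc = C + 2qn/(n - q - 1)$ with $q$ the number of directed edges;
standardized path coefficients (all continuous traits z-scored) are averaged
over models within 2 CICc of the best, weighted by CICc weights. One
structural caveat is inherent to the method: Markov-equivalent DAGs (a chain
and its reversal) share a basis set and can never be separated by CICc;
recovery claims are only meaningful against non-equivalent alternatives.

## The synthetic world

The generator states its world once; these are modelling commitments, not
tuning knobs:

* **Trees** — birth–death simulations conditioned on the number of extant
  tips (default pure birth), rescaled to mean branch length 0.1. A
  posterior sample is emulated by multiplicative lognormal jitter
  (σ = 0.1) of branch lengths on a fixed topology; topological uncertainty
  is deliberately out of scope at desk scale.
* **Rates** — discrete-trait rates default to 0.2–0.3 per unit branch
  length in the scaled units. This is the regime the analysis prior
  (exponential with mean at most 0.1) anticipates, and it yields tens of
  transition events on trees of 200–600 tips — the same order as the
  empirical transition counts the method is used to estimate. Rates of
  order 1 and above in these units saturate the tree and put the truth far
  into the prior's tail, a regime the stated analysis world never
  contemplates.
* **Categories** — the four-category trait defaults to latent-BM
  thresholding at the target marginal quantiles (default frequencies
  (0.08, 0.12, 0.47, 0.33) normalized; the printed empirical percentages
  are internally inconsistent, so frequencies are configuration). The
  threshold construction guarantees the marginal distribution while keeping
  phylogenetic signal; an alternative `mk` method simulates under the
  mostly-sequential rate matrix, with only approximate marginals. Neither
  emulates everything about real data: the threshold method has no
  transition-event truth for the categories, and the Mk method does not hit
  the marginals. A green frequency test therefore establishes the marginal
  contract, not Mk realism.
* **Continuous traits** — Brownian motion with per-edge increments recorded,
  so true node values and true event tallies (for discrete simulations) are
  exact bookkeeping, never reconstructions. Causally linked traits are
  built in topological order as coefficient-weighted parent sums plus
  independent BM noise.

All generators are bit-reproducible from a seed; the pipeline derives named
per-stage sub-seeds from one master seed.

## Numerical choices

* Transition probabilities inside the C++ pruning core use a complex
  spectral decomposition of $Q$ computed once per likelihood evaluation,
  with an automatic fall back to a scaling-and-squaring matrix exponential
  when $Q$ is defective (reconstruction error above $10^{-9}$ relative).
  The R-side oracle and ASR paths use `Matrix::expm` (Padé), deliberately a
  different algorithm, so the two routes cross-check each other.
* Impossible data return a $-\infty$ log-likelihood sentinel, never an
  error; per-node rescaling guards against underflow on large trees.
* ML fitting optimizes log-rates with L-BFGS-B from several random starts
  within $[10^{-9}, 10^4]$.
* The stepping-stone chain warm-starts each rung from the previous one,
  discards a 10% burn-in per rung, and errors (naming the stone) on any
  non-finite contribution.
* `binarize_by_center` drops exactly `round(b·n)` species; ties broken by
  rank; values equal to the center score 0.

## Known limitations

* Topological uncertainty is emulated only through branch-length jitter.
* The stepping-stone estimator at desk-scale settings carries a standard
  deviation of a few tenths of a log unit; Bayes factors near a threshold
  should be re-run at the full 100×10,000 schedule.
* Hidden-rate models share one class-switching rate and forbid simultaneous
  state-and-class changes.
* The BPMM's ordinal family anchors the first cutpoint at zero and updates
  the others by small-step Metropolis moves; extremely unbalanced category
  tables will mix slowly.
* No multiple-testing correction is applied across the regression battery,
  matching the practice the package reproduces; every test reports its own
  pMCMC.
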