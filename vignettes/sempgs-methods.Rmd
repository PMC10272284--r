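---
title: "Separating direct genetic effects, genetic nurture, and vertical transmission with haplotypic polygenic scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating direct genetic effects, genetic nurture, and vertical transmission with haplotypic polygenic scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sempgs)
```

## The problem

Parents and children resemble each other because parents transmit half of
their alleles, because heritable parental traits shape the rearing
environment (*vertical transmission*), and because both happen at once: a
child of, say, highly educated parents receives both education-associated
alleles and an education-rich environment, making genes and environment
correlated (*genetic nurture*, the classic passive gene-environment
correlation). Phasing parent-offspring trios splits each parent's genome
into the haplotype **transmitted** to the child and the complementary
**nontransmitted** haplotype. A polygenic score (PGS) computed on the
nontransmitted haplotype is genetically unrelated to the child, so any
association it shows with the child's trait must run through the parental
phenotype and the rearing environment. `sempgs` embeds that contrast in a
structural equation model (SEM) so that direct genetic effects, genetic
nurture, vertical transmission, and assortative mating are estimated
jointly rather than read off a single regression.

## The model

For each trio the observed variables, in the package's fixed order, are the
four haplotypic PGSs `PGS_T,p`, `PGS_NT,p`, `PGS_T,m`, `PGS_NT,m` and the
offspring phenotype `Y_o`; the parental phenotypes `Y_p`, `Y_m` may be
observed (7-variable system) or left latent (5-variable system).
Structurally,

* `Y = delta * (h_1 + h_2) + k * (l_1 + l_2) + F + eps` within each person,
  where `h_1, h_2` are the two haplotypic PGSs, `l_1, l_2` a latent
  haplotypic genetic component capturing the heritability the PGS misses,
  and `eps ~ N(0, V_eps)`;
* `F = f * (Y_father + Y_mother)` is the familial environment: `f` is the
  vertical-transmission path;
* mates are matched through a single copath `mu` joining their mating-basis
  variables (phenotype by default; familial environment or full genetic
  value as clearly labelled extensions), with spousal covariance
  `mu * V_K^2` on basis variance `V_K`;
* assortment and transmission leave second-moment footprints: `g`, the
  within-person covariance between the two haplotypic PGSs built up by
  prior-generation assortment, and `w`, the covariance between a haplotypic
  PGS and its owner's familial environment (genetic nurture).

The key observable contrast is
`cov(PGS_T, Y_o) - cov(PGS_NT, Y_o) = delta * (v - g)`: only transmitted
scores carry the direct effect, while nurture and assortment load on both.

### Equilibrium recurrences

The generation-to-generation recurrences are derived by path tracing with
gametes modelled as mid-haplotype plus a segregation deviate of variance
`V_h0 / 2` (free recombination):

```
v'   = (v + g)/2 + V_h0/2          haplotypic variance
g'   = mu * psi^2                  within-person cross-haplotype covariance
w'   = f * (theta + mu * psi * psi_Y)   genetic nurture
V_F' = 2 f^2 (V_Y + mu * psi_Y^2)  familial variance
```

where `theta = cov(haplotypic PGS, own phenotype)` and `psi_x = cov(x, K)`
for mating basis `K`. `derive_equilibrium()` iterates these to a fixed
point (tolerance `1e-10`, at most 1000 generations; an explosive regime,
e.g. `|f|` too large, errors out). Under random mating the nurture
covariance has the closed form `w = f * delta * V_h / (1 - f)`, which the
solver reproduces to `1e-10` and the simulator confirms empirically. At
equilibrium `V_F = 2 f^2 V_Y (1 + mu V_Y)` holds as an identity, so `V_F`
is always a derived quantity (reported with a delta-method standard error),
never a free parameter.

### Expected covariance, two ways

`expected_covariance()` assembles the model-implied matrix in closed form;
`expected_covariance_paths()` re-derives every element by exhaustive
enumeration of legitimate chains on the path diagram and the two agree to
machine precision (the suite checks `1e-12` over ~100 random parameter
sets). Chains follow trace-back/trace-forward semantics in which the two
legs of a variance chain may share pass-through nodes (required for the
offspring familial environment, which both parents feed); a chain may cross
the copath once, splicing a chain to one mate's basis variable, `mu`, and a
chain from the other mate's basis variable - so the classic assortment
chain from a nontransmitted score through both parental phenotypes to the
offspring appears automatically, alongside the single genetic-nurture chain
`PGS_NT,p -> Y_p -> F_o -> Y_o` whose contribution is `f * delta * V_h`
under random mating. Prior-generation infinite regress is absorbed into the
exogenous `g` and `w` edges, which is what keeps the diagram finite.

## Model variants and identifiability

`sempgs_variant()` names four regimes: `random_mating`,
`disequilibrium_am` (one generation of assortment: between-mate covariance
through the copath, `g = 0`), `equilibrium_free` (`g`, `w` free; 6
parameters), and `equilibrium_constrained` (`g`, `w`, `V_F` tied to
`delta, f, mu` by the equilibrium solver; 4 parameters). The haplotypic
scale is fixed from the sample: the observed haplotypic variance satisfies
`v = V_h + g`, so `V_h` is profiled as `s2_hap - g` at every likelihood
evaluation. Fixing the scale this way is what makes exactly the listed
parameters estimable; treating `V_h` as free would add an unidentified
scale dimension.

A consequence worth knowing, verifiable with `identifiability_check()`:
with only the 5 trio variables the `equilibrium_free` variant is rank 5 for
its 6 free parameters (the diagonal is pinned by the profiled scale, and
`g` plus the four symmetric between-mate covariances, the two offspring
covariances, and `V_Y` leave one flat direction shared by
`f, mu, w, V_eps`). Observing parental phenotypes restores full rank, and
the equilibrium-constrained variants are identified in both systems. We
therefore recommend the constrained variant for trio-only data and treat
the free variant as a saturated-structure check (its `-2 logL` can never
exceed the constrained one, which the suite asserts). The
`disequilibrium_am` variant is similarly rank-deficient by one on trio-only
data and is intended for use with observed parental phenotypes. The latent
extension (`k`, for a PGS that captures only a fraction of heritability) is
allowed only under `equilibrium_constrained`, with parental phenotypes
observed in all shipped experiments; its sign is not identified (only even
powers of `k` enter), so the positive root is reported.

## Estimation

`fit_sempgs()` minimizes the multivariate-normal `-2 logL` summed over
missingness patterns: every family contributes the sub-matrix of the
implied covariance matching its observed variables, so parent-offspring
pairs, spouse pairs, and incomplete trios are all used without imputation,
and estimates are unbiased under data missing at random. Column means are
profiled as available-case means (exact under missingness completely at
random, the setting of the shipped experiments; under general
missing-at-random mechanisms jointly estimated means would be marginally
more efficient). Start values are method-of-moments; optimization is
Nelder-Mead followed by BFGS on a transformed scale (`log V_eps`), with
infeasible regions (non-positive-definite implied matrices, spousal
correlation at or beyond 1, explosive equilibria) handled by penalty.
Standard errors come from the numeric observed information; derived
quantities (`V_F`, `V_Y`, `g`, `w`, the variance share `V_F / V_Y`, the
spousal correlation) get delta-method errors. Convergence is declared only
when the relative gradient max-norm is below `1e-4`; non-convergence is
carried loudly through `print()` and `summary()`. Nested hypotheses (e.g.
`f = 0`) are tested with `lrt()` on refits with `fixed = c(f = 0)`;
p-values are reported raw, with no multiplicity adjustment, as at most one
or two hypotheses are tested per fit. Sibling likelihood contributions are
not implemented: the family unit is the trio and its sub-patterns.

## The simulator and what it does (not) emulate

`simulate_population()` is a forward-time generative model and the
package's canonical oracle: founders are drawn at the random-mating
equilibrium, each generation mates (rank-based Gaussian coupling hitting a
target spousal correlation on the chosen basis), transmits, and builds
phenotypes, and the final generation is emitted as trios. Two transmission
modes agree on all first and second moments: Gaussian haplotypic scores
(mid-haplotype plus segregation deviate, used for large replicate studies)
and allele-level transmission (explicit phased haplotypes, per-locus
Bernoulli(1/2) inheritance under free recombination, allele frequencies
Uniform(0.05, 0.5), Normal effect sizes rescaled to the target predictive
ability) whose output round-trips exactly through the VCF writer and the
haplotypic scorer.

Defaults encode the study conditions used throughout the experiments:
`V_h0 = pgs_r2 / (2 delta^2)` and `V_eps = 1 - h2`, so the measured PGS
explains `pgs_r2` and all additive effects `h2` of the phenotypic variance
on the random-mating baseline scale (assortment and transmission then
inflate `V_Y` above 1, exactly as the model predicts); twenty generations
of burn-in, which puts the residual distance to the fixed point far below
Monte-Carlo noise for the parameter ranges exercised.

The simulator deliberately omits linkage and LD structure (only haplotypic
PGS moments matter to the model), selection, population stratification,
sibling sets, gene-by-age interaction (`delta` constant across
generations), and multi-trait architecture. Passing tests therefore show
fidelity to this generative world, not robustness to stratified or
LD-structured real cohorts. The mating mechanism is one choice among
several that produce a given spousal correlation; alternatives (e.g.
threshold mixing) would alter higher moments but not the second moments the
model uses.

## Numerical choices

* Equilibrium solver: forward iteration, tolerance `1e-10`, cap 1000
  generations; restart at the fixed point moves less than `1e-12`.
* The offspring-phenotype variance is assembled from the parental state
  with stationary haplotypic variances, making the closed form and the path
  enumeration algebraically identical rather than equal only to solver
  tolerance.
* FIML per-pattern terms use Cholesky factorizations; patterns with one
  observed variable still contribute variance information but are flagged
  as carrying no covariance information.
* Scorer: Mendelian-inconsistent loci (including loci consistent only
  under a phase swap) are dropped and counted; a trio with more than 1% of
  such loci is dropped entirely rather than silently re-phased, because
  mis-assigned transmission biases `g` and `w`. Weights whose alleles match
  the VCF pair in neither orientation are dropped and counted. Swapping
  (effect, other) alleles with a sign flip shifts every haplotypic score by
  the constant `-sum(beta_swapped)`; all covariances and
  transmitted-minus-nontransmitted contrasts are invariant.
* Partially phased data are a hard error, not a heuristic.

## Problem sizes in the shipped experiments

The test suite runs the oracle-equivalence check on 20 random parameter
sets with 200,000 simulated families each (20 replicate populations of
10,000, pooled, with across-replicate Monte-Carlo standard errors - the
honest choice, since population moments autocorrelate across generations);
parameter recovery on 50 replicates of 16,000 trios; null calibration of
the transmission test on 500 replicates of 4,000 trios; the
missing-at-random comparison on 40 paired replicates; and the
precision-versus-predictive-ability curve at `pgs_r2` in
{0.25, 0.10, 0.05, 0.02} with 8,000 trios and `h2 = 0.5`.
`scripts/acceptance.R` recomputes the same quantities at moderately
reduced replicate counts.

## Known limitations

Beyond the simulator's scope above: the estimator assumes equal PGS
predictive ability in parents and offspring; the social and genetic mating
bases are extensions validated only against the simulator (the estimator
places the copath on the stated basis but external calibration for them
does not exist); `V_eps` is homoscedastic; and the baseline
transmitted/nontransmitted regression is intentionally naive - with a fully
predictive PGS its nontransmitted coefficient is exactly null under pure
assortment (the offspring trait is then linear in the summed transmitted
score), so the classic assortment bias it illustrates requires a partially
predictive PGS, which is how the package's contrast experiment is
configured.

## A worked example

```{r example, eval = FALSE}
cfg <- sempgs_sim_config(n_families = 16000, delta = 0.3, f = 0.15,
                         pgs_r2 = 0.3, r_mate = 0.3, n_generations = 20,
                         seed = 1)
sim <- simulate_population(cfg)
fit <- fit_sempgs(sim$families, sempgs_variant("equilibrium_constrained",
                                               parental_phenotypes = TRUE))
summary(fit)
lrt(fit_sempgs(sim$families,
               sempgs_variant("equilibrium_constrained",
                              parental_phenotypes = TRUE),
               fixed = c(f = 0), se = FALSE),
    fit)
```
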