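---
title: "Estimating causal effects in partially observed pathways: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating causal effects in partially observed pathways: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A biomolecular pathway is a directed graph whose nodes are genes, transcripts
or proteins and whose edges are causal regulatory relationships. The question
a perturbation experiment answers — "if we clamp X at x', what happens to
Y?" — is the interventional quantity P(Y | do(X = x')) or its expectation,
which is *not* in general the observational conditional P(Y | X = x'),
because pathway components left unmeasured (unknown regulators, proteins
without antibodies) confound cause and effect.

`dolvm` implements the latent-variable-model route to this problem:

1. model the pathway as a **causal LVM** — a DAG over observed nodes V and
   latent nodes U with one parametric conditional per node,
   P(U, V) = ∏ⱼ P(Vⱼ | Pa(Vⱼ)) ∏ₗ P(Uₗ | Pa(Uₗ));
2. decide, from the graph alone, whether the query is **identifiable** — i.e.
   whether every model that projects onto the same acyclic directed mixed
   graph (ADMG) and agrees with the observational distribution agrees on the
   query;
3. if it is, train the LVM on observational data by MCMC and estimate the
   query by **graph mutilation plus posterior-predictive sampling**: sever
   the edges into the targets, clamp them, and ancestrally sample all
   variables under each posterior parameter draw.

The package's central claim, exercised by its test suite, is that this
estimator is accurate *whenever the query is identifiable*, even though
individual parameters of a latent-variable model are typically not
identified, and even when the number of latent variables is misspecified —
provided the misspecified model projects onto the same ADMG.

## Graphs and identification

`mixed_graph()` holds directed edges, bidirected edges and latent flags, in
two disciplines kept deliberately apart: an *explicit-latent DAG* (latent
nodes flagged) and an *ADMG* (bidirected edges standing for latent
confounding). `latent_project()` converts the former to the latter by the
three simplification rules — drop childless latents, bypass latents with
parents, drop latents whose children are a subset of another's — then turns
each surviving latent into a bidirected clique among its children.

d-separation expands each bidirected edge into a fresh latent common parent
and then applies the moralized-ancestral-graph test; this is equivalent to
native m-separation and much easier to verify, which the test suite does by
exhaustive path enumeration (all DAGs on 3 and 4 nodes with every
conditioning set, randomized mixed graphs on 5 and 8 nodes — full
enumeration of all 5-node graphs with all set triples is combinatorially out
of reach, so coverage beyond 4 nodes is randomized under a fixed seed).

`identify()` tries the back-door criterion, then the front-door criterion
(both as fast paths that also label which textbook criterion applied), then
the complete recursive identification algorithm over confounded districts
(c-components). The recursion manipulates a symbolic *estimand* — an
expression tree of conditionals, sums, products and fractions over observed
variables only — and either returns it or raises a hedge. Soundness is
checked numerically rather than syntactically: on hundreds of random
discrete parameterizations of each benchmark ADMG, the estimand evaluated on
the enumerated observational table must equal graph-surgery truth to 1e-10
(observed agreement is at machine precision). Completeness is inherited from
the published algorithm, not re-proved.

Two evaluation conventions matter. Conditionals with zero-mass conditioning
events contribute zero (the front-door precondition P(x, z) > 0 rules the
case out for well-posed problems; 0/0 → 0 keeps evaluation total). And
ratio-form estimands, such as the napkin motif's, carry a free context
variable — the mediated-chain node — in which the expression is provably
constant for any joint that is Markov to the graph; evaluation averages over
that variable's observational marginal, which equals the constant while
being robust to floating-point noise.

## Node families and their parameters

Each node carries one of four observational families, chosen to match how
the corresponding quantity is measured:

| family            | form                                               | use                              |
|-------------------|----------------------------------------------------|----------------------------------|
| `gaussian_linear` | v = b0 + Σ bₚ·pa + N(0, σ)                         | relative expression, RT-PCR      |
| `bernoulli_logit` | P(v = 1) = logistic(b0 + Σ bₚ·pa)                  | on/off regulatory states         |
| `gamma`           | mean exp(b0 + Σ bₚ·pa), shape k                    | fluorescent-reporter intensities |
| `hill_sigmoid`    | v ~ N(cap·logistic(b0 + Σ bₚ·pa), σ)               | saturating signaling kinetics    |

The Hill family's sign convention deserves a note: its mean is
cap/(1 + exp(−(b0 + Σ bₚ·pa))), so a positively constrained weight
*increases* the mean. The alternative convention (positive sign inside the
exponent) would invert the stated semantics of "increase"/"decrease" edge
types; we adopt the form under which a positive weight on an activating edge
does what the word says. `scale_cap` defaults to 100, the initial molecule
count of the stochastic-simulation benchmark, putting the response on the
abundance scale.

Priors are normal with optional half-line constraints: diffuse N(0, 10)
throughout the benchmarks, informative N(m, 1) with m ∈ [20, 45] for the
latent regulator abundances of the SARS-CoV-2 case (the text states the
range without itemizing parameters; the builder draws the means once from
the case seed and exposes them as an argument), and sign constraints
encoding edge types (positive for activation, negative for repression,
enforced by truncation during MCMC and respected by every posterior draw).

**Latent anchoring.** In the pathway case studies, latent regulators are
fixed at N(0, 1) by near-point-mass priors. A latent's location and scale
are pure nuisance: they are absorbed exactly into the children's intercepts
and weights, so fixing them changes neither the observational model class
nor the projected ADMG — it only removes a non-identified posterior ridge
that MCMC would otherwise have to traverse. The two motivating examples
deliberately keep learnable latent hyperparameters with the stated priors,
because the contrast between non-identified parameters and an identified
query is the point of those demonstrations.

## Inference

`fit()` trains the model by MCMC in JAGS: per-replicate latent values are
sampled alongside the global parameters, targeting the model's full joint
with the declared (truncated) priors. The `glm` block-sampling module is
loaded at package load; block updates of the conjugate linear-Gaussian
substructure mix far better on latent-confounder ridges than scalar Gibbs.
We use the centered parameterization — the usual non-centered trick is a
remedy for gradient-based samplers' geometry and mixes worse under
conjugate block Gibbs. Defaults are 2 chains, 500 warmup and 500 kept
iterations; chain seeds derive deterministically from one user seed, so
fits are exactly reproducible.

Convergence is reported per parameter (split-R̂, effective sample size) by
`diagnostics_report()`, which deliberately distinguishes two levels: with
latent confounding, some parameters are structurally non-identified and
their chains never pin down (enormous R̂ is *expected* there), while the
observational fit and every identifiable query functional converge. The
report's thresholds apply to the parameter level; the query-level checks in
the test suite are the meaningful ones. Divergence counts are reported as
NA — Gibbs sampling has no divergent transitions.

## The estimator and its oracles

`estimate_query()` implements mutilation plus posterior-predictive
sampling: check identifiability on the latent projection (refusing
non-identifiable queries with a typed condition unless explicitly forced —
the forcing flag exists solely to demonstrate the bias of non-identifiable
estimation); clamp the targets and sever their incoming edges (bidirected
ones included — an intervention cuts *all* incoming influence); then for
each of S posterior draws sample every variable L times in topological
order (lexicographic tie-break, for reproducibility) and pool the S·L
outcome draws. Defaults S = 500, L = 20. Both the pooled density (Gaussian
KDE, Silverman bandwidth, 512-point grid) and the per-draw curves are
exposed, the latter reproducing the thin-curve sampling-variability
displays.

Three independent routes validate it:

* `closed_form_linear_gaussian()` — exact interventional means and
  variances by path-coefficient propagation on the mutilated graph
  (all-Gaussian models only);
* `plugin_frontdoor()` / `plugin_backdoor()` — the adjustment formulas
  evaluated directly from data, exactly on empirical tables for discrete
  variables, and by quadratic-with-interaction regression plus a Gaussian
  conditional for continuous ones (adequate for the linear-Gaussian systems
  they validate; they are estimators of convenience, not contributions);
* interventional simulation truth — averaging samples drawn under the true
  parameters (10 000 by default).

On the mediated linear-Gaussian system the three agree within Monte-Carlo
error of one another, which is the front-door-equivalence check at the
heart of the validation suite.

## The benchmark systems and their generators

`build_example()` and `build_case()` construct eight systems. The source
figures were not available in extracted form, so topologies are
reconstructed from the textual constraints — node names, family statements,
latent counts, and above all the stated identification outcomes, which the
catalog test verifies exactly: the confounded bow is not identifiable; the
mediated bow and both feed-forward motifs are front-door identifiable (the
multi-cause one with three simultaneous targets, mediator hns); the napkin
motifs require the full do-calculus; the SARS-CoV-2 sIL6Rα query is
back-door identifiable while the EGFR query needs the do-calculus. In the
SARS-CoV-2 network, the one confounded pair the text leaves unnamed is
placed on (EGFR, IL6AMP) — the placement under which the stated
identification pattern holds. The napkin mediator of the experimental case
is named fnr (the crp → fnr → fur chain); the feed-forward mediator hns
(H-NS silences the cas operon and is regulated by the named factors).

Ground-truth parameters are fixed per case by a stored seed. The motivating
examples draw truth from their stated priors. The pathway cases use a
*realistic-effect law* instead (`draw_true_parameters()`): weights of
magnitude 0.5–2 with random or constrained sign, log-link weights 0.25–1,
Hill weights 0.02–0.08 per abundance unit with intercepts centering the
response near half-maximum, noise SDs 0.5–2, gamma shapes 2–6. Values drawn
from N(0, 10) would saturate every logit and push log-link means across
hundreds of orders of magnitude — diffuse priors express ignorance, not
plausible biology.

The signaling case generates data by exact stochastic simulation
(`gillespie()`): mass-action kinetics with one catalytic production
reaction per activating edge, first-order decay, an Akt-catalyzed Raf
degradation for the one repressive edge, every species initialized at 100
molecules, and replicates created by randomizing the exogenous growth
factors EGF and IGF uniformly on [40, 160]. Rates (production and decay
0.05, inhibition 5e-4) were chosen so steady-state abundances track parent
abundances near 100 and relaxation completes inside the 40-time-unit
horizon; no published rate constants exist for this benchmark, so they are
plain arguments. The SSA itself is validated against closed-form birth-death
moments. Interventions are simulated by clamping: reactions that would
change the clamped species are disabled while its catalytic role is kept.

What the generators do *not* emulate: library-size or batch effects,
count-overdispersion structure of real RNA-seq, measurement-error layers
beyond the stated families, feedback loops (the graphs are acyclic by
construction), or time-course dynamics beyond the SSA endpoint. Passing
tests therefore demonstrate correctness of identification and estimation
under the stated generative families — not robustness to the full messiness
of experimental compendia. The experimental-data cases are run on synthetic
stand-ins drawn from their stated Gaussian models; no expression compendium
is downloaded.

## Evaluation protocol and problem sizes

`run_sampling_experiment()` reproduces the sampling-distribution protocol:
for each training-set size and repeat, generate observational data, fit,
estimate, and compare against simulation truth computed once; both the
correct and the misspecified variant are run, giving the
correct-vs-misspecified convergence comparison (their estimates approach
each other, and truth, as N grows).

The suite's study sizes are desk-scale by design: consistency is checked on
the mediated example at N ∈ {50, 500, 5000} and on the multi-cause and
napkin cases at N up to 2000/1500 with 4–5 repeats; the front-door
equivalence runs at N = 10 000; identification soundness uses 200 random
parameterizations per benchmark ADMG; SSA exactness uses 1000 trajectories.
A napkin fit at N = 2000 costs roughly a minute of MCMC, which is what sets
these sizes. All tolerances are expressed in the estimators' own
Monte-Carlo standard errors, never as absolute constants, so smaller
problem sizes widen bands honestly rather than silently weakening checks.

## Numerical choices and edge cases

* Topological sorting breaks ties lexicographically; seeded runs are
  bit-reproducible end to end (datasets, posterior draws, experiment
  tables).
* The gamma log-link's linear predictor is clamped at 30 inside the sampler
  to keep early adaptation finite.
* Mutilated nodes become point-mass families; `mutilate_model()` followed
  by observational sampling equals interventional sampling draw for draw
  under equal seeds, which is tested.
* Interventions on latent nodes are refused: a target must be observed. The
  restriction is flagged at the model-mutilation boundary.
* Adjustment-set search enumerates candidates by increasing size (capped at
  5 for back-door, 3 for front-door witnesses), so reported witnesses are
  minimal.
* The density summary can degenerate when an outcome is constant (a clamped
  or deterministic node); the estimate then reports the point mass rather
  than a bandwidth-zero KDE.

## Limitations

Cyclic/feedback models, selection bias, conditional effects P(Y | do(x), w)
and counterfactual (layer-3) queries are out of scope. Variational
inference is not offered — the estimator's guarantees lean on
asymptotically exact sampling. The continuous plug-in estimators use fixed
quadratic regression forms and are validation tools, not general-purpose
semiparametric estimators. Identifiability is decided on the graph; a
misspecified *skeleton* (as opposed to a misspecified latent count) voids
the guarantees, and nothing in the package can detect it.
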