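---
title: "Segment-count constrained inference in HMMs: models, algorithms, conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segment-count constrained inference in HMMs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ksegment)
```

## The model

A discrete-state HMM with `M` hidden states generates a hidden path
`x = (x_1, ..., x_N)` from a Markov chain with initial distribution `pi0`
and row-stochastic transition matrix `A`, and observations
`y = (y_1, ..., y_N)` independently given the path from per-state emission
densities (Gaussian with state-specific mean and variance, or categorical
over a shared vocabulary). `hmm()` holds θ = (π0, A, φ) and validates
stochasticity to 1e-8.

A *segment* is a maximal run of identical consecutive states; a path has
`c_x = 1 + Σ_{n≥2} 1(x_{n-1} ≠ x_n)` segments. The package computes, exactly
and in time linear in `N`, quantities of the posterior `p(x | y)` restricted
to events about `c_x`.

## The counting-chain construction

The central device is an auxiliary sequence `s` unrolled deterministically
alongside `x`: `s_1` is fixed by the initial state and `s_n` increments by
at most one per step, so that `s_N` equals the count of interest.
Conditioning on `x`, `p(s | x)` is a chain of delta masses; multiplying it
into the joint leaves `p(x, y)` untouched when `s` is marginalized. All
constrained problems then become classical recursions on the extended state
`(x_n, s_n)`:

* forward pass → `p(s_N = k, y)` for all `k` at once (`kseg_forward()`);
* max-product with backpointers → constrained MAP (`kseg_viterbi()`,
  `kseg_summary()`);
* forward filtering / backward sampling → draws from the conditional
  posterior (`kseg_sample()`);
* forward-backward with the terminal counter restricted → event-conditioned
  site and pairwise marginals (`constrained_marginals()`), the E-step of
  constrained EM.

Three counting variants share one implementation (`counting_standard()`,
`counting_generalized()`, `counting_excursion()`):

* **standard**: `s_1 = 1`, increment whenever `x_{n-1} ≠ x_n`;
* **generalized `(μ, C)`**: `s_1 = μ(x_1) ∈ {0, 1}`, increment when
  `C(x_{n-1}, x_n) = 1` (`C` binary, zero diagonal). Standard counting is
  `μ = 1`, `C(i, j) = 1(i ≠ j)`, and the package's tests verify the two
  induce identical counts path by path;
* **excursions**: a second binary layer `e_n` flags "inside an excursion":
  it switches to 1 on a null→abnormal transition, back to 0 on
  abnormal→null, and is copied otherwise; `s` increments exactly on the
  1→0 switches, i.e. on completed excursions. *Restricted* excursions
  additionally treat a switch between two different abnormal states while
  `e = 1` as pushing `e` out of {0, 1}; the augmented model assigns such
  paths probability zero, which amounts to conditioning inference on the
  feasible set. The enumeration oracle normalizes the same way.

Two conventions the construction leaves open are fixed as follows and
asserted in tests:

* an excursion still open at `n = N` (`e_N = 1`) is **not** counted — only
  completed returns to the null set count;
* combining excursion counting with a nontrivial `(μ, C)` is rejected
  rather than given ad-hoc semantics.

## Events, absorption, and the k_max + 1 summary

Events are `{c = k}`, `{c ≤ k}`, `{k1 ≤ c ≤ k2}` and `{c > k}`
(constructors or strings; the grammar deliberately excludes `c >= k` — use
`c > k-1`). Internally every event maps to a counter cap and a set of
allowed terminal values: the counter *absorbs* at `cap = k + 1` (or
`k2 + 1`), so values below the cap stay exact and the cap accumulates
exactly the tail mass `p(c > cap − 1, y)`. Maximizing, marginalizing or
sampling the terminal counter over the allowed set then handles all event
types with a single recursion whose state space is `(k_max + 2) · M`
(counter values `0..k_max+1`; standard counting never occupies 0, costing
one unused slot in exchange for a uniform layout).

`kseg_summary()` extracts per-terminal-value optima from one pass: the MAP
path for each `k` up to `k_max` plus the MAP under `{c > k_max}`. The
standard Viterbi path always appears — at the entry whose `k` equals its own
segment count, or at the absorbing entry when that count exceeds `k_max`.
Infeasible entries are reported with score `-Inf` rather than aborting the
summary. A zero-probability event in `kseg_viterbi()` / `kseg_sample()` /
`constrained_marginals()` raises a condition of class
`"ksegment_infeasible"`; zero probability is an exact log-domain `-Inf`,
never a tolerance judgement.

## Numerical conventions

* All recursions run in the log domain with log-sum-exp accumulation; there
  are no scaling constants. Zero probabilities are `-Inf` and transitions
  with `A[i, j] = 0` are never traversed.
* Viterbi ties are broken deterministically toward the lexicographically
  smallest extended state (smaller counter, then smaller state index); the
  plain `viterbi()` inherits the smallest-state-index rule.
* The dynamic programming core (forward, backward, max-product, backward
  sampling on the `(x, e, s)` state) is C++ (Rcpp). The counter is bounded
  by `min(position, cap)`, which keeps the full, absorption-free
  decomposition `Σ_k p(s_N = k, y) = p(y)` affordable even at `N = 10^4`
  (used as a self-check in the tests at tolerance 1e-8).
* Sampling consumes one uniform draw per position in order `n = N..1` per
  sample, from a single `set.seed(seed)` per call, so streams are exactly
  reproducible.
* The best-list (top-P) decoder uses Lawler partitioning on the first point
  of divergence with precomputed backward max messages; it is exact, and
  returns all `M^N` paths with a warning if `P` exceeds them.

## Learning under constraints

`constrained_em()` maximizes `log p(event, y)`. The E-step computes
event-conditioned site and pairwise marginals on the augmented model; the
M-step is the ordinary Baum–Welch update applied to those marginals:

* Gaussian variances are floored at `1e-8 · var(y)` (constrained posteriors
  concentrate mass and can collapse a component's variance); a warning is
  logged when the floor binds.
* States that receive no posterior mass keep their emission parameters, and
  transition rows with zero expected mass collapse to a self-transition.
  The Q-function is flat in such rows, so some convention is required; the
  self-transition choice keeps the fitted matrix consistent with the
  constraint's support instead of leaking initialization values, and makes
  the fitted transition matrix under `{c ≤ 1}` exactly the identity.
* Convergence: relative change of the objective below `tol` (default 1e-6,
  `max_iter` 500). The trace is monotone up to 1e-8 and is checked
  throughout the tests.
* Categorical fits accept a Dirichlet pseudo-count (`smooth`) and can hold
  designated emission rows fixed — used by the topic-model fitter where the
  relevant topic's emissions come from supervised counts.

`prospective_vs_retrospective()` compares, per `k`, `log p(c ≤ k, y)` from
constrained EM against evaluating the unconstrained fit under the
constraint. Initializing the constrained runs at the unconstrained solution
guarantees (by EM monotonicity) that the prospective value is never lower;
the default EM initialization spreads means over `[min(y)/2, max(y)/2]`,
sets large variances, and uses the sticky transition matrix
`A_ii = 10/12, A_ij = 1/12` — an informative recipe that mirrors how the
benchmark data are generated.

`constrained_gibbs()` alternates exact constrained path draws with exact
conjugate parameter draws. The prior families are fixed to what conjugacy
requires: Dirichlet on `pi0` and transition rows, Normal–Inverse-Gamma on
Gaussian emissions, Dirichlet (default concentration 1, the add-one rule)
on categorical rows. Non-conjugate configurations are rejected. Model
selection across `k` is deliberately left to external criteria (held-out
likelihood); the package provides no automatic chooser, and no
importance-sampling combination across constraints.

## Simulation designs and what they show

`simulation_design()` defaults to the three-state Gaussian benchmark used
across the test-suite: means `(-2, -1, 1)`, σ = 0.9, uniform `pi0`,
transition matrix

```
0.980 0.015 0.005
0.005 0.980 0.015
0.015 0.005 0.980
```

and `N = 1000`. Under this design segment counts are
`1 + Binomial(N−1, 0.02)` in distribution, which the generator's tests check
via a central 99.9% envelope. It emulates a piecewise-constant signal with
moderate class overlap (neighboring means one standard deviation apart) —
the regime where constrained decoding is informative. It does **not**
emulate heavy-tailed noise, heteroscedastic states, long-range dependence,
or position-dependent transition rates; passing tests say nothing about
robustness to those.

`synth_documents()` generates the two-topic retrieval benchmark: background
documents from an irrelevant-topic word distribution with zero or more
relevant-topic segments inserted at recorded, non-touching positions
(insertion count and length are exposed parameters, drawn per document).
Two topics, a shared small vocabulary and well-separated emission profiles
are a deliberate simplification; real corpora add vocabulary burstiness and
topic drift that the generator does not model. Detection quality uses the
interval Jaccard ratio with the conventional 0.8 threshold, and the
per-document detection rate divides by the *requested* list size `k`, not
the number of predictions made — so returning fewer, high-precision
segments is not rewarded per se. Segmental classification error is reported
after the optimal one-to-one relabeling of states, since state labels are
not identified.

Problem sizes in the shipped tests were chosen to keep the whole suite in
the minutes range while leaving no algorithmic path untested: enumeration
cross-checks use `M ∈ {2, 3, 4}`, `N ≤ 10` (hundreds of instances at
tolerance 1e-10); statistical checks use 20,000–50,000 draws at `N = 4`
with χ² at α = 0.001; benchmark-design experiments use the full `N = 1000`
with 10–20 replicates; the linearity check times the forward recursion at
`N = 10^3..10^5` and `k_max ∈ {5, 50}` against the `O(k_max M² N)` model.

## Limitations

* Exact counts only for single-step-increment counters; waiting-time or
  pattern statistics requiring larger increments are out of scope.
* Continuous-state, semi-Markov and explicit-duration models are out of
  scope; so are approximate/beam variants of the constrained recursions.
* `kseg_summary()` keeps backpointers for the full extended state, so its
  memory grows as `N · M · (k_max + 2)`; for very long sequences prefer
  `kseg_forward()` (constant memory in `N`) plus targeted decoding.
* For events far in the posterior tail the conditional probabilities reach
  the log-domain floor; `p(event) = 0` is reported via `-Inf`/infeasibility,
  but probabilities below about `exp(-745)` are indistinguishable from zero
  in double precision.
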