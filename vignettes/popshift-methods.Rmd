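---
title: "Methods: signatures, mixtures, and population shifts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signatures, mixtures, and population shifts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popshift)
```

`popshift` treats two population-composition artifacts of bulk expression
profiling — the recurrent slow-growth signature of deletion compendia, and
the cell-cycle population shift underlying much of the environmental stress
response — as explicit, removable models. This vignette documents the
methods, their assumptions, the numerical choices, and what the synthetic
benchmarks do and do not demonstrate.

## The slow-growth signature as a first singular mode

The input is a complete genes × samples matrix $M$ of log2 expression
ratios (M-values) against a common reference. The SVD
$M = U S V^{\mathsf T}$ decomposes $M$ into rank-1 modes
$s_k U_k V_k^{\mathsf T}$ ordered by decreasing importance. When many
samples share one dominant expression program — here, the transcriptional
correlate of slow growth — that program is captured by the first mode:
$U_1$ is the gene pattern, $V_1$ its per-sample loading, and
$s_1^2/\sum_k s_k^2$ the fraction of total variation it carries.
`remove_first_mode()` returns $M^* = M - s_1 U_1 V_1^{\mathsf T}$, whose
columns are exactly orthogonal to $U_1$; `remove_signature_from_profile()`
applies the same idea to a single external profile $p$ by Gram–Schmidt,
$p' = p - \langle p,\hat u\rangle \hat u$, with $\hat u$ the signature
re-normalized over the genes the profile shares with the model.

Assumptions worth making explicit:

* **One dominant mode.** The method removes exactly one rank-1 component.
  If slow growth contributes several modes, or a biological program rivals
  it in variance, the first mode is a mixture and removal is partial. The
  variance fraction reported by `glance()` is the diagnostic.
* **No centering by default.** M-values are already ratios against a
  reference, so the mean profile is meaningful signal; `center = TRUE` is
  available for classical PCA behavior.
* **Sign convention.** Singular vectors are defined up to sign. We orient
  so the largest-magnitude entry of $U_1$ is positive (first index on
  ties); $V_1$ and the signature profile follow. This makes results
  deterministic across BLAS implementations.
* **Gene matching is by identifier,** with order realignment and an
  explicit warning for dropped genes; positional matching across platforms
  is never attempted.

The *signature profile* in M-value units is the largest-norm column of
$M^{(1)}$ (ties broken at the smallest column index), i.e. $s_1 v_{1j^*}
U_1$; per-sample similarity is the projection $\langle m_{\cdot j}, U_1
\rangle$, proportional to covariance for centered data.

## Spline-weighted deconvolution into cycle phases

A bulk profile of an asynchronous population is the average of the
profiles of its cells. If cells differ mainly by cell-cycle position, a
stress profile $y$ (over genes) should be expressible as a weighted sum of
cycle time-course profiles: $\hat y = X w$, where $X$ is the genes ×
timepoints cycle matrix and $w$ a vector of population fractions
($w_t \ge 0$, $\sum_t w_t = 1$).

To prevent overfitting 14 free weights, a single cubic spline governs all
of them: its four control points sit at fixed fractions 0.2, 0.4, 0.6, 0.8
of the cycle duration (78, 156, 234, 312 min for a 390-min cycle), and only
the four ordinates are free. `spline_weights()` evaluates the interpolating
spline (`stats::splinefun`, Forsythe–Malcolm–Moler end conditions; a
natural-spline mode is available) at the timepoints, clamps negatives to
zero and normalizes to the simplex. The ordinates themselves are
unconstrained and carry no meaning beyond the weights they induce.
`fit_deconvolution()` maximizes the Pearson correlation
$r(Xw, y)$ with Nelder–Mead (`stats::optim`, default tolerances), restarted
at least 10 times from ordinates drawn uniformly in $(0,1)$. The fit is
declared converged when the best three restarts agree — coefficient of
variation of their correlations $\le 0.01$ and pairwise correlation of
their weight vectors $\ge 0.95$ — otherwise restarts continue (one at a
time) to a budget of 100, after which the best fit is returned flagged
unconverged. Restarts that clamp to an all-zero spline are scored $-\infty$
and excluded; ties in the top-3 selection break by restart index. The
correlation objective makes the fit invariant to affine rescaling of the
target, which is the right behavior for log-ratio data whose absolute scale
mixes RNA amount and normalization choices.

Three guards accompany every serious fit, each refitting from scratch:
permuting which gene carries which target value
(`randomize_gene_labels_control()`), independently permuting every
timepoint column of the cycle matrix (`randomize_matrix_control()`), and
split-half cross-validation (`cross_validate()`: control points from a
random half of the genes, correlation scored on the held-out half). On
genuine shared structure the first two collapse toward zero while the third
matches the full fit.

### Identifiability: what the weights can and cannot mean

The weight vector is only as identifiable as the dictionary $X$ is rich.
Two structural degeneracies matter:

1. **The $t=0$ column is identically zero** (M-values are relative to
   $t=0$), so its weight affects the virtual profile only through the
   normalization; any mass parked there rescales the rest without changing
   $r$. The same applies to a final timepoint that completes a full cycle.
   The default fit keeps the $t=0$ weight (the natural "14 weights"
   convention); since it cannot influence the correlation, interpreting it
   requires external information.
2. **Low-rank trajectories.** The bundled generator's default single-cosine
   trajectories, $x_g(t) = A_g[\cos(2\pi(t/D - \phi_g)) -
   \cos(2\pi\phi_g)]$, span exactly two gene-space directions
   ($A\cos 2\pi\phi$ and $A\sin 2\pi\phi$), so $X$ has rank 2 and the map
   $w \mapsto Xw$ collapses 14 dimensions onto a plane: infinitely many
   weight vectors produce *identical* virtual profiles. On such data the
   achieved correlation is a valid measure of explanatory power, but the
   individual weights are not unique, and the restart-agreement check
   correctly reports non-convergence — the honest reading of its `FALSE` is
   "the optimum is a ridge, not a point". With `n_harmonics >= 2` the
   generated trajectories span the full timepoint space and the planted
   weights are recovered essentially exactly (unit tests demonstrate weight
   correlation 1.0 with convergence in the minimum 10 restarts). Real
   synchrony time courses contain many waveforms beyond the first harmonic
   and sit in the identifiable regime; the rank (or the singular spectrum)
   of the supplied series is the user's diagnostic.

## The START-arrest slot model

The cycling population is a circular array of $n$ one-minute slots (default
77: G1 21, S 14, G2 14, M 21, M.G1 7), each holding the relative number of
cells at that cycle position; each simulated minute moves every slot's mass
to the next slot, the last wrapping to the first. Division transfers
relative mass unchanged — there is no doubling term — because the state is
a *distribution*: this is the only convention under which the
unsynchronized uniform state is a fixed point, matching the observation
that an undisturbed population stays asynchronous. A shock at $t=0$ erects
a barrier at the START checkpoint, between slots 14 and 15: the 14→15
transfer is blocked for the 25-min recovery, upstream slots keep feeding
slot 14 (mass piles up; slots are not exclusive), and the slots beyond
START empty out. Release is deliberately pluggable because the recovery
rule is underdetermined by the data the model targets:

* `cohort` (default): the barrier lifts and the accumulated mass advances
  as one synchronized block — the simplest rule that produces a
  synchronized-cohort wave; the deterministic model never disperses it.
* `drain`: at most one steady-state slot-mass ($1/n$) passes per minute
  until slot 14 is back to steady state.

Readouts: cells in slots 1–28 are scored 1N DNA content (G1 precedes
replication), the rest 2N; for display the 77 slots average into eleven
7-min bins; and the expression-magnitude model takes each bin's occupancy
fold change against $t=0$ (with an $\epsilon = 10^{-6}$ floor against empty
bins), keeps bins changing more than 1.7-fold — the same threshold applied
to expression data — and averages their log2 fold changes, up and down
separately, finally normalizing each curve to its own maximum: the
proportionality constant between cell-number changes and bulk expression
changes is not identifiable without matched real data, so the output is a
shape, not a scale. Two consequences the model predicts, and the test suite
verifies against an independently coded bookkeeping oracle: the 1N fraction
stays exactly at $28/77$ through $t = 14$ (early-G1 gain balances the
emptying wave until it crosses slot 28) before rising to $39/77$ at
$t = 25$, and the magnitude transient switches on only at $t = 5$, when the
pile bin first exceeds 1.7-fold ($({7+t})/{7} > 1.7$).

## Enrichment and growth-rate statistics

Changed genes are selected with strict inequalities — $|M| > \log_2 1.7$
and $p < 0.05$ — matching the "more than 1.7-fold" convention used
throughout; a strain counts as robustly affected when strictly more than 3
transcripts qualify. Set enrichment is the exact upper-tail hypergeometric
probability $P(X \ge k)$ for overlap $k$ between a selection of size $n$
and a set of size $K$ in a universe of $N$ genes (genes outside the
universe are dropped from both sides with a message — platform mismatches
are routine); multiple sets are Bonferroni-corrected, $\min(1, pm)$.
Doubling time is $1/\text{slope}$ of the least-squares line of
$\log_2(\mathrm{OD}_{600})$ against time over the exponential window —
defaulting to the trailing half of the supplied readings, since "the linear
part just prior to harvest" is in practice a manual choice that an explicit
`window` argument overrides — and strain-versus-reference growth is
reported as $\log_2(dt_{\text{mut}}/dt_{\text{wt}})$.

## Synthetic data: what it emulates, and what it does not

All generators are pure functions of their parameters and a seed, and they
carry their ground truth:

* `make_compendium()` (2000 genes × 200 strains by default) plants a rank-1
  signature — 600 genes, half at $+1$, half at $-1$ — whose per-strain
  loading equals the strain's log2 relative doubling time, drawn uniform on
  $(-0.1, 1)$ to span the range observed across deletion collections; 40
  strains get 20 private ±2 spikes apiece (the mutant-specific responses
  that coexist with the shared signature), over N(0, 0.25²) noise, a noise
  scale at which single-array M-values of unchanged genes rarely cross the
  1.7-fold threshold. P-values come from a two-sided z-test against the
  known noise scale — cheap, and sufficient to exercise threshold logic.
* `make_cycle_series()` mirrors a 14-point, 30-min elutriation geometry
  (0–390 min), single-cosine by default (see the identifiability note).
* `make_mixture_target()` builds targets exactly as the deconvolution
  assumes, from known control ordinates.
* `make_enrichment_scenario()` plants a 50-gene target set *outside* the
  signature support, adds a direct $+1.5$ effect, contaminates the profile
  with the shared signature at loading 0.8 (mid-range of the growth-rate
  distribution), and supplies a matching compendium so the signature can be
  learned and removed. Before removal the contamination drags hundreds of
  signature genes over the selection threshold and dilutes the target set's
  enrichment; after removal the selection collapses to the direct effect.
* `make_growth_curve()` is exponential OD600 from 0.05 with optional
  log-normal noise.

What passing these benchmarks does **not** show: robustness to microarray
technical structure (dye bias, spatial artifacts, missing-not-at-random
holes), to synchrony loss in real time courses, to signatures that occupy
more than one singular mode, or to p-values with realistic
variance-estimation noise. The generators are designed to make the
*algorithms'* contracts testable, not to simulate a platform.

Missing values are filled by k-nearest-neighbour imputation (default
$k = 10$): neighbours ranked by RMS difference over co-observed columns,
holes replaced by the neighbours' column mean, with a column-mean fallback
(and a warning) when fewer than $k$ eligible neighbours exist. Observed
entries are never modified and complete matrices pass through untouched.

## Problem sizes and runtime

The test suite and `scripts/acceptance.R` run everything at the generator
defaults: 2000 × 200 compendia for signature recovery, 400-gene series for
deconvolution fits and cross-validation (20 half-splits), 200-gene series
for the two randomization controls (20 each), 200-min simulator traces
checked minute-by-minute against the oracle in both release modes, and
exhaustive hypergeometric enumeration for every design up to $N = 12$.
These sizes keep a full run in a few minutes on one core while leaving
every recovery margin wide (e.g. signature cosine 0.998 against a 0.95
bound).

## Known limitations

* One signature, removed once: serial extraction of further modes is out of
  scope, as are sparse or robust SVD variants.
* The deconvolution reports correlation, not a goodness-of-fit test; use
  the randomization controls as the null reference.
* The slot model is deterministic and slot-synchronous: no cell-to-cell
  variability in cycle length, no dispersion of the released cohort, no
  fitting of model curves to measured flow-cytometry or expression data.
* CLI subcommands cover the pipeline stages; plotting stays in R via
  `autoplot()`.
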