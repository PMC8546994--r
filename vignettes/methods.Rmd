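---
title: "Methods: temporal alignment and constrained DBN learning for longitudinal multi-omics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: temporal alignment and constrained DBN learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its methods: the model and its
assumptions, the tunables that matter, what the synthetic generator does and
does not emulate, and the numerical choices made where the design was
genuinely open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## Data model and preprocessing

An `OmicsDataset` holds, per subject, irregular longitudinal matrices for
each dynamic omic layer (taxa, microbial genes, metabolites), optional static
layers (host genes profiled once, used as per-subject constants), and
environmental covariates attached to samples. Time is stored in days; a
metadata column named `week` is converted as week × 7, because cohort
designs of this kind mix week labels with day-based sampling rates.

Preprocessing follows a fixed order: total-sum scaling per omic and sample
(each layer sums to 1), a metabolite filter (drop features with pooled mean
relative intensity < 0.1% or zero variance over the originally sampled
points), a subject filter (every dynamic omic layer must have ≥ 5 measured
time points), optional top-variance feature selection, and finally an
optional additive log-ratio (ALR) transform of taxa against a fixed
reference species. The ALR reference's transformed trajectory is identically
zero. Zeros are replaced by half the smallest nonzero value of the layer
*before* the log — this keeps every transformed value finite, keeps
`log(x/x_ref)` exact for strictly positive values, and is the only place a
pseudocount enters. A consequence worth knowing: ALR is exactly
scale-invariant only on zero-free data; on data with zeros the pseudocount
couples weakly to the normalization, and the tests assert exact invariance
only in the zero-free case.

The mean-intensity threshold is interpreted on the sum-to-1 scale, so
"0.1%" is 0.001. Ties in top-variance selection break lexicographically by
feature name, purely for reproducibility.

## Trajectories

Each subject/feature series is represented by a cubic spline with knots at
the observed times. Two modes exist behind `spline.smoothing`:

* `"none"`: exact interpolation with Forsythe–Malcolm–Moler end conditions,
  which reproduce any global cubic exactly — this is the mode the oracle
  tests use, and the contract is residuals < 1e-8 at the observed times;
* `"gcv"` (default): `smooth.spline` with the smoothing parameter chosen by
  generalized cross-validation per curve. The underlying study says only
  that smoothed curves enable principled estimation, without naming a
  criterion; GCV is the standard automatic choice and is config-exposed.

Curves are never extrapolated: evaluation outside the observed domain is an
error, and resampling intersects the uniform grid `{origin, origin + rate,
…}` (forward from the origin) with the domain. For relative-abundance data
negative spline excursions are clipped to zero at resampling time; in ALR
mode values are legitimately signed and are not clipped.

## Temporal alignment

Subjects progress at different rates, so one subject's day 40 need not be
another's. Alignment warps each subject's clock linearly, τ(t) = a·t + b,
onto a reference subject. The error functional is a declared design choice
(the study defers to earlier work without restating a formula): the squared
difference between the reference curve and the warped sample curve,
integrated by the trapezoid rule on a 1-day grid over the overlapping
interval, divided by overlap length, summed over the alignment features.
Candidates are searched on a grid (a ∈ [0.5, 2] step 0.05, b ∈ [−30, 30]
step 1) and refined by Nelder–Mead; a candidate must overlap at least 50% of
the reference domain, which prevents degenerate "perfect" alignments on
vanishing overlaps. The reference subject is the one minimizing the total
pairwise error, ties broken by subject id. Subjects whose error exceeds
μ + 2δ (moments over non-reference subjects) are dropped — possibly none.
The warp learned on one omic layer is applied unchanged to the subject's
other dynamic layers; values are never modified, only time stamps.

The alignment layer defaults to microbial genes with the 10 highest-mean
features (`alignment.layer`, `alignment.n_features`): expression has been
reported to be less dominated by technical noise than taxon abundances, and
the rule for selecting alignment features is not otherwise specified, so a
simple mean-abundance cut is used and exposed in config.

## The two-slice DBN

Aligned, gridded data are arranged into one row per consecutive grid pair
(tᵢ, tᵢ₊₁) per subject; |D| is the row count. Static host genes and the
environmental variable are copied into both slices; the variable named
`week` takes the aligned grid time divided by 7 (the raw-versus-aligned
choice is not settled by the source material; the aligned reading is
implemented and the interpolating alternative applies to any other env
column). Each dynamic node at slice t+1 carries a conditional linear-
Gaussian CPD; parameters are the Gaussian MLE (OLS coefficients, mean
squared residual as σ², floored at 1e-9 so noiseless fits keep a finite
log-likelihood). Parameters are tied across time: one CPD per node, with
intra-edges estimated within slice t+1.

Structure search is greedy hill-climbing on the BIC score
`log P(D|Θ,G) − |Θ|/2·log|D|`, with |Θ| counting β₀, β₁..β_k and σ² per
child. The search starts from a self-loop inter-edge on every dynamic node
and repeatedly adds the single constraint-valid edge with the largest
strictly positive BIC gain (the score decomposes per child, so a gain is
just the child's log-likelihood improvement minus log|D|/2). There are no
deletions or reversals; ties break lexicographically by (child, parent,
lag); rank-deficient candidate designs are treated as gain −∞. The
self-loop counts toward the 3-parent cap, so at most two further parents
can join a child — consistent with the per-iteration edge bound the
constraint framework implies.

The constraint matrix is the model's main inductive bias. The *skeleton*
preset allows, within a slice, environment → taxa, host genes → taxa,
taxa → genes, genes → metabolites; across slices, metabolites → taxa plus
self-loops for every dynamic node; environmental and host-gene nodes accept
no edges. The *augmented* preset adds direct taxa → metabolite edges; their
slice placement is genuinely open, so both intra and inter cells are enabled
by default behind `dbn.augmented_intra` / `dbn.augmented_inter`. Custom
matrices load from JSON.

Bootstrap confidence: each of `n_reps` repetitions resamples subjects with
replacement (a subject drawn twice contributes its rows twice), rebuilds the
table, and relearns. The reported network is the union of edges with
support = occurrence fraction and averaged coefficients — the union is
deliberately larger than any single-repetition network. Per-repetition seeds
derive from the master seed, so results are independent of execution order.

Edge influence is reported as the standardized coefficient
β·sd(parent)/sd(child) (`normalized_weight`); the original normalization
formula is not restated in the source material, and the standardized
coefficient is the declared surrogate: it is invariant to rescaling either
variable and preserves sign. Metabolite → taxon edges are ranked for
follow-up by |normalized weight| × bootstrap support.

## Evaluation

*Forward prediction.* Leave-one-subject-out: train on the remaining
subjects (a single structure learn per fold by default — whether the
cross-validated predictions should use bootstrap-averaged coefficients is
not specified, and the single-model fold is the tractable reading; a
`cv_bootstrap` flag enables the alternative), then predict each target node
at every grid time from the second onward, feeding *observed* values —
inter-parents from tᵢ, intra-parents from tᵢ₊₁ — never chained predictions.
In relative mode predicted taxa are clipped at zero and renormalized to the
simplex before computing the per-feature mean absolute error; the overall
MAE averages features, then subjects.

*Edge validation.* A database of known (parent, child) pairs with declared
parent/child universes scores the network: edges of the database's kind
whose endpoints are both in the universes are *evaluable*; listed pairs are
*validated*; precision is their ratio, swept over bootstrap-support
thresholds 0, 0.1, …, 0.9 (strictly-greater selection). Chance significance
uses the exact Poisson-binomial upper tail over per-edge chance
probabilities, computed by the O(n²) convolution recursion — no normal
approximation — where an edge's chance probability is its child's validated
in-degree divided by the parent-universe size. This per-child heterogeneity
is the reason a plain binomial test is wrong: hub metabolites or essential
genes are validated against almost any parent. The tail is computed over the
same evaluable set as precision, for consistency between the two numbers.
The random baseline draws, 1000 times, as many edges as the learned network
from the constraint-allowed pair list (without within-run duplicates) and
averages both metrics.

## The synthetic world

`generate()` draws a constraint-respecting random DBN — self-loops always
present, cross-edges per allowed cell with probability `edge_density`
(default 0.15), coefficient magnitudes in [0.5, 1] with 33% negative, at
most 3 parents per child — and simulates each subject forward through the
CPDs on the reference grid (default 50 subjects, 25 points, 14 days apart,
process noise σ = 0.1), after a 50-step burn-in toward stationarity.
Stability is enforced on the *effective* slice-to-slice transition
(I − B)⁻¹A, where A and B collect inter- and intra-slice coefficients: a
condition on A alone is insufficient, because intra-slice chains can amplify
a stable A into divergence (this was observed, not hypothesized — an early
draft checked only A and produced series with standard deviations near
1e10).

Defaults are deliberately the learner's own model family: identity warps, no
sampling jitter, no missingness, raw (latent-value) emission. Under these
defaults a recovery failure indicates a bug, not model mismatch — that is
what the green structure-recovery tests establish, and *only* that. The
knobs that make the data realistic — subject-specific linear warps, ±3-day
jitter, missingness, softmax emission onto the simplex per omic — are
exercised explicitly by the alignment and IO tests, which make weaker
claims (warp recovery within a grid step; round-trips; monotone behavior).
Softmax emission breaks the linear-Gaussian family on purpose; structure
recovery through it is not asserted anywhere, and a user should not expect
exact recovery through compositional emission either. Environmental
("week") edges are off by default in the generator: a linear-in-time parent
makes the simulated process non-stationary and swamps the autoregressive
signal that the recovery tests target.

Ground truth ships with the dataset: the true model, the true warps, and
validation databases assembled from the planted taxon → gene and
taxon → metabolite relations (optionally diluted with decoy pairs), so every
pipeline stage can be tested without downloads.

## Numerical choices and limitations

* σ² is floored at 1e-9; BIC gains must exceed 0 strictly; candidate ties
  break lexicographically — all three keep runs bit-reproducible.
* The network TSV writes numeric fields at 17 significant digits and
  round-trips exactly; dataset TSVs canonicalize subject/time order and
  round-trip at 12 significant digits.
* Greedy search is additions-only and can, in principle, prefer a
  correlated proxy parent over the true one when several parents carry
  overlapping signal; the exhaustive-enumeration oracle in the tests bounds
  greedy from above rather than asserting equality.
* Alignment is linear by design; nonlinear (dynamic-time-warping) alignment
  is out of scope, as are discrete CPDs, Bayesian–Dirichlet scoring, and any
  runtime database lookups.
* The configuration surface is a single JSON file; YAML is not supported
  because no YAML parser is part of the package's minimal dependency set.
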