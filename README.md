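# modbn — dynamic Bayesian networks for longitudinal multi-omics microbiome data

`modbn` reconstructs temporal interaction networks from longitudinal
multi-omics microbiome studies: microbial taxon abundances, microbial gene
(e.g. enzyme-module) expression, metabolite intensities, baseline host gene
expression, and environmental covariates, measured repeatedly and irregularly
over months for tens of subjects. It is aimed at computational biologists who
have per-omic feature tables plus sample metadata and want an interpretable,
validated model of who-drives-whom over time.

## The model

Each subject's series is first normalized (total-sum scaling per omic, with
an optional additive log-ratio transform of taxa against a fixed reference
species), fitted with cubic B-spline curves, and temporally aligned to an
optimal reference subject by a linear warp τ(t) = a·t + b chosen to minimize
the squared curve difference over the overlap. Warps learned on one omic are
propagated to the others, subjects whose alignment error exceeds μ + 2δ are
dropped, and the aligned curves are sampled on a uniform grid (default every
14 days).

On the gridded data `modbn` learns a two-slice dynamic Bayesian network with
conditional linear-Gaussian local distributions: each node x at slice t+1 is

    x | u1, …, uk  ~  N(β0 + Σi βi·ui, σ²),

with parents taken from slice t (inter-edges) or the same slice
(intra-edges). Structure search is greedy hill-climbing scored by

    BIC(G, D) = log P(D | Θ, G) − |Θ|/2 · log |D|,

initialized with a self-loop for every dynamic node, restricted by a
biologically motivated constraint matrix (environment/host genes → taxa →
microbial genes → metabolites within a slice; metabolites → taxa across
slices; the *augmented* preset additionally allows direct taxa ↔ metabolite
edges), and capped at 3 parents per child. Edge confidence comes from a
subject-level bootstrap (resample subjects with replacement, relearn, report
each edge's occurrence fraction). Models are evaluated by leave-one-subject-
out forward prediction (mean absolute error of renormalized taxon
compositions) and by in-silico validation of taxon→gene / taxon→metabolite
edges against an interaction database, with precision, an exact
Poisson-binomial chance-validation tail, and a 1000-network random baseline.

## Worked example

```r
library(modbn)

sim <- generate(simulation_config(n_subjects = 12, n_taxa = 4, n_genes = 3,
                                  n_metabolites = 3, n_host_genes = 2,
                                  n_points = 12, seed = 42))
rs  <- resample_dataset(sim$dataset, rate_days = 14, origin = 0,
                        smoothing = "none")
tab <- build_observations(rs)
m   <- learn_structure(tab, "augmented")
m
#> DBNModel: 10 children, 22 edges (constraints: augmented, BIC: 1082.753)

truth <- sim$truth$model$edges
mean(do.call(paste, m$edges[1:5]) %in% do.call(paste, truth[1:5]))
#> [1] 0.9545455
```

The learned model has one conditional-Gaussian CPD per dynamic node (10
children here); 21 of its 22 edges (self-loops plus planted cross-edges)
match the generator's ground truth from a single run on this small
12-subject dataset — at the default scale (50 subjects) with bootstrap
support filtering, recovery is essentially exact. Bootstrapping
(`bootstrap_network(rs, "augmented", n_reps = 100, seed = 1)`) adds a
support fraction to each edge; `loocv_mae()` reports forward-prediction
error; `validate_edges()` scores the network against an interaction database.

A JSON-configured command-line pipeline covers the same flow end to end:

```r
run_pipeline(list(seed = 1, out = "out",
                  simulate = list(n_subjects = 12, seed = 1)))
# writes out/network.tsv, out/network.graphml, out/warps.tsv,
#        out/prediction_report.tsv, out/effective_config.json
```

or `Rscript -e 'modbn::main_cli()' run --config cfg.json --seed 1 --out out`.

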