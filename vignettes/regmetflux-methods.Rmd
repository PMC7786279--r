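---
title: "Methods: integrated regulatory-metabolic modeling with regmetflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrated regulatory-metabolic modeling with regmetflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(regmetflux)
```

This vignette is the package's own account of the science it
implements: the models, their assumptions, the tunable parameters, the
numerical choices, and what the synthetic study conditions do and do not
demonstrate.

## Constraint-based core

A metabolic model is a set of reactions with stoichiometry, flux bounds
(mmol·gDW⁻¹·h⁻¹) and optional gene–protein–reaction (GPR) rules. Flux
balance analysis assumes steady state (`S·v = 0`) and maximizes the
biomass pseudo-flux, a proxy for growth rate, within the bounds
`a_j ≤ v_j ≤ b_j`. Bounds missing from an SBML file default to ±1000,
the conventional "effectively unbounded" value in constraint-based
modeling; irreversible reactions default to `[0, 1000]`.

The LPs are solved by `pracma::linprog` behind an internal wrapper that
shifts variables to the solver's native nonnegative domain
(`x = v − lb`), encodes upper bounds as inequality rows, and substitutes
out fixed (`lb = ub`) variables before pivoting — fixed variables arise
constantly from knockouts, and the degenerate rows they would add
destabilize simplex pivoting. Feasibility is reported honestly: an
infeasible LP yields status `infeasible`, never an exception, and a
knockout that cannot grow reads as growth ratio 0 (lethal).

Numerical tolerances: LP feasibility at the solver's default
(~1e-9-grade pivot tolerances), all reporting comparisons at 1e-6, and
the mass-balance residual `|S·v|` of every returned optimum is below
1e-6 (enforced by tests).

GPR rules use continuous Boolean semantics — AND is the minimum of its
children (a complex limited by its scarcest subunit), OR the maximum
(the best isozyme) — the standard convention shared by PROM-style and
E-Flux-style integration. A hard gene deletion sets the deleted genes to
0, all others to 1, and closes (`[0, 0]`) each reaction whose rule
evaluates to 0. Genes missing from an activity map default to 1, so an
absent measurement never fabricates a constraint.

Plain FBA optima have degenerate flux vectors, which would make
per-reaction flux comparisons across patients irreproducible. Flux
tables for the reprogramming classifier therefore default to
parsimonious FBA: among vectors achieving at least 99.9% of the optimal
growth, the one minimizing total absolute flux. The 0.999 optimality
fraction (configurable) trades exact optimality for numerical
robustness of the flux-minimization stage; plain FBA remains available
(`cohort_flux_table(..., parsimonious = FALSE)`).

## PROM-style regulatory integration

Expression is binarized at a single pooled quantile (default 0.33, the
PROM convention) of all finite values; a value strictly above the
threshold is ON. Per edge, `P(target ON | TF OFF)` is the raw count
fraction over TF-OFF samples — no pseudocount, matching the plain
conditional-probability definition. When fewer than `min_off_samples`
(default 5) TF-OFF samples exist, the probability is set to 1 and
flagged: insufficient evidence must not fabricate lethality.

A TF knockout re-evaluates each reaction's GPR with every regulated
target gene at its conditional probability (other genes at 1), giving
κ ∈ [0, 1]; the upper bound tightens to `κ·Vmax` when `Vmax > 0`, the
lower to `κ·Vmin` when `Vmin < 0`, with Vmin/Vmax from FVA of the
unconstrained model at objective fraction 0 (the full feasible envelope,
hence the widest valid Vmax; configurable). Bounds never loosen, so
every knockout growth ratio is ≤ 1 — a property the tests fuzz. If a
positive lower bound crosses a scaled-down upper bound, the lower bound
is relaxed onto the upper bound to keep the LP well posed rather than
declaring an artificial lethality.

Edge signs matter: in the default `sign_aware` mode, inhibition edges do
not constrain (losing an inhibitor cannot starve its target), while
activation and unknown-sign edges do — unknown-sign edges were inferred
from co-expression, so activation is the conservative reading. The
`prom_pure` mode ignores signs for comparison with classic PROM. Signs
are assigned from Spearman correlation between TF and target expression;
|ρ| below 0.05 stays `unknown`, a deliberately narrow null band that
avoids flipping constraints on noise at cohort-scale n while leaving
genuinely weak edges unsigned.

A TF that itself carries GPR membership in the model is additionally
deleted as a metabolic gene during its own knockout.

Condition-specific TFs are those with growth ratio below an impact
threshold in one screen and at or above a neutral threshold in the
other; the 0.98 default for both mirrors the "ratio < 0.98" convention
for calling an impaired knockout.

## NMF consensus stratification

`nmf_factorize` implements KL-divergence multiplicative updates
(Frobenius available), random uniform initialization from an explicit
seed, convergence when the relative divergence change drops below `tol`
(default 1e-6) or `max_iter` (default 2000) is reached. The divergence
trace is retained and is non-increasing — a property the tests check
over random seeds.

Consensus clustering runs `n_runs` random restarts per rank (default
200, read as restarts — the consensus-clustering convention — not
update steps); each restart assigns samples to their argmax-H pattern,
and the consensus matrix is the mean co-clustering indicator. Final
labels cut the average-linkage dendrogram of `1 − consensus` at the
rank. Restarts inside the consensus loop default to `max_iter = 500`,
`tol = 1e-5`: the ensemble needs many cheap restarts more than it needs
each restart converged to machine precision. Per-run seeds derive from
the master seed by a fixed fan-out (`seed + 1000·rank + run`), so runs
are reproducible and never collide across ranks.

Rank selection maximizes the cophenetic correlation between consensus
dissimilarities and their dendrogram's cophenetic distances; ties break
toward the higher average silhouette width, then the smaller rank. A
perfect block consensus scores exactly 1; the degenerate constant
consensus has no defined correlation and returns `NA` with a warning
(with one special case: when the dendrogram heights are constant *and*
equal to the dissimilarities, the clustering is perfect and 1 is
returned). Expression input to NMF is min-shifted to nonnegative when
log-scale input contains negatives, and all-zero rows are dropped.

Survival uses the product-limit estimator with tied events handled
jointly and the k-sample log-rank test (hypergeometric expectation and
covariance, quadratic form over k−1 groups, chi-square reference); a
singular covariance falls back to a pseudoinverse. Both are
cross-checked against the `survival` package to 1e-8 in tests.

## Differential expression and enrichment

The moderated t shrinks per-gene pooled variances toward a prior fitted
by moment matching on `log s²` (digamma/trigamma moments of
log-chi-square), inverting the trigamma by Newton iteration. When the
observed log-variances show no excess dispersion beyond sampling noise,
the prior degrees of freedom are infinite and the prior variance is the
plain mean of the s² — variances are then exchangeable. The total df of
the t reference is capped at the pooled residual df of the experiment:
the prior cannot contribute more information than the data that
estimated it. Zero-variance genes are excluded from the prior fit and
flagged (±Inf t when means differ). Forcing prior df to 0 reproduces
the ordinary two-sample t exactly; both limits are verified numerically,
and the full pipeline matches `limma` to 1e-9 in tests while remaining
an independent implementation.

DEG calling uses |log2FC| ≥ 1 and raw P ≤ 0.05 by default — the
BH-adjusted column is always emitted, and `use_adjusted = TRUE` switches
the filter, since conventions differ between DEG calling (raw) and
enrichment (adjusted). The poor-class signature is the
direction-concordant intersection of the class's two pairwise
contrasts; discordant genes are excluded and reported. Enrichment is a
local upper-tail hypergeometric test over user-supplied gene sets with
BH adjustment — a deliberate replacement for web enrichment services,
which are out of scope.

## Cohort essentiality and flux reprogramming

Essentiality consensus collects genes with growth ratio below
`essential_cutoff` (default 0.01, near-lethal) in at least
`ceiling(min_fraction · n)` ("at least half", default) of a class's
patients, after excluding genes whose knockout has no influence in any
patient; an "influential" report at cutoff 0.95 is available by raising
the cutoff, and the consensus list is provably monotone in the cutoff.
Genes absent from a patient's model are masked — a deletion the model
cannot see is a no-op, not evidence.

Flux categories use `epsilon = 1e-6` (flux units) for "zero". A
reaction's class category must be a strict majority (> 0.5, per the
"over half" wording) of that class's patients, with absent reactions
excluded from the denominators. The four types are a function of the
category triple — (negative elsewhere → positive in the poor class) = 1,
(positive → negative) = 2, (consistent non-zero → zero) = 3,
(zero → non-zero) = 4 — so types are mutually exclusive by construction.

The bundled pipeline derives per-class patient models from the base
model by scaling GPR-gated bounds with within-class gene ON-frequencies
(the same constraint engine as the TF knockout, driven by class activity
instead of knockout probabilities). This is a deliberately simple
expression-integration stand-in: reconstruction of genuinely
patient-specific models (tINIT-style) is out of scope, and users with
such models can pass them directly to `cohort_essentiality()` and
`cohort_flux_table()`.

## Synthetic study conditions

The generator plants ground truth as *exact empirical frequencies*, not
merely expectations: each TF is OFF in `round(tf_off_rate·n)` samples
(default 0.4), each target is ON in exactly `round(p·n_off)` of them,
and continuous levels are a two-Gaussian mixture separated by
`effect_size · noise_sd` (default 5σ, OFF mean 5, σ = 1 on a log2-like
scale). Planted probabilities are therefore recoverable up to rounding
(±1/(2·n_off)) plus rare binarization misclassification (the pooled
threshold sits at the cloud boundary, ~2.5σ from each mean). Class
structure is a mean shift of the same size on per-class signature genes;
survival is exponential with class hazards defaulting to 0.002, 0.006,
0.003 events/day (the second class is the poor-prognosis class, hazard
ratio 3) under uniform censoring whose horizon is solved per class to
give the requested censoring fraction (default 30%, typical cohort
shape).

What passing recovery tests show: the estimator, the screen, the
clustering and the classifier correctly invert the generative model at
realistic sizes. What they do not show: performance under real-data
features the generator deliberately omits — heavy-tailed and
batch-affected expression, correlated regulons, mixed identifier
spaces, incomplete GPRs, non-exponential hazards — and no claim is made
about recovering any specific cohort's class sizes or gene lists.

Problem sizes used by the tests and the acceptance script (chosen to
exercise every property at desk scale): 50 random toy models
(9–15 reactions) for dual-solver LP equivalence with every LP re-solved
independently; 200-sample cohorts for probability recovery; 60-sample
3-class cohorts at 5σ separation, ranks 2:5, 50 restarts per rank and
20 seeds for stratification recovery; 50 replicates of 5000-gene global
nulls and 1000 log-rank null replicates for calibration; 100 planted
reactions across the four types for the classifier.

## Known limitations

- The LP backend is a dense simplex; it is sized for toy-to-moderate
  models, not for whole-genome models with tens of thousands of
  reactions, where a sparse interior-point/HiGHS backend would be the
  right tool.
- SBML support covers L3+fbc and the COBRA L2 kineticLaw dialect;
  exotic SBML constructs (species references with math, compartments
  with volumes affecting stoichiometry) are not interpreted.
- Gene identifiers are opaque strings; harmonization across identifier
  spaces is the caller's responsibility.
- Inhibition edges are treated as non-tightening during TF knockout;
  modeling de-repression (bound loosening) would require information a
  growth-maximizing LP cannot use anyway, but other readings exist.
- The pipeline's per-class activity models share one base model; true
  patient-specific reconstructions will generally sharpen both the
  essentiality consensus and the flux-pattern contrast.
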