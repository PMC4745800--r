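---
title: "Protein-anchored metagenes: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Protein-anchored metagenes: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rppasig)
```

## The model

`rppasig` assumes that behind each (phospho-)protein measured by RPPA there
is a latent pathway-activation level that leaves a transcriptional
footprint: a set of genes whose expression moves up or down with
activation. The package estimates that footprint as a *metagene* — a gene
set with per-gene coefficients $s_i \in \{-1, +1\}$ — and summarises it per
sample by the signed sum

$$\mathrm{sigscore} = \sum_{i=1}^{n} e_i \, s_i,$$

where $e_i$ is the member gene's (log-scale) expression. The score is a
linear read-out: doubling expression doubles the score, and flipping every
coefficient negates it. No per-gene weighting or standardisation is applied
by default — the score is the plain scalar product — so scores are
comparable across samples within one dataset but carry the dataset's scale;
cross-dataset use goes through `quantile_align()` first.

## Derivation

Samples are split at the protein's quartiles: `low` = values $\le Q_1$,
`high` = values $\ge Q_3$ (intermediate samples are set aside). Quartiles
— like every quantile in the package (median dichotomisation, alignment) —
use linear interpolation between order statistics (type 7), stated here
once and applied consistently. Boundary ties are inclusive, so heavily tied
proteins can have outer groups larger than 25%. Proteins with fewer than 8
usable measurements or a constant profile are skipped: quartile groups of
two or three samples carry no usable information.

Differential expression between `high` and `low` uses a Student-type
statistic on robust estimators, with Welch–Satterthwaite degrees of freedom.
The estimator pairing is a genuine design freedom, and the package
deliberately isolates it behind `robust_t(estimator = ...)`:

* **`"trimmed"` (default)** — Yuen's test: 20%-trimmed means, winsorized
  variances. In null simulations it rejects at 0.0498 for $\alpha = 0.05$
  ($n = 50 + 50$, 10,000 replicates) and stays calibrated deep in the
  tail.
* **`"median"`** — medians with $1.4826 \times$ MAD scale, the variance
  terms inflated by $\pi/2$ (the sampling variance of a median under
  approximate normality is $\tfrac{\pi}{2}\sigma^2/n$; omitting the factor
  inflates the null rejection rate to ~11%). With the correction it holds
  the nominal level, but its extreme tail is heavier than the t reference:
  across thousands of genes the minimum p-value is then too small too
  often, and ~20% of pure-noise proteins acquire a (one-gene) metagene.

The trimmed pairing is the default because metagene membership is decided
by the far tail of per-gene p-values under BH correction: with it, a
pure-noise protein delivers a non-empty metagene in roughly the nominal 5%
of simulations, matching the FDR semantics of the membership rule. The
membership rule itself is: BH-adjust the p-values *within* each protein,
keep genes with $q \le 0.05$, coefficient = sign of the robust location
difference. A protein may end up with no members — it then simply yields no
metagene, which is expected behaviour, not an error.

Degenerate inputs follow fixed rules rather than NaN propagation: two
zero-spread groups with equal locations give $t = 0, p = 1$; with unequal
locations $p = 0$ with a `degenerate` flag.

## External validation

Validation is two-gated on an independent cohort with matched expression
and RPPA: Pearson $r \ge 0.5$ between the score and the *continuous*
protein level (signed, not $|r|$ — a correctly oriented metagene must
correlate positively), and a Mann–Whitney AUC, computed on the validation
cohort's **own** quartile-derived high/low groups, whose p-value survives
BH across the tested metagenes ($q \le 0.05$). Quartile (rather than
median) grouping for the AUC keeps validation symmetric with derivation;
intermediate samples contribute to the correlation but not the AUC. The
AUC p-value is the normal approximation with tie correction — exactly the
test of AUC = 0.5. Metagenes whose source protein is not measured in the
validation panel are reported untestable and excluded from the BH family.

## Overlap network, enrichment and cluster similarity

Metagene–metagene and metagene–functional-class intersections are tested
with the exact hypergeometric upper tail $P(X \ge n)$ (computed in log
space via `phyper`). Overlap counts the union of up- and down-members;
coefficient signs are ignored for intersection purposes. The universe $N$
defaults to the genes measured in the derivation expression matrix and is
always explicit in the API, because the p-value is quite sensitive to it.
Network edges require both $q \le 0.05$ (BH across all pairs) *and* at
least 5 shared genes; the size floor keeps trivially small but
"significant" overlaps out of the graph. Node grouping is by connected
component, with an optional label-propagation pass; heavier graph
clustering is out of scope and the graph is exported (GraphML/SIF) for
external tools.

Similarity between two correlation structures (e.g. metagene scores vs
RPPA profiles) is measured by clustering each Pearson correlation matrix
(Euclidean distance, complete linkage, cut at $k = 3$) and comparing the
partitions with the plain, unadjusted Rand index.

## Survival screen

The screen asks whether a metagene *modifies treatment benefit*. Scores are
dichotomised at the median (inclusive-low tie rule). Within each stratum, a
Cox proportional-hazards model (partial likelihood, Efron ties) estimates
the treated-vs-control hazard ratio with Wald CI; the interaction itself is
the Wald test of the arm × score product term in a joint model, computed
both for the stratum indicator and for the continuous score. BH across
metagenes uses the dichotomous interaction p-value; the continuous result
is reported alongside. Monotone likelihood (e.g. an event-free cell) is
flagged with an infinite CI sentinel instead of an exception, and a
metagene with an empty stratum × arm cell is marked untestable rather than
fitted. The multivariate covariate set is fully caller-specified (the
screen makes no assumption about which clinical variables exist); the
default is the univariate model.

## The synthetic cohort generator

`sim_config()`/`generate_cohort()` emulate the data *structure* the method
needs: per protein $p$ a latent activation $A_p \sim N(0,1)$ per sample;
RPPA value $= A_p + \varepsilon$; member-gene expression
$= \mu + s_i \beta A_p + \eta$ with $s_i = -1$ for a 30% minority
(`frac_negative_members`), so coefficient signs are genuinely exercised;
all other genes pure noise. Defaults: 200 samples per cohort, 20 proteins
of which 10 informative, 50 genes per metagene, effect size
$\beta = 1$, unit noise. The 2,000-gene total keeps planted members a 25%
minority, and the baseline of 6 puts values on a log2-microarray-like
positive scale where multiplicative 0.95-quantile alignment is meaningful.
Survival is exponential — chosen for closed-form hazard-ratio truth — with
baseline hazard 0.05/month (median ~14 months untreated), treatment
log-HR $\log 0.7$, an additional treated-arm log-HR of 1.0 per SD of the
interaction metagene's score, and independent exponential censoring whose
rate is solved numerically to hit the target 30% censoring fraction.
`generate_two_datasets()` draws two cohorts from one membership structure
and maps the validation expression through an affine transform (default
$2x$), exercising alignment and cross-platform validation. Optional latent
blocks (`latent_blocks`, within-block correlation 0.6) mimic co-activated
pathway groups for network and Rand-index work; proteins are independent
by default.

What the generator does *not* emulate: heavy-tailed microarray noise,
probe-level artefacts, batch effects, missingness patterns in RPPA,
non-proportional hazards, or correlated censoring. Passing tests on this
generator therefore demonstrate correctness of the machinery and
calibration under clean Gaussian/exponential conditions, not robustness to
every pathology of real cohort data.

## Numerical and procedural choices

* Quantiles: type 7 everywhere; median split sends ties to `low`.
* Duplicate gene identifiers collapse to the arithmetic per-sample mean;
  collapsing is idempotent and rows are returned in lexicographic order
  for determinism. Identifiers are matched case-sensitively after
  whitespace trimming.
* `quantile_align` rescales each dataset multiplicatively so its pooled
  0.95-quantile matches the first (reference) dataset. Per-dataset
  multiplicative matching is the simplest reading of upper-quantile
  normalization; the quantile is a parameter, and a dataset whose
  0.95-quantile is non-positive is rejected rather than flipped.
* Expression matrices must be complete; RPPA missing values are excluded
  pairwise (grouping, correlation), with an 8-measurement floor.
* BH families are deliberately local: per protein for membership, across
  tested metagenes for validation AUCs, across all pairs for the network,
  per collection for enrichment, across testable metagenes for the screen.
* Scoring requires ≥ 50% member coverage by default; absent members are
  skipped, not imputed.

## Problem sizes used in the checks

The packaged checks run at the generator's default conditions: 100 seeds
for member recovery (one derivation each), 25 seeds for the paired
derive–validate–screen loop, 10,000 null replicates for the robust test's
level, 1,000 null cohorts ($n = 200$) for the interaction test's level,
and a single $n = 2{,}000$ cohort for hazard-ratio recovery. These sizes
give Monte-Carlo standard errors comfortably inside the asserted bands.

## Known limitations

* The derivation test assumes exchangeable samples within groups; no
  covariate adjustment or empirical-Bayes moderation is offered.
* No gene filtering (expression floor, variance) is applied before
  testing; with very small cohorts this costs some power.
* The hypergeometric universe is user-specified; results are only as
  meaningful as that choice.
* The screen's per-stratum hazard ratios are descriptive fits within
  data-defined strata and inherit the usual caveats of median splits.
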