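---
title: "Gene set-level scoring and network inference for toxicogenomics data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene set-level scoring and network inference for toxicogenomics data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tgxtools)
```

# Scope and model

tgxtools evaluates chemical-induced transcriptome perturbations at the
level of curated toxicogenomics (TGx) biomarker gene sets rather than
individual probes. Its inputs are already-normalized log2 expression
values with optional Affymetrix-style detection calls; CEL-file parsing,
normalization (MAS5/RMA) and probe annotation are deliberately out of
scope — those belong to the upstream preprocessing pipeline.

For one treatment condition (compound x dose x timepoint with matched
controls), every probe $i$ carries

- an effect $e_i$: mean treated log2 intensity minus mean control log2
  intensity (a log2 ratio of group means), and
- a quality weight $w_i \in [0,1]$: the mean detection-call weight over
  *all* samples of the condition, mapping Present $\to 1$,
  Marginal $\to 0.5$, Absent $\to 0$.

Averaging the calls over controls and treated alike reflects what the
weight is for: a probe that is undetectable in half the condition's
samples is unreliable for that condition as a whole, whichever arm the
Absent calls fall in.

## The two scores

For a gene set with $n$ probes present on the array, with $n_{up}$
up-regulated ($e_i > 0$) and $n_{down}$ down-regulated ($e_i < 0$):

$$\mathrm{TGP1} = \frac{n_{up} - n_{down}}{n} \cdot \frac{1}{n}\sum_i |e_i|,
\qquad
\mathrm{Dscore} = \frac{C}{n} \sum_i w_i\, e_i .$$

The TGP1 direction and magnitude indices are defined here as the simplest
pair realizing the three properties the score is known for: its sign
follows the majority direction, it approaches zero when directions are
divergent, and it grows with the uniform change level. Probes with
$e_i = 0$ count in $n$ but in neither direction count, which pulls the
direction index toward zero — consistent with the divergence property.
The D-score is the minimal formula combining the two stated ingredients,
expression changing level and data quality; with the default scale
$C = 10$, a uniform 2-fold change at full quality scores 10, and the
conventional radar-chart reference circle sits at a D-score of 20 (a
uniform 4-fold change). Both scores are exactly odd —
$\mathrm{score}(-e) = -\mathrm{score}(e)$ — and all-Absent data scores
exactly zero regardless of the apparent effect.

Two policies worth noting. Probes listed in a biomarker set but absent
from the array are dropped with a warning (sets and platforms evolve
independently; an error would make every legacy set unusable), and no
per-probe significance filter is applied by default — `min_abs_effect`
exists but defaults to 0, since the scores are means, not test statistics.
Scoring operates at probe level throughout; collapsing probes to genes is
the user's preprocessing decision.

# The Gaussian graphical model

Across a panel of conditions, gene-set D-scores and phenotype changing
levels (organ weight, blood chemistry, hematology endpoints, supplied
as-is) are assembled into one condition x feature matrix: conditions
intersected, rows with any missing phenotype dropped listwise (the
simplest defensible policy for the modest missingness expected here),
zero-variance columns dropped, and every column standardized so scores
and phenotypes are commensurate.

The network estimator is the standard small-n-large-p shrinkage GGM of
the gene-network literature: with sample correlation matrix $S$,

$$S^* = (1-\lambda) S + \lambda I, \qquad \Omega = (S^*)^{-1}, \qquad
\rho_{ij} = \frac{-\Omega_{ij}}{\sqrt{\Omega_{ii}\Omega_{jj}}}.$$

$\lambda = 0$ gives classical partial correlations (identical to
correlating the residuals of each pair regressed on all other features —
the package's test suite checks this equivalence to $10^{-8}$);
$\lambda = 1$ collapses to the identity. `lambda = "auto"` uses the
analytic Ledoit–Wolf-style estimator for the identity-target correlation
shrinkage: the ratio of the summed estimated variances of the empirical
correlations to their summed squares, clipped to $[0,1]$. At the scale
this package targets (~60 features, ~150 conditions) the auto intensity
is typically 0.05–0.3 and the shrunken matrix is always invertible. The
estimator sits behind a small interface (`partial_cor`,
`shrinkage_lambda`) and is substitutable, e.g. by a graphical lasso,
without touching the rest of the package.

Edge selection is a presentation decision, not part of the estimator, so
three interchangeable rules are provided: an absolute threshold (default
0.1), top-k by $|\rho|$, and a permutation FDR that permutes each column
independently, refits at the same $\lambda$, and applies a step-up
empirical-FDR cut. The permutation rule is seeded and bit-reproducible.
Exports carry the sign and $|\rho|$ of every edge (GraphML for Cytoscape;
DOT with purple/green encoding positive/negative and penwidth
proportional to $|\rho|$; TSV round-trips losslessly).

# Presentation conventions

The radar chart plots **absolute** D-scores — one axis per gene set in
collection order, a red score polyline, and a blue reference circle at
level 20 — because its question is "which endpoints moved, and how
much?". The heat map and the supervised network plot **signed** scores on
a diverging blue–white–red scale, because their question includes
direction. The two conventions intentionally differ; each follows the
established usage for that display. Color limits are symmetric at the
global $\pm\max|score|$ per figure rather than per-row, so intensity is
comparable across sets. All renderers are deterministic (fixed styling,
no timestamps): identical input yields byte-identical SVG.

The supervised network's topology is a curated input (a TSV edge list),
never a computation — it encodes prior toxicological knowledge and must
be maintained as such. The package only paints scores onto it.

# What the synthetic generators emulate

`simulate_expression` draws a per-probe baseline
$\mathcal N(\mu_{base}, \sigma_{base}^2)$ on the log2 scale (defaults
8 and 1.5), adds i.i.d. replicate noise $\mathcal N(0, \sigma^2)$
(default $\sigma = 0.3$, a typical inter-animal log2 SD for liver
microarrays), and shifts probes of perturbed sets by a planted $\delta$
in treated samples. Detection calls follow a logistic-in-intensity model:
Present with probability $\mathrm{logit}^{-1}((v - 6)/1)$, otherwise
Marginal within 1 log2 unit of the midpoint and Absent beyond — so dim
probes are low-quality, giving the quality-weighting machinery real
signal to act on. Defaults are 58 gene sets of 10–20 probes and 3
replicates per group, the shape of a typical biomarker panel applied to a
single-compound rat-liver study. Gene sets are sampled disjoint by
default (an `overlap` option shares members between neighboring sets)
because disjointness makes recovery tests crisp even though real
biomarker sets overlap.

What this generator does *not* emulate: heteroscedastic (intensity-
dependent) noise, probe-level correlation within genes, batch effects,
and platform artifacts. Passing recovery tests on these fixtures
therefore demonstrates the algebraic and statistical correctness of the
scoring chain, not robustness to real-array pathology.

`simulate_features` draws conditions i.i.d. from
$\mathcal N(0, \Omega^{-1})$ for a known sparse precision matrix
$\Omega$, so the true edge set and the population partial correlations
are available exactly. `random_precision` plants a chosen number of
off-diagonal entries with magnitudes in $[0.2, 0.4]$, unit diagonal, and
adds the minimal ridge keeping the smallest eigenvalue at 0.05 — the
planted magnitudes are preserved while positive definiteness is
guaranteed.

`simulate_case_study` generates a four-timepoint (2/6/12/24 h)
hepatotoxicant-like study in which seven named sets follow a planted
mechanistic schedule — early glutathione depletion and DNA damage (6 h),
oxidative stress plus inflammation and compensatory glutathione
homeostasis (12 h), peak inflammation with suppressed cholesterol
synthesis and glycolysis (24 h) — over 51 flat background sets. The
planted effect sizes (0.5–2 log2 units) were chosen once as
representative of a strong hepatotoxic response at a high dose; the
schedule is returned as ground truth so the temporal pattern is
assertable.

# Numerical choices and degenerate inputs

- Score tables are written at 17 significant digits, so write/read round
  trips are lossless to double precision; files are LF-terminated UTF-8
  TSV on every platform.
- `partial_cor` symmetrizes $(\rho + \rho^\top)/2$ after inversion to
  remove round-off asymmetry, and refuses a singular $S^*$ with advice to
  use $\lambda > 0$.
- Edge ordering is deterministic: decreasing $|\rho|$, ties broken by
  node names, so top-k selections and exports never depend on memory
  layout.
- Empty gene sets, conditions without both arms, duplicate set names,
  non-finite expression values and unknown detection-call tokens are all
  rejected at read/validation time with messages naming the offender.
- An all-zero score table renders as a uniform mid-color heat map and a
  degenerate (origin) radar polyline with the reference circle intact.

# Problem sizes used in validation

The test suite and the acceptance script validate at the scale the
package targets while staying quick: score-algebra identities on 1,000
random effect vectors; perturbation recovery on 100 simulated studies
(58 sets, 5 perturbed at $\delta = 1$, 3 replicates, $\sigma = 0.3$);
GGM oracle agreement at $p = 6, n = 5000$; planted-edge recovery on 20
panels of $p = 20$, 30 edges, $n = 150$ conditions; and the case-study
pattern on 100 seeds. These sizes were chosen as the smallest that make
the stochastic checks statistically meaningful.

# Known limitations

- The D-score inherits the detection-call convention; arrays without
  calls degrade gracefully (all weights 1) but then the D-score is just a
  scaled mean log2 ratio.
- Partial-correlation networks are undirected and linear; no causal or
  time-lagged structure is inferred.
- The permutation FDR treats features as exchangeable under independent
  column permutation, which ignores the conditions' dose/time structure;
  with strongly nested designs the null is optimistic.
- Phenotype changing levels are consumed as-given; any per-endpoint
  monotone transform (e.g. log ratios vs percent change) is the user's
  responsibility before the join.
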