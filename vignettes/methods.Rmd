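---
title: "Methods: ageing trajectories of small RNA cargo in plasma fractions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ageing trajectories of small RNA cargo in plasma fractions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and data model

`evaging` analyses small non-coding RNA expression measured in two plasma
fractions of the same mice — RNA bound to or enclosed in extracellular
vesicles (EV) and free-circulating RNA in vesicle-depleted plasma (fc) —
across a cohort spanning five ages (2, 6, 8, 12, 18 months). The substrate
of every stage is a non-negative feature-by-sample matrix
(`ExpressionMatrix`) with a sample sheet (age in months, fraction, mouse)
and a feature sheet (one of ten small-RNA classes per feature: miRNA,
tRNA fragments, rRNA, snoRNA, snRNA, piRNA, lincRNA, circRNA, scaRNA,
misc). The class vocabulary is configurable; feature totals are always
data-derived, never assumed.

Counts are normalized to reads per million (RPM): every sample column is
scaled so its library sums to 10^6. Library size is the column sum over
*all* features in the matrix, computed once before any class subsetting.
The expression filter keeps features with at least 5 RPM in at least one
sample; the threshold is inclusive and both knobs are parameters.

# Trajectory statistics

For every feature and fraction we compute two age-dependence measures
across samples:

- the Pearson correlation $r$ of expression with age in months, and
- the sample distance correlation
  $\mathrm{dCor} = \mathrm{dCov}/\sqrt{\mathrm{dVar}_x\,\mathrm{dVar}_y}$
  computed from double-centred pairwise Euclidean distance matrices
  (the V-statistic form; $\mathrm{dCor}=0$ by convention when either
  distance variance vanishes).

Pearson captures monotone-linear trends; dCor responds to any
dependence, including U- and bell-shaped trajectories. A feature with
zero variance has no defined correlation and is excluded from summaries
rather than assigned $r = 0$.

**Nonlinearity screen.** A cubic smoothing spline of dCor on $r$ is fit
across features (`stats::smooth.spline`) at 7 equivalent degrees of
freedom, and features whose dCor deviates from the spline by at least
0.15 in absolute value are called predominantly nonlinear —
`nonlinear_positive` when $r > 0$, `nonlinear_negative` otherwise. Both
the degrees of freedom (7 by default, 8 supported) and the residual
threshold are parameters; the deviation is read symmetrically (above or
below the spline) since only a distance is specified. The flagged set is
monotone non-increasing in the threshold.

Two caveats matter at cohort scale. First, the sample dCor is biased
upward at small $n$: with 15–20 samples a pure-noise feature averages
dCor ≈ 0.35–0.40, and a *noiseless* linearly-orthogonal quadratic only
reaches ≈ 0.6, so the screen has limited headroom by construction.
Second, the spline tracks the bulk of the point cloud: if nonlinear
features were a large subpopulation they would pull the spline toward
themselves at $r \approx 0$ and mask each other. The screen is therefore
a tool for finding *exceptional* trajectories, which matches the
biological setting it was designed for.

**Quadrant concordance.** Features are classified by the sign pair of
their age correlation in EV and fc. Under independent random signs each
of the four quadrants holds 25%; the observed counts are tested with a
chi-square goodness-of-fit (exact multinomial enumeration when any
expected count is below 5). Features with a zero or undefined
correlation in either fraction are excluded and reported separately.

**Mean-shift permutation test.** The statistic is the difference of the
mean per-feature Pearson correlation between fractions. The null is
built by shuffling age labels across samples within each fraction —
feature values stay attached to their sample, so the correlation
structure *among* features is preserved while the age signal is broken.
The two-sided p-value uses the add-one correction
$p = (b+1)/(B+1)$, so $p \ge 1/(B+1)$ always.

# Constrained NMF age classification

Samples are classified into young (2 m), middle (6–8 m) and old
(12–18 m) by factorizing the max-rescaled matrix $D \in [0,1]^{m\times n}$
as $D \approx TP$ with

$$\min_{T,P} \|D - TP\|_F^2
\quad\text{s.t.}\quad 0 \le T \le 1,\; 0 \le P \le 1,\;
\textstyle\sum_s P_{sj} = 1 \;\forall j.$$

Columns of $P$ are membership probabilities over the $k=3$ age groups;
columns of $T$ are typical group profiles. The solver is alternating
projected least squares: the $T$-step solves the row-wise least-squares
problem and clips to the unit box; the $P$-step solves the column-wise
least-squares problem and projects each column onto the probability
simplex (Euclidean projection, sort-based). Projected least squares is
not a guaranteed-descent scheme, so a sweep is accepted only if it does
not increase the objective; the solver otherwise stops. This makes the
returned objective provably no worse than its own initialization. Ten
seeded random restarts (uniform $T$, flat-Dirichlet $P$ columns) are run
and the best objective kept; restarts, tolerance (relative objective
change $< 10^{-6}$) and the seed are recorded in the result, since no
solver details were externally fixed.

Labels are the per-column argmax of $P$ (ties to the lowest index).
Because the rows of $P$ are only identified up to permutation, accuracy
is the maximum over all $k!$ bijections from predicted indices to group
names; for balanced truth the mean over bijections is exactly $1/k$, so
the reported accuracy is always $\ge 1/k$. The per-class-by-fraction
splitting (the "20 matrices" orchestration) is a pipeline
responsibility, not part of the solver.

# Clustering and cross-fraction mapping

Features passing the expression filter are standardized per feature to
mean 0, variance 1 (population variance, recorded in metadata),
clustered with complete-linkage agglomerative hierarchical clustering on
Euclidean distances, and cut at (maximal merge height)/1.25. The two
readings of "1/1.25 of the maximal height" coincide, but the divisor is
exposed as a parameter, as is the linkage. Zero-variance features are
excluded with a warning. Cluster summaries attach mean Pearson and
distance correlation per cluster, and the cross-fraction map counts
shared features for every (EV cluster, fc cluster) pair; those counts
sum to the number of features clustered in both fractions.

# Variance attribution

A PVCA-style decomposition: principal components of the standardized
sample-by-feature matrix are retained until cumulative explained
variance reaches 0.6 (default). On each retained component, a variance
component is estimated for each factor (age, fraction, mouse by default;
interactions optional) by one-way random-effects method of moments,
$\hat\sigma^2_f = \max\{0, (\mathrm{MSB}-\mathrm{MSW})/n_0\}$ with the
unbalanced-design $n_0$; the residual is the pooled within-cell variance
of the full factor cross (or the smallest within-factor mean square when
the cross has no residual degrees of freedom). Per-component
attributions are normalized, averaged with eigenvalue weights, and
re-normalized to sum to 1. Method of moments was chosen over REML to
keep the estimator transparent and dependency-light; it is adequate for
attribution *ranking*, which is how the output is meant to be read.
Factors confounded one-to-one are rejected by name, since no estimator
can separate them.

# Set enrichment and the fraction contrast

miRNAs are ranked by descending age correlation within one fraction. For
a category with $K$ members in a list of $N$, the unweighted running sum
gains $N-K$ at each member and loses $K$ at each non-member, so it
terminates at exactly 0; the enrichment score is the maximum absolute
deviation. Significance comes from permutations that reshuffle category
membership over list positions, with the add-one correction, and all
categories are reported at nominal p (threshold 1) with
Benjamini–Hochberg adjustment across categories. Ranks only — the
correlation magnitudes order the list but do not weight the sum.

One numerical subtlety: the enrichment score is integer-valued, so for
short lists observed and permuted scores tie often and the add-one
p-value becomes visibly conservative (its null distribution piles mass
near 1). At $N = 100$, $K = 15$ the effect is negligible; calibration
checks are run at that size.

The EV-vs-fc contrast flags categories whose nominal p-values differ by
at least 3 orders of magnitude (parameter; a 2-order variant is also in
common use) and lists categories significant after BH in both fractions.

# Target network and concordance

The miRNA-to-gene edge table is filtered to strong-evidence
(experimentally validated) interactions; the mapping from source
vocabularies to strong/weak happens at read time. Hub genes are those
targeted by at least 3 distinct miRNAs. Two concordance views are
computed: (1) per tissue and per miRNA sign group (age-up/age-down per
fraction, inclusion threshold $|r| \ge 0.5$ by default, matching the
nominal-significance landmark), the mean age correlation of the union of
the group's target genes, where gene age correlations use mean
expression per age when replicates exist; (2) the direct correlation of
each miRNA with each of its targets across shared samples, with miRNAs
ordered by ascending mean so the most consistent repressors come first.

# ΔΔCt quantification

Per sample, $\Delta Ct = Ct_{target} - \tfrac12(Ct_{ctl1}+Ct_{ctl2})$ —
the two endogenous controls (miR-191a and let-7a by default) are
combined per sample as the arithmetic mean on the Ct scale, equivalent
to a geometric mean of linear quantities. $\Delta\Delta Ct$ is the
difference of group means (old minus young) and
$\log_2 FC = -\Delta\Delta Ct$. Per-sample (not per-group) control
averaging is used and documented, since the original description does
not distinguish the two. Spike-in QC assays are tolerated in the input
but never enter the computation. No amplification-efficiency correction
is applied (no efficiencies are available to apply).

# The synthetic cohort: what it emulates and what it does not

`simulate_cohort()` generates the full study design: 5 ages × 2
fractions × 4 replicates (the study used 2–4; the default sits at the
top of that range deliberately, see below), 10 RNA classes, the same
mouse contributing one EV and one fc sample. Feature means live on the
log scale; counts are gamma-mixed Poisson (negative binomial), the
standard overdispersion model for RNA-seq, with dispersion 0.1 — typical
for genetically homogeneous inbred mice. Planted structure:

- **linear** features shift monotonically by `effect_size` (default 2)
  within-group log-sd units across the age range, half up, half down;
- **discordant** features (a fraction of the linear ones) flip slope
  sign between EV and fc;
- **nonlinear** features follow a quadratic made exactly orthogonal to
  the linear age covariate at the design level, so their planted linear
  component is zero, with amplitude `nonlinear_gain` (default 4) times
  the linear swing, and curvature signs alternating between bell and U
  shapes;
- an optional **fraction effect** gives each feature its own Gaussian
  EV-vs-fc loading.

Three of these choices are load-bearing and worth explaining:

1. *Nonlinear features are rare by default* (4%). The screen's spline
   follows the bulk of the point cloud; a large planted nonlinear
   subpopulation at $r \approx 0$ raises the spline onto itself and the
   residual rule can no longer see it. The small default matches the
   "few exceptions" regime the screen exists for, and makes the
   recovery criterion meaningful rather than self-defeating.
2. *Curvature signs alternate.* A one-signed nonlinear subpopulation
   swings total library size with age, and RPM normalization then
   divides every feature by that swing: the planted features partially
   cancel themselves and imprint an inverted copy of their trajectory
   on every other feature. Balanced curvature keeps the library
   composition stable. The same logic is why the fraction effect is a
   per-feature loading: a global EV multiplier would cancel exactly
   under RPM.
3. *Four replicates.* The small-sample bias of dCor (null mean ≈ 0.40
   at $n=15$ vs ≈ 0.35 at $n=20$) is the binding constraint on the
   screen; the top of the study's stated replicate range buys the
   margin.

The generator does **not** emulate: sequencing-depth variation between
samples, batch effects, zero inflation beyond what the negative binomial
produces, class-specific abundance profiles, or any read-level artefact
(mapping, adapters, UMIs are out of scope end to end). A green recovery
test therefore establishes that the statistics recover the structure
they were designed for under idealized noise — not that they would
behave identically on the real cohort.

`simulate_target_atlas()` plants miRNA age slopes (half up, half down)
and sets each gene's age trend to −`repression_strength` times the sum
of its *strong-evidence* regulators' slopes plus Gaussian noise. Most
genes carry a single regulator (regulator-count distribution 0.55 /
0.2 / 0.15 / 0.1 for 1–4): with uniformly many regulators per gene,
mixed-sign regulator sets cancel and the group-level repression signal
can vanish on the edge draw alone, which would make sign-recovery tests
measure the luck of the draw rather than the method. The tail of the
distribution still produces ≥3-miRNA hub genes.

`simulate_qpcr()` plants a log2 fold change directly as a Ct shift in
the old group with controls held flat — noiseless tables recover the
planted value exactly, which pins the sign conventions of the whole
ΔΔCt chain.

All generators derive independent sub-streams (design, means, noise)
from the master seed, so fixtures are bitwise-stable under a fixed seed
and edits to one block do not perturb the others.

# Numerical and policy choices collected

- Permutation p-values always use the add-one correction; two-sided
  where a direction is not prespecified.
- Zero-variance features: excluded from correlation summaries (not
  $r=0$), excluded from clustering with a warning.
- Argmax ties in classification: lowest index, for determinism.
- Chi-square vs exact: exact multinomial whenever an expected quadrant
  count is below 5.
- The NMF accepts a sweep only if the objective does not increase.
- `effect_size = 0` plants no trajectories at all: truth is all-flat,
  so null cohorts are genuinely null.
- The pipeline records every output with an MD5 checksum in a manifest;
  identical config and master seed reproduce byte-identical outputs.

# Known limitations

- The dCor small-sample bias bounds what the nonlinearity screen can
  see below ~20 samples; the 0.15 rule is not scale-free in $n$.
- Method-of-moments variance components ignore factor correlation
  beyond the 1:1 confounding check; proportions are for ranking, not
  inference.
- Enrichment p-values are permutation-based (not exact order
  statistics) and inherit grid discreteness at small list sizes.
- The per-class NMF orchestration skips classes below 10 features by
  default rather than fitting unstable factorizations.
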