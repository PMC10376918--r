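# evaging

Ageing trajectories of small non-coding RNA cargo in two mouse plasma
fractions: RNA bound to or inside extracellular vesicles (**EV**) and
free-circulating RNA in vesicle-depleted plasma (**fc**). The package
re-implements, as tested and reusable R code, the computational analysis
of such a cohort — five ages across the lifespan (2, 6, 8, 12, 18
months), two fractions per mouse, ten small-RNA classes — together with
a seeded synthetic-cohort generator so that every stage can be exercised
and validated without access to external sequencing data.

## What it computes

| Stage | Core statistic |
|---|---|
| Normalization & filtering | reads per million; ≥ 5 RPM in ≥ 1 sample |
| Trajectory statistics | Pearson *r* and distance correlation (dCor) of each feature with age, per fraction |
| Nonlinearity screen | residual ≥ 0.15 from a smoothing spline (df = 7) of dCor on *r* |
| Cross-fraction concordance | sign-quadrant table vs the uniform 25% null (χ², exact fallback) |
| Mean-shift test | permutation test of the mean correlation difference between fractions |
| Age classification | constrained NMF `D ≈ TP`, `0 ≤ T,P ≤ 1`, column-stochastic `P`; accuracy maximized over label permutations |
| Clustering | complete-linkage on z-scored features, dendrogram cut at h_max/1.25, EV↔fc cluster mapping |
| Variance attribution | PVCA-style eigenvalue-weighted method-of-moments components for age / fraction / mouse |
| Set enrichment | unweighted running-sum score over the age-ranked miRNA list, permutation p, BH q, EV-vs-fc orders-of-magnitude contrast |
| Target network | strong-evidence miRNA→gene graph, ≥3-miRNA hub genes, target age-concordance across tissues |
| qPCR | ΔΔCt with two conjoint endogenous controls (miR-191a + let-7a), log2FC = −ΔΔCt |

The model at the centre of the age classifier is

```
min_{T,P} ||D − TP||_F²   s.t.  0 ≤ T ≤ 1,  0 ≤ P ≤ 1,  Σ_s P_sj = 1 ∀j
```

solved by alternating projected least squares with Euclidean simplex
projection; columns of `P` are the samples' membership probabilities
over young (2 m) / middle (6–8 m) / old (12–18 m).

## Worked example

```r
library(evaging)

# a synthetic cohort with the study's design: 5 ages x 2 fractions x 4
# replicates, 10 classes, planted linear/nonlinear/discordant trajectories
sim <- simulate_cohort(simulation_config(seed = 42))
rpm <- filter_expressed(normalize_rpm(sim$expr))
rpm
#> ExpressionMatrix: 500 features x 40 samples [rpm]

st <- trajectory_stats(rpm, sim$samples)
ev <- classify_nonlinear(st[st$fraction == "EV", ])
table(ev$category)
#>             linear nonlinear_negative nonlinear_positive
#>                480                 11                  9

fc <- st[st$fraction == "fc", ]
q <- quadrant_concordance(ev$pearson_r, fc$pearson_r)
round(q$fractions, 3)
#> EV+/fc+ EV+/fc- EV-/fc+ EV-/fc-
#>   0.312   0.182   0.186   0.320
signif(q$p_value, 3)
#> [1] 1.26e-07

gm <- simulate_group_matrix(seed = 42)   # 200 features, 30 samples, 3 groups
sc <- classify_and_score(fit_age_nmf(gm$D, seed = 42), gm$truth)
sc$accuracy
#> [1] 1
```

Reading the output: the cohort plants 20 pure-nonlinear features (4% of
500) and the screen flags exactly those (11 with negative, 9 with
positive Pearson sign). The quadrant table shows the planted concordant
excess — 63% of features fall in the two concordant quadrants against
the 50% expected by chance, and the chi-square test rejects the uniform
25% null. The constrained NMF recovers all 30 planted group memberships.

## Pipeline and CLI

```r
fx  <- generate_fixtures("tiny", seed = 1)        # complete TSV input set
cfg <- pipeline_config(input_dir = fx, out_dir = "results", seed = 1)
manifest <- run_pipeline(cfg)                     # stage -> file -> md5
```

or from a shell:

```sh
Rscript -e 'evaging::evaging_cli()' simulate --preset tiny --seed 1 --out fx
Rscript -e 'evaging::evaging_cli()' run --in fx --seed 1 --out results
```

Single-stage verbs (`trajectory`, `nmf`, `cluster`, `variance`,
`enrich`, `network`, `qpcr`) run the pipeline up to that stage and write
only its outputs. Reruns with the same config and master seed are
byte-identical (checked via the manifest's MD5 column).

## Scope notes

The package consumes count matrices; read-level processing (mapping,
adapter handling, reference databases) is out of scope, as are wet-lab
concerns and figure styling. See `vignettes/methods.Rmd` for the full
model description, parameter rationale, and the limits of what the
synthetic generator does and does not emulate.
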