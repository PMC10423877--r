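# crossdecomp

**Does your choice of multivariate method change your brain–behavior
conclusions?**  `crossdecomp` fits the three cross-decomposition methods
most used to relate a block of brain measures to a block of behavioral
measures — canonical correlation analysis (CCA), partial least squares
correlation (PLSC) and partial least squares regression (PLSR) — on the
same data, tests every latent component by permutation, and quantifies
where the methods agree or diverge.  It is aimed at researchers in
developmental/psychiatric neuroimaging and at methodologists who want a
transparent, oracle-tested reference implementation of the three
estimators and of the comparison workflow.

## The methods in one paragraph

Given preprocessed blocks $X \in \mathbb{R}^{n\times p}$ (e.g. 87
regional gray-matter volumes) and $Y \in \mathbb{R}^{n\times m}$ (e.g. 4
orthogonal psychopathology factors: general, ADHD, conduct,
internalizing), all three methods seek weight pairs $(u, v)$ and latent
scores $(Xu, Yv)$:

| method | objective | solver | within-block covariance |
|---|---|---|---|
| CCA  | max corr$(Xu, Yv)$ | SVD of $S_x^{-1/2} S_{xy} S_y^{-1/2}$ | whitened away (noise) |
| PLSC | max cov$(Xu, Yv)$  | SVD of $S_{xy} = X^{\top}Y/(n-1)$ | retained (signal) |
| PLSR | predictive PLS2    | per-component SVD + X-deflation | retained, asymmetric |

Components are interpreted through *structure coefficients* (the
correlation of each observed variable with its block's latent score),
tested with row-permutation of $Y$ ($p = (1+\#\{\rho^{null}\ge
\rho\})/(1+B)$), and matched across methods by greedy maximum |cosine|
of concatenated loading vectors.  Covariates (age, sex, race/ethnicity,
scanner manufacturer, optionally ICV) are regressed out of both blocks
before standardization.  A synthetic generator reproduces the
ABCD-style data skeleton (n samples × 87 brain volumes × 4 orthogonal
factors, demographic covariate structure, planted low-rank cross-block
signal) with full ground truth for recovery studies.

## Worked example

A full run at the emulated study scale (n = 9,027; planted component
strengths 0.16 and 0.11; age/sex/race/scanner covariates):

```r
library(crossdecomp)
spec <- default_abcd_like_spec(9027, seed = 42)
d    <- generate_dataset(spec)
pre  <- preprocess_blocks(d$brain, d$psych, d$confounds)

fit <- fit_cca(pre$x, pre$y, k = 4)
permutation_test(pre$x, pre$y, "CCA", k = 4, B = 1000, seed = 43)
#> <permutation_report> method=CCA, B=1000, seed=43
#>   component    rho        p   ev_x   ev_y
#> 1        C1 0.1693 0.000999 0.0134 0.2531
#> 2        C2 0.1437 0.000999 0.0124 0.2508
#> 3        C3 0.0950 0.357600 0.0117 0.2476
#> 4        C4 0.0768 0.909100 0.0115 0.2484
```

Two of four components are significant (the add-one p-value floors at
1/1001 ≈ 0.001 with B = 1000): a leading component with latent
correlation 0.169 and a second with 0.144; the other two sit inside the
permutation null.  `ev_x`/`ev_y` are the per-component explained
variance fractions of each block.  Comparing all three methods:

```r
fits <- lapply(setNames(, c("CCA", "PLSC", "PLSR")),
               function(m) fit_method(pre$x, pre$y, m, k = 4))
reps <- Map(function(m, s) permutation_test(pre$x, pre$y, m, k = 4,
                                            B = 1000, seed = s),
            names(fits), 43:45)
compare_methods(fits, reps, alpha = 0.05)
#> <comparison_report> alpha=0.05
#> significant components per method:
#>  CCA PLSC PLSR
#>    2    2    2
#> dominant behavior dimension per component:
#>      C1      C2   C3            C4
#> CCA  general adhd internalizing conduct
#> PLSC general adhd internalizing conduct
#> PLSR general adhd internalizing conduct
#> CCA_vs_PLSC matched |cosines|: 0.997  0.996  0.997  0.997
#> CCA_vs_PLSR matched |cosines|: 0.997  0.995  0.996  0.997
#> PLSC_vs_PLSR matched |cosines|: 1.000  0.999  0.999  1.000
```

All methods recover the planted structure: a leading component dominated
by the general psychopathology factor and a second driven by ADHD, with
near-perfect cross-method agreement (cosines ≥ 0.995).  On *real*
volumetric data the strong covariance among brain regions makes CCA
(which whitens it away) and PLS (which keeps it) diverge on the later
components; the generator's independent-noise blocks deliberately do not
reproduce that — see the vignette for why, and for what a green test
does and does not establish.

## Command line

```sh
inst/cli/crossdecomp simulate --n 2000 --seed 1 --out data/
inst/cli/crossdecomp run-all  --synthetic-n 2000 --B 1000 --seed 1 --out run1/
inst/cli/crossdecomp run-all  --x brain.csv --y psych.csv \
    --confounds confounds.csv --methods CCA,PLSC,PLSR --out run2/
```

Subcommands `simulate`, `fit`, `permtest`, `compare`, `run-all`; exit
codes 0 (success), 2 (validation error), 3 (numerical failure).  Every
output JSON embeds the seed and a hash of the run configuration;
identical configurations produce byte-identical outputs.

## Package layout

* `R/synthetic.R` — ABCD-like two-block generator with planted ground truth
* `R/preprocess.R` — confound encoding/residualization, standardization, VIF
* `R/fit.R` — CCA / PLSC / PLSR and structure coefficients
* `R/inference.R` — permutation testing, explained variance
* `R/comparison.R` — component alignment and the cross-method report
* `R/pipeline.R`, `R/cli.R`, `R/io.R` — driver, CLI, serialization
* `vignettes/method-comparison.Rmd` — models, assumptions, numerical
  choices, limitations
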