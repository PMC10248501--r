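---
title: "Methods: two-sample MR screening in mrscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR screening in mrscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrscreen)
```

## The model and its assumptions

`mrscreen` implements two-sample Mendelian randomization: a set of SNPs
instruments an exposure $X$ (e.g. the standardized abundance of one
gut-microbiota taxon), and their effects on a binary outcome $Y$ (log-odds
scale) are read from an independent GWAS.  Writing $\gamma_j$ for the true
SNP–exposure effect, $\alpha_j$ for any direct (horizontally pleiotropic)
SNP–outcome effect, and $\theta$ for the causal effect of interest, the
working model per instrument $j$ is

$$\Gamma_j = \theta\,\gamma_j + \alpha_j,$$

with observed $\hat\beta_{Xj} \sim N(\gamma_j, \sigma_{Xj}^2)$ and
$\hat\beta_{Yj} \sim N(\Gamma_j, \sigma_{Yj}^2)$ independent between the
two samples.  The three instrumental-variable assumptions map onto the
pipeline as follows: *relevance* is enforced by the association threshold
and the F-statistic filter; *independence from confounders* is argued from
Mendelian inheritance and supported by an optional exclusion list of
confounder-associated SNPs (supplied by the user, e.g. from a phenome-wide
lookup — no web query is performed); *exclusion restriction*
($\alpha_j = 0$) is probed, not assumed, by the MR-Egger intercept,
Cochran's Q, leave-one-out, and funnel diagnostics.

IVW is consistent when all $\alpha_j = 0$; the weighted median tolerates
up to half the weight coming from invalid instruments; the MR-Egger slope
is consistent under the weaker InSIDE condition (instrument strength
independent of direct effects), at a substantial cost in precision.  A
significant IVW estimate whose direction is shared by the WM and Egger
point estimates is treated as causal evidence; a significant estimate with
a direction-reversed Egger slope keeps its category but carries a
`caution` flag rather than being demoted — when the intercept and Q tests
are clean, the IVW estimate remains the headline.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `p_threshold` | 1e-5 | – | Relaxed ("suggestive") threshold; microbiome-scale exposures rarely have genome-wide significant hits, and the F filter guards strength downstream. |
| `r2_max` | 0.1 | – | Instruments with pairwise $r^2 \ge 0.1$ within the window are pruned; estimators assume independent instruments. |
| `window_kb` | 500 | kb | Clumping window half-width, index-SNP-centred, inclusive, position-to-position. |
| `f_min` | 10 | – | Conventional weak-instrument boundary; `F < 10` eliminated, `F = 10` kept (inequalities are strict in the stated direction). |
| `tolerance` | 0.08 | allele freq. | Palindromic SNPs with either EAF in $[0.42, 0.58]$ are dropped as strand-ambiguous; the dominant community default, configurable, with `drop_all_palindromic` as the stricter switch. |
| `n_boot` | 1000 | reps | Weighted-median parametric bootstrap; seedable. |
| `alpha` | 0.05 | – | Two-sided significance for classification and the leave-one-out flag. |

No multiple-testing correction drives classification (raw p-values are
reported, matching the screening design's stated preference for
sensitivity over strict family-wise control); a Benjamini–Hochberg column
is emitted as optional extra output.

## Numerical choices

* **Wald ratio SE** is first-order, $\sigma_{Yj}/|\hat\beta_{Xj}|$.  This
  makes IVW algebraically identical to WLS of $\hat\beta_Y$ on
  $\hat\beta_X$ through the origin with weights $\sigma_{Yj}^{-2}$, which
  the tests exploit as an independent oracle (`lm()` vs the closed form,
  agreement to 1e-10).
* **"Random effects" IVW** means a multiplicative overdispersion scale
  $\phi = \max(1, \sqrt{Q/(J-1)})$ applied to the fixed-effect SE:
  under-dispersion never shrinks a standard error.  A side effect worth
  knowing: under exact homogeneity the test is mildly conservative — at
  $J = 30$ the exact type-I rate is
  $E[2\Phi(-1.96\,\max(1,\sqrt{Q/29}))] \approx 0.042$, not 0.050.
* **MR-Egger** orients every instrument to $\hat\beta_X \ge 0$ before
  regression (required for the intercept to mean average *directional*
  pleiotropy), applies the same $\phi$-flooring to both coefficient SEs,
  and uses t inference on $J-2$ df (a fitted intercept with few
  instruments deserves the heavier tail; a `ci_type = "normal"` switch is
  provided).  IVW uses normal quantiles.
* **Weighted median** interpolates the weighted quantile function at 0.5
  via $p_j = (S_j - w_j/2)/S$; with more than one positive weight
  $p_1 = w_1/(2S) < 0.5$, so the boundary clause only binds for a single
  value.  Its SE is a parametric bootstrap over ratio estimates (the
  original method's formulation), not a nonparametric resampling of
  instruments.
* **Ties and determinism**: clumping breaks equal p-values by
  (chrom, pos, snp\_id); duplicate SNP ids keep the smallest p (ties:
  first occurrence); per-exposure bootstrap seeds are derived as
  `base_seed + polynomial_hash(name) mod (2^31 - 1)`, so screens are
  invariant to exposure ordering and to splitting across invocations.
* **Degenerate inputs**: $\hat\beta_X = 0$ is a degenerate instrument
  (error); below the method minima (IVW 2, WM/Egger 3) an exposure is
  reported not-analyzable rather than failing the screen; zero variance in
  $\hat\beta_X$ is a collinearity error for Egger.

## The synthetic-data generator

`simulate_study()` draws summary statistics directly from the working
model above: MAF $\sim U(0.05, 0.5)$,
$\gamma_j \sim N(0.12, 0.03^2)$, and, for a configurable invalid fraction,
$\alpha_j \sim N(\mu_\alpha, \sigma_\alpha^2)$ drawn independently of
$\gamma_j$ (so InSIDE holds; an `inside_violation` knob correlates them
for exploratory use).  Standard errors follow the per-allele variance
approximation for a standardized trait,
$\sigma = (2\,\mathrm{maf}(1-\mathrm{maf})N)^{-1/2}$, with the default
sample sizes of the motivating application (exposure $N$ = 18,340;
outcome $N$ = 45,563).  The $\gamma$ distribution was chosen once so that
simulated instruments have $F \approx 40$–150 at those sample sizes —
i.e. they look like instruments that already survived an $F \ge 10$
screen, which is the regime every estimator here assumes; it is a
testability choice, not an empirical fit to any real taxon.  Alleles are
assigned at random with a 20% palindromic fraction, and effect alleles are
minor or major at random, so harmonization code paths are exercised by
construction.  Instruments are placed megabases apart on alternating
chromosomes (post-clumping independence); LD fixtures come separately from
`simulate_ld_block()`, whose exponential decay default (0.025/kb at 50 kb
spacing) guarantees pairs on both sides of the $r^2 = 0.1$ threshold in
any block of three or more.

What a green simulation test does **not** establish: realism of the
effect-size distribution of real taxa (unknown and not modelled), LD with
untyped causal variants, winner's-curse bias from selecting instruments in
the same sample, sample overlap between exposure and outcome GWAS, or
case-control ascertainment effects beyond the log-odds SE approximation.

## Open design points and their resolutions

* Acceptance simulations with unstated parameters were pinned once:
  the pleiotropy-recovery scenario uses $\theta = 0$ (bias comparisons are
  then unambiguous), the robustness-ordering scenario uses $\theta = 0.3$,
  $\mu_\alpha = 0.1$, $\sigma_\alpha = 0.02$ with 40% invalid instruments,
  and its bootstrap is scaled to 50 replicates since only point-estimate
  biases are compared.
* Configuration files are JSON (`read_column_map()`); the schema-mapping
  `column_map` exists because public summary-statistics releases do not
  share a header convention.
* Positions are 1-based; indels and multi-character alleles are rejected
  at parse time (harmonization logic is defined for SNVs only); stored
  p-values inconsistent with $2\Phi(-|\beta/se|)$ beyond two-fold warn but
  are kept, since published files often truncate p.

## Known limitations

No LD-proxy lookup for outcome-missing SNPs, no reverse-direction MR, no
MR-PRESSO/mode-based/multivariable estimators, no genotype-level or
coalescent simulation, and no retrieval of real consortium data — the
shipped worked-example table contains published per-method estimates only,
and the headline per-taxon ORs of the motivating screen are not
recomputable without the original summary statistics and LD reference
panel.
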