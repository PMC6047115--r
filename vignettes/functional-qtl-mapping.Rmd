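---
title: "Functional QTL mapping of longitudinal plant phenotypes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional QTL mapping of longitudinal plant phenotypes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

High-throughput phenomics platforms image every plant of a mapping population
daily, producing per-plant trajectories of traits such as projected area
(mm²), height (mm), yellow (senescent) area (mm²) and daily water use (ml)
over days after sowing (DAS). Mapping each timepoint separately tells you
*when* a marker matters; it does not summarise *how* the trait develops.
Functional mapping compresses each trajectory into the parameters of a
biologically interpretable growth model and maps those parameters as
quantitative traits. `growthqtl` implements both views for a multiparental
(MAGIC) recombinant-inbred population and a simulator that generates
populations with known founder mosaics and planted QTL effects, so the whole
chain can be validated against ground truth.

# Growth models

Three non-linear models are fitted per (line, replicate, trait) series:

* logistic: $f(t) = L / (1 + e^{-k (t - t_0)})$ — upper asymptote $L$,
  rate $k$ (per day), midpoint $t_0$ (DAS);
* 4-parameter logistic (4PL):
  $f(t) = D + (A - D) / (1 + (t/C)^B)$ — bottom/top asymptotes $A, D$ (trait
  units), inflection $C$ (DAS, where the curve is halfway between $A$ and
  $D$), and hill slope $B$ (dimensionless, either sign). Note this $B$ is a
  curve parameter; the permutation count below is a different $B$ — the
  clash is historical and both names are kept because each is standard in
  its own literature;
* Gompertz: $f(t) = a e^{-b e^{-c t}}$ — asymptote $a$, displacement
  $b > 0$, rate $c > 0$ (per day).

Polynomials of degree 2–4 in DAS are available as a baseline
(`fit_polynomial()`): they fit the numbers but their coefficients have no
growth interpretation, which is the argument for the non-linear models.

Model selection uses the coefficient of determination
$R^2 = 1 - \sum_i (y_i - \hat y_i)^2 / \sum_i (y_i - \bar y)^2$
(`r_squared()`, `select_model()`), with exact ties broken toward fewer
parameters. On simulated sigmoid data the 4PL wins for area, height and
senescence, matching what the per-trait mean curves look like.

## Numerical choices

Fitting is bounded Levenberg–Marquardt least squares (`minpack.lm::nls.lm`),
chosen because it damps through the near-singular Jacobians that steep
sigmoids produce on coarse DAS grids (a plain Gauss–Newton front end rejects
such starts outright). Starting values are data-driven exact inversions of
each model away from its asymptotes — for the 4PL, $A \approx \min y$,
$D \approx \max y$, $C$ from the half-range crossing, and $B$ and a refined
$C$ from the slope and intercept of $\log\frac{A-y}{y-D}$ on $\log t$ —
followed by three deterministic multi-starts (scale factors 1, 0.7, 1.4);
the converged start with lowest residual sum of squares wins. Parameters are
unconstrained except for positivity where the model requires it ($C > 0$;
Gompertz $b, c > 0$). Constant series are returned as non-converged rather
than as errors, and non-converged fits are excluded from all downstream
mapping. Curve evaluators clamp exponents at ±700 so values are finite for
any finite input.

# The bimodal water-use curve

Daily water use is not sigmoid: it has an uptake mode during stem extension
(around 130 DAS) and a second after heading (around 180 DAS). It is modelled
as a two-component Gaussian mixture on the time axis. A daily curve is
converted to weighted observations — each DAS is an observation weighted by
that day's ml (`curve_to_samples()`) — and fitted by
expectation–maximization (`em_fit()`): posteriors from the current
components (E-step), weighted maximum-likelihood updates of
$(\pi_k, \mu_k, \sigma_k)$ (M-step), iterated until the weighted
log-likelihood improves by less than `tol` ($10^{-8}$) or 500 iterations.
Amplitudes are reported as $\lambda_k = \pi_k \sum_n w_n$, the water volume
attributed to each mode, and the mode distance is summarised by the bimodal
separation $S = (\mu_2 - \mu_1) / (2\sigma_1 + 2\sigma_2)$.

Initialization splits the weighted sample at its weighted median and uses
block moments — deterministic, so fits are reproducible and invariant to
component labelling (components are returned sorted by mean). If a component
s.d. collapses below $10^{-3}$ of the data range it is re-seeded once; a
second collapse flags the fit. Because the mixture is fitted on the
observation window (here ≤ 200 DAS), a mode close to the window edge is
truncated and its $\sigma$ (and slightly its $\mu$) biased low; the direct
least-squares backend (`fit_water_mixture(..., backend = "nls")`), which
fits $\lambda_1 N(t;\mu_1,\sigma_1) + \lambda_2 N(t;\mu_2,\sigma_2)$ to the
curve itself, does not share this bias and serves as a cross-check. The
mixture's conditional-covariate generalisation (component densities
$f(y\,|\,x,\theta)$) is deliberately not implemented: only time-axis modes
are used downstream.

# Heritability and genetic correlations

With $r$ replicates per line, a one-way random-effects decomposition by the
method of moments separates genetic from environmental variance:
$\hat s^2_e$ = within-line mean square,
$\hat s^2_g$ = (between-line MS − within-line MS)$/r$ (replicate-weighted
$r_0$ when unbalanced), truncated at zero (and flagged) since the model
presumes non-negative variance. Heritability is
$H^2 = s^2_g / (s^2_g + s^2_e)$. Method of moments was chosen over REML
because it is exactly testable against closed forms and matches the
simplicity of the variance-ratio definition; REML is out of scope.

Covariances between two parameters use the sum-trait identity
$S_i(x, y) = \big(s^2_i(x+y) - s^2_i(x) - s^2_i(y)\big)/2$ for
$i \in \{g, e\}$, and correlations default to the product-moment form
$r_i = S_i(x,y) / \sqrt{s^2_i(x)\, s^2_i(y)}$. An alternative
normalisation by the arithmetic mean $(s^2_i(x) + s^2_i(y))/2$ is available
behind `denominator = "arithmetic"` for comparison with reports that print
that form; it is not the default because it is not a correlation (it is not
scale-invariant and only reaches ±1 when the two variances are equal).
Raw values outside $[-1, 1]$ — possible with noisy moment estimates — are
clamped and flagged; a zero component variance yields `NA` for that
component rather than an error.

# Genome scans and significance

At each marker, lines are grouped by observed genotype (A/B, plus a
heterozygote class kept only when it has ≥ 3 lines) and tested by classical
one-way ANOVA; replicates are collapsed to line means beforehand. For
simulated data the ground-truth founder mosaic supports an alternative
8-class founder grouping (`grouping = "founder"`), which reports per-founder
means — the multiparental analogue of founder-effect columns. Ancestral
haplotype-probability inference from SNPs is out of scope; grouping is by
what is observed (or, in simulation, known). Each marker also reports the
variance it explains, SSB/SST, labelled `marker_h2` to distinguish it from
the replicate-based line $H^2$ above.

Genome-wide significance is calibrated by permutation: line labels of the
phenotype vector are shuffled $B$ times (default 1000) jointly across all
markers, the genome-wide maximum $-\log_{10} p$ is recorded per shuffle, and
the empirical p-value is $K/B$, the fraction of null maxima at least as
large as the observed maximum. Maxing over markers controls family-wise
error across the genome; per-marker permutation p-values would not. A QTL is
called when $-\log_{10} p > 4$ *and* empirical $p < 0.05$. Support
intervals use a drop method: the contiguous run of markers within 1.5
$-\log_{10} p$ units of the peak, reported in bp; 1.5 gives ≈ 90% coverage
of the planted marker in the package's own simulations. Multiple peaks per
chromosome are called iteratively outside already-claimed support regions.
No additional multiple-testing adjustment is made across traits or
timepoints — each scan carries its own permutation threshold, and readers
should treat the per-timepoint trajectories as descriptive.

Two longitudinal views are provided: `longitudinal_scan()` runs the scan at
every retained DAS and tabulates each marker's $-\log_{10} p$ and
`marker_h2` trajectory (when a marker becomes and ceases to be
significant), and `parameter_scan()` maps the fitted curve/mixture
parameters. `marker_effect_regression()` complements them with per-DAS OLS
of the trait on allele dose (A = 0, H = 1, B = 2), giving signed effect
trajectories.

# Data cleaning

Two rules run before any fitting. First, a DAS is discarded unless every
line of the roster was observed at it (partial imaging days are not
comparable across lines). Second, per (line, replicate, trait) series,
Cook's distances are computed against an OLS cubic-in-DAS reference and
observations above 4× the series' mean distance are removed. The reference
regression, the multiplier and the per-series removal cap (5%) are explicit
options because the threshold rule "> 4 µ" fixes neither the reference nor
the meaning of µ; 4× the mean Cook's distance is the standard reading, and
per-series (not pooled) computation follows from Cook's distance being
defined relative to a single regression fit. The polynomial is fitted on an
orthogonal basis (hat matrix and residuals are basis-invariant) and a series
whose residuals are at rounding-noise level gets all-zero distances rather
than noise ratios. Limitation: on coarse DAS grids a cubic underfits a steep
sigmoid, the lack-of-fit inflates distances systematically, and removal
tends to run into the 5% cap (flagged in the report); with dense daily
series — the intended regime — the reference is adequate.

# The simulator

`simulate_founders()` lays out chromosomes with strictly increasing cM maps
and biallelic founder alleles (minor-allele share among founders bounded by
`founder_maf`). `simulate_magic_rils()` crosses eight founders through the
standard funnel — four 2-way crosses, two 4-way, one 8-way, i.e. three
cycles of recombination — followed by five rounds of selfing, tracking
founder origin per homologue. Meiosis is a Markov walk over marker
intervals with Haldane recombination fractions
$r = (1 - e^{-2d/100})/2$ (no interference), exact at marker resolution.
Because the funnel leaves every locus heterozygous by founder origin at the
onset of selfing, residual heterozygosity has expectation $(1/2)^s$ after
$s$ selfings — the calibration the tests check at $s = 5$ (3.125%). Extra
intercross generations between funnel and selfing are available
(`n_intercross`) but default to zero: the funnel itself already provides
the three recombination cycles of the emulated population's pedigree, and
intercrossing between independent funnels would allow founder-origin
collisions (probability 1/8 per locus), pushing expected residual
heterozygosity below the closed form. The exact pedigree of the emulated
population is not public; the funnel is an approximation and is labelled as
such.

Phenotypes are generated from the growth models themselves: a line's
genetic parameter vector is baseline + planted QTL effects (per-founder
additive effects at a marker; heterozygous positions get the mean of the two
founder effects) + a polygenic line-level deviation; each replicate adds an
independent environmental deviation to the parameters and Gaussian
observation noise to every timepoint, with negative values floored at zero.
QTL effects act on the latent parameters, not on observations — the
generative assumption functional mapping makes — so parameter recovery is
the natural test surface. Default baselines and noise levels are scaled to
glasshouse wheat phenomics (area levelling near 8.5·10⁴ mm² around 130
DAS, height near 700 mm, late-rising senescent area, water-use modes near
130/180 DAS; observation noise ~2% of the asymptote), and the default
design is 208 lines × 2 replicates.

What the simulator does *not* emulate: genotyping error, segregation
distortion, crossover interference, epistasis, G×E, trait-model
misspecification (real trajectories are not exactly 4PL) and spatial or
temporal autocorrelation of the glasshouse environment. Passing tests
therefore demonstrate correctness of the estimators under their own
generative model, not robustness to these real-data features.

# Problem sizes used in validation

The automated checks run at deliberately desk-sized scales, chosen so each
stage still has the statistical resolution its tolerance needs: residual
heterozygosity at 2000 lines; heritability recovery at 200 lines × 2
replicates × 20 Monte-Carlo draws per planted $H^2 \in \{0, 0.5, 0.8\}$
(tolerance ±0.1 on the mean); EM recovery at 5000 samples (modes within ±1
day, weights ±0.05); curve recovery over 100 noiseless series per model
(relative error < 10⁻³) and 200 series at 2% noise (slope unbiased within
2 s.e.); scan calibration over 50 null datasets with B = 200 permutations
and power over 20 replicates of a QTL explaining 30% of line variance at
208 lines (expected detection ≥ 90%). The full pipeline runs at 120 lines,
2 chromosomes × 15 markers, 23 timepoints, B = 200. The analysis scripts
under `analysis/` use the full 208-line design with B = 1000.

# Known limitations

* Single-marker ANOVA ignores kinship/population structure; in a balanced
  MAGIC RIL design this is mild, but the scan is not a mixed model.
* The EM backend inherits edge truncation from the observation window (see
  above); compare with the NLS backend when a mode sits near the window
  boundary.
* Method-of-moments variance components can be noisy at small line counts;
  genetic correlations built from them are poorly estimated whenever either
  heritability is low, and the clamping flag should be taken seriously.
* The support-interval drop value (1.5) is calibrated under the simulator's
  marker density; sparser maps widen true coverage.
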