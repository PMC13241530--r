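---
title: "Methods: multivariate calibration of overlapped UV spectra with chemocal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multivariate calibration of overlapped UV spectra with chemocal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The analytical problem

Cefepime (CFPM) and tazobactam (TAZO) are co-formulated antibiotics whose UV
absorption spectra overlap severely below 250 nm: tazobactam's dominant band
sits near 211 nm with a weak shoulder near 280 nm, while cefepime combines
its principal 257--275 nm region with the steep mid-UV end absorption typical
of beta-lactams. No isoabsorptive or interference-free wavelength exists, so
single-wavelength spectrophotometry cannot quantify the pair and the standard
answer is either chromatography or multivariate calibration. `chemocal`
implements the multivariate route end to end: structured calibration design,
D-optimal validation-set selection, three calibration paradigms (PCR,
firefly-optimized PLS, constrained MCR-ALS), the full validation-statistics
suite, and per-sample sustainability calculators.

Working ranges are 1.00--17.00 µg/mL for CFPM and 1.00--9.00 µg/mL for TAZO,
absorbances on the 210--350 nm grid at 1 nm (141 variables), matched 1 cm
path length absorbed into the absorptivities.

## The synthetic-spectra generator

No instrument data ships with the package; every analysis runs on synthetic
spectra with the statistical structure the calibration methods assume:

* **Beer--Lambert additivity.** A mixture's absorbance is
  \(A_{i\lambda} = \sum_k c_{ik}\,\varepsilon_k(\lambda)\) plus noise. Each
  pure-component absorptivity \(\varepsilon_k\) is a sum of Gaussian bands.
* **Default band library.** TAZO: (211 nm, sigma 8, peak 0.12 AU·mL/µg) and
  (280, 10, 0.02). CFPM: (257, 12, 0.05), (275, 9, 0.07), (235, 15, 0.03)
  plus the end-absorption band (214, 10, 0.08). The last band is what makes
  the sub-250 nm overlap *severe* (cosine similarity of the two absorptivity
  vectors over 210--250 nm is about 0.77); without it the two shapes below
  250 nm are too dissimilar to reproduce the near-collinearity that motivates
  the multivariate treatment. Published spectra constrain only band
  *positions*, so the absorptivity scale is a free design choice; we set it
  so mixtures span roughly 0.1--1.5 AU (up to ~2.5 AU at the joint
  upper-range corner), comfortably inside a double-beam instrument's linear
  range.
* **Noise.** Homoscedastic Gaussian absorbance noise, default sigma = 0.002
  AU -- typical double-beam photometric noise -- with an optional slow
  sinusoidal baseline (off by default). Identical seeds give bit-identical
  realizations.
* **Plasma matrix.** Post-extraction plasma is modeled as a per-analyte
  multiplicative suppression of the Beer--Lambert term (default ~2%,
  i.e. matrix factors near 0.98) plus a small smooth exponential background
  (≤0.01 AU). `simulate_plasma_set()` returns the true matrix factors so the
  matrix-effect statistics can be checked against ground truth.

What the generator does **not** emulate: day-to-day instrument drift,
stray-light or detector nonlinearity at high absorbance, pH/solvatochromic
band shifts, and correlated (pink) noise. Tests passing on this generator
therefore demonstrate the *algorithms* are correct and noise-efficient, not
that any instrument will achieve the same figures of merit.

```{r}
library(chemocal)
pure <- build_pure_spectra()
cal  <- generate_brereton()
spectra <- simulate_mixtures(cal, pure, noise_model(0.002, seed = 1))
plot_spectra(spectra)
```

## Experimental design

**Calibration: Brereton multilevel grid.** Five levels per analyte
(−2...+2) mapped affinely onto each working range give the full 5×5 = 25
mixture grid; CFPM levels are {1, 5, 9, 13, 17} and TAZO levels
{1, 3, 5, 7, 9} µg/mL with level 0 at the range centers (9 and 5). Run
order follows the cyclic-shift convention (the second factor's level
sequence rotates by the block index); ordering does not affect any
downstream computation.

**Validation: Fedorov exchange.** Candidates are the 1 µg/mL lattice over
the domain (17 × 9 = 153 points) minus the 25 calibration coordinates.
`fedorov_select()` maximizes \(\det(X^\top X)\) of a quadratic
response-surface model \([1, x_1, x_2, x_1x_2, x_1^2, x_2^2]\) on
[−1, 1]-scaled factors, using the classical delta rule
\(\Delta = d(x_{in}) - d(x_{out}) - [d(x_{in})d(x_{out}) - d(x_{in},x_{out})^2]\)
with variance function \(d(x) = x^\top (X^\top X)^{-1} x\). The quadratic
model is the substantive choice here: a linear information model is maximized
by corner replicates only, whereas a 13-point quadratic-optimal set spans
peripheral, intermediate and centroidal regions of the domain -- the spatial
spread one wants in an external validation set. Defaults: 20 random
restarts, relative-improvement tolerance 1e−9, ties broken toward the lowest
candidate index. Scaling is derived from the candidate pool, so an affine
rescaling of the domain leaves the selected subset unchanged.

## Calibration models

All three models share one contract: fit on a (spectra, concentrations)
pair, predict concentration tibbles for new spectra on the same grid.

**PCR.** SVD of the preprocessed calibration matrix; concentrations are
regressed on the leading scores; the component count minimizes leave-one-out
RMSECV (preprocessing refit inside every fold), with ties at numerical zero
resolved to the smallest k and an optional parsimony tolerance.
*Preprocessing default is mean-centering only.* Full autoscaling is
implemented (`scale = TRUE`) but deliberately not the default: with
band-shaped spectra large parts of the 210--350 nm window carry no analyte
signal, and dividing those channels by their (noise-level) standard
deviation promotes them to unit-variance pure noise. On the default
simulation this inflates validation errors by one to two orders of magnitude
and biases recoveries; mean-centering keeps PCR noise-limited. The
autoscaled mode remains available for comparability studies and is the
configuration under which PCR shows its textbook disadvantage against
FA-PLS and MCR-ALS.

**FA-PLS.** A firefly swarm performs wavelength selection, then a NIPALS
PLS1 model is fitted per analyte on the masked channels with k chosen by
leave-one-out RMSECV. Swarm mechanics: continuous positions in
\([0,1]^p\), mask = position > 0.5; brightness is the inverse 5-fold
cross-validated RMSECV of PLS on the masked channels at a fixed inner
dimension (2 latent variables -- leave-one-out inside a 100-generation swarm
would be needlessly costly); each firefly moves toward every brighter one
with attractiveness \(\beta_0 e^{-\gamma r^2}\) plus uniform perturbation
\(\alpha(u - 0.5)\), and the global best is exempt from movement (elitism),
making the best-so-far fitness non-increasing. \(r^2\) is the *mean* squared
position difference: with 141-dimensional positions a raw Euclidean
\(r^2\) would be O(p) and \(e^{-\gamma r^2}\) would vanish for the tuned
\(\gamma\) of 0.8--0.9, freezing all attraction; normalizing by dimension
keeps the attractiveness scale where those coefficients are meaningful.
Masks that fall below `min_wavelengths` are repaired by activating the
highest-position channels. Tuned parameters: population 25, 100
generations, \(\beta_0 = 1\), \(\alpha\)/\(\gamma\) = 0.25/0.9 for CFPM and
0.20/0.8 for TAZO, one swarm per analyte (the parameters differ per
analyte, which is why fitting is per-analyte rather than joint).

**MCR-ALS.** Bilinear decomposition \(X \approx C S^\top\) by alternating
non-negative least squares (per-row NNLS, unconstrained solve fast-path when
no constraint binds). The rank comes from evolving factor analysis:
singular values of growing forward/backward row windows, with rank = number
of full-matrix singular values above a noise threshold. The default
threshold is \(2\sigma(\sqrt{n} + \sqrt{p})\) -- twice the upper
Marchenko--Pastur edge of an iid noise matrix -- with sigma supplied or
estimated from the median of the smaller half of the spectrum, floored at
machine precision for noiseless input. Constraints: non-negativity on both
factors; closure rescales each calibration row of C to the known mixture
total; optional unit-norm spectral normalization moves the compensating
scale into C so \(CS^\top\) is unchanged. Closure and normalization both
pin the scale of the decomposition, so they are mutually exclusive: the
default applies closure whenever reference concentrations are available and
normalization otherwise. Initialization uses the reference concentrations
when supplied (rectified singular vectors otherwise); resolved components
are assigned to analytes by maximal correlation with the reference profiles,
and a per-analyte affine map converts resolved profiles to µg/mL. Unknowns
are resolved with non-negativity only (their totals are unknown, so closure
cannot apply). Convergence: relative change in the percent lack of fit
below 0.1%, cap 50 iterations.

## Validation statistics

For reference \(y_i\) and predictions \(\hat y_i\) over n samples:
RMSE \(= \sqrt{\sum(y_i - \hat y_i)^2 / n}\), bias \(= \sum(y_i - \hat y_i)/n\),
SEC \(= \sqrt{\sum(y_i - \hat y_i - bias)^2/(n-1)}\), and the identity
RMSE² = bias² + ((n−1)/n)·SEC² is asserted in the tests. Two relative-RMSEP
conventions are reported side by side: the *standard* RMSE/\(\bar y\) × 100,
and the *printed* variant that divides the root summed squares by n rather
than \(\sqrt n\) (exactly \(1/\sqrt{n}\) times the standard form). The
dimensional bookkeeping only works under the standard convention -- a ~0.3
µg/mL error on a ~7 µg/mL mean is a few percent, not a few tenths -- so the
standard form is what performance statements refer to; the printed variant
is kept so the two can be compared explicitly. BCRMSEP is defined as the
bias-removed SEC-style spread on a prediction set (with n−1, by analogy to
SEC).

**NAS detection limits.** The net analyte signal of analyte k is the
projection of its unit-concentration spectrum onto the orthogonal complement
of the other components' span; its norm is the multivariate sensitivity SEN,
and LOD = 3.3·\(\delta_r\)/SEN, LOQ = 10·\(\delta_r\)/SEN (so LOQ/LOD =
10/3.3 always). \(\delta_r\) defaults to the fitted model's RMS spectral
reconstruction residual on the calibration data and can be overridden. For
MCR the component spectra are the resolved ones; for PCR/PLS they are the
classical least-squares estimates \(\hat S = (Y^\top Y)^{-1} Y^\top X\) from
the known calibration concentrations.

**Inference.** Recoveries are tested against 100% with the one-sample t
statistic (critical values at upper-tail 0.025 and 0.01 from the t quantile
function); recovery vectors of the different models on the shared validation
set form the groups of a classical one-way ANOVA (base `aov`), with the
critical F at the group-derived degrees of freedom rather than any
hard-coded constant. The elliptical joint confidence region fits
\(\hat y = a + b\,y\) (predicted on reference) and draws
\(\{\beta : (\beta - \hat\beta)^\top X^\top X (\beta - \hat\beta) \le
2 s^2 F_{2, n-2, 1-\alpha}\}\); the ellipse geometry comes from the
eigendecomposition of \(2 s^2 F (X^\top X)^{-1}\), and the method is judged
unbiased when the region contains (0, 1). A perfect fit (s² = 0) yields a
zero-area region which is reported as containing the ideal point with an
explicit `zero_area` flag rather than erroring. Matrix factors are
MF = plasma/neat prediction per spike level, ME% = (MF − 1)·100.

## Sustainability calculators

The per-sample carbon footprint is the double sum
\(CF = \sum_i P_i\,t_i\,EF_{elec} + \sum_j m_j\,EF_j\) over instrument
electricity use and consumable masses; the package ships an editable example
inventory (`example_cf_inventory()`) rather than claiming any particular
published total, since cradle-to-gate emission factors are institution
specific. Whiteness-style panels aggregate by a weighted arithmetic mean
(equal weights by default) rounded half-up to the requested decimals; the
four sub-scores 90.1/86.2/87.9/70.0 aggregate to 83.6.

## Numerical choices, test scales, and limitations

* All stochastic routines take explicit seeds; the pipeline derives
  per-stage seeds from one master seed (default 20260605) by fixed offsets
  and echoes the config hash into every artifact.
* Firefly fitness values are memoised per mask within a swarm, which makes
  the full 25 × 100 swarm run in seconds on the 25 × 141 calibration matrix
  without changing any result.
* Property-style tests run at deliberately reduced sizes chosen as the
  package's own test scale: swarm tendencies use population 10 over 15
  generations across 10 seeds; noise monotonicity uses 6 seeds at three
  noise levels; EFA rank stability uses 100 seeded simulations; EJCR
  coverage uses 1000 simulated unbiased prediction sets; the end-to-end
  checks run the full default pipeline (complete swarm) once.
* On exact bilinear synthetic data every sensibly configured linear
  calibration reaches the same noise-limited floor, so the default pipeline
  shows near-ties between center-only PCR, FA-PLS and MCR-ALS. The
  qualitative hierarchy MCR-ALS ≤ FA-PLS ≤ PCR emerges when PCR is run
  full-spectrum autoscaled -- its textbook configuration under pronounced
  collinearity -- and that is how the hierarchy property is tested.
* MCR-ALS rotational ambiguity is mild here because closure plus
  non-negativity and a rank-2 system constrain the solution tightly;
  with more components or without closure, resolved spectra are unique only
  up to the usual rotational bands.
* The EJCR assumes homoscedastic regression residuals; with
  concentration-proportional errors its nominal coverage degrades.

```{r}
run <- run_pipeline(chemo_config(seed = 20260605))
tidy(run)       # per-model, per-analyte validation metrics
glance(run)     # one-line run summary
autoplot(run$validation$`MCR-ALS`$ejcr$CFPM)
```
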