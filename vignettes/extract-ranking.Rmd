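---
title: "Ranking extract preparations and attributing their bioactivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking extract preparations and attributing their bioactivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemoscore)
```

`chemoscore` answers two questions about a panel of extract preparations
characterised across many assays: *which preparation is best overall?* and
*which measured constituents drive the bioactivities?* This vignette
documents the models behind each stage, the parameters that matter, the
conventions the package fixes where the methodology leaves room, and what
the test suite does and does not establish.

## The data model and the not-detected state

A `measurement_matrix` holds non-negative assay means (extracts × variables)
with optional per-cell standard deviations and an explicit **not-detected
(ND)** marker. ND is neither zero nor missing: it records that an instrument
saw nothing above its detection limit. In the packaged beetroot tables the
eight supercritical-CO2 extracts are ND for all eleven phytochemical
variables — CO2 is non-polar and does not extract the polar phenolics and
betalains — while their bioactivity assays are measured and substantial.

Because downstream stages want different resolutions, ND is resolved
explicitly per stage (`apply_nd_policy()`):

* `zero` — ranking: below detection means "contributes nothing on this
  criterion". This is the convention under which the packaged tables
  reproduce the published ranking, with column extremes taken over all 20
  extracts including the resolved zeros.
* `drop_rows` — surrogate fitting: the network needs complete input
  profiles, so only the 12 non-supercritical extracts are used.
* `error` — strict stages that should never silently impute.

## Assay reduction

The betalain stage implements the von Elbe three-wavelength correction.
From absorbances $a$ (538 nm), $b$ (476 nm), $c$ (600 nm):

$$X = 1.095\,(a - c), \qquad Z = a - X, \qquad Y = b - Z - X/3.1,$$

where $X$ is betanin absorbance corrected for coloured impurities, $Y$ the
corrected vulgaxanthin-I absorbance and $Z$ the impurity absorbance.
Concentration follows $C\,[\mathrm{mg}/100\,\mathrm{mL}] = A \cdot F \cdot
1000 / A^{1\%}$ with dilution factor $F$ (25 and 12.5 are the documented
microplate presets, any positive value is accepted) and absorbance
coefficients $A^{1\%} = 1120$ (betanin) and $750$ (vulgaxanthin-I).

Two deliberate choices:

* **Negative corrected absorbances are flagged, never clamped.** A negative
  $Y$ or $Z$ is physically impossible and therefore diagnostic of blank or
  scatter problems; clamping would hide exactly the wells QC should see.
* **The per-100-g-material conversion is a hook, not a formula.** The
  equations end at mg/100 mL of assay solution; converting to a per-mass
  basis needs the sample mass and extract volume of each preparation, which
  are protocol knowledge. `reduce_absorbance_panel(scale = )` accepts the
  factor; the packaged tables ship already-reduced values and bypass this
  stage entirely.

DPPH scavenging is $100\,(A_{control} - A_{sample})/A_{control}$, bounded in
$[0, 100]$ for valid readings. Other assays (ABTS, reducing power,
β-carotene bleaching, the two pharmacological inhibitions) publish no
reduction formula here; their values enter as data, and a generic
ordinary-least-squares standard curve (`fit_calibration()` /
`apply_calibration()`) covers equivalent-based units.

## Standard-score ranking

Each variable is min-max normalized over the retained extracts,
$\bar{x}_i = (x_i - \min x_i)/(\max x_i - \min x_i)$, and each extract gets
the weighted score $SS_e = \sum_i w_i \bar{x}_{ei}$ with $w_i \ge 0$,
$\sum w_i = 1$. All nine ranking variables are treated as
larger-is-better; a smaller-is-better variable would need a direction flag
before normalization, which the packaged study does not require.

**Weights.** The published account multiplies the nine normalized variables
by weights whose values it never states. Equal weights $w_i = 1/9$
reproduce the five published scores to about the third decimal
(0.6745, 0.6290, 0.5805, 0.5692, 0.5612 against printed values 0.674,
0.629, 0.581, 0.568, 0.561), so equal weighting is the package default.
One printed value (0.568) differs from the recomputation by 0.0012 —
slightly more than printing precision; the remaining four agree to
≤ 0.0005. We treat 0.5692 as the correct value of that extract's score
under the stated convention.

**Ties** are broken by input row order (stable), so ranking is a pure
function of the matrix.

## Correlation PCA

`fit_pca()` eigendecomposes the correlation matrix by default. The panel
mixes units spanning five orders of magnitude (ABTS ~10³ µmol TE/100 g,
caffeic acid ~10⁻² mg/g); covariance PCA would be an ABTS ranking in
disguise. Covariance scaling remains available for same-unit panels.

Conventions: eigenvalues are clipped at zero against numerical noise;
each component is sign-flipped so its largest-magnitude loading is positive
(deterministic output); the contribution of variable $i$ to component $k$
is $100\,v_{ik}^2 / \sum_i v_{ik}^2$, and the loading sign is reported
separately. An alternative reading — contribution to *total* variance,
$100\,\lambda_k v_{ik}^2 / \sum_k \lambda_k$ — is easily derived from the
returned eigenvalues and loadings but is not the default, since
per-component shares are what loading plots display.

The published explained-variance percentages for this panel (33.50, 22.57,
12.53%) cannot be pinned down: they depend on whether the 20-extract
ND→0 matrix or the 12 complete rows entered the PCA, which is not stated.
Both conventions are exposed (`nd = "zero"` vs `nd = "drop_rows"`); neither
is asserted against the printed numbers, and the package's own checks
validate the eigenstructure against an independent SVD oracle instead.

## The perceptron surrogate and weight-path sensitivity

`fit_mlp()` fits $Y = f_1(W_2 \cdot f_2(W_1 X + B_1) + B_2)$ on min-max
normalized inputs and outputs, minimising the sum of squared residuals
(SOS) by BFGS with analytic gradients and multiple random restarts
(uniform initial weights in ±0.5). Defaults follow the study's selected
configuration: tanh hidden / identity output, 8 hidden neurons, ≥ 20
restarts, up to 2000 iterations per restart — a budget at which the SOS for
the packaged 12 × (11 → 6) problem plateaus at interpolation
(SOS ≈ 10⁻²⁷, pooled R² = 1). `screen_topologies()` reproduces the
topology-screening step (hidden sizes 5–20 by default, selection by
validation SOS, or training SOS when no validation split is held out) and
returns the full screening table so the selection is auditable.

**The surrogate interpolates by design.** With 12 samples and 150
weights-plus-biases the network can drive the training SOS to zero; pooled
R² ≥ 0.999 certifies the surrogate reproduces the data, not that it
generalises. Its purpose is the sensitivity decomposition:

$$RI_{ij}(\%) = \frac{\sum_k w^{(1)}_{ik} w^{(2)}_{kj}}
{\sum_i \bigl|\sum_k w^{(1)}_{ik} w^{(2)}_{kj}\bigr|} \cdot 100$$

the Yoon weight-path importance: signed, biases excluded, and normalized so
magnitudes sum to exactly 100% per output. The denominator takes the
absolute value of each input's aggregated path sum — the standard reading,
under which signed importances with magnitudes summing to 100 (as in the
published figures) are well defined. The literal signed-sum denominator is
available as `yoon_ri(literal = TRUE)` for comparison; it loses the
100%-sum property whenever path sums disagree in sign. Published
importance percentages depend on one specific trained weight set that is
not reproducible from the available text, so the package validates the
operator by brute-force path enumeration and by teacher-network recovery
instead (below).

`exponential` is accepted as an activation alongside identity, logistic and
tanh, standing in for the logarithmic/exponential family named in
screening-software activation menus.

## What the synthetic-data generator emulates

`gen_extract_matrix()` draws multivariate-normal extract × variable
matrices with block correlation structure, truncates at zero and stamps an
ND block; `sim_config_beetroot()` mimics the shape of the packaged study
(20 × 17, an 8 × 11 ND block, a positively correlated phenolics block and a
positively correlated antioxidant-assay block, means and sds at table
scale). Zero-truncation biases marginal means when the mean/sd ratio is
small; the Monte-Carlo checks therefore use configurations with
mean ≥ 3 sd. `gen_absorbance_panel()` inverts the betalain equations from
known pigment concentrations (plus impurity level and Gaussian read noise),
giving the reduction stage a ground truth; `gen_teacher_network()` supplies
exact recovery targets for the trainer and for the importance operator.

What passing these tests shows — and does not show. The generators produce
clean Gaussian blocks, exact correction-equation inverses and noise-free
teachers; real assay panels have skewed marginals, heteroscedastic
replicate error, inter-assay nonlinearity, and detection limits that censor
rather than delete. The tests certify the *arithmetic* of every stage and
the *conventions* (ND handling, normalization, sign and tie rules); they do
not certify that equal weights, ND→0, or an interpolating surrogate are the
right scientific choices for a new dataset.

## Numerical choices and problem sizes

* Optimizer: `stats::optim` BFGS, relative tolerance 10⁻¹², analytic
  gradients; any quasi-Newton or better method satisfies the contract.
* Determinism: every stochastic routine takes a seed and is a pure
  function of (inputs, configuration, seed).
* Test problem sizes were chosen once as the smallest that exercise each
  property cleanly: teacher recovery uses a 3-4-2 network on 150 noise-free
  samples (10 restarts); Monte-Carlo generator checks use n = 10 000 rows
  for correlations (±0.02) and n = 1000 wells for unbiasedness; the
  study-scale surrogate uses its own 12 × (11 → 6) problem with 20
  restarts.
* Degenerate inputs fail fast with named offenders: constant columns under
  correlation scaling or min-max normalization, non-PSD correlation
  blocks, all-zero path sums, zero-variance targets.

## Known limitations

* The ranking propagates means only; the ± sd columns are carried but no
  uncertainty is propagated into SS or ranks.
* Yoon importance is a weight-path linearisation; for strongly nonlinear
  surrogates it can disagree with perturbation-based sensitivity.
* The HPLC-input surrogate can only be fitted on extracts with complete
  chromatographic profiles; conclusions about the supercritical extracts'
  bioactivity drivers are outside its support.
* No multi-criteria methods beyond the weighted standard score (no
  TOPSIS/AHP), no factor rotation in PCA, no deep architectures.
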