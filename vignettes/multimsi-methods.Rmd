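---
title: "Correlative multimodal MSI: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlative multimodal MSI: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multimsi)
```

# The problem

Mass spectrometry imaging (MSI) records a full mass spectrum at every pixel
of a tissue section, producing hundreds of ion-intensity images at a
spatial resolution of ~10 µm. Hyperspectral fluorescence microscopy of the
same (or a consecutive) section records a 32-channel emission spectrum per
pixel at sub-micrometer resolution. Relating the two — e.g. to ask which
lipid and peptide species co-localize with structurally distinct regions of
amyloid plaques — requires three things this package provides:

1. **pixel-precise geometric alignment** of modalities acquired on
   different instruments with different grids and fields of view;
2. **multiblock decomposition** of the aligned pixel-by-variable matrix
   into variation shared by all modalities, variation shared by a subset,
   and variation unique to one;
3. **data-driven image fusion** that uses the registered microscopy
   channels to predict individual ion distributions beyond the MSI
   acquisition resolution.

Everything operates on a single container, the `msi_cube` (pixel grid ×
spectral variables), flattened to a `pixel_matrix` over *data pixels* —
pixels whose total ion current is nonzero. Pixels with zero total ion
current ("black pixels", off-tissue or outside the acquisition area) never
enter any model and are reinstated only for visualization
(`restore_score_image()`).

## Grid convention

Stated once, used everywhere: pixels are addressed 1-based as (row, col);
continuous coordinates are x = col, y = row with pixel centers at integer
positions, so pixel (r, c) covers [c−0.5, c+0.5) × [r−0.5, r+0.5). imzML
1-based coordinates map directly onto this convention. (A 0-based
convention was considered and rejected: R is natively 1-based, and a mixed
convention is the classic source of off-by-one registration bugs.)

# Preprocessing

* **Baseline correction** (`baseline_correct()`): a rolling minimum over a
  centered window (default 101 variables) is subtracted per spectrum. The
  window includes the point itself, so the baseline never exceeds the
  signal and corrected intensities stay nonnegative. The method is
  deliberately simple and monotone; no model of peak shape is assumed.
* **Normalization** (`rms_normalize()`): each data-pixel spectrum is
  divided by its own root-mean-square intensity, leaving every data pixel
  at RMS exactly 1. Black pixels are untouched by definition, so the pixel
  partition is invariant under normalization.
* **Peak-region extraction** (`peak_extract()`): noise between peaks of
  the dataset mean spectrum is removed by keeping the variable columns
  where the mean spectrum reaches `noise_factor` (default 3) times the
  median absolute deviation (`stats::mad`, with the 1.4826 consistency
  constant) of the mean spectrum. All data points over a peak are kept —
  no centroiding and no binning, so overlapping species survive as
  separate columns. Retention is monotone in `noise_factor`, and a factor
  of 0 keeps everything.

# Registration

Single ion images are too noisy for intensity-based registration, so each
modality is summarized by a **PCA score image** (`pca_reference_images()`,
default PC1, selectable because the most informative component can differ
between modalities). The chain in `register_modalities()` is:

1. optional **coarse alignment** from control points
   (`coarse_align()`, least-squares affine; ≥3 pairs required, ≥5
   spread over the tissue recommended);
2. **1+1-evolutionary refinement** (`one_plus_one_register()`) under a
   Mattes-style mutual-information objective (`mattes_mi()`: joint
   histogram, 60 bins per axis, dense evaluation by default, in bits).
   The objective uses a first-order Parzen (triangular) histogram window:
   hard box binning makes the MI surface jagged under sub-pixel motion
   and traps the optimizer, while the triangular window varies smoothly.
   The reported metric keeps box binning as its default so the identity
   MI(A, A) = H(A) holds exactly; both windows are exposed;
3. an **exhaustive search** over optimizer parameters
   (`exhaustive_search()`) selecting the run with the best structural
   similarity, ties broken by MI;
4. **bicubic resampling** of the full cube (`apply_transform()`), with
   out-of-domain pixels set to 0 (black) and bicubic overshoot clipped at
   zero.

## Optimizer parameterization

The evolutionary optimizer perturbs a 6-parameter affine (tx, ty,
rotation, log-scales, shear) with an isotropic Gaussian step of the
current search radius; a child replaces the parent only if its MI
improves, the radius grows by `growth_factor` on success and shrinks by
its reciprocal on failure, and the search stops at `max_iterations` or
when the radius falls below `epsilon`. The result can never be worse than
its initialization. A (1+1) strategy gains roughly one parameter
direction of progress per evaluation, so single direct runs default to
300 iterations; inside the exhaustive parameter search each grid point
runs the conventional constant of 100 iterations. An optional
multiresolution pyramid (`pyramid_levels`) widens the capture range when
no coarse alignment is available.

Parameters are scaled so **one radius unit corresponds to about one
image-width of border displacement**. Under this normalization the
conventional radius limits (6.25×10⁻⁴ … 6.25×10⁻²) correspond to
sub-pixel up to ~8-pixel steps on a 128-pixel image. A scaling of one
pixel per unit was considered and rejected: it would make the
conventional radius limits produce steps of at most 0.06 px, i.e. an
inert optimizer.

The published parameter ranges for the exhaustive search are written with
"increment 1" on scales of 10⁻⁷–10⁻³, where an additive increment of 1 is
meaningless; `default_search_grid()` therefore spans the stated limits
with four log-spaced values for ε and the initial radius, and sub-samples
the growth-factor sequence 1.005–1.1 (step 0.0005) to at most 20 points.
`register_modalities()` defaults to a reduced 4-point grid
(growth ∈ {1.02, 1.05} × radius ∈ {6.25×10⁻³, 2×10⁻²}) chosen inside the
stated limits in the region where 100-iteration runs reliably reach
sub-pixel alignment on structured references; the full grid remains one
argument away.

During optimization the moving reference is warped with *linear*
interpolation (cheap, smooth objective); the final cube resampling is
*bicubic*, which gave the best structural similarity in our evaluations
and is the default everywhere.

## Evaluation metrics

`similarity_report()` returns MSE, SSIM (11×11 Gaussian window, σ = 1.5,
K1 = 0.01, K2 = 0.03), multi-class Jaccard, and mutual information with
the individual and joint entropies. Histogram-based metrics quantize both
images to 8-bit unsigned integers by a **joint** linear min–max rescale to
[0, 255] followed by floor — joint scaling keeps the intensity-label
mapping comparable across the pair (per-image scaling is available). The
multi-class Jaccard averages the per-intensity-label Jaccard over labels
present in either image; a binary (>0 foreground) mode is exposed. All
entropies use log base 2 ("bits") with zero-probability bins contributing
0, and the three metrics are deterministic — no sampling.

The three metrics are reported **separately and never aggregated**: how to
combine them into a single registration-accuracy number is a qualitative
judgement we do not automate.

# Multiblock OnPLS decomposition

Registered cubes are cropped to the common grid and stacked over one
shared pixel index (`assemble_multimodal()`); a pixel is treated as black
if it is black in *any* block, which guarantees the model matrix has no
missing values (the decomposition cannot process missing values). Blocks
are mean-centered for descriptive decomposition and unit-variance scaled
for predictive modeling (`center_scale()`).

`fit_onpls()` partitions each centered block X_b into

    X_b = globally joint + locally joint + unique + residual,

extracted sequentially with deflation. Three design choices matter, all
adopted after the obvious alternatives failed on phantoms with known
ground truth:

* **Global consensus by subspace intersection.** For three or more blocks,
  maximizing the plain sum of pairwise score covariances lets structure
  shared by only one block pair leak into the "all blocks" component. The
  globally joint weight of block i is instead required to lie in *every*
  cross-covariance subspace span(X_iᵀX_j): it is the top eigenvector of
  the summed subspace projectors. Only cross-covariance directions whose
  singular values stand out above the bulk (>2× the median) are admitted,
  capped at rank 5 — without this gate, random subspace overlap in narrow
  blocks (e.g. a 20-variable peptide block) manufactures joint structure
  out of independent noise. For two blocks the criterion reduces to the
  dominant SVD direction of X₁ᵀX₂ refined by an alternating update in
  which each block's weight is driven only by the other block's score.
* **Leave-one-out deflation.** Each block is deflated against the
  normalized consensus of the *other* blocks' scores, never against a
  direction containing its own score. A block therefore cannot certify
  its own variance as joint: for mutually independent noise blocks the
  spurious joint share collapses to chance level (~1/n). Deflating
  against the pooled span of all per-block scores was rejected for a
  subtler reason as well: per-block joint scores are nearly collinear, so
  orthonormalizing their span amplifies their small block-specific
  admixtures into full extra directions that silently strip locally joint
  and unique variance.
* **Per-block orthonormal deflation directions.** Successive deflation
  directions of one block are Gram-Schmidt-orthogonalized against that
  block's earlier ones, so the four parts are mutually orthogonal, their
  Frobenius norms are additive, and the reconstruction identity holds to
  machine precision. Unique components (dominant principal directions of
  the remainder) are exactly orthogonal to the block's joint deflation
  directions; orthogonality to another block's *raw* score holds only up
  to the (high) correlation between that score and the consensus.

Locally joint components repeat the consensus extraction on the deflated
blocks of each *explicitly requested* subset (`n_local = list("1,2" = 1)`)
— which subsets are meaningful is a modeling decision the caller makes,
not something inferred from the data. Component counts are user-chosen;
`cross_validate_components()` gives an advisory count from seven-fold
venetian-blind (interleaved rows) cross-validated Q², recommending the
largest count that still improves Q² by more than 1 percentage point.
Held-out elements are predicted through the loading space from the other
columns of their row (leave-one-column-out); naively projecting held-out
rows onto the loadings would shrink residuals for *any* loadings,
including pure noise, and would always recommend more components.
Blocks are *not* rescaled relative to one another beyond column
preprocessing; the width imbalance between blocks (673/553/20 in the
emulated datasets) is part of the data and deliberately not hidden.

No claim is made that this decomposition numerically matches any
commercial implementation; it satisfies the stated contracts
(reconstruction, additivity, orthogonality, ground-truth recovery on
phantoms) and is fully reproducible.

# OPLS, VIP and image fusion

For predictive modeling the concatenated, unit-variance-scaled MSI matrix
is X and the block-averaged hyperspectral channels are Y
(`downsample_hyperspectral()`: every microscopy pixel center is mapped
through the registration transform and averaged into its MSI pixel
footprint). `fit_opls()` removes `n_orthogonal` structured Y-orthogonal
components from X, then fits `n_predictive` PLS components (NIPALS).

Variable importance in projection (`vip()`) is

    VIP_k = sqrt( K_p · Σ_a w²_ak · SS_comp,a / SS_cum ),

with per-component predictive weights normalized to unit length — the
normalization is what makes the identity Σ VIP² = K_p (average VIP = 1)
hold exactly, for any data. Variables with VIP > 1 are "more important
than average" and are the default selection for fusion
(`select_variables()`).

`fuse()` trains, per selected ion, a univariate PLS regression from the
block-averaged microscopy features to the measured ion image, then applies
it at full microscopy resolution. Per-ion models (rather than one
multivariate model) keep the per-ion reconstruction scores independent.
Each ion gets:

* the high-resolution prediction;
* a **reconstruction score** = 100 × (1 − SS_res/SS_tot), comparing the
  block-averaged prediction with the measurement at MSI resolution — the
  standard variance-explained reading of "deviation of prediction from
  measurement" (the score is stored from exactly this computation, so
  recomputing it from the stored images reproduces it identically);
* an absolute-residual image at MSI resolution;
* a **95% CI half-width image** from linear-regression
  prediction-interval propagation in the latent score space
  (t-quantile × σ × sqrt(1/n + zᵀ(ZᵀZ)⁻¹z)), documented as one admissible
  reading since no formula is published. Note the statistics: the CI is
  *narrow* where features sit near the training mean (for tissue imagery,
  the abundant background) and *wide* at high-leverage feature values;
* the original, non-interpolated ion image, stored alongside so fusion
  results can always be cross-checked against the measurement.

Microscopy features are the raw channels by default; optional local 3×3
mean/variance texture features sit behind a config flag (off for
parsimony). Ions with zero variance are skipped with a warning.

# The synthetic phantom

`make_phantom()` generates the stated world every test runs in:

* a smooth elliptical tissue region on a 64×64 grid of 10 µm pixels
  (~2400 data pixels) with off-tissue zeros; the tissue base intensity is
  **flat** inside the ellipse — a constant base is removed exactly by
  mean-centering, so the planted patterns are the only structured
  covariance (an intensity gradient would itself be a dominant global
  component and would confound every recovery experiment);
* 6 non-overlapping plaque-like foci of 50–100 µm diameter, alternating
  cored (30–40 µm core) and diffuse morphotypes;
* three MSI blocks of 673/553/20 variables (the 53%/43%/2% width split of
  the emulated datasets); 10% of each block's variables load on each
  applicable planted pattern: one global map (whole plaques), a core map
  local to blocks 1+2, a periphery map local to blocks 2+3, and one
  unique map per block. All maps are normalized to unit variance over
  tissue pixels so a stated effect size (default 3× the tissue base)
  means the same thing for sparse focal and diffuse patterns, and are
  re-drawn until pairwise |r| < 0.2;
* noise: multiplicative log-normal (σ = 0.2, i.e. single-pixel SNR ≈ 5,
  the MSI-like heteroscedastic regime) plus a small additive half-normal
  floor;
* a 32-channel hyperspectral cube (415–690 nm, 8.9 nm bands) at 4× finer
  resolution mixing two smooth synthetic emission endmembers (480 nm
  "core-type", 545 nm "periphery-type") over the high-resolution core and
  periphery maps, plus broad autofluorescence. The endmembers emulate the
  spectral separation of amyloid-binding probes; no claim is made that
  they match any real dye;
* per-modality affine misalignments (recorded as ground truth before
  warping) and the exact microscopy→MSI coordinate mapping.

`n_features = 0` produces fully featureless cubes — mutually independent
noise — used for the null experiments. What a green phantom test does
*not* establish: performance on real tissue chemistry (correlated peaks,
matrix clusters, isotopes), non-affine tissue deformation, or vendor
file-format quirks; all of these are outside the generator's model.

# Numerical and degenerate-input policy

* All decompositions are SVD-based with a deterministic sign convention
  (largest-magnitude loading positive), so results are bit-reproducible.
* Stochastic steps (the 1+1-ES, spatial sampling) take explicit seeds,
  recorded in results; the pipeline derives every stage seed from one
  root seed.
* Constant images yield MI = 0 with a warning; zero-variance columns
  under unit-variance scaling are flagged and left centered; requested
  component counts beyond the available rank truncate with a warning;
  empty ROI masks, empty peak sets, empty block intersections and
  non-invertible transforms are hard errors.
* imzML integrity on read is enforced by UUID agreement between XML and
  ibd plus declared byte extents (no SHA-1 digest is computed in this
  environment); a mismatch is a format error.
* Hyperspectral input is accepted as multi-channel CSV arrays
  (`read_hyperspectral_csv()`) rather than vendor formats; conversion
  from proprietary cubes is documented as the user's step.

# Known limitations

* Registration is affine only; tissue data needing non-rigid alignment is
  out of scope by design, and badly non-affine inputs are flagged by poor
  SSIM rather than rejected.
* The OnPLS scheme is one documented member of the family of sequential
  multiblock decompositions; different deflation conventions give
  different (equally defensible) variance attributions.
* Linear models throughout: nonlinear relations between modalities are
  invisible to OnPLS, OPLS and PLS fusion alike.
* The 95% CI images propagate regression uncertainty only; they do not
  model registration error or MSI measurement noise.
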