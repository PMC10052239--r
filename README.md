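# multimsi

Correlative chemical imaging of tissue sections: registration of
multimodal mass spectrometry imaging (MSI) and hyperspectral fluorescence
microscopy into one pixel-aligned data matrix, multiblock OnPLS
decomposition of that matrix, and VIP-gated image fusion that predicts
individual ion distributions at microscopy resolution.

**Who it is for.** Imaging mass-spectrometrists and spatial-omics analysts
who acquire several MSI modalities (e.g. negative/positive ion mode lipids,
peptides) plus functional microscopy of the same tissue, and who want the
cross-modality chemistry — what co-varies everywhere, what is shared by a
subset of modalities, and what is unique to one — at single-pixel (10 µm)
precision, with predictions pushed to the microscope's sub-micrometer
grid.

## The methods in brief

* **Registration.** PCA score images serve as low-noise reference images
  per modality. After an optional control-point coarse alignment, a
  1+1-evolutionary optimizer refines a 2-D affine under a Mattes mutual
  information objective MI(A,B) = H(A) + H(B) − H(A,B) (60-bin joint
  histogram, bits), with an exhaustive search over optimizer parameters
  (growth factor 1.005–1.1, search radii 6.25×10⁻⁴–6.25×10⁻², 100
  iterations) selected by structural similarity. Alignment quality is
  reported as MSE, SSIM, multi-class Jaccard (on jointly 8-bit-quantized
  images) and MI — never aggregated.
* **Spatial chemometrics.** Registered cubes are cropped to the common
  grid; pixels with zero total ion current ("black pixels", Σⱼ Xᵢⱼ = 0)
  are excluded; data-pixel rows × spectral columns form the multimodal
  matrix. A multiblock OnPLS model partitions each mean-centered block
  into X_b = globally joint + locally joint + unique + residual, with
  exact reconstruction and additive variance shares.
* **Fusion.** With the block-averaged hyperspectral channels as Y, an
  OPLS model ranks MSI variables by variable importance in projection,
  VIP_k = √(K_p · Σₐ w²ₐₖ · SS_comp,a / SS_cum); Σ VIP² = K_p holds by
  construction, so VIP > 1 means "more important than average". Selected
  ions are re-expressed by per-ion PLS regressions on the microscopy
  channels and predicted at full resolution, each with a reconstruction
  score 100·(1 − SS_res/SS_tot), residual and 95% CI images, next to the
  original non-interpolated ion image.
* **Phantoms.** A generator builds ground-truthed synthetic datasets —
  elliptical tissue, 50–100 µm plaque-like foci with 30–40 µm cores,
  three MSI blocks of 673/553/20 variables with planted
  global/local/unique covariance, and a 32-channel hyperspectral cube at
  4× resolution — so every stage is testable without downloads.

See `vignettes/multimsi-methods.Rmd` for models, parameter meanings and
design decisions.

## Worked example

```r
library(multimsi)

## ground-truthed phantom: 3 MSI blocks + hyperspectral cube
ph <- make_phantom(phantom_spec(seed = 0, misalign = "none"))

## decompose the registered multimodal matrix
ds <- center_scale(assemble_multimodal(ph$msi), "mean_center")
model <- fit_onpls(ds, n_global = 1,
                   n_local = list("1,2" = 1, "2,3" = 1), n_unique = 1)
model
#> <onpls_model> 3 blocks: 1 global, 2 local, unique (1,1,1)
#>   block 1 (lipid_neg): global 33.8%, local 29.3%, unique 31.0%, residual 5.8%
#>   block 2 (lipid_pos): global 23.4%, local 46.5%, unique 22.9%, residual 7.3%
#>   block 3 (peptide): global 19.5%, local 52.0%, unique 21.6%, residual 6.9%

## the recovered global score image matches the planted plaque map
lin <- ds$partition$data_linear
cor(model$global[[1]]$scores[, 1], ph$truth$maps$global[lin])
#> [1] 0.9956287

## VIP ranking against the hyperspectral channels
x <- concat_blocks(center_scale(assemble_multimodal(ph$msi), "unit_variance"))
y <- downsample_hyperspectral(ph$hyperspectral, ds$partition,
                              ph$truth$transform_hyper)
v <- vip(fit_opls(x, y, n_predictive = 2, n_orthogonal = 1))
sum(v$vip^2) / length(v$vip)   # the VIP mean-square identity
#> [1] 1
v
#> <vip_result> 237 / 1246 variables selected at VIP > 1
```

The variance-share table reads: about a third of block 1's centered
variance is shared by all three modalities (the planted plaque pattern),
another third is shared with block 2 only (the core pattern), a third is
unique to it, and the remainder is noise. The VIP identity `= 1` is the
analytic anchor: the mean squared importance is 1 for any fitted model,
so the 237 variables above threshold 1 are the ones carrying
more-than-average covariance with the microscopy channels.

Registration of a deliberately misaligned modality, from jittered (±2 px)
control points to sub-pixel automated alignment:

```r
ph2 <- make_phantom(phantom_spec(grid = c(128, 128), upscale = 1,
                                 n_features = 10,
                                 block_widths = c(40, 30, 20), seed = 1,
                                 misalign = "default"))
tt <- ph2$truth$transforms[[2]]          # planted misalignment of block 2
pts_fixed <- cbind(x = c(40, 90, 64, 50, 80), y = c(40, 40, 90, 70, 70))
set.seed(0)
pts_moving <- transform_points(invert_affine(tt), pts_fixed) +
  matrix(runif(10, -2, 2), ncol = 2)     # imprecise manual picks
rr <- register_modalities(ph2$msi[[1]], ph2$msi[[2]],
                          control_points = list(fixed = pts_fixed,
                                                moving = pts_moving),
                          config = list(seed = 0))
rr$result
#> <registration_result> 100 iterations; MSE 0.0229, SSIM 0.5568,
#>   Jaccard 0.0015, MI 0.4145 bits

eval_pts <- cbind(x = c(30, 100, 64, 45, 85), y = c(30, 95, 64, 80, 45))
truth_pts <- transform_points(invert_affine(tt), eval_pts)
landmark_error(coarse_align(pts_fixed, pts_moving), eval_pts, truth_pts)
#> [1] 1.529897                            # coarse alignment alone
landmark_error(rr$transform, eval_pts, truth_pts)
#> [1] 0.9505383                           # after automated refinement
```

## Pipeline and CLI

```r
cfg <- pipeline_config("out/", seed = 0)
run_pipeline(cfg)   # simulate -> preprocess -> register -> OnPLS -> VIP -> fuse
```

Each stage writes versioned artifacts plus a `.done.json` marker keyed to
the configuration hash, so rerunning a finished pipeline recomputes
nothing and every artifact is traceable to its configuration. A thin CLI
wraps the same calls:

```sh
Rscript inst/cli/multimsi.R run       --config run.json
Rscript inst/cli/multimsi.R register  --fixed a.imzML --moving b.imzML \
        --points pts.csv --seed 0 --out transform.json
Rscript inst/cli/multimsi.R metrics   --a img1.csv --b img2.csv --out metrics.json
```

## Scope notes

Affine registration only (no B-splines, no 3-D); no vendor raw formats
(hyperspectral cubes enter as open CSV arrays, MSI as imzML); no MS/MS
annotation; no GUI segmentation (ROIs enter as mask files); linear models
throughout.
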