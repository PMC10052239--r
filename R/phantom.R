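#' Specification of a synthetic multimodal phantom
#'
#' The phantom emulates the statistical and spatial structure the workflow
#' assumes: a smooth tissue ellipse with off-tissue black pixels on a
#' nominal 10 um MSI grid; plaque-like focal features 50-100 um across
#' (cored morphotypes carry a 30-40 um core); three MSI blocks of very
#' different widths (673 / 553 / 20 variables, the 53%/43%/2% split);
#' planted cross-block covariance (one pattern global to all blocks, core
#' and periphery patterns local to block pairs, one unique pattern per
#' block); a 32-channel hyperspectral cube at `upscale` x finer resolution
#' whose two emission endmembers linearly encode the core and periphery
#' maps; and known affine misalignments between modalities.
#'
#' @param grid MSI grid `c(height, width)` (default 64 x 64, about 2000
#'   tissue pixels).
#' @param upscale integer microscopy resolution factor (default 4).
#' @param n_features number of plaque-like foci (default 6).
#' @param feature_diameter diameter range in micrometers (default
#'   `c(50, 100)`).
#' @param pixel_size MSI pixel edge in micrometers (default 10).
#' @param block_widths variables per MSI block (default
#'   `c(673, 553, 20)`).
#' @param structure_plan fraction of each block's variables loading on
#'   each planted pattern (remaining variables carry tissue background
#'   only).
#' @param effect_size planted pattern amplitude relative to the tissue
#'   base intensity (default 3).
#' @param noise_sigma log-normal multiplicative noise sigma; the default
#'   0.2 gives single-pixel SNR of about 5 on planted variables.
#' @param additive_floor additive Gaussian noise floor on tissue pixels.
#' @param misalign `"default"` (small planted affines per MSI modality),
#'   `"none"`, or a list of `affine2d` (moving modality -> reference
#'   frame, one per MSI block).
#' @param n_channels hyperspectral channel count (default 32, 415-690 nm).
#' @param patterns which planted patterns are active; by default one
#'   global, two locally joint (core on blocks 1+2, periphery on blocks
#'   2+3) and one unique pattern per block.
#' @param seed RNG seed; identical seeds reproduce the phantom
#'   bit-identically.
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(grid = c(64, 64), upscale = 4, n_features = 6,
                         feature_diameter = c(50, 100), pixel_size = 10,
                         block_widths = c(673, 553, 20),
                         structure_plan = list(global = 0.1, local = 0.1,
                                               unique = 0.1),
                         effect_size = 3, noise_sigma = 0.2,
                         additive_floor = 0.01, misalign = "default",
                         n_channels = 32,
                         patterns = c("global", "local_12", "local_23",
                                      "unique_1", "unique_2", "unique_3"),
                         seed = 0) {
  stopifnot(all(feature_diameter > 0), upscale >= 1, all(block_widths >= 1),
            n_features >= 0)
  structure(as.list(environment()), class = "phantom_spec")
}

disc_map <- function(h, w, cx, cy, radius, sharpness = 1.6) {
  # smooth radial bump, ~0 beyond ~1.5 radii
  dx <- outer(rep(1, h), seq_len(w)) - cx
  dy <- outer(seq_len(h), rep(1, w)) - cy
  exp(-((dx^2 + dy^2) / radius^2) * sharpness)
}

# flat unit intensity inside the tissue ellipse: a spatially constant base
# is removed exactly by mean-centering, so the planted patterns are the
# only structured covariance
tissue_profile <- function(h, w) {
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  a <- 0.45 * w; b <- 0.42 * h
  dx <- outer(rep(1, h), seq_len(w)) - cx
  dy <- outer(seq_len(h), rep(1, w)) - cy
  r2 <- (dx / a)^2 + (dy / b)^2
  (r2 <= 1) + 0
}

# sample non-overlapping feature centers inside the tissue ellipse
place_features <- function(spec, h, w) {
  n <- spec$n_features
  if (n == 0) return(data.frame())
  rad_px <- stats::runif(n, spec$feature_diameter[1],
                         spec$feature_diameter[2]) / 2 / spec$pixel_size
  core_px <- stats::runif(n, 30, 40) / 2 / spec$pixel_size
  morph <- rep(c("cored", "diffuse"), length.out = n)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  a <- 0.45 * w; b <- 0.42 * h
  centers <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(400)) {
      x <- stats::runif(1, cx - a, cx + a)
      y <- stats::runif(1, cy - b, cy + b)
      if (((x - cx) / a)^2 + ((y - cy) / b)^2 > 0.7^2) next  # keep inside
      if (i > 1) {
        d <- sqrt((centers[seq_len(i - 1), 1] - x)^2 +
                  (centers[seq_len(i - 1), 2] - y)^2)
        if (any(d < rad_px[i] + rad_px[seq_len(i - 1)] + 2)) next
      }
      centers[i, ] <- c(x, y)
      placed <- TRUE
      break
    }
    if (!placed) stop("features do not fit the phantom grid: reduce n_features or diameters")
  }
  data.frame(x = centers[, 1], y = centers[, 2], radius = rad_px,
             core_radius = core_px, morphotype = morph,
             stringsAsFactors = FALSE)
}

pattern_cor <- function(maps, mask) {
  idx <- which(mask)
  m <- vapply(maps, function(p) p[idx], numeric(length(idx)))
  m <- m[, apply(m, 2, stats::sd) > 0, drop = FALSE]  # all-zero maps are
  if (ncol(m) < 2) return(0)                          # trivially orthogonal
  cc <- stats::cor(m)
  max(abs(cc[upper.tri(cc)]))
}

#' Generate a synthetic multimodal phantom with ground truth
#'
#' Builds three MSI cubes and one hyperspectral cube according to a
#' [phantom_spec()], together with a `phantom_truth` record sufficient to
#' score every recovery experiment: planted spatial maps at MSI and
#' microscopy resolution, the feature table, the variable-to-pattern
#' loading table, the true misalignment transforms and high-resolution
#' ground-truth ion images. Pattern maps are re-drawn (new feature
#' placement) until all planted maps are pairwise near-orthogonal
#' (|r| < 0.2 over tissue pixels). Truth is recorded before the
#' misalignment warps are applied.
#'
#' @param spec a [phantom_spec()].
#' @return list with `msi` (list of 3 [msi_cube]), `hyperspectral`
#'   ([msi_cube]) and `truth`.
#' @export
make_phantom <- function(spec = phantom_spec()) {
  set.seed(spec$seed)
  h <- spec$grid[1]; w <- spec$grid[2]
  u <- spec$upscale
  tissue <- tissue_profile(h, w)
  mask <- tissue > 0

  build_maps <- function() {
    feats <- place_features(spec, h, w)
    n <- nrow(feats)
    groups <- if (n > 0) rep_len(c("global", "local", "unique"), n) else character(0)
    zero <- matrix(0, h, w)
    msum <- function(idx, radii) {
      m <- zero
      for (i in idx) m <- m + disc_map(h, w, feats$x[i], feats$y[i], radii[i])
      m
    }
    gi <- which(groups == "global"); li <- which(groups == "local")
    ui <- which(groups == "unique")
    plaque_g <- msum(gi, feats$radius)
    core_l <- msum(li, feats$core_radius)
    plaque_l <- msum(li, feats$radius)
    periphery_l <- pmax(plaque_l - 1.6 * core_l, 0)
    maps <- list(
      global = plaque_g,
      local_12 = core_l,
      local_23 = periphery_l,
      unique_1 = msum(ui, feats$radius),
      unique_2 = tissue *
        (1 + sin(2 * pi * outer(rep(1, h), seq_len(w)) / w)) / 2,
      unique_3 = tissue *
        (1 + sin(2 * pi * outer(seq_len(h), rep(1, w)) / h)) / 2)
    # a featureless spec means featureless cubes: no planted structure at
    # all, so the blocks are mutually independent noise
    if (n == 0) maps <- lapply(maps, function(m) m * 0)
    # nonnegative maps at unit variance over tissue pixels, so the stated
    # effect size means the same thing for focal and diffuse patterns
    maps <- lapply(maps, function(m) {
      m <- m * (tissue > 0)
      s <- stats::sd(m[tissue > 0])
      if (is.finite(s) && s > 0) m / s else m
    })
    list(feats = feats, maps = maps, groups = groups)
  }

  built <- NULL
  for (try in seq_len(25)) {
    built <- build_maps()
    if (spec$n_features == 0) break
    if (pattern_cor(built$maps, mask) < 0.2) break
    if (try == 25) warning("planted maps exceed |r| < 0.2 after 25 placements")
  }
  feats <- built$feats; maps <- built$maps

  # pattern assignment per block: which planted maps can load on block b,
  # filtered by the spec's active pattern set
  block_patterns <- lapply(list(
    c("global", "local_12", "unique_1"),
    c("global", "local_12", "local_23", "unique_2"),
    c("global", "local_23", "unique_3")),
    function(p) intersect(p, spec$patterns))

  wavelengths <- seq(415, by = 8.9, length.out = spec$n_channels)
  axes <- list(seq(400, by = 1.1, length.out = spec$block_widths[1]),
               seq(450, by = 1.3, length.out = spec$block_widths[2]),
               seq(4000, by = 17, length.out = spec$block_widths[3]))

  loading_tab <- list()
  cubes <- vector("list", 3)
  noise_on <- spec$noise_sigma > 0 || spec$additive_floor > 0
  for (b in 1:3) {
    k <- spec$block_widths[b]
    pats <- block_patterns[[b]]
    n_global_v <- max(1, round(k * spec$structure_plan$global))
    n_local_v <- max(1, round(k * spec$structure_plan$local))
    n_unique_v <- max(1, round(k * spec$structure_plan$unique))
    assign <- rep("background", k)
    pos <- 1
    for (p in pats) {
      cnt <- if (p == "global") n_global_v
             else if (startsWith(p, "local")) n_local_v
             else n_unique_v
      cnt <- min(cnt, k - pos + 1)
      if (cnt <= 0) next
      assign[pos:(pos + cnt - 1)] <- p
      pos <- pos + cnt
    }
    vals <- array(0, dim = c(h, w, k))
    base_load <- stats::runif(k, 0.2, 1)
    pat_load <- stats::runif(k, 0.5, 1.5) * spec$effect_size
    for (j in seq_len(k)) {
      sig <- tissue * base_load[j]
      if (assign[j] != "background")
        sig <- sig + maps[[assign[j]]] * pat_load[j]
      if (noise_on) {
        nz <- sig * exp(stats::rnorm(h * w, 0, spec$noise_sigma)) +
          abs(stats::rnorm(h * w, 0, spec$additive_floor))
        sig <- matrix(nz, h, w)
      }
      vals[, , j] <- sig * mask
    }
    loading_tab[[b]] <- data.frame(block = b, variable = axes[[b]],
                                   pattern = assign,
                                   loading = ifelse(assign == "background",
                                                    0, pat_load),
                                   stringsAsFactors = FALSE)
    cubes[[b]] <- msi_cube(vals, axes[[b]], spec$pixel_size,
                           c("lipid_neg", "lipid_pos", "peptide")[b])
  }

  # high-resolution maps on the microscopy grid
  hh <- h * u; ww <- w * u
  up_xy <- function(v) (v - 0.5) * u + 0.5   # MSI coord -> microscopy coord
  tissue_hr <- tissue_profile(hh, ww)
  mask_hr <- tissue_hr > 0
  zero_hr <- matrix(0, hh, ww)
  msum_hr <- function(idx, radii) {
    m <- zero_hr
    for (i in idx) m <- m + disc_map(hh, ww, up_xy(feats$x[i]),
                                     up_xy(feats$y[i]), radii[i] * u)
    m
  }
  n <- nrow(feats)
  all_i <- seq_len(n)
  core_hr <- if (n) msum_hr(all_i, feats$core_radius) * mask_hr else zero_hr
  plaque_hr <- if (n) msum_hr(all_i, feats$radius) * mask_hr else zero_hr
  periphery_hr <- pmax(plaque_hr - 1.6 * core_hr, 0)

  gauss <- function(center, width) exp(-((wavelengths - center)^2) / (2 * width^2))
  e_core <- gauss(480, 25)        # blue-shifted endmember
  e_peri <- gauss(545, 35)        # red-shifted endmember
  e_bg <- 0.3 * gauss(620, 80)    # broad autofluorescence
  hs_vals <- array(0, dim = c(hh, ww, spec$n_channels))
  for (ch in seq_len(spec$n_channels)) {
    sig <- core_hr * e_core[ch] + periphery_hr * e_peri[ch] +
      tissue_hr * e_bg[ch]
    if (noise_on)
      sig <- sig + matrix(abs(stats::rnorm(hh * ww, 0,
                                           spec$additive_floor)), hh, ww)
    hs_vals[, , ch] <- sig * mask_hr
  }
  hyper <- msi_cube(hs_vals, wavelengths, spec$pixel_size / u,
                    "hyperspectral")

  # true transforms: modality-b frame -> reference (block 1) frame
  center <- c((w + 1) / 2, (h + 1) / 2)
  transforms <- if (identical(spec$misalign, "none")) {
    replicate(3, affine2d(), simplify = FALSE)
  } else if (identical(spec$misalign, "default")) {
    list(affine2d(),
         affine_from_params(tx = 2, ty = -1, rotation = 3 * pi / 180,
                            center = center),
         affine_from_params(tx = -3, ty = 2, rotation = -2 * pi / 180,
                            center = center))
  } else spec$misalign
  # microscopy -> MSI coordinate mapping (pure resolution change)
  t_hyper <- affine2d(matrix(c(1 / u, 0, 0.5 - 0.5 / u,
                               0, 1 / u, 0.5 - 0.5 / u,
                               0, 0, 1), 3, 3, byrow = TRUE),
                      frame_from = "hyperspectral", frame_to = "reference")

  observed <- lapply(1:3, function(b) {
    if (max(abs(transforms[[b]]$matrix - diag(3))) < 1e-12) return(cubes[[b]])
    # the acquired cube lives in its own (misaligned) frame: resample the
    # reference-frame scene through the inverse of the true transform
    apply_transform(cubes[[b]], invert_affine(transforms[[b]]),
                    interpolation = "bicubic")
  })

  truth <- list(
    tissue_mask = mask, tissue_profile = tissue,
    tissue_mask_hr = mask_hr,
    features = feats, feature_groups = built$groups,
    maps = maps,
    maps_hr = list(core = core_hr, periphery = periphery_hr,
                   plaque = plaque_hr),
    loading_table = do.call(rbind, loading_tab),
    transforms = transforms, transform_hyper = t_hyper,
    endmembers = list(core = e_core, periphery = e_peri,
                      background = e_bg, wavelengths = wavelengths),
    spec = spec)
  list(msi = observed, hyperspectral = hyper, truth = truth)
}

#' Write a small fixture suite for tests and pipeline runs
#'
#' Emits a 64 x 64 phantom as three imzML datasets, the hyperspectral cube
#' as a plain CSV array, and the scalar parts of the ground truth as JSON,
#' regenerated bit-identically from the pinned seed.
#'
#' @param out_dir output directory.
#' @param spec [phantom_spec()]; the default uses reduced block widths so
#'   the files stay small.
#' @return named list of file paths, invisibly.
#' @export
write_fixture_suite <- function(out_dir,
                                spec = phantom_spec(
                                  grid = c(64, 64), upscale = 2,
                                  block_widths = c(60, 50, 20))) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ph <- make_phantom(spec)
  paths <- list()
  for (b in seq_along(ph$msi)) {
    p <- file.path(out_dir, sprintf("msi_block%d.imzML", b))
    write_imzml(ph$msi[[b]], p, mode = "continuous", skip_black = TRUE)
    paths[[sprintf("msi_block%d", b)]] <- p
  }
  hp <- file.path(out_dir, "hyperspectral.csv")
  write_hyperspectral_csv(ph$hyperspectral, hp)
  paths$hyperspectral <- hp
  tp <- file.path(out_dir, "truth.json")
  truth_small <- list(
    seed = spec$seed, grid = spec$grid, upscale = spec$upscale,
    block_widths = spec$block_widths,
    features = ph$truth$features,
    feature_groups = ph$truth$feature_groups,
    # column-major 9-vectors under names, stable across JSON round trips
    transforms = stats::setNames(
      lapply(ph$truth$transforms, function(t) as.vector(t$matrix)),
      sprintf("block%d", seq_along(ph$truth$transforms))),
    transform_hyper = as.vector(ph$truth$transform_hyper$matrix),
    loading_table = ph$truth$loading_table)
  jsonlite::write_json(truth_small, tp, digits = NA, auto_unbox = TRUE)
  paths$truth <- tp
  invisible(paths)
}

#' Write / read a hyperspectral cube as a CSV array
#'
#' Long layout: columns `x`, `y` then one column per wavelength channel;
#' one row per pixel. An open stand-in for vendor hyperspectral formats.
#'
#' @param cube a hyperspectral [msi_cube].
#' @param path CSV path.
#' @return the path (write) or an [msi_cube] (read).
#' @export
write_hyperspectral_csv <- function(cube, path) {
  h <- cube_height(cube); w <- cube_width(cube); k <- cube_nvar(cube)
  flat <- matrix(cube$values, nrow = h * w, ncol = k)
  df <- data.frame(x = rep(seq_len(w), each = h),
                   y = rep(seq_len(h), times = w))
  df <- cbind(df, as.data.frame(flat))
  names(df)[-(1:2)] <- format(cube$variables, trim = TRUE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hyperspectral_csv
#' @param pixel_size pixel edge length in micrometers for the cube read
#'   back.
#' @export
read_hyperspectral_csv <- function(path, pixel_size = 2.5) {
  df <- utils::read.csv(path, check.names = FALSE)
  w <- max(df$x); h <- max(df$y)
  k <- ncol(df) - 2L
  vals <- array(0, dim = c(h, w, k))
  lin <- (df$x - 1L) * h + df$y
  flat <- matrix(0, h * w, k)
  flat[lin, ] <- as.matrix(df[, -(1:2)])
  vals <- array(flat, dim = c(h, w, k))
  msi_cube(vals, as.numeric(names(df)[-(1:2)]), pixel_size,
           "hyperspectral")
}
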