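#' PCA score images as registration references
#'
#' Single ion images are noisy and low-contrast; PCA score images of a
#' modality give the smooth, high-contrast reference images used for
#' intensity-based registration. The pixel matrix is mean-centered
#' internally, decomposed by SVD, and each component's score vector is
#' restored to the image grid with black pixels at 0. Components are
#' ordered by explained variance with a deterministic sign convention (the
#' largest-magnitude loading is positive).
#'
#' @param pm a [to_pixel_matrix()] result.
#' @param n_components number of score images to return.
#' @return list of score-image matrices with attribute
#'   `explained_variance` (fraction per component).
#' @export
pca_reference_images <- function(pm, n_components = 1) {
  x <- scale(pm$values, center = TRUE, scale = FALSE)
  r <- min(dim(x))
  if (n_components > r) {
    warning(sprintf("n_components truncated from %d to rank bound %d",
                    n_components, r))
    n_components <- r
  }
  sv <- svd(x, nu = n_components, nv = n_components)
  flip <- vapply(seq_len(n_components), function(j) {
    l <- sv$v[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  scores <- sweep(sv$u, 2, sv$d[seq_len(n_components)] * flip, "*")
  lin <- (pm$coords[, "col"] - 1L) * pm$grid[1] + pm$coords[, "row"]
  imgs <- lapply(seq_len(n_components), function(j) {
    img <- matrix(0, pm$grid[1], pm$grid[2])
    img[lin] <- scores[, j]
    img
  })
  ev <- sv$d^2 / sum(sv$d^2)
  attr(imgs, "explained_variance") <- ev[seq_len(n_components)]
  imgs
}

#' Mattes-style mutual information registration objective
#'
#' Mutual information (bits) of the joint intensity histogram of a fixed
#' and an already-resampled moving image, with box binning over `n_bins`
#' levels per axis. By default all pixels enter the histogram (dense
#' evaluation, the configuration used for MSI reference images); setting
#' `use_all_pixels = FALSE` draws `n_samples` spatial samples instead.
#'
#' @param fixed,moving image matrices on a common grid.
#' @param n_samples number of spatial samples when sampling (default 500).
#' @param n_bins histogram bins per intensity axis (default 60).
#' @param seed RNG seed for spatial sampling.
#' @param use_all_pixels dense evaluation overriding sampling (default
#'   TRUE).
#' @param window histogram window: `"box"` (plain hard binning, default;
#'   it preserves the identity MI(A, A) = H(A)) or `"linear"`
#'   (first-order Parzen / triangular, which spreads each sample over the
#'   two adjacent bins so the metric varies smoothly under sub-pixel
#'   motion — the registration objective uses this).
#' @return mutual information in bits (0, with a warning, for a constant
#'   image).
#' @export
mattes_mi <- function(fixed, moving, n_samples = 500, n_bins = 60,
                      seed = 0, use_all_pixels = TRUE,
                      window = c("box", "linear")) {
  window <- match.arg(window)
  check_same_dim(fixed, moving)
  a <- as.vector(fixed); b <- as.vector(moving)
  if (!use_all_pixels && n_samples < length(a)) {
    set.seed(seed)
    idx <- sample.int(length(a), n_samples)
    a <- a[idx]; b <- b[idx]
  }
  if (min(a) == max(a) || min(b) == max(b)) {
    warning("constant image: mutual information is 0")
    return(0)
  }
  ent <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  if (window == "box") {
    bin <- function(x) {
      q <- floor((x - min(x)) / (max(x) - min(x)) * n_bins)
      pmin(as.integer(q), n_bins - 1L)
    }
    ba <- bin(a); bb <- bin(b)
    joint <- tabulate(ba * n_bins + bb + 1L, nbins = n_bins^2)
    p <- joint / sum(joint)
  } else {
    # fractional bin coordinates; each sample contributes to its two
    # neighboring bins with triangular weights, jointly to four cells
    coord <- function(x) (x - min(x)) / (max(x) - min(x)) * (n_bins - 1L)
    ca <- coord(a); cb <- coord(b)
    ia <- pmin(as.integer(floor(ca)), n_bins - 2L)
    ib <- pmin(as.integer(floor(cb)), n_bins - 2L)
    fa <- ca - ia; fb <- cb - ib
    counts <- numeric(n_bins^2)
    for (da in 0:1) for (db in 0:1) {
      wgt <- (if (da == 0) 1 - fa else fa) * (if (db == 0) 1 - fb else fb)
      idx <- (ia + da) * n_bins + (ib + db) + 1L
      acc <- rowsum(wgt, group = idx, reorder = FALSE)
      counts[as.integer(rownames(acc))] <-
        counts[as.integer(rownames(acc))] + acc[, 1]
    }
    p <- counts / sum(counts)
  }
  pa <- rowSums(matrix(p, n_bins, n_bins, byrow = TRUE))
  pb <- colSums(matrix(p, n_bins, n_bins, byrow = TRUE))
  ent(pa) + ent(pb) - ent(p)
}

# normalized 1+1-ES parameterization: theta is a 6-vector
# (tx, ty, rotation, log sx, log sy, shear) in units where one radius unit
# moves the image border by about one image width -- the scaling under
# which the conventional radius limits (6.25e-4 .. 6.25e-2) correspond to
# sub-pixel .. few-pixel steps.
theta_to_transform <- function(theta, ref_dim, frame_from = "moving",
                               frame_to = "fixed") {
  d <- max(ref_dim)
  center <- c((ref_dim[2] + 1) / 2, (ref_dim[1] + 1) / 2)
  affine_from_params(tx = theta[1] * d, ty = theta[2] * d,
                     rotation = theta[3] * 2,
                     sx = exp(theta[4] * 2), sy = exp(theta[5] * 2),
                     shear = theta[6] * 2, center = center,
                     frame_from = frame_from, frame_to = frame_to)
}

#' Optimizer parameters for the 1+1-evolutionary registration
#'
#' @param max_iterations iteration budget (default 300 for direct
#'   single-run use; the exhaustive parameter search runs its
#'   conventional constant of 100 per grid point).
#' @param growth_factor search-radius growth on success (> 1, shrink is its
#'   reciprocal; default 1.02).
#' @param epsilon minimal search radius; termination threshold.
#' @param initial_radius starting search radius (must exceed `epsilon`).
#' @param seed RNG seed for the mutation draws.
#' @return list of class `optimizer_params`.
#' @export
optimizer_params <- function(max_iterations = 300, growth_factor = 1.02,
                             epsilon = 1.5e-7, initial_radius = 6.25e-3,
                             seed = 0) {
  stopifnot(max_iterations >= 1, growth_factor > 1,
            epsilon < initial_radius)
  structure(list(max_iterations = max_iterations,
                 growth_factor = growth_factor, epsilon = epsilon,
                 initial_radius = initial_radius, seed = seed),
            class = "optimizer_params")
}

# block-mean downsampling by an integer factor (trailing rows/cols that do
# not fill a block are averaged over the pixels present)
downsample_image <- function(img, f) {
  if (f == 1) return(img)
  h <- nrow(img); w <- ncol(img)
  ho <- ceiling(h / f); wo <- ceiling(w / f)
  ri <- ceiling(seq_len(h) / f)
  ci <- ceiling(seq_len(w) / f)
  sums <- rowsum(img, ri)
  sums <- t(rowsum(t(sums), ci))
  cnt <- tabulate(ri, ho) %o% tabulate(ci, wo)
  sums / cnt
}

# coordinate map fine frame -> coarse frame for a downsampling factor f
level_scale_transform <- function(f) {
  affine2d(matrix(c(1 / f, 0, 0.5 - 0.5 / f,
                    0, 1 / f, 0.5 - 0.5 / f,
                    0, 0, 1), 3, 3, byrow = TRUE),
           frame_from = "fine", frame_to = "coarse")
}

# one pyramid level of the 1+1 evolutionary search; returns the updated
# transform, the parent-MI trace and whether any step improved
one_plus_one_level <- function(fixed, moving, init, params, interpolation,
                               seed) {
  ref_dim <- dim(fixed)
  obj <- function(theta) {
    tt <- compose_affine(theta_to_transform(theta, ref_dim), init)
    warped <- warp_image(moving, tt, out_dim = ref_dim,
                         method = interpolation)
    suppressWarnings(mattes_mi(fixed, warped, window = "linear"))
  }
  set.seed(seed)
  theta <- numeric(6)
  cur <- obj(theta)
  init_mi <- cur
  if (!is.finite(cur)) stop("non-finite registration metric at init")
  radius <- params$initial_radius
  trace <- numeric(0)
  for (it in seq_len(params$max_iterations)) {
    if (radius < params$epsilon) break
    child <- theta + radius * stats::rnorm(6)
    mi_c <- obj(child)
    if (!is.finite(mi_c))
      stop(sprintf("non-finite registration metric at iteration %d (trace: %s)",
                   it, paste(signif(trace, 6), collapse = ", ")))
    if (mi_c > cur) {
      theta <- child; cur <- mi_c
      radius <- radius * params$growth_factor
    } else {
      radius <- radius / params$growth_factor
    }
    trace <- c(trace, cur)
  }
  list(transform = compose_affine(theta_to_transform(theta, ref_dim), init),
       trace = trace, improved = cur > init_mi, init_mi = init_mi)
}

#' 1+1-evolutionary affine registration
#'
#' Stochastic hill-climb over affine parameters under the Mattes mutual
#' information objective: at each iteration a child transform perturbs the
#' parent by an isotropic Gaussian step of the current search radius; the
#' child replaces the parent iff its MI improves; the radius grows by
#' `growth_factor` on success and shrinks by its reciprocal on failure,
#' which lets the search step out of non-optimal local minima. Each level
#' terminates at `max_iterations` or when the radius falls below
#' `epsilon`. The result never has worse MI than `init`.
#'
#' Optionally the search runs over a multiresolution pyramid (block-mean
#' downsampling by powers of two, coarsest first), the standard device for
#' widening the capture range when no coarse alignment is available;
#' `metric_trace` records the full-resolution level. The default is a
#' single full-resolution level, which is the best-performing
#' configuration when a control-point coarse alignment initializes the
#' search.
#'
#' @param fixed,moving reference images (matrices, common grid).
#' @param init initial `affine2d` (moving -> fixed), e.g. from
#'   [coarse_align()]; identity by default.
#' @param params an [optimizer_params()] list.
#' @param interpolation interpolation used when warping the moving image
#'   for metric evaluation (default linear, for speed; the final cube
#'   resampling is bicubic regardless).
#' @param pyramid_levels number of resolution levels (1 = single scale).
#' @return object of class `registration_result`: `transform`,
#'   `metric_trace` (parent MI per iteration at full resolution,
#'   non-decreasing), `final_metrics`, `params_used`, `improved`.
#' @export
one_plus_one_register <- function(fixed, moving, init = affine2d(),
                                  params = optimizer_params(),
                                  interpolation = "linear",
                                  pyramid_levels = 1) {
  transform <- init
  trace <- numeric(0)
  improved <- FALSE
  init_mi <- NA_real_
  for (lev in seq(pyramid_levels, 1)) {
    f <- 2^(lev - 1)
    fx <- downsample_image(fixed, f)
    mv <- downsample_image(moving, f)
    s <- level_scale_transform(f)
    init_l <- compose_affine(s, compose_affine(transform, invert_affine(s)))
    res <- one_plus_one_level(fx, mv, init_l, params, interpolation,
                              seed = params$seed + lev - 1)
    transform <- compose_affine(invert_affine(s),
                                compose_affine(res$transform, s))
    transform$frame_from <- init$frame_from
    transform$frame_to <- init$frame_to
    improved <- improved || res$improved
    trace <- res$trace
    if (lev == 1) init_mi <- res$init_mi
  }
  warped <- warp_image(moving, transform, out_dim = dim(fixed),
                       method = interpolation)
  structure(
    list(transform = transform,
         metric_trace = trace,
         final_metrics = list(
           mse = mse(fixed, warped),
           ssim = ssim(fixed, warped),
           jaccard = jaccard(fixed, warped),
           mutual_information = mutual_information(fixed, warped)),
         params_used = params,
         init_mi = init_mi,
         improved = improved),
    class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  m <- x$final_metrics
  cat(sprintf(
    "<registration_result> %d iterations; MSE %.4g, SSIM %.4f, Jaccard %.4f, MI %.4f bits\n",
    length(x$metric_trace), m$mse, m$ssim, m$jaccard, m$mutual_information))
  invisible(x)
}

#' Default exhaustive-search parameter grid
#'
#' Spans the conventional optimizer limits: growth factor 1.005 to 1.1 in
#' steps of 0.0005 (sub-sampled to at most `max_growth` points), minimal
#' radius (epsilon) 1.5e-7 to 1.5e-3 and initial radius 6.25e-4 to 6.25e-2,
#' each as `n_log` log-spaced values between the limits.
#'
#' @param max_growth cap on growth-factor grid points (default 20).
#' @param n_log log-spaced points for epsilon and initial radius
#'   (default 4).
#' @return data.frame with columns `growth_factor`, `epsilon`,
#'   `initial_radius`.
#' @export
default_search_grid <- function(max_growth = 20, n_log = 4) {
  g <- seq(1.005, 1.1, by = 0.0005)
  if (length(g) > max_growth)
    g <- g[unique(round(seq(1, length(g), length.out = max_growth)))]
  eps <- 10^seq(log10(1.5e-7), log10(1.5e-3), length.out = n_log)
  r <- 10^seq(log10(6.25e-4), log10(6.25e-2), length.out = n_log)
  expand.grid(growth_factor = g, epsilon = eps, initial_radius = r,
              KEEP.OUT.ATTRS = FALSE)
}

# compact grid used by register_modalities() so full-chain registration
# stays within interactive runtimes; values sit inside the conventional
# limits, in the region where 100-iteration runs converge to sub-pixel
# alignment on structured references. The full grid remains available.
reduced_search_grid <- function() {
  expand.grid(growth_factor = c(1.02, 1.05),
              epsilon = 1.5e-7,
              initial_radius = c(6.25e-3, 2e-2),
              KEEP.OUT.ATTRS = FALSE)
}

#' Exhaustive search over optimizer parameters
#'
#' Runs [one_plus_one_register()] once per grid point and returns the
#' parameter set whose registered result maximizes the structural
#' similarity between the fixed image and the resampled moving image; ties
#' break toward higher mutual information, then earlier grid order. If no
#' grid point improves MI over `init`, the init-equivalent result is
#' returned with a warning.
#'
#' @inheritParams one_plus_one_register
#' @param grid data.frame with columns `growth_factor`, `epsilon`,
#'   `initial_radius` (default [default_search_grid()]).
#' @param max_iterations,seed shared optimizer settings.
#' @return list `params` ([optimizer_params()]) and `result`
#'   (`registration_result`).
#' @export
exhaustive_search <- function(fixed, moving, init = affine2d(),
                              grid = default_search_grid(),
                              max_iterations = 100, seed = 0,
                              interpolation = "linear") {
  if (nrow(grid) == 0) stop("empty parameter grid")
  best <- NULL
  for (i in seq_len(nrow(grid))) {
    p <- optimizer_params(max_iterations = max_iterations,
                          growth_factor = grid$growth_factor[i],
                          epsilon = grid$epsilon[i],
                          initial_radius = grid$initial_radius[i],
                          seed = seed)
    res <- one_plus_one_register(fixed, moving, init = init, params = p,
                                 interpolation = interpolation)
    key <- c(res$final_metrics$ssim, res$final_metrics$mutual_information)
    if (is.null(best) || key[1] > best$key[1] ||
        (key[1] == best$key[1] && key[2] > best$key[2])) {
      best <- list(params = p, result = res, key = key)
    }
  }
  if (!best$result$improved) {
    warning("no grid point improved MI over init: returning init-equivalent result")
    best$result$transform <- init
  }
  list(params = best$params, result = best$result)
}

#' Full automated registration chain between two modalities
#'
#' The single-pixel alignment workflow: PCA score images of both cubes
#' serve as reference images; an optional control-point coarse alignment
#' initializes the transform; the 1+1-evolutionary optimizer with
#' exhaustive parameter search refines it under Mattes MI; the moving cube
#' is then resampled into the fixed frame with bicubic interpolation, and
#' the evaluation metrics (MSE, SSIM, Jaccard, MI) are reported on the
#' reference-image pair.
#'
#' @param fixed_cube,moving_cube preprocessed [msi_cube] objects.
#' @param control_points optional list with matrices `fixed` and `moving`
#'   (n x 2, (x, y)) for coarse alignment.
#' @param config list of options: `pca_component` (default 1), `grid`
#'   (search grid, default [reduced_search_grid()]), `max_iterations`
#'   (100), `seed` (0), `interpolation` ("bicubic", final resampling).
#' @return list `transform`, `result` (`registration_result`),
#'   `registered_cube`, `fixed_reference`, `moving_reference`, `overlay`
#'   (h x w x 2 array of the rescaled reference pair).
#' @export
register_modalities <- function(fixed_cube, moving_cube,
                                control_points = NULL, config = list()) {
  cfg <- utils::modifyList(
    list(pca_component = 1, grid = reduced_search_grid(),
         max_iterations = 100, seed = 0, interpolation = "bicubic"),
    config)
  ref_of <- function(cube) {
    part <- partition_pixels(cube)
    pm <- to_pixel_matrix(cube, part)
    img <- pca_reference_images(pm, cfg$pca_component)[[cfg$pca_component]]
    rng <- range(img)
    if (diff(rng) > 0) img <- (img - rng[1]) / diff(rng)
    img
  }
  ref_f <- ref_of(fixed_cube)
  ref_m <- ref_of(moving_cube)
  init <- if (!is.null(control_points)) {
    coarse_align(control_points$fixed, control_points$moving,
                 frame_from = moving_cube$modality,
                 frame_to = fixed_cube$modality)
  } else {
    affine2d(frame_from = moving_cube$modality,
             frame_to = fixed_cube$modality)
  }
  sr <- exhaustive_search(ref_f, ref_m, init = init, grid = cfg$grid,
                          max_iterations = cfg$max_iterations,
                          seed = cfg$seed)
  transform <- sr$result$transform
  registered <- apply_transform(moving_cube, transform,
                                interpolation = cfg$interpolation,
                                out_dim = dim(ref_f))
  warped_ref <- warp_image(ref_m, transform, out_dim = dim(ref_f),
                           method = "bicubic")
  final_metrics <- list(
    mse = mse(ref_f, warped_ref),
    ssim = ssim(ref_f, warped_ref),
    jaccard = jaccard(ref_f, warped_ref),
    mutual_information = mutual_information(ref_f, warped_ref))
  sr$result$final_metrics <- final_metrics
  list(transform = transform, result = sr$result,
       registered_cube = registered,
       fixed_reference = ref_f, moving_reference = ref_m,
       overlay = array(c(ref_f, warped_ref), dim = c(dim(ref_f), 2)))
}
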