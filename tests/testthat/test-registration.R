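make_ref <- function(cube, comp = 1) {
  pm <- to_pixel_matrix(cube, partition_pixels(cube))
  img <- pca_reference_images(pm, comp)[[comp]]
  (img - min(img)) / diff(range(img))
}

test_that("PCA reference images recover planted spatial patterns", {
  # rank-1: one spatial pattern x one spectrum
  set.seed(1)
  pat <- matrix(runif(100), 10, 10)
  spec <- runif(6) + 0.5
  vals <- array(as.vector(pat) %o% spec, c(10, 10, 6))
  cube <- msi_cube(vals, 1:6)
  pm <- to_pixel_matrix(cube, partition_pixels(cube))
  img <- pca_reference_images(pm, 1)[[1]]
  expect_gt(abs(cor(as.vector(img), as.vector(pat))), 1 - 1e-10)

  # two planted patterns, mean-zero and mutually orthogonal so centering
  # cannot mix them, land in the first two components
  p1 <- matrix(0, 12, 12); p1[2:5, 2:5] <- 1; p1[2:5, 8:11] <- -1
  p2 <- matrix(0, 12, 12); p2[8:11, 2:5] <- 1; p2[8:11, 8:11] <- -1
  set.seed(2)
  l1 <- rnorm(20); l2 <- rnorm(20)
  l2 <- l2 - sum(l1 * l2) / sum(l1^2) * l1   # known orthogonal loadings
  vals2 <- array(as.vector(p1) %o% (3 * l1) + as.vector(p2) %o% l2 +
                   rnorm(144 * 20, 0, 1e-4), c(12, 12, 20))
  vals2 <- vals2 - min(vals2)
  cube2 <- msi_cube(vals2, 1:20)
  pm2 <- to_pixel_matrix(cube2, partition_pixels(cube2))
  imgs <- pca_reference_images(pm2, 2)
  expect_gt(abs(cor(as.vector(imgs[[1]]), as.vector(p1))), 0.99)
  expect_gt(abs(cor(as.vector(imgs[[2]]), as.vector(p2))), 0.99)
  expect_warning(pca_reference_images(pm2, 200), "truncated")
})

test_that("white-noise PCA spreads variance near 1/min(dims)", {
  evs <- vapply(1:20, function(s) {
    set.seed(s)
    vals <- array(runif(16 * 16 * 12), c(16, 16, 12))
    pm <- to_pixel_matrix(msi_cube(vals, 1:12), partition_pixels(msi_cube(vals, 1:12)))
    pca_reference_images(pm, 1)
    attr(pca_reference_images(pm, 1), "explained_variance")[1]
  }, numeric(1))
  # leading eigenvalue of a centered white-noise matrix: above the 1/12
  # equal-share floor but nowhere near a dominant component
  expect_gt(mean(evs), 1 / 12)
  expect_lt(mean(evs), 3 / 12)
})

test_that("mattes_mi: identity equals entropy, independence near zero", {
  set.seed(3)
  a <- matrix(runif(128 * 128), 128, 128)
  mi_aa <- mattes_mi(a, a)
  bins <- pmin(floor((a - min(a)) / (max(a) - min(a)) * 60), 59)
  p <- tabulate(as.integer(bins) + 1L, 60); p <- p[p > 0] / sum(p)
  expect_equal(mi_aa, -sum(p * log2(p)), tolerance = 1e-10)
  # independence: at 512 x 512 over 60 x 60 joint bins the finite-sample
  # bias floor (~(K-1)^2 / (2 N ln 2) ~ 0.01 bits) sits below 0.05
  mis <- vapply(1:20, function(s) {
    set.seed(s)
    mattes_mi(matrix(runif(512 * 512), 512, 512),
              matrix(runif(512 * 512), 512, 512))
  }, numeric(1))
  expect_lt(mean(mis), 0.05)
  set.seed(4)
  shuf <- matrix(a[sample(length(a))], 128, 128)
  expect_lt(mattes_mi(a, shuf), mi_aa)
  expect_warning(mattes_mi(matrix(1, 4, 4), a[1:4, 1:4]), "constant")
  # sampling path is seeded and reproducible
  m1 <- mattes_mi(a, shuf, n_samples = 500, seed = 7, use_all_pixels = FALSE)
  m2 <- mattes_mi(a, shuf, n_samples = 500, seed = 7, use_all_pixels = FALSE)
  expect_identical(m1, m2)
})

test_that("one_plus_one_register: optimum at start stays put, trace monotone", {
  ph <- registration_phantom()
  ref <- make_ref(ph$msi[[1]])
  res <- one_plus_one_register(ref, ref, params = optimizer_params(seed = 1))
  expect_true(all(diff(res$metric_trace) >= 0))
  expect_lt(max(abs(transform_points(res$transform, cbind(c(20, 100), c(20, 100))) -
                    cbind(c(20, 100), c(20, 100)))), 1.5)
  expect_gte(tail(res$metric_trace, 1), res$init_mi)
})

test_that("one_plus_one_register recovers a pure translation within half a pixel", {
  ph <- registration_phantom()
  fixed <- make_ref(ph$msi[[1]])
  shift <- affine_from_params(tx = 4, ty = 3)
  moving <- warp_image(fixed, invert_affine(shift), method = "bicubic")
  res <- one_plus_one_register(fixed, moving,
                               params = optimizer_params(growth_factor = 1.02,
                                                         seed = 0))
  pts <- cbind(c(30, 100, 64), c(30, 95, 40))
  err <- landmark_error(res$transform, pts,
                        transform_points(invert_affine(shift), pts))
  expect_lt(err, 0.5)
  # bit-exact reproducibility under a fixed seed
  res2 <- one_plus_one_register(fixed, moving,
                                params = optimizer_params(growth_factor = 1.02,
                                                          seed = 0))
  expect_identical(res$transform$matrix, res2$transform$matrix)
  expect_identical(res$metric_trace, res2$metric_trace)
})

test_that("exhaustive_search honors its grid and fallback contracts", {
  ph <- registration_phantom()
  fixed <- make_ref(ph$msi[[1]])
  shift <- affine_from_params(tx = 2, ty = -1)
  moving <- warp_image(fixed, invert_affine(shift), method = "bicubic")
  g1 <- data.frame(growth_factor = 1.05, epsilon = 1.5e-5,
                   initial_radius = 6.25e-3)
  es <- exhaustive_search(fixed, moving, grid = g1, seed = 2)
  single <- one_plus_one_register(fixed, moving,
                                  params = optimizer_params(
                                    max_iterations = 100,
                                    growth_factor = 1.05, epsilon = 1.5e-5,
                                    initial_radius = 6.25e-3, seed = 2))
  expect_identical(es$result$transform$matrix, single$transform$matrix)
  expect_error(exhaustive_search(fixed, moving, grid = g1[0, ]), "empty")
  # a grid that cannot move (radius below epsilon immediately) returns the
  # init-equivalent transform with a warning
  expect_warning(
    es0 <- exhaustive_search(fixed, moving, init = affine2d(),
                             grid = data.frame(growth_factor = 1.01,
                                               epsilon = 0.2,
                                               initial_radius = 0.25),
                             max_iterations = 1, seed = 1),
    "init-equivalent")
  expect_equal(es0$result$transform$matrix, diag(3))
})

test_that("default search grid spans the documented limits", {
  g <- default_search_grid()
  expect_lte(length(unique(g$growth_factor)), 20)
  expect_equal(range(g$growth_factor), c(1.005, 1.1))
  expect_equal(range(g$epsilon), c(1.5e-7, 1.5e-3))
  expect_equal(range(g$initial_radius), c(6.25e-4, 6.25e-2))
})

test_that("register_modalities on identical cubes is near-identity", {
  ph <- tiny_phantom()
  cube <- ph$msi[[1]]
  rr <- register_modalities(cube, cube, config = list(seed = 1))
  expect_gt(rr$result$final_metrics$ssim, 0.99)
  pts <- cbind(c(5, 25), c(5, 25))
  expect_lt(landmark_error(rr$transform, pts, pts), 0.5)
  expect_equal(dim(rr$overlay), c(32, 32, 2))
})

test_that("strongly non-affine distortion degrades metrics without crashing", {
  ph <- tiny_phantom()
  cube <- ph$msi[[1]]
  # non-affine warp: swirl the pixel content
  vals <- cube$values
  h <- dim(vals)[1]; w <- dim(vals)[2]
  warped <- vals
  for (r in 1:h) {
    shift <- round(6 * sin(2 * pi * r / h))
    warped[r, , ] <- vals[r, ((seq_len(w) - 1 + shift) %% w) + 1, ]
  }
  for (c in 1:w) {
    shift <- round(5 * sin(2 * pi * c / w))
    warped[, c, ] <- warped[((seq_len(h) - 1 + shift) %% h) + 1, c, ]
  }
  moved <- msi_cube(warped, cube$variables, cube$pixel_size, cube$modality)
  rr <- register_modalities(cube, moved, config = list(seed = 1))
  # far below the > 0.99 an affine-consistent pair reaches: flagged as poor
  expect_lt(rr$result$final_metrics$ssim, 0.95)
  expect_true(is.finite(rr$result$final_metrics$mutual_information))
})
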