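scale_mat <- function(x) {
  s <- scale(x)
  s[, attr(s, "scaled:scale") == 0] <- 0
  s
}

test_that("fit_opls recovers an exact linear X-Y link", {
  set.seed(1)
  n <- 150
  x <- matrix(rnorm(n * 20), n, 20)
  y <- x[, 1:3] %*% c(2, -1, 0.5)
  # PLS converges to an exact linear relation along its Krylov sequence;
  # a few components beyond the 3 informative columns suffice
  m <- fit_opls(scale_mat(x), y, n_predictive = 5, n_orthogonal = 0)
  pred <- predict(m, scale_mat(x))
  r2 <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  expect_gt(r2, 0.999)
  # the informative columns dominate the first predictive weights
  w1 <- abs(m$weights[, 1])
  expect_true(all(rank(-w1)[1:3] <= 3))
})

test_that("OPLS reconstructs X from predictive + orthogonal + residual", {
  set.seed(2)
  n <- 120
  x <- matrix(rnorm(n * 15), n, 15)
  y <- cbind(x[, 1] + rnorm(n, 0, 0.1), x[, 2] - x[, 3] + rnorm(n, 0, 0.1))
  xs <- scale_mat(x)
  m <- fit_opls(xs, y, n_predictive = 2, n_orthogonal = 2)
  xc <- sweep(xs, 2, m$x_center)
  recon <- m$scores %*% t(m$x_loadings) + m$residual_x
  if (!is.null(m$t_ortho)) recon <- recon + m$t_ortho %*% t(m$p_ortho)
  expect_lt(max(abs(xc - recon)), 1e-8)
  expect_true(all(diff(m$ss_cum) >= -1e-12))
})

test_that("Y independent of X gives near-zero held-out R2Y", {
  set.seed(3)
  n <- 300
  x <- matrix(rnorm(n * 30), n, 30)
  y <- matrix(rnorm(n * 2), n, 2)
  train <- 1:200; test <- 201:300
  m <- fit_opls(scale_mat(x)[train, ], y[train, ],
                n_predictive = 2, n_orthogonal = 1)
  pred <- predict(m, scale_mat(x)[test, ])
  r2 <- 1 - sum((y[test, ] - pred)^2) /
    sum(sweep(y[test, ], 2, colMeans(y[test, ]))^2)
  # no predictive power: held-out R2 at or below zero (overfit makes it
  # mildly negative), never meaningfully positive
  expect_lt(r2, 0.05)
  expect_gt(r2, -0.7)
})

test_that("structured Y-orthogonal variation barely tilts predictive loadings", {
  set.seed(4)
  n <- 400
  latent <- rnorm(n)
  x <- matrix(rnorm(n * 25, 0, 0.05), n, 25)
  dir_pred <- c(rep(1, 5), rep(0, 20)) / sqrt(5)
  x <- x + latent %*% t(dir_pred)
  y <- latent + rnorm(n, 0, 0.05)
  base <- fit_opls(x, y, n_predictive = 1, n_orthogonal = 1)
  # add a strong structured component exactly orthogonal to y
  ortho_t <- rnorm(n)
  ortho_t <- ortho_t - y * sum(ortho_t * y) / sum(y^2)
  dir_orth <- c(rep(0, 20), rep(1, 5)) / sqrt(5)
  x2 <- x + 3 * ortho_t %*% t(dir_orth)
  with_o <- fit_opls(x2, y, n_predictive = 1, n_orthogonal = 1)
  ang <- acos(min(1, abs(sum(base$weights[, 1] * with_o$weights[, 1])))) *
    180 / pi
  expect_lt(ang, 1)
})

test_that("VIP identity and symmetry hold, planted variables are selected", {
  # single component, equal weights -> every VIP exactly 1
  set.seed(5)
  t <- rnorm(80)
  x <- t %*% t(rep(1, 6)) + matrix(rnorm(480, 0, 1e-8), 80, 6)
  m1 <- fit_opls(x, t, n_predictive = 1, n_orthogonal = 0)
  v1 <- vip(m1)
  expect_equal(unname(v1$vip), rep(1, 6), tolerance = 1e-4)

  sens <- c(); fpr <- c()
  for (s in 1:10) {
    set.seed(s)
    n <- 400
    x <- matrix(rnorm(n * 200), n, 200)
    latent <- rnorm(n)
    x[, 1:5] <- x[, 1:5] * 0.3 + latent %*% t(runif(5, 0.8, 1.2))
    y <- cbind(latent + rnorm(n, 0, 0.1), 0.5 * latent + rnorm(n, 0, 0.1))
    m <- fit_opls(scale_mat(x), y, n_predictive = 2, n_orthogonal = 1)
    v <- vip(m)
    expect_equal(sum(v$vip^2), 200, tolerance = 1e-8)   # the identity
    expect_true(all(v$vip >= 0))
    sens <- c(sens, mean(v$selected[1:5]))
    fpr <- c(fpr, mean(v$selected[-(1:5)]))
    expect_true(all(rank(-v$vip)[1:5] <= 5))
  }
  expect_equal(mean(sens), 1)
  expect_lt(mean(fpr), 0.05)
})

test_that("select_variables subsets columns and block_map consistently", {
  ph <- tiny_phantom()
  ds <- center_scale(assemble_multimodal(ph$msi), "unit_variance")
  x <- concat_blocks(ds)
  k <- ncol(x$values)
  fake_vip <- structure(list(vip = seq_len(k) / k * 2,
                             selected = seq_len(k) / k * 2 > 1,
                             threshold = 1), class = "vip_result")
  xs <- select_variables(x, fake_vip)
  expect_equal(ncol(xs$values), sum(fake_vip$selected))
  expect_equal(sum(xs$block_map$end - xs$block_map$start + 1),
               ncol(xs$values))
  all_vip <- fake_vip; all_vip$selected <- rep(TRUE, k); all_vip$threshold <- 0
  expect_equal(ncol(select_variables(x, all_vip)$values), k)
  none <- fake_vip; none$selected <- rep(FALSE, k); none$threshold <- 99
  expect_error(select_variables(x, none), "threshold")
  short <- fake_vip; short$vip <- short$vip[-1]
  expect_error(select_variables(x, short), "length")
})

test_that("downsample_hyperspectral block-averages exactly", {
  # checkerboard at exactly 2x resolution: each MSI pixel = mean of its 4
  # children
  u <- 2; gh <- 4; gw <- 4
  hh <- gh * u; ww <- gw * u
  board <- outer(seq_len(hh), seq_len(ww), function(i, j) (i + j) %% 2)
  vals <- array(c(board, board * 3 + 1), c(hh, ww, 2))
  cube <- msi_cube(vals, c(450, 550), 5, "hyperspectral")
  tm <- affine2d(matrix(c(1 / u, 0, 0.5 - 0.5 / u,
                          0, 1 / u, 0.5 - 0.5 / u,
                          0, 0, 1), 3, 3, byrow = TRUE))
  part <- structure(list(grid = c(gh, gw),
                         data_pixels = cbind(row = rep(1:gh, gw),
                                             col = rep(1:gw, each = gh)),
                         data_linear = 1:(gh * gw)),
                    class = "pixel_partition")
  y <- downsample_hyperspectral(cube, part, tm)
  for (px in seq_len(gh * gw)) {
    r <- part$data_pixels[px, "row"]; c <- part$data_pixels[px, "col"]
    rows <- ((r - 1) * u + 1):(r * u); cols <- ((c - 1) * u + 1):(c * u)
    expect_equal(unname(y$values[px, 1]), mean(board[rows, cols]))
    expect_equal(unname(y$values[px, 2]), mean(board[rows, cols] * 3 + 1))
  }
  # constant cube -> constant Y; identity transform on equal grids -> copy
  const <- msi_cube(array(2.5, c(gh, gw, 2)), c(450, 550), 5, "hyperspectral")
  y2 <- downsample_hyperspectral(const, part, affine2d())
  expect_true(all(y2$values == 2.5))
  rnd <- msi_cube(array(runif(gh * gw * 2), c(gh, gw, 2)), c(450, 550), 5,
                  "hyperspectral")
  y3 <- downsample_hyperspectral(rnd, part, affine2d())
  expect_equal(y3$values[, 1],
               as.vector(rnd$values[, , 1]))
})

make_fusion_fixture <- function(seed = 7, noise = 0) {
  set.seed(seed)
  u <- 4; gh <- 16; gw <- 16
  hh <- gh * u; ww <- gw * u
  base <- matrix(0, hh, ww)
  for (i in 1:6)
    base <- base + multimsi:::disc_map(hh, ww, runif(1, 10, ww - 10),
                                       runif(1, 10, hh - 10), runif(1, 4, 8))
  ch2 <- 0.5 * base + 0.1
  if (noise > 0) {
    base <- base + matrix(rnorm(hh * ww, 0, noise), hh, ww)
    ch2 <- ch2 + matrix(rnorm(hh * ww, 0, noise), hh, ww)
  }
  micro <- msi_cube(array(pmax(c(base, ch2), 0), c(hh, ww, 2)),
                    c(450, 550), 2.5, "hyperspectral")
  tm <- affine2d(matrix(c(1 / u, 0, 0.5 - 0.5 / u,
                          0, 1 / u, 0.5 - 0.5 / u,
                          0, 0, 1), 3, 3, byrow = TRUE))
  part <- structure(list(grid = c(gh, gw),
                         data_pixels = cbind(row = rep(1:gh, gw),
                                             col = rep(1:gw, each = gh)),
                         data_linear = 1:(gh * gw)),
                    class = "pixel_partition")
  list(micro = micro, tm = tm, part = part, u = u)
}

test_that("fuse: perfect linear link scores 100 with vanishing CI", {
  fx <- make_fusion_fixture()
  ylow <- downsample_hyperspectral(fx$micro, fx$part, fx$tm)
  ion <- ylow$values[, 1]
  xs <- structure(list(values = cbind(ion1 = ion),
                       coords = fx$part$data_pixels, grid = fx$part$grid,
                       variables = 1, block_map = NULL),
                  class = "pixel_matrix")
  fm <- fuse(xs, fx$micro, fx$tm, config = list(n_comp = 2))
  expect_equal(unname(fm$scores), 100, tolerance = 0.1)
  expect_lt(max(fm$ions[[1]]$ci_image), 1e-6)
  # self-consistency: recomputing the stored score from the stored images
  meas <- fm$ions[[1]]$measured_image[fx$part$data_linear]
  resid <- fm$ions[[1]]$residual_image[fx$part$data_linear]
  expect_equal(100 * (1 - sum(resid^2) / sum((meas - mean(meas))^2)),
               unname(fm$scores), tolerance = 1e-10)
})

test_that("fuse flags uninformative and degenerate ions", {
  fx <- make_fusion_fixture()
  set.seed(8)
  indep <- runif(256)
  xs <- structure(list(values = cbind(indep = indep, flat = rep(2, 256)),
                       coords = fx$part$data_pixels, grid = fx$part$grid,
                       variables = 1:2, block_map = NULL),
                  class = "pixel_matrix")
  expect_warning(fm <- fuse(xs, fx$micro, fx$tm, config = list(n_comp = 2)),
                 "zero variance")
  expect_equal(fm$skipped, "flat")
  expect_lt(abs(fm$scores[["indep"]]), 15)    # ~0: nothing to predict
})

test_that("reconstruction scores degrade monotonically with microscopy noise", {
  ylow0 <- with(make_fusion_fixture(noise = 0), {
    downsample_hyperspectral(micro, part, tm)
  })
  ion <- ylow0$values[, 1]
  meds <- vapply(c(0, 0.05, 0.1, 0.2, 0.4), function(nz) {
    fx <- make_fusion_fixture(noise = nz)
    xs <- structure(list(values = cbind(ion1 = ion),
                         coords = fx$part$data_pixels, grid = fx$part$grid,
                         variables = 1, block_map = NULL),
                    class = "pixel_matrix")
    fm <- fuse(xs, fx$micro, fx$tm, config = list(n_comp = 2))
    unname(fm$scores)
  }, numeric(1))
  expect_true(all(diff(meds) < 0))
})

test_that("phantom fusion localizes the core feature at high resolution", {
  ph <- default_phantom(seed = 0)
  ds <- center_scale(assemble_multimodal(ph$msi), "unit_variance")
  x <- concat_blocks(ds)
  lt <- ph$truth$loading_table
  idx <- which(lt$block == 1 & lt$pattern == "local_12")[1]
  xs <- x
  xs$values <- x$values[, idx, drop = FALSE]
  xs$variables <- x$variables[idx]
  fm <- fuse(xs, ph$hyperspectral, ph$truth$transform_hyper,
             config = list(n_comp = 8))
  expect_gt(dice_overlap(fm$ions[[1]]$prediction, ph$truth$maps_hr$core),
            0.8)
})

test_that("fusion_report writes per-ion imagery and the score table", {
  fx <- make_fusion_fixture()
  ylow <- downsample_hyperspectral(fx$micro, fx$part, fx$tm)
  xs <- structure(list(values = cbind(a = ylow$values[, 1],
                                      b = ylow$values[, 2]),
                       coords = fx$part$data_pixels, grid = fx$part$grid,
                       variables = 1:2, block_map = NULL),
                  class = "pixel_matrix")
  fm <- fuse(xs, fx$micro, fx$tm, config = list(n_comp = 2))
  out <- file.path(tempdir(), "fusion_report")
  tab <- fusion_report(fm, out)
  expect_equal(nrow(tab), 2)                 # one row per selected ion
  expect_true(file.exists(file.path(out, "reconstruction_scores.csv")))
  files <- list.files(out)
  for (what in c("measured_image", "prediction", "residual_image",
                 "ci_image"))
    expect_equal(sum(grepl(what, files)), 2)
  # CI is wider where features are near-constant (low information)
  fxn <- make_fusion_fixture(noise = 0.05)
  xs2 <- xs
  fm2 <- fuse(xs2, fxn$micro, fxn$tm, config = list(n_comp = 2))
  ci <- fm2$ions[[1]]$ci_image
  feat <- fxn$micro$values[, , 1]
  hi_info <- feat > stats::quantile(feat, 0.9)
  lo_info <- feat <= stats::quantile(feat, 0.1)
  expect_gt(mean(ci[hi_info]), mean(ci[lo_info]))
})
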