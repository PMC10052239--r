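as_dataset <- function(blocks, tags = NULL) {
  if (is.null(tags)) tags <- paste0("block", seq_along(blocks))
  structure(list(blocks = blocks, partition = NULL, tags = tags),
            class = "multimodal_dataset")
}

test_that("assemble_multimodal intersects data masks and aligns rows", {
  ph <- tiny_phantom()
  ds1 <- assemble_multimodal(ph$msi[1])
  expect_equal(ds1$blocks[[1]],
               to_pixel_matrix(ph$msi[[1]],
                               partition_pixels(ph$msi[[1]]))$values)

  # offset black borders: the common mask is the intersection
  a <- small_cube(seed = 1, h = 6, w = 6, k = 3)
  b <- small_cube(seed = 2, h = 6, w = 6, k = 4)
  a$values[, 1, ] <- 0                       # black column in a
  b$values[6, , ] <- 0                       # black row in b
  ds <- assemble_multimodal(list(a, b))
  tic_a <- tic_image(a); tic_b <- tic_image(b)
  expect_equal(sort(ds$partition$data_linear),
               which(tic_a != 0 & tic_b != 0))
  expect_equal(nrow(ds$blocks[[1]]), nrow(ds$blocks[[2]]))

  ds3 <- assemble_multimodal(ph$msi)
  expect_equal(ds3$block_map$tag, c("lipid_neg", "lipid_pos", "peptide"))

  z <- a; z$values[] <- 0
  expect_error(assemble_multimodal(list(a, z)), "empty")
})

test_that("center_scale centers, scales, flags and inverts", {
  ph <- tiny_phantom()
  ds <- assemble_multimodal(ph$msi)
  dc <- center_scale(ds, "mean_center")
  for (b in seq_along(dc$blocks))
    expect_lt(max(abs(colMeans(dc$blocks[[b]]))), 1e-12)
  duv <- center_scale(ds, "unit_variance")
  sds <- apply(duv$blocks[[1]], 2, sd)
  expect_equal(unname(sds), rep(1, length(sds)), tolerance = 1e-12)
  back <- inverse_center_scale(duv)
  expect_equal(back$blocks[[1]], ds$blocks[[1]], tolerance = 1e-10)

  # zero-variance column: flagged, left centered only
  ds2 <- ds
  ds2$blocks[[1]][, 3] <- 5
  duv2 <- center_scale(ds2, "unit_variance")
  expect_true(duv2$preprocessing[[1]]$zero_variance[3])
  expect_equal(unname(duv2$blocks[[1]][, 3]),
               rep(0, nrow(duv2$blocks[[1]])))
})

test_that("fit_pca: rank-1 capture, orthonormal loadings, variance bookkeeping", {
  set.seed(1)
  t <- rnorm(50); p <- rnorm(8)
  x <- scale(tcrossprod(t, p), scale = FALSE)
  f <- fit_pca(x, 2)
  expect_gt(f$explained_variance[1], 0.999)
  set.seed(2)
  x2 <- scale(matrix(rnorm(50 * 8), 50, 8), scale = FALSE)
  f2 <- fit_pca(x2, 5)
  expect_equal(crossprod(f2$loadings), diag(5), tolerance = 1e-10)
  expect_true(all(diff(f2$explained_variance) <= 1e-12))
  expect_lte(sum(f2$explained_variance), 1 + 1e-12)
  expect_warning(fit_pca(x2, 20), "truncated")
})

test_that("fit_onpls recovers exact shared structure of two blocks", {
  set.seed(4)
  t <- rnorm(200); p1 <- rnorm(30); p2 <- rnorm(40)
  ds <- as_dataset(list(scale(tcrossprod(t, p1), scale = FALSE),
                        scale(tcrossprod(t, p2), scale = FALSE)))
  m <- fit_onpls(ds, n_global = 1, n_unique = 0)
  expect_gt(abs(cor(m$global[[1]]$scores[, 1], t)), 0.999)
  expect_gt(abs(cor(m$global[[1]]$scores[, 2], t)), 0.999)
  for (b in 1:2)
    expect_lt(sum(m$parts[[b]]$residual^2), 1e-20)
})

test_that("fit_onpls validates inputs", {
  set.seed(5)
  x <- scale(matrix(rnorm(60), 20, 3), scale = FALSE)
  ds <- as_dataset(list(x, x))
  ds$blocks[[1]][2, 2] <- NA
  expect_error(fit_onpls(ds), "missing values")
  expect_error(fit_onpls(as_dataset(list(x))), "at least 2")
  expect_error(fit_onpls(as_dataset(list(x + 5, x))), "mean-centered")
  expect_error(fit_onpls(as_dataset(list(x, x)), n_local = list("1" = 1)),
               "subset")
  expect_warning(fit_onpls(as_dataset(list(x, x)), n_unique = 10),
                 "truncated")
})

test_that("planted global/local/unique structure is recovered on the phantom", {
  ph <- default_phantom(seed = 0, noise_sigma = 0.2)
  ds <- center_scale(assemble_multimodal(ph$msi), "mean_center")
  m <- fit_onpls(ds, n_global = 1,
                 n_local = list("1,2" = 1, "2,3" = 1), n_unique = 1)
  lin <- ds$partition$data_linear
  truth_of <- function(nm) ph$truth$maps[[nm]][lin]
  expect_true(all(abs(cor(m$global[[1]]$scores, truth_of("global"))) > 0.9))
  expect_true(all(abs(cor(m$local[[1]]$scores, truth_of("local_12"))) > 0.9))
  expect_true(all(abs(cor(m$local[[2]]$scores, truth_of("local_23"))) > 0.9))
  expect_gt(abs(cor(m$unique[[1]]$scores[, 1], truth_of("unique_1"))), 0.9)
  expect_gt(abs(cor(m$unique[[2]]$scores[, 1], truth_of("unique_2"))), 0.9)
  expect_gt(abs(cor(m$unique[[3]]$scores[, 1], truth_of("unique_3"))), 0.9)

  # the local(1,2) pattern must not load on block 3: block 3's parts are
  # uncorrelated with the core map beyond chance
  core_in_b3 <- abs(cor(m$parts[[3]]$local %*% rep(1, ncol(m$parts[[3]]$local)),
                        truth_of("local_12")))
  expect_lt(core_in_b3, 0.35)

  # reconstruction and additivity per block
  for (b in 1:3) {
    p <- m$parts[[b]]
    x <- ds$blocks[[b]]
    expect_lt(max(abs(x - (p$global + p$local + p$unique + p$residual))),
              1e-8)
    tot <- sum(x^2)
    parts_ss <- sum(p$global^2) + sum(p$local^2) + sum(p$unique^2) +
      sum(p$residual^2)
    expect_lt(abs(parts_ss - tot) / tot, 1e-8)
    shares <- m$variance_shares[[b]]
    expect_true(all(shares >= 0) && sum(shares) <= 1 + 1e-8)
  }

  # unique scores orthogonal to the block's joint deflation directions
  for (b in 1:3)
    expect_lt(max(abs(crossprod(m$unique[[b]]$scores,
                                m$joint_directions[[b]]))), 1e-6)

  # globally joint scores pairwise highly correlated by construction
  cg <- cor(m$global[[1]]$scores)
  expect_true(all(cg[upper.tri(cg)] > 0.9))
})

test_that("independent-noise blocks show no spurious joint structure", {
  shares <- sapply(1:10, function(s) {
    ph <- make_phantom(phantom_spec(grid = c(48, 48),
                                    block_widths = c(120, 90, 20),
                                    n_features = 0, misalign = "none",
                                    seed = 100 + s))
    ds <- center_scale(assemble_multimodal(ph$msi), "mean_center")
    m <- fit_onpls(ds, n_global = 1, n_local = list(), n_unique = 0)
    vapply(m$variance_shares, function(v) v[["global"]], numeric(1))
  })
  expect_lt(max(colMeans(shares)), 0.05)
  expect_true(all(shares < 0.05))
})

test_that("score images restore model scores with black background", {
  ph <- tiny_phantom()
  ds <- center_scale(assemble_multimodal(ph$msi), "mean_center")
  m <- fit_onpls(ds, n_global = 1, n_local = list(), n_unique = 1)
  imgs <- onpls_score_images(m, "global", 1)
  expect_length(imgs, 3)
  expect_equal(imgs[[2]][ds$partition$data_linear],
               m$global[[1]]$scores[, 2])
  ui <- onpls_score_images(m, "unique", 1, block = 2, background = NA)
  expect_true(all(is.na(ui[[1]][ds$partition$black_pixels])))
})

test_that("cross-validation recommends the planted component count", {
  set.seed(6)
  n <- 140
  # rank-1 noise-free
  x1 <- tcrossprod(rnorm(n), rnorm(12))
  expect_equal(cross_validate_components(x1, 0:4)$recommended, 1)
  # planted 3 components with small noise
  scores <- matrix(rnorm(n * 3), n, 3)
  loads <- matrix(rnorm(36), 12, 3)
  x3 <- tcrossprod(scores, loads) + matrix(rnorm(n * 12, 0, 0.05), n, 12)
  expect_equal(cross_validate_components(x3, 0:6)$recommended, 3)
  # pure noise: nothing predicts out of fold
  xn <- matrix(rnorm(n * 12), n, 12)
  expect_equal(cross_validate_components(xn, 0:4)$recommended, 0)
})
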