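#' Block-average a hyperspectral cube onto the MSI pixel grid
#'
#' Maps every microscopy pixel center through the registration transform
#' into the MSI frame and averages all microscopy intensities falling into
#' each MSI pixel footprint, per channel. The result is the Y matrix for
#' OPLS modeling and the low-resolution feature matrix for fusion.
#'
#' @param cube hyperspectral [msi_cube] (microscopy frame).
#' @param target_partition [pixel_partition] of the MSI grid (data pixels
#'   define the rows of the result).
#' @param t `affine2d` mapping microscopy pixel coordinates to MSI pixel
#'   coordinates.
#' @return a `pixel_matrix` of block-averaged channel intensities, rows
#'   aligned with the partition's data pixels.
#' @export
downsample_hyperspectral <- function(cube, target_partition, t) {
  h <- cube_height(cube); w <- cube_width(cube); k <- cube_nvar(cube)
  gh <- target_partition$grid[1]; gw <- target_partition$grid[2]
  src_x <- rep(seq_len(w), each = h)
  src_y <- rep(seq_len(h), times = w)
  mapped <- transform_points(t, cbind(src_x, src_y))
  col_i <- floor(mapped[, 1] + 0.5)
  row_i <- floor(mapped[, 2] + 0.5)
  ok <- col_i >= 1 & col_i <= gw & row_i >= 1 & row_i <= gh
  lin <- (col_i[ok] - 1) * gh + row_i[ok]
  counts <- tabulate(lin, nbins = gh * gw)
  data_lin <- target_partition$data_linear
  if (any(counts[data_lin] == 0))
    stop("grid mismatch after transform: some MSI data pixels receive no microscopy pixels")
  flat <- matrix(cube$values, nrow = h * w, ncol = k)
  y <- matrix(0, length(data_lin), k)
  for (j in seq_len(k)) {
    sums <- rowsum(flat[ok, j], group = lin, reorder = FALSE)
    acc <- numeric(gh * gw)
    acc[as.integer(rownames(sums))] <- sums
    y[, j] <- acc[data_lin] / counts[data_lin]
  }
  colnames(y) <- format(cube$variables, trim = TRUE)
  structure(
    list(values = y, coords = target_partition$data_pixels,
         grid = target_partition$grid, variables = cube$variables,
         block_map = data.frame(tag = cube$modality, start = 1L, end = k,
                                stringsAsFactors = FALSE)),
    class = "pixel_matrix")
}

# univariate PLS1 regression by NIPALS; returns enough state to predict
# and to propagate prediction variance
pls1_fit <- function(f, y, n_comp) {
  f <- as.matrix(f)
  mu_f <- colMeans(f); mu_y <- mean(y)
  fc <- sweep(f, 2, mu_f); yc <- y - mu_y
  n_comp <- min(n_comp, qr(fc)$rank)
  W <- P <- list(); q <- numeric(0)
  scores <- NULL
  for (a in seq_len(n_comp)) {
    w <- as.vector(crossprod(fc, yc))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t <- as.vector(fc %*% w)
    if (sum(t^2) < 1e-20) break
    p <- as.vector(crossprod(fc, t) / sum(t^2))
    qa <- sum(yc * t) / sum(t^2)
    fc <- fc - tcrossprod(t, p)
    yc <- yc - qa * t
    W[[a]] <- w; P[[a]] <- p; q <- c(q, qa)
    scores <- cbind(scores, t)
  }
  if (!length(W)) {
    # constant features: fall back to intercept-only model
    return(list(coef = matrix(0, ncol(f), 1), intercept = mu_y,
                mu_f = mu_f, scores = matrix(0, nrow(f), 0),
                rot = matrix(0, ncol(f), 0), q = numeric(0),
                sigma2 = stats::var(y), df = length(y) - 1))
  }
  W <- do.call(cbind, W); P <- do.call(cbind, P)
  rot <- W %*% solve(crossprod(P, W))      # features -> scores
  coef <- rot %*% q
  resid <- yc
  df <- max(length(y) - ncol(W) - 1, 1)
  list(coef = coef, intercept = mu_y, mu_f = mu_f, scores = scores,
       rot = rot, q = q, sigma2 = sum(resid^2) / df, df = df)
}

pls1_predict <- function(fit, f_new) {
  as.vector(sweep(as.matrix(f_new), 2, fit$mu_f) %*% fit$coef) +
    fit$intercept
}

# 95% prediction-interval half-width of the fitted mean at new feature
# rows: t-quantile x sigma x sqrt(1/n + z' (Z'Z)^-1 z) in latent space
pls1_ci_halfwidth <- function(fit, f_new, level = 0.95) {
  n <- nrow(fit$scores)
  if (ncol(fit$rot) == 0) return(rep(0, nrow(as.matrix(f_new))))
  z_new <- sweep(as.matrix(f_new), 2, fit$mu_f) %*% fit$rot
  ztz_inv <- solve(crossprod(fit$scores))
  lev <- rowSums((z_new %*% ztz_inv) * z_new)
  tq <- stats::qt(1 - (1 - level) / 2, df = fit$df)
  tq * sqrt(pmax(fit$sigma2, 0) * (1 / n + pmax(lev, 0)))
}

#' Data-driven MSI-microscopy image fusion
#'
#' For each VIP-selected MSI variable (ion), trains a PLS regression
#' predicting the ion's measured MSI-resolution intensity from microscopy
#' channel features block-averaged onto the MSI pixels, then applies the
#' trained regression at full microscopy resolution to predict the ion
#' distribution beyond the MSI acquisition resolution. Per ion the model
#' stores: the high-resolution prediction, a reconstruction score
#' `100 * (1 - SS_res / SS_tot)` comparing the block-averaged prediction
#' with the measurement, the absolute-residual image at MSI resolution, a
#' 95% confidence-interval half-width image at high resolution, and the
#' original, non-interpolated ion image for independent cross-evaluation.
#'
#' @param x_selected `pixel_matrix` of VIP-selected ions at MSI resolution
#'   (from [select_variables()]).
#' @param microscopy hyperspectral [msi_cube] at full resolution.
#' @param t `affine2d` microscopy -> MSI pixel coordinates (from
#'   registration).
#' @param config list: `n_comp` PLS components (default
#'   `min(10, n_channels)`), `texture_features` add local 3x3 mean and
#'   variance of each channel as extra features (default FALSE).
#' @return object of class `fusion_model`: per-ion list `ions` with
#'   `prediction` (high-res matrix), `score`, `residual_image`,
#'   `ci_image`, `measured_image`; plus `scores` (named vector) and
#'   `skipped`.
#' @export
fuse <- function(x_selected, microscopy, t, config = list()) {
  cfg <- utils::modifyList(
    list(n_comp = min(10, cube_nvar(microscopy)), texture_features = FALSE),
    config)
  part <- list(grid = x_selected$grid,
               data_pixels = x_selected$coords,
               data_linear = (x_selected$coords[, "col"] - 1L) *
                 x_selected$grid[1] + x_selected$coords[, "row"])
  class(part) <- "pixel_partition"
  feat_cube <- microscopy
  if (cfg$texture_features)
    feat_cube <- add_texture_channels(microscopy)
  f_low <- downsample_hyperspectral(feat_cube, part, t)$values
  h <- cube_height(feat_cube); w <- cube_width(feat_cube)
  k <- cube_nvar(feat_cube)
  f_high <- matrix(feat_cube$values, nrow = h * w, ncol = k)
  # mapping of every microscopy pixel to its MSI pixel, for block-averaged
  # scoring of the high-resolution predictions
  src_x <- rep(seq_len(w), each = h)
  src_y <- rep(seq_len(h), times = w)
  mapped <- transform_points(t, cbind(src_x, src_y))
  col_i <- floor(mapped[, 1] + 0.5); row_i <- floor(mapped[, 2] + 0.5)
  gh <- part$grid[1]; gw <- part$grid[2]
  ok <- col_i >= 1 & col_i <= gw & row_i >= 1 & row_i <= gh
  lin_map <- (col_i[ok] - 1) * gh + row_i[ok]
  counts <- tabulate(lin_map, nbins = gh * gw)

  ions <- list(); skipped <- character(0)
  for (j in seq_len(ncol(x_selected$values))) {
    ion_name <- colnames(x_selected$values)[j]
    if (is.null(ion_name)) ion_name <- sprintf("ion%03d", j)
    y <- x_selected$values[, j]
    if (stats::var(y) == 0) {
      warning("ion ", ion_name, " has zero variance: skipped")
      skipped <- c(skipped, ion_name)
      next
    }
    fit <- pls1_fit(f_low, y, cfg$n_comp)
    pred_high_v <- pls1_predict(fit, f_high)
    pred_high <- matrix(pred_high_v, h, w)
    # block-average the prediction back to MSI pixels
    sums <- rowsum(pred_high_v[ok], group = lin_map, reorder = FALSE)
    acc <- numeric(gh * gw)
    acc[as.integer(rownames(sums))] <- sums
    pred_low <- acc[part$data_linear] / counts[part$data_linear]
    ss_res <- sum((y - pred_low)^2)
    ss_tot <- sum((y - mean(y))^2)
    score <- 100 * (1 - ss_res / ss_tot)
    ci <- matrix(pls1_ci_halfwidth(fit, f_high), h, w)
    ions[[ion_name]] <- list(
      prediction = pred_high,
      score = score,
      residual_image = restore_score_image(abs(y - pred_low), part),
      ci_image = ci,
      measured_image = restore_score_image(y, part),
      fit = fit)
  }
  if (!length(ions)) stop("no ion with nonzero variance to fuse")
  structure(
    list(ions = ions,
         scores = vapply(ions, function(i) i$score, numeric(1)),
         skipped = skipped,
         grid_low = part$grid, grid_high = c(h, w),
         transform = t),
    class = "fusion_model")
}

# append per-channel local 3x3 mean and variance as extra feature channels
add_texture_channels <- function(cube) {
  h <- cube_height(cube); w <- cube_width(cube); k <- cube_nvar(cube)
  box <- function(m) {
    pr <- function(i, n) pmin(pmax(i, 1), n)
    acc <- matrix(0, h, w)
    for (dr in -1:1) for (dc in -1:1)
      acc <- acc + m[pr(seq_len(h) + dr, h), pr(seq_len(w) + dc, w)]
    acc / 9
  }
  vals <- array(0, dim = c(h, w, 3 * k))
  for (j in seq_len(k)) {
    m <- cube$values[, , j]
    mu <- box(m)
    vals[, , j] <- m
    vals[, , k + j] <- mu
    vals[, , 2 * k + j] <- pmax(box(m^2) - mu^2, 0)
  }
  # synthetic channel ids appended after the real ones, keeping the axis
  # strictly increasing
  ids <- c(cube$variables,
           max(cube$variables) + seq_len(2 * k))
  msi_cube(vals, ids, cube$pixel_size, cube$modality, cube$origin)
}

#' @export
print.fusion_model <- function(x, ...) {
  cat(sprintf("<fusion_model> %d ions fused %s -> %s; reconstruction scores %.1f..%.1f%%\n",
              length(x$ions),
              paste(x$grid_low, collapse = "x"),
              paste(x$grid_high, collapse = "x"),
              min(x$scores), max(x$scores)))
  invisible(x)
}

#' Export fusion imagery and a score table
#'
#' Writes, per fused ion: the measured (original, non-interpolated) ion
#' image, the high-resolution prediction, the absolute-residual image and
#' the 95% CI half-width image as CSV matrices, plus a summary table of
#' reconstruction scores.
#'
#' @param model a `fusion_model`.
#' @param out_dir output directory (created if absent).
#' @return data.frame of reconstruction scores, invisibly; files on disk.
#' @export
fusion_report <- function(model, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tab <- data.frame(ion = names(model$ions),
                    reconstruction_score = unname(model$scores),
                    stringsAsFactors = FALSE)
  utils::write.csv(tab, file.path(out_dir, "reconstruction_scores.csv"),
                   row.names = FALSE)
  for (nm in names(model$ions)) {
    ion <- model$ions[[nm]]
    safe <- gsub("[^0-9A-Za-z._-]", "_", nm)
    for (what in c("measured_image", "prediction", "residual_image",
                   "ci_image")) {
      utils::write.table(
        ion[[what]],
        file.path(out_dir, sprintf("%s_%s.csv", safe, what)),
        sep = ",", row.names = FALSE, col.names = FALSE)
    }
  }
  invisible(tab)
}
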