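#' Rolling-minimum baseline correction
#'
#' Subtracts, per pixel spectrum, a rolling minimum over a centered window
#' of `window` variables (truncated at the spectrum edges). Because the
#' window includes the point itself the baseline never exceeds the signal,
#' so corrected intensities are nonnegative; a flat spectrum is reduced to
#' zero and an isolated peak keeps its height while losing its offset.
#'
#' @param cube an [msi_cube].
#' @param window odd window length >= 3, in variables (default 101).
#' @return baseline-corrected [msi_cube].
#' @export
baseline_correct <- function(cube, window = 101) {
  k <- cube_nvar(cube)
  if (window < 3 || window %% 2 == 0)
    stop("`window` must be odd and >= 3")
  if (window > k)
    stop(sprintf("window (%d) exceeds variable count (%d)", window, k))
  h <- cube_height(cube); w <- cube_width(cube)
  flat <- matrix(cube$values, nrow = h * w, ncol = k)
  half <- (window - 1) / 2
  base <- flat
  for (o in seq_len(half)) {
    # shift left / right along the variable axis, edge-truncated
    base[, seq_len(k - o)] <- pmin(base[, seq_len(k - o), drop = FALSE],
                                   flat[, seq_len(k - o) + o, drop = FALSE])
    base[, seq_len(k - o) + o] <- pmin(base[, seq_len(k - o) + o, drop = FALSE],
                                       flat[, seq_len(k - o), drop = FALSE])
  }
  out <- flat - base
  msi_cube(array(out, dim = c(h, w, k)), cube$variables, cube$pixel_size,
           cube$modality, cube$origin)
}

#' Root-mean-square normalization
#'
#' Divides every data-pixel spectrum by its own RMS intensity so each data
#' pixel leaves with RMS exactly 1; black (all-zero) pixels are untouched by
#' definition. Cannot create or destroy black pixels, so the pixel
#' partition is invariant under this operation.
#'
#' @param cube an [msi_cube] with at least one data pixel.
#' @return normalized [msi_cube].
#' @export
rms_normalize <- function(cube) {
  h <- cube_height(cube); w <- cube_width(cube); k <- cube_nvar(cube)
  flat <- matrix(cube$values, nrow = h * w, ncol = k)
  rms <- sqrt(rowMeans(flat^2))
  if (all(rms == 0)) stop("cube has no data pixels")
  scale <- ifelse(rms > 0, 1 / rms, 0)
  flat <- flat * scale
  msi_cube(array(flat, dim = c(h, w, k)), cube$variables, cube$pixel_size,
           cube$modality, cube$origin)
}

#' Peak-region extraction on the mean spectrum
#'
#' Removes the noise between peaks of the dataset mean spectrum and keeps
#' all data points over the peaks, without binning or centroiding: columns
#' are retained where the mean spectrum (over data pixels) reaches
#' `noise_factor` times the median absolute deviation of the mean spectrum.
#' Contiguous above-threshold runs therefore survive as separate column
#' ranges — overlapping peaks are never merged into one centroid. A
#' `noise_factor` of 0 keeps every column; retention is monotone
#' (a larger factor never keeps more columns).
#'
#' @param cube an [msi_cube].
#' @param noise_factor nonnegative multiplier of the MAD threshold
#'   (default 3).
#' @return [msi_cube] restricted to the retained variable columns.
#' @export
peak_extract <- function(cube, noise_factor = 3) {
  if (noise_factor < 0) stop("noise_factor must be nonnegative")
  part <- partition_pixels(cube)
  h <- cube_height(cube); w <- cube_width(cube); k <- cube_nvar(cube)
  flat <- matrix(cube$values, nrow = h * w, ncol = k)
  if (nrow(part$data_pixels) == 0) stop("no data pixels: mean spectrum undefined")
  mean_spec <- colMeans(flat[part$data_linear, , drop = FALSE])
  thr <- noise_factor * stats::mad(mean_spec)
  keep <- mean_spec >= thr
  if (!any(keep))
    stop(sprintf("no variable column exceeds the peak threshold %.4g", thr))
  msi_cube(cube$values[, , keep, drop = FALSE], cube$variables[keep],
           cube$pixel_size, cube$modality, cube$origin)
}
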