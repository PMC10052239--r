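#' Spectral image cube
#'
#' The unit of all imaging I/O in multimsi: a rectangular pixel grid where
#' every pixel carries a spectral vector. For MSI modalities the spectral
#' axis holds m/z centroids, for hyperspectral microscopy it holds
#' wavelength-band centers in nanometers.
#'
#' Grid convention (stated once, used everywhere): pixels are addressed
#' 1-based as (row, col); continuous coordinates use x = col, y = row with
#' pixel centers at integer coordinates, so pixel (r, c) covers
#' `[c - 0.5, c + 0.5) x [r - 0.5, r + 0.5)`. imzML 1-based coordinates map
#' directly onto this convention.
#'
#' @param values numeric array of dimension `c(height, width, n_variables)`
#'   with finite, nonnegative intensities (negatives only appear after
#'   mean-centering, never at load time).
#' @param variables strictly increasing numeric channel identifiers
#'   (m/z or nm).
#' @param pixel_size isotropic pixel edge length in micrometers.
#' @param modality one of `"lipid_neg"`, `"lipid_pos"`, `"peptide"`,
#'   `"hyperspectral"`.
#' @param origin absolute (row, col) of the cube's (1, 1) pixel in its parent
#'   frame; kept so ROI subsets retain absolute coordinates.
#'
#' @return an object of class `msi_cube`.
#' @export
msi_cube <- function(values, variables, pixel_size = 10,
                     modality = c("lipid_neg", "lipid_pos", "peptide",
                                  "hyperspectral"),
                     origin = c(1L, 1L)) {
  modality <- match.arg(modality)
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3-d array (height x width x variables)")
  variables <- as.numeric(variables)
  if (length(variables) != dim(values)[3L])
    stop("length(variables) must equal dim(values)[3]")
  if (is.unsorted(variables, strictly = TRUE))
    stop("variable identifiers must be strictly increasing")
  if (any(!is.finite(values)))
    stop("intensities must be finite")
  if (pixel_size <= 0) stop("pixel_size must be positive")
  structure(
    list(values = values, variables = variables,
         pixel_size = pixel_size, modality = modality,
         origin = as.integer(origin)),
    class = "msi_cube")
}

#' @export
print.msi_cube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<msi_cube> %s: %d x %d pixels (%.4g um), %d variables [%.4g..%.4g]\n",
              x$modality, d[1], d[2], x$pixel_size, d[3],
              min(x$variables), max(x$variables)))
  invisible(x)
}

#' @export
dim.msi_cube <- function(x) dim(x$values)

cube_height <- function(cube) dim(cube$values)[1L]
cube_width  <- function(cube) dim(cube$values)[2L]
cube_nvar   <- function(cube) dim(cube$values)[3L]

#' Total-ion-current image of a cube
#'
#' Per-pixel sum over the spectral axis; zero exactly at black pixels.
#'
#' @param cube an [msi_cube].
#' @return numeric matrix `height x width`.
#' @export
tic_image <- function(cube) {
  apply(cube$values, c(1, 2), sum)
}

#' Partition a cube into data pixels and black pixels
#'
#' A pixel i is black iff its summed intensity over all variables is exactly
#' zero, and a data pixel otherwise; only data pixels enter modeling. The
#' two index sets are disjoint and cover the grid.
#'
#' @param cube an [msi_cube].
#' @return an object of class `pixel_partition` with integer matrices
#'   `data_pixels` and `black_pixels` (columns `row`, `col`), the grid
#'   dimensions and the linear (column-major) indices of the data pixels.
#' @export
partition_pixels <- function(cube) {
  tic <- tic_image(cube)
  h <- nrow(tic); w <- ncol(tic)
  data_lin <- which(tic != 0)
  black_lin <- which(tic == 0)
  as_rc <- function(lin) {
    cbind(row = ((lin - 1L) %% h) + 1L,
          col = ((lin - 1L) %/% h) + 1L)
  }
  structure(
    list(data_pixels = as_rc(data_lin),
         black_pixels = as_rc(black_lin),
         data_linear = data_lin,
         grid = c(h, w)),
    class = "pixel_partition")
}

#' @export
print.pixel_partition <- function(x, ...) {
  cat(sprintf("<pixel_partition> %d x %d grid: %d data, %d black pixels\n",
              x$grid[1], x$grid[2],
              nrow(x$data_pixels), nrow(x$black_pixels)))
  invisible(x)
}

#' Flatten a cube to a pixel-by-variable matrix
#'
#' Data-pixel rows only (one row per data pixel, in column-major linear-index
#' order of the grid, the package's canonical row order), columns the
#' spectral variables. The operation is exactly invertible on data pixels via
#' [restore_score_image()].
#'
#' @param cube an [msi_cube].
#' @param partition a [partition_pixels()] result for the same grid.
#' @return an object of class `pixel_matrix`: list with `values`
#'   (n_data x n_var matrix), `coords`, `grid`, `variables` and `block_map`
#'   (data.frame `tag`, `start`, `end`, one row here).
#' @export
to_pixel_matrix <- function(cube, partition) {
  if (!identical(as.integer(partition$grid),
                 as.integer(dim(cube$values)[1:2])))
    stop("partition grid does not match cube grid")
  h <- cube_height(cube); w <- cube_width(cube); k <- cube_nvar(cube)
  flat <- matrix(cube$values, nrow = h * w, ncol = k)
  vals <- flat[partition$data_linear, , drop = FALSE]
  colnames(vals) <- format(cube$variables, trim = TRUE)
  structure(
    list(values = vals,
         coords = partition$data_pixels,
         grid = partition$grid,
         variables = cube$variables,
         block_map = data.frame(tag = cube$modality, start = 1L,
                                end = k, stringsAsFactors = FALSE)),
    class = "pixel_matrix")
}

#' @export
print.pixel_matrix <- function(x, ...) {
  cat(sprintf("<pixel_matrix> %d data pixels x %d variables (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(x$block_map$tag, collapse = "+")))
  invisible(x)
}

#' Restore a per-data-pixel vector to the image grid
#'
#' Exact inverse of the row ordering used by [to_pixel_matrix()]: black
#' pixels are reinstated at a sentinel background value and no interpolation
#' is performed (images are never interpolated beyond the acquisition
#' resolution).
#'
#' @param scores numeric vector, one value per data pixel.
#' @param partition the [pixel_partition] that produced the matrix rows.
#' @param background sentinel value for black pixels (default 0).
#' @return numeric matrix `height x width`.
#' @export
restore_score_image <- function(scores, partition, background = 0) {
  n <- nrow(partition$data_pixels)
  if (length(scores) != n)
    stop(sprintf("score length %d != number of data pixels %d",
                 length(scores), n))
  img <- matrix(background, partition$grid[1], partition$grid[2])
  img[partition$data_linear] <- scores
  img
}

#' Subset a cube to a region of interest
#'
#' Crops the cube to the bounding box of a binary mask; pixels inside the
#' box but outside the mask are zeroed (they become black pixels). Absolute
#' coordinates of the crop are retained in `origin`.
#'
#' @param cube an [msi_cube].
#' @param mask logical (or 0/1) matrix on the same grid.
#' @return an [msi_cube] cropped to the mask bounding box.
#' @export
roi_subset <- function(cube, mask) {
  mask <- mask != 0
  if (!identical(dim(mask), dim(cube$values)[1:2]))
    stop("mask grid does not match cube grid")
  if (!any(mask)) stop("empty ROI mask")
  rr <- range(which(rowSums(mask) > 0))
  cc <- range(which(colSums(mask) > 0))
  vals <- cube$values[rr[1]:rr[2], cc[1]:cc[2], , drop = FALSE]
  sub_mask <- mask[rr[1]:rr[2], cc[1]:cc[2]]
  vals <- sweep(vals, c(1, 2), sub_mask + 0, "*")
  out <- msi_cube(vals, cube$variables, cube$pixel_size, cube$modality,
                  origin = cube$origin + c(rr[1], cc[1]) - 1L)
  out
}
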