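#' 2D affine transforms between pixel coordinate frames
#'
#' Transforms are stored as 3x3 homogeneous matrices acting on column
#' vectors `(x, y, 1)` with x = col, y = row (pixel centers at integers).
#' `frame_from`/`frame_to` tag the modality frames the map connects.
#'
#' @param matrix 3x3 numeric matrix with last row `(0, 0, 1)` and
#'   invertible upper-left 2x2 part.
#' @param frame_from,frame_to modality tags (free-form strings).
#' @return object of class `affine2d`.
#' @export
affine2d <- function(matrix = diag(3), frame_from = "moving",
                     frame_to = "fixed") {
  matrix <- unname(as.matrix(matrix))
  stopifnot(identical(dim(matrix), c(3L, 3L)))
  if (max(abs(matrix[3, ] - c(0, 0, 1))) > 1e-12)
    stop("last row of an affine matrix must be (0, 0, 1)")
  if (abs(det(matrix[1:2, 1:2])) < 1e-12)
    stop("affine transform is not invertible")
  structure(list(matrix = matrix, frame_from = frame_from,
                 frame_to = frame_to),
            class = "affine2d")
}

#' @export
print.affine2d <- function(x, ...) {
  cat(sprintf("<affine2d> %s -> %s\n", x$frame_from, x$frame_to))
  print(round(x$matrix, 6))
  invisible(x)
}

#' Build an affine transform from translation / rotation / scale / shear
#'
#' Parameters are applied about `center` (x, y), in the order shear, scale,
#' rotation, translation.
#'
#' @param tx,ty translation in pixels.
#' @param rotation counter-clockwise rotation in radians.
#' @param sx,sy scale factors.
#' @param shear shear coefficient (x' = x + shear * y).
#' @param center (x, y) of the rotation/scale center.
#' @inheritParams affine2d
#' @return `affine2d`.
#' @export
affine_from_params <- function(tx = 0, ty = 0, rotation = 0, sx = 1, sy = 1,
                               shear = 0, center = c(0, 0),
                               frame_from = "moving", frame_to = "fixed") {
  tr  <- function(dx, dy) matrix(c(1, 0, 0, 0, 1, 0, dx, dy, 1), 3, 3)
  rot <- matrix(c(cos(rotation), sin(rotation), 0,
                  -sin(rotation), cos(rotation), 0, 0, 0, 1), 3, 3)
  sc  <- diag(c(sx, sy, 1))
  sh  <- matrix(c(1, 0, 0, shear, 1, 0, 0, 0, 1), 3, 3)
  m <- tr(center[1] + tx, center[2] + ty) %*% rot %*% sc %*% sh %*%
    tr(-center[1], -center[2])
  affine2d(m, frame_from, frame_to)
}

#' Compose two affine transforms
#'
#' `compose_affine(b, a)` applies `a` first, then `b`.
#'
#' @param b,a `affine2d` objects.
#' @return `affine2d` mapping `a$frame_from` to `b$frame_to`.
#' @export
compose_affine <- function(b, a) {
  affine2d(b$matrix %*% a$matrix, frame_from = a$frame_from,
           frame_to = b$frame_to)
}

#' Invert an affine transform
#' @param t an `affine2d`.
#' @return the inverse `affine2d` (frames swapped).
#' @export
invert_affine <- function(t) {
  affine2d(solve(t$matrix), frame_from = t$frame_to,
           frame_to = t$frame_from)
}

#' Apply an affine transform to points
#'
#' @param t an `affine2d`.
#' @param pts n x 2 matrix of (x, y) coordinates.
#' @return n x 2 matrix of transformed (x, y).
#' @export
transform_points <- function(t, pts) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  out <- cbind(pts, 1) %*% t(t$matrix)
  out[, 1:2, drop = FALSE]
}

#' Least-squares affine from control points
#'
#' Coarse alignment from manually (or synthetically) selected control-point
#' pairs: finds the affine T minimizing `sum ||T(moving_i) - fixed_i||^2`.
#' Three point pairs suffice for an exact affine; at least five, spread over
#' the tissue, are recommended in practice so that one badly placed point
#' does not dominate.
#'
#' @param fixed_points,moving_points n x 2 matrices of (x, y) coordinates,
#'   n >= 3, rows paired.
#' @inheritParams affine2d
#' @return `affine2d` mapping the moving frame to the fixed frame.
#' @export
coarse_align <- function(fixed_points, moving_points,
                         frame_from = "moving", frame_to = "fixed") {
  fixed_points <- matrix(as.numeric(fixed_points), ncol = 2)
  moving_points <- matrix(as.numeric(moving_points), ncol = 2)
  n <- nrow(fixed_points)
  if (n != nrow(moving_points)) stop("point lists must be paired")
  if (n < 3) stop("at least 3 control point pairs are required")
  A <- cbind(moving_points, 1)
  if (qr(A)$rank < 3)
    stop("control points are collinear: affine fit is degenerate")
  # two independent least-squares fits (x' and y' rows of the affine)
  coefs <- qr.solve(A, fixed_points)        # 3 x 2
  m <- rbind(t(coefs), c(0, 0, 1))
  affine2d(m, frame_from, frame_to)
}

#' Root-mean-square landmark error of a transform
#'
#' @param t candidate `affine2d` (moving -> fixed).
#' @param fixed_points,moving_points paired landmark coordinates.
#' @return mean Euclidean error in pixels.
#' @export
landmark_error <- function(t, fixed_points, moving_points) {
  pred <- transform_points(t, moving_points)
  mean(sqrt(rowSums((pred - matrix(as.numeric(fixed_points), ncol = 2))^2)))
}
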