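#' Quantize images to 8-bit unsigned integers
#'
#' Linear min-max rescale to `[0, 255]` followed by floor, the conversion
#' applied before Jaccard and entropy-based metrics. With
#' `scaling = "joint"` (default) the min/max are taken over both images so
#' the intensity-label mapping is comparable across the pair.
#'
#' @param a image matrix; `b` optional second image.
#' @param scaling `"joint"` or `"per_image"`.
#' @return integer matrix in 0..255, or list of two when `b` is given.
#' @export
quantize8 <- function(a, b = NULL, scaling = c("joint", "per_image")) {
  scaling <- match.arg(scaling)
  q1 <- function(x, lo, hi) {
    if (hi <= lo) return(matrix(0L, nrow(x), ncol(x)))
    q <- floor((x - lo) / (hi - lo) * 256)
    matrix(as.integer(pmin(q, 255)), nrow(x), ncol(x))
  }
  if (is.null(b)) {
    return(q1(a, min(a), max(a)))
  }
  if (scaling == "joint") {
    lo <- min(a, b); hi <- max(a, b)
    list(a = q1(a, lo, hi), b = q1(b, lo, hi))
  } else {
    list(a = q1(a, min(a), max(a)), b = q1(b, min(b), max(b)))
  }
}

check_same_dim <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("image dimensions differ: %s vs %s",
                 paste(dim(a), collapse = "x"),
                 paste(dim(b), collapse = "x")))
}

#' Mean square error between two images
#'
#' `MSE = (1 / (m n)) * sum_(i,j) (I_ij - K_ij)^2` for an m x n fixed image
#' I and moving image K.
#'
#' @param i,k image matrices of identical dimension.
#' @return nonnegative scalar.
#' @export
mse <- function(i, k) {
  check_same_dim(i, k)
  mean((i - k)^2)
}

#' Jaccard similarity coefficient of two images
#'
#' Images are converted to 8-bit unsigned integers, then the Jaccard index
#' `|A intersect B| / |A union B|` is computed per intensity label and
#' averaged over the labels present in either image (multi-class
#' convention). `mode = "binary"` instead thresholds at > 0 and scores the
#' foreground class only.
#'
#' @param a,b image matrices of identical dimension.
#' @param mode `"multiclass"` (default) or `"binary"`.
#' @param scaling passed to [quantize8()].
#' @return scalar in `[0, 1]`.
#' @export
jaccard <- function(a, b, mode = c("multiclass", "binary"),
                    scaling = "joint") {
  mode <- match.arg(mode)
  check_same_dim(a, b)
  q <- quantize8(a, b, scaling = scaling)
  if (mode == "binary") {
    fa <- q$a > 0; fb <- q$b > 0
    uni <- sum(fa | fb)
    if (uni == 0) return(1)   # both empty: identical segmentations
    return(sum(fa & fb) / uni)
  }
  labels <- sort(unique(c(as.vector(q$a), as.vector(q$b))))
  js <- vapply(labels, function(l) {
    ia <- q$a == l; ib <- q$b == l
    sum(ia & ib) / sum(ia | ib)   # union nonempty since l is present
  }, numeric(1))
  mean(js)
}

hist256 <- function(qa) tabulate(as.vector(qa) + 1L, nbins = 256L)

#' Shannon entropy of an image (bits)
#'
#' `H(A) = -sum_x p(x) log2 p(x)` over the 256-level histogram of the 8-bit
#' quantized image; zero-probability bins contribute 0 and constant images
#' have entropy 0.
#'
#' @param a image matrix (floats are 8-bit quantized first) .
#' @param quantized set TRUE when `a` is already integer 0..255.
#' @return entropy in bits.
#' @export
img_entropy <- function(a, quantized = FALSE) {
  qa <- if (quantized) a else quantize8(a)
  p <- hist256(qa)
  p <- p[p > 0] / sum(p)
  -sum(p * log2(p))
}

#' Joint entropy of two images (bits)
#'
#' `H(A,B)` over the 256 x 256 joint histogram of the jointly 8-bit
#' quantized pair. Minimized when pixels of the two images correspond
#' exactly; grows as their statistical relationship weakens.
#'
#' @inheritParams jaccard
#' @return joint entropy in bits, `>= max(H(A), H(B))`.
#' @export
joint_entropy <- function(a, b, scaling = "joint") {
  check_same_dim(a, b)
  q <- quantize8(a, b, scaling = scaling)
  joint <- as.vector(q$a) * 256L + as.vector(q$b)
  p <- tabulate(joint + 1L, nbins = 256L * 256L)
  p <- p[p > 0] / sum(p)
  -sum(p * log2(p))
}

#' Mutual information of two images (bits)
#'
#' `MI(A,B) = H(A) + H(B) - H(A,B)`; nonnegative, symmetric, and equal to
#' `H(A)` when B is a deterministic bijection of A. Marginal entropies are
#' computed from the same joint quantization as the joint entropy so the
#' identity is exact.
#'
#' @inheritParams jaccard
#' @return mutual information in bits.
#' @export
mutual_information <- function(a, b, scaling = "joint") {
  check_same_dim(a, b)
  q <- quantize8(a, b, scaling = scaling)
  img_entropy(q$a, quantized = TRUE) + img_entropy(q$b, quantized = TRUE) -
    joint_entropy_q(q$a, q$b)
}

joint_entropy_q <- function(qa, qb) {
  joint <- as.vector(qa) * 256L + as.vector(qb)
  p <- tabulate(joint + 1L, nbins = 256L * 256L)
  p <- p[p > 0] / sum(p)
  -sum(p * log2(p))
}

#' Structural similarity index (mean SSIM)
#'
#' Standard windowed SSIM with an 11 x 11 Gaussian window (sigma = 1.5),
#' stability constants K1 = 0.01, K2 = 0.03 on the pair's joint dynamic
#' range. Returns the mean over all window positions; `ssim(a, a) = 1`.
#'
#' @param a,b image matrices of identical dimension.
#' @return scalar in `[-1, 1]`.
#' @export
ssim <- function(a, b) {
  check_same_dim(a, b)
  rng <- max(a, b) - min(a, b)
  if (rng == 0) return(1)      # two equal constant images
  L <- rng
  c1 <- (0.01 * L)^2; c2 <- (0.03 * L)^2
  g <- stats::dnorm(seq(-5, 5), sd = 1.5)
  g <- g / sum(g)
  blur <- function(x) {
    # separable Gaussian filter, replicate padding
    x <- apply_sep(x, g)
    x
  }
  mu_a <- blur(a); mu_b <- blur(b)
  sa <- blur(a * a) - mu_a^2
  sb <- blur(b * b) - mu_b^2
  sab <- blur(a * b) - mu_a * mu_b
  s <- ((2 * mu_a * mu_b + c1) * (2 * sab + c2)) /
    ((mu_a^2 + mu_b^2 + c1) * (sa + sb + c2))
  mean(s)
}

# separable filter with replicate padding (rows then cols)
apply_sep <- function(x, g) {
  half <- (length(g) - 1) / 2
  pad_idx <- function(n) pmin(pmax(seq(1 - half, n + half), 1), n)
  conv1 <- function(m) {
    # filter along rows of m
    n <- nrow(m)
    mp <- m[pad_idx(n), , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (o in seq_along(g))
      out <- out + g[o] * mp[seq_len(n) + (o - 1), , drop = FALSE]
    out
  }
  t(conv1(t(conv1(x))))
}

#' All pairwise similarity metrics at once
#'
#' Convenience wrapper returning the evaluation suite used for registration
#' diagnostics: MSE, SSIM, multi-class Jaccard, mutual information and the
#' individual and joint entropies.
#'
#' @inheritParams jaccard
#' @return named list `mse`, `ssim`, `jaccard`, `mi`, `h_a`, `h_b`, `h_ab`.
#' @export
similarity_report <- function(a, b, scaling = "joint") {
  q <- quantize8(a, b, scaling = scaling)
  list(mse = mse(a, b),
       ssim = ssim(a, b),
       jaccard = jaccard(a, b, scaling = scaling),
       mi = mutual_information(a, b, scaling = scaling),
       h_a = img_entropy(q$a, quantized = TRUE),
       h_b = img_entropy(q$b, quantized = TRUE),
       h_ab = joint_entropy(a, b, scaling = scaling))
}
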