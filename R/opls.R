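#' Orthogonal projections to latent structures (OPLS)
#'
#' Two-block predictive model separating Y-predictive from Y-orthogonal
#' variation in X: `n_orthogonal` components of structured X variation
#' uncorrelated with Y are removed first, then `n_predictive` PLS
#' components regress the filtered X against Y. X is expected
#' unit-variance scaled (see [center_scale()]); Y is centered internally.
#'
#' @param x n x K predictor matrix (unit-variance scaled), or a
#'   `pixel_matrix`.
#' @param y n x q response matrix (e.g. hyperspectral channels at MSI
#'   resolution), or a `pixel_matrix`.
#' @param n_predictive number of predictive components.
#' @param n_orthogonal number of Y-orthogonal components removed.
#' @return object of class `opls_model`: predictive `weights` (unit
#'   length, per component), `scores`, `x_loadings`, `y_loadings`,
#'   orthogonal `w_ortho`/`t_ortho`/`p_ortho`, `ss_comp` (explained SS of
#'   Y per predictive component), `ss_cum`, `x_center`, `y_center`,
#'   `residual_x`.
#' @export
fit_opls <- function(x, y, n_predictive = 2, n_orthogonal = 1) {
  if (inherits(x, "pixel_matrix")) x <- x$values
  if (inherits(y, "pixel_matrix")) y <- y$values
  x <- as.matrix(x); y <- as.matrix(y)
  if (nrow(x) != nrow(y)) stop("x and y must have the same rows")
  if (n_predictive < 1) stop("need at least one predictive component")
  x_center <- colMeans(x); y_center <- colMeans(y)
  xc <- sweep(x, 2, x_center); yc <- sweep(y, 2, y_center)
  x0 <- xc
  K <- ncol(xc)

  first_weight <- function(xm, ym) {
    s <- crossprod(xm, ym)           # K x q
    w <- svd(s, nu = 1, nv = 0)$u[, 1]
    w / sqrt(sum(w^2))
  }

  # strip Y-orthogonal structured variation
  w_o <- t_o <- p_o <- list()
  for (j in seq_len(n_orthogonal)) {
    w <- first_weight(xc, yc)
    t <- as.vector(xc %*% w)
    p <- as.vector(crossprod(xc, t) / sum(t^2))
    wo <- p - as.vector(crossprod(w, p)) * w
    nwo <- sqrt(sum(wo^2))
    if (nwo < 1e-12) break           # no orthogonal variation left
    wo <- wo / nwo
    to <- as.vector(xc %*% wo)
    po <- as.vector(crossprod(xc, to) / sum(to^2))
    xc <- xc - tcrossprod(to, po)
    w_o[[j]] <- wo; t_o[[j]] <- to; p_o[[j]] <- po
  }

  # NIPALS PLS2 on the filtered X
  W <- T <- P <- C <- list()
  ss_comp <- numeric(0)
  r <- qr(xc)$rank
  if (n_predictive > r) {
    warning(sprintf("predictive components truncated from %d to rank %d",
                    n_predictive, r))
    n_predictive <- r
  }
  for (a in seq_len(n_predictive)) {
    w <- first_weight(xc, yc)
    t <- as.vector(xc %*% w)
    if (sum(t^2) < 1e-20) {
      warning(sprintf("predictive components truncated at %d", a - 1))
      break
    }
    c_ <- as.vector(crossprod(yc, t) / sum(t^2))
    p <- as.vector(crossprod(xc, t) / sum(t^2))
    xc <- xc - tcrossprod(t, p)
    explained <- sum(t^2) * sum(c_^2)
    yc <- yc - tcrossprod(t, c_)
    W[[a]] <- w; T[[a]] <- t; P[[a]] <- p; C[[a]] <- c_
    ss_comp <- c(ss_comp, explained)
  }
  if (!length(W)) stop("no predictive component could be extracted")
  structure(
    list(weights = do.call(cbind, W), scores = do.call(cbind, T),
         x_loadings = do.call(cbind, P), y_loadings = do.call(cbind, C),
         w_ortho = if (length(w_o)) do.call(cbind, w_o) else NULL,
         t_ortho = if (length(t_o)) do.call(cbind, t_o) else NULL,
         p_ortho = if (length(p_o)) do.call(cbind, p_o) else NULL,
         ss_comp = ss_comp, ss_cum = cumsum(ss_comp),
         x_center = x_center, y_center = y_center,
         residual_x = xc, x0 = x0,
         n_predictive = length(W), n_orthogonal = length(w_o),
         var_names = colnames(x)),
    class = "opls_model")
}

#' @export
print.opls_model <- function(x, ...) {
  cat(sprintf("<opls_model> %d predictive + %d orthogonal components over %d variables\n",
              x$n_predictive, x$n_orthogonal, nrow(x$weights)))
  invisible(x)
}

#' Predict responses from a fitted OPLS model
#'
#' @param object an `opls_model`.
#' @param newdata n x K matrix on the same X scale as the training data.
#' @param ... unused.
#' @return n x q matrix of predicted responses.
#' @export
predict.opls_model <- function(object, newdata, ...) {
  xc <- sweep(as.matrix(newdata), 2, object$x_center)
  if (!is.null(object$w_ortho)) {
    for (j in seq_len(ncol(object$w_ortho))) {
      to <- xc %*% object$w_ortho[, j]
      xc <- xc - tcrossprod(to, object$p_ortho[, j])
    }
  }
  W <- object$weights; P <- object$x_loadings; C <- object$y_loadings
  B <- W %*% solve(crossprod(P, W)) %*% t(C)
  sweep(xc %*% B, 2, object$y_center, "+")
}

#' Variable importance in projection (VIP)
#'
#' Per-variable relevance in the predictive part of an OPLS model:
#' `VIP_k = sqrt( K_p * sum_a w_ak^2 * SS_comp_a / SS_cum )` over the
#' `A_p` predictive components, where `K_p` is the number of predictive
#' X variables, the per-component weights `w_a` are normalized to unit
#' length, `SS_comp_a` is the explained sum of squares of component `a`
#' and `SS_cum` the cumulative explained SS. The sum of squares of all
#' VIPs equals the number of terms in the model, hence the average VIP is
#' 1, and variables with VIP > 1 are the most relevant for explaining Y.
#'
#' @param model an `opls_model`.
#' @param threshold selection threshold (default 1).
#' @return object of class `vip_result`: `vip` (nonnegative, named when X
#'   had column names), `selected` (vip > threshold), `threshold`.
#' @export
vip <- function(model, threshold = 1) {
  if (model$n_predictive < 1) stop("model has no predictive component")
  sscum <- model$ss_cum[model$n_predictive]
  if (sscum <= 0) stop("zero cumulative explained sum of squares")
  Kp <- nrow(model$weights)
  w2 <- model$weights^2           # columns already unit length
  v <- sqrt(Kp * as.vector(w2 %*% (model$ss_comp / sscum)))
  names(v) <- model$var_names
  structure(list(vip = v, selected = v > threshold, threshold = threshold),
            class = "vip_result")
}

#' @export
print.vip_result <- function(x, ...) {
  cat(sprintf("<vip_result> %d / %d variables selected at VIP > %g\n",
              sum(x$selected), length(x$vip), x$threshold))
  invisible(x)
}

#' Restrict a pixel matrix to VIP-selected variables
#'
#' @param pm a `pixel_matrix` (columns must match the VIP length).
#' @param vips a [vip()] result.
#' @return the `pixel_matrix` restricted to selected columns, with the
#'   `block_map` subset preserved.
#' @export
select_variables <- function(pm, vips) {
  keep <- which(vips$selected)
  if (length(vips$vip) != ncol(pm$values))
    stop("VIP length does not match pixel-matrix columns")
  if (!length(keep))
    stop("no variable exceeds the VIP threshold ", vips$threshold,
         "; lower the threshold")
  bm <- pm$block_map
  new_bm <- do.call(rbind, lapply(seq_len(nrow(bm)), function(i) {
    cols <- keep[keep >= bm$start[i] & keep <= bm$end[i]]
    if (!length(cols)) return(NULL)
    data.frame(tag = bm$tag[i], n = length(cols),
               stringsAsFactors = FALSE)
  }))
  if (!is.null(new_bm)) {
    ends <- cumsum(new_bm$n)
    new_bm <- data.frame(tag = new_bm$tag,
                         start = c(1L, utils::head(ends, -1) + 1L),
                         end = ends, stringsAsFactors = FALSE)
  }
  out <- pm
  out$values <- pm$values[, keep, drop = FALSE]
  out$variables <- pm$variables[keep]
  out$block_map <- new_bm
  out$selected_columns <- keep
  out
}
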