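#' Assemble registered cubes into a multimodal dataset
#'
#' Crops all registered cubes to their common spatial grid and stacks them
#' as blocks over one shared pixel index. A pixel is treated as black if it
#' is black in any block, which guarantees the assembled matrix has no
#' missing values — the OnPLS algorithm cannot process missing values.
#'
#' @param cubes list of [msi_cube] objects registered into one frame
#'   (equal grids).
#' @return object of class `multimodal_dataset`: `blocks` (list of
#'   n_pixels x n_vars matrices), `partition` (common [pixel_partition]),
#'   `variables`, `tags`, `grid`, `block_map`.
#' @export
assemble_multimodal <- function(cubes) {
  stopifnot(length(cubes) >= 1)
  grids <- vapply(cubes, function(c) dim(c$values)[1:2], integer(2))
  h <- min(grids[1, ]); w <- min(grids[2, ])
  cubes <- lapply(cubes, function(cc) {
    if (cube_height(cc) == h && cube_width(cc) == w) return(cc)
    msi_cube(cc$values[seq_len(h), seq_len(w), , drop = FALSE],
             cc$variables, cc$pixel_size, cc$modality, cc$origin)
  })
  tics <- lapply(cubes, tic_image)
  data_mask <- Reduce("&", lapply(tics, function(tt) tt != 0))
  if (!any(data_mask)) stop("empty common data-pixel intersection across blocks")
  masked <- lapply(cubes, function(cc) {
    vals <- sweep(cc$values, c(1, 2), data_mask + 0, "*")
    msi_cube(vals, cc$variables, cc$pixel_size, cc$modality, cc$origin)
  })
  part <- partition_pixels(masked[[1]])
  blocks <- lapply(masked, function(cc) to_pixel_matrix(cc, part)$values)
  widths <- vapply(blocks, ncol, integer(1))
  ends <- cumsum(widths)
  structure(
    list(blocks = blocks,
         partition = part,
         variables = lapply(cubes, function(c) c$variables),
         tags = vapply(cubes, function(c) c$modality, character(1)),
         grid = c(h, w),
         block_map = data.frame(
           tag = vapply(cubes, function(c) c$modality, character(1)),
           start = c(1L, utils::head(ends, -1) + 1L), end = ends,
           stringsAsFactors = FALSE),
         preprocessing = NULL),
    class = "multimodal_dataset")
}

#' @export
print.multimodal_dataset <- function(x, ...) {
  cat(sprintf("<multimodal_dataset> %d blocks (%s), %d shared data pixels\n",
              length(x$blocks), paste(x$tags, collapse = ", "),
              nrow(x$blocks[[1]])))
  invisible(x)
}

#' Concatenate the blocks of a multimodal dataset into one pixel matrix
#'
#' Columns of the blocks are joined side by side over the shared pixel
#' index; the `block_map` records the contiguous, non-overlapping column
#' range contributed by each modality.
#'
#' @param dataset a `multimodal_dataset`.
#' @return a `pixel_matrix` spanning all blocks.
#' @export
concat_blocks <- function(dataset) {
  vals <- do.call(cbind, dataset$blocks)
  structure(
    list(values = vals,
         coords = dataset$partition$data_pixels,
         grid = dataset$partition$grid,
         variables = unlist(dataset$variables),
         block_map = dataset$block_map),
    class = "pixel_matrix")
}

#' Column-wise centering / scaling of a multimodal dataset
#'
#' Mean-centering is used for descriptive data mining (PCA, OnPLS); unit
#' variance scaling (which includes centering) for predictive modeling
#' (OPLS with hyperspectral channels). Transform parameters are stored per
#' block so the operation is invertible; zero-variance columns under
#' `unit_variance` are flagged and left centered only.
#'
#' @param dataset a `multimodal_dataset`.
#' @param mode `"mean_center"` or `"unit_variance"`.
#' @return the dataset with transformed blocks and a `preprocessing`
#'   record.
#' @export
center_scale <- function(dataset, mode = c("mean_center", "unit_variance")) {
  mode <- match.arg(mode)
  if (nrow(dataset$blocks[[1]]) < 2) stop("need at least 2 rows")
  prep <- vector("list", length(dataset$blocks))
  for (b in seq_along(dataset$blocks)) {
    x <- dataset$blocks[[b]]
    mu <- colMeans(x)
    x <- sweep(x, 2, mu)
    sdv <- rep(1, ncol(x))
    flagged <- logical(ncol(x))
    if (mode == "unit_variance") {
      sdv <- apply(x, 2, stats::sd)
      flagged <- sdv == 0
      sdv[flagged] <- 1
      x <- sweep(x, 2, sdv, "/")
    }
    dataset$blocks[[b]] <- x
    prep[[b]] <- list(center = mu, scale = sdv, zero_variance = flagged,
                      mode = mode)
  }
  dataset$preprocessing <- prep
  dataset
}

#' Invert [center_scale()]
#' @param dataset a centered/scaled `multimodal_dataset`.
#' @return the dataset on its original intensity scale.
#' @export
inverse_center_scale <- function(dataset) {
  if (is.null(dataset$preprocessing)) return(dataset)
  for (b in seq_along(dataset$blocks)) {
    p <- dataset$preprocessing[[b]]
    x <- sweep(dataset$blocks[[b]], 2, p$scale, "*")
    dataset$blocks[[b]] <- sweep(x, 2, p$center, "+")
  }
  dataset$preprocessing <- NULL
  dataset
}

#' Principal component analysis of a block or dataset
#'
#' SVD-based PCA with a deterministic sign convention (largest-magnitude
#' loading positive per component). The input is expected centered.
#'
#' @param x numeric matrix, or a `multimodal_dataset` (blocks are
#'   concatenated).
#' @param n_components number of components.
#' @return list `scores`, `loadings`, `explained_variance` (fractions,
#'   non-increasing).
#' @export
fit_pca <- function(x, n_components = 2) {
  if (inherits(x, "multimodal_dataset")) x <- do.call(cbind, x$blocks)
  r <- min(dim(x))
  if (n_components > r) {
    warning(sprintf("n_components truncated from %d to rank bound %d",
                    n_components, r))
    n_components <- r
  }
  sv <- svd(x, nu = n_components, nv = n_components)
  flip <- vapply(seq_len(n_components), function(j)
    sign(sv$v[which.max(abs(sv$v[, j])), j]), numeric(1))
  flip[flip == 0] <- 1
  scores <- sweep(sv$u, 2, sv$d[seq_len(n_components)] * flip, "*")
  loadings <- sweep(sv$v, 2, flip, "*")
  list(scores = scores, loadings = loadings,
       explained_variance = (sv$d^2 / sum(sv$d^2))[seq_len(n_components)])
}

# one consensus component across the given blocks.
#
# For two blocks this is the dominant direction of the cross-block
# covariance X1'X2, refined by the Horst iteration (each block's weight is
# driven only by the other blocks' scores, so variance unique to one block
# cannot self-reinforce into the joint part).
#
# For three or more blocks, maximizing the plain sum of pairwise score
# covariances would let structure shared by only one pair of blocks leak
# into the "all blocks" component; instead the weight of block i is
# required to lie in EVERY cross-covariance subspace span(X_i'X_j): it is
# the top eigenvector of the summed subspace projectors, whose eigenvalue
# approaches B-1 exactly when a common direction exists. `r_cross` bounds
# the rank of each cross-covariance subspace (the number of structured
# shared directions assumed per block pair).
#
# Returns per-block scores (n x B) and unit weights; NULL when degenerate.
consensus_component <- function(blocks, tol = 1e-10, max_iter = 500,
                                r_cross = 5) {
  B <- length(blocks)
  norms <- vapply(blocks, function(x) sqrt(sum(x^2)), numeric(1))
  if (any(norms < 1e-12)) return(NULL)
  ws <- vector("list", B)
  if (B == 2) {
    ws[[1]] <- svd(crossprod(blocks[[1]], blocks[[2]]), nu = 1, nv = 0)$u[, 1]
    ws[[2]] <- as.vector(crossprod(blocks[[2]],
                                   blocks[[1]] %*% ws[[1]]))
    ws <- lapply(ws, function(w) w / sqrt(sum(w^2)))
    ts <- mapply(function(x, w) as.vector(x %*% w), blocks, ws,
                 SIMPLIFY = FALSE)
    for (it in seq_len(max_iter)) {
      delta <- 0
      for (i in 1:2) {
        w <- as.vector(crossprod(blocks[[i]], ts[[3 - i]]))
        nw <- sqrt(sum(w^2))
        if (nw < 1e-12) return(NULL)
        w <- w / nw
        delta <- max(delta, max(abs(w - ws[[i]])))
        ws[[i]] <- w
        ts[[i]] <- as.vector(blocks[[i]] %*% w)
      }
      if (delta < tol) break
    }
  } else {
    for (i in seq_len(B)) {
      proj_sum <- 0
      for (j in setdiff(seq_len(B), i)) {
        cc <- crossprod(blocks[[i]], blocks[[j]])
        sv <- svd(cc, nu = min(r_cross, min(dim(cc))), nv = 0)
        # keep only directions whose singular values stand out above the
        # bulk (structured shared covariance); without this, random
        # subspace overlap in narrow blocks manufactures joint structure
        # from independent noise
        d_all <- svd(cc, nu = 0, nv = 0)$d
        r <- max(1, sum(sv$d[seq_len(ncol(sv$u))] >
                          2 * stats::median(d_all)))
        r <- min(r, ncol(sv$u))
        v <- sv$u[, seq_len(r), drop = FALSE]
        proj_sum <- proj_sum + tcrossprod(v)
      }
      w <- eigen(proj_sum, symmetric = TRUE)$vectors[, 1]
      ws[[i]] <- w / sqrt(sum(w^2))
    }
    ts <- mapply(function(x, w) as.vector(x %*% w), blocks, ws,
                 SIMPLIFY = FALSE)
    # align score signs to block 1 so the consensus is coherent
    for (i in 2:B) {
      if (sum(ts[[i]] * ts[[1]]) < 0) {
        ws[[i]] <- -ws[[i]]; ts[[i]] <- -ts[[i]]
      }
    }
  }
  # deterministic sign: largest-|weight| entry of block 1 positive
  w1 <- ws[[1]]
  s <- sign(w1[which.max(abs(w1))])
  if (s == 0) s <- 1
  ts <- lapply(ts, function(t) s * t)
  # one consensus score per component: dominant direction of the
  # normalized per-block scores. Deflating against this single direction
  # (rather than the pooled span of all per-block scores) matters: the
  # per-block scores are nearly collinear, so orthonormalizing their span
  # would amplify their small block-specific admixtures into full extra
  # directions and silently strip locally joint / unique variance.
  tn <- do.call(cbind, lapply(ts, function(t) t / sqrt(sum(t^2))))
  u <- svd(tn, nu = 1, nv = 0)$u[, 1]
  if (sum(u * tn[, 1]) < 0) u <- -u
  list(scores = do.call(cbind, ts),
       weights = lapply(ws, function(w) s * w),
       consensus = u)
}

# project the columns of each listed block onto the orthogonal complement
# of the consensus score direction(s); returns the projections (the
# extracted "part") and the deflated blocks
deflate_against <- function(blocks, consensus) {
  Q <- qr.Q(qr(as.matrix(consensus)))
  parts <- lapply(blocks, function(x) Q %*% crossprod(Q, x))
  deflated <- mapply(function(x, p) x - p, blocks, parts, SIMPLIFY = FALSE)
  list(parts = parts, deflated = deflated)
}

# orthogonalize a candidate deflation direction against the directions a
# block has already been deflated with; NULL when nothing new remains
ortho_direction <- function(u, used) {
  if (!is.null(used)) u <- u - used %*% crossprod(used, u)
  n <- sqrt(sum(u^2))
  if (n < 1e-10) return(NULL)
  u / n
}

# leave-one-out consensus: the normalized sum of the OTHER blocks'
# normalized scores. Deflating block b against this direction (instead of
# a consensus containing its own score) means a block cannot certify its
# own variance as joint: for independent noise blocks the direction is
# random with respect to the block and the joint share collapses to
# chance level ~1/n.
loo_consensus <- function(scores, b) {
  tn <- sweep(scores, 2, sqrt(colSums(scores^2)), "/")
  u <- rowSums(tn[, -b, drop = FALSE])
  u / sqrt(sum(u^2))
}

#' Multiblock OnPLS decomposition
#'
#' Partitions the total variation of each centered block into globally
#' joint (shared by all blocks), locally joint (shared by a stated subset
#' of blocks), unique (one block) and residual parts, by sequential
#' deflation:
#'
#' 1. each globally joint component is a consensus direction maximizing
#'    shared covariance among all blocks (subspace-intersection criterion
#'    over the cross-block covariances); each block is then deflated
#'    against the leave-one-out consensus of the other blocks' scores, so
#'    a block can never certify its own variance as joint — independent
#'    noise yields joint shares at chance level;
#' 2. locally joint components repeat the consensus extraction on the
#'    deflated blocks of each requested subset, deflating those blocks
#'    only;
#' 3. unique components are the dominant principal directions of what
#'    remains in each block; they are exactly orthogonal to every joint
#'    deflation direction of that block.
#'
#' The per-block sum of the four parts reconstructs the centered block
#' exactly, and the per-block deflation directions are orthonormalized so
#' the parts are mutually orthogonal and their variance shares additive.
#'
#' @param dataset a centered `multimodal_dataset` with >= 2 blocks.
#' @param n_global number of globally joint components.
#' @param n_local named list: names are comma-separated block indices
#'   (e.g. `"1,2"`), values component counts for that subset.
#' @param n_unique integer vector of per-block unique component counts
#'   (recycled).
#' @return object of class `onpls_model` with `global` (scores: n x B per
#'   component, weights), `local`, `unique`, `parts` (per block: global /
#'   local / unique part matrices and residual), `variance_shares`,
#'   `partition`, `block_map`.
#' @export
fit_onpls <- function(dataset, n_global = 1,
                      n_local = list(), n_unique = 1) {
  blocks <- dataset$blocks
  B <- length(blocks)
  if (B < 2) stop("OnPLS needs at least 2 blocks")
  if (any(vapply(blocks, function(x) any(is.na(x)), logical(1))))
    stop("the OnPLS algorithm cannot process missing values")
  centered_ok <- all(vapply(blocks, function(x)
    max(abs(colMeans(x))) < 1e-6, logical(1)))
  if (!centered_ok)
    stop("dataset must be mean-centered (see center_scale)")
  n_unique <- rep_len(n_unique, B)
  X0 <- blocks
  work <- blocks
  zero_part <- lapply(blocks, function(x) x * 0)
  global_parts <- zero_part
  local_parts <- zero_part
  unique_parts <- zero_part
  global_comps <- list()
  local_comps <- list()
  unique_comps <- replicate(B, list(), simplify = FALSE)

  used <- vector("list", B)   # per-block orthonormal deflation directions

  # deflate block `bi` (index into `work`) against the leave-one-out
  # consensus of the component's scores; returns the removed part
  deflate_block <- function(bi, u) {
    d <- ortho_direction(u, used[[bi]])
    if (is.null(d)) return(NULL)
    part <- d %*% crossprod(d, work[[bi]])
    work[[bi]] <<- work[[bi]] - part
    used[[bi]] <<- cbind(used[[bi]], d)
    part
  }

  for (g in seq_len(n_global)) {
    cc <- consensus_component(work)
    if (is.null(cc)) {
      warning(sprintf("global components truncated at %d (rank exhausted)", g - 1))
      break
    }
    for (b in seq_len(B)) {
      part <- deflate_block(b, loo_consensus(cc$scores, b))
      if (!is.null(part)) global_parts[[b]] <- global_parts[[b]] + part
    }
    global_comps[[g]] <- cc
  }

  for (nm in names(n_local)) {
    subset <- as.integer(strsplit(nm, ",")[[1]])
    if (length(subset) < 2 || any(subset < 1 | subset > B))
      stop("local subset '", nm, "' must name >= 2 valid block indices")
    for (l in seq_len(n_local[[nm]])) {
      cc <- consensus_component(work[subset])
      if (is.null(cc)) {
        warning(sprintf("local components for subset %s truncated at %d",
                        nm, l - 1))
        break
      }
      for (j in seq_along(subset)) {
        part <- deflate_block(subset[j], loo_consensus(cc$scores, j))
        if (!is.null(part))
          local_parts[[subset[j]]] <- local_parts[[subset[j]]] + part
      }
      cc$subset <- subset
      local_comps[[length(local_comps) + 1L]] <- cc
    }
  }

  for (b in seq_len(B)) {
    if (n_unique[b] == 0) next
    r <- min(dim(work[[b]]))
    nu <- min(n_unique[b], r)
    if (nu < n_unique[b])
      warning(sprintf("unique components of block %d truncated to %d", b, nu))
    if (nu == 0 || sum(work[[b]]^2) < 1e-20) next
    pc <- fit_pca(work[[b]], nu)
    part <- pc$scores %*% t(pc$loadings)
    unique_parts[[b]] <- unique_parts[[b]] + part
    work[[b]] <- work[[b]] - part
    unique_comps[[b]] <- pc
  }

  parts <- lapply(seq_len(B), function(b)
    list(global = global_parts[[b]], local = local_parts[[b]],
         unique = unique_parts[[b]], residual = work[[b]]))
  variance_shares <- lapply(seq_len(B), function(b) {
    tot <- sum(X0[[b]]^2)
    if (tot == 0) tot <- 1
    c(global = sum(global_parts[[b]]^2) / tot,
      local = sum(local_parts[[b]]^2) / tot,
      unique = sum(unique_parts[[b]]^2) / tot,
      residual = sum(work[[b]]^2) / tot)
  })
  structure(
    list(global = global_comps, local = local_comps, unique = unique_comps,
         joint_directions = used,
         parts = parts, variance_shares = variance_shares,
         component_counts = list(global = length(global_comps),
                                 local = length(local_comps),
                                 unique = vapply(unique_comps, function(u)
                                   if (length(u)) ncol(u$scores) else 0L,
                                   integer(1))),
         partition = dataset$partition, tags = dataset$tags,
         block_map = dataset$block_map),
    class = "onpls_model")
}

#' @export
print.onpls_model <- function(x, ...) {
  cc <- x$component_counts
  cat(sprintf("<onpls_model> %d blocks: %d global, %d local, unique (%s)\n",
              length(x$parts), cc$global, cc$local,
              paste(cc$unique, collapse = ",")))
  for (b in seq_along(x$variance_shares)) {
    v <- x$variance_shares[[b]]
    cat(sprintf("  block %d (%s): global %.1f%%, local %.1f%%, unique %.1f%%, residual %.1f%%\n",
                b, x$tags[b], 100 * v["global"], 100 * v["local"],
                100 * v["unique"], 100 * v["residual"]))
  }
  invisible(x)
}

#' Score images of an OnPLS model
#'
#' Restores the requested component's per-block score vectors to the pixel
#' grid (black pixels reinstated at `background`).
#'
#' @param model an `onpls_model`.
#' @param part `"global"`, `"local"` or `"unique"`.
#' @param component component index within the part.
#' @param block for `"unique"`, which block; for joint parts all member
#'   blocks are returned.
#' @param background sentinel for black pixels.
#' @return list of score-image matrices (one per member block).
#' @export
onpls_score_images <- function(model, part = c("global", "local", "unique"),
                               component = 1, block = 1, background = 0) {
  part <- match.arg(part)
  if (part == "unique") {
    u <- model$unique[[block]]
    if (!length(u)) stop("block has no unique components")
    return(list(restore_score_image(u$scores[, component],
                                    model$partition, background)))
  }
  comp <- if (part == "global") model$global[[component]]
          else model$local[[component]]
  lapply(seq_len(ncol(comp$scores)), function(j)
    restore_score_image(comp$scores[, j], model$partition, background))
}

#' Advisory component count by seven-fold venetian-blind cross-validation
#'
#' Rows are split into 7 interleaved folds by row order. For each candidate
#' count k, PCA loadings are fitted on the training folds and every
#' held-out matrix element (i, j) is predicted from the other columns of
#' its own row (leave-one-column-out projection through the k-component
#' loading space) — projecting held-out rows onto the loadings directly
#' would reduce the residual for any loadings, including noise, so that
#' naive Q^2 grows with every added component. The elementwise scheme gives
#' Q^2 = 1 - PRESS/SS against the train-mean baseline; the recommended
#' count is the largest that still improves Q^2 by more than 1 percentage
#' point (absolute); pure noise recommends 0.
#'
#' @param dataset a centered `multimodal_dataset` (blocks concatenated) or
#'   numeric matrix.
#' @param candidate_counts integer vector of counts to evaluate.
#' @param n_folds number of interleaved folds (default 7).
#' @return list `recommended`, `q2` (named by count).
#' @export
cross_validate_components <- function(dataset, candidate_counts = 1:5,
                                      n_folds = 7) {
  x <- if (inherits(dataset, "multimodal_dataset"))
    do.call(cbind, dataset$blocks) else dataset
  n <- nrow(x)
  p <- ncol(x)
  if (n < 2 * n_folds) stop("need at least ", 2 * n_folds, " rows")
  folds <- rep_len(seq_len(n_folds), n)
  # the zero-component (train-mean) model is the Q^2 baseline
  candidate_counts <- sort(unique(c(0L, candidate_counts)))
  if (max(candidate_counts) > p - 1)
    stop("candidate counts must stay below ncol - 1")
  press <- stats::setNames(numeric(length(candidate_counts)),
                           candidate_counts)
  ss <- 0
  for (ci in seq_along(candidate_counts)) {
    k <- candidate_counts[ci]
    tot <- 0
    for (f in seq_len(n_folds)) {
      train <- x[folds != f, , drop = FALSE]
      test <- x[folds == f, , drop = FALSE]
      mu <- colMeans(train)
      tc <- sweep(test, 2, mu)
      if (ci == 1) ss <- ss + sum(tc^2)
      if (k == 0) {
        tot <- tot + sum(tc^2)     # train-mean model
        next
      }
      v <- svd(sweep(train, 2, mu), nu = 0, nv = k)$v
      for (j in seq_len(p)) {
        vj <- v[-j, , drop = FALSE]
        # scores from the other columns, then predict column j
        sc <- tc[, -j, drop = FALSE] %*%
          (vj %*% solve(crossprod(vj) + 1e-12 * diag(k)))
        tot <- tot + sum((tc[, j] - sc %*% v[j, ])^2)
      }
    }
    press[ci] <- tot
  }
  q2 <- 1 - press / ss
  rec <- 0
  prev <- q2[1]                     # baseline: 0 components
  for (ci in seq_along(candidate_counts)[-1]) {
    if (q2[ci] - prev > 0.01) {
      rec <- candidate_counts[ci]
      prev <- q2[ci]
    } else break
  }
  list(recommended = rec, q2 = q2)
}
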