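#' Resample an open curve at equal arc-length spacing
#'
#' Places `n` points along a piecewise-linear curve so that consecutive
#' points are separated by equal arc length; the first and last output
#' points coincide with the curve endpoints (which anchor to the adjacent
#' fixed landmarks when building an entheseal configuration).
#'
#' @param curve ordered numeric matrix (>= 2 x 3) of curve points.
#' @param n number of output points (>= 2).
#' @return an n x 3 matrix.
#' @export
resample_equidistant <- function(curve, n = 30) {
  curve <- as.matrix(curve)
  stopifnot(nrow(curve) >= 2, ncol(curve) == 3, n >= 2)
  seg <- sqrt(rowSums(diff(curve)^2))
  L <- sum(seg)
  if (L <= 0) stop("zero-length curve")
  s <- c(0, cumsum(seg))
  targets <- seq(0, L, length.out = n)
  out <- matrix(0, n, 3)
  for (k in seq_len(n)) {
    t <- targets[k]
    idx <- findInterval(t, s, rightmost.closed = TRUE)
    idx <- min(max(idx, 1L), length(seg))
    w <- if (seg[idx] > 0) (t - s[idx]) / seg[idx] else 0
    out[k, ] <- (1 - w) * curve[idx, ] + w * curve[idx + 1, ]
  }
  out[1, ] <- curve[1, ]
  out[n, ] <- curve[nrow(curve), ]
  out
}

#' Entheseal landmark configuration
#'
#' Builds the 36-point configuration quantifying the metacarpal insertion
#' enthesis of m. opponens pollicis: six geometrically defined fixed
#' landmarks on the entheseal outline (the four most extreme borders plus
#' the two outline angles) and 30 equidistant sliding semilandmarks
#' resampled from the outline segments between consecutive fixed
#' landmarks.
#'
#' @param specimen_id identifier.
#' @param fixed 6 x 3 matrix of fixed landmarks (rownames `F1`-`F6`),
#'   ordered along the outline.
#' @param curves list of 6 ordered point matrices, curve `k` running from
#'   fixed landmark `k` to fixed landmark `k %% 6 + 1`.
#' @param allocation integer vector: semilandmarks per segment (sums to
#'   `n_semi`; default 5 per segment).
#' @param n_semi total number of semilandmarks (default 30).
#' @return object of class `entheseal_config`: `points` (36 x 3),
#'   `fixed_idx`, `semi_idx`, `topology` (per-semilandmark previous/next
#'   neighbour indices along the outline), `specimen_id`.
#' @export
entheseal_config <- function(specimen_id, fixed, curves,
                             allocation = NULL, n_semi = 30) {
  fixed <- as.matrix(fixed)
  stopifnot(nrow(fixed) == 6, ncol(fixed) == 3, length(curves) == 6)
  if (is.null(rownames(fixed))) rownames(fixed) <- paste0("F", 1:6)
  if (anyDuplicated(fixed) > 0) stop("fixed landmarks must be distinct")
  if (is.null(allocation)) {
    base <- n_semi %/% 6
    allocation <- rep(base, 6)
    extra <- n_semi - sum(allocation)
    if (extra > 0) allocation[seq_len(extra)] <- allocation[seq_len(extra)] + 1
  }
  stopifnot(sum(allocation) == n_semi)
  semis <- list(); topo <- list()
  idx0 <- 6L
  for (k in 1:6) {
    nk <- allocation[k]
    if (nk == 0) next
    a <- k; b <- k %% 6 + 1
    curve <- rbind(fixed[a, ], as.matrix(curves[[k]]), fixed[b, ])
    rs <- resample_equidistant(curve, nk + 2)
    pts <- rs[2:(nk + 1), , drop = FALSE]
    semis[[k]] <- pts
    ids <- idx0 + seq_len(nk)
    for (m in seq_len(nk)) {
      prev <- if (m == 1) a else ids[m - 1]
      nxt <- if (m == nk) b else ids[m + 1]
      topo[[length(topo) + 1L]] <- c(prev = prev, self = ids[m], next_ = nxt)
    }
    idx0 <- idx0 + nk
  }
  semi <- do.call(rbind, semis)
  rownames(semi) <- paste0("S", seq_len(nrow(semi)))
  pts <- rbind(fixed, semi)
  structure(list(specimen_id = specimen_id, points = pts,
                 fixed_idx = 1:6, semi_idx = 6 + seq_len(nrow(semi)),
                 topology = do.call(rbind, topo)),
            class = "entheseal_config")
}

#' @export
print.entheseal_config <- function(x, ...) {
  cat(sprintf("<entheseal_config> %s: %d fixed + %d semilandmarks\n",
              x$specimen_id, length(x$fixed_idx), length(x$semi_idx)))
  invisible(x)
}

# Center and scale one configuration to unit centroid size.
gpa_normalize <- function(X) {
  X <- sweep(X, 2, colMeans(X))
  X / centroid_size(X)
}

#' Generalized Procrustes superimposition
#'
#' Removes translation, scale and rotation from a set of landmark
#' configurations: each configuration is centred and scaled to unit
#' centroid size, mirrored (left) configurations are reflected to the
#' chirality of the first configuration, and all are iteratively rotated
#' onto the evolving mean shape until the mean changes by less than `tol`.
#' Reflection is never part of the rotational fit itself.
#'
#' @param configs list of k x 3 landmark matrices (equal k, matched
#'   ordering), or of [entheseal_config()] objects.
#' @param tol convergence tolerance on the mean shape (default 1e-8).
#' @param max_iter iteration cap (default 100).
#' @return list of class `gpa_fit`: `aligned` (list of k x 3 matrices),
#'   `mean_shape`, `centroid_sizes`, `reflected` (logical per config),
#'   `iterations`.
#' @export
generalized_procrustes <- function(configs, tol = 1e-8, max_iter = 100) {
  mats <- lapply(configs, function(cf)
    if (inherits(cf, "entheseal_config")) cf$points else as.matrix(cf))
  k <- unique(vapply(mats, nrow, integer(1)))
  if (length(mats) < 2) stop("need at least 2 configurations")
  if (length(k) != 1) stop("configurations must have equal landmark counts")
  sizes <- vapply(mats, centroid_size, numeric(1))
  if (any(sizes <= 0)) stop("degenerate (zero-size) configuration")
  norm <- lapply(mats, gpa_normalize)

  # common chirality: reflect configs whose full orthogonal fit to the
  # first configuration is a reflection
  reflected <- logical(length(norm))
  ref <- norm[[1]]
  for (i in seq_along(norm)) {
    H <- crossprod(norm[[i]], ref)
    sv <- svd(H)
    if (det(sv$u %*% t(sv$v)) < 0) {
      norm[[i]][, 1] <- -norm[[i]][, 1]
      reflected[i] <- TRUE
    }
  }

  mshape <- gpa_normalize(Reduce(`+`, norm) / length(norm))
  iters <- 0L
  repeat {
    iters <- iters + 1L
    aligned <- lapply(norm, function(X) X %*% kabsch_rotation(X, mshape))
    new_mean <- gpa_normalize(Reduce(`+`, aligned) / length(aligned))
    delta <- sqrt(sum((new_mean - mshape)^2))
    mshape <- new_mean
    norm <- aligned
    if (delta < tol || iters >= max_iter) break
  }
  structure(list(aligned = norm, mean_shape = mshape,
                 centroid_sizes = sizes, reflected = reflected,
                 iterations = iters),
            class = "gpa_fit")
}

# Sum of squared Procrustes distances of aligned configs to their mean.
gpa_objective <- function(aligned, mshape = NULL) {
  if (is.null(mshape)) mshape <- Reduce(`+`, aligned) / length(aligned)
  sum(vapply(aligned, function(X) sum((X - mshape)^2), numeric(1)))
}

#' Slide semilandmarks to minimize Procrustes distance
#'
#' Displaces each semilandmark along its local outline tangent (central
#' difference between its outline neighbours) toward the mean shape,
#' re-superimposes after every pass, and iterates until the summed squared
#' Procrustes distance to the mean stabilizes. This is the minimum
#' Procrustes distance sliding criterion.
#'
#' @param fit a [generalized_procrustes()] result.
#' @param fixed_idx indices of fixed landmarks (not slid).
#' @param topology matrix with columns `prev`, `self`, `next_` giving each
#'   semilandmark's outline neighbours (as from [entheseal_config()]).
#' @param max_iter sliding passes (default 10).
#' @param tol convergence tolerance on the objective (default 1e-6).
#' @return updated `gpa_fit` with elements `objective_trace` and
#'   `slid = TRUE`; warns if not converged within `max_iter`.
#' @export
slide_semilandmarks <- function(fit, fixed_idx, topology,
                                max_iter = 10, tol = 1e-6) {
  stopifnot(inherits(fit, "gpa_fit"))
  aligned <- fit$aligned
  mshape <- fit$mean_shape
  trace <- gpa_objective(aligned, mshape)
  for (it in seq_len(max_iter)) {
    for (i in seq_along(aligned)) {
      X <- aligned[[i]]
      for (r in seq_len(nrow(topology))) {
        s <- topology[r, "self"]
        tg <- X[topology[r, "next_"], ] - X[topology[r, "prev"], ]
        tn <- vec_norm(tg)
        if (tn == 0) next
        tg <- tg / tn
        X[s, ] <- X[s, ] + tg * sum(tg * (mshape[s, ] - X[s, ]))
      }
      aligned[[i]] <- X
    }
    # re-superimpose the slid configurations
    refit <- generalized_procrustes(aligned, tol = 1e-10)
    aligned <- refit$aligned
    mshape <- refit$mean_shape
    obj <- gpa_objective(aligned, mshape)
    trace <- c(trace, obj)
    if (abs(trace[length(trace) - 1] - obj) < tol) break
  }
  if (length(trace) == max_iter + 1 &&
      abs(diff(utils::tail(trace, 2))) >= tol)
    warning(sprintf("sliding not converged: final delta %.3g",
                    abs(diff(utils::tail(trace, 2)))))
  fit$aligned <- aligned
  fit$mean_shape <- mshape
  fit$objective_trace <- trace
  fit$slid <- TRUE
  fit
}

#' Shape principal component analysis
#'
#' PCA of the flattened Procrustes-aligned coordinates (covariance-based).
#' PC1 can be oriented so that a reference group's mean score is positive
#' via `positive_ids` (the convention here: higher entheseal bone
#' projection scores positive).
#'
#' @param fit a [generalized_procrustes()] (optionally slid) result.
#' @param ids optional specimen identifiers (default names or indices).
#' @param positive_ids ids whose mean PC1 score is made positive.
#' @return list of class `shape_pca`: `scores`, `eigenvalues`,
#'   `variance_fractions`, `loadings`, `mean_flat`, `ids`, `sign_convention`.
#' @export
shape_pca <- function(fit, ids = NULL, positive_ids = NULL) {
  stopifnot(inherits(fit, "gpa_fit"))
  n <- length(fit$aligned)
  if (n < 3) stop("shape PCA needs at least 3 specimens")
  if (is.null(ids)) ids <- names(fit$aligned)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  X <- t(vapply(fit$aligned, function(m) as.numeric(t(m)),
                numeric(3 * nrow(fit$aligned[[1]]))))
  mean_flat <- colMeans(X)
  Xc <- sweep(X, 2, mean_flat)
  sv <- svd(Xc)
  eig <- sv$d^2 / (n - 1)
  scores <- Xc %*% sv$v
  loadings <- sv$v
  tot <- sum(eig)
  sign_tag <- "unoriented"
  if (!is.null(positive_ids)) {
    sel <- ids %in% positive_ids
    if (any(sel) && mean(scores[sel, 1]) < 0) {
      scores[, 1] <- -scores[, 1]
      loadings[, 1] <- -loadings[, 1]
    }
    sign_tag <- "PC1 positive for reference group"
  }
  rownames(scores) <- ids
  structure(list(scores = scores, eigenvalues = eig,
                 variance_fractions = if (tot > 0) eig / tot else eig,
                 loadings = loadings, mean_flat = mean_flat,
                 ids = ids, sign_convention = sign_tag),
            class = "shape_pca")
}

#' Project a new configuration into a fitted shape space
#'
#' Aligns a held-out configuration to the fitted mean shape (centring,
#' unit-centroid-size scaling, chirality correction, rotation-only
#' Procrustes fit, and optionally tangent sliding against the fixed mean)
#' and projects its centred coordinates onto the loading vectors.
#'
#' @param model a [shape_pca()] result.
#' @param fit the [generalized_procrustes()] fit the model came from
#'   (provides the mean shape).
#' @param new_config k x 3 matrix or [entheseal_config()].
#' @param topology optional slider topology for sliding against the mean.
#' @param slide_iter sliding passes (default 3; 0 disables sliding).
#' @param normalize centre and scale the configuration to unit centroid
#'   size before alignment (default `TRUE`; set `FALSE` for inputs already
#'   in the fitted shape space, such as the PCA centre itself).
#' @return numeric vector of scores on all components.
#' @export
project_shape <- function(model, fit, new_config, topology = NULL,
                          slide_iter = 3, normalize = TRUE) {
  stopifnot(inherits(model, "shape_pca"), inherits(fit, "gpa_fit"))
  X <- if (inherits(new_config, "entheseal_config")) new_config$points
       else as.matrix(new_config)
  if (nrow(X) != nrow(fit$mean_shape))
    stop("configuration has mismatched landmark count")
  mshape <- fit$mean_shape
  if (normalize) X <- gpa_normalize(X)
  H <- crossprod(X, mshape)
  sv <- svd(H)
  if (det(sv$u %*% t(sv$v)) < 0) X[, 1] <- -X[, 1]
  X <- X %*% kabsch_rotation(X, mshape)
  if (!is.null(topology) && slide_iter > 0) {
    for (it in seq_len(slide_iter)) {
      for (r in seq_len(nrow(topology))) {
        s <- topology[r, "self"]
        tg <- X[topology[r, "next_"], ] - X[topology[r, "prev"], ]
        tn <- vec_norm(tg)
        if (tn == 0) next
        tg <- tg / tn
        X[s, ] <- X[s, ] + tg * sum(tg * (mshape[s, ] - X[s, ]))
      }
      X <- gpa_normalize(X)
      X <- X %*% kabsch_rotation(X, mshape)
    }
  }
  flat <- as.numeric(t(X)) - model$mean_flat
  drop(flat %*% model$loadings)
}
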