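test_that("equidistant resampling spaces points evenly and anchors the endpoints", {
  seg <- cbind(seq(0, 29, length.out = 30), 0, 0)
  rs <- resample_equidistant(seg, 30)
  expect_equal(diff(rs[, 1]), rep(1, 29), tolerance = 1e-12)
  expect_equal(rs[1, ], seg[1, ])
  expect_equal(rs[30, ], seg[30, ])
  # densely sampled semicircle: equal arc-length gaps
  th <- seq(0, pi, length.out = 2000)
  semi <- cbind(cos(th), sin(th), 0)
  rs2 <- resample_equidistant(semi, 30)
  gaps <- sqrt(rowSums(diff(rs2)^2))
  expect_lt(diff(range(gaps)) / mean(gaps), 1e-5)
  expect_error(resample_equidistant(rbind(c(0, 0, 0), c(0, 0, 0)), 5),
               "zero-length")
})

test_that("the entheseal configuration holds 6 fixed plus 30 sliding semilandmarks", {
  cfg <- toy_entheseal()
  expect_identical(nrow(cfg$points), 36L)
  expect_identical(length(cfg$semi_idx), 30L)
  expect_identical(nrow(cfg$topology), 30L)
  # every semilandmark's neighbours are valid indices along the outline
  expect_true(all(cfg$topology >= 1 & cfg$topology <= 36))
})

test_that("Procrustes superimposition removes rigid motion and scale", {
  A <- toy_entheseal(proj = 1.5, noise = 0.1, seed = 1)$points
  g0 <- generalized_procrustes(list(A, A))
  expect_equal(sum((g0$aligned[[1]] - g0$aligned[[2]])^2), 0, tolerance = 1e-18)
  set.seed(2)
  R <- rand_rotation(); tv <- rnorm(3, 0, 10)
  B <- sweep(2.3 * A %*% t(R), 2, tv, `+`)
  g1 <- generalized_procrustes(list(A, B))
  expect_equal(sum((g1$aligned[[1]] - g1$aligned[[2]])^2), 0, tolerance = 1e-15)
  # mirrored configuration is reflected back to the common chirality
  M <- A; M[, 1] <- -M[, 1]
  g2 <- generalized_procrustes(list(A, M))
  expect_true(g2$reflected[2])
  expect_equal(sum((g2$aligned[[1]] - g2$aligned[[2]])^2), 0, tolerance = 1e-15)
  expect_error(generalized_procrustes(list(A, matrix(1, 36, 3))), "degenerate")
})

test_that("pairwise Procrustes distance matches the independent vegan oracle", {
  skip_if_not_installed("vegan")
  set.seed(8)
  for (rep in 1:5) {
    A <- matrix(rnorm(36), 12, 3)
    B <- matrix(rnorm(36), 12, 3)
    g <- generalized_procrustes(list(A, B), tol = 1e-12)
    ourd2 <- sum((g$aligned[[1]] - g$aligned[[2]])^2)
    ss <- vegan::procrustes(A, B, symmetric = TRUE)$ss
    expect_equal(ourd2, 2 - 2 * sqrt(1 - ss), tolerance = 1e-8)
  }
})

test_that("three-config superimposition is at a fixed point of closed-form re-alignment", {
  set.seed(14)
  cfgs <- lapply(1:3, function(k) matrix(rnorm(36, sd = 2), 12, 3))
  g <- generalized_procrustes(cfgs, tol = 1e-12)
  m <- Reduce(`+`, g$aligned) / 3
  for (i in 1:3) {
    X <- g$aligned[[i]]
    # closed-form optimal rotation oracle: no further improvement possible
    H <- crossprod(X, m); sv <- svd(H)
    d <- sign(det(sv$v %*% t(sv$u)))
    Ropt <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
    expect_equal(sum((X %*% Ropt - m)^2), sum((X - m)^2), tolerance = 1e-9)
  }
})

test_that("sliding is a no-op on identical configurations and descends the objective", {
  cfg <- toy_entheseal(proj = 2, noise = 0, seed = 3)
  g <- generalized_procrustes(list(cfg$points, cfg$points, cfg$points))
  s <- slide_semilandmarks(g, cfg$fixed_idx, cfg$topology)
  expect_equal(s$aligned[[1]], g$aligned[[1]], tolerance = 1e-12)
  # noisy cohort: the objective trace never increases
  cfgs <- lapply(1:6, function(k) toy_entheseal(proj = 2, noise = 0.15, seed = k))
  g2 <- generalized_procrustes(cfgs)
  s2 <- suppressWarnings(slide_semilandmarks(g2, cfgs[[1]]$fixed_idx,
                                             cfgs[[1]]$topology))
  expect_true(all(diff(s2$objective_trace) <= 1e-10))
  expect_lt(s2$objective_trace[length(s2$objective_trace)],
            s2$objective_trace[1])
})

test_that("one sliding pass matches a brute-force tangent grid search", {
  cfgA <- toy_entheseal(proj = 2, noise = 0, seed = 5)
  cfgB <- toy_entheseal(proj = 2, noise = 0.2, seed = 6)
  g <- generalized_procrustes(list(cfgA$points, cfgB$points))
  mshape <- g$mean_shape
  X <- g$aligned[[2]]
  topo <- cfgB$topology
  for (r in sample(nrow(topo), 5)) {
    s <- topo[r, "self"]
    tg <- X[topo[r, "next_"], ] - X[topo[r, "prev"], ]
    tg <- tg / sqrt(sum(tg^2))
    # analytic projection used by the implementation
    p_impl <- X[s, ] + tg * sum(tg * (mshape[s, ] - X[s, ]))
    # brute-force grid over tangent offsets
    grid <- seq(-0.5, 0.5, by = 1e-4)
    obj <- vapply(grid, function(t_)
      sum((X[s, ] + t_ * tg - mshape[s, ])^2), numeric(1))
    p_grid <- X[s, ] + grid[which.min(obj)] * tg
    expect_equal(p_impl, p_grid, tolerance = 1e-3)
  }
})

test_that("shape PCA matches a brute-force eigendecomposition oracle", {
  set.seed(17)
  cfgs <- lapply(1:8, function(k) matrix(rnorm(36, sd = 2), 12, 3))
  g <- generalized_procrustes(cfgs)
  p <- shape_pca(g)
  expect_equal(sum(p$variance_fractions), 1, tolerance = 1e-9)
  # oracle: eigendecomposition of the covariance of flattened coordinates
  X <- t(sapply(g$aligned, function(m) as.numeric(t(m))))
  ev <- eigen(stats::cov(X), symmetric = TRUE)$values
  expect_equal(p$eigenvalues[1:7], ev[1:7], tolerance = 1e-8)
  # reconstruction from all components reproduces the aligned coordinates
  rec <- p$scores %*% t(p$loadings)
  rec <- sweep(rec, 2, p$mean_flat, `+`)
  expect_equal(rec, X, tolerance = 1e-9, ignore_attr = TRUE)
  # identical specimens: all eigenvalues zero
  g0 <- generalized_procrustes(list(cfgs[[1]], cfgs[[1]], cfgs[[1]]))
  p0 <- shape_pca(g0)
  expect_equal(max(abs(p0$eigenvalues)), 0, tolerance = 1e-15)
})

test_that("projection into the fitted shape space reproduces scores and centres the mean", {
  cfgs <- lapply(1:6, function(k) toy_entheseal(proj = 1 + 0.3 * k,
                                                noise = 0.1, seed = 20 + k))
  g <- generalized_procrustes(cfgs)
  p <- shape_pca(g)
  # a fitting-sample specimen reproduces its fitted score
  sc <- project_shape(p, g, g$aligned[[3]], slide_iter = 0)
  expect_equal(sc[1:5], p$scores[3, 1:5], tolerance = 1e-9, ignore_attr = TRUE)
  # the mean shape (PCA centre) projects to the origin
  ctr <- matrix(p$mean_flat, ncol = 3, byrow = TRUE)
  sc0 <- project_shape(p, g, ctr, slide_iter = 0, normalize = FALSE)
  expect_equal(max(abs(sc0)), 0, tolerance = 1e-9)
  # held-out configuration equals the dot-product oracle
  new <- toy_entheseal(proj = 2.2, noise = 0.1, seed = 99)
  got <- project_shape(p, g, new, slide_iter = 0)
  Xn <- new$points
  Xn <- sweep(Xn, 2, colMeans(Xn)) / centroid_size(Xn)
  H <- crossprod(Xn, g$mean_shape); sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  Xn <- Xn %*% (sv$u %*% diag(c(1, 1, d)) %*% t(sv$v))
  want <- drop((as.numeric(t(Xn)) - p$mean_flat) %*% p$loadings)
  expect_equal(got, want, tolerance = 1e-9)
})

test_that("shape scores are invariant to rigid motion and scale of any input and to ordering", {
  cfgs <- lapply(1:6, function(k) toy_entheseal(proj = 1 + 0.4 * k,
                                                noise = 0.1, seed = 40 + k))
  run <- function(cs) {
    g <- generalized_procrustes(cs)
    g <- suppressWarnings(slide_semilandmarks(g, cfgs[[1]]$fixed_idx,
                                              cfgs[[1]]$topology))
    shape_pca(g, ids = as.character(seq_along(cs)),
              positive_ids = as.character(length(cs)))$scores[, 1]
  }
  base <- run(lapply(cfgs, `[[`, "points"))
  set.seed(50)
  R <- rand_rotation(); tv <- rnorm(3, 0, 20)
  moved <- lapply(cfgs, `[[`, "points")
  moved[[2]] <- sweep(1.7 * moved[[2]] %*% t(R), 2, tv, `+`)
  got <- run(moved)
  expect_equal(unname(got), unname(base), tolerance = 1e-6)
  # permuting specimen order permutes but does not change scores
  perm <- c(3, 1, 2, 6, 4, 5)
  g2 <- generalized_procrustes(lapply(cfgs[perm], `[[`, "points"))
  g1 <- generalized_procrustes(lapply(cfgs, `[[`, "points"))
  s1 <- shape_pca(g1)$scores[, 1]
  s2 <- shape_pca(g2)$scores[, 1]
  expect_equal(abs(unname(s2)), abs(unname(s1[perm])), tolerance = 1e-9)
})

test_that("greater generated projection yields greater shape PC1", {
  make_group <- function(proj, seeds)
    lapply(seeds, function(s) toy_entheseal(proj = proj, noise = 0.1, seed = s))
  low <- make_group(1.0, 1:4)
  mid <- make_group(2.0, 11:14)
  high <- make_group(3.0, 21:24)
  all_cfg <- c(low, mid, high)
  g <- generalized_procrustes(all_cfg)
  g <- suppressWarnings(slide_semilandmarks(g, all_cfg[[1]]$fixed_idx,
                                            all_cfg[[1]]$topology))
  p <- shape_pca(g, ids = as.character(1:12),
                 positive_ids = as.character(9:12))
  m <- tapply(p$scores[, 1], rep(c("low", "mid", "high"), each = 4), mean)
  expect_lt(m[["low"]], m[["mid"]])
  expect_lt(m[["mid"]], m[["high"]])
})
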