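make_fake_tables <- function(ids, f = 1) {
  tabs <- lapply(seq_along(ids), function(k) {
    grid <- expand.grid(origin = paste0("ORI", 1:3),
                        insertion = paste0("INS", 1:3),
                        stringsAsFactors = FALSE)
    grid$magnitude <- f * (400 + 20 * k + seq_len(9))
    grid
  })
  names(tabs) <- ids
  tabs
}

test_that("the feature table joins torques and shape scores with exact values", {
  ids <- c(paste0("h", 1:5), paste0("c", 1:5), "f1", "f2")
  tabs <- make_fake_tables(ids)
  shape <- setNames(rnorm(12), ids)
  groups <- setNames(c(rep("human", 5), rep("chimp", 5), "fossil", "fossil"), ids)
  ft <- build_feature_table(tabs, shape, groups, reference = c("human", "chimp"))
  expect_identical(nrow(ft), 12L)
  expect_identical(sum(ft$reference), 10L)
  # join oracle: row values equal the torque-table entries exactly
  for (id in ids) {
    tab <- tabs[[id]]
    for (ins in paste0("INS", 1:3)) {
      want <- tab$magnitude[tab$origin == "ORI1" & tab$insertion == ins]
      expect_identical(ft[ft$id == id, paste0("torque_", ins)], want)
    }
    expect_identical(ft$shapePC1[ft$id == id], unname(shape[id]))
  }
  # duplicated fossils under both paradigms: 10 + 4 rows
  tabs2 <- c(tabs[1:10], setNames(tabs[11:12], c("f1.P1", "f2.P1")),
             setNames(lapply(tabs[11:12], function(t) {
               t$magnitude <- t$magnitude * 39 / 66; t
             }), c("f1.P2", "f2.P2")))
  groups2 <- setNames(c(groups[1:10], rep("fossil", 4)), names(tabs2))
  spec_of <- setNames(c(ids[1:10], "f1", "f2", "f1", "f2"), names(tabs2))
  ft2 <- build_feature_table(tabs2, shape, groups2,
                             reference = c("human", "chimp"),
                             specimen_of = spec_of)
  expect_identical(nrow(ft2), 14L)
  # a specimen without the required origin errors by name
  bad <- tabs
  bad$h1 <- bad$h1[bad$h1$origin != "ORI1", ]
  expect_error(build_feature_table(bad, shape, groups), "h1")
})

test_that("the reference PCA matches a brute-force correlation eigendecomposition", {
  set.seed(23)
  n <- 12
  ft <- data.frame(id = as.character(1:n),
                   group = rep(c("human", "chimp"), each = n / 2),
                   reference = TRUE, paradigm = "1",
                   torque_INS1 = rnorm(n, 600, 80),
                   torque_INS2 = rnorm(n, 580, 70),
                   torque_INS3 = rnorm(n, 560, 60),
                   shapePC1 = rnorm(n, 0, 0.05))
  m <- fit_reference_pca(ft, positive_group = "human")
  expect_equal(sum(m$eigenvalues), 4, tolerance = 1e-9)
  expect_equal(sum(m$variance_fractions), 1, tolerance = 1e-12)
  expect_equal(colMeans(m$scores), rep(0, 4), tolerance = 1e-10,
               ignore_attr = TRUE)
  # oracle: standardize then eigendecompose
  X <- as.matrix(ft[, c("torque_INS1", "torque_INS2", "torque_INS3", "shapePC1")])
  e <- eigen(cor(X), symmetric = TRUE)
  expect_equal(m$eigenvalues, e$values, tolerance = 1e-10)
  expect_equal(abs(m$loadings), abs(e$vectors), tolerance = 1e-9,
               ignore_attr = TRUE)
  # factor loadings are eigenvectors scaled by component SDs
  expect_equal(m$factor_loadings[, 1], m$loadings[, 1] * sqrt(m$eigenvalues[1]),
               tolerance = 1e-12)
  # orientation: positive-group mean score positive on PC1
  expect_gte(mean(m$scores[ft$group == "human", 1]), 0)
})

test_that("rank-1 feature tables put 100% of variance on PC1", {
  base <- c(1, 2, 3, 4, 5, 6, 7, 8)
  ft <- data.frame(id = as.character(1:8),
                   group = rep(c("human", "chimp"), 4),
                   reference = TRUE, paradigm = "1",
                   torque_INS1 = 10 * base, torque_INS2 = 5 * base + 2,
                   torque_INS3 = base, shapePC1 = -base)
  m <- fit_reference_pca(ft)
  expect_equal(m$variance_fractions[1], 1, tolerance = 1e-9)
})

test_that("PCA scores are invariant to rescaling any feature column", {
  set.seed(29)
  n <- 10
  ft <- data.frame(id = as.character(1:n),
                   group = rep(c("human", "chimp"), each = n / 2),
                   reference = TRUE, paradigm = "1",
                   torque_INS1 = rnorm(n, 600, 80),
                   torque_INS2 = rnorm(n, 580, 70),
                   torque_INS3 = rnorm(n, 560, 60),
                   shapePC1 = rnorm(n))
  m1 <- fit_reference_pca(ft, positive_group = "human")
  ft2 <- ft
  ft2$torque_INS2 <- ft2$torque_INS2 * 1000
  m2 <- fit_reference_pca(ft2, positive_group = "human")
  expect_equal(abs(m2$scores), abs(m1$scores), tolerance = 1e-9)
})

test_that("projection standardizes by reference statistics and reproduces fitted scores", {
  set.seed(31)
  n <- 10
  ft <- data.frame(id = as.character(1:n),
                   group = rep(c("human", "chimp"), each = n / 2),
                   reference = TRUE, paradigm = "1",
                   torque_INS1 = rnorm(n, 600, 80),
                   torque_INS2 = rnorm(n, 580, 70),
                   torque_INS3 = rnorm(n, 560, 60),
                   shapePC1 = rnorm(n))
  m <- fit_reference_pca(ft, positive_group = "human")
  sc <- project_rows(m, ft)
  expect_equal(sc, m$scores, tolerance = 1e-10, ignore_attr = TRUE)
  # the reference mean row projects to the origin
  feature_names <- c("torque_INS1", "torque_INS2", "torque_INS3", "shapePC1")
  mu <- ft[1, ]
  mu[, feature_names] <- as.list(colMeans(ft[, feature_names]))
  expect_equal(max(abs(project_rows(m, mu))), 0, tolerance = 1e-10)
  # random rows equal the matrix-product oracle
  new <- ft[1:3, ]
  new[, feature_names] <- matrix(rnorm(12, 500, 100), 3, 4)
  got <- project_rows(m, new)
  want <- scale(as.matrix(new[, feature_names]), center = m$center,
                scale = m$scale) %*% m$loadings
  expect_equal(got, want, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("torque-on-shape regression recovers exact linear structure and its closed form", {
  x <- seq(-2, 2, length.out = 12)
  ft <- data.frame(id = as.character(1:12), group = "human",
                   reference = TRUE, paradigm = "1",
                   torque_INS1 = 100 + 50 * x, torque_INS2 = 80 + 30 * x,
                   torque_INS3 = 60 + 10 * x, shapePC1 = x)
  r <- suppressWarnings(regress_torque_on_shape(ft))  # exact fit: lm warns
  expect_equal(r$per_response$r_squared, rep(1, 3), tolerance = 1e-12)
  expect_equal(r$per_response$slope, c(50, 30, 10), tolerance = 1e-9)
  expect_equal(r$per_response$intercept, c(100, 80, 60), tolerance = 1e-9)
  # closed-form least-squares oracle on noisy data
  set.seed(37)
  ft$torque_INS1 <- 100 + 50 * x + rnorm(12, 0, 5)
  r2 <- suppressWarnings(regress_torque_on_shape(ft))  # two responses stay exact
  b <- cov(ft$torque_INS1, x) / var(x)
  a <- mean(ft$torque_INS1) - b * mean(x)
  expect_equal(r2$per_response$slope[1], b, tolerance = 1e-9)
  expect_equal(r2$per_response$intercept[1], a, tolerance = 1e-9)
  expect_equal(r2$per_response$r_squared[1],
               cor(ft$torque_INS1, x)^2, tolerance = 1e-9)
  expect_error(regress_torque_on_shape(transform(ft, shapePC1 = 1)), "constant")
})

test_that("permuted predictors give near-zero explained variance", {
  set.seed(41)
  n <- 100
  y <- rnorm(n)
  x <- rnorm(n)
  r2s <- replicate(1000, cor(sample(x), y)^2)
  expect_lt(mean(r2s), 0.05)
})

test_that("species grand means average the nine pair means and identical groups give 100%", {
  ids <- c("a1", "a2", "b1", "b2")
  tabs <- make_fake_tables(ids)
  tabs[["b1"]] <- tabs[["a1"]]; tabs[["b2"]] <- tabs[["a2"]]
  groups <- setNames(c("human", "human", "chimp", "chimp"), ids)
  s <- species_torque_summary(tabs, groups)
  expect_equal(s$percentage, 100, tolerance = 1e-12)
  # direct oracle for the grand mean
  want <- mean(c(sapply(split(tabs[["a1"]]$magnitude,
                              paste(tabs[["a1"]]$origin, tabs[["a1"]]$insertion)), mean) +
                   sapply(split(tabs[["a2"]]$magnitude,
                                paste(tabs[["a2"]]$origin, tabs[["a2"]]$insertion)), mean)) / 2)
  expect_equal(unname(s$grand_means[["human"]]), want, tolerance = 1e-9)
  expect_error(species_torque_summary(list(), groups), "no torque tables")
})

test_that("a deposited-style torque table round-trips through the grand-mean computation", {
  # synthetic stand-in for an archived long-form torque table
  ids <- c(paste0("H", 1:3), paste0("C", 1:3))
  tabs <- make_fake_tables(ids)
  for (id in paste0("C", 1:3))
    tabs[[id]]$magnitude <- tabs[[id]]$magnitude * 0.44
  long <- do.call(rbind, lapply(ids, function(id)
    cbind(specimen = id, tabs[[id]])))
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(long, f, row.names = FALSE)
  # reload and recompute
  rl <- read.csv(f, stringsAsFactors = FALSE)
  tabs2 <- lapply(split(rl, rl$specimen), function(d)
    d[, c("origin", "insertion", "magnitude")])
  groups <- setNames(c(rep("human", 3), rep("chimp", 3)), c(paste0("H", 1:3), paste0("C", 1:3)))
  s <- species_torque_summary(tabs2, groups)
  s0 <- species_torque_summary(tabs, groups)
  expect_equal(s$percentage, s0$percentage, tolerance = 1e-9)
})
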