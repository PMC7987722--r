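#' Assemble the four-variable feature table
#'
#' One row per specimen (and per PCSA-paradigm / trapezium-substitution
#' variant for projected fossils), with the three torques based on each
#' metacarpal insertion landmark paired with the first trapezium origin
#' landmark -- the origin preserved in all specimens -- plus the entheseal
#' shape PC1 score. Torques sharing an insertion landmark are highly
#' intercorrelated across origins, so one origin suffices and keeps the
#' variable count low.
#'
#' @param torque_tables named list of [torque_table()] data frames (one
#'   per row to create; names become row ids).
#' @param shape_scores named numeric vector of shape-PC1 scores keyed by
#'   specimen id.
#' @param groups named character vector of group labels keyed by row id.
#' @param reference character vector of group labels forming the reference
#'   (PCA-fitting) sample.
#' @param paradigms optional named vector tagging each row's PCSA paradigm.
#' @param specimen_of optional named vector mapping row id to specimen id
#'   for the shape-score lookup (default: row id itself).
#' @param origin origin landmark to use (default `"ORI1"`).
#' @return data frame of class `feature_table` with columns `id`, `group`,
#'   `reference`, `paradigm`, `torque_INS1`, `torque_INS2`, `torque_INS3`,
#'   `shapePC1`.
#' @export
build_feature_table <- function(torque_tables, shape_scores, groups,
                                reference = NULL, paradigms = NULL,
                                specimen_of = NULL, origin = "ORI1") {
  ids <- names(torque_tables)
  if (is.null(ids)) stop("torque_tables must be a named list")
  if (is.null(specimen_of)) specimen_of <- stats::setNames(ids, ids)
  rows <- lapply(ids, function(id) {
    tab <- torque_tables[[id]]
    sub <- tab[tab$origin == origin, ]
    need <- paste0("INS", 1:3)
    if (!all(need %in% sub$insertion))
      stop(sprintf("specimen '%s' lacks %s torques for origin %s", id,
                   paste(setdiff(need, sub$insertion), collapse = ","), origin))
    spec <- specimen_of[[id]]
    if (!spec %in% names(shape_scores))
      stop(sprintf("specimen '%s' has no shape score", spec))
    data.frame(id = id, group = groups[[id]],
               paradigm = if (is.null(paradigms)) NA_character_
                          else as.character(paradigms[[id]]),
               torque_INS1 = sub$magnitude[sub$insertion == "INS1"],
               torque_INS2 = sub$magnitude[sub$insertion == "INS2"],
               torque_INS3 = sub$magnitude[sub$insertion == "INS3"],
               shapePC1 = unname(shape_scores[[spec]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$reference <- if (is.null(reference)) TRUE else out$group %in% reference
  out <- out[, c("id", "group", "reference", "paradigm",
                 "torque_INS1", "torque_INS2", "torque_INS3", "shapePC1")]
  class(out) <- c("feature_table", class(out))
  out
}

feature_cols <- c("torque_INS1", "torque_INS2", "torque_INS3", "shapePC1")

#' Correlation-matrix PCA fitted on the reference sample
#'
#' Standardizes the four feature columns by the reference-sample means and
#' standard deviations and eigendecomposes the reference correlation
#' matrix (a correlation matrix is used because the variables are on
#' different scales). PC1 is oriented so the nominated group's mean score
#' is positive. Non-reference rows are projected afterwards with
#' [project_rows()], never refitted.
#'
#' @param table a [build_feature_table()] result (reference rows used).
#' @param positive_group group whose mean PC1 score is made positive
#'   (default `"human"` when present, else the first group).
#' @return list of class `integrative_pca`: `center`, `scale`,
#'   `eigenvalues` (sum 4), `variance_fractions`, `loadings`
#'   (eigenvectors, used for projection), `factor_loadings` (variable-
#'   component correlations, the reported loadings), `scores` (reference
#'   rows), `ids`, `groups`, `positive_group`.
#' @export
fit_reference_pca <- function(table, positive_group = NULL) {
  ref <- table[table$reference, , drop = FALSE]
  if (nrow(ref) < 4) stop("need at least 4 reference rows")
  if (length(unique(ref$group)) < 2) stop("need at least 2 reference groups")
  X <- as.matrix(ref[, feature_cols])
  if (anyNA(X)) stop("missing cells in reference rows")
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  if (any(scl == 0)) stop("zero-variance feature column")
  Z <- scale(X, center = ctr, scale = scl)
  C <- stats::cor(X)
  e <- eigen(C, symmetric = TRUE)
  loadings <- e$vectors
  rownames(loadings) <- feature_cols
  # sd denominator: cor() uses n-1; scores consistent with Z %*% v
  scores <- Z %*% loadings
  if (is.null(positive_group))
    positive_group <- if ("human" %in% ref$group) "human" else ref$group[1]
  sel <- ref$group == positive_group
  if (any(sel) && mean(scores[sel, 1]) < 0) {
    scores[, 1] <- -scores[, 1]
    loadings[, 1] <- -loadings[, 1]
  }
  rownames(scores) <- ref$id
  colnames(scores) <- paste0("PC", 1:4)
  colnames(loadings) <- paste0("PC", 1:4)
  # factor loadings: correlation of each variable with each component
  # (eigenvector scaled by the component's standard deviation)
  factor_loadings <- loadings %*% diag(sqrt(pmax(e$values, 0)))
  dimnames(factor_loadings) <- dimnames(loadings)
  structure(list(center = ctr, scale = scl, eigenvalues = e$values,
                 variance_fractions = e$values / sum(e$values),
                 loadings = loadings, factor_loadings = factor_loadings,
                 scores = scores,
                 ids = ref$id, groups = ref$group,
                 positive_group = positive_group),
            class = "integrative_pca")
}

#' @export
print.integrative_pca <- function(x, ...) {
  cat(sprintf("<integrative_pca> PC1 %.1f%% of variance; factor loadings: %s\n",
              100 * x$variance_fractions[1],
              paste(sprintf("%.2f", x$factor_loadings[, 1]), collapse = ", ")))
  invisible(x)
}

#' Project rows into a fitted correlation-matrix PCA
#'
#' Standardizes rows with the reference means/SDs and multiplies by the
#' loading vectors; a reference row reproduces its fitted score.
#'
#' @param model an [fit_reference_pca()] result.
#' @param rows data frame containing the four feature columns.
#' @return score matrix (rows x 4), rownames from `rows$id` when present.
#' @export
project_rows <- function(model, rows) {
  stopifnot(inherits(model, "integrative_pca"))
  if (!all(feature_cols %in% names(rows)))
    stop("rows lack the four feature columns")
  X <- as.matrix(rows[, feature_cols])
  Z <- scale(X, center = model$center, scale = model$scale)
  sc <- Z %*% model$loadings
  if (!is.null(rows$id)) rownames(sc) <- rows$id
  colnames(sc) <- paste0("PC", 1:4)
  sc
}

#' Multivariate regression of torques on entheseal shape
#'
#' Ordinary least squares of the three torque columns on shape PC1 (one
#' model per torque plus the joint multivariate test): slope, intercept,
#' R-squared and p-value per response, a Wilks-type joint statistic, and a
#' residual z-score outlier report.
#'
#' @param table a [build_feature_table()] result (all rows used).
#' @param z_threshold |z| above which a residual is reported (default 3).
#' @return list of class `torque_shape_regression`: `per_response` data
#'   frame, `wilks` (statistic, approx F, p), `outliers`, `n`.
#' @export
regress_torque_on_shape <- function(table, z_threshold = 3) {
  if (nrow(table) < 5) stop("need at least 5 rows")
  x <- table$shapePC1
  if (stats::sd(x) == 0) stop("constant predictor")
  Y <- as.matrix(table[, c("torque_INS1", "torque_INS2", "torque_INS3")])
  fit <- stats::lm(Y ~ x)
  sm <- summary(fit)
  per <- do.call(rbind, lapply(seq_along(sm), function(k) {
    cf <- sm[[k]]$coefficients
    data.frame(response = colnames(Y)[k],
               intercept = cf[1, 1], slope = cf[2, 1],
               r_squared = sm[[k]]$r.squared,
               p_value = cf[2, 4], stringsAsFactors = FALSE)
  }))
  wilks <- tryCatch({
    an <- stats::anova(fit, test = "Wilks")
    wrow <- which(rownames(an) == "x")
    list(statistic = an[wrow, "Wilks"], approx_F = an[wrow, "approx F"],
         p_value = an[wrow, "Pr(>F)"])
  }, error = function(e) {
    # degenerate residual covariance (e.g. an exact linear relation)
    list(statistic = 0, approx_F = Inf, p_value = 0)
  })
  Z <- scale(stats::residuals(fit))
  out_idx <- which(abs(Z) > z_threshold, arr.ind = TRUE)
  outliers <- if (nrow(out_idx) > 0)
    data.frame(id = table$id[out_idx[, 1]],
               response = colnames(Y)[out_idx[, 2]],
               z = Z[out_idx], stringsAsFactors = FALSE)
  else data.frame(id = character(), response = character(), z = numeric())
  structure(list(per_response = per, wilks = wilks, outliers = outliers,
                 n = nrow(table)),
            class = "torque_shape_regression")
}

#' Species grand-mean torques and the chimpanzee/human percentage
#'
#' For each group, averages every origin-insertion pair's torque over the
#' group's specimens, then takes the grand mean of those (up to nine) pair
#' means. The chimpanzee grand mean is reported as a percentage of the
#' modern-human grand mean -- the model-validation statistic compared
#' against cadaveric experiments.
#'
#' @param torque_tables named list of [torque_table()] data frames.
#' @param groups named character vector of group labels keyed by specimen.
#' @param chimp_group,human_group group labels for the percentage
#'   (defaults `"chimp"`, `"human"`).
#' @return list of class `species_torque_summary`: `pair_means` (long data
#'   frame), `grand_means` (named vector), `percentage` (chimp / human *
#'   100, `NA` when either group is absent).
#' @export
species_torque_summary <- function(torque_tables, groups,
                                   chimp_group = "chimp",
                                   human_group = "human") {
  ids <- names(torque_tables)
  if (length(ids) == 0) stop("no torque tables supplied")
  if (!all(ids %in% names(groups))) stop("every specimen needs a group label")
  long <- do.call(rbind, lapply(ids, function(id) {
    tab <- torque_tables[[id]]
    data.frame(id = id, group = groups[[id]],
               pair = paste(tab$origin, tab$insertion, sep = "-"),
               magnitude = tab$magnitude, stringsAsFactors = FALSE)
  }))
  pm <- stats::aggregate(magnitude ~ group + pair, data = long, FUN = mean)
  gm <- vapply(split(pm$magnitude, pm$group), mean, numeric(1))
  pct <- if (all(c(chimp_group, human_group) %in% names(gm)))
    100 * gm[[chimp_group]] / gm[[human_group]] else NA_real_
  structure(list(pair_means = pm, grand_means = gm, percentage = pct),
            class = "species_torque_summary")
}

#' @export
print.species_torque_summary <- function(x, ...) {
  cat("<species_torque_summary> grand means (N mm):\n")
  print(round(x$grand_means, 2))
  if (!is.na(x$percentage))
    cat(sprintf("  chimp/human torque percentage: %.2f%%\n", x$percentage))
  invisible(x)
}
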