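#' Read a landmark table
#'
#' Canonical tabular dialect: comma-separated, header row
#' `specimen_id,bone,name,x,y,z`, coordinates in mm. Comment lines
#' starting with `#` are ignored. Duplicate (specimen, bone, name) keys
#' and malformed rows are rejected with their line number.
#'
#' @param path file path.
#' @return data frame with the five columns above.
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", raw) & nzchar(trimws(raw))
  df <- utils::read.csv(text = raw[keep], stringsAsFactors = FALSE)
  need <- c("specimen_id", "bone", "name", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("landmark table must have columns specimen_id,bone,name,x,y,z")
  bad <- which(!stats::complete.cases(df[, c("x", "y", "z")]) |
                 !vapply(seq_len(nrow(df)), function(i)
                   all(is.finite(as.numeric(df[i, c("x", "y", "z")]))), logical(1)))
  line_of <- function(i) which(keep)[i + 1L]  # +1 for the header
  if (length(bad) > 0)
    stop(sprintf("malformed coordinates at line %d", line_of(bad[1])))
  key <- paste(df$specimen_id, df$bone, df$name)
  dup <- which(duplicated(key))
  if (length(dup) > 0)
    stop(sprintf("duplicated landmark '%s' at line %d",
                 df$name[dup[1]], line_of(dup[1])))
  df[, need]
}

#' Write a landmark table
#'
#' @param df data frame with columns `specimen_id,bone,name,x,y,z`.
#' @param path output path.
#' @param header optional comment lines (written prefixed with `#`).
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(df, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  writeLines("specimen_id,bone,name,x,y,z", con)
  writeLines(sprintf("%s,%s,%s,%.12g,%.12g,%.12g", df$specimen_id, df$bone,
                     df$name, df$x, df$y, df$z), con)
  invisible(path)
}

#' Bone models from a landmark table
#'
#' Splits a [read_landmarks()] data frame into [bone_model()] objects.
#' Rows named `FACET<k>` (in order) form the articular facet outline;
#' every other row is a named model landmark.
#'
#' @param df landmark data frame.
#' @param side side flag for all bones (default `"right"`).
#' @return nested list: `bones[[specimen_id]][[bone]]`.
#' @export
bones_from_landmark_table <- function(df, side = "right") {
  out <- list()
  for (sid in unique(df$specimen_id)) {
    sub <- df[df$specimen_id == sid, ]
    out[[sid]] <- list()
    for (bn in unique(sub$bone)) {
      bb <- sub[sub$bone == bn, ]
      is_facet <- grepl("^FACET[0-9]+$", bb$name)
      fac <- bb[is_facet, ]
      fac <- fac[order(as.integer(sub("FACET", "", fac$name))), ]
      lm <- as.matrix(bb[!is_facet, c("x", "y", "z")])
      rownames(lm) <- bb$name[!is_facet]
      out[[sid]][[bn]] <- bone_model(
        paste(sid, bn, sep = "_"), side, lm,
        facet = if (nrow(fac) >= 3) as.matrix(fac[, c("x", "y", "z")]) else NULL)
    }
  }
  out
}

#' Landmark table of a synthetic study
#'
#' Flattens the bones of a study into the canonical landmark dialect
#' (model landmarks plus `FACET<k>` outline rows), so synthetic data can
#' be written and re-read through the same path as real data.
#'
#' @param study a [generate_study()] result.
#' @return landmark data frame.
#' @export
landmark_table_of_study <- function(study) {
  rows <- lapply(study$specimens, function(sp) {
    one <- function(bone, tag) {
      lm <- bone$landmarks
      fc <- bone$facet
      rbind(data.frame(specimen_id = sp$specimen_id, bone = tag,
                       name = rownames(lm), x = lm[, 1], y = lm[, 2],
                       z = lm[, 3], stringsAsFactors = FALSE),
            if (!is.null(fc))
              data.frame(specimen_id = sp$specimen_id, bone = tag,
                         name = paste0("FACET", seq_len(nrow(fc))),
                         x = fc[, 1], y = fc[, 2], z = fc[, 3],
                         stringsAsFactors = FALSE))
    }
    rbind(one(sp$metacarpal, "metacarpal"), one(sp$trapezium, "trapezium"))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a TPS landmark file
#'
#' Minimal TPS dialect used by morphometrics tooling: per specimen a
#' `LM3=<k>` block of 3D coordinates, an optional `CURVES=<n>` section
#' whose curves each start with `POINTS=<m>`, and an `ID=` line.
#'
#' @param path file path.
#' @return list of specimens: each a list with `id`, `landmarks`
#'   (k x 3 matrix), `curves` (list of matrices).
#' @export
read_tps <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  out <- list()
  i <- 1
  nmax <- length(lines)
  read_pts <- function(start, n) {
    m <- t(vapply(lines[start:(start + n - 1)], function(l)
      as.numeric(strsplit(l, "\\s+")[[1]]), numeric(3), USE.NAMES = FALSE))
    m
  }
  while (i <= nmax) {
    if (!grepl("^LM3=", lines[i])) stop(sprintf("expected LM3= at line %d", i))
    k <- as.integer(sub("LM3=", "", lines[i]))
    lm <- read_pts(i + 1, k)
    i <- i + 1 + k
    curves <- list()
    if (i <= nmax && grepl("^CURVES=", lines[i])) {
      nc <- as.integer(sub("CURVES=", "", lines[i]))
      i <- i + 1
      for (ci in seq_len(nc)) {
        m <- as.integer(sub("POINTS=", "", lines[i]))
        curves[[ci]] <- read_pts(i + 1, m)
        i <- i + 1 + m
      }
    }
    id <- if (i <= nmax && grepl("^ID=", lines[i])) {
      v <- sub("ID=", "", lines[i]); i <- i + 1; v
    } else sprintf("specimen_%d", length(out) + 1)
    out[[id]] <- list(id = id, landmarks = lm, curves = curves)
  }
  out
}

#' Write a TPS landmark file
#'
#' @param specimens list as returned by [read_tps()] (elements with `id`,
#'   `landmarks`, optional `curves`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tps <- function(specimens, path) {
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- function(m) sprintf("%.12g %.12g %.12g", m[, 1], m[, 2], m[, 3])
  for (sp in specimens) {
    writeLines(sprintf("LM3=%d", nrow(sp$landmarks)), con)
    writeLines(fmt(sp$landmarks), con)
    if (!is.null(sp$curves) && length(sp$curves) > 0) {
      writeLines(sprintf("CURVES=%d", length(sp$curves)), con)
      for (cv in sp$curves) {
        writeLines(sprintf("POINTS=%d", nrow(cv)), con)
        writeLines(fmt(cv), con)
      }
    }
    writeLines(sprintf("ID=%s", sp$id), con)
  }
  invisible(path)
}

#' Read a run configuration (YAML)
#'
#' @param path YAML file path.
#' @return configuration list (validated by [run_pipeline()]).
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}

cfg_hash <- function(config) {
  s <- paste(deparse(config), collapse = "")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_len(nchar(s)) %% 97 + 1)) %% .Machine$integer.max)
}

#' Run the full analysis pipeline
#'
#' Executes pose, clearance, torque (raw and size-adjusted), entheseal
#' shape, feature assembly, the four correlation-matrix PCAs (fossil
#' paradigm human/chimpanzee x raw/size-adjusted), out-of-sample
#' projection, the torque-on-shape regression, and the species torque
#' summary. Inputs come either from a seeded synthetic study block or
#' from landmark/TPS files written in the package dialects.
#'
#' @param config list (or path handled by [read_run_config()]) with
#'   elements: `synthetic` (list: `n_human`, `n_chimp`, `singletons`,
#'   `seed`) or `landmarks`/`tps` paths; optional `gap_mm` (1.5),
#'   `flexion_deg` (11), `size_adjust` (TRUE), `outdir`.
#' @return list of class `pipeline_result`: `posed`, `torque_tables`
#'   (per paradigm id used), `size_adjusted`, `shape` (gpa fit + pca +
#'   scores), `analyses` (4 PCA result sets with projections and
#'   regression), `summary` (species torque summary), `config`, `seed`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  gap <- config$gap_mm %||% 1.5
  flex <- config$flexion_deg %||% 11
  size_adjust <- config$size_adjust %||% TRUE

  if (!is.null(config$synthetic)) {
    sb <- config$synthetic
    study <- generate_study(n_human = sb$n_human %||% 5,
                            n_chimp = sb$n_chimp %||% 5,
                            singletons = sb$singletons %||% 2,
                            seed = sb$seed %||% 0)
  } else if (!is.null(config$study)) {
    study <- config$study
  } else {
    stop("config must contain a 'synthetic' block or a 'study' object")
  }

  specimens <- study$specimens
  groups <- study$groups

  posed <- lapply(names(specimens), function(id) {
    sp <- specimens[[id]]
    tryCatch(pose_tmc(sp$metacarpal, sp$trapezium, gap_mm = gap,
                      flexion_deg = flex),
             error = function(e) stop(sprintf("pose failed for '%s': %s",
                                              id, conditionMessage(e))))
  })
  names(posed) <- names(specimens)

  # torque tables under each paradigm needed (reference groups use their
  # own paradigm; singletons are run under both requested paradigms)
  paradigm_of_group <- c(human = 1, chimp = 2)
  needed <- sort(unique(c(unname(paradigm_of_group[groups[groups %in% study$reference]]),
                          study$singleton_paradigms)))
  tq <- list()
  tq_adj <- list()
  for (pid in needed) {
    par <- make_paradigm(pid)
    tq[[as.character(pid)]] <- lapply(posed, torque_table, params = par)
    if (size_adjust)
      tq_adj[[as.character(pid)]] <-
        size_adjusted_table(posed, par)$tables
  }

  # entheseal shape: GPA + sliding + shape PCA over all specimens
  configs <- lapply(specimens, `[[`, "entheseal")
  fit <- generalized_procrustes(configs)
  fit <- slide_semilandmarks(fit, fixed_idx = configs[[1]]$fixed_idx,
                             topology = configs[[1]]$topology)
  names(fit$aligned) <- names(specimens)
  spca <- shape_pca(fit, ids = names(specimens),
                    positive_ids = names(specimens)[groups == "human"])
  shape_scores <- stats::setNames(spca$scores[, 1], names(specimens))

  own_paradigm <- function(id) {
    g <- groups[[id]]
    if (g %in% names(paradigm_of_group)) paradigm_of_group[[g]] else NA
  }

  analyses <- list()
  for (fossil_pid in study$singleton_paradigms) {
    for (space in c("raw", if (size_adjust) "size_adjusted")) {
      src <- if (space == "raw") tq else tq_adj
      ids <- names(specimens)
      tabs <- lapply(ids, function(id) {
        pid <- own_paradigm(id)
        if (is.na(pid)) pid <- fossil_pid
        src[[as.character(pid)]][[id]]
      })
      names(tabs) <- ids
      paradigms <- vapply(ids, function(id) {
        pid <- own_paradigm(id); if (is.na(pid)) fossil_pid else pid
      }, numeric(1))
      ft <- build_feature_table(tabs, shape_scores, groups,
                                reference = study$reference,
                                paradigms = paradigms)
      pca <- fit_reference_pca(ft, positive_group = "human")
      proj <- project_rows(pca, ft[!ft$reference, , drop = FALSE])
      reg <- regress_torque_on_shape(ft)
      analyses[[sprintf("fossilP%d_%s", fossil_pid, space)]] <-
        list(feature_table = ft, pca = pca, projected = proj,
             regression = reg, fossil_paradigm = fossil_pid, space = space)
    }
  }

  own_tabs <- lapply(names(specimens), function(id) {
    pid <- own_paradigm(id)
    if (is.na(pid)) pid <- study$singleton_paradigms[1]
    tq[[as.character(pid)]][[id]]
  })
  names(own_tabs) <- names(specimens)
  summary <- species_torque_summary(own_tabs, groups)

  res <- structure(list(posed = posed, torque_tables = tq,
                        size_adjusted = tq_adj,
                        shape = list(fit = fit, pca = spca,
                                     scores = shape_scores),
                        analyses = analyses, summary = summary,
                        config = config, seed = study$seed),
                   class = "pipeline_result")
  if (!is.null(config$outdir)) write_pipeline_outputs(res, config$outdir)
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d specimens, %d analyses; seed %s\n",
              length(x$posed), length(x$analyses), x$seed))
  if (!is.na(x$summary$percentage))
    cat(sprintf("  chimp/human grand-mean torque: %.2f%%\n",
                x$summary$percentage))
  for (nm in names(x$analyses))
    cat(sprintf("  %s: PC1 %.1f%% of variance\n", nm,
                100 * x$analyses[[nm]]$pca$variance_fractions[1]))
  invisible(x)
}

#' Write pipeline result tables
#'
#' Writes the torque tables (long form), shape scores, feature tables and
#' PCA score/loading exports to `outdir` as CSV, each with a header
#' recording package version, configuration hash and seed.
#'
#' @param res a [run_pipeline()] result.
#' @param outdir output directory (created if absent).
#' @return `outdir`, invisibly.
#' @export
write_pipeline_outputs <- function(res, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  hdr <- sprintf("tmctorque %s; config %s; seed %s",
                 as.character(utils::packageVersion("tmctorque")),
                 cfg_hash(res$config), res$seed)
  wcsv <- function(df, name) {
    p <- file.path(outdir, name)
    con <- file(p, "w")
    writeLines(paste0("# ", hdr), con)
    utils::write.csv(df, con, row.names = FALSE)
    close(con)
  }
  long <- do.call(rbind, lapply(names(res$torque_tables), function(pid) {
    do.call(rbind, lapply(names(res$torque_tables[[pid]]), function(id) {
      tab <- res$torque_tables[[pid]][[id]]
      cbind(specimen = id, paradigm = pid, as.data.frame(tab))
    }))
  }))
  wcsv(long, "torques.csv")
  wcsv(data.frame(specimen = names(res$shape$scores),
                  shapePC1 = unname(res$shape$scores)), "shape_scores.csv")
  for (nm in names(res$analyses)) {
    an <- res$analyses[[nm]]
    wcsv(an$feature_table, sprintf("feature_table_%s.csv", nm))
    sc <- rbind(data.frame(id = rownames(an$pca$scores),
                           projected = FALSE,
                           as.data.frame(an$pca$scores)),
                data.frame(id = rownames(an$projected),
                           projected = TRUE,
                           as.data.frame(an$projected)))
    wcsv(sc, sprintf("pca_scores_%s.csv", nm))
    wcsv(as.data.frame(an$pca$factor_loadings),
         sprintf("pca_loadings_%s.csv", nm))
  }
  invisible(outdir)
}
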