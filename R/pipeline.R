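# Delimited-matrix + JSON-sidecar I/O and the end-to-end pipeline driver.
# All tables are UTF-8, tab-delimited, one-line header; panels are one file
# per subject (rows = frames, cols = parcels) plus a sidecar recording tr
# and the file list.

#' Write / read a tab-delimited numeric table
#'
#' Lossless round-trip of finite values at full precision (values are
#' written with 17 significant digits).
#'
#' @param x matrix or data frame.
#' @param path output path.
#' @return `write_table()` returns `path` invisibly; `read_table_strict()`
#'   returns a tibble and errors, naming the row, on ragged or non-numeric
#'   input.
#' @export
write_table <- function(x, path) {
  df <- as.data.frame(x)
  utils::write.table(format(df, digits = 17, scientific = TRUE,
                            trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_table
#' @param numeric_only error on any non-numeric cell.
#' @export
read_table_strict <- function(path, numeric_only = TRUE) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 2L) stop("File '", path, "' has no data rows.",
                               call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  widths <- lengths(fields)
  if (length(unique(widths)) != 1L) {
    bad <- which(widths != widths[1])[1]
    stop("Ragged row ", bad, " in '", path, "': expected ", widths[1],
         " fields, found ", widths[bad], ".", call. = FALSE)
  }
  header <- fields[[1]]
  body <- fields[-1]
  cols <- lapply(seq_along(header), function(j) {
    vapply(body, `[[`, character(1), j)
  })
  names(cols) <- header
  if (numeric_only) {
    cols <- lapply(seq_along(cols), function(j) {
      v <- suppressWarnings(as.numeric(cols[[j]]))
      if (anyNA(v)) {
        bad <- which(is.na(v))[1] + 1L
        stop("Non-numeric cell in '", path, "', row ", bad, ", column '",
             header[j], "'.", call. = FALSE)
      }
      v
    })
    names(cols) <- header
  }
  tibble::as_tibble(cols)
}

#' Write and read a time-series panel directory
#'
#' One TSV per subject (`subject_0001.tsv`, rows = frames, cols = parcels)
#' plus a `panel.json` sidecar recording `tr`, dimensions, the file list
#' and, when present, the block design. Reading demands the sidecar and its
#' `tr`.
#'
#' @param panel a [ts_panel()].
#' @param dir directory to create/use.
#' @return `write_panel()` the directory, invisibly; `read_panel()` a
#'   `ts_panel`.
#' @export
write_panel <- function(panel, dir) {
  panel <- as_ts_panel(panel)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bold <- panel_mean_runs(panel)
  n_sub <- dim(bold)[1]
  files <- sprintf("subject_%04d.tsv", seq_len(n_sub))
  for (i in seq_len(n_sub)) {
    m <- t(bold[i, , ])                      # frames x parcels
    colnames(m) <- sprintf("parcel_%04d", seq_len(ncol(m)))
    write_table(m, file.path(dir, files[i]))
  }
  sidecar <- list(tr = panel$tr, n_subjects = n_sub,
                  n_parcels = dim(bold)[2], n_time = dim(bold)[3],
                  files = files)
  if (!is.null(panel$design)) sidecar$design <- panel$design
  jsonlite::write_json(sidecar, file.path(dir, "panel.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_panel
#' @export
read_panel <- function(dir) {
  sidecar_path <- file.path(dir, "panel.json")
  if (!file.exists(sidecar_path)) {
    stop("Missing sidecar '", sidecar_path, "'.", call. = FALSE)
  }
  sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  if (is.null(sc$tr)) {
    stop("Sidecar '", sidecar_path, "' lacks the required `tr` field.",
         call. = FALSE)
  }
  bold <- array(NA_real_, dim = c(sc$n_subjects, sc$n_parcels, sc$n_time))
  for (i in seq_along(sc$files)) {
    tb <- read_table_strict(file.path(dir, sc$files[i]))
    bold[i, , ] <- t(as.matrix(tb))
  }
  design <- if (!is.null(sc$design)) tibble::as_tibble(sc$design) else NULL
  ts_panel(bold, tr = sc$tr, design = design)
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Orchestrates, in dependency order: cohort simulation, DFA Hurst
#' estimation (full-run and per-condition blocks), behavioral PLS with
#' permutation and bootstrap inference, stable-region masking and pattern
#' scoring, term-map simulation and the term axis, the ROI threshold sweep,
#' block-level contrast analysis, and stratified cross-validation. Optional
#' sensitivity variants refit the PLS after deduplicating families, with
#' sampling weights, with the alternate (syndrome-scale) outcome set, or
#' after dropping a random subject subset (motion-censor emulation), each
#' reporting the brain-loading correlation with the main model.
#'
#' @param config a [cohort_config()] describing the cohort.
#' @param n_perm,n_boot PLS permutation / bootstrap counts.
#' @param n_surrogates surrogate maps for spin tests; the default 1000
#'   makes p-values fine enough for Benjamini-Hochberg at `alpha = 0.01`
#'   across the term family (the attainable minimum is 1/(n+1)).
#' @param n_terms term maps to simulate (a few planted in each direction).
#' @param z_grid threshold grid for the sweeps.
#' @param k_folds folds for cross-validation (`NULL` skips the stage).
#' @param block_config [dfa_config()] used for block-level estimation; the
#'   default widens the high-frequency bound to 0.3 Hz so that short task
#'   blocks admit enough window sizes.
#' @param weighted use the cohort's sampling weights in the main PLS.
#' @param family_dedup,alternate_outcomes,motion_censor_emulation
#'   sensitivity variants (logical).
#' @param out_dir optional directory; when given, all stage tables and a
#'   JSON run manifest are written there.
#' @param seed integer seed for every stochastic stage downstream of the
#'   cohort (the cohort itself uses `config$seed`).
#' @return a list of class `pipeline_result` with the per-stage objects and
#'   a `manifest` (seeds, config echo, stage summary).
#' @export
run_pipeline <- function(config, n_perm = 500, n_boot = 500,
                         n_surrogates = 1000, n_terms = 60,
                         z_grid = seq(0.5, 3, by = 0.25), k_folds = NULL,
                         block_config = NULL, weighted = FALSE,
                         family_dedup = FALSE, alternate_outcomes = FALSE,
                         motion_censor_emulation = FALSE,
                         out_dir = NULL, seed = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  cohort <- simulate_cohort(config)
  cfg_dfa <- dfa_config(tr = config$tr)
  hurst <- hurst_panel(cohort$panel, cfg_dfa)
  if (is.null(block_config)) {
    block_config <- dfa_config(tr = config$tr, f_high = 0.3)
  }
  h2 <- block_hurst(cohort$panel, condition = "2-back",
                    config = block_config)
  h0 <- block_hurst(cohort$panel, condition = "0-back",
                    config = block_config)

  w <- if (weighted) cohort$weights$weight else NULL
  model <- pls_analysis(hurst, cohort$factors, weights = w,
                        n_perm = n_perm, n_boot = n_boot, seed = seed)
  mask <- stable_region_mask(model)
  scores <- pattern_scores(hurst, model)

  hpp <- model$brain_loadings[, 1]
  terms <- simulate_term_maps(cohort$geometry, n_terms = n_terms,
                              smoothness = 30, planted_target = hpp,
                              n_planted_pos = 3, n_planted_neg = 3,
                              seed = seed + 1L)
  axis <- term_axis(hpp, terms, cohort$geometry,
                    n_surrogates = n_surrogates, seed = seed + 2L)
  pos_terms <- attr(axis, "positive_set")
  neg_terms <- attr(axis, "negative_set")
  sweep_res <- contrast_res <- NULL
  if (length(pos_terms) > 0 && length(neg_terms) > 0) {
    pos_map <- combine_term_maps(terms$z_maps[pos_terms, , drop = FALSE])
    neg_map <- combine_term_maps(terms$z_maps[neg_terms, , drop = FALSE])
    sweep_res <- roi_sweep(pos_map, neg_map, hurst$values,
                           scores$pattern_score, z_grid = z_grid,
                           n_perm = min(n_perm, 500), seed = seed + 3L)
    contrast_res <- block_contrast_analysis(h2, h0, pos_map, neg_map,
                                            z_grid = z_grid,
                                            behavior = cohort$behavior,
                                            pattern_scores = scores,
                                            n_boot = min(n_boot, 500),
                                            seed = seed + 4L)
  }

  cv <- NULL
  if (!is.null(k_folds)) {
    folds <- stratified_folds(
      data.frame(stratum = cohort$weights$stratum,
                 severity = cohort$factors$general),
      k = k_folds, seed = seed + 5L)
    cv <- crossval_pls(hurst, cohort$factors, cohort$behavior, folds,
                       cohort$geometry, full_model = model,
                       n_surrogates = n_surrogates, seed = seed + 6L)
  }

  sensitivity <- list()
  loading_cor_with <- function(m2) {
    u2 <- m2$brain_loadings[, 1]
    u1 <- model$brain_loadings[, 1]
    if (sum(u1 * u2) < 0) u2 <- -u2
    spearman_cor(u1, u2)
  }
  if (family_dedup) {
    keep <- with_seed(seed + 7L, {
      idx <- sample.int(nrow(cohort$weights))
      idx[!duplicated(cohort$weights$family[idx])]
    })
    m2 <- fit_pls(hurst$values[keep, , drop = FALSE],
                  cohort$factors[keep, , drop = FALSE])
    sensitivity$family_dedup <- list(n_kept = length(keep),
                                     loading_cor = loading_cor_with(m2))
  }
  if (alternate_outcomes) {
    m2 <- fit_pls(hurst$values, cohort$syndrome_scales)
    sensitivity$alternate_outcomes <- list(loading_cor = loading_cor_with(m2))
  }
  if (motion_censor_emulation) {
    keep <- with_seed(seed + 8L,
                      sort(sample.int(config$n_subjects,
                                      round(0.9 * config$n_subjects))))
    m2 <- fit_pls(hurst$values[keep, , drop = FALSE],
                  cohort$factors[keep, , drop = FALSE])
    sensitivity$motion_censor <- list(n_kept = length(keep),
                                      loading_cor = loading_cor_with(m2))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("hurstpls")),
    cohort_seed = config$seed, pipeline_seed = seed,
    n_subjects = config$n_subjects, n_parcels = config$n_parcels,
    n_perm = n_perm, n_boot = n_boot, n_surrogates = n_surrogates,
    weighted = weighted,
    lv1_p = model$perm_p[1],
    lv1_cov_explained = model$covariance_explained[1],
    n_stable_parcels = sum(mask$stable),
    positive_terms = pos_terms, negative_terms = neg_terms
  )

  result <- structure(
    list(cohort = cohort, hurst = hurst, h2back = h2, h0back = h0,
         model = model, mask = mask, pattern_scores = scores,
         terms = terms, term_axis = axis, roi_sweep = sweep_res,
         block_contrast = contrast_res, cv = cv,
         sensitivity = sensitivity, manifest = manifest),
    class = "pipeline_result"
  )
  if (!is.null(out_dir)) write_pipeline(result, out_dir)
  result
}

write_pipeline <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_table(result$hurst$values, file.path(out_dir, "hurst.tsv"))
  write_table(result$hurst$fit_quality, file.path(out_dir, "hurst_r2.tsv"))
  write_table(result$model$brain_loadings,
              file.path(out_dir, "brain_loadings.tsv"))
  write_table(result$model$design_loadings,
              file.path(out_dir, "design_loadings.tsv"))
  write_table(result$pattern_scores, file.path(out_dir, "pattern_scores.tsv"))
  write_table(result$cohort$factors, file.path(out_dir, "factors.tsv"))
  write_table(result$cohort$behavior, file.path(out_dir, "behavior.tsv"))
  write_table(result$cohort$weights, file.path(out_dir, "weights.tsv"))
  write_table(result$cohort$geometry$centroids,
              file.path(out_dir, "centroids.tsv"))
  write_table(result$cohort$design, file.path(out_dir, "block_design.tsv"))
  write_table(as.data.frame(result$term_axis),
              file.path(out_dir, "term_axis.tsv"))
  if (!is.null(result$roi_sweep)) {
    write_table(as.data.frame(result$roi_sweep),
                file.path(out_dir, "roi_sweep.tsv"))
  }
  if (!is.null(result$cv)) {
    write_table(as.data.frame(result$cv), file.path(out_dir, "cv.tsv"))
  }
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  m <- x$manifest
  cat("Pipeline run\n")
  cat(sprintf("  cohort: %d subjects x %d parcels\n", m$n_subjects,
              m$n_parcels))
  cat(sprintf("  LV1: p = %.4g, %.0f%% covariance explained, %d stable parcels\n",
              m$lv1_p, 100 * m$lv1_cov_explained, m$n_stable_parcels))
  cat(sprintf("  term axis: %d positive, %d negative term(s)\n",
              length(m$positive_terms), length(m$negative_terms)))
  invisible(x)
}
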