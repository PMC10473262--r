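#' Parcellated time-series panel
#'
#' Container for subjects x parcels x time BOLD-like signals. Multiple runs
#' may be supplied as a list of identically shaped arrays; estimation
#' averages them frame-wise per subject before fitting, mirroring the usual
#' multi-run treatment.
#'
#' @param bold a subjects x parcels x time array, or a list of such arrays
#'   (one per run).
#' @param tr repetition time in seconds.
#' @param design optional block-design tibble (see [make_block_design()]).
#' @return an object of class `ts_panel`.
#' @export
ts_panel <- function(bold, tr, design = NULL) {
  if (is.list(bold) && !is.array(bold)) {
    dims <- unique(lapply(bold, dim))
    if (length(dims) != 1L || length(dims[[1]]) != 3L) {
      stop("All runs must be subjects x parcels x time arrays of one shape.",
           call. = FALSE)
    }
    runs <- bold
  } else {
    if (length(dim(bold)) != 3L) {
      stop("`bold` must be a subjects x parcels x time array.", call. = FALSE)
    }
    runs <- list(bold)
  }
  if (any(vapply(runs, function(r) any(!is.finite(r)), logical(1)))) {
    stop("Panel contains non-finite values.", call. = FALSE)
  }
  assert_scalar_number(tr, "tr", 0, Inf, strict = TRUE)
  if (!is.null(design)) validate_block_design(design, dim(runs[[1]])[3])
  structure(list(runs = runs, tr = tr, design = design), class = "ts_panel")
}

as_ts_panel <- function(x) {
  if (inherits(x, "ts_panel")) return(x)
  stop("Expected a `ts_panel` (see ts_panel()).", call. = FALSE)
}

panel_mean_runs <- function(panel) {
  if (length(panel$runs) == 1L) return(panel$runs[[1]])
  Reduce(`+`, panel$runs) / length(panel$runs)
}

#' @export
print.ts_panel <- function(x, ...) {
  d <- dim(x$runs[[1]])
  cat(sprintf("ts_panel: %d subjects x %d parcels x %d frames, %d run(s), tr = %g s\n",
              d[1], d[2], d[3], length(x$runs), x$tr))
  invisible(x)
}

#' Block design for an n-back style task
#'
#' Lays out alternating 0-back and 2-back blocks separated by fixation, in
#' the spirit of the emotional n-back task (four blocks of each load
#' condition per run). Onsets are 0-based frame indices.
#'
#' @param n_time frames in the run.
#' @param n_blocks_per_condition task blocks per load condition.
#' @param block_length frames per task block.
#' @param lead_fixation frames of fixation before the first block.
#' @param gap_fixation frames of fixation between consecutive blocks.
#' @return tibble with columns `condition`, `onset`, `duration`.
#' @export
make_block_design <- function(n_time = 362, n_blocks_per_condition = 4,
                              block_length = 40, lead_fixation = 10,
                              gap_fixation = 4) {
  conds <- rep(c("0-back", "2-back"), n_blocks_per_condition)
  n_blocks <- length(conds)
  onsets <- lead_fixation +
    (seq_len(n_blocks) - 1L) * (block_length + gap_fixation)
  design <- tibble::tibble(condition = conds,
                           onset = as.integer(onsets),
                           duration = as.integer(block_length))
  validate_block_design(design, n_time)
  design
}

validate_block_design <- function(design, n_time) {
  stopifnot(is.data.frame(design),
            all(c("condition", "onset", "duration") %in% names(design)))
  if (any(design$onset + design$duration > n_time)) {
    stop("Block design extends past n_time = ", n_time, ".", call. = FALSE)
  }
  d <- design[order(design$onset), ]
  if (nrow(d) > 1L &&
      any(d$onset[-1] < (d$onset + d$duration)[-nrow(d)])) {
    stop("Blocks overlap in the design.", call. = FALSE)
  }
  invisible(design)
}

#' Parcel geometry from centroid coordinates
#'
#' @param centroids n_parcels x 3 matrix of centroid coordinates (mm).
#' @return object of class `parcel_geometry` with `centroids` and the
#'   Euclidean `distance` matrix.
#' @export
parcel_geometry <- function(centroids) {
  centroids <- as.matrix(centroids)
  if (ncol(centroids) != 3L) stop("`centroids` must be n x 3.", call. = FALSE)
  d <- as.matrix(stats::dist(centroids))
  structure(list(centroids = centroids, distance = d),
            class = "parcel_geometry")
}

# Uniform centroids in a brain-sized box (mm); no anatomical files needed.
random_geometry <- function(n_parcels) {
  parcel_geometry(cbind(stats::runif(n_parcels, 0, 140),
                        stats::runif(n_parcels, 0, 170),
                        stats::runif(n_parcels, 0, 120)))
}

#' Cohort generator configuration
#'
#' Describes the statistical world the synthetic cohort is drawn from: a
#' one-dimensional latent severity score couples a spatial pattern of Hurst
#' reductions to psychopathology factor scores (loaded on the general and
#' ADHD factors), task ability drives both behavior and block-level H
#' suppression in "cognitive" parcels, and stratified inclusion
#' probabilities produce realistic survey weights.
#'
#' @param n_subjects number of subjects.
#' @param n_parcels number of parcels (study-scale default 392; tests use
#'   fewer).
#' @param n_time frames per run (default 362).
#' @param tr repetition time in seconds (default 0.8).
#' @param baseline_h per-parcel mean Hurst level; `NULL` draws
#'   `0.72 + 0.08 * z` per parcel (clamped to (0.5, 0.85)) — a plausible
#'   task-fMRI prior kept clear of the H clamp so planted effects stay
#'   linear; configurable because the empirical distribution is not pinned
#'   down.
#' @param latent_brain_loadings per-parcel nonnegative weights of the
#'   planted Hurst-reduction pattern; `NULL` plants a brain-wide pattern
#'   (0.4 global + up to 0.6 from a smooth local field) whose top-30%
#'   parcels double as the "cognitive" set where task-load suppression
#'   operates. When supplied explicitly, the cognitive set is the top 30%
#'   of the supplied vector.
#' @param latent_design_loadings named 4-vector over
#'   (general, externalizing, internalizing, adhd).
#' @param latent_effect_sd scale of the latent effect on H (H units per
#'   unit latent score at loading 1).
#' @param noise_sd_h per-cell independent noise on true H.
#' @param factor_noise_sd independent noise on each factor score; the
#'   implied latent-to-factor correlation is
#'   `l / sqrt(l^2 + factor_noise_sd^2)`.
#' @param suppression_effect block-level H reduction in cognitive parcels
#'   per unit ability during 2-back blocks.
#' @param behavior_coupling correlation scale between (negative) latent
#'   severity and task ability, between 0 and 1.
#' @param n_strata number of sampling strata.
#' @param sibling_rate fraction of subjects given a shared family id.
#' @param n_time frames per run.
#' @param seed integer seed; every cohort is a deterministic function of
#'   (config, seed).
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects, n_parcels = 392L, n_time = 362L,
                          tr = 0.8, baseline_h = NULL,
                          latent_brain_loadings = NULL,
                          latent_design_loadings = c(general = 0.8,
                                                     externalizing = 0.1,
                                                     internalizing = 0.1,
                                                     adhd = 0.55),
                          latent_effect_sd = 0.08, noise_sd_h = 0.05,
                          factor_noise_sd = 0.6,
                          suppression_effect = 0.12,
                          behavior_coupling = 0.6, n_strata = 5L,
                          sibling_rate = 0.1, seed = 1L) {
  n_subjects <- assert_count(n_subjects, "n_subjects")
  n_parcels <- assert_count(n_parcels, "n_parcels")
  n_time <- assert_count(n_time, "n_time", 16L)
  assert_scalar_number(tr, "tr", 0, Inf, strict = TRUE)
  if (!is.null(baseline_h)) {
    stopifnot(length(baseline_h) == n_parcels)
    if (any(baseline_h <= 0 | baseline_h >= 1)) {
      stop("`baseline_h` must lie strictly inside (0, 1).", call. = FALSE)
    }
  }
  if (!is.null(latent_brain_loadings) &&
      length(latent_brain_loadings) != n_parcels) {
    stop("`latent_brain_loadings` must have length n_parcels.", call. = FALSE)
  }
  if (length(latent_design_loadings) != 4L) {
    stop("`latent_design_loadings` must be a 4-vector over ",
         "(general, externalizing, internalizing, adhd).", call. = FALSE)
  }
  assert_scalar_number(latent_effect_sd, "latent_effect_sd", 0, Inf)
  assert_scalar_number(noise_sd_h, "noise_sd_h", 0, Inf)
  assert_scalar_number(behavior_coupling, "behavior_coupling", 0, 1)
  structure(
    list(n_subjects = n_subjects, n_parcels = n_parcels, n_time = n_time,
         tr = tr, baseline_h = baseline_h,
         latent_brain_loadings = latent_brain_loadings,
         latent_design_loadings = latent_design_loadings,
         latent_effect_sd = latent_effect_sd, noise_sd_h = noise_sd_h,
         factor_noise_sd = factor_noise_sd,
         suppression_effect = suppression_effect,
         behavior_coupling = behavior_coupling,
         n_strata = assert_count(n_strata, "n_strata"),
         sibling_rate = sibling_rate,
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}

clamp_h <- function(h) pmin(pmax(h, 0.05), 0.95)

#' Simulate a synthetic cohort with planted latent structure
#'
#' Generates everything the analysis pipeline consumes: parcellated
#' BOLD-like fGn time series with per-cell true Hurst exponents, factor
#' scores coupled to a latent severity score, n-back behavior coupled to
#' ability, stratified sampling weights, parcel geometry, a block design,
#' and the ground truth needed for recovery tests.
#'
#' Per subject i and parcel j the true full-run Hurst exponent is
#' `clamp(baseline_h[j] - loading[j] * latent[i] * latent_effect_sd + noise)`,
#' clamped to `[0.05, 0.95]`. During 2-back blocks, parcels in the cognitive
#' set (loading above half its maximum) have H further reduced by
#' `suppression_effect * ability[i]`; block-modulated series are built by
#' concatenating condition-specific fGn segments so that block-level truth
#' is well defined.
#'
#' @param config a [cohort_config()].
#' @param generate_timeseries set `FALSE` to skip BOLD synthesis (fast path
#'   when only true H fields, scores, behavior and weights are needed).
#' @return a list of class `cohort` with elements `panel`, `factors`,
#'   `syndrome_scales`, `behavior`, `weights`, `geometry`, `design`, and
#'   `truth` (planted parameters: `true_h`, `latent_scores`, `ability`,
#'   `cognitive_parcels`, implied factor correlations, config).
#' @export
simulate_cohort <- function(config, generate_timeseries = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, simulate_cohort_impl(config, generate_timeseries))
}

simulate_cohort_impl <- function(config, generate_timeseries) {
  ns <- config$n_subjects; np <- config$n_parcels; nt <- config$n_time
  geometry <- random_geometry(np)

  baseline <- config$baseline_h
  if (is.null(baseline)) {
    # Kept below ~0.85 so the planted effects rarely hit the [0.05, 0.95]
    # clamp, which would otherwise attenuate the latent pattern.
    baseline <- pmin(pmax(0.72 + 0.08 * stats::rnorm(np), 0.5), 0.85)
  }
  loadings <- config$latent_brain_loadings
  cog_field <- NULL
  if (is.null(loadings)) {
    # Distributed severity pattern: a global component everywhere plus a
    # smooth local component that peaks in the "cognitive" parcel set, so
    # the severity effect is brain-wide while still spatially patterned.
    cog_field <- grf_maps(1, geometry, smoothness = 40)[1, ]
    f01 <- (cog_field - min(cog_field)) / diff(range(cog_field))
    loadings <- 0.4 + 0.6 * f01
  } else {
    cog_field <- loadings
  }
  latent <- stats::rnorm(ns)

  dl <- config$latent_design_loadings
  factor_mat <- outer(latent, dl) +
    matrix(stats::rnorm(ns * 4, sd = config$factor_noise_sd), ns, 4)
  colnames(factor_mat) <- names(dl)
  # Alternate outcome set: CBCL-syndrome-like scales, all loaded positively
  # on the same latent severity.
  n_scales <- 8L
  scale_load <- stats::runif(n_scales, 0.3, 0.8)
  syndrome <- outer(latent, scale_load) +
    matrix(stats::rnorm(ns * n_scales, sd = config$factor_noise_sd), ns)
  colnames(syndrome) <- paste0("scale_", seq_len(n_scales))

  noise <- matrix(stats::rnorm(ns * np, sd = config$noise_sd_h), ns, np)
  true_h <- clamp_h(
    matrix(baseline, ns, np, byrow = TRUE) -
      config$latent_effect_sd * outer(latent, loadings) + noise
  )

  b <- config$behavior_coupling
  ability <- -b * latent + sqrt(max(1 - b^2, 0)) * stats::rnorm(ns)
  hit <- stats::plogis(1.4 + 0.8 * ability)
  fa <- stats::plogis(-1.4 - 0.8 * ability)
  behavior <- tibble::tibble(
    subject = seq_len(ns), hit = hit, fa = fa,
    dprime = dprime(hit, fa),
    accuracy_2back = stats::plogis(1.2 + 0.7 * ability +
                                     0.2 * stats::rnorm(ns)),
    out_of_scanner_score = 0.5 * ability + stats::rnorm(ns, sd = 0.8)
  )

  # Strata on a demographic proxy mildly correlated with severity; inclusion
  # probabilities evenly spread over [0.2, 1].
  proxy <- 0.4 * latent + stats::rnorm(ns)
  stratum <- cut(proxy,
                 breaks = stats::quantile(proxy,
                                          probs = seq(0, 1,
                                                      length.out = config$n_strata + 1L)),
                 include.lowest = TRUE, labels = FALSE)
  incl <- seq(0.2, 1.0, length.out = config$n_strata)[stratum]
  family <- seq_len(ns)
  n_sib <- floor(config$sibling_rate * ns / 2)
  if (n_sib > 0) {
    pairs <- matrix(sample(ns, 2 * n_sib), ncol = 2)
    family[pairs[, 2]] <- family[pairs[, 1]]
  }
  weights <- tibble::tibble(
    subject = seq_len(ns), stratum = stratum,
    inclusion_prob = incl, weight = 1 / incl, family = family
  )

  design <- make_block_design(nt)
  cognitive <- which(cog_field > stats::quantile(cog_field, 0.7))

  panel <- NULL
  if (generate_timeseries) {
    bold <- array(0, dim = c(ns, np, nt))
    seg <- design_segments(design, nt)
    for (i in seq_len(ns)) {
      supp <- config$suppression_effect * ability[i]
      for (j in seq_len(np)) {
        h0 <- true_h[i, j]
        if (j %in% cognitive && supp != 0) {
          x <- numeric(nt)
          for (s in seq_len(nrow(seg))) {
            h_seg <- if (seg$condition[s] == "2-back") clamp_h(h0 - supp) else h0
            idx <- seg$from[s]:seg$to[s]
            x[idx] <- if (length(idx) == 1L) stats::rnorm(1)
                      else fgn_core(h_seg, length(idx))
          }
          bold[i, j, ] <- x
        } else {
          bold[i, j, ] <- fgn_core(h0, nt)
        }
      }
    }
    panel <- ts_panel(bold, tr = config$tr, design = design)
  }

  implied_factor_cor <- dl / sqrt(dl^2 + config$factor_noise_sd^2)
  structure(
    list(panel = panel,
         factors = tibble::as_tibble(cbind(tibble::tibble(subject = seq_len(ns)),
                                           as.data.frame(factor_mat))),
         syndrome_scales = tibble::as_tibble(
           cbind(tibble::tibble(subject = seq_len(ns)),
                 as.data.frame(syndrome))),
         behavior = behavior, weights = weights, geometry = geometry,
         design = design,
         truth = list(true_h = true_h, latent_scores = latent,
                      ability = ability, baseline_h = baseline,
                      latent_brain_loadings = loadings,
                      cognitive_parcels = cognitive,
                      implied_factor_cor = implied_factor_cor,
                      config = config)),
    class = "cohort"
  )
}

# Partition [1, n_time] into consecutive segments labelled by block
# condition, with inter-block frames labelled "fixation".
design_segments <- function(design, n_time) {
  design <- design[order(design$onset), ]
  from <- integer(0); to <- integer(0); cond <- character(0)
  cursor <- 1L
  for (b in seq_len(nrow(design))) {
    s <- design$onset[b] + 1L
    e <- design$onset[b] + design$duration[b]
    if (s > cursor) {
      from <- c(from, cursor); to <- c(to, s - 1L); cond <- c(cond, "fixation")
    }
    from <- c(from, s); to <- c(to, e); cond <- c(cond, design$condition[b])
    cursor <- e + 1L
  }
  if (cursor <= n_time) {
    from <- c(from, cursor); to <- c(to, n_time); cond <- c(cond, "fixation")
  }
  tibble::tibble(condition = cond, from = from, to = to)
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects, %d parcels%s\n",
              nrow(x$truth$true_h), ncol(x$truth$true_h),
              if (is.null(x$panel)) " (no time series)" else ""))
  invisible(x)
}

# Gaussian random fields over parcel centroids with exponential covariance
# exp(-d / smoothness); rows are maps. smoothness -> 0 gives i.i.d. fields.
grf_maps <- function(n_maps, geometry, smoothness) {
  if (smoothness <= 0) stop("`smoothness` must be positive.", call. = FALSE)
  np <- nrow(geometry$distance)
  sigma <- exp(-geometry$distance / smoothness)
  ch <- chol(sigma + diag(1e-8, np))
  z <- matrix(stats::rnorm(n_maps * np), n_maps, np)
  z %*% ch
}

#' Simulate meta-analytic term-association maps
#'
#' Each term map is a Gaussian random field over the parcel centroids with
#' exponential spatial covariance of the given length scale, standardized to
#' z-scores. Optionally a subset of terms is "planted": they mix in (plus or
#' minus) a standardized target map with weight `mixing_weight`, emulating
#' terms genuinely associated with a brain pattern.
#'
#' @param geometry a [parcel_geometry()].
#' @param n_terms number of term maps.
#' @param smoothness spatial length scale in mm (> 0).
#' @param planted_target optional per-parcel map mixed into planted terms.
#' @param n_planted_pos,n_planted_neg number of terms mixing in
#'   `+planted_target` / `-planted_target`; their sum must not exceed
#'   `n_terms`.
#' @param mixing_weight mixing weight between 0 and 1; 1 reproduces the target
#'   exactly.
#' @param seed integer seed.
#' @return object of class `term_map_set`: list with `labels`, `z_maps`
#'   (terms x parcels), and a `metadata` tibble recording planted status and
#'   mixing weight.
#' @export
simulate_term_maps <- function(geometry, n_terms, smoothness = 30,
                               planted_target = NULL, n_planted_pos = 0,
                               n_planted_neg = 0, mixing_weight = 0.8,
                               seed = NULL) {
  stopifnot(inherits(geometry, "parcel_geometry"))
  n_terms <- assert_count(n_terms, "n_terms")
  if (n_planted_pos + n_planted_neg > n_terms) {
    stop("n_planted_pos + n_planted_neg must not exceed n_terms.",
         call. = FALSE)
  }
  if ((n_planted_pos + n_planted_neg) > 0 && is.null(planted_target)) {
    stop("`planted_target` required when planting terms.", call. = FALSE)
  }
  with_seed(seed, {
    maps <- grf_maps(n_terms, geometry, smoothness)
    planted <- rep("none", n_terms)
    if (n_planted_pos + n_planted_neg > 0) {
      tgt <- as.numeric(scale(planted_target))
      idx <- seq_len(n_planted_pos + n_planted_neg)
      signs <- c(rep(1, n_planted_pos), rep(-1, n_planted_neg))
      for (k in seq_along(idx)) {
        maps[idx[k], ] <- mixing_weight * signs[k] * tgt +
          sqrt(1 - mixing_weight^2) * as.numeric(scale(maps[idx[k], ]))
      }
      planted[idx] <- ifelse(signs > 0, "pos", "neg")
    }
    maps <- t(apply(maps, 1, function(m) as.numeric(scale(m))))
    labels <- sprintf("term_%03d", seq_len(n_terms))
    rownames(maps) <- labels
    structure(
      list(labels = labels, z_maps = maps,
           metadata = tibble::tibble(term = labels, planted = planted,
                                     mixing_weight = ifelse(planted == "none",
                                                            NA_real_,
                                                            mixing_weight))),
      class = "term_map_set"
    )
  })
}
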