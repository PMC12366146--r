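#' Simulation configuration
#'
#' Parameters of the synthetic world. Defaults mirror the clinical cohort the
#' pipeline is designed for: 33 severely affected stroke patients, mean WMH
#' load 15.3 ml split into ~9.5 ml periventricular and ~5.8 ml deep, mean
#' stroke lesion 37.9 ml, age ~ N(70.7, 12.2), NIHSS ~ 7.8 +/- 3.6, and a
#' 7-level ordinal outcome (mRS 0-6) generated from a proportional-odds
#' model.
#'
#' @param grid_shape voxel counts per axis (length 1 or 3).
#' @param voxel_size_mm voxel edge length(s) in mm (length 1 or 3).
#' @param n_regions number of atlas regions (>= 2).
#' @param n_streamlines reference streamline count.
#' @param n_patients cohort size.
#' @param pwmh_volume_ml,dwmh_volume_ml expected periventricular / deep WMH
#'   volumes per patient (ml); dwmh may be 0.
#' @param stroke_volume_ml expected stroke lesion volume (ml).
#' @param causal_region_ids regions whose disconnectivity truly affects the
#'   outcome (subset of 1..n_regions).
#' @param causal_mask_type which mask type's ChaCo drives the outcome.
#' @param beta_disconnect log-odds effect of the dichotomized high-
#'   disconnectivity indicator (proportional-odds scale).
#' @param beta_age,beta_nihss,beta_logvol covariate effects (per year, per
#'   NIHSS point, per log10-ml; `beta_logvol` applies to both lesion and WMH
#'   volume).
#' @param n_outcome_levels ordinal outcome levels (default 7, mRS 0-6).
#' @param seed integer master seed.
#' @return validated list of class `simulation_config`.
#' @export
simulation_config <- function(grid_shape = c(40, 40, 40),
                              voxel_size_mm = 2,
                              n_regions = 12,
                              n_streamlines = 600,
                              n_patients = 33,
                              pwmh_volume_ml = 9.5,
                              dwmh_volume_ml = 5.8,
                              stroke_volume_ml = 37.9,
                              causal_region_ids = c(1L, 2L),
                              causal_mask_type = "pwmh",
                              beta_disconnect = 2,
                              beta_age = 0.03,
                              beta_nihss = 0.15,
                              beta_logvol = 0.5,
                              n_outcome_levels = 7,
                              seed = 1) {
  grid_shape <- as.integer(rep(grid_shape, length.out = 3))
  voxel_size_mm <- rep(as.numeric(voxel_size_mm), length.out = 3)
  stopifnot(all(grid_shape >= 5), all(voxel_size_mm > 0))
  if (n_regions < 2) stop("n_regions must be >= 2")
  if (n_outcome_levels < 2) stop("n_outcome_levels must be >= 2")
  if (pwmh_volume_ml <= 0) stop("pwmh_volume_ml must be > 0")
  if (dwmh_volume_ml < 0) stop("dwmh_volume_ml must be >= 0")
  if (stroke_volume_ml <= 0) stop("stroke_volume_ml must be > 0")
  causal_region_ids <- as.integer(causal_region_ids)
  if (length(causal_region_ids) &&
      !all(causal_region_ids %in% seq_len(n_regions)))
    stop("causal_region_ids must be a subset of 1..n_regions")
  causal_mask_type <- match.arg(causal_mask_type, c("pwmh", "dwmh", "wmh", "stroke"))
  stopifnot(is.finite(beta_disconnect), is.finite(beta_age),
            is.finite(beta_nihss), is.finite(beta_logvol))
  structure(list(grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
                 n_regions = as.integer(n_regions),
                 n_streamlines = as.integer(n_streamlines),
                 n_patients = as.integer(n_patients),
                 pwmh_volume_ml = pwmh_volume_ml,
                 dwmh_volume_ml = dwmh_volume_ml,
                 stroke_volume_ml = stroke_volume_ml,
                 causal_region_ids = causal_region_ids,
                 causal_mask_type = causal_mask_type,
                 beta_disconnect = beta_disconnect,
                 beta_age = beta_age, beta_nihss = beta_nihss,
                 beta_logvol = beta_logvol,
                 n_outcome_levels = as.integer(n_outcome_levels),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# affine putting the grid centre at world origin, axis-aligned
config_affine <- function(config) {
  A <- diag(c(config$voxel_size_mm, 1))
  A[1:3, 4] <- -(config$grid_shape - 1) / 2 * config$voxel_size_mm
  A
}

#' Generate a toy atlas and ventricle mask
#'
#' Places `n_regions` non-overlapping spherical regions by rejection
#' sampling around a central ellipsoidal "ventricle" structure. Regions near
#' the grid boundary are flagged cortical, central ones subcortical;
#' hemisphere is decided by the first-axis midplane.
#'
#' @param config a `simulation_config`.
#' @return list with `atlas` (integer labels 1..n_regions, 0 background),
#'   `ventricles` (binary `labeled_volume`) and `regions` (metadata
#'   data.frame: region_id, name, hemisphere, cortical).
#' @export
make_atlas <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(derive_seed(config$seed, 1L), {
    dm <- config$grid_shape
    A <- config_affine(config)
    half_ext <- (dm - 1) / 2 * config$voxel_size_mm
    # voxel centre coordinates
    xs <- lapply(1:3, function(a) ((seq_len(dm[a]) - 1) - (dm[a] - 1) / 2) *
                   config$voxel_size_mm[a])
    X <- xs[[1]][slice.index(array(0, dm), 1)]
    Y <- xs[[2]][slice.index(array(0, dm), 2)]
    Z <- xs[[3]][slice.index(array(0, dm), 3)]
    # central ellipsoidal ventricles: thin left-right, long front-back
    semi <- pmax(c(0.09, 0.30, 0.16) * half_ext, config$voxel_size_mm)
    vent <- array(as.numeric((X / semi[1])^2 + (Y / semi[2])^2 +
                               (Z / semi[3])^2 <= 1), dm)
    if (sum(vent) == 0)
      stop("grid too small: central ventricle ellipsoid contains no voxel")
    r <- max(1.5 * max(config$voxel_size_mm), 0.06 * min(2 * half_ext))
    centers <- matrix(NA_real_, config$n_regions, 3)
    placed <- 0L
    budget <- 500L * config$n_regions
    tries <- 0L
    while (placed < config$n_regions && tries < budget) {
      tries <- tries + 1L
      c_try <- vapply(1:3, function(a)
        stats::runif(1, -half_ext[a] + r, half_ext[a] - r), numeric(1))
      if (sum((c_try / (semi + r))^2) <= 1) next  # would clip the ventricles
      if (placed > 0) {
        dmin <- min(sqrt(rowSums((centers[seq_len(placed), , drop = FALSE] -
                                    matrix(c_try, placed, 3, byrow = TRUE))^2)))
        if (dmin < 2 * r + min(config$voxel_size_mm)) next
      }
      placed <- placed + 1L
      centers[placed, ] <- c_try
    }
    if (placed < config$n_regions)
      stop("grid too small to place ", config$n_regions,
           " non-overlapping regions of radius ", signif(r, 3),
           " mm (placed ", placed, " in ", budget, " attempts); ",
           "enlarge grid_shape or reduce n_regions")
    lab <- array(0, dm)
    for (k in seq_len(config$n_regions)) {
      inside <- (X - centers[k, 1])^2 + (Y - centers[k, 2])^2 +
        (Z - centers[k, 3])^2 <= r^2
      lab[inside & lab == 0 & vent == 0] <- k
    }
    if (!all(seq_len(config$n_regions) %in% unique(as.vector(lab))))
      stop("grid too small: a placed region of radius ", signif(r, 3),
           " mm covers no voxel centre")
    rho <- sqrt(rowSums((centers / matrix(half_ext, config$n_regions, 3,
                                          byrow = TRUE))^2) / 3)
    regions <- data.frame(
      region_id = seq_len(config$n_regions),
      name = sprintf("region_%02d", seq_len(config$n_regions)),
      hemisphere = ifelse(centers[, 1] < 0, "L", "R"),
      cortical = rho > 0.45,
      stringsAsFactors = FALSE)
    list(atlas = labeled_volume(lab, A),
         ventricles = labeled_volume(vent, A),
         regions = regions)
  })
}

#' Generate a synthetic reference streamline connectome
#'
#' Streamline endpoints are voxel centres of two (possibly identical) atlas
#' regions; interior points follow the straight line between the endpoints,
#' resampled at half-voxel steps, with Gaussian jitter. Every region is
#' guaranteed to be the endpoint of at least one streamline (bounded
#' resampling, else an error naming the uncovered regions).
#'
#' @param atlas output of [make_atlas()] (or a compatible list with `atlas`
#'   and `regions`).
#' @param config a `simulation_config`.
#' @return a `streamline_set` with endpoint regions assigned.
#' @export
make_streamlines <- function(atlas, config) {
  stopifnot(inherits(config, "simulation_config"))
  vol <- atlas$atlas
  n_regions <- config$n_regions
  if (length(unique(setdiff(as.vector(vol$data), 0))) < 2)
    stop("atlas must contain at least 2 regions")
  with_seed(derive_seed(config$seed, 2L), {
    dm <- dim(vol$data)
    region_vox <- lapply(seq_len(n_regions), function(r) which(vol$data == r))
    step <- 0.5 * min(voxel_sizes(vol))
    jitter_sd <- 0.3 * min(voxel_sizes(vol))
    pairs <- NULL
    for (attempt in 1:50) {
      cand <- cbind(sample.int(n_regions, config$n_streamlines, replace = TRUE),
                    sample.int(n_regions, config$n_streamlines, replace = TRUE))
      if (all(seq_len(n_regions) %in% as.vector(cand))) { pairs <- cand; break }
    }
    if (is.null(pairs)) {
      miss <- setdiff(seq_len(n_regions), as.vector(cand))
      stop("could not cover region(s) ", paste(miss, collapse = ", "),
           " with ", config$n_streamlines, " streamlines after 50 attempts")
    }
    sl <- vector("list", config$n_streamlines)
    for (s in seq_len(config$n_streamlines)) {
      a <- voxel_mm_coords(sample(region_vox[[pairs[s, 1]]], 1), dm, vol$affine)
      b <- voxel_mm_coords(sample(region_vox[[pairs[s, 2]]], 1), dm, vol$affine)
      path <- resample_polyline(rbind(a, b), step)
      n_mid <- nrow(path) - 2L
      if (n_mid > 0) {
        path[2:(nrow(path) - 1L), ] <- path[2:(nrow(path) - 1L), ] +
          matrix(stats::rnorm(3 * n_mid, 0, jitter_sd), n_mid, 3)
      }
      sl[[s]] <- path
    }
    streamline_set(sl, pairs)
  })
}

#' Generate one patient's WMH and stroke masks
#'
#' The WMH mask is the union of a periventricular rim component seeded
#' inside the 10 mm band around the ventricles and isolated deep spots
#' beyond the band; expected component volumes come from the config with
#' lognormal between-patient variation. The stroke mask is a single random
#' blob. All masks are binary on the atlas grid.
#'
#' @param atlas `labeled_volume` defining the grid (labels unused).
#' @param ventricles binary `labeled_volume`, nonempty.
#' @param config a `simulation_config`.
#' @param patient_seed integer seed for this patient (see
#'   [derive_seed()]-style derivation in [simulate_cohort()]).
#' @param dist_mm optional precomputed `edt_mm(ventricles)`.
#' @param band_mm periventricular band width (mm), default 10.
#' @return list with binary `labeled_volume`s `wmh` and `stroke`.
#' @export
make_patient_masks <- function(atlas, ventricles, config, patient_seed,
                               dist_mm = NULL, band_mm = 10) {
  stopifnot(inherits(config, "simulation_config"))
  if (sum(ventricles$data) == 0) stop("ventricle mask is empty")
  if (is.null(dist_mm)) dist_mm <- edt_mm(ventricles)
  dm <- dim(atlas$data)
  vox_ml <- abs(det(atlas$affine[1:3, 1:3])) / 1000
  band_idx <- which(ventricles$data == 0 & dist_mm <= band_mm)
  deep_idx <- which(dist_mm > band_mm)
  tissue_idx <- which(ventricles$data == 0)
  if (!length(band_idx)) stop("no voxels inside the periventricular band")
  with_seed(patient_seed, {
    lognorm <- function() exp(stats::rnorm(1, 0, 0.25) - 0.25^2 / 2)
    pick_blobs <- function(pool_idx, n_target, n_seeds) {
      coords <- voxel_mm_coords(pool_idx, dm, atlas$affine)
      chosen <- integer(0)
      remaining <- seq_along(pool_idx)
      per <- ceiling(n_target / n_seeds)
      for (s in seq_len(n_seeds)) {
        if (!length(remaining) || length(chosen) >= n_target) break
        ctr <- coords[remaining[sample.int(length(remaining), 1)], ]
        d <- sqrt(rowSums((coords[remaining, , drop = FALSE] -
                             matrix(ctr, length(remaining), 3, byrow = TRUE))^2))
        take <- remaining[order(d)[seq_len(min(per, length(remaining)))]]
        chosen <- c(chosen, take)
        remaining <- setdiff(remaining, take)
      }
      pool_idx[chosen[seq_len(min(length(chosen), n_target))]]
    }
    n_p <- max(1L, round(config$pwmh_volume_ml / vox_ml * lognorm()))
    n_p <- min(n_p, floor(0.8 * length(band_idx)))
    n_p <- max(n_p, 1L)
    p_idx <- pick_blobs(band_idx, n_p, n_seeds = 2L)
    d_idx <- integer(0)
    if (config$dwmh_volume_ml > 0 && length(deep_idx)) {
      n_d <- max(1L, round(config$dwmh_volume_ml / vox_ml * lognorm()))
      n_d <- min(n_d, floor(0.8 * length(deep_idx)))
      d_idx <- pick_blobs(deep_idx, n_d, n_seeds = 3L)
    }
    n_s <- max(1L, round(config$stroke_volume_ml / vox_ml * lognorm()))
    n_s <- min(n_s, floor(0.5 * length(tissue_idx)))
    s_idx <- pick_blobs(tissue_idx, n_s, n_seeds = 1L)
    wmh <- array(0, dm); wmh[c(p_idx, d_idx)] <- 1
    stroke <- array(0, dm); stroke[s_idx] <- 1
    list(wmh = labeled_volume(wmh, atlas$affine),
         stroke = labeled_volume(stroke, atlas$affine))
  })
}

# Covariates for the outcome generator when volumes are not available from
# masks; distributions follow the cohort the pipeline emulates.
sim_covariates <- function(n) {
  data.frame(
    age = clamp(stats::rnorm(n, 70.7, 12.2), 40, 95),
    nihss = round(clamp(stats::rnorm(n, 7.8, 3.6), 1, 17)))
}

# Generative covariate centring constants (population-scale anchors); the
# latent score is centred so that fixed equally spaced cutpoints spread the
# outcome over all levels.
outcome_centers <- list(age = 70.7, nihss = 7.8,
                        log_lesion = log10(37.9), log_wmh = log10(15.3))

#' Draw ordinal outcomes from the generative proportional-odds model
#'
#' latent = beta_disconnect * 1(high) + covariate terms + logistic noise,
#' cut at fixed, equally spaced cutpoints into `n_outcome_levels` grades
#' (0 .. K-1). `high` is the within-sample dichotomization of the causal
#' disconnectivity score at its median (median itself goes to the low
#' group). Cutpoints are returned so recovery tests are identified.
#'
#' @param chaco_truth per-patient causal-region mean disconnectivity.
#' @param covariates data.frame with columns age, nihss, lesion_volume_ml,
#'   wmh_volume_ml.
#' @param config a `simulation_config`.
#' @param seed RNG seed for the noise draw.
#' @return list: `mrs` (integer grades 0..K-1), `high` (0/1 indicator),
#'   `cutpoints`, `eta` (latent linear predictor, noise-free).
#' @export
make_outcomes <- function(chaco_truth, covariates, config,
                          seed = derive_seed(config$seed, 3L)) {
  stopifnot(inherits(config, "simulation_config"))
  n <- length(chaco_truth)
  need <- c("age", "nihss", "lesion_volume_ml", "wmh_volume_ml")
  if (!all(need %in% names(covariates)))
    stop("covariates must have columns ", paste(need, collapse = ", "))
  if (any(!stats::complete.cases(covariates[need])))
    stop("covariates must be complete")
  if (any(covariates$lesion_volume_ml <= 0) || any(covariates$wmh_volume_ml <= 0))
    stop("volumes must be > 0 before log transform")
  med <- stats::median(chaco_truth)
  high <- as.integer(chaco_truth > med)
  eta <- config$beta_disconnect * high +
    config$beta_age * (covariates$age - outcome_centers$age) +
    config$beta_nihss * (covariates$nihss - outcome_centers$nihss) +
    config$beta_logvol * (log10(covariates$lesion_volume_ml) - outcome_centers$log_lesion) +
    config$beta_logvol * (log10(covariates$wmh_volume_ml) - outcome_centers$log_wmh)
  if (any(!is.finite(eta))) stop("non-finite latent score")
  K <- config$n_outcome_levels
  cutpoints <- seq(-2, 2, length.out = K - 1) + config$beta_disconnect / 2
  mrs <- with_seed(seed, {
    z <- eta + stats::rlogis(n)
    rowSums(outer(z, cutpoints, ">"))
  })
  list(mrs = as.integer(mrs), high = high, cutpoints = cutpoints, eta = eta)
}

#' Build the fixed part of a synthetic world
#'
#' Atlas, ventricles, streamlines, ventricle distance map and streamline
#' voxel cache — everything shared across patients and cohorts. Reuse this
#' when simulating many cohorts against one reference connectome.
#'
#' @param config a `simulation_config`.
#' @return list (class `synthetic_world`).
#' @export
simulate_world <- function(config) {
  at <- make_atlas(config)
  sl <- make_streamlines(at, config)
  structure(list(atlas = at$atlas, ventricles = at$ventricles,
                 regions = at$regions, streamlines = sl,
                 dist_mm = edt_mm(at$ventricles),
                 cache = streamline_voxel_cache(sl, at$atlas),
                 config = config),
            class = "synthetic_world")
}

#' Simulate a full synthetic cohort
#'
#' Generates (or reuses) a world, draws per-patient WMH/stroke masks, splits
#' WMH into periventricular and deep components, computes cleaned ChaCo for
#' every mask type, assembles the cohort table (volumes from the masks,
#' age/NIHSS from the cohort distributions) and draws ordinal outcomes from
#' the proportional-odds generator. Per-patient randomness derives from
#' (seed, patient index), so earlier patients are stable when the cohort
#' grows.
#'
#' @param config a `simulation_config`.
#' @param world optional [simulate_world()] result to reuse.
#' @param cohort_stream extra stream offset so many cohorts can share one
#'   world under one master seed.
#' @return list of class `synthetic_cohort`: `world`, `masks` (per patient:
#'   wmh/pwmh/dwmh/stroke), `chaco` (list of patients x regions matrices,
#'   raw and cleaned, per mask type), `cohort` (data.frame), `truth`.
#' @export
simulate_cohort <- function(config, world = NULL, cohort_stream = 0L) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(world)) world <- simulate_world(config)
  n <- config$n_patients
  nr <- config$n_regions
  mask_types <- c("wmh", "pwmh", "dwmh", "stroke")
  raw <- lapply(mask_types, function(t) matrix(NA_real_, n, nr))
  names(raw) <- mask_types
  masks <- vector("list", n)
  vols <- matrix(NA_real_, n, 4,
                 dimnames = list(NULL, c("lesion", "wmh", "pwmh", "dwmh")))
  for (i in seq_len(n)) {
    ps <- derive_seed(config$seed, 1000L + cohort_stream * 100000L + i)
    m <- make_patient_masks(world$atlas, world$ventricles, config, ps,
                            dist_mm = world$dist_mm)
    sp <- split_wmh(m$wmh, world$ventricles, threshold_mm = 10,
                    dist_mm = world$dist_mm)
    pm <- list(wmh = m$wmh, pwmh = sp$pwmh, dwmh = sp$dwmh, stroke = m$stroke)
    masks[[i]] <- pm
    vols[i, ] <- c(mask_volume_ml(m$stroke), mask_volume_ml(m$wmh),
                   mask_volume_ml(sp$pwmh), mask_volume_ml(sp$dwmh))
    for (t in mask_types)
      raw[[t]][i, ] <- compute_chaco(pm[[t]], world$streamlines, nr,
                                     cache = world$cache, mask_type = t,
                                     patient_id = i)
  }
  cleaned <- lapply(raw, clean_chaco)
  for (t in mask_types) {
    dimnames(raw[[t]]) <- dimnames(cleaned[[t]]) <-
      list(sprintf("p%03d", seq_len(n)), paste0("region_", seq_len(nr)))
  }
  cov <- with_seed(derive_seed(config$seed, 4L + cohort_stream * 7L),
                   sim_covariates(n))
  cov$lesion_volume_ml <- pmax(vols[, "lesion"], 1e-3)
  cov$wmh_volume_ml <- pmax(vols[, "wmh"], 1e-3)
  cov$pwmh_volume_ml <- vols[, "pwmh"]
  cov$dwmh_volume_ml <- vols[, "dwmh"]
  causal <- config$causal_region_ids
  cm <- cleaned[[config$causal_mask_type]]
  chaco_truth <- if (length(causal)) {
    v <- rowMeans(cm[, causal, drop = FALSE], na.rm = TRUE)
    ifelse(is.finite(v), v, 0)
  } else rep(0, n)
  out <- make_outcomes(chaco_truth, cov, config,
                       seed = derive_seed(config$seed, 3L + cohort_stream * 13L))
  cohort <- data.frame(patient_id = sprintf("p%03d", seq_len(n)),
                       age = cov$age, nihss = cov$nihss, mrs = out$mrs,
                       lesion_volume_ml = cov$lesion_volume_ml,
                       wmh_volume_ml = cov$wmh_volume_ml,
                       pwmh_volume_ml = cov$pwmh_volume_ml,
                       dwmh_volume_ml = cov$dwmh_volume_ml,
                       stringsAsFactors = FALSE)
  structure(list(world = world, masks = masks,
                 chaco = list(raw = raw, cleaned = cleaned),
                 cohort = cohort,
                 truth = list(config = config, cutpoints = out$cutpoints,
                              high = out$high, chaco_truth = chaco_truth,
                              eta = out$eta,
                              causal_region_ids = causal,
                              causal_mask_type = config$causal_mask_type)),
            class = "synthetic_cohort")
}

#' Simulate an outcomes-only proportional-odds cohort
#'
#' Skips the imaging stages: draws covariates and a continuous
#' disconnectivity score directly, dichotomizes at the sample median, and
#' generates ordinal outcomes from the same proportional-odds generator as
#' [simulate_cohort()]. Used for model-level calibration and recovery
#' studies where the imaging pipeline would only add runtime.
#'
#' @param n cohort size.
#' @param config a `simulation_config` (betas and level count are used).
#' @param seed RNG seed.
#' @return data.frame: age, nihss, lesion_volume_ml, wmh_volume_ml,
#'   chaco_cont, high, mrs; cutpoints in attribute `"cutpoints"`.
#' @export
simulate_outcome_cohort <- function(n, config, seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"))
  cov <- with_seed(derive_seed(seed, 11L), {
    d <- sim_covariates(n)
    d$lesion_volume_ml <- 10^stats::rnorm(n, outcome_centers$log_lesion, 0.45)
    d$wmh_volume_ml <- 10^stats::rnorm(n, outcome_centers$log_wmh, 0.30)
    d$chaco_cont <- stats::rbeta(n, 2, 6)
    d
  })
  out <- make_outcomes(cov$chaco_cont, cov, config,
                       seed = derive_seed(seed, 12L))
  cov$high <- out$high
  cov$mrs <- out$mrs
  attr(cov, "cutpoints") <- out$cutpoints
  cov
}

#' Write a synthetic cohort to disk
#'
#' NIfTI volumes (atlas, ventricles, per-patient masks), streamlines (TCK
#' and the plain-text dialect), region metadata and cohort CSVs, ChaCo CSV,
#' and a truth JSON.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- cohort$world
  write_nifti(w$atlas, file.path(dir, "atlas.nii.gz"))
  write_nifti(w$ventricles, file.path(dir, "ventricles.nii.gz"))
  write_tck(w$streamlines, file.path(dir, "connectome.tck"))
  write_streamlines_text(w$streamlines, file.path(dir, "connectome.txt"))
  utils::write.csv(w$regions, file.path(dir, "regions.csv"), row.names = FALSE)
  mdir <- file.path(dir, "masks")
  dir.create(mdir, showWarnings = FALSE)
  for (i in seq_along(cohort$masks)) {
    for (t in names(cohort$masks[[i]]))
      write_nifti(cohort$masks[[i]][[t]],
                  file.path(mdir, sprintf("p%03d_%s.nii.gz", i, t)))
  }
  utils::write.csv(cohort$cohort, file.path(dir, "cohort.csv"), row.names = FALSE)
  vectors <- list()
  for (t in names(cohort$chaco$cleaned)) {
    m <- cohort$chaco$cleaned[[t]]
    for (i in seq_len(nrow(m)))
      vectors[[length(vectors) + 1L]] <-
        structure(m[i, ], mask_type = t, patient_id = rownames(m)[i],
                  class = "chaco_vector")
  }
  write_chaco_csv(vectors, file.path(dir, "chaco.csv"))
  truth <- cohort$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
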