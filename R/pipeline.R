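#' Load and validate a run configuration
#'
#' YAML (or JSON) with exactly one of a `simulate:` block (fields of
#' [simulation_config()]) or an `inputs:` block (paths: atlas, ventricles,
#' connectome, masks_dir, cohort), plus optional `options:` (floor,
#' threshold_mm, skew_limit, r2_method, ci_method, base_adjust, fdr_alpha),
#' `seed` and `out_dir`.
#'
#' @param path config file path, or a pre-parsed list.
#' @return validated config list of class `run_config`.
#' @export
load_run_config <- function(path) {
  cfg <- if (is.list(path)) path
    else if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
  has_sim <- !is.null(cfg$simulate)
  has_inp <- !is.null(cfg$inputs)
  if (has_sim == has_inp)
    stop("config must contain exactly one of `simulate` or `inputs`")
  opts <- cfg$options %||% list()
  defaults <- list(floor = 0.02, threshold_mm = 10, skew_limit = 1.3,
                   r2_method = "nagelkerke", ci_method = "wald",
                   base_adjust = "wmh_volume", fdr_alpha = 0.05)
  for (nm in names(defaults)) if (is.null(opts[[nm]])) opts[[nm]] <- defaults[[nm]]
  extra <- setdiff(names(opts), names(defaults))
  if (length(extra)) stop("unknown option(s): ", paste(extra, collapse = ", "))
  stopifnot(opts$floor >= 0, opts$threshold_mm >= 0, opts$skew_limit > 0,
            opts$fdr_alpha > 0, opts$fdr_alpha < 1)
  structure(list(simulate = cfg$simulate, inputs = cfg$inputs,
                 options = opts, seed = cfg$seed %||% 1L,
                 out_dir = cfg$out_dir), class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

load_real_inputs <- function(inputs, threshold_mm) {
  need <- c("atlas", "ventricles", "connectome", "masks_dir", "cohort")
  miss <- setdiff(need, names(inputs))
  if (length(miss)) stop("inputs block missing: ", paste(miss, collapse = ", "))
  atlas <- read_nifti(inputs$atlas)
  ventricles <- read_nifti(inputs$ventricles)
  sl <- if (grepl("\\.tck$", inputs$connectome)) read_tck(inputs$connectome)
    else read_streamlines_text(inputs$connectome)
  sl <- assign_endpoint_regions(sl, atlas)
  cohort <- utils::read.csv(inputs$cohort, stringsAsFactors = FALSE)
  dist_mm <- edt_mm(ventricles)
  pats <- cohort$patient_id
  masks <- lapply(pats, function(p) {
    wmh <- read_nifti(file.path(inputs$masks_dir, paste0(p, "_wmh.nii.gz")))
    stroke_path <- file.path(inputs$masks_dir, paste0(p, "_stroke.nii.gz"))
    stroke <- if (file.exists(stroke_path)) read_nifti(stroke_path) else NULL
    sp <- split_wmh(wmh, ventricles, threshold_mm = threshold_mm,
                    dist_mm = dist_mm)
    c(list(wmh = wmh), sp, if (!is.null(stroke)) list(stroke = stroke))
  })
  n_regions <- max(atlas$data)
  list(atlas = atlas, ventricles = ventricles, streamlines = sl,
       dist_mm = dist_mm, masks = masks, cohort = cohort,
       n_regions = as.integer(n_regions),
       cache = streamline_voxel_cache(sl, atlas))
}

#' Run the full analysis pipeline
#'
#' simulate (or load real inputs) -> periventricular/deep split -> ChaCo per
#' mask type -> group-level statistics and region filter -> region-wise
#' proportional-odds outcome models with FDR, in separate iterations for
#' total WMH, pWMH and dWMH. All stage outputs plus a manifest (seed,
#' options, md5 hashes) land in the run directory; a rerun with the same
#' config and seed reproduces identical outputs.
#'
#' @param config path to a YAML/JSON config, or a list ([load_run_config()]).
#' @param out_dir output directory; overrides the config's `out_dir`.
#' @return (invisibly) list: per-mask-type results, filter reports, group
#'   statistics, manifest path.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- load_run_config(config)
  out_dir <- out_dir %||% cfg$out_dir %||%
    file.path("wmhnet_runs", format(Sys.time(), "run_%Y%m%d_%H%M%S"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  opts <- cfg$options
  if (!is.null(cfg$simulate)) {
    sim_args <- cfg$simulate
    sim_args$seed <- sim_args$seed %||% cfg$seed
    sc <- do.call(simulation_config, sim_args)
    cohort_sim <- simulate_cohort(sc)
    write_cohort(cohort_sim, file.path(out_dir, "simulated"))
    chaco_raw <- cohort_sim$chaco$raw
    cohort <- cohort_sim$cohort
    regions_meta <- cohort_sim$world$regions
  } else {
    ri <- load_real_inputs(cfg$inputs, opts$threshold_mm)
    mask_types <- intersect(c("wmh", "pwmh", "dwmh"), names(ri$masks[[1]]))
    chaco_raw <- lapply(mask_types, function(t) {
      do.call(rbind, lapply(seq_along(ri$masks), function(i)
        as.numeric(compute_chaco(ri$masks[[i]][[t]], ri$streamlines,
                                 ri$n_regions, cache = ri$cache,
                                 mask_type = t, patient_id = i))))
    })
    names(chaco_raw) <- mask_types
    cohort <- ri$cohort
    regions_meta <- data.frame(region_id = seq_len(ri$n_regions),
                               cortical = TRUE)
  }
  mask_types <- intersect(c("wmh", "pwmh", "dwmh"), names(chaco_raw))
  chaco_clean <- lapply(chaco_raw[mask_types], clean_chaco, floor = opts$floor)
  results <- list(); filters <- list(); group <- list()
  for (t in mask_types) {
    m <- chaco_clean[[t]]
    gt <- region_disconnection_test(m)
    utils::write.csv(gt, file.path(out_dir, paste0("group_ttest_", t, ".csv")),
                     row.names = FALSE)
    fr <- filter_regions(m, skew_limit = opts$skew_limit)
    utils::write.csv(fr, file.path(out_dir, paste0("filter_", t, ".csv")),
                     row.names = FALSE)
    rr <- run_region_models(m, cohort, fr$region_id[fr$kept],
                            base_adjust = opts$base_adjust,
                            ci_method = opts$ci_method,
                            r2_method = opts$r2_method)
    utils::write.csv(rr, file.path(out_dir, paste0("results_", t, ".csv")),
                     row.names = FALSE)
    results[[t]] <- rr; filters[[t]] <- fr; group[[t]] <- gt
  }
  if (all(c("wmh", "pwmh", "dwmh") %in% mask_types) &&
      "cortical" %in% names(regions_meta)) {
    cmp <- lapply(c("cortical", "subcortical"), function(s) {
      tryCatch(compare_mask_types(chaco_clean$wmh, chaco_clean$pwmh,
                                  chaco_clean$dwmh, regions_meta, stratum = s),
               error = function(e) NULL)
    })
    cmp <- do.call(rbind, cmp)
    if (!is.null(cmp))
      utils::write.csv(cmp, file.path(out_dir, "mask_type_comparisons.csv"),
                       row.names = FALSE)
  }
  files <- sort(list.files(out_dir, recursive = TRUE))
  manifest <- list(
    package = "wmhnet",
    version = as.character(utils::packageVersion("wmhnet")),
    seed = cfg$seed, options = opts,
    simulate = cfg$simulate, inputs = cfg$inputs,
    files = as.list(stats::setNames(
      unname(tools::md5sum(file.path(out_dir, files))), files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(results = results, filters = filters, group = group,
                 out_dir = out_dir,
                 manifest = file.path(out_dir, "manifest.json")))
}
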