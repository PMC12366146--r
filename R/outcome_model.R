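#' Median-split dichotomization of regional disconnectivity
#'
#' Values strictly above the sample median go to the *high* group; values at
#' or below the median go to *low* (with an odd sample size the true median
#' observation itself lands in the low group).
#'
#' @param values per-patient ChaCo values for one region (no `NA`s).
#' @return integer 0/1 vector (1 = high), with attribute `group_sizes`
#'   (named: low, high) and `median`.
#' @export
dichotomize <- function(values) {
  if (any(is.na(values))) stop("values must not contain NA")
  if (length(unique(values)) < 2)
    stop("all values identical; region should have been filtered out")
  med <- stats::median(values)
  high <- as.integer(values > med)
  structure(high,
            group_sizes = c(low = sum(high == 0L), high = sum(high == 1L)),
            median = med)
}

#' Residualize a covariate against a disconnectivity measure
#'
#' Ordinary least squares of `covariate` on an intercept plus `against`;
#' returns the residuals, which have exactly zero mean and zero sample
#' covariance with `against`.
#'
#' @param covariate,against numeric vectors of equal length.
#' @return residual vector.
#' @export
residualize <- function(covariate, against) {
  if (length(covariate) != length(against)) stop("lengths differ")
  if (any(is.na(covariate)) || any(is.na(against))) stop("NA in inputs")
  if (stats::var(against) == 0) stop("`against` has zero variance")
  stats::lm.fit(cbind(1, against), covariate)$residuals
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values: sort ascending, multiply by m/rank, enforce
#' monotonicity from the largest down, cap at 1.
#'
#' @param p_values numeric vector of p-values in \[0, 1\] (`NA` passed
#'   through and not counted in m).
#' @return adjusted p-values in the original order.
#' @export
fdr_adjust <- function(p_values) {
  ok <- !is.na(p_values)
  p <- p_values[ok]
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  out <- rep(NA_real_, length(p_values))
  if (m) {
    o <- order(p, decreasing = TRUE)
    ro <- order(o)
    adj <- pmin(1, cummin(m * p[o] / (m:1)))[ro]
    out[ok] <- adj
  }
  out
}

# intercept-only proportional-odds fit (cutpoints only)
fit_po_null <- function(outcome) {
  fit_proportional_odds(outcome, matrix(numeric(0), length(outcome), 0))
}

#' Region-wise ordinal outcome models
#'
#' For every kept region: dichotomize its cleaned ChaCo values at the
#' median; build the design \[high indicator, residualized age, NIHSS,
#' log10 lesion volume, residualized log10 WMH volume\] (age and WMH volume
#' are residualized against the region's *continuous* ChaCo, configurable to
#' the indicator); fit the proportional-odds model and its base model (same
#' covariates, no indicator); extract OR/CI/p for the indicator; compute the
#' pseudo-R-squared gain; FDR-adjust the raw p-values across the mask
#' type's successfully fitted regions. Per-region failures are recorded,
#' not fatal.
#'
#' The sensitivity variant `base_adjust = "global_chaco"` replaces the total
#' WMH volume covariate with the patient's global mean ChaCo for the mask
#' type.
#'
#' @param chaco patients x regions matrix of cleaned ChaCo values.
#' @param cohort data.frame with columns age, nihss, mrs, lesion_volume_ml,
#'   wmh_volume_ml; rows aligned with `chaco`.
#' @param kept_regions integer region ids to model (from [filter_regions()]).
#' @param base_adjust "wmh_volume" (default) or "global_chaco".
#' @param residualize_on "continuous" (default) or "indicator".
#' @param ci_method passed to [extract_effect()].
#' @param r2_method passed to [pseudo_r2()].
#' @return data.frame (one row per region): region_id, or, ci_low, ci_high,
#'   p_raw, p_fdr, r2_base, r2_full, r2_gain, n_low, n_high, status; run
#'   options in attribute `"meta"`.
#' @export
run_region_models <- function(chaco, cohort, kept_regions,
                              base_adjust = c("wmh_volume", "global_chaco"),
                              residualize_on = c("continuous", "indicator"),
                              ci_method = "wald",
                              r2_method = "nagelkerke") {
  base_adjust <- match.arg(base_adjust)
  residualize_on <- match.arg(residualize_on)
  stopifnot(is.matrix(chaco), nrow(chaco) == nrow(cohort))
  need <- c("age", "nihss", "mrs", "lesion_volume_ml", "wmh_volume_ml")
  if (!all(need %in% names(cohort)))
    stop("cohort must have columns ", paste(need, collapse = ", "))
  if (any(cohort$lesion_volume_ml <= 0) || any(cohort$wmh_volume_ml <= 0))
    stop("volumes must be > 0 before log10 transform")
  global <- apply(chaco, 1, function(r) mean(r, na.rm = TRUE))
  log_lesion <- log10(cohort$lesion_volume_ml)
  adj_raw <- if (base_adjust == "wmh_volume") log10(cohort$wmh_volume_ml) else global
  adj_name <- if (base_adjust == "wmh_volume") "log10_wmh_vol_resid" else "global_chaco_resid"
  rows <- lapply(kept_regions, function(r) {
    blank <- data.frame(region_id = r, or = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, p_raw = NA_real_, p_fdr = NA_real_,
                        r2_base = NA_real_, r2_full = NA_real_,
                        r2_gain = NA_real_, n_low = NA_integer_,
                        n_high = NA_integer_, status = "error",
                        stringsAsFactors = FALSE)
    tryCatch({
      vals <- chaco[, r]
      keep <- !is.na(vals)
      if (sum(keep) < nrow(cohort))
        stop("missing ChaCo for ", sum(!keep), " patient(s)")
      high <- dichotomize(vals)
      target <- if (residualize_on == "continuous") vals else as.numeric(high)
      design_base <- cbind(
        age_resid = residualize(cohort$age, target),
        nihss = cohort$nihss,
        log10_lesion_vol = log_lesion)
      design_base <- cbind(design_base, residualize(adj_raw, target))
      colnames(design_base)[ncol(design_base)] <- adj_name
      design_full <- cbind(high = as.numeric(high), design_base)
      fit_full <- fit_proportional_odds(cohort$mrs, design_full)
      fit_base <- fit_proportional_odds(cohort$mrs, design_base)
      fit_null <- fit_po_null(cohort$mrs)
      eff <- extract_effect(fit_full, "high", ci_method = ci_method)
      r2f <- pseudo_r2(fit_full, fit_null, method = r2_method)
      r2b <- pseudo_r2(fit_base, fit_null, method = r2_method)
      gs <- attr(high, "group_sizes")
      data.frame(region_id = r, or = eff$or, ci_low = eff$ci_low,
                 ci_high = eff$ci_high, p_raw = eff$p, p_fdr = NA_real_,
                 r2_base = r2b, r2_full = r2f, r2_gain = r2f - r2b,
                 n_low = gs[["low"]], n_high = gs[["high"]], status = "ok",
                 stringsAsFactors = FALSE)
    }, error = function(e) { blank$status <- conditionMessage(e); blank })
  })
  res <- do.call(rbind, rows)
  res$p_fdr <- fdr_adjust(res$p_raw)
  attr(res, "meta") <- list(base_adjust = base_adjust,
                            residualize_on = residualize_on,
                            ci_method = ci_method, r2_method = r2_method,
                            n_tested = sum(!is.na(res$p_raw)))
  res
}
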