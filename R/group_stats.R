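#' Sample skewness (gamma_1)
#'
#' Adjusted Fisher-Pearson estimator by default
#' (\eqn{g_1 \sqrt{n(n-1)}/(n-2)} with \eqn{g_1 = m_3/m_2^{3/2}});
#' `adjusted = FALSE` gives the plain moment version \eqn{g_1}.
#'
#' @param x numeric vector; `NA`s dropped.
#' @param adjusted apply the small-sample correction (default TRUE).
#' @return scalar skewness; `NA` when fewer than 3 values or zero variance.
#' @export
skewness_g1 <- function(x, adjusted = TRUE) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3) return(NA_real_)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= 0) return(NA_real_)
  g1 <- mean((x - m)^3) / m2^1.5
  if (adjusted) g1 * sqrt(n * (n - 1)) / (n - 2) else g1
}

#' Group-level regional disconnection test
#'
#' One-sample, one-sided (greater than zero) t-test of each region's ChaCo
#' values against 0 — which regions are significantly disconnected at group
#' level. Zero-variance columns are flagged degenerate with p = 0 when the
#' mean is positive and p = 1 otherwise; columns with fewer than 2
#' non-missing values are skipped.
#'
#' @param matrix patients x regions matrix of cleaned ChaCo values.
#' @return data.frame: region_id, n, mean, t, p, status
#'   ("ok" | "degenerate" | "skipped").
#' @export
region_disconnection_test <- function(matrix) {
  stopifnot(is.matrix(matrix))
  res <- lapply(seq_len(ncol(matrix)), function(j) {
    x <- matrix[, j]
    x <- x[!is.na(x)]
    n <- length(x)
    if (n < 2)
      return(data.frame(region_id = j, n = n, mean = if (n) mean(x) else NA_real_,
                        t = NA_real_, p = NA_real_, status = "skipped"))
    m <- mean(x); s <- stats::sd(x)
    if (s == 0)
      return(data.frame(region_id = j, n = n, mean = m, t = NA_real_,
                        p = if (m > 0) 0 else 1, status = "degenerate"))
    tstat <- m / (s / sqrt(n))
    data.frame(region_id = j, n = n, mean = m, t = tstat,
               p = stats::pt(tstat, df = n - 1, lower.tail = FALSE),
               status = "ok")
  })
  do.call(rbind, res)
}

#' Region-exclusion filter for outcome modeling
#'
#' Excludes regions exhibiting (almost) complete connection or
#' disconnection: sample skewness gamma_1 outside (-`skew_limit`,
#' `skew_limit`) or a column median of exactly 0 or exactly 1 (exact
#' comparison is meaningful post-cleaning, which clamps to 0/1). Entirely
#' missing or too-short columns are excluded with their own reasons.
#'
#' @param matrix patients x regions cleaned ChaCo matrix.
#' @param skew_limit absolute skewness bound (default 1.3).
#' @param adjusted passed to [skewness_g1()].
#' @return data.frame: region_id, kept, skewness, median, reason
#'   ("none" | "skewness" | "median" | "missing" | "too_few").
#' @export
filter_regions <- function(matrix, skew_limit = 1.3, adjusted = TRUE) {
  stopifnot(is.matrix(matrix))
  res <- lapply(seq_len(ncol(matrix)), function(j) {
    x <- matrix[, j]
    x <- x[!is.na(x)]
    if (!length(x))
      return(data.frame(region_id = j, kept = FALSE, skewness = NA_real_,
                        median = NA_real_, reason = "missing"))
    med <- stats::median(x)
    if (length(x) < 3)
      return(data.frame(region_id = j, kept = FALSE, skewness = NA_real_,
                        median = med, reason = "too_few"))
    g1 <- skewness_g1(x, adjusted = adjusted)
    reason <- if (!is.na(g1) && abs(g1) > skew_limit) "skewness"
      else if (med == 0 || med == 1) "median"
      else "none"
    data.frame(region_id = j, kept = reason == "none", skewness = g1,
               median = med, reason = reason)
  })
  do.call(rbind, res)
}

#' Compare mean ChaCo between mask types within a stratum
#'
#' Per stratum (cortical or subcortical), computes a per-unit mean ChaCo for
#' each mask type and runs paired two-tailed t-tests between the three mask
#' types. The pairing unit is explicit: `"region"` pairs region means
#' (averaged over patients; default, restricted to regions significantly
#' disconnected under both mask types of a pair), `"patient"` pairs patient
#' means (averaged over the stratum's regions).
#'
#' @param matrix_wmh,matrix_pwmh,matrix_dwmh patients x regions cleaned
#'   ChaCo matrices on identical patients and regions.
#' @param regions region metadata data.frame with columns region_id and
#'   cortical (logical).
#' @param stratum "cortical" or "subcortical".
#' @param pairing "region" or "patient".
#' @param alpha significance level for the region-selection t-test (default
#'   0.05, uncorrected).
#' @return data.frame: comparison, pairing, n_pairs, t, df, p.
#' @export
compare_mask_types <- function(matrix_wmh, matrix_pwmh, matrix_dwmh,
                               regions, stratum = c("cortical", "subcortical"),
                               pairing = c("region", "patient"),
                               alpha = 0.05) {
  stratum <- match.arg(stratum)
  pairing <- match.arg(pairing)
  mats <- list(wmh = matrix_wmh, pwmh = matrix_pwmh, dwmh = matrix_dwmh)
  dims <- lapply(mats, dim)
  if (length(unique(vapply(dims, paste, collapse = "x", character(1)))) != 1)
    stop("matrices must share patients and regions")
  in_stratum <- if (stratum == "cortical") regions$cortical else !regions$cortical
  cols <- regions$region_id[in_stratum]
  if (!length(cols)) stop("no regions in stratum ", stratum)
  sig <- lapply(mats, function(m) {
    tt <- region_disconnection_test(m[, cols, drop = FALSE])
    cols[!is.na(tt$p) & tt$p < alpha]
  })
  combos <- list(c("wmh", "pwmh"), c("wmh", "dwmh"), c("pwmh", "dwmh"))
  res <- lapply(combos, function(cmb) {
    a <- mats[[cmb[1]]]; b <- mats[[cmb[2]]]
    if (pairing == "region") {
      use <- intersect(sig[[cmb[1]]], sig[[cmb[2]]])
      xa <- colMeans(a[, use, drop = FALSE], na.rm = TRUE)
      xb <- colMeans(b[, use, drop = FALSE], na.rm = TRUE)
    } else {
      xa <- rowMeans(a[, cols, drop = FALSE], na.rm = TRUE)
      xb <- rowMeans(b[, cols, drop = FALSE], na.rm = TRUE)
    }
    ok <- is.finite(xa) & is.finite(xb)
    xa <- xa[ok]; xb <- xb[ok]
    if (length(xa) < 2)
      stop("fewer than 2 pairs for ", paste(cmb, collapse = " vs "),
           " in stratum ", stratum)
    d <- xa - xb
    if (stats::sd(d) < 1e-10 * max(abs(mean(d)), .Machine$double.eps)) {
      # all pairwise differences (numerically) identical
      tt <- if (abs(mean(d)) < 1e-12)
        list(statistic = 0, parameter = length(d) - 1, p.value = 1)
      else
        list(statistic = sign(mean(d)) * Inf, parameter = length(d) - 1,
             p.value = 0)
    } else {
      tt <- stats::t.test(xa, xb, paired = TRUE)
    }
    data.frame(comparison = paste(cmb, collapse = "_vs_"),
               stratum = stratum, pairing = pairing, n_pairs = length(d),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value)
  })
  do.call(rbind, res)
}
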