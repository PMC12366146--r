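#' Per-region change of connectivity (ChaCo)
#'
#' For each atlas region r, the raw ChaCo value is the fraction of reference
#' streamlines with at least one endpoint assigned to r that pass through the
#' lesion mask:
#' \deqn{ChaCo(r) = \frac{\#\{s : r \in ends(s),\ s \cap mask \neq \emptyset\}}
#'                      {\#\{s : r \in ends(s)\}}}
#' Streamlines with both endpoints in r are counted once. Regions to which no
#' streamline connects get `NA` ("no information", distinct from 0 = "no
#' damage") and are excluded downstream.
#'
#' @param mask binary `labeled_volume` on the connectome's grid.
#' @param connectome `streamline_set` with endpoint regions assigned.
#' @param n_regions number of atlas regions (labels 1..n_regions).
#' @param cache optional [streamline_voxel_cache()] for the mask's grid.
#' @param mask_type tag stored on the result ("wmh", "pwmh", "dwmh", "stroke").
#' @param patient_id tag stored on the result.
#' @return numeric vector of length `n_regions` (class `chaco_vector`),
#'   values in \[0,1\] or `NA`.
#' @export
compute_chaco <- function(mask, connectome, n_regions, cache = NULL,
                          mask_type = "wmh", patient_id = NA_character_) {
  stopifnot(inherits(mask, "labeled_volume"), inherits(connectome, "streamline_set"))
  assert_binary(mask)
  if (is.null(connectome$endpoint_regions))
    stop("connectome has no endpoint region assignments; run assign_endpoint_regions()")
  if (is.null(cache)) {
    cache <- streamline_voxel_cache(connectome, mask)
  } else if (length(cache) != length(connectome$streamlines)) {
    stop("voxel cache length does not match the connectome")
  }
  maskvec <- as.vector(mask$data) == 1
  hit <- vapply(cache, function(idx) length(idx) > 0 && any(maskvec[idx]),
                logical(1))
  ends <- connectome$endpoint_regions
  denom <- numer <- integer(n_regions)
  for (r in seq_len(n_regions)) {
    connected <- ends[, 1] == r | ends[, 2] == r
    denom[r] <- sum(connected)
    numer[r] <- sum(connected & hit)
  }
  val <- ifelse(denom > 0, numer / denom, NA_real_)
  structure(val, names = paste0("region_", seq_len(n_regions)),
            mask_type = mask_type, patient_id = patient_id,
            class = "chaco_vector")
}

#' Apply the ChaCo value-cleaning rule
#'
#' Values strictly below `floor` (default 0.02) are set to 0; values above 1
#' are clamped to 1. The boundary value `floor` itself is untouched. Missing
#' values are preserved. Idempotent.
#'
#' @param raw numeric vector (typically a `chaco_vector`).
#' @param floor noise floor, >= 0.
#' @return cleaned vector, same attributes.
#' @export
clean_chaco <- function(raw, floor = 0.02) {
  if (!is.numeric(floor) || length(floor) != 1 || floor < 0)
    stop("`floor` must be a single non-negative number")
  out <- raw
  out[!is.na(out) & out < floor] <- 0
  out[!is.na(out) & out > 1] <- 1
  out
}

#' Global (mean) ChaCo over regions
#'
#' Arithmetic mean over non-missing regions — the "global network damage"
#' summary used in the sensitivity base models.
#'
#' @param vector a `chaco_vector` or numeric vector.
#' @return scalar mean.
#' @export
global_chaco <- function(vector) {
  if (all(is.na(vector))) stop("all ChaCo values are missing")
  mean(vector, na.rm = TRUE)
}

#' Write per-patient ChaCo values as CSV
#'
#' Long format: patient_id, mask_type, region_id, chaco (NA for regions with
#' no connected streamlines).
#'
#' @param vectors list of `chaco_vector`s.
#' @param path output CSV path.
#' @export
write_chaco_csv <- function(vectors, path) {
  rows <- lapply(vectors, function(v) {
    data.frame(patient_id = attr(v, "patient_id"),
               mask_type = attr(v, "mask_type"),
               region_id = seq_along(v),
               chaco = as.numeric(v))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read a ChaCo CSV into patients x regions matrices
#'
#' @param path CSV written by [write_chaco_csv()].
#' @return named list of matrices (one per mask_type), rows = patients,
#'   columns = regions.
#' @export
read_chaco_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "mask_type", "region_id", "chaco")
  if (!all(need %in% names(df)))
    stop("ChaCo CSV must have columns ", paste(need, collapse = ", "))
  lapply(split(df, df$mask_type), function(d) {
    pids <- unique(d$patient_id)
    rids <- sort(unique(d$region_id))
    m <- matrix(NA_real_, length(pids), length(rids),
                dimnames = list(pids, paste0("region_", rids)))
    m[cbind(match(d$patient_id, pids), match(d$region_id, rids))] <- d$chaco
    m
  })
}

#' Assemble a patients x regions ChaCo matrix
#'
#' @param vectors list of `chaco_vector`s sharing a mask type.
#' @return numeric matrix, rows named by patient id.
#' @export
chaco_matrix <- function(vectors) {
  m <- do.call(rbind, lapply(vectors, as.numeric))
  rownames(m) <- vapply(vectors, function(v) as.character(attr(v, "patient_id")),
                        character(1))
  colnames(m) <- paste0("region_", seq_len(ncol(m)))
  m
}
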