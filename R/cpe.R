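#' Voxelwise delayed enhancement ratio map
#'
#' Computes the per-voxel ratio (S_late - S_early) / S_early between two
#' post-contrast series of a DCE study. Voxels whose early signal falls below
#' a positivity floor (`eps_frac` times the maximum early intensity) cannot
#' support a meaningful ratio and are flagged invalid (`NA`) rather than
#' producing unbounded values.
#'
#' @param study a [dce_study()].
#' @param early_time,late_time requested acquisition times in seconds; each
#'   must match an acquisition time of the study within `time_tol`.
#' @param eps_frac positivity floor for the early signal, as a fraction of
#'   the early volume's maximum intensity.
#' @param time_tol matching tolerance in seconds.
#' @return A 3-D numeric array of dimension equal to the study volumes, with
#'   `NA` at invalid voxels; attributes `early_time` and `late_time` record
#'   the matched times.
#' @export
enhancement_ratio_map <- function(study, early_time = 90, late_time = 360,
                                  eps_frac = 1e-6, time_tol = 1e-6) {
  stopifnot(inherits(study, "dce_study"))
  match_time <- function(t) {
    i <- which.min(abs(study$acquisition_times - t))
    if (abs(study$acquisition_times[i] - t) > time_tol)
      stop(sprintf("no acquisition at %g s; available times: %s", t,
                   paste(study$acquisition_times, collapse = ", ")))
    i
  }
  ie <- match_time(early_time)
  il <- match_time(late_time)
  if (study$acquisition_times[il] <= study$acquisition_times[ie])
    stop("late_time must be after early_time")
  s_early <- study$volumes[[ie]]
  s_late <- study$volumes[[il]]
  eps <- eps_frac * max(s_early)
  ratio <- (s_late - s_early) / s_early
  ratio[s_early <= eps] <- NA_real_
  attr(ratio, "early_time") <- study$acquisition_times[ie]
  attr(ratio, "late_time") <- study$acquisition_times[il]
  ratio
}

#' Contralateral parenchymal enhancement (CPE)
#'
#' CPE is the mean of the top fraction (by default 10%) of voxelwise delayed
#' enhancement ratios within the fibroglandular tissue of the contralateral
#' breast: a dimensionless summary of delayed parenchymal enhancement. Ratios
#' are sorted in descending order and the top `ceiling(top_fraction * m)`
#' averaged, where m counts the valid in-mask voxels. Ties at the cut
#' boundary are broken by voxel linear index, which makes the selected set
#' deterministic and leaves the value itself order-independent.
#'
#' @param ratio_map enhancement-ratio array from [enhancement_ratio_map()];
#'   `NA` marks voxels excluded for an invalid (near-zero) denominator.
#' @param masks a [tissue_masks()] whose fibroglandular mask selects the
#'   voxels eligible for the statistic.
#' @param top_fraction fraction in (0, 1] of eligible voxels to average.
#' @return An object of class `cpe_value`: list with `value`,
#'   `top_fraction`, `n_voxels_used`, `n_voxels_mask`, `n_voxels_excluded`.
#' @export
compute_cpe <- function(ratio_map, masks, top_fraction = 0.10) {
  stopifnot(inherits(masks, "tissue_masks"))
  if (!identical(dim(ratio_map), dim(masks$fibroglandular_mask)))
    stop("ratio map and mask dimensions differ")
  if (!(top_fraction > 0 && top_fraction <= 1))
    stop("top_fraction must be in (0, 1]")
  in_mask <- ratio_map[masks$fibroglandular_mask]
  n_mask <- length(in_mask)
  if (n_mask == 0L) stop("fibroglandular mask is empty")
  valid <- in_mask[!is.na(in_mask)]
  m <- length(valid)
  if (m == 0L) stop("no valid in-mask voxels (all denominators invalid)")
  n_used <- max(1L, as.integer(ceiling(top_fraction * m)))
  # stable descending sort; boundary ties resolved by voxel linear index
  top <- sort(valid, decreasing = TRUE, method = "radix")[seq_len(n_used)]
  structure(
    list(value = mean(top),
         top_fraction = top_fraction,
         n_voxels_used = n_used,
         n_voxels_mask = n_mask,
         n_voxels_excluded = n_mask - m),
    class = "cpe_value")
}

#' @export
print.cpe_value <- function(x, ...) {
  cat(sprintf(
    "CPE = %.4f (top %.0f%% of %d valid voxels: %d used, %d excluded)\n",
    x$value, 100 * x$top_fraction,
    x$n_voxels_mask - x$n_voxels_excluded, x$n_voxels_used,
    x$n_voxels_excluded))
  invisible(x)
}

#' CPE for a study in one call
#'
#' Convenience wrapper: ratio map then top-fraction mean.
#'
#' @inheritParams enhancement_ratio_map
#' @inheritParams compute_cpe
#' @return A `cpe_value`.
#' @export
cpe_from_study <- function(study, masks, early_time = 90, late_time = 360,
                           top_fraction = 0.10) {
  compute_cpe(enhancement_ratio_map(study, early_time, late_time), masks,
              top_fraction)
}

#' Standardize a vector to SD units with reusable parameters
#'
#' Centers and scales so a one-unit increase in the output corresponds to a
#' one-standard-deviation increase on the original scale. The training mean
#' and SD are stored so new values (e.g. a validation cohort) can be placed
#' on the same reference scale with [apply_standardization()].
#'
#' @param values numeric vector with at least two distinct finite values.
#' @return Numeric vector with attributes `center` and `scale` and class
#'   `standardized`.
#' @export
standardize <- function(values) {
  if (!all(is.finite(values))) stop("values must be finite")
  if (length(unique(values)) < 2L) stop("need at least 2 distinct values")
  m <- mean(values)
  s <- stats::sd(values)
  if (s == 0) stop("zero variance")
  structure((values - m) / s, center = m, scale = s, class = "standardized")
}

#' Apply stored standardization parameters to new values
#'
#' @param new_values numeric vector on the original scale.
#' @param reference a `standardized` vector from [standardize()].
#' @return Numeric vector on the reference SD scale.
#' @export
apply_standardization <- function(new_values, reference) {
  stopifnot(inherits(reference, "standardized"))
  (new_values - attr(reference, "center")) / attr(reference, "scale")
}
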