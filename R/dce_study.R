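#' Multi-timepoint DCE-MRI study container
#'
#' Bundles an ordered series of registered 3-D signal-intensity volumes with
#' their acquisition times. The first volume is the pre-contrast series;
#' subsequent volumes are post-contrast. All computation downstream (the
#' enhancement-ratio map, the CPE statistic) assumes the volumes are already
#' bias-corrected and registered to the pre-contrast frame: registration and
#' segmentation are inputs to this package, not computations it performs.
#'
#' @param volumes list of 3-D numeric arrays, all of identical dimension,
#'   ordered by acquisition time.
#' @param acquisition_times numeric vector of seconds since contrast
#'   injection, one per volume, strictly increasing; the first entry is the
#'   pre-contrast series (typically 0).
#' @param voxel_spacing numeric length-3, voxel edge lengths in mm.
#' @return An object of class `dce_study`.
#' @export
dce_study <- function(volumes, acquisition_times,
                      voxel_spacing = c(1.35, 1.35, 1.35)) {
  if (!is.list(volumes) || length(volumes) < 3L)
    stop("'volumes' must be a list of at least 3 arrays (pre + early + late)")
  dims <- lapply(volumes, dim)
  if (any(vapply(dims, length, 1L) != 3L))
    stop("all volumes must be 3-D arrays")
  if (!all(vapply(dims, function(d) identical(d, dims[[1L]]), TRUE)))
    stop("all volumes must share the same dimensions")
  if (length(acquisition_times) != length(volumes))
    stop("one acquisition time per volume required")
  if (any(diff(acquisition_times) <= 0))
    stop("acquisition times must be strictly increasing")
  if (!all(vapply(volumes, function(v) all(is.finite(v)), TRUE)))
    stop("volume intensities must be finite")
  structure(
    list(volumes = volumes,
         acquisition_times = as.numeric(acquisition_times),
         voxel_spacing = as.numeric(voxel_spacing)),
    class = "dce_study")
}

#' @export
print.dce_study <- function(x, ...) {
  d <- dim(x$volumes[[1L]])
  cat(sprintf("dce_study: %d volumes of %dx%dx%d voxels\n",
              length(x$volumes), d[1L], d[2L], d[3L]))
  cat("acquisition times (s):", paste(x$acquisition_times, collapse = ", "),
      "\n")
  invisible(x)
}

#' Breast and fibroglandular tissue masks
#'
#' The fibroglandular mask delimits the dense parenchymal tissue of the
#' contralateral breast, the region over which CPE is computed; it must be
#' contained in the breast mask and match the study's volume dimensions.
#'
#' @param breast_mask logical 3-D array.
#' @param fibroglandular_mask logical 3-D array, subset of `breast_mask`.
#' @return An object of class `tissue_masks`.
#' @export
tissue_masks <- function(breast_mask, fibroglandular_mask) {
  breast_mask <- array(as.logical(breast_mask), dim(breast_mask))
  fibroglandular_mask <- array(as.logical(fibroglandular_mask),
                               dim(fibroglandular_mask))
  if (!identical(dim(breast_mask), dim(fibroglandular_mask)))
    stop("mask dimensions differ")
  if (any(fibroglandular_mask & !breast_mask))
    stop("fibroglandular mask must be contained in the breast mask")
  structure(list(breast_mask = breast_mask,
                 fibroglandular_mask = fibroglandular_mask),
            class = "tissue_masks")
}

#' Read a DCE study from NIfTI files
#'
#' @param pre path to the pre-contrast NIfTI volume.
#' @param post character vector of post-contrast NIfTI paths, in acquisition
#'   order.
#' @param times acquisition times in seconds for `c(pre, post)`; defaults to
#'   0 followed by 90-second spacing.
#' @return A `dce_study`.
#' @export
read_dce_study <- function(pre, post, times = seq(0, by = 90,
                                                  length.out = length(post) + 1L)) {
  paths <- c(pre, post)
  vols <- lapply(paths, function(p) {
    v <- RNifti::readNifti(p)
    array(as.numeric(v), dim(v))
  })
  spacing <- RNifti::pixdim(RNifti::readNifti(pre))[1:3]
  dce_study(vols, times, voxel_spacing = spacing)
}

#' Read tissue masks from NIfTI files
#'
#' Nonzero voxels are taken as in-mask.
#'
#' @param breast,fibroglandular NIfTI paths.
#' @return A `tissue_masks`.
#' @export
read_tissue_masks <- function(breast, fibroglandular) {
  rd <- function(p) {
    v <- RNifti::readNifti(p)
    array(as.numeric(v) != 0, dim(v))
  }
  tissue_masks(rd(breast), rd(fibroglandular))
}

#' Write a DCE study and masks as NIfTI files
#'
#' @param study a `dce_study`.
#' @param masks a `tissue_masks`.
#' @param dir output directory, created if absent.
#' @param prefix file-name prefix.
#' @return Invisibly, the named character vector of written paths.
#' @export
write_dce_study <- function(study, masks, dir, prefix = "study") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (i in seq_along(study$volumes)) {
    lab <- if (i == 1L) "pre" else sprintf("post%03ds",
                                           round(study$acquisition_times[i]))
    p <- file.path(dir, sprintf("%s_%s.nii.gz", prefix, lab))
    RNifti::writeNifti(RNifti::asNifti(study$volumes[[i]],
                                       pixdim = study$voxel_spacing), p)
    paths[lab] <- p
  }
  for (m in c("breast_mask", "fibroglandular_mask")) {
    p <- file.path(dir, sprintf("%s_%s.nii.gz", prefix, m))
    RNifti::writeNifti(RNifti::asNifti(array(as.integer(masks[[m]]),
                                             dim(masks[[m]])),
                                       pixdim = study$voxel_spacing), p)
    paths[m] <- p
  }
  invisible(paths)
}
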