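#' Seeded threshold region-growing segmentation
#'
#' Emulates semi-automatic lumen segmentation on a time-averaged,
#' magnitude-weighted speed image: voxels at or above a speed threshold are
#' kept, the 26-connected component(s) containing at least one seed are
#' selected, then a morphological closing (1-voxel ball) and interior hole
#' filling regularize the surface. Deterministic for fixed inputs.
#'
#' @param speed 3-axis speed image (m/s), e.g. from
#'   [magnitude_weighted_speed()].
#' @param seeds n x 3 matrix (or length-3 vector) of 1-based voxel indices
#'   inside the vessel.
#' @param meta the grid's [acquisition_meta()].
#' @param threshold absolute speed threshold in m/s; when `NULL`, defaults to
#'   `threshold_frac` times the 99th-percentile speed.
#' @param threshold_frac fraction of the 99th-percentile speed used when
#'   `threshold` is `NULL` (default 0.10).
#' @param close_radius closing ball radius in voxels (default 1; 0 disables).
#' @return A [vessel_mask()].
#' @export
threshold_region_grow <- function(speed, seeds, meta, threshold = NULL,
                                  threshold_frac = 0.10, close_radius = 1) {
  stopifnot(length(dim(speed)) == 3L)
  seeds <- matrix(as.integer(seeds), ncol = 3L)
  d <- dim(speed)
  if (any(seeds < 1L) || any(seeds[, 1L] > d[1L]) ||
      any(seeds[, 2L] > d[2L]) || any(seeds[, 3L] > d[3L]))
    stop("seed outside the image grid", call. = FALSE)
  if (is.null(threshold))
    threshold <- threshold_frac *
      stats::quantile(speed, 0.99, names = FALSE, type = 7)
  if (!is.finite(threshold) || threshold <= 0)
    stop("threshold must be > 0", call. = FALSE)
  above <- speed >= threshold
  grown <- flood_select(above, seeds, connectivity = 26L)
  if (!any(grown))
    stop("empty segmentation: no voxel at/above threshold is connected to a ",
         "seed", call. = FALSE)
  if (close_radius > 0) grown <- binary_close(grown, close_radius)
  grown <- fill_holes(grown)
  vessel_mask(grown, meta)
}

#' Restrict a mask with oriented cut planes
#'
#' Trims a segmentation to the anatomical region of interest (e.g. tunnel
#' above the hepatic veins, SVC below the brachiocephalic vein, PAs up to the
#' segmental branches) by removing voxels on the outward side of any cut
#' plane. Also the mechanism for excluding device/stent artefact regions.
#'
#' @param mask a [vessel_mask()].
#' @param cut_planes list of planes, each `list(origin =, normal =)` in world
#'   mm with the normal pointing into the kept half-space.
#' @return A [vessel_mask()]; error if every voxel is removed.
#' @export
restrict_roi <- function(mask, cut_planes) {
  stopifnot(inherits(mask, "vessel_mask"))
  if (length(cut_planes) == 0L) return(mask)
  vals <- mask$values
  idx <- which(vals, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty segmentation: mask has no voxels",
                            call. = FALSE)
  w <- voxel_to_world(mask$meta, idx - 1L)
  keep <- rep(TRUE, nrow(idx))
  for (pl in cut_planes) {
    n <- as.numeric(pl$normal)
    n <- n / sqrt(sum(n^2))
    keep <- keep & (sweep(w, 2L, as.numeric(pl$origin), `-`) %*% n >= 0)
  }
  if (!any(keep))
    stop("empty segmentation: cut planes removed every voxel", call. = FALSE)
  out <- array(FALSE, dim(vals))
  out[idx[keep, , drop = FALSE]] <- TRUE
  vessel_mask(out, mask$meta)
}
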