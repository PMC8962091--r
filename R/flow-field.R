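#' Acquisition metadata for a 4D phase-contrast dataset
#'
#' Physical metadata attached to every velocity field and mask: voxel spacing,
#' number of reconstructed cardiac phases, RR interval, velocity encoding
#' limit (VENC) and the rigid voxel-to-world transform.
#'
#' Velocities are stored internally in m/s; the VENC is kept in cm/s, the unit
#' in which it is prescribed at the scanner, and converted where needed.
#'
#' @param spacing numeric length-3, voxel spacing in mm per axis (> 0).
#' @param n_phases integer, reconstructed phases per cardiac cycle (>= 1).
#' @param venc_cm_s velocity encoding limit in cm/s (> 0).
#' @param rr_ms RR interval in ms (> 0).
#' @param origin numeric length-3, world-space position (mm) of voxel (0,0,0).
#' @param orientation 3x3 orthonormal matrix mapping voxel axes to world (RAS)
#'   axes.
#' @return An object of class `acquisition_meta`.
#' @export
acquisition_meta <- function(spacing, n_phases, venc_cm_s, rr_ms = 1000,
                             origin = c(0, 0, 0), orientation = diag(3)) {
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  stopifnot(length(spacing) == 3L, all(is.finite(spacing)), all(spacing > 0))
  n_phases <- as.integer(n_phases)
  stopifnot(length(n_phases) == 1L, n_phases >= 1L)
  stopifnot(is.numeric(venc_cm_s), length(venc_cm_s) == 1L, venc_cm_s > 0)
  stopifnot(is.numeric(rr_ms), length(rr_ms) == 1L, rr_ms > 0)
  origin <- as.numeric(origin)
  stopifnot(length(origin) == 3L, all(is.finite(origin)))
  orientation <- as.matrix(orientation)
  stopifnot(dim(orientation) == c(3L, 3L))
  if (max(abs(crossprod(orientation) - diag(3))) > 1e-6)
    stop("`orientation` must be orthonormal", call. = FALSE)
  structure(
    list(spacing = spacing, n_phases = n_phases, venc_cm_s = venc_cm_s,
         rr_ms = rr_ms, origin = origin, orientation = orientation),
    class = "acquisition_meta"
  )
}

#' 4D flow velocity field
#'
#' Container for the measured three-component velocity on a voxel grid across
#' cardiac phases.
#'
#' @param values 5-axis numeric array `[x, y, z, phase, component]`, velocity
#'   in m/s; the component axis has length 3 and the phase axis must match
#'   `meta$n_phases`. All values must be finite.
#' @param meta an [acquisition_meta()] object.
#' @param magnitude optional 4-axis array `[x, y, z, phase]` of signal
#'   magnitude (arbitrary units) used to weight speed images.
#' @return An object of class `flow_field`.
#' @export
flow_field <- function(values, meta, magnitude = NULL) {
  stopifnot(inherits(meta, "acquisition_meta"))
  d <- dim(values)
  if (length(d) != 5L || d[5L] != 3L)
    stop("`values` must be a 5-axis array [x, y, z, phase, 3]", call. = FALSE)
  if (d[4L] != meta$n_phases)
    stop(sprintf("phase axis length %d != meta$n_phases %d", d[4L],
                 meta$n_phases), call. = FALSE)
  if (!all(is.finite(values)))
    stop("velocity values must all be finite", call. = FALSE)
  if (!is.null(magnitude)) {
    dm <- dim(magnitude)
    if (length(dm) != 4L || any(dm != d[1:4]))
      stop("`magnitude` must be a 4-axis array matching [x, y, z, phase]",
           call. = FALSE)
  }
  structure(list(values = values, meta = meta, magnitude = magnitude),
            class = "flow_field")
}

#' Binary vessel mask on a velocity-field grid
#'
#' @param values logical 3-axis array on the same spatial grid as the field it
#'   accompanies.
#' @param meta an [acquisition_meta()] object.
#' @return An object of class `vessel_mask`.
#' @export
vessel_mask <- function(values, meta) {
  stopifnot(inherits(meta, "acquisition_meta"))
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3-axis array", call. = FALSE)
  storage.mode(values) <- "logical"
  structure(list(values = values, meta = meta), class = "vessel_mask")
}

#' @export
print.acquisition_meta <- function(x, ...) {
  cat(sprintf(
    "<acquisition_meta> spacing %s mm, %d phases, RR %.0f ms, VENC %.0f cm/s\n",
    paste(format(x$spacing), collapse = "x"), x$n_phases, x$rr_ms,
    x$venc_cm_s))
  invisible(x)
}

#' @export
print.flow_field <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<flow_field> %dx%dx%d voxels, %d phases, 3 components; |v| max %.3f m/s\n",
    d[1], d[2], d[3], d[4], sqrt(max(rowSums(matrix(x$values, ncol = 3)^2)))))
  print(x$meta)
  invisible(x)
}

#' @export
print.vessel_mask <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<vessel_mask> %dx%dx%d voxels, %d foreground\n",
              d[1], d[2], d[3], sum(x$values)))
  invisible(x)
}

# voxel (0-based ijk) -> world mm, voxel-centred coordinates
voxel_to_world <- function(meta, ijk0) {
  ijk0 <- matrix(as.numeric(ijk0), ncol = 3L)
  sweep(ijk0 %*% t(meta$orientation * rep(meta$spacing, each = 3L)), 2L,
        meta$origin, `+`)
}

# world mm -> continuous 0-based voxel coordinates
world_to_voxel <- function(meta, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3L)
  v <- sweep(xyz, 2L, meta$origin, `-`) %*% meta$orientation
  sweep(v, 2L, meta$spacing, `/`)
}

# check two metas describe congruent grids (spacing + transform)
assert_same_grid <- function(a, b) {
  stopifnot(inherits(a, "acquisition_meta"), inherits(b, "acquisition_meta"))
  ok <- max(abs(a$spacing - b$spacing)) < 1e-6 &&
    max(abs(a$origin - b$origin)) < 1e-3 &&
    max(abs(a$orientation - b$orientation)) < 1e-6
  if (!ok) stop("grids are not congruent (spacing/origin/orientation differ)",
                call. = FALSE)
  invisible(TRUE)
}
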