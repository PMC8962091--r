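#' Energetics configuration
#'
#' Physical constants and numerical choices for kinetic energy (KE) and
#' viscous energy loss rate (EL) computation.
#'
#' @param blood_density mass density rho in kg/m^3 (default 1060, standard
#'   whole blood).
#' @param dynamic_viscosity mu in Pa.s (default 3.2e-3, standard blood at
#'   high shear).
#' @param include_divergence_term include the -(2/3)(div v)^2 compressibility
#'   correction in the dissipation function. Measured phase-contrast fields
#'   are not exactly divergence-free, so the term is on by default; it
#'   vanishes on analytic laminar phantoms.
#' @param boundary_scheme `"one_sided"` (default) uses one-sided differences
#'   at mask boundaries; `"interior_only"` zeroes derivative contributions
#'   across out-of-mask faces. One-sided is the default because dropping
#'   boundary voxels systematically underestimates wall-shear-dominated
#'   dissipation.
#' @return An object of class `energetics_config`.
#' @export
energetics_config <- function(blood_density = 1060,
                              dynamic_viscosity = 3.2e-3,
                              include_divergence_term = TRUE,
                              boundary_scheme = c("one_sided",
                                                  "interior_only")) {
  stopifnot(blood_density > 0, dynamic_viscosity > 0)
  boundary_scheme <- match.arg(boundary_scheme)
  structure(list(blood_density = blood_density,
                 dynamic_viscosity = dynamic_viscosity,
                 include_divergence_term = include_divergence_term,
                 boundary_scheme = boundary_scheme),
            class = "energetics_config")
}

#' Velocity gradient tensor over a mask
#'
#' Finite-difference velocity gradients dv_i/dx_j (s^-1) restricted to mask
#' voxels: central differences where both axis neighbours are in-mask,
#' one-sided differences where exactly one is (under the `one_sided` scheme),
#' zero across out-of-mask faces under `interior_only`. Out-of-mask
#' velocities never enter a difference, so wall gradients are estimated from
#' lumen data only.
#'
#' @param field a [flow_field()].
#' @param mask a [vessel_mask()] on the same grid.
#' @param phase 1-based cardiac phase index.
#' @param scheme boundary scheme, see [energetics_config()].
#' @return A list: `grad`, array `[x, y, z, i, j]` of dv_i/dx_j in s^-1
#'   (zero outside the mask); `isolated`, logical array flagging in-mask
#'   voxels with no in-mask axis neighbour at all.
#' @export
velocity_gradient_tensor <- function(field, mask, phase = 1L,
                                     scheme = c("one_sided",
                                                "interior_only")) {
  stopifnot(inherits(field, "flow_field"), inherits(mask, "vessel_mask"))
  scheme <- match.arg(scheme)
  m <- mask$values
  if (!any(m)) stop("mask is empty", call. = FALSE)
  d <- dim(m)
  stopifnot(all(dim(field$values)[1:3] == d))
  h <- field$meta$spacing / 1000  # m
  grad <- array(0, c(d, 3L, 3L))
  has_any <- array(FALSE, d)
  ej <- diag(3L)
  for (j in 1:3) {
    mp <- shift_arr3(m, -ej[j, 1], -ej[j, 2], -ej[j, 3], FALSE)  # +1 nb in
    mm <- shift_arr3(m, ej[j, 1], ej[j, 2], ej[j, 3], FALSE)     # -1 nb in
    has_any <- has_any | mp | mm
    for (i in 1:3) {
      a <- field$values[, , , phase, i, drop = TRUE]
      dim(a) <- d
      ap <- shift_arr3(a, -ej[j, 1], -ej[j, 2], -ej[j, 3], 0)
      am <- shift_arr3(a, ej[j, 1], ej[j, 2], ej[j, 3], 0)
      g <- array(0, d)
      central <- m & mp & mm
      g[central] <- (ap[central] - am[central]) / (2 * h[j])
      if (scheme == "one_sided") {
        # second-order one-sided stencil where two inward neighbours exist
        # (exact for quadratic profiles, so wall shear of parabolic flow is
        # captured); first-order fallback otherwise
        app <- shift_arr3(a, -2 * ej[j, 1], -2 * ej[j, 2], -2 * ej[j, 3], 0)
        amm <- shift_arr3(a, 2 * ej[j, 1], 2 * ej[j, 2], 2 * ej[j, 3], 0)
        mpp <- shift_arr3(m, -2 * ej[j, 1], -2 * ej[j, 2], -2 * ej[j, 3],
                          FALSE)
        mmm <- shift_arr3(m, 2 * ej[j, 1], 2 * ej[j, 2], 2 * ej[j, 3],
                          FALSE)
        fwd2 <- m & mp & !mm & mpp
        g[fwd2] <- (-3 * a[fwd2] + 4 * ap[fwd2] - app[fwd2]) / (2 * h[j])
        fwd1 <- m & mp & !mm & !mpp
        g[fwd1] <- (ap[fwd1] - a[fwd1]) / h[j]
        bwd2 <- m & !mp & mm & mmm
        g[bwd2] <- (3 * a[bwd2] - 4 * am[bwd2] + amm[bwd2]) / (2 * h[j])
        bwd1 <- m & !mp & mm & !mmm
        g[bwd1] <- (a[bwd1] - am[bwd1]) / h[j]
      }
      grad[, , , i, j] <- g
    }
  }
  list(grad = grad, isolated = m & !has_any)
}

#' Kinetic energy per cardiac phase
#'
#' KE(t) = sum over mask voxels of (1/2) rho |v|^2 V_voxel, in mJ.
#'
#' @inheritParams velocity_gradient_tensor
#' @param cfg an [energetics_config()].
#' @param keep_maps return per-phase voxel-wise KE density maps (J/m^3).
#' @return Numeric vector of length `n_phases` (mJ); with `keep_maps`, the
#'   maps are attached as attribute `density`.
#' @export
kinetic_energy <- function(field, mask, cfg = energetics_config(),
                           keep_maps = FALSE) {
  stopifnot(inherits(field, "flow_field"), inherits(mask, "vessel_mask"))
  m <- mask$values
  d <- dim(field$values)
  vvox <- prod(field$meta$spacing) * 1e-9  # m^3
  ke <- numeric(d[4L])
  maps <- if (keep_maps) array(0, d[1:4])
  for (ph in seq_len(d[4L])) {
    v2 <- array(0, d[1:3])
    for (i in 1:3) {
      a <- field$values[, , , ph, i, drop = TRUE]
      dim(a) <- d[1:3]
      v2 <- v2 + a^2
    }
    dens <- 0.5 * cfg$blood_density * v2       # J/m^3
    ke[ph] <- sum(dens[m]) * vvox * 1000       # mJ
    if (keep_maps) {
      dens[!m] <- 0
      maps[, , , ph] <- dens
    }
  }
  if (keep_maps) attr(ke, "density") <- maps
  ke
}

#' Viscous energy loss rate per cardiac phase
#'
#' The rate at which kinetic energy is converted to heat by friction,
#' computed from the Navier-Stokes viscous dissipation function under the
#' laminar-flow assumption:
#' \deqn{\Phi_v = \tfrac12 \sum_{i,j} \left(\partial_j v_i + \partial_i
#'   v_j\right)^2 - \tfrac23 (\nabla\cdot v)^2}
#' EL(t) = sum over mask voxels of mu Phi_v V_voxel, in mW. Per-voxel
#' negative Phi_v (possible only through the divergence correction on noisy
#' fields) is clipped to zero; the clipped-voxel count is attached as
#' attribute `n_clipped`.
#'
#' @inheritParams kinetic_energy
#' @return Numeric vector of length `n_phases` (mW); with `keep_maps`,
#'   per-phase EL density maps (W/m^3) as attribute `density`.
#' @export
viscous_energy_loss_rate <- function(field, mask, cfg = energetics_config(),
                                     keep_maps = FALSE) {
  stopifnot(inherits(field, "flow_field"), inherits(mask, "vessel_mask"))
  m <- mask$values
  d <- dim(field$values)
  vvox <- prod(field$meta$spacing) * 1e-9
  el <- numeric(d[4L])
  n_clipped <- 0L
  maps <- if (keep_maps) array(0, d[1:4])
  for (ph in seq_len(d[4L])) {
    gt <- velocity_gradient_tensor(field, mask, ph, cfg$boundary_scheme)
    g <- gt$grad
    phi <- array(0, d[1:3])
    for (i in 1:3) for (j in 1:3)
      phi <- phi + 0.5 * (g[, , , i, j] + g[, , , j, i])^2
    if (cfg$include_divergence_term) {
      div <- g[, , , 1, 1] + g[, , , 2, 2] + g[, , , 3, 3]
      phi <- phi - (2 / 3) * div^2
      neg <- m & phi < 0
      n_clipped <- n_clipped + sum(neg)
      phi[neg] <- 0
    }
    dens <- cfg$dynamic_viscosity * phi        # W/m^3
    el[ph] <- sum(dens[m]) * vvox * 1000       # mW
    if (keep_maps) {
      dens[!m] <- 0
      maps[, , , ph] <- dens
    }
  }
  attr(el, "n_clipped") <- n_clipped
  if (keep_maps) attr(el, "density") <- maps
  el
}

#' Cardiac-cycle average of a per-phase series
#'
#' Retrospective ECG gating reconstructs phases of equal duration, so the
#' cycle average is the unweighted arithmetic mean.
#'
#' @param series numeric per-phase values (length >= 1).
#' @return The scalar mean.
#' @export
cycle_average <- function(series) {
  if (length(series) < 1L) stop("empty per-phase series", call. = FALSE)
  mean(as.numeric(series))
}

#' Flow (and length) normalization of cycle-averaged energetics
#'
#' Total-TCPC energetics are normalized for inflow (SVC + Fontan tunnel flow,
#' L/min); branch segments are additionally normalized for segment length
#' (cm) because segments are not always completely available; the Fontan
#' confluence is normalized for flow only.
#'
#' @param ke_avg cycle-averaged KE, mJ.
#' @param el_avg cycle-averaged EL, mW.
#' @param inflow inflow in L/min (> 0).
#' @param length segment length in cm, or `NULL` for flow-only
#'   normalization.
#' @return A list of class `normalized_energetics`: `ke_norm_flow`
#'   (mJ per L/min), `el_norm_flow` (mW per L/min) and, when `length` is
#'   given, `ke_norm_flow_length` / `el_norm_flow_length` (per cm).
#' @export
normalize_energetics <- function(ke_avg, el_avg, inflow, length = NULL) {
  if (!is.finite(inflow) || inflow <= 0)
    stop("normalization requires inflow > 0 (L/min)", call. = FALSE)
  out <- list(ke_norm_flow = ke_avg / inflow,
              el_norm_flow = el_avg / inflow,
              inflow_l_min = inflow, flow_only = is.null(length))
  if (!is.null(length)) {
    if (!is.finite(length) || length <= 0)
      stop("segment length must be > 0 (cm)", call. = FALSE)
    out$length_cm <- length
    out$ke_norm_flow_length <- ke_avg / (inflow * length)
    out$el_norm_flow_length <- el_avg / (inflow * length)
  }
  class(out) <- "normalized_energetics"
  out
}

#' Per-phase and cycle-averaged energetics over a mask
#'
#' Convenience wrapper bundling [kinetic_energy()],
#' [viscous_energy_loss_rate()] and [cycle_average()].
#'
#' @inheritParams kinetic_energy
#' @return An object of class `energetics_series` with `ke_per_phase` (mJ),
#'   `el_per_phase` (mW), `ke_cycle_avg`, `el_cycle_avg`.
#' @export
energetics_series <- function(field, mask, cfg = energetics_config(),
                              keep_maps = FALSE) {
  ke <- kinetic_energy(field, mask, cfg, keep_maps = keep_maps)
  el <- viscous_energy_loss_rate(field, mask, cfg, keep_maps = keep_maps)
  structure(list(ke_per_phase = as.numeric(ke), el_per_phase = as.numeric(el),
                 ke_cycle_avg = cycle_average(ke),
                 el_cycle_avg = cycle_average(el),
                 n_clipped = attr(el, "n_clipped"),
                 ke_density = attr(ke, "density"),
                 el_density = attr(el, "density")),
            class = "energetics_series")
}

#' @export
print.energetics_series <- function(x, ...) {
  cat(sprintf(
    "<energetics_series> %d phases; KE avg %.4g mJ, EL avg %.4g mW\n",
    length(x$ke_per_phase), x$ke_cycle_avg, x$el_cycle_avg))
  invisible(x)
}
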