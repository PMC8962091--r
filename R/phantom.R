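#' Specification of a synthetic 4D flow phantom
#'
#' Describes a pulsatile laminar phantom with analytic ground truth:
#' parabolic (Poiseuille) profiles in straight branches, scaled per cardiac
#' phase by a nonnegative waveform, with optional additive Gaussian velocity
#' noise and VENC wrapping applied after the analytic field is recorded.
#'
#' Geometries:
#' * `straight_tube` — one grid-aligned tube (axis z).
#' * `tilted_tube` — one tube with axis tilted `tilt_deg` from z in the x-z
#'   plane.
#' * `two_tube_disjoint` — two parallel, disconnected z-tubes.
#' * `tcpc_junction` — four branches (Fontan tunnel and SVC inflows along
#'   z, LPA/RPA outflows along x) meeting in a blended cross junction. The
#'   junction blend is explicitly non-analytic (no Navier-Stokes solve) and
#'   is excluded from closed-form comparisons.
#'
#' Defaults emulate a resting Fontan circulation: total venous return 3.5
#' L/min with 70% carried by the tunnel, an LPA fraction of 0.45, branch
#' radii of 9 mm (tunnel, ~18 mm conduit), 7 mm (SVC), 6 mm (LPA) and 7 mm
#' (RPA), VENC 80 cm/s, 24 phases, and a raised-cosine venous waveform with
#' peak/mean ratio 2.
#'
#' @param geometry one of `"straight_tube"`, `"tilted_tube"`,
#'   `"two_tube_disjoint"`, `"tcpc_junction"`.
#' @param radius_mm branch radius in mm; for `tcpc_junction` a named vector
#'   with entries `tunnel`, `svc`, `lpa`, `rpa` (missing entries take the
#'   defaults above).
#' @param length_mm branch length in mm (same naming rule).
#' @param q_l_min mean flow in L/min: the (single) tube flow, or for the
#'   junction the total venous return (tunnel + SVC).
#' @param tunnel_fraction fraction of total inflow carried by the tunnel
#'   (default 0.7).
#' @param flow_split LPA fraction of total outflow (default 0.45).
#' @param waveform nonnegative per-phase weights of mean 1 (length
#'   `n_phases`), or `NULL` for the raised-cosine default; `"steady"` gives
#'   constant 1.
#' @param n_phases cardiac phases (default 24).
#' @param spacing_mm isotropic voxel spacing (default 1).
#' @param noise_sd additive Gaussian velocity noise SD in m/s (default 0,
#'   i.e. the uncorrupted phantom).
#' @param venc_cm_s velocity encoding limit stored with the data (default
#'   80).
#' @param wrap apply VENC wrapping to the output field (default FALSE).
#' @param tilt_deg tilt angle for `tilted_tube` (default 30).
#' @param rr_ms RR interval (default 1000).
#' @param seed integer seed fixing all randomness.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(geometry = c("straight_tube", "tilted_tube",
                                      "two_tube_disjoint", "tcpc_junction"),
                         radius_mm = NULL, length_mm = NULL, q_l_min = 3.5,
                         tunnel_fraction = 0.7, flow_split = 0.45,
                         waveform = NULL, n_phases = 24L, spacing_mm = 1,
                         noise_sd = 0, venc_cm_s = 80, wrap = FALSE,
                         tilt_deg = 30, rr_ms = 1000, seed = 1L) {
  geometry <- match.arg(geometry)
  n_phases <- as.integer(n_phases)
  stopifnot(n_phases >= 1L, q_l_min >= 0, spacing_mm > 0, venc_cm_s > 0,
            noise_sd >= 0, tunnel_fraction > 0, tunnel_fraction < 1,
            flow_split > 0, flow_split < 1)
  if (geometry == "tcpc_junction") {
    rdef <- c(tunnel = 9, svc = 7, lpa = 6, rpa = 7)
    ldef <- c(tunnel = 45, svc = 40, lpa = 40, rpa = 40)
    radius_mm <- fill_named(radius_mm, rdef)
    length_mm <- fill_named(length_mm, ldef)
  } else {
    if (is.null(radius_mm)) radius_mm <- 8
    if (is.null(length_mm)) length_mm <- 100
    radius_mm <- unname(radius_mm[1L])
    length_mm <- unname(length_mm[1L])
  }
  stopifnot(all(radius_mm > 0), all(length_mm > 0))
  if (identical(waveform, "steady")) waveform <- rep(1, n_phases)
  if (is.null(waveform))
    waveform <- 1 + cos(2 * pi * (seq_len(n_phases) - 1L) / n_phases)
  waveform <- as.numeric(waveform)
  if (length(waveform) != n_phases)
    stop("waveform length must equal n_phases", call. = FALSE)
  if (any(waveform < 0) || abs(mean(waveform) - 1) > 1e-8)
    stop("waveform must be nonnegative with mean 1", call. = FALSE)
  structure(list(geometry = geometry, radius_mm = radius_mm,
                 length_mm = length_mm, q_l_min = q_l_min,
                 tunnel_fraction = tunnel_fraction, flow_split = flow_split,
                 waveform = waveform, n_phases = n_phases,
                 spacing_mm = spacing_mm, noise_sd = noise_sd,
                 venc_cm_s = venc_cm_s, wrap = wrap, tilt_deg = tilt_deg,
                 rr_ms = rr_ms, seed = as.integer(seed)),
            class = "phantom_spec")
}

fill_named <- function(x, defaults) {
  out <- defaults
  if (!is.null(x)) {
    if (is.null(names(x)) && length(x) == length(defaults))
      names(x) <- names(defaults)
    bad <- setdiff(names(x), names(defaults))
    if (length(bad)) stop("unknown branch name(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    out[names(x)] <- x
  }
  out
}

# closed-form steady Poiseuille energetics for one branch
# q m^3/s, r m, l m -> KE in mJ, EL in mW
poiseuille_closed_form <- function(q_m3s, r_m, l_m,
                                   rho = 1060, mu = 3.2e-3) {
  list(ke_mj = (2 / 3) * rho * q_m3s^2 * l_m / (pi * r_m^2) * 1000,
       el_mw = 8 * mu * l_m * q_m3s^2 / (pi * r_m^4) * 1000)
}

#' Generate a synthetic 4D flow phantom with ground truth
#'
#' Builds the analytic laminar field for the requested geometry, records the
#' uncorrupted ground-truth bundle (field, geometric mask, segment labels,
#' analytic centerlines, per-branch flows and closed-form energetics), then
#' applies noise and VENC wrapping in that fixed order to produce the
#' "measured" field. All randomness is fixed by `spec$seed`.
#'
#' Ground-truth energetics are the closed forms for steady Poiseuille flow,
#' KE = (2/3) rho Q^2 L / (pi R^2) and EL = 8 mu L Q^2 / (pi R^4), scaled per
#' phase by `w(t)^2`; they are computed, not measured, and apply to the
#' straight-branch portions only (the junction blend carries no closed form).
#'
#' @param spec a [phantom_spec()].
#' @param rho,mu density (kg/m^3) and viscosity (Pa.s) used for the
#'   closed-form ground truth (defaults match [energetics_config()]).
#' @return A list: `field` (the corrupted [flow_field()]), and `truth` with
#'   `field` (analytic), `mask` ([vessel_mask()]), `labels` (integer array,
#'   0 background then tunnel/svc/lpa/rpa/confluence = 1..5 for the
#'   junction, 1 per tube), `branches` (data frame with radius, length, flow
#'   and closed-form energetics per branch), `centerline` (list of
#'   data frames x,y,z,arclength in world mm), `endpoints` (labeled world-mm
#'   endpoint seeds), `junction_world`, `q_per_phase` (branch x phase
#'   L/min), `waveform`, and `spec`.
#' @export
generate_phantom <- function(spec, rho = 1060, mu = 3.2e-3) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  h <- spec$spacing_mm
  geom <- switch(spec$geometry,
                 straight_tube = build_tube(spec, tilt = 0),
                 tilted_tube = build_tube(spec, tilt = spec$tilt_deg),
                 two_tube_disjoint = build_two_tubes(spec),
                 tcpc_junction = build_tcpc(spec))
  meta <- acquisition_meta(spacing = rep(h, 3L), n_phases = spec$n_phases,
                           venc_cm_s = spec$venc_cm_s, rr_ms = spec$rr_ms)
  d <- dim(geom$mask)
  nt <- spec$n_phases
  values <- array(0, c(d, nt, 3L))
  for (ph in seq_len(nt)) {
    w <- spec$waveform[ph]
    for (i in 1:3) values[, , , ph, i] <- geom$vel[, , , i] * w
  }
  truth_field <- flow_field(values, meta)

  # per-branch closed forms
  br <- geom$branches
  cf <- poiseuille_closed_form(br$q_l_min / 60000, br$radius_mm / 1000,
                               br$length_mm / 1000, rho = rho, mu = mu)
  w2 <- mean(spec$waveform^2)
  br$ke_steady_mj <- cf$ke_mj
  br$el_steady_mw <- cf$el_mw
  br$ke_cycle_mj <- cf$ke_mj * w2
  br$el_cycle_mw <- cf$el_mw * w2
  q_per_phase <- outer(br$q_l_min, spec$waveform)
  rownames(q_per_phase) <- br$branch

  # corruption: analytic -> noise -> aliasing (ground truth is pre-wrap)
  corrupted <- values
  if (spec$noise_sd > 0)
    corrupted <- corrupted + array(stats::rnorm(length(corrupted),
                                                sd = spec$noise_sd),
                                   dim(corrupted))
  if (spec$wrap) {
    venc <- spec$venc_cm_s / 100
    over <- abs(corrupted) > venc  # in-range values stay bit-identical
    corrupted[over] <- ((corrupted[over] + venc) %% (2 * venc)) - venc
  }
  field <- flow_field(corrupted, meta)

  list(field = field,
       truth = list(field = truth_field,
                    mask = vessel_mask(geom$mask, meta),
                    labels = geom$labels,
                    branches = br,
                    centerline = geom$centerline,
                    endpoints = geom$endpoints,
                    junction_world = geom$junction,
                    q_per_phase = q_per_phase,
                    waveform = spec$waveform,
                    spec = spec))
}

# world coordinate arrays for a grid (voxel centres, origin 0, identity
# orientation)
coord_arrays <- function(d, h) {
  list(x = array(rep((seq_len(d[1]) - 1) * h, times = d[2] * d[3]), d),
       y = array(rep(rep((seq_len(d[2]) - 1) * h, each = d[1]),
                     times = d[3]), d),
       z = array(rep((seq_len(d[3]) - 1) * h, each = d[1] * d[2]), d))
}

# parabolic profile sampled on branch local coordinates
# returns list(inside, s, r2) for axis through c0 with unit direction u
branch_coords <- function(co, c0, u, radius, len) {
  dx <- co$x - c0[1]; dy <- co$y - c0[2]; dz <- co$z - c0[3]
  s <- dx * u[1] + dy * u[2] + dz * u[3]
  r2 <- (dx - s * u[1])^2 + (dy - s * u[2])^2 + (dz - s * u[3])^2
  list(s = s, r2 = r2,
       inside = r2 <= radius^2 & s >= 0 & s <= len)
}

centerline_df <- function(c0, u, len, step = 1) {
  s <- seq(0, len, by = step)
  data.frame(x = c0[1] + s * u[1], y = c0[2] + s * u[2],
             z = c0[3] + s * u[3], arclength = s)
}

build_tube <- function(spec, tilt = 0) {
  h <- spec$spacing_mm
  R <- spec$radius_mm; L <- spec$length_mm
  th <- tilt * pi / 180
  u <- c(sin(th), 0, cos(th))
  margin <- max(2, 2 * h)
  if (tilt == 0) {
    # grid-aligned tube spans the whole z extent (a vessel crossing the
    # FOV): no artificial end faces, and the voxelized volume matches the
    # nominal length L exactly (nz * h = L)
    nx <- ny <- 2L * ceiling((R + margin) / h) + 1L
    nz <- max(3L, round(L / h))
    d <- c(nx, ny, nz)
    ctr <- (d - 1) / 2 * h
    c0 <- c(ctr[1], ctr[2], 0)
    Leff <- (nz - 1) * h
  } else {
    # bounding box of the clipped cylinder + margin
    half_x <- L / 2 * abs(u[1]) + R + margin
    half_z <- L / 2 * abs(u[3]) + R * abs(u[1]) + margin
    nx <- 2L * ceiling(half_x / h) + 1L
    ny <- 2L * ceiling((R + margin) / h) + 1L
    nz <- 2L * ceiling(half_z / h) + 1L
    d <- c(nx, ny, nz)
    ctr <- (d - 1) / 2 * h
    c0 <- ctr - u * L / 2
    Leff <- L
  }
  co <- coord_arrays(d, h)
  bc <- branch_coords(co, c0, u, R, Leff)
  vmax <- 2 * (spec$q_l_min / 60000) / (pi * (R / 1000)^2)  # m/s
  prof <- vmax * pmax(0, 1 - bc$r2 / R^2)
  vel <- array(0, c(d, 3L))
  for (i in 1:3) vel[, , , i] <- ifelse(bc$inside, prof * u[i], 0)
  labels <- array(0L, d)
  labels[bc$inside] <- 1L
  list(mask = bc$inside, vel = vel, labels = labels,
       branches = data.frame(branch = "tube", radius_mm = R, length_mm = L,
                             q_l_min = spec$q_l_min,
                             stringsAsFactors = FALSE),
       centerline = list(tube = centerline_df(c0, u, Leff)),
       endpoints = data.frame(branch = c("tube_start", "tube_end"),
                              x = c(c0[1], c0[1] + u[1] * Leff),
                              y = c(c0[2], c0[2] + u[2] * Leff),
                              z = c(c0[3], c0[3] + u[3] * Leff),
                              stringsAsFactors = FALSE),
       junction = NULL)
}

build_two_tubes <- function(spec) {
  h <- spec$spacing_mm
  R <- spec$radius_mm; L <- spec$length_mm
  margin <- max(2, 2 * h)
  gap <- max(4, 4 * h)
  cx <- c(R + margin, R + margin + 2 * R + gap)
  nx <- ceiling((2 * (2 * R + margin) + gap) / h) + 1L
  ny <- 2L * ceiling((R + margin) / h) + 1L
  nz <- max(2L, round(L / h))
  d <- c(nx, ny, nz)
  cy <- (ny - 1) / 2 * h
  co <- coord_arrays(d, h)
  u <- c(0, 0, 1)
  vmax <- 2 * (spec$q_l_min / 60000) / (pi * (R / 1000)^2)
  mask <- array(FALSE, d)
  labels <- array(0L, d)
  vel <- array(0, c(d, 3L))
  cl <- list()
  for (t in 1:2) {
    c0 <- c(cx[t], cy, 0)
    bc <- branch_coords(co, c0, u, R, (nz - 1) * h)
    mask <- mask | bc$inside
    labels[bc$inside] <- t
    vz <- vel[, , , 3]
    vz[bc$inside] <- vmax * (1 - bc$r2[bc$inside] / R^2)
    vel[, , , 3] <- vz
    cl[[paste0("tube_", letters[t])]] <- centerline_df(c0, u, (nz - 1) * h)
  }
  list(mask = mask, vel = vel, labels = labels,
       branches = data.frame(branch = c("tube_a", "tube_b"),
                             radius_mm = R, length_mm = (nz - 1) * h,
                             q_l_min = spec$q_l_min,
                             stringsAsFactors = FALSE),
       centerline = cl,
       endpoints = data.frame(branch = c("a_start", "a_end"),
                              x = cx[c(1, 1)], y = c(cy, cy),
                              z = c(0, (nz - 1) * h),
                              stringsAsFactors = FALSE),
       junction = NULL)
}

build_tcpc <- function(spec) {
  h <- spec$spacing_mm
  R <- spec$radius_mm
  L <- spec$length_mm
  Q <- spec$q_l_min
  qb <- c(tunnel = Q * spec$tunnel_fraction,
          svc = Q * (1 - spec$tunnel_fraction),
          lpa = Q * spec$flow_split,
          rpa = Q * (1 - spec$flow_split))
  # unit axis direction (from junction outward) and flow direction per branch
  dirs <- list(tunnel = c(0, 0, -1), svc = c(0, 0, 1),
               lpa = c(-1, 0, 0), rpa = c(1, 0, 0))
  flow <- list(tunnel = c(0, 0, 1), svc = c(0, 0, -1),
               lpa = c(-1, 0, 0), rpa = c(1, 0, 0))
  margin <- max(2, 2 * h)
  nx <- ceiling((L["lpa"] + L["rpa"] + 2 * margin) / h) + 1L
  ny <- 2L * ceiling((max(R) + margin) / h) + 1L
  nz <- ceiling((L["tunnel"] + L["svc"] + 2 * margin) / h) + 1L
  d <- c(nx, ny, nz)
  C <- c(L["lpa"] + margin, (ny - 1) / 2 * h, L["tunnel"] + margin)
  names(C) <- NULL
  co <- coord_arrays(d, h)
  r_blend <- 1.25 * max(R)
  dc2 <- (co$x - C[1])^2 + (co$y - C[2])^2 + (co$z - C[3])^2
  in_ball <- dc2 <= r_blend^2

  branches <- names(dirs)
  bcs <- lapply(branches, function(b)
    branch_coords(co, C, dirs[[b]], R[b], L[b]))
  names(bcs) <- branches

  # branch cylinders may collide in thin corner slivers just outside the
  # blend ball; such near-junction collisions are absorbed into the
  # junction region. Collisions far from the junction mean the requested
  # geometry is invalid.
  pure_any <- array(FALSE, d)
  collision <- array(FALSE, d)
  for (b in branches) {
    pure0 <- bcs[[b]]$inside & !in_ball
    collision <- collision | (pure_any & pure0)
    pure_any <- pure_any | pure0
  }
  if (any(collision)) {
    if (any(collision & dc2 > (2 * r_blend)^2))
      stop("spec error: branches geometrically overlap outside the ",
           "junction", call. = FALSE)
    in_ball <- in_ball | collision
  }

  mask <- in_ball
  vel <- array(0, c(d, 3L))
  wsum <- array(0, d)
  vbx <- array(0, d); vby <- array(0, d); vbz <- array(0, d)
  rel <- vector("list", 4L); names(rel) <- branches
  for (b in branches) {
    u <- dirs[[b]]
    bc <- bcs[[b]]
    rel[[b]] <- sqrt(bc$r2) / R[b]
    mask <- mask | bc$inside
    vmax <- 2 * (qb[b] / 60000) / (pi * (R[b] / 1000)^2)
    prof <- vmax * pmax(0, 1 - bc$r2 / R[b]^2)
    # pure branch region: inside the cylinder, beyond the blend ball
    pure <- bc$inside & !in_ball
    f <- flow[[b]]
    for (i in 1:3) {
      vi <- vel[, , , i]
      vi[pure] <- prof[pure] * f[i]
      vel[, , , i] <- vi
    }
    # blended contribution inside the ball from the extended profile; the
    # axial factor fades a branch out on the far side of the junction so
    # opposed inflows do not cancel across the ball
    wgt <- pmax(0, 1 - rel[[b]])^2 * pmax(0, 1 + bc$s / r_blend)
    contrib <- in_ball & wgt > 0
    wsum[contrib] <- wsum[contrib] + wgt[contrib]
    vbx[contrib] <- vbx[contrib] + wgt[contrib] * prof[contrib] * f[1]
    vby[contrib] <- vby[contrib] + wgt[contrib] * prof[contrib] * f[2]
    vbz[contrib] <- vbz[contrib] + wgt[contrib] * prof[contrib] * f[3]
  }
  bl <- in_ball & wsum > 0
  for (i in 1:3) {
    vi <- vel[, , , i]
    src <- list(vbx, vby, vbz)[[i]]
    vi[bl] <- src[bl] / wsum[bl]
    vel[, , , i] <- vi
  }

  # ground-truth labels: containing branch by smallest relative radius;
  # confluence where the axial station is within the confluence margin
  conf_margin <- mean(R)
  lab <- array(0L, d)
  best <- array(Inf, d)
  best_s <- array(Inf, d)
  for (bi in seq_along(branches)) {
    bc <- bcs[[bi]]
    better <- bc$inside & rel[[bi]] < best
    lab[better] <- bi
    best[better] <- rel[[bi]][better]
    best_s[better] <- bc$s[better]
  }
  lab[mask & lab == 0L] <- 5L                   # ball corners -> confluence
  lab[mask & lab > 0L & best_s < conf_margin] <- 5L
  lab[!mask] <- 0L

  cl <- lapply(branches, function(b)
    centerline_df(C, dirs[[b]], L[b]))
  names(cl) <- branches
  ep <- do.call(rbind, lapply(branches, function(b) {
    p <- C + dirs[[b]] * L[b]
    data.frame(branch = b, x = p[1], y = p[2], z = p[3],
               stringsAsFactors = FALSE)
  }))
  list(mask = mask, vel = vel, labels = lab,
       branches = data.frame(branch = branches,
                             radius_mm = unname(R[branches]),
                             length_mm = unname(L[branches]),
                             q_l_min = unname(qb[branches]),
                             stringsAsFactors = FALSE),
       centerline = cl, endpoints = ep, junction = C)
}
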