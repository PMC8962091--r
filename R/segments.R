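#' Divide a TCPC mask into five anatomical segments
#'
#' Assigns every mask voxel to the branch of its nearest centerline node;
#' voxels whose nearest node lies within `confluence_margin` (arclength from
#' the junction) form the central Fontan confluence. Branch segment lengths
#' are the centerline arclength outside the confluence; segments shorter
#' than 1.5 cm are flagged excluded (too few voxels for reliable
#' energetics).
#'
#' @param mask a [vessel_mask()].
#' @param centerline a 4-branch [extract_centerline()] tree with a junction.
#' @param confluence_margin margin in mm; default one local mean radius,
#'   estimated from the erosion depth at the junction ends of the branches.
#' @param min_length_cm inclusion threshold for branch segments (default
#'   1.5).
#' @return An object of class `segment_set`: `labels` (integer array, 0
#'   background, branches in tree order then confluence last), `segments`
#'   (names in label order), `lengths_cm`, `included` flags and the margin
#'   used.
#' @export
label_segments <- function(mask, centerline, confluence_margin = NULL,
                           min_length_cm = 1.5) {
  stopifnot(inherits(mask, "vessel_mask"),
            inherits(centerline, "centerline_tree"))
  if (length(centerline$branches) != 4L || is.null(centerline$junction))
    stop("labeling error: five-segment division needs a 4-branch ",
         "centerline with a junction", call. = FALSE)
  m <- mask$values
  d <- dim(m)
  h <- mask$meta$spacing

  if (is.null(confluence_margin)) {
    depth <- erosion_depth(m)
    # local vessel radius from the erosion depth at mid-branch (away from
    # the junction, where the lumen is a plain tube)
    r_est <- vapply(centerline$branches, function(br) {
      p <- as.numeric(br[ceiling(nrow(br) / 2), c("x", "y", "z")])
      v <- round(world_to_voxel(mask$meta, p)) + 1L
      v <- pmin(pmax(v, 1L), matrix(d, 1L))
      depth[v[1L], v[2L], v[3L]] * mean(h)
    }, 1)
    confluence_margin <- mean(r_est)
  }

  nodes <- do.call(rbind, lapply(seq_along(centerline$branches), function(b) {
    br <- centerline$branches[[b]]
    cbind(br$x, br$y, br$z, b, br$arclength)
  }))
  idx <- which(m)
  ijk <- arrayInd(idx, d)
  w <- voxel_to_world(mask$meta, ijk - 1L)
  # nearest centerline node, chunked to bound memory
  nb <- integer(length(idx))
  chunk <- 20000L
  for (start in seq(1L, length(idx), by = chunk)) {
    rows <- start:min(start + chunk - 1L, length(idx))
    d2 <- outer(rowSums(w[rows, , drop = FALSE]^2), rowSums(nodes[, 1:3]^2),
                `+`) - 2 * (w[rows, , drop = FALSE] %*% t(nodes[, 1:3]))
    nb[rows] <- max.col(-d2, ties.method = "first")
  }
  branch_of <- nodes[nb, 4L]
  arc_of <- nodes[nb, 5L]

  segs <- c(names(centerline$branches), "confluence")
  conf_id <- length(segs)
  lab_vox <- ifelse(arc_of < confluence_margin, conf_id, branch_of)
  labels <- array(0L, d)
  labels[idx] <- lab_vox

  lengths_cm <- vapply(centerline$branches, function(br)
    max(0, branch_length(br) - confluence_margin) / 10, 1)
  lengths_cm <- c(lengths_cm, confluence = NA_real_)
  names(lengths_cm) <- segs
  included <- ifelse(is.na(lengths_cm), TRUE, lengths_cm >= min_length_cm)
  empty <- !(seq_along(segs) %in% unique(lab_vox))
  included[empty] <- FALSE

  structure(list(labels = labels, segments = segs,
                 lengths_cm = lengths_cm, included = included,
                 confluence_margin_mm = confluence_margin,
                 meta = mask$meta),
            class = "segment_set")
}

#' @export
print.segment_set <- function(x, ...) {
  cat("<segment_set>\n")
  for (i in seq_along(x$segments))
    cat(sprintf("  %d %-12s %6d voxels, length %s cm%s\n", i, x$segments[i],
                sum(x$labels == i),
                ifelse(is.na(x$lengths_cm[i]), "--",
                       sprintf("%.1f", x$lengths_cm[i])),
                ifelse(x$included[i], "", "  [excluded]")))
  invisible(x)
}

#' Logical mask of one segment
#' @param segset a [label_segments()] result.
#' @param segment segment name or index.
#' @param meta grid metadata (defaults to the set's).
#' @return A [vessel_mask()].
#' @export
segment_mask <- function(segset, segment, meta = segset$meta) {
  i <- if (is.character(segment)) match(segment, segset$segments) else
    as.integer(segment)
  if (is.na(i)) stop("unknown segment: ", segment, call. = FALSE)
  vessel_mask(segset$labels == i, meta)
}

#' Cross-sectional area profile along a centerline branch
#'
#' At 1 mm arclength intervals the mask is resampled on a plane
#' perpendicular to the local centerline tangent (nearest-neighbour
#' sampling on a 0.25 mm in-plane grid); the CSA at each station is the
#' area of the in-plane connected component containing the centerline
#' point. Stations with an empty cross-section are skipped and reported.
#'
#' @param mask a [vessel_mask()].
#' @param branch a branch data frame from [extract_centerline()].
#' @param bsa body surface area in m^2 (for the BSA-normalized profile);
#'   `NULL` to skip normalization.
#' @param step arclength sampling interval, mm (default 1).
#' @param inplane_step in-plane sampling pitch, mm (default 0.25).
#' @param inplane_halfwidth in-plane half-extent, mm (default 15).
#' @return An object of class `csa_profile`: data frame `profile`
#'   (`arclength`, `csa_cm2`, `csa_bsa`), `mean_csa_cm2`, `mean_csa_bsa`,
#'   `n_skipped`.
#' @export
csa_profile <- function(mask, branch, bsa = NULL, step = 1,
                        inplane_step = 0.25, inplane_halfwidth = 15) {
  stopifnot(inherits(mask, "vessel_mask"))
  if (branch_length(branch) < 2)
    stop("branch shorter than 2 mm", call. = FALSE)
  if (!is.null(bsa) && bsa <= 0) stop("bsa must be > 0", call. = FALSE)
  poly <- resample_polyline(branch, step)
  n <- nrow(poly)
  pts <- as.matrix(poly[, c("x", "y", "z")])
  # tangents: central differences along the resampled polyline
  tang <- rbind(pts[2, ] - pts[1, ],
                if (n > 2) pts[3:n, , drop = FALSE] -
                  pts[1:(n - 2), , drop = FALSE],
                pts[n, ] - pts[n - 1, ])
  tang <- tang / sqrt(rowSums(tang^2))
  g <- seq(-inplane_halfwidth, inplane_halfwidth, by = inplane_step)
  gg <- as.matrix(expand.grid(a = g, b = g))
  ng <- length(g)
  ctr_cell <- (ng + 1L) %/% 2L
  m <- mask$values
  d <- dim(m)
  csa <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    tb <- plane_basis(tang[i, ])
    pw <- matrix(pts[i, ], nrow(gg), 3L, byrow = TRUE) +
      gg[, 1L] %o% tb$e1 + gg[, 2L] %o% tb$e2
    v <- round(world_to_voxel(mask$meta, pw)) + 1L
    inb <- v[, 1] >= 1L & v[, 1] <= d[1] & v[, 2] >= 1L & v[, 2] <= d[2] &
      v[, 3] >= 1L & v[, 3] <= d[3]
    inm <- logical(nrow(v))
    inm[inb] <- m[v[inb, , drop = FALSE]]
    plane <- array(inm, c(ng, ng, 1L))
    if (!plane[ctr_cell, ctr_cell, 1L]) next
    comp <- flood_select(plane, cbind(ctr_cell, ctr_cell, 1L),
                         connectivity = 26L)
    csa[i] <- sum(comp) * inplane_step^2 / 100  # cm^2
  }
  ok <- !is.na(csa)
  profile <- data.frame(arclength = poly$arclength[ok], csa_cm2 = csa[ok])
  if (!is.null(bsa)) profile$csa_bsa <- profile$csa_cm2 / bsa
  structure(list(profile = profile,
                 mean_csa_cm2 = mean(profile$csa_cm2),
                 mean_csa_bsa = if (!is.null(bsa))
                   mean(profile$csa_cm2) / bsa,
                 n_skipped = sum(!ok)),
            class = "csa_profile")
}

# orthonormal in-plane basis perpendicular to a unit tangent
plane_basis <- function(t) {
  a <- if (abs(t[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- c(t[2] * a[3] - t[3] * a[2], t[3] * a[1] - t[1] * a[3],
          t[1] * a[2] - t[2] * a[1])
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(t[2] * e1[3] - t[3] * e1[2], t[3] * e1[1] - t[1] * e1[3],
          t[1] * e1[2] - t[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

#' @export
print.csa_profile <- function(x, ...) {
  cat(sprintf("<csa_profile> %d stations, mean CSA %.3f cm^2%s\n",
              nrow(x$profile), x$mean_csa_cm2,
              if (!is.null(x$mean_csa_bsa))
                sprintf(" (%.3f cm^2/m^2)", x$mean_csa_bsa) else ""))
  invisible(x)
}

#' Through-plane flow
#'
#' Flux of the velocity field through an oriented plane restricted to the
#' vessel mask: the plane is sampled on a 0.5 mm in-plane grid, velocities
#' are trilinearly interpolated, and the flux is the sum of (v . n) dA over
#' in-mask samples, converted to L/min. The sign convention follows the
#' supplied normal (point it toward the confluence for inflow-positive
#' branches).
#'
#' @param field a [flow_field()].
#' @param mask a [vessel_mask()].
#' @param origin,normal plane origin and normal in world mm.
#' @param inplane_step sampling pitch, mm (default 0.5).
#' @param inplane_halfwidth half-extent, mm (default 20).
#' @return A list: `per_phase` (L/min per cardiac phase), `cycle_mean`.
#' @export
plane_flow <- function(field, mask, origin, normal, inplane_step = 0.5,
                       inplane_halfwidth = 20) {
  stopifnot(inherits(field, "flow_field"), inherits(mask, "vessel_mask"))
  nrm <- as.numeric(normal)
  nrm <- nrm / sqrt(sum(nrm^2))
  tb <- plane_basis(nrm)
  g <- seq(-inplane_halfwidth, inplane_halfwidth, by = inplane_step)
  gg <- as.matrix(expand.grid(a = g, b = g))
  pw <- matrix(as.numeric(origin), nrow(gg), 3L, byrow = TRUE) +
    gg[, 1L] %o% tb$e1 + gg[, 2L] %o% tb$e2
  vox <- world_to_voxel(field$meta, pw)
  d <- dim(mask$values)
  vr <- round(vox) + 1L
  inb <- vr[, 1] >= 1L & vr[, 1] <= d[1] & vr[, 2] >= 1L & vr[, 2] <= d[2] &
    vr[, 3] >= 1L & vr[, 3] <= d[3]
  inm <- logical(nrow(vr))
  inm[inb] <- mask$values[vr[inb, , drop = FALSE]]
  if (!any(inm))
    stop("geometry error: plane does not intersect the mask", call. = FALSE)
  pts <- vox[inm, , drop = FALSE]
  da <- inplane_step^2 * 1e-6  # m^2
  nt <- field$meta$n_phases
  # mask-normalized interpolation: out-of-lumen voxels carry no velocity
  # information, so interpolate v*m and divide by the interpolated mask
  # weight (avoids wall-adjacent underestimation)
  mnum <- array(as.numeric(mask$values), d)
  wm <- trilinear(mnum, pts)
  wm[wm <= 0] <- 1
  per_phase <- numeric(nt)
  for (ph in seq_len(nt)) {
    vn <- numeric(nrow(pts))
    for (i in 1:3) {
      a <- field$values[, , , ph, i, drop = TRUE]
      dim(a) <- d
      vn <- vn + nrm[i] * trilinear(a * mnum, pts) / wm
    }
    per_phase[ph] <- sum(vn) * da * 60000  # m^3/s -> L/min
  }
  list(per_phase = per_phase, cycle_mean = mean(per_phase))
}

# trilinear interpolation of a 3D array at continuous 0-based voxel coords
trilinear <- function(a, p) {
  d <- dim(a)
  p0 <- pmin(pmax(p, 0), matrix(d - 1, nrow(p), 3L, byrow = TRUE))
  f <- floor(p0)
  t <- p0 - f
  i0 <- f + 1L
  i1 <- pmin(i0 + 1L, matrix(d, nrow(p), 3L, byrow = TRUE))
  val <- numeric(nrow(p))
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    wgt <- (if (cx) t[, 1] else 1 - t[, 1]) *
      (if (cy) t[, 2] else 1 - t[, 2]) *
      (if (cz) t[, 3] else 1 - t[, 3])
    ii <- cbind(if (cx) i1[, 1] else i0[, 1],
                if (cy) i1[, 2] else i0[, 2],
                if (cz) i1[, 3] else i0[, 3])
    val <- val + wgt * a[ii]
  }
  val
}

#' Haycock body surface area
#'
#' BSA (m^2) = 0.024265 * weight^0.5378 * height^0.3964, with weight in kg
#' and height in cm.
#'
#' @param weight_kg body weight, kg (> 0).
#' @param height_cm body height, cm (> 0).
#' @export
haycock_bsa <- function(weight_kg, height_cm) {
  if (any(!is.finite(weight_kg)) || any(weight_kg <= 0) ||
      any(!is.finite(height_cm)) || any(height_cm <= 0))
    stop("weight and height must be positive", call. = FALSE)
  0.024265 * weight_kg^0.5378 * height_cm^0.3964
}
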