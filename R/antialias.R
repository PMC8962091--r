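#' Correct velocity aliasing (VENC wrapping)
#'
#' Phase-contrast velocities beyond +/- VENC wrap around by multiples of
#' 2*VENC. Correction proceeds per component and cardiac phase by
#' quality-guided region growing, the standard spatial phase-unwrapping
#' strategy: voxels with |v| <= 0.6*VENC are taken as reliable anchors
#' (slow flow cannot be wrapped), the remaining candidates are visited in
#' order of increasing |v|, and each is shifted by the multiple of 2*VENC
#' that brings it closest to the mean of its already-reliable 6-connected
#' neighbours. A wrapped region is thereby peeled from its rim inward,
#' which also resolves contiguous wrapped cores whose interior is locally
#' self-consistent. Clean fields are returned unchanged and the corrected
#' output is a fixed point of the operator (idempotence).
#'
#' True speeds beyond ~2*VENC (double wraps relative to their
#' surroundings) are resolved toward the nearest consistent multiple; the
#' intended regime is the mild aliasing seen when peaks exceed VENC by a
#' modest fraction.
#'
#' @param field a [flow_field()]; `meta$venc_cm_s` must be set.
#' @param anchor_frac fraction of VENC below which a voxel is treated as a
#'   reliable anchor (default 0.6).
#' @return A list with `field` (corrected [flow_field()]) and `n_corrected`
#'   (total voxel-component-phase values shifted; 0 for clean fields).
#' @export
antialias_correct <- function(field, anchor_frac = 0.6) {
  stopifnot(inherits(field, "flow_field"))
  venc <- field$meta$venc_cm_s / 100  # m/s
  v <- field$values
  d <- dim(v)
  n_corrected <- 0L
  for (comp in 1:3) {
    for (ph in seq_len(d[4L])) {
      a <- v[, , , ph, comp, drop = TRUE]
      dim(a) <- d[1:3]
      res <- unwrap_volume(a, venc, anchor_frac)
      n_corrected <- n_corrected + res$n
      v[, , , ph, comp] <- res$a
    }
  }
  out <- field
  out$values <- v
  list(field = out, n_corrected = n_corrected)
}

# region-growing unwrap of one 3D volume: reliable anchors grow outward in
# waves; each wave unwraps the not-yet-visited candidates adjacent to the
# visited set against the mean of their visited 6-neighbours
unwrap_volume <- function(a, venc, anchor_frac) {
  d <- dim(a)
  cand <- abs(a) > anchor_frac * venc
  if (!any(cand)) return(list(a = a, n = 0L))
  visited <- !cand
  off <- offsets_face()
  n <- 0L
  repeat {
    nsum <- array(0, d)
    ncnt <- array(0L, d)
    av <- a
    av[!visited] <- 0
    for (i in seq_len(nrow(off))) {
      nsum <- nsum + shift_arr3(av, off[i, 1], off[i, 2], off[i, 3], 0)
      ncnt <- ncnt + shift_arr3(visited, off[i, 1], off[i, 2], off[i, 3],
                                FALSE)
    }
    sel <- cand & !visited & ncnt > 0L
    if (!any(sel)) break
    ref <- nsum[sel] / ncnt[sel]
    k <- round((ref - a[sel]) / (2 * venc))
    a[sel] <- a[sel] + 2 * k * venc
    n <- n + sum(k != 0)
    visited[sel] <- TRUE
  }
  list(a = a, n = n)
}

#' Magnitude-weighted, time-averaged speed image
#'
#' The segmentation substrate: per voxel, the average over cardiac phases of
#' the speed `|v|`, weighted by the signal magnitude when available (uniform
#' weights otherwise). Nonnegative everywhere.
#'
#' @param field a [flow_field()].
#' @return A 3-axis array of speeds (m/s).
#' @export
magnitude_weighted_speed <- function(field) {
  stopifnot(inherits(field, "flow_field"))
  d <- dim(field$values)
  speed <- sqrt(rowSums(matrix(field$values, ncol = 3L)^2))
  dim(speed) <- d[1:4]
  if (is.null(field$magnitude)) {
    out <- apply(speed, 1:3, mean)
  } else {
    w <- field$magnitude
    wsum <- apply(w, 1:3, sum)
    out <- apply(speed * w, 1:3, sum) / ifelse(wsum > 0, wsum, 1)
  }
  dim(out) <- d[1:3]
  out
}
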