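# Small vectorized 3D binary-array routines used by segmentation and
# geometry: neighbourhood shifts, seeded flood fill (26-connectivity),
# closing, hole filling and an erosion-depth (city-block medialness) map.

# shift a 3D array by (dx, dy, dz), padding with `fill`
shift_arr3 <- function(a, dx, dy, dz, fill = 0) {
  d <- dim(a)
  out <- array(fill, d)
  sx <- seq_len(d[1]); sy <- seq_len(d[2]); sz <- seq_len(d[3])
  fx <- sx - dx; fy <- sy - dy; fz <- sz - dz
  kx <- fx >= 1 & fx <= d[1]; ky <- fy >= 1 & fy <= d[2]
  kz <- fz >= 1 & fz <= d[3]
  out[sx[kx], sy[ky], sz[kz]] <- a[fx[kx], fy[ky], fz[kz]]
  out
}

# neighbourhood offset tables
offsets_face <- function() {
  rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
        c(0, 0, 1), c(0, 0, -1))
}

offsets_full <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
}

# offsets within a Euclidean ball of radius r voxels
offsets_ball <- function(r) {
  s <- seq(-floor(r), floor(r))
  g <- as.matrix(expand.grid(dx = s, dy = s, dz = s))
  g[rowSums(g^2) <= r^2 & rowSums(abs(g)) > 0, , drop = FALSE]
}

# seeded flood fill: connected region of `mask` containing seed voxels.
# seeds: n x 3 matrix of 1-based voxel indices. Returns logical array.
flood_select <- function(mask, seeds, connectivity = 26L) {
  d <- dim(mask)
  off <- if (connectivity == 26L) offsets_full() else offsets_face()
  seeds <- matrix(as.integer(seeds), ncol = 3L)
  lin <- function(m) m[, 1L] + (m[, 2L] - 1L) * d[1L] +
    (m[, 3L] - 1L) * (d[1L] * d[2L])
  visited <- array(FALSE, d)
  sl <- lin(seeds)
  ok <- mask[sl]
  if (!any(ok)) return(visited)
  frontier <- seeds[ok, , drop = FALSE]
  visited[lin(frontier)] <- TRUE
  while (nrow(frontier) > 0L) {
    n <- nrow(frontier)
    cand <- frontier[rep(seq_len(n), each = nrow(off)), , drop = FALSE] +
      off[rep(seq_len(nrow(off)), times = n), , drop = FALSE]
    inb <- cand[, 1L] >= 1L & cand[, 1L] <= d[1L] &
      cand[, 2L] >= 1L & cand[, 2L] <= d[2L] &
      cand[, 3L] >= 1L & cand[, 3L] <= d[3L]
    cand <- cand[inb, , drop = FALSE]
    cl <- lin(cand)
    keep <- mask[cl] & !visited[cl]
    cand <- cand[keep, , drop = FALSE]
    cl <- cl[keep]
    if (length(cl) == 0L) break
    dup <- !duplicated(cl)
    frontier <- cand[dup, , drop = FALSE]
    visited[cl[dup]] <- TRUE
  }
  visited
}

binary_dilate <- function(mask, off) {
  out <- mask
  for (i in seq_len(nrow(off)))
    out <- out | shift_arr3(mask, off[i, 1], off[i, 2], off[i, 3], FALSE)
  out
}

binary_erode <- function(mask, off) {
  out <- mask
  for (i in seq_len(nrow(off)))
    out <- out & shift_arr3(mask, off[i, 1], off[i, 2], off[i, 3], FALSE)
  out
}

# morphological closing with a Euclidean ball of radius r voxels
binary_close <- function(mask, r = 1) {
  off <- offsets_ball(r)
  binary_erode(binary_dilate(mask, off), off)
}

# fill interior cavities: background connected (6-conn) to the array border
# stays background, the rest becomes foreground
fill_holes <- function(mask) {
  d <- dim(mask)
  bg <- !mask
  border <- array(FALSE, d)
  border[c(1L, d[1L]), , ] <- TRUE
  border[, c(1L, d[2L]), ] <- TRUE
  border[, , c(1L, d[3L])] <- TRUE
  seeds <- which(bg & border, arr.ind = TRUE)
  if (nrow(seeds) == 0L) return(mask)
  outside <- flood_select(bg, seeds, connectivity = 6L)
  mask | (bg & !outside)
}

# erosion depth: number of 6-conn erosions a voxel survives, a city-block
# distance-to-background used as a medialness weight for centerline paths
erosion_depth <- function(mask) {
  depth <- array(0, dim(mask))
  cur <- mask
  off <- offsets_face()
  while (any(cur)) {
    depth[cur] <- depth[cur] + 1
    cur <- binary_erode(cur, off)
  }
  depth
}
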