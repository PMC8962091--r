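#' Extract a labeled centerline tree from a vessel mask
#'
#' Centerlines are computed as medialness-weighted shortest paths on the
#' 26-connected voxel graph of the mask: edge lengths (mm) are divided by
#' the squared mean erosion depth of their endpoints, so minimal paths hug
#' the medial axis. The first endpoint seed is the root; the union of the
#' root-to-seed paths, split at the last node common to all of them (the
#' junction), gives one polyline per labeled branch. Polylines are smoothed
#' by an endpoint-preserving iterated moving average and carry a strictly
#' increasing arclength parameterization in mm, measured from the junction
#' (or from the root for a single branch).
#'
#' @param mask a [vessel_mask()].
#' @param endpoint_seeds data frame with columns `branch`, `x`, `y`, `z`:
#'   labeled endpoint positions in world mm near distinct mask extremities
#'   (2 for a single vessel, 4 for a TCPC).
#' @param smooth_iter moving-average smoothing iterations (default 10).
#' @param max_seed_dist_mm maximum allowed distance from a seed to the mask
#'   (default 10).
#' @return An object of class `centerline_tree`: `branches` (named list of
#'   data frames `x`, `y`, `z`, `arclength`), `junction` (world mm, or
#'   `NULL` for a single branch).
#' @export
extract_centerline <- function(mask, endpoint_seeds, smooth_iter = 10L,
                               max_seed_dist_mm = 10) {
  stopifnot(inherits(mask, "vessel_mask"))
  m <- mask$values
  d <- dim(m)
  if (sum(m) < 9L)
    stop("topology error: mask too small for centerline extraction",
         call. = FALSE)
  stopifnot(is.data.frame(endpoint_seeds),
            all(c("branch", "x", "y", "z") %in% names(endpoint_seeds)))
  if (nrow(endpoint_seeds) < 2L)
    stop("labeling error: need at least 2 endpoint seeds", call. = FALSE)

  idx <- which(m)
  ijk <- arrayInd(idx, d)
  w <- voxel_to_world(mask$meta, ijk - 1L)
  vid <- array(0L, d)
  vid[idx] <- seq_along(idx)
  depth <- erosion_depth(m)
  dep <- depth[idx]

  # edges: 13 positive offsets of the 26-neighbourhood
  off <- offsets_full()
  off <- off[off[, 1] * 9 + off[, 2] * 3 + off[, 3] > 0, , drop = FALSE]
  h <- mask$meta$spacing
  efrom <- integer(0); eto <- integer(0); ew <- numeric(0)
  for (o in seq_len(nrow(off))) {
    nb <- ijk + matrix(off[o, ], nrow(ijk), 3L, byrow = TRUE)
    ok <- nb[, 1] >= 1L & nb[, 1] <= d[1] & nb[, 2] >= 1L & nb[, 2] <= d[2] &
      nb[, 3] >= 1L & nb[, 3] <= d[3]
    nl <- nb[ok, 1] + (nb[ok, 2] - 1L) * d[1] + (nb[ok, 3] - 1L) * d[1] * d[2]
    tv <- vid[nl]
    keep <- tv > 0L
    fv <- seq_along(idx)[ok][keep]
    tv <- tv[keep]
    len <- sqrt(sum((off[o, ] * h)^2))
    med <- ((dep[fv] + dep[tv]) / 2)^2
    efrom <- c(efrom, fv); eto <- c(eto, tv); ew <- c(ew, len / med)
  }
  g <- igraph::make_graph(rbind(efrom, eto), n = length(idx),
                          directed = FALSE)

  # snap seeds to nearest mask voxel
  seed_v <- vapply(seq_len(nrow(endpoint_seeds)), function(s) {
    p <- as.numeric(endpoint_seeds[s, c("x", "y", "z")])
    d2 <- (w[, 1] - p[1])^2 + (w[, 2] - p[2])^2 + (w[, 3] - p[3])^2
    j <- which.min(d2)
    if (sqrt(d2[j]) > max_seed_dist_mm)
      stop("labeling error: seed '", endpoint_seeds$branch[s],
           "' is more than ", max_seed_dist_mm, " mm from the mask",
           call. = FALSE)
    j
  }, integer(1))
  if (anyDuplicated(seed_v))
    stop("labeling error: endpoint seeds collapse onto the same voxel",
         call. = FALSE)

  get_path <- function(from, to) {
    # unreachable targets surface as an empty path (handled below), so
    # igraph's reachability warning is redundant
    p <- as.integer(suppressWarnings(
      igraph::shortest_paths(g, from = from, to = to, weights = ew,
                             output = "vpath"))$vpath[[1L]])
    if (length(p) == 0L)
      stop("topology error: mask is disconnected between endpoint seeds",
           call. = FALSE)
    p
  }

  labels <- as.character(endpoint_seeds$branch)
  if (length(seed_v) == 2L) {
    poly <- smooth_polyline(w[get_path(seed_v[1L], seed_v[2L]), ,
                              drop = FALSE], smooth_iter)
    br <- list(polyline_df(poly))
    names(br) <- labels[2L]
    tree <- list(branches = br, junction = NULL)
  } else if (length(seed_v) == 4L) {
    # cross junction: seeds are ordered (caval pair, pulmonary pair); the
    # junction is the closest-node pair between the caval path (seed 1 to
    # seed 2) and the pulmonary path (seed 3 to seed 4), which avoids the
    # root-side bias of a path-divergence junction
    pa <- get_path(seed_v[1L], seed_v[2L])
    pb <- get_path(seed_v[3L], seed_v[4L])
    wa <- w[pa, , drop = FALSE]
    wb <- w[pb, , drop = FALSE]
    d2 <- outer(rowSums(wa^2), rowSums(wb^2), `+`) - 2 * (wa %*% t(wb))
    hit <- arrayInd(which.min(d2), dim(d2))
    jv <- pa[hit[1L]]
    jw <- w[jv, ]
    branches <- lapply(seed_v, function(s)
      polyline_df(smooth_polyline(w[get_path(jv, s), , drop = FALSE],
                                  smooth_iter)))
    names(branches) <- labels
    tree <- list(branches = branches, junction = unname(jw))
  } else {
    # generic star: paths from the first seed, split at the last node
    # common to all of them
    paths <- lapply(seed_v[-1L], function(s) get_path(seed_v[1L], s))
    pref_len <- min(vapply(paths, length, 1L))
    common <- 1L
    for (k in seq_len(pref_len)) {
      nk <- vapply(paths, function(p) p[k], integer(1))
      if (all(nk == nk[1L])) common <- k else break
    }
    jv <- paths[[1L]][common]
    jw <- w[jv, ]
    branches <- list()
    rootseg <- rev(paths[[1L]][seq_len(common)])
    branches[[labels[1L]]] <- polyline_df(
      smooth_polyline(w[rootseg, , drop = FALSE], smooth_iter))
    for (t in seq_along(paths)) {
      seg <- paths[[t]][common:length(paths[[t]])]
      branches[[labels[t + 1L]]] <- polyline_df(
        smooth_polyline(w[seg, , drop = FALSE], smooth_iter))
    }
    tree <- list(branches = branches, junction = unname(jw))
  }
  class(tree) <- "centerline_tree"
  tree
}

# endpoint-preserving iterated moving-average smoothing of an n x 3 polyline
smooth_polyline <- function(p, iterations = 10L, window = 5L) {
  n <- nrow(p)
  if (n < 3L || iterations < 1L) return(p)
  half <- window %/% 2L
  for (it in seq_len(iterations)) {
    q <- p
    for (i in 2:(n - 1L)) {
      lo <- max(1L, i - half); hi <- min(n, i + half)
      q[i, ] <- colMeans(p[lo:hi, , drop = FALSE])
    }
    p <- q
  }
  p
}

polyline_df <- function(p) {
  seg <- sqrt(rowSums(diff(p)^2))
  # drop zero-length duplicates so arclength is strictly increasing
  keep <- c(TRUE, seg > 1e-9)
  p <- p[keep, , drop = FALSE]
  s <- c(0, cumsum(sqrt(rowSums(diff(p)^2))))
  data.frame(x = p[, 1], y = p[, 2], z = p[, 3], arclength = s)
}

#' Total arclength of a centerline branch (mm)
#' @param branch a branch data frame from [extract_centerline()].
#' @export
branch_length <- function(branch) max(branch$arclength)

# resample a branch polyline at fixed arclength steps (mm)
resample_polyline <- function(branch, step = 1) {
  s <- seq(0, max(branch$arclength), by = step)
  data.frame(
    x = stats::approx(branch$arclength, branch$x, s)$y,
    y = stats::approx(branch$arclength, branch$y, s)$y,
    z = stats::approx(branch$arclength, branch$z, s)$y,
    arclength = s)
}

#' @export
print.centerline_tree <- function(x, ...) {
  cat(sprintf("<centerline_tree> %d branch(es): %s\n", length(x$branches),
              paste(sprintf("%s (%.1f mm)", names(x$branches),
                            vapply(x$branches, branch_length, 1)),
                    collapse = ", ")))
  invisible(x)
}

#' Export a centerline tree as a polyline CSV
#' @param tree a [extract_centerline()] result.
#' @param path output CSV (columns x, y, z, arclength, branch).
#' @export
write_centerline_csv <- function(tree, path) {
  rows <- do.call(rbind, lapply(names(tree$branches), function(b) {
    df <- tree$branches[[b]]
    df$branch <- b
    df
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
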