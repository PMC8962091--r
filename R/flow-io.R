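#' Read a 4D flow velocity dataset
#'
#' Reads three per-component NIfTI volumes (phase as the 4th axis), an
#' optional magnitude volume, and a plain-text sidecar with the acquisition
#' metadata, and returns a validated [flow_field()].
#'
#' @param path either a directory containing `vx.nii.gz`, `vy.nii.gz`,
#'   `vz.nii.gz`, optionally `magnitude.nii.gz`, and `meta.txt`, or a
#'   character vector of the three component files (x, y, z order).
#' @param sidecar path to the sidecar file; defaults to `meta.txt` next to
#'   the first component file.
#' @return A [flow_field()] in m/s with the world transform populated.
#' @export
read_velocity_field <- function(path, sidecar = NULL) {
  if (length(path) == 1L && dir.exists(path)) {
    comp <- file.path(path, paste0("v", c("x", "y", "z"), ".nii.gz"))
    magf <- file.path(path, "magnitude.nii.gz")
    if (is.null(sidecar)) sidecar <- file.path(path, "meta.txt")
  } else {
    if (length(path) != 3L)
      stop("component file(s) not found: `path` must be a dataset ",
           "directory or the three component files", call. = FALSE)
    comp <- path
    magf <- file.path(dirname(path[1L]), "magnitude.nii.gz")
    if (is.null(sidecar)) sidecar <- file.path(dirname(path[1L]), "meta.txt")
  }
  missing <- comp[!file.exists(comp)]
  if (length(missing))
    stop("component file(s) not found: ", paste(missing, collapse = ", "),
         call. = FALSE)
  meta <- read_sidecar(sidecar)
  vols <- lapply(comp, function(f) {
    a <- as.array(RNifti::readNifti(f))
    if (length(dim(a)) == 3L) dim(a) <- c(dim(a), 1L)
    a
  })
  d1 <- dim(vols[[1L]])
  for (i in 2:3)
    if (!identical(dim(vols[[i]]), d1))
      stop(sprintf("component %d spatial/phase shape mismatch: %s vs %s", i,
                   paste(dim(vols[[i]]), collapse = "x"),
                   paste(d1, collapse = "x")), call. = FALSE)
  if (d1[4L] != meta$n_phases)
    stop("phase axis length disagrees with sidecar n_phases", call. = FALSE)
  values <- array(0, c(d1, 3L))
  for (i in 1:3) values[, , , , i] <- vols[[i]]
  magnitude <- if (file.exists(magf)) {
    a <- as.array(RNifti::readNifti(magf))
    if (length(dim(a)) == 3L) dim(a) <- c(dim(a), 1L)
    a
  }
  flow_field(values, meta, magnitude = magnitude)
}

#' Write a 4D flow velocity dataset
#'
#' Writes one 4D NIfTI file per velocity component (float32, phase as 4th
#' axis), the magnitude volume when present, and a plain-text sidecar
#' (`meta.txt`) carrying VENC, RR interval, phase count and the world
#' transform. The write/read round trip is lossless within float32
#' quantization.
#'
#' @param field a [flow_field()].
#' @param path output directory, created if absent.
#' @return Invisibly, the paths written.
#' @export
write_velocity_field <- function(field, path) {
  stopifnot(inherits(field, "flow_field"))
  if (!dir.exists(path) &&
      !dir.create(path, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", path, call. = FALSE)
  meta <- field$meta
  comp <- file.path(path, paste0("v", c("x", "y", "z"), ".nii.gz"))
  for (i in 1:3) {
    a <- field$values[, , , , i, drop = TRUE]
    if (length(dim(a)) == 3L) dim(a) <- c(dim(a), 1L)
    img <- RNifti::asNifti(a)
    RNifti::pixdim(img) <- meta$spacing
    RNifti::writeNifti(img, comp[i], datatype = "float")
  }
  written <- comp
  if (!is.null(field$magnitude)) {
    magf <- file.path(path, "magnitude.nii.gz")
    img <- RNifti::asNifti(field$magnitude)
    RNifti::pixdim(img) <- meta$spacing
    RNifti::writeNifti(img, magf, datatype = "float")
    written <- c(written, magf)
  }
  sidecar <- file.path(path, "meta.txt")
  write_sidecar(meta, sidecar)
  invisible(c(written, sidecar))
}

write_sidecar <- function(meta, path) {
  num <- function(x) paste(format(x, digits = 17, scientific = FALSE,
                                  trim = TRUE), collapse = " ")
  lines <- c(
    paste0("venc_cm_s: ", num(meta$venc_cm_s)),
    paste0("rr_ms: ", num(meta$rr_ms)),
    paste0("n_phases: ", meta$n_phases),
    paste0("spacing_mm: ", num(meta$spacing)),
    paste0("origin_mm: ", num(meta$origin)),
    paste0("orientation: ", num(as.vector(t(meta$orientation))))
  )
  writeLines(lines, path)
  invisible(path)
}

read_sidecar <- function(path) {
  if (!file.exists(path))
    stop("sidecar not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  kv <- strsplit(lines[nzchar(lines)], ":", fixed = TRUE)
  keys <- vapply(kv, function(x) trimws(x[1L]), "")
  vals <- lapply(kv, function(x)
    as.numeric(strsplit(trimws(paste(x[-1L], collapse = ":")), "\\s+")[[1L]]))
  names(vals) <- keys
  if (is.null(vals$venc_cm_s) || !is.finite(vals$venc_cm_s))
    stop("sidecar is missing VENC (venc_cm_s)", call. = FALSE)
  if (is.null(vals$n_phases))
    stop("sidecar is missing n_phases", call. = FALSE)
  acquisition_meta(
    spacing = if (is.null(vals$spacing_mm)) c(1, 1, 1) else vals$spacing_mm,
    n_phases = vals$n_phases,
    venc_cm_s = vals$venc_cm_s,
    rr_ms = if (is.null(vals$rr_ms)) 1000 else vals$rr_ms,
    origin = if (is.null(vals$origin_mm)) c(0, 0, 0) else vals$origin_mm,
    orientation = if (is.null(vals$orientation)) diag(3) else
      matrix(vals$orientation, 3L, 3L, byrow = TRUE)
  )
}

#' Write a vessel mask as NIfTI uint8
#' @param mask a [vessel_mask()].
#' @param path output file (`.nii` or `.nii.gz`).
#' @export
write_vessel_mask <- function(mask, path) {
  stopifnot(inherits(mask, "vessel_mask"))
  img <- RNifti::asNifti(array(as.integer(mask$values), dim(mask$values)))
  RNifti::pixdim(img) <- mask$meta$spacing
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Read a vessel mask written by [write_vessel_mask()]
#' @param path NIfTI file; nonzero voxels become foreground.
#' @param meta the [acquisition_meta()] of the grid the mask lives on.
#' @export
read_vessel_mask <- function(path, meta) {
  a <- as.array(RNifti::readNifti(path))
  vessel_mask(a != 0, meta)
}
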