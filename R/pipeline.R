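#' Run the TCPC energetics pipeline end to end
#'
#' Orchestrates: anti-aliasing, time-averaged speed image, lumen
#' segmentation (or a supplied mask), centerline extraction and five-segment
#' labeling, through-plane flows, total and per-segment energetics with
#' flow (and length) normalization, and CSA profiles. Inputs come either
#' from a phantom spec (synthetic run) or from files on disk; with a fixed
#' seed two runs produce byte-identical CSV outputs.
#'
#' Config fields (a plain list, YAML-compatible; see
#' [read_pipeline_config()]):
#' \describe{
#'   \item{phantom}{list of [phantom_spec()] arguments (synthetic runs).}
#'   \item{input}{alternatively `field_dir` (from
#'     [write_velocity_field()]), optional `mask_file`, and
#'     `endpoint_seeds` (data frame or list: `branch`, `x`, `y`, `z`, world
#'     mm).}
#'   \item{seed}{integer; overrides the phantom seed.}
#'   \item{segmentation}{`threshold`, `threshold_frac`, `seeds` (n x 3
#'     voxel indices; phantom runs derive them from the ground truth).}
#'   \item{energetics}{arguments for [energetics_config()].}
#'   \item{segmental}{logical: run the five-segment analysis (default TRUE
#'     when 4 endpoint seeds are available).}
#'   \item{inflow_branches}{branch labels flowing toward the confluence
#'     (default `c("tunnel", "svc")`).}
#'   \item{bsa}{body surface area, m^2, for CSA normalization (default
#'     1.6).}
#'   \item{confluence_margin}{mm; `NULL` for the radius-adaptive default.}
#'   \item{flow_plane_offset_mm}{flow-plane distance beyond the confluence
#'     boundary (default 5).}
#' }
#'
#' @param config configuration list or path to a YAML file.
#' @param out_dir directory for the report bundle (config echo, log, CSVs,
#'   NIfTI maps); `NULL` computes without writing.
#' @return Invisibly, a list with all stage products: `field`, `mask`,
#'   `speed`, `centerline`, `segments`, `flows`, `total` (energetics +
#'   normalization), `per_segment` (data frame), `csa` (list), `config`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(is.list(config))
  log_lines <- character(0)
  note <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  if (is.null(config$phantom) && is.null(config$input))
    stop("validation error: config needs either 'phantom' or 'input'",
         call. = FALSE)
  if (!is.null(config$input) && is.null(config$input$mask_file) &&
      is.null(config$input$endpoint_seeds) &&
      is.null(config$segmentation$seeds))
    stop("validation error: file input needs a mask or segmentation seeds",
         call. = FALSE)

  truth <- NULL
  if (!is.null(config$phantom)) {
    args <- config$phantom
    if (!is.null(config$seed)) args$seed <- config$seed
    ph <- stage("phantom", generate_phantom(do.call(phantom_spec, args)))
    field <- ph$field
    truth <- ph$truth
    endpoint_seeds <- truth$endpoints
    note("phantom '%s' generated (%s voxels in truth mask)",
         truth$spec$geometry, sum(truth$mask$values))
  } else {
    field <- stage("read", read_velocity_field(config$input$field_dir))
    endpoint_seeds <- config$input$endpoint_seeds
    if (!is.null(endpoint_seeds))
      endpoint_seeds <- as.data.frame(endpoint_seeds)
  }

  aa <- stage("antialias", antialias_correct(field))
  field <- aa$field
  note("anti-aliasing: %d voxel values corrected", aa$n_corrected)

  speed <- stage("speed_image", magnitude_weighted_speed(field))

  if (!is.null(config$input$mask_file)) {
    mask <- stage("mask", read_vessel_mask(config$input$mask_file,
                                           field$meta))
  } else {
    seeds <- config$segmentation$seeds
    if (is.null(seeds)) {
      if (is.null(truth))
        stop("validation error: segmentation seeds required", call. = FALSE)
      # phantom run: seed voxels at the centerline branch midpoints
      seeds <- do.call(rbind, lapply(truth$centerline, function(br) {
        mid <- br[ceiling(nrow(br) / 2), c("x", "y", "z")]
        round(world_to_voxel(field$meta, as.numeric(mid))) + 1L
      }))
    }
    mask <- stage("segmentation", threshold_region_grow(
      speed, seeds, field$meta, threshold = config$segmentation$threshold,
      threshold_frac = config$segmentation$threshold_frac %||% 0.10))
  }
  note("mask: %d voxels", sum(mask$values))

  ecfg <- do.call(energetics_config, config$energetics %||% list())
  total_series <- stage("energetics", energetics_series(field, mask, ecfg))

  segmental <- config$segmental %||%
    (!is.null(endpoint_seeds) && nrow(endpoint_seeds) == 4L)
  centerline <- segments <- flows <- csa <- per_segment <- NULL
  total_norm <- NULL

  if (segmental) {
    centerline <- stage("centerline",
                        extract_centerline(mask, endpoint_seeds))
    segments <- stage("segments", label_segments(
      mask, centerline, confluence_margin = config$confluence_margin))
    margin <- segments$confluence_margin_mm
    offset <- config$flow_plane_offset_mm %||% 5
    inflow_branches <- config$inflow_branches %||% c("tunnel", "svc")
    flows <- stage("flows", lapply(names(centerline$branches), function(b) {
      br <- centerline$branches[[b]]
      s0 <- min(margin + offset, branch_length(br) * 0.9)
      poly <- resample_polyline(br, 1)
      i <- which.min(abs(poly$arclength - s0))
      tang <- tangent_at(poly, i)
      if (b %in% inflow_branches) tang <- -tang  # positive toward confluence
      pf <- plane_flow(field, mask, as.numeric(poly[i, c("x", "y", "z")]),
                       tang)
      pf$branch <- b
      pf
    }))
    names(flows) <- names(centerline$branches)
    inflow <- sum(vapply(flows[intersect(inflow_branches, names(flows))],
                         function(f) f$cycle_mean, 1))
    note("inflow (%s): %.2f L/min",
         paste(inflow_branches, collapse = " + "), inflow)
    total_norm <- normalize_energetics(total_series$ke_cycle_avg,
                                       total_series$el_cycle_avg, inflow)

    bsa <- config$bsa %||% 1.6
    csa <- list()
    rows <- list()
    for (i in seq_along(segments$segments)) {
      segname <- segments$segments[i]
      smask <- segment_mask(segments, i)
      if (!any(smask$values)) next
      is_conf <- segname == "confluence"
      if (!segments$included[i]) {
        rows[[segname]] <- data.frame(
          segment = segname, included = FALSE,
          length_cm = segments$lengths_cm[i], flow_l_min = NA,
          mean_csa_cm2 = NA, mean_csa_bsa = NA, ke_mj = NA, el_mw = NA,
          ke_norm = NA, el_norm = NA)
        next
      }
      es <- energetics_series(field, smask, ecfg)
      segflow <- if (is_conf) inflow else flows[[segname]]$cycle_mean
      nrm <- if (is_conf)
        normalize_energetics(es$ke_cycle_avg, es$el_cycle_avg, segflow)
      else
        normalize_energetics(es$ke_cycle_avg, es$el_cycle_avg, segflow,
                             length = segments$lengths_cm[i])
      mean_csa <- mean_csa_bsa <- NA_real_
      if (!is_conf) {
        br <- centerline$branches[[segname]]
        outer_part <- br[br$arclength >= margin, , drop = FALSE]
        if (nrow(outer_part) >= 2L &&
            max(outer_part$arclength) - min(outer_part$arclength) >= 2) {
          outer_part$arclength <- outer_part$arclength -
            min(outer_part$arclength)
          cp <- stage(paste0("csa_", segname),
                      csa_profile(smask, outer_part, bsa = bsa))
          csa[[segname]] <- cp
          mean_csa <- cp$mean_csa_cm2
          mean_csa_bsa <- cp$mean_csa_bsa
        }
      }
      rows[[segname]] <- data.frame(
        segment = segname, included = TRUE,
        length_cm = segments$lengths_cm[i], flow_l_min = segflow,
        mean_csa_cm2 = mean_csa, mean_csa_bsa = mean_csa_bsa,
        ke_mj = es$ke_cycle_avg, el_mw = es$el_cycle_avg,
        ke_norm = if (is_conf) nrm$ke_norm_flow else nrm$ke_norm_flow_length,
        el_norm = if (is_conf) nrm$el_norm_flow else nrm$el_norm_flow_length)
    }
    per_segment <- do.call(rbind, rows)
    rownames(per_segment) <- NULL
  }

  result <- list(field = field, mask = mask, speed = speed,
                 centerline = centerline, segments = segments,
                 flows = flows, total = list(series = total_series,
                                             normalized = total_norm),
                 per_segment = per_segment, csa = csa, config = config,
                 truth = truth, log = log_lines)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    writeLines(yaml::as.yaml(config), file.path(out_dir, "config.yaml"))
    per_phase <- data.frame(phase = seq_along(total_series$ke_per_phase),
                            ke_mj = total_series$ke_per_phase,
                            el_mw = total_series$el_per_phase)
    utils::write.csv(per_phase, file.path(out_dir, "per_phase.csv"),
                     row.names = FALSE)
    summary_df <- data.frame(
      ke_cycle_avg_mj = total_series$ke_cycle_avg,
      el_cycle_avg_mw = total_series$el_cycle_avg,
      ke_norm_flow_mj_per_l_min = total_norm$ke_norm_flow %||% NA,
      el_norm_flow_mw_per_l_min = total_norm$el_norm_flow %||% NA,
      inflow_l_min = total_norm$inflow_l_min %||% NA)
    utils::write.csv(summary_df, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
    if (!is.null(per_segment))
      utils::write.csv(per_segment, file.path(out_dir, "segments.csv"),
                       row.names = FALSE)
    if (!is.null(centerline))
      write_centerline_csv(centerline, file.path(out_dir, "centerline.csv"))
    if (!is.null(segments)) {
      img <- RNifti::asNifti(segments$labels)
      RNifti::pixdim(img) <- field$meta$spacing
      RNifti::writeNifti(img, file.path(out_dir, "segment_labels.nii.gz"),
                         datatype = "uint8")
    }
    write_vessel_mask(mask, file.path(out_dir, "mask.nii.gz"))
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }
  invisible(result)
}

tangent_at <- function(poly, i) {
  n <- nrow(poly)
  lo <- max(1L, i - 1L); hi <- min(n, i + 1L)
  t <- as.numeric(poly[hi, c("x", "y", "z")]) -
    as.numeric(poly[lo, c("x", "y", "z")])
  t / sqrt(sum(t^2))
}

#' Read a pipeline configuration from YAML
#' @param path YAML file.
#' @return The configuration list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$input$endpoint_seeds))
    cfg$input$endpoint_seeds <- as.data.frame(
      do.call(rbind, lapply(cfg$input$endpoint_seeds, as.data.frame)))
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a
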