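#' Default synthetic-cohort parameterization
#'
#' Means, SDs and pairwise correlations for the default synthetic Fontan
#' cohort: total-TCPC flow-normalized kinetic energy and viscous energy
#' loss rate (mJ and mW per L/min), liver cT1 (ms), peak VO2 (ml/kg/min),
#' percent-predicted peak VO2 (%), cardiac index (L/min/m^2) and ejection
#' fraction (%). Energetics-outcome correlations carry the published
#' effect pattern (energetics positively related to cT1, negatively to
#' exercise capacity, essentially unrelated to resting cardiac index and
#' EF); the few pairs without a published value (KE-EL, VO2-%VO2,
#' cT1-exercise, CI-EF) are fixed plausibility choices that keep the
#' matrix positive semi-definite.
#'
#' @return A list with `means`, `sds` (named vectors) and `correlation`
#'   (7 x 7 matrix).
#' @export
default_cohort_parameters <- function() {
  vars <- c("ke_norm_flow", "el_norm_flow", "ct1", "peak_vo2",
            "pct_pred_vo2", "cardiac_index", "ef")
  means <- c(0.260, 0.075, 964, 27.1, 57, 3.4, 48)
  sds <- c(0.068, 0.022, 63, 6.2, 12, 0.1, 7)
  names(means) <- names(sds) <- vars
  R <- diag(7)
  dimnames(R) <- list(vars, vars)
  set <- function(a, b, r) {
    R[a, b] <<- r
    R[b, a] <<- r
  }
  set("ke_norm_flow", "el_norm_flow", 0.85)
  set("ke_norm_flow", "ct1", 0.50)
  set("el_norm_flow", "ct1", 0.39)
  set("ke_norm_flow", "peak_vo2", -0.61)
  set("el_norm_flow", "peak_vo2", -0.54)
  set("ke_norm_flow", "pct_pred_vo2", -0.44)
  set("el_norm_flow", "pct_pred_vo2", -0.46)
  set("ke_norm_flow", "cardiac_index", -0.189)
  set("el_norm_flow", "cardiac_index", -0.147)
  set("ke_norm_flow", "ef", -0.030)
  set("el_norm_flow", "ef", 0.048)
  set("ct1", "peak_vo2", -0.35)
  set("ct1", "pct_pred_vo2", -0.30)
  set("peak_vo2", "pct_pred_vo2", 0.80)
  set("cardiac_index", "ef", 0.20)
  list(means = means, sds = sds, correlation = R)
}

#' Specification of a synthetic patient cohort
#'
#' @param n number of patients (default 62, the study cohort size).
#' @param means,sds named numeric vectors (same names, SDs >= 0); defaults
#'   from [default_cohort_parameters()].
#' @param correlation correlation matrix (symmetric, unit diagonal,
#'   positive semi-definite) matching the variables.
#' @param seed integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 62L, means = NULL, sds = NULL,
                        correlation = NULL, seed = 1L) {
  def <- default_cohort_parameters()
  if (is.null(means)) means <- def$means
  if (is.null(sds)) sds <- def$sds
  if (is.null(correlation)) correlation <- def$correlation
  n <- as.integer(n)
  stopifnot(n >= 1L, length(means) == length(sds),
            identical(names(means), names(sds)), all(sds >= 0))
  p <- length(means)
  correlation <- as.matrix(correlation)
  stopifnot(nrow(correlation) == p, ncol(correlation) == p)
  if (max(abs(correlation - t(correlation))) > 1e-10 ||
      max(abs(diag(correlation) - 1)) > 1e-10)
    stop("correlation matrix must be symmetric with unit diagonal",
         call. = FALSE)
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    near <- nearest_psd(correlation)
    stop("correlation matrix is not positive semi-definite (min eigenvalue ",
         format(min(ev), digits = 3), "); nearest PSD correction would ",
         "change entries by up to ",
         format(max(abs(near - correlation)), digits = 3), call. = FALSE)
  }
  structure(list(n = n, means = means, sds = sds, correlation = correlation,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# eigenvalue-clipped nearest PSD correlation (suggestion only)
nearest_psd <- function(R) {
  e <- eigen(R, symmetric = TRUE)
  lam <- pmax(e$values, 1e-8)
  S <- e$vectors %*% diag(lam) %*% t(e$vectors)
  d <- 1 / sqrt(diag(S))
  S * (d %o% d)
}

#' Draw a synthetic patient cohort
#'
#' `n` seeded draws from the multivariate normal with the spec's moments.
#' Gaussianity is an idealization: real cohort variables are positive and
#' bounded, and values are deliberately not truncated.
#'
#' @param spec a [cohort_spec()].
#' @return A data frame (one row per patient, `patient_id` first, columns
#'   in spec order) with the spec attached as attribute `"spec"`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  Sigma <- spec$correlation * (spec$sds %o% spec$sds)
  x <- MASS::mvrnorm(spec$n, mu = spec$means, Sigma = Sigma)
  if (spec$n == 1L) x <- matrix(x, nrow = 1L,
                                dimnames = list(NULL, names(spec$means)))
  out <- data.frame(patient_id = seq_len(spec$n), x, check.names = FALSE)
  attr(out, "spec") <- spec
  out
}

#' Write a cohort table as CSV with a YAML provenance header
#'
#' The header (comment lines starting `#`) records the generating spec and
#' seed so a cohort file is self-describing.
#'
#' @param cohort a [generate_cohort()] data frame.
#' @param path output CSV path.
#' @export
write_cohort_csv <- function(cohort, path) {
  spec <- attr(cohort, "spec")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(spec)) {
    prov <- list(n = spec$n, seed = spec$seed,
                 means = as.list(spec$means), sds = as.list(spec$sds),
                 correlation = apply(spec$correlation, 1L, as.list,
                                     simplify = FALSE))
    hdr <- strsplit(yaml::as.yaml(prov), "\n")[[1L]]
    writeLines(paste("#", hdr), con)
  }
  utils::write.csv(cohort, con, row.names = FALSE)
  invisible(path)
}

#' Read a cohort CSV written by [write_cohort_csv()]
#' @param path CSV path; `#` header lines are skipped.
#' @export
read_cohort_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", check.names = FALSE)
}
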