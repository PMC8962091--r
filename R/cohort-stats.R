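# Cohort statistics layer: normality-driven descriptives, correlation
# analysis with strength labels, segment comparisons and two-group tests.

# Shapiro-Wilk p, NA when inapplicable (n < 3, constant, or after
# subsampling cap); shapiro.test accepts at most 5000 values, so larger
# samples are tested on their first 5000 (deterministic)
shapiro_p <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 3L || stats::sd(x) == 0) return(NA_real_)
  if (length(x) > 5000L) x <- x[1:5000]
  stats::shapiro.test(x)$p.value
}

#' Per-variable descriptives with normality-driven presentation
#'
#' Mean (SD) when the Shapiro-Wilk test does not reject normality at alpha
#' = 0.05, median (IQR) otherwise; constant or too-short variables are
#' flagged. Missing values are excluded per variable and `n` is always
#' reported.
#'
#' @param table a data frame (e.g. from [generate_cohort()]).
#' @param variables variables to summarize (default: all numeric columns
#'   except `patient_id`).
#' @param alpha normality test level (default 0.05).
#' @return A data frame: `variable`, `n`, `mean`, `sd`, `median`, `iqr`,
#'   `shapiro_p`, `normal`, `presentation`.
#' @export
describe_cohort <- function(table, variables = NULL, alpha = 0.05) {
  if (is.null(variables))
    variables <- setdiff(names(table)[vapply(table, is.numeric, TRUE)],
                         "patient_id")
  rows <- lapply(variables, function(v) {
    x <- table[[v]]
    x <- x[is.finite(x)]
    n <- length(x)
    if (n == 0L)
      return(data.frame(variable = v, n = 0L, mean = NA, sd = NA,
                        median = NA, iqr = NA, shapiro_p = NA, normal = NA,
                        presentation = "flagged"))
    sw <- shapiro_p(x)
    normal <- if (is.na(sw)) NA else sw >= alpha
    pres <- if (is.na(normal)) "flagged" else
      if (normal) "mean_sd" else "median_iqr"
    data.frame(variable = v, n = n, mean = mean(x), sd = stats::sd(x),
               median = stats::median(x), iqr = stats::IQR(x),
               shapiro_p = sw, normal = normal, presentation = pres)
  })
  do.call(rbind, rows)
}

# strength labels for |r|: weak 0.3-0.5, moderate 0.5-0.7, strong 0.7-0.9,
# excellent > 0.9 (boundary 0.5 resolves to moderate, 0.7 to strong, 0.9
# stays strong)
correlation_strength <- function(r) {
  a <- round(abs(r), 9)  # keep band boundaries stable under float noise
  if (a > 0.9) "excellent"
  else if (a >= 0.7) "strong"
  else if (a >= 0.5) "moderate"
  else if (a >= 0.3) "weak"
  else "negligible"
}

#' Correlation analysis with strength label
#'
#' Pearson or Spearman correlation on complete pairs, with a two-sided p
#' and the field's strength label. `method = "auto"` picks Pearson when
#' both variables pass Shapiro-Wilk at alpha = 0.05 and Spearman
#' otherwise. Spearman p-values are exact for n <= 9 without ties,
#' asymptotic (t approximation) otherwise.
#'
#' @param x,y numeric vectors.
#' @param method `"auto"`, `"pearson"` or `"spearman"`.
#' @param alpha normality level driving the auto choice.
#' @return A list: `method`, `estimate`, `p`, `n`, `label`.
#' @export
correlate <- function(x, y, method = c("auto", "pearson", "spearman"),
                      alpha = 0.05) {
  method <- match.arg(method)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance", call. = FALSE)
  if (method == "auto") {
    px <- shapiro_p(x); py <- shapiro_p(y)
    method <- if (!is.na(px) && !is.na(py) && px >= alpha && py >= alpha)
      "pearson" else "spearman"
  }
  ct <- if (method == "spearman") {
    ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
    suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                     exact = n <= 9L && !ties))
  } else {
    stats::cor.test(x, y, method = "pearson")
  }
  r <- unname(ct$estimate)
  list(method = method, estimate = r, p = ct$p.value, n = n,
       label = correlation_strength(r))
}

#' Run a set of labeled correlations on a cohort table
#'
#' @param table data frame.
#' @param pairs 2-column character matrix (or data frame) of variable
#'   pairs.
#' @param method passed to [correlate()].
#' @return Long-format data frame: `var_x`, `var_y`, `method`, `n`,
#'   `estimate`, `p`, `label`.
#' @export
correlate_pairs <- function(table, pairs, method = "auto") {
  pairs <- as.matrix(pairs)
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    r <- correlate(table[[pairs[i, 1]]], table[[pairs[i, 2]]],
                   method = method)
    data.frame(var_x = pairs[i, 1], var_y = pairs[i, 2], method = r$method,
               n = r$n, estimate = r$estimate, p = r$p, label = r$label)
  })
  do.call(rbind, rows)
}

#' Compare segment-specific energetics across groups
#'
#' Omnibus Kruskal-Wallis test (H with tie correction) across segment
#' groups, followed by pairwise Mann-Whitney U tests with Bonferroni
#' adjustment (raw p multiplied by the number of pairs, capped at 1).
#' Groups with fewer than 2 observations are excluded with a warning.
#'
#' For small samples the chi-square reference distribution of H is a poor
#' approximation, so `p_method = "auto"` (the default) computes the
#' omnibus p by exhaustive enumeration of the permutation distribution of
#' H whenever the number of distinct group assignments is at most
#' `exact_limit`, and falls back to the chi-square approximation
#' otherwise.
#'
#' @param values numeric vector.
#' @param groups factor (or coercible) of the same length.
#' @param alpha significance level for the adjusted flags (default 0.05).
#' @param p_method `"auto"`, `"exact"` (exhaustive permutation) or
#'   `"asymptotic"` (chi-square).
#' @param exact_limit assignment-count cap for the automatic exact path.
#' @return A list: `h_statistic`, `omnibus_p`, `omnibus_method`, `groups`,
#'   `pairwise_raw` and `pairwise_adjusted` (matrices), `significant`
#'   (logical matrix at adjusted p < alpha), `n_pairs`.
#' @export
compare_segments <- function(values, groups, alpha = 0.05,
                             p_method = c("auto", "exact", "asymptotic"),
                             exact_limit = 5e5) {
  p_method <- match.arg(p_method)
  groups <- factor(groups)
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]; groups <- droplevels(groups[ok])
  sizes <- table(groups)
  if (any(sizes < 2L)) {
    warning("excluding group(s) with n < 2: ",
            paste(names(sizes)[sizes < 2L], collapse = ", "))
    keep <- groups %in% names(sizes)[sizes >= 2L]
    values <- values[keep]; groups <- droplevels(groups[keep])
  }
  lev <- levels(groups)
  if (length(lev) < 2L) stop("need at least 2 groups with n >= 2",
                             call. = FALSE)
  if (stats::sd(values) == 0) {
    h <- 0; omnibus_p <- 1; omnibus_method <- "degenerate"
  } else {
    kw <- stats::kruskal.test(values, groups)
    h <- unname(kw$statistic); omnibus_p <- kw$p.value
    omnibus_method <- "asymptotic"
    n_assign <- kw_assignment_count(table(groups))
    if (p_method == "exact" ||
        (p_method == "auto" && n_assign <= exact_limit)) {
      omnibus_p <- kw_exact_p(values, groups)
      omnibus_method <- "exact"
    }
  }
  k <- length(lev)
  n_pairs <- k * (k - 1L) / 2L
  raw <- matrix(NA_real_, k, k, dimnames = list(lev, lev))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    a <- values[groups == lev[i]]; b <- values[groups == lev[j]]
    p <- if (stats::sd(c(a, b)) == 0) 1 else
      suppressWarnings(stats::wilcox.test(a, b)$p.value)
    raw[i, j] <- raw[j, i] <- p
  }
  adj <- pmin(raw * n_pairs, 1)
  list(h_statistic = h, omnibus_p = omnibus_p,
       omnibus_method = omnibus_method, groups = lev,
       pairwise_raw = raw, pairwise_adjusted = adj,
       significant = adj < alpha, n_pairs = n_pairs)
}

# number of distinct assignments of ranks to groups (multinomial count)
kw_assignment_count <- function(sizes) {
  sizes <- as.integer(sizes)
  n <- sum(sizes)
  out <- 1
  for (s in sizes) {
    out <- out * choose(n, s)
    n <- n - s
  }
  out
}

# exhaustive permutation p of the Kruskal-Wallis H (tie-corrected): all
# assignments of the observed ranks to the group sizes are enumerated; the
# last two groups are vectorized, outer groups are plain loops
kw_exact_p <- function(values, groups) {
  groups <- factor(groups)
  sizes <- as.integer(table(groups))
  k <- length(sizes)
  r <- rank(values)
  n <- length(r)
  tie_tab <- table(r)
  tie_corr <- 1 - sum(tie_tab^3 - tie_tab) / (n^3 - n)
  h_from_sums <- function(S) {  # S: matrix k x m of per-group rank sums
    h <- 12 / (n * (n + 1)) * colSums(S^2 / sizes) - 3 * (n + 1)
    h / tie_corr
  }
  S_obs <- vapply(levels(groups), function(g) sum(r[groups == g]), 1)
  h_obs <- h_from_sums(matrix(S_obs, ncol = 1))

  count <- 0
  total <- 0
  # recursive enumeration; the final two groups are closed in one step
  recurse <- function(avail, S_head) {
    if (length(S_head) == k - 2L) {
      ra <- r[avail]
      cmb <- utils::combn(length(avail), sizes[k - 1L])
      S_k1 <- colSums(matrix(ra[cmb], nrow = sizes[k - 1L]))
      S_k <- sum(ra) - S_k1
      S <- rbind(matrix(S_head, nrow = k - 2L, ncol = length(S_k1)),
                 S_k1, S_k)
      h <- h_from_sums(S)
      count <<- count + sum(h >= h_obs - 1e-12)
      total <<- total + length(h)
    } else {
      j <- length(S_head) + 1L
      cmb <- utils::combn(length(avail), sizes[j])
      for (ci in seq_len(ncol(cmb))) {
        pick <- cmb[, ci]
        recurse(avail[-pick], c(S_head, sum(r[avail[pick]])))
      }
    }
  }
  recurse(seq_len(n), numeric(0))
  count / total
}

#' Two-group difference with normality-driven test choice
#'
#' Welch t-test when both groups pass Shapiro-Wilk at alpha = 0.05,
#' Mann-Whitney U otherwise (always two-sided).
#'
#' @param values numeric vector.
#' @param group binary grouping vector.
#' @param alpha normality level for the test choice.
#' @return A list: `test` (`"t"` or `"mann_whitney"`), `statistic`, `p`,
#'   `n` (per-group counts).
#' @export
group_difference <- function(values, group, alpha = 0.05) {
  group <- factor(group)
  ok <- is.finite(values) & !is.na(group)
  values <- values[ok]; group <- droplevels(group[ok])
  if (nlevels(group) != 2L)
    stop("group must have exactly 2 levels", call. = FALSE)
  a <- values[group == levels(group)[1L]]
  b <- values[group == levels(group)[2L]]
  if (length(a) < 2L || length(b) < 2L)
    stop("both groups need n >= 2", call. = FALSE)
  pa <- shapiro_p(a); pb <- shapiro_p(b)
  normal <- !is.na(pa) && !is.na(pb) && pa >= alpha && pb >= alpha
  if (normal) {
    tt <- stats::t.test(a, b)
    list(test = "t", statistic = unname(tt$statistic), p = tt$p.value,
         n = c(length(a), length(b)))
  } else {
    p <- if (stats::sd(values) == 0) 1 else
      suppressWarnings(stats::wilcox.test(a, b)$p.value)
    w <- if (stats::sd(values) == 0) length(a) * length(b) / 2 else
      unname(suppressWarnings(stats::wilcox.test(a, b)$statistic))
    list(test = "mann_whitney", statistic = w, p = p,
         n = c(length(a), length(b)))
  }
}
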