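#!/usr/bin/env Rscript
# Runs the full pipeline on TCPC junction phantoms: segmentation on the
# speed image, centerline + five-segment labeling, through-plane flows,
# total and per-segment normalized energetics, CSA profiles. Then sweeps
# the Fontan-tunnel radius at fixed flow to show the geometry-energetics
# relationship that motivates conduit sizing concerns.
# Writes results/02_segments.csv and results/02_tunnel_sweep.csv.

suppressPackageStartupMessages(library(tcpcflow))
dir.create("results", showWarnings = FALSE)
seed <- 5L

cfg <- list(phantom = list(geometry = "tcpc_junction", spacing_mm = 1.5,
                           n_phases = 24L, noise_sd = 0.01, seed = seed))
res <- run_pipeline(cfg, out_dir = "results/02_pipeline")
message("total TCPC: KE ", signif(res$total$series$ke_cycle_avg, 4),
        " mJ, EL ", signif(res$total$series$el_cycle_avg, 4), " mW; ",
        "KE_norm_flow ", signif(res$total$normalized$ke_norm_flow, 4),
        " mJ per L/min, EL_norm_flow ",
        signif(res$total$normalized$el_norm_flow, 4), " mW per L/min")
write.csv(res$per_segment, "results/02_segments.csv", row.names = FALSE)
print(res$per_segment, row.names = FALSE, digits = 3)

# label agreement against the generator's ground truth
both <- res$segments$labels > 0L & res$truth$labels > 0L
message(sprintf("segment label agreement vs ground truth: %.1f%%",
                100 * mean(res$segments$labels[both] ==
                             res$truth$labels[both])))

# tunnel radius sweep at fixed total flow: EL_norm_flow+length ~ 1/R^4
sweep <- do.call(rbind, lapply(c(9, 8, 7, 6), function(rt) {
  r <- run_pipeline(list(phantom = list(
    geometry = "tcpc_junction", radius_mm = c(tunnel = rt),
    waveform = "steady", n_phases = 1L, spacing_mm = 1.5, seed = seed)))
  ps <- r$per_segment[r$per_segment$segment == "tunnel", ]
  data.frame(tunnel_radius_mm = rt, conduit_diameter_mm = 2 * rt,
             mean_csa_cm2 = ps$mean_csa_cm2,
             el_norm_flow_length = ps$el_norm,
             ke_norm_flow_length = ps$ke_norm)
}))
write.csv(sweep, "results/02_tunnel_sweep.csv", row.names = FALSE)
message("tunnel radius sweep (fixed Q):")
print(sweep, row.names = FALSE, digits = 3)
message("normalized dissipation rises steeply as the conduit narrows, ",
        "mirroring the inverse CSA-energetics association seen in vivo.")
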