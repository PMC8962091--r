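# shared phantoms for the geometry tests (built once per file)
tube_ph <- steady_tube(radius = 8, length = 60, q = 2, spacing = 1)
tcpc_ph <- generate_phantom(phantom_spec("tcpc_junction",
                                         waveform = "steady",
                                         n_phases = 1L, spacing_mm = 1.5,
                                         seed = 5))

test_that("tube centerline recovers the analytic axis and length", {
  tr <- extract_centerline(tube_ph$truth$mask, tube_ph$truth$endpoints)
  expect_length(tr$branches, 1L)
  br <- tr$branches[[1]]
  truth_len <- max(tube_ph$truth$centerline$tube$arclength)
  expect_lt(abs(branch_length(br) - truth_len), 2)  # 2 voxels at 1 mm
  ax <- tube_ph$truth$centerline$tube[1, c("x", "y")]
  expect_lt(max(abs(br$x - ax$x)), 1)
  expect_lt(max(abs(br$y - ax$y)), 1)
  expect_true(all(diff(br$arclength) > 0))
})

test_that("degenerate and disconnected masks raise topology errors", {
  m <- array(FALSE, c(6, 6, 6))
  m[3, 3, 3] <- m[3, 3, 4] <- TRUE
  seeds <- data.frame(branch = c("a", "b"), x = c(2, 2), y = c(2, 2),
                      z = c(2, 3))
  expect_error(extract_centerline(vessel_mask(m, meta_iso()), seeds),
               "topology error")

  ph2 <- generate_phantom(phantom_spec("two_tube_disjoint", radius_mm = 5,
                                       length_mm = 25, q_l_min = 1,
                                       waveform = "steady", n_phases = 1L,
                                       spacing_mm = 1, seed = 1))
  cl <- ph2$truth$centerline
  seeds <- data.frame(branch = c("a", "b"),
                      x = c(cl$tube_a$x[1], cl$tube_b$x[1]),
                      y = c(cl$tube_a$y[1], cl$tube_b$y[1]),
                      z = c(cl$tube_a$z[1], max(cl$tube_b$z)))
  expect_error(extract_centerline(ph2$truth$mask, seeds),
               "disconnected")
})

test_that("TCPC centerline finds 4 branches meeting at the junction", {
  tr <- extract_centerline(tcpc_ph$truth$mask, tcpc_ph$truth$endpoints)
  expect_length(tr$branches, 4L)
  expect_named(tr$branches, c("tunnel", "svc", "lpa", "rpa"))
  expect_lt(sqrt(sum((tr$junction - tcpc_ph$truth$junction_world)^2)), 4)
  for (b in tr$branches) expect_true(all(diff(b$arclength) > 0))
})

test_that("five-segment labeling agrees with the generator labels", {
  tr <- extract_centerline(tcpc_ph$truth$mask, tcpc_ph$truth$endpoints)
  segs <- label_segments(tcpc_ph$truth$mask, tr)
  expect_identical(segs$segments,
                   c("tunnel", "svc", "lpa", "rpa", "confluence"))
  pred <- segs$labels
  tru <- tcpc_ph$truth$labels
  both <- pred > 0L & tru > 0L
  expect_gte(mean(pred[both] == tru[both]), 0.90)
  # segment masks partition the mask: every foreground voxel exactly once
  expect_equal(sum(pred > 0L), sum(tcpc_ph$truth$mask$values))
  # a 2-endpoint tube cannot be divided into five segments
  tube_tr <- extract_centerline(tube_ph$truth$mask,
                                tube_ph$truth$endpoints)
  expect_error(label_segments(tube_ph$truth$mask, tube_tr),
               "labeling error")
})

test_that("short branches are flagged excluded", {
  tr <- extract_centerline(tcpc_ph$truth$mask, tcpc_ph$truth$endpoints)
  segs <- label_segments(tcpc_ph$truth$mask, tr)
  expect_true(all(segs$included[1:4]))
  # truncate the svc branch polyline to 1.0 cm beyond the margin
  tr2 <- tr
  margin <- segs$confluence_margin_mm
  keep <- tr2$branches$svc$arclength <= margin + 10
  tr2$branches$svc <- tr2$branches$svc[keep, ]
  segs2 <- label_segments(tcpc_ph$truth$mask, tr2,
                          confluence_margin = margin)
  expect_false(segs2$included[segs2$segments == "svc"])
  expect_lt(segs2$lengths_cm[segs2$segments == "svc"], 1.5)
})

test_that("CSA profiles recover pi R^2 for straight and tilted tubes", {
  tr <- extract_centerline(tube_ph$truth$mask, tube_ph$truth$endpoints)
  cp <- csa_profile(tube_ph$truth$mask, tr$branches[[1]], bsa = 1.6)
  truth_csa <- pi * 0.8^2
  expect_lt(abs(cp$mean_csa_cm2 / truth_csa - 1), 0.05)
  expect_equal(cp$mean_csa_bsa, cp$mean_csa_cm2 / 1.6)

  tilted <- generate_phantom(phantom_spec("tilted_tube", radius_mm = 8,
                                          length_mm = 60, q_l_min = 2,
                                          waveform = "steady",
                                          n_phases = 1L, spacing_mm = 1,
                                          tilt_deg = 30, seed = 1))
  trt <- extract_centerline(tilted$truth$mask, tilted$truth$endpoints)
  cpt <- csa_profile(tilted$truth$mask, trt$branches[[1]], bsa = 1.6)
  expect_lt(abs(cpt$mean_csa_cm2 / truth_csa - 1), 0.05)
})

test_that("a 50 mm branch is sampled at 51 stations", {
  # exactly 50 mm of the analytic axis (1 mm node spacing)
  br50 <- tube_ph$truth$centerline$tube[1:51, ]
  cp <- csa_profile(tube_ph$truth$mask, br50)
  expect_equal(nrow(cp$profile) + cp$n_skipped, 51L)
  expect_equal(cp$n_skipped, 0L)
})

test_that("plane flow matches closed arithmetic and the generator", {
  # uniform 0.1 m/s through a 2 cm^2 rectangular duct -> 1.2 L/min
  d <- c(30, 20, 12)
  vals <- array(0, c(d, 1, 3))
  m <- array(FALSE, d)
  m[6:25, 6:15, ] <- TRUE  # 20 x 10 mm = 2 cm^2 at 1 mm spacing
  vals[, , , 1, 3] <- 0.1 * m
  f <- flow_field(vals, meta_iso())
  pf <- plane_flow(f, vessel_mask(m, f$meta),
                   origin = c(14.5, 9.5, 5), normal = c(0, 0, 1),
                   inplane_halfwidth = 25)
  expect_equal(pf$cycle_mean, 1.2, tolerance = 0.02)

  # zero field -> 0 L/min
  f0 <- f; f0$values[] <- 0
  expect_equal(plane_flow(f0, vessel_mask(m, f$meta),
                          origin = c(14.5, 9.5, 5),
                          normal = c(0, 0, 1))$cycle_mean, 0)

  # Poiseuille mid-plane flux within 2% of Q
  midz <- (dim(tube_ph$truth$mask$values)[3] - 1) / 2
  ctr <- (dim(tube_ph$truth$mask$values)[1] - 1) / 2
  pf2 <- plane_flow(tube_ph$truth$field, tube_ph$truth$mask,
                    origin = c(ctr, ctr, midz), normal = c(0, 0, 1))
  expect_lt(abs(pf2$cycle_mean / 2 - 1), 0.02)

  expect_error(plane_flow(f, vessel_mask(m, f$meta),
                          origin = c(0, 0, 500), normal = c(0, 0, 1)),
               "geometry error")
})

test_that("steady TCPC conserves mass within discretization tolerance", {
  tr <- extract_centerline(tcpc_ph$truth$mask, tcpc_ph$truth$endpoints)
  segs <- label_segments(tcpc_ph$truth$mask, tr)
  flows <- vapply(names(tr$branches), function(b) {
    poly <- tcpcflow:::resample_polyline(tr$branches[[b]], 1)
    i <- which.min(abs(poly$arclength -
                         (segs$confluence_margin_mm + 5)))
    tang <- tcpcflow:::tangent_at(poly, i)
    if (b %in% c("tunnel", "svc")) tang <- -tang
    plane_flow(tcpc_ph$truth$field, tcpc_ph$truth$mask,
               as.numeric(poly[i, c("x", "y", "z")]), tang)$cycle_mean
  }, 1)
  inflow <- flows[["tunnel"]] + flows[["svc"]]
  outflow <- flows[["lpa"]] + flows[["rpa"]]
  expect_lt(abs(inflow - outflow) / inflow, 0.05)
  expect_gt(inflow, 0)
})

test_that("Haycock BSA evaluates the published power law", {
  expect_equal(haycock_bsa(70, 170), 0.024265 * 70^0.5378 * 170^0.3964,
               tolerance = 1e-12)
  expect_equal(haycock_bsa(70, 170), 1.826, tolerance = 0.001)
  expect_equal(haycock_bsa(140, 170) / haycock_bsa(70, 170), 2^0.5378,
               tolerance = 1e-12)
  expect_error(haycock_bsa(70, 0), "positive")
  expect_error(haycock_bsa(-1, 170), "positive")
})
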