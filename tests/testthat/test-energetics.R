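# Independent verification of the Poiseuille closed forms by radial
# quadrature (done once here; the closed forms are then trusted as oracles):
#   EL = integral over the lumen of mu (dv/dr)^2  = 8 mu L Q^2 / (pi R^4)
#   KE = integral of 1/2 rho v^2                  = (2/3) rho Q^2 L / (pi R^2)
test_that("closed-form tube energetics agree with radial quadrature", {
  q <- 3 / 60000; r <- 0.008; l <- 0.1; mu <- 3.2e-3; rho <- 1060
  vmax <- 2 * q / (pi * r^2)
  el_quad <- l * stats::integrate(function(x)
    mu * (-2 * vmax * x / r^2)^2 * 2 * pi * x, 0, r,
    rel.tol = 1e-10)$value
  ke_quad <- l * stats::integrate(function(x)
    0.5 * rho * (vmax * (1 - x^2 / r^2))^2 * 2 * pi * x, 0, r,
    rel.tol = 1e-10)$value
  expect_equal(el_quad * 1000, poiseuille_el_mw(3, 8, 100), tolerance = 1e-8)
  expect_equal(ke_quad * 1000, poiseuille_ke_mj(3, 8, 100), tolerance = 1e-8)
})

test_that("velocity gradients: uniform, linear shear and Poiseuille wall", {
  f <- uniform_field(v = c(0.2, -0.1, 0.3), d = 8L)
  g <- velocity_gradient_tensor(f, full_mask(f))
  expect_equal(max(abs(g$grad)), 0)
  expect_false(any(g$isolated))

  # v_x = k y, k = 10/s: dvx/dy = 10 at interior voxels, everything else 0
  f <- shear_field(k = 10, d = 10L)
  g <- velocity_gradient_tensor(f, full_mask(f))$grad
  interior <- g[2:9, 2:9, 2:9, , ]
  expect_equal(interior[, , , 1, 2], array(10, c(8, 8, 8)),
               tolerance = 1e-10)
  interior[, , , 1, 2] <- 0
  expect_equal(max(abs(interior)), 0)

  # Poiseuille: central differences are exact for the parabolic profile
  ph <- steady_tube(radius = 8, length = 20, q = 2, spacing = 1)
  g <- velocity_gradient_tensor(ph$truth$field, ph$truth$mask)$grad
  d <- dim(ph$truth$mask$values)
  ctr <- c((d[1] - 1) / 2, (d[2] - 1) / 2)  # axis position, mm
  q_si <- 2 / 60000; R <- 0.008
  for (vox in list(c(9, 11, 10), c(13, 11, 5), c(11, 14, 15))) {
    x_m <- ((vox[1] - 1) - ctr[1]) / 1000
    expected <- -4 * q_si * x_m / (pi * R^4)
    expect_equal(g[vox[1], vox[2], vox[3], 3, 1], expected,
                 tolerance = 1e-6)
  }
})

test_that("kinetic energy matches closed arithmetic and the tube oracle", {
  # uniform 0.5 m/s over 1000 voxels of 1 mm^3 -> 0.1325 mJ
  f <- uniform_field(v = c(0, 0, 0.5), d = 10L)
  expect_equal(kinetic_energy(f, full_mask(f)), 0.1325, tolerance = 1e-12)

  z <- uniform_field(v = c(0, 0, 0), d = 6L, n_phases = 3L)
  expect_equal(kinetic_energy(z, full_mask(z)), rep(0, 3))

  ph <- steady_tube(radius = 8, length = 100, q = 3, spacing = 1)
  ke <- kinetic_energy(ph$truth$field, ph$truth$mask)
  expect_equal(ke, poiseuille_ke_mj(3, 8, 100), tolerance = 0.02)
})

test_that("viscous dissipation: exact zeros and the linear-shear value", {
  f <- uniform_field(v = c(0.3, 0.2, -0.1), d = 8L)
  expect_equal(viscous_energy_loss_rate(f, full_mask(f)), 0,
               ignore_attr = TRUE)

  rot <- rotation_field(omega = 5, d = 10L)
  el_rot <- viscous_energy_loss_rate(rot, full_mask(rot))
  expect_lt(abs(el_rot), 1e-12)

  # shear k = 10/s over 1 cm^3: mu k^2 V = 3.2e-4 mW, to 4 significant digits
  f <- shear_field(k = 10, d = 10L)
  el <- viscous_energy_loss_rate(f, full_mask(f))
  expect_equal(as.numeric(el), 3.2e-4, tolerance = 1e-4)
})

test_that("tube dissipation approaches the closed form as the grid refines", {
  errs <- vapply(c(2, 1), function(h) {
    ph <- steady_tube(radius = 8, length = 100, q = 3, spacing = h)
    el <- viscous_energy_loss_rate(ph$truth$field, ph$truth$mask)
    abs(as.numeric(el) / poiseuille_el_mw(3, 8, 100) - 1)
  }, 1)
  expect_lt(errs[2], errs[1])
  expect_lt(errs[2], 0.05)
})

test_that("dissipation is invariant to uniform offsets and scales as Q^2", {
  ph <- steady_tube(radius = 6, length = 30, q = 2, spacing = 1)
  el0 <- as.numeric(viscous_energy_loss_rate(ph$truth$field,
                                             ph$truth$mask))
  shifted <- ph$truth$field
  for (i in 1:3) shifted$values[, , , , i] <- shifted$values[, , , , i] +
    c(0.05, -0.03, 0.08)[i]
  el1 <- as.numeric(viscous_energy_loss_rate(shifted, ph$truth$mask))
  expect_equal(el1, el0, tolerance = 1e-10)

  scaled <- ph$truth$field
  scaled$values <- scaled$values * 1.7
  expect_equal(as.numeric(viscous_energy_loss_rate(scaled, ph$truth$mask)),
               1.7^2 * el0, tolerance = 1e-12)
  expect_equal(as.numeric(kinetic_energy(scaled, ph$truth$mask)),
               1.7^2 * as.numeric(kinetic_energy(ph$truth$field,
                                                 ph$truth$mask)),
               tolerance = 1e-12)
})

test_that("per-phase totals equal the sum of the voxel-wise maps", {
  ph <- generate_phantom(phantom_spec("straight_tube", radius_mm = 5,
                                      length_mm = 20, q_l_min = 1.5,
                                      n_phases = 4L, spacing_mm = 1.5,
                                      noise_sd = 0.02, seed = 6))
  m <- ph$truth$mask
  vvox <- prod(m$meta$spacing) * 1e-9
  ke <- kinetic_energy(ph$field, m, keep_maps = TRUE)
  el <- viscous_energy_loss_rate(ph$field, m, keep_maps = TRUE)
  for (phs in 1:4) {
    expect_equal(sum(attr(ke, "density")[, , , phs]) * vvox * 1000,
                 as.numeric(ke)[phs], tolerance = 1e-12)
    expect_equal(sum(attr(el, "density")[, , , phs]) * vvox * 1000,
                 as.numeric(el)[phs], tolerance = 1e-12)
  }
})

test_that("pulsatile energetics scale with the squared waveform", {
  w <- 1 + cos(2 * pi * (0:23) / 24)
  ph <- generate_phantom(phantom_spec("straight_tube", radius_mm = 8,
                                      length_mm = 30, q_l_min = 2,
                                      waveform = w, n_phases = 24L,
                                      spacing_mm = 1, seed = 1))
  st <- steady_tube(radius = 8, length = 30, q = 2, spacing = 1)
  el_steady <- as.numeric(viscous_energy_loss_rate(st$truth$field,
                                                   st$truth$mask))
  el_puls <- viscous_energy_loss_rate(ph$truth$field, ph$truth$mask)
  expect_equal(as.numeric(el_puls), el_steady * w^2, tolerance = 1e-10)
  expect_equal(cycle_average(el_puls), el_steady * mean(w^2),
               tolerance = 1e-10)
})

test_that("cycle averaging and normalization follow their contracts", {
  expect_equal(cycle_average(c(1, 3)), 2)
  expect_equal(cycle_average(7), 7)
  expect_error(cycle_average(numeric(0)), "empty")

  n <- normalize_energetics(0.91, 0.26, inflow = 3.5)
  expect_equal(n$ke_norm_flow, 0.26)
  n2 <- normalize_energetics(0.34, 0.1, inflow = 2, length = 5)
  expect_equal(n2$ke_norm_flow_length, 0.034)
  expect_equal(normalize_energetics(0, 0, 3)$ke_norm_flow, 0)
  expect_error(normalize_energetics(1, 1, 0), "inflow")
  expect_error(normalize_energetics(1, 1, 2, length = -1), "length")
})

test_that("boundary schemes bracket and converge on the tube phantom", {
  errs <- sapply(c(2, 1), function(h) {
    ph <- steady_tube(radius = 8, length = 60, q = 3, spacing = h)
    one <- as.numeric(viscous_energy_loss_rate(
      ph$truth$field, ph$truth$mask,
      energetics_config(boundary_scheme = "one_sided")))
    int <- as.numeric(viscous_energy_loss_rate(
      ph$truth$field, ph$truth$mask,
      energetics_config(boundary_scheme = "interior_only")))
    c(one, int) / poiseuille_el_mw(3, 8, 60) - 1
  })
  # interior-only always underestimates more strongly; both improve with h
  expect_true(all(errs[2, ] < errs[1, ]))
  expect_lt(abs(errs[1, 2]), abs(errs[1, 1]))
  expect_lt(abs(errs[2, 2]), abs(errs[2, 1]))
})
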