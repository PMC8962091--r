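# Small in-memory fields used across tests. All are built from code; no
# fixture files.

meta_iso <- function(spacing = 1, n_phases = 1L, venc = 80) {
  acquisition_meta(spacing = spacing, n_phases = n_phases, venc_cm_s = venc)
}

# constant-velocity field on a d^3 grid
uniform_field <- function(v = c(0.1, 0, 0), d = 8L, n_phases = 1L,
                          spacing = 1) {
  vals <- array(0, c(d, d, d, n_phases, 3L))
  for (i in 1:3) vals[, , , , i] <- v[i]
  flow_field(vals, meta_iso(spacing, n_phases))
}

full_mask <- function(field) {
  vessel_mask(array(TRUE, dim(field$values)[1:3]), field$meta)
}

# linear shear v_x = k * y (k in 1/s, y in m)
shear_field <- function(k = 10, d = 10L, spacing = 1) {
  vals <- array(0, c(d, d, d, 1L, 3L))
  y_m <- (seq_len(d) - 1) * spacing / 1000
  vals[, , , 1L, 1L] <- array(rep(y_m, each = d), c(d, d, d)) * k
  flow_field(vals, meta_iso(spacing))
}

# rigid rotation v = omega x r about the grid centre (z axis)
rotation_field <- function(omega = 5, d = 10L, spacing = 1) {
  vals <- array(0, c(d, d, d, 1L, 3L))
  ctr <- (d - 1) / 2 * spacing / 1000
  x_m <- (seq_len(d) - 1) * spacing / 1000 - ctr
  X <- array(rep(x_m, times = d * d), c(d, d, d))
  Y <- array(rep(rep(x_m, each = d), times = d), c(d, d, d))
  vals[, , , 1L, 1L] <- -omega * Y
  vals[, , , 1L, 2L] <- omega * X
  flow_field(vals, meta_iso(spacing))
}

# quick steady Poiseuille phantom
steady_tube <- function(radius = 8, length = 100, q = 3, spacing = 1,
                        seed = 1, ...) {
  generate_phantom(phantom_spec("straight_tube", radius_mm = radius,
                                length_mm = length, q_l_min = q,
                                waveform = "steady", n_phases = 1L,
                                spacing_mm = spacing, seed = seed, ...))
}

binary_erode_test <- function(m)
  tcpcflow:::binary_erode(m, tcpcflow:::offsets_face())

binary_dilate_test <- function(m)
  tcpcflow:::binary_dilate(m, tcpcflow:::offsets_full())

# closed forms for a steady Poiseuille tube (Q in L/min, R mm, L mm)
poiseuille_el_mw <- function(q, r, l, mu = 3.2e-3)
  8 * mu * (l / 1000) * (q / 60000)^2 / (pi * (r / 1000)^4) * 1000

poiseuille_ke_mj <- function(q, r, l, rho = 1060)
  (2 / 3) * rho * (q / 60000)^2 * (l / 1000) / (pi * (r / 1000)^2) * 1000
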