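test_that("radial profiles conserve mass and charge", {
  # one atom of mass m at radius r0: all mass in one bin, integral = m
  tr <- traj_from_coords(rbind(c(0, 0, 0), c(1.23, 0, 0)),
                         tibble::tibble(atom_id = 1:2, mass = c(1e9, 7),
                                        charge = 0, role = "dendrimer"))
  p <- radial_profile(tr, 2, "mass_density", bin_width = 0.05, r_max = 2,
                      center_selection = 1)
  occupied <- which(p$value > 0)
  expect_length(occupied, 1)
  expect_true(p$r_lo[occupied] <= 1.23 && p$r_hi[occupied] >= 1.23)
  shell_mass <- sum(p$value * 4 * pi / 3 * (p$r_hi^3 - p$r_lo^3))
  expect_equal(shell_mass, 7)
  # uniform ball: flat density M / (4/3 pi R^3) inside, 0 outside
  d <- gen_dendrimer(2e5, 2, bead_mass = 1, seed = 41)
  pd <- radial_profile(d, "dendrimer", "mass_density", bin_width = 0.1,
                       r_max = 3)
  expected <- 2e5 / (4 / 3 * pi * 8)
  inner <- pd$value[pd$r_hi <= 1.8 & pd$r_lo >= 0.4]
  expect_equal(mean(inner) / expected, 1, tolerance = 0.05)
  # beyond the ball (allowing for the sample centre-of-mass offset)
  expect_true(all(pd$value[pd$r_lo >= 2.2] == 0))
  # mass conservation to 0.1% at fine bins
  pd2 <- radial_profile(d, "dendrimer", "mass_density", bin_width = 0.05,
                        r_max = 2.5)
  expect_equal(sum(pd2$value * 4 * pi / 3 * (pd2$r_hi^3 - pd2$r_lo^3)) / 2e5, 1,
               tolerance = 0.001)
  expect_error(radial_profile(d, "dendrimer", bin_width = 0), "bin_width")
})

test_that("linear charge density integrates to the net charge", {
  host <- gen_dendrimer(300, 1.5, terminal_count = 16,
                        spacer_charge_sites = 28, box_edge = 8, seed = 2)
  ic <- gen_ion_cloud(host, 44, condensed_fraction = 0.5, condensed_radius = 2,
                      seed = 3)
  qp <- radial_profile(ic, "all", "charge_linear", bin_width = 0.05)
  expect_equal(sum(qp$value * (qp$r_hi - qp$r_lo)), 0, tolerance = 1e-10)
  # cumulative charge: starts near 0-accumulation, ends at the net charge
  Qr <- cumulative_charge(qp)
  expect_equal(Qr$value[nrow(Qr)], 0, tolerance = 1e-10)
  # dendrimer-only profile accumulates monotonically to Qbare
  qd <- radial_profile(ic, "dendrimer", "charge_linear", bin_width = 0.05)
  Qd <- cumulative_charge(qd)
  expect_true(all(diff(Qd$value) >= -1e-12))
  expect_equal(Qd$value[nrow(Qd)], 44)
  # wrong profile kind is a type error
  md <- radial_profile(ic, "dendrimer", "mass_density", bin_width = 0.5)
  expect_error(cumulative_charge(md), "charge_linear")
})

test_that("effective radius/charge extraction follows the maximum rule", {
  # constructed double layer: +16 inside 2 nm, -16 spread outside
  bw <- 0.1
  r_lo <- seq(0, 5.9, by = bw); r_hi <- r_lo + bw
  q <- numeric(length(r_lo))
  q[r_lo < 2] <- 16 / 2 / 1  # uniform linear density inside: integral 16
  q[r_lo >= 3] <- -16 / (max(r_hi) - 3)
  qp <- dendritrace:::new_profile(r_lo, r_hi, q, "charge_linear", bw)
  Qr <- cumulative_charge(qp)
  eff <- effective_radius_charge(Qr)
  expect_equal(eff$q_star, 16, tolerance = 1e-9)
  # the cumulative maximum is first attained at the edge of the positive
  # region; the smallest r among the tied plateau bins is returned
  expect_equal(eff$r_max, 2 - bw / 2, tolerance = 1e-9)
  # tie-break: two equal maxima -> smaller r
  q2 <- dendritrace:::new_profile(c(0, 1, 2), c(1, 2, 3), c(5, -5, 5),
                                  "charge_cumulative", 1)
  expect_equal(effective_radius_charge(q2)$r_max, 0.5)
  flat <- dendritrace:::new_profile(c(0, 1), c(1, 2), c(0, 0),
                                    "charge_cumulative", 1)
  expect_error(effective_radius_charge(flat), "no maximum")
})

test_that("Bjerrum length matches physical constants and scaling", {
  expect_equal(bjerrum_length(298.15, 80), 0.700, tolerance = 0.002)
  expect_equal(bjerrum_length(310, 80), 0.674, tolerance = 0.002)
  expect_equal(bjerrum_length(300, 160), bjerrum_length(300, 80) / 2)
  expect_error(bjerrum_length(-1), "> 0")
})

test_that("Poisson solver reproduces closed forms", {
  lB <- 0.7; D <- 3
  # zero source -> zero potential
  z <- uniform_ball_qprofile(1, 1, D, 0.01)
  z$value <- 0
  psi0 <- poisson_potential(z, lB, D = D)
  expect_true(all(psi0$value == 0))
  # point-like charge at the origin: psi = lB Q (1/r - 1/D) outside the source
  bw <- 0.01
  qpt <- dendritrace:::new_profile(seq(0, D - bw, bw), seq(bw, D, bw),
                                   c(16 / bw, rep(0, D / bw - 1)),
                                   "charge_linear", bw)
  psi_pt <- poisson_potential(qpt, lB, D = D)
  out <- psi_pt$r > 0.3 & psi_pt$r < 2.9
  expect_equal(psi_pt$value[out], lB * 16 * (1 / psi_pt$r[out] - 1 / D),
               tolerance = 1e-3)
  # uniformly charged ball: piecewise closed form, within 0.5%
  Q <- 16; R <- 1
  qb <- uniform_ball_qprofile(Q, R, D, 0.01)
  psi_b <- poisson_potential(qb, lB, D = D)
  exact <- ifelse(psi_b$r < R,
                  lB * Q * (3 / (2 * R) - psi_b$r^2 / (2 * R^3)) - lB * Q / D,
                  lB * Q * (1 / psi_b$r - 1 / D))
  expect_lt(max(abs(psi_b$value - exact)) / max(abs(exact)), 0.005)
  expect_error(poisson_potential(qb, lB, D = 10), "does not reach")
})

test_that("Poisson solver error contracts like the square of the bin width", {
  lB <- 0.7; D <- 3; Q <- 16; R <- 1
  err_at <- function(bw) {
    qb <- uniform_ball_qprofile(Q, R, D, bw)
    psi <- poisson_potential(qb, lB, D = D)
    exact <- ifelse(psi$r < R,
                    lB * Q * (3 / (2 * R) - psi$r^2 / (2 * R^3)) - lB * Q / D,
                    lB * Q * (1 / psi$r - 1 / D))
    max(abs(psi$value - exact))
  }
  e1 <- err_at(0.04); e2 <- err_at(0.02)
  expect_gt(e1 / e2, 3)  # halving the bin cuts the error ~4x
})

test_that("zeta potential and surface charge density follow their formulas", {
  bw <- 0.01; D <- 3
  qb <- uniform_ball_qprofile(16, 1, D, bw)
  psi <- poisson_potential(qb, bjerrum_length(310), D = D)
  zs <- zeta_and_sigma(psi, r_max = 2.53, q_star = 9.31, temperature = 310)
  expect_equal(zs$sigma, 9.31 / (4 * pi * 2.53^2))
  kT_e_mV <- 1.380649e-23 * 310 / 1.602176634e-19 * 1000
  expect_equal(zs$zeta_mV, zs$zeta_dimensionless * kT_e_mV)
  # doubling Rmax at fixed Q* quarters sigma
  zs2 <- zeta_and_sigma(psi, r_max = 1, q_star = 10, temperature = 310)
  zs3 <- zeta_and_sigma(psi, r_max = 2, q_star = 10, temperature = 310)
  expect_equal(zs2$sigma / zs3$sigma, 4)
  # psi == 0 everywhere gives zeta = 0
  psi0 <- psi; psi0$value <- 0
  expect_equal(zeta_and_sigma(psi0, 1, 1, 310)$zeta_mV, 0)
  expect_error(zeta_and_sigma(psi, r_max = 10, q_star = 1, temperature = 310),
               "outside")
})

test_that("soft-sphere effective charge solves the cell-model relation", {
  lB <- bjerrum_length(310)
  D <- sqrt(3) * 7.5 / 2
  for (Q in c(16, 44)) {
    qs <- soft_sphere_effective_charge(Q, 2.5, D, lB)
    rhs <- (2.5 / lB) / (2 * 3 / 5) * log((Q / as.numeric(qs) - 1) * (D^3 / 2.5^3 - 1))
    expect_lt(abs(as.numeric(qs) - rhs), 1e-10)
    expect_lt(attr(qs, "residual"), 1e-10)
    expect_true(as.numeric(qs) > 0 && as.numeric(qs) < Q)
  }
  # Q* increases with the sphere radius in the dilute regime R << D (as R
  # approaches the cell radius the log factor collapses and Q* turns over,
  # so the scan stays below D/3)
  Rs <- seq(0.5, 2, by = 0.25)
  qvals <- vapply(Rs, function(R)
    as.numeric(soft_sphere_effective_charge(16, R, 6.5, lB)), 0)
  expect_true(all(diff(qvals) > 0))
  # vanishing R/lambdaB prefactor sends Q* to zero
  expect_lt(as.numeric(soft_sphere_effective_charge(16, 1e-4, 6.5, lB)), 0.01)
  expect_error(soft_sphere_effective_charge(16, 3, 2, lB), "D > R")
})

test_that("ion-pair counting equals the brute-force double loop", {
  host <- gen_dendrimer(40, 1.2, terminal_count = 8, box_edge = 8, seed = 5)
  ic <- gen_ion_cloud(host, 8, condensed_fraction = 0.5, condensed_radius = 1.6,
                      pair_fraction = 0.25, seed = 6)
  ip <- ion_pair_count(ic, pair_cutoff = 0.4)
  fr <- frame_atoms(ic, 1)
  ions <- fr[fr$role == "counterion", ]
  sites <- fr[fr$role != "counterion" & fr$charge != 0, ]
  n_bf <- 0
  for (i in seq_len(nrow(ions))) for (j in seq_len(nrow(sites))) {
    dij <- sqrt((ions$x[i] - sites$x[j])^2 + (ions$y[i] - sites$y[j])^2 +
                  (ions$z[i] - sites$z[j])^2)
    if (dij < 0.4) n_bf <- n_bf + 1
  }
  expect_equal(ip$n_ionpairs, n_bf)
  expect_equal(n_bf, 2)  # round(0.25 * 8) constructed pairs
  # rdf has its spike in the 0.3 nm bin
  peak_bin <- ip$rdf[ip$rdf$value == max(ip$rdf$value), ]
  expect_true(peak_bin$r_lo[1] <= 0.3 && peak_bin$r_hi[1] >= 0.3)
})

test_that("osmotic ion bookkeeping reproduces the charge balance", {
  expect_equal(osmotic_ions(16, 9.31, 0.67), 6.02)
  expect_equal(osmotic_ions(44, 12.93, 3.38), 27.69)
  expect_equal(osmotic_ions(10, 10, 0), 0)
  expect_warning(osmotic_ions(5, 6, 1), "negative")
})

test_that("electro_summary composes the stages coherently", {
  host <- gen_dendrimer(400, 2, terminal_count = 16, box_edge = 7.5, seed = 9)
  ic <- gen_ion_cloud(host, 16, condensed_fraction = 0.25, condensed_radius = 2,
                      seed = 10)
  es <- electro_summary(ic, temperature = 310)
  gl <- glance(es)
  expect_equal(gl$q_bare, 16)
  expect_gt(gl$q_star, 0)
  expect_lte(gl$q_star, 16)
  expect_equal(gl$n_osmotic, gl$q_bare - gl$q_star - gl$n_ionpairs)
  expect_true(gl$q_ratio > 0 && gl$q_ratio <= 1)
  expect_s3_class(autoplot(es$cumulative), "ggplot")
})
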