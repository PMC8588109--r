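test_that("plane normal comes from the cross-product construction", {
  at <- atoms_tbl(c(0, 1, 0), c(0, 0, 1), c(0, 0, 0))
  n <- plane_normal(at, c(1, 2, 3))
  expect_equal(abs(n), c(0, 0, 1))
  at2 <- atoms_tbl(c(0, 0, 0), c(0, 1, 0), c(0, 0, 1))
  expect_equal(abs(plane_normal(at2, c(1, 2, 3))), c(1, 0, 0))
  # orthogonal to both edges for random non-degenerate triples
  set.seed(3)
  for (k in 1:5) {
    p <- matrix(rnorm(9), 3)
    at3 <- atoms_tbl(p[, 1], p[, 2], p[, 3])
    n3 <- plane_normal(at3, 1:3)
    e1 <- p[2, ] - p[1, ]; e2 <- p[3, ] - p[1, ]
    expect_lt(abs(sum(n3 * e1)), 1e-12)
    expect_lt(abs(sum(n3 * e2)), 1e-12)
    expect_equal(sum(n3^2), 1)
  }
  # collinear triple is a geometry error
  at4 <- atoms_tbl(c(0, 1, 2), c(0, 0, 0), c(0, 0, 0))
  expect_error(plane_normal(at4, 1:3), "collinear")
})

test_that("pair geometry folds the inter-plane angle to [0, 90]", {
  g1 <- list(triple = list(1:3), center_atoms = list(1:3))
  g2 <- list(triple = list(4:6), center_atoms = list(4:6))
  # parallel planes, centres 0.4 nm apart
  base <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  par <- rbind(base, sweep(base, 2, c(0, 0, 0.4), "+"))
  at <- atoms_tbl(par[, 1], par[, 2], par[, 3])
  pg <- pair_geometry(at, g1, g2)
  expect_equal(pg$r, 0.4)
  expect_equal(pg$theta, 0)
  # orthogonal planes
  ortho <- rbind(base, rbind(c(2, 0, 0), c(2, 1, 0), c(2, 0, 1)))
  at2 <- atoms_tbl(ortho[, 1], ortho[, 2], ortho[, 3])
  expect_equal(pair_geometry(at2, g1, g2)$theta, 90)
  # normals at a raw angle of 120 degrees fold to 60
  R <- dendritrace:::rot_about(c(1, 0, 0), 120 * pi / 180)
  tilt <- rbind(base, sweep(base %*% t(R), 2, c(1, 0, 0), "+"))
  at3 <- atoms_tbl(tilt[, 1], tilt[, 2], tilt[, 3])
  expect_equal(pair_geometry(at3, g1, g2)$theta, 60, tolerance = 1e-9)
  # rigid-motion invariance, including sign flips of either normal
  m <- rigid_motion(tilt, seed = 9)
  at4 <- atoms_tbl(m[, 1], m[, 2], m[, 3])
  expect_equal(pair_geometry(at4, g1, g2)$theta, 60, tolerance = 1e-9)
  g2_flipped <- list(triple = list(c(4, 6, 5)), center_atoms = list(4:6))
  expect_equal(pair_geometry(at3, g1, g2_flipped)$theta, 60, tolerance = 1e-9)
})

test_that("pair matrix classifies by spacer and recovers exact geometry", {
  pp <- tibble::tibble(r = 0.4, theta = 30, neighboring = TRUE)
  g <- gen_planar_groups(pp, seed = 2)
  Mn <- pair_matrix(g, "neighboring")
  expect_equal(sum(Mn$count), 1)
  hit <- Mn[Mn$count > 0, ]
  expect_true(hit$r_lo <= 0.4 && hit$r_hi >= 0.4)
  expect_true(hit$theta_lo <= 30 && hit$theta_hi >= 30)
  # the same pair is absent from the non-neighboring matrix
  expect_warning(Mnn <- pair_matrix(g, "non_neighboring"), "no non_neighboring")
  expect_equal(sum(Mnn$count), 0)
  # different spacers: appears only in the non-neighboring matrix
  g2 <- gen_planar_groups(tibble::tibble(r = 0.4, theta = 30,
                                         neighboring = FALSE), seed = 2)
  expect_equal(sum(pair_matrix(g2, "non_neighboring")$count), 1)
})

test_that("pair matrix equals an all-pairs brute force on a 20-group fixture", {
  set.seed(44)
  pp <- tibble::tibble(r = runif(6, 0.3, 1.6), theta = runif(6, 1, 89),
                       neighboring = rep(c(TRUE, FALSE), 3))
  g <- gen_planar_groups(pp, n_isolated = 8, seed = 15)
  gr <- g$selections$planar_groups
  fr <- frame_atoms(g, 1)
  for (cl in c("neighboring", "non_neighboring")) {
    M <- pair_matrix(g, cl, theta_bin = 5, r_bin = 0.1)
    bf <- matrix(0, nrow = length(unique(M$theta)), ncol = length(unique(M$r)))
    th_edges <- sort(unique(c(M$theta_lo, M$theta_hi)))
    r_edges <- sort(unique(c(M$r_lo, M$r_hi)))
    for (i in 1:(nrow(gr) - 1)) for (j in (i + 1):nrow(gr)) {
      same <- gr$spacer_id[i] == gr$spacer_id[j]
      if ((cl == "neighboring") != same) next
      pg <- pair_geometry(fr, gr[i, ], gr[j, ])
      if (pg$r >= 1.8) next
      ti <- max(min(findInterval(pg$theta, th_edges,
                                 rightmost.closed = TRUE), nrow(bf)), 1)
      ri <- max(min(findInterval(pg$r, r_edges,
                                 rightmost.closed = TRUE), ncol(bf)), 1)
      bf[ti, ri] <- bf[ti, ri] + 1
    }
    got <- matrix(M$count, nrow = nrow(bf), byrow = TRUE)
    expect_equal(got, bf, ignore_attr = TRUE)
  }
  # class totals partition the all-pairs total within the cut-off
  tot <- sum(pair_matrix(g, "neighboring")$count) +
    sum(pair_matrix(g, "non_neighboring")$count)
  expect_equal(tot, 6)
})

test_that("radial marginal conserves matrix totals", {
  pp <- tibble::tibble(r = c(0.4, 0.9, 1.4), theta = c(10, 50, 80),
                       neighboring = FALSE)
  g <- gen_planar_groups(pp, seed = 5)
  M <- pair_matrix(g, "non_neighboring")
  npr <- radial_marginal(M)
  expect_equal(sum(npr$count), sum(M$count))
  # single-bin matrix -> single-bin marginal
  expect_equal(sum(npr$count > 0), 3)
  # first-peak integral: only the 0.4 nm pair is below 0.55 nm
  expect_equal(first_peak_count(npr, 0.55), 1)
  expect_equal(first_peak_count(npr, 1.8), 3)
  expect_lte(first_peak_count(npr, 0.55), sum(npr$count))
  expect_error(first_peak_count(npr, 99), "beyond")
})

test_that("pairing ACF is normalised and static pairs never decay", {
  # permanently formed pair: C(t) = 1 everywhere
  b <- bond_events(matrix(TRUE, 2, 50), 1)
  a <- pairing_acf(b)
  expect_equal(a$acf$C, rep(1, nrow(a$acf)), tolerance = 1e-9)
  expect_equal(a$tau_LF, Inf)
  # C(0) = 1 for any non-degenerate series
  s <- gen_telegraph_series(5, 10, 30, 1, 400, seed = 2)
  expect_equal(pairing_acf(s)$acf$C[1], 1)
  expect_error(pairing_acf(bond_events(matrix(FALSE, 1, 10), 1)), "no formed")
})

test_that("ACF relaxation time recovers the telegraph correlation time", {
  mean_on <- 20; mean_off <- 2000
  tau_c <- mean_on * mean_off / (mean_on + mean_off)
  s <- gen_telegraph_series(60, mean_on, mean_off, 1, 20000, seed = 31)
  a <- pairing_acf(s, max_lag = 500)
  expect_equal(a$tau_LF, tau_c, tolerance = 0.1)
  # crossing variant also sits near tau_c for a near-exponential decay
  a2 <- pairing_acf(s, max_lag = 500, method = "crossing")
  expect_equal(a2$tau_LF, tau_c, tolerance = 0.15)
})

test_that("FFT autocorrelation sums equal the direct lag sums", {
  set.seed(8)
  b <- as.numeric(runif(200) < 0.3)
  s_fft <- dendritrace:::acf_sums_fft(b)
  direct <- vapply(0:199, function(t) sum(b[1:(200 - t)] * b[(1 + t):200]), 0)
  expect_equal(s_fft, direct, tolerance = 1e-8)
})

test_that("pairing events track the formation cut-off over frames", {
  pp <- tibble::tibble(r = c(0.4, 1.0), theta = c(20, 20),
                       neighboring = c(FALSE, FALSE))
  g <- gen_planar_groups(pp, seed = 7)
  ev <- pairing_events(g, "non_neighboring", form_cutoff = 0.55)
  # among non-neighboring pairs only the constructed 0.4 nm pair is formed
  expect_equal(sum(ev$presence[, 1]), 1)
})
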