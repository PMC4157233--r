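test_that("microstate energies follow the occupancy convention", {
  sys <- titration_system(
    data.frame(id = c("h1", "h2"), kind = "proton", intrinsic = c(6, 8)),
    matrix(c(0, 1.5, 1.5, 0), 2))
  expect_equal(microstate_energy(sys, c(0, 0), 7, -0.4), 0)
  # single site at pH = pKa: bound and unbound degenerate
  expect_equal(microstate_energy(sys, c(1, 0), 6, -0.4), 0)
  # both bound at their pKa values pays only the coupling
  sys_eq <- titration_system(
    data.frame(id = c("h1", "h2"), kind = "proton", intrinsic = c(7, 7)),
    matrix(c(0, 1.5, 1.5, 0), 2))
  expect_equal(microstate_energy(sys_eq, c(1, 1), 7, -0.4), 1.5)
  # electron site pays F(E - E0) when reduced
  se <- titration_system(
    data.frame(id = "e1", kind = "electron", intrinsic = -0.4))
  expect_equal(microstate_energy(se, 1, 7, -0.3), 23.0605 * 0.1)
  expect_error(microstate_energy(se, c(1, 0), 7, -0.3), "0/1 vector")
})

test_that("system construction rejects malformed couplings", {
  sites <- data.frame(id = c("a", "b"), kind = "proton", intrinsic = 7)
  expect_error(titration_system(sites, matrix(c(0, 1, 2, 0), 2)),
               "symmetric")
  expect_error(titration_system(sites, matrix(c(1, 0, 0, 0), 2)),
               "diagonal")
  expect_error(
    titration_system(data.frame(id = c("a", "a"), kind = "proton",
                                intrinsic = 7)), "unique")
})

test_that("exact enumeration reproduces closed-form single-site curves", {
  hh <- titration_system(
    data.frame(id = "h", kind = "proton", intrinsic = 7))
  g <- grid_spec(ph = c(5, 6, 7, 8, 9), potential_mv = -400)
  occ <- exact_titration(hh, g)
  expect_equal(occ$theta[1, , 1], hh_theta(c(5, 6, 7, 8, 9), 7),
               tolerance = 1e-12)
  expect_equal(unname(occ$theta[1, 3, 1]), 0.5)
  expect_equal(unname(occ$theta[1, 1, 1]), 0.990, tolerance = 1e-3)

  ne <- titration_system(
    data.frame(id = "e", kind = "electron", intrinsic = -0.45))
  gv <- grid_spec(ph = 7, potential_mv = seq(-750, -200, 50))
  occ_e <- exact_titration(ne, gv)
  expect_equal(occ_e$theta[1, 1, ],
               nernst_theta(gv$potential_mv / 1000, -0.45),
               tolerance = 1e-12)
})

test_that("exact enumeration matches the hand-written 4-state sum for a coupled pair", {
  sys <- make_two_site_system(w = -5, pka = 7, e0 = -0.45)
  g <- grid_spec(ph = 7.5, potential_mv = -450)
  occ <- exact_titration(sys, g)
  rt <- 1.9872e-3 * 300
  ge <- 23.0605 * (-0.450 - (-0.45))
  gh <- rt * log(10) * (7.5 - 7)
  e <- c(0, ge, gh, ge + gh - 5) # states 00, e, h, eh
  w4 <- exp(-e / rt); w4 <- w4 / sum(w4)
  expect_equal(unname(occ$theta[1, 1, 1]), w4[2] + w4[4], tolerance = 1e-12)
  expect_equal(unname(occ$theta[2, 1, 1]), w4[3] + w4[4], tolerance = 1e-12)
  expect_error(
    exact_titration(titration_system(
      data.frame(id = sprintf("s%d", 1:21), kind = "proton", intrinsic = 7)),
      g), "20 sites")
})

test_that("Monte Carlo occupancies agree with exact enumeration within 4 sigma", {
  gen <- gen_titration_system(10, seed = 1, n_electron = 2,
                              coupling_density = 0.4, coupling_scale = 3)
  g <- grid_spec(ph = c(5, 7, 9), potential_mv = c(-700, -450, -250),
                 steps_scan = 2e4, steps_production = 2e5,
                 clamp_threshold = 1, seed = 2)
  ex <- exact_titration(gen$system, g)
  mc <- mc_titration(gen$system, g)
  dev <- abs(mc$theta - ex$theta) / pmax(mc$se, 1e-12)
  expect_lt(max(dev[mc$se > 0]), 4 + 1e-9)
})

test_that("identical seeds give bit-identical occupancy maps", {
  gen <- gen_titration_system(6, seed = 5)
  g <- grid_spec(ph = c(6, 8), potential_mv = c(-500, -300),
                 steps_scan = 5e3, steps_production = 2e4, seed = 9)
  a <- mc_titration(gen$system, g)
  b <- mc_titration(gen$system, g)
  expect_identical(a$theta, b$theta)
  expect_identical(a$se, b$se)
  g2 <- grid_spec(ph = c(6, 8), potential_mv = c(-500, -300),
                  steps_scan = 5e3, steps_production = 2e4, seed = 10)
  c_ <- mc_titration(gen$system, g2)
  expect_false(identical(a$theta, c_$theta))
})

test_that("extreme sites are clamped after the scan and never sampled", {
  sys <- titration_system(
    data.frame(id = c("locked", "free"), kind = "proton",
               intrinsic = c(25, 7)))
  g <- grid_spec(ph = seq(5, 9, 1), potential_mv = -400,
                 steps_scan = 2e4, steps_production = 5e4,
                 clamp_threshold = 0.9, seed = 3)
  occ <- mc_titration(sys, g)
  expect_equal(occ$clamped, c(1L, 0L))
  expect_true(all(occ$theta[1, , ] == 1))
  expect_true(all(occ$se[1, , ] == 0))
  expect_warning(site_correlation(occ, c("locked", "free"), 7, -400),
                 "clamped")
})

test_that("detailed balance: MC microstate frequencies match Boltzmann", {
  gen <- gen_titration_system(3, seed = 8, n_electron = 1,
                              coupling_density = 1, coupling_scale = 2)
  g <- grid_spec(ph = 7, potential_mv = -450, steps_scan = 1e4,
                 steps_production = 1e6, clamp_threshold = 1, seed = 4)
  mc <- mc_titration(gen$system, g, track_states = TRUE)
  counts <- mc$state_counts[[1]]
  n_tot <- sum(counts)
  states <- as.matrix(expand.grid(rep(list(0:1), 3)))
  e <- apply(states, 1, function(s)
    microstate_energy(gen$system, s, 7, -0.45))
  rt <- 1.9872e-3 * 300
  p <- exp(-(e - min(e)) / rt); p <- p / sum(p)
  # 4-sigma binomial check per microstate (correlated samples make this a
  # generous but meaningful bound at 1e6 steps)
  p_hat <- counts / n_tot
  sigma <- sqrt(p * (1 - p) / (n_tot / 20)) # thin by typical correlation time
  expect_true(all(abs(p_hat - p) < 4 * sigma + 1e-4))
})

test_that("midpoints and Nernst slopes recover coupled proton uptake", {
  # fully coupled electron/proton pair: pKa 3 oxidized, strongly shifted
  # when reduced, so every reduction in pH 5-9 carries one proton
  sys <- make_two_site_system(w = -12, pka = 3, e0 = -0.75)
  g <- grid_spec(ph = c(5, 7, 9), potential_mv = seq(-750, -200, 10))
  ex <- exact_titration(sys, g)
  ms <- midpoint_and_slope(ex, "e1")
  expect_equal(ms$slope_mv_per_ph, -59.5, tolerance = 0.02)
  expect_equal(ms$protons_per_electron, 1, tolerance = 0.01)

  # uncoupled electron site: flat midpoint, zero proton uptake
  un <- titration_system(
    data.frame(id = c("e1", "h1"), kind = c("electron", "proton"),
               intrinsic = c(-0.45, 7)))
  ex_un <- exact_titration(un, g)
  ms_un <- midpoint_and_slope(ex_un, "e1")
  expect_equal(ms_un$slope_mv_per_ph, 0, tolerance = 1e-9)
  expect_equal(unname(ms_un$e_half["7"]), -450, tolerance = 0.01)

  # midpoint outside the potential window is an explicit error
  out <- titration_system(
    data.frame(id = "e1", kind = "electron", intrinsic = -0.1))
  ex_out <- exact_titration(out, g)
  expect_error(midpoint_and_slope(ex_out, "e1"), "out of window")
  expect_error(midpoint_and_slope(ex, "h1"), "electron sites")
})

test_that("a partially coupled pair shows fractional proton uptake", {
  # oxidized pKa 6.4: at pH 7 about 0.8 proton taken up per electron,
  # giving a slope near -47.6 mV/pH (exact-enumeration oracle)
  sys <- make_two_site_system(w = -12, pka = 6.4, e0 = -0.95)
  g <- grid_spec(ph = c(6.9, 7, 7.1), potential_mv = seq(-750, -200, 5))
  ms <- midpoint_and_slope(exact_titration(sys, g), "e1",
                           ph_values = c(6.9, 7.1))
  expect_equal(ms$slope_mv_per_ph, -47.6, tolerance = 0.7)
  expect_equal(ms$protons_per_electron, 0.8, tolerance = 0.012)
})

test_that("site correlations have the sign and limits the coupling dictates", {
  g <- grid_spec(ph = 7, potential_mv = -450, steps_scan = 1e4,
                 steps_production = 2e5, clamp_threshold = 1, seed = 6)
  # negative W favors co-occupancy: positive correlation
  co <- make_two_site_system(w = -3, pka = 7, e0 = -0.45)
  ex_co <- exact_titration(co, grid_spec(ph = 7, potential_mv = -450))
  expect_gt(site_correlation(ex_co, c("e1", "h1"), 7, -450), 0.3)
  mc_co <- mc_titration(co, g)
  expect_gt(site_correlation(mc_co, c("e1", "h1"), 7, -450), 0.3)
  # positive W disfavors co-occupancy
  anti <- make_two_site_system(w = 3, pka = 7, e0 = -0.45)
  expect_lt(site_correlation(exact_titration(
    anti, grid_spec(ph = 7, potential_mv = -450)), c("e1", "h1"), 7, -450),
    -0.3)
  # independence and self-correlation
  ind <- titration_system(
    data.frame(id = c("e1", "h1"), kind = c("electron", "proton"),
               intrinsic = c(-0.45, 7)))
  mc_ind <- mc_titration(ind, g)
  expect_lt(abs(site_correlation(mc_ind, c("e1", "h1"), 7, -450)), 0.02)
  expect_equal(site_correlation(mc_ind, c("e1", "e1"), 7, -450), 1)
})
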