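test_that("Coulomb evaluator matches hand arithmetic and scaling laws", {
  cs <- charge_set(data.frame(x = c(0, 3.320636), y = 0, z = 0,
                              charge = c(1, -1),
                              region = c("active", "environment")))
  expect_equal(coulomb_energy(cs), -100)
  expect_equal(delta_prot(cs), -100)
  # doubling all distances halves the energy
  cs2 <- charge_set(transform(as.data.frame(cs), x = 2 * x, y = 2 * y,
                              z = 2 * z))
  expect_equal(coulomb_energy(cs2), coulomb_energy(cs) / 2)
  # coincident atoms are rejected
  bad <- charge_set(data.frame(x = c(0, 0), y = 0, z = 0, charge = 1,
                               region = "active"))
  expect_error(coulomb_energy(bad), "zero distance")
})

test_that("Coulomb evaluator matches the O(N^2) reference loop on random fixtures", {
  for (seed in 1:100) {
    cs <- gen_charge_fixture(30, seed = seed)
    expect_equal(coulomb_energy(cs), coulomb_loop(cs), tolerance = 1e-10)
  }
  # larger fixture, every pair selection
  cs <- gen_charge_fixture(50, seed = 1234)
  for (p in c("all", "active", "environment", "cross")) {
    expect_lt(abs(coulomb_energy(cs, p) - coulomb_loop(cs, p)), 1e-8)
  }
})

test_that("delta_prot decomposes into cross and environment terms", {
  cs <- gen_charge_fixture(40, seed = 77)
  expect_equal(delta_prot(cs),
               coulomb_loop(cs, "cross") + coulomb_loop(cs, "environment"),
               tolerance = 1e-10)
  expect_equal(delta_prot(cs, cross_only = TRUE), coulomb_loop(cs, "cross"),
               tolerance = 1e-10)
  expect_equal(delta_prot(cs),
               coulomb_loop(cs, "all") - coulomb_loop(cs, "active"),
               tolerance = 1e-10)
  # rigidly far-displaced environment: cross term vanishes
  far <- as.data.frame(cs)
  env <- far$region == "environment"
  far$x[env] <- far$x[env] + 1e8
  expect_lt(abs(delta_prot(charge_set(far), cross_only = TRUE)), 1e-4)
  # active-only set has no protein contribution
  act <- charge_set(as.data.frame(cs)[!env, ])
  expect_equal(delta_prot(act), 0)
})

test_that("PQR round trip preserves coordinates, charges and regions", {
  path <- tempfile(fileext = ".pqr")
  writeLines(c(
    "ATOM      1  N   ASP A  274      10.000  -1.500   2.250 -0.5163 1.8240",
    "ATOM      2  CA  ASP A  274      11.104  -0.750   2.850  0.0381 1.9080",
    "ATOM      3  MG  PCH B    1       4.000   5.000   6.000  0.8000 1.4500",
    "HETATM    4  O   HOH     17       0.500   0.250   9.000 -0.8340 1.6612"),
    path)
  cs <- read_pqr(path, active_residues = c("PCH", "ASP"))
  expect_equal(nrow(cs), 4)
  expect_equal(cs$region, c("active", "active", "active", "environment"))
  expect_equal(cs$charge, c(-0.5163, 0.0381, 0.8, -0.834))
  expect_equal(cs$x, c(10, 11.104, 4, 0.5))
  expect_error(suppressWarnings(read_pqr(tempfile())),
               "cannot open|No such|no ATOM")
})

test_that("microstate step energies are additive in site contributions", {
  tab <- site_contribution_table(
    matrix(c(-5, 2, 1.5, 0.5, -1, 3), nrow = 3,
           dimnames = list(c("s1", "s2", "s3"), c("step1", "step2"))))
  expect_equal(microstate_step_energy(tab, "step1", c(0, 0, 0), 2), 2)
  expect_equal(microstate_step_energy(tab, "step1", c(1, 0, 0), 2), -3)
  # additivity over disjoint occupations
  e0 <- microstate_step_energy(tab, "step2", c(0, 0, 0))
  e1 <- microstate_step_energy(tab, "step2", c(1, 0, 0))
  e2 <- microstate_step_energy(tab, "step2", c(0, 1, 1))
  e12 <- microstate_step_energy(tab, "step2", c(1, 1, 1))
  expect_equal(e12 - e0, (e1 - e0) + (e2 - e0))
  expect_error(microstate_step_energy(tab, "nope", c(0, 0, 0)), "unknown step")
  expect_error(microstate_step_energy(tab, "step1", c(1, 0)), "length")
})

test_that("Boltzmann-averaged correction handles degenerate ensembles and bounds", {
  tab <- site_contribution_table(
    matrix(c(-30, 12), 2, 1, dimnames = list(c("a", "b"), "step")))
  # single certain microstate returns its energy exactly
  pop <- microstate_population(list(list(
    sites = c("a", "b"), states = rbind(c(1, 0)), probs = 1)))
  expect_equal(boltzmann_average_correction(tab, "step", pop), -30)
  # equal energies average to themselves
  pop0 <- microstate_population(list(list(
    sites = c("a", "b"), states = rbind(c(0, 0), c(0, 0) * 0), probs = c(0.5, 0.5))))
  expect_equal(boltzmann_average_correction(tab, "step", pop0), 0)
  # [min, max] bound on random populations, including spans of tens of
  # kcal/mol that would overflow naive exponentials
  set.seed(21)
  for (i in 1:20) {
    n <- 6
    popi <- gen_population(n, seed = i, correlation = runif(1, 0, 0.8))
    contrib <- matrix(runif(n, -60, 60), n, 1,
                      dimnames = list(popi$sites, "step"))
    tabi <- site_contribution_table(contrib)
    full <- microstate_population(list(list(
      sites = popi$sites, states = popi$states, probs = popi$probs)))
    avg <- boltzmann_average_correction(tabi, "step", full)
    de <- drop(popi$states %*% contrib[popi$sites, 1])
    expect_gte(avg, min(de) - 1e-9)
    expect_lte(avg, max(de) + 1e-9)
    # and agreement with the direct (non-log-sum-exp) reference at the
    # scales it can evaluate
    expect_equal(avg, boltzmann_direct(contrib[popi$sites, 1], popi$states,
                                       popi$probs), tolerance = 1e-9)
  }
  expect_error(boltzmann_average_correction(tab, "step",
    microstate_population(list(list(sites = "a", states = rbind(0, 1),
                                    probs = c(0.5, 0.5))))),
    "partition")
})

test_that("group factorization is exact for product-form populations", {
  pop <- gen_population(12, seed = 33, correlation = 0)
  contrib <- matrix(runif(12, -20, 20), 12, 1,
                    dimnames = list(pop$sites, "step"))
  tab <- site_contribution_table(contrib)
  full <- microstate_population(list(list(
    sites = pop$sites, states = pop$states, probs = pop$probs)))
  halves <- population_marginals(pop, list(pop$sites[1:6], pop$sites[7:12]))
  thirds <- population_marginals(pop, list(pop$sites[1:4], pop$sites[5:8],
                                           pop$sites[9:12]))
  e_full <- boltzmann_average_correction(tab, "step", full)
  expect_equal(boltzmann_average_correction(tab, "step", halves), e_full,
               tolerance = 1e-9)
  expect_equal(boltzmann_average_correction(tab, "step", thirds), e_full,
               tolerance = 1e-9)
  # invariance under site and group relabeling
  perm <- c(7:12, 1:6)
  perm_groups <- population_marginals(pop, list(pop$sites[perm[1:6]],
                                                pop$sites[perm[7:12]]))
  expect_equal(boltzmann_average_correction(tab, "step", perm_groups), e_full,
               tolerance = 1e-9)
})

test_that("factorization error grows with injected inter-group correlation", {
  errs <- vapply(c(0.15, 0.45, 0.85), function(strength) {
    pop <- gen_population(10, seed = 55, correlation = strength)
    contrib <- matrix(seq(-12, 15, length.out = 10), 10, 1,
                      dimnames = list(pop$sites, "step"))
    tab <- site_contribution_table(contrib)
    full <- microstate_population(list(list(
      sites = pop$sites, states = pop$states, probs = pop$probs)))
    split2 <- population_marginals(pop, list(pop$sites[1:5], pop$sites[6:10]))
    abs(boltzmann_average_correction(tab, "step", split2) -
          boltzmann_average_correction(tab, "step", full))
  }, numeric(1))
  expect_true(all(diff(errs) > 0))
  expect_gt(errs[1], 0)
})

test_that("correlation-guided grouping recovers separable blocks", {
  # two independent blocks: exact recovery
  corr <- diag(6)
  corr[1:3, 1:3] <- 0.6; corr[4:6, 4:6] <- 0.7; diag(corr) <- 1
  dimnames(corr) <- list(letters[1:6], letters[1:6])
  res <- group_sites(corr, max_group_size = 3)
  groups <- lapply(res$groups, sort)
  expect_true(any(vapply(groups, identical, logical(1), c("a", "b", "c"))))
  expect_true(any(vapply(groups, identical, logical(1), c("d", "e", "f"))))
  expect_equal(res$max_neglected, 0)
  # 44 sites with a 10-site cap cannot fit in fewer than 5 groups
  set.seed(99)
  m <- matrix(runif(44 * 44, -0.5, 0.5), 44)
  m <- (m + t(m)) / 2; diag(m) <- 1
  dimnames(m) <- list(sprintf("r%02d", 1:44), sprintf("r%02d", 1:44))
  res44 <- group_sites(m, max_group_size = 10)
  expect_gte(length(res44$groups), 5)
  expect_true(all(lengths(res44$groups) <= 10))
  expect_setequal(unlist(res44$groups), rownames(m))
  # all-zero off-diagonal correlations: nothing to merge, nothing neglected
  z <- diag(4)
  dimnames(z) <- list(letters[1:4], letters[1:4])
  resz <- group_sites(z, max_group_size = 2)
  expect_equal(resz$max_neglected, 0)
  expect_equal(lengths(resz$groups), rep(1L, 4))
  expect_error(group_sites(corr, max_group_size = 0), "max_group_size")
})

test_that("effective-dielectric screening scales corrections as 1/eps", {
  expect_equal(screen_by_effective_dielectric(-12.4, 1), -12.4)
  expect_equal(screen_by_effective_dielectric(-12.4, 2), -6.2)
  expect_error(screen_by_effective_dielectric(-12.4, 0.9), ">= 1")
  # a small screening increase shifts a redox potential by
  # -dE * (1 - 1/eps) / F volts
  de <- -155
  shift <- potential_from_delta_g(
    screen_by_effective_dielectric(de, 1.06) - de, 1)
  expect_equal(shift, de * (1 - 1 / 1.06) / 23.0605, tolerance = 1e-12)
  expect_lt(shift, 0)
})
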