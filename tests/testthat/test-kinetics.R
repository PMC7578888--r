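test_that("forster_radius obeys the sixth-power scaling laws", {
  r0 <- forster_radius(0.5, 1.4, 1e14)
  expect_equal(forster_radius(0.5, 1.4, 2^6 * 1e14), 2 * r0)
  expect_equal(forster_radius(0.5, 2 * 1.4, 1e14), 2^(-2 / 3) * r0)
  expect_equal(forster_radius(2 * 0.5, 1.4, 1e14), 2^(1 / 6) * r0)
  expect_error(forster_radius(0, 1.4, 1e14), "> 0")
})

test_that("forster_radius matches the 0.211-Angstrom rule", {
  # independent anchor: R0[A] = 0.211 (kappa^2 n^-4 Q J)^(1/6), J in
  # M^-1 cm^-1 nm^4 (prefactor rounded to three digits, hence 1% slack)
  r0_rule_nm <- 0.0211 * ((2 / 3) * 1.4^-4 * 1 * 1e15)^(1 / 6)
  expect_equal(forster_radius(1, 1.4, 1e15), r0_rule_nm, tolerance = 0.01)
})

test_that("rates follow (3/2) k_d kappa^2 Delta^-6", {
  g <- build_model("D2A")
  cfg <- sample_configuration(g, 1, 1, case_spec("i"))
  sys <- build_rate_system(cfg)
  expect_equal(sys$k_da, rep(sys$k_d, 2)) # (3/2)(2/3)(1^-6) = 1
  expect_equal(sys$k_dd, t(sys$k_dd))
  expect_equal(diag(sys$k_dd), c(0, 0))

  cfg$kappa2_da <- c(0, 0)
  expect_equal(build_rate_system(cfg)$k_da, c(0, 0))

  cfg2 <- cfg
  cfg2$kappa2_da <- c(2 / 3, 2 / 3)
  cfg2$delta_da <- cfg$delta_da / 2
  expect_equal(build_rate_system(cfg2)$k_da, 64 * sys$k_da)

  cfg$delta_da[1] <- 0
  expect_error(build_rate_system(cfg), "singular rate")
})

test_that("physical-distance mode divides by the Forster radii", {
  cfg <- sample_configuration(build_model("D2A"), 1, 1, case_spec("i"))
  cfg$delta_da <- c(2.43, 2.43) # nm, equal to r0_da
  cfg$delta_dd[1, 2] <- cfg$delta_dd[2, 1] <- 1.92
  cfg$physical <- TRUE
  p <- photophysical_params(r0_da = 2.43, r0_dd = 1.92)
  sys <- build_rate_system(cfg, p)
  expect_equal(sys$k_da, rep(p$k_d, 2))
  expect_equal(sys$k_dd[1, 2], p$k_d)
  expect_error(build_rate_system(cfg, photophysical_params()), "r0_da")
})

test_that("huge rates are capped without changing the efficiency", {
  cfg <- sample_configuration(build_model("D2A"), 1, 1, case_spec("i"))
  cfg$delta_dd[1, 2] <- cfg$delta_dd[2, 1] <- 1e-6 # rate ~ 1e36 k_d uncapped
  sys <- build_rate_system(cfg)
  expect_equal(sys$k_dd[1, 2], 1e9 * sys$k_d)
  phi <- absorption_probability(sys)
  expect_true(all(is.finite(phi)))
  # the two donors are a fused pair: identical efficiencies
  expect_equal(phi[1], phi[2], tolerance = 1e-6)
})

test_that("single-pair efficiency has the closed Forster form", {
  g <- build_model("D1A")
  for (delta in c(0.5, 1, 1.5)) {
    cfg <- sample_configuration(g, delta, 1, case_spec("i"))
    phi <- absorption_probability(build_rate_system(cfg))
    expect_equal(phi, 1 / (1 + delta^6), tolerance = 1e-12)
  }
})

test_that("case-(i) symmetric models reduce to the single-pair efficiency", {
  # homo-transfer cancels in the total donor population: Phi must not
  # depend on delta_dd or on the number of donors
  for (nm in c("D4A", "D12A", "D20A")) {
    g <- build_model(nm)
    for (ddd in c(0.2, 1, 2)) {
      cfg <- sample_configuration(g, 0.9, ddd, case_spec("i"))
      phi <- absorption_probability(build_rate_system(cfg))
      expect_equal(phi, rep(1 / (1 + 0.9^6), g$n_donors), tolerance = 1e-10)
    }
  }
})

test_that("first-passage solve agrees with time integration", {
  set.seed(51)
  for (rep in 1:5) {
    n <- sample(2:6, 1)
    sys <- random_rate_system(n)
    i <- sample(n, 1)
    expect_equal(absorption_probability(sys, i),
                 phi_by_integration(sys, i), tolerance = 1e-6)
  }
})

test_that("efficiency is invariant under global rate rescaling", {
  set.seed(52)
  sys <- random_rate_system(5)
  phi <- absorption_probability(sys)
  for (f in c(1e-6, 1e3)) {
    scaled <- sys
    scaled$k_da <- f * sys$k_da
    scaled$k_dd <- f * sys$k_dd
    scaled$k_d <- f * sys$k_d
    expect_equal(absorption_probability(scaled), phi, tolerance = 1e-10)
  }
})

test_that("efficiency is monotone in the direct transfer rates", {
  set.seed(53)
  sys <- random_rate_system(4)
  phi0 <- absorption_probability(sys)
  up <- sys
  up$k_da <- sys$k_da * 1.5
  expect_true(all(absorption_probability(up) > phi0))
})

test_that("time courses behave physically", {
  # no transfer: pure exponential donor decay, nothing captured
  sys0 <- structure(list(k_da = 0, k_dd = matrix(0, 1, 1), k_d = 0.002,
                         k_a = 0, n_donors = 1L), class = "rate_system")
  tc <- integrate_populations(sys0, 1, horizon = 2000, n_times = 101)
  expect_equal(tc$D1, exp(-0.002 * tc$time), tolerance = 1e-8)
  expect_equal(tc$A, rep(0, 101))

  set.seed(54)
  sys <- random_rate_system(3)
  tc <- integrate_populations(sys, 2, horizon = 30, n_times = 301)
  pops <- as.matrix(tc[, c("D1", "D2", "D3", "A", "ground")])
  expect_true(all(pops > -1e-10))
  expect_equal(rowSums(pops), rep(1, 301), tolerance = 1e-8)
})

test_that("acceptor decay is supported by the integration path only", {
  set.seed(55)
  sys <- random_rate_system(2)
  sys$k_a <- 0.5
  expect_error(absorption_probability(sys), "k_a = 0")
  tc <- integrate_populations(sys, 1, horizon = 100, n_times = 501)
  # captured flux still converges to the k_a = 0 absorption probability
  ka0 <- sys
  ka0$k_a <- 0
  expect_equal(tc$captured[nrow(tc)], absorption_probability(ka0, 1),
               tolerance = 1e-6)
  # but the excited acceptor population has decayed below it
  expect_lt(tc$A[nrow(tc)], tc$captured[nrow(tc)])
})
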