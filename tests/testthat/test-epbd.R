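test_that("Morse term matches its closed form and limits", {
  # equilibrium: zero energy iff u = v
  expect_equal(morse_energy(0.3, 0.3, 0.05, 4.2), 0)
  expect_gt(morse_energy(0.3, 0.1, 0.05, 4.2), 0)
  # dissociation plateau -> D
  expect_equal(morse_energy(100, 0, 0.05, 4.2), 0.05, tolerance = 1e-12)
  # frozen scalar: D (exp(-a*y) - 1)^2 at D=0.05, a=4.2, y=0.5
  expect_equal(morse_energy(0.5, 0, 0.05, 4.2),
               0.05 * (exp(-2.1) - 1)^2, tolerance = 1e-15)
  expect_equal(morse_energy(0.5, 0, 0.05, 4.2), 0.038504,
               tolerance = 1e-5)
})

test_that("stacking term reduces to the hand-computed harmonic form", {
  # no relative displacement -> zero
  expect_equal(stacking_energy(0.4, 0.4, -0.2, -0.2, 0.025, 0.025), 0)
  # rho = 0: the two quadratic strand terms only
  w <- stacking_energy(0.1, 0.5, 0.0, -0.3, 0.02, 0.03, rho = 0)
  expect_equal(w, 0.5 * 0.02 * 0.4^2 + 0.5 * 0.03 * 0.3^2, tolerance = 1e-15)
  # strand exchange symmetry of the harmonic part when K_u = K_v
  w1 <- stacking_energy(0.1, 0.5, 0.0, -0.3, 0.025, 0.025, rho = 0)
  w2 <- stacking_energy(0.0, -0.3, 0.1, 0.5, 0.025, 0.025, rho = 0)
  expect_equal(w1, w2, tolerance = 1e-15)
  # full anharmonic value against direct arithmetic
  u <- c(0.1, 0.5); v <- c(0.0, -0.3)
  q <- sqrt(0.025) * 0.4 - sqrt(0.025) * (-0.3)
  expect_equal(stacking_energy(u[1], u[2], v[1], v[2], 0.025, 0.025,
                               rho = 2, beta_anh = 0.35),
               0.5 * 0.025 * (0.4^2 + 0.3^2) +
                 0.5 * exp(-0.35 * ((0.5 + 0.3) + 0.1)) * q^2,
               tolerance = 1e-15)
  expect_gte(stacking_energy(-1, 2, 1, -2, 0.02, 0.03), 0)
})

test_that("total potential is non-negative, local, and matches compiled code", {
  set.seed(8)
  s <- random_dna(12, 0.5)
  par <- epbd_params()
  # global equilibrium
  expect_equal(total_potential(lattice_state(rep(0, 12), rep(0, 12)), s, par),
               0)
  # single displaced site touches its Morse term and two adjacent bonds only
  u <- rep(0, 12); u[5] <- 0.4
  sp <- cyclizer:::.epbd_site_params(s, par)
  expected <- morse_energy(0.4, 0, sp$D[5], sp$a[5]) +
    stacking_energy(0, 0.4, 0, 0, sp$K_u[4], sp$K_v[4]) +
    stacking_energy(0.4, 0, 0, 0, sp$K_u[5], sp$K_v[5])
  expect_equal(total_potential(lattice_state(u, rep(0, 12)), s, par),
               expected, tolerance = 1e-14)
  # incremental-vs-full oracle: a one-site move changes the total by exactly
  # the change in the local terms
  for (i in 1:5) {
    u0 <- rnorm(12, 0, 0.3); v0 <- rnorm(12, 0, 0.3)
    st0 <- lattice_state(u0, v0)
    k <- sample(12, 1)
    u1 <- u0; u1[k] <- u1[k] + rnorm(1, 0, 0.2)
    st1 <- lattice_state(u1, v0)
    local <- function(u, v, k) {
      nb <- function(b) stacking_energy(u[b], u[b %% 12 + 1], v[b],
                                        v[b %% 12 + 1], sp$K_u[b], sp$K_v[b])
      morse_energy(u[k], v[k], sp$D[k], sp$a[k]) +
        nb((k - 2) %% 12 + 1) + nb(k)
    }
    expect_equal(total_potential(st1, s, par) - total_potential(st0, s, par),
                 local(u1, v0, k) - local(u0, v0, k), tolerance = 1e-8)
    # R reference equals compiled implementation
    expect_equal(total_potential(st0, s, par),
                 cyclizer:::cpp_total_potential(u0, v0, sp$D, sp$a, sp$K_u,
                                                sp$K_v, par$rho, par$beta_anh,
                                                TRUE),
                 tolerance = 1e-12)
    expect_gte(total_potential(st0, s, par), 0)
  }
})

test_that("acceptance rule satisfies the detailed-balance ratio", {
  # min(1, e^-x) / min(1, e^x) = e^-x for any energy difference x
  acc <- function(dV, kT) min(1, exp(-dV / kT))
  kT <- 0.0259
  for (dV in c(-0.1, -0.01, 0, 0.005, 0.08)) {
    expect_equal(acc(dV, kT) / acc(-dV, kT), exp(-dV / kT),
                 tolerance = 1e-12)
  }
})

test_that("near-zero temperature sweeps only move downhill", {
  s <- poly_seq("A", 8)
  st <- lattice_state(rnorm(8, 0, 0.5), rnorm(8, 0, 0.5))
  v0 <- total_potential(st, s)
  cold <- mcmc_settings(temperature = 1e-6, y_max = 5)
  out <- metropolis_sweeps(st, s, settings = cold, n_sweeps = 50, seed = 3)
  expect_lt(total_potential(out, s), v0)
})

test_that("opening profiles are deterministic given the seed", {
  s <- random_dna(15, 0.5)
  p1 <- sample_opening_profile(s, settings = fast_epbd_settings(), seed = 99)
  p2 <- sample_opening_profile(s, settings = fast_epbd_settings(), seed = 99)
  expect_identical(p1$p, p2$p)
  expect_equal(p1$source, "epbd_mcmc")
})

test_that("an unreachable opening threshold gives an all-zero profile", {
  s <- random_dna(10, 0.5)
  p <- sample_opening_profile(
    s, settings = mcmc_settings(n_equil = 200, n_sweeps = 1000, thin = 2,
                                threshold = 999, y_max = 1000), seed = 1)
  expect_true(all(p$p == 0))
})

test_that("opening probability decreases with base-pair binding strength", {
  # paired runs with shared seed at elevated temperature: deeper Morse wells
  # (scaled D) must open less, and poly(AT) opens at least as much as
  # poly(GC) site by site
  st <- fast_epbd_settings(temperature = 400, n_sweeps = 16000)
  sAT <- poly_seq("A", 12)
  sGC <- poly_seq("G", 12)
  # the acceptance-rate diagnostic fires at this temperature; irrelevant here
  pAT <- suppressWarnings(sample_opening_profile(sAT, settings = st,
                                                 seed = 17))
  pGC <- suppressWarnings(sample_opening_profile(sGC, settings = st,
                                                 seed = 17))
  expect_gt(mean(pAT$p), 0)            # openings actually occur
  expect_true(all(pAT$p >= pGC$p))

  strong <- epbd_params(D = c(AT = 0.1, GC = 0.15))
  p_strong <- suppressWarnings(sample_opening_profile(sAT, params = strong,
                                                      settings = st,
                                                      seed = 17))
  expect_lt(mean(p_strong$p), mean(pAT$p))
})

test_that("mismatch positions are forced to probability one", {
  prof <- opening_profile(c(0.1, 0.2, 0.3))
  out <- set_mismatch(prof, 2)
  expect_equal(out$p, c(0.1, 1.0, 0.3))
  expect_identical(set_mismatch(out, 2)$p, out$p)  # idempotent
  expect_error(set_mismatch(prof, 4), "outside|\\[1, 3\\]")

  # via the sampler: a central mismatch is exactly 1 in the stored profile
  s <- dna_seq(fifty_bp, id = "mm", mismatch = 25L)
  p <- sample_opening_profile(s, settings = fast_epbd_settings(
    n_equil = 200, n_sweeps = 1000), seed = 5)
  expect_identical(p$p[25], 1.0)
})

test_that("an ill-tuned proposal width triggers the acceptance warning", {
  s <- random_dna(10, 0.5)
  expect_warning(
    sample_opening_profile(s, settings = mcmc_settings(
      n_equil = 100, n_sweeps = 500, width = 25, y_max = 5), seed = 2),
    "acceptance rate")
})
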