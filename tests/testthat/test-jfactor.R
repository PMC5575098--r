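test_that("count accumulation nests the three gates in order", {
  th <- closure_thresholds()
  one <- function(r, cg, cp) data.frame(r = r, cos_gamma = cg, cos_phi = cp)
  c1 <- accumulate_counts(one(0, 1, 1), th)
  expect_equal(unlist(unclass(c1)), c(n_total = 1, n_r = 1, n_gamma = 1,
                                      n_phi = 1))
  # fails the first gate: never counted downstream
  c2 <- accumulate_counts(one(100, 1, 1), th)
  expect_equal(unlist(unclass(c2)), c(n_total = 1, n_r = 0, n_gamma = 0,
                                      n_phi = 0))
  # passes gamma but fails r: still not counted in n_gamma
  c3 <- accumulate_counts(one(50, 0.99, 0.99), th)
  expect_equal(c3$n_gamma, 0)

  # nesting invariant and permutation invariance on random streams
  set.seed(9)
  obs <- data.frame(r = runif(500, 0, 60), cos_gamma = runif(500, -1, 1),
                    cos_phi = runif(500, -1, 1))
  cc <- accumulate_counts(obs, th)
  expect_true(cc$n_total >= cc$n_r && cc$n_r >= cc$n_gamma &&
                cc$n_gamma >= cc$n_phi)
  perm <- accumulate_counts(obs[sample(nrow(obs)), ], th)
  expect_identical(unclass(cc), unclass(perm))
  expect_error(cyclization_counts(10, 5, 6, 1), "n_total >= n_r")
})

test_that("widening any threshold never decreases the matching count", {
  set.seed(10)
  obs <- data.frame(r = runif(2000, 0, 80), cos_gamma = runif(2000, -1, 1),
                    cos_phi = runif(2000, -1, 1))
  base <- accumulate_counts(obs, closure_thresholds(30, 0.86, 0.86))
  wide_r <- accumulate_counts(obs, closure_thresholds(45, 0.86, 0.86))
  wide_g <- accumulate_counts(obs, closure_thresholds(30, 0.7, 0.86))
  wide_p <- accumulate_counts(obs, closure_thresholds(30, 0.86, 0.7))
  expect_gte(wide_r$n_r, base$n_r)
  expect_gte(wide_g$n_gamma, base$n_gamma)
  expect_gte(wide_p$n_phi, base$n_phi)
})

test_that("the W estimator recovers a known uniform density", {
  # points uniform in a ball of radius 60: density n/V(60) everywhere, so
  # the windowed estimate at any capture radius must match it
  set.seed(13)
  n <- 2e5
  R0 <- 60
  r <- R0 * runif(n)^(1 / 3)
  obs <- data.frame(r = r, cos_gamma = 1, cos_phi = 1)
  const <- physical_constants()
  rho0 <- n / ((4 / 3) * pi * R0^3 / const$angstrom3_per_liter)
  for (rc in c(20, 40)) {
    cc <- accumulate_counts(obs, closure_thresholds(r_c = rc))
    Vc <- (4 / 3) * pi * rc^3 / const$angstrom3_per_liter
    W_hat <- cc$n_r / Vc
    p <- (rc / R0)^3
    se <- sqrt(n * p * (1 - p)) / Vc
    expect_lt(abs(W_hat - rho0), 3 * se)
  }
  # doubling r_c changes the enclosed count consistently with the volume
  c20 <- accumulate_counts(obs, closure_thresholds(r_c = 20))
  c40 <- accumulate_counts(obs, closure_thresholds(r_c = 40))
  expect_equal(c40$n_r / c20$n_r, 8, tolerance = 0.1)
})

test_that("isotropic orientations give the uniform cos-gamma density 0.5", {
  set.seed(14)
  n <- 4e4
  obs <- data.frame(r = 0, cos_gamma = runif(n, -1, 1),
                    cos_phi = runif(n, -1, 1))
  cc <- accumulate_counts(obs, closure_thresholds())
  p <- cc$n_gamma / cc$n_r
  se <- sqrt(0.07 * 0.93 / n)
  expect_lt(abs(p - 0.07), 3 * se)
  Gam <- p / (1 - 0.86)
  expect_lt(abs(Gam - 0.5), 3 * se / 0.14)
})

test_that("J-factor algebra handles degenerate and nominal counts", {
  th <- closure_thresholds()
  # no fully closed chain: J = 0 with the insufficient-sampling flag
  est0 <- jfactor_from_counts(cyclization_counts(1000, 5, 2, 0), th)
  expect_equal(est0$J, 0)
  expect_true("insufficient_sampling" %in% est0$flags)
  expect_error(jfactor_from_counts(cyclization_counts(0, 0, 0, 0), th),
               "positive")

  # uniform-measure identity: with pass ratios exactly matching the uniform
  # measure on cos gamma and phi, J must reduce to W / N_A, the end
  # concentration of a fully orientation-decorrelated chain
  const <- physical_constants()
  th2 <- closure_thresholds(r_c = 30, c_gamma = 0.8, c_phi = cos(pi / 4))
  # uniform pass fractions: (1 - 0.8)/2 = 0.1 of n_r; (pi/2)/(2 pi) = 1/4
  cc <- cyclization_counts(1e6, 1000, 100, 25)
  est <- jfactor_from_counts(cc, th2)
  Vc <- (4 / 3) * pi * 30^3 / const$angstrom3_per_liter
  W <- (1000 / 1e6) / Vc
  expect_equal(est$J, W / const$avogadro, tolerance = 1e-12)
  expect_gt(est$stderr, 0)
})

test_that("counts merge across partitioned runs (merge-equivalence)", {
  tab <- synthetic_step_table()
  set.seed(15)
  s <- random_dna(40, 0.5)
  th <- closure_thresholds(r_c = 60, c_gamma = 0.3, c_phi = 0.3)
  prof <- opening_profile(rep(0.5, 40))
  e1 <- estimate_jfactor(s, tab, thresholds = th, profile = prof,
                         n_chains = 4000, seed = 1, store_max = 4000)
  e2 <- estimate_jfactor(s, tab, thresholds = th, profile = prof,
                         n_chains = 4000, seed = 2, store_max = 4000)
  merged <- combine_counts(e1$counts, e2$counts)
  pooled <- accumulate_counts(rbind(attr(e1, "observables"),
                                    attr(e2, "observables")), th)
  expect_identical(unclass(merged), unclass(pooled))
  # J from merged counts equals J from the pooled stream
  expect_equal(jfactor_from_counts(merged, th)$J,
               jfactor_from_counts(pooled, th)$J)
})

test_that("an all-zero profile reproduces the hinge-free model exactly", {
  tab <- synthetic_step_table()
  set.seed(16)
  s <- random_dna(60, 0.5)
  th <- closure_thresholds(r_c = 100, c_gamma = 0.2, c_phi = 0.2)
  a <- estimate_jfactor(s, tab, thresholds = th, profile = NULL,
                        n_chains = 5000, seed = 7)
  b <- estimate_jfactor(s, tab, thresholds = th,
                        profile = opening_profile(rep(0, 60)),
                        n_chains = 5000, seed = 7)
  expect_identical(unclass(a$counts), unclass(b$counts))
  expect_equal(a$J, b$J)
  expect_equal(a$mode, "cso")
  expect_equal(b$mode, "cso_epbd")
})

test_that("estimates are deterministic given the seed", {
  tab <- synthetic_step_table()
  set.seed(17)
  s <- random_dna(50, 0.4)
  prof <- opening_profile(runif(50, 0, 0.2))
  th <- closure_thresholds(r_c = 80, c_gamma = 0.3, c_phi = 0.3)
  a <- estimate_jfactor(s, tab, thresholds = th, profile = prof,
                        n_chains = 3000, seed = 123)
  b <- estimate_jfactor(s, tab, thresholds = th, profile = prof,
                        n_chains = 3000, seed = 123)
  expect_identical(unclass(a$counts), unclass(b$counts))
})

test_that("a fully open short chain cyclizes readily (ssDNA limit)", {
  # all-ones profile: every step uses the single-strand widths, so a 40-bp
  # chain behaves like a floppy polymer and closes at observable rates,
  # unlike its duplex counterpart
  tab <- synthetic_step_table()
  set.seed(18)
  s <- random_dna(40, 0.5)
  th <- closure_thresholds()
  ss <- estimate_jfactor(s, tab, thresholds = th,
                         profile = opening_profile(rep(1, 40)),
                         n_chains = 3e4, seed = 9)
  ds <- estimate_jfactor(s, tab, thresholds = th, profile = NULL,
                         n_chains = 3e4, seed = 9)
  expect_gt(ss$counts$n_r, 0)
  expect_gt(ss$J, ds$J)
  expect_equal(ds$counts$n_r, 0)
})

test_that("free-energy diagnostic follows the logarithm identity", {
  fe <- free_energy_equivalent(opening_profile(c(1, exp(-10))))
  expect_equal(fe$per_site, c(0, 10))
  expect_equal(fe$mean, 5)
  expect_equal(fe$n_infinite, 0)
  fe2 <- free_energy_equivalent(opening_profile(c(0, exp(-2), exp(-4))))
  expect_equal(fe2$n_infinite, 1)
  expect_equal(fe2$mean, 3)
})

test_that("profile length must match the sequence", {
  tab <- straight_step_table()
  s <- random_dna(30, 0.5)
  expect_error(estimate_jfactor(s, tab, profile = opening_profile(runif(29)),
                                n_chains = 10), "length")
})
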