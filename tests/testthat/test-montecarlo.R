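test_that("HG inverse-CDF sampling has the right limits and moments", {
  u <- seq(0, 1, by = 0.05)
  # isotropic limit
  expect_equal(sample_hg(0, u), 2 * u - 1, tolerance = 1e-14)
  # frozen snapshot against numerical CDF inversion (g = 0.9, u = 0.5)
  expect_equal(sample_hg(0.9, 0.5), 0.9855, tolerance = 1e-10)
  # empirical mean cosine within 3 standard errors of g
  set.seed(101)
  n <- 2e5
  x <- sample_hg(0.9, runif(n))
  expect_true(all(x >= -1 & x <= 1))
  se <- sd(x) / sqrt(n)
  expect_lt(abs(mean(x) - 0.9), 3 * se + 1e-4)
})

test_that("TTHG mixture selects lobes by weight and has g1 = 0.835", {
  pf <- phase_function("tthg")
  # published lobe weights 0.45/0.05 normalise to 0.9/0.1
  expect_equal(pf$weight_fwd, 0.9)
  expect_equal(pf$weight_bwd, 0.1)
  pf_paper <- phase_function("tthg", weight_fwd = 0.45, weight_bwd = 0.05)
  expect_equal(pf_paper$weight_fwd, 0.9)
  expect_equal(pf_paper$weight_normalization, 0.5)  # recorded, not silent
  expect_equal(pf_paper$g1, pf$g1)
  expect_equal(pf$g1, 0.835, tolerance = 1e-14)
  # u1 below the forward weight behaves as plain HG(0.95)
  u2 <- seq(0.05, 0.95, by = 0.1)
  expect_equal(sample_tthg(pf, rep(0.1, length(u2)), u2),
               sample_hg(0.95, u2))
  # degenerate weights reduce to a single HG lobe
  pf1 <- phase_function("tthg", weight_fwd = 1, weight_bwd = 0)
  expect_equal(sample_tthg(pf1, runif(length(u2)), u2),
               sample_hg(0.95, u2))
  # empirical mean cosine
  set.seed(202)
  n <- 2e5
  x <- sample_tthg(pf, runif(n), runif(n))
  se <- sd(x) / sqrt(n)
  expect_lt(abs(mean(x) - 0.835), 3 * se + 1e-4)
})

test_that("pencil-beam runs are reproducible and conserve weight", {
  cfg <- mc_config(ref_props(), phase_function("hg", 0.9),
                   n_photons = 5e3, bin_width = 0.01, n_bins = 5000,
                   seed = 7)
  rr1 <- run_pencil_beam(cfg)
  rr2 <- run_pencil_beam(cfg)
  expect_identical(rr1$values, rr2$values)   # same seed, bitwise equal
  cfg$seed <- 8L
  rr3 <- run_pencil_beam(cfg)
  expect_false(identical(rr1$values, rr3$values))
  # weight bookkeeping: detected + absorbed + overflow = 1 up to the
  # (unbiased) roulette fluctuation
  for (rr in list(rr1, rr3)) {
    total <- rr$detected_fraction + rr$absorbed_fraction +
      rr$overflow_fraction
    expect_lt(abs(total - 1), 1e-3)
  }
  # binned transform at f = 0 is exactly the detected fraction
  expect_equal(hankel_transform_binned(rr1, 0), rr1$detected_fraction,
               tolerance = 1e-12)
})

test_that("absorption-dominated media absorb nearly everything", {
  cfg <- mc_config(optical_properties(10, 0.5), phase_function("hg", 0.9),
                   n_photons = 2e3, bin_width = 0.01, n_bins = 1000,
                   seed = 3)
  rr <- run_pencil_beam(cfg)
  expect_gt(rr$absorbed_fraction, 0.95)
  expect_lt(rr$detected_fraction, 0.05)
})

test_that("MC total reflectance agrees with diffusion theory for a diffuse medium", {
  p <- optical_properties(0.001, 1)      # mu_s'/mu_a = 1000
  cfg <- mc_config(p, phase_function("hg", 0.9), n_photons = 5e3,
                   bin_width = 0.01, n_bins = 120000, seed = 5)
  rr <- run_pencil_beam(cfg)
  r_mc <- rr$detected_fraction + rr$overflow_fraction
  r_pcbc <- reflectance_model("pcbc", p, 0, ref_boundary())
  expect_lt(abs(r_mc - r_pcbc) / r_pcbc, 0.05)
})

test_that("similarity scaling maps profiles between similar media", {
  base <- mc_config(optical_properties(0.002, 1), phase_function("hg", 0.9),
                    n_photons = 2e4, bin_width = 0.01, n_bins = 40000,
                    seed = 9)
  rr1 <- run_pencil_beam(base)
  scaled <- scale_profile(rr1, 5)        # -> (0.01, 5) medium
  direct <- run_pencil_beam(mc_config(
    optical_properties(0.01, 5), phase_function("hg", 0.9),
    n_photons = 2e4, bin_width = 0.002, n_bins = 40000, seed = 10))
  f <- c(0, 0.2, 1)
  s1 <- hankel_transform_binned(scaled, f)
  s2 <- hankel_transform_binned(direct, f)
  expect_equal(scaled$config$props$mu_s_prime, 5)
  expect_equal(s1, s2, tolerance = 0.05)  # independent runs: MC noise only
  # detected energy is scale invariant
  expect_equal(sum(scaled$values * pi *
                     diff((seq(0, by = scaled$bin_width,
                               length.out = length(scaled$values) + 1))^2)),
               rr1$detected_fraction, tolerance = 1e-10)
})
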