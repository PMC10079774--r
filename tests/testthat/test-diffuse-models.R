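test_that("closed-form models match high-precision scalar evaluation", {
  b <- ref_boundary()
  p <- ref_props()
  # frozen oracle values for mu_a = 0.01, mu_s' = 5, f = 0, A = 2.515361
  expect_equal(reflectance_model("cuccia", p, 0, b), 0.81992682,
               tolerance = 1e-7)
  expect_equal(reflectance_model("pcbc", p, 0, b), 0.8158780,
               tolerance = 1e-6)
  expect_equal(reflectance_model("ebc", p, 0, b), 0.8204522,
               tolerance = 1e-6)
  expect_error(reflectance_model("farrell", p, 0, b), "one of")
})

test_that("all models give a' at zero attenuation and vanish at high f", {
  b <- ref_boundary()
  for (m in c("cuccia", "pcbc", "ebc")) {
    # mu_eff' = 0 limit: absorption-free medium at f = 0
    expect_equal(reflectance_model(m, optical_properties(0, 5), 0, b), 1,
                 tolerance = 1e-12, label = m)
    # f -> infinity kills every model
    expect_lt(reflectance_model(m, ref_props(), 1e4, b), 1e-4)
    # strict monotone decrease in f, values in (0, a']
    f <- c(0, 10^seq(-3, 1.5, length.out = 40))
    r <- reflectance_model(m, ref_props(), f, b)
    expect_true(all(diff(r) < 0), label = m)
    expect_true(all(r > 0), label = m)
    ap <- derive_diffusion_params(ref_props())$albedo_reduced
    expect_true(all(r <= ap + 1e-15), label = m)
  }
})

test_that("PCBC/EBC exponent equals 2 z_b mu_eff' on random media", {
  set.seed(11)
  b <- ref_boundary()
  for (i in 1:25) {
    p <- optical_properties(runif(1, 1e-4, 0.5), runif(1, 0.5, 60))
    dp <- derive_diffusion_params(p)
    f <- runif(1, 0, 5)
    zb <- 2 * b$A * dp$D
    mep <- mu_eff_prime(dp, f)
    expect_equal(2 * zb * mep, (4 * b$A / 3) * (mep / dp$mu_tr),
                 tolerance = 1e-12)
  }
})

test_that("radial Green's functions match the scalar formulas", {
  dp <- derive_diffusion_params(ref_props())
  b <- ref_boundary()
  # frozen snapshots from an independent scalar implementation
  expect_equal(radial_green("pcbc", 1, 0.2, dp, b), 4.9659343487e-02,
               tolerance = 1e-9)
  expect_equal(radial_green("ebc", 1, 0.2, dp, b), 4.1029607869e-02,
               tolerance = 1e-9)
  # zero-attenuation limit of the PCBC kernel
  dp0 <- derive_diffusion_params(optical_properties(0, 5))
  b0 <- boundary_params(1.33, 1.0, dp = dp0)
  rho <- 0.7; z0 <- 0.3
  r1 <- sqrt(z0^2 + rho^2); r2 <- sqrt((z0 + 2 * b0$z_b)^2 + rho^2)
  expect_equal(radial_green("pcbc", rho, z0, dp0, b0),
               1 / (4 * pi * 2 * b0$A * dp0$D) * (1 / r1 - 1 / r2),
               tolerance = 1e-14)
  # monotone decay in rho; -> 0 at large rho
  rg <- radial_green("ebc", c(0.5, 1, 2, 5, 20), 0.2, dp, b)
  expect_true(all(diff(rg) < 0))
  expect_lt(rg[5], 1e-6)
  expect_error(radial_green("pcbc", 0, 0, dp, b), "singular")
})

test_that("source term is a normalised exponential in depth", {
  dp <- derive_diffusion_params(ref_props())
  ap <- dp$albedo_reduced
  expect_equal(source_term(0, dp), ap * dp$mu_tr, tolerance = 1e-14)
  expect_equal(source_term(1 / dp$mu_tr, dp), ap * dp$mu_tr / exp(1),
               tolerance = 1e-14)
  total <- integrate(function(z) source_term(z, dp), 0, Inf,
                     rel.tol = 1e-10)$value
  expect_equal(total, ap, tolerance = 1e-9)
})

test_that("source-integrated radial reflectance agrees with adaptive quadrature", {
  dp <- derive_diffusion_params(ref_props())
  b <- ref_boundary()
  # frozen oracle values (adaptive quadrature at 1e-12 tolerance)
  expect_equal(radial_reflectance("pcbc", 1, dp, b), 4.6110954346e-02,
               tolerance = 1e-7)
  expect_equal(radial_reflectance("ebc", 1, dp, b), 3.8081764831e-02,
               tolerance = 1e-7)
  # monotone in rho
  rr <- radial_reflectance("pcbc", c(1, 2, 5), dp, b)
  expect_true(all(diff(rr) < 0))
  # truncation convergence: doubling z0_max changes nothing
  r1 <- radial_reflectance("pcbc", 2, dp, b, z0_max = 100)
  r2 <- radial_reflectance("pcbc", 2, dp, b, z0_max = 200)
  expect_equal(r1, r2, tolerance = 1e-6)
  # live cross-check against stats::integrate at another radius
  oracle <- integrate(function(z) {
    radial_green("ebc", 2.5, z, dp, b) * source_term(z, dp)
  }, 0, 100, rel.tol = 1e-11)$value
  expect_equal(radial_reflectance("ebc", 2.5, dp, b), oracle,
               tolerance = 1e-7)
})

test_that("continuous Hankel transform handles point masses and f = 0", {
  # unit-mass narrow Gaussian at the origin: transform approaches 1 and
  # matches the exact Gaussian transform exp(-(k sigma)^2 / 2)
  sig <- 0.002
  gauss <- function(r) exp(-r^2 / (2 * sig^2)) / (2 * pi * sig^2)
  f <- c(0, 0.5, 2)
  got <- hankel_transform_continuous(gauss, f, rho_max = 0.5)
  expect_equal(got, exp(-(2 * pi * f * sig)^2 / 2), tolerance = 1e-6)
  expect_equal(got, c(1, 1, 1), tolerance = 1e-3)
  # f = 0 equals the plain area integral
  dp <- derive_diffusion_params(ref_props())
  b <- ref_boundary()
  Rfun <- function(r) radial_reflectance("pcbc", r, dp, b)
  area <- 2 * pi * integrate(function(r) r * Rfun(r), 0, 100,
                             rel.tol = 1e-10)$value
  expect_equal(hankel_transform_continuous(Rfun, 0), area,
               tolerance = 1e-6)
})

test_that("Hankel of the Green's-function route matches the closed forms", {
  # spot equivalence at one medium (the full-grid sweep lives in the
  # acceptance suite)
  p <- ref_props()
  dp <- derive_diffusion_params(p)
  b <- ref_boundary()
  for (m in c("pcbc", "ebc")) {
    h <- hankel_transform_continuous(
      function(r) radial_reflectance(m, r, dp, b), c(0.05, 0.5, 2))
    cf <- reflectance_model(m, p, c(0.05, 0.5, 2), b)
    expect_equal(h, cf, tolerance = 1e-4, label = m)
  }
})

test_that("binned Hankel transform obeys its exact identities", {
  prof <- structure(list(bin_centers = c(0.005, 0.015, 0.025),
                         values = c(0, 0, 0), bin_width = 0.01),
                    class = "radial_reflectance_profile")
  expect_equal(hankel_transform_binned(prof, c(0, 0.5, 3)), c(0, 0, 0))
  # single unit-weight bin: one-term sum
  prof$values <- c(0, 1, 0)
  f <- 0.8
  expect_equal(hankel_transform_binned(prof, f),
               2 * pi * 0.015 * 0.01 * besselJ(2 * pi * f * 0.015, 0),
               tolerance = 1e-14)
  expect_error(hankel_transform_binned(list(bin_centers = 1), 0), "carry")
})
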