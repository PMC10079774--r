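test_that("the property grid enumerates 50 media including the corners", {
  g <- property_grid()
  expect_equal(nrow(g), 50)
  expect_equal(sum(g$phase_id == "hg"), 25)
  expect_equal(sum(g$phase_id == "tthg"), 25)
  expect_true(any(g$mu_a == 0.001 & g$mu_s_prime == 1 & g$phase_id == "hg"))
  expect_true(any(g$mu_a == 0.1 & g$mu_s_prime == 50 & g$phase_id == "tthg"))
  expect_equal(standard_phase("hg")$g1, 0.9)
  expect_equal(standard_phase("tthg")$g1, 0.835)
})

test_that("the frequency grid is log-spaced in mu_s'/f", {
  for (musp in c(1, 5, 50)) {
    f <- frequency_grid(musp)
    expect_length(f, 20)
    expect_equal(min(f), musp / 1000, tolerance = 1e-12)
    expect_equal(max(f), 10 * musp, tolerance = 1e-12)
    x <- musp / f
    ratios <- x[-20] / x[-1]
    expect_equal(ratios, rep((1000 / 0.1)^(1 / 19), 19), tolerance = 1e-9)
  }
  expect_equal(range(frequency_grid(1)), c(0.001, 10), tolerance = 1e-12)
})

test_that("diffusion-validity filter implements both readings", {
  dp <- derive_diffusion_params(ref_props())
  expect_true(diffusion_validity_filter(0, dp, "literal"))
  expect_true(diffusion_validity_filter(0, dp, "strict"))
  # the literal rule keeps even the highest grid frequency
  expect_true(diffusion_validity_filter(10 * 5, dp, "literal"))
  # the strict f << mu_tr reading drops f = mu_tr
  expect_false(diffusion_validity_filter(dp$mu_tr, dp, "strict"))
  expect_error(diffusion_validity_filter(1, dp, "harsh"))
})

test_that("relative error is the symmetric absolute ratio", {
  expect_equal(relative_error(0.5, 0.5), 0)
  expect_equal(relative_error(0.55, 0.5), 0.1)
  expect_equal(relative_error(0.45, 0.5), 0.1)
  expect_error(relative_error(0.5, 0), "positive")
})

test_that("a model identical to the MC source scores zero error", {
  cfg <- study_config(n_photons = 1, repeats = 1, n_freq = 4)
  boundary <- boundary_params(cfg$n_in, cfg$n_out)
  fake_source <- list(
    spectrum = function(mu_a, mu_s_prime, phase_id, f) {
      p <- optical_properties(mu_a, mu_s_prime)
      list(mean = reflectance_model("pcbc", p, f, boundary),
           se = rep(0, length(f)))
    },
    config = cfg)
  grid <- property_grid()[c(1, 30), ]
  res <- suppressMessages(
    run_reflectance_study(cfg, source = fake_source, grid = grid))
  expect_equal(res$summary$median[res$summary$model == "pcbc"], 0,
               tolerance = 1e-12)
  expect_gt(res$summary$median[res$summary$model == "cuccia"], 0)
  # paired comparison: identical record counts for the three models
  expect_equal(length(unique(res$summary$n_points)), 1L)
  expect_true(all(res$records$diffusion_valid))  # literal mode drops nothing

  ext <- suppressMessages(
    run_extraction_study(cfg, source = fake_source, grid = grid))
  pc <- ext$summary[ext$summary$model == "pcbc", ]
  expect_lt(max(pc$median), 1e-6)       # noise-free self-inversion
})

test_that("error summaries order their quartiles", {
  st <- desk_study()
  s <- st$refl$summary
  expect_true(all(s$q25 <= s$median & s$median <= s$q75))
  expect_true(all(st$refl$records$R_mc > 0))
  # summaries over the identical record set for all models
  expect_equal(length(unique(s$n_points)), 1L)
  # deterministic given the seed list: re-running two media of the same
  # study config reproduces identical MC spectra
  cfg <- st$cfg
  src2 <- mc_reflectance_source(cfg)
  g <- property_grid()[c(3, 40), ]
  again <- suppressMessages(run_reflectance_study(cfg, source = src2,
                                                  grid = g))
  sub <- st$refl$records
  sub <- sub[paste(sub$mu_a, sub$mu_s_prime, sub$phase_id) %in%
               paste(g$mu_a, g$mu_s_prime, g$phase_id), ]
  expect_equal(again$records$R_mc, sub$R_mc, tolerance = 1e-12)
})
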