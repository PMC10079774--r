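# Shared fixtures: a reference medium, boundary, and a memoised
# desk-scale Monte Carlo study reused by the evaluation and acceptance
# tests (the simulations dominate the suite's runtime, so they are run
# once per session).

ref_props <- function() optical_properties(mu_a = 0.01, mu_s_prime = 5)
ref_boundary <- function() boundary_params(1.33, 1.00)

.study_store <- new.env(parent = emptyenv())

desk_study_config <- function() {
  study_config(n_photons = 5e3, repeats = 3L,
               bin_width = 0.01, n_bins = 120000L, seed = 42L)
}

# Desk-scale study shared by the model-vs-MC tests: one canonical
# simulation per distinct (mu_a/mu_s', phase) ratio, three repeats.
desk_study <- function() {
  if (is.null(.study_store$study)) {
    cfg <- desk_study_config()
    src <- mc_reflectance_source(cfg)
    refl <- suppressMessages(run_reflectance_study(cfg, source = src))
    ext <- suppressMessages(run_extraction_study(cfg, source = src))
    .study_store$study <- list(refl = refl, ext = ext, cfg = cfg)
  }
  .study_store$study
}
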