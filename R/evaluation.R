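#' The validation property grid
#'
#' All combinations of mu_a in \{0.001, 0.005, 0.01, 0.05, 0.1\} mm^-1,
#' mu_s' in \{1, 5, 10, 20, 50\} mm^-1, and two phase functions (HG with
#' g = 0.9 and the default TTHG with g1 = 0.835): 50 media in total.
#'
#' @return A data frame with columns `mu_a`, `mu_s_prime`, `phase_id`.
#' @export
property_grid <- function() {
  g <- expand.grid(mu_a = c(0.001, 0.005, 0.01, 0.05, 0.1),
                   mu_s_prime = c(1, 5, 10, 20, 50),
                   phase_id = c("hg", "tthg"),
                   stringsAsFactors = FALSE)
  g[order(g$phase_id, g$mu_s_prime, g$mu_a), , drop = FALSE]
}

#' Standard phase function by grid identifier
#'
#' @param phase_id `"hg"` (Henyey-Greenstein, g = 0.9) or `"tthg"` (the
#'   default two-term mixture, g1 = 0.835).
#' @return A [phase_function()].
#' @export
standard_phase <- function(phase_id) {
  switch(phase_id,
         hg = phase_function("hg", g = 0.9),
         tthg = phase_function("tthg"),
         stop("unknown phase_id: ", phase_id, call. = FALSE))
}

#' Spatial-frequency grid for one medium
#'
#' 20 frequencies such that the dimensionless ratio mu_s'/f spans 0.1 to
#' 1000 in equal steps on a log scale; the grid therefore covers deep
#' subdiffuse (mu_s'/f = 0.1) through fully diffuse (mu_s'/f = 1000)
#' conditions for every medium.
#'
#' @param mu_s_prime Reduced scattering coefficient (mm^-1).
#' @param n Number of frequencies (default 20).
#' @return Ascending spatial frequencies (mm^-1).
#' @export
frequency_grid <- function(mu_s_prime, n = 20L) {
  stopifnot(mu_s_prime > 0)
  x <- 10^seq(log10(1000), log10(0.1), length.out = n)  # mu_s'/f, descending
  mu_s_prime / x
}

#' Diffusion-validity filter for a (frequency, medium) pair
#'
#' Diffusion theory requires f << mu_tr.  The published exclusion rule,
#' read literally, drops simulations with f > 15 mu_tr — which excludes
#' nothing on the study grid (max f = 10 mu_s' < 15 mu_tr).  A strict
#' reading consistent with f << mu_tr drops f > mu_tr / 15.  Both are
#' implemented; results under each mode are reported rather than guessing
#' which one the published medians used.
#'
#' @param f Spatial frequency (mm^-1), vectorised.
#' @param dp A [derive_diffusion_params()] object.
#' @param mode `"literal"` (default) or `"strict"`.
#' @return Logical: `TRUE` where the point passes the filter.
#' @export
diffusion_validity_filter <- function(f, dp, mode = c("literal", "strict")) {
  mode <- match.arg(mode)
  stopifnot(inherits(dp, "diffusion_params"))
  if (mode == "literal") f <= 15 * dp$mu_tr else f <= dp$mu_tr / 15
}

#' Relative error of a model reflectance against Monte Carlo
#'
#' RE = |R_model - R_mc| / R_mc, the study's accuracy metric.
#'
#' @param R_model Model reflectance (vectorised).
#' @param R_mc Monte Carlo reflectance (> 0).
#' @return Non-negative relative error.
#' @export
relative_error <- function(R_model, R_mc) {
  if (any(R_mc <= 0)) stop("`R_mc` must be positive", call. = FALSE)
  abs(R_model - R_mc) / R_mc
}

#' Study configuration
#'
#' Settings for [run_reflectance_study()] and [run_extraction_study()].
#' The defaults describe a desk-scale run; a full-scale validation raises
#' `n_photons` until the repeat-to-repeat standard deviation over the mean
#' transformed reflectance falls below 1%.
#'
#' Canonical-medium geometry: simulations are run at mu_s' = 1 mm^-1 per
#' distinct (mu_a/mu_s', phase) pair and rescaled exactly to each grid
#' medium (see [scale_profile()]), so `bin_width`/`n_bins` refer to the
#' canonical scale where the transport mean free path is 1 mm.  The
#' default 0.01 mm x 1.2e5 bins reaches 1200 transport lengths, beyond
#' any grid medium's diffuse halo.
#'
#' @param n_photons Photons per simulation.
#' @param repeats Independent repeats per medium, averaged (default 3).
#' @param bin_width,n_bins Radial detector geometry (canonical scale).
#' @param n_in,n_out Refractive indices.
#' @param f_ac AC frequency for property extraction (mm^-1).
#' @param filter_mode `"literal"` or `"strict"` (see
#'   [diffusion_validity_filter()]).
#' @param dedup_scaled Reuse one canonical simulation per distinct
#'   (mu_a/mu_s', phase) via exact similarity scaling (default `TRUE`).
#' @param seed Base seed; every per-run seed derives from it.
#' @param n_freq Frequencies per medium.
#' @return An object of class `study_config`.
#' @export
study_config <- function(n_photons = 1e5, repeats = 3L,
                         bin_width = 0.01, n_bins = 1.2e5,
                         n_in = 1.33, n_out = 1.00,
                         f_ac = 0.5,
                         filter_mode = c("literal", "strict"),
                         dedup_scaled = TRUE,
                         seed = 1L, n_freq = 20L) {
  filter_mode <- match.arg(filter_mode)
  structure(list(n_photons = n_photons, repeats = as.integer(repeats),
                 bin_width = bin_width, n_bins = as.integer(n_bins),
                 n_in = n_in, n_out = n_out, f_ac = f_ac,
                 filter_mode = filter_mode,
                 dedup_scaled = isTRUE(dedup_scaled),
                 seed = as.integer(seed), n_freq = as.integer(n_freq)),
            class = "study_config")
}

# Deterministic per-run seed derived from the base seed and a run index.
derive_seed <- function(base, index) {
  as.integer((as.numeric(base) * 48271 + index * 7919) %% 2147483629)
}

# Order-independent integer hash of a cache key (djb2), so per-run seeds
# depend only on (base seed, medium, phase, repeat) -- never on the order
# in which media were requested.
key_hash <- function(key) {
  h <- 5381
  for (v in utf8ToInt(key)) h <- (h * 33 + v) %% 2147483629
  h
}

#' Monte Carlo reflectance source for a study
#'
#' Runs (and caches) the simulations a study needs and exposes the
#' Hankel-transformed reflectance per medium.  With `dedup_scaled` the
#' cache holds one canonical mu_s' = 1 simulation per distinct
#' (mu_a/mu_s', phase) pair and serves every similar medium through the
#' exact scaling identity R_s(f) = R(f/s).
#'
#' @param cfg A [study_config()].
#' @return A list with `spectrum(mu_a, mu_s_prime, phase_id, f)` returning
#'   `list(mean, se)` (per-frequency mean over repeats and its standard
#'   error), and `profiles()` giving access to the underlying runs.
#' @export
mc_reflectance_source <- function(cfg) {
  stopifnot(inherits(cfg, "study_config"))
  cache <- new.env(parent = emptyenv())

  get_profiles <- function(mu_a, mu_s_prime, phase_id) {
    if (cfg$dedup_scaled) {
      ratio <- mu_a / mu_s_prime
      key <- sprintf("%s|%.10g", phase_id, ratio)
      sim_props <- optical_properties(ratio, 1)
    } else {
      key <- sprintf("%s|%.10g|%.10g", phase_id, mu_a, mu_s_prime)
      sim_props <- optical_properties(mu_a, mu_s_prime)
    }
    if (is.null(cache[[key]])) {
      h <- key_hash(key)
      cache[[key]] <- lapply(seq_len(cfg$repeats), function(i) {
        run_pencil_beam(mc_config(
          props = sim_props, phase = standard_phase(phase_id),
          n_in = cfg$n_in, n_out = cfg$n_out,
          n_photons = cfg$n_photons,
          bin_width = cfg$bin_width, n_bins = cfg$n_bins,
          seed = derive_seed(cfg$seed, h * 131 + i)))
      })
    }
    cache[[key]]
  }

  spectrum <- function(mu_a, mu_s_prime, phase_id, f) {
    profs <- get_profiles(mu_a, mu_s_prime, phase_id)
    f_eval <- if (cfg$dedup_scaled) f / mu_s_prime else f
    per_rep <- vapply(profs, function(p) hankel_transform_binned(p, f_eval),
                      numeric(length(f)))
    per_rep <- matrix(per_rep, nrow = length(f))
    m <- rowMeans(per_rep)
    se <- if (cfg$repeats > 1L) {
      apply(per_rep, 1L, stats::sd) / sqrt(cfg$repeats)
    } else {
      rep(NA_real_, length(f))
    }
    list(mean = m, se = se)
  }

  list(spectrum = spectrum,
       profiles = function(mu_a, mu_s_prime, phase_id)
         get_profiles(mu_a, mu_s_prime, phase_id),
       config = cfg)
}

#' Score the three models against Monte Carlo across the property grid
#'
#' For every grid medium: simulate (or reuse) the pencil-beam profile,
#' Hankel-transform it at that medium's frequency grid, evaluate the
#' Cuccia, PCBC and EBC closed forms, and record the relative error of
#' each.  Frequencies failing the diffusion-validity filter are flagged
#' and excluded from the summary medians.
#'
#' @param cfg A [study_config()].
#' @param source Optionally a pre-built [mc_reflectance_source()] (reused
#'   across studies); defaults to a fresh one.
#' @param grid Property grid (default [property_grid()]).
#' @return A list with `records` (one row per medium x frequency;
#'   evaluation records) and `summary` (per-model median/quartiles of the
#'   relative error over valid records).
#' @export
run_reflectance_study <- function(cfg = study_config(), source = NULL,
                                  grid = property_grid()) {
  stopifnot(inherits(cfg, "study_config"))
  if (is.null(source)) source <- mc_reflectance_source(cfg)
  boundary <- boundary_params(cfg$n_in, cfg$n_out)
  if (cfg$filter_mode == "literal")
    message("validity filter mode 'literal' (f > 15 mu_tr): excludes no ",
            "grid point; use mode 'strict' for the f << mu_tr reading")
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    mu_a <- grid$mu_a[i]; musp <- grid$mu_s_prime[i]
    phase_id <- grid$phase_id[i]
    props <- optical_properties(mu_a, musp)
    dp <- derive_diffusion_params(props)
    f <- frequency_grid(musp, cfg$n_freq)
    mc <- source$spectrum(mu_a, musp, phase_id, f)
    data.frame(
      mu_a = mu_a, mu_s_prime = musp, phase_id = phase_id, f = f,
      R_mc = mc$mean, R_mc_se = mc$se,
      R_cuccia = reflectance_model("cuccia", props, f, boundary),
      R_pcbc = reflectance_model("pcbc", props, f, boundary),
      R_ebc = reflectance_model("ebc", props, f, boundary),
      diffusion_valid = diffusion_validity_filter(f, dp, cfg$filter_mode),
      stringsAsFactors = FALSE)
  })
  records <- do.call(rbind, rows)
  usable <- records$R_mc > 0
  for (m in c("cuccia", "pcbc", "ebc")) {
    records[[paste0("rel_err_", m)]] <- NA_real_
    records[[paste0("rel_err_", m)]][usable] <-
      relative_error(records[[paste0("R_", m)]][usable],
                     records$R_mc[usable])
  }
  list(records = records,
       summary = summarize_errors(records),
       config = cfg)
}

#' Median and interquartile summary of model errors
#'
#' @param records Evaluation records from [run_reflectance_study()].
#' @param valid_only Summarise only records passing the diffusion-validity
#'   filter (default), over the identical record set for all three models.
#' @return A data frame with one row per model: `median`, `q25`, `q75`,
#'   `n_points`.
#' @export
summarize_errors <- function(records, valid_only = TRUE) {
  keep <- records$R_mc > 0 & !is.na(records$rel_err_cuccia)
  if (valid_only) keep <- keep & records$diffusion_valid
  do.call(rbind, lapply(c("cuccia", "pcbc", "ebc"), function(m) {
    e <- records[[paste0("rel_err_", m)]][keep]
    q <- stats::quantile(e, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(model = m, median = q[2], q25 = q[1], q75 = q[3],
               n_points = length(e), stringsAsFactors = FALSE)
  }))
}

#' Two-frequency property-extraction study
#'
#' For every grid medium, take the Monte Carlo reflectance at f = 0 and at
#' the AC frequency (default 0.5 mm^-1, used for every medium regardless
#' of regime), invert each closed-form model, and summarise the relative
#' errors of the recovered mu_a and mu_s' against the true grid values.
#'
#' @param cfg A [study_config()].
#' @param source Optionally a pre-built [mc_reflectance_source()].
#' @param grid Property grid (default [property_grid()]).
#' @return A list with `records` (one row per medium x model) and
#'   `summary` (per-model, per-parameter median/quartiles).  Bounded
#'   best fits that did not reach a root (subdiffuse inputs the model
#'   cannot reproduce) are kept in the medians — they are what a user of
#'   that model would obtain — and counted in `n_not_converged`; hard
#'   failures are excluded with a message and counted in `n_failed`.
#' @export
run_extraction_study <- function(cfg = study_config(), source = NULL,
                                 grid = property_grid()) {
  stopifnot(inherits(cfg, "study_config"))
  if (is.null(source)) source <- mc_reflectance_source(cfg)
  boundary <- boundary_params(cfg$n_in, cfg$n_out)
  rows <- list()
  for (i in seq_len(nrow(grid))) {
    mu_a <- grid$mu_a[i]; musp <- grid$mu_s_prime[i]
    phase_id <- grid$phase_id[i]
    mc <- source$spectrum(mu_a, musp, phase_id, c(0, cfg$f_ac))
    for (m in c("cuccia", "pcbc", "ebc")) {
      res <- tryCatch(
        extract_properties(m, mc$mean[1], mc$mean[2], cfg$f_ac, boundary),
        error = function(e) NULL)
      rows[[length(rows) + 1L]] <- data.frame(
        mu_a = mu_a, mu_s_prime = musp, phase_id = phase_id, model = m,
        R_dc = mc$mean[1], R_ac = mc$mean[2],
        mu_a_hat = if (is.null(res)) NA_real_ else res$mu_a_hat,
        mu_s_prime_hat = if (is.null(res)) NA_real_ else res$mu_s_prime_hat,
        converged = if (is.null(res)) FALSE else res$converged,
        stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, rows)
  records$rel_err_mu_a <- abs(records$mu_a_hat - records$mu_a) /
    records$mu_a
  records$rel_err_mu_s_prime <-
    abs(records$mu_s_prime_hat - records$mu_s_prime) / records$mu_s_prime
  n_failed <- sum(is.na(records$mu_a_hat))
  n_not_converged <- sum(!records$converged & !is.na(records$mu_a_hat))
  if (n_failed > 0L)
    message(n_failed, " inversion(s) failed outright; excluded from medians")
  if (n_not_converged > 0L)
    message(n_not_converged, " inversion(s) returned a bounded best fit ",
            "without reaching a root; kept in medians")
  keep <- is.finite(records$mu_a_hat)
  summary <- do.call(rbind, lapply(c("cuccia", "pcbc", "ebc"), function(m) {
    sel <- keep & records$model == m
    do.call(rbind, lapply(c("mu_a", "mu_s_prime"), function(param) {
      e <- records[[paste0("rel_err_", param)]][sel]
      q <- stats::quantile(e, c(0.25, 0.5, 0.75), names = FALSE)
      data.frame(model = m, parameter = param, median = q[2], q25 = q[1],
                 q75 = q[3], n_points = length(e), stringsAsFactors = FALSE)
    }))
  }))
  list(records = records, summary = summary, n_failed = n_failed,
       n_not_converged = n_not_converged, config = cfg)
}
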