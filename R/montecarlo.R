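#' Single-scattering phase function (HG or two-term HG)
#'
#' Describes the angular probability density of single-scattering
#' deflection.  `"hg"` is the one-parameter Henyey-Greenstein function with
#' anisotropy `g`; `"tthg"` is a normalized two-term mixture of a forward
#' and a backward HG lobe, the form that best describes most published
#' tissue phase-function measurements.  The default TTHG parameters are the
#' forward/backward pair (g = 0.95 / g = -0.2) mixed 0.9/0.1, giving a mean
#' cosine g1 = 0.835.  Mixture weights are normalized to sum to one; the
#' normalization applied is recorded in the returned object.
#'
#' @param kind `"hg"` or `"tthg"`.
#' @param g Anisotropy for `"hg"` (|g| < 1).
#' @param weight_fwd,g_fwd Forward-lobe weight and anisotropy for `"tthg"`.
#' @param weight_bwd,g_bwd Backward-lobe weight and anisotropy.
#' @return An object of class `phase_function` with a `g1` field (mean
#'   cosine).
#' @examples
#' phase_function("hg", g = 0.9)
#' phase_function("tthg")                    # g1 = 0.835
#' phase_function("tthg", weight_fwd = 0.45, weight_bwd = 0.05)  # same
#' @export
phase_function <- function(kind = c("hg", "tthg"), g = 0.9,
                           weight_fwd = 0.9, g_fwd = 0.95,
                           weight_bwd = 0.1, g_bwd = -0.2) {
  kind <- match.arg(kind)
  if (kind == "hg") {
    stopifnot(abs(g) < 1)
    out <- list(kind = "hg", g = g, g1 = g)
  } else {
    stopifnot(weight_fwd > 0, weight_bwd >= 0, abs(g_fwd) < 1, abs(g_bwd) < 1)
    total <- weight_fwd + weight_bwd
    out <- list(kind = "tthg",
                weight_fwd = weight_fwd / total,
                g_fwd = g_fwd,
                weight_bwd = weight_bwd / total,
                g_bwd = g_bwd,
                weight_normalization = total)
    out$g1 <- out$weight_fwd * g_fwd + out$weight_bwd * g_bwd
  }
  stopifnot(abs(out$g1) < 1)
  structure(out, class = "phase_function")
}

#' @export
print.phase_function <- function(x, ...) {
  if (x$kind == "hg") {
    cat(sprintf("<phase_function> HG, g = %g\n", x$g))
  } else {
    cat(sprintf("<phase_function> TTHG, %.3g*HG(%g) + %.3g*HG(%g), g1 = %g\n",
                x$weight_fwd, x$g_fwd, x$weight_bwd, x$g_bwd, x$g1))
  }
  invisible(x)
}

#' Sample a Henyey-Greenstein deflection cosine by inverse CDF
#'
#' Closed-form inverse of the HG cumulative distribution; for g = 0 this is
#' the isotropic cos(theta) = 2u - 1.
#'
#' @param g Anisotropy, |g| < 1.
#' @param u Uniform(0,1) variate(s).
#' @return Deflection cosine(s) in \[-1, 1\].
#' @export
sample_hg <- function(g, u) {
  stopifnot(abs(g) < 1, all(u >= 0 & u <= 1))
  if (abs(g) < 1e-8) return(2 * u - 1)
  s <- (1 - g^2) / (1 - g + 2 * g * u)
  pmin(pmax((1 + g^2 - s^2) / (2 * g), -1), 1)
}

#' Sample a two-term HG deflection cosine
#'
#' Picks the forward or backward lobe with its mixture probability (via
#' `u1`) and then samples that lobe's HG distribution (via `u2`).
#'
#' @param pf A TTHG [phase_function()].
#' @param u1,u2 Uniform(0,1) variates (same length).
#' @return Deflection cosine(s).
#' @export
sample_tthg <- function(pf, u1, u2) {
  stopifnot(inherits(pf, "phase_function"), pf$kind == "tthg")
  ifelse(u1 < pf$weight_fwd, sample_hg(pf$g_fwd, u2), sample_hg(pf$g_bwd, u2))
}

#' Monte Carlo run configuration
#'
#' Collects everything that determines one pencil-beam simulation.  The
#' default detector geometry (1-um bins out to 400 mm) matches a full-scale
#' validation run; tests and quick studies use far coarser binning.
#'
#' @param props An [optical_properties()] object.
#' @param phase A [phase_function()] object.
#' @param n_in,n_out Refractive indices (sample / external medium).
#' @param n_photons Photons to launch.
#' @param bin_width Radial bin width (mm).
#' @param n_bins Number of radial bins.
#' @param seed Integer RNG seed; fully determines the output.
#' @param roulette_threshold Weight below which Russian roulette triggers.
#' @param roulette_survival Roulette survival probability.
#' @param include_specular Kept `FALSE`: photons start just inside the
#'   medium with unit weight, because the analytic models describe light
#'   already delivered into the tissue and SFDI calibration absorbs source
#'   constants.
#' @return An object of class `mc_config`.
#' @export
mc_config <- function(props, phase = phase_function("hg", 0.9),
                      n_in = 1.33, n_out = 1.00,
                      n_photons = 1e6,
                      bin_width = 0.001, n_bins = 4e5,
                      seed = 1L,
                      roulette_threshold = 1e-4,
                      roulette_survival = 0.1,
                      include_specular = FALSE) {
  stopifnot(inherits(props, "optical_properties"),
            inherits(phase, "phase_function"),
            n_photons > 0, bin_width > 0, n_bins > 0,
            roulette_threshold > 0, roulette_survival > 0,
            roulette_survival <= 1)
  if (isTRUE(include_specular))
    stop("specular reflection at entry is not modelled", call. = FALSE)
  structure(list(props = props, phase = phase,
                 n_in = n_in, n_out = n_out,
                 n_photons = as.numeric(n_photons),
                 bin_width = bin_width, n_bins = as.integer(n_bins),
                 seed = as.integer(seed),
                 roulette_threshold = roulette_threshold,
                 roulette_survival = roulette_survival,
                 include_specular = FALSE),
            class = "mc_config")
}

#' Scattering coefficient implied by mu_s' and the phase function
#'
#' mu_s = mu_s' / (1 - g1), the similarity relation: the simulation needs
#' the full scattering coefficient, while the grid specifies only the
#' reduced one.
#'
#' @param props An [optical_properties()] object.
#' @param phase A [phase_function()] object.
#' @return mu_s (mm^-1).
#' @export
mu_s_from_reduced <- function(props, phase) {
  stopifnot(inherits(props, "optical_properties"),
            inherits(phase, "phase_function"))
  props$mu_s_prime / (1 - phase$g1)
}

#' Run a pencil-beam Monte Carlo simulation
#'
#' Weighted-photon transport in a semi-infinite homogeneous medium: photons
#' launch at the origin directed into the medium with unit weight, take
#' exponential steps of mean 1/mu_t, deposit w mu_a/mu_t at each
#' interaction, scatter via the configured phase function, and on reaching
#' the surface deposit the Fresnel-transmitted part of their weight into
#' the radial bin of the exit point (regardless of exit angle) while the
#' reflected part re-enters.  Low weights undergo Russian roulette.
#'
#' @param cfg An [mc_config()] object.
#' @return An object of class `radial_reflectance_profile` with fields
#'   `bin_centers` (mm), `values` (reflectance per unit area, mm^-2,
#'   normalized per launched photon), `bin_width`, `n_photons`,
#'   `detected_fraction`, `absorbed_fraction`, `overflow_fraction`, `seed`,
#'   and the generating `config`.
#' @examples
#' \donttest{
#' cfg <- mc_config(optical_properties(0.01, 5), n_photons = 1e4,
#'                  bin_width = 0.01, n_bins = 2e3, seed = 7)
#' rr <- run_pencil_beam(cfg)
#' hankel_transform_binned(rr, c(0, 0.1, 0.5))
#' }
#' @export
run_pencil_beam <- function(cfg) {
  stopifnot(inherits(cfg, "mc_config"))
  mu_s <- mu_s_from_reduced(cfg$props, cfg$phase)
  ph <- cfg$phase
  raw <- mc_pencil_beam_cpp(
    mu_a = cfg$props$mu_a, mu_s = mu_s,
    phase_kind = if (ph$kind == "hg") 0L else 1L,
    g_hg = if (ph$kind == "hg") ph$g else 0,
    w_fwd = if (ph$kind == "tthg") ph$weight_fwd else 1,
    g_fwd = if (ph$kind == "tthg") ph$g_fwd else 0,
    g_bwd = if (ph$kind == "tthg") ph$g_bwd else 0,
    n_in = cfg$n_in, n_out = cfg$n_out,
    n_photons_d = cfg$n_photons,
    bin_width = cfg$bin_width, n_bins = cfg$n_bins,
    roulette_threshold = cfg$roulette_threshold,
    roulette_survival = cfg$roulette_survival,
    seed = cfg$seed)
  edges <- seq(0, by = cfg$bin_width, length.out = cfg$n_bins + 1L)
  area <- pi * diff(edges^2)              # exact annulus areas
  detected <- sum(raw$bin_weights) / cfg$n_photons
  structure(list(
    bin_centers = (edges[-1L] + edges[-length(edges)]) / 2,
    values = raw$bin_weights / (cfg$n_photons * area),
    bin_width = cfg$bin_width,
    n_photons = cfg$n_photons,
    detected_fraction = detected,
    absorbed_fraction = raw$absorbed / cfg$n_photons,
    overflow_fraction = raw$overflow / cfg$n_photons,
    mean_steps_per_photon = raw$total_steps / cfg$n_photons,
    seed = cfg$seed,
    config = cfg
  ), class = "radial_reflectance_profile")
}

#' @export
print.radial_reflectance_profile <- function(x, ...) {
  cat(sprintf(paste0("<radial_reflectance_profile> %d bins x %g mm, ",
                     "%g photons (seed %d)\n",
                     "  detected %.4f + absorbed %.4f + overflow %.4f",
                     " = %.4f\n"),
              length(x$values), x$bin_width, x$n_photons, x$seed,
              x$detected_fraction, x$absorbed_fraction, x$overflow_fraction,
              x$detected_fraction + x$absorbed_fraction +
                x$overflow_fraction))
  invisible(x)
}

#' Rescale a radial profile to a similar medium
#'
#' Transport in (s mu_a, s mu_s') is transport in (mu_a, mu_s') with all
#' lengths divided by s: profiles map as R_s(rho) = s^2 R(s rho), and the
#' Hankel spectrum as R_s(f) = R(f/s).  This exact similarity lets one
#' canonical simulation per (mu_a/mu_s', phase function) serve every
#' scaled medium on a property grid.
#'
#' @param rr A `radial_reflectance_profile`.
#' @param s Scale factor (> 0) multiplying both optical coefficients.
#' @return A `radial_reflectance_profile` for the scaled medium.
#' @export
scale_profile <- function(rr, s) {
  stopifnot(inherits(rr, "radial_reflectance_profile"), s > 0)
  rr$bin_centers <- rr$bin_centers / s
  rr$bin_width <- rr$bin_width / s
  rr$values <- rr$values * s^2
  if (!is.null(rr$config)) {
    rr$config$props$mu_a <- rr$config$props$mu_a * s
    rr$config$props$mu_s_prime <- rr$config$props$mu_s_prime * s
    rr$config$bin_width <- rr$config$bin_width / s
  }
  rr
}
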