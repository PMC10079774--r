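#' Optical properties of a turbid medium
#'
#' Bundle the absorption coefficient and the reduced scattering coefficient
#' that define one homogeneous medium. All coefficients are in mm^-1.
#'
#' @param mu_a Absorption coefficient (mm^-1), must be >= 0.
#' @param mu_s_prime Reduced scattering coefficient (mm^-1), must be > 0.
#' @return An object of class `optical_properties`.
#' @examples
#' optical_properties(mu_a = 0.01, mu_s_prime = 5)
#' @export
optical_properties <- function(mu_a, mu_s_prime) {
  stopifnot(is.numeric(mu_a), length(mu_a) == 1L, is.finite(mu_a),
            is.numeric(mu_s_prime), length(mu_s_prime) == 1L,
            is.finite(mu_s_prime))
  if (mu_a < 0) stop("`mu_a` must be non-negative", call. = FALSE)
  if (mu_s_prime <= 0) stop("`mu_s_prime` must be positive", call. = FALSE)
  structure(list(mu_a = mu_a, mu_s_prime = mu_s_prime),
            class = "optical_properties")
}

#' @export
print.optical_properties <- function(x, ...) {
  cat(sprintf("<optical_properties> mu_a = %g mm^-1, mu_s' = %g mm^-1\n",
              x$mu_a, x$mu_s_prime))
  invisible(x)
}

#' Derive diffusion-theory parameters from optical properties
#'
#' Computes the transport coefficient mu_tr = mu_a + mu_s', the diffusion
#' coefficient D, the effective attenuation coefficient
#' mu_eff = sqrt(mu_a / D), and the reduced albedo a' = mu_s'/mu_tr.
#'
#' Whether absorption belongs in the diffusion coefficient is a long-running
#' debate in tissue optics.  The default keeps it, D = 1/(3 (mu_s' + mu_a)),
#' which matches the convention used by the Cuccia SFDI model and therefore
#' makes the three reflectance models directly comparable;
#' `diffusion_coefficient = "mus_only"` switches to D = 1/(3 mu_s').
#'
#' @param props An [optical_properties()] object.
#' @param diffusion_coefficient Either `"mus_plus_mua"` (default) or
#'   `"mus_only"`.
#' @return An object of class `diffusion_params` with fields `D` (mm),
#'   `mu_tr` (mm^-1), `mu_eff` (mm^-1), `albedo_reduced`, and the originating
#'   `props`.
#' @examples
#' derive_diffusion_params(optical_properties(0.01, 5))
#' @export
derive_diffusion_params <- function(props,
                                    diffusion_coefficient = c("mus_plus_mua",
                                                              "mus_only")) {
  stopifnot(inherits(props, "optical_properties"))
  diffusion_coefficient <- match.arg(diffusion_coefficient)
  mu_tr <- props$mu_a + props$mu_s_prime
  D <- if (diffusion_coefficient == "mus_plus_mua") {
    1 / (3 * mu_tr)
  } else {
    1 / (3 * props$mu_s_prime)
  }
  structure(list(
    D = D,
    mu_tr = mu_tr,
    mu_eff = sqrt(props$mu_a / D),
    albedo_reduced = props$mu_s_prime / mu_tr,
    props = props,
    diffusion_coefficient = diffusion_coefficient
  ), class = "diffusion_params")
}

#' @export
print.diffusion_params <- function(x, ...) {
  cat(sprintf(paste0("<diffusion_params> D = %g mm, mu_tr = %g mm^-1, ",
                     "mu_eff = %g mm^-1, a' = %g\n"),
              x$D, x$mu_tr, x$mu_eff, x$albedo_reduced))
  invisible(x)
}

#' Spatial-frequency-generalised effective attenuation coefficient
#'
#' Under sinusoidal illumination at spatial frequency f the diffusion
#' equation keeps its form but with mu_eff replaced by
#' mu_eff' = sqrt(mu_eff^2 + k^2), k = 2 pi f.  This is the scalar through
#' which the projected pattern enters every closed-form SFDI model.
#'
#' @param dp A [derive_diffusion_params()] object.
#' @param f Spatial frequency (mm^-1), vectorised, must be >= 0.
#' @return mu_eff' (mm^-1), same length as `f`.
#' @export
mu_eff_prime <- function(dp, f) {
  stopifnot(inherits(dp, "diffusion_params"), is.numeric(f))
  if (any(f < 0)) stop("spatial frequency `f` must be non-negative",
                       call. = FALSE)
  sqrt(dp$mu_eff^2 + (2 * pi * f)^2)
}

#' Unpolarised Fresnel reflectance at an internal interface
#'
#' Average of the s- and p-polarised Fresnel reflectances for light inside a
#' medium of index `n_in` hitting the planar interface with an external
#' medium of index `n_out`, at internal incidence cosine `cos_theta`.
#' Beyond the critical angle (only possible when `n_in > n_out`) the
#' reflectance is 1 (total internal reflection).
#'
#' @param cos_theta Cosine of the internal incidence angle, in \[0, 1\];
#'   vectorised.
#' @param n_in Refractive index of the medium the light travels in.
#' @param n_out Refractive index on the far side of the interface.
#' @return Reflectance in \[0, 1\], same length as `cos_theta`.
#' @examples
#' fresnel_unpolarized(1, 1.33, 1.0)           # normal incidence, ~0.0201
#' fresnel_unpolarized(cos(50 * pi / 180), 1.33, 1.0)  # beyond critical: 1
#' @export
fresnel_unpolarized <- function(cos_theta, n_in, n_out) {
  stopifnot(is.numeric(cos_theta), n_in > 0, n_out > 0)
  if (any(cos_theta < -1e-12 | cos_theta > 1 + 1e-12))
    stop("`cos_theta` must lie in [0, 1]", call. = FALSE)
  if (isTRUE(all.equal(n_in, n_out)))   # no interface, nothing reflects
    return(rep(0, length(cos_theta)))
  ct <- pmin(pmax(cos_theta, 0), 1)
  st <- sqrt(1 - ct^2)
  sin_r <- n_in / n_out * st
  out <- rep(1, length(ct))        # total internal reflection branch
  ok <- sin_r < 1
  if (any(ok)) {
    ctr <- sqrt(1 - sin_r[ok]^2)   # cosine of the refraction angle
    a <- ct[ok]
    rs <- ((n_in * a - n_out * ctr) / (n_in * a + n_out * ctr))^2
    rp <- ((n_out * a - n_in * ctr) / (n_out * a + n_in * ctr))^2
    out[ok] <- 0.5 * (rs + rp)
  }
  out
}

# Per-session cache: A depends only on (n_in, n_out) and the quadrature is
# not free, so compute once per boundary.
.A_cache <- new.env(parent = emptyenv())

#' Internal-reflection parameter A from angular Fresnel integrals
#'
#' Numerically evaluates
#' A = (1 + 3 I2) / (1 - 2 I1) with
#' I1 = integral of R_F(cos t) cos t sin t dt and
#' I2 = integral of R_F(cos t) cos^2 t sin t dt over t in \[0, pi/2\].
#' The integration domain is split at the critical angle, where R_F has a
#' derivative discontinuity, and each half is integrated adaptively.
#'
#' @param n_in Sample refractive index.
#' @param n_out External refractive index.
#' @param rel_tol Relative tolerance passed to the adaptive quadrature.
#' @return The dimensionless parameter A >= 1 (A = 1 for matched indices).
#' @examples
#' compute_A(1.33, 1.0)  # 2.515 for the tissue/air-like mismatch
#' @export
compute_A <- function(n_in, n_out, rel_tol = 1e-10) {
  stopifnot(n_in > 0, n_out > 0)
  key <- sprintf("%.12g|%.12g", n_in, n_out)
  if (!is.null(.A_cache[[key]])) return(.A_cache[[key]])
  if (isTRUE(all.equal(n_in, n_out))) {
    .A_cache[[key]] <- 1
    return(1)
  }
  f1 <- function(th) fresnel_unpolarized(cos(th), n_in, n_out) *
    cos(th) * sin(th)
  f2 <- function(th) fresnel_unpolarized(cos(th), n_in, n_out) *
    cos(th)^2 * sin(th)
  breaks <- c(0, pi / 2)
  if (n_in > n_out) {
    breaks <- sort(c(breaks, asin(n_out / n_in)))
  }
  quad <- function(f) {
    pieces <- vapply(seq_len(length(breaks) - 1L), function(i) {
      r <- stats::integrate(f, breaks[i], breaks[i + 1L],
                            rel.tol = rel_tol, abs.tol = 1e-12,
                            subdivisions = 500L)
      if (r$message != "OK")
        stop("quadrature for A failed: ", r$message, call. = FALSE)
      r$value
    }, numeric(1))
    sum(pieces)
  }
  A <- (1 + 3 * quad(f2)) / (1 - 2 * quad(f1))
  .A_cache[[key]] <- A
  A
}

#' Boundary parameters for a refractive-index mismatched interface
#'
#' Collects the refractive indices, the internal-reflection parameter A,
#' the effective reflectance R_eff = (A - 1)/(A + 1), and (when diffusion
#' parameters are supplied) the extrapolation distance z_b = 2 A D at which
#' the extrapolated-boundary condition forces the fluence to zero.
#'
#' @param n_in Sample refractive index (default 1.33, tissue-like).
#' @param n_out External refractive index (default 1.00, air).
#' @param dp Optional [derive_diffusion_params()] object; if given, `z_b`
#'   is included.
#' @return An object of class `boundary_params` with fields `n_in`, `n_out`,
#'   `A`, `R_eff`, and optionally `z_b` (mm).
#' @examples
#' boundary_params()                       # tissue/air, A ~ 2.515
#' @export
boundary_params <- function(n_in = 1.33, n_out = 1.00, dp = NULL) {
  A <- compute_A(n_in, n_out)
  out <- list(n_in = n_in, n_out = n_out, A = A,
              R_eff = (A - 1) / (A + 1))
  if (!is.null(dp)) {
    stopifnot(inherits(dp, "diffusion_params"))
    out$z_b <- 2 * A * dp$D
  }
  structure(out, class = "boundary_params")
}

#' @export
print.boundary_params <- function(x, ...) {
  cat(sprintf("<boundary_params> n_in = %g, n_out = %g, A = %.6g, R_eff = %.6g",
              x$n_in, x$n_out, x$A, x$R_eff))
  if (!is.null(x$z_b)) cat(sprintf(", z_b = %.6g mm", x$z_b))
  cat("\n")
  invisible(x)
}
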