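#' @title Closed-form SFDI diffuse-reflectance models
#' @description
#' Evaluates one of the three closed-form models for the spatially modulated
#' diffuse reflectance of a semi-infinite turbid medium:
#'
#' * `"cuccia"` — the widely used model obtained by solving the diffusion
#'   equation for a plane-wave source,
#'   R = 3 a' / \[(2 A x + 3)(x + 1)\], with x = mu_eff'/mu_tr;
#' * `"pcbc"` — derived by radially integrating the pencil-beam Green's
#'   function under the partial-current boundary condition,
#'   R = a' (1 - exp(-e)) / \[e (1 + x)\], e = (4A/3) x;
#' * `"ebc"`  — the same route under the extrapolated boundary condition,
#'   R = (a'/2) (1 + exp(-e)) / (1 + x).
#'
#' All three reduce to the reduced albedo a' as mu_eff' -> 0 and decrease
#' strictly with spatial frequency.
#'
#' @param model One of `"cuccia"`, `"pcbc"`, `"ebc"`.
#' @param props An [optical_properties()] object.
#' @param f Spatial frequency (mm^-1), vectorised, >= 0.
#' @param boundary A [boundary_params()] object (only `A` is used).
#' @param diffusion_coefficient Passed to [derive_diffusion_params()].
#' @return Dimensionless reflectance, same length as `f`.
#' @examples
#' b <- boundary_params(1.33, 1.0)
#' p <- optical_properties(0.01, 5)
#' reflectance_model("pcbc", p, f = c(0, 0.1, 0.5), b)
#' @export
reflectance_model <- function(model, props, f, boundary,
                              diffusion_coefficient = "mus_plus_mua") {
  model <- match_model(model)
  stopifnot(inherits(props, "optical_properties"),
            inherits(boundary, "boundary_params"))
  if (any(f < 0)) stop("`f` must be non-negative", call. = FALSE)
  dp <- derive_diffusion_params(props, diffusion_coefficient)
  x <- mu_eff_prime(dp, f) / dp$mu_tr
  ap <- dp$albedo_reduced
  A <- boundary$A
  switch(model,
    cuccia = 3 * ap / ((2 * A * x + 3) * (x + 1)),
    pcbc = {
      e <- (4 * A / 3) * x
      # (1 - exp(-e))/e -> 1 as e -> 0; expm1 keeps it accurate
      frac <- ifelse(e < 1e-12, 1, -expm1(-e) / e)
      ap * frac / (1 + x)
    },
    ebc = ap / 2 * (1 + exp(-(4 * A / 3) * x)) / (1 + x)
  )
}

match_model <- function(model, allowed = c("cuccia", "pcbc", "ebc")) {
  if (!is.character(model) || length(model) != 1L ||
      !(tolower(model) %in% allowed))
    stop("`model` must be one of: ", paste(allowed, collapse = ", "),
         call. = FALSE)
  tolower(model)
}

#' Pencil-beam radial Green's functions for diffuse reflectance
#'
#' Radial diffuse reflectance per unit area at the surface, at radius `rho`
#' from an isotropic point source buried at depth `z0`, for the
#' partial-current (`"pcbc"`) or extrapolated (`"ebc"`) boundary condition.
#' With r1 = sqrt(z0^2 + rho^2) and r2 = sqrt((z0 + 2 z_b)^2 + rho^2):
#'
#' * PCBC: R = 1/(4 pi 2 A D) \[exp(-mu_eff r1)/r1 - exp(-mu_eff r2)/r2\]
#' * EBC (image-source dipole):
#'   R = 1/(4 pi) \[z0 (mu_eff + 1/r1) exp(-mu_eff r1)/r1^2 +
#'   (z0 + 2 z_b) (mu_eff + 1/r2) exp(-mu_eff r2)/r2^2\]
#'
#' @param model `"pcbc"` or `"ebc"`.
#' @param rho Radial distance (mm), vectorised, >= 0.
#' @param z0 Source depth (mm), vectorised (recycled against `rho`), > 0
#'   unless rho > 0.
#' @param dp A [derive_diffusion_params()] object.
#' @param boundary A [boundary_params()] object.
#' @return Reflectance per unit area (mm^-2).
#' @export
radial_green <- function(model, rho, z0, dp, boundary) {
  model <- match_model(model, c("pcbc", "ebc"))
  stopifnot(inherits(dp, "diffusion_params"),
            inherits(boundary, "boundary_params"))
  if (any(rho < 0)) stop("`rho` must be non-negative", call. = FALSE)
  if (any(z0 < 0)) stop("`z0` must be non-negative", call. = FALSE)
  if (any(rho == 0 & z0 == 0))
    stop("rho = z0 = 0 is a singular input", call. = FALSE)
  A <- boundary$A
  zb <- 2 * A * dp$D
  mueff <- dp$mu_eff
  r1 <- sqrt(z0^2 + rho^2)
  r2 <- sqrt((z0 + 2 * zb)^2 + rho^2)
  if (model == "pcbc") {
    1 / (4 * pi * 2 * A * dp$D) *
      (exp(-mueff * r1) / r1 - exp(-mueff * r2) / r2)
  } else {
    1 / (4 * pi) *
      (z0 * (mueff + 1 / r1) * exp(-mueff * r1) / r1^2 +
         (z0 + 2 * zb) * (mueff + 1 / r2) * exp(-mueff * r2) / r2^2)
  }
}

#' Distributed photon source term
#'
#' Exponential source S(z) = a' mu_tr exp(-mu_tr z) describing where
#' collimated pencil-beam light is converted to diffuse light; integrates
#' to the reduced albedo a' over depth.
#'
#' @param z Depth (mm), vectorised, >= 0.
#' @param dp A [derive_diffusion_params()] object.
#' @return Source density (mm^-1).
#' @export
source_term <- function(z, dp) {
  stopifnot(inherits(dp, "diffusion_params"))
  if (any(z < 0)) stop("`z` must be non-negative", call. = FALSE)
  dp$albedo_reduced * dp$mu_tr * exp(-dp$mu_tr * z)
}

# Composite Gauss-Legendre nodes/weights over panels with roughly
# logarithmic spacing from `inner` out to `b`; resolves both the
# short-depth structure of the Green's function and the exponential tail.
gauss_panels <- function(breaks, n_nodes = 8L) {
  gl <- pracma::gaussLegendre(n_nodes, -1, 1)
  nodes <- weights <- numeric(0)
  for (i in seq_len(length(breaks) - 1L)) {
    a <- breaks[i]; b <- breaks[i + 1L]
    h <- (b - a) / 2
    nodes <- c(nodes, a + h * (gl$x + 1))
    weights <- c(weights, h * gl$w)
  }
  list(x = nodes, w = weights)
}

#' Source-integrated radial reflectance
#'
#' The pencil-beam radial reflectance
#' R(rho) = integral over z0 of R(rho, z0) S(z0) dz0,
#' computed by composite Gauss-Legendre quadrature on log-spaced depth
#' panels.  This is the numerical route whose Hankel transform the
#' closed-form models must reproduce.
#'
#' @param model `"pcbc"` or `"ebc"`.
#' @param rho Radial distances (mm), vectorised, > 0.
#' @param dp A [derive_diffusion_params()] object.
#' @param boundary A [boundary_params()] object.
#' @param z0_max Truncation depth of the source integral (mm). The source
#'   decays as exp(-mu_tr z0), so the default 100 mm truncates far beyond
#'   machine precision for any medium with mu_tr >= 1 mm^-1.
#' @param n_panels,n_nodes Quadrature refinement (panels x nodes per panel).
#' @return Reflectance per unit area (mm^-2), same length as `rho`.
#' @export
radial_reflectance <- function(model, rho, dp, boundary, z0_max = 100,
                               n_panels = 50L, n_nodes = 8L) {
  model <- match_model(model, c("pcbc", "ebc"))
  if (any(rho <= 0)) stop("`rho` must be positive", call. = FALSE)
  if (z0_max <= 0) stop("`z0_max` must be positive", call. = FALSE)
  # log-spaced panel edges from well below the transport length to z0_max
  inner <- min(1e-5 / dp$mu_tr, z0_max / 1e6)
  breaks <- c(0, exp(seq(log(inner), log(z0_max), length.out = n_panels)))
  q <- gauss_panels(breaks, n_nodes)
  s <- source_term(q$x, dp)
  # matrix of Green's function values: rows = rho, cols = z0 nodes
  G <- outer(rho, q$x, function(r, z) radial_green(model, r, z, dp, boundary))
  as.vector(G %*% (q$w * s))
}

#' Zeroth-order Hankel transform of a radial function
#'
#' Computes R(k) = 2 pi * integral of rho J0(k rho) R(rho) drho with
#' k = 2 pi f, by panel-wise Gauss-Legendre quadrature between consecutive
#' zeros of the oscillatory Bessel kernel, accumulating panels until the
#' partial sum stabilises.  At f = 0 the kernel is 1 and the transform is
#' the plain area integral, evaluated on log-spaced panels.
#'
#' @param R_of_rho Function of a numeric vector `rho` returning R(rho)
#'   (mm^-2).
#' @param f Spatial frequencies (mm^-1), vectorised.
#' @param rho_max Radial truncation (mm).  500 mm leaves the result
#'   unchanged at the default tolerance for every medium on the study grid.
#' @param rel_tol Relative partial-sum stopping tolerance.
#' @param n_nodes Gauss-Legendre nodes per panel.
#' @return Dimensionless reflectance, same length as `f`.
#' @export
hankel_transform_continuous <- function(R_of_rho, f, rho_max = 500,
                                        rel_tol = 1e-8, n_nodes = 9L) {
  stopifnot(is.function(R_of_rho), rho_max > 0)
  if (any(f < 0)) stop("`f` must be non-negative", call. = FALSE)
  vapply(f, function(fi) {
    k <- 2 * pi * fi
    if (k * rho_max < pi) {
      # non-oscillatory: log panels resolve the near-origin structure
      inner <- rho_max * 1e-8
      breaks <- c(0, exp(seq(log(inner), log(rho_max), length.out = 60L)))
      q <- gauss_panels(breaks, n_nodes)
      return(2 * pi * sum(q$w * q$x * besselJ(k * q$x, 0) * R_of_rho(q$x)))
    }
    # panel edges at (approximate) zeros of J0(k rho); the edges need not
    # be exact zeros -- they only delimit the quadrature panels
    zeros <- (seq_len(ceiling(k * rho_max / pi) + 1L) - 0.25) * pi / k
    zeros <- zeros[zeros < rho_max]
    # refine the first panel: R(rho) has a logarithmic peak at the origin
    first <- zeros[1]
    head_breaks <- c(0, first * 10^seq(-6, 0, length.out = 13L))
    breaks <- unique(c(head_breaks, zeros, rho_max))
    total <- 0
    tail_small <- 0L
    i <- 1L
    n_head <- length(head_breaks)
    while (i < length(breaks)) {
      q <- gauss_panels(breaks[c(i, i + 1L)], n_nodes)
      piece <- 2 * pi * sum(q$w * q$x * besselJ(k * q$x, 0) * R_of_rho(q$x))
      total <- total + piece
      if (i >= n_head) {  # only judge convergence on oscillation panels
        if (abs(piece) < rel_tol * max(abs(total), .Machine$double.xmin)) {
          tail_small <- tail_small + 1L
          if (tail_small >= 3L) break
        } else tail_small <- 0L
      }
      i <- i + 1L
    }
    total
  }, numeric(1))
}

#' Hankel transform of a binned Monte Carlo radial profile
#'
#' Midpoint-rule transform
#' R(f) = 2 pi * sum_i rho_i J0(2 pi f rho_i) R_i drho
#' of a binned radial reflectance profile.  At f = 0 this equals the total
#' detected diffuse reflectance of the profile.
#'
#' @param rr A `radial_reflectance_profile` object (see
#'   [run_pencil_beam()]), or any list with fields `bin_centers`, `values`,
#'   `bin_width`.
#' @param f_list Spatial frequencies (mm^-1).
#' @return Numeric vector of reflectance values, one per frequency.
#' @export
hankel_transform_binned <- function(rr, f_list) {
  if (is.null(rr$bin_centers) || is.null(rr$values) || is.null(rr$bin_width))
    stop("`rr` must carry `bin_centers`, `values` and `bin_width`",
         call. = FALSE)
  if (length(rr$values) == 0L) stop("empty radial profile", call. = FALSE)
  if (any(f_list < 0)) stop("`f_list` must be non-negative", call. = FALSE)
  nz <- which(rr$values != 0)        # empty far bins cannot contribute
  if (length(nz) == 0L) return(rep(0, length(f_list)))
  rho <- rr$bin_centers[nz]
  base <- 2 * pi * rho * rr$values[nz] * rr$bin_width
  vapply(f_list, function(fi) sum(base * besselJ(2 * pi * fi * rho, 0)),
         numeric(1))
}
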