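#' Top-level run configuration
#'
#' A flat, serialisable set of keys controlling boundary, Monte Carlo,
#' grid, filter and solver settings.  Unknown keys are rejected with a
#' hint, so typos in config files fail loudly.
#'
#' @param ... Named overrides of the defaults.
#' @return An object of class `run_config` (a named list).
#' @examples
#' run_config()                     # all defaults
#' run_config(n_in = 1.4, f_ac = 0.3)
#' @export
run_config <- function(...) {
  defaults <- list(
    n_in = 1.33, n_out = 1.00,
    diffusion_coefficient = "mus_plus_mua",
    n_photons = 1e5, repeats = 3L,
    bin_width = 0.01, n_bins = 120000L,
    roulette_threshold = 1e-4, roulette_survival = 0.1,
    f_ac = 0.5, filter_mode = "literal",
    dedup_scaled = TRUE,
    z0_max = 100, rho_max = 500,
    seed = 1L, n_freq = 20L,
    out_dir = ".")
  overrides <- list(...)
  if (length(overrides) > 0 &&
      (is.null(names(overrides)) || any(names(overrides) == "")))
    stop("all config values must be named", call. = FALSE)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0) {
    hint <- if (any(grepl("mu", unknown)))
      " (optical properties belong in the study grid, not the config)"
    else ""
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), hint,
         call. = FALSE)
  }
  cfg <- utils::modifyList(defaults, overrides)
  stopifnot(cfg$n_photons > 0, cfg$bin_width > 0, cfg$n_bins > 0,
            cfg$repeats >= 1)
  structure(cfg, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (k in names(x)) cat(sprintf("  %s: %s\n", k, format(x[[k]])))
  invisible(x)
}

#' Convert a run configuration to study settings
#'
#' @param cfg A [run_config()].
#' @return The corresponding [study_config()].
#' @export
as_study_config <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  study_config(n_photons = cfg$n_photons, repeats = cfg$repeats,
               bin_width = cfg$bin_width, n_bins = cfg$n_bins,
               n_in = cfg$n_in, n_out = cfg$n_out, f_ac = cfg$f_ac,
               filter_mode = cfg$filter_mode,
               dedup_scaled = cfg$dedup_scaled,
               seed = cfg$seed, n_freq = cfg$n_freq)
}

#' Load / save a run configuration (JSON)
#'
#' Missing keys take their defaults; unknown keys are rejected naming the
#' offender.  `save_config()` then `load_config()` round-trips losslessly.
#'
#' @param path File path.
#' @return A [run_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (length(raw) == 0) return(run_config())
  raw$repeats <- if (!is.null(raw$repeats)) as.integer(raw$repeats)
  raw$n_bins <- if (!is.null(raw$n_bins)) as.integer(raw$n_bins)
  raw$seed <- if (!is.null(raw$seed)) as.integer(raw$seed)
  raw$n_freq <- if (!is.null(raw$n_freq)) as.integer(raw$n_freq)
  do.call(run_config, raw[!vapply(raw, is.null, logical(1))])
}

#' @rdname load_config
#' @param cfg A [run_config()] to write.
#' @export
save_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Short provenance hash of a configuration
#'
#' MD5 of the canonical JSON serialisation, embedded in every output file
#' header so each artifact names the configuration that produced it.
#'
#' @param cfg A configuration (any serialisable list).
#' @return A 32-character hex string.
#' @export
config_hash <- function(cfg) {
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(strip(cfg), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Write / read a radial reflectance profile (CSV)
#'
#' Plain CSV with columns `rho_mm`, `R_per_mm2` and `#`-prefixed header
#' comments carrying the package version, seed, summary fractions and the
#' config hash, so the file is reproducible from its own header.
#'
#' @param rr A `radial_reflectance_profile` (from [run_pencil_beam()]).
#' @param path File path.
#' @return `write_profile()`: the path, invisibly.  `read_profile()`: a
#'   `radial_reflectance_profile` (without the full generating config).
#' @export
write_profile <- function(rr, path) {
  stopifnot(inherits(rr, "radial_reflectance_profile"))
  meta <- c(
    sprintf("# sfdimodels profile v%s",
            as.character(utils::packageVersion("sfdimodels"))),
    sprintf("# seed: %d", rr$seed),
    sprintf("# n_photons: %g", rr$n_photons),
    sprintf("# bin_width_mm: %.12g", rr$bin_width),
    sprintf("# detected_fraction: %.12g", rr$detected_fraction),
    sprintf("# absorbed_fraction: %.12g", rr$absorbed_fraction),
    sprintf("# overflow_fraction: %.12g", rr$overflow_fraction),
    if (!is.null(rr$config))
      sprintf("# config_hash: %s", config_hash(rr$config)),
    if (!is.null(rr$config))
      sprintf("# mu_a: %.12g", rr$config$props$mu_a),
    if (!is.null(rr$config))
      sprintf("# mu_s_prime: %.12g", rr$config$props$mu_s_prime))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  writeLines("rho_mm,R_per_mm2", con)
  utils::write.table(
    data.frame(rho = sprintf("%.12g", rr$bin_centers),
               R = sprintf("%.12g", rr$values)),
    con, sep = ",", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  if (!file.exists(path)) stop("profile not found: ", path, call. = FALSE)
  lines <- readLines(path)
  meta_lines <- grep("^#", lines)
  header_at <- length(meta_lines) + 1L
  if (header_at > length(lines) ||
      !grepl("rho_mm", lines[header_at], fixed = TRUE))
    stop("malformed profile: expected 'rho_mm,R_per_mm2' header at line ",
         header_at, call. = FALSE)
  df <- utils::read.csv(text = lines[-seq_len(header_at)], header = FALSE,
                        col.names = c("rho_mm", "R_per_mm2"))
  if (nrow(df) == 0) stop("empty profile: ", path, call. = FALSE)
  meta <- lines[meta_lines]
  pick <- function(key) {
    m <- grep(paste0("^# ", key, ":"), meta, value = TRUE)
    if (length(m) == 0) return(NA_real_)
    as.numeric(sub(paste0("^# ", key, ": *"), "", m[1]))
  }
  centers <- df$rho_mm
  structure(list(
    bin_centers = centers,
    values = df$R_per_mm2,
    bin_width = if (!is.na(pick("bin_width_mm"))) pick("bin_width_mm")
                else stats::median(diff(centers)),
    n_photons = pick("n_photons"),
    detected_fraction = pick("detected_fraction"),
    absorbed_fraction = pick("absorbed_fraction"),
    overflow_fraction = pick("overflow_fraction"),
    seed = as.integer(pick("seed"))
  ), class = "radial_reflectance_profile")
}

#' Write a study summary as JSON
#'
#' @param x A list of summary data frames / scalars.
#' @param path File path.
#' @param cfg Optional configuration whose hash and seed are embedded.
#' @return The path, invisibly.
#' @export
write_summary <- function(x, path, cfg = NULL) {
  out <- list(package_version =
                as.character(utils::packageVersion("sfdimodels")))
  if (!is.null(cfg)) {
    out$config_hash <- config_hash(cfg)
    out$seed <- cfg$seed
  }
  out <- c(out, x)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
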