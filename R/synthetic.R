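#' Specification for synthetic dispersion experiments
#'
#' Describes a two-channel (gravimetric + turbidimetric) dispersion
#' experiment generated from the Hill law. Three archetypes mirror the
#' qualitative regimes seen in beeswax/DES screening:
#'
#' * `"high"` — strongly dispersing fatty-acid eutectic: `a = 5` g,
#'   `b = 80` min (endpoint ~4.5 g at 720 min);
#' * `"moderate"` — intermediate terpene eutectic: `a = 1.72` g,
#'   `b = 130` min (endpoint ~1.46 g);
#' * `"negligible"` — incompatible polar eutectic: `a = 0.02` g,
#'   `b = 100` min (values remain near 0.02 g);
#'
#' all with `c = 1`. Saturation levels are anchored to reported endpoint
#' masses; the half-saturation times are the package's own synthetic
#' choices (fitted values for the real curves are unpublished).
#' The turbidity channel maps true mass through a linear turbidimeter
#' response (default slope 280.26 NTU/g, intercept -209.14 NTU, the
#' literature turbidity--mass calibration for a strongly dispersing
#' system), clamped at 0 NTU before noise since negative turbidity is
#' unphysical. Noise is additive Gaussian, homoscedastic per channel.
#'
#' @param archetype `"high"`, `"moderate"` or `"negligible"`; ignored if
#'   `params` is given.
#' @param params optional explicit [hill_params()].
#' @param noise_sd_mass Gaussian noise SD on the mass channel, g, >= 0.
#' @param noise_sd_turbidity Gaussian noise SD on the turbidity channel,
#'   NTU, >= 0.
#' @param turbidity_slope,turbidity_intercept linear turbidity--mass map
#'   (NTU/g, NTU).
#' @param times sampling grid, minutes, strictly increasing from 0.
#' @param replicates number of replicate series per channel, >= 1.
#' @param seed integer seed making the generated dataset reproducible.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(archetype = c("high", "moderate", "negligible"),
                           params = NULL,
                           noise_sd_mass = 0.1,
                           noise_sd_turbidity = 20,
                           turbidity_slope = 280.26,
                           turbidity_intercept = -209.14,
                           times = c(0, 30, 60, 120, 240, 360, 480, 720),
                           replicates = 3,
                           seed = 1L) {
  if (is.null(params)) {
    archetype <- match.arg(archetype)
    params <- switch(archetype,
                     high = hill_params(5.0, 80),
                     moderate = hill_params(1.72, 130),
                     negligible = hill_params(0.02, 100))
  } else {
    stopifnot(inherits(params, "hill_params"))
    archetype <- "custom"
  }
  assert_scalar_number(noise_sd_mass, "noise_sd_mass", non_negative = TRUE)
  assert_scalar_number(noise_sd_turbidity, "noise_sd_turbidity",
                       non_negative = TRUE)
  if (times[1] != 0 || is.unsorted(times, strictly = TRUE))
    stop_deswax("`times` must be strictly increasing from 0",
                class = "deswax_domain_error")
  if (replicates < 1 || replicates != round(replicates))
    stop_deswax("`replicates` must be a positive integer",
                class = "deswax_domain_error")
  structure(list(archetype = archetype, params = params,
                 noise_sd_mass = noise_sd_mass,
                 noise_sd_turbidity = noise_sd_turbidity,
                 turbidity_slope = turbidity_slope,
                 turbidity_intercept = turbidity_intercept,
                 times = as.numeric(times),
                 replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate paired synthetic dispersion series
#'
#' For each replicate, draws
#' `mass(t) = hill_eval(params, t) + N(0, noise_sd_mass)` floored at 0,
#' and `turbidity(t) = max(0, slope * mass_true(t) + intercept) +
#' N(0, noise_sd_turbidity)` floored at 0 (the turbidity map is applied to
#' the *noise-free* mass: the two channels are independent measurements of
#' the same underlying process, not of each other's noise). Identical
#' seeds give bit-identical output; the RNG state of the session is left
#' untouched.
#'
#' @param spec a [synthetic_spec()].
#' @return an object of class `synthetic_dataset`: list with `spec`,
#'   `mass` and `turbidity` (each a list of [kinetic_series()], one per
#'   replicate), and `truth` (the noise-free mass curve).
#' @examples
#' sim <- simulate_dispersion(synthetic_spec("high", seed = 42))
#' sim$mass[[1]]
#' @export
simulate_dispersion <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  tt <- spec$times
  f_true <- hill_eval(spec$params, tt)
  turb_true <- pmax(spec$turbidity_slope * f_true +
                      spec$turbidity_intercept, 0)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)
  mass <- vector("list", spec$replicates)
  turb <- vector("list", spec$replicates)
  for (r in seq_len(spec$replicates)) {
    m <- pmax(f_true + rnorm(length(tt), 0, spec$noise_sd_mass), 0)
    u <- pmax(turb_true + rnorm(length(tt), 0, spec$noise_sd_turbidity), 0)
    mass[[r]] <- kinetic_series(tt, m, kind = "mass")
    turb[[r]] <- kinetic_series(tt, u, kind = "turbidity")
  }
  structure(list(spec = spec, mass = mass, turbidity = turb,
                 truth = kinetic_series(tt, f_true, kind = "mass")),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "<synthetic_dataset> archetype '%s', %d replicate(s), %d time points, seed %d\n",
    x$spec$archetype, x$spec$replicates, length(x$spec$times),
    x$spec$seed))
  invisible(x)
}

#' Average replicate series of a synthetic dataset
#'
#' @param dataset a [simulate_dispersion()] result.
#' @param channel `"mass"` or `"turbidity"`.
#' @return a [kinetic_series()] of per-time replicate means, with the
#'   replicate standard deviation in `sd`.
#' @export
average_replicates <- function(dataset, channel = c("mass", "turbidity")) {
  channel <- match.arg(channel)
  series <- dataset[[channel]]
  vals <- do.call(rbind, lapply(series, `[[`, "values"))
  kinetic_series(series[[1]]$times, colMeans(vals), kind = channel,
                 sd = apply(vals, 2, stats::sd))
}

#' Write a synthetic dataset to disk
#'
#' Writes the long-format time-series table (`time_min,value,kind,
#' replicate`) that [read_kinetic_series()] consumes, plus a JSON manifest
#' recording the generating specification, seed and package version.
#'
#' @param dataset a [simulate_dispersion()] result.
#' @param dir output directory (created if missing).
#' @param name file stem, default `"synthetic"`.
#' @return invisibly, the paths written.
#' @export
write_simulation <- function(dataset, dir, name = "synthetic") {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (channel in c("mass", "turbidity"))
    for (r in seq_along(dataset[[channel]])) {
      s <- dataset[[channel]][[r]]
      rows[[length(rows) + 1L]] <-
        data.frame(time_min = s$times, value = s$values, kind = channel,
                   replicate = r)
    }
  tab <- do.call(rbind, rows)
  data_path <- file.path(dir, paste0(name, ".csv"))
  write.csv(tab, data_path, row.names = FALSE, quote = FALSE)
  spec <- dataset$spec
  manifest <- list(
    package = "deswax",
    version = as.character(utils::packageVersion("deswax")),
    archetype = spec$archetype,
    params = list(a = spec$params$a, b = spec$params$b, c = spec$params$c),
    noise_sd_mass = spec$noise_sd_mass,
    noise_sd_turbidity = spec$noise_sd_turbidity,
    turbidity_slope = spec$turbidity_slope,
    turbidity_intercept = spec$turbidity_intercept,
    times = spec$times, replicates = spec$replicates, seed = spec$seed)
  manifest_path <- file.path(dir, paste0(name, "_manifest.json"))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(data = data_path, manifest = manifest_path))
}
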