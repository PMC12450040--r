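#' Hill dispersion model parameters
#'
#' Parameters of the saturation-limited Hill dispersion law
#' \deqn{f(t) = a\left(1 - \frac{1}{1 + (t/b)^c}\right)
#'            = \frac{a\,t^c}{b^c + t^c}}
#' where `a` is the saturation level (response units), `b` the
#' half-saturation time (minutes; \eqn{f(b) = a/2} for every `c`) and `c`
#' the dimensionless shape parameter. `c = 1` gives the
#' Michaelis--Menten/rectangular-hyperbola form \eqn{a t/(b+t)}
#' (non-autocatalytic); `c != 1` gives a sigmoid; \eqn{c \to \infty}
#' approaches the logistic law. The derived rate constant is `k = b / c`.
#'
#' @param a saturation level, > 0.
#' @param b half-saturation time, minutes, > 0.
#' @param c shape parameter, > 0 (default 1).
#' @return an object of class `hill_params` with fields `a`, `b`, `c`, `k`.
#' @examples
#' p <- hill_params(a = 5, b = 80)
#' hill_eval(p, c(0, 80, 720))
#' @export
hill_params <- function(a, b, c = 1) {
  assert_scalar_number(a, "a", positive = TRUE)
  assert_scalar_number(b, "b", positive = TRUE)
  assert_scalar_number(c, "c", positive = TRUE)
  structure(list(a = a, b = b, c = c, k = b / c), class = "hill_params")
}

#' @export
print.hill_params <- function(x, ...) {
  cat(sprintf(
    "<hill_params> a = %.4g, b = %.4g min, c = %.4g (k = b/c = %.4g min)\n",
    x$a, x$b, x$c, x$k))
  invisible(x)
}

#' Evaluate the Hill dispersion curve
#'
#' @param params a [hill_params()].
#' @param t time(s) in minutes, >= 0.
#' @return dispersed response at `t`; `f(0) = 0`, monotone increasing,
#'   `f(t) < a` for finite `t`.
#' @export
hill_eval <- function(params, t) {
  stopifnot(inherits(params, "hill_params"))
  if (any(t < 0)) stop_deswax("t must be >= 0",
                              class = "deswax_domain_error")
  with(params, a * t^c / (b^c + t^c))
}

#' Dispersion rate as a function of the dispersed fraction
#'
#' For `c = 1` the rate law is the quadratic-deficit form
#' \deqn{\frac{df}{dt} = \frac{a}{b}\left(1 - \frac{f}{a}\right)^2,}
#' i.e. the rate falls with the *square* of the remaining capacity (at
#' variance with the first-order Noyes--Whitney law). For general `c`,
#' with `k = b/c`,
#' \deqn{\frac{df}{dt} = \frac{a}{k}\left(\frac{f}{a}\right)^{1 - 1/c}
#'   \left(1 - \frac{f}{a}\right)^{1 + 1/c},}
#' whose \eqn{f^{1-1/c}} factor carries the autocatalytic (sigmoidal)
#' contribution; it reduces exactly to the quadratic form at `c = 1`.
#'
#' @param params a [hill_params()].
#' @param f dispersed response, `0 <= f < a`.
#' @return rate in response units per minute; tends to 0 as `f` approaches
#'   `a`.
#' @export
hill_rate <- function(params, f) {
  stopifnot(inherits(params, "hill_params"))
  if (any(f < 0) || any(f >= params$a))
    stop_deswax("f must satisfy 0 <= f < a (saturation exceeded)",
                class = "deswax_domain_error")
  with(params, {
    u <- f / a
    if (c == 1) (a / b) * (1 - u)^2
    else (a / k) * u^(1 - 1 / c) * (1 - u)^(1 + 1 / c)
  })
}

#' Noyes--Whitney dissolution rate
#'
#' The classical first-order law \eqn{df/dt = K (1 - f/a)}, provided for
#' model comparison. The Hill `c = 1` rate can be written in this form
#' with an effective, concentration-dependent coefficient
#' \eqn{\tilde K = (a/b)(1 - f/a)}, computed when `K = NULL`.
#'
#' @param K rate constant, response units per minute (or `NULL` to use the
#'   effective \eqn{\tilde K} for the given `a`, `b`).
#' @param a saturation level.
#' @param f dispersed response, `0 <= f <= a`.
#' @param b half-saturation time, needed only when `K = NULL`.
#' @return rate in response units per minute.
#' @export
noyes_whitney_rate <- function(K, a, f, b = NULL) {
  if (any(f < 0) || any(f > a))
    stop_deswax("f must satisfy 0 <= f <= a",
                class = "deswax_domain_error")
  if (is.null(K)) {
    assert_scalar_number(b, "b", positive = TRUE)
    K <- (a / b) * (1 - f / a)
  }
  K * (1 - f / a)
}

#' Integrate the Hill rate law numerically
#'
#' Solves the rate ODE of [hill_rate()] with `deSolve` (adaptive LSODA)
#' and returns the trajectory on the requested grid. The closed form
#' [hill_eval()] is the exact solution, so this is chiefly a consistency
#' check of the model algebra: the numerical solution matches the closed
#' form pointwise to within the solver tolerance. For `c > 1` the origin
#' `f = 0` is a degenerate fixed point of the rate law, so integration
#' starts at a small `t_eps > 0` from the closed-form value.
#'
#' @param params a [hill_params()].
#' @param times time grid in minutes, starting at 0, strictly increasing.
#' @param t_eps positive offset at which integration starts when
#'   `c != 1`; by default the time where the closed form reaches
#'   `1e-6 * a`, far enough from the fixed point for the solver to track
#'   the departing trajectory. Grid points at or below `t_eps` are filled
#'   from the closed form.
#' @param rtol,atol solver tolerances (`atol` is scaled by `a`).
#' @return a [kinetic_series()] with the integrated response.
#' @export
integrate_hill <- function(params, times, t_eps = NULL,
                           rtol = 1e-10, atol = 1e-12) {
  stopifnot(inherits(params, "hill_params"))
  if (times[1] != 0 || is.unsorted(times, strictly = TRUE))
    stop_deswax("`times` must start at 0 and be strictly increasing",
                class = "deswax_domain_error")
  deriv <- function(t, y, parms) {
    f <- min(max(y[1], 0), params$a * (1 - 1e-15))
    list(hill_rate(params, f))
  }
  if (params$c == 1) {
    grid <- times
    y0 <- 0
  } else {
    if (is.null(t_eps))
      t_eps <- params$b * (1e-6 / (1 - 1e-6))^(1 / params$c)
    grid <- unique(c(t_eps, times[times > t_eps]))
    y0 <- hill_eval(params, t_eps)
  }
  sol <- deSolve::ode(y = c(f = y0), times = grid, func = deriv,
                      parms = NULL, rtol = rtol,
                      atol = atol * max(1, params$a))
  if (attr(sol, "istate")[1] < 0)
    stop_deswax("ODE integration failed (istate = %d)",
                attr(sol, "istate")[1], class = "deswax_integration_error")
  f <- approx_on_grid(grid, sol[, "f"], times, params)
  kinetic_series(times, f, kind = "mass")
}

# map solver output back onto the requested grid (fills t <= t_eps from the
# closed form, where the ODE was not integrated)
approx_on_grid <- function(grid, values, times, params) {
  out <- numeric(length(times))
  for (i in seq_along(times)) {
    j <- match(times[i], grid)
    out[i] <- if (!is.na(j)) values[j] else hill_eval(params, times[i])
  }
  out
}

#' A dispersion time course
#'
#' @param times minutes, strictly increasing, >= 0, length >= 3.
#' @param values response values (NTU for turbidity, g for dispersed
#'   mass), >= 0, same length as `times`.
#' @param kind `"turbidity"` or `"mass"`.
#' @param sd optional per-time standard deviations (replicate spread).
#' @return an object of class `kinetic_series`.
#' @export
kinetic_series <- function(times, values, kind = c("mass", "turbidity"),
                           sd = NULL) {
  kind <- match.arg(kind)
  if (length(times) != length(values))
    stop_deswax("times and values must have equal length",
                class = "deswax_domain_error")
  if (length(times) < 3)
    stop_deswax("a kinetic series needs at least 3 points",
                class = "deswax_domain_error")
  if (any(times < 0) || is.unsorted(times, strictly = TRUE))
    stop_deswax("times must be >= 0 and strictly increasing",
                class = "deswax_domain_error")
  if (any(values < 0))
    stop_deswax("response values must be >= 0",
                class = "deswax_domain_error")
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 kind = kind, sd = sd),
            class = "kinetic_series")
}

#' @export
print.kinetic_series <- function(x, ...) {
  cat(sprintf("<kinetic_series> %s, n = %d, t in [%g, %g] min\n",
              x$kind, length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

#' Read kinetic time series from file
#'
#' Expects columns `time_min,value,kind` and optionally `replicate` and
#' `series` (a label separating independent experiments). Replicates are
#' averaged per time point; the replicate standard deviation is kept in
#' the `sd` field of each series.
#'
#' @param path delimited text file.
#' @return named list of [kinetic_series()], one per `series`/`kind`
#'   combination.
#' @export
read_kinetic_series <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  required <- c("time_min", "value", "kind")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    stop_deswax("time-series file '%s' lacks column(s): %s", path,
                paste(missing_cols, collapse = ", "),
                class = "deswax_format_error")
  if (!nrow(tab))
    stop_deswax("time-series file '%s' is empty", path,
                class = "deswax_format_error")
  bad_kind <- setdiff(unique(tab$kind), c("turbidity", "mass"))
  if (length(bad_kind))
    stop_deswax("unknown series kind(s): %s",
                paste(bad_kind, collapse = ", "),
                class = "deswax_format_error")
  if (!"series" %in% names(tab)) tab$series <- "series"
  out <- list()
  for (s in unique(tab$series)) for (k in unique(tab$kind)) {
    sub <- tab[tab$series == s & tab$kind == k, , drop = FALSE]
    if (!nrow(sub)) next
    mu <- tapply(sub$value, sub$time_min, mean)
    sdv <- tapply(sub$value, sub$time_min, stats::sd)
    tt <- as.numeric(names(mu))
    ord <- order(tt)
    out[[paste(s, k, sep = ".")]] <-
      kinetic_series(tt[ord], pmax(as.numeric(mu)[ord], 0), kind = k,
                     sd = as.numeric(sdv)[ord])
  }
  out
}
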