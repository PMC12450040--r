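#' Fit the Hill dispersion model to a kinetic series
#'
#' Unweighted nonlinear least squares of [hill_eval()] against the series,
#' log-parameterized so `a`, `b` (and `c` when free) stay positive.
#' Deterministic initialization: `a0 = 1.1 * max(values)`, `b0` the time at
#' which the series first crosses half its maximum (linear interpolation),
#' `c0 = 1`. With `fix_c = TRUE` (the default, the non-autocatalytic
#' model) two parameters are estimated; with `fix_c = FALSE` the shape is
#' free and three are estimated.
#'
#' @param series a [kinetic_series()].
#' @param fix_c keep the shape parameter fixed at 1?
#' @return an object of class `hill_fit`: fields `params`
#'   ([hill_params()]), `stats` ([fit_stats()] panel), `vcov` (covariance
#'   of the natural-scale parameters, delta method from the log scale),
#'   `fitted`, `residuals`, `series`, `fix_c`.
#' @examples
#' s <- kinetic_series(c(0, 30, 60, 120, 240, 360, 480, 720),
#'                     hill_eval(hill_params(5, 80),
#'                               c(0, 30, 60, 120, 240, 360, 480, 720)))
#' fit_hill(s)
#' @export
fit_hill <- function(series, fix_c = TRUE) {
  stopifnot(inherits(series, "kinetic_series"))
  t <- series$times
  y <- series$values
  k_params <- if (fix_c) 2L else 3L
  if (length(y) < k_params + 1)
    stop_deswax("need at least %d points to fit %d parameters",
                k_params + 1, k_params, class = "deswax_fit_error")
  if (max(y) <= 0)
    stop_deswax("series has no signal to fit", class = "deswax_fit_error")
  a0 <- 1.1 * max(y)
  b0 <- half_crossing_time(t, y)
  start <- if (fix_c) c(la = log(a0), lb = log(b0))
           else c(la = log(a0), lb = log(b0), lc = 0)
  model <- function(p, t) {
    cc <- if (fix_c) 1 else exp(p[["lc"]])
    exp(p[["la"]]) * t^cc / (exp(p[["lb"]])^cc + t^cc)
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start,
                       fn = function(p) y - model(p, t),
                       control = minpack.lm::nls.lm.control(
                         maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
    error = function(e)
      stop_deswax("Hill fit failed: %s", conditionMessage(e),
                  class = "deswax_fit_error"))
  if (fit$info %in% c(0, 9))
    stop_deswax("Hill fit did not converge (info = %d): %s", fit$info,
                fit$message, class = "deswax_fit_error")
  p <- fit$par
  params <- hill_params(a = exp(p[["la"]]), b = exp(p[["lb"]]),
                        c = if (fix_c) 1 else exp(p[["lc"]]))
  pred <- hill_eval(params, t)
  st <- fit_stats(y, pred, k_params = k_params)
  # delta-method covariance on the natural scale; singular for a perfect fit
  vc <- tryCatch({
    cov_log <- vcov_nls_lm(fit, n = length(y))
    scale <- diag(c(params$a, params$b,
                    if (!fix_c) params$c), nrow = k_params)
    v <- scale %*% cov_log %*% scale
    dimnames(v) <- list(c("a", "b", if (!fix_c) "c"),
                        c("a", "b", if (!fix_c) "c"))
    v
  }, error = function(e) NULL)
  structure(list(params = params, stats = st, vcov = vc, fitted = pred,
                 residuals = y - pred, series = series, fix_c = fix_c),
            class = "hill_fit")
}

# first upward crossing of max(y)/2, linearly interpolated
half_crossing_time <- function(t, y) {
  half <- max(y) / 2
  i <- which(y >= half)[1]
  if (is.na(i)) return(max(t[t > 0], 1))
  if (i == 1 || y[i] == half) return(max(t[i], 1e-6))
  t0 <- t[i - 1]; t1 <- t[i]
  y0 <- y[i - 1]; y1 <- y[i]
  max(t0 + (half - y0) / (y1 - y0) * (t1 - t0), 1e-6)
}

vcov_nls_lm <- function(fit, n) {
  k <- length(fit$par)
  sigma2 <- fit$deviance / max(n - k, 1)
  solve(fit$hessian) * 2 * sigma2
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("Hill dispersion fit (%s, c %s)\n", x$series$kind,
              if (x$fix_c) "fixed at 1" else "free"))
  print(x$params)
  se <- if (!is.null(x$vcov)) sqrt(diag(x$vcov)) else rep(NA_real_, 2)
  cat(sprintf("  a = %.4g +/- %.3g   b = %.4g +/- %.3g min%s\n",
              x$params$a, se[1], x$params$b, se[2],
              if (!x$fix_c) sprintf("   c = %.4g +/- %.3g",
                                    x$params$c, se[3]) else ""))
  print(x$stats)
  invisible(x)
}

#' Regression statistics panel for a fitted curve
#'
#' Computes the panel customarily reported for dissolution-curve
#' regressions: with residual sum of squares `RSS` and total sum of
#' squares `TSS` about the mean,
#' `R2 = 1 - RSS/TSS`;
#' `aR2 = 1 - (1 - R2)(n - 1)/(n - k)`;
#' `SE = sqrt(RSS/(n - k))`;
#' Gaussian-likelihood information criteria counting only the `k` curve
#' parameters: `AIC = n log(RSS/n) + 2k`, `BIC = n log(RSS/n) + k log n`,
#' `AICc = AIC + 2k(k+1)/(n - k - 1)`;
#' regression F-statistic `F = ((TSS - RSS)/(k - 1))/(RSS/(n - k))` with
#' p-value from the upper tail of `F(k - 1, n - k)`.
#'
#' @param observed,predicted response vectors of equal length `n`.
#' @param k_params number of fitted curve parameters, `< n`.
#' @return an object of class `fit_stats`: list with `R2`, `aR2`, `SE`,
#'   `p_value`, `AIC`, `BIC`, `AICc`, `F`, `DoF` (`n - k`), `n`,
#'   `k_params`.
#' @export
fit_stats <- function(observed, predicted, k_params) {
  stopifnot(length(observed) == length(predicted))
  n <- length(observed)
  k <- as.integer(k_params)
  if (n <= k)
    stop_deswax("need n > k_params (n = %d, k = %d)", n, k,
                class = "deswax_fit_error")
  rss <- sum((observed - predicted)^2)
  tss <- sum((observed - mean(observed))^2)
  if (tss <= 0)
    stop_deswax("degenerate data: zero total variance",
                class = "deswax_degenerate_error")
  r2 <- 1 - rss / tss
  ar2 <- 1 - (1 - r2) * (n - 1) / (n - k)
  se <- sqrt(rss / (n - k))
  aic <- n * log(rss / n) + 2 * k
  bic <- n * log(rss / n) + k * log(n)
  aicc <- aic + 2 * k * (k + 1) / (n - k - 1)
  f <- ((tss - rss) / (k - 1)) / (rss / (n - k))
  p <- pf(f, k - 1, n - k, lower.tail = FALSE)
  structure(list(R2 = r2, aR2 = ar2, SE = se, p_value = p, AIC = aic,
                 BIC = bic, AICc = aicc, F = f, DoF = n - k, n = n,
                 k_params = k),
            class = "fit_stats")
}

#' @export
print.fit_stats <- function(x, ...) {
  cat(sprintf(
    paste0("  R2 = %.4g  aR2 = %.4g  SE = %.4g  p = %.3g\n",
           "  AIC = %.4g  BIC = %.4g  F = %.4g  DoF = %d  AICc = %.4g\n"),
    x$R2, x$aR2, x$SE, x$p_value, x$AIC, x$BIC, x$F, x$DoF, x$AICc))
  invisible(x)
}

#' Prediction interval width from a standard error
#'
#' The approximate two-sided prediction interval width `2 * SE` used when
#' judging the predictive accuracy of a dispersion fit.
#'
#' @param se standard error, response units, >= 0.
#' @return interval width in response units.
#' @examples
#' prediction_interval(27.577) # ~55.2
#' @export
prediction_interval <- function(se) {
  assert_scalar_number(se, "se", non_negative = TRUE)
  2 * se
}

#' Relative error of a prediction at an observed value
#'
#' `100 * (2 * SE) / value`: the prediction-interval half-width-pair over
#' the observation, in percent.
#'
#' @param se standard error, response units, >= 0.
#' @param value observed response, > 0.
#' @return percent relative error.
#' @examples
#' relative_error(0.19, 4.5) # ~8.4%
#' @export
relative_error <- function(se, value) {
  assert_scalar_number(se, "se", non_negative = TRUE)
  assert_scalar_number(value, "value", positive = TRUE)
  100 * prediction_interval(se) / value
}

#' Linear turbidity--mass correlation
#'
#' Ordinary least squares of turbidity (NTU) on dispersed mass (g) over a
#' shared time grid, the standard check that turbidity rises
#' proportionally with dispersed mass so the two channels can be mapped
#' onto each other.
#'
#' @param turbidity,mass [kinetic_series()] objects on identical time
#'   grids.
#' @return an object of class `linear_map`: `slope` (NTU/g), `intercept`
#'   (NTU), `R2`, plus the underlying `lm` fit.
#' @export
linear_correlation <- function(turbidity, mass) {
  stopifnot(inherits(turbidity, "kinetic_series"),
            inherits(mass, "kinetic_series"))
  if (length(turbidity$times) != length(mass$times) ||
      any(turbidity$times != mass$times))
    stop_deswax("turbidity and mass series are on different time grids",
                class = "deswax_alignment_error")
  x <- mass$values
  y <- turbidity$values
  if (stats::var(x) == 0)
    stop_deswax("degenerate data: constant mass, slope undefined",
                class = "deswax_degenerate_error")
  fit <- lm(y ~ x)
  r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 R2 = r2, fit = fit),
            class = "linear_map")
}

#' @export
print.linear_map <- function(x, ...) {
  cat(sprintf("<linear_map> y = %.4g x %+.4g  (R2 = %.4f)\n",
              x$slope, x$intercept, x$R2))
  invisible(x)
}
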