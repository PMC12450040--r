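#' Hansen distance between two substances
#'
#' \deqn{R_a = \sqrt{4(\delta_{d,1}-\delta_{d,2})^2 +
#'   (\delta_{p,1}-\delta_{p,2})^2 + (\delta_{h,1}-\delta_{h,2})^2}}
#' The factor 4 on the dispersive axis is the empirical weighting of the
#' Hansen sphere. Symmetric in its arguments; satisfies the triangle
#' inequality under the rescaled metric \eqn{(2\delta_d, \delta_p,
#' \delta_h)}.
#'
#' @param a,b [hansen()] triplets (or numeric length-3 vectors ordered
#'   `delta_d`, `delta_p`, `delta_h`).
#' @return distance in MPa^0.5.
#' @examples
#' ra_distance(hansen(16, 2, 7), hansen(15, 2, 7)) # = 2
#' @export
ra_distance <- function(a, b) {
  a <- as.numeric(unclass(a)); b <- as.numeric(unclass(b))
  stopifnot(length(a) == 3, length(b) == 3)
  sqrt(4 * (a[1] - b[1])^2 + (a[2] - b[2])^2 + (a[3] - b[3])^2)
}

#' Solute reference: Hansen center plus interaction radius
#'
#' @param center a [hansen()] triplet locating the solute in Hansen space.
#' @param r0 interaction radius R0, MPa^0.5, > 0 — the largest Ra at which
#'   a solvent is still considered effective.
#' @param rms optional root-mean-square RED residual recorded by
#'   [calibrate_solute()].
#' @return an object of class `solute_reference`.
#' @export
solute_reference <- function(center, r0, rms = NA_real_) {
  if (!inherits(center, "hansen"))
    center <- hansen(center[[1]], center[[2]], center[[3]])
  assert_scalar_number(r0, "r0", positive = TRUE)
  structure(list(center = center, r0 = r0, rms = rms),
            class = "solute_reference")
}

#' @export
print.solute_reference <- function(x, ...) {
  cat(sprintf(
    "<solute_reference> center (%.2f, %.2f, %.2f) MPa^0.5, R0 = %.2f\n",
    x$center[["delta_d"]], x$center[["delta_p"]], x$center[["delta_h"]],
    x$r0))
  if (!is.na(x$rms))
    cat(sprintf("  calibration RMS residual: %.4g RED units\n", x$rms))
  invisible(x)
}

#' Relative energy difference
#'
#' `RED = Ra / R0`. Values below 1 place the solvent inside the solute's
#' interaction sphere (predicted compatible); 0 is a perfect match.
#'
#' @param ra Hansen distance(s), MPa^0.5, >= 0.
#' @param reference a [solute_reference()] (or a positive scalar R0).
#' @return dimensionless RED value(s).
#' @export
red_value <- function(ra, reference) {
  r0 <- if (inherits(reference, "solute_reference")) reference$r0
        else reference
  assert_scalar_number(r0, "R0", positive = TRUE)
  if (any(ra < 0)) stop_deswax("Ra must be >= 0",
                               class = "deswax_domain_error")
  ra / r0
}

#' Score solvent-solute compatibility for a table of solvents
#'
#' @param hansen_df data frame with columns `des_name`, `delta_d`,
#'   `delta_p`, `delta_h` (e.g. from [hansen_report()]).
#' @param reference a [solute_reference()].
#' @param threshold RED compatibility threshold, default 1.
#' @return data frame `des_name`, `Ra`, `RED`, `compatible`, one row per
#'   solvent (input order preserved; see [rank_by_red()]).
#' @export
score_compatibility <- function(hansen_df, reference, threshold = 1) {
  stopifnot(inherits(reference, "solute_reference"))
  assert_scalar_number(threshold, "threshold", positive = TRUE)
  ra <- vapply(seq_len(nrow(hansen_df)), function(i)
    ra_distance(with(hansen_df[i, ],
                     c(delta_d, delta_p, delta_h)),
                reference$center), numeric(1))
  red <- red_value(ra, reference)
  data.frame(des_name = hansen_df$des_name, Ra = ra, RED = red,
             compatible = red < threshold)
}

#' Rank compatibility scores by ascending RED
#'
#' Deterministic ordering: ascending RED, ties broken lexicographically by
#' solvent name.
#'
#' @param scores data frame from [score_compatibility()].
#' @return the same data frame, reordered.
#' @export
rank_by_red <- function(scores) {
  if (!nrow(scores)) stop_deswax("no scores to rank",
                                 class = "deswax_domain_error")
  scores[order(scores$RED, scores$des_name), , drop = FALSE]
}

#' Calibrate a solute reference from observed RED values
#'
#' Inverts a list of observed RED values to the four-parameter solute
#' reference (center \eqn{\delta_{d0}, \delta_{p0}, \delta_{h0}} and
#' radius \eqn{R_0}) that generated them, by minimizing
#' \eqn{\sum_i (R_{a,i}/R_0 - \mathrm{RED}_i)^2} over a bounded box with
#' multi-start local least squares. Starts are placed on a Halton
#' low-discrepancy sequence over the box, so the procedure is fully
#' deterministic. Intended for recovering an unpublished reference (e.g. a
#' beeswax/white-spirit center) from published RED screening values.
#'
#' @param triplets data frame with columns `delta_d`, `delta_p`, `delta_h`
#'   (one row per solvent), or a list of [hansen()] triplets.
#' @param target_red observed RED values, same length/order as `triplets`.
#' @param lower,upper box bounds for `(delta_d0, delta_p0, delta_h0, R0)`,
#'   MPa^0.5.
#' @param n_starts number of multistart points, default 32.
#' @return a [solute_reference()] carrying the RMS residual (`$rms`); the
#'   per-solvent fitted REDs are attached as attribute `"fitted_red"`.
#' @examples
#' h <- data.frame(delta_d = c(16, 11, 15, 14, 17.5),
#'                 delta_p = c(2, 5, 2.2, 2.5, 2.8),
#'                 delta_h = c(7, 9.5, 7.8, 8.3, 4.5))
#' truth <- solute_reference(hansen(15.8, 0.2, 0.5), 10)
#' red <- apply(h, 1, function(r) red_value(ra_distance(r, truth$center), truth))
#' calibrate_solute(h, red)
#' @export
calibrate_solute <- function(triplets, target_red,
                             lower = c(12, 0, 0, 2),
                             upper = c(18, 6, 10, 20),
                             n_starts = 32) {
  if (is.list(triplets) && !is.data.frame(triplets))
    triplets <- do.call(rbind, lapply(triplets, function(h)
      as.data.frame(as.list(unclass(h)))))
  m <- as.matrix(triplets[, c("delta_d", "delta_p", "delta_h")])
  if (nrow(m) != length(target_red))
    stop_deswax("need one target RED per triplet",
                class = "deswax_domain_error")
  if (nrow(m) < 5)
    stop_deswax(
      "under-determined calibration: %d pairs for 4 free parameters (need >= 5)",
      nrow(m), class = "deswax_underdetermined_error")
  objective <- function(p) {
    ra <- sqrt(4 * (m[, 1] - p[1])^2 + (m[, 2] - p[2])^2 +
                 (m[, 3] - p[3])^2)
    sum((ra / p[4] - target_red)^2)
  }
  starts <- halton_sequence(n_starts, 4)
  starts <- sweep(sweep(starts, 2, upper - lower, `*`), 2, lower, `+`)
  best <- NULL
  for (i in seq_len(n_starts)) {
    fit <- tryCatch(
      optim(starts[i, ], objective, method = "L-BFGS-B",
            lower = lower, upper = upper,
            control = list(factr = 1e4, maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    # polish with a derivative-free pass; L-BFGS-B can stall on box edges
    fit <- optim(fit$par, objective,
                 control = list(reltol = 1e-14, maxit = 5000))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop_deswax("calibration failed: no optimizer start converged",
                class = "deswax_calibration_error")
  p <- best$par
  ra <- sqrt(4 * (m[, 1] - p[1])^2 + (m[, 2] - p[2])^2 +
               (m[, 3] - p[3])^2)
  ref <- solute_reference(hansen(p[1], p[2], p[3]), p[4],
                          rms = sqrt(best$value / nrow(m)))
  attr(ref, "fitted_red") <- ra / p[4]
  ref
}

#' Shipped calibrated beeswax reference
#'
#' The solute reference obtained by running [calibrate_solute()] over the
#' shipped reference Hansen triplets and RED screening values for the
#' twelve eutectic formulations (see [des_reference_hansen()] and
#' [des_reference_red()]). The center lands on white-spirit-like
#' coordinates, consistent with beeswax solubility being referenced to
#' white spirit. Stored as a plain-text fixture together with its
#' calibration RMS residual; a different reference can be supplied via
#' [read_solute_reference()].
#'
#' @return a [solute_reference()].
#' @export
beeswax_reference <- function() {
  read_solute_reference(
    system.file("extdata", "beeswax_reference.csv", package = "deswax",
                mustWork = TRUE))
}

#' Read a solute reference from file
#'
#' Expects columns `delta_d,delta_p,delta_h,R0` (optional `rms`).
#'
#' @param path delimited text file.
#' @return a [solute_reference()].
#' @export
read_solute_reference <- function(path) {
  tab <- read.csv(path, comment.char = "#")
  required <- c("delta_d", "delta_p", "delta_h", "R0")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    stop_deswax("solute reference '%s' lacks column(s): %s", path,
                paste(missing_cols, collapse = ", "),
                class = "deswax_format_error")
  solute_reference(hansen(tab$delta_d[1], tab$delta_p[1], tab$delta_h[1]),
                   tab$R0[1],
                   rms = if ("rms" %in% names(tab)) tab$rms[1]
                         else NA_real_)
}

#' Reference Hansen/Teas values for the twelve shipped formulations
#'
#' Literature screening values (Hansen triplets to one decimal, Teas
#' fractions as integers) for the twelve eutectic formulations in
#' [`mixtures.csv`][read_mixture_table()]. Used as calibration input and as
#' a validation yardstick for the group-contribution pipeline.
#'
#' @return data frame `des_name`, `delta_d`, `delta_p`, `delta_h`, `F_d`,
#'   `F_p`, `F_h`.
#' @export
des_reference_hansen <- function() {
  read.csv(system.file("extdata", "des_reference_hansen.csv",
                       package = "deswax", mustWork = TRUE))
}

#' Reference RED screening values for the twelve shipped formulations
#'
#' @return data frame `des_name`, `RED` (dimensionless, 2 decimals).
#' @export
des_reference_red <- function() {
  read.csv(system.file("extdata", "des_reference_red.csv",
                       package = "deswax", mustWork = TRUE))
}
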