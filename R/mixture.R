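#' Define a eutectic mixture of components
#'
#' A mixture is a set of components combined at a molar ratio. Binary
#' mixtures are the common case; the volume-fraction formalism generalizes
#' to any number of components, so n-ary mixtures are accepted. Optional
#' per-component scaling factors `s` (dimensionless, default 1) multiply
#' each component's contribution in the mixing rule; with `s = 1` the rule
#' is the plain volume-fraction average.
#'
#' @param components list of [des_component()] objects (length >= 2, or 1
#'   for a degenerate self-mixture).
#' @param ratio positive molar ratio, same length as `components` (e.g.
#'   `c(1, 2)` for 1:2).
#' @param s positive scaling factors, recycled to the number of components.
#' @param name mixture label used in reports.
#' @return an object of class `des_mixture`.
#' @examples
#' lauric <- des_component("dodecanoic acid",
#'   c(CH3 = 1, CH2 = 10, COOH = 1), 200.32, density = 0.8679)
#' capric <- des_component("decanoic acid",
#'   c(CH3 = 1, CH2 = 8, COOH = 1), 172.26, density = 0.8886)
#' des8 <- des_mixture(list(lauric, capric), c(1, 2), name = "DES 8")
#' volume_fractions(des8)
#' @export
des_mixture <- function(components, ratio, s = 1, name = NULL) {
  if (inherits(components, "des_component")) components <- list(components)
  stopifnot(length(components) >= 1,
            all(vapply(components, inherits, TRUE, "des_component")))
  if (length(ratio) != length(components))
    stop_deswax("`ratio` must have one entry per component",
                class = "deswax_domain_error")
  if (any(!is.finite(ratio)) || any(ratio <= 0))
    stop_deswax("molar ratio entries must be > 0",
                class = "deswax_domain_error")
  s <- rep_len(s, length(components))
  if (any(!is.finite(s)) || any(s <= 0))
    stop_deswax("scaling factors `s` must be > 0",
                class = "deswax_domain_error")
  if (is.null(name))
    name <- paste(vapply(components, `[[`, "", "name"), collapse = " / ")
  structure(list(name = name, components = components,
                 ratio = as.numeric(ratio), s = as.numeric(s)),
            class = "des_mixture")
}

#' @export
print.des_mixture <- function(x, ...) {
  cat(sprintf("<des_mixture> %s  [%s at %s]\n", x$name,
              paste(vapply(x$components, `[[`, "", "name"),
                    collapse = " + "),
              paste(x$ratio, collapse = ":")))
  invisible(x)
}

#' Volume fractions of a mixture
#'
#' \deqn{\varphi_i = \frac{x_i v_i}{\sum_j x_j v_j}} with molar fractions
#' \eqn{x_i} from the molar ratio and molar volumes \eqn{v_i} from
#' [molar_volume()]. Fractions sum to 1.
#'
#' @param mix a [des_mixture()].
#' @return numeric vector of volume fractions, named by component.
#' @export
volume_fractions <- function(mix) {
  stopifnot(inherits(mix, "des_mixture"))
  x <- mix$ratio / sum(mix$ratio)
  v <- vapply(mix$components, molar_volume, numeric(1))
  phi <- x * v / sum(x * v)
  setNames(phi, vapply(mix$components, `[[`, "", "name"))
}

#' Hansen parameters of a eutectic mixture
#'
#' Each mixture parameter is the \eqn{s \varphi}-weighted sum of the pure
#' component parameters, e.g.
#' \eqn{\delta_{d,M} = \sum_i \delta_{d,i} s_i \varphi_i}. With the default
#' `s = 1` this is the volume-fraction-weighted mean, so each mixture
#' parameter lies between the pure-component values.
#'
#' @inheritParams volume_fractions
#' @param groups group-contribution table, see [hvk_table()].
#' @return a [hansen()] triplet, MPa^0.5.
#' @export
mixture_hansen <- function(mix, groups = hvk_table()) {
  stopifnot(inherits(mix, "des_mixture"))
  phi <- volume_fractions(mix)
  h <- vapply(mix$components, function(cc)
    unclass(component_hansen(cc, groups)), numeric(3))
  w <- mix$s * phi
  hansen(sum(h[1, ] * w), sum(h[2, ] * w), sum(h[3, ] * w))
}

#' Teas fractions of a Hansen triplet
#'
#' Normalizes the three partial parameters to percent contributions
#' \eqn{F_i = 100\,\delta_i / (\delta_d + \delta_p + \delta_h)}; the
#' unrounded fractions sum to exactly 100. Teas fractions are invariant
#' under rescaling of the triplet.
#'
#' @param hsp a [hansen()] triplet (or numeric length-3 vector) with
#'   positive sum.
#' @return an object of class `teas`: named numeric vector `F_d`, `F_p`,
#'   `F_h` in percent.
#' @examples
#' teas_fractions(hansen(16.0, 2.1, 7.0))
#' @export
teas_fractions <- function(hsp) {
  x <- as.numeric(unclass(hsp))
  if (length(x) != 3 || any(!is.finite(x)) || any(x < 0))
    stop_deswax("`hsp` must be three finite non-negative numbers",
                class = "deswax_domain_error")
  if (sum(x) <= 0)
    stop_deswax("Teas fractions undefined for an all-zero triplet",
                class = "deswax_domain_error")
  structure(setNames(100 * x / sum(x), c("F_d", "F_p", "F_h")),
            class = "teas")
}

#' @export
print.teas <- function(x, ...) {
  cat(sprintf("<teas> F_d = %.1f%%, F_p = %.1f%%, F_h = %.1f%%\n",
              x[["F_d"]], x[["F_p"]], x[["F_h"]]))
  invisible(x)
}

#' Round Teas fractions to integers
#'
#' `"nearest"` rounds each fraction half-up independently (the convention
#' that matches published integer tables; the rounded triplet may sum to
#' 99--101). `"largest_remainder"` apportions so the integers sum to
#' exactly 100.
#'
#' @param teas a [teas_fractions()] result.
#' @param method rounding rule.
#' @return integer vector `F_d`, `F_p`, `F_h`.
#' @export
round_teas <- function(teas, method = c("nearest", "largest_remainder")) {
  method <- match.arg(method)
  x <- unclass(teas)
  if (method == "nearest") return(setNames(as.integer(round_half_up(x)),
                                           names(x)))
  fl <- floor(x)
  short <- 100L - as.integer(sum(fl))
  rem <- x - fl
  take <- order(rem, decreasing = TRUE)[seq_len(short)]
  fl[take] <- fl[take] + 1
  setNames(as.integer(fl), names(x))
}

#' Ternary-to-Cartesian Teas chart coordinates
#'
#' Standard projection `x = F_p + F_h / 2`, `y = sqrt(3)/2 * F_h` used to
#' place a solvent on the Teas triangle.
#'
#' @param teas a [teas_fractions()] result (percent).
#' @return named numeric vector `x`, `y`.
#' @export
teas_coordinates <- function(teas) {
  x <- unclass(teas)
  c(x = x[["F_p"]] + x[["F_h"]] / 2, y = sqrt(3) / 2 * x[["F_h"]])
}

#' Read a mixture table from file
#'
#' Expects columns `des_name,component1,component2,n1,n2` (binary
#' mixtures); component names must resolve against the supplied component
#' list. The twelve shipped formulations are available as
#' `system.file("extdata", "mixtures.csv", package = "deswax")`.
#'
#' @param path delimited text file.
#' @param components named list from [read_component_table()].
#' @return list of [des_mixture()] objects.
#' @export
read_mixture_table <- function(path, components) {
  tab <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  required <- c("des_name", "component1", "component2", "n1", "n2")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    stop_deswax("mixture table '%s' lacks column(s): %s", path,
                paste(missing_cols, collapse = ", "),
                class = "deswax_format_error")
  if (!nrow(tab))
    stop_deswax("mixture table '%s' is empty", path,
                class = "deswax_format_error")
  lapply(seq_len(nrow(tab)), function(i) {
    wanted <- c(tab$component1[i], tab$component2[i])
    missing_comp <- setdiff(wanted, names(components))
    if (length(missing_comp))
      stop_deswax("mixture '%s' references unknown component(s): %s",
                  tab$des_name[i], paste(missing_comp, collapse = ", "),
                  class = "deswax_lookup_error")
    des_mixture(components[wanted], c(tab$n1[i], tab$n2[i]),
                name = tab$des_name[i])
  })
}

#' Hansen/Teas report for a set of mixtures
#'
#' Computes mixture Hansen triplets, Teas fractions and Teas-chart
#' coordinates for each mixture. Full-precision values are returned;
#' rounding (Hansen to 1 decimal, Teas to integers) is left to the
#' reporting layer, see [run_hsp()].
#'
#' @param mixtures list of [des_mixture()] objects.
#' @param groups group-contribution table.
#' @return data frame with columns `des_name`, `delta_d`, `delta_p`,
#'   `delta_h`, `F_d`, `F_p`, `F_h`, `teas_x`, `teas_y`.
#' @export
hansen_report <- function(mixtures, groups = hvk_table()) {
  rows <- lapply(mixtures, function(m) {
    h <- mixture_hansen(m, groups)
    f <- teas_fractions(h)
    xy <- teas_coordinates(f)
    data.frame(des_name = m$name,
               delta_d = h[["delta_d"]], delta_p = h[["delta_p"]],
               delta_h = h[["delta_h"]],
               F_d = f[["F_d"]], F_p = f[["F_p"]], F_h = f[["F_h"]],
               teas_x = xy[["x"]], teas_y = xy[["y"]])
  })
  do.call(rbind, rows)
}
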