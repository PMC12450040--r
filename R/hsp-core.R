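#' Hoftyzer--Van Krevelen group-contribution table
#'
#' Loads a table of molar attraction constants and hydrogen-bonding energies
#' per functional group. With `path = NULL` the table shipped with the
#' package is returned: a transcription of the standard Hoftyzer--Van
#' Krevelen constants (`F_d`, `F_p` in MPa^0.5 cm^3 mol^-1, `E_h` in
#' J mol^-1), extended with polysubstituted aromatic aggregates (`C6H3`,
#' `C6H2`) extrapolated from the phenyl-to-phenylene decrement of 160
#' MPa^0.5 cm^3 mol^-1 per ring substitution. Alternative editions of the
#' constants can be supplied as a delimited file with columns
#' `group,F_d,F_p,E_h`.
#'
#' @param path optional path to a user-supplied group table (CSV, header
#'   row mandatory, dot decimal separator).
#' @return a data frame of class `hvk_table` with columns `group`, `F_d`,
#'   `F_p`, `E_h`.
#' @examples
#' head(hvk_table())
#' @export
hvk_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "hvk_groups.csv", package = "deswax",
                        mustWork = TRUE)
  read_group_table(path)
}

#' Read a group-contribution table from file
#'
#' @param path delimited text file with columns `group,F_d,F_p,E_h`.
#' @return a validated `hvk_table` data frame.
#' @export
read_group_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  required <- c("group", "F_d", "F_p", "E_h")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    stop_deswax("group table '%s' lacks column(s): %s", path,
                paste(missing_cols, collapse = ", "),
                class = "deswax_format_error")
  if (anyDuplicated(tab$group))
    stop_deswax("group table '%s' has duplicated group labels: %s", path,
                paste(unique(tab$group[duplicated(tab$group)]),
                      collapse = ", "),
                class = "deswax_format_error")
  if (any(!is.finite(tab$E_h)) || any(tab$E_h < 0))
    stop_deswax("E_h must be finite and >= 0 for every group",
                class = "deswax_domain_error")
  rownames(tab) <- tab$group
  class(tab) <- c("hvk_table", "data.frame")
  tab
}

#' Define a molecular component as a bag of functional groups
#'
#' A component is described by its functional-group multiplicities plus the
#' molar mass and either a density or a molar volume (the latter wins if
#' both are given).
#'
#' @param name component name.
#' @param groups named integer vector of group counts, labels matching the
#'   group-contribution table (e.g. `c(CH3 = 1, CH2 = 10, COOH = 1)`).
#' @param molar_mass g/mol, > 0.
#' @param density g/cm^3, > 0 (optional if `molar_volume` given).
#' @param molar_volume cm^3/mol, > 0 (optional if `density` given).
#' @return an object of class `des_component`.
#' @examples
#' lauric <- des_component("dodecanoic acid",
#'   c(CH3 = 1, CH2 = 10, COOH = 1), molar_mass = 200.32, density = 0.8679)
#' molar_volume(lauric)
#' @export
des_component <- function(name, groups, molar_mass,
                          density = NA_real_, molar_volume = NA_real_) {
  if (!is.numeric(groups) || is.null(names(groups)) ||
      any(!nzchar(names(groups))))
    stop_deswax("`groups` must be a named numeric vector of counts",
                class = "deswax_domain_error")
  if (any(groups < 0) || any(groups != round(groups)))
    stop_deswax("group counts must be non-negative integers",
                class = "deswax_domain_error")
  groups <- groups[groups > 0]
  if (!length(groups))
    stop_deswax("component '%s' has no group with count > 0", name,
                class = "deswax_domain_error")
  assert_scalar_number(molar_mass, "molar_mass", positive = TRUE)
  if (is.na(density) && is.na(molar_volume))
    stop_deswax(
      "component '%s': at least one of density or molar_volume is required",
      name, class = "deswax_config_error")
  structure(
    list(name = name, groups = groups, molar_mass = molar_mass,
         density = density, molar_volume = molar_volume),
    class = "des_component")
}

#' @export
print.des_component <- function(x, ...) {
  cat(sprintf("<des_component> %s  (M = %.2f g/mol, V = %.1f cm3/mol)\n",
              x$name, x$molar_mass, molar_volume(x)))
  cat("  groups:",
      paste(sprintf("%s x%d", names(x$groups), as.integer(x$groups)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Molar volume of a component
#'
#' Returns the stated molar volume when present, otherwise `molar_mass /
#' density`.
#'
#' @param component a [des_component()].
#' @return molar volume in cm^3/mol.
#' @examples
#' molar_volume(des_component("x", c(CH3 = 2), 30.07, density = 0.5))
#' @export
molar_volume <- function(component) {
  stopifnot(inherits(component, "des_component"))
  v <- if (!is.na(component$molar_volume)) component$molar_volume
       else if (!is.na(component$density))
         component$molar_mass / component$density
       else stop_deswax(
         "component '%s': neither density nor molar_volume available",
         component$name, class = "deswax_config_error")
  if (!is.finite(v) || v <= 0)
    stop_deswax("component '%s': molar volume must be > 0 (got %g)",
                component$name, v, class = "deswax_domain_error")
  v
}

#' Hansen solubility parameter triplet
#'
#' @param delta_d,delta_p,delta_h partial solubility parameters, MPa^0.5,
#'   each finite and >= 0.
#' @return an object of class `hansen` (named numeric vector of length 3).
#' @examples
#' hansen(16.0, 2.1, 7.0)
#' @export
hansen <- function(delta_d, delta_p, delta_h) {
  x <- c(delta_d = delta_d, delta_p = delta_p, delta_h = delta_h)
  if (any(!is.finite(x)) || any(x < 0))
    stop_deswax("Hansen parameters must be finite and >= 0",
                class = "deswax_domain_error")
  structure(x, class = "hansen")
}

#' @export
print.hansen <- function(x, ...) {
  cat(sprintf("<hansen> delta_d = %.2f, delta_p = %.2f, delta_h = %.2f MPa^0.5\n",
              x[["delta_d"]], x[["delta_p"]], x[["delta_h"]]))
  invisible(x)
}

#' Group-contribution Hansen parameters of a pure component
#'
#' Evaluates the Hoftyzer--Van Krevelen expressions over the component's
#' group bag (counts enter as multiplicities):
#' \deqn{\delta_d = \frac{\sum_i n_i F_{d,i}}{V}, \quad
#'       \delta_p = \frac{\sqrt{\sum_i n_i F_{p,i}^2}}{V}, \quad
#'       \delta_h = \sqrt{\frac{\sum_i n_i E_{h,i}}{V}}}
#' where \eqn{V} is the molar volume from [molar_volume()]. Note the polar
#' term sums *squared* constants per group occurrence.
#'
#' @param component a [des_component()].
#' @param groups a group-contribution table from [hvk_table()] or
#'   [read_group_table()].
#' @return a [hansen()] triplet, MPa^0.5.
#' @examples
#' lauric <- des_component("dodecanoic acid",
#'   c(CH3 = 1, CH2 = 10, COOH = 1), molar_mass = 200.32, density = 0.8679)
#' component_hansen(lauric)
#' @export
component_hansen <- function(component, groups = hvk_table()) {
  stopifnot(inherits(component, "des_component"))
  n <- component$groups
  unknown <- setdiff(names(n), groups$group)
  if (length(unknown))
    stop_deswax("component '%s' uses group(s) absent from the table: %s",
                component$name, paste(unknown, collapse = ", "),
                class = "deswax_lookup_error")
  v <- molar_volume(component)
  g <- groups[names(n), , drop = FALSE]
  hansen(
    delta_d = sum(n * g$F_d) / v,
    delta_p = sqrt(sum(n * g$F_p^2)) / v,
    delta_h = sqrt(sum(n * g$E_h) / v))
}

#' Read a component table from file
#'
#' Expects columns `name,molar_mass,density,molar_volume,groups` where
#' `groups` is `label:count` pairs joined by `;` (e.g.
#' `CH3:1;CH2:10;COOH:1`). Empty density or molar_volume cells are allowed
#' (at least one must be present per row). The table of the ten components
#' used in the shipped eutectic formulations is available as
#' `system.file("extdata", "components.csv", package = "deswax")`.
#'
#' @param path delimited text file.
#' @return a named list of [des_component()] objects.
#' @export
read_component_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  required <- c("name", "molar_mass", "density", "molar_volume", "groups")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    stop_deswax("component table '%s' lacks column(s): %s", path,
                paste(missing_cols, collapse = ", "),
                class = "deswax_format_error")
  out <- lapply(seq_len(nrow(tab)), function(i) {
    des_component(
      name = tab$name[i],
      groups = parse_group_string(tab$groups[i], tab$name[i]),
      molar_mass = tab$molar_mass[i],
      density = if (is.na(tab$density[i])) NA_real_ else tab$density[i],
      molar_volume = if (is.na(tab$molar_volume[i])) NA_real_
                     else tab$molar_volume[i])
  })
  names(out) <- tab$name
  out
}

parse_group_string <- function(s, name) {
  pairs <- strsplit(trimws(s), ";", fixed = TRUE)[[1]]
  pairs <- pairs[nzchar(trimws(pairs))]
  if (!length(pairs))
    stop_deswax("component '%s': empty group specification", name,
                class = "deswax_format_error")
  parts <- strsplit(pairs, ":", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad))
    stop_deswax("component '%s': malformed group token(s): %s", name,
                paste(pairs[bad], collapse = ", "),
                class = "deswax_format_error")
  counts <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
  if (any(is.na(counts)))
    stop_deswax("component '%s': non-numeric group count", name,
                class = "deswax_format_error")
  setNames(counts, trimws(vapply(parts, `[`, "", 1L)))
}
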