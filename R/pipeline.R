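#' Load a pipeline run configuration
#'
#' A YAML file with any of the keys below; unset keys fall back to the
#' packaged fixtures and defaults, so `run_config()` with no file runs
#' the shipped screening study end to end.
#'
#' Keys: `group_table`, `component_table`, `mixture_table`,
#' `solute_reference` (path, or `"calibrate"` to calibrate from
#' `reference_red`), `reference_hansen`, `reference_red`, `series`
#' (vector of time-series files), `out_dir`, `seed`, `red_threshold`,
#' `activity_floor`, `fix_c`, `hansen_digits`, `red_digits`.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return a named list of class `run_config`; carries the config file's
#'   MD5 hash (`$config_hash`) for report provenance.
#' @export
run_config <- function(path = NULL) {
  defaults <- list(
    group_table = system.file("extdata", "hvk_groups.csv",
                              package = "deswax", mustWork = TRUE),
    component_table = system.file("extdata", "components.csv",
                                  package = "deswax", mustWork = TRUE),
    mixture_table = system.file("extdata", "mixtures.csv",
                                package = "deswax", mustWork = TRUE),
    solute_reference = system.file("extdata", "beeswax_reference.csv",
                                   package = "deswax", mustWork = TRUE),
    reference_hansen = system.file("extdata", "des_reference_hansen.csv",
                                   package = "deswax", mustWork = TRUE),
    reference_red = system.file("extdata", "des_reference_red.csv",
                                package = "deswax", mustWork = TRUE),
    series = character(),
    out_dir = ".",
    seed = 1L,
    red_threshold = 1.0,
    activity_floor = 0.05,
    fix_c = TRUE,
    hansen_digits = 1L,
    red_digits = 2L)
  hash <- "defaults"
  if (!is.null(path)) {
    if (!file.exists(path))
      stop_deswax("config file '%s' does not exist", path,
                  class = "deswax_config_error")
    user <- yaml::read_yaml(path)
    unknown <- setdiff(names(user), names(defaults))
    if (length(unknown))
      stop_deswax("unknown config key(s): %s",
                  paste(unknown, collapse = ", "),
                  class = "deswax_config_error")
    defaults <- modifyList(defaults, user)
    hash <- unname(tools::md5sum(path))
  }
  if (defaults$red_threshold <= 0)
    stop_deswax("red_threshold must be > 0", class = "deswax_config_error")
  for (key in c("group_table", "component_table", "mixture_table"))
    if (!file.exists(defaults[[key]]))
      stop_deswax("config: %s '%s' does not exist", key, defaults[[key]],
                  class = "deswax_config_error")
  defaults$config_hash <- hash
  class(defaults) <- "run_config"
  defaults
}

report_header <- function(config) {
  c(sprintf("# deswax %s", utils::packageVersion("deswax")),
    sprintf("# config %s", config$config_hash),
    sprintf("# seed %d", as.integer(config$seed)))
}

write_report <- function(df, path, config) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(report_header(config), con)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Compute the Hansen/Teas screening report
#'
#' Drives the group-contribution pipeline over the configured component
#' and mixture tables and writes two delimited reports under
#' `config$out_dir`: `hansen_report.csv` (`des_name,delta_d,delta_p,
#' delta_h,F_d,F_p,F_h`, Hansen rounded to `hansen_digits`, Teas to
#' integers) and `teas_coordinates.csv` (`des_name,x,y`, the standard
#' ternary-to-Cartesian projection). Rounding happens only at this
#' reporting layer; the returned data frame is full precision.
#'
#' @param config a [run_config()].
#' @return invisibly, the full-precision [hansen_report()] data frame.
#' @export
run_hsp <- function(config = run_config()) {
  groups <- read_group_table(config$group_table)
  components <- read_component_table(config$component_table)
  mixtures <- read_mixture_table(config$mixture_table, components)
  report <- hansen_report(mixtures, groups)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  rounded <- data.frame(
    des_name = report$des_name,
    delta_d = round_half_up(report$delta_d, config$hansen_digits),
    delta_p = round_half_up(report$delta_p, config$hansen_digits),
    delta_h = round_half_up(report$delta_h, config$hansen_digits))
  teas_int <- t(vapply(seq_len(nrow(report)), function(i)
    round_teas(structure(c(F_d = report$F_d[i], F_p = report$F_p[i],
                           F_h = report$F_h[i]), class = "teas")),
    integer(3)))
  rounded <- cbind(rounded, as.data.frame(teas_int))
  write_report(rounded, file.path(config$out_dir, "hansen_report.csv"),
               config)
  write_report(
    data.frame(des_name = report$des_name,
               x = report$teas_x, y = report$teas_y),
    file.path(config$out_dir, "teas_coordinates.csv"), config)
  invisible(report)
}

#' Screen solvents against the solute reference by RED
#'
#' Scores each formulation in the configured reference Hansen table (or a
#' freshly computed [run_hsp()] report when `use_computed = TRUE`)
#' against the solute reference, ranks ascending by RED and writes
#' `red_ranking.csv` (`des_name,Ra,RED,compatible`). With
#' `solute_reference: "calibrate"` the reference is calibrated on the fly
#' from the configured reference RED list.
#'
#' @param config a [run_config()].
#' @param use_computed score the package-computed mixture Hansen values
#'   instead of the reference table.
#' @return invisibly, the ranked score data frame (full precision).
#' @export
run_screen <- function(config = run_config(), use_computed = FALSE) {
  hansen_df <- if (use_computed) run_hsp(config)
               else read.csv(config$reference_hansen)
  reference <- if (identical(config$solute_reference, "calibrate")) {
    red <- read.csv(config$reference_red)
    calibrate_solute(read.csv(config$reference_hansen), red$RED)
  } else if (is.character(config$solute_reference) &&
             file.exists(config$solute_reference)) {
    read_solute_reference(config$solute_reference)
  } else {
    stop_deswax(
      "no solute reference: set `solute_reference` to a file or 'calibrate'",
      class = "deswax_config_error")
  }
  scores <- rank_by_red(
    score_compatibility(hansen_df, reference, config$red_threshold))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- data.frame(des_name = scores$des_name,
                    Ra = round_half_up(scores$Ra, 2),
                    RED = round_half_up(scores$RED, config$red_digits),
                    compatible = scores$compatible)
  write_report(out, file.path(config$out_dir, "red_ranking.csv"), config)
  invisible(scores)
}

#' Fit the Hill model to configured kinetic series
#'
#' Reads every configured time-series file, averages replicates, and fits
#' the `c = 1` Hill model per series (plus the free-shape alternative when
#' `fix_c = FALSE` is configured, reporting both panels). Series whose
#' value range is below `activity_floor` are skipped with a reason — the
#' negligible-dispersion regime where a saturation fit is meaningless.
#' Fit failures are reported per series and the run continues. Writes
#' `kinetics_report.csv` with parameters and the full statistics panel.
#'
#' @param config a [run_config()].
#' @param series optional named list of [kinetic_series()] to fit instead
#'   of reading `config$series` files.
#' @return invisibly, a list with `fits` (per-series [fit_hill()] results
#'   or skip reasons) and `report` (the summary data frame).
#' @export
run_fit <- function(config = run_config(), series = NULL) {
  if (is.null(series)) {
    if (!length(config$series))
      stop_deswax("no time-series inputs configured",
                  class = "deswax_config_error")
    series <- list()
    for (path in config$series) series <- c(series,
                                            read_kinetic_series(path))
  }
  fits <- list()
  rows <- list()
  for (nm in names(series)) {
    s <- series[[nm]]
    if (diff(range(s$values)) < config$activity_floor) {
      fits[[nm]] <- sprintf(
        "skipped: value range %.3g below activity floor %.3g (negligible dispersion)",
        diff(range(s$values)), config$activity_floor)
      next
    }
    fit <- tryCatch(fit_hill(s, fix_c = config$fix_c),
                    error = function(e) conditionMessage(e))
    fits[[nm]] <- fit
    if (!inherits(fit, "hill_fit")) next
    st <- fit$stats
    rows[[nm]] <- data.frame(
      series = nm, kind = s$kind, a = fit$params$a, b = fit$params$b,
      c = fit$params$c, R2 = st$R2, aR2 = st$aR2, SE = st$SE,
      p_value = st$p_value, AIC = st$AIC, BIC = st$BIC, F = st$F,
      DoF = st$DoF, AICc = st$AICc)
  }
  report <- if (length(rows)) do.call(rbind, rows) else
    data.frame()
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_report(report, file.path(config$out_dir, "kinetics_report.csv"),
               config)
  skipped <- Filter(is.character, fits)
  if (length(skipped))
    writeLines(c(report_header(config),
                 sprintf("%s: %s", names(skipped), unlist(skipped))),
               file.path(config$out_dir, "kinetics_skipped.txt"))
  invisible(list(fits = fits, report = report))
}

#' Generate and persist a synthetic dispersion dataset
#'
#' Thin driver over [simulate_dispersion()] + [write_simulation()]: the
#' configured seed makes the dataset byte-reproducible, and the manifest
#' records the generating spec.
#'
#' @param config a [run_config()].
#' @param archetype generator archetype, see [synthetic_spec()].
#' @param ... further arguments passed to [synthetic_spec()].
#' @return invisibly, the [simulate_dispersion()] dataset.
#' @export
run_simulate <- function(config = run_config(), archetype = "high", ...) {
  spec <- synthetic_spec(archetype = archetype, seed = config$seed, ...)
  dataset <- simulate_dispersion(spec)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_simulation(dataset, config$out_dir,
                   name = paste0("synthetic_", spec$archetype))
  invisible(dataset)
}
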