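.config_defaults <- function() {
  list(
    physical = .baseline_physical,
    network = list(n_generations = 3, nv = 4),
    timing = list(dtv = 0.5, dtg = 0.5),
    boundary = list(pa_cmH2O = 6, pb_cmH2O = 9, pe_cmH2O = 2),
    solver = list(rtol = 1e-6, atol = 1e-10, method = "lsoda",
                  min_cycles = 10, max_cycles = 200, cycle_rel_tol = 0.005,
                  cycle_abs_tol_ml_hr = 2e-4, pts_per_cycle = 80),
    output = list(dir = ".", series = FALSE)
  )
}

#' Load a run configuration
#'
#' Reads a YAML configuration with sections `physical`, `network`, `timing`,
#' `boundary`, `solver` and `output`. Every key is optional and defaults to
#' the baseline value; unknown sections or keys are rejected with the
#' offending key path named. Pressures in configuration files are in cmH2O;
#' conversion to internal units happens when the configuration is realised
#' with [config_inputs()].
#'
#' @param path Path to a YAML file. An empty file (or `NULL` content) yields
#'   the full baseline configuration.
#' @return An object of class `lymph_config`: the fully resolved nested list.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  resolve_config(raw)
}

#' @rdname load_config
#' @param raw A nested list as read from YAML (or `NULL`).
#' @export
resolve_config <- function(raw = NULL) {
  defaults <- .config_defaults()
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("configuration must be a mapping", call. = FALSE)
  bad <- setdiff(names(raw), names(defaults))
  if (length(bad)) {
    stop("unknown configuration section(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  cfg <- defaults
  for (sec in names(raw)) {
    keys <- names(raw[[sec]])
    badk <- setdiff(keys, names(defaults[[sec]]))
    if (length(badk)) {
      stop("unknown configuration key(s): ",
           paste(paste0(sec, ".", badk), collapse = ", "), call. = FALSE)
    }
    cfg[[sec]] <- modifyList(cfg[[sec]], raw[[sec]])
  }
  structure(cfg, class = "lymph_config")
}

#' Realise a configuration into simulator inputs
#'
#' @param cfg A `lymph_config` object.
#' @return A list with `topology`, `schedule`, `bc`, `params`, `settings`.
#' @export
config_inputs <- function(cfg) {
  stopifnot(inherits(cfg, "lymph_config"))
  params <- do.call(lymph_params, cfg$physical)
  topo <- build_network(cfg$network$n_generations, cfg$network$nv)
  sch <- contraction_schedule(topo, cfg$timing$dtv, cfg$timing$dtg,
                              params$Tc, params$tr)
  bc <- boundary_conditions(cfg$boundary$pa_cmH2O, cfg$boundary$pb_cmH2O,
                            cfg$boundary$pe_cmH2O)
  settings <- do.call(solver_settings, cfg$solver)
  list(topology = topo, schedule = sch, bc = bc, params = params,
       settings = settings)
}

#' @rdname load_config
#' @param cfg A `lymph_config` object.
#' @param out Path to write the resolved configuration echo to (YAML).
#' @export
write_config <- function(cfg, out) {
  stopifnot(inherits(cfg, "lymph_config"))
  yaml::write_yaml(unclass(cfg), out, precision = 15)
  invisible(out)
}

#' Write tidy outputs
#'
#' `write_summary_csv()` writes a one-row CSV with the full configuration echo
#' plus `Qbar_ml_hr` and convergence flags; `write_series_csv()` writes the
#' last-cycle time series in long form (`time_s`, `entity_type`, `entity_id`,
#' `variable`, `value`); `write_sweep_csv()` writes a sweep in long form.
#'
#' @param sim A [run_simulation()] result.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_summary_csv <- function(sim, path) {
  stopifnot(inherits(sim, "lymph_sim"))
  row <- glance(sim)
  write.csv(row, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_summary_csv
#' @export
write_series_csv <- function(sim, path) {
  stopifnot(inherits(sim, "lymph_sim"))
  if (is.null(sim$series)) {
    stop("simulation was run with keep_series = FALSE", call. = FALSE)
  }
  write.csv(sim$series, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_summary_csv
#' @param sweep A `lymph_sweep` result.
#' @export
write_sweep_csv <- function(sweep, path) {
  stopifnot(inherits(sweep, "lymph_sweep"))
  out <- dplyr::mutate(tibble::as_tibble(sweep),
                       swept_var = attr(sweep, "swept"), .before = 1)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
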