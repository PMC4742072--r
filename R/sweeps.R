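#' @importFrom tibble tibble as_tibble
NULL

# Shared sweep runner: one simulation per grid value.
.run_sweep <- function(values, swept, config_fn, settings, quiet = TRUE) {
  if (!length(values)) stop("sweep grid must be nonempty", call. = FALSE)
  if (is.unsorted(values, strictly = TRUE) &&
      is.unsorted(rev(values), strictly = TRUE)) {
    stop("sweep grid must be strictly monotone", call. = FALSE)
  }
  rows <- purrr::map(values, function(v) {
    cfg <- config_fn(v)
    res <- tryCatch(
      run_simulation(cfg$topology, cfg$schedule, cfg$bc, cfg$params,
                     settings = settings),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      if (!quiet) message("sweep point ", v, " failed: ",
                          conditionMessage(res))
      tibble(value = v, qbar_ml_hr = NA_real_, converged = FALSE,
             n_cycles = NA_integer_)
    } else {
      tibble(value = v, qbar_ml_hr = res$qbar_ml_hr,
             converged = isTRUE(res$converged), n_cycles = res$n_cycles)
    }
  })
  out <- dplyr::bind_rows(rows)
  names(out)[1] <- swept
  structure(out, swept = swept,
            class = c("lymph_sweep", class(tibble::tibble())))
}

#' Pump function curve
#'
#' Mean outlet flow versus the axial pressure difference `dP = pb - pa`, for a
#' 3-generation bifurcating network with `nv` lymphangions per vessel. All
#' other parameters stay at their baseline values unless overridden.
#'
#' @param nv Lymphangions per vessel.
#' @param pb_values Outlet pressures, cmH2O (strictly monotone grid).
#' @param pa,pe Inlet and external pressures, cmH2O.
#' @param dtv,dtg Contraction wave delays, s.
#' @param params A [lymph_params()] object.
#' @param settings A [solver_settings()] object.
#' @param n_generations Tree depth (default 3).
#' @return A `lymph_sweep` tibble with columns `pb_cmH2O`, `dP_cmH2O`,
#'   `qbar_ml_hr`, `converged`, `n_cycles`.
#' @export
pump_function_curve <- function(nv, pb_values, pa = 6, pe = 2, dtv = 0.5,
                                dtg = 0.5, params = lymph_params(),
                                settings = solver_settings(),
                                n_generations = 3) {
  topo <- build_network(n_generations, nv)
  sch <- contraction_schedule(topo, dtv, dtg, params$Tc, params$tr)
  out <- .run_sweep(pb_values, "pb_cmH2O", function(pb) {
    list(topology = topo, schedule = sch,
         bc = boundary_conditions(pa, pb, pe), params = params)
  }, settings)
  out <- dplyr::mutate(out, dP_cmH2O = .data$pb_cmH2O - pa, .after = 1)
  structure(out, swept = "pb_cmH2O", nv = nv,
            class = c("lymph_sweep", class(tibble::tibble())))
}

#' External-pressure (transmural pressure) sweep
#'
#' Mean outlet flow as the steady external pressure varies at fixed axial
#' pressure difference. Reports the transmural-pressure axis `pa - pe`
#' alongside the swept `pe`.
#'
#' @param nv Lymphangions per vessel.
#' @param pe_values External pressures, cmH2O (strictly monotone grid).
#' @param dP Axial pressure difference `pb - pa`, cmH2O.
#' @inheritParams pump_function_curve
#' @return A `lymph_sweep` tibble with columns `pe_cmH2O`, `ptm_cmH2O`
#'   (`pa - pe`), `qbar_ml_hr`, `converged`, `n_cycles`.
#' @export
sweep_external_pressure <- function(nv, pe_values, dP = 3, pa = 6, dtv = 0.5,
                                    dtg = 0.5, params = lymph_params(),
                                    settings = solver_settings(),
                                    n_generations = 3) {
  topo <- build_network(n_generations, nv)
  sch <- contraction_schedule(topo, dtv, dtg, params$Tc, params$tr)
  out <- .run_sweep(pe_values, "pe_cmH2O", function(pe) {
    list(topology = topo, schedule = sch,
         bc = boundary_conditions(pa, pa + dP, pe), params = params)
  }, settings)
  out <- dplyr::mutate(out, ptm_cmH2O = pa - .data$pe_cmH2O, .after = 1)
  structure(out, swept = "pe_cmH2O", nv = nv, dP = dP,
            class = c("lymph_sweep", class(tibble::tibble())))
}

#' Contraction-wave time-delay sweep
#'
#' Mean outlet flow as the joint delay `dtv = dtg` varies over `[0, T]`.
#' Delays below `T/2` correspond to a forward (inlet-to-outlet) propagating
#' contraction wave; larger delays are equivalent to reverse propagation with
#' delay `T - dt` (see [reverse_equivalent_delay()]).
#'
#' @param nv Lymphangions per vessel.
#' @param dt_values Joint delays `dtv = dtg`, s (strictly monotone grid within
#'   `[0, T]`).
#' @param dP Axial pressure difference, cmH2O.
#' @param pe External pressure, cmH2O.
#' @inheritParams pump_function_curve
#' @return A `lymph_sweep` tibble with columns `dt_s`, `direction`,
#'   `reverse_dt_s`, `qbar_ml_hr`, `converged`, `n_cycles`.
#' @export
sweep_time_delay <- function(nv, dt_values, dP = 0, pe = 2, pa = 6,
                             params = lymph_params(),
                             settings = solver_settings(),
                             n_generations = 3) {
  topo <- build_network(n_generations, nv)
  if (any(dt_values < 0 | dt_values > params$T)) {
    stop("delays must lie within [0, T]", call. = FALSE)
  }
  out <- .run_sweep(dt_values, "dt_s", function(dt) {
    list(topology = topo,
         schedule = contraction_schedule(topo, dt, dt, params$Tc, params$tr),
         bc = boundary_conditions(pa, pa + dP, pe), params = params)
  }, settings)
  out <- dplyr::mutate(
    out,
    direction = delay_direction(.data$dt_s, params$Tc, params$tr),
    reverse_dt_s = reverse_equivalent_delay(.data$dt_s, params$Tc, params$tr),
    .after = 1
  )
  structure(out, swept = "dt_s", nv = nv, dP = dP, pe = pe,
            class = c("lymph_sweep", class(tibble::tibble())))
}

#' Diastolic-period sweep
#'
#' Mean outlet flow as the diastolic period `tr` varies. Changing `tr` changes
#' the full cycle `T = Tc + tr`, and hence the modulus of the contraction
#' schedule; the schedule is rebuilt per point.
#'
#' @param nv Lymphangions per vessel.
#' @param tr_values Diastolic periods, s (strictly monotone grid, >= 0).
#' @param pb Outlet pressure, cmH2O.
#' @inheritParams pump_function_curve
#' @return A `lymph_sweep` tibble with columns `tr_s`, `qbar_ml_hr`,
#'   `converged`, `n_cycles`.
#' @export
sweep_diastolic_period <- function(nv, tr_values, pb = 9, pa = 6, pe = 2,
                                   dtv = 0.5, dtg = 0.5,
                                   params = lymph_params(),
                                   settings = solver_settings(),
                                   n_generations = 3) {
  topo <- build_network(n_generations, nv)
  if (any(tr_values < 0)) stop("tr must be >= 0", call. = FALSE)
  out <- .run_sweep(tr_values, "tr_s", function(tr) {
    pars <- do.call(lymph_params, c(
      list(tr = tr),
      .stored_overrides(params, skip = "tr")
    ))
    list(topology = topo,
         schedule = contraction_schedule(topo, dtv, dtg, pars$Tc, pars$tr),
         bc = boundary_conditions(pa, pb, pe), params = pars)
  }, settings)
  structure(out, swept = "tr_s", nv = nv, pb = pb,
            class = c("lymph_sweep", class(tibble::tibble())))
}

# Recover the non-default stored fields of a params object so that a variant
# can be rebuilt with one field changed.
.stored_overrides <- function(params, skip = character()) {
  keep <- setdiff(names(.baseline_physical), skip)
  over <- params[keep]
  over <- over[!purrr::map2_lgl(over, .baseline_physical[keep], identical)]
  c(over, list(c9_mode = params$c9_mode, md_form = params$md_form,
               half_segment = params$half_segment))
}

#' Locate the peak of a sweep
#'
#' Grid argmax of the mean outlet flow over the converged points of a sweep;
#' no interpolation is performed. Ties are broken toward the smaller grid
#' value.
#'
#' @param sweep A `lymph_sweep` result.
#' @return A list with `argmax` (the swept value at the peak), `peak`
#'   (ml/hr) and `swept` (the name of the swept variable).
#' @export
find_peak <- function(sweep) {
  stopifnot(inherits(sweep, "lymph_sweep"))
  swept <- attr(sweep, "swept")
  ok <- !is.na(sweep$qbar_ml_hr)
  if (!any(ok)) stop("no converged sweep points", call. = FALSE)
  vals <- sweep[[swept]][ok]
  q <- sweep$qbar_ml_hr[ok]
  ord <- order(vals)
  vals <- vals[ord]
  q <- q[ord]
  i <- which(q == max(q))[1]  # earliest (smallest grid value) on ties
  list(argmax = vals[i], peak = q[i], swept = swept)
}

#' @export
print.lymph_sweep <- function(x, ...) {
  cat(sprintf("<lymph_sweep> over %s (%d points)\n", attr(x, "swept"),
              nrow(x)))
  NextMethod()
}
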