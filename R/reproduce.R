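#' Regenerate the published result families
#'
#' Drivers that enumerate the simulation conditions of the study's result
#' figures and return long-form tibbles of mean outlet flow. Every family
#' fixes unlisted parameters at baseline. The full grids are large (hundreds
#' of simulations for the complete pump-function family); the grid arguments
#' accept subsets for quicker partial reproduction.
#'
#' * `"fig3"` — pump function curves over network size: `nv` 1-14, outlet
#'   pressure 3-41 cmH2O.
#' * `"fig4"` — external-pressure sweeps: `nv` in (2, 4, 8), `dP` in
#'   (3, 10, 16) cmH2O, `pe` 1-5 cmH2O in 0.2 steps.
#' * `"fig5"` — diastolic-period pump functions: `nv` 4, `tr` 0-3.5 s in 0.5
#'   steps, outlet pressure 3-36 cmH2O.
#' * `"fig6"` — coordination patterns: (`dtv`, `dtg`) in ((0,0), (0,0.5),
#'   (0.5,0.5)), `pe` in (2, 3) cmH2O, outlet pressure 3-36 cmH2O.
#' * `"fig7"` — joint time-delay sweeps: `nv` 4, `dt` 0-3.5 s in 0.05 steps,
#'   `dP` in (-3, 0, 6, 12, 18, 24) cmH2O.
#'
#' @param family One of `"fig3"` to `"fig7"`.
#' @param ... Overrides of the family's grid arguments (see each
#'   `reproduce_*` function).
#' @return A long-form tibble with the swept conditions and `qbar_ml_hr`.
#' @export
reproduce <- function(family = c("fig3", "fig4", "fig5", "fig6", "fig7"),
                      ...) {
  family <- match.arg(family)
  switch(family,
         fig3 = reproduce_network_size(...),
         fig4 = reproduce_external_pressure(...),
         fig5 = reproduce_diastolic_period(...),
         fig6 = reproduce_coordination(...),
         fig7 = reproduce_time_delay(...))
}

#' @rdname reproduce
#' @param nv_values,pb_values,pe_values,dP_values,tr_values,dt_values Grids.
#' @param settings A [solver_settings()] object.
#' @export
reproduce_network_size <- function(nv_values = 1:14,
                                   pb_values = seq(3, 41, by = 1),
                                   settings = solver_settings()) {
  purrr::map_dfr(nv_values, function(nv) {
    sw <- pump_function_curve(nv, pb_values, settings = settings)
    dplyr::mutate(tibble::as_tibble(sw), nv = nv, .before = 1)
  })
}

#' @rdname reproduce
#' @export
reproduce_external_pressure <- function(nv_values = c(2, 4, 8),
                                        dP_values = c(3, 10, 16),
                                        pe_values = seq(1, 5, by = 0.2),
                                        settings = solver_settings()) {
  purrr::map_dfr(nv_values, function(nv) {
    purrr::map_dfr(dP_values, function(dP) {
      sw <- sweep_external_pressure(nv, pe_values, dP = dP,
                                    settings = settings)
      dplyr::mutate(tibble::as_tibble(sw), nv = nv, dP_cmH2O = dP,
                    .before = 1)
    })
  })
}

#' @rdname reproduce
#' @export
reproduce_diastolic_period <- function(tr_values = seq(0, 3.5, by = 0.5),
                                       pb_values = seq(3, 36, by = 1),
                                       settings = solver_settings()) {
  purrr::map_dfr(tr_values, function(tr) {
    sw <- pump_function_curve(4, pb_values, params = lymph_params(tr = tr),
                              settings = settings)
    dplyr::mutate(tibble::as_tibble(sw), tr_s = tr, .before = 1)
  })
}

#' @rdname reproduce
#' @param delay_patterns List of `c(dtv, dtg)` pairs.
#' @export
reproduce_coordination <- function(delay_patterns = list(c(0, 0), c(0, 0.5),
                                                         c(0.5, 0.5)),
                                   pe_values = c(2, 3),
                                   pb_values = seq(3, 36, by = 1),
                                   settings = solver_settings()) {
  purrr::map_dfr(delay_patterns, function(dd) {
    purrr::map_dfr(pe_values, function(pe) {
      sw <- pump_function_curve(4, pb_values, pe = pe, dtv = dd[1],
                                dtg = dd[2], settings = settings)
      dplyr::mutate(tibble::as_tibble(sw), dtv_s = dd[1], dtg_s = dd[2],
                    pe_cmH2O = pe, .before = 1)
    })
  })
}

#' @rdname reproduce
#' @export
reproduce_time_delay <- function(dt_values = seq(0, 3.5, by = 0.05),
                                 dP_values = c(-3, 0, 6, 12, 18, 24),
                                 settings = solver_settings()) {
  purrr::map_dfr(dP_values, function(dP) {
    sw <- sweep_time_delay(4, dt_values, dP = dP, settings = settings)
    dplyr::mutate(tibble::as_tibble(sw), dP_cmH2O = dP, .before = 1)
  })
}
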