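#' Tidy a simulation result
#'
#' Returns the per-cycle mean outlet flows, one row per simulated contraction
#' cycle, in ml/hr — the trace whose stabilisation defines the periodic state.
#'
#' @param x A [run_simulation()] result.
#' @param ... Unused.
#' @return A tibble with columns `cycle` and `qbar_ml_hr`.
#' @export
tidy.lymph_sim <- function(x, ...) x$cycle_means

#' One-row summary of a simulation
#'
#' @param x A [run_simulation()] result.
#' @param ... Unused.
#' @return A one-row tibble echoing the configuration (network size, boundary
#'   pressures, timing) plus `qbar_ml_hr`, `converged` and `n_cycles`.
#' @export
glance.lymph_sim <- function(x, ...) {
  tibble::tibble(
    n_generations = x$topology$n_generations, nv = x$topology$nv,
    pa_cmH2O = x$bc$pa_cmH2O, pb_cmH2O = x$bc$pb_cmH2O,
    pe_cmH2O = x$bc$pe_cmH2O, dP_cmH2O = x$bc$dP_cmH2O,
    tr_s = x$schedule$tr, Tc_s = x$schedule$Tc,
    dtv_s = x$schedule$dtv, dtg_s = x$schedule$dtg,
    Qbar_ml_hr = x$qbar_ml_hr, converged = x$converged,
    n_cycles = x$n_cycles
  )
}

#' @export
tidy.lymph_sweep <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.lymph_sweep <- function(x, ...) {
  pk <- find_peak(x)
  tibble::tibble(swept = attr(x, "swept"), n_points = nrow(x),
                 n_converged = sum(x$converged, na.rm = TRUE),
                 argmax = pk$argmax, peak_ml_hr = pk$peak)
}

#' Plot a sweep
#'
#' Mean outlet flow against the swept variable.
#'
#' @param object A `lymph_sweep` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lymph_sweep <- function(object, ...) {
  swept <- attr(object, "swept")
  lab <- c(pb_cmH2O = "outlet pressure p_b (cmH2O)",
           pe_cmH2O = "external pressure p_e (cmH2O)",
           dt_s = "joint time delay Δt (s)",
           tr_s = "diastolic period t_r (s)")[swept]
  if (is.na(lab)) lab <- swept
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data[[swept]], y = .data$qbar_ml_hr)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$converged)) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                guide = "none") +
    ggplot2::labs(x = lab, y = expression(bar(Q) ~ "(ml/hr)")) +
    ggplot2::theme_minimal()
}

#' Plot the approach to the periodic pumping state
#'
#' Last-cycle outlet flow waveform (top) and the per-cycle mean outlet flow
#' across the whole run (bottom) for a completed simulation.
#'
#' @param object A [run_simulation()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lymph_sim <- function(object, ...) {
  wave <- dplyr::mutate(object$outlet_flow,
                        q_ml_hr = 3600 * .data$q_cm3s)
  ggplot2::ggplot(wave, ggplot2::aes(x = .data$time_s, y = .data$q_ml_hr)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$qbar_ml_hr, linetype = 2) +
    ggplot2::labs(x = "time (s)", y = "outlet flow (ml/hr)",
                  title = sprintf("nv = %d, dP = %g cmH2O: Qbar = %.3f ml/hr",
                                  object$topology$nv, object$bc$dP_cmH2O,
                                  object$qbar_ml_hr)) +
    ggplot2::theme_minimal()
}

#' Plot last-cycle diameter traces
#'
#' Requires `keep_series = TRUE` in [run_simulation()].
#'
#' @param sim A [run_simulation()] result with a stored series.
#' @return A ggplot object faceted by vessel.
#' @export
plot_diameters <- function(sim) {
  stopifnot(inherits(sim, "lymph_sim"))
  if (is.null(sim$series)) {
    stop("simulation was run with keep_series = FALSE", call. = FALSE)
  }
  dd <- dplyr::filter(sim$series, .data$variable == "D_cm")
  dd <- dplyr::mutate(dd, vessel = substr(.data$entity_id, 1, 4))
  ggplot2::ggplot(dd, ggplot2::aes(x = .data$time_s, y = .data$value,
                                   group = .data$entity_id)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::facet_wrap(~vessel) +
    ggplot2::labs(x = "time (s)", y = "diameter (cm)") +
    ggplot2::theme_minimal()
}
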