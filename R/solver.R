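#' Solver settings
#'
#' Controls the stiff integration and the periodic-state detection. The model
#' is integrated cycle by cycle; the run stops once two successive
#' cycle-averaged outlet flows agree within `cycle_rel_tol` (relative) or
#' `cycle_abs_tol_ml_hr` (absolute, for near-zero outputs), after at least
#' `min_cycles` cycles and within at most `max_cycles`.
#'
#' @param rtol,atol Relative/absolute integrator tolerances (atol applies to
#'   diameters, cm).
#' @param method `deSolve` integration method; the dynamics are stiff
#'   (valve resistances span four orders of magnitude), so the default is
#'   `"lsoda"`.
#' @param min_cycles,max_cycles Minimum/maximum number of contraction cycles.
#' @param cycle_rel_tol Relative agreement of successive cycle means that
#'   declares periodic convergence.
#' @param cycle_abs_tol_ml_hr Absolute floor for that comparison, ml/hr.
#' @param pts_per_cycle Output grid points per cycle (used for the
#'   trapezoidal cycle averages and the returned series).
#' @param fixed_cycles If non-`NULL`, integrate exactly this many cycles with
#'   no convergence test (used for fast regression fixtures).
#' @return A `lymph_solver_settings` list.
#' @export
solver_settings <- function(rtol = 1e-6, atol = 1e-10, method = "lsoda",
                            min_cycles = 10, max_cycles = 200,
                            cycle_rel_tol = 0.005,
                            cycle_abs_tol_ml_hr = 2e-4,
                            pts_per_cycle = 80, fixed_cycles = NULL) {
  if (rtol <= 0 || atol <= 0) stop("tolerances must be positive",
                                   call. = FALSE)
  if (min_cycles < 2) stop("min_cycles must be >= 2", call. = FALSE)
  structure(list(rtol = rtol, atol = atol, method = method,
                 min_cycles = min_cycles, max_cycles = max_cycles,
                 cycle_rel_tol = cycle_rel_tol,
                 cycle_abs_tol_ml_hr = cycle_abs_tol_ml_hr,
                 pts_per_cycle = pts_per_cycle, fixed_cycles = fixed_cycles),
            class = "lymph_solver_settings")
}

# Build the C++ model object for a given configuration.
.build_model <- function(topology, schedule, bc, params) {
  stopifnot(inherits(topology, "lymph_topology"), inherits(bc, "lymph_bc"),
            inherits(params, "lymph_params"))
  if (is.null(schedule)) {
    schedule <- contraction_schedule(topology, dtv = 0.5, dtg = 0.5,
                                     Tc = params$Tc, tr = params$tr)
  }
  if (abs(attr(schedule, "T") - params$T) > 1e-12) {
    stop("schedule cycle length (", attr(schedule, "T"),
         " s) does not match params (T = ", params$T, " s)", call. = FALSE)
  }
  segs <- topology$segments
  kind <- c(inlet = 0L, lymph = 1L, junction = 2L, outlet = 3L)
  seg_list <- list(
    up_kind = kind[segs$up_type], up_idx = as.integer(segs$up_id) - 1L,
    dn_kind = kind[segs$down_type], dn_idx = as.integer(segs$down_id) - 1L,
    has_valve = as.integer(segs$has_valve)
  )
  juncs <- list(
    child_seg1 = as.integer(topology$junctions$child_seg1) - 1L,
    child_seg2 = as.integer(topology$junctions$child_seg2) - 1L,
    parent_seg = as.integer(topology$junctions$parent_seg) - 1L
  )
  ptr <- .model_build(.cpp_params(params), seg_list,
                      as.integer(topology$lymphangions$in_seg) - 1L,
                      as.integer(topology$lymphangions$out_seg) - 1L,
                      juncs, schedule$offset, bc$pa, bc$pb, bc$pe)
  list(ptr = ptr, schedule = schedule)
}

#' Flow through one resistive path with an optional valve
#'
#' Solves `Q * (R_up + RV(dp_valve) + R_down) = p_up - p_down` for the flow
#' `Q`, where the valve pressure difference `dp_valve` is the total driving
#' difference less the Poiseuille drops on either side. The valve resistance
#' is bounded, so the root is bracketed and found to high precision; without a
#' valve the flow is the closed-form two-resistor solution.
#'
#' @param p_up,p_down Upstream/downstream pressures, dyn/cm2.
#' @param R_up,R_down Poiseuille half resistances, g/(cm^4 s).
#' @param has_valve Whether a valve lies on this path.
#' @param params A [lymph_params()] object.
#' @return A list with `Q` (cm^3/s), `dp_valve` and `RV`.
#' @export
solve_segment_flow <- function(p_up, p_down, R_up, R_down, has_valve = TRUE,
                               params = lymph_params()) {
  if (R_up < 0 || R_down < 0) stop("resistances must be >= 0", call. = FALSE)
  .core_segment_flow(p_up, p_down, R_up, R_down, has_valve,
                     .cpp_params(params))
}

#' Instantaneous network pressure/flow solution
#'
#' Given all lymphangion diameters at time `t`, computes every midpoint
#' pressure explicitly from the wall force balance and resolves all segment
#' flows and junction pressures by scalar root finding.
#'
#' @param t Time, s.
#' @param D Vector of lymphangion diameters (canonical order), cm.
#' @param topology A [build_network()] object.
#' @param schedule A [contraction_schedule()]; `NULL` for the baseline delays.
#' @param bc A [boundary_conditions()] object.
#' @param params A [lymph_params()] object.
#' @return A list of class `lymph_flow` with tibbles `lymphangions` (diameter,
#'   activation, midpoint/up/down pressures, dD/dt), `segments` (flow, valve
#'   pressure difference, valve resistance) and `junctions` (node pressure),
#'   plus `mass_residual`, the largest junction mass-balance error relative to
#'   the local flow scale.
#' @export
network_flow_solve <- function(t, D, topology, schedule = NULL,
                               bc = boundary_conditions(),
                               params = lymph_params()) {
  if (length(D) != nrow(topology$lymphangions)) {
    stop("D must have one entry per lymphangion", call. = FALSE)
  }
  m <- .build_model(topology, schedule, bc, params)
  sol <- .model_flow(m$ptr, t, D)
  segs <- tibble::tibble(
    seg_id = topology$segments$seg_id,
    role = topology$segments$role,
    has_valve = topology$segments$has_valve,
    Q = sol$Q, dp_valve = ifelse(topology$segments$has_valve, sol$dp_valve,
                                 NA_real_),
    RV = ifelse(topology$segments$has_valve, sol$RV, NA_real_)
  )
  ly <- tibble::tibble(
    lymph_id = topology$lymphangions$lymph_id,
    label = topology$lymphangions$label,
    D = D, Mt = sol$Mt, p_mid = sol$p_mid, p_up = sol$p_up, p_dn = sol$p_dn,
    dDdt = sol$dDdt
  )
  jn <- tibble::tibble(junction_id = topology$junctions$junction_id,
                       p = sol$p_junction)
  resid <- 0
  if (nrow(jn)) {
    for (j in seq_len(nrow(jn))) {
      q1 <- segs$Q[topology$junctions$child_seg1[j]]
      q2 <- segs$Q[topology$junctions$child_seg2[j]]
      qp <- segs$Q[topology$junctions$parent_seg[j]]
      resid <- max(resid, abs(q1 + q2 - qp) /
                     max(abs(q1), abs(q2), abs(qp), 1e-12))
    }
  }
  structure(list(lymphangions = ly, segments = segs, junctions = jn,
                 mass_residual = resid, t = t),
            class = "lymph_flow")
}

#' Diameter rate of change for the whole network
#'
#' Conservation of mass per lymphangion:
#' `dD/dt = 2 * (Q_in - Q_out) / (pi * D * L)`.
#'
#' @inheritParams network_flow_solve
#' @return Numeric vector `dD/dt`, cm/s, in canonical lymphangion order.
#' @export
ode_rhs <- function(t, D, topology, schedule = NULL,
                    bc = boundary_conditions(), params = lymph_params()) {
  m <- .build_model(topology, schedule, bc, params)
  .model_rhs(m$ptr, t, D)
}

#' Simulate a lymphatic network to its periodic pumping state
#'
#' Integrates the stiff diameter ODE system from relaxed passive-equilibrium
#' initial diameters, cycle by cycle, until the cycle-averaged outlet flow
#' stabilises (the initial transient is discarded by this criterion). The
#' reported mean outlet flow is the trapezoidal time average of the flow
#' through the final outlet valve over the last full cycle, in ml/hr.
#'
#' @inheritParams network_flow_solve
#' @param settings A [solver_settings()] object.
#' @param keep_series Keep the last-cycle diameter/flow/pressure series
#'   (tidy tibble) in the result.
#' @param init_diameter Optional vector of initial diameters (cm); defaults to
#'   the passive equilibrium at transmural pressure `pa - pe`.
#' @return An object of class `lymph_sim`: a list with `qbar_ml_hr`,
#'   `converged`, `n_cycles`, per-cycle means `cycle_means`, last-cycle
#'   `outlet_flow`, optional tidy `series`, and the configuration echo.
#' @examples
#' \donttest{
#' topo <- build_network(3, 1)
#' sim <- run_simulation(topo, bc = boundary_conditions(6, 9, 2))
#' sim$qbar_ml_hr
#' }
#' @export
run_simulation <- function(topology, schedule = NULL,
                           bc = boundary_conditions(),
                           params = lymph_params(),
                           settings = solver_settings(),
                           keep_series = FALSE, init_diameter = NULL) {
  m <- .build_model(topology, schedule, bc, params)
  schedule <- m$schedule
  nly <- nrow(topology$lymphangions)
  if (is.null(init_diameter)) {
    y <- rep(passive_equilibrium_diameter(bc$pa - bc$pe, params), nly)
  } else {
    stopifnot(length(init_diameter) == nly, all(init_diameter > 0))
    y <- as.numeric(init_diameter)
  }
  T <- params$T
  pts <- settings$pts_per_cycle
  outlet0 <- as.integer(topology$outlet_seg) - 1L
  rhs <- function(t, y, p) list(.model_rhs(m$ptr, t, y))
  abs_tol_cm3s <- settings$cycle_abs_tol_ml_hr / 3600

  n_cycles <- if (is.null(settings$fixed_cycles)) settings$max_cycles
              else settings$fixed_cycles
  means <- numeric(0)
  converged <- FALSE
  last <- NULL
  for (k in seq_len(n_cycles)) {
    times <- seq((k - 1) * T, k * T, length.out = pts + 1)
    sol <- deSolve::ode(y = y, times = times, func = rhs, parms = NULL,
                        method = settings$method, rtol = settings$rtol,
                        atol = settings$atol)
    if (attr(sol, "istate")[1] < 0) {
      stop("stiff integration failed in cycle ", k, call. = FALSE)
    }
    Dmat <- unname(sol[, -1, drop = FALSE])
    if (any(Dmat <= 0)) stop("negative diameter produced in cycle ", k,
                             call. = FALSE)
    qout <- .model_outlet_flow(m$ptr, sol[, 1], Dmat, outlet0)
    mk <- .trapz_mean(sol[, 1], qout)
    means <- c(means, mk)
    y <- Dmat[nrow(Dmat), ]
    last <- list(times = sol[, 1], D = Dmat, qout = qout)
    if (is.null(settings$fixed_cycles) && k >= settings$min_cycles) {
      prev <- means[k - 1]
      if (abs(mk - prev) < max(settings$cycle_rel_tol * abs(mk),
                               abs_tol_cm3s)) {
        converged <- TRUE
        break
      }
    }
  }
  if (!is.null(settings$fixed_cycles)) converged <- NA

  qbar <- 3600 * means[length(means)]
  series <- NULL
  if (keep_series) series <- .collect_series(m$ptr, topology, last)
  structure(
    list(qbar_ml_hr = qbar, converged = converged, n_cycles = length(means),
         cycle_means = tibble::tibble(cycle = seq_along(means),
                                      qbar_ml_hr = 3600 * means),
         outlet_flow = tibble::tibble(time_s = last$times,
                                      q_cm3s = last$qout),
         series = series,
         final_state = y,
         topology = list(n_generations = topology$n_generations,
                         nv = topology$nv),
         bc = bc, params = params,
         schedule = list(dtv = attr(schedule, "dtv"),
                         dtg = attr(schedule, "dtg"),
                         Tc = attr(schedule, "Tc"),
                         tr = attr(schedule, "tr")),
         settings = settings),
    class = "lymph_sim"
  )
}

.trapz_mean <- function(t, q) {
  n <- length(t)
  sum(diff(t) * (q[-1] + q[-n]) / 2) / (t[n] - t[1])
}

.collect_series <- function(ptr, topology, last) {
  purrr::map_dfr(seq_along(last$times), function(k) {
    sol <- .model_flow(ptr, last$times[k], last$D[k, ])
    dplyr::bind_rows(
      tibble::tibble(time_s = last$times[k], entity_type = "lymphangion",
                     entity_id = topology$lymphangions$label,
                     variable = "D_cm", value = last$D[k, ]),
      tibble::tibble(time_s = last$times[k], entity_type = "segment",
                     entity_id = as.character(topology$segments$seg_id),
                     variable = "Q_cm3s", value = sol$Q),
      tibble::tibble(time_s = last$times[k], entity_type = "node",
                     entity_id = topology$lymphangions$label,
                     variable = "p_dyncm2", value = sol$p_mid)
    )
  })
}

#' Mean outlet flow over the final cycles of a simulation
#'
#' Trapezoidal time average of the outlet-valve flow over the final `n_periods`
#' full cycles of a completed simulation, converted to ml/hr
#' (1 cm^3/s = 3600 ml/hr). With `n_periods = 1` this equals `qbar_ml_hr`
#' stored in the result.
#'
#' @param result A [run_simulation()] result.
#' @param n_periods Number of final cycles to average (integer >= 1; only the
#'   final stored cycle is available unless cycle means are used).
#' @return Mean outlet flow, ml/hr.
#' @export
mean_outlet_flow <- function(result, n_periods = 1) {
  stopifnot(inherits(result, "lymph_sim"))
  if (n_periods != round(n_periods) || n_periods < 1) {
    stop("n_periods must be a positive integer", call. = FALSE)
  }
  if (n_periods == 1) {
    return(3600 * .trapz_mean(result$outlet_flow$time_s,
                              result$outlet_flow$q_cm3s))
  }
  cm <- result$cycle_means$qbar_ml_hr
  if (n_periods > length(cm)) {
    stop("simulation has only ", length(cm), " cycles", call. = FALSE)
  }
  mean(tail(cm, n_periods))
}

#' @export
print.lymph_sim <- function(x, ...) {
  cat(sprintf(
    "<lymph_sim> %d generations, nv = %d | dP = %g cmH2O, pe = %g cmH2O\n",
    x$topology$n_generations, x$topology$nv, x$bc$dP_cmH2O, x$bc$pe_cmH2O))
  cat(sprintf("  Qbar = %.4f ml/hr after %d cycles (%s)\n", x$qbar_ml_hr,
              x$n_cycles,
              if (isTRUE(x$converged)) "converged"
              else if (is.na(x$converged)) "fixed-length run"
              else "NOT converged"))
  invisible(x)
}
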