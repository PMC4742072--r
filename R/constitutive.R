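#' Passive pressure-diameter tube law
#'
#' Transmural pressure sustained passively by the vessel wall at diameter `D`,
#' fitted to isolated rat mesenteric collecting lymphatics. The law is highly
#' nonlinear: a cubic collapse term dominates at small diameters (pressure
#' falls to -Inf as D -> 0) and an exponential stiffening term dominates at
#' large diameters.
#'
#' @param D Diameter(s), cm; must be positive.
#' @param params A [lymph_params()] object.
#' @return Passive transmural pressure, dyn/cm2.
#' @examples
#' p <- lymph_params()
#' passive_pressure(p$c9, p)
#' @export
passive_pressure <- function(D, params = lymph_params()) {
  if (any(!(D > 0))) stop("diameter must be positive", call. = FALSE)
  x <- D / params$c9
  params$Pd * (params$c1 * (x - params$c2)^2 +
               params$c3 * exp(params$c4 * (x - params$c5)) + params$c6 +
               params$c7 * (x - params$c8) + params$c10 * (params$c9 / D)^3)
}

#' Normalized contraction time course
#'
#' Raised-cosine systolic waveform: within a contraction starting at
#' `t_start`, `Mt = (1 - cos(2*pi*f*(t - t_start)))/2`; during the diastolic
#' period that follows, `Mt = 0`. The pattern repeats with period
#' `T = 1/f + tr`.
#'
#' @param t Time(s), s.
#' @param t_start Contraction start time (phase offset), s.
#' @param params A [lymph_params()] object.
#' @return Dimensionless activation in `[0, 1]`.
#' @export
muscle_time_course <- function(t, t_start = 0, params = lymph_params()) {
  tau <- (t - t_start) %% params$T
  ifelse(tau < params$Tc, (1 - cos(2 * pi * params$f * tau)) / 2, 0)
}

#' Diameter-dependent muscle length factor
#'
#' Sigmoidal dependence of active tension on muscle length (vessel diameter):
#' a smooth bump that is ~0 for collapsed or over-distended vessels and
#' saturates near 1 for diameters between `Da = 0.85*c9` and `Db = 2*c9`.
#'
#' @inheritParams passive_pressure
#' @return Dimensionless factor in `(-1, 1)`.
#' @export
muscle_length_factor <- function(D, params = lymph_params()) {
  if (any(!(D > 0))) stop("diameter must be positive", call. = FALSE)
  upper <- if (identical(params$md_form, "literal")) params$Da else params$Db
  stats::plogis(params$sd * (D - params$Da)) +
    stats::plogis(-params$sd * (D - upper)) - 1
}

#' Active pressure generated by muscle contraction
#'
#' Laplace-law conversion of wall tension to pressure:
#' `fa = 2 * M0 * Md(D) * Mt / D`.
#'
#' @inheritParams passive_pressure
#' @param Mt Normalized activation in `[0, 1]` (see [muscle_time_course()]).
#' @return Active pressure, dyn/cm2.
#' @export
active_pressure <- function(D, Mt, params = lymph_params()) {
  if (any(!(D > 0))) stop("diameter must be positive", call. = FALSE)
  2 * params$M0 * muscle_length_factor(D, params) * Mt / D
}

#' Lymphangion midpoint pressure
#'
#' Wall force balance: the internal midpoint pressure is the external pressure
#' plus the passive and active wall contributions,
#' `p_m = pe + fp(D) + fa(D, t)`. This is an explicit function of the state.
#'
#' @inheritParams passive_pressure
#' @param t Time, s.
#' @param t_start Contraction start time of this lymphangion, s.
#' @param pe External pressure, dyn/cm2.
#' @return Midpoint pressure, dyn/cm2.
#' @export
midpoint_pressure <- function(D, t, t_start = 0, pe = 0,
                              params = lymph_params()) {
  pe + passive_pressure(D, params) +
    active_pressure(D, muscle_time_course(t, t_start, params), params)
}

#' Valve resistance
#'
#' Smooth sigmoidal valve law. For a forward pressure difference the
#' resistance is the open value `RVn`; at slightly negative differences
#' (below the closing threshold `dpo`) it transitions to the closed value
#' `RVn + RVx`; at strongly negative differences (below the failure pressure
#' `dpf`) the valve prolapses and the resistance returns to `RVn`.
#'
#' @param dp Pressure difference across the valve (upstream minus
#'   downstream), dyn/cm2.
#' @param params A [lymph_params()] object.
#' @return Resistance, g/(cm^4 s).
#' @export
valve_resistance <- function(dp, params = lymph_params()) {
  params$RVn + params$RVx *
    (stats::plogis(params$sf * (dp - params$dpf)) +
     stats::plogis(-params$so * (dp - params$dpo)) - 1)
}

#' Poiseuille resistance of one lymphangion
#'
#' `Rves = 64 * mu * L / (pi * D^4)` for fully developed laminar flow through
#' a lymphangion of length `L` at diameter `D`.
#'
#' @inheritParams passive_pressure
#' @return Resistance, g/(cm^4 s).
#' @export
poiseuille_resistance <- function(D, params = lymph_params()) {
  if (any(D < 0)) stop("diameter must be nonnegative", call. = FALSE)
  64 * params$mu * params$L / (pi * D^4)
}

#' Invert the passive tube law
#'
#' Diameter at which the passive wall pressure balances a given transmural
#' pressure, used for relaxed-vessel initial conditions. The tube law is
#' strictly increasing on the physiological branch `(0.02*c9, 4*c9)`, so the
#' inverse is computed there by bracketed root finding.
#'
#' @param ptm Transmural pressure(s), dyn/cm2.
#' @param params A [lymph_params()] object.
#' @return Diameter(s), cm.
#' @examples
#' p <- lymph_params()
#' passive_equilibrium_diameter(passive_pressure(p$c9, p), p)
#' @export
passive_equilibrium_diameter <- function(ptm, params = lymph_params()) {
  lo <- 0.02 * params$c9
  hi <- 4 * params$c9
  flo <- passive_pressure(lo, params)
  fhi <- passive_pressure(hi, params)
  vapply(ptm, function(pt) {
    if (pt < flo || pt > fhi) {
      stop("transmural pressure ", pt,
           " dyn/cm2 outside the attainable passive range", call. = FALSE)
    }
    uniroot(function(D) passive_pressure(D, params) - pt,
            lower = lo, upper = hi, tol = 1e-14)$root
  }, numeric(1))
}
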