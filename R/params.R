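#' Convert pressures between cmH2O and dyn/cm2
#'
#' The physiological reporting unit for lymphatic pressures is centimetres of
#' water; all internal computation uses CGS units (dyn/cm2). One cmH2O is
#' taken as 980.665 dyn/cm2 (conventional standard gravity and water density).
#'
#' @param p Numeric vector of pressures.
#' @return Numeric vector of converted pressures.
#' @examples
#' cmh2o_to_dyncm2(1)
#' dyncm2_to_cmh2o(cmh2o_to_dyncm2(-18.4))
#' @export
cmh2o_to_dyncm2 <- function(p) p * 980.665

#' @rdname cmh2o_to_dyncm2
#' @export
dyncm2_to_cmh2o <- function(p) p / 980.665

# Baseline parameter set: rat mesenteric collecting lymphatic vessel,
# pressures in the units in which they are conventionally reported.
.baseline_physical <- list(
  mu = 0.01,          # fluid viscosity, g/(cm s)
  L = 0.3,            # lymphangion length, cm
  Pd = 732,           # tube-law pressure scale, dyn/cm2
  Dd = 0.00845,       # tube-law diameter constant, cm
  M0 = 250,           # active tension scale, dyn/cm
  f = 0.5,            # contraction frequency, Hz (systole lasts 1/f s)
  tr = 1.5,           # diastolic (refractory) period, s
  RVn = 0.5e6,        # minimum (open) valve resistance, g/(cm^4 s)
  RVx = 9.9e9,        # maximum (closed) valve resistance, g/(cm^4 s)
  sf = 0.049,         # valve failure (prolapse) slope, cm2/dyn
  so = 0.4,           # valve closing slope, cm2/dyn
  dpf_cmH2O = -18.4,  # valve failure pressure, cmH2O
  dpo_dyncm2 = -15,   # valve closing threshold, dyn/cm2
  c1 = -2.34457751, c2 = 1.1262924, c3 = 3.76013762, c4 = 79.991135,
  c5 = 1.0028029, c6 = 1.59133174, c7 = 3.69692633, c8 = 0.20699868,
  c10 = -0.0180867408, c11 = 0.32538081
)

#' Physical parameters of the lymphangion model
#'
#' Builds the unit-consistent parameter record used by every constitutive
#' relation and by the network simulator. All values default to the baseline
#' rat mesenteric set; any stored field can be overridden by name. Derived
#' quantities (the characteristic diameter `c9`, muscle-length slope
#' `sd = 3.25/Dd`, the active-tension support bounds `Da = 0.85*c9` and
#' `Db = 2*c9`, the valve failure pressure in dyn/cm2, the contraction period
#' `Tc = 1/f` and the full cycle `T = Tc + tr`) are always recomputed and are
#' never stored in configuration files.
#'
#' @param ... Named overrides of stored fields (`mu`, `L`, `Pd`, `Dd`, `M0`,
#'   `f`, `tr`, `RVn`, `RVx`, `sf`, `so`, `dpf_cmH2O`, `dpo_dyncm2`,
#'   `c1`..`c8`, `c10`, `c11`).
#' @param c9_mode How to resolve the characteristic tube-law diameter from
#'   `Dd` and `c11`: `"ratio"` gives `c9 = Dd/c11` (~260 um, physiological and
#'   the default); `"product"` gives `Dd*c11` (~27 um), retained for audit.
#' @param md_form `"bump"` uses a second sigmoid centred at `Db`, giving an
#'   active-tension bump supported on `[Da, Db]`; `"literal"` centres both
#'   sigmoids at `Da`, which cancels identically to zero (retained for audit).
#' @param half_segment If `TRUE`, each half-lymphangion pressure drop uses the
#'   Poiseuille resistance of half the lymphangion length; the default uses
#'   the full length in each half drop.
#' @return An object of class `lymph_params`: a named list with stored and
#'   derived fields.
#' @examples
#' p <- lymph_params()
#' p$c9
#' lymph_params(tr = 0.5, f = 0.8)$T
#' @export
lymph_params <- function(..., c9_mode = c("ratio", "product"),
                         md_form = c("bump", "literal"),
                         half_segment = FALSE) {
  c9_mode <- match.arg(c9_mode)
  md_form <- match.arg(md_form)
  over <- list(...)
  bad <- setdiff(names(over), names(.baseline_physical))
  if (length(bad)) {
    stop("unknown physical parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  p <- modifyList(.baseline_physical, over)
  p$c9_mode <- c9_mode
  p$md_form <- md_form
  p$half_segment <- isTRUE(half_segment)
  p$c9 <- if (c9_mode == "ratio") p$Dd / p$c11 else p$Dd * p$c11
  p$sd <- 3.25 / p$Dd
  p$Da <- 0.85 * p$c9
  p$Db <- 2 * p$c9
  p$dpf <- cmh2o_to_dyncm2(p$dpf_cmH2O)
  p$dpo <- p$dpo_dyncm2
  p$Tc <- 1 / p$f
  p$T <- p$Tc + p$tr
  validate_lymph_params(p)
  structure(p, class = "lymph_params")
}

validate_lymph_params <- function(p) {
  pos <- c("mu", "L", "Pd", "Dd", "RVn", "RVx", "f", "sf", "so")
  for (nm in pos) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !(p[[nm]] > 0)) {
      stop("parameter '", nm, "' must be a positive scalar", call. = FALSE)
    }
  }
  if (p$tr < 0) stop("diastolic period 'tr' must be >= 0", call. = FALSE)
  if (p$RVx <= p$RVn) stop("RVx must exceed RVn", call. = FALSE)
  if (!(p$dpf < p$dpo && p$dpo < 0)) {
    stop("valve thresholds must satisfy dpf < dpo < 0 (in dyn/cm2)",
         call. = FALSE)
  }
  invisible(p)
}

#' @export
print.lymph_params <- function(x, ...) {
  cat("<lymph_params>\n")
  cat(sprintf("  tube law: Pd = %g dyn/cm2, c9 = %.5f cm (%s form)\n",
              x$Pd, x$c9, x$c9_mode))
  cat(sprintf("  muscle:   M0 = %g dyn/cm, f = %g Hz, tr = %g s (T = %g s)\n",
              x$M0, x$f, x$tr, x$T))
  cat(sprintf("  valve:    RVn = %.3g, RVx = %.3g g/(cm^4 s); dpf = %.4g, dpo = %.4g dyn/cm2\n",
              x$RVn, x$RVx, x$dpf, x$dpo))
  cat(sprintf("  fluid:    mu = %g g/(cm s), L = %g cm\n", x$mu, x$L))
  invisible(x)
}

# Flat list in the layout the C++ core expects.
.cpp_params <- function(params) {
  list(mu = params$mu, L = params$L, Pd = params$Pd, M0 = params$M0,
       f = params$f, tr = params$tr, RVn = params$RVn, RVx = params$RVx,
       sf = params$sf, so = params$so, dpf = params$dpf, dpo = params$dpo,
       c1 = params$c1, c2 = params$c2, c3 = params$c3, c4 = params$c4,
       c5 = params$c5, c6 = params$c6, c7 = params$c7, c8 = params$c8,
       c10 = params$c10, c9 = params$c9, sd = params$sd,
       Da = params$Da, Db = params$Db,
       md_literal = identical(params$md_form, "literal"),
       half_segment = isTRUE(params$half_segment))
}
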