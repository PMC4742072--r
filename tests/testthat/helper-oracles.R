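# Independent oracles: literal re-evaluations of the model's printed
# formulas and brute-force solvers. These share no code with the package
# implementation paths they check.

oracle_fp <- function(D, p) {
  p$Pd * (p$c1 * (D / p$c9 - p$c2)^2 +
            p$c3 * exp(p$c4 * (D / p$c9 - p$c5)) + p$c6 +
            p$c7 * (D / p$c9 - p$c8) + p$c10 * (p$c9 / D)^3)
}

oracle_mt <- function(t, t_start, p) {
  T <- 1 / p$f + p$tr
  tau <- (t - t_start) - floor((t - t_start) / T) * T
  if (tau <= 1 / p$f) (1 - cos(2 * pi * p$f * tau)) / 2 else 0
}

oracle_md <- function(D, p) {
  1 / (1 + exp(-p$sd * (D - p$Da))) + 1 / (1 + exp(p$sd * (D - p$Db))) - 1
}

oracle_fa <- function(D, t, t_start, p) {
  2 * p$M0 * oracle_md(D, p) * oracle_mt(t, t_start, p) / D
}

oracle_rv <- function(dp, p) {
  p$RVn + p$RVx * (1 / (1 + exp(-p$sf * (dp - p$dpf))) +
                     1 / (1 + exp(p$so * (dp - p$dpo))) - 1)
}

oracle_rves <- function(D, p) 64 * p$mu * p$L / (pi * D^4)

# Brute-force valved-segment flow: bisection on
# g(Q) = Q * (Rs + RV(dp_total - Rs*Q)) - dp_total over a sign-changing
# bracket, refined to near machine precision.
oracle_segment_flow <- function(p_up, p_down, R_up, R_down, p) {
  dpt <- p_up - p_down
  if (dpt == 0) return(0)
  Rs <- R_up + R_down
  g <- function(Q) Q * (Rs + oracle_rv(dpt - Rs * Q, p)) - dpt
  qb <- dpt / (Rs + 0.5 * p$RVn)
  lo <- min(0, qb)
  hi <- max(0, qb)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (g(mid) * g(lo) <= 0) hi <- mid else lo <- mid
    if (hi - lo < 1e-16 * max(abs(lo), abs(hi), 1e-300)) break
  }
  (lo + hi) / 2
}

# Monolithic network flow oracle: solves the full simultaneous system of
# momentum and junction mass-balance equations with one damped Newton
# iteration on the complete residual vector. The unknowns are the pressure
# difference across every valve plus every junction pressure (all on the
# same pressure scale, which keeps the Jacobian well conditioned); each
# valved flow follows explicitly as Q = dpv / RV(dpv). Midpoint pressures
# come from the wall force balance through the package's exported scalar
# functions, which are themselves oracle-checked against the formulas above.
monolithic_flow_oracle <- function(t, D, topo, sched, bc, params,
                                   tol = 1e-9, max_iter = 300) {
  segs <- topo$segments
  nseg <- nrow(segs)
  njunc <- nrow(topo$junctions)
  nly <- nrow(topo$lymphangions)
  pm <- vapply(seq_len(nly), function(i) {
    midpoint_pressure(D[i], t, sched$offset[i], bc$pe, params)
  }, numeric(1))
  rv_half <- poiseuille_resistance(D, params) *
    (if (isTRUE(params$half_segment)) 0.5 else 1)

  val <- which(segs$has_valve)
  pla <- which(!segs$has_valve)
  nval <- length(val)
  # static node pressures (junction entries filled per evaluation)
  p_of <- function(type, id, pJ) {
    ifelse(type == "inlet", bc$pa,
           ifelse(type == "outlet", bc$pb,
                  ifelse(type == "lymph", pm[pmax(id, 1)], pJ[pmax(id, 1)])))
  }
  r_of <- function(type, id) ifelse(type == "lymph", rv_half[pmax(id, 1)], 0)
  Ru <- r_of(segs$up_type, segs$up_id)
  Rd <- r_of(segs$down_type, segs$down_id)
  Rs <- Ru + Rd

  flows <- function(z) {
    dpv <- z[seq_len(nval)]
    pJ <- z[nval + seq_len(njunc)]
    pu <- p_of(segs$up_type, segs$up_id, pJ)
    pd <- p_of(segs$down_type, segs$down_id, pJ)
    Q <- numeric(nseg)
    Q[val] <- dpv / oracle_rv(dpv, params)
    Q[pla] <- (pu[pla] - pd[pla]) / Rs[pla]
    list(Q = Q, pu = pu, pd = pd, dpv = dpv)
  }
  resid <- function(z) {
    fl <- flows(z)
    r_mom <- (fl$pu[val] - fl$pd[val]) - fl$Q[val] * Rs[val] - fl$dpv
    r_mass <- fl$Q[topo$junctions$child_seg1] +
      fl$Q[topo$junctions$child_seg2] - fl$Q[topo$junctions$parent_seg]
    c(r_mom, r_mass * 1e7)  # bring mass rows to the pressure scale
  }

  pJ0 <- rep(mean(pm), njunc)
  pu0 <- p_of(segs$up_type, segs$up_id, pJ0)
  pd0 <- p_of(segs$down_type, segs$down_id, pJ0)
  dp0 <- (pu0 - pd0)[val]
  dpv0 <- dp0 * oracle_rv(dp0, params) / (Rs[val] + oracle_rv(dp0, params))
  z <- c(dpv0, pJ0)
  r <- resid(z)
  it <- 0
  n <- length(z)
  for (it in seq_len(max_iter)) {
    if (max(abs(r)) < tol * max(abs(pm), 1)) break
    J <- matrix(0, n, n)
    for (k in seq_len(n)) {
      h <- 1e-6 * max(abs(z[k]), 1)
      zp <- z
      zp[k] <- zp[k] + h
      J[, k] <- (resid(zp) - r) / h
    }
    dz <- tryCatch(solve(J, -r), error = function(e) NULL)
    mu <- 1e-10 * max(abs(J))
    while (is.null(dz)) {
      dz <- tryCatch(solve(crossprod(J) + mu * diag(n), -crossprod(J, r)),
                     error = function(e) NULL)
      mu <- mu * 100
    }
    lam <- 1
    repeat {
      zn <- z + lam * dz
      r2 <- resid(zn)
      if (all(is.finite(r2)) &&
          (sqrt(sum(r2^2)) < sqrt(sum(r^2)) || lam < 1e-14)) break
      lam <- lam / 2
    }
    z <- zn
    r <- r2
  }
  fl <- flows(z)
  list(Q = fl$Q, p_junction = z[nval + seq_len(njunc)],
       resid = r, iters = it,
       converged = max(abs(r)) < tol * max(abs(pm), 1))
}

# Deterministic random network states for oracle comparisons. Diameters are
# drawn from the band actually visited at physiological transmural pressures
# (the exponential wall term makes the tube law astronomically stiff beyond
# ~1.1 c9, so wider draws are unreachable states with pressures ~1e30).
random_state <- function(topo, params, seed) {
  set.seed(seed)
  n <- nrow(topo$lymphangions)
  list(D = runif(n, 0.6 * params$c9, 1.05 * params$c9),
       t = runif(1, 0, params$T))
}
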