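params <- lymph_params()

test_that("pressure unit conversion is definitional and round-trips", {
  expect_identical(cmh2o_to_dyncm2(0), 0)
  expect_equal(cmh2o_to_dyncm2(1), 980.665)
  expect_equal(cmh2o_to_dyncm2(-18.4), -18044.236)
  x <- c(-20, -3.5, 0, 2, 17)
  expect_equal(dyncm2_to_cmh2o(cmh2o_to_dyncm2(x)), x)
})

test_that("derived parameters take their documented values", {
  expect_equal(params$c9, 0.00845 / 0.32538081)
  expect_equal(params$sd, 3.25 / 0.00845)
  expect_equal(params$Da, 0.85 * params$c9)
  expect_equal(params$Db, 2 * params$c9)
  expect_equal(params$T, 3.5)
  # alternative c9 reading retained behind the switch
  expect_equal(lymph_params(c9_mode = "product")$c9, 0.00845 * 0.32538081)
})

test_that("parameter invariants are enforced", {
  expect_error(lymph_params(mu = -1), "positive")
  expect_error(lymph_params(RVx = 1e5), "RVx")
  expect_error(lymph_params(dpo_dyncm2 = 5), "dpf < dpo < 0")
  expect_error(lymph_params(viscocity = 0.01), "viscocity")
})

test_that("passive tube law matches its hand-derived anchor and limits", {
  # sum of the five terms at D = c9 with the baseline constants
  expect_equal(passive_pressure(params$c9, params), 5469.818, tolerance = 1e-6)
  expect_lt(passive_pressure(0.05 * params$c9, params), -1e5)  # collapse
  expect_gt(passive_pressure(3 * params$c9, params), 1e10)     # stiffening
  expect_error(passive_pressure(-0.01, params), "positive")
})

test_that("passive tube law is strictly increasing on the working branch", {
  D <- seq(0.02, 4, length.out = 4001) * params$c9
  expect_true(all(diff(passive_pressure(D, params)) > 0))
})

test_that("contraction waveform has the right anchors, period, continuity", {
  expect_equal(muscle_time_course(0, 0, params), 0)
  expect_equal(muscle_time_course(1, 0, params), 1)  # t_start + 1/(2f)
  expect_equal(muscle_time_course(2.75, 0, params), 0)  # mid-diastole
  t <- seq(0, 7, by = 0.01)
  expect_equal(muscle_time_course(t + params$T, 0.3, params),
               muscle_time_course(t, 0.3, params))
  # continuous at the systole/diastole boundary
  eps <- 1e-9
  expect_lt(abs(muscle_time_course(params$Tc - eps, 0, params)), 1e-8)
  expect_true(all(muscle_time_course(t, 0.7, params) >= 0 &
                    muscle_time_course(t, 0.7, params) <= 1))
})

test_that("muscle length factor peaks between Da and Db and vanishes outside", {
  expect_equal(muscle_length_factor(params$Da, params), 0.4999897,
               tolerance = 1e-6)
  mid <- (params$Da + params$Db) / 2
  expect_equal(muscle_length_factor(mid, params), 1, tolerance = 0.01)
  expect_lt(abs(muscle_length_factor(1e-4, params)), 1e-3)
  expect_lt(abs(muscle_length_factor(5 * params$c9, params)), 1e-3)
  # as literally printed the two sigmoids cancel identically
  lit <- lymph_params(md_form = "literal")
  D <- seq(0.5, 1.5, length.out = 11) * lit$c9
  expect_equal(muscle_length_factor(D, lit), rep(0, 11))
})

test_that("active pressure obeys the Laplace scaling", {
  expect_equal(active_pressure(0.03, 0, params), 0)
  expect_equal(active_pressure(0.025, 1, params),
               2 * 250 * muscle_length_factor(0.025, params) / 0.025)
  # linear in M0 and Mt; 1/D at fixed tension
  p2 <- lymph_params(M0 = 500)
  D <- 0.027
  expect_equal(active_pressure(D, 0.4, p2), 2 * active_pressure(D, 0.4, params))
  expect_equal(active_pressure(D, 0.8, params),
               2 * active_pressure(D, 0.4, params))
  fa_over_tension <- function(D) {
    active_pressure(D, 1, params) * D / muscle_length_factor(D, params)
  }
  expect_equal(fa_over_tension(0.02), fa_over_tension(0.04))
})

test_that("midpoint pressure composes the wall force balance", {
  pe <- cmh2o_to_dyncm2(2)
  expect_equal(midpoint_pressure(params$c9, t = 2.5, t_start = 0, pe = pe,
                                 params = params),
               pe + 5469.818, tolerance = 1e-6)  # Mt = 0 in diastole
  # additivity in pe at fixed state
  expect_equal(
    midpoint_pressure(0.025, 0.8, 0, pe + 500, params) -
      midpoint_pressure(0.025, 0.8, 0, pe, params), 500)
  # inverse consistency through the equilibrium diameter
  ptm <- cmh2o_to_dyncm2(3)
  D <- passive_equilibrium_diameter(ptm, params)
  expect_equal(midpoint_pressure(D, 2.5, 0, pe, params), pe + ptm)
})

test_that("valve resistance has its three regimes and stays bounded", {
  expect_equal(valve_resistance(1e4, params), params$RVn,
               tolerance = 1e-3)  # open
  expect_equal(valve_resistance(params$dpo, params), 4.9505e9,
               tolerance = 1e-3)  # half-closed at the closing threshold
  expect_equal(valve_resistance(-3e4, params), params$RVn,
               tolerance = 1e-3)  # prolapsed (failed open)
  dp <- seq(-5e4, 5e4, length.out = 20001)
  rv <- valve_resistance(dp, params)
  expect_true(all(rv >= params$RVn - 1e-6 * params$RVx))
  expect_true(all(rv <= params$RVn + params$RVx))
})

test_that("Poiseuille resistance follows the D^-4 law", {
  expect_equal(poiseuille_resistance(0.025, params),
               64 * 0.01 * 0.3 / (pi * 0.025^4))
  expect_equal(poiseuille_resistance(0.05, params),
               poiseuille_resistance(0.025, params) / 16)
  pL <- lymph_params(L = 0.6)
  expect_equal(poiseuille_resistance(0.025, pL),
               2 * poiseuille_resistance(0.025, params))
})

test_that("passive equilibrium diameter inverts the tube law", {
  expect_equal(
    passive_equilibrium_diameter(passive_pressure(params$c9, params), params),
    params$c9, tolerance = 1e-10)
  # round trip over 100 random attainable pressures
  set.seed(11)
  ptm <- runif(100, passive_pressure(0.3 * params$c9, params),
               passive_pressure(1.2 * params$c9, params))
  D <- passive_equilibrium_diameter(ptm, params)
  expect_equal(passive_pressure(D, params), ptm, tolerance = 1e-9)
  expect_error(passive_equilibrium_diameter(-1e7, params), "attainable")
})

test_that("equilibrium diameter agrees with a dense-grid bisection oracle", {
  grid_oracle <- function(pt) {
    D <- seq(0.1 * params$c9, 4 * params$c9, length.out = 2000)
    i <- which(diff(sign(oracle_fp(D, params) - pt)) != 0)[1]
    lo <- D[i]; hi <- D[i + 1]
    for (k in 1:100) {
      mid <- (lo + hi) / 2
      if ((oracle_fp(mid, params) - pt) * (oracle_fp(lo, params) - pt) <= 0) {
        hi <- mid
      } else {
        lo <- mid
      }
    }
    (lo + hi) / 2
  }
  for (pt in c(-500, 1000, 3923, 9000)) {
    expect_equal(passive_equilibrium_diameter(pt, params), grid_oracle(pt),
                 tolerance = 1e-8)
  }
})

test_that("all constitutive relations agree with literal formula oracles", {
  set.seed(42)
  n <- 1000
  D <- runif(n, 0.3 * params$c9, 1.2 * params$c9)
  t <- runif(n, -5, 10)
  ts <- runif(n, 0, params$T)
  dp <- runif(n, -2e4, 2e4)
  expect_equal(passive_pressure(D, params), oracle_fp(D, params),
               tolerance = 1e-12)
  expect_equal(muscle_time_course(t, ts, params),
               purrr::map2_dbl(t, ts, oracle_mt, p = params),
               tolerance = 1e-12)
  expect_equal(muscle_length_factor(D, params), oracle_md(D, params),
               tolerance = 1e-12)
  mtv <- purrr::map2_dbl(t, ts, oracle_mt, p = params)
  expect_equal(active_pressure(D, mtv, params),
               purrr::pmap_dbl(list(D, t, ts), oracle_fa, p = params),
               tolerance = 1e-12)
  expect_equal(valve_resistance(dp, params), oracle_rv(dp, params),
               tolerance = 1e-12)
  expect_equal(poiseuille_resistance(D, params), oracle_rves(D, params),
               tolerance = 1e-12)
})
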