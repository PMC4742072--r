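params <- lymph_params()

test_that("a passive network conducts forward and blocks adverse gradients", {
  passive <- lymph_params(M0 = 1e-12)
  topo <- build_network(3, 1)
  # favorable gradient: steady forward conduction
  fav <- run_simulation(topo, bc = boundary_conditions(6, 3, 2),
                        params = passive)
  expect_gt(fav$qbar_ml_hr, 0.5)
  q <- fav$outlet_flow$q_cm3s
  expect_lt(diff(range(q)) / mean(q), 1e-3)  # essentially constant
  # adverse gradient: valves shut, no pumping without muscle
  adv <- run_simulation(topo, bc = boundary_conditions(6, 9, 2),
                        params = passive)
  expect_lt(abs(adv$qbar_ml_hr), 1e-3)
})

test_that("mean outlet flow is a trapezoidal average in ml/hr", {
  fake <- structure(list(
    outlet_flow = tibble::tibble(time_s = seq(0, 3.5, length.out = 71),
                                 q_cm3s = rep(2e-4, 71)),
    cycle_means = tibble::tibble(cycle = 1:3,
                                 qbar_ml_hr = c(0.9, 0.72, 0.7201))
  ), class = "lymph_sim")
  expect_equal(mean_outlet_flow(fake), 0.72)
  t <- seq(0, 3.5, length.out = 351)
  fake$outlet_flow <- tibble::tibble(time_s = t,
                                     q_cm3s = sin(2 * pi * t / 3.5))
  expect_equal(mean_outlet_flow(fake), 0, tolerance = 1e-10)
  expect_error(mean_outlet_flow(fake, n_periods = 1.5), "positive integer")
  expect_error(mean_outlet_flow(fake, n_periods = 5), "only 3 cycles")
})

test_that("cycle averages stabilise: 2- vs 4-cycle windows agree", {
  topo <- build_network(3, 1)
  sim <- run_simulation(topo, bc = boundary_conditions(6, 9, 2),
                        params = params)
  expect_true(sim$converged)
  m2 <- mean_outlet_flow(sim, n_periods = 2)
  m4 <- mean_outlet_flow(sim, n_periods = 4)
  expect_equal(m2, m4, tolerance = 5e-3)
  expect_equal(mean_outlet_flow(sim), sim$qbar_ml_hr)
})

test_that("the periodic state forgets phase and initial conditions", {
  topo <- build_network(3, 2)
  bc <- boundary_conditions(6, 9, 2)
  sch <- contraction_schedule(topo, 0.5, 0.5, params$Tc, params$tr)
  base <- run_simulation(topo, sch, bc, params)
  # global phase shift of every contraction start
  shifted <- sch
  shifted$offset <- (shifted$offset + 0.7) %% params$T
  sim_shift <- run_simulation(topo, shifted, bc, params)
  expect_equal(sim_shift$qbar_ml_hr, base$qbar_ml_hr, tolerance = 0.01)
  # perturbed initial diameters
  n <- nrow(topo$lymphangions)
  D0 <- rep(passive_equilibrium_diameter(bc$pa - bc$pe, params), n) * 1.08
  sim_pert <- run_simulation(topo, sch, bc, params, init_diameter = D0)
  expect_equal(sim_pert$qbar_ml_hr, base$qbar_ml_hr, tolerance = 0.01)
})

test_that("mass is conserved globally at the periodic state", {
  topo <- build_network(3, 2)
  sim <- run_simulation(topo, bc = boundary_conditions(6, 9, 2),
                        params = params, keep_series = TRUE)
  expect_true(sim$converged)
  qseg <- dplyr::filter(sim$series, .data$entity_type == "segment")
  mean_q <- function(sid) {
    x <- dplyr::filter(qseg, .data$entity_id == as.character(sid))
    sum(diff(x$time_s) * (x$value[-1] + x$value[-nrow(x)]) / 2) /
      diff(range(x$time_s))
  }
  inflow <- sum(vapply(topo$inlet_segs, mean_q, numeric(1)))
  outflow <- mean_q(topo$outlet_seg)
  expect_equal(inflow, outflow, tolerance = 5e-3)
  # diameters never go nonpositive
  dser <- dplyr::filter(sim$series, .data$variable == "D_cm")
  expect_gt(min(dser$value), 0)
})

test_that("the reported flow matches the outlet lymphangion mid-segment mean", {
  # at periodic steady state the outlet-valve and outlet-midpoint means agree
  topo <- build_network(3, 1)
  sim <- run_simulation(topo, bc = boundary_conditions(6, 9, 2),
                        params = params, keep_series = TRUE)
  qseg <- dplyr::filter(sim$series, .data$entity_type == "segment")
  out_lymph <- nrow(topo$lymphangions)
  in_seg <- topo$lymphangions$in_seg[out_lymph]
  mean_q <- function(sid) {
    x <- dplyr::filter(qseg, .data$entity_id == as.character(sid))
    3600 * sum(diff(x$time_s) * (x$value[-1] + x$value[-nrow(x)]) / 2) /
      diff(range(x$time_s))
  }
  expect_equal(mean_q(in_seg), sim$qbar_ml_hr, tolerance = 5e-3)
})

test_that("tightening integrator tolerances leaves the output unchanged", {
  topo <- build_network(3, 1)
  bc <- boundary_conditions(6, 9, 2)
  loose <- run_simulation(topo, bc = bc, params = params,
                          settings = solver_settings(rtol = 1e-6,
                                                     atol = 1e-10,
                                                     fixed_cycles = 8))
  tight <- run_simulation(topo, bc = bc, params = params,
                          settings = solver_settings(rtol = 1e-8,
                                                     atol = 1e-12,
                                                     fixed_cycles = 8))
  expect_equal(loose$qbar_ml_hr, tight$qbar_ml_hr, tolerance = 1e-3)
})

test_that("simulation results carry a tidy interface", {
  topo <- build_network(2, 1)
  sim <- run_simulation(topo, bc = boundary_conditions(6, 9, 2),
                        params = params,
                        settings = solver_settings(fixed_cycles = 3))
  td <- tidy(sim)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("cycle", "qbar_ml_hr"))
  expect_equal(nrow(td), 3)
  gl <- glance(sim)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$nv, 1)
  expect_equal(gl$dP_cmH2O, 3)
  expect_equal(gl$Qbar_ml_hr, sim$qbar_ml_hr)
  p <- autoplot(sim)
  expect_s3_class(p, "ggplot")
})
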