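# Frozen regression configurations: short fixed-length runs (6 cycles,
# deterministic) spanning the studied condition space. regression_qbar()
# recomputes the mean outlet flow for one row of the fixture table.
regression_qbar <- function(row) {
  params <- lymph_params(tr = row$tr, f = row$f)
  topo <- build_network(3, row$nv)
  sch <- contraction_schedule(topo, row$dtv, row$dtg, params$Tc, params$tr)
  sim <- run_simulation(topo, sch, boundary_conditions(6, row$pb, row$pe),
                        params, solver_settings(fixed_cycles = 6))
  sim$qbar_ml_hr
}
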