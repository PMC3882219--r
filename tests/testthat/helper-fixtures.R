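# shared fixtures: default parameter set and config, plus a coarse solver
# step that still divides the arrest duration exactly
default_p <- model_params()
default_cfg <- resolve_config()
dt_fast <- 0.02

# drug-free logistic run used by several tests
logistic_run <- function(p = default_p, T0 = 50, horizon = 28,
                         dt = dt_fast) {
  simulate_model(p, list(), system_state(p, T0), t0 = 19,
                 horizon = horizon, dt = dt)
}
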