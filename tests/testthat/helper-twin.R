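# Shared fixtures: the default twin and a noiseless variant for exact checks.

noiseless_config <- function(...) {
  cfg <- default_config()
  cfg$calibration$trace_noise_sd <- 0
  extra <- list(...)
  for (nm in names(extra)) cfg$calibration[[nm]] <- extra[[nm]]
  cfg
}

# Full synthesis path for one flowrate: train -> 3 injections -> trace.
make_trace <- function(q_gold, cal = calibration_model(),
                       flows = flow_settings(), duration = 2,
                       seed = NULL, noise = TRUE) {
  train <- generate_droplets(flows, cal, duration)
  train <- inject_all(train, q_gold, cal)
  synth_trace(train, q_gold, cal, flows, duration = duration,
              seed = seed, noise = noise)
}
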