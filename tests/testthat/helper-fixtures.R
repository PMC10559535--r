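# standard-shape curve (15000 samples @ 125 Hz) from a function of time
curve_from_fun <- function(f, rate = 125, n = 15000L, ...) {
  t <- (seq_len(n) - 1L) / rate
  response_curve(f(t), sample_rate = rate, ...)
}

# a small desk-scale synthetic cohort shared by dataset tests
desk_config <- function(seed = 101L) {
  synthetic_config(n_patients_per_class = 2L, containers_per_patient = 1L,
                   acquisitions_per_container = 1L, seed = seed)
}

# all (model, gas) calibrations with alpha != 0
invertible_calibrations <- function(models = sensor_models()) {
  out <- list()
  for (m in models) {
    for (cal in m$calibrations) {
      if (cal$available && cal$alpha != 0) {
        out[[paste(m$model_id, cal$gas_name)]] <- cal
      }
    }
  }
  out
}
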