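#' Configuration of the synthetic cohort generator
#'
#' The generator emulates the acquisition format and the redundancy design of
#' a urine-headspace screening study: per class (benign hyperplasia vs
#' prostate cancer) a set of patients, per patient several containers, per
#' container repeated acquisitions, per acquisition 32 sensor curves. Each
#' curve is a baseline plus a double-exponential response peaking near
#' `peak_time`, with the class encoded in the mean peak amplitude, a shared
#' per-patient amplitude offset (so patient-disjoint splitting is a real
#' leakage test) and additive Gaussian sample noise.
#'
#' Defaults mirror the standard study design: 20 patients per class, 4
#' containers, 5 acquisitions (800 files), 15000 samples at 125 Hz over
#' 120 s. Amplitude means of 1.0 V (label 0) and 1.4 V (label 1) against a
#' 0.1 V patient effect give a clearly separable cohort; tighten the gap to
#' emulate a harder problem.
#'
#' @param n_patients_per_class patients per class (default 20).
#' @param containers_per_patient containers per patient (default 4).
#' @param acquisitions_per_container acquisitions per container (default 5).
#' @param sample_rate Hz (default 125).
#' @param duration seconds (default 120; 15000 samples at the default rate).
#' @param baseline_volts pre-injection baseline (default 0.5 V).
#' @param peak_amplitude length-2 vector of mean peak amplitudes in volts for
#'   labels 0 and 1 (default `c(1.0, 1.4)`).
#' @param peak_time mean time of the response maximum in seconds (default 80).
#' @param peak_time_sd per-curve spread of the peak time (default 2 s).
#' @param tau_rise,tau_decay rise and decay time constants in seconds
#'   (defaults 25 and 70; must satisfy `tau_decay > tau_rise`).
#' @param noise_sd additive voltage noise s.d. (default 0.01 V).
#' @param patient_effect_sd s.d. of the per-patient amplitude offset
#'   (default 0.1 V).
#' @param seed generator seed.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_patients_per_class = 20L,
                             containers_per_patient = 4L,
                             acquisitions_per_container = 5L,
                             sample_rate = 125,
                             duration = 120,
                             baseline_volts = 0.5,
                             peak_amplitude = c(1.0, 1.4),
                             peak_time = 80,
                             peak_time_sd = 2,
                             tau_rise = 25,
                             tau_decay = 70,
                             noise_sd = 0.01,
                             patient_effect_sd = 0.1,
                             seed = 1L) {
  stopifnot(all(n_patients_per_class >= 0L), sum(n_patients_per_class) >= 1L,
            containers_per_patient >= 1L,
            acquisitions_per_container >= 1L, sample_rate > 0, duration > 0,
            length(peak_amplitude) == 2L, all(peak_amplitude > 0),
            tau_rise > 0, tau_decay > tau_rise, peak_time > 0,
            peak_time_sd >= 0, noise_sd >= 0, patient_effect_sd >= 0)
  structure(as.list(environment()), class = "synthetic_config")
}

# time from injection to the maximum of exp(-s/td) - exp(-s/tr)
peak_delay <- function(tau_rise, tau_decay) {
  tau_rise * tau_decay / (tau_decay - tau_rise) * log(tau_decay / tau_rise)
}

# deterministic per-socket sensitivity, spanning 0.8-1.2 across the array
socket_gain <- function(socket_index) 0.8 + 0.4 * socket_index / 31

#' Simulate one sensor response curve
#'
#' Draws a double-exponential response
#' \eqn{v(t) = b + a (e^{-(t-t_0)/\tau_d} - e^{-(t-t_0)/\tau_r})/s_{max}}
#' for \eqn{t \ge t_0} (baseline before injection), normalised so the
#' noiseless peak equals `a`; the injection time \eqn{t_0} is placed so the
#' peak lands on the drawn peak time. Amplitude
#' `a = peak_amplitude[class] + patient_effect`, scaled by the socket's
#' deterministic sensitivity. Consumes the R RNG stream (seed it, or go
#' through [simulate_cohort()]).
#'
#' @param class_label 0 or 1.
#' @param patient_effect additive amplitude offset shared by one patient's
#'   curves (volts).
#' @param config a [synthetic_config()].
#' @param socket_index socket 0-31 (sets sensitivity and sensor model).
#' @return a [response_curve()] of `round(duration * sample_rate)` samples.
#' @export
simulate_curve <- function(class_label, patient_effect = 0,
                           config = synthetic_config(), socket_index = 0L) {
  stopifnot(class_label %in% c(0L, 1L), inherits(config, "synthetic_config"))
  n <- round(config$duration * config$sample_rate)
  t <- (seq_len(n) - 1L) / config$sample_rate
  tp <- config$peak_time +
    if (config$peak_time_sd > 0) stats::rnorm(1L, 0, config$peak_time_sd) else 0
  t0 <- tp - peak_delay(config$tau_rise, config$tau_decay)
  s <- pmax(t - t0, 0)
  shape <- exp(-s / config$tau_decay) - exp(-s / config$tau_rise)
  smax <- {
    d <- peak_delay(config$tau_rise, config$tau_decay)
    exp(-d / config$tau_decay) - exp(-d / config$tau_rise)
  }
  a <- (config$peak_amplitude[class_label + 1L] + patient_effect) *
    socket_gain(socket_index)
  v <- config$baseline_volts + a * shape / smax
  if (config$noise_sd > 0) v <- v + stats::rnorm(n, 0, config$noise_sd)
  response_curve(v, sample_rate = config$sample_rate,
                 socket_index = socket_index,
                 model_id = default_socket_map()[socket_index + 1L])
}

#' Simulate a full cohort of acquisition files
#'
#' Writes `patients x containers x acquisitions` acquisition CSV/JSON pairs
#' in the dialect of [read_acquisition()], each holding 32 curves, plus a
#' `manifest.csv` of files, patients and labels. The per-patient amplitude
#' offset is drawn once per patient and shared across all of that patient's
#' files. Fully seeded: the same config regenerates byte-identical files.
#'
#' @param config a [synthetic_config()].
#' @param dir output directory (created if needed).
#' @return the manifest `data.frame` (same columns as [enumerate_cohort()]),
#'   invisibly, with the output `dir` as an attribute.
#' @export
simulate_cohort <- function(config = synthetic_config(), dir = tempfile("cohort")) {
  stopifnot(inherits(config, "synthetic_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- enumerate_cohort(config$n_patients_per_class,
                               config$containers_per_patient,
                               config$acquisitions_per_container)
  with_seed(config$seed, {
    patients <- unique(manifest$patient_id)
    effects <- stats::setNames(
      stats::rnorm(length(patients), 0, config$patient_effect_sd), patients)
    for (i in seq_len(nrow(manifest))) {
      lab <- manifest$label[i]
      eff <- effects[[manifest$patient_id[i]]]
      curves <- vapply(0:31, function(s) {
        simulate_curve(lab, eff, config, socket_index = s)$samples
      }, numeric(round(config$duration * config$sample_rate)))
      write_acquisition(curves, file.path(dir, manifest$file[i]),
                        provenance = list(patient_id = manifest$patient_id[i],
                                          container = manifest$container[i],
                                          acquisition = manifest$acquisition[i],
                                          label = lab),
                        sample_rate = config$sample_rate)
    }
  })
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  attr(manifest, "dir") <- dir
  invisible(manifest)
}
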