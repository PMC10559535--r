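#' A single sensor response curve
#'
#' One socket's voltage trace for one acquisition. The standard acquisition
#' holds 15000 samples spanning 120 s, i.e. a 125 Hz sampling rate; the
#' acquisition reader enforces that shape, while the constructor accepts any
#' positive length so reduced toy curves can be built in examples and tests.
#'
#' @param samples numeric voltage sequence (volts).
#' @param sample_rate samples per second (default 125).
#' @param socket_index socket position 0-31.
#' @param model_id sensor model identifier (see [enose_sensor_models()]).
#' @param provenance list with `patient_id`, `container` (1-4) and
#'   `acquisition` (1-5); may be `NULL` for free-standing curves.
#' @return an object of class `response_curve`.
#' @export
response_curve <- function(samples, sample_rate = 125, socket_index = 0L,
                           model_id = enose_sensor_models()[1L],
                           provenance = NULL) {
  stopifnot(is.numeric(samples), length(samples) > 0L, all(is.finite(samples)),
            sample_rate > 0, socket_index >= 0L, socket_index <= 31L)
  structure(list(samples = as.numeric(samples),
                 sample_rate = sample_rate,
                 socket_index = as.integer(socket_index),
                 model_id = model_id,
                 provenance = provenance),
            class = "response_curve")
}

#' @export
print.response_curve <- function(x, ...) {
  cat(sprintf("<response_curve> %d samples @ %g Hz, socket %d (%s)\n",
              length(x$samples), x$sample_rate, x$socket_index, x$model_id))
  invisible(x)
}

# sample index (1-based) for time t seconds: i = min(round(t*rate), n-1) + 1,
# so sample i sits at time (i-1)/rate and t = 120 s maps onto the final
# sample of a 15000-point 125 Hz trace.
time_index <- function(t, sample_rate, n) {
  pmin(round(t * sample_rate), n - 1L) + 1L
}

# reflect x across both edges by k samples (k < length(x))
reflect_pad <- function(x, k) {
  n <- length(x)
  c(x[(k + 1L):2L], x, x[(n - 1L):(n - k)])
}

#' Smooth and offset-correct a response curve
#'
#' Median filter (despiking) followed by a centred moving average, both with
#' edge reflection, then baseline subtraction: the offset is the mean of the
#' first second of the smoothed trace.
#'
#' @param curve a [response_curve()].
#' @param median_window odd median-filter width in samples (default 5).
#' @param mean_window moving-average width in samples (default 25).
#' @return the preprocessed [response_curve()], same length.
#' @export
preprocess <- function(curve, median_window = 5L, mean_window = 25L) {
  stopifnot(inherits(curve, "response_curve"))
  x <- curve$samples
  n <- length(x)
  if (median_window >= n || mean_window >= n) {
    stop("filter window longer than curve", call. = FALSE)
  }
  if (median_window %% 2L == 0L) {
    stop("median_window must be odd", call. = FALSE)
  }
  if (median_window > 1L) {
    k <- (median_window - 1L) %/% 2L
    padded <- reflect_pad(x, k)
    x <- stats::runmed(padded, median_window, endrule = "keep")[(k + 1L):(k + n)]
  }
  if (mean_window > 1L) {
    k <- mean_window %/% 2L
    padded <- reflect_pad(x, k)
    sm <- stats::filter(padded, rep(1 / mean_window, mean_window), sides = 2L)
    # a centred even window extends one extra sample left; both parities are
    # covered by taking the aligned interior
    start <- k + 1L
    x <- as.numeric(sm[start:(start + n - 1L)])
  }
  n_base <- max(1L, min(n, round(curve$sample_rate)))
  offset <- mean(x[seq_len(n_base)])
  out <- curve
  out$samples <- x - offset
  out
}

#' Characteristic points of a response curve
#'
#' The five voltages that summarise the curve's shape: fixed-time readings
#' VA (40 s), VD (60 s), VE (100 s), VC (120 s) and the global maximum VB at
#' its (earliest) time tB.
#'
#' @param VA,VB,VC,VD,VE voltages (volts).
#' @param tB time of the maximum in seconds.
#' @param tA,tD,tE,tC fixed reading times, defaulting to 40/60/100/120 s.
#' @return an object of class `characteristic_points`.
#' @export
characteristic_points <- function(VA, VB, VC, VD, VE, tB,
                                  tA = 40, tD = 60, tE = 100, tC = 120) {
  structure(list(VA = VA, VB = VB, VC = VC, VD = VD, VE = VE,
                 tA = tA, tB = tB, tC = tC, tD = tD, tE = tE),
            class = "characteristic_points")
}

#' @export
print.characteristic_points <- function(x, ...) {
  cat(sprintf("VA=%.4g@%gs VD=%.4g@%gs VB=%.4g@%gs VE=%.4g@%gs VC=%.4g@%gs\n",
              x$VA, x$tA, x$VD, x$tD, x$VB, x$tB, x$VE, x$tE, x$VC, x$tC))
  invisible(x)
}

#' Extract the characteristic points from a curve
#'
#' Reads VA, VD, VE, VC at the samples nearest 40, 60, 100 and 120 s
#' (t = 120 s mapping onto the final sample of the standard trace) and takes
#' VB as the global maximum, earliest sample on ties.
#'
#' @param curve a (preprocessed) [response_curve()] spanning at least 120 s.
#' @return a [characteristic_points()] object.
#' @export
extract_points <- function(curve) {
  stopifnot(inherits(curve, "response_curve"))
  x <- curve$samples
  n <- length(x)
  span <- (n - 1L) / curve$sample_rate
  if (span < 120 - 1 / curve$sample_rate) {
    stop("curve spans less than 120 s", call. = FALSE)
  }
  idx <- time_index(c(40, 60, 100, 120), curve$sample_rate, n)
  ib <- which.max(x)           # earliest maximum
  characteristic_points(VA = x[idx[1L]], VD = x[idx[2L]], VE = x[idx[3L]],
                        VC = x[idx[4L]], VB = x[ib],
                        tB = (ib - 1L) / curve$sample_rate)
}

#' Slope features between characteristic points
#'
#' The seven finite-difference slopes AB, BC, AD, DE, EC, BE, DB, each the
#' voltage change over the time change between two characteristic points
#' (V/s). A time gap smaller than 1e-9 s (e.g. the maximum falling exactly on
#' a fixed reading time) yields a 0 slope with a warning instead of dividing
#' by zero.
#'
#' @param points a [characteristic_points()] object.
#' @return named numeric vector of the 7 slopes.
#' @export
compute_slopes <- function(points) {
  stopifnot(inherits(points, "characteristic_points"))
  p <- points
  guard <- function(num, den, name) {
    if (abs(den) < 1e-9) {
      warning("degenerate time gap for ", name, "; slope set to 0",
              call. = FALSE)
      return(0)
    }
    num / den
  }
  c(slope_AB = guard(p$VB - p$VA, p$tB - p$tA, "slope_AB"),
    slope_BC = guard(p$VC - p$VB, p$tC - p$tB, "slope_BC"),
    slope_AD = guard(p$VD - p$VA, p$tD - p$tA, "slope_AD"),
    slope_DE = guard(p$VE - p$VD, p$tE - p$tD, "slope_DE"),
    slope_EC = guard(p$VC - p$VE, p$tC - p$tE, "slope_EC"),
    slope_BE = guard(p$VE - p$VB, p$tE - p$tB, "slope_BE"),
    slope_DB = guard(p$VB - p$VD, p$tB - p$tD, "slope_DB"))
}

#' Difference features between the maximum and the fixed points
#'
#' VB minus each of VA, VC, VD, VE (volts); all nonnegative whenever VB is
#' the global maximum.
#'
#' @param points a [characteristic_points()] object.
#' @return named numeric vector of the 4 differences.
#' @export
compute_differences <- function(points) {
  stopifnot(inherits(points, "characteristic_points"))
  c(dif_BA = points$VB - points$VA,
    dif_BC = points$VB - points$VC,
    dif_BD = points$VB - points$VD,
    dif_BE = points$VB - points$VE)
}

# histogram mode for a continuous signal: 0.01 V bins over the observed
# range, centre of the fullest bin, lowest bin on ties
binned_mode <- function(x, binwidth = 0.01) {
  rng <- range(x)
  if (diff(rng) < .Machine$double.eps * max(1, abs(rng[2L]))) return(rng[1L])
  nbins <- max(1L, ceiling(diff(rng) / binwidth))
  breaks <- rng[1L] + binwidth * 0:nbins
  counts <- tabulate(findInterval(x, breaks, all.inside = TRUE), nbins = nbins)
  breaks[which.max(counts)] + binwidth / 2
}

# adjusted Fisher-Pearson skewness; 0 for degenerate input
sample_skewness <- function(x) {
  n <- length(x)
  if (n < 3L) return(0)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 < .Machine$double.eps^2) return(0)
  g1 <- mean((x - m)^3) / m2^1.5
  sqrt(n * (n - 1)) / (n - 2) * g1
}

#' Distribution statistics of a preprocessed curve
#'
#' Eight summary statistics of the voltage sample distribution: 75th
#' percentile, standard deviation, binned mode, mean, median, interquartile
#' range, coefficient of variation (0 when the mean is numerically zero) and
#' adjusted Fisher-Pearson skewness. Quantiles use the linear-interpolation
#' rule.
#'
#' @param curve a [response_curve()] or plain numeric vector.
#' @return named numeric vector of the 8 statistics.
#' @export
compute_statistics <- function(curve) {
  x <- if (inherits(curve, "response_curve")) curve$samples else curve
  stopifnot(is.numeric(x), length(x) > 0L)
  m <- mean(x)
  s <- stats::sd(x)
  if (is.na(s)) s <- 0
  c(stat_p75 = unname(stats::quantile(x, 0.75, type = 7)),
    stat_sd = s,
    stat_mode = binned_mode(x),
    stat_mean = m,
    stat_median = stats::median(x),
    stat_iqr = stats::IQR(x, type = 7),
    stat_cv = if (abs(m) < 1e-12) 0 else s / m,
    stat_skew = sample_skewness(x))
}

#' Per-gas ppm estimates from the curve maximum
#'
#' Converts the peak voltage VB to an element resistance through the
#' load-divider circuit, scales it by the circuit's reference resistance into
#' the dimensionless sensor units of the calibration tables, and inverts the
#' power law for each of the seven gases. Gases with no published calibration
#' or a non-invertible (alpha = 0) model, and peak voltages outside the
#' divider's valid range (0, Vcc), yield the 0.0 sentinel so the feature
#' vector stays numeric.
#'
#' @param points a [characteristic_points()] object.
#' @param model a `sensor_model` from [sensor_models()].
#' @param circuit a [divider_circuit()].
#' @return named numeric vector of 7 ppm estimates (`ppm_<gas>`).
#' @export
estimate_ppm_features <- function(points, model, circuit = divider_circuit()) {
  stopifnot(inherits(points, "characteristic_points"),
            inherits(model, "sensor_model"))
  vb <- points$VB
  out <- stats::setNames(numeric(7L), paste0("ppm_", enose_gases()))
  if (!is.finite(vb) || vb <= 0 || vb >= circuit$supply_voltage) return(out)
  rs_units <- resistance_from_voltage(vb, circuit) / circuit$reference_resistance
  for (g in enose_gases()) {
    cal <- model$calibrations[[g]]
    if (cal$available && cal$alpha != 0) {
      out[paste0("ppm_", g)] <- concentration_from_resistivity(cal, rs_units)
    }
  }
  out
}

#' Sensor/socket identifier code
#'
#' Deterministic integer `model_ordinal * 100 + socket_index`; injective over
#' the 4 models x 32 sockets of the array.
#'
#' @param model_id sensor model identifier.
#' @param socket_index socket position 0-31.
#' @return integer code.
#' @export
encode_identifier <- function(model_id, socket_index) {
  ord <- match(model_id, enose_sensor_models())
  if (is.na(ord)) stop("unknown sensor model: ", model_id, call. = FALSE)
  socket_index <- as.integer(socket_index)
  stopifnot(socket_index >= 0L, socket_index <= 31L)
  (ord - 1L) * 100L + socket_index
}

#' The frozen 32-feature order
#'
#' Column order of every feature vector and feature table the package
#' produces: 5 point voltages, 7 slopes, 4 differences, 7 ppm estimates,
#' 8 statistics, 1 identifier code. Trained models depend on this order.
#'
#' @return character vector of length 32.
#' @export
feature_names <- function() {
  c("VA", "VB", "VC", "VD", "VE",
    "slope_AB", "slope_BC", "slope_AD", "slope_DE", "slope_EC", "slope_BE",
    "slope_DB",
    "dif_BA", "dif_BC", "dif_BD", "dif_BE",
    paste0("ppm_", enose_gases()),
    "stat_p75", "stat_sd", "stat_mode", "stat_mean", "stat_median",
    "stat_iqr", "stat_cv", "stat_skew",
    "id_code")
}

#' Assemble the 32-parameter feature vector of one curve
#'
#' Runs the full per-curve chain: [preprocess()], [extract_points()],
#' [compute_slopes()], [compute_differences()], [estimate_ppm_features()],
#' [compute_statistics()] and [encode_identifier()], assembled in the frozen
#' [feature_names()] order. Pure: identical inputs give identical vectors.
#'
#' @param curve a raw [response_curve()].
#' @param model a `sensor_model` from [sensor_models()]; defaults to the
#'   model referenced by the curve, resolved against the shipped tables.
#' @param circuit a [divider_circuit()].
#' @param models the calibration table set used to resolve `model` when it is
#'   not given explicitly.
#' @return named numeric vector of length 32.
#' @export
featurize <- function(curve, model = NULL, circuit = divider_circuit(),
                      models = sensor_models()) {
  stopifnot(inherits(curve, "response_curve"))
  if (is.null(model)) {
    model <- models[[curve$model_id]]
    if (is.null(model)) stop("unknown sensor model: ", curve$model_id,
                             call. = FALSE)
  }
  pre <- preprocess(curve)
  pts <- extract_points(pre)
  v <- c(VA = pts$VA, VB = pts$VB, VC = pts$VC, VD = pts$VD, VE = pts$VE,
         compute_slopes(pts),
         compute_differences(pts),
         estimate_ppm_features(pts, model, circuit),
         compute_statistics(pre),
         id_code = encode_identifier(model$model_id, curve$socket_index))
  v[feature_names()]
}
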