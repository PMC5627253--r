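# Synthetic single-lead ECG and cohort generator.
#
# The beat template is deliberately schematic (Gaussian P and T waves, a
# triangular QRS, a strictly linear ST segment): it is a test harness for the
# downstream pipeline, not a physiological simulator. The one property it
# guarantees is that the 16-sample ST extraction window contains exactly
# `st_level + st_slope * (k - window centre)` in the noiseless case, so planted
# morphology is recoverable to machine precision.

# Template fiducial offsets, in samples at the 128 Hz reference rate. The
# geometry keeps the ST-T complex a minority of the beat period so that a
# median-filter baseline estimate is not dragged up by the ST level, while
# the S-to-T-label span (25 samples) satisfies the 16..32-sample retention
# rule and the 16-sample extraction window (offsets 35..50) sits strictly
# inside the linear ST region (32..59) even under +/-3-sample delineation
# error.
.TPL <- list(
  p_c = 10, p_sd = 1.8, p_amp = 0.15,
  q_on = 22, q_dip = 24, q_amp = -0.10,
  r = 27,
  s = 31, s_amp = -0.20,
  st_on = 32, st_off = 59, st_center = 42.5,
  t_lab = 55, t_c = 71, t_sd = 3.5, t_amp = 0.30,
  taper = 4, span = 92
)

# Evaluate `code` under `seed` without clobbering the caller's RNG stream.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Beat template parameters for the synthetic ECG generator
#'
#' @param heart_rate beats per minute (> 0).
#' @param st_level mV offset of the ST plateau relative to the isoelectric
#'   line.
#' @param st_slope mV per sample across the 16-sample ST window.
#' @param st_jitter_sd mV; per-beat Gaussian perturbation of the ST level
#'   (and, scaled by 1/8, of the slope).
#' @param noise_sd mV; additive white noise.
#' @param baseline_amp mV; amplitude of 0.3 Hz sinusoidal baseline wander.
#' @param r_amp mV; R-peak amplitude.
#' @return an object of class `beat_template_params`.
#' @export
beat_template_params <- function(heart_rate = 55, st_level = 0.1,
                                 st_slope = 0, st_jitter_sd = 0,
                                 noise_sd = 0, baseline_amp = 0,
                                 r_amp = 1.0) {
  if (!is.numeric(heart_rate) || heart_rate <= 0)
    stop_strisk("heart_rate must be > 0", "strisk_parameter_error")
  for (nm in c("st_jitter_sd", "noise_sd", "baseline_amp")) {
    v <- get(nm)
    if (!is.numeric(v) || v < 0)
      stop_strisk(sprintf("%s must be >= 0", nm), "strisk_parameter_error")
  }
  structure(list(heart_rate = heart_rate, st_level = st_level,
                 st_slope = st_slope, st_jitter_sd = st_jitter_sd,
                 noise_sd = noise_sd, baseline_amp = baseline_amp,
                 r_amp = r_amp),
            class = "beat_template_params")
}

#' Construct a continuous single-lead ECG signal object
#'
#' @param samples numeric vector of voltages (mV).
#' @param fs sampling rate in Hz (> 0).
#' @param patient_id,lead identifiers.
#' @return an `ecg_signal` object.
#' @export
ecg_signal <- function(samples, fs, patient_id = "unknown", lead = "II") {
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop_strisk("fs must be a positive scalar", "strisk_parameter_error")
  if (length(samples) < 1L || !all(is.finite(samples)))
    stop_strisk("samples must be non-empty and finite",
                "strisk_parameter_error")
  structure(list(samples = as.numeric(samples), fs = fs,
                 patient_id = patient_id, lead = lead),
            class = "ecg_signal")
}

#' @export
print.ecg_signal <- function(x, ...) {
  cat(sprintf("<ecg_signal> patient %s, lead %s: %d samples at %g Hz (%.1f s)\n",
              x$patient_id, x$lead, length(x$samples), x$fs,
              length(x$samples) / x$fs))
  invisible(x)
}

.one_beat <- function(lev, slo, r_amp, fs, L) {
  sc <- fs / 128
  o <- lapply(.TPL, function(v) v * sc)
  k <- 0:(L - 1L)
  y <- numeric(L)
  pre <- k < round(o$q_on)
  # truncated Gaussian P wave: an exactly-zero diastolic floor keeps the
  # running-median baseline estimate at zero outside the ST-T complex
  pg <- .TPL$p_amp * exp(-((k[pre] - o$p_c)^2) / (2 * o$p_sd^2))
  pg[abs(k[pre] - o$p_c) > 2.8 * o$p_sd] <- 0
  y[pre] <- pg
  qk <- round(o$q_on):round(o$s)
  nodes_x <- c(o$q_on, o$q_dip, o$r, o$s)
  nodes_y <- c(0, .TPL$q_amp, r_amp, .TPL$s_amp)
  y[qk + 1L] <- approx(nodes_x, nodes_y, xout = qk, rule = 2)$y
  stk <- round(o$st_on):round(o$st_off)
  y[stk + 1L] <- lev + slo * (stk - o$st_center)
  tail_k <- k[k > round(o$st_off)]
  st_end <- lev + slo * (round(o$st_off) - o$st_center)
  tg <- .TPL$t_amp * exp(-((tail_k - o$t_c)^2) / (2 * o$t_sd^2))
  tg[abs(tail_k - o$t_c) > 2.6 * o$t_sd] <- 0
  y[tail_k + 1L] <- st_end * pmax(0, 1 - (tail_k - round(o$st_off)) /
                                    o$taper) + tg
  y
}

#' Generate a synthetic ECG record with per-beat ground truth
#'
#' Concatenates template beats at the requested heart rate, with per-beat
#' ST level/slope jitter, additive white noise and low-frequency baseline
#' wander. Ground-truth fiducials and planted ST morphology are returned for
#' every emitted beat.
#'
#' @param params a [beat_template_params()] object.
#' @param n_beats number of beats (>= 1).
#' @param fs sampling rate in Hz (default 128, the target recorder rate).
#' @param seed integer seed; identical seeds give identical records.
#' @param patient_id,lead identifiers stored on the signal.
#' @return a list with elements `signal` (an `ecg_signal`) and `truth`
#'   (a data frame with one row per beat: 1-based fiducial sample indices
#'   `p_idx`, `qrs_on_idx`, `r_idx`, `s_idx`, `t_idx`, and the realized
#'   `st_level` and `st_slope`).
#' @export
make_ecg_record <- function(params, n_beats, fs = 128, seed = 1,
                            patient_id = "synthetic", lead = "II") {
  if (!inherits(params, "beat_template_params"))
    params <- do.call(beat_template_params, as.list(params))
  if (!is.numeric(n_beats) || n_beats < 1)
    stop_strisk("n_beats must be >= 1", "strisk_parameter_error")
  if (!is.numeric(fs) || fs <= 0)
    stop_strisk("fs must be > 0", "strisk_parameter_error")
  n_beats <- as.integer(n_beats)
  sc <- fs / 128
  L <- as.integer(round(fs * 60 / params$heart_rate))
  if (L < ceiling(.TPL$span * sc))
    stop_strisk("heart_rate too high for the beat template at this fs",
                "strisk_parameter_error")
  with_seed(seed, {
    levs <- params$st_level + rnorm(n_beats, 0, params$st_jitter_sd)
    slos <- params$st_slope + rnorm(n_beats, 0, params$st_jitter_sd / 8)
    x <- unlist(lapply(seq_len(n_beats), function(i)
      .one_beat(levs[i], slos[i], params$r_amp, fs, L)), use.names = FALSE)
    n <- length(x)
    if (params$baseline_amp > 0) {
      phase <- runif(1, 0, 2 * pi)
      x <- x + params$baseline_amp *
        sin(2 * pi * 0.3 * (seq_len(n) - 1) / fs + phase)
    }
    if (params$noise_sd > 0) x <- x + rnorm(n, 0, params$noise_sd)
    starts <- (seq_len(n_beats) - 1L) * L
    off <- function(v) as.integer(starts + round(v * sc) + 1L)
    truth <- data.frame(
      beat = seq_len(n_beats),
      p_idx = off(.TPL$p_c), qrs_on_idx = off(.TPL$q_on),
      r_idx = off(.TPL$r), s_idx = off(.TPL$s), t_idx = off(.TPL$t_lab),
      st_level = levs, st_slope = slos)
    list(signal = ecg_signal(x, fs, patient_id, lead), truth = truth)
  })
}

#' Specification of a synthetic patient cohort
#'
#' Defaults describe the emulated study population: a ~3.4% one-year
#' cardiovascular-death rate, seven baseline history features with
#' prevalences matching a typical post-ACS trial population, and a hazard
#' that depends on the history features plus a latent ST-series temporal
#' irregularity (the standard deviation of first differences of the per-beat
#' ST level).
#'
#' @param n_patients number of patients (>= 2).
#' @param event_rate target event fraction in (0, 1) at `follow_up_days`.
#' @param history_effects named numeric vector of 7 log-hazard coefficients
#'   on the \[0,1\]-scaled history features (age, female, smoker,
#'   hypertension, diabetes, prior_mi, prior_angiography).
#' @param st_irregularity_effect log-hazard coefficient on the standardized
#'   ST temporal-irregularity latent.
#' @param follow_up_days administrative censoring time.
#' @param seed integer seed.
#' @param n_series_beats beats generated per patient for the "first day"
#'   coefficient series (desk-scale stand-in for a day of Holter data).
#' @param series logical; build per-patient coefficient series objects.
#' @return a `cohort_spec` object.
#' @export
cohort_spec <- function(n_patients, event_rate = 0.034,
                        history_effects = c(age = 1.6, female = -0.5,
                                            smoker = 0.5, hypertension = 0.65,
                                            diabetes = 0.8, prior_mi = 0.8,
                                            prior_angiography = 0.3),
                        st_irregularity_effect = 1.5,
                        follow_up_days = 365, seed = 1,
                        n_series_beats = 200, series = TRUE) {
  if (!is.numeric(n_patients) || n_patients < 2)
    stop_strisk("n_patients must be >= 2", "strisk_parameter_error")
  if (event_rate <= 0 || event_rate >= 1)
    stop_strisk("event_rate must be in (0,1)", "strisk_parameter_error")
  if (length(history_effects) != 7L || !all(is.finite(history_effects)))
    stop_strisk("history_effects must be 7 finite coefficients",
                "strisk_parameter_error")
  if (!is.finite(st_irregularity_effect))
    stop_strisk("st_irregularity_effect must be finite",
                "strisk_parameter_error")
  structure(list(n_patients = as.integer(n_patients),
                 event_rate = event_rate,
                 history_effects = history_effects,
                 st_irregularity_effect = st_irregularity_effect,
                 follow_up_days = follow_up_days, seed = seed,
                 n_series_beats = as.integer(n_series_beats),
                 series = isTRUE(series)),
            class = "cohort_spec")
}

# AR(1) series with given marginal sd around `base`.
.ar1 <- function(n, base, rho, sd_marg) {
  z <- rnorm(n)
  e <- numeric(n)
  e[1] <- z[1]
  if (n > 1) for (t in 2:n) e[t] <- rho * e[t - 1] + sqrt(1 - rho^2) * z[t]
  base + sd_marg * e
}

#' Generate a synthetic patient cohort with planted survival structure
#'
#' Draws seven baseline history features, optional TIMI risk score / LVEF /
#' BNP, a per-patient ST-coefficient series with patient-specific temporal
#' structure, and exponential proportional-hazards survival times whose
#' log-hazard is `history_effects . x + st_irregularity_effect * z`, where
#' `z` is the standardized SD of first differences of the per-beat ST level.
#' The baseline hazard is calibrated so the expected event fraction at
#' `follow_up_days` equals `event_rate`.
#'
#' @param spec a [cohort_spec()] object.
#' @return an `st_cohort` object: list with `patients` (data frame including
#'   `event`, `time_days`, the planted `latent` and `latent_history` linear
#'   predictors and the `irregularity` latent) and `series` (per-patient
#'   [coefficient_series] with components c1 = level, c2 = slope, or NULL).
#' @export
make_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_patients
  with_seed(spec$seed, {
    age <- pmin(pmax(round(rnorm(n, 63, 12)), 30), 95)
    female <- rbinom(n, 1, 0.35)
    smoker <- rbinom(n, 1, 0.26)
    hypertension <- rbinom(n, 1, 0.73)
    diabetes <- rbinom(n, 1, 0.33)
    prior_mi <- rbinom(n, 1, 0.33)
    prior_angiography <- rbinom(n, 1, 0.34)
    trs <- sample(1:7, n, replace = TRUE,
                  prob = c(0.10, 0.17, 0.26, 0.27, 0.12, 0.05, 0.03))
    lvef_pct <- pmin(pmax(round(rnorm(n, 52, 10)), 15), 75)
    bnp <- round(rlnorm(n, log(50), 1.0), 1)

    # per-patient ST series: AR(1) level/slope with patient-specific
    # jitter scale and autocorrelation
    jitter <- rlnorm(n, log(0.02), 0.5)
    rho <- runif(n, 0, 0.9)
    base_lev <- rnorm(n, 0.05, 0.02)
    base_slo <- rnorm(n, 0, 0.005)
    nb <- spec$n_series_beats
    levels <- lapply(seq_len(n), function(i)
      .ar1(nb, base_lev[i], rho[i], jitter[i]))
    slopes <- lapply(seq_len(n), function(i)
      .ar1(nb, base_slo[i], rho[i], jitter[i] / 8))
    irregularity <- vapply(levels, function(l) sd(diff(l)), 0)
    z <- as.numeric(scale(irregularity))

    agev <- (age - min(age)) / max(1e-12, diff(range(age)))
    X <- cbind(age = agev, female = female, smoker = smoker,
               hypertension = hypertension, diabetes = diabetes,
               prior_mi = prior_mi, prior_angiography = prior_angiography)
    lp_hx <- as.numeric(X %*% spec$history_effects)
    lp <- lp_hx + spec$st_irregularity_effect * z

    # calibrate baseline hazard so E[event fraction] = event_rate
    Tmax <- spec$follow_up_days
    f <- function(loglam)
      mean(1 - exp(-exp(loglam + lp) * Tmax)) - spec$event_rate
    lam0 <- exp(uniroot(f, c(-30, 5), tol = 1e-12)$root)
    tt <- rexp(n, rate = lam0 * exp(lp))
    event <- as.integer(tt <= Tmax)
    time_days <- pmin(tt, Tmax)

    patients <- data.frame(
      patient_id = sprintf("P%05d", seq_len(n)),
      age = age, female = female, smoker = smoker,
      hypertension = hypertension, diabetes = diabetes,
      prior_mi = prior_mi, prior_angiography = prior_angiography,
      trs = trs, lvef_pct = lvef_pct, bnp = bnp,
      event = event, time_days = time_days,
      latent = lp, latent_history = lp_hx, irregularity = irregularity,
      stringsAsFactors = FALSE)

    series <- NULL
    if (spec$series) {
      series <- lapply(seq_len(n), function(i) {
        coefficient_series(cbind(
          c1 = 4 * levels[[i]] + rnorm(nb, 0, 0.01),
          c2 = sqrt(340) * slopes[[i]] + rnorm(nb, 0, 0.01)))
      })
      names(series) <- patients$patient_id
    }
    structure(list(patients = patients, series = series, spec = spec),
              class = "st_cohort")
  })
}

#' @export
print.st_cohort <- function(x, ...) {
  cat(sprintf("<st_cohort> %d patients, %d events (%.2f%%), %s series\n",
              nrow(x$patients), sum(x$patients$event),
              100 * mean(x$patients$event),
              if (is.null(x$series)) "no" else "with"))
  invisible(x)
}
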