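#' Dipolar source specification for the simulator
#'
#' A fixed-location, fixed-orientation current dipole whose moment follows a
#' smooth unimodal (Hanning) envelope after each of its triggers:
#' `evoked` sources fire at every tone onset of every trial, `deviance`
#' sources fire only at the final-tone onset of deviant trials — emulating a
#' deviance-specific mismatch generator.  The orientation is projected onto
#' the tangential plane at the source location (radial components are
#' magnetically silent in a spherical conductor and would be wasted).
#'
#' @param location Length-3 position in meters (inside the head sphere).
#' @param orientation Length-3 direction; its tangential component is used.
#' @param response_kind `"evoked"` or `"deviance"`.
#' @param latency_s Envelope peak time after the trigger, seconds.
#' @param width_s Total envelope duration (Hanning support), seconds.
#' @param amplitude Peak dipole moment, A·m.
#' @param gain_jitter_sd Standard deviation of the multiplicative per-trial
#'   amplitude jitter (mean 1, truncated at 0); models trial-to-trial
#'   response variability and decorrelates simultaneous sources.
#' @return An object of class `source_spec`.
#' @export
source_spec <- function(location, orientation, response_kind = c("deviance", "evoked"),
                        latency_s = 0.15, width_s = 0.12, amplitude = 30e-9,
                        gain_jitter_sd = 0.2) {
  response_kind <- match.arg(response_kind)
  stopifnot(length(location) == 3, length(orientation) == 3,
            latency_s >= 0, width_s > 0, amplitude >= 0)
  structure(list(location = as.numeric(location),
                 orientation = as.numeric(orientation),
                 response_kind = response_kind,
                 latency_s = latency_s, width_s = width_s,
                 amplitude = amplitude,
                 gain_jitter_sd = gain_jitter_sd),
            class = "source_spec")
}

#' Simulation configuration
#'
#' Acquisition defaults follow a whole-head axial system: 600 Hz sampling
#' with a 150 Hz acquisition low-pass (4th-order Butterworth, applied
#' forward-backward).  Background activity is modeled as spatially
#' correlated "brain noise" from many random tangential dipoles with white
#' Gaussian amplitude time courses, plus white sensor noise per channel.
#'
#' @param sources List of [source_spec()] objects.
#' @param sampling_rate Hz.
#' @param acquisition_lowpass Hz; must be below half the sampling rate.
#' @param background_dipoles Number of random background dipoles.
#' @param background_amplitude Per-dipole white moment SD, A·m.
#' @param sensor_noise_sd White sensor-noise SD per sample, tesla.
#' @param correlated_bilateral If `TRUE`, all deviance sources share a
#'   single per-trial gain (their time courses become fully correlated at
#'   zero lag) — used to probe beamformer correlated-source suppression.
#' @param seed Integer seed for this recording.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(sources = list(), sampling_rate = 600,
                       acquisition_lowpass = 150,
                       background_dipoles = 200L,
                       background_amplitude = 10e-9,
                       sensor_noise_sd = 20e-15,
                       correlated_bilateral = FALSE,
                       seed = 1L) {
  if (is.finite(acquisition_lowpass) &&
      sampling_rate <= 2 * acquisition_lowpass)
    stop("sampling_rate must exceed twice the acquisition low-pass")
  structure(list(sources = sources, sampling_rate = sampling_rate,
                 acquisition_lowpass = acquisition_lowpass,
                 background_dipoles = as.integer(background_dipoles),
                 background_amplitude = background_amplitude,
                 sensor_noise_sd = sensor_noise_sd,
                 correlated_bilateral = isTRUE(correlated_bilateral),
                 seed = as.integer(seed)),
            class = "sim_config")
}

hanning_envelope <- function(t, peak, width) {
  # Raised-cosine bump supported on [peak - width/2, peak + width/2].
  u <- (t - peak) / width
  ifelse(abs(u) <= 0.5, 0.5 * (1 + cos(2 * pi * u)), 0)
}

source_trigger_times <- function(src, events, spec) {
  if (src$response_kind == "evoked") {
    k <- seq_len(spec$tones_per_sequence) - 1L
    as.numeric(outer(events$onset, k * spec$tone_duration, `+`))
  } else {
    events$onset[events$trial_type == "deviant"] +
      final_tone_offset(spec)
  }
}

#' Simulate one continuous oddball MEG recording
#'
#' Sums, channel by channel, the forward-projected source envelopes, the
#' background dipole noise, and white sensor noise, then applies the
#' acquisition low-pass (zero phase).  Deterministic for a fixed
#' `config$seed`.
#'
#' @param config A [sim_config()].
#' @param events Rows of an `event_table` for a single run (must carry the
#'   `trial_spec` used to create it, or pass `spec`).
#' @param head A [head_model()].
#' @param array A `sensor_array`.
#' @param spec The [trial_spec()]; defaults to the one attached to `events`.
#' @param tail_s Recording time kept after the last sequence ends, seconds
#'   (generous enough for 3.6 s epochs).
#' @return An object of class `sensor_recording`: list with `data`
#'   (`n_channels x n_samples`, tesla), `sampling_rate`, `array`, `run_id`,
#'   `config`.
#' @export
simulate_recording <- function(config, events, head, array,
                               spec = attr(events, "spec"), tail_s = 4) {
  stopifnot(inherits(config, "sim_config"), inherits(head, "head_model"))
  if (is.null(spec)) stop("events carry no trial_spec; pass `spec`")
  if (length(unique(events$run_id)) > 1)
    stop("simulate_recording expects events from a single run")
  fs <- config$sampling_rate
  dur <- max(events$onset) + sequence_duration(spec) + tail_s
  nsamp <- ceiling(dur * fs)
  tvec <- (seq_len(nsamp) - 1) / fs
  nch <- nrow(array)
  data <- matrix(0, nch, nsamp)

  with_seed(config$seed, {
    ## deterministic + jittered dipolar sources
    n_src <- length(config$sources)
    if (n_src > 0) {
      # Pre-draw per-trigger gains source by source so the stream is stable.
      shared_gain <- NULL
      for (si in seq_len(n_src)) {
        src <- config$sources[[si]]
        d <- vnorm(src$location - head$center)
        if (d >= head$radius) stop("source outside head sphere")
        trig <- source_trigger_times(src, events, spec)
        if (!length(trig)) next
        gains <- if (src$gain_jitter_sd > 0) {
          pmax(0, stats::rnorm(length(trig), 1, src$gain_jitter_sd))
        } else rep(1, length(trig))
        if (config$correlated_bilateral && src$response_kind == "deviance") {
          if (is.null(shared_gain)) shared_gain <- gains
          gains <- shared_gain[seq_along(trig)]
        }
        s <- numeric(nsamp)
        for (k in seq_along(trig)) {
          pk <- trig[k] + src$latency_s
          i0 <- max(1L, floor((pk - src$width_s / 2) * fs) + 1L)
          i1 <- min(nsamp, ceiling((pk + src$width_s / 2) * fs) + 1L)
          if (i1 < i0) next
          idx <- i0:i1
          s[idx] <- s[idx] +
            gains[k] * hanning_envelope(tvec[idx], pk, src$width_s)
        }
        orient <- tangentialize(src$orientation, src$location - head$center)
        f <- sarvas_field(src$location, orient, head, array)
        nz <- which(s != 0)
        if (length(nz))
          data[, nz] <- data[, nz] + (src$amplitude * f) %*% t(s[nz])
      }
    }

    ## background brain noise: random tangential dipoles, white moments
    nb <- config$background_dipoles
    if (nb > 0 && config$background_amplitude > 0) {
      # positions uniform in a sphere of 0.8 * radius around the center
      u <- matrix(stats::rnorm(3 * nb), nb, 3)
      u <- u / sqrt(rowSums(u^2))
      rad <- 0.8 * head$radius * stats::runif(nb)^(1 / 3)
      bp <- sweep(u * rad, 2, head$center, `+`)
      Fbg <- matrix(0, nch, nb)
      for (b in seq_len(nb)) {
        v <- stats::rnorm(3)
        ori <- tryCatch(tangentialize(v, bp[b, ] - head$center),
                        error = function(e) c(1, 0, 0))
        Fbg[, b] <- sarvas_field(bp[b, ], ori, head, array)
      }
      S <- cpp_randn(nb, nsamp, config$background_amplitude)
      data <- data + Fbg %*% S
    }

    ## white sensor noise
    if (config$sensor_noise_sd > 0)
      data <- data + cpp_randn(nch, nsamp, config$sensor_noise_sd)
  })

  ## acquisition anti-alias low-pass, zero phase
  if (is.finite(config$acquisition_lowpass) && any(data != 0)) {
    bf <- signal::butter(4, config$acquisition_lowpass / (fs / 2),
                         type = "low")
    data <- filtfilt_rows(data, bf)
  }

  structure(list(data = data, sampling_rate = fs, array = array,
                 run_id = unique(events$run_id), config = config,
                 spec = spec),
            class = "sensor_recording")
}

#' @export
print.sensor_recording <- function(x, ...) {
  cat(sprintf("Sensor recording: %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$sampling_rate,
              ncol(x$data) / x$sampling_rate))
  invisible(x)
}

#' Inject transient high-amplitude artifacts
#'
#' Adds `n_events` smooth 0.5 s deflections at random times, spatially
#' weighted toward frontal channels (eye-blink-like topography), each scaled
#' so that its peak field slightly exceeds `amplitude` in at least one
#' channel.  Returns the modified recording and a log of injection times.
#'
#' @param recording A `sensor_recording`.
#' @param n_events Number of artifacts.
#' @param amplitude Nominal peak amplitude in tesla (e.g. `4e-12`).
#' @param seed Integer seed.
#' @param duration_s Artifact duration.
#' @return List with elements `recording` and `log` (data.frame: `time_s`,
#'   `peak_channel`, `amplitude`).
#' @export
inject_artifacts <- function(recording, n_events, amplitude, seed = 1L,
                             duration_s = 0.5) {
  stopifnot(inherits(recording, "sensor_recording"), amplitude > 0)
  n_events <- as.integer(n_events)
  if (n_events == 0)
    return(list(recording = recording,
                log = data.frame(time_s = numeric(0),
                                 peak_channel = character(0),
                                 amplitude = numeric(0))))
  fs <- recording$sampling_rate
  nsamp <- ncol(recording$data)
  dur_total <- nsamp / fs
  w <- ifelse(recording$array$region == "frontal", 1, 0.2)
  w <- w / max(w)   # peak channel always reaches the nominal amplitude
  peak_ch <- which.max(w)
  log <- with_seed(seed, {
    times <- sort(stats::runif(n_events, duration_s,
                               dur_total - duration_s))
    for (tt in times) {
      idx0 <- floor((tt - duration_s / 2) * fs) + 1L
      idx1 <- min(nsamp, idx0 + round(duration_s * fs))
      idx <- max(1L, idx0):idx1
      env <- hanning_envelope((idx - 1) / fs, tt, duration_s)
      # 1.05 factor guarantees a strictly super-threshold peak sample
      recording$data[, idx] <- recording$data[, idx] +
        (1.05 * amplitude * w) %*% t(env)
    }
    data.frame(time_s = times,
               peak_channel = recording$array$name[peak_ch],
               amplitude = amplitude)
  })
  list(recording = recording, log = log)
}

#' Save / load a recording or epoch container
#'
#' Recordings and epoch sets are self-describing lists (data, sampling
#' metadata, channel table, and the full simulation provenance including the
#' seed); they are serialized with R's native RDS container, one file per
#' subject/run.
#'
#' @param x A `sensor_recording` or `epoch_set`.
#' @param path File path (conventionally `.rds`).
#' @export
write_container <- function(x, path) {
  saveRDS(x, path)
  invisible(path)
}

#' @rdname write_container
#' @export
read_container <- function(path) readRDS(path)
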