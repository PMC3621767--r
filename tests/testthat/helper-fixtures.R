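# Shared small-scale fixtures.  Module tests run on reduced arrays and
# short sessions; the full-size defaults are exercised by the acceptance
# tests.

small_head <- function() head_model(radius = 0.09)

small_array <- function(n = 64) make_sensor_array(n_channels = n)

short_spec <- function(n_standard = 13, n_deviant = 4, n_runs = 1)
  trial_spec(n_standard = n_standard, n_deviant = n_deviant, n_runs = n_runs)

# Build an epoch_set directly from a trials x channels x samples array,
# with the deviant-tone onset at t = 0 so covariance windows address
# samples directly.
make_epochs <- function(data, fs = 100, condition = NULL,
                        array = NULL) {
  ntr <- dim(data)[1]
  structure(list(
    epochs = data,
    sampling_rate = fs,
    t0_offset_s = 0,
    condition = condition %||% rep(c("standard", "deviant"),
                                   length.out = ntr),
    trial_index = seq_len(ntr) - 1L,
    run_id = rep(1L, ntr),
    deviant_offset_s = 0,
    array = array %||% data.frame(
      name = sprintf("C%02d", seq_len(dim(data)[2])),
      region = "other")
  ), class = "epoch_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One simulated, filtered, epoched subject session.
sim_subject <- function(sources, spec, head, array, seed,
                        correlated = FALSE, band = c(1, 30), ...) {
  ev <- generate_oddball_events(spec, seed = seed)
  sc <- sim_config(sources = sources, correlated_bilateral = correlated,
                   seed = seed + 5000L, ...)
  rec <- simulate_recording(sc, ev, head, array)
  rec <- bandpass_filter(rec, band[1], band[2])
  ep <- reject_artifacts(extract_epochs(rec, ev))
  list(epochs = ep, events = ev, pairs = select_analysis_trials(ev))
}
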