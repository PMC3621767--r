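# Module tests run a reduced array and short sessions; sampling follows the
# acquisition defaults only where the assertion depends on them.

test_that("a configuration with no sources and no noise yields silence", {
  head <- small_head(); arr <- small_array(16)
  ev <- generate_oddball_events(short_spec(4, 1), seed = 1)
  sc <- sim_config(sources = list(), background_dipoles = 0,
                   background_amplitude = 0, sensor_noise_sd = 0, seed = 1)
  rec <- simulate_recording(sc, ev, head, arr)
  expect_true(all(rec$data == 0))
  expect_equal(rec$sampling_rate, 600)
})

test_that("deviance-only sources are silent outside deviant final tones", {
  head <- small_head(); arr <- small_array(24)
  spec <- short_spec(6, 3)
  ev <- generate_oddball_events(spec, seed = 2)
  src <- source_spec(c(0.05, -0.02, 0.04), c(0, 1, 0), "deviance",
                     latency_s = 0.15, width_s = 0.12, amplitude = 30e-9,
                     gain_jitter_sd = 0)
  sc <- sim_config(sources = list(src), background_dipoles = 0,
                   background_amplitude = 0, sensor_noise_sd = 0, seed = 3)
  rec <- simulate_recording(sc, ev, head, arr)
  fs <- rec$sampling_rate
  active <- rep(FALSE, ncol(rec$data))
  for (on in ev$deviant_onset[ev$trial_type == "deviant"]) {
    i0 <- floor((on + 0.15 - 0.09) * fs); i1 <- ceiling((on + 0.15 + 0.09) * fs)
    active[max(1, i0):min(length(active), i1)] <- TRUE
  }
  # a little slack for the acquisition filter's (tiny) tails
  pow <- colSums(rec$data^2)
  expect_gt(sum(pow[active]), 0)
  expect_lt(max(pow[!active]), 1e-6 * max(pow[active]))
  # standard trials carry nothing at all
  for (on in ev$onset[ev$trial_type == "standard"]) {
    idx <- floor(on * fs):ceiling((on + 1.8) * fs)
    expect_lt(max(pow[idx[!active[idx]]]), 1e-6 * max(pow))
  }
})

test_that("sensor signals equal envelope times forward field for one source", {
  head <- small_head(); arr <- small_array(24)
  spec <- short_spec(4, 2)
  ev <- generate_oddball_events(spec, seed = 5)
  loc <- c(0.04, 0.01, 0.05)
  src <- source_spec(loc, c(1, 0, 0), "deviance", latency_s = 0.15,
                     width_s = 0.12, amplitude = 50e-9, gain_jitter_sd = 0)
  sc <- sim_config(sources = list(src), background_dipoles = 0,
                   background_amplitude = 0, sensor_noise_sd = 0,
                   acquisition_lowpass = Inf, seed = 6)
  rec <- simulate_recording(sc, ev, head, arr)
  # every active sample's channel pattern is proportional to one field
  f <- rec$data[, which.max(colSums(rec$data^2))]
  prj <- crossprod(rec$data, f) / sum(f^2)
  resid <- rec$data - f %*% t(prj)
  expect_lt(max(abs(resid)), 1e-10 * max(abs(rec$data)))
})

test_that("the configured sensor noise SD is reproduced empirically", {
  head <- small_head(); arr <- small_array(24)
  ev <- generate_oddball_events(short_spec(6, 2), seed = 7)
  s <- 30e-15
  sc <- sim_config(sources = list(), background_dipoles = 0,
                   background_amplitude = 0, sensor_noise_sd = s,
                   acquisition_lowpass = Inf, seed = 8)
  rec <- simulate_recording(sc, ev, head, arr)
  expect_lt(abs(sd(rec$data) - s) / s, 0.05)
})

test_that("simulation is reproducible per seed and varies across seeds", {
  head <- small_head(); arr <- small_array(16)
  ev <- generate_oddball_events(short_spec(4, 1), seed = 9)
  mk <- function(seed) simulate_recording(
    sim_config(sources = list(), background_dipoles = 20,
               background_amplitude = 5e-9, sensor_noise_sd = 1e-14,
               seed = seed), ev, small_head(), arr)
  expect_identical(mk(11)$data, mk(11)$data)
  expect_false(identical(mk(11)$data, mk(12)$data))
})

test_that("a source outside the head sphere is rejected", {
  head <- small_head(); arr <- small_array(16)
  ev <- generate_oddball_events(short_spec(4, 1), seed = 1)
  src <- source_spec(c(0.1, 0, 0), c(0, 1, 0), "deviance")
  sc <- sim_config(sources = list(src), background_dipoles = 0,
                   background_amplitude = 0, sensor_noise_sd = 0, seed = 2)
  expect_error(simulate_recording(sc, ev, head, arr), "outside")
})

test_that("correlated-bilateral mode locks deviance sources to one time course", {
  head <- small_head(); arr <- small_array(24)
  spec <- short_spec(8, 4)
  ev <- generate_oddball_events(spec, seed = 13)
  mkrec <- function(corr) {
    s1 <- source_spec(c(0.05, -0.02, 0.04), c(0, 1, 0), "deviance",
                      amplitude = 50e-9, gain_jitter_sd = 0.5)
    s2 <- source_spec(c(-0.05, -0.02, 0.04), c(0, 1, 0), "deviance",
                      amplitude = 50e-9, gain_jitter_sd = 0.5)
    simulate_recording(
      sim_config(sources = list(s1, s2), background_dipoles = 0,
                 background_amplitude = 0, sensor_noise_sd = 0,
                 acquisition_lowpass = Inf, correlated_bilateral = corr,
                 seed = 14),
      ev, head, arr)
  }
  peak_per_trial <- function(rec, ch) {
    fs <- rec$sampling_rate
    vapply(ev$deviant_onset[ev$trial_type == "deviant"], function(on) {
      idx <- floor((on + 0.09) * fs):ceiling((on + 0.21) * fs)
      max(abs(rec$data[ch, idx]))
    }, numeric(1))
  }
  # channels closest to each source dominate its field
  chR <- which.max(abs(sarvas_field(c(0.05, -0.02, 0.04), c(0, 1e-8, 0),
                                    head, arr)))
  chL <- which.max(abs(sarvas_field(c(-0.05, -0.02, 0.04), c(0, 1e-8, 0),
                                    head, arr)))
  rec_c <- mkrec(TRUE)
  ratio_c <- peak_per_trial(rec_c, chR) / peak_per_trial(rec_c, chL)
  expect_lt(sd(ratio_c) / mean(ratio_c), 1e-6)   # shared per-trial gains
  rec_u <- mkrec(FALSE)
  ratio_u <- peak_per_trial(rec_u, chR) / peak_per_trial(rec_u, chL)
  expect_gt(sd(ratio_u) / mean(ratio_u), 0.05)   # independent jitter
})

test_that("injected artifacts are logged, super-threshold, and removable", {
  head <- small_head(); arr <- small_array(40)
  ev <- generate_oddball_events(short_spec(20, 5), seed = 15)
  sc <- sim_config(sources = list(), background_dipoles = 20,
                   background_amplitude = 2e-9, sensor_noise_sd = 1e-14,
                   seed = 16)
  rec <- simulate_recording(sc, ev, head, arr)

  same <- inject_artifacts(rec, 0, 4e-12)
  expect_identical(same$recording$data, rec$data)
  expect_equal(nrow(same$log), 0L)

  inj <- inject_artifacts(rec, 5, 4e-12, seed = 17)
  expect_equal(nrow(inj$log), 5L)
  fs <- rec$sampling_rate
  for (tt in inj$log$time_s) {
    idx <- floor((tt - 0.25) * fs):ceiling((tt + 0.25) * fs)
    expect_gt(max(abs(inj$recording$data[, idx])), 3e-12)
  }
  # end to end: every epoch covering an artifact's super-threshold core is
  # rejected, and every rejection overlaps some artifact
  ep <- extract_epochs(inj$recording, ev)
  clean <- reject_artifacts(ep)
  rep <- attr(clean, "rejections")
  core_hit <- unique(unlist(lapply(inj$log$time_s, function(tt)
    which(ev$onset - 0.2 <= tt - 0.08 & ev$onset - 0.2 + 3.6 >= tt + 0.08))))
  any_hit <- unique(unlist(lapply(inj$log$time_s, function(tt)
    which(ev$onset - 0.2 <= tt + 0.26 & ev$onset - 0.2 + 3.6 >= tt - 0.26))))
  expect_true(all(core_hit %in% rep$trial))
  expect_true(all(rep$trial %in% any_hit))

  # sub-threshold artifacts survive rejection
  weak <- inject_artifacts(rec, 5, 1e-15, seed = 18)
  ep2 <- reject_artifacts(extract_epochs(weak$recording, ev))
  expect_equal(nrow(attr(ep2, "rejections")), 0L)
})
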