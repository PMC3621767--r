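#' Oddball trial specification
#'
#' Describes the temporal structure of one oddball session: a short melodic
#' sequence (`tones_per_sequence` tones of `tone_duration` seconds each)
#' repeated at a fixed stimulus-onset asynchrony of sequence duration plus
#' `inter_sequence_interval`.  A minority of sequences end in a deviant final
#' tone.  Defaults reproduce a six-tone, 300 ms/tone melody (1.8 s) with a
#' 900 ms silent gap, 320 standards and 80 deviants per run, two runs.
#'
#' @param tone_duration Tone duration in seconds.
#' @param tones_per_sequence Number of tones per sequence.
#' @param inter_sequence_interval Silent gap between sequences, seconds.
#' @param n_standard Standards per run.
#' @param n_deviant Deviants per run.
#' @param n_runs Number of runs.
#' @param lead_in_s Time from run start to the first sequence onset, seconds.
#' @return An object of class `trial_spec`.
#' @export
trial_spec <- function(tone_duration = 0.3, tones_per_sequence = 6L,
                       inter_sequence_interval = 0.9,
                       n_standard = 320L, n_deviant = 80L, n_runs = 2L,
                       lead_in_s = 1.0) {
  if (tone_duration <= 0) stop("configuration error: tone_duration must be > 0")
  if (n_deviant > n_standard)
    stop("configuration error: n_deviant must not exceed n_standard")
  if (inter_sequence_interval < 0)
    stop("configuration error: inter_sequence_interval must be >= 0")
  structure(list(
    tone_duration = tone_duration,
    tones_per_sequence = as.integer(tones_per_sequence),
    inter_sequence_interval = inter_sequence_interval,
    n_standard = as.integer(n_standard),
    n_deviant = as.integer(n_deviant),
    n_runs = as.integer(n_runs),
    lead_in_s = lead_in_s
  ), class = "trial_spec")
}

#' @export
print.trial_spec <- function(x, ...) {
  cat(sprintf(
    "Oddball trial spec: %d x %.0f ms tones (%.0f ms sequence), %.0f ms gap\n",
    x$tones_per_sequence, x$tone_duration * 1000,
    sequence_duration(x) * 1000, x$inter_sequence_interval * 1000))
  cat(sprintf("  %d standards + %d deviants per run, %d run(s)\n",
              x$n_standard, x$n_deviant, x$n_runs))
  invisible(x)
}

#' Sequence (melody) duration in seconds
#' @param spec A [trial_spec()].
#' @export
sequence_duration <- function(spec) spec$tones_per_sequence * spec$tone_duration

#' Onset of the final tone relative to sequence onset, seconds
#' @param spec A [trial_spec()].
#' @export
final_tone_offset <- function(spec)
  (spec$tones_per_sequence - 1L) * spec$tone_duration

#' Generate an oddball event table
#'
#' Lays out `n_standard + n_deviant` trials per run at a fixed
#' stimulus-onset asynchrony and assigns deviant positions uniformly at
#' random among the placements that keep (i) the first trial a standard and
#' (ii) no two deviants adjacent.  Non-adjacency guarantees that every
#' deviant has a standard immediately before it, so the deviant-vs-preceding-
#' standard contrast analyzes exactly as many standards as deviants.
#'
#' Deviant placement uses rejection-free sequential sampling: among the
#' standards, `n_deviant` of the `n_standard` gaps *after* a standard are
#' drawn without replacement, which is in bijection with the admissible
#' arrangements.
#'
#' @param spec A [trial_spec()].
#' @param seed Integer seed; the table is a deterministic function of
#'   `(spec, seed)`.
#' @return A data.frame of class `event_table` with columns `run_id`,
#'   `trial_index` (0-based within run), `onset` (s from run start),
#'   `duration` (s), `trial_type` (`"standard"`/`"deviant"`), and
#'   `deviant_onset` (onset of the final tone, s from run start).
#' @export
generate_oddball_events <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "trial_spec"))
  if (spec$n_deviant > 0 && spec$n_deviant >= spec$n_standard)
    stop("configuration error: need n_deviant < n_standard for non-adjacent placement")
  n_trials <- spec$n_standard + spec$n_deviant
  soa <- sequence_duration(spec) + spec$inter_sequence_interval
  with_seed(seed, {
    runs <- lapply(seq_len(spec$n_runs), function(r) {
      types <- rep("standard", n_trials)
      if (spec$n_deviant > 0) {
        # Choose which standards are followed by a deviant, then interleave.
        gaps <- sort(sample.int(spec$n_standard, spec$n_deviant))
        types <- character(0)
        for (i in seq_len(spec$n_standard)) {
          types <- c(types, "standard")
          if (i %in% gaps) types <- c(types, "deviant")
        }
      }
      onset <- spec$lead_in_s + (seq_len(n_trials) - 1) * soa
      data.frame(
        run_id = r,
        trial_index = seq_len(n_trials) - 1L,
        onset = onset,
        duration = sequence_duration(spec),
        trial_type = types,
        deviant_onset = onset + final_tone_offset(spec),
        stringsAsFactors = FALSE
      )
    })
    out <- do.call(rbind, runs)
    rownames(out) <- NULL
    class(out) <- c("event_table", "data.frame")
    attr(out, "spec") <- spec
    out
  })
}

#' Select deviant / directly-preceding-standard trial pairs
#'
#' For each deviant trial whose immediate predecessor (within the same run)
#' is a standard, returns the pair; each standard appears in at most one
#' pair.  A deviant preceded by another deviant cannot be contrasted this
#' way and is dropped with a message (this cannot happen for tables from
#' [generate_oddball_events()]).
#'
#' @param events An `event_table`.
#' @return A data.frame with columns `run_id`, `standard_trial`,
#'   `deviant_trial` (0-based trial indices within run).
#' @export
select_analysis_trials <- function(events) {
  stopifnot(is.data.frame(events),
            all(c("run_id", "trial_index", "trial_type") %in% names(events)))
  out <- lapply(split(events, events$run_id), function(ev) {
    ev <- ev[order(ev$trial_index), ]
    is_dev <- ev$trial_type == "deviant"
    idx <- which(is_dev)
    pairs <- list()
    for (i in idx) {
      if (i == 1L || ev$trial_type[i - 1L] == "deviant") {
        message(sprintf(
          "dropping deviant trial %d (run %d): no preceding standard",
          ev$trial_index[i], ev$run_id[i]))
        next
      }
      pairs[[length(pairs) + 1L]] <- data.frame(
        run_id = ev$run_id[i],
        standard_trial = ev$trial_index[i - 1L],
        deviant_trial = ev$trial_index[i])
    }
    if (length(pairs)) do.call(rbind, pairs) else
      data.frame(run_id = integer(0), standard_trial = integer(0),
                 deviant_trial = integer(0))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Write / read event tables as tab-separated values
#'
#' Columns follow BIDS-events naming (`onset`, `duration`, `trial_type`,
#' `run_id`, plus `trial_index` and `deviant_onset`); times are seconds with
#' millisecond precision or better.
#'
#' @param events An `event_table`.
#' @param path Output path.
#' @export
write_events_tsv <- function(events, path) {
  cols <- c("onset", "duration", "trial_type", "run_id", "trial_index",
            "deviant_onset")
  utils::write.table(events[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @param path Path to a TSV written by [write_events_tsv()].
#' @export
read_events_tsv <- function(path) {
  ev <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  class(ev) <- c("event_table", "data.frame")
  ev
}
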