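#' Beamformer weights at an arbitrary location
#'
#' Convenience wrapper: computes the gain at `location_mm` (head-frame mm)
#' with the forward model, picks the optimal orientation from the pooled
#' window covariance of the analyzed trial pairs, and returns the unit-gain
#' spatial filter.  By convention the weights come from the early
#' (mismatch-peak) analysis window.
#'
#' @param location_mm Length-3, millimeters, head frame.
#' @param pairs Analyzed trial pairs ([select_analysis_trials()]).
#' @param epochs An `epoch_set`.
#' @param head A [head_model()].
#' @param windows A [window_pair()]; default early window 100-200 ms.
#' @param channels Channel subset.
#' @param regularization Diagonal-loading fraction.
#' @return A `spatial_filter`.
#' @export
location_weights <- function(location_mm, pairs, epochs, head,
                             windows = window_pair(),
                             channels = NULL, regularization = 0.05) {
  if (is.null(channels)) channels <- seq_len(dim(epochs$epochs)[2])
  ep_key <- paste(epochs$run_id, epochs$trial_index)
  dev_rows <- match(paste(pairs$run_id, pairs$deviant_trial), ep_key)
  std_rows <- match(paste(pairs$run_id, pairs$standard_trial), ep_key)
  ok <- !is.na(dev_rows) & !is.na(std_rows)
  Ca <- compute_covariance(epochs, windows$active, trials = dev_rows[ok],
                           channels = channels)
  Cc <- compute_covariance(epochs, windows$control, trials = std_rows[ok],
                           channels = channels)
  Cpool <- Ca
  Cpool$matrix <- (Ca$matrix + Cc$matrix) / 2
  arr <- epochs$array[channels, , drop = FALSE]
  gain <- cbind(sarvas_field(location_mm / 1000, c(1, 0, 0), head, arr),
                sarvas_field(location_mm / 1000, c(0, 1, 0), head, arr),
                sarvas_field(location_mm / 1000, c(0, 0, 1), head, arr))
  ori <- optimal_orientation(gain, Cpool, regularization)
  flt <- sam_weights(gain, ori, Cpool, regularization)
  flt$channels <- channels
  flt
}

#' Virtual channel: project epochs through beamformer weights
#'
#' Applies one location's spatial filter to the sensor data of every trial,
#' yielding a per-trial source time series over the whole epoch.
#'
#' @param filter A `spatial_filter` (its `channels` must be a subset of the
#'   epoch channels; `NULL` means all).
#' @param epochs An `epoch_set`.
#' @return Object of class `virtual_channel`: `traces`
#'   (`trials x samples`), `condition`, `time_post_deviant_s`,
#'   `sampling_rate`.
#' @export
extract_virtual_channel <- function(filter, epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  w <- if (inherits(filter, "spatial_filter")) filter$weights else
    as.numeric(filter)
  channels <- if (inherits(filter, "spatial_filter") &&
                  !is.null(filter$channels)) filter$channels else
    seq_len(dim(epochs$epochs)[2])
  if (length(w) != length(channels) ||
      max(channels) > dim(epochs$epochs)[2])
    stop("filter channels do not match the epoch channels")
  ntr <- dim(epochs$epochs)[1]
  nsamp <- dim(epochs$epochs)[3]
  traces <- matrix(0, ntr, nsamp)
  for (tr in seq_len(ntr))
    traces[tr, ] <- w %*% epochs$epochs[tr, channels, , drop = TRUE]
  structure(list(traces = traces, condition = epochs$condition,
                 time_post_deviant_s = epoch_times_post_deviant(epochs),
                 sampling_rate = epochs$sampling_rate),
            class = "virtual_channel")
}

#' Group RMS difference waveform and mismatch peak latency
#'
#' Per subject and condition the virtual-channel activity is summarized as
#' the RMS over trials at each sample (`method = "trials"`, default) or as
#' the absolute trial-averaged evoked trace (`method = "evoked"`).  Subject
#' waveforms are averaged; the difference (deviant minus standard) traces
#' the mismatch time course, and its peak latency is located within the
#' search window after the deviant-tone onset.
#'
#' @param traces List of `virtual_channel` objects, one per subject, all on
#'   the same time axis.
#' @param method `"trials"` or `"evoked"` (see above).
#' @param latency_window Length-2 seconds post-deviant for the peak search.
#' @return List of class `vc_waveform`: `time_s` (post-deviant),
#'   `standard_rms`, `deviant_rms`, `difference`, `peak_latency_s` (NA when
#'   the difference is identically zero).
#' @export
rms_difference_waveform <- function(traces, method = c("trials", "evoked"),
                                    latency_window = c(0, 0.3)) {
  method <- match.arg(method)
  stopifnot(length(traces) >= 1)
  per_cond <- function(vc, cond) {
    sel <- which(vc$condition == cond)
    if (!length(sel)) stop("subject lacks condition '", cond, "'")
    X <- vc$traces[sel, , drop = FALSE]
    if (method == "trials") sqrt(colMeans(X^2)) else abs(colMeans(X))
  }
  std <- rowMeans(vapply(traces, per_cond, numeric(ncol(traces[[1]]$traces)),
                         cond = "standard"))
  dev <- rowMeans(vapply(traces, per_cond, numeric(ncol(traces[[1]]$traces)),
                         cond = "deviant"))
  diff <- dev - std
  t <- traces[[1]]$time_post_deviant_s
  sel <- which(t >= latency_window[1] & t <= latency_window[2])
  peak <- if (all(abs(diff[sel]) < .Machine$double.eps * 100)) NA_real_ else
    t[sel[which.max(diff[sel])]]
  structure(list(time_s = t, standard_rms = std, deviant_rms = dev,
                 difference = diff, peak_latency_s = peak),
            class = "vc_waveform")
}

#' Write a virtual-channel waveform as TSV
#' @param wf A `vc_waveform`.
#' @param path Output path.
#' @export
write_waveform_tsv <- function(wf, path) {
  utils::write.table(
    data.frame(time_s = wf$time_s, standard_rms = wf$standard_rms,
               deviant_rms = wf$deviant_rms, difference = wf$difference),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
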