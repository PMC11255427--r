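# Epoch-based vigilance-state scoring from EEG band powers and EMG tone.
#
# The rule cascade is deliberately transparent and quantile-calibrated
# per recording (EMG gain is hardware-dependent, so absolute thresholds
# do not transfer between rigs):
#   1. high muscle tone               -> WAKE
#   2. theta-dominant EEG + atonia    -> REM
#   3. otherwise                      -> NREM

#' Scoring thresholds
#'
#' @param emg_wake_quantile per-recording EMG RMS quantile above which an
#'   epoch is scored WAKE (default 0.60). The quantile should
#'   approximate one minus the expected wake fraction of the recording;
#'   see the package vignette.
#' @param theta_delta_rem_threshold minimum theta/delta power ratio for
#'   REM (default 2).
#' @param emg_atonia_quantile EMG RMS quantile below which muscle atonia
#'   is assumed (default 0.25).
#' @param smoothing_min_bout_epochs minimum bout length (epochs) used by
#'   [smooth_hypnogram()] (default 2).
#' @return Object of class `scoring_thresholds`.
#' @export
scoring_thresholds <- function(emg_wake_quantile = 0.60,
                               theta_delta_rem_threshold = 2.0,
                               emg_atonia_quantile = 0.25,
                               smoothing_min_bout_epochs = 2L) {
  if (emg_wake_quantile <= 0 || emg_wake_quantile >= 1 ||
      emg_atonia_quantile <= 0 || emg_atonia_quantile >= 1)
    stop("scoring_thresholds: quantiles must lie in (0, 1)")
  if (theta_delta_rem_threshold <= 0)
    stop("scoring_thresholds: theta/delta threshold must be positive")
  if (smoothing_min_bout_epochs < 1)
    stop("scoring_thresholds: smoothing_min_bout_epochs must be >= 1")
  structure(list(emg_wake_quantile = emg_wake_quantile,
                 theta_delta_rem_threshold = theta_delta_rem_threshold,
                 emg_atonia_quantile = emg_atonia_quantile,
                 smoothing_min_bout_epochs =
                   as.integer(smoothing_min_bout_epochs)),
            class = "scoring_thresholds")
}

#' Per-epoch scoring features
#'
#' Welch PSD per epoch on the first EEG channel (0.5 Hz bins; band sums
#' over the configured delta and theta edges) and per-epoch EMG RMS on
#' the first EMG channel. The trailing partial epoch is discarded.
#'
#' @param record a [signal_record()] with at least one EEG and one EMG
#'   channel.
#' @param epoch_s epoch length, seconds.
#' @param bands band-edge table (single source of truth shared with the
#'   spectral module), default [default_bands()].
#' @return `data.frame` of class `epoch_features` with columns `epoch`,
#'   `delta_power`, `theta_power`, `theta_delta_ratio`, `emg_rms`;
#'   attributes `epoch_s` and `start_zt`.
#' @export
compute_epoch_features <- function(record, epoch_s = 10,
                                   bands = default_bands()) {
  stopifnot(inherits(record, "signal_record"))
  emg <- record$samples[, channel_by_role(record, "EMG")]
  if (record$duration_s < epoch_s)
    stop("compute_epoch_features: record shorter than one epoch")
  max_hz <- if (record$fs >= 128) 64 else record$fs / 2
  sp <- epoch_psd(record, epoch_s = epoch_s, max_hz = max_hz)
  f <- sp$freq_hz
  dsel <- f >= bands$lo_hz[bands$name == "delta"] &
    f < bands$hi_hz[bands$name == "delta"]
  tsel <- f >= bands$lo_hz[bands$name == "theta"] &
    f < bands$hi_hz[bands$name == "theta"]
  delta <- rowSums(sp$psd[, dsel, drop = FALSE])
  theta <- rowSums(sp$psd[, tsel, drop = FALSE])
  n_ep <- as.integer(round(record$fs * epoch_s))
  n_epochs <- nrow(sp$psd)
  emg_rms <- vapply(seq_len(n_epochs), function(e)
    sqrt(mean(emg[((e - 1L) * n_ep + 1L):(e * n_ep)]^2)), 0)
  out <- data.frame(epoch = seq_len(n_epochs), delta_power = delta,
                    theta_power = theta,
                    theta_delta_ratio = ifelse(delta > 0, theta / delta,
                                               NA_real_),
                    emg_rms = emg_rms)
  attr(out, "epoch_s") <- epoch_s
  attr(out, "start_zt") <- record$start_zt
  class(out) <- c("epoch_features", "data.frame")
  out
}

#' Classify epochs into vigilance states
#'
#' Rule cascade per epoch: (1) EMG RMS above the recording's
#' `emg_wake_quantile` quantile scores WAKE (muscle tone takes
#' precedence over any EEG pattern); (2) otherwise, a theta/delta ratio
#' above `theta_delta_rem_threshold` together with EMG RMS below the
#' `emg_atonia_quantile` quantile scores REM; (3) otherwise NREM.
#'
#' @param features an [compute_epoch_features()] result.
#' @param thresholds a [scoring_thresholds()].
#' @return A [hypnogram()].
#' @export
classify_epochs <- function(features, thresholds = scoring_thresholds()) {
  stopifnot(inherits(features, "epoch_features"),
            inherits(thresholds, "scoring_thresholds"))
  if (all(features$delta_power == 0 & features$theta_power == 0))
    stop("classify_epochs: unscorable record (all-zero EEG power)")
  q_wake <- stats::quantile(features$emg_rms,
                            thresholds$emg_wake_quantile, names = FALSE)
  q_atonia <- stats::quantile(features$emg_rms,
                              thresholds$emg_atonia_quantile, names = FALSE)
  ratio <- features$theta_delta_ratio
  ratio[is.na(ratio)] <- Inf   # no delta power at all reads as theta-dominant
  lab <- rep("NREM", nrow(features))
  lab[ratio > thresholds$theta_delta_rem_threshold &
        features$emg_rms < q_atonia] <- "REM"
  lab[features$emg_rms > q_wake] <- "WAKE"
  hypnogram(lab, epoch_s = attr(features, "epoch_s"),
            start_zt = attr(features, "start_zt"))
}

#' Smooth a hypnogram by suppressing short bouts
#'
#' Repeatedly reassigns any maximal run shorter than `min_bout_epochs`
#' to the preceding state (the first run is exempt) until a fixed point
#' is reached. Never increases the number of bouts.
#'
#' @param h a [hypnogram()].
#' @param min_bout_epochs minimum run length in epochs (>= 1; 1 is the
#'   identity).
#' @return A smoothed [hypnogram()].
#' @export
smooth_hypnogram <- function(h, min_bout_epochs = 2L) {
  stopifnot(inherits(h, "hypnogram"), min_bout_epochs >= 1)
  lab <- as.character(h)
  repeat {
    r <- rle(lab)
    short <- which(r$lengths < min_bout_epochs)
    short <- short[short > 1L]
    if (!length(short)) break
    i <- short[1L]
    r$values[i] <- r$values[i - 1L]
    lab <- inverse.rle(r)
  }
  hypnogram(lab, epoch_s = attr(h, "epoch_s"),
            start_zt = attr(h, "start_zt"))
}
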