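# Per-epoch Welch power spectra and relative band-power normalization.
#
# Conventions fixed here and used by both scoring and spectral outputs:
#  * 0.5 Hz frequency resolution (Welch segments of 2*fs samples, Hann
#    window, 50% overlap), bins spanning [0, 64) Hz;
#  * frequency bands are half-open [lo, hi);
#  * per-epoch "total power" is the sum over the fifty 0.5 Hz bins with
#    0 < f <= 25 Hz: the DC bin is excluded (amplifier offset is not
#    physiology) and the 25.0 Hz bin closes the set at exactly 50 bins.

#' Default EEG frequency bands
#'
#' Rodent conventions, half-open in Hz: delta `[0.5, 4)`, theta
#' `[4.5, 8.5)`, sigma `[10, 14)`. All band-level results depend on
#' these configurable edges.
#'
#' @return `data.frame` with columns `name`, `lo_hz`, `hi_hz`.
#' @export
default_bands <- function() {
  data.frame(name = c("delta", "theta", "sigma"),
             lo_hz = c(0.5, 4.5, 10.0),
             hi_hz = c(4.0, 8.5, 14.0),
             stringsAsFactors = FALSE)
}

check_bands <- function(bands, total_lo = 0, total_hi = 25) {
  if (!all(c("name", "lo_hz", "hi_hz") %in% names(bands)))
    stop("bands need columns name, lo_hz, hi_hz")
  if (any(bands$lo_hz < total_lo) || any(bands$hi_hz > total_hi) ||
      any(bands$lo_hz >= bands$hi_hz))
    stop(sprintf("band edges must satisfy %g <= lo < hi <= %g",
                 total_lo, total_hi))
  bands
}

hann <- function(n) 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))

# Welch PSD of a single segment-partitioned vector; returns one-sided
# density over freqs (0:(nper/2)) * fs/nper
welch_psd <- function(x, fs, nper) {
  step <- nper %/% 2L
  n <- length(x)
  starts <- seq(1L, n - nper + 1L, by = step)
  w <- hann(nper)
  scale <- 1 / (fs * sum(w^2))
  nbins <- nper %/% 2L + 1L
  acc <- numeric(nbins)
  for (s0 in starts) {
    seg <- x[s0:(s0 + nper - 1L)] * w
    p <- abs(stats::fft(seg)[seq_len(nbins)])^2 * scale
    p[2:(nbins - 1L)] <- 2 * p[2:(nbins - 1L)]  # fold negative freqs
    acc <- acc + p
  }
  acc / length(starts)
}

#' Per-epoch Welch power spectral density
#'
#' Splits the first EEG channel into consecutive epochs (trailing partial
#' epoch discarded) and computes a Welch PSD per epoch: Hann-windowed
#' segments of `2*fs` samples (0.5 Hz resolution) at 50% overlap. Bins at
#' and above `max_hz` are discarded.
#'
#' @param record a [signal_record()] with an EEG channel.
#' @param epoch_s epoch length, seconds (default 10).
#' @param max_hz upper edge of the retained bins, default 64 (requires
#'   `fs >= 128`; pass a lower value for slower recordings).
#' @return Object of class `spectral_epochs`: list with `psd`
#'   (n_epochs x n_bins matrix, density units^2/Hz), `freq_hz` (bin
#'   frequencies, each bin covering `[f, f + 0.5)`), `epoch_s`, `fs`.
#' @export
epoch_psd <- function(record, epoch_s = 10, max_hz = 64) {
  stopifnot(inherits(record, "signal_record"))
  eeg <- record$samples[, channel_by_role(record, "EEG")]
  fs <- record$fs
  if (fs < 2 * max_hz)
    stop(sprintf(
      "epoch_psd: Nyquist below %g Hz (fs = %g); lower max_hz to analyse",
      max_hz, fs))
  n_ep <- as.integer(round(fs * epoch_s))
  nper <- as.integer(round(2 * fs))
  if (n_ep < nper)
    stop("epoch_psd: epoch shorter than one Welch segment (2 s)")
  n_epochs <- length(eeg) %/% n_ep
  if (n_epochs < 1L) stop("epoch_psd: record shorter than one epoch")
  nbins_keep <- as.integer(max_hz / 0.5)
  psd <- matrix(0, n_epochs, nbins_keep)
  for (e in seq_len(n_epochs)) {
    seg <- eeg[((e - 1L) * n_ep + 1L):(e * n_ep)]
    psd[e, ] <- welch_psd(seg, fs, nper)[seq_len(nbins_keep)]
  }
  structure(list(psd = psd, freq_hz = (seq_len(nbins_keep) - 1L) * 0.5,
                 epoch_s = epoch_s, fs = fs),
            class = "spectral_epochs")
}

#' Relative band power per epoch
#'
#' Normalizes each epoch's band power to the epoch's total power, the
#' sum of the fifty 0.5 Hz bins with `total_lo < f <= total_hi`
#' (DC excluded). Band membership is half-open: bins with
#' `lo_hz <= f < hi_hz`.
#'
#' @param spectral a [epoch_psd()] result (or a compatible list with
#'   `psd` and `freq_hz`).
#' @param bands band definition table, default [default_bands()].
#' @param total_lo,total_hi edges of the total-power span, Hz.
#' @return Long `data.frame` (`epoch`, `band`, `relative_power_pct`)
#'   where `epoch` is 1-based; percentages lie in `[0, 100]`.
#' @export
relative_band_power <- function(spectral, bands = default_bands(),
                                total_lo = 0, total_hi = 25) {
  bands <- check_bands(bands, total_lo, total_hi)
  f <- spectral$freq_hz
  psd <- spectral$psd
  tot_sel <- f > total_lo & f <= total_hi
  total <- rowSums(psd[, tot_sel, drop = FALSE])
  if (any(total <= 0))
    stop("relative_band_power: degenerate epoch ", which(total <= 0)[1],
         " (zero total power)")
  out <- vector("list", nrow(bands))
  for (b in seq_len(nrow(bands))) {
    sel <- f >= bands$lo_hz[b] & f < bands$hi_hz[b]
    out[[b]] <- data.frame(
      epoch = seq_len(nrow(psd)),
      band = bands$name[b],
      relative_power_pct = 100 * rowSums(psd[, sel, drop = FALSE]) / total,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Per-bin relative power over the total-power span
#'
#' Expresses every 0.5 Hz bin inside the total-power span
#' (`total_lo < f <= total_hi`, fifty bins for the default 0-25 Hz) as a
#' percentage of the epoch's total power. By construction each row sums
#' to exactly 100; this is the normalization identity behind all
#' band-level percentages.
#'
#' @inheritParams relative_band_power
#' @return Matrix n_epochs x n_total_bins of percentages; column names
#'   are the bin frequencies.
#' @export
relative_bin_power <- function(spectral, total_lo = 0, total_hi = 25) {
  f <- spectral$freq_hz
  sel <- f > total_lo & f <= total_hi
  sub <- spectral$psd[, sel, drop = FALSE]
  total <- rowSums(sub)
  if (any(total <= 0))
    stop("relative_bin_power: degenerate epoch ", which(total <= 0)[1],
         " (zero total power)")
  out <- 100 * sub / total
  colnames(out) <- f[sel]
  out
}

#' Aggregate relative band power by state, phase and group
#'
#' Computes, per animal, the mean relative power over epochs of each
#' vigilance state within each light/dark phase, then summarizes across
#' animals within treatment groups (mean, SEM, n). This is the long
#' state x phase x group x band summary used for band-power
#' dose-response figures.
#'
#' @param tables named list (one element per animal) of
#'   [relative_band_power()] tables.
#' @param hypnograms named list of matching [hypnogram()]s (epoch indices
#'   aligned with the band tables).
#' @param groups named character vector mapping animal id to group.
#' @return `data.frame` with columns `state`, `phase`, `group`, `band`,
#'   `mean`, `sem`, `n`. Cells with no epochs for an animal contribute
#'   `n = 0` and are flagged with `NA` means.
#' @export
aggregate_band_power <- function(tables, hypnograms, groups) {
  stopifnot(is.list(tables), is.list(hypnograms))
  animals <- names(tables)
  if (is.null(animals) || !setequal(animals, names(hypnograms)) ||
      !all(animals %in% names(groups)))
    stop("aggregate_band_power: tables, hypnograms and groups must share names")
  per_animal <- list()
  for (a in animals) {
    h <- hypnograms[[a]]
    tab <- tables[[a]]
    if (max(tab$epoch) > length(h))
      stop("aggregate_band_power: band table of ", a,
           " has epochs beyond its hypnogram")
    ph <- zt_phase(epoch_zt(h))
    st <- as.character(h)
    key <- expand.grid(state = VIGILANCE_STATES,
                       phase = c("light", "dark"),
                       band = unique(tab$band), stringsAsFactors = FALSE)
    key$group <- unname(groups[a])
    key$animal <- a
    key$value <- NA_real_
    for (i in seq_len(nrow(key))) {
      ep <- which(st == key$state[i] & ph == key$phase[i])
      v <- tab$relative_power_pct[tab$band == key$band[i] &
                                    tab$epoch %in% ep]
      if (length(v)) key$value[i] <- mean(v)
    }
    per_animal[[a]] <- key
  }
  long <- do.call(rbind, per_animal)
  agg <- stats::aggregate(value ~ state + phase + group + band, data = long,
                          FUN = function(v) c(mean = mean(v),
                                              sem = stats::sd(v) /
                                                sqrt(length(v)),
                                              n = length(v)),
                          na.action = stats::na.omit)
  out <- cbind(agg[, c("state", "phase", "group", "band")],
               as.data.frame(agg$value))
  names(out)[5:7] <- c("mean", "sem", "n")
  # flag state x phase cells absent for every animal of a group
  full <- unique(long[, c("state", "phase", "group", "band")])
  out <- merge(full, out, all.x = TRUE,
               by = c("state", "phase", "group", "band"))
  out$n[is.na(out$n)] <- 0
  out[order(out$state, out$phase, out$group, out$band), , drop = FALSE]
}
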