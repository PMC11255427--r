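# Domain types shared by every analysis stage. All constructors validate
# their invariants up front so downstream code can assume clean inputs.

VIGILANCE_STATES <- c("WAKE", "NREM", "REM")

#' Multichannel EEG/EMG signal record
#'
#' Container for a polysomnographic recording: a sample matrix with one
#' column per channel, channel labels and roles, the sampling rate, and the
#' recording start expressed in Zeitgeber time (hours since lights-on).
#' Times within the record are always seconds from recording start; ZT is
#' carried as metadata only.
#'
#' @param samples numeric matrix, one column per channel (rows are samples).
#' @param labels character vector of channel labels, one per column.
#' @param roles character vector of channel roles, each one of
#'   `"EEG"`, `"EMG"` or `"OTHER"`.
#' @param fs sampling rate in Hz (> 0).
#' @param start_zt recording start in Zeitgeber hours, in `[0, 24)`.
#' @param units character vector of physical units per channel (recycled).
#'
#' @return An object of class `signal_record` with fields `samples`,
#'   `labels`, `roles`, `fs`, `start_zt`, `units`, `duration_s`.
#' @export
signal_record <- function(samples, labels, roles, fs, start_zt = 0,
                          units = "uV") {
  if (!is.matrix(samples)) samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  nch <- ncol(samples)
  if (nch == 0L || nrow(samples) == 0L)
    stop("signal_record: zero-length channel data")
  if (length(labels) != nch)
    stop("signal_record: need one label per channel")
  if (length(roles) != nch)
    stop("signal_record: need one role per channel")
  roles <- toupper(as.character(roles))
  bad <- setdiff(roles, c("EEG", "EMG", "OTHER"))
  if (length(bad))
    stop("signal_record: unknown channel role(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(labels))
    stop("signal_record: duplicated channel labels")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("signal_record: fs must be a single positive number")
  if (!is.numeric(start_zt) || start_zt < 0 || start_zt >= 24)
    stop("signal_record: start_zt must lie in [0, 24)")
  units <- rep_len(as.character(units), nch)
  structure(
    list(samples = samples, labels = as.character(labels), roles = roles,
         fs = fs, start_zt = as.numeric(start_zt), units = units,
         duration_s = nrow(samples) / fs),
    class = "signal_record")
}

#' @export
print.signal_record <- function(x, ...) {
  cat(sprintf("<signal_record> %d channel(s), fs = %g Hz, %.1f s, start ZT %.2f\n",
              ncol(x$samples), x$fs, x$duration_s, x$start_zt))
  for (i in seq_along(x$labels))
    cat(sprintf("  %-8s %-5s [%s]\n", x$labels[i], x$roles[i], x$units[i]))
  invisible(x)
}

# index of the first channel with a given role, or error
channel_by_role <- function(record, role) {
  i <- which(record$roles == role)
  if (!length(i))
    stop(sprintf("signal_record has no channel with role %s", role))
  i[1L]
}

#' Hypnogram: epoch-wise vigilance-state labels
#'
#' An ordered sequence of vigilance-state labels (`WAKE`, `NREM`, `REM`),
#' one per fixed-length epoch, anchored in Zeitgeber time.
#'
#' @param labels character or factor vector over `WAKE`/`NREM`/`REM`.
#' @param epoch_s epoch length in seconds (default 10).
#' @param start_zt Zeitgeber hour of the first epoch, in `[0, 24)`.
#' @return Object of class `hypnogram`: a factor with attributes
#'   `epoch_s` and `start_zt`.
#' @export
hypnogram <- function(labels, epoch_s = 10, start_zt = 0) {
  labels <- as.character(labels)
  if (!length(labels)) stop("hypnogram: labels must be non-empty")
  bad <- setdiff(unique(labels), VIGILANCE_STATES)
  if (length(bad))
    stop("hypnogram: label(s) outside {WAKE, NREM, REM}: ",
         paste(bad, collapse = ", "))
  if (!is.numeric(epoch_s) || length(epoch_s) != 1L || epoch_s <= 0)
    stop("hypnogram: epoch_s must be a single positive number")
  if (!is.numeric(start_zt) || start_zt < 0 || start_zt >= 24)
    stop("hypnogram: start_zt must lie in [0, 24)")
  structure(factor(labels, levels = VIGILANCE_STATES),
            epoch_s = as.numeric(epoch_s), start_zt = as.numeric(start_zt),
            class = c("hypnogram", "factor"))
}

#' @export
print.hypnogram <- function(x, ...) {
  tb <- table(unclass_hypnogram(x))
  cat(sprintf("<hypnogram> %d epochs x %g s, start ZT %.2f | %s\n",
              length(x), attr(x, "epoch_s"), attr(x, "start_zt"),
              paste(sprintf("%s %d", names(tb), tb), collapse = ", ")))
  invisible(x)
}

unclass_hypnogram <- function(h) {
  factor(as.character(h), levels = VIGILANCE_STATES)
}

# Zeitgeber hour of each epoch start
epoch_zt <- function(h) {
  (attr(h, "start_zt") + (seq_along(h) - 1) * attr(h, "epoch_s") / 3600) %% 24
}

# light = ZT [0, 12), dark = ZT [12, 24)
zt_phase <- function(zt) ifelse(zt %% 24 < 12, "light", "dark")

#' Spike train with optional dose-block annotations
#'
#' @param times_s strictly increasing spike times in seconds, all within
#'   `[0, duration_s)`.
#' @param duration_s total recording duration in seconds.
#' @param blocks optional data frame with columns `label`, `start_s`,
#'   `end_s` and `dose_mg_per_kg` (NA for vehicle); blocks must be
#'   non-overlapping and lie within `[0, duration_s]`. Block membership is
#'   half-open: a spike at `end_s` belongs to the next block.
#' @return Object of class `spike_train`.
#' @export
spike_train <- function(times_s, duration_s, blocks = NULL) {
  times_s <- as.numeric(times_s)
  if (anyNA(times_s) || (length(times_s) && any(!is.finite(times_s))))
    stop("spike_train: non-finite spike times")
  if (length(times_s) && (min(times_s) < 0 || max(times_s) >= duration_s))
    stop("spike_train: spike times must lie in [0, duration_s)")
  if (length(times_s) > 1L && any(diff(times_s) <= 0))
    stop("spike_train: spike times not strictly increasing")
  if (!is.numeric(duration_s) || duration_s <= 0)
    stop("spike_train: duration_s must be positive")
  if (!is.null(blocks)) {
    blocks <- as.data.frame(blocks)
    need <- c("label", "start_s", "end_s")
    if (!all(need %in% names(blocks)))
      stop("spike_train: blocks need columns label, start_s, end_s")
    if (is.null(blocks$dose_mg_per_kg)) blocks$dose_mg_per_kg <- NA_real_
    if (any(blocks$end_s <= blocks$start_s))
      stop("spike_train: block end_s must exceed start_s")
    if (any(blocks$start_s < 0) || any(blocks$end_s > duration_s))
      stop("spike_train: blocks must lie within [0, duration_s]")
    o <- order(blocks$start_s)
    blocks <- blocks[o, , drop = FALSE]
    if (nrow(blocks) > 1L &&
        any(blocks$start_s[-1L] < blocks$end_s[-nrow(blocks)]))
      stop("spike_train: blocks overlap")
    rownames(blocks) <- NULL
  }
  structure(list(times_s = times_s, duration_s = as.numeric(duration_s),
                 blocks = blocks),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spikes over %.1f s (%.3f Hz)%s\n",
              length(x$times_s), x$duration_s,
              length(x$times_s) / x$duration_s,
              if (is.null(x$blocks)) "" else
                sprintf(", %d block(s)", nrow(x$blocks))))
  invisible(x)
}

#' Concentration-time profile for pharmacokinetic analysis
#'
#' @param times_min strictly increasing sampling times, minutes post dose.
#' @param conc_ng_per_ml non-negative plasma concentrations, ng/ml.
#' @param dose_mg_per_kg administered dose (metadata).
#' @param route administration route (metadata, e.g. `"sc"`, `"iv"`).
#' @return Object of class `pk_profile`.
#' @export
pk_profile <- function(times_min, conc_ng_per_ml, dose_mg_per_kg = NA_real_,
                       route = "sc") {
  times_min <- as.numeric(times_min)
  conc <- as.numeric(conc_ng_per_ml)
  if (length(times_min) != length(conc))
    stop("pk_profile: times and concentrations differ in length")
  if (length(times_min) < 1L) stop("pk_profile: empty profile")
  if (anyNA(times_min) || anyNA(conc))
    stop("pk_profile: missing values")
  if (length(times_min) > 1L && any(diff(times_min) <= 0))
    stop("pk_profile: times not strictly increasing")
  if (any(conc < 0)) stop("pk_profile: negative concentration")
  structure(list(times_min = times_min, conc_ng_per_ml = conc,
                 dose_mg_per_kg = dose_mg_per_kg, route = route),
            class = "pk_profile")
}

#' qPCR cycle-threshold table
#'
#' Long-format Ct table with one row per (sample, gene) measurement.
#' Groups are `"test"` and `"control"`; completeness of target/reference
#' genes per sample is checked at quantification time by [ddct()].
#'
#' @param sample_id sample identifiers.
#' @param group group membership, `"test"` or `"control"`.
#' @param gene gene name measured in the row.
#' @param ct finite cycle-threshold value.
#' @return A `data.frame` of class `ct_table`.
#' @export
ct_table <- function(sample_id, group, gene, ct) {
  group <- as.character(group)
  bad <- setdiff(unique(group), c("test", "control"))
  if (length(bad))
    stop("ct_table: group must be 'test' or 'control', got: ",
         paste(bad, collapse = ", "))
  ct <- as.numeric(ct)
  if (anyNA(ct) || any(!is.finite(ct)))
    stop("ct_table: Ct values must be finite")
  out <- data.frame(sample_id = as.character(sample_id), group = group,
                    gene = as.character(gene), ct = ct,
                    stringsAsFactors = FALSE)
  class(out) <- c("ct_table", "data.frame")
  out
}
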