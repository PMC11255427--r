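# Locus-ceruleus spike-train analysis: block firing rates, baseline
# normalization, two-threshold ISI burst detection and the five burst
# metrics reported for LC-NE neurons.

#' Firing rate per dose block
#'
#' Rate = spike count in the block divided by the block duration.
#' Block membership is half-open `[start_s, end_s)`: a spike exactly at
#' a block's end boundary counts in the next block.
#'
#' @param train a [spike_train()].
#' @param blocks block table (`label`, `start_s`, `end_s`,
#'   `dose_mg_per_kg`); defaults to `train$blocks`.
#' @return `data.frame` (`label`, `dose_mg_per_kg`, `rate_hz`).
#' @export
block_firing_rate <- function(train, blocks = NULL) {
  stopifnot(inherits(train, "spike_train"))
  if (is.null(blocks)) blocks <- train$blocks
  if (is.null(blocks)) stop("block_firing_rate: no blocks supplied")
  dur <- blocks$end_s - blocks$start_s
  if (any(dur <= 0)) stop("block_firing_rate: zero-duration block")
  counts <- vapply(seq_len(nrow(blocks)), function(b)
    sum(train$times_s >= blocks$start_s[b] &
          train$times_s < blocks$end_s[b]), 0L)
  data.frame(label = blocks$label,
             dose_mg_per_kg = blocks$dose_mg_per_kg,
             rate_hz = counts / dur, stringsAsFactors = FALSE)
}

#' Express block rates as percent of a baseline block
#'
#' @param rates a [block_firing_rate()] table.
#' @param baseline_label label of the baseline (vehicle or antagonist)
#'   block.
#' @return The table with a `pct_of_baseline` column
#'   (`100 * rate / baseline rate`); the baseline row is exactly 100.
#' @export
normalize_to_baseline <- function(rates, baseline_label = "vehicle") {
  i <- which(rates$label == baseline_label)
  if (length(i) != 1L)
    stop("normalize_to_baseline: baseline block '", baseline_label,
         "' not found (or not unique)")
  base <- rates$rate_hz[i]
  if (base <= 0)
    stop("normalize_to_baseline: silent baseline, cannot normalize")
  rates$pct_of_baseline <- 100 * rates$rate_hz / base
  rates
}

#' Detect bursts by the two-threshold ISI criterion
#'
#' A burst is a train of at least two spikes opened by an interspike
#' interval strictly below 80 ms and extended while each subsequent
#' interval is at most 160 ms. The scan is greedy left-to-right: a spike
#' belongs to at most one burst, and a new burst may open on the spike
#' immediately following a closed one.
#'
#' @param train a [spike_train()].
#' @param open_isi_s opening ISI threshold, strict (default 0.080 s).
#' @param close_isi_s continuation ISI threshold, inclusive
#'   (default 0.160 s).
#' @return `data.frame` of class `burst_set`, one row per burst:
#'   `first_spike` (index), `n_spikes`, `onset_s`, `offset_s`,
#'   `length_s`, `mean_isi_s`. Bursts are disjoint and ordered.
#' @export
detect_bursts <- function(train, open_isi_s = 0.080, close_isi_s = 0.160) {
  stopifnot(inherits(train, "spike_train"))
  t <- train$times_s
  n <- length(t)
  first <- integer(0); last <- integer(0)
  i <- 1L
  while (i < n) {
    if (t[i + 1L] - t[i] < open_isi_s) {
      j <- i + 1L
      while (j < n && t[j + 1L] - t[j] <= close_isi_s) j <- j + 1L
      first <- c(first, i); last <- c(last, j)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  out <- data.frame(first_spike = first,
                    n_spikes = last - first + 1L,
                    onset_s = t[first], offset_s = t[last])
  if (!nrow(out))
    out <- data.frame(first_spike = integer(0), n_spikes = integer(0),
                      onset_s = numeric(0), offset_s = numeric(0))
  out$length_s <- out$offset_s - out$onset_s
  out$mean_isi_s <- ifelse(out$n_spikes > 1L,
                           out$length_s / (out$n_spikes - 1L), NA_real_)
  class(out) <- c("burst_set", "data.frame")
  out
}

#' Burst-firing metrics
#'
#' The five metrics reported for LC-NE burst activity: bursts per 200 s
#' (count linearly normalized to `window_s`), percentage of spikes in
#' bursts, mean spikes per burst, mean intra-burst interspike interval
#' (mean over bursts of each burst's mean ISI), and mean burst length.
#' With zero spikes all metrics are missing; with spikes but no bursts
#' the counts are 0 and the means missing.
#'
#' @param bursts a [detect_bursts()] result.
#' @param train the [spike_train()] the bursts came from.
#' @param window_s normalization window, seconds (default 200).
#' @return One-row `data.frame`: `bursts_per_200s`,
#'   `pct_spikes_in_bursts`, `mean_spikes_per_burst`,
#'   `mean_intra_burst_isi_s`, `mean_burst_length_s`, `window_s`.
#' @export
burst_metrics <- function(bursts, train, window_s = 200) {
  stopifnot(inherits(train, "spike_train"), window_s > 0)
  n_spikes <- length(train$times_s)
  if (n_spikes == 0L)
    return(data.frame(bursts_per_200s = NA_real_,
                      pct_spikes_in_bursts = NA_real_,
                      mean_spikes_per_burst = NA_real_,
                      mean_intra_burst_isi_s = NA_real_,
                      mean_burst_length_s = NA_real_,
                      window_s = window_s))
  nb <- nrow(bursts)
  data.frame(
    bursts_per_200s = nb * window_s / train$duration_s,
    pct_spikes_in_bursts = 100 * sum(bursts$n_spikes) / n_spikes,
    mean_spikes_per_burst = if (nb) mean(bursts$n_spikes) else NA_real_,
    mean_intra_burst_isi_s = if (nb) mean(bursts$mean_isi_s) else NA_real_,
    mean_burst_length_s = if (nb) mean(bursts$length_s) else NA_real_,
    window_s = window_s)
}

#' Per-neuron dose-block analysis
#'
#' Convenience wrapper running the whole single-neuron pipeline: block
#' firing rates, baseline normalization, and burst detection plus burst
#' metrics within each block.
#'
#' @param train a [spike_train()] with dose blocks.
#' @param baseline_label baseline block label.
#' @return `data.frame`, one row per block: rate, percent of baseline,
#'   and the five burst metrics computed on the spikes of that block.
#' @export
analyze_neuron <- function(train, baseline_label = "vehicle") {
  rates <- normalize_to_baseline(block_firing_rate(train), baseline_label)
  blocks <- train$blocks
  mets <- lapply(seq_len(nrow(blocks)), function(b) {
    sel <- train$times_s >= blocks$start_s[b] &
      train$times_s < blocks$end_s[b]
    sub <- spike_train(train$times_s[sel] - blocks$start_s[b],
                       duration_s = blocks$end_s[b] - blocks$start_s[b])
    burst_metrics(detect_bursts(sub), sub)
  })
  cbind(rates, do.call(rbind, mets))
}

#' Long dose-response table across neurons
#'
#' Stacks per-neuron block tables into the tidy
#' (`neuron_id`, `label`, `dose`, `metric`, `value`) layout consumed by
#' the repeated-measures ANOVA stage. Neurons missing blocks present in
#' other neurons are kept and flagged with a warning, never dropped
#' silently.
#'
#' @param per_neuron named list of [analyze_neuron()] tables (one per
#'   neuron; one neuron per rat in the source design).
#' @return Long `data.frame` sorted by metric, neuron and dose.
#' @export
dose_response_table <- function(per_neuron) {
  stopifnot(is.list(per_neuron), length(per_neuron) > 0)
  ids <- names(per_neuron)
  if (is.null(ids)) ids <- sprintf("neuron_%02d", seq_along(per_neuron))
  all_labels <- unique(unlist(lapply(per_neuron, `[[`, "label")))
  rows <- lapply(seq_along(per_neuron), function(i) {
    df <- as.data.frame(per_neuron[[i]])
    missing <- setdiff(all_labels, df$label)
    if (length(missing))
      warning("dose_response_table: neuron ", ids[i],
              " is missing block(s): ", paste(missing, collapse = ", "))
    value_cols <- setdiff(names(df), c("label", "dose_mg_per_kg",
                                       "window_s"))
    long <- do.call(rbind, lapply(value_cols, function(m)
      data.frame(neuron_id = ids[i], label = df$label,
                 dose = df$dose_mg_per_kg, metric = m, value = df[[m]],
                 stringsAsFactors = FALSE)))
    long
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$metric, out$neuron_id, out$dose,
                   method = "radix", na.last = FALSE), , drop = FALSE]
  rownames(out) <- NULL
  out
}
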