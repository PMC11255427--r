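# Sleep-architecture statistics: bouts, state durations per light/dark
# phase, and the sleep fragmentation index.
#
# Architecture metrics are a pure function of the hypnogram: no minimum
# bout length is imposed here (smoothing belongs to the scoring stage).

#' Detect bouts (maximal runs of one state)
#'
#' A bout spanning the light/dark boundary is assigned to the phase
#' containing its start epoch.
#'
#' @param h a [hypnogram()].
#' @return `data.frame` with columns `state`, `start_epoch` (1-based),
#'   `n_epochs`, `duration_min`, `phase`. Bouts partition the hypnogram.
#' @export
detect_bouts <- function(h) {
  stopifnot(inherits(h, "hypnogram"))
  epoch_s <- attr(h, "epoch_s")
  r <- rle(as.character(h))
  start <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  zt <- (attr(h, "start_zt") + (start - 1) * epoch_s / 3600) %% 24
  data.frame(state = r$values, start_epoch = start,
             n_epochs = r$lengths,
             duration_min = r$lengths * epoch_s / 60,
             phase = zt_phase(zt), stringsAsFactors = FALSE)
}

#' Minutes spent in each state per window
#'
#' @param h a [hypnogram()].
#' @param windows windows to report; any of `"light"`, `"dark"`,
#'   `"24h"` (the full recording).
#' @return `data.frame` (`state`, `window`, `minutes`). Light and dark
#'   minutes sum exactly to the full-recording row. If the hypnogram
#'   covers less than 24 h the result carries attribute
#'   `partial_window = TRUE`.
#' @export
state_durations <- function(h, windows = c("light", "dark", "24h")) {
  stopifnot(inherits(h, "hypnogram"))
  epoch_min <- attr(h, "epoch_s") / 60
  ph <- zt_phase(epoch_zt(h))
  st <- factor(as.character(h), levels = VIGILANCE_STATES)
  out <- list()
  for (w in windows) {
    sel <- if (w == "24h") rep(TRUE, length(h)) else ph == w
    tb <- table(st[sel]) * epoch_min
    out[[w]] <- data.frame(state = names(tb), window = w,
                           minutes = as.numeric(tb),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "partial_window") <- length(h) * epoch_min < 24 * 60
  res
}

#' Sleep fragmentation index
#'
#' Number of awakenings from sleep (transitions NREM -> WAKE or
#' REM -> WAKE, both epochs inside the window) divided by the total
#' NREM + REM time in hours within the window. Transitions between NREM
#' and REM do not break sleep. Units: awakenings per hour of sleep.
#'
#' @param h a [hypnogram()].
#' @param window `"24h"` (full recording), `"light"` or `"dark"`.
#' @return Single number, `>= 0`; zero iff no sleep-to-wake transition
#'   occurs in the window. Errors if the window contains no sleep.
#' @export
sleep_fragmentation_index <- function(h, window = c("24h", "light", "dark")) {
  stopifnot(inherits(h, "hypnogram"))
  window <- match.arg(window)
  ph <- zt_phase(epoch_zt(h))
  sel <- if (window == "24h") rep(TRUE, length(h)) else ph == window
  st <- as.character(h)
  sleep_h <- sum(sel & st %in% c("NREM", "REM")) * attr(h, "epoch_s") / 3600
  if (sleep_h == 0)
    stop("sleep_fragmentation_index: SFI undefined (zero sleep time in ",
         window, " window)")
  n <- length(st)
  from_sleep <- st[-n] %in% c("NREM", "REM") & st[-1] == "WAKE"
  in_window <- sel[-n] & sel[-1]
  awakenings <- sum(from_sleep & in_window)
  awakenings / sleep_h
}
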