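# Synthetic-data generators with known ground truth: semi-Markov
# hypnograms under a 12 h light/dark cycle, state-dependent EEG/EMG
# signals, locus-ceruleus-like spike trains with injected bursts and
# dose-block rate multipliers, one-compartment absorption PK curves,
# and two-reference-gene qPCR Ct tables.
#
# Every generator is a pure function of (parameters, seed): the global
# RNG state is saved and restored around each call.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

check_transition_matrix <- function(P, what) {
  if (!is.matrix(P) || any(dim(P) != 3L))
    stop(what, ": transition matrix must be 3x3")
  if (any(diag(P) != 0))
    stop(what, ": transition matrix must have a zero diagonal")
  if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-8))
    stop(what, ": transition rows must be non-negative and sum to 1")
  P
}

#' Semi-Markov hypnogram model
#'
#' Per-phase (light/dark) bout-duration means and embedded-chain
#' transition probabilities, plus a multiplicative light-phase effect on
#' transitions into REM (the generator's stand-in for a REM-promoting
#' drug acting during the inactive phase).
#'
#' Defaults emulate a vehicle-treated rat under a 12 h light/dark
#' cycle: stationary occupancies of roughly 47/44/9% wake/NREM/REM in
#' the light (inactive) phase and 67/30/4% in the dark (active) phase,
#' REM entered almost exclusively from NREM, and markedly less REM in
#' the dark. Bout-duration means are set short enough (frequent
#' ultradian cycling) that a phase-specific REM effect of plausible
#' magnitude is statistically detectable in a 20-animal two-group
#' design; see the package vignette for the calibration rationale.
#'
#' @param light,dark per-phase parameter lists with elements
#'   `mean_bout_min` (named numeric, minutes, `> 0`, names
#'   `WAKE`/`NREM`/`REM`) and `trans` (row-stochastic 3x3 matrix with
#'   zero diagonal, rows/cols ordered `WAKE`, `NREM`, `REM`).
#' @param rem_effect multiplicative factor (>= 0) applied to transition
#'   probabilities into REM during the light phase, then renormalized.
#'   `1` means no drug effect.
#' @return Object of class `hypnogram_model`.
#' @export
hypnogram_model <- function(light = NULL, dark = NULL, rem_effect = 1) {
  trans_light <- matrix(c(0, 0.95, 0.05,
                          0.62, 0, 0.38,
                          0.90, 0.10, 0), 3, 3, byrow = TRUE,
                        dimnames = list(VIGILANCE_STATES, VIGILANCE_STATES))
  trans_dark <- matrix(c(0, 0.95, 0.05,
                         0.80, 0, 0.20,
                         0.92, 0.08, 0), 3, 3, byrow = TRUE,
                       dimnames = list(VIGILANCE_STATES, VIGILANCE_STATES))
  if (is.null(light))
    light <- list(mean_bout_min = c(WAKE = 1.25, NREM = 1.15, REM = 0.5),
                  trans = trans_light)
  if (is.null(dark))
    dark <- list(mean_bout_min = c(WAKE = 2.15, NREM = 0.95, REM = 0.4),
                 trans = trans_dark)
  for (ph in list(light, dark)) {
    if (any(ph$mean_bout_min <= 0))
      stop("hypnogram_model: mean bout durations must be positive")
    check_transition_matrix(ph$trans, "hypnogram_model")
  }
  if (!is.numeric(rem_effect) || rem_effect < 0)
    stop("hypnogram_model: rem_effect must be >= 0")
  structure(list(light = light, dark = dark, rem_effect = rem_effect),
            class = "hypnogram_model")
}

#' Simulate a hypnogram from a semi-Markov model
#'
#' Alternating-state realization: bout durations are exponential with the
#' phase-specific mean for the current state (rounded up to whole epochs,
#' minimum one epoch); the next state is drawn from the phase-specific
#' embedded-chain row, with transitions into REM boosted by
#' `model$rem_effect` (then renormalized) when the transition occurs in
#' the light phase. Phase is evaluated at the start of each bout.
#'
#' @param model a [hypnogram_model()].
#' @param duration_h recording length, hours.
#' @param epoch_s epoch length, seconds.
#' @param start_zt Zeitgeber hour of the first epoch.
#' @param start_state initial state (default `"WAKE"`).
#' @param seed integer seed; identical seeds give identical label
#'   sequences.
#' @return A [hypnogram()].
#' @export
simulate_hypnogram <- function(model, duration_h = 24, epoch_s = 10,
                               start_zt = 0, start_state = "WAKE",
                               seed = NULL) {
  stopifnot(inherits(model, "hypnogram_model"), duration_h > 0)
  n <- as.integer(round(duration_h * 3600 / epoch_s))
  state <- match(match.arg(start_state, VIGILANCE_STATES), VIGILANCE_STATES)
  with_seed(seed, {
    labels <- integer(n)
    t <- 0L
    while (t < n) {
      zt <- (start_zt + t * epoch_s / 3600) %% 24
      ph <- if (zt < 12) model$light else model$dark
      mu_s <- ph$mean_bout_min[state] * 60
      k <- max(1L, as.integer(ceiling(stats::rexp(1L, rate = 1 / mu_s) /
                                        epoch_s)))
      k <- min(k, n - t)
      labels[(t + 1L):(t + k)] <- state
      t <- t + k
      row <- ph$trans[state, ]
      if (zt < 12) row[3L] <- row[3L] * model$rem_effect
      if (sum(row) == 0)
        stop("simulate_hypnogram: absorbing state (all-zero transition row)")
      state <- sample.int(3L, 1L, prob = row)
    }
    hypnogram(VIGILANCE_STATES[labels], epoch_s = epoch_s,
              start_zt = start_zt)
  })
}

#' Stationary state occupancy of a semi-Markov phase model
#'
#' Closed-form long-run time-in-state fractions for one phase of a
#' [hypnogram_model()]: stationary distribution `pi` of the embedded
#' transition chain, weighted by the expected bout length in epochs.
#' Because simulated bout durations are exponential draws rounded up to
#' whole epochs (minimum one), the expected length in epochs is
#' `1 / (1 - exp(-epoch_s / mu))` for mean duration `mu`, not `mu/epoch_s`.
#'
#' @param model a [hypnogram_model()].
#' @param phase `"light"` or `"dark"`.
#' @param epoch_s epoch length used by the simulation, seconds.
#' @param apply_rem_effect boost light-phase REM entries by
#'   `model$rem_effect` before solving (as the simulator does).
#' @return Named numeric occupancy fractions summing to 1.
#' @export
stationary_occupancy <- function(model, phase = c("light", "dark"),
                                 epoch_s = 10, apply_rem_effect = TRUE) {
  phase <- match.arg(phase)
  ph <- model[[phase]]
  P <- ph$trans
  if (phase == "light" && apply_rem_effect) {
    P[, 3L] <- P[, 3L] * model$rem_effect
    P <- P / rowSums(P)
  }
  # pi P = pi, sum(pi) = 1
  A <- rbind(t(P) - diag(3), rep(1, 3))
  pi_emb <- qr.solve(A, c(0, 0, 0, 1))
  mu_s <- ph$mean_bout_min * 60
  mean_epochs <- 1 / (1 - exp(-epoch_s / mu_s))
  occ <- pi_emb * mean_epochs
  stats::setNames(occ / sum(occ), VIGILANCE_STATES)
}

#' EEG/EMG synthesis specification
#'
#' Per-state EEG band weights (per-bin power multipliers over the delta,
#' theta and sigma bands, plus a broadband level elsewhere), per-state
#' EMG RMS amplitudes (which must be strictly ordered REM < NREM < WAKE),
#' and a pink-noise floor.
#'
#' @param fs sampling rate, Hz.
#' @param eeg_weights 3x4 numeric matrix (rows `WAKE`,`NREM`,`REM`;
#'   columns `delta`,`theta`,`sigma`,`broadband`) of non-negative power
#'   weights.
#' @param emg_rms named numeric of per-state EMG RMS (arbitrary units).
#' @param pink_floor amplitude of the 1/f power floor added to the EEG.
#' @param bands band edges used for the weighted bands; defaults to
#'   [default_bands()].
#' @return Object of class `signal_spec`.
#' @export
signal_spec <- function(fs = 250,
                        eeg_weights = NULL,
                        emg_rms = c(WAKE = 1.0, NREM = 0.4, REM = 0.1),
                        pink_floor = 0.05,
                        bands = default_bands()) {
  if (is.null(eeg_weights)) {
    eeg_weights <- matrix(c(1.0, 1.2, 0.5, 1.0,    # WAKE: mixed, desynchronized
                            4.0, 1.0, 1.5, 0.8,    # NREM: delta-dominant
                            0.8, 3.0, 0.5, 0.5),   # REM: theta-dominant
                          3, 4, byrow = TRUE,
                          dimnames = list(VIGILANCE_STATES,
                                          c("delta", "theta", "sigma",
                                            "broadband")))
  }
  if (any(eeg_weights < 0)) stop("signal_spec: weights must be >= 0")
  emg_rms <- emg_rms[VIGILANCE_STATES]
  if (anyNA(emg_rms) ||
      !(emg_rms["REM"] < emg_rms["NREM"] && emg_rms["NREM"] < emg_rms["WAKE"]))
    stop("signal_spec: EMG RMS must satisfy REM < NREM < WAKE strictly")
  structure(list(fs = fs, eeg_weights = eeg_weights, emg_rms = emg_rms,
                 pink_floor = pink_floor, bands = bands),
            class = "signal_spec")
}

#' Synthesize EEG/EMG signals matching a hypnogram
#'
#' Per epoch, the EEG is Gaussian noise shaped in the frequency domain:
#' the target power profile equals the current state's band weight inside
#' each configured band, its broadband weight elsewhere below 25 Hz, plus
#' a 1/f floor. The EMG is white Gaussian noise at the state's RMS.
#' Epochs are statistically stationary; no cross-fade is applied at
#' boundaries.
#'
#' @param h a [hypnogram()].
#' @param spec a [signal_spec()].
#' @param seed integer seed.
#' @return A [signal_record()] with channels `EEG1` and `EMG1`.
#' @export
synthesize_signals <- function(h, spec, seed = NULL) {
  stopifnot(inherits(h, "hypnogram"), inherits(spec, "signal_spec"))
  epoch_s <- attr(h, "epoch_s")
  fs <- spec$fs
  n_ep <- as.integer(round(fs * epoch_s))
  n <- n_ep * length(h)
  freqs <- seq(0, fs - fs / n_ep, by = fs / n_ep)
  freqs <- pmin(freqs, fs - freqs)          # two-sided grid folded
  # per-state amplitude shaping on the epoch FFT grid
  shape <- matrix(0, 3, n_ep)
  for (s in 1:3) {
    w <- rep(0, n_ep)
    inband <- rep(FALSE, n_ep)
    for (b in seq_len(nrow(spec$bands))) {
      sel <- freqs >= spec$bands$lo_hz[b] & freqs < spec$bands$hi_hz[b]
      w[sel] <- spec$eeg_weights[s, spec$bands$name[b]]
      inband <- inband | sel
    }
    w[!inband & freqs > 0 & freqs < 25] <- spec$eeg_weights[s, "broadband"]
    w <- w + spec$pink_floor^2 / pmax(freqs, 0.5)
    shape[s, ] <- sqrt(w)
  }
  with_seed(seed, {
    eeg <- numeric(n)
    emg <- numeric(n)
    idx_state <- as.integer(unclass_hypnogram(h))
    for (e in seq_along(h)) {
      s <- idx_state[e]
      z <- stats::fft(stats::rnorm(n_ep))  # white spectrum, hermitian
      x <- Re(stats::fft(z * shape[s, ], inverse = TRUE)) / n_ep
      rng <- ((e - 1L) * n_ep + 1L):(e * n_ep)
      eeg[rng] <- x
      emg[rng] <- stats::rnorm(n_ep, sd = spec$emg_rms[s])
    }
    signal_record(cbind(eeg, emg), labels = c("EEG1", "EMG1"),
                  roles = c("EEG", "EMG"), fs = fs,
                  start_zt = attr(h, "start_zt"), units = c("uV", "uV"))
  })
}

#' Spike-train generative model
#'
#' Tonic spikes from a Poisson process plus burst events from an
#' independent Poisson process; each burst event is replaced by `k >= 2`
#' spikes whose first intra-burst interval is below 80 ms and subsequent
#' intervals at most 160 ms, so ground-truth burst labels exist by
#' construction. Per dose block, both process rates are multiplied by the
#' block's rate multiplier.
#'
#' @param tonic_rate_hz baseline tonic rate, must lie in the locus
#'   ceruleus range `[0.5, 7.5]` Hz.
#' @param burst_rate_hz burst-initiation rate (events per second, >= 0).
#' @param spikes_per_burst integer vector of admissible burst sizes
#'   (all >= 2), sampled uniformly.
#' @param first_isi_range_s range of the burst's first intra-burst ISI
#'   (must stay below 0.080 s).
#' @param later_isi_range_s range of subsequent intra-burst ISIs (must
#'   stay at or below 0.160 s).
#' @param refractory_s minimum spike separation enforced on the merged
#'   train (default 1 ms).
#' @return Object of class `spike_model`.
#' @export
spike_model <- function(tonic_rate_hz = 2.0, burst_rate_hz = 0.05,
                        spikes_per_burst = 2:4,
                        first_isi_range_s = c(0.015, 0.070),
                        later_isi_range_s = c(0.020, 0.150),
                        refractory_s = 0.001) {
  if (tonic_rate_hz < 0.5 || tonic_rate_hz > 7.5)
    stop("spike_model: tonic rate outside the LC range [0.5, 7.5] Hz")
  if (burst_rate_hz < 0) stop("spike_model: burst_rate_hz must be >= 0")
  if (any(spikes_per_burst < 2))
    stop("spike_model: bursts must have at least 2 spikes")
  if (max(first_isi_range_s) >= 0.080)
    stop("spike_model: first intra-burst ISI must be < 80 ms")
  if (max(later_isi_range_s) > 0.160)
    stop("spike_model: intra-burst ISIs must be <= 160 ms")
  structure(list(tonic_rate_hz = tonic_rate_hz,
                 burst_rate_hz = burst_rate_hz,
                 spikes_per_burst = as.integer(spikes_per_burst),
                 first_isi_range_s = first_isi_range_s,
                 later_isi_range_s = later_isi_range_s,
                 refractory_s = refractory_s),
            class = "spike_model")
}

#' Simulate a dose-blocked spike train
#'
#' @param model a [spike_model()].
#' @param blocks data frame with columns `label`, `start_s`, `end_s`,
#'   optionally `dose_mg_per_kg` and `multiplier` (rate multiplier in
#'   `(0, 1]`, default 1 = baseline).
#' @param seed integer seed.
#' @return A [spike_train()] carrying `blocks` (without the multiplier
#'   column, which is generator ground truth, kept in
#'   `attr(, "multipliers")`).
#' @export
simulate_spike_train <- function(model, blocks, seed = NULL) {
  stopifnot(inherits(model, "spike_model"))
  blocks <- as.data.frame(blocks)
  if (is.null(blocks$multiplier)) blocks$multiplier <- 1
  if (any(blocks$multiplier <= 0 | blocks$multiplier > 1))
    stop("simulate_spike_train: multipliers must lie in (0, 1]")
  duration_s <- max(blocks$end_s)
  with_seed(seed, {
    times <- numeric(0)
    for (b in seq_len(nrow(blocks))) {
      len <- blocks$end_s[b] - blocks$start_s[b]
      m <- blocks$multiplier[b]
      n_tonic <- stats::rpois(1L, model$tonic_rate_hz * m * len)
      tt <- stats::runif(n_tonic, blocks$start_s[b], blocks$end_s[b])
      n_burst <- stats::rpois(1L, model$burst_rate_hz * m * len)
      bt <- stats::runif(n_burst, blocks$start_s[b], blocks$end_s[b])
      for (t0 in bt) {
        k <- sample(model$spikes_per_burst, 1L)
        isis <- c(stats::runif(1L, model$first_isi_range_s[1],
                               model$first_isi_range_s[2]),
                  if (k > 2L) stats::runif(k - 2L,
                                           model$later_isi_range_s[1],
                                           model$later_isi_range_s[2]))
        tt <- c(tt, t0 + cumsum(c(0, isis)))
      }
      times <- c(times, tt)
    }
    times <- sort(times[times < duration_s & times >= 0])
    # enforce the refractory floor: drop any spike closer than refractory_s
    # to the previously kept one
    if (length(times) > 1L) {
      keep <- logical(length(times))
      keep[1L] <- TRUE
      last <- times[1L]
      for (i in 2L:length(times)) {
        if (times[i] - last >= model$refractory_s) {
          keep[i] <- TRUE
          last <- times[i]
        }
      }
      times <- times[keep]
    }
    out <- spike_train(times, duration_s = duration_s,
                       blocks = blocks[, c("label", "start_s", "end_s",
                                           "dose_mg_per_kg")])
    attr(out, "multipliers") <- stats::setNames(blocks$multiplier,
                                                blocks$label)
    out
  })
}

#' Standard cumulative-dosing block layout
#'
#' Five consecutive 5-minute blocks: vehicle baseline then cumulative
#' doses of 3.5, 7, 10.5 and 14 mg/kg.
#'
#' @param block_s block length in seconds (default 300).
#' @param multipliers optional numeric vector of length 5 of ground-truth
#'   rate multipliers for the generator (baseline first).
#' @return Block `data.frame` suitable for [simulate_spike_train()].
#' @export
dose_blocks <- function(block_s = 300, multipliers = NULL) {
  doses <- c(NA, 3.5, 7, 10.5, 14)
  out <- data.frame(
    label = c("vehicle", paste0("dose_", doses[-1])),
    start_s = (0:4) * block_s,
    end_s = (1:5) * block_s,
    dose_mg_per_kg = doses)
  if (!is.null(multipliers)) out$multiplier <- multipliers
  out
}

#' One-compartment absorption PK model
#'
#' `C(t) = scale * ka/(ka-ke) * (exp(-ke t) - exp(-ka t))` with optional
#' multiplicative lognormal noise.
#'
#' @param scale lumped `F*D/V` scale, concentration units.
#' @param ka absorption rate constant, 1/min.
#' @param ke elimination rate constant, 1/min (`ka != ke`, both > 0).
#' @param cv lognormal coefficient of variation (>= 0).
#' @param dose_mg_per_kg dose metadata.
#' @return Object of class `pk_model`.
#' @export
pk_model <- function(scale = 200, ka = 0.05, ke = 0.0033, cv = 0,
                     dose_mg_per_kg = 7) {
  if (ka <= 0 || ke <= 0) stop("pk_model: ka and ke must be positive")
  if (ka == ke) stop("pk_model: ka must differ from ke")
  if (cv < 0) stop("pk_model: cv must be >= 0")
  structure(list(scale = scale, ka = ka, ke = ke, cv = cv,
                 dose_mg_per_kg = dose_mg_per_kg), class = "pk_model")
}

#' Simulate a concentration-time profile
#'
#' @param model a [pk_model()].
#' @param times_min increasing sampling times, minutes.
#' @param seed integer seed (noise only).
#' @return A [pk_profile()].
#' @export
simulate_pk <- function(model, times_min = c(30, 60, 120, 240),
                        seed = NULL) {
  stopifnot(inherits(model, "pk_model"))
  mu <- model$scale * model$ka / (model$ka - model$ke) *
    (exp(-model$ke * times_min) - exp(-model$ka * times_min))
  with_seed(seed, {
    if (model$cv > 0) {
      sigma <- sqrt(log(1 + model$cv^2))
      mu <- mu * exp(stats::rnorm(length(mu), 0, sigma))
    }
    pk_profile(times_min, mu, dose_mg_per_kg = model$dose_mg_per_kg)
  })
}

#' Simulate a two-reference-gene qPCR Ct table
#'
#' Control-group target Ct equals the reference Ct plus a baseline
#' offset; the test group's target Ct is additionally shifted by
#' `delta_ct_shift` (positive shift = lower expression). Gaussian noise
#' of SD `noise_sd` is added to every Ct measurement.
#'
#' @param delta_ct_shift ground-truth ddCt of the test group; the
#'   recovered fold change is `2^-delta_ct_shift`.
#' @param n_per_group samples per group (>= 2).
#' @param noise_sd per-measurement Ct noise SD.
#' @param seed integer seed.
#' @param target_gene,reference_genes gene names.
#' @param ref_ct,baseline_offset reference-gene Ct level and the
#'   target-minus-reference baseline offset.
#' @return A [ct_table()].
#' @export
simulate_qpcr <- function(delta_ct_shift, n_per_group = 5, noise_sd = 0,
                          seed = NULL, target_gene = "MT1",
                          reference_genes = c("ACTB", "POLR2A"),
                          ref_ct = 20, baseline_offset = 6) {
  if (n_per_group < 2) stop("simulate_qpcr: n_per_group must be >= 2")
  genes <- c(target_gene, reference_genes)
  with_seed(seed, {
    rows <- list()
    for (grp in c("control", "test")) {
      shift <- if (grp == "test") delta_ct_shift else 0
      for (i in seq_len(n_per_group)) {
        id <- sprintf("%s_%02d", grp, i)
        cts <- c(ref_ct + baseline_offset + shift,
                 rep(ref_ct, length(reference_genes))) +
          stats::rnorm(length(genes), 0, noise_sd)
        rows[[length(rows) + 1L]] <-
          data.frame(sample_id = id, group = grp, gene = genes, ct = cts)
      }
    }
    df <- do.call(rbind, rows)
    ct_table(df$sample_id, df$group, df$gene, df$ct)
  })
}
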