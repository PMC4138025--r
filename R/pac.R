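PAC_REGIMES <- c("subthreshold_following", "peak_locked", "trough_locked",
                 "persistent_gamma_theta_mean", "biphasic")

#' Predict the coupling regime from a drive excursion and the window
#'
#' The regime is determined by where the slow drive's minimum `m` and
#' maximum `M` fall relative to the oscillation window `(CR1, CR2)`:
#' \itemize{
#'   \item `M < CR1`: `subthreshold_following` - low-amplitude output at the
#'     drive frequency, no intrinsic gamma;
#'   \item `m < CR1 <= M <= CR2`: `peak_locked` - gamma bursts nested around
#'     the drive peaks;
#'   \item `CR1 <= m`, `M > CR2`: `trough_locked` - gamma around the drive
#'     troughs;
#'   \item `CR1 <= m <= M <= CR2`: `persistent_gamma_theta_mean` -
#'     near-constant-amplitude gamma whose mean varies at the drive
#'     frequency;
#'   \item `m < CR1` and `M > CR2`: `biphasic` - gamma locked to both the
#'     ascending and descending drive phases.
#' }
#'
#' @param window A `wc_window` from [find_hopf_points()].
#' @param drive A sinusoidal [drive_sinusoid()] on the same axis as the
#'   window.
#' @param axis Axis the drive acts on; must match `window$axis`.
#' @return One of the five regime labels.
#' @export
predict_regime <- function(window, drive, axis = window$axis) {
  stopifnot(inherits(window, "wc_window"), inherits(drive, "wc_drive"))
  if (!identical(axis, window$axis))
    stop(sprintf("axis mismatch: window is on %s but the drive acts on %s",
                 window$axis, axis))
  r <- drive_range(drive)
  m <- r[1]; M <- r[2]
  CR1 <- window$lower; CR2 <- window$upper
  if (M < CR1) return("subthreshold_following")
  if (m < CR1 && M > CR2) return("biphasic")
  if (m < CR1) return("peak_locked")
  if (M > CR2) return("trough_locked")
  "persistent_gamma_theta_mean"
}

# FFT-based analytic signal; magnitude gives the instantaneous envelope.
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' Gamma-band amplitude envelope of a trajectory
#'
#' Band-passes the post-transient activity with a zero-phase Butterworth
#' filter and takes the analytic-signal magnitude. The default band is the
#' gamma range 40-100 Hz, appropriate for circuits with `tau = 0.0032` s
#' whose intrinsic rhythm sits near 55 Hz.
#'
#' @param traj A `wc_trajectory`.
#' @param band Length-2 pass band in 1/time-units (Hz for `tau` in
#'   seconds); must lie below the Nyquist frequency of the sampling.
#' @param settle_fraction Fraction of the run discarded as transient.
#' @param population `"E"` or `"I"`: which activity series to analyse.
#' @param order Butterworth filter order.
#' @return A `wc_envelope`: list with `t`, `filtered`, `envelope`, `band`,
#'   `population`.
#' @export
extract_envelope <- function(traj, band = c(40, 100), settle_fraction = 0.5,
                             population = c("E", "I"), order = 4L) {
  stopifnot(inherits(traj, "wc_trajectory"))
  population <- match.arg(population)
  fs <- 1 / traj$dt
  if (band[2] >= fs / 2)
    stop(sprintf("band upper edge %g is at or above the Nyquist frequency %g",
                 band[2], fs / 2))
  if (band[1] <= 0 || band[1] >= band[2])
    stop("'band' must satisfy 0 < low < high")
  seg <- post_transient(traj, settle_fraction)
  # decimate to a working rate near 8x the band's upper edge: a Butterworth
  # band-pass is numerically singular when the band is a tiny fraction of
  # the Nyquist frequency (the trajectory is smooth, so plain subsampling
  # loses nothing in the pass band)
  thin <- max(1L, floor(fs / (8 * band[2])))
  sub <- seq(1L, length(seg$t), by = thin)
  x <- seg[[population]][sub]
  dt_work <- traj$dt * thin
  bf <- signal::butter(order, band * 2 * dt_work, type = "pass")
  xf <- signal::filtfilt(bf, x - mean(x))
  structure(list(t = seg$t[sub], dt = dt_work, filtered = xf,
                 envelope = Mod(analytic_signal(xf)), band = band,
                 population = population),
            class = "wc_envelope")
}

#' Normalized Kullback-Leibler modulation index
#'
#' Bins the fast-oscillation amplitude envelope by the phase of the slow
#' drive, normalizes the bin means to a distribution, and returns its KL
#' divergence from uniform divided by `log(n_bins)`. The index lies in
#' `[0, 1]`: 0 for a phase-independent envelope, 1 when all amplitude
#' concentrates in a single bin. It is invariant to positive rescaling of
#' the envelope. Bins containing no samples are merged with their clockwise
#' neighbour and the result is flagged with attribute `bins_merged`.
#'
#' @param envelope Numeric envelope series (or a `wc_envelope`).
#' @param phase Slow-drive phase in degrees, aligned and equal length.
#' @param n_bins Number of phase bins (>= 8).
#' @return The modulation index, with attribute `bins_merged`.
#' @export
modulation_index <- function(envelope, phase, n_bins = 18L) {
  if (inherits(envelope, "wc_envelope")) envelope <- envelope$envelope
  if (length(envelope) != length(phase))
    stop("'envelope' and 'phase' must be aligned series of equal length")
  if (n_bins < 8) stop("'n_bins' must be at least 8")
  bin <- floor((phase %% 360) / (360 / n_bins)) + 1L
  means <- vapply(seq_len(n_bins),
                  function(b) if (any(bin == b)) mean(envelope[bin == b]) else NA_real_,
                  numeric(1))
  merged <- anyNA(means)
  if (merged) {
    # pool each empty bin with its clockwise neighbour
    for (b in which(is.na(means))) {
      nb <- b
      repeat {
        nb <- if (nb == n_bins) 1L else nb + 1L
        if (!is.na(means[nb]) || nb == b) break
      }
      if (is.na(means[nb])) stop("all phase bins are empty")
      bin[bin == b] <- nb
    }
    keep <- sort(unique(bin))
    means <- vapply(keep, function(b) mean(envelope[bin == b]), numeric(1))
  }
  n_eff <- length(means)
  tot <- sum(means)
  if (tot <= 0) return(structure(0, bins_merged = merged))
  p <- means / tot
  p <- p[p > 0]
  mi <- (log(n_eff) + sum(p * log(p))) / log(n_eff)
  structure(max(0, mi), bins_merged = merged)
}

circ_mean_deg <- function(phi_deg, w = NULL) {
  if (is.null(w)) w <- rep(1, length(phi_deg))
  z <- sum(w * exp(1i * phi_deg * pi / 180)) / sum(w)
  list(mean = (Arg(z) * 180 / pi) %% 360, R = Mod(z))
}

ang_dist <- function(a, b) {
  d <- abs((a - b) %% 360)
  pmin(d, 360 - d)
}

#' Classify the observed coupling regime from a trajectory
#'
#' Operationalizes the regime taxonomy on simulated activity. The
#' gamma-band envelope is computed per slow-drive cycle; bursts are
#' contiguous stretches where the envelope exceeds half its cycle maximum
#' (and an absolute floor separating gamma from filter leakage) for at
#' least `min_burst_periods` gamma periods. The regime is assigned from the
#' burst-centre phases:
#' concentrated near 0 degrees = peak-locked, near 180 = trough-locked, two
#' antipodal clusters near 90/270 = biphasic; an envelope that stays high
#' through most of every cycle = persistent gamma with theta-varying mean;
#' no bursts at all = subthreshold following of the drive.
#'
#' The preferred phase is the envelope-weighted circular mean of the drive
#' phase (degrees, 0 at the drive peak), reported only when the modulation
#' index exceeds `mi_floor`. Phase can be measured at the drive source
#' (default) or substituted with the theta-filtered local activity by other
#' tooling; the source convention is used throughout the package.
#'
#' @param traj A `wc_trajectory` at least 10 slow cycles long after the
#'   transient.
#' @param drive The sinusoidal slow drive used in the simulation.
#' @param band Gamma pass band, as in [extract_envelope()].
#' @param settle_fraction Transient fraction discarded.
#' @param population Activity series to classify (`"E"` or `"I"`).
#' @param n_bins Phase bins for the modulation index.
#' @param burst_floor Absolute envelope floor below which no gamma burst is
#'   recognized.
#' @param min_burst_periods Minimum burst duration in gamma periods.
#' @param mi_floor Modulation-index noise floor below which no preferred
#'   phase is reported.
#' @return A `wc_pac_report` with `regime_observed`, `preferred_phase`,
#'   `modulation_index`, `gamma_frequency`, `n_gamma_bursts_per_theta_cycle`,
#'   `burst_phases`, `coverage`.
#' @export
classify_observed_regime <- function(traj, drive, band = c(40, 100),
                                     settle_fraction = 0.5,
                                     population = "E", n_bins = 18L,
                                     burst_floor = 0.01,
                                     min_burst_periods = 2,
                                     mi_floor = 0.01) {
  stopifnot(inherits(traj, "wc_trajectory"), inherits(drive, "wc_drive"))
  if (drive$kind != "sinusoid")
    stop("regime classification requires a sinusoidal slow drive")
  env <- extract_envelope(traj, band, settle_fraction, population)
  n_cycles <- (max(env$t) - min(env$t)) * drive$frequency
  if (n_cycles < 10)
    stop(sprintf(paste0("post-transient trajectory covers %.1f slow cycles; ",
                        "at least 10 are required"), n_cycles))
  ph <- drive_phase(drive, env$t)
  mi <- modulation_index(env$envelope, ph, n_bins)
  pref <- if (mi > mi_floor) circ_mean_deg(ph, env$envelope)$mean else NA_real_

  # the same preference measured against the local theta oscillation of the
  # analysed population (theta-filtered activity, Hilbert phase, 0 deg at the
  # local peak) - coupling can sit on a different phase locally than at the
  # drive source
  theta_band <- drive$frequency * c(0.5, 2)
  seg <- post_transient(traj, settle_fraction)
  sub <- seq(1L, length(seg$t), by = max(1L, floor((1 / traj$dt) /
                                                     (16 * theta_band[2]))))
  xs <- seg[[population]][sub]
  bf_th <- signal::butter(2, theta_band * 2 * (traj$dt * (sub[2] - sub[1])),
                          type = "pass")
  xth <- signal::filtfilt(bf_th, xs - mean(xs))
  z <- analytic_signal(xth)
  # interpolate the analytic signal, not the wrapped phase
  zi <- complex(real = stats::approx(seg$t[sub], Re(z), xout = env$t,
                                     rule = 2)$y,
                imaginary = stats::approx(seg$t[sub], Im(z), xout = env$t,
                                          rule = 2)$y)
  ph_local <- (Arg(zi) * 180 / pi) %% 360
  pref_local <- if (mi > mi_floor) circ_mean_deg(ph_local, env$envelope)$mean
                else NA_real_

  # dominant gamma frequency from the band-passed spectrum
  nfft <- length(env$filtered)
  spec <- Mod(fft(env$filtered))[seq_len(floor(nfft / 2))]
  freqs <- (seq_len(floor(nfft / 2)) - 1) / (nfft * env$dt)
  inband <- freqs >= band[1] & freqs <= band[2]
  gamma_freq <- if (any(inband) && max(env$envelope) > burst_floor)
    freqs[inband][which.max(spec[inband])] else NA_real_

  # burst detection on the whole post-transient series (a global half-max
  # threshold avoids splitting bursts at arbitrary cycle boundaries)
  gamma_period <- if (is.finite(gamma_freq) && gamma_freq > 0)
    1 / gamma_freq else 1 / mean(band)
  min_len <- min_burst_periods * gamma_period
  n_full_cycles <- floor((max(env$t) - min(env$t)) * drive$frequency)
  thr <- max(max(env$envelope) / 2, burst_floor)
  above <- env$envelope > thr
  # bridge sub-gamma-period dips so amplitude ripple within one burst does
  # not fragment it
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (j in which(!r$values)) {
    if (j > 1 && j < length(r$values) &&
        env$t[ends[j]] - env$t[starts[j]] < gamma_period)
      above[starts[j]:ends[j]] <- TRUE
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  burst_phi <- numeric(0)
  n_bursts <- 0L
  for (j in which(r$values)) {
    if (env$t[ends[j]] - env$t[starts[j]] >= min_len) {
      idx <- starts[j]:ends[j]
      burst_phi <- c(burst_phi,
                     circ_mean_deg(ph[idx], env$envelope[idx])$mean)
      n_bursts <- n_bursts + 1L
    }
  }
  coverage <- mean(above)

  # gamma present at every drive phase (it never rings fully down) marks the
  # persistent regime; bin the envelope by phase and require the weakest bin
  # to stay above both the absolute floor and a fraction of the strongest
  bin <- floor((ph %% 360) / (360 / n_bins)) + 1L
  bin_means <- vapply(seq_len(n_bins), function(b) {
    if (any(bin == b)) mean(env$envelope[bin == b]) else 0
  }, numeric(1))
  persistent <- min(bin_means) > max(burst_floor, 0.2 * max(bin_means))

  regime <- if (max(env$envelope) <= burst_floor || n_bursts == 0) {
    "subthreshold_following"
  } else if (persistent) {
    "persistent_gamma_theta_mean"
  } else {
    s1 <- circ_mean_deg(burst_phi)
    s2 <- circ_mean_deg(2 * burst_phi)
    if (s1$R < 0.6 && s2$R >= 0.5) {
      "biphasic"
    } else if (ang_dist(s1$mean, 0) <= 90) {
      "peak_locked"
    } else {
      "trough_locked"
    }
  }
  structure(list(regime_observed = regime, preferred_phase = pref,
                 preferred_phase_local = pref_local,
                 modulation_index = as.numeric(mi),
                 gamma_frequency = gamma_freq,
                 n_gamma_bursts_per_theta_cycle =
                   if (n_full_cycles > 0) n_bursts / n_full_cycles
                   else NA_real_,
                 burst_phases = burst_phi,
                 coverage = coverage,
                 population = population, band = band),
            class = "wc_pac_report")
}

#' @export
print.wc_pac_report <- function(x, ...) {
  cat("phase-amplitude coupling report (", x$population, " population)\n",
      sep = "")
  if (!is.null(x$regime_predicted))
    cat(sprintf("  predicted regime: %s\n", x$regime_predicted))
  cat(sprintf("  observed regime:  %s\n", x$regime_observed))
  cat(sprintf("  modulation index: %.4f\n", x$modulation_index))
  if (is.finite(x$preferred_phase))
    cat(sprintf("  preferred phase:  %.1f deg (0 = drive peak)\n",
                x$preferred_phase))
  if (is.finite(x$gamma_frequency))
    cat(sprintf("  gamma frequency:  %.1f, %.2f burst(s) per slow cycle\n",
                x$gamma_frequency, x$n_gamma_bursts_per_theta_cycle))
  invisible(x)
}

#' Full phase-amplitude coupling analysis of a driven circuit
#'
#' Locates the oscillation window on the driven axis, predicts the coupling
#' regime from the drive excursion, simulates the driven circuit, and
#' classifies the observed regime from the gamma-band envelope.
#'
#' @param circuit A [wc_circuit()].
#' @param drive Sinusoidal slow drive.
#' @param axis `"theta_E"` or `"theta_I"`: the driven input.
#' @param fixed_other Constant level of the other input.
#' @param window Optional precomputed `wc_window` (saves the root-find).
#' @param n_cycles Number of slow-drive cycles to simulate (>= 10 retained
#'   after the transient at `settle_fraction = 0.5`, so >= 20 simulated).
#' @param dt Integration step; default `min(tau)/100`.
#' @param search_interval Interval handed to [find_hopf_points()].
#' @param ... Passed to [classify_observed_regime()].
#' @return A `wc_pac_report` that also carries `regime_predicted`, the
#'   `window`, and the trajectory as attribute `"trajectory"`.
#' @examples
#' \donttest{
#' circ <- wc_circuit()
#' rep <- pac_analysis(circ, drive_sinusoid(0.3, 0.3, 4), axis = "theta_E")
#' rep$regime_predicted
#' }
#' @export
pac_analysis <- function(circuit, drive, axis = c("theta_E", "theta_I"),
                         fixed_other = 0, window = NULL, n_cycles = 24,
                         dt = NULL, search_interval = c(0, 2), ...) {
  stopifnot(inherits(circuit, "wc_circuit"), inherits(drive, "wc_drive"))
  axis <- match.arg(axis)
  if (is.null(window))
    window <- find_hopf_points(circuit, axis, fixed_other, search_interval)
  predicted <- predict_regime(window, drive, axis)
  duration <- max(n_cycles / drive$frequency,
                  100 * max(circuit$tau_E, circuit$tau_I))
  dE <- if (axis == "theta_E") drive else drive_constant(fixed_other)
  dI <- if (axis == "theta_I") drive else drive_constant(fixed_other)
  traj <- simulate_circuit(circuit, dE, dI, duration = duration, dt = dt)
  rep <- classify_observed_regime(traj, drive, ...)
  rep$regime_predicted <- predicted
  rep$window <- window
  attr(rep, "trajectory") <- traj
  rep
}

#' Sample a random drive that realizes a given coupling regime
#'
#' Draws sinusoidal drive parameters whose excursion satisfies the regime's
#' rule relative to the oscillation window, with at least `margin` clearance
#' from the window edges. For the biphasic regime the excursion is
#' additionally kept moderate (edge clearance at most 0.25 on either side):
#' a slow drive that sweeps the window too fast leaves too little dwell time
#' for the fast oscillation to ring up, so extreme excursions do not express
#' the regime (the circuit's response is set by the instantaneous input
#' level, but developing a gamma cycle takes time).
#'
#' @param regime One of the five regime labels (see [predict_regime()]).
#' @param window A `wc_window`.
#' @param frequency Drive frequency in Hz.
#' @param margin Minimum clearance of the excursion extremes from the window
#'   edges.
#' @return A [drive_sinusoid()]; uses the current RNG state.
#' @export
sample_regime_drive <- function(regime, window, frequency = 4,
                                margin = 0.05) {
  stopifnot(inherits(window, "wc_window"))
  CR1 <- window$lower; CR2 <- window$upper
  mM <- switch(match.arg(regime, PAC_REGIMES),
    subthreshold_following = {
      amp <- stats::runif(1, 0.05, min(0.15, (CR1 - margin) / 2))
      mean <- stats::runif(1, amp, CR1 - margin - amp)
      c(mean - amp, mean + amp)
    },
    peak_locked = c(stats::runif(1, 0, CR1 - margin),
                    stats::runif(1, CR1 + margin, CR2 - margin)),
    trough_locked = c(stats::runif(1, CR1 + margin, CR2 - margin),
                      stats::runif(1, CR2 + margin, CR2 + 0.6)),
    persistent_gamma_theta_mean = {
      repeat {
        v <- sort(stats::runif(2, CR1 + margin, CR2 - margin))
        if (diff(v) >= 0.05) break
      }
      v
    },
    biphasic = c(stats::runif(1, CR1 - 0.25, CR1 - max(margin, 0.1)),
                 stats::runif(1, CR2 + max(margin, 0.1), CR2 + 0.25)))
  drive_sinusoid(mean(mM), diff(mM) / 2, frequency)
}

#' Write a coupling report as JSON
#'
#' @param report A `wc_pac_report`.
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @return JSON string (invisibly when written).
#' @export
pac_report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "wc_pac_report"))
  out <- unclass(report)
  out$window <- if (!is.null(out$window)) unclass(out$window)
  attr(out, "trajectory") <- NULL
  js <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
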