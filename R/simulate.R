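#' Integrate the circuit under external drive
#'
#' Fixed-step fourth-order Runge-Kutta integration of the two-population
#' system from a given initial state. The scheme is deterministic: identical
#' inputs give bit-identical trajectories. The phase square `[0, 1]^2` is a
#' trapping region of the flow, so trajectories started inside it remain
#' inside (up to integration tolerance).
#'
#' @param circuit A [wc_circuit()].
#' @param drive_E,drive_I External inputs: a [drive_constant()],
#'   [drive_sinusoid()], or a bare number (treated as a constant level).
#' @param duration Total integration time; at least `100 * max(tau)` so the
#'   transient can be discarded meaningfully.
#' @param dt Integration step; defaults to `min(tau)/100` and must not exceed
#'   `min(tau)/20` (halving the default step moves the final state by less
#'   than 1e-6 across the preset experiments).
#' @param init Initial state `c(E, I)`; the reference experiments start at
#'   the origin.
#' @param thin Keep every `thin`-th sample (the final state is always kept).
#' @return A `wc_trajectory`: list with `t`, `E`, `I`, `theta_E`, `theta_I`,
#'   `dt`, the effective sampling step `dt * thin`, the circuit snapshot and
#'   the time-unit convention ("seconds" or "natural").
#' @examples
#' circ <- wc_circuit()
#' traj <- simulate_circuit(circ, drive_E = 0.7, duration = 0.5)
#' measure_oscillation(traj)
#' @export
simulate_circuit <- function(circuit, drive_E = 0, drive_I = 0,
                             duration = NULL, dt = NULL,
                             init = c(0, 0), thin = 1L) {
  stopifnot(inherits(circuit, "wc_circuit"))
  drive_E <- as_drive(drive_E); drive_I <- as_drive(drive_I)
  tau_min <- min(circuit$tau_E, circuit$tau_I)
  tau_max <- max(circuit$tau_E, circuit$tau_I)
  if (is.null(dt)) dt <- tau_min / 100
  if (dt > tau_min / 20 + 1e-15)
    stop(sprintf(paste0(
      "dt = %g is too large relative to the time constants; use dt <= ",
      "min(tau)/20 = %g (default min(tau)/100 = %g)"),
      dt, tau_min / 20, tau_min / 100))
  if (is.null(duration)) duration <- 200 * tau_max
  if (duration < 100 * tau_max)
    stop(sprintf("duration must be at least 100 * max(tau) = %g", 100 * tau_max))
  if (length(init) != 2L || any(!is.finite(init)))
    stop("'init' must be a finite length-2 state c(E, I)")
  thin <- as.integer(thin)
  stopifnot(thin >= 1L)
  m <- rk4_integrate_cpp(circuit_spec(circuit), drive_spec(drive_E),
                         drive_spec(drive_I), duration, dt,
                         init[[1]], init[[2]], thin)
  structure(list(t = m[, "t"], E = m[, "E"], I = m[, "I"],
                 theta_E = m[, "theta_E"], theta_I = m[, "theta_I"],
                 dt = dt * thin, step = dt, params = circuit,
                 drive_E = drive_E, drive_I = drive_I,
                 time_units = time_units(circuit)),
            class = "wc_trajectory")
}

circuit_spec <- function(circuit) {
  c(circuit$w_EE, circuit$w_IE, circuit$w_EI, circuit$beta,
    circuit$threshold, circuit$tau_E, circuit$tau_I)
}

#' @export
print.wc_trajectory <- function(x, ...) {
  cat(sprintf(
    "Wilson-Cowan trajectory: %d samples over %g %s (dt = %g, sampled every %g)\n",
    length(x$t), max(x$t), x$time_units, x$step, x$dt))
  cat(sprintf("  final state: E = %.6f, I = %.6f\n",
              x$E[length(x$E)], x$I[length(x$I)]))
  invisible(x)
}

#' @export
plot.wc_trajectory <- function(x, ..., show_drive = FALSE) {
  old <- par(no.readonly = TRUE); on.exit(par(old))
  if (show_drive) {
    par(mfrow = c(2, 1), mar = c(2, 4, 1, 1))
    plot(x$t, x$theta_E, type = "l", xlab = "", ylab = "drive", col = "grey40")
    lines(x$t, x$theta_I, col = "black")
    legend("topright", c("theta_E", "theta_I"), lty = 1,
           col = c("grey40", "black"), bty = "n")
  }
  plot(x$t, x$E, type = "l", col = "grey50",
       xlab = sprintf("time (%s)", x$time_units), ylab = "activity",
       ylim = range(c(x$E, x$I)), ...)
  lines(x$t, x$I, col = "black")
  legend("topright", c("E", "I"), lty = 1, col = c("grey50", "black"),
         bty = "n")
  invisible(x)
}

#' Simulate method for circuits
#'
#' Thin wrapper so `simulate(circuit, ...)` works with the stats generic;
#' the integration itself is deterministic and ignores `seed`.
#'
#' @param object A [wc_circuit()].
#' @param nsim Unused (one trajectory is returned).
#' @param seed Unused; present for generic compatibility.
#' @param ... Passed to [simulate_circuit()].
#' @return A `wc_trajectory`.
#' @export
simulate.wc_circuit <- function(object, nsim = 1, seed = NULL, ...) {
  simulate_circuit(object, ...)
}

post_transient <- function(traj, settle_fraction) {
  if (settle_fraction < 0.25 || settle_fraction > 0.9)
    stop("'settle_fraction' must lie in [0.25, 0.9]")
  keep <- traj$t >= settle_fraction * max(traj$t)
  lapply(list(t = traj$t, E = traj$E, I = traj$I,
              theta_E = traj$theta_E, theta_I = traj$theta_I),
         function(v) v[keep])
}

# Interpolated times of upward crossings of `level` by series (t, x).
upward_crossings <- function(t, x, level = 0) {
  s <- x - level
  i <- which(s[-length(s)] < 0 & s[-1] >= 0)
  if (length(i) == 0) return(numeric(0))
  t[i] + (t[i + 1] - t[i]) * (-s[i]) / (s[i + 1] - s[i])
}

#' Measure oscillation amplitude and frequency from a trajectory
#'
#' Discards the initial transient, then reports the peak-to-peak excursion
#' of the excitatory activity and its dominant frequency estimated from
#' upward mean-crossings (robust to the non-sinusoidal relaxation shape of
#' the limit cycle). The system is labelled oscillating when the
#' post-transient peak-to-peak exceeds `amplitude_threshold`; near a
#' supercritical Hopf point the amplitude vanishes continuously, so
#' simulated window edges are threshold-dependent and the eigenvalue
#' root-finder of [find_hopf_points()] is authoritative for them.
#'
#' @param traj A `wc_trajectory`.
#' @param settle_fraction Fraction of the run discarded as transient
#'   (in \[0.25, 0.9\]).
#' @param amplitude_threshold Peak-to-peak level above which the trajectory
#'   counts as oscillating.
#' @return A `wc_oscillation`: list with `peak_to_peak`, `frequency` (same
#'   time units as the trajectory; NA when not measurable), `oscillating`,
#'   and `n_crossings`.
#' @export
measure_oscillation <- function(traj, settle_fraction = 0.5,
                                amplitude_threshold = 1e-3) {
  stopifnot(inherits(traj, "wc_trajectory"))
  seg <- post_transient(traj, settle_fraction)
  ptp <- max(seg$E) - min(seg$E)
  cross <- upward_crossings(seg$t, seg$E - mean(seg$E))
  oscillating <- ptp > amplitude_threshold
  if (oscillating && length(cross) < 2)
    stop(paste0("inconsistent trajectory: amplitude above threshold but ",
                "fewer than 2 mean-crossings; the analysis window is too short"))
  freq <- if (length(cross) >= 2)
    (length(cross) - 1) / (cross[length(cross)] - cross[1]) else NA_real_
  structure(list(peak_to_peak = ptp,
                 frequency = if (oscillating) freq else NA_real_,
                 oscillating = oscillating,
                 n_crossings = length(cross),
                 time_units = traj$time_units),
            class = "wc_oscillation")
}

#' @export
print.wc_oscillation <- function(x, ...) {
  if (x$oscillating) {
    cat(sprintf("oscillating: peak-to-peak %.4g, frequency %.4g (1/%s)\n",
                x$peak_to_peak, x$frequency, x$time_units))
  } else {
    cat(sprintf("not oscillating (peak-to-peak %.3g)\n", x$peak_to_peak))
  }
  invisible(x)
}

#' Oscillation measures across a grid of constant inputs
#'
#' Integrates the circuit from the origin at each input level on one drive
#' axis (the other held constant) and measures the post-transient
#' oscillation. As the swept input rises through the oscillatory window the
#' frequency first increases and then falls off together with the amplitude
#' before oscillations disappear.
#'
#' @param circuit A [wc_circuit()].
#' @param theta_values Sorted numeric vector of input levels to sweep.
#' @param axis `"theta_E"` or `"theta_I"`: which drive is swept.
#' @param fixed_other Constant level of the other drive.
#' @param duration,dt,settle_fraction,amplitude_threshold Passed to
#'   [simulate_circuit()] and [measure_oscillation()].
#' @return A data frame with one row per input level: `theta`,
#'   `peak_to_peak`, `frequency`, `oscillating`.
#' @export
frequency_vs_input <- function(circuit, theta_values,
                               axis = c("theta_E", "theta_I"),
                               fixed_other = 0, duration = NULL, dt = NULL,
                               settle_fraction = 0.5,
                               amplitude_threshold = 1e-3) {
  axis <- match.arg(axis)
  if (is.unsorted(theta_values)) stop("'theta_values' must be sorted")
  rows <- lapply(theta_values, function(th) {
    dE <- if (axis == "theta_E") drive_constant(th) else drive_constant(fixed_other)
    dI <- if (axis == "theta_I") drive_constant(th) else drive_constant(fixed_other)
    traj <- simulate_circuit(circuit, dE, dI, duration = duration, dt = dt)
    m <- measure_oscillation(traj, settle_fraction, amplitude_threshold)
    data.frame(theta = th, peak_to_peak = m$peak_to_peak,
               frequency = m$frequency, oscillating = m$oscillating)
  })
  do.call(rbind, rows)
}

#' Write or read a trajectory as CSV
#'
#' Columns `t, E, I, theta_E, theta_I`, formatted with 10 significant
#' digits so identical runs produce byte-identical files.
#'
#' @param traj A `wc_trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly (writer); a data frame (reader).
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "wc_trajectory"))
  df <- data.frame(t = traj$t, E = traj$E, I = traj$I,
                   theta_E = traj$theta_E, theta_I = traj$theta_I)
  cols <- vapply(df, function(v) formatC(v, format = "g", digits = 10),
                 character(nrow(df)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(paste(names(df), collapse = ","),
               apply(cols, 1, paste, collapse = ",")), con)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  utils::read.csv(path)
}
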