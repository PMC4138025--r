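#' External drive signals
#'
#' A drive is either a constant input level or a sinusoid
#' `value(t) = mean + amplitude * cos(2 pi frequency t + phase_offset * pi/180)`.
#' The cosine convention puts phase 0 degrees at the drive peak; slow-drive
#' phase reported by the coupling analyses follows the same convention
#' (descending phase is (0, 180) degrees, ascending (180, 360)).
#'
#' @param mean Drive level (dimensionless, same units as theta).
#' @param amplitude Half peak-to-peak excursion (>= 0).
#' @param frequency Oscillation frequency in Hz (> 0).
#' @param phase_offset Phase offset in degrees; a drive lagging another by
#'   30 degrees has `phase_offset = -30`.
#' @return An object of class `wc_drive`.
#' @examples
#' theta <- drive_sinusoid(mean = 0.3, amplitude = 0.3, frequency = 4)
#' drive_value(theta, c(0, 0.125, 0.25))
#' @export
drive_constant <- function(mean = 0) {
  if (!is.numeric(mean) || length(mean) != 1L || !is.finite(mean))
    stop("'mean' must be a single finite number")
  structure(list(kind = "constant", mean = mean, amplitude = 0,
                 frequency = 0, phase_offset = 0), class = "wc_drive")
}

#' @rdname drive_constant
#' @export
drive_sinusoid <- function(mean, amplitude, frequency, phase_offset = 0) {
  for (nm in c("mean", "amplitude", "frequency", "phase_offset")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop(sprintf("'%s' must be a single finite number", nm))
  }
  if (amplitude < 0) stop("'amplitude' must be non-negative")
  if (frequency <= 0) stop("'frequency' must be positive for a sinusoid")
  structure(list(kind = "sinusoid", mean = mean, amplitude = amplitude,
                 frequency = frequency, phase_offset = phase_offset),
            class = "wc_drive")
}

#' @export
print.wc_drive <- function(x, ...) {
  if (x$kind == "constant") {
    cat(sprintf("constant drive: level %g\n", x$mean))
  } else {
    cat(sprintf(
      "sinusoidal drive: mean %g, amplitude %g, %g Hz, phase offset %g deg\n",
      x$mean, x$amplitude, x$frequency, x$phase_offset))
  }
  invisible(x)
}

#' Evaluate a drive at given times
#'
#' @param drive A [drive_constant()] or [drive_sinusoid()].
#' @param t Time(s), in the same units as the simulation.
#' @return Drive value(s).
#' @export
drive_value <- function(drive, t) {
  stopifnot(inherits(drive, "wc_drive"))
  if (drive$kind == "constant") return(rep(drive$mean, length(t)))
  drive$mean + drive$amplitude *
    cos(2 * pi * drive$frequency * t + drive$phase_offset * pi / 180)
}

#' Instantaneous phase of a sinusoidal drive, in degrees
#'
#' Phase 0 at the drive peak (cosine convention), increasing with time,
#' wrapped to \[0, 360).
#'
#' @inheritParams drive_value
#' @return Phase(s) in degrees.
#' @export
drive_phase <- function(drive, t) {
  stopifnot(inherits(drive, "wc_drive"))
  if (drive$kind != "sinusoid") stop("phase is defined for sinusoidal drives only")
  (360 * drive$frequency * t + drive$phase_offset) %% 360
}

#' Extreme values of a drive
#'
#' @inheritParams drive_value
#' @return `c(min, max)` of the drive over a full cycle.
#' @export
drive_range <- function(drive) {
  stopifnot(inherits(drive, "wc_drive"))
  c(drive$mean - drive$amplitude, drive$mean + drive$amplitude)
}

# Pack a drive into the numeric layout the compiled integrator expects.
drive_spec <- function(drive) {
  c(if (drive$kind == "constant") 0 else 1, drive$mean, drive$amplitude,
    drive$frequency, drive$phase_offset * pi / 180)
}

as_drive <- function(x) {
  if (inherits(x, "wc_drive")) return(x)
  if (is.numeric(x) && length(x) == 1L) return(drive_constant(x))
  stop("expected a 'wc_drive' or a single constant input level")
}
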