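#' Locate the Hopf-bounded oscillation window along one drive axis
#'
#' Tracks the (unique) equilibrium as the chosen constant input varies and
#' root-finds the zero crossings of the real part of its Jacobian
#' eigenvalues. With equal time constants the eigenvalues are complex at the
#' crossings, so the real part is `trace/2` and the crossings are Hopf
#' bifurcations bounding the window of inputs for which the circuit is an
#' intrinsic oscillator: inside it the single equilibrium is unstable and,
#' by the Poincare-Bendixson theorem applied to the `[0,1]^2` trapping
#' region, a limit cycle exists. Analysis is done in natural time units;
#' the window location does not depend on `tau` when `tau_E = tau_I`.
#'
#' A trace zero at which the determinant is not positive (real eigenvalues)
#' would signal a non-Hopf mechanism and raises an error.
#'
#' @param circuit A [wc_circuit()] with `tau_E == tau_I`.
#' @param axis `"theta_E"` or `"theta_I"`: the swept drive.
#' @param fixed_other Constant level of the other drive.
#' @param search_interval Numeric length-2 interval scanned for crossings.
#' @param n_scan Number of scan points used to bracket the crossings.
#' @return A `wc_window`: list with `axis`, `fixed_other`, `lower`, `upper`,
#'   `method = "eigenvalue_rootfind"`, and the residual real parts at the
#'   two endpoints.
#' @examples
#' find_hopf_points(wc_circuit(), axis = "theta_E", search_interval = c(0, 2))
#' @export
find_hopf_points <- function(circuit, axis = c("theta_E", "theta_I"),
                             fixed_other = 0, search_interval = c(0, 2),
                             n_scan = 201L) {
  stopifnot(inherits(circuit, "wc_circuit"))
  axis <- match.arg(axis)
  if (circuit$tau_E != circuit$tau_I)
    stop("Hopf window location requires tau_E == tau_I")
  if (length(search_interval) != 2L || diff(search_interval) <= 0)
    stop("'search_interval' must be an increasing length-2 interval")
  eq_at <- function(theta) {
    eqs <- if (axis == "theta_E")
      find_equilibria(circuit, theta, fixed_other)
    else find_equilibria(circuit, fixed_other, theta)
    if (length(eqs) != 1L)
      stop(sprintf(paste0(
        "%d equilibria at %s = %g; the tracked fixed point must be unique ",
        "on the search interval (inspect with count_equilibria())"),
        length(eqs), axis, theta))
    eqs[[1]]
  }
  re_lambda <- function(theta) eq_at(theta)$trace / 2
  grid <- seq(search_interval[1], search_interval[2], length.out = n_scan)
  vals <- vapply(grid, re_lambda, numeric(1))
  idx <- which(vals[-n_scan] * vals[-1] < 0)
  idx <- c(idx, which(vals == 0))
  if (length(idx) == 0)
    stop("no Hopf bifurcation in the search interval: Re(lambda) does not change sign")
  roots <- sort(vapply(idx, function(i) {
    if (vals[i] == 0) return(grid[i])
    uniroot(re_lambda, c(grid[i], grid[i + 1]), tol = 1e-12)$root
  }, numeric(1)))
  if (length(roots) != 2L)
    stop(sprintf(paste0(
      "expected an oscillation window bounded by two Hopf points but found ",
      "%d crossing(s) in [%g, %g]; widen or split the search interval"),
      length(roots), search_interval[1], search_interval[2]))
  for (r in roots) {
    e <- eq_at(r)
    if (e$determinant <= e$trace^2 / 4)
      stop(sprintf(paste0(
        "trace-zero crossing at %s = %g has real eigenvalues ",
        "(determinant below trace^2/4): not a Hopf bifurcation"), axis, r))
  }
  structure(list(axis = axis, fixed_other = fixed_other,
                 lower = roots[1], upper = roots[2],
                 method = "eigenvalue_rootfind",
                 re_lambda_at_edges = vapply(roots, re_lambda, numeric(1)),
                 analysis_units = "natural (tau = 1)"),
            class = "wc_window")
}

#' @export
print.wc_window <- function(x, ...) {
  cat(sprintf(
    "oscillation window on %s (other drive at %g): (%.6f, %.6f) [%s]\n",
    x$axis, x$fixed_other, x$lower, x$upper, x$method))
  invisible(x)
}

#' Write an oscillation window as JSON
#'
#' @param window A `wc_window`.
#' @param path Optional output path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written).
#' @export
window_json <- function(window, path = NULL) {
  stopifnot(inherits(window, "wc_window"))
  js <- jsonlite::toJSON(unclass(window), auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Post-transient activity envelope across a grid of constant inputs
#'
#' Integrates the circuit from the origin at each swept input level and
#' records the post-transient minimum and maximum of the excitatory
#' activity; the two separate exactly over the oscillatory window, closing
#' continuously at its edges (supercritical onset).
#'
#' @inheritParams find_hopf_points
#' @param values Sorted input levels to sweep.
#' @param duration Integration time per level; default `600 * max(tau)`. The
#'   long default is deliberate: at one grid step (0.01) from a window edge
#'   the eigenvalue real part is only ~0.015-0.03 in magnitude (natural
#'   units), so resolving the edge to one step needs a transient of several
#'   hundred time constants for near-edge ring-up/ring-down to separate from
#'   the limit cycle.
#' @param dt Integration step, default `min(tau)/100`.
#' @param settle_fraction Fraction discarded as transient.
#' @param amplitude_threshold Peak-to-peak level above which a point counts
#'   as oscillating.
#' @param init Initial state.
#' @return Data frame with `theta`, `E_min`, `E_max`, `oscillating`.
#' @export
sweep_envelope <- function(circuit, axis = c("theta_E", "theta_I"), values,
                           fixed_other = 0, duration = NULL, dt = NULL,
                           settle_fraction = 0.5, amplitude_threshold = 1e-3,
                           init = c(0, 0)) {
  stopifnot(inherits(circuit, "wc_circuit"))
  axis <- match.arg(axis)
  if (is.unsorted(values)) stop("'values' must be sorted")
  tau_max <- max(circuit$tau_E, circuit$tau_I)
  if (is.null(duration)) duration <- 600 * tau_max
  if (is.null(dt)) dt <- min(circuit$tau_E, circuit$tau_I) / 100
  spec <- circuit_spec(circuit)
  other <- drive_spec(drive_constant(fixed_other))
  res <- vapply(values, function(th) {
    d <- drive_spec(drive_constant(th))
    ex <- if (axis == "theta_E")
      rk4_extrema_cpp(spec, d, other, duration, dt, init[1], init[2],
                      settle_fraction)
    else rk4_extrema_cpp(spec, other, d, duration, dt, init[1], init[2],
                         settle_fraction)
    ex[c("E_min", "E_max")]
  }, numeric(2))
  data.frame(theta = values, E_min = res[1, ], E_max = res[2, ],
             oscillating = (res[2, ] - res[1, ]) > amplitude_threshold)
}

#' Oscillation window estimated from a simulation sweep
#'
#' Converts the output of [sweep_envelope()] into a `wc_window` whose edges
#' are the first and last oscillating grid values; they agree with the
#' eigenvalue-located Hopf points within one grid step.
#'
#' @param sweep Data frame from [sweep_envelope()].
#' @param axis,fixed_other Metadata copied into the window record.
#' @return A `wc_window` with `method = "simulation_sweep"`.
#' @export
window_from_sweep <- function(sweep, axis = "theta_E", fixed_other = 0) {
  if (!all(c("theta", "oscillating") %in% names(sweep)))
    stop("'sweep' must come from sweep_envelope()")
  on <- which(sweep$oscillating)
  if (length(on) == 0) stop("no oscillating grid point in the sweep")
  structure(list(axis = axis, fixed_other = fixed_other,
                 lower = sweep$theta[min(on)], upper = sweep$theta[max(on)],
                 method = "simulation_sweep",
                 grid_step = if (length(sweep$theta) > 1)
                   stats::median(diff(sweep$theta)) else NA_real_),
            class = "wc_window")
}

#' Two-parameter map of the oscillatory region
#'
#' Classifies every cell of a `(theta_E, theta_I)` grid as oscillatory or
#' not by direct simulation from the origin (post-transient peak-to-peak
#' threshold rule). Increasing the E-to-I weight `w_EI` from 2 to 2.5
#' shrinks the oscillatory region; for `w_EE <= 1` the map is empty because
#' the unique equilibrium is always stable.
#'
#' @param circuit A [wc_circuit()].
#' @param theta_E_range,theta_I_range Length-2 ranges of the grid.
#' @param step Grid step (the reference map uses 0.01).
#' @param duration,dt,settle_fraction,amplitude_threshold,init As in
#'   [sweep_envelope()].
#' @return A `wc_region_map`: list with the two grids, a logical matrix
#'   `oscillatory` (rows indexed by `theta_E`), the circuit snapshot and the
#'   classification settings.
#' @export
region_map <- function(circuit, theta_E_range = c(0, 2),
                       theta_I_range = c(0, 1), step = 0.01,
                       duration = NULL, dt = NULL, settle_fraction = 0.5,
                       amplitude_threshold = 1e-3, init = c(0, 0)) {
  stopifnot(inherits(circuit, "wc_circuit"))
  if (step <= 0) stop("'step' must be positive")
  tau_max <- max(circuit$tau_E, circuit$tau_I)
  if (is.null(duration)) duration <- 100 * tau_max
  if (is.null(dt)) dt <- min(circuit$tau_E, circuit$tau_I) / 100
  thE <- seq(theta_E_range[1], theta_E_range[2], by = step)
  thI <- seq(theta_I_range[1], theta_I_range[2], by = step)
  spec <- circuit_spec(circuit)
  osc <- matrix(FALSE, length(thE), length(thI),
                dimnames = list(NULL, NULL))
  for (j in seq_along(thI)) {
    dI <- drive_spec(drive_constant(thI[j]))
    for (i in seq_along(thE)) {
      ex <- rk4_extrema_cpp(spec, drive_spec(drive_constant(thE[i])), dI,
                            duration, dt, init[1], init[2], settle_fraction)
      osc[i, j] <- (ex[["E_max"]] - ex[["E_min"]]) > amplitude_threshold
    }
  }
  structure(list(theta_E_grid = thE, theta_I_grid = thI, oscillatory = osc,
                 params = circuit, step = step, duration = duration,
                 dt = dt, settle_fraction = settle_fraction,
                 amplitude_threshold = amplitude_threshold),
            class = "wc_region_map")
}

#' @export
print.wc_region_map <- function(x, ...) {
  cat(sprintf(
    "oscillatory region map: %d x %d grid (step %g), %d oscillatory cells (%.1f%%)\n",
    length(x$theta_E_grid), length(x$theta_I_grid), x$step,
    sum(x$oscillatory), 100 * mean(x$oscillatory)))
  invisible(x)
}

#' @export
plot.wc_region_map <- function(x, ...) {
  image(x$theta_E_grid, x$theta_I_grid, x$oscillatory * 1,
        col = c("steelblue", "firebrick"), xlab = "theta_E",
        ylab = "theta_I", ...)
  invisible(x)
}

#' Write a region map as CSV matrix plus JSON sidecar
#'
#' The CSV holds the 0/1 oscillatory matrix (rows = `theta_E` values,
#' columns = `theta_I` values); the sidecar records the grids, the circuit
#' parameters and the classification settings.
#'
#' @param map A `wc_region_map`.
#' @param csv_path,json_path Output paths.
#' @return `csv_path`, invisibly.
#' @export
write_region_map <- function(map, csv_path, json_path) {
  stopifnot(inherits(map, "wc_region_map"))
  m <- map$oscillatory * 1L
  con <- file(csv_path, "wb")
  writeLines(apply(m, 1, paste, collapse = ","), con)
  close(con)
  meta <- list(theta_E_grid = map$theta_E_grid,
               theta_I_grid = map$theta_I_grid, step = map$step,
               params = unclass(map$params), duration = map$duration,
               dt = map$dt, settle_fraction = map$settle_fraction,
               amplitude_threshold = map$amplitude_threshold)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
             json_path)
  invisible(csv_path)
}
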