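# Shared fixtures: the reference parameterization and its natural-units twin.
default_circuit <- function() wc_circuit()
natural_circuit <- function() natural_units(wc_circuit())

# Memoized oscillation windows (the root-find is cheap but used everywhere).
.cache <- new.env(parent = emptyenv())
window_theta_E <- function() {
  if (is.null(.cache$wE))
    .cache$wE <- find_hopf_points(default_circuit(), "theta_E", 0, c(0, 2))
  .cache$wE
}
window_theta_I <- function() {
  if (is.null(.cache$wI))
    .cache$wI <- find_hopf_points(default_circuit(), "theta_I", 1.3, c(0, 1))
  .cache$wI
}

# Closed-form Hopf inputs for equal time constants: the trace-zero condition
# w_EE * beta * E* (1 - E*) = 2 fixes E*, and the nullclines then give the
# input level. Independent of the package's root-finder.
hopf_oracle_theta_E <- function(w_EE = 2.4, w_EI = 2, w_IE = 2, beta = 4) {
  E <- (1 + c(-1, 1) * sqrt(1 - 8 / (beta * w_EE))) / 2
  finv <- function(y) 1 + log(y / (1 - y)) / beta
  f <- function(x) 1 / (1 + exp(-beta * (x - 1)))
  sort(finv(E) - w_EE * E + w_IE * f(w_EI * E))
}
hopf_oracle_theta_I <- function(theta_E = 1.3, w_EE = 2.4, w_EI = 2,
                                w_IE = 2, beta = 4) {
  E <- (1 + c(-1, 1) * sqrt(1 - 8 / (beta * w_EE))) / 2
  finv <- function(y) 1 + log(y / (1 - y)) / beta
  I <- (w_EE * E + theta_E - finv(E)) / w_IE
  sort(finv(I) - w_EI * E)
}

# Build a bare trajectory object around an analytic signal (for testing the
# envelope and modulation-index estimators against known inputs).
synthetic_trajectory <- function(x, dt, duration = length(x) * dt) {
  t <- seq(0, by = dt, length.out = length(x))
  structure(list(t = t, E = x, I = x * 0, theta_E = x * 0, theta_I = x * 0,
                 dt = dt, step = dt, params = wc_circuit(),
                 time_units = "seconds"),
            class = "wc_trajectory")
}
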