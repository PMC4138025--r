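#' Define a two-population excitatory-inhibitory circuit
#'
#' Constructs the static parameterization of the firing-rate model
#' \deqn{\tau_E \dot E = -E + f(w_{EE} E - w_{IE} I + \theta_E)}
#' \deqn{\tau_I \dot I = -I + f(w_{EI} E + \theta_I)}
#' where \eqn{f} is the logistic sigmoid of [sigmoid()]. All weights are
#' non-negative magnitudes; the inhibitory sign of the I-to-E synapse is
#' applied inside the equations. Subscripts read source-to-target: `w_EI` is
#' the weight of the excitatory projection onto the inhibitory population
#' (it appears in the I equation), `w_IE` the weight of the inhibitory
#' projection onto the excitatory population (E equation), and `w_EE` the
#' recurrent excitatory self-connection required for intrinsic oscillations.
#'
#' Defaults are the reference parameterization: `w_EE = 2.4`,
#' `w_EI = w_IE = 2`, `beta = 4`, and membrane time constants of 0.0032 s,
#' which place the intrinsic oscillation at 55 Hz (gamma) under constant
#' drive `theta_E = 0.5`. Stability and bifurcation analyses are carried out
#' in natural time units (`tau_E = tau_I = 1`, see [natural_units()]); with
#' equal time constants the stability classification is invariant to this
#' rescaling.
#'
#' @param w_EE Recurrent E-to-E synaptic weight (dimensionless, >= 0).
#' @param w_EI E-to-I synaptic weight (>= 0).
#' @param w_IE I-to-E synaptic weight (>= 0).
#' @param beta Sigmoid steepness (> 0); 4 makes the maximum slope exactly 1.
#' @param tau_E,tau_I Population time constants in seconds (> 0).
#' @param threshold Sigmoid mean threshold; fixed at 1 in the reference
#'   parameterization.
#' @return An object of class `wc_circuit`.
#' @examples
#' circ <- wc_circuit()
#' find_equilibria(circ, theta_E = 0, theta_I = 0)
#' @export
wc_circuit <- function(w_EE = 2.4, w_EI = 2, w_IE = 2, beta = 4,
                       tau_E = 0.0032, tau_I = 0.0032, threshold = 1) {
  for (nm in c("w_EE", "w_EI", "w_IE", "beta", "tau_E", "tau_I", "threshold")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop(sprintf("'%s' must be a single finite number", nm))
  }
  if (w_EE < 0 || w_EI < 0 || w_IE < 0)
    stop("synaptic weights must be non-negative; signs are applied in the equations")
  if (beta <= 0) stop("'beta' must be positive")
  if (tau_E <= 0 || tau_I <= 0) stop("time constants must be positive")
  structure(list(w_EE = w_EE, w_EI = w_EI, w_IE = w_IE, beta = beta,
                 tau_E = tau_E, tau_I = tau_I, threshold = threshold),
            class = "wc_circuit")
}

#' @export
print.wc_circuit <- function(x, ...) {
  cat("Wilson-Cowan E/I circuit\n")
  cat(sprintf("  weights: w_EE = %g, w_EI = %g (E->I), w_IE = %g (I->E)\n",
              x$w_EE, x$w_EI, x$w_IE))
  cat(sprintf("  sigmoid: beta = %g, threshold = %g\n", x$beta, x$threshold))
  cat(sprintf("  time constants: tau_E = %g s, tau_I = %g s (%s units)\n",
              x$tau_E, x$tau_I, time_units(x)))
  invisible(x)
}

#' Rescale a circuit to natural time units
#'
#' Returns a copy of the circuit with `tau_E = tau_I = 1`. With equal time
#' constants this is a uniform positive rescaling of the vector field, so
#' trajectories are identical up to a time dilation and all stability labels
#' are unchanged; frequencies scale by `1/tau`.
#'
#' @param circuit A [wc_circuit()].
#' @return A `wc_circuit` with unit time constants.
#' @export
natural_units <- function(circuit) {
  stopifnot(inherits(circuit, "wc_circuit"))
  circuit$tau_E <- 1
  circuit$tau_I <- 1
  circuit
}

time_units <- function(circuit) {
  if (circuit$tau_E == 1 && circuit$tau_I == 1) "natural" else "seconds"
}

#' Sigmoidal population response function
#'
#' The logistic activation \eqn{f(x) = 1/(1 + e^{-\beta (x - 1)})} used by
#' both populations (threshold fixed at 1 unless overridden). It is strictly
#' increasing, maps onto (0, 1), satisfies `f(1) = 1/2`, and has `f(0) > 0`
#' so a population with zero input retains spontaneous activity. At
#' `beta = 4` the maximum slope, attained at the threshold, is exactly 1.
#'
#' @param x Input level(s); must be finite.
#' @param beta Steepness (> 0).
#' @param threshold Mean threshold (default 1).
#' @return Activation value(s) in (0, 1).
#' @seealso [sigmoid_inverse()], [sigmoid_deriv()]
#' @export
sigmoid <- function(x, beta = 4, threshold = 1) {
  if (beta <= 0) stop("'beta' must be positive")
  if (any(!is.finite(x))) stop("'x' must be finite: invalid state")
  1 / (1 + exp(-beta * (x - threshold)))
}

#' Inverse of the sigmoidal response function
#'
#' Solves `sigmoid(x, beta) = y` for `x`, i.e.
#' \eqn{f^{-1}(y) = 1 + \log(y / (1 - y)) / \beta}. Needed to express the
#' E-nullcline in closed form.
#'
#' @param y Activation value(s), strictly inside (0, 1).
#' @inheritParams sigmoid
#' @return Input level(s).
#' @export
sigmoid_inverse <- function(y, beta = 4, threshold = 1) {
  if (beta <= 0) stop("'beta' must be positive")
  if (any(!is.finite(y)) || any(y <= 0) || any(y >= 1))
    stop("'y' must lie strictly inside (0, 1)")
  threshold + log(y / (1 - y)) / beta
}

#' Derivative of the sigmoidal response function
#'
#' \eqn{f'(x) = \beta f(x) (1 - f(x))}; maximal at the threshold where it
#' equals `beta / 4`.
#'
#' @inheritParams sigmoid
#' @return Slope value(s), positive everywhere.
#' @export
sigmoid_deriv <- function(x, beta = 4, threshold = 1) {
  fx <- sigmoid(x, beta, threshold)
  beta * fx * (1 - fx)
}

#' Vector field of the circuit
#'
#' Time derivatives `(dE/dt, dI/dt)` at a state for given constant input
#' levels. Zero exactly at fixed points.
#'
#' @param state Numeric length-2 vector `c(E, I)`.
#' @param circuit A [wc_circuit()].
#' @param theta_E,theta_I Constant external inputs to the two populations.
#' @return Named numeric vector `c(dE, dI)`.
#' @export
vector_field <- function(state, circuit, theta_E = 0, theta_I = 0) {
  stopifnot(inherits(circuit, "wc_circuit"), length(state) == 2L)
  if (any(!is.finite(state))) stop("'state' must be finite: invalid state")
  E <- state[[1]]; I <- state[[2]]
  a_E <- circuit$w_EE * E - circuit$w_IE * I + theta_E
  a_I <- circuit$w_EI * E + theta_I
  c(dE = (-E + sigmoid(a_E, circuit$beta, circuit$threshold)) / circuit$tau_E,
    dI = (-I + sigmoid(a_I, circuit$beta, circuit$threshold)) / circuit$tau_I)
}

#' Jacobian of the circuit at a state
#'
#' With `a_E = w_EE E - w_IE I + theta_E` and `a_I = w_EI E + theta_I`, the
#' Jacobian is
#' \deqn{J = \begin{pmatrix} (-1 + w_{EE} f'(a_E))/\tau_E &
#'   -w_{IE} f'(a_E)/\tau_E \\ w_{EI} f'(a_I)/\tau_I & -1/\tau_I
#'   \end{pmatrix}.}
#' Its sign structure is fixed except for the top-left entry: the
#' off-diagonals are respectively negative and positive and the bottom-right
#' entry is always negative, so instability can only enter through
#' `w_EE f'(a_E) > 1`. In particular `w_EE < 1` forces stability since the
#' sigmoid slope never exceeds 1 at `beta = 4`.
#'
#' @inheritParams vector_field
#' @return A 2x2 numeric matrix.
#' @export
wc_jacobian <- function(state, circuit, theta_E = 0, theta_I = 0) {
  stopifnot(inherits(circuit, "wc_circuit"), length(state) == 2L)
  E <- state[[1]]; I <- state[[2]]
  a_E <- circuit$w_EE * E - circuit$w_IE * I + theta_E
  a_I <- circuit$w_EI * E + theta_I
  fpE <- sigmoid_deriv(a_E, circuit$beta, circuit$threshold)
  fpI <- sigmoid_deriv(a_I, circuit$beta, circuit$threshold)
  matrix(c((-1 + circuit$w_EE * fpE) / circuit$tau_E,
           -circuit$w_IE * fpE / circuit$tau_E,
           circuit$w_EI * fpI / circuit$tau_I,
           -1 / circuit$tau_I),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("dE", "dI"), c("E", "I")))
}

#' Nullclines of the circuit
#'
#' The E-nullcline solves `dE/dt = 0` for I as a function of E:
#' \eqn{I = (w_{EE} E + \theta_E - f^{-1}(E)) / w_{IE}} (an inverse-sigmoid
#' shape, defined for E strictly inside (0, 1)). The I-nullcline solves
#' `dI/dt = 0`: \eqn{I = f(w_{EI} E + \theta_I)}, a sigmoid strictly
#' increasing in E. Their intersections are the equilibria of the system;
#' the nullcline geometry admits one, three or five of them.
#'
#' @param E Excitatory activity value(s); strictly inside (0, 1) for
#'   `e_nullcline`.
#' @param circuit A [wc_circuit()].
#' @param theta_E,theta_I Constant input level.
#' @return Inhibitory activity value(s) on the nullcline.
#' @export
e_nullcline <- function(E, circuit, theta_E = 0) {
  stopifnot(inherits(circuit, "wc_circuit"))
  if (any(!is.finite(E)) || any(E <= 0) || any(E >= 1))
    stop("'E' must lie strictly inside (0, 1) on the E-nullcline")
  (circuit$w_EE * E + theta_E -
     sigmoid_inverse(E, circuit$beta, circuit$threshold)) / circuit$w_IE
}

#' @rdname e_nullcline
#' @export
i_nullcline <- function(E, circuit, theta_I = 0) {
  stopifnot(inherits(circuit, "wc_circuit"))
  sigmoid(circuit$w_EI * E + theta_I, circuit$beta, circuit$threshold)
}
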