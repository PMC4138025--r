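#' Find all equilibria for constant inputs
#'
#' Equilibria are intersections of the two nullclines. The difference
#' `g(E) = e_nullcline(E) - i_nullcline(E)` is smooth with at most five
#' roots, so roots are located by sign-change bracketing on a dense E grid
#' followed by bisection polishing (and are therefore reproducible without
#' continuation machinery). `g` is positive near `E = 0` and negative near
#' `E = 1`, so at least one equilibrium always exists. Eigenvalues and
#' stability labels are computed from the natural-time-unit Jacobian
#' (`tau = 1`); with equal time constants the labels are invariant to that
#' rescaling.
#'
#' A root at which `g` is tangent to zero (a nullcline tangency, generic
#' only on measure-zero parameter sets) is flagged `degenerate` rather than
#' treated as an error.
#'
#' @param circuit A [wc_circuit()].
#' @param theta_E,theta_I Constant input levels.
#' @param n_grid Number of scan points on `E` in `[1e-6, 1 - 1e-6]`.
#' @return A list of `wc_equilibrium` objects sorted by `E_star`, of class
#'   `wc_equilibria`. Each has `E_star`, `I_star`, `jacobian` (tau = 1),
#'   `trace`, `determinant`, `eigenvalues` (complex pair from the
#'   trace/determinant closed form), `stability`, `degenerate`, `residual`.
#' @examples
#' find_equilibria(wc_circuit(), theta_E = 0.7, theta_I = 0)
#' @export
find_equilibria <- function(circuit, theta_E = 0, theta_I = 0,
                            n_grid = 10001L) {
  stopifnot(inherits(circuit, "wc_circuit"))
  nat <- natural_units(circuit)
  g <- function(E) e_nullcline(E, nat, theta_E) - i_nullcline(E, nat, theta_I)
  eps <- 1e-6
  Eg <- seq(eps, 1 - eps, length.out = n_grid)
  gv <- g(Eg)
  roots <- numeric(0)
  # exact zeros on grid points
  zero_idx <- which(gv == 0)
  roots <- c(roots, Eg[zero_idx])
  sgn <- sign(gv)
  idx <- which(sgn[-n_grid] * sgn[-1] < 0)
  for (i in idx) {
    r <- uniroot(g, c(Eg[i], Eg[i + 1]), tol = 1e-14)$root
    roots <- c(roots, r)
  }
  roots <- sort(roots)
  if (length(roots) > 1)
    roots <- roots[c(TRUE, diff(roots) > 1e-9)]
  h <- 1e-7
  eqs <- lapply(roots, function(E) {
    I <- i_nullcline(E, nat, theta_I)
    J <- wc_jacobian(c(E, I), nat, theta_E, theta_I)
    tr <- J[1, 1] + J[2, 2]
    dt <- J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]
    disc <- as.complex(tr^2 / 4 - dt)
    lam <- tr / 2 + c(1, -1) * sqrt(disc)
    gp <- (g(min(E + h, 1 - eps)) - g(max(E - h, eps))) /
      (min(E + h, 1 - eps) - max(E - h, eps))
    res <- max(abs(vector_field(c(E, I), nat, theta_E, theta_I)))
    structure(list(E_star = E, I_star = I, theta_E = theta_E,
                   theta_I = theta_I, jacobian = J, trace = tr,
                   determinant = dt, eigenvalues = lam,
                   stability = classify_stability(tr, dt),
                   degenerate = abs(gp) < 1e-5, residual = res,
                   analysis_units = "natural (tau = 1)"),
              class = "wc_equilibrium")
  })
  structure(eqs, class = "wc_equilibria")
}

#' @export
print.wc_equilibrium <- function(x, ...) {
  cat(sprintf("equilibrium (E*, I*) = (%.6f, %.6f) at theta = (%g, %g)\n",
              x$E_star, x$I_star, x$theta_E, x$theta_I))
  cat(sprintf("  %s; tr = %.5f, det = %.5f; eigenvalues %s [%s]%s\n",
              x$stability, x$trace, x$determinant,
              paste(format(x$eigenvalues, digits = 4), collapse = ", "),
              x$analysis_units,
              if (isTRUE(x$degenerate)) " (degenerate tangency)" else ""))
  invisible(x)
}

#' @export
print.wc_equilibria <- function(x, ...) {
  cat(sprintf("%d equilibrium(-ia):\n", length(x)))
  for (e in x) print(e)
  invisible(x)
}

#' Number of equilibria for constant inputs
#'
#' The nullcline geometry admits one, three or five intersections. An even
#' count signals a tangency (degenerate) configuration, reported with the
#' `degenerate` attribute set.
#'
#' @inheritParams find_equilibria
#' @return Integer count, with attribute `degenerate`.
#' @export
count_equilibria <- function(circuit, theta_E = 0, theta_I = 0,
                             n_grid = 10001L) {
  eqs <- find_equilibria(circuit, theta_E, theta_I, n_grid)
  n <- length(eqs)
  degen <- any(vapply(eqs, function(e) isTRUE(e$degenerate), logical(1))) ||
    n %% 2L == 0L
  structure(n, degenerate = degen)
}

#' Classify the stability of a planar equilibrium
#'
#' Labels follow the trace/determinant criteria for a 2x2 Jacobian, whose
#' eigenvalues are `tr/2 +/- sqrt(tr^2/4 - det)`: a negative determinant
#' gives a saddle; complex eigenvalues (`tr^2/4 < det`) give a stable or
#' unstable focus by the sign of `tr`; real eigenvalues of a common sign
#' give a node. Real parts within `tol` of zero are flagged
#' `nonhyperbolic`, never silently classified.
#'
#' @param x A `wc_equilibrium`, or the Jacobian trace as a number.
#' @param determinant Jacobian determinant (when `x` is the trace).
#' @param tol Real parts smaller than this in magnitude count as zero.
#' @return One of `"stable_node"`, `"stable_focus"`, `"unstable_node"`,
#'   `"unstable_focus"`, `"saddle"`, `"nonhyperbolic"`.
#' @examples
#' classify_stability(0.4, 2.5)   # unstable focus
#' classify_stability(-1, 0.1)    # stable node
#' @export
classify_stability <- function(x, determinant = NULL, tol = 1e-8) {
  if (inherits(x, "wc_equilibrium")) {
    tr <- x$trace; dt <- x$determinant
  } else {
    tr <- x; dt <- determinant
    if (is.null(dt)) stop("'determinant' is required when passing the trace")
  }
  disc <- tr^2 / 4 - dt
  if (disc < 0) {                       # complex pair, real part tr/2
    if (abs(tr / 2) < tol) return("nonhyperbolic")
    return(if (tr < 0) "stable_focus" else "unstable_focus")
  }
  lam <- tr / 2 + c(1, -1) * sqrt(disc) # real eigenvalues
  if (any(abs(lam) < tol)) return("nonhyperbolic")
  if (dt < 0) return("saddle")
  if (tr < 0) "stable_node" else "unstable_node"
}

#' Export equilibria as JSON records
#'
#' Complex eigenvalues are written as `[re, im]` pairs.
#'
#' @param eqs A `wc_equilibria` list from [find_equilibria()].
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to a file).
#' @export
equilibria_json <- function(eqs, path = NULL) {
  stopifnot(inherits(eqs, "wc_equilibria"))
  recs <- lapply(eqs, function(e) {
    list(E_star = e$E_star, I_star = e$I_star, theta_E = e$theta_E,
         theta_I = e$theta_I, trace = e$trace, determinant = e$determinant,
         eigenvalues = lapply(e$eigenvalues, function(l) c(Re(l), Im(l))),
         stability = e$stability, degenerate = e$degenerate,
         analysis_units = e$analysis_units)
  })
  js <- jsonlite::toJSON(recs, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
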