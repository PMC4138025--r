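test_that("printed equilibria are recovered with their stability", {
  circ <- default_circuit()
  e0 <- find_equilibria(circ, 0, 0)
  expect_length(e0, 1)
  expect_equal(round(e0[[1]]$E_star, 4), 0.0181)
  expect_equal(round(e0[[1]]$I_star, 4), 0.0207)
  expect_match(e0[[1]]$stability, "^stable")

  e13 <- find_equilibria(circ, 1.3, 0)
  expect_equal(round(e13[[1]]$E_star, 4), 0.8873)
  expect_equal(round(e13[[1]]$I_star, 4), 0.9568)
  expect_match(e13[[1]]$stability, "^stable")

  e07 <- find_equilibria(circ, 0.7, 0)
  expect_length(e07, 1)
  expect_equal(round(e07[[1]]$E_star, 2), 0.46)
  expect_identical(e07[[1]]$stability, "unstable_focus")
  # complex pair with positive real part (the printed magnitudes are not
  # reproduced by the reconstructed Jacobian; the signs are)
  expect_gt(Re(e07[[1]]$eigenvalues[1]), 0)
  expect_true(Im(e07[[1]]$eigenvalues[1]) != 0)
})

test_that("every equilibrium sits on both nullclines to 1e-8", {
  circ <- default_circuit()
  set.seed(5)
  for (i in 1:20) {
    thE <- runif(1, 0, 2); thI <- runif(1, 0, 1)
    for (eq in find_equilibria(circ, thE, thI)) {
      expect_lt(abs(e_nullcline(eq$E_star, circ, thE) - eq$I_star), 1e-8)
      expect_lt(abs(i_nullcline(eq$E_star, circ, thI) - eq$I_star), 1e-8)
      expect_lt(eq$residual, 1e-10)
    }
  }
})

test_that("equilibrium counts are odd and w_EE <= 1 forces a single one", {
  circ <- default_circuit()
  set.seed(6)
  for (i in 1:15) {
    n <- count_equilibria(circ, runif(1, 0, 2), runif(1, 0, 1))
    if (!attr(n, "degenerate")) expect_true(as.integer(n) %in% c(1L, 3L, 5L))
  }
  weak <- wc_circuit(w_EE = 1, tau_E = 1, tau_I = 1)
  for (thE in seq(0, 2, 0.25)) for (thI in c(0, 0.5)) {
    expect_equal(as.integer(count_equilibria(weak, thE, thI)), 1L)
  }
})

test_that("an exact on-grid root is still counted once", {
  # at theta_E = 0.8 the equilibrium sits exactly at E = 0.5 by symmetry
  circ <- default_circuit()
  n <- count_equilibria(circ, 0.8, 0)
  expect_equal(as.integer(n), 1L)
  eq <- find_equilibria(circ, 0.8, 0)[[1]]
  expect_equal(eq$E_star, 0.5, tolerance = 1e-9)
})

test_that("stability labels follow the trace/determinant rules", {
  expect_identical(classify_stability(-1, 0.1), "stable_node")
  expect_identical(classify_stability(-1, 2), "stable_focus")
  expect_identical(classify_stability(0.4, 2.5), "unstable_focus")
  expect_identical(classify_stability(1, 0.1), "unstable_node")
  expect_identical(classify_stability(0.5, -1), "saddle")
  expect_identical(classify_stability(0, 2), "nonhyperbolic")
  expect_identical(classify_stability(1, 0), "nonhyperbolic")
  expect_error(classify_stability(0.4), "determinant")
  # works directly on an equilibrium object
  eq <- find_equilibria(default_circuit(), 0.7, 0)[[1]]
  expect_identical(classify_stability(eq), eq$stability)
})

test_that("closed-form eigenvalues match the numeric 2x2 solver", {
  circ <- natural_circuit()
  set.seed(8)
  for (i in 1:20) {
    for (eq in find_equilibria(circ, runif(1, 0, 2), runif(1, 0, 1))) {
      lam_num <- eigen(eq$jacobian, only.values = TRUE)$values
      expect_equal(sort(Re(eq$eigenvalues)), sort(Re(lam_num)),
                   tolerance = 1e-12)
      expect_equal(sort(abs(Im(eq$eigenvalues))), sort(abs(Im(lam_num))),
                   tolerance = 1e-12)
    }
  }
})

test_that("a decreasing E-nullcline at the crossing implies stability", {
  set.seed(9)
  h <- 1e-6
  for (i in 1:30) {
    circ <- wc_circuit(w_EE = runif(1, 0.2, 3), w_EI = runif(1, 1, 3),
                       w_IE = runif(1, 1, 3), tau_E = 1, tau_I = 1)
    thE <- runif(1, 0, 1.5); thI <- runif(1, 0, 0.8)
    for (eq in find_equilibria(circ, thE, thI)) {
      slope <- (e_nullcline(min(eq$E_star + h, 1 - 1e-7), circ, thE) -
                  e_nullcline(max(eq$E_star - h, 1e-7), circ, thE)) / (2 * h)
      if (slope < -1e-6) expect_match(eq$stability, "^stable")
    }
  }
})

test_that("a single unstable equilibrium certifies a limit cycle", {
  # Poincare-Bendixson: all equilibria unstable inside the trapping region
  # forces an oscillation, visible from the origin
  circ <- default_circuit()
  set.seed(10)
  tried <- 0
  for (i in 1:40) {
    thE <- runif(1, 0, 2); thI <- runif(1, 0, 1)
    eqs <- find_equilibria(circ, thE, thI)
    if (length(eqs) == 1 && grepl("^unstable", eqs[[1]]$stability)) {
      tried <- tried + 1
      traj <- simulate_circuit(circ, thE, thI, duration = 0.64)
      expect_gt(measure_oscillation(traj)$peak_to_peak, 1e-3)
    }
  }
  expect_gt(tried, 3)  # the draw actually exercised the certificate
})

test_that("stability labels are invariant to uniform time rescaling", {
  secs <- default_circuit()
  nat <- natural_circuit()
  for (thE in c(0, 0.41, 0.7, 1.19, 1.3)) {
    a <- find_equilibria(secs, thE, 0)[[1]]
    b <- find_equilibria(nat, thE, 0)[[1]]
    expect_identical(a$stability, b$stability)
  }
})

test_that("equilibria export as JSON with [re, im] eigenvalue pairs", {
  eqs <- find_equilibria(default_circuit(), 0.7, 0)
  js <- jsonlite::fromJSON(equilibria_json(eqs), simplifyVector = FALSE)
  expect_length(js, 1)
  expect_equal(js[[1]]$stability, "unstable_focus")
  expect_length(js[[1]]$eigenvalues[[1]], 2)
  expect_equal(js[[1]]$eigenvalues[[1]][[1]], js[[1]]$eigenvalues[[2]][[1]])
  p <- tempfile(fileext = ".json")
  equilibria_json(eqs, p)
  expect_true(file.exists(p))
})
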