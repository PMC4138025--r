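test_that("trajectories converge, oscillate or persist as the drive dictates", {
  circ <- default_circuit()
  # low drive: settles to a steady state
  low <- simulate_circuit(circ, drive_E = 0.2, duration = 0.64)
  m_low <- measure_oscillation(low)
  expect_false(m_low$oscillating)
  expect_lt(m_low$peak_to_peak, 1e-3)
  # mid-window drive: sustained oscillation
  mid <- simulate_circuit(circ, drive_E = 0.7, duration = 0.64)
  expect_gt(measure_oscillation(mid)$peak_to_peak, 0.1)
  # started at the stable zero-input equilibrium, the state stays put
  eq <- find_equilibria(circ, 0, 0)[[1]]
  still <- simulate_circuit(circ, 0, 0, duration = 0.64,
                            init = c(eq$E_star, eq$I_star))
  expect_lt(max(abs(still$E - eq$E_star)), 1e-3)
  expect_lt(max(abs(still$I - eq$I_star)), 1e-3)
})

test_that("integration refuses oversized steps and short runs", {
  circ <- default_circuit()
  expect_error(simulate_circuit(circ, 0.5, duration = 0.64, dt = 0.001),
               "too large")
  expect_error(simulate_circuit(circ, 0.5, duration = 0.01), "at least")
  expect_error(simulate_circuit(circ, 0.5, duration = 0.64,
                                init = c(NA, 0)), "finite")
})

test_that("the phase square is a trapping region across drives", {
  circ <- default_circuit()
  set.seed(3)
  for (i in 1:8) {
    thE <- runif(1, 0, 2); thI <- runif(1, 0, 1)
    init <- runif(2)
    traj <- simulate_circuit(circ, thE, thI, duration = 0.4, init = init,
                             thin = 10L)
    expect_true(all(traj$E >= -1e-6 & traj$E <= 1 + 1e-6))
    expect_true(all(traj$I >= -1e-6 & traj$I <= 1 + 1e-6))
  }
  # sinusoidal drive too
  traj <- simulate_circuit(circ, drive_sinusoid(0.8, 0.6, 4), 0,
                           duration = 2, thin = 10L)
  expect_true(all(traj$E >= -1e-6 & traj$E <= 1 + 1e-6))
})

test_that("halving the step leaves the final state unchanged to 1e-6", {
  circ <- default_circuit()
  for (thE in c(0.2, 0.7, 1.3)) {
    a <- simulate_circuit(circ, thE, 0, duration = 0.4, dt = 3.2e-5)
    b <- simulate_circuit(circ, thE, 0, duration = 0.4, dt = 1.6e-5)
    expect_lt(abs(a$E[length(a$E)] - b$E[length(b$E)]), 1e-6)
  }
})

test_that("intrinsic frequency is 55 Hz in seconds and 0.176 in natural units", {
  circ <- default_circuit()
  traj <- simulate_circuit(circ, 0.5, 0, duration = 2)
  f_hz <- measure_oscillation(traj)$frequency
  expect_equal(f_hz, 55, tolerance = 1 / 55)
  nat <- simulate_circuit(natural_circuit(), 0.5, 0, duration = 600)
  f_nat <- measure_oscillation(nat)$frequency
  expect_equal(f_nat, 0.176, tolerance = 0.005 / 0.176)
  # the two conventions are a pure time rescaling
  expect_equal(f_hz * 0.0032, f_nat, tolerance = 1e-3)
})

test_that("frequency rises after onset: eigenvalue oracle agrees", {
  circ <- natural_circuit()
  fv <- frequency_vs_input(circ, c(0.41, 0.5), "theta_E", duration = 400)
  expect_true(all(fv$oscillating))
  expect_gt(fv$frequency[2], fv$frequency[1])
  # oracle: the imaginary part of the equilibrium eigenvalues orders the same
  im <- vapply(c(0.41, 0.5), function(th)
    Im(find_equilibria(circ, th, 0)[[1]]$eigenvalues[1]), numeric(1))
  expect_gt(im[2], im[1])
})

test_that("oscillation measures match the window position on both axes", {
  circ <- default_circuit()
  fvE <- frequency_vs_input(circ, c(0.2, 0.4, 0.7, 1.18), "theta_E",
                            duration = 0.64)
  expect_equal(fvE$oscillating[c(1, 3, 4)], c(FALSE, TRUE, TRUE))
  # 0.4 sits within numerical hair of the Hopf point: borderline by design
  expect_lt(fvE$peak_to_peak[1], 1e-3)
  fvI <- frequency_vs_input(circ, c(0.05, 0.12, 0.4, 0.6), "theta_I",
                            fixed_other = 1.3, duration = 0.64)
  expect_equal(fvI$oscillating[1:3], c(FALSE, TRUE, TRUE))
  expect_lt(fvI$peak_to_peak[4], 0.05)  # damped back toward stability
})

test_that("near the Hopf point the cycle frequency matches Im(lambda)/2pi", {
  circ <- natural_circuit()
  win <- window_theta_E()
  th <- win$lower + 0.01
  eq <- find_equilibria(circ, th, 0)[[1]]
  f_lin <- Im(eq$eigenvalues[1]) / (2 * pi)
  traj <- simulate_circuit(circ, th, 0, duration = 800)
  f_sim <- measure_oscillation(traj)$frequency
  expect_equal(f_sim, f_lin, tolerance = 0.05)
})

test_that("measure_oscillation validates its window and inputs", {
  circ <- default_circuit()
  traj <- simulate_circuit(circ, 0.7, 0, duration = 0.64)
  expect_error(measure_oscillation(traj, settle_fraction = 0.95), "0.25")
  m <- measure_oscillation(traj, settle_fraction = 0.25)
  expect_true(m$oscillating)
  expect_gt(m$frequency, 0)
})

test_that("trajectory CSV writer is deterministic and round-trips", {
  circ <- default_circuit()
  traj <- simulate_circuit(circ, 0.7, 0, duration = 0.4, thin = 50L)
  p1 <- tempfile(fileext = ".csv"); p2 <- tempfile(fileext = ".csv")
  write_trajectory_csv(traj, p1)
  write_trajectory_csv(simulate_circuit(circ, 0.7, 0, duration = 0.4,
                                        thin = 50L), p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  df <- read_trajectory_csv(p1)
  expect_named(df, c("t", "E", "I", "theta_E", "theta_I"))
  expect_equal(df$E, traj$E, tolerance = 1e-9)
})
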