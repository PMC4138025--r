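test_that("regime prediction implements the excursion taxonomy", {
  win <- window_theta_E()
  CR1 <- win$lower; CR2 <- win$upper
  pred <- function(m, M) predict_regime(win, drive_sinusoid((m + M) / 2,
                                                            (M - m) / 2, 4))
  expect_identical(pred(0.05, CR1 - 0.05), "subthreshold_following")
  expect_identical(pred(0.1, mean(c(CR1, CR2))), "peak_locked")
  expect_identical(pred(CR1 + 0.1, CR2 + 0.3), "trough_locked")
  expect_identical(pred(CR1 + 0.1, CR2 - 0.1), "persistent_gamma_theta_mean")
  expect_identical(pred(CR1 - 0.2, CR2 + 0.2), "biphasic")
  wI <- window_theta_I()
  expect_error(predict_regime(wI, drive_sinusoid(0.3, 0.3, 4),
                              axis = "theta_E"), "axis mismatch")
})

test_that("envelope extraction recovers tone amplitude and rejects bad bands", {
  dt <- 1e-4
  t <- seq(0, 4, by = dt)
  tone <- 0.12 * cos(2 * pi * 55 * t)
  traj <- synthetic_trajectory(tone, dt)
  env <- extract_envelope(traj, band = c(40, 100))
  # interior of the envelope is flat at the tone amplitude (5%)
  n <- length(env$envelope)
  core <- env$envelope[round(n * 0.2):round(n * 0.8)]
  expect_true(all(abs(core - 0.12) / 0.12 < 0.05))
  # constant signal: envelope collapses to ~0
  flat <- synthetic_trajectory(rep(0.3, length(t)), dt)
  expect_lt(max(extract_envelope(flat, c(40, 100))$envelope), 1e-6)
  expect_error(extract_envelope(traj, band = c(40, 1e5)), "Nyquist")
  expect_error(extract_envelope(traj, band = c(-1, 50)), "low")
})

test_that("modulation index: uniform, one-bin, and scale-invariance anchors", {
  n <- 20 * 360                       # 20 cycles, one sample per degree
  phase <- rep(seq(0, 359.9, length.out = 360), 20)
  # phase-independent envelope
  expect_lt(modulation_index(rep(1.3, n), phase), 1e-12)
  # all amplitude in a single bin of 18 -> maximal concentration
  env1 <- ifelse(phase < 20, 1, 0)
  expect_equal(as.numeric(modulation_index(env1, phase, 18)), 1)
  # scale invariance to 1e-12
  env <- 1 + cos(phase * pi / 180)
  m1 <- as.numeric(modulation_index(env, phase))
  m2 <- as.numeric(modulation_index(env * 731.4, phase))
  expect_lt(abs(m1 - m2), 1e-12)
  # empty bins are merged and flagged
  half <- phase[phase < 180]
  mi <- modulation_index(rep(1, length(half)), half)
  expect_true(attr(mi, "bins_merged"))
  expect_error(modulation_index(1:5, 1:4), "equal length")
  expect_error(modulation_index(1:5, 1:5, n_bins = 4), "at least 8")
})

test_that("figure presets land in their predicted regimes", {
  circ <- default_circuit()
  win <- window_theta_E()
  cases <- list(fig4a = "subthreshold_following", fig4b = "peak_locked",
                fig4c = "trough_locked",
                fig4d = "persistent_gamma_theta_mean", fig4e = "biphasic")
  for (nm in names(cases)) {
    d <- wc_preset(nm)$config$drive_E
    rep <- pac_analysis(circ, d, axis = "theta_E", window = win)
    expect_identical(rep$regime_predicted, cases[[nm]])
    expect_identical(rep$regime_observed, cases[[nm]])
  }
})

test_that("subthreshold output follows the drive frequency with no bursts", {
  circ <- default_circuit()
  d <- wc_preset("fig4a")$config$drive_E
  traj <- simulate_circuit(circ, d, 0, duration = 6)
  rep <- classify_observed_regime(traj, d)
  expect_identical(rep$regime_observed, "subthreshold_following")
  expect_equal(rep$n_gamma_bursts_per_theta_cycle, 0)
  # dominant output frequency equals the drive frequency
  m <- measure_oscillation(traj)
  expect_equal(m$frequency, d$frequency, tolerance = 0.2 / 4)
})

test_that("peak-locked bursts sit at the drive peak", {
  circ <- default_circuit()
  d <- wc_preset("fig4b")$config$drive_E
  traj <- simulate_circuit(circ, d, 0, duration = 6)
  rep <- classify_observed_regime(traj, d)
  # circular distance of the envelope-weighted preferred phase from 0
  dist0 <- min(rep$preferred_phase %% 360, 360 - rep$preferred_phase %% 360)
  expect_lt(dist0, 20)
  expect_gt(rep$gamma_frequency, 40)
  expect_lt(rep$gamma_frequency, 100)
})

test_that("raising w_EI weakens the gamma envelope for the same drive", {
  # a drive straddling the lower window edge: at w_EI = 2.5 the (shifted)
  # window is barely reached, so the gamma bursts shrink sharply
  d <- drive_sinusoid(0.3, 0.3, 4)
  peak_env <- vapply(c(2, 2.5), function(w) {
    traj <- simulate_circuit(wc_circuit(w_EI = w), d, 0, duration = 6)
    max(extract_envelope(traj)$envelope)
  }, numeric(1))
  expect_gt(peak_env[1], 2 * peak_env[2])
})

test_that("randomized drives respect their regime rules and mostly classify back", {
  set.seed(104)
  circ <- default_circuit()
  win <- window_theta_E()
  for (rg in c("peak_locked", "biphasic")) {
    hits <- 0
    for (i in 1:5) {
      d <- sample_regime_drive(rg, win)
      r <- drive_range(d)
      expect_identical(predict_regime(win, d), rg)
      if (rg == "biphasic") {
        expect_lt(r[1], win$lower - 0.02)
        expect_gt(r[2], win$upper + 0.02)
      }
      traj <- simulate_circuit(circ, d, 0, duration = 6)
      if (classify_observed_regime(traj, d)$regime_observed == rg)
        hits <- hits + 1
    }
    expect_gte(hits, 4)
  }
})

test_that("classification requires a sinusoid and enough slow cycles", {
  circ <- default_circuit()
  d <- drive_sinusoid(0.7, 0.2, 4)
  short <- simulate_circuit(circ, d, 0, duration = 2)  # 4 post-transient cycles
  expect_error(classify_observed_regime(short, d), "at least 10")
  const <- simulate_circuit(circ, 0.7, 0, duration = 2)
  expect_error(classify_observed_regime(const, drive_constant(0.7)),
               "sinusoidal")
})

test_that("dual-drive presets reproduce the reference behaviours", {
  # 4 Hz to E against 2 Hz to I: gamma on alternate theta cycles
  out_e <- run_preset("fig7e", out_dir = file.path(tempdir(), "wc_f7e"))
  expect_lt(out_e$pac$n_gamma_bursts_per_theta_cycle, 0.75)
  expect_gt(out_e$pac$n_gamma_bursts_per_theta_cycle, 0.25)
  # both at 4 Hz with a 30-degree offset: I prefers the ascending phase
  out_f <- run_preset("fig7f", out_dir = file.path(tempdir(), "wc_f7f"))
  expect_gt(out_f$pac$preferred_phase, 180)
  expect_identical(out_f$pac$population, "I")
})
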