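# Registry of the reference experiments. Values printed in the source
# figures are tagged "paper" in run logs; everything else (drive amplitudes
# and means for the coupling figures, durations, integration steps) is our
# documented choice and tagged "assumed".
preset_table <- function() {
  th4 <- function(mean, amp, phase = 0) drive_sinusoid(mean, amp, 4, phase)
  list(
    fig2 = list(
      desc = "phase plane at theta_E = 0.7: nullclines, unstable focus, limit cycle",
      config = experiment_config(drive_E = 0.7,
                                 analyses = c("simulate", "equilibria")),
      paper_keys = c("drive_E.mean")),
    fig3 = list(
      desc = "constant drive to E: envelope sweep and Hopf window on theta_E",
      config = experiment_config(drive_E = 0.7,
                                 analyses = c("simulate", "sweep", "hopf")),
      axis = "theta_E", fixed_other = 0,
      sweep_values = seq(0, 1.4, by = 0.01), search_interval = c(0, 1.4),
      paper_keys = c("drive_E.mean", "sweep.step")),
    fig4a = list(
      desc = "subthreshold theta drive to E: output follows the drive",
      config = experiment_config(drive_E = th4(0.2, 0.15), analyses = "pac"),
      axis = "theta_E", fixed_other = 0, search_interval = c(0, 2),
      paper_keys = character(0)),
    fig4b = list(
      desc = "theta drive straddling the lower Hopf edge: peak-locked gamma",
      config = experiment_config(drive_E = th4(0.3, 0.3), analyses = "pac"),
      axis = "theta_E", fixed_other = 0, search_interval = c(0, 2),
      paper_keys = character(0)),
    fig4c = list(
      desc = "theta drive straddling the upper Hopf edge: trough-locked gamma",
      config = experiment_config(drive_E = th4(0.95, 0.45), analyses = "pac"),
      axis = "theta_E", fixed_other = 0, search_interval = c(0, 2),
      paper_keys = character(0)),
    fig4d = list(
      desc = "theta drive inside the window: persistent gamma, theta-varying mean",
      config = experiment_config(drive_E = th4(0.8, 0.3), analyses = "pac"),
      axis = "theta_E", fixed_other = 0, search_interval = c(0, 2),
      paper_keys = character(0)),
    fig4e = list(
      desc = "theta drive across the whole window: biphasic gamma",
      config = experiment_config(drive_E = th4(0.8, 0.6), analyses = "pac"),
      axis = "theta_E", fixed_other = 0, search_interval = c(0, 2),
      paper_keys = character(0)),
    fig5 = list(
      desc = "constant drive to I at theta_E = 1.3: sweep and Hopf window on theta_I",
      config = experiment_config(drive_E = 1.3, drive_I = 0.4,
                                 analyses = c("simulate", "sweep", "hopf")),
      axis = "theta_I", fixed_other = 1.3,
      sweep_values = seq(0, 0.7, by = 0.01), search_interval = c(0, 0.7),
      paper_keys = c("drive_E.mean", "drive_I.mean", "sweep.step")),
    fig6a = list(
      desc = "subthreshold theta drive to I at theta_E = 1.3",
      config = experiment_config(drive_E = 1.3, drive_I = th4(0.05, 0.04),
                                 analyses = "pac"),
      axis = "theta_I", fixed_other = 1.3, search_interval = c(0, 1),
      paper_keys = c("drive_E.mean")),
    fig6b = list(
      desc = "theta drive to I straddling the lower Hopf edge: nested gamma",
      config = experiment_config(drive_E = 1.3, drive_I = th4(0.1, 0.1),
                                 analyses = "pac"),
      axis = "theta_I", fixed_other = 1.3, search_interval = c(0, 1),
      paper_keys = c("drive_E.mean")),
    fig6c = list(
      desc = "theta drive to I straddling the upper Hopf edge: trough/ascending gamma",
      config = experiment_config(drive_E = 1.3, drive_I = th4(0.38, 0.25),
                                 analyses = "pac"),
      axis = "theta_I", fixed_other = 1.3, search_interval = c(0, 1),
      paper_keys = c("drive_E.mean")),
    fig6d = list(
      desc = "theta drive to I inside the window: persistent gamma",
      config = experiment_config(drive_E = 1.3, drive_I = th4(0.3, 0.15),
                                 analyses = "pac"),
      axis = "theta_I", fixed_other = 1.3, search_interval = c(0, 1),
      paper_keys = c("drive_E.mean")),
    fig6e = list(
      desc = "theta drive across the whole theta_I window: biphasic gamma",
      config = experiment_config(drive_E = 1.3, drive_I = th4(0.3, 0.3),
                                 analyses = "pac"),
      axis = "theta_I", fixed_other = 1.3, search_interval = c(0, 1),
      paper_keys = c("drive_E.mean")),
    fig7a = list(
      desc = "oscillatory region over (theta_E, theta_I), default weights",
      config = experiment_config(analyses = "region"),
      region = list(theta_E_range = c(0, 2), theta_I_range = c(0, 1),
                    step = 0.01),
      paper_keys = c("region.step")),
    fig7b = list(
      desc = "oscillatory region with w_EI = 2.5: smaller than fig7a",
      config = experiment_config(params = wc_circuit(w_EI = 2.5),
                                 analyses = "region"),
      region = list(theta_E_range = c(0, 2), theta_I_range = c(0, 1),
                    step = 0.01),
      paper_keys = c("params.w_EI", "region.step")),
    fig7c = list(
      desc = "theta-gamma coupling at default weights (modulation index reference)",
      config = experiment_config(drive_E = th4(0.5, 0.45), analyses = "pac"),
      axis = "theta_E", fixed_other = 0, search_interval = c(0, 2),
      paper_keys = character(0)),
    fig7d = list(
      desc = "theta-gamma coupling with w_EI = 2.5: weaker gamma, lower MI",
      config = experiment_config(params = wc_circuit(w_EI = 2.5),
                                 drive_E = th4(0.5, 0.45), analyses = "pac"),
      axis = "theta_E", fixed_other = 0, search_interval = c(0, 2),
      window_method = "sweep", window_sweep = seq(0, 2, by = 0.01),
      paper_keys = c("params.w_EI")),
    fig7e = list(
      desc = "4 Hz drive to E with 2 Hz drive to I: gamma on alternate theta cycles",
      config = experiment_config(drive_E = th4(0.3, 0.3),
                                 drive_I = drive_sinusoid(0.2, 0.2, 2),
                                 analyses = "pac"),
      axis = "theta_E", observe_only = TRUE,
      paper_keys = c("drive_E.frequency", "drive_I.frequency")),
    fig7f = list(
      desc = "both drives at 4 Hz, theta_E lagging theta_I by 30 degrees",
      config = experiment_config(drive_E = th4(0.5, 0.35, phase = 30),
                                 drive_I = th4(0.1, 0.1),
                                 analyses = "pac"),
      axis = "theta_I", observe_only = TRUE, population = "I",
      paper_keys = c("drive_E.frequency", "drive_I.frequency",
                     "drive_E.phase_offset")))
}

#' Names of the built-in figure presets
#'
#' @return Character vector of preset names accepted by [wc_preset()] and
#'   [run_preset()].
#' @export
wc_preset_names <- function() names(preset_table())

#' Retrieve a figure preset
#'
#' @param name Preset name; see [wc_preset_names()].
#' @return A list with the preset `config` (a `wc_config`), a description,
#'   and the analysis settings.
#' @export
wc_preset <- function(name) {
  tab <- preset_table()
  if (!name %in% names(tab))
    stop(sprintf("unknown preset '%s'; valid presets: %s", name,
                 paste(names(tab), collapse = ", ")))
  tab[[name]]
}

log_config_lines <- function(preset) {
  cfg <- preset$config
  tmp <- tempfile()
  on.exit(unlink(tmp))
  write_config(cfg, tmp)
  lines <- readLines(tmp)
  keys <- sub(" =.*$", "", lines)
  always_paper <- c("params.w_EE", "params.w_EI", "params.w_IE",
                    "params.beta", "params.threshold", "params.tau_E",
                    "params.tau_I")
  tag <- ifelse(keys %in% c(always_paper, preset$paper_keys),
                "[paper]", "[assumed]")
  # w_EI = 2.5 variants: the changed weight is printed in the figure caption
  paste(lines, tag)
}

#' Run a figure preset and write its result bundle
#'
#' Executes the analyses a preset encodes (simulation, equilibrium listing,
#' envelope sweep, Hopf window, region map, coupling analysis) and writes a
#' trajectory CSV where applicable, an `analysis.json` with the numeric
#' results, and a `run.log` recording every parameter used, each tagged
#' `[paper]` (printed in the reference figure) or `[assumed]` (our
#' documented choice). Outputs are deterministic: identical configurations
#' give byte-identical files.
#'
#' @param name Preset name from [wc_preset_names()].
#' @param out_dir Output directory (created if needed).
#' @param ... Overrides forwarded to [region_map()] for the region presets
#'   (e.g. a coarser `step` for a quick look).
#' @return Named list of results, invisibly; files are the primary output.
#' @export
run_preset <- function(name, out_dir = name, ...) {
  preset <- wc_preset(name)
  cfg <- preset$config
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list(preset = name, description = preset$desc)
  analysis <- list()

  if (any(c("simulate", "pac") %in% cfg$analyses)) {
    duration <- cfg$duration
    if ("pac" %in% cfg$analyses && is.null(duration)) {
      slow <- if (cfg$drive_E$kind == "sinusoid") cfg$drive_E else cfg$drive_I
      duration <- 24 / slow$frequency
    }
    traj <- simulate_circuit(cfg$params, cfg$drive_E, cfg$drive_I,
                             duration = duration, dt = cfg$dt, thin = 4L)
    write_trajectory_csv(traj, file.path(out_dir, "trajectory.csv"))
    results$trajectory <- traj
  }
  if ("equilibria" %in% cfg$analyses) {
    eqs <- find_equilibria(cfg$params, cfg$drive_E$mean, cfg$drive_I$mean)
    analysis$equilibria <- jsonlite::fromJSON(equilibria_json(eqs),
                                              simplifyVector = FALSE)
    results$equilibria <- eqs
  }
  if ("hopf" %in% cfg$analyses) {
    win <- find_hopf_points(cfg$params, preset$axis, preset$fixed_other,
                            preset$search_interval)
    analysis$window <- unclass(win)
    results$window <- win
  }
  if ("sweep" %in% cfg$analyses) {
    sw <- sweep_envelope(cfg$params, preset$axis, preset$sweep_values,
                         preset$fixed_other,
                         settle_fraction = cfg$settle_fraction)
    utils::write.csv(sw, file.path(out_dir, "sweep.csv"), row.names = FALSE)
    analysis$sweep_window <- unclass(window_from_sweep(sw, preset$axis,
                                                       preset$fixed_other))
    results$sweep <- sw
  }
  if ("region" %in% cfg$analyses) {
    rm_args <- utils::modifyList(preset$region, list(...))
    map <- do.call(region_map, c(list(cfg$params), rm_args))
    write_region_map(map, file.path(out_dir, "region.csv"),
                     file.path(out_dir, "region.json"))
    analysis$region <- list(step = map$step,
                            oscillatory_cells = sum(map$oscillatory),
                            total_cells = length(map$oscillatory))
    results$region <- map
  }
  if ("pac" %in% cfg$analyses) {
    slow <- if (preset$axis == "theta_E") cfg$drive_E else cfg$drive_I
    win <- if (isTRUE(preset$observe_only)) {
      # both drives oscillate: no constant-input window applies, classify only
      NULL
    } else if (identical(preset$window_method, "sweep")) {
      # used where the equilibrium branch is not unique over the whole
      # search interval (e.g. w_EI = 2.5), so eigenvalue tracking refuses
      window_from_sweep(
        sweep_envelope(cfg$params, preset$axis, preset$window_sweep,
                       preset$fixed_other),
        preset$axis, preset$fixed_other)
    } else {
      find_hopf_points(cfg$params, preset$axis, preset$fixed_other,
                       preset$search_interval)
    }
    pop <- if (is.null(preset$population)) "E" else preset$population
    rep <- classify_observed_regime(results$trajectory, slow,
                                    settle_fraction = cfg$settle_fraction,
                                    population = pop)
    if (!isTRUE(preset$observe_only))
      rep$regime_predicted <- predict_regime(win, slow, preset$axis)
    rep$window <- win
    pac_report_json(rep, file.path(out_dir, "pac.json"))
    analysis$pac <- jsonlite::fromJSON(pac_report_json(rep),
                                       simplifyVector = FALSE)
    results$pac <- rep
  }

  writeLines(jsonlite::toJSON(analysis, auto_unbox = TRUE, digits = NA,
                              null = "null", pretty = TRUE),
             file.path(out_dir, "analysis.json"))
  writeLines(c(sprintf("preset = %s", name),
               sprintf("description = %s", preset$desc),
               log_config_lines(preset),
               "settle_fraction basis: fraction of run discarded [assumed]",
               "integrator: fixed-step RK4, dt = min(tau)/100 [assumed]"),
             file.path(out_dir, "run.log"))
  invisible(results)
}
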