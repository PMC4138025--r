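CONFIG_KEYS <- c(
  "params.w_EE", "params.w_EI", "params.w_IE", "params.beta",
  "params.tau_E", "params.tau_I", "params.threshold",
  "drive_E.kind", "drive_E.mean", "drive_E.amplitude", "drive_E.frequency",
  "drive_E.phase_offset",
  "drive_I.kind", "drive_I.mean", "drive_I.amplitude", "drive_I.frequency",
  "drive_I.phase_offset",
  "duration", "dt", "settle_fraction", "analyses", "out_dir", "rng_seed")

#' Experiment configuration
#'
#' Bundles a circuit, the two drives, integration settings, the analyses to
#' run and output options into a single validated record that serializes to
#' a flat `key = value` text format ([write_config()] / [read_config()]).
#' The defaults are the reference parameterization.
#'
#' @param params A [wc_circuit()].
#' @param drive_E,drive_I Drives (constants accepted).
#' @param duration Simulation length (seconds); `NULL` for the simulator
#'   default.
#' @param dt Integration step; `NULL` for the default `min(tau)/100`.
#' @param settle_fraction Transient fraction discarded by analyses.
#' @param analyses Character vector drawn from `"simulate"`, `"equilibria"`,
#'   `"sweep"`, `"hopf"`, `"region"`, `"pac"`.
#' @param out_dir Output directory for [run_preset()]-style runs.
#' @param rng_seed Optional integer seed recorded for randomized test
#'   batteries; the simulator itself is deterministic.
#' @return A `wc_config`.
#' @export
experiment_config <- function(params = wc_circuit(),
                              drive_E = drive_constant(0),
                              drive_I = drive_constant(0),
                              duration = NULL, dt = NULL,
                              settle_fraction = 0.5,
                              analyses = "simulate",
                              out_dir = ".", rng_seed = NULL) {
  stopifnot(inherits(params, "wc_circuit"))
  drive_E <- as_drive(drive_E); drive_I <- as_drive(drive_I)
  ok <- c("simulate", "equilibria", "sweep", "hopf", "region", "pac")
  bad <- setdiff(analyses, ok)
  if (length(bad))
    stop(sprintf("unknown analyses: %s (valid: %s)",
                 paste(bad, collapse = ", "), paste(ok, collapse = ", ")))
  if (!is.null(duration) && duration <= 0) stop("'duration' must be positive")
  if (!is.null(dt) && dt <= 0) stop("'dt' must be positive")
  if (settle_fraction < 0.25 || settle_fraction > 0.9)
    stop("'settle_fraction' must lie in [0.25, 0.9]")
  if (!is.null(rng_seed)) rng_seed <- as.integer(rng_seed)
  structure(list(params = params, drive_E = drive_E, drive_I = drive_I,
                 duration = duration, dt = dt,
                 settle_fraction = settle_fraction, analyses = analyses,
                 out_dir = out_dir, rng_seed = rng_seed),
            class = "wc_config")
}

fmt_num <- function(x) trimws(formatC(x, format = "g", digits = 15))

#' Write or read a configuration as a flat key-value document
#'
#' One `key = value` pair per line in a fixed canonical order and number
#' format, so that write -> read -> write round-trips byte-identically.
#' Unset optional values (`duration`, `dt`, `rng_seed`) are omitted.
#'
#' @param config A `wc_config`.
#' @param path File path.
#' @return `path` invisibly (writer); a `wc_config` (reader).
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "wc_config"))
  p <- config$params
  lines <- c(
    paste("params.w_EE =", fmt_num(p$w_EE)),
    paste("params.w_EI =", fmt_num(p$w_EI)),
    paste("params.w_IE =", fmt_num(p$w_IE)),
    paste("params.beta =", fmt_num(p$beta)),
    paste("params.tau_E =", fmt_num(p$tau_E)),
    paste("params.tau_I =", fmt_num(p$tau_I)),
    paste("params.threshold =", fmt_num(p$threshold)))
  for (nm in c("drive_E", "drive_I")) {
    d <- config[[nm]]
    lines <- c(lines,
               paste0(nm, ".kind = ", d$kind),
               paste0(nm, ".mean = ", fmt_num(d$mean)),
               paste0(nm, ".amplitude = ", fmt_num(d$amplitude)),
               paste0(nm, ".frequency = ", fmt_num(d$frequency)),
               paste0(nm, ".phase_offset = ", fmt_num(d$phase_offset)))
  }
  if (!is.null(config$duration))
    lines <- c(lines, paste("duration =", fmt_num(config$duration)))
  if (!is.null(config$dt))
    lines <- c(lines, paste("dt =", fmt_num(config$dt)))
  lines <- c(lines,
             paste("settle_fraction =", fmt_num(config$settle_fraction)),
             paste("analyses =", paste(config$analyses, collapse = ",")),
             paste("out_dir =", config$out_dir))
  if (!is.null(config$rng_seed))
    lines <- c(lines, paste("rng_seed =", config$rng_seed))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  validate_config(path)
}

#' Parse and validate a configuration file
#'
#' Rejects unknown keys and invariant violations with diagnostics naming
#' the offending line and field.
#'
#' @param path Path to a flat key-value configuration.
#' @return A validated `wc_config`.
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  raw <- readLines(path, warn = FALSE)
  kv <- list()
  for (i in seq_along(raw)) {
    line <- trimws(raw[i])
    if (line == "" || startsWith(line, "#")) next
    m <- regmatches(line, regexec("^([A-Za-z_][A-Za-z0-9_.]*)\\s*=\\s*(.*)$",
                                  line))[[1]]
    if (length(m) != 3)
      stop(sprintf("line %d: expected 'key = value', got: %s", i, raw[i]))
    key <- m[2]
    if (!key %in% CONFIG_KEYS)
      stop(sprintf("line %d: unknown key '%s'", i, key))
    if (!is.null(kv[[key]]))
      stop(sprintf("line %d: duplicate key '%s'", i, key))
    kv[[key]] <- trimws(m[3])
  }
  num <- function(key, default = NULL) {
    if (is.null(kv[[key]])) return(default)
    v <- suppressWarnings(as.numeric(kv[[key]]))
    if (is.na(v)) stop(sprintf("field '%s': not a number: %s", key, kv[[key]]))
    v
  }
  mk_drive <- function(prefix) {
    kind <- kv[[paste0(prefix, ".kind")]]
    if (is.null(kind)) kind <- "constant"
    if (!kind %in% c("constant", "sinusoid"))
      stop(sprintf("field '%s.kind': must be constant or sinusoid", prefix))
    if (kind == "constant")
      drive_constant(num(paste0(prefix, ".mean"), 0))
    else
      drive_sinusoid(num(paste0(prefix, ".mean"), 0),
                     num(paste0(prefix, ".amplitude"), 0),
                     num(paste0(prefix, ".frequency"), NA_real_),
                     num(paste0(prefix, ".phase_offset"), 0))
  }
  params <- wc_circuit(
    w_EE = num("params.w_EE", 2.4), w_EI = num("params.w_EI", 2),
    w_IE = num("params.w_IE", 2), beta = num("params.beta", 4),
    tau_E = num("params.tau_E", 0.0032), tau_I = num("params.tau_I", 0.0032),
    threshold = num("params.threshold", 1))
  analyses <- if (is.null(kv[["analyses"]])) "simulate"
              else strsplit(kv[["analyses"]], ",\\s*")[[1]]
  experiment_config(
    params = params, drive_E = mk_drive("drive_E"),
    drive_I = mk_drive("drive_I"),
    duration = num("duration"), dt = num("dt"),
    settle_fraction = num("settle_fraction", 0.5),
    analyses = analyses,
    out_dir = if (is.null(kv[["out_dir"]])) "." else kv[["out_dir"]],
    rng_seed = if (is.null(kv[["rng_seed"]])) NULL else num("rng_seed"))
}

#' @export
print.wc_config <- function(x, ...) {
  cat("experiment configuration\n")
  print(x$params)
  cat("drive_E: "); print(x$drive_E)
  cat("drive_I: "); print(x$drive_I)
  cat(sprintf("analyses: %s\n", paste(x$analyses, collapse = ", ")))
  invisible(x)
}
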