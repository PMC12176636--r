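#' Load model parameters from a JSON configuration file
#'
#' Reads a flat JSON object with keys among `chi_w`, `chi_s`, `mu_w`,
#' `mu_s`, `H0_plus`, `H0_minus`, `a`, `T_f`, `waveform`. Omitted `mu_w`,
#' `mu_s`, `T_f` and `waveform` default to 1, 0, 24 and `"cosine"` (the
#' scaled form used throughout the literature); the remaining five keys are
#' required. Unknown keys and ordering violations raise descriptive
#' configuration errors.
#'
#' @param path Path to a JSON file.
#' @return A [two_process_params()] object.
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    tpm_stop("tpm_config_error", sprintf("config file not found: %s", path))
  cfg <- tryCatch(jsonlite::fromJSON(path),
                  error = function(e)
                    tpm_stop("tpm_config_error",
                             sprintf("cannot parse %s as JSON: %s", path,
                                     conditionMessage(e))))
  if (!is.list(cfg) || is.null(names(cfg)) || !length(cfg))
    tpm_stop("tpm_config_error", "config must be a non-empty JSON object")
  known <- c("chi_w", "chi_s", "mu_w", "mu_s", "H0_plus", "H0_minus",
             "a", "T_f", "waveform")
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    tpm_stop("tpm_config_error",
             sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")))
  required <- c("chi_w", "chi_s", "H0_plus", "H0_minus", "a")
  miss <- setdiff(required, names(cfg))
  if (length(miss))
    tpm_stop("tpm_config_error",
             sprintf("missing required key(s): %s", paste(miss, collapse = ", ")))
  defaults <- list(mu_w = 1, mu_s = 0, T_f = 24, waveform = "cosine")
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  do.call(two_process_params, cfg)
}

#' Write model parameters to a JSON configuration file
#'
#' Inverse of [load_config()]: round-tripping reproduces an identical
#' parameter set. Function waveforms cannot be serialised.
#'
#' @param p A [two_process_params()] object.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_config <- function(p, path) {
  stopifnot(inherits(p, "two_process_params"))
  if (is.function(p$waveform))
    tpm_stop("tpm_config_error", "cannot serialise a function waveform to JSON")
  x <- unclass(p)[c("chi_w", "chi_s", "mu_w", "mu_s", "H0_plus", "H0_minus",
                    "a", "T_f", "waveform")]
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Canonical parameter sets from the literature
#'
#' Named parameter sets reproducing the published example regimes of the
#' two-process model:
#' \describe{
#'   \item{`fig1b`}{standard human monophasic regime: `chi_s` = 4.2 h,
#'     `chi_w` = 18.2 h, thresholds 0.67/0.17, `a` = 0.12 (one sleep per
#'     day).}
#'   \item{`fig1c`}{thresholds 0.75/0.09, `a` = 0.07: three sleeps every
#'     four days.}
#'   \item{`fig1d`}{thresholds 0.75/0.50, `a` = 0.07: three sleeps every
#'     two days.}
#'   \item{`fig1e`}{thresholds 0.75/0.58, `a` = 0.07: polyphasic, two
#'     sleeps per day.}
#'   \item{`fig6a`}{standard constants with zero circadian amplitude (the
#'     unforced 22.6 h relaxation oscillator).}
#'   \item{`fig7_base`}{standard constants at the `a` = 0.08 slice used for
#'     tongue cross-sections.}
#'   \item{`fig8_base`}{standard constants at `a` = 0.12, the Devil's
#'     staircase amplitude.}
#'   \item{`mouse`}{murine homeostatic time constants `chi_w` = 8.3 h,
#'     `chi_s` = 1.7 h with otherwise standard scaled parameters.}
#' }
#'
#' @param name One of the fixture names above.
#' @return A [two_process_params()] object.
#' @export
two_process_fixture <- function(name) {
  sets <- list(
    fig1b = list(chi_s = 4.2, chi_w = 18.2, H0_plus = 0.67, H0_minus = 0.17,
                 a = 0.12),
    fig1c = list(chi_s = 4.2, chi_w = 18.2, H0_plus = 0.75, H0_minus = 0.09,
                 a = 0.07),
    fig1d = list(chi_s = 4.2, chi_w = 18.2, H0_plus = 0.75, H0_minus = 0.50,
                 a = 0.07),
    fig1e = list(chi_s = 4.2, chi_w = 18.2, H0_plus = 0.75, H0_minus = 0.58,
                 a = 0.07),
    fig6a = list(chi_s = 4.2, chi_w = 18.2, H0_plus = 0.67, H0_minus = 0.17,
                 a = 0),
    fig7_base = list(chi_s = 4.2, chi_w = 18.2, H0_plus = 0.67,
                     H0_minus = 0.17, a = 0.08),
    fig8_base = list(chi_s = 4.2, chi_w = 18.2, H0_plus = 0.67,
                     H0_minus = 0.17, a = 0.12),
    mouse = list(chi_s = 1.7, chi_w = 8.3, H0_plus = 0.67, H0_minus = 0.17,
                 a = 0.12))
  if (!is.character(name) || length(name) != 1L || !name %in% names(sets))
    tpm_stop("tpm_config_error",
             sprintf("unknown fixture '%s'; available: %s",
                     as.character(name)[1],
                     paste(names(sets), collapse = ", ")))
  do.call(two_process_params, sets[[name]])
}

provenance_header <- function(p, what) {
  sprintf(paste0("# twoprocess %s %s; chi_s=%g chi_w=%g H0_plus=%g ",
                 "H0_minus=%g a=%g mu_w=%g mu_s=%g T_f=%g waveform=%s"),
          as.character(utils::packageVersion("twoprocess")), what,
          p$chi_s, p$chi_w, p$H0_plus, p$H0_minus, p$a, p$mu_w, p$mu_s,
          p$T_f, if (is.function(p$waveform)) "custom" else p$waveform)
}

#' Write and read episode logs as CSV
#'
#' Episode CSV has a `#`-prefixed provenance header (parameter echo and
#' package version) followed by the columns
#' `kind,t_start_h,t_end_h,duration_h,phase_start,phase_end` at 6 decimal
#' places. `read_episodes_csv()` restores the episode data frame.
#'
#' @param result A `sim_result`.
#' @param path File path.
#' @return The path (writer) or an episode data frame (reader).
#' @export
write_episodes_csv <- function(result, path) {
  stopifnot(inherits(result, "sim_result"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(result$params, "episodes"), con)
  writeLines("kind,t_start_h,t_end_h,duration_h,phase_start,phase_end", con)
  e <- result$episodes
  writeLines(sprintf("%s,%.6f,%.6f,%.6f,%.6f,%.6f", e$kind, e$t_start,
                     e$t_end, e$duration, e$phase_start, e$phase_end), con)
  invisible(path)
}

#' @rdname write_episodes_csv
#' @export
read_episodes_csv <- function(path) {
  e <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  names(e) <- c("kind", "t_start", "t_end", "duration", "phase_start",
                "phase_end")
  e
}

#' Write a sampled trajectory as CSV
#'
#' Columns `t_h,H,upper,lower`, with the same provenance header as
#' [write_episodes_csv()]. Requires a `sim_result` produced with
#' `sample_step`.
#'
#' @inheritParams write_episodes_csv
#' @export
write_trajectory_csv <- function(result, path) {
  stopifnot(inherits(result, "sim_result"))
  if (is.null(result$samples))
    tpm_stop("tpm_config_error",
             "no sampled trajectory: rerun simulate_sleep_wake() with sample_step")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(result$params, "trajectory"), con)
  writeLines("t_h,H,upper,lower", con)
  s <- result$samples
  writeLines(sprintf("%.6f,%.6f,%.6f,%.6f", s$t, s$H, s$upper, s$lower), con)
  invisible(path)
}
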