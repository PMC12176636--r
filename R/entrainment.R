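#' One step of the first-return (circle) map
#'
#' The two-process dynamics reduce to a map of the circle: each hit of the
#' upper threshold (a sleep onset) determines the next one. Starting from
#' an upper-threshold hit at circadian phase `phase` (fraction of `T_f`
#' since the circadian maximum), exactly one sleep and one wake segment are
#' simulated; the map returns the phase of the next upper-threshold hit and
#' the lift increment `advance` (elapsed time in forcing periods). At zero
#' amplitude the map is the rigid rotation by `T_nat / T_f`.
#'
#' @param phase Circadian phase in `[0, 1)` of an upper-threshold hit.
#' @param p A [two_process_params()] object.
#' @inheritParams find_next_switch
#' @return List with `next_phase` in `[0, 1)`, `advance` (>= 0,
#'   dimensionless) and `status` (`"OK"` or `"NONTERMINATING"`).
#' @export
circle_map_step <- function(phase, p, step = p$T_f / 2048, tol = 1e-9,
                            dwell = 1e-6) {
  stopifnot(inherits(p, "two_process_params"),
            phase >= 0, phase < 1)
  lift <- circle_lift(p, phase, 1L, step, tol, dwell)
  if (lift$status != "OK")
    return(list(next_phase = NA_real_, advance = NA_real_,
                status = lift$status))
  t2 <- lift$hits[1L]
  list(next_phase = (t2 / p$T_f) %% 1,
       advance = (t2 - phase * p$T_f) / p$T_f,
       status = "OK")
}

# shared driver: successive upper-threshold hit times from phase0
circle_lift <- function(p, phase0, n_steps, step, tol, dwell) {
  if (is.function(p$waveform)) {
    t <- phase0 * p$T_f
    H <- threshold_upper(t, p)
    hits <- numeric(n_steps); status <- "OK"; done <- 0L
    for (k in seq_len(n_steps)) {
      r1 <- next_crossing_r(t, H, FALSE, p, step, tol, dwell, t + 1e4 * p$T_f)
      if (!is.finite(r1$t)) { status <- if (is.nan(r1$t)) "NONTERMINATING" else "UNRESOLVED"; break }
      H1 <- if (isTRUE(r1$immediate)) H else sleep_pressure(r1$t - t, H, p)
      r2 <- next_crossing_r(r1$t, H1, TRUE, p, step, tol, dwell, r1$t + 1e4 * p$T_f)
      if (!is.finite(r2$t)) { status <- if (is.nan(r2$t)) "NONTERMINATING" else "UNRESOLVED"; break }
      H <- if (isTRUE(r2$immediate)) H1 else wake_pressure(r2$t - r1$t, H1, p)
      t <- r2$t; hits[k] <- t; done <- k
    }
    list(hits = hits, n_done = done, status = status)
  } else {
    cpp_circle_lift(unclass(p), phase0, as.integer(n_steps), step, tol, dwell)
  }
}

#' Rotation number of the sleep-wake oscillation
#'
#' Average number of sleep onsets per forcing period, computed from the
#' circle-map lift: after `transient_iter` discarded iterations the mean
#' lift increment over `n_iter` iterations is formed and its reciprocal
#' returned. Onset-to-onset accumulation avoids the aliasing that
#' day-boundary bin counting suffers near tongue edges.
#'
#' @param p A [two_process_params()] object.
#' @param n_iter Number of averaged map iterations (>= 100).
#' @param transient_iter Discarded initial iterations.
#' @param phase0 Starting phase in `[0, 1)`.
#' @inheritParams find_next_switch
#' @return The rotation number (sleeps per forcing period).
#' @export
rotation_number <- function(p, n_iter = 400, transient_iter = 100,
                            phase0 = 0, step = p$T_f / 2048, tol = 1e-9,
                            dwell = 1e-6) {
  stopifnot(inherits(p, "two_process_params"), n_iter >= 100,
            transient_iter >= 0)
  total <- as.integer(n_iter + transient_iter)
  lift <- circle_lift(p, phase0, total, step, tol, dwell)
  if (lift$status != "OK")
    tpm_stop("tpm_nonterminating",
             sprintf("circle map iteration failed: %s", lift$status))
  t_a <- if (transient_iter > 0) lift$hits[transient_iter] else phase0 * p$T_f
  t_b <- lift$hits[total]
  n_iter / ((t_b - t_a) / p$T_f)
}

#' Classify a rotation number as rational locking or quasiperiodicity
#'
#' Finds the minimal-denominator fraction `n/m` with `m <= q_max` lying
#' within `tol` of `rho`, via the Stern-Brocot (mediant bisection) search
#' for the simplest rational in the interval `[rho - tol, rho + tol]` --
#' the same best-approximation structure as the continued-fraction
#' convergents of `rho`. If the simplest such fraction needs a denominator
#' above `q_max` the dynamics are classified quasiperiodic.
#'
#' @param rho Rotation number (finite, >= 0).
#' @param q_max Largest admissible denominator.
#' @param tol Locking tolerance on `|rho - n/m|`.
#' @return An object of class `entrainment_class`: list with `rho`, `n`,
#'   `m` (coprime integers, or `NA`) and `status` (`"RATIONAL"` or
#'   `"QUASIPERIODIC"`).
#' @export
classify_rotation <- function(rho, q_max = 12, tol = 1e-3) {
  if (!is.numeric(rho) || length(rho) != 1L || !is.finite(rho) || rho < 0)
    tpm_stop("tpm_domain_error", "rho must be a finite scalar >= 0")
  f <- simplest_fraction(max(0, rho - tol), rho + tol)
  if (f[2L] <= q_max)
    structure(list(rho = rho, n = f[1L], m = f[2L], status = "RATIONAL"),
              class = "entrainment_class")
  else
    structure(list(rho = rho, n = NA_integer_, m = NA_integer_,
                   status = "QUASIPERIODIC"),
              class = "entrainment_class")
}

#' @export
print.entrainment_class <- function(x, ...) {
  if (x$status == "RATIONAL")
    cat(sprintf("rho = %.6f: %d:%d locking (%d sleeps per %d forcing periods)\n",
                x$rho, x$n, x$m, x$n, x$m))
  else
    cat(sprintf("rho = %.6f: %s\n", x$rho, x$status))
  invisible(x)
}

# simplest (minimal-denominator) fraction n/m with lo <= n/m <= hi;
# Stern-Brocot descent, assumes 0 <= lo <= hi
simplest_fraction <- function(lo, hi) {
  i <- ceiling(lo)
  if (i <= hi) return(c(as.integer(i), 1L))
  fl <- floor(lo)
  r <- simplest_fraction(1 / (hi - fl), 1 / (lo - fl))
  c(as.integer(fl * r[1L] + r[2L]), r[1L])
}

#' Empirical sleeps per forcing period from a simulation
#'
#' Counts sleep onsets in the retained window of a [simulate_sleep_wake()]
#' result and divides by the elapsed number of forcing periods. A
#' cross-check for [rotation_number()]; agreement within `1/50` is expected
#' on records spanning at least 50 forcing periods (a warning is issued on
#' shorter records).
#'
#' @param result A `sim_result`.
#' @return Sleeps per forcing period; 0 with attribute `status =
#'   "NONTERMINATING"` when the simulation flagged a non-terminating state.
#' @export
sleeps_per_day <- function(result) {
  stopifnot(inherits(result, "sim_result"))
  span <- (result$horizon - result$transient_discarded) / result$params$T_f
  if (span < 50)
    warning(sprintf("record spans only %.1f forcing periods; rotation estimate is coarse", span),
            call. = FALSE)
  rho <- length(result$onsets) / span
  if (result$status == "NONTERMINATING") attr(rho, "status") <- "NONTERMINATING"
  rho
}

#' Arnold tongue scan over a parameter and the circadian amplitude
#'
#' Computes the rotation number over a grid: one axis sweeps a model
#' parameter that moves the natural period (`H0_plus`, `H0_minus`,
#' `chi_s`, `chi_w` or `mu_w`), the other sweeps the circadian amplitude.
#' Regions of rational rotation number form the Arnold tongues, with the
#' `(n, m)` tongue tip at zero amplitude where `T_nat = (m/n) * T_f`. Each
#' swept value is annotated with its analytic natural period (the dual
#' horizontal axes of the tongue diagram). Cells whose parameters are
#' invalid or whose dynamics do not terminate are marked in the status
#' matrix, never silently interpolated.
#'
#' @param sweep_param Name of the swept parameter.
#' @param sweep_values Numeric vector of swept values.
#' @param amplitudes Numeric vector of circadian amplitudes.
#' @param base A [two_process_params()] object supplying the remaining
#'   parameters.
#' @param n_iter,transient_iter Passed to [rotation_number()].
#' @inheritParams find_next_switch
#' @return An object of class `tongue_grid`: list with `sweep_param`,
#'   `sweep_values`, `T_nat` (analytic, per swept value), `amplitudes`,
#'   `rho` (matrix, amplitudes x values) and `status` (matrix of `"OK"`,
#'   `"INVALID"` or `"UNRESOLVED"`).
#' @export
tongue_scan <- function(sweep_param = c("H0_plus", "H0_minus", "chi_s",
                                        "chi_w", "mu_w"),
                        sweep_values, amplitudes, base,
                        n_iter = 400, transient_iter = 100,
                        step = base$T_f / 2048, tol = 1e-9, dwell = 1e-6) {
  sweep_param <- match.arg(sweep_param)
  stopifnot(inherits(base, "two_process_params"),
            is.numeric(sweep_values), is.numeric(amplitudes))
  nv <- length(sweep_values); na <- length(amplitudes)
  rho <- matrix(NA_real_, na, nv)
  status <- matrix("OK", na, nv)
  T_nat <- rep(NA_real_, nv)
  for (j in seq_len(nv)) {
    args <- unclass(base)[c("chi_s", "chi_w", "H0_plus", "H0_minus", "a",
                            "mu_w", "mu_s", "T_f", "waveform")]
    args[[sweep_param]] <- sweep_values[j]
    for (i in seq_len(na)) {
      args$a <- amplitudes[i]
      pj <- tryCatch(do.call(two_process_params, args), tpm_error = function(e) NULL)
      if (is.null(pj) || !pj$ordering_ok) {
        status[i, j] <- "INVALID"
        next
      }
      if (i == 1L && is.na(T_nat[j]))
        T_nat[j] <- natural_periods(pj)$T_nat
      r <- tryCatch(rotation_number(pj, n_iter, transient_iter,
                                    step = step, tol = tol, dwell = dwell),
                    tpm_error = function(e) NA_real_)
      if (is.na(r)) status[i, j] <- "UNRESOLVED" else rho[i, j] <- r
    }
    if (is.na(T_nat[j])) {   # amplitude row 1 may have been invalid
      args$a <- 0
      pj <- tryCatch(do.call(two_process_params, args), tpm_error = function(e) NULL)
      if (!is.null(pj) && pj$ordering_ok) T_nat[j] <- natural_periods(pj)$T_nat
    }
  }
  if (any(status == "INVALID"))
    warning(sprintf("%d grid cells had invalid parameters and were skipped",
                    sum(status == "INVALID")), call. = FALSE)
  structure(list(sweep_param = sweep_param, sweep_values = sweep_values,
                 T_nat = T_nat, amplitudes = amplitudes,
                 rho = rho, status = status),
            class = "tongue_grid")
}

#' Devil's staircase: rotation number along an upper-threshold sweep
#'
#' At fixed circadian amplitude, sweeps the mean upper threshold (which
#' moves the natural period) and records the rotation number for each
#' value. Plotted against `T_nat` the rotation number forms the
#' plateau-rich Devil's staircase: each plateau is a rational locking
#' `n/m`, and the staircase is monotone non-increasing because larger
#' natural periods give fewer sleeps per forcing period.
#'
#' @param H0_plus_values Ascending vector of mean upper-threshold values.
#' @param base A [two_process_params()] object (its `a` is the fixed
#'   amplitude).
#' @param q_max,class_tol Passed to [classify_rotation()] for the plateau
#'   labels.
#' @inheritParams tongue_scan
#' @return A data frame with columns `H0_plus`, `T_nat`, `rho`, `n`, `m`,
#'   `status`.
#' @export
devils_staircase <- function(H0_plus_values, base,
                             n_iter = 400, transient_iter = 100,
                             q_max = 12, class_tol = 1e-3,
                             step = base$T_f / 2048, tol = 1e-9,
                             dwell = 1e-6) {
  stopifnot(inherits(base, "two_process_params"),
            !is.unsorted(H0_plus_values))
  g <- tongue_scan("H0_plus", H0_plus_values, base$a, base,
                   n_iter = n_iter, transient_iter = transient_iter,
                   step = step, tol = tol, dwell = dwell)
  out <- data.frame(H0_plus = H0_plus_values, T_nat = g$T_nat,
                    rho = g$rho[1L, ], n = NA_integer_, m = NA_integer_,
                    status = g$status[1L, ], stringsAsFactors = FALSE)
  for (k in seq_len(nrow(out))) {
    if (out$status[k] != "OK") next
    cl <- classify_rotation(out$rho[k], q_max = q_max, tol = class_tol)
    out$status[k] <- cl$status
    if (cl$status == "RATIONAL") { out$n[k] <- cl$n; out$m[k] <- cl$m }
  }
  out
}

#' Export a tongue grid or staircase to long-format CSV
#'
#' @param grid A `tongue_grid` from [tongue_scan()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_tongue_csv <- function(grid, path) {
  stopifnot(inherits(grid, "tongue_grid"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# twoprocess %s tongue scan; sweep=%s",
                     as.character(utils::packageVersion("twoprocess")),
                     grid$sweep_param), con)
  writeLines("sweep_param,sweep_value,T_nat_h,amplitude,rho,status", con)
  for (j in seq_along(grid$sweep_values))
    for (i in seq_along(grid$amplitudes))
      writeLines(sprintf("%s,%.6f,%.6f,%.6f,%s,%s",
                         grid$sweep_param, grid$sweep_values[j],
                         grid$T_nat[j], grid$amplitudes[i],
                         ifelse(is.na(grid$rho[i, j]), "NA",
                                sprintf("%.6f", grid$rho[i, j])),
                         grid$status[i, j]), con)
  invisible(path)
}
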