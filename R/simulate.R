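#' Vigilance state of the hybrid system
#'
#' A labelled point of the hybrid dynamics: the current vigilance state
#' (`"WAKE"` or `"SLEEP"`), the current time and the current homeostatic
#' pressure. The label determines which closed form governs the pressure
#' and which threshold is active (the upper threshold during wake, the
#' lower during sleep).
#'
#' @param label `"WAKE"` or `"SLEEP"`.
#' @param t Time, hours.
#' @param H Homeostatic pressure (finite).
#' @return An object of class `vigilance_state`.
#' @export
vigilance_state <- function(label = c("WAKE", "SLEEP"), t = 0, H = 0.5) {
  label <- match.arg(label)
  stopifnot(is.finite(t), is.finite(H))
  structure(list(label = label, t = as.numeric(t), H = as.numeric(H)),
            class = "vigilance_state")
}

# Pure-R crossing finder for arbitrary (pluggable) waveforms; mirrors the
# C++ routine for the cosine case and is cross-checked against it in the
# tests.  Waveform range within [-1, 1] is part of the pluggable contract,
# so the same analytic scan windows apply.
next_crossing_r <- function(t0, H0, wake, p, step, tol, dwell, t_max) {
  base <- if (wake) p$H0_plus else p$H0_minus
  thr <- function(t) base + p$a * circadian_waveform(t, p)
  pres <- function(t) {
    if (wake) p$mu_w + (H0 - p$mu_w) * exp(-(t - t0) / p$chi_w)
    else p$mu_s + (H0 - p$mu_s) * exp(-(t - t0) / p$chi_s)
  }
  crossed <- if (wake) function(g) g >= 0 else function(g) g <= 0
  tmax <- t_max - t0

  if (p$a == 0) {
    if (wake) {
      if (H0 >= base) return(list(t = t0 + dwell, immediate = TRUE))
      if (p$mu_w <= base) return(list(t = NaN, immediate = FALSE))
      dt <- p$chi_w * log((p$mu_w - H0) / (p$mu_w - base))
    } else {
      if (H0 <= base) return(list(t = t0 + dwell, immediate = TRUE))
      if (p$mu_s >= base) return(list(t = NaN, immediate = FALSE))
      dt <- p$chi_s * log((H0 - p$mu_s) / (base - p$mu_s))
    }
    return(list(t = if (dt <= tmax) t0 + dt else Inf, immediate = FALSE))
  }

  thrMin <- base - p$a; thrMax <- base + p$a
  if (crossed(pres(t0 + dwell) - thr(t0 + dwell)))
    return(list(t = t0 + dwell, immediate = TRUE))
  lo <- dwell
  if (wake) {
    if (p$mu_w <= thrMin) return(list(t = NaN, immediate = FALSE))
    if (H0 < thrMin)
      lo <- max(dwell, p$chi_w * log((p$mu_w - H0) / (p$mu_w - thrMin)))
    hi <- if (p$mu_w > thrMax)
      p$chi_w * log((p$mu_w - H0) / (p$mu_w - thrMax))
    else p$chi_w * log((p$mu_w - H0) / (p$mu_w - (p$mu_w + thrMin) / 2)) + p$T_f
  } else {
    if (p$mu_s >= thrMax) return(list(t = NaN, immediate = FALSE))
    if (H0 > thrMax)
      lo <- max(dwell, p$chi_s * log((H0 - p$mu_s) / (thrMax - p$mu_s)))
    hi <- if (p$mu_s < thrMin)
      p$chi_s * log((H0 - p$mu_s) / (thrMin - p$mu_s))
    else p$chi_s * log((H0 - p$mu_s) / ((p$mu_s + thrMax) / 2 - p$mu_s)) + p$T_f
  }
  hi <- min(hi + step, tmax)
  if (lo >= hi) return(list(t = Inf, immediate = FALSE))

  grid <- seq(t0 + lo, t0 + hi, by = step)
  if (grid[length(grid)] < t0 + hi) grid <- c(grid, t0 + hi)
  g <- pres(grid) - thr(grid)
  hit <- if (wake) which(g >= 0) else which(g <= 0)
  if (!length(hit)) return(list(t = Inf, immediate = FALSE))
  i <- hit[1L]
  ta <- if (i == 1L) t0 + dwell else grid[i - 1L]
  tb <- grid[i]
  while (tb - ta > tol) {
    tm <- (ta + tb) / 2
    if (crossed(pres(tm) - thr(tm))) tb <- tm else ta <- tm
  }
  list(t = (ta + tb) / 2, immediate = FALSE)
}

#' Time of the next threshold crossing
#'
#' From a [vigilance_state()], locates the first time at which the
#' homeostatic pressure meets the active threshold (upper during wake,
#' lower during sleep). At zero circadian amplitude the crossing is the
#' exact closed-form logarithm; otherwise the residual is bracketed on a
#' uniform scan grid (default step `T_f/2048`) and refined by bisection to
#' `tol` hours.
#'
#' @param state A [vigilance_state()].
#' @param p A [two_process_params()] object.
#' @param t_max Give up after this absolute time (hours).
#' @param step Scan grid step, hours.
#' @param tol Bisection tolerance on the crossing time, hours.
#' @param dwell Minimum dwell after a switch before a new crossing is
#'   accepted, hours.
#' @return A list with `t` (crossing time in hours, or `NA`), `status`
#'   (`"OK"`, `"NONE"` if no crossing before `t_max`, `"NONTERMINATING"` if
#'   none can ever occur) and `immediate` (`TRUE` when the state already
#'   lies on the crossing side and re-switches after the dwell guard).
#' @export
find_next_switch <- function(state, p, t_max = state$t + 20 * p$T_f,
                             step = p$T_f / 2048, tol = 1e-9, dwell = 1e-6) {
  stopifnot(inherits(state, "vigilance_state"), inherits(p, "two_process_params"))
  wake <- state$label == "WAKE"
  if (is.function(p$waveform)) {
    r <- next_crossing_r(state$t, state$H, wake, p, step, tol, dwell, t_max)
  } else {
    r <- cpp_next_crossing(unclass(p), state$t, state$H, wake, t_max,
                           step, tol, dwell)
  }
  tc <- r$t
  if (is.nan(tc)) list(t = NA_real_, status = "NONTERMINATING", immediate = FALSE)
  else if (!is.finite(tc)) list(t = NA_real_, status = "NONE", immediate = FALSE)
  else list(t = tc, status = "OK", immediate = isTRUE(r$immediate))
}

#' Simulate the two-process model
#'
#' Event-driven simulation of the hybrid dynamics: within each vigilance
#' state the pressure follows its exact exponential closed form and the
#' state switches at the first crossing of the active circadian-modulated
#' threshold. There is no numerical ODE integration anywhere; accuracy is
#' set by the crossing tolerance `tol`.
#'
#' The default initial condition is wake at `t = 0` with pressure midway
#' between the mean thresholds; the default transient of `50 * T_f` hours
#' is discarded (episodes are clipped to `[transient, horizon]`) so that
#' classification of the attractor is insensitive to the initial state at
#' small circadian amplitude. At high amplitude more than one attractor may
#' coexist; pass `init` to explore dependence on the initial state.
#'
#' @inheritParams find_next_switch
#' @param horizon Total simulated time, hours (`> transient`).
#' @param init Optional [vigilance_state()] initial condition.
#' @param transient Hours discarded from the start of the record.
#' @param sample_step If non-`NULL`, also return the trajectory sampled on
#'   a uniform grid of this step (hours) over `[transient, horizon]`.
#' @param on_nonterminating `"error"` to raise a classed error when the
#'   pressure can never reach the active threshold, `"flag"` to return the
#'   partial result with `status = "NONTERMINATING"` instead.
#' @return An object of class `sim_result`: list with `params`, `episodes`
#'   (data frame: `kind`, `t_start`, `t_end`, `duration`, `phase_start`,
#'   `phase_end`), `onsets` (unclipped sleep onset times in the retained
#'   window), `switches` (full switch log), `transient_discarded`,
#'   `horizon`, `status` and optionally `samples`
#'   (`t`, `H`, `upper`, `lower`).
#' @examples
#' res <- simulate_sleep_wake(two_process_params(), horizon = 60 * 24)
#' head(res$episodes)
#' @export
simulate_sleep_wake <- function(p, horizon, init = NULL,
                                transient = 50 * p$T_f,
                                step = p$T_f / 2048, tol = 1e-9, dwell = 1e-6,
                                sample_step = NULL,
                                on_nonterminating = c("error", "flag")) {
  stopifnot(inherits(p, "two_process_params"))
  on_nonterminating <- match.arg(on_nonterminating)
  if (!is.numeric(horizon) || horizon <= transient || transient < 0)
    tpm_stop("tpm_domain_error", "need horizon > transient >= 0")
  if (is.null(init))
    init <- vigilance_state("WAKE", t = 0, H = (p$H0_plus + p$H0_minus) / 2)
  stopifnot(inherits(init, "vigilance_state"))

  if (is.function(p$waveform)) {
    t <- init$t; H <- init$H; wake <- init$label == "WAKE"
    times <- numeric(0); press <- numeric(0); ended <- integer(0)
    status <- "OK"
    repeat {
      r <- next_crossing_r(t, H, wake, p, step, tol, dwell, horizon + p$T_f)
      if (is.nan(r$t)) { status <- "NONTERMINATING"; break }
      if (!is.finite(r$t) || r$t > horizon) break
      Hc <- if (isTRUE(r$immediate)) H else {
        if (wake) wake_pressure(r$t - t, H, p) else sleep_pressure(r$t - t, H, p)
      }
      times <- c(times, r$t); press <- c(press, Hc)
      ended <- c(ended, as.integer(wake))
      t <- r$t; H <- Hc; wake <- !wake
    }
    log <- list(t = times, H = press, ended_wake = ended, status = status)
  } else {
    log <- cpp_simulate_switches(unclass(p), init$t, init$H,
                                 init$label == "WAKE", horizon,
                                 step, tol, dwell)
  }
  if (log$status == "NONTERMINATING" && on_nonterminating == "error")
    tpm_stop("tpm_nonterminating",
             "pressure can never reach the active threshold (non-terminating state)")

  # segment boundaries: init time, switches, horizon
  st <- log$t
  n_sw <- length(st)
  seg_start <- c(init$t, st)
  seg_end <- c(st, horizon)
  seg_H0 <- c(init$H, log$H)
  wake0 <- init$label == "WAKE"
  seg_wake <- rep(c(wake0, !wake0), length.out = n_sw + 1L)

  keep <- seg_end > transient & seg_start < horizon
  eps <- data.frame(
    kind = ifelse(seg_wake[keep], "WAKE", "SLEEP"),
    t_start = pmax(seg_start[keep], transient),
    t_end = pmin(seg_end[keep], horizon),
    stringsAsFactors = FALSE)
  eps$duration <- eps$t_end - eps$t_start
  eps$phase_start <- (eps$t_start / p$T_f) %% 1
  eps$phase_end <- (eps$t_end / p$T_f) %% 1
  eps <- eps[eps$duration > 0, , drop = FALSE]
  rownames(eps) <- NULL

  onsets <- st[log$ended_wake == 1L]          # wake ended -> sleep onset
  onsets <- onsets[onsets >= transient & onsets <= horizon]

  res <- structure(
    list(params = p, episodes = eps, onsets = onsets,
         switches = data.frame(t = st, H = log$H,
                               to = ifelse(log$ended_wake == 1L, "SLEEP", "WAKE")),
         transient_discarded = transient, horizon = horizon,
         init = init, status = log$status, samples = NULL),
    class = "sim_result")

  if (!is.null(sample_step)) {
    tg <- seq(transient, horizon, by = sample_step)
    idx <- findInterval(tg, seg_start)
    Hg <- ifelse(seg_wake[idx],
                 p$mu_w + (seg_H0[idx] - p$mu_w) * exp(-(tg - seg_start[idx]) / p$chi_w),
                 p$mu_s + (seg_H0[idx] - p$mu_s) * exp(-(tg - seg_start[idx]) / p$chi_s))
    res$samples <- data.frame(t = tg, H = Hg,
                              upper = threshold_upper(tg, p),
                              lower = threshold_lower(tg, p))
  }
  res
}

#' @export
print.sim_result <- function(x, ...) {
  slp <- x$episodes[x$episodes$kind == "SLEEP", , drop = FALSE]
  cat(sprintf("Two-process simulation: %.0f h horizon (%.0f h transient discarded)\n",
              x$horizon, x$transient_discarded))
  cat(sprintf("  %d episodes retained (%d sleep), %d sleep onsets, status %s\n",
              nrow(x$episodes), nrow(slp), length(x$onsets), x$status))
  invisible(x)
}

#' Fold sleep episodes into raster-plot rows
#'
#' Produces the day-by-day raster ("actogram") representation: row `i`
#' (1-based) covers absolute time `[(i-1) * row_length, i * row_length)`
#' and carries the sleep intervals falling inside it, each mapped to
#' `[0, row_length)`. Episodes spanning a row boundary are split, so the
#' union of plotted intervals conserves total sleep time.
#'
#' @param result A `sim_result` from [simulate_sleep_wake()].
#' @param row_length Row length in hours (e.g. 24).
#' @return A list of rows; each row is a two-column matrix of interval
#'   `start`/`end` offsets within `[0, row_length)`.
#' @export
episodes_to_raster <- function(result, row_length) {
  stopifnot(inherits(result, "sim_result"), row_length > 0)
  n_rows <- max(1L, ceiling(result$horizon / row_length))
  rows <- rep(list(matrix(numeric(0), ncol = 2,
                          dimnames = list(NULL, c("start", "end")))), n_rows)
  slp <- result$episodes[result$episodes$kind == "SLEEP", , drop = FALSE]
  for (k in seq_len(nrow(slp))) {
    s <- slp$t_start[k]; e <- slp$t_end[k]
    while (s < e) {
      i <- floor(s / row_length)              # 0-based row index
      seg_end <- min(e, (i + 1) * row_length)
      if (i + 1 <= n_rows)
        rows[[i + 1]] <- rbind(rows[[i + 1]],
                               c(s - i * row_length, seg_end - i * row_length))
      s <- seg_end
    }
  }
  rows
}

#' Times of the circadian minimum
#'
#' For the cosine waveform the minima lie at `T_f/2 + k * T_f`; for a
#' pluggable waveform the argmin over one period is located numerically
#' (grid search refined by [stats::optimize()]).
#'
#' @param p A [two_process_params()] object.
#' @param horizon Return minima up to this time (hours).
#' @return Numeric vector of minimum times in `[0, horizon]`.
#' @export
circadian_min_times <- function(p, horizon) {
  stopifnot(inherits(p, "two_process_params"), horizon >= 0)
  if (is.function(p$waveform)) {
    g <- seq(0, p$T_f, length.out = 513)[-513]
    v <- p$waveform(g, p$T_f)
    i <- which.min(v)
    lo <- g[max(i - 1, 1)]; hi <- g[min(i + 1, length(g))]
    t0 <- stats::optimize(function(t) p$waveform(t, p$T_f), c(lo, hi))$minimum
  } else t0 <- p$T_f / 2
  out <- seq(t0, by = p$T_f, length.out = max(0, floor((horizon - t0) / p$T_f) + 1))
  out[out <= horizon]
}
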