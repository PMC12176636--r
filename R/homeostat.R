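#' Homeostatic sleep pressure during wake
#'
#' Closed-form pressure `dt` hours after sleep offset, starting from
#' `H_off`: \eqn{\mu_w + (H_{off} - \mu_w) e^{-dt/\chi_w}}. Strictly
#' increasing in `dt` and bounded above by the asymptote `mu_w`.
#'
#' @param dt Hours since sleep offset (vectorised, `dt >= 0`).
#' @param H_off Pressure at sleep offset; must satisfy `H_off < mu_w`.
#' @param p A [two_process_params()] object.
#' @return Pressure value(s), same length as `dt`.
#' @export
wake_pressure <- function(dt, H_off, p) {
  stopifnot(inherits(p, "two_process_params"), all(dt >= 0))
  if (H_off >= p$mu_w)
    tpm_stop("tpm_invalid_state",
             sprintf("H_off (%g) must lie below the wake asymptote mu_w (%g)",
                     H_off, p$mu_w))
  p$mu_w + (H_off - p$mu_w) * exp(-dt / p$chi_w)
}

#' Homeostatic sleep pressure during sleep
#'
#' Closed-form pressure `dt` hours after sleep onset, starting from `H_on`:
#' \eqn{\mu_s + (H_{on} - \mu_s) e^{-dt/\chi_s}}. Strictly decreasing in
#' `dt` and bounded below by the asymptote `mu_s`.
#'
#' @inheritParams wake_pressure
#' @param H_on Pressure at sleep onset; must satisfy `H_on > mu_s`.
#' @return Pressure value(s), same length as `dt`.
#' @export
sleep_pressure <- function(dt, H_on, p) {
  stopifnot(inherits(p, "two_process_params"), all(dt >= 0))
  if (H_on <= p$mu_s)
    tpm_stop("tpm_invalid_state",
             sprintf("H_on (%g) must lie above the sleep asymptote mu_s (%g)",
                     H_on, p$mu_s))
  p$mu_s + (H_on - p$mu_s) * exp(-dt / p$chi_s)
}

#' Circadian modulation waveform
#'
#' Evaluates the `T_f`-periodic waveform `C(t)` modulating both thresholds,
#' with range in \eqn{[-1, 1]}. The default `"cosine"` waveform is
#' \eqn{\cos(2\pi t / T_f)}: `t = 0` is the circadian maximum and
#' `t = T_f/2` the circadian minimum.
#'
#' @param t Time(s) in hours (vectorised).
#' @param p A [two_process_params()] object.
#' @return Waveform value(s) in \eqn{[-1, 1]}.
#' @export
circadian_waveform <- function(t, p) {
  stopifnot(inherits(p, "two_process_params"))
  if (is.function(p$waveform)) return(p$waveform(t, p$T_f))
  cos(2 * pi * t / p$T_f)
}

#' Circadian-modulated switching thresholds
#'
#' `threshold_upper()` is the wake-to-sleep threshold
#' \eqn{H^+(t) = H_0^+ + a C(t)}; `threshold_lower()` the sleep-to-wake
#' threshold \eqn{H^-(t) = H_0^- + a C(t)}. Both share the same circadian
#' modulation, so their gap is the constant \eqn{H_0^+ - H_0^-}.
#'
#' @inheritParams circadian_waveform
#' @return Threshold value(s) in pressure units.
#' @export
threshold_upper <- function(t, p) {
  stopifnot(inherits(p, "two_process_params"))
  p$H0_plus + p$a * circadian_waveform(t, p)
}

#' @rdname threshold_upper
#' @export
threshold_lower <- function(t, p) {
  stopifnot(inherits(p, "two_process_params"))
  p$H0_minus + p$a * circadian_waveform(t, p)
}

#' Natural period of the unforced sleep-wake oscillator
#'
#' With zero circadian amplitude the model is a relaxation oscillator whose
#' sleep and wake durations follow in closed form from the exponential
#' segments:
#' \deqn{T_{sleep} = \chi_s \log(\tilde H_0^+ / \tilde H_0^-), \qquad
#'       T_{wake} = \chi_w \log\{(1 - \tilde H_0^-) / (1 - \tilde H_0^+)\},}
#' evaluated on the scaled thresholds
#' \eqn{\tilde H_0^\pm = (H_0^\pm - \mu_s)/(\mu_w - \mu_s)}, and
#' \eqn{T_{nat} = T_{sleep} + T_{wake}}. For the standard human parameters
#' this gives 5.8 h sleep, 16.8 h wake, a 22.6 h natural period with about
#' 26\% of the cycle spent asleep.
#'
#' @param p A [two_process_params()] object (the circadian amplitude is
#'   ignored: these are the zero-amplitude formulas).
#' @return An object of class `period_summary`: a list with `T_sleep`,
#'   `T_wake`, `T_nat` (hours) and `fraction_asleep`.
#' @export
natural_periods <- function(p) {
  stopifnot(inherits(p, "two_process_params"))
  if (p$H0_plus >= p$mu_w)
    tpm_stop("tpm_perpetual_wake",
             "H0_plus >= mu_w: pressure never reaches the upper threshold (perpetual wake)")
  if (p$H0_minus <= p$mu_s)
    tpm_stop("tpm_perpetual_sleep",
             "H0_minus <= mu_s: pressure never reaches the lower threshold (perpetual sleep)")
  mu <- p$mu_w - p$mu_s
  hp <- (p$H0_plus - p$mu_s) / mu
  hm <- (p$H0_minus - p$mu_s) / mu
  T_sleep <- p$chi_s * log(hp / hm)
  T_wake <- p$chi_w * log((1 - hm) / (1 - hp))
  T_nat <- T_sleep + T_wake
  structure(list(T_sleep = T_sleep, T_wake = T_wake, T_nat = T_nat,
                 fraction_asleep = T_sleep / T_nat),
            class = "period_summary")
}

#' @export
print.period_summary <- function(x, ...) {
  cat(sprintf("T_sleep = %.3f h, T_wake = %.3f h, T_nat = %.3f h (%.1f%% asleep)\n",
              x$T_sleep, x$T_wake, x$T_nat, 100 * x$fraction_asleep))
  invisible(x)
}

#' Upper threshold level giving a target natural period
#'
#' Inverts the closed-form natural period with respect to the mean upper
#' threshold: `T_nat` is continuous and strictly increasing in `H0_plus` on
#' `(H0_minus, mu_w)` with range \eqn{(0, \infty)}, so the inverse is unique
#' and found by bracketed bisection ([stats::uniroot()]).
#'
#' @param target_T_nat Desired natural period, hours (> 0).
#' @param p A [two_process_params()] object supplying all parameters other
#'   than `H0_plus` (its `H0_plus` field is ignored).
#' @return The `H0_plus` value whose natural period equals `target_T_nat`
#'   to within 1e-9 h.
#' @export
invert_natural_period <- function(target_T_nat, p) {
  stopifnot(inherits(p, "two_process_params"))
  if (!is.numeric(target_T_nat) || length(target_T_nat) != 1L ||
      !is.finite(target_T_nat) || target_T_nat <= 0)
    tpm_stop("tpm_domain_error", "target_T_nat must be a positive finite scalar")
  f <- function(h) {
    q <- two_process_params(chi_s = p$chi_s, chi_w = p$chi_w,
                            H0_plus = h, H0_minus = p$H0_minus, a = p$a,
                            mu_w = p$mu_w, mu_s = p$mu_s, T_f = p$T_f,
                            waveform = p$waveform)
    natural_periods(q)$T_nat - target_T_nat
  }
  span <- p$mu_w - p$H0_minus
  lo <- p$H0_minus + 1e-12 * span
  hi <- p$mu_w - 1e-12 * span
  # shrink the bracket until f is finite and straddles zero
  while (f(lo) > 0) lo <- p$H0_minus + (lo - p$H0_minus) / 2
  while (f(hi) < 0) hi <- p$mu_w - (p$mu_w - hi) / 2
  r <- stats::uniroot(f, c(lo, hi), tol = .Machine$double.eps)
  r$root
}
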