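#' Parameter set for the two-process model
#'
#' Constructs and validates the eight-parameter two-process model of
#' sleep-wake regulation: homeostatic sleep pressure rises exponentially
#' toward the upper asymptote `mu_w` with time constant `chi_w` during wake,
#' decays toward the lower asymptote `mu_s` with time constant `chi_s` during
#' sleep, and switches state on hitting circadian-modulated thresholds
#' `H0_plus + a*C(t)` (wake to sleep) and `H0_minus + a*C(t)` (sleep to
#' wake), where `C(t)` is a `T_f`-periodic waveform with range in
#' \eqn{[-1, 1]} (a cosine by default, with `C(0) = 1` at the circadian
#' maximum).
#'
#' Defaults are the standard human parameters used throughout the literature
#' (`chi_s` = 4.2 h, `chi_w` = 18.2 h, thresholds 0.67/0.17, amplitude 0.12,
#' asymptotes 1/0, 24 h forcing).
#'
#' Hard violations (non-positive time constants or period, negative
#' amplitude, `mu_w <= mu_s`, `H0_minus >= H0_plus`) raise an error of class
#' `tpm_invalid_params`. The orderings `H0_plus < mu_w` and
#' `H0_minus > mu_s` are required for sustained oscillation but a parameter
#' set violating them is still constructible: it is flagged (see
#' `$ordering_ok`) and [natural_periods()] raises the perpetual-wake /
#' perpetual-sleep error for it.
#'
#' @param chi_s Sleep (dissipation) time constant, hours.
#' @param chi_w Wake (rise) time constant, hours.
#' @param H0_plus Mean level of the upper (wake-to-sleep) threshold,
#'   pressure units.
#' @param H0_minus Mean level of the lower (sleep-to-wake) threshold,
#'   pressure units.
#' @param a Circadian amplitude of the threshold modulation, pressure units.
#' @param mu_w Upper asymptote of pressure during wake.
#' @param mu_s Lower asymptote of pressure during sleep.
#' @param T_f Circadian (forcing) period, hours.
#' @param waveform Either the string `"cosine"` or a function
#'   `f(t, T_f)` returning values in \eqn{[-1, 1]} with period `T_f`.
#' @return An object of class `two_process_params`.
#' @examples
#' p <- two_process_params()
#' natural_periods(p)
#' @seealso [rescale_params()], [natural_periods()], [simulate_sleep_wake()]
#' @export
two_process_params <- function(chi_s = 4.2, chi_w = 18.2,
                               H0_plus = 0.67, H0_minus = 0.17,
                               a = 0.12, mu_w = 1, mu_s = 0,
                               T_f = 24, waveform = "cosine") {
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      tpm_stop("tpm_invalid_params", sprintf("`%s` must be a finite scalar", nm))
    as.numeric(x)
  }
  chi_s <- num1(chi_s, "chi_s"); chi_w <- num1(chi_w, "chi_w")
  H0_plus <- num1(H0_plus, "H0_plus"); H0_minus <- num1(H0_minus, "H0_minus")
  a <- num1(a, "a"); mu_w <- num1(mu_w, "mu_w"); mu_s <- num1(mu_s, "mu_s")
  T_f <- num1(T_f, "T_f")

  if (chi_s <= 0 || chi_w <= 0)
    tpm_stop("tpm_invalid_params", "time constants chi_s, chi_w must be > 0")
  if (T_f <= 0)
    tpm_stop("tpm_invalid_params", "forcing period T_f must be > 0")
  if (a < 0)
    tpm_stop("tpm_invalid_params", "circadian amplitude a must be >= 0")
  if (mu_w <= mu_s)
    tpm_stop("tpm_invalid_params",
             sprintf("upper asymptote mu_w (%g) must exceed lower asymptote mu_s (%g)",
                     mu_w, mu_s))
  if (H0_minus >= H0_plus)
    tpm_stop("tpm_invalid_params",
             sprintf("mean lower threshold H0_minus (%g) must lie below H0_plus (%g)",
                     H0_minus, H0_plus))
  if (!is.function(waveform) &&
      !(is.character(waveform) && length(waveform) == 1L && waveform == "cosine"))
    tpm_stop("tpm_config_error",
             'waveform must be "cosine" or a function f(t, T_f)')

  p <- structure(
    list(chi_s = chi_s, chi_w = chi_w,
         H0_plus = H0_plus, H0_minus = H0_minus, a = a,
         mu_w = mu_w, mu_s = mu_s, T_f = T_f, waveform = waveform,
         # sustained oscillation requires mu_s < H0_minus < H0_plus < mu_w
         ordering_ok = (H0_plus < mu_w) && (H0_minus > mu_s)),
    class = "two_process_params")
  p
}

#' @export
print.two_process_params <- function(x, ...) {
  cat("Two-process model parameters\n")
  cat(sprintf("  chi_s = %g h, chi_w = %g h\n", x$chi_s, x$chi_w))
  cat(sprintf("  H0_plus = %g, H0_minus = %g, a = %g\n",
              x$H0_plus, x$H0_minus, x$a))
  cat(sprintf("  mu_w = %g, mu_s = %g, T_f = %g h, waveform = %s\n",
              x$mu_w, x$mu_s, x$T_f,
              if (is.function(x$waveform)) "<function>" else x$waveform))
  if (!x$ordering_ok)
    cat("  NOTE: thresholds not strictly inside the asymptotes;",
        "sustained oscillation impossible\n")
  invisible(x)
}

#' Shift-and-rescale to the non-dimensional form
#'
#' Removes the two asymptote parameters by the affine change of variable
#' \eqn{H = (\mu_w - \mu_s)\tilde H + \mu_s}: the returned parameter set has
#' `mu_w = 1`, `mu_s = 0`,
#' \eqn{\tilde H_0^\pm = (H_0^\pm - \mu_s)/(\mu_w - \mu_s)} and
#' \eqn{\tilde a = a/(\mu_w - \mu_s)}. Time constants and forcing period are
#' unchanged, so all switch times of the simulated dynamics are invariant
#' under this transformation.
#'
#' @param p A [two_process_params()] object.
#' @return A `two_process_params` object in scaled form.
#' @export
rescale_params <- function(p) {
  stopifnot(inherits(p, "two_process_params"))
  mu <- p$mu_w - p$mu_s
  two_process_params(
    chi_s = p$chi_s, chi_w = p$chi_w,
    H0_plus = (p$H0_plus - p$mu_s) / mu,
    H0_minus = (p$H0_minus - p$mu_s) / mu,
    a = p$a / mu, mu_w = 1, mu_s = 0,
    T_f = p$T_f, waveform = p$waveform)
}

# classed conditions so callers/tests can dispatch on failure mode
tpm_stop <- function(class, msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "tpm_error"), call = call))
}
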