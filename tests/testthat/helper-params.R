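# Shared fixtures and generators for the suite.

std_params <- function(a = 0.12) {
  two_process_params(chi_s = 4.2, chi_w = 18.2, H0_plus = 0.67,
                     H0_minus = 0.17, a = a)
}

# n random parameter sets satisfying the ordering invariant, with general
# (non-scaled) asymptotes; deterministic under the given seed
random_valid_params <- function(n, seed = 42, a = 0) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      mu_s <- runif(1, -0.3, 0.3)
      mu_w <- mu_s + runif(1, 0.7, 1.6)
      span <- mu_w - mu_s
      hm <- mu_s + runif(1, 0.05, 0.35) * span
      hp <- hm + runif(1, 0.15, 0.9) * (mu_w - hm) * 0.95
      two_process_params(chi_s = runif(1, 1.5, 8), chi_w = runif(1, 6, 30),
                         H0_plus = hp, H0_minus = hm, a = a,
                         mu_w = mu_w, mu_s = mu_s)
    })
  })
}

# exhaustive-search oracle for rational classification: all n/m with
# m <= q_max, smallest denominator within tol (NULL if none)
oracle_lowest_fraction <- function(rho, q_max = 12, tol = 1e-3) {
  for (m in seq_len(q_max)) {
    n <- round(rho * m)
    if (abs(rho - n / m) < tol) {
      g <- .gcd(n, m)
      return(c(n / g, m / g))
    }
  }
  NULL
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)
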