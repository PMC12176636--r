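# twoprocess

Simulation and entrainment analysis for the two-process model of
sleep-wake regulation.

## The science

The two-process model describes sleep timing as the interplay of a
homeostatic sleep pressure *H* (Process S) and a circadian modulation
(Process C). During wake, pressure saturates exponentially toward an upper
asymptote; during sleep it decays toward a lower one:

    wake:   H(t) = mu_w + (H(t_off) - mu_w) exp(-(t - t_off)/chi_w)
    sleep:  H(t) = mu_s + (H(t_on)  - mu_s) exp(-(t - t_on)/chi_s)

Switching happens at two circadian-modulated thresholds,

    H+(t) = H0+ + a C(t)      (wake -> sleep)
    H-(t) = H0- + a C(t)      (sleep -> wake)

with `C(t) = cos(2 pi t / T_f)` by default. With zero circadian amplitude
the model is a relaxation oscillator with closed-form natural period

    T_nat = T_sleep + T_wake
    T_sleep = chi_s log(H0+/H0-)
    T_wake  = chi_w log((mu - H0-)/(mu - H0+)),   mu = mu_w - mu_s.

With `a > 0` the sleep-wake oscillator is periodically forced by the
circadian rhythm and the whole apparatus of forced-oscillator entrainment
applies: the dynamics reduce to a circle map (each upper-threshold hit
determines the next), whose rotation number counts sleep onsets per
circadian period. Rational rotation numbers n/m ("n sleeps per m circadian
days") occupy Arnold tongues in the (natural period) x (circadian
amplitude) plane; slicing the tongues at fixed amplitude yields a Devil's
staircase. This single structure organises monophasic sleep, napping and
polyphasic patterns, bicircadian rhythms and internal desynchrony.

The package is aimed at sleep/circadian modellers and at anyone studying
forced relaxation oscillators: it provides the parameter container with
the shift-and-rescale non-dimensionalisation, an exact event-driven
simulator (closed forms within each state, bracketing + bisection for the
switching times — no ODE solver), the circle-map/rotation-number
machinery, tongue scans, staircase sweeps, raster utilities, JSON
configuration and a CLI.

## Worked example

```r
library(twoprocess)

p <- two_process_params()   # standard human parameters
natural_periods(p)
#> T_sleep = 5.760 h, T_wake = 16.786 h, T_nat = 22.547 h (25.5% asleep)
```

A 22.5 h natural period: left alone, this oscillator free-runs faster than
the day. Forcing it with a circadian amplitude of 0.12 entrains it to
exactly one sleep per 24 h day:

```r
res <- simulate_sleep_wake(p, horizon = 150 * 24)   # 50-day transient
sleeps_per_day(res)
#> [1] 1
classify_rotation(rotation_number(p))
#> rho = 1.000000: 1:1 locking (1 sleeps per 1 forcing periods)
```

Shrinking the natural period to 8 h (one third of a day) does *not* give
three sleeps a day — the curvature of the tongues puts it on the 2/day
plateau of the Devil's staircase:

```r
h8 <- invert_natural_period(8, two_process_fixture("fig8_base"))
p8 <- two_process_params(H0_plus = h8, H0_minus = 0.17, a = 0.12)
classify_rotation(rotation_number(p8))
#> rho = 2.000000: 2:1 locking (2 sleeps per 1 forcing periods)
```

Named fixtures reproduce the published regimes: `two_process_fixture("fig1c")`
gives 3 sleeps every 4 days (rotation number 0.75), `"fig1d"` 3 per 2 days,
`"fig1e"` 2 per day, `"mouse"` the murine time constants (8.3 h / 1.7 h).

A scaled-down Arnold tongue scan (2,400 cells, ~10 s):

```r
g <- tongue_scan("H0_plus", seq(0.3, 0.95, length.out = 60),
                 seq(0, 0.12, length.out = 40), two_process_fixture("fig7_base"))
write_tongue_csv(g, "tongues.csv")
```

## Command line

```sh
Rscript inst/cli/twoprocess periods --fixture fig6a
# {"T_sleep":5.7602...,"T_wake":16.7865...,"T_nat":22.5467...,"fraction_asleep":0.2554...}
Rscript inst/cli/twoprocess simulate --fixture fig1e --horizon-days 30 --out episodes.csv
Rscript inst/cli/twoprocess staircase --fixture fig8_base --h0plus-range 0.3:0.95:60
Rscript inst/cli/twoprocess tongue --sweep H0_plus --sweep-range 0.3:0.95:60 --amp-range 0:0.12:40
```

Exit codes: 0 success, 2 configuration error, 3 non-terminating dynamics.

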