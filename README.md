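# howlspot

Passive acoustic monitoring can localize loud, far-carrying animal calls —
wolf howls above all — with a sparse grid of autonomous recorders spread
over tens of square kilometres. Planning such a survey raises questions
that are expensive to answer in the field: how many broadcasts will any
recorder catch, how many will reach the four microphones a localization
needs, how accurate will the estimated positions be, and which estimates
should be discarded as unreliable?

howlspot answers them in silico. It simulates a complete broadcast
campaign over a low-density microphone array (20 two-channel recorders at
1 km spacing over 6 × 5 km, 0.67 recorders/km²; 60 stratified broadcast
sites per area over 3 nights × 3 periods), solves the time-of-arrival
(TOA) localization problem, screens estimates with the pairwise
temporal-error reliability statistic, and analyses what drives
localization accuracy. It is aimed at ecologists designing acoustic
surveys and at anyone who wants a tested, reproducible TOA pipeline on
tabular data.

## The method

A source at $(x, y)$ emitting at time $t_0$ reaches microphone $i$ at
$t_i = t_0 + d_i/c + \varepsilon_i$ with $d_i$ the Euclidean distance and
$c = 331.3\sqrt{1 + T/273.15}$ m/s the speed of sound at air temperature
$T$. The solver minimises $\sum_i (t_i - t_0 - d_i/c)^2$ over $(x, y)$
with $t_0$ profiled out in closed form, and reports the **temporal
error**: the RMS over all microphone pairs of the mismatch between
observed delays $t_i - t_j$ and the delays $(d_i - d_j)/c$ implied by the
estimate, in ms. Zero means a perfectly consistent solution; estimates
above a 200 ms threshold are set aside as unreliable. An exhaustive
grid-search oracle verifies the solver in the tests.

## Worked example

Localize one broadcast from four recorders with 5 ms TOA noise:

```r
library(howlspot)
library(dplyr)

mics <- tibble::tibble(
  mic_id = paste0("R0", 1:4, "A"), recorder_id = paste0("R0", 1:4),
  channel = "A", x = c(-500, -500, 500, 500), y = c(-500, 500, -500, 500)
)
cc <- sound_speed(12)            # 338.5 m/s at 12 degrees C
src <- c(150, -220)              # true source
set.seed(1)
mics$toa <- 3 + sqrt((mics$x - src[1])^2 + (mics$y - src[2])^2) / cc +
  rnorm(4, sd = 0.005)
mics$snr_db <- 20

fit <- localize(toa_set(mics, temperature_c = 12, broadcast_id = "demo"))
fit
#> <toa_localization> demo
#>   position (149.4, -222.2) m, t0 3.000 s
#>   temporal error 2.81 ms, 4 mics (4 recorders), ok
```

The estimate lands 2.3 m from the true source and its temporal error
(2.8 ms) is far below the 200 ms reliability threshold, so the estimate
would be kept. `tidy(fit)` returns the same as a one-row tibble.

A full two-area campaign, end to end:

```r
res <- run_pipeline(seed = 42)   # 354 broadcasts, two areas
nrow(res$estimates)              # 142 localizable broadcasts
res$summary
#> # A tibble: 3 × 6
#>   array     n  mean    sd   min   max
#>   <chr> <int> <dbl> <dbl> <dbl> <dbl>
#> 1 CM       69  61.4  249. 0.541 1566.
#> 2 VM       73  86.4  300. 0.760 1977.
#> 3 Total   142  74.2  276. 0.541 1977.
```

Mean localization accuracy (distance from estimated to true position) is
74 m over the 142 estimates, similar in the two simulated areas. The
distance effect on accuracy is recovered with a positive coefficient:

```r
tidy(res$models) %>% filter(model == "m2", term == "dist")
#> # A tibble: 1 × 4
#>   model term  estimate std_error
#>   <chr> <chr>    <dbl>     <dbl>
#> 1 m2    dist     0.130    0.0548
```

i.e. accuracy degrades by ~0.13 m per metre of distance from the
microphone-hull centroid. `autoplot()` methods and
`plot_accuracy_error()` give the standard diagnostic figures, and
`run_pipeline(cfg, outdir = "run1")` writes every stage as schema-checked
CSV plus a JSON run manifest. A thin command-line wrapper lives at
`inst/cli/howlspot.R`.

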