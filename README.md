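# imeswitch

Simulation and analysis of the regulatory circuit that gates meiotic
entry in budding yeast through the *IME1* promoter. Two long noncoding
RNAs are transcribed across this promoter: **IRT1** represses *IME1* by
transcriptional interference, and **IRT2** plays a dual role on *IRT1* —
a low, threshold-crossing level of *IRT2* transcription licenses the
*IRT1* promoter (a one-way, hysteretic switch), while higher levels
repress it dose-dependently. *IRT1* itself is driven by the transcription
factor **Rme1**, abundant in single-mating-type (haploid-like) cells and
scarce in MATa/alpha diploids. The package is for systems biologists who
want to simulate this hybrid circuit, analyze its steady-state
dose-response, and test inference pipelines on synthetic data with a
known ground truth.

## The model

Scaled variables (all in [0, 1]): *IME1* mRNA `Im`, Ime1 protein `Ip`,
starvation input `s`, transcription rates `I1` (*IRT1*), `I2` (*IRT2*),
`It` (*IME1*); time in hours.

    dIm/dt = s/(s + k3*I1) - k4*Im      (synthesis term absent when s = 0)
    dIp/dt = k5*Im - k6*Ip
    I2     = max(Ip - k2, 0)
    chi    = 1  iff  I2 >= A  or  I1 > 0      (hysteretic latch)
    I1     = chi * r/(r + k1*I2)              (0 when r = I2 = 0)

from `Im(0) = Ip(0) = 0`, with defaults `k1 = 5, k2 = 0.05, k3 = 10,
k4 = k5 = k6 = 1/h, A = 0.01`, Rme1 level `r` in [0, 5]. The latch `chi`
is carried as a discrete mode of an event-aware adaptive Runge–Kutta
integration; switching times are localized by bisection plus a Newton
polish. Three *IRT2* regimes: `wildtype`, `activating_only` (`I2 = A`
clamped: licensing without repression), `null` (`I2 = 0`).

## Worked example

```r
library(imeswitch)

# haploid-like cell (high Rme1): simulate to steady state
tr <- simulate_cell_type("haploid", t_end = 50, grid_dt = 0.1)
circuit_events(tr)
#> # A tibble: 2 x 2
#>   name            time
#>   <chr>          <dbl>
#> 1 i2_onset       0.355
#> 2 chi_activation 0.394
tail(tr$Ip, 1)
#> [1] 0.09458
```

Ime1 protein rises with the unrepressed cascade until 0.355 h, when it
crosses `k2` and *IRT2* transcription turns on; at 0.394 h the *IRT2*
rate reaches the licensing threshold `A`, the latch fires, and
Rme1-driven *IRT1* interference pushes Ime1 down to a repressed steady
state of about 0.095 — this cell will not enter meiosis. A `diploid`
preset (`r = 0.1`) instead settles at 0.79 (active), and under
`mode = "null"` (no *IRT2*) both cell types reach 1.0: without the
licensing lncRNA, *IME1* activation loses its mating-type specificity.

```r
# steady-state dose-response over Rme1 and its switch shape
m <- sigmoid_metrics(dose_response())
m
#> # A tibble: 1 x 5
#>   r_half dynamic_range max_abs_slope switch_like mode
#>    <dbl>         <dbl>         <dbl> <lgl>       <chr>
#> 1   0.25          10.6          1.13 TRUE        wildtype
```

The wildtype curve is a high-contrast switch: half-maximal Ime1 at
`r = 0.25` (exactly, from the fixed-point algebra) and a 10.6-fold range
between the diploid and haploid plateaus. Rerunning with
`mode = "activating_only"` collapses `r_half` 45-fold to `1/180` and
with `mode = "null"` flattens the curve entirely — only the dual
(activate-then-repress) *IRT2* function produces the bimodal
relationship. `autoplot()` methods draw trajectories, dose-response
curves, cell populations and recovery summaries.

```r
# synthetic smFISH population: no IRT2, haploid Rme1, 30-copy cut
pop <- generate_cell_population(2000, cell_r_sampler("point", r = 5),
                                mode = "null", seed = 1)
fraction_high(pop)
#> [1] 0.998
```

99.8% of *IRT2*-null cells exceed 30 mRNA copies; the wildtype fraction
at the same Rme1 level is 0 (mean ~4.7 copies).

A thin CLI wraps the same functions
(`inst/cli/imeswitch.R simulate|dose|synth|fit|recover`), writing TSV
trajectories with event footers, JSON run manifests, and YAML/JSON
configs that default to the table above.

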