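# polyspike

Spike-in normalized quantification of polysome profiling RT-qPCR data.

## The problem

Polysome profiling resolves a transcript's translational state by
sedimenting cell lysate through a sucrose gradient and collecting ~20
fractions, from free mRNPs (light) to heavy polysomes. The transcript is
then quantified per fraction by RT-qPCR, and a treatment effect is read as a
shift of the distribution toward heavier fractions. The catch: RNA is
isolated from each fraction independently, and recovery varies strongly
tube to tube, distorting the very distribution being measured.

A cost-effective fix is to add a constant amount of total RNA from a
distant species (yeast, measured via its RLP24 transcript) to every fraction
*before* isolation. Any per-fraction loss then multiplies target and
spike-in alike and cancels when the target's relative quantity is divided by
the spike-in's in the same fraction. `polyspike` implements this analysis
and a simulator of the loss process that lets you verify the cancellation —
exactly — and measure the statistical power it buys.

## The statistics

Per profile (one gene, one sample, across fractions), Cq values become
relative quantities `RQ_i = E^(Cq_min − Cq_i)` (amplification efficiency
`E`, within-profile minimum Cq as calibrator), optionally divided by the
spike-in: `NRQ_i = RQ_i / RQ_i^spike`. Over the analysis window (default
fractions 2–16: 40S, 60S, 80S and polysomes), percentages
`p_i = 100·v_i / Σ v_j` summarise to the signal-weighted mean fraction

    F_W = Σ_i f_i · p_i / 100,

and the per-replicate treatment shift is `ΔF_W = F_W(treated) −
F_W(control)`. Arms (e.g. control vs knockdown siRNA) are compared with a
one-tailed paired Student's t-test on ΔF_W, alongside the Pearson pairing
correlation as a diagnostic of how much replicate-level structure the
paired design captures.

## Worked example

Simulate a two-arm experiment (siCTRL shifts by 0.3 fractions under stress,
siARK5 by 1.0; per-fraction loss SD 0.5, Cq noise 0.2 cycles, 3 paired
replicates) and run the full pipeline:

```r
library(polyspike)
library(dplyr)

res <- run_pipeline(sim_config(arms = c(siCTRL = 0.3, siARK5 = 1), seed = 42))

res$shifts |>
  filter(mode == "spikein_normalized") |>
  select(sample_id, replicate, fw_control, fw_treated, delta_fw)
#> # A tibble: 6 × 5
#>   sample_id replicate fw_control fw_treated delta_fw
#>   <chr>         <int>      <dbl>      <dbl>    <dbl>
#> 1 siARK5            1       8.48       9.85    1.37
#> 2 siARK5            2       8.63       9.44    0.809
#> 3 siARK5            3       8.71       9.94    1.23
#> 4 siCTRL            1       8.48       9.25    0.774
#> 5 siCTRL            2       8.38       8.60    0.216
#> 6 siCTRL            3       8.79       9.01    0.221

res$comparison |>
  select(mode, mean_difference, t_statistic, p_one_tailed, pairing_r, more_discernible)
#> # A tibble: 2 × 6
#>   mode       mean_difference t_statistic p_one_tailed pairing_r more_discernible
#>   <chr>                <dbl>       <dbl>        <dbl>     <dbl> <lgl>
#> 1 raw                  1.38         5.32       0.0168     0.189 FALSE
#> 2 spikein_n…           0.732        5.34       0.0166     0.704 TRUE
```

Reading it: each replicate's F_W rises under treatment, more in the siARK5
arm; the spike-in normalized mode estimates the arm difference in ΔF_W
(0.73, close to the simulated 0.7) with a far better pairing correlation
(0.70 vs 0.19) — the spike-in removes isolation-loss noise, leaving the
shared replicate-level biology that the paired design exploits. Raw-mode
values drift with the loss noise (its mean difference 1.38 overshoots).
`res$percent` holds the per-fraction percentage distributions
(`plot_fraction_distribution(res$percent)`), `res$recovery` the
per-fraction spike-in recovery report, and on simulated input `res$truth`
the generating truth.

Step-by-step equivalents: `read_cq_table()` / `simulate_experiment()` →
`relative_quantity()` → `normalize_to_spikein()` (or `quantify_cq()` for
both modes at once) → `percent_signal()` → `weighted_average_fw()` →
`delta_fw()` → `compare_normalization_modes()`; all take and return tidy
tables. A command-line wrapper with `simulate` / `quantify` / `fw` /
`compare` / `run` subcommands lives at `inst/scripts/polyspike-cli.R`.

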