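# placeremap

Analysis of place-cell remapping in light/dark/light (L1/D/L2) open-field
foraging experiments, with a fully seeded synthetic-data generator so the
entire pipeline can be exercised and validated without animal recordings.

Place cells fire preferentially when an animal occupies a particular
location (the cell's *place field*). When visual input is removed mid
experiment, fields in some regions shift to a new, consistent location and
return when the lights come back. `placeremap` implements the standard
analysis chain for quantifying this:

- **Rate maps** — occupancy and spike counts binned over the arena
  (default 2.5 cm bins), with occupancy-weighted boxcar smoothing and a
  minimum-occupancy validity mask.
- **Place fields and centres of mass (COM)** — largest 4-connected
  supra-threshold component of the smoothed map; COM is the rate-weighted
  mean of the field's bin centres.
- **Remapping statistics** — for each unit with fields in all three
  sessions, the pairwise COM distances
  `Δ(a,b) = √((y_b−y_a)² + (x_b−x_a)²)` and the L1DL2 angle

  ```
  angle = arccos( (DL1 · DL2) / (‖DL1‖ ‖DL2‖) )
  ```

  where `DL1` and `DL2` are the vectors from the dark-session COM to the
  two light-session COMs. A large angle means the dark field lies between
  two similar light fields; a consistent intermediate angle (~50° in the
  claustrum) indicates systematic remapping in darkness.
- **Unit metrics and classification** — Skaggs spatial information
  `I = Σᵢ pᵢ (λᵢ/λ̄) log₂(λᵢ/λ̄)` (bits/spike), spatial coherence
  (correlation of the raw map with its neighbour-average map), waveform
  amplitude/width, ISI and burst metrics (bursts: runs of ISIs ≤ 6 ms,
  merged below a 50 ms inter-burst interval). Place cells require
  information ≥ 0.5, coherence ≥ 0.25, rate ≥ 0.25 Hz and a detected
  field; fast, heavily bursting, non-spatial units are bursting cells.
- **LFP band power** — Welch periodogram (2 s Hamming windows, 50%
  overlap) integrated with Simpson's rule over delta (1.5–4 Hz), theta
  (5–11 Hz) and gamma (30–90 Hz); relative power divides by total power
  over 1.5–90 Hz.
- **Paired session statistics** — two-tailed paired t or Wilcoxon
  signed-rank tests (Shapiro gate at α = 0.05), unadjusted for multiple
  comparisons.
- **Synthetic experiments** — Ornstein–Uhlenbeck foraging trajectories,
  inhomogeneous-Poisson place cells with Gaussian fields, renewal-process
  bursting units, and spectrally shaped LFP noise, arranged into
  on-disk L1/D/L2 sessions with a ground-truth manifest.

## Worked example

Simulate a small experiment (six place cells remapping by 50° and
12.75 cm in darkness, two bursting cells, 10-minute sessions) and analyse
it:

```r
library(placeremap)

dir <- file.path(tempdir(), "demo")
generate_ldl_experiment(dir, seed = 7, angle = 50, shift = 12.75,
                        n_place_cells = 6, n_burst_cells = 2,
                        duration = 600)
report <- run_ldl_analysis(file.path(dir, "L1"), file.path(dir, "D"),
                           file.path(dir, "L2"))
report
#> <ldl_report> 8 units (4 place, 2 bursting); angle 53.7 deg, dL1D 12.1 cm

dplyr::select(tidy(report, "remapping"), unit_id:d_dl2_cm)
#> # A tibble: 6 × 5
#>   unit_id angle_deg d_l1d_cm d_l1l2_cm d_dl2_cm
#>   <chr>       <dbl>    <dbl>     <dbl>    <dbl>
#> 1 u01          67.9     12.3     14.3     13.2
#> 2 u02          43.5     10.4      8.23    11.6
#> 3 u03          40.5     12.5      8.54    12.1
#> 4 u04          50.9     14.7     11.6     11.2
#> 5 u05          44.3     10.1     11.4     16.2
#> 6 u06          75.2     12.5     13.7      9.60
```

Per-unit angles scatter around the configured 50° and the L1→D distances
around the configured 12.75 cm; the light–light distances are smaller,
i.e. fields return near their original location after darkness. The dark
session uses a higher-theta/lower-delta LFP profile, which the spectral
chain recovers:

```r
dplyr::filter(tidy(report, "band_powers"), band == "theta")
#> # A tibble: 3 × 7
#>   session channel band  relative
#>   <chr>   <chr>   <chr>    <dbl>
#> 1 L1      ch1     theta    0.274
#> 2 D       ch1     theta    0.316
#> 3 L2      ch1     theta    0.268
```

`tidy(report, "metrics")` gives per-unit, per-session firing, waveform,
information, coherence and burst metrics with classification labels;
`tidy(report, "paired_tests")` the session contrasts;
`autoplot(report)` a histogram of remapping angles; and
`write_report(report, out_dir)` deterministic CSV/JSON tables.

A thin command-line wrapper with `simulate` and `analyze` subcommands is
installed at `inst/scripts/placeremap-cli.R`.

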