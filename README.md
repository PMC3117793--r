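# pinnasonar

Information-theoretic modeling of sound localization by constant-frequency
(CF) echolocating bats that scan echoes with moving pinnae.

Horseshoe bats emit narrowband multi-harmonic calls and rock their ears in
anti-phase while echoes arrive. Because the hearing directionality moves
rigidly with the pinna, an echo from direction *θ* is amplitude-modulated
in a *θ*-specific way: the sequence of received levels over ear positions is
a directional signature. `pinnasonar` treats localization as Bayesian
template matching on these signatures and asks, in bits, how much one echo
reveals about its direction of arrival — as a function of call frequency,
echo strength, and the amplitude noise a fluttering insect imposes.

The package is for computational bioacousticians and sensory ecologists who
want to quantify how a directivity pattern (real or synthetic) trades a
"wide view" against a "focused view" of the frontal hemisphere across the
harmonics of a sonar call.

## The model

- The frontal hemisphere is divided into *N* equal-area cells (default
  *N* = 256; recursive zonal equal-area partitioning), the discrete
  hypothesis space. A uniform posterior has entropy log₂ *N* = 8 bits —
  chance level.
- For each cell and frequency, the template **T** is the expected dB level
  at 7 left-ear plus 7 right-ear positions of the sweep (−15°…+15° in 5°
  steps, anti-phase), built from the emission beam times the rigidly
  rotated hearing field, normalized per frequency so the best raw element
  is 0 dB.
- A measurement is **b** = max(**T** + *A* + **ε**, 0): echo strength *A*
  (dB SNR), correlated flutter noise **ε** ~ 𝒩(0, **Σ**) (default
  σ = 5 dB, within-ear lag correlation 0.2, interaural correlation 0.9),
  and a 0 dB detection floor acting as an elementwise maximum.
- The posterior over cells marginalizes *A* over a uniform 0–50 dB prior;
  its Shannon entropy *H* = −Σ p log₂ p measures the remaining
  directional uncertainty, and (2π/*N*)·2^*H* converts it to an angular
  resolution in steradians.
- A perch-hunting Monte Carlo converts prey distance to echo strength via
  the sonar equation (105 dB call at 0.1 m, two-way spreading, ISO 9613-1
  atmospheric absorption, −40 dB target strength, 12 dB ear gain) and
  averages the expected entropy over 1000 random prey within a 1–5 m
  foraging radius.

Synthetic per-frequency directivity fields (Gaussian main lobes with
beamwidth ∝ λ/aperture, rippled sidelobe skirts, offset ear axes, and a
two-isotropic-source control emitter with 4.2 mm spacing) stand in for
specimen-specific simulated fields, so the whole analysis runs from code
alone. See the methods vignette (`vignettes/pinna-sonar-model.Rmd`) for
the model, its assumptions, and every default.

## Worked example

```r
library(pinnasonar)

partition <- partition_hemisphere(256)
cov <- build_covariance(sigma_db = 5, lag_corr = 0.2, interaural_corr = 0.9)

head <- synthetic_head("focused")
fields <- head_fields(head, 80, partition)
templates <- build_templates(fields$emission, fields$hearing_left,
                             fields$hearing_right)
templates
#> <template_set> 256 cells x 14 elements at 80 kHz (max raw gain 15.72 dB)

em <- entropy_map(templates, cov, snr_grid_db = c(15, 25, 35),
                  n_realizations = 20, seed = 1)
entropy_summary(em)
#> # A tibble: 3 × 4
#>   frequency_khz snr_db mean_entropy_bits range_entropy_bits
#>           <dbl>  <dbl>             <dbl>              <dbl>
#> 1            80     15              7.21               7.53
#> 2            80     25              6.65               7.87
#> 3            80     35              6.16               7.87
```

At 80 kHz the hemisphere-averaged entropy falls from 7.21 bits for weak
(15 dB) echoes toward 6.16 bits at 35 dB, but the worst-minus-best range
across directions is nearly the full 8 bits: the focused beam localizes
central echoes precisely while peripheral ones stay at chance. For a
strong echo from straight ahead the posterior collapses:

```r
h <- expected_entropy(1, templates, cov, a_db = 35, seed = 1)
round(h, 2)
#> [1] 0
round(angular_resolution(h, 256), 3)
#> [1] 0.025
```

0 bits of residual uncertainty — an effective resolution of one cell
(2π/256 ≈ 0.025 sr). `autoplot(em)` maps the entropy over the hemisphere;
`run_pipeline(run_config(), out_dir)` chains fields → templates → entropy
maps → perch hunt and writes tidy CSVs plus a JSON manifest.

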