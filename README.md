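# petiqdose

Choosing a small-animal PET reconstruction by its image-quality and
dosimetry consequences — a desk-scale, fully synthetic implementation of
the whole decision chain for Cu-64 immuno-PET.

Image-based internal dosimetry reads activity off reconstructed images,
so the reconstruction algorithm and filter propagate straight into the
reported dose: across a standard configuration family (filtered back
projection under six apodization windows, OSEM with 16 subsets at
iterations 1–10, MAP-EM at several smoothing strengths β), tumor
absorbed-dose estimates for the same animal can differ by a factor of
two.  `petiqdose` provides, in one package:

* a **NEMA NU4-2008 image-quality phantom simulator** (30 mm cylinder,
  1–5 mm hot rods, air/water cold chambers; 128 × 128 × 159 grid at
  0.776 × 0.776 × 0.796 mm³, 3.7 MBq) with a 2D parallel-beam projector,
  attenuation, detector blur, convolution scatter, and Poisson noise;
* **reconstruction**: FBP (ramp, Butterworth, Hamming, Hanning, Parzen,
  Shepp–Logan windows at cutoff 0.5 × Nyquist), OSEM (non-negative,
  attenuation/scatter in the forward model), one-step-late MAP-EM with a
  quadratic prior, Gaussian post-filters;
* the **NU4 metrics**: recovery coefficient RC = peak/true per rod,
  non-uniformity NU = 100·SD/mean in a 22.5 × 10 mm VOI, spill-over
  ratio SOR = cold-VOI mean / uniform mean;
* the **selection criterion** `0.9 < RC(3 mm) < 1.0` and `NU < 10 %`
  (strict inequalities) on the RC–NU trade-off;
* the **MIRD dosimetry chain**: decay-uncorrected time–activity curves
  (Cu-64, T½ = 12.7 h), cumulated activity Ã (trapezoid + physical-decay
  tail), residence time τ = Ã/A₀, sphere-model tumor dose τ·S(m) with a
  power-law S(m) = a·mᵇ fit, weighted organ doses;
* a **comparison engine** expressing dose tables as symmetric percent
  differences `200·(x − ref)/(x + ref)` against a gold-standard column.

All inputs are synthetic or packaged plain-text tables; nothing is
downloaded.  See the methods vignette
(`vignettes/reconstruction-selection-dosimetry.Rmd`) for the model,
conventions, and limitations.

## Worked example

Reproduce the percent-difference analysis from a packaged dose table
(tumor in mGy/MBq, organs in mSv/MBq; OSEM2D iteration 1 as the gold
standard):

```r
library(petiqdose)

t1 <- read_dose_table()                      # 24 regions x 19 configurations
cmp <- compare_to_reference(t1, "osem2d_it1", rounded = TRUE)
cmp[cmp$region %in% c("Tumor", "Kidneys"),
    c("region", "fbp_butterworth", "osem2d_it10")]
#> # A tibble: 2 × 3
#>   region  fbp_butterworth osem2d_it10
#>   <chr>             <dbl>       <dbl>
#> 1 Tumor             -35.4        32.4
#> 2 Kidneys           -20.9       155.
```

Iterating OSEM to 10 overestimates the tumor dose by 32.4 % (the kidney
dose by 154.7 %) relative to the gold standard, while FBP with a
Butterworth window underestimates them by 35.4 % and 20.9 %.  The tumor
row spans almost a factor of two:

```r
range_spread(as.numeric(t1[t1$region == "Tumor", attr(t1, "config_columns")]))
#> # A tibble: 1 × 3
#>     min   max rel_spread_percent
#>   <dbl> <dbl>              <dbl>
#> 1   923  1830               98.3
```

The selection criterion that singles out OSEM2D iteration 1:

```r
entries <- tibble::tribble(~config, ~rc_3mm, ~nu_percent,
  "osem2d_it1_partial", 0.92, 7.0,
  "osem2d_it1_ac",      0.94, 7.1,
  "osem2d_it1_acsc",    0.70, 7.0)
tradeoff_table(entries)
#> # A tibble: 3 × 4
#>   config                rc nu_percent passes
#>   <chr>              <dbl>      <dbl> <lgl>
#> 1 osem2d_it1_partial  0.92        7   TRUE
#> 2 osem2d_it1_ac       0.94        7.1 TRUE
#> 3 osem2d_it1_acsc     0.7         7   FALSE
```

An RC of 0.92 with 7.0 % NU sits inside the acceptance box; once the RC
deteriorates to 0.70 the configuration fails at any NU.

End-to-end phantom study (simulate → reconstruct everything → score →
select), about a minute at the default scaled-down conditions:

```r
sim <- simulate_iq_study(seed = 42)          # 5e6 counts, metric slices
iq  <- run_iq_grid(sim)                      # 6 FBP + 10 OSEM + 3 MAP-EM rows
autoplot(tradeoff_table(iq))                 # RC-NU scatter with the red box
```

And the dosimetry chain on a synthetic tumor curve (values in %ID/g at
2/15/40/64 h; the S-value table is a synthetic power-law fixture):

```r
kin <- mouse_kinetics_spec()
tac <- generate_organ_tac(kin, timepoint_schedule(), "tumor")
tau <- residence_time_from_tac(tac)          # 0.394 h
fit <- fit_sphere_svalue(
  readr::read_csv(petiq_extdata("svalues_cu64_sphere_synthetic.csv")))
tumor_absorbed_dose(tau, mass_g = 0.2, fit)  # 127.3 mGy/MBq
```

A thin command-line veneer over the same functions lives at
`inst/cli/petiqdose.R` (`simulate | iq | select | dose | compare`).

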