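# utecine

Simulation and reconstruction of prospectively ECG-gated **3D radial
ultra-short echo-time (UTE) cine MRI** of the mouse heart with
ultrasmall superparamagnetic iron-oxide (USPIO) contrast agents — as a
fully self-contained, desk-scale R toolkit. No scanner or animal data are
needed: the package generates beating digital mouse-thorax phantoms,
simulates the raw k-space acquisition, reconstructs cine volumes and
measures the image-quality and cardiac-function numbers.

## Who this is for

Researchers developing or teaching non-Cartesian MRI reconstruction and
preclinical cardiac imaging protocols: the package lets you study, end to
end and reproducibly, how the block-of-4 gated radial encoding, the
Kaiser-Bessel gridding chain and the USPIO relaxivity mechanism interact —
before touching a spectrometer.

## The science in brief

USPIOs shorten both relaxation times: `1/T1 = 1/T1_0 + r1·C` and
`1/T2* = 1/T2*_0 + r2·C` (measured r1/r2 per mM Fe: 1.14/36.46 at 4.7 T,
1.13/65.21 at 7 T, 1.14/86.23 at 9.4 T). In a spoiled gradient echo,

    S = M0 · sin α · (1 − E1)/(1 − E1 cos α) · exp(−TE/T2*),  E1 = exp(−TR/T1),

so at ultra-short TE (0.031 ms, center-out radial readout starting at
k = 0) the `exp(−TE/T2*)` penalty is negligible and the T1 shortening
makes iron-loaded blood *bright* at any field strength — positive contrast
where a conventional echo time would lose it.

The gated encoding plays a block of 4 radial half-projections after each
ECG trigger and repeats it `floor(RR/(4·TR))` times per heartbeat;
directions follow a pole-to-pole spiral over the sphere. One acquisition
reconstructs either 10 high-spatial-resolution frames (all projections
each) or 40 high-temporal-resolution frames (one block slot each, 4× fewer
projections). Reconstruction is the standard gridding chain: radial
density compensation, Kaiser-Bessel gridding at 2× oversampling, inverse
FFT, deapodization, magnitude per coil, sum-of-squares combination.

## Worked example

```r
library(utecine)

# frame counts and scan time for the high-resolution cine protocol
g <- gating_params(rr_interval = 0.150, tr = 0.0035, block_size = 4)
frame_counts(g)
#> # A tibble: 1 x 2
#>   n_hsr n_htr
#>   <int> <int>
#> 1    10    40
predicted_scan_time(52540, g)
#> [1] 1970.25        # seconds = 32 min 50 s (13135 heartbeats x 150 ms)

# tissue signals at 7 T after 200 umol Fe/kg (TR 3.5 ms, TE 0.031 ms, 15 deg)
tissue_signals(field = 7, dose = 200)[, c("tissue", "conc", "t1", "t2s", "signal")]
#> # A tibble: 5 x 5
#>   tissue      conc    t1     t2s  signal
#>   <chr>      <dbl> <dbl>   <dbl>   <dbl>
#> 1 blood       2.60 0.295 0.00456 0.0633
#> 2 myocardium  0    1.6   0.01    0.0140
#> 3 muscle      0    1.5   0.015   0.0141
#> 4 liver       3.90 0.188 0.00264 0.0818
#> 5 lung        0    1.3   0.0015  0.00279
```

Blood T1 collapses from 2.2 s to 0.30 s while TE is too short for the
shortened T2* (4.6 ms) to matter — blood ends up ~4.5× brighter than
myocardium, where pre-contrast it was darker.

A full simulated experiment (phantom → schedule → acquisition → recon →
metrics), scaled to a 64³ matrix so it runs in about a minute:

```r
ex <- run_experiment("midres_cine", seed = 1, matrix = 64)
ex$metrics[1, c("snr_blood", "cnr_blood_myocardium")]
#>   snr_blood cnr_blood_myocardium
#> 1      33.1                 25.4
seed_vox <- round(c(1.5, -0.5, 0.6) / 20 * 64 + 32) + 1   # LV center voxel
function_report(ex$cine, seed_vox, threshold = 0.5)
#> # A tibble: 1 x 7
#>   chamber edv_ul esv_ul sv_ul ef_pct ed_frame es_frame
#> 1 lv        41.7   15.7  26.0   62.3        0        3
ground_truth_function(ex$phantom)  # analytic truth: LVEF 64.1%, LVSV 27.1 uL
autoplot(ex$cine, frame = 0)       # mid-thorax slice, ggplot2
```

The recovered ejection fraction (62.3 %) sits within two points of the
phantom's analytic ground truth; pre-contrast repeats of the same study
give *negative* blood-myocardium CNR (about −2 to −3).

A thin CLI wraps the same functions (`inst/cli/utecine`):

```sh
Rscript inst/cli/utecine run --preset midres_cine --matrix 64 --seed 1 --out-dir out/
Rscript inst/cli/utecine recon --raw out/raw.rds --mode htr --out cine_htr.nii.gz
```

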