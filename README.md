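# octspeckle

Estimation of the scattering coefficient μs and the scattering
anisotropy factor g of corneal stroma from the speckle statistics of a
single OCT B-scan.

Direct measurement of corneal scattering parameters normally requires
double-integrating-sphere or spectroscopic setups on excised tissue.
`octspeckle` implements an alternative that works on an ordinary OCT
image: a Monte-Carlo OCT simulator builds a **look-up map** of
reference B-scans over a grid of known (μs, g) pairs, and the unknown
scan is assigned the parameters of the reference its speckle statistics
match best. It is aimed at researchers in ocular imaging and tissue
optics who want a reproducible, fully scriptable implementation of the
simulator, the statistics, and the matcher.

## Method at a glance

1. **Photon transport** — packets traverse a layered slab
   (default: 600 µm stroma, n = 1.376, air above, aqueous humor below)
   by the multilayer hop/drop/spin scheme with Henyey–Greenstein
   scattering, probabilistic Fresnel boundaries, and a disc detector
   (radius 0.2 cm, 100 µm above the surface). The core is compiled
   (Rcpp) and traces ~10⁷ packets per second.
2. **A-scan synthesis** — detected packets become coherence-gated
   phasors: U(j) = Σᵢ √Wᵢ G(ΔLᵢⱼ) exp(i·2π·ΔLᵢⱼ/λ₀), with a Gaussian
   gate whose FWHM is the coherence length
   l_c = 2·ln2·λ₀²/(π·Δλ) (6.38 µm at 850/50 nm). The envelope |U|
   forms one column of a 223 × 40 B-scan; the top 193 rows (521 µm)
   are the analysis ROI.
3. **Speckle statistics** — the contrast ratio CR = sd/mean and a
   Gaussian kernel density estimate of the normalized ROI.
4. **Matching** — three distances against every reference:
   D_CR = |CR − CRₖ|, D_RMS = ∫(f̂ − f̂ₖ)² dx, and the
   Kullback–Leibler divergence D_KL = Σ p·ln(p/q). The three argmin
   grid pairs are averaged into the ensemble estimate (μ̂s, ĝ).

## Worked example

Build a reduced-budget look-up map (165 references at 10⁵ packets per
A-scan, a few minutes), generate a synthetic device-like scan at known
parameters, and estimate them back:

```r
library(octspeckle)

cfg <- oct_config(n_ascans = 40, n_packets = 1e5, seed = 1)
map <- build_map(parameter_grid(), cfg, master_seed = 2025)

f   <- make_fixture(0.15, 0.90, n_packets = 1e5, seed = 42)
roi <- locate_surface_and_roi(f$image, width_px = 40, depth_px = 193)
match_sample(speckle_summary(roi, "exp"), map)
#> <estimate_result>
#>   d_cr  min = 0.0031  ->  mu_s = 0.14, g = 0.85
#>   d_rms min = 0.5013  ->  mu_s = 0.20, g = 0.85
#>   d_kl  min = 7.8174  ->  mu_s = 0.20, g = 0.99
#>   ensemble: mu_s_hat = 0.180 mm^-1, g_hat = 0.897
```

The three rows are the per-distance minima and their picked grid
pairs; the last line is their ensemble average. The individual
distances carry visible biases (the published per-eyeball table shows
the same behaviour), which is exactly why three of them are ensembled:
here the estimate lands 0.03 mm⁻¹ / 0.003 from the true (0.15, 0.90)
at this strongly reduced budget, and the averaged recovery error over
many fixtures is about 0.03 in both parameters. A raw transport run
shows the detection bookkeeping:

```r
run_simulation(corneal_stack(0.1, 0.99), detector_spec(),
               n_packets = 1e6, seed = 7)
#> <transport_tally>
#>   launched:      1000000
#>   backscattered: 293 (0.0293%)
#>   detected:      289 (0.0289%)
```

At this weakest-backscatter grid corner about 0.03% of launched
packets return through the top surface and nearly all of those reach
the detector disc.

The published per-eyeball estimation table for porcine corneas ships
as plain text (`porcine_table()`), and `inst/scripts/octspeckle-cli.R`
wraps the same functions as `simulate` / `build-map` / `estimate` /
`make-fixture` subcommands for shell use.

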