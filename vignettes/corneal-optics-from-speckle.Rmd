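---
title: "Estimating corneal stroma optics from OCT speckle: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating corneal stroma optics from OCT speckle: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

The scattering coefficient $\mu_s$ and the scattering anisotropy factor
$g$ of corneal stroma are classically measured with double integrating
spheres or spectroscopy — techniques that cannot be applied in vivo.
OCT images of the cornea, however, carry a speckle pattern whose
statistics depend on the very same microstructural scattering
parameters. `octspeckle` implements a look-up-table inversion of that
relationship: a Monte-Carlo OCT simulator produces a library of
reference B-scans with *known* $(\mu_s, g)$, and an unknown scan is
assigned the parameters of the reference whose speckle statistics it
matches best, under an ensemble of three distance measures.

# The forward model

## Photon-packet transport

Photon packets are launched at the origin of the top surface of a
plane-parallel layered slab, pointing straight down (the beam is
modelled as infinitely thin; lateral resolution is not represented).
Transport follows the standard multilayer hop/drop/spin scheme:

* **hop** — step lengths are drawn from $s = -\ln(u)/\mu_t$ with
  $\mu_t = \mu_s + \mu_a$; in a non-scattering medium the packet moves
  straight to the next boundary;
* **drop** — a fraction $\mu_a/\mu_t$ of the packet weight is absorbed
  per interaction, with Russian roulette (threshold $10^{-4}$, survival
  chance $1/10$) terminating light packets. The corneal default is
  $\mu_a = 0$, which makes this machinery inert and keeps every weight
  exactly 1 — the speckle phasor amplitudes are then homogeneous;
* **spin** — deflection cosines are sampled from the Henyey–Greenstein
  phase function by its closed-form inverse CDF; azimuths are uniform.

Boundary events are *probabilistic*: at a refractive-index step the
unpolarized Fresnel reflectance $R$ is compared with a uniform draw and
the whole packet either specularly reflects or refracts by Snell's law
(total internal reflection beyond the critical angle). Whole-packet
boundary events, rather than weight splitting, are what preserve unit
weights at $\mu_a = 0$. Packets are launched just inside the tissue, so
no specular entry event is charged to the launch.

The default geometry is a single 600 µm stromal layer with $n = 1.376$,
air ($n = 1$) above and aqueous humor ($n = 1.33$) below. A packet
leaving the top surface is *backscattered*; it is *detected* if the
straight-line continuation of its refracted exit ray lands within a
disc of radius 0.2 cm placed 100 µm above the surface. This purely
geometric acceptance absorbs the (very low) numerical aperture of the
modelled spectral-domain system; no additional angular cut is applied.
Optical pathlength accumulates as geometric length × local refractive
index, so detected-packet delays are directly comparable with
reference-arm delays.

Each A-scan uses a private, counter-derived seed of a self-contained
xoshiro256++ stream, so A-scans are independent speckle realizations
and every run is reproducible bit for bit regardless of R's global RNG
state.

## Coherence-gated A-scan synthesis

Detected packets are summed as phasors of a common carrier. For depth
pixel $j$ at geometric depth $z_j = (j-1)\,\Delta z$ (axial pixel
$\Delta z = 2.7$ µm, 223 pixels ≈ 600 µm) the reference delay is
$L_{ref}(j) = 2 n z_j$ with $n = 1.376$, so tissue features land at
geometric depth on the pixel grid; the air path above the sample is
common to both interferometer arms and cancels. The complex amplitude
is

$$U(j) = \sum_i \sqrt{W_i}\; G(\Delta L_{ij})\,
  e^{\,i 2\pi \Delta L_{ij}/\lambda_0},
  \qquad \Delta L_{ij} = L_i - L_{ref}(j),$$

with a Gaussian coherence gate $G(\Delta) = \exp(-4\ln 2\,
(\Delta/l_c)^2)$ whose FWHM equals the coherence length
$l_c = 2\ln 2\,\lambda_0^2/(\pi \Delta\lambda)$ (6.38 µm for the
850/50 nm source). The raw signal $\mathrm{Re}\,U(j)$ oscillates about
zero with the carrier; the envelope is taken as $|U(j)|$ — equivalent
to demodulating the raw signal when all phasors share one frequency,
and numerically cleaner than a Hilbert transform. The Gaussian gate
shape and a unit reference-arm amplitude are this package's choices
(the normalizations downstream remove absolute scale); contributions
beyond six coherence lengths from a pixel are dropped (the gate is
below $10^{-30}$ there).

A B-scan stacks 40 independent A-scans. The analysis ROI keeps the top
193 pixels (521 µm): the deepest rows contain a bright specular flash
from the stroma–aqueous interface and are excluded.

# The inverse method

## Speckle statistics

Simulated ROIs are normalized by their maximum and then by the RMS of
the result (RMS becomes exactly 1; the statistic is scale free).
Experimental 8-bit ROIs are divided by 255, divided by their RMS, and
inverse-transformed with $y = 10^x$, undoing the device's logarithmic
display compression. Two statistics summarize an ROI:

* the **contrast ratio** CR = sample standard deviation / mean of the
  pixel amplitudes (the standard speckle-contrast definition, with the
  $n-1$ variance — the source work does not print a formula, so the
  definition is centralized and swappable);
* a **Gaussian kernel density estimate** of the pixel values with
  Silverman's rule-of-thumb bandwidth, evaluated on a shared, equally
  spaced grid of 512 points spanning $[0, 1.05\times$ the larger
  maximum of the two compared blocks$]$. Kernel, bandwidth and grid are
  likewise this package's recorded choices.

## Distances and the ensemble estimate

For each reference $k$ three distances are computed:
$D_{CR}(k) = |CR - CR_k|$; the integrated squared density difference
$D_{RMS}(k) = \int (\hat f - \hat f_k)^2 dx$ by trapezoid quadrature
(conventionally called an RMS error; the monotone square root is
omitted, leaving every argmin unchanged); and the discrete
Kullback–Leibler divergence $D_{KL}(k) = \sum_x p \ln(p/q)$ after both
densities are floored at $10^{-12}$ and renormalized to unit mass on
the grid, which keeps the divergence finite and non-negative. Each
distance is minimized over $k$ (first occurrence on ties, which are
reported), and the final estimate $(\hat\mu_s, \hat g)$ is the
arithmetic mean of the three picked grid pairs. The default grid spans
$\mu_s \in \{0.10, \ldots, 0.20\}$ mm⁻¹ (step 0.01) and
$g \in \{0.85, \ldots, 0.99\}$ (step 0.01): 165 references. Matching
is to grid nodes only; no interpolation is attempted.

Matching an entry's own summary returns that entry's parameters with
all three distances exactly zero, and any ensemble estimate lies inside
the grid's convex hull — both properties are asserted in the tests.

# What the synthetic fixtures emulate

The porcine image dataset behind the original study is not publicly
deposited, so the package ships a fixture generator that inverts the
experimental normalization: a simulated ROI is log10-compressed,
affinely mapped to the 8-bit range [40, 250], embedded below a
synthetic parabolic surface in a larger frame over a low-level noise
background, and returned together with its ground truth. This exercises
the full experimental path — surface detection, per-column ROI
flattening, `normalize_exp`, matching — and supports the recovery tests.
Fixtures do **not** emulate device shot/readout noise beyond a uniform
background, lateral beam width, corneal curvature of the *internal*
layers, epithelium, or motion artifacts; passing recovery tests
therefore demonstrates the consistency and resolving power of the
method under its own forward model, not clinical performance on real
corneas.

Apex detection is deliberately simple (threshold on raw intensity
confirmed by a leading running mean over the rows below, then the
middle of the run of minimal surface rows in the central third of the
frame); a `center_column` override bypasses it entirely.

# Numerical and scale choices

* **Photon budgets.** The reference operating budget is 15 million
  packets per A-scan, at which roughly 4.6×10³ packets are detected at
  the weakest-backscatter grid corner ($\mu_s = 0.1$ mm⁻¹,
  $g = 0.99$). The speckle contrast of the ROI decreases monotonically
  with budget and flattens: 0.71 at 15 M, 0.59 at 30 M, 0.55 at 60 M,
  0.53 at 120 M per A-scan (the doubling increment first falls below
  0.02 at 120 M). The acceptance script runs this ladder from the 15 M
  operating point, capped at 120 M.
* **Reduced scales.** The test suite builds its full 165-entry map at
  10⁵ packets per A-scan and its 2×2 smoke maps at 3×10⁴, sizes chosen
  so the whole suite completes in minutes while each entry still
  collects tens of detections per A-scan.
* **Detection-count trends.** Mean detected counts fall monotonically
  with $g$ at every $\mu_s$. They rise with $\mu_s$ wherever volume
  backscatter dominates ($g \lesssim 0.95$); along the $g = 0.99$ row
  the specular interface flash — which *attenuates* like
  $e^{-2\mu_s d}$ and makes up ~90% of detections there — cancels the
  volume trend, so the $\mu_s$ trend is asserted in aggregate across
  the map rather than per row.
* **Persistence.** Look-up maps are serialized with R's native
  serialization plus an explicit schema version; loading verifies the
  schema and reports found/expected versions on mismatch. Provenance
  (grid, seeds, budgets, source and detector specifications) travels
  inside the file so a map cannot silently be matched against a sample
  simulated under different system assumptions.
* **Open numerical details.** The numerical-aperture formula of the
  modelled device with a 20 µm transversal resolution evaluates to
  ≈ 0.019 rather than the sometimes-quoted 0.0159; the value is unused
  after the NA is normalized into the disc-detector geometry, so the
  discrepancy is recorded but has no effect.

# Known limitations

Gaussian beams and lateral resolution, corneal curvature, non-zero
$\mu_a$, polarization, a distinct epithelial layer, and
spectral-domain artefacts (k-space sampling, shot noise) are outside
the forward model. The density-based distances compare a 193×308-pixel
experimental ROI against 193×40-pixel simulated references; both widths
are configurable, and the sample-size imbalance of the kernel density
estimates is left to the user's judgement. The contrast-ratio distance
is strongly biased toward the high-contrast corner of the grid (as is
visible in the published per-distance picks); the ensemble over three
distances is what keeps the final estimate well behaved.
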