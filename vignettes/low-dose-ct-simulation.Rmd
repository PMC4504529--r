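---
title: "Low-dose CT simulation: model, calibration and validation design"
author: "ldctsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Low-dose CT simulation: model, calibration and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

This vignette is the package's account of the science it implements: the
measurement and noise-insertion model, the calibration loop, what the
digital phantoms do and do not emulate, the numerical choices, and the
limitations a user should know before trusting a simulated scan.

## The measurement model

A CT projection measurement for one detector ray is modeled in the count
domain. With line integral $p$ of the linear attenuation coefficient
$\mu = \mu_w (1 + \mathrm{HU}/1000)$ and an incident photon budget
$N_0 = \text{eff.mAs} \times k$ (with $k$ photons per ray per eff. mAs),
the expected detected count is $\lambda = N_0 e^{-p}$ and the recorded
projection is

$$\hat p = -\log\!\big(\max(N, \varepsilon)/N_0\big), \qquad
  N \sim \mathrm{Poisson}(\lambda) + \mathcal N(0, \sigma_e^2).$$

Two noise sources enter: quantum noise from the finite photon count and
Gaussian electronic noise of the data-acquisition system, added in the
count domain *before* the log because that is where detector electronics
act. The delta method gives the per-ray projection variance

$$\mathrm{Var}[\hat p] \;\approx\; \frac{1}{\lambda} + \frac{\sigma_e^2}{\lambda^2},$$

whose two terms explain the regimes that matter clinically: at normal
doses $1/\lambda$ dominates and image noise follows the familiar
$1/\sqrt{\text{mAs}}$ law; at ultra-low doses the $\sigma_e^2/\lambda^2$
term takes over and noise grows faster than the square-root law predicts.
`acquire()` implements this chain; the clipping floor
$\varepsilon = 1$ count guards the log against photon starvation, and
more than 1% of clipped rays raises a warning (an error in strict mode).

## Noise insertion

`insert_noise()` converts a measured sinogram into a simulated scan at
dose fraction $\alpha \le 1$. The per-ray count is estimated from the
measurement itself, $\hat\lambda = N_0 e^{-\hat p}$ (the plug-in choice:
the true $p$ is unknown in practice), the target count is
$\lambda_\alpha = \alpha \hat\lambda$, and zero-mean Gaussian noise is
added in the line-integral domain with the ray-dependent variance gap

$$\sigma^2_\text{ins} \;=\; c \left(\frac{1}{\lambda_\alpha} +
  \frac{\sigma_e^2}{\lambda_\alpha^2}\right) -
  \left(\frac{1}{\hat\lambda} + \frac{\sigma_e^2}{\hat\lambda^2}\right),$$

clamped at zero (near $\alpha = 1$ the gap can go marginally negative;
noise is never removed). The insertion is unbiased
($E[\hat p'] = \hat p$), which is what preserves mean attenuation in the
reconstructions, and to first order the output matches a direct
acquisition at $\alpha N_0$ — the property the whole package exists for,
and the one its validation suite checks hardest.

A second mode honors the count-domain intuition directly: binomial
thinning $N' \sim \mathrm{Binomial}(N, \alpha)$, which maps Poisson
counts to exact Poisson counts at $\alpha\lambda$, with the electronic
component (scaled by $\alpha$ in the thinning) topped up by an
independent Gaussian of variance $\sigma_e^2 (1 - \alpha^2)$. Both modes
are tested against the direct-acquisition oracle; the Gaussian mode is
the default because its calibration factor acts on the full inserted
variance rather than on a correction term.

Dose increase ($\alpha > 1$) is refused: there is no information in the
data to undo noise.

## Calibration

The factor $c$ (nominally 1) absorbs everything the first-order model
does not capture. `calibrate()` reproduces the automated water-phantom
procedure: acquire a 20-cm water cylinder at the reference protocol
(200 eff. mAs), measure the image noise as the SD of a central 5-cm ROI
in the reconstruction, predict the expected noise at the 6.25% target
dose from the variance model, then iterate — insert noise at
$\alpha = 0.0625$, reconstruct, measure, and update

$$c \leftarrow c \cdot
  \frac{\mathrm{SD}^2_\text{target} - \mathrm{SD}^2_\text{full}}
       {\mathrm{SD}^2_\text{meas} - \mathrm{SD}^2_\text{full}}$$

until the achieved SD is within 1% of the target (at most 20 iterations).
Because reconstruction is linear, the inserted image variance is
proportional to $c$ and the update is a one-step solve up to Monte-Carlo
noise; in practice it converges in about 3 iterations even from a
four-fold variance mis-scale. Each iteration reuses the same
iteration-fixed seeds (8 insertions, averaged), which makes the loop a
deterministic contraction for a given root seed.

The predicted target SD scales the measured full-dose SD by the root of
the per-ray variance ratio averaged over the rays that traverse the
central ROI, not over all rays: the ROI noise is a functional of exactly
those rays, and with $\sigma_e > 0$ the variance ratio depends on
$\lambda$, so the global average would be biased (we measured a ~5%
offset in the fixed point before restricting). With $\sigma_e = 0$ the
ratio is $1/\alpha$ for every ray and the prediction reduces to the
$1/\sqrt{\alpha}$ law — at 6.25% target dose, four times the full-dose
noise.

The electronic noise level itself is *not* calibrated: $\sigma_e$ is
treated as a known protocol constant, as it is measurable on a real
scanner from air scans without X-ray.

## Phantoms and what they emulate

Two digital phantoms drive everything; both are piecewise-constant HU
maps sampled at pixel centers, so their histograms contain exactly the
specified material values and generation is bit-deterministic.

* **Water calibration phantom** — a 20-cm cylinder of water (0 HU) in
  air, the geometry the calibration loop and the noise-law checks use.
* **Head phantom** — a soft-tissue ellipse (40 HU, semi-axes
  70 × 88 mm) with a 6-mm skull ring (1200 HU) and two pairs of
  contrast-filled tubes (16 mm diameter) attached laterally, one pair
  per dilution. The dilution-to-HU mapping (3% → 290 HU, 4% → 370 HU)
  is chosen so the pooled tube mean is exactly 330 HU, the enhancement
  level of the contrasted neck vessels the tubes stand in for; the
  mirror-symmetric placement makes the four pixel masks congruent, so
  the pooled mean is exact, not approximate. Skull and tissue values are
  typical-literature choices; tube positions and diameters are
  plausible defaults, configurable in `phantom_spec()`.

The reduction from the physical 3-D phantom to a single 2-D slice is
deliberate: the noise-insertion claims concern photon statistics per
ray, not helix geometry, and the study's ROI analysis is per-slice
anyway. Likewise the scanner model is monoenergetic parallel-beam, so
beam hardening, bowtie filtration, tube-current modulation, scatter and
detector crosstalk are all outside the model. Passing tests therefore
demonstrate the statistical correctness of the insertion contract under
ideal projection physics — not vendor-grade realism on clinical raw
data.

## Scanner and reconstruction numerics

*Forward projection* is a distance-driven-style splat: each pixel's
footprint on the detector is a rectangle of width
$\Delta x (|\cos\theta| + |\sin\theta|)$ and each bin receives its exact
overlap fraction. The footprint width equals the projected pixel pitch
at axis-aligned views, which cancels the lattice/detector Moiré ripple
that a point-splat projector exhibits (and which a ramp filter amplifies
into tens of HU of pseudo-noise); mass is conserved at every angle.

*Reconstruction* is filtered backprojection: the discrete band-limited
ramp is built in the spatial domain (avoiding the DC bias of a naively
sampled $|f|$), apodized by a Hann window by default — the stand-in for
a proprietary soft-tissue kernel, whose exact modulation transfer is not
public — with Shepp–Logan and pure ramp available. Backprojection uses
linear interpolation on pixel-centered coordinates, origin at the grid
center. The noiseless round trip leaves about 0.5 HU of artifact SD at
the default geometry, against noise levels of 10–45 HU in the studied
regimes.

Because backprojection is per-pixel, `fbp()` accepts a pixel mask and
reconstructs only those pixels, bit-identically to the full image. The
validation suite uses this to afford 60 noise realizations per dose
level; the equality of masked and full reconstructions is itself a
tested invariant.

Default sizes: phantoms 512 × 512 over a 250 mm field of view; sinograms
360 views over 180° × 600 bins; reconstructions 256 × 256 over the
180 mm reconstruction field of view. Slice thickness and increment are
carried as metadata only in 2-D.

## Key parameters

| parameter | default | meaning |
|---|---|---|
| `photons_per_mas` | 5300 /ray/mAs | sets the photon budget; anchored so the 20-cm water phantom at 200 eff. mAs reconstructs with ~10 HU central-ROI SD, a typical soft-kernel noise level |
| `sigma_e` | 20 counts | electronic noise SD; negligible (<1%) at full dose, a clear (~11%) excess over the square-root law at the 6.25% dose level |
| `eff_mas` | — | effective tube current–time product; dose and $N_0$ are proportional to it |
| `alpha` | — | simulated dose fraction, in (0, 1] |
| `calib_factor` | 1 | multiplier on inserted variance, fixed by `calibrate()` |
| `mu_water` | 0.019 mm⁻¹ | water attenuation for HU conversion, used identically in projection and reconstruction |

## The validation experiment

`run_phantom_experiment()` mirrors the physical protocol: true scans at
$\alpha \times 160$ eff. mAs versus simulations derived from the
160 eff. mAs reference, at $\alpha \in \{1, 0.75, 0.5, 0.25\}$, with 10
ROIs in the contrast tubes (5 per dilution). One physical scan per level
has no statistical power on a desk, so each level is realized
`n_realizations` times (default 10; the validation suite uses 60), with
every random stage drawing from a named substream of one root seed —
reports are byte-reproducible.

Two design points deserve a note:

* The tube ROIs default to 40% of the tube cross-section, placed
  centrally. At the two-thirds-area convention used for patient vessel
  lumina, the ROI rim sits within the reconstruction kernel's
  edge-spread region of the tube wall and the deterministic edge
  gradient (~65 HU) swamps the noise the ROI is supposed to measure;
  40% keeps every ROI clear of it. The two-thirds convention remains
  available via `head_phantom_rois(area_fraction = 2/3)`.
* ROIs within one tube overlap, so their SDs measured on the same
  realization are correlated and a paired sign test across ROIs would
  see correlated signs. The experiment therefore assigns each ROI its
  own disjoint block of realizations for the sign-test comparison,
  making the ten paired signs independent under the null. The
  Mann–Whitney comparison of mean attenuation uses one pooled tube mean
  per realization and arm as its sampling unit for the same reason.

Degenerate inputs are refused loudly: dose fractions outside (0, 1],
ROIs leaving the image or the field of view, overlapping tubes,
non-square grids, reconstruction fields of view beyond the scanned
support, all-tied sign tests (p = 1 with a warning), and
single-category κ (undefined, flagged rather than coerced to a number).

## Statistics

The comparison toolkit is implemented from first principles with
brute-force oracles in the tests: the exact two-sided sign test
(ties dropped, doubled smaller binomial tail, capped at 1), the
Mann–Whitney U with midranks (exact by enumeration of all
$\binom{n_1+n_2}{n_1}$ assignments for $n_1 + n_2 \le 12$, normal
approximation with tie and continuity correction above), and unweighted
Cohen's κ with the conventional agreement bands (≤0 none, to 0.2 slight,
to 0.4 fair, to 0.6 moderate, to 0.8 substantial, above almost perfect).
The reader-study module books scores on a segment × patient × dose-level
ledger in which an exclusion (an occluded or resected vessel cannot be
scored at any dose) removes the pair at every dose level — 34 excluded
pairs over 40 × 30 × 4 cells leave 4664 of 4800 scorable. Its synthetic
score generator (latent quality $a \log \mathrm{SNR}$ plus reader noise,
rounded onto the 1–5 scale) is a fixture for exercising the bookkeeping
and agreement statistics; it models no actual human reader.

## Known limitations

* Monoenergetic parallel-beam physics: no spectra, bowtie, scatter,
  tube-current modulation or cone-beam geometry; conclusions transfer to
  the photon-statistics contract, not to vendor raw-data pipelines.
* The plug-in $\hat\lambda$ inherits the measurement's noise; at extreme
  starvation (clipped rays) the insertion contract degrades — hence the
  starvation guard.
* The Hann-apodized kernel approximates a proprietary soft kernel's
  noise behavior, not its exact modulation transfer function.
* Iterative reconstruction is intentionally out of scope; all claims are
  about filtered backprojection.
* A single global calibration factor is used; per-channel calibration is
  not modeled.
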