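# ldctsim

Simulation of reduced-dose CT scans by inserting properly scaled quantum
and electronic noise into projection data, together with the digital
phantoms, reconstruction chain and statistical machinery needed to
validate the simulation against true low-dose acquisitions.

## The problem

Prospective comparisons of CT protocols at several dose levels would
require scanning the same patient repeatedly — ethically untenable and,
for contrast-enhanced angiography, technically compromised by bolus
timing. Dose simulation sidesteps this: a single full-dose acquisition is
degraded *in the raw-data (sinogram) domain* so that the result is
statistically equivalent to a scan acquired at a fraction α of the dose.
Radiologists and physicists can then study dose reduction on matched
images of the same anatomy.

## The model

CT projection noise has two principal sources. For a detector ray with
line integral *p*, the expected detected count at incident photon budget
`N0 = eff_mas × photons_per_mas` is

    λ = N0 · exp(−p)

and the measurement chain records

    N ~ Poisson(λ) + Normal(0, σ_e²),   p̂ = −log(max(N, ε) / N0)

with σ_e the electronic noise of the data-acquisition system (a known,
measurable scanner constant) and ε a photon-starvation floor. To first
order, `Var[p̂] = 1/λ + σ_e²/λ²`: quantum noise dominates at clinical
doses, electronic noise at ultra-low doses.

Dose simulation at fraction α estimates the per-ray count from the
measurement itself (`λ̂ = N0·e^{−p̂}`) and adds zero-mean noise whose
variance is the gap between a direct acquisition at `λ_α = α·λ̂` and the
noise already present:

    Var_inserted = c · (1/λ_α + σ_e²/λ_α²) − (1/λ̂ + σ_e²/λ̂²)

The insertion is unbiased, so attenuation values (HU) are preserved while
image noise scales as it would in a true low-dose scan (as `1/sqrt(α)` in
the quantum regime). A binomial count-thinning mode is also provided;
both modes are checked against direct low-dose acquisitions. The
dimensionless factor *c* (nominally 1) is fixed by an automated
calibration loop on a 20-cm water phantom: insert noise at a 6.25% target
dose, reconstruct, measure the central 5-cm ROI standard deviation and
rescale *c* until the noise matches the level predicted by the variance
model, to 1% in a handful of iterations.

The package also contains the validation study around the method: a head
phantom with contrast-filled tubes (two dilutions, pooled mean 330 HU)
emulating neck vessels, filtered backprojection with a soft
(Hann-apodized) kernel, ROI mean/SD/SNR analysis replicated across
matched dose series, a segment × patient × dose-level quality-score
ledger with dichotomization, and the exact sign test, Mann–Whitney U test
and Cohen's κ used to compare true and simulated series.

## Worked example

```r
library(ldctsim)

phantom  <- make_water_phantom(diameter = 200, grid_size = 512, fov = 250)
protocol <- scan_protocol(eff_mas = 200)
protocol
#> <scan_protocol> 100 kV, 200 eff.mAs, N0 = 1.06e+06 photons/ray, sigma_e = 20

sino_full    <- acquire(phantom, protocol, seed = 42)
sino_quarter <- insert_noise(sino_full, noise_model(alpha = 0.25), seed = 43)
sino_quarter
#> <sinogram> 360 views x 600 bins, bin 0.417 mm, noisy, 50 eff.mAs

img_full    <- fbp(sino_full,    kernel = "hann", fov = 180, grid_size = 256)
img_quarter <- fbp(sino_quarter, kernel = "hann", fov = 180, grid_size = 256)

roi <- roi_spec(0, 0, diameter = 50, label = "central")
replicate_rois(list(roi), list(full = img_full, quarter = img_quarter))
#>     image   label    mean    sd      snr n_pixels snr_defined
#> 1    full central -0.0103  9.91 -0.00104     3972        TRUE
#> 2 quarter central -0.1509 20.60 -0.00732     3972        TRUE
```

The mean attenuation stays at water (0 HU) while the ROI noise rises
from 9.9 to 20.6 HU — a ratio of 2.08, the `1/sqrt(0.25)` law up to
Monte-Carlo scatter of this single realization.

The full validation experiment (true scans at 160·α eff. mAs versus
simulations derived from the 160 eff. mAs reference, 10 tube ROIs,
sign tests on noise and Mann–Whitney on attenuation) is one call:

```r
report <- run_phantom_experiment(experiment_config(seed = 1))
report$tests
```

A command-line interface wrapping the same functions is in
`inst/scripts/ldct.R` (`phantom`, `scan`, `simulate-dose`, `calibrate`,
`recon`, `roi`, `experiment`, `stats` subcommands).

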