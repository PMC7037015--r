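---
title: "Models and numerical methods in zsrelax"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical methods in zsrelax}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zsrelax)
```

## Scope and signal model

`zsrelax` simulates arrayed relaxation experiments on weakly coupled
proton spin systems and fits the resulting intensity decays. Two
acquisition modes are modelled:

**Conventional acquisition.** Every site contributes its first-order
multiplet, every z isochromat its local field offset:

$$ s(t) \;=\; \sum_{\text{sites}} n_{eq}\, w_s \sum_{\text{lines}} a_\ell
   \,\Big\langle e^{\,i 2\pi (\nu_s + \delta_\ell + \delta_z) t}\Big\rangle_z
   \, e^{-t/T_{2,s}} $$

where $w_s$ is the per-site relaxation weight of the arrayed experiment:
$w_s(\tau_1) = 1 - (1+\epsilon)\,e^{-\tau_1/T_{1,s}}$ for inversion
recovery with inversion efficiency $\epsilon$ (the ideal $\epsilon = 1$
gives the textbook factor $1 - 2e^{-\tau_1/T_1}$), and
$w_s(\Delta) = e^{-\Delta/T_{2,s}}$ for CPMG. During the CPMG train we
take the ideal short-interval limit $\tau_2 \ll 1/J$: chemical shift,
field inhomogeneity and J modulation are treated as fully refocused, so
only the intrinsic $T_2$ decay survives. Finite-$\tau_2$ residual J
modulation is a stated non-goal.

**Real-time pure-shift acquisition.** The acquisition window
$t_1 = n\,\tau_c$ is cut into a leading half chunk, $n-1$ full chunks of
duration $\tau_c$, and a trailing half chunk. Between chunks an
instantaneous decoupling element (hard π on all spins followed by a
selective π on the active spin in its slice) inverts the passive coupling
partners, so scalar-coupling evolution is refocused at every chunk
midpoint while chemical-shift phase accumulates continuously. In closed
form, within the chunk whose refocusing midpoint is $t_m(k)$:

$$ s(t_1) = \sum_{\text{sites}} f_s\, n_{eq}\, w_s\,
   e^{\,i2\pi(\nu_s + \delta_{z_s}) t_1}\, e^{-t_1/T_{2,s}}
   \prod_{\text{partners}} \cos^{\,n_p}\!\big(\pi J (t_1 - t_m(k))\big)
   \cdot \lambda^{\,k} $$

$f_s$ is the slice volume fraction of the site, $\delta_{z_s}$ the
(small) field-inhomogeneity offset at the slice center, and $\lambda$ a
per-element amplitude retention (default 1). The half chunks at the ends
put refocusing midpoints at $t_1 = 0$ and $t_1 = t_{1,\max}$. The
residual in-chunk cosine ripple is periodic with period $\tau_c$, which
is exactly why chunking sidebands appear at $\pm k/\tau_c$ around each
singlet; the test suite verifies both the sideband positions and their
exact cancellation when all $J = 0$.

The closed form is not taken on faith: a brute-force oracle in the test
suite propagates the full 4×4 density matrix of an AX pair in ≤ 10 µs
steps under the secular weak-coupling Hamiltonian with ideal pulses, and
the closed-form FID agrees with it to better than $10^{-6}$ per point.

**Assumptions inherited from the model.** Weak coupling only (the
constructor warns when $|\Delta\nu| < 5J$); equivalent protons within a
site do not split each other; antiphase terms are not tracked past
acquisition; radiation damping, diffusion, intermolecular NOE, chemical
exchange and B1 inhomogeneity are ignored. Coherence-selection gradients
are modelled as an ideal pathway filter — only the intended pathway
survives — because that is their sole role in the sequence.

## Slice geometry and its calibration

Under the weak gradient $G_4$ the slice for a resonance at offset $\nu$
(relative to the carrier) is centred at $z = \nu/(\gamma G_4)$ with width
$BW/(\gamma G_4)$, where the selective pulse's effective inversion band
is idealized as a top-hat of width $BW = K/\text{duration}$. The
detected volume fraction is $\min(\text{width}, L)/L$.

The default $K = 0.84$ is the Gaussian-envelope FWHM heuristic. With the
published bromobutane settings (16.2 ms pulse, $G_4 = 0.56$ G/cm,
$L = 1.5$ cm) this gives a slice fraction of about 1.5%, whereas
sensitivities of roughly 5–10% of conventional are reported for such
experiments. The effective-bandwidth convention behind those figures is
not stated, so we treat $K$ as an open calibration knob
(`slice_pulse(duration, bandwidth_factor)`) rather than tune it; all
quantitative round trips in this package are insensitive to $K$ because
peak heights are normalized per site by the fit amplitude.

Field inhomogeneity defaults to a linear profile, `offset = slope * z`,
emulating a deliberate linear-shim offset; the full-sample spread is then
exactly `slope * L`, which is how the deshimmed-line-width round trip
calibrates the slope (e.g. 177.35 Hz over 1.5 cm). An arbitrary
`inhom_profile` function can replace the linear law. Isochromats are
placed on an inclusive uniform grid over $[-L/2, L/2]$ with equal
weights; `n_z` is purely a quadrature resolution knob (1 for
well-shimmed work, a few hundred for smooth inhomogeneous lineshapes).

## Reconstruction choices

`fid_to_spectrum()` applies optional exponential apodization
$e^{-\pi\,lb\,t}$, halves the first FID point, zero-fills to
`zero_fill` times the next power of two, Fourier transforms, and
presents descending ppm axes. Two choices deserve explanation:

- **First-point halving (default on).** The discrete transform of a
  truncated decay leaves a flat baseline of $s(0)/2$ across the whole
  spectrum. In an arrayed experiment that baseline varies with the delay
  as the *sum* of all sites' weights, so it contaminates every tracked
  peak height with a multi-exponential term. Halving the first point
  removes it; without this correction the many-site round-trip error
  rises from under 0.05% to over 1% for weak fast-relaxing sites. It is
  switchable off for identities (e.g. Parseval) that assume the raw
  transform.
- **Signed real-part heights.** Intensities are read from the phased real
  spectrum at fixed positions (linear interpolation between grid points),
  never from magnitude spectra. This preserves the negative early IR
  points and the null crossing, on which the 3-parameter IR fit relies.

Reference peaks are picked once, on the series member with the largest
total signal magnitude — the fully recovered last IR spectrum, the
shortest-delay first CPMG spectrum — and their positions are then held
fixed across the array. Because the lineshape of a noiseless site does
not change across the array, the tracked height is exactly linear in the
relaxation weight, which is what makes sub-0.1% parameter recovery
possible irrespective of truncation or sideband structure. Half chunks
are kept at native weighting (no reweighting); peak positions are refined
by three-point parabolic interpolation; FWHM is measured by walking
outward from the maximum to the linearly interpolated half-height
crossings.

## Fitting

`fit_ir()` fits $I(\tau) = I_0(1 - (1+w)e^{-\tau/T_1})$ by
Levenberg–Marquardt least squares (`minpack.lm::nlsLM`). The efficiency
$w$ floats by default because the exact inversion performance of any real
experiment is unknown; `fix_efficiency = TRUE` pins $w = 1$, and on ideal
noiseless data both give identical $T_1$. Starting values: $I_0$ from the
last (most recovered) intensity, $T_1$ from the interpolated zero
crossing divided by $\ln 2$ (an exact-zero datum is taken as the null
delay directly — the tie-break); $w = 1$. `fit_cpmg()` fits
$I(\Delta) = I_0 e^{-\Delta/T_2}$ with starting values from a log-linear
regression restricted to points above 5% of the maximum (log of near-zero
intensities is noise-dominated).

Reported uncertainties are asymptotic standard errors from the
residual-scaled Jacobian covariance, matching the usual "±" convention of
per-proton relaxation tables; a residual bootstrap (`n_boot`) is
available and agrees with the asymptotic errors within a factor of ~3 at
1% noise. Degenerate inputs (all-zero or constant intensities, solver
failure, non-positive fitted time) return `converged = FALSE` rather
than raising; genuinely unusable inputs (too few points, NA, length
mismatch) raise errors. `relaxation_table()` joins IR and CPMG fits by
peak position with a 0.02 ppm tolerance and reports, never silently
drops, unmatched peaks.

## What the fixtures emulate — and what they do not

The three built-in systems mirror published per-proton measurements:
1-bromobutane (the 3.42 ppm site carries the published 4.99 s / 2.77 s;
the other shifts, relaxation times and the 7 Hz vicinal J chain are
plausible inventions, tagged `"invented"` in `$meta$provenance`), quinine
(18 resonances, literature shifts and relaxation times; J set to zero
because the values are measured on decoupled singlets, with an optional
invented coupling network), and azithromycin (25 singlet resonances).
Where a conventional-experiment value is also published (quinine protons
6 and 7; azithromycin 7′, 8′, 7″, 8″) a `variant = "conventional"`
fixture carries it. The acquisition bundles reproduce the printed delay
grids, chunk counts (40 × 20 ms and 30 × 20 ms), spectral widths,
selective-pulse durations and G4 amplitudes; carriers are placed
mid-range of each sample's shifts so the printed spectral width contains
all resonances.

The noise model adds independent Gaussian perturbations to the real and
imaginary channels, scaled by the largest magnitude across the series so
that late weak members get the same absolute noise floor as early ones,
and is deterministic under its seed. What passing tests on these
synthetic data do **not** show about real data: strong-coupling
(second-order) multiplets, pulse imperfections and finite element
durations (summarized only by `per_element_loss`), receiver artifacts,
baseline drift, and literature-accurate coupling networks for the two
complex samples. The simulated sinusoidal baseline distortion from
chunking sidebands is qualitatively, not quantitatively, comparable to
experiment.

## Numerical conventions and problem sizes

- Time grids start at $t = 0$ with dwell `1/spectral_width_hz`; the dwell
  must divide the chunk duration (checked to 1e-9 relative), and CPMG
  delays must be integer multiples of τ2 at the same tolerance.
- Frequencies are relative to a configurable carrier
  (`field_model(carrier_ppm = ...)`); ppm axes are presented descending;
  Hz axes are absolute (relative to 0 ppm) so that `hz = ppm × MHz`.
- The weak-coupling warning threshold is $|\Delta\nu| \ge 5J$.
- Simulation sizes in the test suite are chosen for speed at full
  fidelity of the published grids: single-isochromat well-shimmed
  synthesis for recovery tests, 301–801 isochromats for inhomogeneous
  lineshapes, 4 s conventional acquisitions for the many-site quinine
  round trip (letting every line decay below truncation-ripple level),
  and a 5–6-chunk window for the density-matrix oracle. The full suite
  runs in well under a minute.

## Known limitations

First-order multiplets only; no explicit Bloch simulation of shaped
pulses (top-hat inversion band); no gradient-dephasing simulation for the
coherence-selection gradients; zero-order phasing only (the simulators
produce zero-phase data by construction); no baseline correction,
reference deconvolution or sideband suppression; no multi-exponential or
stretched-exponential fitting; proprietary raw spectrometer directories
are not read (CSV/JCAMP-DX and the YAML config are the interchange
formats).
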