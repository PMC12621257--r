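---
title: "Methods: spectral similarity scoring and geometry benchmarking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral similarity scoring and geometry benchmarking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uvvisbench)
```

## Scope and model

`uvvisbench` scores quantum-chemistry predictions of metal complexes
against experimental references on two axes.

**Spectral axis.** A set of vertical transitions $\{f_i, E_i\}$
(oscillator strengths, transition energies in eV) is convolved into a
continuous band spectrum by shifted Gaussian broadening,

$$I^{\mathrm{comp}}(E;\delta,\sigma)
  = N \sum_i f_i\,
    \exp\!\left(-\frac{(E - E_i + \delta)^2}{2\sigma^2}\right),$$

with $N$ normalizing the maximum on the evaluation grid to one. The same
width $\sigma$ and shift $\delta$ apply to every transition: the model
assumes a single effective band width and a single systematic energy error
per method/compound pair. A positive $\delta$ moves all bands to lower
energy. Agreement with the conditioned experimental spectrum
$I^{\mathrm{exptl}}$ over a window $[E_1, E_2]$ is the cosine similarity

$$S(\delta,\sigma) =
  \frac{\int_{E_1}^{E_2} I^{\mathrm{exptl}} I^{\mathrm{comp}}\,dE}
  {\sqrt{\int_{E_1}^{E_2} (I^{\mathrm{exptl}})^2 dE
         \int_{E_1}^{E_2} (I^{\mathrm{comp}})^2 dE}},$$

maximized over $(\delta,\sigma)$ inside the box
$\delta \in [-1.5, 1.5]$ eV, $\sigma \in (0, 0.5]$ eV. $S$ is
scale-invariant, so only band *shape* is scored; absolute extinction
coefficients never enter. $S^{\max}$ scores shape agreement and
$|\delta|$ at the optimum proxies the method's mean excitation-energy
error.

**Geometry axis.** Computed vs reference structures are compared by (i)
the root-mean-square Cartesian deviation after optimal rigid-body
superposition (centroid alignment plus the SVD/Kabsch rotation restricted
to proper rotations — a reflection would superpose enantiomers, which are
different physical conformers), and (ii) the mean unsigned and signed
errors of the metal–ligand bond lengths over the coordination sphere.
Bond distances are superposition-independent. Hydrogens are excluded from
both metrics: X-ray positions of H atoms near heavy elements are
unreliable.

## Input conditioning

Digitized wavelength-domain spectra are converted with $E = hc/\lambda$
($hc$ = 1239.841984 eV·nm throughout) and the Jacobian intensity factor
$I(E) \propto I(\lambda)\lambda^2$, which preserves integrated band areas.
They are then smoothed, linearly interpolated to a uniform grid, clipped
at zero and max-normalized by `condition()`.

Tunable parameters, their defaults, and why:

| parameter | default | unit | rationale |
|---|---|---|---|
| grid `spacing` | `cm1_to_ev(100)` ≈ 0.0124 | eV | ~100 cm⁻¹, fine enough that bands of $\sigma \ge 0.05$ eV are resolved by many points |
| `smoothing` | Savitzky–Golay, window 5, order 2 | — | order-preserving moving-window polynomial; mild; pluggable (a function) or `NULL` to disable |
| `interpolation` | linear | — | monotone, no ringing on noisy digitized data; cubic spline available |
| bond `tolerance` | 1.3 | — | scale on the covalent-radius sum (Cordero 2008 radii, pinned in the package); generous enough for elongated high-spin bonds, below typical second-sphere contacts |
| box bounds | $\delta \in [-1.5, 1.5]$, $\sigma \in [0.005, 0.5]$ | eV | shifts beyond 1.5 eV or widths beyond 0.5 eV are chemically meaningless fits |

An explicit ligand list in the manifest (`ligand_indices`) overrides bond
detection and is the source of truth when the coordination sphere is known.

## Numerical choices

* **Quadrature.** All similarity integrals use composite Simpson weights
  on the shared uniform grid. Composite Simpson needs an even number of
  intervals; with an odd count the final interval falls back to the
  trapezoid rule (tolerance-tested against analytic integrals). The
  computed spectrum is evaluated on *exactly* the experimental grid, so
  the integrand is pointwise aligned and no second interpolation occurs.
* **Optimization.** Nelder–Mead (`stats::optim`) is unconstrained in its
  classic form; the box is enforced by clipping the evaluated point to the
  box plus a quadratic penalty ($10^4 \times$ squared violation) on the
  raw point, which preserves simplex behavior near the boundary. The
  search restarts from a fixed 3×3 grid of interior starting points — no
  randomness, so results are reproducible without seeds. Relative
  convergence tolerance $10^{-10}$, 500 iterations per restart. Ties
  across restarts break toward higher $S$, then smaller $|\delta|$, then
  smaller $\sigma$. Non-convergence is flagged in the diagnostics, never
  thrown. The σ lower bound is 0.005 eV (one grid-step order) because
  $\sigma = 0$ is singular in the broadening model.
* **Normalization.** $N$ depends on both $\delta$ and $\sigma$ and is
  recomputed at every parameter value, never cached. Transitions whose
  shifted centers leave the window still contribute their tails.
* **Degenerate inputs.** All-zero stick spectra, identically zero spectrum
  operands, mismatched grids, collinear (<3 independent atoms) geometries
  and misordered element sequences raise errors; a stick file with a
  single $f = 0$ row parses but is flagged (`has_intensity()`).
* **Reporting both conventions.** Published "broadening" values are
  sometimes $\sigma$ and sometimes the FWHM; the result object reports
  both (`sigma_opt`, `fwhm_opt` = 2.355·σ). Likewise the shift is
  reported both as the $\delta$ of the broadening model and as the
  apparent band displacement $-\delta$, to avoid sign confusion.
* **Quantile convention.** Box-plot quartiles use linear interpolation
  between order statistics (`quantile` type 7) with the 1.5×IQR outlier
  rule; whiskers sit at the extreme non-outlier points. Average and
  median rankings are reported side by side and never collapsed — they
  can legitimately disagree.

## The synthetic-data generator

Because vertical-excitation tables and crystal structures cannot ship with
the package, every stage is validated closed-loop on generated inputs with
recorded ground truth:

* `gen_sticks()` draws transition energies uniformly in a window and
  oscillator strengths log-uniformly over two decades, so a few transitions
  dominate the band shape as in real vertical-excitation spectra. Defaults
  emulate a 40-state calculation over the 1.4–6.2 eV span typical of
  iron-complex benchmarks.
* `gen_experimental()` broadens the true sticks with a known
  $(\delta^*, \sigma^*)$, applies multiplicative zero-mean Gaussian noise
  (digitization and baseline errors scale with signal; an additive
  baseline option exists), clips and renormalizes. Default noise 2%,
  matching the few-percent accuracy of plot digitization.
* `gen_structure_pair()` stretches each metal–ligand bond along its bond
  vector by known signed amounts, optionally jitters non-bonded atoms, and
  applies a seeded rigid motion. At zero jitter the ground-truth MUE/MSE
  are exact by construction.
* `simulate_benchmark()` writes a complete text bundle (XYZ pairs, stick
  tables, pseudo-experimental spectra, YAML manifest, ground-truth
  sidecar) consumable by `run_benchmark()`; the whole bundle is a pure
  function of its seed.

What passing on synthetic data does *not* show: the generator produces
Gaussian bands by construction, so it cannot probe vibronic structure,
asymmetric band shapes, solvent-dependent broadening, or intensity
inversions between bands — the situations where real computed spectra
genuinely disagree with experiment. It validates the *scoring machinery*,
not any electronic-structure method.

## Validation problem sizes

The test suite and the acceptance script use study sizes chosen to
exercise every code path at desktop scale: 50 seeded recovery scenarios
(40 transitions each, $\delta^* \in [-1, 1]$ eV,
$\sigma^* \in [0.05, 0.45]$ eV, 0–5% noise), 10 optimizer-vs-exhaustive
scan comparisons on a 0.01 × 0.005 eV grid, 100 random rigid motions and
20 brute-force superposition cross-checks, 1000 randomized bond-error
scenarios, and a 4-compound × 3-method end-to-end determinism run.

## Known limitations

* Atom correspondence is positional (index by index after hydrogen
  filtering) with a strict element-sequence check; no graph matching or
  permutation-invariant RMSD. Freely rotating ligands that were digitized
  or optimized in different conformations will show large residuals rather
  than being remapped — deliberate, so mismatches fail loudly.
* Gaussian band shapes only; no Lorentzian/Voigt profiles,
  energy-dependent widths, per-band shifts, or oscillator-strength
  rescaling.
* Crystallographic disorder handling and CIF parsing are out of scope;
  references are supplied as XYZ.
* Whether experimental spectra are max-normalized before comparison does
  not affect $S$ (scale invariance) — it only matters for plotting.
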