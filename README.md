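# uvvisbench

Benchmarking toolkit for computed structures and UV–vis absorption spectra
of transition-metal (chiefly iron) coordination complexes.

Quantum-chemistry benchmarks of such complexes need two kinds of scoring
against experiment: how close an optimized geometry is to the
crystallographic structure, and how well a set of computed vertical
excitations reproduces the measured absorption band shape. `uvvisbench`
implements both scorers, the aggregation that ranks methods across a
compound set, and a synthetic-data generator with known ground truth so the
whole pipeline is testable without any electronic-structure calculations.
It is aimed at computational chemists running functional/method benchmarks
and anyone needing a reproducible stick-spectrum-to-band comparison.

## The model

**Spectra.** Digitized experimental spectra (wavelength vs intensity) are
converted to the energy domain with the Jacobian factor — E = hc/λ,
I(E) ∝ I(λ)·λ² so band areas are preserved — then smoothed
(Savitzky–Golay), resampled to a uniform 100 cm⁻¹ (≈0.0124 eV) grid inside
an energy window \[E₁, E₂\], and max-normalized. A computed spectrum is
built from the vertical transitions {fᵢ, Eᵢ} by shifted Gaussian
broadening:

    I_comp(E; δ, σ) = N Σᵢ fᵢ exp( −(E − Eᵢ + δ)² / 2σ² )

where N normalizes the maximum to 1, σ is the common band width
(FWHM = 2√(2 ln 2)·σ ≈ 2.355σ) and a positive shift δ moves bands to lower
energy. Experimental and computed spectra are compared by cosine
similarity over the window,

    S(δ, σ) = ∫ I_exp I_comp dE / √( ∫ I_exp² dE · ∫ I_comp² dE )

with each integral by composite Simpson quadrature on the shared grid, and

    S_max = max over δ ∈ [−1.5, 1.5] eV, σ ∈ (0, 0.5] eV of S(δ, σ)

found by multi-start Nelder–Mead with box constraints. S_max ∈ \[0, 1\]
scores the band-shape agreement; |δ| at the optimum proxies the method's
systematic excitation-energy error.

**Structures.** Geometries are compared by the RMSE of optimally
superposed Cartesian coordinates (proper-rotation Kabsch fit, hydrogens
excluded) and by the mean unsigned/signed errors of the metal–ligand bond
lengths R(M–X) over the coordination sphere:

    MUE = (1/n) Σ_X |R_X^comp − R_X^ref|,   MSE = (1/n) Σ_X (R_X^comp − R_X^ref)

MSE's sign reveals systematic over- or under-estimation of the
coordination sphere.

**Ranking.** Per-method averages and medians over compounds (absolute
shift |δ| for the energy ranking), plus box-plot statistics
(linear-interpolation quartiles, 1.5×IQR outlier rule), overall and by
compound subgroup.

## Worked example

Recover a known shift and broadening from a noisy pseudo-experimental
spectrum, then score a perturbed geometry:

```r
library(uvvisbench)

sticks <- gen_sticks(40, c(2.2, 5.8), seed = 42)
scen <- spectrum_scenario(sticks, delta_true = 0.30, sigma_true = 0.20,
                          noise_level = 0.02, window = c(2.0, 6.0), seed = 7)
fit <- optimize_similarity(gen_experimental(scen), sticks)
fit
#> <similarity_result> S_max = 0.9998 (100.0%)
#>   shift delta = +0.2999 eV (apparent band shift -0.2999 eV)
#>   width sigma = 0.1995 eV (FWHM 0.4697 eV)
#>   window [2.000, 6.000] eV, converged: TRUE

toy <- gen_octahedral_toy(2.0, 6)   # ideal FeN6 octahedron, 2.0 A bonds
pair <- gen_structure_pair(structure_scenario(
  toy, bond_deltas = c(0.05, -0.10, 0, 0, 0, 0), jitter = 0, seed = 17))
met <- structure_metrics(pair$comp, pair$ref)
sprintf("RMSE = %.4f A, MUE = %.4f A, MSE = %+.4f A over %d Fe-N bonds",
        met$rmse, met$mue, met$mse, met$n_bonds)
#> "RMSE = 0.0364 A, MUE = 0.0250 A, MSE = -0.0083 A over 6 Fe-N bonds"
```

The optimizer recovers the true (δ, σ) = (0.30, 0.20) eV to three decimals
despite 2% multiplicative noise, with near-perfect shape similarity; the
bond metrics equal the constructed perturbations exactly (mean |Δ| = 0.025 Å,
mean Δ = −0.05/6 Å) and the RMSE reflects the same two displaced atoms
after superposition.

## The analysis workflow

Numbered drivers under `analysis/` run the full study on synthetic data and
write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R    # synthetic compounds, methods, manifest
Rscript analysis/02_structures.R  # superposition RMSE + bond MUE/MSE
Rscript analysis/03_spectra.R     # S_max, optimal shift and width
Rscript analysis/04_rank.R        # per-method aggregates, box plots, subgroups
```

`run_benchmark("…/manifest.yaml")` drives the same computation from any
manifest of real digitized spectra, stick-spectrum tables and XYZ files —
see the vignette for the manifest schema.

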