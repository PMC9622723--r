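# holocyte

Label-free biophysical cytometry of single spherical cells from one
off-axis hologram plus one Brillouin spectrum. The package is aimed at
groups running (or building) combined quantitative-phase / Brillouin
microscopes, and at anyone who needs the full processing chain —
holographic demodulation, phase unwrapping, sphere refractometry,
dry-mass densitometry, VIPA spectrum fitting and viscoelastic parameter
computation — as tested, scriptable R functions with forward simulators
standing in for the instrument.

## What it computes

For each cell, fifteen parameters from a single paired acquisition:
diameter D, cell/dry/fluid volumes, mean refractive index n̄, dry mass
m_dry, mass density ρ, water content by mass and by volume, Brillouin
shift ν_B and corrected linewidth Γ_B, and the viscoelastic set

    M'  = ρ (ν_B λ_B / 2 n̄)²          longitudinal (storage) modulus
    M'' = ρ Γ_B ν_B (λ_B / 2 n̄)²      loss modulus
    η   = M'' / (2π ν_B)               longitudinal viscosity
    tanφ = M'' / M'                    loss tangent

The key idea is that neither modality alone suffices: the spherical
geometry (freshly plated cells) decouples refractive index from thickness
in the phase image, and the QPI-derived ρ and n̄ then close the Brillouin
equations without assuming literature values. Density and water content
come from a two-component mixture model (protein-like dry matter at
1.37 pg/µm³ in a water-like fluid at 1 pg/µm³) driven by the integrated
phase via the refractive-index increment α ≈ 0.2 mL/g.

## Worked example

Simulate one control-like cell (D = 13 µm, n = 1.371, ν_B = 7.865 GHz,
Γ_B = 1.279 GHz) and push it through the full chain:

```r
library(holocyte)

cell <- synthetic_cell_spec(diameter_um = 13, n_cell = 1.371,
                            nu_b_ghz = 7.865, gamma_true_ghz = 1.279)
hcfg <- hologram_sim_config(seed = 1)   # PSF blur + 1% fringe noise
scfg <- spectrum_sim_config(seed = 1)   # Poisson counts, ~32 dB SNR

holo <- simulate_interferogram(simulate_phase_object(cell, hcfg), hcfg)
spec <- simulate_brillouin_spectrum(cell, scfg)
rec  <- analyze_cell(holo, spec, condition = "control")

round(unlist(rec[c("diameter_um", "v_cell_um3", "n_cell_mean", "m_dry_pg",
                   "rho_g_per_ml", "u_h2o_pct", "theta_h2o_pct")]), 3)
#>   diameter_um    v_cell_um3   n_cell_mean      m_dry_pg  rho_g_per_ml
#>        13.056      1165.158         1.369       207.090         1.048
#>     u_h2o_pct theta_h2o_pct
#>        83.041        87.027
round(unlist(rec[c("nu_b_ghz", "gamma_b_ghz", "m_prime_gpa", "m_dprime_gpa",
                   "eta_pa_s", "loss_tangent", "snr_db")]), 4)
#>     nu_b_ghz  gamma_b_ghz  m_prime_gpa m_dprime_gpa     eta_pa_s loss_tangent
#>       7.8646       1.2775       2.4457       0.3973       0.0080       0.1624
#>       snr_db
#>      32.2190
```

Reading the output: the calibrated Hough diameter (13.06 µm, +0.4% of
truth) fixes the cell volume; the mean refractive index 1.369 and dry mass
207 pg (closed form for this cell: 207.1 pg) feed the mixture model, giving
ρ = 1.048 g/mL and ~83% / 87% water by mass / volume. The Lorentzian pair
is fitted to 7.8646 GHz shift and 1.2775 GHz corrected linewidth (truth
7.865 / 1.279), and the combination yields M′ = 2.446 GPa,
M″ = 0.397 GPa, η = 0.008 Pa·s, tanφ = 0.162 at 32.2 dB spectral SNR.

Whole cohorts: `make_cohort(cohort_preset("control"))` →
`analyze_cohort()` → `summarize_cohort()`, `compare_groups()` (Welch
t-tests + KS normality) and `correlate()` (per-group and pooled OLS with
R² and 95% confidence bands). A command-line front end with `simulate`,
`phase`, `spectrum`, `analyze` and `cohort` subcommands is installed from
`exec/holocyte`.

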