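# azoswitch

Characterisation toolkit for azobenzene photoswitches — the
Ph–N=N–Ph chromophores that flip between *trans* (E) and *cis* (Z)
configurations under light and relax back thermally in the dark.
Red-shifted, *ortho*-substituted derivatives can be addressed with
visible and near-IR light inside the bio-optical window, which makes
them candidates for photopharmacology; characterising one means
answering four quantitative questions, and the package implements each:

1. **Thermokinetics** — how stable is the *cis* isomer? A measured
   dark half-life fixes a first-order rate, k = ln 2 / t½, and the
   Eyring equation

   k = κ (k_B T / h) exp(−ΔG‡ / RT),  κ = 1

   converts it to an activation free energy (and back, and across
   temperatures): `barrier_from_halflife()`, `halflife_from_barrier()`,
   `extrapolate_halflife()`, `batch_barrier_table()`.
2. **Ensemble UV–vis spectra** — what do the bands look like and why?
   Broadened nuclear-ensemble spectra from tables of per-snapshot
   vertical excitations, I(E) = (1/N) Σ fᵢ G(E−Eᵢ; fwhm), plus
   systematic-shift calibration against measured spectra, band maxima,
   *cis–trans* band splits, and band-tail extents:
   `assemble_spectrum()`, `calibrate_shift()`, `band_metrics()`.
3. **Flexibility analysis** — which nuclear motions tune the
   excitation? Torsions ψ (around N=N) and φ (around each C–N) from
   multi-frame XYZ trajectories, their cosine transforms, and Pearson
   correlation matrices against photo-properties:
   `read_xyz_trajectory()`, `dihedral()`, `feature_table()`,
   `pearson_matrix()`.
4. **Photokinetics** — how efficiently does light switch it? A
   two-state irradiation ODE, closed-form photostationary states,
   quantum-yield estimation from absorbance traces anchored by NMR
   isomer ratios, and mono-/bi-exponential decay fitting for thermal
   relaxation and glutathione-degradation traces:
   `simulate_photoswitching()`, `pss_closed_form()`,
   `estimate_quantum_yield()`, `fit_decay()`.

A seeded synthetic-data module (`gen_ensemble()`, `gen_trace()`,
`gen_experimental_spectrum()`, `gen_qy_experiment()`) generates every
input the pipeline consumes with known ground truth, so all estimators
are tested by parameter recovery.

## Worked example

Invert a measured half-life (3.16 h at 55 °C) to its barrier,
extrapolate to room temperature, and batch-process a table:

```r
library(azoswitch)

barrier_from_halflife(halflife("3.16 h"), temperature(celsius = 55))
#> dG* = 25.60 kcal/mol at 328.15 K [from_experiment]

extrapolate_halflife(halflife("3.16 h"), temperature(celsius = 55),
                     room_temperature())
#> 7.53 d (650449 s)

batch_barrier_table(azo_benchmark_halflives()[1:4, ])
#>   compound t_half_s temp_K   k_per_s dG_kcal_mol dG_rounded error
#> 1        1    11376  328.1 6.093e-05       25.60       25.6  <NA>
#> 2        2    14292  363.1 4.850e-05       28.57       28.6  <NA>
#> 3        3    13320  363.1 5.204e-05       28.52       28.5  <NA>
#> 4        4     6552  363.1 1.058e-04       28.01       28.0  <NA>
```

The 25.6 kcal/mol barrier is what 3.16 h at 328.15 K *means*
thermodynamically; the extrapolation assumes that barrier is
temperature independent (see the methods vignette for why, and for why
multi-temperature extrapolations differ).

Generate a synthetic 6000-snapshot ensemble of a twisted,
electron-poor azobenzene, assemble its spectrum, and correlate
structure with excitation energy:

```r
ens <- gen_ensemble("dfdc_ester_like", n = 6000, seed = 1,
                    build_frames = FALSE)
bm <- band_metrics(to_wavelength(assemble_spectrum(ens$records)))
sprintf("lambda_max = %.1f nm, 1%% tail extent = %.1f nm",
        bm$lambda_max_nm, bm$tail_extent_nm)
#> "lambda_max = 524.4 nm, 1% tail extent = 593.1 nm"

pearson_matrix(ens$records,
               columns = c("energy_eV", "osc_strength", "cos_psi",
                           "planarity"))
#> Pearson correlation matrix (n = 6000)
#>              energy_eV osc_strength cos_psi planarity
#> energy_eV        1.000       -0.018   0.014    -0.702
#> osc_strength    -0.018        1.000   0.003     0.011
#> cos_psi          0.014        0.003   1.000     0.003
#> planarity       -0.702        0.011   0.003     1.000
```

The −0.70 energy–planarity correlation is the planted mechanism:
planar ring configurations delocalise the π* orbital and red-shift the
n→π* excitation, and the electron-withdrawing *para* group amplifies
the coupling.

Fit a noisy two-step degradation trace (half-lives 20 min / 160 min
planted):

```r
fit_bi_decay(gen_trace("bi", noise_sd = 0.02, seed = 1))
#> bi-exponential decay fit
#>   k_a = 0.0005713 1/s  (t1/2 = 20.2 min)
#>   k_b = 7.22e-05 1/s  (t1/2 = 2.67 h)
#>   offset = 0.0498, residual sigma = 0.0198, AICc = -3767.85
```

A thin command-line wrapper over the same functions lives at
`inst/cli/azoswitch.R` (subcommands `barrier`, `extrapolate`, `batch`,
`spectrum`, `fit-decay`, `dihedrals`, `correlate`).

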