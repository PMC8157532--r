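# msmdesign

Tools for characterising — and rationally redesigning — protein free-energy
landscapes whose conformational states live on the millisecond timescale,
modelled on the loop dynamics of a prolyl isomerase (CypA-like) system in
which two surface loops (residues 65–77, the "70s loop", and 100–110, the
"100s loop") exchange between open and closed conformations.

The package is aimed at computational structural biologists who want a
tested, fully synthetic-data-driven sandbox for the complete analysis chain:

1. **Kinetic landscape generation** (`build_canonical_model`,
   `expand_to_microstates`, `simulate_dtrajs`, `emit_observables`): a
   five-macrostate ground-truth model with detailed-balance rate matrices
   (off-diagonal rates k_ij = c_ij π_j with symmetric c_ij), microstate
   expansion, and state-conditioned emissions (2-D loop-openness features,
   Bernoulli hydrogen-bond indicators, per-state amide chemical shifts).
   The wild-type landscape holds 41% in the 100s-open/70s-closed ground
   state with a 70:30 closed:open balance of the 70s loop; the D66A
   variant inverts this to 25:75 with ~12-fold faster 70s kinetics; H70A
   matches wild type.
2. **Markov state model estimation** (`count_transitions`,
   `estimate_reversible_T`, `pcca_lump`, `mfpt`, `bootstrap_msm`,
   `validate_msm`): reversible maximum-likelihood transition matrices
   (detailed-balance constrained fixed-point iteration), spectral
   PCCA-style coarse-graining, set-to-set mean first passage times by
   linear solve, whole-trajectory bootstrap intervals, implied-timescale
   and Chapman–Kolmogorov diagnostics.
3. **Designability scoring** (`detect_hbonds`, `state_hbond_profiles`,
   `designability_rank`, `structure_metrics`): geometric hydrogen-bond
   detection on multi-model PDB ensembles (D–A ≤ 3.5 Å, D–H···A ≥ 120°),
   per-state bond-count distributions, and ranking of residues by the
   closed-vs-open difference in their expected bond count to the 70s
   loop — the signature that singles out D66 as the designable position.
4. **NMR forward prediction** (`ensemble_average_shifts`, `csp`,
   `map_to_exchange_model`, `rex_forward`, `noe_from_modelfree`):
   population-averaged shifts, combined ¹H/¹⁵N chemical shift
   perturbations √(ΔδH² + (0.14·ΔδN)²), mapping of the five-state model
   onto a two-state NMR exchange model along the 70s-loop coordinate
   (kex = 1/MFPT(A→B) + 1/MFPT(B→A)), forward exchange broadening, and
   model-free heteronuclear ¹⁵N–{¹H} NOE.
5. **Relaxation dispersion** (`simulate_dispersion`,
   `r2eff_two_state_cpmg`, `r1rho_two_state`, `rex_estimate`,
   `global_fit_two_state`, `model_compare`): two-state CPMG via the
   Carver–Richards closed form cross-checked against a numerical
   Bloch–McConnell echo-train propagator; spin-lock R1ρ via the
   Trott–Palmer expression against a 6×6 propagator; global weighted
   least-squares fits sharing kex and pB across residues, fields and
   experiments, with multi-start initialisation, residual-resampling
   bootstrap intervals and F-test model selection.
6. **Pipeline** (`pipeline_config`, `run_pipeline`): a deterministic
   simulate → estimate → design → predict → fit chain with plain-text
   intermediates and hash-stable reports.

## Worked example

```r
library(msmdesign)

model <- expand_to_microstates(build_canonical_model("WT"), 20)
traj  <- simulate_dtrajs(model, n_traj = 100, n_steps = 20000, seed = 1)
est   <- estimate_reversible_T(count_transitions(traj, lag = 1))
lump  <- pcca_lump(est, 5, timestep = model$timestep_ns * 1e-6)
map   <- match_macrostates(lump, model$micro_to_macro, pi = est$pi)
setNames(round(100 * lump$macro_pi[match(1:5, map)], 1), model$labels)
#>     o100_c70     c100_c70 intermediate     o100_o70     c100_o70
#>         38.4         27.9          4.7         15.4         13.7
```

The estimated populations recover the planted landscape (ground state
41%, 70s-closed aggregate 70%) to within sampling error of the 2,000,000
simulated frames. Dispersion fitting works the same way:

```r
d   <- simulate_dispersion(canonical_dispersion_spec("WT"), seed = 2)
fit <- global_fit_two_state(d, seed = 2)
fit
#> Two-state global fit: kex = 2196 /s, pB = 2.03%, chi2/dof = 1.18
#>   |dw| (ppm): 55=0.59 66=3.48 67=2.01 71=2.77 72=3.99 74=3.17 101=1.47
```

i.e. the fit recovers the planted exchange parameters (kex 2200 s⁻¹,
pB 2.0%) and per-residue shift differences from noisy synthetic data.

## Vignette

`vignettes/landscape-design.Rmd` documents the model, the calibration of
the canonical rate matrices, the numerical conventions of the dispersion
forward models, and the known limitations of the synthetic-data design.
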