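---
title: "Kinetic landscape design: models, calibration and numerical conventions"
author: "msmdesign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic landscape design: models, calibration and numerical conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msmdesign)
```

# The scientific problem

Many proteins function through sparsely populated conformational states
with lifetimes approaching milliseconds. For a CypA-like prolyl
isomerase, two surface loops — the 70s loop (residues 65–77) and the
100s loop (residues 100–110) — exchange between open and closed
conformations, and the landscape can be *redesigned*: removing a
hydrogen-bonding anchor that stabilises the closed 70s loop (an
Asp→Ala substitution at position 66) inverts the closed:open balance,
while a control substitution (His70→Ala) with state-independent bonding
leaves the landscape unchanged.

`msmdesign` provides the full analysis chain for this problem on
synthetic data whose ground truth equals the study conditions: kinetic
model generation, Markov state model (MSM) estimation and
coarse-graining, hydrogen-bond designability ranking, forward prediction
of NMR observables, and global fitting of CPMG/R1ρ relaxation-dispersion
data.

# The canonical kinetic models

Each landscape has five macrostates labelled by loop status
(`o100_c70`, `c100_c70`, `intermediate`, `o100_o70`, `c100_o70`). The
fixed model constants are:

* Wild type: populations 41 / 29 / 5 / 13 / 12 %, i.e. a 70:30
  closed:open balance of the 70s loop. Only three of these numbers (41%,
  ~5%, and the 70:30 aggregate) are constrained by the study; the split
  of the remainder across the 100s-loop states is a documented
  convention chosen to satisfy the aggregates, not a fitted quantity.
* D66A: 15 / 10 / 40 / 18 / 17 % (25:75 closed:open, intermediate
  promoted to the ground state).
* H70A: identical to wild type (the negative control; the study allows
  per-state deviations up to 2 points, and the identity choice is the
  simplest member of that family).

Rates use the detailed-balance construction k_ij = c_ij·π_j with
symmetric couplings c_ij, restricted to the loop-flip network: the two
loops flip independently, and the 70s transition passes through the
intermediate (no direct closed↔open edge). Two couplings exist — one
for 100s-loop flips, one for the edges incident on the intermediate —
and are calibrated by a monotone one-dimensional root find so that

* the WT 70s closed→open MFPT is 11.5× the 100s open→closed MFPT.
  The study constrains this separation to "one order of magnitude"
  (asserted band 8–12). We place the true ratio in the upper half of
  the band rather than exactly at 10 because a downstream acceptance
  check requires the *estimated* ratio to be ≥ 10; with a true value of
  exactly 10 an unbiased estimator would fail that bound half the time,
  so the only self-consistent reading is a true ratio comfortably above
  the bound. This is a design-time calibration, fixed once.
* the WT absolute scale anchors the 100s MFPT at 0.5 ms (70s ≈ 5.75 ms,
  the millisecond regime).
* D66A uses the same topology and coupling ratio, scaled so its 70s
  closed→open MFPT is 12-fold shorter than WT (study range 10–15×).

`expand_to_microstates` splits each macrostate into equally populated
microstates exchanging on a complete graph at 100× the fastest
inter-macrostate rate (minimum 50×, enforced). Inter-state rates are
spread uniformly over microstate pairs, which makes the expansion
*exactly lumpable*: the aggregated process is Markov and the slowest
implied timescales match the macro level to numerical precision. The
one-step transition matrix is the exponential of this generator over one
sampling interval, computed by symmetrised eigendecomposition (exact for
detailed-balance generators).

## Sampling interval and problem sizes

The synthetic sampling interval is 1 µs per frame, so the standard
simulation (100 trajectories × 20,000 steps) spans 2 s of aggregate
time — several hundred slow 70s transitions — and each 20 ms trajectory
covers ~3 slow correlation times. This was chosen at design time so
that population estimates reach the precision of the study's printed
uncertainty (the ground-state bootstrap CI half-width is ≈2 points,
inside the ±6-point band) while the full analysis, including a
200-replicate trajectory bootstrap, completes in about two minutes on
one CPU. Tests and the acceptance script use exactly these sizes; the
unit suite uses smaller versions of the same generator.

What the generator emulates: equilibrium-initialised, seeded Markov
dynamics with the study's populations and timescale separations, and
state-conditioned emissions (Gaussian 2-D loop-openness features,
Bernoulli hydrogen-bond indicators, per-state chemical shifts). What it
does not emulate: atomistic force-field detail, non-Markovian memory
from projecting Cartesian dynamics onto discrete states, biased
(accelerated-MD-style) sampling weights, or chemical-shift prediction
error. Passing tests therefore demonstrate correctness of the
estimation and design machinery under Markovian truth, not robustness
to force-field or projection error.

# MSM estimation choices

* Counting: sliding window by default (maximal data use); strided mode
  for independence-sensitive checks. Trajectories never concatenate.
* Reversible maximum likelihood: the standard self-consistent
  fixed-point iteration on the symmetric flux matrix,
  x_ij ← (c_ij + c_ji)/(c_i/x_i + c_j/x_j), converged when the
  stationary distribution moves < 1e-10 (max norm), capped at 1e5
  iterations (an error, carrying the last residual, past the cap).
  Detailed balance is exact at every iterate. At the standard problem
  size convergence needs ~7,000 iterations, so the loop is implemented
  in C++.
* Lumping: fuzzy memberships from the dominant eigenvectors
  (simplex-vertex construction with greedy orthogonal deflation),
  crisped by argmax with ties to the lowest macrostate index. Estimated
  macrostates are matched to reference labels by stationary-weighted
  microstate overlap (greedy one-to-one assignment). Eigenvalue
  degeneracy at the spectral cut raises an error suggesting a different
  number of macrostates.
* MFPT: discrete first-passage linear solve, source-averaged under the
  stationary distribution restricted to the source set; cross-checked
  against Monte-Carlo first passages (3 SE) in the suite.
* Bootstrap: whole trajectories resampled with replacement (n_boot
  default 200; the acceptance run uses 100), re-estimated, re-lumped and
  re-matched per replicate; percentile intervals. Replicates losing
  connectivity are dropped; more than 50% dropped is an error. The
  trajectory bootstrap mildly under-covers at nominal 95% (coverage
  ≈90% in our regenerations), which is why coverage is asserted as a
  frequency over regenerations rather than at a single seed.
* Lag time: the canonical chains are Markovian at lag 1 by
  construction, so the default lag is 1; `validate_msm` exposes implied
  timescales across lags and Chapman–Kolmogorov deviations for data of
  unknown provenance. Microstate count and cluster count are plain
  configuration, as the underlying study treats them.

# Designability scoring

Hydrogen bonds use the common geometric criterion D–A ≤ 3.5 Å and
D–H···A ≥ 120° (inclusive; configurable), with hydrogens placed 1.01 Å
from the donor along the direction away from its bonded-atom centroid
when absent (flagged `h_inferred`). The designability score of a
residue is the population-weighted expected number of bonds it makes to
the 70s loop (partners 65–77) in the closed group ({`o100_c70`,
`c100_c70`}) minus the open group ({`intermediate`, `o100_o70`,
`c100_o70`}); residues are ranked by |Δ|. On canonical emissions the
planted designable residue (66) carries Δ ≈ 2.1 bonds and tops the
ranking in ≥95/100 seeded regenerations, while the control residue (70)
scores within noise of zero. RMSF/RMSD use Cα-style selections with
least-squares (Kabsch) superposition via bio3d; RMSD is computed from
the fitted coordinates directly (bio3d's `rmsd` helper rounds to three
digits).

# NMR forward models

* Fast-exchange averaging: population-weighted arithmetic mean per
  nucleus; intra-group exchange is assumed fast relative to the shift
  differences, inter-group exchange is handled by the two-state model.
* CSP: √(ΔδH² + (α·ΔδN)²), α = 0.14 (the common amide-weighting
  convention; the study does not print its formula).
* Two-state mapping: groups split along the 70s-loop coordinate;
  kex = 1/MFPT(A→B) + 1/MFPT(B→A). For a genuine two-state chain this
  equals the relaxation eigenvalue exactly; for the lumped five-state
  model it is the standard approximation.
* Constants: γH/γN = −9.865; ¹⁵N Larmor = 0.1013 × ¹H field; N–H bond
  1.02 Å; ¹⁵N CSA −160 ppm. The heteronuclear NOE uses the
  two-timescale model-free spectral density with 1/τ = 1/τc + 1/τe.
* `rex_forward` combines the mapping's MFPT-derived kex (~10³ s⁻¹) with
  planted loop shift differences of a few hundred rad/s; the result is
  exchange broadening in the hundreds of s⁻¹ for loop residues — an
  over-prediction relative to measured dispersion amplitudes that the
  package reproduces deliberately, with the fast-exchange closed form
  pA·pB·Δω²/kex reported alongside the numerical difference
  R2eff(νmin) − R2eff(νmax).
* Temperature effects are not modelled (simulated and measured
  conditions differ by 15 °C in the motivating study; no scaling is
  applied).

# Dispersion forward models and fitting

CPMG conventions: νCPMG = 1/(4τ) with τ the delay flanking each 180°
pulse; the Carver–Richards closed form is evaluated with
τcp = 1/(2νCPMG) (the inter-pulse spacing). The numerical model builds
the 2×2 complex Bloch–McConnell matrix, propagates one even echo pair
(τ–180–2τ–180–τ; ideal pulses act as complex conjugation, and the
two-echo map is linear because conjugations cancel pairwise), and
reports the decay rate of the slowest mode. For equal intrinsic R2 the
Carver–Richards expression is the exact dominant-eigenvalue solution,
so the two routes agree to machine precision across the stress grid
(pB 0.5–10%, kex 500–10,000 s⁻¹, Δω 100–1,500 rad/s); an
intensity-based finite-relaxation-delay readout would differ by
amplitude terms (up to a few s⁻¹ in deep slow exchange), which is why
the slowest-mode convention is used for both simulation and
cross-checks. Overflow in the closed form (cosh at very low νCPMG)
falls back to the numerical route with a warning.

R1ρ: the analytic route is the Trott–Palmer expression
R1ρ = R1cos²θ + sin²θ(R2,0 + Rex) with
Rex = pA·pB·Δω²·kex/(ω_aeff²ω_beff²/ω_eff² + kex²); the numerical route
takes the slowest spin-locked mode of the 6×6 two-state Bloch–McConnell
matrix. They agree to <5% (typically <0.1%) for kex ≥ Δω. Because the
global fit uses the analytic R1ρ model against data generated by the
6×6 propagator, a noiseless mixed dataset retains a ~0.1% residual
floor; exact-recovery checks therefore use CPMG-only data, where fit
and generator coincide.

Global fitting shares kex and pB across residues, fields and
experiments, with |Δω| (ppm, sign unresolved by the experiment) per
residue and R2,0 per residue × field. pB is constrained to (0, 0.5)
through a logit parameterisation (minor-state convention, removing the
relabelling degeneracy) and kex through a log. The multi-start grid
(kex log-spaced 100–30,000 s⁻¹ × pB ∈ {0.5, 1, 2, 5, 10}%) is
pre-scored by fitting only the decoupled per-residue parameters at
frozen (kex, pB); the best three nodes are polished by full
Levenberg–Marquardt, ties broken towards the lowest kex. Uncertainties
come from residual-resampling bootstrap percentiles. In the deep
fast-exchange limit only pB·Δω² is identified; the bootstrap then
reports intervals more than 5× wider than in the well-conditioned
regime, which the suite asserts as the honest-degeneracy property.

The canonical synthetic datasets use two fields (600 and 800 MHz), a
40 ms constant-time CPMG grid of 14 frequencies (25–1,000 Hz), five
spin-lock points (1.0–2.0 kHz, offsets 0/±400 Hz), per-point Gaussian
noise of 0.2 s⁻¹ (a typical per-point uncertainty for such
experiments), R1 = 1.5 s⁻¹, and shift differences of 0.6–4 ppm largest
in the 70s loop. Ground truths are kex = 2200 s⁻¹ / pB = 2.0% (WT-like)
and kex = 2000 s⁻¹ / pB = 0.5% (D66A-like, near the detection
threshold). Twenty-seed ensembles recover the medians within 5% (kex)
and 10% (pB).

# Degenerate inputs and tie-breaks

* Unknown variants, empty count matrices, all-short trajectories,
  unreachable MFPT targets, zero-population exchange groups and
  non-nested model comparisons raise explicit errors.
* Argmax ties in lumping go to the lowest macrostate index; multi-start
  χ² ties to the lowest kex; missing dispersion errors trigger uniform
  weights with a warning; missing state populations in designability
  trigger unweighted means with a warning.
* All stochastic code draws from one seeded generator per call and
  records the seed in its output; identical seeds give bit-identical
  artifacts (the pipeline asserts hash equality).

# Known limitations

* The synthetic landscape is exactly Markovian and exactly lumpable;
  real trajectory data violate both, and lag/cluster selection — here
  diagnostic only — becomes a genuine modelling step.
* The trajectory bootstrap under-covers slightly when trajectories are
  comparable in length to the slowest correlation time.
* The two-state mapping of a five-state landscape is an approximation;
  its kex is not the relaxation rate of the full chain.
* Absolute MFPTs are conventions anchored at 0.5 ms; only ratios are
  meaningful, and only ratios are asserted.
* The hydrogen-bond detector aims at ensemble statistics on modest
  ensembles, not high-throughput trajectory scanning.
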