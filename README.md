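# trfret

Time-resolved FRET distance distributions, MD-ready distance restraints,
and structure validation metrics for protein complexes — built around the
cardiac troponin use case, usable for any donor–acceptor labelled system.

## The problem

Crystal structures of large regulatory complexes such as cardiac troponin
(cTnC–cTnI–cTnT) leave functionally central regions unresolved, and they
freeze a single conformation of what is in solution a dynamic ensemble.
Time-resolved Förster resonance energy transfer (FRET) fills that gap: the
fluorescence decay of a donor dye quenched by an acceptor at distance *r*
reports on *r* through the Förster rate factor, and the decay of an
*ensemble* of donor–acceptor pairs encodes the whole distance distribution
P(r).  Those distributions can then drive restrained molecular-dynamics
refinement and validate the resulting models.

`trfret` implements that chain end to end:

1. **Forward model.**  A multi-exponential donor
   (I_D(t) = Σᵢ αᵢ e^(−t/τᵢ)) quenched by an acceptor at distance *r*
   decays as

   I_DA(t; r) = Σᵢ αᵢ exp[−(t/τᵢ)(1 + (R₀/r)⁶)],

   and an ensemble with Gaussian P(r) (mean r̄, half-width HW = 2.35 σ)
   as ∫ P(r) I_DA(t; r) dr.  R₀ is the Förster critical distance, at which
   the transfer efficiency E = 1/(1 + (r/R₀)⁶) is exactly 0.5; it can be
   supplied directly or computed from quantum yield, overlap integral, κ²
   and refractive index.
2. **Inverse problem.**  `fit_donor()` recovers the donor photophysics
   from a donor-only TCSPC decay; `fit_fret()` then recovers (r̄, HW) from
   the donor–acceptor decay by Poisson-weighted Levenberg–Marquardt, with
   the donor frozen, χ²_red goodness of fit, and standard errors.  Both
   return classed objects with `print`/`summary`/`coef`/`predict`/`plot`/
   `residuals`/`simulate` methods.
3. **Restraints.**  `build_restraints()` turns a FRET distance table into
   flat-bottom Cα–Cα restraints (lower bound = r̄, upper bound = r̄ + 7 Å
   for the probe linker; half-widths become Boltzmann-consistent force
   constants k = k_BT/σ²) written in a GROMACS-style
   `[ distance_restraints ]` dialect.
4. **Validation.**  Site distances through user-editable site maps,
   N-domain pocket openness via the TnC 13–51 distance, geometric
   hydrogen bonds, backbone-pattern helix assignment and axis angles,
   Kabsch RMSD, per-residue RMSF, and ±10 % + linker FRET-agreement
   reports.
5. **Synthetic data.**  Poisson TCSPC decays from known (r̄, HW, R₀),
   ideal helices/extended chains/dumbbells with prescribed distances, and
   jittered trajectories — every stage is testable with known ground
   truth.

The package ships the measured troponin distance table (45 donor–acceptor
pairs in each of the Ca²⁺-free and Ca²⁺-saturated states) as
`fret_table1()`, plus default site maps for the relevant PDB entries.

## Worked example

Simulate a donor-only and a donor–acceptor decay at the first measured
pair's regime (r̄ = 48.1 Å, HW = 10.2 Å, R₀ = 40 Å, 10⁶ photons), refit
them, and emit restraints:

```r
library(trfret)

donor <- donor_model(c(0.6, 0.4), c(5, 15))        # AEDANS-like, <tau> ~ 11.7 ns
don_curve <- simulate_decay(donor, total_counts = 1e6, seed = 101)
da_curve  <- simulate_decay(donor, R0 = 40,
                            dist = distance_distribution(48.1, 10.2),
                            total_counts = 1e6, seed = 102)

don_fit <- fit_donor(don_curve, n_components = 2)
fret    <- fit_fret(da_curve, don_fit, R0 = 40)
summary(fret)
#> FRET distance-distribution fit (donor frozen)
#>   rbar = 48.28 +/- 0.15 A
#>   HW   = 11.49 +/- 1.26 A (sigma = 4.89 A)
#>   R0   = 40.00 A  => efficiency at rbar: 0.244
#>   scale = 1.345, baseline = 0
#>   chi2_red = 1.09; converged: TRUE
```

The generating values (48.1, 10.2) are recovered within the shot-noise
uncertainty of a 10⁶-photon experiment, and χ²_red ≈ 1 says the model
accounts for the data at the Poisson noise level.

```r
tab  <- fret_table1()
recs <- build_restraints(tab, state = "ca_saturated")
write_distance_restraints(recs, "restraints_ca_saturated.itp")
head(readLines("restraints_ca_saturated.itp"), 4)
#> [ distance_restraints ]
#> ;  ai   aj funct index type       low       up1       up2         kfac  ; label
#>     1   15     1     0    1    4.8100    5.5100    5.7100    13.240086  ; cTnI:131--cTnT:240/ca_saturated
#>     2   15     1     1    1    5.5600    6.2600    6.4600     6.736263  ; cTnI:145--cTnT:240/ca_saturated
```

Distances are written in nm: the first record restrains cTnI-131 to
cTnT-240 between 48.1 and 55.1 Å with a 2 Å linear ramp and a force
constant from its 10.2 Å half-width.  Comparing the packaged table's
published model distances against the measured distances under the
±10 % + 7 Å rule:

```r
agr <- fret_agreement(tab$rbar_A, tab$model_A)
mean(agr$within_tolerance)
#> [1] 1
```

A thin CLI wraps the same functions
(`inst/cli/trfret.R simulate | fit-decay | build-restraints |
analyze-structure | pocket | rmsf | run`), and `run_pipeline()` drives
decays → distances → restraints → validation from one YAML config with
deterministic, hash-stamped outputs.

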