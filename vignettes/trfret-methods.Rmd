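---
title: "Models and methods behind trfret"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind trfret}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trfret)
```

This vignette explains the models the package implements, the numerical
choices made where the underlying methodology leaves them open, and what
the synthetic-data tests do and do not establish about real experiments.

## The forward model

A donor dye with multi-exponential photophysics decays as
$I_D(t) = \sum_i \alpha_i e^{-t/\tau_i} + b$, with lifetimes $\tau_i$ in
ns, dimensionless amplitudes $\alpha_i$, and an additive baseline $b$
(dark counts per channel).  Energy transfer to an acceptor at distance
$r$ adds a de-excitation rate $(1/\tau_i)(R_0/r)^6$ to every component:

$$I_{DA}(t;r) = \sum_i \alpha_i
  \exp\!\left[-\frac{t}{\tau_i}\Big(1 + (R_0/r)^6\Big)\right].$$

$R_0$ is the Förster critical distance — the separation at which the
transfer efficiency $E = 1/(1+(r/R_0)^6)$ is exactly one half.  It is
either supplied (40 Å for an AEDANS–DABM-like pair, 29 Å for
MIANS–DDPM-like short-range work) or computed from
$R_0^6 = 8.79\times10^{-5}\,\kappa^2 n^{-4} Q_D J$ with $J$ in
M⁻¹cm⁻¹nm⁴ and $R_0$ in Å.  The default orientation factor is
$\kappa^2 = 2/3$, the isotropic-averaging value; no attempt is made to
model $\kappa^2$ distributions (a known ±10 % distance-uncertainty
contribution, carried instead as a tolerance in the agreement reports).

A flexible protein does not hold the dyes at one distance.  The ensemble
decay integrates the fixed-distance decay over a Gaussian distance
distribution $P(r)$ with mean $\bar r$ and half-width (FWHM)
$HW = 2.35\,\sigma$:

$$I_{DA}(t) = \int P(r)\, I_{DA}(t;r)\, dr .$$

Conventions adopted where the method description is silent:

* **The 2.35 constant.**  The conversion between half-width and standard
  deviation uses the conventional rounded factor 2.35, not
  $2\sqrt{2\ln 2} = 2.3548$; the package applies it consistently in both
  directions, so no round-trip error arises.
* **Truncation at $r>0$.**  A Gaussian assigns (unphysical) mass to
  negative distances when $HW$ is large relative to $\bar r$.  $P(r)$ is
  truncated at $r > 0$ and renormalised on the integration grid; the
  renormalisation is part of the model, so the integral of $P$ over the
  grid is 1 to 1e-6 for every valid distribution.
* **Quadrature.**  Composite Simpson on 201 points spanning
  $\bar r \pm 5\sigma$ (clipped at $r>0$).  Gaussian mass outside
  $\pm 5\sigma$ is below $6\times10^{-7}$, and on smooth integrands this
  grid agrees with an 8001-point reference to ~1e-12 relative — far below
  shot noise at any realistic photon count.  The Monte-Carlo cross-check
  (averaging $I_{DA}(t;r)$ over Gaussian draws) agrees within sampling
  error on randomised regimes.
* **Instrument response.**  Optional discrete convolution with a supplied
  IRF; off by default.  The analysis chain targets decays whose rise
  region is excluded by the fit window (below), which is how the tail-fit
  tradition treats LED-excited TCSPC data.

## Decay fitting

`fit_donor()` and `fit_fret()` are Levenberg–Marquardt least-squares fits
(via `minpack.lm`) of the forward model to binned photon counts with
Neyman weights $1/\max(y_k, 1)$ — the standard TCSPC weighting, exact in
the large-count limit.  Choices that matter:

* **Fit window.**  Channels strictly after the counts maximum through the
  last channel with ≥ 10 counts.  The lower edge avoids the rise/IRF
  region the pure-decay model does not describe; the upper edge drops the
  regime where Gaussian weighting of Poisson counts is unreliable.  Times
  are kept on the curve's own axis (no re-origin), since shifting the
  time origin of a distance-distribution decay would tilt the effective
  $P(r)$.
* **Donor frozen.**  The donor amplitudes and lifetimes are fitted once,
  from the donor-only decay measured under identical conditions, and held
  fixed during the donor–acceptor fit.  Refitting them jointly would
  reintroduce a near-degeneracy between donor heterogeneity and distance
  heterogeneity that the two-measurement design exists to remove.  The
  free parameters of the distance fit are $(\bar r, HW,
  \text{scale}, \text{baseline})$; baseline fitting is on by default
  (real detectors have dark counts) and can be pinned to zero.
* **Initialisation and restarts.**  $\bar r_0$ comes from a
  mean-arrival-time efficiency estimate (computed against the donor model
  on the same truncated window, so it is free of truncation bias);
  $HW_0 = 10$ Å.  If the first fit converges poorly (χ²_red > 1.5) or
  runs into a distance bound, the fit restarts from
  $0.8\bar r_0$ and $1.2\bar r_0$ and keeps the best optimum — a cheap
  tie-break for the occasionally multimodal χ² surface.
* **Kernel evaluation.**  During optimisation the decay kernel
  $K(t, r)$ is precomputed on a fixed 1–180 Å grid (1201 Simpson points),
  so each model evaluation is one matrix–vector product; distributions
  narrower than ~3 grid steps fall back to the moving $\bar r \pm
  5\sigma$ grid.  The two quadratures agree to ~3e-7 relative, which is
  negligible against shot noise.
* **Determinability floor.**  When the donor–acceptor decay is
  indistinguishable from the donor-only decay (estimated efficiency
  below 2 %), the fit refuses with a `trfret_no_transfer` condition
  rather than reporting an arbitrary large distance.  This mirrors the
  experimental practice of switching to a shorter-$R_0$ dye pair for
  short distances: with $R_0 = 29$ Å a 75 Å separation transfers ~0.3 %
  of the energy and carries no distance information at 10⁶ photons.
* **Goodness of fit and errors.**  χ²_red is
  $\sum_k (y_k - m_k)^2/\max(m_k,1)/(N-p)$; standard errors come from the
  Gauss–Newton covariance scaled by the residual variance.

Synthetic calibration (the package's own acceptance study): across
$\bar r \in \{20,30,45,60,75\}$ Å × $HW \in \{3,10,20\}$ Å ×
$R_0 \in \{29,40\}$ Å at 10⁶ counts and 50 Poisson seeds per condition,
with the donor itself refit from a simulated donor-only decay, the median
absolute $\bar r$ recovery error is well under 2 % and mean χ²_red is
1.00 ± 0.05.  Half-width recovery is markedly softer: donor-fit
uncertainty propagates into $HW$ (±1–2 Å at this photon budget), and the
$HW$ variance grows as $\bar r/R_0$ grows — the identifiability reason
for matching the dye pair to the distance range.

## From distributions to restraints

`build_restraints()` converts each table row into a flat-bottom Cα–Cα
restraint.  The default bounds are **lower = $\bar r$, upper =
$\bar r + 7$ Å**: the probe linker (~10 Å arm) folds randomly and
effectively adds up to ~7 Å between the dye and the backbone attachment
point, so the Cα separation may legitimately exceed the dye separation by
that much.  The alternative schemes trialled historically
($\bar r \pm 7$; point restraints) remain selectable.  Two further
choices are the package's own:

* **Force constant.**  The measured half-width became a "bond energy"
  in the original refinement protocol without a published formula.  The
  package uses the Boltzmann-consistent harmonic width: a well of
  stiffness $k$ at temperature $T$ has equilibrium width
  $\sigma = \sqrt{k_BT/k}$, so $k = k_BT/\sigma^2$ with
  $\sigma = HW/2.35$ in nm, giving kJ mol⁻¹ nm⁻².  Broad (dynamic)
  distances restrain weakly, which is the physically defensible reading;
  the mapping is a single pluggable function.
* **Second upper bound.**  The GROMACS dialect needs an `up2` where the
  penalty turns linear; the package uses `up1 + 2` Å, a conventional
  linear-regime onset, since no second bound exists in the source
  protocol.

The writer emits deterministic, stable-ordered text (distances ×0.1 to
nm) and the reader inverts it exactly at the written precision;
`score_restraints()` reports per-record violations
$\max(0, low - d, d - up1)$ on any structure.

## Structure and trajectory metrics

* **Site maps.**  FRET tables speak (subunit, residue); structures speak
  (chain, author resno).  A YAML site map lists chain assignments per
  crystallographic copy plus per-subunit numbering offsets; all metrics
  take a `copy` selector, and the packaged maps for the troponin entries
  list both copies of the deposited asymmetric unit so printed values can
  be scanned for across copies.
* **Pocket openness.**  The TnC N-domain pocket state is a threshold
  call on the 13–51 Cα distance; the default threshold of 24 Å is the
  midpoint of the published closed/open anchors (19.21/29.06 Å) and is
  configurable.  Ties count as open.
* **Hydrogen bonds.**  Ligplot-style geometric criteria on heavy atoms:
  D–A ≤ 3.5 Å and D–H⋯A ≥ 120° with amide hydrogens inferred from the
  local backbone geometry; donors whose hydrogen cannot be placed fall
  back to an antecedent-angle proxy (C–D⋯A ≥ 90°).  Intra-residue pairs
  and sequence-adjacent amide–carbonyl contacts are excluded.  The
  original analysis names its tools but not their parameters; these are
  those tools' conventional defaults.
* **Helix assignment.**  A DSSP-like rule on the i → i+4 backbone bond
  ladder: two consecutive bonds (i, i+4) and (i+1, i+5) mark residues
  i+1…i+5, runs of ≥ 4 are segments, chain breaks split.  Requiring
  consecutive bonds (rather than one) makes a genuine local break in the
  ladder split a helix instead of being bridged by a single spanning
  bond.  This is deliberately a two-state (helix/coil) assignment, not
  DSSP's eight-state alphabet.
* **Axes, RMSD, RMSF.**  Helix axes are the first principal component of
  the segment's centred Cα coordinates (≥ 5 residues), oriented N→C.
  RMSD uses Kabsch superposition (via bio3d's fitting, recomputed at full
  precision from the fitted coordinates and cross-checked in the tests
  against an independent Kearsley quaternion oracle).  RMSF is the
  per-residue root mean square deviation from the mean structure over
  post-equilibration frames, on Cα atoms by default; frames are assumed
  superposed, with an optional internal superposition.

## The synthetic-data generator

`simulate_decay()` draws independent Poisson counts per channel around
the exact forward-model expectation — the generator and the fitted model
share their physics by construction, which is what makes the recovery
studies a test of the *inverse* problem rather than of the model.  The
default instrument emulates the measured setup: 1024 channels, and a
0.055 ns channel width so the window spans ≈ 5 lifetimes of an ~11 ns
donor; the default synthetic donor is bi-exponential
(α = 0.6/0.4, τ = 5/15 ns, intensity-weighted mean ≈ 11.7 ns,
AEDANS-like).  What the generator deliberately omits: afterpulsing,
pile-up, scattered excitation light, and detector IRF (available but off)
— so a green test suite shows the estimator is correct and calibrated
*under Poisson statistics*, not that real instruments have no systematic
effects.  `make_structure()` builds ideal poly-alanine backbones by
natural-extension (NeRF) placement at canonical dihedrals (α: φ=−57°,
ψ=−47°; strand: −139°/135°) with standard bond geometry — which is why
the i → i+4 bond ladder and the 1.5 Å rise/100° twist emerge rather than
being painted on — and embeds prescribed inter-site distances exactly
(classical MDS for >2 sites, with a realizability check).
`make_trajectory()` adds isotropic per-residue Gaussian jitter, whose
per-residue RMSF is $\sqrt{3}\sigma$ by the moment identity the tests
verify at 2000 frames.

## Problem sizes and determinism

The shipped test suite runs the full recovery study (24 measurable
conditions × 50 seeds at 10⁶ photons — the two conditions with
efficiency below the 2 % floor drop out by design), 2000-frame RMSF
studies, and 100-fold writer round-trips; the whole suite completes in
roughly ten minutes on one core.  All stochastic steps take explicit
integer seeds; the pipeline stamps every output with a hash of its
configuration, and identical config + seed reproduces outputs
byte-for-byte.

## Known limitations

* Gaussian $P(r)$ only — no maximum-entropy or multi-modal recovery, no
  global analysis across decays, no time-resolved anisotropy (so κ² stays
  at 2/3).
* The restraint force-constant mapping is one defensible convention, not
  a recovered protocol; anyone matching a different refinement engine
  should swap the mapping function.
* The crystal-distance checks depend on the deposited PDB entries, which
  the package cannot redistribute; without them those tests report the
  structures as unavailable.  The packaged chain maps for the deposited
  entries are best-effort defaults and user-overridable.
* Published simulation-derived observables (helix folding ranges, domain
  rotation angles, state occupancies, hydrogen-bond inventories) require
  the original long trajectories, which are not deposited; the
  corresponding metrics are therefore validated on synthetic ground
  truth and exposed for use on any supplied trajectory, not numerically
  reproduced.
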