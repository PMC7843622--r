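---
title: "Methods: from administered activity to DNA strand breaks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from administered activity to DNA strand breaks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(posidose)
```

This vignette is the package's own account of its models, assumptions and
numerical choices. It states no empirical result that the test suite or
`scripts/acceptance.R` do not themselves compute.

# Decaying-source dosimetry

## Model

A radionuclide of decay constant $\lambda = \ln 2 / t_{1/2}$ mixed
uniformly into a small medium volume delivers, over an irradiation time
$T$,

$$D = \frac{\tilde A \, \bar E \, \kappa}{m}, \qquad
  \tilde A = A_0 \int_0^T e^{-\lambda t}\,dt
           = \frac{A_0\,(1 - e^{-\lambda T})}{\lambda},$$

where $\tilde A$ is the cumulated activity (total decays), $\bar E$ the
mean kinetic energy of the emitted positron, $\kappa$ the $\beta^+$
branching ratio and $m$ the medium mass. The closed form is used
throughout; the tests cross-check it against trapezoid quadrature of the
decaying integrand at 0.1 s resolution (relative agreement $<10^{-6}$).

## Assumptions and limitations

* **Local absorption.** All $\beta^+$ kinetic energy is absorbed in the
  medium (absorbed fraction 1). For ¹⁸F in a ~2 mL vessel this is a good
  approximation: the mean positron range in water is ~0.6 mm, small
  against vessel dimensions, though a few-percent edge loss is real and
  is the main reason sphere-model codes report slightly different doses.
* **Annihilation photons excluded.** The 0.511 MeV photon pair mostly
  escapes a 2 mL flask; its dose contribution is excluded by
  construction ($\bar E$ and $\kappa$ refer to the $\beta^+$ channel
  only). This is a documented limitation, not an option.
* **Water-equivalent medium.** The medium mass defaults to volume at
  1 g/mL; an explicit mass may override it (with a 1% consistency check
  against unit density, defeatable for non-aqueous media).

With the built-in ¹⁸F record ($t_{1/2} = 109.77$ min, $\kappa = 0.9673$,
$\bar E = 249.8$ keV), 52.4 MBq decaying for 18 h in 2 mL gives 9.63 Gy;
inverse planning returns the initial activity for a target dose by exact
algebra, and the forward/inverse round trip is tested to $10^{-10}$
relative.

# Clonogenic survival, the LQ model and RBE

## Reduction

Plating efficiency is the mean colonies-per-seeded-cell ratio of the
unirradiated control replicates; the survival fraction at dose $D$ is the
treated ratio normalised by it, so $SF(0) = 1$ by construction. The
standard error of each point propagates both the replicate scatter at the
dose and in the control:
$SE(SF) = SF\sqrt{cv_D^2 + cv_0^2}$. Doses at which no replicate formed a
colony are flagged below-detection and excluded from log-domain fitting
(the log is undefined there); the exclusion is warned about, never
silent. These plating-efficiency and SF definitions are the standard
clonogenic-assay conventions and are stated here as an explicit
assumption of the reduction.

## Fitting

The linear-quadratic model $SF = e^{-(\alpha D + \beta D^2)}$ is fitted
as weighted least squares of $\ln SF$ on $(D, D^2)$ through the origin —
the standard linearisation in radiobiology — with weights
$1/(SE_{SF}/SF)^2$, the delta-method inverse variance of $\ln SF$.
Parameter covariance uses the estimated-$\sigma^2$ convention of weighted
least squares. Both $\alpha$ and $\beta$ are constrained non-negative:
when the unconstrained solution leaves the physical region the fit is
repeated with the offending coefficient pinned at zero and the feasible
model with the smallest weighted residual sum of squares is returned
(unconstrained fits remain available via `constrain = FALSE`).

The confidence interval for $\alpha/\beta$ is a delta-method interval
with a $t$ quantile at the fit's residual degrees of freedom. With the
4-dose assay design used throughout (3 positive doses, 2 parameters, 1
residual df) this calibrates at 91–93% empirical coverage for a nominal
95% interval in the package's own 500-dataset recovery simulations —
acceptably close given the tiny df.

## Isoeffect dose and RBE

The dose at survival level $s$ solves
$\beta D^2 + \alpha D + \ln s = 0$ (positive root; $-\ln s/\alpha$ when
$\beta = 0$), verified against bisection to $10^{-9}$ Gy. RBE at level
$s$ is $D_{\text{ref}}(s) / D_{\text{test}}(s)$. Two routes are provided
because sparse or nearly-linear test-arm data can make an LQ fit poor:
the default uses both arms' LQ fits; `method = "interp"` (automatic when
the test arm is a measured curve) reads the test isoeffect dose off a
piecewise log-linear interpolation of the measured points, with an
explicit extrapolation flag when the level lies outside the measured
range.

**RBE confidence interval.** The delta-method variance of
$\log \mathrm{RBE}$ combines two components, each carrying very few
residual degrees of freedom (often 1). A normal-quantile interval
undercovers badly there (we measured ~67% for a nominal 95%), and a
Satterthwaite df only partially repairs it (~88%). The package therefore
uses the conservative minimum-df $t$ rule for this Behrens–Fisher-type
problem, which we measured at ≥99% coverage — deliberately conservative
rather than anticonservative, and documented as such. Identical fits give
RBE exactly 1 with no interval ambiguity.

# The linear DNA model

The scoring geometry is a straight 100-base double-helix abstraction:
34 nm long along $z$, outer diameter 2.37 nm, base diameter 1 nm, one
axial slab of 0.34 nm per base. Within each slab the inner cylinder holds
two half-cylinder *base* volumes and the surrounding annulus two
quarter-cylinder *backbone* volumes, diametrically opposed, one per
strand. The published description fixes the dimensions but not the
azimuthal sector boundaries or any helical twist, so these are
parameters, not fixed truths:

* backbone sectors are centred at azimuth 0° (strand 0) and 180°
  (strand 1), each 90° wide; base half-cylinders cover the matching
  half-planes;
* the model is untwisted by default; `twist_per_base = 36` gives a
  B-DNA-like helical rotation of the sector pattern;
* boundary conventions are half-open with the lower bound inclusive
  (axial and azimuthal); radially the base region is
  $r \le r_\text{base}$ and the backbone annulus
  $r_\text{base} < r \le r_\text{outer}$.

Classification of points into volumes is pure and vectorised, and is
tested against an independent per-volume membership oracle, a
strand-parity property (180° rotation swaps strands), and Monte Carlo
volume-fraction closure.

The particle source is a coaxial cylinder enclosing the molecule. Its
dimensions are not published; the default (radius twice the outer DNA
radius, extending one outer radius beyond each end) is a compact
enclosure, is configurable, and is recorded with every campaign.
Emissions inside the scoring volumes are permitted — the source overlaps
the DNA — and directions are isotropic.

# The parameterized track-structure model

## What it is and is not

Event-by-event transport of sub-keV electrons and positrons in water with
published absolute accuracy requires condensed-history cross-section
libraries. This package does not reimplement those. Instead the engine is
an explicitly parameterized surrogate with the right structure: discrete
energy losses of tens of eV ("spurs"), nanometre-scale inelastic mean
free paths, elastic deflections, a terminal "blob" at the transport
cutoff, and a positron annihilation channel. All parameters are
configuration with recorded defaults:

| parameter | default | meaning |
|---|---|---|
| inelastic mfp | 2 nm @ 250 eV → 6 nm @ 1500 eV, log-linear | spur spacing scale |
| elastic mfp | 0.5 × inelastic | deflection frequency |
| elastic deflection | Gaussian, σ = 30° | direction change per elastic event |
| energy loss per collision | truncated exponential, scale 40 eV, max 100 eV | spur energy spectrum |
| transport cutoff | 100 eV | below this the particle terminates |
| blob smearing (positron) | Gaussian, σ = 2 nm | spatial extent of the terminal blob |
| annihilation ionizations | 2 × 20 eV at the terminus | extra localized damage channel |
| core-annihilation probability | 0 | qualitative Auger flag; doubles the annihilation ionization count when drawn |

The defaults were chosen once to give (a) per-collision losses of order
tens of eV, (b) nm-scale mean free paths at sub-keV energies, and (c)
ensemble LET that falls with increasing initial energy over 250–1500 eV.
Absolute strand-break frequencies, the published integral SSB/DSB
percentage differences and the ~7% LET excess at 250 eV all depend on the
cross sections a full toolkit carries and are **declared out of reach**
of this surrogate; what the package checks are the trends and invariants:
positron damage ≥ electron damage at every energy once the annihilation
channel is on, a positive integral excess, LET monotone in energy, and
exact energy bookkeeping.

## Mechanics and bookkeeping

A history alternates exponential free flights (combined
inelastic+elastic mean free path) with collisions; inelastic collisions
deposit a sampled energy at the collision point and degrade the particle
by the same amount, elastic collisions only deflect. At or below the
cutoff the residual energy is deposited as a blob (smeared for
positrons), and positrons append their annihilation ionizations,
flagged separately. The sum of non-annihilation event energies equals the
initial energy exactly (floating-point exact, tested at $10^{-9}$
relative); annihilation photons are not transported — their interaction
probability over nanometres is negligible — and secondary electrons are
not independently tracked, since sub-100 eV secondaries sit below the
transport cutoff; their energy stays at the spur point.

Track-averaged LET is total deposited energy (including the annihilation
channel) over path length; with energy in eV and path in nm the number is
already in keV/μm.

## Reproducibility

Every history owns an independent RNG stream (xoshiro256++ seeded by
SplitMix64 from the campaign seed and the primary id). Campaigns are
therefore bit-reproducible, parallelizable in principle, and —
importantly for the tests — electron and positron campaigns run with the
same seed are paired history-by-history: with the annihilation channel
and blob smearing disabled the two species produce identical event
streams, a limit the suite asserts as strict equality.

# Strand-break scoring

Energy is accumulated per backbone volume (strand, base) per primary
history; a volume reaching **17.5 eV** (inclusive) carries one SSB.
Accumulation-per-volume is the convention of the nanodosimetry scorers
this model emulates; a per-event mode is available for sensitivity
analysis. Base-region depositions never break the backbone. Two SSBs on
opposite strands within **10 bases** (inclusive) form a DSB. Both
thresholds read most naturally as attainable bounds, hence inclusive
comparisons; both are configurable, as is a relaxed same-strand pairing
flag (off by default — a double-strand break physically requires both
strands severed).

DSB pairing is a greedy sweep in ascending base index taking the nearest
eligible partner, each SSB consumed at most once. For this two-strand
proximity structure the greedy attains the maximum matching: the leftmost
unconsumed break's nearest eligible partner is also its leftmost, which
is the classical optimal greedy for matching two point sets on a line
within a tolerance. The suite verifies equality with an
exhaustive-search maximum matching over 10⁴ random break sets rather
than trusting the argument.

Monotonicity properties (raising the threshold cannot increase damage;
DSBs ≤ ⌊SSBs/2⌋) are tested on fixed event sets.

# Synthetic data: what it emulates and what it does not

* `make_survival_dataset` draws colonies as
  Poisson(cells × PE × SF(D)), truncated at the seeded count — the
  standard clonogenic noise model in the regime where colonies ≪ seeded
  cells; a binomial variant exists. The default design mirrors the
  published layouts: X-ray doses 0–7.5 Gy in 2.5 Gy steps and a
  radionuclide arm at 0 + 10–30 Gy, 3 replicates, plating efficiency
  0.6, and seeding graded from 100 to 10⁴ cells so expected colony
  counts stay countable (~60–110 per dish). These are the package's
  chosen study conditions; they are realistic for a prostate-cancer
  clonogenic assay but emulate no particular measured dataset.
* `make_two_arm_study` scales the test arm as
  $\alpha_t = \alpha\,\mathrm{RBE}$, $\beta_t = \beta\,\mathrm{RBE}^2$,
  which stretches the whole reference curve in dose by
  $1/\mathrm{RBE}$ so the constructed isoeffect ratio is exact at every
  survival level — a clean ground truth for recovery tests.
* `make_event_stream` produces deposition streams either uniform in the
  source or placed exactly at named volume centres with known energies,
  giving scoring tests fully constructed truths.

What passing these tests shows: the estimators recover the parameters of
data generated by their own assumed models, with calibrated uncertainty.
What they do not show: recovery under model misspecification (non-LQ
survival shapes, dose-rate repair effects, non-Poisson colony
over-dispersion), or any statement about real cell lines.

# Numerical choices and degenerate inputs

* Times are seconds and energies eV internally; nuclide records keep keV
  at the boundary and convert at the point of use (1 eV =
  1.602176634 × 10⁻¹⁹ J exactly).
* Mean-free-path interpolation is log-linear in energy, clamped at the
  table ends.
* A particle whose initial energy is at or below the cutoff terminates
  immediately: one blob event, zero path length, undefined LET (`NA`,
  never a division by zero).
* An energy-loss draw exceeding the remaining energy is capped at it, so
  bookkeeping stays exact.
* Degenerate fits (all doses equal) error out; a fit with
  $\alpha = \beta = 0$ has no finite isoeffect dose and says so.
* Ties in DSB pairing break deterministically (lower base index, then
  lower strand), making scoring a pure function of its inputs.

# Problem sizes

The test suite and the acceptance script run at sizes chosen to make the
statistical checks decisive while staying desk-scale: 500 synthetic
assays for LQ recovery, 40 two-arm studies for RBE, 10⁴ random break
sets against the exhaustive matcher, 10⁵ paired histories for the
positron-as-electron equivalence test and 2 × 10⁴ histories per
(species, energy, seed) for the damage-excess and LET-trend checks. The
engine simulates roughly 10⁵ sub-keV histories per second per core, so
campaigns at 10⁶ primaries per energy — the scale a full study would use
— remain practical.

# Known limitations

* The dose model ignores positron escape and annihilation-photon dose;
  both bias the analytic dose slightly high relative to transport-code
  sphere models (a few percent for ¹⁸F in 2 mL).
* The LQ machinery has no dose-rate (repair-kinetics) term; protracted
  exposures are compared to acute ones purely through the fitted curves.
* The track physics is a surrogate: no cross-section library, no
  positronium chemistry, no radical (indirect) damage, no base damage or
  complex-lesion classification, no repair. Its absolute damage
  frequencies are internally consistent but not comparable to published
  absolute values — only its trends and invariants are meaningful.
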