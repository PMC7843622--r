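# posidose

Positron (β⁺) emitters such as ¹⁸F are the workhorses of PET imaging, but
their own radiobiology — what a β⁺ does to a cell before it annihilates —
is rarely quantified. `posidose` is an R package for assessing the
therapeutic potential of β⁺-emitting radionuclides in vitro, covering the
full chain from administered activity to DNA damage:

1. **Decaying-source dosimetry.** For a radionuclide uniformly mixed into a
   culture medium, the absorbed dose follows the cumulated-activity
   formalism

   D = Ã · Ē · κ / m,  Ã = A₀ ∫₀ᵀ e^(−λt) dt = A₀ (1 − e^(−λT)) / λ

   with Ē the mean β⁺ kinetic energy, κ the β⁺ branching ratio, m the
   medium mass, and λ = ln 2 / t½. Forward dose, dose-rate profiles and
   inverse planning (activity needed for a target dose) are provided; an
   evaluated ¹⁸F record (t½ = 109.77 min, κ = 0.9673, Ē = 249.8 keV) ships
   with the package.

2. **Clonogenic survival and RBE.** Colony-count tables are reduced to
   survival fractions via plating efficiency, fitted with the
   linear-quadratic model SF = exp(−(αD + βD²)) by weighted least squares
   in the log domain, and compared across radiation qualities through the
   relative biological effectiveness RBE = D_reference / D_test at a
   stated survival level (default SF = 0.5).

3. **Sub-keV track structure and strand-break scoring.** An event-by-event
   Monte Carlo (Rcpp engine) transports 250–1500 eV electrons and
   positrons in water with a parameterized discrete-energy-loss model:
   exponential free flights, spur-like inelastic losses, elastic
   deflections, and a terminal blob at the 100 eV transport cutoff.
   Positrons additionally deposit annihilation-channel ionizations at the
   track terminus. Tracks irradiate a linear 100-bp DNA model (34 nm long,
   2.37 nm outer / 1 nm base diameter; quarter-cylinder backbone and
   half-cylinder base volumes per strand and base). Backbone volumes
   accumulating ≥ 17.5 eV score a single-strand break (SSB); two SSBs on
   opposite strands within 10 bases score a double-strand break (DSB);
   frequencies are reported per 10⁶ primaries with across-seed spread, and
   track-averaged LET (keV/μm) alongside.

A synthetic-data module generates colony tables with Poisson noise and
deposition-event streams with known ground truth, so the entire pipeline
is testable without any external data.

## Worked example

```r
library(posidose)

## dose from 52.4 MBq of F-18 decaying 18 h in 2 mL of medium
plan <- irradiation_plan(builtin_f18(), A0 = 52.4e6,
                         duration = 18 * 3600, medium_volume = 2)
absorbed_dose(plan)
#> <dose_result> dose 9.627 Gy over 4.974e+11 decays
#>   dose rate: initial 60.86 mGy/min, mean 8.914 mGy/min

## LQ fit of a synthetic clonogenic assay (truth alpha/beta = 3.66)
records <- make_survival_dataset(alpha = 0.2, beta = 0.2/3.66, seed = 42)
fit <- fit_lq(survival_fractions(records))
fit
#> <lq_fit> xray: alpha = 0.2089 Gy^-1, beta = 0.05236 Gy^-2, alpha/beta = 3.99 Gy

## RBE at SF = 0.5 from a two-arm study constructed with RBE truth 0.42
st <- make_two_arm_study(0.42, seed = 7)
rbe(fit_lq(survival_fractions(st$reference)),
    fit_lq(survival_fractions(st$test)), sf_level = 0.5)
#> <rbe_result> RBE = 0.4053 at SF = 0.5 (D_ref = 2.075 Gy / D_test = 5.119 Gy)
#>   CI: [0.303, 0.5421]

## positron vs electron strand breaks on the linear DNA model
camp <- run_campaign(c("electron", "positron"),
                     energies_ev = c(250, 500, 1000),
                     n_primaries = 5000, seeds = 1)
aggregate_damage(score_campaign(camp, dna_geometry()))
#>    species energy_ev n_seeds ssb_per_1e6 ... dsb_per_1e6 ... let_kev_um
#> 1 electron       250       1       98200          2800         32.47
#> 2 electron       500       1       79200          1800         17.51
#> 3 electron      1000       1       47400           200         11.00
#> 4 positron       250       1      124400          4600         37.66
#> 5 positron       500       1       83600          2600         18.91
#> 6 positron      1000       1       48000           400         11.44
```

Reading the output: 52.4 MBq of ¹⁸F delivers ≈ 9.6 Gy over 18 h to a 2 mL
medium (the dose rate falls from ~61 to ~0.07 mGy/min as the source
decays). The LQ fit recovers the generating α/β within its confidence
interval, and the two-arm study recovers the constructed RBE of 0.42. In
the track campaign, SSB and DSB frequencies fall with increasing primary
energy while positrons out-damage electrons at every energy — most
strongly at 250 eV, where thermalization and annihilation deposit their
energy within a few nanometres of the track end.

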