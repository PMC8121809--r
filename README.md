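# photokin

Global-fit analysis of time-resolved difference spectroscopy for
microbial-rhodopsin photocycles — written for spectroscopists who record
flash-induced absorbance-difference matrices (merged step-scan/rapid-scan
FTIR, or flash-photolysis UV/VIS) and need to turn them into photocycle
kinetics: shared rate constants, amplitude spectra, species-associated
difference spectra, marker-band time courses, and kinetic-scheme
comparisons. The motivating system is the anion channelrhodopsin GtACR1,
whose two-step channel opening and closing, weak late N/O intermediate and
absent light-adapted *syn* photocycle the built-in synthetic generator
reproduces; everything also applies to bacteriorhodopsin-like photocycles
generally.

## The model

A photocycle is a network of first-order reactions, so every measured
channel is a sum of exponentials in the shared apparent rates. The fit
minimises the weighted squared error

```
F = Σₙ Σₘ w(ν̃ₙ)² ( ΔE(ν̃ₙ, tₘ) − a∞(ν̃ₙ) − Σᵢ aᵢ(ν̃ₙ) e^(−kᵢ tₘ) )²
```

over N shared rate constants kᵢ, per-channel amplitude spectra aᵢ(ν̃) and
offsets a∞(ν̃), with per-channel weights w(ν̃). The problem is separable
and is solved by **variable projection**: an outer bounded quasi-Newton
search over log₁₀ kᵢ (multi-start: greedy sequential initialisation plus
seeded jittered starts) with the linear coefficients eliminated exactly by
per-channel least squares at every step. Half-lives are reported as
t₁/₂ = ln 2 / k. Downstream, amplitude spectra are converted to
intermediate-minus-ground species spectra by inverting the closed-form
population solution of an irreversible scheme, and candidate L-state
wirings are compared by direct scheme-level fits ranked by BIC, with an
explicit indistinguishability flag for topologies that are
reparameterisations of the same exponential-sum model.

## A worked example

```r
library(photokin)
model   <- default_gtacr1_model()      # branched photocycle, marker-band spectra
dataset <- simulate_dataset(model)     # 350 channels x 120 times, noiseless
fit     <- fit_global(dataset, n_exp = 6, n_starts = 8, seed = 1)
print(fit)
```

```
Global multi-exponential fit: N = 6, 350 channels x 120 times
  objective F = 1.3198e-19   converged: TRUE   (8 starts, weights: uniform)
        rate halflife
T1 1.540e+06 4.50e-07
T2 3.851e+04 1.80e-05
T3 3.648e+02 1.90e-03
T4 1.980e+01 3.50e-02
T5 6.478e+00 1.07e-01
T6 1.575e-01 4.40e+00
```

The six recovered half-lives — 450 ns, 18 µs, 1.9 ms, 35 ms, 107 ms,
4.4 s — are the generator's ground truth: K decay, fast and slow channel
opening, fast and slow channel closing, and ground-state recovery.
`assign_transitions(fit, gtacr1_reference_transitions("FTIR"))` labels
them accordingly (all fitted/reference ratios print as 1.000 on noiseless
data). From here, `amplitude_spectra_to_species()` recovers the
intermediate difference spectra (the conducting-state spectrum carries the
+1691 cm⁻¹ marker and the 1708(−)/1716(+) carbonyl pair; the M spectrum
lacks the 1184 cm⁻¹ protonated-retinal band), `extract_trace()` pulls
marker-band kinetics, `detect_band()` verifies the absence of the
1154 cm⁻¹ *syn*-cycle marker, and `discriminate_topologies()` ranks
candidate L-state wirings.

A command-line wrapper with `simulate` / `fit` / `species` / `markers` /
`compare` subcommands ships in `inst/exec/photokin`.

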