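---
title: "Global-fit analysis of photocycle difference spectra with photokin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Global-fit analysis of photocycle difference spectra with photokin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photokin)
```

## The measurement and the model

Flash-photolysis difference spectroscopy of microbial rhodopsins records a
matrix $\Delta E(\tilde\nu_n, t_m)$: the absorbance change relative to the
dark ground state at $N_{\tilde\nu}$ spectral channels (wavenumbers for FTIR,
wavelengths for UV/VIS) and $N_t$ delay times after an actinic laser flash at
$t = 0$. Photoproduct bands are positive, depleted educt bands negative.
Because step-scan FTIR covers sub-microsecond to millisecond delays and
rapid-scan FTIR covers milliseconds to seconds, full photocycle datasets are
merged from two acquisition segments; `merge_segments()` implements this with
an explicit overlap policy (least-squares scaling of the late segment, or
plain concatenation with duplicate delays averaged), since instrument
vendors leave this reconciliation step unspecified.

The photocycle itself is modelled as a network of first-order reactions
among intermediate states (K, L, M, N/O, ...) that returns to the ground
state. Writing $Q$ for the rate matrix ($Q_{ji} = k_{i \to j}$,
$Q_{ii} = -\sum_j k_{i \to j}$), the state populations obey
$P(t) = e^{Qt} P(0)$, so every observable time course is a sum of
exponentials in the *apparent rates* — the negated non-zero eigenvalues
of $Q$. For an irreversible chain these equal the step rate constants.
Populations are computed by eigendecomposition, with a
scaling-and-squaring matrix exponential as fallback when the
eigenvector matrix is ill-conditioned (relative eigenvalue gaps below
$10^{-9}$ are treated as degenerate); direct ODE integration is avoided
because photocycle rates span some seven decades and make the system
stiff. Half-lives, time constants and rates are interconverted as
$t_{1/2} = \tau \ln 2 = \ln 2 / k$, the convention used throughout.

## The global fit

The central estimator is `fit_global()`, which minimises the weighted
squared-error objective

$$
F \;=\; \sum_{n=1}^{N_{\tilde\nu}} \sum_{m=1}^{N_t} w(\tilde\nu_n)^2
\Bigl(\Delta E(\tilde\nu_n, t_m) - a_\infty(\tilde\nu_n)
- \sum_{i=1}^{N} a_i(\tilde\nu_n)\, e^{-k_i t_m}\Bigr)^2
$$

over $N$ shared rate constants $k_i$, per-channel amplitude spectra
$a_i(\tilde\nu)$ and offsets $a_\infty(\tilde\nu)$. The problem is
separable: for fixed rates the amplitudes are exact per-channel linear
least-squares solutions (`solve_amplitudes()`), so the outer search runs
only over $\log_{10} k_i$ — variable projection. A minimiser of the
projected problem minimises the full objective; eliminating the
thousands of linear coefficients is what makes the fit tractable and
reproducible. Because each channel's weight is constant along time, the
weights cancel from the per-channel normal equations and enter only the
aggregated objective.

Numerical choices, all tunable through arguments:

* **Rate parameterisation.** $\log_{10} k$ enforces positivity and
  handles the seven-decade dynamic range; bounds default to
  $[1/(10\,t_{\max}),\; 10/t_{\min}]$.
* **Multi-start.** The outer bounded quasi-Newton search (`nlminb`) runs
  from `n_starts` tuples: a greedy sequential start (components added
  one at a time from a 36-point log grid, polishing after each
  addition), an evenly log-spaced tuple, and seeded jittered/uniform
  tuples. The greedy start was added after diagnosing basin-of-attraction
  failures of purely random starts on noisy data; the best start wins.
* **Convergence.** Relative objective tolerance $10^{-10}$ by default.
  A result is flagged `converged` when the winning start stopped
  cleanly, or when a cleanly stopped start reached the same objective
  within tolerance (`nlminb` reports a spurious "false convergence"
  when started at an already-polished optimum).
* **Offsets.** $a_\infty$ is fitted by default because the objective
  includes it; a closed photocycle implies $a_\infty \approx 0$, and
  `with_offset = FALSE` pins it. Note that over a finite time window the
  offset is nearly collinear with the slowest exponential; when the
  slowest component is weak, fitting offsets visibly inflates its
  uncertainty.
* **Identifiability.** Exponential analysis cannot separate rates closer
  than roughly a factor of three; fitted rate pairs inside that factor
  are recorded in the result's `notes`, as a warning rather than an
  error.
* **Weights.** The weighting factors are "noise-dependent" by
  convention but not uniquely defined; two estimators are provided and
  the choice is recorded in the result. `"uniform"` (default) sets all
  weights to 1; `"inverse_noise"` uses $1/\hat\sigma(\tilde\nu)$ with
  $\hat\sigma$ the standard deviation of second differences along time
  divided by $\sqrt 6$, floored at the 5th percentile across channels so
  no weight diverges.

`select_order()` chooses $N$ by BIC, counting the shared rates plus
every per-channel amplitude (and offset) as parameters. The number of
exponentials in published photocycle work is usually fixed by chemical
reasoning; the automated criterion is a convenience, not a claim.

## The synthetic-data generator

The measured datasets behind the reference kinetics are not publicly
deposited, so the package carries a first-class forward generator.
`default_gtacr1_model()` encodes a branched anion-channelrhodopsin
photocycle whose six apparent rates equal $\ln 2 / t_{1/2}$ for the
reference half-lives 450 ns, 18 µs, 1.9 ms, 35 ms, 107 ms and 4.4 s
(FTIR column of the transition table; a UV/VIS variant uses 3 µs, 23 µs,
2.3 ms, 23 ms, 200 ms, 3.5 s), and whose species spectra are composed of
Gaussian/Lorentzian bands implementing the established marker-band
assignments on a 1100–1798 cm$^{-1}$ axis at 2 cm$^{-1}$ spacing:

| band (cm$^{-1}$) | amplitude | states | meaning |
|---|---|---|---|
| 1529 (−) | −1.0 (reference scale) | all intermediates | ground-state retinal C=C bleach |
| 1184 (+) | +0.6 | K, L1, L1′, L2 | protonated 13-*cis* retinal; decays upon M formation |
| 1644 (−) | −0.5 | L2 | amide-I conformational change of channel opening |
| 1691 (+) | +0.35 | L2 | conducting-state marker |
| 1708 (−) | −0.25 | L1 onward | protonated-glutamate bleach (central-gate residue) |
| 1716 (+) | +0.25 | L2 onward | its reprotonated, H-bond-shifted counterpart |
| 1515 (+) | +0.5 | K | red-shifted ethylenic photoproduct |
| N/O | ×0.1 | N/O | spectrally weak late intermediate |

Absolute difference-absorbance values are not published; the amplitudes
are declared conventions chosen to reproduce the qualitative band
hierarchy of the measured kinetics, with FWHM 8 cm$^{-1}$
(fingerprint/carbonyl) and 12 cm$^{-1}$ (amide I). Two constructions
deserve comment. First, the glutamate deprotonates "within
sub-microseconds, early in the photocycle", which this model realises by
switching the 1708(−) bleach on at the K → L1 step; together with the
K-specific ethylenic band — the universal signature of red-shifted
K states in microbial rhodopsins — this gives the 450 ns transition a
non-zero difference spectrum. Without some K/L1 spectral contrast that
transition would be invisible to any fit. Second, the reversible
L2 ⇌ M reaction (back/forward ratio `r_rev`, default 0.3 — the
magnitude is experimentally unconstrained) would shift the block's
eigenvalues away from the target rates, so the generator calibrates the
L2→M, M→L2 and M→N/O rate constants in closed form such that the
apparent rates still equal the targets. The branching fraction toward
the fast-opening branch defaults to $\phi = 0.7$, reflecting that the
first opening rate is the more prominent one. No state carries the
1154 cm$^{-1}$ band that marks the 13-*cis*,C=N-*syn* retinal of a
light-adapted parallel photocycle: its absence *is* the modelled
biology, and `detect_band()` confirms absence unless a band is injected.

Noise is i.i.d. Gaussian per cell (optionally per-channel
heteroscedastic, to exercise the weights), drawn from a private RNG
stream fully determined by an explicit `seed`; `noise_sigma = 0` gives
the exact forward model, which by construction lies inside the
multi-exponential model class. The generator does **not** emulate
baseline drift, water-vapour lines, photoselection anisotropy,
correlated detector noise, or light-adaptation effects — passing tests
on synthetic data therefore demonstrates correctness of the estimator,
not robustness to every artefact of real interferograms.

Default problem sizes: 350 channels × 120 log-spaced times from 100 ns
to 20 s for FTIR work; reduced grids (for example every fourth or
seventh channel, 60–90 times) are used in unit tests and in the
topology-discrimination analysis to keep runs in the seconds-to-minutes
range. These are stated sizes of the analyses, and all reported numbers
are computed at run time.

## From amplitude spectra to photocycle quantities

`amplitude_spectra_to_species()` converts fitted amplitude spectra into
intermediate-minus-ground *species* spectra by inverting
$a_i(\tilde\nu) = \sum_s X_{si}\, \Delta A_s(\tilde\nu)$, where
$P_s(t) = \sum_i X_{si} e^{-k_i t}$ is the closed-form population
solution. This inversion is only well-posed for irreversible schemes
(the transient subgraph must be acyclic) with matched rates (fitted vs
scheme apparent rates within 20 % after sorting) and a well-conditioned
$X$ (condition number below $10^8$); reversible schemes are refused and
routed to the direct scheme-level fit instead. The
`reversible = FALSE` variant of the default model exists precisely for
this route.

`assign_transitions()` matches fitted half-lives to a reference table of
processes by rank order — deterministic under noise, unlike
nearest-value matching — and reports per-pair ratios.
`scale_to_band()` reproduces the common practice of scaling difference
spectra to a shared band (e.g. at 1234 cm$^{-1}$) before comparison.

`discriminate_topologies()` addresses the wiring of the three L states.
Each candidate scheme template is fitted directly: nonlinear search over
its rate (and branching) parameters with per-state spectra eliminated by
per-channel least squares on the population courses — variable
projection at the scheme level — and candidates are ranked by BIC
(scheme parameters plus one spectral value per state and channel; no
spectral-smoothness penalty, the simplest defensible count). A
fundamental caveat is stated openly: topologies with the same number of
transient states that can realise the same apparent rates are exact
reparameterisations of one exponential-sum model and can never be
separated by this data alone — the same limit that leaves the
L1/L1′ wiring undecided experimentally. The ranking therefore flags
indistinguishability whenever the top candidates lie within
$\Delta\mathrm{BIC} < 10$ (the conventional decisive-evidence cut), and
under-parameterised candidates (e.g. a single-open-state scheme) are
rejected only while the noise level still resolves the missing
components.

## Known limitations

* No error bars on fitted rates (bootstrap or profile likelihood would
  be natural extensions; `simulate()` on a fitted object provides
  parametric replicates as a starting point).
* At noise levels of a few percent of the maximum signal, the
  information content of the data itself limits rate recovery: the
  Fisher information of the exponential model puts the spectrally weak
  N/O decay and the partially overlapping opening/closing rate pairs at
  relative uncertainties of tens of percent, regardless of estimator.
  The identifiability notes on the fit object exist for this reason.
* FTIR and UV/VIS datasets are fitted independently; no shared-rate
  joint mode is offered, matching the practice of reporting separate
  half-life columns per method.
* The UV/VIS species bands are placeholders (no measured absorption
  maxima are reproduced).
* Proprietary interferometer formats are not parsed; datasets enter as
  the documented TSV matrix dialect.

## A worked example

```{r example, eval = FALSE}
model <- default_gtacr1_model()
dataset <- simulate_dataset(model)          # 350 channels x 120 times, noiseless
fit <- fit_global(dataset, n_exp = 6, n_starts = 8, seed = 1)
print(fit)
assign_transitions(fit, gtacr1_reference_transitions("FTIR"))

species <- amplitude_spectra_to_species(
  fit_global(simulate_dataset(default_gtacr1_model(reversible = FALSE)),
             n_exp = 6, n_starts = 8, seed = 1),
  default_gtacr1_model(reversible = FALSE)$scheme)
detect_band(species$L2, 1154, 12, threshold = 0.05)   # syn marker: absent
```
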