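---
title: "Methods: additive free-energy optimization of peptide ligands"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: additive free-energy optimization of peptide ligands}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peptadd)
```

## The model

peptadd treats a short unstructured peptide ligand as a collection of
residues that contact a protein target largely independently. Under that
assumption the standard binding free energy of a variant carrying several
point substitutions is additive:

$$\Delta G^\circ_{\text{combo}} = \Delta G^\circ_{\text{lead}} +
  \sum_i \Delta\Delta G_i, \qquad
  \Delta\Delta G_i = \Delta G^\circ_{\text{variant}_i} -
  \Delta G^\circ_{\text{lead}},$$

with $\Delta G^\circ = RT\,\ln K_d$ ($K_d$ in molar). All standard errors
propagate in quadrature (root-sum-square), which is exact for the linear
sum and first-order for the nonlinear maps ($\ln$, $\exp$, ratios).
Additivity is expected to hold when substitutions do not interact
structurally; adjacent substitutions — especially two bulky aromatics side
by side — can interfere and yield *sub-additive* combinations (observed
binding weaker than predicted, a positive deviation in our sign
convention). Cooperative (super-additive) behaviour is representable in
the simulator but is not what short unstructured peptides show.

**Temperature.** The measurement temperature is not part of the tabulated
inputs, so the package fixes $T = 298.15$ K with
$R = 1.9872\times10^{-3}$ kcal mol$^{-1}$ K$^{-1}$ as the default; this
choice reproduces the published micromolar Kd ranges from the published
free energies (e.g. $-8.10 \pm 0.29$ kcal/mol $\to$ 1.9–0.7 µM). $T$ is an
argument everywhere it matters.

**Units.** Kd is molar and energies are kcal/mol internally; µM/nM and
2-significant-figure formatting appear only at I/O, matching the
conventions of affinity tables.

**Replicate aggregation.** $\Delta G^\circ$ and $K_d$ are averaged
*separately* across replicate experiments (mean and standard error of the
mean). The package carries both and never recomputes one mean from the
other — the published tables were built the same way, which is why a
printed $\Delta G^\circ$ can deviate by ~0.01–0.03 kcal/mol from
$RT \ln \bar K_d$. One consequence the tests document explicitly: the
D4Y+M7K prediction prints as −6.66 kcal/mol while the sum of the printed
single-variant inputs is −6.67.

## Error propagation and its validity envelope

Propagation is first-order throughout: $se(\Delta G) = RT\,se(K_d)/K_d$,
$se(K_d) = K_d\,se(\Delta G)/RT$, ratios combine relative errors in
quadrature. Against a $10^5$-draw Gaussian Monte-Carlo oracle, the linear
additive sum is exact, the log map agrees to well under 1% at the
relative errors in the packaged tables (~12%), and the Kd *ratio*
(fold-change) agrees to ~2% when the denominator's relative error is
$\lesssim$ 12%. The ratio distribution grows heavy-tailed as the
denominator error grows: at ~19% relative error the Monte-Carlo SD already
exceeds first-order by ~16%. Fold-change standard errors on inputs with
relative errors much above ~15% should therefore be read as lower bounds;
the package reports first-order values because that is the convention of
the tables it mirrors.

## Binding models and fitters

Three measurement modalities share one 1:1 interaction model:

* equilibrium isotherm $R = R_{max} C/(C + K_d)$;
* kinetics $R(t) = R_{eq}(1 - e^{-k_{obs}t})$ with
  $k_{obs} = k_{on}C + k_{off}$, dissociation $R_0 e^{-k_{off}t}$, and
  $K_d = k_{off}/k_{on}$;
* anisotropy titration through the exact 1:1 depletion quadratic, coded in
  the numerically stable conjugate form
  $f = 2P/\big(a + \sqrt{a^2 - 4PL}\big)$, $a = P+L+K_d$, which passes
  smoothly to the dilute hyperbola as the labeled concentration
  $L \to 0$.

No mass-transport, bivalent-analyte or drift terms are modeled: the
kinetic analyses this package mirrors report single $k_{on}/k_{off}$
pairs.

Fitting is Levenberg–Marquardt least squares (`minpack.lm::nls.lm`).
Numerical choices:

* all rate and affinity parameters are fit in log-space, so positivity
  holds by construction and no bounded solver is needed;
* multi-start initialization: Kd starts on a $10^{\pm2}$ log-grid around
  the geometric mean of the concentration grid with
  $R_{max,0} = 1.2\times$ the maximum response; kinetics starts on a
  $5\times5$ log-grid of $(k_{on}, k_{off})$; the best SSE wins, ties
  resolved toward the smaller first parameter;
* kinetic fits are *global* across concentrations by default (shared
  $k_{on}, k_{off}$, per-curve $R_{max}$) — whether the original fits were
  global or per-curve is not recorded, so global is the default and a
  single-curve fit is permitted with a warning;
* standard errors come from the fit covariance and map back through the
  delta method, $se(\theta) = \theta\,se(\log\theta)$;
* identifiability warnings are non-fatal: a fitted Kd outside the
  concentration series, or fewer than three distinct concentrations,
  warns rather than errors (the estimate is extrapolated and its SE
  widens accordingly);
* a titration with essentially constant signal is rejected as
  unidentifiable;
* when sensorgrams are reduced to isotherm points, the equilibrium readout
  is the response at the end of the association window.

Empirically (seeded simulations in the test suite), all three fitters
recover truth to solver tolerance on noiseless data, and their
$\pm 2\,SE$ intervals cover truth in $\ge 90\%$ of 200 noisy replicates
(60 for kinetics, whose fits are costlier).

## The simulator: what it emulates and what it does not

`energy_landscape()` is the ground truth: a per-(position, residue)
$\Delta\Delta G$ table (identity entries zero) plus optional
nearest-neighbour coupling terms $\varepsilon$ added when *both* adjacent
positions carry substitutions. Positive $\varepsilon$ weakens binding
(sub-additivity), the only deviation direction seen in short peptides;
negative values are allowed but off by default. No quantitative magnitude
for the nearest-neighbour deviation is established experimentally, so the
default draw range 0.3–0.7 kcal/mol is a package choice, flagged as such —
it is comparable to a single substitution's gain, large enough to detect.

`random_landscape()` draws exactly `n_enhancing` enhancing cells from
`ddg_range` (default −0.9 to −0.5 kcal/mol, the scale of measured
single-substitution gains), a mildly detrimental background (0 to
+0.5 kcal/mol) elsewhere, and a lead $\Delta G^\circ$ of −5.21 kcal/mol
(a high-micromolar lead) — together a caricature of a productive
point-variant scan.

`simulate_screen()` generates the single-concentration screen
*mechanistically*: a finite 60 s association under 1:1 kinetics with a
shared reference $k_{on}$ (default $10^4\ \mathrm{M^{-1}s^{-1}}$) and
$k_{off} = k_{on} K_d$, rather than assuming equilibrium — a slow binder
need not equilibrate in 60 s. Responses scale with the analyte's molecular
weight relative to the lead (RU tracks bound mass); the
molecular-weight adjustment in `fold_change_map()` inverts exactly that
factor. Screening below the lead Kd compresses saturation less and widens
the usable fold-change range: for a 10-fold Kd gain the noiseless
fold-change is 3.18 at 50 µM but 7.86 at 5 µM. Noise is i.i.d. Gaussian on
the response scale; drift, spikes, regeneration artifacts and
off-target/specificity effects are *not* simulated, so passing tests
demonstrate the algorithm's statistical behaviour under its own model, not
robustness to instrument pathology or non-specific binding.

All randomness flows from one explicit integer seed per call; independent
artifacts within a call derive sub-seeds from fixed streams, so outputs
are reproducible piecewise.

## Pipeline design choices

* **Two enumeration modes.** A 17-position scan over an 8-letter set gives
  132 variants excluding identity substitutions; a 19-letter scan counted
  as $17 \times 19 = 323$ includes them. Both published counts are
  reproduced by `exclude_identity` (default) and `include_identity`
  respectively; which convention the 323-member library actually used is
  not stated, so both are provided rather than guessing.
* **Selection threshold.** Default 15-fold, the documented choice for the
  TNF1 scan; the count of positions exceeding 10-fold is attached as a
  secondary summary. The boundary is a strict $\ge$.
* **Adjacency rule.** When two chosen candidates at adjacent positions
  would both introduce a bulky aromatic ({W, Y, F}), the position with the
  smaller $|\Delta\Delta G|$ switches to its best non-bulky alternative if
  one exists. This mirrors the judgment call that picked serine over
  tyrosine at position 4 next to a tyrosine at position 5; because it is a
  judgment call, the rule is optional (`adjacency_rule = FALSE`) and every
  decision is logged in the plan. Per-position ties break by substitution
  letter, making planning deterministic and idempotent.
* **Both slope estimators.** The observed-vs-predicted regression is
  reported both as ordinary least squares with intercept and as regression
  through the origin, each with a 95% CI. On the packaged seven-variant
  table these give 0.942 and 0.965; the published figure quotes
  0.97 ± 0.01, which neither estimator reproduces from the printed values
  (the original fit was presumably error-weighted or used unrounded
  internals). No attempt is made to match it.
* **Deviation flagging.** A variant set is flagged sub-additive when
  $|\Delta G_{obs} - \Delta G_{pred}|$ exceeds
  $\max(2\,SE_{combined}, \text{threshold})$. At the 2-SE default an
  occasional false positive is expected by construction; across 50 seeded
  additive ($\varepsilon = 0$) runs the flag rate is 4.2% and the mean OLS
  slope is 0.998, while a +0.5 kcal/mol adjacent coupling is flagged in
  40/40 coupled combinations.

## Problem sizes used in the test suite

End-to-end simulations run a deliberately compact configuration chosen to
exercise every stage with comfortable statistics: the full 17-position
randomized region over a 3-letter substitution set (49 variants), a 10 µM
screen with 0.5 RU noise and triplicate injections, a 1.5-fold selection
threshold (the simulated single-variant gains top out near 3-fold at this
concentration), and three independent 6-concentration isotherm experiments
per peptide, aggregated as separate $\Delta G$/$K_d$ means. The
50-seed additivity suite and the coupled-landscape detection suite both
use this configuration.

## Known limitations

* First-order error propagation understates fold-change uncertainty for
  inputs with large (>15%) relative errors (see the validity envelope
  above).
* The simulator's noise model is idealized; conclusions about instrument
  artifacts, surface avidity, or specificity against competitor mixtures
  are out of scope.
* The additivity machinery detects sub-additive coupling but does not
  model it predictively — combining more than ~4 substitutions, or pushing
  into the low-nanomolar range where steric crowding accumulates, is
  outside the validated regime.
* Enthalpy/entropy decomposition is not attempted; only standard free
  energies are handled.
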