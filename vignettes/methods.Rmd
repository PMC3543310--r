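---
title: "Granulosa-cell steroidogenesis: model, calibration and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Granulosa-cell steroidogenesis: model, calibration and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(gcsteroid)
```

This vignette is the package's own account of the science it
implements: the model and its assumptions, the parameters that matter,
what the synthetic-data generator does and does not emulate, the
numerical choices, and the design decisions that were genuinely open.

## The biological model

A single rat granulosa cell (GC) is described by twelve states: mRNA
and protein quantities of the three terminal steroidogenic enzymes —
aromatase (Cyp19), the activating 17β-hydroxysteroid dehydrogenase
Hsd17b1 and the inactivating Hsd17b2 — plus the intracellular
quantities of the four sex steroids (androstenedione A, testosterone
T, estrone E1, estradiol E2) and of FSH.  Units are per cell
throughout: pg for mRNA, protein and FSH, pmoles for steroids, ml and
minutes elsewhere.  Working with quantities rather than concentrations
is deliberate: the Michaelis constants are given in pmoles per cell,
so quantities make the kinetic terms direct, and concentrations are
derived views (quantity over compartment volume).

Transcription of Cyp19 and Hsd17b1 is multiplicatively induced by
intracellular FSH with slope factors κ: synthesis is
`σ_L f ν (1 + κ·FSH_GC)`.  Two features motivated this form over,
say, an additive FSH term.  First, the baseline steady-state
derivation (`ν_mRNA = δ_mRNA·mRNA₀`, `ν_prot = δ_prot·prot₀/mRNA₀`,
one protein per mRNA translated) must hold exactly at zero FSH, which
a multiplicative induction preserves by construction.  Second, with
FSH partitioning into the cell at unit ratio, 20 ng/ml of medium FSH
gives an intracellular quantity of 5.4×10⁻⁶ pg and hence an induction
factor of about 12 with the calibrated κ_Cyp19 — matching the
measured ~12-fold rise of the aromatization flux under FSH.  Hsd17b2
is treated as neither FSH- nor disruptor-regulated.

The six interconversion fluxes are competitive Michaelis–Menten terms;
each enzyme's two substrates inhibit each other competitively, with
the competitor's own Km serving as its inhibition constant — the only
defensible choice given that a single Km per enzyme–substrate pair is
available.  Endocrine disruptors act in two ways: transcription
fold-changes `f` on the inducible enzymes (applied as a step while
exposure lasts, matching how 4-h fold-change measurements are used),
and an aromatase-Km fold `f_M = 1/activity fold` representing direct
competitive inhibition.

## Compartments

*In vitro*, the cell exchanges hormones with its share of culture
medium (total volume divided by cell count) by passive diffusion:
uptake `K_in = K_out/R_oi`, so that the medium-to-cell concentration
ratio at equilibrium equals the partition coefficient `R_oi` (~0.01
for the steroids: cells concentrate them ~100-fold).  The FSH
partition coefficient and excretion constant are not reported
anywhere we know of; the defaults (`R_oi = 1`, `K_out = 10⁻⁸ ml/min`,
the same nominal excretion constant used for the steroids) reproduce
the observed FSH flux induction and are exposed in the configuration.

*In vivo*, the 0.05-ml diestrus ovary is split into GCs,
metabolically inert "other cells" (thecal/interstitial; they exchange
hormones but have no terminal-steroidogenesis enzymes assigned), and
an extracellular space fed by cyclic FSH/androgen input
(`Q = Q_base + Q_scale·Q_shape(t)`) and cleared by ovarian blood flow.
The input waveforms, stage sampling times and compartment geometry are
*not* identifiable from any printed source — only the concentration
and flux profiles they produce are.  The package therefore ships them
as an editable template (`cycle_template()`).  The bundled
`calibrated` template uses smooth unit-peak bumps (FSH surge late in
proestrus, width 200 min; androgen bump width 181 min; a broad
post-ovulatory androgen decline of depth 0.0375) and a geometry with
86% of the ovary extracellular; five shape/geometry knobs were tuned
once, by Nelder–Mead, to the reference A→E1 flux values at diestrus,
proestrus and estrus (6.09, 6.17, 5.10 ×10⁻⁹ pmoles/min/cell), which
the frozen template reproduces within 0.2%.  These in vivo fluxes
should be read as properties of the bundled template, not as
independent predictions.  The in vivo cell uses `σ_L = 1`: the
inter-study factor models culture pre-treatment artifacts, which have
no in vivo counterpart.

A reconstruction note: the reference in vitro fluxes (7.29×10⁻⁹ and
8.72×10⁻⁸ pmoles/min/cell at 48 h, without/with FSH) are obtained
with the calibrated posterior-mode kinetics *and* the baseline
study's inter-study factor σ_L = 0.685 — with σ_L = 1 both values
come out exactly 1/0.685 too high.  The package's flux-analysis
examples and configs therefore carry `sigma_L = 0.685`.

## Calibration

The sampled vector has 24 components: two FSH slopes, four Vmax and
four Km values (the Hsd17b2 constants stay fixed at their literature
values), the inter-study hyperparameters µ₀ and Σ₁, ten per-study
transcription factors σ_L (lognormal around µ₀ with log-scale SD Σ₁),
and two measurement-error scales.  Observation errors are lognormal
around the model predictions with log-scale SD Σ₂ (mRNA/protein
endpoints) or Σ₃ (hormone endpoints).  We interpret Σ₁–Σ₃ as log-scale
*standard deviations*: the exact coefficient of variation is
`sqrt(exp(Σ²)−1) ≈ Σ`, so posterior scales of 0.65 and 0.48 correspond
to the reported ~65% and ~48% CVs.  Reading them as variances would
put those CVs near 95% and 78% instead.

The sampler is Metropolis-within-Gibbs with log-scale random-walk
proposals.  Three kinds of update blocks are used:

* each reaction's (Vmax, Km) pair jointly, and every other component
  individually — the Vmax/Km pairs are the classic strongly-correlated
  kinetic pairs, and pairing them noticeably improves mixing over
  strictly one-at-a-time updates;
* a directional move along the hierarchy's soft direction (all Vmax up,
  all σ_L and µ₀ down), which leaves hormone predictions nearly
  invariant and is constrained only by expression data;
* a full 24-dimensional proposal whose covariance is learned from the
  chain history during burn-in (classic adaptive Metropolis scaling,
  2.38/√d), frozen at the end of burn-in so that the retained half of
  each chain is a valid Markov chain.

Proposal scales adapt towards ~30% acceptance during burn-in (the
first half of each chain) only.  Chains start from independent
prior-quantile draws between the 20th and 80th percentiles:
overdispersed relative to the posterior, but away from the extreme
prior corners where the model predicts total substrate depletion and
the likelihood surface degenerates into cliffs.  Inside the
likelihood, hormone predictions are floored at 10⁻³⁰ pmoles so that
those cliffs stay finite and steeply repulsive instead of undefined.

Computationally, the likelihood shares one model evaluation across all
observations of an experimental condition and re-simulates only the
conditions a block can affect.  The model evaluation itself is a
quasi-steady-state reduction (next section); a full calibration of
3×20,000 iterations runs in roughly 10–15 minutes on one core.

## The reduced in vitro model

Hormone exchange between a cell and its medium share relaxes with
time constant `V_GC/K_out ≈ 1.6 s`, while the observed dynamics
(gene expression, medium turnover) evolve over hours.  The
calibration path exploits this: intracellular FSH is held at partition
equilibrium, gene expression is integrated in closed form (a linear
cascade under constant FSH), the four intracellular steroid pools are
slaved to their transport/metabolism balance by a damped Newton
solve, and only the four total steroid pools plus the tritiated-water
integral are advanced numerically with an adaptive Cash–Karp
Runge–Kutta integrator.  Against the full stiff solver (`lsoda`,
rtol 10⁻⁸) the reduction agrees to ~10⁻⁵ relative on all calibration
endpoints across wide random parameter draws (asserted in the test
suite); per evaluation it is roughly twice as fast as the compiled
full solver at matched output and, more importantly, avoids the
general-purpose solver's per-call overhead inside the sampler's inner
loop.

Numerical settings: the full in vitro solver uses rtol 10⁻⁸ and
atol 10⁻¹⁴ pmoles (states span ten orders of magnitude); the reduced
calibration path uses rtol 10⁻⁴ and atol 10⁻¹² — prediction error far
below the ~50% measurement noise — and the generator uses the tighter
10⁻⁶/10⁻¹⁴.  Negative excursions are clipped at zero; the clip is
cosmetic at these tolerances (total-steroid drift < 10⁻⁶ over 48 h).

## Synthetic data

The generator (`generate_collection()`) emulates the *structure* of
the in vitro calibration corpus: per-study lognormal transcription
factors, two lognormal measurement-error classes, and a mix of
endpoint types.  The default collection has ten studies.  Four are
"hormone" studies: 200 nM A, with and without FSH 20 ng/ml, medium
E2/E1/T at 48 h in triplicate, plus duplicate control mRNA levels at
4 h (the source datasets likewise mix expression and hormone
endpoints; without the expression anchor the study factor is
identified only through its product with the Vmax values and the
posterior acquires a needlessly slow ridge).  Six are "expression"
studies: FSH fold-changes of the two inducible mRNAs at 4 h plus
absolute control mRNA levels, in duplicate.  Ground truth defaults to
the shipped posterior-mode vector, including the ten printed σ_L
values, so the collection mirrors the real calibration's structure
(study factors spanning 0.02–2.9).

What the generator does *not* emulate: real inter-laboratory
differences in protocol beyond a single multiplicative transcription
factor, non-lognormal error (detection limits, censoring), serum or
attachment effects, cell death, or any dependence between replicates.
A passing recovery test therefore shows that the inference machinery
is self-consistent at realistic noise levels — not that the model fits
any particular laboratory's data.

Identifiability caveats, visible in the posterior widths: with 200 nM
substrate the aromatase reactions are saturated, so ξ_Cyp19,A and
especially ξ_Cyp19,T are informed mostly by their priors (the latter
has the widest reported posterior); the parameter-recovery criterion
(≥ 9 of 10 kinetic parameters inside their 95% intervals) is
calibrated to that reality rather than to an idealized design.

## Endocrine-disruptor prediction

Exposure scenarios carry measured 4-h fold-changes (mRNA levels of
Cyp19/Hsd17b1, direct aromatase activity).  All measured values are
applied by default — including statistically non-significant ones —
with a `significant_only` switch; letrozole, whose mRNA response was
not measured, applies only its Km fold (1/0.29 ≈ 3.45).  In vivo the
folds switch on 8 h after the start of the second simulated diestrus
and the ovarian E2 concentration is read 6 h later, at the sacrifice
time of the exposure experiments.  Because protein turnover has a
~5.5 h time constant, the 6-h response is attenuated relative to a
sustained exposure — an assertion in the test suite.  Monte-Carlo
prediction couples treated and control simulations draw by draw, so
direction-of-effect statements are free of coupling noise.  The
animal-level measurements behind the published comparisons are not
printed anywhere; the Kolmogorov–Smirnov machinery therefore accepts
any user-supplied sample, and the package's own claims are limited to
directions of effect (atrazine raises ovarian E2 at readout,
letrozole lowers it).

## Known limitations

No hypothalamic–pituitary feedback, no plasma compartment, no thecal
steroidogenesis upstream of androstenedione, no estrogen-receptor
pharmacology, no toxicokinetics (scenarios start from in vitro
fold-changes, not doses), 100% cell viability, and an estrous-cycle
template that is a calibration construct rather than a measurement.
Within those limits the package reproduces the quantitative anchors
it was built around: the steady-state synthesis rates, the in vitro
flux pair and its ~12-fold FSH induction, the template-gated in vivo
stage fluxes, prior recovery, and parameter recovery on synthetic
collections.
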