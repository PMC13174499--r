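---
title: "Carbon routing, tracers and the midflux model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Carbon routing, tracers and the midflux model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(midflux)
```

## The model

`midflux` models steady-state ¹³C labeling in central carbon metabolism
as a *pool-mixing* system. Each metabolite pool (pyruvate, lactate,
alanine, mitochondrial and chromatin acetyl-CoA, citrate, αKG,
glutamate, glutamine, succinate, fumarate, malate, oxaloacetate,
aspartate) is fed by a small set of sources — reactions drawing on
upstream pools, tracer injection points, or unlabeled dilution — with
non-negative mixing weights summing to one. The state of a pool with
$n$ carbons is the probability vector over its $2^n$ positional
labeling patterns, and the steady state is the fixed point of

$$x(\text{pool}) = \sum_{\text{sources}} f_{\text{source}}\,
T_{\text{source}}(x),$$

where $T$ applies the source reaction's carbon atom map. Bimolecular
reactions (citrate synthase, PC with CO₂, reductive IDH1 with CO₂) take
the product distribution of their substrates' isotopomer distributions;
because pools are well mixed, this independence is exact in the model,
not an approximation. Tracer sources inject the tracer's positional
pattern at purity $p$ and the unlabeled pattern at $1-p$.

The mixing weights are *relative activities*, not absolute fluxes: at
isotopic steady state the labeling of a pool depends only on the
normalized composition of its inflows, and tracing experiments of this
design report ratios, never flux values. This is the minimal model
faithful to that observable. Absolute-flux estimation (¹³C-MFA with
confidence intervals) is out of scope.

### Carbon numbering and atom-map conventions

Carbon 1 is the carboxyl drawn first in standard structures (pyruvate
C1 = carboxyl; glutamine, glutamate and αKG C1 = α-carboxyl), which
makes [1-¹³C] tracer definitions unambiguous. The experimental
literature reports MID-level schematics, not positional atom maps, so
the maps follow standard TCA biochemistry and the *binding contract* is
a suite of eight executable carbon-fate constraints
(`validateNetwork`), each pinned to an experimentally reported labeling pattern:

* C1 — [U-¹³C]glucose via PDH: M2 acetyl + M0 OAA → M2 citrate → M2
  αKG → M2 succinate.
* C2 — [U-¹³C]glutamine oxidative: M5 αKG → M4
  succinate/fumarate/malate/OAA → M4 citrate; on the second turn M4
  citrate forms M3 αKG.
* C3 — [1-¹³C]pyruvate: PDH releases the label as CO₂ (M0 acetyl); PC
  retains it (M1 OAA).
* C4 — [1-¹³C]glutamine: αKGDH releases αKG C1, so succinate is M0;
  the reductive route parks the label in the citrate OAA arm, so ACLY
  returns M1 OAA and M0 acetyl.
* C5 — fully reductive [U-¹³C]glutamine: M5 citrate, cleaved to M2
  acetyl-CoA + M3 OAA.
* C6 — malic enzyme: M4 malate → M3 pyruvate + CO₂.
* C7 — PC with unlabeled CO₂: M3 pyruvate → M3 OAA.
* C8 — condensation: M2 acetyl + M4 OAA → M6 citrate.

Ogston stereospecificity is respected: aconitase acts on a prochiral
citrate, so citrate carbons are never scrambled, while succinate and
fumarate carry a two-fold rotation symmetry (their isotopomer vectors
are symmetrized every sweep, and scrambled with probability 1/2 along
Monte-Carlo ancestries).

Two conventions were genuinely open and are fixed as follows:

* **Which OAA-derived carboxyl leaves at which decarboxylation.** At
  MID level both assignments satisfy C1–C8. The default releases the
  citrate carbon derived from the PC-fixed carboxyl (citrate C4) at the
  oxidative IDH step, and the OAA-C1 lineage (αKG C1) at αKGDH.
* **OAA → malate exchange.** Reversibility is represented only through
  explicit exchange sources: glutamate ↔ αKG and aspartate ↔ OAA
  (rapid transamination equilibration), plus malate ← OAA
  (`mdh_from_oaa`, MDH running toward malate). The last one is required
  for [1-¹³C]pyruvate logic: around the full cycle the PC-fixed label
  is always lost as CO₂ before reaching malate, so the observed M1
  malate can only arise from OAA back-exchange. Fumarate ↔ malate
  reversibility is *not* modeled; consequently [1-¹³C] tracers produce
  M1 malate but no M1 fumarate in this model, a known simplification.

CO₂ is an infinite pool with a configurable labeled fraction (default
0): released ¹³CO₂ is not re-fixed.

### Tracers

Five tracers are built in: [U-¹³C]glucose, [U-¹³C]lactate,
[U-¹³C]glutamine, [1-¹³C]pyruvate, [1-¹³C]glutamine. Glucose is
specified at the pyruvate level (three carbons): glycolytic cleavage of
a uniformly labeled hexose yields two uniformly labeled trioses, so the
distinction matters only for non-uniform glucose labels, which are not
part of the design. Tracer purity defaults to 0.99 and acts linearly
(all-or-none per molecule).

## Numerical choices

* Solver: Jacobi fixed-point iteration from the all-unlabeled state;
  default tolerance $10^{-12}$ (max-norm per sweep), `maxIter` 10,000.
  The iteration is a contraction whenever every directed cycle passes
  some dilution or injection; pathological all-recycling configurations
  are reported through `converged = FALSE`, never an exception. The
  fixed point is verified to be independent of initialization
  (all-unlabeled versus all-labeled starts agree to $10\,\mathrm{tol}$).
* State space: full positional isotopomers ($2^n \le 64$ states). An
  EMU-style decomposition would be faster but the network is tiny and
  the positional form is what makes constraint C4 directly testable.
* The Monte-Carlo oracle samples molecule ancestries recursively
  (compiled code), truncating at `maxDepth` 200 by returning unlabeled —
  consistent with iteration from the unlabeled state. A single seeded
  generator drives each call; the caller's RNG state is restored.
* Natural-abundance correction is carbon-only (p13 default 0.0107,
  overridable); the inverse uses non-negative least squares
  (`pracma::lsqnonneg`) and renormalizes, guaranteeing simplex outputs
  on noisy data where plain inversion can go negative. Isotope effects,
  heteroatom corrections and resolution-dependent overlap are out of
  scope.
* `recoverFluxFractions` minimizes the summed squared MID error over the
  free source fractions with L-BFGS-B, multi-started from a fixed grid
  (spacing 0.1 up to two free parameters, 0.25 beyond that, full
  factorial); identifiability is asserted empirically — a flat objective
  across the grid is flagged, not silently resolved.
* Undefined ratios (zero denominators) propagate as `NA` with a logged
  count and are excluded from group tests; silent zeros would bias the
  rank-based statistics.

## Condition presets and their contract

`conditionPreset` ships routings for the pluripotency transition (ESC,
EpiLC day 1–3, EpiSC), embryo lineages (E3.5 ICM/TE, E6.5 EPI/EC) and a
CRISPRi knockdown panel (Neg plus Pcx, Me1, Me2 and triple knockdowns at
efficiency 0.9). The numeric values are calibration choices anchored to
reported fractional labelings (M5 αKG near 46% in ESC and 80% at EpiLC
day 1; M5 citrate reaching ≈30% at the primed end; PC-derived labeling
peaking at EpiLC day 1), but the *binding contract* is the set of
orderings, each verified by noise-free simulation in the test suite:

* αKG glutamine sourcing: EpiLC day 1 above ESC;
* the PC fraction of oxaloacetate peaks at EpiLC day 1;
* reductive carboxylation active (positive) in every preset;
* second-turn ratio lower in the E6.5 EPI than the E3.5 ICM;
* chromatin acetyl-CoA: glutamine-tracer M2 above glucose-tracer M2 in
  every stem-cell preset, with the gap growing monotonically from ESC
  to EpiSC;
* knockdown presets are exactly `applyKnockdown` of Neg.

Only orderings are contractual because the underlying numbers are
measurements on systems whose raw data are external; fitting invented
point values would overstate what the generator knows.

The glutamine-withdrawal scenario (`withdrawGlutamine`) moves the
glutamine-fed fraction of each pool into that pool's *unlabeled* source
rather than renormalizing proportionally: acute deprivation is filled by
unlabeled anaplerosis (other amino acids), not by instantly faster
cycling. This choice is what makes the glucose-tracer chromatin signal
exactly invariant under withdrawal, mirroring the observed lack of
glucose compensation.

## Noise models and what the generators do not emulate

Replicate MIDs are drawn from a Dirichlet with concentration 500 around
the natural-abundance-convolved truth (coefficient of variation ≈4% at
$m = 0.5$) — simplex-respecting noise, chosen over per-isotopologue
Gaussians which can leave the simplex. Raw intensities (pixels, peptide
AUCs) get multiplicative log-normal noise with mean one (default cv
0.1). True replicate and embryo-to-embryo variance components are not
published for this design; these defaults are stated choices, not
inferences.

Embryo layouts are stylized geometric regions (an ICM disk inside a TE
ring; stacked EPI/EC bands), not morphologically realistic sections,
with exact pixel-level annotations. Pixel spectral noise structure,
matrix effects, clustering and lipid annotation are not simulated: the
spatial stage takes cluster labels as given. Histone peptides are
modeled as independently and identically labeled acetyl sites fed by an
M0-or-M2 acetyl-CoA pool (singly labeled acetyl from scrambled sources
is ignored); deacetylation dynamics are collapsed into a single
`turnover` parameter. Passing tests therefore demonstrate internal
consistency of the pipeline under these assumptions — not instrument- or
biology-level realism.

Default problem sizes — $2\times10^5$ molecules for the oracle
cross-check, 200+ pixels per lineage, 100 random MIDs for the correction
round trip, 6 replicates for noisy recovery — were chosen so every
statistic sits well inside its sampling tolerance while the whole suite
stays quick on a laptop.

## Known limitations

* One pyruvate pool: the observed discordance between lactate and
  pyruvate labeling under glucose tracing (lactate above pyruvate)
  cannot be reproduced, since modeled lactate is downstream of the
  single pyruvate pool. Distinct glycolytic and mitochondrial pyruvate
  pools would be required.
* No fumarate ↔ malate exchange (see above): M1 fumarate under
  [1-¹³C] tracers is zero in the model.
* Only acetyl-CoA is compartmentalized (mitochondrial versus
  chromatin); all other pools are whole-cell averages.
* Steady state only: the 5-hour labeling window is taken as converged;
  kinetic (pre-steady-state) labeling curves are out of scope.
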