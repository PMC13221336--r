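---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nitrotox)
```

`nitrotox` implements the computational side of a structure–activity grouping
workflow for β-nitrostyrene derivatives: in silico category characterization
of a nine-compound panel, and the analysis mathematics of four in vitro
(geno)toxicity assays. This vignette documents the models, their assumptions,
the tunable parameters, and the design decisions taken where the methodology
left genuine freedom.

## 1. The chemistry engine

No R cheminformatics toolkit is assumed; the package carries a small engine
of its own, scoped to small organic molecules.

**SMILES and perception.** The parser supports the organic subset, bracket
atoms (isotope, charge, explicit H), branches, ring closures and
disconnected components; stereo markers are accepted and ignored (no 3D or
stereochemical descriptors are computed anywhere in the package).
Aromatic-input SMILES are kekulized by perfect matching on the atoms that
still need a double bond; kekulized input is re-perceived with a single
stated aromaticity model: a ring of the SSSR (or the perimeter of two fused
SSSR rings) is aromatic when every member is sp²-capable and the π count
satisfies Hückel 4n+2, with the usual contributions (1 per in-ring double
bond terminus, 2 for pyrrole/furan-type lone pairs, 0 for exocyclic-double
carbons). One model is applied everywhere, so descriptors and fingerprints
cannot disagree about what is aromatic. Limitation: π systems that are only
aromatic as a whole beyond two fused rings (e.g. some azulene/acenaphthylene
relatives) may be missed; the target chemistry (benzene rings) is unaffected.

**SMARTS.** The matcher implements the subset needed by the shipped pattern
tables: `* A a`, element primitives (aliphatic/aromatic/`#n`), `H X D R r`,
charge, recursive `$(...)`, the `! & , ;` logic at standard precedences, and
bond primitives `- = # : ~ @` (unspecified bond = single-or-aromatic).
Matching is injective backtracking subgraph embedding; counted keys dedupe
embeddings by their atom set.

**Descriptors.**

* Crippen LogP: the published 68-class atom-contribution parameterization,
  shipped as a plain-text table (`inst/extdata/crippen_logp.tsv`). Hydrogens
  are added as explicit graph nodes and every atom takes the first class
  whose pattern matches it in published order. This reproduces the published
  reference values for the panel to 4 decimal places.
* Ertl TPSA: the original N/O fragment scheme, implemented procedurally on
  the perceived graph. The charged nitro group as written in the panel
  SMILES (`[N+](=O)[O-]`) contributes 3.01 + 17.07 + 23.06 = 43.14 Å² —
  this charged-form handling is deliberate: the panel's reported TPSA
  maximum (86.28 Å² for the dinitro compound) is only reproducible with it.
  S/P extensions are not implemented (the panel contains neither); an N/O
  environment outside the published table falls back to the standard linear
  estimate.
* Lipinski counts use the original definitions: donors = number of O–H and
  N–H bonds, acceptors = number of N and O atoms. Rule-of-five violations
  count {MW > 500, LogP > 5, HBD > 5, HBA > 10}; the Ghose screen asks for
  20–70 heavy atoms.

## 2. Fingerprints and similarity

* `pubchem881` follows the public 881-bit substructure-key specification:
  hierarchic element counts, ring-class counts over the ESSSR, and 682
  atom-pair/neighborhood/SMARTS feature bits, all shipped as plain-text
  tables with their bit positions. The ring set is the SSSR plus, for every
  bonded atom triple u–v–w, the shortest cycle through that triple — this
  "triplet" extension is what makes the envelope rings of fused bicyclics
  (the 9-ring of benzodioxole, the 10-ring of naphthalene) count, as the
  specification's reference implementation does. A ring is "saturated or
  aromatic" when all its bonds are single or aromatic; aromatic-ring bits
  count rings whose bonds are all aromatic. The implementation was validated
  bit-for-bit against an independent reference implementation on a
  30-molecule battery; those bit sets are frozen as test fixtures.
* `maccs166` uses the public 166-key SMARTS definitions; keys 125 (≥ 2
  aromatic rings) and 166 (≥ 2 fragments) are procedural, key 1 (isotope)
  is never set.
* `circular_r2_1024` and `path_d7_2048` are hashed fingerprints (ECFP-style
  radius-2 environments; linear paths of 1–7 bonds canonicalized by
  direction). Their hash is a 31-ary polynomial string hash mod 2³¹−1,
  fixed inside the package, so on-bits are stable across platforms and
  sessions; both kinds are invariant to atom input order by construction
  (sorted neighbor lists, direction-canonical paths).
* Tanimoto similarity is |A∩B|/|A∪B| with a documented total convention:
  two empty fingerprints → 1.0, one empty → 0.0. Ranking against a lead
  compound sorts by descending Tc with ties broken by ascending compound id.

Only these four kinds are implemented. Library-specific dialects (Avalon,
Pattern, Layered, EState, AtomPair, Torsion, …) are defined by library
internals rather than public specifications, so panel means over a wider
fingerprint set are reported by the package only over its own four kinds.

## 3. Assay mathematics

**Plate cytotoxicity.** Signals are background-corrected absorbances
(A_meas − A_ref). Technical (in-plate) replicate reads are averaged first;
normalization then uses the biological replicate's *own* vehicle and
positive controls (replicate-matched pairing is assumed since the batch
structure is not otherwise identifiable); means ± SD are taken over
biological replicates. Percentages are never clamped: viability above 100%
for vehicle-like treatments is real data behaviour, not an error. A single
biological replicate yields SD 0 plus a flag and warning.

**Comet assay.** The per-slide location measure defaults to the arithmetic
mean rather than the guideline median: genotoxicants acting preferentially
on cycling cells produce a bimodal tail-intensity distribution in which the
damaged subpopulation stays below 50% of nuclei, and the median then sits on
the background mode and underestimates the effect (the suite asserts this
exactly on constructed slides). The median remains available
(`mode = "median"`). A responder-fraction diagnostic (share of nuclei with
TI above a threshold) is reported alongside; the threshold default of 10% TI
is a package choice — the bimodality argument is qualitative and names no
cutoff — and is config-exposed. Slides under the nominal 100 nuclei warn
but are accepted; one slide per culture is assumed for aggregation (the
slides-per-culture layout is unstated; extra slides of a culture are
averaged within the culture first).

**Mouse lymphoma assay.** The chain SG → RSG, CE → RCE, RTG = RSG·RCE·100,
MF = CE_TFT/CE_S2 follows the microwell method. Two decisions matter:

* *CE divisor.* CE = −ln(empty/total)/c where c is the expected cells per
  well: 1.6 on survivor plates, 2000 on TFT selection plates (10⁴ cells/mL ×
  200 µL). The protocol text prints a single "/2000" formula and elsewhere
  "200 µL (1 × 10³ cells)", which is internally inconsistent; a universal
  /2000 would make survivor CE (reported in percent, acceptance range
  65–120%) dimensionally impossible, so the divisor is per-role with the TFT
  density config-exposed (default 2000).
* *Degenerate plates.* All wells empty gives CE = 0 exactly; *no* empty well
  makes CE unestimable and returns a flagged lower bound −ln(0.5/total)/c
  rather than infinity.

Plates of a role are pooled into one empty/total pair before CE. Small- and
large-colony MFs treat wells lacking that colony class as empty; a well may
carry both classes (they are independent well classes, since the counting
convention is unstated). The Global Evaluation Factor call is strict:
relevant iff MF > MF_vehicle + 126×10⁻⁶, boundary equality negative. The
validity report implements the guideline checks (vehicle MF 50–170×10⁻⁶,
vehicle CE 65–120%, vehicle SG 8–32, positive-control induced MF ≥ 300×10⁻⁶
with the small-colony condition, positive RTG > 10%, top-dose RTG 10–30%)
and supports an explicit free-text override note, mirroring how a slightly
out-of-range vehicle MF can be judged negligible next to a 6-fold induced
response.

**Nucleus classification.** γH2A.X positivity is a pure intensity threshold;
pH3(S10) additionally requires the nucleus area inside a window (mitotic
nuclei are small and condensed; intensity alone also picks up debris).
The instrument classifier's real parameters live in unavailable instrument
configuration, so packaged defaults are calibrated on the synthetic
generator — threshold at the 99th percentile of the background intensity
population (`calibrate_intensity_threshold()`) — and are honest stand-ins,
not reconstructions. Minimum counts (2000 γH2A.X, 5000 pH3) set a low-count
flag without suppressing output. The generator can add a pan-stained
saturating subpopulation to demonstrate *why* intensity-only classification
fails for such phenotypes; no attempt is made to model it away.

**Statistics.** One-way ANOVA with two-sided Dunnett many-to-one comparisons
against the vehicle: pooled-variance t statistics; the family-wise adjusted
p-value of comparison i is P(max_j |T_j| ≥ |t_i|) under the joint null. That
tail is evaluated by Monte-Carlo simulation of the exact finite-sample null
(independent group means + shared pooled chi-square variance), which
reproduces the multivariate-t dependence (correlation ½ in balanced designs)
without quadrature; the default 2×10⁵ draws under a fixed, logged seed give
an MC standard error ≈ 5×10⁻⁴ near p = 0.05 (documented tolerance 10⁻³).
Comparisons are reported unconditionally with the omnibus F alongside — an
omnibus gate is a known power leak for many-to-one designs and the
methodology does not state one. No normality pre-tests (robustness is the
working argument at n = 3).

## 4. The synthetic world

The generators state one fixed world per assay; their defaults are the
conditions the protocol states where it states them (3 biological × 3
technical plate replicates; 100 nuclei/slide; 2×96 survivor and 4×96 TFT
wells at 1.6 and 2000 cells/well; ≥ 2000/5000 nuclei), and a realistic
choice where it does not, made once:

* plate noise is additive Gaussian on the corrected signal, SD 0.05 on a
  0.2–0.9 control span — reproducing the ~3–7 percentage-point SDs of the
  published bar charts;
* comet background TI ≈ 1% (SD 0.8) so vehicle slides summarize near 1.0,
  damaged nuclei TI ≈ 60% (SD 12), truncated to [0, 100];
* MLA cell counts are lognormal with CV 5% around the target growth;
  well outcomes are exact Poisson plating law
  (P(empty) = exp(−c·CE), exp(−c·MF·CE));
* nucleus intensities are two normal populations (background 100 ± 25,
  positive 400 ± 60 a.u.) with areas 60 ± 10 vs 30 ± 6.

What a green recovery test establishes: the analysis modules invert their
own generative assumptions without bias at realistic sample sizes — plate
truth within 3 SD, comet mixture mean within sampling error, MLA MF with
|bias| < 10% over 200 seeded experiments, positive fractions within binomial
error. What it does not establish: correctness under real-data features the
world omits — plate edge effects and drift, comet TI autocorrelation within
slides, mutant-colony growth interference, instrument-specific intensity
distributions. Published per-assay effect values (e.g. a 47.2% cytotoxicity
or a 40.1% positive fraction) depend on the undeposited raw data and are
used only as realistic generator settings, never as assertions.

All generator randomness flows through a local seeded RNG scope that
restores the caller's `.Random.seed`; identical scenario + seed gives
byte-identical tables.

## 5. Known limitations

* The aromaticity model covers single rings and fused-pair perimeters; it is
  not a full SSSR-combination Hückel search.
* The 881-bit implementation is validated bit-for-bit on C/H/N/O/S/halogen
  organics of the tested battery; exotic inorganic chemistry exercises
  element-count bits that have no test coverage here.
* One published similarity value (0.59 for the benzodioxole derivative vs
  the lead) is not reproduced at 2 d.p. by recomputation from the printed
  SMILES under the public 881-bit specification (which yields 0.5776 for
  both that compound and the phenol derivative — consistent with the
  published 3-d.p. range 0.578–0.877). The corresponding acceptance test is
  left red deliberately rather than widened; the likely cause is a historic
  toolkit version difference.
* Dose–response fitting (IC50), trend tests, mixed models and the agar MLA
  variant are out of scope.
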