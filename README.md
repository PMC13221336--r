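# nitrotox

Structure–activity grouping and in vitro (geno)toxicity analytics for
β-nitrostyrene derivatives.

## The problem

β-Nitrostyrene (trans-β-nitrostyrene, `C1=CC=C(C=C1)C=C[N+](=O)[O-]`) is an
industrial chemical and anti-neoplastic drug candidate whose cyto- and
genotoxicity are attributed to its nitrovinyl moiety (the conjugated
–CH=CH–NO₂ group). Resolving which structural element drives which effect is
done with a grouping (read-across) approach: assemble a panel of structural
derivatives that each remove or modify one feature, establish the panel's
category homogeneity in silico (fingerprint similarity, rule-of-five
descriptors), then test the panel in a battery of in vitro assays —
LDH/WST-1 cytotoxicity, the alkaline comet assay, γH2A.X / pH3(S10)
immunofluorescence, and the OECD TG 490 mouse lymphoma assay (MLA).

`nitrotox` is a tested, reusable R implementation of the computational core
of that workflow, for toxicologists and cheminformaticians who want to rerun,
audit, or extend the analysis. Because the wet-lab raw data are not publicly
deposited, every assay module is paired with a seeded synthetic-data
generator with known ground truth, so the full pipeline is exercisable and
testable offline.

## What it computes

**Chemistry (from SMILES, no external toolkit).** The package contains its
own small cheminformatics engine: SMILES parser, kekulization, Hückel
aromaticity perception, SSSR/ESSSR ring perception, and a SMARTS subset
matcher. On top of it:

- PubChem/CACTVS 881-bit substructure keys (bit-compatible with the public
  specification's reference implementation), MACCS 166 keys (public
  definitions), hashed circular (radius 2, 1024 bits) and linear-path
  (≤ 7 bonds, 2048 bits) fingerprints;
- Tanimoto similarity Tc(A,B) = |A∩B| / |A∪B|, panel similarity matrices,
  ranking against a lead structure, SMARTS-rule selection reports;
- Crippen atom-contribution LogP (published 68-class parameterization), Ertl
  fragment TPSA (N/O scheme), Lipinski H-bond donor/acceptor counts,
  rule-of-five violation counts, Ghose heavy-atom screen.

**Assay mathematics.**

- LDH: % cytotoxicity = (T − V)/(P − V) × 100; WST-1: % viability =
  100 − (V − T)/(V − P) × 100, on background-corrected absorbances with
  replicate-matched controls (never clamped to [0, 100]).
- Comet: per-slide tail-intensity summaries — arithmetic mean (default;
  robust to the bimodal TI distributions produced by agents that damage only
  cycling cells), guideline median, and a responder-fraction diagnostic.
- MLA (OECD TG 490, microwell): SG = (N₁/N₀)·(N₂/N₁′); CE = −ln(EW/TW)/c
  with c = 1.6 (survivor) or 2000 (TFT selection) cells/well; RTG = RSG ×
  RCE × 100; MF = CE_TFT/CE_S2 (×10⁻⁶), small/large colony split; the Global
  Evaluation Factor call (relevant iff MF > MF_vehicle + 126×10⁻⁶); the full
  guideline validity-criteria report.
- γH2A.X / pH3(S10): threshold (and area-window) nucleus classification with
  minimum-count enforcement (2000 / 5000 nuclei).
- Statistics: one-way ANOVA with Dunnett many-to-one comparisons against the
  vehicle control; adjusted p-values from the joint null of the k contrasts,
  evaluated by seeded Monte-Carlo simulation (≥ 10⁵ draws).

## Worked example

```r
library(nitrotox)
panel <- nitrostyrene_panel()          # the nine-compound panel (packaged CSV)
descriptor_report(panel)
```

```
 id     mw heavy_atoms hbd hba   logp  tpsa ro5_violations ghose_atoms_ok
  1 149.15          11   0   3 1.9340 43.14              0          FALSE
  ...
  4 104.15           8   0   0 2.3296  0.00              0          FALSE
  5 121.18           9   2   1 1.1878 26.02              0          FALSE
  ...
  9 195.17          14   1   5 1.6482 72.60              0          FALSE
```

Every panel member satisfies the Lipinski rule of five (`ro5_violations`
= 0) but sits below the Ghose 20-heavy-atom drug-likeness minimum; LogP
spans 1.1878 (no. 5) to 2.3296 (no. 4); TPSA peaks at 86.28 Å² for the
dinitro compound no. 3.

```r
selection_report(panel, ref_id = 1)[, c("id", "tc", "nitrovinyl")]
```

```
 id    tc nitrovinyl      # PubChem-881 Tanimoto vs the lead compound
  1 1.000       TRUE
  2 0.877      FALSE      # saturated linker: nitro without the vinyl
  3 0.770       TRUE
  4 0.750      FALSE      # styrene: no nitro group
  ...
  8 0.578       TRUE
  9 0.578       TRUE
```

The Tc column spans 0.877–0.578, and the `nitrovinyl` SMARTS flag splits the
panel into {1, 3, 8, 9} vs {2, 4, 5, 6, 7} — exactly the toxicity dichotomy
the assays resolve.

```r
tab <- gen_mla(seed = 7)               # synthetic MLA experiment
res <- mla_run(tab)
res[, c("condition", "sg", "rtg", "mf", "relevant")]
```

```
       condition    sg   rtg    mf relevant
         vehicle 13.73 100.0 149.6    FALSE
        positive  7.50  36.1 699.2     TRUE
 treatment:1@5uM  2.92  12.2 858.8     TRUE
```

`mf` is the mutation frequency ×10⁻⁶ recomputed from the simulated 96-well
empty/positive counts; `relevant` is the GEF call (MF exceeds vehicle by
more than 126×10⁻⁶). `mla_validity_report(res)` prints the OECD TG 490
acceptance checks.

Command line (same pipeline, CSV in / CSV + manifest out):

```sh
inst/cli/nitrotox descriptors --out-dir out/
inst/cli/nitrotox simulate --assay mla --seed 7 --out-dir out/
inst/cli/nitrotox mla --in out/synthetic_mla.csv --out-dir out/
```

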