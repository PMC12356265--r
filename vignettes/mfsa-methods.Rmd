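---
title: "Methods: modular fragmentation-based annotation of complex natural products"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modular fragmentation-based annotation of complex natural products}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mfsa)
```

# The problem and the model

Complex natural products (CNPs) such as daphnane-type diterpenoids — a
5/7/6 tricyclic skeleton with seven or more contiguous stereocenters,
heavy oxidation and optional macrocyclic bridges — are poorly covered by
public MS/MS libraries, and cosine-similarity networking clusters them
unreliably because small structural changes reshape whole spectra. What
such a class *does* conserve is its fragmentation logic: the same skeleton
produces the same families of product ions and neutral losses, with
element compositions that shift predictably as substructures vary.

`mfsa` formalizes this. The class skeleton is divided into ordered module
slots; each slot offers submodule variants. A submodule is (a) a SMILES
fragment whose atoms shared with adjacent modules carry atom-map labels,
and (b) one row of a mass-shift matrix per diagnostic ion family: integer
shifts `(ΔC, ΔH, ΔO, ΔN)`. Each ion family has a template — its kind
(product ion or neutral loss), an initial composition `m0` taken from the
class reference compound, and the slots whose shifts apply. The predicted
composition for any combination of submodules is the element-wise sum

$$ m_{\text{predict}} = m_0 + \sum_k \Delta m(M^k_{j}) $$

Key assumptions:

* **Compositional additivity.** Structural variation in one module shifts
  a family's composition independently of the other modules. This is the
  core empirical claim behind modular fragmentation; it holds for
  skeleton-derived ions whose bond cleavages do not involve the varying
  module.
* **Initial-formula anchoring.** For skeleton-fragmenting classes
  (terpenoids), `m0` is a high-frequency, high-intensity carbon-skeleton
  product ion; for classes fragmenting mainly by substituent losses
  (alkaloids), the precursor-ion formula serves as `m0`. Both are
  expressible as templates.
* **Formula-level matching beats m/z-level matching.** Recognition and
  labeling operate on element compositions at ppm tolerance, not on raw
  m/z or intensity patterns, which makes them robust to instrument- and
  concentration-dependent intensity variation.

# Workflow stages and their parameters

## Structure assembly

Fragments merge on shared atom-map labels: atoms with equal labels across
fragments are unified into one atom inheriting the union of bonds, with
hydrogens re-derived from standard valence and the merged molecule
sanitized and canonicalized. SMILES parsing, valence checking and
canonicalization are delegated to RDKit through a bundled Python helper
(`inst/python/assemble.py`) invoked in batch over a JSON pipe; R has no
cheminformatics toolkit and reimplementing a SMILES parser would be both
error-prone and pointless. The merge algorithm itself — label grouping,
bond transfer, duplicate-bond suppression for fused-ring sharing, hydrogen
re-derivation — is this package's own code inside the helper.

Labels seen only once are an error unless declared in the module set's
`optional_labels`: those are hydrogen-capped, which is how an *absent*
module (e.g. "no macrocycle") leaves its attachment points.

## Target recognition

| parameter | default | meaning |
|---|---|---|
| `tol_ppm` | 5 ppm | closed ppm window per diagnostic formula |
| `mz_range` | 200–400 | max-min normalization window (positive mode) |
| `noise_threshold` | 0.1 | minimum normalized intensity considered signal |
| `min_matching_ions` | 2 | matched formulas required for a hit |

Windows are closed: a value exactly at ±5 ppm matches. Peak-to-formula
assignment is one-to-one, greedy by smallest |ppm|, ties to the more
intense peak.

Two points required interpretation:

* **The noise rule.** The source description of noise exclusion is
  grammatically ambiguous ("noise having a minimum relative intensity
  greater than 0.1 were excluded"). Read literally it would discard strong
  peaks and keep weak ones, defeating its purpose. We exclude peaks with
  normalized intensity *below* the threshold, which matches the stated
  intent of removing noise; the threshold is configurable, including 0.
* **`min_matching_ions`** has no published default; we ship 2 (one match
  can be coincidental at 5 ppm inside a 200 Th window; two independent
  diagnostic formulas rarely are), exposed in the settings.

Degenerate normalization (all in-range intensities equal, including a
single peak) maps everything to 1 rather than 0/NaN, keeping a lone
diagnostic peak visible.

## Formula and adduct assignment

The formula database enumerates every `C_a H_b O_c N_d` inside per-element
bounds (guarded by a combination cap), sorted by mass for binary search.
Seven electrospray adducts are pre-configured: `[M+H]+`, `[M+NH4]+`,
`[M+H−H2O]+`, `[M+CH3CN+H]+`, `[M+CH3NH2+H]+`, `[M−H]−`, `[M+HCOO]−`.
Candidates within the ppm window whose neutral RDBE lies in a plausibility
range (default 0–40, configurable per class; no published bounds exist)
are ranked by |ppm|.

Numerical choices:

* **Electron mass.** Ion m/z subtracts `charge × 0.0005486` Da. The
  source is silent on this; ignoring it would bias every theoretical m/z
  by ≈ 2 ppm at m/z 253, a large fraction of a 5 ppm budget, so we state
  and test the correction rather than leave it implementation-defined.
* **Tie-breaking.** `[M+H]+` of M and `[M+H−H2O]+` of M·H2O predict
  *identical* theoretical m/z, so |ppm| comparisons are rounded to 0.001
  ppm before tie-breaking; ties then prefer RDBE closest to the midpoint
  of the plausibility range, then fewer nitrogens, then lexicographic
  formula — fully deterministic.
* **Class-specific element bounds.** The shipped daphnane settings use
  `N ∈ [0, 0]`: daphnanes are CHO compounds, and restricting the element
  ranges to the class is exactly what the per-class range configuration is
  for. With nitrogen admitted, amine/nitrile adduct combinations create
  near-degenerate assignments that no mass accuracy can separate.

## Evidence labeling

Neutral losses are computed only between ion pairs whose compositions
carry specified carbon counts, which suppresses the combinatorial noise of
all-pairs neutral-loss analysis. The published formulation filters both
pair members to a single `C_target`; the worked daphnane case, however,
pairs a C20 ion with the C17 core ion (Δ = C3H4O2). We therefore
generalize `C_target` to an ordered pair `(C_heavier, C_lighter)`; the
same-count case is `(c, c)`. The shipped daphnane rules use `(20, 17)` for
the B-ring loss and `(30, 20)` for the macrocycle losses
C10H16O2/C10H14O2/C10H12O2.

Scores, on normalized intensities: `IA = (I1+I2)/2`,
`IDF = 1/(1+|I1−I2|/IA)` (guarded to 0 when `IA = 0`), loss score
`IA × IDF`; feature-ion score `I_i / I_max`. All lie in [0, 1].

The range-limited cosine uses in-range peak intensities *as given*,
pairing peaks greedily by nearest m/z within 10 ppm (no published value;
configurable), each peak used once. Max-min scaling is deliberately not
re-applied inside the cosine: it is an affine (not linear) map that would
send the weakest in-range peak to zero and distort the similarity; the
cosine is already invariant to uniform intensity scaling.

## Assembly and ranking

Rules assert "evidence ⇒ slot gets submodule". A rule is satisfied when
all its evidence items are observed; contradictory assignments to one slot
produce multiple candidates, all kept and ranked — never silently dropped.
The priority score of a candidate sums `w·s` over the *distinct* evidence
items of its supporting rules (an item required by two rules counts once);
weights are binary by contract and the validator rejects fractional
weights. Ties break by more evidence, then smaller mean |ppm|, then a
lexicographic key.

Per-submodule rules can be derived automatically from the library
(`derive_rules()`): every single-slot ion family contributes one rule per
submodule, asserting that observing that submodule's predicted formula
assigns the submodule. Multi-slot families cannot be attributed to one
slot and are skipped. MS1-pattern rules (below) are supplied explicitly.

The library lookup applies the assigned precursor formula as a constraint
only when that formula occurs in the library at all; otherwise (or when
the constraint empties the result) the lookup relaxes, so a borderline
formula assignment degrades confidence rather than destroying the
annotation. Confidence tiers: **A** — single structure consistent with
the formula constraint; **B** — several structures or partial module
vector; **C** — recognized, no rule satisfied. No numeric definition of
"high confidence" is published; the tiers are this package's
operationalization.

**MS1 adduct pattern.** C-ring 9,13,14-triol compounds show
`[M+H−H2O]+` more intense than `[M+H]+` in MS1, while orthoesters show
the opposite. This is supported as an optional evidence predicate over
the feature table: a companion feature at `mz − 18.0106` co-eluting
within `rt_tol` (default 0.1 min) with larger total area ⇒
"dehydration_dominant". Pattern evidence ships with weight 0: it assigns
a module but does not enter the priority score, which the published score
defines over ions and losses only.

# The shipped example module system

`inst/extdata/daphnane_modules.json` is a ~15-submodule desk-scale system
(3 core × 2 B-ring × 4 acyl × 2 C-ring × 4 macrocycle = 192 combinations):
C17 core-ion variants (C17H17O2 at m/z 253, C17H17O3 at 269, C17H19O2),
C20 initial ions (C20H25O6 at m/z 361, …), acylium ions for the acyl
module, the B-ring C3H4O2-class loss and the macrocycle C10-class losses.
Its structures are simplified two-dimensional sketches that evoke the
5/7/6 ring system — chemically valid and pairwise distinct, but not
literature daphnane structures, and deliberately far smaller than a
production library (the full published system spans ~1420 aglycones × 96
substituents, defined in sources that are not machine-readable). Slot
multiplicity is fully configurable, so any convention for substitution
positions can be expressed in a user module set.

# The synthetic-data generator

`simulate_dataset()` emulates an MZmine export: a quant CSV (feature id,
m/z, RT, per-sample area), an MGF keyed by feature id, and a truth table.
Member spectra realize every predicted family of a library compound:
product-ion families as peaks, loss families as the implied ion pair
(the family's `pair_base` ion plus the heavy partner), and the `[M+H]+`
precursor. Decoy spectra draw peaks rejected from within 50 ppm of *any*
diagnostic window, so zero decoy recognition at 5 ppm holds by
construction.

Stated world (defaults): 50 members + 50 decoys; diagnostic intensities
uniform in [0.5, 1] of the range maximum; noise uniform in [0, 0.08] —
below the 0.1 noise floor — with 8 in-window and 4 out-of-window noise
peaks per spectrum; m/z jitter multiplicative, `mz·(1 + ε/10⁶)`,
`ε ~ N(0, 1 ppm)`; dropout 0. Noise peaks anchor the normalization
minimum, mirroring real spectra where the weakest in-window signal is
never a diagnostic ion. Everything is deterministic given the seed;
changing the seed changes noise, never the truth-table structure.

What the generator does **not** emulate — and therefore what a green
end-to-end test does *not* establish: chromatographic peak shape, isotope
envelopes, co-isolation chimeras, intensity-dependent mass error,
fragmentation competition between modules, or real instrument noise
statistics above the noise floor. A perfect recovery on fixtures verifies
the *pipeline logic* (prediction → recognition → labeling → ranking is
mutually consistent and invertible in the noiseless limit), not field
performance on biological extracts.

The sensitivity harness simulates one dataset from the full library, then
annotates it against libraries degraded to 50 %, 33 % and 10 % submodule
retention (uniform random, at least one submodule per slot, rounding half
up; 10 replicates each). Because a dropped submodule removes every
compound using it, recovery falls steeply and monotonically — the
qualitative behavior expected of incomplete module design. The toy
system's five small slots make the drop sharper than in a large library,
where each slot retains more alternatives.

# Serialization choices

The module set, rule set, adduct table and the persisted library are JSON
(the library store is a schema-versioned single-file relational layout
with compound and ion tables; loading refuses other schema versions and
corrupted files without returning partial data). The environment provides
no R bindings for SQLite or YAML; JSON through `jsonlite` preserves the
contracts — single file, round-trip equality, indexed lookup by ion
formula and by module choice — without adding dependencies.

# Known limitations

* Elements beyond the configurable CHON(S, P, Cl) table, charge states
  |z| ≥ 2, and isotope-pattern verification are out of scope.
* Retention-time-based discrimination of positional isomers is not
  automated (it requires empirical standards), and geometric (E/Z)
  isomers are indistinguishable at the formula level by construction.
* The assembled structures are two-dimensional; stereochemistry is
  neither generated nor checked.
* Rule evidence is presence-based; partially co-eluting chimeric spectra
  can in principle satisfy rules from two compounds and produce merged
  candidates (they are then ranked, not suppressed).
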