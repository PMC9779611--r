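---
title: "Methods: structure-aware annotation of tick salivary proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structure-aware annotation of tick salivary proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tickfold)
```

## The problem

Tick salivary transcriptomes encode thousands of putative secreted
proteins, grouped into families by sequence clustering and PSSM searches.
Many families have no detectable sequence similarity to characterized
proteins, yet predicted 3D models place them firmly into known folds.
`tickfold` implements the analysis layer of that structure-aware
annotation: disulfide topology from model coordinates, motif scanning,
Z-score-driven reclassification, disintegrin hairpin detection and family
fingerprinting. It does **not** run structure prediction or structural
database searches — it consumes their outputs (PDB models, hit tables).

## Disulfide topology

A disulfide bond is called when two cysteine Sγ atoms lie at a distance
below `cutoff` (default **3.0 Å**, the convention used when deriving
connectivity from predicted models; true disulfides sit near 2.05 Å, so
the cutoff is deliberately generous to tolerate model error).
Methionine Sδ atoms are excluded: only cysteine Sγ pairs are candidates.
We restrict to cysteines because the analysis concerns cystine
frameworks, and document this since "all sulfur atoms" is ambiguous.

Geometry from predicted models can put one Sγ within the cutoff of two
partners. Conflicts are resolved by **greedy ascending-distance
matching** — shortest candidate pair first, each Sγ used at most once.
Greedy is deterministic and, at 3 Å geometry, almost always optimal; an
exhaustive maximum-matching mode (`method = "maxweight"`, maximising
bond count then minimising total distance) is available for the rare
chain-of-near-contacts case, and is exact because salivary proteins
carry at most ~21 cysteines.

Cysteine ordinals are per chain in sequence order. Connectivity is
rendered in three interconvertible notations used in the literature —
dash (`C1-C6, C2-C4, C3-C5`), pipe (`|C:1 C:6 |C:2 C:4`) and
chain-qualified for inter-chain bridges (`A:7|B:7`). The parser accepts
both hyphen and en-dash (printed patterns mix them); output always uses
the ASCII hyphen. Conservation holds by construction: twice the bond
count plus the free count equals the number of Sγ-bearing cysteines.
Cysteines lacking an Sγ atom in the model are reported free with a
warning rather than silently dropped.

No pLDDT filtering is applied by default (the upstream annotation
applied none); `plddt_min` lets a user exclude low-confidence residues.

`consensus_topology()` calls a bond conserved when it appears in at
least a fraction `threshold` (default **0.8**) of a family's models — a
simple vote that tolerates an occasional broken bond in one model
without inventing bonds seen only sporadically.

## Motif scanning

Patterns use PROSITE syntax (`-`-separated elements, `x` wildcard,
`[..]` allowed sets, `{..}` excluded sets, `(n)`/`(n,m)` repeats,
`<`/`>` anchors). Semantics follow ps_scan: every start position is
reported (overlaps allowed); within a start, variable repeats resolve
greedily so the longest match at that start is the hit. Coordinates are
1-based inclusive throughout.

Masked residues get a conservative rule: the wildcard matches `X`, but a
specific letter or allowed set never does (an exclusion set matches `X`
unless `X` is excluded). This prevents spurious motif calls on masked
positions while keeping wildcards permissive. The scanner is validated
against a brute-force oracle that expands every repeat assignment into a
concrete regular expression — a deliberately different computational
route.

Built-ins: the metalloprotease zinc-binding motif
`H-E-x(2)-H-x(2)-G-x(2)-H`, the P450 heme-pocket motif
`F-x-x-G-x-[HR]-x-C-x-G` (its invariant cysteine ligates the heme iron)
and the P450 catalytic motif `[AG]-G-x-[ED]-T`. The disintegrin block
set ships as a PROSITE-format file
(`inst/extdata/disintegrin_blocks.prosite`) encoding the five triads
RGD, KGD, KTS, RTS, RED, plus variants requiring a cysteine within 10
residues on each side. The *bare* triads are the default because the
exact composition of the original block database is not public; the
flanked variants and a loader for a user-supplied file make the scan
reproducible against the real blocks when available.

## Z-score bands and reclassification rules

Dali-manual interpretation: Z ≥ 20 homologous, 8–20 probably homologous,
2–8 gray area, < 2 not significant. The prose intervals share endpoints,
so bands are **half-open**: `[20, ∞)`, `[8, 20)`, `[2, 8)`, `(−∞, 2)` —
a boundary value belongs to the stronger band. `zband()` is total and
monotone over finite Z.

`classify()` applies rules in a fixed priority order; the first match
fires and the stored evidence (best target, Z, band, motif flags) makes
every decision replayable:

| rule | condition | new group |
|------|-----------|-----------|
| R1 | metalloprotease-fold best hit, band ≥ probably homologous, zinc motif **absent** | Metalloproteoid |
| R2 | as R1, zinc motif **present** | Metalloprotease |
| R3 | bacterial pore-forming toxin target, Z ≥ 10 | Cytotoxin |
| R4 | mite-allergen/JHBP target, Z > 10 | Der f 7 allergen/JHBP |
| R5 | ML-domain target, Z > 12 | Niemann-Pick |
| R6 | lipocalin target, band ≥ probably homologous | Lipocalin |
| R6s | sulfotransferase target, Z ≥ 2 | Sulfotransferase |
| R7 | fall-through | no significant structural match |

R1/R2 outrank the category rules because motif evidence overrides prior
labels: a protein whose fold matches metalloproteases but which lacks
`HExxHxxGxxH` cannot be catalytic — the defining property of the
metalloproteoid group. The per-rule Z floors mirror the ranges reported
per family (10–16 for the toxin matches, > 10 for the allergen group,
> 12 for ML domains); they are config values (`rule_z_floors()`), not
constants, because the source material applies them per family rather
than uniformly. **R6s is this package's addition**: the documented
137-sequence reclassification scenario includes two sulfotransferase
matches that no other rule covers; without R6s the partition property
(counts per group sum to batch size, here 94 + 32 + 2 + 9 = 137) could
not reproduce the published split. R7 also catches queries whose
significant best hit matches no rule — classification is total either
way.

Target categorisation is data, not code: a config map of PDB id sets
(e.g. the seven pore-forming toxin structures 2d42-A, 4rhz-A, 3zjx-A,
2ztb-B, 7ml9-A, 6lh8-A, 1w3a-A) and lowercase description keywords, with
id matches taking precedence. The subgroup of an assignment is the old
family label when present, else `"unspecified"`.

## Disintegrin hairpin criterion

A triad alone is weak evidence — roughly 5% of a salivary database
matches some triad by chance. The structural criterion requires (a) a
cysteine at most `window` residues before the triad and one at most
`window` after, disulfide-bonded to each other (the staple), and (b)
protrusion. "A few amino acids up or down" is operationalised as
**window = 10** residues (snake-venom disintegrin loops put the flanking
cystine 4–6 residues out; 10 is a permissive ceiling), configurable.
When several cysteines qualify, the nearest on each side is used —
deterministic and equal to the minimal combined distance.

Protrusion is a centroid-distance z-score: with $d_i$ the distance of
residue $i$'s Cα from the whole-chain Cα centroid, and $D$ the distance
of the triad's Cα centroid from it,

$$ z = \frac{D - \bar d}{\mathrm{sd}(d)} . $$

A hairpin requires $z \ge$ **1.5** (the triad sits further out than ~93%
of a Gaussian residue-distance distribution). This was chosen over
solvent accessibility because it needs no probe machinery, is exactly
invariant under rigid motion, and separates the constructed positives
(z ≈ 2.9) from helix-embedded and buried decoys (z ≤ 0) by a wide
margin. Both threshold and window are explicit stand-ins for a published
visual-inspection step and are exposed in the config; the tool
reproduces the screen, not any manual curation applied after it.

## Superposition, secondary structure, fingerprints

Kabsch superposition uses the SVD of the cross-covariance matrix with
the reflection corrected (det = +1 always). Inputs with fewer than three
points or collinear geometry are rejected. The returned transform
satisfies `mobile %*% rotation + translation ≈ ref` and the reported
RMSD is minimal over rigid motions (checked against a singular-value
identity oracle to 1e-9).

Secondary structure is assigned from Cα geometry alone (models may lack
full backbones): a residue window is helix-like when d(i,i+3) ∈
[5.0, 6.2] Å **and** d(i,i+4) ∈ [5.9, 7.2] Å, strand-like when
d(i,i+2) ∈ [6.2, 7.2] Å; the condition must hold at ≥ 4 (helix) or ≥ 3
(strand) consecutive window starts, P-SEA style. The consecutive-run
requirement matters: single accidental windows are common in random
coils (a ~3.8 Å random walk lands in the strand window ~20% of the
time), and requiring runs keeps self-avoiding random walks below 20%
H+E on average while ideal helices/strands label fully. All thresholds
live in `sse_defaults()` because no canonical Cα-only definition exists.

Family fingerprints are all-pairs Kabsch RMSDs with **pairing by residue
index** — family models are assumed alignable with equal residue counts
(alignment construction is out of scope) — restricted to residues
assigned H or E in *every* model, summarised as min–max ± sd (the
convention for reported per-family ranges). The SSE restriction is
brittle under large synthetic coordinate noise (jitter near a window
edge removes residues non-linearly), so the statistical tests of the
jitter model use `sse_only = FALSE`; for paired i.i.d. Gaussian noise of
sd σ per coordinate the expected RMSD is ≈ σ√6, which the generator
reproduces within a few percent and scales linearly in σ.

## Synthetic data: what it does and does not emulate

The fixture generators state a world rather than tune one:

* `make_cys_structure()` realises exact Sγ–Sγ distances (bonded pairs at
  2.05 Å unless specified; non-paired Sγ ≥ 8 Å apart) on a chain with
  ~3.8 Å consecutive Cα spacing. Pair axes are drawn from the signed
  coordinate axes so the 3-decimal PDB columns reproduce requested
  distances exactly; distances with more than three decimals quantize to
  format precision.
* `make_hairpin()` builds a compact body plus a protruding stapled
  two-arm hairpin with the triad at the apex; `bury = TRUE` parks the
  same sequence inside the body as a negative control, and
  `make_helix_decoy()` embeds the triad mid-helix with unbonded
  cysteines.
* `make_family()` adds i.i.d. Gaussian coordinate noise; at σ ≤ 0.3 Å
  topology is preserved by construction margin (2.05 Å bonds vs a 3 Å
  cutoff and ≥ 8 Å separations).
* `make_partition_scenario()` emits the 137-row hit table splitting
  94/32/2/9 across allergen, toxin, sulfotransferase and no-match
  outcomes, with Z scores drawn inside each family's reported range.

None of this emulates real side-chain packing, correlated model error,
pLDDT structure, or the sequence diversity of real families. A green
test therefore establishes that the algorithms implement their stated
definitions and invariants — not that the package reproduces any
published database-scale count. Those counts (≈15.8k records, family
sizes, the 804 motif-flagged sequences) are checked by an acceptance
test that requires the supplementary annotation spreadsheet, which
cannot ship in this text-only repository and must be supplied by the
user; offline that criterion reports red by design. The printed record
totals themselves disagree by one between sections (15,796 vs 15,797);
the loader reports whatever the supplied file contains.

## Numerical and design choices

* Band boundaries half-open, boundary to the stronger band (documented
  above).
* Disulfide cutoff comparison is strict (`< 3.0`), matching "smaller
  than".
* Best-hit ties break by lower RMSD, then lexicographic target id —
  full determinism.
* FASTA and PDB I/O are implemented in-package: round-trips must be
  byte-faithful for ids/order/sequences, errors must name the offending
  record, line or character, and no installed R package provides
  xlsx reading — the minimal reader walks the worksheet XML directly
  (shared strings, inline strings and plain values; first sheet only).
* The annotation loader treats a cell as a positive motif flag iff it is
  non-empty and not an explicit negative ("0", "false", "no", "na").
* Degenerate inputs fail loudly: empty FASTA, missing mapped columns
  (the error lists available headers), non-numeric PDB coordinates (with
  line number), non-finite Z scores, ordinal reuse in connectivity
  notations.
* Generators restore the caller's RNG state (`with_seed()`), so fixture
  creation never perturbs surrounding randomness.

## Known limitations

* No structure prediction, no structural searching, no Z-score
  computation — hit tables are inputs.
* Fingerprint pairing is by residue index; families whose members differ
  in length need an upstream alignment, which is out of scope.
* The Cα-only secondary-structure assignment is coarse by design; it is
  not a DSSP replacement.
* The disintegrin screen nominates candidates; integrin-specificity and
  affinity are biological questions beyond structural screening.
* mmCIF models must be converted to PDB text at the boundary.
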