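---
title: "Saturation stability scanning for missense and in-frame deletion variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Saturation stability scanning for missense and in-frame deletion variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddgscan)
```

## The problem

Many disease-linked missense variants and single-residue in-frame deletions
do not ablate a protein's function directly: they destabilize the fold,
and the destabilized protein is cleared by cellular protein quality
control. A change in folding free energy (ΔΔG) of roughly 3 kcal/mol is
typically enough to trigger degradation. Predicting ΔΔG for *every*
possible single-site change across a domain — 19 substitutions plus one
deletion per position — and joining the predictions with population allele
frequencies and clinical labels therefore gives a triage map: common,
benign variants should cluster near ΔΔG ≈ 0, while rare pathogenic
variants spread toward high ΔΔG (the "fishtail" shape).

Missense ΔΔG prediction is routine for all-atom force fields. Single-residue
deletions are not: removing a residue leaves a backbone gap that must be
re-closed, straining the neighbourhood. This package implements the full
deletion protocol — model ensembles, independent relax trajectories, median
aggregation, a percentile baseline and kcal/mol scaling — in a
backend-agnostic way, together with the missense protocol, the annotation
joins, heatmap/fishtail outputs and a synthetic-data module that makes
every stage testable without downloads.

## The protocols

**Missense.** For variant $v$ at a resolved position, both the wild-type
structure and the substituted structure are scored $n_{\mathrm{iter}} = 3$
times each (one seeded relax-then-score per iteration), and

$$\Delta\Delta G_v \;=\; \frac{\overline{E}_{\mathrm{variant}} -
\overline{E}_{\mathrm{wild\ type}}}{2.9}\ \text{kcal/mol.}$$

The sign convention is **positive = destabilizing** (the variant costs
energy relative to wild type). Identity "variants" (alt == wt) are the
wild-type reference rows and are defined as exactly 0 rather than
re-scored, so the reference carries no sampling noise.

**Deletion.** For a deletion at position $i$:

1. build $n_{\mathrm{models}} = 25$ gap-closed backbone models (below);
2. relax each model in $n_{\mathrm{traj}} = 2$ independent seeded
   trajectories, giving $25 \times 2 = 50$ scores;
3. the raw ΔG of the deletion is the **median** of those 50 scores
   (even count: mean of the two middle values);
4. across the whole domain, subtract the **10th percentile** of the ΔG
   distribution as baseline, then divide by 2.9:
   $\Delta\Delta G_i = (\tilde{G}_i - G_{P10}) / 2.9$.

The percentile baseline makes deletion scores relative destabilization
estimates: by construction at most ⌈0.1·N⌉ of them can be negative. The
divisor 2.9 is a configuration constant appropriate for the external
all-atom backend it was calibrated against; it is applied to any backend
for scale consistency but has no deeper meaning for the built-in scorer.
Baseline subtraction and division commute for the difference; the audit
trail stores the subtract-then-divide order.

All protocol constants live in `protocol_config()` and are serialized into
every output record; `ddg_kcal * kcal_divisor` reconstructs the unscaled
statistic to 1e-9 by invariant.

## Gap closure for deletions

Deleting residue $i$ leaves the flanking Cα atoms one virtual bond too far
apart (≈5.5 Å mid-helix, up to ≈7.6 Å in extended chain). Closure uses
shifted-sequence threading over a window of $w = 3$ residues per side:
each window residue is translated toward the vacated template slot with a
tapered fraction (full adaptive fraction at the gap — chosen so the new
junction bond lands near 3.8 Å whatever the local geometry — down to $1/w$
of it at the window edge). Because a pure taper can leave corner bonds
slightly outside the validated [2.8, 4.3] Å band where secondary-structure
elements meet, the window Cαs are then smoothed by an iterative bond
projection (consecutive virtual bonds pulled into [3.3, 4.15] Å, anchors
fixed). Each ensemble member receives an independent seeded jitter
(σ = 0.3 Å rigid per-residue on the window, re-projected, plus σ/3
per-atom), giving the median real spread to aggregate over. Every
non-terminal model re-validates geometry; failures re-jitter with a
derived seed and error after a bounded number of retries. Terminal
deletions trim the chain without closure and are flagged. Side chains in
the window are reduced to Cβ stubs — the built-in scorer is coarse-grained
and never looks past Cβ.

Author (deposited) residue numbering is kept throughout, with the deleted
position vacated, so variant positions always match the literature.

## The built-in scorer (and what it is not)

The published protocol drives an external all-atom force field. That force
field is deliberately **not** re-implemented; its invocation contract is
(`external_adapter()`: write PDB, run the configured command template,
parse the returned score table, never fall back silently). For desk-scale
work and testing, a deterministic coarse-grained potential stands in:

| term | form | intent |
|---|---|---|
| clash | $k\sum (r_c - d)^2$ over non-bonded pairs $< r_c = 2.8$ Å | steric overlap |
| burial mismatch | $\sum \mathrm{KD}(aa)\,(\mathrm{exposure} - \mathrm{expected})$ | hydrophobics belong inside |
| backbone strain | squared deviation of Cα virtual bonds (3.8 Å) and angles (91°) | closure/distortion cost |
| volume mismatch | $k_V \sum (V_{aa} - V_{\mathrm{template}})^2$ at buried sites | cavity/overpacking |

Exposure is a Cβ-contact-count proxy (cutoff 7 Å, saturation at 8
contacts); hydrophobicity is the Kyte–Doolittle scale; volumes are standard
residue volumes. The total is exactly the sum of the four terms, the score
is invariant under rigid motion, and scoring is bit-deterministic. The
virtual-angle reference is the α-helical value: regular helix scores near
zero strain and looser geometry carries a constant offset that cancels in
ΔΔG differences and is absorbed by the percentile baseline in deletion
scans.

**The built-in scorer's numbers are not comparable to published all-atom
ΔΔG values.** Reproducing the reference per-variant values (e.g. 5.0
kcal/mol for the well-known destabilizing deletion at position 508 of the
domain the protocol was published on) requires the external backend and
the crystal structure; those are optional adapter-path benchmarks. What
the built-in scorer supports — and what the test suite establishes — is
the *protocol*: exact counts, exact aggregation, correct sign, and the
qualitative orderings (buried > exposed, mid-helix deletion > linker
deletion, common ≈ neutral vs rare-pathogenic ≈ destabilized).

`relax()` is seeded jitter plus greedy accept-if-better descent with a
relative-improvement stop — not the external tool's relax schedule. The
contract the protocol layer relies on is: seeded ⇒ bit-reproducible;
monotone (never returns a score above the input structure's); terminating.

## Synthetic data: the stated world

`make_ideal_helix()` builds backbones from ideal internal coordinates
(φ = −57°, ψ = −47°, standard bond lengths/angles), so Cα–Cα ≈ 3.8 Å and
rise ≈ 1.5 Å hold by construction. `make_two_helix_bundle()` packs two
antiparallel ideal helices at 9 Å inter-axis distance joined by an arc
linker sampled at ~3.8 Å spacing. Ground truth is geometric burial by
Cβ-contact count (≥ 5 contacts at 7 Å, counted on the Cβ-complete
backbone): in this packed geometry those are exactly the interface-facing
sites, and every buried position out-contacts every linker position. The
`"auto"` sequence places L/I/V/F at buried sites, E/K/Q/S at exposed ones
and G/S in the linker.

`make_annotation_tables()` draws the fishtail world as stated: a common
stratum with ΔΔG ~ N(0, 0.5²) kcal/mol and log-uniform allele frequency in
[1e-3, 1e-1] with benign labels, and a rare pathogenic stratum with ΔΔG ~
N(4, 1²), frequency in [1e-6, 1e-4] and pathogenic labels (~30% of them
deletions). With the 3 kcal/mol destabilized threshold the expected
recovery sensitivity is Φ(1) ≈ 0.84, which is what the acceptance test
checks to within 3 standard errors at n = 20. Frequencies are reported as
exact allele-count ratios against a fixed allele number of 2×10⁶.

What a green test does **not** establish: that the built-in potential
ranks real variants of real proteins correctly; that closure reproduces
all-atom deletion geometry; or that the synthetic bundle represents
β-sheet, loop-rich or multi-domain architecture. The synthetic world has
no measurement noise in frequencies, no VUS/conflicting labels, and
perfectly ideal geometry.

## Classification, joins and motifs

`classify_stability()` uses neutral < 1.0 ≤ intermediate < 3.0 ≤
destabilized (kcal/mol), the 3.0 anchor being the quality-control
engagement scale; the boundary is inclusive on the destabilized side.
`build_fishtail()` outer-joins on the ΔΔG side: every record yields a row;
a variant absent from the frequency table gets `NA` frequency, because
absence from a population database is censoring, not frequency zero.
Duplicate annotations are an error naming the variant; unmatched
annotation rows are reported, never dropped silently.

`scan_usp7_motifs()` scans position-wise residue-class consensus patterns
(deubiquitinase-recognition motifs by default: `[PA]xxS` for the
TRAF-domain pocket, `KxKxxxK` consistent with the known UBL1/2-domain
sites). The exact consensus definitions are configuration — every report
states the patterns used — and matches may overlap.

## Numerical choices and degenerate inputs

* Percentile method: linear interpolation (the common type-7 rule) by
  default; `"lower"` and `"nearest"` are available. The choice matters at
  small N and is serialized with every scan.
* Seeds: every child seed is a stable 31-bit hash of (master seed, variant
  label, model index, trajectory index) — reproducible across sessions and
  safe for parallel-by-variant execution; outputs are written in variant
  order regardless. Package internals never disturb the caller's RNG.
* Altlocs resolve to highest occupancy, ties by altloc character order.
* Residues missing N/CA/C are flagged and excluded from scans, never
  silently dropped; slices record absent author positions.
* A single-residue domain has no deletion baseline: `deletion_scan()`
  errors rather than inventing one.
* Identity cells in heatmaps are exactly 0; missing cells are `NA`, not 0.
* Ties in greedy descent: a proposal is accepted only on strict
  improvement, so the trajectory is independent of floating-point
  tie-break order.

## Known limitations

* The built-in potential has no hydrogen bonds, no electrostatics and no
  side chains beyond Cβ; its ΔΔG scale is internal.
* Closure is interpolation-based, not fragment- or loop-modelling; for
  real structures the external adapter path should carry the models.
* Multi-residue deletions, insertions and frameshifts are out of scope, as
  are mmCIF input and multi-model NMR files.
* The external adapter is exercised in tests with a scripted fake tool;
  it has not been run against the real external binary in this
  environment.
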