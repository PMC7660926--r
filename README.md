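# ddgscan

Saturation stability scanning of protein domains for **missense variants
and single-residue in-frame deletions**, with downstream triage of the
predictions against population allele frequencies and clinical labels.

## Who this is for

Structural bioinformaticians and variant curators who want to ask, for a
domain of known structure: *which single-site changes destabilize the
fold enough to become protein-quality-control targets?* Destabilization of
roughly 3 kcal/mol is typically enough to trigger cellular degradation, so
a predicted ΔΔG map across all 19 substitutions + 1 deletion per position,
joined with gnomAD-style frequencies and ClinVar-style labels, separates
common/benign near-neutral variants from rare, destabilized, likely
pathogenic ones — the "fishtail" pattern.

## What it computes

**Missense ΔΔG** — variant and wild type are each scored 3 times
(seeded relax-then-score); ΔΔG = (mean variant − mean wild type) / 2.9
kcal/mol. Positive = destabilizing. Wild-type reference rows are exactly 0.

**Deletion ΔΔG** — the distinctive part. Deleting residue *i* leaves a
backbone gap, which is re-closed by tapered shifted-sequence threading
over a ±3-residue window:

1. build **25** gap-closed models with independent seeded jitter;
2. relax each in **2** independent trajectories → **50** scores;
3. raw ΔG = **median** of the 50;
4. ΔΔG = (ΔG − 10th percentile of the domain's ΔG distribution) / **2.9**.

Both protocols are backend-agnostic: a deterministic built-in
coarse-grained scorer (clash + burial mismatch + backbone strain + volume
mismatch) supports desk-scale work and testing, and an adapter contract
(`external_adapter()`) drives an external all-atom relax/score tool for
production numbers. **Built-in scores are not comparable to published
all-atom ΔΔG values** (e.g. the reference values 2.9 for R362C or 5.0 for
ΔK508 on the domain the protocol was published with require the external
backend and the crystal structure); the built-in scorer exists to make the
protocol itself exactly testable.

## Worked example

```r
library(ddgscan)

## a synthetic two-helix bundle with known buried/exposed/linker truth
b <- make_two_helix_bundle(synth_structure_spec())
b$structure
#> <ddg_structure 'synthetic-two_helix_bundle'>: 28 residues (28 resolved), 138 atoms

## one missense variant: buried hydrophobic -> aspartate
cfg <- protocol_config(n_models = 5, n_traj = 1, master_seed = 1)
missense_ddg(b$structure, parse_variant("L5D"), scorer_spec(), cfg)
#> <ddg_record> L5D: ddG = 1.286 kcal/mol (3 score(s), builtin)

## all 28 single-residue deletions
del <- deletion_scan(b$structure, scorer_spec(), cfg)
del
#> <ddg_deletion_scan> 28 positions; baseline 21.247; ddG range -0.26..6.93
```

Mid-helix deletions average **3.23 kcal/mol** against **0.17 kcal/mol**
for linker deletions — deleting inside regular secondary structure strains
the closed backbone, deleting in a flexible linker is nearly free, which
is exactly the qualitative behaviour reported for real domains (helix
deletions destabilizing, linker deletions tolerated). `classify_stability(
c(0.1, 2.2, 4.7))` returns `"neutral" "intermediate" "destabilized"`
(thresholds 1 and 3 kcal/mol, inclusive upper boundary).

The burial signal is there too: across the bundle, buried
hydrophobic→charged substitutions average a higher ΔΔG than the same
substitutions at exposed positions (run `tests/testthat/test-acceptance.R`
criterion 4 to see it asserted).

### Command line

```sh
Rscript -e 'ddgscan::ddgscan_run(commandArgs(TRUE))' \
    scan --structure domain.pdb --chain A --seed 1 --out-dir out/
```

Subcommands: `scan`, `deletion-scan`, `annotate`, `heatmap`, `synth`,
`motif-scan`. Every run writes `manifest.json` (full config + seeds)
before computing; result TSVs embed the manifest hash, and re-running the
same configuration reproduces them byte-identically.

## Package layout

| | |
|---|---|
| `R/structure-io.R` | fixed-column PDB read/validate/slice/write, author numbering |
| `R/variants.R` | variant labels ("R362C", "ΔK508"/"delK508"), saturation enumeration |
| `R/energy.R` | built-in coarse-grained scorer, seeded relax, external adapter |
| `R/deletion-modeling.R` | gap-closed deletion model ensembles |
| `R/ddg-protocol.R` | missense/deletion aggregation protocols, scan tables |
| `R/annotate.R` | frequency/label joins, fishtail, heatmaps, motif scans |
| `R/synthetic.R` | ideal helices, two-helix bundle with ground truth, annotation tables |
| `R/cli.R` | subcommand CLI, manifests, logs |

See `vignettes/stability-scanning.Rmd` for the model, its assumptions and
the reasoning behind every tunable constant.
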