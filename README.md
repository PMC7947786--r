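# divcons — differential conservation analysis of paralogous protein families

After a gene duplication, two paralogous enzyme subfamilies can evolve
opposite activities while keeping the same fold — the Pup-ligase PafA and the
depupylase Dop of the bacterial pupylation system are a canonical example.
The residues responsible for such functional divergence leave a
recognisable signature: positions that are **maximally conserved in one
family but free in the other** (uniquely conserved), or **maximally
conserved in both families around different residues** (differently
conserved), concentrated near the active site. `divcons` finds those
positions and converts them into concrete mutant designs — reciprocal
substitutions, combinatorial segment libraries, and single-reversion
series.

## Method

For homolog sequences `S` and two subfamily reference structures:

1. **Family partitioning.** All-vs-all Smith–Waterman bit scores
   (BLOSUM62, affine gaps 11/1) form a sequence-similarity network; the
   connected components at a bit-score threshold *T* are the families.
2. **Per-family conservation.** Each family is aligned progressively along
   a neighbor-joining guide tree (k-mer distances). For column *c* with
   Henikoff-weighted residue frequencies *p<sub>c</sub>* and background
   *q*, the conservation score is

   *s(c) = (1 − gap<sub>c</sub>) · JSD(p<sub>c</sub>, q) / max<sub>a</sub> JSD(δ<sub>a</sub>, q)*

   with base-2 Jensen–Shannon divergence; scores are binned
   equal-frequency into grades 1–9 (9 = maximal, ConSurf convention).
3. **Cross-family mapping.** The two reference structures are superposed
   by iteratively refined Kabsch superposition with colinear
   re-pairing (dynamic programming on the inter-CA distance matrix,
   cutoff 5 Å); the residue correspondence is lifted to a
   column↔column map between the family alignments. Columns without a
   partner mark family-specific insertions such as the Dop-loop.
4. **Classification and spatial filter.** Each mapped position is
   classified as `shared_identical`, `differently_conserved`,
   `unique_A`/`unique_B`, `indel`, or `unconserved`, and candidates
   farther than 20 Å (CA–CA) from the user-supplied active site are
   discarded.
5. **Mutant design.** Selected positions become substitution units
   ("S27A"), deletions and insertions; segment groupings enumerate
   2<sup>k</sup> combinatorial libraries and single-reversion series.

A synthetic-data module generates fully labelled two-family bundles
(planted constraint classes, toy structures with a known rigid transform
and optional insertion), so every stage is validated against ground truth.

## Worked example

```r
library(divcons)

bundle <- simulate_families(sim_config(seed = 42))   # 50 + 50 sequences, 200 residues
run    <- divcons_bundle_run(bundle)                  # full analysis
run
#> divcons analysis
#>   sequences: 100 in 2 clusters; families A/B: 50 / 50
#>   columns A/B: 200 / 200 ; matched: 200 ; superposition rmsd: 0.536 A
#>   candidates: 33 ; selected (<= 20 A): 27

summary(run)
#> divcons summary
#>   class counts:
#>     shared_identical          4  (selected: 0)
#>     unique_A                 14  (selected: 10)
#>     unique_B                 14  (selected: 12)
#>     differently_conserved     5  (selected: 5)
#>     indel                     0  (selected: 0)
#>     unconserved             163  (selected: 0)
#>   matched columns: 200 ; candidates: 33 ; selected: 27

evaluate_recovery(run$positions, bundle$truth)[c("precision", "recall")]
#> precision 0.926, recall 1.000
```

The 100 sequences fall into two pure 50-member clusters; all 200 columns
map one-to-one through the structural superposition (RMSD 0.54 Å, the
generator's coordinate noise); 27 positions pass the 20 Å filter, and they
recover the planted candidate sites with precision 0.93 and recall 1.00 on
this seed. The first selected rows of `candidate_report(run$positions)`:

```
   res_a aa_a aa_b grade_a grade_b                 class distance
76    76    I    I       9       7              unique_A    18.18
78    78    N    E       9       9 differently_conserved    15.32
79    79    G    G       4       9              unique_B    14.25
```

Mutant design from the bundled Dop/PafA tables:

```r
units <- position_units()                 # 20 positions + the Dop-loop deletion
base  <- read_fasta(dop_pafa_file("base"))
lib   <- enumerate_library(read_segments())   # 2^5 = 32 mutants
write_mutants(lib, base, "library.fasta")
```

A thin command-line wrapper with subcommands
(`run|simulate|cluster|conserve|map|classify|design`) is installed at
`inst/cli/divcons.R`.

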