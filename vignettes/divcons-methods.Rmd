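---
title: "divcons: methods, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{divcons: methods, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divcons)
```

## The problem

Two paralogous enzyme subfamilies — such as the Pup-ligase PafA and the
depupylase/deamidase Dop of the bacterial pupylation system — can share a
fold and most of their active site yet catalyse opposite reactions. The
positions responsible for that divergence are expected to be (a) under
strong purifying selection *within* each subfamily, (b) *different*
between the subfamilies, and (c) close to the catalytic machinery.
`divcons` operationalises this signature: it partitions homologs into
subfamilies, profiles per-column conservation in each, maps the two family
alignments onto each other through their reference structures, classifies
every mapped position, filters by active-site distance, and emits mutant
designs for the survivors.

## Stage by stage

### Family partitioning

All sequence pairs are scored by Smith–Waterman local alignment
(Biostrings) under BLOSUM62 with affine gaps (a length-*L* gap costs
`gap_open + L * gap_extend`, defaults 11/1, the standard protein-search
convention). Raw scores are expressed in bits with the standard gapped
Karlin–Altschul constants per matrix; the conversion is approximate by
design, which is why the clustering threshold is a required configuration
value rather than a constant. Unknown residues (`X`) score 0 against
everything. Families are the connected components of the thresholded
network, ordered by size and then by the lexicographically smallest member
so reports are deterministic. All-vs-all scoring is quadratic; a
`max_pairs` guard rejects inputs beyond desk scale.

### Guide tree and progressive alignment

Each family is aligned with a deliberately basic progressive aligner:
a neighbor-joining guide tree (ape) on k-mer distances
(`1 − shared/min`, k = 3), then profile–profile Needleman–Wunsch up the
tree, scoring column pairs by the expected substitution score between
residue-frequency profiles. Once a gap column is inserted it is never
removed. Two numerical choices matter:

* **Gap opening 15 for profile merges** (pairwise local scoring keeps
  11). Expected profile–profile column scores are weaker than
  single-sequence scores, and with the softer penalty a single deeply
  diverged sequence merging into a large profile can trigger runaway gap
  insertion. With gap opening 15, indel-free families align gap-free
  across the development seeds — a property the test suite asserts.
* Frequencies are normalised by the number of rows, so gappy profile
  columns score proportionally less and attract further gaps rather than
  repelling them.

Families beyond desk scale, or with substantial indel structure, should be
aligned externally and supplied via `read_alignment()`; the pipeline then
skips its alignment stage and notes that in the run summary.

### Conservation scores and grades

Sequences are weighted by the Henikoff–Henikoff position-based scheme
(gaps count as a 21st symbol), a deterministic proxy for phylogenetic
down-weighting of redundant sequences. For a column with weighted residue
frequencies $p$ and background $q$,

$$ s = (1 - g)\,\frac{\mathrm{JSD}_2(p, q)}{\max_a \mathrm{JSD}_2(\delta_a, q)} $$

where $g$ is the weighted gap fraction and the denominator is the largest
divergence any single-residue column can reach against $q$ (JSD is convex
in $p$, so point masses are extremal). Scores live in $[0, 1]$: an
invariant gap-free column scores 1 against a uniform background, and a
column matching the background scores 0. The default background is the
BLOSUM62 marginal frequencies; `background = "uniform"` removes the
rarity preference (a conserved tryptophan then no longer outranks a
conserved leucine).

Grades 1–9 are assigned by **equal-frequency binning** of the scores over
columns with gap fraction ≤ 0.5 (gappier columns are deemed unreliable and
receive grade 1); grade 9 holds the most-conserved ninth of the columns,
ties share the higher grade. Equal-frequency binning guarantees a
non-empty top bin whatever the score distribution, mirroring how 1–9
conservation colour scales are used in practice.

This score is an explicit, oracle-checkable stand-in for empirical-Bayes
rate estimation (Rate4Site-style). Absolute grades will therefore not
reproduce a web server's output on real data; only the downstream
classification logic consumes the grades, and that logic is what the
package tests.

### Structure-based cross-family mapping

Structures are CA-only (`read_structure()` keeps one CA per residue,
first MODEL, altloc blank/A; residues are renumbered sequentially from 1
and the author numbering kept as a label — internal arithmetic and
active-site lists use the sequential numbering, which equals the 1-based
position in the structure's sequence). The Kabsch superposition is solved
by SVD with a determinant sign flip, so reflections are never returned.

`iterative_structural_align()` alternates Kabsch on the current residue
pairs with colinear re-pairing: a dynamic program on the inter-CA distance
matrix that maximises the number of pairs within the cutoff (default
5 Å, max 20 iterations) and breaks ties by minimal total distance, so the
correspondence always has the shape of a sequence alignment. Because the
greedy iteration can lock into a shifted register when the initial
sequence-based seed is poor (distant paralogs), the refinement is
**multi-start**: the sequence seed plus a fan of diagonal-register seeds
are each refined, and the result pairing the most residues (ties: lowest
RMSD) is kept. The procedure is fully deterministic.

The final residue pairs are lifted to a column↔column map between the two
family alignments via each reference row's ungapped positions. Columns
with no partner — including family-specific insertions like the
Dop-loop — are reported as unmatched.

### Classification and the spatial filter

For a matched column pair with grades $(g_A, g_B)$ and consensus residues
$(c_A, c_B)$:

| class | rule |
|---|---|
| `shared_identical` | $g_A = g_B = 9$, $c_A = c_B$ |
| `differently_conserved` | $g_A = g_B = 9$, $c_A \ne c_B$ |
| `unique_A` / `unique_B` | grade 9 on one side, grade ≤ `low_cutoff` (or no partner) on the other |
| `indel` | unmatched column with grade 9 on its own side |
| `unconserved` | everything else |

`low_cutoff` is the highest grade still counted as "not conserved"; the
default is 8, i.e. *anything below the maximal grade*. This follows the
observation that genuinely family-discriminating positions routinely show
grade 7–8 in the partner family (the Dop/PafA position table bundled with
the package contains uniquely conserved positions whose partner grade is
8), and it is the only reading under which equal-frequency binning leaves
the classifier with usable recall: grades 7–8 necessarily hold two-ninths
of the columns, so demanding a partner grade below 6 misclassifies about a
quarter of truly unique sites as unconserved. The value is exposed in the
configuration and echoed in output metadata.

Candidates are then filtered by minimum CA–CA distance to the active-site
residues (default threshold 20 Å, measured on CA because the structure
model is CA-only). Indel records lacking a residue on the active-site
structure's side inherit the smallest distance of their flanking matched
columns — an inserted loop sits near its flanks — and records with no
computable distance are never selected. A `forced` list can inject
manually chosen positions (e.g. substitutions needed to preserve secondary
structure) past the class rules; they are flagged as selected regardless.

### Mutant design

Selected positions become `MutationUnit`s: substitutions named `X27Y`
(base residue, position, counterpart consensus), deletions over inclusive
ranges, insertions anchored *after* their stated position. Units store the
expected base residue and applying them re-checks it, which guards against
coordinate drift between tables and sequences. Application order is
canonical descending-coordinate, so earlier anchors stay valid; the test
suite proves equivalence with naive left-to-right re-anchoring and the
apply-then-invert identity. `enumerate_library()` expands k disjoint
segments into all $2^k$ on/off combinations in binary-counting order
(backbone first, full mutant last; a guard rejects k > 20), and
`reversion_series()` drops one unit group at a time, with grouped units
(e.g. a substitution block spanning an insertion) reverting together.

## The synthetic generator

`simulate_families()` draws an ancestral sequence from the BLOSUM62
background, duplicates it, and evolves each copy along a stem and then an
independent random tree (`ape::rtree`, exponential branch lengths) with
per-site Poisson substitutions and background replacements. Constraint
classes are enforced at the leaves: each constrained site shows its family
target with probability $1-\varepsilon$, otherwise a non-target background
residue — so the per-site violation rate is exactly $\varepsilon$ and
directly verifiable (the suite checks it against binomial error).

Default study conditions: 50 sequences per family, 200 residues,
10 unique-A + 10 unique-B + 5 differently-conserved + 5 shared sites,
$\varepsilon = 0.02$. Values the conditions leave open were fixed once, on
realism grounds:

* **Stem 2.0 substitutions/site per family.** Free sites between families
  are then essentially at background identity (~8–10% observed), well
  below the within-family level, so the similarity network separates the
  families cleanly; the generator's documented separation threshold is
  **40 bits** (between-family maxima ~30 bits, within-family networks
  connected and pure from 35 to 45 bits across development seeds).
* **Mean branch length 0.1 substitutions/site** within families
  (within-family identity ≈ 45%). Within-family identity must exceed the
  between-family level — real paralog pairs of this kind sit near 37%
  identity — and the trees must be deep enough that unconstrained columns
  are visibly variable across 50 leaves; with much shallower trees,
  chance-invariant free columns crowd the equal-frequency top bin and
  displace genuinely constrained sites, an artifact of tree depth rather
  than of the classifier.
* **Constrained sites are planted inside positions 76–124, around
  active-site anchors {88, 100, 112}.** This mirrors the biological
  premise of the method: specificity determinants cluster near the
  catalytic cradle, and the >20 Å filter exists precisely to discard
  remote, spuriously conserved positions.
* **Toy structures** are CA traces of an alpha-helix (rise 1.5 Å, 100°
  turn, radius 2.3 Å) wound on a gently curved axis (radius 90 Å).  A
  perfectly straight ideal helix has an exact screw symmetry — shifting
  the residue register equals a rigid transform — which makes the true
  register unidentifiable from geometry; the curvature breaks that
  degeneracy while keeping consecutive CA spacing helix-like. Structure B
  is structure A minus/plus the planted insertion, under a random proper
  rigid transform plus 0.3 Å Gaussian noise, with the transform and
  correspondence recorded as truth.

What the generator deliberately does **not** emulate: rate heterogeneity
across sites, realistic exchangeabilities, indel evolution (outside the
single planted insertion region), covarion behaviour, horizontal transfer,
or realistic protein geometry. Passing the recovery tests therefore shows
that the pipeline's logic is sound under its own assumptions — near-binary
contrast between constrained and free sites — not that it reproduces any
particular web-server scores on real families.

## Problem sizes used by the test suite

The suite validates each operation against independent oracles (quadratic
Smith–Waterman DP, union-find components, direct-summation JSD, exhaustive
distance scans, construct-and-recover transforms) and runs the full
pipeline on 20 seeded bundles at the default conditions, asserting mean
precision and recall of at least 0.9 for recovered candidate positions.
`scripts/acceptance.R` recomputes the same quantities from scratch with a
caller-supplied seed. Twenty bundles of 50+50 sequences × 200 residues
keep the whole suite comfortably within a few minutes on one CPU and give
stable means.

## Known limitations

* The conservation score is a weighted-JSD stand-in, not an evolutionary
  rate model; grades are comparable within a run only.
* The progressive aligner is basic by design (no iterative refinement, no
  position-specific gap penalties); deeply diverged or indel-rich families
  should be aligned externally.
* CA-only structures: distances are CA–CA, no side-chain or all-atom
  geometry, no flexible/multi-domain superposition, no mmCIF input.
* Active sites are user-supplied; there is no automatic detection.
* The run summary records wall-clock timings, so `summary.json` differs
  between repeated runs; all scientific artifacts (network, clusters,
  alignments, profiles, map, candidate table) are byte-identical given
  identical inputs and configuration, and the suite asserts that.
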