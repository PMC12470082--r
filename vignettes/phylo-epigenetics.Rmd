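---
title: "Phylo-epigenetic analysis of CpG island erosion: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylo-epigenetic analysis of CpG island erosion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyloCpG)
```

## The biological model

Cytosines in CpG dinucleotides are the principal substrate of mammalian DNA
methylation, and 5-methylcytosine deaminates to thymine far more readily
than unmethylated cytosine does. The resulting T:G mismatch is repaired
inefficiently, so the transition rate from a methylated CpG to TpG is of the
order of 10--50 times the background transition rate. Because CpG is
palindromic, the same process on the antisense strand converts CpG to CpA on
the sense strand. CpG-dense, GC-rich islands in and around the first exons
of developmentally regulated genes therefore erode along evolutionary
lineages in a methylation-dependent way, and the pattern of CpG
presence/absence at orthologous positions carries phylogenetic signal of an
epigenetic origin -- a "phylo-epigenetic" character set.

phyloCpG implements the complete comparative workflow around this model:

1. **Island detection** (`findCpgIslands`) and per-species concatenation of
   island loci (`concatenateLoci`), alignment ingestion (`buildMsa`).
2. **Orthologous dinucleotide annotation** (`tileDinucleotides`,
   `classifyPositions`): the alignment is tiled into non-overlapping column
   pairs and each position is classed as conserved CpG, variable CpG,
   conserved non-CpG, variable non-CpG, or excluded.
3. **Variability and spectrum statistics** (`variabilityStats`,
   `substitutionSpectrum`, `cladeMarkers`, `contextCounts`).
4. **Recoding** (`recodeCpg`): CpG presence/absence becomes a per-species
   A/T/- character matrix.
5. **Trees** (`pDistance`, `upgmaTree`, `calibrateTree`): UPGMA under the
   molecular-clock assumption on (a) all changes and (b) CpG-only
   characters, with absolute-time calibration on a known species-pair
   divergence.
6. **Simulation** (`erosionParams`, `simulateStudyDataset`): a
   context-dependent erosion simulator that supplies ground truth for every
   stage above.

## Island detection

An island is an interval satisfying GC fraction $\ge$ 0.5,
observed/expected CpG ratio $\ge$ 0.6 and length $\ge$ 200 bp, with

$$\mathrm{obs/exp} = \frac{n_{CG}\cdot L}{n_C \cdot n_G}.$$

The GC-content threshold alone does not make island calling well-posed, so
the classical obs/exp and length criteria are adopted as configurable
defaults. The algorithm is deliberately simple and oracle-checkable:
200-bp sliding windows (step 1) that pass all thresholds are merged when
they overlap, and each merged interval is trimmed to its longest passing
subinterval, leftmost on ties. Coordinates are 0-based half-open in all
exports; `N` counts as neither C nor G and never forms a CpG; only the plus
strand is scanned (the antisense CpA outcome is handled downstream as a
dinucleotide class, never by reverse-complementing input).

## Dinucleotide annotation choices

Several conventions are required where the analysis is otherwise
ambiguous; each is surfaced as a documented, testable rule:

* **Tiling frame.** Non-overlapping column pairs anchored at the first
  alignment column, `floor(ncol/2)` positions, trailing odd column ignored.
  An overlapping scan would double-count the same CpG.
* **Gap rule.** A gap belonging to a run of $\ge$ 2 alignment columns in any
  species excludes the whole position (indels of that size make orthology
  of the pair doubtful); a single-column gap, or an `N`, merely drops that
  species from the position. This rule is applied uniformly to every
  per-position analysis.
* **Classification.** With the evaluable species at a position (no gap/N in
  either column): all states `CG` $\rightarrow$ conserved CpG; at least one
  but not all `CG` $\rightarrow$ variable CpG; otherwise conserved or
  variable non-CpG. Fewer than two evaluable species $\rightarrow$
  excluded.
* **Spectrum counting unit.** Each *distinct* non-CG state at a variable
  CpG position contributes one count to its CG$\to$XY bin, however many
  species share it. Counting per species instead would inflate bins by
  clade sizes; counting per position only would hide secondary alternative
  states. Under strong hypermutability the CG$\to$TG and CG$\to$CA bins
  (the two deamination products) dominate, and the test suite asserts this
  on simulated data.
* **Clade markers.** A variable CpG position is a marker for a two-clade
  partition when every evaluable member of one clade has `CG` and every
  evaluable member of the other does not, in either polarity (the marker
  set is polarity-invariant; both clades must be represented). The SNV
  analogue requires internally uniform, disjoint clade base sets at a
  non-CpG column.
* **Substitution contexts.** For a two-species comparison, the context of a
  changed reference base is its nearest non-gap left neighbour in the
  reference row plus the base itself, which places an altered G second
  (CpG, GpG, ApG, TpG) and tallies altered adenines in CpA separately.

## Recoding rule

Two readings of the A/T transformation exist: a species-invariant one
(conserved CpG positions become "A", variable positions "T" -- identical
rows for every species) and a per-species one (each species' state at a
CpG-bearing position: `CG` $\rightarrow$ `A`, other $\rightarrow$ `T`,
non-evaluable $\rightarrow$ `-`). Only the per-species reading yields
between-species variation, and a distance tree built from the characters is
only meaningful under it, so it is the default; the species-invariant
variant is available as `rule = "uniform"` for exploration and returns a
plain matrix with a warning. Constant-A columns (fully conserved CpGs) are
retained: they carry no distance signal but keep the character set equal to
"conserved CpGs plus all species-specific CpG substitutions", and their
count is an internal-consistency check against `variabilityStats`.

## Distances, UPGMA and calibration

`pDistance` is an uncorrected proportion of mismatching comparable
positions. For the "all changes" tree, `indels = "mismatch"` counts a
gap-vs-base column as one mismatch and excludes gap-vs-gap, which is the
simplest way to fold insertions and deletions into the distance; the
gap-excluding mode satisfies `pid/100 + d = 1` against `percentIdentity`
on gap-free alignments. `upgmaTree` is a direct implementation of
average-linkage clustering with merge height $d_{\min}/2$; exact ties are
broken by the lexicographic order of each cluster's smallest member label,
which makes the output deterministic and reproducible. The output is
ultrametric by construction and validated to $10^{-6}$ relative spread.

`calibrateTree` multiplies all node heights by
$t_{\mathrm{anchor}} / h_{\mathrm{MRCA(anchor)}}$, after which heights read
as absolute ages; calibrating twice with the same anchor is a no-op. Note
two caveats for absolute ages. First, p-distances are uncorrected, so
character saturation compresses deep nodes relative to shallow ones and
deep ages are underestimated. Second, anchoring on the *shallowest* split
(as the 1.7-unit A1/A2 pair of the default design does) divides every
height by a quantity estimated from only a handful of differing characters
-- roughly a dozen at 5 kb -- so ages far above the anchor are extremely
noisy and can vary severalfold across simulation seeds. A distance
correction is deliberately out of scope; the trees' topology and the
anchor's own age are the supported quantities.

`rfDistance` counts non-trivial unrooted bipartitions present in exactly
one tree; it is cross-checked in the tests against an independent
implementation.

## The erosion simulator

The simulator is event-driven (Gillespie-style) because CpG context makes
site evolution non-independent: each substitution changes its neighbours'
rates, so per-branch transition-matrix exponentiation would be wrong.
Along each branch, with sequence length $L$ and $n_{CG}$ current CpGs:

* background events arrive at total rate $L\mu$, hitting a uniform site;
  the new base is the transition with probability $\kappa/(\kappa+2)$,
  otherwise one of the two transversions;
* deamination events arrive at total rate $2 n_{CG}\mu(\lambda-1)$: a
  uniformly chosen CpG loses either its C (C$\to$T, yielding TpG) or its G
  (G$\to$A, yielding CpA) with equal probability -- the two strands of the
  palindrome, implemented without any reverse-complement bookkeeping.

Contexts are re-evaluated after every event. There are no indels, so the
leaf sequences are aligned by construction and annotation can be tested
independently of an external aligner. Every event is logged (branch, site,
time, from/to, 3-mer context, channel), and replaying the log from the
root must reproduce the leaves bitwise -- an invariant the tests assert.
For a short branch $t$ the expected number of deamination events is
$2 L_{CG}\,\mu(\lambda-1)t$, which the test suite and acceptance script
verify against 500-replicate Monte Carlo means.

Parameters and defaults:

| parameter | default | meaning |
|---|---|---|
| `mu` | 1 | background rate per site per unit branch length (branch lengths are then expected background substitutions/site) |
| `lambdaCpg` | 25 | CpG hypermutability multiplier; the biologically motivated range is 10--50 |
| `kappa` | 2 | transition/transversion ratio of background events |
| `rootLength` | 5000 | ancestral sequence length (three concatenated islands' worth) |
| `cpgFraction` | 0.085 | CpG dinucleotides per nucleotide of root sequence; 0.085 is the density seen in dense intragenic islands (about one CpG per six dinucleotide positions) |
| `seed` | 1 | master seed; the root generator uses `seed`, the evolver `seed + 1`, and replicate $r$ of any experiment should pass `seed + r` |

The root generator places exactly `round(cpgFraction * L)` CpGs on the
in-frame tiles and fills the remainder GC-rich (per-base probabilities
0.35/0.35 C/G) while rejecting any draw that would create an additional
CG within or across tiles, so the CpG count is exact and `cpgFraction = 0`
yields a CG-free sequence.

### The default study tree

`studyTree()` is a fixed two-clade chronogram -- 7 + 5 leaves (A1..A7,
B1..B5), node depths 1.7 to 25 time units, scaled by 1.6e-4
substitutions/site per unit so the root sits at height 0.004. The design
emulates the structure of a hominid-like and an Old World monkey-like
clade in a 12-species comparison: with the default erosion parameters,
pairwise identity of the simulated leaves stays above ~95%, about
two-thirds of CpG positions end up variable somewhere on the tree, and
every internal branch is long enough (at least 1.8 units, i.e. roughly
five-to-ten informative CpG characters at 5 kb) for the clustering to have
usable signal. The deepest pair of clade A (A1, A2) diverges at 1.7 units
and serves as the conventional calibration anchor.

### What the simulator does and does not emulate

It reproduces the features the pipeline's correctness depends on --
CpG-context hypermutability with both deamination products, clock-like
evolution, island-like base composition, closely related taxa. It does
**not** model indels (real alignments need an aligner and the gap rules
above), rate variation among lineages or sites, selection, biased gene
conversion, or methylation-state dynamics (every CpG is treated as
methylated). Green tests therefore certify the pipeline's algebra and its
statistical behaviour under the stated model, not the biological fidelity
of any real-data conclusion.

## Numerical and degenerate-input choices

* Uppercasing and U$\to$T mapping at FASTA ingestion; characters outside
  `A,C,G,T,N[,-]` are rejected with the record id and offset.
* All-N sequences produce an empty island list with a warning; a species
  pair with no co-ungapped columns is an error naming the pair.
* Newick branch lengths are written with 15 significant digits; round
  trips preserve node heights to well below $10^{-9}$.
* UPGMA rejects NaN/negative/asymmetric inputs rather than silently
  proceeding.
* An empty recoded matrix (no CpG anywhere) cannot be written to FASTA;
  the error says why.

## Problem sizes used in the test suite

The packaged experiments run at sizes chosen to exercise every code path
while keeping the suite fast: oracle-equivalence checks use 100 random
alignments of 3--8 species and 16--80 columns per operation; UPGMA
reconstruction uses 100 random ultrametric trees of 5--15 taxa; simulator
calibration uses 200 replicates (neutrality, $\lambda = 1$) and 500
replicates (deamination expectation, $\lambda = 25$) on 600--1000-site
sequences; the end-to-end recovery experiment uses the full 12-taxon,
5000-site configuration. At that size the whole suite completes in under a
minute.

## Known limitations

* Uncorrected distances compress deep divergence times (see above); only
  topology and anchor-consistent ages should be interpreted.
* Topology recovery at 5 kb is statistical: internal branches separated by
  only a handful of informative CpG characters can occasionally be
  misplaced by one node under an unlucky seed.
* Real island boundaries must be supplied by the user (or fetched with the
  optional network helper); the package does not reproduce any particular
  browser extraction.
* The Methods-style species-invariant recoding variant is exposed but
  unsupported for tree building, by design.
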