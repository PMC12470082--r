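# phyloCpG

Comparative ("phylo-epigenetic") analysis of CpG dinucleotide conservation
in alignments of CpG-island loci from closely related species.

## The problem

Methylated CpG dinucleotides deaminate to TpG — and, via the antisense
strand, to CpA — at 10–50× the background transition rate, so CpG-dense
islands in developmental master genes erode along evolutionary lineages in
a methylation-dependent way. Comparing *where* CpGs survive across a set of
closely related genomes turns that erosion into a character system: at each
orthologous dinucleotide position of a multiple alignment, every species
either retains the CpG or carries a decay product. phyloCpG is for
researchers in molecular evolution and comparative epigenomics who want to
quantify this signal and ask whether CpG presence/absence alone recovers
the species phylogeny.

The package provides, as composable S4-based building blocks:

* **CpG island detection** with the classical triple criterion
  (GC ≥ 0.5, obs/exp CpG = n(CG)·L / (n(C)·n(G)) ≥ 0.6, length ≥ 200 bp),
  plus FASTA I/O, per-species locus concatenation and alignment ingestion
  (external MAFFT call or pre-aligned input).
* **Orthologous dinucleotide annotation**: non-overlapping column-pair
  tiling; classification into conserved CpG / variable CpG / non-CpG
  classes with explicit gap and N rules; variability statistics; the
  CG→XY substitution spectrum; clade-distinguishing markers; substitution
  context counts.
* **Recoding** of CpG presence/absence into a per-species A/T/− character
  matrix (species with CG → A, other evaluable state → T, missing → −).
* **Trees**: percent identity, p-distances (with or without indel
  scoring), a deterministic UPGMA implementation (merge height d/2,
  lexicographic tie-breaks), absolute-time calibration on an anchor pair,
  Newick I/O and Robinson–Foulds comparison.
* **A context-dependent erosion simulator** (Gillespie-style, no indels,
  both deamination strands, full event log) that provides ground truth for
  every stage, including an analytic expectation for deamination counts,
  2·L(CG)·μ·(λ−1)·t, on short branches.

See the methods vignette (`vignettes/phylo-epigenetics.Rmd`) for the model,
parameter meanings and design decisions.

## Worked example

Simulate a 12-taxon, 5 kb two-clade dataset under 25× CpG hypermutability,
annotate it, and rebuild the tree from CpG characters alone:

```r
library(phyloCpG)

params <- erosionParams(seed = 7)        # 5000 sites, lambdaCpg = 25
sim <- simulateStudyDataset(params)
sim
#> SimResult: 12 leaves, 5000 sites, 528 events (415 CpG deaminations)

msa <- simMsa(sim)                       # no-indel model: already aligned
tb  <- classifyPositions(tileDinucleotides(msa))
variabilityStats(tb, msa)
#> CpG variability summary
#>   dinucleotide positions : 2500 (5000 nt columns)
#>   CpG positions          : 429 (132 conserved, 297 variable)
#>   non-CpG variable nt    : 90
#>   variable CpG / CpG         : 69.2%
#>   conserved CpG / CpG        : 30.8%
#>   variable CpG / dinuc       : 11.9%
#>   non-CpG variable nt / nt   : 1.8%

head(substitutionSpectrum(tb), 4)        # deamination products dominate
#>  TG  CA  CC  CT
#> 183 164   5   3

length(cladeMarkers(tb, studyPartition(), "cpg"))
#> [1] 24

rc   <- recodeCpg(tb)                    # 12 species x 429 A/T/- characters
tree <- calibrateTree(upgmaTree(pDistance(rc)), c("A1", "A2"), 1.7)
rfDistance(tree, sim@tree)               # CpG-only tree recovers the truth
#> [1] 0
```

The variability summary says: of 2500 orthologous dinucleotide positions,
429 carry a CpG in at least one species; 297 of those (69%) are variable
somewhere on the tree while only 1.8% of nucleotide columns outside CpGs
vary — the CpG hypermutability signature. The spectrum's two largest bins
are the deamination products TpG and CpA. After calibrating the CpG-only
UPGMA tree so that the (A1, A2) split sits at 1.7 time units, its topology
matches the generating tree exactly (Robinson–Foulds distance 0).

An end-to-end run over a YAML config (simulated or real input) is available
as `runPipeline()` / `validateConfig()`; it writes the full report bundle
(position table, statistics, spectrum, markers, recoded FASTA, percent
identity, both calibrated Newick trees, manifest) into an output directory,
byte-reproducibly for a fixed seed.

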