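# MetaCAZ

Comparative functional profiling of assembled metagenomes by
carbohydrate-active and lignin-oxidase gene families.

Biomass-degrading microbial communities are best compared not by which
species they contain but by which enzyme families they encode: glycoside
hydrolases (GH), glycosyl transferases (GT), carbohydrate esterases (CE),
carbohydrate-binding modules (CBM) from the CAZy classification, and
lignin oxidases (LO1–LO3) and auxiliary enzymes (LDA) from the FOLy
classification. MetaCAZ implements, as a tested and reusable R package,
the tiled translated-homology profiling computation that makes such
comparisons robust to dataset size:

1. **Tile** — contigs are divided into 300 nt tiles overlapping by 150 nt,
   so long scaffolds and short contigs contribute per nucleotide on an
   equal footing (`tileContig`).
2. **Search** — each tile is compared against a family-labeled protein
   database by six-frame Smith–Waterman alignment with BLOSUM62 and
   Karlin–Altschul-style e-values; hits with e ≥ 1e-10 are discarded
   (`searchContigs`, or ingest external 12-column tabular hits with
   `readHitTable`).
3. **Collect runs** — the best hit per tile labels its aligned nucleotides
   with a family; spans of overlapping tiles that agree are unioned so the
   overlap is never double counted (`bestHitPerTile`, `collectRuns`).
4. **Weight and normalize** — run lengths × mean contig depth, totaled by
   family and divided by the depth-weighted total bases:

   perMillion(f) = 1e6 · Σ_runs(f) len·depth / Σ_contigs len·depth

   "nucleotides per million depth-weighted nucleotides"
   (`familyTotals`, `normalizePerMillion`).
5. **Bin** — contigs are assigned to population bins by strand-symmetric
   trinucleotide composition against trained centroids, with a "no match"
   class (`trainBinModel`, `classifyContigs`), and per-bin family profiles
   are computed over contigs ≥ 1 kb (`binProfiles`).
6. **Compare** — metagenome profiles are compared by Spearman correlation
   distance (1 − ρ) on GH families, with UPGMA clustering, classical MDS
   and biomass-enzyme scatter tables (`spearmanDistance`,
   `clusterProfiles`, `mdsEmbedding`, `pairwiseScatter`).

A first-class synthetic-data module simulates populations with controlled
G+C and 3-mer structure, family databases, planted genes, shredded contigs
with depths, and multi-metagenome panels with group structure (for
example "gut-like" communities lacking lignin-oxidase families versus
"free-living-like" communities carrying them), all with ground-truth
tables — so every stage is testable without downloads.

## A worked example

```r
library(MetaCAZ)

fdb   <- buildFamilyDB(c("GH13", "GH5", "LO2"), perFamily = 2, seed = 7)
spec  <- populationSpec("demo", gc = 0.5, genomeLen = 50000, seed = 3)
sim   <- simulatePopulationGenome(spec, list(c("GH13", 3), c("LO2", 2)),
                                  fdb$db, seed = 11)
shred <- shredToContigs(sim$seq, sim$genes, seed = 5)
hits  <- searchContigs(shred$contigs, fdb$db)
prof  <- profileMetagenome(shred$contigs, hits = hits, label = "demo")
prof
#> FamilyProfile 'demo': 2 families, 3.453e+05 depth-weighted bases
#>   top families (nt/Mnt): GH13=19804.3, LO2=8871.8
```

The three planted GH13 genes and two LO2 genes were recovered as
depth-weighted family abundances: GH13 carries ~19,804 and LO2 ~8,872
nucleotides per million depth-weighted nucleotides of this 50 kb synthetic
metagenome. On the same run, 96% of planted coding nucleotides were
covered by a correct-family run and no unplanted family received any
signal.

The full pipeline — simulate a two-group panel, search, profile, bin,
compare, evaluate against truth — is one call:

```r
res <- runEndToEnd(list(seed = 42), outdir = "run1")
res$report$groupSeparation
#> [1] "separated"
```

which writes profile/distance/MDS/scatter tables, bin assignments, a
Newick tree, the resolved configuration and a truth-evaluation report into
`run1/`, byte-identically reproducible from the seed.

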