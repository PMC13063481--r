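# trnacycle

Analysis of transfer-RNA gene repertoires and their regulation across the
starvation-induced social cycle of the amoeba *Dictyostelium discoideum* —
or any genome with a similarly restricted anticodon set.

## The scientific problem

Eukaryotic genomes typically carry hundreds of tRNA genes but lack genes
for many of the 61 possible anticodons. Translation still works because
wobble pairing at anticodon position 34 lets one tRNA read several codons:
G34 reads codons ending in U (G:U), U34 reads codons ending in G (U:G),
and inosine (deaminated A34) reads codons ending in C or A (I:C, I:A).
This package asks, for a given genome: which anticodons are encoded, which
missing anticodons can be compensated through wobble decoding, does codon
usage in coding sequences track the wobble-expanded repertoire rather than
the literal one, and how is the repertoire deployed across a developmental
cycle — which genes sit in open chromatin, and how do mature tRNA levels
shift between stages?

The central object is the **decoding potential graph**: a directed graph on
the 61 sense anticodons with an arc `a2 -> a1` (labelled G:U, U:G, I:C or
I:A) whenever `a2`, suitably modified at position 34, can read the cognate
codon of `a1`. For the standard code the graph has 60 arcs: 16 G:U, 14 U:G,
16 I:C and 14 I:A. Grouping tRNA gene copy numbers and codon usage by these
arcs restores the copy-number/usage correlation that collapses at the raw
anticodon (isoacceptor) level in wobble-reliant genomes.

Around the graph, the package provides the full analysis pipeline:

* **repertoire** — tRNAscan-SE tabular parsing, mature-sequence extraction
  (intron removal, strand-aware), clustering of identical mature sequences
  into isodecoders with artificial mapping references
  (10 nt upstream flank + mature sequence + `CCA`), repertoire summaries at
  gene/isodecoder/isoacceptor/isotype level, and a Monte-Carlo multivariate
  hypergeometric test for non-random isotype localization per chromosome.
* **codon usage** — in-frame codon counting over CDS FASTA and Pearson
  correlations (t-transform p-values) at isotype, isoacceptor, arc-grouped
  and per-wobble-label resolution.
* **accessibility** — a tRNA gene counts as transcriptionally available at
  a stage iff its span is *fully embedded* in a nucleosome-free-region
  (ATAC-seq) peak of that stage; genes are binned into constitutive /
  stage-specific / partial / never categories with upset-style
  union/intersection counts.
* **mature-tRNA quantification** — SAM-level re-application of the
  CCA-selective (LOTTE-seq-style) filters: a read counts only if it is
  (i) uniquely mapped (`NH:i:1`), (ii) starts after the artificial flank,
  (iii) ends in `CCA`, and (iv) its alignment reaches the reference 3' end;
  counts per isodecoder cluster aggregate exactly to isoacceptors and
  isotypes.
* **differential expression** — a lightweight TMM-normalized
  negative-binomial stage (exact-style conditional test, Holm correction,
  sign calls) for stage transitions at each equivalence level.
* **synthetic data** — seeded generators for every input (genome + gene
  table, CDS, per-stage peak BEDs, labelled SAM records, count matrices)
  with planted ground truth, so the whole pipeline is testable offline.

## Worked example

```r
library(trnacycle)

## the decoding potential graph of the standard code
g <- build_graph(existing = sense_anticodons())
print(g)
#> decoding potential graph: 61 anticodon vertices ( 61 existing / 0 missing ), 60 arcs
#> G:U I:A I:C U:G
#>  16  14  16  14

## a wobble-skewed synthetic genome: copies sit on compensating anticodons
cfg <- sim_config(seed = 1, wobble_skew = 1)
sg  <- synth_genome(cfg)
cl  <- cluster_isodecoders(sg$genes, sg$genome)
nrow(sg$genes); nrow(cl)
#> [1] 400
#> [1] 77

## codon usage correlates with the repertoire only through the graph
u <- count_codons(synth_cds(cfg, sg$truth$copy_number))
correlate_levels(u, sg$truth$copy_number)[1:3, ]
#>           level          r            p  n
#> 1       isotype  0.9734038 5.742561e-13 20
#> 2   isoacceptor -0.2102626 1.038498e-01 61
#> 3 graph_grouped  0.6118938 1.611637e-07 61

## CCA-selective read filtering against the cluster references
lt <- synth_lotte(cfg, cl)
v  <- validate_reads(parse_sam(lt$sam), cl)
sum(v$valid); nrow(v)
#> [1] 40067
#> [1] 50000
```

The correlation table is the package's core readout: at isotype level the
correlation is high, at raw isoacceptor level it collapses (many heavily
used codons have no cognate gene), and grouping by the arcs of the decoding
potential graph restores it — the signature of a genome that leans on
wobble decoding.

## Command line

A thin CLI over the same functions ships in `inst/cli/trnacycle.R`:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/trnacycle.R", package="trnacycle"))')
Rscript $CLI simulate all --seed 3 --out simdata
Rscript $CLI repertoire summarize --genes simdata/trnascan.txt --genome simdata/genome.fa
Rscript $CLI access classify --genes simdata/trnascan.txt \
    --stage vegetative=simdata/vegetative.bed --stage streaming=simdata/streaming.bed
Rscript $CLI lotte count --sam simdata/reads.sam --sample veg1 \
    --genes simdata/trnascan.txt --genome simdata/genome.fa --out counts.tsv
Rscript $CLI de run --counts simdata/counts.tsv --design design.tsv \
    --contrast vegetative:streaming --level cluster
```

See `vignettes/decoding-potential.Rmd` for the model, its assumptions, the
tunable parameters and the limits of what the synthetic world establishes.
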