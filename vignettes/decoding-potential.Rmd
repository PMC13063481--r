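---
title: "Wobble decoding, repertoire availability and tRNA expression: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wobble decoding, repertoire availability and tRNA expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trnacycle)
```

This vignette is the package's own account of its science: the models and
their assumptions, the parameters that matter, what the synthetic world
does and does not establish, and the places where the design was genuinely
open and a choice had to be made.

## 1. The decoding potential graph

### Model

Anticodons and codons are stored in the DNA alphabet, 5'→3'; an anticodon
is the reverse complement of its cognate codon, so the wobble position
(tRNA position 34) is the anticodon's *first* base and pairs the codon's
*third* base. Four non-Watson–Crick pairings at position 34 are modelled:

| label | anticodon base 34 | codon base 3 | target anticodon base 34 |
|-------|-------------------|--------------|--------------------------|
| G:U   | G                 | T (U)        | A                        |
| U:G   | T (U)             | G            | C                        |
| I:C   | A (read as inosine) | C          | G                        |
| I:A   | A (read as inosine) | A          | T                        |

Inosine arises by deamination of A34 and is represented by its genomic
precursor A — the convention of gene predictors and FASTA, and the reason
the I:C and I:A arcs of one source anticodon are later merged on demand:
they originate from the same physical molecule.

The graph's vertices are the 61 sense anticodons (anticodons of stop
codons are never vertices; UGA-mediated selenocysteine is excluded
throughout, because counting UGA as sense would contaminate codon usage
with genuine stop codons). An arc `a2 -> a1` with label `w` exists iff
`a2` and `a1` agree at positions 35–36 and their wobble bases match rule
`w` — direction is compensator → compensated. Arcs are a property of the
genetic code alone; a repertoire only flags vertices existing/missing.
For the standard code this yields 60 arcs: 16 G:U, 14 U:G, 16 I:C, 14 I:A
(every count verified in the test suite against an independent brute-force
enumerator over all ordered pairs and all four rules).

### Non-synonymy: structural vs realizable

Six arcs connect anticodons of different amino acids: `TAT -> CAT`
(Ile reading the Met codon AUG via U:G) and five I:A arcs whose *sources*
are the A34 anticodons of split codon boxes (`AAA, ACT, ATC, ATG, ATT`).
Those five anticodons are essentially never encoded in eukaryotic genomes
— inosine editing is confined to family boxes precisely because it would
otherwise cause misreading — so in any realistic repertoire the unique
non-synonymous replacement that can actually occur is Ile(TAT) decoding
the Met codon. `nonsynonymous_arcs()` therefore reports the structural
flag by default and offers `existing_only = TRUE` for the realizable
reading. We treat the structural count (6) and the realizable count (1,
under a repertoire lacking split-box A34 anticodons) as two different
statements and test both.

A related labelling wrinkle: under the anticodon-base-first convention
used here, the Ile→Met arc is a *U:G* arc (U34 paired with codon base G).
Texts that name the same arc "G:U" are using codon-base-first order for
that sentence; we follow the anticodon-first convention uniformly.

### Correlation analyses

`correlate_levels()` reports Pearson r with the usual t-transform p-value
(n−2 degrees of freedom) at four resolutions: isotype (20 amino acids;
selenocysteine is excluded by construction, so the isotype-level n is 20),
isoacceptor (all 61 sense codons, missing anticodons entering with copy
number 0), arc-grouped, and per-wobble-label. Correlations are computed on
raw counts by default — Pearson r is scale-invariant, so per-mille
normalization would change nothing — with an optional `log10(x+1)` switch
for display-scale parity. Three grouping modes are available
(`per_arc`, `merged_inosine`, `component`); none is asserted to be *the*
canonical one, per-arc is the default, and component mode is the one that
conserves global totals (each anticodon counted exactly once), which the
tests exploit.

## 2. Repertoire parsing, isodecoders, localization test

Coordinates are 1-based inclusive internally (the tRNAscan-SE dialect);
all BED I/O converts to 0-based half-open at the boundary. Minus-strand
genes arrive with begin > end and are normalized. Pseudogenes are kept in
gene-level counts and clustering (real gene tallies include them) but stay
flagged; genes with undetermined anticodons are excluded from
isoacceptor/isotype tallies.

Isodecoder clusters group genes with *identical* mature sequences
(introns excised, coding strand). Each cluster's mapping reference is
`flank(10 nt) + mature + CCA`, where the flank is taken 5' of the
cluster's *representative* on its coding strand ("upstream" is read
strand-aware). The representative is the lexicographically smallest
gene id — determinism in place of "an arbitrary gene". A flank running off
the contig edge is padded with N and warned about.

The chromosomal localization test asks whether a chromosome's isotype
composition could be a uniform draw without replacement from the
genome-wide pool. The statistic is the multivariate hypergeometric point
probability of the observed composition; the p-value is Monte-Carlo with
add-one correction, `p = (b+1)/(n_draws+1)` where `b` counts draws whose
point probability is at most the observed one. Ties count as extreme
(conservative). Draws use the sequential-conditional construction
(vectorized `rhyper` per isotype), which makes 999-draw tests on hundreds
of genomes cheap. Default `n_draws` is 10,000 and a seed is mandatory;
p-values are reported per chromosome without multiplicity correction
(a Holm option exists). Calibration is verified empirically: the type-I
error at α = 0.05 over 1,000 null genomes lies within [0.03, 0.07], and
on a 2×2 toy the Monte-Carlo p matches an exhaustive enumeration within
three standard errors.

## 3. Availability by full embedding

A gene is transcriptionally available at a stage iff some single peak of
that stage fully contains it: `peak.start <= gene.start0` and
`gene.end0 <= peak.end` after coordinate conversion, equality allowed at
both boundaries (an exactly coextensive peak counts). Partial overlap
never counts — the synthetic generator plants partial-overlap decoy peaks
specifically to trap classifiers that accept it. Strand is ignored
(chromatin accessibility is strandless) and peaks are not merged before
testing: embedding in any one peak suffices, which makes the classifier
order-independent whether or not replicate peaks were merged upstream.
Categories: constitutive (all stages), stage-specific (exactly one),
never (none), partial (the rest), with union/intersection counts per
stage combination.

## 4. Mature-tRNA read validation

The quantification stage consumes post-alignment SAM records against the
cluster references and re-applies the CCA-selection filters; mapping
itself (two-pass masked-genome routing) is external and out of scope. A
record is a valid mature-tRNA observation iff all four criteria hold:

1. *unique* — NH multiplicity 1 (absent NH tags are read as 1, with a
   warning);
2. *past_flank* — leftmost aligned base at `flank_len + 1` or later, read
   strictly: an alignment touching the flank at position `flank_len` fails;
3. *cca_end* — the stored read sequence ends in `CCA`; evaluated on the
   sequence as stored, not on the alignment, so a soft-clipped CCA fails
   criterion 4 instead;
4. *reaches_3prime* — `pos + span - 1` equals the reference length
   exactly; an alignment ending even one base inside the appended CCA
   fails (the stricter reading of "extends to the 3' end").

Verdicts name every failed criterion, the failure histogram is part of
the count object, and aggregation to isoacceptor/isotype is an exact
partition sum (column totals conserved). Reads of 8–21 nt and ≥ 22 nt are
routed short/long at the documented thresholds; < 8 nt are discarded.

## 5. The differential-expression stage

This stage is explicitly a lightweight approximation of a full
GLM package; numerical parity with any particular package is a non-goal —
directional agreement on synthetic truth is the contract. Design:

* **Normalization** — our own TMM implementation (30% M-trim, 5% A-trim,
  precision-weighted, factors anchored to geometric mean 1), checked in
  the tests against the reference implementation on composition-biased
  fixtures (agreement within 3%).
* **Dispersion** — method-of-moments per feature, pooled across the two
  groups, shrunk toward the across-feature mean with weight 0.7 (with
  three replicates per group the per-feature moment estimate is noise;
  the weight is configurable).
* **Test** — conditional on the total of the two groups' library-scaled
  sums, the NB probabilities of all splits are enumerated and the
  two-sided p is the mass of splits no more likely than the observed one
  (Poisson limit for dispersion → 0; normal fallback for totals beyond
  2·10^5). logFC uses a 0.5 prior count and is oriented so that a
  positive call means up-regulation across the transition A→B.
* **Decision** — Holm within each contrast × level family (no
  cross-contrast correction), call = sign(logFC) where adjusted p ≤ α
  (default 0.05). All-zero features get p = 1, call 0.

The aggregation-masking phenomenon is reproduced constructively: the
generator plants two up-regulated and one down-regulated isodecoder in a
single isoacceptor with magnitudes chosen so the group sum is flat; the
pipeline then calls all three at cluster level and nothing at isoacceptor
level.

## 6. The synthetic world, and what a green test establishes

Generator defaults are fixed once to mirror the scale of the real system:
6 chromosomes, 400 tRNA genes (mature 69–87 nt, gene spans ≤ 95 bp with
an intron inserted after the anticodon loop), ~10% new-isodecoder rate
(giving ≈ 75–95 isodecoders per 400 genes, matching the observed ratio),
AT-rich (77%) background sequence, 2,000 CDS, 50,000 reads with 5%
single-criterion failures of each kind, and a 60-feature count matrix with
3 replicates per stage, NB dispersion 0.05 and planted |log2FC| = 2.
Isotype sampling weights default to codon-box degeneracy. One master seed
fans out to per-generator substreams, so regenerating one stage never
perturbs another; every generator is byte-reproducible.

Two deliberately constructed regimes matter:

* **wobble_skew** — with `wobble_skew = 1`, anticodon choice is restricted
  to wobble-capable (compensating) anticodons and CDS codons are drawn
  proportional to the copies of the anticodons that *decode* them through
  the graph rather than their literal cognates. This guarantees, by
  construction, low isoacceptor-level and high arc-grouped correlation;
  the acceptance property asserts the ordering in ≥ 95 of 100 seeds.
* **planted localization skew** — the documented default planted effect is
  an 8× enrichment of one large isotype family (Leu) on one chromosome,
  at which the localization test's power is ≈ 1.0; a 5× effect at the
  default scale yields only ≈ 0.8 power under the omnibus multivariate
  statistic, which is worth knowing before applying the test to a
  6-chromosome genome.

What a green suite does **not** establish: the generators draw i.i.d.
bases (no sequence composition structure beyond AT content, no
modification-induced misincorporations, no sequencing error or quality
model), peaks are placed gene-centrically rather than from a fragment
model, CDS have no codon autocorrelation, and the count model is exactly
the NB the test assumes — so the DE power numbers are an upper bound on
real-data behaviour, and real-data quantities (gene counts, ATAC
availability fractions, expression contrasts) are not reproduced here at
all; they require external downloads and are outside the desk-scale test
surface.

## 7. Numerical details and degenerate inputs

* Zero-variance vectors make `pearson_with_p()` return a flagged NA
  result, not an error.
* Monte-Carlo tie handling uses a 1e-9 log-space tolerance when counting
  draws at least as extreme as observed.
* A single-isotype genome makes every chromosome's localization p exactly
  1, with a warning.
* Empty inputs (CDS stream, SAM, gene table) produce zero-valued objects
  with warnings rather than failures; malformed rows (tRNAscan, SAM,
  CIGAR) fail loudly with the offending line.
* All outputs are deterministically ordered (lexicographic vertices,
  arcs, clusters), so diffs between runs are meaningful.
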