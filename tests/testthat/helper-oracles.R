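# Independent oracles and small fixture builders. These deliberately do not
# reuse the package's construction code paths.

# brute-force decoding-graph enumerator: all ordered pairs of sense
# anticodons x the four pairing rules, written out long-hand
oracle_enumerate_arcs <- function() {
  gc1 <- Biostrings::GENETIC_CODE
  stops <- names(gc1)[gc1 == "*"]
  sense_codons <- setdiff(names(gc1), stops)
  rc <- function(x) chartr("ACGT", "TGCA",
                           vapply(strsplit(x, ""), function(ch)
                             paste(rev(ch), collapse = ""), character(1)))
  acs <- rc(sense_codons)
  rules <- data.frame(label = c("G:U", "U:G", "I:C", "I:A"),
                      s34 = c("G", "T", "A", "A"),
                      t34 = c("A", "C", "G", "T"), stringsAsFactors = FALSE)
  # exhaustive scan: every ordered anticodon pair under every rule
  grid <- expand.grid(source = acs, target = acs, rule = seq_len(4),
                      stringsAsFactors = FALSE)
  keep <- grid$source != grid$target &
    substr(grid$source, 2, 3) == substr(grid$target, 2, 3) &
    substr(grid$source, 1, 1) == rules$s34[grid$rule] &
    substr(grid$target, 1, 1) == rules$t34[grid$rule]
  hit <- grid[keep, , drop = FALSE]
  out <- data.frame(source = hit$source, target = hit$target,
                    label = rules$label[hit$rule],
                    nonsynonymous = unname(gc1[rc(hit$source)] != gc1[rc(hit$target)]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$source, out$target, out$label), ]
  rownames(out) <- NULL
  out
}

# enumeration oracle for compensated_missing on an arbitrary repertoire
oracle_compensated <- function(existing, labels) {
  arcs <- oracle_enumerate_arcs()
  acs <- sort(unique(c(arcs$source, arcs$target)))
  missing <- setdiff(acs, existing)
  hit <- arcs$label %in% labels & arcs$source %in% existing &
    arcs$target %in% missing
  sort(unique(arcs$target[hit]))
}

# exact two-isotype enrichment p-value for one chromosome: enumerate every
# possible composition, hypergeometric pmf, sum of outcomes at most as
# probable as the observed one
oracle_exact_2iso_p <- function(obs_a, n_c, K_a, K_b) {
  ks <- max(0, n_c - K_b):min(n_c, K_a)
  pmf <- stats::dhyper(ks, K_a, K_b, n_c)
  p_obs <- stats::dhyper(obs_a, K_a, K_b, n_c)
  sum(pmf[pmf <= p_obs + 1e-12])
}

# naive all-pairs full-embedding scan
oracle_embed <- function(genes, peaks) {
  vapply(seq_len(nrow(genes)), function(i) {
    any(peaks$chrom == genes$chrom[i] &
          peaks$start <= genes$start[i] - 1L &
          genes$end[i] <= peaks$end)
  }, logical(1))
}

# a tiny hand-built genome with planted tRNA genes; everything derivable by
# hand from the construction
tiny_genome_fixture <- function() {
  set.seed(424242)
  bases <- c("A", "C", "G", "T")
  rand <- function(n) paste(sample(bases, n, replace = TRUE), collapse = "")
  mat1 <- rand(72)                       # shared by gene1 (+) and gene2 (-)
  mat2 <- rand(74)                       # gene3, with a 12-nt intron
  intron <- rand(12)
  gene3_genomic <- paste0(substr(mat2, 1, 37), intron, substr(mat2, 38, 74))
  chrA <- paste0(rand(100), mat1, rand(100), revcomp(mat1), rand(100))
  chrB <- paste0(rand(60), gene3_genomic, rand(80))
  genome <- Biostrings::DNAStringSet(c(chrA = chrA, chrB = chrB))
  genes <- data.frame(
    gene_id = c("chrA.trna1", "chrA.trna2", "chrB.trna1"),
    chrom = c("chrA", "chrA", "chrB"),
    start = c(101L, 273L, 61L),
    end = c(172L, 344L, 146L),
    strand = c("+", "-", "+"),
    isotype = c("Ala", "Ala", "Gly"),
    anticodon = c("AGC", "AGC", "GCC"),
    intron_start = c(NA, NA, 98L),
    intron_end = c(NA, NA, 109L),
    pseudogene = c(FALSE, FALSE, FALSE),
    score = c(70.1, 70.1, 55.3),
    stringsAsFactors = FALSE)
  class(genes) <- c("trna_genes", "data.frame")
  list(genome = genome, genes = genes, mature = c(mat1, mat1, mat2))
}

# tRNAscan-SE tabular fixture: 5 rows, one pseudogene, one intron, one
# minus-strand record (begin > end)
trnascan_fixture_lines <- function() {
  c("Sequence\t\ttRNA\tBounds\ttRNA\tAnti\tIntron Bounds\t\tInf\t",
    "Name    \ttRNA #\tBegin\tEnd\tType\tCodon\tBegin\tEnd\tScore\tNote",
    "--------\t------\t-----\t----\t----\t-----\t-----\t----\t------\t----",
    "chr1\t1\t1000\t1071\tAla\tAGC\t0\t0\t72.5\t",
    "chr1\t2\t2085\t2000\tSer\tTGA\t0\t0\t61.0\tpseudo",
    "chr2\t1\t500\t585\tLeu\tCAA\t537\t548\t66.2\t",
    "chr2\t2\t900\t971\tGly\tGCC\t0\t0\t70.0\t",
    "chr3\t1\t150\t77\tVal\tTAC\t0\t0\t68.8\t")
}
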