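small_cfg <- function(seed, ...) {
  sim_config(seed = seed, n_genes = 80, n_chroms = 3,
             chrom_lengths = rep(50000L, 3), n_cds = 150, n_reads = 1500, ...)
}

test_that("generators are pure functions of (cfg, seed)", {
  cfg <- small_cfg(5551)
  a <- synth_genome(cfg); b <- synth_genome(cfg)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$genes, b$genes)
  expect_identical(synth_cds(cfg, a$truth$copy_number),
                   synth_cds(cfg, a$truth$copy_number))
  cl <- cluster_isodecoders(a$genes, a$genome)
  expect_identical(synth_lotte(cfg, cl)$records, synth_lotte(cfg, cl)$records)
  expect_identical(synth_peaks(cfg, a$genes)$truth, synth_peaks(cfg, a$genes)$truth)
  expect_identical(synth_counts(cfg)$counts, synth_counts(cfg)$counts)
  # substreams: regenerating one stage does not perturb another
  cfg2 <- small_cfg(5551)
  synth_counts(cfg2)
  expect_identical(as.character(synth_genome(cfg2)$genome),
                   as.character(a$genome))
  expect_error(sim_config(), "seed")
})

test_that("synth_genome respects its structural constraints", {
  cfg <- small_cfg(5552, intron_prob = 0.3)
  sg <- synth_genome(cfg)
  g <- sg$genes
  # non-overlapping placement per chromosome
  for (ch in unique(g$chrom)) {
    sub <- g[g$chrom == ch, ]
    sub <- sub[order(sub$start), ]
    if (nrow(sub) > 1) expect_true(all(sub$start[-1] > sub$end[-nrow(sub)]))
  }
  # length windows: mature 69-87, gene span at most 95
  mat_len <- nchar(sg$truth$mature_seq)
  expect_true(all(mat_len >= 69 & mat_len <= 87))
  expect_true(all(g$end - g$start + 1 <= 95))
  # introns inside their gene, consistent with the length bookkeeping
  wi <- !is.na(g$intron_start)
  expect_true(any(wi))
  expect_true(all(g$intron_start[wi] >= g$start[wi] &
                    g$intron_end[wi] <= g$end[wi]))
  # extraction of every gene reproduces the truth sequences
  mat <- vapply(seq_len(nrow(g)), function(i) extract_mature(g[i, ], sg$genome),
                character(1))
  expect_identical(mat, sg$truth$mature_seq)
  # copy-number truth matches the gene table
  expect_equal(sg$truth$copy_number,
               stats::setNames(as.numeric(table(g$anticodon)),
                               names(table(g$anticodon))))
  # impossible placement is rejected with advice
  expect_error(synth_genome(sim_config(seed = 1, n_genes = 500, n_chroms = 1,
                                       chrom_lengths = 10000L)),
               "chrom_lengths")
})

test_that("null genomes give uniform localization p-values, skewed ones do not", {
  cfg <- small_cfg(5553)
  g <- synth_gene_table(cfg)
  res <- chrom_isotype_test(g, n_draws = 999, seed = 1)
  expect_true(all(res$p_value > 0 & res$p_value <= 1))
  # moderate sample: fraction of null p <= 0.1 should be loosely near 0.1
  ps <- unlist(lapply(1:30, function(r) {
    chrom_isotype_test(synth_gene_table(small_cfg(6000 + r)),
                       n_draws = 499, seed = r)$p_value
  }))
  expect_gt(mean(ps <= 0.1), 0.02)
  expect_lt(mean(ps <= 0.1), 0.25)
})

test_that("synth_cds emits clean CDS and the wobble-skew construction works", {
  cfg <- small_cfg(5554)
  sg <- synth_gene_table(cfg)
  cn <- stats::setNames(as.numeric(table(sg$anticodon)),
                        names(table(sg$anticodon)))
  cds <- synth_cds(cfg, cn)
  w <- Biostrings::width(cds)
  expect_true(all(w %% 3 == 0))
  # no internal stops in frame
  stops <- c("TAA", "TAG", "TGA")
  internal <- vapply(as.character(cds), function(s) {
    cods <- substring(s, seq(1, nchar(s) - 5, 3), seq(3, nchar(s) - 3, 3))
    any(cods %in% stops)
  }, logical(1))
  expect_false(any(internal))
  # plain mode: isoacceptor correlation is nearly perfect
  u <- count_codons(cds)
  r_plain <- correlate_levels(u, cn)
  expect_gte(r_plain$r[r_plain$level == "isoacceptor"], 0.95)
  # wobble-skew mode: grouped correlation beats isoacceptor correlation
  cfgw <- small_cfg(5554, wobble_skew = 1)
  gw <- synth_gene_table(cfgw)
  cnw <- stats::setNames(as.numeric(table(gw$anticodon)),
                         names(table(gw$anticodon)))
  uw <- count_codons(synth_cds(cfgw, cnw))
  rw <- correlate_levels(uw, cnw)
  expect_gt(rw$r[rw$level == "graph_grouped"],
            rw$r[rw$level == "isoacceptor"])
})

test_that("synth_peaks plants recoverable categories with decoys", {
  cfg <- small_cfg(5555, decoy_prob = 0.5)
  sg <- synth_genome(cfg)
  pk <- synth_peaks(cfg, sg$genes)
  m <- suppressWarnings(embed_classify(sg$genes, pk$peaks))
  expect_equal(m$available, pk$available)
  s <- availability_summary(m)
  expect_equal(unname(s$category), unname(pk$truth$category))
  # decoys exist (peaks overlapping an unavailable gene partially)
  decoys <- unlist(lapply(pk$peaks, function(p) grep("decoy", p$name)))
  expect_gt(length(decoys), 0)
  # degenerate coverage configs
  all_on <- small_cfg(5555, category_probs = c(constitutive = 1,
                                               stage_specific = 0,
                                               partial = 0, never = 0))
  pk_on <- synth_peaks(all_on, sg$genes)
  expect_true(all(pk_on$available))
  all_off <- small_cfg(5555, category_probs = c(constitutive = 0,
                                                stage_specific = 0,
                                                partial = 0, never = 1),
                       decoy_prob = 0)
  pk_off <- synth_peaks(all_off, sg$genes)
  expect_false(any(pk_off$available))
})

test_that("synth_lotte labels are exhaustive and respect read-length routing", {
  cfg <- small_cfg(5556)
  sg <- synth_genome(cfg)
  cl <- cluster_isodecoders(sg$genes, sg$genome)
  lt <- synth_lotte(cfg, cl)
  expect_setequal(unique(lt$truth$label),
                  c("valid", "unique", "past_flank", "cca_end", "reaches_3prime"))
  expect_true(all(nchar(lt$records$read_seq) >= 8))
  # zero failure fractions -> all reads valid
  cfg0 <- small_cfg(5556, fail_fracs = c(unique = 0, past_flank = 0,
                                         cca_end = 0, reaches_3prime = 0))
  lt0 <- synth_lotte(cfg0, cl)
  expect_true(all(lt0$truth$label == "valid"))
  v0 <- validate_reads(lt0$records, cl)
  expect_true(all(v0$valid))
  # SAM round trip preserves the verdicts
  v_df <- validate_reads(lt$records, cl)
  v_sam <- validate_reads(parse_sam(lt$sam), cl)
  expect_equal(v_sam$valid, v_df$valid)
})

test_that("synth_counts plants effects and the opposite-sign motif", {
  cfg <- sim_config(seed = 5557)
  sc <- synth_counts(cfg)
  expect_equal(dim(sc$counts), c(60L, 9L))
  expect_identical(sort(unique(unname(sc$stages))),
                   sort(unique(cfg$count_stages)))
  motif <- sc$truth[sc$truth$motif, ]
  expect_equal(nrow(motif), 3)
  expect_equal(sort(motif$log2fc), c(-2, 2, 2))
  # the motif trio shares one isoacceptor
  fi <- sc$feature_info
  expect_equal(length(unique(fi$isoacceptor[fi$feature %in% motif$feature])), 1L)
  # group sum is approximately conserved across the first transition
  mu_before <- rowMeans(sc$counts[motif$feature, sc$stages == "vegetative"])
  mu_after <- rowMeans(sc$counts[motif$feature, sc$stages == "streaming"])
  expect_lt(abs(log2(sum(mu_after) / sum(mu_before))), 0.6)
})
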