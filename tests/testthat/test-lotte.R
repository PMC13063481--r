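test_that("mask_genome hard-masks exactly the gene intervals, idempotently", {
  fx <- tiny_genome_fixture()
  masked <- mask_genome(fx$genome, fx$genes)
  # masked intervals are all N, of the right length
  g1 <- fx$genes[1, ]
  expect_equal(as.character(Biostrings::subseq(masked[["chrA"]], g1$start, g1$end)),
               strrep("N", g1$end - g1$start + 1))
  # everything else byte-identical
  expect_equal(as.character(Biostrings::subseq(masked[["chrA"]], 1, 100)),
               as.character(Biostrings::subseq(fx$genome[["chrA"]], 1, 100)))
  # idempotence and the no-gene identity
  expect_equal(as.character(mask_genome(masked, fx$genes)), as.character(masked))
  expect_equal(as.character(mask_genome(fx$genome, fx$genes[0, ])),
               as.character(fx$genome))
  oob <- fx$genes[1, ]; oob$end <- 10 ^ 6L
  expect_error(mask_genome(fx$genome, oob), "out of bounds")
})

test_that("split_by_length partitions at the 8/22 thresholds", {
  reads <- vapply(c(7, 8, 21, 22, 40), function(n) strrep("A", n), character(1))
  sp <- split_by_length(reads)
  expect_equal(sp$counts, c(short = 2L, long = 2L, discarded = 1L))
  expect_setequal(nchar(sp$short), c(8, 21))
  expect_setequal(nchar(sp$long), c(22, 40))
  expect_equal(nchar(sp$discarded), 7)
  expect_equal(sum(sp$counts), length(reads))
  sp0 <- split_by_length(character(0))
  expect_true(all(sp0$counts == 0))
})

# a small fixed cluster set for the validation tests
fixture_clusters <- function() {
  set.seed(313)
  mat <- vapply(1:3, function(i)
    paste(sample(c("A", "C", "G", "T"), 72, replace = TRUE), collapse = ""),
    character(1))
  data.frame(cluster_id = paste0("cluster", 1:3),
             mature_seq = mat,
             members = paste0("g", 1:3), n_members = 1L,
             representative = paste0("g", 1:3),
             isotype = c("Ala", "Ala", "Gly"),
             anticodon = c("AGC", "CGC", "GCC"),
             reference_seq = paste0(strrep("T", 10), mat, "CCA"),
             flank_len = 10L, stringsAsFactors = FALSE)
}

test_that("validate_reads applies the four criteria with exact boundaries", {
  cl <- fixture_clusters()
  ref_len <- nchar(cl$reference_seq[1])  # 85
  mk <- function(pos, span, seq, mult = 1L) {
    data.frame(query = "r", ref = "cluster1", pos = pos,
               cigar = paste0(span, "M"), aln_span = span, read_seq = seq,
               multiplicity = mult, mapped = TRUE, stringsAsFactors = FALSE)
  }
  tail_seq <- function(pos) substr(cl$reference_seq[1], pos, ref_len)
  # all-pass construction
  ok <- validate_reads(mk(11L, ref_len - 10L, tail_seq(11L)), cl)
  expect_true(ok$valid)
  expect_equal(ok$failed, "")
  # multiplicity 2 fails exactly criterion (i)
  dup <- validate_reads(mk(11L, ref_len - 10L, tail_seq(11L), mult = 2L), cl)
  expect_false(dup$valid)
  expect_equal(dup$failed, "unique")
  # pos = flank_len rejected, pos = flank_len + 1 accepted
  at_flank <- validate_reads(mk(10L, ref_len - 9L, tail_seq(10L)), cl)
  expect_false(at_flank$valid)
  expect_equal(at_flank$failed, "past_flank")
  past <- validate_reads(mk(11L, ref_len - 10L, tail_seq(11L)), cl)
  expect_true(past$valid)
  # non-CCA end fails (iii) only
  s <- tail_seq(11L); substr(s, nchar(s), nchar(s)) <- "G"
  no_cca <- validate_reads(mk(11L, ref_len - 10L, s), cl)
  expect_equal(no_cca$failed, "cca_end")
  # alignment stopping one base short fails (iv) only (read still ends CCA)
  s2 <- substr(cl$reference_seq[1], 11, ref_len - 1)
  substr(s2, nchar(s2) - 2, nchar(s2)) <- "CCA"
  short3p <- validate_reads(mk(11L, ref_len - 11L, s2), cl)
  expect_equal(short3p$failed, "reaches_3prime")
  # unknown cluster and unmapped records are rejected
  bad <- mk(11L, 10L, "ACGTACGCCA"); bad$ref <- "nope"
  expect_error(validate_reads(bad, cl), "unknown cluster")
  um <- mk(11L, 10L, "ACGTACGCCA"); um$mapped <- FALSE
  expect_error(validate_reads(um, cl), "unmapped")
})

test_that("SAM parsing extracts NH, CIGAR span and flags", {
  sam <- c("@HD\tVN:1.6",
           "@SQ\tSN:cluster1\tLN:85",
           "r1\t0\tcluster1\t11\t255\t75M\t*\t0\t0\tACGT\t*\tNH:i:1",
           "r2\t0\tcluster1\t5\t255\t10M2D65M\t*\t0\t0\tACGT\t*\tNH:i:3",
           "r3\t4\t*\t0\t255\t*\t*\t0\t0\tACGT\t*\tNH:i:1",
           "r4\t0\tcluster1\t3\t255\t5S70M\t*\t0\t0\tACGT\t*")
  expect_warning(rec <- parse_sam(sam), "NH tag")
  expect_equal(nrow(rec), 3)  # unmapped r3 dropped
  expect_equal(rec$multiplicity, c(1L, 3L, 1L))
  expect_equal(rec$aln_span, c(75L, 77L, 70L))  # D consumes, S does not
  rec2 <- suppressWarnings(parse_sam(sam, keep_unmapped = TRUE))
  expect_equal(nrow(rec2), 4)
  expect_false(rec2$mapped[rec2$query == "r3"])
  expect_error(parse_sam("r5\t0\tcluster1\t1\t255\t10M"), "malformed SAM")
})

test_that("count_clusters counts valid reads and is linear", {
  cfg <- sim_config(seed = 17, n_reads = 500)
  cl <- fixture_clusters()
  lt <- synth_lotte(cfg, cl)
  n_valid <- sum(lt$truth$label == "valid")
  cm <- count_clusters(list(s1 = lt$sam), cl)
  expect_equal(sum(cm$counts), n_valid)
  # per-cluster totals match the truth labels
  valid_by_cluster <- table(factor(lt$truth$cluster[lt$truth$label == "valid"],
                                   levels = cl$cluster_id))
  expect_equal(unname(cm$counts[, "s1"]), as.integer(valid_by_cluster))
  # failure histogram matches truth
  fr <- cm$filter_report
  for (crit in c("unique", "past_flank", "cca_end", "reaches_3prime")) {
    expect_equal(fr$n_failed[fr$criterion == crit],
                 sum(lt$truth$label == crit), info = crit)
  }
  # duplicated stream doubles every count
  cm2 <- count_clusters(list(s1 = c(lt$sam, lt$sam[!startsWith(lt$sam, "@")])), cl)
  expect_equal(cm2$counts, cm$counts * 2L)
  # empty SAM -> zero matrix
  cm0 <- count_clusters(list(s1 = "@HD\tVN:1.6"), cl)
  expect_true(all(cm0$counts == 0L))
})

test_that("aggregation conserves totals through every level", {
  cfg <- sim_config(seed = 19, n_reads = 800)
  cl <- fixture_clusters()
  lt <- synth_lotte(cfg, cl)
  cm <- count_clusters(list(a = lt$sam, b = lt$sam), cl)
  acc <- aggregate_counts(cm, "isoacceptor")
  iso <- aggregate_counts(cm, "isotype")
  expect_equal(colSums(acc$counts), colSums(cm$counts))
  expect_equal(colSums(iso$counts), colSums(cm$counts))
  # 2 Ala clusters with different anticodons stay separate isoacceptors
  expect_equal(nrow(acc$counts), 3L)
  expect_equal(nrow(iso$counts), 2L)
  # 3 clusters of one anticodon sum to the isoacceptor count
  g <- stats::setNames(rep("acc1", 3), paste0("cluster", 1:3))
  one <- aggregate_counts(cm$counts, "isoacceptor", grouping = g)
  expect_equal(unname(one$counts["acc1", ]), unname(colSums(cm$counts)))
  # identity when each cluster is its own group
  idg <- stats::setNames(paste0("cluster", 1:3), paste0("cluster", 1:3))
  idm <- aggregate_counts(cm$counts, "isoacceptor", grouping = idg)
  expect_equal(idm$counts[paste0("cluster", 1:3), ], cm$counts)
  # unmapped feature rejected
  expect_error(aggregate_counts(cm$counts, "isotype",
                                grouping = c(cluster1 = "x")), "cover")
})
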