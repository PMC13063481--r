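test_that("genetic code and anticodon algebra are involutive", {
  code <- standard_genetic_code()
  expect_length(code$sense_codons, 61)
  expect_setequal(code$stop_codons, c("TAA", "TAG", "TGA"))
  expect_false("Sec" %in% code$table)  # UGA stays a stop

  acs <- sense_anticodons(code)
  expect_length(acs, 61)
  # cognate_codon(anticodon(c)) == c for every sense codon
  expect_setequal(anticodon_to_codon(codon_to_anticodon(code$sense_codons)),
                  code$sense_codons)
  # anticodons of stop codons are never sense anticodons
  expect_length(intersect(acs, c("TTA", "CTA", "TCA")), 0)
})

test_that("build_graph equals the brute-force enumerator on the full code", {
  g <- build_graph()
  oracle <- oracle_enumerate_arcs()
  expect_equal(nrow(g$vertices), 61)
  got <- g$arcs
  rownames(got) <- rownames(oracle) <- NULL
  expect_equal(got, oracle)
  # frozen census, computed by the oracle
  expect_equal(as.vector(table(g$arcs$label)[c("G:U", "U:G", "I:C", "I:A")]),
               c(16L, 14L, 16L, 14L))
  expect_equal(nrow(g$arcs), 60)
})

test_that("arc structure follows the wobble rules", {
  g <- build_graph()
  rules <- wobble_rules()
  for (i in seq_len(nrow(rules))) {
    sub <- g$arcs[g$arcs$label == rules$label[i], ]
    expect_true(all(substr(sub$source, 1, 1) == rules$source_wobble[i]))
    expect_true(all(substr(sub$target, 1, 1) == rules$target_wobble[i]))
  }
  expect_true(all(substr(g$arcs$source, 2, 3) == substr(g$arcs$target, 2, 3)))
  # no arc touches a stop-codon anticodon
  expect_length(intersect(c(g$arcs$source, g$arcs$target),
                          c("TTA", "CTA", "TCA")), 0)
  # arc set does not depend on the existing/missing flags
  g2 <- build_graph(existing = c("GTT", "AGC", "TAT"))
  expect_equal(g$arcs, g2$arcs)
})

test_that("build_graph matches the enumerator on random sub-repertoires", {
  acs <- sense_anticodons()
  set.seed(11)
  for (rep in 1:50) {
    existing <- sample(acs, sample(5:45, 1))
    g <- build_graph(existing)
    expect_equal(sort(g$vertices$anticodon[g$vertices$existing]),
                 sort(existing))
    expect_equal(g$arcs, oracle_enumerate_arcs())
  }
})

test_that("build_graph rejects non-sense anticodons by name", {
  expect_error(build_graph(existing = c("AGC", "TCA")), "TCA")
  expect_error(build_graph(existing = "NNN"), "NNN")
})

test_that("nonsynonymous arcs match the oracle; TAT->CAT is the unique one
           realizable without split-box A34 anticodons", {
  g <- build_graph(existing = sense_anticodons())
  ns <- nonsynonymous_arcs(g)
  oracle <- oracle_enumerate_arcs()
  expect_equal(ns[c("source", "target", "label")],
               oracle[oracle$nonsynonymous, c("source", "target", "label")],
               ignore_attr = TRUE)
  # structurally: TAT->CAT (U:G) plus five I:A arcs from split-box A34 sources
  expect_equal(sum(ns$label != "I:A"), 1L)
  expect_equal(ns[ns$label != "I:A", c("source", "target")],
               data.frame(source = "TAT", target = "CAT"), ignore_attr = TRUE)
  expect_setequal(ns$source[ns$label == "I:A"],
                  c("AAA", "ACT", "ATC", "ATG", "ATT"))
  # in a repertoire without split-box A34 anticodons (the eukaryotic norm),
  # the only realizable non-synonymous replacement is Ile(TAT) -> Met(CAT)
  rep_no_a34_split <- setdiff(sense_anticodons(),
                              c("AAA", "ACT", "ATC", "ATG", "ATT"))
  g2 <- build_graph(existing = rep_no_a34_split)
  ns2 <- nonsynonymous_arcs(g2, existing_only = TRUE)
  expect_equal(nrow(ns2), 1L)
  expect_equal(ns2$source, "TAT")
  expect_equal(ns2$target, "CAT")
})

test_that("arcs within four-fold family boxes are synonymous", {
  g <- build_graph()
  fam <- g$vertices$anticodon[g$vertices$isotype %in% c("Ala", "Gly")]
  sub <- g$arcs[g$arcs$source %in% fam & g$arcs$target %in% fam, ]
  expect_gt(nrow(sub), 0)
  expect_false(any(sub$nonsynonymous))
})

test_that("compensated_missing follows the worked example and the oracle", {
  # all existing -> nothing missing to compensate
  g_all <- build_graph(existing = sense_anticodons())
  expect_length(compensated_missing(g_all), 0)
  # GTT compensates ATT through G:U
  g1 <- build_graph(existing = "GTT")
  expect_equal(compensated_missing(g1, "G:U"), "ATT")
  # synthetic repertoires against the enumeration oracle
  set.seed(21)
  for (rep in 1:20) {
    existing <- sample(sense_anticodons(), 10)
    labels <- sample(wobble_rules()$label, sample(1:4, 1))
    g <- build_graph(existing)
    expect_equal(compensated_missing(g, labels),
                 oracle_compensated(existing, labels))
  }
  expect_error(compensated_missing(g1, "X:Y"), "unknown")
})

test_that("group_by_arcs sums copies and usage as specified", {
  usage <- stats::setNames(rep(0, 61), standard_genetic_code()$sense_codons)
  g <- build_graph()
  # two-vertex toy: GTT(5 copies) -> ATT(0); usages AAC=10, AAT=90
  cn <- c(GTT = 5)
  usage["AAC"] <- 10; usage["AAT"] <- 90
  per_arc <- group_by_arcs(g, cn, usage, mode = "per_arc")
  row <- per_arc[per_arc$group_id == "GTT>ATT", ]
  expect_equal(row$copies, 5)
  expect_equal(row$usage, 100)
  # merged inosine: source AAT has I:C arc to GAT and I:A arc to TAT
  cn2 <- c(AAT = 7, GAT = 2, TAT = 3)
  usage2 <- usage; usage2[] <- 0
  usage2[anticodon_to_codon(c("AAT", "GAT", "TAT"))] <- c(11, 13, 17)
  merged <- group_by_arcs(g, cn2, usage2, mode = "merged_inosine")
  mrow <- merged[grepl("^AAT>", merged$group_id), ]
  expect_equal(nrow(mrow), 1L)
  expect_equal(mrow$copies, 7 + 2 + 3)
  expect_equal(mrow$usage, 11 + 13 + 17)
  expect_equal(mrow$label, "I:A/I:C")
  # component mode conserves totals
  set.seed(31)
  cn3 <- stats::setNames(rpois(61, 4), sense_anticodons())
  usage3 <- stats::setNames(rpois(61, 50), standard_genetic_code()$sense_codons)
  comp <- group_by_arcs(g, cn3, usage3, mode = "component")
  expect_equal(sum(comp$copies), sum(cn3))
  expect_equal(sum(comp$usage), sum(usage3))
  expect_error(group_by_arcs(g, c(GTT = -1), usage3), "negative")
})

test_that("group_by_arcs on an arc-free graph is the identity mapping", {
  # a repertoire-independent way to get singletons: restrict attention to
  # the rows labelled "none" never appearing when arcs touch all vertices
  g <- build_graph()
  touched <- unique(c(g$arcs$source, g$arcs$target))
  singletons <- setdiff(g$vertices$anticodon, touched)
  cn <- stats::setNames(rep(1, 61), sense_anticodons())
  usage <- stats::setNames(rep(2, 61), standard_genetic_code()$sense_codons)
  per_arc <- group_by_arcs(g, cn, usage, mode = "per_arc")
  none_rows <- per_arc[per_arc$label == "none", ]
  expect_setequal(none_rows$group_id, singletons)
  expect_true(all(none_rows$copies == 1))
  expect_true(all(none_rows$usage == 2))
})

test_that("pearson_with_p matches the t-transform and flags degeneracy", {
  x <- c(1, 2, 3, 4); y <- c(1, 3, 2, 4)
  res <- pearson_with_p(x, y)
  ct <- stats::cor.test(x, y)  # independent route to the same t transform
  expect_equal(res$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(res$p, ct$p.value, tolerance = 1e-12)
  expect_equal(res$n, 4L)
  # perfect linear dependence
  lin <- pearson_with_p(1:10, 2 * (1:10) + 1)
  expect_equal(lin$r, 1)
  expect_equal(lin$p, 0)
  expect_equal(pearson_with_p(1:10, -(1:10))$r, -1)
  # zero variance is flagged, not thrown
  flat <- pearson_with_p(rep(1, 5), 1:5)
  expect_true(flat$degenerate)
  expect_true(is.na(flat$r))
  expect_error(pearson_with_p(1:3, 1:4), "equal length")
  expect_error(pearson_with_p(1:2, 2:3), "at least 3")
})

test_that("edge-list writer emits the documented columns", {
  g <- build_graph(existing = "GTT")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(g, f)
  d <- utils::read.delim(f)
  expect_equal(names(d), c("source", "target", "label", "nonsynonymous"))
  expect_equal(nrow(d), 60)
  expect_true(all(d$nonsynonymous %in% 0:1))
})
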