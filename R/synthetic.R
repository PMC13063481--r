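#' Configuration for the synthetic-data generators
#'
#' Bundles every knob of the simulators with defaults chosen once to mirror
#' the scale of the real system: a 6-chromosome nuclear genome bearing ~400
#' tRNA genes (mature lengths 69-87 nt, gene spans up to 95 bp with an
#' intron), ~2,000 coding sequences, 50,000 mature-tRNA reads and a
#' 60-feature count matrix with 3 replicates per stage. All generators are
#' pure functions of this configuration: the single \code{seed} fans out to
#' per-generator substreams so each stage can be regenerated independently.
#'
#' @param seed mandatory integer seed.
#' @param n_chroms,chrom_lengths chromosome number and lengths (bp).
#' @param n_genes number of tRNA genes.
#' @param isotype_weights named sampling weights per isotype; default
#'   proportional to each amino acid's codon-box degeneracy.
#' @param chrom_skew optional list chrom -> named multiplier vector
#'   (isotype -> factor) planting chromosomal isotype enrichment; NULL = null
#'   model.
#' @param wobble_skew in [0,1]: fraction of anticodon choices forced onto
#'   wobble-capable (compensating) anticodons; 0 = uniform within isotype.
#' @param mature_len_range mature tRNA length window (nt).
#' @param intron_prob,intron_len_range per-gene intron probability and
#'   length range (gene span capped at \code{max_gene_len}).
#' @param max_gene_len maximal gene span including intron (bp).
#' @param pseudogene_fraction fraction of genes flagged as pseudogenes.
#' @param new_isodecoder_prob probability that a gene founds a new isodecoder
#'   rather than reusing an existing mature sequence of its isoacceptor.
#' @param stages ATAC stage labels, in cycle order.
#' @param category_probs probabilities of the four availability categories.
#' @param decoy_prob probability of a partial-overlap decoy peak at an
#'   unavailable (gene, stage) pair.
#' @param n_cds,cds_len_range CDS count and length range (codons, excluding
#'   start/stop).
#' @param n_reads total mature-tRNA reads.
#' @param fail_fracs named fractions of reads failing each single criterion
#'   (unique, past_flank, cca_end, reaches_3prime); remainder is valid.
#' @param short_frac fraction of valid reads routed as short (8-21 nt).
#' @param count_stages stage labels of the count matrix.
#' @param n_features,n_reps,nb_dispersion count-matrix scale and NB
#'   dispersion.
#' @param base_mean_meanlog,base_mean_sdlog lognormal baseline feature means.
#' @param planted_lfc absolute planted log2 fold change for DE features.
#' @param n_de_per_transition planted up- and down-regulated features per
#'   transition (each).
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(seed,
                       n_chroms = 6L,
                       chrom_lengths = rep(150000L, n_chroms),
                       n_genes = 400L,
                       isotype_weights = NULL,
                       chrom_skew = NULL,
                       wobble_skew = 0,
                       mature_len_range = c(69L, 87L),
                       intron_prob = 0.08,
                       intron_len_range = c(8L, 26L),
                       max_gene_len = 95L,
                       pseudogene_fraction = 0.0075,
                       new_isodecoder_prob = 0.1,
                       stages = c("vegetative", "streaming", "mound", "fruiting"),
                       category_probs = c(constitutive = 0.85,
                                          stage_specific = 0.02,
                                          partial = 0.08, never = 0.05),
                       decoy_prob = 0.3,
                       n_cds = 2000L,
                       cds_len_range = c(100L, 400L),
                       n_reads = 50000L,
                       fail_fracs = c(unique = 0.05, past_flank = 0.05,
                                      cca_end = 0.05, reaches_3prime = 0.05),
                       short_frac = 0.3,
                       count_stages = c("vegetative", "streaming", "fruiting"),
                       n_features = 60L,
                       n_reps = 3L,
                       nb_dispersion = 0.05,
                       base_mean_meanlog = log(200),
                       base_mean_sdlog = 0.7,
                       planted_lfc = 2,
                       n_de_per_transition = 5L) {
  if (missing(seed)) stop("sim_config requires a seed")
  stopifnot(wobble_skew >= 0, wobble_skew <= 1,
            all(fail_fracs >= 0), sum(fail_fracs) <= 1,
            abs(sum(category_probs) - 1) < 1e-9)
  if (is.null(isotype_weights)) {
    code <- standard_genetic_code()
    tab <- table(code$table[code$sense_codons])
    isotype_weights <- stats::setNames(as.numeric(tab), names(tab))
  }
  structure(as.list(environment()), class = "sim_config")
}

# deterministic substream: each generator reseeds from the master seed and
# an offset, so stages can be regenerated independently
substream <- function(cfg, name) {
  off <- c(genome = 101L, cds = 211L, peaks = 307L, lotte = 401L, counts = 503L)
  set.seed((as.integer(cfg$seed) %% 2000000000L) + off[[name]])
}

# anticodons that can compensate a same-isotype partner via a wobble arc;
# used to concentrate gene copies on wobble-capable anticodons
compensator_anticodons <- function(g) {
  syn <- g$arcs[!g$arcs$nonsynonymous, , drop = FALSE]
  sort(unique(syn$source))
}

#' Simulate a tRNA gene table (fast path, no sequences)
#'
#' Generates chromosome assignments, isotype/anticodon identities,
#' non-overlapping coordinates, strands, introns and pseudogene flags -
#' everything the localization test needs - without assembling genomic
#' sequence. Used directly for statistical calibration at scale;
#' \code{\link{synth_genome}} builds on it.
#'
#' @param cfg a \code{sim_config}.
#' @param reseed reseed the substream from cfg$seed (default TRUE; internal
#'   callers that already seeded pass FALSE).
#' @return a \code{trna_genes} data.frame with an extra \code{mature_len}
#'   column.
#' @export
synth_gene_table <- function(cfg, reseed = TRUE) {
  stopifnot(inherits(cfg, "sim_config"))
  if (reseed) substream(cfg, "genome")
  code <- standard_genetic_code()
  g <- build_graph(character(0), code)
  comp <- compensator_anticodons(g)
  acs <- sense_anticodons(code)
  iso_of <- anticodon_isotype(acs, code)

  chroms <- paste0("chr", seq_len(cfg$n_chroms))
  chrom <- sample(chroms, cfg$n_genes, replace = TRUE,
                  prob = cfg$chrom_lengths / sum(cfg$chrom_lengths))

  isotypes <- names(cfg$isotype_weights)
  isotype <- character(cfg$n_genes)
  for (i in seq_len(cfg$n_genes)) {
    w <- cfg$isotype_weights
    sk <- cfg$chrom_skew[[chrom[i]]]
    if (!is.null(sk)) w[names(sk)] <- w[names(sk)] * sk
    isotype[i] <- sample(isotypes, 1L, prob = w)
  }

  anticodon <- vapply(isotype, function(a) {
    pool <- acs[iso_of == a]
    if (cfg$wobble_skew > 0 && stats::runif(1) < cfg$wobble_skew) {
      cpool <- intersect(pool, comp)
      if (length(cpool)) pool <- cpool
    }
    if (length(pool) == 1L) pool else sample(pool, 1L)
  }, character(1))

  # isodecoder structure: genes of an isoacceptor reuse an existing mature
  # form with probability 1 - new_isodecoder_prob; mature length is a
  # property of the isodecoder, so gene copies are sequence-identical
  isodec <- integer(cfg$n_genes)
  iso_lens <- integer(0)
  pool_ids <- list()
  next_id <- 0L
  for (i in seq_len(cfg$n_genes)) {
    key <- paste(isotype[i], anticodon[i], sep = "|")
    pool <- pool_ids[[key]]
    if (is.null(pool) || stats::runif(1) < cfg$new_isodecoder_prob) {
      next_id <- next_id + 1L
      iso_lens[next_id] <- sample(cfg$mature_len_range[1]:cfg$mature_len_range[2], 1L)
      pool_ids[[key]] <- c(pool, next_id)
      isodec[i] <- next_id
    } else {
      isodec[i] <- if (length(pool) == 1L) pool else sample(pool, 1L)
    }
  }
  mature_len <- iso_lens[isodec]
  has_intron <- stats::runif(cfg$n_genes) < cfg$intron_prob
  intron_len <- integer(cfg$n_genes)
  for (i in which(has_intron)) {
    cap <- min(cfg$intron_len_range[2], cfg$max_gene_len - mature_len[i])
    if (cap < cfg$intron_len_range[1]) { has_intron[i] <- FALSE; next }
    intron_len[i] <- sample(cfg$intron_len_range[1]:cap, 1L)
  }
  gene_len <- mature_len + intron_len
  strand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
  pseudo <- stats::runif(cfg$n_genes) < cfg$pseudogene_fraction

  # non-overlapping placement per chromosome with >= 200 bp spacing
  start <- integer(cfg$n_genes)
  margin <- 200L
  for (ch in chroms) {
    idx <- which(chrom == ch)
    if (!length(idx)) next
    L <- cfg$chrom_lengths[match(ch, chroms)]
    need <- sum(gene_len[idx]) + (length(idx) + 1L) * margin
    if (need > L) {
      stop("cannot place ", length(idx), " genes on ", ch, " (", L,
           " bp); increase chrom_lengths or reduce n_genes")
    }
    free <- L - sum(gene_len[idx]) - (length(idx) + 1L) * margin
    cuts <- sort(sample.int(free + 1L, length(idx) + 1L, replace = TRUE) - 1L)
    gaps <- diff(c(0L, cuts))[seq_along(idx)] + margin
    pos <- cumsum(gaps + c(0L, gene_len[idx][-length(idx)])) + 1L
    start[idx] <- pos
  }
  end <- start + gene_len - 1L

  # introns sit after the anticodon loop; on the coding strand that is
  # ~37 nt into the mature sequence, converted to genomic coordinates
  intron_start <- rep(NA_integer_, cfg$n_genes)
  intron_end <- rep(NA_integer_, cfg$n_genes)
  ioff <- 37L
  for (i in which(has_intron)) {
    if (strand[i] == "+") {
      intron_start[i] <- start[i] + ioff
      intron_end[i] <- intron_start[i] + intron_len[i] - 1L
    } else {
      intron_end[i] <- end[i] - ioff
      intron_start[i] <- intron_end[i] - intron_len[i] + 1L
    }
  }

  ord <- order(chrom, start)
  genes <- data.frame(
    gene_id = sprintf("%s.trna%d", chrom[ord],
                      stats::ave(seq_along(ord), chrom[ord], FUN = seq_along)),
    chrom = chrom[ord], start = start[ord], end = end[ord],
    strand = strand[ord], isotype = isotype[ord], anticodon = anticodon[ord],
    intron_start = intron_start[ord], intron_end = intron_end[ord],
    pseudogene = pseudo[ord], score = round(stats::runif(cfg$n_genes, 40, 90), 1),
    mature_len = mature_len[ord],
    isodecoder = isodec[ord],
    stringsAsFactors = FALSE
  )
  class(genes) <- c("trna_genes", "data.frame")
  genes
}

#' Simulate a multi-chromosome genome bearing tRNA genes
#'
#' Builds the gene table of \code{\link{synth_gene_table}}, draws one mature
#' sequence per isodecoder (genes of the same isoacceptor reuse existing
#' mature sequences with probability \code{1 - new_isodecoder_prob}, creating
#' realistic isodecoder clusters), plants gene sequences - anticodon at
#' mature positions 34-36, intron after the anticodon loop - into an AT-rich
#' random background, and records the full ground truth.
#'
#' @param cfg a \code{sim_config}.
#' @return list with \code{genome} (\code{DNAStringSet}), \code{genes}
#'   (a \code{trna_genes} data.frame), and \code{truth} (list:
#'   \code{mature_seq} per gene, \code{copy_number} per anticodon,
#'   \code{isodecoder} id per gene).
#' @export
synth_genome <- function(cfg) {
  substream(cfg, "genome")
  genes <- synth_gene_table(cfg, reseed = FALSE)
  n <- nrow(genes)

  # one mature sequence per isodecoder; gene copies are identical
  iso_ids <- sort(unique(genes$isodecoder))
  iso_seq <- vapply(iso_ids, function(id) {
    i <- which(genes$isodecoder == id)[1]
    random_mature_seq(genes$mature_len[i], genes$anticodon[i])
  }, character(1))
  mature <- iso_seq[match(genes$isodecoder, iso_ids)]
  isodec <- genes$isodecoder

  # AT-rich background (the real nuclear genome is ~77% A+T)
  chroms <- paste0("chr", seq_len(cfg$n_chroms))
  base_probs <- c(A = 0.385, C = 0.115, G = 0.115, T = 0.385)
  contigs <- lapply(cfg$chrom_lengths, function(L) {
    paste(sample(names(base_probs), L, replace = TRUE, prob = base_probs),
          collapse = "")
  })
  genome <- Biostrings::DNAStringSet(unlist(contigs))
  names(genome) <- chroms

  for (ch in chroms) {
    idx <- which(genes$chrom == ch)
    if (!length(idx)) next
    plant <- vapply(idx, function(i) {
      s <- mature[i]
      if (!is.na(genes$intron_start[i])) {
        il <- genes$intron_end[i] - genes$intron_start[i] + 1L
        intr <- paste(sample(c("A", "C", "G", "T"), il, replace = TRUE,
                             prob = base_probs), collapse = "")
        s <- paste0(substr(s, 1L, 37L), intr, substr(s, 38L, nchar(s)))
      }
      if (genes$strand[i] == "-") s <- revcomp(s)
      s
    }, character(1))
    genome[[ch]] <- Biostrings::replaceAt(
      genome[[ch]], IRanges::IRanges(genes$start[idx], genes$end[idx]),
      Biostrings::DNAStringSet(plant))
  }

  cn_tab <- table(genes$anticodon)
  truth <- list(mature_seq = mature,
                copy_number = stats::setNames(as.numeric(cn_tab), names(cn_tab)),
                isodecoder = isodec)
  list(genome = genome, genes = genes, truth = truth)
}

# random mature tRNA body with the anticodon planted at positions 34-36
random_mature_seq <- function(len, anticodon) {
  s <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  if (nchar(anticodon) == 3L && len >= 36L) {
    s[34:36] <- strsplit(anticodon, "")[[1]]
  }
  paste(s, collapse = "")
}

#' Write a gene table in tRNAscan-SE tabular dialect
#'
#' Emits the three banner lines and one row per gene, with minus-strand
#' genes written begin > end as the predictor does, so the output round-trips
#' through \code{\link{parse_trnascan}}.
#'
#' @param genes a \code{trna_genes} data.frame.
#' @param path output file.
#' @export
write_trnascan <- function(genes, path) {
  hdr <- c("Sequence\t\ttRNA\tBounds\ttRNA\tAnti\tIntron Bounds\t\tInf\t",
           "Name    \ttRNA #\tBegin\tEnd\tType\tCodon\tBegin\tEnd\tScore\tNote",
           "--------\t------\t-----\t----\t----\t-----\t-----\t----\t------\t----")
  num <- sub("^.*\\.trna", "", genes$gene_id)
  b <- ifelse(genes$strand == "+", genes$start, genes$end)
  e <- ifelse(genes$strand == "+", genes$end, genes$start)
  ib <- ifelse(is.na(genes$intron_start), 0L,
               ifelse(genes$strand == "+", genes$intron_start, genes$intron_end))
  ie <- ifelse(is.na(genes$intron_start), 0L,
               ifelse(genes$strand == "+", genes$intron_end, genes$intron_start))
  rows <- sprintf("%s\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%.1f\t%s",
                  genes$chrom, num, b, e, genes$isotype, genes$anticodon,
                  ib, ie, genes$score,
                  ifelse(genes$pseudogene, "pseudo", ""))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Simulate coding sequences with codon usage tied to the tRNA repertoire
#'
#' In plain mode (\code{cfg$wobble_skew == 0}) codons are drawn with
#' probability proportional to their exact cognate anticodon's gene copy
#' number, so codon usage and isoacceptor copy number correlate almost
#' perfectly. In wobble-skewed mode the weight of each codon is shifted onto
#' the copy numbers of the anticodons that can wobble-decode it (the
#' in-neighbours of its cognate anticodon in the decoding potential graph):
#' isoacceptor-level correlation collapses while arc-grouped correlation
#' stays high - the construction the restoration analysis detects.
#'
#' @param cfg a \code{sim_config}.
#' @param copy_number named numeric vector anticodon -> gene copies.
#' @param g a \code{decoding_graph} (defaults to the full standard graph).
#' @return \code{DNAStringSet} of CDS (ATG + sense codons + TAA; lengths
#'   divisible by 3, no internal stops).
#' @export
synth_cds <- function(cfg, copy_number, g = NULL) {
  substream(cfg, "cds")
  code <- standard_genetic_code()
  if (is.null(g)) g <- build_graph(names(copy_number), code)
  acs <- sense_anticodons(code)
  cn <- stats::setNames(numeric(length(acs)), acs)
  known <- intersect(names(copy_number), acs)
  cn[known] <- copy_number[known]

  incoming <- split(g$arcs$source, g$arcs$target)
  w_wobble <- vapply(acs, function(a) {
    src <- incoming[[a]]
    if (is.null(src)) 0 else sum(cn[src])
  }, numeric(1))
  w <- (1 - cfg$wobble_skew) * cn + cfg$wobble_skew * w_wobble
  w <- w + 0.1  # floor so every sense codon stays reachable
  codons <- anticodon_to_codon(acs)

  lens <- sample(cfg$cds_len_range[1]:cfg$cds_len_range[2], cfg$n_cds,
                 replace = TRUE)
  seqs <- vapply(lens, function(L) {
    body <- sample(codons, L, replace = TRUE, prob = w)
    paste0("ATG", paste(body, collapse = ""), "TAA")
  }, character(1))
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- sprintf("cds%04d", seq_len(cfg$n_cds))
  out
}

#' Simulate per-stage NFR peak sets with known availability truth
#'
#' Assigns each gene an availability category (constitutive, stage-specific,
#' partial, never) at the configured probabilities, then emits per-stage
#' peaks that fully embed the gene where it is available. Unavailable
#' (gene, stage) pairs receive, with probability \code{decoy_prob}, a decoy
#' peak covering only part of the gene - a trap for any classifier that
#' accepts partial overlap.
#'
#' @param cfg a \code{sim_config}.
#' @param genes a \code{trna_genes} data.frame.
#' @return list with \code{peaks} (named list stage -> BED-like data.frame,
#'   0-based half-open), \code{truth} (data.frame gene_id, category,
#'   one logical column per stage).
#' @export
synth_peaks <- function(cfg, genes) {
  substream(cfg, "peaks")
  n <- nrow(genes)
  stages <- cfg$stages
  ns <- length(stages)
  cats <- sample(names(cfg$category_probs), n, replace = TRUE,
                 prob = cfg$category_probs)
  avail <- matrix(FALSE, n, ns, dimnames = list(genes$gene_id, stages))
  cat_label <- character(n)
  for (i in seq_len(n)) {
    cat_label[i] <- cats[i]
    if (cats[i] == "constitutive") {
      avail[i, ] <- TRUE
    } else if (cats[i] == "stage_specific") {
      st <- sample(stages, 1L)
      avail[i, st] <- TRUE
      cat_label[i] <- paste0("stage_specific:", st)
    } else if (cats[i] == "partial") {
      k <- if (ns > 3L) sample(2:(ns - 1L), 1L) else ns - 1L
      avail[i, sample(stages, k)] <- TRUE
    }
  }
  peaks <- lapply(stages, function(st) {
    rows <- list()
    for (i in seq_len(n)) {
      g0 <- genes$start[i] - 1L  # 0-based half-open gene interval
      g1 <- genes$end[i]
      if (avail[i, st]) {
        pad_l <- sample(0:150, 1L)  # 0 allowed: exact-fit boundary case
        pad_r <- sample(0:150, 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = genes$chrom[i], start = max(0L, g0 - pad_l), end = g1 + pad_r,
          name = sprintf("%s_peak%d", st, i), stringsAsFactors = FALSE)
      } else if (stats::runif(1) < cfg$decoy_prob) {
        mid <- g0 + (g1 - g0) %/% 2L
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = genes$chrom[i], start = mid, end = g1 + sample(10:80, 1L),
          name = sprintf("%s_decoy%d", st, i), stringsAsFactors = FALSE)
      }
    }
    if (length(rows)) do.call(rbind, rows)
    else data.frame(chrom = character(0), start = integer(0),
                    end = integer(0), name = character(0))
  })
  names(peaks) <- stages
  truth <- data.frame(gene_id = genes$gene_id, category = cat_label,
                      avail + 0L, check.names = FALSE,
                      stringsAsFactors = FALSE)
  list(peaks = peaks, truth = truth, available = avail)
}

#' Simulate labelled mature-tRNA alignment records
#'
#' Emits SAM-style records against the cluster references: valid reads
#' (unique, starting past the flank, ending in CCA exactly at the reference
#' 3' end) and, at the configured fractions, reads failing exactly one
#' criterion - NH:i:2 multi-mappers, starts inside the flank (including the
#' boundary position flank_len), non-CCA 3' ends, and alignments stopping
#' short of the reference end. Each read carries a per-read truth label.
#'
#' @param cfg a \code{sim_config}.
#' @param clusters an \code{isodecoder_clusters} data.frame.
#' @return list with \code{records} (data.frame ready for
#'   \code{\link{write_sam}} / \code{\link{validate_reads}}), \code{truth}
#'   (data.frame query, cluster, label), \code{sam} (character SAM lines).
#' @export
synth_lotte <- function(cfg, clusters) {
  substream(cfg, "lotte")
  n <- cfg$n_reads
  labels <- c(names(cfg$fail_fracs), "valid")
  probs <- c(cfg$fail_fracs, valid = 1 - sum(cfg$fail_fracs))
  lab <- sample(labels, n, replace = TRUE, prob = probs)
  abund <- stats::rlnorm(nrow(clusters), meanlog = 0, sdlog = 1)
  ci <- sample.int(nrow(clusters), n, replace = TRUE, prob = abund)
  ref <- clusters$reference_seq[ci]
  ref_len <- nchar(ref)
  flank <- clusters$flank_len[ci]

  want_short <- stats::runif(n) < cfg$short_frac
  # read length target: short 8-21 nt, long 22..(mature+CCA)
  max_len <- ref_len - flank  # mature + CCA, fully past the flank
  len <- ifelse(want_short, pmin(sample(8:21, n, replace = TRUE), max_len),
                pmin(22L + sample(0:60, n, replace = TRUE), max_len))
  pos <- ref_len - len + 1L                 # align to the 3' end
  end <- ref_len
  seqs <- substr(ref, pos, end)

  adjust <- function(i) {
    switch(lab[i],
      valid = NULL,
      unique = NULL,                         # only NH changes
      past_flank = {
        p <- sample.int(flank[i], 1L)        # 1..flank_len, boundary included
        pos[i] <<- p
        seqs[i] <<- substr(ref[i], p, end[i])
      },
      cca_end = {
        s <- seqs[i]
        substr(s, nchar(s), nchar(s)) <- "T" # ...CCA -> ...CCT
        seqs[i] <<- s
      },
      reaches_3prime = {
        d <- sample.int(5L, 1L)
        end[i] <<- ref_len[i] - d
        p <- min(pos[i], end[i] - 8L + 1L)
        pos[i] <<- max(flank[i] + 1L, p)
        s <- substr(ref[i], pos[i], end[i])
        substr(s, nchar(s) - 2L, nchar(s)) <- "CCA"  # keep the CCA criterion green
        seqs[i] <<- s
      })
    invisible(NULL)
  }
  for (i in seq_len(n)) adjust(i)
  span <- end - pos + 1L
  keep <- span >= 8L & pos >= 1L
  records <- data.frame(
    query = sprintf("read%06d", seq_len(n))[keep],
    ref = clusters$cluster_id[ci][keep],
    pos = pos[keep],
    cigar = paste0(span[keep], "M"),
    aln_span = span[keep],
    read_seq = seqs[keep],
    multiplicity = ifelse(lab[keep] == "unique", 2L, 1L),
    mapped = TRUE,
    stringsAsFactors = FALSE
  )
  truth <- data.frame(query = records$query,
                      cluster = records$ref,
                      label = lab[keep], stringsAsFactors = FALSE)
  ref_lengths <- stats::setNames(nchar(clusters$reference_seq),
                                 clusters$cluster_id)
  sam <- write_sam(records, ref_lengths)
  list(records = records, truth = truth, sam = sam)
}

#' Simulate a count matrix with planted differential expression
#'
#' Negative-binomial counts across the configured stages with
#' \code{n_reps} replicates each. Per transition, \code{n_de_per_transition}
#' features are planted up- and down-regulated at \code{planted_lfc}
#' (effects accumulate along the stage order). Three features form the
#' opposite-sign isodecoder construction: they share one isoacceptor group,
#' two shift up and one shifts down in the first transition with magnitudes
#' chosen so the group sum barely moves - differential expression is then
#' visible at cluster level but masked at isoacceptor level.
#'
#' @param cfg a \code{sim_config}.
#' @param feature_info optional data.frame \code{feature}, \code{isoacceptor},
#'   \code{isotype}; generated when NULL.
#' @return list with \code{counts} (matrix feature x sample), \code{stages}
#'   (named vector sample -> stage), \code{feature_info}, \code{truth}
#'   (data.frame feature, transition, log2fc, motif flag).
#' @export
synth_counts <- function(cfg, feature_info = NULL) {
  substream(cfg, "counts")
  st <- cfg$count_stages
  n_tr <- length(st) - 1L
  nf <- cfg$n_features
  if (is.null(feature_info)) {
    n_acc <- max(3L, nf %/% 3L)
    acc <- paste0("acc", rep_len(seq_len(n_acc), nf))
    iso <- paste0("iso", rep_len(seq_len(max(2L, n_acc %/% 2L)),
                                 n_acc))[as.integer(sub("acc", "", acc))]
    feature_info <- data.frame(feature = sprintf("cluster%03d", seq_len(nf)),
                               isoacceptor = acc, isotype = iso,
                               stringsAsFactors = FALSE)
  }
  nf <- nrow(feature_info)
  base <- stats::rlnorm(nf, cfg$base_mean_meanlog, cfg$base_mean_sdlog)

  # planted effects: distinct features per transition, none in the motif trio
  motif_idx <- which(feature_info$isoacceptor == feature_info$isoacceptor[1])[1:3]
  free <- setdiff(seq_len(nf), motif_idx)
  effects <- list()
  lfc_mat <- matrix(0, nf, n_tr)
  for (t in seq_len(n_tr)) {
    pick <- sample(free, min(2L * cfg$n_de_per_transition, length(free)))
    if (length(pick) == 0L) next
    up <- pick[seq_len(length(pick) %/% 2L)]
    dn <- setdiff(pick, up)
    lfc_mat[up, t] <- cfg$planted_lfc
    lfc_mat[dn, t] <- -cfg$planted_lfc
    effects[[t]] <- data.frame(
      feature = feature_info$feature[c(up, dn)],
      transition = paste(st[t], st[t + 1L], sep = ">"),
      log2fc = c(rep(cfg$planted_lfc, length(up)),
                 rep(-cfg$planted_lfc, length(dn))),
      motif = FALSE, stringsAsFactors = FALSE)
  }
  # opposite-sign isodecoder motif in the first transition: the two up
  # features' gain equals the down feature's loss, so the group sum is flat
  lfc <- cfg$planted_lfc
  b <- base[motif_idx]
  b[1] <- 150; b[2] <- 150
  b[3] <- (b[1] + b[2]) * (2^lfc - 1) / (1 - 2^(-lfc))
  base[motif_idx] <- b
  lfc_mat[motif_idx, 1L] <- c(lfc, lfc, -lfc)
  effects[[n_tr + 1L]] <- data.frame(
    feature = feature_info$feature[motif_idx],
    transition = paste(st[1], st[2], sep = ">"),
    log2fc = c(lfc, lfc, -lfc), motif = TRUE, stringsAsFactors = FALSE)

  mu <- matrix(base, nf, length(st))
  for (t in seq_len(n_tr)) mu[, t + 1L] <- mu[, t] * 2^lfc_mat[, t]
  samples <- paste(rep(st, each = cfg$n_reps), seq_len(cfg$n_reps), sep = "_")
  stage_map <- stats::setNames(rep(st, each = cfg$n_reps), samples)
  counts <- matrix(0L, nf, length(samples),
                   dimnames = list(feature_info$feature, samples))
  for (j in seq_along(samples)) {
    k <- match(stage_map[j], st)
    counts[, j] <- stats::rnbinom(nf, mu = mu[, k], size = 1 / cfg$nb_dispersion)
  }
  list(counts = counts, stages = stage_map, feature_info = feature_info,
       truth = do.call(rbind, effects))
}
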