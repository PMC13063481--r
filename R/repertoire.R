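#' Parse tRNAscan-SE tabular output
#'
#' Reads the standard tabular dialect of tRNAscan-SE (v2.x): one row per
#' predicted gene with columns sequence name, tRNA number, begin, end,
#' isotype, anticodon, intron begin, intron end, bit score and an optional
#' note column. Header lines are tolerated. Minus-strand genes, which the
#' predictor reports with begin > end, are normalized to start <= end with
#' strand "-". Intron coordinates are normalized the same way. Pseudogene
#' notes and undetermined ("Undet"/"???") anticodons are preserved.
#'
#' @param path path to a tRNAscan-SE tabular file, or a character vector of
#'   its lines.
#' @param plausible_length length window (gene span, bp) outside which a
#'   warning is raised; records are kept either way.
#' @return data.frame of class \code{trna_genes} with columns
#'   \code{gene_id}, \code{chrom}, \code{start}, \code{end} (1-based
#'   inclusive), \code{strand}, \code{isotype}, \code{anticodon},
#'   \code{intron_start}, \code{intron_end} (NA when intronless),
#'   \code{pseudogene}, \code{score}.
#' @export
parse_trnascan <- function(path, plausible_length = c(60L, 120L)) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  known_isotypes <- c(unname(Biostrings::AMINO_ACID_CODE[strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]]),
                      "iMet", "fMet", "SeC", "Sup", "Undet")
  recs <- list()
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(trimws(ln))) next
    f <- trimws(strsplit(ln, "\t", fixed = TRUE)[[1]])
    # header lines: three-line banner whose third field is not a number
    if (length(f) < 3L || is.na(suppressWarnings(as.numeric(f[3])))) {
      if (grepl("^-+$", gsub("[\t ]", "", ln)) ||
          grepl("^(Sequence|Name)", ln)) next
      if (i <= 3L) next
      stop("malformed tRNAscan row at line ", i, ": ", ln)
    }
    if (length(f) < 9L) stop("malformed tRNAscan row at line ", i,
                             ": expected >= 9 fields, got ", length(f))
    begin <- suppressWarnings(as.integer(f[3])); end <- suppressWarnings(as.integer(f[4]))
    ib <- suppressWarnings(as.integer(f[7])); ie <- suppressWarnings(as.integer(f[8]))
    score <- suppressWarnings(as.numeric(f[9]))
    if (anyNA(c(begin, end, ib, ie, score))) {
      stop("malformed tRNAscan row at line ", i, ": non-numeric coordinates/score")
    }
    strand <- if (begin > end) "-" else "+"
    if (strand == "-") { tmp <- begin; begin <- end; end <- tmp }
    if (ib == 0L && ie == 0L) { ib <- NA_integer_; ie <- NA_integer_ }
    else if (!is.na(ib) && ib > ie) { tmp <- ib; ib <- ie; ie <- tmp }
    isotype <- f[5]
    if (!isotype %in% known_isotypes) {
      warning("unknown isotype symbol '", isotype, "' at line ", i, "; record kept")
    }
    anticodon <- f[6]
    if (anticodon %in% c("???", "NNN", "")) anticodon <- "Undet"
    note <- if (length(f) >= 10L) f[10] else ""
    recs[[length(recs) + 1L]] <- data.frame(
      gene_id = paste0(f[1], ".trna", f[2]),
      chrom = f[1], start = begin, end = end, strand = strand,
      isotype = isotype, anticodon = anticodon,
      intron_start = ib, intron_end = ie,
      pseudogene = grepl("pseudo", note, ignore.case = TRUE),
      score = score, stringsAsFactors = FALSE
    )
  }
  genes <- if (length(recs)) do.call(rbind, recs) else empty_trna_genes()
  len <- genes$end - genes$start + 1L
  out_of_window <- which(len < plausible_length[1] | len > plausible_length[2])
  if (length(out_of_window)) {
    warning(length(out_of_window), " gene(s) outside the plausible length window [",
            plausible_length[1], ",", plausible_length[2], "]")
  }
  bad_intron <- which(!is.na(genes$intron_start) &
                        (genes$intron_start < genes$start | genes$intron_end > genes$end))
  if (length(bad_intron)) {
    stop("intron outside gene bounds for: ",
         paste(genes$gene_id[bad_intron], collapse = ", "))
  }
  class(genes) <- c("trna_genes", "data.frame")
  genes
}

empty_trna_genes <- function() {
  data.frame(gene_id = character(0), chrom = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             isotype = character(0), anticodon = character(0),
             intron_start = integer(0), intron_end = integer(0),
             pseudogene = logical(0), score = numeric(0),
             stringsAsFactors = FALSE)
}

#' Extract the mature (intron-removed) tRNA sequence of a gene
#'
#' Returns the coding-strand sequence of a gene with intron intervals
#' excised: for minus-strand genes the genomic substring is
#' reverse-complemented after excision. Mature lengths outside 69-87 nt are
#' reported with a warning (plausibility log), not an error.
#'
#' @param gene one row of a \code{trna_genes} data.frame (or a list with the
#'   same fields).
#' @param genome named \code{DNAStringSet} (or named character vector).
#' @param warn_length if TRUE, warn when the mature length leaves 69-87 nt.
#' @return single character string, 5'->3' on the coding strand.
#' @export
extract_mature <- function(gene, genome, warn_length = FALSE) {
  genome <- as_dnastringset(genome)
  if (!gene$chrom %in% names(genome)) stop("unknown sequence: ", gene$chrom)
  contig <- genome[[gene$chrom]]
  if (gene$start < 1L || gene$end > length(contig)) {
    stop("coordinates of ", gene$gene_id, " out of bounds for ", gene$chrom)
  }
  s <- Biostrings::subseq(contig, gene$start, gene$end)
  if (!is.na(gene$intron_start)) {
    at <- IRanges::IRanges(gene$intron_start - gene$start + 1L,
                           gene$intron_end - gene$start + 1L)
    s <- Biostrings::replaceAt(s, at, Biostrings::DNAStringSet(""))
  }
  if (gene$strand == "-") s <- Biostrings::reverseComplement(s)
  out <- as.character(s)
  if (warn_length && (nchar(out) < 69L || nchar(out) > 87L)) {
    warning("mature length ", nchar(out), " nt for ", gene$gene_id,
            " outside the 69-87 plausibility window")
  }
  out
}

as_dnastringset <- function(genome) {
  if (inherits(genome, "DNAStringSet")) return(genome)
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    return(Biostrings::readDNAStringSet(genome))
  }
  Biostrings::DNAStringSet(genome)
}

#' Cluster tRNA genes into isodecoders
#'
#' Genes whose mature sequences (introns removed, coding strand) are
#' identical form one isodecoder cluster. Each cluster receives an
#' artificial reference sequence for read mapping: the 10 nt immediately
#' upstream (5' on the coding strand) of the cluster's representative gene,
#' the mature sequence, and a terminal "CCA" mimicking the
#' post-transcriptionally added tail. The representative is the
#' lexicographically smallest gene_id, making the choice of flank donor
#' deterministic.
#'
#' @param genes a \code{trna_genes} data.frame.
#' @param genome named \code{DNAStringSet} or FASTA path.
#' @param flank_len upstream flank length in nt (default 10).
#' @return data.frame of class \code{isodecoder_clusters}: \code{cluster_id},
#'   \code{mature_seq}, \code{members} (comma-joined gene ids),
#'   \code{n_members}, \code{representative}, \code{isotype},
#'   \code{anticodon}, \code{reference_seq}, \code{flank_len}; sorted by
#'   cluster_id.
#' @export
cluster_isodecoders <- function(genes, genome, flank_len = 10L) {
  genome <- as_dnastringset(genome)
  if (nrow(genes) == 0L) {
    out <- data.frame(cluster_id = character(0), mature_seq = character(0),
                      members = character(0), n_members = integer(0),
                      representative = character(0), isotype = character(0),
                      anticodon = character(0), reference_seq = character(0),
                      flank_len = integer(0), stringsAsFactors = FALSE)
    class(out) <- c("isodecoder_clusters", "data.frame")
    return(out)
  }
  mature <- vapply(seq_len(nrow(genes)), function(i)
    extract_mature(genes[i, ], genome), character(1))
  groups <- split(seq_len(nrow(genes)), mature)
  groups <- groups[order(names(groups))]
  rows <- lapply(seq_along(groups), function(k) {
    idx <- groups[[k]]
    ids <- sort(genes$gene_id[idx])
    rep_id <- ids[1]
    ri <- idx[genes$gene_id[idx] == rep_id][1]
    flank <- upstream_flank(genes[ri, ], genome, flank_len)
    data.frame(
      cluster_id = sprintf("cluster%03d", k),
      mature_seq = names(groups)[k],
      members = paste(ids, collapse = ","),
      n_members = length(ids),
      representative = rep_id,
      isotype = genes$isotype[ri],
      anticodon = genes$anticodon[ri],
      reference_seq = paste0(flank, names(groups)[k], "CCA"),
      flank_len = as.integer(flank_len),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("isodecoder_clusters", "data.frame")
  out
}

# internal: flank immediately 5' of the gene on its coding strand; pads with
# N (and warns) when it would run off the contig edge
upstream_flank <- function(gene, genome, flank_len) {
  contig <- genome[[gene$chrom]]
  if (gene$strand == "+") {
    from <- gene$start - flank_len; to <- gene$start - 1L
  } else {
    from <- gene$end + 1L; to <- gene$end + flank_len
  }
  lo <- max(from, 1L); hi <- min(to, length(contig))
  core <- if (lo > hi) "" else as.character(Biostrings::subseq(contig, lo, hi))
  pad <- strrep("N", flank_len - nchar(core))
  if (nzchar(pad)) warning("flank of ", gene$gene_id,
                           " extends beyond contig edge; padded with N")
  s <- if (gene$strand == "+") paste0(pad, core) else paste0(core, pad)
  if (gene$strand == "-") s <- revcomp(s)
  s
}

#' Summarize a tRNA gene repertoire
#'
#' Counts at the four equivalence levels (genes, isodecoders, isoacceptors,
#' isotypes), gene density per chromosome, and the per-isotype anticodon
#' breakdown. Genes with an undetermined anticodon are counted at gene level
#' but excluded from isoacceptor/isotype tallies; the isodecoder count
#' requires sequences and is NA when no genome is supplied.
#'
#' @param genes a \code{trna_genes} data.frame.
#' @param genome optional genome (for isodecoder counting and per-Mb density).
#' @param include_pseudogenes keep pseudogenes in all counts (default TRUE,
#'   matching gene-level reporting that includes them).
#' @return list with \code{counts} (named vector genes/isodecoders/
#'   isoacceptors/isotypes), \code{per_chromosome} (data.frame chrom,
#'   n_genes, density_per_mb), \code{by_isotype} (data.frame isotype,
#'   anticodon, n_genes).
#' @export
summarize_repertoire <- function(genes, genome = NULL, include_pseudogenes = TRUE) {
  if (!include_pseudogenes) genes <- genes[!genes$pseudogene, , drop = FALSE]
  known_ac <- genes$anticodon != "Undet"
  known_iso <- genes$isotype != "Undet"
  isodec <- NA_integer_
  if (!is.null(genome) && nrow(genes) > 0L) {
    isodec <- nrow(cluster_isodecoders(genes, genome))
  } else if (nrow(genes) == 0L) isodec <- 0L
  counts <- c(
    genes = nrow(genes),
    isodecoders = isodec,
    isoacceptors = length(unique(genes$anticodon[known_ac])),
    isotypes = length(unique(genes$isotype[known_iso]))
  )
  tab <- table(factor(genes$chrom, levels = sort(unique(genes$chrom))))
  per_chrom <- data.frame(chrom = names(tab), n_genes = as.integer(tab),
                          stringsAsFactors = FALSE)
  per_chrom$density_per_mb <- rep(NA_real_, nrow(per_chrom))
  if (!is.null(genome)) {
    genome <- as_dnastringset(genome)
    hit <- per_chrom$chrom %in% names(genome)
    per_chrom$density_per_mb[hit] <-
      per_chrom$n_genes[hit] / (Biostrings::width(genome)[match(per_chrom$chrom[hit],
                                                                names(genome))] / 1e6)
  }
  bi <- genes[known_ac & known_iso, c("isotype", "anticodon")]
  by_isotype <- if (nrow(bi)) {
    ag <- stats::aggregate(list(n_genes = rep(1L, nrow(bi))),
                           by = bi[c("isotype", "anticodon")], FUN = sum)
    ag[order(ag$isotype, ag$anticodon), , drop = FALSE]
  } else data.frame(isotype = character(0), anticodon = character(0),
                    n_genes = integer(0))
  rownames(by_isotype) <- NULL
  list(counts = counts, per_chromosome = per_chrom, by_isotype = by_isotype)
}

# log point probability of the multivariate hypergeometric distribution:
# drawing k (vector over isotypes) from a pool K without replacement
log_dmvhyper <- function(k, K) {
  sum(lchoose(K, k)) - lchoose(sum(K), sum(k))
}

# n_draws multivariate hypergeometric draws of size n from pool K,
# vectorized over draws via the sequential-conditional construction
rmvhyper_mat <- function(n_draws, K, n) {
  d <- length(K)
  out <- matrix(0L, nrow = n_draws, ncol = d)
  n_rem <- rep.int(n, n_draws)
  N_rem <- sum(K)
  for (i in seq_len(d - 1L)) {
    ki <- stats::rhyper(n_draws, m = K[i], n = N_rem - K[i], k = n_rem)
    out[, i] <- ki
    n_rem <- n_rem - ki
    N_rem <- N_rem - K[i]
  }
  out[, d] <- n_rem
  out
}

#' Monte-Carlo multivariate hypergeometric test of chromosomal isotype
#' localization
#'
#' For each chromosome, asks whether its isotype composition is compatible
#' with drawing that many genes at random (without replacement) from the
#' genome-wide isotype pool. The test statistic is the multivariate
#' hypergeometric point probability of the observed composition; the
#' Monte-Carlo p-value with add-one correction is
#' p = (b + 1) / (n_draws + 1), where b counts null draws whose point
#' probability is at most the observed one (ties count as extreme, which is
#' conservative).
#'
#' @param genes a \code{trna_genes} data.frame (>= 2 chromosomes and >= 2
#'   isotypes for a non-degenerate test).
#' @param n_draws number of Monte-Carlo draws per chromosome (default 10000).
#' @param seed mandatory integer seed.
#' @param adjust optional p-value adjustment across chromosomes
#'   ("none" default, or "holm").
#' @return data.frame \code{chrom}, \code{n_genes}, \code{log_pmf},
#'   \code{p_value}, \code{degenerate}, plus attributes \code{seed},
#'   \code{n_draws}.
#' @export
chrom_isotype_test <- function(genes, n_draws = 10000L, seed,
                               adjust = c("none", "holm")) {
  if (missing(seed)) stop("a seed is mandatory for the Monte-Carlo test")
  adjust <- match.arg(adjust)
  if (n_draws < 1L) stop("n_draws must be >= 1")
  pool_tab <- table(genes$isotype)
  K <- as.integer(pool_tab)
  names(K) <- names(pool_tab)
  chroms <- sort(unique(genes$chrom))
  if (length(chroms) < 2L) warning("fewer than 2 chromosomes; test is weak")
  degenerate <- length(K) < 2L
  if (degenerate) warning("single isotype genome-wide; p = 1 everywhere")
  set.seed(as.integer(seed))
  rows <- lapply(chroms, function(ch) {
    obs <- as.integer(table(factor(genes$isotype[genes$chrom == ch],
                                   levels = names(K))))
    n_c <- sum(obs)
    lp_obs <- log_dmvhyper(obs, K)
    if (degenerate) {
      return(data.frame(chrom = ch, n_genes = n_c, log_pmf = lp_obs,
                        p_value = 1, degenerate = TRUE, stringsAsFactors = FALSE))
    }
    draws <- rmvhyper_mat(n_draws, K, n_c)
    lp <- lchoose_rows(draws, K) - lchoose(sum(K), n_c)
    b <- sum(lp <= lp_obs + 1e-9)
    data.frame(chrom = ch, n_genes = n_c, log_pmf = lp_obs,
               p_value = (b + 1) / (n_draws + 1), degenerate = FALSE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (adjust == "holm") out$p_adj <- stats::p.adjust(out$p_value, "holm")
  attr(out, "seed") <- as.integer(seed)
  attr(out, "n_draws") <- as.integer(n_draws)
  out
}

# rowwise sum of lchoose(K[j], draws[, j])
lchoose_rows <- function(draws, K) {
  acc <- numeric(nrow(draws))
  for (j in seq_along(K)) acc <- acc + lchoose(K[j], draws[, j])
  acc
}
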