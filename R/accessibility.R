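#' Read a BED3+ file of peaks
#'
#' First three columns (chrom, start, end; 0-based half-open) are mandatory;
#' further columns (name, score, ...) are kept opaque.
#'
#' @param path BED file path.
#' @return data.frame \code{chrom}, \code{start}, \code{end} plus any extra
#'   columns.
#' @export
read_bed <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(d) < 3L) stop("BED file needs at least 3 columns: ", path)
  names(d)[1:3] <- c("chrom", "start", "end")
  if (any(d$start >= d$end)) stop("BED intervals must satisfy start < end: ", path)
  d
}

#' Write peaks as BED3+
#' @param peaks data.frame with chrom/start/end first.
#' @param path output file.
#' @export
write_bed <- function(peaks, path) {
  utils::write.table(peaks, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Classify tRNA genes as transcriptionally available per stage
#'
#' A gene is available at a stage when its full span is embedded in a single
#' nucleosome-free-region peak of that stage: peak.start <= gene.start and
#' gene.end <= peak.end after converting the gene's 1-based inclusive
#' coordinates to the peaks' 0-based half-open system. Equality at both
#' boundaries counts as embedded; partial overlap does not. Strand is
#' ignored (chromatin accessibility is strandless), and peaks are not merged
#' beforehand - embedding in any one peak suffices.
#'
#' @param genes a \code{trna_genes} data.frame.
#' @param peaks_by_stage named list stage -> peak data.frame (chrom, start,
#'   end, 0-based half-open; e.g. from \code{\link{read_bed}}).
#' @return object of class \code{availability_matrix}: list with
#'   \code{genes} (gene ids), \code{stages}, \code{available} (logical
#'   gene x stage matrix), \code{isotype} (per gene, for category
#'   breakdowns).
#' @export
embed_classify <- function(genes, peaks_by_stage) {
  stopifnot(is.list(peaks_by_stage), !is.null(names(peaks_by_stage)))
  stages <- names(peaks_by_stage)
  gr_genes <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end)
  )
  avail <- matrix(FALSE, nrow = nrow(genes), ncol = length(stages),
                  dimnames = list(genes$gene_id, stages))
  for (st in stages) {
    pk <- peaks_by_stage[[st]]
    if (nrow(pk) == 0L) next
    miss <- setdiff(unique(genes$chrom), unique(pk$chrom))
    if (length(miss)) {
      warning("stage ", st, ": no peaks on ", paste(miss, collapse = ", "),
              "; genes there unavailable")
    }
    gr_pk <- GenomicRanges::GRanges(
      seqnames = pk$chrom,
      ranges = IRanges::IRanges(start = pk$start + 1L, end = pk$end)
    )
    hits <- GenomicRanges::findOverlaps(gr_genes, gr_pk, type = "within",
                                        ignore.strand = TRUE)
    avail[unique(S4Vectors::queryHits(hits)), st] <- TRUE
  }
  structure(list(genes = genes$gene_id, stages = stages, available = avail,
                 isotype = genes$isotype),
            class = "availability_matrix")
}

#' Summarize an availability matrix into transcriptional categories
#'
#' Genes are binned into: \code{constitutive} (available at every stage),
#' \code{stage_specific:<stage>} (exactly one stage), \code{never} (none),
#' and \code{partial} (some but not all stages, more than one). Union and
#' intersection counts are reported for every non-empty stage combination
#' (upset-style), together with per-isotype category proportions when the
#' matrix carries isotypes.
#'
#' @param m an \code{availability_matrix}.
#' @return list with \code{category} (named character per gene),
#'   \code{category_counts}, \code{combos} (data.frame combo/size/union/
#'   intersection), and \code{by_isotype} (proportion table or NULL).
#' @export
availability_summary <- function(m) {
  stopifnot(inherits(m, "availability_matrix"))
  av <- m$available
  k <- rowSums(av)
  n_st <- length(m$stages)
  category <- character(nrow(av))
  category[k == n_st] <- "constitutive"
  category[k == 0L] <- "never"
  one <- which(k == 1L & n_st > 1L)
  category[one] <- paste0("stage_specific:",
                          m$stages[apply(av[one, , drop = FALSE], 1, which)])
  category[category == ""] <- "partial"
  names(category) <- m$genes

  lv <- c("constitutive",
          paste0("stage_specific:", m$stages), "partial", "never")
  category_counts <- table(factor(category, levels = lv))

  combos <- do.call(rbind, lapply(seq_len(n_st), function(sz) {
    cmb <- utils::combn(m$stages, sz, simplify = FALSE)
    do.call(rbind, lapply(cmb, function(set) {
      sub <- av[, set, drop = FALSE]
      data.frame(combo = paste(set, collapse = "+"), size = sz,
                 union = sum(rowSums(sub) >= 1L),
                 intersection = sum(rowSums(sub) == sz),
                 stringsAsFactors = FALSE)
    }))
  }))

  by_isotype <- NULL
  if (!is.null(m$isotype)) {
    simple <- ifelse(grepl("^stage_specific", category), "stage_specific", category)
    tb <- table(m$isotype, factor(simple, levels = c("constitutive",
                                                     "stage_specific",
                                                     "partial", "never")))
    by_isotype <- prop.table(tb, margin = 1)
  }
  list(category = category, category_counts = category_counts,
       combos = combos, by_isotype = by_isotype)
}

#' Write an availability matrix as TSV
#' @param m an \code{availability_matrix}.
#' @param path output file.
#' @export
write_availability_tsv <- function(m, path) {
  stopifnot(inherits(m, "availability_matrix"))
  out <- data.frame(gene_id = m$genes, m$available + 0L, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
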