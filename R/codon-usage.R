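#' Count codon usage over a set of coding sequences
#'
#' Reads every CDS in frame from its first position in non-overlapping
#' triplets. Records whose length is not a multiple of 3 are processed up to
#' the last complete triplet and flagged. Triplets containing non-ACGT
#' characters are skipped and tallied; stop codons (including UGA, i.e. the
#' selenocysteine recoding is excluded) are skipped and tallied separately.
#'
#' @param cds \code{DNAStringSet}, named character vector, or FASTA path.
#' @param code a \code{genetic_code}.
#' @return object of class \code{codon_usage}: list with \code{counts}
#'   (named integer over the 61 sense codons), \code{aa_counts} (push-forward
#'   through the code), \code{n_cds}, \code{n_stop}, \code{skipped}
#'   (ambiguous triplets), \code{n_incomplete} (records flagged for frame
#'   remainder).
#' @export
count_codons <- function(cds, code = standard_genetic_code()) {
  cds <- as_dnastringset(cds)
  if (length(cds) == 0L) {
    warning("empty CDS stream; zero usage")
    counts <- stats::setNames(integer(61), code$sense_codons)
    return(new_codon_usage(counts, 0L, 0L, 0L, 0L, code))
  }
  w <- Biostrings::width(cds)
  n_incomplete <- sum(w %% 3L != 0L)
  # trinucleotideFrequency with step=3 counts in-frame ACGT triplets only;
  # triplets touching ambiguity codes simply do not appear in any column
  freq <- Biostrings::trinucleotideFrequency(cds, step = 3)
  tot <- colSums(freq)
  skipped <- sum(w %/% 3L) - sum(tot)
  n_stop <- sum(tot[code$stop_codons])
  counts <- as.integer(tot[code$sense_codons])
  names(counts) <- code$sense_codons
  new_codon_usage(counts, length(cds), n_stop, as.integer(skipped),
                  n_incomplete, code)
}

new_codon_usage <- function(counts, n_cds, n_stop, skipped, n_incomplete, code) {
  aa <- code$table[names(counts)]
  aa_counts <- tapply(counts, aa, sum)
  structure(list(counts = counts,
                 aa_counts = stats::setNames(as.integer(aa_counts), names(aa_counts)),
                 n_cds = n_cds, n_stop = n_stop, skipped = skipped,
                 n_incomplete = n_incomplete, code = code),
            class = "codon_usage")
}

#' @export
print.codon_usage <- function(x, ...) {
  cat("codon usage over", x$n_cds, "CDS:", sum(x$counts), "sense codons,",
      x$n_stop, "stops,", x$skipped, "ambiguous triplets skipped\n")
  invisible(x)
}

#' Correlate codon usage with tRNA gene copy numbers at several levels
#'
#' Runs the Pearson correlation between genomic usage and gene copy number
#' at the resolutions that bracket the wobble-decoding question:
#' \describe{
#'   \item{isotype}{amino-acid usage vs copies summed per isotype (n = 20)}
#'   \item{isoacceptor}{each sense codon's usage vs its exact cognate
#'     anticodon's copies, 0 for missing anticodons (n = 61)}
#'   \item{graph_grouped}{usage and copies summed over anticodons joined by
#'     arcs of the decoding potential graph (see \code{\link{group_by_arcs}})}
#'   \item{per-wobble levels}{graph grouping restricted to arcs of a single
#'     wobble label}
#' }
#'
#' @param usage a \code{codon_usage}.
#' @param copy_number named numeric vector anticodon -> gene copies.
#' @param g a \code{decoding_graph} (defaults to the graph of the usage's
#'   code with \code{existing = names(copy_number)}).
#' @param graph_mode grouping mode passed to \code{group_by_arcs}.
#' @param log10p1 correlate on log10(x+1) scale instead of raw counts.
#' @return data.frame \code{level}, \code{r}, \code{p}, \code{n}.
#' @export
correlate_levels <- function(usage, copy_number, g = NULL,
                             graph_mode = c("per_arc", "merged_inosine", "component"),
                             log10p1 = FALSE) {
  stopifnot(inherits(usage, "codon_usage"))
  graph_mode <- match.arg(graph_mode)
  code <- usage$code
  if (is.null(g)) g <- build_graph(names(copy_number), code)
  acs <- sense_anticodons(code)
  cn <- stats::setNames(numeric(length(acs)), acs)
  known <- intersect(names(copy_number), acs)
  cn[known] <- copy_number[known]

  # isotype: amino-acid usage vs copies per isotype (20 standard aa)
  iso <- anticodon_isotype(acs, code)
  cn_iso <- tapply(cn, iso, sum)
  aas <- sort(names(usage$aa_counts))
  res_iso <- pearson_with_p(as.numeric(usage$aa_counts[aas]),
                            as.numeric(cn_iso[aas]), log10p1 = log10p1)

  # isoacceptor: codon usage vs exact-anticodon copies over all 61 codons
  cods <- anticodon_to_codon(acs)
  res_acc <- pearson_with_p(as.numeric(usage$counts[cods]), as.numeric(cn),
                            log10p1 = log10p1)

  grouped <- group_by_arcs(g, cn, usage$counts, mode = graph_mode)
  res_grp <- pearson_with_p(grouped$usage, grouped$copies, log10p1 = log10p1)

  rows <- list(
    data.frame(level = "isotype", r = res_iso$r, p = res_iso$p, n = res_iso$n),
    data.frame(level = "isoacceptor", r = res_acc$r, p = res_acc$p, n = res_acc$n),
    data.frame(level = "graph_grouped", r = res_grp$r, p = res_grp$p, n = res_grp$n)
  )
  for (lab in wobble_rules()$label) {
    sub <- grouped[grouped$label == lab | grepl(lab, grouped$label, fixed = TRUE), ,
                   drop = FALSE]
    if (nrow(sub) >= 3L) {
      res <- pearson_with_p(sub$usage, sub$copies, log10p1 = log10p1)
      rows[[length(rows) + 1L]] <-
        data.frame(level = paste0("wobble_", lab), r = res$r, p = res$p, n = res$n)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a codon-usage table as TSV
#'
#' Columns: codon, anticodon, aa, count, per_mille.
#' @param usage a \code{codon_usage}.
#' @param path output file.
#' @export
write_usage_tsv <- function(usage, path) {
  stopifnot(inherits(usage, "codon_usage"))
  total <- sum(usage$counts)
  out <- data.frame(
    codon = names(usage$counts),
    anticodon = codon_to_anticodon(names(usage$counts)),
    aa = unname(usage$code$table[names(usage$counts)]),
    count = unname(usage$counts),
    per_mille = if (total > 0) round(1000 * unname(usage$counts) / total, 3) else 0,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
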