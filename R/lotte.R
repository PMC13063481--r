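#' Hard-mask tRNA genes in a genome
#'
#' Replaces every gene interval by N, leaving all other bases untouched.
#' Masking is idempotent.
#'
#' @param genome named \code{DNAStringSet}, character vector, or FASTA path.
#' @param genes a \code{trna_genes} data.frame.
#' @return \code{DNAStringSet} with masked intervals.
#' @export
mask_genome <- function(genome, genes) {
  genome <- as_dnastringset(genome)
  if (nrow(genes) == 0L) return(genome)
  if (!all(genes$chrom %in% names(genome))) {
    stop("genes on unknown sequences: ",
         paste(setdiff(genes$chrom, names(genome)), collapse = ", "))
  }
  for (ch in unique(genes$chrom)) {
    idx <- which(genes$chrom == ch)
    contig_len <- Biostrings::width(genome)[match(ch, names(genome))]
    if (any(genes$start[idx] < 1L) || any(genes$end[idx] > contig_len)) {
      stop("gene interval out of bounds on ", ch)
    }
    at <- IRanges::reduce(IRanges::IRanges(genes$start[idx], genes$end[idx]))
    genome[[ch]] <- Biostrings::replaceAt(
      genome[[ch]], at, Biostrings::DNAStringSet(strrep("N", IRanges::width(at))))
  }
  genome
}

#' Split reads by length into the short/long mapping routes
#'
#' Post-trim reads of 8-21 nt take the short route (direct mapping to the
#' cluster references), reads of >= 22 nt the long route (masked-genome
#' subtraction first); reads under 8 nt are discarded.
#'
#' @param reads \code{DNAStringSet} or character vector of read sequences.
#' @return list with \code{short}, \code{long}, \code{discarded} (same type
#'   as input subset) and \code{counts}.
#' @export
split_by_length <- function(reads) {
  w <- if (inherits(reads, "XStringSet")) Biostrings::width(reads) else nchar(reads)
  short <- reads[w >= 8L & w <= 21L]
  long <- reads[w >= 22L]
  discarded <- reads[w < 8L]
  list(short = short, long = long, discarded = discarded,
       counts = c(short = length(short), long = length(long),
                  discarded = length(discarded)))
}

# reference-consumed span of a CIGAR string (M/D/N/=/X operations)
cigar_ref_span <- function(cigar) {
  vapply(cigar, function(cg) {
    if (cg == "*") return(0L)
    ops <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1]]
    if (!length(ops) || paste(ops, collapse = "") != cg) {
      stop("malformed CIGAR: ", cg)
    }
    lens <- as.integer(sub("[MIDNSHP=X]$", "", ops))
    kinds <- sub("^[0-9]+", "", ops)
    sum(lens[kinds %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

#' Parse an uncompressed SAM file into alignment records
#'
#' A deliberately small reader for the post-alignment filtering stage:
#' header lines are skipped, the mandatory fields are parsed, the NH tag
#' supplies the hit multiplicity (inferred as 1 with a warning when
#' absent), and the reference span is derived from the CIGAR.
#'
#' @param path SAM file path or character vector of SAM lines.
#' @param keep_unmapped keep records with the unmapped flag (default FALSE).
#' @return data.frame \code{query}, \code{flag}, \code{ref}, \code{pos},
#'   \code{cigar}, \code{aln_span}, \code{multiplicity}, \code{read_seq},
#'   \code{mapped}.
#' @export
parse_sam <- function(path, keep_unmapped = FALSE) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(query = character(0), flag = integer(0),
                      ref = character(0), pos = integer(0),
                      cigar = character(0), aln_span = integer(0),
                      multiplicity = integer(0), read_seq = character(0),
                      mapped = logical(0), stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 11L)) {
    stop("malformed SAM record at line(s): ",
         paste(utils::head(which(nf < 11L), 5), collapse = ", "))
  }
  get <- function(i) vapply(parts, `[[`, character(1), i)
  flag <- as.integer(get(2))
  nh <- vapply(parts, function(p) {
    tag <- grep("^NH:i:", p[-(1:11)], value = TRUE)
    if (length(tag)) as.integer(sub("^NH:i:", "", tag[1])) else NA_integer_
  }, integer(1))
  if (anyNA(nh)) {
    warning(sum(is.na(nh)), " record(s) without NH tag; multiplicity taken as 1")
    nh[is.na(nh)] <- 1L
  }
  out <- data.frame(
    query = get(1), flag = flag, ref = get(3),
    pos = as.integer(get(4)), cigar = get(6),
    aln_span = cigar_ref_span(get(6)),
    multiplicity = nh, read_seq = get(10),
    mapped = bitwAnd(flag, 4L) == 0L,
    stringsAsFactors = FALSE
  )
  if (!keep_unmapped) out <- out[out$mapped, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Validate mature-tRNA alignment records against cluster references
#'
#' A read counts as a valid mature-tRNA observation only when all four
#' criteria hold:
#' \describe{
#'   \item{unique}{the query maps uniquely (NH multiplicity 1)}
#'   \item{past_flank}{the leftmost aligned position lies strictly after the
#'     artificial upstream flank, i.e. \code{pos >= flank_len + 1}}
#'   \item{cca_end}{the stored read sequence ends in "CCA" (the
#'     post-transcriptional tail the protocol selects for)}
#'   \item{reaches_3prime}{the alignment extends to the final base of the
#'     reference, \code{pos + aln_span - 1 == nchar(reference_seq)}}
#' }
#'
#' @param records alignment data.frame from \code{\link{parse_sam}} (mapped
#'   records only).
#' @param clusters an \code{isodecoder_clusters} data.frame; reference
#'   lengths and flank lengths are looked up per record by cluster_id.
#' @return data.frame: the records plus logical columns \code{unique},
#'   \code{past_flank}, \code{cca_end}, \code{reaches_3prime}, \code{valid},
#'   and \code{failed} (comma-joined failed criteria, "" when valid).
#' @export
validate_reads <- function(records, clusters) {
  if (any(!records$mapped)) stop("unmapped records must be filtered out upstream")
  if (is.null(records$aln_span)) records$aln_span <- cigar_ref_span(records$cigar)
  m <- match(records$ref, clusters$cluster_id)
  if (anyNA(m)) {
    stop("records reference unknown cluster(s): ",
         paste(unique(records$ref[is.na(m)]), collapse = ", "))
  }
  ref_len <- nchar(clusters$reference_seq)[m]
  flank <- clusters$flank_len[m]
  ok_unique <- records$multiplicity == 1L
  ok_flank <- records$pos >= flank + 1L
  ok_cca <- endsWith(records$read_seq, "CCA")
  ok_3p <- records$pos + records$aln_span - 1L == ref_len
  crit <- cbind(unique = ok_unique, past_flank = ok_flank,
                cca_end = ok_cca, reaches_3prime = ok_3p)
  failed <- apply(crit, 1L, function(r) paste(colnames(crit)[!r], collapse = ","))
  out <- cbind(records, as.data.frame(crit))
  out$valid <- rowSums(crit) == ncol(crit)
  out$failed <- failed
  out
}

#' Count valid reads per isodecoder cluster
#'
#' Applies \code{\link{validate_reads}} per sample and counts one increment
#' per valid read; invalid reads are tallied by failure reason.
#'
#' @param sam_by_sample named list sample -> SAM path, SAM lines, or a
#'   pre-parsed record data.frame.
#' @param clusters an \code{isodecoder_clusters} data.frame.
#' @return object of class \code{trna_counts}: list with \code{counts}
#'   (integer matrix cluster x sample), \code{level = "cluster"},
#'   \code{feature_info} (cluster metadata), and \code{filter_report}
#'   (data.frame sample, criterion, n_failed, n_valid, n_total).
#' @export
count_clusters <- function(sam_by_sample, clusters) {
  stopifnot(is.list(sam_by_sample), !is.null(names(sam_by_sample)))
  samples <- names(sam_by_sample)
  counts <- matrix(0L, nrow = nrow(clusters), ncol = length(samples),
                   dimnames = list(clusters$cluster_id, samples))
  report <- list()
  for (s in samples) {
    rec <- sam_by_sample[[s]]
    if (!is.data.frame(rec)) rec <- parse_sam(rec)
    if (nrow(rec) > 0L) {
      v <- validate_reads(rec, clusters)
      tab <- table(factor(v$ref[v$valid], levels = clusters$cluster_id))
      counts[, s] <- as.integer(tab)
      fail_tab <- table(factor(unlist(strsplit(v$failed[!v$valid], ",")),
                               levels = c("unique", "past_flank",
                                          "cca_end", "reaches_3prime")))
      report[[s]] <- data.frame(sample = s,
                                criterion = names(fail_tab),
                                n_failed = as.integer(fail_tab),
                                n_valid = sum(v$valid), n_total = nrow(v),
                                stringsAsFactors = FALSE)
    } else {
      report[[s]] <- data.frame(sample = s, criterion = "none",
                                n_failed = 0L, n_valid = 0L, n_total = 0L,
                                stringsAsFactors = FALSE)
    }
  }
  structure(list(counts = counts, level = "cluster",
                 feature_info = clusters[, c("cluster_id", "isotype", "anticodon")],
                 filter_report = do.call(rbind, report)),
            class = "trna_counts")
}

#' Aggregate cluster counts to isoacceptor or isotype level
#'
#' Sums, per sample, the counts of all isodecoder clusters sharing an
#' anticodon (isoacceptor) or an amino acid (isotype). Column totals are
#' conserved.
#'
#' @param m a \code{trna_counts} at cluster level (or any count object whose
#'   \code{feature_info} maps features to groups), or a plain matrix with a
#'   \code{grouping} vector.
#' @param level "isoacceptor" or "isotype".
#' @param grouping optional named vector feature -> group overriding the
#'   \code{feature_info} lookup; must cover every feature.
#' @return a \code{trna_counts} at the requested level.
#' @export
aggregate_counts <- function(m, level = c("isoacceptor", "isotype"),
                             grouping = NULL) {
  level <- match.arg(level)
  counts <- if (inherits(m, "trna_counts")) m$counts else m
  if (is.null(grouping)) {
    if (!inherits(m, "trna_counts")) stop("grouping required for a bare matrix")
    fi <- m$feature_info
    key <- if (level == "isoacceptor") paste(fi$isotype, fi$anticodon, sep = "-")
           else fi$isotype
    grouping <- stats::setNames(key, fi$cluster_id)
  }
  if (!all(rownames(counts) %in% names(grouping))) {
    stop("grouping does not cover: ",
         paste(setdiff(rownames(counts), names(grouping)), collapse = ", "))
  }
  grp <- grouping[rownames(counts)]
  agg <- rowsum(counts, group = grp, reorder = TRUE)
  structure(list(counts = agg, level = level,
                 feature_info = data.frame(feature = rownames(agg),
                                           stringsAsFactors = FALSE),
                 filter_report = if (inherits(m, "trna_counts")) m$filter_report),
            class = "trna_counts")
}

#' Write cluster reference sequences as FASTA
#' @param clusters an \code{isodecoder_clusters} data.frame.
#' @param path output FASTA path.
#' @export
write_cluster_fasta <- function(clusters, path) {
  refs <- Biostrings::DNAStringSet(clusters$reference_seq)
  names(refs) <- clusters$cluster_id
  Biostrings::writeXStringSet(refs, path)
  invisible(path)
}

#' Write alignment records as a minimal SAM file
#'
#' Emits an @HD line, @SQ lines for the given references, and one record per
#' row with an NH tag. Used by the synthetic-data generator.
#'
#' @param records data.frame with \code{query}, \code{ref}, \code{pos},
#'   \code{cigar}, \code{read_seq}, \code{multiplicity}.
#' @param ref_lengths named integer vector reference -> length.
#' @param path output path; when NULL the SAM lines are returned invisibly.
#' @return the SAM lines, invisibly.
#' @export
write_sam <- function(records, ref_lengths, path = NULL) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lengths), ref_lengths))
  body <- sprintf("%s\t0\t%s\t%d\t255\t%s\t*\t0\t0\t%s\t*\tNH:i:%d",
                  records$query, records$ref, records$pos, records$cigar,
                  records$read_seq, records$multiplicity)
  lines <- c(hdr, body)
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
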