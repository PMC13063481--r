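#' The four wobble pairing rules
#'
#' Each rule describes how an anticodon whose wobble base (position 34) is
#' \code{source_wobble} can decode the cognate codon of the anticodon with
#' wobble base \code{target_wobble} and identical bases at positions 35-36.
#' Labels are written anticodon-base-first (base 34 : codon position 3):
#' \describe{
#'   \item{G:U}{G34 reads codons ending in T (target anticodons with A34)}
#'   \item{U:G}{U34 reads codons ending in G (target anticodons with C34)}
#'   \item{I:C}{inosine (genomically A34) reads codons ending in C (target G34)}
#'   \item{I:A}{inosine (genomically A34) reads codons ending in A (target T34)}
#' }
#' Inosine arises by deamination of adenosine at position 34 and is modelled
#' as its genomic precursor A, matching gene-prediction output.
#'
#' @return data.frame with columns \code{label}, \code{source_wobble},
#'   \code{target_wobble}.
#' @export
wobble_rules <- function() {
  data.frame(
    label         = c("G:U", "U:G", "I:C", "I:A"),
    source_wobble = c("G",   "T",   "A",   "A"),
    target_wobble = c("A",   "C",   "G",   "T"),
    stringsAsFactors = FALSE
  )
}

#' Build the decoding potential graph
#'
#' The decoding potential graph is a directed graph on the 61 sense
#' anticodons. An arc source -> target (labelled with a wobble rule) states
#' that the source anticodon can decode the cognate codon of the target
#' anticodon via that wobble pairing; e.g. GTT -> ATT with label G:U says
#' that GTT (tRNA UUG) can read the codon AAT normally read by ATT.
#' Vertices are flagged existing/missing given a genome's anticodon
#' repertoire; the arc set itself depends only on the genetic code.
#'
#' @param existing character vector of anticodons present in the repertoire
#'   (may be empty). Every element must be a sense anticodon.
#' @param code a \code{genetic_code}.
#' @return Object of class \code{decoding_graph}: list with
#'   \item{vertices}{data.frame \code{anticodon}, \code{codon} (cognate),
#'     \code{isotype}, \code{existing} (logical); sorted by anticodon}
#'   \item{arcs}{data.frame \code{source}, \code{target}, \code{label},
#'     \code{nonsynonymous} (logical); sorted by source, target, label}
#' @examples
#' g <- build_graph(existing = c("GTT"))
#' subset(g$arcs, source == "GTT" & target == "ATT")  # the G:U arc
#' @export
build_graph <- function(existing = character(0), code = standard_genetic_code()) {
  existing <- unique(as.character(existing))
  acs <- sense_anticodons(code)
  bad <- setdiff(existing, acs)
  if (length(bad) > 0L) {
    stop("not sense anticodons under this code: ", paste(bad, collapse = ", "))
  }
  vertices <- data.frame(
    anticodon = acs,
    codon     = anticodon_to_codon(acs),
    isotype   = anticodon_isotype(acs, code),
    existing  = acs %in% existing,
    stringsAsFactors = FALSE
  )
  rules <- wobble_rules()
  arcs <- do.call(rbind, lapply(seq_len(nrow(rules)), function(i) {
    src <- acs[wobble_base(acs) == rules$source_wobble[i]]
    tgt <- paste0(rules$target_wobble[i], substr(src, 2L, 3L))
    keep <- tgt %in% acs
    data.frame(source = src[keep], target = tgt[keep],
               label = rules$label[i], stringsAsFactors = FALSE)
  }))
  aa <- function(x) anticodon_isotype(x, code)
  arcs$nonsynonymous <- aa(arcs$source) != aa(arcs$target)
  arcs <- arcs[order(arcs$source, arcs$target, arcs$label), , drop = FALSE]
  rownames(arcs) <- NULL
  structure(list(vertices = vertices, arcs = arcs, code = code),
            class = "decoding_graph")
}

#' @export
print.decoding_graph <- function(x, ...) {
  cat("decoding potential graph:", nrow(x$vertices), "anticodon vertices (",
      sum(x$vertices$existing), "existing /", sum(!x$vertices$existing),
      "missing ),", nrow(x$arcs), "arcs\n")
  print(table(x$arcs$label))
  invisible(x)
}

#' Arcs connecting anticodons of different isotypes
#'
#' Structurally, the standard-code graph contains six such arcs: TAT -> CAT
#' (U:G; Ile reading the Met codon ATG) and five I:A arcs whose sources are
#' the split-box A34 anticodons (AAA, ACT, ATC, ATG, ATT). Those five
#' anticodons are absent from typical eukaryotic repertoires (inosine
#' editing is confined to family boxes), so with \code{existing_only = TRUE}
#' on such a repertoire the unique non-synonymous replacement that can
#' actually occur is Ile(TAT) decoding the Met codon.
#'
#' @param g a \code{decoding_graph}.
#' @param existing_only if TRUE, keep only arcs whose source anticodon is
#'   flagged existing, i.e. replacements the repertoire can realize.
#' @return data.frame of arcs (same columns as \code{g$arcs}), sorted.
#' @export
nonsynonymous_arcs <- function(g, existing_only = FALSE) {
  stopifnot(inherits(g, "decoding_graph"))
  out <- g$arcs[g$arcs$nonsynonymous, , drop = FALSE]
  if (existing_only) {
    ex <- g$vertices$anticodon[g$vertices$existing]
    out <- out[out$source %in% ex, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Missing anticodons compensated by existing ones
#'
#' A missing anticodon counts as compensated when at least one incoming arc
#' with a label in \code{labels} originates from an existing anticodon.
#'
#' @param g a \code{decoding_graph} built with an existing/missing partition.
#' @param labels subset of \code{c("G:U","U:G","I:C","I:A")}.
#' @return sorted character vector of compensated missing anticodons.
#' @export
compensated_missing <- function(g, labels = wobble_rules()$label) {
  stopifnot(inherits(g, "decoding_graph"))
  bad <- setdiff(labels, wobble_rules()$label)
  if (length(bad) > 0L) stop("unknown wobble label(s): ", paste(bad, collapse = ", "))
  ex <- g$vertices$anticodon[g$vertices$existing]
  miss <- g$vertices$anticodon[!g$vertices$existing]
  a <- g$arcs[g$arcs$label %in% labels & g$arcs$source %in% ex, , drop = FALSE]
  sort(intersect(miss, a$target))
}

#' Group copy numbers and codon usage by the arcs of the graph
#'
#' Sums tRNA gene copy numbers and cognate-codon usage over anticodons that
#' are directly connected in the decoding potential graph. Anticodons with
#' no incident arc always form singleton rows (label \code{"none"}).
#'
#' @param g a \code{decoding_graph}.
#' @param copy_number named numeric vector anticodon -> gene copies; missing
#'   anticodons default to 0.
#' @param codon_usage named numeric vector codon -> count, covering the
#'   sense codons.
#' @param mode grouping:
#'   \describe{
#'     \item{per_arc}{one row per arc (copies/usage of source + target)}
#'     \item{merged_inosine}{as per_arc, but I:C and I:A arcs sharing a
#'       source are merged into one row, since both come from the same
#'       inosine-modified anticodon}
#'     \item{component}{one row per weakly connected component; copies and
#'       usage sums over rows then equal the global totals}
#'   }
#' @return data.frame \code{group_id}, \code{copies}, \code{usage},
#'   \code{label}, \code{anticodons} (comma-joined members).
#' @export
group_by_arcs <- function(g, copy_number, codon_usage,
                          mode = c("per_arc", "merged_inosine", "component")) {
  stopifnot(inherits(g, "decoding_graph"))
  mode <- match.arg(mode)
  acs <- g$vertices$anticodon
  cn <- stats::setNames(numeric(length(acs)), acs)
  if (length(copy_number) > 0L) {
    if (any(copy_number < 0)) stop("negative copy numbers")
    known <- intersect(names(copy_number), acs)
    cn[known] <- copy_number[known]
  }
  if (any(codon_usage < 0)) stop("negative codon usage")
  usage_by_ac <- stats::setNames(numeric(length(acs)), acs)
  cods <- anticodon_to_codon(acs)
  hit <- cods %in% names(codon_usage)
  usage_by_ac[hit] <- codon_usage[cods[hit]]

  arcs <- g$arcs
  singletons <- setdiff(acs, unique(c(arcs$source, arcs$target)))
  single_rows <- data.frame(
    group_id = singletons,
    copies = unname(cn[singletons]),
    usage = unname(usage_by_ac[singletons]),
    label = rep("none", length(singletons)),
    anticodons = singletons, stringsAsFactors = FALSE
  )

  rows <- switch(mode,
    per_arc = data.frame(
      group_id = paste0(arcs$source, ">", arcs$target),
      copies = unname(cn[arcs$source] + cn[arcs$target]),
      usage = unname(usage_by_ac[arcs$source] + usage_by_ac[arcs$target]),
      label = arcs$label,
      anticodons = paste(arcs$source, arcs$target, sep = ","),
      stringsAsFactors = FALSE
    ),
    merged_inosine = {
      ino <- arcs$label %in% c("I:C", "I:A")
      plain <- arcs[!ino, , drop = FALSE]
      out <- data.frame(
        group_id = paste0(plain$source, ">", plain$target),
        copies = unname(cn[plain$source] + cn[plain$target]),
        usage = unname(usage_by_ac[plain$source] + usage_by_ac[plain$target]),
        label = plain$label,
        anticodons = paste(plain$source, plain$target, sep = ","),
        stringsAsFactors = FALSE
      )
      if (any(ino)) {
        merged <- do.call(rbind, lapply(split(arcs[ino, , drop = FALSE],
                                              arcs$source[ino]), function(d) {
          members <- unique(c(d$source[1], sort(d$target)))
          data.frame(
            group_id = paste0(d$source[1], ">", paste(sort(d$target), collapse = "+")),
            copies = sum(cn[members]),
            usage = sum(usage_by_ac[members]),
            label = paste(sort(unique(d$label)), collapse = "/"),
            anticodons = paste(members, collapse = ","),
            stringsAsFactors = FALSE
          )
        }))
        out <- rbind(out, merged)
      }
      out
    },
    component = {
      comp <- weak_components(acs, arcs)
      do.call(rbind, lapply(split(names(comp), comp), function(members) {
        members <- sort(members)
        labs <- sort(unique(arcs$label[arcs$source %in% members]))
        data.frame(
          group_id = paste(members, collapse = "+"),
          copies = sum(cn[members]),
          usage = sum(usage_by_ac[members]),
          label = if (length(labs)) paste(labs, collapse = "/") else "none",
          anticodons = paste(members, collapse = ","),
          stringsAsFactors = FALSE
        )
      }))
    }
  )
  out <- if (mode == "component") rows else rbind(rows, single_rows)
  out <- out[order(out$group_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# internal: weakly connected components by union-find over arcs
weak_components <- function(vertices, arcs) {
  parent <- stats::setNames(seq_along(vertices), vertices)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_len(nrow(arcs))) {
    a <- find(match(arcs$source[k], vertices))
    b <- find(match(arcs$target[k], vertices))
    if (a != b) parent[b] <- a
  }
  roots <- vapply(seq_along(vertices), find, integer(1))
  stats::setNames(match(roots, unique(roots)), vertices)
}

#' Pearson correlation with a t-transform p-value
#'
#' Computes Pearson's r and the two-sided p-value from
#' t = r * sqrt((n-2)/(1-r^2)) with n-2 degrees of freedom. A zero-variance
#' input yields a flagged NA result rather than an error, so pipelines over
#' degenerate synthetic repertoires keep running.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param log10p1 if TRUE, correlate log10(x+1) and log10(y+1) instead of
#'   the raw counts (display-scale parity; Pearson on raw counts is the
#'   default).
#' @return list with \code{r}, \code{p}, \code{n}, \code{degenerate}.
#' @export
pearson_with_p <- function(x, y, log10p1 = FALSE) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations")
  if (log10p1) {
    x <- log10(x + 1)
    y <- log10(y + 1)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = n, degenerate = TRUE))
  }
  r <- stats::cor(x, y)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(abs(tval), df = n - 2, lower.tail = FALSE)
  }
  list(r = r, p = p, n = n, degenerate = FALSE)
}

#' Convert a decoding graph to igraph
#'
#' @param g a \code{decoding_graph}.
#' @return an \pkg{igraph} directed graph with vertex attribute
#'   \code{existing} and edge attributes \code{label}, \code{nonsynonymous}.
#' @export
as_igraph <- function(g) {
  stopifnot(inherits(g, "decoding_graph"))
  if (!requireNamespace("igraph", quietly = TRUE)) {
    stop("package 'igraph' is required for as_igraph()")
  }
  igraph::graph_from_data_frame(g$arcs, directed = TRUE, vertices = g$vertices)
}

#' Write the arc list as TSV
#'
#' Columns: source, target, label, nonsynonymous (0/1).
#' @param g a \code{decoding_graph}.
#' @param path output file.
#' @export
write_edge_list <- function(g, path) {
  stopifnot(inherits(g, "decoding_graph"))
  out <- g$arcs
  out$nonsynonymous <- as.integer(out$nonsynonymous)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
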