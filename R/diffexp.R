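#' TMM library scaling factors
#'
#' Trimmed mean of M-values normalization: for each sample against a
#' reference column (the one whose 75th percentile of scaled counts is
#' closest to the mean of those percentiles), log-ratios (M) and average
#' log-abundances (A) are computed over features expressed in both, doubly
#' trimmed (30% on M, 5% on A by default), and combined in a
#' precision-weighted mean. Factors are anchored so that they multiply to 1
#' across samples.
#'
#' @param counts non-negative count matrix, features x samples.
#' @param logratio_trim two-sided trim fraction on M (default 0.3).
#' @param sum_trim two-sided trim fraction on A (default 0.05).
#' @return named numeric vector of scaling factors (geometric mean 1).
#' @export
tmm_factors <- function(counts, logratio_trim = 0.3, sum_trim = 0.05) {
  counts <- as.matrix(counts)
  lib <- colSums(counts)
  if (any(lib == 0)) {
    stop("all-zero sample(s): ",
         paste(colnames(counts)[lib == 0], collapse = ", "))
  }
  uq <- apply(counts, 2L, function(x) stats::quantile(x[x > 0], 0.75))
  ref <- which.min(abs(uq / lib - mean(uq / lib)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    if (j == ref) return(1)
    tmm_pair(counts[, j], counts[, ref], lib[j], lib[ref],
             logratio_trim, sum_trim)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(counts))
}

# pairwise TMM factor of obs against ref (both raw count vectors)
tmm_pair <- function(obs, ref, n_obs, n_ref, logratio_trim, sum_trim) {
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  if (!length(obs)) return(1)
  p_o <- obs / n_obs; p_r <- ref / n_ref
  M <- log2(p_o / p_r)
  A <- (log2(p_o) + log2(p_r)) / 2
  # asymptotic variance of M (delta method), as in standard TMM weighting
  w <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  if (max(abs(M)) < 1e-6) return(1)
  n <- length(M)
  loM <- floor(n * logratio_trim) + 1L; hiM <- n + 1L - loM
  loA <- floor(n * sum_trim) + 1L; hiA <- n + 1L - loA
  keep2 <- rank(M, ties.method = "first") >= loM &
    rank(M, ties.method = "first") <= hiM &
    rank(A, ties.method = "first") >= loA &
    rank(A, ties.method = "first") <= hiA
  if (!any(keep2)) return(1)
  2^(sum(M[keep2] / w[keep2]) / sum(1 / w[keep2]))
}

#' Negative-binomial differential expression between two stages
#'
#' A deliberately lightweight stand-in for a full GLM package: counts are
#' normalized by TMM-scaled effective library sizes, a common dispersion is
#' estimated by the method of moments across features and each feature's
#' moment estimate is shrunk toward it, and a two-sided p-value comes from
#' an exact-style conditional comparison of the two groups' summed
#' pseudo-counts under the negative binomial. Holm correction is applied
#' across features within the contrast; significance yields a sign call.
#'
#' @param m a \code{trna_counts} (with a \code{samples} data.frame mapping
#'   sample -> stage) or a plain count matrix plus \code{stages}.
#' @param contrast length-2 character vector \code{c(stageA, stageB)}; the
#'   reported logFC is log2 of B relative to A, so a positive call means
#'   up-regulation across the A -> B transition.
#' @param stages named vector sample -> stage (required for a bare matrix).
#' @param alpha significance level on the Holm-adjusted p (default 0.05).
#' @param shrink weight of the common dispersion in the per-feature
#'   dispersion (0 = pure per-feature moments, 1 = common only; default 0.7,
#'   reflecting that with 3 replicates per group the per-feature moment
#'   estimate is noisy).
#' @return data.frame of class \code{de_result}: \code{feature},
#'   \code{contrast}, \code{logFC}, \code{p}, \code{p_adj}, \code{call}
#'   (-1/0/+1).
#' @export
nb_test <- function(m, contrast, stages = NULL, alpha = 0.05, shrink = 0.7) {
  if (inherits(m, "trna_counts")) {
    counts <- m$counts
    if (is.null(stages)) stages <- m$stage_map
  } else counts <- as.matrix(m)
  if (is.null(stages)) stop("a sample -> stage map is required")
  stopifnot(length(contrast) == 2L)
  sel_a <- names(stages)[stages == contrast[1]]
  sel_b <- names(stages)[stages == contrast[2]]
  if (length(sel_a) < 2L || length(sel_b) < 2L) {
    stop("both stages need >= 2 samples (got ", length(sel_a), " and ",
         length(sel_b), ")")
  }
  sub <- counts[, c(sel_a, sel_b), drop = FALSE]
  eff <- colSums(sub) * tmm_factors(sub)
  mean_eff <- exp(mean(log(eff)))
  # pseudo-counts on a common library scale
  pseudo <- sweep(sub, 2L, mean_eff / eff, `*`)
  a <- pseudo[, sel_a, drop = FALSE]
  b <- pseudo[, sel_b, drop = FALSE]
  na <- length(sel_a); nb <- length(sel_b)

  mu_a <- rowMeans(a); mu_b <- rowMeans(b)
  v_a <- apply(a, 1L, stats::var); v_b <- apply(b, 1L, stats::var)
  # per-feature method-of-moments dispersion pooled over the two groups
  mu_pool <- (na * mu_a + nb * mu_b) / (na + nb)
  v_pool <- (v_a * (na - 1) + v_b * (nb - 1)) / (na + nb - 2)
  disp_i <- (v_pool - mu_pool) / mu_pool^2
  disp_i[!is.finite(disp_i) | disp_i < 0] <- 0
  common <- if (any(mu_pool > 0)) mean(disp_i[mu_pool > 0]) else 0
  disp <- shrink * common + (1 - shrink) * disp_i

  s_a <- round(rowSums(a)); s_b <- round(rowSums(b))
  p <- vapply(seq_len(nrow(sub)), function(i) {
    nb_exact_p(s_a[i], s_b[i], na, nb, disp[i])
  }, numeric(1))
  logFC <- log2((mu_b + 0.5) / (mu_a + 0.5))
  zero <- rowSums(sub) == 0
  p[zero] <- 1; logFC[zero] <- 0
  p_adj <- stats::p.adjust(p, method = "holm")
  call <- ifelse(p_adj <= alpha & logFC != 0, sign(logFC), 0)
  out <- data.frame(feature = rownames(sub),
                    contrast = paste(contrast, collapse = ">"),
                    logFC = logFC, p = p, p_adj = p_adj, call = as.integer(call),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("de_result", "data.frame")
  out
}

# two-sided exact-style NB test: conditional on the total T = sA + sB, sum
# the probabilities of all splits no more likely than the observed one.
# Group sums of n iid NB(mu, disp) counts are NB(n*mu, disp/n).
nb_exact_p <- function(s_a, s_b, na, nb, disp) {
  total <- s_a + s_b
  if (total == 0) return(1)
  mu <- total / (na + nb)
  if (total > 200000) {
    # normal fallback for huge totals, where enumeration is wasteful;
    # variance of the group-A sum of NB counts at the pooled mean
    va <- na * mu * (1 + mu * disp)
    z <- (s_a - na * mu) / sqrt(va)
    return(min(1, 2 * stats::pnorm(-abs(z))))
  }
  y <- 0:total
  if (disp <= 1e-8) {
    lp <- stats::dpois(y, na * mu, log = TRUE) +
      stats::dpois(total - y, nb * mu, log = TRUE)
  } else {
    lp <- stats::dnbinom(y, size = na / disp, mu = na * mu, log = TRUE) +
      stats::dnbinom(total - y, size = nb / disp, mu = nb * mu, log = TRUE)
  }
  lp <- lp - max(lp)
  pr <- exp(lp); pr <- pr / sum(pr)
  obs <- pr[s_a + 1L]
  min(1, sum(pr[pr <= obs + 1e-12]))
}

#' Tabulate up/down/unchanged proportions per level and transition
#'
#' @param results named list: level -> list of \code{de_result} data.frames
#'   (one per transition), or level -> single \code{de_result}.
#' @param transitions optional ordering of the contrasts in the output.
#' @return data.frame \code{level}, \code{transition}, \code{up},
#'   \code{down}, \code{unchanged} (counts) and \code{prop_up},
#'   \code{prop_down}, \code{prop_unchanged}.
#' @export
transition_report <- function(results, transitions = NULL) {
  rows <- list()
  for (lvl in names(results)) {
    parts <- results[[lvl]]
    if (is.data.frame(parts)) parts <- list(parts)
    for (d in parts) {
      for (tr in unique(d$contrast)) {
        sub <- d[d$contrast == tr, , drop = FALSE]
        n <- nrow(sub)
        up <- sum(sub$call == 1L); down <- sum(sub$call == -1L)
        rows[[length(rows) + 1L]] <- data.frame(
          level = lvl, transition = tr, up = up, down = down,
          unchanged = n - up - down,
          prop_up = up / n, prop_down = down / n,
          prop_unchanged = (n - up - down) / n,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(transitions)) {
    out <- out[order(match(out$transition, transitions), out$level), ,
               drop = FALSE]
  }
  rownames(out) <- NULL
  out
}
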