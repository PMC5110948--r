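#' Average log-likelihood ratio between two motif columns
#'
#' `ALLR(c1, c2) = (sum_k N2_k ln(f1_k/f0_k) + sum_k N1_k ln(f2_k/f0_k)) /
#' (sum_k N1_k + N2_k)`, with frequencies pseudocount-smoothed from the
#' counts. Symmetric in its two arguments; zero when both columns match the
#' background.
#'
#' @param n1,n2 length-4 count vectors (A,C,G,T).
#' @param f0 background base frequencies.
#' @param eps pseudocount used to form column frequencies.
#' @return scalar.
#' @export
allr_column <- function(n1, n2, f0, eps = 1) {
  stopifnot(length(n1) == 4L, length(n2) == 4L, sum(n1) >= 0, sum(n2) >= 0)
  if (sum(n1) + sum(n2) == 0) return(0)   # two evidence-free columns
  f1 <- (n1 + eps) / (sum(n1) + 4 * eps)
  f2 <- (n2 + eps) / (sum(n2) + 4 * eps)
  (sum(n2 * log(f1 / f0)) + sum(n1 * log(f2 / f0))) / (sum(n1) + sum(n2))
}

#' ALLR similarity between two motifs over all overlaps
#'
#' Maximizes the summed column [allr_column()] over all offset pairs whose
#' overlap length is at least `min_overlap` (6 columns by default). Ties go
#' to the smallest `w1`, then `w2`.
#'
#' @param m1,m2 `epp_motif` objects (width >= `min_overlap`).
#' @param B a `markov_bg` (marginals used).
#' @param min_overlap minimum aligned segment length.
#' @param eps pseudocount.
#' @return list with `sim` (maximal summed ALLR) and `alignment`: list
#'   `(w1, w2, length)` of 1-based start columns and overlap length.
#' @export
motif_similarity <- function(m1, m2, B, min_overlap = 6L, eps = 1) {
  l1 <- m1$width
  l2 <- m2$width
  # motifs narrower than the canonical 6-column segment align full-width
  min_overlap <- min(min_overlap, l1, l2)
  best <- list(sim = -Inf, alignment = NULL)
  for (shift in (-(l2 - min_overlap)):(l1 - min_overlap)) {
    w1 <- max(1L, 1L + shift)
    w2 <- max(1L, 1L - shift)
    ls <- min(l1 - w1, l2 - w2) + 1L
    if (ls < min_overlap) next
    s <- 0
    for (h in 0:(ls - 1L)) {
      s <- s + allr_column(m1$counts[w1 + h, ], m2$counts[w2 + h, ],
                           B$f0, eps = eps)
    }
    if (s > best$sim) {
      best <- list(sim = s, alignment = list(w1 = w1, w2 = w2, length = ls))
    }
  }
  best
}

#' Combine two aligned motifs into a longer motif
#'
#' Columns are laid out on the common coordinate system implied by the
#' alignment. Member sites are the union of both motifs\' sites (duplicated
#' genomic sites dropped), each re-anchored by its source motif\'s column
#' offset, and the combined count matrix is rebuilt from those deduplicated
#' sites — a site discovered by both inputs is counted once, so combining
#' two routes to the same motif does not artificially sharpen its PFM.
#' Columns covered by only one source keep that source\'s evidence. The
#' combined IC is the members\' dependency-aware IC when all sites span the
#' full width, otherwise (ragged coverage) the PFM-column relative entropy
#' against the background marginals.
#'
#' @param m1,m2 `epp_motif` objects.
#' @param alignment alignment list from [motif_similarity()].
#' @param B a `markov_bg`.
#' @param eps pseudocount.
#' @return a combined `epp_motif` whose width is at least the wider input.
#' @export
combine_motifs <- function(m1, m2, alignment, B, eps = 1) {
  shift <- alignment$w1 - alignment$w2     # column 1 of m2 in m1 coordinates
  start1 <- 1L
  start2 <- 1L + shift
  lo <- min(start1, start2)
  hi <- max(start1 + m1$width - 1L, start2 + m2$width - 1L)
  width <- hi - lo + 1L
  s1 <- m1$sites
  s1$offset <- (start1 - lo) + 1L
  s2 <- m2$sites
  s2$offset <- (start2 - lo) + 1L
  sites <- rbind(s1, s2)
  sites <- sites[!duplicated(sites[, c("seq_index", "start")]), ]
  sites <- sites[order(sites$seq_index, sites$start), ]
  rownames(sites) <- NULL
  counts <- matrix(0, width, 4L)
  for (i in seq_len(nrow(sites))) {
    v <- encode_seq(sites$text[i])
    cols <- sites$offset[i] + seq_along(v) - 1L
    counts[cbind(cols, v)] <- counts[cbind(cols, v)] + 1
  }
  freqs <- (counts + eps) / (rowSums(counts) + 4 * eps)
  uniform_span <- length(unique(sites$offset)) == 1L &&
    length(unique(nchar(sites$text))) == 1L
  ic <- if (uniform_span) {
    ic_dependent(sites$text, B, eps = eps)
  } else {
    term <- freqs * log(sweep(freqs, 2, B$f0, "/"))
    sum(term)
  }
  cons <- decode_ints(apply(counts, 1L, which.max))
  structure(list(idx = NULL, counts = counts, freqs = freqs,
                 width = width, ic = ic, ic_trace = NULL,
                 consensus = cons, sites = sites,
                 n_members = nrow(sites), combined = TRUE),
            class = "epp_motif")
}

#' Maintain the top-u motif list with similarity-aware insertion
#'
#' Streams motifs into a bounded list: a new motif that duplicates a stored
#' one is combined with it — repeatedly, until no duplicate remains —
#' otherwise it is inserted, evicting the minimum-IC motif once the list
#' holds `u` entries and the newcomer scores higher. Two motifs count as
#' redundant when (i) their ALLR similarity reaches `sim_frac` times the
#' smaller of the two self-similarities and (ii) the maximizing alignment
#' is nested: the overlap covers the narrower motif completely. The nesting
#' requirement separates true redundancy (the same motif re-discovered, or
#' a short motif contained in a longer composite) from distinct shift
#' registers of one motif, whose optimal alignment is always a proper
#' partial overlap and whose relative similarity can exceed any fixed
#' threshold. The result is IC-descending.
#'
#' @param motifs list of `epp_motif` objects, in stream order.
#' @param u list capacity (default 20).
#' @param B a `markov_bg`.
#' @param sim_frac similarity threshold as a fraction of the smaller
#'   self-similarity (default 0.7).
#' @param min_overlap minimal aligned segment for similarity.
#' @param eps pseudocount.
#' @return list of at most `u` motifs, IC-descending.
#' @export
maintain_top <- function(motifs, u = 20L, B, sim_frac = 0.7,
                         min_overlap = 6L, eps = 1) {
  stopifnot(u >= 1L)
  selfsim <- function(m)
    motif_similarity(m, m, B, min_overlap = min_overlap, eps = eps)$sim
  kept <- list()
  kept_self <- numeric(0)
  for (m in motifs) {
    m_self <- selfsim(m)
    repeat {
      if (length(kept) == 0L) break
      sims <- numeric(length(kept))
      aligns <- vector("list", length(kept))
      for (j in seq_along(kept)) {
        ms <- motif_similarity(m, kept[[j]], B, min_overlap = min_overlap,
                               eps = eps)
        sims[j] <- ms$sim
        aligns[[j]] <- ms$alignment
      }
      thr <- sim_frac * pmin(m_self, kept_self)
      nested <- vapply(seq_along(kept), function(j) {
        al <- aligns[[j]]
        al$length >= min(m$width, kept[[j]]$width)
      }, logical(1))
      hit <- which(sims >= thr & nested)
      if (length(hit) == 0L) break
      j <- hit[which.max(sims[hit])]
      m <- combine_motifs(m, kept[[j]], aligns[[j]], B, eps = eps)
      kept <- kept[-j]
      kept_self <- kept_self[-j]
      m_self <- selfsim(m)
    }
    if (length(kept) < u) {
      kept[[length(kept) + 1L]] <- m
      kept_self <- c(kept_self, m_self)
    } else {
      ics <- vapply(kept, function(k) k$ic, numeric(1))
      if (m$ic > min(ics)) {
        j <- which.min(ics)
        kept[[j]] <- m
        kept_self[j] <- m_self
      }
    }
  }
  kept[order(-vapply(kept, function(k) k$ic, numeric(1)))]
}

#' Trim a motif to the maximum-information window of a fixed width
#'
#' Combining shift-register rediscoveries widens a motif beyond the
#' requested width; the informative core is the width-`l` column window of
#' maximal summed relative entropy. Each member site is re-anchored through
#' its column offset to the genomic window under the trimmed columns and
#' resolved back to the corresponding l-mer, so all registers of one
#' instance collapse to a single site. Motifs no wider than `l` are
#' returned unchanged.
#'
#' @param m an `epp_motif`.
#' @param l target width.
#' @param X the [extract_lmers()] set of the same discovery run.
#' @param B a `markov_bg`.
#' @param eps pseudocount.
#' @return an `epp_motif` of width `min(width, l)`.
#' @export
trim_motif <- function(m, l, X, B, eps = 1) {
  if (m$width <= l) return(m)
  colic <- rowSums(m$freqs * log(sweep(m$freqs, 2, B$f0, "/")))
  winic <- vapply(seq_len(m$width - l + 1L),
                  function(w) sum(colic[w:(w + l - 1L)]), numeric(1))
  w0 <- which.max(winic)
  offs <- if (is.null(m$sites$offset)) rep(1L, nrow(m$sites)) else
    m$sites$offset
  start2 <- m$sites$start - (offs - 1L) + (w0 - 1L)
  idx <- unique(vapply(seq_along(start2), function(i) {
    j <- which(X$seq_index == m$sites$seq_index[i] &
                 X$start == start2[i])
    if (length(j) == 1L) j else NA_integer_
  }, integer(1)))
  idx <- idx[!is.na(idx)]
  if (length(idx) < 2L) return(m)
  .make_motif(X, idx, B, eps = eps)
}
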