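#' Subset-size thresholds for a sequence model
#'
#' Defaults follow the sequence-model semantics: OOPS (one occurrence per
#' sequence) takes `max_size = t`, `min_size = floor(3t/4)`; ZOOPS takes
#' `max_size = t`, `min_size = floor(t/2)`; TCM takes
#' `max_size = floor(3t/2)`, `min_size = t`. Explicit overrides replace the
#' formula values.
#'
#' @param model one of `"OOPS"`, `"ZOOPS"`, `"TCM"`.
#' @param t number of sequences.
#' @param min_size,max_size optional explicit overrides.
#' @return list with integer `min_size` and `max_size`.
#' @export
thresholds_for_model <- function(model = c("OOPS", "ZOOPS", "TCM"), t,
                                 min_size = NULL, max_size = NULL) {
  model <- match.arg(model)
  stopifnot(t >= 1L)
  def <- switch(model,
    OOPS  = c(floor(3 * t / 4), t),
    ZOOPS = c(floor(t / 2), t),
    TCM   = c(t, floor(3 * t / 2)))
  out <- list(min_size = as.integer(if (is.null(min_size)) def[1] else min_size),
              max_size = as.integer(if (is.null(max_size)) def[2] else max_size))
  out$min_size <- max(1L, out$min_size)
  if (out$min_size > out$max_size)
    stop("min_size must not exceed max_size")
  out
}

# Relative entropy per column of the l-mers indexed by `idx`, with
# eps-pseudocounts, against the background marginals.
.subset_entropy <- function(mat, idx, B, eps = 1) {
  F <- build_pfm(mat[idx, , drop = FALSE], eps = eps)
  position_entropy(F, B)
}

#' Select the projection position of a subset
#'
#' The column of maximal relative entropy (subset PFM vs background
#' marginals) among positions not already fixed along the subset's
#' projection path; ties broken by the smallest position index.
#'
#' @param X an [extract_lmers()] set.
#' @param idx row indices of the subset's members.
#' @param fixed integer vector of positions already fixed on this path.
#' @param B a `markov_bg`.
#' @param eps PFM pseudocount.
#' @return integer position in `1..l`.
#' @export
select_projection_position <- function(X, idx, fixed = integer(0), B,
                                       eps = 1) {
  free <- setdiff(seq_len(X$l), fixed)
  if (length(free) == 0L)
    stop("all positions fixed: subset cannot be split further")
  H <- .subset_entropy(X$mat, idx, B, eps = eps)
  free[which.max(H[free])]
}

#' Split a subset by its base at a position
#'
#' Partitions members into four children by the observed base at column
#' `q`, in alphabet order A, C, G, T. Children are pairwise disjoint and
#' their union is the parent.
#'
#' @param X an [extract_lmers()] set.
#' @param idx parent member indices.
#' @param q split position.
#' @return list of four integer vectors, named A, C, G, T.
#' @export
split_at <- function(X, idx, q) {
  b <- X$mat[idx, q]
  out <- lapply(1:4, function(k) idx[b == k])
  names(out) <- DNA_BASES
  out
}

#' Entropy-guided cluster projection of the l-mer set
#'
#' Breadth-first recursive partition of all l-mers: a subset smaller than
#' `min_size` is dropped; one larger than `max_size` is split at its maximal
#' relative-entropy position (excluding positions fixed along its path);
#' one inside the window is emitted as a candidate. Fully deterministic:
#' FIFO worklist, children in alphabet order, entropy ties to the smallest
#' position. A subset whose path has fixed every position but that still
#' exceeds `max_size` (a degenerate repeat such as a homopolymer run) is
#' emitted with a warning flag.
#'
#' @param X an [extract_lmers()] set.
#' @param B a `markov_bg`.
#' @param min_size,max_size candidate size window.
#' @param eps PFM pseudocount for entropy computation.
#' @return list with `candidates` (each a list with `idx`, `fixed` — a
#'   two-column matrix of (position, base code) pairs — `depth` and
#'   `overflow` flag), `tree` (per-node accounting data frame) and
#'   `n_dropped` (l-mers lost to undersized subsets).
#' @export
project <- function(X, B, min_size, max_size, eps = 1) {
  stopifnot(inherits(X, "lmer_set"), nrow(X$mat) >= 1L,
            min_size >= 1L, min_size <= max_size)
  queue <- list(list(idx = seq_len(nrow(X$mat)),
                     fixed = matrix(integer(0), 0L, 2L), depth = 0L))
  head <- 1L
  candidates <- list()
  tr_depth <- integer(0); tr_size <- integer(0)
  tr_action <- character(0); tr_fixed <- character(0)
  n_dropped <- 0L
  while (head <= length(queue)) {
    node <- queue[[head]]
    head <- head + 1L
    s <- length(node$idx)
    action <- NULL
    if (s < min_size) {
      action <- "dropped"
      n_dropped <- n_dropped + s
    } else if (s <= max_size) {
      action <- "emitted"
      candidates[[length(candidates) + 1L]] <-
        list(idx = node$idx, fixed = node$fixed, depth = node$depth,
             overflow = FALSE)
    } else {
      free <- setdiff(seq_len(X$l), node$fixed[, 1L])
      if (length(free) == 0L) {
        action <- "emitted_overflow"
        warning("subset at full projection depth still exceeds max_size (",
                s, " members); emitted as degenerate candidate")
        candidates[[length(candidates) + 1L]] <-
          list(idx = node$idx, fixed = node$fixed, depth = node$depth,
               overflow = TRUE)
      } else {
        H <- .subset_entropy(X$mat, node$idx, B, eps = eps)
        q <- free[which.max(H[free])]
        children <- split_at(X, node$idx, q)
        if (all(lengths(children) < min_size)) {
          # unsplittable: dividing would annihilate a coherent cluster, so
          # keep the parent as an oversized candidate
          action <- "emitted_overflow"
          candidates[[length(candidates) + 1L]] <-
            list(idx = node$idx, fixed = node$fixed, depth = node$depth,
                 overflow = TRUE)
        } else {
          for (k in 1:4) {
            queue[[length(queue) + 1L]] <-
              list(idx = children[[k]],
                   fixed = rbind(node$fixed, c(q, k)),
                   depth = node$depth + 1L)
          }
          action <- paste0("split@", q)
        }
      }
    }
    tr_depth <- c(tr_depth, node$depth)
    tr_size <- c(tr_size, s)
    tr_action <- c(tr_action, action)
    tr_fixed <- c(tr_fixed,
                  paste(paste0(node$fixed[, 1L], DNA_BASES[node$fixed[, 2L]]),
                        collapse = ","))
  }
  list(candidates = candidates,
       tree = data.frame(depth = tr_depth, size = tr_size,
                         action = tr_action, fixed = tr_fixed),
       n_dropped = n_dropped)
}
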