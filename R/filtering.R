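#' Single-string complexity score
#'
#' The inverse-multinomial complexity `C(x) = (1/4^l) * l! / prod_k(n_k!)`
#' with `n_k` the count of base `k` in `x`: maximal for balanced base
#' composition, minimal (`4^-l`) for homopolymers. Used to down-weight
#' low-complexity repeat subsets during candidate filtering.
#'
#' @param x an l-mer as a string or integer code vector, or an integer
#'   matrix (one row per l-mer).
#' @return numeric vector of scores in `(0, 1]`.
#' @export
complexity_score <- function(x) {
  if (is.character(x)) {
    return(vapply(x, function(s) complexity_score(encode_seq(s)),
                  numeric(1), USE.NAMES = FALSE))
  }
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  l <- ncol(x)
  vapply(seq_len(nrow(x)), function(i) {
    nk <- tabulate(x[i, ], nbins = 4L)
    exp(lfactorial(l) - sum(lfactorial(nk)) - l * log(4))
  }, numeric(1))
}

#' Mean complexity of a candidate subset
#'
#' @param X an [extract_lmers()] set.
#' @param idx member row indices.
#' @return scalar: arithmetic mean of [complexity_score()] over members.
#' @export
subset_complexity <- function(X, idx) {
  mean(complexity_score(X$mat[idx, , drop = FALSE]))
}

#' Filter candidate subsets by complexity and information content
#'
#' Scores every candidate by its mean member complexity `J(m)` and its
#' dependency-aware information content `I(m)`, then retains subsets that
#' are information-content outliers without being low-complexity outliers,
#' using a fraction `alpha` of the score radii
#' `phi = max deviation from the mean`: a subset qualifies when
#' `I(m) - Ibar > alpha * phi_IC` (its information content stands above the
#' candidate pool by a margin) and `J(m) - Jbar >= -alpha * phi_J` (its
#' complexity is not an outlier on the low side — the complexity score
#' exists to discard repeat-dominated subsets such as homopolymer or
#' dinucleotide runs, whose inverse-multinomial score collapses).
#' The maximal-`I` subset is always retained, which also guarantees a
#' non-empty result when the criterion selects nothing (e.g. a single
#' candidate, or all candidates identical, where both radii are zero).
#'
#' @param candidates list of candidate subsets from [project()].
#' @param X an [extract_lmers()] set.
#' @param B a `markov_bg`.
#' @param alpha radius fraction in `(0, 1]` (default 0.5).
#' @param eps pseudocount for PFMs and pair tables.
#' @param keep_top also retain at least the `keep_top` highest-`I`
#'   candidates regardless of the radius criterion (0 disables). The
#'   discovery pipeline sets this to its output capacity `u`: producing the
#'   top `u` motifs requires refining at least `u` candidate subsets, and
#'   the filter is a cost bound, not a verdict.
#' @return list with `qualified` (the retained subsets, a subsequence of
#'   `candidates`) and `scores` (data frame: candidate, size, J, I,
#'   qualified flag).
#' @export
filter_candidates <- function(candidates, X, B, alpha = 0.5, eps = 1,
                              keep_top = 0L) {
  stopifnot(length(candidates) >= 1L, alpha > 0, alpha <= 1)
  J <- vapply(candidates, function(cc) subset_complexity(X, cc$idx),
              numeric(1))
  I <- vapply(candidates, function(cc)
    ic_dependent(X$mat[cc$idx, , drop = FALSE], B, eps = eps), numeric(1))
  Jbar <- mean(J)
  Ibar <- mean(I)
  phi_J <- max(max(J) - Jbar, min(J) - Jbar)
  phi_IC <- max(max(I) - Ibar, min(I) - Ibar)
  pass <- (I - Ibar > alpha * phi_IC) & (J - Jbar >= -alpha * phi_J)
  pass[which.max(I)] <- TRUE
  if (keep_top > 0L)
    pass[order(-I)[seq_len(min(keep_top, length(I)))]] <- TRUE
  scores <- data.frame(candidate = seq_along(candidates),
                       size = vapply(candidates, function(cc)
                         length(cc$idx), integer(1)),
                       J = J, I = I, qualified = pass)
  list(qualified = candidates[pass], scores = scores)
}
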