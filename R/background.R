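#' Estimate a Markov background model from a sequence set
#'
#' Fits conditional base probabilities of order 0..`order` by counting
#' (context, base) occurrences over all sequences, with add-pseudocount
#' smoothing. A context that was never observed falls back to the
#' next-lower-order distribution. Order 3 is the default background used by
#' the discovery pipeline.
#'
#' @param S a [seq_set()].
#' @param order Markov order, 0..3.
#' @param pseudocount added to every (context, base) cell.
#' @return An object of class `markov_bg`: list with `order`, `f0` (marginal
#'   base frequencies, A,C,G,T) and `cond`, a list whose element `o + 1` is a
#'   `4^o x 4` matrix of conditional probabilities for order `o` (contexts
#'   indexed by base-4 encoding of the preceding bases, most recent base
#'   last).
#' @export
estimate_background <- function(S, order = 3L, pseudocount = 0.25) {
  stopifnot(inherits(S, "seq_set"), order %in% 0:3, pseudocount >= 0)
  enc <- lapply(S$seq, encode_seq)
  cond <- vector("list", order + 1L)
  for (o in 0:order) {
    counts <- matrix(0, nrow = 4L^o, ncol = 4L)
    for (v in enc) {
      n <- length(v)
      if (n < o + 1L) next
      pos <- seq.int(o + 1L, n)
      ctx <- rep.int(1L, length(pos))
      if (o > 0L) {
        ctx <- 0L
        for (j in seq_len(o)) ctx <- ctx * 4L + (v[pos - o + j - 1L] - 1L)
        ctx <- ctx + 1L
      }
      ok <- !is.na(ctx) & !is.na(v[pos])
      if (any(ok)) {
        tab <- table(factor(ctx[ok], levels = seq_len(4L^o)),
                     factor(v[pos][ok], levels = 1:4))
        counts <- counts + unclass(tab)
      }
    }
    probs <- (counts + pseudocount) /
      (rowSums(counts) + 4 * pseudocount)
    # unobserved contexts inherit the lower-order distribution
    if (o > 0L) {
      empty <- rowSums(counts) == 0
      if (any(empty)) {
        lower <- cond[[o]]
        for (r in which(empty)) {
          parent <- ((r - 1L) %% 4L^(o - 1L)) + 1L
          probs[r, ] <- lower[parent, ]
        }
      }
    }
    cond[[o + 1L]] <- probs
  }
  structure(list(order = as.integer(order), f0 = as.numeric(cond[[1L]]),
                 cond = cond, pseudocount = pseudocount),
            class = "markov_bg")
}

#' Uniform background model
#'
#' Convenience constructor for an order-0 background with equal base
#' frequencies; useful for tests and closed-form checks.
#'
#' @return A `markov_bg` of order 0 with `f0 = rep(0.25, 4)`.
#' @export
uniform_background <- function() {
  structure(list(order = 0L, f0 = rep(0.25, 4),
                 cond = list(matrix(0.25, 1L, 4L)), pseudocount = 0),
            class = "markov_bg")
}

#' @export
print.markov_bg <- function(x, ...) {
  cat("markov_bg: order", x$order, " f0 =",
      paste(sprintf("%.3f", x$f0), collapse = " "), "\n")
  invisible(x)
}

# Context indices (1-based) for position w of integer-coded rows in `mat`
# under order o: encodes bases at columns (w-o)..(w-1).
.context_index <- function(mat, w, o) {
  if (o == 0L) return(rep.int(1L, nrow(mat)))
  ctx <- 0L
  for (j in seq_len(o)) ctx <- ctx * 4L + (mat[, w - o + j - 1L] - 1L)
  ctx + 1L
}

#' Log-probability of l-mers under the background model
#'
#' Chain of conditionals: position 1 uses the order-0 marginal, position 2
#' order 1, position 3 order 2, and positions 4..l the full model order
#' (capped at the model's own order).
#'
#' @param x an l-mer as a string, an integer code vector, or an integer
#'   matrix (one row per l-mer).
#' @param B a [estimate_background()] model.
#' @return numeric vector of natural-log probabilities, one per l-mer.
#' @export
background_logprob <- function(x, B) {
  stopifnot(inherits(B, "markov_bg"))
  if (is.character(x)) x <- encode_seq(x)
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  l <- ncol(x)
  lp <- numeric(nrow(x))
  for (w in seq_len(l)) {
    o <- min(w - 1L, B$order)
    ctx <- .context_index(x, w, o)
    lp <- lp + log(B$cond[[o + 1L]][cbind(ctx, x[, w])])
  }
  lp
}
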