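#' Build a position frequency matrix from aligned members
#'
#' Counts bases per column and converts to frequencies with pseudocounts:
#' `f[w,k] = (N[w,k] + eps) / (sum_k N[w,k] + 4*eps)`.
#'
#' @param members integer code matrix (rows = aligned l-mers), or a character
#'   vector of equal-length strings.
#' @param eps pseudocount (default 1).
#' @return An object of class `pfm`: list with `counts` and `freqs`
#'   (`l x 4` matrices, columns A,C,G,T), `eps`, `n_members`, `l`.
#' @export
build_pfm <- function(members, eps = 1) {
  mat <- as_member_matrix(members)
  l <- ncol(mat)
  counts <- t(vapply(seq_len(l),
                     function(w) tabulate(mat[, w], nbins = 4L),
                     numeric(4)))
  freqs <- (counts + eps) / (rowSums(counts) + 4 * eps)
  structure(list(counts = counts, freqs = freqs, eps = eps,
                 n_members = nrow(mat), l = l),
            class = "pfm")
}

# Accept strings or an integer matrix of aligned members.
as_member_matrix <- function(members) {
  if (is.character(members)) {
    l <- unique(nchar(members))
    if (length(l) != 1L) stop("members must have equal length")
    members <- t(vapply(members, encode_seq, numeric(l)))
    if (anyNA(members)) stop("members contain non-ACGT characters")
    members <- matrix(as.integer(members), ncol = l)
  }
  if (!is.matrix(members) || nrow(members) < 1L)
    stop("members must be a non-empty matrix or character vector")
  members
}

#' @export
print.pfm <- function(x, ...) {
  cat("pfm:", x$l, "columns from", x$n_members, "members (eps =",
      x$eps, ")\n")
  m <- t(round(x$freqs, 3))
  rownames(m) <- DNA_BASES
  print(m)
  invisible(x)
}

#' Per-position relative entropy of a PFM against the background
#'
#' `H_w = sum_k f[w,k] * log(f[w,k] / f0[k])` (natural log), the information
#' content of column `w` relative to the background marginals. Non-negative
#' by Gibbs' inequality; zero columns of an unsmoothed PFM contribute 0.
#'
#' @param F a [build_pfm()] object.
#' @param B a `markov_bg` (only its `f0` marginals are used).
#' @return numeric vector of length `l`.
#' @export
position_entropy <- function(F, B) {
  stopifnot(inherits(F, "pfm"), inherits(B, "markov_bg"))
  f <- F$freqs
  term <- f * log(sweep(f, 2, B$f0, "/"))
  term[f == 0] <- 0
  rowSums(term)
}

#' Independent-column information content
#'
#' Sum of [position_entropy()] over all columns — the classical IC of a
#' motif under position independence.
#'
#' @inheritParams position_entropy
#' @return scalar.
#' @export
ic_independent <- function(F, B) sum(position_entropy(F, B))

#' Adjacent-pair frequency table of aligned members
#'
#' `Phi[w, k1, k2]` is the pseudocount-smoothed frequency of the base pair
#' `(k1, k2)` at columns `(w, w+1)` across members; `Phi0` is the background
#' adjacent-pair distribution (`f0` chained with the order-1 conditionals
#' when the background has order >= 1).
#'
#' @param members integer matrix or character vector of aligned l-mers
#'   (length >= 2 columns).
#' @param B a `markov_bg`.
#' @param eps pseudocount per (k1, k2) cell. The default 0.25 makes the
#'   pair table marginal-consistent with an `eps = 1` PFM: adding 1/4 per
#'   cell adds 1 per base to each marginal, so `sum_k2 Phi[w, k1, k2]`
#'   equals the column frequency `(N[w,k1] + 1) / (m + 4)` exactly, and the
#'   dependency correction vanishes on independent columns instead of
#'   rewarding unseen pairs.
#' @return list with `phi` (`(l-1) x 4 x 4` array) and `phi0` (`4 x 4`).
#' @export
pair_table <- function(members, B, eps = 0.25) {
  mat <- as_member_matrix(members)
  l <- ncol(mat)
  if (l < 2L) stop("pair_table needs l >= 2")
  m <- nrow(mat)
  phi <- array(0, dim = c(l - 1L, 4L, 4L))
  for (w in seq_len(l - 1L)) {
    idx <- (mat[, w] - 1L) * 4L + mat[, w + 1L]
    cnt <- tabulate(idx, nbins = 16L)
    phi[w, , ] <- matrix((cnt + eps) / (m + 16 * eps), 4L, 4L, byrow = TRUE)
  }
  phi0 <- if (B$order >= 1L) {
    B$f0 * B$cond[[2L]]
  } else {
    outer(B$f0, B$f0)
  }
  list(phi = phi, phi0 = phi0)
}

# Per-member log-likelihood-ratio scores under the dependency-aware motif
# model: position log-frequencies plus adjacent-pair log-ratio correction,
# minus the Markov background log-probability.
.dependency_scores <- function(mat, F, P, B, logp0 = NULL) {
  l <- ncol(mat)
  n <- nrow(mat)
  lf <- log(F$freqs)
  s <- numeric(n)
  for (w in seq_len(l)) s <- s + lf[cbind(w, mat[, w])]
  if (l >= 2L) {
    for (w in seq_len(l - 1L)) {
      k1 <- mat[, w]
      k2 <- mat[, w + 1L]
      s <- s + log(P$phi[cbind(w, k1, k2)]) -
        lf[cbind(w, k1)] - lf[cbind(w + 1L, k2)]
    }
  }
  if (is.null(logp0)) logp0 <- background_logprob(mat, B)
  s - logp0
}

# Expected background log-probability of an l-mer drawn from the
# dependency-aware motif model (first-order chain with marginals f and
# adjacent pairs Phi). For each position the joint distribution of the
# background context window is built by chaining pair transitions, then
# contracted against the log conditionals of the Markov background.
.chain_logp0_expect <- function(F, P, B) {
  l <- F$l
  f <- F$freqs
  total <- 0
  for (w in seq_len(l)) {
    o <- min(w - 1L, B$order)
    # joint over positions (w-o)..(w), newest base fastest-varying
    J <- f[w - o, ]
    if (o > 0L) {
      for (j in (w - o):(w - 1L)) {
        Tj <- P$phi[j, , ] / f[j, ]          # transition rows k1 -> k2
        last <- ((rep(seq_along(J), each = 4L) - 1L) %% 4L) + 1L
        J <- rep(J, each = 4L) *
          Tj[cbind(last, rep.int(seq_len(4L), length(J)))]
      }
    }
    i <- seq_along(J)
    k <- ((i - 1L) %% 4L) + 1L
    ctx <- ((i - 1L) %/% 4L) + 1L
    total <- total + sum(J * log(B$cond[[o + 1L]][cbind(ctx, k)]))
  }
  total
}

#' Dependency-aware information content of a member set
#'
#' The expected log-likelihood ratio between the motif model fitted to the
#' members and the background: `E[log p(x|F) - log p0(x)]` with the
#' expectation under the motif model itself — the direct generalization of
#' the classical per-column IC `sum_k f log(f/f0)`, which is the same
#' expectation under column independence. The motif model is the
#' first-order chain with column marginals `f` and adjacent-pair table
#' `Phi`; its log-likelihood decomposes into position log-frequencies plus
#' a dependency correction `log(Phi[w,k1,k2] / (f[w,k1] f[w+1,k2]))` whose
#' expectation is the adjacent-column mutual information, vanishing when
#' neighbouring columns are independent. The background term is the exact
#' expectation of the Markov-chain log-probability under the motif model.
#' This is the information content used for candidate filtering and
#' refinement: it grows when a recruited instance sharpens the columns and
#' shrinks when an outlier flattens them.
#'
#' @param members integer matrix or character vector of aligned l-mers.
#' @param B a `markov_bg`.
#' @param eps pseudocount for the PFM and pair table (pairs use `eps/4`,
#'   keeping the pair marginals identical to the column frequencies).
#' @return scalar (natural-log units).
#' @export
ic_dependent <- function(members, B, eps = 1) {
  mat <- as_member_matrix(members)
  F <- build_pfm(mat, eps = eps)
  l <- F$l
  f <- F$freqs
  e_logp <- sum(f[1L, ] * log(f[1L, ]))
  if (l >= 2L) {
    P <- pair_table(mat, B, eps = eps / 4)
    for (w in seq_len(l - 1L)) {
      phi <- P$phi[w, , ]
      e_logp <- e_logp + sum(phi * (log(phi) - log(f[w, ])))
    }
  } else {
    P <- list(phi = array(0, c(0L, 4L, 4L)), phi0 = outer(B$f0, B$f0))
  }
  e_logp - .chain_logp0_expect(F, P, B)
}

#' Majority-base consensus of aligned members
#'
#' Per-position most frequent base; ties resolved in alphabet order
#' A < C < G < T.
#'
#' @param members integer matrix or character vector of aligned l-mers.
#' @param as_string return a string (default) or the integer code vector.
#' @return consensus string or integer vector.
#' @export
consensus_of <- function(members, as_string = TRUE) {
  mat <- as_member_matrix(members)
  cons <- vapply(seq_len(ncol(mat)),
                 function(w) which.max(tabulate(mat[, w], nbins = 4L)),
                 integer(1))
  if (as_string) decode_ints(cons) else cons
}
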