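#' Hamming distance between equal-length strings
#'
#' @param a,b strings or integer code vectors of equal length.
#' @return integer count of mismatching positions.
#' @export
hamming <- function(a, b) {
  if (is.character(a)) a <- encode_seq(a)
  if (is.character(b)) b <- encode_seq(b)
  if (length(a) != length(b)) stop("hamming distance needs equal lengths")
  sum(a != b)
}

# Symmetric pairwise hamming distance matrix of the rows of `mat`.
.pairwise_hamming <- function(mat) {
  m <- nrow(mat)
  D <- matrix(0L, m, m)
  for (i in seq_len(m - 1L)) {
    di <- hamming_to_all(mat[(i + 1L):m, , drop = FALSE], mat[i, ])
    D[i, (i + 1L):m] <- di
    D[(i + 1L):m, i] <- di
  }
  D
}

#' Prune fake instances from a qualified subset
#'
#' Instances of one motif with mutation budget `d` can disagree pairwise at
#' no more than `2d` positions. Two pruning strategies are provided.
#' `"consensus"` (the pipeline default) iterates to a fixed point: compute
#' the majority consensus, remove the member farthest from it while any
#' member exceeds `2d` from the consensus, recompute. Because the majority
#' base at every column of a mixed subset is set by the coherent instance
#' core rather than by background members, this keeps the core that the
#' projection path selected. `"pairwise"` instead removes, while any
#' pairwise distance exceeds `2d`, the member with the largest mean
#' distance to the others; it guarantees max pairwise distance `<= 2d` but
#' on an evenly mixed subset can converge to whichever clique is denser.
#' Ties drop the later-indexed member in both strategies.
#'
#' @param mat integer member matrix.
#' @param d mutation budget.
#' @param method `"consensus"` or `"pairwise"`.
#' @return list with `keep` (logical vector over input rows) and
#'   `degenerate` flag (fewer than 2 survivors).
#' @export
prune_subset <- function(mat, d, method = c("consensus", "pairwise")) {
  method <- match.arg(method)
  stopifnot(d >= 0, nrow(mat) >= 1L)
  keep <- rep(TRUE, nrow(mat))
  if (nrow(mat) < 2L) return(list(keep = keep, degenerate = TRUE))
  if (method == "pairwise") {
    D <- .pairwise_hamming(mat)
    while (sum(keep) >= 2L) {
      sub <- D[keep, keep, drop = FALSE]
      if (max(sub) <= 2 * d) break
      meand <- rowMeans(sub)
      worst <- which(meand == max(meand))
      worst <- worst[length(worst)]           # tie: later index goes
      keep[which(keep)[worst]] <- FALSE
    }
  } else {
    while (sum(keep) >= 2L) {
      sub <- mat[keep, , drop = FALSE]
      dist <- hamming_to_all(sub, consensus_of(sub, as_string = FALSE))
      if (max(dist) <= 2 * d) break
      worst <- which(dist == max(dist))
      worst <- worst[length(worst)]           # tie: later index goes
      keep[which(keep)[worst]] <- FALSE
    }
  }
  list(keep = keep, degenerate = sum(keep) < 2L)
}

# Per-member dependency log-likelihood-ratio score of each row; their sum is
# the subset total information maximized during recruitment.
.member_scores <- function(mat, B, eps = 1, logp0 = NULL) {
  F <- build_pfm(mat, eps = eps)
  P <- if (ncol(mat) >= 2L) pair_table(mat, B, eps = eps / 4) else
    list(phi = array(0, c(0L, 4L, 4L)))
  .dependency_scores(mat, F, P, B, logp0 = logp0)
}

# Total information of a member set: the sum over members of the
# dependency-aware log-likelihood ratio against the background.
.total_information <- function(mat, B, eps = 1, logp0 = NULL) {
  sum(.member_scores(mat, B, eps = eps, logp0 = logp0))
}

#' Recruit missed instances from the full l-mer set
#'
#' Scans `X` in deterministic order (sequence-major, offset-minor) and adds
#' an l-mer when (i) its hamming distance to the current majority consensus
#' is at most `2d` and (ii) adding it strictly increases the subset\'s total
#' information content — the sum over members of the dependency-aware
#' log-likelihood ratio against the background. The total (rather than the
#' per-member average) is the monotone-friendly reading of the
#' IC-increase condition: a genuine instance carrying the motif signal
#' always contributes positive information even when it scores below the
#' current member average, while the `2d` distance bound keeps incoherent
#' l-mers out. Under the OOPS model at most one member per sequence is
#' allowed: the occupant of each sequence is the maximum-likelihood window
#' under the motif model's positional frequencies among eligible l-mers
#' (the incumbent always being one of the candidates), still gated by a
#' positive total-information gain. Every accepted *addition* strictly
#' increases the total; OOPS site reassignments (replacement or removal of
#' an incumbent) enforce the sequence model and are labelled separately in
#' the returned trace.
#'
#' @param member_idx row indices of the (pruned) subset in `X`.
#' @param X an [extract_lmers()] set.
#' @param d mutation budget (distance bound is `2d`).
#' @param B a `markov_bg`.
#' @param model `"OOPS"`, `"ZOOPS"` or `"TCM"`.
#' @param eps pseudocount.
#' @param logp0 optional precomputed background log-probabilities for all
#'   rows of `X$mat`.
#' @return list with `idx` (final member rows), `ic` (final
#'   [ic_dependent()] of the members), `total` (final total information),
#'   `ic_trace` (total information after each accepted change, starting
#'   value first) and `trace_kind` (`"start"`, `"addition"`,
#'   `"replacement"` or `"removal"` per trace entry).
#' @export
recruit_instances <- function(member_idx, X, d, B,
                              model = c("OOPS", "ZOOPS", "TCM"),
                              eps = 1, logp0 = NULL) {
  model <- match.arg(model)
  stopifnot(length(member_idx) >= 1L)
  if (is.null(logp0)) logp0 <- background_logprob(X$mat, B)
  idx <- member_idx
  total <- .total_information(X$mat[idx, , drop = FALSE], B, eps = eps,
                              logp0 = logp0[idx])
  trace <- total
  kinds <- "start"
  gain_of <- function(cand_row) {
    rows <- c(idx, cand_row)
    .total_information(X$mat[rows, , drop = FALSE], B, eps = eps,
                       logp0 = logp0[rows]) - total
  }
  if (model == "OOPS") {
    # one member per sequence from the start: keep the best-scoring one
    if (anyDuplicated(X$seq_index[idx])) {
      sc <- .member_scores(X$mat[idx, , drop = FALSE], B, eps = eps,
                           logp0 = logp0[idx])
      ord <- order(X$seq_index[idx], -sc, X$start[idx])
      idx <- idx[ord][!duplicated(X$seq_index[idx][ord])]
      total <- .total_information(X$mat[idx, , drop = FALSE], B, eps = eps,
                                  logp0 = logp0[idx])
      trace <- total
      kinds <- "start"
    }
    for (pass in 1:3) {
    changed <- FALSE
    for (i in seq_along(X$ids)) {
      occ <- idx[X$seq_index[idx] == i]
      base <- setdiff(idx, occ)
      if (length(base) < 2L) next
      base_total <- .total_information(X$mat[base, , drop = FALSE], B,
                                       eps = eps, logp0 = logp0[base])
      cons <- consensus_of(X$mat[base, , drop = FALSE], as_string = FALSE)
      rows <- which(X$seq_index == i)
      if (length(rows) == 0L) next
      dist <- hamming_to_all(X$mat[rows, , drop = FALSE], cons)
      elig <- union(rows[dist <= 2 * d], occ)  # incumbent always a candidate
      if (length(elig) == 0L) next
      # the sequence's site is the maximum-likelihood window under the
      # motif model (columns weighted by their frequencies, so a mismatch
      # at a degenerate column costs less than one at a conserved column);
      # the noisy estimated-background term plays no part in locating the
      # site; inclusion is gated by a positive total-information gain
      lf <- log(build_pfm(X$mat[base, , drop = FALSE], eps = eps)$freqs)
      wcols <- seq_len(ncol(X$mat))
      pos_score <- vapply(elig, function(r)
        sum(lf[cbind(wcols, X$mat[r, ])]), numeric(1))
      cand <- elig[which.max(pos_score)]       # first max: smallest offset
      gain <- {
        rows2 <- c(base, cand)
        .total_information(X$mat[rows2, , drop = FALSE], B, eps = eps,
                           logp0 = logp0[rows2]) - base_total
      }
      new_idx <- if (gain > 0) c(base, cand) else base
      new_total <- base_total + max(gain, 0)
      if (!identical(sort(new_idx), sort(idx))) {
        kind <- if (length(occ) == 0L) "addition"
                else if (length(new_idx) > length(base)) "replacement"
                else "removal"
        idx <- new_idx
        total <- new_total
        trace <- c(trace, total)
        kinds <- c(kinds, kind)
        changed <- TRUE
      } else {
        total <- new_total
      }
    }
    if (!changed) break
    }
  } else {
    cons <- consensus_of(X$mat[idx, , drop = FALSE], as_string = FALSE)
    dist <- hamming_to_all(X$mat, cons)
    for (r in seq_len(nrow(X$mat))) {
      if (r %in% idx) next
      if (dist[r] > 2 * d) next
      g <- gain_of(r)
      if (g > 0) {
        idx <- c(idx, r)
        total <- total + g
        trace <- c(trace, total)
        kinds <- c(kinds, "addition")
        cons <- consensus_of(X$mat[idx, , drop = FALSE], as_string = FALSE)
        if (r < nrow(X$mat))
          dist[(r + 1L):nrow(X$mat)] <-
            hamming_to_all(X$mat[(r + 1L):nrow(X$mat), , drop = FALSE], cons)
      }
    }
  }
  list(idx = idx, ic = ic_dependent(X$mat[idx, , drop = FALSE], B,
                                    eps = eps),
       total = total, ic_trace = trace, trace_kind = kinds)
}

# Assemble an epp_motif object from member rows of X.
.make_motif <- function(X, idx, B, eps = 1, logp0 = NULL,
                        ic = NULL, ic_trace = NULL) {
  mat <- X$mat[idx, , drop = FALSE]
  F <- build_pfm(mat, eps = eps)
  if (is.null(ic)) ic <- ic_dependent(mat, B, eps = eps)
  sites <- data.frame(seq_index = X$seq_index[idx],
                      seq_id = X$ids[X$seq_index[idx]],
                      start = X$start[idx],
                      end = X$start[idx] + X$l - 1L,
                      text = lmer_texts(X, idx))
  structure(list(idx = idx, counts = F$counts, freqs = F$freqs,
                 width = X$l, ic = ic, ic_trace = ic_trace,
                 consensus = consensus_of(mat), sites = sites,
                 n_members = length(idx), combined = FALSE),
            class = "epp_motif")
}

#' @export
print.epp_motif <- function(x, ...) {
  cat("epp_motif:", x$consensus, " width", x$width,
      " members", x$n_members, sprintf(" IC %.3f", x$ic),
      if (x$combined) " (combined)" else "", "\n", sep = "")
  invisible(x)
}

#' Refine all qualified subsets into motifs
#'
#' Each qualified subset is pruned by the 2d-hamming rule, then missing
#' instances are recruited from `X`; subsets degenerate after pruning
#' (fewer than 2 members) or smaller than `min_size` once refined are
#' dropped. Output motifs are sorted by decreasing information content.
#'
#' @param qualified list of subsets (from [filter_candidates()]).
#' @param X an [extract_lmers()] set.
#' @param d mutation budget.
#' @param min_size minimum refined subset size.
#' @param B a `markov_bg`.
#' @param model sequence model; under OOPS each motif keeps at most one
#'   member per sequence (best per-member score).
#' @param eps pseudocount.
#' @param logp0 optional precomputed background log-probabilities.
#' @return list of `epp_motif` objects, IC-descending.
#' @export
refine_all <- function(qualified, X, d, min_size, B,
                       model = c("OOPS", "ZOOPS", "TCM"),
                       eps = 1, logp0 = NULL,
                       prune_method = c("consensus", "pairwise")) {
  model <- match.arg(model)
  prune_method <- match.arg(prune_method)
  if (is.null(logp0)) logp0 <- background_logprob(X$mat, B)
  lookup <- .position_lookup(X)
  motifs <- list()
  for (cc in qualified) {
    idx <- cc$idx
    pr <- prune_subset(X$mat[idx, , drop = FALSE], d, method = prune_method)
    if (pr$degenerate) next
    idx <- idx[pr$keep]
    if (model == "OOPS") {
      # one member per sequence: keep the best-scoring one
      sc <- .member_scores(X$mat[idx, , drop = FALSE], B, eps = eps,
                           logp0 = logp0[idx])
      ord <- order(X$seq_index[idx], -sc, X$start[idx])
      idx <- idx[ord][!duplicated(X$seq_index[idx][ord])]
    }
    rec <- recruit_instances(idx, X, d, B, model = model, eps = eps,
                             logp0 = logp0)
    rec <- .optimize_phase(rec, X, d, B, model = model, eps = eps,
                           logp0 = logp0, lookup = lookup)
    if (length(rec$idx) < min_size) next
    tr <- rec$ic_trace
    attr(tr, "kind") <- rec$trace_kind
    motifs[[length(motifs) + 1L]] <-
      .make_motif(X, rec$idx, B, eps = eps, logp0 = logp0,
                  ic = rec$ic, ic_trace = tr)
  }
  motifs[order(-vapply(motifs, function(m) m$ic, numeric(1)))]
}

# Row index of the l-mer starting at a given (sequence, offset), NA when out
# of range or excluded.
.position_lookup <- function(X) {
  lk <- matrix(NA_integer_, length(X$ids), max(X$start))
  lk[cbind(X$seq_index, X$start)] <- seq_len(nrow(X$mat))
  lk
}

# Phase-shift optimization: a refined subset can converge onto a shifted
# register of the true motif (every member window off by the same delta).
# Sliding all member windows by the delta that maximizes the dependency-
# aware IC, then re-recruiting at the new phase, snaps the motif onto the
# register where its columns are most informative. Deterministic: all
# shifts evaluated, strict improvement required, ties go to the smaller
# |delta| (negative first); at most `max_iter` rounds.
.optimize_phase <- function(rec, X, d, B, model, eps = 1, logp0 = NULL,
                            lookup = NULL, max_iter = 4L) {
  if (is.null(lookup)) lookup <- .position_lookup(X)
  l <- X$l
  deltas <- unlist(lapply(seq_len(l - 1L), function(a) c(-a, a)))
  for (iter in seq_len(max_iter)) {
    ic0 <- ic_dependent(X$mat[rec$idx, , drop = FALSE], B, eps = eps)
    best <- list(ic = ic0, idx = NULL)
    for (delta in deltas) {
      st <- X$start[rec$idx] + delta
      ok <- st >= 1L & st <= ncol(lookup)
      if (sum(ok) < max(3L, length(rec$idx) %/% 2L)) next
      rows <- lookup[cbind(X$seq_index[rec$idx][ok], st[ok])]
      rows <- rows[!is.na(rows)]
      if (length(rows) < max(3L, length(rec$idx) %/% 2L)) next
      ic_d <- ic_dependent(X$mat[rows, , drop = FALSE], B, eps = eps)
      if (ic_d > best$ic) best <- list(ic = ic_d, idx = rows)
    }
    if (is.null(best$idx)) break
    rec <- recruit_instances(best$idx, X, d, B, model = model, eps = eps,
                             logp0 = logp0)
  }
  rec
}
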