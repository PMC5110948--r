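WIDTH_CLASSES <- list(short = 8:10, middle = 14:16, long = 19:21)

#' Per-position emission table for a planted motif
#'
#' High conservation: every position emits a randomly chosen dominant base
#' with probability 0.91 and each other base with 0.03. Low conservation:
#' `round(0.6 * l)` randomly placed positions are highly conserved as
#' above, the remaining positions emit their dominant base with probability
#' 0.55 (others 0.15 each).
#'
#' @param l motif width.
#' @param conservation `"high"` or `"low"`.
#' @return list with `probs` (`l x 4` matrix, rows summing to 1),
#'   `dominant` (integer base codes) and `high_positions`.
#' @export
make_emission_table <- function(l, conservation = c("high", "low")) {
  conservation <- match.arg(conservation)
  stopifnot(l >= 1L)
  dominant <- sample.int(4L, l, replace = TRUE)
  n_high <- if (conservation == "high") l else round(0.6 * l)
  high_pos <- sort(sample.int(l, n_high))
  probs <- matrix(0, l, 4L)
  for (w in seq_len(l)) {
    if (w %in% high_pos) {
      probs[w, ] <- 0.03
      probs[w, dominant[w]] <- 0.91
    } else {
      probs[w, ] <- 0.15
      probs[w, dominant[w]] <- 0.55
    }
  }
  list(probs = probs, dominant = dominant, high_positions = high_pos)
}

#' Generate a planted-motif benchmark dataset
#'
#' Emulates the synthetic protocol used to benchmark the discovery
#' pipeline: `t` sequences of `n` i.i.d. uniform background bases, each
#' carrying exactly one embedded instance drawn from a random motif's
#' emission table (instance replaces the background at a uniform random
#' offset, so sequence length stays `n`). Fully reproducible from `seed`.
#'
#' @param width_class `"short"` (8-10 bp), `"middle"` (14-16 bp) or
#'   `"long"` (19-21 bp); ignored when `l` is given.
#' @param conservation `"high"` or `"low"`.
#' @param t number of sequences (default 20).
#' @param n sequence length (default 600).
#' @param l explicit motif width (overrides `width_class`).
#' @param seed RNG seed; recorded in the metadata.
#' @return An object of class `epp_synth`: list with `S` (a [seq_set()]),
#'   `truth` (data frame `seq_id`, `start`, `end`), `consensus` (dominant
#'   bases), `emission`, `l` and `meta`.
#' @export
generate_dataset <- function(width_class = c("short", "middle", "long"),
                             conservation = c("high", "low"),
                             t = 20L, n = 600L, l = NULL, seed = 1L) {
  conservation <- match.arg(conservation)
  set.seed(seed)
  if (is.null(l)) {
    width_class <- match.arg(width_class)
    rng <- WIDTH_CLASSES[[width_class]]
    l <- rng[sample.int(length(rng), 1L)]
  } else {
    width_class <- "explicit"
  }
  stopifnot(l <= n)
  em <- make_emission_table(l, conservation)
  seqs <- character(t)
  starts <- integer(t)
  for (i in seq_len(t)) {
    bg <- sample.int(4L, n, replace = TRUE)
    inst <- vapply(seq_len(l), function(w)
      sample.int(4L, 1L, prob = em$probs[w, ]), integer(1))
    s0 <- sample.int(n - l + 1L, 1L)
    bg[s0:(s0 + l - 1L)] <- inst
    seqs[i] <- decode_ints(bg)
    starts[i] <- s0
  }
  ids <- sprintf("synth_%02d", seq_len(t))
  truth <- data.frame(seq_id = ids, start = starts, end = starts + l - 1L)
  structure(list(S = seq_set(seqs, ids), truth = truth,
                 consensus = decode_ints(em$dominant), emission = em,
                 l = l,
                 meta = list(width_class = width_class,
                             conservation = conservation, t = t, n = n,
                             l = l, seed = seed)),
            class = "epp_synth")
}

#' Generate a planted (l, d) fixture
#'
#' Each sequence carries one instance equal to a random consensus with
#' up-to-`d` random substitutions (the number of substitutions is drawn
#' uniformly from `0..d`, positions without replacement, substituted base
#' always different). Pairwise instance distances are therefore at most
#' `2d`.
#'
#' @param t,n,l,d problem dimensions; `d < l`.
#' @param seed RNG seed.
#' @return An `epp_synth` object (see [generate_dataset()]).
#' @export
make_planted_ld_fixture <- function(t, n, l, d, seed = 1L) {
  stopifnot(d >= 0, d < l, l <= n)
  set.seed(seed)
  cons <- sample.int(4L, l, replace = TRUE)
  seqs <- character(t)
  starts <- integer(t)
  for (i in seq_len(t)) {
    bg <- sample.int(4L, n, replace = TRUE)
    inst <- cons
    k <- sample.int(d + 1L, 1L) - 1L
    if (k > 0L) {
      pos <- sample.int(l, k)
      for (p in pos) inst[p] <- sample(setdiff(1:4, inst[p]), 1L)
    }
    s0 <- sample.int(n - l + 1L, 1L)
    bg[s0:(s0 + l - 1L)] <- inst
    seqs[i] <- decode_ints(bg)
    starts[i] <- s0
  }
  ids <- sprintf("plant_%02d", seq_len(t))
  truth <- data.frame(seq_id = ids, start = starts, end = starts + l - 1L)
  structure(list(S = seq_set(seqs, ids), truth = truth,
                 consensus = decode_ints(cons), emission = NULL, l = l,
                 meta = list(width_class = "explicit",
                             conservation = "planted_ld", t = t, n = n,
                             l = l, d = d, seed = seed)),
            class = "epp_synth")
}

#' Write a synthetic dataset to disk
#'
#' Emits `<prefix>.fasta`, `<prefix>_sites.tsv` (BED-like truth) and
#' `<prefix>_meta.json` (spec, seed, consensus, emission table).
#'
#' @param ds an `epp_synth` object.
#' @param prefix output path prefix.
#' @return character vector of the three paths, invisibly.
#' @export
write_dataset <- function(ds, prefix) {
  fa <- paste0(prefix, ".fasta")
  write_fasta(ds$S, fa)
  ts <- paste0(prefix, "_sites.tsv")
  write_sites(ds$truth, ts)
  js <- paste0(prefix, "_meta.json")
  meta <- ds$meta
  meta$consensus <- ds$consensus
  if (!is.null(ds$emission)) {
    meta$emission <- ds$emission$probs
    meta$high_positions <- ds$emission$high_positions
  }
  jsonlite::write_json(meta, js, auto_unbox = TRUE, digits = NA)
  invisible(c(fa, ts, js))
}

#' @export
print.epp_synth <- function(x, ...) {
  cat("epp_synth:", x$meta$t, "sequences x", x$meta$n, "bp, motif width",
      x$l, paste0("(", x$meta$conservation, ")"), "consensus",
      x$consensus, "\n")
  invisible(x)
}
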