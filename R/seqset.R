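# DNA alphabet used throughout; integer codes 1..4 in this column order.
DNA_BASES <- c("A", "C", "G", "T")

#' Construct a sequence set
#'
#' A `seq_set` holds named, uppercase DNA sequences over `{A,C,G,T,N}` and is
#' the source of all l-mers. Sequences are validated and uppercased; `N`
#' bases are allowed (and flagged) but any other letter is an error.
#'
#' @param seqs character vector of DNA sequences.
#' @param ids record identifiers; defaults to `names(seqs)` or `seq1..seqT`.
#' @return An object of class `seq_set`: a list with elements `id`, `seq`
#'   (uppercase character vectors), `t` (number of sequences) and `n`
#'   (per-sequence lengths).
#' @export
seq_set <- function(seqs, ids = names(seqs)) {
  if (length(seqs) < 1L) stop("a sequence set needs at least one sequence")
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  seqs <- toupper(as.character(seqs))
  n <- nchar(seqs)
  if (any(n < 1L)) stop("empty sequence in record(s): ",
                        paste(ids[n < 1L], collapse = ", "))
  bad <- vapply(seqs, function(s) {
    ch <- unique(strsplit(s, "", fixed = TRUE)[[1]])
    length(setdiff(ch, c(DNA_BASES, "N"))) > 0L
  }, logical(1))
  if (any(bad)) {
    stop("non-nucleotide characters (other than N) in record(s): ",
         paste(ids[bad], collapse = ", "))
  }
  n_count <- sum(vapply(seqs, function(s)
    sum(strsplit(s, "", fixed = TRUE)[[1]] == "N"), integer(1)))
  if (n_count > 0L)
    message("sequence set contains ", n_count, " ambiguous (N) bases")
  structure(list(id = as.character(ids), seq = seqs,
                 t = length(seqs), n = unname(n)),
            class = "seq_set")
}

#' Read a multi-FASTA file into a sequence set
#'
#' Records may be line-wrapped or unwrapped. Sequences are uppercased; `N`
#' is tolerated, any other non-ACGT character aborts with the offending
#' record id.
#'
#' @param path path to a FASTA file.
#' @return A [seq_set()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0L) stop("no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(x))
  seq_set(as.character(x), ids)
}

#' Write a sequence set as FASTA
#'
#' @param S a [seq_set()].
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(S, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(S$t)) {
    writeLines(paste0(">", S$id[i]), con)
    s <- S$seq[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' @export
print.seq_set <- function(x, ...) {
  cat("seq_set:", x$t, "sequences, lengths",
      min(x$n), "-", max(x$n), "\n")
  invisible(x)
}

# Encode a DNA string as integer codes 1..4 (N and anything else -> NA).
encode_seq <- function(s) {
  match(strsplit(s, "", fixed = TRUE)[[1]], DNA_BASES)
}

decode_ints <- function(v) paste(DNA_BASES[v], collapse = "")

#' Extract all l-mers from a sequence set
#'
#' Enumerates the `n_i - l + 1` substrings of length `l` of every sequence,
#' in sequence order then offset order. l-mers containing `N` are excluded
#' and the exclusion count reported via `message()`.
#'
#' @param S a [seq_set()].
#' @param l motif length; must not exceed the shortest sequence.
#' @return An object of class `lmer_set`: list with `mat` (integer matrix,
#'   one row per l-mer, codes 1..4 for A,C,G,T), `seq_index`, `start`
#'   (1-based), `l`, `ids` (sequence ids) and `n_excluded`.
#' @export
extract_lmers <- function(S, l) {
  stopifnot(inherits(S, "seq_set"), l >= 1L)
  if (l > min(S$n)) {
    stop("motif length l = ", l, " exceeds the shortest sequence (",
         min(S$n), " bp)")
  }
  mats <- vector("list", S$t)
  seqi <- vector("list", S$t)
  offs <- vector("list", S$t)
  for (i in seq_len(S$t)) {
    v <- encode_seq(S$seq[i])
    k <- S$n[i] - l + 1L
    starts <- seq_len(k)
    m <- vapply(0:(l - 1L), function(o) v[starts + o], numeric(k))
    if (k == 1L) m <- matrix(m, nrow = 1L)
    mats[[i]] <- m
    seqi[[i]] <- rep.int(i, k)
    offs[[i]] <- starts
  }
  mat <- do.call(rbind, mats)
  seq_index <- unlist(seqi)
  start <- unlist(offs)
  keep <- stats::complete.cases(mat)
  n_excluded <- sum(!keep)
  if (n_excluded > 0L)
    message(n_excluded, " l-mers containing N excluded")
  structure(list(mat = matrix(as.integer(mat[keep, , drop = FALSE]),
                              ncol = l),
                 seq_index = seq_index[keep], start = start[keep],
                 l = l, ids = S$id, n_excluded = n_excluded),
            class = "lmer_set")
}

#' @export
print.lmer_set <- function(x, ...) {
  cat("lmer_set:", nrow(x$mat), "l-mers of length", x$l, "from",
      length(x$ids), "sequences\n")
  invisible(x)
}

#' Spell out l-mers as strings
#'
#' @param X an [extract_lmers()] result.
#' @param idx row indices (default all).
#' @return character vector of l-mer texts.
#' @export
lmer_texts <- function(X, idx = seq_len(nrow(X$mat))) {
  apply(X$mat[idx, , drop = FALSE], 1L, decode_ints)
}

# Row-wise hamming distance of every l-mer in `mat` to an integer-coded
# consensus vector.
hamming_to_all <- function(mat, cons) {
  rowSums(mat != matrix(cons, nrow(mat), length(cons), byrow = TRUE))
}
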