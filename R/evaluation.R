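#' Match predicted against true sites with a shift tolerance
#'
#' Greedy 1-1 matching within each sequence: predicted sites (in start
#' order) claim the nearest unused true site whose start differs by at most
#' `shift` bases (ties to the earlier true site). Matched predictions are
#' true positives; unmatched predictions false positives; unclaimed true
#' sites false negatives.
#'
#' @param pred,truth data frames with columns `seq_id` (or `seq_index`) and
#'   `start`.
#' @param shift maximum allowed start offset (default 3).
#' @return list with counts `tp`, `fp`, `fn`.
#' @export
match_sites <- function(pred, truth, shift = 3L) {
  stopifnot(shift >= 0)
  key <- function(d) {
    if (!is.null(d$seq_id)) as.character(d$seq_id)
    else as.character(d$seq_index)
  }
  pk <- key(pred)
  tk <- key(truth)
  tp <- 0L
  used <- rep(FALSE, nrow(truth))
  for (s in unique(c(pk, tk))) {
    pi <- which(pk == s)
    pi <- pi[order(pred$start[pi])]
    ti <- which(tk == s)
    for (p in pi) {
      cand <- ti[!used[ti] & abs(truth$start[ti] - pred$start[p]) <= shift]
      if (length(cand) == 0L) next
      j <- cand[order(abs(truth$start[cand] - pred$start[p]),
                      truth$start[cand])][1L]
      used[j] <- TRUE
      tp <- tp + 1L
    }
  }
  list(tp = tp, fp = nrow(pred) - tp, fn = nrow(truth) - tp)
}

#' Precision, recall and F score from match counts
#'
#' `P = TP/(TP+FP)`, `R = TP/(TP+FN)`, `F = 2PR/(P+R)`; zero denominators
#' give 0 by convention.
#'
#' @param tp,fp,fn nonnegative counts.
#' @return named list `precision`, `recall`, `f`.
#' @export
precision_recall_f <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  list(precision = p, recall = r, f = f)
}

#' Nucleotide-level performance coefficient
#'
#' `nPC = nTP / (nTP + nFP + nFN)` over individual base positions: the size
#' of the intersection of predicted and true site positions divided by the
#' size of their union. Symmetric in its arguments and in `[0, 1]`.
#'
#' @param pred,truth data frames with columns `seq_id` (or `seq_index`),
#'   `start` and `end` (1-based inclusive).
#' @return scalar in `[0, 1]` (1 when both are empty).
#' @export
npc <- function(pred, truth) {
  key <- function(d) {
    if (!is.null(d$seq_id)) as.character(d$seq_id)
    else as.character(d$seq_index)
  }
  pos_set <- function(d, k, s) {
    i <- which(k == s)
    if (length(i) == 0L) return(integer(0))
    unique(unlist(mapply(seq.int, d$start[i], d$end[i], SIMPLIFY = FALSE)))
  }
  pk <- key(pred)
  tk <- key(truth)
  ntp <- 0L
  nun <- 0L
  for (s in unique(c(pk, tk))) {
    pp <- pos_set(pred, pk, s)
    tt <- pos_set(truth, tk, s)
    ntp <- ntp + length(intersect(pp, tt))
    nun <- nun + length(union(pp, tt))
  }
  if (nun == 0L) return(1)
  ntp / nun
}

#' Read a BED-like site table
#'
#' Tab-separated columns: sequence id, start, end (1-based inclusive),
#' optional motif label; header optional (detected).
#'
#' @param path file path.
#' @return data frame with `seq_id`, `start`, `end` (and `label` if
#'   present).
#' @export
read_sites <- function(path) {
  first <- readLines(path, n = 1L)
  header <- grepl("seq", strsplit(first, "\t")[[1]][1], ignore.case = TRUE)
  d <- utils::read.table(path, sep = "\t", header = header,
                         stringsAsFactors = FALSE)
  wanted <- c("seq_id", "start", "end")
  if (!all(wanted %in% names(d))) {
    # positional layout: sequence id, start, end[, label]
    names(d)[1:3] <- wanted
    if (ncol(d) >= 4L) names(d)[4L] <- "label"
  }
  d[order(d$seq_id, d$start), , drop = FALSE]
}

#' Write a BED-like site table
#'
#' @param sites data frame with `seq_id`, `start`, `end` and optionally
#'   more columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sites <- function(sites, path) {
  utils::write.table(sites, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
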