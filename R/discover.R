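#' Default mutation budget for a motif width
#'
#' `d = floor((l - 1) / 4)`, the usual planted-motif convention relating
#' mutation budget to width; always user-overridable in [epp_discover()].
#'
#' @param l motif width.
#' @return integer mutation budget.
#' @export
default_d <- function(l) as.integer(floor((l - 1) / 4))

#' Discover motifs by entropy-based position projection
#'
#' Runs the full pipeline on a sequence set: extract all l-mers, estimate
#' the Markov background, recursively project the l-mer set into
#' bounded-size candidate subsets at maximal-entropy positions, filter
#' candidates by the joint complexity/information-content outlier
#' criterion, refine the qualified subsets (2d-hamming pruning + greedy
#' instance recruitment), and merge similar motifs by ALLR similarity into
#' a top-`u` list. Deterministic for a given input and configuration.
#'
#' @param S a [seq_set()] or path to a FASTA file.
#' @param l motif width (must not exceed the shortest sequence).
#' @param d mutation budget; default [default_d()].
#' @param model sequence model: `"OOPS"`, `"ZOOPS"` or `"TCM"` (sets the
#'   projection size window via [thresholds_for_model()]).
#' @param min_size,max_size explicit size-window overrides.
#' @param alpha radius fraction for [filter_candidates()].
#' @param u capacity of the final motif list.
#' @param sim_frac ALLR similarity threshold fraction for merging.
#' @param bg_order Markov background order (default 3).
#' @param bg_pseudocount background smoothing pseudocount.
#' @param eps PFM/pair-table pseudocount.
#' @param verbose emit per-stage accounting via `message()`.
#' @return An object of class `epp_result`: list with `motifs` (final
#'   merged top-`u` list of `epp_motif`), `refined` (pre-merge motifs),
#'   `stats` (per-stage accounting), `scores` (candidate score table),
#'   `tree` (projection tree), `background` and `config`.
#' @export
epp_discover <- function(S, l, d = default_d(l),
                         model = c("OOPS", "ZOOPS", "TCM"),
                         min_size = NULL, max_size = NULL, alpha = 0.5,
                         u = 20L, sim_frac = 0.7, bg_order = 3L,
                         bg_pseudocount = 0.25, eps = 1, verbose = FALSE) {
  model <- match.arg(model)
  if (is.character(S)) S <- read_fasta(S)
  stopifnot(inherits(S, "seq_set"))
  thr <- thresholds_for_model(model, S$t, min_size = min_size,
                              max_size = max_size)
  X <- extract_lmers(S, l)
  B <- estimate_background(S, order = bg_order,
                           pseudocount = bg_pseudocount)
  logp0 <- background_logprob(X$mat, B)
  pr <- project(X, B, thr$min_size, thr$max_size, eps = eps)
  if (length(pr$candidates) == 0L)
    stop("projection produced no candidate subsets; relax min_size")
  fl <- filter_candidates(pr$candidates, X, B, alpha = alpha, eps = eps,
                          keep_top = u)
  refined <- refine_all(fl$qualified, X, d, thr$min_size, B, model = model,
                        eps = eps, logp0 = logp0)
  motifs <- maintain_top(refined, u = u, B = B, sim_frac = sim_frac,
                         eps = eps)
  # combined motifs can exceed the requested width; report the best width-l
  # core of each, collapsing register duplicates
  motifs <- lapply(motifs, function(m) trim_motif(m, l, X, B, eps = eps))
  if (model == "OOPS")
    motifs <- lapply(motifs, function(m) .dedupe_sites_oops(m, X, B, eps))
  if (length(motifs) > 1L) {
    key <- vapply(motifs, function(m)
      paste(m$consensus, paste(m$sites$seq_index, m$sites$start,
                               collapse = ";")), character(1))
    motifs <- motifs[!duplicated(key)]
  }
  motifs <- motifs[order(-vapply(motifs, function(m) m$ic, numeric(1)))]
  n_qual_lmers <- sum(vapply(fl$qualified, function(cc) length(cc$idx),
                             integer(1)))
  stats <- list(total_lmers = nrow(X$mat),
                min_size = thr$min_size, max_size = thr$max_size,
                n_candidates = length(pr$candidates),
                n_qualified = length(fl$qualified),
                lmers_in_qualified = n_qual_lmers,
                reduction = 1 - n_qual_lmers / nrow(X$mat),
                n_refined = length(refined),
                n_final = length(motifs))
  if (verbose) {
    message(sprintf(paste0("l-mers %d | window [%d,%d] | candidates %d | ",
                           "qualified %d (%d l-mers, %.0f%% reduction) | ",
                           "refined %d | final %d"),
                    stats$total_lmers, thr$min_size, thr$max_size,
                    stats$n_candidates, stats$n_qualified,
                    n_qual_lmers, 100 * stats$reduction,
                    stats$n_refined, stats$n_final))
  }
  structure(list(motifs = motifs, refined = refined, stats = stats,
                 scores = fl$scores, tree = pr$tree, background = B,
                 config = list(l = l, d = d, model = model,
                               min_size = thr$min_size,
                               max_size = thr$max_size, alpha = alpha,
                               u = u, sim_frac = sim_frac,
                               bg_order = bg_order,
                               bg_pseudocount = bg_pseudocount,
                               eps = eps)),
            class = "epp_result")
}

#' @export
print.epp_result <- function(x, ...) {
  s <- x$stats
  cat("EPP motif discovery (", x$config$model, ", l = ", x$config$l,
      ", d = ", x$config$d, ")\n", sep = "")
  cat(sprintf("  %d l-mers -> %d candidates -> %d qualified -> %d motifs (%.0f%% l-mer reduction)\n",
              s$total_lmers, s$n_candidates, s$n_qualified, s$n_final,
              100 * s$reduction))
  for (i in seq_along(x$motifs)) {
    m <- x$motifs[[i]]
    cat(sprintf("  %2d. %-24s width %2d  members %3d  IC %.3f%s\n", i,
                m$consensus, m$width, m$n_members, m$ic,
                if (m$combined) "  (combined)" else ""))
  }
  invisible(x)
}

#' Predicted sites of a discovered motif
#'
#' @param result an `epp_result`.
#' @param rank motif rank in the final list (default 1, the top motif).
#' @return data frame of sites (`seq_id`, `start`, `end`, ...).
#' @export
epp_sites <- function(result, rank = 1L) {
  stopifnot(inherits(result, "epp_result"),
            rank >= 1L, rank <= length(result$motifs))
  result$motifs[[rank]]$sites
}

#' Benchmark the pipeline on the synthetic planted-motif grid
#'
#' For each width-class x conservation cell, generates `replicates`
#' datasets, runs [epp_discover()] with the dataset's true width, and
#' scores the top motif's sites against the embedded truth with the
#' nucleotide-level performance coefficient [npc()].
#'
#' @param widths width classes to run.
#' @param conservations conservation levels to run.
#' @param replicates datasets per cell (default 10).
#' @param t,n dataset dimensions.
#' @param model sequence model passed to discovery.
#' @param seed base seed; replicate r of cell c uses
#'   `seed + 97 * c + r` so cells are independent and reproducible.
#' @param verbose print one line per cell.
#' @return data frame: width, conservation, replicates, mean_npc, sd_npc.
#' @export
epp_benchmark <- function(widths = c("short", "middle", "long"),
                          conservations = c("low", "high"),
                          replicates = 10L, t = 20L, n = 600L,
                          model = "OOPS", seed = 1L, verbose = FALSE) {
  rows <- list()
  cell <- 0L
  for (cons in conservations) {
    for (wc in widths) {
      cell <- cell + 1L
      scores <- vapply(seq_len(replicates), function(r) {
        ds <- generate_dataset(wc, cons, t = t, n = n,
                               seed = seed + 97L * cell + r)
        res <- epp_discover(ds$S, l = ds$l, model = model)
        if (length(res$motifs) == 0L) return(0)
        npc(epp_sites(res, 1L), ds$truth)
      }, numeric(1))
      rows[[cell]] <- data.frame(width = wc, conservation = cons,
                                 replicates = replicates,
                                 mean_npc = mean(scores),
                                 sd_npc = stats::sd(scores))
      if (verbose)
        message(sprintf("%-6s %-4s  nPC %.3f +/- %.3f", wc, cons,
                        mean(scores), stats::sd(scores)))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write motifs in minimal MEME format
#'
#' @param motifs list of `epp_motif` objects (or an `epp_result`).
#' @param path output path.
#' @param B optional `markov_bg` for the background frequency line.
#' @return `path`, invisibly.
#' @export
write_meme <- function(motifs, path, B = NULL) {
  if (inherits(motifs, "epp_result")) {
    if (is.null(B)) B <- motifs$background
    motifs <- motifs$motifs
  }
  f0 <- if (is.null(B)) rep(0.25, 4) else B$f0
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: +", "",
               "Background letter frequencies",
               paste(sprintf("%s %.5f", DNA_BASES, f0), collapse = " "),
               ""), con)
  for (i in seq_along(motifs)) {
    m <- motifs[[i]]
    writeLines(sprintf("MOTIF %s EPP_%d", m$consensus, i), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
      m$width, m$n_members), con)
    writeLines(apply(m$freqs, 1L, function(r)
      paste(sprintf("%.6f", r), collapse = " ")), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Write a motif's count matrix in JASPAR-style format
#'
#' Four labelled rows of per-position counts.
#'
#' @param motif an `epp_motif`.
#' @param path output path.
#' @param name motif name (defaults to the consensus).
#' @return `path`, invisibly.
#' @export
write_jaspar <- function(motif, path, name = motif$consensus) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0(">", name), con)
  cnt <- t(motif$counts)
  for (k in 1:4) {
    writeLines(paste0(DNA_BASES[k], "  [ ",
                      paste(format(cnt[k, ], width = 4), collapse = " "),
                      " ]"), con)
  }
  invisible(path)
}

# Under OOPS a motif carries at most one site per sequence; merging unions
# the site lists of duplicate discoveries, so re-impose the constraint by
# keeping the best-scoring site (motif-model log-likelihood of the site
# text under the PFM) per sequence and rebuilding the motif from the kept
# l-mers.
.dedupe_sites_oops <- function(m, X, B, eps = 1) {
  if (!anyDuplicated(m$sites$seq_index)) return(m)
  lf <- log(m$freqs)
  score <- vapply(seq_len(nrow(m$sites)), function(i) {
    v <- encode_seq(m$sites$text[i])
    w <- seq_along(v)
    sum(lf[cbind(w, v)])
  }, numeric(1))
  ord <- order(m$sites$seq_index, -score, m$sites$start)
  keep <- ord[!duplicated(m$sites$seq_index[ord])]
  sites <- m$sites[sort(keep), ]
  idx <- vapply(seq_len(nrow(sites)), function(i) {
    j <- which(X$seq_index == sites$seq_index[i] &
                 X$start == sites$start[i])
    if (length(j) == 1L) j else NA_integer_
  }, integer(1))
  idx <- idx[!is.na(idx)]
  if (length(idx) < 2L) return(m)
  .make_motif(X, idx, B, eps = eps)
}
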