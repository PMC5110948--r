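# shared fixture builders; everything generated in code, no files

BASES <- c("A", "C", "G", "T")

rand_dna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

# a lmer_set whose rows are exactly `strings` (one sequence per string)
lmers_of <- function(strings) {
  extract_lmers(seq_set(strings), nchar(strings[1]))
}

# integer member matrix from strings
mat_of <- function(strings) {
  t(vapply(strings, function(s) match(strsplit(s, "")[[1]], BASES),
           integer(nchar(strings[1]))))
}

tmp_fasta <- function(lines) {
  path <- tempfile(fileext = ".fasta")
  writeLines(lines, path)
  path
}

# exhaustive maximum 1-1 site matching (oracle for match_sites), small inputs
exhaustive_match_count <- function(pred, truth, shift) {
  if (nrow(pred) == 0L || nrow(truth) == 0L) return(0L)
  compat <- outer(seq_len(nrow(pred)), seq_len(nrow(truth)),
                  Vectorize(function(i, j) {
                    pred$seq_id[i] == truth$seq_id[j] &&
                      abs(pred$start[i] - truth$start[j]) <= shift
                  }))
  best <- 0L
  recurse <- function(i, used, count) {
    if (i > nrow(pred)) {
      best <<- max(best, count)
      return(invisible())
    }
    recurse(i + 1L, used, count)                  # leave pred i unmatched
    for (j in which(compat[i, ] & !used)) {
      used2 <- used
      used2[j] <- TRUE
      recurse(i + 1L, used2, count + 1L)
    }
  }
  recurse(1L, rep(FALSE, nrow(truth)), 0L)
  best
}

# exhaustive planted-motif search: over every consensus within hamming <= d
# of some l-mer, pick per sequence the nearest l-mer within d (ties by
# position); optimum = max coverage, then min total distance, then the
# lexicographically smallest consensus
oracle_planted <- function(ds, d) {
  X <- extract_lmers(ds$S, ds$l)
  enc <- X$mat
  cands <- unique(unlist(lapply(seq_len(nrow(enc)), function(i) {
    v <- enc[i, ]
    out <- list(v)
    if (d >= 1) {
      for (p in seq_len(ds$l)) {
        for (b in setdiff(1:4, v[p])) {
          w <- v
          w[p] <- b
          out[[length(out) + 1L]] <- w
        }
      }
    }
    vapply(out, paste, character(1), collapse = "")
  })))
  best <- NULL
  for (cs in sort(cands)) {
    cv <- as.integer(strsplit(cs, "")[[1]])
    D <- rowSums(enc != matrix(cv, nrow(enc), ds$l, byrow = TRUE))
    members <- integer(0)
    tot <- 0L
    for (i in seq_len(ds$S$t)) {
      rows <- which(X$seq_index == i & D <= d)
      if (length(rows)) {
        j <- rows[order(D[rows], X$start[rows])][1L]
        members <- c(members, j)
        tot <- tot + D[j]
      }
    }
    if (is.null(best) || length(members) > best$cov ||
        (length(members) == best$cov && tot < best$tot)) {
      best <- list(cov = length(members), tot = tot,
                   key = sort(paste(X$seq_index[members], X$start[members])))
    }
  }
  best
}
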