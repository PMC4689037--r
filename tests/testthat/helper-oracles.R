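# Independent oracles used by unit and acceptance tests.  Each is a
# deliberately naive reimplementation (brute force, enumeration, or an
# unrelated library) of a quantity the package computes by another route.

# O(n^2) double-loop pair enumeration over raw trimer occurrences.
brute_pairs <- function(sequence, trimers = c("AGA", "AAG", "GAA"),
                        k_min = 3L) {
  L <- nchar(sequence)
  occ_pos <- integer(0); occ_tri <- character(0)
  for (i in seq_len(max(0L, L - 2L))) {
    t <- substr(sequence, i, i + 2L)
    if (t %in% trimers) { occ_pos <- c(occ_pos, i); occ_tri <- c(occ_tri, t) }
  }
  out <- list()
  for (u in seq_along(occ_pos)) for (d in seq_along(occ_pos)) {
    if (occ_pos[d] - occ_pos[u] >= k_min)
      out[[length(out) + 1L]] <- data.frame(
        up_pos = occ_pos[u], up_trimer = occ_tri[u],
        down_pos = occ_pos[d], down_trimer = occ_tri[d],
        stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(up_pos = integer(0), up_trimer = character(0),
                      down_pos = integer(0), down_trimer = character(0)))
  out <- do.call(rbind, out)
  out[order(out$up_pos, out$down_pos), , drop = FALSE]
}

# Exact one-sided hypergeometric tail P(X >= a) by explicit enumeration
# with log-factorials (independent of stats::phyper).
hyper_tail_enum <- function(a, b, c, d) {
  m <- a + c; n <- b + d; k <- a + b
  lfact <- lgamma(seq_len(m + n + 1))       # lfact[x+1] = log(x!)
  lch <- function(nn, kk) ifelse(kk < 0 | kk > nn, -Inf,
                                 lfact[nn + 1] - lfact[kk + 1] -
                                   lfact[nn - kk + 1])
  xs <- max(0L, k - n):min(k, m)
  logp <- lch(m, xs) + lch(n, k - xs) - lch(m + n, k)
  sum(exp(logp[xs >= a]))
}

# Per-position boxcar running mean with truncated windows (double loop).
brute_boxcar <- function(x, window) {
  h <- (window - 1) %/% 2
  out <- numeric(length(x))
  for (i in seq_along(x)) {
    lo <- max(1, i - h); hi <- min(length(x), i + h)
    out[i] <- sum(x[lo:hi]) / (hi - lo + 1)
  }
  out
}

# Exhaustive Hamming-distance mapper oracle built on Biostrings
# (the package's mapper is independent Rcpp code).  Returns a data.frame
# aligned with map_inserts() semantics: NA rows where the insert is
# unmapped or multimapped at its best stratum.
biostrings_map_oracle <- function(inserts, genome) {
  out <- data.frame(chrom = NA_character_, strand = NA_character_,
                    start = NA_integer_, mismatches = NA_integer_,
                    n_best = 0L)[rep(1L, length(inserts)), ]
  rownames(out) <- NULL
  for (r in seq_along(inserts)) {
    ins <- Biostrings::DNAString(inserts[r])
    rc <- Biostrings::reverseComplement(ins)
    hits <- list()
    for (ch in names(genome)) {
      subj <- genome[[ch]]
      for (st in c("+", "-")) {
        q <- if (st == "+") ins else rc
        m1 <- Biostrings::matchPattern(q, subj, max.mismatch = 1)
        if (!length(m1)) next
        nmm <- Biostrings::neditStartingAt(q, subj,
                                           starting.at = IRanges::start(m1))
        hits[[length(hits) + 1L]] <- data.frame(
          chrom = ch, strand = st, start = IRanges::start(m1) - 1L,
          mismatches = nmm)
      }
    }
    if (!length(hits)) next
    h <- do.call(rbind, hits)
    best <- min(h$mismatches)
    h <- h[h$mismatches == best, , drop = FALSE]
    out$n_best[r] <- nrow(h)
    if (nrow(h) == 1L) {
      out$chrom[r] <- h$chrom; out$strand[r] <- h$strand
      out$start[r] <- h$start; out$mismatches[r] <- h$mismatches
    }
  }
  out
}

# Longest perfect tandem run (in unit copies) of any period-3 unit.
brute_max_trimer_run <- function(sequence) {
  L <- nchar(sequence)
  best <- 0L
  for (i in seq_len(max(0L, L - 2L))) {
    unit <- substr(sequence, i, i + 2L)
    n <- 1L
    while (i + 3L * n + 2L <= L &&
           substr(sequence, i + 3L * n, i + 3L * n + 2L) == unit)
      n <- n + 1L
    best <- max(best, n)
  }
  best
}

random_seq <- function(n, prob = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}
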