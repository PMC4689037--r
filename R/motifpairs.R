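#' Extract an analysis region from an exon record
#'
#' Regions are the four 50-nt windows of the trimer analyses: the first
#' or last 50 nt of the exon, the last 50 nt of the upstream intron, or
#' the first 50 nt of the downstream intron (all in transcript
#' orientation).  Records whose sequence cannot cover the region return
#' `NA` and are skipped by callers.
#'
#' @param exons Exon record data.frame (needs `sequence`; intron regions
#'   additionally need `upstream_intron_seq` / `downstream_intron_seq`).
#' @param region One of `"exon_first50"`, `"exon_last50"`,
#'   `"upstream_intron_last50"`, `"downstream_intron_first50"`.
#' @param region_length Region width in nt (default 50).
#' @return Character vector of region sequences (NA where unavailable).
#' @export
region_sequences <- function(exons, region = c("exon_last50",
                                               "exon_first50",
                                               "upstream_intron_last50",
                                               "downstream_intron_first50"),
                             region_length = clip_defaults()$region_length) {
  region <- match.arg(region)
  src <- switch(region,
                exon_first50 = , exon_last50 = exons$sequence,
                upstream_intron_last50 = exons$upstream_intron_seq,
                downstream_intron_first50 = exons$downstream_intron_seq)
  if (is.null(src))
    stop("exon records lack the sequence column needed for ", region)
  n <- nchar(src)
  out <- rep(NA_character_, length(src))
  ok <- !is.na(src) & n >= region_length
  from_start <- region %in% c("exon_first50", "downstream_intron_first50")
  out[ok] <- if (from_start) substr(src[ok], 1L, region_length)
             else substr(src[ok], n[ok] - region_length + 1L, n[ok])
  out
}

# 1-based start positions of each target trimer in a sequence
# (overlapping occurrences included).
trimer_positions <- function(sequence, trimers) {
  L <- nchar(sequence)
  if (is.na(sequence) || L < 3L)
    return(data.frame(pos = integer(0), trimer = character(0)))
  subs <- substring(sequence, 1:(L - 2L), 3:L)
  hit <- subs %in% trimers
  data.frame(pos = which(hit), trimer = subs[hit],
             stringsAsFactors = FALSE)
}

#' Mark trimer start positions in target and control exon regions
#'
#' Position `i` of the region is marked for an exon iff one of the
#' target trimers starts there.  Per-position marked counts of the
#' target set are compared with the control set by Fisher's exact test
#' (two-sided by default, since no direction is asserted per position).
#'
#' @param target_exons,control_exons Exon record data.frames; pass
#'   `control_exons = NULL` to skip the tests.
#' @param trimers Target trimers (default AGA, AAG, GAA).
#' @param region,region_length See [region_sequences()].
#' @param alternative Sidedness of the per-position test.
#' @return Object of class `positional_counts`: data.frame `position`
#'   (1-based within the region), `target_marked`, `control_marked`,
#'   `p` (NA when controls absent); attributes `n_target`, `n_control`,
#'   `n_skipped_target`, `n_skipped_control` (records not covering the
#'   region).
#' @export
mark_positions <- function(target_exons, control_exons = NULL,
                           trimers = clip_defaults()$target_trimers,
                           region = "exon_last50",
                           region_length = clip_defaults()$region_length,
                           alternative = "two.sided") {
  count_marks <- function(exons) {
    seqs <- region_sequences(exons, region, region_length)
    seqs <- seqs[!is.na(seqs)]
    counts <- integer(region_length)
    for (s in seqs) {
      tp <- trimer_positions(s, trimers)
      counts[tp$pos] <- counts[tp$pos] + 1L
    }
    list(counts = counts, n = length(seqs))
  }
  tg <- count_marks(target_exons)
  out <- data.frame(position = seq_len(region_length),
                    target_marked = tg$counts)
  n_ctrl <- 0L; skipped_ctrl <- 0L
  if (!is.null(control_exons)) {
    ct <- count_marks(control_exons)
    n_ctrl <- ct$n
    skipped_ctrl <- nrow(control_exons) - ct$n
    out$control_marked <- ct$counts
    out$p <- vapply(seq_len(region_length), function(i)
      stats::fisher.test(matrix(c(tg$counts[i], tg$n - tg$counts[i],
                                  ct$counts[i], ct$n - ct$counts[i]),
                                nrow = 2L),
                         alternative = alternative)$p.value,
      numeric(1))
  } else {
    out$control_marked <- NA_integer_
    out$p <- NA_real_
  }
  structure(out, n_target = tg$n, n_control = n_ctrl,
            n_skipped_target = nrow(target_exons) - tg$n,
            n_skipped_control = skipped_ctrl,
            class = c("positional_counts", "data.frame"))
}

#' Enumerate qualifying trimer pairs in a region sequence
#'
#' A qualifying pair is an ordered pair of target-trimer occurrences
#' both fully inside the region, with the downstream start at least
#' `k_min` positions after the upstream start (k = 3 excludes pairs
#' arising from overlapping sequences such as AAGA).
#'
#' @param sequence The region sequence (a single string).
#' @param trimers Target trimers.
#' @param k_min Minimum start-offset (default 3; must be >= 3).
#' @return data.frame: `up_pos`, `up_trimer`, `down_pos`,
#'   `down_trimer` (positions 1-based within the region).
#' @export
#' @examples
#' find_pairs("AAGAAGA")   # 3 qualifying pairs
#' find_pairs("AAGA")      # none: overlap excluded
find_pairs <- function(sequence, trimers = clip_defaults()$target_trimers,
                       k_min = clip_defaults()$k_min) {
  stopifnot(k_min >= 3L)
  occ <- trimer_positions(sequence, trimers)
  empty <- data.frame(up_pos = integer(0), up_trimer = character(0),
                      down_pos = integer(0), down_trimer = character(0))
  if (nrow(occ) < 2L) return(empty)
  idx <- which(outer(occ$pos, occ$pos,
                     function(u, d) d - u >= k_min), arr.ind = TRUE)
  if (!nrow(idx)) return(empty)
  out <- data.frame(up_pos = occ$pos[idx[, 1]],
                    up_trimer = occ$trimer[idx[, 1]],
                    down_pos = occ$pos[idx[, 2]],
                    down_trimer = occ$trimer[idx[, 2]],
                    stringsAsFactors = FALSE)
  out[order(out$up_pos, out$down_pos), , drop = FALSE]
}

# Per-exon presence of >=1 qualifying (up, down) pair; down may be "Any".
pair_presence <- function(region_seqs, up_trimer, down_trimer, trimers,
                          k_min) {
  vapply(region_seqs, function(s) {
    if (is.na(s)) return(NA)
    p <- find_pairs(s, trimers, k_min)
    if (!nrow(p)) return(FALSE)
    any(p$up_trimer == up_trimer &
          (down_trimer == "Any" | p$down_trimer == down_trimer))
  }, logical(1), USE.NAMES = FALSE)
}

# One-sided (over-representation) Fisher p for table
# [a, b; c, d] = [target with pair, without; control with, without].
fisher_one_sided <- function(a, b, c, d) {
  stats::phyper(a - 1L, a + c, b + d, a + b, lower.tail = FALSE)
}

#' Per-exon pair-presence matrix for a set of motif pairs
#'
#' Pair presence is a fixed attribute of an exon's region sequence, so
#' it can be precomputed once and reused across bootstrap trials.  An
#' exon has a pair (up, down) iff some occurrence of the downstream
#' trimer starts at least `k_min` positions after some occurrence of
#' the upstream trimer, i.e. iff
#' `max(down positions) - min(up positions) >= k_min`.
#'
#' @param region_seqs Character vector of region sequences (NAs are
#'   dropped).
#' @param pairs data.frame with `up_trimer`, `down_trimer` (may be
#'   `"Any"`).
#' @param trimers Target trimer set.
#' @param k_min Minimum start-offset.
#' @return Numeric 0/1 matrix, one row per retained sequence, one
#'   column per pair (named "up>down").
#' @export
pair_presence_matrix <- function(region_seqs, pairs,
                                 trimers = clip_defaults()$target_trimers,
                                 k_min = clip_defaults()$k_min) {
  seqs <- region_seqs[!is.na(region_seqs)]
  m <- matrix(0, nrow = length(seqs), ncol = nrow(pairs),
              dimnames = list(NULL, paste0(pairs$up_trimer, ">",
                                           pairs$down_trimer)))
  for (i in seq_along(seqs)) {
    occ <- trimer_positions(seqs[i], trimers)
    if (nrow(occ) < 2L) next
    mins <- tapply(occ$pos, occ$trimer, min)
    maxs <- tapply(occ$pos, occ$trimer, max)
    any_max <- max(occ$pos)
    for (k in seq_len(nrow(pairs))) {
      up <- pairs$up_trimer[k]; dn <- pairs$down_trimer[k]
      if (is.na(mins[up])) next
      dmax <- if (dn == "Any") any_max else maxs[dn]
      if (!is.na(dmax) && dmax - mins[up] >= k_min) m[i, k] <- 1
    }
  }
  m
}

#' Bootstrap null p-values for motif pairs
#'
#' Draws `n_trials` samples of `sample_size` exons without replacement
#' from the population and, for every motif pair, computes the same
#' one-sided Fisher p-value against the control set as [pair_test()].
#'
#' @param population_exons,control_exons Exon record data.frames.
#' @param pairs data.frame with `up_trimer`, `down_trimer`; defaults to
#'   the nine specific plus three degenerate pairs.
#' @inheritParams bootstrap_fdr
#' @return Numeric matrix, `n_trials` rows by pair columns.
#' @export
bootstrap_trial_pvalues <- function(population_exons, control_exons,
                                    pairs = NULL,
                                    n_trials = clip_defaults()$n_trials,
                                    sample_size = clip_defaults()$sample_size,
                                    seed = 1L,
                                    region = "exon_last50",
                                    region_length =
                                      clip_defaults()$region_length,
                                    k_min = clip_defaults()$k_min,
                                    trimers =
                                      clip_defaults()$target_trimers) {
  if (n_trials < 1L) stop("n_trials must be >= 1")
  if (is.null(pairs))
    pairs <- rbind(expand.grid(up_trimer = trimers, down_trimer = trimers,
                               stringsAsFactors = FALSE),
                   data.frame(up_trimer = trimers, down_trimer = "Any"))
  ps <- region_sequences(population_exons, region, region_length)
  ps <- ps[!is.na(ps)]
  if (length(ps) < sample_size)
    stop("population (", length(ps), ") smaller than sample_size (",
         sample_size, ")")
  cs <- region_sequences(control_exons, region, region_length)
  cs <- cs[!is.na(cs)]
  pop_pres <- pair_presence_matrix(ps, pairs, trimers, k_min)
  ctrl_with <- colSums(pair_presence_matrix(cs, pairs, trimers, k_min))
  bootstrap_trials_core(pop_pres, ctrl_with, length(cs), n_trials,
                        sample_size, seed)
}

# Trial loop over a precomputed population presence matrix; split out so
# repeated calibration runs can reuse the expensive presence scan.
bootstrap_trials_core <- function(pop_pres, ctrl_with, n_ctrl, n_trials,
                                  sample_size, seed) {
  out <- matrix(NA_real_, nrow = n_trials, ncol = ncol(pop_pres),
                dimnames = list(NULL, colnames(pop_pres)))
  with_seed(seed, {
    for (t in seq_len(n_trials)) {
      idx <- sample.int(nrow(pop_pres), sample_size)
      a <- colSums(pop_pres[idx, , drop = FALSE])
      out[t, ] <- fisher_one_sided(a, sample_size - a, ctrl_with,
                                   n_ctrl - ctrl_with)
    }
  })
  out
}

#' Test one motif pair for over-representation in a target exon set
#'
#' Counts, in each set, the exons whose region contains at least one
#' qualifying (upstream, downstream) pair, and tests the resulting 2x2
#' table (target with/without pair vs control with/without) by Fisher's
#' exact test, one-sided for over-representation in the target set by
#' default.
#'
#' @param target_exons,control_exons Exon record data.frames (apply
#'   [repeat_filter()] first).
#' @param up_trimer Upstream trimer.
#' @param down_trimer Downstream trimer, or `"Any"` for the degenerate
#'   pair (any of the three target trimers downstream).
#' @param region,region_length See [region_sequences()].
#' @param k_min Minimum pair start-offset.
#' @param trimers Target trimer set.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return One-row data.frame: `up_trimer`, `down_trimer`, `region`,
#'   `a`, `b`, `c`, `d`, `p_fisher`.
#' @export
pair_test <- function(target_exons, control_exons, up_trimer,
                      down_trimer = "Any", region = "exon_last50",
                      region_length = clip_defaults()$region_length,
                      k_min = clip_defaults()$k_min,
                      trimers = clip_defaults()$target_trimers,
                      alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (!nrow(target_exons) || !nrow(control_exons))
    stop("both exon sets must be non-empty")
  ts <- region_sequences(target_exons, region, region_length)
  cs <- region_sequences(control_exons, region, region_length)
  tp <- pair_presence(ts[!is.na(ts)], up_trimer, down_trimer, trimers, k_min)
  cp <- pair_presence(cs[!is.na(cs)], up_trimer, down_trimer, trimers, k_min)
  if (!length(tp) || !length(cp))
    stop("no exon covers region ", region)
  a <- sum(tp); b <- length(tp) - a
  cc <- sum(cp); d <- length(cp) - cc
  p <- if (alternative == "greater") fisher_one_sided(a, b, cc, d)
       else stats::fisher.test(matrix(c(a, b, cc, d), 2L))$p.value
  data.frame(up_trimer = up_trimer, down_trimer = down_trimer,
             region = region, a = a, b = b, c = cc, d = d, p_fisher = p,
             stringsAsFactors = FALSE)
}

#' Test all specific and degenerate trimer pairs in a region
#'
#' Runs [pair_test()] for the nine ordered specific pairs and the three
#' degenerate pairs (specific upstream trimer, `"Any"` downstream) and
#' ranks results by ascending p, then descending target count `a`, then
#' pair name.
#'
#' @inheritParams pair_test
#' @return data.frame of 12 [pair_test()] rows with a `rank` column.
#' @export
pair_test_all <- function(target_exons, control_exons,
                          region = "exon_last50",
                          region_length = clip_defaults()$region_length,
                          k_min = clip_defaults()$k_min,
                          trimers = clip_defaults()$target_trimers,
                          alternative = "greater") {
  combos <- rbind(expand.grid(up = trimers, down = trimers,
                              stringsAsFactors = FALSE),
                  data.frame(up = trimers, down = "Any"))
  res <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i)
    pair_test(target_exons, control_exons, combos$up[i], combos$down[i],
              region, region_length, k_min, trimers, alternative)))
  ord <- order(res$p_fisher, -res$a,
               paste(res$up_trimer, res$down_trimer))
  res$rank <- integer(nrow(res))
  res$rank[ord] <- seq_len(nrow(res))
  res[order(res$rank), , drop = FALSE]
}

#' Bootstrap false-discovery estimate for motif-pair tests
#'
#' For each of `n_trials` trials, `sample_size` exons are drawn without
#' replacement from a population of known exons and every motif pair is
#' tested against the (fixed) control set exactly as in [pair_test()].
#' The FDR of a pair is the fraction of trials whose p-value is at most
#' the observed p-value for that pair; when no trial beats the observed
#' p the FDR is reported as below `1/n_trials`.  Observed p-values
#' above `alpha_ns` (default 5e-4) are marked not significant.
#'
#' @param observed_results A [pair_test_all()] table.
#' @param population_exons Exon records to resample from (must have at
#'   least `sample_size` rows covering the region).
#' @param control_exons The control set used for the observed tests.
#' @param n_trials Bootstrap trials (default 10000).
#' @param sample_size Exons per trial (default 109).
#' @param seed RNG seed.
#' @param alpha_ns Not-significant threshold on the observed p.
#' @inheritParams pair_test
#' @return `observed_results` with columns `fdr_bootstrap`,
#'   `fdr_below_resolution` (TRUE when zero trials beat the observed p)
#'   and `significant`.
#' @export
bootstrap_fdr <- function(observed_results, population_exons,
                          control_exons,
                          n_trials = clip_defaults()$n_trials,
                          sample_size = clip_defaults()$sample_size,
                          seed = 1L,
                          region = "exon_last50",
                          region_length = clip_defaults()$region_length,
                          k_min = clip_defaults()$k_min,
                          trimers = clip_defaults()$target_trimers,
                          alpha_ns = clip_defaults()$alpha_ns) {
  if (n_trials < 1L) stop("n_trials must be >= 1")
  pairs <- observed_results[, c("up_trimer", "down_trimer")]
  p_trial <- bootstrap_trial_pvalues(population_exons, control_exons,
                                     pairs, n_trials, sample_size, seed,
                                     region, region_length, k_min, trimers)
  beat <- colSums(p_trial <= matrix(observed_results$p_fisher,
                                    nrow = n_trials, ncol = nrow(pairs),
                                    byrow = TRUE))
  observed_results$fdr_bootstrap <- beat / n_trials
  observed_results$fdr_below_resolution <- beat == 0L
  observed_results$significant <- observed_results$p_fisher <= alpha_ns
  observed_results
}

#' Design trimer-ablating mutations
#'
#' Replaces every G lying inside an occurrence of AAG, AGA or GAA with
#' C, re-scanning until no target trimer remains.  Only G-to-C
#' substitutions are ever made; since a C can never create a new
#' purine trimer, the scan converges.
#'
#' @param sequence A single A/C/G/T string.
#' @param trimers Target trimers (default AGA, AAG, GAA).
#' @return List: `sequence` (mutated) and `changes` (data.frame
#'   `position` 1-based, `from`, `to`).
#' @export
#' @examples
#' mutate_trimers("GAAGA")$sequence   # "CAACA"
mutate_trimers <- function(sequence,
                           trimers = clip_defaults()$target_trimers) {
  stopifnot(length(sequence) == 1L, !grepl("[^ACGT]", sequence))
  changes <- list()
  repeat {
    occ <- trimer_positions(sequence, trimers)
    if (!nrow(occ)) break
    covered <- unique(unlist(lapply(occ$pos, function(p) p:(p + 2L))))
    ch <- strsplit(sequence, "")[[1]]
    gpos <- covered[ch[covered] == "G"]
    if (!length(gpos)) break   # unreachable for purine trimers
    ch[gpos] <- "C"
    changes[[length(changes) + 1L]] <- data.frame(
      position = sort(gpos), from = "G", to = "C")
    sequence <- paste(ch, collapse = "")
  }
  changes <- if (length(changes))
    do.call(rbind, c(changes, list(make.row.names = FALSE)))
  else data.frame(position = integer(0), from = character(0),
                  to = character(0))
  list(sequence = sequence, changes = changes)
}
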