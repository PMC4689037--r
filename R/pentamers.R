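#' Extract oriented windows around crosslink sites
#'
#' Returns the 61-nt (2 * `half_window` + 1) genomic window centered on
#' each crosslink site, reverse-complemented for "-" strand sites so
#' every window reads in transcript orientation.  Sites closer than
#' `half_window` to a contig end are dropped (default) or clipped.
#'
#' @param sites Crosslink-site data.frame.
#' @param genome [Biostrings::DNAStringSet].
#' @param half_window Half-window in nt (default 30, i.e. -30..+30).
#' @param edge `"drop"` (default) or `"clip"`.
#' @return [Biostrings::DNAStringSet] of windows with attribute `kept`
#'   (indices into `sites` of the windows returned, in order).
#' @export
window_sequences <- function(sites, genome,
                             half_window = clip_defaults()$half_window,
                             edge = c("drop", "clip")) {
  edge <- match.arg(edge)
  clen <- setNames(Biostrings::width(genome), names(genome))
  lo <- sites$position - half_window          # 0-based inclusive
  hi <- sites$position + half_window
  if (edge == "drop") {
    kept <- which(lo >= 0L & hi < unname(clen[sites$chrom]))
  } else {
    kept <- seq_len(nrow(sites))
    lo <- pmax(lo, 0L)
    hi <- pmin(hi, clen[sites$chrom] - 1L)
  }
  out <- vector("list", length(kept))
  s <- sites[kept, , drop = FALSE]
  res <- character(length(kept))
  for (ch in unique(s$chrom)) {
    i <- which(s$chrom == ch)
    v <- Biostrings::Views(genome[[ch]], start = lo[kept][i] + 1L,
                           end = hi[kept][i] + 1L)
    w <- as(v, "DNAStringSet")
    minus <- s$strand[i] == "-"
    if (any(minus)) w[minus] <- Biostrings::reverseComplement(w[minus])
    res[i] <- as.character(w)
  }
  out <- Biostrings::DNAStringSet(res)
  attr(out, "kept") <- kept
  out
}

#' Randomize crosslink sites within their own region instance
#'
#' Each site is assigned to the annotated region instance containing it
#' (resolving overlaps by the ncRNA > ORF > UTR5 > UTR3 > intron
#' precedence) and `n_rand` uniform random positions are drawn over that
#' instance.  CDS-resident sites are thereby randomized within the same
#' CDS; sites in other region classes are randomized within their own
#' instance of that class.  Sites outside any annotated region are
#' excluded and counted.
#'
#' @param sites Crosslink-site data.frame.
#' @param models `gene_models` or region data.frame.
#' @param n_rand Number of randomized copies (default 100).
#' @return List: `sites` (the retained sites), `positions` (integer
#'   matrix, retained sites x n_rand, 0-based), `kept` (indices into
#'   the input), `n_excluded`.
#' @export
randomize_sites <- function(sites, models,
                            n_rand = clip_defaults()$n_rand) {
  stopifnot(n_rand >= 1L)
  regions <- if (is(models, "gene_models")) models$regions else models
  prec <- match(regions$region_class, REGION_PRECEDENCE)
  reg_gr <- GenomicRanges::GRanges(
    regions$chrom, IRanges::IRanges(regions$start + 1L, regions$end))
  site_gr <- GenomicRanges::GRanges(
    sites$chrom, IRanges::IRanges(sites$position + 1L, width = 1L))
  ov <- GenomicRanges::findOverlaps(site_gr, reg_gr, ignore.strand = TRUE)
  q <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  ord <- order(q, prec[sh], sh)
  q <- q[ord]; sh <- sh[ord]
  first <- !duplicated(q)
  assign_reg <- rep(NA_integer_, nrow(sites))
  assign_reg[q[first]] <- sh[first]
  kept <- which(!is.na(assign_reg))
  n_excluded <- nrow(sites) - length(kept)
  reg <- assign_reg[kept]
  lo <- regions$start[reg]; hi <- regions$end[reg] - 1L
  pos <- matrix(rint(length(kept) * n_rand, rep(lo, n_rand),
                     rep(hi, n_rand)),
                nrow = length(kept), ncol = n_rand)
  list(sites = sites[kept, , drop = FALSE], positions = pos,
       kept = kept, n_excluded = n_excluded)
}

# Per-pentamer statistic over a window set: windows containing >=1
# occurrence ("windows", default) or total occurrences ("occurrences").
pentamer_counts <- function(windows, count_mode = c("windows",
                                                    "occurrences")) {
  count_mode <- match.arg(count_mode)
  m <- Biostrings::oligonucleotideFrequency(windows, 5L)
  if (count_mode == "windows") colSums(m > 0L) else colSums(m)
}

#' Pentamer Z-scores against randomized crosslink positions
#'
#' For each of the 1024 pentamers, compares its observed statistic in
#' the true crosslink windows with its mean and standard deviation over
#' the randomized window sets: `z = (observed - mean) / sd`, with the
#' standard deviation floored at 1e-9 (pentamers never seen in any
#' randomization are flagged).
#'
#' @param observed_windows [Biostrings::DNAStringSet] of true-site
#'   windows.
#' @param randomized_window_sets List of [Biostrings::DNAStringSet],
#'   one per randomization.
#' @param count_mode `"windows"` (windows containing the pentamer;
#'   default) or `"occurrences"` (total occurrence count).
#' @return data.frame: `pentamer`, `observed`, `random_mean`,
#'   `random_sd`, `z`, `flagged` (TRUE where sd hit the floor), sorted
#'   by decreasing z.
#' @export
pentamer_z <- function(observed_windows, randomized_window_sets,
                       count_mode = c("windows", "occurrences")) {
  count_mode <- match.arg(count_mode)
  if (length(observed_windows) == 0L)
    stop("no observed windows; cannot compute Z-scores")
  if (length(randomized_window_sets) < 1L)
    stop("at least one randomization is required")
  obs <- pentamer_counts(observed_windows, count_mode)
  rnd <- vapply(randomized_window_sets, pentamer_counts,
                numeric(length(obs)), count_mode = count_mode)
  rnd <- matrix(rnd, nrow = length(obs))
  mu <- rowMeans(rnd)
  sdv <- if (ncol(rnd) > 1L)
    sqrt(rowSums((rnd - mu)^2) / (ncol(rnd) - 1L)) else rep(0, length(obs))
  eps <- 1e-9
  flagged <- sdv < eps
  z <- (obs - mu) / pmax(sdv, eps)
  out <- data.frame(pentamer = names(obs), observed = as.numeric(obs),
                    random_mean = mu, random_sd = sdv, z = z,
                    flagged = flagged, row.names = NULL)
  out[order(-out$z, out$pentamer), ]
}

#' One-call pentamer scoring for a site set
#'
#' Convenience wrapper: randomizes sites within their region instances,
#' extracts observed and randomized windows, and computes the Z-score
#' table.
#'
#' @inheritParams randomize_sites
#' @inheritParams window_sequences
#' @inheritParams pentamer_z
#' @param seed RNG seed for the randomization.
#' @return List: `scores` (the [pentamer_z()] table), `observed_windows`,
#'   `randomized_windows` (list), `n_excluded`.
#' @export
pentamer_scores <- function(sites, genome, models,
                            half_window = clip_defaults()$half_window,
                            n_rand = clip_defaults()$n_rand,
                            count_mode = "windows", seed = 1L) {
  with_seed(seed, {
    rnd <- randomize_sites(sites, models, n_rand)
    obs_w <- window_sequences(rnd$sites, genome, half_window)
    rand_w <- lapply(seq_len(n_rand), function(r) {
      s <- rnd$sites
      s$position <- rnd$positions[, r]
      window_sequences(s, genome, half_window)
    })
    list(scores = pentamer_z(obs_w, rand_w, count_mode),
         observed_windows = obs_w, randomized_windows = rand_w,
         n_excluded = rnd$n_excluded)
  })
}

#' Positional occurrence profiles of selected pentamers
#'
#' For each pentamer and each start offset within the window
#' (-half_window .. half_window - 4), computes the ratio of the observed
#' start frequency to the mean randomized start frequency; 0/0 is
#' reported as 1 and x/0 as Inf with a flag.
#'
#' @param top_pentamers Character vector of pentamers to profile.
#' @param observed_windows,randomized_window_sets As in [pentamer_z()].
#' @param half_window Half-window used to build the windows.
#' @return data.frame: `pentamer`, `offset` (pentamer start relative to
#'   the crosslink nucleotide), `observed_freq`, `random_freq`, `ratio`,
#'   `flagged`.
#' @export
positional_profile <- function(top_pentamers, observed_windows,
                               randomized_window_sets,
                               half_window = clip_defaults()$half_window) {
  stopifnot(length(top_pentamers) >= 1L)
  wlen <- 2L * half_window + 1L
  n_off <- wlen - 4L
  start_counts <- function(windows, pent) {
    x <- as.character(windows)
    vapply(seq_len(n_off), function(i)
      sum(substr(x, i, i + 4L) == pent), numeric(1))
  }
  out <- list()
  for (pent in top_pentamers) {
    obs <- start_counts(observed_windows, pent) / length(observed_windows)
    rnd <- rowMeans(vapply(randomized_window_sets, function(w)
      start_counts(w, pent) / length(w), numeric(n_off)))
    ratio <- obs / rnd
    ratio[obs == 0 & rnd == 0] <- 1
    flagged <- rnd == 0 & obs > 0
    out[[pent]] <- data.frame(pentamer = pent,
                              offset = seq_len(n_off) - 1L - half_window,
                              observed_freq = obs, random_freq = rnd,
                              ratio = ratio, flagged = flagged)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Replicate concordance of pentamer Z-scores
#'
#' Pearson correlation of the 1024-dimensional Z-score vectors for every
#' replicate pair, plus the shared members of each pair's top-k
#' pentamers.
#'
#' @param score_tables Named list of [pentamer_z()] tables, one per
#'   replicate.
#' @param top_k Size of the top set compared (default 5).
#' @return data.frame: `rep1`, `rep2`, `r`, `n_shared_top`,
#'   `shared_top` (comma-collapsed).
#' @export
concordance <- function(score_tables, top_k = 5L) {
  stopifnot(length(score_tables) >= 2L)
  ids <- names(score_tables)
  if (is.null(ids)) ids <- paste0("rep", seq_along(score_tables))
  zs <- lapply(score_tables, function(t) {
    t <- t[order(t$pentamer), ]
    setNames(t$z, t$pentamer)
  })
  out <- list()
  for (i in seq_len(length(zs) - 1L)) for (j in (i + 1L):length(zs)) {
    zi <- zs[[i]]; zj <- zs[[j]][names(zi)]
    if (sd(zi) == 0 || sd(zj) == 0)
      stop("degenerate (constant) z-vector for replicate ", ids[i],
           " or ", ids[j])
    topi <- names(sort(zi, decreasing = TRUE))[seq_len(top_k)]
    topj <- names(sort(zj, decreasing = TRUE))[seq_len(top_k)]
    shared <- intersect(topi, topj)
    out[[length(out) + 1L]] <- data.frame(
      rep1 = ids[i], rep2 = ids[j], r = cor(zi, zj),
      n_shared_top = length(shared),
      shared_top = paste(shared, collapse = ","))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
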