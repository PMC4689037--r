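#' Simulate regulated, control and population cassette-exon sets
#'
#' Generates four exon classes with background base composition:
#' `up` and `down` (differential p-values drawn below 0.05 with fold
#' changes beyond +/-2), `control` (p-values above 0.95, small fold
#' changes) and `population` (unlabeled, for bootstrap resampling).
#' With probability `pair_plant_rate`, each `down` exon receives a
#' planted trimer pair inside its last 50 nt: an AGA followed, at a
#' start-offset of at least `k_min`, by one of AGA/AAG/GAA.  All exons
#' are at least 100 nt long so the two 50-nt analysis windows fit.
#'
#' @param cfg A [sim_config()].
#' @param k_min Minimum start-offset between planted pair members
#'   (default 3, the trimer non-overlap rule).
#' @return List of class `sim_exon_sets` with `exons` (one data.frame of
#'   exon records: exon_id, gene_id, chrom, start, end, strand, sequence,
#'   midas_p, fold_change, class_label) and `truth` (class `sim_truth`;
#'   `planted_pair_exons` records exon_id, up_trimer, down_trimer and the
#'   planted 1-based start positions within the exon sequence).
#' @export
#' @examples
#' es <- make_exon_sets(sim_config(seed = 2, n_regulated_exons = 10))
#' table(es$exons$class_label)
make_exon_sets <- function(cfg, k_min = clip_defaults()$k_min) {
  stopifnot(is(cfg, "sim_config"))
  with_seed(cfg$seed, {
    n_reg <- cfg$n_regulated_exons
    n_pop <- cfg$n_population_exons
    counts <- c(up = n_reg, down = n_reg, control = n_reg,
                population = n_pop)
    n_tot <- sum(counts)
    lens <- rint(n_tot, max(100L, cfg$exon_len_range[1]),
                 max(100L, cfg$exon_len_range[2]))
    seqs <- vapply(lens, random_dna, character(1),
                   base_composition = cfg$base_composition)
    cls <- rep(names(counts), counts)
    midas_p <- numeric(n_tot)
    fold <- numeric(n_tot)
    is_up <- cls == "up"; is_dn <- cls == "down"
    is_ct <- cls == "control"; is_po <- cls == "population"
    midas_p[is_up | is_dn] <- runif(sum(is_up | is_dn), 0, 0.049)
    midas_p[is_ct] <- runif(sum(is_ct), 0.951, 1)
    midas_p[is_po] <- runif(sum(is_po), 0, 1)
    fold[is_up] <- runif(sum(is_up), 2.1, 8)
    fold[is_dn] <- -runif(sum(is_dn), 2.1, 8)
    fold[is_ct | is_po] <- runif(sum(is_ct | is_po), -1.5, 1.5)

    # plant AGA -> {AGA,AAG,GAA} pairs in the last 50 nt of down exons
    planted <- list()
    trimers <- clip_defaults()$target_trimers
    for (i in which(is_dn)) {
      if (runif(1) >= cfg$pair_plant_rate) next
      L <- lens[i]
      reg0 <- L - 50L                       # 0-based start of last-50 region
      gap <- rint(1L, k_min, 10L)
      up_off <- rint(1L, 0L, 47L - gap)     # 0-based offset within region
      dn_tri <- sample(trimers, 1L)
      up_pos <- reg0 + up_off + 1L          # 1-based in exon sequence
      dn_pos <- up_pos + gap
      substr(seqs[i], up_pos, up_pos + 2L) <- "AGA"
      substr(seqs[i], dn_pos, dn_pos + 2L) <- dn_tri
      planted[[length(planted) + 1L]] <- data.frame(
        exon_idx = i, up_trimer = "AGA", down_trimer = dn_tri,
        up_pos = up_pos, down_pos = dn_pos)
    }
    ids <- sprintf("%s_exon_%05d", cls, seq_len(n_tot))
    # synthetic coordinates: exons tiled on a virtual contig, gap 100 nt
    starts <- cumsum(c(0L, head(lens, -1L) + 100L))
    exons <- data.frame(exon_id = ids,
                        gene_id = sprintf("gene_%05d", seq_len(n_tot)),
                        chrom = "chrV", start = starts,
                        end = starts + lens, strand = "+",
                        sequence = seqs, midas_p = midas_p,
                        fold_change = fold, class_label = cls,
                        stringsAsFactors = FALSE)
    planted_df <- if (length(planted)) {
      p <- do.call(rbind, planted)
      data.frame(exon_id = ids[p$exon_idx], up_trimer = p$up_trimer,
                 down_trimer = p$down_trimer, up_pos = p$up_pos,
                 down_pos = p$down_pos, stringsAsFactors = FALSE)
    } else data.frame(exon_id = character(0), up_trimer = character(0),
                      down_trimer = character(0), up_pos = integer(0),
                      down_pos = integer(0))
    truth <- structure(list(planted_pair_exons = planted_df, config = cfg),
                       class = "sim_truth")
    structure(list(exons = exons, truth = truth), class = "sim_exon_sets")
  })
}

#' Simulate a control-exon selection cohort with planted filter defects
#'
#' Builds a small annotated world (one contig per gene, each gene a
#' chain of introns and exons with one or two cassette-exon candidates),
#' a differential-exon table, and a 3+3-replicate expression table.  A
#' known subset of candidate exons is given exactly one disqualifying
#' defect each — a low MiDAS p-value, under-threshold expression in one
#' condition, a terminal (non-internal) position, length below 100 nt,
#' an overlapping twin exon, or an ambiguous nucleotide — while the rest
#' qualify on every criterion.  The truth object lists the qualifying
#' exon ids, determined purely by construction.
#'
#' @param cfg A [sim_config()]; `n_genes` genes are generated.
#' @return List of class `sim_cohort`: `genome`, `annotation`
#'   (`gene_models`), `diff_table`, `expression`, `truth` (qualifying
#'   exon ids plus the per-exon defect table).
#' @export
make_control_cohort <- function(cfg) {
  stopifnot(is(cfg, "sim_config"))
  defects <- c("none", "low_p", "low_expr", "terminal", "short",
               "overlap", "ambiguous")
  with_seed(cfg$seed + 1L, {
    n <- max(cfg$n_genes, 7L)               # at least one of each defect
    defect <- c(defects,
                sample(c("none", defects), n - length(defects),
                       replace = TRUE, prob = c(4, rep(1, 7))))[seq_len(n)]
    defect <- sample(defect)                # shuffle over genes
    seqs <- character(n); regions <- list(); diff <- list(); expr <- list()
    truth_rows <- list()
    for (g in seq_len(n)) {
      gid <- sprintf("cg_%03d", g)
      chrom <- sprintf("ctg_%03d", g)
      d <- defect[g]
      strand <- sample(c("+", "-"), 1L)
      ex_len <- if (d == "short") 99L else rint(1L, 120L, 260L)
      il <- rint(4L, 150L, 400L)
      flank_ex <- rint(2L, 120L, 200L)
      if (d == "terminal") {
        # candidate exon is the transcript's first exon: no upstream intron
        lens <- c(ex_len, il[1], flank_ex[1], il[2], flank_ex[2])
        cls <- c("ORF", "intron", "ORF", "intron", "ORF")
        cand_block <- 1L
      } else {
        lens <- c(flank_ex[1], il[1], ex_len, il[2], flank_ex[2])
        cls <- c("ORF", "intron", "ORF", "intron", "ORF")
        cand_block <- 3L
      }
      starts <- cumsum(c(100L, lens[-length(lens)]))
      gseq <- random_dna(100L + sum(lens) + 100L, cfg$base_composition)
      if (d == "ambiguous") {
        p <- starts[cand_block] + rint(1L, 5L, lens[cand_block] - 5L)
        substr(gseq, p, p) <- "N"
      }
      seqs[g] <- gseq
      regions[[g]] <- data.frame(
        chrom = chrom, start = starts, end = starts + lens,
        strand = strand, gene_id = gid, transcript_id = gid,
        region_class = cls)
      cand <- list(data.frame(
        exon_id = paste0(gid, "_e1"), gene_id = gid, chrom = chrom,
        start = starts[cand_block], end = starts[cand_block] +
          lens[cand_block], strand = strand))
      if (d == "overlap") {
        # a second isoform's exon overlapping the candidate; both must go
        regions[[g]]$transcript_id <- gid
        iso <- regions[[g]]
        iso$transcript_id <- paste0(gid, "_iso2")
        shift <- 30L
        iso$start[cand_block] <- iso$start[cand_block] + shift
        iso$end[cand_block] <- iso$end[cand_block] + shift
        iso$end[cand_block - 1L] <- iso$start[cand_block]
        iso$start[cand_block + 1L] <- iso$end[cand_block]
        regions[[g]] <- rbind(regions[[g]], iso)
        cand[[2]] <- data.frame(
          exon_id = paste0(gid, "_e2"), gene_id = gid, chrom = chrom,
          start = iso$start[cand_block], end = iso$end[cand_block],
          strand = strand)
      }
      for (cd in cand) {
        p_val <- if (d == "low_p") runif(1, 0.05, 0.9) else runif(1, 0.951, 1)
        diff[[length(diff) + 1L]] <- cbind(
          cd, midas_p = p_val, fold_change = runif(1, -1.5, 1.5))
      }
      base_counts <- rint(6L, 1100L, 3000L)
      if (d == "low_expr") {
        cond <- sample(1:2, 1L)
        k <- if (cond == 1L) 1:3 else 4:6
        base_counts[k] <- c(999L, 1000L, 1000L)  # total 2999 < 3000
      }
      expr[[g]] <- data.frame(gene_id = gid,
                              c1_r1 = base_counts[1], c1_r2 = base_counts[2],
                              c1_r3 = base_counts[3], c2_r1 = base_counts[4],
                              c2_r2 = base_counts[5], c2_r3 = base_counts[6])
      truth_rows[[g]] <- data.frame(gene_id = gid, defect = d,
                                    exon_id = paste0(gid, "_e1"))
    }
    genome <- Biostrings::DNAStringSet(setNames(seqs, sprintf(
      "ctg_%03d", seq_len(n))))
    annotation <- structure(
      list(regions = do.call(rbind, regions),
           transcripts = NULL, motif_instances = NULL),
      class = "gene_models")
    truth_df <- do.call(rbind, truth_rows)
    truth <- structure(
      list(defects = truth_df,
           qualifying_exons = sort(truth_df$exon_id[truth_df$defect ==
                                                      "none"]),
           config = cfg),
      class = "sim_truth")
    structure(list(genome = genome, annotation = annotation,
                   diff_table = do.call(rbind, diff),
                   expression = do.call(rbind, expr), truth = truth),
              class = "sim_cohort")
  })
}
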