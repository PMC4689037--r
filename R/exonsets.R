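#' Call up- and down-regulated exons from a differential-exon table
#'
#' Applies the significance and magnitude thresholds (MiDAS p < 0.05 and
#' fold change beyond +/-2) to label exons `up` or `down`; all other
#' exons are left unlabeled.  Fold changes may be supplied as signed
#' ratios (negative = down, magnitude = ratio) or as log2 ratios, which
#' are converted to signed ratios first.
#'
#' @param diff_table data.frame with at least `midas_p` and
#'   `fold_change` columns.
#' @param fold_convention `"signed"` (default) or `"log2"`.
#' @param p_threshold,fold_threshold Thresholds (defaults 0.05 and 2).
#' @return `diff_table` with a `class_label` column (`"up"`, `"down"`,
#'   or `NA`).
#' @export
#' @examples
#' d <- data.frame(midas_p = c(0.04, 0.04), fold_change = c(2.5, 1.5))
#' call_regulated(d)$class_label   # "up", NA
call_regulated <- function(diff_table, fold_convention = c("signed", "log2"),
                           p_threshold = clip_defaults()$midas_sig,
                           fold_threshold = clip_defaults()$fold_threshold) {
  fold_convention <- match.arg(fold_convention)
  if (!all(c("midas_p", "fold_change") %in% names(diff_table)))
    stop("diff_table must have midas_p and fold_change columns")
  fc <- diff_table$fold_change
  if (fold_convention == "log2")
    fc <- ifelse(fc >= 0, 2^fc, -(2^(-fc)))
  sig <- diff_table$midas_p < p_threshold
  lab <- rep(NA_character_, nrow(diff_table))
  lab[sig & fc > fold_threshold] <- "up"
  lab[sig & fc < -fold_threshold] <- "down"
  diff_table$class_label <- lab
  diff_table
}

#' Select unchanged control cassette exons
#'
#' Applies the control-selection funnel in order, logging the survivor
#' count after each filter:
#' \enumerate{
#'   \item MiDAS p > 0.95 (confidently unchanged);
#'   \item gene expression of at least 3,000 total reads (3 replicates)
#'     in each condition separately;
#'   \item exon internal to a transcript (flanking introns on both
#'     sides);
#'   \item exon length at least 100 nt (so two 50-nt windows fit);
#'   \item exons mutually non-overlapping (every member of an
#'     overlapping cluster is dropped);
#'   \item exon sequence free of ambiguous nucleotides.
#' }
#'
#' @param diff_table data.frame: `exon_id`, `gene_id`, `chrom`,
#'   `start`, `end`, `strand`, `midas_p`.
#' @param expression data.frame: `gene_id` plus three replicate count
#'   columns per condition (columns 2-4 = condition 1, 5-7 =
#'   condition 2).
#' @param models `gene_models` or region data.frame with
#'   `transcript_id`.
#' @param genome [Biostrings::DNAStringSet] for sequence extraction.
#' @param p_threshold MiDAS control threshold (default 0.95).
#' @param min_reads Per-condition read total threshold (default 3000).
#' @param min_length Minimum exon length (default 100).
#' @param intron_flank Length of flanking intron sequence attached to
#'   each record (default 50 nt; truncated at the intron).
#' @return Control exon records (data.frame with `sequence`,
#'   `upstream_intron_seq`, `downstream_intron_seq`,
#'   `class_label = "control"`), sorted by coordinate, with attribute
#'   `funnel` (named survivor counts).  An empty result is a warning,
#'   not an error.
#' @export
select_controls <- function(diff_table, expression, models, genome,
                            p_threshold = clip_defaults()$midas_ctrl,
                            min_reads = clip_defaults()$min_reads,
                            min_length = clip_defaults()$min_exon_length,
                            intron_flank = 50L) {
  need <- c("exon_id", "gene_id", "chrom", "start", "end", "strand",
            "midas_p")
  if (!all(need %in% names(diff_table)))
    stop("diff_table must have columns: ", paste(need, collapse = ", "))
  regions <- if (is(models, "gene_models")) models$regions else models
  funnel <- c(input = nrow(diff_table))

  d <- diff_table[diff_table$midas_p > p_threshold, , drop = FALSE]
  funnel["midas_p"] <- nrow(d)

  cond1 <- rowSums(expression[, 2:4, drop = FALSE])
  cond2 <- rowSums(expression[, 5:7, drop = FALSE])
  good_genes <- expression$gene_id[cond1 >= min_reads & cond2 >= min_reads]
  d <- d[d$gene_id %in% good_genes, , drop = FALSE]
  funnel["expression"] <- nrow(d)

  internal <- internal_exons(regions)
  key <- paste(d$chrom, d$start, d$end, sep = ":")
  d <- d[key %in% paste(internal$chrom, internal$start, internal$end,
                        sep = ":"), , drop = FALSE]
  funnel["internal"] <- nrow(d)

  d <- d[d$end - d$start >= min_length, , drop = FALSE]
  funnel["length"] <- nrow(d)

  if (nrow(d)) {
    gr <- GenomicRanges::GRanges(d$chrom,
                                 IRanges::IRanges(d$start + 1L, d$end))
    ov <- GenomicRanges::countOverlaps(gr, gr, ignore.strand = TRUE)
    d <- d[ov == 1L, , drop = FALSE]   # drop every overlapping exon
  }
  funnel["non_overlapping"] <- nrow(d)

  seqs <- flank_up <- flank_dn <- character(nrow(d))
  if (nrow(d)) {
    for (i in seq_len(nrow(d))) {
      ex <- extract_exon_seqs(d[i, ], regions, genome, intron_flank)
      seqs[i] <- ex$sequence
      flank_up[i] <- ex$upstream; flank_dn[i] <- ex$downstream
    }
    ok <- !grepl("[^ACGT]", seqs)
    d <- d[ok, , drop = FALSE]
    seqs <- seqs[ok]; flank_up <- flank_up[ok]; flank_dn <- flank_dn[ok]
  }
  funnel["unambiguous"] <- nrow(d)

  if (!nrow(d)) warning("no exons survive the control-selection funnel")
  d <- cbind(d, sequence = seqs, upstream_intron_seq = flank_up,
             downstream_intron_seq = flank_dn,
             stringsAsFactors = FALSE)
  d$class_label <- rep("control", nrow(d))
  d <- d[order(d$chrom, d$start, d$end), , drop = FALSE]
  rownames(d) <- NULL
  attr(d, "funnel") <- funnel
  d
}

# Exonic regions with intron neighbors on both sides within their
# transcript (in genomic block order; orientation does not matter for
# the both-sides condition).
internal_exons <- function(regions) {
  out <- list()
  for (tx in split(regions, regions$transcript_id)) {
    tx <- tx[order(tx$start), , drop = FALSE]
    n <- nrow(tx)
    if (n < 3L) next
    for (i in 2:(n - 1L)) {
      if (tx$region_class[i] %in% EXONIC_CLASSES &&
          tx$region_class[i - 1L] == "intron" &&
          tx$region_class[i + 1L] == "intron")
        out[[length(out) + 1L]] <- tx[i, , drop = FALSE]
    }
  }
  if (!length(out))
    return(regions[0, , drop = FALSE])
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# Transcript-orientation exon sequence plus flanking intron sequence.
extract_exon_seqs <- function(ex, regions, genome, flank) {
  g <- genome[[ex$chrom]]
  seq <- as.character(Biostrings::subseq(g, ex$start + 1L, ex$end))
  left <- as.character(Biostrings::subseq(
    g, max(1L, ex$start - flank + 1L), ex$start))
  right_end <- min(length(g), ex$end + flank)
  right <- if (right_end > ex$end)
    as.character(Biostrings::subseq(g, ex$end + 1L, right_end)) else ""
  if (ex$strand == "+") {
    list(sequence = seq, upstream = left, downstream = right)
  } else {
    list(sequence = revcomp(seq), upstream = revcomp(right),
         downstream = revcomp(left))
  }
}

#' Remove exons containing simple period-3 tandem repeats
#'
#' A lightweight stand-in for repeat masking at toy scale: exons whose
#' sequence contains a perfect tandem run of any trinucleotide unit
#' repeated at least `min_run` times (default 6 copies = 18 nt, e.g.
#' `(AAG)6`) are removed.
#'
#' @param exons Exon record data.frame with a `sequence` column.
#' @param min_run Minimum number of tandem unit copies; `Inf` disables
#'   filtering.
#' @return List: `kept` (filtered exons) and `removed` (data.frame
#'   `exon_id`, `unit`, `start`, `end`; 1-based span of the matched
#'   run).
#' @export
#' @examples
#' e <- data.frame(exon_id = "x", sequence = strrep("AAG", 8))
#' repeat_filter(e)$removed
repeat_filter <- function(exons, min_run = clip_defaults()$min_repeat_run) {
  removed <- data.frame(exon_id = character(0), unit = character(0),
                        start = integer(0), end = integer(0))
  if (!is.finite(min_run))
    return(list(kept = exons, removed = removed))
  stopifnot(min_run >= 2L)
  pat <- sprintf("([ACGT]{3})\\1{%d,}", min_run - 1L)
  m <- regexpr(pat, exons$sequence, perl = TRUE)
  hit <- m != -1L
  if (any(hit)) {
    len <- attr(m, "match.length")[hit]
    removed <- data.frame(
      exon_id = exons$exon_id[hit],
      unit = substr(exons$sequence[hit], m[hit], m[hit] + 2L),
      start = as.integer(m[hit]),
      end = as.integer(m[hit] + len - 1L))
  }
  list(kept = exons[!hit, , drop = FALSE], removed = removed)
}
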