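#' Demultiplex barcoded iCLIP reads
#'
#' Splits reads by the 4-nt experiment index at read positions 3-6
#' (0-based; the read layout is NN + XXXX + NNN + insert).  The index is
#' compared to the supplied map with zero mismatches.  The two
#' degenerate blocks flanking the index are concatenated into the 5-nt
#' random barcode; the remainder of the read is the insert.
#'
#' @param reads data.frame with `read_id`, `seq` (see
#'   [read_fastq_reads()]).
#' @param index_map Named character vector mapping 4-nt experiment
#'   indices to sample names, e.g. `c(AACC = "rep1", ACAC = "rep2")`.
#' @return List with `samples` (named list of per-sample data.frames:
#'   `read_id`, `experiment_index`, `random_barcode`, `insert`) and
#'   `rejected` (data.frame `read_id`, `reason`).
#' @export
#' @examples
#' r <- data.frame(read_id = "r1", seq = "GTAACCTAGACGTACGTACGTACG")
#' demultiplex(r, c(AACC = "s1"))$samples$s1
demultiplex <- function(reads, index_map) {
  idx <- toupper(names(index_map))
  if (any(nchar(idx) != 4L) || anyDuplicated(idx))
    stop("index_map names must be distinct 4-nt strings")
  names(index_map) <- idx
  short <- nchar(reads$seq) < 9L
  rejected <- data.frame(read_id = reads$read_id[short],
                         reason = rep("too_short", sum(short)),
                         stringsAsFactors = FALSE)
  ok <- reads[!short, , drop = FALSE]
  exp_idx <- substr(ok$seq, 3L, 6L)
  sample <- unname(index_map[exp_idx])
  unmatched <- is.na(sample)
  if (any(unmatched))
    rejected <- rbind(rejected, data.frame(
      read_id = ok$read_id[unmatched],
      reason = rep("unknown_index", sum(unmatched)),
      stringsAsFactors = FALSE))
  kept <- ok[!unmatched, , drop = FALSE]
  out <- data.frame(read_id = kept$read_id,
                    experiment_index = exp_idx[!unmatched],
                    random_barcode = paste0(substr(kept$seq, 1L, 2L),
                                            substr(kept$seq, 7L, 9L)),
                    insert = substr(kept$seq, 10L, nchar(kept$seq)),
                    stringsAsFactors = FALSE)
  samples <- split(out, factor(sample[!unmatched],
                               levels = unique(unname(index_map))))
  samples <- lapply(samples, function(d) { rownames(d) <- NULL; d })
  list(samples = samples, rejected = rejected)
}

#' Map inserts to a toy genome allowing one mismatch
#'
#' A naive exhaustive scanner intended for toy genomes (up to a few Mb):
#' every insert is compared at every position of both strands, hits are
#' stratified by mismatch count (0 beats 1), and inserts with more than
#' one hit in their best stratum are discarded as multimappers.  For
#' real data, supply pre-aligned reads via [read_alignments_bed()]
#' instead.
#'
#' @param reads data.frame with `insert` and `random_barcode` columns
#'   (one sample from [demultiplex()]).
#' @param genome [Biostrings::DNAStringSet].
#' @param min_insert Minimum insert length to attempt mapping
#'   (default 15 nt).
#' @return data.frame of aligned inserts (`chrom`, `strand`, `start`,
#'   `end` 0-based half-open, `mismatches`, `random_barcode`,
#'   `read_id`), with attribute `map_stats` (named counts: input,
#'   too_short, unmapped, multimapped, mapped).
#' @export
map_inserts <- function(reads, genome, min_insert = clip_defaults()$min_insert) {
  stopifnot(all(c("insert", "random_barcode") %in% names(reads)))
  n_in <- nrow(reads)
  long <- nchar(reads$insert) >= min_insert
  r <- reads[long, , drop = FALSE]
  hit <- naive_map_cpp(as.character(genome), r$insert)
  mapped <- !is.na(hit$best_mm) & hit$n_best == 1L
  multi <- !is.na(hit$best_mm) & hit$n_best > 1L
  a <- r[mapped, , drop = FALSE]
  h <- hit[mapped, , drop = FALSE]
  out <- data.frame(chrom = names(genome)[h$contig], strand = h$strand,
                    start = h$start, end = h$start + nchar(a$insert),
                    mismatches = h$best_mm,
                    random_barcode = a$random_barcode,
                    read_id = if ("read_id" %in% names(a)) a$read_id
                              else rep(NA_character_, nrow(a)),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "map_stats") <- c(input = n_in, too_short = sum(!long),
                              unmapped = sum(!mapped & !multi),
                              multimapped = sum(multi),
                              mapped = sum(mapped))
  out
}

#' Collapse aligned inserts into deduplicated crosslink sites
#'
#' Implements the iCLIP truncation model: reads truncating at the same
#' genomic nucleotide and sharing the same random barcode are PCR
#' copies of one cDNA.  Alignments are grouped by (chrom, strand,
#' truncation nucleotide) and the unique-cDNA count of each site is the
#' number of distinct barcodes in its group.  Under the default
#' `"upstream"` convention the crosslink site is the nucleotide
#' immediately 5' of the read start on the read's strand (position
#' `start - 1` on "+", position `end` on "-"); `"start"` uses the first
#' read nucleotide itself.
#'
#' @param alignments data.frame from [map_inserts()],
#'   [read_alignments_bed()] or [truth_alignments()].
#' @param convention `"upstream"` (default) or `"start"`.
#' @return Crosslink-site data.frame (`chrom`, `strand`, `position`
#'   0-based, `cdna_count`), sorted by chrom, position, strand.
#' @export
deduplicate <- function(alignments, convention = c("upstream", "start")) {
  convention <- match.arg(convention)
  stopifnot(all(c("chrom", "strand", "start", "end",
                  "random_barcode") %in% names(alignments)))
  pos <- if (convention == "upstream") {
    ifelse(alignments$strand == "+", alignments$start - 1L, alignments$end)
  } else {
    ifelse(alignments$strand == "+", alignments$start, alignments$end - 1L)
  }
  dt <- data.table::data.table(chrom = alignments$chrom,
                               strand = alignments$strand,
                               position = as.integer(pos),
                               barcode = alignments$random_barcode)
  sites <- dt[, list(cdna_count = data.table::uniqueN(barcode)),
              by = c("chrom", "strand", "position")]
  data.table::setorderv(sites, c("chrom", "position", "strand"))
  as.data.frame(sites[, c("chrom", "strand", "position", "cdna_count")])
}
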