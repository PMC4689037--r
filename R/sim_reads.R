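#' Simulate barcoded iCLIP reads truncating at planted crosslink sites
#'
#' Draws `n_crosslink_events` unique cDNA events: with probability
#' `motif_site_fraction` an event sits at a planted motif instance (the
#' crosslink nucleotide at `crosslink_offset` within the motif, in
#' transcript orientation), otherwise uniformly over ORF exon positions.
#' Each event receives a random 5-nt barcode and yields
#' `1 + Poisson(pcr_duplication_mean)` identical reads.  Read sequences
#' begin at the nucleotide immediately 3' of the crosslink site on the
#' transcript strand; the first 9 nt are NN + 4-nt experiment index +
#' NNN (the NN and NNN concatenated form the 5-nt random barcode).
#'
#' Ground truth records every event and the number of *distinguishable*
#' unique cDNAs, i.e. distinct (chrom, strand, position, barcode) tuples:
#' two events that collide in both position and barcode are one cDNA to
#' any downstream observer, so that is the count deduplication can and
#' must recover exactly.
#'
#' @param genome [Biostrings::DNAStringSet] from [make_genome()].
#' @param annotation `gene_models` from [make_genome()].
#' @param cfg The [sim_config()] used to build the genome.
#' @return List with `reads` (data.frame `read_id`, `seq`) and `truth`
#'   (class `sim_truth`: `planted_crosslinks` data.frame with chrom,
#'   strand, position (0-based crosslink nucleotide), barcode,
#'   from_motif, n_reads, insert_len, truncated; and
#'   `unique_cdna_count`).
#' @export
#' @examples
#' cfg <- sim_config(seed = 3, n_genes = 4, n_crosslink_events = 50)
#' sim <- make_genome(cfg)
#' rr <- plant_crosslink_reads(sim$genome, sim$annotation, cfg)
#' rr$truth$unique_cdna_count
plant_crosslink_reads <- function(genome, annotation, cfg) {
  stopifnot(is(cfg, "sim_config"))
  regions <- annotation$regions
  inst <- annotation$motif_instances
  orf <- regions[regions$region_class == "ORF", , drop = FALSE]
  if (nrow(orf) == 0L) stop("annotation has no ORF regions")
  frac <- cfg$motif_site_fraction
  if (nrow(inst) == 0L && frac > 0) {
    warning("no motif instances available; motif_site_fraction forced to 0")
    frac <- 0
  }
  mlen <- nchar(cfg$crosslink_motif)
  contig_len <- setNames(Biostrings::width(genome), names(genome))
  with_seed(cfg$seed, {
    n <- cfg$n_crosslink_events
    at_motif <- runif(n) < frac
    chrom <- character(n); strand <- character(n); posn <- integer(n)
    n_mot <- sum(at_motif)
    if (n_mot) {
      pick <- sample.int(nrow(inst), n_mot, replace = TRUE)
      chrom[at_motif] <- inst$chrom[pick]
      strand[at_motif] <- inst$strand[pick]
      # transcript-orientation offset within the planted motif
      posn[at_motif] <- ifelse(inst$strand[pick] == "+",
                               inst$start[pick] + cfg$crosslink_offset,
                               inst$start[pick] + mlen - 1L -
                                 cfg$crosslink_offset)
    }
    n_bg <- n - n_mot
    if (n_bg) {
      w <- orf$end - orf$start
      reg <- sample.int(nrow(orf), n_bg, replace = TRUE, prob = w)
      chrom[!at_motif] <- orf$chrom[reg]
      strand[!at_motif] <- orf$strand[reg]
      posn[!at_motif] <- rint(n_bg, orf$start[reg], orf$end[reg] - 1L)
    }
    barcode <- paste0(
      random_dna_vec(n, 5L))
    dup <- rpois(n, cfg$pcr_duplication_mean)
    insert_max <- cfg$read_len - 9L
    # insert covers [pos+1, pos+1+L) on "+", [pos-L, pos) on "-";
    # clip at contig bounds and flag
    clen <- contig_len[chrom]
    avail <- ifelse(strand == "+", clen - (posn + 1L), posn)
    insert_len <- pmin(insert_max, avail)
    truncated <- insert_len < insert_max
    events <- data.frame(chrom = chrom, strand = strand, position = posn,
                         barcode = barcode, from_motif = at_motif,
                         n_reads = 1L + dup, insert_len = insert_len,
                         truncated = truncated, stringsAsFactors = FALSE)
    unique_cdna <- nrow(unique(events[, c("chrom", "strand", "position",
                                          "barcode")]))
    inserts <- extract_inserts(genome, events)
    reads_seq <- paste0(substr(events$barcode, 1L, 2L), cfg$barcode_index,
                        substr(events$barcode, 3L, 5L), inserts)
    idx <- rep.int(seq_len(n), events$n_reads)
    seqs <- reads_seq[idx]
    if (cfg$seq_error_rate > 0) seqs <- add_seq_errors(seqs,
                                                      cfg$seq_error_rate)
    reads <- data.frame(read_id = sprintf("read_%06d", seq_along(idx)),
                        seq = seqs, stringsAsFactors = FALSE)
    truth <- structure(list(planted_crosslinks = events,
                            unique_cdna_count = unique_cdna,
                            config = cfg),
                       class = "sim_truth")
    list(reads = reads, truth = truth)
  })
}

# n random DNA strings of length k (vectorized).
random_dna_vec <- function(n, k) {
  m <- matrix(sample(c("A", "C", "G", "T"), n * k, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

# Transcript-strand insert sequence immediately 3' of each crosslink.
extract_inserts <- function(genome, events) {
  out <- character(nrow(events))
  for (ch in unique(events$chrom)) {
    i <- which(events$chrom == ch)
    g <- genome[[ch]]
    plus <- i[events$strand[i] == "+"]
    if (length(plus)) {
      v <- Biostrings::Views(g, start = events$position[plus] + 2L,
                             width = events$insert_len[plus])
      out[plus] <- as.character(as(v, "DNAStringSet"))
    }
    minus <- i[events$strand[i] == "-"]
    if (length(minus)) {
      v <- Biostrings::Views(g,
                             start = events$position[minus] -
                               events$insert_len[minus] + 1L,
                             width = events$insert_len[minus])
      out[minus] <- as.character(
        Biostrings::reverseComplement(as(v, "DNAStringSet")))
    }
  }
  out
}

add_seq_errors <- function(seqs, rate) {
  vapply(seqs, function(s) {
    n <- nchar(s)
    hit <- which(runif(n) < rate)
    if (!length(hit)) return(s)
    ch <- strsplit(s, "")[[1]]
    ch[hit] <- vapply(ch[hit], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Expand simulation truth into aligned-insert records
#'
#' Converts the event table of a [plant_crosslink_reads()] truth object
#' into the alignment format consumed by [deduplicate()], replicating
#' each event by its PCR copy number.  This is the mapper-free route for
#' testing the deduplication rule in isolation.
#'
#' @param truth A `sim_truth` object.
#' @return Alignment data.frame (`chrom`, `strand`, `start`, `end`,
#'   `mismatches`, `random_barcode`).
#' @export
truth_alignments <- function(truth) {
  ev <- truth$planted_crosslinks
  idx <- rep.int(seq_len(nrow(ev)), ev$n_reads)
  e <- ev[idx, , drop = FALSE]
  start <- ifelse(e$strand == "+", e$position + 1L,
                  e$position - e$insert_len)
  data.frame(chrom = e$chrom, strand = e$strand, start = start,
             end = start + e$insert_len, mismatches = 0L,
             random_barcode = e$barcode, row.names = NULL,
             stringsAsFactors = FALSE)
}
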