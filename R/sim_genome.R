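#' Generate a toy genome with gene models and planted crosslink motifs
#'
#' Builds a single-contig random genome in which `n_genes` non-overlapping
#' genes are laid out with intergenic gaps.  Coding genes carry a 5'UTR,
#' at least three ORF exons separated by introns, and a 3'UTR; a fraction
#' of genes are single-block ncRNAs.  Region classes tile each gene
#' exactly (no gaps or overlaps within a transcript).  Instances of the
#' crosslink motif are planted in transcript orientation inside every ORF
#' exon and recorded so that crosslink events can later be concentrated
#' on them.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `sim_genome` with elements:
#'   \describe{
#'     \item{genome}{[Biostrings::DNAStringSet] with one contig.}
#'     \item{annotation}{list of class `gene_models`: `regions` (data.frame
#'       chrom, start, end, strand, gene_id, transcript_id, region_class;
#'       0-based half-open), `transcripts` (one row per transcript), and
#'       `motif_instances` (chrom, strand, start, gene_id; `start` is the
#'       leftmost genomic coordinate of the planted motif).}
#'     \item{config}{the input configuration.}
#'   }
#' @export
#' @examples
#' sim <- make_genome(sim_config(seed = 7, n_genes = 3))
#' names(sim$genome)
#' head(sim$annotation$regions)
make_genome <- function(cfg) {
  stopifnot(is(cfg, "sim_config"))
  with_seed(cfg$seed, {
    chrom <- "chr1"
    pieces <- character(0)
    regions <- list()
    transcripts <- list()
    pos <- 0L
    for (g in seq_len(cfg$n_genes)) {
      gap <- rint(1L, cfg$intergenic_len_range[1], cfg$intergenic_len_range[2])
      pieces <- c(pieces, random_dna(gap, cfg$base_composition))
      pos <- pos + gap
      gene_id <- sprintf("gene_%03d", g)
      strand <- sample(c("+", "-"), 1L)
      # gene 1 is always coding so >=1 internal cassette exon exists
      is_nc <- g > 1L && runif(1) < cfg$ncrna_fraction
      if (is_nc) {
        len <- rint(1L, cfg$exon_len_range[1], 2L * cfg$exon_len_range[2])
        regions[[length(regions) + 1L]] <- data.frame(
          chrom = chrom, start = pos, end = pos + len, strand = strand,
          gene_id = gene_id, transcript_id = gene_id, region_class = "ncRNA")
        pieces <- c(pieces, random_dna(len, cfg$base_composition))
        transcripts[[length(transcripts) + 1L]] <- data.frame(
          chrom = chrom, start = pos, end = pos + len, strand = strand,
          gene_id = gene_id, transcript_id = gene_id, type = "ncRNA",
          n_exons = 1L)
        pos <- pos + len
        next
      }
      n_ex <- rint(1L, cfg$n_exons_range[1], cfg$n_exons_range[2])
      ex_len <- rint(n_ex, cfg$exon_len_range[1], cfg$exon_len_range[2])
      in_len <- rint(n_ex - 1L, cfg$intron_len_range[1],
                     cfg$intron_len_range[2])
      utr <- rint(2L, cfg$utr_len_range[1], cfg$utr_len_range[2])
      # transcript-order blocks: UTR5, exon1, intron1, ..., exonN, UTR3
      cls <- c("UTR5", as.vector(rbind(rep("ORF", n_ex),
                                       c(rep("intron", n_ex - 1L), NA))))
      cls <- c(cls[!is.na(cls)], "UTR3")
      lens <- c(utr[1], as.vector(rbind(ex_len, c(in_len, NA))))
      lens <- c(lens[!is.na(lens)], utr[2])
      if (strand == "-") { cls <- rev(cls); lens <- rev(lens) }
      starts <- pos + cumsum(c(0L, lens[-length(lens)]))
      regions[[length(regions) + 1L]] <- data.frame(
        chrom = chrom, start = starts, end = starts + lens, strand = strand,
        gene_id = gene_id, transcript_id = gene_id, region_class = cls)
      pieces <- c(pieces, random_dna(sum(lens), cfg$base_composition))
      transcripts[[length(transcripts) + 1L]] <- data.frame(
        chrom = chrom, start = pos, end = pos + sum(lens), strand = strand,
        gene_id = gene_id, transcript_id = gene_id, type = "coding",
        n_exons = n_ex)
      pos <- pos + sum(lens)
    }
    tail_gap <- rint(1L, cfg$intergenic_len_range[1],
                     cfg$intergenic_len_range[2])
    pieces <- c(pieces, random_dna(tail_gap, cfg$base_composition))
    pos <- pos + tail_gap
    if (!is.null(cfg$genome_len)) {
      if (pos > cfg$genome_len)
        stop("genome too small: requested genes need ", pos,
             " nt but genome_len is ", cfg$genome_len)
      pieces <- c(pieces, random_dna(cfg$genome_len - pos,
                                     cfg$base_composition))
      pos <- cfg$genome_len
    }
    seq <- paste(pieces, collapse = "")
    regions <- do.call(rbind, regions)
    transcripts <- do.call(rbind, transcripts)
    rownames(regions) <- rownames(transcripts) <- NULL

    planted <- plant_motifs(seq, regions, cfg)
    genome <- Biostrings::DNAStringSet(setNames(planted$seq, chrom))
    annotation <- structure(
      list(regions = regions, transcripts = transcripts,
           motif_instances = planted$instances),
      class = "gene_models")
    structure(list(genome = genome, annotation = annotation, config = cfg),
              class = "sim_genome")
  })
}

# Overwrite motif instances (transcript orientation) into every ORF exon.
plant_motifs <- function(seq, regions, cfg) {
  motif <- cfg$crosslink_motif
  mlen <- nchar(motif)
  orf <- regions[regions$region_class == "ORF", , drop = FALSE]
  inst <- list()
  for (i in seq_len(nrow(orf))) {
    lo <- orf$start[i] + 5L                 # keep clear of region edges
    hi <- orf$end[i] - 5L - mlen
    if (hi <= lo) next
    k <- min(cfg$motifs_per_exon, max(0L, (hi - lo) %/% (2L * mlen)))
    if (k == 0L) next
    starts <- sort(sample(seq.int(lo, hi), k))
    keep <- c(TRUE, diff(starts) >= mlen)   # no overlapping plants
    starts <- starts[keep]
    ins <- if (orf$strand[i] == "+") motif else revcomp(motif)
    for (s in starts)                        # s is 0-based genomic
      substr(seq, s + 1L, s + mlen) <- ins
    inst[[length(inst) + 1L]] <- data.frame(
      chrom = orf$chrom[i], strand = orf$strand[i], start = starts,
      gene_id = orf$gene_id[i])
  }
  instances <- if (length(inst)) do.call(rbind, inst) else
    data.frame(chrom = character(0), strand = character(0),
               start = integer(0), gene_id = character(0))
  rownames(instances) <- NULL
  list(seq = seq, instances = instances)
}

#' @export
print.sim_genome <- function(x, ...) {
  cat("sim_genome:", sum(Biostrings::width(x$genome)), "nt,",
      nrow(x$annotation$transcripts), "genes,",
      nrow(x$annotation$motif_instances), "planted",
      x$config$crosslink_motif, "instances\n")
  invisible(x)
}
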