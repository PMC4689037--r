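# Plain-text readers/writers for the pipeline's on-disk formats.
# All genomic coordinates on disk are 0-based half-open; strand is "+"/"-".

#' Read a genome FASTA file
#'
#' @param path Path to an (uncompressed or gzipped) FASTA file.
#' @return A [Biostrings::DNAStringSet] named by contig.
#' @export
read_genome <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' Write a genome FASTA file
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Read iCLIP reads from FASTQ
#'
#' Base qualities are ignored throughout the pipeline, so only read ids
#' and sequences are retained.
#'
#' @param path FASTQ path (gzipped allowed).
#' @return data.frame with columns `read_id`, `seq`.
#' @export
read_fastq_reads <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(read_id = names(x), seq = as.character(x),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write reads to FASTQ with constant quality
#'
#' @param reads data.frame with columns `read_id`, `seq`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq_reads <- function(reads, path) {
  stopifnot(all(c("read_id", "seq") %in% names(reads)))
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(reads)) {
    qual <- vapply(nchar(reads$seq), function(n) strrep("I", n), character(1))
    writeLines(paste0("@", reads$read_id, "\n", reads$seq, "\n+\n", qual), con)
  }
  invisible(path)
}

#' Write crosslink sites as 6-column BED
#'
#' One row per site: chrom, start, end = start + 1, name, score =
#' unique-cDNA count, strand.
#'
#' @param sites data.frame with columns `chrom`, `strand`, `position`,
#'   `cdna_count`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(sites, path) {
  bed <- data.frame(chrom = sites$chrom, start = sites$position,
                    end = sites$position + 1L,
                    name = sprintf("site_%d", seq_len(nrow(sites))),
                    score = sites$cdna_count, strand = sites$strand)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read crosslink sites from 6-column BED
#'
#' @param path BED path written by [write_sites_bed()] (or equivalent).
#' @return data.frame with columns `chrom`, `strand`, `position`,
#'   `cdna_count`.
#' @export
read_sites_bed <- function(path) {
  bed <- read.table(path, sep = "\t", header = FALSE,
                    col.names = c("chrom", "start", "end", "name",
                                  "score", "strand"),
                    colClasses = c("character", "integer", "integer",
                                   "character", "integer", "character"),
                    comment.char = "")
  data.frame(chrom = bed$chrom, strand = bed$strand, position = bed$start,
             cdna_count = bed$score, stringsAsFactors = FALSE)
}

#' Read aligned inserts from 6-column BED with barcoded names
#'
#' The name field must be `readid#BARCODE`; this is the pre-aligned entry
#' point that bypasses the naive mapper for real data.
#'
#' @param path BED path.
#' @return data.frame with columns `chrom`, `strand`, `start`, `end`,
#'   `mismatches` (NA), `random_barcode`, `read_id`.
#' @export
read_alignments_bed <- function(path) {
  bed <- read.table(path, sep = "\t", header = FALSE,
                    col.names = c("chrom", "start", "end", "name",
                                  "score", "strand"),
                    colClasses = c("character", "integer", "integer",
                                   "character", "integer", "character"),
                    comment.char = "")
  parts <- strsplit(bed$name, "#", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad))
    stop("alignment BED name field must be 'readid#BARCODE'; offending row ",
         which(bad)[1])
  data.frame(chrom = bed$chrom, strand = bed$strand, start = bed$start,
             end = bed$end, mismatches = NA_integer_,
             random_barcode = vapply(parts, `[`, character(1), 2L),
             read_id = vapply(parts, `[`, character(1), 1L),
             stringsAsFactors = FALSE)
}

#' Write aligned inserts as 6-column BED with barcoded names
#'
#' @param alignments data.frame as produced by [map_inserts()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignments_bed <- function(alignments, path) {
  ids <- if ("read_id" %in% names(alignments)) alignments$read_id
         else sprintf("aln_%d", seq_len(nrow(alignments)))
  bed <- data.frame(chrom = alignments$chrom, start = alignments$start,
                    end = alignments$end,
                    name = paste0(ids, "#", alignments$random_barcode),
                    score = 0L, strand = alignments$strand)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a region annotation table
#'
#' @param regions data.frame with columns `chrom`, `start`, `end`,
#'   `strand`, `gene_id`, `region_class`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions_tsv <- function(regions, path) {
  write.table(regions[, c("chrom", "start", "end", "strand",
                          "gene_id", "region_class")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a region annotation table
#'
#' @param path TSV written by [write_regions_tsv()].
#' @return Region data.frame.
#' @export
read_regions_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write an exon set as FASTA plus a sidecar TSV
#'
#' @param exons An exon record data.frame (see [make_exon_sets()]); must
#'   have `exon_id` and `sequence` columns.
#' @param fasta_path,tsv_path Output paths.
#' @return `tsv_path`, invisibly.
#' @export
write_exon_set <- function(exons, fasta_path, tsv_path) {
  seqs <- Biostrings::DNAStringSet(exons$sequence)
  names(seqs) <- exons$exon_id
  Biostrings::writeXStringSet(seqs, fasta_path)
  cols <- intersect(c("exon_id", "gene_id", "chrom", "start", "end", "strand",
                      "midas_p", "fold_change", "class_label"), names(exons))
  write.table(exons[, cols], tsv_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(tsv_path)
}

#' Read an exon set written by [write_exon_set()]
#'
#' @param fasta_path,tsv_path Paths written by [write_exon_set()].
#' @return Exon record data.frame including the `sequence` column.
#' @export
read_exon_set <- function(fasta_path, tsv_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  tab <- read.table(tsv_path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
  idx <- match(tab$exon_id, names(seqs))
  if (anyNA(idx)) stop("exon ids in TSV missing from FASTA")
  tab$sequence <- as.character(seqs)[idx]
  tab
}
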