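#' Classify crosslink sites by genomic region and compute enrichment
#'
#' Assigns every site to one of the six region classes (ncRNA, ORF,
#' 5'UTR, 3'UTR, intron, intergenic) and tabulates, per class, the
#' crosslink-tag count, the precedence-resolved genomic length, the tag
#' density (tags per nucleotide) and the fold enrichment of that density
#' over the genome-average density.  Where annotations overlap, a
#' nucleotide takes the highest-precedence class
#' (ncRNA > ORF > UTR5 > UTR3 > intron > intergenic).
#'
#' @param sites Crosslink-site data.frame (`chrom`, `strand`,
#'   `position`, `cdna_count`); tags are counted with their
#'   `cdna_count` weight.
#' @param models A `gene_models` object or a region data.frame
#'   (chrom, start, end, strand, gene_id, region_class; 0-based
#'   half-open).
#' @param genome_lengths Named integer vector of contig lengths (e.g.
#'   `Biostrings::width()` of the genome, named by contig).
#' @return List with `site_class` (character vector parallel to
#'   `sites`), `density` (data.frame region_class, tag_count,
#'   total_length, density, enrichment) and `proportions` (data.frame
#'   region_class, proportion).
#' @export
classify_sites <- function(sites, models, genome_lengths) {
  regions <- if (is(models, "gene_models")) models$regions else models
  stopifnot(!is.null(names(genome_lengths)))
  missing_chrom <- setdiff(unique(sites$chrom), names(genome_lengths))
  if (length(missing_chrom))
    stop("sites on contigs absent from genome_lengths: ",
         paste(missing_chrom, collapse = ", "))
  unknown <- setdiff(unique(sites$chrom), unique(regions$chrom))
  if (length(unknown))
    warning("sites on contigs absent from the annotation are classified ",
            "intergenic: ", paste(unknown, collapse = ", "))

  classes <- c(REGION_PRECEDENCE, "intergenic")
  lvl <- names(genome_lengths)   # shared seqlevels silence merge warnings
  site_gr <- GenomicRanges::GRanges(
    factor(sites$chrom, lvl), IRanges::IRanges(sites$position + 1L,
                                               width = 1L))
  site_class <- rep("intergenic", nrow(sites))
  claimed <- GenomicRanges::GRanges(seqinfo = GenomeInfoDb::Seqinfo(lvl))
  lengths <- setNames(numeric(length(classes)), classes)
  for (cl in REGION_PRECEDENCE) {
    r <- regions[regions$region_class == cl, , drop = FALSE]
    if (!nrow(r)) next
    gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
      factor(r$chrom, lvl), IRanges::IRanges(r$start + 1L, r$end)))
    eff <- GenomicRanges::setdiff(gr, claimed)
    lengths[cl] <- sum(GenomicRanges::width(eff))
    hit <- unique(S4Vectors::queryHits(
      GenomicRanges::findOverlaps(site_gr, eff, ignore.strand = TRUE)))
    site_class[hit[site_class[hit] == "intergenic"]] <- cl
    claimed <- GenomicRanges::reduce(c(claimed, eff))
  }
  total_len <- sum(genome_lengths)
  lengths["intergenic"] <- total_len - sum(lengths[REGION_PRECEDENCE])

  w <- sites$cdna_count
  tag_count <- vapply(classes, function(cl) sum(w[site_class == cl]),
                      numeric(1))
  total_tags <- sum(w)
  density <- tag_count / lengths
  genome_density <- total_tags / total_len
  density_tab <- data.frame(region_class = classes, tag_count = tag_count,
                            total_length = as.numeric(lengths),
                            density = density,
                            enrichment = density / genome_density,
                            row.names = NULL)
  proportions <- data.frame(region_class = classes,
                            proportion = tag_count / total_tags,
                            row.names = NULL)
  list(site_class = site_class, density = density_tab,
       proportions = proportions)
}

#' Extract splice junctions from gene models
#'
#' A 3' splice site (3'ss) is an intron-to-exon transition in transcript
#' orientation and is anchored at the first exonic nucleotide; a 5'
#' splice site (5'ss) is an exon-to-intron transition anchored at the
#' last exonic nucleotide.  Positive offsets run downstream in
#' transcript orientation, so at a 3'ss negative offsets are intronic
#' and at a 5'ss positive offsets are intronic.
#'
#' @param models `gene_models` or region data.frame.
#' @return data.frame: `chrom`, `strand`, `anchor` ("3ss"/"5ss"),
#'   `anchor_pos` (0-based genomic position of offset 0), `gene_start`,
#'   `gene_end` (transcript extent, for spanning normalization).
#' @export
splice_junctions <- function(models) {
  regions <- if (is(models, "gene_models")) models$regions else models
  out <- list()
  for (tx in split(regions, regions$transcript_id)) {
    strand <- tx$strand[1]
    tx <- tx[order(tx$start, decreasing = (strand == "-")), , drop = FALSE]
    gs <- min(tx$start); ge <- max(tx$end)
    for (i in seq_len(nrow(tx) - 1L)) {
      a <- tx[i, ]; b <- tx[i + 1L, ]   # transcript order
      a_ex <- a$region_class %in% EXONIC_CLASSES
      b_ex <- b$region_class %in% EXONIC_CLASSES
      if (a_ex && b$region_class == "intron") {        # 5'ss
        pos <- if (strand == "+") a$end - 1L else a$start
        out[[length(out) + 1L]] <- data.frame(
          chrom = a$chrom, strand = strand, anchor = "5ss",
          anchor_pos = pos, gene_start = gs, gene_end = ge)
      } else if (a$region_class == "intron" && b_ex) { # 3'ss
        pos <- if (strand == "+") b$start else b$end - 1L
        out[[length(out) + 1L]] <- data.frame(
          chrom = b$chrom, strand = strand, anchor = "3ss",
          anchor_pos = pos, gene_start = gs, gene_end = ge)
      }
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(0), strand = character(0),
                      anchor = character(0), anchor_pos = integer(0),
                      gene_start = integer(0), gene_end = integer(0)))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Splice-junction RNA map of crosslink density
#'
#' Accumulates crosslink counts at offsets within +/-`flank` nt of every
#' junction of the chosen type, divides each offset's count by the
#' number of junctions whose transcript spans the absolute coordinate
#' at that offset, scales by 1e9 / total crosslink count, and smooths
#' with a centered running mean (truncated at the profile ends).
#'
#' @param sites Crosslink-site data.frame.
#' @param models `gene_models` or region data.frame.
#' @param anchor `"3ss"` or `"5ss"`.
#' @param flank Half-width of the profile in nt (default 300).
#' @param smooth_window Odd running-mean window in nt (default 5).
#' @return Object of class `rna_map`: data.frame `offset` (-flank..
#'   +flank; 0 is the junction per the [splice_junctions()] convention),
#'   `raw` (crosslink count), `n_span` (junctions spanning the offset),
#'   `normalized`, `smoothed`; attributes `anchor`, `total_crosslinks`,
#'   `n_junctions`.
#' @export
rna_map <- function(sites, models, anchor = c("3ss", "5ss"),
                    flank = clip_defaults()$rna_map_flank,
                    smooth_window = clip_defaults()$smooth_window) {
  anchor <- match.arg(anchor)
  stopifnot(flank >= 1L, smooth_window %% 2L == 1L)
  jn <- splice_junctions(models)
  jn <- jn[jn$anchor == anchor, , drop = FALSE]
  offsets <- seq.int(-flank, flank)
  raw <- setNames(numeric(length(offsets)), offsets)
  n_span <- setNames(numeric(length(offsets)), offsets)
  if (!nrow(jn)) {
    warning("no junctions of type ", anchor, " in the annotation")
  } else {
    sgn <- ifelse(jn$strand == "+", 1L, -1L)
    # spanning: offsets whose absolute coordinate the transcript covers
    dmin <- pmax(-flank, ifelse(sgn == 1L, jn$gene_start - jn$anchor_pos,
                                jn$anchor_pos - (jn$gene_end - 1L)))
    dmax <- pmin(flank, ifelse(sgn == 1L, (jn$gene_end - 1L) - jn$anchor_pos,
                               jn$anchor_pos - jn$gene_start))
    for (j in seq_len(nrow(jn))) {
      if (dmin[j] <= dmax[j]) {
        k <- (dmin[j] + flank + 1L):(dmax[j] + flank + 1L)
        n_span[k] <- n_span[k] + 1L
      }
      same <- sites$chrom == jn$chrom[j] & sites$strand == jn$strand[j]
      if (!any(same)) next
      d <- (sites$position[same] - jn$anchor_pos[j]) * sgn[j]
      in_win <- d >= -flank & d <= flank
      if (any(in_win)) {
        tab <- tapply(sites$cdna_count[same][in_win],
                      d[in_win] + flank + 1L, sum)
        k <- as.integer(names(tab))
        raw[k] <- raw[k] + tab
      }
    }
  }
  total <- sum(sites$cdna_count)
  normalized <- ifelse(n_span > 0, raw / n_span, 0) * 1e9 / total
  smoothed <- running_mean(normalized, smooth_window)
  structure(data.frame(offset = offsets, raw = as.numeric(raw),
                       n_span = as.numeric(n_span),
                       normalized = normalized, smoothed = smoothed,
                       row.names = NULL),
            anchor = anchor, total_crosslinks = total,
            n_junctions = nrow(jn), class = c("rna_map", "data.frame"))
}

# Centered running mean with truncated windows at the profile ends.
running_mean <- function(x, window) {
  h <- (window - 1L) %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i)
    mean(x[max(1L, i - h):min(n, i + h)]), numeric(1))
}
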