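#' Configuration for the synthetic iCLIP world
#'
#' Bundles every tunable of the synthetic-data generator: the toy genome
#' layout, the crosslink placement model, the PCR duplication model, the
#' read layout, and the cassette-exon class sets.  Defaults describe the
#' standard simulated world used by the package's tests: a ~20-gene toy
#' genome, crosslinks concentrated on planted GAAGA instances inside
#' coding exons, Poisson(3) PCR duplication, and AGA-anchored trimer
#' pairs planted in the last 50 nt of "down" exons at rate 0.6.
#'
#' @param seed Integer RNG seed; identical configurations produce
#'   byte-identical outputs.
#' @param n_genes Number of genes on the toy genome.
#' @param exon_len_range,intron_len_range,utr_len_range Integer pairs
#'   (nt) for uniform length draws.
#' @param intergenic_len_range Integer pair (nt) for gaps between genes.
#' @param n_exons_range Integer pair; exons per coding gene (min 3 so
#'   internal cassette exons exist).
#' @param ncrna_fraction Probability a gene is a single-block ncRNA.
#' @param base_composition Probability 4-vector over A,C,G,T; must sum
#'   to 1 within 1e-9.
#' @param crosslink_motif Motif planted in coding exons at which
#'   crosslinks concentrate (default `"GAAGA"`).
#' @param crosslink_offset 0-based offset of the crosslink nucleotide
#'   within a planted motif instance (default 1, the first A of GAAGA).
#'   The within-motif crosslink position is a free parameter of the
#'   simulation, not an inference.
#' @param motifs_per_exon Motif instances planted per coding exon.
#' @param motif_site_fraction Fraction of crosslink events placed at
#'   planted motif instances; the rest are uniform over coding exons.
#' @param n_crosslink_events Number of unique cDNA events to simulate.
#' @param pcr_duplication_mean Mean extra PCR copies per unique cDNA
#'   (each cDNA yields `1 + Poisson(mean)` reads).
#' @param read_len Total read length including the 9-nt barcode block.
#' @param barcode_index 4-nt experiment index embedded in each read.
#' @param seq_error_rate Per-base substitution rate applied to read
#'   copies (default 0 so deduplication tests are exact).
#' @param n_regulated_exons Exons per regulated class (up/down/control).
#' @param n_population_exons Size of the exon population used for
#'   bootstrap resampling.
#' @param pair_plant_rate Fraction of "down" exons receiving a planted
#'   trimer pair in their last 50 nt.
#' @param genome_len Optional total genome length; an error is raised if
#'   the requested genes cannot be packed into it, and the remainder is
#'   padded with intergenic sequence.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, n_genes = 5)
#' cfg$crosslink_motif
sim_config <- function(seed = 1L,
                       n_genes = 20L,
                       exon_len_range = c(120L, 300L),
                       intron_len_range = c(200L, 600L),
                       utr_len_range = c(60L, 200L),
                       intergenic_len_range = c(300L, 800L),
                       n_exons_range = c(3L, 5L),
                       ncrna_fraction = 0.15,
                       base_composition = c(A = 0.25, C = 0.25,
                                            G = 0.25, T = 0.25),
                       crosslink_motif = "GAAGA",
                       crosslink_offset = 1L,
                       motifs_per_exon = 2L,
                       motif_site_fraction = 0.5,
                       n_crosslink_events = 1000L,
                       pcr_duplication_mean = 3,
                       read_len = 45L,
                       barcode_index = "AACC",
                       seq_error_rate = 0,
                       n_regulated_exons = 100L,
                       n_population_exons = 2000L,
                       pair_plant_rate = 0.6,
                       genome_len = NULL) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              exon_len_range = as.integer(exon_len_range),
              intron_len_range = as.integer(intron_len_range),
              utr_len_range = as.integer(utr_len_range),
              intergenic_len_range = as.integer(intergenic_len_range),
              n_exons_range = as.integer(n_exons_range),
              ncrna_fraction = ncrna_fraction,
              base_composition = base_composition,
              crosslink_motif = toupper(crosslink_motif),
              crosslink_offset = as.integer(crosslink_offset),
              motifs_per_exon = as.integer(motifs_per_exon),
              motif_site_fraction = motif_site_fraction,
              n_crosslink_events = as.integer(n_crosslink_events),
              pcr_duplication_mean = pcr_duplication_mean,
              read_len = as.integer(read_len),
              barcode_index = toupper(barcode_index),
              seq_error_rate = seq_error_rate,
              n_regulated_exons = as.integer(n_regulated_exons),
              n_population_exons = as.integer(n_population_exons),
              pair_plant_rate = pair_plant_rate,
              genome_len = if (is.null(genome_len)) NULL
                           else as.integer(genome_len))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(length(cfg$base_composition) == 4L,
            all(cfg$base_composition >= 0))
  if (abs(sum(cfg$base_composition) - 1) > 1e-9)
    stop("base_composition must sum to 1 within 1e-9")
  for (f in c("motif_site_fraction", "pair_plant_rate", "ncrna_fraction")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || v < 0 || v > 1)
      stop(f, " must lie in [0, 1]")
  }
  for (f in c("exon_len_range", "intron_len_range", "utr_len_range",
              "intergenic_len_range", "n_exons_range")) {
    r <- cfg[[f]]
    if (length(r) != 2L || any(r <= 0L) || r[2] < r[1])
      stop(f, " must be a positive non-decreasing integer pair")
  }
  if (cfg$n_genes < 1L) stop("n_genes must be >= 1")
  if (cfg$n_exons_range[1] < 3L)
    stop("coding genes need >= 3 exons so internal cassette exons exist")
  if (nchar(cfg$barcode_index) != 4L)
    stop("barcode_index must be a 4-nt string")
  if (cfg$crosslink_offset < 0L ||
      cfg$crosslink_offset >= nchar(cfg$crosslink_motif))
    stop("crosslink_offset must fall inside the motif")
  if (cfg$read_len <= 9L + 14L)
    stop("read_len must exceed the 9-nt barcode block plus a mappable insert")
  if (cfg$pcr_duplication_mean < 0) stop("pcr_duplication_mean must be >= 0")
  if (cfg$seq_error_rate < 0 || cfg$seq_error_rate > 1)
    stop("seq_error_rate must lie in [0, 1]")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config: seed", x$seed, "|", x$n_genes, "genes |",
      x$n_crosslink_events, "crosslink events on", x$crosslink_motif,
      sprintf("(site fraction %.2f)", x$motif_site_fraction), "\n")
  invisible(x)
}
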