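# Shared fixtures, built once per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env))
    assign(name, builder(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# Small default world: genome + reads at moderate depth.
small_sim <- function() fixture("small_sim", function() {
  cfg <- sim_config(seed = 101, n_genes = 8, n_crosslink_events = 400,
                    pcr_duplication_mean = 2)
  sim <- make_genome(cfg)
  rr <- plant_crosslink_reads(sim$genome, sim$annotation, cfg)
  list(cfg = cfg, sim = sim, reads = rr$reads, truth = rr$truth)
})

# Hand-built two-gene annotation on a 1000-nt contig for interval tests.
# gene A ("+"): UTR5 100-150, ORF 150-250, intron 250-400, ORF 400-500,
#               UTR3 500-550.  gene B ("-"): ncRNA 700-800.
hand_models <- function() {
  regions <- data.frame(
    chrom = "chrT",
    start = c(100L, 150L, 250L, 400L, 500L, 700L),
    end   = c(150L, 250L, 400L, 500L, 550L, 800L),
    strand = c(rep("+", 5), "-"),
    gene_id = c(rep("gA", 5), "gB"),
    transcript_id = c(rep("gA", 5), "gB"),
    region_class = c("UTR5", "ORF", "intron", "ORF", "UTR3", "ncRNA"))
  structure(list(regions = regions, transcripts = NULL,
                 motif_instances = NULL), class = "gene_models")
}

hand_genome <- function() {
  set.seed(424)
  Biostrings::DNAStringSet(c(chrT = random_seq(1000)))
}

make_sites <- function(positions, chrom = "chrT", strand = "+", count = 1L) {
  data.frame(chrom = chrom, strand = strand, position = as.integer(positions),
             cdna_count = as.integer(count), stringsAsFactors = FALSE)
}

# Minimal exon-record table from bare sequences.
seq_exons <- function(seqs, prefix = "e") {
  data.frame(exon_id = sprintf("%s%03d", prefix, seq_along(seqs)),
             sequence = seqs, stringsAsFactors = FALSE)
}
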