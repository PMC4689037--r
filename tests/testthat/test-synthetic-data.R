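test_that("sim_config validates its invariants", {
  expect_error(sim_config(base_composition = c(0.3, 0.3, 0.3, 0.2)),
               "sum to 1")
  expect_error(sim_config(motif_site_fraction = 1.5), "\\[0, 1\\]")
  expect_error(sim_config(pair_plant_rate = -0.1), "\\[0, 1\\]")
  expect_error(sim_config(n_exons_range = c(2L, 4L)), "internal")
  expect_error(sim_config(barcode_index = "AAC"), "4-nt")
  expect_s3_class(sim_config(), "sim_config")
})

test_that("make_genome is deterministic and genes are non-overlapping", {
  cfg <- sim_config(seed = 7, n_genes = 20)
  a <- make_genome(cfg)
  b <- make_genome(cfg)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$annotation$regions, b$annotation$regions)

  # brute-force pairwise overlap check over gene extents
  tx <- a$annotation$transcripts
  expect_equal(nrow(tx), 20L)
  for (i in seq_len(nrow(tx) - 1L)) for (j in (i + 1L):nrow(tx)) {
    expect_true(tx$end[i] <= tx$start[j] || tx$end[j] <= tx$start[i],
                label = sprintf("genes %d and %d disjoint", i, j))
  }
})

test_that("region classes tile each transcript exactly", {
  sim <- small_sim()$sim
  reg <- sim$annotation$regions
  for (tx in split(reg, reg$transcript_id)) {
    tx <- tx[order(tx$start), ]
    expect_true(all(tx$start[-1] == tx$end[-nrow(tx)]),
                label = paste("no gaps/overlaps in", tx$transcript_id[1]))
    ext <- sim$annotation$transcripts
    ext <- ext[ext$transcript_id == tx$transcript_id[1], ]
    expect_equal(min(tx$start), ext$start)
    expect_equal(max(tx$end), ext$end)
  }
})

test_that("a 3-exon gene yields exactly one internal cassette candidate", {
  cfg <- sim_config(seed = 5, n_genes = 1, n_exons_range = c(3L, 3L),
                    ncrna_fraction = 0)
  sim <- make_genome(cfg)
  internal <- clipmotifs:::internal_exons(sim$annotation$regions)
  expect_equal(nrow(internal), 1L)
  expect_equal(internal$region_class, "ORF")
})

test_that("planted motifs appear in transcript orientation and truth is
           verifiable by re-scan", {
  sim <- small_sim()$sim
  inst <- sim$annotation$motif_instances
  expect_gt(nrow(inst), 0L)
  motif <- sim$config$crosslink_motif
  g <- sim$genome[[1]]
  for (i in seq_len(nrow(inst))) {
    found <- as.character(Biostrings::subseq(g, inst$start[i] + 1L,
                                             inst$start[i] + nchar(motif)))
    expected <- if (inst$strand[i] == "+") motif else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(motif)))
    expect_identical(found, expected)
  }
})

test_that("generated sequence composition matches base_composition", {
  comp <- c(A = 0.4, C = 0.1, G = 0.2, T = 0.3)
  cfg <- sim_config(seed = 31, n_genes = 10, motifs_per_exon = 0L,
                    base_composition = comp)
  sim <- make_genome(cfg)
  n <- sum(Biostrings::width(sim$genome))
  freq <- Biostrings::letterFrequency(sim$genome,
                                      c("A", "C", "G", "T"))[1, ] / n
  se <- sqrt(comp * (1 - comp) / n)
  expect_true(all(abs(freq - comp) <= 3 * se))
})

test_that("impossible genome packing raises a sizing error", {
  expect_error(make_genome(sim_config(seed = 1, n_genes = 20,
                                      genome_len = 1000L)),
               "genome too small")
})

test_that("pcr_duplication_mean = 0 gives one read per event", {
  cfg <- sim_config(seed = 9, n_genes = 5, n_crosslink_events = 200,
                    pcr_duplication_mean = 0)
  sim <- make_genome(cfg)
  rr <- plant_crosslink_reads(sim$genome, sim$annotation, cfg)
  expect_equal(nrow(rr$reads), 200L)
  expect_true(all(rr$truth$planted_crosslinks$n_reads == 1L))
})

test_that("motif_site_fraction = 1 places every crosslink at a planted
           motif instance at the configured offset", {
  cfg <- sim_config(seed = 13, n_genes = 5, n_crosslink_events = 100,
                    motif_site_fraction = 1)
  sim <- make_genome(cfg)
  rr <- plant_crosslink_reads(sim$genome, sim$annotation, cfg)
  ev <- rr$truth$planted_crosslinks
  g <- sim$genome[[1]]
  motif <- cfg$crosslink_motif; off <- cfg$crosslink_offset
  mlen <- nchar(motif)
  for (i in seq_len(nrow(ev))) {
    mstart <- if (ev$strand[i] == "+") ev$position[i] - off
              else ev$position[i] - (mlen - 1L - off)
    found <- as.character(Biostrings::subseq(g, mstart + 1L, mstart + mlen))
    if (ev$strand[i] == "-")
      found <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(found)))
    expect_identical(found, motif)
  }
})

test_that("replaying the generator reproduces read totals byte-for-byte", {
  cfg <- sim_config(seed = 17, n_genes = 4, n_crosslink_events = 150,
                    pcr_duplication_mean = 2)
  sim <- make_genome(cfg)
  r1 <- plant_crosslink_reads(sim$genome, sim$annotation, cfg)
  r2 <- plant_crosslink_reads(sim$genome, sim$annotation, cfg)
  expect_identical(r1$reads, r2$reads)
  expect_equal(nrow(r1$reads),
               sum(r1$truth$planted_crosslinks$n_reads))
})

test_that("emitted reads encode the barcode layout and genomic insert", {
  ss <- small_sim()
  ev <- ss$truth$planted_crosslinks
  # reads are emitted in event order, replicated by n_reads
  idx <- rep.int(seq_len(nrow(ev)), ev$n_reads)
  g <- ss$sim$genome[[1]]
  pick <- seq(1, nrow(ss$reads), length.out = 25)
  for (r in as.integer(pick)) {
    e <- ev[idx[r], ]
    seq <- ss$reads$seq[r]
    expect_identical(substr(seq, 3, 6), ss$cfg$barcode_index)
    expect_identical(paste0(substr(seq, 1, 2), substr(seq, 7, 9)),
                     e$barcode)
    insert <- substr(seq, 10, nchar(seq))
    genomic <- if (e$strand == "+")
      as.character(Biostrings::subseq(g, e$position + 2L,
                                      e$position + 1L + e$insert_len))
    else
      as.character(Biostrings::reverseComplement(Biostrings::subseq(
        g, e$position - e$insert_len + 1L, e$position)))
    expect_identical(insert, genomic)
  }
})

test_that("make_exon_sets plants pairs per pair_plant_rate", {
  cfg0 <- sim_config(seed = 21, n_regulated_exons = 30,
                     n_population_exons = 50, pair_plant_rate = 0)
  es0 <- make_exon_sets(cfg0)
  expect_equal(nrow(es0$truth$planted_pair_exons), 0L)

  cfg1 <- sim_config(seed = 22, n_regulated_exons = 50,
                     n_population_exons = 50, pair_plant_rate = 1)
  es1 <- make_exon_sets(cfg1)
  down <- es1$exons[es1$exons$class_label == "down", ]
  expect_equal(nrow(es1$truth$planted_pair_exons), 50L)
  # brute-force scan: every down exon has a qualifying pair in last 50 nt
  for (s in down$sequence) {
    last50 <- substr(s, nchar(s) - 49L, nchar(s))
    expect_gt(nrow(brute_pairs(last50)), 0L)
  }
})

test_that("exon set statistics respect class construction", {
  es <- make_exon_sets(sim_config(seed = 23, n_regulated_exons = 40,
                                  n_population_exons = 60))
  ex <- es$exons
  expect_true(all(ex$midas_p[ex$class_label == "control"] > 0.95))
  expect_true(all(ex$midas_p[ex$class_label %in% c("up", "down")] < 0.05))
  expect_true(all(ex$fold_change[ex$class_label == "up"] > 2))
  expect_true(all(ex$fold_change[ex$class_label == "down"] < -2))
  expect_true(all(nchar(ex$sequence) >= 100L))
  expect_true(all(nchar(ex$sequence) == ex$end - ex$start))
  # determinism
  es2 <- make_exon_sets(sim_config(seed = 23, n_regulated_exons = 40,
                                   n_population_exons = 60))
  expect_identical(es$exons, es2$exons)
})

test_that("control cohort plants one defect per gene and truth is by
           construction", {
  cc <- make_control_cohort(sim_config(seed = 30, n_genes = 25))
  expect_setequal(unique(cc$truth$defects$defect),
                  c("none", "low_p", "low_expr", "terminal", "short",
                    "overlap", "ambiguous"))
  d <- cc$truth$defects
  expect_identical(cc$truth$qualifying_exons,
                   sort(d$exon_id[d$defect == "none"]))
  # planted ambiguity is really in the genome
  amb <- d$gene_id[d$defect == "ambiguous"]
  for (g in amb) {
    ctg <- cc$diff_table$chrom[cc$diff_table$gene_id == g][1]
    expect_true(grepl("N", as.character(cc$genome[[ctg]])))
  }
})
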