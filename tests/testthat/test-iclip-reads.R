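test_that("demultiplex assigns by exact index at positions 3-6 and
           conserves reads", {
  reads <- data.frame(
    read_id = c("r1", "r2", "r3", "r4"),
    seq = c(paste0("GTAACCTAG", strrep("A", 20)),   # AACC -> s1
            paste0("CCACACGGT", strrep("A", 20)),   # ACAC -> s2
            paste0("TTAGGTCCA", strrep("A", 20)),   # AGGT -> unmatched
            "ATATATAT"))                            # 8 nt -> too short
  dm <- demultiplex(reads, c(AACC = "s1", ACAC = "s2"))
  expect_equal(dm$samples$s1$read_id, "r1")
  expect_equal(dm$samples$s2$read_id, "r2")
  expect_setequal(dm$rejected$read_id, c("r3", "r4"))
  expect_equal(dm$rejected$reason[dm$rejected$read_id == "r4"],
               "too_short")
  # barcode layout: NN + index + NNN
  expect_equal(dm$samples$s1$random_barcode, "GTTAG")
  expect_equal(dm$samples$s1$insert, strrep("A", 20))
  expect_equal(nchar(dm$samples$s1$insert),
               nchar(reads$seq[1]) - 9L)

  ss <- small_sim()
  dm2 <- demultiplex(ss$reads, c(AACC = "rep1", ACAC = "rep2",
                                 AGGT = "rep3"))
  expect_equal(sum(vapply(dm2$samples, nrow, integer(1))) +
                 nrow(dm2$rejected), nrow(ss$reads))
  expect_error(demultiplex(ss$reads, c(AACC = "a", AACC = "b")),
               "distinct")
})

test_that("map_inserts applies the one-mismatch unique-hit policy", {
  set.seed(88)
  g <- random_seq(4000)
  # plant an exact duplicate locus
  dup <- substr(g, 501, 530)
  substr(g, 2001, 2030) <- dup
  genome <- Biostrings::DNAStringSet(c(chrM = g))

  uniq <- substr(g, 1001, 1030)
  one_mm <- uniq; substr(one_mm, 15, 15) <- setdiff(c("A", "C", "G", "T"),
                                                    substr(one_mm, 15, 15))[1]
  two_mm <- one_mm; substr(two_mm, 25, 25) <- setdiff(c("A", "C", "G", "T"),
                                                      substr(two_mm, 25, 25))[1]
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(g, 3001, 3030))))
  reads <- data.frame(read_id = sprintf("q%d", 1:5),
                      insert = c(uniq, one_mm, two_mm, dup, rc),
                      random_barcode = "AAAAA")
  aln <- map_inserts(reads, genome)
  st <- attr(aln, "map_stats")
  expect_equal(unname(st["mapped"]), 3L)
  expect_equal(unname(st["unmapped"]), 1L)       # two mismatches
  expect_equal(unname(st["multimapped"]), 1L)    # duplicate locus
  expect_equal(aln$start[aln$read_id == "q1"], 1000L)
  expect_equal(aln$mismatches[aln$read_id == "q1"], 0L)
  expect_equal(aln$mismatches[aln$read_id == "q2"], 1L)
  expect_equal(aln$strand[aln$read_id == "q5"], "-")
  expect_equal(aln$start[aln$read_id == "q5"], 3000L)
  # short inserts are not attempted
  st2 <- attr(map_inserts(data.frame(insert = "ACGTACGT",
                                     random_barcode = "AAAAA"),
                          genome), "map_stats")
  expect_equal(unname(st2["too_short"]), 1L)
})

test_that("map_inserts agrees with the Biostrings exhaustive oracle", {
  ss <- small_sim()
  dm <- demultiplex(ss$reads, c(AACC = "s1"))$samples$s1
  set.seed(3)
  take <- dm[sample.int(nrow(dm), 150), , drop = FALSE]
  # corrupt a third with 1 substitution, a sixth with 2
  mutate_at <- function(s, k) {
    p <- sample.int(nchar(s), k)
    ch <- strsplit(s, "")[[1]]
    for (i in p) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
    paste(ch, collapse = "")
  }
  n <- nrow(take)
  take$insert[1:50] <- vapply(take$insert[1:50], mutate_at, character(1), 1L)
  take$insert[51:75] <- vapply(take$insert[51:75], mutate_at, character(1), 2L)
  aln <- map_inserts(take, ss$sim$genome)
  oracle <- biostrings_map_oracle(take$insert, ss$sim$genome)
  # align row-wise: reconstruct per-read outcome from aln by read_id
  got <- data.frame(chrom = NA_character_, strand = NA_character_,
                    start = NA_integer_, mismatches = NA_integer_)
  got <- got[rep(1L, n), ]; rownames(got) <- NULL
  hit <- match(take$read_id, aln$read_id)
  ok <- !is.na(hit)
  got[ok, ] <- aln[hit[ok], c("chrom", "strand", "start", "mismatches")]
  mappable <- oracle$n_best == 1L
  expect_identical(got$start, oracle$start)
  expect_identical(got$strand, oracle$strand)
  expect_identical(got$mismatches[mappable], oracle$mismatches[mappable])
})

test_that("deduplicate counts distinct barcodes per truncation site", {
  aln <- data.frame(chrom = "c", strand = "+", start = 100L, end = 130L,
                    random_barcode = c("AAAAA", "AAAAA", "AAAAA"))
  s <- deduplicate(aln)
  expect_equal(nrow(s), 1L)
  expect_equal(s$cdna_count, 1L)
  expect_equal(s$position, 99L)   # nucleotide 5' of the read start

  aln$random_barcode <- c("AAAAA", "AAAAC", "AAAAA")
  expect_equal(deduplicate(aln)$cdna_count, 2L)

  # "-" strand: truncation site is at end
  alnm <- data.frame(chrom = "c", strand = "-", start = 100L, end = 130L,
                     random_barcode = "CCCCC")
  expect_equal(deduplicate(alnm)$position, 130L)
  # "start" convention
  expect_equal(deduplicate(aln, convention = "start")$position, 100L)
  expect_equal(deduplicate(alnm, convention = "start")$position, 129L)
})

test_that("deduplication conserves counts and is a fixed point", {
  ss <- small_sim()
  aln <- truth_alignments(ss$truth)
  sites <- deduplicate(aln)
  expect_lte(sum(sites$cdna_count), nrow(aln))
  expect_equal(sum(sites$cdna_count), ss$truth$unique_cdna_count)

  # expand each site into one alignment per distinct cDNA and re-dedup
  idx <- rep.int(seq_len(nrow(sites)), sites$cdna_count)
  expanded <- data.frame(
    chrom = sites$chrom[idx], strand = sites$strand[idx],
    start = ifelse(sites$strand[idx] == "+", sites$position[idx] + 1L,
                   sites$position[idx] - 30L),
    end = ifelse(sites$strand[idx] == "+", sites$position[idx] + 31L,
                 sites$position[idx]),
    random_barcode = paste0("BC", sequence(sites$cdna_count)))
  again <- deduplicate(expanded)
  expect_equal(again[, c("chrom", "strand", "position", "cdna_count")],
               sites[, c("chrom", "strand", "position", "cdna_count")])
})

test_that("full pipeline recovers planted unique-cDNA counts exactly", {
  for (mean_dup in c(0, 1, 5)) {
    cfg <- sim_config(seed = 300 + mean_dup, n_genes = 6,
                      n_crosslink_events = 250,
                      pcr_duplication_mean = mean_dup)
    sim <- make_genome(cfg)
    rr <- plant_crosslink_reads(sim$genome, sim$annotation, cfg)
    dm <- demultiplex(rr$reads, c(AACC = "s1"))
    aln <- map_inserts(dm$samples$s1, sim$genome)
    sites <- deduplicate(aln)
    expect_equal(sum(sites$cdna_count), rr$truth$unique_cdna_count,
                 label = sprintf("recovered cDNAs (mean_dup=%d)", mean_dup))
    if (mean_dup == 0)
      expect_equal(sum(sites$cdna_count), nrow(aln))
  }
})

test_that("site BED round-trips through disk", {
  ss <- small_sim()
  sites <- deduplicate(truth_alignments(ss$truth))
  path <- withr::local_tempfile(fileext = ".bed")
  write_sites_bed(sites, path)
  back <- read_sites_bed(path)
  expect_equal(back, sites)
})
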