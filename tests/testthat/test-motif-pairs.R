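test_that("find_pairs handles the canonical worked examples", {
  p <- find_pairs("AAGAAGA")
  expect_equal(nrow(p), 3L)
  expect_equal(p$up_pos, c(1L, 1L, 2L))
  expect_equal(p$up_trimer, c("AAG", "AAG", "AGA"))
  expect_equal(p$down_pos, c(4L, 5L, 5L))
  expect_equal(p$down_trimer, c("AAG", "AGA", "AGA"))

  expect_equal(nrow(find_pairs("AAGA")), 0L)     # overlap excluded
  expect_equal(nrow(find_pairs("CCCCCC")), 0L)
  expect_error(find_pairs("AAGAAGA", k_min = 2L))
})

test_that("find_pairs equals the O(n^2) brute-force oracle on random
           sequences", {
  set.seed(70)
  for (i in 1:200) {
    s <- random_seq(50, prob = c(0.35, 0.15, 0.35, 0.15))
    got <- find_pairs(s)
    want <- brute_pairs(s)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want, label = paste("seq", i))
  }
})

test_that("pair_presence_matrix agrees with the find_pairs route", {
  set.seed(71)
  seqs <- vapply(1:150, function(i)
    random_seq(50, prob = c(0.3, 0.2, 0.3, 0.2)), character(1))
  trimers <- clip_defaults()$target_trimers
  pairs <- rbind(expand.grid(up_trimer = trimers, down_trimer = trimers,
                             stringsAsFactors = FALSE),
                 data.frame(up_trimer = trimers, down_trimer = "Any"))
  m <- pair_presence_matrix(seqs, pairs)
  for (k in seq_len(nrow(pairs))) {
    slow <- vapply(seqs, function(s) {
      p <- find_pairs(s)
      if (!nrow(p)) return(FALSE)
      any(p$up_trimer == pairs$up_trimer[k] &
            (pairs$down_trimer[k] == "Any" |
               p$down_trimer == pairs$down_trimer[k]))
    }, logical(1), USE.NAMES = FALSE)
    expect_equal(m[, k], as.numeric(slow),
                 label = paste(pairs$up_trimer[k], pairs$down_trimer[k]))
  }
})

test_that("mark_positions equals an independent per-position regex scan", {
  set.seed(72)
  seqs <- vapply(1:20, function(i) random_seq(120), character(1))
  exons <- seq_exons(seqs)
  pc <- mark_positions(exons, region = "exon_last50")
  trimers <- clip_defaults()$target_trimers
  for (pos in seq_len(50)) {
    manual <- sum(vapply(seqs, function(s) {
      last50 <- substr(s, nchar(s) - 49L, nchar(s))
      substr(last50, pos, pos + 2L) %in% trimers
    }, logical(1)))
    expect_equal(pc$target_marked[pos], manual)
  }
  # all-C controls have zero marks and two-sided Fisher p computed
  ctrl <- seq_exons(rep(strrep("C", 120), 10), prefix = "c")
  pc2 <- mark_positions(exons, ctrl)
  expect_true(all(pc2$control_marked == 0L))
  expect_true(all(pc2$p >= 0 & pc2$p <= 1))
  # exons shorter than the region are skipped and logged
  mixed <- seq_exons(c(seqs[1], random_seq(30)))
  pc3 <- mark_positions(mixed)
  expect_equal(attr(pc3, "n_skipped_target"), 1L)
})

test_that("pair_test matches the exact hypergeometric oracle", {
  # the spec's worked table: a=5, b=5, c=0, d=10
  p <- clipmotifs:::fisher_one_sided(5, 5, 0, 10)
  expect_equal(p, hyper_tail_enum(5, 5, 0, 10), tolerance = 1e-12)
  # assorted tables, relative error < 1e-10
  set.seed(73)
  for (i in 1:200) {
    tot <- sample(4:60, 1)
    cuts <- sort(sample(0:tot, 3, replace = TRUE))
    a <- cuts[1]; b <- cuts[2] - cuts[1]; cc <- cuts[3] - cuts[2]
    d <- tot - cuts[3]
    got <- clipmotifs:::fisher_one_sided(a, b, cc, d)
    want <- hyper_tail_enum(a, b, cc, d)
    expect_lt(abs(got - want) / max(want, .Machine$double.xmin), 1e-10)
  }
})

test_that("pair_test counts presence per exon and identical sets are
           non-significant", {
  target <- seq_exons(c("AAGCCCAGA", "CCCCCCCCC", "AAGAAGAAA"))
  ctrl <- seq_exons(c("AAGCCCAGA", "CCCCCCCCC", "CCCCCCCCC"),
                    prefix = "c")
  res <- pair_test(target, ctrl, "AAG", "Any", region = "exon_first50",
                   region_length = 9L)
  expect_equal(res$a, 2L)   # two target exons contain an AAG->Any pair
  expect_equal(res$c, 1L)
  expect_equal(res$a + res$b, 3L)
  expect_equal(res$p_fisher,
               hyper_tail_enum(res$a, res$b, res$c, res$d),
               tolerance = 1e-12)

  same <- pair_test(target, target, "AAG", "Any",
                    region = "exon_first50", region_length = 9L)
  expect_equal(same$p_fisher,
               hyper_tail_enum(same$a, same$b, same$c, same$d),
               tolerance = 1e-12)
  expect_gt(same$p_fisher, 0.5)   # no difference => not significant
  expect_error(pair_test(target[0, ], ctrl, "AAG"), "non-empty")
})

test_that("degenerate Any pairs dominate their specific members", {
  es <- make_exon_sets(sim_config(seed = 74, n_regulated_exons = 60,
                                  n_population_exons = 60))
  ex <- es$exons
  res <- pair_test_all(ex[ex$class_label == "down", ],
                       ex[ex$class_label == "control", ])
  expect_equal(nrow(res), 12L)
  expect_setequal(res$rank, 1:12)
  for (t in clip_defaults()$target_trimers) {
    any_a <- res$a[res$up_trimer == t & res$down_trimer == "Any"]
    spec_a <- res$a[res$up_trimer == t & res$down_trimer != "Any"]
    expect_gte(any_a, max(spec_a))
  }
  # planted upstream anchor is recovered at the top of the ranking
  expect_equal(res$up_trimer[res$rank == 1], "AGA")
})

test_that("bootstrap_fdr semantics: p = 1 gives fdr 1, bounds and
           monotonicity hold", {
  es <- make_exon_sets(sim_config(seed = 75, n_regulated_exons = 40,
                                  n_population_exons = 300))
  ex <- es$exons
  down <- ex[ex$class_label == "down", ]
  ctrl <- ex[ex$class_label == "control", ]
  pop <- ex[ex$class_label == "population", ]
  res <- pair_test_all(down, ctrl)
  res$p_fisher[12] <- 1   # force an observed p of 1 for the worst pair
  fdr <- bootstrap_fdr(res, pop, ctrl, n_trials = 200, sample_size = 40,
                       seed = 7)
  expect_equal(fdr$fdr_bootstrap[12], 1)
  expect_false(fdr$significant[12])
  expect_true(all(fdr$fdr_bootstrap >= 0 & fdr$fdr_bootstrap <= 1))
  # monotone in observed p (same trials)
  ord <- order(fdr$p_fisher)
  expect_true(all(diff(fdr$fdr_bootstrap[ord]) >= 0))
  # below-resolution reporting
  expect_true(all(fdr$fdr_below_resolution == (fdr$fdr_bootstrap == 0)))
  # determinism
  fdr2 <- bootstrap_fdr(res, pop, ctrl, n_trials = 200, sample_size = 40,
                        seed = 7)
  expect_equal(fdr$fdr_bootstrap, fdr2$fdr_bootstrap)
  expect_error(bootstrap_fdr(res, pop, ctrl, n_trials = 0), "n_trials")
  expect_error(bootstrap_fdr(res, pop[1:10, ], ctrl, n_trials = 10,
                             sample_size = 40), "smaller")
})

test_that("mutate_trimers ablates all target trimers with G->C edits
           only", {
  m <- mutate_trimers("GAAGA")
  expect_equal(m$sequence, "CAACA")
  expect_equal(m$changes$position, c(1L, 4L))
  expect_true(all(m$changes$from == "G" & m$changes$to == "C"))

  expect_equal(mutate_trimers("CCCTTT")$sequence, "CCCTTT")

  set.seed(76)
  for (i in 1:100) {
    s <- random_seq(80, prob = c(0.3, 0.2, 0.3, 0.2))
    m <- mutate_trimers(s)
    expect_equal(nrow(clipmotifs:::trimer_positions(
      m$sequence, clip_defaults()$target_trimers)), 0L)
    # only G -> C substitutions; everything else untouched
    a <- strsplit(s, "")[[1]]; b <- strsplit(m$sequence, "")[[1]]
    ch <- which(a != b)
    expect_true(all(a[ch] == "G" & b[ch] == "C"))
    expect_setequal(ch, m$changes$position)
    # idempotent
    expect_equal(mutate_trimers(m$sequence)$sequence, m$sequence)
  }
})
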