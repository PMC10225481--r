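# IGS scoring, ranking, origin/terminus prediction.

mk_igs <- function(sequence, start = 0, L = NULL, record_id = "r") {
  len <- nchar(sequence)
  list(record_id = record_id, start = start, end = start + len,
       length = len, midpoint = start + len / 2, sequence = sequence,
       left_idx = NA_integer_, right_idx = NA_integer_)
}

mk_indicator <- function(start, end, class = "primary", strand = "+") {
  data.frame(locus_tag = "i", gene_name = "dnaA", product = "",
             start = start, end = end, strand = strand, kind = "CDS",
             indicator_class = class, midpoint = (start + end) / 2,
             stringsAsFactors = FALSE)
}

test_that("indicator genes match by name, product and chromosome type", {
  f <- data.frame(locus_tag = c("a", "b", "c", "d"),
                  gene_name = c("dnaA", "", "rctB", "polA"),
                  product = c("", "chromosomal replication initiator protein DnaA",
                              "", "DNA polymerase I"),
                  start = c(0, 100, 200, 300), end = c(90, 190, 290, 390),
                  strand = "+", kind = "CDS", stringsAsFactors = FALSE)
  rec <- genome_record("t", random_seq(400), features = f, source = "simulated")

  ind <- find_indicator_genes(rec, indicator_table())
  expect_setequal(ind$locus_tag, c("a", "b", "c"))
  expect_equal(ind$indicator_class[ind$locus_tag == "a"], "primary")
  expect_equal(ind$indicator_class[ind$locus_tag == "b"], "primary")
  expect_equal(ind$indicator_class[ind$locus_tag == "c"], "secondary")

  ind2 <- find_indicator_genes(rec, indicator_table(chromosome_type = "secondary"))
  expect_equal(ind2$indicator_class[ind2$locus_tag == "c"], "primary")
})

test_that("score_igs reproduces the worked component values", {
  L <- 100000
  # maximal case: midpoint at the GC minimum, dnaA flank, 3 exact boxes
  seq1 <- paste0("CCGG", strrep(paste0("TTATCCACA", "CGGCC"), 3), "CCGG")
  igs1 <- mk_igs(seq1, start = 1000)
  ind1 <- mk_indicator(900, 1000)  # ends exactly at the IGS start
  c1 <- score_igs(igs1, gc_min_pos = igs1$midpoint, L = L,
                  topology = "circular", indicators = ind1)
  expect_equal(c1$s_dist, 1)
  expect_equal(c1$s_gene, 1)
  expect_equal(c1$s_box, 1)
  expect_equal(c1$total, 3)

  # partial case: d = L/4, no indicator, one box at one mismatch
  seq2 <- paste0(strrep("C", 20), "TTATGCACA", strrep("C", 20))
  igs2 <- mk_igs(seq2, start = 0)
  c2 <- score_igs(igs2, gc_min_pos = (igs2$midpoint + L / 4) %% L, L = L,
                  topology = "circular", indicators = NULL)
  expect_equal(c2$s_dist, 0.5)
  expect_equal(c2$s_gene, 0)
  expect_equal(c2$s_box, (1 / 2) / 3)
  expect_equal(c2$total, 0.5 + 1 / 6)

  # null case: no boxes, no indicator, antipodal midpoint
  igs3 <- mk_igs(strrep("C", 100), start = 0)
  c3 <- score_igs(igs3, gc_min_pos = (igs3$midpoint + L / 2) %% L, L = L,
                  topology = "circular", indicators = NULL)
  expect_equal(c3$total, 0)
})

test_that("secondary flank and proximity tiers score 0.75 and 0.5", {
  seqc <- strrep("C", 100)
  igs <- mk_igs(seqc, start = 5000)
  sec <- mk_indicator(4900, 5000, class = "secondary")
  cs <- score_igs(igs, gc_min_pos = igs$midpoint, L = 100000,
                  topology = "circular", indicators = sec)
  expect_equal(cs$s_gene, 0.75)

  near <- mk_indicator(8000, 9000)  # midpoint 8500, within 5 kb of the IGS
  cn <- score_igs(igs, gc_min_pos = igs$midpoint, L = 100000,
                  topology = "circular", indicators = near)
  expect_equal(cn$s_gene, 0.5)

  far <- mk_indicator(40000, 41000)
  cf <- score_igs(igs, gc_min_pos = igs$midpoint, L = 100000,
                  topology = "circular", indicators = far)
  expect_equal(cf$s_gene, 0)
})

test_that("score components stay bounded on random inputs", {
  set.seed(301)
  L <- 50000
  for (i in 1:20) {
    igs <- mk_igs(random_seq(sample(80:500, 1)),
                  start = sample(0:(L - 600), 1))
    ind <- if (runif(1) < 0.5) mk_indicator(1000, 1900) else NULL
    cs <- score_igs(igs, gc_min_pos = sample(0:L, 1), L = L,
                    topology = sample(c("circular", "linear"), 1),
                    indicators = ind)
    expect_true(cs$s_dist >= 0 && cs$s_dist <= 1)
    expect_true(cs$s_gene >= 0 && cs$s_gene <= 1)
    expect_true(cs$s_box >= 0 && cs$s_box <= 1)
    expect_true(cs$total >= 0 && cs$total <= 3)
  }
})

test_that("adding a box or approaching the GC minimum never lowers the score", {
  set.seed(302)
  L <- 50000
  for (i in 1:10) {
    s <- random_seq(200)
    igs_a <- mk_igs(s, start = 1000)
    igs_b <- mk_igs(paste0("TTATCCACA", s), start = 1000)
    igs_b$length <- igs_a$length; igs_b$midpoint <- igs_a$midpoint
    a <- score_igs(igs_a, 3000, L, "circular", NULL)
    b <- score_igs(igs_b, 3000, L, "circular", NULL)
    expect_gte(b$total, a$total)

    d1 <- sample(0:(L / 2), 1)
    d2 <- sample(0:d1, 1)  # closer
    s1 <- score_igs(igs_a, (igs_a$midpoint + d1) %% L, L, "circular", NULL)
    s2 <- score_igs(igs_a, (igs_a$midpoint + d2) %% L, L, "circular", NULL)
    expect_gte(s2$s_dist, s1$s_dist)
  }
})

test_that("rank_candidates orders by total then element screens", {
  mk <- function(total, trios = 0, gatc = 0, at = 0.5, start = 0) {
    structure(list(total = total, n_trios = trios, gatc_count = gatc,
                   at_frac = at, igs = list(start = start)),
              class = "candidate_score")
  }
  r <- rank_candidates(list(mk(1.4, start = 10), mk(2.1, start = 20)))
  expect_equal(r[[1]]$total, 2.1)

  r2 <- rank_candidates(list(mk(2, 0, start = 1), mk(2, 1, start = 2)))
  expect_equal(r2[[1]]$n_trios, 1)

  r3 <- rank_candidates(list(mk(2, 1, 5, start = 1), mk(2, 1, 9, start = 2)))
  expect_equal(r3[[1]]$gatc_count, 9)

  r4 <- rank_candidates(list(mk(2, at = 0.3, start = 1), mk(2, at = 0.9, start = 2)))
  expect_equal(r4[[1]]$at_frac, 0.9)

  r5 <- rank_candidates(list(mk(2, start = 500), mk(2, start = 100)))
  expect_equal(r5[[1]]$igs$start, 100)

  expect_warning(rank_candidates(list()), "no candidates")
})

test_that("predict_oric recovers a planted origin", {
  sim <- simulate_genome(sim_params(L = 100000, seed = 7))
  p <- predict_oric(sim$record)
  expect_s3_class(p, "oric_scan")
  top <- p$candidates[[p$predictions[1]]]
  expect_true(top$igs$start < sim$truth_oric["end"] &&
              top$igs$end > sim$truth_oric["start"])
  expect_equal(nrow(top$boxes[top$boxes$mismatches == 0 &
                              top$boxes$strand == "+", ]), 3)
  expect_gte(top$n_trios, 1)
  expect_equal(top$s_gene, 1)
})

test_that("tied identical candidates are both reported", {
  # two IGSs equidistant from the (flat-curve) GC minimum, both flanked
  # by the same dnaA gene, identical sequence content: an exact tie
  L <- 10000
  f <- data.frame(locus_tag = c("g1", "g2", "g3"),
                  gene_name = c("", "dnaA", ""), product = "",
                  start = c(0, 2100, 8100), end = c(1900, 7900, 10000),
                  strand = "+", kind = "CDS", stringsAsFactors = FALSE)
  rec <- genome_record("twin", strrep("A", L), topology = "circular",
                       features = f, source = "simulated")
  p <- predict_oric(rec)
  expect_equal(length(p$predictions), 2)
  starts <- sort(vapply(p$predictions, function(i)
    p$candidates[[i]]$igs$start, numeric(1)))
  expect_equal(starts, c(1900, 7900))
  tot <- vapply(p$predictions, function(i) p$candidates[[i]]$total,
                numeric(1))
  expect_equal(tot[1], tot[2])
  expect_equal(tot[1], 0.6 + 1)  # s_dist 0.6, dnaA flank 1, no boxes
})

test_that("a fully coding genome yields an empty prediction with warning", {
  rec <- toy_record(random_seq(500), list(c(0, 500)))
  expect_warning(p <- predict_oric(rec), "nothing to predict")
  expect_length(p$predictions, 0)
})

test_that("draft mode pools contigs and scores against per-contig minima", {
  sim <- simulate_genome(sim_params(L = 100000, seed = 11))
  p_full <- predict_oric(sim$record)
  top_full <- p_full$candidates[[p_full$predictions[1]]]

  ctgs <- split_genome_record(sim$record, c(33000, 66000))
  p_draft <- predict_oric_draft(ctgs)
  expect_true(p_draft$draft)
  top <- p_draft$candidates[[p_draft$predictions[1]]]
  expect_equal(top$igs$record_id, ctgs[[1]]$id)
  # contig 1 starts at genome position 0, so coordinates are comparable
  expect_true(top$igs$start < top_full$igs$end &&
              top$igs$end > top_full$igs$start)

  # the winning contig's s_dist uses its own GC minimum
  d1 <- disparity_curves(ctgs[[1]]$sequence)
  ex1 <- gc_extrema(d1, "linear")
  L1 <- nchar(ctgs[[1]]$sequence)
  expect_equal(top$s_dist,
               max(0, 1 - abs(top$igs$midpoint - ex1$min_pos) / (L1 / 2)))
})

test_that("draft winner comes from the contig holding boxes and indicator", {
  set.seed(303)
  empty_ctg <- toy_record(random_seq(5000), list(c(0, 2000), c(2400, 5000)),
                          id = "plain")
  seqc <- random_seq(5000)
  planted <- paste0(substr(seqc, 1, 2000),
                    "CC", strrep("TTATCCACACGCGG", 3), strrep("AT", 50),
                    substr(seqc, 2001 + 2 + 42 + 100, 5000))
  f <- data.frame(locus_tag = c("d", "x"), gene_name = c("dnaA", ""),
                  product = "", start = c(0, 2400), end = c(2000, 5000),
                  strand = "+", kind = "CDS", stringsAsFactors = FALSE)
  rich_ctg <- genome_record("rich", planted, features = f, source = "simulated")
  p <- predict_oric_draft(list(empty_ctg, rich_ctg))
  expect_equal(p$candidates[[p$predictions[1]]]$igs$record_id, "rich")
})

test_that("terminus prediction uses dif when configured, gc_max otherwise", {
  sim <- simulate_genome(sim_params(L = 100000, seed = 13, plant_dif = TRUE))
  cfg <- motif_config(dif = dif_ecoli)
  t1 <- predict_terminus(sim$record, cfg)
  expect_equal(t1$method, "dif")
  expect_lt(circular_distance(t1$position, sim$truth_ter, 100000, "circular"),
            nchar(dif_ecoli))

  t2 <- predict_terminus(sim$record, motif_config())
  expect_equal(t2$method, "gc_max")
  expect_lt(circular_distance(t2$position, sim$truth_ter, 100000, "circular"),
            2000)

  ctgs <- split_genome_record(sim$record, c(50000))
  expect_error(predict_terminus(ctgs, cfg), "complete genomes")
})
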