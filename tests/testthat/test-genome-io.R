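# FASTA/GenBank parsing, ORF fallback, IGS extraction.

write_tmp <- function(lines, ext = ".txt") {
  p <- tempfile(fileext = ext)
  writeLines(lines, p)
  p
}

test_that("read_fasta parses minimal, multi-record and wrapped input", {
  p <- write_tmp(c(">g1", "ACGT"), ".fasta")
  recs <- read_fasta(p)
  expect_length(recs, 1)
  expect_equal(recs[[1]]$sequence, "ACGT")
  expect_equal(nrow(recs[[1]]$features), 0)
  expect_equal(recs[[1]]$topology, "linear")

  p2 <- write_tmp(c(">a", "AC", ">b", "GT"), ".fasta")
  recs2 <- read_fasta(p2)
  expect_equal(vapply(recs2, `[[`, character(1), "id"), c("a", "b"))

  p3 <- write_tmp(c(">g", "ac", "gt"), ".fasta")
  expect_equal(read_fasta(p3)[[1]]$sequence, "ACGT")

  p4 <- write_tmp(c(">g", "ACGT"), ".fasta")
  expect_equal(read_fasta(p4, topology = "circular")[[1]]$topology, "circular")
})

test_that("read_fasta rejects empty files and names bad characters", {
  p <- tempfile(fileext = ".fasta")
  file.create(p)
  expect_error(read_fasta(p), "empty")
  expect_error(read_fasta(tempfile()), "not found")
  p2 <- write_tmp(c(">g", "ACXGT"), ".fasta")
  expect_error(read_fasta(p2), "'X'.*line 2")
})

gbk_lines <- function(feature_lines, seq = strrep("ACGT", 400),
                      topology = "circular") {
  L <- nchar(seq)
  origin <- vapply(seq(1, L, 60), function(s)
    sprintf("%9d %s", s, tolower(substr(seq, s, min(s + 59, L)))),
    character(1))
  c(sprintf("LOCUS       test_rec %d bp    DNA     %s BCT 01-JAN-2026",
            L, topology),
    "DEFINITION  toy record",
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", L),
    feature_lines, "ORIGIN", origin, "//")
}

test_that("read_genbank converts coordinates, strands and topology", {
  p <- write_tmp(gbk_lines(c(
    "     CDS             101..1402",
    "                     /locus_tag=\"t1\"",
    "                     /gene=\"dnaA\"",
    "                     /product=\"chromosomal replication initiator",
    "                     protein DnaA\"",
    "     CDS             complement(5..10)",
    "                     /locus_tag=\"t2\"")), ".gbk")
  rec <- read_genbank(p)[[1]]
  expect_equal(rec$topology, "circular")
  expect_equal(rec$id, "test_rec")
  f <- rec$features
  expect_equal(nrow(f), 2)
  minus <- f[f$locus_tag == "t2", ]
  plus <- f[f$locus_tag == "t1", ]
  expect_equal(c(plus$start, plus$end), c(100, 1402))
  expect_equal(plus$strand, "+")
  expect_equal(c(minus$start, minus$end), c(4, 10))
  expect_equal(minus$strand, "-")
  expect_match(plus$product, "protein DnaA")
})

test_that("read_genbank splits join() locations and drops bad coordinates", {
  p <- write_tmp(gbk_lines(c(
    "     CDS             join(1501..1590,1..30)",
    "                     /locus_tag=\"wrap\"",
    "     CDS             10..99999",
    "                     /locus_tag=\"bad\"")), ".gbk")
  expect_warning(rec <- read_genbank(p)[[1]], "dropped")
  f <- rec$features
  expect_equal(nrow(f), 2)  # join split into two segments, bad one dropped
  expect_setequal(f$start, c(1500, 0))
  expect_setequal(f$end, c(1590, 30))
  expect_false("bad" %in% f$locus_tag)
})

test_that("read_genbank requires an ORIGIN sequence", {
  p <- write_tmp(c("LOCUS       x 10 bp DNA linear", "FEATURES", "//"))
  expect_error(read_genbank(p), "ORIGIN")
})

test_that("GenBank writer round-trips simulated annotation", {
  sim <- simulate_genome(sim_params(L = 20000, seed = 5))
  p <- tempfile(fileext = ".gbk")
  write_genbank(sim$record, p)
  back <- read_genbank(p)[[1]]
  expect_equal(back$sequence, sim$record$sequence)
  expect_equal(back$topology, "circular")
  expect_equal(back$features$start, sim$record$features$start)
  expect_equal(back$features$end, sim$record$features$end)
  expect_equal(back$features$strand, sim$record$features$strand)
  expect_equal(back$features$gene_name, sim$record$features$gene_name)
})

test_that("ORF fallback finds constructed ORFs and matches the oracle", {
  orf <- paste0("ATG", strrep("GCA", 98), "TAA")  # 300 nt, no internal stops
  rec <- toy_record(orf)
  f <- find_orfs_fallback(rec, 300)
  expect_equal(nrow(f), 1)
  expect_equal(c(f$start, f$end), c(0, 300))
  expect_equal(f$strand, "+")

  expect_equal(nrow(find_orfs_fallback(toy_record(strrep("C", 400)), 300)), 0)

  rc <- oracle_revcomp(orf)
  f2 <- find_orfs_fallback(toy_record(rc), 300)
  expect_equal(nrow(f2), 1)
  expect_equal(f2$strand, "-")
  expect_equal(c(f2$start, f2$end), c(0, 300))

  set.seed(31)
  for (i in 1:5) {
    s <- random_seq(600)
    got <- find_orfs_fallback(toy_record(s), 120)
    want <- oracle_orfs(s, 120)
    expect_equal(got[, c("start", "end", "strand")], want,
                 ignore_attr = TRUE)
  }
})

test_that("extract_igs returns maximal feature-free intervals with flanks", {
  rec <- toy_record(random_seq(300), list(c(0, 100), c(200, 300)))
  g <- extract_igs(rec, min_len = 1)
  expect_equal(nrow(g), 1)
  expect_equal(c(g$start, g$end, g$length), c(100, 200, 100))
  expect_equal(g$left_idx, 1)
  expect_equal(g$right_idx, 2)
  expect_equal(g$sequence, substr(rec$sequence, 101, 200))

  # circular wrap-around gap
  set.seed(1)
  rec2 <- toy_record(random_seq(250), list(c(50, 100), c(150, 200)),
                     topology = "circular")
  g2 <- extract_igs(rec2, min_len = 1)
  expect_equal(nrow(g2), 2)
  inner <- g2[g2$start == 100, ]
  expect_equal(inner$end, 150)
  wrap <- g2[g2$start == 200, ]
  expect_equal(c(wrap$end, wrap$length), c(50, 100))
  expect_equal(wrap$sequence,
               paste0(substr(rec2$sequence, 201, 250),
                      substr(rec2$sequence, 1, 50)))

  # overlapping genes leave no gap
  rec3 <- toy_record(random_seq(300), list(c(0, 150), c(100, 300)))
  expect_equal(nrow(extract_igs(rec3, min_len = 1)), 0)

  # featureless record is one whole-sequence IGS
  rec4 <- toy_record(random_seq(500))
  g4 <- extract_igs(rec4, min_len = 1)
  expect_equal(c(g4$start, g4$end, g4$length), c(0, 500, 500))

  # min_len filter
  rec5 <- toy_record(random_seq(300), list(c(0, 100), c(150, 300)))
  expect_equal(nrow(extract_igs(rec5, min_len = 80)), 0)
  expect_equal(nrow(extract_igs(rec5, min_len = 50)), 1)
})

test_that("features plus IGSs tile the genome exactly once", {
  set.seed(7)
  for (topo in c("linear", "circular")) {
    L <- 2000
    genes <- list(c(100, 400), c(380, 700), c(900, 1200), c(1500, 1900))
    rec <- toy_record(random_seq(L), genes, topology = topo)
    g <- extract_igs(rec, min_len = 1)
    cov <- integer(L)
    for (i in seq_len(nrow(rec$features))) {
      idx <- (rec$features$start[i] + 1):rec$features$end[i]
      cov[idx] <- cov[idx] + 1
    }
    cov <- pmin(cov, 1)  # merged feature blocks count once
    for (i in seq_len(nrow(g))) {
      idx <- if (g$end[i] > g$start[i]) (g$start[i] + 1):g$end[i]
             else c((g$start[i] + 1):L, seq_len(g$end[i]))
      cov[idx] <- cov[idx] + 1
    }
    expect_true(all(cov == 1), info = topo)
  }
})

test_that("split_genome_record remaps features and drops straddlers", {
  rec <- toy_record(random_seq(1000), list(c(100, 300), c(450, 650), c(700, 900)))
  ctgs <- split_genome_record(rec, c(500))
  expect_length(ctgs, 2)
  expect_equal(nchar(ctgs[[1]]$sequence), 500)
  expect_equal(ctgs[[1]]$features$start, 100)   # straddler [450,650) dropped
  expect_equal(ctgs[[2]]$features$start, 200)   # 700 - 500
  expect_equal(paste0(ctgs[[1]]$sequence, ctgs[[2]]$sequence), rec$sequence)
})
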