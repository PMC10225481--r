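# Synthetic circular genomes with a planted oriC architecture.

#' Simulation parameters
#'
#' Describes a synthetic circular chromosome with a planted origin at
#' coordinate 0 and terminus at L/2. The defaults emulate a small
#' bacterial chromosome: GC skew of 0.04 (probability excess of G over C
#' on the leading strand) and TA skew 0.02, placeholder genes of 900 bp
#' separated by 150 bp intergenic gaps, and a planted oriC IGS carrying
#' three exact DnaA boxes, a GAT DnaA-trio run linked to a box, a 30 bp
#' AT-rich unwinding element (AT fraction 0.9) and an immediately
#' flanking dnaA gene.
#'
#' @param L Chromosome length (bp).
#' @param skew_gc Leading-strand G-over-C probability excess.
#' @param skew_ta Leading-strand T-over-A probability excess.
#' @param n_boxes Exact DnaA boxes planted in the oriC IGS.
#' @param include_trio Plant a GAT trio run (4 units) next to a box.
#' @param due_len Length of the AT-rich island (bp).
#' @param due_at AT fraction inside the island.
#' @param gene_len Placeholder gene length (bp).
#' @param igs_len Intergenic gap length (bp); also the planted oriC IGS
#'   length.
#' @param dnaa_adjacent Name the gene immediately downstream of the
#'   planted IGS `dnaA`.
#' @param plant_dif Overwrite the terminus with the E. coli dif site.
#' @param seed RNG seed; the genome is fully seed-deterministic.
#' @return Object of class `sim_params`.
#' @export
sim_params <- function(L = 200000, skew_gc = 0.04, skew_ta = 0.02,
                       n_boxes = 3, include_trio = TRUE, due_len = 30,
                       due_at = 0.9, gene_len = 900, igs_len = 150,
                       dnaa_adjacent = TRUE, plant_dif = FALSE, seed = 1) {
  p <- list(L = as.integer(L), skew_gc = skew_gc, skew_ta = skew_ta,
            n_boxes = as.integer(n_boxes), include_trio = include_trio,
            due_len = as.integer(due_len), due_at = due_at,
            gene_len = as.integer(gene_len), igs_len = as.integer(igs_len),
            dnaa_adjacent = dnaa_adjacent, plant_dif = plant_dif,
            seed = as.integer(seed))
  if (p$L < 10 * p$gene_len) stop("L must be >= 10 * gene_len", call. = FALSE)
  if (skew_gc < 0 || skew_gc >= 0.5 || skew_ta < 0 || skew_ta >= 0.5) {
    stop("skews must lie in [0, 0.5)", call. = FALSE)
  }
  planted <- 10 + p$n_boxes * 9 + max(0, p$n_boxes - 1) * 5 +
    (if (include_trio) 22 else 0) + p$due_len + 5
  if (planted > p$igs_len) {
    stop("infeasible packing: planted elements need ", planted,
         " bp but igs_len is ", p$igs_len, call. = FALSE)
  }
  structure(p, class = "sim_params")
}

#' Simulate a circular genome with a planted oriC
#'
#' Generates a seed-deterministic circular chromosome whose two
#' replichores carry opposite GC/TA composition skews (so the cumulative
#' GC disparity has its minimum at the planted origin, coordinate 0, and
#' its maximum at the planted terminus, L/2). Placeholder genes are tiled
#' around the chromosome with fixed intergenic gaps; the gap at the
#' origin is the planted oriC IGS and receives the configured DnaA
#' boxes, DnaA-trio run, and AT-rich island. The sequence is resampled
#' (same layout) in the rare event that background sequence creates a
#' spurious exact DnaA box inside the planted IGS, so the truth interval
#' contains exactly `n_boxes` forward exact boxes.
#'
#' @param params A [sim_params()] object.
#' @return Object of class `simulated_genome`: `record` (a
#'   [genome_record], source `"simulated"`), `truth_oric` (0-based
#'   half-open interval), `truth_ter` (position), `params`.
#' @examples
#' sim <- simulate_genome(sim_params(L = 20000, seed = 1))
#' sim$truth_oric
#' @export
simulate_genome <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  with_seed(params$seed, simulate_genome_impl(params))
}

simulate_genome_impl <- function(p) {
  L <- p$L
  half <- L %/% 2
  bases <- c("A", "C", "G", "T")
  # forward-strand base probabilities per replichore: the forward strand
  # is the leading strand on arc 1 (ori -> ter), lagging on arc 2
  p1 <- c(A = 0.25 - p$skew_ta / 2, C = 0.25 - p$skew_gc / 2,
          G = 0.25 + p$skew_gc / 2, T = 0.25 + p$skew_ta / 2)
  p2 <- c(A = 0.25 + p$skew_ta / 2, C = 0.25 + p$skew_gc / 2,
          G = 0.25 - p$skew_gc / 2, T = 0.25 - p$skew_ta / 2)

  # gene layout: planted IGS [0, igs_len), then genes separated by
  # igs_len gaps; the final gene is stretched to end exactly at L so the
  # planted IGS is the only origin-spanning gap
  unit <- p$gene_len + p$igs_len
  starts <- seq.int(p$igs_len, L - p$gene_len, by = unit)
  ends <- starts + p$gene_len
  ends[length(ends)] <- L
  n_genes <- length(starts)
  strands <- sample(c("+", "-"), n_genes, replace = TRUE)
  gene_name <- rep("", n_genes)
  product <- rep("hypothetical protein", n_genes)
  if (p$dnaa_adjacent) {
    gene_name[1] <- "dnaA"
    product[1] <- "chromosomal replication initiator protein DnaA"
    strands[1] <- "+"
  }
  features <- data.frame(
    locus_tag = sprintf("SIM_%04d", seq_len(n_genes)),
    gene_name = gene_name, product = product,
    start = as.integer(starts), end = as.integer(ends),
    strand = strands, kind = "CDS", stringsAsFactors = FALSE)

  planted <- planted_igs_seq(p)
  box <- "TTATCCACA"
  for (attempt in 1:25) {
    seq_vec <- c(sample(bases, half, replace = TRUE, prob = p1),
                 sample(bases, L - half, replace = TRUE, prob = p2))
    seq_vec[seq_len(p$igs_len)] <- planted$chars
    sequence <- paste(seq_vec, collapse = "")
    igs_seq <- substr(sequence, 1, p$igs_len)
    n_fwd <- nrow(scan_iupac(igs_seq, motif_pattern("box", box), 0, "plus"))
    if (n_fwd == p$n_boxes) break
    if (attempt == 25) {
      stop("could not realize exactly n_boxes planted DnaA boxes", call. = FALSE)
    }
  }
  if (p$plant_dif) {
    dif <- dif_ecoli
    substr(sequence, half + 1 - nchar(dif) %/% 2,
           half - nchar(dif) %/% 2 + nchar(dif)) <- dif
  }
  rec <- genome_record(id = sprintf("sim_seed%d", p$seed),
                       sequence = sequence,
                       description = sprintf(
                         "simulated circular genome, L=%d, planted oriC [0,%d)",
                         L, p$igs_len),
                       topology = "circular", features = features,
                       source = "simulated")
  structure(list(record = rec,
                 truth_oric = c(start = 0L, end = p$igs_len),
                 truth_ter = half, params = p),
            class = "simulated_genome")
}

# fixed part of the planted oriC IGS (boxes, trio, DUE) plus random filler
planted_igs_seq <- function(p) {
  box <- "TTATCCACA"
  bases <- c("A", "C", "G", "T")
  rand <- function(n) if (n > 0) sample(bases, n, replace = TRUE) else character(0)
  out <- rand(10)
  for (b in seq_len(p$n_boxes)) {
    out <- c(out, strsplit(box, "")[[1]])
    if (b < p$n_boxes) out <- c(out, rand(5))
  }
  if (p$include_trio) {
    # 10 bp gap after the last box (within box-linkage range), 4 GAT units
    out <- c(out, rand(10), strsplit("GATGATGATGAT", "")[[1]])
  }
  due <- sample(c("A", "T", "G", "C"), p$due_len, replace = TRUE,
                prob = c(p$due_at / 2, p$due_at / 2,
                         (1 - p$due_at) / 2, (1 - p$due_at) / 2))
  out <- c(out, rand(5), due)
  if (length(out) > p$igs_len) stop("infeasible packing", call. = FALSE)
  out <- c(out, rand(p$igs_len - length(out)))
  list(chars = out)
}

#' @export
print.simulated_genome <- function(x, ...) {
  cat(sprintf("<simulated_genome> seed %d\n", x$params$seed))
  print(x$record)
  cat(sprintf("  truth: oriC [%d, %d), terminus %s\n",
              x$truth_oric["start"], x$truth_oric["end"],
              format(x$truth_ter, big.mark = ",")))
  invisible(x)
}

#' Write a fixture set for simulated genomes
#'
#' For each simulated genome, writes a FASTA file, a GenBank flat file
#' (re-readable with [read_genbank()]), and a TSV with the planted truth
#' (oriC interval and terminus), all named after the record id.
#'
#' @param genomes A `simulated_genome` or list of them.
#' @param dir Output directory (created if needed).
#' @return Character vector of file paths, invisibly.
#' @export
write_fixture_set <- function(genomes, dir) {
  if (inherits(genomes, "simulated_genome")) genomes <- list(genomes)
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory ", dir, call. = FALSE)
  }
  paths <- character(0)
  for (g in genomes) {
    stopifnot(inherits(g, "simulated_genome"))
    base <- file.path(dir, g$record$id)
    fa <- paste0(base, ".fasta")
    set <- Biostrings::DNAStringSet(g$record$sequence)
    names(set) <- paste(g$record$id, g$record$description)
    Biostrings::writeXStringSet(set, fa)
    gb <- paste0(base, ".gbk")
    write_genbank(g$record, gb)
    tr <- paste0(base, "_truth.tsv")
    utils::write.table(
      data.frame(record_id = g$record$id,
                 oric_start = g$truth_oric["start"],
                 oric_end = g$truth_oric["end"],
                 ter = g$truth_ter, seed = g$params$seed),
      tr, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, fa, gb, tr)
  }
  invisible(paths)
}

#' Write a genome record as a GenBank flat file
#'
#' Minimal writer covering what [read_genbank()] parses: LOCUS with
#' topology, DEFINITION, CDS features with locus_tag/gene/product
#' qualifiers, and the ORIGIN sequence block.
#'
#' @param record A [genome_record].
#' @param path Output file.
#' @return Invisibly, the path.
#' @export
write_genbank <- function(record, path) {
  stopifnot(inherits(record, "genome_record"))
  L <- nchar(record$sequence)
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(sprintf(...), con)
  wl("LOCUS       %s %d bp    DNA     %s BCT 01-JAN-2026",
     record$id, L, record$topology)
  wl("DEFINITION  %s", if (nzchar(record$description)) record$description else record$id)
  wl("FEATURES             Location/Qualifiers")
  wl("     source          1..%d", L)
  f <- record$features
  for (i in seq_len(nrow(f))) {
    loc <- sprintf("%d..%d", f$start[i] + 1, f$end[i])
    if (f$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
    wl("     CDS             %s", loc)
    if (nzchar(f$locus_tag[i])) wl("                     /locus_tag=\"%s\"", f$locus_tag[i])
    if (nzchar(f$gene_name[i])) wl("                     /gene=\"%s\"", f$gene_name[i])
    if (nzchar(f$product[i]))   wl("                     /product=\"%s\"", f$product[i])
  }
  wl("ORIGIN")
  pos <- seq(1, L, by = 60)
  for (s in pos) {
    chunk <- substr(record$sequence, s, min(s + 59, L))
    groups <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    wl("%9d %s", s, tolower(paste(groups, collapse = " ")))
  }
  wl("//")
  invisible(path)
}
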