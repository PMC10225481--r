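# Replichore partitioning and leading/lagging strand-bias statistics.

#' Partition a circular chromosome into replichores
#'
#' Given the oriC and terminus positions, the chromosome splits into two
#' arcs replicated by the two forks: arc 1 runs from oriC to terminus in
#' the direction of increasing coordinates (modulo L), arc 2 is its
#' complement. The arc lengths are what this package reports as the
#' "lengths of the leading and lagging strands" (the replichore-arc
#' interpretation; on the forward strand, arc 1 is the leading template
#' of one fork).
#'
#' @param oric_pos oriC position (midpoint), 0-based.
#' @param ter_pos Terminus position, 0-based.
#' @param L Chromosome length (bp).
#' @param topology Must be `"circular"`; replichores are undefined for
#'   linear fragments.
#' @return Object of class `replichore_partition` with `arc1`/`arc2`
#'   (0-based half-open, modulo L) and their percentage lengths.
#' @export
partition_replichores <- function(oric_pos, ter_pos, L,
                                  topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  if (topology != "circular") {
    stop("replichore partitioning requires a circular genome", call. = FALSE)
  }
  oric_pos <- oric_pos %% L
  ter_pos <- ter_pos %% L
  if (oric_pos == ter_pos) stop("oriC and terminus coincide", call. = FALSE)
  len1 <- (ter_pos - oric_pos) %% L
  structure(list(L = L, oric_pos = oric_pos, ter_pos = ter_pos,
                 arc1 = c(start = oric_pos, end = ter_pos),
                 arc2 = c(start = ter_pos, end = oric_pos),
                 arc1_len = len1, arc2_len = L - len1,
                 arc1_frac = 100 * len1 / L,
                 arc2_frac = 100 * (L - len1) / L),
            class = "replichore_partition")
}

#' @export
print.replichore_partition <- function(x, ...) {
  cat(sprintf("<replichore_partition> L = %s bp\n", format(x$L, big.mark = ",")))
  cat(sprintf("  oriC %s -> ter %s: arc1 %s bp (%.2f%%), arc2 %s bp (%.2f%%)\n",
              format(x$oric_pos + 1, big.mark = ","),
              format(x$ter_pos + 1, big.mark = ","),
              format(x$arc1_len, big.mark = ","), x$arc1_frac,
              format(x$arc2_len, big.mark = ","), x$arc2_frac))
  invisible(x)
}

in_arc <- function(pos, arc, L) {
  p <- pos %% L
  s <- arc["start"]; e <- arc["end"]
  if (s < e) p >= s & p < e else p >= s | p < e
}

#' Leading/lagging gene-orientation bias
#'
#' A gene is on the leading strand when it is transcribed co-directionally
#' with the replication fork: plus-strand genes on arc 1, minus-strand
#' genes on arc 2. Genes straddling the oriC or terminus boundary are
#' classified by their midpoint.
#'
#' @param features Feature data frame with `start`, `end`, `strand` (and
#'   `kind`).
#' @param partition A [partition_replichores()] result.
#' @param coding_only Count only `CDS`/`ORF_fallback` features (default).
#' @return List: `leading`, `lagging` counts and `leading_frac`,
#'   `lagging_frac` percentages.
#' @export
gene_strand_bias <- function(features, partition, coding_only = TRUE) {
  stopifnot(inherits(partition, "replichore_partition"))
  f <- features
  if (coding_only && nrow(f) > 0 && "kind" %in% names(f)) {
    f <- f[f$kind %in% c("CDS", "ORF_fallback"), , drop = FALSE]
  }
  if (nrow(f) == 0) {
    return(list(leading = 0L, lagging = 0L,
                leading_frac = NA_real_, lagging_frac = NA_real_))
  }
  mid <- ((f$start + f$end) / 2) %% partition$L
  a1 <- in_arc(mid, partition$arc1, partition$L)
  leading <- sum((a1 & f$strand == "+") | (!a1 & f$strand == "-"))
  lagging <- nrow(f) - leading
  list(leading = leading, lagging = lagging,
       leading_frac = 100 * leading / nrow(f),
       lagging_frac = 100 * lagging / nrow(f))
}

count_bases <- function(seqc) {
  x <- utf8ToInt(seqc)
  c(A = sum(x == 65L), T = sum(x == 84L), G = sum(x == 71L),
    C = sum(x == 67L))
}

#' Leading/lagging strand base composition
#'
#' The leading strand is reconstructed as the forward-strand bases of
#' arc 1 concatenated with the reverse complement of arc 2; the lagging
#' strand is the complementary selection. Percentages are over A/T/G/C
#' only (N excluded).
#'
#' @param sequence Chromosome sequence.
#' @param partition A [partition_replichores()] result.
#' @return List with `leading` and `lagging`, each a named percentage
#'   vector (A, T, G, C), plus raw `leading_counts`/`lagging_counts`.
#' @export
base_strand_bias <- function(sequence, partition) {
  stopifnot(inherits(partition, "replichore_partition"))
  L <- partition$L
  stopifnot(nchar(sequence) == L)
  arc_seq <- function(arc) {
    s <- arc["start"]; e <- arc["end"]
    if (s < e) substr(sequence, s + 1, e)
    else paste0(substr(sequence, s + 1, L), substr(sequence, 1, e))
  }
  a1 <- arc_seq(partition$arc1)
  a2 <- arc_seq(partition$arc2)
  leading <- count_bases(a1) + count_bases(revcomp(a2))
  lagging <- count_bases(revcomp(a1)) + count_bases(a2)
  list(leading = 100 * leading / sum(leading),
       lagging = 100 * lagging / sum(lagging),
       leading_counts = leading, lagging_counts = lagging)
}

#' Full strand-bias report for a complete genome
#'
#' Convenience wrapper: partitions the replichores and computes both the
#' gene-orientation and base-composition biases.
#'
#' @param record A circular [genome_record].
#' @param oric_pos,ter_pos oriC and terminus positions (0-based).
#' @param coding_only Passed to [gene_strand_bias()].
#' @return Object of class `strand_bias_report`.
#' @examples
#' sim <- simulate_genome(sim_params(L = 50000, seed = 3))
#' strand_bias_report(sim$record, oric_pos = 75, ter_pos = 25000)
#' @export
strand_bias_report <- function(record, oric_pos, ter_pos,
                               coding_only = TRUE) {
  stopifnot(inherits(record, "genome_record"))
  part <- partition_replichores(oric_pos, ter_pos, nchar(record$sequence),
                                record$topology)
  genes <- gene_strand_bias(record$features, part, coding_only)
  bases <- base_strand_bias(record$sequence, part)
  structure(list(partition = part, genes = genes, bases = bases),
            class = "strand_bias_report")
}

#' @export
print.strand_bias_report <- function(x, ...) {
  print(x$partition)
  g <- x$genes
  cat(sprintf("  genes: leading %d (%.2f%%), lagging %d (%.2f%%)\n",
              g$leading, g$leading_frac, g$lagging, g$lagging_frac))
  cat(sprintf("  leading strand bases: A %.2f%%  T %.2f%%  G %.2f%%  C %.2f%%\n",
              x$bases$leading["A"], x$bases$leading["T"],
              x$bases$leading["G"], x$bases$leading["C"]))
  cat(sprintf("  lagging strand bases: A %.2f%%  T %.2f%%  G %.2f%%  C %.2f%%\n",
              x$bases$lagging["A"], x$bases$lagging["T"],
              x$bases$lagging["G"], x$bases$lagging["C"]))
  invisible(x)
}
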