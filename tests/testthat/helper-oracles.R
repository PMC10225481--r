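# Independent brute-force oracles and small construction helpers.
# These deliberately avoid the package's scanning/ORF code paths.

`%||%` <- function(a, b) if (is.null(a)) b else a

ORACLE_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N",
            R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
            B = "V", D = "H", H = "D", V = "B")
  paste(rev(unname(comp[strsplit(s, "")[[1]]])), collapse = "")
}

# mismatches of one window vs an IUPAC pattern; N in the pattern matches
# anything, N in the window mismatches every non-N pattern symbol
oracle_mm <- function(window, pattern) {
  w <- strsplit(window, "")[[1]]
  p <- strsplit(pattern, "")[[1]]
  sum(vapply(seq_along(p), function(i) {
    if (p[i] == "N") return(FALSE)
    !(w[i] %in% ORACLE_SETS[[p[i]]])
  }, logical(1)))
}

# exhaustive position-by-position scanner, both strands
oracle_scan <- function(sequence, pattern, max_mm = 0, strands = "both") {
  k <- nchar(pattern)
  L <- nchar(sequence)
  rows <- list()
  if (k <= L) {
    pats <- list(`+` = pattern, `-` = oracle_revcomp(pattern))
    use <- if (strands == "both") c("+", "-") else "+"
    for (pos in 0:(L - k)) {
      win <- substr(sequence, pos + 1, pos + k)
      for (st in use) {
        mm <- oracle_mm(win, pats[[st]])
        if (mm <= max_mm) {
          rows[[length(rows) + 1]] <- data.frame(
            start = pos, strand = st, mismatches = mm,
            matched_seq = if (st == "+") win else oracle_revcomp(win),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(start = integer(0), strand = character(0),
                      mismatches = integer(0), matched_seq = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

random_seq <- function(n, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

random_iupac_pattern <- function(n) {
  # mostly plain bases with some degenerate symbols sprinkled in
  syms <- c(rep(c("A", "C", "G", "T"), 5), "N", "R", "Y", "W", "S")
  paste(sample(syms, n, replace = TRUE), collapse = "")
}

# brute-force six-frame ORF enumeration (longest ORF per stop codon)
oracle_orfs <- function(sequence, min_len = 300) {
  L <- nchar(sequence)
  res <- list()
  for (strand in c("+", "-")) {
    sq <- if (strand == "+") sequence else oracle_revcomp(sequence)
    for (frame in 0:2) {
      i <- frame + 1
      codons <- character(0)
      pos <- integer(0)
      while (i + 2 <= L) {
        codons <- c(codons, substr(sq, i, i + 2))
        pos <- c(pos, i)
        i <- i + 3
      }
      last_stop <- 0
      for (j in seq_along(codons)) {
        if (codons[j] %in% c("TAA", "TAG", "TGA")) {
          starts <- which(codons %in% c("ATG", "GTG", "TTG"))
          starts <- starts[starts > last_stop & starts < j]
          if (length(starts) > 0) {
            a <- min(starts)
            len <- (j - a + 1) * 3
            if (len >= min_len) {
              p1 <- pos[a]; p2 <- pos[j] + 2
              if (strand == "+") iv <- c(p1 - 1, p2)
              else iv <- c(L - p2, L - p1 + 1)
              res[[length(res) + 1]] <- data.frame(
                start = iv[1], end = iv[2], strand = strand,
                stringsAsFactors = FALSE)
            }
          }
          last_stop <- j
        }
      }
    }
  }
  if (length(res) == 0) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  out[order(out$start, out$end), , drop = FALSE]
}

# minimal hand-built record: genes given as list(c(start, end, strand))
toy_record <- function(sequence, genes = list(), topology = "linear",
                       id = "toy", names = NULL) {
  n <- length(genes)
  f <- data.frame(
    locus_tag = sprintf("g%02d", seq_len(max(n, 0))),
    gene_name = if (is.null(names)) rep("", n) else names,
    product = rep("", n),
    start = vapply(genes, function(g) as.integer(g[1]), integer(1)),
    end = vapply(genes, function(g) as.integer(g[2]), integer(1)),
    strand = vapply(genes, function(g)
      if (length(g) >= 3 && g[3] == -1) "-" else "+", character(1)),
    kind = rep("CDS", n), stringsAsFactors = FALSE)
  if (n == 0) f <- NULL
  genome_record(id, sequence, topology = topology, features = f,
                source = "simulated")
}
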