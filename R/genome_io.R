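# Genome input: FASTA and GenBank flat files, ORF fallback, IGS extraction.

#' Read a FASTA file into genome records
#'
#' Multi-record, wrapped and case-insensitive FASTA is accepted. FASTA files
#' carry no annotation, so the returned records have empty feature tables;
#' run [find_orfs_fallback()] to delimit intergenic sequences on them.
#'
#' @param path Path to a FASTA file.
#' @param topology Topology assigned to every record; FASTA has no topology
#'   field, so the default is `"linear"` (override for complete circular
#'   chromosomes).
#' @return List of [genome_record] objects, input order preserved.
#' @seealso [read_genbank()] for annotated input.
#' @export
read_fasta <- function(path, topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  if (file.size(path) == 0) stop("empty FASTA file: ", path, call. = FALSE)
  validate_fasta_alphabet(path)
  set <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) diagnose_fasta(path, conditionMessage(e))
  )
  if (length(set) == 0) stop("no FASTA records in ", path, call. = FALSE)
  headers <- names(set)
  lapply(seq_along(set), function(i) {
    h <- strsplit(headers[i], "\\s+")[[1]]
    genome_record(id = h[1],
                  sequence = as.character(set[[i]]),
                  description = trimws(sub("^\\S+\\s*", "", headers[i])),
                  topology = topology, source = "fasta")
  })
}

# reject non-IUPAC sequence characters up front, naming the character and
# line (readDNAStringSet would silently drop them)
validate_fasta_alphabet <- function(path) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (startsWith(ln, ">") || !nzchar(trimws(ln))) next
    chars <- unique(strsplit(toupper(gsub("[\\s-]", "", ln, perl = TRUE)),
                             "")[[1]])
    bad <- setdiff(chars, IUPAC_CHARS)
    if (length(bad) > 0) {
      stop(sprintf("invalid non-IUPAC character '%s' on line %d of %s",
                   bad[1], i, path), call. = FALSE)
    }
  }
  invisible(TRUE)
}

diagnose_fasta <- function(path, orig_msg) {
  stop("cannot parse FASTA file ", path, ": ", orig_msg, call. = FALSE)
}

#' Read a GenBank flat file into genome records
#'
#' Minimal parser for LOCUS / DEFINITION / FEATURES / ORIGIN blocks. `CDS`
#' and `gene` features are extracted with their `locus_tag`, `gene` and
#' `product` qualifiers; GenBank 1-based inclusive locations are converted
#' to the 0-based half-open convention used internally. `complement()`
#' locations set the minus strand and `join()` locations are split into one
#' feature per segment (which also handles origin-spanning features on
#' circular replicons). Topology is taken from the LOCUS line.
#'
#' @param path Path to a GenBank flat file (one or more records).
#' @return List of [genome_record] objects.
#' @export
read_genbank <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (!any(startsWith(lines, "LOCUS"))) {
    stop("not a GenBank flat file (no LOCUS line): ", path, call. = FALSE)
  }
  # split records on the // terminator
  ends <- c(which(trimws(lines) == "//"), if (trimws(lines[length(lines)]) != "//") length(lines))
  starts <- c(1, head(ends, -1) + 1)
  recs <- list()
  for (k in seq_along(starts)) {
    chunk <- lines[starts[k]:ends[k]]
    if (!any(startsWith(chunk, "LOCUS"))) next
    recs[[length(recs) + 1]] <- parse_genbank_record(chunk)
  }
  if (length(recs) == 0) stop("no GenBank records in ", path, call. = FALSE)
  recs
}

parse_genbank_record <- function(lines) {
  locus <- lines[startsWith(lines, "LOCUS")][1]
  toks <- strsplit(trimws(locus), "\\s+")[[1]]
  id <- if (length(toks) >= 2) toks[2] else "unknown"
  topology <- if (grepl("circular", locus, ignore.case = TRUE)) "circular" else "linear"
  def <- lines[startsWith(lines, "DEFINITION")]
  description <- if (length(def)) trimws(sub("^DEFINITION", "", def[1])) else ""

  oi <- which(startsWith(lines, "ORIGIN"))
  if (length(oi) == 0) stop("GenBank record without ORIGIN sequence", call. = FALSE)
  seq_lines <- lines[(oi[1] + 1):length(lines)]
  seq_lines <- seq_lines[trimws(seq_lines) != "//"]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!nzchar(sequence)) stop("GenBank record without ORIGIN sequence", call. = FALSE)
  L <- nchar(sequence)

  fi <- which(startsWith(lines, "FEATURES"))
  features <- feature_df()
  if (length(fi) > 0) {
    fl <- lines[(fi[1] + 1):(oi[1] - 1)]
    features <- parse_genbank_features(fl, L)
  }
  genome_record(id = id, sequence = sequence, description = description,
                topology = topology, features = features, source = "genbank")
}

parse_genbank_features <- function(fl, L) {
  key_re <- "^ {5}(\\S+) +(\\S.*)$"
  is_key <- grepl(key_re, fl)
  idx <- which(is_key)
  out <- list()
  for (j in seq_along(idx)) {
    first <- idx[j]
    last <- if (j < length(idx)) idx[j + 1] - 1 else length(fl)
    key <- sub(key_re, "\\1", fl[first])
    if (!key %in% c("CDS", "gene")) next
    body <- trimws(fl[first:last])
    body[1] <- sub(key_re, "\\2", fl[first])
    # location may wrap onto continuation lines until the first qualifier
    qstart <- which(startsWith(body, "/"))[1]
    loc_lines <- if (is.na(qstart)) body else body[seq_len(qstart - 1)]
    loc <- gsub("\\s", "", paste(loc_lines, collapse = ""))
    quals <- parse_qualifiers(if (is.na(qstart)) character(0) else body[qstart:length(body)])
    segs <- parse_location(loc)
    if (is.null(segs)) next
    for (s in seq_len(nrow(segs))) {
      out[[length(out) + 1]] <- data.frame(
        locus_tag = quals[["locus_tag"]] %||% "",
        gene_name = quals[["gene"]] %||% "",
        product = quals[["product"]] %||% "",
        start = segs$start[s], end = segs$end[s],
        strand = segs$strand[s], kind = key, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) return(feature_df())
  validate_features(do.call(rbind, out), L, what = "GenBank feature")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_qualifiers <- function(lines) {
  if (length(lines) == 0) return(list())
  # re-join wrapped qualifier values
  joined <- character(0)
  for (ln in lines) {
    if (startsWith(ln, "/")) joined <- c(joined, ln)
    else if (length(joined)) joined[length(joined)] <- paste(joined[length(joined)], ln)
  }
  quals <- list()
  for (q in joined) {
    m <- regmatches(q, regexec('^/([A-Za-z_]+)=?"?([^"]*)"?$', q))[[1]]
    if (length(m) == 3) quals[[m[2]]] <- m[3]
  }
  quals
}

# GenBank location string -> data.frame(start, end, strand), 0-based half-open
parse_location <- function(loc) {
  strand <- "+"
  if (startsWith(loc, "complement(")) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (startsWith(loc, "join(") || startsWith(loc, "order(")) {
    loc <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
  }
  parts <- strsplit(loc, ",", fixed = TRUE)[[1]]
  starts <- ends <- integer(0)
  for (p in parts) {
    p <- gsub("[<>]", "", p)
    if (grepl("^complement\\(", p)) {
      strand <- "-"
      p <- sub("^complement\\((.*)\\)$", "\\1", p)
    }
    if (grepl("^\\d+\\.\\.\\d+$", p)) {
      ab <- as.integer(strsplit(p, "..", fixed = TRUE)[[1]])
    } else if (grepl("^\\d+$", p)) {
      ab <- c(as.integer(p), as.integer(p))
    } else {
      return(NULL)  # unsupported location form
    }
    starts <- c(starts, ab[1] - 1L)
    ends <- c(ends, ab[2])
  }
  data.frame(start = starts, end = ends, strand = strand,
             stringsAsFactors = FALSE)
}

#' Six-frame ORF finder fallback for unannotated genomes
#'
#' Crude stand-in for a dedicated gene finder, used only to delimit
#' intergenic sequences when no annotation is available: open reading
#' frames from an ATG/GTG/TTG start codon to the next in-frame stop
#' (standard genetic code), on both strands in all six frames. Only the
#' longest ORF per stop codon is kept (non-nested) and ORFs shorter than
#' `min_len` are discarded.
#'
#' @param record A [genome_record] without features.
#' @param min_len Minimum ORF length in nucleotides, start through stop
#'   codon inclusive (default 300).
#' @return Feature data frame of kind `"ORF_fallback"`, sorted by start.
#' @export
find_orfs_fallback <- function(record, min_len = 300) {
  stopifnot(inherits(record, "genome_record"), min_len >= 60)
  s <- record$sequence
  L <- nchar(s)
  out <- list()
  for (strand in c("+", "-")) {
    sq <- if (strand == "+") s else revcomp(s)
    for (frame in 0:2) {
      n_codons <- (L - frame) %/% 3
      if (n_codons < 2) next
      cs <- frame + 1 + 3 * (seq_len(n_codons) - 1)
      codons <- substring(sq, cs, cs + 2)
      is_stop <- codons %in% c("TAA", "TAG", "TGA")
      is_start <- codons %in% c("ATG", "GTG", "TTG")
      stop_idx <- which(is_stop)
      prev_stop <- 0L
      for (st in stop_idx) {
        # first (leftmost) start since the previous stop -> longest ORF
        cand <- which(is_start[(prev_stop + 1):(st - 1)])
        if (st - prev_stop > 1 && length(cand) > 0) {
          a <- prev_stop + cand[1]
          len <- (st - a + 1L) * 3L
          if (len >= min_len) {
            p1 <- cs[a]             # 1-based start of start codon on sq
            p2 <- cs[st] + 2L       # 1-based end of stop codon on sq
            if (strand == "+") {
              fs <- p1 - 1L; fe <- p2
            } else {
              fs <- L - p2; fe <- L - p1 + 1L
            }
            out[[length(out) + 1]] <- c(fs, fe, strand)
          }
        }
        prev_stop <- st
      }
    }
  }
  if (length(out) == 0) return(feature_df())
  m <- do.call(rbind, out)
  feats <- data.frame(
    locus_tag = sprintf("orf_%04d", seq_len(nrow(m))),
    gene_name = "", product = "",
    start = as.integer(m[, 1]), end = as.integer(m[, 2]),
    strand = m[, 3], kind = "ORF_fallback", stringsAsFactors = FALSE)
  feats <- feats[order(feats$start, feats$end), , drop = FALSE]
  feats$locus_tag <- sprintf("orf_%04d", seq_len(nrow(feats)))
  rownames(feats) <- NULL
  feats
}

#' Split a genome record into contigs
#'
#' Cuts a record at the given breakpoints into linear contig records
#' (emulating a draft assembly of a complete genome). Features fully
#' inside a contig are remapped to contig coordinates; features
#' straddling a breakpoint are dropped, as they would be broken in a
#' real assembly.
#'
#' @param record A [genome_record].
#' @param breakpoints Increasing 0-based cut positions in `(0, L)`.
#' @return List of linear [genome_record] contigs covering the sequence
#'   from position 0, in order.
#' @export
split_genome_record <- function(record, breakpoints) {
  stopifnot(inherits(record, "genome_record"))
  L <- nchar(record$sequence)
  breakpoints <- sort(unique(as.integer(breakpoints)))
  stopifnot(all(breakpoints > 0 & breakpoints < L))
  bounds <- c(0L, breakpoints, L)
  lapply(seq_len(length(bounds) - 1), function(i) {
    a <- bounds[i]; b <- bounds[i + 1]
    f <- record$features
    f <- f[f$start >= a & f$end <= b, , drop = FALSE]
    f$start <- f$start - a
    f$end <- f$end - a
    genome_record(id = sprintf("%s_ctg%d", record$id, i),
                  sequence = substr(record$sequence, a + 1, b),
                  description = sprintf("%s contig %d [%d,%d)", record$id, i, a, b),
                  topology = "linear", features = f, source = record$source)
  })
}

#' Extract intergenic sequences (IGSs)
#'
#' Returns every maximal feature-free interval of at least `min_len` bp.
#' On circular records the gap spanning the coordinate origin is returned
#' as a single wrap-around IGS (with `end < start`, interpreted modulo the
#' genome length). The nearest flanking gene on each side is attached. A
#' record without any feature yields one IGS covering the whole sequence.
#'
#' @param record A [genome_record].
#' @param min_len Minimum IGS length in bp (default 80).
#' @return Data frame with columns `record_id`, `start`, `end`, `length`,
#'   `midpoint`, `sequence`, `left_idx`, `right_idx` (row indices into
#'   `record$features`, `NA` when absent). Coordinates 0-based half-open.
#' @export
extract_igs <- function(record, min_len = 80) {
  stopifnot(inherits(record, "genome_record"), min_len >= 1)
  L <- nchar(record$sequence)
  f <- record$features
  igs_row <- function(start, end) {
    len <- if (end > start) end - start else (end - start) %% L
    if (len == 0) len <- L  # whole-genome gap
    seq <- if (end > start) substr(record$sequence, start + 1, end)
           else paste0(substr(record$sequence, start + 1, L),
                       substr(record$sequence, 1, end))
    data.frame(record_id = record$id, start = start, end = end,
               length = len, midpoint = (start + len / 2) %% L,
               sequence = seq, left_idx = NA_integer_,
               right_idx = NA_integer_, stringsAsFactors = FALSE)
  }
  if (nrow(f) == 0) {
    g <- igs_row(0L, L)
    return(g[g$length >= min_len, , drop = FALSE])
  }
  # merge feature intervals
  o <- order(f$start, f$end)
  ms <- me <- integer(0)
  for (i in o) {
    if (length(ms) > 0 && f$start[i] <= me[length(me)]) {
      me[length(me)] <- max(me[length(me)], f$end[i])
    } else {
      ms <- c(ms, f$start[i]); me <- c(me, f$end[i])
    }
  }
  gaps <- list()
  if (record$topology == "circular") {
    # gaps between consecutive merged blocks, plus the wrap-around gap
    n <- length(ms)
    for (i in seq_len(n - 1)) {
      if (ms[i + 1] > me[i]) gaps[[length(gaps) + 1]] <- c(me[i], ms[i + 1])
    }
    wrap_len <- (ms[1] - me[n]) %% L
    if (!(me[n] >= L && ms[1] <= 0) && (wrap_len > 0 || (me[n] %% L) != ms[1])) {
      if (wrap_len > 0) gaps[[length(gaps) + 1]] <- c(me[n] %% L, ms[1])
    }
  } else {
    if (ms[1] > 0) gaps[[length(gaps) + 1]] <- c(0L, ms[1])
    n <- length(ms)
    for (i in seq_len(n - 1)) {
      if (ms[i + 1] > me[i]) gaps[[length(gaps) + 1]] <- c(me[i], ms[i + 1])
    }
    if (me[n] < L) gaps[[length(gaps) + 1]] <- c(me[n], L)
  }
  if (length(gaps) == 0) return(igs_row(0L, 0L)[0, , drop = FALSE])
  rows <- lapply(gaps, function(g) {
    r <- igs_row(g[1], g[2] %% if (record$topology == "circular") L else (L + 1))
    # flanking features: the ones whose boundary delimits the gap
    li <- which(f$end %% L == g[1] %% L)
    ri <- which(f$start == g[2] %% L)
    if (length(li)) r$left_idx <- li[which.max(f$start[li])]
    if (length(ri)) r$right_idx <- ri[which.min(f$end[ri])]
    r
  })
  res <- do.call(rbind, rows)
  res <- res[res$length >= min_len, , drop = FALSE]
  res <- res[order(res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}
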