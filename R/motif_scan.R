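# Degenerate IUPAC motif scanning and oriC functional-element finders.

#' Built-in DnaA box motifs
#'
#' The standard E. coli DnaA box plus the two published species-specific
#' variants shipped with the package. Any other motif can be supplied
#' directly to [motif_config()].
#'
#' @return Named character vector of IUPAC motifs.
#' @export
dnaa_box_table <- function() {
  c(e_coli = "TTATCCACA",
    cyanobacteria = "TTTTCCACA",
    thermotoga_maritima = "AAACCTACCACC")
}

#' E. coli dif site (XerC/XerD chromosome-dimer resolution site), usable as
#' a terminus marker via [predict_terminus()].
#' @format Character scalar, 28 bp.
#' @export
dif_ecoli <- "GGTGCGCATAATGTATATTATGTTAAAT"

#' Define a degenerate nucleotide motif
#'
#' @param name Short label used in hit tables and reports.
#' @param iupac Motif over the IUPAC alphabet (`N` matches any base).
#' @param max_mm Mismatch budget used when the motif is scanned as part of
#'   a [motif_config()] `user_motifs` list.
#' @return Object of class `motif_pattern`.
#' @export
motif_pattern <- function(name, iupac, max_mm = 0) {
  iupac <- toupper(iupac)
  bad <- setdiff(unique(strsplit(iupac, "")[[1]]), IUPAC_CHARS)
  if (length(bad) > 0 || !nzchar(iupac)) {
    stop("invalid IUPAC symbol '", paste(bad, collapse = ""),
         "' in motif ", name, call. = FALSE)
  }
  structure(list(name = name, iupac = iupac, length = nchar(iupac),
                 max_mm = max_mm),
            class = "motif_pattern")
}

as_motif <- function(x, name) {
  if (inherits(x, "motif_pattern")) x else motif_pattern(name, x)
}

#' Motif configuration for oriC element scanning
#'
#' Bundles the motifs and mismatch limits used for scoring and annotation:
#' the DnaA box (default: standard E. coli TTATCCACA, scored at up to 1
#' mismatch), the 6-mer ATP-DnaA box AGATCT, the Dam methylation site
#' GATC, the CtrA binding site TTAA-N7-TTAA (mismatch budget applying to
#' the two TTAA half-sites; the N7 spacer is free), the DnaA-trio repeat
#' unit (default GAT, at least 3 tandem copies, linked to a DnaA box
#' within 50 bp upstream), an optional dif motif for terminus prediction,
#' and arbitrary user motifs.
#'
#' @param dnaa_box DnaA box motif (IUPAC string or [motif_pattern()]).
#' @param dnaa_box_max_mm Mismatch limit for *scoring* DnaA boxes.
#' @param atp_dnaa_box ATP-DnaA box motif, matched exactly.
#' @param gatc Dam methylation site, matched exactly.
#' @param ctra CtrA binding motif.
#' @param ctra_max_mm Mismatch budget over the CtrA half-sites.
#' @param trio_unit DnaA-trio repeat unit (3-mer).
#' @param trio_min_units Minimum tandem copies to call a trio array.
#' @param trio_max_gap_to_box Maximum gap (bp) between a DnaA box and a
#'   downstream trio array for box linkage.
#' @param dif dif motif (IUPAC string/[motif_pattern()]) or `NULL`.
#' @param dif_max_mm Mismatch limit for dif scanning.
#' @param user_motifs List of [motif_pattern()] objects scanned with their
#'   own `max_mm`.
#' @return Object of class `motif_config`.
#' @export
motif_config <- function(dnaa_box = "TTATCCACA", dnaa_box_max_mm = 1,
                         atp_dnaa_box = "AGATCT", gatc = "GATC",
                         ctra = "TTAANNNNNNNTTAA", ctra_max_mm = 1,
                         trio_unit = "GAT", trio_min_units = 3,
                         trio_max_gap_to_box = 50,
                         dif = NULL, dif_max_mm = 2,
                         user_motifs = list()) {
  cfg <- list(
    dnaa_box = as_motif(dnaa_box, "dnaa_box"),
    dnaa_box_max_mm = as.integer(dnaa_box_max_mm),
    atp_dnaa_box = as_motif(atp_dnaa_box, "atp_dnaa_box"),
    gatc = as_motif(gatc, "gatc"),
    ctra = as_motif(ctra, "ctra"),
    ctra_max_mm = as.integer(ctra_max_mm),
    trio_unit = toupper(trio_unit),
    trio_min_units = as.integer(trio_min_units),
    trio_max_gap_to_box = as.integer(trio_max_gap_to_box),
    dif = if (is.null(dif)) NULL else as_motif(dif, "dif"),
    dif_max_mm = as.integer(dif_max_mm),
    user_motifs = lapply(seq_along(user_motifs), function(i)
      as_motif(user_motifs[[i]],
               names(user_motifs)[i] %||% sprintf("user_%d", i))))
  if (nchar(cfg$trio_unit) != 3 ||
      any(!strsplit(cfg$trio_unit, "")[[1]] %in% c("A", "C", "G", "T"))) {
    stop("trio_unit must be a 3-mer over {A,C,G,T}", call. = FALSE)
  }
  if (cfg$trio_min_units < 1) stop("trio_min_units must be >= 1", call. = FALSE)
  structure(cfg, class = "motif_config")
}

empty_hits <- function() {
  data.frame(pattern_name = character(0), start = integer(0),
             end = integer(0), strand = character(0),
             mismatches = integer(0), matched_seq = character(0),
             stringsAsFactors = FALSE)
}

#' Scan a sequence for a degenerate motif with mismatches
#'
#' IUPAC-aware sliding-window scan: an ambiguity code in the pattern
#' matches any compatible base (`N` matches everything and never counts as
#' a mismatch), while an `N` in the *sequence* mismatches every non-`N`
#' pattern symbol. Minus-strand hits are reported in forward coordinates
#' with `strand == "-"` and `matched_seq` as read on the minus strand.
#'
#' @param sequence DNA string.
#' @param pattern IUPAC motif ([motif_pattern()] or character).
#' @param max_mm Maximum Hamming mismatches.
#' @param strands `"both"` or `"plus"`.
#' @return Hit data frame: `pattern_name`, `start` (0-based), `end`,
#'   `strand`, `mismatches`, `matched_seq`; sorted by start then strand.
#' @examples
#' scan_iupac("GGTTATCCACAGG", "TTATCCACA")
#' @export
scan_iupac <- function(sequence, pattern, max_mm = 0,
                       strands = c("both", "plus")) {
  strands <- match.arg(strands)
  pattern <- as_motif(pattern, if (is.character(pattern)) pattern else "motif")
  if (pattern$length > nchar(sequence)) return(empty_hits())
  subj <- Biostrings::DNAString(sequence)
  fx <- c(pattern = FALSE, subject = TRUE)
  scan_one <- function(pat_str, strand) {
    pat <- Biostrings::DNAString(pat_str)
    m <- Biostrings::matchPattern(pat, subj, max.mismatch = max_mm, fixed = fx)
    starts <- IRanges::start(m)
    # matchPattern also reports matches hanging off the sequence ends;
    # only fully contained windows are hits here
    starts <- starts[starts >= 1 & starts + pattern$length - 1 <= nchar(sequence)]
    if (length(starts) == 0) return(empty_hits())
    mm <- Biostrings::neditStartingAt(pat, subj, starting.at = starts,
                                      fixed = fx)
    win <- substring(sequence, starts, starts + pattern$length - 1)
    data.frame(pattern_name = pattern$name, start = starts - 1L,
               end = starts - 1L + pattern$length, strand = strand,
               mismatches = as.integer(mm),
               matched_seq = if (strand == "+") win else revcomp_each(win),
               stringsAsFactors = FALSE)
  }
  hits <- scan_one(pattern$iupac, "+")
  if (strands == "both") {
    hits <- rbind(hits, scan_one(revcomp(pattern$iupac), "-"))
  }
  hits <- hits[order(hits$start, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

revcomp_each <- function(v) vapply(v, revcomp, character(1), USE.NAMES = FALSE)

# Vectorized variant of scan_iupac over many (short) sequences: one
# vmatchPattern call per pattern/strand instead of one matchPattern call
# per sequence. Returns a list of hit data frames, one per input
# sequence, identical to lapply(seqs, scan_iupac, ...).
scan_iupac_set <- function(seqs, pattern, max_mm = 0,
                           strands = c("both", "plus")) {
  strands <- match.arg(strands)
  pattern <- as_motif(pattern, if (is.character(pattern)) pattern else "motif")
  res <- replicate(length(seqs), empty_hits(), simplify = FALSE)
  lens <- nchar(seqs)
  fx <- c(pattern = FALSE, subject = TRUE)
  ss <- Biostrings::DNAStringSet(seqs)
  scan_strand <- function(pat_str, strand) {
    pat <- Biostrings::DNAString(pat_str)
    mi <- Biostrings::vmatchPattern(pat, ss, max.mismatch = max_mm, fixed = fx)
    for (i in seq_along(seqs)) {
      r <- mi[[i]]
      if (length(r) == 0) next
      starts <- IRanges::start(r)
      ok <- starts >= 1 & starts + pattern$length - 1 <= lens[i]
      starts <- starts[ok]
      if (length(starts) == 0) next
      mm <- if (max_mm == 0) rep(0L, length(starts)) else
        as.integer(Biostrings::neditStartingAt(
          pat, Biostrings::DNAString(seqs[i]), starting.at = starts,
          fixed = fx))
      win <- substring(seqs[i], starts, starts + pattern$length - 1)
      df <- data.frame(pattern_name = pattern$name, start = starts - 1L,
                       end = starts - 1L + pattern$length, strand = strand,
                       mismatches = mm,
                       matched_seq = if (strand == "+") win
                                     else revcomp_each(win),
                       stringsAsFactors = FALSE)
      res[[i]] <<- rbind(res[[i]], df)
    }
  }
  if (pattern$length <= max(lens)) {
    scan_strand(pattern$iupac, "+")
    if (strands == "both") scan_strand(revcomp(pattern$iupac), "-")
  }
  lapply(res, function(h) {
    h <- h[order(h$start, h$strand), , drop = FALSE]
    rownames(h) <- NULL
    h
  })
}

is_palindromic <- function(iupac) identical(iupac, revcomp(iupac))

# drop the minus-strand duplicate of a palindromic motif at the same
# forward position
dedup_palindrome <- function(hits, iupac) {
  if (!is_palindromic(iupac) || nrow(hits) == 0) return(hits)
  keep <- !duplicated(hits[, c("pattern_name", "start")])
  hits[keep, , drop = FALSE]
}

#' Find DnaA boxes
#'
#' Scans both strands for the configured DnaA box at the configured
#' scoring mismatch limit.
#'
#' @param sequence DNA string.
#' @param config A [motif_config()].
#' @return Hit data frame (see [scan_iupac()]).
#' @export
find_dnaa_boxes <- function(sequence, config = motif_config()) {
  stopifnot(inherits(config, "motif_config"))
  scan_iupac(sequence, config$dnaa_box, config$dnaa_box_max_mm, "both")
}

#' Find DnaA-trio arrays
#'
#' Maximal tandem runs of the trio repeat unit (default GAT) with at least
#' `trio_min_units` copies, on either strand. Each array is linked to the
#' nearest same-strand DnaA box whose end lies within
#' `trio_max_gap_to_box` bp upstream of the run (the box + trio pair forms
#' the basal unwinding system), if one exists.
#'
#' @param sequence DNA string.
#' @param boxes DnaA box hits from [find_dnaa_boxes()] (may be empty).
#' @param config A [motif_config()].
#' @return Data frame: `start`, `end` (0-based half-open, forward
#'   coordinates), `strand`, `n_units`, `linked_box_start` (`NA` if no box
#'   within range).
#' @export
find_dnaa_trios <- function(sequence, boxes = empty_hits(),
                            config = motif_config()) {
  stopifnot(inherits(config, "motif_config"))
  unit <- config$trio_unit
  k <- config$trio_min_units
  runs_of <- function(u, strand) {
    re <- sprintf("(?:%s){%d,}", u, k)
    m <- gregexpr(re, sequence, perl = TRUE)[[1]]
    if (m[1] == -1) return(NULL)
    len <- attr(m, "match.length")
    data.frame(start = as.integer(m) - 1L,
               end = as.integer(m) - 1L + (len %/% 3L) * 3L,
               strand = strand, n_units = len %/% 3L,
               stringsAsFactors = FALSE)
  }
  fw <- runs_of(unit, "+")
  rv <- if (is_palindromic(unit)) NULL else runs_of(revcomp(unit), "-")
  arr <- rbind(fw, rv)
  if (is.null(arr) || nrow(arr) == 0) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), n_units = integer(0),
                      linked_box_start = integer(0), stringsAsFactors = FALSE))
  }
  arr$linked_box_start <- NA_integer_
  if (nrow(boxes) > 0) {
    for (i in seq_len(nrow(arr))) {
      b <- boxes[boxes$strand == arr$strand[i], , drop = FALSE]
      if (nrow(b) == 0) next
      # upstream = 5' of the run on its own strand
      gap <- if (arr$strand[i] == "+") arr$start[i] - b$end
             else b$start - arr$end[i]
      ok <- which(gap >= 0 & gap <= config$trio_max_gap_to_box)
      if (length(ok) > 0) {
        arr$linked_box_start[i] <- b$start[ok[which.min(gap[ok])]]
      }
    }
  }
  arr <- arr[order(arr$start, arr$strand), , drop = FALSE]
  rownames(arr) <- NULL
  arr
}

#' Find fixed oriC functional elements
#'
#' Exact-match Dam/GATC sites and ATP-DnaA boxes (AGATCT) on both strands,
#' CtrA TTAA-N7-TTAA sites within the configured half-site mismatch
#' budget, plus any user motifs at their declared limits. Hits of
#' palindromic motifs are deduplicated to one per forward position.
#'
#' @param sequence DNA string.
#' @param config A [motif_config()].
#' @return Hit data frame (see [scan_iupac()]).
#' @export
find_fixed_elements <- function(sequence, config = motif_config()) {
  stopifnot(inherits(config, "motif_config"))
  out <- list(
    dedup_palindrome(scan_iupac(sequence, config$gatc, 0, "both"),
                     config$gatc$iupac),
    dedup_palindrome(scan_iupac(sequence, config$atp_dnaa_box, 0, "both"),
                     config$atp_dnaa_box$iupac),
    dedup_palindrome(scan_iupac(sequence, config$ctra, config$ctra_max_mm,
                                "both"),
                     config$ctra$iupac))
  for (um in config$user_motifs) {
    out[[length(out) + 1]] <-
      dedup_palindrome(scan_iupac(sequence, um, um$max_mm, "both"), um$iupac)
  }
  hits <- do.call(rbind, out)
  hits <- hits[order(hits$start, hits$pattern_name, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Sliding-window AT-richness profile
#'
#' A+T fraction in a sliding window (step 1), used to locate the AT-rich
#' island most likely to act as the DNA unwinding element (DUE) of an
#' origin. The window with the highest AT fraction (leftmost on ties) is
#' reported as the putative DUE via the `"due"` attribute.
#'
#' @param sequence DNA string.
#' @param window Window size in bp (>= 10, <= sequence length).
#' @return Numeric vector of length `L - window + 1` with the AT fraction
#'   of each window; attributes `window` and `due` (0-based half-open
#'   interval of the best window).
#' @export
at_richness_profile <- function(sequence, window = 30) {
  L <- nchar(sequence)
  if (window < 10) stop("window must be >= 10", call. = FALSE)
  if (window > L) stop("window larger than sequence", call. = FALSE)
  x <- utf8ToInt(toupper(sequence))
  is_at <- as.integer(x == utf8ToInt("A") | x == utf8ToInt("T"))
  cs <- c(0L, cumsum(is_at))
  vals <- (cs[(window + 1):(L + 1)] - cs[1:(L - window + 1)]) / window
  best <- which.max(vals) - 1L
  structure(vals, window = window, due = c(start = best, end = best + window))
}
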