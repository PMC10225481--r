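# Internal helpers: sequence validation, IUPAC handling, misc.

IUPAC_CHARS <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N")

# complement map covering the full IUPAC alphabet
COMP_FROM <- "ACGTURYSWKMBDHVN"
COMP_TO   <- "TGCAAYRSWMKVHDBN"

#' Reverse complement of a DNA string
#'
#' Plain-character reverse complement over the IUPAC alphabet.
#'
#' @param x Character scalar, DNA sequence.
#' @return Character scalar.
#' @keywords internal
#' @noRd
revcomp <- function(x) {
  if (!nzchar(x)) return(x)
  intToUtf8(rev(utf8ToInt(chartr(COMP_FROM, COMP_TO, x))))
}

#' Normalize a raw sequence to the {A,C,G,T,N} alphabet
#'
#' Uppercases, maps ambiguity codes other than N to N (with a warning), and
#' errors on characters outside the IUPAC alphabet.
#' @noRd
clean_sequence <- function(x, context = "sequence") {
  x <- toupper(x)
  x <- gsub("U", "T", x, fixed = TRUE)
  chars <- unique(strsplit(x, "")[[1]])
  bad <- setdiff(chars, IUPAC_CHARS)
  if (length(bad) > 0) {
    stop(sprintf("invalid non-IUPAC character '%s' in %s", bad[1], context),
         call. = FALSE)
  }
  amb <- setdiff(chars, c("A", "C", "G", "T", "N"))
  if (length(amb) > 0) {
    warning(sprintf("%s: ambiguity codes (%s) replaced by N", context,
                    paste(amb, collapse = ",")), call. = FALSE)
    x <- chartr(paste(amb, collapse = ""),
                strrep("N", length(amb)), x)
  }
  x
}

#' Empty gene-feature table
#' @noRd
feature_df <- function(n = 0) {
  data.frame(locus_tag = character(n), gene_name = character(n),
             product = character(n), start = integer(n), end = integer(n),
             strand = character(n), kind = character(n),
             stringsAsFactors = FALSE)
}

validate_features <- function(features, L, what = "feature") {
  stopifnot(is.data.frame(features))
  if (nrow(features) == 0) return(features)
  ok <- features$start >= 0 & features$start < features$end & features$end <= L
  if (any(!ok)) {
    warning(sprintf("%d %s(s) with coordinates outside [0, %d) dropped",
                    sum(!ok), what, L), call. = FALSE)
    features <- features[ok, , drop = FALSE]
  }
  features[order(features$start, features$end), , drop = FALSE]
}

#' Construct a genome record
#'
#' A `genome_record` holds one replicon or contig: its sequence (uppercase,
#' alphabet `{A,C,G,T,N}`), topology, and an ordered table of gene features
#' in 0-based half-open coordinates.
#'
#' @param id Record identifier.
#' @param sequence DNA sequence (character scalar).
#' @param description Free-text description.
#' @param topology `"circular"` or `"linear"`.
#' @param features Data frame with columns `locus_tag`, `gene_name`,
#'   `product`, `start`, `end`, `strand`, `kind`, or `NULL` for none.
#' @param source One of `"genbank"`, `"fasta"`, `"simulated"`.
#' @return An object of class `genome_record`.
#' @examples
#' g <- genome_record("toy", "ACGTACGT")
#' nchar(g$sequence)
#' @export
genome_record <- function(id, sequence, description = "",
                          topology = c("linear", "circular"),
                          features = NULL, source = "fasta") {
  topology <- match.arg(topology)
  sequence <- clean_sequence(sequence, context = sprintf("record '%s'", id))
  if (nchar(sequence) < 1) stop("empty sequence", call. = FALSE)
  if (is.null(features)) features <- feature_df()
  features <- validate_features(features, nchar(sequence))
  structure(list(id = id, description = description, sequence = sequence,
                 topology = topology, features = features, source = source),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s (%s, %s)\n", x$id, x$topology, x$source))
  cat(sprintf("  %s bp, %d feature(s)\n",
              format(nchar(x$sequence), big.mark = ","), nrow(x$features)))
  if (nzchar(x$description)) cat(" ", x$description, "\n")
  invisible(x)
}

#' @export
length.genome_record <- function(x) nchar(x$sequence)

# tiny polynomial hash used only to stamp run configurations in logs
fnv1a <- function(s) {
  h <- 17
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

# run code with a temporary RNG seed, restoring global state afterwards
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
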