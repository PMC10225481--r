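# Run orchestration and report generation (JSON/TSV/BED/annotated text).

#' Run configuration
#'
#' Bundles every knob of a prediction run for [run_predict()]. Exactly
#' one input mode applies per run: complete (single replicon) or draft
#' (multi-contig, `draft = TRUE`).
#'
#' @param input Path to a FASTA or GenBank file.
#' @param format `"auto"` (detect by first non-blank character: `>` means
#'   FASTA), `"fasta"` or `"genbank"`.
#' @param topology Topology override for FASTA input (`NULL` keeps the
#'   format default: linear for FASTA, LOCUS line for GenBank).
#' @param draft Treat the input as a draft genome (pooled per-contig
#'   prediction).
#' @param motif A [motif_config()].
#' @param indicators An [indicator_table()].
#' @param weights Score weights (dist, gene, box).
#' @param min_igs Minimum IGS length (bp).
#' @param min_score,epsilon Reporting threshold and co-ranking margin.
#' @param orf_min_len Minimum ORF length for the annotation fallback.
#' @param strand_bias Also run the strand-bias analysis (complete
#'   circular genomes only).
#' @param out_dir Output directory.
#' @param seed Seed recorded in the log (prediction is deterministic).
#' @param verbose Print progress.
#' @return Object of class `run_config`.
#' @export
run_config <- function(input, format = c("auto", "fasta", "genbank"),
                       topology = NULL, draft = FALSE,
                       motif = motif_config(),
                       indicators = indicator_table(),
                       weights = c(1, 1, 1), min_igs = 80, min_score = 0,
                       epsilon = 0, orf_min_len = 300, strand_bias = FALSE,
                       out_dir = ".", seed = 1, verbose = FALSE) {
  format <- match.arg(format)
  if (!is.null(topology)) {
    topology <- match.arg(topology, c("circular", "linear"))
  }
  if (draft && strand_bias) {
    stop("strand-bias analysis is defined for complete genomes only",
         call. = FALSE)
  }
  structure(list(input = input, format = format, topology = topology,
                 draft = draft, motif = motif, indicators = indicators,
                 weights = weights, min_igs = min_igs,
                 min_score = min_score, epsilon = epsilon,
                 orf_min_len = orf_min_len, strand_bias = strand_bias,
                 out_dir = out_dir, seed = as.integer(seed),
                 verbose = verbose),
            class = "run_config")
}

detect_format <- function(path) {
  con <- file(path, "r")
  on.exit(close(con))
  repeat {
    ln <- readLines(con, n = 1, warn = FALSE)
    if (length(ln) == 0) stop("empty input file: ", path, call. = FALSE)
    ln <- trimws(ln)
    if (nzchar(ln)) return(if (startsWith(ln, ">")) "fasta" else "genbank")
  }
}

#' Run a full oriC prediction and write all reports
#'
#' Reads the input, predicts the origin (and, for complete genomes, the
#' terminus), and writes five outputs into `out_dir`: `result.json`
#' (machine-readable summary, 1-based inclusive coordinates),
#' `candidates.tsv` (one row per scored IGS), `elements.bed` (BED6 of
#' functional-element hits in the predicted oriC), `curves.tsv` (the
#' four disparity curves), and `oric_annotated.txt` plus
#' `oric_annotated.html` (the oriC sequence with elements labeled
#' inline). When the strand-bias analysis is requested (complete
#' circular genomes), its results additionally go to `strand_bias.tsv`
#' and into the JSON.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the `oric_scan`, the terminus, the
#'   strand-bias report (or `NULL`) and the output file `paths`.
#' @export
run_predict <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!file.exists(config$input)) {
    stop("input file not found: ", config$input, call. = FALSE)
  }
  fmt <- if (config$format == "auto") detect_format(config$input) else config$format
  records <- if (fmt == "fasta") {
    read_fasta(config$input, topology = config$topology %||% "linear")
  } else {
    read_genbank(config$input)
  }
  if (fmt == "genbank" && !is.null(config$topology)) {
    records <- lapply(records, function(r) { r$topology <- config$topology; r })
  }
  if (!config$draft && length(records) > 1) {
    stop("input has ", length(records),
         " records; use draft mode for multi-contig input", call. = FALSE)
  }
  if (!dir.exists(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE)
  }
  say <- function(...) if (config$verbose) message(sprintf(...))
  say("[oriscan] %d record(s) read from %s (%s)", length(records),
      config$input, fmt)

  scan <- if (config$draft) {
    predict_oric_draft(records, min_igs = config$min_igs,
                       config = config$motif, indicators = config$indicators,
                       weights = config$weights, epsilon = config$epsilon,
                       min_score = config$min_score,
                       orf_min_len = config$orf_min_len)
  } else {
    predict_oric(records[[1]], min_igs = config$min_igs,
                 config = config$motif, indicators = config$indicators,
                 weights = config$weights, epsilon = config$epsilon,
                 min_score = config$min_score,
                 orf_min_len = config$orf_min_len)
  }
  ter <- NULL
  if (!config$draft) ter <- predict_terminus(records[[1]], config$motif)
  sb <- NULL
  if (config$strand_bias && !config$draft &&
      records[[1]]$topology == "circular" && length(scan$predictions) > 0) {
    top <- scan$candidates[[scan$predictions[1]]]
    sb <- strand_bias_report(records[[1]],
                             oric_pos = floor(top$igs$midpoint),
                             ter_pos = ter$position)
  }

  paths <- write_reports(scan, ter, sb, records, config)
  say("[oriscan] wrote %d output files to %s", length(paths), config$out_dir)
  invisible(list(scan = scan, terminus = ter, strand_bias = sb,
                 paths = paths))
}

write_reports <- function(scan, ter, sb, records, config) {
  od <- config$out_dir
  paths <- c(result = file.path(od, "result.json"),
             candidates = file.path(od, "candidates.tsv"),
             elements = file.path(od, "elements.bed"),
             curves = file.path(od, "curves.tsv"),
             annotated = file.path(od, "oric_annotated.txt"),
             annotated_html = file.path(od, "oric_annotated.html"))

  # candidate table, 1-based inclusive for users
  tab <- scan$table
  if (nrow(tab) > 0) {
    tab$start <- tab$start + 1L
    # half-open end == 1-based inclusive end
  }
  utils::write.table(tab, paths["candidates"], sep = "\t", quote = FALSE,
                     row.names = FALSE)

  # curves (complete mode; draft scans are per-contig and curves are not
  # pooled): thin long genomes to keep the file reasonable
  if (!is.null(scan$curves)) {
    step <- max(1L, scan$curves$length %/% 100000L)
    export_curves_tsv(scan$curves, paths["curves"], step = step)
  } else {
    writeLines("position\tAT\tGC\tRY\tMK", paths["curves"])
  }

  # BED6 of elements in the predicted oriC(s)
  bed <- data.frame(chrom = character(0), start = integer(0),
                    end = integer(0), name = character(0),
                    score = integer(0), strand = character(0))
  for (i in scan$predictions) {
    cand <- scan$candidates[[i]]
    el <- cand$elements
    if (nrow(el) > 0) {
      Lr <- if (scan$draft) scan$L[match(cand$igs$record_id, scan$record_id)]
            else scan$L
      bed <- rbind(bed, data.frame(
        chrom = cand$igs$record_id, start = el$start_genome,
        end = el$start_genome + (el$end - el$start),
        name = el$pattern_name, score = el$mismatches,
        strand = el$strand, stringsAsFactors = FALSE))
    }
    for (t in seq_len(nrow(cand$trios))) {
      bed <- rbind(bed, data.frame(
        chrom = cand$igs$record_id,
        start = (cand$igs$start + cand$trios$start[t]),
        end = (cand$igs$start + cand$trios$end[t]),
        name = "dnaa_trio", score = 0L,
        strand = cand$trios$strand[t], stringsAsFactors = FALSE))
    }
  }
  utils::write.table(bed, paths["elements"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  # annotated oriC sequence
  ann <- if (length(scan$predictions) > 0) {
    rec1 <- if (scan$draft) NULL else records[[1]]
    render_annotated_oric(scan$candidates[[scan$predictions[1]]], rec1)
  } else "no oriC predicted\n"
  writeLines(ann, paths["annotated"])
  writeLines(c("<html><body><pre>", ann, "</pre></body></html>"),
             paths["annotated_html"])

  if (!is.null(sb)) {
    sb_path <- file.path(od, "strand_bias.tsv")
    sb_tab <- data.frame(
      quantity = c("arc1_len_bp", "arc2_len_bp", "arc1_pct", "arc2_pct",
                   "leading_genes", "lagging_genes", "leading_gene_pct",
                   paste0("leading_", names(sb$bases$leading), "_pct"),
                   paste0("lagging_", names(sb$bases$lagging), "_pct")),
      value = c(sb$partition$arc1_len, sb$partition$arc2_len,
                sb$partition$arc1_frac, sb$partition$arc2_frac,
                sb$genes$leading, sb$genes$lagging, sb$genes$leading_frac,
                unname(sb$bases$leading), unname(sb$bases$lagging)))
    utils::write.table(sb_tab, sb_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, strand_bias = sb_path)
  }

  # machine-readable result
  res <- list(
    tool = "oriscan",
    version = as.character(utils::packageVersion("oriscan")),
    seed = config$seed,
    config_hash = fnv1a(paste(deparse(config[setdiff(names(config), "out_dir")]),
                              collapse = "")),
    input = basename(config$input),
    mode = if (scan$draft) "draft" else "complete",
    records = lapply(records, function(r)
      list(id = r$id, length = nchar(r$sequence), topology = r$topology,
           n_features = nrow(r$features))),
    n_candidates = length(scan$candidates),
    predictions = lapply(scan$predictions, function(i) {
      x <- scan$candidates[[i]]
      list(record_id = x$igs$record_id %||% scan$record_id[1],
           start = x$igs$start + 1, end = x$igs$end,
           wraps_origin = x$igs$end < x$igs$start,
           length = x$igs$length,
           s_dist = x$s_dist, s_gene = x$s_gene, s_box = x$s_box,
           total = x$total, n_dnaa_boxes = nrow(x$boxes),
           n_dnaa_trios = x$n_trios, n_gatc = x$gatc_count,
           elements = if (nrow(x$elements)) x$elements else NULL)
    }))
  if (!is.null(ter)) {
    res$terminus <- list(position = ter$position + 1, method = ter$method)
  }
  if (!is.null(sb)) {
    res$strand_bias <- list(
      note = "strand lengths are replichore-arc lengths",
      arc1_frac = sb$partition$arc1_frac,
      arc2_frac = sb$partition$arc2_frac,
      leading_genes = sb$genes$leading, lagging_genes = sb$genes$lagging,
      leading_gene_frac = sb$genes$leading_frac,
      leading_bases = as.list(sb$bases$leading),
      lagging_bases = as.list(sb$bases$lagging))
  }
  if (length(scan$predictions) == 0) {
    res$warning <- "no oriC found above the minimum score"
  }
  jsonlite::write_json(res, paths["result"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths
}

# display priority when inline labels would overlap (highest wins)
ELEMENT_PRIORITY <- c(dnaa_box = 1, dnaa_box_relaxed = 2, dnaa_trio = 3,
                      atp_dnaa_box = 4, ctra = 5, gatc = 6, due = 7)

#' Render an oriC candidate with inline element labels
#'
#' The candidate's sequence with each functional element wrapped in a
#' non-destructive bracket label, `[name>SEQUENCE]`. Overlaps are
#' resolved by display priority (DnaA box > trio > ATP-DnaA box > CtrA >
#' GATC > DUE); every hit remains in the candidate's element table
#' regardless of display. Stripping the labels (`[name>` and `]`)
#' restores the raw sequence byte for byte. Flanking gene names are
#' appended when the source record is supplied.
#'
#' @param candidate A [score_igs()] result.
#' @param record Optionally, the [genome_record] the IGS came from (for
#'   flank names).
#' @return Character scalar (multi-line).
#' @export
render_annotated_oric <- function(candidate, record = NULL) {
  stopifnot(inherits(candidate, "candidate_score"))
  seqc <- candidate$igs$sequence
  spans <- data.frame(name = character(0), start = integer(0),
                      end = integer(0), prio = integer(0))
  el <- candidate$elements
  if (nrow(el) > 0) {
    spans <- rbind(spans, data.frame(
      name = el$pattern_name, start = el$start, end = el$end,
      prio = unname(ELEMENT_PRIORITY[el$pattern_name]) %|NA|% 5L))
  }
  if (nrow(candidate$trios) > 0) {
    spans <- rbind(spans, data.frame(
      name = "dnaa_trio", start = candidate$trios$start,
      end = candidate$trios$end,
      prio = ELEMENT_PRIORITY[["dnaa_trio"]]))
  }
  if (!is.null(candidate$due_window)) {
    spans <- rbind(spans, data.frame(
      name = "due", start = candidate$due_window[["start"]],
      end = candidate$due_window[["end"]],
      prio = ELEMENT_PRIORITY[["due"]]))
  }
  # greedy non-overlapping selection by priority, then position
  spans <- spans[order(spans$prio, spans$start), , drop = FALSE]
  taken <- rep(FALSE, nchar(seqc))
  keep <- logical(nrow(spans))
  for (i in seq_len(nrow(spans))) {
    idx <- (spans$start[i] + 1):spans$end[i]
    if (!any(taken[idx])) {
      keep[i] <- TRUE
      taken[idx] <- TRUE
    }
  }
  spans <- spans[keep, , drop = FALSE]
  spans <- spans[order(spans$start), , drop = FALSE]
  out <- character(0)
  cursor <- 0
  for (i in seq_len(nrow(spans))) {
    if (spans$start[i] > cursor) {
      out <- c(out, substr(seqc, cursor + 1, spans$start[i]))
    }
    out <- c(out, sprintf("[%s>%s]", spans$name[i],
                          substr(seqc, spans$start[i] + 1, spans$end[i])))
    cursor <- spans$end[i]
  }
  if (cursor < nchar(seqc)) out <- c(out, substr(seqc, cursor + 1, nchar(seqc)))
  body <- paste(out, collapse = "")
  header <- sprintf("# predicted oriC %s:%d..%d (%d bp), total score %.4f",
                    candidate$igs$record_id %||% "?",
                    candidate$igs$start + 1, candidate$igs$end,
                    candidate$igs$length, candidate$total)
  flanks <- ""
  if (!is.null(record) && inherits(record, "genome_record")) {
    nm <- function(idx) {
      if (is.null(idx) || is.na(idx)) return("-")
      g <- record$features[idx, ]
      if (nzchar(g$gene_name)) g$gene_name else g$locus_tag
    }
    flanks <- sprintf("# upstream gene: %s | downstream gene: %s",
                      nm(candidate$igs$left_idx), nm(candidate$igs$right_idx))
  }
  paste(c(header, flanks[nzchar(flanks)], body), collapse = "\n")
}

`%|NA|%` <- function(a, b) { a[is.na(a)] <- b; a }

#' Strip inline element labels from an annotated oriC rendering
#'
#' Inverse of the labeling in [render_annotated_oric()]: removes
#' `[name>` and `]` markers and header lines, restoring the raw
#' sequence.
#'
#' @param text Output of [render_annotated_oric()].
#' @return Character scalar, the unlabeled sequence.
#' @export
strip_oric_labels <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- lines[!startsWith(lines, "#")]
  gsub("\\[[A-Za-z0-9_.+-]+>|\\]", "", paste(lines, collapse = ""))
}
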