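# IGS scoring, ranking and oriC / terminus prediction.

#' Indicator-gene table
#'
#' Genes whose chromosomal adjacency marks the likely oriC neighbourhood.
#' The principal indicator is dnaA; secondary-chromosome initiators
#' (dnaN, repA, rctB by default) score lower unless `chromosome_type` is
#' `"secondary"`, in which case the secondary list is treated as the
#' principal indicator set (e.g. rctB-initiated Vibrio chromosome 2).
#'
#' @param primary Character vector of principal indicator gene names.
#' @param secondary Character vector of secondary indicator gene names.
#' @param chromosome_type `"primary"` or `"secondary"`.
#' @return Object of class `indicator_table`.
#' @export
indicator_table <- function(primary = "dnaA",
                            secondary = c("dnaN", "repA", "rctB"),
                            chromosome_type = c("primary", "secondary")) {
  chromosome_type <- match.arg(chromosome_type)
  if (length(primary) == 0) stop("primary indicator list must be non-empty",
                                 call. = FALSE)
  structure(list(primary = primary, secondary = secondary,
                 chromosome_type = chromosome_type),
            class = "indicator_table")
}

matches_pattern <- function(gene_name, product, pat) {
  if (tolower(gene_name) == tolower(pat)) return(TRUE)
  nzchar(product) &&
    grepl(paste0("\\b", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", pat), "\\b"),
          product, ignore.case = TRUE)
}

#' Find indicator genes in an annotated record
#'
#' A feature matches when its gene name equals an indicator pattern
#' (case-insensitively) or its product description contains the pattern
#' as a word (so product "chromosomal replication initiator protein DnaA"
#' matches "dnaA"). ORF-fallback features carry no names and never match.
#'
#' @param record A [genome_record].
#' @param table An [indicator_table()].
#' @return Feature data frame with added columns `indicator_class`
#'   (`"primary"`/`"secondary"`) and `midpoint`.
#' @export
find_indicator_genes <- function(record, table = indicator_table()) {
  stopifnot(inherits(record, "genome_record"), inherits(table, "indicator_table"))
  f <- record$features
  if (nrow(f) == 0) return(cbind(f, indicator_class = character(0), midpoint = numeric(0)))
  cls <- rep(NA_character_, nrow(f))
  for (i in seq_len(nrow(f))) {
    if (any(vapply(table$primary, function(p)
      matches_pattern(f$gene_name[i], f$product[i], p), logical(1)))) {
      cls[i] <- "primary"
    } else if (any(vapply(table$secondary, function(p)
      matches_pattern(f$gene_name[i], f$product[i], p), logical(1)))) {
      cls[i] <- if (table$chromosome_type == "secondary") "primary" else "secondary"
    }
  }
  keep <- !is.na(cls)
  out <- f[keep, , drop = FALSE]
  out$indicator_class <- cls[keep]
  out$midpoint <- (out$start + out$end) / 2
  rownames(out) <- NULL
  out
}

#' Score one intergenic sequence as an oriC candidate
#'
#' Three additive evidence components, each in `[0, 1]`:
#' \describe{
#'   \item{`s_dist`}{base composition: `max(0, 1 - d / (L/2))` where `d`
#'     is the (topology-aware) distance from the IGS midpoint to the
#'     minimum of the GC disparity curve.}
#'   \item{`s_gene`}{indicator genes: 1 if a principal indicator gene is
#'     an immediate flank of the IGS, 0.75 if a secondary indicator
#'     flanks it, 0.5 if any indicator gene midpoint lies within 5 kb,
#'     else 0.}
#'   \item{`s_box`}{DnaA boxes: `min(sum((k+1-m)/(k+1)) / 3, 1)` over all
#'     boxes with at most `k = dnaa_box_max_mm` mismatches, i.e. one
#'     perfect box contributes one third and the score saturates at three
#'     box-equivalents (a DnaA box cluster).}
#' }
#' The total is the weighted sum (default weights 1,1,1, so total in
#' `[0, 3]`). All other functional elements (DnaA-trios with linked
#' boxes, relaxed ≤ 4-mismatch boxes adjacent to trios, GATC, ATP-DnaA
#' boxes, CtrA sites, user motifs, and the AT-richest window as putative
#' DUE) are annotated on the candidate for tie-breaking and display.
#'
#' @param igs One IGS (single row of [extract_igs()] output, or a list
#'   with `start`, `end`, `length`, `midpoint`, `sequence`).
#' @param gc_min_pos GC-disparity minimum of the containing replicon
#'   (per-contig for draft genomes).
#' @param L Replicon/contig length in bp.
#' @param topology `"circular"` or `"linear"`.
#' @param indicators Output of [find_indicator_genes()] (may have 0 rows).
#' @param config A [motif_config()].
#' @param weights Length-3 numeric: weights for dist, gene, box.
#' @param due_window Window (bp) for the AT-richness DUE proxy; skipped
#'   when the IGS is shorter than the window.
#' @param indicator_radius Proximity radius (bp) for the 0.5 gene-score
#'   tier.
#' @return Object of class `candidate_score`.
#' @export
score_igs <- function(igs, gc_min_pos, L,
                      topology = c("circular", "linear"),
                      indicators = NULL, config = motif_config(),
                      weights = c(1, 1, 1), due_window = 30,
                      indicator_radius = 5000) {
  topology <- match.arg(topology)
  igs <- as.list(igs)
  seqc <- igs$sequence
  boxes <- find_dnaa_boxes(seqc, config)
  trios <- find_dnaa_trios(seqc, boxes, config)
  fixed <- find_fixed_elements(seqc, config)
  score_igs_core(igs, gc_min_pos, L, topology, indicators, config,
                 weights, due_window, indicator_radius,
                 boxes = boxes, trios = trios, fixed = fixed)
}

# scoring/annotation core shared by score_igs() (per-IGS scans) and the
# bulk path in predict_oric() (genome-batched scans); element hits are
# identical either way.
score_igs_core <- function(igs, gc_min_pos, L, topology, indicators,
                           config, weights, due_window, indicator_radius,
                           boxes, trios, fixed) {
  seqc <- igs$sequence

  # --- base composition ---
  d <- circular_distance(igs$midpoint, gc_min_pos, L, topology)
  s_dist <- max(0, 1 - d / (L / 2))

  # --- indicator genes ---
  s_gene <- 0
  if (!is.null(indicators) && nrow(indicators) > 0) {
    flank <- (indicators$end %% L) == (igs$start %% L) |
             (indicators$start %% L) == (igs$end %% L)
    if (any(flank & indicators$indicator_class == "primary")) {
      s_gene <- 1
    } else if (any(flank & indicators$indicator_class == "secondary")) {
      s_gene <- 0.75
    } else {
      dmid <- pmin(
        circular_distance(indicators$midpoint, igs$start %% L, L, topology),
        circular_distance(indicators$midpoint, igs$end %% L, L, topology))
      if (any(dmid <= indicator_radius)) s_gene <- 0.5
    }
  }

  # --- DnaA boxes ---
  k <- config$dnaa_box_max_mm
  s_box <- if (nrow(boxes) == 0) 0 else
    min(sum((k + 1 - boxes$mismatches) / (k + 1)) / 3, 1)

  # --- functional-element annotation ---
  relaxed <- relaxed_boxes_near_trios(seqc, boxes, trios, config)
  due <- NULL
  if (igs$length >= max(10, due_window)) {
    prof <- at_richness_profile(seqc, due_window)
    due <- attr(prof, "due")
  }
  elements <- rbind(boxes, fixed, relaxed)
  if (nrow(elements) > 0) {
    elements$start_genome <- (igs$start + elements$start) %% L
    elements <- elements[order(elements$start), , drop = FALSE]
    rownames(elements) <- NULL
  } else {
    elements$start_genome <- integer(0)
  }
  x <- utf8ToInt(seqc)
  at_frac <- mean(x == 65L | x == 84L)

  total <- sum(weights * c(s_dist, s_gene, s_box))
  structure(list(igs = igs, s_dist = s_dist, s_gene = s_gene, s_box = s_box,
                 total = total, boxes = boxes, trios = trios,
                 n_trios = nrow(trios),
                 gatc_count = sum(elements$pattern_name == "gatc"),
                 elements = elements, due_window = due, at_frac = at_frac),
            class = "candidate_score")
}

# Batched equivalent of lapply(rows, score_igs, ...): scans all IGS
# sequences of a replicon in a handful of vectorized pattern searches.
score_all_igs <- function(igs, gc_min_pos, L, topology, indicators, config,
                          weights, due_window, indicator_radius = 5000) {
  n <- nrow(igs)
  if (n == 0) return(list())
  seqs <- igs$sequence
  boxes <- scan_iupac_set(seqs, config$dnaa_box, config$dnaa_box_max_mm,
                          "both")
  pats <- c(list(config$gatc, config$atp_dnaa_box, config$ctra),
            config$user_motifs)
  mms <- c(0, 0, config$ctra_max_mm,
           vapply(config$user_motifs, `[[`, numeric(1), "max_mm"))
  per_pat <- lapply(seq_along(pats), function(j) {
    hits <- scan_iupac_set(seqs, pats[[j]], mms[j], "both")
    lapply(hits, dedup_palindrome, iupac = pats[[j]]$iupac)
  })
  lapply(seq_len(n), function(i) {
    fixed <- do.call(rbind, lapply(per_pat, `[[`, i))
    fixed <- fixed[order(fixed$start, fixed$pattern_name, fixed$strand), ,
                   drop = FALSE]
    rownames(fixed) <- NULL
    trios <- find_dnaa_trios(seqs[i], boxes[[i]], config)
    score_igs_core(as.list(igs[i, ]), gc_min_pos, L, topology, indicators,
                   config, weights, due_window, indicator_radius,
                   boxes = boxes[[i]], trios = trios, fixed = fixed)
  })
}

# DnaA boxes at up to 4 mismatches that sit adjacent to a DnaA-trio run
# (annotation only, never scored)
relaxed_boxes_near_trios <- function(seqc, boxes, trios, config) {
  if (nrow(trios) == 0) return(empty_hits())
  all4 <- scan_iupac(seqc, config$dnaa_box, 4, "both")
  if (nrow(all4) == 0) return(empty_hits())
  if (nrow(boxes) > 0) {
    scored <- paste(boxes$start, boxes$strand)
    all4 <- all4[!paste(all4$start, all4$strand) %in% scored, , drop = FALSE]
  }
  if (nrow(all4) == 0) return(empty_hits())
  keep <- vapply(seq_len(nrow(all4)), function(i) {
    same <- trios[trios$strand == all4$strand[i], , drop = FALSE]
    if (nrow(same) == 0) return(FALSE)
    gap <- pmax(same$start - all4$end[i], all4$start[i] - same$end)
    any(gap <= config$trio_max_gap_to_box)
  }, logical(1))
  out <- all4[keep, , drop = FALSE]
  if (nrow(out) > 0) out$pattern_name <- "dnaa_box_relaxed"
  out
}

#' @export
print.candidate_score <- function(x, ...) {
  cat(sprintf("<candidate_score> IGS %d..%d (%d bp)\n",
              x$igs$start + 1, x$igs$end, x$igs$length))
  cat(sprintf("  total %.4f = dist %.4f + gene %.2f + box %.4f\n",
              x$total, x$s_dist, x$s_gene, x$s_box))
  cat(sprintf("  %d DnaA box(es), %d trio array(s), %d GATC site(s)\n",
              nrow(x$boxes), x$n_trios, x$gatc_count))
  invisible(x)
}

#' Rank scored oriC candidates
#'
#' Descending total score; exact ties are screened with functional
#' elements, in order: more DnaA-trio arrays, more GATC sites, higher IGS
#' AT fraction, then the smaller start coordinate for determinism.
#'
#' @param candidates List of [score_igs()] results.
#' @return The list, reordered; empty input returns empty with a warning.
#' @export
rank_candidates <- function(candidates) {
  if (length(candidates) == 0) {
    warning("no candidates to rank", call. = FALSE)
    return(candidates)
  }
  key <- data.frame(
    total = vapply(candidates, `[[`, numeric(1), "total"),
    trios = vapply(candidates, `[[`, numeric(1), "n_trios"),
    gatc = vapply(candidates, `[[`, numeric(1), "gatc_count"),
    at = vapply(candidates, `[[`, numeric(1), "at_frac"),
    start = vapply(candidates, function(x) x$igs$start, numeric(1)))
  o <- order(-key$total, -key$trios, -key$gatc, -key$at, key$start)
  candidates[o]
}

candidate_table <- function(candidates) {
  if (length(candidates) == 0) {
    return(data.frame(rank = integer(0), record_id = character(0),
                      start = integer(0), end = integer(0),
                      length = integer(0), s_dist = numeric(0),
                      s_gene = numeric(0), s_box = numeric(0),
                      total = numeric(0), n_boxes = integer(0),
                      n_trios = integer(0), gatc = integer(0),
                      at_frac = numeric(0)))
  }
  do.call(rbind, lapply(seq_along(candidates), function(i) {
    x <- candidates[[i]]
    data.frame(rank = i, record_id = x$igs$record_id %||% "",
               start = x$igs$start, end = x$igs$end, length = x$igs$length,
               s_dist = x$s_dist, s_gene = x$s_gene, s_box = x$s_box,
               total = x$total, n_boxes = nrow(x$boxes),
               n_trios = x$n_trios, gatc = x$gatc_count,
               at_frac = x$at_frac, stringsAsFactors = FALSE)
  }))
}

#' Predict the replication origin of a complete genome
#'
#' End-to-end prediction on one replicon: compute the GC-disparity
#' minimum, delimit intergenic sequences (running the six-frame ORF
#' fallback first if the record has no annotation), score every IGS with
#' [score_igs()], rank with [rank_candidates()], and report the top
#' candidate. Candidates whose total comes within `epsilon` of the best
#' (default: exact ties only) are all reported, reflecting chromosomes
#' that carry multiple origins; candidates with total at or below
#' `min_score` are never reported.
#'
#' @param record A [genome_record].
#' @param min_igs Minimum IGS length (bp).
#' @param config A [motif_config()].
#' @param indicators An [indicator_table()].
#' @param weights Score weights (dist, gene, box).
#' @param epsilon Score margin for reporting co-ranked candidates.
#' @param min_score Minimum reportable total (strict).
#' @param orf_min_len Minimum ORF length for the annotation fallback.
#' @param due_window DUE proxy window (bp).
#' @return Object of class `oric_scan`.
#' @examples
#' sim <- simulate_genome(sim_params(L = 50000, seed = 42))
#' p <- predict_oric(sim$record)
#' p
#' @export
predict_oric <- function(record, min_igs = 80, config = motif_config(),
                         indicators = indicator_table(),
                         weights = c(1, 1, 1), epsilon = 0, min_score = 0,
                         orf_min_len = 300, due_window = 30) {
  stopifnot(inherits(record, "genome_record"))
  if (nrow(record$features) == 0) {
    record$features <- find_orfs_fallback(record, orf_min_len)
  }
  curves <- disparity_curves(record$sequence)
  ex <- gc_extrema(curves, record$topology)
  L <- nchar(record$sequence)
  igs <- extract_igs(record, min_igs)
  ind <- find_indicator_genes(record, indicators)
  cands <- score_all_igs(igs, ex$min_pos, L, record$topology, ind, config,
                         weights, due_window)
  if (length(cands) == 0) {
    warning("no intergenic sequence of length >= ", min_igs,
            "; nothing to predict", call. = FALSE)
  }
  ranked <- if (length(cands)) rank_candidates(cands) else cands
  preds <- integer(0)
  if (length(ranked) > 0 && ranked[[1]]$total > min_score) {
    top <- ranked[[1]]$total
    preds <- which(vapply(ranked, `[[`, numeric(1), "total") >= top - epsilon &
                   vapply(ranked, `[[`, numeric(1), "total") > min_score)
  } else if (length(ranked) > 0) {
    warning("no candidate exceeds the minimum score; nothing to predict",
            call. = FALSE)
  }
  structure(list(record_id = record$id, L = L, topology = record$topology,
                 draft = FALSE, gc_min = ex$min_pos, gc_max = ex$max_pos,
                 curves = curves, candidates = ranked,
                 table = candidate_table(ranked), predictions = preds),
            class = "oric_scan")
}

#' Predict oriC across the contigs of a draft genome
#'
#' Each contig is treated as a linear fragment and scored against its own
#' GC-disparity minimum and its own length (a global minimum is
#' meaningless across unordered contigs); candidates from all contigs are
#' then pooled and ranked with the same criteria. Unannotated contigs get
#' the ORF fallback; a wholly gene-free contig is scored as one IGS.
#'
#' @param records List of [genome_record] contigs.
#' @inheritParams predict_oric
#' @return Object of class `oric_scan` with `draft = TRUE`.
#' @export
predict_oric_draft <- function(records, min_igs = 80, config = motif_config(),
                               indicators = indicator_table(),
                               weights = c(1, 1, 1), epsilon = 0,
                               min_score = 0, orf_min_len = 300,
                               due_window = 30) {
  if (inherits(records, "genome_record")) records <- list(records)
  stopifnot(length(records) >= 1)
  cands <- list()
  for (r in records) {
    stopifnot(inherits(r, "genome_record"))
    r$topology <- "linear"
    if (nrow(r$features) == 0) {
      r$features <- find_orfs_fallback(r, orf_min_len)
    }
    curves <- disparity_curves(r$sequence)
    ex <- gc_extrema(curves, "linear")
    Lc <- nchar(r$sequence)
    igs <- extract_igs(r, min_igs)
    ind <- find_indicator_genes(r, indicators)
    cands <- c(cands, score_all_igs(igs, ex$min_pos, Lc, "linear", ind,
                                    config, weights, due_window))
  }
  if (length(cands) == 0) {
    warning("no intergenic sequence of length >= ", min_igs,
            " on any contig; nothing to predict", call. = FALSE)
  }
  ranked <- if (length(cands)) rank_candidates(cands) else cands
  preds <- integer(0)
  if (length(ranked) > 0 && ranked[[1]]$total > min_score) {
    top <- ranked[[1]]$total
    tot <- vapply(ranked, `[[`, numeric(1), "total")
    preds <- which(tot >= top - epsilon & tot > min_score)
  }
  structure(list(record_id = vapply(records, `[[`, character(1), "id"),
                 L = vapply(records, function(r) nchar(r$sequence), numeric(1)),
                 topology = "linear", draft = TRUE, gc_min = NA, gc_max = NA,
                 curves = NULL, candidates = ranked,
                 table = candidate_table(ranked), predictions = preds),
            class = "oric_scan")
}

#' Predict the replication terminus of a complete genome
#'
#' Uses the dif chromosome-dimer-resolution site when a dif motif is
#' configured and found (best hit = fewest mismatches, then nearest to
#' the GC-disparity maximum; terminus = hit midpoint); otherwise falls
#' back on the position of the GC-disparity maximum.
#'
#' @param record A single [genome_record] (complete genome). Multi-contig
#'   drafts are rejected: contig order is unknown, so a terminus is
#'   undefined.
#' @param config A [motif_config()]; set its `dif` slot to enable
#'   dif-based prediction (see [dif_ecoli]).
#' @return Object of class `terminus_prediction`: `position`, `method`
#'   (`"dif"` or `"gc_max"`), `dif_hit`.
#' @export
predict_terminus <- function(record, config = motif_config()) {
  if (is.list(record) && !inherits(record, "genome_record")) {
    if (length(record) == 1 && inherits(record[[1]], "genome_record")) {
      record <- record[[1]]
    } else {
      stop("terminus prediction is defined for complete genomes only, ",
           "not multi-contig drafts", call. = FALSE)
    }
  }
  stopifnot(inherits(record, "genome_record"))
  curves <- disparity_curves(record$sequence)
  ex <- gc_extrema(curves, record$topology)
  L <- nchar(record$sequence)
  if (!is.null(config$dif)) {
    hits <- scan_iupac(record$sequence, config$dif, config$dif_max_mm, "both")
    if (nrow(hits) > 0) {
      mid <- (hits$start + hits$end) / 2
      o <- order(hits$mismatches,
                 circular_distance(mid, ex$max_pos, L, record$topology))
      best <- hits[o[1], , drop = FALSE]
      return(structure(list(position = floor((best$start + best$end) / 2),
                            method = "dif", dif_hit = best),
                       class = "terminus_prediction"))
    }
  }
  structure(list(position = ex$max_pos, method = "gc_max", dif_hit = NULL),
            class = "terminus_prediction")
}

#' @export
print.terminus_prediction <- function(x, ...) {
  cat(sprintf("<terminus_prediction> position %s (method: %s)\n",
              format(x$position + 1, big.mark = ","), x$method))
  invisible(x)
}

#' @export
print.oric_scan <- function(x, ...) {
  kind <- if (x$draft) "draft genome" else sprintf("%s genome", x$topology)
  cat(sprintf("<oric_scan> %s, %d candidate IGS(s) scored\n",
              kind, length(x$candidates)))
  if (length(x$predictions) == 0) {
    cat("  no oriC predicted\n")
    return(invisible(x))
  }
  for (i in x$predictions) {
    c1 <- x$candidates[[i]]
    cat(sprintf("  oriC #%d: %s:%s..%s (%d bp)  total %.4f (dist %.4f, gene %.2f, box %.4f)\n",
                i, c1$igs$record_id %||% x$record_id[1],
                format(c1$igs$start + 1, big.mark = ","),
                format(if (c1$igs$end >= c1$igs$start) c1$igs$end
                       else c1$igs$end, big.mark = ","),
                c1$igs$length, c1$total, c1$s_dist, c1$s_gene, c1$s_box))
    cat(sprintf("    %d DnaA box(es), %d DnaA-trio array(s), %d GATC site(s)\n",
                nrow(c1$boxes), c1$n_trios, c1$gatc_count))
  }
  invisible(x)
}

#' @export
summary.oric_scan <- function(object, n = 5, ...) {
  print(object)
  cat("\nTop candidates:\n")
  print(utils::head(object$table, n), row.names = FALSE, digits = 4)
  invisible(object$table)
}

#' Plot an origin scan
#'
#' Disparity curves with the GC extrema and the predicted oriC interval
#' marked (complete genomes only).
#'
#' @param x An `oric_scan`.
#' @param ... Passed to [plot.disparity_set()].
#' @export
plot.oric_scan <- function(x, ...) {
  if (is.null(x$curves)) {
    stop("no stored curves (draft-mode scans are per-contig)", call. = FALSE)
  }
  plot(x$curves, ...)
  if (length(x$predictions) > 0) {
    top <- x$candidates[[x$predictions[1]]]
    graphics::abline(v = top$igs$start, col = "purple", lwd = 2)
  }
  invisible(x)
}
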