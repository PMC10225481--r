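# Z-curve derived cumulative disparity curves and their extrema.

#' Cumulative base-disparity curves (Z-curve method)
#'
#' Computes the four prefix-cumulative disparity curves over a sequence:
#' AT (A minus T), GC (G minus C), RY (purine minus pyrimidine) and MK
#' (amino minus keto). Entry `n + 1` of each curve is the cumulative
#' disparity of the first `n` bases; entry 1 is 0. `N` bases contribute 0
#' to all four curves. The identities `RY = AT + GC` and `MK = AT - GC`
#' hold at every prefix.
#'
#' The minimum of the GC curve marks the replication-origin neighbourhood
#' on a typical bacterial chromosome and its maximum the terminus.
#'
#' @param sequence DNA string over `{A,C,G,T,N}`.
#' @return An object of class `disparity_set`: list with `length` and
#'   integer vectors `AT`, `GC`, `RY`, `MK`, each of length `length + 1`.
#' @examples
#' d <- disparity_curves("GGGCCC")
#' d$GC
#' @export
disparity_curves <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1 || !nzchar(sequence)) {
    stop("sequence must be a non-empty DNA string", call. = FALSE)
  }
  x <- utf8ToInt(toupper(sequence))
  bad <- setdiff(unique(x), utf8ToInt("ACGTN"))
  if (length(bad) > 0) {
    stop("invalid character '", intToUtf8(bad[1]), "' in sequence", call. = FALSE)
  }
  inc <- function(plus, minus) {
    v <- integer(256)
    v[utf8ToInt(plus)] <- 1L
    v[utf8ToInt(minus)] <- -1L
    v
  }
  at <- cumsum(inc("A", "T")[x])
  gc <- cumsum(inc("G", "C")[x])
  structure(list(length = length(x),
                 AT = c(0L, at), GC = c(0L, gc),
                 RY = c(0L, at + gc), MK = c(0L, at - gc)),
            class = "disparity_set")
}

#' @export
print.disparity_set <- function(x, ...) {
  cat(sprintf("<disparity_set> %s bp\n", format(x$length, big.mark = ",")))
  gx <- gc_extrema(x)
  cat(sprintf("  GC disparity: min %d at %s, max %d at %s\n",
              min(x$GC), format(gx$min_pos, big.mark = ","),
              max(x$GC), format(gx$max_pos, big.mark = ",")))
  invisible(x)
}

#' Positions of the GC-disparity extrema
#'
#' The global minimum of the cumulative GC disparity is used as
#' base-composition evidence for the origin; the maximum marks the
#' terminus neighbourhood. Ties are broken by the smallest index. The
#' curve is taken on the given linearization; no rotation search is done
#' for circular replicons.
#'
#' @param curves A `disparity_set` from [disparity_curves()].
#' @param topology `"circular"` or `"linear"` (recorded, extrema identical).
#' @return List with `min_pos` and `max_pos`, 0-based positions in
#'   `[0, length]`.
#' @export
gc_extrema <- function(curves, topology = c("circular", "linear")) {
  stopifnot(inherits(curves, "disparity_set"))
  topology <- match.arg(topology)
  list(min_pos = which.min(curves$GC) - 1L,
       max_pos = which.max(curves$GC) - 1L)
}

#' Distance between two genome positions
#'
#' Shortest distance respecting topology: along either arc for circular
#' replicons, absolute difference for linear ones.
#'
#' @param a,b Positions in `[0, L]`.
#' @param L Sequence length in bp.
#' @param topology `"circular"` or `"linear"`.
#' @return Distance in bp.
#' @export
circular_distance <- function(a, b, L, topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  d <- abs(a - b)
  if (topology == "circular") pmin(d, L - d) else d
}

#' Write disparity curves to a TSV file
#'
#' One row per position (`0..L`), columns `position`, `AT`, `GC`, `RY`,
#' `MK`, suitable for external plotting.
#'
#' @param curves A `disparity_set`.
#' @param path Output file.
#' @param step Report every `step`-th position (default 1; raise for long
#'   genomes).
#' @return Invisibly, the path.
#' @export
export_curves_tsv <- function(curves, path, step = 1) {
  stopifnot(inherits(curves, "disparity_set"), step >= 1)
  idx <- seq(1, curves$length + 1, by = step)
  df <- data.frame(position = idx - 1L, AT = curves$AT[idx],
                   GC = curves$GC[idx], RY = curves$RY[idx],
                   MK = curves$MK[idx])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# centred moving-average smoothing, for display only (never used to locate
# extrema for prediction)
smooth_disparity <- function(y, window) {
  if (window <= 1) return(y)
  as.numeric(stats::filter(y, rep(1 / window, window), sides = 2))
}

#' Plot the four disparity curves
#'
#' Base-graphics plot of the AT, GC, RY and MK curves with the GC extrema
#' marked. Optional moving-average smoothing affects the display only.
#'
#' @param x A `disparity_set`.
#' @param window Smoothing window in bp (default 1 = none).
#' @param ... Passed to [graphics::matplot()].
#' @return Invisibly, `x`.
#' @export
plot.disparity_set <- function(x, window = 1, ...) {
  pos <- 0:x$length
  m <- cbind(AT = x$AT, GC = x$GC, RY = x$RY, MK = x$MK)
  if (window > 1) m <- apply(m, 2, smooth_disparity, window = window)
  graphics::matplot(pos, m, type = "l", lty = 1,
                    col = c("red", "darkgreen", "blue", "orange"),
                    xlab = "position (bp)", ylab = "cumulative disparity", ...)
  ex <- gc_extrema(x)
  graphics::abline(v = c(ex$min_pos, ex$max_pos), lty = 3,
                   col = c("darkblue", "lightblue3"))
  graphics::legend("topleft", c("AT", "GC", "RY", "MK"), lty = 1,
                   col = c("red", "darkgreen", "blue", "orange"), bty = "n")
  invisible(x)
}
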