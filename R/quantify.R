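#' Per-base numeric track over a locus
#'
#' @param locus_name Locus identifier.
#' @param values Numeric vector, one value per locus position.
#' @param kind \code{"coverage"}, \code{"signal"} or
#'   \code{"log2_ratio"}.
#' @return A \code{genomic_track} list.
#' @export
genomic_track <- function(locus_name, values,
                          kind = c("coverage", "signal", "log2_ratio")) {
  kind <- match.arg(kind)
  values <- as.numeric(values)
  if (kind %in% c("coverage", "signal") && any(values < 0, na.rm = TRUE))
    stop(kind, " track values must be >= 0")
  structure(list(locus = locus_name, values = values, kind = kind),
            class = "genomic_track")
}

#' @export
print.genomic_track <- function(x, ...) {
  cat("genomic_track [", x$kind, "] on ", x$locus, ": ",
      length(x$values), " nt, range [",
      signif(min(x$values), 4), ", ", signif(max(x$values), 4), "]\n",
      sep = "")
  invisible(x)
}

#' Count cDNA barcodes with whitelist correction
#'
#' Extracts barcodes from transcript reads, maps them through the
#' whitelist variant map, and tallies per-canonical read counts.  Reads
#' whose barcode cannot be extracted, matches no variant, or is
#' ambiguous between canonicals are discarded (and counted); reads
#' rescued by error correction are tallied separately from exact
#' matches.
#'
#' @param reads Character vector of barcode-bearing reads.
#' @param whitelist A \code{\link{build_whitelist}} index.
#' @param anchor_left,anchor_right Constant sequences flanking the
#'   barcode.
#' @param max_mismatch Anchor mismatch tolerance (default 1).
#' @return A \code{barcode_counts}: list with \code{counts} (named
#'   integer per canonical), \code{corrected}, \code{discarded},
#'   \code{total_reads}.
#' @export
count_barcodes <- function(reads, whitelist,
                           anchor_left = .ANCHOR_LEFT,
                           anchor_right = .ANCHOR_RIGHT,
                           max_mismatch = 1L) {
  stopifnot(inherits(whitelist, "whitelist_index"))
  bl <- nchar(whitelist$canonicals[1])
  bc <- extract_barcodes(reads, anchor_left, anchor_right, bl, max_mismatch)
  cr <- correct_barcodes(whitelist, bc)
  ok <- !is.na(cr$canonical)
  counts <- table(factor(cr$canonical[ok], levels = whitelist$canonicals))
  counts <- setNames(as.integer(counts), whitelist$canonicals)
  structure(list(counts = counts,
                 corrected = sum(cr$status == "corrected"),
                 discarded = sum(!ok),
                 total_reads = length(reads)),
            class = "barcode_counts")
}

#' @export
print.barcode_counts <- function(x, ...) {
  cat("barcode_counts: ", x$total_reads, " reads; ",
      sum(x$counts), " assigned (", x$corrected, " corrected), ",
      x$discarded, " discarded\n", sep = "")
  invisible(x)
}

#' Accumulate barcode counts into a per-base signal track
#'
#' Value at position p is the sum, over association-map entries whose
#' interval contains p, of that barcode's read count.  Counted barcodes
#' absent from the map are skipped and reported via the
#' \code{skipped_barcodes} attribute.
#'
#' @param counts A \code{\link{count_barcodes}} result (or named numeric
#'   vector of per-barcode counts).
#' @param map A \code{barcode_map} from \code{\link{build_association}}.
#' @param locus The \code{\link{reference_locus}}.
#' @return A \code{\link{genomic_track}} of kind \code{signal}.
#' @export
signal_track <- function(counts, map, locus) {
  cts <- if (inherits(counts, "barcode_counts")) counts$counts else counts
  i <- match(names(cts), map$barcode)
  skipped <- names(cts)[is.na(i) & cts > 0]
  use <- !is.na(i) & cts > 0
  vals <- .interval_accumulate(map$start[i[use]], map$end[i[use]],
                               as.numeric(cts[use]), locus$length)
  tr <- genomic_track(locus$name, vals, "signal")
  attr(tr, "skipped_barcodes") <- skipped
  tr
}

#' Depth-normalised log2 enrichment track
#'
#' Both tracks are first scaled to a common total mass (one
#' count-equivalent per position on average), then the per-position
#' value is \code{log2((cdna + pseudocount) / (input + pseudocount))}.
#' The depth normalisation makes the result invariant to multiplying
#' either input track by any positive constant.
#'
#' @param cdna cDNA barcode \code{\link{genomic_track}}.
#' @param input_lib Association-library (input abundance) track.
#' @param pseudocount Added to both scaled tracks (default 1
#'   count-equivalent per position).
#' @return A \code{\link{genomic_track}} of kind \code{log2_ratio}.
#' @export
normalize_log2 <- function(cdna, input_lib, pseudocount = 1) {
  stopifnot(inherits(cdna, "genomic_track"),
            inherits(input_lib, "genomic_track"),
            pseudocount > 0)
  if (length(cdna$values) != length(input_lib$values))
    stop("tracks must have equal length")
  if (all(input_lib$values == 0)) stop("input track is all zero")
  if (all(cdna$values == 0)) stop("cdna track is all zero")
  L <- length(cdna$values)
  a <- cdna$values * (L / sum(cdna$values))
  b <- input_lib$values * (L / sum(input_lib$values))
  genomic_track(cdna$locus, log2((a + pseudocount) / (b + pseudocount)),
                "log2_ratio")
}

#' Trapezoidal AUC of a track over a region of interest
#'
#' Integrates the per-base signal across the ROI by the trapezoidal
#' rule with unit (1 nt) spacing.
#'
#' @param track A \code{\link{genomic_track}}.
#' @param start,end ROI as 0-based half-open interval on the locus.
#' @param name ROI label.
#' @return Data frame row: \code{roi}, \code{start}, \code{end},
#'   \code{auc}.
#' @export
track_auc <- function(track, start, end, name = "roi") {
  stopifnot(inherits(track, "genomic_track"))
  if (end - start < 2) stop("ROI must span at least 2 positions")
  if (start < 0 || end > length(track$values))
    stop("ROI outside track bounds")
  v <- track$values[(start + 1L):end]
  n <- length(v)
  auc <- sum((v[-1L] + v[-n]) / 2)
  data.frame(roi = name, start = start, end = end, auc = auc,
             stringsAsFactors = FALSE)
}

#' Normalise AUC values to a reference condition
#'
#' @param results Data frame with columns \code{roi}, \code{condition},
#'   \code{auc} (e.g. rows of \code{\link{track_auc}} across
#'   conditions).
#' @param reference The condition to normalise to (e.g. the 0-hour
#'   timepoint).
#' @return The input with a \code{normalized_auc} column,
#'   \code{auc / auc[reference]} within each ROI.
#' @export
normalize_auc_to_reference <- function(results, reference) {
  stopifnot(all(c("roi", "condition", "auc") %in% names(results)))
  if (!reference %in% results$condition)
    stop("reference condition not present")
  ref <- results[results$condition == reference, ]
  refauc <- setNames(ref$auc, ref$roi)
  if (any(refauc == 0)) stop("reference AUC is zero")
  results$normalized_auc <- results$auc / refauc[results$roi]
  results
}

#' Call peaks on a per-base track
#'
#' Maximal runs of positions with value >= \code{threshold}; runs
#' separated by gaps of at most \code{merge_gap} nt are merged, and
#' merged runs narrower than \code{min_width} are discarded.
#'
#' @param track A \code{\link{genomic_track}}.
#' @param threshold Calling threshold on the track value.
#' @param min_width Minimum peak width in nt (default 1).
#' @param merge_gap Maximum gap bridged between runs (default 0).
#' @return Data frame of peaks: \code{name}, \code{start}, \code{end}
#'   (0-based half-open), \code{center}, \code{max_value}, sorted by
#'   start.
#' @export
call_peaks <- function(track, threshold, min_width = 1L, merge_gap = 0L) {
  stopifnot(inherits(track, "genomic_track"), min_width >= 1)
  above <- track$values >= threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values] - 1L, end = ends[r$values])
  if (!nrow(runs))
    return(data.frame(name = character(0), start = integer(0),
                      end = integer(0), center = numeric(0),
                      max_value = numeric(0)))
  # merge runs separated by <= merge_gap
  merged <- runs[1, ]
  if (nrow(runs) > 1) {
    for (i in 2:nrow(runs)) {
      if (runs$start[i] - merged$end[nrow(merged)] <= merge_gap)
        merged$end[nrow(merged)] <- runs$end[i]
      else merged <- rbind(merged, runs[i, ])
    }
  }
  merged <- merged[merged$end - merged$start >= min_width, , drop = FALSE]
  if (!nrow(merged))
    return(data.frame(name = character(0), start = integer(0),
                      end = integer(0), center = numeric(0),
                      max_value = numeric(0)))
  mx <- vapply(seq_len(nrow(merged)), function(i)
    max(track$values[(merged$start[i] + 1L):merged$end[i]]), numeric(1))
  data.frame(name = paste0("peak_", seq_len(nrow(merged))),
             start = merged$start, end = merged$end,
             center = (merged$start + merged$end) / 2,
             max_value = mx, stringsAsFactors = FALSE)
}
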