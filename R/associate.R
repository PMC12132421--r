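#' Extract transcript barcodes from barcode-bearing reads
#'
#' Locates the left anchor allowing at most \code{max_mismatch}
#' mismatches, then requires the right anchor (same tolerance)
#' immediately after the barcode, and returns the intervening bases.
#' Reads failing either anchor yield \code{NA} (a typed failure the
#' caller counts, never an exception).
#'
#' @param reads Character vector of read sequences.
#' @param anchor_left,anchor_right Constant flanking sequences.
#' @param barcode_length Barcode length in nt.
#' @param max_mismatch Mismatches tolerated per anchor (default 1).
#' @return Character vector of barcodes, \code{NA} where extraction
#'   failed.
#' @export
extract_barcodes <- function(reads,
                             anchor_left = .ANCHOR_LEFT,
                             anchor_right = .ANCHOR_RIGHT,
                             barcode_length = 24L,
                             max_mismatch = 1L) {
  if (!nchar(anchor_left) || !nchar(anchor_right))
    stop("anchors must be nonempty")
  .scan_anchor_cpp(as.character(reads), anchor_left, anchor_right,
                   as.integer(barcode_length), as.integer(max_mismatch))
}

#' Build a k-mer seed index over a locus
#'
#' Exact-seed index used by the internal small-scale mapper: every
#' locus k-mer with its (unique) start position; k-mers occurring more
#' than once are flagged so reads seeding in repeats fail as
#' multi-mapping.
#'
#' @param locus A \code{\link{reference_locus}}.
#' @param k Seed length (default 21).
#' @return A \code{locus_index} list.
#' @export
locus_index <- function(locus, k = 21L) {
  stopifnot(inherits(locus, "reference_locus"), k >= 1,
            locus$length >= k)
  n <- locus$length - k + 1L
  kmers <- substring(locus$sequence, 1:n, k:locus$length)
  first <- !duplicated(kmers)
  multi_k <- unique(kmers[duplicated(kmers)])
  structure(list(locus = locus, k = as.integer(k),
                 kmer = kmers[first], pos = which(first),   # 1-based
                 multi = kmers[first] %in% multi_k),
            class = "locus_index")
}

#' Map reads to the locus with an exact seed + mismatch-bounded extension
#'
#' The read's first \code{k} bases must match a unique locus k-mer; the
#' full read is then verified against the locus with a mismatch fraction
#' of at most \code{max_mismatch_frac}.  Reads whose seed is absent,
#' falls in a repeated k-mer, or whose extension exceeds the mismatch
#' bound fail (with a reason), never silently misplace.
#'
#' @param reads Character vector of read sequences.
#' @param index A \code{\link{locus_index}}.
#' @param max_mismatch_frac Maximum mismatch fraction over the read
#'   (default 0.05).
#' @return Data frame with \code{start} (0-based locus position,
#'   \code{NA} on failure) and \code{reason} (\code{mapped},
#'   \code{no_seed}, \code{multi_map}, \code{too_divergent},
#'   \code{out_of_bounds}).
#' @export
map_fragments <- function(reads, index, max_mismatch_frac = 0.05) {
  stopifnot(inherits(index, "locus_index"))
  reads <- as.character(reads)
  seed <- substr(reads, 1L, index$k)
  hit <- match(seed, index$kmer)
  reason <- rep("mapped", length(reads))
  reason[is.na(hit)] <- "no_seed"
  multi <- !is.na(hit) & index$multi[hit]
  reason[multi] <- "multi_map"
  start1 <- ifelse(reason == "mapped", index$pos[hit], NA_integer_)
  mm <- .mismatch_at_cpp(index$locus$sequence, reads, as.integer(start1))
  oob <- reason == "mapped" & is.na(mm)
  reason[oob] <- "out_of_bounds"
  bad <- reason == "mapped" & !is.na(mm) & mm / nchar(reads) > max_mismatch_frac
  reason[bad] <- "too_divergent"
  start1[reason != "mapped"] <- NA_integer_
  data.frame(start = start1 - 1L, reason = reason, stringsAsFactors = FALSE)
}

#' @rdname map_fragments
#' @param read A single read sequence.
#' @export
map_fragment <- function(read, index, max_mismatch_frac = 0.05) {
  map_fragments(read, index, max_mismatch_frac)
}

#' Associate barcodes with fragment intervals
#'
#' Collates per-pair (barcode, interval) observations into a
#' barcode-fragment map.  Pairs with a failed barcode are counted
#' \code{dropped_unparsed}; pairs with a failed interval
#' \code{dropped_unmapped}.  A barcode observed with interval starts
#' spreading more than \code{tolerance} nt is dropped as ambiguous
#' (conservative: one barcode, one fragment); otherwise its interval is
#' the modal one and the supporting-read count is recorded.
#'
#' @param barcodes Character vector (NA = extraction failure).
#' @param starts,ends Integer vectors of 0-based half-open interval
#'   coordinates (NA = mapping failure).
#' @param tolerance Maximum allowed spread of start positions per
#'   barcode (default 5 nt).
#' @return A \code{barcode_map}: data frame (\code{barcode},
#'   \code{start}, \code{end}, \code{reads}) with accounting attributes
#'   \code{n_input}, \code{dropped_unparsed}, \code{dropped_unmapped},
#'   \code{dropped_ambiguous} (barcode count) and
#'   \code{dropped_ambiguous_reads}.
#' @export
build_association <- function(barcodes, starts, ends, tolerance = 5L) {
  n_input <- length(barcodes)
  stopifnot(length(starts) == n_input, length(ends) == n_input)
  unparsed <- is.na(barcodes)
  unmapped <- !unparsed & (is.na(starts) | is.na(ends))
  keep <- !unparsed & !unmapped
  dt <- data.table::data.table(barcode = barcodes[keep],
                               start = starts[keep], end = ends[keep])
  if (nrow(dt)) {
    per <- dt[, {
      if (max(start) - min(start) > tolerance) {
        list(start = NA_integer_, end = NA_integer_, reads = .N)
      } else {
        key <- paste(start, end)
        modal <- which.max(tabulate(match(key, unique(key))))
        uk <- !duplicated(key)
        list(start = start[uk][modal], end = end[uk][modal], reads = .N)
      }
    }, by = "barcode"]
  } else {
    per <- data.table::data.table(barcode = character(0),
                                  start = integer(0), end = integer(0),
                                  reads = integer(0))
  }
  amb <- is.na(per$start)
  out <- as.data.frame(per[!amb])
  out <- out[order(out$start, out$barcode), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("barcode_map", "data.frame")
  attr(out, "n_input") <- n_input
  attr(out, "dropped_unparsed") <- sum(unparsed)
  attr(out, "dropped_unmapped") <- sum(unmapped)
  attr(out, "dropped_ambiguous") <- sum(amb)
  attr(out, "dropped_ambiguous_reads") <- sum(per$reads[amb])
  out
}

#' End-to-end association from simulated or real read pairs
#'
#' Convenience wrapper running barcode extraction on read 1, start
#' mapping on read 2, end mapping on the read-1 fragment tail, and
#' \code{\link{build_association}}.
#'
#' @param pairs Data frame with columns \code{read1}, \code{read2}.
#' @param locus A \code{\link{reference_locus}}.
#' @param cfg A \code{\link{sim_config}} supplying anchors, barcode
#'   length and read length.
#' @param k Seed length for the mapper.
#' @param max_mismatch_frac Mapper mismatch bound.
#' @param tolerance Association start tolerance (nt).
#' @return A \code{barcode_map} (see \code{\link{build_association}}).
#' @export
associate_pairs <- function(pairs, locus, cfg = sim_config(), k = 21L,
                            max_mismatch_frac = 0.05, tolerance = 5L) {
  idx <- locus_index(locus, k)
  bc <- extract_barcodes(pairs$read1, cfg$anchor_left, cfg$anchor_right,
                         cfg$barcode_pattern$length)
  m2 <- map_fragments(pairs$read2, idx, max_mismatch_frac)
  # fragment 3' tail rides read 1 after the right anchor, reverse
  # complemented; its mapped start + length gives the fragment end
  skip <- nchar(cfg$anchor_left) + cfg$barcode_pattern$length +
    nchar(cfg$anchor_right)
  tail_rc <- substr(pairs$read1, skip + 1L, cfg$read_length)
  tail_fwd <- revcomp(tail_rc)
  m1 <- map_fragments(tail_fwd, idx, max_mismatch_frac)
  ends <- m1$start + nchar(tail_fwd)
  build_association(bc, m2$start, ends, tolerance)
}

#' Filter an association map by read support
#'
#' Barcodes arising from sequencing errors in true barcodes enter the
#' association map with very low read support (typically singletons at
#' any realistic depth, while genuine barcodes are supported by most of
#' their fragment's reads).  This drops entries below a support
#' threshold; the default is self-calibrating: one tenth of the
#' read-mass-weighted median support (the support level at which half
#' of all association reads sit in better-supported entries - robust
#' to a large swarm of singleton error entries), and at least 2 reads.
#'
#' @param map A \code{barcode_map}.
#' @param min_reads Minimum supporting reads; \code{NULL} for the
#'   self-calibrating default.
#' @return The filtered \code{barcode_map}; accounting attributes are
#'   preserved and \code{dropped_low_support} added.
#' @export
filter_association <- function(map, min_reads = NULL) {
  if (is.null(min_reads)) {
    o <- order(map$reads)
    cum <- cumsum(map$reads[o])
    wmed <- map$reads[o][which(cum >= sum(map$reads) / 2)[1]]
    min_reads <- max(2, ceiling(0.1 * wmed))
  }
  keep <- map$reads >= min_reads
  out <- map[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("barcode_map", "data.frame")
  for (a in c("n_input", "dropped_unparsed", "dropped_unmapped",
              "dropped_ambiguous", "dropped_ambiguous_reads"))
    attr(out, a) <- attr(map, a)
  attr(out, "dropped_low_support") <- sum(!keep)
  attr(out, "min_reads") <- min_reads
  out
}

#' Coverage track of a barcode-fragment map
#'
#' Value at position p = number of map entries whose interval contains
#' p.
#'
#' @param map A \code{barcode_map}.
#' @param locus The \code{\link{reference_locus}}.
#' @return A \code{\link{genomic_track}} of kind \code{coverage}.
#' @export
coverage_track <- function(map, locus) {
  vals <- .interval_accumulate(map$start, map$end,
                               rep(1, nrow(map)), locus$length)
  genomic_track(locus$name, vals, "coverage")
}

# Sum `weight` over [start, end) intervals onto a per-position vector
# via the difference-array trick (0-based half-open inputs).
.interval_accumulate <- function(start, end, weight, length) {
  delta <- numeric(length + 1L)
  s <- pmax(start, 0L) + 1L
  e <- pmin(end, length) + 1L
  for (i in seq_along(s)) {
    delta[s[i]] <- delta[s[i]] + weight[i]
    delta[e[i]] <- delta[e[i]] - weight[i]
  }
  cumsum(delta)[seq_len(length)]
}
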