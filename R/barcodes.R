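#' @name iupac
#' @title IUPAC degeneracy codes
#' @description Mapping from IUPAC nucleotide codes to the set of literal
#'   bases each allows.  Degenerate transcript barcodes are specified as a
#'   string of these codes, e.g. \code{"SW"} repeated twelve times gives the
#'   default 24-nt barcode alternating strong (G/C) and weak (A/T) bases,
#'   which caps GC content at 50\% and rules out homopolymer runs longer
#'   than two.
#' @keywords internal
NULL

.IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

.AMBIGUOUS <- "AMBIGUOUS"

#' Define a degenerate barcode pattern
#'
#' @param symbols A string (or character vector) of IUPAC codes, one per
#'   barcode position, e.g. \code{"SWSW"} or \code{c("V","H","B","D")}.
#' @param times Number of times the symbol block is repeated (default 1).
#' @return An object of class \code{degenerate_pattern}.
#' @examples
#' degenerate_pattern("SW", times = 12)   # the default 24-nt barcode
#' degenerate_pattern("VHBD", times = 4)  # the 16-nt alternative
#' @export
degenerate_pattern <- function(symbols, times = 1L) {
  sym <- toupper(unlist(strsplit(paste(symbols, collapse = ""), "")))
  sym <- rep(sym, times)
  bad <- setdiff(sym, names(.IUPAC))
  if (length(bad))
    stop("invalid IUPAC code(s): ", paste(unique(bad), collapse = ", "))
  if (!length(sym)) stop("pattern must have length > 0")
  structure(list(symbols = sym, length = length(sym)),
            class = "degenerate_pattern")
}

#' @export
print.degenerate_pattern <- function(x, ...) {
  cat("degenerate_pattern: ", paste(x$symbols, collapse = ""),
      " (", x$length, " nt)\n", sep = "")
  invisible(x)
}

#' Sample random barcodes from a degenerate pattern
#'
#' Each position is drawn uniformly from the bases its IUPAC code allows.
#' Uses R's global RNG; call \code{set.seed()} first for reproducibility.
#'
#' @param n Number of barcodes to draw.
#' @param pattern A \code{\link{degenerate_pattern}} (default: twelve SW
#'   repeats, a 24-nt barcode).
#' @return Character vector of \code{n} barcodes.
#' @export
sample_barcodes <- function(n, pattern = degenerate_pattern("SW", 12L)) {
  stopifnot(inherits(pattern, "degenerate_pattern"), n >= 0)
  if (n == 0) return(character(0))
  cols <- lapply(pattern$symbols, function(s) {
    bases <- .IUPAC[[s]]
    if (length(bases) == 1L) rep(bases, n)
    else bases[sample.int(length(bases), n, replace = TRUE)]
  })
  do.call(paste0, cols)
}

#' Hamming distance between equal-length sequences
#'
#' Vectorised over \code{a}; \code{b} may be a single sequence recycled
#' against \code{a}.
#'
#' @param a,b Character vectors of equal-length sequences.
#' @return Integer vector of position-wise mismatch counts.
#' @examples
#' hamming("ATACAGGC", "TGTGCAAG")  # 8
#' @export
hamming <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  .hamming_cpp(a, b)
}

#' Minimum pairwise Hamming distance of a sequence set
#'
#' @param seqs Character vector of two or more equal-length sequences.
#' @return Smallest Hamming distance over all pairs.
#' @export
min_pairwise_hamming <- function(seqs) {
  .min_pairwise_hamming_cpp(as.character(seqs))
}

#' Enumerate all sequences within a Hamming radius
#'
#' Returns every equal-length string within Hamming distance
#' \code{radius} of \code{barcode}, including the barcode itself.  The
#' number of variants follows the closed form
#' \eqn{\sum_{k \le r} \binom{L}{k} 3^k}.
#'
#' @param barcode A single A/C/G/T string.
#' @param radius Maximum Hamming distance (non-negative integer).
#' @return Character vector of variants (barcode first).
#' @export
enumerate_variants <- function(barcode, radius) {
  stopifnot(length(barcode) == 1L, radius >= 0)
  barcode <- as.character(barcode)
  L <- nchar(barcode)
  radius <- min(as.integer(radius), L)
  out <- barcode
  if (radius == 0L) return(out)
  chars <- strsplit(barcode, "")[[1]]
  bases <- c("A", "C", "G", "T")
  for (k in seq_len(radius)) {
    pos_sets <- utils::combn(L, k)
    for (ci in seq_len(ncol(pos_sets))) {
      pos <- pos_sets[, ci]
      alts <- lapply(pos, function(p) setdiff(bases, chars[p]))
      grid <- as.matrix(expand.grid(alts, stringsAsFactors = FALSE))
      for (ri in seq_len(nrow(grid))) {
        v <- chars
        v[pos] <- grid[ri, ]
        out <- c(out, paste(v, collapse = ""))
      }
    }
  }
  out
}

#' Build an error-correcting barcode whitelist
#'
#' Enumerates, for every canonical barcode, all sequence variants within
#' \code{radius} mismatches and maps them back to the canonical.  Variants
#' reachable from two or more canonicals are flagged ambiguous and are
#' dropped (never assigned) during correction.  In strict mode the radius
#' must not exceed \eqn{\lfloor (d_{min}-1)/2 \rfloor}, where
#' \eqn{d_{min}} is the minimum pairwise Hamming distance of the
#' canonicals; within that radius no misread barcode can be corrected to
#' the wrong canonical.
#'
#' @param canonicals Character vector of equal-length barcodes.
#' @param radius Correction radius in mismatches.
#' @param strict Enforce the guaranteed-correction radius bound
#'   (default TRUE).
#' @return An object of class \code{whitelist_index} with elements
#'   \code{canonicals}, \code{radius}, \code{variants}, \code{targets}
#'   (canonical per variant, \code{NA} = ambiguous) and
#'   \code{min_pairwise_distance}.
#' @export
build_whitelist <- function(canonicals, radius = NULL, strict = TRUE) {
  canonicals <- unique(as.character(canonicals))
  if (!length(canonicals)) stop("canonicals must be nonempty")
  if (length(unique(nchar(canonicals))) != 1L)
    stop("canonicals must have equal length")
  dmin <- if (length(canonicals) >= 2L) min_pairwise_hamming(canonicals)
          else NA_integer_
  safe <- if (is.na(dmin)) Inf else max(0L, (dmin - 1L) %/% 2L)
  if (is.null(radius)) radius <- if (is.finite(safe)) safe else 1L
  radius <- as.integer(radius)
  if (radius < 0) stop("radius must be >= 0")
  if (strict && radius > safe)
    stop("radius ", radius, " exceeds guaranteed-correction bound ",
         safe, " (min pairwise distance ", dmin, "); use strict = FALSE ",
         "to allow frequency-free greedy correction with ambiguity dropping")
  if (radius == 0L) {
    variants <- canonicals
    targets <- canonicals
  } else {
    vl <- lapply(canonicals, enumerate_variants, radius = radius)
    variants <- unlist(vl, use.names = FALSE)
    targets <- rep(canonicals, lengths(vl))
    # a variant reachable from >1 canonical is ambiguous
    dup <- duplicated(variants) | duplicated(variants, fromLast = TRUE)
    if (any(dup)) {
      amb <- unique(variants[dup])
      keep <- !duplicated(variants)
      variants <- variants[keep]
      targets <- targets[keep]
      targets[variants %in% amb] <- NA_character_
      # canonicals always map to themselves even if within radius of another
      self <- match(canonicals, variants)
      targets[self] <- canonicals
    }
  }
  structure(list(canonicals = canonicals, radius = radius,
                 variants = variants, targets = targets,
                 min_pairwise_distance = dmin, strict = strict),
            class = "whitelist_index")
}

#' @export
print.whitelist_index <- function(x, ...) {
  cat("whitelist_index: ", length(x$canonicals), " canonicals (",
      nchar(x$canonicals[1]), " nt), radius ", x$radius,
      ", min pairwise distance ",
      ifelse(is.na(x$min_pairwise_distance), "NA", x$min_pairwise_distance),
      ", ", sum(is.na(x$targets)), " ambiguous variants\n", sep = "")
  invisible(x)
}

#' Correct observed barcodes against a whitelist
#'
#' @param whitelist A \code{\link{build_whitelist}} index.
#' @param barcodes Character vector of observed barcodes (NA allowed).
#' @return Data frame with columns \code{barcode}, \code{canonical}
#'   (\code{NA} when ambiguous or unmatched) and \code{status}
#'   (\code{exact}, \code{corrected}, \code{ambiguous}, \code{nomatch}).
#' @export
correct_barcodes <- function(whitelist, barcodes) {
  stopifnot(inherits(whitelist, "whitelist_index"))
  i <- match(barcodes, whitelist$variants)
  canonical <- whitelist$targets[i]
  status <- rep("nomatch", length(barcodes))
  status[!is.na(i) & is.na(canonical)] <- "ambiguous"
  hit <- !is.na(canonical)
  status[hit] <- ifelse(canonical[hit] == barcodes[hit], "exact", "corrected")
  status[is.na(barcodes)] <- "nomatch"
  data.frame(barcode = barcodes, canonical = canonical, status = status,
             stringsAsFactors = FALSE)
}

#' Write / read a whitelist as two-column TSV (variant, canonical)
#'
#' Ambiguous variants are serialised with the literal canonical
#' \code{"AMBIGUOUS"}.
#'
#' @param whitelist A \code{whitelist_index}.
#' @param path Output / input file path.
#' @rdname whitelist_io
#' @export
write_whitelist <- function(whitelist, path) {
  stopifnot(inherits(whitelist, "whitelist_index"))
  canon <- ifelse(is.na(whitelist$targets), .AMBIGUOUS, whitelist$targets)
  write.table(data.frame(variant = whitelist$variants, canonical = canon),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @param radius,strict Metadata restored onto the read index (the TSV
#'   stores only the variant map).
#' @rdname whitelist_io
#' @export
read_whitelist <- function(path, radius = NA_integer_, strict = TRUE) {
  tab <- read.table(path, sep = "\t", header = FALSE,
                    col.names = c("variant", "canonical"),
                    colClasses = "character")
  targets <- ifelse(tab$canonical == .AMBIGUOUS, NA_character_, tab$canonical)
  canonicals <- unique(targets[!is.na(targets)])
  dmin <- if (length(canonicals) >= 2L) min_pairwise_hamming(canonicals)
          else NA_integer_
  structure(list(canonicals = canonicals, radius = radius,
                 variants = tab$variant, targets = targets,
                 min_pairwise_distance = dmin, strict = strict),
            class = "whitelist_index")
}
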