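#' Read a FASTQ file
#'
#' Phred+33 FASTQ, gzip-compressed input handled transparently.  Parsed
#' with Biostrings; a malformed file is reported with the index of the
#' offending record where it can be determined.
#'
#' @param path FASTQ (optionally .gz) path.
#' @return Data frame with \code{id}, \code{sequence}, \code{quality}.
#' @export
read_fastq <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  nl <- 0L
  repeat {
    chunk <- length(readLines(con, n = 1000000L, warn = FALSE))
    nl <- nl + chunk
    if (chunk < 1000000L) break
  }
  close(con)
  if (nl %% 4L != 0L)
    stop("malformed FASTQ '", path, "': truncated at record ",
         nl %/% 4L + 1L, call. = FALSE)
  seqs <- tryCatch(
    withCallingHandlers(
      Biostrings::readQualityScaledDNAStringSet(path),
      # Biostrings warns that it drops the (empty) mcols it created
      # itself while pairing sequences with qualities; not actionable
      warning = function(w) {
        if (grepl("metadata columns", conditionMessage(w)))
          invokeRestart("muffleWarning")
      }),
    error = function(e) {
      stop("malformed FASTQ '", path, "': ", conditionMessage(e),
           call. = FALSE)
    })
  data.frame(id = unname(names(seqs)),
             sequence = unname(as.character(seqs)),
             quality = unname(as.character(Biostrings::quality(seqs))),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write records to FASTQ
#'
#' @param records Data frame with \code{id}, \code{sequence},
#'   \code{quality} (phred+33).  A missing quality column defaults to
#'   constant Q30.
#' @param path Output path; a \code{.gz} suffix enables compression.
#' @return The path, invisibly.
#' @export
write_fastq <- function(records, path) {
  qual <- if (!is.null(records$quality)) records$quality
          else strrep("?", nchar(records$sequence))
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(records$sequence),
    Biostrings::PhredQuality(qual))
  names(x) <- records$id
  Biostrings::writeQualityScaledXStringSet(
    x, path, compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Write a FASTA file
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTA file as a reference locus
#' @param path FASTA path (first record used).
#' @return A \code{\link{reference_locus}}.
#' @export
read_locus_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  reference_locus(names(x)[1], as.character(x[[1]]))
}

.track_granges <- function(track) {
  r <- rle(track$values)
  ends <- cumsum(r$lengths)
  GenomicRanges::GRanges(track$locus,
                         IRanges::IRanges(start = ends - r$lengths + 1L,
                                          end = ends),
                         score = signif(r$values, 6))
}

#' Write a track as bedGraph
#'
#' 0-based half-open bedGraph; runs of equal value are merged into
#' single lines and values printed to 6 significant digits.
#'
#' @param track A \code{\link{genomic_track}}.
#' @param path Output path.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "genomic_track"))
  if (any(!is.finite(track$values))) stop("track has non-finite values")
  rtracklayer::export.bedGraph(.track_granges(track), path)
  invisible(path)
}

#' Read a bedGraph file back into a track
#'
#' @param path bedGraph path.
#' @param locus_length Track length (positions not covered by any line
#'   are 0).
#' @param kind Track kind of the result.
#' @return A \code{\link{genomic_track}}.
#' @export
read_bedgraph <- function(path, locus_length,
                          kind = c("signal", "coverage", "log2_ratio")) {
  kind <- match.arg(kind)
  gr <- rtracklayer::import(path, format = "bedGraph")
  values <- numeric(locus_length)
  st <- GenomicRanges::start(gr); en <- GenomicRanges::end(gr)
  sc <- S4Vectors::mcols(gr)$score
  for (i in seq_along(gr)) values[st[i]:en[i]] <- sc[i]
  genomic_track(as.character(GenomicRanges::seqnames(gr))[1], values, kind)
}

#' Write peaks / regions of interest as BED
#'
#' @param rois Data frame with \code{name}, \code{start}, \code{end}
#'   (0-based half-open) and optionally \code{max_value} (used as BED
#'   score).
#' @param path Output path.
#' @param locus_name Chromosome / locus column value.
#' @export
write_bed <- function(rois, path, locus_name = "locus") {
  gr <- GenomicRanges::GRanges(locus_name,
                               IRanges::IRanges(start = rois$start + 1L,
                                                end = rois$end),
                               name = rois$name)
  if (!is.null(rois$max_value))
    S4Vectors::mcols(gr)$score <- pmin(1000, round(rois$max_value * 100))
  rtracklayer::export.bed(gr, path)
  invisible(path)
}

#' Read a BED file of regions
#' @param path BED path.
#' @return Data frame \code{name}, \code{start}, \code{end} (0-based
#'   half-open).
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(name = if (!is.null(S4Vectors::mcols(gr)$name))
                      S4Vectors::mcols(gr)$name
                    else paste0("roi_", seq_along(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
}

#' Read alignments from SAM
#'
#' For real data aligned externally: exposes reference name, 1-based
#' position, CIGAR, sequence and (optionally) a tag field carrying the
#' transcript barcode.
#'
#' @param path SAM (or BAM) path.
#' @param barcode_tag Optional two-letter tag holding the barcode.
#' @return Data frame with \code{qname}, \code{rname}, \code{pos},
#'   \code{cigar}, \code{seq} and, when requested, \code{barcode}.
#' @export
read_sam <- function(path, barcode_tag = NULL) {
  bam <- if (grepl("\\.sam$", path, ignore.case = TRUE))
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                     indexDestination = FALSE)
  else path
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "cigar", "seq"),
    tag = if (is.null(barcode_tag)) character(0) else barcode_tag)
  res <- Rsamtools::scanBam(bam, param = param)[[1]]
  out <- data.frame(qname = res$qname,
                    rname = as.character(res$rname),
                    pos = res$pos, cigar = res$cigar,
                    seq = as.character(res$seq),
                    stringsAsFactors = FALSE)
  if (!is.null(barcode_tag)) out$barcode <- res$tag[[barcode_tag]]
  out
}

#' Write / read a barcode-fragment association map as TSV
#'
#' Columns: barcode, start, end (0-based half-open), reads.
#'
#' @param map A \code{barcode_map}.
#' @param path File path.
#' @rdname association_io
#' @export
write_association <- function(map, path) {
  write.table(as.data.frame(map)[, c("barcode", "start", "end", "reads")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname association_io
#' @export
read_association <- function(path) {
  out <- read.table(path, sep = "\t", header = TRUE,
                    colClasses = c("character", "integer", "integer",
                                   "integer"))
  class(out) <- c("barcode_map", "data.frame")
  out
}

#' Write a per-position profile table as TSV
#'
#' @param profile A \code{position_profile} or \code{effect_profile}.
#' @param path File path.
#' @export
write_profile <- function(profile, path) {
  df <- as.data.frame(profile)
  num <- vapply(df, is.numeric, logical(1)) & names(df) != "position"
  df[num] <- lapply(df[num], signif, digits = 6)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sparse or dense cell-by-gene count matrix
#'
#' MTX triplet input (with row/column name sidecars) or dense TSV with
#' row names in the first column and gene names in the header.
#'
#' @param path .mtx or .tsv path.
#' @param cells,genes Sidecar paths (one name per line) for MTX input;
#'   rows of the MTX are cells, columns genes.
#' @return Matrix with cells in rows and genes in columns.
#' @export
read_count_matrix <- function(path, cells = NULL, genes = NULL) {
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    m <- as.matrix(Matrix::readMM(path))
    if (!is.null(cells)) rownames(m) <- readLines(cells)
    if (!is.null(genes)) colnames(m) <- readLines(genes)
    m
  } else {
    as.matrix(read.table(path, sep = "\t", header = TRUE, row.names = 1L,
                         check.names = FALSE))
  }
}
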