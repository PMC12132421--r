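#' Reference locus
#'
#' A named nucleotide sequence standing in for the BAC insert (LS-MPRA)
#' or the CRM amplicon (d-MPRA).  All interval coordinates in the package
#' are 0-based half-open on this sequence.
#'
#' @param name Locus identifier.
#' @param sequence A/C/G/T string.
#' @return A \code{reference_locus} list with \code{name},
#'   \code{sequence}, \code{length}.
#' @export
reference_locus <- function(name, sequence) {
  sequence <- toupper(as.character(sequence))
  if (grepl("[^ACGT]", sequence)) stop("sequence alphabet must be A/C/G/T")
  structure(list(name = name, sequence = sequence, length = nchar(sequence)),
            class = "reference_locus")
}

#' @export
print.reference_locus <- function(x, ...) {
  cat("reference_locus ", x$name, ": ", x$length, " nt\n", sep = "")
  invisible(x)
}

#' Generate a random reference locus
#'
#' @param length Locus length in nt.
#' @param name Locus identifier.
#' @return A \code{\link{reference_locus}}.
#' @export
random_locus <- function(length, name = "locus") {
  bases <- c("A", "C", "G", "T")
  reference_locus(name,
                  paste(bases[sample.int(4L, length, replace = TRUE)],
                        collapse = ""))
}

# Fixed synthetic 20-mers standing in for the vector context flanking the
# transcribed barcode, and a filler for the constant downstream sequence.
.ANCHOR_LEFT  <- "ACGGTCTAGCATCGACTGTA"
.ANCHOR_RIGHT <- "TGACGTCAGTACGGATCTCA"
.FILLER <- paste(rep("GATCCAGTTACGCTAGGCTA", 10L), collapse = "")

#' Simulation configuration
#'
#' Houses the knobs of the synthetic-data generator.  Defaults encode the
#' desk-scale study conditions: 400-600 nt size-selected fragments, 2x150
#' paired-end reads, 0.5\% per-base substitution error, and for the
#' degenerate-MPRA clone pool a per-nucleotide mutation frequency
#' \code{mu} of 0.1\% (the error-prone PCR regime of roughly 0.02-0.2\%
#' per nucleotide) with 10\% of mutations being 1-nt deletions.
#'
#' @param fragment_size_range Length-2 integer, fragment size bounds (nt).
#' @param n_fragments Number of fragments in the association library.
#' @param seq_error_rate Per-base substitution error probability of raw
#'   reads.
#' @param mu Per-nucleotide mutation probability of the error-prone PCR
#'   clone pool.
#' @param deletion_fraction Share of clone mutations that are 1-nt
#'   deletions (the rest are substitutions).
#' @param read_depth Reads per fragment (association) or total-read
#'   multiplier (cDNA).
#' @param read_length Read length in nt (2x150 bp paired-end layout).
#' @param barcode_pattern \code{\link{degenerate_pattern}} of the
#'   transcript barcode.
#' @param anchor_left,anchor_right Constant sequences flanking the
#'   barcode on read 1.
#' @param seed Optional integer; when non-NULL the generator calls
#'   \code{set.seed(seed)} before drawing.
#' @return A \code{sim_config} list.
#' @export
sim_config <- function(fragment_size_range = c(400L, 600L),
                       n_fragments = 1000L,
                       seq_error_rate = 0.005,
                       mu = 0.001,
                       deletion_fraction = 0.1,
                       read_depth = 100L,
                       read_length = 150L,
                       barcode_pattern = degenerate_pattern("SW", 12L),
                       anchor_left = .ANCHOR_LEFT,
                       anchor_right = .ANCHOR_RIGHT,
                       seed = NULL) {
  stopifnot(length(fragment_size_range) == 2L,
            fragment_size_range[1] <= fragment_size_range[2],
            n_fragments >= 1, read_length >= 1,
            seq_error_rate >= 0, seq_error_rate <= 1,
            mu >= 0, mu <= 1,
            deletion_fraction >= 0, deletion_fraction <= 1)
  structure(list(fragment_size_range = as.integer(fragment_size_range),
                 n_fragments = as.integer(n_fragments),
                 seq_error_rate = seq_error_rate, mu = mu,
                 deletion_fraction = deletion_fraction,
                 read_depth = as.integer(read_depth),
                 read_length = as.integer(read_length),
                 barcode_pattern = barcode_pattern,
                 anchor_left = anchor_left, anchor_right = anchor_right,
                 seed = seed),
            class = "sim_config")
}

#' Simulation configuration for d-MPRA libraries
#'
#' \code{\link{sim_config}} with defaults for degenerate-MPRA amplicon
#' simulations: the read-pair layout fully overlaps the CRM, so the
#' effective per-base error is the residual consensus error of
#' overlap-merged amplicon sequencing (about 1e-4) rather than the raw
#' instrument rate - it must sit well below \code{mu} or the
#' experimental/plasmid frequency ratio is diluted toward 1.
#'
#' @param seq_error_rate Residual per-base substitution error
#'   (default 1e-4).
#' @param ... Passed to \code{\link{sim_config}}.
#' @return A \code{sim_config}.
#' @export
dmpra_config <- function(seq_error_rate = 1e-4, ...) {
  sim_config(seq_error_rate = seq_error_rate, ...)
}

.maybe_seed <- function(cfg) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  invisible(NULL)
}

#' Planted per-base activity landscape
#'
#' Ground truth for the LS-MPRA simulator: a nonnegative activity value
#' per locus position plus a positive baseline.  A fragment's sampling
#' weight in the cDNA library is \code{baseline + max(activity over the
#' fragment interval)} - a CRM drives the whole reporter regardless of
#' where it sits within the fragment.
#'
#' CRMs are planted as raised-cosine bumps: activity at distance d from a
#' CRM centre of span w is \code{amplitude * (1 + cos(2*pi*d/w)) / 2} for
#' \code{|d| < w/2}, 0 outside.  The graded flanks emulate regulatory
#' elements whose activity decays with truncation and keep per-fragment
#' weights continuous rather than binary.
#'
#' @param locus_length Locus length (nt).
#' @param crm_centers Integer vector of CRM centre positions (0-based).
#' @param crm_span Full width of each bump in nt (default 6000).
#' @param amplitude Peak activity; with \code{baseline = 1} an amplitude
#'   of 3 gives a 4x expression ratio at the CRM centre.
#' @param baseline Baseline expression weight (default 1).
#' @return An \code{activity_landscape}: list with \code{activity}
#'   (numeric per position), \code{baseline}, \code{crm_centers},
#'   \code{crm_span}.
#' @export
activity_landscape <- function(locus_length, crm_centers = integer(0),
                               crm_span = 6000L, amplitude = 3,
                               baseline = 1) {
  stopifnot(locus_length >= 1, baseline > 0, amplitude >= 0)
  activity <- numeric(locus_length)
  half <- crm_span / 2
  for (ctr in crm_centers) {
    lo <- max(0L, floor(ctr - half)); hi <- min(locus_length - 1L, ceiling(ctr + half))
    pos <- lo:hi
    d <- abs(pos - ctr)
    bump <- ifelse(d < half, amplitude * (1 + cos(pi * d / half)) / 2, 0)
    activity[pos + 1L] <- pmax(activity[pos + 1L], bump)
  }
  structure(list(activity = activity, baseline = baseline,
                 crm_centers = as.integer(crm_centers),
                 crm_span = crm_span),
            class = "activity_landscape")
}

#' Random fragmentation of a locus
#'
#' Emulates enzymatic fragmentation followed by size selection: fragment
#' sizes are uniform within \code{cfg$fragment_size_range}, starts are
#' uniform over the positions at which the fragment fits inside the
#' locus, and each fragment receives a fresh degenerate barcode.
#'
#' @param locus A \code{\link{reference_locus}}.
#' @param cfg A \code{\link{sim_config}}.
#' @return Data frame (class \code{fragment_set}) with columns
#'   \code{start}, \code{end} (0-based half-open), \code{barcode}.
#' @export
fragment_locus <- function(locus, cfg = sim_config()) {
  stopifnot(inherits(locus, "reference_locus"))
  if (cfg$fragment_size_range[2] > locus$length)
    stop("max fragment size exceeds locus length")
  .maybe_seed(cfg)
  n <- cfg$n_fragments
  sizes <- sample.int(diff(cfg$fragment_size_range) + 1L, n,
                      replace = TRUE) + cfg$fragment_size_range[1] - 1L
  starts <- vapply(locus$length - sizes + 1L,
                   function(m) sample.int(m, 1L), integer(1)) - 1L
  barcodes <- sample_barcodes(n, cfg$barcode_pattern)
  out <- data.frame(start = starts, end = starts + sizes,
                    barcode = barcodes, stringsAsFactors = FALSE)
  class(out) <- c("fragment_set", "data.frame")
  attr(out, "locus_name") <- locus$name
  out
}

.frag_seq <- function(fragments, locus) {
  substring(locus$sequence, fragments$start + 1L, fragments$end)
}

#' Per-fragment expression weights under a planted landscape
#'
#' @param fragments A \code{\link{fragment_locus}} result.
#' @param landscape An \code{\link{activity_landscape}}.
#' @return Numeric weights, \code{baseline + max(activity)} per fragment.
#' @export
fragment_weights <- function(fragments, landscape) {
  a <- landscape$activity
  landscape$baseline +
    vapply(seq_len(nrow(fragments)),
           function(i) max(a[(fragments$start[i] + 1L):fragments$end[i]]),
           numeric(1))
}

#' Simulate association-library read pairs
#'
#' Read 1 carries the barcode between the two constant anchors followed
#' by the reverse complement of the fragment's 3' end; read 2 is the
#' fragment's 5' prefix.  This mirrors the paired layout in which one
#' mate identifies the barcode and the fragment end while the other maps
#' the fragment start, so error-free pairs recover the exact fragment
#' interval.  Substitution errors are injected at
#' \code{cfg$seq_error_rate}; each fragment receives exactly
#' \code{cfg$read_depth} pairs.
#'
#' @param fragments A \code{\link{fragment_locus}} result.
#' @param locus The \code{\link{reference_locus}} the fragments tile.
#' @param cfg A \code{\link{sim_config}}.
#' @return Data frame with columns \code{read1}, \code{read2} and
#'   attribute \code{fragment} (1-based origin index per pair).
#' @export
simulate_association_reads <- function(fragments, locus, cfg = sim_config()) {
  .maybe_seed(cfg)
  depth <- cfg$read_depth
  if (depth < 1) stop("read depth must be >= 1")
  idx <- rep(seq_len(nrow(fragments)), each = depth)
  fseq <- .frag_seq(fragments, locus)
  tail_len <- cfg$read_length -
    nchar(cfg$anchor_left) - cfg$barcode_pattern$length -
    nchar(cfg$anchor_right)
  if (tail_len < 0) stop("read too short for anchors + barcode")
  flen <- nchar(fseq)
  tail_len_i <- pmin(tail_len, flen)
  tail_seq <- revcomp(substring(fseq, flen - tail_len_i + 1L, flen))
  read1 <- paste0(cfg$anchor_left, fragments$barcode, cfg$anchor_right,
                  tail_seq)[idx]
  read2 <- substring(fseq, 1L, pmin(cfg$read_length, flen))[idx]
  if (cfg$seq_error_rate > 0) {
    read1 <- .mutate_bases_cpp(read1, cfg$seq_error_rate)
    read2 <- .mutate_bases_cpp(read2, cfg$seq_error_rate)
  }
  out <- data.frame(read1 = read1, read2 = read2, stringsAsFactors = FALSE)
  attr(out, "fragment") <- idx
  out
}

#' Simulate cDNA barcode reads
#'
#' Fragments are sampled multinomially with weight
#' \code{baseline + max(activity over fragment)}; each sampled fragment
#' emits one barcode-bearing transcript read (anchors + barcode +
#' constant filler), with substitution errors at
#' \code{cfg$seq_error_rate}.
#'
#' @param fragments A \code{\link{fragment_locus}} result.
#' @param landscape An \code{\link{activity_landscape}} over the same
#'   locus.
#' @param cfg A \code{\link{sim_config}}.
#' @param n_reads Total reads to draw (default
#'   \code{cfg$read_depth * nrow(fragments)}).
#' @return Character vector of reads with attributes \code{fragment}
#'   (origin index per read) and \code{weights} (the planted
#'   per-fragment weights).
#' @export
simulate_cdna_reads <- function(fragments, landscape, cfg = sim_config(),
                                n_reads = cfg$read_depth * nrow(fragments)) {
  if (length(landscape$activity) < max(fragments$end))
    stop("landscape shorter than fragment coordinates")
  .maybe_seed(cfg)
  w <- fragment_weights(fragments, landscape)
  if (all(w <= 0)) stop("all fragment weights are zero")
  if (n_reads == 0)
    return(structure(character(0), fragment = integer(0), weights = w))
  idx <- sample.int(nrow(fragments), n_reads, replace = TRUE, prob = w)
  body <- paste0(cfg$anchor_left, fragments$barcode, cfg$anchor_right)
  pad_len <- cfg$read_length - nchar(body[1])
  pad <- if (pad_len > 0) substr(.FILLER, 1L, pad_len) else ""
  reads <- paste0(body, pad)[idx]
  if (cfg$seq_error_rate > 0) reads <- .mutate_bases_cpp(reads, cfg$seq_error_rate)
  structure(reads, fragment = idx, weights = w)
}

#' Simulate an error-prone PCR clone pool
#'
#' Each clone mutates every reference position independently with
#' probability \code{cfg$mu}; a mutated position becomes a uniformly
#' chosen different base, or a 1-nt deletion with probability
#' \code{cfg$deletion_fraction}.
#'
#' @param crm A \code{\link{reference_locus}} holding the CRM sequence.
#' @param cfg A \code{\link{sim_config}} (fields \code{mu},
#'   \code{deletion_fraction}, \code{seed}).
#' @param n_clones Number of clones in the pool.
#' @return A \code{clone_pool}: list with \code{sequences} (character),
#'   \code{mutations} (data frame \code{clone}, \code{position} 0-based
#'   on the reference, \code{ref}, \code{alt} with \code{"-"} for
#'   deletion, \code{kind}), and \code{reference}.
#' @export
simulate_dmpra_clones <- function(crm, cfg = sim_config(), n_clones = 1000L) {
  stopifnot(inherits(crm, "reference_locus"))
  .maybe_seed(cfg)
  L <- crm$length
  ref_chars <- strsplit(crm$sequence, "")[[1]]
  n_mut <- rbinom(n_clones, L, cfg$mu)
  mut_clone <- integer(0); mut_pos <- integer(0)
  mut_alt <- character(0)
  sequences <- rep(crm$sequence, n_clones)
  bases <- c("A", "C", "G", "T")
  for (i in which(n_mut > 0L)) {
    pos <- sort(sample.int(L, n_mut[i]))          # 1-based
    is_del <- runif(n_mut[i]) < cfg$deletion_fraction
    alt <- character(n_mut[i])
    alt[is_del] <- "-"
    if (any(!is_del))
      alt[!is_del] <- vapply(pos[!is_del], function(p)
        sample(setdiff(bases, ref_chars[p]), 1L), character(1))
    chars <- ref_chars
    chars[pos] <- ifelse(is_del, "", alt)
    sequences[i] <- paste(chars, collapse = "")
    mut_clone <- c(mut_clone, rep(i, n_mut[i]))
    mut_pos <- c(mut_pos, pos - 1L)
    mut_alt <- c(mut_alt, alt)
  }
  mutations <- data.frame(clone = mut_clone, position = mut_pos,
                          ref = ref_chars[mut_pos + 1L], alt = mut_alt,
                          kind = ifelse(mut_alt == "-", "deletion",
                                        "substitution"),
                          stringsAsFactors = FALSE)
  structure(list(sequences = sequences, mutations = mutations,
                 reference = crm, n_clones = n_clones),
            class = "clone_pool")
}

#' Per-position multiplicative effect map
#'
#' Ground truth for d-MPRA simulations: the factor by which a mutation at
#' each CRM position changes the clone's expression weight.  Factors
#' below 1 mark activator-binding nucleotides (mutating them loses
#' expression, so they are depleted in the experimental library and
#' appear as troughs in the effect profile); factors above 1 mark
#' repressor sites (peaks).
#'
#' @param length CRM length (nt).
#' @param sites Data frame with columns \code{start}, \code{end}
#'   (0-based half-open) and \code{factor}.
#' @return Numeric vector of length \code{length}.
#' @export
effect_map <- function(length, sites = NULL) {
  em <- rep(1, length)
  if (!is.null(sites)) {
    for (i in seq_len(nrow(sites)))
      em[(sites$start[i] + 1L):sites$end[i]] <- sites$factor[i]
  }
  em
}

#' Simulate d-MPRA read pairs over the duplicated CRM barcode
#'
#' Clones are sampled uniformly for plasmid libraries; for experimental
#' libraries each clone's weight is the product of effect-map factors
#' over its mutated positions (wild-type clones have weight 1).  Each
#' sampled clone emits an overlapping read pair spanning the full
#' mutated CRM copy: read 1 is the clone 5' prefix, read 2 the reverse
#' complement of the clone 3' suffix.  Substitution errors are injected
#' at \code{cfg$seq_error_rate}; post-merge consensus error in the
#' overlap is handled downstream by quality-aware merging.
#'
#' @param clones A \code{\link{simulate_dmpra_clones}} pool.
#' @param em Per-position effect map (\code{\link{effect_map}});
#'   ignored for plasmid libraries.
#' @param cfg A \code{\link{sim_config}}.
#' @param library_kind \code{"plasmid"} or \code{"experimental"}.
#' @param n_reads Number of read pairs.
#' @return Data frame with columns \code{read1}, \code{qual1},
#'   \code{read2}, \code{qual2} and attribute \code{clone} (origin
#'   index per pair).
#' @export
simulate_dmpra_reads <- function(clones, em, cfg = sim_config(),
                                 library_kind = c("plasmid", "experimental"),
                                 n_reads = 10000L) {
  library_kind <- match.arg(library_kind)
  stopifnot(inherits(clones, "clone_pool"))
  .maybe_seed(cfg)
  L <- clones$reference$length
  if (length(em) != L) stop("effect map must cover every CRM position")
  if (library_kind == "plasmid") {
    w <- rep(1, clones$n_clones)
  } else {
    w <- rep(1, clones$n_clones)
    mt <- clones$mutations
    if (nrow(mt)) {
      fac <- vapply(split(em[mt$position + 1L], mt$clone), prod, numeric(1))
      w[as.integer(names(fac))] <- fac
    }
  }
  idx <- sample.int(clones$n_clones, n_reads, replace = TRUE, prob = w)
  seqs <- clones$sequences[idx]
  len <- nchar(seqs)
  rl <- pmin(cfg$read_length, len)
  read1 <- substring(seqs, 1L, rl)
  read2 <- revcomp(substring(seqs, len - rl + 1L, len))
  if (cfg$seq_error_rate > 0) {
    read1 <- .mutate_bases_cpp(read1, cfg$seq_error_rate)
    read2 <- .mutate_bases_cpp(read2, cfg$seq_error_rate)
  }
  q <- strrep("?", rl)     # constant Q30, phred+33
  out <- data.frame(read1 = read1, qual1 = q, read2 = read2, qual2 = q,
                    stringsAsFactors = FALSE)
  attr(out, "clone") <- idx
  out
}
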