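#' Merge overlapping read pairs
#'
#' Read 2 is reverse-complemented, the best suffix(read1)/prefix(read2)
#' overlap of at least \code{min_overlap} nt with mismatch fraction at
#' most \code{max_mismatch_fraction} is chosen, and disagreeing overlap
#' bases resolve to the higher-quality base (ties to read 1).  Pairs
#' with no qualifying overlap yield \code{NA} rows (typed failures the
#' caller counts).
#'
#' @param read1,qual1 Read 1 sequences and phred+33 quality strings.
#' @param read2,qual2 Read 2 (as sequenced; reverse-complemented
#'   internally).
#' @param min_overlap Minimum overlap length in nt (default 20).
#' @param max_mismatch_fraction Maximum mismatch fraction in the
#'   overlap (default 0.1).
#' @return Data frame with \code{sequence}, \code{quality},
#'   \code{overlap}, \code{mismatches}; attribute \code{n_failed}.
#' @export
merge_pairs <- function(read1, qual1, read2, qual2,
                        min_overlap = 20L, max_mismatch_fraction = 0.1) {
  stopifnot(length(read1) == length(read2))
  r2 <- revcomp(read2)
  q2 <- .reverse_strings(as.character(qual2))
  res <- .merge_pairs_cpp(as.character(read1), as.character(qual1),
                          r2, q2, as.integer(min_overlap),
                          max_mismatch_fraction)
  out <- data.frame(sequence = res$sequence, quality = res$quality,
                    overlap = res$overlap, mismatches = res$mismatches,
                    stringsAsFactors = FALSE)
  attr(out, "n_failed") <- sum(is.na(res$sequence))
  out
}

#' Find homopolymer runs in a reference sequence
#'
#' Maximal runs of a single base with length at least \code{min_run}.
#' Deletions inside such runs have ambiguous coordinates and are
#' filtered out of mutation calls.
#'
#' @param ref Reference sequence (single string).
#' @param min_run Minimum run length (default 3).
#' @return Data frame with \code{start}, \code{end} (0-based half-open)
#'   and \code{base}.
#' @export
find_homopolymers <- function(ref, min_run = 3L) {
  stopifnot(min_run >= 2)
  chars <- strsplit(toupper(ref), "")[[1]]
  r <- rle(chars)
  ends <- cumsum(r$lengths)
  keep <- r$lengths >= min_run
  data.frame(start = (ends - r$lengths)[keep], end = ends[keep],
             base = r$values[keep], stringsAsFactors = FALSE)
}

#' Align merged reads to the CRM reference and call mutations
#'
#' Reads whose length equals the reference take a gap-free fast path
#' (under the affine scoring used here - match +1, mismatch -2, gap
#' open -4, extend -1 - the optimal global alignment of equal-length
#' sequences at low divergence has no gaps, so position-wise comparison
#' is exact).  Other reads are globally aligned with those affine-gap
#' scores via \code{Biostrings::pairwiseAlignment}.  Reads failing to
#' align fully across the reference are discarded and counted: the
#' aligned reference range must cover every reference position, and no
#' deletion run may exceed \code{max_deletion_run} nt (a truncated read
#' masquerades as one long deletion).  Reads more divergent than
#' \code{max_divergence} also fail.
#'
#' @param reads Character vector of merged read sequences (NA rows
#'   allowed; they fail).
#' @param crm_ref Reference sequence (single string).
#' @param max_divergence Maximum fraction of called positions per read
#'   (guards against foreign sequence; default 0.2).
#' @param max_deletion_run Longest deletion accepted as a genuine
#'   mutation rather than a truncation artifact (default 3 nt).
#' @return A \code{mutation_calls}: list with \code{n_reads},
#'   \code{read_ids} (ids of full-span reads), \code{calls} (data frame
#'   \code{read}, \code{position} 0-based, \code{kind}, \code{ref},
#'   \code{alt}) and \code{n_failed}.
#' @export
align_and_call <- function(reads, crm_ref, max_divergence = 0.2,
                           max_deletion_run = 3L) {
  crm_ref <- toupper(as.character(crm_ref))
  if (!nchar(crm_ref)) stop("reference must be nonempty")
  L <- nchar(crm_ref)
  reads <- as.character(reads)
  n <- length(reads)
  failed <- is.na(reads)
  eq <- !failed & nchar(reads) == L
  calls_list <- list()
  if (any(eq)) {
    res <- .call_substitutions_cpp(reads[eq], crm_ref)
    calls_eq <- data.frame(read = which(eq)[res$read],
                           position = res$position,
                           kind = rep("substitution", length(res$position)),
                           ref = res$ref, alt = res$alt,
                           stringsAsFactors = FALSE)
    # apply the divergence guard to the fast path too
    nmut <- tabulate(match(calls_eq$read, which(eq)), nbins = sum(eq))
    bad <- which(eq)[nmut / L > max_divergence]
    failed[bad] <- TRUE
    calls_list$eq <- calls_eq[!(calls_eq$read %in% bad), , drop = FALSE]
  }
  oth <- which(!failed & nchar(reads) != L)
  if (length(oth)) {
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2)
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(reads[oth]),
      Biostrings::DNAString(crm_ref),
      type = "global", substitutionMatrix = mat,
      gapOpening = 4, gapExtension = 1)
    sub_aln <- Biostrings::subject(aln)
    # full-span rule: the aligned reference range must be 1..L, and no
    # deletion run longer than max_deletion_run
    dels <- Biostrings::deletion(Biostrings::indel(aln))
    spans <- BiocGenerics::start(sub_aln) == 1L &
      BiocGenerics::end(sub_aln) == L
    too_long <- vapply(dels, function(d)
      length(d) > 0 && max(BiocGenerics::width(d)) > max_deletion_run,
      logical(1))
    mt <- Biostrings::mismatchTable(aln)
    n_sub <- tabulate(mt$PatternId, nbins = length(oth))
    n_del <- vapply(dels, function(d) sum(BiocGenerics::width(d)),
                    numeric(1))
    bad_i <- !spans | too_long | (n_sub + n_del) / L > max_divergence
    failed[oth[bad_i]] <- TRUE
    ok_i <- which(!bad_i)
    sub_calls <- if (nrow(mt)) {
      keep <- mt$PatternId %in% ok_i
      data.frame(read = oth[mt$PatternId[keep]],
                 position = mt$SubjectStart[keep] - 1L,
                 kind = "substitution",
                 ref = as.character(mt$SubjectSubstring[keep]),
                 alt = as.character(mt$PatternSubstring[keep]),
                 stringsAsFactors = FALSE)
    } else NULL
    ref_chars <- strsplit(crm_ref, "")[[1]]
    del_calls <- do.call(rbind, lapply(ok_i, function(i) {
      d <- dels[[i]]
      if (!length(d)) return(NULL)
      p <- unlist(lapply(seq_along(d), function(j)
        BiocGenerics::start(d)[j]:BiocGenerics::end(d)[j]))
      data.frame(read = oth[i], position = p - 1L, kind = "deletion",
                 ref = ref_chars[p], alt = "-", stringsAsFactors = FALSE)
    }))
    calls_list$oth <- rbind(sub_calls, del_calls)
  }
  calls <- do.call(rbind, calls_list)
  if (is.null(calls))
    calls <- data.frame(read = integer(0), position = integer(0),
                        kind = character(0), ref = character(0),
                        alt = character(0), stringsAsFactors = FALSE)
  calls <- calls[, c("read", "position", "kind", "ref", "alt")]
  rownames(calls) <- NULL
  structure(list(n_reads = n, read_ids = which(!failed), calls = calls,
                 n_failed = sum(failed), reference = crm_ref),
            class = "mutation_calls")
}

#' Filter mutation calls for homopolymer-deletion artifacts
#'
#' A read carrying any deletion call inside a homopolymer run is
#' dropped entirely (read-level exclusion); substitutions inside
#' homopolymers are unaffected, and call-free (wild-type) reads always
#' pass.
#'
#' @param mc A \code{\link{align_and_call}} result.
#' @param homopolymers A \code{\link{find_homopolymers}} table.
#' @return The filtered \code{mutation_calls}, with attribute
#'   \code{dropped_homopolymer} (number of reads removed).
#' @export
filter_calls <- function(mc, homopolymers) {
  stopifnot(inherits(mc, "mutation_calls"))
  calls <- mc$calls
  in_hp <- rep(FALSE, nrow(calls))
  if (nrow(homopolymers) && nrow(calls)) {
    del <- calls$kind == "deletion"
    for (i in seq_len(nrow(homopolymers))) {
      in_hp <- in_hp | (del & calls$position >= homopolymers$start[i] &
                          calls$position < homopolymers$end[i])
    }
  }
  bad_reads <- unique(calls$read[in_hp])
  out <- mc
  out$read_ids <- setdiff(mc$read_ids, bad_reads)
  out$calls <- calls[!(calls$read %in% bad_reads), , drop = FALSE]
  attr(out, "dropped_homopolymer") <- length(bad_reads)
  out
}

#' Monte-Carlo subsampling configuration
#'
#' @param replicates Number of independent subsampling replicates
#'   (default 10).
#' @param subsample_depth Reads drawn (without replacement) per
#'   replicate; default NULL = 80\% of the available reads, set at
#'   tally time.
#' @param seed Optional integer seed applied before subsampling.
#' @return An \code{mc_config} list.
#' @export
mc_config <- function(replicates = 10L, subsample_depth = NULL,
                      seed = NULL) {
  stopifnot(replicates >= 1)
  structure(list(replicates = as.integer(replicates),
                 subsample_depth = subsample_depth, seed = seed),
            class = "mc_config")
}

#' Per-position mutation frequencies with Monte-Carlo subsampling
#'
#' For each replicate, \code{subsample_depth} retained reads are drawn
#' without replacement; the primary per-position frequency is
#' (substitution + deletion count) / (wild-type read count in the
#' replicate), and the per-coverage rate (count / subsampled reads) is
#' reported alongside.  Means and standard deviations are taken across
#' replicates.
#'
#' @param mc A (filtered) \code{\link{align_and_call}} result.
#' @param config An \code{\link{mc_config}}.
#' @return A \code{position_profile}: data frame with \code{position}
#'   (0-based), \code{freq_wt_mean}, \code{freq_wt_sd},
#'   \code{rate_mean}, \code{rate_sd}, \code{sub_mean},
#'   \code{del_mean}; attributes \code{replicates}, \code{depth},
#'   \code{n_retained}, \code{wt_mean} (mean wild-type reads per
#'   replicate) and \code{reference}.
#' @export
tally_mutations <- function(mc, config = mc_config()) {
  stopifnot(inherits(mc, "mutation_calls"))
  ids <- mc$read_ids
  L <- nchar(mc$reference)
  depth <- config$subsample_depth
  if (is.null(depth)) depth <- floor(0.8 * length(ids))
  if (depth > length(ids))
    stop("subsample depth ", depth, " exceeds retained reads ",
         length(ids))
  if (depth < 1) stop("no reads to subsample")
  if (!is.null(config$seed)) set.seed(config$seed)
  calls <- mc$calls
  mutated <- unique(calls$read)
  R <- config$replicates
  freq <- rate <- subs <- dels <- matrix(0, nrow = L, ncol = R)
  wt_counts <- integer(R)
  for (r in seq_len(R)) {
    take <- ids[sample.int(length(ids), depth)]
    inset <- calls$read %in% take
    wt <- depth - length(unique(calls$read[inset]))
    if (wt == 0)
      stop("no wild-type reads in a subsampling replicate; increase ",
           "depth or check the mutation load")
    cs <- calls[inset, ]
    sub_c <- tabulate(cs$position[cs$kind == "substitution"] + 1L, nbins = L)
    del_c <- tabulate(cs$position[cs$kind == "deletion"] + 1L, nbins = L)
    subs[, r] <- sub_c; dels[, r] <- del_c
    freq[, r] <- (sub_c + del_c) / wt
    rate[, r] <- (sub_c + del_c) / depth
    wt_counts[r] <- wt
  }
  sd_or_zero <- function(m) if (R > 1) apply(m, 1, sd) else rep(0, L)
  out <- data.frame(position = 0:(L - 1L),
                    freq_wt_mean = rowMeans(freq),
                    freq_wt_sd = sd_or_zero(freq),
                    rate_mean = rowMeans(rate),
                    rate_sd = sd_or_zero(rate),
                    sub_mean = rowMeans(subs),
                    del_mean = rowMeans(dels))
  class(out) <- c("position_profile", "data.frame")
  attr(out, "replicates") <- R
  attr(out, "depth") <- depth
  attr(out, "n_retained") <- length(ids)
  attr(out, "wt_mean") <- mean(wt_counts)
  attr(out, "reference") <- mc$reference
  out
}

#' Raw per-position effect profile
#'
#' log2 ratio of experimental to plasmid wild-type-normalised mutation
#' frequencies; only positions with nonzero frequency in both libraries
#' are retained (others are NA and recorded).
#'
#' @param experimental,plasmid \code{\link{tally_mutations}} profiles
#'   over the same reference.
#' @return An \code{effect_profile}: data frame \code{position},
#'   \code{value} (NA where dropped), with attributes
#'   \code{reference_length}, \code{dropped_positions}, \code{stage}.
#' @export
effect_profile <- function(experimental, plasmid) {
  stopifnot(inherits(experimental, "position_profile"),
            inherits(plasmid, "position_profile"))
  if (attr(experimental, "reference") != attr(plasmid, "reference"))
    stop("profiles come from different references")
  fe <- experimental$freq_wt_mean
  fp <- plasmid$freq_wt_mean
  shared <- fe > 0 & fp > 0
  if (!any(shared)) stop("no positions shared by both libraries")
  value <- rep(NA_real_, length(fe))
  value[shared] <- log2(fe[shared] / fp[shared])
  out <- data.frame(position = experimental$position, value = value)
  class(out) <- c("effect_profile", "data.frame")
  attr(out, "reference_length") <- length(fe)
  attr(out, "dropped_positions") <- experimental$position[!shared]
  attr(out, "stage") <- list(baseline_corrected = FALSE, smoothed = FALSE,
                             trimmed = FALSE)
  attr(out, "window") <- NA_integer_
  attr(out, "head_trim") <- 0L
  attr(out, "tail_trim") <- 0L
  out
}

# NA-aware centred moving average with a shrinking window at the ends:
# each output is the mean of the values present within +/- (w-1)/2.
.moving_average <- function(x, window) {
  h <- (window - 1L) %/% 2L
  n <- length(x)
  ok <- !is.na(x)
  xz <- ifelse(ok, x, 0)
  cs <- cumsum(c(0, xz))
  cn <- cumsum(c(0, as.numeric(ok)))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  tot <- cs[hi + 1L] - cs[lo]
  cnt <- cn[hi + 1L] - cn[lo]
  ifelse(cnt > 0, tot / cnt, NA_real_)
}

#' Baseline-correct, smooth and trim an effect profile
#'
#' Order of operations: (1) subtract the median value (baseline
#' correction, making the profile invariant to uniform offsets), (2)
#' centred moving average of odd width \code{window} over the positions
#' present (the window shrinks at profile ends rather than padding),
#' (3) drop the first \code{head_trim} and last \code{tail_trim}
#' reference positions, which carry construct-assembly sequence rather
#' than CRM information.
#'
#' @param raw A raw \code{\link{effect_profile}}.
#' @param window Smoothing window in positions (odd, default 5).
#' @param head_trim,tail_trim Excluded flank lengths (defaults 18 and
#'   14).
#' @return The finalised \code{effect_profile} (length
#'   \code{reference_length - head_trim - tail_trim}).
#' @export
finalize_profile <- function(raw, window = 5L, head_trim = 18L,
                             tail_trim = 14L) {
  stopifnot(inherits(raw, "effect_profile"))
  if (window %% 2L != 1L || window < 1L) stop("window must be odd and >= 1")
  L <- attr(raw, "reference_length")
  if (L <= head_trim + tail_trim + window)
    stop("profile too short for the requested trims and window")
  v <- raw$value - median(raw$value, na.rm = TRUE)
  v <- .moving_average(v, window)
  keep <- raw$position >= head_trim & raw$position < L - tail_trim
  out <- data.frame(position = raw$position[keep], value = v[keep])
  class(out) <- c("effect_profile", "data.frame")
  attr(out, "reference_length") <- L
  attr(out, "dropped_positions") <- attr(raw, "dropped_positions")
  attr(out, "stage") <- list(baseline_corrected = TRUE, smoothed = TRUE,
                             trimmed = TRUE)
  attr(out, "window") <- as.integer(window)
  attr(out, "head_trim") <- as.integer(head_trim)
  attr(out, "tail_trim") <- as.integer(tail_trim)
  out
}

#' Average effect profiles across replicates
#'
#' Per-position arithmetic mean over the replicates in which the
#' position is present (non-NA); positions absent from every replicate
#' stay NA.
#'
#' @param profiles List of \code{effect_profile}s at the same stage
#'   over the same reference.
#' @return An \code{effect_profile} with an added \code{sd} column
#'   (between-replicate standard deviation).
#' @export
average_replicates <- function(profiles) {
  if (!length(profiles)) stop("empty profile list")
  stopifnot(all(vapply(profiles, inherits, logical(1), "effect_profile")))
  Ls <- vapply(profiles, function(p) attr(p, "reference_length"), numeric(1))
  if (length(unique(Ls)) != 1L) stop("profiles span different references")
  st <- lapply(profiles, attr, "stage")
  if (length(unique(vapply(st, function(s) paste(unlist(s), collapse = ","),
                           character(1)))) != 1L)
    stop("profiles are at different processing stages")
  pos <- profiles[[1]]$position
  vals <- vapply(profiles, function(p) p$value, numeric(length(pos)))
  vals <- matrix(vals, nrow = length(pos))
  out <- data.frame(position = pos,
                    value = rowMeans(vals, na.rm = TRUE),
                    sd = if (length(profiles) > 1)
                           apply(vals, 1, sd, na.rm = TRUE)
                         else rep(0, length(pos)))
  out$value[is.nan(out$value)] <- NA_real_
  class(out) <- c("effect_profile", "data.frame")
  for (a in c("reference_length", "stage", "window", "head_trim",
              "tail_trim"))
    attr(out, a) <- attr(profiles[[1]], a)
  attr(out, "n_replicates") <- length(profiles)
  out
}

#' Full d-MPRA profiling pipeline over in-memory read pairs
#'
#' Runs merge, align-and-call, homopolymer filtering, Monte-Carlo
#' tallying, effect-profile computation, finalisation and replicate
#' averaging.
#'
#' @param plasmid Data frame of plasmid-library read pairs
#'   (\code{read1}, \code{qual1}, \code{read2}, \code{qual2}).
#' @param experimental List of such data frames, one per experimental
#'   replicate.
#' @param crm_ref CRM reference sequence.
#' @param window,head_trim,tail_trim Finalisation parameters (defaults
#'   5, 18, 14).
#' @param mc \code{\link{mc_config}} for subsampling (default 10
#'   replicates, depth 80\% of the smallest library).
#' @param min_overlap,max_mismatch_fraction Merge parameters.
#' @param homopolymer_min_run Minimum homopolymer run filtered
#'   (default 3).
#' @return List with \code{averaged} (final averaged
#'   \code{effect_profile}), \code{replicates} (per-replicate final
#'   profiles), \code{plasmid_profile}, \code{experimental_profiles}
#'   (\code{position_profile}s) and \code{accounting} (per-library read
#'   accounting rows).
#' @export
run_dmpra <- function(plasmid, experimental, crm_ref,
                      window = 5L, head_trim = 18L, tail_trim = 14L,
                      mc = mc_config(), min_overlap = 20L,
                      max_mismatch_fraction = 0.1,
                      homopolymer_min_run = 3L) {
  crm_ref <- toupper(crm_ref)
  hp <- find_homopolymers(crm_ref, homopolymer_min_run)
  process <- function(pairs, label) {
    m <- merge_pairs(pairs$read1, pairs$qual1, pairs$read2, pairs$qual2,
                     min_overlap, max_mismatch_fraction)
    ok <- !is.na(m$sequence)
    mc_calls <- align_and_call(m$sequence[ok], crm_ref)
    flt <- filter_calls(mc_calls, hp)
    acct <- data.frame(library = label, pairs = nrow(pairs),
                       merged = sum(ok), merge_failed = sum(!ok),
                       align_failed = mc_calls$n_failed,
                       homopolymer_dropped =
                         attr(flt, "dropped_homopolymer"),
                       retained = length(flt$read_ids),
                       stringsAsFactors = FALSE)
    list(calls = flt, accounting = acct)
  }
  pl <- process(plasmid, "plasmid")
  ex <- lapply(seq_along(experimental), function(i)
    process(experimental[[i]], paste0("experimental_", i)))
  depth <- mc$subsample_depth
  if (is.null(depth)) {
    smallest <- min(c(length(pl$calls$read_ids),
                      vapply(ex, function(e) length(e$calls$read_ids),
                             numeric(1))))
    depth <- floor(0.8 * smallest)
  }
  mc_use <- mc_config(mc$replicates, depth, mc$seed)
  plasmid_profile <- tally_mutations(pl$calls, mc_use)
  exp_profiles <- lapply(ex, function(e) tally_mutations(e$calls, mc_use))
  finals <- lapply(exp_profiles, function(p)
    finalize_profile(effect_profile(p, plasmid_profile),
                     window, head_trim, tail_trim))
  list(averaged = average_replicates(finals), replicates = finals,
       plasmid_profile = plasmid_profile,
       experimental_profiles = exp_profiles,
       accounting = rbind(pl$accounting,
                          do.call(rbind, lapply(ex, `[[`, "accounting"))))
}
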