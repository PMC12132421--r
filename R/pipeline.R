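#' Pipeline run configuration
#'
#' Collects the tunable parameters of both pipelines with their live
#' defaults: smoothing window 5, edge trims 18/14, 10 Monte-Carlo
#' subsampling replicates, minimum tag Hamming distance 5, pseudocount
#' 1 count-equivalent per position, seed fan-out for per-stage
#' reproducibility.
#'
#' @param seed Global integer seed; stages derive their own seeds as
#'   \code{seed + stage offset} (fragmentation +1, association reads
#'   +2, cDNA reads +3, clone pool +4, plasmid reads +5, experimental
#'   reads +6..., subsampling +20).
#' @param window,head_trim,tail_trim d-MPRA finalisation parameters.
#' @param mc_replicates Monte-Carlo subsampling replicates.
#' @param min_tag_distance Minimum pairwise Hamming distance of
#'   multiplexing tags.
#' @param pseudocount Log2-ratio pseudocount.
#' @param kmer Mapper seed length.
#' @param max_mismatch_frac Mapper extension mismatch bound.
#' @param association_tolerance Barcode-association start tolerance
#'   (nt).
#' @param min_overlap,max_mismatch_fraction Read-pair merge parameters.
#' @param homopolymer_min_run Minimum homopolymer run filtered.
#' @return A \code{run_config} list.
#' @export
run_config <- function(seed = 1L, window = 5L, head_trim = 18L,
                       tail_trim = 14L, mc_replicates = 10L,
                       min_tag_distance = 5L, pseudocount = 1,
                       kmer = 21L, max_mismatch_frac = 0.05,
                       association_tolerance = 5L, min_overlap = 20L,
                       max_mismatch_fraction = 0.1,
                       homopolymer_min_run = 3L) {
  structure(list(seed = as.integer(seed), window = as.integer(window),
                 head_trim = as.integer(head_trim),
                 tail_trim = as.integer(tail_trim),
                 mc_replicates = as.integer(mc_replicates),
                 min_tag_distance = as.integer(min_tag_distance),
                 pseudocount = pseudocount, kmer = as.integer(kmer),
                 max_mismatch_frac = max_mismatch_frac,
                 association_tolerance = as.integer(association_tolerance),
                 min_overlap = as.integer(min_overlap),
                 max_mismatch_fraction = max_mismatch_fraction,
                 homopolymer_min_run = as.integer(homopolymer_min_run)),
            class = "run_config")
}

#' Quantify an LS-MPRA run from in-memory reads
#'
#' Association, whitelist construction from the associated barcodes
#' (correction radius auto-set to the guaranteed bound
#' \eqn{\lfloor (d_{min}-1)/2 \rfloor}), cDNA counting, and the
#' depth-normalised log2 enrichment track.
#'
#' @param assoc_pairs Data frame of association read pairs
#'   (\code{read1}, \code{read2}).
#' @param cdna_reads Character vector of cDNA barcode reads.
#' @param locus A \code{\link{reference_locus}}.
#' @param cfg A \code{\link{sim_config}} describing read layout.
#' @param config A \code{\link{run_config}}.
#' @return List with \code{map}, \code{whitelist}, \code{counts},
#'   \code{library_track}, \code{cdna_track}, \code{log2_track} and
#'   \code{manifest} (read-accounting counters).
#' @export
ls_quantify <- function(assoc_pairs, cdna_reads, locus,
                        cfg = sim_config(), config = run_config()) {
  map <- associate_pairs(assoc_pairs, locus, cfg, config$kmer,
                         config$max_mismatch_frac,
                         config$association_tolerance)
  map <- filter_association(map)
  wl <- build_whitelist(map$barcode, radius = NULL, strict = TRUE)
  counts <- count_barcodes(cdna_reads, wl, cfg$anchor_left,
                           cfg$anchor_right)
  lib <- signal_track(setNames(map$reads, map$barcode), map, locus)
  cdna <- signal_track(counts, map, locus)
  lg <- normalize_log2(cdna, lib, config$pseudocount)
  manifest <- list(
    association_pairs = attr(map, "n_input"),
    association_entries = nrow(map),
    dropped_unparsed = attr(map, "dropped_unparsed"),
    dropped_unmapped = attr(map, "dropped_unmapped"),
    dropped_ambiguous = attr(map, "dropped_ambiguous"),
    dropped_low_support = attr(map, "dropped_low_support"),
    whitelist_size = length(wl$canonicals),
    whitelist_radius = wl$radius,
    whitelist_min_distance = wl$min_pairwise_distance,
    cdna_reads = counts$total_reads,
    cdna_assigned = sum(counts$counts),
    cdna_corrected = counts$corrected,
    cdna_discarded = counts$discarded)
  list(map = map, whitelist = wl, counts = counts, library_track = lib,
       cdna_track = cdna, log2_track = lg, manifest = manifest)
}

#' Run a pipeline end to end from files
#'
#' File-based front end binding the stages together.  For
#' \code{pipeline = "ls"}: association FASTQ pair + cDNA FASTQ + locus
#' FASTA in, association TSV, library/cDNA/log2 bedGraph tracks, peak
#' BED and a manifest out.  For \code{pipeline = "dmpra"}: plasmid and
#' experimental FASTQ pairs + CRM FASTA in, per-stage profile TSVs and
#' a manifest out.  Outputs are reproducible byte for byte from config
#' + inputs + seed.
#'
#' @param pipeline \code{"ls"} or \code{"dmpra"}.
#' @param inputs Named list of input paths.  ls: \code{assoc_r1},
#'   \code{assoc_r2}, \code{cdna}, \code{locus}.  dmpra:
#'   \code{plasmid_r1}, \code{plasmid_r2}, \code{exp_r1},
#'   \code{exp_r2} (the latter two may be vectors, one per replicate),
#'   \code{crm}.
#' @param out_prefix Output path prefix.
#' @param config A \code{\link{run_config}}.
#' @param cfg A \code{\link{sim_config}} describing read layout (ls
#'   only).
#' @param peak_threshold Optional log2 threshold for peak calling (ls
#'   only; default: half the track maximum).
#' @return The manifest list (also written to
#'   \code{<out_prefix>.manifest.txt}).
#' @export
run_pipeline <- function(pipeline = c("ls", "dmpra"), inputs, out_prefix,
                         config = run_config(), cfg = sim_config(),
                         peak_threshold = NULL) {
  pipeline <- match.arg(pipeline)
  if (pipeline == "ls") {
    r1 <- read_fastq(inputs$assoc_r1)
    r2 <- read_fastq(inputs$assoc_r2)
    if (nrow(r1) != nrow(r2)) stop("association mates differ in count")
    cdna <- read_fastq(inputs$cdna)
    locus <- read_locus_fasta(inputs$locus)
    res <- ls_quantify(data.frame(read1 = r1$sequence,
                                  read2 = r2$sequence,
                                  stringsAsFactors = FALSE),
                       cdna$sequence, locus, cfg, config)
    if (is.null(peak_threshold))
      peak_threshold <- max(res$log2_track$values) / 2
    peaks <- call_peaks(res$log2_track, peak_threshold,
                        min_width = 200L, merge_gap = 500L)
    write_association(res$map, paste0(out_prefix, ".association.tsv"))
    write_bedgraph(res$library_track, paste0(out_prefix, ".library.bedgraph"))
    write_bedgraph(res$cdna_track, paste0(out_prefix, ".cdna.bedgraph"))
    write_bedgraph(res$log2_track, paste0(out_prefix, ".log2.bedgraph"))
    write_bed(peaks, paste0(out_prefix, ".peaks.bed"), locus$name)
    manifest <- c(list(pipeline = "ls", seed = config$seed,
                       peak_threshold = signif(peak_threshold, 6),
                       n_peaks = nrow(peaks)),
                  res$manifest)
  } else {
    crm <- read_locus_fasta(inputs$crm)
    load_pairs <- function(p1, p2) {
      a <- read_fastq(p1); b <- read_fastq(p2)
      data.frame(read1 = a$sequence, qual1 = a$quality,
                 read2 = b$sequence, qual2 = b$quality,
                 stringsAsFactors = FALSE)
    }
    plasmid <- load_pairs(inputs$plasmid_r1, inputs$plasmid_r2)
    stopifnot(length(inputs$exp_r1) == length(inputs$exp_r2))
    experimental <- Map(load_pairs, inputs$exp_r1, inputs$exp_r2)
    res <- run_dmpra(plasmid, experimental, crm$sequence,
                     window = config$window,
                     head_trim = config$head_trim,
                     tail_trim = config$tail_trim,
                     mc = mc_config(config$mc_replicates,
                                    seed = config$seed + 20L),
                     min_overlap = config$min_overlap,
                     max_mismatch_fraction = config$max_mismatch_fraction,
                     homopolymer_min_run = config$homopolymer_min_run)
    write_profile(res$plasmid_profile,
                  paste0(out_prefix, ".plasmid_profile.tsv"))
    for (i in seq_along(res$replicates))
      write_profile(res$replicates[[i]],
                    paste0(out_prefix, ".effect_rep", i, ".tsv"))
    write_profile(res$averaged, paste0(out_prefix, ".effect_averaged.tsv"))
    write.table(res$accounting, paste0(out_prefix, ".accounting.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    acct <- res$accounting
    manifest <- list(pipeline = "dmpra", seed = config$seed,
                     window = config$window,
                     head_trim = config$head_trim,
                     tail_trim = config$tail_trim,
                     mc_replicates = config$mc_replicates,
                     libraries = nrow(acct),
                     pairs_total = sum(acct$pairs),
                     merged_total = sum(acct$merged),
                     retained_total = sum(acct$retained))
    # conservation identities asserted at pipeline end
    stopifnot(all(acct$merged + acct$merge_failed == acct$pairs),
              all(acct$retained + acct$homopolymer_dropped +
                    acct$align_failed == acct$merged))
  }
  mpath <- paste0(out_prefix, ".manifest.txt")
  writeLines(paste0(names(manifest), "=",
                    vapply(manifest, function(x)
                      paste(format(x, trim = TRUE), collapse = ","),
                      character(1))), mpath)
  invisible(manifest)
}
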