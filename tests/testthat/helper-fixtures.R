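# Shared fixture builders; everything is generated in code under fixed
# seeds so the suite needs no data files.

# brute-force Hamming distance, the oracle the fast kernel is checked
# against
oracle_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# exhaustive enumeration of all A/C/G/T strings of length L
all_kmers <- function(L) {
  do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), L),
                              stringsAsFactors = FALSE))
}

# the four multiplexing library tags used throughout the tag tests
PRINTED_TAGS <- c("ATACAGGC", "TGTGCAAG", "CACGAAGA", "GTGAACCT")

# tiny LS-MPRA scene: locus, two planted CRMs, fragments
small_ls_scene <- function(seed = 101, locus_len = 20000,
                           n_fragments = 600, depth = 20,
                           error = 0.005) {
  set.seed(seed)
  locus <- random_locus(locus_len)
  landscape <- activity_landscape(locus_len,
                                  crm_centers = c(5000, 15000),
                                  crm_span = 3000)
  cfg <- sim_config(n_fragments = n_fragments, read_depth = depth,
                    seq_error_rate = error)
  fragments <- fragment_locus(locus, cfg)
  list(locus = locus, landscape = landscape, cfg = cfg,
       fragments = fragments)
}

# tiny clone pool + read pairs for the d-MPRA tests
small_dmpra_scene <- function(seed = 202, crm_len = 120, mu = 0.01,
                              n_clones = 300, n_reads = 3000,
                              error = 0, deletion_fraction = 0.1) {
  set.seed(seed)
  crm <- random_locus(crm_len, "crm")
  cfg <- dmpra_config(seq_error_rate = error, mu = mu,
                      deletion_fraction = deletion_fraction,
                      read_length = 100L)
  clones <- simulate_dmpra_clones(crm, cfg, n_clones = n_clones)
  em <- effect_map(crm_len)
  pairs <- simulate_dmpra_reads(clones, em, cfg, "plasmid",
                                n_reads = n_reads)
  list(crm = crm, cfg = cfg, clones = clones, em = em, pairs = pairs)
}

# build a raw effect_profile directly from a value vector (unit tests
# of finalize/average without running the whole profiler)
raw_profile <- function(values) {
  out <- data.frame(position = seq_along(values) - 1L, value = values)
  class(out) <- c("effect_profile", "data.frame")
  attr(out, "reference_length") <- length(values)
  attr(out, "dropped_positions") <- integer(0)
  attr(out, "stage") <- list(baseline_corrected = FALSE,
                             smoothed = FALSE, trimmed = FALSE)
  attr(out, "window") <- NA_integer_
  attr(out, "head_trim") <- 0L
  attr(out, "tail_trim") <- 0L
  out
}
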