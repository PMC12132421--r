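#' GC fraction of a sequence
#' @param seq Character vector of A/C/G/T sequences.
#' @return Numeric vector of (G+C)/length.
#' @export
gc_fraction <- function(seq) {
  vapply(strsplit(toupper(seq), ""), function(x) mean(x %in% c("G", "C")),
         numeric(1))
}

#' Longest identical-base run
#' @param seq Character vector of sequences.
#' @return Integer vector of maximal run lengths.
#' @export
max_base_run <- function(seq) {
  vapply(strsplit(toupper(seq), ""),
         function(x) max(rle(x)$lengths), integer(1))
}

#' Reverse complement
#' @param seq Character vector of A/C/G/T sequences.
#' @return Reverse-complemented sequences.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

#' Tag design constraints
#'
#' Rules a set of multiplexing library tags must satisfy: a minimum
#' pairwise Hamming distance, a cap on identical-base runs (a
#' \code{max_run} of 2 excludes any triplet repeat), GC-content bounds,
#' and optionally a ban on self-reverse-complementary tags.
#'
#' @param min_hamming Minimum pairwise Hamming distance (default 5).
#' @param max_run Longest allowed identical-base run (default 2).
#' @param gc_bounds Length-2 numeric, inclusive GC-fraction bounds
#'   (default \code{c(0.375, 0.625)}).
#' @param forbid_self_complement Disallow tags equal to their own reverse
#'   complement (default TRUE).
#' @return A \code{tag_constraints} list.
#' @export
tag_constraints <- function(min_hamming = 5L, max_run = 2L,
                            gc_bounds = c(0.375, 0.625),
                            forbid_self_complement = TRUE) {
  stopifnot(min_hamming >= 1, max_run >= 1, length(gc_bounds) == 2L,
            gc_bounds[1] >= 0, gc_bounds[2] <= 1,
            gc_bounds[1] <= gc_bounds[2])
  structure(list(min_hamming = as.integer(min_hamming),
                 max_run = as.integer(max_run),
                 gc_bounds = as.numeric(gc_bounds),
                 forbid_self_complement = isTRUE(forbid_self_complement)),
            class = "tag_constraints")
}

#' Validate a set of multiplexing library tags
#'
#' A tag passes when it has no base run longer than \code{max_run}, its
#' GC fraction lies within \code{gc_bounds}, it is not its own reverse
#' complement (when forbidden), and its Hamming distance to every other
#' tag is at least \code{min_hamming}.
#'
#' @param tags Character vector of equal-length tags.
#' @param constraints A \code{\link{tag_constraints}} object.
#' @return A \code{tag_validation} list: \code{per_tag} data frame (one
#'   row per tag with logical rule columns and overall \code{pass}),
#'   \code{min_pairwise_distance}, and \code{all_pass}.
#' @examples
#' validate_tag_set(c("ATACAGGC", "TGTGCAAG", "CACGAAGA", "GTGAACCT"))
#' @export
validate_tag_set <- function(tags, constraints = tag_constraints()) {
  tags <- as.character(tags)
  if (!length(tags)) stop("tag set must be nonempty")
  if (length(unique(nchar(tags))) != 1L)
    stop("tags must have equal length")
  gc <- gc_fraction(tags)
  run_ok <- max_base_run(tags) <= constraints$max_run
  gc_ok <- gc >= constraints$gc_bounds[1] & gc <= constraints$gc_bounds[2]
  sc_ok <- if (constraints$forbid_self_complement) tags != revcomp(tags)
           else rep(TRUE, length(tags))
  if (length(tags) >= 2L) {
    dm <- outer(seq_along(tags), seq_along(tags),
                function(i, j) hamming(tags[i], tags[j]))
    diag(dm) <- NA_integer_
    near <- apply(dm, 1L, min, na.rm = TRUE)
    dist_ok <- near >= constraints$min_hamming
    dmin <- min(dm, na.rm = TRUE)
  } else {
    dist_ok <- TRUE
    dmin <- NA_integer_
  }
  per_tag <- data.frame(tag = tags, gc = gc, run_ok = run_ok, gc_ok = gc_ok,
                        self_complement_ok = sc_ok, distance_ok = dist_ok,
                        pass = run_ok & gc_ok & sc_ok & dist_ok,
                        stringsAsFactors = FALSE)
  structure(list(per_tag = per_tag, min_pairwise_distance = dmin,
                 all_pass = all(per_tag$pass), constraints = constraints),
            class = "tag_validation")
}

#' @export
print.tag_validation <- function(x, ...) {
  cat("tag_validation: ", sum(x$per_tag$pass), "/", nrow(x$per_tag),
      " tags pass; min pairwise Hamming distance ",
      x$min_pairwise_distance, "\n", sep = "")
  print(x$per_tag, row.names = FALSE)
  invisible(x)
}

#' Design a set of multiplexing library tags
#'
#' Greedy rejection sampling: candidate tags are drawn uniformly over
#' A/C/G/T, filtered by the per-tag rules, and accepted when at least
#' \code{min_hamming} away from every tag accepted so far.  Deterministic
#' under a fixed seed (set via \code{set.seed()}).
#'
#' @param n Number of tags required.
#' @param length Tag length in nt (default 8).
#' @param constraints A \code{\link{tag_constraints}} object.
#' @param max_attempts Candidate draws before giving up (default 10000).
#' @return Character vector of \code{n} tags; the returned set passes
#'   \code{\link{validate_tag_set}} under the same constraints.
#' @export
design_tags <- function(n, length = 8L, constraints = tag_constraints(),
                        max_attempts = 10000L) {
  stopifnot(n >= 1, length >= 1)
  if (4^length < n)
    stop("infeasible: alphabet^length smaller than requested set")
  bases <- c("A", "C", "G", "T")
  accepted <- character(0)
  attempts <- 0L
  while (length(accepted) < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop("tag search exhausted after ", max_attempts,
           " attempts; constraints may be infeasible for n = ", n,
           ", length = ", length)
    cand <- paste(bases[sample.int(4L, length, replace = TRUE)],
                  collapse = "")
    if (max_base_run(cand) > constraints$max_run) next
    gc <- gc_fraction(cand)
    if (gc < constraints$gc_bounds[1] || gc > constraints$gc_bounds[2]) next
    if (constraints$forbid_self_complement && cand == revcomp(cand)) next
    if (length(accepted) &&
        min(hamming(accepted, cand)) < constraints$min_hamming) next
    accepted <- c(accepted, cand)
  }
  accepted
}
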