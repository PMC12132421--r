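test_that("pair merging finds the overlap and resolves by quality", {
  set.seed(39)
  ref <- random_locus(100)$sequence   # aperiodic: unique best overlap
  r1 <- substr(ref, 1, 70)
  r2 <- revcomp(substr(ref, 31, 100))     # 40 nt true overlap
  q <- strrep("I", 70)
  m <- merge_pairs(r1, q, r2, q)
  expect_identical(nchar(m$sequence), 70L + 70L - 40L)
  expect_identical(m$sequence, ref)
  expect_identical(m$overlap, 40L)
  # overlap below the minimum fails (typed, counted)
  r2short <- revcomp(substr(ref, 61, 100))  # only 10 nt overlap
  m2 <- merge_pairs(substr(ref, 1, 70), strrep("I", 70), r2short,
                    strrep("I", 40), min_overlap = 20)
  expect_true(is.na(m2$sequence))
  expect_identical(attr(m2, "n_failed"), 1L)
  # a disagreement resolves to the higher-quality base
  r1d <- r1
  substr(r1d, 50, 50) <- "T"   # ref has G at 50 -> disagreement
  q1 <- strrep("+", 70)        # Q10 on read 1
  q2 <- strrep("I", 70)        # Q40 on read 2
  m3 <- merge_pairs(r1d, q1, revcomp(substr(ref, 31, 100)), q2)
  expect_identical(substr(m3$sequence, 50, 50), substr(ref, 50, 50))
  m4 <- merge_pairs(r1d, q2, revcomp(substr(ref, 31, 100)), q1)
  expect_identical(substr(m4$sequence, 50, 50), "T")
})

test_that("mutation calling recovers substitutions and deletions", {
  set.seed(40)
  ref <- as.character(random_locus(200)$sequence)
  # single substitution at 0-based position 50
  rd <- ref
  substr(rd, 51, 51) <- setdiff(c("A", "C", "G", "T"),
                                substr(rd, 51, 51))[1]
  mc <- align_and_call(rd, ref)
  expect_identical(nrow(mc$calls), 1L)
  expect_identical(mc$calls$position, 50L)
  expect_identical(mc$calls$kind, "substitution")
  expect_identical(mc$calls$ref, substr(ref, 51, 51))
  # single 1-nt deletion at position 80
  del <- paste0(substr(ref, 1, 80), substr(ref, 82, 200))
  mcd <- align_and_call(del, ref)
  expect_identical(mcd$calls$kind, "deletion")
  expect_identical(nrow(mcd$calls), 1L)
  # deletions inside homopolymers are coordinate-ambiguous; accept any
  # position within the containing run of the true deletion
  hp <- find_homopolymers(ref, 2)
  pos_ok <- mcd$calls$position == 80L ||
    any(hp$start <= 80 & hp$end > 80 &
          mcd$calls$position >= hp$start & mcd$calls$position < hp$end)
  expect_true(pos_ok)
  # truncated reads fail the full-span rule
  tr <- align_and_call(substr(ref, 21, 200), ref)
  expect_identical(tr$n_failed, 1L)
  expect_length(tr$read_ids, 0L)
  tr2 <- align_and_call(substr(ref, 1, 180), ref)
  expect_identical(tr2$n_failed, 1L)
  # wild-type read: retained with zero calls
  wt <- align_and_call(ref, ref)
  expect_identical(wt$read_ids, 1L)
  expect_identical(nrow(wt$calls), 0L)
})

test_that("the caller recovers planted mutations on error-free reads", {
  sc <- small_dmpra_scene(seed = 404, mu = 0.01, n_clones = 500,
                          n_reads = 4000, error = 0)
  m <- merge_pairs(sc$pairs$read1, sc$pairs$qual1,
                   sc$pairs$read2, sc$pairs$qual2)
  mc <- align_and_call(m$sequence, sc$crm$sequence)
  clone_of <- attr(sc$pairs, "clone")
  truth <- sc$clones$mutations
  hp <- find_homopolymers(sc$crm$sequence, 2)
  in_hp <- function(p) any(hp$start <= p & p < hp$end)
  n_checked <- 0L; n_ok <- 0L
  calls_by_read <- split(mc$calls, mc$calls$read)
  for (i in mc$read_ids) {
    tm <- truth[truth$clone == clone_of[i], ]
    # skip reads whose planted deletion has a coordinate-ambiguous
    # representation: inside a homopolymer (the called position shifts
    # within the run), at a reference edge (full-span ambiguity), or
    # adjacent to another mutation (equal-score alignment paths)
    if (nrow(tm) && any(tm$kind == "deletion")) {
      dpos <- tm$position[tm$kind == "deletion"]
      near_other <- vapply(dpos, function(p)
        any(abs(setdiff(tm$position, p) - p) <= 1), logical(1))
      if (any(vapply(dpos, in_hp, logical(1)) |
                dpos %in% c(0L, nchar(sc$crm$sequence) - 1L) |
                near_other))
        next
    }
    got <- calls_by_read[[as.character(i)]]
    key_got <- if (is.null(got)) character(0)
               else paste(got$position, got$kind, got$alt)
    key_true <- paste(tm$position, tm$kind, tm$alt)
    n_checked <- n_checked + 1L
    n_ok <- n_ok + as.integer(setequal(key_got, key_true))
  }
  expect_gt(n_checked, 3000)
  expect_gte(n_ok / n_checked, 0.999)
})

test_that("homopolymer detection matches a brute-force scan", {
  expect_identical(find_homopolymers("AAAT", 3),
                   data.frame(start = 0L, end = 3L, base = "A",
                              stringsAsFactors = FALSE))
  expect_identical(nrow(find_homopolymers("ACGT", 2)), 0L)
  set.seed(50)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 60, TRUE,
                      prob = c(0.4, 0.1, 0.1, 0.4)), collapse = "")
    hp <- find_homopolymers(s, 3)
    ch <- strsplit(s, "")[[1]]
    if (nrow(hp)) {
      for (j in seq_len(nrow(hp))) {
        run <- ch[(hp$start[j] + 1):hp$end[j]]
        expect_identical(unique(run), hp$base[j])      # uniform base
        expect_gte(length(run), 3L)
        # maximal: neighbours differ
        if (hp$start[j] > 0)
          expect_false(ch[hp$start[j]] == hp$base[j])
        if (hp$end[j] < 60)
          expect_false(ch[hp$end[j] + 1] == hp$base[j])
      }
      # disjoint
      expect_true(all(hp$start[-1] >= head(hp$end, -1)))
    }
    # every >= 3 run is reported: count by rle
    r <- rle(ch)
    expect_identical(nrow(hp), sum(r$lengths >= 3))
  }
  expect_error(find_homopolymers("ACGT", 1), "min_run")
})

test_that("homopolymer filtering drops whole reads, deletions only", {
  ref <- "CCAAAGTCGT"
  hp <- find_homopolymers(ref, 3)      # run A at [2,5)
  mk_calls <- function(df, n) {
    structure(list(n_reads = n, read_ids = seq_len(n), calls = df,
                   n_failed = 0L, reference = ref),
              class = "mutation_calls")
  }
  calls <- data.frame(read = c(1L, 2L, 3L),
                      position = c(3L, 3L, 8L),
                      kind = c("deletion", "substitution", "deletion"),
                      ref = c("A", "A", "G"), alt = c("-", "T", "-"),
                      stringsAsFactors = FALSE)
  out <- filter_calls(mk_calls(calls, 4), hp)
  # read 1 (deletion inside the run) dropped entirely; read 2
  # (substitution in the run) and read 3 (deletion outside) retained;
  # read 4 (no calls, wild-type) retained
  expect_identical(out$read_ids, c(2L, 3L, 4L))
  expect_identical(attr(out, "dropped_homopolymer"), 1L)
  expect_identical(sort(unique(out$calls$read)), c(2L, 3L))
})

test_that("Monte-Carlo tallies report wild-type-normalised frequencies", {
  ref <- strrep("ACGT", 25)
  mk_calls <- function(df, ids) {
    structure(list(n_reads = max(ids), read_ids = ids, calls = df,
                   n_failed = 0L, reference = ref),
              class = "mutation_calls")
  }
  # all wild type: zero frequency, zero sd everywhere
  wt <- mk_calls(data.frame(read = integer(0), position = integer(0),
                            kind = character(0), ref = character(0),
                            alt = character(0)), 1:50)
  tp <- tally_mutations(wt, mc_config(10, 40, seed = 1))
  expect_true(all(tp$freq_wt_mean == 0))
  expect_true(all(tp$freq_wt_sd == 0))
  expect_identical(attr(tp, "replicates"), 10L)
  # single replicate: sd reported as zero
  tp1 <- tally_mutations(wt, mc_config(1, 40, seed = 1))
  expect_true(all(tp1$freq_wt_sd == 0))
  # full subsample of a known call set gives exact frequencies
  calls <- data.frame(read = c(1L, 2L, 2L),
                      position = c(10L, 10L, 20L),
                      kind = "substitution", ref = "A", alt = "C",
                      stringsAsFactors = FALSE)
  tp2 <- tally_mutations(mk_calls(calls, 1:10), mc_config(5, 10))
  expect_equal(tp2$freq_wt_mean[tp2$position == 10], 2 / 8)
  expect_equal(tp2$freq_wt_mean[tp2$position == 20], 1 / 8)
  expect_equal(tp2$rate_mean[tp2$position == 10], 2 / 10)
  # depth exceeding retained reads errors
  expect_error(tally_mutations(wt, mc_config(10, 100)), "exceeds")
  # all reads mutated: wild-type normalisation is undefined
  allmut <- mk_calls(data.frame(read = 1:5, position = 0L,
                                kind = "substitution", ref = "A",
                                alt = "C"), 1:5)
  expect_error(tally_mutations(allmut, mc_config(2, 5)), "wild-type")
})

test_that("per-position rate recovers the generating mutation rate", {
  sc <- small_dmpra_scene(seed = 505, mu = 0.005, n_clones = 2000,
                          n_reads = 20000, error = 0,
                          deletion_fraction = 0)
  m <- merge_pairs(sc$pairs$read1, sc$pairs$qual1, sc$pairs$read2,
                   sc$pairs$qual2)
  mc <- align_and_call(m$sequence, sc$crm$sequence)
  flt <- filter_calls(mc, find_homopolymers(sc$crm$sequence, 3))
  tp <- tally_mutations(flt, mc_config(10, seed = 2))
  est <- mean(tp$rate_mean)
  expect_lt(abs(est - 0.005) / 0.005, 0.2)
})

test_that("effect profiles are log2 ratios over shared positions", {
  ref <- strrep("ACGT", 25)
  mk_prof <- function(freq) {
    out <- data.frame(position = seq_along(freq) - 1L,
                      freq_wt_mean = freq, freq_wt_sd = 0,
                      rate_mean = freq, rate_sd = 0,
                      sub_mean = freq, del_mean = 0)
    class(out) <- c("position_profile", "data.frame")
    attr(out, "reference") <- ref
    out
  }
  f <- rep(0.01, 100)
  expect_true(all(effect_profile(mk_prof(f), mk_prof(f))$value == 0))
  f4 <- f; f4[31] <- 0.04
  ep <- effect_profile(mk_prof(f4), mk_prof(f))
  expect_equal(ep$value[31], 2)
  # a position absent from the plasmid profile is dropped (NA)
  f0 <- f; f0[61] <- 0
  ep2 <- effect_profile(mk_prof(f), mk_prof(f0))
  expect_true(is.na(ep2$value[61]))
  expect_identical(attr(ep2, "dropped_positions"), 60L)
  expect_error(effect_profile(mk_prof(rep(0, 100)), mk_prof(f)),
               "shared")
})

test_that("finalisation median-centres, smooths and trims", {
  # constant profile: identically zero after baseline correction
  cst <- finalize_profile(raw_profile(rep(3.7, 100)))
  expect_true(all(cst$value == 0))
  expect_identical(nrow(cst), 68L)        # 100 - 18 - 14
  expect_identical(cst$position[1], 18L)
  expect_identical(cst$position[68], 85L)
  # impulse of height 5, window 5: centre smooths to 1
  v <- rep(0, 100); v[51] <- 5
  fp <- finalize_profile(raw_profile(v))
  expect_equal(fp$value[fp$position == 50], 1)
  # kernel support equals the window width
  expect_identical(sum(fp$value != 0), 5L)
  # invariant to uniform offsets (median subtraction)
  set.seed(60)
  r <- rnorm(100)
  expect_equal(finalize_profile(raw_profile(r))$value,
               finalize_profile(raw_profile(r + 11))$value)
  expect_error(finalize_profile(raw_profile(rep(1, 30))), "too short")
  expect_error(finalize_profile(raw_profile(rnorm(100)), window = 4),
               "odd")
})

test_that("replicate averaging is the per-position mean", {
  a <- finalize_profile(raw_profile(rnorm(100)))
  expect_equal(average_replicates(list(a))$value, a$value)
  b <- a; b$value <- -a$value
  attr(b, "stage") <- attr(a, "stage")
  expect_true(all(abs(average_replicates(list(a, b))$value) < 1e-12))
  cs <- lapply(c(1, 2, 6), function(k)
    finalize_profile(raw_profile(rep(0, 100) + k * c(rep(0, 50),
                                                     rep(1, 50)))))
  av <- average_replicates(cs)
  expect_equal(av$value, (cs[[1]]$value + cs[[2]]$value +
                            cs[[3]]$value) / 3)
  expect_error(average_replicates(list()), "empty")
})
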