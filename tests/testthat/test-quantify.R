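test_that("barcode counting separates exact, corrected and discarded", {
  cfg <- sim_config()
  wl <- build_whitelist(c("AAAAAAAA", "TTTTTTTT", "AACCGGTT"), radius = 1)
  mk <- function(bc) paste0(cfg$anchor_left, bc, cfg$anchor_right, "AC")
  reads <- mk(c("AAAAAAAA",      # exact
                "AAAAAAAT",      # corrected to AAAAAAAA
                "ACGTACGT",      # no match
                "GGGGGGGG"))     # no match
  bc <- count_barcodes(reads, wl)
  expect_identical(unname(bc$counts["AAAAAAAA"]), 2L)
  expect_identical(bc$corrected, 1L)
  expect_identical(bc$discarded, 2L)
  expect_identical(sum(bc$counts) + bc$discarded, bc$total_reads)
  # a barcode equidistant (within radius) from two canonicals is
  # discarded, not assigned
  wl2 <- build_whitelist(c("AAAA", "AATT"), radius = 1, strict = FALSE)
  amb_read <- paste0(cfg$anchor_left, "AATA", cfg$anchor_right, "AC")
  bc2 <- count_barcodes(amb_read, wl2)
  expect_identical(sum(bc2$counts), 0L)
  expect_identical(bc2$discarded, 1L)
})

test_that("signal tracks accumulate per-barcode counts over intervals", {
  locus <- reference_locus("toy", strrep("A", 20))
  map <- structure(data.frame(barcode = c("b1", "b2"),
                              start = c(0L, 5L), end = c(10L, 15L),
                              reads = c(1L, 1L)),
                   class = c("barcode_map", "data.frame"))
  tr <- signal_track(c(b1 = 3, b2 = 5), map, locus)
  expect_identical(tr$values,
                   c(rep(3, 5), rep(8, 5), rep(5, 5), rep(0, 5)))
  # conservation: sum over positions = sum of count * interval length
  expect_identical(sum(tr$values), 3 * 10 + 5 * 10)
  # zero counts give an all-zero track; unmapped barcodes are reported
  tr0 <- signal_track(c(b1 = 0, b2 = 0, zz = 4), map, locus)
  expect_true(all(tr0$values == 0))
  expect_identical(attr(tr0, "skipped_barcodes"), "zz")
})

test_that("log2 normalisation is depth-invariant and correct on toys", {
  t1 <- genomic_track("x", c(10, 20, 30), "signal")
  expect_true(all(normalize_log2(t1, t1)$values == 0))
  # doubling one track changes nothing after depth normalisation
  t2 <- genomic_track("x", 2 * c(10, 20, 30), "signal")
  expect_equal(normalize_log2(t2, t1)$values, rep(0, 3))
  # closed form on a 3-position toy with a genuine 2x excess at p = 1
  cdna <- genomic_track("x", c(10, 40, 10), "signal")
  input <- genomic_track("x", c(10, 20, 10), "signal")
  pc <- 0.5
  a <- c(10, 40, 10) * 3 / 60
  b <- c(10, 20, 10) * 3 / 40
  expect_equal(normalize_log2(cdna, input, pc)$values,
               log2((a + pc) / (b + pc)))
  expect_error(normalize_log2(t1, genomic_track("x", c(0, 0, 0),
                                                "signal")),
               "all zero")
  # multiplying either track by any positive constant is a no-op
  for (k in c(0.2, 7)) {
    tk <- genomic_track("x", k * c(10, 40, 10), "signal")
    expect_equal(normalize_log2(tk, input)$values,
                 normalize_log2(cdna, input)$values)
  }
})

test_that("trapezoidal AUC matches closed forms and fine quadrature", {
  const <- genomic_track("x", rep(3, 101), "signal")
  expect_equal(track_auc(const, 0, 101)$auc, 100 * 3)
  tri <- genomic_track("x", c(0, 1, 2, 1, 0), "signal")
  expect_equal(track_auc(tri, 0, 5)$auc, 4)
  # independent quadrature oracle: fine midpoint rule on the linear
  # interpolant, with subintervals aligned to the nt grid so every
  # panel is exactly linear (midpoint rule is exact on linear pieces)
  set.seed(30)
  v <- runif(200)
  tr <- genomic_track("x", v, "signal")
  a <- track_auc(tr, 10, 150)$auc
  f <- approxfun(0:139, v[11:150])
  h <- 0.1
  q <- sum(f(seq(h / 2, 139 - h / 2, by = h))) * h
  expect_lt(abs(a - q), 1e-9)
  expect_error(track_auc(tr, 5, 6), "at least 2")
})

test_that("AUC normalisation to a reference condition", {
  res <- data.frame(roi = rep(c("r1", "r2"), 2),
                    condition = rep(c("0h", "24h"), each = 2),
                    auc = c(2, 4, 2, 8))
  out <- normalize_auc_to_reference(res, "0h")
  expect_equal(out$normalized_auc, c(1, 1, 1, 2))
  # invariant to rescaling all AUCs by a constant
  res2 <- res; res2$auc <- res2$auc * 13
  expect_equal(normalize_auc_to_reference(res2, "0h")$normalized_auc,
               out$normalized_auc)
  expect_error(normalize_auc_to_reference(res, "48h"), "not present")
  res$auc[1] <- 0
  expect_error(normalize_auc_to_reference(res, "0h"), "zero")
})

test_that("peak calling finds, merges and filters threshold runs", {
  v <- rep(0, 100)
  v[21:40] <- 2
  tr <- genomic_track("x", v, "signal")
  pk <- call_peaks(tr, 1)
  expect_identical(nrow(pk), 1L)
  expect_identical(c(pk$start, pk$end), c(20L, 40L))
  # two plateaus split by a small gap merge into one
  v2 <- v; v2[51:60] <- 2
  pk2 <- call_peaks(genomic_track("x", v2, "signal"), 1, merge_gap = 15)
  expect_identical(nrow(pk2), 1L)
  expect_identical(c(pk2$start, pk2$end), c(20L, 60L))
  # without merging they stay separate; min_width discards the smaller
  pk3 <- call_peaks(genomic_track("x", v2, "signal"), 1, min_width = 15)
  expect_identical(nrow(pk3), 1L)
  expect_identical(pk3$end, 40L)
  expect_identical(nrow(call_peaks(tr, 5)), 0L)
})

test_that("planted CRMs are recovered end to end on a small locus", {
  sc <- small_ls_scene(seed = 303, depth = 30)
  rp <- simulate_association_reads(sc$fragments, sc$locus, sc$cfg)
  cd <- simulate_cdna_reads(sc$fragments, sc$landscape, sc$cfg,
                            n_reads = 30 * nrow(sc$fragments))
  res <- ls_quantify(rp, cd, sc$locus, sc$cfg)
  pk <- call_peaks(res$log2_track, max(res$log2_track$values) / 2,
                   min_width = 300, merge_gap = 800)
  expect_identical(nrow(pk), 2L)
  expect_true(all(abs(sort(pk$center) -
                        sc$landscape$crm_centers) <= 150))
  # accounting: assigned + discarded = total cDNA reads
  expect_identical(sum(res$counts$counts) + res$counts$discarded,
                   res$counts$total_reads)
})
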