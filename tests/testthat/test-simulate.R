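test_that("fragmentation respects size selection and locus bounds", {
  set.seed(1)
  locus <- random_locus(10000)
  cfg <- sim_config(fragment_size_range = c(400, 600),
                    n_fragments = 1000)
  fr <- fragment_locus(locus, cfg)
  sizes <- fr$end - fr$start
  expect_true(all(sizes >= 400 & sizes <= 600))
  expect_true(all(fr$start >= 0 & fr$end <= locus$length))
  expect_identical(nrow(fr), 1000L)
  # mean per-base coverage close to n * mean_size / L = 50
  cov <- coverage_track(structure(fr, class = c("barcode_map",
                                                "data.frame")), locus)
  expect_lt(abs(mean(cov$values) - 50) / 50, 0.1)
  # single fragment
  one <- fragment_locus(locus, sim_config(n_fragments = 1))
  expect_identical(nrow(one), 1L)
  expect_error(fragment_locus(random_locus(500),
                              sim_config(fragment_size_range = c(400, 600))),
               "exceeds locus length")
})

test_that("generators are bit-reproducible under a fixed seed", {
  locus <- random_locus(5000)
  cfg <- sim_config(n_fragments = 50, read_depth = 3, seed = 42)
  f1 <- fragment_locus(locus, cfg)
  f2 <- fragment_locus(locus, cfg)
  expect_identical(f1, f2)
  expect_identical(simulate_association_reads(f1, locus, cfg),
                   simulate_association_reads(f1, locus, cfg))
  land <- activity_landscape(5000)
  expect_identical(as.character(simulate_cdna_reads(f1, land, cfg)),
                   as.character(simulate_cdna_reads(f1, land, cfg)))
  crm <- random_locus(150, "crm")
  c1 <- simulate_dmpra_clones(crm, cfg, 100)
  c2 <- simulate_dmpra_clones(crm, cfg, 100)
  expect_identical(c1, c2)
})

test_that("association read simulation emits depth pairs per fragment", {
  set.seed(2)
  locus <- random_locus(5000)
  cfg <- sim_config(n_fragments = 40, read_depth = 1,
                    seq_error_rate = 0)
  fr <- fragment_locus(locus, cfg)
  rp <- simulate_association_reads(fr, locus, cfg)
  expect_identical(nrow(rp), 40L)
  # error-free read 2 is a verbatim fragment prefix
  expect_identical(rp$read2,
                   substring(locus$sequence, fr$start + 1,
                             pmin(fr$start + 150, fr$end)))
  # every read traces to a fragment record (no orphans)
  expect_true(all(attr(rp, "fragment") %in% seq_len(nrow(fr))))
})

test_that("cDNA sampling follows the planted activity weights", {
  set.seed(3)
  locus <- random_locus(6000)
  cfg <- sim_config(n_fragments = 60, seq_error_rate = 0)
  fr <- fragment_locus(locus, cfg)
  # flat landscape: counts consistent with a uniform multinomial
  flat <- activity_landscape(6000, baseline = 2)
  reads <- simulate_cdna_reads(fr, flat, cfg, n_reads = 6000)
  counts <- tabulate(attr(reads, "fragment"), nbins = 60)
  expect_gt(chisq.test(counts)$p.value, 0.01)
  # a 9x-weight fragment takes the closed-form expected share; use
  # disjoint tiles so only one fragment picks up the activity boost
  tiles <- data.frame(start = (0:59) * 100L, end = (0:59) * 100L + 100L,
                      barcode = sample_barcodes(60))
  land9 <- activity_landscape(6000, baseline = 2)
  land9$activity[1:100] <- 16                 # (2+16)/2 = 9x baseline
  expect_equal(fragment_weights(tiles, land9),
               c(18, rep(2, 59)))
  reads9 <- simulate_cdna_reads(tiles, land9, cfg, n_reads = 20000)
  share <- mean(attr(reads9, "fragment") == 1)
  expected <- 9 / (9 + 59)
  expect_lt(abs(share - expected) / expected, 0.15)
  # degenerate cases
  expect_length(simulate_cdna_reads(fr, flat, cfg, n_reads = 0), 0L)
  zero <- activity_landscape(6000, baseline = 1)
  zero$baseline <- 0
  expect_error(simulate_cdna_reads(fr, zero, cfg), "zero")
})

test_that("clone pools realise the configured mutation process", {
  crm <- random_locus(200, "crm")
  # mu = 0: all clones identical to the reference
  c0 <- simulate_dmpra_clones(crm, sim_config(mu = 0, seed = 1), 50)
  expect_true(all(c0$sequences == crm$sequence))
  expect_identical(nrow(c0$mutations), 0L)
  # fraction of clones carrying a mutation matches 1 - (1-mu)^L
  cfg <- sim_config(mu = 0.002, seed = 2)
  cp <- simulate_dmpra_clones(crm, cfg, 10000)
  frac <- length(unique(cp$mutations$clone)) / 10000
  expected <- 1 - (1 - 0.002)^200
  expect_lt(abs(frac - expected) / expected, 0.1)
  # per-base empirical mutation rate converges to mu
  rate <- nrow(cp$mutations) / (10000 * 200)
  expect_lt(abs(rate - 0.002) / 0.002, 0.1)
  # no deletions when deletion_fraction = 0
  cnd <- simulate_dmpra_clones(crm, sim_config(mu = 0.01,
                                               deletion_fraction = 0,
                                               seed = 3), 500)
  expect_false(any(cnd$mutations$kind == "deletion"))
  # mutations reproduce the stored sequences
  mt <- cp$mutations[cp$mutations$clone == cp$mutations$clone[1], ]
  expect_identical(unique(mt$ref),
                   unique(substring(crm$sequence, mt$position + 1,
                                    mt$position + 1)))
})

test_that("d-MPRA read weighting depletes mutated activator sites", {
  set.seed(4)
  crm <- random_locus(150, "crm")
  cfg <- dmpra_config(mu = 0.02, deletion_fraction = 0,
                      seq_error_rate = 0, read_length = 100L)
  clones <- simulate_dmpra_clones(crm, cfg, 4000)
  em1 <- effect_map(150)
  # neutral effect map: plasmid and experimental draws are
  # statistically indistinguishable
  pl <- simulate_dmpra_reads(clones, em1, cfg, "plasmid", 20000)
  ex <- simulate_dmpra_reads(clones, em1, cfg, "experimental", 20000)
  tp <- tabulate(attr(pl, "clone"), nbins = 4000)
  te <- tabulate(attr(ex, "clone"), nbins = 4000)
  keep <- tp + te > 10
  expect_gt(chisq.test(cbind(tp[keep], te[keep]))$p.value, 0.01)
  # a 0.25x activator site depletes clones mutated there ~4-fold
  em <- effect_map(150, data.frame(start = 50, end = 58, factor = 0.25))
  ex2 <- simulate_dmpra_reads(clones, em, cfg, "experimental", 50000)
  hit <- unique(clones$mutations$clone[
    clones$mutations$position >= 50 & clones$mutations$position < 58])
  # restrict to single-mutation clones so the expected ratio is exact
  nm <- table(factor(clones$mutations$clone, levels = 1:4000))
  single_hit <- intersect(hit, which(nm == 1))
  pl2 <- simulate_dmpra_reads(clones, em, cfg, "plasmid", 50000)
  fr_pl <- sum(attr(pl2, "clone") %in% single_hit) / 50000
  fr_ex <- sum(attr(ex2, "clone") %in% single_hit) / 50000
  expect_lt(abs(fr_pl / fr_ex - 4) / 4, 0.35)
  # single wild-type clone: every read is the reference
  wt <- simulate_dmpra_clones(crm, sim_config(mu = 0, seed = 5), 1)
  rd <- simulate_dmpra_reads(wt, em1, cfg, "plasmid", 10)
  merged <- merge_pairs(rd$read1, rd$qual1, rd$read2, rd$qual2)
  expect_true(all(merged$sequence == crm$sequence))
})
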