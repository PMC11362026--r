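test_that("TSS score is ~1 under a uniform insertion null", {
  # insertions uniform over the +/-2 kb window of a single TSS
  set.seed(41)
  n <- 50000  # 100,000 insertions
  pos <- sample(3000:7000, n, replace = TRUE)
  fs <- fragment_set(data.frame(contig = "chr1", start = pos, end = pos + 1L,
                                barcode = "cell1"),
                     "accessibility", c(chr1 = 20000L), collapse = FALSE)
  te <- tss_enrichment(fs, data.frame(contig = "chr1", position = 5000L))
  expect_lt(abs(te$tss_score - 1), 0.1)
})

test_that("TSS score matches a brute-force oracle on a hand-listed toy", {
  # 12 insertions around one TSS at 1000: 6 in the centre, 4 in the flanks,
  # 2 elsewhere in the window
  ins <- c(960, 980, 1000, 1010, 1020, 1049,    # centre [950, 1050]
           -960, -940, 2920, 2980,              # flanks [-1000,-901],[1901,2000]
           1500, 300) + 1000L                   # window offsets relative to TSS-1000
  # place insertions as 1-bp fragments (each fragment contributes both ends
  # to the same position)
  fs <- fragment_set(data.frame(contig = "c", start = ins, end = ins + 1L,
                                barcode = "b"),
                     "accessibility", c(c = 10000L), collapse = FALSE)
  te <- tss_enrichment(fs, data.frame(contig = "c", position = 2000L))
  # oracle: each 1-bp fragment has both ends at the same bp -> weight 2
  center <- 2 * 6; flanks <- 2 * 4
  oracle <- (center / 101) / ((flanks + 1) / 200)
  expect_equal(te$tss_score, oracle)
})

test_that("TSS score exercises the pseudocount floor when flanks are empty", {
  ins <- rep(5000L, 10)
  fs <- fragment_set(data.frame(contig = "c", start = ins, end = ins + 1L,
                                barcode = "b"),
                     "accessibility", c(c = 10000L), collapse = FALSE)
  te <- tss_enrichment(fs, data.frame(contig = "c", position = 5000L))
  expect_true(is.finite(te$tss_score))
  expect_equal(te$tss_score, (20 / 101) / (1 / 200))
})

test_that("FRiP is exact on toys and matches the planted fraction in bulk", {
  pk <- data.frame(contig = "c", start = c(100L, 500L), end = c(200L, 600L))
  fr <- data.frame(contig = "c",
                   start = c(110L, 150L, 510L, 800L),
                   end = c(160L, 260L, 590L, 900L),
                   barcode = "b")
  fs <- fragment_set(fr, "accessibility", c(c = 1000L), collapse = FALSE)
  expect_equal(frip(fs, pk)$frip, 0.75)
  fs_all <- fragment_set(fr[1:3, ], "accessibility", c(c = 1000L),
                         collapse = FALSE)
  expect_equal(frip(fs_all, pk)$frip, 1.0)

  # simulated: mean FRiP within 0.02 of the planted in-peak fraction
  cfg <- sim_config(n_cells = c(typeA = 200L),
                    fragments_per_cell = list(
                      histone = list(mean = 2, dispersion = 2),
                      accessibility = list(mean = 1000, dispersion = 8)),
                    in_peak_fraction = c(histone = 0.6, accessibility = 0.6),
                    duplicate_rate = 0, ambient_fraction = 0,
                    n_genes = 60L, seed = 43L)
  tr <- generate_truth(cfg)
  fx <- generate_fragments(tr)
  fs2 <- sim_fragset(fx, "accessibility", tr)
  pk2 <- tr$peaks[tr$peaks$cell_type == "typeA" &
                    tr$peaks$modality == "accessibility", ]
  fp <- frip(fs2, pk2)
  expect_lt(abs(mean(fp$frip) - 0.6), 0.02)
})

test_that("cell filters reproduce the strict modality-specific thresholds", {
  qc <- data.frame(barcode = c("a", "b", "c", "d", "e"),
                   n_fragments = c(600L, 600L, 499L, 500L, 600L),
                   tss_score = c(1.5, 2.0, 5.0, 2.0, 0.0))
  # accessibility: TSS threshold 2
  kept <- filter_cells(qc, "accessibility")
  expect_false("a" %in% kept$barcode)   # tss 1.5 < 2
  expect_true("b" %in% kept$barcode)    # tss exactly 2: kept
  expect_false("c" %in% kept$barcode)   # 499 fragments: removed despite tss
  expect_true("d" %in% kept$barcode)    # exactly 500: kept
  # histone: TSS threshold 0, a zero score passes
  kept_h <- filter_cells(qc, "histone")
  expect_true("e" %in% kept_h$barcode)
  expect_false("c" %in% kept_h$barcode)
  expect_error(filter_cells(qc, "methylation"), "unknown modality")
})

test_that("raising any filter threshold never admits a new cell", {
  set.seed(44)
  qc <- data.frame(barcode = paste0("b", 1:500),
                   n_fragments = rpois(500, 600),
                   tss_score = rexp(500, 0.5))
  base <- filter_cells(qc, "accessibility")$barcode
  for (thr in c(2.5, 3, 4)) {
    kept <- filter_cells(qc, "accessibility",
                         tss_thresholds = c(histone = 0, accessibility = thr))$barcode
    expect_true(all(kept %in% base))
    base <- kept
  }
  for (mf in c(600L, 700L)) {
    kept <- filter_cells(qc, "accessibility", min_fragments = mf)$barcode
    expect_true(all(kept %in% filter_cells(qc, "accessibility")$barcode))
  }
})

test_that("QC metrics are invariant under fragment-row shuffling", {
  cfg <- small_config(seed = 45L)
  tr <- generate_truth(cfg)
  fx <- generate_fragments(tr)
  sub <- fx[fx$modality == "accessibility", ][1:5000, ]
  pk <- tr$peaks[tr$peaks$modality == "accessibility" &
                   tr$peaks$cell_type == "typeA", ]
  tss <- data.frame(contig = tr$genes$contig, position = tr$genes$tss)
  f1 <- fragment_set(sub[, c("contig", "start", "end", "barcode")],
                     "accessibility", tr$contigs)
  set.seed(1)
  f2 <- fragment_set(sub[sample(nrow(sub)), c("contig", "start", "end", "barcode")],
                     "accessibility", tr$contigs)
  a <- frip(f1, pk); b <- frip(f2, pk)
  data.table::setorder(a, barcode); data.table::setorder(b, barcode)
  expect_equal(a, b)
  ta <- tss_enrichment(f1, tss); tb <- tss_enrichment(f2, tss)
  data.table::setorder(ta, barcode); data.table::setorder(tb, barcode)
  expect_equal(ta, tb)
})

test_that("size distribution flags a single mode and no ladder when degenerate", {
  fs <- fragment_set(data.frame(contig = "c", start = 0:999,
                                end = 200:1199, barcode = "b"),
                     "histone", c(c = 2000L), collapse = FALSE)
  sd1 <- size_distribution(fs)
  expect_equal(sd1$modes$size, 200)
  expect_false(sd1$ladder)
  expect_equal(sd1$periodicity, 0)
  expect_false(sd1$periodicity_defined)
  expect_error(size_distribution(fragment_set(
    data.frame(contig = character(), start = integer(), end = integer(),
               barcode = character()), "histone", c(c = 100L))), "empty")
})

test_that("uniform sizes yield no prominent modes; mixtures yield the ladder", {
  set.seed(46)
  start <- sample(0:10000, 50000, replace = TRUE)
  len <- sample(50:700, 50000, replace = TRUE)
  fs <- fragment_set(data.frame(contig = "c", start = start,
                                end = start + len, barcode = "b"),
                     "histone", c(c = 20000L), collapse = FALSE)
  sd_u <- size_distribution(fs)
  # no interior mode stands out of a flat histogram
  expect_false(sd_u$ladder)

  cfg <- sim_config(n_cells = c(t = 40L),
                    fragments_per_cell = list(
                      histone = list(mean = 1500, dispersion = 5),
                      accessibility = list(mean = 1000, dispersion = 5)),
                    size_weights = c(0, 0.4, 0.3, 0.3),
                    n_genes = 40L, duplicate_rate = 0, ambient_fraction = 0,
                    seed = 47L)
  tr <- generate_truth(cfg)
  fx <- generate_fragments(tr)
  fs2 <- fragment_set(fx[, c("contig", "start", "end", "barcode")], "histone",
                      tr$contigs, collapse = FALSE)
  sd_m <- size_distribution(fs2)
  expect_true(sd_m$ladder)
  for (m in c(200, 400, 600)) {
    expect_true(any(abs(sd_m$modes$size - m) <= 15))
  }
  expect_gt(sd_m$periodicity, 0)
})

test_that("signal-to-noise reports planted enrichment and sentinels", {
  # coverage identical everywhere -> ratio 1
  fs <- fragment_set(data.frame(contig = "c", start = seq(0, 9900, by = 100),
                                end = seq(100, 10000, by = 100), barcode = "b"),
                     "histone", c(c = 10000L), collapse = FALSE)
  pk <- data.frame(contig = "c", start = 2000L, end = 3000L)
  sn <- signal_to_noise(fs, pk, n_shuffles = 5L, seed = 1L)
  expect_equal(sn$ratio, 1)

  # coverage only inside peaks -> background-zero sentinel
  fs2 <- fragment_set(data.frame(contig = "c", start = rep(2100L, 10),
                                 end = rep(2300L, 10), barcode = "b"),
                      "histone", c(c = 10000L), collapse = FALSE)
  sn2 <- signal_to_noise(fs2, pk, n_shuffles = 5L, seed = 1L)
  expect_true(sn2$background_zero)
  expect_equal(sn2$ratio, Inf)

  # planted ~10x enrichment recovered within [8, 12]
  set.seed(48)
  n <- 100000
  pk3 <- data.frame(contig = "c", start = seq(0, 1900000, by = 100000),
                    end = seq(0, 1900000, by = 100000) + 10000)
  fin <- (10 * 0.1) / (10 * 0.1 + 0.9)
  inp <- runif(n) < fin
  pos <- integer(n)
  j <- sample(nrow(pk3), sum(inp), replace = TRUE)
  pos[inp] <- pk3$start[j] + sample(0:9799, sum(inp), replace = TRUE)
  # background strictly outside the peaks (incl. a fragment-length margin)
  bg_pool <- setdiff(0:1999799, unlist(lapply(pk3$start, function(s)
    (s - 200):(s + 9999))))
  pos[!inp] <- sample(bg_pool, n - sum(inp), replace = TRUE)
  fs3 <- fragment_set(data.frame(contig = "c", start = pos, end = pos + 200L,
                                 barcode = "b"),
                      "accessibility", c(c = 2000000L), collapse = FALSE)
  sn3 <- signal_to_noise(fs3, pk3, n_shuffles = 3L, seed = 2L)
  expect_gte(sn3$ratio, 8); expect_lte(sn3$ratio, 12)
  # seed determinism
  sn3b <- signal_to_noise(fs3, pk3, n_shuffles = 3L, seed = 2L)
  expect_identical(sn3, sn3b)
})
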