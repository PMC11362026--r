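test_that("gene scores match the decay formula and a brute-force oracle", {
  gm <- gene_model(data.frame(gene_id = "g1", contig = "c", strand = "+",
                              body_start = 10000L, body_end = 12000L,
                              tss = 10000L))
  # single fragment inside the body: pre-normalization score 1
  fs <- fragment_set(data.frame(contig = "c", start = 10500L, end = 10700L,
                                barcode = "cell1"),
                     "accessibility", c(c = 300000L), collapse = FALSE)
  gs <- gene_scores(fs, gm, normalize = FALSE)
  expect_equal(as.numeric(gs$scores["cell1", "g1"]), 1)

  # fragment at exactly one decay length from the region edge: weight e^-1
  fs2 <- fragment_set(data.frame(contig = "c", start = 16900L, end = 17100L,
                                 barcode = "cell1"),
                      "accessibility", c(c = 300000L), collapse = FALSE)
  gs2 <- gene_scores(fs2, gm, decay = 5000, normalize = FALSE)
  expect_equal(as.numeric(gs2$scores["cell1", "g1"]), exp(-1))

  # toy 5-gene / 3-cell layout vs an independent per-fragment loop
  set.seed(61)
  genes <- data.frame(gene_id = paste0("g", 1:5), contig = "c",
                      strand = c("+", "-", "+", "-", "+"),
                      body_start = c(10000L, 50000L, 90000L, 130000L, 170000L))
  genes$body_end <- genes$body_start + 2000L
  genes$tss <- ifelse(genes$strand == "+", genes$body_start, genes$body_end)
  gm3 <- gene_model(genes)
  n <- 500
  fr <- data.frame(contig = "c",
                   start = sample(0:199000, n, replace = TRUE),
                   barcode = sample(paste0("cell", 1:3), n, replace = TRUE))
  fr$end <- fr$start + 200L
  fs3 <- fragment_set(fr, "accessibility", c(c = 300000L), collapse = FALSE)
  gs3 <- gene_scores(fs3, gm3, normalize = FALSE)

  oracle <- matrix(0, 3, 5,
                   dimnames = list(paste0("cell", 1:3), genes$gene_id))
  for (i in seq_len(n)) {
    mid <- fr$start[i] + 100L
    for (g in seq_len(5)) {
      rs <- if (genes$strand[g] == "+") genes$body_start[g] - 2000L
            else genes$body_start[g]
      re <- if (genes$strand[g] == "+") genes$body_end[g]
            else genes$body_end[g] + 2000L
      d <- max(0, rs - mid, mid - re)
      if (d <= 100000) {
        w <- min(exp(-d / 5000), 4)
        oracle[fr$barcode[i], g] <- oracle[fr$barcode[i], g] + w
      }
    }
  }
  expect_equal(as.matrix(gs3$scores)[rownames(oracle), ], oracle,
               tolerance = 1e-12)

  # additivity over disjoint fragment subsets before normalization
  h <- seq_len(n %/% 2)
  gs_a <- gene_scores(fragment_set(fr[h, ], "accessibility", c(c = 300000L),
                                   collapse = FALSE), gm3, normalize = FALSE)
  gs_b <- gene_scores(fragment_set(fr[-h, ], "accessibility", c(c = 300000L),
                                   collapse = FALSE), gm3, normalize = FALSE)
  tot <- as.matrix(gs_a$scores)[rownames(oracle), ] +
    as.matrix(gs_b$scores)[rownames(oracle), ]
  expect_equal(tot, as.matrix(gs3$scores)[rownames(oracle), ],
               tolerance = 1e-12)

  # per-cell normalization sums to the target
  gsn <- gene_scores(fs3, gm3, normalize = TRUE)
  expect_true(all(abs(Matrix::rowSums(gsn$scores) - 10000) < 1e-6))
})

test_that("state classification recovers planted regulatory states", {
  cfg <- sim_config(n_cells = c(typeA = 60L, typeB = 60L),
                    fragments_per_cell = list(
                      histone = list(mean = 800, dispersion = 4),
                      accessibility = list(mean = 1000, dispersion = 4)),
                    n_genes = 100L, seed = 62L)
  tr <- generate_truth(cfg)
  fx <- generate_fragments(tr)
  gm <- gene_model(tr$genes[, c("gene_id", "contig", "strand",
                                "body_start", "body_end", "tss")])
  gsA <- gene_scores(sim_fragset(fx, "accessibility", tr), gm)
  gsR <- gene_scores(sim_fragset(fx, "histone", tr), gm)
  groups <- setNames(tr$cells$cell_type, tr$cells$barcode)
  cs <- classify_states(gsA, gsR, groups)
  m <- merge(cs$calls, tr$states,
             by.x = c("gene_id", "group"), by.y = c("gene_id", "cell_type"))
  recall <- m[, .(r = mean(state.x == state.y)), by = state.y]
  expect_true(all(recall$r >= 0.95))

  # invariance to positive rescaling of either score matrix
  cs2 <- classify_states(gsA$scores * 7, gsR$scores * 0.1, groups)
  expect_equal(cs2$calls$state, cs$calls$state)
})

test_that("state classification degenerate and expression summaries", {
  A <- matrix(c(10, 10, 1, 1), 2, 2, byrow = TRUE,
              dimnames = list(c("c1", "c2"), c("gA", "gB")))
  A <- rbind(A, A); rownames(A) <- paste0("c", 1:4)
  A <- cbind(A, gC = 0, gD = 0)
  R <- A * 0
  groups <- setNames(rep("grp", 4), paste0("c", 1:4))
  cs <- classify_states(A, R, groups, access_q = 0.75, repress_q = 0.75)
  # all repression scores zero: nothing is accessible_silenced
  expect_false(any(cs$calls$state == "accessible_silenced"))

  # expression all-positive for accessible genes -> not-expressed fraction 0
  expr <- matrix(c(5, 5, 0, 0), 4, 1, dimnames = list(colnames(A), "grp"))
  cs2 <- classify_states(A, R, groups, expression = expr)
  expect_equal(cs2$expression_summary$frac_accessible_not_expressed, 0)
})

test_that("region co-occupancy equals a per-bp bitmap oracle", {
  expect_equal(unname(modality_region_overlap(
    data.frame(contig = "c", start = 0L, end = 100L),
    data.frame(contig = "c", start = 0L, end = 100L),
    1000)$union_fractions["both"]), 1)
  expect_equal(unname(modality_region_overlap(
    data.frame(contig = "c", start = 0L, end = 100L),
    data.frame(contig = "c", start = 500L, end = 600L),
    1000)$union_fractions["both"]), 0)

  set.seed(63)
  for (rep_i in 1:5) {
    G <- 100000L
    A <- data.frame(contig = "c", start = sample(0:(G - 200), 30))
    A$end <- A$start + sample(50:2000, 30, replace = TRUE)
    A$end <- pmin(A$end, G)
    B <- data.frame(contig = "c", start = sample(0:(G - 200), 20))
    B$end <- B$start + sample(50:5000, 20, replace = TRUE)
    B$end <- pmin(B$end, G)
    got <- modality_region_overlap(A, B, G)

    bmA <- logical(G); bmB <- logical(G)
    for (i in seq_len(nrow(A))) bmA[(A$start[i] + 1):A$end[i]] <- TRUE
    for (i in seq_len(nrow(B))) bmB[(B$start[i] + 1):B$end[i]] <- TRUE
    u <- sum(bmA | bmB)
    expect_equal(unname(got$bp["both"]), sum(bmA & bmB))
    expect_equal(unname(got$union_fractions["both"]), sum(bmA & bmB) / u)
    expect_equal(unname(got$union_fractions["access_only"]),
                 sum(bmA & !bmB) / u)
    expect_equal(unname(got$union_fractions["repress_only"]),
                 sum(!bmA & bmB) / u)
    expect_equal(sum(got$union_fractions), 1)
    expect_equal(unname(got$genome_fractions["neither"]),
                 sum(!bmA & !bmB) / G)
  }
})

test_that("TSS preference follows the A/(1+R) rule with tie handling", {
  gm <- gene_model(
    data.frame(gene_id = "g", contig = "c", strand = "+",
               body_start = 10000L, body_end = 30000L),
    tss_table = data.frame(gene_id = "g", contig = "c",
                           position = c(10000L, 20000L), strand = "+"))
  mk <- function(positions, md) {
    fragment_set(data.frame(contig = rep("c", length(positions)),
                            start = positions, end = positions + 1L,
                            barcode = rep("b", length(positions))),
                 md, c(c = 50000L), collapse = FALSE)
  }
  # equal accessibility at both, repression only at TSS1: prefer TSS2
  acc <- mk(c(rep(10000L, 10), rep(20000L, 10)), "accessibility")
  rep_ <- mk(rep(10000L, 9), "histone")
  tp <- tss_preference("g", gm, acc, rep_)
  expect_equal(tp$preferred, 20000L)
  expect_false(tp$tie)

  # exact tie: lower coordinate wins, flagged
  tp2 <- tss_preference("g", gm, acc, mk(integer(0), "histone"))
  expect_true(tp2$tie)
  expect_equal(tp2$preferred, 10000L)

  # zero signal everywhere: no call
  tp3 <- tss_preference("g", gm, mk(integer(0), "accessibility"),
                        mk(integer(0), "histone"))
  expect_true(tp3$no_signal)
  expect_true(is.na(tp3$preferred))
})

test_that("planted preferred TSSs are recovered across replicate genes", {
  set.seed(64)
  n_genes <- 100
  hits <- 0
  for (g in seq_len(n_genes)) {
    tss_pos <- c(10000L, 20000L)
    preferred <- sample(1:2, 1)
    gm <- gene_model(
      data.frame(gene_id = "g", contig = "c", strand = "+",
                 body_start = 10000L, body_end = 30000L),
      tss_table = data.frame(gene_id = "g", contig = "c",
                             position = tss_pos, strand = "+"))
    # accessibility: 40 insertions at the preferred TSS, 10 at the other;
    # repression: broad fragments over the non-preferred TSS
    n_pref <- 40; n_other <- 10
    acc_pos <- c(tss_pos[preferred] + sample(-400:400, n_pref, replace = TRUE),
                 tss_pos[3 - preferred] + sample(-400:400, n_other, replace = TRUE))
    acc <- fragment_set(data.frame(contig = "c", start = acc_pos,
                                   end = acc_pos + 1L, barcode = "b"),
                        "accessibility", c(c = 50000L), collapse = FALSE)
    rep_pos <- tss_pos[3 - preferred] + sample(-2000:1800, 30, replace = TRUE)
    rep_ <- fragment_set(data.frame(contig = "c", start = rep_pos,
                                    end = rep_pos + 200L, barcode = "b"),
                         "histone", c(c = 50000L), collapse = FALSE)
    tp <- tss_preference("g", gm, acc, rep_)
    if (!is.na(tp$preferred) && tp$preferred == tss_pos[preferred])
      hits <- hits + 1
  }
  expect_gte(hits / n_genes, 0.95)
})

test_that("PSI equals brute-force per-donor normalization", {
  # donor with junction counts (3, 1) -> PSI 0.75 / 0.25
  jt <- data.frame(cell = "c1", donor_site = "d1",
                   junction_id = c("j8", "j9"), count = c(3, 1))
  expect_equal(psi(jt)$psi, c(0.75, 0.25))
  # single junction at a donor -> 1.0
  jt2 <- data.frame(cell = "c1", donor_site = "d2",
                    junction_id = "j1", count = 7)
  expect_equal(psi(jt2)$psi, 1)
  # zero family total -> missing
  jt3 <- data.frame(cell = "c1", donor_site = "d3",
                    junction_id = c("a", "b"), count = c(0, 0))
  expect_true(all(is.na(psi(jt3)$psi)))

  set.seed(65)
  tab <- expand.grid(cell = paste0("c", 1:8), donor_site = paste0("d", 1:5),
                     junction_id = paste0("j", 1:3),
                     stringsAsFactors = FALSE)
  tab$count <- rpois(nrow(tab), 2)
  got <- psi(tab)
  for (i in seq_len(nrow(got))) {
    fam <- tab$count[tab$cell == got$cell[i] &
                       tab$donor_site == got$donor_site[i]]
    expected <- if (sum(fam) == 0) NA_real_ else got$count[i] / sum(fam)
    expect_equal(got$psi[i], expected)
  }
})

test_that("cluster correspondence finds the optimal label mapping", {
  labs <- setNames(rep(c("0", "1", "2"), each = 20), paste0("c", 1:60))
  expect_equal(cluster_correspondence(labs, labs)$matched_fraction, 1)
  # permuted label names still map perfectly
  perm <- setNames(c("2", "0", "1")[as.integer(labs) + 1L], names(labs))
  expect_equal(cluster_correspondence(labs, perm)$matched_fraction, 1)
  expect_error(cluster_correspondence(labs, perm, character(0)), "empty")

  # random confusion structures vs exhaustive permutation search (k = 3, 4)
  set.seed(66)
  for (k in c(3L, 4L)) {
    for (rep_i in 1:5) {
      n <- 60L
      la <- setNames(sample(as.character(seq_len(k)), n, replace = TRUE),
                     paste0("c", seq_len(n)))
      lh <- setNames(sample(as.character(seq_len(k)), n, replace = TRUE),
                     paste0("c", seq_len(n)))
      got <- cluster_correspondence(la, lh)
      conf <- table(la, lh)
      best <- 0
      for (p in combinat_perms(k)) {
        agree <- sum(vapply(seq_len(k), function(i) conf[i, p[i]], 0L))
        best <- max(best, agree)
      }
      expect_equal(got$matched_fraction, best / n)
    }
  }
})

test_that("marker features honour the significance and fold-change gates", {
  set.seed(67)
  n <- 40
  scores <- cbind(
    up = c(rnorm(n / 2, 10), rnorm(n / 2, 2)),     # enriched in cluster a
    flat = rnorm(n, 5),
    weak = c(rnorm(n / 2, 5.2), rnorm(n / 2, 5)))  # lfc below the gate
  rownames(scores) <- paste0("c", seq_len(n))
  labels <- setNames(rep(c("a", "b"), each = n / 2), rownames(scores))
  mf <- marker_features(scores, labels)
  expect_true(mf[cluster == "a" & feature == "up"]$significant)
  expect_false(mf[cluster == "a" & feature == "flat"]$significant)
  expect_false(mf[cluster == "a" & feature == "weak"]$significant)
})

test_that("gene models load from GTF with strand-aware multi-TSS handling", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    paste("chr1", "src", "transcript", "1001", "5000", ".", "+", ".",
          "gene_id \"g1\"; transcript_id \"g1.t1\";", sep = "\t"),
    paste("chr1", "src", "transcript", "2001", "5000", ".", "+", ".",
          "gene_id \"g1\"; transcript_id \"g1.t2\";", sep = "\t"),
    paste("chr2", "src", "transcript", "3001", "6000", ".", "-", ".",
          "gene_id \"g2\"; transcript_id \"g2.t1\";", sep = "\t")), gtf)
  gm <- suppressWarnings(read_gene_model(gtf))
  expect_equal(gm$genes$body_start, c(1000L, 3000L))
  expect_equal(sort(gm$tss[gm$tss$gene_id == "g1", ]$position),
               c(1000L, 2000L))
  # minus-strand TSS is the interval end
  expect_equal(gm$tss[gm$tss$gene_id == "g2", ]$position, 6000L)
})
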