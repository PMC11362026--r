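# Shared fixtures: schemes, small simulation configs, and independent oracles
# used across test files. Everything is generated in code; no stored data.

# a tiny two-tag scheme with wide separation, for hand-constructed trios
tiny_scheme <- function(max_mismatch_tag = 1L, whitelist = NULL) {
  barcode_scheme(
    data.frame(tag_id = c("H1", "A1"),
               seq = c("AAAAAAAA", "TTTTTTTT"),
               modality = c("histone", "accessibility")),
    max_mismatch_tag = max_mismatch_tag,
    whitelist = whitelist)
}

# a small simulation: 2 cell types, shallow depth, fast everywhere
small_config <- function(seed = 1L, ...) {
  sim_config(n_cells = c(typeA = 25L, typeB = 25L),
             fragments_per_cell = list(
               histone = list(mean = 300, dispersion = 2),
               accessibility = list(mean = 400, dispersion = 2)),
             n_genes = 60L, n_distal_access = 30L, n_distal_histone = 15L,
             seed = seed, ...)
}

# independent brute-force Hamming distance
oracle_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# build a FragmentSet straight from a simulated assignment table
sim_fragset <- function(assignments, md, truth, ambient = FALSE) {
  sub <- assignments[assignments$modality == md &
                       (ambient | !assignments$is_ambient), ]
  fragment_set(sub[, c("contig", "start", "end", "barcode")], md,
               truth$contigs)
}

# write a FASTQ trio from explicit per-read fields (for fuzz tests)
write_trio_files <- function(dir, ids, r1, r2, bc) {
  paths <- file.path(dir, c("r1.fastq", "r2.fastq", "bc.fastq"))
  for (k in 1:3) {
    seqs <- list(r1, r2, bc)[[k]]
    writeLines(paste0("@", ids, "\n", seqs, "\n+\n", strrep("I", nchar(seqs))),
               paths[k])
  }
  paths
}

# adjusted Rand index between two labelings (mclust's implementation)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# a single accessibility library over a large peak universe with lognormal
# per-peak intensities, for replicate-correlation properties
make_replicate_library <- function(seed, n = 200000L, n_peaks = 2000L,
                                   contigs = c(chr1 = 2000000L,
                                               chr2 = 2000000L)) {
  set.seed(seed)
  per <- n_peaks / length(contigs)
  peaks <- data.frame(contig = rep(names(contigs), each = per),
                      start = rep(seq(0L, 1999000L, by = 1000L)[1:per],
                                  length(contigs)))
  peaks$end <- peaks$start + 400L
  w <- exp(rnorm(n_peaks, 0, 1.5))
  inp <- runif(n) < 0.9
  k <- sum(inp)
  j <- sample(n_peaks, k, replace = TRUE, prob = w)
  pos <- integer(n); ctg <- character(n)
  pos[inp] <- peaks$start[j] + sample(0:399, k, replace = TRUE)
  ctg[inp] <- peaks$contig[j]
  u <- sample.int(sum(contigs), n - k, replace = TRUE) - 1L
  ctg[!inp] <- names(contigs)[1 + (u >= contigs[1])]
  pos[!inp] <- ifelse(u >= contigs[1], u - contigs[1], u)
  fs <- fragment_set(data.frame(contig = ctg, start = pos, end = pos + 200L,
                                barcode = "bulk"),
                     "accessibility", contigs, collapse = FALSE)
  list(fs = fs, peaks = peaks, weights = w)
}

# brute-force interval overlap oracle: for each interval in A, scan all of B
oracle_overlaps_any <- function(A, B) {
  vapply(seq_len(nrow(A)), function(i) {
    any(B$contig == A$contig[i] & B$start < A$end[i] & B$end > A$start[i])
  }, logical(1))
}

# all permutations of 1..k (for the factorial correspondence oracle)
combinat_perms <- function(k) {
  if (k == 1L) return(list(1L))
  out <- list()
  for (p in combinat_perms(k - 1L)) {
    for (pos in seq_len(k)) {
      out[[length(out) + 1L]] <- append(p, k, after = pos - 1L)
    }
  }
  out
}

make_punctate_sim <- function(seed, n = 100000L,
                              contigs = c(chr1 = 1000000L, chr2 = 1000000L)) {
  set.seed(seed)
  true_pk <- data.frame(contig = rep(names(contigs), each = 10),
                        start = rep(seq(50000L, 950000L, by = 100000L), 2))
  true_pk$end <- true_pk$start + 1000L
  # 10x enrichment over 1% of the genome
  fin <- 0.1 / (0.1 + 0.99)
  inp <- runif(n) < fin
  k <- sum(inp)
  j <- sample(nrow(true_pk), k, replace = TRUE)
  pos <- integer(n); ctg <- character(n)
  pos[inp] <- true_pk$start[j] + sample(0:999, k, replace = TRUE)
  ctg[inp] <- true_pk$contig[j]
  pos[!inp] <- sample.int(1000000L, n - k, replace = TRUE) - 1L
  ctg[!inp] <- sample(names(contigs), n - k, replace = TRUE)
  fs <- fragment_set(data.frame(contig = ctg, start = pos, end = pos + 200L,
                                barcode = "bulk"),
                     "accessibility", contigs, collapse = FALSE)
  list(fs = fs, truth = true_pk)
}

make_broad_sim <- function(seed, n = 100000L,
                           contigs = c(chr1 = 1000000L, chr2 = 1000000L)) {
  set.seed(seed)
  dom <- data.frame(contig = rep(names(contigs), each = 50),
                    start = rep(seq(10000L, 990000L, by = 20000L), 2)[1:100])
  dom$end <- dom$start + 2000L
  # broad domains over a sparse background whose isolated-fragment block
  # count matches the caller's 5% retention semantics (~19 background
  # blocks per true domain)
  fin <- 0.96
  inp <- runif(n) < fin
  k <- sum(inp)
  j <- sample(nrow(dom), k, replace = TRUE)
  pos <- integer(n); ctg <- character(n)
  pos[inp] <- dom$start[j] + sample(0:1999, k, replace = TRUE)
  ctg[inp] <- dom$contig[j]
  pos[!inp] <- sample.int(1000000L, n - k, replace = TRUE) - 1L
  ctg[!inp] <- sample(names(contigs), n - k, replace = TRUE)
  fs <- fragment_set(data.frame(contig = ctg, start = pos, end = pos + 300L,
                                barcode = "bulk"),
                     "histone", contigs, collapse = FALSE)
  list(fs = fs, truth = dom)
}

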