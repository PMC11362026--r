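# Simplified peak calling for the two signal classes, plus annotation,
# overlap and CPM quantification. Both callers are declared simplifications
# of the widely used external tools, pinned by explicit contracts so their
# behaviour is exactly testable: a Poisson/Benjamini-Hochberg insertion-bin
# caller for punctate accessibility signal (honouring the q <= 0.01
# threshold), and a quantile block caller for broad sparse-enrichment
# domains (honouring the top-5% "stringent" semantics).

#' Call punctate peaks from insertion counts (Poisson + BH)
#'
#' Pseudo-bulk insertions (both fragment ends) are binned; each bin's count
#' is tested against a one-sided Poisson null with the genome-wide rate
#' \eqn{\lambda \cdot} \code{bin_size}; p-values are Benjamini-Hochberg
#' adjusted across all bins; significant bins (q \eqn{\le} \code{q_max}) are
#' merged within \code{merge_gap} bp, and peaks narrower than
#' \code{min_width} bp are dropped.
#'
#' @param fragset a \code{FragmentSet}.
#' @param bin_size bin width in bp.
#' @param q_max BH-adjusted significance threshold (default 0.01).
#' @param merge_gap maximal gap (bp) bridged when merging significant bins.
#' @param min_width minimal peak width (bp).
#' @return data.table of peaks: \code{contig}, \code{start}, \code{end}
#'   (0-based half-open), \code{score} (fold enrichment over the global
#'   rate), \code{q_value} (minimal bin q inside the peak). Empty input
#'   yields an empty table.
#' @export
call_peaks_insertion <- function(fragset, bin_size = 50L, q_max = 0.01,
                                 merge_gap = 150L, min_width = 100L) {
  empty <- data.table::data.table(contig = character(), start = integer(),
                                  end = integer(), score = numeric(),
                                  q_value = numeric())
  fr <- fragset$fragments
  if (nrow(fr) == 0L) return(empty)
  ins <- .insertions(fragset)
  genome_size <- sum(as.numeric(fragset$contigs))
  total <- sum(ins$w)
  lambda <- total / genome_size * bin_size

  bins <- list()
  for (cn in names(fragset$contigs)) {
    L <- fragset$contigs[[cn]]
    nb <- as.integer(ceiling(L / bin_size))
    sub <- ins[contig == cn]
    cnt <- integer(nb)
    if (nrow(sub)) {
      b <- pmin(sub$pos %/% bin_size + 1L, nb)
      agg <- tapply(sub$w, b, sum)
      cnt[as.integer(names(agg))] <- as.integer(agg)
    }
    bins[[cn]] <- data.table::data.table(contig = cn, bin = seq_len(nb) - 1L,
                                         count = cnt)
  }
  bins <- data.table::rbindlist(bins)
  bins[, p := stats::ppois(count - 1L, lambda, lower.tail = FALSE)]
  bins[, q := stats::p.adjust(p, method = "BH")]
  sig <- bins[q <= q_max & count > 0L]
  if (nrow(sig) == 0L) return(empty)
  sig[, `:=`(start = bin * bin_size,
             end = pmin((bin + 1L) * bin_size,
                        as.integer(fragset$contigs[contig])))]

  gr <- GenomicRanges::GRanges(sig$contig,
                               IRanges::IRanges(sig$start + 1L, sig$end),
                               q = sig$q, count = sig$count)
  merged <- GenomicRanges::reduce(gr, min.gapwidth = merge_gap + 1L)
  hits <- GenomicRanges::findOverlaps(gr, merged)
  qmin <- tapply(sig$q[S4Vectors::queryHits(hits)],
                 S4Vectors::subjectHits(hits), min)
  cmean <- tapply(sig$count[S4Vectors::queryHits(hits)],
                  S4Vectors::subjectHits(hits), mean)
  out <- data.table::data.table(
    contig = as.character(GenomicRanges::seqnames(merged)),
    start = GenomicRanges::start(merged) - 1L,
    end = GenomicRanges::end(merged),
    score = as.numeric(cmean) / lambda,
    q_value = as.numeric(qmin))
  out <- out[end - start >= min_width]
  data.table::setorder(out, contig, start)
  out[]
}

#' Call broad domains from a sparse coverage profile (quantile blocks)
#'
#' Enumerates contiguous blocks of nonzero coverage; a block's signal is its
#' area under the coverage curve. Blocks whose signal reaches the
#' \eqn{(1 - }\code{threshold_fraction}\eqn{)} quantile of block signals are
#' retained (ties at the quantile are kept); \code{"stringent"} mode
#' additionally requires the block maximum to reach the same quantile of
#' block maxima.
#'
#' @param fragset a \code{FragmentSet}; full fragment lengths contribute to
#'   coverage (duplicate-weighted).
#' @param threshold_fraction retained fraction of blocks (default 0.05).
#' @param mode \code{"stringent"} or \code{"relaxed"}.
#' @return data.table of domains: \code{contig}, \code{start}, \code{end},
#'   \code{score} (block AUC), \code{max_cov}. All-zero coverage yields an
#'   empty table.
#' @export
call_peaks_sparse <- function(fragset, threshold_fraction = 0.05,
                              mode = c("stringent", "relaxed")) {
  mode <- match.arg(mode)
  empty <- data.table::data.table(contig = character(), start = integer(),
                                  end = integer(), score = numeric(),
                                  max_cov = numeric())
  fr <- fragset$fragments
  if (nrow(fr) == 0L) return(empty)
  gr <- GenomicRanges::GRanges(fr$contig, IRanges::IRanges(fr$start + 1L, fr$end))
  cov <- GenomicRanges::coverage(gr, weight = as.numeric(fr$duplicate_count))

  blocks <- list()
  for (cn in names(cov)) {
    rl <- cov[[cn]]
    v <- IRanges::slice(rl, lower = 1e-9, rangesOnly = FALSE)
    if (length(v) == 0L) next
    auc <- IRanges::viewSums(v)
    mx <- IRanges::viewMaxs(v)
    blocks[[cn]] <- data.table::data.table(
      contig = cn,
      start = IRanges::start(v) - 1L,
      end = IRanges::end(v),
      score = as.numeric(auc),
      max_cov = as.numeric(mx))
  }
  blocks <- data.table::rbindlist(blocks)
  if (is.null(blocks) || nrow(blocks) == 0L) return(empty)

  thr_sig <- stats::quantile(blocks$score, 1 - threshold_fraction, type = 1)
  keep <- blocks$score >= thr_sig
  if (mode == "stringent") {
    thr_max <- stats::quantile(blocks$max_cov, 1 - threshold_fraction, type = 1)
    keep <- keep & blocks$max_cov >= thr_max
  }
  out <- blocks[keep]
  data.table::setorder(out, contig, start)
  out[]
}

#' Annotate peaks against a gene model
#'
#' Each peak is assigned one category by its midpoint with precedence
#' promoter > genic > distal; the promoter is a strand-aware window around
#' the TSS.
#'
#' @param peaks data.frame with \code{contig}, \code{start}, \code{end}.
#' @param gene_model a \code{GeneModel} (see \code{\link{gene_model}}).
#' @param promoter_window numeric length-2, promoter extent relative to the
#'   TSS in transcription direction (default \code{c(-3000, 3000)}).
#' @return list with \code{categories} (per-peak character vector) and
#'   \code{fractions} (named numeric over promoter/genic/distal summing to 1;
#'   all 0 with \code{empty = TRUE} flag for an empty peak set).
#' @export
annotate_peaks <- function(peaks, gene_model, promoter_window = c(-3000, 3000)) {
  pk <- data.table::as.data.table(peaks)
  if (nrow(pk) == 0L)
    return(list(categories = character(0),
                fractions = c(promoter = 0, genic = 0, distal = 0),
                empty = TRUE))
  genes <- gene_model$genes
  tss <- gene_model$tss
  mid <- pk$start + (pk$end - pk$start) %/% 2L

  up <- promoter_window[1]; dn <- promoter_window[2]
  prom <- data.table::data.table(
    contig = tss$contig,
    start = as.integer(ifelse(tss$strand == "+", tss$position + up,
                              tss$position - dn)),
    end = as.integer(ifelse(tss$strand == "+", tss$position + dn,
                            tss$position - up)))
  prom[, start := pmax(start, 0L)]
  genic <- data.table::data.table(contig = genes$contig,
                                  start = genes$body_start,
                                  end = genes$body_end)
  midq <- data.table::data.table(contig = pk$contig, start = mid, end = mid + 1L)

  in_set <- function(q, set) {
    if (nrow(set) == 0L) return(rep(FALSE, nrow(q)))
    ov <- .overlaps_halfopen(q, set, nomatch = NULL)
    res <- rep(FALSE, nrow(q))
    res[unique(ov$xid)] <- TRUE
    res
  }
  is_prom <- in_set(midq, prom)
  is_genic <- in_set(midq, genic)
  cat <- ifelse(is_prom, "promoter", ifelse(is_genic, "genic", "distal"))
  fr <- c(promoter = mean(cat == "promoter"),
          genic = mean(cat == "genic"),
          distal = mean(cat == "distal"))
  list(categories = cat, fractions = fr, empty = FALSE)
}

#' Fraction of one peak set overlapping another
#'
#' Both sets are merged internally; the fraction is the share of merged A
#' intervals overlapping at least one merged B interval by >= 1 bp. The
#' symmetric direction is reported alongside.
#'
#' @param peaksA,peaksB data.frames with \code{contig}, \code{start},
#'   \code{end}.
#' @return list with \code{fraction_A_in_B}, \code{fraction_B_in_A},
#'   \code{n_A}, \code{n_B}; an empty A (after merging) yields
#'   \code{fraction_A_in_B = NA} with \code{undefined_A = TRUE}.
#' @export
overlap_fraction <- function(peaksA, peaksB) {
  A <- .merge_intervals(data.table::as.data.table(peaksA))
  B <- .merge_intervals(data.table::as.data.table(peaksB))
  frac <- function(X, Y) {
    if (nrow(X) == 0L) return(NA_real_)
    if (nrow(Y) == 0L) return(0)
    ov <- .overlaps_halfopen(X, Y, nomatch = NULL)
    length(unique(ov$xid)) / nrow(X)
  }
  list(fraction_A_in_B = frac(A, B), fraction_B_in_A = frac(B, A),
       n_A = nrow(A), n_B = nrow(B),
       undefined_A = nrow(A) == 0L, undefined_B = nrow(B) == 0L)
}

#' Quantify peak signal across samples as counts per million
#'
#' Counts fragments overlapping each peak (>= 1 bp, duplicate-weighted) per
#' sample, converts to CPM over the sample's total fragment count, and
#' reports pairwise Pearson correlations on \code{log1p(CPM)}.
#'
#' @param peaks shared peak universe (\code{contig}, \code{start},
#'   \code{end}); merged internally.
#' @param fragsets named list of \code{FragmentSet}s.
#' @param include_background add a final pseudo-row holding all fragments
#'   not in any peak, so each sample's column sums to 1e6.
#' @return list with \code{counts}, \code{cpm} (peaks x samples matrices) and
#'   \code{correlation} (samples x samples, on log1p CPM).
#' @export
quantify_cpm <- function(peaks, fragsets, include_background = FALSE) {
  pk <- .merge_intervals(data.table::as.data.table(peaks))
  nmz <- names(fragsets)
  if (is.null(nmz)) nmz <- paste0("sample", seq_along(fragsets))
  counts <- matrix(0, nrow = nrow(pk) + include_background,
                   ncol = length(fragsets),
                   dimnames = list(NULL, nmz))
  totals <- numeric(length(fragsets))
  for (j in seq_along(fragsets)) {
    fr <- fragsets[[j]]$fragments
    total <- sum(fr$duplicate_count)
    if (total == 0) stop("zero-total sample: ", nmz[j])
    totals[j] <- total
    ov <- .overlaps_halfopen(fr, pk, nomatch = NULL)
    if (nrow(ov)) {
      # a fragment spanning two merged peaks is counted once per peak
      agg <- tapply(fr$duplicate_count[ov$xid], ov$yid, sum)
      counts[as.integer(names(agg)), j] <- as.numeric(agg)
    }
    if (include_background) {
      in_pk <- sum(fr$duplicate_count[unique(ov$xid)])
      counts[nrow(pk) + 1L, j] <- total - in_pk
    }
  }
  cpm <- sweep(counts, 2, totals, "/") * 1e6
  corr <- stats::cor(log1p(cpm))
  list(peaks = pk, counts = counts, cpm = cpm, correlation = corr)
}
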