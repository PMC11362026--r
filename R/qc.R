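# Per-cell and per-library quality control: fragment-size ladder, TSS
# enrichment, FRiP, the modality-specific cell filters, and a shuffle-based
# signal-to-noise ratio.

#' Fragment-size distribution and nucleosomal-ladder metrics
#'
#' Histograms fragment sizes at 1-bp resolution up to \code{max_size},
#' smooths with a centred running mean, and reports local maxima with their
#' prominence, a mono/di amplitude ratio, and a periodicity score: the
#' normalized autocorrelation of the (mean-centred) histogram at the local
#' maximum nearest the nucleosomal repeat band (lag 180--220 bp).
#'
#' @param fragset a \code{FragmentSet} (duplicate-weighted).
#' @param max_size histogram upper bound (bp).
#' @param smooth_window running-mean window (odd, bp).
#' @param prominence_min minimal relative prominence (fraction of the global
#'   smoothed maximum) for a mode to be reported.
#' @return list with \code{histogram} (size, count, smoothed), \code{modes}
#'   (data.frame: size, height, prominence), \code{mono_di_ratio},
#'   \code{periodicity} (0 when undefined, with \code{periodicity_defined}
#'   flag), and \code{ladder} (TRUE when >= 2 prominent modes separated by
#'   140--260 bp).
#' @export
size_distribution <- function(fragset, max_size = 1000L, smooth_window = 11L,
                              prominence_min = 0.05) {
  fr <- fragset$fragments
  if (nrow(fr) == 0L) stop("empty fragment set")
  sizes <- rep(fr$end - fr$start, fr$duplicate_count)
  sizes <- sizes[sizes >= 1L & sizes <= max_size]
  if (!length(sizes)) stop("no fragments within the size range")
  count <- tabulate(sizes, nbins = max_size)
  sm <- .running_mean(count, smooth_window)

  modes <- .local_maxima(sm, prominence_min * max(sm))
  mono <- modes$size[which.min(abs(modes$size - 200))]
  di <- modes$size[which.min(abs(modes$size - 400))]
  mono_di_ratio <- if (length(mono) && length(di) && mono != di)
    sm[mono] / sm[di] else NA_real_

  ac <- stats::acf(count - mean(count), lag.max = min(400L, max_size - 1L),
                   plot = FALSE)$acf[-1]
  locmax <- which(diff(sign(diff(ac))) == -2) + 1L
  band <- locmax[locmax >= 150 & locmax <= 250]
  periodicity <- 0
  periodicity_defined <- FALSE
  if (length(band)) {
    nearest <- band[which.min(pmax(0, abs(band - 200) - 20))]
    if (ac[nearest] > 0) {
      periodicity <- ac[nearest]
      periodicity_defined <- TRUE
    }
  }

  ladder <- FALSE
  if (nrow(modes) >= 2L) {
    gaps <- diff(sort(modes$size))
    ladder <- any(gaps >= 140 & gaps <= 260)
  }
  list(histogram = data.frame(size = seq_len(max_size), count = count,
                              smoothed = sm),
       modes = modes, mono_di_ratio = mono_di_ratio,
       periodicity = periodicity, periodicity_defined = periodicity_defined,
       ladder = ladder)
}

.running_mean <- function(x, w) {
  if (w <= 1L) return(as.numeric(x))
  sm <- as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
  na <- is.na(sm)
  sm[na] <- x[na]
  sm
}

# local maxima of a smoothed series with standard topographic prominence:
# drop from the peak to the highest saddle separating it from a higher peak
.local_maxima <- function(sm, min_prom) {
  n <- length(sm)
  # strict rise on the left, non-increase on the right: marks the first
  # index of a plateau as well as simple maxima
  cand <- which(sm > c(-Inf, sm[-n]) & sm >= c(sm[-1], -Inf))
  cand <- cand[cand > 1L & cand < n]
  # report plateau centres
  cand <- vapply(cand, function(i) {
    j <- i
    while (j < n && sm[j + 1L] == sm[i]) j <- j + 1L
    (i + j) %/% 2L
  }, 1L)
  if (!length(cand))
    return(data.frame(size = integer(0), height = numeric(0),
                      prominence = numeric(0)))
  prom <- numeric(length(cand))
  for (k in seq_along(cand)) {
    i <- cand[k]; h <- sm[i]
    left <- sm[seq_len(i - 1L)]
    higher_l <- which(left > h)
    base_l <- if (length(higher_l)) min(sm[max(higher_l):i]) else min(sm[1:i])
    right <- sm[seq(i + 1L, n)]
    higher_r <- which(right > h)
    base_r <- if (length(higher_r)) min(sm[i:(i + min(higher_r))]) else min(sm[i:n])
    prom[k] <- h - max(base_l, base_r)
  }
  keep <- prom >= min_prom
  # collapse plateaus/jitter: keep the highest candidate within 40 bp
  out <- data.frame(size = cand[keep], height = sm[cand[keep]],
                    prominence = prom[keep])
  if (nrow(out) > 1L) {
    out <- out[order(-out$height), ]
    sel <- logical(nrow(out))
    for (k in seq_len(nrow(out))) {
      if (!any(abs(out$size[sel] - out$size[k]) < 40)) sel[k] <- TRUE
    }
    out <- out[sel, ]
    out <- out[order(out$size), ]
  }
  rownames(out) <- NULL
  out
}

#' Per-cell TSS enrichment score
#'
#' Both fragment ends are insertion events. For each cell, the score is the
#' mean insertion density (per bp) within \eqn{\pm}\code{center_halfwidth} of
#' any TSS divided by the mean density within the outermost \code{flank} bp
#' at each edge of the \eqn{\pm}\code{window} region, with a +1 pseudocount
#' added to the flank count so the ratio is always finite.
#'
#' @param fragset a \code{FragmentSet}.
#' @param tss data.frame with \code{contig}, \code{position} (0-based TSS
#'   coordinates); a strand column is accepted and ignored (windows are
#'   symmetric).
#' @param window half-width of the scored region around each TSS (bp).
#' @param center_halfwidth half-width of the central window (bp).
#' @param flank width of the background window at each edge (bp).
#' @return data.table with \code{barcode} and \code{tss_score} (cells with no
#'   insertions in any window score 0).
#' @export
tss_enrichment <- function(fragset, tss, window = 2000L,
                           center_halfwidth = 50L, flank = 100L) {
  stopifnot(nrow(tss) > 0L)
  ins <- .insertions(fragset)
  tssdt <- data.table::as.data.table(tss)

  center_bp <- 2L * center_halfwidth + 1L
  flank_bp <- 2L * flank

  cen <- .count_in_windows(ins, tssdt, -center_halfwidth, center_halfwidth)
  fl_l <- .count_in_windows(ins, tssdt, -window, -window + flank - 1L)
  fl_r <- .count_in_windows(ins, tssdt, window - flank + 1L, window)

  all_bc <- unique(ins$barcode)
  out <- data.table::data.table(barcode = all_bc)
  out <- merge(out, cen, by = "barcode", all.x = TRUE)
  data.table::setnames(out, "n", "center")
  out <- merge(out, fl_l, by = "barcode", all.x = TRUE)
  data.table::setnames(out, "n", "flank_l")
  out <- merge(out, fl_r, by = "barcode", all.x = TRUE)
  data.table::setnames(out, "n", "flank_r")
  for (cl in c("center", "flank_l", "flank_r"))
    out[is.na(get(cl)), (cl) := 0L]
  out[, tss_score := (center / center_bp) /
        ((flank_l + flank_r + 1) / flank_bp)]
  out[center + flank_l + flank_r == 0L, tss_score := 0]
  out[, .(barcode, tss_score)]
}

# insertion events: both ends of every fragment, duplicate-weighted
.insertions <- function(fragset) {
  fr <- fragset$fragments
  dt <- data.table::rbindlist(list(
    fr[, .(contig, pos = start, barcode, w = duplicate_count)],
    fr[, .(contig, pos = end - 1L, barcode, w = duplicate_count)]))
  dt
}

# total (weighted) insertions per barcode falling into [position+lo,
# position+hi] around any row of `centers` (data.table: contig, position)
.count_in_windows <- function(ins, centers, lo, hi) {
  win <- data.table::data.table(contig = centers$contig,
                                start = centers$position + lo,
                                end = centers$position + hi)
  data.table::setkey(win, contig, start, end)
  q <- ins[, .(contig, start = pos, end = pos, barcode, w)]
  ov <- data.table::foverlaps(q, win, type = "within", nomatch = NULL)
  ov[, .(n = sum(w)), by = barcode]
}

#' Per-cell fraction of fragments in peaks (FRiP)
#'
#' @param fragset a \code{FragmentSet}.
#' @param peaks data.frame with \code{contig}, \code{start}, \code{end};
#'   merged internally.
#' @return data.table with \code{barcode}, \code{n_fragments},
#'   \code{in_peaks}, \code{frip}. Cells absent from the fragment set are
#'   simply absent.
#' @export
frip <- function(fragset, peaks) {
  pk <- .merge_intervals(data.table::as.data.table(peaks))
  fr <- fragset$fragments
  ov <- .overlaps_halfopen(fr, pk)
  hit <- !is.na(ov$yid)
  hit_rows <- unique(ov$xid[hit])
  fr2 <- data.table::copy(fr)
  fr2[, in_peak := FALSE]
  fr2[hit_rows, in_peak := TRUE]
  out <- fr2[, .(n_fragments = sum(duplicate_count),
                 in_peaks = sum(duplicate_count[in_peak])), by = barcode]
  out[, frip := in_peaks / n_fragments]
  out
}

# >= 1 bp overlaps between two half-open interval tables; returns
# data.table(xid, yid) including NA yid for unmatched x rows
.overlaps_halfopen <- function(x, y, nomatch = NA) {
  x2 <- data.table::data.table(contig = x$contig, start = x$start,
                               end = x$end - 1L)
  y2 <- data.table::data.table(contig = y$contig, start = y$start,
                               end = y$end - 1L)
  data.table::setkey(y2, contig, start, end)
  data.table::foverlaps(x2, y2, type = "any", which = TRUE, nomatch = nomatch)
}

# merge overlapping/adjacent intervals (0-based half-open)
.merge_intervals <- function(dt) {
  dt <- dt[, .(contig, start = as.integer(start), end = as.integer(end))]
  data.table::setorder(dt, contig, start, end)
  gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    dt$contig, IRanges::IRanges(dt$start + 1L, dt$end)))
  data.table::data.table(contig = as.character(GenomicRanges::seqnames(gr)),
                         start = GenomicRanges::start(gr) - 1L,
                         end = GenomicRanges::end(gr))
}

#' Apply the per-cell quality filters
#'
#' A cell participates in downstream analysis only if its TSS score is not
#' below the modality-specific threshold (histone-modification data: 0,
#' chromatin-accessibility data: 2) and it has at least \code{min_fragments}
#' fragments (default 500); both "below" comparisons are strict, so a cell
#' exactly at a threshold is kept.
#'
#' @param qc_table data.frame/data.table with \code{barcode},
#'   \code{n_fragments}, \code{tss_score}.
#' @param modality \code{"histone"} or \code{"accessibility"}.
#' @param tss_thresholds named numeric thresholds per modality.
#' @param min_fragments minimal fragment count.
#' @return the filtered table (rows that pass), with a \code{pass_filter}
#'   column added to a copy of the input accessible via
#'   \code{attr(, "full")}.
#' @export
filter_cells <- function(qc_table, modality,
                         tss_thresholds = c(histone = 0, accessibility = 2),
                         min_fragments = 500L) {
  if (!modality %in% names(tss_thresholds))
    stop("unknown modality: ", modality)
  dt <- data.table::as.data.table(qc_table)
  stopifnot(all(c("barcode", "n_fragments", "tss_score") %in% names(dt)))
  dt <- data.table::copy(dt)
  dt[, pass_filter := tss_score >= tss_thresholds[[modality]] &
       n_fragments >= min_fragments]
  out <- dt[pass_filter == TRUE]
  data.table::setattr(out, "full", dt)
  out
}

#' Assemble a per-cell QC profile table
#'
#' @param fragset a \code{FragmentSet}.
#' @param peaks peak intervals for FRiP.
#' @param tss TSS table for the enrichment score.
#' @return data.table: barcode, modality, n_fragments, n_unique, frip,
#'   tss_score, median_size.
#' @export
qc_profile <- function(fragset, peaks, tss) {
  fr <- fragset$fragments
  base <- fr[, .(n_fragments = sum(duplicate_count), n_unique = .N,
                 median_size = stats::median(rep(end - start, duplicate_count))),
             by = barcode]
  fp <- frip(fragset, peaks)[, .(barcode, frip)]
  ts <- tss_enrichment(fragset, tss)
  out <- Reduce(function(a, b) merge(a, b, by = "barcode", all.x = TRUE),
                list(base, fp, ts))
  out[is.na(frip), frip := 0]
  out[is.na(tss_score), tss_score := 0]
  out[, modality := fragset$modality]
  out[]
}

#' Shuffle-based signal-to-noise ratio of a fragment library
#'
#' Ratio of the mean per-bp coverage inside peaks to the mean per-bp coverage
#' in \code{n_shuffles} size-matched random placements drawn outside the
#' peaks. When the background coverage is exactly zero the ratio is reported
#' as an infinity sentinel with \code{background_zero = TRUE}.
#'
#' @param fragset a \code{FragmentSet} (pseudo-bulk).
#' @param peaks peak intervals.
#' @param n_shuffles number of random placements per peak.
#' @param seed RNG seed (placements are seed-deterministic).
#' @return list with \code{ratio}, \code{signal}, \code{background},
#'   \code{background_zero}.
#' @export
signal_to_noise <- function(fragset, peaks, n_shuffles = 10L, seed = 1L) {
  set.seed(seed)
  pk <- .merge_intervals(data.table::as.data.table(peaks))
  sig <- .mean_coverage(fragset, pk)

  widths <- pk$end - pk$start
  bg_means <- numeric(0)
  for (s in seq_len(n_shuffles)) {
    plc <- .random_nonpeak_placements(widths, fragset$contigs, pk)
    bg_means <- c(bg_means, .mean_coverage(fragset, plc))
  }
  bg <- mean(bg_means)
  if (bg == 0)
    return(list(ratio = Inf, signal = sig, background = 0,
                background_zero = TRUE))
  list(ratio = sig / bg, signal = sig, background = bg,
       background_zero = FALSE)
}

# mean per-bp duplicate-weighted coverage of `fragset` over intervals `iv`
.mean_coverage <- function(fragset, iv) {
  fr <- fragset$fragments
  q <- data.table::data.table(contig = iv$contig, start = iv$start, end = iv$end)
  data.table::setkey(q, contig, start, end)
  ov <- data.table::foverlaps(fr, q, type = "any", nomatch = NULL)
  if (nrow(ov) == 0L) return(0)
  covered <- ov[, sum(as.numeric(duplicate_count) *
                        (pmin(end, i.end) - pmax(start, i.start)))]
  covered / sum(as.numeric(iv$end - iv$start))
}

.random_nonpeak_placements <- function(widths, contigs, peaks,
                                       max_tries = 50L) {
  n <- length(widths)
  out <- data.table::data.table(contig = character(n), start = integer(n),
                                end = integer(n))
  data.table::setkey(peaks, contig, start, end)
  for (i in seq_len(n)) {
    for (t in seq_len(max_tries)) {
      ci <- sample.int(length(contigs), 1L, prob = as.numeric(contigs))
      s <- floor(stats::runif(1) * (contigs[ci] - widths[i]))
      cand <- data.table::data.table(contig = names(contigs)[ci],
                                     start = as.integer(s),
                                     end = as.integer(s + widths[i]))
      data.table::setkey(cand, contig, start, end)
      if (nrow(data.table::foverlaps(cand, peaks, nomatch = NULL)) == 0L) break
    }
    data.table::set(out, i, "contig", cand$contig)
    data.table::set(out, i, "start", cand$start)
    data.table::set(out, i, "end", cand$end)
  }
  out
}

#' Export per-cell coverage as bedGraph text
#'
#' Subsets a fragment set to one barcode and writes its per-bp coverage as a
#' bedGraph (0-based half-open), the text-format counterpart of per-cell
#' track splitting.
#'
#' @param fragset a \code{FragmentSet}.
#' @param barcode cell barcode to export.
#' @param path output path.
#' @return (invisibly) the path.
#' @export
export_cell_bedgraph <- function(fragset, barcode, path) {
  fr <- fragset$fragments[fragset$fragments$barcode == barcode]
  if (nrow(fr) == 0L) stop("barcode not present: ", barcode)
  gr <- GenomicRanges::GRanges(fr$contig,
                               IRanges::IRanges(fr$start + 1L, fr$end))
  cov <- GenomicRanges::coverage(gr, weight = fr$duplicate_count)
  rows <- list()
  for (cn in names(cov)) {
    rl <- cov[[cn]]
    v <- S4Vectors::runValue(rl)
    ln <- S4Vectors::runLength(rl)
    e <- cumsum(ln)
    s <- e - ln
    keep <- v > 0
    if (any(keep))
      rows[[cn]] <- data.table::data.table(contig = cn, start = s[keep],
                                           end = e[keep], value = v[keep])
  }
  out <- data.table::rbindlist(rows)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
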