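# Fragment building: aligned, tagged read pairs -> sorted, deduplicated,
# Tn5-corrected per-cell fragment sets, plus cell calling and cross-modality
# barcode pairing. One barcode is treated as one cell throughout.

#' Build a Tn5-corrected fragment set from aligned read pairs
#'
#' Tn5 tagmentation duplicates 9 bp at each insertion; the standard
#' correction shifts the plus-strand start by +4 and the minus-strand end by
#' -5 so fragment ends mark insertion centres. Identical
#' (contig, start, end, barcode) records are collapsed into one fragment with
#' an incremented \code{duplicate_count}.
#'
#' @param aligned data.frame/data.table of properly paired records with
#'   columns \code{contig}, \code{start} (plus-strand outer start, 0-based),
#'   \code{end} (minus-strand outer end, exclusive), \code{barcode};
#'   optional \code{mapq}.
#' @param modality \code{"histone"} or \code{"accessibility"}.
#' @param contigs named integer vector of contig lengths.
#' @param shift_plus,shift_minus Tn5 end corrections (defaults +4 / -5).
#' @param min_mapq records with \code{mapq} below this are discarded (only
#'   applied when a \code{mapq} column is present).
#' @return A \code{FragmentSet}: list with \code{modality}, \code{fragments}
#'   (data.table sorted by contig/start/end/barcode with
#'   \code{duplicate_count}), \code{per_barcode} totals, \code{contigs}, and
#'   \code{discards} (itemized counts of dropped records).
#' @export
build_fragments <- function(aligned, modality, contigs,
                            shift_plus = 4L, shift_minus = -5L,
                            min_mapq = 30L) {
  dt <- data.table::as.data.table(aligned)
  req <- c("contig", "start", "end", "barcode")
  if (!all(req %in% names(dt)))
    stop("aligned records need columns: ", paste(req, collapse = ", "))
  discards <- c(low_mapq = 0L, no_barcode = 0L, inverted = 0L, clamped = 0L)

  if ("mapq" %in% names(dt)) {
    low <- dt$mapq < min_mapq
    discards[["low_mapq"]] <- sum(low)
    dt <- dt[!low]
  }
  nobc <- is.na(dt$barcode) | dt$barcode == ""
  discards[["no_barcode"]] <- sum(nobc)
  no_barcode_bin <- dt[nobc]
  dt <- dt[!nobc]

  dt[, `:=`(start = as.integer(start + shift_plus),
            end = as.integer(end + shift_minus))]
  neg <- dt$start < 0L
  discards[["clamped"]] <- sum(neg)
  dt[neg, start := 0L]
  inv <- dt$start >= dt$end
  discards[["inverted"]] <- sum(inv)
  dt <- dt[!inv]
  if (!missing(contigs) && !is.null(contigs)) {
    bad <- !(dt$contig %in% names(contigs))
    if (any(bad)) stop("records on unknown contigs: ",
                       paste(unique(dt$contig[bad]), collapse = ", "))
    dt[, end := pmin(end, as.integer(contigs[contig]))]
  } else {
    contigs <- tapply(dt$end, dt$contig, max)
    contigs <- stats::setNames(as.integer(contigs), names(contigs))
  }

  frags <- dt[, .(duplicate_count = .N), by = .(contig, start, end, barcode)]
  data.table::setorder(frags, contig, start, end, barcode)
  per_barcode <- frags[, .(n_fragments = sum(duplicate_count),
                           n_unique = .N), by = barcode]

  structure(list(modality = modality, fragments = frags,
                 per_barcode = per_barcode, contigs = contigs,
                 discards = discards,
                 no_barcode_records = nrow(no_barcode_bin)),
            class = "FragmentSet")
}

#' Construct a FragmentSet directly from fragment intervals
#'
#' Convenience for simulated data and for reading standard fragment files:
#' intervals are assumed already Tn5-corrected.
#'
#' @param fragments data.frame/data.table with \code{contig}, \code{start},
#'   \code{end}, \code{barcode}, optional \code{duplicate_count}.
#' @param modality modality label.
#' @param contigs named integer vector of contig lengths.
#' @param collapse collapse identical records into duplicate counts
#'   (default TRUE).
#' @return A \code{FragmentSet}.
#' @export
fragment_set <- function(fragments, modality, contigs, collapse = TRUE) {
  dt <- data.table::as.data.table(fragments)
  stopifnot(all(c("contig", "start", "end", "barcode") %in% names(dt)))
  if (collapse || !"duplicate_count" %in% names(dt)) {
    if ("duplicate_count" %in% names(dt)) {
      frags <- dt[, .(duplicate_count = sum(duplicate_count)),
                  by = .(contig, start, end, barcode)]
    } else {
      frags <- dt[, .(duplicate_count = .N), by = .(contig, start, end, barcode)]
    }
  } else {
    frags <- dt[, c("contig", "start", "end", "barcode", "duplicate_count")]
  }
  data.table::setorder(frags, contig, start, end, barcode)
  if (missing(contigs) || is.null(contigs)) {
    contigs <- tapply(frags$end, frags$contig, max)
    contigs <- stats::setNames(as.integer(contigs), names(contigs))
  }
  per_barcode <- frags[, .(n_fragments = sum(duplicate_count),
                           n_unique = .N), by = barcode]
  structure(list(modality = modality, fragments = frags,
                 per_barcode = per_barcode, contigs = contigs,
                 discards = c(low_mapq = 0L, no_barcode = 0L,
                              inverted = 0L, clamped = 0L),
                 no_barcode_records = 0L),
            class = "FragmentSet")
}

#' @export
print.FragmentSet <- function(x, ...) {
  cat(sprintf("FragmentSet (%s): %d unique fragments, %d total, %d barcodes, %d contigs\n",
              x$modality, nrow(x$fragments), sum(x$fragments$duplicate_count),
              nrow(x$per_barcode), length(x$contigs)))
  invisible(x)
}

#' Write / read a fragment file
#'
#' Plain TSV \code{contig start end barcode duplicate_count}, 0-based
#' half-open, sorted -- the standard currency of single-cell chromatin
#' pipelines. A \code{<path>.contigs} sidecar stores the contig table.
#'
#' @param fragset a \code{FragmentSet}.
#' @param path output path.
#' @return (invisibly) the path.
#' @export
write_fragments <- function(fragset, path) {
  data.table::fwrite(fragset$fragments, path, sep = "\t", col.names = FALSE)
  data.table::fwrite(data.table::data.table(contig = names(fragset$contigs),
                                            length = as.integer(fragset$contigs)),
                     paste0(path, ".contigs"), sep = "\t")
  invisible(path)
}

#' @rdname write_fragments
#' @param modality modality label for the loaded set.
#' @export
read_fragments <- function(path, modality) {
  dt <- data.table::fread(path, header = FALSE,
                          col.names = c("contig", "start", "end", "barcode",
                                        "duplicate_count"))
  contigs <- NULL
  sidecar <- paste0(path, ".contigs")
  if (file.exists(sidecar)) {
    ct <- data.table::fread(sidecar)
    contigs <- stats::setNames(as.integer(ct$length), ct$contig)
  }
  fragment_set(dt, modality, contigs, collapse = FALSE)
}

#' Call cell-containing barcodes from per-barcode fragment counts
#'
#' Threshold mode keeps barcodes with at least \code{min_fragments} fragments
#' (the assay's QC uses 500: cells with fewer are excluded, "fewer than" being
#' strict). Knee mode finds the point of maximum distance from the chord of
#' the log-rank/log-count curve and keeps barcodes above it.
#'
#' @param per_barcode data.frame/data.table with \code{barcode} and
#'   \code{n_fragments} (a \code{FragmentSet}'s \code{per_barcode} works).
#' @param min_fragments threshold-mode cutoff (default 500).
#' @param method \code{"threshold"} or \code{"knee"}.
#' @return character vector of cell barcodes.
#' @export
call_cells <- function(per_barcode, min_fragments = 500L,
                       method = c("threshold", "knee")) {
  method <- match.arg(method)
  dt <- data.table::as.data.table(per_barcode)
  if (nrow(dt) == 0L) {
    warning("empty barcode count table")
    return(character(0))
  }
  if (method == "threshold")
    return(dt$barcode[dt$n_fragments >= min_fragments])

  data.table::setorder(dt, -n_fragments)
  x <- log10(seq_len(nrow(dt)))
  y <- log10(pmax(dt$n_fragments, 1L))
  if (nrow(dt) < 3L) return(dt$barcode)
  # maximum perpendicular distance from the chord joining the curve endpoints
  x1 <- x[1]; y1 <- y[1]; x2 <- x[length(x)]; y2 <- y[length(y)]
  dist <- abs((y2 - y1) * x - (x2 - x1) * y + x2 * y1 - y2 * x1) /
    sqrt((y2 - y1)^2 + (x2 - x1)^2)
  knee <- which.max(dist)
  dt$barcode[seq_len(knee)]
}

#' Pair the two modalities by identical cell barcode
#'
#' Profiles from the same droplet share the bead cell barcode, so pairing is
#' an exact string-match join.
#'
#' @param cells_accessibility,cells_histone character vectors of called cell
#'   barcodes per modality.
#' @return list with \code{table} (data.table: barcode, in_accessibility,
#'   in_histone), \code{paired} (intersection), \code{accessibility_only},
#'   \code{histone_only}, and \code{paired_fraction} (of the union).
#' @export
pair_modalities <- function(cells_accessibility, cells_histone) {
  all_bc <- union(cells_accessibility, cells_histone)
  tab <- data.table::data.table(
    barcode = all_bc,
    in_accessibility = all_bc %in% cells_accessibility,
    in_histone = all_bc %in% cells_histone)
  paired <- tab$barcode[tab$in_accessibility & tab$in_histone]
  list(table = tab,
       paired = paired,
       accessibility_only = setdiff(cells_accessibility, cells_histone),
       histone_only = setdiff(cells_histone, cells_accessibility),
       paired_fraction = if (length(all_bc)) length(paired) / length(all_bc) else NA_real_)
}

#' Subset a FragmentSet to a set of barcodes
#'
#' @param fragset a \code{FragmentSet}.
#' @param barcodes barcodes to keep.
#' @return a filtered \code{FragmentSet}.
#' @export
subset_cells <- function(fragset, barcodes) {
  fragment_set(fragset$fragments[barcode %in% barcodes], fragset$modality,
               fragset$contigs, collapse = FALSE)
}
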