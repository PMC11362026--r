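#' @import data.table
#' @importFrom methods as
#' @importFrom stats ppois p.adjust quantile rbinom rnbinom rnorm runif
#'   setNames kmeans dist cor wilcox.test acf median filter
#' @importFrom utils write.table
NULL

# ---- BarcodeScheme -----------------------------------------------------------

#' Construct a barcode scheme
#'
#' A \code{BarcodeScheme} is the single source of truth for how raw reads of a
#' dual-modality tagmentation assay encode (i) which transposase created a
#' fragment -- the antibody-tethered pG-Tn5 (histone-modification modality) or
#' the free Tn5 (chromatin-accessibility modality) -- via a short modality tag
#' embedded in the adapter, and (ii) the droplet cell barcode carried on a
#' separate barcode read.
#'
#' @param tags data.frame with columns \code{tag_id}, \code{seq},
#'   \code{modality} (values \code{"histone"} or \code{"accessibility"}).
#'   All sequences must share one length and be pairwise distinguishable:
#'   minimum Hamming distance \eqn{\ge 2 \cdot}\code{max_mismatch_tag}\eqn{+ 1},
#'   which guarantees unambiguous single-pass error correction.
#' @param tag_reads character vector, which reads carry the modality tag
#'   (subset of \code{"read1"}, \code{"read2"}). When both are listed the two
#'   ends must agree on modality, otherwise the read is left unassigned.
#' @param tag_offset 0-based offset of the tag window within each tag read.
#' @param cell_segments data.frame with columns \code{offset}, \code{length}
#'   (0-based, within the barcode read); their concatenation is the cell
#'   barcode.
#' @param barcode_read_length expected length of the barcode read in bases.
#' @param whitelist optional character vector of valid cell barcodes.
#' @param library_tag optional list \code{list(seq=, modality=)}: when set, the
#'   whole run is forced to that modality (separately amplified libraries) and
#'   per-read tags serve only as a QC cross-check.
#' @param max_mismatch_tag,max_mismatch_cell maximum substitutions tolerated
#'   when matching the modality tag and the cell barcode.
#' @return An object of class \code{BarcodeScheme}.
#' @export
barcode_scheme <- function(tags,
                           tag_reads = c("read1", "read2"),
                           tag_offset = 0L,
                           cell_segments = data.frame(offset = c(0L, 20L),
                                                      length = c(10L, 10L)),
                           barcode_read_length = 48L,
                           whitelist = NULL,
                           library_tag = NULL,
                           max_mismatch_tag = 1L,
                           max_mismatch_cell = 1L) {
  stopifnot(is.data.frame(tags), all(c("tag_id", "seq", "modality") %in% names(tags)))
  tags <- data.frame(tag_id = as.character(tags$tag_id),
                     seq = toupper(as.character(tags$seq)),
                     modality = as.character(tags$modality),
                     stringsAsFactors = FALSE)
  if (anyDuplicated(tags$tag_id))
    stop("duplicate tag_id: ", paste(unique(tags$tag_id[duplicated(tags$tag_id)]), collapse = ", "))
  dup <- duplicated(tags$seq)
  if (any(dup)) {
    i <- which(tags$seq == tags$seq[which(dup)[1]])
    stop("duplicate tag sequence shared by ", paste(tags$tag_id[i], collapse = " and "))
  }
  if (!all(tags$modality %in% c("histone", "accessibility")))
    stop("tag modalities must be 'histone' or 'accessibility'")
  if (length(unique(tags$modality)) != 2L)
    stop("tags must cover both modalities (histone and accessibility)")
  lens <- nchar(tags$seq)
  if (length(unique(lens)) != 1L)
    stop("all tag sequences must have identical length")
  tag_length <- lens[1]
  if (!all(strsplit(paste(tags$seq, collapse = ""), "")[[1]] %in% c("A", "C", "G", "T")))
    stop("tag sequences must be over {A,C,G,T}")

  max_mismatch_tag <- as.integer(max_mismatch_tag)
  max_mismatch_cell <- as.integer(max_mismatch_cell)
  need <- 2L * max_mismatch_tag + 1L
  dmin <- .min_pairwise_hamming(tags$seq)
  if (nrow(tags) > 1L && dmin$d < need)
    stop(sprintf("minimum pairwise tag distance %d between %s and %s is below required %d (= 2*max_mismatch_tag + 1)",
                 dmin$d, dmin$a, dmin$b, need))

  tag_reads <- match.arg(tag_reads, c("read1", "read2"), several.ok = TRUE)
  cell_segments <- data.frame(offset = as.integer(cell_segments$offset),
                              length = as.integer(cell_segments$length))
  if (any(cell_segments$length <= 0L) || any(cell_segments$offset < 0L))
    stop("invalid cell segment layout")
  if (max(cell_segments$offset + cell_segments$length) > barcode_read_length)
    stop("cell segments exceed the barcode-read length")
  cb_len <- sum(cell_segments$length)
  if (!is.null(whitelist)) {
    whitelist <- toupper(as.character(whitelist))
    if (any(nchar(whitelist) != cb_len))
      stop("whitelist entries must have length ", cb_len)
  }
  if (!is.null(library_tag)) {
    stopifnot(is.list(library_tag), !is.null(library_tag$modality))
    if (!library_tag$modality %in% c("histone", "accessibility"))
      stop("library_tag modality must be 'histone' or 'accessibility'")
  }

  structure(list(tags = tags,
                 tag_length = tag_length,
                 tag_reads = tag_reads,
                 tag_offset = as.integer(tag_offset),
                 cell_segments = cell_segments,
                 barcode_read_length = as.integer(barcode_read_length),
                 cell_barcode_length = cb_len,
                 whitelist = whitelist,
                 library_tag = library_tag,
                 max_mismatch_tag = max_mismatch_tag,
                 max_mismatch_cell = max_mismatch_cell),
            class = "BarcodeScheme")
}

#' @export
print.BarcodeScheme <- function(x, ...) {
  cat(sprintf("BarcodeScheme: %d tags of length %d (%d histone / %d accessibility)\n",
              nrow(x$tags), x$tag_length,
              sum(x$tags$modality == "histone"),
              sum(x$tags$modality == "accessibility")))
  cat(sprintf("  tag window: offset %d on %s; cell barcode: %d bp from %d segment(s) of a %d-bp barcode read\n",
              x$tag_offset, paste(x$tag_reads, collapse = "+"),
              x$cell_barcode_length, nrow(x$cell_segments), x$barcode_read_length))
  cat(sprintf("  tolerances: tag <= %d mismatch, cell <= %d mismatch; whitelist: %s; library tag: %s\n",
              x$max_mismatch_tag, x$max_mismatch_cell,
              if (is.null(x$whitelist)) "none" else length(x$whitelist),
              if (is.null(x$library_tag)) "none" else x$library_tag$modality))
  invisible(x)
}

# minimum pairwise Hamming distance among equal-length strings
.min_pairwise_hamming <- function(seqs) {
  n <- length(seqs)
  if (n < 2L) return(list(d = Inf, a = NA, b = NA))
  m <- do.call(rbind, strsplit(seqs, ""))
  best <- list(d = Inf, a = NA, b = NA)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      d <- sum(m[i, ] != m[j, ])
      if (d < best$d) best <- list(d = d, a = seqs[i], b = seqs[j])
    }
  }
  best
}

#' Load a barcode scheme from a YAML config document
#'
#' The config carries a tag table plus layout and tolerance keys; see
#' \code{\link{barcode_scheme}} for field semantics. Minimal document:
#' \preformatted{
#' tag_length: 8
#' max_mismatch_tag: 1
#' tag_reads: [read1, read2]
#' tags:
#'   - {tag_id: B1, seq: ACGTACGT, modality: histone}
#'   - {tag_id: B9, seq: TGCATGCA, modality: accessibility}
#' cell_segments:
#'   - {offset: 0, length: 10}
#'   - {offset: 20, length: 10}
#' }
#'
#' @param path path to a YAML file (or a YAML string).
#' @return A validated \code{BarcodeScheme}.
#' @export
load_scheme <- function(path) {
  doc <- if (file.exists(path)) yaml::read_yaml(path) else yaml::yaml.load(path)
  if (is.null(doc$tags)) stop("scheme config must supply a 'tags' table")
  tags <- do.call(rbind, lapply(doc$tags, function(t)
    data.frame(tag_id = t$tag_id, seq = t$seq, modality = t$modality,
               stringsAsFactors = FALSE)))
  segs <- if (is.null(doc$cell_segments)) {
    data.frame(offset = c(0L, 20L), length = c(10L, 10L))
  } else {
    do.call(rbind, lapply(doc$cell_segments, function(s)
      data.frame(offset = s$offset, length = s$length)))
  }
  lt <- doc$library_tag
  bs <- barcode_scheme(
    tags = tags,
    tag_reads = if (is.null(doc$tag_reads)) c("read1", "read2") else unlist(doc$tag_reads),
    tag_offset = if (is.null(doc$tag_offset)) 0L else doc$tag_offset,
    cell_segments = segs,
    barcode_read_length = if (is.null(doc$barcode_read_length)) 48L else doc$barcode_read_length,
    whitelist = if (is.null(doc$whitelist)) NULL else unlist(doc$whitelist),
    library_tag = lt,
    max_mismatch_tag = if (is.null(doc$max_mismatch_tag)) 1L else doc$max_mismatch_tag,
    max_mismatch_cell = if (is.null(doc$max_mismatch_cell)) 1L else doc$max_mismatch_cell)
  if (!is.null(doc$tag_length) && doc$tag_length != bs$tag_length)
    stop("declared tag_length disagrees with tag table")
  bs
}

#' Default 16-tag scheme
#'
#' The assay loads eight adapter tags (B1--B8) on the antibody-tethered pG-Tn5
#' and eight (B9--B16) on the free Tn5, so the tag partition encodes modality.
#' Published adapter sequences are not available, so this scheme ships a
#' deterministic self-generated set: 16 length-8 tags chosen greedily from a
#' seeded pseudo-random stream so that every pair differs at >= 3 positions
#' (hence 1-mismatch correction is always unambiguous).
#'
#' @param max_mismatch_tag,max_mismatch_cell tolerances, see
#'   \code{\link{barcode_scheme}}.
#' @param whitelist optional cell-barcode whitelist.
#' @return A \code{BarcodeScheme} with tags B1--B8 (histone) and B9--B16
#'   (accessibility).
#' @export
default_scheme <- function(max_mismatch_tag = 1L, max_mismatch_cell = 1L,
                           whitelist = NULL) {
  seqs <- .default_tag_seqs()
  tags <- data.frame(tag_id = paste0("B", 1:16),
                     seq = seqs,
                     modality = rep(c("histone", "accessibility"), each = 8L),
                     stringsAsFactors = FALSE)
  barcode_scheme(tags, max_mismatch_tag = max_mismatch_tag,
                 max_mismatch_cell = max_mismatch_cell, whitelist = whitelist)
}

# deterministic greedy code construction: fixed internal RNG stream, does not
# touch the caller's .Random.seed
.default_tag_seqs <- function(n = 16L, len = 8L, min_dist = 3L) {
  state <- 20240829L
  nextu <- function() {
    # Park-Miller minimal standard LCG
    state <<- as.integer((as.double(state) * 48271) %% 2147483647)
    state / 2147483647
  }
  bases <- c("A", "C", "G", "T")
  chosen <- character(0)
  chosen_m <- matrix(character(0), ncol = len)
  while (length(chosen) < n) {
    cand <- bases[floor(vapply(seq_len(len), function(i) nextu(), 0) * 4) + 1L]
    if (length(chosen) == 0L ||
        all(rowSums(sweep(chosen_m, 2, cand, "!=")) >= min_dist)) {
      chosen <- c(chosen, paste(cand, collapse = ""))
      chosen_m <- rbind(chosen_m, cand)
    }
  }
  chosen
}

# ---- Sequence matching -------------------------------------------------------

#' Match an observed sequence against a candidate set
#'
#' Finds the unique candidate at minimal Hamming distance
#' \eqn{\le}\code{max_mismatch}. \code{N} (or any non-ACGT symbol) in the
#' observed sequence counts as a mismatch to every base. If two candidates tie
#' at the minimal admissible distance the match is rejected as ambiguous.
#'
#' @param observed a single nucleotide string.
#' @param candidates character vector of candidate strings, all the same
#'   length as \code{observed}.
#' @param max_mismatch maximum tolerated Hamming distance.
#' @return list with \code{match} (the winning candidate or \code{NA}),
#'   \code{mismatches} (distance to the best candidate), and \code{ambiguous}
#'   (\code{TRUE} when two candidates tie at the minimal distance).
#' @export
match_sequence <- function(observed, candidates, max_mismatch = 1L) {
  if (length(candidates) == 0L) stop("empty candidate set")
  if (length(observed) != 1L) stop("observed must be a single string")
  if (any(nchar(candidates) != nchar(observed)))
    stop("candidates must have the same length as the observed sequence")
  r <- .match_many(observed, candidates, max_mismatch)
  list(match = if (is.na(r$idx)) NA_character_ else candidates[r$idx],
       mismatches = r$mism,
       ambiguous = r$ambiguous)
}

# Vectorized Hamming matcher: `observed` is a character vector of strings all
# of length nchar(candidates[1]). Returns data.frame(idx, mism, ambiguous);
# idx NA when no candidate within max_mismatch or on a tie.
.match_many <- function(observed, candidates, max_mismatch) {
  n <- length(observed)
  L <- nchar(candidates[1])
  obs_m <- matrix(unlist(strsplit(observed, ""), use.names = FALSE),
                  nrow = n, ncol = L, byrow = TRUE)
  D <- matrix(0L, nrow = n, ncol = length(candidates))
  for (j in seq_along(candidates)) {
    cj <- strsplit(candidates[j], "")[[1]]
    D[, j] <- rowSums(obs_m != matrix(cj, nrow = n, ncol = L, byrow = TRUE))
  }
  best <- apply(D, 1L, min)
  nbest <- rowSums(D == best)
  ok <- best <= max_mismatch
  ambiguous <- ok & nbest > 1L
  idx <- ifelse(ok & !ambiguous, max.col(-D, ties.method = "first"), NA_integer_)
  data.frame(idx = idx, mism = as.integer(best), ambiguous = ambiguous)
}

# ---- Read assignment ---------------------------------------------------------

#' Build a read trio record
#'
#' @param read_id read identifier (shared by the three reads).
#' @param read1,read2,barcode_read nucleotide strings.
#' @return list of class \code{ReadTrio}.
#' @export
read_trio <- function(read_id, read1, read2, barcode_read) {
  if (!nzchar(read_id)) stop("read_id must be nonempty")
  structure(list(read_id = read_id, read1 = toupper(read1),
                 read2 = toupper(read2), barcode_read = toupper(barcode_read)),
            class = "ReadTrio")
}

#' Assign modality and cell identity to one read trio
#'
#' Extracts the tag window from each configured read, matches it against the
#' modality tags, extracts and (when a whitelist is present) corrects the cell
#' barcode, and trims the tag bases off the genomic reads. A read that fails
#' either match is returned with \code{modality = "unassigned"} -- it is never
#' dropped. When the scheme carries a \code{library_tag}, modality is forced
#' to the library's and the per-read tags are only recorded as a cross-check.
#'
#' @param trio a \code{ReadTrio} (see \code{\link{read_trio}}).
#' @param scheme a \code{BarcodeScheme}.
#' @return list of class \code{TaggedRead} with fields \code{read_id},
#'   \code{modality}, \code{tag_id}, \code{corrected_cell_barcode},
#'   \code{tag_mismatches}, \code{cell_mismatches}, \code{reason},
#'   \code{read1}, \code{read2} (trimmed genomic portions).
#' @export
assign_read <- function(trio, scheme) {
  if (!inherits(trio, "ReadTrio")) stop("trio must be a ReadTrio")
  df <- .assign_many(data.frame(read_id = trio$read_id, read1 = trio$read1,
                                read2 = trio$read2, barcode_read = trio$barcode_read,
                                stringsAsFactors = FALSE), scheme)
  out <- as.list(df[1L, ])
  out$tag_id <- if (is.na(out$tag_id)) NULL else out$tag_id
  out$corrected_cell_barcode <- if (is.na(out$cell_barcode)) NULL else out$cell_barcode
  out$cell_barcode <- NULL
  structure(out, class = "TaggedRead")
}

# Vectorized core shared by assign_read() and demultiplex_run().
# reads: data.frame(read_id, read1, read2, barcode_read).
# Returns data.frame(read_id, modality, tag_id, cell_barcode, tag_mismatches,
# cell_mismatches, reason, read1, read2) where reason is "" for assigned reads
# or one of tag_unmatched / tag_ambiguous / tag_conflict / cell_unmatched.
.assign_many <- function(reads, scheme) {
  n <- nrow(reads)
  L <- scheme$tag_length
  off <- scheme$tag_offset

  bl <- nchar(reads$barcode_read)
  if (any(bl < max(scheme$cell_segments$offset + scheme$cell_segments$length)))
    stop("barcode read shorter than the scheme's cell-segment layout")

  tag_id <- rep(NA_character_, n)
  modality <- rep("unassigned", n)
  tag_mm <- rep(NA_integer_, n)
  reason <- rep("", n)

  per_read <- lapply(scheme$tag_reads, function(rd) {
    win <- substr(reads[[rd]], off + 1L, off + L)
    if (any(nchar(win) < L)) stop("read too short for the tag window (", rd, ")")
    .match_many(win, scheme$tags$seq, scheme$max_mismatch_tag)
  })

  if (length(per_read) == 1L) {
    m <- per_read[[1]]
    hit <- !is.na(m$idx)
    tag_id[hit] <- scheme$tags$tag_id[m$idx[hit]]
    tag_mm[hit] <- m$mism[hit]
    reason[!hit] <- ifelse(m$ambiguous[!hit], "tag_ambiguous", "tag_unmatched")
  } else {
    m1 <- per_read[[1]]; m2 <- per_read[[2]]
    hit1 <- !is.na(m1$idx); hit2 <- !is.na(m2$idx)
    mod1 <- ifelse(hit1, scheme$tags$modality[m1$idx], NA)
    mod2 <- ifelse(hit2, scheme$tags$modality[m2$idx], NA)
    agree <- hit1 & hit2 & mod1 == mod2
    tag_id[agree] <- scheme$tags$tag_id[m1$idx[agree]]
    tag_mm[agree] <- m1$mism[agree] + m2$mism[agree]
    conflict <- hit1 & hit2 & mod1 != mod2
    reason[conflict] <- "tag_conflict"
    nohit <- !agree & !conflict
    reason[nohit] <- ifelse(m1$ambiguous[nohit] | m2$ambiguous[nohit],
                            "tag_ambiguous", "tag_unmatched")
  }
  hit <- !is.na(tag_id)
  modality[hit] <- scheme$tags$modality[match(tag_id[hit], scheme$tags$tag_id)]

  # library-level mode: C1/C2-style separately amplified libraries fix the
  # modality for the whole file; per-read tags are kept as a cross-check only
  if (!is.null(scheme$library_tag)) {
    modality <- rep(scheme$library_tag$modality, n)
    reason <- rep("", n)
  }

  # cell barcode: concatenate segments, correct against whitelist if present
  cb <- .extract_cell_barcode(reads$barcode_read, scheme)
  cell_mm <- rep(0L, n)
  if (!is.null(scheme$whitelist)) {
    exact <- match(cb, scheme$whitelist)
    todo <- which(is.na(exact) & modality != "unassigned")
    if (length(todo)) {
      m <- .match_many(cb[todo], scheme$whitelist, scheme$max_mismatch_cell)
      ok <- !is.na(m$idx)
      cb[todo[ok]] <- scheme$whitelist[m$idx[ok]]
      cell_mm[todo[ok]] <- m$mism[ok]
      bad <- todo[!ok]
      modality[bad] <- "unassigned"
      tag_id[bad] <- NA_character_
      reason[bad] <- "cell_unmatched"
      cb[bad] <- NA_character_
    }
  }
  cb[modality == "unassigned"] <- NA_character_
  tag_mm[modality == "unassigned"] <- NA_integer_

  # trim tag bases off the genomic reads
  r1 <- reads$read1; r2 <- reads$read2
  if ("read1" %in% scheme$tag_reads)
    r1 <- paste0(substr(r1, 1L, off), substr(r1, off + L + 1L, nchar(r1)))
  if ("read2" %in% scheme$tag_reads)
    r2 <- paste0(substr(r2, 1L, off), substr(r2, off + L + 1L, nchar(r2)))

  data.frame(read_id = reads$read_id, modality = modality, tag_id = tag_id,
             cell_barcode = cb, tag_mismatches = tag_mm,
             cell_mismatches = cell_mm, reason = reason,
             read1 = r1, read2 = r2, stringsAsFactors = FALSE)
}

.extract_cell_barcode <- function(barcode_read, scheme) {
  segs <- scheme$cell_segments
  parts <- lapply(seq_len(nrow(segs)), function(i)
    substr(barcode_read, segs$offset[i] + 1L, segs$offset[i] + segs$length[i]))
  do.call(paste0, parts)
}
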