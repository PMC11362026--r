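# Streaming demultiplexer: routes every read of a FASTQ trio to histone,
# accessibility or unassigned, based on the adapter modality tags and the
# droplet cell barcode.

#' Demultiplex a FASTQ trio by modality tag and cell barcode
#'
#' Reads are paired across the three files by record order (read identifiers
#' are cross-checked); each trio is assigned through
#' \code{\link{assign_read}}'s vectorized core. Assigned reads are written as
#' trimmed FASTQ pairs per modality with a structured read-name suffix
#' \code{|CB:<barcode>|TAG:<tag_id>}; reads failing either match are written
#' to an \code{unassigned} pair, never dropped.
#'
#' @param r1,r2,bc paths to read1, read2 and barcode-read FASTQ files
#'   (gzip allowed).
#' @param scheme a \code{BarcodeScheme}.
#' @param out_prefix output path prefix; set \code{NULL} to skip writing.
#' @param chunk_size records per streaming chunk.
#' @return A \code{DemuxReport}: list with \code{total}, \code{assigned}
#'   (named by modality), \code{unassigned} (named by cause:
#'   \code{tag_unmatched}, \code{tag_ambiguous}, \code{tag_conflict},
#'   \code{cell_unmatched}), \code{per_tag} and \code{per_cell} count tables,
#'   and \code{files}. Also carries the full per-read assignment table as
#'   \code{reads} (data.table).
#' @export
demultiplex_run <- function(r1, r2, bc, scheme, out_prefix = NULL,
                            chunk_size = 100000L) {
  f1 <- .read_fastq(r1)
  f2 <- .read_fastq(r2)
  fb <- .read_fastq(bc)
  ns <- c(nrow(f1), nrow(f2), nrow(fb))
  if (length(unique(ns)) != 1L) {
    short <- c(r1, r2, bc)[which.min(ns)]
    stop(sprintf("record counts differ across the trio (%d/%d/%d); shortest file: %s",
                 ns[1], ns[2], ns[3], short))
  }
  if (!all(f1$id == f2$id) || !all(f1$id == fb$id))
    stop("read identifiers disagree across the trio")

  n <- nrow(f1)
  if (n == 0L) {
    warning("zero reads in input")
    reads <- data.table::data.table(read_id = character(), modality = character(),
                                    tag_id = character(), cell_barcode = character(),
                                    tag_mismatches = integer(), cell_mismatches = integer(),
                                    reason = character(), read1 = character(),
                                    read2 = character())
  } else {
    chunks <- split(seq_len(n), (seq_len(n) - 1L) %/% chunk_size)
    reads <- data.table::rbindlist(lapply(chunks, function(i) {
      .assign_many(data.frame(read_id = f1$id[i], read1 = f1$seq[i],
                              read2 = f2$seq[i], barcode_read = fb$seq[i],
                              stringsAsFactors = FALSE), scheme)
    }))
    data.table::setDT(reads)
  }

  report <- .demux_report(reads)
  report$files <- NULL
  if (!is.null(out_prefix) && n > 0L) {
    report$files <- .write_demux_outputs(reads, out_prefix)
  }
  report$reads <- reads
  report
}

.demux_report <- function(reads) {
  causes <- c("tag_unmatched", "tag_ambiguous", "tag_conflict", "cell_unmatched")
  assigned <- c(histone = sum(reads$modality == "histone"),
                accessibility = sum(reads$modality == "accessibility"))
  unassigned <- vapply(causes, function(cs) sum(reads$reason == cs), 0L)
  per_tag <- if (nrow(reads)) table(reads$tag_id[!is.na(reads$tag_id)]) else table(character())
  per_cell <- if (nrow(reads)) table(reads$cell_barcode[!is.na(reads$cell_barcode)]) else table(character())
  structure(list(total = nrow(reads), assigned = assigned,
                 unassigned = unassigned,
                 per_tag = per_tag, per_cell = per_cell),
            class = "DemuxReport")
}

.write_demux_outputs <- function(reads, out_prefix) {
  suffix <- ifelse(reads$modality == "unassigned", "",
                   paste0("|CB:", reads$cell_barcode, "|TAG:", reads$tag_id))
  ids <- paste0(reads$read_id, suffix)
  files <- list()
  for (md in c("histone", "accessibility", "unassigned")) {
    i <- which(reads$modality == md)
    p1 <- paste0(out_prefix, "_", md, "_R1.fastq")
    p2 <- paste0(out_prefix, "_", md, "_R2.fastq")
    .write_fastq(ids[i], reads$read1[i], p1)
    .write_fastq(ids[i], reads$read2[i], p2)
    files[[md]] <- c(p1, p2)
  }
  tsv <- paste0(out_prefix, "_assignments.tsv")
  data.table::fwrite(reads[, c("read_id", "modality", "tag_id", "cell_barcode",
                               "tag_mismatches", "cell_mismatches", "reason")],
                     tsv, sep = "\t")
  files$assignments <- tsv
  files
}

#' Render a demultiplexing report as a summary table
#'
#' @param report a \code{DemuxReport}.
#' @param path optional TSV output path.
#' @return data.frame with one row per category and columns \code{category},
#'   \code{count}, \code{percent} (2 decimals, of total). A zero-read run
#'   renders all shares as 0 with a warning row.
#' @export
summarize_demux <- function(report, path = NULL) {
  stopifnot(inherits(report, "DemuxReport"))
  total <- report$total
  pct <- function(x) if (total == 0) 0 else round(100 * x / total, 2)
  rows <- data.frame(
    category = c("total", paste0("assigned_", names(report$assigned)),
                 paste0("unassigned_", names(report$unassigned))),
    count = c(total, unname(report$assigned), unname(report$unassigned)),
    stringsAsFactors = FALSE)
  rows$percent <- sprintf("%.2f", vapply(rows$count, pct, 0))
  if (length(report$per_tag)) {
    tag_rows <- data.frame(category = paste0("tag_", names(report$per_tag)),
                           count = as.integer(report$per_tag),
                           stringsAsFactors = FALSE)
    tag_rows$percent <- sprintf("%.2f", vapply(tag_rows$count, pct, 0))
    rows <- rbind(rows, tag_rows)
  }
  if (total == 0)
    rows <- rbind(rows, data.frame(category = "warning_zero_reads", count = 0L,
                                   percent = "0.00"))
  if (!is.null(path)) utils::write.table(rows, path, sep = "\t",
                                         quote = FALSE, row.names = FALSE)
  rows
}

#' @export
print.DemuxReport <- function(x, ...) {
  cat(sprintf("DemuxReport: %d reads; histone %d, accessibility %d, unassigned %d\n",
              x$total, x$assigned[["histone"]], x$assigned[["accessibility"]],
              sum(x$unassigned)))
  invisible(x)
}

# FASTQ reader (plain or gzip) via Biostrings; returns data.frame(id, seq)
.read_fastq <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- tryCatch(Biostrings::readDNAStringSet(path, format = "fastq"),
                 error = function(e)
                   stop(sprintf("malformed FASTQ %s: %s", path, conditionMessage(e)),
                        call. = FALSE))
  data.frame(id = sub("\\s.*$", "", names(ss)),
             seq = toupper(as.character(ss)),
             stringsAsFactors = FALSE)
}
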