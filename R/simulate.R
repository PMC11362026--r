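# Synthetic dual-modality data generator.
#
# The generator plants a fully known ground truth -- cells with types, genes
# with per-type regulatory states, per-modality peak structure -- and then
# draws fragments, duplicates and ambient background from it, so that every
# downstream stage (demux, fragment building, QC, peak calling, integration,
# clustering) can be tested by round-trip against the planted truth.

#' Simulation configuration
#'
#' Defaults emulate the assay's published per-cell depths (on average 1724
#' histone-modification and 3129 chromatin-accessibility fragments per cell
#' after QC) and a nucleosomal fragment-size ladder with sub-nucleosomal,
#' mono-, di- and tri-nucleosome components. Regulatory states are planted
#' per gene per cell type:
#' \describe{
#'   \item{active_accessible}{open promoter, no repressive domain}
#'   \item{accessible_silenced}{open promoter underneath a broad repressive
#'     (H3K27me3-like) domain -- the joint-modality state of interest}
#'   \item{repressed_closed}{repressive domain, closed promoter}
#'   \item{inactive}{neither signal}
#' }
#'
#' @param n_cells named integer vector, cells per cell type.
#' @param contigs named integer vector of contig lengths (bp).
#' @param fragments_per_cell named list per modality with \code{mean} and
#'   \code{dispersion} (negative-binomial size) of the per-cell fragment count.
#' @param size_means,size_sds,size_weights fragment-size mixture (truncated
#'   normals); weights must sum to 1.
#' @param in_peak_fraction named numeric, fraction of a cell's fragments
#'   placed inside that modality's true peak set.
#' @param duplicate_rate probability that a fragment is a PCR copy of an
#'   earlier fragment of the same cell and modality.
#' @param ambient_fraction fraction of all emitted fragments that are ambient
#'   background (uniform on the genome, barcode sampled from all cells).
#' @param n_genes number of genes; \code{gene_body_length} their body span.
#' @param state_fractions named numeric over the four regulatory states,
#'   summing to 1; non-inactive states are allocated by \code{ceiling}
#'   so planted counts are exact.
#' @param n_distal_access,n_distal_histone distal (gene-free) peaks/domains
#'   per modality.
#' @param distal_type_specific_fraction fraction of distal regulatory slots
#'   owned by a single cell type (assigned round-robin); the rest are shared
#'   by all types. Distal elements (enhancer-like) are the most
#'   cell-type-specific part of real chromatin landscapes, and this is what
#'   makes simulated cell types separable at realistic depth.
#' @param overlap_fraction fraction of distal regulatory slots carrying both
#'   marks (an accessibility peak inside a repressive domain). Setting it to 0
#'   together with a nonzero \code{accessible_silenced} fraction is rejected:
#'   that state is co-marked at the promoter by definition.
#' @param access_peak_width,histone_domain_width widths (bp) of promoter/distal
#'   accessibility peaks and of broad repressive domains.
#' @param read1_length,read2_length genomic read lengths for FASTQ emission.
#' @param error_rate uniform per-base substitution rate applied on write.
#' @param seed integer seed; all draws are deterministic given it.
#' @return list of class \code{SimConfig}.
#' @export
sim_config <- function(n_cells = c(typeA = 300L, typeB = 300L),
                       contigs = c(chr1 = 2000000L, chr2 = 2000000L),
                       fragments_per_cell = list(
                         histone = list(mean = 1724, dispersion = 2),
                         accessibility = list(mean = 3129, dispersion = 2)),
                       size_means = c(80, 200, 400, 600),
                       size_sds = c(15, 25, 35, 45),
                       size_weights = c(0.15, 0.50, 0.20, 0.15),
                       in_peak_fraction = c(histone = 0.53, accessibility = 0.60),
                       duplicate_rate = 0.3,
                       ambient_fraction = 0.05,
                       n_genes = 200L,
                       gene_body_length = 2000L,
                       state_fractions = c(active_accessible = 0.10,
                                           accessible_silenced = 0.15,
                                           repressed_closed = 0.10,
                                           inactive = 0.65),
                       n_distal_access = 100L,
                       n_distal_histone = 50L,
                       distal_type_specific_fraction = 0.5,
                       overlap_fraction = 0.027,
                       access_peak_width = 500L,
                       histone_domain_width = 5000L,
                       read1_length = 50L,
                       read2_length = 50L,
                       error_rate = 0,
                       seed = 1L) {
  stopifnot(all(n_cells >= 0), all(contigs > 0), !is.null(names(contigs)),
            !anyDuplicated(names(contigs)))
  stopifnot(length(size_means) == length(size_sds),
            length(size_means) == length(size_weights))
  if (abs(sum(size_weights) - 1) > 1e-8) stop("size_weights must sum to 1")
  stopifnot(all(in_peak_fraction >= 0 & in_peak_fraction <= 1),
            duplicate_rate >= 0, duplicate_rate <= 1,
            ambient_fraction >= 0, ambient_fraction < 1,
            overlap_fraction >= 0, overlap_fraction <= 1,
            distal_type_specific_fraction >= 0,
            distal_type_specific_fraction <= 1)
  states <- c("active_accessible", "accessible_silenced", "repressed_closed", "inactive")
  if (!setequal(names(state_fractions), states))
    stop("state_fractions must name exactly the four regulatory states")
  state_fractions <- state_fractions[states]
  if (any(state_fractions < 0) || abs(sum(state_fractions) - 1) > 1e-8)
    stop("state_fractions must be nonnegative and sum to 1")
  if (overlap_fraction == 0 && state_fractions["accessible_silenced"] > 0)
    stop("overlap_fraction = 0 is incompatible with a nonzero accessible_silenced fraction")
  structure(as.list(environment()), class = "SimConfig")
}

#' Generate the ground-truth skeleton: genome, genes, states, peaks, cells
#'
#' Genes and distal regulatory slots are laid out on a regular grid (one slot
#' per 10 kb so that broad domains never collide). Accessibility peaks sit on
#' promoters of accessible genes; repressive domains are broad and centred on
#' the TSS of repressed genes; distal slots carry one mark each except for a
#' configurable fraction carrying both.
#'
#' @param config a \code{SimConfig}.
#' @return list of class \code{SimTruth} with elements \code{contigs},
#'   \code{genes} (data.table: gene_id, contig, tss, strand, body_start,
#'   body_end), \code{states} (gene_id x cell_type long table),
#'   \code{peaks} (per cell_type per modality intervals),
#'   \code{cells} (barcode, cell_type), and \code{config}.
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  contigs <- config$contigs

  spacing <- 10000L
  margin <- max(config$histone_domain_width, 2L * config$access_peak_width,
                config$gene_body_length) + 1000L
  slot_tbl <- data.table::rbindlist(lapply(names(contigs), function(cn) {
    centers <- seq(margin, contigs[[cn]] - margin, by = spacing)
    data.table::data.table(contig = cn, center = as.integer(centers))
  }))
  n_both <- as.integer(ceiling(config$overlap_fraction *
                               (config$n_distal_access + config$n_distal_histone)))
  n_distal_slots <- config$n_distal_access + config$n_distal_histone - n_both
  n_needed <- config$n_genes + n_distal_slots
  if (n_needed > nrow(slot_tbl))
    stop(sprintf("peak/gene demand (%d slots) exceeds genome capacity (%d slots)",
                 n_needed, nrow(slot_tbl)))
  slots <- slot_tbl[sample(.N)]  # seeded shuffle spreads genes over contigs

  gene_slots <- slots[seq_len(config$n_genes)]
  distal_slots <- slots[config$n_genes + seq_len(n_distal_slots)]

  strand <- rep(c("+", "-"), length.out = config$n_genes)
  tss <- gene_slots$center
  body_start <- ifelse(strand == "+", tss, tss - config$gene_body_length)
  genes <- data.table::data.table(
    gene_id = sprintf("gene%04d", seq_len(config$n_genes)),
    contig = gene_slots$contig,
    tss = as.integer(tss),
    strand = strand,
    body_start = as.integer(body_start),
    body_end = as.integer(body_start + config$gene_body_length))

  # exact per-type state allocation: ceiling for the explicit states,
  # remainder inactive
  sf <- config$state_fractions
  n_active <- as.integer(ceiling(sf[["active_accessible"]] * config$n_genes))
  n_silenced <- as.integer(ceiling(sf[["accessible_silenced"]] * config$n_genes))
  n_closed <- as.integer(ceiling(sf[["repressed_closed"]] * config$n_genes))
  if (n_active + n_silenced + n_closed > config$n_genes)
    stop("state fractions allocate more genes than exist")
  states <- data.table::rbindlist(lapply(names(config$n_cells), function(ct) {
    ord <- sample(config$n_genes)
    st <- rep("inactive", config$n_genes)
    st[ord[seq_len(n_active)]] <- "active_accessible"
    st[ord[n_active + seq_len(n_silenced)]] <- "accessible_silenced"
    st[ord[n_active + n_silenced + seq_len(n_closed)]] <- "repressed_closed"
    data.table::data.table(gene_id = genes$gene_id, cell_type = ct, state = st)
  }))

  half_a <- config$access_peak_width %/% 2L
  half_h <- config$histone_domain_width %/% 2L

  # distal slots: first n_both carry both marks; a configurable fraction of
  # slots is owned by one cell type (enhancer-like specificity), the rest
  # are shared by all types
  distal <- list()
  if (nrow(distal_slots)) {
    n_spec <- round(config$distal_type_specific_fraction * nrow(distal_slots))
    owner <- rep("shared", nrow(distal_slots))
    if (n_spec > 0L)
      owner[seq_len(n_spec)] <- rep(names(config$n_cells), length.out = n_spec)
    idx_both <- seq_len(n_both)
    idx_a <- n_both + seq_len(config$n_distal_access - n_both)
    idx_h <- n_both + (config$n_distal_access - n_both) +
      seq_len(config$n_distal_histone - n_both)
    mk <- function(i, half, modality, kind)
      if (length(i)) data.table::data.table(
        contig = distal_slots$contig[i],
        start = as.integer(distal_slots$center[i] - half),
        end = as.integer(distal_slots$center[i] + half),
        modality = modality, kind = kind, owner = owner[i])
    distal <- data.table::rbindlist(list(
      mk(idx_both, half_a, "accessibility", "distal_both"),
      mk(idx_both, half_h, "histone", "distal_both"),
      mk(idx_a, half_a, "accessibility", "distal"),
      mk(idx_h, half_h, "histone", "distal")))
  }

  peaks <- data.table::rbindlist(lapply(names(config$n_cells), function(ct) {
    st <- states[cell_type == ct]
    g <- genes[match(st$gene_id, gene_id)]
    acc <- g[st$state %in% c("active_accessible", "accessible_silenced")]
    rep_ <- g[st$state %in% c("accessible_silenced", "repressed_closed")]
    out <- list()
    if (nrow(acc)) out$acc <- data.table::data.table(
      contig = acc$contig, start = as.integer(acc$tss - half_a),
      end = as.integer(acc$tss + half_a),
      modality = "accessibility", kind = "promoter", owner = ct)
    if (nrow(rep_)) out$rep <- data.table::data.table(
      contig = rep_$contig, start = as.integer(rep_$tss - half_h),
      end = as.integer(rep_$tss + half_h),
      modality = "histone", kind = "domain", owner = ct)
    own_distal <- if (length(distal)) distal[owner %in% c("shared", ct)]
    pk <- data.table::rbindlist(c(out, if (length(distal)) list(own_distal)))
    pk[, cell_type := ct]
    pk
  }))
  data.table::setkey(peaks, cell_type, modality, contig, start)

  bc <- .random_barcodes(sum(config$n_cells), 20L)
  cells <- data.table::data.table(
    barcode = bc,
    cell_type = rep(names(config$n_cells), times = config$n_cells))

  structure(list(contigs = contigs, genes = genes, states = states,
                 peaks = peaks, cells = cells, config = config),
            class = "SimTruth")
}

.random_barcodes <- function(n, len) {
  repeat {
    bc <- vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
      character(1))
    if (!anyDuplicated(bc)) return(bc)
  }
}

#' Draw per-read fragment assignments from a planted truth
#'
#' Per cell and modality the fragment count is negative-binomial; a configured
#' fraction of fragments lands inside that cell type's true peak set of the
#' matching modality (uniform within peaks, width-weighted), the rest lands
#' uniformly on the genome. Fragment sizes come from the nucleosomal-ladder
#' mixture. Duplicates copy an earlier fragment of the same cell and modality;
#' ambient fragments are placed uniformly and given a barcode sampled from all
#' cells.
#'
#' @param truth a \code{SimTruth}.
#' @param config usually \code{truth$config}; may override depth parameters.
#' @return data.table with one row per read: \code{read_id}, \code{barcode},
#'   \code{cell_type}, \code{modality}, \code{contig}, \code{start},
#'   \code{end} (0-based half-open), \code{is_duplicate}, \code{is_ambient}.
#' @export
generate_fragments <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "SimTruth"))
  set.seed(config$seed + 1L)
  contigs <- truth$contigs
  modalities <- c("histone", "accessibility")

  per_cell <- data.table::rbindlist(lapply(modalities, function(md) {
    fp <- config$fragments_per_cell[[md]]
    n <- stats::rnbinom(nrow(truth$cells), mu = fp$mean, size = fp$dispersion)
    data.table::data.table(barcode = truth$cells$barcode,
                           cell_type = truth$cells$cell_type,
                           modality = md, n = pmax(n, 1L))
  }))

  blocks <- lapply(seq_len(nrow(per_cell)), function(i) {
    row <- per_cell[i]
    .draw_cell_fragments(row$n, row$barcode, row$cell_type, row$modality,
                         truth, config)
  })
  frags <- data.table::rbindlist(blocks)
  frags[, is_ambient := FALSE]

  n_real <- nrow(frags)
  n_amb <- as.integer(round(n_real * config$ambient_fraction /
                              (1 - config$ambient_fraction)))
  if (n_amb > 0L) {
    amb <- .draw_uniform_fragments(n_amb, contigs, config)
    pick <- sample.int(nrow(truth$cells), n_amb, replace = TRUE)
    amb[, `:=`(barcode = truth$cells$barcode[pick],
               cell_type = truth$cells$cell_type[pick],
               modality = sample(modalities, n_amb, replace = TRUE),
               is_duplicate = FALSE, is_ambient = TRUE)]
    frags <- data.table::rbindlist(list(frags, amb), use.names = TRUE)
  }
  frags[, read_id := sprintf("read%08d", seq_len(.N))]
  data.table::setcolorder(frags, c("read_id", "barcode", "cell_type", "modality",
                                   "contig", "start", "end",
                                   "is_duplicate", "is_ambient"))
  frags[]
}

# fragments for one cell x modality, including PCR duplicates
.draw_cell_fragments <- function(n, bc, ct, md, truth, config) {
  pk <- truth$peaks[data.table::CJ(cell_type = ct, modality = md), nomatch = 0L]
  in_peak <- stats::runif(n) < config$in_peak_fraction[[md]]
  if (nrow(pk) == 0L) in_peak[] <- FALSE
  sizes <- .draw_sizes(n, config)
  mid <- integer(n)
  contig <- character(n)
  n_in <- sum(in_peak)
  if (n_in > 0L) {
    w <- pk$end - pk$start
    j <- sample.int(nrow(pk), n_in, replace = TRUE, prob = w)
    mid[in_peak] <- pk$start[j] + as.integer(floor(stats::runif(n_in) * w[j]))
    contig[in_peak] <- pk$contig[j]
  }
  n_bg <- n - n_in
  if (n_bg > 0L) {
    u <- .draw_uniform_positions(n_bg, truth$contigs)
    mid[!in_peak] <- u$pos
    contig[!in_peak] <- u$contig
  }
  dt <- .sized_intervals(contig, mid, sizes, truth$contigs)

  # duplicates: each fragment after the first is a PCR copy with prob rate
  is_dup <- stats::runif(n) < config$duplicate_rate
  is_dup[1L] <- FALSE
  dup_i <- which(is_dup)
  if (length(dup_i)) {
    # a PCR copy replicates an original molecule drawn before it
    pool <- which(!is_dup)
    n_avail <- findInterval(dup_i - 1L, pool)
    src <- pool[ceiling(stats::runif(length(dup_i)) * n_avail)]
    data.table::set(dt, dup_i, "contig", dt$contig[src])
    data.table::set(dt, dup_i, "start", dt$start[src])
    data.table::set(dt, dup_i, "end", dt$end[src])
  }
  dt[, `:=`(barcode = bc, cell_type = ct, modality = md, is_duplicate = is_dup)]
  dt
}

.draw_sizes <- function(n, config) {
  comp <- sample.int(length(config$size_weights), n, replace = TRUE,
                     prob = config$size_weights)
  sz <- stats::rnorm(n, config$size_means[comp], config$size_sds[comp])
  pmax(as.integer(round(sz)), 20L)
}

.draw_uniform_positions <- function(n, contigs) {
  ci <- sample.int(length(contigs), n, replace = TRUE,
                   prob = as.numeric(contigs))
  list(contig = names(contigs)[ci],
       pos = as.integer(floor(stats::runif(n) * contigs[ci])))
}

.sized_intervals <- function(contig, mid, sizes, contigs) {
  start <- mid - sizes %/% 2L
  end <- start + sizes
  len <- contigs[contig]
  start <- pmax(start, 0L)
  end <- pmin(end, as.integer(len))
  start <- pmin(start, end - 1L)
  data.table::data.table(contig = contig, start = as.integer(start),
                         end = as.integer(end))
}

.draw_uniform_fragments <- function(n, contigs, config) {
  u <- .draw_uniform_positions(n, contigs)
  .sized_intervals(u$contig, u$pos, .draw_sizes(n, config), contigs)
}

#' Write a simulated run to disk: FASTQ trio, aligned table and truth files
#'
#' Each fragment becomes one read trio. The modality tag (sampled uniformly
#' among that modality's tags) is embedded at the scheme's tag window of read1
#' and read2; the cell barcode fills the scheme's segments of the barcode
#' read; remaining read bases come from a fixed pseudo-random sequence per
#' contig (alignment is bypassed by the emitted aligned table, so sequence
#' content is cosmetic). An optional uniform substitution-error rate is
#' applied, and \code{tag_errors} forces exactly that many substitutions into
#' every tag occurrence (for error-correction round-trip checks).
#'
#' @param assignments output of \code{\link{generate_fragments}}.
#' @param truth the \code{SimTruth} the assignments came from.
#' @param scheme a \code{BarcodeScheme}; its cell-barcode length must equal
#'   the simulated barcode length.
#' @param out_prefix path prefix for all output files.
#' @param error_rate per-base substitution probability (default from config).
#' @param tag_errors exact substitutions to inject into each tag window.
#' @return (invisibly) named list of written file paths.
#' @export
write_reads <- function(assignments, truth, scheme, out_prefix,
                        error_rate = truth$config$error_rate,
                        tag_errors = 0L) {
  config <- truth$config
  set.seed(config$seed + 2L)
  n <- nrow(assignments)
  if (scheme$cell_barcode_length != nchar(truth$cells$barcode[1]))
    stop("scheme cell-barcode length does not match simulated barcodes")

  tag_pool <- split(scheme$tags$seq, scheme$tags$modality)
  tag_seq <- character(n)
  for (md in names(tag_pool)) {
    i <- which(assignments$modality == md)
    tag_seq[i] <- sample(tag_pool[[md]], length(i), replace = TRUE)
  }

  gen1 <- .contig_filler(assignments, truth, config$read1_length - scheme$tag_length,
                         from_start = TRUE)
  gen2 <- .contig_filler(assignments, truth, config$read2_length - scheme$tag_length,
                         from_start = FALSE)
  read1 <- paste0(tag_seq, gen1)
  read2 <- paste0(tag_seq, gen2)

  bcread <- .fill_barcode_read(assignments$barcode, scheme)

  if (tag_errors > 0L) {
    read1 <- .inject_window_errors(read1, scheme$tag_offset, scheme$tag_length, tag_errors)
    read2 <- .inject_window_errors(read2, scheme$tag_offset, scheme$tag_length, tag_errors)
  }
  if (error_rate > 0) {
    read1 <- .inject_uniform_errors(read1, error_rate)
    read2 <- .inject_uniform_errors(read2, error_rate)
    bcread <- .inject_uniform_errors(bcread, error_rate)
  }

  paths <- list(r1 = paste0(out_prefix, "_R1.fastq"),
                r2 = paste0(out_prefix, "_R2.fastq"),
                bc = paste0(out_prefix, "_BC.fastq"),
                aligned = paste0(out_prefix, "_aligned.tsv"),
                truth_reads = paste0(out_prefix, "_truth_reads.tsv"),
                truth_cells = paste0(out_prefix, "_truth_cells.tsv"),
                truth_genes = paste0(out_prefix, "_truth_genes.tsv"),
                truth_states = paste0(out_prefix, "_truth_states.tsv"),
                truth_peaks = paste0(out_prefix, "_truth_peaks.tsv"),
                config = paste0(out_prefix, "_config.yaml"))

  .write_fastq(assignments$read_id, read1, paths$r1)
  .write_fastq(assignments$read_id, read2, paths$r2)
  .write_fastq(assignments$read_id, bcread, paths$bc)

  aligned <- data.table::data.table(
    read_id = assignments$read_id,
    contig = assignments$contig,
    start = assignments$start - 4L,   # uncorrected plus-strand outer start
    end = assignments$end + 5L,       # uncorrected minus-strand outer end
    strand = "+",
    mapq = 60L)
  data.table::fwrite(aligned, paths$aligned, sep = "\t")
  data.table::fwrite(assignments, paths$truth_reads, sep = "\t")
  data.table::fwrite(truth$cells, paths$truth_cells, sep = "\t")
  data.table::fwrite(truth$genes, paths$truth_genes, sep = "\t")
  data.table::fwrite(truth$states, paths$truth_states, sep = "\t")
  data.table::fwrite(truth$peaks, paths$truth_peaks, sep = "\t")
  cfg <- config
  class(cfg) <- NULL
  yaml::write_yaml(cfg, paths$config)
  invisible(paths)
}

# fixed pseudo-random contig sequences, independent of the simulation seed
# (the caller's RNG state is saved and restored)
.contig_sequence <- function(name, length) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(h %% 1000003L))
  paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
}

.contig_cache <- new.env(parent = emptyenv())

.get_contig_sequence <- function(name, length) {
  key <- paste0(name, ":", length)
  if (is.null(.contig_cache[[key]]))
    .contig_cache[[key]] <- .contig_sequence(name, length)
  .contig_cache[[key]]
}

.contig_filler <- function(assignments, truth, len, from_start = TRUE) {
  out <- character(nrow(assignments))
  for (cn in names(truth$contigs)) {
    i <- which(assignments$contig == cn)
    if (!length(i)) next
    seqc <- .get_contig_sequence(cn, truth$contigs[[cn]])
    pos <- if (from_start) assignments$start[i] + 1L
           else pmax(assignments$end[i] - len, 1L)
    pos <- pmin(pmax(pos, 1L), nchar(seqc) - len + 1L)
    out[i] <- substring(seqc, pos, pos + len - 1L)
  }
  out
}

.fill_barcode_read <- function(barcodes, scheme) {
  template <- paste(rep(c("A", "C", "G", "T"),
                        length.out = scheme$barcode_read_length), collapse = "")
  out <- rep(template, length(barcodes))
  segs <- scheme$cell_segments
  cum <- c(0L, cumsum(segs$length))
  for (i in seq_len(nrow(segs))) {
    part <- substr(barcodes, cum[i] + 1L, cum[i + 1L])
    substr(out, segs$offset[i] + 1L, segs$offset[i] + segs$length[i]) <- part
  }
  out
}

.inject_window_errors <- function(reads, offset, len, k) {
  n <- length(reads)
  for (e in seq_len(k)) {
    pos <- offset + sample.int(len, n, replace = TRUE)
    cur <- substr(reads, pos, pos)
    alt <- c(A = "C", C = "G", G = "T", T = "A", N = "A")[cur]
    substr(reads, pos, pos) <- unname(alt)
  }
  reads
}

.inject_uniform_errors <- function(reads, rate) {
  L <- nchar(reads[1])
  n <- length(reads)
  nerr <- stats::rbinom(n, L, rate)
  idx <- which(nerr > 0L)
  for (i in idx) {
    pos <- sample.int(L, nerr[i])
    for (p in pos) {
      cur <- substr(reads[i], p, p)
      substr(reads[i], p, p) <- c(A = "C", C = "G", G = "T", T = "A", N = "A")[cur]
    }
  }
  reads
}

.write_fastq <- function(ids, seqs, path) {
  if (length(ids) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  qual <- strrep("I", nchar(seqs))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", ids, "\n", seqs, "\n+\n", qual), con, sep = "\n")
}
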