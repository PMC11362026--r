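# Joint two-modality analyses: distance-weighted gene scores, classification
# of accessible-but-silenced regulatory states, base-pair co-occupancy of the
# two signal classes, alternative-TSS preference, percent-spliced-in and
# cross-modality cluster correspondence.

#' Build a gene model
#'
#' @param genes data.frame with \code{gene_id}, \code{contig}, \code{strand},
#'   \code{body_start}, \code{body_end} and either a \code{tss} column (one
#'   TSS) or accompanied by \code{tss_table}.
#' @param tss_table optional data.frame \code{gene_id}, \code{contig},
#'   \code{position}, \code{strand} for genes with multiple TSSs.
#' @return list of class \code{GeneModel} with \code{genes} and \code{tss}
#'   data.tables.
#' @export
gene_model <- function(genes, tss_table = NULL) {
  g <- data.table::as.data.table(genes)
  stopifnot(all(c("gene_id", "contig", "strand", "body_start", "body_end")
                %in% names(g)))
  if (any(g$body_start >= g$body_end)) stop("gene body start must be < end")
  if (is.null(tss_table)) {
    if (!"tss" %in% names(g)) stop("supply a tss column or a tss_table")
    tss <- g[, .(gene_id, contig, position = as.integer(tss), strand)]
  } else {
    tss <- data.table::as.data.table(tss_table)
    stopifnot(all(c("gene_id", "contig", "position", "strand") %in% names(tss)))
    if (!all(tss$gene_id %in% g$gene_id))
      stop("tss_table references unknown genes")
  }
  structure(list(genes = g[, .(gene_id, contig, strand,
                               body_start = as.integer(body_start),
                               body_end = as.integer(body_end))],
                 tss = tss), class = "GeneModel")
}

#' Load a gene model from GTF or BED12
#'
#' GTF: transcripts are grouped by \code{gene_id}; each transcript
#' contributes one TSS and the gene body is the union extent. BED12: each
#' record is one transcript; records sharing \code{name} form one gene.
#'
#' @param path file path (\code{.gtf} or \code{.bed}).
#' @return a \code{GeneModel}.
#' @export
read_gene_model <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("reading GTF/BED12 requires the rtracklayer package")
  gr <- rtracklayer::import(path)
  df <- as.data.frame(gr)
  if ("type" %in% names(df)) {            # GTF
    tx <- df[df$type %in% c("transcript", "mRNA"), , drop = FALSE]
    if (nrow(tx) == 0L) tx <- df[df$type == "gene", , drop = FALSE]
    id <- tx$gene_id
  } else {                                 # BED-like
    tx <- df
    id <- tx$name
  }
  tx$gene <- id
  dt <- data.table::as.data.table(tx)
  genes <- dt[, .(contig = seqnames[1], strand = as.character(strand[1]),
                  body_start = min(start) - 1L, body_end = max(end)),
              by = .(gene_id = gene)]
  tss <- dt[, .(gene_id = gene, contig = as.character(seqnames),
                position = ifelse(as.character(strand) == "-", end, start - 1L),
                strand = as.character(strand))]
  tss <- unique(tss)
  gene_model(genes[, .(gene_id, contig = as.character(contig), strand,
                       body_start, body_end)], tss)
}

#' Distance-weighted gene scores per cell
#'
#' Each fragment contributes weight 1 to a gene when its midpoint lies in the
#' gene body or the promoter-side \code{upstream} window, and weight
#' \eqn{e^{-d/\code{decay}}} (capped at \code{weight_cap}) when it lies
#' within \code{max_distance} of that region, where \eqn{d} is the distance
#' to the region edge. Scores are then depth-normalized per cell to a total
#' of \code{norm_total}.
#'
#' @param fragset a \code{FragmentSet}.
#' @param gene_model a \code{GeneModel}.
#' @param decay exponential decay length (bp).
#' @param upstream promoter-side extension of the gene body (bp).
#' @param weight_cap upper bound on any single fragment weight.
#' @param max_distance fragments farther than this from the gene region
#'   contribute nothing (bp).
#' @param normalize depth-normalize per cell (default TRUE).
#' @param norm_total per-cell total after normalization.
#' @return list of class \code{GeneScoreMatrix}: \code{scores} (sparse cells
#'   x genes \code{dgCMatrix}), \code{modality}, \code{normalization}, and
#'   \code{flags} (genes on contigs absent from the fragment set).
#' @export
gene_scores <- function(fragset, gene_model, decay = 5000, upstream = 2000,
                        weight_cap = 4, max_distance = 100000,
                        normalize = TRUE, norm_total = 10000) {
  genes <- gene_model$genes
  fr <- fragset$fragments
  cells <- sort(unique(fr$barcode))
  ci <- seq_along(cells); names(ci) <- cells

  region_start <- ifelse(genes$strand == "+",
                         genes$body_start - upstream, genes$body_start)
  region_end <- ifelse(genes$strand == "+",
                       genes$body_end, genes$body_end + upstream)
  flags <- setdiff(unique(genes$contig), unique(fr$contig))

  mids <- fr[, .(contig, mid = start + (end - start) %/% 2L,
                 barcode, w0 = as.numeric(duplicate_count))]
  triplets <- vector("list", nrow(genes))
  for (g in seq_len(nrow(genes))) {
    win_s <- region_start[g] - max_distance
    win_e <- region_end[g] + max_distance
    sub <- mids[contig == genes$contig[g] & mid >= win_s & mid < win_e]
    if (nrow(sub) == 0L) next
    d <- pmax(0, pmax(region_start[g] - sub$mid, sub$mid - region_end[g]))
    sub[, wt := w0 * pmin(exp(-d / decay), weight_cap)]
    sc <- sub[, .(v = sum(wt)), by = barcode]
    triplets[[g]] <- data.table::data.table(i = ci[sc$barcode], j = g, v = sc$v)
  }
  tr <- data.table::rbindlist(triplets)
  m <- Matrix::sparseMatrix(i = if (nrow(tr)) tr$i else integer(0),
                            j = if (nrow(tr)) tr$j else integer(0),
                            x = if (nrow(tr)) tr$v else numeric(0),
                            dims = c(length(cells), nrow(genes)),
                            dimnames = list(cells, genes$gene_id))
  norm_tag <- "none"
  if (normalize) {
    rs <- Matrix::rowSums(m)
    rs[rs == 0] <- 1
    m <- Matrix::Diagonal(x = norm_total / rs) %*% m
    m <- methods::as(m, "CsparseMatrix")
    dimnames(m) <- list(cells, genes$gene_id)
    norm_tag <- sprintf("per-cell total %g", norm_total)
  }
  structure(list(scores = m, modality = fragset$modality,
                 normalization = norm_tag, flags = flags),
            class = "GeneScoreMatrix")
}

#' Classify per-group regulatory gene states from the two score matrices
#'
#' Within each cell group, a gene is called accessible when its group-mean
#' accessibility score reaches the \code{access_q} quantile of group means
#' across genes, and repressed when its group-mean repression
#' (H3K27me3-like) score reaches the \code{repress_q} quantile; ties at the
#' quantile are kept (the comparison is \eqn{\ge}). The two calls combine
#' into four states: accessible & !repressed = \code{active_accessible};
#' accessible & repressed = \code{accessible_silenced} (open promoter yet
#' silenced); !accessible & repressed = \code{repressed_closed}; otherwise
#' \code{inactive}. When an expression matrix is supplied the summary also
#' reports, per group, the fraction of accessible genes that are not
#' expressed and the fraction of those carrying repression.
#'
#' @param access_scores,repress_scores \code{GeneScoreMatrix} objects (or
#'   bare cells x genes matrices) on a shared gene universe.
#' @param groups named character vector: cell barcode -> group label.
#' @param access_q,repress_q quantile thresholds (default 0.75).
#' @param expression optional genes x groups (or cells) matrix/data.frame of
#'   expression; a gene counts as expressed in a group when its value > 0.
#' @return list with \code{calls} (data.table: gene_id, group,
#'   access_score, repress_score, accessible, repressed, state, thresholds)
#'   and, when expression is given, \code{expression_summary}.
#' @export
classify_states <- function(access_scores, repress_scores, groups,
                            access_q = 0.75, repress_q = 0.75,
                            expression = NULL) {
  A <- if (inherits(access_scores, "GeneScoreMatrix")) access_scores$scores else access_scores
  R <- if (inherits(repress_scores, "GeneScoreMatrix")) repress_scores$scores else repress_scores
  shared_genes <- intersect(colnames(A), colnames(R))
  if (length(shared_genes) == 0L) stop("no shared genes between the matrices")
  A <- A[, shared_genes, drop = FALSE]
  R <- R[, shared_genes, drop = FALSE]

  group_means <- function(M) {
    bc <- intersect(rownames(M), names(groups))
    M <- M[bc, , drop = FALSE]
    g <- groups[bc]
    t(vapply(split(seq_along(g), g), function(i)
      Matrix::colMeans(M[i, , drop = FALSE]), numeric(ncol(M))))
  }
  mA <- group_means(A)
  mR <- group_means(R)
  shared_groups <- intersect(rownames(mA), rownames(mR))

  calls <- data.table::rbindlist(lapply(shared_groups, function(gr) {
    a <- mA[gr, ]; r <- mR[gr, ]
    ta <- stats::quantile(a, access_q, type = 7)
    tr <- stats::quantile(r, repress_q, type = 7)
    # ties at the quantile are kept, but a score of exactly zero is absence
    # of signal and never makes a positive call
    accessible <- a >= ta & a > 0
    repressed <- r >= tr & r > 0
    state <- ifelse(accessible & !repressed, "active_accessible",
             ifelse(accessible & repressed, "accessible_silenced",
             ifelse(repressed, "repressed_closed", "inactive")))
    data.table::data.table(gene_id = shared_genes, group = gr,
                           access_score = as.numeric(a),
                           repress_score = as.numeric(r),
                           accessible = accessible, repressed = repressed,
                           state = state,
                           access_threshold = as.numeric(ta),
                           repress_threshold = as.numeric(tr))
  }))

  out <- list(calls = calls,
              parameters = c(access_q = access_q, repress_q = repress_q))
  if (!is.null(expression)) {
    ex <- as.matrix(expression)
    summ <- data.table::rbindlist(lapply(shared_groups, function(gr) {
      sub <- calls[group == gr]
      col <- if (gr %in% colnames(ex)) ex[, gr] else rowMeans(ex)
      expressed <- names(col)[col > 0]
      acc_genes <- sub$gene_id[sub$accessible]
      not_expr <- setdiff(acc_genes, expressed)
      with_rep <- sub$gene_id[sub$repressed]
      data.table::data.table(
        group = gr,
        n_accessible = length(acc_genes),
        frac_accessible_not_expressed =
          if (length(acc_genes)) length(not_expr) / length(acc_genes) else NA_real_,
        frac_not_expressed_with_repression =
          if (length(not_expr)) mean(not_expr %in% with_rep) else NA_real_)
    }))
    out$expression_summary <- summ
  }
  out
}

#' Base-pair co-occupancy of the two signal classes
#'
#' Partitions the union of the (merged) accessibility and repressive peak
#' sets into both / accessibility-only / repression-only base pairs, and
#' reports fractions of the union (summing to 1) plus genome-relative
#' fractions including \code{neither}.
#'
#' @param peaks_access,peaks_repress peak tables (\code{contig},
#'   \code{start}, \code{end}).
#' @param genome_size total genome length (bp).
#' @return list with \code{union_fractions}, \code{genome_fractions},
#'   \code{bp} (raw base-pair counts) and an \code{empty_union} flag.
#' @export
modality_region_overlap <- function(peaks_access, peaks_repress, genome_size) {
  A <- .merge_intervals(data.table::as.data.table(peaks_access))
  R <- .merge_intervals(data.table::as.data.table(peaks_repress))
  grA <- GenomicRanges::GRanges(A$contig, IRanges::IRanges(A$start + 1L, A$end))
  grR <- GenomicRanges::GRanges(R$contig, IRanges::IRanges(R$start + 1L, R$end))
  both <- sum(GenomicRanges::width(GenomicRanges::intersect(grA, grR)))
  a_only <- sum(GenomicRanges::width(GenomicRanges::setdiff(grA, grR)))
  r_only <- sum(GenomicRanges::width(GenomicRanges::setdiff(grR, grA)))
  u <- both + a_only + r_only
  if (u == 0)
    return(list(union_fractions = c(both = NA, access_only = NA,
                                    repress_only = NA),
                genome_fractions = c(both = 0, access_only = 0,
                                     repress_only = 0, neither = 1),
                bp = c(both = 0, access_only = 0, repress_only = 0),
                empty_union = TRUE))
  list(union_fractions = c(both = both / u, access_only = a_only / u,
                           repress_only = r_only / u),
       genome_fractions = c(both = both / genome_size,
                            access_only = a_only / genome_size,
                            repress_only = r_only / genome_size,
                            neither = 1 - u / genome_size),
       bp = c(both = both, access_only = a_only, repress_only = r_only),
       empty_union = FALSE)
}

#' Alternative-TSS preference from joint accessibility and repression
#'
#' For a gene with several TSSs, each TSS window (\eqn{\pm}\code{halfwidth})
#' gets an accessibility insertion density \eqn{A(t)} (insertions per bp) and
#' a repression fragment density \eqn{R(t)}; the preference score is
#' \eqn{S(t) = A(t) / (1 + R(t))}: an accessible TSS free of repressive
#' signal wins over an equally accessible one buried in it. The preferred
#' TSS is the argmax (ties resolved to the lower coordinate and flagged).
#'
#' @param gene one gene's \code{gene_id} present in \code{gene_model}.
#' @param gene_model a \code{GeneModel} whose \code{tss} table lists >= 2
#'   TSSs for the gene.
#' @param fragset_access,fragset_repress per-modality \code{FragmentSet}s;
#'   may be pre-subset to a cell group.
#' @param halfwidth TSS window half-width (bp).
#' @return list with \code{table} (per-TSS position, A, R, score),
#'   \code{preferred} (position or NA), \code{tie} and \code{no_signal}
#'   flags.
#' @export
tss_preference <- function(gene, gene_model, fragset_access, fragset_repress,
                           halfwidth = 500L) {
  tss <- gene_model$tss[gene_id == gene]
  if (nrow(tss) < 2L) stop("gene must have >= 2 TSSs")
  bp <- 2L * halfwidth + 1L
  ins <- .insertions(fragset_access)
  acc <- vapply(seq_len(nrow(tss)), function(i)
    ins[contig == tss$contig[i] & pos >= tss$position[i] - halfwidth &
          pos <= tss$position[i] + halfwidth, sum(w)], numeric(1))
  fr <- fragset_repress$fragments
  rep_ <- vapply(seq_len(nrow(tss)), function(i)
    fr[contig == tss$contig[i] & start <= tss$position[i] + halfwidth &
         end > tss$position[i] - halfwidth, sum(duplicate_count)], numeric(1))
  A <- acc / bp
  R <- rep_ / bp
  S <- A / (1 + R)
  tab <- data.table::data.table(position = tss$position, A = A, R = R,
                                score = S)
  if (all(acc == 0) && all(rep_ == 0))
    return(list(table = tab, preferred = NA_integer_, tie = FALSE,
                no_signal = TRUE))
  best <- max(S)
  cand <- tss$position[S == best]
  list(table = tab, preferred = min(cand), tie = length(cand) > 1L,
       no_signal = FALSE)
}

#' Percent spliced in (PSI) per junction
#'
#' Junctions competing for the same donor site form a family; a junction's
#' PSI is its count divided by the family total. Cells where the family
#' total is 0 get \code{NA}.
#'
#' @param junction_counts data.frame with \code{cell}, \code{donor_site},
#'   \code{junction_id}, \code{count}.
#' @return data.table with \code{cell}, \code{donor_site},
#'   \code{junction_id}, \code{count}, \code{psi}.
#' @export
psi <- function(junction_counts) {
  dt <- data.table::as.data.table(junction_counts)
  req <- c("cell", "donor_site", "junction_id", "count")
  if (!all(req %in% names(dt)))
    stop("junction table needs columns: ", paste(req, collapse = ", "))
  if (any(dt$count < 0)) stop("junction counts must be >= 0")
  dt <- data.table::copy(dt)
  dt[, total := sum(count), by = .(cell, donor_site)]
  dt[, psi := ifelse(total > 0, count / total, NA_real_)]
  dt[, total := NULL]
  dt[]
}

#' Cross-modality cluster correspondence
#'
#' Builds the confusion matrix of the two labelings over the paired cells
#' and finds the one-to-one cluster-label mapping maximizing agreement
#' (exact assignment by bitmask dynamic programming). The matched fraction
#' is the share of paired cells whose labels agree under that mapping.
#'
#' @param labels_access,labels_histone named vectors (names = cell barcodes)
#'   of cluster labels.
#' @param paired_cells barcodes present in both labelings.
#' @return list with \code{matched_fraction}, \code{mapping} (named vector:
#'   accessibility label -> histone label), \code{confusion}.
#' @export
cluster_correspondence <- function(labels_access, labels_histone,
                                   paired_cells = intersect(names(labels_access),
                                                            names(labels_histone))) {
  if (length(paired_cells) == 0L) stop("empty cell pairing")
  la <- as.character(labels_access[paired_cells])
  lh <- as.character(labels_histone[paired_cells])
  conf <- table(access = la, histone = lh)
  m <- .max_assignment(unclass(conf))
  agree <- sum(vapply(seq_along(m$cols), function(i) {
    if (is.na(m$cols[i])) 0L else conf[i, m$cols[i]]
  }, 0L))
  mapping <- stats::setNames(colnames(conf)[m$cols], rownames(conf))
  list(matched_fraction = agree / length(paired_cells),
       mapping = mapping, confusion = conf)
}

# exact maximum-weight one-to-one assignment (rows -> columns) via bitmask DP
# over the smaller dimension; returns cols[i] = column index for row i (NA
# when rows > cols and row i is unmatched)
.max_assignment <- function(w) {
  transposed <- FALSE
  if (ncol(w) < nrow(w)) { w <- t(w); transposed <- TRUE }
  nr <- nrow(w); nc <- ncol(w)
  if (nc > 20L) stop("assignment supports at most 20 clusters")
  # dp over rows; state = bitmask of used columns
  nstates <- bitwShiftL(1L, nc)
  NEG <- -Inf
  dp <- matrix(NEG, nrow = nr + 1L, ncol = nstates)
  choice <- matrix(NA_integer_, nrow = nr + 1L, ncol = nstates)
  dp[1L, 1L] <- 0
  for (r in seq_len(nr)) {
    for (s in 0:(nstates - 1L)) {
      cur <- dp[r, s + 1L]
      if (cur == NEG) next
      for (cc in seq_len(nc)) {
        bit <- bitwShiftL(1L, cc - 1L)
        if (bitwAnd(s, bit) != 0L) next
        ns <- bitwOr(s, bit)
        val <- cur + w[r, cc]
        if (val > dp[r + 1L, ns + 1L]) {
          dp[r + 1L, ns + 1L] <- val
          choice[r + 1L, ns + 1L] <- cc
        }
      }
    }
  }
  s_best <- which.max(dp[nr + 1L, ]) - 1L
  cols <- integer(nr)
  s <- s_best
  for (r in rev(seq_len(nr))) {
    cc <- choice[r + 1L, s + 1L]
    cols[r] <- cc
    s <- bitwAnd(s, bitwNot(bitwShiftL(1L, cc - 1L)))
  }
  if (transposed) {
    # cols maps (original columns) -> original rows; invert
    inv <- rep(NA_integer_, nc)
    inv[cols] <- seq_len(nr)
    list(cols = inv)
  } else {
    list(cols = cols)
  }
}

#' Per-cluster marker features (Wilcoxon rank-sum)
#'
#' Tests each feature (peak or gene score) for enrichment in one cluster
#' versus all other cells with a Wilcoxon rank-sum test, adjusts p-values by
#' Benjamini-Hochberg, and flags features with adjusted p <= \code{p_max}
#' and log2 fold change >= \code{lfc_min}.
#'
#' @param scores cells x features matrix.
#' @param labels named cluster labels for the rows of \code{scores}.
#' @param p_max adjusted-p threshold (default 0.05).
#' @param lfc_min log2 fold-change threshold (default 0.5).
#' @param pseudocount added to group means before the ratio.
#' @return data.table: cluster, feature, log2fc, p, p_adj, significant.
#' @export
marker_features <- function(scores, labels, p_max = 0.05, lfc_min = 0.5,
                            pseudocount = 1) {
  M <- as.matrix(scores)
  labels <- labels[rownames(M)]
  out <- list()
  for (cl in sort(unique(labels))) {
    in_cl <- labels == cl
    p <- apply(M, 2L, function(x)
      stats::wilcox.test(x[in_cl], x[!in_cl], exact = FALSE)$p.value)
    lfc <- log2((colMeans(M[in_cl, , drop = FALSE]) + pseudocount) /
                (colMeans(M[!in_cl, , drop = FALSE]) + pseudocount))
    out[[cl]] <- data.table::data.table(cluster = cl, feature = colnames(M),
                                        log2fc = lfc, p = p)
  }
  res <- data.table::rbindlist(out)
  res[, p_adj := stats::p.adjust(p, method = "BH")]
  res[, significant := p_adj <= p_max & log2fc >= lfc_min]
  res[]
}
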