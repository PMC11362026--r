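# Tile-matrix construction and TF-IDF/LSI embedding with clustering. Tile
# sizes default to the modality convention: 500 bp for accessibility, 5000 bp
# for the broad histone-modification signal.

#' Build a cells x genomic-tiles count matrix
#'
#' Contigs are partitioned into fixed-width tiles; each fragment is counted
#' in the tile containing its midpoint (duplicate-weighted), so a fragment
#' spanning a tile boundary contributes to exactly one tile.
#'
#' @param fragset a \code{FragmentSet}.
#' @param tile_size tile width in bp (convention: 500 for accessibility,
#'   5000 for histone-modification data).
#' @return list of class \code{TileMatrix} with \code{counts} (sparse
#'   \code{dgCMatrix}, cells x tiles; all-zero cell rows retained),
#'   \code{tiles} (data.table: contig, start, end), \code{tile_size},
#'   \code{modality}.
#' @export
tile_matrix <- function(fragset, tile_size = 500L) {
  fr <- fragset$fragments
  contigs <- fragset$contigs
  n_tiles_per <- as.integer(ceiling(as.numeric(contigs) / tile_size))
  offset <- c(0L, cumsum(n_tiles_per))[seq_along(contigs)]
  names(offset) <- names(contigs)
  total_tiles <- sum(n_tiles_per)

  cells <- sort(unique(fr$barcode))
  ci <- seq_along(cells); names(ci) <- cells
  mid <- fr$start + (fr$end - fr$start) %/% 2L
  tile <- offset[fr$contig] + pmin(mid %/% tile_size,
                                   n_tiles_per[match(fr$contig, names(contigs))] - 1L) + 1L
  agg <- data.table::data.table(i = ci[fr$barcode], j = as.integer(tile),
                                x = as.numeric(fr$duplicate_count))
  agg <- agg[, .(x = sum(x)), by = .(i, j)]
  m <- Matrix::sparseMatrix(i = agg$i, j = agg$j, x = agg$x,
                            dims = c(length(cells), total_tiles),
                            dimnames = list(cells, NULL))
  tiles <- data.table::rbindlist(lapply(seq_along(contigs), function(k) {
    s <- seq_len(n_tiles_per[k]) - 1L
    data.table::data.table(contig = names(contigs)[k],
                           start = s * tile_size,
                           end = pmin((s + 1L) * tile_size,
                                      as.integer(contigs[[k]])))
  }))
  structure(list(counts = m, tiles = tiles, tile_size = tile_size,
                 modality = fragset$modality),
            class = "TileMatrix")
}

#' TF-IDF / LSI embedding of a tile matrix
#'
#' Single-pass latent semantic indexing: binarize, keep the
#' \code{top_features} most prevalent tiles, weight by term frequency
#' (per-cell) times \eqn{\log(1 + N_{cells}/df)}, and take a truncated SVD.
#' The first component is typically dominated by per-cell depth and is
#' dropped by default.
#'
#' @param tiles a \code{TileMatrix} (or bare cells x features sparse matrix).
#' @param k number of retained components (default 30).
#' @param top_features number of most-prevalent features kept (default
#'   25000).
#' @param drop_first drop the depth-correlated first component.
#' @param seed recorded in the result; the decomposition itself is
#'   deterministic.
#' @return list of class \code{Embedding}: \code{coords} (cells x k),
#'   \code{d} (singular values), \code{dropped_first}, \code{seed}.
#' @export
lsi_embed <- function(tiles, k = 30L, top_features = 25000L,
                      drop_first = TRUE, seed = 1L) {
  X <- if (inherits(tiles, "TileMatrix")) tiles$counts else tiles
  if (nrow(X) < 2L) stop("need at least 2 cells")
  X@x[X@x > 0] <- 1

  df <- Matrix::colSums(X)
  keep <- which(df > 0)
  if (length(keep) > top_features)
    keep <- keep[order(df[keep], decreasing = TRUE)[seq_len(top_features)]]
  X <- X[, keep, drop = FALSE]
  df <- df[keep]

  n_comp <- k + as.integer(drop_first)
  if (n_comp > min(dim(X))) stop("k too large for the matrix dimensions")

  rs <- Matrix::rowSums(X)
  rs[rs == 0] <- 1
  tf <- Matrix::Diagonal(x = 1 / rs) %*% X
  idf <- log(1 + nrow(X) / df)
  Xw <- tf %*% Matrix::Diagonal(x = idf)

  # exact truncated SVD via the (cells x cells) Gram matrix: cell counts in
  # this setting are far below feature counts
  G <- as.matrix(Matrix::tcrossprod(Xw))
  eig <- eigen(G, symmetric = TRUE)
  d2 <- pmax(eig$values[seq_len(n_comp)], 0)
  U <- eig$vectors[, seq_len(n_comp), drop = FALSE]
  # deterministic sign: largest-magnitude loading positive
  for (j in seq_len(ncol(U))) {
    i <- which.max(abs(U[, j]))
    if (U[i, j] < 0) U[, j] <- -U[, j]
  }
  coords <- U %*% diag(sqrt(d2), nrow = n_comp)
  if (drop_first) coords <- coords[, -1L, drop = FALSE]
  rownames(coords) <- rownames(X)
  colnames(coords) <- paste0("LSI", seq_len(ncol(coords)))
  structure(list(coords = coords, d = sqrt(d2), dropped_first = drop_first,
                 seed = seed),
            class = "Embedding")
}

#' Cluster cells in an embedding
#'
#' Deterministic seeded k-means by default; a shared-nearest-neighbour graph
#' option is available behind \code{method = "graph"} (connected components
#' of the SNN graph thresholded at \code{snn_min}).
#'
#' @param embedding an \code{Embedding} (or bare coordinate matrix).
#' @param k_clusters number of clusters (k-means).
#' @param seed RNG seed.
#' @param method \code{"kmeans"} or \code{"graph"}.
#' @param snn_k,snn_min graph-mode parameters: neighbours per cell and
#'   minimal shared-neighbour fraction for an edge.
#' @return list with \code{labels} (named integer vector, 0-based),
#'   \code{silhouette} (mean silhouette width; NA for a single cluster),
#'   \code{seed}.
#' @export
cluster_cells <- function(embedding, k_clusters = 2L, seed = 1L,
                          method = c("kmeans", "graph"),
                          snn_k = 15L, snn_min = 0.25) {
  method <- match.arg(method)
  X <- if (inherits(embedding, "Embedding")) embedding$coords else embedding
  if (!all(is.finite(X))) stop("embedding must be finite")
  if (method == "kmeans") {
    if (k_clusters > nrow(X)) stop("k_clusters exceeds the number of cells")
    set.seed(seed)
    km <- stats::kmeans(X, centers = k_clusters, nstart = 10L, iter.max = 100L)
    labels <- km$cluster - 1L
  } else {
    d <- as.matrix(stats::dist(X))
    n <- nrow(d)
    kk <- min(snn_k, n - 1L)
    nn <- t(apply(d, 1L, function(r) order(r)[2:(kk + 1L)]))
    adj <- matrix(FALSE, n, n)
    for (i in seq_len(n)) {
      for (j in nn[i, ]) {
        shared <- length(intersect(nn[i, ], nn[j, ])) / kk
        if (shared >= snn_min) adj[i, j] <- adj[j, i] <- TRUE
      }
    }
    labels <- .connected_components(adj) - 1L
  }
  names(labels) <- rownames(X)
  sil <- .mean_silhouette(X, labels)
  list(labels = labels, silhouette = sil, seed = seed)
}

.connected_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

.mean_silhouette <- function(X, labels) {
  if (length(unique(labels)) < 2L) return(NA_real_)
  d <- as.matrix(stats::dist(X))
  n <- nrow(d)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    a <- if (sum(own) > 1L) mean(d[i, own & seq_len(n) != i]) else 0
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(l)
      mean(d[i, labels == l]), numeric(1)))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

#' Write a sparse matrix as MatrixMarket with index sidecars
#'
#' @param m sparse matrix with dimnames.
#' @param prefix output path prefix; writes \code{<prefix>.mtx},
#'   \code{<prefix>.rows.tsv}, \code{<prefix>.cols.tsv}.
#' @return (invisibly) the mtx path.
#' @export
write_mtx <- function(m, prefix) {
  p <- paste0(prefix, ".mtx")
  Matrix::writeMM(methods::as(m, "CsparseMatrix"), p)
  writeLines(rownames(m), paste0(prefix, ".rows.tsv"))
  if (!is.null(colnames(m))) writeLines(colnames(m), paste0(prefix, ".cols.tsv"))
  invisible(p)
}
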