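## Graph-based phenotyping of the compensated cell catalog: 99th-percentile
## range normalisation, k-nearest-neighbour Jaccard graph under Manhattan
## distance, Louvain community detection, and z-scored cluster profiles.

#' Range-normalise marker expression to the 99th percentile
#'
#' Per channel, values are divided by that channel's 99th percentile over
#' all cells and (by default) clipped at 1, so every marker gets equal
#' weight in clustering. A channel whose 99th percentile is 0 maps to all
#' zeros. The operation is idempotent on its own output.
#'
#' @param expr numeric cells x channels matrix (non-negative).
#' @param clip clip values above the percentile at 1 (default); set
#'   `FALSE` to divide without clipping.
#' @return normalised matrix in `[0, 1]` (or unbounded when `clip = FALSE`).
#' @export
normalize_p99 <- function(expr, clip = TRUE) {
  expr <- as.matrix(expr)
  if (any(expr < 0)) .stopf("expression values must be non-negative")
  out <- apply(expr, 2, function(x) {
    ## type-1 (order-statistic) quantile: with the top 1% clipped to the
    ## percentile, the 99th percentile of the output is exactly 1, so the
    ## normalisation is idempotent
    p <- quantile(x, 0.99, names = FALSE, type = 1)
    if (p <= 0) return(rep(0, length(x)))
    if (clip) pmin(x, p) / p else x / p
  })
  out <- matrix(out, nrow(expr), ncol(expr))
  dimnames(out) <- dimnames(expr)
  out
}

#' Cluster cells on a k-nearest-neighbour Jaccard graph
#'
#' Builds the k-nearest-neighbour graph of the normalised expression matrix
#' under Manhattan distance, weights each edge by the Jaccard overlap of the
#' two cells' neighbour sets, and maximises modularity with the Louvain
#' algorithm (fixed seed). Because a k-NN graph with k far below the
#' phenotype sizes always carries local substructure, a fixed resolution
#' over-partitions planted phenotypes; by default the resolution is
#' therefore selected from a small grid by the mean silhouette width of the
#' resulting partition on the same distances (ties to the coarser
#' partition). Pass a numeric `resolution` to pin it instead. Cells left in
#' singleton communities are labelled -1 (outliers); remaining clusters are
#' numbered by decreasing size.
#'
#' @param expr normalised cells x channels matrix (see [normalize_p99()]).
#' @param k number of nearest neighbours.
#' @param metric distance metric, `"manhattan"` (default) or `"euclidean"`.
#' @param seed RNG seed for the community detection.
#' @param resolution Louvain resolution parameter, or `NULL` (default) for
#'   silhouette-based selection over `resolution_grid`.
#' @param resolution_grid candidate resolutions for the automatic choice.
#' @return list of class `cluster_result`: `labels` (integer per cell, -1 =
#'   outlier), `counts` (table), `k`, `seed`, `resolution` (the value
#'   used).
#' @export
cluster_cells <- function(expr, k = 10, metric = "manhattan", seed = 42,
                          resolution = NULL,
                          resolution_grid = c(0.01, 0.02, 0.05, 0.1, 0.2,
                                              0.4, 0.8, 1)) {
  expr <- as.matrix(expr)
  n <- nrow(expr)
  if (k >= n) .stopf("k = %d must be smaller than the number of cells (%d)",
                     k, n)
  D0 <- as.matrix(dist(expr, method = metric))
  D <- D0
  diag(D) <- Inf
  nn <- t(apply(D, 1, function(r) order(r)[seq_len(k)]))
  ## Jaccard weights via the shared-neighbour count matrix
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k),
                            j = as.vector(t(nn)), x = 1, dims = c(n, n))
  common <- Matrix::tcrossprod(A)
  edges <- unique(cbind(pmin(rep(seq_len(n), each = k), as.vector(t(nn))),
                        pmax(rep(seq_len(n), each = k), as.vector(t(nn)))))
  cm <- common[edges]
  w <- cm / (2 * k - cm)
  keep <- w > 0
  g <- igraph::graph_from_edgelist(edges[keep, , drop = FALSE],
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  louvain <- function(res) {
    set.seed(seed)
    as.integer(igraph::membership(
      igraph::cluster_louvain(g, weights = w[keep], resolution = res)))
  }
  if (!is.null(resolution)) {
    mem <- louvain(resolution)
    res_used <- resolution
  } else {
    grid <- sort(resolution_grid)
    best_mem <- NULL; best_sil <- -Inf; res_used <- grid[1]
    for (res in grid) {
      mem <- louvain(res)
      sil <- .mean_silhouette(D0, mem)
      if (is.finite(sil) && sil > best_sil + 1e-9) {
        best_sil <- sil; best_mem <- mem; res_used <- res
      }
      if (is.null(best_mem)) { best_mem <- mem; res_used <- res }
    }
    mem <- best_mem
  }
  sizes <- table(mem)
  lab <- mem
  lab[lab %in% as.integer(names(sizes))[sizes == 1]] <- -1L
  ## relabel by decreasing size
  good <- sort(table(lab[lab != -1L]), decreasing = TRUE)
  lut <- stats::setNames(seq_along(good), names(good))
  out <- ifelse(lab == -1L, -1L, lut[as.character(lab)])
  structure(list(labels = as.integer(out),
                 counts = table(factor(out, levels = sort(unique(out)))),
                 k = k, seed = seed, resolution = res_used),
            class = "cluster_result")
}

#' Mean silhouette width of a partition given a distance matrix
#' (single-member clusters contribute 0; one-cluster partitions are NA)
#' @noRd
.mean_silhouette <- function(D0, mem) {
  cls <- sort(unique(mem))
  if (length(cls) < 2) return(NA_real_)
  n <- length(mem)
  ind <- outer(mem, cls, `==`)
  counts <- colSums(ind)
  sums <- D0 %*% ind                     # n x K total distance to clusters
  own <- sums[cbind(seq_len(n), match(mem, cls))]
  a <- ifelse(counts[match(mem, cls)] > 1,
              own / (counts[match(mem, cls)] - 1), 0)
  means <- sweep(sums, 2, counts, `/`)
  means[cbind(seq_len(n), match(mem, cls))] <- Inf
  b <- apply(means, 1, min)
  s <- ifelse(counts[match(mem, cls)] > 1, (b - a) / pmax(a, b), 0)
  mean(s)
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result: %d cells, %d cluster(s)%s\n",
              length(x$labels), sum(names(x$counts) != "-1"),
              if ("-1" %in% names(x$counts))
                sprintf(" + %d outlier(s)", x$counts[["-1"]]) else ""))
  print(x$counts)
  invisible(x)
}

#' Per-cluster expression profile
#'
#' Per-cluster mean of the normalised expression, z-scored per channel
#' across clusters (a channel with zero variance across clusters gets
#' z-scores of 0), plus absolute cell counts.
#'
#' @param expr normalised cells x channels matrix.
#' @param labels integer cluster label per cell (may include -1).
#' @return list: `z` (clusters x channels z-score matrix), `means`
#'   (raw cluster means), `counts`.
#' @export
cluster_profile <- function(expr, labels) {
  expr <- as.matrix(expr)
  stopifnot(nrow(expr) == length(labels))
  means <- rowsum(expr, labels) / as.vector(table(labels))
  z <- apply(means, 2, function(m) {
    s <- sd(m)
    if (!is.finite(s) || s < 1e-12) rep(0, length(m)) else (m - mean(m)) / s
  })
  z <- matrix(z, nrow(means), ncol(means), dimnames = dimnames(means))
  list(z = z, means = means, counts = table(labels))
}
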