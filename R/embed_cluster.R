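#' Log-normalize counts
#'
#' Library-size normalization followed by a log transform:
#' `ln(1 + count * scale / cell_total)`, per cell.
#'
#' @param m a [count_matrix] or a sparse cells x genes matrix.
#' @param scale size scaling factor (default 1e4).
#' @return Sparse cells x genes matrix of normalized values.
#' @export
lognormalize <- function(m, scale = 1e4) {
  x <- if (inherits(m, "count_matrix")) m$counts else
    methods::as(methods::as(m, "CsparseMatrix"), "generalMatrix")
  tot <- Matrix::rowSums(x)
  if (any(tot == 0))
    stop("cells with zero total counts: ",
         paste(utils::head(rownames(x)[tot == 0], 3), collapse = ", "),
         call. = FALSE)
  out <- Matrix::Diagonal(x = scale / tot) %*% x
  out <- methods::as(out, "CsparseMatrix")
  out@x <- log1p(out@x)
  dimnames(out) <- dimnames(x)
  out
}

#' Select highly variable genes
#'
#' Ranks genes by standardized variance: the variance of the normalized
#' values divided by a mean-variance trend fitted by loess on log scale.
#' Constant genes (zero variance) rank last; ties break by ascending gene
#' id, so the selection is deterministic.
#'
#' @param normalized sparse cells x genes matrix from [lognormalize()].
#' @param hvg_n number of genes to return (default 2000).
#' @return Character vector of `hvg_n` gene ids, ordered by decreasing
#'   standardized variance.
#' @export
select_hvg <- function(normalized, hvg_n = 2000) {
  genes <- colnames(normalized)
  if (hvg_n > ncol(normalized))
    stop("hvg_n = ", hvg_n, " exceeds the ", ncol(normalized),
         " available genes", call. = FALSE)
  n <- nrow(normalized)
  mu <- Matrix::colMeans(normalized)
  ex2 <- Matrix::colMeans(normalized^2)
  v <- (ex2 - mu^2) * n / max(n - 1, 1)
  std_var <- rep(0, length(v))
  pos <- v > 0 & mu > 0
  if (sum(pos) >= 10) {
    fit <- stats::loess(log(v[pos]) ~ log(mu[pos]), degree = 2,
                        span = 0.5)
    trend <- exp(stats::fitted(fit))
    std_var[pos] <- v[pos] / trend
  } else {
    std_var[pos] <- v[pos]
  }
  ord <- order(-std_var, genes)
  genes[ord][seq_len(hvg_n)]
}

#' Z-score genes and clip extreme values
#'
#' Centers and scales each gene across cells (population standard
#' deviation, denominator n), then truncates to `[-clip, +clip]`.
#' Zero-variance genes scale to 0 rather than NaN.
#'
#' @param normalized cells x genes matrix (sparse or dense).
#' @param clip truncation bound (default 10).
#' @return Dense cells x genes matrix of clipped z-scores.
#' @export
scale_clip <- function(normalized, clip = 10) {
  x <- as.matrix(normalized)
  mu <- colMeans(x)
  sd_pop <- sqrt(pmax(colMeans(x^2) - mu^2, 0))
  x <- sweep(x, 2, mu, "-")
  nz <- sd_pop > 0
  x[, nz] <- sweep(x[, nz, drop = FALSE], 2, sd_pop[nz], "/")
  x[, !nz] <- 0
  x[x > clip] <- clip
  x[x < -clip] <- -clip
  x
}

#' Principal component analysis of a scaled matrix
#'
#' Truncated PCA via the eigendecomposition of the smaller Gram matrix of
#' the (already centered) scaled matrix.  Loading signs are fixed so each
#' column's largest-magnitude entry is positive, making the decomposition
#' reproducible up to machine precision.
#'
#' @param scaled dense cells x genes matrix from [scale_clip()].
#' @param n_dims number of components to keep.
#' @return An object of class `embedding`: `scores` (cells x PCs),
#'   `loadings` (genes x PCs, orthonormal columns), `variance_explained`
#'   (proportions, non-increasing), `n_dims`.
#' @export
run_pca <- function(scaled, n_dims) {
  x <- as.matrix(scaled)
  n <- nrow(x); p <- ncol(x)
  if (n_dims < 1 || n_dims > min(n, p))
    stop("n_dims must lie in 1..", min(n, p), call. = FALSE)
  total <- sum(x^2)
  if (p <= n) {
    e <- eigen(crossprod(x), symmetric = TRUE)
    ev <- pmax(e$values, 0)
    rank <- sum(ev > max(ev) * 1e-12)
    if (n_dims > rank)
      stop("n_dims = ", n_dims, " exceeds the achievable rank ", rank,
           call. = FALSE)
    loadings <- e$vectors[, seq_len(n_dims), drop = FALSE]
    scores <- x %*% loadings
  } else {
    e <- eigen(tcrossprod(x), symmetric = TRUE)
    ev <- pmax(e$values, 0)
    rank <- sum(ev > max(ev) * 1e-12)
    if (n_dims > rank)
      stop("n_dims = ", n_dims, " exceeds the achievable rank ", rank,
           call. = FALSE)
    u <- e$vectors[, seq_len(n_dims), drop = FALSE]
    d <- sqrt(ev[seq_len(n_dims)])
    loadings <- crossprod(x, u) %*% diag(1 / d, n_dims)
    scores <- u %*% diag(d, n_dims)
  }
  # orient each component so its largest-|loading| gene points positive
  for (j in seq_len(n_dims)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  dimnames(scores) <- list(rownames(x), paste0("PC", seq_len(n_dims)))
  dimnames(loadings) <- list(colnames(x), paste0("PC", seq_len(n_dims)))
  structure(list(scores = scores, loadings = loadings,
                 variance_explained = ev[seq_len(n_dims)] / total,
                 n_dims = n_dims),
            class = "embedding")
}

#' @export
print.embedding <- function(x, ...) {
  cat(sprintf("embedding: %d cells x %d PCs (%.1f%% variance)\n",
              nrow(x$scores), x$n_dims,
              100 * sum(x$variance_explained)))
  invisible(x)
}

#' Shared-nearest-neighbor graph clustering
#'
#' Builds a k-nearest-neighbor graph on the first `n_dims` PC scores,
#' reweights edges by the Jaccard similarity of neighbor sets (each set
#' includes the cell itself), prunes weak edges, and partitions the graph
#' by modularity-based Leiden community detection at the given resolution.
#' Cluster labels are integers 1..K ordered by decreasing cluster size.
#'
#' @param embedding an [run_pca()] `embedding`.
#' @param n_dims number of PCs to use (default: all available).
#' @param resolution modularity resolution (default 0.55).
#' @param k neighbors per cell (default 20).
#' @param prune Jaccard weights below this are dropped (default 1/15).
#' @param seed RNG seed for the community search (default 1).
#' @return Named integer vector of cluster labels, one per cell.
#' @export
snn_cluster <- function(embedding, n_dims = NULL, resolution = 0.55,
                        k = 20, prune = 1 / 15, seed = 1L) {
  stopifnot(inherits(embedding, "embedding"))
  s <- embedding$scores
  if (!is.null(n_dims)) s <- s[, seq_len(min(n_dims, ncol(s))), drop = FALSE]
  n <- nrow(s)
  if (k >= n) stop("k = ", k, " must be below the number of cells ", n,
                   call. = FALSE)
  nn <- .knn_indices(s, k)
  # sparse membership matrix of neighbor sets (self included)
  i <- rep(seq_len(n), each = k + 1)
  j <- as.vector(t(cbind(seq_len(n), nn)))
  a <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(a)
  shared <- methods::as(methods::as(shared, "CsparseMatrix"), "generalMatrix")
  shared@x <- shared@x / (2 * (k + 1) - shared@x)  # Jaccard
  shared@x[shared@x < prune] <- 0
  snn <- Matrix::drop0(shared)
  Matrix::diag(snn) <- 0
  g <- igraph::graph_from_adjacency_matrix(snn, mode = "undirected",
                                           weighted = TRUE)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  comm <- igraph::cluster_leiden(g, objective_function = "modularity",
                                 resolution = resolution, n_iterations = 10)
  memb <- igraph::membership(comm)
  sizes <- table(memb)
  new_id <- stats::setNames(seq_along(sizes),
                            names(sizes)[order(-sizes, as.integer(names(sizes)))])
  labels <- as.integer(new_id[as.character(memb)])
  names(labels) <- rownames(s)
  labels
}

# k nearest neighbors (excluding self) by blocked exact search
.knn_indices <- function(s, k, block = 1000L) {
  n <- nrow(s)
  sq <- rowSums(s^2)
  out <- matrix(0L, n, k)
  for (start in seq(1, n, by = block)) {
    rows <- start:min(start + block - 1, n)
    d2 <- outer(sq[rows], sq, "+") - 2 * s[rows, , drop = FALSE] %*% t(s)
    for (ii in seq_along(rows)) {
      ord <- order(d2[ii, ])
      ord <- ord[ord != rows[ii]]
      out[rows[ii], ] <- ord[seq_len(k)]
    }
  }
  out
}

#' Cluster marker genes by Wilcoxon rank-sum test
#'
#' For each cluster, compares each gene's normalized expression in the
#' cluster against all other cells.  Only genes whose absolute log2 fold
#' change of mean expression (expm1-mean with pseudocount 1) reaches
#' `lfc_threshold` are tested; p-values use the normal approximation with
#' tie correction and are BH-adjusted within each cluster's tested set.
#'
#' @param normalized sparse cells x genes matrix from [lognormalize()].
#' @param labels per-cell cluster labels.
#' @param lfc_threshold minimum |log2 fold change| to test (default 0.5).
#' @param min_cells clusters smaller than this are skipped with a warning
#'   (default 3).
#' @return data.frame: cluster, gene_id, avg_log2fc, p, p_adj, ordered by
#'   cluster then p.
#' @export
find_markers <- function(normalized, labels, lfc_threshold = 0.5,
                         min_cells = 3) {
  if (length(labels) != nrow(normalized))
    stop("labels length does not match cells", call. = FALSE)
  cl <- sort(unique(labels))
  if (length(cl) < 2) stop("need at least two clusters", call. = FALSE)
  expm1_mat <- normalized
  expm1_mat@x <- expm1(expm1_mat@x)
  res <- list()
  for (c0 in cl) {
    in_cl <- labels == c0
    if (sum(in_cl) < min_cells) {
      warning("cluster ", c0, " has fewer than ", min_cells,
              " cells; skipped")
      next
    }
    mu_in <- Matrix::colMeans(expm1_mat[in_cl, , drop = FALSE])
    mu_out <- Matrix::colMeans(expm1_mat[!in_cl, , drop = FALSE])
    lfc <- log2(mu_in + 1) - log2(mu_out + 1)
    cand <- which(abs(lfc) >= lfc_threshold)
    if (!length(cand)) next
    x <- as.matrix(normalized[, cand, drop = FALSE])
    w <- .rank_sum_matrix(x, in_cl)
    res[[as.character(c0)]] <- data.frame(
      cluster = c0, gene_id = colnames(normalized)[cand],
      avg_log2fc = lfc[cand], p = w$p,
      p_adj = stats::p.adjust(w$p, "BH"),
      stringsAsFactors = FALSE)
  }
  if (!length(res))
    return(data.frame(cluster = integer(), gene_id = character(),
                      avg_log2fc = numeric(), p = numeric(),
                      p_adj = numeric()))
  out <- do.call(rbind, res)
  out <- out[order(out$cluster, out$p, out$gene_id), ]
  rownames(out) <- NULL
  out
}

# Vectorized two-sided Wilcoxon rank-sum over matrix columns
# (normal approximation with tie correction, no continuity correction).
.rank_sum_matrix <- function(x, g1) {
  n1 <- sum(g1); n2 <- sum(!g1); n <- n1 + n2
  r <- apply(x, 2, rank)
  if (is.null(dim(r))) r <- matrix(r, ncol = ncol(x))
  r1 <- colSums(r[g1, , drop = FALSE])
  u <- r1 - n1 * (n1 + 1) / 2
  tie_term <- apply(x, 2, function(v) {
    len <- rle(sort(v))$lengths
    sum(len^3 - len)
  })
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  z <- ifelse(sigma2 > 0, (u - n1 * n2 / 2) / sqrt(sigma2), 0)
  p <- ifelse(sigma2 > 0, pmin(1, 2 * stats::pnorm(-abs(z))), 1)
  list(U = u, z = z, p = p)
}
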