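test_that("lognormalize follows ln(1 + scale * count / total)", {
  counts <- rbind(c(1, 9, 0), c(2, 2, 6))
  m <- count_matrix(counts, c("c1", "c2"), c("g1", "g2", "g3"),
                    rep("host", 3))
  norm <- lognormalize(m, scale = 1e4)
  expect_equal(norm[1, 1], log(1 + 1e4 * 1 / 10))  # ln(1001) ~ 6.9088
  expect_equal(norm[1, 1], 6.9088, tolerance = 1e-4)
  expect_equal(norm[1, 3], 0)

  m2 <- count_matrix(counts * 2, m$cell_ids, m$gene_ids, m$gene_origin)
  expect_equal(as.matrix(lognormalize(m2)), as.matrix(norm))

  m0 <- count_matrix(rbind(c(1, 1, 1), c(0, 0, 0)), c("a", "zero"),
                     m$gene_ids, m$gene_origin)
  expect_error(lognormalize(m0), "zero")
})

test_that("select_hvg ranks by trend-standardized variance, deterministically", {
  set.seed(2)
  x <- matrix(rpois(100 * 50, 5), 100, 50,
              dimnames = list(paste0("c", 1:100), sprintf("g%02d", 1:50)))
  norm <- lognormalize(count_matrix(x, rownames(x), colnames(x),
                                    rep("host", 50)))
  norm[, 50] <- 0.5  # constant normalized gene
  hvg <- select_hvg(norm, 49)
  expect_false("g50" %in% hvg)
  expect_setequal(select_hvg(norm, 50), colnames(x))
  expect_error(select_hvg(norm, 51), "exceeds")
})

test_that("planted cluster markers are selected as variable genes", {
  fx <- small_fixture()
  host <- subset_cells(fx$m, genes = fx$m$gene_origin == "host")
  norm <- lognormalize(host)
  hvg <- select_hvg(norm, 150)
  markers <- fx$sim$genes$gene_id[grepl("^cluster",
                                        fx$sim$genes$geneset)]
  expect_gt(mean(markers %in% hvg), 0.9)
})

test_that("scale_clip z-scores with population sd and truncates", {
  x <- cbind(g1 = c(0, 2), g2 = c(5, 5))
  s <- scale_clip(x)
  expect_equal(unname(s[, 1]), c(-1, 1))  # population sd of {0,2} is 1
  expect_equal(unname(s[, 2]), c(0, 0))   # constant gene -> 0, not NaN

  y <- cbind(g = c(rep(0, 1000), 37))
  expect_equal(max(scale_clip(y, clip = 10)), 10)
})

test_that("run_pca matches a dense SVD oracle and is well-formed", {
  set.seed(4)
  x <- scale_clip(matrix(rnorm(50 * 30), 50, 30,
                         dimnames = list(paste0("c", 1:50),
                                         paste0("g", 1:30))))
  e <- run_pca(x, 10)
  sv <- svd(x)
  for (j in 1:10) {
    ref <- sv$u[, j] * sv$d[j]
    sgn <- sign(sum(ref * e$scores[, j]))
    expect_lt(max(abs(e$scores[, j] - sgn * ref)), 1e-6)
  }
  g <- crossprod(e$loadings)
  expect_lt(max(abs(g - diag(10))), 1e-8)
  expect_true(all(diff(e$variance_explained) <= 1e-12))
})

test_that("rank-1 data put all variance on PC1 and rank errors are explicit", {
  z <- seq(-2, 2, length.out = 20)
  x <- cbind(g1 = z, g2 = 2 * z)
  rownames(x) <- paste0("c", 1:20)
  e <- run_pca(x, 1)
  expect_equal(e$variance_explained[1], 1, tolerance = 1e-12)
  expect_error(run_pca(x, 2), "rank")
})

test_that("loading sign convention makes PCA deterministic", {
  set.seed(8)
  x <- scale_clip(matrix(rnorm(40 * 12), 40, 12,
                         dimnames = list(paste0("c", 1:40),
                                         paste0("g", 1:12))))
  e <- run_pca(x, 5)
  for (j in 1:5)
    expect_gt(e$loadings[which.max(abs(e$loadings[, j])), j], 0)
})

test_that("snn_cluster separates two well-separated blobs and is deterministic", {
  set.seed(10)
  n <- 80
  # neighborhoods must span a fair share of each blob, or modularity will
  # find spatial substructure inside a blob
  sc <- rbind(matrix(rnorm(n * 2), n, 2),
              matrix(rnorm(n * 2, mean = 10), n, 2))
  rownames(sc) <- paste0("c", seq_len(2 * n))
  emb <- structure(list(scores = sc, loadings = diag(2),
                        variance_explained = c(0.6, 0.4), n_dims = 2),
                   class = "embedding")
  lab <- snn_cluster(emb, k = 30, resolution = 0.5, seed = 3)
  expect_equal(length(unique(lab)), 2L)
  expect_equal(length(unique(lab[1:n])), 1L)
  expect_equal(length(unique(lab[(n + 1):(2 * n)])), 1L)
  expect_identical(lab, snn_cluster(emb, k = 30, resolution = 0.5, seed = 3))
  expect_error(snn_cluster(emb, k = 500), "below the number of cells")
})

test_that("clustering recovers the planted clusters and commutes with cell permutation", {
  fx <- small_fixture()
  host <- subset_cells(fx$m, genes = fx$m$gene_origin == "host")
  norm <- lognormalize(host)
  emb <- run_pca(scale_clip(norm[, select_hvg(norm, 150)]), 15)
  lab <- snn_cluster(emb, resolution = 0.5, seed = 2)
  expect_gte(mclust::adjustedRandIndex(lab, fx$truth$cluster), 0.9)

  set.seed(99)
  perm <- sample(nrow(emb$scores))
  emb_p <- emb
  emb_p$scores <- emb$scores[perm, , drop = FALSE]
  lab_p <- snn_cluster(emb_p, resolution = 0.5, seed = 2)
  expect_gte(mclust::adjustedRandIndex(lab_p, lab[perm]), 0.999)
})

test_that("find_markers flags an exclusively expressed gene and drops flat genes", {
  set.seed(6)
  n <- 60
  counts <- matrix(rpois(n * 20, 3), n, 20)
  counts[, 20] <- 3                         # identical across clusters
  counts[1:30, 19] <- rpois(30, 25)         # cluster-1-only gene
  counts[31:60, 19] <- 0
  m <- count_matrix(counts, sprintf("c%02d", 1:n), sprintf("g%02d", 1:20),
                    rep("host", 20))
  norm <- lognormalize(m)
  res <- find_markers(norm, rep(c(1, 2), each = 30))
  top1 <- res[res$cluster == 1, ][1, ]
  expect_equal(top1$gene_id, "g19")
  expect_lt(top1$p_adj, 0.05)
  expect_false("g20" %in% res$gene_id)
})

test_that("marker Wilcoxon matches the wilcox.test oracle", {
  set.seed(7)
  x <- matrix(rnorm(40 * 8), 40, 8)
  x[, 5] <- round(x[, 5])                   # introduce ties
  g <- rep(c(TRUE, FALSE), each = 20)
  mine <- symbiocell:::.rank_sum_matrix(x, g)
  for (j in c(1, 5, 8)) {
    o <- wilcox.test(x[g, j], x[!g, j], exact = FALSE, correct = FALSE)
    expect_equal(mine$U[j], unname(o$statistic), tolerance = 1e-12)
    expect_equal(mine$p[j], o$p.value, tolerance = 1e-12)
  }
})

test_that("marker p-values are uniform under a label-permutation null", {
  set.seed(12)
  x <- matrix(rnorm(100 * 2000), 100, 2000)
  g <- sample(rep(c(TRUE, FALSE), each = 50))
  p <- symbiocell:::.rank_sum_matrix(x, g)$p
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("planted cluster markers are recovered for every cluster", {
  fx <- small_fixture()
  host <- subset_cells(fx$m, genes = fx$m$gene_origin == "host")
  norm <- lognormalize(host)
  res <- find_markers(norm, fx$truth$cluster)
  for (k in 1:3) {
    planted <- fx$sim$genes$gene_id[fx$sim$genes$geneset ==
                                      sprintf("cluster%d", k)]
    found <- res$gene_id[res$cluster == k & res$p_adj < 0.05 &
                           res$avg_log2fc > 0]
    expect_gt(mean(planted %in% found), 0.8)
  }
})
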