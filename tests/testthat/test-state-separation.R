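test_that("pc_state_anova matches the closed-form one-way ANOVA", {
  scores <- cbind(PC1 = c(1, 2, 3, 7, 8, 9))
  rownames(scores) <- paste0("c", 1:6)
  emb <- structure(list(scores = scores, loadings = diag(1),
                        variance_explained = 1, n_dims = 1),
                   class = "embedding")
  states <- rep(c("symbiotic", "aposymbiotic"), each = 3)
  res <- pc_state_anova(emb, states, n_pcs = 1)
  # closed form: SSB = 54, SSW = 4 on (1, 4) df
  expect_equal(res$F, 54, tolerance = 1e-10)
  expect_equal(res$p, pf(54, 1, 4, lower.tail = FALSE), tolerance = 1e-10)
  expect_true(res$significant)
  expect_equal(res$p, 0.0018, tolerance = 0.02)
})

test_that("identical score distributions give F = 0 and errors are explicit", {
  scores <- cbind(PC1 = c(1, 2, 3, 1, 2, 3))
  rownames(scores) <- paste0("c", 1:6)
  emb <- structure(list(scores = scores, loadings = diag(1),
                        variance_explained = 1, n_dims = 1),
                   class = "embedding")
  states <- rep(c("s", "a"), each = 3)
  res <- pc_state_anova(emb, states, n_pcs = 1)
  expect_equal(res$F, 0)
  expect_false(res$significant)
  expect_error(pc_state_anova(emb, rep("s", 6)), "two states")
  expect_error(pc_state_anova(emb, c("s", rep("a", 5))), "at least 2 cells")
})

test_that("top_loading_genes returns k per direction ordered by |loading|", {
  l <- cbind(PC1 = c(a = 0.9, b = -0.8, c = 0.1, d = -0.05))
  emb <- toy_embedding(l)
  res <- top_loading_genes(emb, 1, k = 1)
  expect_identical(res$gene_id, c("a", "b"))
  expect_identical(res$direction, c("+", "-"))
  expect_equal(res$loading, c(0.9, -0.8))

  w <- capture_warnings(res5 <- top_loading_genes(emb, 1, k = 10))
  expect_match(w, "returning all", all = TRUE)
  expect_length(w, 2)   # one per direction
  expect_equal(nrow(res5), 4L)
  expect_error(top_loading_genes(emb, 3), "1..")
})

test_that("reclustering subsets the requested cluster and reproduces under a seed", {
  fx <- small_fixture()
  rec <- recluster_subset(fx$m, fx$truth$cluster, 1, n_dims = 15,
                          hvg_n = 150, seed = 4)
  expect_setequal(rec$cells,
                  fx$m$cell_ids[fx$truth$cluster == 1])
  rec2 <- recluster_subset(fx$m, fx$truth$cluster, 1, n_dims = 15,
                           hvg_n = 150, seed = 4)
  expect_identical(rec$subclusters, rec2$subclusters)
  expect_error(recluster_subset(fx$m, fx$truth$cluster, 1, k = 1000),
               "at least")
})

test_that("the effect cluster yields a nearly state-pure subcluster", {
  fx <- small_fixture()
  rec <- recluster_subset(fx$m, fx$truth$cluster,
                          fx$sim$config$effect_cluster_id,
                          n_dims = 15, hvg_n = 150, resolution = 0.4,
                          seed = 4)
  st <- fx$truth$state[fx$truth$cluster == fx$sim$config$effect_cluster_id]
  purity <- vapply(split(st, rec$subclusters),
                   function(s) max(table(s)) / length(s), numeric(1))
  expect_gte(max(purity), 0.9)
})

test_that("NB Wald DE recovers planted fold changes with the right sign", {
  fx <- small_fixture()
  eff <- fx$truth$cluster == fx$sim$config$effect_cluster_id
  de <- de_between_states(fx$m, fx$truth$state, cells = which(eff))
  imm <- fx$sim$genes$gene_id[fx$sim$genes$geneset == "immune"]
  lfc <- de$log2fc[match(imm, de$gene_id)]
  expect_gte(mean(lfc < 0), 0.95)
  expect_gte(mean(imm %in% de$gene_id[de$p_adj < 0.05]), 0.8)
  # planted magnitude roughly recovered (lfc = -1.5)
  expect_lt(abs(median(lfc) - (-1.5)), 0.4)
})

test_that("the null cluster shows no differential expression", {
  fx <- small_fixture()
  nul <- fx$truth$cluster == fx$sim$config$null_cluster_id
  de <- de_between_states(fx$m, fx$truth$state, cells = which(nul))
  expect_equal(sum(de$p_adj < 0.05), 0L)
  expect_lte(mean(de$p < 0.05), 0.08)  # raw p near nominal
})

test_that("a single gene with equal counts in both states is null", {
  counts <- cbind(g1 = rep(5, 8), g2 = rep(3, 8))
  m <- count_matrix(counts, paste0("c", 1:8), c("g1", "g2"), rep("host", 2))
  de <- de_between_states(m, rep(c("symbiotic", "aposymbiotic"), each = 4))
  expect_equal(de$log2fc, c(0, 0))
  expect_equal(de$p, c(1, 1))
})

test_that("NB Wald agrees with a DESeq2 cross-check on the effect cluster", {
  suppressPackageStartupMessages(library(DESeq2))
  fx <- small_fixture()
  eff <- which(fx$truth$cluster == fx$sim$config$effect_cluster_id)
  host <- subset_cells(fx$m, cells = eff,
                       genes = fx$m$gene_origin == "host")
  keep <- Matrix::colSums(host$counts) > 10
  host <- subset_cells(host, genes = keep)
  st <- factor(fx$truth$state[eff], levels = c("aposymbiotic", "symbiotic"))

  dds <- DESeqDataSetFromMatrix(t(as.matrix(host$counts)),
                                S4Vectors::DataFrame(state = st), ~state)
  dds <- suppressMessages(DESeq(dds, fitType = "mean", quiet = TRUE))
  ref <- results(dds)

  de <- de_between_states(host, fx$truth$state[eff])
  common <- intersect(de$gene_id, rownames(ref))
  lfc_mine <- de$log2fc[match(common, de$gene_id)]
  lfc_ref <- ref$log2FoldChange[match(common, rownames(ref))]
  expect_gt(cor(lfc_mine, lfc_ref, use = "complete.obs"), 0.9)

  # both routes recover the planted immune set
  imm <- intersect(fx$sim$genes$gene_id[fx$sim$genes$geneset == "immune"],
                   common)
  hit_ref <- imm %in% rownames(ref)[!is.na(ref$padj) & ref$padj < 0.05]
  hit_mine <- imm %in% de$gene_id[de$p_adj < 0.05]
  expect_gte(mean(hit_ref), 0.8)
  expect_gte(mean(hit_mine), 0.8)
  expect_gte(mean(hit_ref == hit_mine), 0.8)
})

test_that("wilcox alternative ranks the planted genes like the NB test", {
  fx <- small_fixture()
  eff <- fx$truth$cluster == fx$sim$config$effect_cluster_id
  de <- de_between_states(fx$m, fx$truth$state, cells = which(eff),
                          method = "wilcox")
  imm <- fx$sim$genes$gene_id[fx$sim$genes$geneset == "immune"]
  expect_gte(mean(imm %in% de$gene_id[de$p_adj < 0.05]), 0.8)
})

test_that("driver report de-duplicates genes across PCs and applies the Pfam gate", {
  l <- cbind(PC1 = c(shared = 0.9, p1 = -0.8, nopfam = 0.05, x = -0.01),
             PC2 = c(shared = 0.7, p1 = 0.01, nopfam = -0.6, x = 0.02))
  emb <- toy_embedding(l)
  anova <- data.frame(pc = 1:2, F = c(10, 10), p = c(0.01, 0.01),
                      significant = TRUE)
  de <- data.frame(gene_id = c("shared", "p1"), log2fc = c(1, -2),
                   p = c(0.001, 0.2), p_adj = c(0.01, 0.4))
  ann <- data.frame(gene_id = c("shared", "p1", "nopfam", "x"),
                    pfam = c(TRUE, TRUE, FALSE, TRUE),
                    go = c("GO:0006955", "", "", ""),
                    cog = c("", "O", "", ""))
  rep <- build_driver_report(anova, emb, de, ann, k = 1)
  # 2 PCs x k=1 per direction with one shared gene -> 3 unique drivers
  # (shared, p1, nopfam); the one without a Pfam domain is then removed
  expect_equal(rep$summary[["n_drivers"]] + rep$summary[["n_unannotated"]], 3L)
  expect_setequal(rep$drivers$gene_id, c("shared", "p1"))
  expect_equal(rep$drivers$pcs[rep$drivers$gene_id == "shared"], "1,2")
  expect_equal(rep$summary[["n_unannotated"]], 1L)
  expect_equal(rep$summary[["n_de"]], 1L)
  expect_equal(rep$summary[["n_immune"]], 1L)
  expect_equal(rep$summary[["n_chaperone"]], 1L)
  # containment invariants
  expect_true(all(rep$drivers$gene_id[rep$drivers$de] %in%
                    rep$drivers$gene_id))
  expect_true(all(rep$drivers$gene_id[rep$drivers$immune_go] %in%
                    rep$drivers$gene_id))
})

test_that("no significant PCs yields an empty report with per-PC stats retained", {
  emb <- toy_embedding(cbind(PC1 = c(a = 0.9, b = -0.8)))
  anova <- data.frame(pc = 1, F = 0.1, p = 0.9, significant = FALSE)
  de <- data.frame(gene_id = character(), log2fc = numeric(),
                   p = numeric(), p_adj = numeric())
  ann <- data.frame(gene_id = c("a", "b"), pfam = TRUE, go = "", cog = "")
  rep <- build_driver_report(anova, emb, de, ann)
  expect_equal(nrow(rep$drivers), 0L)
  expect_equal(rep$summary[["n_significant_pcs"]], 0L)
  expect_identical(rep$anova, anova)
})

test_that("effect cluster is flagged and null cluster is not, end to end", {
  fx <- small_fixture()
  cfg <- fx$sim$config
  ann <- fx$sim$genes[, c("gene_id", "pfam", "go", "cog")]
  run_one <- function(cl) {
    rec <- recluster_subset(fx$m, fx$truth$cluster, cl, n_dims = 15,
                            hvg_n = 150, seed = 2)
    st <- fx$truth$state[fx$truth$cluster == cl]
    an <- pc_state_anova(rec$embedding, st)
    de <- de_between_states(fx$m, fx$truth$state,
                            cells = which(fx$truth$cluster == cl))
    build_driver_report(an, rec$embedding, de, ann)
  }
  eff <- run_one(cfg$effect_cluster_id)
  expect_gte(eff$summary[["n_significant_pcs"]], 1)
  expect_gte(sum(eff$drivers$de & eff$drivers$immune_go), 5)

  nul <- run_one(cfg$null_cluster_id)
  flagged <- nul$summary[["n_significant_pcs"]] >= 1 &&
    sum(nul$drivers$de & nul$drivers$immune_go) >= 5
  expect_false(flagged)
})
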