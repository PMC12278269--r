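# Small, fast study-shaped fixture shared across test files: 3 clusters
# (effect = 1, null = 2, hosting = 3), 400 host + 60 symbiont genes.
small_config <- function(seed = 1L, ...) {
  args <- list(n_cells_per_state = 300,
               n_host_genes = 400, n_symbiont_genes = 60,
               n_clusters = 3,
               hosting_cluster_id = 3, effect_cluster_id = 1,
               null_cluster_id = 2,
               cluster_marker_size = 25,
               immune_geneset_size = 30, marker_geneset_size = 6,
               library_size_log_mean = log(1500),
               seed = seed)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

# memoised default small dataset (doublets removed, truth aligned)
.fixture_env <- new.env(parent = emptyenv())
small_fixture <- function() {
  if (is.null(.fixture_env$fx)) {
    ds <- generate_dataset(small_config())
    m <- remove_flagged_doublets(ds$matrix, ds$cells$is_doublet)
    truth <- ds$cells[match(m$cell_ids, ds$cells$barcode), ]
    .fixture_env$fx <- list(sim = ds, m = m, truth = truth)
  }
  .fixture_env$fx
}

# hand-built embedding for loading-level tests
toy_embedding <- function(loadings, scores = NULL) {
  if (is.null(scores))
    scores <- matrix(0, 2, ncol(loadings),
                     dimnames = list(c("c1", "c2"),
                                     colnames(loadings)))
  structure(list(scores = scores, loadings = loadings,
                 variance_explained = rep(0, ncol(loadings)),
                 n_dims = ncol(loadings)),
            class = "embedding")
}
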