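#' Recluster one cell cluster independently
#'
#' Subsets the cells of one cluster, re-selects variable genes on the host
#' genome, rescales, recomputes PCA, and finds subclusters on the SNN
#' graph, returning the embedding for the per-PC state ANOVA.
#'
#' @param m a [count_matrix] (dual-genome or host-only).
#' @param labels per-cell cluster labels aligned with `m`.
#' @param cluster_id the cluster to recluster.
#' @param n_dims PCs to compute (default 30; use 20 for small clusters).
#' @param resolution subcluster resolution (default 0.4; the reference
#'   range is 0.25-0.5).
#' @param hvg_n variable genes to re-select (default 2000, capped at the
#'   available host genes).
#' @param k SNN neighbors (default 20, capped below the subset size).
#' @param host_only restrict to host-genome genes before embedding
#'   (default TRUE).
#' @param seed RNG seed for the community search.
#' @return list: `embedding`, `subclusters` (named integer vector),
#'   `cells` (barcodes of the subset).
#' @export
recluster_subset <- function(m, labels, cluster_id, n_dims = 30,
                             resolution = 0.4, hvg_n = 2000, k = 20,
                             host_only = TRUE, seed = 1L) {
  stopifnot(inherits(m, "count_matrix"))
  if (length(labels) != length(m$cell_ids))
    stop("labels length does not match cells", call. = FALSE)
  sel <- labels == cluster_id
  min_size <- 2 * k
  if (sum(sel) < min_size)
    stop("cluster ", cluster_id, " has ", sum(sel),
         " cells; at least ", min_size, " required", call. = FALSE)
  genes <- if (host_only) m$gene_origin == "host" else
    rep(TRUE, length(m$gene_ids))
  sub <- subset_cells(m, cells = sel, genes = genes)
  norm <- lognormalize(sub)
  hvg <- select_hvg(norm, min(hvg_n, ncol(norm)))
  scaled <- scale_clip(norm[, hvg, drop = FALSE])
  nd <- min(n_dims, nrow(scaled) - 1, ncol(scaled))
  emb <- run_pca(scaled, nd)
  sc <- snn_cluster(emb, n_dims = nd, resolution = resolution,
                    k = min(k, nrow(scaled) - 1), seed = seed)
  list(embedding = emb, subclusters = sc, cells = sub$cell_ids)
}

#' Per-PC one-way ANOVA of symbiotic state
#'
#' Tests, independently for each of the first `n_pcs` principal
#' components, whether cells separate by symbiotic state along that
#' component (one-way ANOVA of PC scores on the two-level state factor).
#' Each PC is judged at `alpha` with no multiplicity correction across
#' PCs.
#'
#' @param embedding an [run_pca()] `embedding` of the reclustered cells.
#' @param states per-cell state labels (exactly two levels, each with at
#'   least 2 cells).
#' @param n_pcs number of leading PCs to test (default 10).
#' @param alpha per-PC significance level (default 0.05).
#' @return data.frame: pc, F, p, significant.
#' @export
pc_state_anova <- function(embedding, states, n_pcs = 10, alpha = 0.05) {
  stopifnot(inherits(embedding, "embedding"))
  states <- as.factor(states)
  if (length(states) != nrow(embedding$scores))
    stop("states length does not match cells", call. = FALSE)
  if (nlevels(droplevels(states)) != 2)
    stop("exactly two states required, got ",
         nlevels(droplevels(states)), call. = FALSE)
  if (min(table(states)) < 2)
    stop("each state needs at least 2 cells", call. = FALSE)
  n_pcs <- min(n_pcs, embedding$n_dims)
  rows <- lapply(seq_len(n_pcs), function(j) {
    a <- stats::anova(stats::lm(embedding$scores[, j] ~ states))
    data.frame(pc = j, F = a$`F value`[1], p = a$`Pr(>F)`[1])
  })
  out <- do.call(rbind, rows)
  out$significant <- out$p < alpha
  out
}

#' Top loading genes of a principal component
#'
#' The k genes with the largest positive loadings and the k with the most
#' negative loadings on one PC — the "driver" genes of that component —
#' each ordered by decreasing |loading| with gene-id tiebreak.
#'
#' @param embedding an [run_pca()] `embedding`.
#' @param pc component index.
#' @param k genes per direction (default 10).
#' @return data.frame: gene_id, pc, direction (`+`/`-`), loading.
#' @export
top_loading_genes <- function(embedding, pc, k = 10) {
  stopifnot(inherits(embedding, "embedding"))
  if (pc < 1 || pc > embedding$n_dims)
    stop("pc must lie in 1..", embedding$n_dims, call. = FALSE)
  l <- embedding$loadings[, pc]
  ids <- rownames(embedding$loadings)
  take <- function(vals, nm, sign_lab) {
    ord <- order(-abs(vals), nm)
    n_take <- min(k, length(vals))
    if (n_take < k)
      warning("only ", length(vals), " genes with ", sign_lab,
              " loading on PC", pc, "; returning all")
    if (n_take == 0)
      return(data.frame(gene_id = character(), pc = integer(),
                        direction = character(), loading = numeric()))
    data.frame(gene_id = nm[ord][seq_len(n_take)], pc = pc,
               direction = sign_lab,
               loading = vals[ord][seq_len(n_take)],
               stringsAsFactors = FALSE)
  }
  pos <- l > 0; neg <- l < 0
  out <- rbind(take(l[pos], ids[pos], "+"), take(l[neg], ids[neg], "-"))
  rownames(out) <- NULL
  out
}

#' Differential expression between symbiotic states
#'
#' Two-group test per gene on raw counts within one cell population.
#' The default `"nb_wald"` is a minimal negative-binomial Wald test:
#' median-of-ratios size factors (geometric means over positive counts),
#' gene-wise method-of-moments dispersion floored at 1e-8, no shrinkage;
#' the log2 fold change contrasts symbiotic over aposymbiotic normalized
#' group means with a pseudocount.  `"wilcox"` tests the log-normalized
#' values instead and bounds sensitivity to the NB model.
#'
#' @param m a [count_matrix] already subset to the cells of interest (or
#'   subset via `cells`).
#' @param states per-cell state labels; the contrast is
#'   `state_test` vs `state_ref`.
#' @param cells optional index/id vector restricting `m` and `states`.
#' @param method `"nb_wald"` (default) or `"wilcox"`.
#' @param state_test,state_ref contrast levels (defaults `"symbiotic"` vs
#'   `"aposymbiotic"`).
#' @param pseudocount added to normalized group means for the fold change
#'   (default 0.1).
#' @param host_only restrict to host genes (default TRUE).
#' @return data.frame of class `de_result`: gene_id, log2fc, p, p_adj
#'   (BH), test; all-zero genes are dropped and their number attached as
#'   `attr(, "n_dropped")`.
#' @export
de_between_states <- function(m, states, cells = NULL,
                              method = c("nb_wald", "wilcox"),
                              state_test = "symbiotic",
                              state_ref = "aposymbiotic",
                              pseudocount = 0.1, host_only = TRUE) {
  stopifnot(inherits(m, "count_matrix"))
  method <- match.arg(method)
  if (!is.null(cells)) {
    idx <- .resolve_idx(cells, m$cell_ids, "cell")
    m <- subset_cells(m, cells = idx)
    if (length(states) != length(idx)) states <- states[idx]
  }
  if (length(states) != length(m$cell_ids))
    stop("states length does not match cells", call. = FALSE)
  if (host_only) m <- subset_cells(m, genes = m$gene_origin == "host")
  g1 <- states == state_test
  g2 <- states == state_ref
  if (sum(g1) < 3 || sum(g2) < 3)
    stop("need at least 3 cells per state (", sum(g1), " vs ", sum(g2),
         ")", call. = FALSE)
  m <- subset_cells(m, cells = g1 | g2)
  g1 <- g1[g1 | g2]

  counts <- m$counts
  nz <- Matrix::colSums(counts) > 0
  n_dropped <- sum(!nz)
  counts <- counts[, nz, drop = FALSE]
  gene_ids <- m$gene_ids[nz]

  if (method == "wilcox") {
    norm <- lognormalize(count_matrix(counts, m$cell_ids, gene_ids,
                                      m$gene_origin[nz]))
    expm1_mat <- norm
    expm1_mat@x <- expm1(expm1_mat@x)
    mu1 <- Matrix::colMeans(expm1_mat[g1, , drop = FALSE])
    mu2 <- Matrix::colMeans(expm1_mat[!g1, , drop = FALSE])
    lfc <- log2(mu1 + 1) - log2(mu2 + 1)
    w <- .rank_sum_matrix(as.matrix(norm), g1)
    out <- data.frame(gene_id = gene_ids, log2fc = lfc, p = w$p,
                      stringsAsFactors = FALSE)
  } else {
    sf <- .size_factors(counts)
    y <- Matrix::Diagonal(x = 1 / sf) %*% counts
    mu <- Matrix::colMeans(y)
    v <- (Matrix::colMeans(y^2) - mu^2) * nrow(y) / (nrow(y) - 1)
    mean_inv_sf <- mean(1 / sf)
    alpha <- pmax((v - mu * mean_inv_sf) / mu^2, 1e-8)
    q1 <- Matrix::colMeans(y[g1, , drop = FALSE])
    q2 <- Matrix::colMeans(y[!g1, , drop = FALSE])
    lfc <- log2(q1 + pseudocount) - log2(q2 + pseudocount)
    var_q <- function(q, grp) {
      qv <- pmax(q, pseudocount)
      (qv * sum(1 / sf[grp]) + alpha * qv^2 * sum(grp)) / sum(grp)^2
    }
    se2 <- var_q(q1, g1) / ((q1 + pseudocount)^2) +
      var_q(q2, !g1) / ((q2 + pseudocount)^2)
    z <- (lfc * log(2)) / sqrt(se2)
    p <- pmin(1, 2 * stats::pnorm(-abs(z)))
    out <- data.frame(gene_id = gene_ids, log2fc = lfc, p = p,
                      stringsAsFactors = FALSE)
  }
  out$p_adj <- stats::p.adjust(out$p, "BH")
  out$test <- method
  out <- out[order(out$p, out$gene_id), ]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  class(out) <- c("de_result", "data.frame")
  out
}

# median-of-ratios size factors robust to zeros: geometric means over
# positive counts; per-cell median ratio over that cell's positive genes
.size_factors <- function(counts) {
  n <- nrow(counts)
  npos <- Matrix::colSums(counts > 0)
  lg <- counts
  lg@x <- log(lg@x)
  geo <- exp(Matrix::colSums(lg) / pmax(npos, 1))
  tm <- methods::as(counts, "TsparseMatrix")
  ratios <- tm@x / geo[tm@j + 1L]
  rows <- factor(tm@i + 1L, levels = seq_len(n))
  sf <- vapply(split(ratios, rows), function(v)
    if (length(v)) stats::median(v) else NA_real_, numeric(1))
  if (anyNA(sf)) stop("cells with no counts; cannot size-factor",
                      call. = FALSE)
  unname(sf / exp(mean(log(sf))))
}

#' Assemble the driver-gene report for one cluster
#'
#' Combines the per-PC ANOVA, the top-loading driver genes of every
#' significant PC, the state differential-expression results and the gene
#' annotations into the cluster's state-separation report: the union of
#' drivers over significant PCs (a gene driving several PCs appears once,
#' all PCs listed), with genes lacking a Pfam annotation removed, DE
#' status joined at `de_alpha`, and immune-GO / COG-chaperone tags.
#'
#' @param anova output of [pc_state_anova()].
#' @param embedding the same cluster's [run_pca()] `embedding`.
#' @param de a `de_result` from [de_between_states()].
#' @param annotations data.frame with columns `gene_id`, `pfam` (logical),
#'   `go` (";"-separated term string) and `cog` (one-letter category).
#' @param k drivers per direction per PC (default 10).
#' @param de_alpha adjusted-p cutoff for DE status (default 0.05).
#' @param immune_terms GO ids counted as immune
#'   (default [immune_go_terms]).
#' @param chaperone_cog COG category counted as chaperone-related
#'   (default [cog_chaperone_label]).
#' @return An object of class `pc_separation_report`: list with `anova`,
#'   `drivers` (one row per retained driver gene), `summary` (named
#'   counts: significant PCs, drivers, DE drivers, immune-tagged,
#'   chaperone-tagged, removed for missing Pfam).
#' @export
build_driver_report <- function(anova, embedding, de, annotations,
                                k = 10, de_alpha = 0.05,
                                immune_terms = immune_go_terms,
                                chaperone_cog = cog_chaperone_label) {
  stopifnot(all(c("pc", "p", "significant") %in% names(anova)),
            inherits(embedding, "embedding"),
            all(c("gene_id", "pfam", "go", "cog") %in% names(annotations)))
  sig <- anova$pc[anova$significant]
  empty <- data.frame(gene_id = character(), pcs = character(),
                      direction = character(), loading = numeric(),
                      de = logical(), log2fc = numeric(),
                      immune_go = logical(), cog_chaperone = logical(),
                      stringsAsFactors = FALSE)
  if (!length(sig)) {
    return(structure(list(anova = anova, drivers = empty,
                          summary = c(n_significant_pcs = 0L, n_drivers = 0L,
                                      n_de = 0L, n_immune = 0L,
                                      n_chaperone = 0L, n_unannotated = 0L)),
                     class = "pc_separation_report"))
  }
  per_pc <- do.call(rbind, lapply(sig, function(pc)
    top_loading_genes(embedding, pc, k)))
  agg <- split(per_pc, per_pc$gene_id)
  drivers <- do.call(rbind, lapply(agg, function(d) {
    best <- which.max(abs(d$loading))
    data.frame(gene_id = d$gene_id[1],
               pcs = paste(sort(unique(d$pc)), collapse = ","),
               direction = d$direction[best], loading = d$loading[best],
               stringsAsFactors = FALSE)
  }))

  ann <- annotations[match(drivers$gene_id, annotations$gene_id), ]
  pfam_ok <- !is.na(ann$gene_id) & ann$pfam
  n_unannotated <- sum(!pfam_ok)
  drivers <- drivers[pfam_ok, , drop = FALSE]
  ann <- ann[pfam_ok, , drop = FALSE]

  de_hit <- de$gene_id[de$p_adj < de_alpha]
  drivers$de <- drivers$gene_id %in% de_hit
  drivers$log2fc <- de$log2fc[match(drivers$gene_id, de$gene_id)]
  go_lists <- strsplit(ifelse(is.na(ann$go), "", ann$go), ";", fixed = TRUE)
  drivers$immune_go <- vapply(go_lists,
                              function(g) any(g %in% immune_terms),
                              logical(1))
  drivers$cog_chaperone <- !is.na(ann$cog) & ann$cog %in% chaperone_cog
  drivers <- drivers[order(-abs(drivers$loading), drivers$gene_id), ]
  rownames(drivers) <- NULL

  structure(list(
    anova = anova, drivers = drivers,
    summary = c(n_significant_pcs = length(sig),
                n_drivers = nrow(drivers),
                n_de = sum(drivers$de),
                n_immune = sum(drivers$immune_go),
                n_chaperone = sum(drivers$cog_chaperone),
                n_unannotated = n_unannotated)),
    class = "pc_separation_report")
}

#' @export
print.pc_separation_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0(
    "pc_separation_report: %d significant PC(s), %d driver genes ",
    "(%d DE, %d immune-tagged, %d chaperone-tagged; %d removed for ",
    "missing Pfam)\n"),
    s["n_significant_pcs"], s["n_drivers"], s["n_de"], s["n_immune"],
    s["n_chaperone"], s["n_unannotated"]))
  invisible(x)
}
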