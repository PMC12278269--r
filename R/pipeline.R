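#' Default pipeline configuration
#'
#' Returns the full run configuration as a nested list; every default is
#' the reference analysis value (QC 3/200/3000, 30 dims at resolution
#' 0.55, symbiont threshold 0.5, gene-set threshold 0.045, per-PC alpha
#' 0.05, DE adjusted-p 0.05, GO FDR 0.1).  Pass overrides as a nested list
#' or a YAML file to [run_pipeline()].
#'
#' @param seed global seed; per-stage seeds derive from it by stable
#'   hashing of the stage name, so adding a stage never perturbs earlier
#'   ones.
#' @return Nested configuration list of class `run_config`.
#' @export
default_run_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    simulate = list(),            # sim_config() overrides; NULL disables
    input = NULL,                 # list(mtx=, features=, barcodes=, cells=)
    qc = list(min_cells_per_gene = 3, min_genes_per_cell = 200,
              max_genes_per_cell = 3000),
    thresholds = list(symbiont = 0.5, geneset = 0.045, alpha = 0.05,
                      de_alpha = 0.05, go_fdr = 0.1),
    cluster = list(n_dims = 30, resolution = 0.55, k = 20, hvg_n = 2000),
    subset = list(n_dims = 30, resolution = 0.4, k = 20),
    marker_trio = NULL,           # gene ids; NULL = planted nutrient trio
    ortholog_table = NULL,        # TSV path: gene_a, orthogroup, gene_b
    de_genes_b = NULL,            # TSV path: DE gene ids of species B
    term_map = NULL               # TSV path: orthogroup, term
  ), class = "run_config")
}

.stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

.merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- .merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order — input or simulation, doublet removal and
#' QC, symbiont partition, embedding and clustering, immune gene-set
#' scoring and GO enrichment, per-cluster state separation, marker-trio
#' co-expression, and (when an ortholog table is supplied) the
#' cross-species DEO comparison — writing every table as TSV and a JSON
#' manifest that records the seed, parameters and per-stage row counts.
#'
#' @param config a `run_config` list from [default_run_config()], a nested
#'   override list, or the path to a YAML file of overrides.
#' @param out_dir output directory (created if absent).
#' @return The output directory path, invisibly; the manifest is
#'   `manifest.json` inside it.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  if (!inherits(config, "run_config"))
    config <- .merge_config(default_run_config(), config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  manifest <- list(package = "symbiocell",
                   version = as.character(utils::packageVersion("symbiocell")),
                   seed = config$seed, parameters = config[
                     c("qc", "thresholds", "cluster", "subset")],
                   stages = list())
  note <- function(stage, ...) {
    manifest$stages[[stage]] <<- list(...)
  }

  # --- input -----------------------------------------------------------
  if (!is.null(config$input)) {
    m <- read_matrix(config$input$mtx, config$input$features,
                     config$input$barcodes)
    cells <- utils::read.delim(config$input$cells, stringsAsFactors = FALSE)
    genes <- attr(m, "features")
    sim <- NULL
  } else {
    sim_args <- config$simulate
    sim_args$seed <- .stage_seed(config$seed, "simulate")
    sim <- generate_dataset(do.call(sim_config, sim_args))
    m <- sim$matrix
    cells <- sim$cells
    genes <- sim$genes
  }
  note("input", n_cells = nrow(m$counts), n_genes = ncol(m$counts))

  # --- doublet removal + QC -------------------------------------------
  if (!is.null(cells$is_doublet)) {
    flags <- cells$is_doublet[match(m$cell_ids, cells$barcode)]
    m <- remove_flagged_doublets(m, flags)
  }
  qc <- qc_filter(m, config$qc$min_cells_per_gene,
                  config$qc$min_genes_per_cell, config$qc$max_genes_per_cell)
  m <- qc$matrix
  cells <- cells[match(m$cell_ids, cells$barcode), ]
  note("qc", genes_removed = qc$report$genes_removed,
       cells_removed = qc$report$cells_removed,
       cells_out = qc$report$cells_out)

  # --- symbiont partition ---------------------------------------------
  fr <- symbiont_fraction(m)
  hosting <- classify_hosting(fr, config$thresholds$symbiont)
  note("symbiont_partition", n_hosting = attr(hosting, "n_hosting"))

  # --- embed + cluster (host genes) -----------------------------------
  host <- subset_cells(m, genes = m$gene_origin == "host")
  norm <- lognormalize(host)
  hvg <- select_hvg(norm, min(config$cluster$hvg_n, ncol(norm)))
  scaled <- scale_clip(norm[, hvg, drop = FALSE])
  nd <- min(config$cluster$n_dims, nrow(scaled) - 1, ncol(scaled))
  emb <- run_pca(scaled, nd)
  labels <- snn_cluster(emb, n_dims = nd,
                        resolution = config$cluster$resolution,
                        k = config$cluster$k,
                        seed = .stage_seed(config$seed, "cluster"))
  host_cl <- assign_hosting_cluster(hosting, labels)
  .write_tsv(data.frame(barcode = m$cell_ids, symbiont_fraction = fr,
                        is_hosting = as.logical(hosting), cluster = labels,
                        state = cells$state),
             file.path(out_dir, "cells.tsv"))
  note("cluster", n_clusters = length(unique(labels)),
       hosting_cluster = host_cl$cluster_id,
       n_hosting_in_cluster = host_cl$n_hosting_in_cluster)

  # --- immune gene-set scoring ----------------------------------------
  go_lists <- strsplit(ifelse(is.na(genes$go), "", genes$go), ";",
                       fixed = TRUE)
  immune_set <- genes$gene_id[vapply(go_lists, function(g)
    any(g %in% immune_go_terms), logical(1))]
  if (length(intersect(immune_set, host$gene_ids))) {
    gs_fr <- cell_geneset_fraction(host, immune_set)
    flagged <- flag_cells(gs_fr, config$thresholds$geneset)
    .write_tsv(data.frame(barcode = host$cell_ids,
                          immune_fraction = gs_fr,
                          flagged = as.logical(flagged)),
               file.path(out_dir, "geneset_fractions.tsv"))
    note("geneset_scoring", n_flagged = attr(flagged, "n_flagged"))
  }

  # --- whole-dataset DE + MWU GO enrichment ---------------------------
  de_all <- de_between_states(m, cells$state)
  scores <- -log10(pmax(de_all$p, 1e-300)) * sign(de_all$log2fc)
  names(scores) <- de_all$gene_id
  tm <- data.frame(gene_id = rep(genes$gene_id, lengths(go_lists)),
                   term = unlist(go_lists), stringsAsFactors = FALSE)
  tm <- tm[tm$term != "", ]
  go_res <- tryCatch(
    mwu_go_enrichment(scores, tm, fdr = config$thresholds$go_fdr),
    error = function(e) NULL)
  if (!is.null(go_res))
    .write_tsv(go_res, file.path(out_dir, "go_enrichment.tsv"))
  note("go_enrichment",
       n_significant = if (is.null(go_res)) 0L else sum(go_res$significant))

  # --- per-cluster state separation -----------------------------------
  ann <- data.frame(gene_id = genes$gene_id, pfam = genes$pfam,
                    go = genes$go, cog = genes$cog,
                    stringsAsFactors = FALSE)
  reports <- list()
  for (cl in sort(unique(labels))) {
    in_cl <- labels == cl
    st <- cells$state[in_cl]
    if (sum(in_cl) < 2 * config$subset$k ||
        min(table(st)) < 3 || length(unique(st)) < 2) next
    rec <- recluster_subset(m, labels, cl,
                            n_dims = config$subset$n_dims,
                            resolution = config$subset$resolution,
                            k = config$subset$k,
                            seed = .stage_seed(config$seed,
                                               paste0("subset", cl)))
    an <- pc_state_anova(rec$embedding, st,
                         alpha = config$thresholds$alpha)
    de <- de_between_states(m, cells$state, cells = which(in_cl))
    rep <- build_driver_report(an, rec$embedding, de, ann,
                               de_alpha = config$thresholds$de_alpha)
    reports[[as.character(cl)]] <- rep
    if (nrow(rep$drivers))
      .write_tsv(rep$drivers,
                 file.path(out_dir, sprintf("drivers_cluster%s.tsv", cl)))
    .write_tsv(rep$anova,
               file.path(out_dir, sprintf("pc_anova_cluster%s.tsv", cl)))
  }
  note("state_separation",
       clusters_tested = length(reports),
       summaries = lapply(reports, function(r) as.list(r$summary)))

  # --- marker-trio co-expression --------------------------------------
  trio <- config$marker_trio
  if (is.null(trio) && !is.null(sim))
    trio <- utils::head(genes$gene_id[genes$geneset == "nutrient"], 3)
  if (!is.null(trio) && all(trio %in% colnames(norm))) {
    co <- coexpression_score(norm, trio)
    .write_tsv(co, file.path(out_dir, "coexpression.tsv"))
    note("coexpression", genes = trio)
  }

  # --- cross-species DEO comparison (optional) ------------------------
  if (!is.null(config$ortholog_table) && !is.null(config$de_genes_b) &&
      !is.null(config$term_map)) {
    ot <- utils::read.delim(config$ortholog_table, stringsAsFactors = FALSE)
    de_b <- utils::read.delim(config$de_genes_b,
                              stringsAsFactors = FALSE)[[1]]
    tm2 <- utils::read.delim(config$term_map, stringsAsFactors = FALSE)
    de_a <- de_all$gene_id[de_all$p_adj < config$thresholds$de_alpha]
    og_a <- map_orthologs(de_a, ot, "A")
    og_b <- map_orthologs(de_b, ot, "B")
    bg <- sort(unique(ot$orthogroup))
    part <- venn_partition(og_a, og_b, bg)
    enr <- lapply(list(shared = part$shared, unique_a = part$unique_a,
                       unique_b = part$unique_b), function(g)
      if (length(g)) tryCatch(
        fisher_enrichment(g, bg, tm2, fdr = config$thresholds$go_fdr),
        error = function(e) NULL))
    for (nm in names(enr))
      if (!is.null(enr[[nm]]))
        .write_tsv(enr[[nm]],
                   file.path(out_dir, sprintf("deo_enrichment_%s.tsv", nm)))
    note("cross_species", sizes = as.list(part$sizes))
  } else {
    note("cross_species", skipped = "no ortholog table configured")
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
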