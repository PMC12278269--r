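#' Read a 10x-style sparse count matrix
#'
#' Reads a MatrixMarket coordinate file (features x barcodes, 1-based
#' indices, the CellRanger layout) together with its features and barcodes
#' tables, and returns the transposed cells x genes [count_matrix].
#'
#' The features file must be a tab-separated table with at least columns
#' `gene_id` and `origin` (values `host`/`symbiont`); extra annotation
#' columns are preserved as the `features` attribute.  The barcodes file is
#' a single column of barcodes with no header.
#'
#' @param mtx_path path to the MatrixMarket `.mtx` file.
#' @param features_path path to the features TSV (header required).
#' @param barcodes_path path to the barcodes TSV (no header).
#' @return A [count_matrix]; the full features table is attached as
#'   `attr(, "features")`.
#' @export
read_matrix <- function(mtx_path, features_path, barcodes_path) {
  for (p in c(mtx_path, features_path, barcodes_path))
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  mm <- Matrix::readMM(mtx_path)
  feats <- utils::read.delim(features_path, header = TRUE,
                             stringsAsFactors = FALSE, check.names = FALSE)
  if (!"gene_id" %in% names(feats))
    stop("features file lacks required column 'gene_id'", call. = FALSE)
  if (!"origin" %in% names(feats))
    stop("features file lacks required column 'origin'", call. = FALSE)
  barcodes <- utils::read.delim(barcodes_path, header = FALSE,
                                stringsAsFactors = FALSE)[[1]]
  if (nrow(mm) != nrow(feats))
    stop("matrix has ", nrow(mm), " features but features file has ",
         nrow(feats), call. = FALSE)
  if (ncol(mm) != length(barcodes))
    stop("matrix has ", ncol(mm), " barcodes but barcodes file has ",
         length(barcodes), call. = FALSE)
  x <- if (methods::is(mm, "sparseMatrix")) mm@x else as.numeric(mm)
  if (length(x) && any(x != floor(x)))
    stop("matrix contains non-integer values", call. = FALSE)
  m <- count_matrix(Matrix::t(mm), barcodes, feats$gene_id, feats$origin)
  attr(m, "features") <- feats
  m
}

#' Write a count matrix in 10x-style layout
#'
#' Inverse of [read_matrix()]: writes `matrix.mtx` (features x barcodes),
#' `features.tsv` and `barcodes.tsv` into `directory`.
#'
#' @param m a [count_matrix].
#' @param directory output directory (created if absent).
#' @param features optional data.frame of per-gene annotations to write in
#'   place of the minimal `gene_id`/`origin` table; must contain those two
#'   columns and one row per gene in `m`'s order.
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_matrix <- function(m, directory, features = NULL) {
  stopifnot(inherits(m, "count_matrix"))
  if (nrow(m$counts) == 0L || ncol(m$counts) == 0L)
    stop("refusing to write an empty matrix (0 cells or 0 genes)",
         call. = FALSE)
  if (!dir.exists(directory))
    if (!dir.create(directory, recursive = TRUE))
      stop("cannot create directory: ", directory, call. = FALSE)
  if (is.null(features)) {
    features <- data.frame(gene_id = m$gene_ids, origin = m$gene_origin,
                           stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("gene_id", "origin") %in% names(features)),
              nrow(features) == length(m$gene_ids),
              identical(as.character(features$gene_id), m$gene_ids))
  }
  paths <- c(mtx = file.path(directory, "matrix.mtx"),
             features = file.path(directory, "features.tsv"),
             barcodes = file.path(directory, "barcodes.tsv"))
  Matrix::writeMM(Matrix::t(m$counts), paths[["mtx"]])
  utils::write.table(features, paths[["features"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(m$cell_ids), paths[["barcodes"]], sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(paths)
}

#' Quality-control filtering of genes and cells
#'
#' Removes genes detected (count >= 1) in fewer than `min_cells_per_gene`
#' cells, then removes cells whose detected-gene number falls outside
#' `[min_genes_per_cell, max_genes_per_cell]`.  The gene filter is applied
#' first; detected-gene counts for the cell filter are computed on the
#' gene-filtered matrix over host and symbiont genes jointly.
#'
#' @param m a [count_matrix].
#' @param min_cells_per_gene genes detected in fewer cells are dropped
#'   (default 3).
#' @param min_genes_per_cell,max_genes_per_cell cells detecting fewer than
#'   `min` or more than `max` genes are dropped (defaults 200 and 3000).
#' @param gene_filter_first apply the gene filter before the cell filter
#'   within each sweep (default `TRUE`).
#' @details Because removing cells can push a gene below the detection
#'   threshold (and vice versa), the two filters are swept repeatedly until
#'   the matrix stops changing, so the result is a fixed point and the
#'   operation is idempotent.  The first sweep removes the overwhelming
#'   majority; later sweeps usually remove nothing.
#' @return A list with `matrix` (the filtered [count_matrix]) and `report`,
#'   a one-row data.frame of removed/retained counts.
#' @export
qc_filter <- function(m, min_cells_per_gene = 3,
                      min_genes_per_cell = 200,
                      max_genes_per_cell = 3000,
                      gene_filter_first = TRUE) {
  stopifnot(inherits(m, "count_matrix"))
  if (min_genes_per_cell >= max_genes_per_cell)
    stop("min_genes_per_cell must be below max_genes_per_cell", call. = FALSE)

  filter_genes <- function(mm) {
    det <- Matrix::colSums(mm$counts > 0)
    keep <- det >= min_cells_per_gene
    list(m = subset_cells(mm, genes = keep), removed = sum(!keep))
  }
  filter_cells <- function(mm) {
    det <- Matrix::rowSums(mm$counts > 0)
    keep <- det >= min_genes_per_cell & det <= max_genes_per_cell
    if (!any(keep))
      stop("all cells removed by QC thresholds (", min_genes_per_cell, "-",
           max_genes_per_cell, " detected genes)", call. = FALSE)
    list(m = subset_cells(mm, cells = keep), removed = sum(!keep))
  }

  out <- m
  genes_removed <- 0L; cells_removed <- 0L
  repeat {
    if (gene_filter_first) {
      g <- filter_genes(out); c <- filter_cells(g$m); nxt <- c$m
    } else {
      c <- filter_cells(out); g <- filter_genes(c$m); nxt <- g$m
    }
    genes_removed <- genes_removed + g$removed
    cells_removed <- cells_removed + c$removed
    if (g$removed == 0 && c$removed == 0) break
    out <- nxt
  }
  report <- data.frame(
    genes_in = ncol(m$counts), cells_in = nrow(m$counts),
    genes_removed = genes_removed, cells_removed = cells_removed,
    genes_out = ncol(out$counts), cells_out = nrow(out$counts))
  list(matrix = out, report = report)
}

#' Remove cells flagged as doublets
#'
#' Doublet detection itself is upstream (an external caller); this drops
#' the flagged barcodes, preserving the order of the remaining cells.
#'
#' @param m a [count_matrix].
#' @param flags logical vector, one per cell, `TRUE` = doublet.
#' @return The [count_matrix] without flagged cells.
#' @export
remove_flagged_doublets <- function(m, flags) {
  stopifnot(inherits(m, "count_matrix"))
  if (!is.logical(flags) || length(flags) != length(m$cell_ids))
    stop("flags must be a logical vector with one entry per cell (",
         length(m$cell_ids), ")", call. = FALSE)
  if (anyNA(flags)) stop("flags contain NA", call. = FALSE)
  subset_cells(m, cells = !flags)
}
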