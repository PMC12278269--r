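#' Construct a dual-genome count matrix
#'
#' A `count_matrix` holds sparse cells x genes integer UMI counts from a
#' host+symbiont concatenated-genome alignment, with a genome-of-origin
#' label per gene.  It is the container every downstream stage consumes.
#'
#' @param counts cells x genes matrix (coerced to [Matrix::dgCMatrix-class])
#'   of nonnegative integers.
#' @param cell_ids character vector of unique cell barcodes (rows).
#' @param gene_ids character vector of unique gene identifiers (columns).
#' @param gene_origin per-gene genome of origin, `"host"` or `"symbiont"`.
#'
#' @return An object of class `count_matrix`: a list with elements
#'   `counts` (dgCMatrix, dimnames set), `cell_ids`, `gene_ids`,
#'   `gene_origin`.
#' @export
count_matrix <- function(counts, cell_ids, gene_ids, gene_origin) {
  if (is.matrix(counts)) counts <- Matrix::Matrix(counts, sparse = TRUE)
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  cell_ids <- as.character(cell_ids)
  gene_ids <- as.character(gene_ids)
  gene_origin <- as.character(gene_origin)
  if (nrow(counts) != length(cell_ids))
    stop("counts has ", nrow(counts), " rows but ", length(cell_ids),
         " cell ids", call. = FALSE)
  if (ncol(counts) != length(gene_ids))
    stop("counts has ", ncol(counts), " columns but ", length(gene_ids),
         " gene ids", call. = FALSE)
  if (length(gene_origin) != length(gene_ids))
    stop("gene_origin length does not match gene_ids", call. = FALSE)
  if (anyDuplicated(cell_ids))
    stop("duplicated barcodes detected: ",
         paste(utils::head(cell_ids[duplicated(cell_ids)], 3), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(gene_ids))
    stop("duplicated gene ids detected", call. = FALSE)
  if (!all(gene_origin %in% c("host", "symbiont")))
    stop("gene_origin must be 'host' or 'symbiont'", call. = FALSE)
  x <- counts@x
  if (length(x) && (any(x < 0) || any(x != floor(x))))
    stop("counts must be nonnegative integers", call. = FALSE)
  dimnames(counts) <- list(cell_ids, gene_ids)
  structure(
    list(counts = counts, cell_ids = cell_ids, gene_ids = gene_ids,
         gene_origin = gene_origin),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf(
    "count_matrix: %d cells x %d genes (%d host, %d symbiont), %d nonzero\n",
    nrow(x$counts), ncol(x$counts),
    sum(x$gene_origin == "host"), sum(x$gene_origin == "symbiont"),
    length(x$counts@x)))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Subset a count matrix by cells and/or genes
#'
#' @param m a [count_matrix].
#' @param cells,genes index vectors (logical, integer or character);
#'   `NULL` keeps all.
#' @return A [count_matrix] restricted to the requested cells/genes, order
#'   preserved as given.
#' @export
subset_cells <- function(m, cells = NULL, genes = NULL) {
  stopifnot(inherits(m, "count_matrix"))
  ci <- if (is.null(cells)) seq_along(m$cell_ids) else .resolve_idx(cells, m$cell_ids, "cell")
  gi <- if (is.null(genes)) seq_along(m$gene_ids) else .resolve_idx(genes, m$gene_ids, "gene")
  count_matrix(m$counts[ci, gi, drop = FALSE],
               m$cell_ids[ci], m$gene_ids[gi], m$gene_origin[gi])
}

.resolve_idx <- function(idx, ids, what) {
  if (is.character(idx)) {
    pos <- match(idx, ids)
    if (anyNA(pos))
      stop("unknown ", what, " ids: ",
           paste(utils::head(idx[is.na(pos)], 3), collapse = ", "),
           call. = FALSE)
    pos
  } else if (is.logical(idx)) {
    if (length(idx) != length(ids))
      stop(what, " logical index length mismatch", call. = FALSE)
    which(idx)
  } else {
    as.integer(idx)
  }
}

.cell_totals <- function(m) {
  tot <- Matrix::rowSums(m$counts)
  names(tot) <- m$cell_ids
  tot
}
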