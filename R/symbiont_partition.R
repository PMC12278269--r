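#' Per-cell symbiont read fraction
#'
#' Fraction of each cell's total UMI counts assigned to symbiont-genome
#' genes, computed on the full dual-genome matrix (before any host-gene
#' subsetting).
#'
#' @param m a [count_matrix] with both genomes present.
#' @return Named numeric vector in `[0, 1]`, one entry per cell.
#' @export
symbiont_fraction <- function(m) {
  stopifnot(inherits(m, "count_matrix"))
  tot <- .cell_totals(m)
  if (any(tot == 0))
    stop("cells with zero total counts: ",
         paste(utils::head(names(tot)[tot == 0], 3), collapse = ", "),
         call. = FALSE)
  sym <- Matrix::rowSums(m$counts[, m$gene_origin == "symbiont",
                                  drop = FALSE])
  fr <- as.numeric(sym) / as.numeric(tot)
  names(fr) <- m$cell_ids
  fr
}

#' Classify algal-hosting cells
#'
#' A cell hosts algae when strictly more than `threshold` of its total
#' reads come from the symbiont genome ("over 50%": the boundary value is
#' not hosting).
#'
#' @param fractions per-cell symbiont read fractions in `[0, 1]`.
#' @param threshold hosting cutoff, strictly exceeded (default 0.5).
#' @return Named logical vector; the number of hosting cells is attached as
#'   `attr(, "n_hosting")`.
#' @export
classify_hosting <- function(fractions, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must be inside (0, 1)", call. = FALSE)
  if (any(fractions < 0 | fractions > 1))
    stop("fractions must lie in [0, 1]", call. = FALSE)
  out <- fractions > threshold
  attr(out, "n_hosting") <- sum(out)
  out
}

#' Locate the algal-hosting cell cluster
#'
#' Returns the cluster containing the most hosting cells.  Ties are broken
#' toward the lower cluster label and reported.
#'
#' @param hosting per-cell logical hosting calls.
#' @param cluster_labels per-cell cluster labels, aligned with `hosting`.
#' @return A list: `cluster_id` (NA if there are no hosting cells),
#'   `n_hosting_in_cluster`, `n_hosting_total`, `tie` (logical).
#' @export
assign_hosting_cluster <- function(hosting, cluster_labels) {
  if (length(hosting) != length(cluster_labels))
    stop("hosting and cluster_labels lengths differ", call. = FALSE)
  n_total <- sum(hosting)
  if (n_total == 0)
    return(list(cluster_id = NA, n_hosting_in_cluster = 0L,
                n_hosting_total = 0L, tie = FALSE))
  tab <- table(cluster_labels[hosting])
  best <- max(tab)
  winners <- names(tab)[tab == best]
  winners <- winners[order(winners)]
  list(cluster_id = utils::type.convert(winners[1], as.is = TRUE),
       n_hosting_in_cluster = as.integer(best),
       n_hosting_total = as.integer(n_total),
       tie = length(winners) > 1)
}
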