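#' Per-cell gene-set read fraction
#'
#' Fraction of each cell's total counts that falls in a gene set (for
#' example, all genes annotated with immune GO terms of interest).
#'
#' @param m a [count_matrix].
#' @param gene_ids character vector of set members; must intersect the
#'   matrix genes.
#' @return Named numeric vector in `[0, 1]`, one entry per cell.
#' @export
cell_geneset_fraction <- function(m, gene_ids) {
  stopifnot(inherits(m, "count_matrix"))
  hit <- m$gene_ids %in% gene_ids
  if (!any(hit))
    stop("gene set has no genes in common with the matrix", call. = FALSE)
  tot <- .cell_totals(m)
  if (any(tot == 0))
    stop("cells with zero total counts: ",
         paste(utils::head(names(tot)[tot == 0], 3), collapse = ", "),
         call. = FALSE)
  fr <- as.numeric(Matrix::rowSums(m$counts[, hit, drop = FALSE])) /
    as.numeric(tot)
  names(fr) <- m$cell_ids
  fr
}

#' Flag cells exceeding a gene-set fraction threshold
#'
#' Strict ">" flagging ("over 4.5% of the total reads"); a fraction exactly
#' at the threshold is not flagged.
#'
#' @param fractions per-cell fractions in `[0, 1]`.
#' @param threshold flagging cutoff (default 0.045).
#' @return Named logical vector with `attr(, "n_flagged")`.
#' @export
flag_cells <- function(fractions, threshold = 0.045) {
  if (any(fractions < 0 | fractions > 1))
    stop("fractions must lie in [0, 1]", call. = FALSE)
  out <- fractions > threshold
  attr(out, "n_flagged") <- sum(out)
  out
}

#' Rank-based (Mann-Whitney U) GO term enrichment
#'
#' For each GO term, tests whether its member genes' scores rank higher or
#' lower than all non-member genes' scores (two-sided Mann-Whitney U,
#' normal approximation with tie correction), then adjusts across terms by
#' Benjamini-Hochberg.  The conventional per-gene score is the signed
#' log-p from a differential-expression contrast,
#' `-log10(p) * sign(log2FC)`, but any finite per-gene statistic works —
#' results are invariant to strictly monotone transforms of the scores.
#'
#' @param gene_scores named numeric vector, one finite score per gene.
#' @param term_map data.frame with columns `gene_id` and `term` (one row
#'   per gene-term pair).
#' @param min_term_size terms with fewer member genes among the scored
#'   genes are dropped (default 5).
#' @param fdr FDR threshold recorded in the `significant` column
#'   (default 0.1).
#' @return data.frame: term, n_genes, U, p, fdr, direction
#'   (`over`/`under`, from the median score difference), significant;
#'   ordered by p.
#' @export
mwu_go_enrichment <- function(gene_scores, term_map, min_term_size = 5,
                              fdr = 0.1) {
  if (is.null(names(gene_scores)))
    stop("gene_scores must be named by gene id", call. = FALSE)
  if (!all(is.finite(gene_scores)))
    stop("gene_scores must be finite", call. = FALSE)
  stopifnot(all(c("gene_id", "term") %in% names(term_map)))
  term_map <- term_map[term_map$gene_id %in% names(gene_scores), ]
  terms <- split(term_map$gene_id, term_map$term)
  terms <- lapply(terms, unique)
  sizes <- lengths(terms)
  terms <- terms[sizes >= min_term_size]
  if (length(terms) < 2)
    stop("fewer than two terms of size >= ", min_term_size, call. = FALSE)
  n <- length(gene_scores)
  full <- vapply(terms, length, integer(1))
  if (any(full == n))
    stop("term(s) equal to the full gene universe: ",
         paste(names(terms)[full == n], collapse = ", "), call. = FALSE)

  r <- rank(gene_scores)                       # one ranking, shared ties
  len <- rle(sort(gene_scores))$lengths
  tie_term <- sum(len^3 - len)
  med_all <- stats::median(gene_scores)

  rows <- lapply(names(terms), function(tm) {
    members <- names(gene_scores) %in% terms[[tm]]
    n1 <- sum(members); n2 <- n - n1
    u <- sum(r[members]) - n1 * (n1 + 1) / 2
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
    z <- if (sigma2 > 0) (u - n1 * n2 / 2) / sqrt(sigma2) else 0
    p <- if (sigma2 > 0) min(1, 2 * stats::pnorm(-abs(z))) else 1
    dir <- if (stats::median(gene_scores[members]) >=
               stats::median(gene_scores[!members])) "over" else "under"
    data.frame(term = tm, n_genes = n1, U = u, p = p, direction = dir,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p, "BH")
  out$significant <- out$fdr < fdr
  out <- out[order(out$p, out$term),
             c("term", "n_genes", "U", "p", "fdr", "direction",
               "significant")]
  rownames(out) <- NULL
  out
}
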