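#' Map differentially expressed genes to orthogroups
#'
#' Projects a species' DE gene list through an ortholog table: the result
#' is the set of orthogroups hit by at least one DE gene of that species.
#' Genes without an orthogroup are dropped; their number is attached as
#' `attr(, "n_unmapped")`.
#'
#' @param de_genes character vector of DE gene ids.
#' @param ortholog_table data.frame with columns `gene_a`, `orthogroup`,
#'   `gene_b` (possibly many-to-many; each gene belongs to at most one
#'   orthogroup).
#' @param species `"A"` or `"B"`: which gene column `de_genes` refers to.
#' @return Character vector of orthogroup ids (a set, de-duplicated).
#' @export
map_orthologs <- function(de_genes, ortholog_table, species = c("A", "B")) {
  species <- match.arg(species)
  stopifnot(all(c("gene_a", "orthogroup", "gene_b") %in%
                  names(ortholog_table)))
  if (nrow(ortholog_table) == 0)
    stop("ortholog table is empty", call. = FALSE)
  col <- if (species == "A") "gene_a" else "gene_b"
  og_per_gene <- unique(ortholog_table[, c(col, "orthogroup")])
  if (anyDuplicated(og_per_gene[[col]]))
    stop("a gene maps to more than one orthogroup", call. = FALSE)
  hit <- og_per_gene[[col]] %in% de_genes
  og <- sort(unique(og_per_gene$orthogroup[hit]))
  mapped_genes <- og_per_gene[[col]][hit]
  out <- og
  attr(out, "n_unmapped") <- length(setdiff(de_genes, og_per_gene[[col]]))
  out
}

#' Venn partition of two differentially-expressed-ortholog sets
#'
#' Splits two species' DEO sets into shared, unique-to-A and unique-to-B
#' groups against a common orthogroup background.
#'
#' @param set_a,set_b orthogroup id vectors (subsets of `background`).
#' @param background the orthogroup universe both species share.
#' @return list of class `deo_partition`: `shared`, `unique_a`,
#'   `unique_b`, `background`, `sizes` (named integer vector).
#' @export
venn_partition <- function(set_a, set_b, background) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  background <- unique(background)
  out_a <- setdiff(set_a, background)
  out_b <- setdiff(set_b, background)
  if (length(out_a) || length(out_b))
    stop("elements outside the background: ",
         paste(utils::head(c(out_a, out_b), 3), collapse = ", "),
         call. = FALSE)
  shared <- sort(intersect(set_a, set_b))
  ua <- sort(setdiff(set_a, set_b))
  ub <- sort(setdiff(set_b, set_a))
  structure(list(
    shared = shared, unique_a = ua, unique_b = ub,
    background = sort(background),
    sizes = c(shared = length(shared), unique_a = length(ua),
              unique_b = length(ub), background = length(background))),
    class = "deo_partition")
}

#' @export
print.deo_partition <- function(x, ...) {
  s <- x$sizes
  cat(sprintf(
    "deo_partition: %d shared, %d unique to A, %d unique to B (background %d)\n",
    s["shared"], s["unique_a"], s["unique_b"], s["background"]))
  invisible(x)
}

#' Fisher exact over-representation of terms in a DEO group
#'
#' For each term, tests the 2x2 table (in group / out of group) x (in term
#' / out of term) over the orthogroup background with a two-sided Fisher
#' exact test (hypergeometric enumeration: the sum of all table
#' probabilities not exceeding the observed one), BH-adjusted across terms.
#'
#' @param group orthogroup id set (subset of `background`).
#' @param background orthogroup universe.
#' @param term_map data.frame with columns `orthogroup` and `term`.
#' @param min_term_size terms with fewer background members are dropped
#'   (default 5).
#' @param fdr FDR threshold recorded in the `significant` column
#'   (default 0.1).
#' @return data.frame: term, n_term, n_overlap, odds_ratio, p, fdr,
#'   significant; ordered by p.  The odds ratio is the sample estimate with
#'   a 0.5 continuity correction applied when the table has a zero cell.
#' @export
fisher_enrichment <- function(group, background, term_map,
                              min_term_size = 5, fdr = 0.1) {
  group <- unique(group); background <- unique(background)
  if (!length(background)) stop("background is empty", call. = FALSE)
  if (length(setdiff(group, background)))
    stop("group contains elements outside the background", call. = FALSE)
  stopifnot(all(c("orthogroup", "term") %in% names(term_map)))
  term_map <- term_map[term_map$orthogroup %in% background, ]
  terms <- lapply(split(term_map$orthogroup, term_map$term), unique)
  terms <- terms[lengths(terms) >= min_term_size]
  if (!length(terms))
    stop("no terms of size >= ", min_term_size, " in the background",
         call. = FALSE)
  n_bg <- length(background); n_grp <- length(group)
  rows <- lapply(names(terms), function(tm) {
    members <- terms[[tm]]
    a <- length(intersect(group, members))          # in group, in term
    b <- n_grp - a                                  # in group, out of term
    c <- length(members) - a                        # out of group, in term
    d <- n_bg - n_grp - c
    or <- if (a * d == 0 || b * c == 0)
      ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5)) else (a * d) / (b * c)
    data.frame(term = tm, n_term = length(members), n_overlap = a,
               odds_ratio = or, p = fisher_exact_p(a, b, c, d),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p, "BH")
  out$significant <- out$fdr < fdr
  out <- out[order(out$p, out$term), ]
  rownames(out) <- NULL
  out
}

#' Two-sided Fisher exact p-value of a 2x2 table
#'
#' Exact hypergeometric enumeration: with margins fixed, sums the
#' probabilities of every table whose probability does not exceed that of
#' the observed table (up to a relative tolerance of 1e-7 for floating-
#' point ties), the standard two-sided convention.
#'
#' @param a,b,c,d nonnegative integer cells of the table
#'   `rbind(c(a, b), c(c, d))`.
#' @return The two-sided p-value.
#' @export
fisher_exact_p <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  x <- lo:hi
  probs <- stats::dhyper(x, m, n, k)
  p0 <- stats::dhyper(a, m, n, k)
  min(1, sum(probs[probs <= p0 * (1 + 1e-7)]))
}
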