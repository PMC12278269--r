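#' Scale per-cell values to a fixed maximum
#'
#' Rescales a nonnegative per-cell expression vector so its maximum equals
#' `cap` (default 10), the convention used for co-expression overlays.  An
#' all-zero vector is returned unchanged rather than divided by zero.
#'
#' @param values nonnegative numeric vector (one entry per cell).
#' @param cap target maximum (default 10).
#' @return Rescaled vector in `[0, cap]`.
#' @export
scale_max <- function(values, cap = 10) {
  if (any(values < 0)) stop("values must be nonnegative", call. = FALSE)
  mx <- max(values)
  if (mx == 0) return(values)
  values * cap / mx
}

#' Joint co-expression score of a marker gene set
#'
#' Scales each gene's per-cell normalized expression to a maximum of `cap`
#' across cells, then summarizes joint expression per cell by the minimum
#' over the set (a cell must express every member to score high) and, as
#' an alternative, the mean.
#'
#' @param normalized cells x genes matrix from [lognormalize()].
#' @param genes character vector of marker gene ids (e.g. a trio of
#'   nutrient-cycling markers).
#' @param cap scaling maximum (default 10).
#' @return data.frame: barcode, one scaled column per gene, `joint_min`,
#'   `joint_mean`; ordered by decreasing `joint_min`.
#' @export
coexpression_score <- function(normalized, genes, cap = 10) {
  missing <- setdiff(genes, colnames(normalized))
  if (length(missing))
    stop("genes absent from the matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  x <- as.matrix(normalized[, genes, drop = FALSE])
  scaled <- apply(x, 2, scale_max, cap = cap)
  if (is.null(dim(scaled))) scaled <- matrix(scaled, ncol = length(genes))
  out <- data.frame(barcode = rownames(normalized), scaled,
                    stringsAsFactors = FALSE, check.names = FALSE)
  names(out) <- c("barcode", genes)
  out$joint_min <- apply(scaled, 1, min)
  out$joint_mean <- rowMeans(scaled)
  out <- out[order(-out$joint_min, out$barcode), ]
  rownames(out) <- NULL
  out
}
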