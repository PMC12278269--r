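#' Absorptance from a reflectance spectrum
#'
#' Converts tissue reflectance to absorptance, `A = 1 - R`, and reports
#' the chlorophyll-a peak absorptance `A_675` (at the measured wavelength
#' nearest 675 nm) and the mean reflectance over the photosynthetically
#' active radiation (PAR) window.
#'
#' @param spectrum data.frame with columns `wavelength` (nm, strictly
#'   increasing) and `R` (reflectance fraction in `[0, 1]`).
#' @param par_range PAR window in nm for the mean reflectance
#'   (default `c(400, 700)`).
#' @return The spectrum with an added `A` column; `attr(, "a_675")` gives
#'   the peak absorptance and `attr(, "par_mean_reflectance")` the mean R
#'   over the PAR window.
#' @export
absorptance <- function(spectrum, par_range = c(400, 700)) {
  stopifnot(all(c("wavelength", "R") %in% names(spectrum)))
  w <- spectrum$wavelength
  if (any(diff(w) <= 0))
    stop("wavelengths must be strictly increasing", call. = FALSE)
  if (any(spectrum$R < 0 | spectrum$R > 1))
    stop("reflectance must lie in [0, 1]", call. = FALSE)
  spectrum$A <- 1 - spectrum$R
  i675 <- which.min(abs(w - 675))
  attr(spectrum, "a_675") <- spectrum$A[i675]
  in_par <- w >= par_range[1] & w <= par_range[2]
  attr(spectrum, "par_mean_reflectance") <- mean(spectrum$R[in_par])
  spectrum
}

#' Symbiont density fold change between states
#'
#' Ratio of mean surface-area-normalized symbiont densities
#' (cells per cm^2), symbiotic over aposymbiotic.
#'
#' @param mean_sym,mean_apo group mean densities; `mean_apo` must be
#'   positive.
#' @return The fold change `mean_sym / mean_apo`.
#' @export
density_fold_change <- function(mean_sym, mean_apo) {
  if (mean_apo <= 0)
    stop("aposymbiotic mean density must be positive", call. = FALSE)
  mean_sym / mean_apo
}

#' Kruskal-Wallis rank-sum comparison of two groups
#'
#' Nonparametric comparison of symbiont densities (or any phenotype)
#' between two groups: Kruskal-Wallis H with tie correction and the
#' chi-square p-value (1 df for two groups).
#'
#' @param group_a,group_b numeric vectors, at least 3 observations each.
#' @return list: `H` (the rank-sum statistic), `p`.
#' @export
rank_sum_compare <- function(group_a, group_b) {
  if (length(group_a) < 3 || length(group_b) < 3)
    stop("need at least 3 observations per group", call. = FALSE)
  if (length(unique(c(group_a, group_b))) == 1)
    stop("all values tied across both groups", call. = FALSE)
  kt <- stats::kruskal.test(list(group_a, group_b))
  list(H = unname(kt$statistic), p = kt$p.value)
}
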