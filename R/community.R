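#' Average quadrat records to site-level mean abundances
#'
#' Field protocols record abundance in several quadrats per site; analyses
#' run on per-site means. Taxa absent from every quadrat of a site get a
#' zero.
#'
#' @param quadrats numeric matrix, quadrats as rows and taxa as columns.
#' @param site character/factor vector of length `nrow(quadrats)` giving
#'   each quadrat's site.
#' @param guild named character vector of guild labels per taxon.
#' @return An `abundance_table` of per-site means.
#' @export
aggregate_quadrats <- function(quadrats, site, guild) {
  quadrats <- as.matrix(quadrats)
  if (length(site) != nrow(quadrats))
    stop("one site label per quadrat row required")
  site <- as.character(site)
  if (any(!nzchar(site)) || anyNA(site)) stop("empty site label")
  sums <- rowsum(quadrats, site, reorder = FALSE)
  n <- as.vector(table(factor(site, levels = rownames(sums))))
  abundance_table(sums / n, guild)
}

#' Drop taxa occurring in too few sites
#'
#' Rare taxa carry little signal and inflate turnover estimates; taxa with
#' occupancy (number of sites with abundance strictly greater than zero)
#' below `min_sites` are removed. The site set is unchanged. The removal is
#' logged via [message()].
#'
#' @param ab an `abundance_table`.
#' @param min_sites minimum occupancy required to retain a taxon
#'   (default 5).
#' @return The filtered `abundance_table`.
#' @export
filter_rare_species <- function(ab, min_sites = 5) {
  if (min_sites < 1) stop("min_sites must be >= 1")
  occ <- colSums(ab$values > 0)
  keep <- occ >= min_sites
  if (!any(keep))
    stop("all taxa occur in fewer than ", min_sites,
         " sites; empty community")
  if (any(!keep))
    message("filter_rare_species: removed ", sum(!keep), " taxa (",
            paste(sprintf("%s:%d", names(occ)[!keep], occ[!keep]),
                  collapse = ", "), ")")
  abundance_table(ab$values[, keep, drop = FALSE], ab$guild[keep])
}

#' Site-based rarefaction curve
#'
#' Accumulates species richness over randomly ordered sites: for each depth
#' k = 1..n_sites, the mean and SD over `n_perm` random site orderings of
#' the number of taxa present in the first k sites. The mean curve is
#' monotone non-decreasing by construction.
#'
#' @param ab an `abundance_table`.
#' @param n_perm number of random orderings (default 100).
#' @param seed optional integer seed.
#' @return Data frame with columns `k`, `mean_richness`, `sd_richness`.
#' @export
rarefaction_curve <- function(ab, n_perm = 100, seed = NULL) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  pres <- ab$values > 0
  n <- nrow(pres)
  rich <- matrix(0, n_perm, n)
  for (p in seq_len(n_perm)) {
    ord <- sample.int(n)
    seen <- matrixStats_colCummax(pres[ord, , drop = FALSE])
    rich[p, ] <- rowSums(seen)
  }
  data.frame(k = seq_len(n),
             mean_richness = colMeans(rich),
             sd_richness = apply(rich, 2, stats::sd))
}

# cumulative "seen so far" union down the rows of a logical matrix
matrixStats_colCummax <- function(m) {
  if (nrow(m) > 1) for (i in 2:nrow(m)) m[i, ] <- m[i, ] | m[i - 1, ]
  m
}

#' Warm-quarter moisture index
#'
#' Ratio of warm-quarter mean precipitation to warm-quarter mean
#' temperature, the P:T moisture surrogate used alongside the bioclimatic
#' predictors.
#'
#' @param map_warm warm-quarter mean precipitation (mm).
#' @param mat_warm warm-quarter mean temperature (degC); must be positive.
#' @return `map_warm / mat_warm` (mm/degC), vectorized.
#' @export
moisture_index <- function(map_warm, mat_warm) {
  if (any(mat_warm <= 0))
    stop("moisture index undefined for non-positive warm-quarter temperature")
  map_warm / mat_warm
}
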