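#' Relative abundances per site
#'
#' Rows of the abundance matrix rescaled to sum to one. Empty sites (zero
#' total abundance) are an error unless `allow_empty = TRUE`, in which case
#' their row stays all-zero.
#'
#' @param ab an `abundance_table` or numeric matrix (sites x taxa).
#' @param allow_empty keep all-zero sites as zero rows instead of erroring.
#' @return Numeric matrix of relative abundances.
#' @export
rel_abundance <- function(ab, allow_empty = FALSE) {
  v <- if (inherits(ab, "abundance_table")) ab$values else as.matrix(ab)
  tot <- rowSums(v)
  if (any(tot == 0)) {
    if (!allow_empty)
      stop("empty site(s): ", paste(rownames(v)[tot == 0], collapse = ", "))
    tot[tot == 0] <- 1
  }
  v / tot
}

#' Gini-Simpson diversity per site
#'
#' `D = 1 - sum(p_i^2)`: the probability that two randomly drawn
#' individuals belong to different taxa. This is the form for which
#' functional redundancy `D - FD` is bounded in `[0, 1]`.
#'
#' @param ab an `abundance_table` or matrix of (relative) abundances.
#' @return Named numeric vector, one value in `[0, 1]` per site.
#' @export
simpson_d <- function(ab) {
  p <- rel_abundance(ab)
  stats::setNames(1 - rowSums(p^2), rownames(p))
}

#' Community-weighted mean traits
#'
#' For each site, the abundance-weighted mean of every quantitative trait
#' (`CWM_j = sum_i p_i t_ij`); categorical traits yield one column of
#' abundance shares per level. Every taxon present at a site must have a
#' trait row.
#'
#' @param ab an `abundance_table` restricted to the trait table's guild.
#' @param traits a `trait_table` covering the present taxa.
#' @return Data frame, sites as rows, one column per quantitative trait and
#'   per categorical level (`trait.level`).
#' @export
cwm <- function(ab, traits) {
  p <- rel_abundance(ab)
  present <- colnames(p)[colSums(p) > 0]
  miss <- setdiff(present, rownames(traits))
  if (length(miss))
    stop("present taxa missing trait rows: ", paste(miss, collapse = ", "))
  p <- p[, present, drop = FALSE]
  tr <- traits[present, , drop = FALSE]
  out <- list()
  for (j in names(tr)) {
    if (is.numeric(tr[[j]])) {
      out[[j]] <- as.vector(p %*% tr[[j]])
    } else {
      for (lev in levels(tr[[j]]))
        out[[paste(j, lev, sep = ".")]] <-
          rowSums(p[, tr[[j]] == lev, drop = FALSE])
    }
  }
  data.frame(out, row.names = rownames(p))
}

#' Gower dissimilarity between taxa from mixed trait data
#'
#' Per trait: quantitative traits contribute `|x_i - x_j| / range`,
#' categorical traits a 0/1 mismatch; traits are combined as an unweighted
#' mean, so the result lies in `[0, 1]` with a zero diagonal. Quantitative
#' traits with zero range carry no information and are dropped with a
#' warning.
#'
#' @param traits a `trait_table` with at least two taxa.
#' @return Symmetric taxon-by-taxon matrix in `[0, 1]`.
#' @export
gower_dissimilarity <- function(traits) {
  if (nrow(traits) < 2) stop("need at least 2 taxa")
  n <- nrow(traits)
  acc <- matrix(0, n, n, dimnames = list(rownames(traits), rownames(traits)))
  used <- 0L
  for (j in names(traits)) {
    x <- traits[[j]]
    if (is.numeric(x)) {
      rng <- diff(range(x))
      if (rng == 0) {
        warning("dropping zero-range trait '", j, "'")
        next
      }
      acc <- acc + abs(outer(x, x, "-")) / rng
    } else {
      acc <- acc + outer(x, x, "!=") * 1
    }
    used <- used + 1L
  }
  if (used == 0L) stop("no informative traits")
  acc / used
}

# internal: validate a trait-dissimilarity matrix against a taxon set
.check_dissim <- function(d, taxa_ids) {
  if (is.null(dimnames(d)) ||
      !all(taxa_ids %in% rownames(d)) || !all(taxa_ids %in% colnames(d)))
    stop("trait dissimilarity matrix not aligned to community taxa")
  d[taxa_ids, taxa_ids, drop = FALSE]
}

#' Rao quadratic entropy per site
#'
#' `Q = sum_ij p_i p_j d_ij`: the expected trait dissimilarity between two
#' randomly drawn individuals. With `d` bounded by 1, `0 <= Q <= D`.
#'
#' @param ab an `abundance_table` (or matrix) for one guild.
#' @param d symmetric taxon dissimilarity matrix in `[0, 1]` whose
#'   row/column names cover the community's taxa.
#' @return Named numeric vector of Q per site.
#' @export
rao_q <- function(ab, d) {
  p <- rel_abundance(ab)
  d <- .check_dissim(d, colnames(p))
  stats::setNames(rowSums((p %*% d) * p), rownames(p))
}

#' Functional redundancy per site
#'
#' `FR = D - FD` with `D` the Gini-Simpson diversity and `FD` Rao's Q.
#' FR = 0 means complete trait divergence (every pair of taxa maximally
#' dissimilar), FR = D means complete convergence; with `d` in `[0, 1]`,
#' FR lies in `[0, 1]`.
#'
#' @inheritParams rao_q
#' @return Named numeric vector of FR per site.
#' @export
functional_redundancy <- function(ab, d) {
  simpson_d(ab) - rao_q(ab, d)
}

#' Bray-Curtis dissimilarity between sites
#'
#' `sum |x - y| / sum (x + y)` over taxa, per site pair; the taxonomic
#' turnover measure. A pair of all-empty sites has no defined dissimilarity
#' and is an error.
#'
#' @param ab an `abundance_table` or abundance matrix with >= 2 sites.
#' @return Symmetric site-by-site matrix in `[0, 1]` with zero diagonal.
#' @export
bray_curtis <- function(ab) {
  v <- if (inherits(ab, "abundance_table")) ab$values else as.matrix(ab)
  if (nrow(v) < 2) stop("need at least 2 sites")
  if (sum(rowSums(v) == 0) >= 2)
    stop("Bray-Curtis undefined for a pair of empty sites")
  as.matrix(vegan::vegdist(v, method = "bray"))
}

#' Functional beta diversity from the Rao decomposition
#'
#' For each site pair, the pooled community (mean of the two
#' relative-abundance vectors) has Rao entropy `Q_gamma`; the pair's mean
#' within-site entropy is `Q_alpha`. The additive excess
#' `Q_gamma - Q_alpha` is the raw functional turnover; the default applies
#' the Jost correction, dividing by `1 - Q_alpha` (equivalent-number
#' scaling), and clips tiny negative values at zero.
#'
#' @inheritParams rao_q
#' @param correction `"jost"` (default) or `"additive"`.
#' @return Symmetric site-by-site matrix with zero diagonal.
#' @export
functional_beta <- function(ab, d, correction = c("jost", "additive")) {
  correction <- match.arg(correction)
  p <- rel_abundance(ab)
  d <- .check_dissim(d, colnames(p))
  C <- p %*% d %*% t(p)          # C[i,j] = p_i' D p_j
  q <- diag(C)                   # within-site Rao Q
  qa <- outer(q, q, "+") / 2                      # mean alpha
  qg <- (outer(q, q, "+") + 2 * C) / 4            # pooled-community Q
  beta <- qg - qa
  if (correction == "jost") {
    if (any(qa[upper.tri(qa)] >= 1))
      stop("Jost correction undefined: within-site Q reaches 1")
    beta <- beta / (1 - qa)
  }
  beta <- pmax(beta, 0)
  diag(beta) <- 0
  dimnames(beta) <- list(rownames(p), rownames(p))
  beta
}

#' Slope test between two site-pair dissimilarity matrices
#'
#' Ordinary least squares of the response dissimilarities on the predictor
#' dissimilarities over the unfolded upper triangle, with the p-value from
#' Mantel-style site permutation: the site labels of the response matrix
#' are permuted `n_perm` times and the slope refitted, and
#' `p = (1 + #[|slope_perm| >= |slope_obs|]) / (n_perm + 1)`. OLS p-values
#' on unfolded pairs overstate the evidence because the n(n-1)/2 pairs
#' share sites; permutation restores the site-level unit of inference.
#'
#' @param response,predictor symmetric site-by-site matrices with matching
#'   dimensions.
#' @param n_perm permutations (default 499).
#' @param seed optional integer seed.
#' @return List with `slope`, `r_squared`, `p_value` (permutation),
#'   `p_ols` (the naive pair-level p, for reference).
#' @export
decoupling_test <- function(response, predictor, n_perm = 499,
                            seed = NULL) {
  stopifnot(all(dim(response) == dim(predictor)))
  if (!is.null(seed)) set.seed(seed)
  ut <- upper.tri(response)
  x <- predictor[ut]
  slope_of <- function(y) stats::cov(y, x) / stats::var(x)
  y <- response[ut]
  fit <- summary(stats::lm(y ~ x))
  obs <- slope_of(y)
  n <- nrow(response)
  perm <- vapply(seq_len(n_perm), function(k) {
    ord <- sample.int(n)
    slope_of(response[ord, ord][ut])
  }, numeric(1))
  list(slope = obs, r_squared = fit$r.squared,
       p_value = (1 + sum(abs(perm) >= abs(obs))) / (n_perm + 1),
       p_ols = fit$coefficients[2, 4])
}

#' Robustness of FD and FR to random trait removal
#'
#' Repeatedly drops k traits at random (k = 1..`n_remove_max`, always
#' leaving at least `always_keep` traits), recomputes the Gower
#' dissimilarity, FD (Rao Q) and FR across sites, and summarises each
#' removal depth against the observed full-trait values.
#'
#' @param ab an `abundance_table` for the trait table's guild.
#' @param traits a `trait_table`.
#' @param n_remove_max deepest removal; must not exceed
#'   `ncol(traits) - always_keep`.
#' @param always_keep minimum number of traits retained (default 4).
#' @param n_iter random subsets per depth (default 99).
#' @param seed optional integer seed.
#' @return Data frame with one row per (k, iteration): columns `k`, `iter`,
#'   `fd_mean`, `fr_mean` (site means), plus the observed values as
#'   attributes `fd_observed`, `fr_observed`.
#' @export
trait_removal_robustness <- function(ab, traits, n_remove_max,
                                     always_keep = 4, n_iter = 99,
                                     seed = NULL) {
  nt <- ncol(traits)
  if (nt <= always_keep) stop("trait count must exceed always_keep")
  if (n_remove_max > nt - always_keep)
    stop("n_remove_max exceeds traits - always_keep")
  if (!is.null(seed)) set.seed(seed)
  d0 <- gower_dissimilarity(traits)
  fd0 <- mean(rao_q(ab, d0))
  fr0 <- mean(functional_redundancy(ab, d0))
  res <- expand.grid(k = seq_len(n_remove_max), iter = seq_len(n_iter))
  res$fd_mean <- NA_real_
  res$fr_mean <- NA_real_
  for (r in seq_len(nrow(res))) {
    drop <- sample.int(nt, res$k[r])
    dk <- gower_dissimilarity(traits[, -drop, drop = FALSE])
    res$fd_mean[r] <- mean(rao_q(ab, dk))
    res$fr_mean[r] <- mean(functional_redundancy(ab, dk))
  }
  attr(res, "fd_observed") <- fd0
  attr(res, "fr_observed") <- fr0
  res
}
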