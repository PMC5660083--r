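#' @useDynLib peatturnover, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# attempted swaps per randomization: burn-in for approximate uniformity
.swap_attempts <- function(values, per_cell = 1000) {
  max(per_cell * sum(values > 0), 1)
}

#' NULL1: occurrence re-assembly
#'
#' Randomly reshuffles species occurrence while keeping every site (row)
#' and species (column) total and the matrix fill (number of occupied
#' cells) intact. Abundances are scaled to integer counts (`x scale`,
#' default 100), randomized by the count quasiswap algorithm
#' (marginal- and fill-preserving 2x2 swaps, via [vegan::nullmodel()]),
#' and scaled back. Per-species occupancy may change. If the matrix is
#' too degenerate to swap the input is returned with a warning.
#'
#' @param ab an `abundance_table`.
#' @param seed optional integer seed.
#' @param scale integerization factor (default 100).
#' @return A randomized `abundance_table`.
#' @export
null1_occurrence <- function(ab, seed = NULL, scale = 100) {
  if (!is.null(seed)) set.seed(seed)
  out <- matrix(.null1_batch(ab$values, 1, scale)[, , 1],
                nrow(ab$values), ncol(ab$values),
                dimnames = dimnames(ab$values))
  abundance_table(out, ab$guild)
}

# batch of NULL1 randomizations as a 3-d array (sites x taxa x nsim)
.null1_batch <- function(values, nsim, scale = 100) {
  m <- round(values * scale)
  storage.mode(m) <- "integer"
  sims <- tryCatch(
    simulate(vegan::nullmodel(m, "quasiswap_count"), nsim = nsim),
    error = function(e) {
      warning("occurrence reshuffle impossible (", conditionMessage(e),
              "); returning input unchanged")
      array(m, c(dim(m), nsim))
    })
  array(sims, c(dim(m), nsim)) / scale
}

#' NULL2: abundance re-assembly
#'
#' Randomly re-assigns abundance among occupied cells only: repeated
#' transfers between the diagonal cells of 2x2 submatrices whose four
#' cells are all non-zero (and stay non-zero), preserving the occurrence
#' pattern and all row and column totals exactly. If no all-non-zero 2x2
#' exists the input is returned with a warning.
#'
#' @inheritParams null1_occurrence
#' @return A randomized `abundance_table` with the same occurrence mask.
#' @export
null2_abundance <- function(ab, seed = NULL, attempts = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (count_swappable_dense(ab$values) == 0) {
    warning("no all-non-zero 2x2 submatrix; returning input unchanged")
    return(ab)
  }
  if (is.null(attempts)) attempts <- .swap_attempts(ab$values)
  out <- abundance_swap_walk(ab$values, attempts)
  dimnames(out) <- dimnames(ab$values)
  abundance_table(out, ab$guild)
}

# resample one abundance value per (species, draw) from the species'
# observed non-zero values
.resample_abundance <- function(values, sp) {
  obs <- values[values[, sp] > 0, sp]
  if (!length(obs)) stop("species '", sp, "' has no non-zero observation")
  obs[sample.int(length(obs), 1)]
}

#' RANDOM: random assembly from the species pool
#'
#' Builds each site anew by drawing `k` species uniformly from the pool
#' (the table's taxa) and assigning each an abundance resampled from that
#' species' observed non-zero site values. Neither occurrences nor
#' marginal totals are preserved.
#'
#' @param ab an `abundance_table` (typically one guild).
#' @param k species per simulated site; the field convention is the mean
#'   observed site richness.
#' @param seed optional integer seed.
#' @return A simulated `abundance_table` with the same sites and taxa.
#' @export
random_assembly <- function(ab, k, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pool <- taxa(ab)
  if (k > length(pool)) stop("k exceeds pool size")
  no_obs <- pool[colSums(ab$values > 0) == 0]
  if (length(no_obs))
    stop("species with no non-zero observations: ",
         paste(no_obs, collapse = ", "))
  out <- ab$values * 0
  for (s in seq_len(nrow(out))) {
    chosen <- pool[sample.int(length(pool), k)]
    for (sp in chosen) out[s, sp] <- .resample_abundance(ab$values, sp)
  }
  abundance_table(out, ab$guild)
}

#' LOSS: remove a co-response cluster
#'
#' Sets every species of the named cluster to zero at every site; the
#' remaining abundances are unchanged (relative abundances renormalize
#' inside the index computations). Sites losing all their species are
#' recorded in the `empty_sites` attribute and should be excluded from FR
#' means.
#'
#' @param ab an `abundance_table`.
#' @param clusters a `cluster_assignment` or named membership vector.
#' @param which cluster label to remove (e.g. `"I"` or `"II"`).
#' @return An `abundance_table` with attribute `empty_sites`.
#' @export
cluster_loss <- function(ab, clusters, which) {
  membership <- if (inherits(clusters, "cluster_assignment"))
    clusters$membership else clusters
  lost <- intersect(names(membership)[membership == which], taxa(ab))
  out <- ab$values
  out[, lost] <- 0
  if (all(out == 0)) stop("cluster loss empties the whole community")
  res <- abundance_table(out, ab$guild)
  empty <- rownames(out)[rowSums(out) == 0]
  if (length(empty))
    message("cluster_loss: ", length(empty),
            " site(s) emptied and flagged: ", paste(empty, collapse = ", "))
  attr(res, "empty_sites") <- empty
  res
}

#' TURNOVER: between-cluster species replacement
#'
#' Per site, `n_replace` randomly chosen present species of the source
#' cluster are removed and replaced by the same number of target-cluster
#' species not already present; each incoming species inherits one removed
#' species' abundance (random pairing), so site totals are conserved when
#' the target pool suffices. If fewer source species are present, all of
#' them are replaced; if the target cluster is exhausted, fewer are added.
#'
#' @param ab an `abundance_table`.
#' @param clusters a `cluster_assignment` or named membership vector.
#' @param direction `"I_to_II"` (cluster I species replaced by cluster II)
#'   or `"II_to_I"`.
#' @param n_replace species replaced per site (default 3).
#' @param seed optional integer seed.
#' @return A simulated `abundance_table`.
#' @export
cluster_turnover <- function(ab, clusters, direction = c("I_to_II",
                                                         "II_to_I"),
                             n_replace = 3, seed = NULL) {
  direction <- match.arg(direction)
  if (n_replace < 0) stop("n_replace must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  membership <- if (inherits(clusters, "cluster_assignment"))
    clusters$membership else clusters
  src_cl <- if (direction == "I_to_II") "I" else "II"
  tgt_cl <- if (direction == "I_to_II") "II" else "I"
  src_pool <- intersect(names(membership)[membership == src_cl], taxa(ab))
  tgt_pool <- intersect(names(membership)[membership == tgt_cl], taxa(ab))
  out <- ab$values
  if (n_replace == 0) return(abundance_table(out, ab$guild))
  short <- 0L
  for (s in seq_len(nrow(out))) {
    present_src <- src_pool[out[s, src_pool] > 0]
    n_rm <- min(n_replace, length(present_src))
    if (n_rm == 0) next
    removed <- present_src[sample.int(length(present_src), n_rm)]
    absent_tgt <- tgt_pool[out[s, tgt_pool] == 0]
    n_add <- min(n_rm, length(absent_tgt))
    if (n_add < n_rm) short <- short + 1L
    added <- absent_tgt[sample.int(length(absent_tgt), n_add)]
    donors <- removed[sample.int(n_rm, n_add)]
    out[s, removed] <- 0
    if (n_add) out[s, added] <- ab$values[s, donors]
  }
  if (short)
    message("cluster_turnover: target cluster exhausted at ", short,
            " site(s); fewer additions made")
  abundance_table(out, ab$guild)
}

#' Standardized effect size against a simulated distribution
#'
#' `SES = (obs - mean(sim)) / sd(sim)`, with a two-sided departure test
#' from the simulated distribution's percentiles
#' (`p = min(1, 2 * (1 + min(#sim <= obs, #sim >= obs)) / (n + 1))`).
#'
#' @param fr_obs observed value.
#' @param fr_sim numeric vector of simulated values (length >= 2 with
#'   non-zero SD).
#' @return List with `ses` and `p_value`.
#' @export
ses <- function(fr_obs, fr_sim) {
  if (length(fr_sim) < 2) stop("need at least 2 simulated values")
  s <- stats::sd(fr_sim)
  if (s == 0) stop("SES undefined: simulated SD is zero")
  n <- length(fr_sim)
  p <- min(1, 2 * (1 + min(sum(fr_sim <= fr_obs),
                           sum(fr_sim >= fr_obs))) / (n + 1))
  list(ses = (fr_obs - mean(fr_sim)) / s, p_value = p)
}

# mean FR over non-empty sites, given relative-abundance-ready values
.mean_fr <- function(values, d, exclude_sites = character(0)) {
  keep <- rowSums(values) > 0
  if (length(exclude_sites) && !is.null(rownames(values)))
    keep <- keep & !(rownames(values) %in% exclude_sites)
  v <- values[keep, , drop = FALSE]
  p <- v / rowSums(v)
  D <- 1 - rowSums(p^2)
  Q <- rowSums((p %*% d) * p)
  mean(D - Q)
}

#' Run one community re-assembly scenario
#'
#' Applies a named scenario `n_iter` times to a guild's community matrix,
#' recomputes the site-mean functional redundancy per iteration, and
#' scores the scenario's effect on FR against the simulated distribution:
#' the reported SES is `(mean(FR_sim) - FR_obs) / sd(FR_sim)`, so a
#' scenario that erodes functional redundancy scores negative and one
#' that leaves it untouched scores near zero (two-sided percentile
#' departure test as in [ses()]).
#' Scenarios: `NULL1` and `NULL2` (marginal-preserving randomizations),
#' `RANDOM` (random assembly of `k` species per site), `LOSS1`/`LOSS2`
#' (cluster removal, with the remaining present species' abundances
#' resampled from their observed non-zero values each iteration, which
#' supplies the simulated distribution), and `TURNOVER1`/`TURNOVER2`
#' (replacement of `n_replace` species by the other cluster's).
#'
#' @param ab an `abundance_table`, already restricted to one guild.
#' @param traits a `trait_table` for that guild (used for the Gower
#'   dissimilarity), or a precomputed dissimilarity via `d`.
#' @param clusters a `cluster_assignment` or membership vector (ignored by
#'   NULL1/NULL2/RANDOM).
#' @param scenario one of `"NULL1"`, `"NULL2"`, `"RANDOM"`, `"LOSS1"`,
#'   `"LOSS2"`, `"TURNOVER1"`, `"TURNOVER2"`.
#' @param n_iter simulated assemblages (default 1000).
#' @param n_replace TURNOVER replacement count (default 3).
#' @param k RANDOM richness; default is the rounded mean observed site
#'   richness.
#' @param seed integer seed (default 1).
#' @param guild label stored in the result.
#' @param d optional precomputed taxon dissimilarity matrix.
#' @return Object of class `reassembly_result`: `scenario`, `guild`,
#'   `fr_observed`, `fr_simulated` (length `n_iter`), `ses`, `p_value`.
#' @export
run_scenario <- function(ab, traits = NULL, clusters = NULL,
                         scenario = c("NULL1", "NULL2", "RANDOM", "LOSS1",
                                      "LOSS2", "TURNOVER1", "TURNOVER2"),
                         n_iter = 1000, n_replace = 3, k = NULL, seed = 1,
                         guild = NA_character_, d = NULL) {
  scenario <- match.arg(scenario)
  if (n_iter < 1) stop("n_iter must be >= 1")
  if (is.null(d)) d <- gower_dissimilarity(traits[taxa(ab), , drop = FALSE])
  d <- .check_dissim(d, taxa(ab))
  fr_obs <- .mean_fr(ab$values, d)
  if (is.null(k) && scenario == "RANDOM")
    k <- max(1L, round(mean(rowSums(ab$values > 0))))
  membership <- if (inherits(clusters, "cluster_assignment"))
    clusters$membership else clusters
  set.seed(seed)
  if (scenario == "NULL1") {
    sims <- .null1_batch(ab$values, n_iter)
    fr_sim <- vapply(seq_len(n_iter),
                     function(it) .mean_fr(sims[, , it], d), numeric(1))
    score <- ses(fr_obs, fr_sim)
    return(structure(list(scenario = scenario, guild = guild,
                          fr_observed = fr_obs, fr_simulated = fr_sim,
                          ses = -score$ses, p_value = score$p_value),
                     class = "reassembly_result"))
  }
  sim_values <- function() {
    switch(scenario,
      NULL2 = null2_abundance(ab)$values,
      RANDOM = random_assembly(ab, k)$values,
      LOSS1 = .loss_resample(ab, membership, "I"),
      LOSS2 = .loss_resample(ab, membership, "II"),
      TURNOVER1 = cluster_turnover(ab, membership, "I_to_II",
                                   n_replace)$values,
      TURNOVER2 = cluster_turnover(ab, membership, "II_to_I",
                                   n_replace)$values)
  }
  fr_sim <- vapply(seq_len(n_iter), function(it) {
    v <- sim_values()
    .mean_fr(v, d, exclude_sites = attr(v, "empty_sites") %||% character(0))
  }, numeric(1))
  score <- ses(fr_obs, fr_sim)
  structure(list(scenario = scenario, guild = guild, fr_observed = fr_obs,
                 fr_simulated = fr_sim, ses = -score$ses,
                 p_value = score$p_value),
            class = "reassembly_result")
}

# cluster removal + abundance resampling of the surviving present species
.loss_resample <- function(ab, membership, which) {
  lost <- suppressMessages(cluster_loss(ab, membership, which))
  v <- lost$values
  for (sp in colnames(v)) {
    occ <- which(v[, sp] > 0)
    if (!length(occ)) next
    obs <- ab$values[ab$values[, sp] > 0, sp]
    v[occ, sp] <- obs[sample.int(length(obs), length(occ),
                                 replace = TRUE)]
  }
  attr(v, "empty_sites") <- attr(lost, "empty_sites")
  v
}

#' @export
print.reassembly_result <- function(x, ...) {
  cat(sprintf("%s (%s): FR_obs = %.4f, SES = %.2f, p = %.4f (%d iter)\n",
              x$scenario, x$guild %||% "?", x$fr_observed, x$ses,
              x$p_value, length(x$fr_simulated)))
  invisible(x)
}
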