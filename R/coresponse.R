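#' MCMC configuration for the species-response sampler
#'
#' @param n_chains number of chains (default 5).
#' @param n_iter iterations per chain (default 5000).
#' @param n_burnin burn-in iterations discarded (default 1000).
#' @param thin thinning factor (default 4).
#' @return A `mcmc_config` list.
#' @export
mcmc_config <- function(n_chains = 5, n_iter = 5000, n_burnin = 1000,
                        thin = 4) {
  stopifnot(n_chains >= 1, thin >= 1, n_burnin >= 0)
  if (n_burnin >= n_iter) stop("burn-in must be smaller than n_iter")
  structure(list(n_chains = n_chains, n_iter = n_iter,
                 n_burnin = n_burnin, thin = thin), class = "mcmc_config")
}

#' Retained posterior samples per chain
#'
#' `floor((n_iter - n_burnin) / thin)`: the post-processing sample count
#' implied by an iteration budget, burn-in and thinning factor.
#'
#' @param n_iter iterations per chain (or a `mcmc_config`, in which case
#'   the other arguments are ignored).
#' @param n_burnin burn-in iterations.
#' @param thin thinning factor.
#' @return Integer count of retained samples per chain.
#' @export
retained_samples <- function(n_iter, n_burnin = 0, thin = 1) {
  if (inherits(n_iter, "mcmc_config")) {
    cfg <- n_iter
    n_iter <- cfg$n_iter; n_burnin <- cfg$n_burnin; thin <- cfg$thin
  }
  if (thin < 1) stop("thin must be >= 1")
  if (n_burnin >= n_iter) stop("burn-in must be smaller than n_iter")
  as.integer(floor((n_iter - n_burnin) / thin))
}

#' Hierarchical model of species responses to environmental gradients
#'
#' Per-species linear regression of transformed abundance
#' (`log(1 + x)`, standardized per species) on standardized environmental
#' variables, with a hierarchical normal prior on each coefficient
#' (mean and variance shared across species) tying the species models
#' together. Sampled by a Gibbs sampler with conjugate updates
#' (coefficients, residual variances, prior means, prior variances).
#'
#' @param ab an `abundance_table`.
#' @param env an `env_table` covering the same sites.
#' @param variables environmental variable names used as predictors.
#' @param config a [mcmc_config()].
#' @param seed integer seed; chain c uses `seed + c - 1`.
#' @return Object of class `species_response_fit`: `samples` (list per
#'   chain of arrays `n_samples x n_species x n_coef`), `coef_mean`
#'   (posterior-mean species x coefficient matrix), `rhat` (split-chain
#'   potential scale reduction per coefficient), `X`, `Y`, `taxa`,
#'   `variables`, `config`.
#' @export
fit_species_responses <- function(ab, env, variables, config = mcmc_config(),
                                  seed = 1) {
  v <- ab$values
  if (any(!is.finite(v))) stop("non-finite abundances")
  if (ncol(v) < 2) stop("need at least 2 species")
  env <- env[match(rownames(v), env$site), ]
  X <- scale(as.matrix(env[, variables, drop = FALSE]))
  if (any(!is.finite(X))) stop("constant environmental variable")
  X <- cbind(intercept = 1, X)
  if (qr(X)$rank < ncol(X)) stop("singular design matrix")
  Y <- scale(log1p(v))
  Y[, attr(Y, "scaled:scale") == 0] <- 0   # constant species: centred zeros
  n <- nrow(Y); S <- ncol(Y); K <- ncol(X)
  XtX <- crossprod(X)
  XtY <- crossprod(X, Y)
  n_keep <- retained_samples(config)
  a0 <- 2; b0 <- 0.5       # inverse-gamma shapes/rates (weakly informative)
  v_mu <- 100              # prior variance of the hierarchical means
  chains <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    set.seed(seed + ch - 1L)
    beta <- matrix(0, S, K)
    sigma2 <- rep(1, S)
    mu <- rep(0, K)
    tau2 <- rep(1, K)
    keep <- array(NA_real_, c(n_keep, S, K))
    kept <- 0L
    for (it in seq_len(config$n_iter)) {
      Tinv <- 1 / tau2
      for (s in seq_len(S)) {
        A <- XtX / sigma2[s] + diag(Tinv, K)
        bvec <- XtY[, s] / sigma2[s] + Tinv * mu
        U <- chol(A)
        m <- backsolve(U, backsolve(U, bvec, transpose = TRUE))
        beta[s, ] <- m + backsolve(U, stats::rnorm(K))
      }
      R <- Y - X %*% t(beta)
      sigma2 <- 1 / stats::rgamma(S, a0 + n / 2, b0 + colSums(R^2) / 2)
      prec <- S / tau2 + 1 / v_mu
      mu <- stats::rnorm(K, (colSums(beta) / tau2) / prec, sqrt(1 / prec))
      tau2 <- 1 / stats::rgamma(K, a0 + S / 2,
                                b0 + colSums(sweep(beta, 2, mu)^2) / 2)
      if (it > config$n_burnin &&
          (it - config$n_burnin) %% config$thin == 0 && kept < n_keep) {
        kept <- kept + 1L
        keep[kept, , ] <- beta
      }
    }
    chains[[ch]] <- keep
  }
  all_samp <- do.call(abind1, chains)
  coef_mean <- apply(all_samp, c(2, 3), mean)
  dimnames(coef_mean) <- list(colnames(v), colnames(X))
  structure(list(samples = chains, coef_mean = coef_mean,
                 rhat = .split_rhat(chains), X = X, Y = Y,
                 taxa = colnames(v), variables = variables,
                 config = config),
            class = "species_response_fit")
}

# bind sample arrays along iterations
abind1 <- function(...) {
  arrs <- list(...)
  out <- array(NA_real_, c(sum(vapply(arrs, function(a) dim(a)[1],
                                      numeric(1))),
                           dim(arrs[[1]])[2], dim(arrs[[1]])[3]))
  at <- 0
  for (a in arrs) {
    out[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}

# split-chain potential scale reduction, summarised per coefficient as the
# maximum over species
.split_rhat <- function(chains) {
  half <- floor(dim(chains[[1]])[1] / 2)
  if (half < 2) return(NULL)
  splits <- list()
  for (a in chains) {
    splits[[length(splits) + 1]] <- a[seq_len(half), , , drop = FALSE]
    splits[[length(splits) + 1]] <-
      a[half + seq_len(half), , , drop = FALSE]
  }
  S <- dim(chains[[1]])[2]; K <- dim(chains[[1]])[3]
  m <- length(splits); n <- half
  rhat <- matrix(NA_real_, S, K)
  for (s in seq_len(S)) for (k in seq_len(K)) {
    means <- vapply(splits, function(a) mean(a[, s, k]), numeric(1))
    vars <- vapply(splits, function(a) stats::var(a[, s, k]), numeric(1))
    W <- mean(vars); B <- n * stats::var(means)
    if (W <= 0) { rhat[s, k] <- 1; next }
    rhat[s, k] <- sqrt(((n - 1) / n * W + B / n) / W)
  }
  apply(rhat, 2, max)
}

#' Decompose species correlations into environmental and residual parts
#'
#' The correlation across sites of two species' environmental linear
#' predictors measures how alike their responses to the gradients are; the
#' correlation of their residuals captures co-occurrence not explained by
#' the environment. With `method = "posterior"` (default) the
#' environmental correlation is the posterior mean of the per-sample
#' predictor correlation, so species whose response direction is not
#' pinned down by the data are pulled towards zero rather than inheriting
#' an arbitrary point-estimate direction; `method = "point"` uses the
#' posterior-mean coefficients directly.
#'
#' @param fit a `species_response_fit`.
#' @param method `"posterior"` or `"point"` (see above).
#' @param max_samples posterior samples used by `"posterior"`
#'   (default 400, evenly thinned).
#' @return Object of class `response_decomposition`: `env_correlation` and
#'   `residual_correlation` (taxon x taxon, unit diagonal), `linear_pred`,
#'   `residuals`, and `flagged` (taxa whose linear predictor is constant,
#'   with undefined correlations set to `NA`).
#' @export
decompose_correlations <- function(fit, method = c("posterior", "point"),
                                   max_samples = 400) {
  method <- match.arg(method)
  L <- fit$X %*% t(fit$coef_mean)   # sites x species linear predictors
  R <- fit$Y - L
  const_l <- apply(L, 2, stats::sd) < 1e-12
  const_r <- apply(R, 2, stats::sd) < 1e-12
  if (method == "point") {
    env_cor <- suppressWarnings(stats::cor(L))
  } else {
    samp <- do.call(abind1, fit$samples)
    n_s <- dim(samp)[1]
    pick <- unique(round(seq(1, n_s, length.out = min(max_samples, n_s))))
    acc <- 0
    for (m in pick) {
      Lm <- fit$X %*% t(samp[m, , ])
      cm <- suppressWarnings(stats::cor(Lm))
      cm[!is.finite(cm)] <- 0
      acc <- acc + cm
    }
    env_cor <- acc / length(pick)
  }
  res_cor <- suppressWarnings(stats::cor(R))
  env_cor[const_l, ] <- NA; env_cor[, const_l] <- NA
  res_cor[const_r, ] <- NA; res_cor[, const_r] <- NA
  diag(env_cor) <- 1; diag(res_cor) <- 1
  dimnames(env_cor) <- dimnames(res_cor) <- list(fit$taxa, fit$taxa)
  if (any(const_l | const_r))
    warning("constant predictor/residual for: ",
            paste(fit$taxa[const_l | const_r], collapse = ", "))
  structure(list(env_correlation = env_cor,
                 residual_correlation = res_cor,
                 linear_pred = L, residuals = R,
                 flagged = fit$taxa[const_l | const_r]),
            class = "response_decomposition")
}

#' Threshold network and co-response clusters
#'
#' Draws a positive edge between species whose shared-environment
#' correlation is at least `threshold` and a negative edge where it is at
#' most `-threshold`. Co-response clusters are the connected components
#' (size >= 2) of the positive-edge graph, labelled by decreasing size with
#' roman numerals; species in no component are `"unrelated"`.
#'
#' @param dec a `response_decomposition` (or a plain correlation matrix).
#' @param threshold edge threshold in `(0, 1]` (default 0.6).
#' @return Object of class `cluster_assignment`: `membership` (named
#'   character: `"I"`, `"II"`, ... or `"unrelated"`), `edges` (data frame
#'   `from`, `to`, `weight`, `sign`), `threshold`.
#' @export
build_network <- function(dec, threshold = 0.6) {
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  M <- if (inherits(dec, "response_decomposition")) dec$env_correlation
       else as.matrix(dec)
  taxa_ids <- rownames(M)
  iu <- which(upper.tri(M), arr.ind = TRUE)
  w <- M[iu]
  keep <- !is.na(w) & abs(w) >= threshold
  edges <- data.frame(from = taxa_ids[iu[keep, 1]],
                      to = taxa_ids[iu[keep, 2]],
                      weight = w[keep],
                      sign = ifelse(w[keep] > 0, "positive", "negative"),
                      stringsAsFactors = FALSE)
  pos <- edges[edges$sign == "positive", , drop = FALSE]
  g <- igraph::graph_from_data_frame(pos[, c("from", "to")],
                                     directed = FALSE,
                                     vertices = data.frame(name = taxa_ids))
  comp <- igraph::components(g)
  membership <- rep("unrelated", length(taxa_ids))
  names(membership) <- taxa_ids
  sizes <- comp$csize
  big <- which(sizes >= 2)
  big <- big[order(sizes[big], decreasing = TRUE)]
  for (r in seq_along(big)) {
    in_comp <- names(comp$membership)[comp$membership == big[r]]
    membership[in_comp] <- as.character(utils::as.roman(r))
  }
  structure(list(membership = membership, edges = edges,
                 threshold = threshold),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  tab <- table(x$membership)
  cat("co-response clusters (threshold ", x$threshold, "): ",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Cluster-specific community-weighted means
#'
#' CWM computed within each co-response cluster's species subset, per
#' site, restricted to taxa that have trait rows (i.e. to the trait
#' table's guild).
#'
#' @param ab an `abundance_table`.
#' @param traits a `trait_table` for one guild.
#' @param clusters a `cluster_assignment` (or named membership vector).
#' @return Named list of CWM data frames, one per cluster label present.
#' @export
cluster_cwm <- function(ab, traits, clusters) {
  membership <- if (inherits(clusters, "cluster_assignment"))
    clusters$membership else clusters
  out <- list()
  for (cl in setdiff(unique(membership), "unrelated")) {
    ids <- intersect(names(membership)[membership == cl], rownames(traits))
    ids <- intersect(ids, taxa(ab))
    if (!length(ids))
      stop("cluster ", cl, " has no trait-bearing species")
    sub <- ab$values[, ids, drop = FALSE]
    keep_sites <- rowSums(sub) > 0
    out[[cl]] <- cwm(sub[keep_sites, , drop = FALSE],
                     traits[ids, , drop = FALSE])
  }
  out
}

#' Rand index between two partitions
#'
#' Proportion of item pairs on which two partitions agree (grouped
#' together in both, or separated in both).
#'
#' @param a,b partition labels (named vectors are matched by name).
#' @return Rand index in `[0, 1]`.
#' @export
rand_index <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) b <- b[names(a)]
  stopifnot(length(a) == length(b))
  n <- length(a)
  same_a <- outer(a, a, "==")[upper.tri(diag(n))]
  same_b <- outer(b, b, "==")[upper.tri(diag(n))]
  mean(same_a == same_b)
}
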