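#' Monotone I-spline basis for one environmental variable
#'
#' Order-2 I-splines (piecewise-quadratic, monotone non-decreasing, rising
#' from 0 at the variable's minimum to 1 at its maximum) with knots at the
#' min, median and max of the variable over sites. Built as cumulative sums
#' of order-3 B-splines on the same knot vector.
#'
#' @param env an `env_table`.
#' @param variable name of the variable.
#' @param n_basis number of basis functions (default 3; interior knots at
#'   evenly spaced quantiles).
#' @return List of class `spline_basis`: `variable`, `knots`, `basis`
#'   (site x n_basis matrix in `[0, 1]`).
#' @export
build_basis <- function(env, variable, n_basis = 3) {
  x <- env[[variable]]
  if (is.null(x)) stop("unknown variable '", variable, "'")
  if (length(unique(x)) < 3) stop("variable '", variable,
                                  "' has fewer than 3 distinct values")
  knots <- stats::quantile(x, seq(0, 1, length.out = n_basis),
                           names = FALSE)
  structure(list(variable = variable, knots = knots,
                 basis = ispline_eval(x, knots)),
            class = "spline_basis")
}

# evaluate the order-2 I-spline basis at x for boundary/interior knots
ispline_eval <- function(x, knots) {
  lo <- knots[1]; hi <- knots[length(knots)]
  xc <- pmin(pmax(x, lo), hi)
  kn <- c(rep(lo, 3), knots[-c(1, length(knots))], rep(hi, 3))
  B <- splines::splineDesign(kn, xc, ord = 3)
  nb <- ncol(B)
  I <- vapply(seq_len(nb - 1),
              function(j) rowSums(B[, (j + 1):nb, drop = FALSE]),
              numeric(length(xc)))
  I <- matrix(I, nrow = length(xc))
  # splineDesign leaves the last basis at 0 on the right boundary limit;
  # force the defining endpoint values
  I[x >= hi, ] <- 1
  I[x <= lo, ] <- 0
  I <- pmin(pmax(I, 0), 1)   # guard against epsilon overshoot
  colnames(I) <- paste0("s", seq_len(nb - 1))
  I
}

#' Build the site-pair table for generalized dissimilarity modelling
#'
#' One row per unordered site pair (i < j): the observed compositional
#' dissimilarity as response and, per environmental variable, the absolute
#' between-site differences of each I-spline basis function; great-circle
#' (haversine) geographic distance in km is one additional predictor,
#' rescaled to `[0, 1]` by its maximum.
#'
#' @param ab_dissim symmetric site-by-site dissimilarity matrix in
#'   `[0, 1]` (e.g. from [bray_curtis()]).
#' @param env an `env_table` covering the same sites.
#' @param variables environmental variable names to include.
#' @param n_basis I-spline basis size per variable (default 3).
#' @param geo include the geographic-distance predictor (default `TRUE`).
#' @return List of class `site_pair_table`: `pairs` (data frame of ids,
#'   response and predictors), `X` (predictor matrix), `var_cols` (map
#'   variable -> column indices), `env`, `variables`, `n_basis`.
#' @export
build_pair_table <- function(ab_dissim, env, variables, n_basis = 3,
                             geo = TRUE) {
  ids <- rownames(ab_dissim)
  if (!all(ids %in% env$site)) stop("site ids of dissimilarity matrix and ",
                                    "env table do not match")
  env <- env[match(ids, env$site), ]
  n <- length(ids)
  idx <- which(upper.tri(ab_dissim), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  i <- idx[, 1]; j <- idx[, 2]
  cols <- list()
  for (v in variables) {
    b <- build_basis(env, v, n_basis)$basis
    d <- abs(b[i, , drop = FALSE] - b[j, , drop = FALSE])
    colnames(d) <- paste(v, colnames(b), sep = ".")
    cols[[v]] <- d
  }
  X <- if (length(cols)) do.call(cbind, cols) else
    matrix(0, length(i), 0)
  var_cols <- stats::setNames(lapply(variables, function(v)
    grep(paste0("^", v, "\\.s\\d+$"), colnames(X))), variables)
  if (geo) {
    gd <- geosphere::distHaversine(cbind(env$lon[i], env$lat[i]),
                                   cbind(env$lon[j], env$lat[j])) / 1000
    gd <- gd / max(gd)
    X <- cbind(X, geographic = gd)
    var_cols$geographic <- ncol(X)
  }
  structure(list(
    pairs = data.frame(site_i = ids[i], site_j = ids[j],
                       response = ab_dissim[cbind(i, j)]),
    X = X, var_cols = var_cols, env = env,
    variables = names(var_cols), n_basis = n_basis),
    class = "site_pair_table")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# binomial-form deviance of responses y against fitted mu (unit weights)
.gdm_deviance <- function(y, mu) {
  eps <- 1e-9
  mu <- pmin(pmax(mu, eps), 1 - eps)
  t1 <- ifelse(y > 0, y * log(y / mu), 0)
  t2 <- ifelse(y < 1, (1 - y) * log((1 - y) / (1 - mu)), 0)
  2 * sum(t1 + t2)
}

# IRLS with non-negative coefficients for d = 1 - exp(-eta), eta = a + Xb
.gdm_irls <- function(X, y, tol = 1e-8, max_iter = 200) {
  Xa <- cbind(intercept = 1, X)
  beta <- rep(0, ncol(Xa))
  beta[1] <- max(-log(1 - min(mean(y), 1 - 1e-6)), 1e-6)
  dev <- Inf
  for (it in seq_len(max_iter)) {
    eta <- as.vector(Xa %*% beta)
    mu <- 1 - exp(-eta)
    mu_eta <- exp(-eta)                       # d mu / d eta
    mu_c <- pmin(pmax(mu, 1e-9), 1 - 1e-9)
    w <- mu_eta^2 / (mu_c * (1 - mu_c))       # binomial variance weights
    z <- eta + (y - mu) / pmax(mu_eta, 1e-9)  # working response
    sw <- sqrt(w)
    fit <- pracma::lsqnonneg(Xa * sw, z * sw)
    beta_new <- fit$x
    dev_new <- .gdm_deviance(y, 1 - exp(-as.vector(Xa %*% beta_new)))
    if (!is.finite(dev_new)) break
    done <- abs(dev - dev_new) < tol
    beta <- beta_new
    dev <- dev_new
    if (done) return(list(beta = beta, deviance = dev, iterations = it,
                          converged = TRUE))
  }
  if (!is.finite(dev))
    stop("GDM IRLS failed to converge: non-finite deviance")
  list(beta = beta, deviance = dev, iterations = max_iter, converged = FALSE)
}

#' Fit a generalized dissimilarity model
#'
#' Fits `d_hat = 1 - exp(-eta)` with `eta = alpha + sum beta * |dBasis|`,
#' all coefficients constrained non-negative, by iteratively reweighted
#' non-negative least squares minimizing the binomial-form deviance of the
#' `[0, 1]` response. Deviance explained is
#' `100 * (1 - dev_model / dev_null)` against the intercept-only model.
#'
#' @param pairs a `site_pair_table` from [build_pair_table()].
#' @return Object of class `gdm_fit`: `intercept`, `coefficients` (named
#'   by predictor column), `importance` (per-variable sum of coefficients,
#'   the partial-curve maximum height), `deviance`, `null_deviance`,
#'   `deviance_explained` (percent), `fitted`, plus the training pair
#'   table.
#' @export
fit_gdm <- function(pairs) {
  y <- pairs$pairs$response
  if (any(y < 0 | y > 1)) stop("responses must lie in [0, 1]")
  X <- pairs$X
  if (all(y == 0)) {
    beta <- rep(0, ncol(X) + 1)
    fit <- list(beta = beta, deviance = 0, iterations = 0, converged = TRUE)
    null_dev <- 0
  } else {
    fit <- .gdm_irls(X, y)
    null_dev <- .gdm_irls(X[, 0, drop = FALSE], y)$deviance
  }
  beta <- fit$beta
  names(beta) <- c("intercept", colnames(X))
  expl <- if (null_dev > 0) 100 * (1 - fit$deviance / null_dev) else 0
  imp <- vapply(pairs$var_cols, function(ix) sum(beta[-1][ix]), numeric(1))
  structure(list(intercept = beta[[1]], coefficients = beta[-1],
                 importance = imp, deviance = fit$deviance,
                 null_deviance = null_dev,
                 deviance_explained = max(expl, 0),
                 fitted = 1 - exp(-as.vector(cbind(1, X) %*% beta)),
                 iterations = fit$iterations, converged = fit$converged,
                 pairs = pairs),
            class = "gdm_fit")
}

#' @export
print.gdm_fit <- function(x, ...) {
  cat("Generalized dissimilarity model\n")
  cat(sprintf("  %d site pairs, deviance explained %.2f%%\n",
              nrow(x$pairs$pairs), x$deviance_explained))
  cat("  variable importance (I-spline max height):\n")
  for (v in names(x$importance))
    cat(sprintf("    %-12s %.4f\n", v, x$importance[[v]]))
  invisible(x)
}

#' Predict pair dissimilarities from a fitted GDM
#'
#' @param object a `gdm_fit`.
#' @param pairs a `site_pair_table` (default: the training table).
#' @param ... unused.
#' @return Predicted dissimilarities in `[0, 1)`.
#' @export
predict.gdm_fit <- function(object, pairs = object$pairs, ...) {
  eta <- object$intercept + as.vector(pairs$X %*% object$coefficients)
  1 - exp(-eta)
}

#' Deviance-explained importance of one variable
#'
#' Refits the model without the variable's basis columns and returns the
#' drop in percent deviance explained (full minus reduced).
#'
#' @param pairs a `site_pair_table`.
#' @param fit the full-model `gdm_fit` (refitted if `NULL`).
#' @param variable variable name.
#' @return Difference in deviance explained (percentage points).
#' @export
variable_importance <- function(pairs, fit = NULL, variable) {
  if (is.null(fit)) fit <- fit_gdm(pairs)
  if (!variable %in% names(pairs$var_cols))
    stop("variable '", variable, "' not in pair table")
  fit$deviance_explained - fit_gdm(.drop_vars(pairs, variable))$deviance_explained
}

# remove variables' predictor columns from a site_pair_table
.drop_vars <- function(pairs, drop) {
  keep <- setdiff(names(pairs$var_cols), drop)
  cols <- unlist(pairs$var_cols[keep], use.names = FALSE)
  out <- pairs
  out$X <- pairs$X[, cols, drop = FALSE]
  out$var_cols <- lapply(pairs$var_cols[keep], function(ix)
    match(ix, cols))
  out$variables <- keep
  out
}

# rebuild one variable's pair-difference columns from permuted site values
.permute_variable <- function(pairs, variable) {
  out <- pairs
  ids <- out$env$site
  i <- match(out$pairs$site_i, ids)
  j <- match(out$pairs$site_j, ids)
  if (variable == "geographic") {
    perm <- sample.int(nrow(out$env))
    lon <- out$env$lon[perm]; lat <- out$env$lat[perm]
    gd <- geosphere::distHaversine(cbind(lon[i], lat[i]),
                                   cbind(lon[j], lat[j])) / 1000
    out$X[, out$var_cols$geographic] <- gd / max(gd)
  } else {
    env_p <- out$env
    env_p[[variable]] <- sample(env_p[[variable]])
    b <- build_basis(env_p, variable, out$n_basis)$basis
    out$X[, out$var_cols[[variable]]] <-
      abs(b[i, , drop = FALSE] - b[j, , drop = FALSE])
  }
  out
}

#' Backward elimination with Monte Carlo permutation tests
#'
#' Iteratively removes uninformative predictors: variables whose
#' deviance-explained importance is at most `threshold` (percentage
#' points) are dropped outright; the rest are tested by permuting the
#' variable's site-level values (rebuilding its pair differences) with
#' `p = (1 + #[imp_perm >= imp_obs]) / (n_perm + 1)`, and non-significant
#' variables are dropped. Repeats until the retained set is stable; only
#' significant variables are retained.
#'
#' @param pairs a `site_pair_table`.
#' @param threshold minimum importance (percentage points of deviance
#'   explained) to even be tested (default 0.5).
#' @param n_perm permutations per test (default 100).
#' @param alpha significance level (default 0.05).
#' @param seed optional integer seed.
#' @return The final `gdm_fit` with extra fields `retained` (variable
#'   names), `p_values` and `importance_history`.
#' @export
backward_eliminate <- function(pairs, threshold = 0.5, n_perm = 100,
                               alpha = 0.05, seed = NULL) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  current <- pairs
  history <- list()
  p_values <- numeric(0)
  repeat {
    vars <- names(current$var_cols)
    if (!length(vars)) break
    fit <- fit_gdm(current)
    imp <- vapply(vars, function(v) variable_importance(current, fit, v),
                  numeric(1))
    history[[length(history) + 1]] <- imp
    weak <- vars[imp <= threshold]
    if (length(weak)) {
      current <- .drop_vars(current, weak)
      next
    }
    p_values <- vapply(vars, function(v) {
      reduced_expl <- fit_gdm(.drop_vars(current, v))$deviance_explained
      imp_perm <- vapply(seq_len(n_perm), function(k) {
        perm <- .permute_variable(current, v)
        fit_gdm(perm)$deviance_explained - reduced_expl
      }, numeric(1))
      (1 + sum(imp_perm >= imp[[v]])) / (n_perm + 1)
    }, numeric(1))
    nonsig <- vars[p_values > alpha]
    if (!length(nonsig)) break
    current <- .drop_vars(current, nonsig)
  }
  fit <- fit_gdm(current)
  fit$retained <- names(current$var_cols)
  fit$p_values <- p_values[intersect(names(p_values), fit$retained)]
  fit$importance_history <- history
  fit
}

#' Partial I-spline response curves
#'
#' For each retained environmental variable, the fitted monotone transform
#' `f(x) = sum_k beta_k I_k(x)` on a grid from the variable's minimum to
#' its maximum. The curve's value at the maximum equals the variable's
#' importance (sum of its coefficients).
#'
#' @param fit a `gdm_fit`.
#' @param env an `env_table` supplying variable ranges (default: the
#'   training table).
#' @param n_points grid size per variable (default 200).
#' @return Data frame with columns `variable`, `x`, `y`.
#' @export
partial_curves <- function(fit, env = fit$pairs$env, n_points = 200) {
  out <- list()
  for (v in setdiff(names(fit$pairs$var_cols), "geographic")) {
    knots <- stats::quantile(fit$pairs$env[[v]],
                             seq(0, 1, length.out = fit$pairs$n_basis),
                             names = FALSE)
    x <- seq(min(env[[v]]), max(env[[v]]), length.out = n_points)
    I <- ispline_eval(x, knots)
    beta <- fit$coefficients[fit$pairs$var_cols[[v]]]
    out[[v]] <- data.frame(variable = v, x = x, y = as.vector(I %*% beta))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
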