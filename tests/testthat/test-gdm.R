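test_that("I-spline basis is monotone with pinned endpoints", {
  env <- default_dataset()$env
  b <- build_basis(env, "MAT")
  expect_equal(ncol(b$basis), 3)
  expect_true(all(b$basis >= 0 & b$basis <= 1))
  # value 0 at the variable's minimum, 1 at its maximum
  expect_equal(unname(b$basis[which.min(env$MAT), ]), rep(0, 3))
  expect_equal(unname(b$basis[which.max(env$MAT), ]), rep(1, 3))
  # finite-difference monotonicity on a dense grid
  knots <- stats::quantile(env$MAT, c(0, 0.5, 1), names = FALSE)
  grid <- seq(min(env$MAT), max(env$MAT), length.out = 1000)
  I <- peatturnover:::ispline_eval(grid, knots)
  expect_true(all(diff(I[, 1]) >= -1e-12))
  expect_true(all(diff(I[, 2]) >= -1e-12))
  expect_true(all(diff(I[, 3]) >= -1e-12))
  # constant variable is rejected
  env2 <- env; env2$MAT <- 1
  expect_error(build_basis(env2, "MAT"), "distinct values")
  expect_error(build_basis(env, "nope"), "unknown variable")
})

test_that("site-pair table has the right combinatorics and distances", {
  ds <- default_dataset()
  env4 <- ds$env[1:4, ]; class(env4) <- class(ds$env)
  bc4 <- bray_curtis(abundance_table(
    filtered_abundance()$values[env4$site, ],
    filtered_abundance()$guild))
  pt <- build_pair_table(bc4, ds$env, c("MAT", "MAP"))
  expect_equal(nrow(pt$pairs), 6)            # 4 choose 2
  expect_equal(ncol(pt$X), 2 * 3 + 1)        # 2 vars x 3 bases + distance
  expect_true(all(pt$X >= 0))
  # geographic column vs an independently coded haversine
  hav <- function(lat1, lon1, lat2, lon2) {
    rad <- pi / 180
    dlat <- (lat2 - lat1) * rad; dlon <- (lon2 - lon1) * rad
    a <- sin(dlat / 2)^2 + cos(lat1 * rad) * cos(lat2 * rad) *
      sin(dlon / 2)^2
    6378137 * 2 * atan2(sqrt(a), sqrt(1 - a)) / 1000
  }
  e <- pt$env
  i <- match(pt$pairs$site_i, e$site); j <- match(pt$pairs$site_j, e$site)
  gd <- hav(e$lat[i], e$lon[i], e$lat[j], e$lon[j])
  expect_equal(unname(pt$X[, "geographic"]), gd / max(gd),
               tolerance = 1e-6)
  # identical environments give all-zero predictor entries for the pair
  env_id <- ds$env[1:4, ]; env_id[2, -1] <- env_id[1, -1]
  class(env_id) <- class(ds$env)
  dm <- matrix(0.5, 4, 4, dimnames = list(env_id$site, env_id$site))
  diag(dm) <- 0
  pt_id <- build_pair_table(dm, env_id, c("MAT", "MAP"), geo = FALSE)
  row12 <- which(pt_id$pairs$site_i == env_id$site[1] &
                   pt_id$pairs$site_j == env_id$site[2])
  expect_equal(unname(pt_id$X[row12, ]), rep(0, 6))
  # mismatched ids error
  dm_bad <- dm; rownames(dm_bad) <- colnames(dm_bad) <- c("w", "x", "y", "z")
  expect_error(build_pair_table(dm_bad, env_id, "MAT"), "do not match")
})

test_that("GDM recovers a model it generated and predicts inside [0, 1)", {
  ds <- default_dataset()
  bc <- bray_curtis(filtered_abundance())
  pt <- build_pair_table(bc, ds$env, c("MAT", "MAP"), geo = FALSE)
  beta_true <- c(0.3, 0.5, 0.2, 0.4, 0, 0.6)
  y <- 1 - exp(-(0.1 + as.vector(pt$X %*% beta_true)))
  pt_sim <- pt; pt_sim$pairs$response <- y
  fit <- fit_gdm(pt_sim)
  expect_gt(fit$deviance_explained, 99)
  expect_equal(unname(fit$coefficients), beta_true, tolerance = 1e-3)
  expect_equal(fit$intercept, 0.1, tolerance = 1e-3)
  expect_true(all(fit$fitted >= 0 & fit$fitted < 1))
  expect_true(all(predict(fit) >= 0 & predict(fit) < 1))
  # importance is the sum of each variable's coefficients
  expect_equal(unname(fit$importance["MAT"]), sum(beta_true[1:3]),
               tolerance = 1e-3)
  # constant-zero response: null model, zero coefficients
  pt0 <- pt; pt0$pairs$response <- rep(0, nrow(pt0$pairs))
  fit0 <- fit_gdm(pt0)
  expect_equal(unname(fit0$coefficients), rep(0, 6))
  expect_equal(fit0$deviance_explained, 0)
  # out-of-range response rejected
  ptb <- pt; ptb$pairs$response[1] <- 1.2
  expect_error(fit_gdm(ptb), "\\[0, 1\\]")
})

test_that("deviance explained is invariant to site relabelling", {
  ds <- default_dataset()
  ab <- filtered_abundance()
  bc <- bray_curtis(ab)
  pt <- build_pair_table(bc, ds$env, c("MAT", "MAP"))
  fit <- fit_gdm(pt)
  ord <- rev(seq_len(nrow(bc)))
  bc2 <- bc[ord, ord]
  fit2 <- fit_gdm(build_pair_table(bc2, ds$env, c("MAT", "MAP")))
  expect_equal(fit$deviance_explained, fit2$deviance_explained,
               tolerance = 1e-6)
})

test_that("variable importance equals a brute-force refit difference", {
  ds <- default_dataset()
  bc <- bray_curtis(filtered_abundance())
  pt <- build_pair_table(bc, ds$env, c("MAT", "TS", "MAP"), geo = FALSE)
  fit <- fit_gdm(pt)
  for (v in c("MAT", "MAP")) {
    reduced <- fit_gdm(build_pair_table(bc, ds$env,
                                        setdiff(c("MAT", "TS", "MAP"), v),
                                        geo = FALSE))
    expect_equal(variable_importance(pt, fit, v),
                 fit$deviance_explained - reduced$deviance_explained,
                 tolerance = 1e-6)
  }
  # a variable whose coefficients are zero contributes ~ nothing
  zero_vars <- names(fit$importance)[fit$importance < 1e-8]
  for (v in zero_vars)
    expect_lt(abs(variable_importance(pt, fit, v)), 0.05)
  expect_error(variable_importance(pt, fit, "PS"), "not in pair table")
})

test_that("backward elimination keeps signal, drops noise, obeys threshold", {
  set.seed(31)
  cfg <- synth_config(n_sites = 30, seed = 31)
  ds <- generate_dataset(cfg)
  env <- ds$env
  env$noisevar <- stats::rnorm(30)
  class(env) <- class(ds$env)
  bc <- bray_curtis(suppressMessages(filter_rare_species(ds$abundance, 3)))
  pt <- build_pair_table(bc, env, c("MAT", "noisevar"), geo = FALSE)
  sel <- backward_eliminate(pt, n_perm = 30, seed = 1)
  expect_true("MAT" %in% sel$retained)
  expect_false("noisevar" %in% sel$retained)
  expect_lte(sel$p_values[["MAT"]], 0.05)
  # threshold above any attainable importance drops everything
  sel_all <- backward_eliminate(pt, threshold = 100, n_perm = 5, seed = 1)
  expect_length(sel_all$retained, 0)
  expect_equal(ncol(sel_all$pairs$X), 0)
})

test_that("null permutation p-values control the type-I error rate", {
  # response independent of the predictor: p-values over many simulated
  # datasets must not be anticonservative at working significance levels
  set.seed(32)
  n <- 14
  lat <- runif(n, 43, 68); lon <- runif(n, -8, 25)
  pvals <- vapply(1:150, function(r) {
    env <- data.frame(site = paste0("s", 1:n), MAT = rnorm(n), TS = rnorm(n),
                      MAP = rnorm(n), PS = rnorm(n), PTwarm = runif(n, 5, 30),
                      SOx = runif(n), NHx = runif(n), NOy = runif(n),
                      lat = lat, lon = lon)
    env <- env_table(env)
    dm <- matrix(0, n, n, dimnames = list(env$site, env$site))
    dm[upper.tri(dm)] <- runif(n * (n - 1) / 2, 0.2, 0.8)
    dm <- dm + t(dm)
    pt <- build_pair_table(dm, env, "MAT", geo = FALSE)
    fit <- fit_gdm(pt)
    imp <- variable_importance(pt, fit, "MAT")
    reduced <- fit_gdm(peatturnover:::.drop_vars(pt, "MAT"))
    imp_perm <- vapply(1:19, function(k) {
      perm <- peatturnover:::.permute_variable(pt, "MAT")
      fit_gdm(perm)$deviance_explained - reduced$deviance_explained
    }, numeric(1))
    (1 + sum(imp_perm >= imp)) / 20
  }, numeric(1))
  # the non-negativity constraint leaves an atom of zero importances, so
  # null p-values are conservative rather than exactly uniform; what must
  # hold is type-I control at the usual working levels
  for (alpha in c(0.05, 0.1, 0.2)) {
    margin <- 2 * sqrt(alpha * (1 - alpha) / length(pvals))
    expect_lte(mean(pvals <= alpha), alpha + margin)
  }
  expect_true(all(pvals > 0 & pvals <= 1))
})

test_that("partial curves are monotone and top out at the importance", {
  ds <- default_dataset()
  bc <- bray_curtis(filtered_abundance())
  pt <- build_pair_table(bc, ds$env, c("MAT", "MAP", "PS"))
  fit <- fit_gdm(pt)
  pc <- partial_curves(fit)
  for (v in c("MAT", "MAP", "PS")) {
    cv <- pc[pc$variable == v, ]
    expect_true(all(diff(cv$y) >= -1e-10))
    expect_equal(cv$y[1], 0, tolerance = 1e-10)
    expect_equal(cv$y[nrow(cv)], unname(fit$importance[[v]]),
                 tolerance = 1e-8)
  }
  # a zero-coefficient variable yields a flat zero curve
  flat_vars <- setdiff(names(fit$importance)[fit$importance < 1e-10],
                       "geographic")
  for (v in flat_vars)
    expect_true(all(pc$y[pc$variable == v] == 0))
})
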