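# small-sample-corrected AIC for an lm fit
.aicc <- function(fit) {
  n <- stats::nobs(fit)
  k <- length(stats::coef(fit)) + 1   # + residual variance
  if (n - k - 1 <= 0) return(Inf)
  stats::AIC(fit) + 2 * k * (k + 1) / (n - k - 1)
}

#' Bidirectional stepwise regression by AICc
#'
#' Selects environmental predictors for a per-site response by greedy
#' bidirectional search on the small-sample-corrected information
#' criterion, starting from the intercept-only model. Effectively
#' collinear predictor pairs (|r| > 0.99, including duplicated columns)
#' are reduced to one with a warning, and the candidate count is capped so
#' the design stays over-determined at every step.
#'
#' @param response named numeric vector of per-site values.
#' @param env an `env_table` (sites matched by name against `response`).
#' @param variables candidate variable names (default: all environmental
#'   columns plus coordinates).
#' @return Object of class `regression_report`: `selected` (named signed
#'   coefficients, intercept excluded), `r_squared`, `f_statistic`, `df`,
#'   `p_value`, `aicc`, and the final `model`.
#' @export
stepwise_regression <- function(response, env,
                                variables = c(.env_columns)) {
  env <- env[match(names(response), env$site), ]
  dat <- data.frame(.y = as.numeric(response),
                    env[, variables, drop = FALSE])
  # drop near-duplicate predictors
  keep <- variables
  cm <- suppressWarnings(stats::cor(dat[, keep, drop = FALSE]))
  drop <- character(0)
  for (a in seq_along(keep)) for (b in seq_len(a - 1)) {
    if (isTRUE(abs(cm[a, b]) > 0.99) && !(keep[a] %in% drop) &&
        !(keep[b] %in% drop)) drop <- c(drop, keep[a])
  }
  if (length(drop)) {
    warning("dropping collinear predictor(s): ", paste(drop, collapse = ", "))
    keep <- setdiff(keep, drop)
  }
  n <- nrow(dat)
  max_terms <- n - 3   # keep residual df at every step
  current <- character(0)
  fit <- stats::lm(.y ~ 1, data = dat)
  best <- .aicc(fit)
  repeat {
    moves <- list()
    if (length(current) < max_terms)
      for (v in setdiff(keep, current))
        moves[[paste0("+", v)]] <- c(current, v)
    for (v in current)
      moves[[paste0("-", v)]] <- setdiff(current, v)
    if (!length(moves)) break
    scores <- vapply(moves, function(vars) {
      f <- if (length(vars))
        stats::lm(stats::reformulate(vars, ".y"), data = dat)
      else stats::lm(.y ~ 1, data = dat)
      .aicc(f)
    }, numeric(1))
    if (min(scores) >= best - 1e-10) break
    mv <- names(scores)[which.min(scores)]
    current <- moves[[mv]]
    best <- min(scores)
    fit <- if (length(current))
      stats::lm(stats::reformulate(current, ".y"), data = dat)
    else stats::lm(.y ~ 1, data = dat)
  }
  sm <- summary(fit)
  fstat <- sm$fstatistic
  structure(list(
    selected = if (length(current)) stats::coef(fit)[-1] else numeric(0),
    r_squared = sm$r.squared,
    f_statistic = if (!is.null(fstat)) unname(fstat[1]) else NA_real_,
    df = if (!is.null(fstat)) unname(fstat[2:3]) else c(0, n - 1),
    p_value = if (!is.null(fstat))
      stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
    else NA_real_,
    aicc = best, model = fit), class = "regression_report")
}

#' @export
print.regression_report <- function(x, ...) {
  cat("stepwise regression (AICc):",
      if (length(x$selected)) paste(names(x$selected), collapse = " + ")
      else "intercept only", "\n")
  if (length(x$selected))
    cat(sprintf("  R2 = %.3f, F(%d,%d) = %.2f, p = %.3g\n", x$r_squared,
                x$df[1], x$df[2], x$f_statistic, x$p_value))
  invisible(x)
}

#' Univariate FR-environment relations in report layout
#'
#' For every guild x group x variable combination, fits the univariate
#' linear model `FR ~ variable` and reports the F statistic, its p-value
#' and the signed correlation r (so that `r^2` equals the model's R
#' squared). Groups with constant FR get `F = 0`, `r = 0`, `p = 1`.
#'
#' @param fr data frame with columns `site`, `guild`, `group` (e.g.
#'   `"community"`, `"I"`, `"II"`) and `fr`.
#' @param env an `env_table`.
#' @param variables environmental variable names to test.
#' @return Data frame with columns `guild`, `group`, `variable`,
#'   `f_value`, `p_value`, `r`, `df1`, `df2`.
#' @export
fr_env_models <- function(fr, env, variables) {
  stopifnot(all(c("site", "guild", "group", "fr") %in% names(fr)))
  out <- list()
  for (g in unique(fr$guild)) for (grp in unique(fr$group[fr$guild == g])) {
    sub <- fr[fr$guild == g & fr$group == grp, ]
    e <- env[match(sub$site, env$site), ]
    for (v in variables) {
      if (stats::sd(sub$fr) == 0) {
        row <- data.frame(guild = g, group = grp, variable = v,
                          f_value = 0, p_value = 1, r = 0,
                          df1 = 1, df2 = nrow(sub) - 2)
      } else {
        m <- stats::lm(sub$fr ~ e[[v]])
        sm <- summary(m)
        fstat <- sm$fstatistic
        r <- sign(stats::coef(m)[2]) * sqrt(sm$r.squared)
        row <- data.frame(guild = g, group = grp, variable = v,
                          f_value = unname(fstat[1]),
                          p_value = stats::pf(fstat[1], fstat[2], fstat[3],
                                              lower.tail = FALSE),
                          r = unname(r), df1 = unname(fstat[2]),
                          df2 = unname(fstat[3]))
      }
      out[[length(out) + 1]] <- row
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Per-site, per-group functional redundancy table
#'
#' Convenience builder for [fr_env_models()]: computes site-level FR for
#' the whole guild community and within each co-response cluster.
#'
#' @param ab an `abundance_table` restricted to one guild.
#' @param traits the guild's `trait_table`.
#' @param clusters a `cluster_assignment` or membership vector.
#' @param guild guild label for the output.
#' @return Data frame with columns `site`, `guild`, `group`, `fr`.
#' @export
fr_by_group <- function(ab, traits, clusters, guild) {
  membership <- if (inherits(clusters, "cluster_assignment"))
    clusters$membership else clusters
  d <- gower_dissimilarity(traits[taxa(ab), , drop = FALSE])
  groups <- list(community = taxa(ab))
  for (cl in setdiff(unique(membership), "unrelated"))
    groups[[cl]] <- intersect(names(membership)[membership == cl], taxa(ab))
  out <- list()
  for (grp in names(groups)) {
    ids <- groups[[grp]]
    if (length(ids) < 2) next
    v <- ab$values[, ids, drop = FALSE]
    keep <- rowSums(v) > 0
    fr <- functional_redundancy(v[keep, , drop = FALSE],
                                d[ids, ids, drop = FALSE])
    out[[grp]] <- data.frame(site = names(fr), guild = guild, group = grp,
                             fr = unname(fr))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
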