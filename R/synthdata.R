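#' Configuration for the synthetic bog-survey generator
#'
#' Parameterizes a synthetic dataset with the statistical structure the
#' turnover analysis assumes: two species clusters with opposite abundance
#' responses along a climate composite, cluster-unrelated species, rare
#' species that trip the occupancy filter, and guild-specific trait tables
#' whose cluster means differ only slightly so functional composition
#' overlaps strongly between clusters.
#'
#' @param n_sites number of sites (default 56).
#' @param n_species_per_cluster species per co-response cluster (default 25).
#' @param n_unrelated cluster-unrelated species (default 9).
#' @param n_rare additional rare species occupying fewer than 5 sites
#'   (default 4).
#' @param env_effect magnitude of the cluster response slope on the climate
#'   composite; cluster I gets `-env_effect`, cluster II `+env_effect`
#'   (default 1).
#' @param trait_shift between-cluster trait-mean offset in within-cluster SD
#'   units (default 0.5).
#' @param noise_sd log-scale SD of abundance noise (default 0.9).
#' @param seed integer seed fixing all randomness (default 1).
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_sites = 56, n_species_per_cluster = 25,
                         n_unrelated = 9, n_rare = 4, env_effect = 1,
                         trait_shift = 0.5, noise_sd = 0.9, seed = 1) {
  stopifnot(n_sites >= 1, n_species_per_cluster >= 1, n_unrelated >= 0,
            n_rare >= 0, noise_sd > 0, trait_shift >= 0)
  seed <- as.integer(seed)
  structure(list(n_sites = n_sites,
                 n_species_per_cluster = n_species_per_cluster,
                 n_unrelated = n_unrelated, n_rare = n_rare,
                 env_effect = env_effect, trait_shift = trait_shift,
                 noise_sd = noise_sd, seed = seed),
            class = "synth_config")
}

#' Generate a synthetic site-by-environment table
#'
#' Sites are scattered over a European-like window. Mean annual temperature
#' decreases with latitude, temperature seasonality increases with it,
#' precipitation follows a west-east/oceanic gradient, and the three
#' deposition variables share a longitudinal trend with independent noise
#' (so they correlate with each other but not perfectly with climate). The
#' warm-quarter moisture index is computed from generated warm-quarter
#' surrogates via [moisture_index()].
#'
#' Stream order (all draws from the single seeded generator): coordinates,
#' then each climate variable in canonical column order, then deposition.
#'
#' @param config a [synth_config()].
#' @return An `env_table` with `config$n_sites` rows.
#' @export
generate_environment <- function(config) {
  n <- config$n_sites
  if (n < 3) stop("need at least 3 sites")
  set.seed(config$seed)
  lat <- stats::runif(n, 43, 68)
  lon <- stats::runif(n, -8, 25)
  MAT <- 18 - 0.28 * lat + stats::rnorm(n, 0, 1)          # degC
  TS  <- 2 + 0.09 * (lat - 43) + 0.05 * (lon + 8) + stats::rnorm(n, 0, 0.6)
  MAP <- 1600 - 18 * (lon + 8) - 8 * (lat - 43) + stats::rnorm(n, 0, 120)
  MAP <- pmax(MAP, 300)
  PS  <- stats::runif(n, 10, 45)
  T_warm <- MAT + 9 + stats::rnorm(n, 0, 0.7)             # warmest quarter
  P_warm <- MAP / 4 + stats::rnorm(n, 0, 25)
  P_warm <- pmax(P_warm, 30)
  dep_grad <- (lon - min(lon)) / diff(range(lon))
  SOx <- 200 + 700 * dep_grad + stats::rnorm(n, 0, 120)
  NHx <- 150 + 600 * dep_grad + stats::rnorm(n, 0, 110)
  NOy <- 120 + 500 * dep_grad + stats::rnorm(n, 0, 100)
  env_table(data.frame(
    site = sprintf("site_%02d", seq_len(n)),
    MAT = MAT, TS = TS, MAP = MAP, PS = PS,
    PTwarm = moisture_index(P_warm, T_warm),
    SOx = pmax(SOx, 0), NHx = pmax(NHx, 0), NOy = pmax(NOy, 0),
    lat = lat, lon = lon))
}

#' Standardized climate composite driving species responses
#'
#' First principal axis of standardized MAT, MAP and -TS, scaled to unit SD
#' and signed so that it correlates positively with MAT.
#'
#' @param env an `env_table`.
#' @return Numeric vector of composite scores, one per site, SD 1.
#' @export
climate_composite <- function(env) {
  m <- scale(cbind(env$MAT, env$MAP, -env$TS))
  g <- stats::prcomp(m, center = FALSE, scale. = FALSE)$x[, 1]
  if (stats::cor(g, env$MAT) < 0) g <- -g
  as.vector(scale(g))
}

# deterministic species layout for a config: ids, cluster truth, response
# slopes and guild labels (both guilds alternate inside every block)
.species_layout <- function(config) {
  npc <- config$n_species_per_cluster
  ids <- c(sprintf("cl1_sp%02d", seq_len(npc)),
           sprintf("cl2_sp%02d", seq_len(npc)),
           if (config$n_unrelated)
             sprintf("unrel_sp%02d", seq_len(config$n_unrelated)),
           if (config$n_rare) sprintf("rare_sp%02d", seq_len(config$n_rare)))
  S <- length(ids)
  blocks <- c(npc, npc, config$n_unrelated, config$n_rare)
  truth <- stats::setNames(rep(c("I", "II", "unrelated", "unrelated"),
                               blocks), ids)
  slope <- stats::setNames(rep(c(-1, 1, 0, 0) * config$env_effect, blocks),
                           ids)
  guild <- stats::setNames(rep("vascular", S), ids)
  guild[seq(2, S, by = 2)] <- "bryophyte"
  # every 5th cluster member is a core dominant: ubiquitous, high cover,
  # trait syndrome near the bog optimum (the Sphagnum-carpet / dwarf-shrub
  # tier of the real vegetation); the rest are occasional species
  core <- stats::setNames(rep(FALSE, S), ids)
  core[seq_len(2 * npc)][(seq_len(2 * npc) - 1) %% 5 == 0] <- TRUE
  list(ids = ids, truth = truth, slope = slope, guild = guild, core = core)
}

# strength of the microhabitat trait-matching term (see generate_abundances)
.match_strength <- 0.35

# standardized per-species mean quantitative trait score, by guild
.trait_score <- function(traits, guild) {
  score <- stats::setNames(rep(0, length(guild)), names(guild))
  for (tab in traits) {
    quant <- vapply(tab, is.numeric, logical(1))
    z <- scale(as.matrix(tab[, quant, drop = FALSE]))
    s <- rowMeans(z)
    score[rownames(tab)] <- as.vector(scale(s))
  }
  score
}

#' Generate synthetic species abundances along the climate composite
#'
#' Each species in cluster I (II) has expected log-abundance
#' `a_s - b*g(site)` (`a_s + b*g(site)`) where `g` is the
#' [climate_composite()] and `b = env_effect`; unrelated and rare species
#' have slope zero. When trait tables are supplied (as [generate_dataset()]
#' does), a trait-matching term `0.35 t_s h_i` is added, where `h` is a
#' latent microhabitat axis per site (iid, independent of the measured
#' environment: the hummock/lawn mosaic the field protocol samples) and
#' `t_s` the species' standardized trait-syndrome score: co-occurring
#' species are functionally more similar than random draws from the pool
#' (the look-a-like assembly of the turnover story), while the axis
#' driving that convergence stays invisible to the environmental tables.
#' Observed abundance is lognormal noise around the expectation, set to
#' zero below a unit-cover hurdle so occupancy varies; rare species are
#' then thinned to fewer than 5 occupied sites.
#'
#' Stream order: microhabitat axis (sites), baseline log-abundances
#' (species), noise matrix (site-major), rare-species site thinning.
#'
#' @param env an `env_table` generated for the same config.
#' @param config a [synth_config()].
#' @param traits optional list with `traits_vascular` and
#'   `traits_bryophyte` (enables the trait-based assembly term).
#' @return List with `abundance` (an `abundance_table`) and `true_cluster`
#'   (named character, values `"I"`, `"II"` or `"unrelated"`).
#' @export
generate_abundances <- function(env, config, traits = NULL) {
  if (config$env_effect == 0)
    warning("env_effect = 0: clusters are undetectable (degenerate design)")
  g <- climate_composite(env)
  n <- config$n_sites
  lay <- .species_layout(config)
  ids <- lay$ids; S <- length(ids)
  truth <- lay$truth
  slope <- lay$slope
  guild <- lay$guild
  tscore <- if (is.null(traits)) rep(0, S) else .trait_score(traits, guild)
  set.seed(config$seed + 1L)
  # species baselines tuned to the survey's occupancy statistics: with the
  # unit-cover hurdle below, a cluster species is present at roughly a
  # quarter of the sites, giving site richness near 7 vascular + 5
  # bryophyte taxa and strong cluster sorting of sites along the gradient.
  h <- stats::rnorm(n)   # latent microhabitat axis (hummock/lawn mosaic)
  # role-specific baselines: core dominants carry high cover everywhere;
  # occasional cluster species turn over along the gradient; unrelated
  # (slope-free) species sit slightly higher so noise alone keeps their
  # occupancy above the rare-species filter
  mu0 <- ifelse(lay$core, 1.5, ifelse(truth == "unrelated", -0.6, -1.2))
  sd0 <- ifelse(lay$core, 0.3, 0.4)
  a0 <- stats::rnorm(S, mu0, sd0)
  eta <- outer(g, slope) + .match_strength * outer(h, tscore) +
    rep(a0, each = n)
  vals <- exp(eta + stats::rnorm(n * S, 0, config$noise_sd))
  vals[vals < 1] <- 0  # hurdle: cover below 1 (percent-like units) -> absent
  dimnames(vals) <- list(env$site, ids)
  if (config$n_rare) {
    rare <- ids[truth == "unrelated"][seq_len(config$n_rare) +
                                        config$n_unrelated]
    for (sp in rare) {
      occ <- which(vals[, sp] > 0)
      if (!length(occ)) {
        vals[sample.int(n, 2), sp] <- 1  # guarantee presence
        next
      }
      n_keep <- min(length(occ), sample(2:4, 1))
      drop <- setdiff(occ, occ[sample.int(length(occ), n_keep)])
      vals[drop, sp] <- 0
    }
  }
  list(abundance = abundance_table(vals, guild), true_cluster = truth)
}

#' Generate guild-specific synthetic trait tables
#'
#' Vascular plants get five quantitative traits (specific leaf area, canopy
#' height, leaf dry matter content, seed mass, seed number) and a
#' categorical life form; bryophytes get eight quantitative traits (plant
#' length, spore diameter, capsule diameter, productivity, tissue N, tissue
#' P, stem width, stem-leaf length). Cluster I and II means differ by
#' `trait_shift` within-cluster SDs (offset split symmetrically), so the
#' between-cluster trait distributions overlap strongly; unrelated species
#' draw from the pooled mean.
#'
#' @param true_cluster named character vector from [generate_abundances()].
#' @param guild named character vector of guild labels per taxon.
#' @param config a [synth_config()].
#' @return List with `traits_vascular` and `traits_bryophyte`
#'   (`trait_table`s).
#' @export
generate_traits <- function(true_cluster, guild, config) {
  set.seed(config$seed + 2L)
  shift <- config$trait_shift
  offs <- function(cl) ifelse(cl == "I", -shift / 2,
                              ifelse(cl == "II", shift / 2, 0))
  # traits load on one stress-tolerance syndrome axis per species (the
  # leaf-economics-style covariation real trait tables show); loading 0.8
  # leaves each trait 36% idiosyncratic variance. The cluster offset acts
  # on the syndrome, so each trait's standardized mean difference is
  # 0.8 * trait_shift.
  lambda <- 0.8
  vasc <- names(guild)[guild == "vascular"]
  bryo <- names(guild)[guild == "bryophyte"]
  # core dominants hug the bog-wide trait optimum; occasional species
  # spread more widely (overall syndrome SD stays near 1)
  core <- .species_layout(config)$core[names(guild)]
  core[is.na(core)] <- FALSE
  u <- stats::setNames(stats::rnorm(length(guild),
                                    ifelse(core, 0, offs(true_cluster)),
                                    ifelse(core, 0.3, 1.15)), names(guild))
  # each trait's between-cluster mean offset is enforced exactly at
  # trait_shift within-cluster SDs, with the direction alternating from
  # trait to trait (real cluster contrasts point both ways: one cluster's
  # species can be shorter yet have higher SLA). The adjustment shifts
  # cluster means only, so within-cluster variances and the syndrome
  # covariance are untouched.
  sign_counter <- local({ k <- 0L; function() { k <<- k + 1L
    if (k %% 2L) 1 else -1 } })
  make_quant <- function(ids, mu, sd) {
    raw <- mu + sd * (lambda * u[ids] +
                        sqrt(1 - lambda^2) * stats::rnorm(length(ids)))
    cl <- true_cluster[ids]
    i1 <- cl == "I"; i2 <- cl == "II"
    if (any(i1) && any(i2)) {
      s_pool <- sqrt((stats::var(raw[i1]) + stats::var(raw[i2])) / 2)
      target <- sign_counter() * shift * s_pool
      delta <- (target - (mean(raw[i2]) - mean(raw[i1]))) / 2
      raw[i2] <- raw[i2] + delta
      raw[i1] <- raw[i1] - delta
    }
    raw
  }
  tv <- data.frame(
    SLA = make_quant(vasc, 15, 4),          # mm2/mg
    height = make_quant(vasc, 25, 8),       # cm
    LDMC = make_quant(vasc, 280, 60),       # mg/g
    seed_mass = make_quant(vasc, 0.4, 0.15),# mg
    seed_number = make_quant(vasc, 900, 300),
    row.names = vasc)
  clv <- true_cluster[vasc]
  lf_levels <- c("chamaephyte", "hemicryptophyte", "graminoid")
  pr <- t(vapply(clv, function(cl) {
    if (cl == "I") c(0.45, 0.35, 0.2) + c(-1, 1, 0) * 0.1 * shift
    else if (cl == "II") c(0.45, 0.35, 0.2) + c(1, -1, 0) * 0.1 * shift
    else c(0.45, 0.35, 0.2)
  }, numeric(3)))
  tv$life_form <- factor(vapply(seq_along(vasc), function(i)
    sample(lf_levels, 1, prob = pr[i, ]), character(1)), levels = lf_levels)
  tb <- data.frame(
    plant_length = make_quant(bryo, 8, 2.5),   # cm
    spore_diameter = make_quant(bryo, 28, 6),  # um
    capsule_diameter = make_quant(bryo, 1.6, 0.4),
    productivity = make_quant(bryo, 250, 70),  # g m-2 yr-1
    tissue_N = make_quant(bryo, 8, 2),         # mg/g
    tissue_P = make_quant(bryo, 0.7, 0.2),
    stem_width = make_quant(bryo, 0.8, 0.25),  # mm
    leaf_length = make_quant(bryo, 1.4, 0.35),
    row.names = bryo)
  list(traits_vascular = trait_table(tv), traits_bryophyte = trait_table(tb))
}

#' Generate a complete synthetic dataset
#'
#' Composes [generate_environment()], [generate_traits()] and
#' [generate_abundances()] (traits drawn first so the trait-based assembly
#' term can act). All randomness flows from `config$seed` through
#' fixed per-stage offsets, so a given config is bitwise reproducible and
#' the site table does not change when species counts do.
#'
#' @param config a [synth_config()] (default: defaults).
#' @return List of class `synth_dataset` with elements `abundance`,
#'   `traits_vascular`, `traits_bryophyte`, `env`, `true_cluster` and
#'   `config`.
#' @export
generate_dataset <- function(config = synth_config()) {
  env <- generate_environment(config)
  lay <- .species_layout(config)
  tr <- generate_traits(lay$truth, lay$guild, config)
  ab <- generate_abundances(env, config, traits = tr)
  structure(list(abundance = ab$abundance,
                 traits_vascular = tr$traits_vascular,
                 traits_bryophyte = tr$traits_bryophyte,
                 env = env, true_cluster = ab$true_cluster,
                 config = config),
            class = "synth_dataset")
}

#' Write a synthetic dataset to a directory of CSV files
#'
#' Emits `abundance.csv`, `guild.csv`, `traits_vascular.csv`,
#' `traits_bryophyte.csv`, `env.csv` and `true_cluster.csv`.
#'
#' @param ds a `synth_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_abundance(ds$abundance, file.path(dir, "abundance.csv"),
                  file.path(dir, "guild.csv"))
  write_traits(ds$traits_vascular, file.path(dir, "traits_vascular.csv"))
  write_traits(ds$traits_bryophyte, file.path(dir, "traits_bryophyte.csv"))
  write_env(ds$env, file.path(dir, "env.csv"))
  .write_csv(data.frame(taxon = names(ds$true_cluster),
                        cluster = unname(ds$true_cluster)),
             file.path(dir, "true_cluster.csv"))
  invisible(dir)
}
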