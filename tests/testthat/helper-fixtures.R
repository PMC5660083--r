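# shared fixtures, all built in code

# small deterministic community: 4 sites x 5 taxa, two guilds
toy_abundance <- function() {
  v <- matrix(c(4, 0, 1, 2, 0,
                2, 2, 0, 1, 1,
                0, 3, 3, 0, 2,
                1, 1, 2, 3, 0),
              nrow = 4, byrow = TRUE,
              dimnames = list(paste0("s", 1:4), paste0("sp", 1:5)))
  abundance_table(v, c(sp1 = "vascular", sp2 = "vascular", sp3 = "vascular",
                       sp4 = "bryophyte", sp5 = "bryophyte"))
}

# random abundance table with guaranteed non-empty sites
random_abundance <- function(n_sites, n_taxa, fill = 0.6) {
  v <- matrix(stats::rexp(n_sites * n_taxa), n_sites, n_taxa,
              dimnames = list(paste0("s", seq_len(n_sites)),
                              paste0("sp", seq_len(n_taxa))))
  v[stats::runif(length(v)) > fill] <- 0
  empty <- rowSums(v) == 0
  v[cbind(which(empty), sample.int(n_taxa, sum(empty), replace = TRUE))] <- 1
  abundance_table(v, stats::setNames(rep(c("vascular", "bryophyte"),
                                         length.out = n_taxa),
                                     colnames(v)))
}

# random mixed trait table aligned to taxa ids
random_traits <- function(taxa_ids, n_quant = 3, n_cat = 1) {
  df <- as.data.frame(matrix(stats::rnorm(length(taxa_ids) * n_quant),
                             ncol = n_quant))
  names(df) <- paste0("q", seq_len(n_quant))
  for (j in seq_len(n_cat))
    df[[paste0("c", j)]] <- factor(sample(letters[1:3], length(taxa_ids),
                                          replace = TRUE))
  rownames(df) <- taxa_ids
  trait_table(df)
}

# memoized default synthetic dataset (expensive pieces computed once)
.fixtures <- new.env(parent = emptyenv())

default_dataset <- function() {
  if (is.null(.fixtures$ds))
    .fixtures$ds <- generate_dataset(synth_config())
  .fixtures$ds
}

filtered_abundance <- function() {
  if (is.null(.fixtures$ab))
    .fixtures$ab <- suppressMessages(filter_rare_species(
      default_dataset()$abundance))
  .fixtures$ab
}

# brute-force oracles, written independently of the package internals
brute_simpson <- function(x) {
  p <- x / sum(x)
  1 - sum(p^2)
}

brute_rao <- function(x, d) {
  p <- x / sum(x)
  tot <- 0
  for (i in seq_along(p)) for (j in seq_along(p))
    tot <- tot + p[i] * p[j] * d[i, j]
  unname(tot)
}

brute_bray <- function(x, y) sum(abs(x - y)) / sum(x + y)

brute_gower <- function(tr) {
  n <- nrow(tr)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    acc <- 0; used <- 0
    for (k in seq_along(tr)) {
      v <- tr[[k]]
      if (is.numeric(v)) {
        rng <- max(v) - min(v)
        if (rng == 0) next
        acc <- acc + abs(v[i] - v[j]) / rng
      } else acc <- acc + as.numeric(v[i] != v[j])
      used <- used + 1
    }
    out[i, j] <- acc / used
  }
  dimnames(out) <- list(rownames(tr), rownames(tr))
  out
}

brute_cwm <- function(x, tvals) {
  p <- x / sum(x)
  sum(p * tvals)
}

# Jost-corrected functional beta for one site pair, from first principles
brute_funcbeta <- function(x, y, d) {
  px <- x / sum(x); py <- y / sum(y)
  pool <- (px + py) / 2
  qg <- brute_rao(pool, d)   # pool sums to 1
  qx <- brute_rao(px, d); qy <- brute_rao(py, d)
  qa <- (qx + qy) / 2
  max((qg - qa) / (1 - qa), 0)
}
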