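test_that("Gini-Simpson diversity matches the closed form and its limits", {
  # single species -> 0; an even 50/50 pair -> 0.5
  one <- matrix(c(3), 1, 1, dimnames = list("s1", "sp1"))
  expect_equal(unname(simpson_d(one)), 0)
  pair <- matrix(c(2, 2), 1, 2, dimnames = list("s1", c("a", "b")))
  expect_equal(unname(simpson_d(pair)), 0.5)
  # random sites vs brute force
  set.seed(11)
  for (r in 1:20) {
    x <- stats::rexp(6)
    m <- matrix(x, 1, 6, dimnames = list("s", paste0("sp", 1:6)))
    expect_equal(unname(simpson_d(m)), brute_simpson(x))
  }
  empty <- matrix(0, 1, 2, dimnames = list("s1", c("a", "b")))
  expect_error(simpson_d(empty), "empty site")
})

test_that("CWM is the abundance-weighted trait mean with categorical shares", {
  tr <- trait_table(data.frame(q = c(2, 4), c = factor(c("x", "y")),
                               row.names = c("a", "b")))
  m <- matrix(c(1, 1), 1, 2, dimnames = list("s1", c("a", "b")))
  out <- cwm(m, tr)
  expect_equal(out$q, 3)              # 0.5/0.5 with traits 2 and 4
  expect_equal(out$c.x, 0.5)
  expect_equal(out$c.y, 0.5)
  # single species -> its trait value
  m1 <- matrix(5, 1, 1, dimnames = list("s1", "a"))
  expect_equal(cwm(m1, tr)$q, 2)
  # 8-species random site vs independent weighted mean
  set.seed(12)
  ids <- paste0("sp", 1:8)
  tr8 <- random_traits(ids, n_quant = 2, n_cat = 0)
  x <- stats::rexp(8)
  m8 <- matrix(x, 1, 8, dimnames = list("s", ids))
  out8 <- cwm(m8, tr8)
  expect_equal(out8$q1, brute_cwm(x, tr8$q1))
  expect_equal(out8$q2, brute_cwm(x, tr8$q2))
  # rescaling all abundances at a site leaves CWM unchanged
  expect_equal(cwm(m8 * 17, tr8), out8)
  # present taxon without a trait row errors
  expect_error(cwm(m8, tr8[-1, ]), "missing trait rows")
})

test_that("Gower dissimilarity handles mixed traits and degenerate columns", {
  # identical rows -> 0; opposite extremes on every trait -> 1
  tr <- trait_table(data.frame(q1 = c(0, 1), q2 = c(5, -5),
                               c1 = factor(c("x", "y")),
                               row.names = c("a", "b")))
  d <- gower_dissimilarity(tr)
  expect_equal(unname(diag(d)), c(0, 0))
  expect_equal(d["a", "b"], 1)
  same <- trait_table(data.frame(q1 = c(1, 1, 2), c1 = factor(c("x", "x", "y")),
                                 row.names = c("a", "b", "c")))
  expect_equal(gower_dissimilarity(same)["a", "b"], 0)
  # 5 taxa x 3 traits vs brute force, and against cluster::daisy
  set.seed(13)
  tr5 <- random_traits(paste0("t", 1:5), n_quant = 2, n_cat = 1)
  d5 <- gower_dissimilarity(tr5)
  expect_equal(d5, brute_gower(tr5))
  expect_true(isSymmetric(unname(d5)))
  skip_if_not_installed("cluster")
  dd <- as.matrix(cluster::daisy(as.data.frame(tr5), metric = "gower"))
  expect_equal(unname(d5), unname(dd), tolerance = 1e-10)
  # zero-range quantitative trait dropped with a warning
  trz <- trait_table(data.frame(q1 = c(1, 1), q2 = c(0, 2),
                                row.names = c("a", "b")))
  expect_warning(dz <- gower_dissimilarity(trz), "zero-range")
  expect_equal(dz["a", "b"], 1)
})

test_that("Rao Q matches the double sum and the algebraic identities", {
  set.seed(14)
  ids <- paste0("sp", 1:6)
  x <- stats::rexp(6)
  m <- matrix(x, 1, 6, dimnames = list("s", ids))
  d <- brute_gower(random_traits(ids, 3, 0))
  expect_equal(unname(rao_q(m, d)), brute_rao(x, d))
  # d == 0 everywhere -> 0; d == 1 off-diagonal -> Simpson diversity
  d0 <- d * 0
  expect_equal(unname(rao_q(m, d0)), 0)
  d1 <- 1 - diag(6); dimnames(d1) <- dimnames(d)
  expect_equal(unname(rao_q(m, d1)), unname(simpson_d(m)))
  # misaligned taxa error
  expect_error(rao_q(m, d[1:3, 1:3]), "not aligned")
})

test_that("functional redundancy spans its analytic limits", {
  ids <- c("a", "b")
  m <- matrix(c(1, 1), 1, 2, dimnames = list("s", ids))
  # complete convergence: FR = D
  d0 <- matrix(0, 2, 2, dimnames = list(ids, ids))
  expect_equal(unname(functional_redundancy(m, d0)), 0.5)
  # complete divergence: FR = 0
  d1 <- matrix(1, 2, 2, dimnames = list(ids, ids)); diag(d1) <- 0
  expect_equal(unname(functional_redundancy(m, d1)), 0)
  # random community: FR = D - Q from independent computations
  set.seed(15)
  ids6 <- paste0("sp", 1:6)
  x <- stats::rexp(6)
  m6 <- matrix(x, 1, 6, dimnames = list("s", ids6))
  d6 <- brute_gower(random_traits(ids6, 3, 1))
  expect_equal(unname(functional_redundancy(m6, d6)),
               brute_simpson(x) - brute_rao(x, d6))
})

test_that("index bounds 0 <= Q <= D <= 1 hold over randomized communities", {
  set.seed(16)
  for (r in 1:30) {
    ab <- random_abundance(5, 7)
    d <- brute_gower(random_traits(taxa(ab), 3, 1))
    D <- simpson_d(ab)
    Q <- rao_q(ab, d)
    expect_true(all(Q >= -1e-12))
    expect_true(all(Q <= D + 1e-12))
    expect_true(all(D <= 1))
    fr <- functional_redundancy(ab, d)
    expect_true(all(fr >= -1e-12 & fr <= 1))
  }
})

test_that("Bray-Curtis matches the formula with its boundary cases", {
  ab <- toy_abundance()
  bc <- bray_curtis(ab)
  expect_true(isSymmetric(unname(bc)))
  expect_equal(unname(diag(bc)), rep(0, 4))
  for (i in 1:3) for (j in (i + 1):4)
    expect_equal(bc[i, j], brute_bray(ab$values[i, ], ab$values[j, ]))
  # identical sites -> 0, disjoint communities -> 1
  v <- rbind(s1 = c(1, 2, 0, 0), s2 = c(1, 2, 0, 0), s3 = c(0, 0, 3, 1))
  colnames(v) <- paste0("sp", 1:4)
  bc2 <- bray_curtis(v)
  expect_equal(bc2["s1", "s2"], 0)
  expect_equal(bc2["s1", "s3"], 1)
  # a pair of empty sites is undefined
  vz <- rbind(s1 = c(0, 0), s2 = c(0, 0), s3 = c(1, 1))
  colnames(vz) <- c("a", "b")
  expect_error(bray_curtis(vz), "empty sites")
})

test_that("functional beta matches the pooled-vs-mean brute force", {
  set.seed(17)
  ab <- random_abundance(4, 6)
  d <- brute_gower(random_traits(taxa(ab), 3, 0))
  fb <- functional_beta(ab, d)
  expect_true(isSymmetric(unname(fb)))
  expect_equal(unname(diag(fb)), rep(0, 4))
  for (i in 1:3) for (j in (i + 1):4)
    expect_equal(fb[i, j],
                 brute_funcbeta(ab$values[i, ], ab$values[j, ], d))
  # identical communities -> 0
  v <- rbind(s1 = c(1, 2, 3), s2 = c(1, 2, 3))
  colnames(v) <- letters[1:3]
  d3 <- brute_gower(random_traits(letters[1:3], 2, 0))
  expect_equal(unname(functional_beta(v, d3)[1, 2]), 0)
  # identical traits everywhere -> 0 for every pair
  dz <- d * 0
  expect_true(all(functional_beta(ab, dz) == 0))
  # additive variant equals Jost numerator
  fb_add <- functional_beta(ab, d, correction = "additive")
  p <- ab$values / rowSums(ab$values)
  q <- vapply(1:4, function(i) brute_rao(p[i, ], d), numeric(1))
  qa12 <- (q[1] + q[2]) / 2
  expect_equal(fb[1, 2], fb_add[1, 2] / (1 - qa12))
})

test_that("decoupling_test recovers a planted association and a null", {
  set.seed(18)
  n <- 25
  base <- matrix(stats::runif(n * n), n, n)
  pred <- (base + t(base)) / 2; diag(pred) <- 0
  noise <- matrix(stats::runif(n * n, 0, 0.02), n, n)
  resp <- 0.5 * pred + (noise + t(noise)) / 2; diag(resp) <- 0
  planted <- decoupling_test(resp, pred, n_perm = 199, seed = 1)
  expect_equal(planted$slope, 0.5, tolerance = 0.05)
  expect_lt(planted$p_value, 0.05)
  rnd <- matrix(stats::runif(n * n), n, n)
  rnd <- (rnd + t(rnd)) / 2; diag(rnd) <- 0
  nullres <- decoupling_test(rnd, pred, n_perm = 199, seed = 1)
  expect_gt(nullres$p_value, 0.05)
})

test_that("trait removal robustness matches exhaustive enumeration", {
  set.seed(19)
  ab <- random_abundance(4, 5)
  tr <- random_traits(taxa(ab), n_quant = 6, n_cat = 0)
  # k = 0 (no removal) is the observed value, exposed as attributes
  res <- trait_removal_robustness(ab, tr, n_remove_max = 2, always_keep = 4,
                                  n_iter = 60, seed = 1)
  d_full <- gower_dissimilarity(tr)
  expect_equal(attr(res, "fd_observed"), mean(rao_q(ab, d_full)))
  expect_equal(attr(res, "fr_observed"),
               mean(functional_redundancy(ab, d_full)))
  # every sampled k = 2 value lies in the exhaustive 15-subset set
  combos <- utils::combn(6, 2)
  exhaustive <- apply(combos, 2, function(drop) {
    dk <- gower_dissimilarity(tr[, -drop, drop = FALSE])
    mean(rao_q(ab, dk))
  })
  sampled <- res$fd_mean[res$k == 2]
  expect_true(all(vapply(sampled, function(s)
    any(abs(s - exhaustive) < 1e-12), logical(1))))
  # fully redundant trait set: removing any one duplicate changes nothing
  tr_dup <- trait_table(data.frame(q1 = tr$q1, q2 = tr$q1, q3 = tr$q1,
                                   q4 = tr$q1, q5 = tr$q1,
                                   row.names = rownames(tr)))
  d_dup <- gower_dissimilarity(tr_dup)
  expect_equal(gower_dissimilarity(tr_dup[, -2, drop = FALSE]), d_dup)
  res_dup <- trait_removal_robustness(ab, tr_dup, n_remove_max = 1,
                                      always_keep = 4, n_iter = 5, seed = 2)
  expect_true(all(abs(res_dup$fd_mean - mean(rao_q(ab, d_dup))) < 1e-12))
  # guard rails
  expect_error(trait_removal_robustness(ab, tr, n_remove_max = 3,
                                        always_keep = 4),
               "exceeds")
  expect_error(trait_removal_robustness(ab, tr[, 1:4], n_remove_max = 1,
                                        always_keep = 4),
               "exceed")
})
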