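test_that("Weir-Cockerham components match hand-evaluated cases", {
  # fixed difference, 50 per population
  dos <- as_dosage(rbind(matrix(2L, 50, 1), matrix(0L, 50, 1)),
                   rep(c("P1", "P2"), each = 50))
  comp <- wc_fst_per_locus(dos)
  expect_equal(comp$a, 0.5)
  expect_equal(comp$b, 0)
  expect_equal(comp$c, 0)
  expect_equal(comp$theta, 1)
  # everyone heterozygous in both populations
  dos2 <- as_dosage(matrix(1L, 100, 1), rep(c("P1", "P2"), each = 50))
  comp2 <- wc_fst_per_locus(dos2)
  expect_equal(comp2$a, 0)
  expect_equal(comp2$b, -0.25)
  expect_equal(comp2$c, 0.5)
  expect_equal(comp2$theta, 0)
})

test_that("vectorized components equal the literal 1984 transcription", {
  set.seed(11)
  for (i in 1:30) {
    r <- sample(2:4, 1)
    ns <- sample(3:10, r, replace = TRUE)
    g <- unlist(lapply(ns, function(n) sample(0:2, n, replace = TRUE)))
    pops <- rep(paste0("P", seq_len(r)), ns)
    dos <- as_dosage(matrix(g, ncol = 1), pops)
    comp <- wc_fst_per_locus(dos)
    p <- tapply(g, pops, function(x) mean(x) / 2)
    h <- tapply(g, pops, function(x) mean(x == 1))
    ora <- wc84_oracle(ns, p, h)
    expect_equal(unlist(comp[1, c("a", "b", "c")]), ora,
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("identical populations show only finite-sample noise", {
  set.seed(3)
  block <- matrix(rbinom(50 * 400, 2, rep(runif(400, 0.1, 0.9),
                                          each = 50)), 50, 400)
  dos <- as_dosage(rbind(block, block), rep(c("P1", "P2"), each = 50))
  th <- attr(wc_fst_per_locus(dos), "theta_global")
  expect_lt(abs(th), 0.02)
})

test_that("aggregate theta is the ratio of sums and permutation-invariant", {
  sim <- simulate_cohort(sim_spec(3, 0.15, 20, 300, seed = 17))
  dos <- to_dosage(sim$cohort)
  comp <- wc_fst_per_locus(dos)
  expect_equal(attr(comp, "theta_global"), theta_ratio_of_sums(comp))
  perm <- sample(ncol(dos))
  dosp <- as_dosage(dos[, perm], attr(dos, "pops"))
  expect_equal(attr(wc_fst_per_locus(dosp), "theta_global"),
               attr(comp, "theta_global"))
  # ratio of sums, not mean of ratios
  expect_false(isTRUE(all.equal(attr(comp, "theta_global"),
                                mean(comp$theta, na.rm = TRUE))))
  expect_true(all(comp$theta <= 1, na.rm = TRUE))
})

test_that("pairwise F_ST is symmetric, zero-diagonal, and recovers F = 0.09", {
  sim <- simulate_cohort(sim_spec(2, 0.09, c(50, 50), 5000, seed = 19))
  dos <- to_dosage(sim$cohort)
  m <- pairwise_fst(dos)
  expect_equal(m, t(m))
  expect_equal(diag(m), c(P1 = 0, P2 = 0))
  expect_gt(m[1, 2], 0.07)
  expect_lt(m[1, 2], 0.11)
})

test_that("Nei distance matches its closed form and handles degeneracy", {
  expect_equal(nei_distance(0.8, 0.2), -log(0.32 / 0.68))
  expect_equal(nei_distance(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(nei_distance(0.8, 0.2), nei_distance(0.2, 0.8))
  expect_warning(d_inf <- nei_distance(1, 0), "infinite")
  expect_equal(d_inf, Inf)
})

test_that("per-population summaries match direct arithmetic", {
  # all-heterozygote population at one locus
  dos <- as_dosage(matrix(1L, 5, 1), rep("P1", 5))
  s <- per_population_summary(dos)
  expect_equal(s$Ho[1], 1)
  expect_equal(s$MAF[1], 0.5)
  # two samples AA and aa: p = 0.5, unbiased He = 2/3, Ho = 0
  dos2 <- as_dosage(matrix(c(2L, 0L), 2, 1), rep("P1", 2))
  s2 <- per_population_summary(dos2)
  expect_equal(s2$He[1], 2 / 3)
  expect_equal(s2$Ho[1], 0)
  # monomorphic locus contributes zeros to the averages
  dos3 <- as_dosage(cbind(c(2L, 0L), c(0L, 0L)), rep("P1", 2))
  s3 <- per_population_summary(dos3)
  expect_equal(s3$He[1], 1 / 3)
  expect_equal(s3$MAF[1], 0.25)
})

test_that("inbreeding coefficient is near zero under random mating", {
  set.seed(23)
  p <- runif(400, 0.1, 0.9)
  dos <- as_dosage(matrix(rbinom(60 * 400, 2, rep(p, each = 60)), 60),
                   rep("P1", 60))
  s <- per_population_summary(dos)
  expect_lt(abs(s$Fis[1]), 0.02)
})

test_that("differentiation indices satisfy their closed forms", {
  # identical populations
  block <- matrix(c(2L, 1L, 0L, 1L), 4, 3)
  dos <- as_dosage(rbind(block, block), rep(c("P1", "P2"), each = 4))
  idx <- differentiation_indices(dos)
  expect_equal(idx$Dst, 0)
  expect_equal(idx$Dest, 0)
  # two populations fixed for opposite alleles
  dos2 <- as_dosage(matrix(c(2L, 2L, 0L, 0L), 4, 1),
                    rep(c("P1", "P2"), each = 2))
  idx2 <- differentiation_indices(dos2)
  expect_equal(idx2$Hs, 0)
  expect_equal(idx2$Ht, 0.5)
  expect_equal(idx2$Dst, 0.5)
  expect_equal(idx2$Dest, 1)
})

test_that("informative-locus selection respects threshold and order", {
  th <- c(0.1, 0.25, 0.5)
  expect_equal(select_informative_loci(th, 0.20), c(2L, 3L))
  expect_equal(select_informative_loci(th, 0.40), 3L)
  expect_equal(select_informative_loci(numeric(0)), integer(0))
  expect_equal(select_informative_loci(c(0.3, NA, 0.21)), c(1L, 3L))
})
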