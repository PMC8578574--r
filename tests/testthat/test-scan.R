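test_that("pairwise scan contracts: length, closed cases, error on bad labels", {
  set.seed(3)
  block <- matrix(rbinom(16 * 200, 2, rep(runif(200, 0.2, 0.8),
                                          each = 16)), 16, 200)
  dos <- as_dosage(rbind(block, block), rep(c("KG", "SW"), each = 16))
  sc <- pairwise_scan(dos, breed_a = "KG", breed_b = "SW")
  # identical breeds: only finite-sample bias remains at n = 16 per side
  expect_lt(median(abs(sc$theta)), 0.05)
  expect_lt(max(abs(sc$theta)), 0.07)
  expect_error(pairwise_scan(dos, breed_a = "KG", breed_b = "XX"),
               "unknown breed")
  # fixed difference scores theta = 1
  dos2 <- dos
  dos2[, 10] <- rep(c(2L, 0L), each = 16)
  attr(dos2, "variants") <- attr(dos, "variants")
  attr(dos2, "pops") <- attr(dos, "pops")
  sc2 <- pairwise_scan(dos2, breed_a = "KG", breed_b = "SW")
  expect_equal(sc2$theta[sc2$name == "m010"], 1)
  # output covers exactly the loci defined in both breeds
  dos3 <- dos2
  dos3[1:16, 5] <- NA                            # KG entirely missing at m005
  attr(dos3, "variants") <- attr(dos, "variants")
  attr(dos3, "pops") <- attr(dos, "pops")
  sc3 <- pairwise_scan(dos3, breed_a = "KG", breed_b = "SW")
  expect_false("m005" %in% sc3$name)
  expect_equal(nrow(sc3), sum(!is.na(
    wc_fst_per_locus(dos3, subset = c("KG", "SW"))$theta)))
})

test_that("sweep calling thresholds, spans and merging follow the rules", {
  scan <- structure(
    data.frame(chrom = "1", pos = c(2e6, 5e6, 5.5e6, 9e6),
               name = paste0("s", 1:4),
               theta = c(0.30, 0.26, 0.28, 0.05)),
    pair = c("A", "B"), class = c("fst_scan", "data.frame"))
  rg <- call_sweeps(scan, threshold = 0.25, flank_bp = 1e6)
  # peaks at 5 and 5.5 Mb merge; the higher-theta locus is the peak
  expect_equal(nrow(rg), 2)
  expect_equal(rg$peak_name, c("s1", "s3"))
  expect_equal(rg$end - rg$start + 1, rep(2e6 + 1, 2))
  expect_equal(rg$n_peaks, c(1, 2))
  expect_true(all(rg$start <= rg$peak_pos & rg$peak_pos <= rg$end))
  # the 0.50 top tier
  rg50 <- call_sweeps(structure(
    data.frame(chrom = "1", pos = c(1e6, 40e6), name = c("a", "b"),
               theta = c(0.30, 0.55)),
    pair = c("A", "B"), class = c("fst_scan", "data.frame")),
    threshold = 0.50)
  expect_equal(nrow(rg50), 1)
  expect_equal(rg50$peak_name, "b")
  # clipping at the chromosome start
  rgc <- call_sweeps(structure(
    data.frame(chrom = "1", pos = 5e5, name = "c", theta = 0.4),
    pair = c("A", "B"), class = c("fst_scan", "data.frame")))
  expect_equal(rgc$start, 1)
})

test_that("threshold zero saturates into one region per merged cluster", {
  scan <- structure(
    data.frame(chrom = rep(c("1", "2"), each = 3),
               pos = rep(c(1e6, 1.5e6, 8e6), 2),
               name = paste0("t", 1:6),
               theta = rep(0.01, 6)),
    pair = c("A", "B"), class = c("fst_scan", "data.frame"))
  rg <- call_sweeps(scan, threshold = 0)
  expect_equal(nrow(rg), 4)                   # 2 clusters per chromosome
  expect_equal(sum(rg$n_peaks), 6)            # every locus covered
})

test_that("annotation respects half-open overlap and tallies QTL classes", {
  rg <- call_sweeps(structure(
    data.frame(chrom = "5", pos = 3e6, name = "p", theta = 0.6),
    pair = c("A", "B"), class = c("fst_scan", "data.frame")))
  # region interval is [2e6 - 1, 4e6) zero-based
  genes <- zebupop:::feature_track(
    chrom = c("5", "5", "5"),
    start = c(rg$end0, 2.5e6, 1e6),   # abutting, inside, overlapping start
    end = c(rg$end0 + 1000, 2.6e6, 2.1e6),
    name = c("ABUT", "IN", "EDGE"), class = "gene")
  qtls <- zebupop:::feature_track(
    chrom = "5", start = rep(2.5e6, 4), end = rep(2.6e6, 4),
    name = paste0("q", 1:4), class = c("MY", "MY", "M/C", "weird"))
  expect_warning(ann <- annotate_regions(rg, genes, qtls), "untallied")
  expect_setequal(ann$genes[[1]], c("IN", "EDGE"))
  expect_equal(ann$qtl_MY, 2L)
  expect_equal(ann$qtl_MC, 0L)
  expect_equal(ann$qtl_M_C, 1L)
  expect_equal(ann$qtl_total, 3L)
  # record order invariance
  ann2 <- suppressWarnings(annotate_regions(rg, genes[3:1, ], qtls[4:1, ]))
  expect_setequal(ann2$genes[[1]], ann$genes[[1]])
  expect_equal(ann2$qtl_total, ann$qtl_total)
  # empty tracks leave zero counts; absent chromosome warns
  ann3 <- annotate_regions(rg)
  expect_equal(ann3$qtl_total, 0L)
  off <- zebupop:::feature_track("9", 1, 10, "x", "MY")
  expect_warning(annotate_regions(rg, genes = off), "absent")
})

test_that("two-proportion test matches its closed form and symmetry", {
  t0 <- two_proportion_test(50, 100, 50, 100)
  expect_equal(t0$z, 0)
  expect_equal(t0$p_value, 1)
  t1 <- two_proportion_test(30, 100, 10, 100)
  expect_equal(t1$pooled, 0.2)
  expect_equal(t1$z, 0.2 / sqrt(0.2 * 0.8 * 0.02), tolerance = 1e-12)
  expect_equal(t1$z, 3.5355, tolerance = 1e-4)
  expect_equal(t1$p_value, 4.07e-4, tolerance = 1e-2)
  t2 <- two_proportion_test(10, 100, 30, 100)
  expect_equal(t2$z, -t1$z)
  expect_equal(t2$p_value, t1$p_value)
  # degenerate pooled proportions
  expect_equal(two_proportion_test(0, 10, 0, 20)$p_value, 1)
  expect_equal(two_proportion_test(10, 10, 20, 20)$z, 0)
  # agreement with the chi-squared formulation
  pt <- prop.test(c(30, 10), c(100, 100), correct = FALSE)
  expect_equal(t1$p_value, pt$p.value, tolerance = 1e-12)
})

test_that("spiked fixed differences are recovered by the permutation filter", {
  sim <- simulate_cohort(sim_spec(2, 0.05, c(16, 16), 500, n_chrom = 5,
                                  seed = 61))
  dos <- to_dosage(sim$cohort)
  v <- attr(dos, "variants")
  spiked <- vapply(as.character(1:5),
                   function(cc) which(v$chrom == cc)[50], integer(1))
  dos[, spiked] <- rep(c(2L, 0L), each = 16)
  attr(dos, "variants") <- v
  sc <- pairwise_scan(dos, breed_a = "P1", breed_b = "P2")
  rg <- call_sweeps(sc, threshold = 0.25, perms = 10000, alpha = 1e-4,
                    seed = 5, dos = dos, pops = attr(dos, "pops"))
  hits <- sum(v$name[spiked] %in% rg$peak_name)
  expect_gte(hits, 4)
})
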