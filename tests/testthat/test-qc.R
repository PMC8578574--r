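test_that("HWE exact test matches worked examples", {
  expect_equal(hwe_exact_test(1, 0, 1), 1 / 3)
  expect_equal(hwe_exact_test(0, 2, 0), 1)
  for (n in c(1, 5, 40)) expect_equal(hwe_exact_test(n, 0, 0), 1)
  expect_error(hwe_exact_test(-1, 0, 1), "negative")
  expect_error(hwe_exact_test(0, 0, 0), "at least one")
})

test_that("HWE exact test equals the enumeration oracle on small totals", {
  # exhaustive up to total 12 here (the full sweep to 30 runs with the
  # acceptance checks)
  for (n in 1:12)
    for (n_aa in 0:n)
      for (n_ab in 0:(n - n_aa)) {
        n_bb <- n - n_aa - n_ab
        expect_equal(hwe_exact_test(n_aa, n_ab, n_bb),
                     hwe_oracle(n_aa, n_ab, n_bb), tolerance = 1e-12)
      }
})

test_that("sample missingness boundary keeps MIND exactly at threshold", {
  # 100 autosomal markers; sample 1 misses 10 (retained), sample 2 misses
  # 11 (removed)
  n_l <- 100
  a1 <- matrix("A", 3, n_l); a2 <- matrix("G", 3, n_l)
  a1[1, 1:10] <- NA; a2[1, 1:10] <- NA
  a1[2, 1:11] <- NA; a2[2, 1:11] <- NA
  co <- cohort(data.frame(id = paste0("s", 1:3), pop = "A"),
               data.frame(chrom = "1", pos = seq_len(n_l) * 100L,
                          name = paste0("m", seq_len(n_l)),
                          a1 = "A", a2 = "G"),
               a1, a2)
  fs <- filter_samples(co, 0.1)
  expect_equal(fs$cohort$samples$id, c("s1", "s3"))
  expect_equal(fs$report$n_removed, 1)
  # no missing calls: nothing removed
  co2 <- co[3, ]
  expect_equal(n_samples(filter_samples(co2, 0)$cohort), 1)
})

test_that("SNP thresholds are inclusive and stages run in order", {
  # 20 samples, crafted markers:
  #  m1: CR exactly 0.95 -> removed at call-rate stage
  #  m2: MAF 0.05 exactly? use 0.04 -> removed; m3: MAF 0.075 kept
  #  m4: on X -> removed at autosome stage
  #  m5: HWE p below 0.001 (all heterozygotes) -> removed at HWE stage
  n <- 20
  dos <- cbind(m1 = c(NA, rep(1L, 19)),
               m2 = c(rep(1L, 2), rep(0L, 18)),  # p = 0.05 -> MAF 0.05
               m3 = c(rep(1L, 3), rep(0L, 17)),
               m4 = rep(1L, 20),
               m5 = rep(1L, 20))
  a1 <- ifelse(dos >= 1, "A", "G"); a2 <- ifelse(dos == 2, "A", "G")
  a1[is.na(dos)] <- NA; a2[is.na(dos)] <- NA
  co <- cohort(data.frame(id = paste0("s", 1:n), pop = "A"),
               data.frame(chrom = c("1", "1", "1", "X", "2"),
                          pos = c(100L, 200L, 300L, 400L, 500L),
                          name = paste0("m", 1:5), a1 = "A", a2 = "G"),
               a1, a2)
  fq <- filter_snps(co, cr_min = 0.95, maf_min = 0.05, hwe_alpha = 0.001)
  rep <- fq$report
  expect_equal(rep$stage, c("autosome", "call_rate", "maf", "hwe"))
  expect_equal(rep$n_removed, c(1, 1, 1, 1))
  expect_equal(fq$cohort$variants$name, "m3")
  # telescoping counts
  expect_equal(rep$n_in - rep$n_removed, rep$n_out)
  expect_equal(rep$n_in[-1], rep$n_out[-length(rep$n_out)])
})

test_that("MAF just above the threshold survives", {
  n <- 500
  dos <- cbind(lo = c(rep(1L, 40), rep(0L, n - 40)),    # MAF 0.04
               hi = c(rep(1L, 51), rep(0L, n - 51)))    # MAF 0.051
  a1 <- ifelse(dos >= 1, "A", "G"); a2 <- ifelse(dos == 2, "A", "G")
  co <- cohort(data.frame(id = paste0("s", 1:n), pop = "A"),
               data.frame(chrom = "1", pos = c(1L, 2L) * 100L,
                          name = c("lo", "hi"), a1 = "A", a2 = "G"),
               a1, a2)
  fq <- filter_snps(co, cr_min = 0, maf_min = 0.05, hwe_alpha = 0)
  expect_equal(fq$cohort$variants$name, "hi")
})

test_that("the SNP filter cascade is idempotent", {
  sim <- simulate_cohort(sim_spec(3, 0.15, 15, 300, missing_rate = 0.08,
                                  seed = 21))
  f1 <- filter_snps(sim$cohort)
  f2 <- filter_snps(f1$cohort)
  expect_equal(f2$cohort$variants$name, f1$cohort$variants$name)
  expect_equal(sum(f2$report$n_removed), 0)
})

test_that("per-population HWE option screens within breeds", {
  # two diverged breeds each in HWE; pooling creates a heterozygote
  # deficit (Wahlund), the per-population option does not reject
  set.seed(4)
  dos <- rbind(matrix(rbinom(30 * 50, 2, 0.9), 30),
               matrix(rbinom(30 * 50, 2, 0.1), 30))
  a1 <- ifelse(dos >= 1, "A", "G"); a2 <- ifelse(dos == 2, "A", "G")
  co <- cohort(data.frame(id = paste0("s", 1:60),
                          pop = rep(c("P1", "P2"), each = 30)),
               data.frame(chrom = "1", pos = seq_len(50) * 100L,
                          name = paste0("m", 1:50), a1 = "A", a2 = "G"),
               a1, a2)
  pooled <- filter_snps(co, cr_min = 0, maf_min = 0, hwe_alpha = 0.001)
  by_pop <- filter_snps(co, cr_min = 0, maf_min = 0, hwe_alpha = 0.001,
                        hwe_by_pop = TRUE)
  expect_gt(sum(pooled$report$n_removed), sum(by_pop$report$n_removed))
})
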