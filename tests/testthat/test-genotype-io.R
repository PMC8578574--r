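test_that("PED/MAP parsing recovers samples, variants and missing calls", {
  paths <- write_toy_pedmap()
  co <- read_ped_map(paths["ped"], paths["map"])
  expect_equal(dim(co), c(2L, 3L))
  expect_equal(co$samples$pop, c("FAM1", "FAM2"))
  expect_equal(co$variants$name, c("rs1", "rs2", "rs3"))
  expect_equal(co$variants$chrom, c("1", "1", "2"))
  # "0 0" is a missing call: sample 1 has call rate 2/3
  expect_true(is.na(co$allele1[1, 3]) && is.na(co$allele2[1, 3]))
  expect_equal(mean(!is.na(co$allele1[1, ])), 2 / 3)
})

test_that("PED/MAP round trip is allele-identical and emits 0 0 for missing", {
  sim <- simulate_cohort(sim_spec(2, 0.1, c(4, 4), 20,
                                  missing_rate = 0.15, seed = 1))
  dir <- withr::local_tempdir()
  write_ped_map(sim$cohort, file.path(dir, "rt"))
  back <- read_ped_map(file.path(dir, "rt.ped"), file.path(dir, "rt.map"))
  expect_equal(unname(back$allele1), unname(sim$cohort$allele1))
  expect_equal(unname(back$allele2), unname(sim$cohort$allele2))
  expect_equal(back$samples$pop, sim$cohort$samples$pop)
  expect_equal(back$variants$pos, sim$cohort$variants$pos)
  line1 <- readLines(file.path(dir, "rt.ped"))[1]
  miss <- which(is.na(sim$cohort$allele1[1, ]))[1]
  toks <- strsplit(line1, " ")[[1]]
  expect_equal(toks[6 + 2 * miss - 1], "0")
  expect_equal(toks[6 + 2 * miss], "0")
})

test_that("degenerate and malformed inputs are handled", {
  dir <- withr::local_tempdir()
  # empty-variant cohort still writes a valid 6-column PED
  co0 <- cohort(data.frame(id = "s1", pop = "A"),
                data.frame(chrom = character(), pos = integer(),
                           name = character(), a1 = character(),
                           a2 = character()),
                matrix(NA_character_, 1, 0), matrix(NA_character_, 1, 0))
  write_ped_map(co0, file.path(dir, "empty"))
  expect_length(strsplit(readLines(file.path(dir, "empty.ped")),
                         " ")[[1]], 6)
  # marker-count mismatch
  paths <- write_toy_pedmap(dir)
  writeLines(c("1\trs1\t0\t1000", "1\trs2\t0\t2000"),
             file.path(dir, "short.map"))
  expect_error(read_ped_map(paths["ped"], file.path(dir, "short.map")),
               "fields")
  # non-numeric bp
  writeLines(c("1\trs1\t0\tabc", "1\trs2\t0\t2000", "2\trs3\t0\t500"),
             file.path(dir, "bad.map"))
  expect_error(read_ped_map(paths["ped"], file.path(dir, "bad.map")),
               "non-numeric")
  # duplicate marker name
  writeLines(c("1\trs1\t0\t1000", "1\trs1\t0\t2000", "2\trs3\t0\t500"),
             file.path(dir, "dup.map"))
  expect_error(read_ped_map(paths["ped"], file.path(dir, "dup.map")),
               "duplicate")
})

test_that("dosage conversion counts the requested allele", {
  paths <- write_toy_pedmap()
  co <- read_ped_map(paths["ped"], paths["map"])
  dos <- to_dosage(co, "a1")
  # rs1: s1 = A/A, s2 = A/G with a1 = "A"
  expect_equal(unname(dos[, 1]), c(2L, 1L))
  # rs2 heterozygote counts 1 under either policy
  dos_m <- to_dosage(co, "minor")
  expect_equal(dos[1, 2], 1L)
  expect_equal(dos_m[1, 2], 1L)
  expect_true(is.na(dos[1, 3]))
  # minor-allele resolution flips the counted allele when a1 is major
  expect_equal(attr(dos_m, "counted_allele")[1], "G")
  expect_equal(unname(dos_m[, 1]), c(0L, 1L))
})

test_that("all-missing marker under minor policy is flagged, dosage missing", {
  co <- cohort(data.frame(id = c("s1", "s2"), pop = "A"),
               data.frame(chrom = "1", pos = 100L, name = "m1",
                          a1 = "A", a2 = "G"),
               matrix(NA_character_, 2, 1), matrix(NA_character_, 2, 1))
  dos <- to_dosage(co, "minor")
  expect_true(all(is.na(dos)))
  expect_true(attr(dos, "undetermined")[1])
})

test_that("dosage plus missing counts reproduce per-marker call counts", {
  sim <- simulate_cohort(sim_spec(3, 0.1, 5, 40, missing_rate = 0.2,
                                  seed = 9))
  dos <- to_dosage(sim$cohort)
  called <- colSums(!is.na(dos))
  expect_equal(called + colSums(is.na(dos)), rep(15, 40),
               ignore_attr = TRUE)
  # every called entry counts alleles of the call
  expect_true(all(dos[!is.na(dos)] %in% 0:2))
})

test_that("feature tracks unify BED and GFF3 coordinate conventions", {
  dir <- withr::local_tempdir()
  writeLines("5\t100\t200\tHMGA2\tMY", file.path(dir, "a.bed"))
  tr <- read_features(file.path(dir, "a.bed"))
  expect_equal(tr$start, 100L)
  expect_equal(tr$end, 200L)
  expect_equal(tr$name, "HMGA2")
  expect_equal(tr$class, "MY")
  # GFF3 1-based closed becomes 0-based half-open
  writeLines(c("##gff-version 3",
               paste("5", "src", "gene", "101", "200", ".", "+", ".",
                     "ID=g1;Name=HMGA2", sep = "\t")),
             file.path(dir, "a.gff3"))
  tr2 <- read_features(file.path(dir, "a.gff3"))
  expect_equal(tr2$start, 100L)
  expect_equal(tr2$end, 200L)
  expect_equal(tr2$name, "HMGA2")
  # empty file -> empty track
  file.create(file.path(dir, "e.bed"))
  expect_equal(nrow(read_features(file.path(dir, "e.bed"))), 0L)
  # end <= start rejected
  writeLines("1\t300\t200\tX", file.path(dir, "bad.bed"))
  expect_error(read_features(file.path(dir, "bad.bed")), "end")
  # BTA prefixes are normalized
  writeLines("BTA4\t10\t20\tY", file.path(dir, "bta.bed"))
  expect_equal(read_features(file.path(dir, "bta.bed"))$chrom, "4")
})
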