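# genotype fixtures
gt_448 <- genotype_table(  # one heterozygote of a 9:1 biallelic locus, n=5
  individual = paste0("i", 1:5), locus = "L1",
  allele1 = c(154, 154, 154, 154, 154),
  allele2 = c(154, 154, 154, 154, 156))
gt_098 <- genotype_table(  # 4:3:2:1 with a single heterozygote, n=5
  individual = paste0("i", 1:5), locus = "L1",
  allele1 = c(98, 98, 110, 118, 110),
  allele2 = c(98, 98, 110, 118, 126))

test_that("allele frequencies count alleles over typed individuals only", {
  fr <- allele_frequencies(gt_448)
  expect_equal(sort(fr$freq), c(0.1, 0.9))
  expect_equal(fr$n_typed, c(5L, 5L))
  one_het <- genotype_table("i1", "L1", 120, 124)
  expect_equal(allele_frequencies(one_het)$freq, c(0.5, 0.5))
  with_missing <- genotype_table(paste0("i", 1:6), "L1",
                                 c(120, 120, 120, 124, 124, NA),
                                 c(120, 120, 124, 124, 124, NA))
  fr2 <- allele_frequencies(with_missing)
  expect_equal(fr2$n_typed, c(5L, 5L))     # denominator 10, not 12
  expect_equal(sum(fr2$freq), 1)
  all_missing <- genotype_table("i1", "L1", NA, NA)
  expect_error(allele_frequencies(all_missing), class = "strmarker_no_data")
})

test_that("observed heterozygosity is the fraction of het individuals", {
  expect_equal(observed_heterozygosity(gt_448)$ho, 0.20)
  all_het <- genotype_table(paste0("i", 1:4), "L1", 1:4 * 2, 1:4 * 2 + 2)
  expect_equal(observed_heterozygosity(all_het)$ho, 1.00)
  all_hom <- genotype_table(paste0("i", 1:4), "L1", rep(2, 4), rep(2, 4))
  expect_equal(observed_heterozygosity(all_hom)$ho, 0.00)
})

test_that("expected heterozygosity, plain and unbiased", {
  expect_equal(expected_heterozygosity(c(0.5, 0.5), unbiased = FALSE), 0.5)
  expect_equal(expected_heterozygosity(c(0.9, 0.1), n_typed = 5),
               (10 / 9) * (1 - 0.82))           # = 0.20
  expect_equal(expected_heterozygosity(c(0.4, 0.3, 0.2, 0.1), n_typed = 5),
               (10 / 9) * 0.70)                 # = 0.778
  expect_gte(expected_heterozygosity(c(0.7, 0.3), n_typed = 4),
             expected_heterozygosity(c(0.7, 0.3), unbiased = FALSE))
  expect_error(expected_heterozygosity(c(0.9, 0.1)),
               class = "strmarker_bad_arg")
  expect_error(expected_heterozygosity(c(0.9, 0.2), n_typed = 5),
               class = "strmarker_bad_freqs")
})

test_that("pid and pid_sib follow the closed forms", {
  expect_equal(pid(c(0.5, 0.5)), 0.375)
  expect_equal(pid_sib(c(0.5, 0.5)), 0.59375)
  expect_equal(pid(c(0.9, 0.1)), 0.6886)
  expect_equal(round(pid_sib(c(0.9, 0.1)), 2), 0.83)
  expect_equal(pid(c(0.4, 0.3, 0.2, 0.1)), 0.1446, tolerance = 1e-10)
  expect_equal(pid_sib(c(0.4, 0.3, 0.2, 0.1)), 0.43615, tolerance = 1e-10)
  expect_equal(round(pid_sib(c(0.4, 0.3, 0.2, 0.1)), 2), 0.44)
})

test_that("pid equals exhaustive genotype enumeration for k <= 4", {
  set.seed(51)
  freqs <- list(c(0.5, 0.5), c(0.9, 0.1), c(1 / 3, 1 / 3, 1 / 3),
                c(0.4, 0.3, 0.2, 0.1), c(0.25, 0.25, 0.25, 0.25))
  for (i in 1:10) {
    k <- sample(2:4, 1)
    p <- stats::runif(k)
    freqs <- c(freqs, list(p / sum(p)))
  }
  for (p in freqs) {
    expect_equal(pid(p), oracle_pid(p), tolerance = 1e-12)
    expect_equal(pid_sib(p), oracle_pid_sib(p), tolerance = 1e-12)
    expect_gte(pid_sib(p), pid(p))
  }
})

test_that("pid is minimised at the uniform frequency vector", {
  set.seed(52)
  for (k in 2:6) {
    u <- rep(1 / k, k)
    for (i in 1:20) {
      d <- stats::runif(k)
      p <- u + 0.2 * (d - mean(d))
      if (any(p <= 0)) next
      p <- p / sum(p)
      expect_gte(pid(p), pid(u) - 1e-12)
      expect_gte(pid_sib(p), pid_sib(u) - 1e-12)
    }
  }
})

test_that("F_IS estimators behave at the boundaries", {
  # polymorphic locus with no heterozygotes -> 1 under both estimators
  no_het <- genotype_table(paste0("i", 1:5), "L1",
                           c(150, 150, 150, 162, 162),
                           c(150, 150, 150, 162, 162))
  expect_equal(fis(no_het, estimator = "simple")$fis, 1)
  expect_equal(fis(no_het, estimator = "weir_cockerham")$fis, 1)
  # monomorphic locus is undefined, not zero
  mono <- genotype_table(paste0("i", 1:5), "L1", rep(100, 5), rep(100, 5))
  expect_true(is.na(fis(mono)$fis))
  # HW-proportioned large sample is near zero
  n <- 500
  hw <- genotype_table(paste0("i", 1:n), "L1",
                       c(rep(100, 125), rep(100, 250), rep(104, 125)),
                       c(rep(100, 125), rep(104, 250), rep(104, 125)))
  expect_lt(abs(fis(hw, estimator = "weir_cockerham")$fis), 0.01)
})

test_that("Weir-Cockerham f matches hand-computed variance components", {
  # all four individuals heterozygous A/B: per allele b = -1/4, c = 1/2;
  # f = 1 - 1/((-0.5) + 1) = -1
  all_het <- genotype_table(paste0("i", 1:4), "L1",
                            rep(100, 4), rep(102, 4))
  expect_equal(fis(all_het, estimator = "weir_cockerham")$fis, -1)
  expect_equal(fis(all_het, estimator = "simple")$fis,
               1 - 1 / (0.5 * 8 / 7))
  # the published Disu098 configuration reproduces the printed 0.76
  expect_equal(round(fis(gt_098, estimator = "weir_cockerham")$fis, 2), 0.76)
  expect_equal(round(fis(gt_098, estimator = "simple")$fis, 2), 0.74)
})

test_that("locus_stats assembles every per-locus column coherently", {
  gt <- dplyr::bind_rows(gt_448,
                         dplyr::mutate(gt_098, locus = "L2"))
  st <- locus_stats(genotype_table(gt$individual, gt$locus,
                                   gt$allele1, gt$allele2))
  expect_equal(nrow(st), 2L)
  expect_equal(st$a, c(2L, 4L))
  expect_equal(round(st$he_unbiased, 2), c(0.20, 0.78))
  expect_equal(round(st$ho, 2), c(0.20, 0.20))
  expect_equal(round(st$pid, 2), c(0.69, 0.14))
  expect_equal(round(st$pid_sib, 2), c(0.83, 0.44))
  expect_true(all(st$he_unbiased >= st$he_plain))
  expect_true(all(st$pid_sib >= st$pid))
})

test_that("panel power orders loci, multiplies, and finds the panel size", {
  s <- tibble::tibble(locus = c("a", "b", "c"),
                      pid = c(0.5, 0.1, 0.3))
  pp <- panel_power(s, "pid", threshold = 0.05)
  expect_equal(pp$locus, c("b", "c", "a"))
  expect_equal(pp$cumulative, cumprod(c(0.1, 0.3, 0.5)))
  expect_equal(attr(pp, "min_loci"), 2L)  # 0.1, then 0.03 < 0.05
  expect_true(all(diff(pp$cumulative) <= 0))
  # brute-force loop agrees with the vectorised product
  naive <- numeric(3)
  acc <- 1
  for (i in seq_along(pp$p)) {
    acc <- acc * pp$p[i]
    naive[i] <- acc
  }
  expect_equal(pp$cumulative, naive)
  # unreachable threshold reports the sentinel
  single <- panel_power(tibble::tibble(locus = "x", pid = 0.5), "pid", 1e-4)
  expect_true(is.na(attr(single, "min_loci")))
  g <- glance(single)
  expect_equal(g$n_loci, 1L)
  expect_true(is.na(g$min_loci))
})

test_that("concordance classifies dropout, false alleles and matches", {
  ref <- genotype_table(c("i1", "i1", "i2", "i2"),
                        c("L1", "L2", "L1", "L2"),
                        c(120, 140, 120, 144), c(124, 140, 120, 148))
  expect_equal(glance(genotype_concordance(ref, ref))$match_rate, 1)
  test <- genotype_table(c("i1", "i1", "i2", "i2"),
                         c("L1", "L2", "L1", "L2"),
                         c(120, 140, 120, 144), c(120, 152, 120, 148))
  conc <- genotype_concordance(ref, test)
  cls <- tidy(conc)$class
  expect_equal(sort(cls), sort(c("allelic_dropout", "false_allele",
                                 "match", "match")))
  expect_equal(glance(conc)$n_het_ref, 2L)
  empty_overlap <- genotype_table("i9", "L9", 1, 1)
  expect_error(genotype_concordance(ref, empty_overlap),
               class = "strmarker_no_overlap")
})
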