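# minimal cluster-like tibble for filter tests
fake_cluster <- function(alleles_bp, support = 5L, motif = "AC",
                         left = NULL, right = NULL, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    cluster_id = "L0001",
    canonical_motif = motif,
    n_reads = sum(support),
    consensus_left = left %||% random_dna_str(60),
    consensus_right = right %||% random_dna_str(60),
    members = list(tibble::tibble()),
    alleles = list(tibble::tibble(length_bp = as.integer(alleles_bp),
                                  support = rep(as.integer(support),
                                                length(alleles_bp)))),
    n_alleles = length(alleles_bp),
    status = if (length(alleles_bp) > 1) "polymorphic" else "monomorphic",
    nonmultiple_spacing = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("repeat-count rule: fewer than 6 units is excluded", {
  ok <- suppressWarnings(filter_loci(fake_cluster(c(20, 24))))   # 10, 12 units
  expect_true(ok$passed)
  bad <- suppressWarnings(filter_loci(fake_cluster(c(8, 10))))   # 4, 5 units
  expect_false(bad$passed)
  expect_true("TOO_FEW_REPEATS" %in% bad$reasons[[1]])
  # the rule looks at the longest allele only
  mixed <- suppressWarnings(filter_loci(fake_cluster(c(8, 14))))  # 4, 7 units
  expect_false("TOO_FEW_REPEATS" %in% mixed$reasons[[1]])
})

test_that("allele spans broader than the cap are excluded", {
  bad <- suppressWarnings(filter_loci(fake_cluster(c(12, 40))))  # span 28 > 20
  expect_true("BROAD_RANGE" %in% bad$reasons[[1]])
  ok <- suppressWarnings(filter_loci(fake_cluster(c(12, 32))))   # span 20
  expect_false("BROAD_RANGE" %in% ok$reasons[[1]])
})

test_that("failures accumulate instead of stopping at the first rule", {
  cl <- fake_cluster(c(12, 40), left = strrep("ACGT", 15))  # span 28 > 20
  out <- suppressWarnings(filter_loci(cl))
  expect_setequal(out$reasons[[1]], c("BROAD_RANGE", "REPETITIVE"))
  expect_false(out$passed)
})

test_that("low_complexity_score matches the triplet-pair-count oracle", {
  # direct triplet-count oracle on random 20-mers
  set.seed(20)
  for (i in 1:10) {
    s <- random_dna_str(20)
    tri <- substring(s, 1:18, 3:20)
    cnt <- table(tri)
    expect_equal(low_complexity_score(s), sum(cnt * (cnt - 1) / 2) / 17)
  }
  # (ACGT)n: window of 20 has triplet counts 5,5,4,4 -> C(5,2)*2+C(4,2)*2
  s <- strrep("ACGT", 5)
  expect_equal(low_complexity_score(s), (10 + 10 + 6 + 6) / 17)
  # homopolymer: one triplet occurs 18 times
  expect_equal(low_complexity_score(strrep("A", 20)), (18 * 17 / 2) / 17)
  expect_error(low_complexity_score("ACGT"), class = "strmarker_short_seq")
})

test_that("low_complexity_score is monotone in triplet over-representation", {
  base <- "ACGTAGCTTGCATGACTGAC"
  rep1 <- "ACGTAGCTTGCATGACGTAG"  # reuses ACG/CGT/GTA triplets
  expect_gte(low_complexity_score(rep1), low_complexity_score(base))
})

test_that("contaminant similarity finds planted matches on both strands", {
  set.seed(21)
  flank <- random_dna_str(50)
  backbone <- random_dna_str(5000)
  contaminated <- paste0(substr(backbone, 1, 2000), flank,
                         substr(backbone, 2001, 5000))
  idx <- c(human1 = contaminated)
  expect_equal(contaminant_similarity(flank, idx)$identity, 1.0)
  expect_equal(contaminant_similarity(dna_revcomp(flank), idx)$identity, 1.0)
  expect_error(contaminant_similarity(flank, character(0)),
               class = "strmarker_empty_index")
})

test_that("random flanks stay below the contaminant threshold", {
  set.seed(22)
  idx <- c(h = random_dna_str(10000))
  worst <- 0
  for (i in 1:25) {
    sim <- contaminant_similarity(random_dna_str(60), idx)
    worst <- max(worst, sim$identity)
  }
  expect_lt(worst, 0.90)
})

test_that("a verbatim contaminant flank triggers CONTAMINANT_LIKE", {
  set.seed(23)
  left <- random_dna_str(60)
  cl <- fake_cluster(c(20, 24), left = left)
  out <- filter_loci(cl, contaminant = c(h = paste0(random_dna_str(500),
                                                    left,
                                                    random_dna_str(500))))
  expect_true("CONTAMINANT_LIKE" %in% out$reasons[[1]])
  # and skipping the index warns rather than silently passing
  expect_warning(filter_loci(cl), class = "strmarker_no_contaminant")
})

test_that("tightening thresholds never lets more loci through", {
  set.seed(24)
  cls <- dplyr::bind_rows(lapply(1:12, function(i) {
    u <- sample(c(6, 10, 14), 1)
    spread <- sample(c(0, 8, 30), 1)
    fake_cluster(c(u * 2, u * 2 + spread), seed = i) |>
      dplyr::mutate(cluster_id = sprintf("L%04d", i))
  }))
  loose <- suppressWarnings(
    filter_loci(cls, filter_config(min_unit_count = 5,
                                   max_allele_range_bp = 30)))
  tight <- suppressWarnings(
    filter_loci(cls, filter_config(min_unit_count = 8,
                                   max_allele_range_bp = 10)))
  expect_lte(sum(tight$passed), sum(loose$passed))
})

test_that("shared flank anchors across clusters flag multi-copy context", {
  set.seed(25)
  shared_left <- random_dna_str(60)
  cls <- dplyr::bind_rows(lapply(1:3, function(i) {
    fake_cluster(c(20, 24), left = shared_left, seed = 100 + i) |>
      dplyr::mutate(cluster_id = sprintf("L%04d", i))
  }))
  out <- suppressWarnings(filter_loci(cls))  # 3 clusters share one anchor
  expect_true(all(vapply(out$reasons,
                         function(r) "REPETITIVE" %in% r, logical(1))))
})
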