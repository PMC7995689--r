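# a tiny planted locus: unique flanks around an (AC)n array
make_locus_reads <- function(left, right, unit = "AC", counts = c(8, 10),
                             per_allele = 4) {
  # keep flank boundaries from extending the planted array
  sf <- safe_flanks(left, right, unit)
  left <- sf$left
  right <- sf$right
  reads <- character()
  for (k in seq_along(counts)) {
    full <- paste0(left, strrep(unit, counts[k]), right)
    for (r in seq_len(per_allele)) {
      s <- full
      if (r %% 2 == 0) s <- dna_revcomp(s)
      reads <- c(reads, s)
    }
  }
  names(reads) <- paste0("a", rep(seq_along(counts), each = per_allele),
                         "_r", rep(seq_len(per_allele), length(counts)))
  reads
}

test_that("orienting a hit and its reverse-complement mate is consistent", {
  reads <- c(fwd = "GGGGGCCCGGGGGGAATTCCCCCACACACACACTTTTTCCTTGGAAGGTT")
  h1 <- scan_reads(reads)
  h2 <- scan_reads(c(rev = dna_revcomp(reads[[1]])))
  o1 <- orient_hits(h1)
  o2 <- orient_hits(h2)
  expect_equal(o1$left_flank, o2$left_flank)
  expect_equal(o1$right_flank, o2$right_flank)
  expect_equal(o1$unit, o2$unit)
  # idempotent
  expect_equal(orient_hits(o1)[names(o1)], o1[names(o1)])
})

test_that("orientation does not depend on read truncation", {
  set.seed(5)
  left <- random_dna_str(40)
  right <- random_dna_str(40)
  full <- paste0(left, strrep("AC", 9), "", right)
  # same locus seen in differently-trimmed windows, both strands
  views <- c(substr(full, 1, 90), substr(full, 8, 98),
             dna_revcomp(substr(full, 3, 95)))
  hits <- orient_hits(scan_reads(stats::setNames(views, paste0("v", 1:3))))
  expect_equal(length(unique(hits$unit)), 1L)
  # all oriented right flanks are prefixes of the longest one
  rf <- hits$right_flank[order(-nchar(hits$right_flank))]
  expect_true(all(startsWith(rf[1], rf)))
})

test_that("one planted locus from both strands forms one cluster", {
  set.seed(11)
  reads <- make_locus_reads(random_dna_str(30), random_dna_str(30))
  cl <- cluster_hits(scan_reads(reads))
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$n_reads, 8L)
  expect_equal(cl$canonical_motif, "AC")
})

test_that("same motif with unrelated flanks yields separate clusters", {
  set.seed(12)
  r1 <- make_locus_reads(random_dna_str(30), random_dna_str(30))
  set.seed(13)
  r2 <- make_locus_reads(random_dna_str(30), random_dna_str(30))
  names(r2) <- paste0("b", names(r2))
  cl <- cluster_hits(scan_reads(c(r1, r2)))
  expect_equal(nrow(cl), 2L)
})

test_that("clustering is invariant to read input order", {
  set.seed(14)
  reads <- c(make_locus_reads(random_dna_str(30), random_dna_str(30)),
             stats::setNames(
               make_locus_reads(random_dna_str(30), random_dna_str(30),
                                unit = "AAG", counts = c(6, 8)),
               paste0("x", 1:8)))
  h <- scan_reads(reads)
  cl1 <- cluster_hits(h)
  set.seed(15)
  cl2 <- cluster_hits(h[sample(nrow(h)), ])
  expect_equal(cl1$canonical_motif, cl2$canonical_motif)
  expect_equal(cl1$n_reads, cl2$n_reads)
  expect_equal(cl1$consensus_left, cl2$consensus_left)
})

test_that("short-flank hits are set aside as unclusterable", {
  reads <- c(r = paste0("GGATC", strrep("AC", 8), "CCTAG"))  # 5 bp flanks
  cl <- cluster_hits(scan_reads(reads), min_flank = 20)
  expect_equal(nrow(cl), 0L)
  expect_equal(nrow(attr(cl, "unclusterable")), 1L)
})

test_that("allele calling counts support and drops rare alleles", {
  set.seed(16)
  left <- random_dna_str(30); right <- random_dna_str(30)
  reads <- make_locus_reads(left, right, counts = c(8, 10), per_allele = 4)
  # one stray read with a third allele, below min_support
  reads <- c(reads, stray = unname(
    make_locus_reads(left, right, counts = 13, per_allele = 1)))
  cl <- call_alleles(cluster_hits(scan_reads(reads)), min_support = 2)
  expect_equal(cl$status, "polymorphic")
  al <- cl$alleles[[1]]
  expect_setequal(al$length_bp, c(16L, 20L))
  expect_equal(al$support[order(al$length_bp)], c(4L, 4L))
})

test_that("arrays touching a read end never vote an allele", {
  set.seed(17)
  left <- random_dna_str(30); right <- random_dna_str(30)
  reads <- make_locus_reads(left, right, counts = c(8), per_allele = 4)
  # truncated view: array runs to the read end, apparent length 6 units;
  # with no right flank it cannot be placed, let alone vote
  reads <- c(reads, trunc = paste0(left, strrep("AC", 6)))
  cl <- call_alleles(cluster_hits(scan_reads(reads)), min_support = 1)
  expect_equal(cl$n_reads, 4L)
  expect_equal(nrow(attr(cl, "unclusterable")), 1L)
  expect_equal(cl$alleles[[1]]$length_bp, 16L)  # 12 bp phantom not called
  expect_equal(cl$status, "monomorphic")
})

test_that("support below min_support on all alleles gives ambiguous", {
  set.seed(18)
  reads <- make_locus_reads(random_dna_str(30), random_dna_str(30),
                            counts = c(8, 10), per_allele = 1)
  cl <- call_alleles(cluster_hits(scan_reads(reads)), min_support = 2)
  expect_equal(cl$status, "ambiguous")
})

test_that("consensus locus sequence reconstructs flank + array + flank", {
  set.seed(19)
  left <- random_dna_str(30); right <- random_dna_str(30)
  reads <- make_locus_reads(left, right, counts = c(8, 8, 10),
                            per_allele = 3)
  cl <- call_alleles(cluster_hits(scan_reads(reads)), min_support = 2)
  cons <- locus_consensus(cl)
  expect_equal(nrow(cons), 1L)
  expect_equal(cons$array_end - cons$array_start, 16L)  # modal allele
  sf <- safe_flanks(left, right, "AC")
  full <- paste0(sf$left, strrep("AC", 8), sf$right)
  expect_true(cons$seq %in% c(full, dna_revcomp(full)))
})
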