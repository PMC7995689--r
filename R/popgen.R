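#' Build a diploid genotype table
#'
#' The package-wide genotype container is a long tibble with one row per
#' (individual, locus) call: columns `individual`, `locus`, `allele1`,
#' `allele2`. Allele labels are allele sizes in bp (integers); a missing
#' call has both alleles `NA`. Allele labels are comparable within a locus
#' only.
#'
#' @param individual,locus Character vectors.
#' @param allele1,allele2 Integer allele labels (`NA` for missing).
#' @return A tibble of class `str_genotypes`.
#' @export
genotype_table <- function(individual, locus, allele1, allele2) {
  half <- xor(is.na(allele1), is.na(allele2))
  if (any(half)) {
    rlang::abort("half-missing calls are not allowed (diploid data)",
                 class = "strmarker_bad_genotypes")
  }
  out <- tibble::tibble(individual = as.character(individual),
                        locus = as.character(locus),
                        allele1 = as.integer(allele1),
                        allele2 = as.integer(allele2))
  class(out) <- c("str_genotypes", class(out))
  out
}

typed_calls <- function(gt, locus) {
  g <- gt[gt$locus == locus & !is.na(gt$allele1), , drop = FALSE]
  if (nrow(g) == 0L) {
    rlang::abort(paste0("no typed individuals at locus ", locus),
                 class = "strmarker_no_data")
  }
  g
}

#' Sample allele frequencies at one or all loci
#'
#' Counting estimator over non-missing calls only: `p_i = count_i / (2 n)`
#' for `n` typed diploid individuals (pairwise deletion of missing data).
#'
#' @param gt A genotype table (see [genotype_table()]).
#' @param locus Optional single locus id; default all loci.
#' @return Tibble with `locus`, `allele`, `freq`, `n_typed`.
#' @export
allele_frequencies <- function(gt, locus = NULL) {
  loci <- if (is.null(locus)) unique(gt$locus) else locus
  purrr::map(loci, function(l) {
    g <- typed_calls(gt, l)
    counts <- table(c(g$allele1, g$allele2))
    tibble::tibble(locus = l,
                   allele = as.integer(names(counts)),
                   freq = as.numeric(counts) / (2 * nrow(g)),
                   n_typed = nrow(g))
  }) |>
    dplyr::bind_rows()
}

#' Observed heterozygosity
#'
#' Fraction of typed individuals carrying two distinct alleles.
#'
#' @inheritParams allele_frequencies
#' @return Tibble with `locus`, `ho`, `n_typed`.
#' @export
observed_heterozygosity <- function(gt, locus = NULL) {
  loci <- if (is.null(locus)) unique(gt$locus) else locus
  purrr::map(loci, function(l) {
    g <- typed_calls(gt, l)
    tibble::tibble(locus = l,
                   ho = mean(g$allele1 != g$allele2),
                   n_typed = nrow(g))
  }) |>
    dplyr::bind_rows()
}

#' Expected heterozygosity from allele frequencies
#'
#' Plain gene diversity `1 - sum(p_i^2)`; the unbiased small-sample
#' estimator multiplies by `2n / (2n - 1)` for `n` typed diploids.
#'
#' @param p Numeric vector of allele frequencies (sums to 1).
#' @param n_typed Number of typed diploid individuals (required when
#'   `unbiased = TRUE`).
#' @param unbiased Apply the `2n/(2n-1)` correction (default TRUE).
#' @return Expected heterozygosity.
#' @examples
#' expected_heterozygosity(c(0.9, 0.1), n_typed = 5)  # 0.20
#' @export
expected_heterozygosity <- function(p, n_typed = NULL, unbiased = TRUE) {
  check_freqs(p)
  he <- 1 - sum(p^2)
  if (!unbiased) return(he)
  if (is.null(n_typed) || n_typed < 1L) {
    rlang::abort("n_typed is required for the unbiased estimator",
                 class = "strmarker_bad_arg")
  }
  he * 2 * n_typed / (2 * n_typed - 1)
}

check_freqs <- function(p) {
  stopifnot(is.numeric(p), length(p) >= 1L, all(p > 0), all(p <= 1))
  if (abs(sum(p) - 1) > 1e-9) {
    rlang::abort("allele frequencies must sum to 1",
                 class = "strmarker_bad_freqs")
  }
}

#' Probability of identity for unrelated individuals
#'
#' The probability that two unrelated individuals drawn from a population
#' in Hardy-Weinberg proportions share a genotype at this locus (Waits,
#' Luikart & Taberlet 2001):
#' `PID = sum(p_i^4) + sum_{i<j} (2 p_i p_j)^2`.
#'
#' @param p Numeric vector of allele frequencies.
#' @return Probability in (0, 1].
#' @examples
#' pid(c(0.5, 0.5))   # 0.375
#' pid(c(0.9, 0.1))   # 0.6886
#' @export
pid <- function(p) {
  check_freqs(p)
  s2 <- sum(p^2)
  s4 <- sum(p^4)
  # sum_{i<j} (2 p_i p_j)^2 = 2 * (s2^2 - s4) ... using (sum p^2)^2 =
  # s4 + 2 sum_{i<j} p_i^2 p_j^2
  s4 + 4 * (s2^2 - s4) / 2
}

#' Probability of identity among full siblings
#'
#' The conservative sibling bound of Waits et al. (2001):
#' `PIDsib = 0.25 + 0.5 sum(p_i^2) + 0.5 (sum(p_i^2))^2 - 0.25 sum(p_i^4)`.
#' Always at least as large as [pid()].
#'
#' @inheritParams pid
#' @return Probability in (0, 1].
#' @examples
#' pid_sib(c(0.5, 0.5))  # 0.59375
#' @export
pid_sib <- function(p) {
  check_freqs(p)
  s2 <- sum(p^2)
  0.25 + 0.5 * s2 + 0.5 * s2^2 - 0.25 * sum(p^4)
}

#' Inbreeding coefficient F_IS
#'
#' Deviation of observed from Hardy-Weinberg expected heterozygosity within
#' one population. `simple` is `1 - Ho / He_unbiased`. `weir_cockerham` is
#' the Weir & Cockerham (1984) single-population estimator `f` from
#' variance components: per allele `i`, with frequency `p_i`, observed
#' heterozygote frequency `h_i` (individuals carrying allele `i`
#' heterozygously) and `n` typed individuals,
#' `b_i = n/(n-1) * (p_i (1-p_i) - h_i (2n-1)/(4n))`, `c_i = h_i / 2`, and
#' `f = 1 - sum(c) / sum(b + c)`.
#'
#' @inheritParams allele_frequencies
#' @param estimator `"weir_cockerham"` (default) or `"simple"`.
#' @return Tibble with `locus`, `fis`, `estimator`, `n_typed`. Monomorphic
#'   loci give `NA` (F_IS is undefined there, not zero).
#' @export
fis <- function(gt, locus = NULL,
                estimator = c("weir_cockerham", "simple")) {
  estimator <- match.arg(estimator)
  loci <- if (is.null(locus)) unique(gt$locus) else locus
  purrr::map(loci, function(l) {
    g <- typed_calls(gt, l)
    n <- nrow(g)
    alleles <- sort(unique(c(g$allele1, g$allele2)))
    if (length(alleles) < 2L || n < 2L) {
      return(tibble::tibble(locus = l, fis = NA_real_,
                            estimator = estimator, n_typed = n))
    }
    val <- if (estimator == "simple") {
      p <- as.numeric(table(c(g$allele1, g$allele2))) / (2 * n)
      1 - mean(g$allele1 != g$allele2) /
        expected_heterozygosity(p, n_typed = n)
    } else {
      het <- g$allele1 != g$allele2
      b <- c <- numeric(length(alleles))
      for (k in seq_along(alleles)) {
        a <- alleles[k]
        p <- mean(c(g$allele1, g$allele2) == a)
        h <- mean(het & (g$allele1 == a | g$allele2 == a))
        b[k] <- n / (n - 1) * (p * (1 - p) - h * (2 * n - 1) / (4 * n))
        c[k] <- h / 2
      }
      1 - sum(c) / sum(b + c)
    }
    tibble::tibble(locus = l, fis = val, estimator = estimator, n_typed = n)
  }) |>
    dplyr::bind_rows()
}

#' Per-locus summary statistics for a marker panel
#'
#' One row per locus: allele count `A`, observed heterozygosity `ho`,
#' expected heterozygosity plain and unbiased, F_IS by both estimators,
#' and the probabilities of identity. Missing calls are dropped locus-wise
#' (pairwise deletion). Internal arithmetic is full precision; use
#' `round(x, 2)` for a report matching the usual 2-decimal display.
#'
#' @inheritParams allele_frequencies
#' @return A tibble of class `str_locus_stats` with columns `locus`,
#'   `n_typed`, `a`, `ho`, `he_plain`, `he_unbiased`, `fis_simple`,
#'   `fis_wc`, `pid`, `pid_sib`.
#' @export
locus_stats <- function(gt) {
  loci <- unique(gt$locus)
  out <- purrr::map(loci, function(l) {
    fr <- allele_frequencies(gt, l)
    p <- fr$freq
    n <- fr$n_typed[1L]
    tibble::tibble(
      locus = l,
      n_typed = n,
      a = length(p),
      ho = observed_heterozygosity(gt, l)$ho,
      he_plain = expected_heterozygosity(p, unbiased = FALSE),
      he_unbiased = expected_heterozygosity(p, n_typed = n),
      fis_simple = fis(gt, l, "simple")$fis,
      fis_wc = fis(gt, l, "weir_cockerham")$fis,
      pid = pid(p),
      pid_sib = pid_sib(p))
  }) |>
    dplyr::bind_rows()
  class(out) <- c("str_locus_stats", class(out))
  out
}

#' Cumulative identity power of a marker panel
#'
#' Orders loci by increasing per-locus probability of identity (the most
#' informative first), multiplies the probabilities across loci, and finds
#' the smallest panel whose cumulative probability drops below the
#' threshold. Under locus independence the product is the probability that
#' two individuals (unrelated, or full siblings for the `pid_sib`
#' criterion) share the full multilocus genotype.
#'
#' @param summaries A data frame with a `locus` column and the criterion
#'   column (`pid` or `pid_sib`), e.g. [locus_stats()] output.
#' @param criterion `"pid"` (default) or `"pid_sib"`.
#' @param threshold Target cumulative probability (default 1e-4).
#' @return A tibble of class `str_panel_power`: `rank`, `locus`, the
#'   per-locus probability `p`, and `cumulative`. Attributes `min_loci`
#'   (smallest rank with cumulative < threshold, `NA_integer_` if never
#'   reached), `criterion` and `threshold`; see [glance.str_panel_power()].
#' @export
panel_power <- function(summaries, criterion = c("pid", "pid_sib"),
                        threshold = 1e-4) {
  criterion <- match.arg(criterion)
  stopifnot(threshold > 0, threshold < 1,
            all(c("locus", criterion) %in% names(summaries)))
  ord <- order(summaries[[criterion]], summaries$locus)
  ps <- summaries[[criterion]][ord]
  out <- tibble::tibble(rank = seq_along(ord),
                        locus = summaries$locus[ord],
                        p = ps,
                        cumulative = cumprod(ps))
  hit <- which(out$cumulative < threshold)
  attr(out, "min_loci") <- if (length(hit)) hit[1L] else NA_integer_
  attr(out, "criterion") <- criterion
  attr(out, "threshold") <- threshold
  class(out) <- c("str_panel_power", class(out))
  out
}

#' Concordance between paired genotype tables
#'
#' Compares calls for the same (individual, locus) between a reference
#' table (for example blood-derived genotypes) and a test table (for
#' example fecal-derived). Each pair with both calls present is classified:
#' `match` (same unordered pair), `allelic_dropout` (heterozygous in the
#' reference, homozygous for one of its alleles in the test), and
#' `false_allele` (the test carries an allele absent from the reference
#' call); anything else is `other_mismatch`. Rate estimates: the
#' false-allele rate is `n_false / n_compared`; the dropout rate divides
#' dropouts by reference heterozygote pairs not already consumed by a false
#' allele, `n_dropout / (n_het_ref * (1 - false_rate))`.
#'
#' @param reference,test Genotype tables (see [genotype_table()]).
#' @return A list of class `str_concordance` with `pairs` (per-pair tibble
#'   with `class` column) and `rates` (one-row tibble of counts and rate
#'   estimates); see [glance.str_concordance()].
#' @export
genotype_concordance <- function(reference, test) {
  j <- dplyr::inner_join(reference, test, by = c("individual", "locus"),
                         suffix = c("_ref", "_test"))
  j <- j[!is.na(j$allele1_ref) & !is.na(j$allele1_test), , drop = FALSE]
  if (nrow(j) == 0L) {
    rlang::abort("no overlapping typed (individual, locus) pairs",
                 class = "strmarker_no_overlap")
  }
  cls <- purrr::pmap_chr(
    j[, c("allele1_ref", "allele2_ref", "allele1_test", "allele2_test")],
    function(allele1_ref, allele2_ref, allele1_test, allele2_test) {
      ref <- sort(c(allele1_ref, allele2_ref))
      tst <- sort(c(allele1_test, allele2_test))
      if (identical(ref, tst)) return("match")
      if (any(!tst %in% ref)) return("false_allele")
      if (ref[1] != ref[2] && tst[1] == tst[2] && tst[1] %in% ref) {
        return("allelic_dropout")
      }
      "other_mismatch"
    })
  pairs <- dplyr::mutate(j, class = cls)
  n <- nrow(pairs)
  n_het_ref <- sum(pairs$allele1_ref != pairs$allele2_ref)
  n_false <- sum(cls == "false_allele")
  n_drop <- sum(cls == "allelic_dropout")
  false_rate <- n_false / n
  dropout_rate <- if (n_het_ref > 0) {
    n_drop / (n_het_ref * (1 - false_rate))
  } else {
    NA_real_
  }
  rates <- tibble::tibble(
    n_compared = n, n_match = sum(cls == "match"),
    n_het_ref = n_het_ref, n_allelic_dropout = n_drop,
    n_false_allele = n_false,
    n_other_mismatch = sum(cls == "other_mismatch"),
    match_rate = sum(cls == "match") / n,
    allelic_dropout_rate = dropout_rate,
    false_allele_rate = false_rate)
  structure(list(pairs = tibble::as_tibble(pairs), rates = rates),
            class = "str_concordance")
}
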