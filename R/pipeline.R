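#' Run the full marker-discovery pipeline on reads
#'
#' Chains the discovery stages: scan reads for perfect STRs, cluster hits
#' into loci by flank identity, call allele spectra and polymorphism,
#' apply the exclusion filters to polymorphic clusters, reconstruct
#' consensus locus sequences, and design primer pairs. Read provenance
#' (an `individual` column on `reads`) is propagated so allele support per
#' individual is retained.
#'
#' @param reads Tibble with `read_id`, `seq`, optionally `individual`.
#' @param contaminant Optional named character vector of contaminant
#'   sequences for the similarity screen.
#' @param min_units Scanner threshold (default 4).
#' @param anchor_k,min_flank,max_mismatch Clustering parameters.
#' @param min_support Reads per allele (default 2).
#' @param filter_cfg A [filter_config()].
#' @param primer_cfg A [primer_constraints()].
#' @return List with `hits`, `clusters` (with allele calls), `candidates`
#'   (polymorphic clusters with filter outcomes), `loci` (consensus
#'   sequences + allele lengths for passing loci) and `primers`.
#' @export
discover_markers <- function(reads, contaminant = NULL, min_units = 4L,
                             anchor_k = 12L, min_flank = 20L,
                             max_mismatch = 2L, min_support = 2L,
                             filter_cfg = filter_config(),
                             primer_cfg = primer_constraints()) {
  hits <- scan_reads(reads, min_units = min_units)
  if ("individual" %in% names(reads)) {
    hits <- dplyr::left_join(hits,
                             dplyr::distinct(reads[, c("read_id",
                                                       "individual")]),
                             by = "read_id")
  }
  clusters <- cluster_hits(hits, anchor_k = anchor_k, min_flank = min_flank,
                           max_mismatch = max_mismatch)
  clusters <- call_alleles(clusters, min_support = min_support)
  poly <- clusters[clusters$status == "polymorphic", , drop = FALSE]
  candidates <- filter_loci(poly, config = filter_cfg,
                            contaminant = contaminant, anchor_k = anchor_k)
  passing <- candidates[candidates$passed, , drop = FALSE]
  loci <- locus_consensus(passing)
  loci$allele_lengths <- purrr::map(
    passing$alleles[match(loci$cluster_id, passing$cluster_id)],
    function(a) sort(a$length_bp))
  primers <- design_primers(loci, constraints = primer_cfg)
  list(hits = hits, clusters = clusters, candidates = candidates,
       loci = loci, primers = primers)
}

#' Per-allele template sequences for a designed locus
#'
#' Rebuilds, for each allele length, the consensus left flank + array +
#' right flank, giving the templates an in-silico PCR validation should
#' amplify.
#'
#' @param loci [locus_consensus()] output with an `allele_lengths` column.
#' @return Tibble with `cluster_id`, `allele_bp`, `template_id`, `seq`.
#' @export
allele_templates <- function(loci) {
  rows <- purrr::pmap(
    list(loci$cluster_id, loci$seq, loci$array_start, loci$array_end,
         loci$unit, loci$allele_lengths),
    function(id, seq, a0, a1, unit, alleles) {
      left <- substr(seq, 1L, a0)
      right <- substr(seq, a1 + 1L, nchar(seq))
      tibble::tibble(
        cluster_id = id,
        allele_bp = alleles,
        template_id = sprintf("%s_a%d", id, alleles),
        seq = vapply(alleles, function(a) {
          paste0(left, substr(strrep(unit, ceiling(a / nchar(unit))), 1L, a),
                 right)
        }, character(1)))
    })
  dplyr::bind_rows(rows)
}

#' Validate designed markers by in-silico PCR round trip
#'
#' Amplifies each designed primer pair against the per-allele templates of
#' its locus and classifies the outcome. For a well-designed pair every
#' allele template yields exactly one product whose length equals the
#' designed per-allele product size.
#'
#' @param primers [design_primers()] output.
#' @param loci The matching [locus_consensus()] table with
#'   `allele_lengths`.
#' @param max_mismatch,three_prime_exact,max_product Passed to [amplify()].
#' @return Tibble with `cluster_id`, `status`, `products` (list) and
#'   `round_trip_exact` (every allele recovered at its designed size).
#' @export
validate_markers <- function(primers, loci, max_mismatch = 2L,
                             three_prime_exact = 3L, max_product = 1000L) {
  templates <- allele_templates(loci)
  rows <- purrr::map(seq_len(nrow(primers)), function(i) {
    pr <- primers[i, ]
    if (is.na(pr$forward)) {
      return(tibble::tibble(cluster_id = pr$cluster_id,
                            status = "no_product", products = list(NULL),
                            round_trip_exact = FALSE))
    }
    tpl <- templates[templates$cluster_id == pr$cluster_id, , drop = FALSE]
    prods <- amplify(pr$forward, pr$reverse,
                     stats::setNames(tpl$seq, tpl$template_id),
                     max_mismatch = max_mismatch,
                     three_prime_exact = three_prime_exact,
                     max_product = max_product)
    cls <- classify_marker(prods)
    expected <- pr$product_size_by_allele[[1L]]
    got <- split(prods$length, prods$template_id)
    exact <- nrow(tpl) > 0L && all(tpl$template_id %in% names(got)) &&
      all(vapply(seq_len(nrow(tpl)), function(k) {
        g <- got[[tpl$template_id[k]]]
        length(g) == 1L &&
          g == expected[as.character(tpl$allele_bp[k])]
      }, logical(1)))
    tibble::tibble(cluster_id = pr$cluster_id, status = cls$status,
                   products = list(prods), round_trip_exact = exact)
  })
  dplyr::bind_rows(rows)
}
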