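#' Filter configuration for candidate loci
#'
#' Thresholds for the exclusion rules applied to polymorphic clusters:
#' minimum tandem-repeat count, maximum allele size range, low-complexity
#' flank score, contaminant similarity, and the amplicon-size cap carried
#' through to primer design.
#'
#' @param min_unit_count Loci whose longest allele has fewer whole repeat
#'   units than this are excluded (default 6).
#' @param max_allele_range_bp Maximum allowed spread between the shortest
#'   and longest allele, in bp (default 20); broader spectra usually signal
#'   cluster collapse of paralogous copies.
#' @param low_complexity_threshold Flanks scoring above this DUST-like
#'   triplet score are treated as repetitive-element context (default 1.5).
#' @param low_complexity_window Sliding window for the score (default 20).
#' @param copy_number_cap A flank anchor k-mer seen in more than this many
#'   distinct clusters marks multi-copy context (default 2).
#' @param contaminant_identity_threshold Minimum ungapped identity, over at
#'   least `contaminant_min_span` bp, for a flank to count as
#'   contaminant-like (default 0.90).
#' @param contaminant_min_span Minimum matched span in bp (default 30).
#' @param max_amplicon_bp Product-size cap for downstream primer design
#'   (default 150), chosen for degraded template DNA.
#' @param flank_window Only this many consensus-flank bases adjacent to the
#'   array (default 60) are screened for complexity and contaminant
#'   similarity: that is the region a short-amplicon primer can occupy, and
#'   consensus flanks further out may run into unrelated neighbouring
#'   sequence.
#' @return A named list of class `str_filter_config`.
#' @export
filter_config <- function(min_unit_count = 6L,
                          max_allele_range_bp = 20L,
                          low_complexity_threshold = 1.5,
                          low_complexity_window = 20L,
                          copy_number_cap = 2L,
                          contaminant_identity_threshold = 0.90,
                          contaminant_min_span = 30L,
                          max_amplicon_bp = 150L,
                          flank_window = 60L) {
  cfg <- list(min_unit_count = min_unit_count,
              max_allele_range_bp = max_allele_range_bp,
              low_complexity_threshold = low_complexity_threshold,
              low_complexity_window = low_complexity_window,
              copy_number_cap = copy_number_cap,
              contaminant_identity_threshold = contaminant_identity_threshold,
              contaminant_min_span = contaminant_min_span,
              max_amplicon_bp = max_amplicon_bp,
              flank_window = flank_window)
  stopifnot(all(vapply(cfg, function(x) is.numeric(x) && x > 0, logical(1))))
  structure(cfg, class = "str_filter_config")
}

#' DUST-like low-complexity score
#'
#' Scores triplet over-representation: within each sliding window of
#' `window` bases, every triplet occurring `c` times contributes
#' `choose(c, 2)`, and the sum is normalised by the number of triplet
#' positions minus one. A window of all-distinct triplets scores 0; a
#' homopolymer run scores the maximum for its window. The score is
#' monotonically non-decreasing in any triplet's count.
#'
#' @param seq Character vector of DNA strings, each at least `window` long.
#' @param window Window size in bases (default 20).
#' @return Numeric vector: the maximum window score per sequence.
#' @export
low_complexity_score <- function(seq, window = 20L) {
  vapply(stringr::str_to_upper(seq), function(s) {
    n <- nchar(s)
    if (n < window) {
      rlang::abort("sequence shorter than the scoring window",
                   class = "strmarker_short_seq")
    }
    starts <- seq_len(n - window + 1L)
    max(vapply(starts, function(i) {
      w <- substr(s, i, i + window - 1L)
      tri <- substring(w, 1:(window - 2L), 3:window)
      cnt <- table(tri)
      sum(cnt * (cnt - 1) / 2) / (window - 3L)
    }, numeric(1)))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Best ungapped similarity of a flank to a contaminant sequence set
#'
#' Seed-and-extend search: exact `seed_k`-mer matches seed ungapped
#' extensions scored +1 per match and -2 per mismatch; the best-scoring
#' segment of at least `min_span` bases on each seeded diagonal is
#' evaluated and the maximum identity over both strands of the query and
#' all index sequences is returned. Deterministic.
#'
#' @param flank DNA string to screen.
#' @param contaminant Named character vector of contaminant sequences (for
#'   example a human decoy set), as read by [read_sequences()].
#' @param seed_k Seed length (default 12).
#' @param min_span Minimum matched span to report (default 30).
#' @return A tibble with `identity` (fraction, 0 if no seeded segment of
#'   sufficient span) and `span` (bp).
#' @export
contaminant_similarity <- function(flank, contaminant, seed_k = 12L,
                                   min_span = 30L) {
  if (length(contaminant) == 0L) {
    rlang::abort("contaminant index is empty", class = "strmarker_empty_index")
  }
  best <- c(0, 0)
  for (q in c(flank, dna_revcomp(flank))) {
    for (s in contaminant) {
      r <- cpp_best_identity(stringr::str_to_upper(q),
                             stringr::str_to_upper(s),
                             as.integer(seed_k), as.integer(min_span))
      if (r[1] > best[1] || (r[1] == best[1] && r[2] > best[2])) best <- r
    }
  }
  tibble::tibble(identity = best[1], span = as.integer(best[2]))
}

#' Apply exclusion rules to polymorphic candidate loci
#'
#' Each cluster accumulates every failing rule (not just the first):
#' `TOO_FEW_REPEATS` when the longest surviving allele has fewer whole
#' units than `min_unit_count`; `BROAD_RANGE` when the allele-length spread
#' exceeds `max_allele_range_bp`; `REPETITIVE` when either consensus flank
#' is low-complexity or its anchor k-mer recurs in more clusters than the
#' copy-number cap; `CONTAMINANT_LIKE` when a flank matches the contaminant
#' set above the identity threshold; `FLANKS_TOO_SHORT` when a consensus
#' flank cannot support the complexity window. With no contaminant set the
#' contaminant check is skipped with a warning, never silently passed.
#'
#' @param clusters Output of [call_alleles()] (polymorphic rows are the
#'   intended input; others are passed through with their rules evaluated).
#' @param config A [filter_config()].
#' @param contaminant Optional named character vector of contaminant
#'   sequences; `NULL` skips the check with a warning.
#' @param anchor_k Anchor length used for the multi-copy rule (default 12).
#' @return `clusters` with added `passed` (logical) and `reasons`
#'   (list-column of character vectors; empty iff passed).
#' @export
filter_loci <- function(clusters, config = filter_config(),
                        contaminant = NULL, anchor_k = 12L) {
  stopifnot(inherits(config, "str_filter_config"),
            "alleles" %in% names(clusters))
  if (is.null(contaminant)) {
    rlang::warn("no contaminant set supplied; CONTAMINANT_LIKE not checked",
                class = "strmarker_no_contaminant")
  }
  # flank regions a primer could occupy, adjacent to the array
  fl <- substr(clusters$consensus_left,
               pmax(1L, nchar(clusters$consensus_left) -
                      config$flank_window + 1L),
               nchar(clusters$consensus_left))
  fr <- substr(clusters$consensus_right, 1L, config$flank_window)
  anchors_l <- substr(fl, pmax(1L, nchar(fl) - anchor_k + 1L), nchar(fl))
  anchors_r <- substr(fr, 1L, anchor_k)
  # clusters per anchor k-mer (multi-copy flank signal)
  anchor_count <- table(c(anchors_l, anchors_r))

  motif_len <- nchar(clusters$canonical_motif)
  reasons <- purrr::pmap(
    list(clusters$alleles, motif_len, fl, fr, anchors_l, anchors_r),
    function(al, ml, cl, cr, al_k, ar_k) {
      r <- character()
      if (nrow(al) > 0L) {
        if (max(al$length_bp %/% ml) < config$min_unit_count) {
          r <- c(r, "TOO_FEW_REPEATS")
        }
        if (diff(range(al$length_bp)) > config$max_allele_range_bp) {
          r <- c(r, "BROAD_RANGE")
        }
      }
      w <- config$low_complexity_window
      if (nchar(cl) < w || nchar(cr) < w) {
        r <- c(r, "FLANKS_TOO_SHORT")
      } else if (max(low_complexity_score(c(cl, cr), w)) >
                 config$low_complexity_threshold) {
        r <- c(r, "REPETITIVE")
      }
      if (!"REPETITIVE" %in% r &&
          max(anchor_count[al_k], anchor_count[ar_k]) >
          config$copy_number_cap) {
        r <- c(r, "REPETITIVE")
      }
      if (!is.null(contaminant)) {
        sim <- dplyr::bind_rows(
          contaminant_similarity(cl, contaminant,
                                 min_span = config$contaminant_min_span),
          contaminant_similarity(cr, contaminant,
                                 min_span = config$contaminant_min_span))
        if (any(sim$identity >= config$contaminant_identity_threshold)) {
          r <- c(r, "CONTAMINANT_LIKE")
        }
      }
      sort(r)
    })
  dplyr::mutate(clusters,
    reasons = reasons,
    passed = lengths(reasons) == 0L)
}
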