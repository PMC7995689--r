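#' Orient STR hits to a strand-canonical representation
#'
#' Shotgun reads come from both strands, so the same genomic locus yields
#' hits whose flanks are reverse complements of each other. Each hit is
#' deterministically flipped to the orientation whose flank sequence read
#' outward from the right edge of the array is lexicographically smaller
#' (the as-read candidate reads `right_flank`, the flipped candidate reads
#' `revcomp(left_flank)`; they are compared over their common length).
#' Because the decision is anchored at the array boundary it does not
#' depend on where the read happens to end, so a hit and its
#' reverse-complement mate - even truncated differently - collapse to one
#' oriented record. Ties (palindromic context) keep the as-read
#' orientation. Idempotent.
#'
#' @param hits A hit tibble from [scan_reads()].
#' @return The hits with flanks, unit and `strand_as_read` in canonical
#'   orientation (`strand_as_read` is `"-"` for flipped hits).
#' @export
orient_hits <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  alt_left <- dna_revcomp(hits$right_flank)
  alt_right <- dna_revcomp(hits$left_flank)
  n <- pmin(nchar(hits$right_flank), nchar(alt_right))
  keep_key <- substr(hits$right_flank, 1L, n)
  alt_key <- substr(alt_right, 1L, n)
  flip <- alt_key < keep_key
  # the flipped unit is the leading unit of the reverse-complemented array;
  # a trailing partial unit shifts the phase, so rebuild it from the span
  span <- hits$end - hits$start
  flipped_unit <- vapply(seq_len(nrow(hits)), function(i) {
    u <- hits$unit[i]
    array <- substr(strrep(u, ceiling(span[i] / nchar(u))), 1L, span[i])
    substr(dna_revcomp(array), 1L, nchar(u))
  }, character(1))
  dplyr::mutate(hits,
    unit = ifelse(flip, flipped_unit, .data$unit),
    left_flank = ifelse(flip, alt_left, .data$left_flank),
    right_flank = ifelse(flip, alt_right, .data$right_flank),
    strand_as_read = ifelse(flip,
                            ifelse(.data$strand_as_read == "+", "-", "+"),
                            .data$strand_as_read)
  )
}

# mismatches between two strings over their overlap, aligned at the end
# that abuts the repeat array
overlap_mismatch <- function(a, b, align) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  if (align == "suffix") {
    a <- substr(a, nchar(a) - n + 1L, nchar(a))
    b <- substr(b, nchar(b) - n + 1L, nchar(b))
  } else {
    a <- substr(a, 1L, n)
    b <- substr(b, 1L, n)
  }
  sum(charToRaw(a) != charToRaw(b))
}

majority_consensus <- function(flanks, align) {
  n <- max(nchar(flanks))
  if (n == 0L) return("")
  pad <- vapply(flanks, function(f) {
    p <- strrep(" ", n - nchar(f))
    if (align == "suffix") paste0(p, f) else paste0(f, p)
  }, character(1))
  mat <- do.call(rbind, strsplit(pad, "", fixed = TRUE))
  cons <- apply(mat, 2L, function(col) {
    col <- col[col != " "]
    tab <- sort(table(col), decreasing = TRUE)
    # majority base; ties resolved alphabetically for determinism
    names(tab)[which(tab == max(tab))[1L]]
  })
  paste(cons, collapse = "")
}

#' Cluster STR hits into candidate loci by flanking-sequence identity
#'
#' Hits sharing a canonical motif are merged into one locus cluster when the
#' `anchor_k` bases of flank immediately adjoining the repeat array match
#' exactly on at least one side and the full overlapping flank regions
#' (suffix-aligned on the left, prefix-aligned on the right) differ by at
#' most `max_mismatch` substitutions in total. Merging is a transitive
#' closure (union-find), so one high-coverage locus forms a single cluster
#' regardless of read order or strand of origin. Hits with either flank
#' shorter than `min_flank` carry too little context to place and are set
#' aside as unclusterable.
#'
#' @param hits A hit tibble from [scan_reads()]; orientation is applied
#'   internally via [orient_hits()] (idempotent).
#' @param anchor_k Exact-match anchor length adjoining the array (default 12).
#' @param min_flank Minimum flank length on both sides for clustering
#'   (default 20).
#' @param max_mismatch Substitution tolerance over the full flank overlap
#'   (default 2).
#' @return A tibble of clusters sorted by motif then consensus flanks:
#'   `cluster_id`, `canonical_motif`, `n_reads`, `consensus_left`,
#'   `consensus_right`, and a `members` list-column of the oriented member
#'   hits. Unclusterable hits are attached as `attr(x, "unclusterable")`.
#' @export
cluster_hits <- function(hits, anchor_k = 12L, min_flank = 20L,
                         max_mismatch = 2L) {
  stopifnot(anchor_k <= min_flank)
  hits <- orient_hits(hits)
  ok <- nchar(hits$left_flank) >= min_flank &
    nchar(hits$right_flank) >= min_flank
  unclusterable <- hits[!ok, , drop = FALSE]
  hits <- hits[ok, , drop = FALSE]

  clusters <- list()
  if (nrow(hits) > 0L) {
    hits <- dplyr::mutate(hits,
      .anchor_l = substr(.data$left_flank,
                         nchar(.data$left_flank) - anchor_k + 1L,
                         nchar(.data$left_flank)),
      .anchor_r = substr(.data$right_flank, 1L, anchor_k)
    )
    for (grp in split(seq_len(nrow(hits)), hits$canonical_motif)) {
      parent <- seq_along(grp)
      find <- function(i) {
        while (parent[i] != i) {
          parent[i] <<- parent[parent[i]]
          i <- parent[i]
        }
        i
      }
      link <- function(i, j) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
      }
      sub <- hits[grp, , drop = FALSE]
      cand <- c(split(seq_along(grp), sub$.anchor_l),
                split(seq_along(grp), sub$.anchor_r))
      for (idx in cand) {
        if (length(idx) < 2L) next
        for (a in seq_len(length(idx) - 1L)) {
          for (b in seq((a + 1L), length(idx))) {
            i <- idx[a]; j <- idx[b]
            if (find(i) == find(j)) next
            mm <- overlap_mismatch(sub$left_flank[i], sub$left_flank[j],
                                   "suffix") +
              overlap_mismatch(sub$right_flank[i], sub$right_flank[j],
                               "prefix")
            if (mm <= max_mismatch) link(i, j)
          }
        }
      }
      roots <- vapply(seq_along(grp), find, integer(1))
      for (members in split(seq_along(grp), roots)) {
        clusters[[length(clusters) + 1L]] <-
          sub[members, setdiff(names(sub), c(".anchor_l", ".anchor_r")),
              drop = FALSE]
      }
    }
  }

  out <- tibble::tibble(
    canonical_motif = vapply(clusters,
                             function(m) m$canonical_motif[1L], character(1)),
    n_reads = vapply(clusters, nrow, integer(1)),
    consensus_left = vapply(clusters, function(m)
      majority_consensus(m$left_flank, "suffix"), character(1)),
    consensus_right = vapply(clusters, function(m)
      majority_consensus(m$right_flank, "prefix"), character(1)),
    members = clusters
  )
  out <- dplyr::arrange(out, .data$canonical_motif, .data$consensus_left,
                        .data$consensus_right)
  out <- dplyr::mutate(out,
    cluster_id = sprintf("L%04d", dplyr::row_number()),
    .before = 1L)
  attr(out, "unclusterable") <- tibble::as_tibble(unclusterable)
  out
}

#' Call allele-length spectra and polymorphism per cluster
#'
#' The allele carried by a read is the span of its repeat array in bp. Only
#' members whose array is fully contained in the read, with at least one
#' flanking base on both sides, have a knowable allele length; reads whose
#' array touches a read end supported clustering but are excluded here.
#' Alleles backed by fewer than `min_support` reads are dropped as likely
#' sequencing artefacts. A cluster is `polymorphic` with two or more
#' surviving alleles, `monomorphic` with exactly one, `ambiguous` with none.
#'
#' @param clusters Output of [cluster_hits()].
#' @param min_support Minimum reads per allele (default 2); with only a
#'   handful of chromosomes sampled this guards against single-read error.
#' @return `clusters` with added columns: `alleles` (list of tibbles with
#'   `length_bp`, `support`, and `individuals` when member hits carry an
#'   `individual` column), `status`, `n_alleles`, and
#'   `nonmultiple_spacing` (TRUE when surviving allele lengths are not all
#'   congruent modulo the motif length, e.g. a flank indel).
#' @export
call_alleles <- function(clusters, min_support = 2L) {
  calls <- purrr::map(clusters$members, function(m) {
    full <- m[nchar(m$left_flank) > 0L & nchar(m$right_flank) > 0L, ,
              drop = FALSE]
    if (nrow(full) == 0L) {
      return(tibble::tibble(length_bp = integer(), support = integer()))
    }
    lens <- full$end - full$start
    tab <- dplyr::count(tibble::tibble(length_bp = lens),
                        .data$length_bp, name = "support")
    if ("individual" %in% names(full)) {
      ind <- tapply(full$individual, lens, function(x)
        paste(sort(unique(x)), collapse = ","))
      tab$individuals <- as.character(ind[as.character(tab$length_bp)])
    }
    tab[tab$support >= min_support, , drop = FALSE]
  })
  motif_len <- nchar(clusters$canonical_motif)
  dplyr::mutate(clusters,
    alleles = calls,
    n_alleles = vapply(calls, nrow, integer(1)),
    status = dplyr::case_when(
      n_alleles >= 2L ~ "polymorphic",
      n_alleles == 1L ~ "monomorphic",
      TRUE ~ "ambiguous"
    ),
    nonmultiple_spacing = purrr::map2_lgl(calls, motif_len, function(a, ml) {
      nrow(a) > 1L && length(unique(a$length_bp %% ml)) > 1L
    })
  )
}

#' Consensus locus sequences for primer design
#'
#' Reconstructs, per cluster, the consensus left flank + the most-supported
#' repeat array + the consensus right flank. The array is rebuilt from the
#' modal oriented unit of the member hits, so the sequence is exact for
#' perfect repeats. Flanks are truncated to the `flank_window` bases
#' adjacent to the array - the region a short-amplicon primer can occupy;
#' consensus further out is less reliable (fewer covering reads) and can
#' run into unrelated neighbouring sequence.
#'
#' @param clusters Output of [call_alleles()].
#' @param flank_window Consensus flank length retained each side
#'   (default 60).
#' @return Tibble with `cluster_id`, `seq`, `array_start`, `array_end`
#'   (0-based half-open array coordinates within `seq`) and `unit`.
#' @export
locus_consensus <- function(clusters, flank_window = 60L) {
  stopifnot("alleles" %in% names(clusters))
  rows <- purrr::pmap(
    list(clusters$cluster_id, clusters$members, clusters$alleles,
         clusters$consensus_left, clusters$consensus_right),
    function(id, m, al, cl, cr) {
      if (nrow(al) == 0L) return(NULL)
      cl <- substr(cl, max(1L, nchar(cl) - flank_window + 1L), nchar(cl))
      cr <- substr(cr, 1L, flank_window)
      unit <- names(sort(table(m$unit), decreasing = TRUE))[1L]
      len <- al$length_bp[which.max(al$support)]
      array <- substr(strrep(unit, ceiling(len / nchar(unit))), 1L, len)
      tibble::tibble(cluster_id = id,
                     seq = paste0(cl, array, cr),
                     array_start = nchar(cl),
                     array_end = nchar(cl) + len,
                     unit = unit)
    })
  proto <- tibble::tibble(cluster_id = character(), seq = character(),
                          array_start = integer(), array_end = integer(),
                          unit = character())
  dplyr::bind_rows(c(list(proto), rows))
}
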