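#' Scan reads for perfect short tandem repeats
#'
#' Detects every maximal perfect tandem array of a primitive di-, tri- or
#' tetranucleotide unit with at least `min_units` whole units. Coordinates
#' are 0-based half-open on the read as given; `N` never matches and
#' terminates an array. The reported span is the full maximal run,
#' including a trailing partial unit where the flanking base happens to
#' continue the repeat: this keeps coordinates exactly mirror-symmetric
#' between strands (so reads from either strand of one locus agree on the
#' array boundaries), while `unit_count` counts whole units only. Among
#' overlapping candidate arrays the longer array wins, ties broken by
#' smaller start and then by shorter unit, so reported hits never overlap
#' and an `(AT)n` array is never re-reported as `(ATAT)n`.
#'
#' @param reads A data frame with columns `read_id` and `seq`, or a named
#'   character vector of sequences.
#' @param min_units Minimum number of whole repeat units (default 4). The
#'   stricter "at least 6 units" rule belongs to the candidate filter, not
#'   the scanner, so borderline loci stay visible for clustering.
#' @return A tibble of STR hits: `read_id`, `canonical_motif`, `unit`,
#'   `start`, `end`, `unit_count`, `left_flank`, `right_flank`,
#'   `strand_as_read` (always `"+"` at scan time). Flanks run to the read
#'   ends and abut the array with no gap.
#' @examples
#' scan_reads(c(r1 = paste0("GGGGG", strrep("AC", 7), "TTTTT")))
#' @export
scan_reads <- function(reads, min_units = 4L) {
  if (min_units < 3L) {
    rlang::abort("min_units must be >= 3", class = "strmarker_bad_arg")
  }
  reads <- as_read_tbl(reads)
  hits <- purrr::map2(reads$read_id, stringr::str_to_upper(reads$seq),
    function(id, s) {
      h <- cpp_scan_seq(s, as.integer(min_units))
      if (nrow(h) == 0L) return(NULL)
      tibble::tibble(
        read_id = id,
        unit = h$unit,
        start = h$start,
        end = h$end,
        unit_count = h$unit_count,
        left_flank = substr(rep(s, nrow(h)), 1L, h$start),
        right_flank = substr(rep(s, nrow(h)), h$end + 1L, nchar(s))
      )
    })
  hits <- dplyr::bind_rows(hits)
  if (nrow(hits) == 0L) {
    return(tibble::tibble(
      read_id = character(), canonical_motif = character(),
      unit = character(), start = integer(), end = integer(),
      unit_count = integer(), left_flank = character(),
      right_flank = character(), strand_as_read = character()
    ))
  }
  hits |>
    dplyr::mutate(
      canonical_motif = canonical_motif(.data$unit),
      strand_as_read = "+"
    ) |>
    dplyr::select("read_id", "canonical_motif", "unit", "start", "end",
                  "unit_count", "left_flank", "right_flank",
                  "strand_as_read")
}

# Accept a named character vector or a data frame with read_id/seq.
as_read_tbl <- function(reads) {
  if (is.character(reads)) {
    ids <- names(reads)
    if (is.null(ids)) ids <- paste0("read", seq_along(reads))
    return(tibble::tibble(read_id = ids, seq = unname(reads)))
  }
  stopifnot(is.data.frame(reads), all(c("read_id", "seq") %in% names(reads)))
  tibble::as_tibble(reads[, c("read_id", "seq")])
}
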