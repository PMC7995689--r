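#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over the ACGTN alphabet.
#'
#' @param x Character vector of DNA strings (ACGTN).
#' @return Character vector of reverse complements.
#' @examples
#' dna_revcomp(c("ACGT", "AAGN"))
#' @export
dna_revcomp <- function(x) {
  stringr::str_to_upper(x) |>
    chartr(old = "ACGTN", new = "TGCAN") |>
    vapply(function(s) {
      paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
    }, character(1), USE.NAMES = FALSE)
}

.check_unit <- function(unit) {
  bad <- !grepl("^[ACGT]{2,4}$", unit)
  if (any(bad)) {
    rlang::abort(paste0(
      "invalid repeat unit(s): ",
      paste(unique(unit[bad]), collapse = ", "),
      " (must be 2-4 bp over ACGT)"
    ), class = "strmarker_bad_unit")
  }
}

.rotations <- function(unit) {
  n <- nchar(unit)
  vapply(seq_len(n) - 1L, function(k) {
    paste0(substr(unit, k + 1L, n), substr(unit, 1L, k))
  }, character(1))
}

#' Canonical representative of a repeat-motif class
#'
#' Two repeat units describe the same microsatellite if one is a cyclic
#' rotation of the other or of its reverse complement: `(AC)n`, `(CA)n` and
#' `(GT)n` arrays are one motif class. The canonical representative is the
#' lexicographically smallest string over all cyclic rotations of the unit
#' and of its reverse complement, so hits from either strand and any phase
#' co-cluster.
#'
#' @param unit Character vector of repeat units (2-4 bp, ACGT).
#' @return Character vector of canonical motifs, same length as `unit`.
#' @examples
#' canonical_motif(c("AC", "GT", "TCT"))  # "AC" "AC" "AAG"
#' @export
canonical_motif <- function(unit) {
  unit <- stringr::str_to_upper(unit)
  .check_unit(unit)
  vapply(unit, function(u) {
    min(c(.rotations(u), .rotations(dna_revcomp(u))))
  }, character(1), USE.NAMES = FALSE)
}

#' Is a repeat unit a valid (primitive) 2-4 bp motif?
#'
#' A unit is valid when it is 2-4 bp over ACGT and is not a whole-number
#' repetition of a shorter unit; this rejects homopolymer-equivalent motifs
#' such as `"CCC"` and degenerate tetramers such as `"ATAT"`.
#'
#' @param unit Character vector of candidate units.
#' @return Logical vector.
#' @examples
#' is_valid_motif(c("AAT", "ATAT", "CCC"))  # TRUE FALSE FALSE
#' @export
is_valid_motif <- function(unit) {
  unit <- stringr::str_to_upper(unit)
  vapply(unit, function(u) {
    n <- nchar(u)
    if (!grepl("^[ACGT]{2,4}$", u)) return(FALSE)
    for (d in seq_len(n - 1)) {
      if (n %% d != 0L) next
      if (u == strrep(substr(u, 1L, d), n / d)) return(FALSE)
    }
    TRUE
  }, logical(1), USE.NAMES = FALSE)
}
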