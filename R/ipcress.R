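#' Find primer binding sites with mismatch tolerance
#'
#' Reports every position, on both strands of the template, where the
#' primer binds with Hamming distance at most `max_mismatch` and its
#' 3'-most `three_prime_exact` bases matching exactly (polymerase extension
#' requires a matched 3' end). Substitutions only, no indels. `N` never
#' matches.
#'
#' @param primer DNA string (5'->3').
#' @param template DNA string.
#' @param max_mismatch Maximum mismatches outside the 3' anchor (default 2).
#' @param three_prime_exact Length of the exact 3' anchor (default 3).
#' @return Tibble with `start`, `end` (0-based half-open, always on the
#'   forward strand of the template), `strand` (`"+"`: primer 3' end points
#'   right; `"-"`: points left) and `mismatches`, ordered by strand then
#'   start.
#' @export
find_binding_sites <- function(primer, template, max_mismatch = 2L,
                               three_prime_exact = 3L) {
  stopifnot(three_prime_exact >= 1L, nchar(primer) <= nchar(template))
  primer <- stringr::str_to_upper(primer)
  template <- stringr::str_to_upper(template)
  m <- nchar(primer)
  plus <- cpp_find_sites(primer, template, as.integer(max_mismatch),
                         as.integer(three_prime_exact), TRUE)
  minus <- cpp_find_sites(dna_revcomp(primer), template,
                          as.integer(max_mismatch),
                          as.integer(three_prime_exact), FALSE)
  dplyr::bind_rows(
    tibble::tibble(start = plus$start, end = plus$start + m, strand = "+",
                   mismatches = plus$mismatches),
    tibble::tibble(start = minus$start, end = minus$start + m, strand = "-",
                   mismatches = minus$mismatches)
  )
}

#' Enumerate in-silico PCR products for a primer pair
#'
#' A product arises wherever one primer binds the forward strand and the
#' other (or the same) primer binds the reverse strand downstream, 3' ends
#' facing, with product length in `(0, max_product]`. All such site
#' combinations are enumerated, for every template.
#'
#' @param forward,reverse Primer sequences (5'->3'; the reverse primer as on
#'   the opposite strand, the usual convention).
#' @param templates Named character vector of template sequences.
#' @param max_mismatch,three_prime_exact As in [find_binding_sites()].
#' @param max_product Maximum product length in bp (default 1000 for
#'   validation; design-time screening uses the amplicon cap instead).
#' @return Tibble with `template_id`, `start`, `end`, `length` (bp),
#'   `fwd_primer`, `rev_primer` (which primer bound left/right),
#'   `fwd_mismatches`, `rev_mismatches`.
#' @export
amplify <- function(forward, reverse, templates, max_mismatch = 2L,
                    three_prime_exact = 3L, max_product = 1000L) {
  ids <- names(templates)
  if (is.null(ids)) ids <- paste0("template", seq_along(templates))
  res <- purrr::map2(ids, as.character(templates), function(id, tpl) {
    sites <- dplyr::bind_rows(
      dplyr::mutate(find_binding_sites(forward, tpl, max_mismatch,
                                       three_prime_exact), primer = "F"),
      dplyr::mutate(find_binding_sites(reverse, tpl, max_mismatch,
                                       three_prime_exact), primer = "R"))
    left <- sites[sites$strand == "+", , drop = FALSE]
    right <- sites[sites$strand == "-", , drop = FALSE]
    if (nrow(left) == 0L || nrow(right) == 0L) return(NULL)
    combos <- tidyr::expand_grid(li = seq_len(nrow(left)),
                                 ri = seq_len(nrow(right)))
    len <- right$end[combos$ri] - left$start[combos$li]
    ok <- len > 0L & len <= max_product
    if (!any(ok)) return(NULL)
    combos <- combos[ok, ]; len <- len[ok]
    tibble::tibble(
      template_id = id,
      start = left$start[combos$li],
      end = right$end[combos$ri],
      length = as.integer(len),
      fwd_primer = left$primer[combos$li],
      rev_primer = right$primer[combos$ri],
      fwd_mismatches = left$mismatches[combos$li],
      rev_mismatches = right$mismatches[combos$ri])
  })
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0L) {
    return(tibble::tibble(template_id = character(), start = integer(),
                          end = integer(), length = integer(),
                          fwd_primer = character(), rev_primer = character(),
                          fwd_mismatches = integer(),
                          rev_mismatches = integer()))
  }
  dplyr::arrange(out, .data$template_id, .data$start, .data$end)
}

#' Classify a candidate marker from its in-silico PCR products
#'
#' Mirrors the bench triage of candidate loci: a marker is rejected when a
#' template yields more than one product outside a single expected-size
#' window (`multiple_products`), when every template yields the same single
#' size (`monomorphic`), when the size spread exceeds the broad-range cap
#' (`broad_range`), or when nothing amplifies (`no_product`); otherwise it
#' is a usable `single_product_polymorphic` marker.
#'
#' @param products Output of [amplify()]; `template_id` identifies the
#'   individual/haplotype template.
#' @param size_window Products within one window of each other on the same
#'   template count as one expected-size band (default 20 bp).
#' @param max_range_bp Broad-range cap on the spread of per-template sizes
#'   (default 20).
#' @return A one-row tibble: `status`, `n_templates_amplified`, `sizes`
#'   (list of per-template size vectors).
#' @export
classify_marker <- function(products, size_window = 20L, max_range_bp = 20L) {
  if (nrow(products) == 0L) {
    return(tibble::tibble(status = "no_product",
                          n_templates_amplified = 0L, sizes = list(NULL)))
  }
  sizes <- split(products$length, products$template_id)
  multi <- any(vapply(sizes, function(s) diff(range(s)) > size_window &&
                        length(s) > 1L, logical(1)))
  per_tpl <- lapply(sizes, function(s) sort(unique(s)))
  all_sizes <- unlist(per_tpl, use.names = FALSE)
  status <- if (multi) {
    "multiple_products"
  } else if (length(unique(all_sizes)) == 1L) {
    "monomorphic"
  } else if (diff(range(all_sizes)) > max_range_bp) {
    "broad_range"
  } else {
    "single_product_polymorphic"
  }
  tibble::tibble(status = status,
                 n_templates_amplified = length(sizes),
                 sizes = list(per_tpl))
}
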