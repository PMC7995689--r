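#' Primer design constraints
#'
#' Numeric bounds for short-amplicon primer design. Per-primer lengths of
#' 18-22 nt make the 36-44 nt pair total attainable and tight; the 150 bp
#' product cap (for the largest known allele) targets the fragment sizes
#' recoverable from degraded template DNA.
#'
#' @param primer_len_min,primer_len_max Per-primer length bounds (18, 22).
#' @param pair_len_min,pair_len_max Bounds on the summed primer lengths
#'   (36, 44).
#' @param gc_min,gc_max GC-fraction window (0.40, 0.60).
#' @param tm_min,tm_max Melting-temperature window in degrees C (54, 62).
#' @param tm_diff_max Maximum |Tm difference| within a pair (3).
#' @param max_homopolymer Longest allowed single-base run (4).
#' @param clamp_gc_max Maximum G/C among the five 3'-terminal bases (3);
#'   the 3'-terminal base itself must be G or C.
#' @param max_amplicon_bp Product cap for the largest allele (150).
#' @param tm_method `"wallace"` or `"nn"` (see [melting_temperature()]).
#' @param primer_nM,na_mM Concentrations used by the `"nn"` method.
#' @return A named list of class `str_primer_constraints`.
#' @export
primer_constraints <- function(primer_len_min = 18L, primer_len_max = 22L,
                               pair_len_min = 36L, pair_len_max = 44L,
                               gc_min = 0.40, gc_max = 0.60,
                               tm_min = 54, tm_max = 62, tm_diff_max = 3,
                               max_homopolymer = 4L, clamp_gc_max = 3L,
                               max_amplicon_bp = 150L,
                               tm_method = c("wallace", "nn"),
                               primer_nM = 500, na_mM = 50) {
  structure(list(primer_len_min = primer_len_min,
                 primer_len_max = primer_len_max,
                 pair_len_min = pair_len_min, pair_len_max = pair_len_max,
                 gc_min = gc_min, gc_max = gc_max,
                 tm_min = tm_min, tm_max = tm_max, tm_diff_max = tm_diff_max,
                 max_homopolymer = max_homopolymer,
                 clamp_gc_max = clamp_gc_max,
                 max_amplicon_bp = max_amplicon_bp,
                 tm_method = match.arg(tm_method),
                 primer_nM = primer_nM, na_mM = na_mM),
            class = "str_primer_constraints")
}

# SantaLucia (1998) unified nearest-neighbor parameters:
# dH in kcal/mol, dS in cal/(mol K)
.nn_dH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
            CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
            CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
            CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
.nn_dS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
            CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
            CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
            CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)

#' Primer melting temperature
#'
#' `wallace`: the rule-of-thumb 2(A+T) + 4(G+C) degrees C. `nn`: unified
#' nearest-neighbor thermodynamics (SantaLucia 1998) with terminal
#' initiation terms, entropy salt correction
#' `dS + 0.368 (L-1) ln[Na+]`, and
#' `Tm = 1000 dH / (dS' + R ln(C/4)) - 273.15` for primer concentration `C`.
#'
#' @param primer Character vector of primers (ACGT only, >= 10 nt).
#' @param method `"wallace"` (default) or `"nn"`.
#' @param primer_nM Primer concentration in nM (nn only; default 500).
#' @param na_mM Monovalent cation concentration in mM (nn only; default 50).
#' @return Numeric vector of Tm in degrees C.
#' @examples
#' melting_temperature("ACGTACGTACGTACGTACGT")  # 60
#' @export
melting_temperature <- function(primer, method = c("wallace", "nn"),
                                primer_nM = 500, na_mM = 50) {
  method <- match.arg(method)
  primer <- stringr::str_to_upper(primer)
  if (any(!grepl("^[ACGT]{10,}$", primer))) {
    rlang::abort("primers must be >= 10 nt over ACGT (no ambiguity codes)",
                 class = "strmarker_bad_primer")
  }
  if (method == "wallace") {
    at <- stringr::str_count(primer, "[AT]")
    gc <- stringr::str_count(primer, "[GC]")
    return(2 * at + 4 * gc)
  }
  vapply(primer, function(p) {
    n <- nchar(p)
    steps <- substring(p, 1:(n - 1L), 2:n)
    dH <- sum(.nn_dH[steps])
    dS <- sum(.nn_dS[steps])
    for (term in c(substr(p, 1L, 1L), substr(p, n, n))) {
      if (term %in% c("G", "C")) {
        dH <- dH + 0.1; dS <- dS - 2.8
      } else {
        dH <- dH + 2.3; dS <- dS + 4.1
      }
    }
    dS <- dS + 0.368 * (n - 1L) * log(na_mM / 1000)
    1000 * dH / (dS + 1.987 * log(primer_nM * 1e-9 / 4)) - 273.15
  }, numeric(1), USE.NAMES = FALSE)
}

gc_fraction <- function(x) {
  stringr::str_count(x, "[GC]") / nchar(x)
}

primer_ok <- function(p, cfg) {
  tm <- melting_temperature(p, cfg$tm_method, cfg$primer_nM, cfg$na_mM)
  gc <- gc_fraction(p)
  last1 <- substr(p, nchar(p), nchar(p))
  last5 <- substr(p, pmax(1L, nchar(p) - 4L), nchar(p))
  gc >= cfg$gc_min & gc <= cfg$gc_max &
    tm >= cfg$tm_min & tm <= cfg$tm_max &
    !grepl(sprintf("A{%1$d,}|C{%1$d,}|G{%1$d,}|T{%1$d,}",
                   cfg$max_homopolymer + 1L), p) &
    last1 %in% c("G", "C") &
    stringr::str_count(last5, "[GC]") <= cfg$clamp_gc_max
}

#' The universal M13 forward tail
#' @return The 18-mer prepended to forward primers for fluorescent
#'   genotyping.
#' @export
m13_tail <- function() "TGTAAAACGACGGCCAGT"

#' Design short-amplicon primer pairs in consensus locus flanks
#'
#' Exhaustively enumerates forward primers ending at or before the repeat
#' array and reverse primers (given 5'->3' on the opposite strand) starting
#' at or after it, keeps pairs satisfying every constraint in
#' [primer_constraints()] - per-primer length, GC, Tm, homopolymer, 3' GC
#' clamp, pair length total, |Tm difference|, and product size for the
#' largest allele within the amplicon cap - and ranks them
#' deterministically by |Tm difference|, then product size, then forward
#' start. Primers never overlap the repeat array.
#'
#' @param loci Tibble from [locus_consensus()], plus an `allele_lengths`
#'   list-column (integer bp lengths per locus); the pipeline wrapper
#'   assembles this from [call_alleles()] output.
#' @param constraints A [primer_constraints()].
#' @param n_best Keep at most this many ranked pairs per locus (default 1).
#' @return Tibble with one row per retained pair: `cluster_id`, `forward`,
#'   `reverse`, `fwd_start`, `rev_end` (0-based half-open on the consensus),
#'   `tm_f`, `tm_r`, `gc_f`, `gc_r`, `product_size_by_allele` (list: named
#'   vector allele bp -> product bp), `max_product`,
#'   `m13_tailed_forward`, `rank`. Loci with no satisfying pair appear with
#'   `NA` primers and reason `NO_PRIMERS` in the `design_note` column.
#' @export
design_primers <- function(loci, constraints = primer_constraints(),
                           n_best = 1L) {
  stopifnot(all(c("cluster_id", "seq", "array_start", "array_end",
                  "allele_lengths") %in% names(loci)))
  cfg <- constraints
  out <- purrr::pmap(
    list(loci$cluster_id, loci$seq, loci$array_start, loci$array_end,
         loci$allele_lengths),
    function(id, seq, a0, a1, alleles) {
      n <- nchar(seq)
      max_allele <- max(alleles)
      empty <- tibble::tibble(
        cluster_id = id, forward = NA_character_, reverse = NA_character_,
        fwd_start = NA_integer_, rev_end = NA_integer_,
        tm_f = NA_real_, tm_r = NA_real_, gc_f = NA_real_, gc_r = NA_real_,
        product_size_by_allele = list(NULL), max_product = NA_integer_,
        m13_tailed_forward = NA_character_, rank = NA_integer_,
        design_note = "NO_PRIMERS")
      if (a0 < cfg$primer_len_min || n - a1 < cfg$primer_len_min) {
        return(empty)  # impossible geometry
      }
      # forward candidates end at e <= a0; reverse start at s >= a1
      fwd <- tidyr::expand_grid(
        len = cfg$primer_len_min:cfg$primer_len_max,
        e = seq_len(a0)) |>
        dplyr::filter(.data$e - .data$len >= 0L) |>
        dplyr::mutate(start = .data$e - .data$len,
                      p = substring(seq, .data$start + 1L, .data$e))
      rev <- tidyr::expand_grid(
        len = cfg$primer_len_min:cfg$primer_len_max,
        s = a1:(n - 1L)) |>
        dplyr::filter(.data$s + .data$len <= n) |>
        dplyr::mutate(end = .data$s + .data$len,
                      p = dna_revcomp(substring(seq, .data$s + 1L,
                                                .data$end)))
      fwd <- fwd[grepl("^[ACGT]+$", fwd$p) & primer_ok(fwd$p, cfg), ]
      rev <- rev[grepl("^[ACGT]+$", rev$p) & primer_ok(rev$p, cfg), ]
      if (nrow(fwd) == 0L || nrow(rev) == 0L) return(empty)
      fwd$tm <- melting_temperature(fwd$p, cfg$tm_method,
                                    cfg$primer_nM, cfg$na_mM)
      rev$tm <- melting_temperature(rev$p, cfg$tm_method,
                                    cfg$primer_nM, cfg$na_mM)
      pairs <- tidyr::expand_grid(fi = seq_len(nrow(fwd)),
                                  ri = seq_len(nrow(rev)))
      f <- fwd[pairs$fi, ]; r <- rev[pairs$ri, ]
      total <- f$len + r$len
      # product size for an allele a: flank distances + a
      prod_max <- (a0 - f$start) + max_allele + (r$end - a1)
      ok <- total >= cfg$pair_len_min & total <= cfg$pair_len_max &
        abs(f$tm - r$tm) <= cfg$tm_diff_max &
        prod_max <= cfg$max_amplicon_bp
      if (!any(ok)) return(empty)
      f <- f[ok, ]; r <- r[ok, ]; prod_max <- prod_max[ok]
      ord <- order(abs(f$tm - r$tm), prod_max, f$start)
      keep <- utils::head(ord, n_best)
      tibble::tibble(
        cluster_id = id,
        forward = f$p[keep],
        reverse = r$p[keep],
        fwd_start = as.integer(f$start[keep]),
        rev_end = as.integer(r$end[keep]),
        tm_f = f$tm[keep],
        tm_r = r$tm[keep],
        gc_f = gc_fraction(f$p[keep]),
        gc_r = gc_fraction(r$p[keep]),
        product_size_by_allele = purrr::map(keep, function(k) {
          stats::setNames((a0 - f$start[k]) + alleles + (r$end[k] - a1),
                          alleles)
        }),
        max_product = as.integer(prod_max[keep]),
        m13_tailed_forward = paste0(m13_tail(), f$p[keep]),
        rank = seq_along(keep),
        design_note = NA_character_)
    })
  dplyr::bind_rows(out)
}

#' Reported amplicon size range with the M13 tail
#'
#' Fluorescent genotyping reads products that carry the 18 bp M13 forward
#' tail, so the size range reported for a marker adds 18 bp to every
#' per-allele product size. The tail never takes part in binding-site
#' search; only the genomic primer binds.
#'
#' @param product_sizes Integer vector of untailed product sizes in bp.
#' @return Named vector `c(min = , max = )` of tailed sizes.
#' @examples
#' reported_size_range(c(120, 126))  # 138, 144
#' @export
reported_size_range <- function(product_sizes) {
  stopifnot(length(product_sizes) >= 1L, all(product_sizes > 0))
  tailed <- product_sizes + nchar(m13_tail())
  c(min = min(tailed), max = max(tailed))
}
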