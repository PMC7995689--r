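#' Simulation configuration
#'
#' Conditions for the synthetic truth sets: a handful of diploid
#' individuals (two by default, i.e. four chromosomes), planted di/tri/
#' tetranucleotide STR loci separated by unique random flanks, and
#' MiSeq-like 300 bp shotgun reads with optional substitution errors.
#'
#' @param n_individuals Diploid individuals (default 2).
#' @param n_loci Planted STR loci (default 30).
#' @param fraction_polymorphic Fraction of loci with >= 2 allele lengths
#'   across the sampled haplotypes (default 0.6).
#' @param motif_weights Sampling weights for unit lengths 2/3/4
#'   (default 0.5/0.3/0.2, dinucleotide-rich as in mammalian genomes).
#' @param unit_count_range Range of base allele unit counts (default 8-14,
#'   comfortably above the 6-unit candidate filter).
#' @param spacer_len Length of the unique inter-locus flanks (default 120,
#'   enough for 60 bp of primer search space each side).
#' @param coverage Per-haplotype read depth (default 30).
#' @param read_len Read length (default 300).
#' @param error_rate Per-base substitution error rate (default 0).
#' @param seed Mandatory RNG seed.
#' @return Named list of class `str_sim_config`.
#' @export
sim_config <- function(n_individuals = 2L, n_loci = 30L,
                       fraction_polymorphic = 0.6,
                       motif_weights = c(0.5, 0.3, 0.2),
                       unit_count_range = c(8L, 14L),
                       spacer_len = 120L, coverage = 30,
                       read_len = 300L, error_rate = 0, seed) {
  if (missing(seed)) {
    rlang::abort("a seed is mandatory for reproducible simulation",
                 class = "strmarker_bad_arg")
  }
  cfg <- list(n_individuals = n_individuals, n_loci = n_loci,
              fraction_polymorphic = fraction_polymorphic,
              motif_weights = motif_weights,
              unit_count_range = unit_count_range,
              spacer_len = spacer_len, coverage = coverage,
              read_len = read_len, error_rate = error_rate, seed = seed)
  stopifnot(n_individuals >= 1, n_loci >= 1, spacer_len >= 40,
            fraction_polymorphic >= 0, fraction_polymorphic <= 1,
            coverage > 0, read_len > 0, error_rate >= 0, error_rate < 1)
  structure(cfg, class = "str_sim_config")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_primitive_unit <- function(len) {
  repeat {
    u <- random_dna(len)
    if (is_valid_motif(u)) return(u)
  }
}

#' Simulate diploid genomes with planted STR loci
#'
#' Builds `2 * n_individuals` haplotypes sharing the same unique random
#' inter-locus spacers, with a perfect tandem array planted between
#' consecutive spacers. Polymorphic loci carry two allele lengths (one to
#' three units apart) distributed over the haplotypes so that both alleles
#' are present; monomorphic loci carry one. Spacer anchor k-mers adjoining
#' the arrays are checked for uniqueness and resampled on collision, so
#' every planted locus has clusterable flanks. Deterministic given the
#' config seed.
#'
#' @param config A [sim_config()].
#' @return List with `haplotypes` (named character vector,
#'   `ind<i>_h<1|2>`), `truth` (tibble: `locus_id`, `unit`,
#'   `canonical_motif`, `polymorphic`, `allele_by_haplotype` list-column of
#'   named bp lengths, `allele_lengths` sorted unique bp lengths) and
#'   `config`.
#' @export
simulate_genomes <- function(config) {
  stopifnot(inherits(config, "str_sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  n_hap <- 2L * cfg$n_individuals
  hap_names <- paste0("ind", rep(seq_len(cfg$n_individuals), each = 2L),
                      "_h", rep(1:2, cfg$n_individuals))

  units <- vapply(sample(2:4, cfg$n_loci, replace = TRUE,
                         prob = cfg$motif_weights),
                  random_primitive_unit, character(1))

  # spacer i is the right flank of locus i-1 and the left flank of locus i;
  # its boundary bases must not continue either planted array, so the
  # scanned array span equals the planted span on every haplotype
  n_spacer <- cfg$n_loci + 1L
  boundary_ok <- function(i, s) {
    ok <- TRUE
    if (i <= cfg$n_loci) {
      u <- units[i]
      ok <- ok && substr(s, nchar(s), nchar(s)) != substr(u, nchar(u),
                                                          nchar(u))
    }
    if (i >= 2L) {
      u <- units[i - 1L]
      ok <- ok && substr(s, 1L, 1L) != substr(u, 1L, 1L)
    }
    ok
  }
  draw_spacer <- function(i) {
    repeat {
      s <- random_dna(cfg$spacer_len)
      if (boundary_ok(i, s)) return(s)
    }
  }
  spacers <- vapply(seq_len(n_spacer), draw_spacer, character(1))
  repeat {
    anchors <- c(substr(spacers, nchar(spacers) - 19L, nchar(spacers)),
                 substr(spacers, 1L, 20L))
    dup <- duplicated(anchors) | duplicated(anchors, fromLast = TRUE)
    if (!any(dup)) break
    bad <- unique((which(dup) - 1L) %% n_spacer + 1L)
    for (i in bad) spacers[i] <- draw_spacer(i)
  }
  base_units <- sample(cfg$unit_count_range[1]:cfg$unit_count_range[2],
                       cfg$n_loci, replace = TRUE)
  poly <- seq_len(cfg$n_loci) <=
    round(cfg$fraction_polymorphic * cfg$n_loci)
  poly <- sample(poly)

  allele_by_hap <- vector("list", cfg$n_loci)
  for (j in seq_len(cfg$n_loci)) {
    ulen <- nchar(units[j])
    if (poly[j] && n_hap >= 2L) {
      delta <- sample(1:3, 1L)
      counts <- rep(base_units[j], n_hap)
      k <- sample(seq_len(n_hap - 1L), 1L)  # 1..n_hap-1 carriers of allele 2
      counts[sample(n_hap, k)] <- base_units[j] + delta
    } else {
      counts <- rep(base_units[j], n_hap)
    }
    allele_by_hap[[j]] <- stats::setNames(counts * ulen, hap_names)
  }

  haplotypes <- vapply(seq_len(n_hap), function(h) {
    parts <- character(2L * cfg$n_loci + 1L)
    parts[seq(1L, length(parts), by = 2L)] <- spacers
    for (j in seq_len(cfg$n_loci)) {
      len <- allele_by_hap[[j]][h]
      parts[2L * j] <- substr(strrep(units[j],
                                     ceiling(len / nchar(units[j]))), 1L, len)
    }
    paste(parts, collapse = "")
  }, character(1))
  names(haplotypes) <- hap_names

  truth <- tibble::tibble(
    locus_id = sprintf("sim%03d", seq_len(cfg$n_loci)),
    unit = units,
    canonical_motif = canonical_motif(units),
    polymorphic = vapply(allele_by_hap,
                         function(a) length(unique(a)) > 1L, logical(1)),
    allele_by_haplotype = allele_by_hap,
    allele_lengths = purrr::map(allele_by_hap,
                                function(a) sort(unique(unname(a)))),
    left_flank = spacers[seq_len(cfg$n_loci)],
    right_flank = spacers[seq_len(cfg$n_loci) + 1L])
  list(haplotypes = haplotypes, truth = truth, config = cfg)
}

#' Simulate uniform shotgun reads from haplotypes
#'
#' Read counts per haplotype are Poisson with mean
#' `coverage * length / read_len`; start positions are uniform, strands
#' balanced, and substitution errors independent per base at `error_rate`.
#' The origin of every read (haplotype, coordinates, strand) is recorded.
#'
#' @param haplotypes Named character vector of haplotype sequences.
#' @param coverage Mean per-haplotype depth.
#' @param read_len Read length (shorter haplotypes are an error).
#' @param error_rate Per-base substitution probability.
#' @param seed RNG seed.
#' @return Tibble: `read_id`, `seq`, `individual` (haplotype name up to
#'   `_h`), `haplotype`, `start` (0-based on the haplotype), `strand`.
#' @export
simulate_reads <- function(haplotypes, coverage = 30, read_len = 300L,
                           error_rate = 0, seed) {
  stopifnot(coverage > 0)
  if (any(nchar(haplotypes) < read_len)) {
    rlang::abort("read_len exceeds a haplotype length",
                 class = "strmarker_bad_arg")
  }
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  out <- purrr::imap(haplotypes, function(hap, hname) {
    n <- stats::rpois(1L, coverage * nchar(hap) / read_len)
    if (n == 0L) return(NULL)
    starts <- sample.int(nchar(hap) - read_len + 1L, n, replace = TRUE) - 1L
    strand <- sample(c("+", "-"), n, replace = TRUE)
    seqs <- substring(hap, starts + 1L, starts + read_len)
    if (error_rate > 0) {
      seqs <- vapply(seqs, function(s) {
        hit <- which(stats::runif(read_len) < error_rate)
        if (length(hit) == 0L) return(s)
        ch <- strsplit(s, "", fixed = TRUE)[[1]]
        ch[hit] <- vapply(ch[hit], function(b)
          sample(setdiff(bases, b), 1L), character(1))
        paste(ch, collapse = "")
      }, character(1), USE.NAMES = FALSE)
    }
    seqs[strand == "-"] <- dna_revcomp(seqs[strand == "-"])
    tibble::tibble(
      read_id = sprintf("%s_r%05d", hname, seq_len(n)),
      seq = seqs,
      individual = sub("_h[12]$", "", hname),
      haplotype = hname,
      start = starts,
      strand = strand)
  })
  dplyr::bind_rows(out)
}

#' Genotype table implied by simulated truth
#'
#' Collapses the per-haplotype planted allele lengths into diploid calls,
#' giving the ground-truth genotype table for the simulated individuals.
#'
#' @param truth The `truth` tibble from [simulate_genomes()].
#' @return A [genotype_table()].
#' @export
truth_genotypes <- function(truth) {
  rows <- purrr::pmap(list(truth$locus_id, truth$allele_by_haplotype),
    function(id, a) {
      inds <- unique(sub("_h[12]$", "", names(a)))
      tibble::tibble(
        individual = inds,
        locus = id,
        allele1 = vapply(inds, function(i)
          unname(a[paste0(i, "_h1")]), numeric(1)),
        allele2 = vapply(inds, function(i)
          unname(a[paste0(i, "_h2")]), numeric(1)))
    })
  g <- dplyr::bind_rows(rows)
  genotype_table(g$individual, g$locus, g$allele1, g$allele2)
}

#' Degrade a genotype table fecal-style
#'
#' Emulates low-template genotyping error: each call is first lost entirely
#' with probability `missing_rate`; each surviving heterozygote loses one
#' allele (becoming homozygous for the other) with probability
#' `dropout_rate`; each surviving call then has one allele replaced by a
#' novel label with probability `false_allele_rate`. Novel labels are
#' integers guaranteed absent from the input table. Deterministic given the
#' seed.
#'
#' @param gt A [genotype_table()].
#' @param dropout_rate,false_allele_rate,missing_rate Probabilities in
#'   `[0, 1]`.
#' @param seed RNG seed.
#' @return A degraded [genotype_table()].
#' @export
degrade_genotypes <- function(gt, dropout_rate = 0, false_allele_rate = 0,
                              missing_rate = 0, seed) {
  stopifnot(all(c(dropout_rate, false_allele_rate, missing_rate) >= 0),
            all(c(dropout_rate, false_allele_rate, missing_rate) <= 1))
  set.seed(seed)
  a1 <- gt$allele1
  a2 <- gt$allele2
  novel_base <- max(c(a1, a2), na.rm = TRUE) + 1L
  n <- nrow(gt)
  gone <- stats::runif(n) < missing_rate
  drop <- !gone & !is.na(a1) & a1 != a2 & stats::runif(n) < dropout_rate
  keep_first <- stats::runif(n) < 0.5
  a1[drop & !keep_first] <- a2[drop & !keep_first]
  a2[drop & keep_first] <- a1[drop & keep_first]
  false <- !gone & !is.na(a1) & stats::runif(n) < false_allele_rate
  which_false <- which(false)
  if (length(which_false)) {
    novel <- novel_base + seq_along(which_false)
    repl_first <- stats::runif(length(which_false)) < 0.5
    a1[which_false[repl_first]] <- novel[repl_first]
    a2[which_false[!repl_first]] <- novel[!repl_first]
  }
  a1[gone] <- NA_integer_
  a2[gone] <- NA_integer_
  genotype_table(gt$individual, gt$locus, a1, a2)
}
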