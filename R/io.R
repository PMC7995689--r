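#' Read sequences from FASTA or FASTQ
#'
#' The format is detected from content (leading `>` versus `@` of the
#' decompressed stream), not the file name; gzip is transparent. Sequences
#' are uppercased and validated against the ACGTN alphabet; a violation is
#' reported with its record number. FASTQ qualities are ignored by the
#' scanner but preserved here.
#'
#' @param path Path to a FASTA or FASTQ file, optionally gzipped.
#' @return Tibble with `read_id`, `seq`, and `qual` (`NA` for FASTA).
#' @export
read_sequences <- function(path) {
  con <- gzfile(path, "rt")
  first <- readLines(con, n = 1L)
  close(con)
  if (length(first) == 0L) {
    rlang::abort(paste0("empty sequence file: ", path),
                 class = "strmarker_bad_file")
  }
  lead <- substr(trimws(first), 1L, 1L)
  if (lead == ">") {
    x <- Biostrings::readBStringSet(path, format = "fasta")
    qual <- rep(NA_character_, length(x))
  } else if (lead == "@") {
    x <- Biostrings::readBStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
    qual <- as.character(S4Vectors::mcols(x)$qualities)
  } else {
    rlang::abort(paste0("cannot detect FASTA/FASTQ format in ", path),
                 class = "strmarker_bad_file")
  }
  ids <- sub("\\s.*$", "", names(x))
  seqs <- stringr::str_to_upper(as.character(x))
  bad <- which(!grepl("^[ACGTN]*$", seqs))
  if (length(bad)) {
    rlang::abort(sprintf(
      "record %d (%s) contains characters outside ACGTN", bad[1L],
      ids[bad[1L]]), class = "strmarker_bad_alphabet")
  }
  tibble::tibble(read_id = ids, seq = seqs, qual = qual)
}

#' Write sequences to FASTA or FASTQ
#'
#' @param x Tibble with `read_id`, `seq` and optionally `qual`, or a named
#'   character vector.
#' @param path Output path; a `.gz` suffix compresses.
#' @param format `"fasta"` (default) or `"fastq"`; FASTQ requires
#'   qualities (a constant high quality is filled in when absent).
#' @return `path`, invisibly.
#' @export
write_sequences <- function(x, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  x <- as_read_tbl_q(x)
  set <- Biostrings::DNAStringSet(stats::setNames(x$seq, x$read_id))
  if (format == "fasta") {
    Biostrings::writeXStringSet(set, path,
                                compress = grepl("\\.gz$", path))
  } else {
    qual <- x$qual
    qual[is.na(qual)] <- strrep("I", nchar(x$seq)[is.na(qual)])
    Biostrings::writeXStringSet(set, path, format = "fastq",
                                qualities = Biostrings::BStringSet(qual),
                                compress = grepl("\\.gz$", path))
  }
  invisible(path)
}

as_read_tbl_q <- function(x) {
  if (is.character(x)) {
    x <- tibble::tibble(read_id = names(x) %||% paste0("read", seq_along(x)),
                        seq = unname(x))
  }
  if (!"qual" %in% names(x)) x$qual <- NA_character_
  tibble::as_tibble(x[, c("read_id", "seq", "qual")])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a genotype CSV
#'
#' The dialect is GenAlEx-like: one header row with `individual` followed
#' by each locus name repeated twice (two columns per locus, the two
#' alleles of the diploid call); one row per individual; `0` or a blank
#' cell marks a missing allele, and a call is missing only when both its
#' cells are. Allele labels are integer sizes in bp. Lossless round trip
#' with [write_genotypes()].
#'
#' @param path Path to the CSV.
#' @return A [genotype_table()].
#' @export
read_genotypes <- function(path) {
  raw <- readr::read_csv(path, col_names = FALSE, col_types =
                           readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(raw) < 3L || (ncol(raw) - 1L) %% 2L != 0L) {
    rlang::abort("genotype CSV must have an individual column plus two columns per locus",
                 class = "strmarker_bad_dialect")
  }
  header <- as.character(raw[1L, ])
  loci <- header[seq(2L, length(header), by = 2L)]
  loci2 <- header[seq(3L, length(header), by = 2L)]
  if (!identical(loci, loci2)) {
    rlang::abort("locus names must appear twice, once per allele column",
                 class = "strmarker_bad_dialect")
  }
  body <- raw[-1L, , drop = FALSE]
  to_int <- function(x) {
    x[is.na(x) | trimws(x) == "" | trimws(x) == "0"] <- NA_character_
    as.integer(x)
  }
  rows <- purrr::map(seq_len(nrow(body)), function(r) {
    tibble::tibble(
      individual = as.character(body[r, 1L][[1L]]),
      locus = loci,
      allele1 = to_int(unlist(body[r, seq(2L, ncol(body), by = 2L)])),
      allele2 = to_int(unlist(body[r, seq(3L, ncol(body), by = 2L)])))
  })
  g <- dplyr::bind_rows(rows)
  # a half-missing cell pair is a dialect error, not a genotype
  half <- xor(is.na(g$allele1), is.na(g$allele2))
  if (any(half)) {
    rlang::abort("half-missing call (one blank cell of a pair)",
                 class = "strmarker_bad_dialect")
  }
  genotype_table(g$individual, g$locus, g$allele1, g$allele2)
}

#' Write a genotype CSV
#'
#' @param gt A [genotype_table()].
#' @param path Output path.
#' @return `path`, invisibly. See [read_genotypes()] for the dialect.
#' @export
write_genotypes <- function(gt, path) {
  loci <- unique(gt$locus)
  inds <- unique(gt$individual)
  header <- c("individual", rep(loci, each = 2L))
  lines <- vapply(inds, function(i) {
    cells <- unlist(lapply(loci, function(l) {
      row <- gt[gt$individual == i & gt$locus == l, , drop = FALSE]
      if (nrow(row) == 0L || is.na(row$allele1[1L])) return(c("0", "0"))
      c(as.character(row$allele1[1L]), as.character(row$allele2[1L]))
    }))
    paste(c(i, cells), collapse = ",")
  }, character(1))
  writeLines(c(paste(header, collapse = ","), lines), path)
  invisible(path)
}

# known pipeline config keys, by section
.config_schema <- list(
  seed = NULL,
  scan = c("min_units"),
  cluster = c("anchor_k", "min_flank", "max_mismatch", "min_support"),
  filter = c("min_unit_count", "max_allele_range_bp",
             "low_complexity_threshold", "low_complexity_window",
             "copy_number_cap", "contaminant_identity_threshold",
             "contaminant_min_span", "max_amplicon_bp"),
  primer = c("primer_len_min", "primer_len_max", "pair_len_min",
             "pair_len_max", "gc_min", "gc_max", "tm_min", "tm_max",
             "tm_diff_max", "max_homopolymer", "clamp_gc_max",
             "max_amplicon_bp", "tm_method", "primer_nM", "na_mM"),
  ipcress = c("max_mismatch", "three_prime_exact", "max_product"),
  stats = c("pid_threshold"),
  sim = c("n_individuals", "n_loci", "fraction_polymorphic", "spacer_len",
          "coverage", "read_len", "error_rate"),
  paths = c("reads", "contaminant", "genotypes", "out_dir"))

#' Read and validate a pipeline configuration file
#'
#' YAML with one section per stage (`scan`, `cluster`, `filter`, `primer`,
#' `ipcress`, `stats`, `sim`, `paths`) plus a top-level `seed`. Unknown
#' sections or keys are rejected so typos cannot silently fall back to
#' defaults.
#'
#' @param path Path to a YAML file.
#' @return Nested named list of class `str_pipeline_config`, with a
#'   `config_hash` attribute (md5 of the normalised YAML).
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), names(.config_schema))
  if (length(unknown)) {
    rlang::abort(paste0("unknown config section(s): ",
                        paste(unknown, collapse = ", ")),
                 class = "strmarker_bad_config")
  }
  for (sec in setdiff(names(cfg), "seed")) {
    bad <- setdiff(names(cfg[[sec]]), .config_schema[[sec]])
    if (length(bad)) {
      rlang::abort(paste0("unknown key(s) in [", sec, "]: ",
                          paste(bad, collapse = ", ")),
                   class = "strmarker_bad_config")
    }
  }
  attr(cfg, "config_hash") <- config_hash(cfg)
  class(cfg) <- "str_pipeline_config"
  cfg
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  attributes(cfg) <- list(names = names(cfg))
  yaml::write_yaml(cfg[order(names(cfg))], tmp)
  unname(tools::md5sum(tmp))
}
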