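#' Published Sumatran rhinoceros microsatellite marker panel
#'
#' The published characterisation of 29 short-amplicon microsatellite
#' markers for the Sumatran rhinoceros (*Dicerorhinus sumatrensis*),
#' transcribed from the printed marker table: primer sequences (untailed;
#' reported size ranges include the 18 bp M13 forward tail), allele count
#' `a`, expected and observed heterozygosity, F_IS (`NA` where not printed,
#' i.e. at Ho = He loci), and the per-locus probabilities of identity for
#' unrelated individuals (`pid`) and full siblings (`pid_sib`), all based
#' on six genotyped individuals. These printed statistics are the standard
#' worked input for [panel_power()] and the panel-average summaries.
#'
#' @param group Optional filter: `"highly_recommended"`, `"recommended"`
#'   or `"not_recommended"`.
#' @return Tibble with columns `locus`, `group`, `forward`, `reverse`,
#'   `a`, `size_min`, `size_max`, `he`, `ho`, `fis`, `pid`, `pid_sib`.
#' @examples
#' panel <- rhino_marker_table()
#' mean(panel$a)
#' @export
rhino_marker_table <- function(group = NULL) {
  path <- system.file("extdata", "sumatran_rhino_markers.csv",
                      package = "strmarker", mustWork = TRUE)
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(group)) x <- x[x$group %in% group, , drop = FALSE]
  x
}
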