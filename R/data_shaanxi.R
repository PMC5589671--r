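#' Published summary tables for a Southern Shaanxi Han population sample
#'
#' The package ships the published locus-level summaries of a forensic STR
#' survey of 214 unrelated Han individuals (108 males, 106 females) from
#' Southern Shaanxi, China, typed with a 15 autosomal + 10 Y-STR
#' co-amplification panel.  They serve as realistic defaults for the
#' synthetic-population generators and as fixed inputs for reproducing the
#' study's derived statistics.
#'
#' * `shaanxi_autosomal_frequencies()` — allele frequencies of the 15
#'   autosomal loci (150 alleles; frequencies printed at 4 decimals over
#'   428 gene copies), with integer counts recovered via [recover_counts()].
#' * `shaanxi_forensic_params()` — the published per-locus forensic
#'   efficiency parameters (MP, PD, PIC, PE, TPI, Ho, He) and
#'   Hardy-Weinberg p-values.
#' * `shaanxi_y_frequencies()` — allele frequencies of the 10 Y-STR loci in
#'   the 108 males (DYS385a,b as unordered pair alleles), counts recovered.
#' * `shaanxi_y_gene_diversities()` — the published Nei gene diversity per
#'   Y locus.
#' * `shaanxi_y_spectrum()` — a haplotype multiplicity spectrum for the 108
#'   males: 94 singletons, 4 doubletons, 2 tripletons.  The published
#'   per-haplotype listing is not redistributed here; this spectrum is the
#'   unique reconstruction consistent with the reported 100 distinct / 94
#'   unique haplotypes and haplotype diversity 0.998269, and is labelled
#'   inferred for that reason.
#'
#' @param recover_cts fill the `count` column from the rounded frequencies.
#' @return Frequency accessors return [allele_freqs()] tables; the others
#'   plain data frames or (for the spectrum) an integer vector of
#'   per-haplotype multiplicities.
#' @name shaanxi_han
NULL

extdata <- function(file) {
  path <- system.file("extdata", file, package = "strforensics")
  if (path == "") abort("bundled data file not found: ", file)
  path
}

#' @rdname shaanxi_han
#' @export
shaanxi_autosomal_frequencies <- function(recover_cts = TRUE) {
  df <- utils::read.csv(extdata("shaanxi_han_autosomal_freqs.csv"),
                        colClasses = "character")
  df$frequency <- as.numeric(df$frequency)
  af <- allele_freqs(df, n_genes = 428)
  if (recover_cts) af <- recover_table_counts(af)
  af
}

#' @rdname shaanxi_han
#' @export
shaanxi_forensic_params <- function() {
  utils::read.csv(extdata("shaanxi_han_forensic_params.csv"),
                  colClasses = c(locus = "character"))
}

#' @rdname shaanxi_han
#' @export
shaanxi_y_frequencies <- function(recover_cts = TRUE) {
  df <- utils::read.csv(extdata("shaanxi_han_y_freqs.csv"),
                        colClasses = "character")
  df$frequency <- as.numeric(df$frequency)
  af <- allele_freqs(df, n_genes = 108)
  if (recover_cts) af <- recover_table_counts(af)
  af
}

#' @rdname shaanxi_han
#' @export
shaanxi_y_gene_diversities <- function() {
  utils::read.csv(extdata("shaanxi_han_y_gd.csv"),
                  colClasses = c(locus = "character"))
}

#' @rdname shaanxi_han
#' @export
shaanxi_y_spectrum <- function() {
  rep(c(1L, 2L, 3L), times = c(94L, 4L, 2L))
}
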