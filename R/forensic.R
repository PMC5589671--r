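#' Forensic efficiency parameters for autosomal STR loci
#'
#' The per-locus statistic suite routinely reported for forensic STR
#' panels.  With allele frequencies `p_i` (exact count fractions), `n`
#' typed individuals, observed heterozygosity `h` and `H = 1 - h`:
#'
#' * `observed_heterozygosity()`: `h` = heterozygous / typed individuals.
#' * `expected_heterozygosity()`: `He = (1 - sum(p_i^2)) * n/(n-1)`.  The
#'   sample-size correction uses the number of *individuals*, the
#'   convention of the forensic "powerstat" worksheets this suite mirrors;
#'   `correction = "genes"` gives the population-genetic `2n/(2n-1)` form
#'   and `"none"` the uncorrected gene diversity.
#' * `pic()`: polymorphism information content, Botstein's
#'   `1 - sum(p^2) - (sum(p^2))^2 + sum(p^4)`.
#' * `match_probability()`: `MP = sum(g_k^2)` over the *observed* genotype
#'   frequencies `g_k` (unordered pairs), and `power_of_discrimination()`
#'   `PD = 1 - MP`.  `expected = TRUE` replaces observed genotype
#'   frequencies by their Hardy-Weinberg expectations.
#' * `power_of_exclusion()`: `PE = h^2 * (1 - 2*h*H^2)` (Brenner form).
#' * `typical_paternity_index()`: `TPI = 1 / (2*H)`; undefined at `h = 1`.
#'
#' @param p numeric vector of allele frequencies (sums to 1).
#' @param n number of typed individuals.
#' @param ho observed heterozygosity in `[0, 1]`.
#' @param correction sample-size correction for `He` (see above).
#' @name forensic_parameters
NULL

#' @rdname forensic_parameters
#' @param gt a [genotype_table()].
#' @param locus autosomal locus name.
#' @export
observed_heterozygosity <- function(gt, locus) {
  m <- gt$autosomal[[locus]]
  if (is.null(m)) abort("not an autosomal locus: ", locus)
  ok <- !is.na(m[, 1])
  if (!any(ok)) abort("locus ", locus, " has no typed samples")
  mean(m[ok, 1] != m[ok, 2])
}

#' @rdname forensic_parameters
#' @export
expected_heterozygosity <- function(p, n,
                                    correction = c("individuals", "genes",
                                                   "none")) {
  correction <- match.arg(correction)
  check_simplex(p)
  d <- 1 - sum(p^2)
  switch(correction,
         individuals = { if (n < 2) abort("need n >= 2"); d * n / (n - 1) },
         genes = { if (n < 1) abort("need n >= 1"); d * 2 * n / (2 * n - 1) },
         none = d)
}

#' @rdname forensic_parameters
#' @export
pic <- function(p) {
  check_simplex(p)
  s2 <- sum(p^2)
  1 - s2 - s2^2 + sum(p^4)
}

#' @rdname forensic_parameters
#' @param expected use Hardy-Weinberg expected genotype frequencies instead
#'   of the observed genotype counts (not the reporting default).
#' @export
match_probability <- function(gt, locus, expected = FALSE) {
  if (expected) {
    af <- allele_frequencies(gt, locus)
    p <- locus_frequencies(af, locus)
    g <- outer(p, p)
    return(sum(diag(g)^2) + sum((2 * g[upper.tri(g)])^2))
  }
  m <- gt$autosomal[[locus]]
  if (is.null(m)) abort("not an autosomal locus: ", locus)
  ok <- !is.na(m[, 1])
  if (!any(ok)) abort("locus ", locus, " has no typed samples")
  g <- table(paste(m[ok, 1], m[ok, 2], sep = "/"))
  sum((g / sum(g))^2)
}

#' @rdname forensic_parameters
#' @param ... passed on to [match_probability()].
#' @export
power_of_discrimination <- function(gt, locus, ...) {
  1 - match_probability(gt, locus, ...)
}

#' @rdname forensic_parameters
#' @export
power_of_exclusion <- function(ho) {
  if (any(ho < 0 | ho > 1)) abort("Ho must be in [0, 1]")
  H <- 1 - ho
  ho^2 * (1 - 2 * ho * H^2)
}

#' @rdname forensic_parameters
#' @export
typical_paternity_index <- function(ho) {
  if (any(ho < 0 | ho > 1)) abort("Ho must be in [0, 1]")
  if (any(ho == 1)) abort("TPI is undefined when every individual is heterozygous")
  1 / (2 * (1 - ho))
}

check_simplex <- function(p, tol = 1e-6) {
  if (any(p < 0)) abort("negative frequency")
  if (abs(sum(p) - 1) > tol) abort("frequencies must sum to 1")
}

#' Per-locus forensic parameter table from genotypes
#'
#' Builds the standard report table (one row per autosomal locus with MP,
#' PD, PIC, PE, TPI, Ho, He) from a genotype table.
#'
#' @param gt a [genotype_table()].
#' @param loci autosomal loci to include (default all).
#' @inheritParams forensic_parameters
#' @return data frame with one row per locus.
#' @seealso [forensic_params_from_counts()] for the frequency-table route,
#'   [combined_powers()] for the across-loci summaries.
#' @export
forensic_params <- function(gt, loci = autosomal_loci(gt),
                            correction = "individuals") {
  rows <- lapply(loci, function(l) {
    af <- allele_frequencies(gt, l)
    p <- locus_frequencies(af, l)
    m <- gt$autosomal[[l]]
    n <- sum(!is.na(m[, 1]))
    ho <- observed_heterozygosity(gt, l)
    mp <- match_probability(gt, l)
    data.frame(locus = l, MP = mp, PD = 1 - mp, PIC = pic(p),
               PE = power_of_exclusion(ho),
               TPI = if (ho < 1) typical_paternity_index(ho) else NA_real_,
               Ho = ho,
               He = expected_heterozygosity(p, n, correction),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Forensic parameters from recovered counts
#'
#' Computes the frequency-driven columns of the report table (PIC, He) from
#' integer allele counts and the heterozygosity-driven columns (PE, TPI)
#' from a heterozygote count, i.e. exactly the information recoverable from
#' a published frequency table plus a printed observed heterozygosity.
#'
#' @param counts named list: locus -> integer allele-count vector.
#' @param n_het named numeric vector: heterozygous individuals per locus
#'   (may be omitted, dropping the PE/TPI/Ho columns).
#' @param n number of typed individuals (counts are over `2 * n` genes).
#' @inheritParams forensic_parameters
#' @return data frame with one row per locus.
#' @export
forensic_params_from_counts <- function(counts, n_het = NULL, n,
                                        correction = "individuals") {
  rows <- lapply(names(counts), function(l) {
    cts <- counts[[l]]
    p <- cts / sum(cts)
    row <- data.frame(locus = l, PIC = pic(p),
                      He = expected_heterozygosity(p, n, correction),
                      stringsAsFactors = FALSE)
    if (!is.null(n_het)) {
      ho <- n_het[[l]] / n
      row$Ho <- ho
      row$PE <- power_of_exclusion(ho)
      row$TPI <- typical_paternity_index(ho)
    }
    row
  })
  do.call(rbind, rows)
}

#' Combined powers of discrimination and exclusion
#'
#' Across loci, `combined PD = 1 - prod(MP_i)` and
#' `combined PE = 1 - prod(1 - PE_i)`.  These complements sit so close to 1
#' (the PD complement is of order 1e-17 for a 15-locus panel) that doubles
#' cannot represent them, so the combined values are returned both as exact
#' decimal strings (computed by integer arithmetic on the rounded inputs)
#' and as machine floats of the complementary products, which remain the
#' machine-precision source of truth.
#'
#' @param mp per-locus matching probabilities.
#' @param pe per-locus powers of exclusion.
#' @param digits decimal places at which the inputs are taken for the exact
#'   string computation (default 4, the reporting precision).
#' @return list with `combined_pd` / `combined_pe` (exact decimal strings),
#'   `prod_mp` / `prod_one_minus_pe` (their float complements), and
#'   `combined_pd_num` / `combined_pe_num` (float versions, may round to 1).
#' @examples
#' combined_powers(mp = c(0.1284, 0.0762), pe = c(0.5058, 0.6593))
#' @export
combined_powers <- function(mp, pe, digits = 4) {
  if (!length(mp) || !length(pe)) abort("need at least one locus")
  if (any(mp < 0 | mp > 1) || any(pe < 0 | pe > 1)) {
    abort("MP and PE must be in [0, 1]")
  }
  pd <- dec_complement_product(fmt_num(mp, digits))
  pe_c <- dec_complement_product(fmt_num(1 - pe, digits))
  list(combined_pd = pd$value,
       combined_pe = pe_c$value,
       prod_mp = prod(mp),
       prod_one_minus_pe = prod(1 - pe),
       combined_pd_num = 1 - prod(mp),
       combined_pe_num = 1 - prod(1 - pe))
}
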