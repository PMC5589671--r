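#' Y-STR haplotypes and diversity statistics
#'
#' `build_haplotypes()` assembles one haplotype per male over the declared
#' Y-locus panel (DYS385a,b compared as an unordered pair) and tallies the
#' multiplicity spectrum.  Males missing any Y locus are excluded with a
#' warning and counted in the result.
#'
#' The diversity suite, for `n` sampled chromosomes:
#' * `gene_diversity()` — Nei's unbiased gene diversity
#'   `GD = n/(n-1) * (1 - sum(p_i^2))` over allele frequencies `p_i`.
#' * `haplotype_diversity()` — the same formula applied to whole-haplotype
#'   frequencies; equals 1 exactly when all haplotypes are distinct.
#' * `discriminatory_capacity()` — distinct haplotypes divided by `n`.
#'
#' `haplotype_diversity()` and `discriminatory_capacity()` accept the
#' per-haplotype multiplicity vector returned in `$multiplicities` (or any
#' integer vector summing to `n`).
#'
#' @param gt a [genotype_table()] with Y loci typed on its males.
#' @param loci Y loci making up the haplotype (default all in the table).
#' @return `build_haplotypes()`: list with `haplotypes` (data frame:
#'   `sample_id`, one column per locus, `haplotype` key, `multiplicity`),
#'   `multiplicities` (integer vector, one entry per *distinct* haplotype),
#'   `spectrum` (data frame `multiplicity` / `n_haplotypes`), `n` males
#'   typed, `n_excluded` males dropped for missing loci.
#' @examples
#' hd <- haplotype_diversity(rep(c(1, 2, 3), c(94, 4, 2)))  # n = 108 males
#' round(hd, 6)
#' @export
build_haplotypes <- function(gt, loci = y_loci(gt)) {
  if (!length(loci)) abort("genotype table has no Y loci")
  males <- which(gt$sex == "male")
  if (!length(males)) abort("no male samples")
  cols <- lapply(loci, function(l) {
    v <- gt$y[[l]]
    if (is.null(v)) abort("unknown Y locus: ", l)
    if (is.matrix(v)) {
      out <- rep(NA_character_, nrow(v))
      ok <- !is.na(v[, 1])
      out[ok] <- paste(v[ok, 1], v[ok, 2], sep = ",")
      out[males]
    } else v[males]
  })
  names(cols) <- loci
  complete <- Reduce(`&`, lapply(cols, function(v) !is.na(v)))
  n_excluded <- sum(!complete)
  if (n_excluded > 0) {
    warning(n_excluded, " male(s) excluded: missing Y-locus calls",
            call. = FALSE)
  }
  if (!any(complete)) abort("no male is typed at every Y locus")
  df <- data.frame(sample_id = gt$sample_id[males][complete],
                   lapply(cols, function(v) v[complete]),
                   check.names = FALSE, stringsAsFactors = FALSE)
  key <- do.call(paste, c(df[loci], sep = "|"))
  tab <- table(key)
  df$haplotype <- key
  df$multiplicity <- as.integer(tab[key])
  mult <- as.integer(tab)
  spec <- table(mult)
  list(haplotypes = df,
       multiplicities = mult,
       spectrum = data.frame(multiplicity = as.integer(names(spec)),
                             n_haplotypes = as.integer(spec)),
       n = sum(complete),
       n_excluded = n_excluded)
}

#' @rdname build_haplotypes
#' @param p allele frequencies (sum to 1), or with `counts`, integer allele
#'   counts from which exact frequencies are formed.
#' @param n number of sampled chromosomes; inferred when counts are given.
#' @param counts integer allele counts (alternative to `p` + `n`).
#' @export
gene_diversity <- function(p = NULL, n = NULL, counts = NULL) {
  if (!is.null(counts)) {
    n <- sum(counts)
    p <- counts / n
  }
  if (is.null(p) || is.null(n)) abort("supply counts, or p and n")
  if (n < 2) abort("need n >= 2 chromosomes")
  check_simplex(p)
  n / (n - 1) * (1 - sum(p^2))
}

#' @rdname build_haplotypes
#' @param multiplicities integer vector of per-haplotype counts.
#' @export
haplotype_diversity <- function(multiplicities) {
  n <- sum(multiplicities)
  gene_diversity(counts = multiplicities)
}

#' @rdname build_haplotypes
#' @export
discriminatory_capacity <- function(multiplicities) {
  n <- sum(multiplicities)
  if (n < 1) abort("empty spectrum")
  length(multiplicities) / n
}

#' Y-STR summary report
#'
#' One call producing the per-locus gene diversity table and the haplotype
#' summary (distinct, unique, DC, HD) for the males of a genotype table.
#'
#' @inheritParams build_haplotypes
#' @return list with `gene_diversity` (data frame locus/gd), `n`,
#'   `n_distinct`, `n_unique`, `dc`, `hd`.
#' @export
ystr_summary <- function(gt, loci = y_loci(gt)) {
  hb <- build_haplotypes(gt, loci)
  af <- allele_frequencies(gt, loci)
  gd <- vapply(loci, function(l) {
    gene_diversity(counts = locus_counts(af, l))
  }, numeric(1))
  list(gene_diversity = data.frame(locus = loci, gd = unname(gd),
                                   stringsAsFactors = FALSE),
       n = hb$n,
       n_distinct = length(hb$multiplicities),
       n_unique = sum(hb$multiplicities == 1L),
       dc = discriminatory_capacity(hb$multiplicities),
       hd = haplotype_diversity(hb$multiplicities))
}
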