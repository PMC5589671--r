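#' Allele frequency tables
#'
#' An `allele_freqs` object is a long data frame with columns `locus`,
#' `allele`, `count`, `frequency`, carrying the number of sampled gene
#' copies per locus (`n_genes`, an attribute: 2n for autosomal loci typed in
#' n individuals, the number of males for haploid Y loci).  When built from
#' genotypes every frequency is exactly `count / n_genes`; when built from a
#' published, rounded table the integer counts are recovered with
#' [recover_counts()].
#'
#' @param df data frame with columns `locus`, `allele`, and `count` and/or
#'   `frequency`.
#' @param n_genes named numeric vector of gene-copy totals per locus, or a
#'   single number recycled to all loci.
#' @return An `allele_freqs` data frame, alleles sorted within locus.
#' @export
allele_freqs <- function(df, n_genes) {
  need <- c("locus", "allele")
  if (!all(need %in% names(df))) abort("df needs locus and allele columns")
  df$locus <- as.character(df$locus)
  df$allele <- canonical_allele_label(df$allele)
  loci <- unique(df$locus)
  if (length(n_genes) == 1 && is.null(names(n_genes))) {
    n_genes <- stats::setNames(rep(n_genes, length(loci)), loci)
  }
  if (!all(loci %in% names(n_genes))) abort("n_genes missing for some loci")
  n_genes <- n_genes[loci]
  if (is.null(df$count) && is.null(df$frequency)) {
    abort("df needs a count or frequency column")
  }
  if (is.null(df$count)) df$count <- NA_real_
  if (is.null(df$frequency)) df$frequency <- df$count / n_genes[df$locus]
  # order alleles numerically within locus, loci in first-appearance order
  df <- df[order(match(df$locus, loci), allele_sort_key(df$allele)), ,
           drop = FALSE]
  rownames(df) <- NULL
  for (l in loci) {
    f <- df$frequency[df$locus == l]
    slack <- 0.5 / n_genes[[l]]
    if (abs(sum(f) - 1) > slack * sum(df$locus == l)) {
      abort("frequencies at locus ", l, " sum to ", format(sum(f)),
            ", outside rounding slack")
    }
  }
  structure(df[c("locus", "allele", "count", "frequency")],
            n_genes = n_genes, class = c("allele_freqs", "data.frame"))
}

#' @rdname allele_freqs
#' @param x an `allele_freqs` object.
#' @export
n_genes <- function(x) attr(x, "n_genes")

#' Allele frequencies from a genotype table
#'
#' Counts allele copies at one locus (or all loci) of a [genotype_table()].
#' Autosomal loci contribute two gene copies per typed individual; haploid
#' Y loci one per typed male; pair-valued Y loci (DYS385a,b) are counted as
#' unordered *pair* alleles, one pair per male, matching the convention of
#' published Y-STR frequency tables.
#'
#' @param gt a [genotype_table()].
#' @param locus locus name, or `NULL` for every locus in the table.
#' @return An [allele_freqs()] table; every frequency equals
#'   `count / n_genes` exactly and sums to 1 per locus.
#' @export
allele_frequencies <- function(gt, locus = NULL) {
  loci <- locus %||% c(names(gt$autosomal), names(gt$y))
  rows <- list()
  ng <- numeric(0)
  for (l in loci) {
    if (!is.null(gt$autosomal[[l]])) {
      m <- gt$autosomal[[l]]
      labs <- c(m[, 1], m[, 2])
      labs <- labs[!is.na(labs)]
    } else if (!is.null(gt$y[[l]])) {
      v <- gt$y[[l]]
      labs <- if (is.matrix(v)) {
        ok <- !is.na(v[, 1])
        paste(v[ok, 1], v[ok, 2], sep = ",")   # unordered pair allele
      } else v[!is.na(v)]
    } else {
      abort("unknown locus: ", l)
    }
    if (!length(labs)) abort("locus ", l, " has no typed samples")
    tab <- table(labs)
    rows[[l]] <- data.frame(locus = l, allele = names(tab),
                            count = as.numeric(tab),
                            stringsAsFactors = FALSE)
    ng[[l]] <- sum(tab)
  }
  allele_freqs(do.call(rbind, rows), ng)
}

#' Recover integer allele counts from a rounded frequency table
#'
#' Published frequency tables print `count / n_genes` rounded to (typically)
#' four decimals.  For the table sizes of forensic studies that rounding is
#' injective, so the integer counts are recovered exactly as
#' `round(frequency * n_genes)`.  The result carries a consistency flag that
#' is `TRUE` iff the counts sum to `n_genes` and every recovered
#' `count/n_genes` is within 5e-5 of the printed frequency; an inconsistent
#' table is reported, never silently renormalised.
#'
#' @param freqs numeric vector of rounded frequencies in `[0, 1]`.
#' @param n_genes integer number of gene copies behind the table.
#' @return list with `counts` (integer vector) and `consistent` (flag).
#' @examples
#' recover_counts(c(0.5210, 0.1192, 0.0234, 0.3154, 0.0210), 428)
#' @export
recover_counts <- function(freqs, n_genes) {
  if (any(freqs < 0 | freqs > 1)) abort("frequencies must be in [0, 1]")
  if (n_genes < 1) abort("n_genes must be >= 1")
  counts <- as.integer(floor(freqs * n_genes + 0.5))
  consistent <- sum(counts) == n_genes &&
    all(abs(counts / n_genes - freqs) <= 5e-5 + 1e-12)
  list(counts = counts, consistent = consistent)
}

#' Attach recovered counts to a published frequency table
#'
#' @param af an [allele_freqs()] table built from printed frequencies.
#' @param strict error (rather than warn) when a locus fails the
#'   [recover_counts()] consistency check.
#' @return the table with its `count` column filled in.
#' @export
recover_table_counts <- function(af, strict = TRUE) {
  ng <- n_genes(af)
  for (l in unique(af$locus)) {
    i <- af$locus == l
    rc <- recover_counts(af$frequency[i], ng[[l]])
    if (!rc$consistent) {
      msg <- paste0("locus ", l, ": rounded frequencies are not consistent ",
                    "with ", ng[[l]], " gene copies")
      if (strict) abort(msg) else warning(msg, call. = FALSE)
    }
    af$count[i] <- rc$counts
  }
  af
}

#' Frequency-table CSV round trip
#'
#' Writes `locus, allele, count, frequency, n_genes` with frequencies at a
#' fixed decimal width so output is bit-stable for fixed input.
#'
#' @param af an [allele_freqs()] table.
#' @param path file path.
#' @param digits decimal width for the frequency column.
#' @return `write_frequency_csv()` returns `path` invisibly;
#'   `read_frequency_csv()` returns an [allele_freqs()] table.
#' @export
write_frequency_csv <- function(af, path, digits = 4) {
  ng <- n_genes(af)
  out <- data.frame(locus = af$locus, allele = af$allele,
                    count = af$count,
                    frequency = fmt_num(af$frequency, digits),
                    n_genes = as.numeric(ng[af$locus]),
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_frequency_csv
#' @export
read_frequency_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = c(locus = "character",
                                             allele = "character"))
  ng <- tapply(df$n_genes, df$locus, function(v) v[1])
  af <- df[c("locus", "allele", "count", "frequency")]
  if (all(is.na(af$count))) af$count <- NULL
  if (!all(is.na(af$count)) && any(is.na(af$count))) af$count <- NULL
  allele_freqs(af, stats::setNames(as.numeric(ng), names(ng)))
}

# frequency vector of one locus, sorted, named by allele
locus_frequencies <- function(af, locus) {
  i <- af$locus == locus
  if (!any(i)) abort("locus not in table: ", locus)
  stats::setNames(af$frequency[i], af$allele[i])
}

locus_counts <- function(af, locus) {
  i <- af$locus == locus
  if (!any(i)) abort("locus not in table: ", locus)
  if (anyNA(af$count[i])) abort("counts not available for locus ", locus)
  stats::setNames(af$count[i], af$allele[i])
}
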