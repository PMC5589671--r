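#' Genotype tables
#'
#' A `genotype_table` holds one row per individual: a sample identifier, a
#' sex, an unordered allele pair per autosomal locus, and (for males) one
#' allele per single-copy Y locus plus an unordered pair for the duplicated
#' DYS385a,b locus.  Allele pairs are canonicalised ascending so genotype
#' identity never depends on input order; missing data are `NA`.
#'
#' @param sample_id character vector of unique sample identifiers.
#' @param sex character vector, `"male"`/`"female"` (or `"M"`/`"F"`).
#' @param autosomal named list of n-by-2 character matrices of allele labels
#'   (rows = samples); a fully `NA` row is a missing genotype.
#' @param y named list of Y-locus calls: a character vector per single-copy
#'   locus, or an n-by-2 matrix for pair-valued loci (e.g. `DYS385ab`).
#'   Entries must be `NA` on female rows.
#' @return An object of class `genotype_table`.
#' @seealso [read_genotype_csv()], [allele_frequencies()]
#' @export
genotype_table <- function(sample_id, sex,
                           autosomal = list(), y = list()) {
  sample_id <- as.character(sample_id)
  n <- length(sample_id)
  if (anyDuplicated(sample_id)) abort("duplicate sample ids")
  sex <- normalize_sex(sex)
  if (length(sex) != n) abort("sex must have one entry per sample")

  autosomal <- lapply(autosomal, function(m) {
    m <- as.matrix(m)
    if (ncol(m) != 2 || nrow(m) != n) {
      abort("each autosomal locus needs an n-by-2 allele matrix")
    }
    half <- xor(is.na(m[, 1]), is.na(m[, 2]))
    if (any(half)) {
      abort("unpaired autosomal allele at row(s) ",
            paste(which(half), collapse = ", "))
    }
    ok <- !is.na(m[, 1])
    m[ok, 1] <- canonical_allele_label(m[ok, 1])
    m[ok, 2] <- canonical_allele_label(m[ok, 2])
    swap <- ok & allele_sort_key(m[, 1]) > allele_sort_key(m[, 2])
    swap[is.na(swap)] <- FALSE
    if (any(swap)) m[swap, ] <- m[swap, c(2, 1)]
    dimnames(m) <- NULL
    m
  })

  is_male <- sex == "male"
  y <- lapply(y, function(v) {
    if (is.matrix(v)) {
      if (nrow(v) != n || ncol(v) != 2) abort("pair-valued Y locus needs n-by-2 matrix")
      if (any(!is.na(v) & !is_male)) abort("Y allele recorded for a female sample")
      ok <- !is.na(v[, 1])
      v[ok, 1] <- canonical_allele_label(v[ok, 1])
      v[ok, 2] <- canonical_allele_label(v[ok, 2])
      swap <- ok & allele_sort_key(v[, 1]) > allele_sort_key(v[, 2])
      swap[is.na(swap)] <- FALSE
      if (any(swap)) v[swap, ] <- v[swap, c(2, 1)]
      dimnames(v) <- NULL
      v
    } else {
      v <- as.character(v)
      if (length(v) != n) abort("Y locus vector has wrong length")
      if (any(!is.na(v) & !is_male)) abort("Y allele recorded for a female sample")
      v[!is.na(v)] <- canonical_allele_label(v[!is.na(v)])
      v
    }
  })

  structure(list(sample_id = sample_id, sex = sex,
                 autosomal = autosomal, y = y),
            class = "genotype_table")
}

normalize_sex <- function(sex) {
  s <- tolower(as.character(sex))
  s[s %in% c("m", "male")] <- "male"
  s[s %in% c("f", "female")] <- "female"
  if (!all(s %in% c("male", "female"))) abort("sex must be male/female")
  s
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("<genotype_table> %d samples (%d male, %d female)\n",
              length(x$sample_id), sum(x$sex == "male"),
              sum(x$sex == "female")))
  cat("  autosomal loci:", paste(names(x$autosomal), collapse = ", "), "\n")
  if (length(x$y)) cat("  Y loci:", paste(names(x$y), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname genotype_table
#' @param gt a `genotype_table`.
#' @export
n_samples <- function(gt) length(gt$sample_id)

#' @rdname genotype_table
#' @export
autosomal_loci <- function(gt) names(gt$autosomal)

#' @rdname genotype_table
#' @export
y_loci <- function(gt) names(gt$y)

#' Read and write genotype CSV files
#'
#' The genotype CSV dialect is one row per individual with columns
#' `sample_id`, `sex`, then one column per locus.  The two alleles of a
#' genotype share a cell joined by `"/"` (`"15/16"`, `"9.3/9.3"`, and for
#' DYS385a,b `"13/18"`); single-copy Y loci hold one allele; a missing cell
#' is `"."`.  Malformed cells are reported with row and column coordinates.
#'
#' @param path file path.
#' @param y_loci character vector naming the Y-chromosomal columns; by
#'   default every column whose name starts with `"DYS"`.
#' @param y_pair_loci Y loci carrying two alleles per male (default any
#'   locus named like DYS385).
#' @param missing the missing-data marker, default `"."`.
#' @return `read_genotype_csv()` returns a [genotype_table()];
#'   `write_genotype_csv()` returns `path` invisibly.
#' @export
read_genotype_csv <- function(path, y_loci = NULL, y_pair_loci = NULL,
                              missing = ".") {
  if (!file.exists(path)) abort("no such file: ", path)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  need <- c("sample_id", "sex")
  if (!all(need %in% names(df))) {
    abort("genotype CSV must have sample_id and sex columns")
  }
  loci <- setdiff(names(df), need)
  if (is.null(y_loci)) y_loci <- grep("^DYS", loci, value = TRUE)
  if (!all(y_loci %in% loci)) {
    abort("unknown Y locus column(s): ",
          paste(setdiff(y_loci, loci), collapse = ", "))
  }
  if (is.null(y_pair_loci)) y_pair_loci <- grep("^DYS385", y_loci, value = TRUE)
  auto_loci <- setdiff(loci, y_loci)

  n <- nrow(df)
  errors <- character(0)
  cell_alleles <- function(locus, expect) {
    cells <- trimws(df[[locus]])
    out <- matrix(NA_character_, n, expect)
    for (i in seq_len(n)) {
      cell <- cells[i]
      if (is.na(cell) || cell == missing || cell == "") next
      parts <- strsplit(cell, "/", fixed = TRUE)[[1]]
      if (length(parts) != expect || any(!nzchar(trimws(parts)))) {
        errors <<- c(errors, sprintf(
          "row %d, column %s: cell %s does not hold %d allele(s)",
          i, locus, sQuote(cell), expect))
        next
      }
      parsed <- tryCatch(canonical_allele_label(parts), error = function(e) NULL)
      if (is.null(parsed)) {
        errors <<- c(errors, sprintf("row %d, column %s: unparseable allele in %s",
                                     i, locus, sQuote(cell)))
        next
      }
      out[i, ] <- parsed
    }
    out
  }

  autosomal <- lapply(auto_loci, cell_alleles, expect = 2L)
  names(autosomal) <- auto_loci
  y <- lapply(y_loci, function(l) {
    if (l %in% y_pair_loci) cell_alleles(l, 2L) else cell_alleles(l, 1L)[, 1]
  })
  names(y) <- y_loci
  if (length(errors)) abort("malformed genotype file:\n  ",
                            paste(errors, collapse = "\n  "))
  gt <- tryCatch(
    genotype_table(df$sample_id, df$sex, autosomal, y),
    error = function(e) abort("invalid genotype table in ", path, ": ",
                              conditionMessage(e)))
  gt
}

#' @rdname read_genotype_csv
#' @param gt a [genotype_table()].
#' @export
write_genotype_csv <- function(gt, path, missing = ".") {
  join <- function(m) {
    out <- rep(missing, nrow(m))
    ok <- !is.na(m[, 1])
    out[ok] <- paste(m[ok, 1], m[ok, 2], sep = "/")
    out
  }
  df <- data.frame(sample_id = gt$sample_id, sex = gt$sex,
                   check.names = FALSE, stringsAsFactors = FALSE)
  for (l in names(gt$autosomal)) df[[l]] <- join(gt$autosomal[[l]])
  for (l in names(gt$y)) {
    v <- gt$y[[l]]
    df[[l]] <- if (is.matrix(v)) join(v) else ifelse(is.na(v), missing, v)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
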