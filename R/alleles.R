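#' STR allele labels
#'
#' STR alleles are named by their repeat count, with microvariant alleles
#' carrying a partial-repeat digit after a decimal point: `"9.3"` is nine full
#' repeats plus three bases, `"31.2"` is thirty-one repeats plus two bases.
#' Multi-copy loci (DYS385a,b) use an unordered *pair* label such as
#' `"13,18"`, stored with the smaller member first.
#'
#' `parse_allele_label()` splits labels into their numeric parts,
#' `canonical_allele_label()` normalises a label to its canonical string
#' (`"15.0"` becomes `"15"`, pair members are sorted ascending), and
#' `allele_order()`/`sort_allele_labels()` give the numeric ordering used in
#' every frequency table: by full repeat count, then partial digit (pairs
#' lexicographically on their sorted members).
#'
#' @param x character vector of allele labels.
#' @return `parse_allele_label()`: data frame with columns `label`,
#'   `repeats`, `partial`, `is_pair`; `canonical_allele_label()`: character
#'   vector; `allele_order()`: integer permutation; `sort_allele_labels()`:
#'   sorted character vector.
#' @examples
#' canonical_allele_label(c("15.0", "9.3", "18,13"))
#' sort_allele_labels(c("10", "9.3", "9", "31.2", "31"))
#' @export
parse_allele_label <- function(x) {
  x <- trimws(as.character(x))
  single <- "^[0-9]+(\\.[0-9])?$"
  pair <- "^[0-9]+(\\.[0-9])?,[0-9]+(\\.[0-9])?$"
  bad <- !is.na(x) & !(grepl(single, x) | grepl(pair, x))
  if (any(bad)) {
    abort("unparseable allele label(s): ",
          paste(sQuote(unique(x[bad])), collapse = ", "))
  }
  is_pair <- !is.na(x) & grepl(",", x, fixed = TRUE)
  rep1 <- rep(NA_real_, length(x))
  part1 <- rep(NA_integer_, length(x))
  sing <- !is.na(x) & !is_pair
  if (any(sing)) {
    v <- x[sing]
    rep1[sing] <- as.integer(sub("\\..*$", "", v))
    part1[sing] <- ifelse(grepl(".", v, fixed = TRUE),
                          as.integer(sub("^.*\\.", "", v)), 0L)
  }
  data.frame(label = x, repeats = rep1, partial = part1,
             is_pair = is_pair, stringsAsFactors = FALSE)
}

#' @rdname parse_allele_label
#' @export
canonical_allele_label <- function(x) {
  x <- trimws(as.character(x))
  is_pair <- !is.na(x) & grepl(",", x, fixed = TRUE)
  sing <- !is.na(x) & !is_pair
  out <- rep(NA_character_, length(x))
  if (any(sing)) {
    p <- parse_allele_label(x[sing])
    out[sing] <- ifelse(p$partial == 0L, as.character(p$repeats),
                        paste0(p$repeats, ".", p$partial))
  }
  if (any(is_pair)) {
    out[is_pair] <- vapply(strsplit(x[is_pair], ",", fixed = TRUE),
                           function(ab) {
                             ab <- canonical_allele_label(ab)
                             paste(sort_allele_labels(ab), collapse = ",")
                           }, character(1))
  }
  out
}

# numeric sort key: repeats + partial/10; pairs get first*1e3 + second
allele_sort_key <- function(x) {
  x <- as.character(x)
  is_pair <- !is.na(x) & grepl(",", x, fixed = TRUE)
  sing <- !is.na(x) & !is_pair
  key <- rep(NA_real_, length(x))
  if (any(sing)) {
    p <- parse_allele_label(x[sing])
    key[sing] <- p$repeats + p$partial / 10
  }
  if (any(is_pair)) {
    key[is_pair] <- vapply(strsplit(x[is_pair], ",", fixed = TRUE),
                           function(ab) {
                             k <- sort(allele_sort_key(ab))
                             k[1] * 1e3 + k[2]
                           }, numeric(1))
  }
  key
}

#' @rdname parse_allele_label
#' @export
allele_order <- function(x) order(allele_sort_key(x))

#' @rdname parse_allele_label
#' @export
sort_allele_labels <- function(x) x[allele_order(x)]

# numeric repeat score of a single-copy allele label (9.3 -> 9.3); used by Rst
allele_repeat_score <- function(x) {
  p <- parse_allele_label(x)
  if (any(p$is_pair)) abort("pair-valued alleles have no single repeat score")
  p$repeats + p$partial / 10
}
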