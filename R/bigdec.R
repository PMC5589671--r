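# Arbitrary-precision complement of a product of short decimal fractions.
#
# Combined forensic powers are quantities like 1 - prod(MP_i) where the
# product is of order 1e-17: the complement is indistinguishable from 1 in
# double precision, so it is carried as an exact decimal string.  Each
# factor is a decimal in [0, 1] with at most 9 decimal places; the product
# is computed exactly as a big integer over a power-of-ten denominator and
# the complement by exact digit arithmetic.

BIGBASE <- 10000

# big integer (little-endian base-1e4 digit vector) times small integer;
# every intermediate stays far below 2^53 because small < 1e9
big_mul <- function(big, small) {
  carry <- 0
  out <- numeric(0)
  for (i in seq_along(big)) {
    v <- big[i] * small + carry
    out[i] <- v %% BIGBASE
    carry <- v %/% BIGBASE
  }
  while (carry > 0) {
    out[length(out) + 1] <- carry %% BIGBASE
    carry <- carry %/% BIGBASE
  }
  if (!length(out)) out <- 0
  out
}

# decimal digit string of a big integer, most significant first
big_to_digits <- function(big) {
  chunks <- vapply(rev(big), function(d) sprintf("%04d", d), character(1))
  s <- sub("^0+", "", paste(chunks, collapse = ""))
  if (s == "") "0" else s
}

# exact decimal string of 1 - prod(x_i), x_i given as decimal strings
dec_complement_product <- function(x) {
  x <- trimws(as.character(x))
  if (!all(grepl("^(0(\\.[0-9]{1,9})?|1(\\.0{1,9})?)$", x))) {
    abort("factors must be decimals in [0, 1] with at most 9 decimals")
  }
  frac <- ifelse(grepl("\\.", x), sub("^[01]\\.", "", x), "")
  d <- nchar(frac)
  n <- as.numeric(paste0(sub("\\..*$", "", x), frac))  # x_i * 10^d_i
  D <- sum(d)
  big <- 1
  for (ni in n) big <- big_mul(big, ni)
  prod_digits <- big_to_digits(big)
  if (nchar(prod_digits) > D) {
    return(list(value = "0", decimals = D))  # all factors equal to 1
  }
  prod_digits <- paste0(strrep("0", D - nchar(prod_digits)), prod_digits)
  p <- as.integer(strsplit(prod_digits, "")[[1]])
  if (all(p == 0L)) return(list(value = "1", decimals = D))
  # 10^D - P = ((10^D - 1) - P) + 1, computed digit-wise
  res <- 9L - p
  i <- D
  repeat {
    res[i] <- res[i] + 1L
    if (res[i] < 10L) break
    res[i] <- 0L
    i <- i - 1L
  }
  list(value = paste0("0.", paste(res, collapse = "")), decimals = D)
}
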