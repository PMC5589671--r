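#' Monte-Carlo exact tests of Hardy-Weinberg and linkage equilibrium
#'
#' `hwe_exact_test()` runs the Monte-Carlo version of the exact
#' Hardy-Weinberg test (Guo-Thompson style): the `2n` observed allele
#' copies are repeatedly shuffled into random pairs, and each arrangement
#' is scored by the conditional probability of its genotype array given the
#' allele counts (Levene's distribution).  The p-value is the fraction of
#' shuffles no more probable than the observed arrangement, with the
#' standard `(b + 1) / (m + 1)` correction so it is never exactly zero.
#'
#' `ld_exact_test()` tests genotypic independence of two loci by permuting
#' one locus' genotypes across individuals; the statistic is the
#' log-likelihood ratio (G) of the two-locus genotype contingency table
#' (the choice made by the Genepop program), with Pearson's chi-squared as
#' an option.  `bonferroni()` returns the corrected significance level
#' `alpha / k`.
#'
#' Both tests require an explicit seed and record it, together with the
#' number of permutations, in the returned result, so any reported p-value
#' can be regenerated exactly.
#'
#' @param gt a [genotype_table()].
#' @param locus,locus_a,locus_b autosomal locus names.
#' @param n_perm number of Monte-Carlo shuffles (at least 1000 recommended;
#'   the default gives p-value granularity 1e-5).
#' @param seed integer RNG seed (mandatory).
#' @param alpha raw significance level for the recorded decision.
#' @param n_tests Bonferroni denominator for the corrected decision.
#' @param statistic LD statistic: `"g"` (log-likelihood ratio) or
#'   `"chisq"`.
#' @return An object of class `str_test` with fields `method`, `loci`,
#'   `p_value`, `statistic_obs`, `n_perm`, `seed`, `alpha`,
#'   `alpha_corrected`, `reject_raw`, `reject_corrected`, `applicable`.
#'   Monomorphic loci yield an explicit not-applicable result
#'   (`applicable = FALSE`, `p_value = NA`).
#' @examples
#' gt <- simulate_hwe_population(sim_config(seed = 1, n_individuals = 50))
#' hwe_exact_test(gt, "TPOX", n_perm = 2000, seed = 7)
#' @export
hwe_exact_test <- function(gt, locus, n_perm = 1e5, seed,
                           alpha = 0.05, n_tests = 1) {
  if (missing(seed)) abort("seed is mandatory")
  if (n_perm < 1) abort("n_perm must be >= 1")
  m <- gt$autosomal[[locus]]
  if (is.null(m)) abort("not an autosomal locus: ", locus)
  ok <- !is.na(m[, 1])
  a1 <- m[ok, 1]; a2 <- m[ok, 2]
  levels <- sort_allele_labels(unique(c(a1, a2)))
  k <- length(levels)
  if (k < 2) {
    return(str_test("hwe_exact", locus, NA_real_, NA_real_, n_perm, seed,
                    alpha, alpha / n_tests, applicable = FALSE))
  }
  c1 <- match(a1, levels); c2 <- match(a2, levels)
  n <- length(c1)
  lg <- lgamma(seq_len(n + 1))          # lg[v + 1] = lgamma(v + 1), v >= 0
  log2c <- log(2)
  stat <- function(x1, x2) {
    # log conditional probability up to an arrangement-invariant constant:
    # h * log 2 - sum(log n_g!) over genotype counts n_g
    lo <- pmin(x1, x2); hi <- pmax(x1, x2)
    tab <- tabulate((lo - 1L) * k + hi, k * k)
    sum(x1 != x2) * log2c - sum(lg[tab[tab > 0L] + 1L])
  }
  t_obs <- stat(c1, c2)
  pool <- sort(c(c1, c2))   # canonical order: p-value invariant to row order
  odd <- seq(1L, 2L * n, by = 2L)
  set.seed(seed)
  b <- 0L
  for (i in seq_len(n_perm)) {
    v <- pool[sample.int(2L * n)]
    if (stat(v[odd], v[odd + 1L]) <= t_obs + 1e-9) b <- b + 1L
  }
  p <- (b + 1) / (n_perm + 1)
  str_test("hwe_exact", locus, p, t_obs, n_perm, seed, alpha,
           alpha / n_tests)
}

#' @rdname hwe_exact_test
#' @export
ld_exact_test <- function(gt, locus_a, locus_b, n_perm = 1e5, seed,
                          statistic = c("g", "chisq"),
                          alpha = 0.05, n_tests = 1) {
  if (missing(seed)) abort("seed is mandatory")
  if (n_perm < 1) abort("n_perm must be >= 1")
  statistic <- match.arg(statistic)
  ma <- gt$autosomal[[locus_a]]; mb <- gt$autosomal[[locus_b]]
  if (is.null(ma) || is.null(mb)) abort("both loci must be autosomal")
  ok <- !is.na(ma[, 1]) & !is.na(mb[, 1])
  if (sum(ok) < 2) abort("need >= 2 individuals typed at both loci")
  ga <- factor(paste(ma[ok, 1], ma[ok, 2], sep = "/"))
  gb <- factor(paste(mb[ok, 1], mb[ok, 2], sep = "/"))
  ka <- nlevels(ga); kb <- nlevels(gb)
  loci <- paste(locus_a, locus_b, sep = ":")
  if (ka < 2 || kb < 2) {
    return(str_test(paste0("ld_", statistic), loci, NA_real_, NA_real_,
                    n_perm, seed, alpha, alpha / n_tests,
                    applicable = FALSE))
  }
  ia <- as.integer(ga); ib <- as.integer(gb)
  ord <- order(ia, ib)      # canonical order: p-value invariant to row order
  ia <- ia[ord]; ib <- ib[ord]
  n <- length(ia)
  rowt <- tabulate(ia, ka); colt <- tabulate(ib, kb)
  if (statistic == "g") {
    # G = 2 * (sum O ln O - sum R ln R - sum C ln C + n ln n); the margins
    # are permutation-invariant, so only sum O ln O varies
    xlx <- function(v) { v <- v[v > 0]; sum(v * log(v)) }
    const <- -xlx(rowt) - xlx(colt) + n * log(n)
    score <- function(jb) xlx(tabulate((ia - 1L) * kb + jb, ka * kb))
  } else {
    e <- as.vector(outer(rowt, colt)) / n   # expected counts, invariant
    score <- function(jb) {
      o <- tabulate((ia - 1L) * kb + jb, ka * kb)
      sum((o - e)^2 / e)
    }
    const <- 0
  }
  s_obs <- score(ib)
  set.seed(seed)
  b <- 0L
  for (i in seq_len(n_perm)) {
    if (score(ib[sample.int(n)]) >= s_obs - 1e-9) b <- b + 1L
  }
  p <- (b + 1) / (n_perm + 1)
  stat_obs <- if (statistic == "g") 2 * (s_obs + const) else s_obs
  str_test(paste0("ld_", statistic), loci, p, stat_obs, n_perm, seed,
           alpha, alpha / n_tests)
}

#' @rdname hwe_exact_test
#' @param k number of tests in the family.
#' @export
bonferroni <- function(alpha, k) {
  if (k < 1) abort("k must be >= 1")
  alpha / k
}

str_test <- function(method, loci, p, stat, n_perm, seed, alpha,
                     alpha_corrected, applicable = TRUE) {
  structure(list(method = method, loci = loci, p_value = p,
                 statistic_obs = stat, n_perm = n_perm, seed = seed,
                 alpha = alpha, alpha_corrected = alpha_corrected,
                 reject_raw = if (applicable) p < alpha else NA,
                 reject_corrected = if (applicable) p < alpha_corrected else NA,
                 applicable = applicable),
            class = "str_test")
}

#' @export
print.str_test <- function(x, ...) {
  if (!x$applicable) {
    cat(sprintf("<%s> %s: not applicable (monomorphic locus)\n",
                x$method, x$loci))
    return(invisible(x))
  }
  cat(sprintf("<%s> %s: p = %.4g (%d permutations, seed %d)\n",
              x$method, x$loci, x$p_value, x$n_perm, x$seed))
  invisible(x)
}

#' Equilibrium test batteries over a genotype table
#'
#' `hwe_test_all()` applies [hwe_exact_test()] to every autosomal locus;
#' `ld_test_matrix()` applies [ld_exact_test()] to every locus pair and
#' returns the lower-triangular p-value matrix that mirrors the standard
#' pairwise-LD report.  Seeds for the individual tests are drawn
#' reproducibly from `seed`.
#'
#' @inheritParams hwe_exact_test
#' @param loci autosomal loci to test (default all).
#' @return `hwe_test_all()`: data frame (locus, p_value, n_perm, seed);
#'   `ld_test_matrix()`: list with `p_matrix` (lower triangle filled) and
#'   `tests` (data frame of pairs).
#' @export
hwe_test_all <- function(gt, loci = autosomal_loci(gt), n_perm = 1e4,
                         seed, alpha = 0.05) {
  if (missing(seed)) abort("seed is mandatory")
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, length(loci))
  rows <- Map(function(l, s) {
    r <- hwe_exact_test(gt, l, n_perm = n_perm, seed = s, alpha = alpha,
                        n_tests = length(loci))
    data.frame(locus = l, p_value = r$p_value, n_perm = n_perm, seed = s,
               stringsAsFactors = FALSE)
  }, loci, seeds)
  do.call(rbind, rows)
}

#' @rdname hwe_test_all
#' @export
ld_test_matrix <- function(gt, loci = autosomal_loci(gt), n_perm = 1e4,
                           seed, alpha = 0.05, statistic = "g") {
  if (missing(seed)) abort("seed is mandatory")
  k <- length(loci)
  if (k < 2) abort("need at least two loci")
  set.seed(seed)
  pm <- matrix(NA_real_, k, k, dimnames = list(loci, loci))
  rows <- list()
  for (i in seq_len(k - 1)) {
    for (j in seq((i + 1), k)) {
      s <- sample.int(.Machine$integer.max, 1)
      r <- ld_exact_test(gt, loci[i], loci[j], n_perm = n_perm, seed = s,
                         statistic = statistic, alpha = alpha,
                         n_tests = length(loci))
      pm[j, i] <- r$p_value
      rows[[length(rows) + 1]] <-
        data.frame(locus_a = loci[i], locus_b = loci[j],
                   p_value = r$p_value, seed = s, stringsAsFactors = FALSE)
    }
  }
  list(p_matrix = pm, tests = do.call(rbind, rows))
}
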