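#' Labelled distance matrices
#'
#' A thin wrapper for the symmetric, zero-diagonal, labelled matrices that
#' feed the ordination and tree stages.  Negative differentiation
#' estimates (small true divergence) are clamped to zero for distance use,
#' with the raw estimates retained in the `"raw"` attribute.
#'
#' @param m symmetric numeric matrix with dimnames.
#' @param metric identifier of the distance/differentiation measure.
#' @param raw optional unclamped estimate matrix.
#' @return matrix of class `dist_matrix` with attributes `metric`, `raw`.
#' @export
dist_matrix <- function(m, metric = "distance", raw = NULL) {
  m <- as.matrix(m)
  if (is.null(rownames(m))) abort("distance matrix needs labels")
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-12) {
    abort("matrix must be square and symmetric")
  }
  diag(m) <- 0
  structure(m, metric = metric, raw = raw %||% m,
            class = c("dist_matrix", "matrix", "array"))
}

# per-locus Weir-Cockerham variance components for r populations.
# p: r x k matrix of allele frequencies; nvec: individuals per population;
# het: r x k matrix of observed heterozygote proportions per allele, or
# NULL for the Hardy-Weinberg approximation 2 p (1 - p) (frequency-only
# published tables).
wc_components <- function(p, nvec, het = NULL) {
  r <- nrow(p)
  if (is.null(het)) het <- 2 * p * (1 - p)
  nbar <- mean(nvec)
  nc <- (r * nbar - sum(nvec^2) / (r * nbar)) / (r - 1)
  a <- b <- cc <- 0
  for (k in seq_len(ncol(p))) {
    pk <- p[, k]
    pbar <- sum(nvec * pk) / (r * nbar)
    s2 <- sum(nvec * (pk - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(nvec * het[, k]) / (r * nbar)
    a <- a + (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- b + (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- cc + hbar / 2
  }
  c(a = a, b = b, c = cc)
}

# frequencies and per-allele heterozygote proportions at one locus
locus_geno_summary <- function(gt, locus, alleles) {
  m <- gt$autosomal[[locus]]
  if (is.null(m)) abort("not an autosomal locus: ", locus)
  ok <- !is.na(m[, 1])
  m <- m[ok, , drop = FALSE]
  n <- nrow(m)
  cnt <- tabulate(match(c(m[, 1], m[, 2]), alleles), length(alleles))
  hetc <- vapply(seq_along(alleles), function(j) {
    a <- alleles[j]
    sum((m[, 1] == a) != (m[, 2] == a))
  }, numeric(1))
  list(n = n, p = cnt / (2 * n), het = hetc / n)
}

#' Weir-Cockerham Fst
#'
#' Estimates the fixation index theta of Weir & Cockerham (1984) across
#' two or more populations.  With raw genotypes the heterozygosity term is
#' exact; with frequency-only populations (published tables) it is
#' approximated by its Hardy-Weinberg expectation and the result is
#' flagged (`mode = "frequencies"`).  The multi-locus estimate is the
#' ratio of summed variance components across loci.
#'
#' @param pops named list of populations: either [genotype_table()]s (exact
#'   mode) or [allele_freqs()] tables accompanied by `n` (frequency mode).
#' @param loci loci to use (default: loci shared by all populations).
#' @param n for frequency mode, named (or scalar) individuals per
#'   population.
#' @return `wc_theta()`: list with `theta` (multi-locus), `by_locus`,
#'   `mode`; `pairwise_fst()`: a [dist_matrix()] of pairwise theta (raw
#'   estimates kept in `attr(, "raw")`).
#' @export
wc_theta <- function(pops, loci = NULL, n = NULL) {
  if (length(pops) < 2) abort("need at least two populations")
  geno_mode <- inherits(pops[[1]], "genotype_table")
  if (geno_mode) {
    loci <- loci %||% Reduce(intersect, lapply(pops, autosomal_loci))
  } else {
    loci <- loci %||% Reduce(intersect, lapply(pops, function(p) unique(p$locus)))
    if (is.null(n)) abort("frequency mode needs per-population sample sizes n")
    if (length(n) == 1) n <- stats::setNames(rep(n, length(pops)), names(pops))
  }
  if (!length(loci)) abort("no shared loci")
  comp <- matrix(0, length(loci), 3, dimnames = list(loci, c("a", "b", "c")))
  for (l in loci) {
    if (geno_mode) {
      alleles <- sort_allele_labels(unique(unlist(lapply(pops, function(g) {
        m <- g$autosomal[[l]]
        m[!is.na(m)]
      }))))
      summ <- lapply(pops, locus_geno_summary, locus = l, alleles = alleles)
      p <- do.call(rbind, lapply(summ, `[[`, "p"))
      het <- do.call(rbind, lapply(summ, `[[`, "het"))
      nvec <- vapply(summ, `[[`, numeric(1), "n")
      comp[l, ] <- wc_components(p, nvec, het)
    } else {
      alleles <- sort_allele_labels(unique(unlist(
        lapply(pops, function(af) af$allele[af$locus == l]))))
      p <- do.call(rbind, lapply(pops, function(af) {
        f <- locus_frequencies(af, l)
        out <- stats::setNames(numeric(length(alleles)), alleles)
        out[names(f)] <- f
        out
      }))
      comp[l, ] <- wc_components(p, as.numeric(n[names(pops)]))
    }
  }
  tot <- colSums(comp)
  denom <- sum(tot)
  list(theta = if (denom > 0) tot[["a"]] / denom else 0,
       by_locus = comp[, "a"] / rowSums(comp),
       components = comp,
       mode = if (geno_mode) "genotypes" else "frequencies")
}

#' @rdname wc_theta
#' @export
pairwise_fst <- function(pops, loci = NULL, n = NULL) {
  labs <- names(pops)
  if (is.null(labs)) abort("populations must be named")
  k <- length(labs)
  raw <- matrix(0, k, k, dimnames = list(labs, labs))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      th <- wc_theta(pops[c(i, j)], loci = loci,
                     n = if (is.null(n)) NULL else n[c(i, j)])$theta
      raw[i, j] <- raw[j, i] <- th
    }
  }
  dist_matrix(pmax(raw, 0), metric = "fst", raw = raw)
}

#' Permutation p-value for pairwise Fst
#'
#' Permutes individuals between two populations and recomputes the
#' multi-locus Weir-Cockerham theta; the p-value is
#' `(#\{theta_perm >= theta_obs\} + 1) / (n_perm + 1)`.
#'
#' @param gt_a,gt_b [genotype_table()]s of the two populations.
#' @inheritParams hwe_exact_test
#' @param loci autosomal loci (default shared).
#' @return an object of class `str_test` (see [hwe_exact_test()]) with the
#'   observed theta in `statistic_obs`.
#' @export
fst_permutation_test <- function(gt_a, gt_b, loci = NULL, n_perm = 1000,
                                 seed, alpha = 0.05, n_tests = 1) {
  if (missing(seed)) abort("seed is mandatory")
  if (n_perm < 1) abort("n_perm must be >= 1")
  loci <- loci %||% intersect(autosomal_loci(gt_a), autosomal_loci(gt_b))
  na <- n_samples(gt_a); nb <- n_samples(gt_b)
  # pooled integer-coded genotypes per locus
  pool <- lapply(loci, function(l) {
    mm <- rbind(gt_a$autosomal[[l]], gt_b$autosomal[[l]])
    alleles <- sort_allele_labels(unique(mm[!is.na(mm)]))
    cbind(match(mm[, 1], alleles), match(mm[, 2], alleles))
  })
  names(pool) <- loci
  nalle <- vapply(pool, function(m) max(m, na.rm = TRUE), numeric(1))
  theta_for <- function(in_a) {
    comp <- c(0, 0, 0)
    for (l in loci) {
      m <- pool[[l]]
      k <- nalle[[l]]
      p <- matrix(0, 2, k); het <- matrix(0, 2, k); nvec <- numeric(2)
      for (g in 1:2) {
        rows <- if (g == 1) which(in_a) else which(!in_a)
        sub <- m[rows, , drop = FALSE]
        sub <- sub[!is.na(sub[, 1]), , drop = FALSE]
        nvec[g] <- nrow(sub)
        cnt <- tabulate(c(sub[, 1], sub[, 2]), k)
        p[g, ] <- cnt / (2 * nrow(sub))
        ishet <- sub[, 1] != sub[, 2]
        for (a in unique(c(sub[ishet, 1], sub[ishet, 2]))) {
          het[g, a] <- sum(ishet & (sub[, 1] == a | sub[, 2] == a)) / nrow(sub)
        }
      }
      comp <- comp + wc_components(p, nvec, het)
    }
    if (sum(comp) > 0) comp[1] / sum(comp) else 0
  }
  obs_assign <- rep(c(TRUE, FALSE), c(na, nb))
  t_obs <- theta_for(obs_assign)
  set.seed(seed)
  b <- 0L
  for (i in seq_len(n_perm)) {
    if (theta_for(sample(obs_assign)) >= t_obs - 1e-12) b <- b + 1L
  }
  str_test("fst_permutation", paste(na, "vs", nb), (b + 1) / (n_perm + 1),
           t_obs, n_perm, seed, alpha, alpha / n_tests)
}

#' AMOVA-style Rst from Y-STR repeat scores
#'
#' Rst is the fixation index on microsatellite repeat counts: an analysis
#' of molecular variance with squared repeat-count differences as the
#' molecular distance, summed over single-copy loci.  Multi-copy loci
#' (DYS385a,b) carry no single repeat difference and are excluded.
#'
#' @param haps_by_pop named list of per-population numeric matrices
#'   (males x loci of repeat scores; use [repeat_matrix()] to build one
#'   from a genotype table).
#' @return `rst_amova()`: list with `rst` and the variance components
#'   `sigma2_among` / `sigma2_within`; `pairwise_rst()`: a
#'   [dist_matrix()] of two-population Rst values.
#' @export
rst_amova <- function(haps_by_pop) {
  r <- length(haps_by_pop)
  if (r < 2) abort("need at least two populations")
  X <- do.call(rbind, haps_by_pop)
  nvec <- vapply(haps_by_pop, nrow, numeric(1))
  N <- sum(nvec)
  pop <- rep(seq_len(r), nvec)
  # sum_{i<j} d2 / N over a group equals the within-group sum of squares
  ssd <- function(rows) {
    sub <- X[rows, , drop = FALSE]
    sum(sweep(sub, 2, colMeans(sub))^2)
  }
  ssd_total <- ssd(seq_len(N))
  ssd_within <- sum(vapply(seq_len(r), function(g) ssd(which(pop == g)),
                           numeric(1)))
  ssd_among <- ssd_total - ssd_within
  s2w <- ssd_within / (N - r)
  nc <- (N - sum(nvec^2) / N) / (r - 1)
  s2a <- (ssd_among / (r - 1) - s2w) / nc
  denom <- s2a + s2w
  list(rst = if (denom > 0) s2a / denom else 0,
       sigma2_among = s2a, sigma2_within = s2w)
}

#' @rdname rst_amova
#' @export
pairwise_rst <- function(haps_by_pop) {
  labs <- names(haps_by_pop)
  if (is.null(labs)) abort("populations must be named")
  k <- length(labs)
  raw <- matrix(0, k, k, dimnames = list(labs, labs))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      raw[i, j] <- raw[j, i] <- rst_amova(haps_by_pop[c(i, j)])$rst
    }
  }
  dist_matrix(pmax(raw, 0), metric = "rst", raw = raw)
}

#' @rdname rst_amova
#' @param gt a [genotype_table()].
#' @param loci single-copy Y loci to keep (default: all non-pair Y loci).
#' @export
repeat_matrix <- function(gt, loci = NULL) {
  loci <- loci %||% names(Filter(Negate(is.matrix), gt$y))
  if (!length(loci)) abort("no single-copy Y loci")
  males <- which(gt$sex == "male")
  cols <- lapply(loci, function(l) {
    v <- gt$y[[l]][males]
    out <- rep(NA_real_, length(v))
    out[!is.na(v)] <- allele_repeat_score(v[!is.na(v)])
    out
  })
  m <- do.call(cbind, cols)
  dimnames(m) <- list(gt$sample_id[males], loci)
  keep <- stats::complete.cases(m)
  if (!all(keep)) {
    warning(sum(!keep), " male(s) dropped from repeat matrix (missing loci)",
            call. = FALSE)
  }
  m[keep, , drop = FALSE]
}

#' Allele-frequency genetic distances between populations
#'
#' Classical distances for tree building from allele-frequency panels,
#' computed over the shared locus set with absent alleles at frequency 0:
#'
#' * `"nei_standard"`: `D = -ln(Jxy / sqrt(Jx * Jy))` with `J`s the
#'   across-locus means of `sum(x y)`, `sum(x^2)`, `sum(y^2)`.
#' * `"reynolds"`: `D = sum_l sum_a (x - y)^2 / (2 * sum_l (1 - sum_a x y))`.
#' * `"cavalli_sforza"`: chord distance, mean over loci of
#'   `(2 / pi) * sqrt(2 * (1 - sum_a sqrt(x y)))`.
#'
#' @param panel named list of [allele_freqs()] tables.
#' @param metric one of `"nei_standard"`, `"reynolds"`, `"cavalli_sforza"`.
#' @return a [dist_matrix()].
#' @export
genetic_distance <- function(panel, metric = c("nei_standard", "reynolds",
                                               "cavalli_sforza")) {
  metric <- match.arg(metric)
  labs <- names(panel)
  if (is.null(labs) || length(labs) < 2) abort("need a named panel of >= 2 populations")
  loci <- Reduce(intersect, lapply(panel, function(p) unique(p$locus)))
  if (!length(loci)) abort("no shared loci")
  freq_mat <- function(l) {
    alleles <- sort_allele_labels(unique(unlist(
      lapply(panel, function(af) af$allele[af$locus == l]))))
    do.call(rbind, lapply(panel, function(af) {
      f <- locus_frequencies(af, l)
      out <- stats::setNames(numeric(length(alleles)), alleles)
      out[names(f)] <- f
      out
    }))
  }
  mats <- lapply(loci, freq_mat)
  k <- length(labs)
  d <- matrix(0, k, k, dimnames = list(labs, labs))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      d[i, j] <- d[j, i] <- switch(metric,
        nei_standard = {
          jxy <- mean(vapply(mats, function(m) sum(m[i, ] * m[j, ]), numeric(1)))
          jx <- mean(vapply(mats, function(m) sum(m[i, ]^2), numeric(1)))
          jy <- mean(vapply(mats, function(m) sum(m[j, ]^2), numeric(1)))
          if (jxy <= 0) abort("populations share no alleles: Nei distance infinite")
          -log(jxy / sqrt(jx * jy))
        },
        reynolds = {
          num <- sum(vapply(mats, function(m) sum((m[i, ] - m[j, ])^2), numeric(1)))
          den <- 2 * sum(vapply(mats, function(m) 1 - sum(m[i, ] * m[j, ]), numeric(1)))
          num / den
        },
        cavalli_sforza = {
          mean(vapply(mats, function(m) {
            (2 / pi) * sqrt(2 * max(0, 1 - sum(sqrt(m[i, ] * m[j, ]))))
          }, numeric(1)))
        })
    }
  }
  dist_matrix(d, metric = metric)
}
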