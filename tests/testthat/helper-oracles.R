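# Fixture builders and independent oracles used across the suite.

withr_local_tempfile <- function(ext = "", env = parent.frame()) {
  withr::local_tempfile(fileext = ext, .local_envir = env)
}

# genotype table for one autosomal locus from "a/b" strings
toy_gt <- function(cells, locus = "L1", sex = NULL) {
  n <- length(cells)
  m <- do.call(rbind, lapply(cells, function(s) {
    if (is.na(s)) c(NA_character_, NA_character_)
    else strsplit(s, "/", fixed = TRUE)[[1]]
  }))
  genotype_table(sprintf("s%02d", seq_len(n)),
                 sex %||% rep("female", n),
                 stats::setNames(list(m), locus))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Exact Hardy-Weinberg test for a biallelic locus by full enumeration of
# Levene's conditional distribution: given allele counts (n1, n2) in n
# diploids, P(n12 heterozygotes) = n! n1! n2! 2^n12 / (n11! n12! n22! (2n)!)
# and the exact p-value sums probabilities of all arrangements no more
# probable than the observed one.
hwe_exact_enum <- function(n11, n12, n22) {
  n <- n11 + n12 + n22
  n1 <- 2 * n11 + n12
  n2 <- 2 * n22 + n12
  hs <- seq(n12 %% 2, min(n1, n2), by = 2)   # feasible heterozygote counts
  logp <- vapply(hs, function(h) {
    a <- (n1 - h) / 2
    b <- (n2 - h) / 2
    lfactorial(n) + lfactorial(n1) + lfactorial(n2) + h * log(2) -
      lfactorial(a) - lfactorial(h) - lfactorial(b) - lfactorial(2 * n)
  }, numeric(1))
  p_obs <- logp[hs == n12]
  sum(exp(logp[logp <= p_obs + 1e-9]))
}

# Exhaustive permutation p-value of the two-locus G statistic for tiny n:
# enumerate all n! assignments of locus-B genotypes to individuals.
ld_exact_enum <- function(ga, gb) {
  n <- length(ga)
  xlx <- function(v) { v <- v[v > 0]; sum(v * log(v)) }
  score <- function(jb) xlx(table(ga, jb))
  perms <- gtools_permutations(n)
  s_obs <- score(gb)
  mean(apply(perms, 1, function(ix) score(gb[ix]) >= s_obs - 1e-9))
}

gtools_permutations <- function(n) {
  # all permutations of 1..n, one per row (n small)
  if (n == 1) return(matrix(1, 1, 1))
  sub <- gtools_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

# Weir-Cockerham theta for TWO populations at ONE biallelic locus, coded
# directly from the published scalar formulas on genotype counts
# (nAA, nAa, naa) per population -- an independent route from the
# package's matrix implementation.
theta_wc_biallelic <- function(cntA, cntB) {
  n_i <- c(sum(cntA), sum(cntB))
  p_i <- c((2 * cntA[1] + cntA[2]) / (2 * n_i[1]),
           (2 * cntB[1] + cntB[2]) / (2 * n_i[2]))
  h_i <- c(cntA[2] / n_i[1], cntB[2] / n_i[2])
  r <- 2
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n_i * p_i) / (r * nbar)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / (r * nbar)
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) /
                        (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  # both alleles of a biallelic locus contribute symmetric components
  2 * a / (2 * (a + b + cc))
}

# brute-force AMOVA Rst from the definition of the sums of squares over
# all individual pairs
rst_brute <- function(mats) {
  X <- do.call(rbind, mats)
  nvec <- vapply(mats, nrow, numeric(1))
  N <- sum(nvec)
  r <- length(mats)
  pop <- rep(seq_len(r), nvec)
  d2 <- as.matrix(stats::dist(X))^2
  ssd_group <- function(rows) {
    if (length(rows) < 2) return(0)
    sum(d2[rows, rows][upper.tri(d2[rows, rows])]) / length(rows)
  }
  ssd_total <- sum(d2[upper.tri(d2)]) / N
  ssd_within <- sum(vapply(seq_len(r), function(g) ssd_group(which(pop == g)),
                           numeric(1)))
  s2w <- ssd_within / (N - r)
  nc <- (N - sum(nvec^2) / N) / (r - 1)
  s2a <- ((ssd_total - ssd_within) / (r - 1) - s2w) / nc
  s2a / (s2a + s2w)
}

# Nei standard genetic distance recoded directly from the literature
# formula (arithmetic means of gene identities across loci)
nei_D_oracle <- function(freqA, freqB) {
  loci <- intersect(unique(freqA$locus), unique(freqB$locus))
  jxy <- jx <- jy <- numeric(0)
  for (l in loci) {
    a <- freqA[freqA$locus == l, ]
    b <- freqB[freqB$locus == l, ]
    alleles <- union(a$allele, b$allele)
    x <- stats::setNames(rep(0, length(alleles)), alleles)
    y <- x
    x[a$allele] <- a$frequency
    y[b$allele] <- b$frequency
    jxy <- c(jxy, sum(x * y))
    jx <- c(jx, sum(x^2))
    jy <- c(jy, sum(y^2))
  }
  -log(mean(jxy) / sqrt(mean(jx) * mean(jy)))
}

# least-squares superimposition residual (rotation + reflection +
# translation), for comparing MDS embeddings with generating coordinates
procrustes_error <- function(X, Y) {
  X <- scale(X, scale = FALSE)
  Y <- scale(Y, scale = FALSE)
  s <- svd(crossprod(Y, X))
  R <- s$u %*% t(s$v)
  sqrt(sum((Y %*% R - X)^2))
}

# population frequency panel over one synthetic locus, one population per
# row of X (rows normalised to the simplex)
panel_from_matrix <- function(X) {
  labs <- rownames(X) %||% paste0("pop", seq_len(nrow(X)))
  lapply(stats::setNames(labs, labs), function(lab) {
    i <- match(lab, labs)
    p <- abs(X[i, ]) / sum(abs(X[i, ]))
    allele_freqs(data.frame(locus = "L1",
                            allele = as.character(seq_along(p) + 5),
                            frequency = p), 1000)
  })
}

# random allele-frequency table over random loci (for round-trip and
# distance properties)
random_freq_table <- function(n_loci = 3, seed = NULL, n_genes = 200) {
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(seq_len(n_loci), function(i) {
    k <- sample(2:6, 1)
    cnt <- as.numeric(stats::rmultinom(1, n_genes, rep(1, k)))
    while (any(cnt == 0)) cnt <- as.numeric(stats::rmultinom(1, n_genes, rep(1, k)))
    data.frame(locus = paste0("L", i),
               allele = as.character(sample(5:40, k)),
               count = cnt, stringsAsFactors = FALSE)
  })
  allele_freqs(do.call(rbind, rows), n_genes)
}
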