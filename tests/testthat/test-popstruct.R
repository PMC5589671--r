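two_pop_gt <- function(cntA, cntB) {
  # biallelic genotype tables from genotype counts (nAA, nAB, nBB)
  mk <- function(cnt, tag) {
    cells <- c(rep("8/8", cnt[1]), rep("8/9", cnt[2]), rep("9/9", cnt[3]))
    toy_gt(cells, locus = "L1")
  }
  list(a = mk(cntA), b = mk(cntB))
}

test_that("theta is essentially zero for identical populations", {
  af <- random_freq_table(3, seed = 2, n_genes = 20000)
  th <- wc_theta(list(a = af, b = af), n = c(a = 10000, b = 10000))
  expect_lt(abs(th$theta), 1e-3)    # O(1/n) estimator noise only
  expect_equal(th$mode, "frequencies")
  pf <- pairwise_fst(list(a = af, b = af), n = c(a = 10000, b = 10000))
  expect_equal(unname(pf["a", "b"]), 0)   # negatives clamped for distance use
  expect_lt(attr(pf, "raw")["a", "b"], 0)
})

test_that("theta approaches one for fixed alternative alleles", {
  fa <- allele_freqs(data.frame(locus = "L1", allele = c("8", "9"),
                                frequency = c(1, 0)), 200)
  fb <- allele_freqs(data.frame(locus = "L1", allele = c("8", "9"),
                                frequency = c(0, 1)), 200)
  th <- wc_theta(list(a = fa, b = fb), n = c(a = 100, b = 100))
  expect_gt(th$theta, 0.98)
})

test_that("genotype-mode theta matches an independently coded biallelic formula", {
  set.seed(33)
  for (i in 1:100) {
    cntA <- c(sample(2:30, 1), sample(2:30, 1), sample(2:30, 1))
    cntB <- c(sample(2:30, 1), sample(2:30, 1), sample(2:30, 1))
    pops <- two_pop_gt(cntA, cntB)
    got <- wc_theta(pops)$theta
    want <- theta_wc_biallelic(cntA, cntB)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("theta is invariant to population order; a twin is at distance zero", {
  pan <- simulate_panel(sim_config(seed = 41, fst_true = 0.1, n_pops = 2,
                                   n_per_pop = 60))
  g <- pan$genotypes
  expect_equal(wc_theta(list(a = g[[1]], b = g[[2]]))$theta,
               wc_theta(list(b = g[[2]], a = g[[1]]))$theta)
  trio <- list(p1 = g[[1]], p2 = g[[2]], twin = g[[2]])
  pf <- pairwise_fst(trio)
  expect_equal(unname(pf["p2", "twin"]), 0)
})

test_that("frequency-mode theta tracks genotype-mode theta", {
  pan <- simulate_panel(sim_config(seed = 43, fst_true = 0.05, n_pops = 2,
                                   n_per_pop = 200))
  th_g <- wc_theta(pan$genotypes)$theta
  freqs <- lapply(pan$genotypes, allele_frequencies)
  th_f <- wc_theta(freqs, n = c(pop1 = 200, pop2 = 200))$theta
  expect_lt(abs(th_g - th_f), 0.01)
})

test_that("Fst permutation test has power against real differentiation", {
  hits <- 0
  reps <- 10
  for (i in seq_len(reps)) {
    pan <- simulate_panel(sim_config(seed = 100 + i, fst_true = 0.05,
                                     n_pops = 2, n_per_pop = 100))
    r <- fst_permutation_test(pan$genotypes[[1]], pan$genotypes[[2]],
                              loci = c("TPOX", "TH01", "vWA", "FGA", "D18S51"),
                              n_perm = 399, seed = i)
    if (r$p_value <= 0.01) hits <- hits + 1
  }
  expect_gte(hits, reps - 1)
})

test_that("Fst permutation test is valid under the null", {
  rej <- 0
  reps <- 60
  for (i in seq_len(reps)) {
    pan <- simulate_panel(sim_config(seed = 300 + i, fst_true = 0,
                                     n_pops = 2, n_per_pop = 40))
    r <- fst_permutation_test(pan$genotypes[[1]], pan$genotypes[[2]],
                              loci = c("TPOX", "TH01"), n_perm = 99,
                              seed = i)
    if (r$p_value <= 0.05) rej <- rej + 1
  }
  # binomial 99.9% upper bound around 0.05 for 60 draws
  expect_lte(rej, 10)
  expect_error(fst_permutation_test(pan$genotypes[[1]], pan$genotypes[[2]],
                                    n_perm = 0, seed = 1), "n_perm")
})

test_that("Rst is zero for identical sets and one for disjoint fixed sets", {
  m <- matrix(c(14, 15, 14, 15, 16, 14), ncol = 2)
  pr <- pairwise_rst(list(a = m, b = m))
  expect_equal(unname(pr["a", "b"]), 0)
  fixed_a <- matrix(14, 5, 3)
  fixed_b <- matrix(17, 5, 3)
  rr <- rst_amova(list(a = fixed_a, b = fixed_b))
  expect_equal(rr$rst, 1)
  expect_equal(rr$sigma2_within, 0)
})

test_that("Rst equals the brute-force AMOVA on small instances", {
  set.seed(51)
  for (i in 1:20) {
    mats <- lapply(1:3, function(g) {
      matrix(sample(10:16, 6 * 2, TRUE), ncol = 2)
    })
    names(mats) <- paste0("p", 1:3)
    expect_equal(rst_amova(mats)$rst, rst_brute(mats), tolerance = 1e-10)
  }
})

test_that("Rst reduces to a frequency-based variance ratio for unit-step biallelic loci", {
  set.seed(52)
  mats <- lapply(1:2, function(g) {
    matrix(sample(c(10, 11), 30, TRUE, prob = c(0.3 + 0.3 * (g == 1), 0.7 - 0.3 * (g == 1))),
           ncol = 1)
  })
  names(mats) <- c("a", "b")
  got <- rst_amova(mats)$rst
  # haploid one-locus AMOVA written out with allele-frequency algebra:
  # within-group SS = n_g p_g (1 - p_g), total SS = N pbar (1 - pbar)
  nvec <- vapply(mats, nrow, numeric(1)); N <- sum(nvec); r <- 2
  pg <- vapply(mats, function(m) mean(m == 11), numeric(1))
  pbar <- sum(nvec * pg) / N
  ssw <- sum(nvec * pg * (1 - pg))
  sst <- N * pbar * (1 - pbar)
  s2w <- ssw / (N - r)
  nc <- (N - sum(nvec^2) / N) / (r - 1)
  s2a <- ((sst - ssw) / (r - 1) - s2w) / nc
  expect_equal(got, s2a / (s2a + s2w), tolerance = 1e-12)
})

test_that("repeat matrices exclude pair loci and keep numeric scores", {
  gt <- simulate_y_haplotypes(sim_config(seed = 16, n_males = 20,
                                         y_freqs = shaanxi_y_frequencies()))
  rm1 <- repeat_matrix(gt)
  expect_false("DYS385ab" %in% colnames(rm1))
  expect_true(is.numeric(rm1))
  expect_equal(ncol(rm1), 8)
})

test_that("genetic distances vanish for identical populations and match the oracle", {
  af <- random_freq_table(4, seed = 6)
  for (metric in c("nei_standard", "reynolds", "cavalli_sforza")) {
    d <- genetic_distance(list(a = af, b = af), metric)
    expect_equal(unname(d["a", "b"]), 0, tolerance = 1e-12)
  }
  set.seed(61)
  for (i in 1:20) {
    fa <- random_freq_table(3, seed = 100 + i)
    # second population over the same allele sets, different counts
    fb_df <- as.data.frame(fa)[c("locus", "allele")]
    fb_df$count <- unlist(lapply(split(fb_df$allele, fb_df$locus), function(a) {
      cnt <- as.numeric(stats::rmultinom(1, 200, rep(1, length(a))))
      cnt + (cnt == 0)   # keep every allele present
    }), use.names = FALSE)
    ng <- tapply(fb_df$count, fb_df$locus, sum)
    fb <- allele_freqs(fb_df, stats::setNames(as.numeric(ng), names(ng)))
    d <- genetic_distance(list(a = fa, b = fb), "nei_standard")
    expect_equal(unname(d["a", "b"]), nei_D_oracle(fa, fb), tolerance = 1e-10)
  }
})

test_that("disjoint allele sets make the Nei distance infinite, an error", {
  fa <- allele_freqs(data.frame(locus = "L1", allele = "8", frequency = 1), 100)
  fb <- allele_freqs(data.frame(locus = "L1", allele = "9", frequency = 1), 100)
  expect_error(genetic_distance(list(a = fa, b = fb), "nei_standard"),
               "infinite")
})
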