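# Published per-locus values used here were verified against the bundled
# summary tables (forensic_params.csv ships the same rows).

test_that("observed heterozygosity is the heterozygote fraction", {
  gt <- toy_gt(c("8/9", "8/8", "8/9", "9/9"))
  expect_equal(observed_heterozygosity(gt, "L1"), 0.5)
  expect_equal(observed_heterozygosity(toy_gt(c("8/8", "9/9")), "L1"), 0)
  expect_equal(observed_heterozygosity(toy_gt(c("8/9", "7/9")), "L1"), 1)
  # 130 heterozygotes among 214 individuals
  cells <- c(rep("8/9", 130), rep("8/8", 84))
  expect_equal(round_half_up(observed_heterozygosity(toy_gt(cells), "L1"), 4),
               0.6075)
})

test_that("expected heterozygosity uses the individuals-based correction", {
  tpox <- c(223, 51, 10, 135, 9) / 428
  expect_equal(round_half_up(expected_heterozygosity(tpox, 214), 4), 0.6167)
  d3 <- c(20, 143, 139, 95, 26, 4, 1) / 428
  expect_equal(round_half_up(expected_heterozygosity(d3, 214), 4), 0.7311)
  expect_equal(expected_heterozygosity(1, 10), 0)
  # alternative conventions remain available
  expect_equal(expected_heterozygosity(c(.5, .5), 10, "none"), 0.5)
  expect_equal(expected_heterozygosity(c(.5, .5), 10, "genes"), 0.5 * 20 / 19)
})

test_that("PIC follows the Botstein formula", {
  d3 <- c(20, 143, 139, 95, 26, 4, 1) / 428
  expect_equal(round_half_up(pic(d3), 4), 0.6795)
  tpox <- c(223, 51, 10, 135, 9) / 428
  expect_equal(round_half_up(pic(tpox), 4), 0.5485)
  expect_equal(pic(1), 0)
})

test_that("matching probability sums squared observed genotype frequencies", {
  expect_equal(match_probability(toy_gt(rep("8/9", 5)), "L1"), 1)
  expect_equal(power_of_discrimination(toy_gt(rep("8/9", 5)), "L1"), 0)
  # genotype counts (2, 1, 1) over 4 individuals: (4 + 1 + 1) / 16
  gt <- toy_gt(c("8/9", "8/9", "8/8", "9/9"))
  expect_equal(match_probability(gt, "L1"), 0.375)
  expect_equal(power_of_discrimination(gt, "L1"), 0.625)
})

test_that("expected-genotype matching probability matches the HWE formula", {
  gt <- toy_gt(c("8/9", "8/9", "8/8", "9/12", "12/12", "8/12"))
  af <- allele_frequencies(gt, "L1")
  p <- stats::setNames(af$frequency, af$allele)
  hom <- sum(p^2 * p^2)
  het <- sum((2 * outer(p, p))[upper.tri(outer(p, p))]^2)
  expect_equal(match_probability(gt, "L1", expected = TRUE), hom + het)
})

test_that("PE and TPI follow from observed heterozygosity", {
  expect_equal(round_half_up(power_of_exclusion(180 / 214), 4), 0.6774)
  expect_equal(round_half_up(typical_paternity_index(180 / 214), 4), 3.1471)
  expect_equal(round_half_up(power_of_exclusion(130 / 214), 4), 0.2999)
  expect_equal(round_half_up(typical_paternity_index(130 / 214), 4), 1.2738)
  expect_equal(power_of_exclusion(0), 0)
  expect_equal(typical_paternity_index(0), 0.5)
  expect_error(typical_paternity_index(1), "undefined")
})

test_that("combined powers collapse to the locus value for one locus", {
  cp <- combined_powers(mp = 0.1284, pe = 0.5058)
  expect_equal(cp$combined_pd_num, 1 - 0.1284)
  expect_equal(cp$combined_pe_num, 0.5058)
  expect_equal(cp$combined_pd, "0.8716")
  expect_equal(cp$combined_pe, "0.5058")
})

test_that("combined powers are monotone as loci are added", {
  fp <- shaanxi_forensic_params()
  pd <- pe <- -Inf
  for (k in seq_len(nrow(fp))) {
    cp <- combined_powers(fp$MP[1:k], fp$PE[1:k])
    expect_gte(cp$combined_pd_num, pd)
    expect_gte(cp$combined_pe_num, pe)
    pd <- cp$combined_pd_num
    pe <- cp$combined_pe_num
  }
})

test_that("exact decimal strings agree with float arithmetic when representable", {
  cp <- combined_powers(mp = c(0.25, 0.5), pe = c(0.5, 0.5))
  expect_equal(as.numeric(cp$combined_pd), 1 - 0.125)
  expect_equal(as.numeric(cp$combined_pe), 0.75)
})

test_that("PIC is bounded by the uncorrected gene diversity", {
  set.seed(3)
  for (i in 1:50) {
    k <- sample(2:12, 1)
    p <- stats::rgamma(k, 1)
    p <- p / sum(p)
    s2 <- sum(p^2)
    expect_gte(pic(p), 0)
    expect_lte(pic(p), 1 - s2 + 1e-12)
  }
})

test_that("Ho and MP approach their HWE limits in large samples", {
  af <- shaanxi_autosomal_frequencies()
  tp <- af[af$locus == "TPOX", c("locus", "allele", "frequency")]
  p <- stats::setNames(tp$frequency, tp$allele)
  n <- 1e4
  gt <- simulate_hwe_population(
    sim_config(seed = 31, n_individuals = n, n_males = n / 2,
               freqs = allele_freqs(tp, 428)))
  he0 <- 1 - sum(p^2)
  ho <- observed_heterozygosity(gt, "TPOX")
  expect_lt(abs(ho - he0), 3 * sqrt(he0 * (1 - he0) / n))
  g <- outer(p, p)
  mp0 <- sum(diag(g)^2) + sum((2 * g[upper.tri(g)])^2)
  mp <- match_probability(gt, "TPOX")
  # MP is a smooth function of genotype proportions; bound via simulation SE
  expect_lt(abs(mp - mp0), 0.01)
})

test_that("forensic_params assembles consistent rows from genotypes", {
  gt <- simulate_hwe_population(sim_config(seed = 5, n_individuals = 80,
                                           n_males = 40))
  fp <- forensic_params(gt, loci = c("TPOX", "TH01", "vWA"))
  expect_equal(fp$PD, 1 - fp$MP)
  expect_true(all(fp$PE <= fp$Ho + 1e-12))
  expect_true(all(fp$TPI >= 0.5))
  expect_equal(fp$TPI, 1 / (2 * (1 - fp$Ho)))
})
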