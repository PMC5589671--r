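test_that("PCA flags a fully degenerate panel", {
  af <- random_freq_table(2, seed = 1)
  res <- pca_frequencies(list(a = af, b = af, c = af))
  expect_true(res$degenerate)
  expect_equal(res$variance_fraction, 0)
})

test_that("a rank-one panel loads everything on PC1", {
  af1 <- random_freq_table(2, seed = 2)
  af2 <- random_freq_table(2, seed = 3)
  res <- pca_frequencies(list(a = af1, b = af1, c = af2))
  expect_equal(res$variance_fraction[1], 1, tolerance = 1e-12)
})

test_that("variance fractions agree with an independent eigensolver", {
  set.seed(9)
  X <- matrix(stats::runif(60), 5, 12)
  pan <- panel_from_matrix(X / rowSums(X))
  res <- pca_frequencies(pan)
  M <- strforensics:::panel_matrix(pan)
  ev <- eigen(stats::cov(M), symmetric = TRUE)$values
  ev <- ev[ev > 1e-12 * ev[1]]
  expect_equal(res$variance_fraction,
               ev / sum(eigen(stats::cov(M), symmetric = TRUE)$values),
               tolerance = 1e-10)
})

test_that("PCA variance fractions ignore population order", {
  pan <- simulate_panel(sim_config(seed = 22, fst_true = 0.08,
                                   n_pops = 5, n_per_pop = 50))$frequencies
  r1 <- pca_frequencies(pan)
  r2 <- pca_frequencies(rev(pan))
  expect_equal(r1$variance_fraction, r2$variance_fraction, tolerance = 1e-10)
})

test_that("classical MDS recovers planar configurations up to rigid motion", {
  set.seed(13)
  P <- cbind(stats::runif(7, 0, 10), stats::runif(7, 0, 10))
  rownames(P) <- paste0("p", 1:7)
  d <- as.matrix(stats::dist(P))
  res <- classical_mds(dist_matrix(d, "euclidean"), k = 2)
  expect_lt(procrustes_error(P, res$coordinates), 1e-8)
  expect_equal(res$n_negative_eigenvalues, 0)
})

test_that("MDS handles degenerate and two-point inputs", {
  z <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_warning(res <- classical_mds(dist_matrix(z), k = 2),
                 "eigenvalues")   # cmdscale reports the rank deficiency
  expect_true(all(res$coordinates == 0))
  two <- matrix(c(0, 3, 3, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  res2 <- classical_mds(dist_matrix(two), k = 1)
  expect_equal(unname(abs(diff(res2$coordinates[, 1]))), 3,
               tolerance = 1e-12)
})

test_that("MDS is idempotent up to rigid motion", {
  set.seed(14)
  P <- matrix(stats::runif(12), 6, 2)
  rownames(P) <- paste0("p", 1:6)
  d1 <- as.matrix(stats::dist(P))
  r1 <- classical_mds(dist_matrix(d1), k = 2)
  d2 <- as.matrix(stats::dist(r1$coordinates))
  r2 <- classical_mds(dist_matrix(d2), k = 2)
  expect_lt(procrustes_error(r1$coordinates, r2$coordinates), 1e-8)
})

test_that("neighbor joining recovers additive trees exactly", {
  # known 4-taxon tree: ((a:2,b:3):1,(c:2,d:4)) as an additive matrix
  labs <- c("a", "b", "c", "d")
  m <- matrix(0, 4, 4, dimnames = list(labs, labs))
  m["a", "b"] <- m["b", "a"] <- 5
  m["a", "c"] <- m["c", "a"] <- 5
  m["a", "d"] <- m["d", "a"] <- 7
  m["b", "c"] <- m["c", "b"] <- 6
  m["b", "d"] <- m["d", "b"] <- 8
  m["c", "d"] <- m["d", "c"] <- 6
  tr <- neighbor_joining(dist_matrix(m))
  pd <- ape::cophenetic.phylo(tr)[labs, labs]
  expect_equal(pd, m, tolerance = 1e-10)
  # a|b vs c|d split present
  splits <- ape::prop.part(ape::unroot(tr))
  expect_true(any(vapply(splits, function(s)
    setequal(tr$tip.label[s], c("a", "b")) ||
      setequal(tr$tip.label[s], c("c", "d")), logical(1))))
})

test_that("three taxa give the closed-form star branch lengths", {
  labs <- c("a", "b", "c")
  m <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(labs, labs))
  tr <- neighbor_joining(dist_matrix(m))
  len <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(len["a"]), (3 + 4 - 5) / 2)
  expect_equal(unname(len["b"]), (3 + 5 - 4) / 2)
  expect_equal(unname(len["c"]), (4 + 5 - 3) / 2)
})

test_that("NJ topology matches the generating hierarchy and ignores label order", {
  set.seed(17)
  tr0 <- ape::rtree(5, br = stats::runif)
  tr0$edge.length <- tr0$edge.length + 0.5   # keep it safely additive
  m <- ape::cophenetic.phylo(tr0)
  tr1 <- neighbor_joining(dist_matrix(m))
  expect_equal(ape::dist.topo(ape::unroot(tr0), tr1), 0,
               ignore_attr = TRUE)
  perm <- sample(nrow(m))
  tr2 <- neighbor_joining(dist_matrix(m[perm, perm]))
  expect_equal(ape::dist.topo(tr1, tr2), 0, ignore_attr = TRUE)
  expect_equal(ape::cophenetic.phylo(tr2)[rownames(m), rownames(m)], m,
               tolerance = 1e-10)
})

test_that("trees round-trip through Newick with branch lengths", {
  pan <- simulate_panel(sim_config(seed = 23, fst_true = 0.1, n_pops = 4,
                                   n_per_pop = 40))$frequencies
  d <- genetic_distance(pan, "nei_standard")
  tr <- neighbor_joining(d)
  p <- withr_local_tempfile(".nwk")
  write_newick(tr, p)
  txt <- readLines(p)
  expect_match(txt, "^\\(.*:[0-9.].*\\);$")
  tr2 <- read_newick(p)
  expect_setequal(tr2$tip.label, rownames(d))
  expect_equal(ape::cophenetic.phylo(tr2)[rownames(d), rownames(d)],
               ape::cophenetic.phylo(tr)[rownames(d), rownames(d)],
               tolerance = 1e-8)
})

test_that("PHYLIP square matrices round-trip", {
  set.seed(19)
  for (i in 1:5) {
    n <- sample(3:8, 1)
    m <- as.matrix(stats::dist(matrix(stats::runif(2 * n), n)))
    dimnames(m) <- list(paste0("pop", 1:n), paste0("pop", 1:n))
    p <- withr_local_tempfile(".phy")
    write_phylip_distance(dist_matrix(m), p, digits = 8)
    back <- read_phylip_distance(p)
    expect_equal(rownames(back), rownames(m))
    expect_equal(unclass(back), unclass(dist_matrix(m)), tolerance = 1e-7,
                 ignore_attr = TRUE)
  }
})
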