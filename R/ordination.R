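#' Principal component analysis of a population-by-allele frequency panel
#'
#' Assembles the population x allele frequency matrix (union of alleles
#' over loci, absent alleles at 0) and eigendecomposes its covariance
#' (optionally correlation) matrix.  Components are sorted by variance and
#' given a deterministic sign: within each component the loading of
#' largest magnitude is positive.
#'
#' @param panel named list of [allele_freqs()] tables (>= 3 populations).
#' @param type `"covariance"` (default) or `"correlation"`; correlation
#'   drops zero-variance allele columns.
#' @return list of class `ordination` with `coordinates` (populations x
#'   components), `variance_fraction`, `method`, `degenerate` flag (no
#'   variance at all).
#' @export
pca_frequencies <- function(panel, type = c("covariance", "correlation")) {
  type <- match.arg(type)
  if (length(panel) < 3) abort("need >= 3 populations")
  X <- panel_matrix(panel)
  vars <- apply(X, 2, stats::var)
  if (all(vars < 1e-30)) {
    co <- matrix(0, nrow(X), 1, dimnames = list(rownames(X), "PC1"))
    return(structure(list(coordinates = co, variance_fraction = 0,
                          method = paste0("pca_", type), degenerate = TRUE),
                     class = "ordination"))
  }
  if (type == "correlation") X <- X[, vars > 1e-30, drop = FALSE]
  pr <- stats::prcomp(X, center = TRUE, scale. = (type == "correlation"))
  keep <- pr$sdev > 1e-12 * pr$sdev[1]
  rot <- pr$rotation[, keep, drop = FALSE]
  sco <- pr$x[, keep, drop = FALSE]
  for (j in seq_len(ncol(rot))) {        # deterministic sign convention
    if (rot[which.max(abs(rot[, j])), j] < 0) {
      rot[, j] <- -rot[, j]
      sco[, j] <- -sco[, j]
    }
  }
  structure(list(coordinates = sco,
                 variance_fraction = pr$sdev[keep]^2 / sum(pr$sdev^2),
                 loadings = rot,
                 method = paste0("pca_", type), degenerate = FALSE),
            class = "ordination")
}

panel_matrix <- function(panel) {
  labs <- names(panel)
  if (is.null(labs)) abort("panel must be named")
  loci <- Reduce(intersect, lapply(panel, function(p) unique(p$locus)))
  if (!length(loci)) abort("no shared loci")
  blocks <- lapply(loci, function(l) {
    alleles <- sort_allele_labels(unique(unlist(
      lapply(panel, function(af) af$allele[af$locus == l]))))
    m <- do.call(rbind, lapply(panel, function(af) {
      f <- locus_frequencies(af, l)
      out <- stats::setNames(numeric(length(alleles)), alleles)
      out[names(f)] <- f
      out
    }))
    colnames(m) <- paste(l, alleles, sep = ".")
    m
  })
  X <- do.call(cbind, blocks)
  rownames(X) <- labs
  X
}

#' Classical (metric) multidimensional scaling
#'
#' Torgerson scaling of a distance matrix: double-centre the squared
#' distances and embed on the top-k eigenvectors scaled by the square
#' roots of their eigenvalues (delegated to [stats::cmdscale()]).
#' Negative eigenvalues — non-Euclidean input — are truncated and
#' reported.
#'
#' @param dm a [dist_matrix()] or symmetric matrix with labels.
#' @param k number of output dimensions.
#' @return list of class `ordination` with `coordinates`,
#'   `variance_fraction` (over positive eigenvalues), `eigenvalues`,
#'   `n_negative_eigenvalues`, `method`.
#' @export
classical_mds <- function(dm, k = 2) {
  m <- as.matrix(dm)
  if (k < 1 || k > nrow(m) - 1) abort("k must be in 1 .. n-1")
  fit <- stats::cmdscale(stats::as.dist(m), k = k, eig = TRUE)
  co <- fit$points
  if (is.null(dim(co))) co <- matrix(co, ncol = 1)
  # cmdscale drops all-zero trailing columns for degenerate input; restore
  if (ncol(co) < k) co <- cbind(co, matrix(0, nrow(co), k - ncol(co)))
  dimnames(co) <- list(rownames(m), paste0("dim", seq_len(k)))
  pos <- pmax(fit$eig, 0)
  structure(list(coordinates = co,
                 variance_fraction = if (sum(pos) > 0)
                   pos[seq_len(k)] / sum(pos) else rep(0, k),
                 eigenvalues = fit$eig,
                 n_negative_eigenvalues = sum(fit$eig < -1e-9 * max(abs(fit$eig), 1)),
                 method = "classical_mds"),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat(sprintf("<ordination: %s> %d points, %d component(s)\n", x$method,
              nrow(x$coordinates), ncol(x$coordinates)))
  vf <- x$variance_fraction
  cat("  variance fractions:",
      paste(sprintf("%.4f", vf[seq_len(min(5, length(vf)))]), collapse = " "),
      "\n")
  invisible(x)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via [ape::nj()]) over an unrooted tree of
#' population labels.  For determinism independent of input order the
#' labels are sorted before joining; this is the documented tie-break.
#' Negative branch lengths (possible on non-additive input) are flagged
#' and, by default, clamped to zero.
#'
#' @param dm a [dist_matrix()] or symmetric labelled matrix (>= 3 labels).
#' @param clamp_negative clamp negative branch lengths to 0 (flag kept in
#'   `attr(tree, "negative_edges")`).
#' @return an [ape::phylo] tree.
#' @export
neighbor_joining <- function(dm, clamp_negative = TRUE) {
  m <- as.matrix(dm)
  if (nrow(m) < 3) abort("need >= 3 labels")
  ord <- order(rownames(m))
  m <- m[ord, ord]
  tree <- ape::nj(stats::as.dist(m))
  neg <- which(tree$edge.length < 0)
  if (clamp_negative && length(neg)) tree$edge.length[neg] <- 0
  attr(tree, "negative_edges") <- neg
  tree
}

#' PHYLIP square distance matrix and Newick I/O
#'
#' `write_phylip_distance()` writes the classical square PHYLIP distance
#' format (taxon count line, then one row per taxon: padded name + fixed
#' width distances); `read_phylip_distance()` reads it back.
#' `write_newick()`/`read_newick()` wrap [ape::write.tree()] and
#' [ape::read.tree()].  Output is bit-stable for fixed input.
#'
#' @param dm a [dist_matrix()] or labelled symmetric matrix.
#' @param path file path.
#' @param digits decimal width of written distances.
#' @return readers return a [dist_matrix()] / [ape::phylo]; writers return
#'   `path` invisibly.
#' @export
write_phylip_distance <- function(dm, path, digits = 6) {
  m <- as.matrix(dm)
  labs <- rownames(m)
  lines <- c(sprintf("%5d", nrow(m)),
             vapply(seq_len(nrow(m)), function(i) {
               paste0(formatC(substr(labs[i], 1, 10), width = -12),
                      paste(formatC(m[i, ], format = "f", digits = digits),
                            collapse = " "))
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_phylip_distance
#' @export
read_phylip_distance <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  rows <- strsplit(trimws(lines[1 + seq_len(n)]), "[[:space:]]+")
  labs <- vapply(rows, `[[`, character(1), 1)
  m <- do.call(rbind, lapply(rows, function(r) as.numeric(r[-1])))
  dimnames(m) <- list(labs, labs)
  dist_matrix(m)
}

#' @rdname write_phylip_distance
#' @param tree an [ape::phylo] tree.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_phylip_distance
#' @export
read_newick <- function(path) ape::read.tree(path)
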