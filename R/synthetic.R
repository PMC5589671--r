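#' Simulation configuration
#'
#' Bundles and validates the parameters of the synthetic-population
#' generators.  The defaults reproduce the design of the study population
#' the package ships summaries for: 214 individuals (108 males, 106
#' females) drawn at Hardy-Weinberg equilibrium from the published
#' autosomal frequencies, with Y haplotypes for the males.
#'
#' @param seed integer RNG seed (mandatory; all generators are
#'   deterministic given the config).
#' @param n_individuals total sample size.
#' @param n_males number of males (the rest are female).
#' @param freqs [allele_freqs()] table supplying autosomal allele
#'   frequencies.
#' @param y_freqs optional [allele_freqs()] table of Y-locus frequencies
#'   (pair-valued loci allowed); `NULL` simulates no Y loci.
#' @param inbreeding Wright's f: homozygote excess
#'   `P(aa) = p^2 + f p (1 - p)`; `f = 1` makes every genotype homozygous.
#' @param duplicate_locus optional LD-positive control,
#'   `list(from =, to =, rho =)`: locus `to` is a copy of locus `from`'s
#'   genotype with probability `rho` per individual (an independent draw
#'   otherwise).
#' @param fst_true differentiation parameter for [simulate_panel()]
#'   (Balding-Nichols variance `fst * p * (1 - p)` around the ancestral
#'   frequencies).
#' @param n_pops,n_per_pop panel shape for [simulate_panel()].
#' @param y_spectrum integer vector of per-haplotype multiplicities for
#'   spectrum-mode Y simulation (e.g. [shaanxi_y_spectrum()]).
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_individuals = 214,
                       n_males = 108,
                       freqs = shaanxi_autosomal_frequencies(),
                       y_freqs = NULL,
                       inbreeding = 0,
                       duplicate_locus = NULL,
                       fst_true = 0.05,
                       n_pops = 2,
                       n_per_pop = 100,
                       y_spectrum = NULL) {
  if (missing(seed)) abort("seed is mandatory")
  stopifnot(n_individuals >= 1, n_males >= 0, n_males <= n_individuals,
            inbreeding >= 0, inbreeding <= 1,
            fst_true >= 0, fst_true < 1, n_pops >= 1, n_per_pop >= 1)
  if (!is.null(duplicate_locus)) {
    stopifnot(all(c("from", "to", "rho") %in% names(duplicate_locus)))
  }
  structure(list(seed = as.integer(seed), n_individuals = n_individuals,
                 n_males = n_males, freqs = freqs, y_freqs = y_freqs,
                 inbreeding = inbreeding, duplicate_locus = duplicate_locus,
                 fst_true = fst_true, n_pops = n_pops,
                 n_per_pop = n_per_pop, y_spectrum = y_spectrum),
            class = "sim_config")
}

draw_locus <- function(alleles, p, n, f) {
  a1 <- sample(alleles, n, replace = TRUE, prob = p)
  a2 <- sample(alleles, n, replace = TRUE, prob = p)
  if (f > 0) {
    force_hom <- stats::runif(n) < f
    a2[force_hom] <- a1[force_hom]
  }
  cbind(a1, a2)
}

#' Simulate a Hardy-Weinberg population
#'
#' Draws a [genotype_table()] of `n_individuals` (first `n_males` male)
#' with autosomal genotypes formed from two independent allele draws per
#' locus (or with a homozygote excess under `inbreeding > 0`), and, when
#' `y_freqs` is supplied, Y-locus alleles drawn independently per locus
#' for the males.  Identical seeds give byte-identical tables.
#'
#' @param cfg a [sim_config()].
#' @return a [genotype_table()].
#' @export
simulate_hwe_population <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_individuals
  sex <- rep(c("male", "female"), c(cfg$n_males, n - cfg$n_males))
  loci <- unique(cfg$freqs$locus)
  autosomal <- lapply(loci, function(l) {
    f <- locus_frequencies(cfg$freqs, l)
    draw_locus(names(f), f, n, cfg$inbreeding)
  })
  names(autosomal) <- loci
  dl <- cfg$duplicate_locus
  if (!is.null(dl)) {
    src <- autosomal[[dl$from]]
    if (is.null(src)) abort("duplicate_locus$from not simulated")
    dup <- autosomal[[dl$to]] %||%
      draw_locus(unique(as.vector(src)),
                 locus_frequencies(cfg$freqs, dl$from), n, cfg$inbreeding)
    copy <- stats::runif(n) < dl$rho
    dup[copy, ] <- src[copy, ]
    autosomal[[dl$to]] <- dup
  }
  y <- list()
  if (!is.null(cfg$y_freqs) && cfg$n_males > 0) {
    is_male <- sex == "male"
    for (l in unique(cfg$y_freqs$locus)) {
      f <- locus_frequencies(cfg$y_freqs, l)
      drawn <- sample(names(f), cfg$n_males, replace = TRUE, prob = f)
      if (any(grepl(",", names(f), fixed = TRUE))) {
        m <- matrix(NA_character_, n, 2)
        m[is_male, ] <- do.call(rbind, strsplit(drawn, ",", fixed = TRUE))
        y[[l]] <- m
      } else {
        v <- rep(NA_character_, n)
        v[is_male] <- drawn
        y[[l]] <- v
      }
    }
  }
  genotype_table(sprintf("S%04d", seq_len(n)), sex, autosomal, y)
}

#' Simulate a structured multi-population panel (Balding-Nichols)
#'
#' Draws each subpopulation's allele frequencies around the ancestral
#' frequencies from a Dirichlet with concentration
#' `p * (1 - fst) / fst` — the Balding-Nichols model, giving each allele
#' variance `fst * p * (1 - p)` and hence a known true Fst for
#' parameter-recovery experiments — then draws per-population genotype
#' tables at Hardy-Weinberg equilibrium.  `fst_true = 0` copies the
#' ancestral frequencies exactly.
#'
#' @param cfg a [sim_config()]; uses `n_pops`, `n_per_pop`, `fst_true`,
#'   `freqs` (ancestral), `seed`.
#' @return list with `frequencies` (named list of [allele_freqs()], the
#'   realised per-population frequencies), `genotypes` (named list of
#'   [genotype_table()]s), `fst_true`.
#' @export
simulate_panel <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_pops < 2) abort("a panel needs >= 2 populations")
  set.seed(cfg$seed)
  loci <- unique(cfg$freqs$locus)
  labs <- paste0("pop", seq_len(cfg$n_pops))
  f <- cfg$fst_true
  pop_freqs <- lapply(labs, function(lab) {
    rows <- lapply(loci, function(l) {
      p <- locus_frequencies(cfg$freqs, l)
      q <- if (f == 0) p else {
        g <- stats::rgamma(length(p), shape = p * (1 - f) / f)
        while (sum(g) == 0) g <- stats::rgamma(length(p), shape = p * (1 - f) / f)
        g / sum(g)
      }
      data.frame(locus = l, allele = names(p), frequency = as.numeric(q),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  names(pop_freqs) <- labs
  genotypes <- lapply(seq_along(labs), function(i) {
    n <- cfg$n_per_pop
    autosomal <- lapply(loci, function(l) {
      df <- pop_freqs[[i]]
      sel <- df$locus == l
      draw_locus(df$allele[sel], df$frequency[sel], n, 0)
    })
    names(autosomal) <- loci
    genotype_table(sprintf("%s_%03d", labs[i], seq_len(n)),
                   rep(c("male", "female"), length.out = n), autosomal)
  })
  names(genotypes) <- labs
  freq_tables <- lapply(pop_freqs, function(df) {
    allele_freqs(df, n_genes = 2 * cfg$n_per_pop)
  })
  list(frequencies = freq_tables, genotypes = genotypes, fst_true = f)
}

#' Simulate Y-STR haplotypes
#'
#' Two modes.  *Spectrum mode* (`y_spectrum` set in the config) draws
#' exactly the requested multiplicity structure: distinct haplotypes are
#' generated (from `y_freqs` when available, otherwise from an arbitrary
#' label space), each repeated according to its multiplicity, and assigned
#' to males in shuffled order — so downstream haplotype diversity and
#' discriminatory capacity are deterministic functions of the spectrum.
#' *Frequency mode* draws each locus independently from `y_freqs`.
#'
#' @param cfg a [sim_config()] with `y_spectrum` and/or `y_freqs` set.
#' @return a [genotype_table()] of `n_males` males with Y loci only.
#' @export
simulate_y_haplotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(cfg$y_spectrum) && is.null(cfg$y_freqs)) {
    abort("need y_spectrum or y_freqs")
  }
  set.seed(cfg$seed + 1L)
  if (!is.null(cfg$y_spectrum)) {
    mult <- as.integer(cfg$y_spectrum)
    n <- sum(mult)
    n_distinct <- length(mult)
    loci <- if (!is.null(cfg$y_freqs)) unique(cfg$y_freqs$locus) else
      paste0("DYS_L", 1:4)
    # draw distinct haplotypes, resampling collisions
    draw_one <- function() {
      vapply(loci, function(l) {
        if (!is.null(cfg$y_freqs)) {
          f <- locus_frequencies(cfg$y_freqs, l)
          sample(names(f), 1, prob = f)
        } else as.character(sample(8:30, 1))
      }, character(1))
    }
    haps <- list()
    keys <- character(0)
    guard <- 0
    while (length(haps) < n_distinct) {
      h <- draw_one()
      k <- paste(h, collapse = "|")
      guard <- guard + 1
      if (guard > 1000 * n_distinct) abort("haplotype space too small for spectrum")
      if (k %in% keys) next
      keys <- c(keys, k)
      haps[[length(haps) + 1]] <- h
    }
    assign <- sample(rep(seq_len(n_distinct), mult))
    hap_mat <- do.call(rbind, haps)[assign, , drop = FALSE]
    colnames(hap_mat) <- loci
  } else {
    n <- cfg$n_males
    loci <- unique(cfg$y_freqs$locus)
    hap_mat <- vapply(loci, function(l) {
      f <- locus_frequencies(cfg$y_freqs, l)
      sample(names(f), n, replace = TRUE, prob = f)
    }, character(n))
    if (is.null(dim(hap_mat))) hap_mat <- matrix(hap_mat, nrow = n,
                                                 dimnames = list(NULL, loci))
  }
  y <- lapply(colnames(hap_mat), function(l) {
    v <- hap_mat[, l]
    if (any(grepl(",", v, fixed = TRUE))) {
      do.call(rbind, strsplit(v, ",", fixed = TRUE))
    } else v
  })
  names(y) <- colnames(hap_mat)
  genotype_table(sprintf("M%04d", seq_len(nrow(hap_mat))),
                 rep("male", nrow(hap_mat)), list(), y)
}
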