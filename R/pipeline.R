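#' Run the full forensic STR analysis pipeline
#'
#' Orchestrates the standard report chain — allele frequencies, forensic
#' efficiency parameters with combined powers, Hardy-Weinberg tests,
#' pairwise linkage-disequilibrium matrix, and (when Y loci are present)
#' the Y-STR frequency/diversity suite — writing one CSV per stage plus a
#' JSON run manifest that records inputs (with MD5 hashes), the seed, the
#' per-stage status and every output file, sufficient to rerun the
#' analysis identically.
#'
#' @param gt a [genotype_table()], or a path to a genotype CSV.
#' @param out_dir output directory (created if needed).
#' @param seed integer seed driving every stochastic stage.
#' @param stages subset of
#'   `c("freq", "forensic", "hwe", "ld", "ystr")` to run.
#' @param n_perm Monte-Carlo permutations for the test stages.
#' @param alpha raw significance level.
#' @return the manifest, invisibly (also written to
#'   `file.path(out_dir, "manifest.json")`).
#' @export
run_str_pipeline <- function(gt, out_dir, seed,
                             stages = c("freq", "forensic", "hwe", "ld",
                                        "ystr"),
                             n_perm = 1e4, alpha = 0.05) {
  if (missing(seed)) abort("seed is mandatory")
  stages <- match.arg(stages, several.ok = TRUE)
  input <- NULL
  if (is.character(gt)) {
    input <- list(path = gt, md5 = unname(tools::md5sum(gt)))
    gt <- read_genotype_csv(gt)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(input = input,
                   seed = seed, n_perm = n_perm, alpha = alpha,
                   n_samples = n_samples(gt),
                   stages = list(), outputs = character(0))
  note <- function(stage, status, files = character(0), extra = NULL) {
    manifest$stages[[stage]] <<- c(list(status = status, files = files),
                                   extra)
    manifest$outputs <<- c(manifest$outputs, files)
  }
  run_stage <- function(stage, fun) {
    if (!stage %in% stages) return(invisible())
    tryCatch(fun(), error = function(e) {
      note(stage, paste("failed:", conditionMessage(e)))
    })
  }

  run_stage("freq", function() {
    f <- file.path(out_dir, "allele_frequencies.csv")
    write_frequency_csv(allele_frequencies(gt, autosomal_loci(gt)), f)
    note("freq", "ok", f)
  })
  run_stage("forensic", function() {
    fp <- forensic_params(gt)
    cp <- combined_powers(fp$MP, fp$PE)
    out <- fp
    for (col in setdiff(names(out), "locus")) out[[col]] <- fmt_num(out[[col]])
    f <- file.path(out_dir, "forensic_params.csv")
    utils::write.csv(out, f, row.names = FALSE, quote = FALSE)
    f2 <- file.path(out_dir, "combined_powers.json")
    jsonlite::write_json(cp[c("combined_pd", "combined_pe",
                              "prod_mp", "prod_one_minus_pe")],
                         f2, auto_unbox = TRUE, digits = NA)
    note("forensic", "ok", c(f, f2))
  })
  run_stage("hwe", function() {
    res <- hwe_test_all(gt, n_perm = n_perm, seed = seed, alpha = alpha)
    f <- file.path(out_dir, "hwe_tests.csv")
    utils::write.csv(res, f, row.names = FALSE, quote = FALSE)
    note("hwe", "ok", f)
  })
  run_stage("ld", function() {
    res <- ld_test_matrix(gt, n_perm = n_perm, seed = seed + 1L,
                          alpha = alpha)
    f <- file.path(out_dir, "ld_pvalues.csv")
    utils::write.csv(as.data.frame(res$p_matrix), f, quote = FALSE)
    note("ld", "ok", f)
  })
  run_stage("ystr", function() {
    if (!length(y_loci(gt)) || !any(gt$sex == "male")) {
      note("ystr", "skipped: no Y loci or no males")
      return(invisible())
    }
    ys <- ystr_summary(gt)
    f <- file.path(out_dir, "y_gene_diversity.csv")
    out <- ys$gene_diversity
    out$gd <- fmt_num(out$gd)
    utils::write.csv(out, f, row.names = FALSE, quote = FALSE)
    f2 <- file.path(out_dir, "y_summary.json")
    jsonlite::write_json(ys[c("n", "n_distinct", "n_unique", "dc", "hd")],
                         f2, auto_unbox = TRUE, digits = NA)
    f3 <- file.path(out_dir, "y_haplotypes.csv")
    hb <- build_haplotypes(gt)
    utils::write.csv(hb$haplotypes, f3, row.names = FALSE, quote = TRUE)
    note("ystr", "ok", c(f, f2, f3))
  })

  failed <- vapply(manifest$stages, function(s)
    startsWith(s$status, "failed"), logical(1))
  manifest$ok <- !any(failed)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (any(failed)) {
    abort("pipeline stage(s) failed: ",
          paste(names(manifest$stages)[failed], collapse = ", "))
  }
  invisible(manifest)
}
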