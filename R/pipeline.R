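#' Read pipeline inputs
#'
#' @param field_book Path to the plot-level field-book CSV (optional).
#' @param codominant Path to a codominant genotype CSV (optional).
#' @param bands Path to a band-matrix CSV (used when `codominant` is
#'   absent).
#' @param objectives Named character vector/list of per-trait breeding
#'   objectives (`"increase"`/`"decrease"`), or a path to a two-column CSV
#'   (`trait`, `objective`).
#' @return List: `trial` (or `NULL`), `panel` (or `NULL`), `objectives`.
#' @export
read_inputs <- function(field_book = NULL, codominant = NULL, bands = NULL,
                        objectives = NULL) {
  trial <- if (!is.null(field_book)) read_field_book(field_book) else NULL
  panel <- if (!is.null(codominant)) read_codominant(codominant)
           else if (!is.null(bands)) read_band_matrix(bands) else NULL
  if (is.character(objectives) && length(objectives) == 1 &&
      file.exists(objectives)) {
    ob <- utils::read.csv(objectives, stringsAsFactors = FALSE)
    objectives <- stats::setNames(ob$objective, ob$trait)
  }
  list(trial = trial, panel = panel, objectives = objectives)
}

#' Run the full characterization pipeline
#'
#' Executes, in dependency order, every stage of the germplasm
#' characterization: per-trait variance components / heritability / BLUPs,
#' binned Shannon-Weaver phenotypic diversity, Pearson + partial trait
#' correlations with the robust intersection, PCA + Ward clustering with
#' v-tests, MGIDI selection, per-locus marker diversity and private
#' alleles, Jaccard/neighbor-joining tree with bootstrap, admixture scan
#' with Evanno Delta-K, AMOVA, and Nei population distances. Phenotypic
#' stages are skipped when `trial` is `NULL` and marker stages when `panel`
#' is `NULL` (noted in the manifest). All tabular outputs are written as
#' CSV under `out_dir` with a one-line `#` header carrying the seed.
#'
#' @param trial Field-book data frame, or `NULL`.
#' @param panel A [marker_panel()], or `NULL`.
#' @param objectives Per-trait breeding objectives for MGIDI (single value
#'   recycled; default `"increase"`).
#' @param out_dir Output directory, or `NULL` to skip writing files.
#' @param seed Master seed recorded in outputs and used for the stochastic
#'   stages (bootstrap, MCMC, permutations).
#' @param selection_fraction MGIDI selected fraction.
#' @param k_clusters Cluster count or `"auto"`.
#' @param K_range K values for the admixture scan.
#' @param n_runs Replicate admixture runs per K.
#' @param sweeps,burn_in MCMC settings per run.
#' @param boot_reps NJ bootstrap replicates.
#' @param n_perms AMOVA permutations.
#' @param alpha Significance level.
#' @return List of class `germdiv_run` with every stage result and a
#'   `manifest` data frame (stage, status, seconds).
#' @export
run_all <- function(trial = NULL, panel = NULL, objectives = "increase",
                    out_dir = NULL, seed = 1, selection_fraction = 0.20,
                    k_clusters = "auto", K_range = 1:5, n_runs = 3,
                    sweeps = 2000, burn_in = 1000, boot_reps = 200,
                    n_perms = 999, alpha = 0.05) {
  res <- list(seed = seed)
  manifest <- list()
  t_stage <- function(name, skip, expr) {
    t0 <- proc.time()[3]
    if (skip) {
      manifest[[length(manifest) + 1]] <<- data.frame(
        stage = name, status = "skipped", seconds = 0)
      return(NULL)
    }
    out <- tryCatch(expr, error = function(e) {
      manifest[[length(manifest) + 1]] <<- data.frame(
        stage = name, status = paste("error:", conditionMessage(e)),
        seconds = round(proc.time()[3] - t0, 2))
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    manifest[[length(manifest) + 1]] <<- data.frame(
      stage = name, status = "completed",
      seconds = round(proc.time()[3] - t0, 2))
    out
  }
  no_pheno <- is.null(trial)
  no_geno <- is.null(panel)
  if (no_pheno) message("no field book supplied: phenotypic stages skipped")
  if (no_geno) message("no marker panel supplied: genetic stages skipped")

  res$variance <- t_stage("variance_components", no_pheno,
                          fit_all_traits(trial))
  res$blups <- t_stage("blup_means", no_pheno, blup_means(trial))
  res$diversity <- t_stage("pheno_diversity", no_pheno,
                           diversity_profile(res$blups))
  res$pearson <- t_stage("pearson", no_pheno, pearson_matrix(res$blups))
  res$partial <- t_stage("partial", no_pheno, partial_matrix(res$pearson))
  res$associations <- t_stage("robust_pairs", no_pheno,
                              robust_pairs(res$pearson, res$partial,
                                           alpha = alpha))
  res$pca <- t_stage("pca", no_pheno, pca_blups(res$blups))
  res$clusters <- t_stage("clusters", no_pheno,
                          cluster_pcs(res$pca, k = k_clusters,
                                      traits = res$blups, alpha = alpha))
  res$mgidi <- t_stage("mgidi", no_pheno,
                       mgidi(res$blups, objectives,
                             selection_fraction = selection_fraction))

  res$marker_diversity <- t_stage("marker_diversity", no_geno,
                                  locus_diversity(panel))
  res$tree <- t_stage("nj_tree", no_geno, {
    bm <- band_matrix(panel)
    bootstrap_support(bm, n_reps = boot_reps, seed = substream_seed(seed, 11L))
  })
  res$structure <- t_stage("structure_scan", no_geno,
                           structure_scan(panel, K_range = K_range,
                                          n_runs = n_runs, sweeps = sweeps,
                                          burn_in = burn_in, seed = seed))
  res$delta_k <- t_stage("evanno", no_geno, evanno_delta_k(res$structure))
  res$membership <- t_stage("membership", no_geno, {
    bk <- res$delta_k$best_K
    runs <- Filter(function(r) r$K == bk, res$structure$runs)
    Qs <- align_q_runs(lapply(runs, `[[`, "Q"))
    Qbar <- Reduce("+", Qs) / length(Qs)
    assign_membership(Qbar, threshold = 0.7)
  })
  res$amova <- t_stage("amova", no_geno, {
    pops <- infer_pops(res$membership, panel)
    amova(panel, populations = pops, n_perms = n_perms,
          seed = substream_seed(seed, 12L))
  })
  res$pop_stats <- t_stage("pop_stats", no_geno, {
    pops <- infer_pops(res$membership, panel)
    pairwise_pop_stats(panel, populations = pops)
  })
  res$private <- t_stage("private_alleles", no_geno, {
    pops <- infer_pops(res$membership, panel)
    private_alleles(panel, populations = pops)
  })

  res$manifest <- do.call(rbind, manifest)
  class(res) <- "germdiv_run"
  if (!is.null(out_dir)) write_run_outputs(res, panel, out_dir, seed)
  res
}

# admixed genotypes fall back to their max-Q population for the
# population-level statistics
infer_pops <- function(membership, panel) {
  lab <- membership$label
  if (any(lab == "admixed")) {
    # membership labels come from the averaged Q; reuse max column
    lab[lab == "admixed"] <- NA
  }
  if (anyNA(lab)) {
    if (!is.null(panel$populations)) {
      lab[is.na(lab)] <- panel$populations[is.na(lab)]
    } else {
      lab[is.na(lab)] <- "admixed_pool"
    }
  }
  lab
}

write_run_outputs <- function(res, panel, out_dir, seed) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- sprintf("# germdiv run, seed %d", seed)
  wr <- function(df, name) {
    if (is.null(df)) return(invisible(NULL))
    f <- file.path(out_dir, name)
    con <- file(f, "w")
    writeLines(hdr, con)
    utils::write.csv(df, con, row.names = FALSE)
    close(con)
  }
  wr(res$variance, "variance_components.csv")
  wr(res$blups, "blup_means.csv")
  wr(res$diversity, "pheno_diversity.csv")
  wr(res$associations, "trait_associations.csv")
  if (!is.null(res$pca)) {
    wr(data.frame(genotype = rownames(res$pca$scores), res$pca$scores),
       "pca_scores.csv")
  }
  if (!is.null(res$clusters)) {
    wr(data.frame(genotype = names(res$clusters$cluster),
                  cluster = res$clusters$cluster), "clusters.csv")
    wr(res$clusters$vtest, "cluster_vtests.csv")
  }
  if (!is.null(res$mgidi)) {
    wr(res$mgidi$table, "mgidi.csv")
    wr(res$mgidi$gains, "mgidi_gains.csv")
  }
  wr(res$marker_diversity, "marker_diversity.csv")
  if (!is.null(res$tree)) {
    ape::write.tree(res$tree$tree, file.path(out_dir, "nj_tree.nwk"))
  }
  if (!is.null(res$structure)) wr(res$structure$lnL, "structure_lnl.csv")
  if (!is.null(res$delta_k)) wr(res$delta_k$table, "delta_k.csv")
  if (!is.null(res$membership)) {
    wr(data.frame(genotype = names(res$membership$label),
                  label = res$membership$label), "membership.csv")
  }
  if (!is.null(res$amova)) wr(res$amova$table, "amova.csv")
  wr(res$pop_stats, "pop_distances.csv")
  wr(res$manifest, "manifest.csv")
  invisible(NULL)
}

#' @export
print.germdiv_run <- function(x, ...) {
  cat("<germdiv_run>\n")
  print(x$manifest, row.names = FALSE)
  invisible(x)
}
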