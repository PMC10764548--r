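#' Configuration for a synthetic germplasm panel
#'
#' Bundles every parameter of the synthetic-panel generator: the field-trial
#' layout (a resolvable incomplete-block design with blocks nested in
#' replicates), the trait architecture (per-trait target plot-basis
#' heritability, genetic correlation structure, trait means), and the marker
#' architecture (number of sub-populations, loci, alleles per locus,
#' divergence, selfing rate, admixture concentration).
#'
#' The defaults emulate a diversity panel of 132 genotypes evaluated in an
#' alpha-lattice with two replicates of 12 incomplete blocks times 11 plots
#' (264 plots), scored for 28 correlated quantitative traits with plot-basis
#' heritabilities spread between 0.16 and 0.98, and genotyped at 14 SSR loci
#' with 2--10 alleles drawn from two weakly diverged sub-populations in a
#' highly selfing species.
#'
#' @param n_genotypes Number of genotypes in the panel.
#' @param n_reps Number of complete replicates.
#' @param n_blocks_per_rep Number of incomplete blocks within each replicate.
#' @param plots_per_block Number of plots per incomplete block.
#' @param n_traits Number of quantitative traits.
#' @param target_H2 Per-trait plot-basis heritability Vg/(Vg+Vblock+Ve),
#'   recycled to `n_traits`. Values in \[0, 1\].
#' @param genetic_corr Trait-by-trait genetic correlation matrix (symmetric,
#'   positive semi-definite, unit diagonal). Default is an AR(1)-like
#'   structure with parameter 0.3.
#' @param trait_means Per-trait grand means, recycled to `n_traits`.
#' @param phen_var Per-trait phenotypic (plot) variance. Default
#'   `(0.2 * trait_means)^2`, i.e. a 20% phenotypic coefficient of variation.
#' @param block_var_share Fraction of the non-genetic variance assigned to
#'   blocks within replicates (the rest is residual).
#' @param K_true Number of ancestral sub-populations for the marker model.
#' @param n_loci Number of SSR loci.
#' @param alleles_per_locus Integer vector of allele counts per locus,
#'   recycled to `n_loci`.
#' @param target_Fst Divergence of sub-population allele frequencies from the
#'   ancestral frequencies (Balding-Nichols parameter), in \[0, 1).
#' @param inbreeding_F Probability that a locus is autozygous (both allele
#'   copies identical by descent), in \[0, 1\]. High values emulate selfing.
#' @param admixture_alpha Dirichlet concentration for individual admixture
#'   proportions. `0` means hard (non-admixed) assignment to sub-populations
#'   in balanced proportions.
#' @param seed Master integer seed; deterministic sub-streams are derived
#'   from it for the trial and marker generators.
#'
#' @return An object of class `panel_config` (a validated list).
#' @examples
#' cfg <- panel_config(seed = 1)
#' cfg$n_genotypes
#' @export
panel_config <- function(n_genotypes = 132,
                         n_reps = 2,
                         plots_per_block = 11,
                         n_blocks_per_rep = ceiling(n_genotypes / plots_per_block),
                         n_traits = 28,
                         target_H2 = seq(0.16, 0.98, length.out = n_traits),
                         genetic_corr = NULL,
                         trait_means = seq(20, 100, length.out = n_traits),
                         phen_var = NULL,
                         block_var_share = 0.25,
                         K_true = 2,
                         n_loci = 14,
                         alleles_per_locus = c(4, 3, 4, 2, 2, 2, 4, 3, 6, 10, 5, 8, 7, 4),
                         target_Fst = 0.11,
                         inbreeding_F = 0.85,
                         admixture_alpha = 0.1,
                         seed = 42L) {
  stopifnot(n_genotypes >= 2, n_reps >= 1, n_blocks_per_rep >= 1,
            plots_per_block >= 1, n_traits >= 1, n_loci >= 1, K_true >= 1)
  target_H2 <- rep_len(target_H2, n_traits)
  trait_means <- rep_len(trait_means, n_traits)
  alleles_per_locus <- as.integer(rep_len(alleles_per_locus, n_loci))
  if (any(target_H2 < 0 | target_H2 > 1)) {
    stop("target_H2 must lie in [0, 1]")
  }
  if (target_Fst < 0 || target_Fst >= 1) stop("target_Fst must lie in [0, 1)")
  if (inbreeding_F < 0 || inbreeding_F > 1) stop("inbreeding_F must lie in [0, 1]")
  if (admixture_alpha < 0) stop("admixture_alpha must be >= 0")
  if (block_var_share < 0 || block_var_share > 1) {
    stop("block_var_share must lie in [0, 1]")
  }
  if (any(alleles_per_locus < 1)) stop("alleles_per_locus must be >= 1")
  if (n_blocks_per_rep * plots_per_block < n_genotypes) {
    stop("infeasible layout: n_blocks_per_rep * plots_per_block (",
         n_blocks_per_rep * plots_per_block, ") < n_genotypes (",
         n_genotypes, ")")
  }
  if (is.null(genetic_corr)) {
    genetic_corr <- 0.3 ^ abs(outer(seq_len(n_traits), seq_len(n_traits), "-"))
  }
  genetic_corr <- as.matrix(genetic_corr)
  if (nrow(genetic_corr) != n_traits || ncol(genetic_corr) != n_traits) {
    stop("genetic_corr must be ", n_traits, " x ", n_traits)
  }
  if (max(abs(genetic_corr - t(genetic_corr))) > 1e-8 ||
      max(abs(diag(genetic_corr) - 1)) > 1e-8) {
    stop("genetic_corr must be symmetric with unit diagonal")
  }
  ev <- eigen(genetic_corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("genetic_corr must be positive semi-definite")
  if (is.null(phen_var)) phen_var <- (0.2 * trait_means)^2
  phen_var <- rep_len(phen_var, n_traits)
  if (any(phen_var <= 0)) stop("phen_var must be positive")

  cfg <- list(
    n_genotypes = as.integer(n_genotypes), n_reps = as.integer(n_reps),
    n_blocks_per_rep = as.integer(n_blocks_per_rep),
    plots_per_block = as.integer(plots_per_block),
    n_traits = as.integer(n_traits), target_H2 = target_H2,
    genetic_corr = genetic_corr, trait_means = trait_means,
    phen_var = phen_var, block_var_share = block_var_share,
    K_true = as.integer(K_true), n_loci = as.integer(n_loci),
    alleles_per_locus = alleles_per_locus, target_Fst = target_Fst,
    inbreeding_F = inbreeding_F, admixture_alpha = admixture_alpha,
    seed = as.integer(seed)
  )
  class(cfg) <- "panel_config"
  cfg
}

#' @export
print.panel_config <- function(x, ...) {
  cat("<panel_config>\n")
  cat(sprintf("  trial : %d genotypes, %d reps x %d blocks x %d plots, %d traits\n",
              x$n_genotypes, x$n_reps, x$n_blocks_per_rep, x$plots_per_block,
              x$n_traits))
  cat(sprintf("  marker: K=%d, %d loci (%d alleles), Fst=%.3g, F=%.3g, alpha=%.3g\n",
              x$K_true, x$n_loci, sum(x$alleles_per_locus), x$target_Fst,
              x$inbreeding_F, x$admixture_alpha))
  cat(sprintf("  seed  : %d\n", x$seed))
  invisible(x)
}

# deterministic sub-stream seed, kept under 2^31
substream_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 1103L + offset * 7919L) %% 2147483629)
}
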