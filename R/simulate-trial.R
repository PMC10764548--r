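#' Simulate a replicated incomplete-block field trial
#'
#' Generates plot-level observations from the random-genotype model
#' `Y = mu + Gen + Block(Rep) + e`. Genetic values are drawn from a
#' multivariate normal with covariance scaled so the plot-basis heritability
#' Vg/(Vg+Vblock+Ve) hits `config$target_H2` exactly for every trait;
#' block-within-rep and residual effects are independent normals. Genotypes
#' are allocated to incomplete blocks by a cyclic resolvable construction:
#' within each replicate every genotype appears exactly once, and the
#' block partition rotates across replicates.
#'
#' @param config A [panel_config()].
#' @return A list with components
#'   \describe{
#'     \item{trial}{data frame with columns `genotype`, `rep`, `block` and one
#'       column per trait (`trait_01`, ...): the field book.}
#'     \item{truth}{ground truth: `genetic_values` (genotype x trait matrix of
#'       true genetic effects), `variance_components` (per-trait Vg, Vblock,
#'       Ve), and the generating `config`.}
#'   }
#' @examples
#' sim <- simulate_trial(panel_config(seed = 1))
#' nrow(sim$trial)  # 264 plots
#' @export
simulate_trial <- function(config) {
  stopifnot(inherits(config, "panel_config"))
  set.seed(substream_seed(config$seed, 1L))
  n <- config$n_genotypes
  Tn <- config$n_traits

  Vg <- config$target_H2 * config$phen_var
  Vrest <- (1 - config$target_H2) * config$phen_var
  Vb <- config$block_var_share * Vrest
  Ve <- Vrest - Vb

  # genetic values: MVN with covariance D^1/2 R D^1/2
  sd_g <- sqrt(Vg)
  Sigma <- config$genetic_corr * tcrossprod(sd_g)
  G <- MASS::mvrnorm(n, mu = rep(0, Tn), Sigma = Sigma)
  G <- matrix(G, nrow = n, ncol = Tn)

  traits <- sprintf("trait_%02d", seq_len(Tn))
  colnames(G) <- traits
  geno_ids <- sprintf("G%03d", seq_len(n))
  rownames(G) <- geno_ids

  layout <- trial_layout(n, config$n_reps, config$n_blocks_per_rep,
                         config$plots_per_block)
  n_plots <- nrow(layout)

  Y <- matrix(NA_real_, n_plots, Tn, dimnames = list(NULL, traits))
  for (t in seq_len(Tn)) {
    blk_key <- paste(layout$rep, layout$block, sep = ":")
    blk_levels <- unique(blk_key)
    b_eff <- stats::rnorm(length(blk_levels), 0, sqrt(Vb[t]))
    names(b_eff) <- blk_levels
    Y[, t] <- config$trait_means[t] + G[layout$genotype_idx, t] +
      b_eff[blk_key] + stats::rnorm(n_plots, 0, sqrt(Ve[t]))
  }

  trial <- data.frame(
    genotype = geno_ids[layout$genotype_idx],
    rep = sprintf("R%d", layout$rep),
    block = sprintf("B%02d", layout$block),
    Y,
    stringsAsFactors = FALSE
  )
  truth <- list(
    genetic_values = G,
    variance_components = data.frame(
      trait = traits, Vg = Vg, Vblock = Vb, Ve = Ve,
      H2 = ifelse(config$phen_var > 0, Vg / (Vg + Vb + Ve), 0),
      stringsAsFactors = FALSE
    ),
    config = config
  )
  list(trial = trial, truth = truth)
}

# cyclic resolvable incomplete-block allocation: one occurrence of each
# genotype per replicate; rep r uses the base partition of a rotated ordering
trial_layout <- function(n_genotypes, n_reps, n_blocks, plots_per_block) {
  if (n_blocks * plots_per_block < n_genotypes) {
    stop("infeasible layout: ", n_blocks * plots_per_block,
         " plots per replicate for ", n_genotypes, " genotypes")
  }
  out <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    # rotate genotypes across the block grid: genotype i sits in
    # block ((i - 1 + (r - 1) * floor(i / n_blocks)) mod n_blocks) in a
    # column-cycled k x b array; this keeps concurrences spread out
    idx <- seq_len(n_genotypes)
    row_of <- (idx - 1L) %/% n_blocks
    col_of <- (idx - 1L) %% n_blocks
    block <- ((col_of + (r - 1L) * row_of) %% n_blocks) + 1L
    # cap block occupancy at plots_per_block by spilling overflow into the
    # emptiest blocks (only triggered when n_blocks * plots > n_genotypes
    # does not divide evenly)
    tab <- tabulate(block, n_blocks)
    while (any(tab > plots_per_block)) {
      over <- which(tab > plots_per_block)[1]
      under <- which.min(tab)
      move <- which(block == over)[1]
      block[move] <- under
      tab <- tabulate(block, n_blocks)
    }
    out[[r]] <- data.frame(genotype_idx = idx, rep = r, block = block)
  }
  do.call(rbind, out)
}
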