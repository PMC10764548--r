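#' Bayesian admixture inference by Gibbs sampling
#'
#' Fits the no-linkage admixture model for a fixed number of populations K:
#' each individual has admixture proportions Q over K populations (symmetric
#' Dirichlet prior), each population has per-locus allele frequencies P
#' (Dirichlet prior), and each allele copy independently draws an origin
#' population from Q and an allele from that population's frequencies. A
#' Gibbs sampler alternates updates of the latent copy origins, P and Q;
#' the reported Q and P are posterior means over the post-burn-in sweeps
#' and `lnL` is the mean data log-likelihood over those sweeps.
#'
#' @param panel A [marker_panel()] (band matrices: convert with
#'   [bands_to_panel()] first).
#' @param K Number of populations (>= 1).
#' @param sweeps Post-burn-in Gibbs sweeps (default 10000, a desk-scale
#'   setting; scale up for production runs).
#' @param burn_in Burn-in sweeps (default 5000).
#' @param alpha Admixture Dirichlet concentration (default 1).
#' @param infer_alpha Update `alpha` by a Metropolis step on its log
#'   (default FALSE).
#' @param lambda Allele-frequency Dirichlet prior parameter (default 1).
#' @param seed Integer seed.
#' @return List of class `structure_run`: `K`, `Q` (genotype x K posterior
#'   means), `P` (list locus -> K x alleles), `lnL`, `lnL_trace`, `alpha`,
#'   `sweeps`, `burn_in`, `seed`.
#' @examples
#' sim <- simulate_markers(panel_config(n_genotypes = 40, seed = 5))
#' run <- admixture_gibbs(sim$panel, K = 2, sweeps = 200, burn_in = 100)
#' head(run$Q)
#' @export
admixture_gibbs <- function(panel, K, sweeps = 10000, burn_in = 5000,
                            alpha = 1, infer_alpha = FALSE, lambda = 1,
                            seed = 1) {
  stopifnot(inherits(panel, "marker_panel"))
  n <- length(panel$genotypes)
  if (K < 1) stop("K must be >= 1")
  if (K > n) stop("K exceeds the number of genotypes")
  empty <- vapply(seq_along(panel$loci),
                  function(l) all(is.na(panel$A1[, l])), logical(1))
  if (any(empty)) {
    stop("locus with no scored call (likelihood undefined): ",
         paste(panel$loci[empty], collapse = ", "))
  }
  A1 <- panel$A1 - 1L; A2 <- panel$A2 - 1L
  A1[is.na(A1)] <- -1L; A2[is.na(A2)] <- -1L
  n_all <- vapply(panel$allele_labels, length, integer(1))
  set.seed(as.integer(seed))
  res <- .admixture_gibbs_cpp(A1, A2, n_all, as.integer(K),
                              as.integer(sweeps), as.integer(burn_in),
                              alpha, lambda, infer_alpha)
  if (!is.finite(res$lnL)) stop("non-finite likelihood in Gibbs sampler")
  rownames(res$Q) <- panel$genotypes
  colnames(res$Q) <- sprintf("pop_%d", seq_len(K))
  names(res$P) <- panel$loci
  out <- c(res, list(K = as.integer(K), sweeps = sweeps, burn_in = burn_in,
                     seed = seed))
  class(out) <- "structure_run"
  out
}

#' @export
print.structure_run <- function(x, ...) {
  cat(sprintf("<structure_run> K = %d, mean lnL = %.2f (%d sweeps + %d burn-in)\n",
              x$K, x$lnL, x$sweeps, x$burn_in))
  invisible(x)
}

#' Run the admixture model across a range of K with replicate runs
#'
#' @param panel A [marker_panel()].
#' @param K_range Integer vector of K values (default 1:10).
#' @param n_runs Replicate runs per K (default 5).
#' @param seed Master seed; run seeds are derived deterministically.
#' @param ... Passed to [admixture_gibbs()] (`sweeps`, `burn_in`, ...).
#' @return List of class `structure_scan`: `runs` (list of `structure_run`),
#'   `lnL` (data frame K, run, lnL).
#' @export
structure_scan <- function(panel, K_range = 1:10, n_runs = 5, seed = 1, ...) {
  runs <- list()
  tab <- list()
  for (K in K_range) {
    for (r in seq_len(n_runs)) {
      run_seed <- substream_seed(seed, 100L * K + r)
      run <- admixture_gibbs(panel, K = K, seed = run_seed, ...)
      runs[[length(runs) + 1]] <- run
      tab[[length(tab) + 1]] <- data.frame(K = K, run = r, lnL = run$lnL)
    }
  }
  structure(list(runs = runs, lnL = do.call(rbind, tab)),
            class = "structure_scan")
}

#' Evanno Delta-K table from replicate admixture runs
#'
#' For each K: `L(K)` is the mean log-likelihood over runs and `sd(K)` its
#' standard deviation; `L'(K) = L(K) - L(K-1)`,
#' `|L''(K)| = |L'(K+1) - L'(K)|`, and `DeltaK = |L''(K)| / sd(K)`. DeltaK
#' is defined only for interior K with at least 2 runs and non-zero sd; the
#' K maximizing DeltaK is the suggested number of populations.
#'
#' @param runs A `structure_scan`, a list of `structure_run` objects, or a
#'   data frame with columns `K` and `lnL`.
#' @return List of class `delta_k_table`: `table` (K, n_runs, mean_lnL,
#'   sd_lnL, Lp, Lpp_abs, deltaK), `best_K`.
#' @examples
#' d <- data.frame(K = rep(1:4, each = 2),
#'                 lnL = c(-1000, -1000, -600, -600, -580, -580, -575, -575))
#' # supply non-degenerate run scatter for a defined DeltaK
#' @export
evanno_delta_k <- function(runs) {
  if (inherits(runs, "structure_scan")) {
    tab <- runs$lnL
  } else if (is.data.frame(runs)) {
    tab <- runs
  } else {
    tab <- do.call(rbind, lapply(runs, function(r)
      data.frame(K = r$K, lnL = r$lnL)))
  }
  Ks <- sort(unique(tab$K))
  if (length(Ks) < 3 || any(diff(Ks) != 1)) {
    stop("need >= 3 consecutive K values for the Delta-K statistic")
  }
  agg <- data.frame(
    K = Ks,
    n_runs = vapply(Ks, function(k) sum(tab$K == k), integer(1)),
    mean_lnL = vapply(Ks, function(k) mean(tab$lnL[tab$K == k]), numeric(1)),
    sd_lnL = vapply(Ks, function(k) stats::sd(tab$lnL[tab$K == k]), numeric(1))
  )
  m <- nrow(agg)
  agg$Lp <- c(NA, diff(agg$mean_lnL))
  agg$Lpp_abs <- c(NA, abs(diff(agg$Lp[-1])), NA)
  if (m >= 3) {
    for (i in 2:(m - 1)) agg$Lpp_abs[i] <- abs(agg$Lp[i + 1] - agg$Lp[i])
  }
  agg$deltaK <- NA_real_
  interior <- seq_len(m) > 1 & seq_len(m) < m
  ok <- interior & agg$n_runs >= 2 & !is.na(agg$sd_lnL) & agg$sd_lnL > 0
  agg$deltaK[ok] <- agg$Lpp_abs[ok] / agg$sd_lnL[ok]
  if (any(interior & !ok)) {
    warning("DeltaK undefined at K = ",
            paste(agg$K[interior & !ok], collapse = ", "),
            " (fewer than 2 runs or zero run-to-run sd)")
  }
  best <- if (all(is.na(agg$deltaK))) NA_integer_ else
    agg$K[which.max(agg$deltaK)]
  structure(list(table = agg, best_K = best), class = "delta_k_table")
}

#' @export
print.delta_k_table <- function(x, ...) {
  print(format(x$table, digits = 4))
  cat("best K:", x$best_K, "\n")
  invisible(x)
}

#' Classify genotypes by admixture membership
#'
#' Assigns each genotype to its maximum-Q population when that membership
#' reaches `threshold`, otherwise labels it `"admixed"`.
#'
#' @param Q Genotype x K admixture matrix (rows sum to 1).
#' @param threshold Membership threshold, in (1/K, 1\] (default 0.7).
#' @return List: `label` (character vector `pop_k` / `"admixed"`), `counts`
#'   (per label), `admixed_fraction`.
#' @export
assign_membership <- function(Q, threshold = 0.7) {
  Q <- as.matrix(Q)
  K <- ncol(Q)
  if (threshold <= 1 / K || threshold > 1) {
    stop("threshold must lie in (1/K, 1]")
  }
  top <- max.col(Q, ties.method = "first")
  topv <- Q[cbind(seq_len(nrow(Q)), top)]
  lab <- ifelse(topv >= threshold, sprintf("pop_%d", top), "admixed")
  names(lab) <- rownames(Q)
  counts <- table(factor(lab, levels = c(sprintf("pop_%d", seq_len(K)),
                                         "admixed")))
  list(label = lab, counts = counts,
       admixed_fraction = mean(lab == "admixed"))
}

#' Align Q matrices across runs (label switching)
#'
#' Population labels are arbitrary across MCMC runs; this matches columns
#' to a reference run by greedy correlation alignment so runs can be
#' compared or averaged.
#'
#' @param Q_list List of genotype x K matrices (first is the reference).
#' @return List of matrices with columns permuted to match the reference;
#'   attribute `"permutations"` records the column orders used.
#' @export
align_q_runs <- function(Q_list) {
  stopifnot(length(Q_list) >= 1)
  ref <- as.matrix(Q_list[[1]])
  K <- ncol(ref)
  perms <- list(seq_len(K))
  out <- list(ref)
  for (r in seq_along(Q_list)[-1]) {
    Qr <- as.matrix(Q_list[[r]])
    cormat <- suppressWarnings(stats::cor(ref, Qr))
    cormat[!is.finite(cormat)] <- 0
    perm <- integer(K)
    for (step in seq_len(K)) {
      # greedy: take the best remaining (ref column, run column) pair
      best <- which(cormat == max(cormat), arr.ind = TRUE)[1, , drop = TRUE]
      perm[best[1]] <- best[2]
      cormat[best[1], ] <- -Inf
      cormat[, best[2]] <- -Inf
    }
    out[[r]] <- Qr[, perm, drop = FALSE]
    colnames(out[[r]]) <- colnames(ref)
    perms[[r]] <- perm
  }
  attr(out, "permutations") <- perms
  out
}
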