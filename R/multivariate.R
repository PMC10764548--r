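#' Principal component analysis of standardized genotype means
#'
#' PCA on z-scored BLUP means. Constant traits are dropped with a warning.
#'
#' @param blups BLUP table (data frame with `genotype` column) or numeric
#'   matrix.
#' @return List of class `panel_pca`: `scores` (genotype x PC), `loadings`
#'   (trait x PC), `eigenvalues`, `explained` (fraction of variance per
#'   dimension), `traits` (retained trait names).
#' @export
pca_blups <- function(blups) {
  X <- trait_matrix(blups)
  v <- apply(X, 2, stats::var)
  if (any(v == 0)) {
    warning("dropping constant traits: ",
            paste(colnames(X)[v == 0], collapse = ", "))
    X <- X[, v > 0, drop = FALSE]
  }
  if (ncol(X) < 2) stop("need >= 2 traits with non-zero variance")
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  eig <- pc$sdev^2
  out <- list(scores = pc$x, loadings = pc$rotation, eigenvalues = eig,
              explained = eig / sum(eig), traits = colnames(X))
  class(out) <- "panel_pca"
  out
}

#' @export
print.panel_pca <- function(x, ...) {
  cat(sprintf("<panel_pca> %d genotypes, %d traits; Dim1 %.2f%%, Dim2 %.2f%%\n",
              nrow(x$scores), length(x$traits), 100 * x$explained[1],
              100 * x$explained[2]))
  invisible(x)
}

#' Ward clustering of PC coordinates with v-test characterization
#'
#' Hierarchical clustering (Ward linkage on Euclidean distance) of the
#' retained principal-component coordinates. With `k = "auto"` the number of
#' clusters is the one with the largest relative drop in within-cluster
#' inertia (elbow), searched over 2..`k_max`. Cluster labels are
#' canonicalized by decreasing cluster size.
#'
#' Each cluster is characterized against the panel by the v-test
#' `v = (mean_c - mean) / sqrt((s2 / n_c) * (N - n_c) / (N - 1))` per trait,
#' with a two-sided normal p-value.
#'
#' @param pca A `panel_pca` (or a numeric score matrix).
#' @param k Number of clusters, or `"auto"`.
#' @param ndim Number of leading PCs to cluster on (default: PCs with
#'   eigenvalue >= 1 when `pca` is a `panel_pca`, else all columns).
#' @param traits Optional genotype x trait data frame/matrix used for the
#'   v-tests (defaults to the PC scores themselves).
#' @param k_max Upper bound for the automatic k search.
#' @param alpha Significance level for characterizing traits.
#' @return List of class `cluster_report`: `cluster` (named integer vector),
#'   `k`, `vtest` (long data frame: cluster, trait, cluster_mean,
#'   overall_mean, v, p, significant), `hclust`.
#' @export
cluster_pcs <- function(pca, k = "auto", ndim = NULL, traits = NULL,
                        k_max = 10, alpha = 0.05) {
  S <- if (inherits(pca, "panel_pca")) pca$scores else as.matrix(pca)
  if (is.null(ndim)) {
    ndim <- if (inherits(pca, "panel_pca")) max(sum(pca$eigenvalues >= 1), 2)
            else ncol(S)
  }
  ndim <- min(ndim, ncol(S))
  S <- S[, seq_len(ndim), drop = FALSE]
  N <- nrow(S)
  hc <- stats::hclust(stats::dist(S), method = "ward.D2")
  if (identical(k, "auto")) {
    k_max <- min(k_max, N - 1)
    W <- vapply(1:k_max, function(kk) within_inertia(S, stats::cutree(hc, kk)),
                numeric(1))
    rel_loss <- (W[-length(W)] - W[-1]) / pmax(W[-length(W)], .Machine$double.eps)
    k <- which.max(rel_loss) + 1L   # candidate k = 2..k_max
  }
  k <- as.integer(k)
  if (k > N) stop("k exceeds the number of genotypes")
  cl_raw <- stats::cutree(hc, k)
  # canonical labels: 1 = largest cluster
  sizes <- sort(table(cl_raw), decreasing = TRUE)
  relab <- stats::setNames(seq_along(sizes), names(sizes))
  cl <- as.integer(relab[as.character(cl_raw)])
  names(cl) <- rownames(S)

  Xc <- if (is.null(traits)) S else trait_matrix(traits)
  if (is.null(colnames(Xc))) colnames(Xc) <- sprintf("dim_%d", seq_len(ncol(Xc)))
  rows <- list()
  for (cc in seq_len(k)) {
    idx <- cl == cc
    n_c <- sum(idx)
    for (j in seq_len(ncol(Xc))) {
      x <- Xc[, j]
      m_all <- mean(x); s2 <- stats::var(x) * (N - 1) / N
      if (n_c == N || s2 == 0) {
        v <- 0; pv <- 1
      } else {
        v <- (mean(x[idx]) - m_all) /
          sqrt((s2 / n_c) * (N - n_c) / (N - 1))
        pv <- 2 * stats::pnorm(abs(v), lower.tail = FALSE)
      }
      rows[[length(rows) + 1]] <- data.frame(
        cluster = cc, trait = colnames(Xc)[j], n = n_c,
        cluster_mean = mean(x[idx]), overall_mean = m_all, v = v, p = pv,
        significant = pv <= alpha, stringsAsFactors = FALSE)
    }
  }
  out <- list(cluster = cl, k = k, vtest = do.call(rbind, rows), hclust = hc)
  class(out) <- "cluster_report"
  out
}

within_inertia <- function(S, cl) {
  sum(vapply(unique(cl), function(cc) {
    M <- S[cl == cc, , drop = FALSE]
    sum(scale(M, scale = FALSE)^2)
  }, numeric(1)))
}

#' @export
print.cluster_report <- function(x, ...) {
  cat(sprintf("<cluster_report> k = %d; sizes: %s\n", x$k,
              paste(table(x$cluster), collapse = ", ")))
  invisible(x)
}

#' Multi-trait genotype-ideotype distance index (MGIDI)
#'
#' Ranks genotypes by their distance to an ideotype in factor space:
#' (1) each trait is rescaled to 0--100 with 100 at the desirable extreme
#' (the axis is inverted for `"decrease"` objectives); (2) an exploratory
#' factor analysis of the rescaled matrix retains factors with eigenvalue at
#' or above `eigen_threshold`, varimax-rotates the loadings and computes
#' regression-method factor scores; (3) the ideotype (100 on every trait) is
#' projected into the same factor space; (4) the index is the Euclidean
#' distance between each genotype's factor scores and the ideotype's.
#' Lower is better; a genotype holding the best observed value for every
#' trait scores exactly 0.
#'
#' @param blups BLUP table (data frame with `genotype`) or numeric matrix.
#' @param objectives Character vector (`"increase"`/`"decrease"`) per trait;
#'   a single value is recycled. Names, if present, are matched to traits.
#' @param selection_fraction Fraction of genotypes selected (default 0.20).
#' @param eigen_threshold Factor-retention threshold on eigenvalues
#'   (default 1).
#' @param reference Optional genotype id; when given, the selected set is
#'   every genotype with an index strictly below the reference's
#'   (`selection_fraction` is ignored).
#' @param h2 Optional per-trait heritabilities used to convert selection
#'   differentials into expected genetic gains.
#' @return List of class `mgidi_result`: `table` (genotype, mgidi, rank,
#'   selected), `gains` (per trait: objective, panel mean, selected mean,
#'   differential, gain_percent, optionally expected_gain, favorable),
#'   `factors` (loadings, eigenvalues, scores, ideotype scores,
#'   communalities), `n_factors`.
#' @examples
#' X <- matrix(rnorm(200), 50, 4,
#'             dimnames = list(sprintf("G%02d", 1:50), paste0("t", 1:4)))
#' res <- mgidi(X, objectives = "increase")
#' head(res$table)
#' @export
mgidi <- function(blups, objectives, selection_fraction = 0.20,
                  eigen_threshold = 1, reference = NULL, h2 = NULL) {
  X <- trait_matrix(blups)
  p0 <- ncol(X)
  if (length(objectives) == 1) objectives <- rep(objectives, p0)
  if (!is.null(names(objectives))) objectives <- objectives[colnames(X)]
  if (length(objectives) != p0 || anyNA(objectives)) {
    stop("objectives must cover every trait")
  }
  objectives <- match.arg(objectives, c("increase", "decrease"),
                          several.ok = TRUE)

  # direction-aware 0-100 rescale: 100 is always desirable
  keep <- rep(TRUE, p0)
  Xr <- X
  for (j in seq_len(p0)) {
    rng <- range(X[, j])
    if (diff(rng) == 0) { keep[j] <- FALSE; next }
    z <- (X[, j] - rng[1]) / diff(rng) * 100
    Xr[, j] <- if (objectives[j] == "decrease") 100 - z else z
  }
  if (any(!keep)) {
    warning("dropping zero-variance traits: ",
            paste(colnames(X)[!keep], collapse = ", "))
  }
  Xr <- Xr[, keep, drop = FALSE]
  obj <- objectives[keep]
  p <- ncol(Xr)
  if (p < 2) stop("need >= 2 traits with variance for MGIDI")

  R <- stats::cor(Xr)
  ed <- eigen(R, symmetric = TRUE)
  nf <- max(1L, sum(ed$values >= eigen_threshold))
  L <- ed$vectors[, seq_len(nf), drop = FALSE] %*%
    diag(sqrt(ed$values[seq_len(nf)]), nf)
  rownames(L) <- colnames(Xr)
  A <- if (nf > 1) {
    vm <- stats::varimax(L)
    L %*% vm$rotmat
  } else L
  colnames(A) <- sprintf("FA%d", seq_len(nf))

  mu <- colMeans(Xr)
  sdv <- apply(Xr, 2, stats::sd)
  Z <- sweep(sweep(Xr, 2, mu), 2, sdv, "/")
  Rinv <- MASS::ginv(R)
  B <- Rinv %*% A                     # regression-method score coefficients
  Fs <- Z %*% B
  z_ideo <- (100 - mu) / sdv
  F_ideo <- drop(z_ideo %*% B)
  d <- sqrt(rowSums(sweep(Fs, 2, F_ideo)^2))

  rk <- rank(d, ties.method = "first")
  tab <- data.frame(genotype = rownames(X), mgidi = d, rank = rk,
                    stringsAsFactors = FALSE)
  if (!is.null(reference)) {
    if (!reference %in% tab$genotype) stop("reference genotype not in panel")
    cut <- tab$mgidi[tab$genotype == reference]
    tab$selected <- tab$mgidi < cut
  } else {
    n_sel <- max(1L, floor(selection_fraction * nrow(tab)))
    tab$selected <- rk <= n_sel
  }
  tab <- tab[order(tab$rank), ]

  sel <- tab$genotype[tab$selected]
  m_all <- colMeans(X[, keep, drop = FALSE])
  m_sel <- colMeans(X[sel, keep, drop = FALSE])
  diffl <- m_sel - m_all
  gains <- data.frame(
    trait = colnames(Xr), objective = obj, panel_mean = m_all,
    selected_mean = m_sel, differential = diffl,
    gain_percent = ifelse(m_all != 0, 100 * diffl / m_all, NA_real_),
    favorable = (diffl >= 0) == (obj == "increase"),
    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(h2)) {
    h2 <- rep_len(h2, p0)[keep]
    gains$expected_gain <- gains$differential * h2
  }

  out <- list(table = tab, gains = gains,
              factors = list(loadings = A, eigenvalues = ed$values,
                             scores = Fs, ideotype = F_ideo,
                             communalities = rowSums(A^2)),
              n_factors = nf)
  class(out) <- "mgidi_result"
  out
}

#' @export
print.mgidi_result <- function(x, ...) {
  cat(sprintf("<mgidi_result> %d genotypes, %d factors, %d selected\n",
              nrow(x$table), x$n_factors, sum(x$table$selected)))
  cat(sprintf("  index range %.3f - %.3f (mean %.3f)\n",
              min(x$table$mgidi), max(x$table$mgidi), mean(x$table$mgidi)))
  invisible(x)
}

#' Kruskal-Wallis comparison of a quantity across groups
#'
#' Rank-based comparison with tie correction; flags a "tendency" when
#' 0.05 < p <= 0.10.
#'
#' @param values Numeric vector.
#' @param groups Group labels, same length.
#' @param alpha Significance level.
#' @return List: `H` (chi-squared statistic), `df`, `p`, `significant`,
#'   `tendency`, `group_medians`.
#' @export
group_compare <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need >= 2 groups")
  if (any(table(groups) == 0)) stop("every group must be non-empty")
  ok <- is.finite(values)
  if (length(unique(values[ok])) < 2) {
    # all observations tied: no evidence of any group difference
    H <- 0; df <- nlevels(droplevels(groups[ok])) - 1; p <- 1
  } else {
    kt <- stats::kruskal.test(values[ok], groups[ok])
    H <- unname(kt$statistic); df <- unname(kt$parameter); p <- kt$p.value
  }
  list(H = H, df = df, p = p,
       significant = !is.na(p) && p <= alpha,
       tendency = !is.na(p) && p > alpha && p <= 0.10,
       group_medians = tapply(values[ok], groups[ok], stats::median))
}
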