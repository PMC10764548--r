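#' Pairwise Pearson correlations between traits
#'
#' All pairwise Pearson correlations between trait columns of a BLUP table,
#' with two-sided t tests on n - 2 degrees of freedom. Traits with zero
#' variance are excluded and reported in attribute `"dropped"`; pairs with
#' fewer than 3 complete observations are flagged (`NA` estimates).
#'
#' @param blups BLUP table data frame (first column `genotype`) or a numeric
#'   matrix of genotype-by-trait means.
#' @return Long-format data frame: `trait1`, `trait2`, `r`, `p`, `n`; one
#'   row per unordered pair. The full correlation matrix is in attribute
#'   `"R"`.
#' @export
pearson_matrix <- function(blups) {
  X <- trait_matrix(blups)
  if (nrow(X) < 3) stop("need >= 3 genotypes for correlation tests")
  v <- apply(X, 2, stats::var, na.rm = TRUE)
  dropped <- colnames(X)[!is.na(v) & v == 0]
  X <- X[, is.na(v) | v > 0, drop = FALSE]
  traits <- colnames(X)
  p <- length(traits)
  R <- matrix(NA_real_, p, p, dimnames = list(traits, traits))
  diag(R) <- 1
  rows <- list()
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      ok <- stats::complete.cases(X[, c(i, j)])
      n <- sum(ok)
      if (n < 3) {
        rows[[length(rows) + 1]] <- data.frame(
          trait1 = traits[i], trait2 = traits[j], r = NA_real_,
          p = NA_real_, n = n, stringsAsFactors = FALSE)
        next
      }
      r <- stats::cor(X[ok, i], X[ok, j])
      R[i, j] <- R[j, i] <- r
      pval <- if (abs(r) >= 1) 0 else {
        tstat <- r * sqrt((n - 2) / (1 - r^2))
        2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
      }
      rows[[length(rows) + 1]] <- data.frame(
        trait1 = traits[i], trait2 = traits[j], r = r, p = pval, n = n,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "R") <- R
  attr(out, "n") <- nrow(X)
  attr(out, "dropped") <- dropped
  out
}

#' Partial correlations from the inverted correlation matrix
#'
#' Partial correlation of each trait pair controlling for all remaining
#' traits: `r_ij.rest = -W_ij / sqrt(W_ii * W_jj)` with `W` the inverse of
#' the Pearson correlation matrix. Near-singular matrices are
#' ridge-regularized (`eps` added to the diagonal, flagged in attribute
#' `"ridged"`). Significance by t test on `n - 2 - g` degrees of freedom,
#' `g` the number of controlled traits.
#'
#' @param pearson Output of [pearson_matrix()], or a correlation matrix with
#'   attribute handling done by the caller (then `n` must be given).
#' @param n Number of genotypes (taken from `pearson` when available).
#' @param eps Ridge added to the diagonal when inversion fails.
#' @return Long-format data frame `trait1`, `trait2`, `r_partial`,
#'   `p_partial`, `df`.
#' @export
partial_matrix <- function(pearson, n = NULL, eps = 1e-8) {
  if (is.matrix(pearson)) {
    R <- pearson
    if (is.null(n)) stop("n must be supplied with a raw correlation matrix")
  } else {
    R <- attr(pearson, "R")
    n <- attr(pearson, "n")
  }
  if (anyNA(R)) stop("correlation matrix has missing entries")
  p <- ncol(R)
  W <- tryCatch(solve(R), error = function(e) NULL)
  ridged <- FALSE
  if (is.null(W) || !all(is.finite(W)) || kappa(R) > 1e12) {
    W <- tryCatch(solve(R + diag(eps, p)), error = function(e) NULL)
    ridged <- TRUE
    if (is.null(W)) {
      # report which traits are collinear with the rest
      sing <- colnames(R)[abs(eigen(R, symmetric = TRUE)$vectors[,
        which.min(eigen(R, symmetric = TRUE)$values)]) > 0.1]
      stop("correlation matrix singular even after regularization; ",
           "collinear traits: ", paste(sing, collapse = ", "))
    }
  }
  g <- p - 2
  df <- n - 2 - g
  rows <- list()
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      r <- -W[i, j] / sqrt(W[i, i] * W[j, j])
      r <- max(-1, min(1, r))
      pv <- if (df <= 0) NA_real_ else if (abs(r) >= 1) 0 else {
        tstat <- r * sqrt(df / (1 - r^2))
        2 * stats::pt(abs(tstat), df = df, lower.tail = FALSE)
      }
      rows[[length(rows) + 1]] <- data.frame(
        trait1 = colnames(R)[i], trait2 = colnames(R)[j],
        r_partial = r, p_partial = pv, df = df, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "ridged") <- ridged
  out
}

#' Strength label of a correlation coefficient
#'
#' Bands: negligible (|r| < 0.10), weak (0.10--0.39), moderate (0.40--0.69),
#' strong (0.70--0.89), very strong (|r| >= 0.90).
#'
#' @param r Numeric vector of correlations.
#' @return Character vector of strength labels.
#' @export
correlation_strength <- function(r) {
  a <- abs(r)
  out <- rep(NA_character_, length(r))
  out[a < 0.10] <- "negligible"
  out[a >= 0.10 & a < 0.40] <- "weak"
  out[a >= 0.40 & a < 0.70] <- "moderate"
  out[a >= 0.70 & a < 0.90] <- "strong"
  out[a >= 0.90] <- "very strong"
  out
}

#' Robust trait associations: Pearson and partial agreement
#'
#' Merges the marginal and partial correlation reports and partitions pairs
#' into both-significant ("robust"), Pearson-only, and partial-only at level
#' `alpha`, attaching strength labels for the Pearson coefficient. An
#' optional Benjamini-Hochberg correction is available (off by default,
#' matching raw per-test significance usage).
#'
#' @param pearson Output of [pearson_matrix()].
#' @param partial Output of [partial_matrix()].
#' @param alpha Significance level (default 0.05).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Data frame per pair: `trait1`, `trait2`, `r`, `p`, `r_partial`,
#'   `p_partial`, `robust`, `class` (one of `"robust"`, `"pearson_only"`,
#'   `"partial_only"`, `"neither"`), `strength`.
#' @export
robust_pairs <- function(pearson, partial, alpha = 0.05,
                         adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  m <- merge(pearson, partial, by = c("trait1", "trait2"))
  p1 <- m$p; p2 <- m$p_partial
  if (adjust == "BH") {
    p1 <- stats::p.adjust(p1, "BH")
    p2 <- stats::p.adjust(p2, "BH")
  }
  sig1 <- !is.na(p1) & p1 <= alpha
  sig2 <- !is.na(p2) & p2 <= alpha
  m$robust <- sig1 & sig2
  m$class <- ifelse(sig1 & sig2, "robust",
             ifelse(sig1, "pearson_only",
             ifelse(sig2, "partial_only", "neither")))
  m$strength <- correlation_strength(m$r)
  m
}

trait_matrix <- function(blups) {
  if (is.data.frame(blups)) {
    cols <- setdiff(names(blups), c("genotype", "population"))
    X <- as.matrix(blups[, cols, drop = FALSE])
    if (!is.null(blups$genotype)) rownames(X) <- blups$genotype
  } else {
    X <- as.matrix(blups)
    if (is.null(colnames(X))) colnames(X) <- sprintf("trait_%02d", seq_len(ncol(X)))
  }
  storage.mode(X) <- "double"
  X
}
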