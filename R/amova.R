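#' Three-level analysis of molecular variance (AMOVA)
#'
#' Partitions the molecular variance of codominant calls into among
#' populations, among individuals within populations, and within
#' individuals, from sums of squared differences between allele copies
#' (mismatch metric: copies differ or not, summed over loci). Variance
#' components are obtained by equating observed and expected mean squares;
#' the fixation indices are `F_ST` (among populations), `F_IS` (among
#' individuals within populations) and `F_IT` (total), with
#' `(1 - F_IT) = (1 - F_ST)(1 - F_IS)`. Significance is assessed by
#' permutation: individuals among populations for `F_ST`/`F_IT`, allele
#' copies among individuals within populations for `F_IS`.
#'
#' Negative method-of-moments components are reported as estimated and
#' flagged; percentages are computed on the components as reported.
#'
#' @param panel A [marker_panel()].
#' @param populations Population labels (default: the panel's).
#' @param n_perms Number of permutations (default 999).
#' @param seed Integer seed for the permutations.
#' @return List of class `amova_result`: `table` (source, df, SS, MS,
#'   variance, percent), `F_ST`, `F_IS`, `F_IT`, `p_ST`, `p_IS`, `p_IT`,
#'   `n_perms`, `negative_components`.
#' @examples
#' sim <- simulate_markers(panel_config(n_genotypes = 60, seed = 2))
#' amova(sim$panel, n_perms = 99)
#' @export
amova <- function(panel, populations = NULL, n_perms = 999, seed = 1) {
  stopifnot(inherits(panel, "marker_panel"))
  pops <- if (!is.null(populations)) as.character(populations) else panel$populations
  if (is.null(pops)) stop("population assignment required")
  keep <- stats::complete.cases(panel$A1) & stats::complete.cases(panel$A2)
  if (!all(keep)) {
    warning(sum(!keep), " genotypes with missing calls dropped from AMOVA")
  }
  A1 <- panel$A1[keep, , drop = FALSE]
  A2 <- panel$A2[keep, , drop = FALSE]
  pops <- factor(pops[keep])
  n <- nrow(A1); L <- ncol(A1)
  G <- nlevels(pops)
  if (G < 2) stop("need >= 2 populations")
  if (any(table(pops) < 2)) stop("every population needs >= 2 individuals")

  ss <- amova_ss(A1, A2, pops)
  comp <- amova_components(ss, pops)

  set.seed(as.integer(seed))
  perm_ST <- perm_IT <- perm_IS <- numeric(n_perms)   # n_perms = 0 skips tests
  for (b in seq_len(n_perms)) {
    pp <- pops[sample.int(n)]
    cb <- amova_components(amova_ss(A1, A2, pp), pp)
    perm_ST[b] <- cb$F_ST
    perm_IT[b] <- cb$F_IT
  }
  for (b in seq_len(n_perms)) {
    sh <- shuffle_copies_within_pops(A1, A2, pops)
    cb <- amova_components(amova_ss(sh$A1, sh$A2, pops), pops)
    perm_IS[b] <- cb$F_IS
  }
  p_of <- function(obs, perm) {
    if (n_perms == 0) return(NA_real_)
    (sum(perm >= obs - 1e-12) + 1) / (n_perms + 1)
  }

  tab <- data.frame(
    source = c("among_populations", "among_individuals", "within_individuals",
               "total"),
    df = c(ss$df_AP, ss$df_AI, ss$df_WI, ss$df_AP + ss$df_AI + ss$df_WI),
    SS = c(ss$SS_AP, ss$SS_AI, ss$SS_WI, ss$SS_AP + ss$SS_AI + ss$SS_WI),
    MS = c(ss$SS_AP / ss$df_AP, ss$SS_AI / ss$df_AI, ss$SS_WI / ss$df_WI, NA),
    variance = c(comp$s_AP, comp$s_AI, comp$s_WI,
                 comp$s_AP + comp$s_AI + comp$s_WI),
    stringsAsFactors = FALSE)
  total_var <- comp$s_AP + comp$s_AI + comp$s_WI
  tab$percent <- 100 * tab$variance / total_var
  neg <- tab$source[seq_len(3)][tab$variance[seq_len(3)] < 0]

  structure(list(
    table = tab, F_ST = comp$F_ST, F_IS = comp$F_IS, F_IT = comp$F_IT,
    p_ST = p_of(comp$F_ST, perm_ST), p_IS = p_of(comp$F_IS, perm_IS),
    p_IT = p_of(comp$F_IT, perm_IT), n_perms = n_perms,
    negative_components = neg), class = "amova_result")
}

# sums of squared copy differences (mismatch metric), pooled over loci
amova_ss <- function(A1, A2, pops) {
  n <- nrow(A1); L <- ncol(A1); G <- nlevels(pops)
  SS_total <- 0; SS_wp <- 0
  SS_WI <- 0
  for (l in seq_len(L)) {
    copies <- c(A1[, l], A2[, l])
    Tt <- length(copies)
    cnt <- tabulate(copies)
    SS_total <- SS_total + (Tt^2 - sum(cnt^2)) / (2 * Tt)
    for (g in levels(pops)) {
      idx <- which(pops == g)
      cp <- c(A1[idx, l], A2[idx, l])
      tg <- length(cp)
      cg <- tabulate(cp)
      SS_wp <- SS_wp + (tg^2 - sum(cg^2)) / (2 * tg)
    }
    SS_WI <- SS_WI + sum(A1[, l] != A2[, l]) / 2
  }
  list(SS_AP = SS_total - SS_wp, SS_AI = SS_wp - SS_WI, SS_WI = SS_WI,
       df_AP = G - 1, df_AI = n - G, df_WI = n)
}

amova_components <- function(ss, pops) {
  n <- length(pops)
  t_g <- 2 * as.numeric(table(pops))
  Tt <- sum(t_g)
  G <- length(t_g)
  n_c <- (Tt - sum(t_g^2) / Tt) / (G - 1)
  MS_AP <- ss$SS_AP / ss$df_AP
  MS_AI <- ss$SS_AI / ss$df_AI
  MS_WI <- ss$SS_WI / ss$df_WI
  s_WI <- MS_WI
  s_AI <- (MS_AI - MS_WI) / 2
  s_AP <- (MS_AP - MS_AI) / n_c
  tot <- s_AP + s_AI + s_WI
  list(s_AP = s_AP, s_AI = s_AI, s_WI = s_WI,
       F_ST = s_AP / tot,
       F_IS = s_AI / (s_AI + s_WI),
       F_IT = (s_AP + s_AI) / tot)
}

shuffle_copies_within_pops <- function(A1, A2, pops) {
  for (g in levels(pops)) {
    idx <- which(pops == g)
    for (l in seq_len(ncol(A1))) {
      cp <- c(A1[idx, l], A2[idx, l])
      cp <- cp[sample.int(length(cp))]
      A1[idx, l] <- cp[seq_along(idx)]
      A2[idx, l] <- cp[seq_along(idx) + length(idx)]
    }
  }
  list(A1 = A1, A2 = A2)
}

#' @export
print.amova_result <- function(x, ...) {
  print(format(x$table, digits = 4))
  cat(sprintf("F_ST = %.4f (p = %.4g), F_IS = %.4f (p = %.4g), F_IT = %.4f (p = %.4g)\n",
              x$F_ST, x$p_ST, x$F_IS, x$p_IS, x$F_IT, x$p_IT))
  invisible(x)
}

#' Nei standard distance and identity between populations
#'
#' Nei (1972) identity `I = Jxy / sqrt(Jx * Jy)` with `Jxy`, `Jx`, `Jy` the
#' across-locus arithmetic means of `sum(p1*p2)`, `sum(p1^2)`, `sum(p2^2)`,
#' and distance `D = -ln I`. Populations fixed for alternative alleles at
#' every locus give identity 0 and infinite distance (flagged).
#'
#' @param panel A [marker_panel()] with population assignments (or supply
#'   `populations`).
#' @param populations Optional labels overriding the panel's.
#' @return Data frame per population pair: `pop1`, `pop2`, `identity`,
#'   `distance`.
#' @export
pairwise_pop_stats <- function(panel, populations = NULL) {
  pops <- if (!is.null(populations)) as.character(populations) else panel$populations
  if (is.null(pops)) stop("population assignment required")
  upop <- sort(unique(pops))
  if (length(upop) < 2) stop("need >= 2 populations")
  af <- allele_frequencies(marker_panel(panel$A1, panel$A2,
                                        genotypes = panel$genotypes,
                                        loci = panel$loci,
                                        allele_labels = panel$allele_labels,
                                        populations = pops))
  rows <- list()
  for (i in seq_along(upop)[-length(upop)]) {
    for (j in (i + 1):length(upop)) {
      f1 <- af$by_pop[[upop[i]]]
      f2 <- af$by_pop[[upop[j]]]
      jxy <- jx <- jy <- numeric(0)
      for (l in seq_along(f1)) {
        p1 <- f1[[l]]; p2 <- f2[[l]]
        if (is.null(p1) || is.null(p2)) next
        jxy <- c(jxy, sum(p1 * p2))
        jx <- c(jx, sum(p1^2))
        jy <- c(jy, sum(p2^2))
      }
      I <- mean(jxy) / sqrt(mean(jx) * mean(jy))
      D <- if (I > 0) -log(I) else Inf
      rows[[length(rows) + 1]] <- data.frame(
        pop1 = upop[i], pop2 = upop[j], identity = I, distance = D,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
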