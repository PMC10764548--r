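#' Fit the random-genotype mixed model for one trait
#'
#' Fits `y = mu + genotype + block(rep) + e` by REML with genotype and
#' block-within-replicate as independent random effects (the standard model
#' for a resolvable incomplete-block trial with genotypes treated as a
#' random sample of the germplasm). Returns the variance decomposition, the
#' significance of the genotype effect, plot-basis broad-sense heritability
#' and the genetic coefficient of variation.
#'
#' The genotype p-value comes from a REML likelihood-ratio test against the
#' model without the genotype term, referred to the boundary-corrected
#' mixture 0.5*chi2(0) + 0.5*chi2(1) (the null value Vg = 0 sits on the edge
#' of the parameter space).
#'
#' @param trial Field-book data frame (`genotype`, `rep`, `block`, traits).
#' @param trait Name of the trait column to fit.
#' @param grand_mean_source `"raw"` (default) uses the raw plot mean for
#'   CVg; `"blup"` uses the model intercept.
#' @return A one-row data frame of class `variance_decomposition`: `trait`,
#'   `Vg`, `Vblock`, `Ve`, `Vp`, `p_genotype`, `H2`, `CVg_percent`,
#'   `grand_mean`, `n_obs`.
#' @seealso [heritability_and_cvg()], [blup_means()]
#' @export
fit_variance_components <- function(trial, trait,
                                    grand_mean_source = c("raw", "blup")) {
  grand_mean_source <- match.arg(grand_mean_source)
  if (!trait %in% names(trial)) stop("trait '", trait, "' not in trial table")
  d <- data.frame(
    y = trial[[trait]],
    genotype = factor(trial$genotype),
    repf = factor(trial$rep),
    block = factor(paste(trial$rep, trial$block, sep = ":"))
  )
  d <- d[is.finite(d$y), , drop = FALSE]
  if (nrow(d) < 3) stop("too few observations for trait '", trait, "'")
  if (length(unique(d$y)) < 2) stop("trait '", trait, "' has < 2 distinct values")
  if (max(table(d$genotype)) < 2) {
    stop("singular design: no genotype has >= 2 replicate plots")
  }

  # exact noiseless limit: every plot of a genotype identical. The REML
  # surface is flat in Vg/Ve there, so return the limit estimator directly:
  # Vg is the between-genotype variance of plot values, Vblock = Ve = 0.
  wss <- sum((d$y - stats::ave(d$y, d$genotype))^2)
  tss <- sum((d$y - mean(d$y))^2)
  if (wss <= 1e-12 * max(tss, 1)) {
    gm <- mean(d$y)
    Vg <- stats::var(tapply(d$y, d$genotype, mean))
    hc <- heritability_and_cvg(Vg, 0, 0, gm)
    out <- data.frame(trait = trait, Vg = Vg, Vblock = 0, Ve = 0, Vp = Vg,
                      p_genotype = if (Vg > 0) 0 else 1, H2 = hc$H2,
                      CVg_percent = hc$CVg, grand_mean = gm,
                      n_obs = nrow(d), stringsAsFactors = FALSE)
    class(out) <- c("variance_decomposition", class(out))
    return(out)
  }

  fit <- fit_lmm(y ~ 1 + (1 | genotype) + (1 | block), d)
  vc <- as.data.frame(lme4::VarCorr(fit))
  get_v <- function(g) {
    v <- vc$vcov[vc$grp == g]
    if (length(v) == 0) 0 else v
  }
  Vg <- get_v("genotype")
  Vb <- get_v("block")
  Ve <- vc$vcov[vc$grp == "Residual"]

  fit0 <- fit_lmm(y ~ 1 + (1 | block), d)
  lrt <- max(0, 2 * (as.numeric(stats::logLik(fit)) -
                       as.numeric(stats::logLik(fit0))))
  p_gen <- if (lrt == 0) 1 else 0.5 * stats::pchisq(lrt, df = 1, lower.tail = FALSE)

  gm <- if (grand_mean_source == "raw") mean(d$y) else
    as.numeric(lme4::fixef(fit)[1])
  hc <- heritability_and_cvg(Vg, Vb, Ve, gm)

  out <- data.frame(
    trait = trait, Vg = Vg, Vblock = Vb, Ve = Ve, Vp = Vg + Vb + Ve,
    p_genotype = p_gen, H2 = hc$H2, CVg_percent = hc$CVg,
    grand_mean = gm, n_obs = nrow(d), stringsAsFactors = FALSE
  )
  class(out) <- c("variance_decomposition", class(out))
  attr(out, "fit") <- fit
  out
}

fit_lmm <- function(formula, data) {
  ctrl <- lme4::lmerControl(
    check.conv.singular = "ignore",
    optCtrl = list(xtol_abs = 1e-14, ftol_abs = 1e-14, xtol_rel = 0,
                   ftol_rel = 0, maxeval = 100000)
  )
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(formula, data = data, REML = TRUE, control = ctrl)
  ))
  if (inherits(fit, "try-error")) stop("REML fit failed to converge")
  fit
}

#' Plot-basis heritability and genetic coefficient of variation
#'
#' `H2 = Vg / (Vg + Vblock + Ve)` (plot basis: the phenotypic variance is
#' the sum of all three components) and `CVg = 100 * sqrt(Vg) / grand_mean`.
#'
#' @param Vg,Vblock,Ve Variance components (or a `variance_decomposition`
#'   row as `Vg`, in which case the other components are taken from it).
#' @param grand_mean Trait grand mean used to scale CVg.
#' @return List with `H2` (fraction) and `CVg` (percent). `CVg` is `NA` with
#'   a warning when `grand_mean` is 0.
#' @examples
#' heritability_and_cvg(13754, 9005, 28638, 700)$H2  # ~0.27
#' @export
heritability_and_cvg <- function(Vg, Vblock = NULL, Ve = NULL, grand_mean) {
  if (inherits(Vg, "variance_decomposition") ||
      (is.data.frame(Vg) && all(c("Vg", "Vblock", "Ve") %in% names(Vg)))) {
    vd <- Vg; Vg <- vd$Vg; Vblock <- vd$Vblock; Ve <- vd$Ve
  }
  if (any(c(Vg, Vblock, Ve) < 0)) stop("variance components must be >= 0")
  Vp <- Vg + Vblock + Ve
  if (Vp <= 0) stop("Vp must be positive")
  H2 <- Vg / Vp
  if (Vg == 0) {
    CVg <- 0
  } else if (grand_mean == 0) {
    warning("grand mean is 0: CVg undefined")
    CVg <- NA_real_
  } else {
    CVg <- 100 * sqrt(Vg) / grand_mean
  }
  list(H2 = H2, CVg = CVg)
}

#' Variance decomposition for every trait in a field book
#'
#' @param trial Field-book data frame.
#' @param traits Trait columns to fit (default: all non-design columns).
#' @param ... Passed to [fit_variance_components()].
#' @return Data frame with one `variance_decomposition` row per trait.
#' @export
fit_all_traits <- function(trial, traits = NULL, ...) {
  if (is.null(traits)) traits <- setdiff(names(trial), c("genotype", "rep", "block"))
  out <- lapply(traits, function(tr) {
    vd <- fit_variance_components(trial, tr, ...)
    attr(vd, "fit") <- NULL
    vd
  })
  do.call(rbind, out)
}

#' BLUP-adjusted genotype means
#'
#' Predicts the random genotype effects from the REML fit (mixed-model
#' equations at the estimated variance components) and returns
#' `mu + effect` per genotype: shrunken genotype means on the trait scale.
#'
#' @param trial Field-book data frame.
#' @param traits Trait columns (default: all non-design columns).
#' @return Data frame, genotypes x traits, first column `genotype`.
#' @examples
#' sim <- simulate_trial(panel_config(n_traits = 3, seed = 7))
#' head(blup_means(sim$trial))
#' @export
blup_means <- function(trial, traits = NULL) {
  if (is.null(traits)) traits <- setdiff(names(trial), c("genotype", "rep", "block"))
  genos <- sort(unique(trial$genotype))
  out <- data.frame(genotype = genos, stringsAsFactors = FALSE)
  for (tr in traits) {
    vd <- fit_variance_components(trial, tr)
    fit <- attr(vd, "fit")
    if (is.null(fit)) {          # noiseless limit: no shrinkage
      out[[tr]] <- as.numeric(tapply(trial[[tr]], trial$genotype, mean)[genos])
      next
    }
    mu <- as.numeric(lme4::fixef(fit)[1])
    re <- lme4::ranef(fit)$genotype
    eff <- stats::setNames(re[, 1], rownames(re))
    out[[tr]] <- mu + ifelse(genos %in% names(eff), eff[genos], 0)
  }
  out
}

#' @export
print.variance_decomposition <- function(x, ...) {
  y <- x; class(y) <- "data.frame"
  print(format(y, digits = 4), ...)
  invisible(x)
}
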