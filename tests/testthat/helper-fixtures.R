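# small deterministic fixtures used across test files

# balanced complete design: every genotype once per rep, block == rep
balanced_trial <- function(n_geno = 20, n_rep = 3, Vg = 4, Vb = 1, Ve = 1,
                           mu = 50, seed = 1) {
  set.seed(seed)
  d <- expand.grid(genotype = sprintf("g%02d", seq_len(n_geno)),
                   rep = sprintf("R%d", seq_len(n_rep)),
                   stringsAsFactors = FALSE)
  d$block <- "B1"
  g <- rnorm(n_geno, 0, sqrt(Vg))
  b <- rnorm(n_rep, 0, sqrt(Vb))
  d$y <- mu + g[as.integer(factor(d$genotype))] +
    b[as.integer(factor(d$rep))] + rnorm(nrow(d), 0, sqrt(Ve))
  d
}

# expected-mean-squares ANOVA estimator for the balanced two-way design
ems_components <- function(d) {
  g <- length(unique(d$genotype))
  r <- length(unique(d$rep))
  m <- tapply(d$y, list(d$genotype, d$rep), mean)
  MSG <- r * var(rowMeans(m))
  MSB <- g * var(colMeans(m))
  MSE <- sum((d$y - ave(d$y, d$genotype) - ave(d$y, d$rep) + mean(d$y))^2) /
    ((g - 1) * (r - 1))
  list(Vg = (MSG - MSE) / r, Vb = (MSB - MSE) / g, Ve = MSE)
}

# tiny codominant panel from explicit allele matrices
tiny_panel <- function(A1, A2, pops = NULL) {
  marker_panel(A1, A2, populations = pops)
}

# accuracy of a 2-population membership labelling against a true split,
# maximized over the label permutation; "admixed" counts as wrong
assignment_accuracy <- function(labels, truth_pop1) {
  p1 <- labels == "pop_1"
  p2 <- labels == "pop_2"
  max(mean((p1 & truth_pop1) | (p2 & !truth_pop1)),
      mean((p2 & truth_pop1) | (p1 & !truth_pop1)))
}
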