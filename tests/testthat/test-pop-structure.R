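test_that("K = 1 admixture collapses to the single-population likelihood", {
  cfg <- panel_config(n_genotypes = 50, n_loci = 10, alleles_per_locus = 3,
                      target_Fst = 0, K_true = 1, admixture_alpha = 0,
                      inbreeding_F = 0.5, seed = 1)
  sim <- simulate_markers(cfg)
  run <- admixture_gibbs(sim$panel, K = 1, sweeps = 400, burn_in = 200,
                         seed = 2)
  expect_true(all(run$Q == 1))
  # multinomial log-likelihood at the posterior-mean frequencies
  lnL_ref <- 0
  for (l in seq_along(sim$panel$loci)) {
    p <- run$P[[l]][1, ]
    a <- c(sim$panel$A1[, l], sim$panel$A2[, l])
    lnL_ref <- lnL_ref + sum(log(p[a[!is.na(a)]]))
  }
  expect_lt(abs(run$lnL - lnL_ref) / abs(lnL_ref), 0.02)
})

test_that("two diverged populations are recovered from the admixture posterior", {
  cfg <- panel_config(n_genotypes = 100, n_loci = 20,
                      alleles_per_locus = rep(c(3, 6), 10), target_Fst = 0.3,
                      admixture_alpha = 0, inbreeding_F = 0.85, seed = 3)
  sim <- simulate_markers(cfg)
  run <- admixture_gibbs(sim$panel, K = 2, sweeps = 1000, burn_in = 500,
                         seed = 4)
  mem <- assign_membership(run$Q, 0.7)
  acc <- assignment_accuracy(mem$label, sim$truth$Q[, 1] > 0.5)
  expect_gt(acc, 0.9)
  expect_true(all(abs(rowSums(run$Q) - 1) < 1e-9))
})

test_that("runs with different seeds agree up to column permutation", {
  cfg <- panel_config(n_genotypes = 60, n_loci = 15, alleles_per_locus = 4,
                      target_Fst = 0.3, admixture_alpha = 0, seed = 5)
  sim <- simulate_markers(cfg)
  r1 <- admixture_gibbs(sim$panel, K = 2, sweeps = 800, burn_in = 400, seed = 10)
  r2 <- admixture_gibbs(sim$panel, K = 2, sweeps = 800, burn_in = 400, seed = 77)
  aligned <- align_q_runs(list(r1$Q, r2$Q))
  expect_lt(max(abs(aligned[[1]] - aligned[[2]])), 0.25)
  expect_gt(cor(aligned[[1]][, 1], aligned[[2]][, 1]), 0.9)
})

test_that("sampler contract errors fire", {
  cfg <- panel_config(n_genotypes = 10, n_loci = 3, alleles_per_locus = 3,
                      seed = 6)
  sim <- simulate_markers(cfg)
  expect_error(admixture_gibbs(sim$panel, K = 0), "K must be")
  expect_error(admixture_gibbs(sim$panel, K = 50), "exceeds")
  pan <- sim$panel
  pan$A1[, 2] <- NA
  pan$A2[, 2] <- NA
  expect_error(admixture_gibbs(pan, K = 2), "no scored call")
})

test_that("Evanno Delta-K reproduces hand arithmetic", {
  # L(K) = (-1000, -600, -580, -575) with run sd 5 at every K
  lnL <- c(-1000, -600, -580, -575)
  tab <- data.frame(K = rep(1:4, each = 3),
                    lnL = rep(lnL, each = 3) + rep(c(-5, 0, 5), 4))
  dk <- evanno_delta_k(tab)
  expect_equal(dk$table$sd_lnL, rep(5, 4))
  expect_equal(dk$table$deltaK[dk$table$K == 2], 380 / 5)
  expect_equal(dk$table$deltaK[dk$table$K == 3], 15 / 5)
  expect_equal(dk$best_K, 2)
  # scale invariance: adding a constant changes nothing
  tab2 <- tab; tab2$lnL <- tab2$lnL + 12345
  expect_equal(evanno_delta_k(tab2)$table$deltaK, dk$table$deltaK)
  # too narrow a K range
  expect_error(evanno_delta_k(tab[tab$K <= 2, ]), "3 consecutive")
  # zero sd flagged
  tab3 <- tab; tab3$lnL[tab3$K == 2] <- -600
  expect_warning(dk3 <- evanno_delta_k(tab3), "undefined")
  expect_true(is.na(dk3$table$deltaK[dk3$table$K == 2]))
})

test_that("membership thresholding follows the 0.7 rule", {
  Q <- rbind(a = c(0.95, 0.05), b = c(0.6, 0.4), c = c(0.3, 0.7))
  m <- assign_membership(Q, 0.7)
  expect_equal(unname(m$label), c("pop_1", "admixed", "pop_2"))
  expect_equal(m$admixed_fraction, 1 / 3)
  m1 <- assign_membership(Q, 1.0)
  expect_equal(unname(m1$label), c("admixed", "admixed", "admixed"))
  expect_error(assign_membership(Q, 0.4), "threshold")
  expect_error(assign_membership(Q, 1.2), "threshold")
})

test_that("Nei identity and distance are mutually consistent", {
  # identical profiles: identity 1, distance 0
  A <- matrix(rep(1:2, each = 10), ncol = 1)
  pan <- marker_panel(rbind(A, A), rbind(A, A),
                      populations = rep(c("P1", "P2"), each = 20))
  ps <- pairwise_pop_stats(pan)
  expect_equal(ps$identity, 1, tolerance = 1e-12)
  expect_equal(ps$distance, 0, tolerance = 1e-12)
  # identity 0.79 corresponds to distance -ln(0.79) ~ 0.236
  expect_equal(-log(0.79), 0.2357, tolerance = 1e-3)
  # alternative fixation: identity 0, infinite distance
  A1 <- matrix(1, 10, 1); A2 <- matrix(2, 10, 1)
  pan2 <- marker_panel(rbind(A1, A2), rbind(A1, A2),
                       populations = rep(c("P1", "P2"), each = 10))
  ps2 <- pairwise_pop_stats(pan2)
  expect_equal(ps2$identity, 0)
  expect_true(is.infinite(ps2$distance))
})
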