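test_that("default trial layout mirrors a two-rep alpha-lattice of 264 plots", {
  sim <- simulate_trial(panel_config(seed = 1))
  expect_equal(nrow(sim$trial), 264)
  expect_true(all(table(sim$trial$genotype) == 2))
  # 12 blocks of 11 plots within each replicate
  for (r in unique(sim$trial$rep)) {
    tb <- table(sim$trial$block[sim$trial$rep == r])
    expect_length(tb, 12)
    expect_true(all(tb == 11))
    # each genotype exactly once per replicate (resolvable design)
    expect_true(all(table(sim$trial$genotype[sim$trial$rep == r]) == 1))
  }
})

test_that("target_H2 = 1 gives identical plot values per genotype", {
  cfg <- panel_config(n_genotypes = 20, n_traits = 2, target_H2 = 1, seed = 3)
  sim <- simulate_trial(cfg)
  spread <- tapply(sim$trial$trait_01, sim$trial$genotype,
                   function(v) diff(range(v)))
  expect_true(all(spread < 1e-10))
})

test_that("generating components hit target_H2 exactly by construction", {
  cfg <- panel_config(n_traits = 5, target_H2 = c(0, 0.25, 0.5, 0.75, 0.98),
                      seed = 2)
  sim <- simulate_trial(cfg)
  vc <- sim$truth$variance_components
  expect_equal(vc$Vg / (vc$Vg + vc$Vblock + vc$Ve), cfg$target_H2,
               tolerance = 1e-12)
})

test_that("REML recovers the simulated heritability on average", {
  # Monte-Carlo recovery at H2 = 0.5; modest replication keeps the run short
  cfg <- panel_config(n_genotypes = 120, n_traits = 1, target_H2 = 0.5,
                      trait_means = 50, seed = 10)
  h2 <- vapply(1:40, function(s) {
    cfg$seed <- 1000L + s
    fit_variance_components(simulate_trial(cfg)$trial, "trait_01")$H2
  }, numeric(1))
  expect_lt(abs(mean(h2) - 0.5), 0.05)
})

test_that("infeasible layouts are rejected with a layout error", {
  expect_error(panel_config(n_genotypes = 200, n_blocks_per_rep = 2,
                            plots_per_block = 10), "infeasible layout")
})

test_that("marker generator respects its degenerate limits", {
  # no divergence: AMOVA-based Fst near zero across many loci
  cfg0 <- panel_config(n_genotypes = 80, n_loci = 50,
                       alleles_per_locus = 4, target_Fst = 0,
                       admixture_alpha = 0, inbreeding_F = 0.5, seed = 7)
  sm0 <- simulate_markers(cfg0)
  am <- amova(sm0$panel, n_perms = 0)
  expect_lt(abs(am$F_ST), 0.02)

  # full selfing: Ho = 0 at every locus
  cfg1 <- panel_config(n_genotypes = 40, inbreeding_F = 1, seed = 8)
  ld <- locus_diversity(simulate_markers(cfg1)$panel)
  expect_true(all(ld$Ho == 0))
})

test_that("observed heterozygosity tracks (1 - F) * He in expectation", {
  cfg <- panel_config(n_genotypes = 300, n_loci = 30, alleles_per_locus = 4,
                      target_Fst = 0, admixture_alpha = 0,
                      inbreeding_F = 0.6, seed = 21)
  ld <- locus_diversity(simulate_markers(cfg)$panel)
  expect_lt(abs(mean(ld$Ho) - 0.4 * mean(ld$He)), 0.03)
})

test_that("mean estimated Fst tracks the divergence target across seeds", {
  for (fst in c(0, 0.15, 0.3)) {
    est <- vapply(1:15, function(s) {
      cfg <- panel_config(n_genotypes = 100, n_loci = 20,
                          alleles_per_locus = 4, target_Fst = fst,
                          admixture_alpha = 0, inbreeding_F = 0.8,
                          seed = 500L + round(1000 * fst) + s)
      amova(simulate_markers(cfg)$panel, n_perms = 0)$F_ST
    }, numeric(1))
    expect_lt(abs(mean(est) - fst), 0.05)
  }
})

test_that("fixture files round-trip and stay mutually consistent", {
  cfg <- panel_config(n_genotypes = 15, n_traits = 3, n_loci = 4,
                      alleles_per_locus = c(2, 3, 4, 10), seed = 5)
  tr <- simulate_trial(cfg)
  mk <- simulate_markers(cfg)
  dir <- tempfile("fix")
  write_fixture_set(tr$trial, mk$panel, dir, truth = list(seed = cfg$seed))
  rt <- read_fixture_set(dir)
  expect_equal(rt$trial, tr$trial, tolerance = 1e-12)
  expect_equal(codominant_table(rt$panel), codominant_table(mk$panel))
  # band view derivable from codominant view
  bm_file <- read_band_matrix(file.path(dir, "bands.csv"))
  expect_equal(unname(band_matrix(bm_file)[, colnames(band_matrix(mk$panel))[
    colSums(band_matrix(mk$panel), na.rm = TRUE) > 0]]),
    unname(band_matrix(mk$panel)[, colSums(band_matrix(mk$panel),
                                           na.rm = TRUE) > 0]))
  expect_equal(rt$truth$seed, cfg$seed)
  expect_error(write_fixture_set(tr$trial[0, ], mk$panel, tempfile()),
               "empty panel")
})
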