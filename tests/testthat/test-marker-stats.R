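test_that("allele frequencies count codominant calls correctly", {
  # 4 homozygotes: 2 of allele 1, 2 of allele 2 -> p = (0.5, 0.5)
  A <- matrix(c(1, 1, 2, 2), 4, 1)
  pan <- tiny_panel(A, A)
  af <- allele_frequencies(pan)
  expect_equal(unname(af$total[[1]]), c(0.5, 0.5))
  # heterozygotes and missing calls
  A1 <- matrix(c(1, 1, NA, 2), 4, 1)
  A2 <- matrix(c(2, 1, NA, 2), 4, 1)
  af2 <- allele_frequencies(tiny_panel(A1, A2))
  expect_equal(unname(af2$total[[1]]), c(3, 3) / 6)
})

test_that("rare-allele pooling merges low-frequency classes", {
  p <- c(a = 0.90, b = 0.06, c = 0.03, d = 0.01)
  # pool at 0.05: c and d merge, b stays
  pooled <- allele_frequencies(
    tiny_panel(matrix(rep(1:4, c(90, 6, 3, 1)), ncol = 1),
               matrix(rep(1:4, c(90, 6, 3, 1)), ncol = 1)),
    pool_threshold = 0.05)$total[[1]]
  expect_equal(unname(pooled), c(0.90, 0.06, 0.04))
  expect_equal(sum(pooled), 1)
  expect_equal(names(pooled)[3], "pooled")
})

test_that("rare-allele census matches direct enumeration", {
  set.seed(1)
  counts <- c(60, 20, 8, 5, 5, 5, 5, 4, 4, 4, 2, 2, 2, 1, 1, 1, 1, 1, 1, 1)
  # frequencies: 6 alleles strictly above 5/133... compute via the module
  A <- matrix(rep(seq_along(counts), counts), ncol = 1)
  ld <- locus_diversity(tiny_panel(A, A))
  p <- counts / sum(counts)
  expect_equal(ld$rare_alleles, sum(p <= 0.05))
  expect_equal(ld$Na, 20)
})

test_that("locus diversity reproduces the closed-form identities", {
  # equifrequent biallelic locus: He = 0.5, Ne = 2, I = ln 2, Ho = 0
  A <- matrix(rep(1:2, each = 10), ncol = 1)
  ld <- locus_diversity(tiny_panel(A, A))
  expect_equal(ld$He, 0.5, tolerance = 1e-12)
  expect_equal(ld$Ne, 2.0, tolerance = 1e-12)
  expect_equal(ld$I, log(2), tolerance = 1e-12)
  expect_equal(ld$Ho, 0)
  expect_equal(ld$PIC, 0.5, tolerance = 1e-12)

  # four equifrequent alleles
  A4 <- matrix(rep(1:4, each = 5), ncol = 1)
  ld4 <- locus_diversity(tiny_panel(A4, A4))
  expect_equal(ld4$He, 0.75, tolerance = 1e-12)
  expect_equal(ld4$Ne, 4, tolerance = 1e-12)
  expect_equal(ld4$PIC, 0.75, tolerance = 1e-12)

  # monomorphic locus
  Am <- matrix(1, 10, 1)
  ldm <- locus_diversity(tiny_panel(Am, Am))
  expect_equal(ldm[, c("Na", "Ne", "I", "Ho", "He", "PIC")],
               data.frame(Na = 1L, Ne = 1, I = 0, Ho = 0, He = 0, PIC = 0),
               ignore_attr = TRUE)
})

test_that("He = 1 - 1/Ne holds for every simulated locus", {
  sim <- simulate_markers(panel_config(seed = 4))
  ld <- locus_diversity(sim$panel)
  expect_equal(ld$He, 1 - 1 / ld$Ne, tolerance = 1e-12)
})

test_that("discriminating power uses genotype-pattern confusion probabilities", {
  # patterns: 3x (1/1), 1x (2/2) -> C = sum g(Ng-1)/(N-1), D = 1 - C
  A1 <- matrix(c(1, 1, 1, 2), 4, 1)
  ld <- locus_diversity(tiny_panel(A1, A1))
  g <- c(3, 1) / 4
  expect_equal(ld$D, 1 - sum(g * (4 * g - 1) / 3), tolerance = 1e-12)
})

test_that("band-matrix conversion round-trips codominant calls", {
  sim <- simulate_markers(panel_config(n_genotypes = 25, seed = 6))
  bm <- band_matrix(sim$panel)
  back <- bands_to_panel(bm)
  expect_equal(codominant_table(back)[, back$loci],
               codominant_table(sim$panel)[, sim$panel$loci],
               ignore_attr = TRUE)
  # >2 bands flagged and reduced
  b3 <- rbind(g1 = c(1, 1, 1), g2 = c(1, 0, 0), g3 = c(1, 1, 0))
  colnames(b3) <- c("L1.a", "L1.b", "L1.c")
  pan3 <- bands_to_panel(b3)
  expect_match(attr(pan3, "flagged"), "L1:g1")
  expect_error(bands_to_panel(matrix(2, 1, 1,
                                     dimnames = list("g", "L1.a"))),
               "non-binary")
})

test_that("private alleles match the exhaustive set-difference oracle", {
  cfg <- panel_config(n_genotypes = 60, target_Fst = 0.3,
                      admixture_alpha = 0, seed = 9)
  sim <- simulate_markers(cfg)
  pa <- private_alleles(sim$panel)
  pops <- sim$panel$populations
  # brute force: per locus, alleles seen in exactly one population
  expected <- 0
  for (l in seq_along(sim$panel$loci)) {
    seen <- lapply(unique(pops), function(pp) {
      idx <- pops == pp
      unique(na.omit(c(sim$panel$A1[idx, l], sim$panel$A2[idx, l])))
    })
    all_seen <- unlist(seen)
    expected <- expected + sum(table(all_seen) == 1)
  }
  expect_equal(nrow(pa), expected)
  # allele present in both populations is never private
  if (nrow(pa) > 0) {
    for (r in seq_len(min(3, nrow(pa)))) {
      l <- match(pa$locus[r], sim$panel$loci)
      a <- match(pa$allele[r], sim$panel$allele_labels[[l]])
      other <- pops != pa$population[r]
      expect_false(any(sim$panel$A1[other, l] %in% a |
                         sim$panel$A2[other, l] %in% a, na.rm = TRUE))
    }
  }
  # single population: empty result with warning
  expect_warning(
    pa1 <- private_alleles(sim$panel, populations = rep("P", 60)),
    "fewer than 2")
  expect_equal(nrow(pa1), 0)
})
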