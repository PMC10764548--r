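test_that("Jaccard dissimilarity matches hand-enumerated band counts", {
  b <- rbind(g1 = c(1, 1, 0, 1), g2 = c(1, 0, 1, 1), g3 = c(0, 0, 1, 0),
             g4 = c(1, 1, 0, 1))
  D <- jaccard_matrix(b)
  expect_equal(D["g1", "g2"], 0.5)          # a=2, b=1, c=1
  expect_equal(D["g1", "g3"], 1)            # disjoint profiles
  expect_equal(D["g1", "g4"], 0)            # identical: duplicate detection
  expect_equal(D, t(D))
  expect_equal(diag(D), c(g1 = 0, g2 = 0, g3 = 0, g4 = 0))
  dup <- find_duplicates(D)
  expect_equal(dup$genotype1, "g1")
  expect_equal(dup$genotype2, "g4")
})

test_that("joint absences are ignored and uninformative pairs flagged", {
  b <- rbind(x = c(1, 0, 0, 1), y = c(1, 0, 0, 1), z = c(NA, NA, NA, NA))
  D <- jaccard_matrix(b)
  expect_equal(D["x", "y"], 0)     # two joint absences carry no weight
  expect_true(is.na(D["z", "x"]))  # z unscored: no pairwise-complete band
  expect_true("x|z" %in% attr(D, "flagged_pairs") ||
                "z|x" %in% attr(D, "flagged_pairs"))
})

test_that("neighbor joining is exact on additive tree metrics", {
  # fixed 6-taxon additive tree; NJ must reproduce its path-length matrix
  ref <- ape::read.tree(text =
    "((A:1,B:2):1.5,((C:0.5,D:1):2,(E:3,F:1):0.5):1);")
  dm <- ape::cophenetic.phylo(ref)
  tree <- neighbor_joining(dm)
  expect_equal(ape::cophenetic.phylo(tree)[rownames(dm), colnames(dm)], dm,
               tolerance = 1e-10)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(ref), tree)), 0)
  # 3 taxa: closed-form three-point branch lengths
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t3 <- neighbor_joining(d3)
  len <- setNames(t3$edge.length, t3$tip.label[t3$edge[, 2]])
  expect_equal(unname(len[c("a", "b", "c")]), c(1, 2, 3))
})

test_that("NJ topology is invariant to taxon input order", {
  set.seed(1)
  b <- matrix(rbinom(10 * 40, 1, 0.4), 10, 40,
              dimnames = list(sprintf("g%02d", 1:10), NULL))
  D <- jaccard_matrix(b)
  t1 <- neighbor_joining(D)
  ord <- sample(10)
  t2 <- neighbor_joining(D[ord, ord])
  expect_equal(as.numeric(ape::dist.topo(t1, t2)), 0)
})

test_that("a duplicated taxon forms a zero-length cherry", {
  set.seed(2)
  b <- matrix(rbinom(5 * 30, 1, 0.5), 5, 30,
              dimnames = list(c("a", "b", "c", "d", "e"), NULL))
  b <- rbind(b, a2 = b["a", ])
  D <- jaccard_matrix(b)
  tree <- neighbor_joining(D)
  cp <- ape::cophenetic.phylo(tree)
  expect_equal(cp["a", "a2"], 0, tolerance = 1e-10)
  expect_error(neighbor_joining(matrix(c(0, NA, NA, 0), 2,
                                       dimnames = list(c("a", "b"),
                                                       c("a", "b")))),
               "missing|>= 3")
})

test_that("bootstrap supports separate simulated clades and are deterministic", {
  cfg <- panel_config(n_genotypes = 24, n_loci = 25, alleles_per_locus = 4,
                      target_Fst = 0.4, admixture_alpha = 0, seed = 12)
  sim <- simulate_markers(cfg)
  bm <- band_matrix(sim$panel)
  bs <- bootstrap_support(bm, n_reps = 100, seed = 3)
  # the deepest split should have solid support under strong divergence
  expect_gt(max(bs$support, na.rm = TRUE), 0.95)
  # determinism and {0,1} supports at a single replicate
  b1 <- bootstrap_support(bm, n_reps = 1, seed = 9)
  b2 <- bootstrap_support(bm, n_reps = 1, seed = 9)
  expect_equal(b1$support, b2$support)
  expect_true(all(b1$support %in% c(0, 1)))
  expect_error(bootstrap_support(bm, n_reps = 0), "n_reps")
  # Newick export carries support labels
  f <- tempfile(fileext = ".nwk")
  ape::write.tree(bs$tree, f)
  expect_true(any(grepl("0\\.", readLines(f))))
})

test_that("support is stable in expectation under uniform band duplication", {
  set.seed(4)
  b <- matrix(rbinom(8 * 30, 1, 0.5), 8, 30,
              dimnames = list(sprintf("g%d", 1:8), NULL))
  s1 <- bootstrap_support(b, n_reps = 150, seed = 5)$support
  s2 <- bootstrap_support(cbind(b, b), n_reps = 150, seed = 6)$support
  expect_lt(mean(abs(sort(s1) - sort(s2))), 0.15)
})

test_that("dissimilarity summary reports mean, sd and a histogram", {
  set.seed(5)
  b <- matrix(rbinom(12 * 50, 1, 0.5), 12, 50,
              dimnames = list(sprintf("g%02d", 1:12), NULL))
  D <- jaccard_matrix(b)
  ds <- dissimilarity_summary(D)
  expect_equal(ds$mean, mean(D[upper.tri(D)]))
  expect_equal(sum(ds$histogram$counts), choose(12, 2))
})
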