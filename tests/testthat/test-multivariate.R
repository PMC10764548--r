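test_that("PCA on standardized traits conserves total variance", {
  set.seed(1)
  X <- matrix(rnorm(50 * 6), 50, 6)
  pc <- pca_blups(X)
  expect_equal(sum(pc$eigenvalues), 6, tolerance = 1e-9)
  expect_equal(sum(pc$explained), 1, tolerance = 1e-12)
})

test_that("two perfectly correlated traits load on a single component", {
  set.seed(2)
  x <- rnorm(40)
  pc <- pca_blups(cbind(a = x, b = 2 * x + 5))
  expect_equal(pc$explained[1], 1, tolerance = 1e-9)
})

test_that("leading null eigenvalue sits near the Marchenko-Pastur edge", {
  set.seed(3)
  n <- 132; p <- 28
  top <- vapply(1:30, function(i) pca_blups(matrix(rnorm(n * p), n, p))$eigenvalues[1],
                numeric(1))
  edge <- (1 + sqrt(p / n))^2
  expect_lt(abs(mean(top) - edge), 0.35)
})

test_that("well-separated blobs are recovered exactly, with auto k", {
  set.seed(4)
  centers <- rbind(c(0, 0), c(12, 0), c(0, 12))
  lab <- rep(1:3, each = 20)
  S <- centers[lab, ] + matrix(rnorm(120, 0, 0.5), 60, 2)
  rownames(S) <- sprintf("g%02d", 1:60)
  cr <- cluster_pcs(S, k = "auto", ndim = 2)
  expect_equal(cr$k, 3)
  expect_equal(length(unique(paste(lab, cr$cluster))), 3)
})

test_that("v-tests match the brute-force formula and vanish for the whole panel", {
  set.seed(5)
  X <- matrix(rnorm(10 * 3), 10, 3, dimnames = list(sprintf("g%d", 1:10),
                                                    c("a", "b", "c")))
  cr <- cluster_pcs(X, k = 2, ndim = 3, traits = X)
  N <- 10
  for (row in seq_len(nrow(cr$vtest))) {
    tr <- cr$vtest$trait[row]; cc <- cr$vtest$cluster[row]
    idx <- cr$cluster == cc; n_c <- sum(idx)
    x <- X[, tr]
    s2 <- var(x) * (N - 1) / N
    v_ref <- (mean(x[idx]) - mean(x)) / sqrt((s2 / n_c) * (N - n_c) / (N - 1))
    expect_equal(cr$vtest$v[row], v_ref, tolerance = 1e-12)
  }
  cr1 <- cluster_pcs(X, k = 1, ndim = 3)
  expect_true(all(cr1$vtest$v == 0))
  expect_error(cluster_pcs(X, k = 50), "exceeds")
})

test_that("a genotype holding every best value has MGIDI 0 and rank 1", {
  set.seed(6)
  X <- matrix(rnorm(40 * 6), 40, 6,
              dimnames = list(sprintf("g%02d", 1:40), sprintf("t%d", 1:6)))
  obj <- c("increase", "decrease", "increase", "increase", "decrease", "increase")
  best <- ifelse(obj == "increase", apply(X, 2, max), apply(X, 2, min))
  X[7, ] <- best
  res <- mgidi(X, obj)
  expect_lt(res$table$mgidi[res$table$genotype == "g07"], 1e-8)
  expect_equal(res$table$rank[res$table$genotype == "g07"], 1)
})

test_that("with exactly uncorrelated traits the factor space is diagonal", {
  # orthogonal design: zero sample correlations, so loadings are the
  # identity and MGIDI reduces to Euclidean distance on standardized
  # rescaled traits (the diagonal-loading oracle)
  set.seed(11)
  C <- scale(matrix(rnorm(80), 20, 4), center = TRUE, scale = FALSE)
  H <- qr.Q(qr(C))   # orthonormal columns, each summing to zero
  X <- H * 10 + 100
  colnames(X) <- sprintf("t%d", 1:4)
  rownames(X) <- sprintf("g%d", 1:20)
  res <- mgidi(X, "increase", eigen_threshold = 0)   # retain all factors
  m <- res$table$mgidi[match(rownames(X), res$table$genotype)]
  Xr <- apply(X, 2, function(v) (v - min(v)) / diff(range(v)) * 100)
  Z <- scale(Xr)
  d_ref <- sqrt(rowSums(sweep(Z, 2,
                              (100 - colMeans(Xr)) / apply(Xr, 2, sd))^2))
  expect_equal(m, unname(d_ref), tolerance = 1e-8)
})

test_that("selection gains are signed consistently with the objectives", {
  set.seed(7)
  X <- matrix(rnorm(60 * 5, mean = 50), 60, 5,
              dimnames = list(sprintf("g%02d", 1:60), sprintf("t%d", 1:5)))
  res <- mgidi(X, c("increase", "increase", "decrease", "increase", "decrease"),
               selection_fraction = 0.2)
  expect_equal(sum(res$table$selected), 12)
  g <- res$gains
  expect_equal(g$favorable, (g$differential >= 0) == (g$objective == "increase"))
  expect_equal(g$gain_percent, 100 * g$differential / g$panel_mean)
})

test_that("a planted all-around-best genotype is reliably selected at 20%", {
  hits <- vapply(1:60, function(s) {
    set.seed(900 + s)
    X <- matrix(rnorm(132 * 28), 132, 28,
                dimnames = list(sprintf("G%03d", 1:132), sprintf("t%02d", 1:28)))
    X[1, ] <- colMeans(X) + apply(X, 2, sd)   # 1 SD toward the objective
    res <- mgidi(X, "increase", selection_fraction = 0.2)
    res$table$selected[res$table$genotype == "G001"]
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("reference-genotype cut selects strictly better genotypes only", {
  set.seed(8)
  X <- matrix(rnorm(30 * 4), 30, 4,
              dimnames = list(sprintf("g%02d", 1:30), sprintf("t%d", 1:4)))
  res <- mgidi(X, "increase", reference = "g15")
  cut <- res$table$mgidi[res$table$genotype == "g15"]
  expect_true(all(res$table$mgidi[res$table$selected] < cut))
  expect_false(res$table$selected[res$table$genotype == "g15"])
})

test_that("Kruskal-Wallis comparison matches stats::kruskal.test and flags tendencies", {
  x <- c(1, 2, 3, 10, 11, 12)
  g <- rep(c("a", "b"), each = 3)
  gc <- group_compare(x, g)
  kt <- kruskal.test(x, factor(g))
  expect_equal(gc$H, unname(kt$statistic))
  expect_equal(gc$p, kt$p.value)
  expect_true(gc$significant)
  # identical groups: no difference
  gc0 <- group_compare(rep(5, 9), rep(c("a", "b", "c"), 3))
  expect_equal(gc0$H, 0)
  expect_equal(gc0$p, 1)
  expect_error(group_compare(1:5, rep("a", 5)), ">= 2 groups")
})

test_that("Kruskal-Wallis type-I error is near nominal", {
  set.seed(9)
  rej <- vapply(1:400, function(i) {
    group_compare(rnorm(60), rep(c("a", "b", "c"), each = 20))$p <= 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.03)
})
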