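test_that("Shannon index: uniform communities hit ln S, worked value checks out", {
  expect_equal(shannon(c(1, 1)), log(2))
  for (S in c(3, 10, 57)) {
    expect_equal(shannon(rep(7, S)), log(S), tolerance = 1e-12)
  }
  expect_equal(shannon(c(0.5, 0.25, 0.25)), 1.5 * log(2), tolerance = 1e-4)
  expect_equal(round(shannon(c(0.5, 0.25, 0.25)), 4), 1.0397)
  # zeros are ignored, scale does not matter
  expect_equal(shannon(c(4, 0, 4)), log(2))
  expect_error(shannon(c(0, 0)), "all-zero")
})

test_that("Bray-Curtis matches the min formula, its bounds, and vegan", {
  expect_equal(bray_curtis(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(bray_curtis(c(1, 0), c(0, 2)), 1)
  expect_equal(bray_curtis(c(2, 0, 1), c(1, 1, 0)), 0.6)
  expect_error(bray_curtis(c(1, 2), c(1, 2, 3)), "length mismatch")
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "all-zero")

  withr::local_seed(61)
  m <- matrix(runif(60), nrow = 10)
  colnames(m) <- paste0("s", 1:6)
  D <- bray_curtis_matrix(m)
  expect_true(all(D >= 0 & D <= 1))
  expect_equal(D, t(D))
  expect_equal(diag(D), stats::setNames(rep(0, 6), colnames(m)))
  skip_if_not_installed("vegan")
  Dv <- as.matrix(vegan::vegdist(t(m), method = "bray"))
  expect_equal(unname(D), unname(Dv), tolerance = 1e-12)
})

test_that("PCoA reconstructs Euclidean-embeddable distances and matches cmdscale", {
  # collinear points at mutual distances 1, 1, 2 embed exactly in 1-D
  D3 <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3)
  res <- pcoa(D3, k = 1)
  rec <- as.matrix(dist(res$coordinates))
  expect_equal(unname(rec), D3, tolerance = 1e-9)

  # random Euclidean point set: full-rank reconstruction within 1e-8
  withr::local_seed(62)
  X <- matrix(rnorm(10 * 3), 10, 3)
  D <- as.matrix(dist(X))
  res <- pcoa(D, k = 9)
  rec <- as.matrix(dist(res$coordinates))
  expect_lt(max(abs(rec - D)), 1e-8)
  # negative eigenvalues are reported, not clamped; variance over positive
  # eigenvalues sums to 1
  expect_equal(length(res$eigenvalues), 10L)
  expect_equal(sum(res$eigenvalues[seq_len(res$n_positive)]) /
                 sum(res$eigenvalues[res$eigenvalues > 0]), 1)
  full_ve <- res$eigenvalues[seq_len(res$n_positive)] /
    sum(res$eigenvalues[seq_len(res$n_positive)])
  expect_equal(sum(full_ve), 1, tolerance = 1e-12)

  # all-zero distances embed at the origin
  expect_true(all(pcoa(matrix(0, 4, 4), k = 2)$coordinates == 0))
  expect_error(pcoa(D3, k = 3), "k must satisfy")

  # cross-check coordinates against classical scaling in stats (up to sign)
  cs <- stats::cmdscale(D, k = 2)
  expect_equal(abs(unname(res$coordinates[, 1:2])), abs(unname(cs)),
               tolerance = 1e-8)
})

test_that("Mantel statistic and p behave at the concordant and exhaustive limits", {
  withr::local_seed(63)
  X <- matrix(rnorm(8 * 2), 8, 2)
  D1 <- as.matrix(dist(X))
  res <- mantel_test(D1, D1, n_perm = 99, seed = 4)
  expect_equal(res$statistic, 1.0)
  expect_equal(res$p_value, 1 / 100)

  # n = 4: sampled-exhaustive mode equals direct enumeration over all 24
  # permutations
  D2 <- as.matrix(dist(matrix(rnorm(4 * 2), 4, 2)))
  Da <- as.matrix(dist(matrix(rnorm(4 * 2), 4, 2)))
  ex <- mantel_test(Da, D2, exhaustive = TRUE)
  expect_equal(ex$n_perm, 23L)
  expect_equal(ex$p_value, oracle_mantel_exhaustive(Da, D2), tolerance = 1e-12)

  expect_error(mantel_test(D1, D2), "mantel")
})

test_that("Mantel and t-test type-I error is calibrated near alpha = 0.05", {
  withr::local_seed(64)
  n_rep <- 200
  rej <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    D1 <- as.matrix(dist(matrix(rnorm(15 * 3), 15, 3)))
    D2 <- as.matrix(dist(matrix(rnorm(15 * 3), 15, 3)))
    rej[i] <- mantel_test(D1, D2, n_perm = 199, seed = i)$p_value <= 0.05
  }
  expect_gte(mean(rej), 0.02)
  expect_lte(mean(rej), 0.08)

  rej_t <- vapply(seq_len(n_rep), function(i) {
    t_test(rnorm(20), rnorm(20))$p_value <= 0.05
  }, logical(1))
  expect_gte(mean(rej_t), 0.02)
  expect_lte(mean(rej_t), 0.08)
})

test_that("Pearson worked value and agreement with stats::cor.test", {
  expect_equal(pearson_test(1:10, 2 * (1:10) + 1)$statistic, 1.0)
  expect_equal(pearson_test(1:10, -(1:10))$statistic, -1.0)
  res <- pearson_test(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(res$statistic, 0.6, tolerance = 1e-12)
  ref <- stats::cor.test(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)
  expect_error(pearson_test(rep(1, 5), 1:5), "constant")
})

test_that("t-test worked values, degenerate cases, and agreement with stats::t.test", {
  same <- t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  res <- t_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, -3.674, tolerance = 1e-3)
  expect_equal(res$df, 4)
  ref <- stats::t.test(c(1, 2, 3), c(4, 5, 6), var.equal = TRUE)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)

  withr::local_seed(65)
  a <- rnorm(12); b <- rnorm(15, sd = 3)
  w <- t_test(a, b, variant = "welch")
  refw <- stats::t.test(a, b)
  expect_equal(w$statistic, unname(refw$statistic), tolerance = 1e-12)
  expect_equal(w$df, unname(refw$parameter), tolerance = 1e-9)
  expect_equal(w$p_value, refw$p.value, tolerance = 1e-12)

  expect_equal(t_test(c(2, 2), c(2, 2))$p_value, 1)
  expect_error(t_test(c(2, 2), c(3, 3)), "zero variance")
})
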