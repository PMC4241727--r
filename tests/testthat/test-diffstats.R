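test_that("fold change: ratio, unity, not-detected, and degenerate input", {
  # a 242-fold enrichment: mean_a 0.653 against mean_b 0.653/242
  expect_equal(fold_change(rep(0.653, 5), rep(0.653 / 242, 6)), 242)
  expect_equal(fold_change(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_identical(fold_change(c(0.02, 0.03), c(0, 0, 0)), Inf)
  expect_error(fold_change(c(0, 0), c(0, 0)), "absent from both")
})

test_that("t-test: identity cases and closed-form oracle agreement", {
  expect_equal(unpaired_ttest(c(1, 2, 3), c(1, 2, 3), tail = "two"), 1)
  expect_equal(unpaired_ttest(c(1, 2, 3), c(1, 2, 3), tail = "one"), 0.5)
  expect_error(unpaired_ttest(1, c(1, 2)), "at least 2")
  set.seed(91)
  for (i in 1:100) {
    x <- rnorm(sample(3:8, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 2))
    y <- rnorm(sample(3:8, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 2))
    expect_equal(unpaired_ttest(x, y, "two"), ttest_oracle(x, y, "two"),
                 tolerance = 1e-9)
    expect_equal(unpaired_ttest(x, y, "one"), ttest_oracle(x, y, "one"),
                 tolerance = 1e-9)
  }
})

test_that("t-test p-value is invariant under common scaling", {
  set.seed(92)
  x <- rnorm(5, 3); y <- rnorm(6, 1)
  expect_equal(unpaired_ttest(x, y), unpaired_ttest(10 * x, 10 * y),
               tolerance = 1e-12)
})

test_that("Pearson correlation matches the closed form", {
  expect_equal(pearson_cor(1:5, 2 * (1:5))$r, 1)
  expect_equal(pearson_cor(1:5, -(1:5))$r, -1)
  expect_error(pearson_cor(1:5, rep(2, 5)), "zero variance")
  expect_error(pearson_cor(1:2, 1:2), "at least 3")
  set.seed(93)
  for (i in 1:50) {
    n <- sample(4:12, 1)
    x <- rnorm(n); y <- rnorm(n) + 0.5 * x
    got <- pearson_cor(x, y)
    want <- pearson_oracle(x, y)
    expect_equal(got$r, want$r, tolerance = 1e-9)
    expect_equal(got$p_value, want$p, tolerance = 1e-9)
  }
})

test_that("enrichment selection implements the tenfold-or-nd AND p rule", {
  tab <- data.frame(category = c("near", "nd", "weak", "strong"),
                    fold = c(9.9, Inf, 12, 15),
                    p_value = c(0.001, 0.003, 0.2, 0.01),
                    stringsAsFactors = FALSE)
  out <- select_enriched(tab)
  expect_equal(out$selected, c(FALSE, TRUE, FALSE, TRUE))
  # min_fold 1, alpha 1: every significant-direction category qualifies
  out2 <- select_enriched(tab, min_fold = 1, alpha = 1)
  expect_true(all(out2$selected))
})

test_that("a differential table recovers exactly the planted enrichments", {
  set.seed(94)
  n_cat <- 50; planted <- paste0("cat", sprintf("%02d", 1:5))
  cats <- paste0("cat", sprintf("%02d", 1:n_cat))
  base <- matrix(rnorm(11 * n_cat, mean = 1, sd = 0.1), nrow = 11,
                 dimnames = list(c(paste0("a", 1:5), paste0("b", 1:6)), cats))
  base <- abs(base)
  base[1:5, planted] <- base[1:5, planted] * 30   # >= tenfold in group a
  a <- base[1:5, ]; b <- base[6:11, ]
  dt <- select_enriched(diff_table(a, b))
  expect_identical(sort(dt$category[dt$selected]), planted)
})

test_that("nd categories keep a p-value computed on the raw abundances", {
  a <- matrix(c(0.02, 0.015, 0.025, 0.02, 0.02), ncol = 1,
              dimnames = list(NULL, "nd_cat"))
  b <- matrix(rep(0, 6), ncol = 1, dimnames = list(NULL, "nd_cat"))
  dt <- diff_table(a, b)
  expect_identical(dt$fold, Inf)
  expect_lt(dt$p_value, 0.05)
  dt2 <- select_enriched(dt)
  expect_true(dt2$selected)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_diff(dt2, path)
  expect_match(readLines(path)[2], "\tnd\t")
})

test_that("covariance PCA: variance bookkeeping and degenerate inputs", {
  set.seed(95)
  X <- matrix(rnorm(8 * 5), nrow = 8)
  p <- pca_covariance(X)
  expect_equal(sum(p$eigenvalues), sum(diag(cov(X))), tolerance = 1e-9)
  expect_true(all(diff(p$eigenvalues) <= 1e-12))
  expect_true(all(p$eigenvalues >= 0))
  # scores' per-component variance equals the eigenvalues
  expect_equal(unname(apply(p$scores, 2, var)), unname(p$eigenvalues),
               tolerance = 1e-9)
  # loadings orthonormal
  expect_equal(crossprod(p$loadings), diag(ncol(X)), tolerance = 1e-9,
               ignore_attr = TRUE)
  # identical rows: no variance anywhere
  same <- matrix(rep(c(1, 2, 3), each = 4), nrow = 4)
  expect_true(all(pca_covariance(same)$eigenvalues < 1e-12))
  expect_error(pca_covariance(X[1, , drop = FALSE]), "at least 2")
  # agreement with an independent SVD-based implementation
  pr <- prcomp(X, center = TRUE, scale. = FALSE)
  expect_equal(unname(p$eigenvalues), unname(pr$sdev^2), tolerance = 1e-9)
})

test_that("rank-2 data concentrates variance in two components", {
  set.seed(96)
  u <- rnorm(10); v <- rnorm(10)
  X <- cbind(u, v, u + v, u - 2 * v, 3 * u + 0.5 * v)
  p <- pca_covariance(X)
  expect_lt(sum(p$eigenvalues[-(1:2)]), 1e-9 * sum(p$eigenvalues))
})
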