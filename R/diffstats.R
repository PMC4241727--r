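#' Fold change between two sample groups
#'
#' Ratio of group means, `mean(a) / mean(b)`. When a category is absent from
#' group b (`mean(b) == 0`) but present in group a the fold is reported as
#' "not detected" (`Inf`, printed `nd`): the enrichment is real but its
#' magnitude is undefined. A category absent from both groups is an error.
#'
#' @param group_a,group_b numeric vectors of per-sample relative abundances.
#' @return Positive number, or `Inf` for not-detected-in-b.
#' @export
fold_change <- function(group_a, group_b) {
  ma <- mean(group_a); mb <- mean(group_b)
  if (ma == 0 && mb == 0) stop("category absent from both groups: fold undefined")
  if (mb == 0) return(Inf)
  ma / mb
}

#' Unpaired two-sample t-test (pooled variance)
#'
#' Student's two-sample statistic with pooled variance, the classic
#' "unpaired t-test". The one-tailed p tests the directed hypothesis
#' a > b: it halves the two-tailed p when the observed direction matches,
#' and is `1 - p_two/2` otherwise. A Welch (unequal-variance) mode is
#' available behind `var_equal = FALSE`.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @param tail `"two"` (default) or `"one"` (directed, x > y).
#' @param var_equal pool the variances (default `TRUE`).
#' @return The p-value.
#' @export
unpaired_ttest <- function(x, y, tail = c("two", "one"), var_equal = TRUE) {
  tail <- match.arg(tail)
  if (length(x) < 2L || length(y) < 2L) stop("each group needs at least 2 values")
  alt <- if (tail == "two") "two.sided" else "greater"
  p <- tryCatch(
    stats::t.test(x, y, alternative = alt, var.equal = var_equal)$p.value,
    error = function(e) {
      # degenerate: both groups constant
      if (isTRUE(all.equal(mean(x), mean(y)))) {
        if (tail == "two") 1 else 0.5
      } else {
        .Machine$double.xmin  # zero pooled variance, nonzero difference
      }
    })
  max(p, .Machine$double.xmin)
}

#' Per-category differential table between two groups
#'
#' Computes group means, standard deviations, fold change (with
#' not-detected semantics) and the unpaired t-test p-value for every shared
#' column of two samples x categories abundance matrices. Categories absent
#' from both groups are kept with `fold = NA` and `p_value = NA`.
#' No multiple-testing correction is applied by default;
#' Benjamini–Hochberg-adjusted p-values are appended when `adjust = TRUE`.
#'
#' @param mat_a,mat_b samples x categories matrices (group a and group b);
#'   columns are matched by name, with missing columns treated as zeros.
#' @param tails `"two"`, `"one"`, or a named per-category vector.
#' @param var_equal pooled-variance t-test (default `TRUE`).
#' @param adjust append `p_adjust` (BH) column (default `FALSE`).
#' @return data.frame: `category`, `mean_a`, `sd_a`, `mean_b`, `sd_b`,
#'   `fold` (`Inf` = nd), `p_value`, `tail`.
#' @export
diff_table <- function(mat_a, mat_b, tails = "two", var_equal = TRUE,
                       adjust = FALSE) {
  cats <- sort(unique(c(colnames(mat_a), colnames(mat_b))))
  col_of <- function(m, cc) if (cc %in% colnames(m)) m[, cc] else rep(0, nrow(m))
  tail_of <- function(cc) {
    if (length(tails) == 1L && is.null(names(tails))) tails
    else if (cc %in% names(tails)) tails[[cc]] else "two"
  }
  rows <- lapply(cats, function(cc) {
    a <- col_of(mat_a, cc); b <- col_of(mat_b, cc)
    tl <- tail_of(cc)
    both_zero <- mean(a) == 0 && mean(b) == 0
    data.frame(category = cc,
               mean_a = mean(a), sd_a = stats::sd(a),
               mean_b = mean(b), sd_b = stats::sd(b),
               fold = if (both_zero) NA_real_ else fold_change(a, b),
               p_value = if (both_zero) NA_real_
                         else unpaired_ttest(a, b, tl, var_equal),
               tail = tl, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (adjust) out$p_adjust <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}

#' Select significantly and strongly enriched categories
#'
#' A category is selected when `p_value < alpha` and its fold change is at
#' least `min_fold` or "not detected" in the comparison group (`Inf`): the
#' fold criterion cannot be evaluated for absent categories, so significance
#' alone decides. Input order is preserved.
#'
#' @param table data.frame from [diff_table()].
#' @param min_fold minimum fold change (default 10).
#' @param alpha significance level (default 0.05).
#' @return The table with a logical `selected` column.
#' @export
select_enriched <- function(table, min_fold = 10, alpha = 0.05) {
  fold_ok <- !is.na(table$fold) & (table$fold >= min_fold | is.infinite(table$fold))
  p_ok <- !is.na(table$p_value) & table$p_value < alpha
  table$selected <- fold_ok & p_ok
  table
}

#' Write a differential table to TSV (`nd` for not-detected folds)
#' @param table data.frame from [diff_table()] / [select_enriched()].
#' @param path output path.
#' @export
write_diff <- function(table, path) {
  out <- table
  out$fold <- ifelse(is.infinite(out$fold), "nd",
                     ifelse(is.na(out$fold), "NA", format(out$fold, digits = 6)))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pearson correlation with two-tailed p-value
#'
#' Sample correlation coefficient and the usual t-approximation p-value.
#'
#' @param x,y numeric vectors of equal length, n >= 3, each with nonzero
#'   variance.
#' @return List: `r`, `p_value`, `n`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance in input")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Principal component analysis by covariance eigendecomposition
#'
#' Columns are mean-centered (never scaled to unit variance) and the sample
#' variance-covariance matrix is eigendecomposed. Scores are the centered
#' data projected on the eigenvectors. Component signs are fixed by making
#' each loading vector's largest-magnitude entry positive, so results are
#' reproducible across platforms.
#'
#' @param mat samples x categories numeric matrix, >= 2 samples.
#' @return A `pca_covariance` list: `scores` (samples x components),
#'   `loadings` (categories x components, orthonormal), `eigenvalues`
#'   (non-increasing), `explained` (fractions of total variance; zero
#'   vector when total variance is 0).
#' @export
pca_covariance <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2L) stop("PCA needs at least 2 samples")
  centered <- scale(mat, center = TRUE, scale = FALSE)
  cv <- stats::cov(mat)
  ee <- eigen(cv, symmetric = TRUE)
  vals <- ee$values
  vals[vals < 0 & vals > -1e-12 * max(abs(vals), 1)] <- 0  # numerical dust
  vecs <- ee$vectors
  for (j in seq_len(ncol(vecs))) {
    i <- which.max(abs(vecs[, j]))
    if (vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
  }
  dimnames(vecs) <- list(colnames(mat), paste0("PC", seq_len(ncol(vecs))))
  scores <- centered %*% vecs
  total <- sum(vals)
  structure(list(scores = scores, loadings = vecs,
                 eigenvalues = stats::setNames(vals, colnames(vecs)),
                 explained = if (total > 0) vals / total else vals * 0),
            class = "pca_covariance")
}

#' @export
print.pca_covariance <- function(x, ...) {
  k <- min(5L, length(x$eigenvalues))
  cat("<pca_covariance>\n  eigenvalues:",
      paste(signif(x$eigenvalues[seq_len(k)], 4), collapse = ", "),
      if (length(x$eigenvalues) > k) "..." else "", "\n")
  cat(sprintf("  PC1 %.1f%%, PC2 %.1f%% of variance\n",
              100 * x$explained[1],
              if (length(x$explained) > 1) 100 * x$explained[2] else 0))
  invisible(x)
}
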