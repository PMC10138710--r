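#' Bray-Curtis dissimilarity between samples
#'
#' Computes the Bray-Curtis semimetric \eqn{d(x, y) = \sum_i |x_i - y_i| /
#' \sum_i (x_i + y_i)} between the rows of an abundance table. Pairs of
#' all-zero samples have undefined dissimilarity and are returned as `NA`.
#'
#' @param x numeric matrix or data frame, samples in rows, non-negative
#'   abundances in columns.
#' @return a symmetric `matrix` of dissimilarities with zero diagonal and
#'   sample ids as dimnames.
#' @examples
#' bray_curtis(rbind(a = c(0.2, 0.8), b = c(0.4, 0.6)))
#' @export
bray_curtis <- function(x) {
  x <- as.matrix(x)
  if (any(x < 0)) stop("bray_curtis: abundances must be non-negative")
  d <- as.matrix(suppressWarnings(vegan::vegdist(x, method = "bray")))
  zero <- rowSums(x) == 0
  if (any(zero)) {
    # vegdist returns NaN for all-zero pairs; normalise to NA marker
    d[zero, zero] <- NA_real_
    diag(d) <- 0
  }
  dimnames(d) <- list(rownames(x), rownames(x))
  d
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Single-factor PERMANOVA on a distance matrix using Anderson's partition
#' of the squared inter-point distances: pseudo-F, R-squared and a
#' permutation p-value with the `(hits + 1) / (n_perm + 1)` convention.
#'
#' @param d distance matrix (`dist`, or square symmetric matrix).
#' @param labels group label per sample; at least two groups, each with at
#'   least two samples.
#' @param n_perm number of label permutations (default 999).
#' @param seed integer seed controlling the permutations.
#' @return list with `pseudo_f`, `r_squared`, `p_value`, `n_permutations`,
#'   `seed`, of class `"permanova"`.
#' @export
permanova <- function(d, labels, n_perm = 999, seed = 1L) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  d <- as.matrix(d)
  if (max(abs(d - t(d))) > 1e-12) stop("permanova: distance matrix must be symmetric")
  labels <- as.factor(labels)
  if (length(labels) != nrow(d)) stop("permanova: labels must match distance matrix")
  if (nlevels(droplevels(labels)) < 2) stop("permanova: need at least 2 groups")
  if (any(table(labels) < 2)) stop("permanova: each group needs >= 2 samples")
  df <- data.frame(group = labels)
  set.seed(seed)
  fit <- vegan::adonis2(stats::as.dist(d) ~ group, data = df,
                        permutations = n_perm)
  out <- list(pseudo_f = fit$F[1],
              r_squared = fit$R2[1],
              p_value = fit$`Pr(>F)`[1],
              n_permutations = n_perm,
              seed = seed)
  class(out) <- "permanova"
  out
}

#' @export
print.permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.4g, R2 = %.4g, p = %.4g (%d permutations)\n",
              x$pseudo_f, x$r_squared, x$p_value, x$n_permutations))
  invisible(x)
}

#' Principal coordinates analysis
#'
#' Classical metric multidimensional scaling (Gower double-centering and
#' eigendecomposition) of a distance matrix. Coordinates are taken from the
#' positive eigenvalues; negative eigenvalues (possible for semimetrics such
#' as Bray-Curtis) are reported, not silently dropped.
#'
#' @param d distance matrix (`dist` or square symmetric matrix).
#' @param n_axes number of ordination axes to return (at most `n - 1`).
#' @return list with `coordinates` (samples x axes), `eigenvalues` (all
#'   `n - 1`, ordered decreasing) and `relative_eig` over positive
#'   eigenvalues.
#' @export
pcoa <- function(d, n_axes = 2) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  n <- nrow(d)
  if (n_axes > n - 1) stop("pcoa: n_axes must be <= n - 1")
  fit <- stats::cmdscale(stats::as.dist(d), k = n_axes, eig = TRUE)
  eig <- fit$eig
  pos <- eig[eig > sqrt(.Machine$double.eps)]
  coords <- fit$points
  if (is.null(dim(coords))) coords <- matrix(coords, ncol = 1)
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  list(coordinates = coords,
       eigenvalues = eig,
       relative_eig = if (length(pos)) eig / sum(pos) else eig * NA_real_)
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value by hypergeometric enumeration, summing the probability
#' of every table at least as extreme (probability-mass convention).
#'
#' @param counts 2x2 matrix of non-negative integer counts.
#' @return two-sided p-value.
#' @examples
#' fisher_exact(matrix(c(4, 11, 9, 5), nrow = 2))
#' @export
fisher_exact <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2, 2))) stop("fisher_exact: need a 2x2 table")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("fisher_exact: counts must be non-negative integers")
  stats::fisher.test(counts)$p.value
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up q-values `q_i = min_{j >= i} m * p_(j) / j`, capped at 1 and
#' mapped back to the input order.
#'
#' @param p vector of p-values in `[0, 1]` (`NA` allowed, propagated).
#' @return vector of q-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("bh_fdr: p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Rank-based two-sample and paired tests
#'
#' Mann-Whitney U for two independent samples (exact for small groups
#' without ties, tie-corrected normal approximation otherwise) or the
#' Wilcoxon signed-rank test for paired samples with zero differences
#' dropped.
#'
#' @param x,y numeric vectors; equal length when `paired`.
#' @param paired logical, use the signed-rank test on `x - y`.
#' @return list with `statistic` (U, or V when paired) and `p_value`
#'   (two-sided).
#' @export
rank_tests <- function(x, y, paired = FALSE) {
  if (paired) {
    if (length(x) != length(y)) stop("rank_tests: paired data must have equal length")
    if (all(x - y == 0)) stop("rank_tests: all paired differences are zero")
    ht <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                              exact = NULL, correct = TRUE))
  } else {
    ht <- suppressWarnings(stats::wilcox.test(x, y, paired = FALSE,
                                              exact = NULL, correct = TRUE))
  }
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}

#' Kruskal-Wallis rank-sum test across groups
#'
#' @param groups list of numeric vectors, one per group (all non-empty).
#' @return list with `h` (tie-corrected statistic), `df` and `p_value`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2) stop("kruskal_wallis: need at least 2 groups")
  if (any(lengths(groups) == 0)) stop("kruskal_wallis: empty group")
  ht <- stats::kruskal.test(groups)
  list(h = unname(ht$statistic), df = unname(ht$parameter), p_value = ht$p.value)
}

#' Robust linear regression (Huber M-estimation)
#'
#' Iteratively reweighted least squares with the Huber psi (tuning constant
#' c = 1.345), the field-standard robust alternative to OLS when a few
#' gross outliers are expected.
#'
#' @param x design matrix (including intercept column if wanted).
#' @param y response vector.
#' @return list with `coefficients` and `se` (asymptotic standard errors).
#' @export
robust_linreg <- function(x, y) {
  x <- as.matrix(x)
  if (qr(x)$rank < ncol(x)) stop("robust_linreg: rank-deficient design")
  fit <- MASS::rlm(x, y, psi = MASS::psi.huber, k = 1.345,
                   maxit = 100, acc = 1e-8)
  sm <- summary(fit)
  list(coefficients = stats::coef(fit), se = sm$coefficients[, "Std. Error"])
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items;
#' 1 for identical partitions (up to renaming), about 0 for independent ones.
#' Used to score recovery of planted module and enterotype structure.
#'
#' @param a,b label vectors of equal length.
#' @return adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("adjusted_rand_index: unequal lengths")
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
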