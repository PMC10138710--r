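test_that("spearman correlation matrix matches rank arithmetic and is monotone-invariant", {
  x <- cbind(a = c(1, 2, 3, 4), b = c(1, 3, 2, 4))
  rho <- correlation_matrix(x)
  expect_equal(rho["a", "b"], 0.8)  # 1 - 6 * 2 / (4 * 15)
  y <- cbind(a = rnorm(20))
  y <- cbind(y, b = exp(3 * y[, "a"]))  # strictly increasing transform
  expect_equal(correlation_matrix(y)["a", "b"], 1)
  coh <- generate_cohort(cohort_config(seed = 5))
  r <- correlation_matrix(coh$features)
  expect_equal(unname(diag(r)), rep(1, ncol(r)))
  expect_lte(max(abs(r)), 1)
  expect_equal(r, t(r))
  bad <- cbind(a = rep(2, 5), b = rnorm(5))
  expect_error(correlation_matrix(bad), "constant feature")
})

test_that("adjacency follows the soft-threshold formulas and decreases in beta", {
  rho <- matrix(c(1, -0.5, -0.5, 1), 2)
  expect_equal(adjacency(rho, 2)[1, 2], 0.25)
  expect_equal(adjacency(matrix(1, 2, 2), 7)[1, 2], 1)
  expect_equal(adjacency(matrix(c(1, .5, .5, 1), 2), 10)[1, 2], 0.5^10)
  expect_equal(adjacency(rho, 2, "signed")[1, 2], 0.25^2)
  expect_error(adjacency(rho, 0.5), ">= 1")
  set.seed(1)
  r <- cor(matrix(rnorm(200), 20, 10))
  a3 <- adjacency(r, 3); a5 <- adjacency(r, 5)
  off <- upper.tri(r) & abs(r) > 0 & abs(r) < 1
  expect_true(all(a5[off] < a3[off]))
  # permutation equivariance
  p <- sample(10)
  expect_equal(adjacency(r[p, p], 3), a3[p, p])
})

test_that("scale-free fit is exact on a constructed power law and NA when degenerate", {
  # equal-width bins centred at 1..10 with counts proportional to 1/k
  k <- rep(1:10, times = round(2520 / (1:10)))
  r2 <- guildnet:::scale_free_fit(k)
  expect_equal(r2, 1, tolerance = 1e-6)
  expect_true(is.na(guildnet:::scale_free_fit(rep(3, 50))))
})

test_that("soft_threshold_scan reports one calibrated row per power", {
  coh <- generate_cohort(cohort_config(seed = 5))
  rho <- correlation_matrix(coh$features)
  sft <- soft_threshold_scan(rho, 1:20)
  expect_equal(nrow(sft), 20)
  expect_equal(sft$power, 1:20)
  expect_true(all(diff(sft$mean_connectivity) < 0))  # connectivity shrinks with beta
  const <- matrix(0.4, 30, 30); diag(const) <- 1
  sft2 <- soft_threshold_scan(const, 1:3)
  expect_true(all(is.na(sft2$scale_free_r2)))  # all-equal degrees: undefined marker
  expect_error(soft_threshold_scan(matrix(1, 5, 5)), ">= 20")
})

test_that("detect_modules recovers planted structure and ignores pure noise", {
  pm <- planted_matrix(n = 60, k = 4, per_module = 25, n_noise = 30,
                       loading = 0.9, noise_sd = 0.3, seed = 42)
  det <- detect_modules(pm$x, min_module_size = 11)
  expect_gte(adjusted_rand_index(pm$truth, det$labels), 0.8)
  noise <- matrix(rnorm(60 * 100), 60, 100,
                  dimnames = list(sprintf("s%d", 1:60), sprintf("f%d", 1:100)))
  det2 <- detect_modules(noise, min_module_size = 11)
  expect_gte(mean(det2$labels == "unclassified"), 0.9)
  # duplicated module features co-cluster rather than splitting
  dup <- cbind(pm$x[, 1:25], pm$x[, 1:25] + matrix(rnorm(60 * 25, 0, 1e-3), 60))
  colnames(dup) <- sprintf("f%03d", seq_len(ncol(dup)))
  det3 <- detect_modules(dup, min_module_size = 11)
  mods <- setdiff(unique(det3$labels), "unclassified")
  expect_equal(length(mods), 1)
  # fewer features than the minimum size: everything unassigned
  tiny <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, paste0("f", 1:4)))
  expect_true(all(detect_modules(tiny, min_module_size = 11)$labels ==
                    "unclassified"))
})

test_that("module eigengenes summarize their factor and are duplication-invariant", {
  set.seed(9)
  n <- 60
  f <- rnorm(n)
  x <- vapply(1:20, function(j) f + rnorm(n, 0, 0.1), numeric(n))
  dimnames(x) <- list(sprintf("s%d", 1:n), sprintf("g%d", 1:20))
  me <- module_eigengene(x, 1:20)
  expect_gte(abs(cor(me, f)), 0.99)
  expect_equal(sd(me), 1)
  # a one-feature module is that feature z-scored
  me1 <- module_eigengene(x, 1)
  expect_equal(unname(me1), as.numeric(scale(x[, 1])), tolerance = 1e-12)
  # duplicating every feature leaves the eigengene unchanged
  me2 <- module_eigengene(cbind(x, x), seq_len(40))
  expect_equal(me, me2, tolerance = 1e-10)
  expect_error(module_eigengene(x, integer(0)), "empty")
})

test_that("signed kME is the profile-eigengene correlation with its sign", {
  set.seed(10)
  x <- matrix(rnorm(50 * 5), 50, 5,
              dimnames = list(NULL, paste0("f", 1:5)))
  me <- cbind(m1 = x[, 1], m2 = -x[, 2])
  kme <- signed_kme(x, me, cor_method = "pearson")
  expect_equal(kme["f1", "m1"], 1)
  expect_equal(kme["f2", "m2"], -1)
  # independent features have small membership at large n
  x2 <- matrix(rnorm(1000 * 50), 1000, 50,
               dimnames = list(NULL, paste0("f", 1:50)))
  kme2 <- signed_kme(x2, cbind(m = rnorm(1000)), cor_method = "pearson")
  expect_gte(mean(abs(kme2) < 0.1), 0.99)
})

test_that("modules merge at eigengene dissimilarity <= 0.25 and not above", {
  # exact construction: module B's profile correlates 0.8 with module A's
  n <- 64
  v1 <- rep(c(1, -1), n / 2); v1 <- v1 / sqrt(sum(v1^2))
  w <- rep(c(1, 1, -1, -1), n / 4); w <- w / sqrt(sum(w^2))
  u_close <- 0.8 * v1 + 0.6 * w       # cor exactly 0.8 -> diss 0.2, merges
  u_far <- 0.7 * v1 + sqrt(1 - 0.49) * w  # cor 0.7 -> diss 0.3, stays
  make_tab <- function(u) {
    x <- cbind(matrix(rep(v1, 12), n), matrix(rep(u, 12), n))
    dimnames(x) <- list(sprintf("s%d", 1:n), sprintf("f%d", 1:24))
    x
  }
  labs <- setNames(rep(c("A", "B"), each = 12), sprintf("f%d", 1:24))
  merged <- merge_modules(make_tab(u_close), labs, 0.25)
  expect_equal(length(unique(merged$labels)), 1)
  expect_equal(nrow(merged$merge_history), 1)
  kept <- merge_modules(make_tab(u_far), labs, 0.25)
  expect_equal(length(unique(kept$labels)), 2)
  # fixed point: every surviving pair has dissimilarity above the threshold
  dd <- 1 - cor(kept$eigengenes)
  expect_true(all(dd[upper.tri(dd)] > 0.25))
})

test_that("membership refinement applies the inclusive 0.30 rule", {
  kme <- matrix(c(0.29, 0.30, 0.95), 3, 1,
                dimnames = list(c("f1", "f2", "f3"), "blue"))
  labels <- setNames(rep("blue", 3), c("f1", "f2", "f3"))
  out <- refine_membership(kme, labels, 0.30)
  expect_equal(unname(out), c("unclassified", "blue", "blue"))
})

test_that("the conet fit is deterministic and its eigengenes have unit variance", {
  coh <- generate_cohort(cohort_config(seed = 3))
  f1 <- suppressMessages(conet(coh$features, scan_powers = FALSE))
  f2 <- suppressMessages(conet(coh$features, scan_powers = FALSE))
  expect_identical(f1$labels, f2$labels)
  expect_identical(f1$eigengenes, f2$eigengenes)
  expect_equal(unname(apply(f1$eigengenes, 2, sd)),
               rep(1, ncol(f1$eigengenes)))
  expect_lte(max(abs(f1$kme)), 1)
  # every feature classified exactly once or unclassified
  expect_setequal(names(f1$labels), colnames(coh$features$values))
  # print and summary run quietly
  expect_output(print(f1), "conet fit")
  expect_output(print(summary(f1)), "block composition")
})
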