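# shared fixtures built in code

# small labelled matrix with planted factor modules and pure-noise features
planted_matrix <- function(n = 60, k = 4, per_module = 25, n_noise = 30,
                           loading = 0.9, noise_sd = 0.3, seed = 1) {
  set.seed(seed)
  f <- matrix(rnorm(n * k), n, k)
  unique_sd <- sqrt(1 - loading^2 + noise_sd^2)
  cols <- lapply(seq_len(k), function(kk)
    vapply(seq_len(per_module), function(j) loading * f[, kk] + unique_sd * rnorm(n),
           numeric(n)))
  x <- cbind(do.call(cbind, cols), matrix(rnorm(n * n_noise), n, n_noise))
  dimnames(x) <- list(sprintf("s%03d", seq_len(n)),
                      sprintf("f%03d", seq_len(ncol(x))))
  list(x = x, factors = f,
       truth = c(rep(seq_len(k), each = per_module), rep(0L, n_noise)))
}

# two-sided Fisher p by direct hypergeometric enumeration
fisher_enum <- function(tab) {
  a <- tab[1, 1]; r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- dhyper(support, c1, n - c1, r1)
  p_obs <- dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exact two-sided Mann-Whitney p by enumerating group assignments
mw_enum <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  idx <- utils::combn(length(pooled), n1)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u_all <- apply(idx, 2, function(i) sum(r[i]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}
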