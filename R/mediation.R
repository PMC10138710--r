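#' Causal mediation analysis for a single mediator
#'
#' Linear-model product-of-coefficients mediation with quasi-Bayesian
#' (Imai-style) uncertainty. The mediator model `M ~ X (+ covariates)` and
#' outcome model `Y ~ X + M (+ covariates)` are fitted by least squares;
#' the point average causal mediation effect is the product of the X-to-M
#' and M-to-Y coefficients, the average direct effect is the outcome-model
#' X coefficient, and in this linear no-interaction setting
#' `ACME + ADE = total` exactly. Uncertainty comes from drawing coefficient
#' vectors from each model's asymptotic normal distribution, recomputing
#' the ACME per draw; the interval is the percentile interval and the
#' p-value is `2 * min(P(draws <= 0), P(draws >= 0))`.
#'
#' @param x exposure vector.
#' @param m mediator vector.
#' @param y outcome vector.
#' @param covariates optional data frame / matrix of covariates entered in
#'   both models.
#' @param n_sims quasi-Bayesian draws (default 1000, minimum 100).
#' @param seed integer seed; fixed seed reproduces the result exactly.
#' @param ci confidence level (default 0.95).
#' @return object of class `"guild_mediation"` with `acme`, `ade`, `total`,
#'   `prop_mediated` (`NA` when the total is near zero or of opposing
#'   sign), `ci` (ACME percentile interval), `p_value`, draws summary,
#'   sample size, and the two fitted models.
#' @examples
#' set.seed(1)
#' x <- rnorm(200); m <- 0.5 * x + rnorm(200); y <- 0.4 * m + rnorm(200)
#' mediate(x, m, y, n_sims = 200, seed = 2)
#' @export
mediate <- function(x, m, y, covariates = NULL, n_sims = 1000, seed = 1L,
                    ci = 0.95) {
  m <- as.matrix(m)
  if (ncol(m) != 1) stop("mediate: one mediator; use mediate_joint() for sets")
  fit <- mediate_fit(x, m, y, covariates, n_sims, seed, ci)
  fit$mediator_id <- colnames(m) %||% "M"
  fit
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# shared engine for single and joint mediation; m is a matrix of mediators
mediate_fit <- function(x, m, y, covariates, n_sims, seed, ci) {
  x <- as.numeric(x); y <- as.numeric(y); m <- as.matrix(m)
  n <- length(x)
  if (n < 10) stop("mediate: need n >= 10")
  if (nrow(m) != n || length(y) != n) stop("mediate: unaligned inputs")
  if (n_sims < 100) stop("mediate: 'n_sims' must be >= 100")
  if (ncol(m) >= n / 2) stop("mediate: mediator count must be < n / 2")
  orig_ids <- colnames(m) %||% paste0("M", seq_len(ncol(m)))
  colnames(m) <- paste0("M", seq_len(ncol(m)))  # syntactic names for lm
  cv <- if (!is.null(covariates)) as.matrix(covariates) else NULL

  # collinearity guards
  xm <- cbind(x, m)
  if (any(!is.finite(xm))) stop("mediate: non-finite values in x or m")
  if (any(apply(xm, 2, stats::sd) == 0))
    stop("mediate: constant exposure or mediator")
  sv <- svd(scale(xm))$d
  if (sv[length(sv)] < 1e-8 || sv[1] / max(sv[length(sv)], 1e-300) > 1e8)
    stop("mediate: exposure and mediator(s) are collinear")

  a_hat <- numeric(ncol(m)); a_cov <- vector("list", ncol(m))
  med_fits <- vector("list", ncol(m))
  for (j in seq_len(ncol(m))) {
    dfj <- data.frame(mj = m[, j], x = x)
    fj <- if (is.null(cv)) stats::lm(mj ~ x, data = dfj) else
      stats::lm(mj ~ x + cv, data = dfj)
    med_fits[[j]] <- fj
    a_hat[j] <- stats::coef(fj)["x"]
    a_cov[[j]] <- stats::vcov(fj)
  }
  dfo <- data.frame(y = y, x = x, m, check.names = FALSE)
  fo <- if (is.null(cv))
    stats::lm(stats::reformulate(c("x", colnames(m)), "y"), data = dfo) else
      stats::lm(stats::reformulate(c("x", colnames(m), "cv"), "y"), data = dfo)
  b_hat <- stats::coef(fo)[colnames(m)]
  acme <- sum(a_hat * b_hat)
  ade <- unname(stats::coef(fo)["x"])
  total <- acme + ade

  set.seed(seed)
  a_draws <- matrix(0, n_sims, ncol(m))
  for (j in seq_len(ncol(m))) {
    cj <- stats::coef(med_fits[[j]])
    dr <- MASS::mvrnorm(n_sims, cj, a_cov[[j]])
    a_draws[, j] <- dr[, "x"]
  }
  od <- MASS::mvrnorm(n_sims, stats::coef(fo), stats::vcov(fo))
  b_draws <- od[, colnames(m), drop = FALSE]
  acme_draws <- rowSums(a_draws * b_draws)
  ade_draws <- od[, "x"]
  alpha <- 1 - ci
  ci_bounds <- unname(stats::quantile(acme_draws, c(alpha / 2, 1 - alpha / 2)))
  p <- min(1, 2 * min(mean(acme_draws <= 0), mean(acme_draws >= 0)))

  prop <- if (abs(total) < 1e-12 || sign(acme) * sign(total) < 0)
    NA_real_ else acme / total
  structure(list(acme = acme, ade = ade, total = total,
                 prop_mediated = prop,
                 ci = ci_bounds, ci_level = ci, p_value = p,
                 a = stats::setNames(a_hat, orig_ids),
                 b = stats::setNames(unname(b_hat), orig_ids),
                 contributions = stats::setNames(a_hat * unname(b_hat),
                                                 orig_ids),
                 acme_draws_summary = stats::quantile(acme_draws,
                                                      c(0.025, 0.5, 0.975)),
                 acme_draws_mean = mean(acme_draws),
                 acme_draws_sd = stats::sd(acme_draws),
                 ade_mean_draw = mean(ade_draws),
                 n = n, n_sims = n_sims, seed = seed,
                 mediator_model = med_fits, outcome_model = fo),
            class = "guild_mediation")
}

#' @export
print.guild_mediation <- function(x, ...) {
  cat(sprintf("mediation (n = %d, %d sims):\n", x$n, x$n_sims))
  cat(sprintf("  ACME %8.4g  [%0.4g, %0.4g]  p = %.4g\n",
              x$acme, x$ci[1], x$ci[2], x$p_value))
  cat(sprintf("  ADE  %8.4g   total %0.4g   prop. mediated %s\n",
              x$ade, x$total,
              if (is.na(x$prop_mediated)) "undefined" else
                sprintf("%.3f", x$prop_mediated)))
  invisible(x)
}

#' @export
coef.guild_mediation <- function(object, ...) {
  c(acme = object$acme, ade = object$ade, total = object$total)
}

#' @export
summary.guild_mediation <- function(object, ...) {
  print(object)
  if (length(object$contributions) > 1) {
    cat("per-mediator path contributions (a_j * b_j):\n")
    print(round(object$contributions, 4))
  }
  invisible(object)
}

#' Joint mediation through a set of mediators
#'
#' Each mediator is regressed on the exposure separately; the outcome is
#' regressed on the exposure and all mediators jointly. The combined ACME
#' is `sum_j a_j b_j`, with the same quasi-Bayesian machinery as
#' [mediate()] and per-mediator path contributions reported.
#'
#' @param x exposure vector.
#' @param m matrix or data frame of mediators (pairwise non-collinear;
#'   fewer than `n / 2` of them).
#' @param y outcome vector.
#' @inheritParams mediate
#' @return a `"guild_mediation"` object.
#' @export
mediate_joint <- function(x, m, y, covariates = NULL, n_sims = 1000,
                          seed = 1L, ci = 0.95) {
  m <- as.matrix(m)
  fit <- mediate_fit(x, m, y, covariates, n_sims, seed, ci)
  fit$mediator_id <- colnames(m)
  fit
}

#' Chained (multi-step) mediation
#'
#' Runs [mediate()] for each (exposure, mediator, outcome) triple of an
#' ordered chain, where one step's outcome may be the next step's
#' exposure. The chain must be acyclic.
#'
#' @param steps list of steps; each a list with numeric `x`, `m`, `y` and
#'   optionally `x_id`, `m_id`, `y_id` labels.
#' @inheritParams mediate
#' @return list of class `"guild_mediation_chain"`: one `"guild_mediation"`
#'   per step plus a `summary` data frame with per-step ACME and sign
#'   (`"green"` positive / `"red"` negative edge semantics).
#' @export
mediate_chain <- function(steps, covariates = NULL, n_sims = 1000, seed = 1L,
                          ci = 0.95) {
  ids <- lapply(seq_along(steps), function(i) {
    s <- steps[[i]]
    c(x = s$x_id %||% paste0("x", i), m = s$m_id %||% paste0("m", i),
      y = s$y_id %||% paste0("y", i))
  })
  edges <- do.call(rbind, lapply(ids, function(v)
    rbind(c(v[["x"]], v[["m"]]), c(v[["m"]], v[["y"]]))))
  g <- igraph::graph_from_edgelist(unique(edges), directed = TRUE)
  if (!igraph::is_dag(g)) stop("mediate_chain: cyclic chain rejected")
  fits <- vector("list", length(steps))
  for (i in seq_along(steps)) {
    s <- steps[[i]]
    fits[[i]] <- mediate(s$x, s$m, s$y, covariates = covariates,
                         n_sims = n_sims, seed = seed + i - 1L, ci = ci)
    fits[[i]]$mediator_id <- ids[[i]][["m"]]
  }
  summary_df <- data.frame(
    step = seq_along(steps),
    x = vapply(ids, `[[`, "", "x"),
    m = vapply(ids, `[[`, "", "m"),
    y = vapply(ids, `[[`, "", "y"),
    acme = vapply(fits, `[[`, 0, "acme"),
    ci_lower = vapply(fits, function(f) f$ci[1], 0),
    ci_upper = vapply(fits, function(f) f$ci[2], 0),
    p_value = vapply(fits, `[[`, 0, "p_value"))
  summary_df$sign <- ifelse(summary_df$acme >= 0, "green", "red")
  structure(list(steps = fits, summary = summary_df),
            class = "guild_mediation_chain")
}

#' @export
print.guild_mediation_chain <- function(x, ...) {
  cat("mediation chain:\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
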