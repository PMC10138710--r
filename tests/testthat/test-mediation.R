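test_that("a noiseless linear cascade is fully mediated", {
  set.seed(1)
  x <- rnorm(40)
  m <- 2 * x + rnorm(40, 0, 1e-4)  # vanishing mediator noise
  y <- 3 * m                       # outcome depends on the mediator only
  f <- mediate(x, m, y, n_sims = 200, seed = 2)
  expect_equal(f$acme, 6, tolerance = 1e-3)
  expect_equal(f$ade, 0, tolerance = 1e-3)
  expect_equal(f$prop_mediated, 1, tolerance = 1e-3)
  expect_equal(f$acme + f$ade, f$total, tolerance = 1e-8)
})

test_that("guards reject degenerate mediation inputs", {
  set.seed(2)
  x <- rnorm(30); m <- 0.5 * x + rnorm(30); y <- rnorm(30)
  expect_error(mediate(x, x, y), "collinear")
  expect_error(mediate(x, m, y, n_sims = 50), ">= 100")
  expect_error(mediate(x[1:5], m[1:5], y[1:5]), "n >= 10")
  expect_error(mediate(rep(1, 30), m, y), "constant")
  expect_error(mediate_joint(x, cbind(m, m), y), "collinear")
  expect_error(mediate_joint(x, matrix(rnorm(30 * 16), 30), y), "n / 2")
})

test_that("linear identity, sign equivariance and seed determinism hold", {
  set.seed(3)
  for (r in 1:10) {
    n <- 40
    x <- rnorm(n); m <- runif(1, -1, 1) * x + rnorm(n)
    y <- runif(1, -1, 1) * m + runif(1, -1, 1) * x + rnorm(n)
    f <- mediate(x, m, y, n_sims = 150, seed = r)
    expect_equal(f$acme + f$ade, f$total, tolerance = 1e-8)
    g <- mediate(x, m, -y, n_sims = 150, seed = r)
    expect_equal(g$acme, -f$acme, tolerance = 1e-10)
    expect_equal(g$ade, -f$ade, tolerance = 1e-10)
    expect_equal(g$total, -f$total, tolerance = 1e-10)
  }
  set.seed(20)
  x <- rnorm(30); m <- 0.4 * x + rnorm(30); y <- 0.3 * m + rnorm(30)
  f1 <- mediate(x, m, y, n_sims = 500, seed = 99)
  set.seed(1234)  # unrelated RNG state must not leak in
  f2 <- mediate(x, m, y, n_sims = 500, seed = 99)
  expect_identical(f1$ci, f2$ci)
  expect_identical(f1$p_value, f2$p_value)
})

test_that("the quasi-Bayesian draw mean converges to the coefficient product", {
  set.seed(4)
  x <- rnorm(80); m <- 0.5 * x + rnorm(80); y <- 0.4 * m + rnorm(80)
  f <- mediate(x, m, y, n_sims = 50000, seed = 5)
  a <- coef(lm(m ~ x))[["x"]]; b <- coef(lm(y ~ x + m))[["m"]]
  mc_se <- f$acme_draws_sd / sqrt(f$n_sims)
  expect_lt(abs(f$acme_draws_mean - a * b), 3 * mc_se + 1e-4)
})

test_that("interval and p-value are calibrated at the planted effect and the null", {
  set.seed(6)
  acmes <- numeric(120); cover <- logical(120)
  for (r in 1:120) {
    x <- rnorm(300); m <- 0.5 * x + rnorm(300); y <- 0.4 * m + rnorm(300)
    f <- mediate(x, m, y, n_sims = 200, seed = r)
    acmes[r] <- f$acme
    cover[r] <- f$ci[1] <= 0.2 && f$ci[2] >= 0.2
  }
  expect_lt(abs(mean(acmes) - 0.2), 0.05)
  expect_gte(mean(cover), 0.88)
  rej <- logical(200)
  for (r in 1:200) {
    x <- rnorm(100); m <- 0.5 * x + rnorm(100); y <- rnorm(100)
    rej[r] <- mediate(x, m, y, n_sims = 200, seed = r)$p_value < 0.05
  }
  expect_gte(mean(rej), 0.01)
  expect_lte(mean(rej), 0.11)
})

test_that("joint mediation sums path products and matches single-mediator fits", {
  set.seed(7)
  n <- 4000
  x <- rnorm(n)
  m1 <- 0.5 * x + rnorm(n); m2 <- 0.3 * x + rnorm(n)
  y <- 0.4 * m1 - 0.2 * m2 + rnorm(n)
  f <- mediate_joint(x, cbind(m1 = m1, m2 = m2), y, n_sims = 400, seed = 8)
  expect_lt(abs(f$acme - 0.14), 0.02)
  expect_equal(sum(f$contributions), f$acme, tolerance = 1e-12)
  expect_named(f$contributions, c("m1", "m2"))
  single <- mediate(x, m1, y - (-0.2) * m2, n_sims = 400, seed = 8)
  expect_equal(unname(f$a["m1"]), unname(single$a), tolerance = 0.05)
  # one-column joint model is exactly the single-mediator path
  fj <- mediate_joint(x, cbind(m = m1), y, n_sims = 300, seed = 9)
  fs <- mediate(x, m1, y, n_sims = 300, seed = 9)
  expect_equal(fj$acme, fs$acme, tolerance = 1e-12)
  expect_equal(fj$ci, fs$ci, tolerance = 1e-12)
})

test_that("chained mediation evaluates each step and rejects cycles", {
  set.seed(10)
  n <- 1500
  x <- rnorm(n)
  m1 <- 0.6 * x + rnorm(n)
  m2 <- 0.5 * m1 + rnorm(n)
  y <- -0.4 * m2 + rnorm(n)
  ch <- mediate_chain(list(
    list(x = x, m = m1, y = m2, x_id = "X", m_id = "M1", y_id = "M2"),
    list(x = m1, m = m2, y = y, x_id = "M1", m_id = "M2", y_id = "Y")),
    n_sims = 300, seed = 11)
  expect_equal(nrow(ch$summary), 2)
  # step ACMEs near their planted products (0.6*0.5 and 0.5*-0.4)
  expect_lt(abs(ch$summary$acme[1] - 0.30), 0.07)
  expect_lt(abs(ch$summary$acme[2] + 0.20), 0.07)
  expect_equal(ch$summary$sign, c("green", "red"))
  # an independent middle variable carries essentially no indirect effect
  ind <- rnorm(n)
  ch2 <- mediate_chain(list(list(x = x, m = ind, y = y, x_id = "X",
                                 m_id = "I", y_id = "Y")), n_sims = 300,
                       seed = 12)
  expect_lt(abs(ch2$summary$acme[1]), 0.05)
  # a one-step chain equals mediate() at the same seed
  f1 <- mediate(x, m1, y, n_sims = 200, seed = 13)
  ch3 <- mediate_chain(list(list(x = x, m = m1, y = y)), n_sims = 200,
                       seed = 13)
  expect_equal(ch3$steps[[1]]$acme, f1$acme, tolerance = 1e-12)
  expect_error(mediate_chain(list(
    list(x = x, m = m1, y = y, x_id = "A", m_id = "B", y_id = "C"),
    list(x = y, m = m2, y = x, x_id = "C", m_id = "D", y_id = "A"))),
    "cyclic")
})

test_that("planted cohort chains are recovered on the generator's scales", {
  coh <- generate_cohort(cohort_config(n_samples = 60, n_increase = 27,
                                       n_decrease = 33, seed = 31))
  meds <- coh$truth$chains[[1]]$mediators
  m <- coh$features$values[, meds]
  taxa_m <- grepl("^taxon\\.", meds)
  m[, taxa_m] <- log(m[, taxa_m])
  cv <- cbind(inc = coh$traits$trajectory == "increase",
              model.matrix(~ factor(coh$truth$enterotype))[, -1])
  f <- mediate_joint(coh$truth$x_std, m, log(coh$traits$FCP_week8),
                     covariates = cv, n_sims = 500, seed = 32)
  truth <- planted_acme(coh$config, "guild")
  expect_lte(f$ci[1], truth)
  expect_gte(f$ci[2], truth)
  expect_lt(f$ci[2], 0)  # the planted negative guild effect is detected
})
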