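test_that("candidate screening admits trait-linked features and few null ones", {
  set.seed(1)
  n <- 60
  mds <- rnorm(n)
  fcp <- rnorm(n)
  x <- matrix(rnorm(n * 40), n, 40, dimnames = list(NULL, sprintf("f%02d", 1:40)))
  x[, 1] <- 0.8 * mds + rnorm(n, 0, 0.6)   # linked to the diet score
  x[, 2] <- 0.8 * fcp + rnorm(n, 0, 0.6)   # linked to inflammation
  scr <- screen_candidates(x, mds, fcp)
  expect_true(all(c("f01", "f02") %in% scr$candidates))
  expect_equal(scr$n_screened, 40)
  # under "both", a single-trait feature is no longer admitted
  scr_both <- screen_candidates(x, mds, fcp, mode = "both")
  expect_false("f01" %in% scr_both$candidates)
  # the q threshold is inclusive: a feature sitting exactly at the cut stays in
  q_f1 <- scr$table$q_mds[scr$table$feature == "f01"]
  scr_edge <- screen_candidates(x, mds, fcp, q_max = q_f1)
  expect_true("f01" %in% scr_edge$candidates)
  # pure-noise screen admits at most a handful at FDR 0.20
  null_scr <- screen_candidates(matrix(rnorm(n * 100), n, 100,
                                       dimnames = list(NULL, sprintf("n%03d", 1:100))),
                                mds, fcp)
  expect_lte(null_scr$n_admitted, 10)
  expect_error(screen_candidates(x[, 0], mds, fcp), "empty module")
})

test_that("module-level mediation recovers a planted eigengene chain", {
  set.seed(2)
  n <- 80
  mds <- rnorm(n)
  me_mediator <- 0.7 * mds + rnorm(n, 0, 0.5)
  fcp <- -0.8 * me_mediator + rnorm(n, 0, 0.5)
  me <- cbind(grey = me_mediator, green = rnorm(n), blue = rnorm(n))
  g <- module_mediation_network(me, mds, fcp, n_sims = 400, seed = 3)
  expect_s3_class(g, "mediation_graph")
  expect_true(any(g$edges$from == "MDS" & g$edges$to == "grey"))
  expect_true(any(g$edges$from == "grey" & g$edges$to == "FCP"))
  ge <- g$tested[g$tested$source == "MDS" & g$tested$mediator == "grey" &
                   g$tested$sink == "FCP", ]
  expect_lt(ge$ci_upper, 0)  # negative indirect path detected
  # graph stays acyclic and reruns identically under the same seed
  ig <- igraph::graph_from_data_frame(g$edges[, c("from", "to")])
  expect_true(igraph::is_dag(ig))
  g2 <- module_mediation_network(me, mds, fcp, n_sims = 400, seed = 3)
  expect_identical(g$edges, g2$edges)
})

test_that("null module networks rarely produce confident mediation edges", {
  set.seed(4)
  n_edges <- integer(15)
  for (r in 1:15) {
    n <- 40
    me <- cbind(m1 = rnorm(n), m2 = rnorm(n), m3 = rnorm(n))
    g <- module_mediation_network(me, rnorm(n), rnorm(n), n_sims = 200,
                                  seed = r)
    n_edges[r] <- sum(g$edges$type == "mediation")
  }
  expect_gte(mean(n_edges == 0), 0.6)
})

test_that("feature-level networks separate mediators from direct-only features", {
  set.seed(5)
  n <- 80
  mds <- rnorm(n)
  med <- 0.8 * mds + rnorm(n, 0, 0.5)          # true mediator
  direct <- rnorm(n)                            # FCP-linked, diet-independent
  fcp <- -0.7 * med + 0.7 * direct + rnorm(n, 0, 0.5)
  x <- cbind(med = med, direct = direct, noise = rnorm(n))
  g <- feature_mediation_network(x, c("med", "direct", "noise"), mds, fcp,
                                 n_sims = 400, seed = 6)
  expect_true(any(g$edges$to == "med" & g$edges$type == "mediation"))
  dir_edges <- g$edges[g$edges$from == "direct", ]
  expect_true(all(dir_edges$type == "direct"))
  expect_true(any(dir_edges$to == "FCP"))
  expect_false(any(g$edges$to == "direct" & g$edges$type == "mediation"))
  # joint fit over the candidates carries per-feature contributions
  expect_s3_class(g$joint, "guild_mediation")
  # chains must reference admitted candidates only
  expect_error(feature_mediation_network(x, c("med"), mds, fcp,
                                         chains = list(c("MDS", "direct", "FCP")),
                                         n_sims = 200, seed = 7),
               "non-candidate")
  expect_error(feature_mediation_network(x, character(0), mds, fcp),
               "empty candidate")
  # chain steps are evaluated and merged into the graph
  g2 <- feature_mediation_network(x, c("med", "direct"), mds, fcp,
                                  chains = list(c("MDS", "med", "FCP")),
                                  n_sims = 200, seed = 8)
  expect_true(any(g2$edges$type == "chain"))
  # graphml export writes a readable file
  path <- tempfile(fileext = ".graphml")
  write_graphml(g2, path)
  expect_true(file.exists(path) && file.size(path) > 0)
})

test_that("all-null candidate sets leave the joint interval covering zero", {
  set.seed(9)
  n <- 50
  x <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("f", 1:5)))
  g <- feature_mediation_network(x, colnames(x), rnorm(n), rnorm(n),
                                 n_sims = 300, seed = 10)
  expect_lte(g$joint$ci[1], 0)
  expect_gte(g$joint$ci[2], 0)
})
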