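#' Screen module features for trait association
#'
#' Per feature, Spearman p-values against the diet score and against the
#' inflammation marker; BH correction applied separately within each trait
#' family. Candidates are features with q at or below the threshold
#' (inclusive) for at least one trait (`mode = "any"`) or for both
#' (`mode = "both"`).
#'
#' @param features samples x features matrix (e.g. one module's submatrix)
#'   or [omics_table].
#' @param mds,fcp per-sample diet score and inflammation marker.
#' @param q_max FDR threshold (default 0.20, inclusive).
#' @param mode `"any"` (default) or `"both"`.
#' @return list with `candidates` (feature ids), `table` (per-feature rho,
#'   p and q for both traits), `n_screened`, `n_admitted`.
#' @export
screen_candidates <- function(features, mds, fcp, q_max = 0.20,
                              mode = c("any", "both")) {
  mode <- match.arg(mode)
  x <- if (inherits(features, "omics_table")) features$values else as.matrix(features)
  if (ncol(x) == 0) stop("screen_candidates: empty module")
  one_trait <- function(tv) {
    res <- vapply(seq_len(ncol(x)), function(j) {
      ct <- suppressWarnings(stats::cor.test(x[, j], tv, method = "spearman"))
      c(ct$estimate, ct$p.value)
    }, numeric(2))
    list(rho = res[1, ], p = res[2, ])
  }
  a <- one_trait(mds); b <- one_trait(fcp)
  tab <- data.frame(feature = colnames(x),
                    rho_mds = a$rho, p_mds = a$p, q_mds = bh_fdr(a$p),
                    rho_fcp = b$rho, p_fcp = b$p, q_fcp = bh_fdr(b$p),
                    row.names = NULL)
  hit_mds <- tab$q_mds <= q_max
  hit_fcp <- tab$q_fcp <= q_max
  admitted <- if (mode == "any") hit_mds | hit_fcp else hit_mds & hit_fcp
  list(candidates = tab$feature[admitted], table = tab,
       n_screened = ncol(x), n_admitted = sum(admitted))
}

# add an edge unless it would create a cycle; returns updated edge df
add_edge_acyclic <- function(edges, from, to, attrs) {
  trial <- rbind(edges[, c("from", "to")], data.frame(from = from, to = to))
  g <- igraph::graph_from_data_frame(trial, directed = TRUE)
  if (!igraph::is_dag(g)) return(edges)
  rbind(edges, cbind(data.frame(from = from, to = to), attrs))
}

empty_edges <- function() {
  data.frame(from = character(), to = character(), type = character(),
             sign = character(), estimate = numeric(), p_value = numeric(),
             ci_lower = numeric(), ci_upper = numeric(), step = integer(),
             mediator = character())
}

#' Inter-module mediation network
#'
#' For the direct (diet score, inflammation) pair plus every ordered module
#' pair passing a marginal-association pre-filter (Spearman p < 0.10
#' between source and sink), tests every other module eigengene as a
#' mediator with [mediate()] and keeps edges whose ACME interval excludes
#' zero. The result is a directed acyclic graph whose edge signs follow
#' the ACME (green positive, red negative).
#'
#' @param eigengenes samples x modules eigengene matrix (from a
#'   `"conet"`).
#' @param mds,fcp per-sample traits.
#' @param n_sims,seed,ci passed to [mediate()].
#' @param prefilter_p marginal-association screen (default 0.10).
#' @return object of class `"mediation_graph"`: `edges` (data frame),
#'   `nodes`, `tested` (every mediation attempted with its ACME/CI).
#' @export
module_mediation_network <- function(eigengenes, mds, fcp, n_sims = 1000,
                                     seed = 1L, ci = 0.95,
                                     prefilter_p = 0.10) {
  me <- as.matrix(eigengenes)
  if (ncol(me) < 1) stop("module_mediation_network: no modules")
  vars <- cbind(MDS = mds, me, FCP = fcp)
  pairs <- list(c("MDS", "FCP"))
  mods <- colnames(me)
  for (i in mods) for (j in mods) if (i != j) pairs <- c(pairs, list(c(i, j)))
  edges <- empty_edges()
  tested <- list()
  k <- 0L
  for (pr in pairs) {
    src <- pr[1]; snk <- pr[2]
    ct <- suppressWarnings(stats::cor.test(vars[, src], vars[, snk],
                                           method = "spearman"))
    if (is.na(ct$p.value) || ct$p.value >= prefilter_p) next
    for (med in setdiff(mods, c(src, snk))) {
      k <- k + 1L
      fit <- mediate(vars[, src], vars[, med], vars[, snk],
                     n_sims = n_sims, seed = seed + k, ci = ci)
      tested[[k]] <- data.frame(source = src, mediator = med, sink = snk,
                                acme = fit$acme, ci_lower = fit$ci[1],
                                ci_upper = fit$ci[2], p_value = fit$p_value)
      if (fit$ci[1] > 0 || fit$ci[2] < 0) {
        sgn <- if (fit$acme >= 0) "green" else "red"
        at <- data.frame(type = "mediation", sign = sgn, estimate = fit$acme,
                         p_value = fit$p_value, ci_lower = fit$ci[1],
                         ci_upper = fit$ci[2], step = NA_integer_,
                         mediator = med)
        edges <- add_edge_acyclic(edges, src, med, at)
        edges <- add_edge_acyclic(edges, med, snk, at)
      }
    }
  }
  structure(list(edges = edges,
                 nodes = data.frame(id = c("MDS", mods, "FCP"),
                                    kind = c("trait", rep("eigengene",
                                                          length(mods)), "trait")),
                 tested = if (length(tested)) do.call(rbind, tested) else NULL),
            class = "mediation_graph")
}

#' Feature-level mediation network
#'
#' Runs diet-to-inflammation mediation through every screened candidate
#' feature, optional multi-step chain specifications, and the joint model
#' over the full candidate set, merging everything into one directed
#' graph. Features associated with the outcome but not admitted as
#' mediators appear as direct-edge nodes only.
#'
#' @param features samples x features matrix or [omics_table].
#' @param candidates candidate feature ids (from [screen_candidates()]).
#' @param mds,fcp per-sample traits.
#' @param chains optional list of chain specs: each a character vector of
#'   feature ids (or `"MDS"`/`"FCP"`) naming x, mediator(s), y in order.
#' @param n_sims,seed,ci passed to the mediation fits.
#' @return a `"mediation_graph"` with `edges`, `nodes`, `per_feature`
#'   (one mediation per candidate), `joint` (the combined fit), `chain_fits`.
#' @export
feature_mediation_network <- function(features, candidates, mds, fcp,
                                      chains = NULL, n_sims = 1000,
                                      seed = 1L, ci = 0.95) {
  x <- if (inherits(features, "omics_table")) features$values else as.matrix(features)
  if (!length(candidates)) stop("feature_mediation_network: empty candidate set")
  missing_c <- setdiff(candidates, colnames(x))
  if (length(missing_c))
    stop("feature_mediation_network: unknown candidate(s): ",
         paste(missing_c, collapse = ", "))
  get_var <- function(id) {
    if (id == "MDS") return(mds)
    if (id == "FCP") return(fcp)
    if (!id %in% colnames(x)) stop("feature_mediation_network: unknown id '", id, "'")
    x[, id]
  }
  edges <- empty_edges()
  per_feature <- list()
  for (i in seq_along(candidates)) {
    f <- candidates[i]
    fit <- mediate(mds, x[, f, drop = FALSE], fcp, n_sims = n_sims,
                   seed = seed + i, ci = ci)
    per_feature[[f]] <- fit
    if (fit$ci[1] > 0 || fit$ci[2] < 0) {
      sgn_a <- if (fit$a >= 0) "green" else "red"
      sgn_b <- if (fit$b >= 0) "green" else "red"
      edges <- add_edge_acyclic(edges, "MDS", f,
        data.frame(type = "mediation", sign = sgn_a, estimate = fit$acme,
                   p_value = fit$p_value, ci_lower = fit$ci[1],
                   ci_upper = fit$ci[2], step = NA_integer_, mediator = f))
      edges <- add_edge_acyclic(edges, f, "FCP",
        data.frame(type = "mediation", sign = sgn_b, estimate = fit$acme,
                   p_value = fit$p_value, ci_lower = fit$ci[1],
                   ci_upper = fit$ci[2], step = NA_integer_, mediator = f))
    } else {
      # direct-only annotation: marginal association with the outcome
      ct <- suppressWarnings(stats::cor.test(x[, f], fcp, method = "spearman"))
      if (!is.na(ct$p.value) && ct$p.value < 0.05) {
        edges <- add_edge_acyclic(edges, f, "FCP",
          data.frame(type = "direct", sign = if (ct$estimate >= 0) "green" else "red",
                     estimate = unname(ct$estimate), p_value = ct$p.value,
                     ci_lower = NA_real_, ci_upper = NA_real_,
                     step = NA_integer_, mediator = NA_character_))
      }
    }
  }
  chain_fits <- NULL
  if (!is.null(chains)) {
    chain_fits <- vector("list", length(chains))
    for (ci_i in seq_along(chains)) {
      spec <- chains[[ci_i]]
      feat_ids <- setdiff(spec, c("MDS", "FCP"))
      bad <- setdiff(feat_ids, candidates)
      if (length(bad))
        stop("feature_mediation_network: chain references non-candidate feature(s): ",
             paste(bad, collapse = ", "))
      steps <- lapply(seq_len(length(spec) - 2), function(s)
        list(x = get_var(spec[s]), m = get_var(spec[s + 1]),
             y = get_var(spec[s + 2]), x_id = spec[s], m_id = spec[s + 1],
             y_id = spec[s + 2]))
      cf <- mediate_chain(steps, n_sims = n_sims, seed = seed + 1000L * ci_i,
                          ci = ci)
      chain_fits[[ci_i]] <- cf
      for (s in seq_len(nrow(cf$summary))) {
        row <- cf$summary[s, ]
        edges <- add_edge_acyclic(edges, row$x, row$m,
          data.frame(type = "chain", sign = row$sign, estimate = row$acme,
                     p_value = row$p_value, ci_lower = row$ci_lower,
                     ci_upper = row$ci_upper, step = s, mediator = row$m))
        edges <- add_edge_acyclic(edges, row$m, row$y,
          data.frame(type = "chain", sign = row$sign, estimate = row$acme,
                     p_value = row$p_value, ci_lower = row$ci_lower,
                     ci_upper = row$ci_upper, step = s, mediator = row$m))
      }
    }
  }
  # joint model over the candidate set, capped well below n to keep the
  # outcome regression identifiable; strongest per-feature mediators first
  max_joint <- max(1L, floor(length(mds) / 3))
  joint_set <- candidates
  if (length(joint_set) > max_joint) {
    pvals <- vapply(per_feature[joint_set], `[[`, 0, "p_value")
    joint_set <- joint_set[order(pvals)][seq_len(max_joint)]
  }
  joint <- if (length(joint_set) >= 2)
    mediate_joint(mds, x[, joint_set, drop = FALSE], fcp, n_sims = n_sims,
                  seed = seed, ci = ci) else per_feature[[joint_set[1]]]
  nodes <- data.frame(id = c("MDS", candidates, "FCP"),
                      kind = c("trait", rep("feature", length(candidates)),
                               "trait"))
  structure(list(edges = edges, nodes = nodes, per_feature = per_feature,
                 joint = joint, chain_fits = chain_fits),
            class = "mediation_graph")
}

#' @export
print.mediation_graph <- function(x, ...) {
  cat(sprintf("mediation_graph: %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  if (nrow(x$edges)) print(utils::head(x$edges, 10), row.names = FALSE)
  if (!is.null(x$joint)) {
    cat("joint mediation over the candidate set:\n")
    print(x$joint)
  }
  invisible(x)
}

#' Export a mediation graph to GraphML
#'
#' @param graph a `"mediation_graph"`.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_graphml <- function(graph, path) {
  stopifnot(inherits(graph, "mediation_graph"))
  nodes <- graph$nodes[graph$nodes$id %in%
                         unique(c(graph$edges$from, graph$edges$to, graph$nodes$id)), ]
  g <- igraph::graph_from_data_frame(graph$edges, directed = TRUE,
                                     vertices = nodes)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
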