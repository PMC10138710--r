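#' Spearman correlation matrix over features
#'
#' Feature-feature Spearman rho with mid-ranks for ties. Constant features
#' have no rank variation and are rejected by name.
#'
#' @param table an [omics_table] or numeric matrix (samples x features).
#' @param method correlation method, `"spearman"` (default) or `"pearson"`.
#' @return symmetric features x features correlation matrix, unit diagonal.
#' @export
correlation_matrix <- function(table, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  x <- if (inherits(table, "omics_table")) table$values else as.matrix(table)
  if (nrow(x) < 3) stop("correlation_matrix: need at least 3 samples")
  const <- apply(x, 2, function(v) max(v) - min(v) == 0)
  if (any(const))
    stop("correlation_matrix: constant feature(s): ",
         paste(colnames(x)[const], collapse = ", "))
  rho <- stats::cor(x, method = method)
  diag(rho) <- 1
  rho
}

#' Soft-thresholded adjacency
#'
#' Raises correlation magnitudes to the power beta, shrinking weak edges
#' towards zero while keeping the network weighted. Unsigned networks use
#' `|rho|^beta`; signed networks use `((1 + rho) / 2)^beta` so negative
#' correlations map near zero.
#'
#' @param rho correlation matrix.
#' @param beta soft-thresholding power (>= 1).
#' @param network_sign `"unsigned"` (default) or `"signed"`.
#' @return adjacency matrix in `[0, 1]` with zero diagonal.
#' @export
adjacency <- function(rho, beta, network_sign = c("unsigned", "signed")) {
  network_sign <- match.arg(network_sign)
  if (beta < 1) stop("adjacency: 'beta' must be >= 1")
  a <- if (network_sign == "unsigned") abs(rho)^beta else ((1 + rho) / 2)^beta
  diag(a) <- 0
  a
}

# log10-log10 OLS fit of the degree distribution: connectivity values are
# placed in equal-width bins; p(k) is the fraction of nodes per bin and the
# bin is summarised by its mean connectivity (scaleFreeFitIndex convention).
scale_free_fit <- function(k, n_bins = 10) {
  if (max(k) - min(k) < .Machine$double.eps^0.5) return(NA_real_)
  bins <- cut(k, n_bins)
  dk <- tapply(k, bins, mean)
  pk <- tapply(k, bins, length) / length(k)
  keep <- !is.na(dk) & dk > 0 & !is.na(pk) & pk > 0
  if (sum(keep) < 3) return(NA_real_)
  fit <- stats::lm(log10(pk[keep]) ~ log10(dk[keep]))
  summary(fit)$r.squared
}

#' Scan soft-thresholding powers for scale-free topology fit
#'
#' For each power, forms the adjacency, computes node connectivities
#' `k_i = sum_j a_ij` and reports the R-squared of the log10-log10
#' regression of the binned degree distribution, plus mean and maximum
#' connectivity. Degenerate all-equal connectivities yield `NA` rather
#' than an error.
#'
#' @param rho correlation matrix (at least 20 features for a meaningful
#'   degree histogram).
#' @param power_range integer powers to scan (default `1:20`).
#' @param network_sign passed to [adjacency()].
#' @return data frame with columns `power`, `scale_free_r2`,
#'   `mean_connectivity`, `max_connectivity`.
#' @export
soft_threshold_scan <- function(rho, power_range = 1:20,
                                network_sign = "unsigned") {
  if (nrow(rho) < 20)
    stop("soft_threshold_scan: need >= 20 features for a degree histogram")
  rows <- lapply(power_range, function(beta) {
    a <- adjacency(rho, beta, network_sign)
    k <- rowSums(a)
    data.frame(power = beta,
               scale_free_r2 = scale_free_fit(k),
               mean_connectivity = mean(k),
               max_connectivity = max(k))
  })
  do.call(rbind, rows)
}

# adaptive cut of the feature dendrogram, scored by weighted Newman
# modularity on the soft-thresholded adjacency: candidate heights are
# scanned, clusters below min_size are dissolved to singletons, and the
# lowest height whose modularity comes within 1% of the maximum is chosen
# (preferring tight modules over ones padded with weakly attached
# features). Features outside qualifying clusters get label 0.
adaptive_cut <- function(hc, adj, min_size, rho, n_samples, cut_height = NULL) {
  # cohesion floor: a qualifying cluster must be visibly more correlated
  # than chance; under independence E|rho| ~ sqrt(2/pi)/sqrt(n - 1), and
  # chance agglomerates sit just above that while planted modules sit
  # several-fold higher
  cohesion_min <- 2 * sqrt(2 / pi) / sqrt(max(2, n_samples - 1))
  effective <- function(lab) {
    sizes <- table(lab)
    ifelse(sizes[as.character(lab)] >= min_size, lab, -seq_along(lab))
  }
  qualified <- function(eff) {
    out <- integer(length(eff))
    keep <- sort(unique(eff[eff > 0]))
    keep <- Filter(function(cl) {
      s <- abs(rho[eff == cl, eff == cl])
      mean(s[upper.tri(s)]) >= cohesion_min
    }, keep)
    for (i in seq_along(keep)) out[eff == keep[i]] <- i
    names(out) <- hc$labels
    out
  }
  if (!is.null(cut_height))
    return(qualified(effective(stats::cutree(hc, h = cut_height))))
  m2 <- sum(adj)
  deg <- rowSums(adj)
  modularity_q <- function(eff) {
    s <- rowsum(adj, eff)
    within <- sum(vapply(unique(eff),
                         function(cl) sum(s[as.character(cl), eff == cl]), 0))
    within / m2 - sum(tapply(deg, eff, sum)^2) / m2^2
  }
  hts <- sort(unique(hc$height))
  cand <- if (length(hts) > 80)
    unique(stats::quantile(hts, seq(0.05, 0.999, length.out = 80))) else
      unique(c(hts - min(diff(c(0, hts))) / 2, max(hts) * 0.999))
  labs <- lapply(cand, function(h) effective(stats::cutree(hc, h = h)))
  qs <- vapply(labs, modularity_q, 0)
  pick <- which(qs >= max(qs) - 0.01 * abs(max(qs)))[1]
  qualified(labs[[pick]])
}

# deterministic module colors by descending size (WGCNA-style palette,
# with numbered fallbacks beyond it); 0 -> "unclassified"
module_palette <- c("turquoise", "blue", "brown", "yellow", "green", "red",
                    "black", "pink", "magenta", "purple", "greenyellow",
                    "tan", "salmon", "cyan", "midnightblue", "lightcyan",
                    "grey60", "lightgreen", "lightyellow", "royalblue")

color_labels <- function(numeric_labels) {
  sizes <- sort(table(numeric_labels[numeric_labels > 0]), decreasing = TRUE)
  ord <- as.integer(names(sizes))
  cols <- c(module_palette, sprintf("module%02d", seq_len(max(0, length(ord) -
                                                                length(module_palette)))))
  map <- stats::setNames(cols[seq_along(ord)], ord)
  out <- rep("unclassified", length(numeric_labels))
  idx <- numeric_labels > 0
  out[idx] <- map[as.character(numeric_labels[idx])]
  names(out) <- names(numeric_labels)
  out
}

#' Detect initial co-abundance modules
#'
#' Builds an average-linkage hierarchical tree over features — by default
#' on the Euclidean distance between standardized (rank-transformed when
#' `cor_method = "spearman"`) feature profiles, optionally on the
#' topological-overlap dissimilarity of the soft-thresholded network — and
#' cuts it adaptively. Clusters smaller than `min_module_size` fall into
#' the unclassified pool (label `"unclassified"`); surviving clusters are
#' named by color in descending size order.
#'
#' @param table an [omics_table] or numeric matrix.
#' @param rho correlation matrix (required for `clustering_input = "tom"`).
#' @param min_module_size smallest admissible module (default 11).
#' @param clustering_input `"profiles"` (Euclidean distance between
#'   standardized profiles, default) or `"tom"`.
#' @param linkage hierarchical linkage (default `"average"`).
#' @param cor_method rank-transform profiles first when `"spearman"`.
#' @param power,network_sign adjacency parameters for `"tom"` input.
#' @param cut_height optional fixed cut height (disables the adaptive cut).
#' @return list with `labels` (color per feature), `tree` (the `hclust`)
#'   and the numeric labels used internally.
#' @export
detect_modules <- function(table, rho = NULL, min_module_size = 11,
                           clustering_input = c("profiles", "tom"),
                           linkage = "average",
                           cor_method = "spearman",
                           power = 10, network_sign = "unsigned",
                           cut_height = NULL) {
  clustering_input <- match.arg(clustering_input)
  x <- if (inherits(table, "omics_table")) table$values else as.matrix(table)
  p <- ncol(x)
  if (p < min_module_size) {
    lab <- stats::setNames(rep("unclassified", p), colnames(x))
    return(list(labels = lab, tree = NULL,
                numeric_labels = stats::setNames(integer(p), colnames(x))))
  }
  if (is.null(rho)) rho <- correlation_matrix(x, cor_method)
  a <- adjacency(rho, power, network_sign)
  if (clustering_input == "profiles") {
    prof <- if (cor_method == "spearman") apply(x, 2, rank) else x
    prof <- scale(prof)
    d <- stats::dist(t(prof))
  } else {
    d <- stats::as.dist(1 - tom_similarity(a))
  }
  hc <- stats::hclust(d, method = linkage)
  num <- adaptive_cut(hc, a, min_module_size, rho, nrow(x), cut_height)
  list(labels = color_labels(num), tree = hc, numeric_labels = num)
}

# topological overlap similarity of an adjacency matrix (zero diagonal)
tom_similarity <- function(a) {
  k <- rowSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  t <- num / den
  diag(t) <- 1
  t
}

#' Module eigengene
#'
#' First principal component of the z-scored module submatrix, scaled to
#' unit variance and sign-oriented so it correlates non-negatively with the
#' module's mean standardized profile. With `rank_based = TRUE` the
#' features are rank-transformed first, placing heterogeneous blocks
#' (compositional taxa, log-normal concentrations, centred diet variables)
#' on the common scale the Spearman network itself uses.
#'
#' @param table an [omics_table] or numeric matrix.
#' @param features character or integer index of the module's features.
#' @param rank_based summarize rank profiles instead of raw values
#'   (default `FALSE`; the full [conet()] fit uses ranks whenever its
#'   correlation is Spearman).
#' @return named per-sample eigengene vector (unit variance).
#' @export
module_eigengene <- function(table, features, rank_based = FALSE) {
  x <- if (inherits(table, "omics_table")) table$values else as.matrix(table)
  sub <- x[, features, drop = FALSE]
  if (rank_based) sub <- apply(sub, 2, rank)
  if (is.null(dim(sub))) sub <- matrix(sub, ncol = length(features))
  if (ncol(sub) == 0) stop("module_eigengene: empty module")
  if (nrow(sub) < 2) stop("module_eigengene: need at least 2 samples")
  z <- scale(sub)
  z[is.na(z)] <- 0  # constant features carry no signal
  sv <- svd(z, nu = 1, nv = 0)
  me <- sv$u[, 1]
  if (stats::sd(me) == 0) stop("module_eigengene: degenerate module")
  me <- me / stats::sd(me)
  if (sum(me * rowMeans(z)) < 0) me <- -me
  stats::setNames(me, rownames(x))
}

#' Signed module membership (kME)
#'
#' Pearson correlation of every feature profile with every module
#' eigengene; the sign carries the direction of association.
#'
#' @param table an [omics_table] or numeric matrix.
#' @param eigengenes samples x modules matrix of eigengenes.
#' @param cor_method rank-transform profiles first when `"spearman"`
#'   (matching the correlation used to build the network); Pearson on the
#'   given profiles otherwise.
#' @return features x modules kME matrix.
#' @export
signed_kme <- function(table, eigengenes, cor_method = "spearman") {
  x <- if (inherits(table, "omics_table")) table$values else as.matrix(table)
  prof <- if (cor_method == "spearman") apply(x, 2, rank) else x
  kme <- suppressWarnings(stats::cor(prof, eigengenes))
  kme[is.na(kme)] <- 0
  kme
}

#' Merge modules with similar eigengenes
#'
#' Iteratively merges modules whose eigengene dissimilarity
#' `1 - cor(ME_i, ME_j)` falls at or below the threshold, using an
#' average-linkage tree over the dissimilarities, recomputing eigengenes
#' after every round until no pair remains below the threshold.
#'
#' @param table an [omics_table] or numeric matrix.
#' @param labels color label per feature (`"unclassified"` ignored).
#' @param me_diss_threshold merge threshold on `1 - cor` (default 0.25).
#' @param rank_based passed to [module_eigengene()].
#' @return list with `labels`, `eigengenes` (samples x modules) and
#'   `merge_history` (data frame of absorbed -> kept pairs per round).
#' @export
merge_modules <- function(table, labels, me_diss_threshold = 0.25,
                          rank_based = FALSE) {
  history <- data.frame(round = integer(), absorbed = character(),
                        into = character())
  round_i <- 0L
  repeat {
    mods <- setdiff(unique(labels), "unclassified")
    me <- eigengene_matrix(table, labels, rank_based)
    if (length(mods) < 2) break
    dd <- 1 - stats::cor(me)
    if (all(dd[upper.tri(dd)] > me_diss_threshold)) break
    round_i <- round_i + 1L
    hc <- stats::hclust(stats::as.dist(dd), method = "average")
    grp <- stats::cutree(hc, h = me_diss_threshold)
    sizes <- table(labels)[colnames(me)]
    for (g in unique(grp)) {
      members <- colnames(me)[grp == g]
      if (length(members) < 2) next
      keep <- members[which.max(sizes[members])]
      for (ab in setdiff(members, keep)) {
        labels[labels == ab] <- keep
        history <- rbind(history, data.frame(round = round_i, absorbed = ab,
                                             into = keep))
      }
    }
    me <- eigengene_matrix(table, labels, rank_based)
  }
  list(labels = labels, eigengenes = me, merge_history = history)
}

# samples x modules eigengene matrix for a label vector
eigengene_matrix <- function(table, labels, rank_based = FALSE) {
  x <- if (inherits(table, "omics_table")) table$values else as.matrix(table)
  mods <- setdiff(unique(labels), "unclassified")
  mods <- mods[order(-as.numeric(table(labels)[mods]), mods)]
  me <- vapply(mods, function(m) module_eigengene(x, which(labels == m),
                                                  rank_based),
               numeric(nrow(x)))
  colnames(me) <- mods
  rownames(me) <- rownames(x)
  me
}

#' Refine module membership by kME
#'
#' Features whose membership score for their own module falls below the
#' threshold (strictly; the threshold itself is retained, membership
#' "score of >= 0.30") are moved to the unclassified set.
#'
#' @param kme features x modules kME matrix.
#' @param labels color label per feature.
#' @param kme_min minimum own-module membership (default 0.30).
#' @return updated label vector.
#' @export
refine_membership <- function(kme, labels, kme_min = 0.30) {
  for (i in seq_along(labels)) {
    m <- labels[i]
    if (m == "unclassified") next
    if (kme[i, m] < kme_min) labels[i] <- "unclassified"
  }
  labels
}

#' Fit a weighted co-abundance network
#'
#' The full network pipeline over a heterogeneous feature table: Spearman
#' correlation, soft-threshold power scan, hierarchical module detection,
#' module eigengenes, eigengene-based merging of near-duplicate modules,
#' signed module membership (kME) and membership refinement. Returns a
#' fitted `"conet"` object.
#'
#' @param table an [omics_table] or numeric samples x features matrix.
#' @param power soft-thresholding power (default 10; the power-scan table
#'   in the fit supports picking an alternative such as 11).
#' @param min_module_size smallest admissible module (default 11).
#' @param merge_diss eigengene-dissimilarity merge threshold (default 0.25).
#' @param kme_min minimum own-module membership to stay classified
#'   (default 0.30).
#' @param network_sign `"unsigned"` (default) or `"signed"`.
#' @param cor_method `"spearman"` (default) or `"pearson"`.
#' @param clustering_input `"profiles"` (default) or `"tom"`.
#' @param linkage hierarchical linkage (default `"average"`).
#' @param power_range powers scanned for the scale-free fit table.
#' @param scan_powers set `FALSE` to skip the power scan.
#' @param cut_height optional fixed dendrogram cut height.
#' @return object of class `"conet"`: `labels` (color per feature,
#'   `"unclassified"` for the unassigned set), `eigengenes` (samples x
#'   modules, unit variance), `kme`, `sft` (power-scan table),
#'   `merge_history`, `tree`, `blocks`, and the configuration used.
#' @examples
#' coh <- generate_cohort(cohort_config(n_samples = 30, n_increase = 14,
#'                                      n_decrease = 16, seed = 1))
#' fit <- conet(coh$features, scan_powers = FALSE)
#' print(fit)
#' @export
conet <- function(table, power = 10, min_module_size = 11, merge_diss = 0.25,
                  kme_min = 0.30, network_sign = c("unsigned", "signed"),
                  cor_method = c("spearman", "pearson"),
                  clustering_input = c("profiles", "tom"),
                  linkage = "average", power_range = 1:20,
                  scan_powers = TRUE, cut_height = NULL) {
  network_sign <- match.arg(network_sign)
  cor_method <- match.arg(cor_method)
  clustering_input <- match.arg(clustering_input)
  if (power %in% c(10, 11))
    message("conet: soft-thresholding power ", power,
            " (10 and 11 are both defensible for this design; see the power scan)")
  x <- if (inherits(table, "omics_table")) table$values else as.matrix(table)
  blocks <- if (inherits(table, "omics_table")) table$blocks else
    stats::setNames(rep("feature", ncol(x)), colnames(x))

  rho <- correlation_matrix(x, cor_method)
  sft <- if (scan_powers && ncol(x) >= 20)
    soft_threshold_scan(rho, power_range, network_sign) else NULL

  det <- detect_modules(x, rho = rho, min_module_size = min_module_size,
                        clustering_input = clustering_input, linkage = linkage,
                        cor_method = cor_method, power = power,
                        network_sign = network_sign, cut_height = cut_height)
  labels <- det$labels
  if (all(labels == "unclassified")) {
    merged <- list(labels = labels, eigengenes = NULL,
                   merge_history = data.frame())
  } else {
    merged <- merge_modules(x, labels, merge_diss,
                            rank_based = cor_method == "spearman")
  }
  labels <- merged$labels
  kme <- NULL
  if (!is.null(merged$eigengenes)) {
    kme <- signed_kme(x, merged$eigengenes, cor_method)
    labels <- refine_membership(kme, labels, kme_min)
    # refinement can empty or shrink a module below the minimum size
    small <- names(which(table(labels[labels != "unclassified"]) < min_module_size))
    labels[labels %in% small] <- "unclassified"
    if (any(labels != "unclassified")) {
      me <- eigengene_matrix(x, labels, rank_based = cor_method == "spearman")
      kme <- signed_kme(x, me, cor_method)
    } else {
      me <- NULL; kme <- NULL
    }
  } else me <- NULL
  structure(list(labels = labels,
                 unclassified = names(labels)[labels == "unclassified"],
                 eigengenes = me, kme = kme, sft = sft,
                 merge_history = merged$merge_history, tree = det$tree,
                 adjacency_power = power, blocks = blocks,
                 config = list(power = power, min_module_size = min_module_size,
                               merge_diss = merge_diss, kme_min = kme_min,
                               network_sign = network_sign,
                               cor_method = cor_method,
                               clustering_input = clustering_input,
                               linkage = linkage)),
            class = "conet")
}

#' @export
print.conet <- function(x, ...) {
  mods <- setdiff(unique(x$labels), "unclassified")
  cat(sprintf("conet fit: %d features -> %d modules (%d classified, %d unclassified)\n",
              length(x$labels), length(mods),
              sum(x$labels != "unclassified"), length(x$unclassified)))
  cat(sprintf("  power = %g (%s, %s), min module size %d, merge diss %.2f, kME >= %.2f\n",
              x$config$power, x$config$network_sign, x$config$cor_method,
              x$config$min_module_size, x$config$merge_diss, x$config$kme_min))
  if (length(mods)) {
    sizes <- sort(table(x$labels[x$labels != "unclassified"]), decreasing = TRUE)
    cat("  module sizes:\n")
    print(sizes)
  }
  invisible(x)
}

#' @export
summary.conet <- function(object, ...) {
  sizes <- table(object$labels)
  blocks_by_module <- table(object$labels, object$blocks)
  out <- list(n_modules = sum(names(sizes) != "unclassified"),
              sizes = sizes, blocks_by_module = blocks_by_module,
              sft = object$sft, merge_history = object$merge_history)
  class(out) <- "summary.conet"
  out
}

#' @export
print.summary.conet <- function(x, ...) {
  cat(sprintf("conet summary: %d modules\n", x$n_modules))
  print(x$sizes)
  cat("block composition:\n")
  print(x$blocks_by_module)
  if (!is.null(x$sft)) {
    cat("scale-free fit by power (head):\n")
    print(utils::head(x$sft))
  }
  invisible(x)
}

#' @export
plot.conet <- function(x, ...) {
  if (is.null(x$tree)) stop("plot.conet: no dendrogram stored")
  op <- graphics::par(mfrow = c(2, 1), mar = c(1, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$tree, labels = FALSE, hang = -1,
                 main = "Feature dendrogram", xlab = "", sub = "")
  ord <- x$tree$order
  cols <- x$labels[ord]
  cols[cols == "unclassified"] <- "grey90"
  cols[!cols %in% grDevices::colors()] <- "grey40"
  graphics::image(matrix(seq_along(ord), ncol = 1),
                  col = cols, axes = FALSE, main = "Module colors")
  invisible(x)
}

#' Export the thresholded network as an edge table
#'
#' @param fit a `"conet"`.
#' @param table the feature table used for the fit.
#' @param cutoff minimum adjacency to keep an edge (default 0.1).
#' @return data frame with `from`, `to`, `adjacency`, `rho`.
#' @export
conet_edges <- function(fit, table, cutoff = 0.1) {
  x <- if (inherits(table, "omics_table")) table$values else as.matrix(table)
  rho <- correlation_matrix(x, fit$config$cor_method)
  a <- adjacency(rho, fit$config$power, fit$config$network_sign)
  idx <- which(upper.tri(a) & a >= cutoff, arr.ind = TRUE)
  data.frame(from = colnames(x)[idx[, 1]], to = colnames(x)[idx[, 2]],
             adjacency = a[idx], rho = rho[idx])
}
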