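#' Jensen-Shannon distance between relative-abundance profiles
#'
#' Square root of the Jensen-Shannon divergence (natural log), the
#' enterotyping-literature community distance. Rows are renormalised to
#' sum to one; zeros contribute nothing to their own term.
#'
#' @param x samples x taxa matrix of non-negative abundances.
#' @return symmetric distance matrix.
#' @export
jsd_distance <- function(x) {
  x <- as.matrix(x)
  if (any(x < 0)) stop("jsd_distance: abundances must be non-negative")
  p <- x / rowSums(x)
  n <- nrow(p)
  kl <- function(a, m) {
    i <- a > 0
    sum(a[i] * log(a[i] / m[i]))
  }
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
    m <- (p[i, ] + p[j, ]) / 2
    d[i, j] <- d[j, i] <- sqrt(0.5 * kl(p[i, ], m) + 0.5 * kl(p[j, ], m))
  }
  d
}

#' Enterotype samples by partitioning around medoids
#'
#' PAM clustering of baseline taxa profiles on a community distance
#' (Jensen-Shannon by default, Bray-Curtis optionally). When a range of k
#' is given, the k maximising the average silhouette width is chosen.
#' PAM's build and swap phases are deterministic given the distance
#' matrix; the seed is set for reproducibility of any downstream use.
#'
#' @param taxa samples x taxa relative-abundance matrix (or [omics_table]
#'   whose `taxon` block is used).
#' @param k single number of clusters or a range (default `2:6`).
#' @param distance `"jsd"` (default) or `"bray"`.
#' @param seed integer seed.
#' @return object of class `"cag_partition"`: `clusters` (sample ->
#'   cluster id), `k`, `medoids`, `silhouette` (average width, `NA` for
#'   k = 1), `silhouette_by_k`, `distance`.
#' @export
enterotype <- function(taxa, k = 2:6, distance = c("jsd", "bray"), seed = 1L) {
  distance <- match.arg(distance)
  if (inherits(taxa, "omics_table")) {
    keep <- taxa$blocks == "taxon"
    if (!any(keep)) stop("enterotype: no taxon block present")
    taxa <- taxa$values[, keep, drop = FALSE]
  }
  taxa <- as.matrix(taxa)
  n <- nrow(taxa)
  if (max(k) >= n) stop("enterotype: k must be < number of samples")
  d <- if (distance == "jsd") stats::as.dist(jsd_distance(taxa)) else
    vegan::vegdist(taxa, method = "bray")
  set.seed(seed)
  if (length(k) == 1 && k == 1) {
    part <- list(clusters = stats::setNames(rep(1L, n), rownames(taxa)),
                 k = 1L, medoids = rownames(taxa)[1],
                 silhouette = NA_real_, silhouette_by_k = NULL,
                 distance = distance)
    class(part) <- "cag_partition"
    return(part)
  }
  fits <- lapply(k, function(kk) cluster::pam(d, k = kk, diss = TRUE))
  sil <- vapply(fits, function(f)
    if (f$medoids[1] != "" && length(unique(f$clustering)) > 1)
      f$silinfo$avg.width else NA_real_, 0)
  best <- which.max(sil)
  fit <- fits[[best]]
  part <- list(clusters = stats::setNames(as.integer(fit$clustering),
                                          rownames(taxa)),
               k = as.integer(k[best]),
               medoids = fit$medoids,
               silhouette = sil[best],
               silhouette_by_k = data.frame(k = k, avg_silhouette = sil),
               distance = distance)
  class(part) <- "cag_partition"
  part
}

#' @export
print.cag_partition <- function(x, ...) {
  cat(sprintf("cag_partition: k = %d (%s distance), avg silhouette %.3f\n",
              x$k, x$distance, x$silhouette))
  print(table(cluster = x$clusters))
  if (!is.null(x$risk)) print(x$risk)
  invisible(x)
}

#' Dominant taxa per enterotype cluster
#'
#' Filters taxa by prevalence (fraction of subjects with abundance > 0),
#' compares abundance across clusters by the Kruskal-Wallis test with BH
#' correction, and assigns each surviving taxon to the cluster where its
#' median abundance is highest.
#'
#' @param taxa samples x taxa abundances (or [omics_table] `taxon` block).
#' @param clusters sample -> cluster id (as from [enterotype()]).
#' @param prevalence_min minimum prevalence (default 0.10).
#' @param fdr_max maximum BH q to call a taxon dominant (default 0.1).
#' @return data frame `taxon`, `cluster`, `prevalence`, `kw_h`, `p_value`,
#'   `q_value`, `dominant` (logical; prevalence and q filters combined).
#' @export
dominant_taxa <- function(taxa, clusters, prevalence_min = 0.10, fdr_max = 0.1) {
  if (inherits(taxa, "omics_table")) {
    keep <- taxa$blocks == "taxon"
    taxa <- taxa$values[, keep, drop = FALSE]
  }
  taxa <- as.matrix(taxa)
  if (length(unique(clusters)) < 2) stop("dominant_taxa: need >= 2 clusters")
  clusters <- clusters[rownames(taxa)]
  prevalence <- colMeans(taxa > 0)
  tested <- prevalence >= prevalence_min
  res <- data.frame(taxon = colnames(taxa), prevalence = prevalence,
                    kw_h = NA_real_, p_value = NA_real_, q_value = NA_real_,
                    cluster = NA_integer_, row.names = NULL)
  if (any(tested)) {
    for (j in which(tested)) {
      grp_vals <- split(taxa[, j], clusters)
      if (max(taxa[, j]) - min(taxa[, j]) == 0) {
        res$kw_h[j] <- 0; res$p_value[j] <- 1
      } else {
        kw <- kruskal_wallis(grp_vals)
        res$kw_h[j] <- kw$h; res$p_value[j] <- kw$p_value
      }
      meds <- vapply(grp_vals, stats::median, 0)
      res$cluster[j] <- as.integer(names(meds)[which.max(meds)])
    }
    res$q_value[tested] <- bh_fdr(res$p_value[tested])
  }
  res$dominant <- tested & !is.na(res$q_value) & res$q_value <= fdr_max
  res
}

#' Label enterotype clusters by inflammation risk
#'
#' Reports the Kruskal-Wallis test of baseline FCP across clusters and
#' labels the cluster with the highest median FCP `"high"`, the lowest
#' `"low"`, all others `"neutral"`. A tie between the extreme medians
#' yields `"neutral"` for the tied clusters, with a warning.
#'
#' @param partition a `"cag_partition"` (or a sample -> cluster vector).
#' @param fcp_baseline per-sample baseline FCP, aligned with the samples.
#' @return the partition with `risk` (cluster -> label) and `fcp_kw`
#'   (list with `h`, `p_value`, `medians`) attached; for a plain vector
#'   input, the same information as a list.
#' @export
classify_risk <- function(partition, fcp_baseline) {
  clusters <- if (inherits(partition, "cag_partition")) partition$clusters else partition
  grp <- split(fcp_baseline, clusters)
  meds <- vapply(grp, stats::median, 0)
  kw <- if (length(grp) >= 2) kruskal_wallis(grp) else list(h = NA, p_value = NA)
  risk <- stats::setNames(rep("neutral", length(meds)), names(meds))
  if (length(meds) >= 2) {
    hi <- names(meds)[meds == max(meds)]
    lo <- names(meds)[meds == min(meds)]
    if (length(hi) == 1 && length(lo) == 1 && hi != lo) {
      risk[hi] <- "high"; risk[lo] <- "low"
    } else {
      warning("classify_risk: tied extreme medians; tied clusters labelled neutral")
      if (length(hi) == 1) risk[hi] <- "high"
      if (length(lo) == 1) risk[lo] <- "low"
    }
  }
  info <- list(h = kw$h, p_value = kw$p_value, medians = meds)
  if (inherits(partition, "cag_partition")) {
    partition$risk <- risk
    partition$fcp_kw <- info
    partition
  } else list(risk = risk, fcp_kw = info)
}

#' Module enrichment for risk-CAG taxa
#'
#' One-sided hypergeometric over-representation of each risk-taxa set in
#' each module, over the universe of all classified taxa, with BH
#' correction across module x set combinations.
#'
#' @param fit a `"conet"` (or a feature -> module label vector).
#' @param risk_sets named list of taxa-id vectors (e.g. `high`, `low`).
#' @param universe taxa universe; defaults to all classified taxa in the
#'   fit (features in the `taxon` block not labelled unclassified).
#' @param fdr_max enrichment call threshold on q (default 0.1).
#' @return data frame `module`, `set`, `overlap`, `module_taxa`,
#'   `set_size`, `universe`, `p_value`, `q_value`, `enriched`.
#' @export
module_cag_enrichment <- function(fit, risk_sets, universe = NULL,
                                  fdr_max = 0.1) {
  labels <- if (inherits(fit, "conet")) fit$labels else fit
  if (is.null(universe)) {
    if (inherits(fit, "conet")) {
      universe <- names(labels)[fit$blocks[names(labels)] == "taxon" &
                                  labels != "unclassified"]
    } else universe <- names(labels)[labels != "unclassified"]
  }
  if (!length(universe)) stop("module_cag_enrichment: empty universe")
  labels <- labels[universe]
  mods <- setdiff(unique(labels), "unclassified")
  rows <- list()
  for (m in mods) for (s in names(risk_sets)) {
    in_mod <- names(labels)[labels == m]
    set_u <- intersect(risk_sets[[s]], universe)
    q <- length(intersect(in_mod, set_u))
    rows[[length(rows) + 1L]] <- data.frame(
      module = m, set = s, overlap = q, module_taxa = length(in_mod),
      set_size = length(set_u), universe = length(universe),
      p_value = stats::phyper(q - 1, length(set_u),
                              length(universe) - length(set_u),
                              length(in_mod), lower.tail = FALSE))
  }
  out <- do.call(rbind, rows)
  out$q_value <- bh_fdr(out$p_value)
  out$enriched <- out$q_value <= fdr_max
  out
}
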