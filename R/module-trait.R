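#' Associate module eigengenes or features with traits
#'
#' Spearman correlation of each entity (eigengene or feature profile) with
#' each trait, with two-sided p-values and the significance tiers used for
#' reporting: `"*"` for p < 0.05, `"@"` for 0.05 <= p < 0.10, `"N"`
#' otherwise.
#'
#' @param profiles samples x entities matrix (eigengenes or features) or an
#'   [omics_table].
#' @param traits data frame of per-sample traits (rownames = sample ids).
#' @param trait_names which trait columns to test (default all numeric).
#' @return data frame with `entity`, `trait`, `rho`, `p_value`, `tier`.
#' @export
associate_traits <- function(profiles, traits, trait_names = NULL) {
  x <- if (inherits(profiles, "omics_table")) profiles$values else as.matrix(profiles)
  if (is.null(trait_names))
    trait_names <- names(traits)[vapply(traits, is.numeric, TRUE)]
  stopifnot(nrow(x) == nrow(traits))
  if (nrow(x) < 4) stop("associate_traits: need >= 4 paired observations")
  rows <- list()
  for (tn in trait_names) {
    tv <- traits[[tn]]
    if (max(tv) - min(tv) == 0) stop("associate_traits: constant trait '", tn, "'")
    for (j in seq_len(ncol(x))) {
      ct <- suppressWarnings(stats::cor.test(x[, j], tv, method = "spearman",
                                             exact = nrow(x) <= 9))
      rows[[length(rows) + 1L]] <-
        data.frame(entity = colnames(x)[j], trait = tn,
                   rho = unname(ct$estimate), p_value = ct$p.value)
    }
  }
  out <- do.call(rbind, rows)
  out$tier <- significance_tier(out$p_value)
  out
}

#' Significance tier from a p-value
#'
#' @param p p-value vector.
#' @return `"*"` (p < 0.05), `"@"` (0.05 <= p < 0.10) or `"N"`.
#' @export
significance_tier <- function(p) {
  ifelse(p < 0.05, "*", ifelse(p < 0.10, "@", "N"))
}

#' Screen taxa for association with a trait
#'
#' Per-taxon Spearman correlation against a trait with BH q-values;
#' positive rho means higher abundance with a higher trait value.
#'
#' @param taxa samples x taxa abundance matrix (or [omics_table] whose
#'   `taxon` block is used).
#' @param trait numeric per-sample trait.
#' @param fdr_q report-only threshold carried in the output attribute
#'   (default 0.05); all taxa are returned, ranked by p.
#' @return data frame `taxon`, `rho`, `p_value`, `q_value`, ordered by p.
#' @export
species_trait_screen <- function(taxa, trait, fdr_q = 0.05) {
  if (inherits(taxa, "omics_table")) {
    keep <- taxa$blocks == "taxon"
    if (!any(keep)) stop("species_trait_screen: no taxon block present")
    taxa <- taxa$values[, keep, drop = FALSE]
  }
  taxa <- as.matrix(taxa)
  res <- lapply(seq_len(ncol(taxa)), function(j) {
    ct <- suppressWarnings(stats::cor.test(taxa[, j], trait, method = "spearman"))
    data.frame(taxon = colnames(taxa)[j], rho = unname(ct$estimate),
               p_value = ct$p.value)
  })
  out <- do.call(rbind, res)
  out$q_value <- bh_fdr(out$p_value)
  out <- out[order(out$p_value), ]
  rownames(out) <- NULL
  attr(out, "fdr_q") <- fdr_q
  out
}
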