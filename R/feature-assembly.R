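#' Omics feature table
#'
#' Light container for a samples x features matrix with a block label per
#' feature (taxon, serum_metabolite, scfa, bile_acid, diet_total,
#' diet_adjusted, food_group_freq). Blocks keep track of which slice of the
#' multi-omics panel a feature came from through network construction,
#' screening and mediation.
#'
#' @param values numeric matrix, samples in rows, features in columns, with
#'   dimnames.
#' @param blocks character vector of block labels, one per feature.
#' @return object of class `"omics_table"`.
#' @export
omics_table <- function(values, blocks) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("omics_table: values needs sample and feature dimnames")
  if (anyDuplicated(rownames(values))) stop("omics_table: duplicate sample ids")
  if (anyDuplicated(colnames(values))) stop("omics_table: duplicate feature ids")
  if (length(blocks) != ncol(values))
    stop("omics_table: one block label per feature required")
  blocks <- as.character(blocks)
  names(blocks) <- colnames(values)
  structure(list(values = values, blocks = blocks), class = "omics_table")
}

#' @export
print.omics_table <- function(x, ...) {
  cat(sprintf("omics_table: %d samples x %d features\n",
              nrow(x$values), ncol(x$values)))
  print(table(x$blocks))
  invisible(x)
}

#' @export
dim.omics_table <- function(x) dim(x$values)

#' Mediterranean diet score from screener criteria
#'
#' Adherence score from the 14-item PREDIMED-style screener with the
#' alcohol item removed (alcohol being contraindicated in IBD), leaving 13
#' yes/no criteria. The score is the count of criteria met, 0-13.
#'
#' @param item_flags logical vector of exactly 13 criterion flags.
#' @return integer score in `[0, 13]`.
#' @export
compute_mds <- function(item_flags) {
  if (length(item_flags) != 13 || anyNA(item_flags) || !is.logical(item_flags))
    stop("compute_mds: item_flags must be 13 non-missing logicals (alcohol item excluded)")
  as.integer(sum(item_flags))
}

#' Energy-adjust a nutrient intake to per-1000-kcal
#'
#' @param amount nutrient quantity per day (any unit).
#' @param energy energy intake, kcal per day; must be positive.
#' @return `amount * 1000 / energy`, in the nutrient unit per 1000 kcal.
#' @export
adjust_per_1000kcal <- function(amount, energy) {
  if (any(energy <= 0)) stop("adjust_per_1000kcal: energy must be > 0")
  amount * 1000 / energy
}

#' Classify the fecal calprotectin trajectory
#'
#' Labels a participant "increase" or "decrease" by the sign of the week-8
#' minus baseline change. Exact ties are rejected: the cohort design keeps
#' only participants whose FCP changed.
#'
#' @param fcp_baseline,fcp_week8 FCP concentrations (mcg/g, >= 0).
#' @return `"increase"` or `"decrease"` (vectorised).
#' @export
classify_fcp_trajectory <- function(fcp_baseline, fcp_week8) {
  if (any(fcp_baseline < 0) || any(fcp_week8 < 0))
    stop("classify_fcp_trajectory: FCP must be >= 0")
  if (any(fcp_week8 == fcp_baseline))
    stop("classify_fcp_trajectory: tie (no FCP change); participant excluded by design",
         call. = FALSE)
  ifelse(fcp_week8 > fcp_baseline, "increase", "decrease")
}

#' Fecal calprotectin category
#'
#' Standard clinical bins: < 100 mcg/g consistent with remission,
#' 100-250 the diagnostic grey zone (both boundaries inclusive),
#' > 250 active inflammation.
#'
#' @param fcp FCP concentration (mcg/g, >= 0), vectorised.
#' @return character vector in `{"remission", "grey_zone", "active"}`.
#' @export
fcp_category <- function(fcp) {
  if (any(fcp < 0)) stop("fcp_category: FCP must be >= 0")
  ifelse(fcp < 100, "remission", ifelse(fcp <= 250, "grey_zone", "active"))
}

#' Assemble per-block feature tables into one analysis-ready table
#'
#' Column-binds the blocks over the shared samples, namespacing feature ids
#' by block prefix, restricting to samples present in every block and with
#' a defined FCP trajectory, imputing or dropping missing values, and
#' dropping constant features (which carry no rank information and break
#' correlation).
#'
#' @param blocks named list of numeric matrices (samples x features), names
#'   are block labels.
#' @param traits data frame with rownames = sample ids and columns at least
#'   `FCP_baseline` and `FCP_week8` (an `MDS` column and medication flags
#'   are carried through when present).
#' @param max_missing maximum tolerated fraction of missing values per
#'   feature before the feature is dropped (default 0.2); below that,
#'   missing cells are median-imputed.
#' @return list with `features` (an [omics_table]) and `traits` (the trait
#'   data frame restricted to the kept samples, with a `trajectory` column).
#' @export
assemble_features <- function(blocks, traits, max_missing = 0.2) {
  if (is.null(names(blocks)) || any(names(blocks) == ""))
    stop("assemble_features: blocks must be a named list")
  blocks <- lapply(blocks, as.matrix)
  shared <- Reduce(intersect, c(lapply(blocks, rownames), list(rownames(traits))))
  dropped <- setdiff(unique(unlist(lapply(blocks, rownames))), shared)
  if (length(dropped))
    message("assemble_features: dropping samples absent from some block: ",
            paste(dropped, collapse = ", "))
  if (length(shared) < 3) stop("assemble_features: fewer than 3 shared samples")
  traits <- traits[shared, , drop = FALSE]
  traits$trajectory <- classify_fcp_trajectory(traits$FCP_baseline, traits$FCP_week8)

  mats <- lapply(names(blocks), function(b) {
    m <- blocks[[b]][shared, , drop = FALSE]
    colnames(m) <- paste(b, colnames(m), sep = ".")
    m
  })
  x <- do.call(cbind, mats)
  labels <- rep(names(blocks), vapply(blocks, ncol, 0L))

  # missingness policy: drop heavily missing features, median-impute the rest
  frac_na <- colMeans(is.na(x))
  if (any(frac_na > max_missing)) {
    message("assemble_features: dropping ", sum(frac_na > max_missing),
            " feature(s) with > ", max_missing * 100, "% missing values")
    keep <- frac_na <= max_missing
    x <- x[, keep, drop = FALSE]
    labels <- labels[keep]
  }
  if (anyNA(x)) {
    for (j in which(colSums(is.na(x)) > 0)) {
      med <- stats::median(x[, j], na.rm = TRUE)
      x[is.na(x[, j]), j] <- med
    }
  }
  constant <- apply(x, 2, function(v) max(v) - min(v) == 0)
  if (any(constant)) {
    warning("assemble_features: dropping ", sum(constant), " constant feature(s): ",
            paste(utils::head(colnames(x)[constant], 5), collapse = ", "),
            if (sum(constant) > 5) ", ..." else "")
    x <- x[, !constant, drop = FALSE]
    labels <- labels[!constant]
  }
  list(features = omics_table(x, labels), traits = traits)
}

#' Centered log-ratio transform of a compositional block
#'
#' Optional transform for relative-abundance taxa: log of each component
#' over the per-sample geometric mean, after adding a pseudocount to zeros.
#'
#' @param x matrix of relative abundances (rows sum to about 1).
#' @param pseudocount value added to all cells before logging (default half
#'   the smallest nonzero entry).
#' @return matrix of CLR-transformed values.
#' @export
clr_transform <- function(x, pseudocount = NULL) {
  x <- as.matrix(x)
  if (is.null(pseudocount)) {
    nz <- x[x > 0]
    if (!length(nz)) stop("clr_transform: all-zero table")
    pseudocount <- min(nz) / 2
  }
  lx <- log(x + pseudocount)
  sweep(lx, 1, rowMeans(lx), "-")
}
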