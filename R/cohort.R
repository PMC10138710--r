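#' Configuration for the synthetic multi-omics cohort generator
#'
#' Defines the study conditions emulated by [generate_cohort()]: a small
#' two-trajectory ulcerative-colitis cohort (13 participants whose fecal
#' calprotectin rises over 8 weeks, 16 whose FCP falls), about 551 mixed
#' features across seven blocks, latent co-abundance modules, compositional
#' taxa, a planted enterotype structure and planted diet-to-inflammation
#' mediation chains.
#'
#' The latent model for a feature in module k is
#' \deqn{z = loading \cdot F_k + \sqrt{1 - loading^2 + noise\_sd^2}\,\epsilon,}
#' so `loading` is the feature-factor correlation in the `noise_sd = 0`
#' limit and two same-module features correlate at `loading^2` there;
#' `noise_sd` inflates the unique variance beyond the unit-variance
#' baseline. Unassigned ("none") features are standard-normal noise.
#'
#' Mediation chains are planted on the within-cohort standardized exposure
#' (per-SD path coefficients): each mediator is `a_j * X_std` plus unit
#' noise and the week-8 outcome (on the log FCP scale; FCP itself is
#' log-normal, hence strictly positive) receives `sum_j b_j * M_j` plus a
#' direct `X` path, the trajectory shift and Gaussian log-scale noise, so
#' the true indirect effect of a chain is `sum_j a_j b_j` on the
#' `log(FCP)` scale.
#'
#' @param n_samples cohort size (default 29).
#' @param n_increase,n_decrease trajectory-group sizes (13/16); must sum to
#'   `n_samples`.
#' @param block_sizes named feature counts per block; the defaults total
#'   551 (taxon 331, serum_metabolite 84, scfa 6, bile_acid 9, diet_total
#'   60, diet_adjusted 40, food_group_freq 21).
#' @param n_modules number of planted co-abundance modules K (default 10).
#' @param loading per-module factor loading in (0, 1].
#' @param noise_sd extra per-feature noise standard deviation (> 0 allowed
#'   to be arbitrarily small).
#' @param noise_fraction fraction of features left unassigned to any module
#'   (default 189/551, about a third).
#' @param mediation_chains list of planted chains; each a list with `id`,
#'   `x` (exposure, `"MDS"`), `y` (outcome, `"FCP_week8"`), `mediators`
#'   (feature ids, or `NULL` to auto-pick from the unassigned pool:
#'   3 taxa + 4 serum metabolites), and numeric path vectors `a`, `b` of
#'   equal length. Default: one 7-mediator chain with joint indirect effect
#'   `sum(a * b) = -1`.
#' @param direct_effect direct exposure-outcome path on the log FCP scale
#'   per SD of exposure (default -0.05).
#' @param trajectory_effect gap between the trajectory groups' mean week-8
#'   log FCP (default 2.9, matching a 961 vs 53 mcg/g contrast).
#' @param fcp_noise_sd log-scale FCP noise (default 1).
#' @param n_enterotypes planted community types in the baseline microbiome
#'   (default 3).
#' @param enterotype_taxa number of signature taxa per enterotype (default 8).
#' @param enterotype_effect latent-scale abundance shift of signature taxa
#'   in their own enterotype (default 2.5, a contrast strong enough that
#'   the community types are unambiguous).
#' @param enterotype_fcp_effect spread of baseline log FCP across
#'   enterotypes (default 3; the first enterotype is the high-FCP one).
#' @param mds_slope slope of the diet factor in the MDS generating model
#'   (default 0.9).
#' @param seed integer RNG seed (default 7).
#' @return object of class `"cohort_config"`.
#' @seealso [generate_cohort()], [planted_acme()]
#' @export
cohort_config <- function(n_samples = 29L,
                          n_increase = 13L,
                          n_decrease = 16L,
                          block_sizes = c(taxon = 331L, serum_metabolite = 84L,
                                          scfa = 6L, bile_acid = 9L,
                                          diet_total = 60L, diet_adjusted = 40L,
                                          food_group_freq = 21L),
                          n_modules = 10L,
                          loading = 0.8,
                          noise_sd = 0.5,
                          noise_fraction = 189 / 551,
                          mediation_chains = NULL,
                          direct_effect = -0.05,
                          trajectory_effect = 2.9,
                          fcp_noise_sd = 1,
                          n_enterotypes = 3L,
                          enterotype_taxa = 8L,
                          enterotype_effect = 2.5,
                          enterotype_fcp_effect = 3,
                          mds_slope = 0.9,
                          seed = 7L) {
  if (n_samples <= 0) stop("cohort_config: 'n_samples' must be positive")
  if (n_increase <= 0 || n_decrease <= 0)
    stop("cohort_config: 'n_increase'/'n_decrease' must be positive")
  if (n_increase + n_decrease != n_samples)
    stop("cohort_config: 'n_increase' + 'n_decrease' must equal 'n_samples'")
  if (any(block_sizes <= 0)) stop("cohort_config: 'block_sizes' must be positive")
  if (is.null(names(block_sizes)) || !"taxon" %in% names(block_sizes))
    stop("cohort_config: 'block_sizes' must be named and include a 'taxon' block")
  if (loading <= 0 || loading > 1) stop("cohort_config: 'loading' must be in (0, 1]")
  if (noise_sd < 0) stop("cohort_config: 'noise_sd' must be >= 0")
  if (noise_fraction < 0 || noise_fraction >= 1)
    stop("cohort_config: 'noise_fraction' must be in [0, 1)")
  if (is.null(mediation_chains)) {
    mediation_chains <- list(list(id = "guild", x = "MDS", y = "FCP_week8",
                                  mediators = NULL,
                                  a = rep(0.4, 7), b = rep(-1 / (7 * 0.4), 7)))
  }
  for (ch in mediation_chains) {
    if (is.null(ch$id)) stop("cohort_config: every chain needs an 'id'")
    if (length(ch$a) != length(ch$b))
      stop("cohort_config: chain '", ch$id, "': 'a' and 'b' lengths differ")
    if (!all(is.finite(ch$a)) || !all(is.finite(ch$b)))
      stop("cohort_config: chain '", ch$id, "': non-finite path coefficients")
    if (length(ch$a) == 0)
      stop("cohort_config: chain '", ch$id, "' is empty")
  }
  structure(list(n_samples = as.integer(n_samples),
                 n_increase = as.integer(n_increase),
                 n_decrease = as.integer(n_decrease),
                 block_sizes = block_sizes, n_modules = as.integer(n_modules),
                 loading = loading, noise_sd = noise_sd,
                 noise_fraction = noise_fraction,
                 mediation_chains = mediation_chains,
                 direct_effect = direct_effect,
                 trajectory_effect = trajectory_effect,
                 fcp_noise_sd = fcp_noise_sd,
                 n_enterotypes = as.integer(n_enterotypes),
                 enterotype_taxa = as.integer(enterotype_taxa),
                 enterotype_effect = enterotype_effect,
                 enterotype_fcp_effect = enterotype_fcp_effect,
                 mds_slope = mds_slope, seed = as.integer(seed)),
            class = "cohort_config")
}

# feature ids per block: taxon -> tax_001 ..., serum_metabolite -> met_001 ...
block_id_prefix <- c(taxon = "tax", serum_metabolite = "met", scfa = "scfa",
                     bile_acid = "ba", diet_total = "nutr", diet_adjusted = "adj",
                     food_group_freq = "food")

feature_ids_for <- function(block, n) {
  prefix <- if (block %in% names(block_id_prefix)) block_id_prefix[[block]] else block
  sprintf("%s_%03d", prefix, seq_len(n))
}

#' Generate a synthetic multi-omics cohort with planted ground truth
#'
#' Draws latent module factors per sample, builds block-wise feature tables
#' (taxa on a logistic-normal scale closed to relative abundances; SCFAs
#' and bile acids as log-normal concentrations; metabolites and diet
#' variables on a centred continuous scale), plants enterotype structure in
#' the baseline taxa, derives an integer 0-13 Mediterranean diet score from
#' the first latent factor, and generates baseline and week-8 fecal
#' calprotectin from the planted mediation chains on the log scale with
#' the configured trajectory split. The same seed reproduces the cohort
#' bit-identically.
#'
#' @param config a [cohort_config()].
#' @return list of class `"synthetic_cohort"` with `features` (an
#'   [omics_table] of the assembled, block-prefixed matrix), `blocks` (raw
#'   per-block matrices), `traits` (data frame: MDS, FCP_baseline,
#'   FCP_week8, trajectory, medication flags), and `truth` (module label
#'   per feature with `"none"` for unassigned, the latent factor matrix,
#'   true ACME per chain, mediator ids per chain, enterotype per sample,
#'   signature taxa per enterotype).
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_samples
  p_block <- config$block_sizes
  p <- sum(p_block)
  sample_ids <- sprintf("S%02d", seq_len(n))

  blocks_of <- rep(names(p_block), p_block)
  ids <- unlist(lapply(names(p_block), function(b) feature_ids_for(b, p_block[[b]])),
                use.names = FALSE)
  full_ids <- paste(blocks_of, ids, sep = ".")

  # --- planted module structure -------------------------------------------
  k <- config$n_modules
  n_noise <- round(config$noise_fraction * p)
  n_classified <- p - n_noise
  perm <- sample.int(p)
  module_of <- rep("none", p)
  module_idx <- perm[seq_len(n_classified)]
  module_of[module_idx] <- sprintf("module%02d",
                                   rep_len(seq_len(k), n_classified))
  noise_idx <- perm[seq.int(n_classified + 1, p)]

  factors <- matrix(stats::rnorm(n * k), n, k,
                    dimnames = list(sample_ids, sprintf("F%02d", seq_len(k))))
  unique_sd <- sqrt(max(0, 1 - config$loading^2) + config$noise_sd^2)
  z <- matrix(stats::rnorm(n * p), n, p, dimnames = list(sample_ids, full_ids))
  for (j in module_idx) {
    km <- as.integer(sub("module", "", module_of[j]))
    z[, j] <- config$loading * factors[, km] + unique_sd * z[, j]
  }

  # --- enterotypes: signature taxa shifted per community type -------------
  # enterotype assignment stratified by trajectory group so community types
  # are balanced across the cohort split
  ent <- integer(n)
  ent[seq_len(config$n_increase)] <- rep_len(seq_len(config$n_enterotypes),
                                             config$n_increase)
  ent[seq.int(config$n_increase + 1, n)] <-
    rep_len(seq_len(config$n_enterotypes), config$n_decrease)
  taxa_cols <- which(blocks_of == "taxon")
  noise_taxa <- intersect(noise_idx, taxa_cols)
  need_sig <- config$n_enterotypes * config$enterotype_taxa
  if (length(noise_taxa) < need_sig)
    stop("generate_cohort: not enough unassigned taxa for enterotype signatures")
  sig <- split(noise_taxa[seq_len(need_sig)],
               rep(seq_len(config$n_enterotypes), each = config$enterotype_taxa))
  for (e in seq_len(config$n_enterotypes)) {
    # signature taxa are community-dominant (high baseline abundance) and
    # further elevated in their own community type, as real enterotype
    # driver genera are
    z[, sig[[e]]] <- z[, sig[[e]]] + config$enterotype_effect
    z[ent == e, sig[[e]]] <- z[ent == e, sig[[e]]] + config$enterotype_effect
  }

  # --- diet score from the first latent factor ----------------------------
  mds <- stats::rbinom(n, 13, stats::plogis(config$mds_slope * factors[, 1]))
  x_std <- as.numeric(scale(mds))
  if (!is.finite(x_std[1])) x_std <- rep(0, n)  # degenerate constant score

  # --- planted mediation chains (per-SD coefficients, log1p FCP scale) ----
  used_sig <- unlist(sig, use.names = FALSE)
  pool_taxa <- setdiff(noise_taxa, used_sig)
  pool_other <- setdiff(noise_idx, c(taxa_cols, used_sig))
  chains <- config$mediation_chains
  chain_idx <- vector("list", length(chains))
  for (ci in seq_along(chains)) {
    ch <- chains[[ci]]
    m <- length(ch$a)
    if (is.null(ch$mediators)) {
      n_tax <- min(3L, m)
      met_pool <- pool_other[blocks_of[pool_other] == "serum_metabolite"]
      if (length(pool_taxa) < n_tax || length(met_pool) < m - n_tax)
        stop("generate_cohort: unassigned pool too small for chain '", ch$id, "'")
      med_idx <- c(pool_taxa[seq_len(n_tax)], met_pool[seq_len(m - n_tax)])
      pool_taxa <- setdiff(pool_taxa, med_idx)
      pool_other <- setdiff(pool_other, med_idx)
    } else {
      med_idx <- match(ch$mediators, full_ids)
      if (anyNA(med_idx))
        stop("generate_cohort: chain '", ch$id, "' references unknown feature(s): ",
             paste(ch$mediators[is.na(med_idx)], collapse = ", "))
    }
    for (jj in seq_len(m))
      z[, med_idx[jj]] <- ch$a[jj] * x_std + stats::rnorm(n)
    chain_idx[[ci]] <- med_idx
    chains[[ci]]$mediators <- full_ids[med_idx]
  }

  # --- observed blocks -----------------------------------------------------
  obs <- z
  expt <- exp(z[, taxa_cols, drop = FALSE])
  obs[, taxa_cols] <- expt / rowSums(expt)          # compositional closure
  conc_cols <- which(blocks_of %in% c("scfa", "bile_acid"))
  obs[, conc_cols] <- exp(z[, conc_cols, drop = FALSE])

  # the outcome responds to the mediators as measured: log relative
  # abundance for compositional taxa, log concentration for SCFAs and bile
  # acids (both equal the latent scale up to the compositional offset),
  # and the centred intensity scale elsewhere
  mediator_value <- function(j) {
    if (blocks_of[j] %in% c("taxon", "scfa", "bile_acid")) log(obs[, j]) else obs[, j]
  }
  mediated <- numeric(n)
  for (ci in seq_along(chains)) {
    mv <- vapply(chain_idx[[ci]], mediator_value, numeric(n))
    mv <- scale(mv, center = TRUE, scale = FALSE)  # keep the FCP location at its design mean
    mediated <- mediated + as.numeric(mv %*% chains[[ci]]$b)
  }

  # --- FCP on the log1p scale ---------------------------------------------
  trajectory <- rep(c("increase", "decrease"), c(config$n_increase, config$n_decrease))
  inc <- trajectory == "increase"
  # the high-risk community type (enterotype 1) elevates inflammation at
  # both time points; shifting both keeps the within-person change driven
  # by the trajectory design
  ent_shift <- config$enterotype_fcp_effect *
    (1 - (ent - 1) / max(1, config$n_enterotypes - 1))
  ent_shift <- ent_shift - mean(ent_shift)
  mu8 <- ifelse(inc, 6.87, 6.87 - config$trajectory_effect)
  eta8 <- mu8 + ent_shift + config$direct_effect * x_std + mediated +
    stats::rnorm(n, 0, config$fcp_noise_sd)
  # baseline mirrors the trajectory design: low-then-rising vs
  # high-then-falling (a moderate split so cluster medians stay unimodal)
  mu0 <- ifelse(inc, 4.7, 6.3)
  eta0 <- mu0 + ent_shift + stats::rnorm(n, 0, config$fcp_noise_sd)
  # keep the trajectory label consistent with the two values; FCP is
  # log-normal (exp of the linear predictor), so order on the log scale is
  # order on the concentration scale and ties have probability zero
  eta0[inc] <- pmin(eta0[inc], eta8[inc] - 0.05)
  eta0[!inc] <- pmax(eta0[!inc], eta8[!inc] + 0.05)

  traits <- data.frame(MDS = as.integer(mds),
                       FCP_baseline = exp(eta0),
                       FCP_week8 = exp(eta8),
                       on_steroids = stats::runif(n) < 0.2,
                       on_5asa = stats::runif(n) < 0.4,
                       row.names = sample_ids)

  raw_blocks <- lapply(names(p_block), function(b) {
    cols <- which(blocks_of == b)
    m <- obs[, cols, drop = FALSE]
    colnames(m) <- ids[cols]
    m
  })
  names(raw_blocks) <- names(p_block)

  assembled <- assemble_features(raw_blocks, traits)
  truth_modules <- stats::setNames(module_of, full_ids)
  # enterotype signature taxa rise and fall together across community types:
  # they are planted co-abundant groups in their own right
  for (e in seq_len(config$n_enterotypes))
    truth_modules[sig[[e]]] <- sprintf("cag%02d", e)
  truth <- list(modules = truth_modules,
                factors = factors,
                acme = stats::setNames(
                  vapply(chains, function(ch) sum(ch$a * ch$b), 0),
                  vapply(chains, `[[`, "", "id")),
                chains = chains,
                x_std = stats::setNames(x_std, sample_ids),
                enterotype = stats::setNames(ent, sample_ids),
                signature_taxa = lapply(sig, function(ix) full_ids[ix]))
  structure(list(features = assembled$features,
                 blocks = raw_blocks,
                 traits = assembled$traits,
                 truth = truth,
                 config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d samples (%d increase / %d decrease), %d features\n",
              nrow(x$features$values), sum(x$traits$trajectory == "increase"),
              sum(x$traits$trajectory == "decrease"), ncol(x$features$values)))
  cat(sprintf("  planted modules: %d (+ %d unassigned features); enterotypes: %d\n",
              x$config$n_modules, sum(x$truth$modules == "none"),
              x$config$n_enterotypes))
  cat("  planted chains:", paste(sprintf("%s (ACME %.3g)", names(x$truth$acme),
                                         x$truth$acme), collapse = ", "), "\n")
  invisible(x)
}

#' True indirect effect of a planted chain
#'
#' Returns `sum_j a_j b_j` for the chain, the oracle value the mediation
#' estimator should recover (on the log FCP scale, per SD of exposure).
#'
#' @param config a [cohort_config()].
#' @param chain_id chain identifier.
#' @return the true ACME.
#' @export
planted_acme <- function(config, chain_id) {
  ids <- vapply(config$mediation_chains, `[[`, "", "id")
  i <- match(chain_id, ids)
  if (is.na(i)) stop("planted_acme: unknown chain id '", chain_id, "'")
  ch <- config$mediation_chains[[i]]
  sum(ch$a * ch$b)
}

#' Write a synthetic cohort to plain-text files
#'
#' Writes `features.tsv` (samples x features), `blocks.tsv` (feature ->
#' block), `traits.tsv`, and `truth.json` into a directory.
#'
#' @param cohort a `"synthetic_cohort"`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("features.tsv", "blocks.tsv", "traits.tsv", "truth.json"))
  utils::write.table(data.frame(sample = rownames(cohort$features$values),
                                cohort$features$values, check.names = FALSE),
                     paths[1], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(feature = names(cohort$features$blocks),
                                block = unname(cohort$features$blocks)),
                     paths[2], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample = rownames(cohort$traits), cohort$traits,
                                check.names = FALSE),
                     paths[3], sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- cohort$truth
  truth$factors <- NULL  # large; regenerable from the seed
  jsonlite::write_json(truth, paths[4], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
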