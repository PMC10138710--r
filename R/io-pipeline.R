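#' Read a samples x features table with a block map
#'
#' Reads a TSV/CSV (delimiter sniffed from the header line) whose first
#' column holds sample ids and remaining columns hold features, plus a
#' sidecar block map (feature, block). Non-numeric cells are reported.
#'
#' @param path feature table file.
#' @param blocks_path optional two-column (feature, block) file; when
#'   omitted, every feature gets block `"feature"`.
#' @return an [omics_table].
#' @export
read_feature_table <- function(path, blocks_path = NULL) {
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stop("read_feature_table: duplicate sample ids")
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(df[-1], is.numeric, TRUE))
    stop("read_feature_table: non-numeric feature column(s): ",
         paste(names(df[-1])[bad], collapse = ", "))
  }
  rownames(m) <- ids
  if (!is.null(blocks_path)) {
    bm <- utils::read.table(blocks_path, header = TRUE, sep = sep,
                            check.names = FALSE, stringsAsFactors = FALSE)
    blocks <- stats::setNames(as.character(bm[[2]]), as.character(bm[[1]]))
    missing_b <- setdiff(colnames(m), names(blocks))
    if (length(missing_b))
      stop("read_feature_table: features missing from block map: ",
           paste(utils::head(missing_b, 5), collapse = ", "))
    blocks <- blocks[colnames(m)]
  } else blocks <- rep("feature", ncol(m))
  omics_table(m, blocks)
}

#' Read a trait table
#'
#' @param path TSV/CSV with a sample-id first column.
#' @return data frame with sample ids as rownames.
#' @export
read_trait_table <- function(path) {
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  rownames(df) <- as.character(df[[1]])
  df[, -1, drop = FALSE]
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full co-abundance / mediation pipeline
#'
#' Drives every stage end-to-end — synthetic cohort (or tables from disk),
#' assembly, network fit, module-trait association, enterotyping with risk
#' labels and module enrichment, candidate screening, per-feature and
#' joint mediation, and the inter-module mediation cascade — writing each
#' stage's outputs under `out_dir` and a JSON manifest with content hashes.
#' Reruns with the same config and seed reproduce identical hashes.
#'
#' @param config list: either `cohort` (a [cohort_config()] or arguments
#'   for one) for a synthetic run, or `features_path`/`blocks_path`/
#'   `traits_path` for tables on disk; optional `network` (arguments for
#'   [conet()]), `cags` (`k`, `distance`, `prevalence_min`, `fdr_max`),
#'   `screen` (`q_max`, `mode`), `mediation` (`n_sims`, `ci`,
#'   `log1p_outcome`), and `seed`. May also be a path to a YAML file with
#'   the same structure.
#' @param out_dir output directory.
#' @return the manifest (named list of file -> md5), invisibly written to
#'   `manifest.json`.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("guildnet_")) {
  if (is.character(config) && length(config) == 1) config <- yaml::read_yaml(config)
  seed <- config$seed %||% 7L
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- character()

  # --- stage: input -------------------------------------------------------
  if (!is.null(config$features_path)) {
    features <- read_feature_table(config$features_path, config$blocks_path)
    traits <- read_trait_table(config$traits_path)
    asm <- assemble_features(split_blocks(features), traits)
  } else {
    cc <- config$cohort
    if (!inherits(cc, "cohort_config"))
      cc <- do.call(cohort_config, c(cc, if (is.null(cc$seed)) list(seed = seed)))
    cohort <- generate_cohort(cc)
    paths <- c(paths, write_cohort(cohort, file.path(out_dir, "cohort")))
    asm <- list(features = cohort$features, traits = cohort$traits)
  }
  features <- asm$features
  traits <- asm$traits
  mds <- traits$MDS
  log1p_outcome <- config$mediation$log1p_outcome %||% TRUE
  fcp <- if (log1p_outcome) log1p(traits$FCP_week8) else traits$FCP_week8

  # --- stage: network -----------------------------------------------------
  net_args <- config$network %||% list()
  fit <- do.call(conet, c(list(table = features), net_args))
  paths <- c(paths, write_tsv(data.frame(feature = names(fit$labels),
                                         block = unname(fit$blocks),
                                         module = unname(fit$labels)),
                              file.path(out_dir, "modules.tsv")))
  if (!is.null(fit$eigengenes))
    paths <- c(paths, write_tsv(data.frame(sample = rownames(fit$eigengenes),
                                           fit$eigengenes, check.names = FALSE),
                                file.path(out_dir, "eigengenes.tsv")))
  if (!is.null(fit$sft))
    paths <- c(paths, write_tsv(fit$sft, file.path(out_dir, "sft.tsv")))

  # --- stage: module-trait ------------------------------------------------
  trait_df <- data.frame(MDS = mds, FCP_week8 = fcp)
  if (!is.null(fit$eigengenes)) {
    assoc <- associate_traits(fit$eigengenes, trait_df)
    paths <- c(paths, write_tsv(assoc, file.path(out_dir, "trait_assoc.tsv")))
  }

  # --- stage: CAGs --------------------------------------------------------
  cag_cfg <- config$cags %||% list()
  taxa_cols <- fit$blocks == "taxon"
  part <- enterotype(features$values[, taxa_cols, drop = FALSE],
                     k = cag_cfg$k %||% 2:6,
                     distance = cag_cfg$distance %||% "jsd",
                     seed = seed + 1L)
  part <- classify_risk(part, traits$FCP_baseline)
  dom <- dominant_taxa(features$values[, taxa_cols, drop = FALSE],
                       part$clusters,
                       prevalence_min = cag_cfg$prevalence_min %||% 0.10,
                       fdr_max = cag_cfg$fdr_max %||% 0.1)
  paths <- c(paths, write_tsv(data.frame(sample = names(part$clusters),
                                         cluster = unname(part$clusters),
                                         risk = unname(part$risk[as.character(part$clusters)])),
                              file.path(out_dir, "cags.tsv")))
  paths <- c(paths, write_tsv(dom, file.path(out_dir, "dominant_taxa.tsv")))
  risk_sets <- lapply(c(high = "high", low = "low"), function(r) {
    cl <- names(part$risk)[part$risk == r]
    dom$taxon[dom$dominant & dom$cluster %in% as.integer(cl)]
  })
  if (any(fit$labels[taxa_cols] != "unclassified") &&
      any(lengths(risk_sets) > 0)) {
    enr <- module_cag_enrichment(fit, risk_sets)
    paths <- c(paths, write_tsv(enr, file.path(out_dir, "module_enrichment.tsv")))
  }

  # --- stage: screen + mediation + cascade --------------------------------
  med_cfg <- config$mediation %||% list()
  n_sims <- med_cfg$n_sims %||% 1000
  ci <- med_cfg$ci %||% 0.95
  scr_cfg <- config$screen %||% list()
  scr <- screen_candidates(features, mds, fcp,
                           q_max = scr_cfg$q_max %||% 0.20,
                           mode = scr_cfg$mode %||% "any")
  paths <- c(paths, write_tsv(scr$table, file.path(out_dir, "screen.tsv")))

  if (!is.null(fit$eigengenes) && ncol(fit$eigengenes) >= 2) {
    mg <- module_mediation_network(fit$eigengenes, mds, fcp, n_sims = n_sims,
                                   seed = seed + 2L, ci = ci)
    paths <- c(paths, write_tsv(mg$edges, file.path(out_dir,
                                                    "module_mediation_edges.tsv")))
  }
  if (length(scr$candidates)) {
    # log-transform compositional mediators so paths are near-linear
    fx <- features$values
    fx[, taxa_cols] <- log(fx[, taxa_cols, drop = FALSE] + 1e-12)
    fg <- feature_mediation_network(fx, scr$candidates, mds, fcp,
                                    n_sims = n_sims, seed = seed + 3L, ci = ci)
    paths <- c(paths, write_tsv(fg$edges, file.path(out_dir,
                                                    "feature_mediation_edges.tsv")))
    med_rows <- data.frame(
      mediator = names(fg$per_feature),
      acme = vapply(fg$per_feature, `[[`, 0, "acme"),
      ci_lower = vapply(fg$per_feature, function(f) f$ci[1], 0),
      ci_upper = vapply(fg$per_feature, function(f) f$ci[2], 0),
      p_value = vapply(fg$per_feature, `[[`, 0, "p_value"))
    joint_row <- data.frame(mediator = "joint", acme = fg$joint$acme,
                            ci_lower = fg$joint$ci[1], ci_upper = fg$joint$ci[2],
                            p_value = fg$joint$p_value)
    paths <- c(paths, write_tsv(rbind(med_rows, joint_row),
                                file.path(out_dir, "mediation.tsv")))
    paths <- c(paths, write_graphml(fg, file.path(out_dir,
                                                  "mediation_graph.graphml")))
  }

  manifest <- as.list(tools::md5sum(sort(unique(paths))))
  names(manifest) <- basename(names(manifest))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(manifest)
}

# split an assembled omics_table back into per-block matrices (ids
# un-prefixed) so assemble_features() can be reapplied uniformly
split_blocks <- function(table) {
  stopifnot(inherits(table, "omics_table"))
  out <- lapply(unique(table$blocks), function(b) {
    m <- table$values[, table$blocks == b, drop = FALSE]
    colnames(m) <- sub(paste0("^", b, "\\."), "", colnames(m))
    m
  })
  names(out) <- unique(table$blocks)
  out
}
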