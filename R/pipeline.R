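#' Default pipeline configuration
#'
#' All thresholds default to the printed parameters of the underlying
#' method: detection needs >= 5 supporting reads at Fisher P < 0.05,
#' rescue needs >= 3 reads at depth > 10, clonality is decided by the 95\%
#' CCF confidence interval overlapping 1, DBSCAN uses support radius 0.05
#' with 1 core point and retains clusters of more than 10 mutations, the
#' interval expansion factor is 3, bootstrapping uses 1000 replicates, the
#' route probability cutoff is 0.75, and the radiomics classifier is a
#' 1-nearest-neighbour under correlation distance.
#'
#' @param ... Overrides of the defaults (each override is reported once via
#'   a message when the pipeline runs).
#' @return Named list of parameters.
#' @export
default_run_config <- function(...) {
  cfg <- list(detect_min_alt = 5L, detect_p = 0.05,
              rescue_min_alt = 3L, rescue_min_depth = 10L,
              conf = 0.95, ccf_clamp = 1.5,
              dbscan_eps = 0.05, dbscan_min_core = 1L, min_cluster_size = 10L,
              expansion_k = 3, bootstrap_B = 1000L, route_cutoff = 0.75,
              presence_threshold = 0.05, knn_k = 1L, seed = 1L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stopf("unknown config field(s): %s", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  attr(cfg, "overridden") <- names(over)
  cfg
}

#' Run the full genomic route-inference pipeline for one patient
#'
#' Chains detection filtering (skipped with a warning when matched-normal
#' counts are absent), cross-region imputation, CCF estimation and
#' clonality calling, per-metastasis selection classes, the LOH-aware
#' presence matrix, the bootstrapped NJ phylogeny with route
#' classification, and subclone-tree reconstruction with bootstrap
#' concordance and shared-private-subclone route confirmation. Stage
#' failures in the subclone arm degrade to a warning so the genomic route
#' call always completes.
#'
#' @param dataset A \code{metroute_patient} (e.g. from
#'   \code{\link{simulate_patient}} or \code{\link{read_variant_table}}).
#' @param config See \code{\link{default_run_config}}.
#' @param subclone_B Bootstrap replicates for the subclone concordance
#'   (defaults to \code{config$bootstrap_B}; set 0 to skip).
#' @param out_dir Optional directory: writes \code{report.json}, the newick
#'   tree and a TSV of per-variant classes.
#' @return List of class \code{metroute_report}.
#' @export
run_genomic_pipeline <- function(dataset, config = default_run_config(),
                                 subclone_B = NULL, out_dir = NULL) {
  stopifnot(inherits(dataset, "metroute_patient"))
  over <- attr(config, "overridden")
  if (length(over))
    message("config overrides: ", paste(over, collapse = ", "))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
  }
  if (!is.null(dataset$variants$normal_alt)) {
    dataset <- stage("detection_filter",
      apply_detection_filter(dataset, min_alt = config$detect_min_alt,
                             p_cutoff = config$detect_p))
  } else {
    warnf("no matched-normal counts: detection filter skipped")
  }
  dataset <- stage("imputation",
    impute_across_regions(dataset, min_alt = config$rescue_min_alt,
                          min_depth = config$rescue_min_depth))
  ccf <- stage("ccf", patient_ccf(dataset, conf = config$conf,
                                  clamp = config$ccf_clamp))

  sm <- dataset$samples
  pre <- sm$timing == "pre_treatment"
  has_sites <- all(SITE_LEVELS %in% sm$site[pre])
  classes <- NULL
  if (has_sites)
    classes <- stage("selection_classes", selection_classes(dataset, ccf))

  phylo <- routes <- NULL
  if (has_sites && sum(pre) >= 3) {
    D <- stage("presence_matrix", presence_matrix(dataset))
    D <- filter_loh_confounded(D, dataset$loh)
    phylo <- stage("phylogeny", {
      ph <- nj_tree(D)
      bootstrap_supports(ph, B = config$bootstrap_B, seed = config$seed)
    })
    routes <- stage("route", classify_route(phylo, sm, cutoff = config$route_cutoff))
  } else {
    warnf("route stage skipped: needs >= 1 pre-treatment sample of each site")
  }

  sub_tree <- NULL; concordance <- NA_real_; route_confirm <- NULL
  sub_err <- tryCatch({
    ccf0 <- ccf$ccf; ccf0[is.na(ccf0)] <- 0
    sub <- cluster_variants(ccf0, eps = config$dbscan_eps,
                            min_core = config$dbscan_min_core,
                            min_size = config$min_cluster_size)
    sub <- subclone_intervals(sub, ccf$ci_low, ccf$ci_high, k = config$expansion_k)
    sub_tree <- build_tree(sub)
    B_sub <- subclone_B %||% config$bootstrap_B
    if (B_sub > 0)
      concordance <- bootstrap_subclone_tree(sub_tree, B = B_sub, seed = config$seed)
    route_confirm <- confirm_route(sub_tree$F, sm,
                                   presence_threshold = config$presence_threshold)
    NULL
  }, error = function(e) conditionMessage(e))
  if (!is.null(sub_err)) warnf("subclone stage incomplete: %s", sub_err)

  report <- structure(list(
    patient_id = dataset$patient_id,
    n_variants = nrow(dataset$variants),
    n_samples = nrow(sm),
    class_counts = if (!is.null(classes))
      lapply(classes, function(col) as.list(table(col))) else NULL,
    classes = classes,
    newick = if (!is.null(phylo)) write_newick(phylo, tempfile(fileext = ".nwk")) else NULL,
    phylo = phylo,
    routes = routes,
    subclone_parent = if (!is.null(sub_tree)) as.list(sub_tree$parent) else NULL,
    subclone_F = if (!is.null(sub_tree)) sub_tree$F else NULL,
    adjustment = if (!is.null(sub_tree)) sub_tree$adjustment else NULL,
    concordance = concordance,
    route_confirmation = if (!is.null(route_confirm)) as.character(route_confirm) else NULL,
    config = config), class = "metroute_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.metroute_report <- function(x, ...) {
  cat(sprintf("<metroute_report> patient %s (%d variants, %d samples)\n",
              x$patient_id, x$n_variants, x$n_samples))
  if (!is.null(x$routes)) { cat("route calls:\n"); print(x$routes) }
  if (!is.null(x$route_confirmation))
    cat("subclone route confirmation:", x$route_confirmation, "\n")
  if (!is.na(x$concordance))
    cat(sprintf("subclone tree bootstrap concordance: %.3f\n", x$concordance))
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  json <- report[c("patient_id", "n_variants", "n_samples", "class_counts",
                   "newick", "adjustment", "concordance", "route_confirmation",
                   "subclone_parent")]
  if (!is.null(report$routes)) json$routes <- as.data.frame(report$routes)
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null")
  if (!is.null(report$phylo))
    write_newick(report$phylo, file.path(out_dir, "tree.nwk"))
  if (!is.null(report$classes))
    utils::write.table(cbind(variant_id = rownames(report$classes), report$classes),
                       file.path(out_dir, "classes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}

#' Leave-one-sample-out stability of the route call
#'
#' Removes one sample at a time, reruns presence-matrix construction, tree
#' building, bootstrapping and route classification on the remainder, and
#' flags whether each metastasis route call changed relative to the
#' full-data call. Removing a sample that makes a site class empty leaves
#' the affected calls undefined and flagged.
#'
#' @param dataset An imputed-ready \code{metroute_patient}.
#' @param config See \code{\link{default_run_config}}.
#' @return Data frame with one row per (removed sample, metastasis) pair:
#'   route, probability and a \code{changed} flag (\code{NA} when the
#'   replicate could not produce a call).
#' @export
leave_one_out_stability <- function(dataset, config = default_run_config()) {
  stopifnot(inherits(dataset, "metroute_patient"))
  if (nrow(dataset$samples) < 4)
    stopf("leave-one-out stability needs >= 4 samples")
  run_routes <- function(ds) {
    ds <- if (!is.null(ds$variants$normal_alt))
      apply_detection_filter(ds, min_alt = config$detect_min_alt,
                             p_cutoff = config$detect_p) else ds
    ds <- impute_across_regions(ds, min_alt = config$rescue_min_alt,
                                min_depth = config$rescue_min_depth)
    D <- filter_loh_confounded(presence_matrix(ds), ds$loh)
    ph <- bootstrap_supports(nj_tree(D), B = config$bootstrap_B, seed = config$seed)
    classify_route(ph, ds$samples, cutoff = config$route_cutoff)
  }
  full <- run_routes(dataset)
  out <- NULL
  for (sid in dataset$samples$sample_id) {
    keep <- dataset$samples$sample_id != sid
    ds <- dataset
    ds$samples <- ds$samples[keep, , drop = FALSE]
    for (f in c("alt_reads", "depth", "status", "copy_number", "multiplicity"))
      ds[[f]] <- ds[[f]][, keep, drop = FALSE]
    res <- tryCatch(suppressWarnings(run_routes(ds)), error = function(e) NULL)
    for (ms in full$metastasis_sample) {
      row <- if (!is.null(res) && ms %in% res$metastasis_sample)
        res[res$metastasis_sample == ms, ] else NULL
      base <- full$route[full$metastasis_sample == ms]
      out <- rbind(out, data.frame(
        removed_sample = sid, metastasis_sample = ms,
        route = if (is.null(row)) NA_character_ else row$route,
        p_lymphatic = if (is.null(row)) NA_real_ else row$p_lymphatic,
        p_hematogenous = if (is.null(row)) NA_real_ else row$p_hematogenous,
        changed = if (is.null(row)) NA else row$route != base,
        stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}
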