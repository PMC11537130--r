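#' Run the full longitudinal metabolomics pipeline
#'
#' Chains every stage on loaded (or simulated) inputs: preprocessing
#' (missingness filter, KNN imputation, median scaling + log), weighted
#' correlation network module detection with eigen-metabolites and module
#' membership, random-intercept mixed-model trend scans over metabolites
#' and modules, permutation pathway enrichment of the metabolite trends,
#' disability response scoring (ODRS / EDSS-Plus) with the Wilcoxon
#' signed-rank EDSS change test, neuro-QOL improvement, and association of
#' metabolome change with improvement (logistic models per module and per
#' metabolite, partial Spearman vs quality-of-life change).
#'
#' With a fixed seed and identical inputs the result is reproducible
#' bit-for-bit; \code{\link{write_results}} then yields byte-identical
#' files.
#'
#' @param data list as returned by \code{\link{load_dataset}} or
#'   \code{\link{generate_cohort}} (elements \code{abundance},
#'   \code{visits}, \code{cohort}, \code{pathways}, \code{clinical})
#' @param config an \code{\link{analysis_config}}; its \code{seed} is
#'   mandatory (the enrichment null is stochastic)
#' @param improvement which composite improvement definition feeds the
#'   association stage: \code{"odrs"} (default) or \code{"edssplus"}
#' @return named list of stage outputs: \code{preprocess_report},
#'   \code{processed}, \code{modules}, \code{eigen}, \code{membership},
#'   \code{trend_metabolites}, \code{trend_modules}, \code{enrichment},
#'   \code{disability}, \code{edss_wilcoxon}, \code{qol_change},
#'   \code{association_modules}, \code{association_metabolites},
#'   \code{volcano}, \code{qol_correlation}
#' @export
run_pipeline <- function(data, config = analysis_config(seed = 1),
                         improvement = c("odrs", "edssplus")) {
  improvement <- match.arg(improvement)
  if (is.null(config$seed)) stop("analysis_config seed is required")
  pre <- preprocess_pipeline(data$abundance, config)
  mat <- pre$matrix

  net <- correlation_adjacency(mat, config$soft_power, config$network_sign)
  tom <- tom_similarity(net)
  modules <- detect_modules(tom, config$tree_cut_height,
                            config$min_module_size)
  eig <- eigenmetabolites(mat, modules)
  mm <- module_membership(mat, eig)

  trend_met <- trend_scan(mat, data$visits, data$cohort)
  trend_mod <- trend_scan(eig, data$visits, data$cohort)

  ranked <- rank_statistics(trend_met)
  enr <- gsea_scan(ranked, data$pathways, config$gsea_min_set,
                   config$n_permutations, config$gsea_weight,
                   seed = config$seed)

  dis <- disability_response_scan(data$clinical)
  base_fin <- lapply(split(data$clinical, data$clinical$patient_id),
                     function(cl) {
                       cl <- cl[order(cl$time_years), ]
                       c(cl$edss[1], cl$edss[nrow(cl)])
                     })
  bf <- do.call(rbind, base_fin)
  wil <- wilcoxon_signed_rank(bf[, 1], bf[, 2])
  qol <- neuroqol_improvement(data$clinical, config$neuroqol_mdc)

  dmod <- delta_features(eig, data$visits)
  dmet <- delta_features(mat, data$visits)
  lab_col <- if (improvement == "odrs") "odrs_improved" else
    "edss_plus_improved"
  improved <- stats::setNames(dis[[lab_col]], dis$patient_id)
  pats <- rownames(dmod$delta)
  improved <- improved[pats]
  ci <- match(pats, data$cohort$patient_id)
  covars <- data.frame(age = data$cohort$age_baseline[ci],
                       sex = data$cohort$sex[ci],
                       follow_up = dmod$follow_up_years[pats],
                       dmt = data$cohort$dmt_history[ci])
  assoc_mod <- do.call(rbind, lapply(
    colnames(dmod$delta)[dmod$informative], function(f)
      logistic_improvement(dmod$delta[, f], improved, covars, f)))
  scan <- metabolite_improvement_scan(dmet, improved, covars)

  qitems <- grep("^qol_", names(data$clinical), value = TRUE)
  qd <- do.call(rbind, lapply(pats, function(p) {
    cl <- data$clinical[data$clinical$patient_id == p, , drop = FALSE]
    cl <- cl[order(cl$time_years), , drop = FALSE]
    as.numeric(cl[nrow(cl), qitems]) - as.numeric(cl[1, qitems])
  }))
  dimnames(qd) <- list(pats, qitems)
  qcor <- qol_correlation(dmod, qd, covars)

  list(preprocess_report = pre$report, processed = mat,
       modules = modules, eigen = eig, membership = mm,
       trend_metabolites = trend_met, trend_modules = trend_mod,
       enrichment = enr, disability = dis,
       edss_wilcoxon = data.frame(W = wil$statistic, p = wil$p,
                                  n_effective = wil$n_effective,
                                  method = wil$method),
       qol_change = qol, association_modules = assoc_mod,
       association_metabolites = scan$results, volcano = scan$volcano,
       qol_correlation = qcor)
}

#' Tabular views of pipeline outputs for writing to disk
#'
#' Converts the result of \code{\link{run_pipeline}} into a named list of
#' plain data frames suitable for \code{\link{write_results}}.
#'
#' @param res list from \code{\link{run_pipeline}}
#' @return named list of data frames
#' @export
pipeline_tables <- function(res) {
  list(
    module_assignments = data.frame(metabolite_id = names(res$modules),
                                    module = unname(unclass(res$modules)),
                                    stringsAsFactors = FALSE),
    eigen_metabolites = data.frame(sample_id = rownames(res$eigen$scores),
                                   res$eigen$scores, check.names = FALSE),
    module_membership = res$membership,
    trend_metabolites = res$trend_metabolites,
    trend_modules = res$trend_modules,
    enrichment = res$enrichment,
    improvement = res$disability,
    edss_wilcoxon = res$edss_wilcoxon,
    qol_change = res$qol_change,
    association_modules = res$association_modules,
    association_metabolites = res$association_metabolites,
    volcano = res$volcano,
    qol_correlation = res$qol_correlation)
}
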