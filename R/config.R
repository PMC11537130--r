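#' Analysis configuration
#'
#' Bundles every tunable parameter of the pipeline with its default. Defaults
#' follow the analysis conventions of the study design this package models:
#' metabolites missing in more than 30% of samples are dropped, KNN imputation
#' uses 10 neighbours, the correlation network uses soft-threshold power 12,
#' and pathway sets need at least five members.
#'
#' @param missing_frac_max maximum tolerated per-metabolite missing fraction;
#'   metabolites strictly above it are removed. Default 0.30.
#' @param knn_k number of neighbour metabolites for imputation. Default 10.
#' @param soft_power soft-threshold power beta for the correlation network.
#'   Default 12.
#' @param network_sign \code{"unsigned"} (adjacency |r|^beta) or
#'   \code{"signed"} (((1+r)/2)^beta). Default unsigned.
#' @param tree_cut_height static cut height on the 1 - TOM dendrogram,
#'   in (0, 1]. Default 0.9999.
#' @param min_module_size smallest cluster reported as a module; smaller
#'   clusters fall into "grey". Default 10.
#' @param gsea_min_set smallest pathway tested for enrichment. Default 5.
#' @param gsea_weight running-sum weight w on |s|; 0 gives the classic
#'   Kolmogorov-Smirnov statistic. Default 1.
#' @param n_permutations permutations for the enrichment null. Default 1000.
#' @param alpha significance level used in reports. Default 0.05.
#' @param seed integer seed; mandatory for any stochastic stage.
#' @param impute_axis \code{"metabolite"} (neighbours are metabolites; the
#'   omics convention) or \code{"sample"} for sensitivity checks.
#' @param neuroqol_mdc data frame with columns \code{item}, \code{direction}
#'   (\code{"higher_worse"} or \code{"higher_better"}) and \code{mdc} (minimal
#'   detectable change, T-score points). Defaults from
#'   \code{\link{neuroqol_items}} are synthetic placeholders, not published
#'   MDC values; supply validated thresholds for real analyses.
#' @return a list of class \code{analysis_config}
#' @export
analysis_config <- function(missing_frac_max = 0.30,
                            knn_k = 10,
                            soft_power = 12,
                            network_sign = c("unsigned", "signed"),
                            tree_cut_height = 0.9999,
                            min_module_size = 10,
                            gsea_min_set = 5,
                            gsea_weight = 1,
                            n_permutations = 1000,
                            alpha = 0.05,
                            seed = NULL,
                            impute_axis = c("metabolite", "sample"),
                            neuroqol_mdc = neuroqol_items()) {
  network_sign <- match.arg(network_sign)
  impute_axis <- match.arg(impute_axis)
  stopifnot(missing_frac_max >= 0, missing_frac_max <= 1,
            knn_k >= 1, soft_power > 0,
            tree_cut_height > 0, tree_cut_height <= 1,
            min_module_size >= 2, gsea_min_set >= 1,
            gsea_weight >= 0, n_permutations >= 1,
            alpha > 0, alpha < 1)
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    stopifnot(is.finite(seed))
  }
  stopifnot(is.data.frame(neuroqol_mdc),
            all(c("item", "direction", "mdc") %in% names(neuroqol_mdc)))
  structure(list(missing_frac_max = missing_frac_max, knn_k = knn_k,
                 soft_power = soft_power, network_sign = network_sign,
                 tree_cut_height = tree_cut_height,
                 min_module_size = min_module_size,
                 gsea_min_set = gsea_min_set, gsea_weight = gsea_weight,
                 n_permutations = n_permutations, alpha = alpha, seed = seed,
                 impute_axis = impute_axis, neuroqol_mdc = neuroqol_mdc),
            class = "analysis_config")
}

#' Neuro-QOL short-form item metadata
#'
#' The 12 neuro-QOL domains with their scoring direction and a minimal
#' detectable change (MDC) threshold used to call per-item improvement.
#'
#' The shipped MDC of 5 T-score points per item is a synthetic placeholder
#' (roughly half an SD on the T metric), not a published conditional MDC:
#' validated thresholds live outside this package and must be supplied via
#' \code{\link{analysis_config}} for real data.
#'
#' @return data frame with columns \code{item}, \code{direction}
#'   (\code{higher_worse}: an increase means deterioration;
#'   \code{higher_better}: an increase means improvement) and \code{mdc}.
#' @export
neuroqol_items <- function() {
  data.frame(
    item = c("anxiety", "depression", "fatigue", "sleep_disturbance",
             "stigma", "emotional_dyscontrol", "cognitive_function",
             "lower_extremity_mobility", "upper_extremity_function",
             "positive_affect_wellbeing", "social_roles_participation",
             "social_roles_satisfaction"),
    direction = c("higher_worse", "higher_worse", "higher_worse",
                  "higher_worse", "higher_worse", "higher_worse",
                  "higher_better", "higher_better", "higher_better",
                  "higher_better", "higher_better", "higher_better"),
    mdc = rep(5, 12),
    stringsAsFactors = FALSE
  )
}
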