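#' Remove metabolites with excessive missingness
#'
#' Drops every metabolite whose missing fraction is strictly greater than
#' \code{max_frac} (a metabolite missing in exactly 30% of samples survives
#' the default 0.30 cutoff). Samples are never removed.
#'
#' @param x an \code{\link{abundance_table}}
#' @param max_frac maximum tolerated missing fraction, in [0, 1]
#' @return list with \code{abundance} (filtered table) and \code{report}
#'   (fields \code{n_removed}, \code{removed_ids}, \code{missing_frac})
#' @export
filter_missingness <- function(x, max_frac = 0.30) {
  stopifnot(inherits(x, "abundance_table"), max_frac >= 0, max_frac <= 1)
  frac <- colMeans(is.na(x$values))
  drop <- frac > max_frac
  if (all(drop))
    stop(sprintf("all %d metabolites exceed the %.0f%% missingness cutoff",
                 ncol(x$values), 100 * max_frac))
  out <- if (any(drop)) subset_metabolites(x, !drop) else x
  list(abundance = out,
       report = list(n_removed = sum(drop),
                     removed_ids = x$metabolite_ids[drop],
                     missing_frac = frac))
}

#' K-nearest-neighbour imputation of missing abundances
#'
#' Neighbours are metabolites (the usual omics convention; set
#' \code{axis = "sample"} for a sensitivity check on the other axis).
#' The distance between two metabolites is the root-mean-square difference
#' over the samples where both are observed — i.e. Euclidean distance
#' normalized by the shared-sample count, so metabolites with different
#' missingness patterns are comparable. Pairs sharing no samples are never
#' neighbours. Each missing entry is replaced by the unweighted mean of the
#' values, in that sample, of the k nearest metabolites observed there;
#' if fewer than k qualify those available are used, and if none do the
#' metabolite's own observed median is used. Observed entries are never
#' modified, so imputing an already-complete table is the identity.
#'
#' @param x an \code{\link{abundance_table}}; every metabolite must have at
#'   least one observed value (run \code{\link{filter_missingness}} first)
#' @param k number of neighbours (default 10)
#' @param axis \code{"metabolite"} or \code{"sample"}
#' @return a complete \code{abundance_table}
#' @export
knn_impute <- function(x, k = 10, axis = c("metabolite", "sample")) {
  stopifnot(inherits(x, "abundance_table"), k >= 1)
  axis <- match.arg(axis)
  v <- x$values
  if (!anyNA(v)) return(x)
  none <- colSums(!is.na(v)) == 0
  if (any(none))
    stop("metabolite(s) with zero observed values: ",
         paste(x$metabolite_ids[none], collapse = ", "),
         " — run filter_missingness first")
  if (axis == "sample") {
    filled <- t(knn_fill(t(v), k))
  } else {
    filled <- knn_fill(v, k)
  }
  abundance_table(filled, x$sample_ids, x$metabolite_ids)
}

# impute columns of m (features) from their k nearest columns
knn_fill <- function(m, k) {
  obs <- !is.na(m)
  p <- ncol(m)
  m0 <- m
  m0[!obs] <- 0
  # pairwise RMS distance over shared observed samples, one pass of matrix
  # algebra: sum_{shared} (xi - xj)^2 = Si + Sj - 2*Cij restricted to shares
  sq <- m0^2
  shared <- crossprod(obs)                       # n shared samples
  cross <- crossprod(m0)                         # sum xi*xj over shared
  si <- crossprod(sq, obs)                       # sum xi^2 over j-observed
  ss <- si + t(si) - 2 * cross                   # squared distance sums
  ss[ss < 0] <- 0                                # numeric guard
  d <- sqrt(ss / shared)                         # NaN where shared == 0
  d[shared == 0] <- Inf
  diag(d) <- Inf

  med <- apply(m, 2, stats::median, na.rm = TRUE)
  out <- m
  for (j in which(colSums(!obs) > 0)) {
    # deterministic neighbour order: distance, then column (id) order
    ord <- order(d[, j], seq_len(p))
    ord <- ord[is.finite(d[ord, j])]
    for (s in which(!obs[, j])) {
      donors <- ord[obs[s, ord]]
      out[s, j] <- if (length(donors)) {
        mean(m[s, utils::head(donors, k)])
      } else med[j]
    }
  }
  out
}

#' Median-scale and log-transform a complete abundance table
#'
#' Each metabolite is divided by its own median across samples (so every
#' post-scaling median is exactly 1) and then natural-log transformed. The
#' result is therefore invariant to per-metabolite rescaling of the raw
#' values. Base e is a display choice; trends scale linearly with the base.
#'
#' @param x a complete \code{\link{abundance_table}} with positive values
#' @return an object of class \code{processed_matrix}: a numeric matrix
#'   (samples x metabolites) of log median-scaled values
#' @export
normalize_abundance <- function(x) {
  stopifnot(inherits(x, "abundance_table"))
  v <- x$values
  if (anyNA(v)) {
    bad <- which(is.na(v), arr.ind = TRUE)[1, ]
    stop(sprintf("missing value at sample '%s', metabolite '%s': impute first",
                 x$sample_ids[bad[1]], x$metabolite_ids[bad[2]]))
  }
  med <- apply(v, 2, stats::median)
  out <- log(sweep(v, 2, med, "/"))
  class(out) <- c("processed_matrix", class(out))
  out
}

#' Full preprocessing pipeline: filter, impute, normalize
#'
#' Applies, in order, the missingness filter, KNN imputation on the raw
#' abundances, then median scaling and log transformation.
#'
#' @param x a raw \code{\link{abundance_table}}
#' @param config an \code{\link{analysis_config}}
#' @return list with \code{matrix} (processed samples x metabolites matrix)
#'   and \code{report}: \code{n_removed}, \code{removed_ids},
#'   \code{n_imputed_entries}, \code{post_scaling_medians}
#' @export
preprocess_pipeline <- function(x, config = analysis_config()) {
  flt <- filter_missingness(x, config$missing_frac_max)
  n_imp <- sum(is.na(flt$abundance$values))
  imp <- knn_impute(flt$abundance, config$knn_k, config$impute_axis)
  med <- apply(imp$values, 2, stats::median)
  mat <- normalize_abundance(imp)
  list(matrix = mat,
       report = list(n_removed = flt$report$n_removed,
                     removed_ids = flt$report$removed_ids,
                     n_imputed_entries = n_imp,
                     post_scaling_medians = stats::setNames(
                       med / med, colnames(imp$values))))
}
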