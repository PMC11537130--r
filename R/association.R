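#' Per-patient feature change, standardized to unit SD
#'
#' For each feature (module eigen-metabolite column or processed metabolite
#' column), computes last-visit minus baseline value per patient, then
#' z-standardizes the deltas across patients so downstream odds ratios are
#' per SD of change. With a single patient the raw delta is returned and a
#' \code{standardized} attribute flags that scaling was skipped; a feature
#' whose deltas have zero variance is flagged non-informative.
#'
#' @param mat samples x features matrix (or an \code{eigen_profile})
#' @param visits visit table mapping samples to patients and times
#' @return list: \code{delta} (patients x features, standardized),
#'   \code{raw_delta}, \code{informative} (logical per feature),
#'   \code{follow_up_years} (per patient, last visit time)
#' @export
delta_features <- function(mat, visits) {
  if (inherits(mat, "eigen_profile")) mat <- mat$scores
  stopifnot(is.matrix(mat))
  idx <- match(rownames(mat), visits$sample_id)
  if (anyNA(idx)) stop("samples without visit metadata")
  v <- visits[idx, , drop = FALSE]
  pats <- unique(v$patient_id)
  delta <- matrix(NA_real_, length(pats), ncol(mat),
                  dimnames = list(pats, colnames(mat)))
  fu <- stats::setNames(rep(NA_real_, length(pats)), pats)
  drop_pat <- character(0)
  for (p in pats) {
    sel <- which(v$patient_id == p)
    tt <- v$time_years[sel]
    if (!any(tt == 0) || length(sel) < 2) {
      drop_pat <- c(drop_pat, p)
      next
    }
    b <- sel[which(tt == 0)]
    f <- sel[which.max(tt)]
    delta[p, ] <- mat[f, ] - mat[b, ]
    fu[p] <- max(tt)
  }
  if (length(drop_pat)) {
    warning("patients without baseline + follow-up excluded: ",
            paste(drop_pat, collapse = ", "))
    delta <- delta[setdiff(pats, drop_pat), , drop = FALSE]
    fu <- fu[setdiff(pats, drop_pat)]
  }
  raw <- delta
  standardized <- nrow(delta) >= 2
  informative <- rep(TRUE, ncol(delta))
  if (standardized) {
    sds <- apply(delta, 2, stats::sd)
    informative <- sds > 0
    delta[, informative] <- scale(delta[, informative, drop = FALSE],
                                  center = FALSE,
                                  scale = sds[informative])
  }
  structure(list(delta = delta, raw_delta = raw,
                 informative = stats::setNames(informative, colnames(delta)),
                 follow_up_years = fu),
            class = "delta_features", standardized = standardized)
}

#' Logistic model of improvement on one feature's change
#'
#' Fits improvement status ~ standardized feature delta + age at baseline +
#' sex + years of follow-up + prior DMT by iteratively reweighted least
#' squares (binomial \code{glm}, deviance tolerance 1e-8, at most 100
#' iterations), and reports the odds ratio per SD of change with a Wald 95%
#' CI. Complete separation (perfect classification / diverging
#' coefficients) is flagged and no odds ratio is reported.
#'
#' @param delta numeric vector per patient (standardized change)
#' @param improved logical/0-1 outcome per patient
#' @param covariates optional data frame of per-patient adjustment
#'   covariates (age, sex, follow-up years, DMT history)
#' @param feature feature name carried into the result
#' @return one-row data frame of class \code{association_result}:
#'   \code{feature}, \code{or}, \code{ci_low}, \code{ci_high}, \code{p},
#'   \code{log_or}, \code{separation}, \code{covariates}
#' @export
logistic_improvement <- function(delta, improved, covariates = NULL,
                                 feature = "feature") {
  improved <- as.integer(improved)
  stopifnot(length(delta) == length(improved))
  if (length(unique(improved[!is.na(improved)])) < 2)
    stop("improvement outcome has a single class; model unidentifiable")
  dat <- data.frame(.y = improved, delta = delta)
  xt <- "delta"
  if (!is.null(covariates)) {
    stopifnot(nrow(covariates) == length(delta))
    dat <- cbind(dat, covariates)
    xt <- c(xt, names(covariates))
  }
  fit <- suppressWarnings(
    stats::glm(stats::reformulate(xt, ".y"), data = dat, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)))
  co <- summary(fit)$coefficients
  b <- co["delta", "Estimate"]
  se <- co["delta", "Std. Error"]
  mu <- stats::fitted(fit)
  sep <- !fit$converged || abs(b) > 15 ||
    all(abs(mu - improved) < 1e-6)
  if (sep) {
    out <- data.frame(feature = feature, or = NA_real_, ci_low = NA_real_,
                      ci_high = NA_real_, p = NA_real_, log_or = NA_real_,
                      separation = TRUE, stringsAsFactors = FALSE)
  } else {
    z <- b / se
    out <- data.frame(feature = feature, or = exp(b),
                      ci_low = exp(b - 1.96 * se),
                      ci_high = exp(b + 1.96 * se),
                      p = 2 * stats::pnorm(-abs(z)), log_or = b,
                      separation = FALSE, stringsAsFactors = FALSE)
  }
  attr(out, "covariates") <- xt[-1]
  class(out) <- c("association_result", class(out))
  out
}

#' Improvement association scan over individual metabolites
#'
#' One logistic improvement model per metabolite's standardized change;
#' returns the association table plus volcano-plot coordinates
#' (\code{log_or}, \code{neg_log10_p}). Separation-flagged metabolites stay
#' in the table but are excluded from the volcano coordinates.
#'
#' @param deltas a \code{delta_features} object over metabolites
#' @param improved per-patient outcome, aligned to \code{rownames(deltas$delta)}
#' @param covariates optional per-patient adjustment data frame
#' @return list: \code{results} (association rows bound together),
#'   \code{volcano} (feature, log_or, neg_log10_p)
#' @export
metabolite_improvement_scan <- function(deltas, improved, covariates = NULL) {
  stopifnot(inherits(deltas, "delta_features"))
  feats <- colnames(deltas$delta)[deltas$informative]
  rows <- lapply(feats, function(f)
    logistic_improvement(deltas$delta[, f], improved, covariates, f))
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  keep <- !res$separation
  volcano <- data.frame(feature = res$feature[keep],
                        log_or = res$log_or[keep],
                        neg_log10_p = -log10(pmax(res$p[keep],
                                                  .Machine$double.eps)),
                        stringsAsFactors = FALSE)
  list(results = res, volcano = volcano)
}

#' Partial Spearman correlation
#'
#' Rank-transforms x, y and each covariate (midranks for ties), regresses
#' the ranked x and ranked y on the ranked covariates plus an intercept by
#' least squares, and returns the Pearson correlation of the two residual
#' vectors. p comes from \eqn{t = \rho \sqrt{(n - 2 - k)/(1 - \rho^2)}} on
#' \eqn{n - 2 - k} degrees of freedom (k covariates). With no covariates
#' this is ordinary Spearman correlation.
#'
#' @param x,y numeric vectors
#' @param covariates optional data frame / matrix of covariates
#' @return list with \code{rho} and \code{p}
#' @export
partial_spearman <- function(x, y, covariates = NULL) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input vector: correlation undefined")
  k <- 0
  rx <- rank(x); ry <- rank(y)
  if (!is.null(covariates)) {
    cv <- as.data.frame(covariates)
    k <- ncol(cv)
    if (n <= k + 2) stop("need n > k + 2 observations")
    rc <- vapply(cv, rank, numeric(n))
    qx <- stats::lm.fit(cbind(1, rc), rx)$residuals
    qy <- stats::lm.fit(cbind(1, rc), ry)$residuals
  } else {
    qx <- rx - mean(rx); qy <- ry - mean(ry)
  }
  # a residual vector that is numerically null (input fully explained by the
  # covariates) carries no information: report zero partial correlation
  # rather than a ratio of rounding noise
  tol <- 1e-10 * n^2
  if (sum(qx^2) < tol || sum(qy^2) < tol)
    return(list(rho = 0, p = 1))
  rho <- sum(qx * qy) / sqrt(sum(qx^2) * sum(qy^2))
  df <- n - 2 - k
  tstat <- rho * sqrt(df / max(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df)
  list(rho = rho, p = p)
}

#' Module eigen-metabolite vs neuro-QOL change correlation table
#'
#' Partial Spearman correlation between each module eigen-metabolite's
#' per-patient change and each neuro-QOL item's change, adjusted for the
#' supplied covariates — the module x item heat-map table.
#'
#' @param module_deltas \code{delta_features} over eigen-metabolites
#' @param qol_deltas patients x items matrix of T-score changes
#' @param covariates optional per-patient adjustment data frame
#' @return data frame: \code{module}, \code{item}, \code{rho}, \code{p}
#' @export
qol_correlation <- function(module_deltas, qol_deltas, covariates = NULL) {
  stopifnot(inherits(module_deltas, "delta_features"))
  md <- module_deltas$delta
  common <- intersect(rownames(md), rownames(qol_deltas))
  rows <- list()
  for (m in colnames(md)) {
    for (it in colnames(qol_deltas)) {
      ok <- common[!is.na(qol_deltas[common, it]) & !is.na(md[common, m])]
      res <- tryCatch(
        partial_spearman(md[ok, m], qol_deltas[ok, it],
                         if (is.null(covariates)) NULL
                         else covariates[ok, , drop = FALSE]),
        error = function(e) list(rho = NA_real_, p = NA_real_))
      rows[[length(rows) + 1L]] <- data.frame(
        module = m, item = it, rho = res$rho, p = res$p,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
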