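#' Fit a random-intercept linear mixed model for one feature
#'
#' Model: \eqn{y_{ij} = \beta_0 + \beta_1 t_{ij} + \gamma' z_i + b_i +
#' \epsilon_{ij}}, with patient random intercepts \eqn{b_i \sim N(0,
#' \sigma^2_b)} and residuals \eqn{\epsilon \sim N(0, \sigma^2_e)}; time is
#' years from each patient's own baseline visit. Fitting is restricted
#' maximum likelihood (REML) via \pkg{lme4}. Inference on the fixed effects
#' is by the Wald normal approximation: 95% CI = estimate +/- 1.96 SE, p
#' from the standard normal — a documented approximation in lieu of
#' finite-sample degrees of freedom, adequate at the cohort sizes this
#' pipeline targets and validated by simulation-based coverage tests.
#'
#' @param y numeric response per visit
#' @param time_years numeric, years from baseline per visit
#' @param patient factor/character patient identifier per visit
#' @param covariates optional data frame of per-visit covariates (e.g. age
#'   at baseline, sex, prior DMT), constant within patient or not
#' @return list of class \code{lme_fit}: \code{coefficients} (data frame:
#'   term, estimate, se, ci_low, ci_high, z, p), \code{sigma2_b},
#'   \code{sigma2_e}, \code{logLik}, \code{n_obs}, \code{n_patients}
#' @export
fit_random_intercept <- function(y, time_years, patient, covariates = NULL) {
  patient <- as.factor(patient)
  n <- length(y)
  stopifnot(length(time_years) == n, length(patient) == n)
  nvis <- table(patient)
  if (sum(nvis >= 2) < 2 || nlevels(patient) < 2)
    stop("need >= 2 patients with >= 2 visits each to identify variance components")
  dat <- data.frame(.y = y, time_years = time_years, .patient = patient)
  xterms <- "time_years"
  if (!is.null(covariates)) {
    stopifnot(is.data.frame(covariates), nrow(covariates) == n)
    dat <- cbind(dat, covariates)
    xterms <- c(xterms, names(covariates))
  }
  X <- stats::model.matrix(
    stats::reformulate(xterms), dat)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    drop_col <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop("singular fixed-effect design; collinear column(s): ",
         paste(drop_col, collapse = ", "))
  }
  form <- stats::reformulate(c(xterms, "(1 | .patient)"), response = ".y")
  fit <- suppressWarnings(suppressMessages(
    lme4::lmer(form, data = dat, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore"))))
  beta <- lme4::fixef(fit)
  se <- fixef_se(fit, X)
  z <- beta / se
  vc <- lme4::VarCorr(fit)
  structure(list(
    coefficients = data.frame(
      term = names(beta), estimate = unname(beta), se = unname(se),
      ci_low = unname(beta - 1.96 * se), ci_high = unname(beta + 1.96 * se),
      z = unname(z), p = unname(2 * stats::pnorm(-abs(z))),
      stringsAsFactors = FALSE),
    sigma2_b = as.numeric(vc$.patient[1]),
    sigma2_e = attr(vc, "sc")^2,
    logLik = as.numeric(stats::logLik(fit)),
    n_obs = n, n_patients = nlevels(patient),
    merMod = fit),
    class = "lme_fit")
}

# slope row (time_years term) of an lme_fit
slope_row <- function(fit) {
  co <- fit$coefficients
  co[co$term == "time_years", , drop = FALSE]
}

#' Longitudinal trend scan over many features
#'
#' Fits one random-intercept model per feature (metabolite column or module
#' eigen-metabolite) with a shared covariate set, and reports the per-year
#' time slope with Wald 95% CI, p, and Benjamini-Hochberg q. Failed fits are
#' reported as NA rows, never dropped silently. Results are sorted by p
#' ascending.
#'
#' @param mat samples x features matrix (processed metabolites, or
#'   \code{eigen_profile$scores})
#' @param visits visit table (\code{patient_id}, \code{sample_id},
#'   \code{time_years}); rows of \code{mat} are matched by sample id
#' @param cohort per-patient covariates (\code{patient_id},
#'   \code{age_baseline}, \code{sex}, \code{dmt_history}); pass NULL to fit
#'   time-only models
#' @return data frame of class \code{trend_result}: \code{feature},
#'   \code{estimate}, \code{ci_low}, \code{ci_high}, \code{p}, \code{q}
#' @export
trend_scan <- function(mat, visits, cohort = NULL) {
  if (inherits(mat, "eigen_profile")) mat <- mat$scores
  stopifnot(is.matrix(mat))
  idx <- match(rownames(mat), visits$sample_id)
  if (anyNA(idx)) stop("samples without visit metadata: ",
                       paste(rownames(mat)[is.na(idx)], collapse = ", "))
  v <- visits[idx, , drop = FALSE]
  covars <- NULL
  if (!is.null(cohort)) {
    ci <- match(v$patient_id, cohort$patient_id)
    if (anyNA(ci)) stop("patients without cohort covariates")
    covars <- data.frame(age = cohort$age_baseline[ci],
                         sex = cohort$sex[ci],
                         dmt = cohort$dmt_history[ci])
  }
  na_row <- function(f) data.frame(feature = f, estimate = NA_real_,
                                   ci_low = NA_real_, ci_high = NA_real_,
                                   p = NA_real_, q = NA_real_,
                                   stringsAsFactors = FALSE)
  base_fit <- NULL
  rows <- lapply(colnames(mat), function(f) {
    res <- tryCatch({
      if (is.null(base_fit)) {
        ft <- fit_random_intercept(mat[, f], v$time_years, v$patient_id,
                                   covars)
        base_fit <<- ft$merMod
        ft
      } else {
        # identical design across features: refit for speed
        refit_feature(base_fit, mat[, f])
      }
    }, error = function(e) {
      warning("fit failed for feature ", f, ": ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) return(na_row(f))
    sr <- slope_row(res)
    data.frame(feature = f, estimate = sr$estimate, ci_low = sr$ci_low,
               ci_high = sr$ci_high, p = sr$p, q = NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ok <- !is.na(out$p)
  out$q[ok] <- bh_adjust(out$p[ok])
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("trend_result", class(out))
  out
}

# Wald standard errors; falls back to the GLS formula with the residual
# variance floored when the fit is degenerate (e.g. noise-free responses)
fixef_se <- function(fit, X = NULL) {
  se <- tryCatch(suppressWarnings(sqrt(diag(as.matrix(stats::vcov(fit))))),
                 error = function(e) NULL)
  if (!is.null(se) && !anyNA(se)) return(se)
  if (is.null(X)) X <- lme4::getME(fit, "X")
  s2 <- max(stats::sigma(fit)^2, .Machine$double.eps)
  sqrt(diag(solve(crossprod(X))) * s2)
}

# fast REML refit of a fitted lmer model with a new response
refit_feature <- function(merfit, y) {
  fit <- suppressWarnings(suppressMessages(lme4::refit(merfit, newresp = y)))
  beta <- lme4::fixef(fit)
  se <- fixef_se(fit)
  z <- beta / se
  vc <- lme4::VarCorr(fit)
  structure(list(
    coefficients = data.frame(
      term = names(beta), estimate = unname(beta), se = unname(se),
      ci_low = unname(beta - 1.96 * se), ci_high = unname(beta + 1.96 * se),
      z = unname(z), p = unname(2 * stats::pnorm(-abs(z))),
      stringsAsFactors = FALSE),
    sigma2_b = as.numeric(vc$.patient[1]),
    sigma2_e = attr(vc, "sc")^2,
    logLik = as.numeric(stats::logLik(fit)),
    n_obs = length(y), n_patients = nrow(lme4::ranef(fit)$.patient),
    merMod = fit),
    class = "lme_fit")
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up FDR control: with p-values sorted ascending,
#' \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} m / j}, capped at 1, returned in
#' the original input order. Delegates to \code{stats::p.adjust}.
#'
#' @param p numeric vector of p-values in [0, 1]
#' @return q-values, same order as the input
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must be finite and in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
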