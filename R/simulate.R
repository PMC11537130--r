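#' Synthetic cohort configuration
#'
#' Defaults emulate a small single-arm longitudinal treatment cohort:
#' 31 patients followed over about three years with four visits each,
#' a few hundred profiled metabolites organised into correlated modules,
#' two modules with negative log-scale treatment trends, and a clinical
#' improvement outcome linked to the change of one target module.
#' Covariate distributions (age ~ N(41, 10), 68\% female, 71\% with prior
#' disease-modifying therapy, 29\% improvement prevalence) follow the
#' demographics typical of such cohorts.
#'
#' @param n_patients number of patients (default 31)
#' @param visits_per_patient visits per patient at 0, 1, 2, ... years
#'   (default 4); the baseline visit is exactly at 0, later visits get
#'   uniform jitter of +/- \code{visit_jitter} years
#' @param visit_jitter jitter half-width in years (default 0.15)
#' @param n_metabolites total metabolites (default 300)
#' @param module_sizes sizes of the planted correlated modules
#'   (default c(40, 30, 25, 20)); must sum to <= \code{n_metabolites}
#' @param within_module_cor nominal within-module correlation rho in [0, 1)
#'   (default 0.6); the realized cross-metabolite correlation is slightly
#'   lower because patient-level intercept variance adds independent noise
#' @param affected_modules indices of modules with a treatment trend
#'   (default 1:2)
#' @param module_slopes per-year log-scale slope for each affected module
#'   (default c(-0.10, -0.12))
#' @param target_module module whose change drives improvement (default 2)
#' @param noise_sd total non-patient log-scale SD per metabolite (default 1)
#' @param patient_intercept_sd SD of the per-metabolite, per-patient random
#'   intercept (default 0.2)
#' @param mu_log mean log abundance level (default 5)
#' @param mu_log_sd SD of per-metabolite mean levels (default 1)
#' @param missing_rate expected fraction of masked entries (default 0.10)
#' @param censor_share share of masked entries drawn from each metabolite's
#'   lowest quartile, emulating left-censoring at the detection limit
#'   (default 0.5)
#' @param improvement_or odds ratio of improvement per SD of target-module
#'   change (default 0.3: a decrease favours improvement)
#' @param improvement_prevalence marginal improvement probability
#'   (default 0.29)
#' @param age_mean,age_sd baseline age distribution (default 41, 10)
#' @param p_female,p_dmt covariate probabilities (default 0.68, 0.71)
#' @param qol_drift favourable neuro-QOL drift in T-score points per year
#'   for improved patients (default 2)
#' @param seed integer seed; required by \code{\link{generate_cohort}}
#' @return list of class \code{sim_config}
#' @export
sim_config <- function(n_patients = 31, visits_per_patient = 4,
                       visit_jitter = 0.15, n_metabolites = 300,
                       module_sizes = c(40, 30, 25, 20),
                       within_module_cor = 0.6,
                       affected_modules = c(1, 2),
                       module_slopes = c(-0.10, -0.12),
                       target_module = 2,
                       noise_sd = 1, patient_intercept_sd = 0.2,
                       mu_log = 5, mu_log_sd = 1,
                       missing_rate = 0.10, censor_share = 0.5,
                       improvement_or = 0.3,
                       improvement_prevalence = 0.29,
                       age_mean = 41, age_sd = 10,
                       p_female = 0.68, p_dmt = 0.71,
                       qol_drift = 2, seed = NULL) {
  # adapt trend/linkage defaults when fewer modules are planted
  k <- length(module_sizes)
  if (missing(affected_modules) && k < 2) {
    affected_modules <- seq_len(k)
    if (missing(module_slopes)) module_slopes <- c(-0.10, -0.12)[seq_len(k)]
  }
  if (missing(target_module)) target_module <- min(2, k)
  stopifnot(n_patients >= 2, visits_per_patient >= 2,
            sum(module_sizes) <= n_metabolites,
            within_module_cor >= 0, within_module_cor < 1,
            length(module_slopes) == length(affected_modules),
            all(affected_modules <= length(module_sizes)),
            target_module <= length(module_sizes),
            missing_rate >= 0, missing_rate < 1,
            censor_share >= 0, censor_share <= 1,
            improvement_or > 0,
            improvement_prevalence > 0, improvement_prevalence < 1,
            p_female >= 0, p_female <= 1, p_dmt >= 0, p_dmt <= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Generate a synthetic longitudinal metabolomics cohort
#'
#' Log-scale generative model for metabolite m (module M), patient i,
#' visit j at time t:
#' \deqn{x = \mu_m + \sqrt{\rho}\, f_{M,ij} + b_{mi} + \delta_M t_{ij} +
#'   \epsilon,\qquad \epsilon \sim N(0, 1-\rho)}
#' with a shared standard-normal module factor f per sample inducing
#' within-module correlation, per-patient intercepts b, and per-year module
#' slopes delta on affected modules. Abundances are emitted as exp(x), so
#' they are positive and log-normal. Improvement labels follow a logistic
#' model in the standardized change of the target module's latent score,
#' with the configured odds ratio and an intercept solved so the marginal
#' prevalence matches the configuration; clinical trajectories are then
#' drawn consistent with each label (improved patients cross the composite
#' improvement thresholds, others stay within them). Missingness is
#' injected last via \code{\link{inject_missingness}}.
#'
#' @param config a \code{\link{sim_config}} with a non-NULL seed
#' @return list: \code{abundance} (masked \code{\link{abundance_table}}),
#'   \code{visits}, \code{cohort}, \code{pathways}, \code{clinical},
#'   \code{truth} (module labels, slopes, improvement probabilities/labels,
#'   complete matrix, missingness mechanism tags)
#' @export
generate_cohort <- function(config = sim_config(seed = NULL)) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(config$seed)) stop("sim_config seed is required")
  set.seed(as.integer(config$seed))
  cf <- config
  np <- cf$n_patients
  nv <- cf$visits_per_patient
  nm <- cf$n_metabolites

  patient_id <- sprintf("P%02d", seq_len(np))
  visits <- do.call(rbind, lapply(seq_len(np), function(i) {
    tt <- c(0, (seq_len(nv - 1)) +
              stats::runif(nv - 1, -cf$visit_jitter, cf$visit_jitter))
    data.frame(patient_id = patient_id[i],
               sample_id = sprintf("%s_V%d", patient_id[i], seq_len(nv)),
               time_years = tt, stringsAsFactors = FALSE)
  }))
  ns <- nrow(visits)

  cohort <- data.frame(
    patient_id = patient_id,
    age_baseline = round(pmax(18, stats::rnorm(np, cf$age_mean, cf$age_sd)), 1),
    sex = stats::rbinom(np, 1, cf$p_female),
    dmt_history = stats::rbinom(np, 1, cf$p_dmt),
    stringsAsFactors = FALSE)

  # module layout: metabolites 1..sum(sizes) in planted modules, rest free
  k <- length(cf$module_sizes)
  module_of <- rep(0L, nm)
  module_of[seq_len(sum(cf$module_sizes))] <-
    rep(seq_len(k), times = cf$module_sizes)
  met_id <- sprintf("M%04d", seq_len(nm))
  slopes <- stats::setNames(rep(0, k), seq_len(k))
  slopes[cf$affected_modules] <- cf$module_slopes

  rho <- cf$within_module_cor
  mu <- stats::rnorm(nm, cf$mu_log, cf$mu_log_sd)
  f <- matrix(stats::rnorm(ns * k), ns, k)           # module factors/sample
  b <- matrix(stats::rnorm(np * nm, 0, cf$patient_intercept_sd), np, nm)
  pidx <- match(visits$patient_id, patient_id)
  x <- matrix(stats::rnorm(ns * nm), ns, nm)
  lam <- sqrt(rho) * cf$noise_sd
  for (m in seq_len(nm)) {
    M <- module_of[m]
    if (M > 0) {
      x[, m] <- mu[m] + lam * f[, M] +
        sqrt(1 - rho) * cf$noise_sd * x[, m] +
        b[pidx, m] + slopes[M] * visits$time_years
    } else {
      x[, m] <- mu[m] + cf$noise_sd * x[, m] + b[pidx, m]
    }
  }
  dimnames(x) <- list(visits$sample_id, met_id)
  complete <- abundance_table(exp(x))

  # improvement: logistic in standardized target-module latent change
  tm <- cf$target_module
  latent <- lam * f[, tm] + slopes[tm] * visits$time_years
  dlat <- vapply(seq_len(np), function(i) {
    sel <- which(pidx == i)
    sel <- sel[order(visits$time_years[sel])]
    latent[sel[length(sel)]] - latent[sel[1]]
  }, numeric(1))
  z <- as.numeric(scale(dlat))
  beta <- log(cf$improvement_or)
  alpha <- stats::uniroot(function(a)
    mean(stats::plogis(a + beta * z)) - cf$improvement_prevalence,
    c(-20, 20))$root
  prob <- stats::plogis(alpha + beta * z)
  label <- stats::rbinom(np, 1, prob) == 1

  clinical <- generate_clinical_outcomes(visits, stats::setNames(label, patient_id),
                                         config = cf)

  pathways <- data.frame(
    metabolite_id = met_id,
    sub_pathway = ifelse(module_of > 0,
                         sprintf("planted_pathway_%d", module_of),
                         sprintf("background_pathway_%02d",
                                 ((seq_len(nm) - 1) %/% 10) %% 25 + 1)),
    super_pathway = ifelse(module_of > 0, "planted", "background"),
    stringsAsFactors = FALSE)

  masked <- inject_missingness(complete, cf$missing_rate, cf$censor_share)

  truth <- list(modules = stats::setNames(module_of, met_id),
                module_slopes = slopes,
                improvement_prob = stats::setNames(prob, patient_id),
                improvement_label = stats::setNames(label, patient_id),
                target_module_delta_z = stats::setNames(z, patient_id),
                complete = complete,
                mechanism = attr(masked, "mechanism"))

  list(abundance = masked, visits = visits, cohort = cohort,
       pathways = pathways, clinical = clinical, truth = truth)
}

#' Inject missingness into a complete abundance table
#'
#' Masks approximately \code{rate} of all entries. For each metabolite, a
#' \code{censor_share} fraction of its masked entries is drawn from its
#' lowest quartile of values (left-censoring, emulating detection-limit
#' dropout); the remainder is masked uniformly at random. Observed entries
#' are never altered.
#'
#' @param x a complete \code{\link{abundance_table}}
#' @param rate expected masked fraction, in [0, 1)
#' @param censor_share fraction of masked entries that are left-censored
#' @param seed optional seed (omit when called inside an already-seeded
#'   generator)
#' @return masked \code{abundance_table} with attribute \code{mechanism}, a
#'   character matrix tagging each entry \code{"observed"},
#'   \code{"censored"} or \code{"random"}
#' @export
inject_missingness <- function(x, rate, censor_share = 0.5, seed = NULL) {
  stopifnot(inherits(x, "abundance_table"))
  if (rate >= 1 || rate < 0) stop("rate must be in [0, 1)")
  stopifnot(censor_share >= 0, censor_share <= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  v <- x$values
  mech <- matrix("observed", nrow(v), ncol(v), dimnames = dimnames(v))
  if (rate > 0) {
    ns <- nrow(v)
    for (j in seq_len(ncol(v))) {
      n_mask <- stats::rbinom(1, ns, rate)
      if (n_mask == 0) next
      n_cens <- round(censor_share * n_mask)
      ord <- order(v[, j])
      qlow <- ord[seq_len(max(n_cens, ceiling(ns / 4)))]
      cens <- if (n_cens > 0) sample(qlow, n_cens) else integer(0)
      rest <- setdiff(seq_len(ns), cens)
      rnd <- if (n_mask - n_cens > 0) sample(rest, n_mask - n_cens)
             else integer(0)
      v[c(cens, rnd), j] <- NA
      mech[cens, j] <- "censored"
      mech[rnd, j] <- "random"
    }
  }
  out <- abundance_table(v, x$sample_ids, x$metabolite_ids)
  attr(out, "mechanism") <- mech
  out
}

#' Generate clinical outcome trajectories consistent with improvement labels
#'
#' Draws per-visit EDSS (half-point grid), timed-test times (positive
#' seconds), a processing-speed score and 12 neuro-QOL T-scores
#' (~N(50, 8) with favourable per-year drift for improved patients). By
#' construction, a patient labelled improved crosses the composite
#' improvement thresholds between baseline and last visit (EDSS -1.0,
#' T25FW -20 to -30\%, dominant 9HPT -15 to -25\%), so their overall
#' disability response score is positive; an unlabelled patient's changes
#' stay strictly inside every threshold, so it is not.
#'
#' @param visits visit table (\code{patient_id}, \code{time_years})
#' @param improvement_labels named logical vector per patient
#' @param seed optional seed (omit inside an already-seeded generator)
#' @param config a \code{\link{sim_config}} (for the quality-of-life drift)
#' @return per-visit clinical data frame (see \code{\link{load_dataset}})
#' @export
generate_clinical_outcomes <- function(visits, improvement_labels,
                                       seed = NULL,
                                       config = sim_config()) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  items <- neuroqol_items()
  pats <- unique(visits$patient_id)
  stopifnot(all(pats %in% names(improvement_labels)))
  rows <- lapply(pats, function(p) {
    vt <- sort(visits$time_years[visits$patient_id == p])
    nv <- length(vt)
    imp <- isTRUE(improvement_labels[[p]])
    edss0 <- sample(seq(1, 4, by = 0.5), 1)
    t25_0 <- exp(stats::rnorm(1, log(6), 0.2))
    hd_0 <- exp(stats::rnorm(1, log(20), 0.15))
    hn_0 <- exp(stats::rnorm(1, log(21), 0.15))
    if (imp) {
      edss_f <- edss0 - 1.0
      t25_f <- t25_0 * (1 - stats::runif(1, 0.20, 0.30))
      hd_f <- hd_0 * (1 - stats::runif(1, 0.15, 0.25))
      hn_f <- hn_0 * (1 + stats::runif(1, -0.05, 0.05))
    } else {
      edss_f <- edss0 + sample(c(0, 0.5), 1)
      t25_f <- t25_0 * (1 + stats::runif(1, -0.10, 0.10))
      hd_f <- hd_0 * (1 + stats::runif(1, -0.10, 0.10))
      hn_f <- hn_0 * (1 + stats::runif(1, -0.10, 0.10))
    }
    w <- vt / max(vt)                 # interpolate baseline -> final
    interp <- function(a, b) a + (b - a) * w *
      exp(stats::rnorm(nv, 0, 0.02) * c(0, rep(1, nv - 2), 0))
    edss <- round((edss0 + (edss_f - edss0) * w) * 2) / 2
    edss[1] <- edss0; edss[nv] <- edss_f
    qol0 <- stats::rnorm(nrow(items), 50, 8)
    drift <- ifelse(items$direction == "higher_worse", -1, 1) *
      (if (imp) config$qol_drift else 0)
    qol <- sapply(seq_len(nrow(items)), function(ii)
      qol0[ii] + drift[ii] * vt + stats::rnorm(nv, 0, 3))
    colnames(qol) <- paste0("qol_", items$item)
    cbind(data.frame(patient_id = p, time_years = vt, edss = edss,
                     t25fw_s = interp(t25_0, t25_f),
                     hpt_dom_s = interp(hd_0, hd_f),
                     hpt_nondom_s = interp(hn_0, hn_f),
                     pst = stats::rnorm(nv, 55, 6),
                     stringsAsFactors = FALSE),
          as.data.frame(qol))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
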