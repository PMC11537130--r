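#' EDSS-Plus composite improvement
#'
#' A patient improves under EDSS-Plus when, comparing the last study visit
#' with baseline, any of the following holds:
#' \itemize{
#'   \item EDSS decreased by at least 1.0 point from a baseline EDSS <= 5.5;
#'   \item EDSS decreased by at least 0.5 point from a baseline EDSS > 5.5;
#'   \item any timed test (T25FW, 9HPT dominant, 9HPT non-dominant) got at
#'     least 20\% faster (reduction in seconds, boundary inclusive).
#' }
#'
#' @param baseline,final lists/rows with \code{edss}, \code{t25fw_s},
#'   \code{hpt_dom_s}, \code{hpt_nondom_s}
#' @return logical flag
#' @export
edss_plus_improved <- function(baseline, final) {
  check_endpoint(baseline); check_endpoint(final)
  edss_dec <- baseline$edss - final$edss
  edss_ok <- (baseline$edss <= 5.5 && edss_dec >= 1.0) ||
    (baseline$edss > 5.5 && edss_dec >= 0.5)
  timed_ok <- any(vapply(c("t25fw_s", "hpt_dom_s", "hpt_nondom_s"),
                         function(cn) pct_reduction(baseline[[cn]],
                                                    final[[cn]]) >= 20,
                         logical(1)))
  isTRUE(edss_ok) || isTRUE(timed_ok)
}

pct_reduction <- function(base, fin) 100 * (base - fin) / base

check_endpoint <- function(x) {
  need <- c("edss", "t25fw_s", "hpt_dom_s", "hpt_nondom_s")
  miss <- need[vapply(need, function(cn)
    is.null(x[[cn]]) || is.na(x[[cn]]), logical(1))]
  if (length(miss))
    stop("incomplete disability record; missing: ",
         paste(miss, collapse = ", "))
  invisible(TRUE)
}

#' Overall Disability Response Score (ODRS)
#'
#' Scores four components (EDSS, T25FW, 9HPT dominant, 9HPT non-dominant)
#' as +1 (improved), -1 (worsened) or 0, and sums them to a total in
#' [-4, +4]; a strictly positive total flags overall improvement.
#' Timed tests improve/worsen at a 15\% or more reduction/increase in time
#' (inclusive). EDSS uses the EDSS-Plus thresholds: a 1.0-point change from
#' baseline <= 5.5, or a 0.5-point change from baseline > 5.5; the
#' improvement threshold is printed, and the same magnitudes are mirrored as
#' the worsening rule (a documented assumption).
#'
#' @inheritParams edss_plus_improved
#' @param patient_id optional identifier carried into the result
#' @return data frame of class \code{disability_response}:
#'   \code{patient_id}, component scores \code{edss}, \code{t25fw},
#'   \code{hpt_dom}, \code{hpt_nondom}, \code{odrs_total},
#'   \code{odrs_improved}, \code{edss_plus_improved}
#' @export
odrs <- function(baseline, final, patient_id = NA_character_) {
  check_endpoint(baseline); check_endpoint(final)
  dec <- baseline$edss - final$edss
  thr <- if (baseline$edss <= 5.5) 1.0 else 0.5
  edss_sc <- if (dec >= thr) 1L else if (-dec >= thr) -1L else 0L
  timed_sc <- vapply(c("t25fw_s", "hpt_dom_s", "hpt_nondom_s"),
                     function(cn) {
                       red <- pct_reduction(baseline[[cn]], final[[cn]])
                       if (red >= 15) 1L else if (red <= -15) -1L else 0L
                     }, integer(1))
  total <- edss_sc + sum(timed_sc)
  out <- data.frame(patient_id = patient_id, edss = edss_sc,
                    t25fw = timed_sc[[1]], hpt_dom = timed_sc[[2]],
                    hpt_nondom = timed_sc[[3]], odrs_total = total,
                    odrs_improved = total > 0,
                    edss_plus_improved = edss_plus_improved(baseline, final),
                    stringsAsFactors = FALSE)
  class(out) <- c("disability_response", class(out))
  out
}

#' Disability response for every patient in a clinical table
#'
#' Applies \code{\link{odrs}} between each patient's baseline
#' (\code{time_years == 0}) and last available visit.
#'
#' @param clinical per-visit clinical table (see \code{\link{load_dataset}})
#' @return \code{disability_response} data frame, one row per patient;
#'   patients with incomplete endpoints are dropped with a warning
#' @export
disability_response_scan <- function(clinical) {
  rows <- lapply(split(clinical, clinical$patient_id), function(cl) {
    cl <- cl[order(cl$time_years), , drop = FALSE]
    tryCatch(odrs(cl[1, ], cl[nrow(cl), ], patient_id = cl$patient_id[1]),
             error = function(e) {
               warning("patient ", cl$patient_id[1], " skipped: ",
                       conditionMessage(e))
               NULL
             })
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Wilcoxon signed-rank test for paired change
#'
#' Zero differences are dropped; absolute differences are ranked with
#' midranks for ties; W is the sum of positive-difference ranks. The
#' two-sided p is exact — full enumeration of all sign assignments — when
#' the effective n is at most 15 and there are no ties; otherwise the
#' normal approximation with tie correction and a 0.5 continuity correction
#' is used. If every difference is zero, p = 1 with a warning.
#'
#' @param baseline,final paired numeric vectors of equal length
#' @return list with \code{statistic} (W), \code{p}, \code{n_effective},
#'   \code{method}
#' @export
wilcoxon_signed_rank <- function(baseline, final) {
  stopifnot(length(baseline) == length(final), length(baseline) >= 1)
  d <- final - baseline
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all paired differences are zero")
    return(list(statistic = 0, p = 1, n_effective = 0L, method = "degenerate"))
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  ties <- anyDuplicated(abs(d)) > 0
  if (n <= 15 && !ties) {
    # exact: enumerate all 2^n sign assignments of the ranks
    dist <- w_distribution(sort(r))
    mu <- n * (n + 1) / 4
    p <- min(1, 2 * min(sum(dist$prob[dist$w <= W]),
                        sum(dist$prob[dist$w >= W])))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    cc <- sign(W - mu) * 0.5
    z <- (W - mu - cc) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal_approx"
  }
  list(statistic = W, p = p, n_effective = n, method = method)
}

# exact distribution of the positive-rank sum by convolution over ranks
w_distribution <- function(ranks) {
  # generating polynomial: prod_r (1 + x^r) / 2^n over rank support
  scale2 <- sum(ranks)                 # ranks are integers (no ties)
  probs <- 1
  offset <- 0
  for (r in ranks) {
    new <- c(probs, rep(0, r)) + c(rep(0, r), probs)
    probs <- new
  }
  probs <- probs / 2^length(ranks)
  list(w = seq(0, scale2), prob = probs)
}

#' Neuro-QOL per-item improvement by minimal detectable change
#'
#' A patient improves on an item when the change from baseline to last
#' visit, taken in the item's favourable direction, strictly exceeds the
#' item's minimal detectable change (MDC). Items without an MDC entry are
#' excluded with a warning.
#'
#' @param clinical per-visit clinical table with \code{qol_<item>} columns
#' @param mdc data frame with \code{item}, \code{direction}, \code{mdc}
#'   (see \code{\link{neuroqol_items}})
#' @return data frame: \code{patient_id}, \code{item}, \code{baseline},
#'   \code{final}, \code{direction}, \code{mdc}, \code{improved}
#' @export
neuroqol_improvement <- function(clinical, mdc = neuroqol_items()) {
  qcols <- grep("^qol_", names(clinical), value = TRUE)
  items <- sub("^qol_", "", qcols)
  known <- items %in% mdc$item
  if (any(!known))
    warning("items without an MDC entry excluded: ",
            paste(items[!known], collapse = ", "))
  items <- items[known]
  rows <- list()
  for (pid in unique(clinical$patient_id)) {
    cl <- clinical[clinical$patient_id == pid, , drop = FALSE]
    cl <- cl[order(cl$time_years), , drop = FALSE]
    for (it in items) {
      m <- mdc[mdc$item == it, ]
      b <- cl[[paste0("qol_", it)]][1]
      f <- cl[[paste0("qol_", it)]][nrow(cl)]
      if (is.na(b) || is.na(f)) next
      fav_change <- if (m$direction == "higher_worse") b - f else f - b
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = pid, item = it, baseline = b, final = f,
        direction = m$direction, mdc = m$mdc,
        improved = fav_change > m$mdc, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
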