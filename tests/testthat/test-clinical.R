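rec <- function(edss, t25 = 10, hd = 20, hn = 20)
  list(edss = edss, t25fw_s = t25, hpt_dom_s = hd, hpt_nondom_s = hn)

test_that("EDSS-Plus applies the printed decision thresholds", {
  # 0.5-point rule above baseline 5.5
  expect_true(edss_plus_improved(rec(6.0), rec(5.5)))
  # 1.0-point rule at baseline <= 5.5: a 0.5 decrease is not enough
  expect_false(edss_plus_improved(rec(3.0), rec(2.5)))
  expect_true(edss_plus_improved(rec(3.0), rec(2.0)))
  # timed 20% boundary is inclusive
  expect_true(edss_plus_improved(rec(3.0, t25 = 10.0), rec(3.0, t25 = 8.0)))
  expect_false(edss_plus_improved(rec(3.0, t25 = 10.0), rec(3.0, t25 = 8.1)))
  # any single timed test suffices
  expect_true(edss_plus_improved(rec(3.0, hn = 30), rec(3.0, hn = 24)))
  # missing component rejected
  expect_error(edss_plus_improved(list(edss = 3, t25fw_s = 10,
                                       hpt_dom_s = NA, hpt_nondom_s = 20),
                                  rec(3)), "hpt_dom_s")
})

test_that("ODRS component scores and total follow the printed rules", {
  # worked decision-boundary case: +1 EDSS, +1 T25FW, 0, -1
  r <- odrs(rec(4.0, t25 = 6.0, hd = 20, hn = 30),
            rec(3.0, t25 = 5.0, hd = 20, hn = 36))
  expect_equal(r$edss, 1L)
  expect_equal(r$t25fw, 1L)       # -16.7%
  expect_equal(r$hpt_dom, 0L)
  expect_equal(r$hpt_nondom, -1L) # +20%
  expect_equal(r$odrs_total, 1L)
  expect_true(r$odrs_improved)

  same <- odrs(rec(3.0), rec(3.0))
  expect_equal(same$odrs_total, 0L)
  expect_false(same$odrs_improved)

  worst <- odrs(rec(4.0, t25 = 10, hd = 20, hn = 20),
                rec(5.0, t25 = 12, hd = 24, hn = 24))
  expect_equal(worst$odrs_total, -4L)

  best <- odrs(rec(4.0, t25 = 10, hd = 20, hn = 20),
               rec(3.0, t25 = 8, hd = 16, hn = 16))
  expect_equal(best$odrs_total, 4L)
})

test_that("ODRS is monotone and bounded over an exhaustive threshold scan", {
  # exhaustive scan: EDSS baseline grid x timed changes -30%..+30%
  for (edss0 in seq(1, 8, by = 0.5)) {
    prev_total <- NULL
    for (chg in seq(-0.30, 0.30, by = 0.05)) {
      fin <- rec(edss0, t25 = 10 * (1 + chg))
      r <- odrs(rec(edss0), fin)
      expect_true(r$odrs_total >= -4 && r$odrs_total <= 4)
      expect_equal(r$odrs_total, r$edss + r$t25fw + r$hpt_dom + r$hpt_nondom)
      # worsening time must never raise the total
      if (!is.null(prev_total)) expect_lte(r$odrs_total, prev_total)
      prev_total <- r$odrs_total
    }
  }
  # improving one component never decreases the total
  set.seed(1)
  for (i in 1:50) {
    e0 <- sample(seq(1, 6, 0.5), 1)
    base <- rec(e0, t25 = runif(1, 4, 12), hd = runif(1, 15, 40),
                hn = runif(1, 15, 40))
    fin <- rec(max(0, e0 - sample(c(0, 0.5, 1), 1)),
               t25 = base$t25fw_s * runif(1, 0.7, 1.3),
               hd = base$hpt_dom_s * runif(1, 0.7, 1.3),
               hn = base$hpt_nondom_s * runif(1, 0.7, 1.3))
    t0 <- odrs(base, fin)$odrs_total
    fin_better <- fin; fin_better$t25fw_s <- base$t25fw_s * 0.5
    expect_gte(odrs(base, fin_better)$odrs_total, t0)
  }
})

test_that("ODRS +1 components relate to EDSS-Plus as the thresholds imply", {
  # EDSS component +1 implies EDSS-Plus improvement
  r <- odrs(rec(4.0), rec(3.0))
  expect_true(r$edss == 1L && r$edss_plus_improved)
  # a 15% timed gain scores ODRS +1 but is below the 20% EDSS-Plus bar
  r2 <- odrs(rec(3.0, t25 = 10), rec(3.0, t25 = 8.5))
  expect_equal(r2$t25fw, 1L)
  expect_false(r2$edss_plus_improved)
  # a 20% timed gain satisfies both
  r3 <- odrs(rec(3.0, t25 = 10), rec(3.0, t25 = 8.0))
  expect_true(r3$t25fw == 1L && r3$edss_plus_improved)
})

test_that("signed-rank test matches hand enumeration on the worked cases", {
  w1 <- wilcoxon_signed_rank(c(0, 0, 0), c(1, 2, 3))
  expect_equal(w1$statistic, 6)
  expect_equal(w1$p, 0.25)
  expect_equal(w1$method, "exact")
  # sign symmetry
  w2 <- wilcoxon_signed_rank(c(1, 2, 3), c(0, 0, 0))
  expect_equal(w2$statistic, 0)
  expect_equal(w2$p, 0.25)
  # midranks with a tie: p = 1 either way
  w3 <- wilcoxon_signed_rank(c(0, 0), c(1, -1))
  expect_equal(w3$p, 1.0)
  # all-zero differences degenerate
  expect_warning(w4 <- wilcoxon_signed_rank(c(1, 2), c(1, 2)), "zero")
  expect_equal(w4$p, 1)
})

test_that("exact signed-rank p equals full enumeration for n <= 10", {
  set.seed(1)
  for (i in 1:200) {
    n <- sample(3:10, 1)
    d <- round(rnorm(n, 0, 2), 3)
    d <- d[d != 0]
    if (length(d) < 2 || anyDuplicated(abs(d))) next
    got <- wilcoxon_signed_rank(rep(0, length(d)), d)
    expect_equal(got$p, wilcox_enum_oracle(d), tolerance = 1e-12)
    # independent cross-check against the standard library test
    ref <- wilcox.test(d, exact = TRUE)
    expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("large-n / tied cases use the corrected normal approximation", {
  set.seed(2)
  d <- round(rnorm(40, 0.3, 1), 1)   # ties by rounding
  d <- d[d != 0]
  got <- wilcoxon_signed_rank(rep(0, length(d)), d)
  expect_equal(got$method, "normal_approx")
  ref <- suppressWarnings(wilcox.test(d, exact = FALSE, correct = TRUE))
  expect_equal(got$p, ref$p.value, tolerance = 1e-10)
})

test_that("neuro-QOL improvement respects direction and strict MDC boundary", {
  mdc <- data.frame(item = c("fatigue", "cognition"),
                    direction = c("higher_worse", "higher_better"),
                    mdc = c(5, 5))
  cl <- data.frame(patient_id = rep("p1", 2), time_years = c(0, 2),
                   qol_fatigue = c(50, 44),      # drop of 6 on higher-is-worse
                   qol_cognition = c(50, 44),    # drop of 6 on higher-is-better
                   qol_unknown = c(50, 40))
  expect_warning(res <- neuroqol_improvement(cl, mdc), "unknown")
  expect_true(res$improved[res$item == "fatigue"])
  expect_false(res$improved[res$item == "cognition"])
  # change exactly at the MDC is not improvement
  cl2 <- data.frame(patient_id = rep("p1", 2), time_years = c(0, 2),
                    qol_fatigue = c(50, 45))
  expect_false(neuroqol_improvement(cl2, mdc)$improved)
})

test_that("disability_response_scan scores baseline vs last visit per patient", {
  cl <- data.frame(patient_id = c("p1", "p1", "p1", "p2", "p2"),
                   time_years = c(0, 1, 2, 0, 2),
                   edss = c(4, 3.5, 3, 2, 2),
                   t25fw_s = c(10, 9, 9.5, 8, 8.2),
                   hpt_dom_s = c(20, 20, 20, 22, 22),
                   hpt_nondom_s = c(20, 20, 20, 24, 23))
  res <- disability_response_scan(cl)
  expect_equal(nrow(res), 2L)
  expect_true(res$odrs_improved[res$patient_id == "p1"])   # EDSS 4 -> 3
  expect_false(res$odrs_improved[res$patient_id == "p2"])
})
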