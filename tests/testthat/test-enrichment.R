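mk_trend <- function(feature, estimate, p) {
  data.frame(feature = feature, estimate = estimate, p = p,
             stringsAsFactors = FALSE)
}

test_that("ranking statistic: sign dominates, ties break by id, p=0 guarded", {
  tr <- mk_trend(c("up1", "dn1"), c(0.5, -0.5), c(0.01, 0.01))
  rk <- rank_statistics(tr)
  expect_equal(rk$metabolite_id, c("up1", "dn1"))
  expect_equal(rk$stat, c(2, -2))

  tr2 <- mk_trend(c("b", "a", "c"), c(1, 1, -1), c(0.05, 0.05, 0.2))
  rk2 <- rank_statistics(tr2)
  expect_equal(rk2$metabolite_id, c("a", "b", "c"))  # tie -> lexicographic

  tr3 <- mk_trend(c("x", "y"), c(1, -1), c(0, 0.5))
  rk3 <- rank_statistics(tr3)
  expect_true(all(is.finite(rk3$stat)))
  expect_equal(rk3$stat[1], -log10(.Machine$double.eps))

  expect_error(rank_statistics(mk_trend(c("a", "a"), c(1, 1), c(0.1, 0.1))),
               "duplicate")
})

test_that("enrichment score matches hand running sums and the walk oracle", {
  rk <- structure(data.frame(metabolite_id = c("a", "b", "c", "d"),
                             stat = c(3, 2, 1, -1)),
                  class = c("ranked_list", "data.frame"))
  expect_equal(enrichment_score(rk, "a"), 1)       # top item concentrates
  expect_equal(enrichment_score(rk, "d"), -1)      # bottom item: max dip -1
  # w = 0 reduces to the classic KS increments 1/n_set
  expect_equal(enrichment_score(rk, c("a", "b"), weight = 0),
               es_walk_oracle(rk$metabolite_id, rk$stat, c("a", "b"), w = 0))
  # random lists against the literal element-by-element walk
  for (s in 1:25) {
    set.seed(s)
    n <- sample(10:60, 1)
    ids <- sprintf("m%03d", seq_len(n))
    stat <- sort(rnorm(n, 0, 2), decreasing = TRUE)
    rkr <- structure(data.frame(metabolite_id = ids, stat = stat),
                     class = c("ranked_list", "data.frame"))
    members <- sample(ids, sample(2:6, 1))
    expect_equal(enrichment_score(rkr, members),
                 es_walk_oracle(ids, stat, members), tolerance = 1e-12)
  }
  expect_error(enrichment_score(rk, character(0)), "empty")
  expect_error(enrichment_score(rk, "zzz"), "not in the ranked list")
})

test_that("ES with w = 0 is invariant to monotone rescaling of the statistic", {
  set.seed(7)
  ids <- sprintf("m%02d", 1:30)
  stat <- sort(rnorm(30), decreasing = TRUE)
  rk1 <- structure(data.frame(metabolite_id = ids, stat = stat),
                   class = c("ranked_list", "data.frame"))
  rk2 <- structure(data.frame(metabolite_id = ids, stat = exp(stat)),
                   class = c("ranked_list", "data.frame"))
  members <- sample(ids, 5)
  expect_equal(enrichment_score(rk1, members, weight = 0),
               enrichment_score(rk2, members, weight = 0), tolerance = 1e-12)
})

test_that("a planted top pathway is detected with positive NES", {
  set.seed(1)
  n <- 100
  ids <- sprintf("m%03d", 1:n)
  stat <- sort(rnorm(n, 0, 1), decreasing = TRUE)
  stat[1:5] <- stat[1:5] + 5
  rk <- structure(data.frame(metabolite_id = ids, stat = stat),
                  class = c("ranked_list", "data.frame"))
  pw <- data.frame(metabolite_id = ids,
                   sub_pathway = c(rep("planted", 5),
                                   sample(rep(sprintf("bg%02d", 1:19), 5))))
  res <- gsea_scan(rk, pw, min_set = 5, n_perm = 1000, seed = 1)
  top <- res[res$pathway == "planted", ]
  expect_gt(top$nes, 0)
  expect_lt(top$p_adj, 0.05)
  expect_equal(top$direction, "up")
  expect_true(all(sign(res$nes) == sign(res$es)))
  expect_true(all(res$p > 0 & res$p <= 1))
  # NES ordering in the output
  expect_false(is.unsorted(rev(abs(res$nes))))
})

test_that("same seed reproduces the enrichment table exactly", {
  set.seed(2)
  ids <- sprintf("m%03d", 1:60)
  stat <- sort(rnorm(60), decreasing = TRUE)
  rk <- structure(data.frame(metabolite_id = ids, stat = stat),
                  class = c("ranked_list", "data.frame"))
  pw <- data.frame(metabolite_id = ids,
                   sub_pathway = rep(sprintf("p%02d", 1:12), each = 5))
  r1 <- gsea_scan(rk, pw, n_perm = 200, seed = 99)
  r2 <- gsea_scan(rk, pw, n_perm = 200, seed = 99)
  expect_identical(r1, r2)
})

test_that("sampled permutation null matches full enumeration on a tiny list", {
  set.seed(3)
  n <- 8
  ids <- letters[1:n]
  stat <- sort(rnorm(n), decreasing = TRUE)
  rk <- structure(data.frame(metabolite_id = ids, stat = stat),
                  class = c("ranked_list", "data.frame"))
  combos <- combn(n, 2)
  enum <- apply(combos, 2, function(ix)
    enrichment_score(rk, ids[ix]))
  sampled <- replicate(4000, enrichment_score(rk, sample(ids, 2)))
  expect_equal(mean(abs(sampled)), mean(abs(enum)), tolerance = 0.05)
  expect_equal(mean(sampled > 0), mean(enum > 0), tolerance = 0.05)
})

test_that("undersized pathways yield an empty table with a warning", {
  rk <- structure(data.frame(metabolite_id = letters[1:10],
                             stat = 10:1),
                  class = c("ranked_list", "data.frame"))
  pw <- data.frame(metabolite_id = letters[1:4],
                   sub_pathway = rep("tiny", 4))
  expect_warning(res <- gsea_scan(rk, pw, min_set = 5, n_perm = 50, seed = 1),
                 "size filter")
  expect_equal(nrow(res), 0L)
  expect_error(gsea_scan(rk, pw, n_perm = 50), "seed")
})
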