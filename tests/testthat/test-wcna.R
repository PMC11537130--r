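test_that("soft-power adjacency matches direct arithmetic", {
  set.seed(1)
  m <- matrix(rnorm(80), 20, 4, dimnames = list(NULL, paste0("m", 1:4)))
  r <- cor(m)
  net_u <- correlation_adjacency(m, beta = 12, sign_mode = "unsigned")
  expect_equal(net_u$adjacency[1, 2], abs(r[1, 2])^12, tolerance = 1e-12)
  net_s <- correlation_adjacency(m, beta = 12, sign_mode = "signed")
  expect_equal(net_s$adjacency[1, 2], ((1 + r[1, 2]) / 2)^12,
               tolerance = 1e-12)
  # r = 1 with itself replicated -> adjacency 1; r = -1 signed -> 0
  m2 <- cbind(a = m[, 1], b = m[, 1], c = -m[, 1] + 1e-9 * 0)
  net2 <- correlation_adjacency(m2, beta = 12)
  expect_equal(net2$adjacency["a", "b"], 1)
  net2s <- correlation_adjacency(m2, beta = 12, sign_mode = "signed")
  expect_equal(net2s$adjacency["a", "c"], 0, tolerance = 1e-12)
  # exact |r| = 0.5 exemplar: a = 0.5^12
  expect_equal(abs(-0.5)^12, 2.44140625e-4)
  # zero-variance metabolite rejected by id
  m3 <- cbind(m, z = rep(1, 20))
  expect_error(correlation_adjacency(m3, 12), "zero-variance.*z")
})

test_that("TOM matches closed forms and the brute-force triple loop", {
  ids <- paste0("m", 1:3)
  ones <- matrix(1, 3, 3, dimnames = list(ids, ids))
  net <- structure(list(adjacency = ones, beta = 1, sign_mode = "unsigned"),
                   class = "metab_network")
  expect_true(all(abs(tom_similarity(net) - 1) < 1e-12))
  zer <- diag(3); dimnames(zer) <- list(ids, ids)
  netz <- structure(list(adjacency = zer, beta = 1, sign_mode = "unsigned"),
                    class = "metab_network")
  tz <- tom_similarity(netz)
  expect_true(all(tz[upper.tri(tz)] == 0))

  for (s in 1:5) {
    set.seed(s)
    a <- matrix(runif(36), 6, 6)
    a <- (a + t(a)) / 2
    diag(a) <- 1
    dimnames(a) <- list(paste0("m", 1:6), paste0("m", 1:6))
    net <- structure(list(adjacency = a, beta = 1, sign_mode = "unsigned"),
                     class = "metab_network")
    tom <- tom_similarity(net)
    brute <- tom_brute_oracle(a)
    expect_true(max(abs(tom - brute)) < 1e-12)
    expect_true(max(abs(tom - t(tom))) < 1e-12)
    expect_true(all(tom >= 0 & tom <= 1))
  }
})

test_that("module detection recovers planted blocks and labels by size", {
  m <- make_block_matrix(60, blocks = c(20, 20), noise = 0.05, seed = 1)
  noise <- matrix(rnorm(60 * 15), 60, 15,
                  dimnames = list(rownames(m), sprintf("N%02d", 1:15)))
  mat <- cbind(m, noise)
  tom <- tom_similarity(correlation_adjacency(mat, 12))
  mods <- detect_modules(tom, min_module_size = 10)
  blocks <- rep(c("b1", "b2", "bg"), c(20, 20, 15))
  expect_equal(sort(unique(mods[blocks == "b1"])), unique(mods[blocks == "b1"]))
  expect_equal(length(unique(mods[blocks == "b1"])), 1L)
  expect_equal(length(unique(mods[blocks == "b2"])), 1L)
  expect_false(unique(mods[blocks == "b1"]) == unique(mods[blocks == "b2"]))
  expect_true(all(mods[blocks == "b1"] != "grey"))
  expect_setequal(setdiff(unique(mods), "grey"), c("turquoise", "blue"))

  # identity TOM: nothing clusters
  idt <- diag(30)
  dimnames(idt) <- list(paste0("m", 1:30), paste0("m", 1:30))
  expect_true(all(detect_modules(idt, min_module_size = 5) == "grey"))

  # one global block: single turquoise module
  one <- make_block_matrix(50, blocks = 25, noise = 0.05, seed = 2)
  tom1 <- tom_similarity(correlation_adjacency(one, 12))
  mods1 <- detect_modules(tom1, min_module_size = 5)
  expect_true(all(mods1 == "turquoise"))
})

test_that("eigen-metabolite is the standardized profile in the rank-1 case", {
  set.seed(3)
  f <- rnorm(30)
  m <- cbind(a = 2 * f + 5, b = 0.5 * f - 1)   # identical standardized profiles
  rownames(m) <- paste0("s", 1:30)
  mods <- structure(setNames(c("turquoise", "turquoise"), c("a", "b")),
                    class = "module_set")
  eig <- eigenmetabolites(m, mods)
  zs <- as.numeric(scale(f))
  expect_equal(abs(cor(eig$scores[, "turquoise"], zs)), 1, tolerance = 1e-12)
  expect_gt(cor(eig$scores[, "turquoise"], zs), 0)  # orientation
  expect_equal(unname(eig$variance_explained["turquoise"]), 1,
               tolerance = 1e-12)
  expect_equal(mean(eig$scores[, 1]), 0, tolerance = 1e-12)
  expect_equal(sd(eig$scores[, 1]), 1, tolerance = 1e-12)

  # flipping all member signs: trajectory unchanged up to orientation
  m2 <- -m + 10
  eig2 <- eigenmetabolites(m2, mods)
  expect_equal(abs(cor(eig$scores[, 1], eig2$scores[, 1])), 1,
               tolerance = 1e-12)
})

test_that("eigen-metabolite maximizes explained variance", {
  set.seed(4)
  m <- make_block_matrix(40, blocks = 5, noise = 0.6, seed = 4)
  mods <- structure(setNames(rep("turquoise", 5), colnames(m)),
                    class = "module_set")
  eig <- eigenmetabolites(m, mods)
  xm <- scale(m)
  # brute-force eigendecomposition of the member correlation matrix
  ev <- eigen(cor(m), symmetric = TRUE)
  expect_equal(unname(eig$variance_explained["turquoise"]),
               ev$values[1] / sum(ev$values), tolerance = 1e-10)
  # beats 1000 random unit-norm combinations
  var_e <- as.numeric(var(xm %*% (ev$vectors[, 1] /
                                    sqrt(sum(ev$vectors[, 1]^2)))))
  rand_vars <- replicate(1000, {
    w <- rnorm(5); w <- w / sqrt(sum(w^2))
    as.numeric(var(xm %*% w))
  })
  expect_true(all(var_e >= rand_vars - 1e-10))
  # the reported eigen-metabolite spans the same direction
  expect_equal(as.numeric(abs(cor(eig$scores[, 1], xm %*% ev$vectors[, 1]))),
               1, tolerance = 1e-8)
})

test_that("module membership is the correlation with the eigen-metabolite", {
  m <- make_block_matrix(40, blocks = c(8, 8), noise = 0.3, seed = 5)
  tom <- tom_similarity(correlation_adjacency(m, 12))
  mods <- detect_modules(tom, min_module_size = 5)
  eig <- eigenmetabolites(m, mods)
  mm <- module_membership(m, eig)
  # hand-check one entry
  one <- mm$metabolite_id[1]
  own <- mm$module[1]
  expect_equal(mm$mm[1], cor(m[, one], eig$scores[, own]), tolerance = 1e-12)
  # planted structure: own-module membership beats cross-module
  assigned <- mm[mm$module != "grey", ]
  cross_cols <- paste0("mm_", setdiff(unique(assigned$module), NA))
  for (i in seq_len(nrow(assigned))) {
    other <- setdiff(cross_cols, paste0("mm_", assigned$module[i]))
    expect_gt(assigned$mm[i], mean(abs(unlist(assigned[i, other]))))
  }
  # single-metabolite module: own membership is exactly 1
  solo <- structure(setNames("turquoise", colnames(m)[1]),
                    class = "module_set")
  eig1 <- eigenmetabolites(m[, 1, drop = FALSE], solo)
  mm1 <- module_membership(m[, 1, drop = FALSE], eig1)
  expect_equal(mm1$mm, 1, tolerance = 1e-12)
})

test_that("planted modules are recovered near-perfectly at default settings", {
  scores <- vapply(1:5, function(s) {
    d <- generate_cohort(sim_config(seed = s, n_metabolites = 120,
                                    module_sizes = c(25, 20, 15)))
    mat <- preprocess_pipeline(d$abundance)$matrix
    tom <- tom_similarity(correlation_adjacency(mat, 12))
    mods <- detect_modules(tom)
    truth <- d$truth$modules[names(mods)]
    keep <- mods != "grey"
    ari_index(mods[keep], truth[keep])
  }, numeric(1))
  expect_true(all(scores >= 0.9))
})
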