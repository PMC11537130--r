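# Independent oracles and fixture builders used across the suite.

# adjusted Rand index between two labellings
ari_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  ex <- si * sj / choose(n, 2)
  (sij - ex) / ((si + sj) / 2 - ex)
}

# exact two-sided signed-rank p by brute enumeration of all sign vectors
wilcox_enum_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- signs %*% r
  mu <- n * (n + 1) / 4
  min(1, 2 * min(mean(ws <= W), mean(ws >= W)))
}

# naive O(n^3) topological overlap
tom_brute_oracle <- function(a) {
  diag(a) <- 0
  n <- nrow(a)
  tom <- diag(n)
  k <- colSums(a)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    den <- min(k[i], k[j]) + 1 - a[i, j]
    tom[i, j] <- if (den <= 0) 1 else (l + a[i, j]) / den
  }
  tom
}

# hand step-up Benjamini-Hochberg
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# literal running-sum enrichment score, walked element by element
es_walk_oracle <- function(ranked_ids, stats, members, w = 1) {
  n <- length(ranked_ids)
  hit <- ranked_ids %in% members
  wts <- abs(stats)^w
  denom <- sum(wts[hit])
  inc <- ifelse(hit, if (denom > 0) wts / denom else 1 / sum(hit),
                -1 / (n - sum(hit)))
  if (denom == 0) inc[hit] <- 1 / sum(hit)
  rs <- cumsum(inc)
  # signed extremum; the documented tie rule favours the positive side
  if (max(rs) >= -min(rs)) max(rs) else min(rs)
}

# small complete abundance fixture with optional planted blocks
make_block_matrix <- function(n_samples, blocks, noise = 0.2, seed = 1) {
  set.seed(seed)
  cols <- list()
  nm <- 0
  for (b in seq_along(blocks)) {
    f <- rnorm(n_samples)
    for (i in seq_len(blocks[b])) {
      nm <- nm + 1
      cols[[nm]] <- f + rnorm(n_samples, 0, noise)
    }
  }
  m <- do.call(cbind, cols)
  dimnames(m) <- list(sprintf("S%03d", seq_len(n_samples)),
                      sprintf("M%03d", seq_len(ncol(m))))
  m
}

# write a minimal five-table dataset to dir; returns the paths
write_toy_dataset <- function(dir, edss_values = c(2, 2, 3, 3)) {
  ab <- data.frame(sample_id = c("s1", "s2", "s3", "s4"),
                   met1 = c(1.0, 2.0, 3.0, 4.0),
                   met2 = c(2.0, 2.5, 3.0, 3.5),
                   met3 = c(5.0, 4.0, 3.0, 2.0))
  visits <- data.frame(patient_id = c("p1", "p1", "p2", "p2"),
                       sample_id = c("s1", "s2", "s3", "s4"),
                       time_years = c(0, 1.1, 0, 0.9))
  cohort <- data.frame(patient_id = c("p1", "p2"),
                       age_baseline = c(40, 45), sex = c(1, 0),
                       dmt_history = c(1, 1))
  pathways <- data.frame(metabolite_id = c("met1", "met2", "met3"),
                         sub_pathway = c("pwA", "pwA", "pwB"),
                         super_pathway = c("SA", "SA", "SB"))
  clinical <- data.frame(patient_id = c("p1", "p1", "p2", "p2"),
                         time_years = c(0, 1.1, 0, 0.9),
                         edss = edss_values,
                         t25fw_s = c(6, 5.5, 7, 7.2),
                         hpt_dom_s = c(20, 19, 21, 22),
                         hpt_nondom_s = c(22, 21, 23, 24),
                         pst = c(55, 56, 50, 49),
                         qol_anxiety = c(50, 48, 52, 53))
  paths <- list(abundance = file.path(dir, "abundance.tsv"),
                visits = file.path(dir, "visits.tsv"),
                cohort = file.path(dir, "cohort.tsv"),
                pathways = file.path(dir, "pathways.tsv"),
                clinical = file.path(dir, "clinical.tsv"))
  write.table(ab, paths$abundance, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(visits, paths$visits, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cohort, paths$cohort, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(pathways, paths$pathways, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(clinical, paths$clinical, sep = "\t", quote = FALSE, row.names = FALSE)
  paths
}

# time slope of an lme_fit
slope_est <- function(fit)
  fit$coefficients$estimate[fit$coefficients$term == "time_years"]
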