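#' Signed ranking statistic from trend results
#'
#' Each tested metabolite gets \eqn{s_m = sign(estimate) \cdot (-\log_{10}
#' p)} — large positive for confidently increasing metabolites, large
#' negative for confidently decreasing ones — and the list is sorted by
#' \eqn{s_m} descending. p-values are floored at machine epsilon so the
#' statistic stays finite; exact ties are broken by metabolite id
#' (lexicographic), making the order total and deterministic.
#'
#' @param trend a \code{trend_result} data frame (columns \code{feature},
#'   \code{estimate}, \code{p})
#' @return data frame of class \code{ranked_list}: \code{metabolite_id},
#'   \code{stat}, sorted descending
#' @export
rank_statistics <- function(trend) {
  stopifnot(all(c("feature", "estimate", "p") %in% names(trend)))
  if (anyDuplicated(trend$feature)) stop("duplicate feature ids")
  keep <- !is.na(trend$p) & !is.na(trend$estimate)
  tr <- trend[keep, , drop = FALSE]
  p <- pmax(tr$p, .Machine$double.eps)
  s <- sign(tr$estimate) * (-log10(p))
  ord <- order(-s, tr$feature)
  out <- data.frame(metabolite_id = tr$feature[ord], stat = s[ord],
                    stringsAsFactors = FALSE)
  class(out) <- c("ranked_list", class(out))
  out
}

#' Weighted running-sum enrichment score
#'
#' The classic weighted Kolmogorov-Smirnov statistic: walking down the
#' ranked list, members of the set ("hits") add \eqn{|s_m|^w / \sum_{hits}
#' |s|^w} and non-members subtract \eqn{1/(N - n_{set})}; the enrichment
#' score is the running sum's maximum deviation from zero, signed; an exact
#' tie between the positive and negative extrema resolves to the positive
#' one. With \eqn{w = 0} hit increments collapse to \eqn{1/n_{set}}
#' (unweighted KS).
#'
#' @param ranked a \code{ranked_list}
#' @param members character vector of set member ids (must all be ranked)
#' @param weight exponent w >= 0 on |s| (default 1)
#' @return enrichment score in [-1, 1]
#' @export
enrichment_score <- function(ranked, members, weight = 1) {
  stopifnot(weight >= 0)
  if (!length(members)) stop("empty member set")
  pos <- match(members, ranked$metabolite_id)
  if (anyNA(pos)) stop("set members not in the ranked list: ",
                       paste(members[is.na(pos)], collapse = ", "))
  es_from_positions(sort(pos), abs(ranked$stat)^weight,
                    nrow(ranked))
}

# running-sum extremum from sorted hit positions; w = |s|^weight for the
# full list. O(n_set): the running sum is extremal at (or just before) hits.
es_from_positions <- function(pos, w, n) {
  nh <- length(pos)
  if (nh >= n) return(1)
  wh <- w[pos]
  tot <- sum(wh)
  hit_cum <- if (tot > 0) cumsum(wh) / tot else seq_len(nh) / nh
  miss_dec <- (pos - seq_len(nh)) / (n - nh)   # misses seen before each hit
  top <- hit_cum - miss_dec                    # value just after each hit
  bottom <- c(0, hit_cum[-nh]) - miss_dec      # value just before each hit
  lo <- min(bottom)                            # bottom[1] <= 0 always
  hi <- max(top)
  if (hi >= -lo) hi else lo
}

#' Permutation pathway enrichment scan
#'
#' Computes the enrichment score of every pathway with at least
#' \code{min_set} ranked members, builds a null by metabolite-label
#' permutation (random same-size sets from the ranked list), and reports a
#' normalized enrichment score NES = ES / mean(|ES*|) over the same-sign
#' permutations — comparable across pathway sizes — with an add-one
#' corrected permutation p and Benjamini-Hochberg adjustment across
#' pathways. Output is sorted by |NES| descending.
#'
#' @param ranked a \code{ranked_list}
#' @param pathways pathway annotation data frame (\code{metabolite_id},
#'   \code{sub_pathway})
#' @param min_set smallest pathway tested (default 5)
#' @param n_perm permutations (default 1000)
#' @param weight running-sum weight (default 1)
#' @param seed integer seed (mandatory: the null is stochastic)
#' @return data frame of class \code{enrichment_result}: \code{pathway},
#'   \code{size}, \code{es}, \code{nes}, \code{p}, \code{p_adj},
#'   \code{direction}
#' @export
gsea_scan <- function(ranked, pathways, min_set = 5, n_perm = 1000,
                      weight = 1, seed) {
  if (missing(seed) || is.null(seed)) stop("seed is required for the permutation null")
  stopifnot(all(c("metabolite_id", "sub_pathway") %in% names(pathways)))
  set.seed(as.integer(seed))
  ids <- ranked$metabolite_id
  n <- length(ids)
  w <- abs(ranked$stat)^weight
  ann <- pathways[!is.na(pathways$sub_pathway) &
                    pathways$metabolite_id %in% ids, , drop = FALSE]
  sets <- split(ann$metabolite_id, ann$sub_pathway)
  sets <- sets[lengths(sets) >= min_set]
  empty <- data.frame(pathway = character(0), size = integer(0),
                      es = numeric(0), nes = numeric(0), p = numeric(0),
                      p_adj = numeric(0), direction = character(0),
                      stringsAsFactors = FALSE)
  if (!length(sets)) {
    warning("no pathway passes the minimum size filter (", min_set, ")")
    class(empty) <- c("enrichment_result", class(empty))
    return(empty)
  }
  # one shared null per set size keeps the scan O(sizes x n_perm)
  sizes <- sort(unique(lengths(sets)))
  null_by_size <- lapply(sizes, function(sz) {
    vapply(seq_len(n_perm), function(i)
      es_from_positions(sort(sample.int(n, sz)), w, n), numeric(1))
  })
  names(null_by_size) <- as.character(sizes)

  rows <- lapply(names(sets), function(pw) {
    members <- sets[[pw]]
    es <- es_from_positions(sort(match(members, ids)), w, n)
    null <- null_by_size[[as.character(length(members))]]
    same <- null[sign(null) == sign(es)]
    if (length(same)) {
      p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
      nes <- es / mean(abs(same))
    } else {
      p <- 1 / (1 + n_perm)
      nes <- es / mean(abs(null))
    }
    data.frame(pathway = pw, size = length(members), es = es, nes = nes,
               p = p, direction = if (es >= 0) "up" else "down",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out <- out[order(-abs(out$nes)), c("pathway", "size", "es", "nes", "p",
                                     "p_adj", "direction")]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", class(out))
  out
}
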