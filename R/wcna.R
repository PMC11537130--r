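#' Soft-thresholded correlation adjacency
#'
#' Pairwise Pearson correlation across samples raised to the soft power
#' \code{beta}. Unsigned networks use \code{|r|^beta}; signed networks use
#' \code{((1+r)/2)^beta} so anticorrelated metabolites get near-zero
#' adjacency rather than high adjacency. The diagonal is set to 1.
#'
#' @param mat processed samples x metabolites matrix (complete, normalized)
#' @param beta soft-threshold power (default 12)
#' @param sign_mode \code{"unsigned"} or \code{"signed"}
#' @return list of class \code{metab_network}: \code{adjacency} (symmetric,
#'   entries in [0,1], unit diagonal), \code{beta}, \code{sign_mode}
#' @export
correlation_adjacency <- function(mat, beta = 12,
                                  sign_mode = c("unsigned", "signed")) {
  sign_mode <- match.arg(sign_mode)
  stopifnot(is.matrix(mat), nrow(mat) >= 3, beta > 0)
  sds <- apply(mat, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance metabolite(s): ",
         paste(colnames(mat)[sds == 0], collapse = ", "))
  r <- stats::cor(mat)
  a <- if (sign_mode == "unsigned") abs(r)^beta else ((1 + r) / 2)^beta
  a[a > 1] <- 1
  diag(a) <- 1
  structure(list(adjacency = a, beta = beta, sign_mode = sign_mode),
            class = "metab_network")
}

#' Topological overlap matrix
#'
#' Neighbourhood-sharing similarity of a weighted network:
#' \deqn{TOM_{ij} = (l_{ij} + a_{ij}) / (\min(k_i, k_j) + 1 - a_{ij})}
#' with \eqn{l_{ij} = \sum_{u \ne i,j} a_{iu} a_{uj}} and connectivity
#' \eqn{k_i = \sum_{u \ne i} a_{iu}}. Two metabolites overlap strongly when
#' they are connected to each other and to the same neighbours; branches of
#' the 1 - TOM dendrogram are the module candidates.
#'
#' @param network a \code{metab_network} from
#'   \code{\link{correlation_adjacency}}
#' @return symmetric matrix in [0,1] with unit diagonal
#' @export
tom_similarity <- function(network) {
  stopifnot(inherits(network, "metab_network"))
  a <- network$adjacency
  diag(a) <- 0
  l <- a %*% a                           # sum_u a_iu a_uj, u free; u = i or j
  # contribute a_ii*a_ij = 0 since diag(a) = 0, so l already excludes i,j
  k <- colSums(a)
  kmin <- outer(k, k, pmin)
  denom <- kmin + 1 - a
  tom <- (l + a) / denom
  tom[denom <= 0] <- 1
  tom[tom > 1] <- 1
  diag(tom) <- 1
  dimnames(tom) <- dimnames(network$adjacency)
  tom
}

# canonical module colour sequence, assigned in decreasing size order
wgcna_colors <- function() {
  c("turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
    "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
    "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
    "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
    "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue")
}

#' Detect modules by static tree cut of the TOM dendrogram
#'
#' Average-linkage hierarchical clustering on dissimilarity 1 - TOM, cut at
#' a fixed height. Clusters reaching \code{min_module_size} become modules
#' and are colour-labelled in decreasing size order with the canonical
#' palette (turquoise, blue, brown, ...); everything else is "grey"
#' (unassigned). A static cut is simpler and fully deterministic; it is a
#' documented deviation from the dynamic hybrid tree cut of canonical
#' weighted correlation network analysis.
#'
#' @param tom TOM similarity matrix from \code{\link{tom_similarity}}
#' @param cut_height dendrogram cut height on 1 - TOM, in (0, 1]
#' @param min_module_size smallest reported module (>= 2)
#' @return named character vector of class \code{module_set}:
#'   metabolite -> colour label
#' @export
detect_modules <- function(tom, cut_height = 0.9999, min_module_size = 10) {
  stopifnot(is.matrix(tom), cut_height > 0, cut_height <= 1,
            min_module_size >= 2)
  ids <- colnames(tom)
  if (is.null(ids)) ids <- paste0("m", seq_len(ncol(tom)))
  if (ncol(tom) < min_module_size) {
    warning("fewer metabolites than min_module_size: all grey")
    return(structure(stats::setNames(rep("grey", ncol(tom)), ids),
                     class = "module_set"))
  }
  diss <- 1 - tom
  h <- stats::hclust(stats::as.dist(diss), method = "average")
  cl <- stats::cutree(h, h = cut_height)
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= min_module_size]
  labels <- stats::setNames(rep("grey", length(cl)), ids)
  if (length(keep)) {
    # decreasing size; ties broken by first member position (deterministic)
    first_pos <- vapply(keep, function(g) min(which(cl == g)), integer(1))
    ord <- keep[order(-sizes[keep], first_pos)]
    pal <- wgcna_colors()
    if (length(ord) > length(pal))
      pal <- c(pal, paste0("module", seq(length(pal) + 1, length(ord))))
    for (i in seq_along(ord)) labels[cl == ord[i]] <- pal[i]
  }
  structure(labels, class = "module_set")
}

#' Eigen-metabolites: first principal component per module
#'
#' For each module, member metabolites are standardized to mean 0 / SD 1
#' across samples and the first principal component of that member matrix is
#' extracted. Scores are scaled to unit sample variance (mean 0) and
#' sign-oriented so the eigen-metabolite correlates non-negatively with the
#' mean standardized member profile — PCA sign being arbitrary otherwise.
#' A one-metabolite module's eigen-metabolite is that standardized profile.
#'
#' @param mat processed samples x metabolites matrix
#' @param modules a \code{module_set}; "grey" is skipped
#' @return list of class \code{eigen_profile}: \code{scores} (samples x
#'   modules matrix), \code{variance_explained} (named vector),
#'   \code{modules} (the input assignment)
#' @export
eigenmetabolites <- function(mat, modules) {
  stopifnot(is.matrix(mat))
  cols <- setdiff(unique(unname(modules)), "grey")
  if (!length(cols)) stop("no non-grey modules")
  scores <- matrix(NA_real_, nrow(mat), length(cols),
                   dimnames = list(rownames(mat), cols))
  ve <- stats::setNames(numeric(length(cols)), cols)
  for (mcol in cols) {
    members <- names(modules)[modules == mcol]
    xm <- scale(mat[, members, drop = FALSE])
    if (length(members) == 1L) {
      e <- xm[, 1]
      ve[mcol] <- 1
    } else {
      sv <- svd(xm, nu = 1, nv = 0)
      e <- sv$u[, 1]
      ve[mcol] <- sv$d[1]^2 / sum(sv$d^2)
    }
    e <- e - mean(e)
    e <- e / stats::sd(e)
    if (stats::cor(e, rowMeans(xm)) < 0) e <- -e
    scores[, mcol] <- e
  }
  structure(list(scores = scores, variance_explained = ve, modules = modules),
            class = "eigen_profile")
}

#' Module membership (kME)
#'
#' Pearson correlation of every metabolite with every module
#' eigen-metabolite. The returned table is sorted, within module, by
#' own-module membership descending — hub metabolites first.
#'
#' @param mat processed samples x metabolites matrix
#' @param eigen an \code{eigen_profile}
#' @return data frame with columns \code{metabolite_id}, \code{module}
#'   (assigned module), \code{mm} (own-module membership; NA for grey) and
#'   one \code{mm_<colour>} column per module
#' @export
module_membership <- function(mat, eigen) {
  stopifnot(inherits(eigen, "eigen_profile"))
  mm_all <- stats::cor(mat, eigen$scores)
  mods <- eigen$modules[colnames(mat)]
  own <- vapply(seq_len(ncol(mat)), function(j) {
    m <- mods[j]
    if (is.na(m) || m == "grey" || !(m %in% colnames(mm_all))) NA_real_
    else mm_all[j, m]
  }, numeric(1))
  out <- data.frame(metabolite_id = colnames(mat),
                    module = unname(mods), mm = own,
                    stringsAsFactors = FALSE)
  colnames(mm_all) <- paste0("mm_", colnames(mm_all))
  out <- cbind(out, as.data.frame(mm_all, row.names = NULL))
  out[order(out$module, -out$mm), , drop = FALSE]
}
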