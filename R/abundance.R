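#' Construct an abundance table
#'
#' A samples x metabolites matrix of positive relative abundances with an
#' explicit missingness mask. Missing entries are stored as \code{NA}; the
#' mask is derived from them. All observed values must be strictly positive
#' (relative abundances from untargeted profiling are ratios of peak areas).
#'
#' @param values numeric matrix, samples in rows, metabolites in columns.
#'   \code{NA} marks a missing measurement. Row and column names are used as
#'   sample and metabolite identifiers if \code{sample_ids}/\code{metabolite_ids}
#'   are not given.
#' @param sample_ids,metabolite_ids optional character vectors of unique
#'   identifiers; defaults to the dimnames of \code{values}.
#' @return an object of class \code{abundance_table}: a list with elements
#'   \code{values} (the matrix, with ids as dimnames), \code{sample_ids} and
#'   \code{metabolite_ids}.
#' @export
abundance_table <- function(values, sample_ids = rownames(values),
                            metabolite_ids = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (samples x metabolites)")
  if (is.null(sample_ids) || is.null(metabolite_ids))
    stop("sample and metabolite identifiers are required (dimnames or arguments)")
  sample_ids <- as.character(sample_ids)
  metabolite_ids <- as.character(metabolite_ids)
  if (length(sample_ids) != nrow(values))
    stop("length(sample_ids) != nrow(values)")
  if (length(metabolite_ids) != ncol(values))
    stop("length(metabolite_ids) != ncol(values)")
  if (anyDuplicated(sample_ids))
    stop("duplicated sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyDuplicated(metabolite_ids))
    stop("duplicated metabolite ids: ",
         paste(unique(metabolite_ids[duplicated(metabolite_ids)]), collapse = ", "))
  if (any(values <= 0, na.rm = TRUE)) {
    bad <- which(values <= 0, arr.ind = TRUE)[1, ]
    stop(sprintf("non-positive abundance at sample '%s', metabolite '%s'",
                 sample_ids[bad[1]], metabolite_ids[bad[2]]))
  }
  dimnames(values) <- list(sample_ids, metabolite_ids)
  structure(list(values = values, sample_ids = sample_ids,
                 metabolite_ids = metabolite_ids),
            class = "abundance_table")
}

#' Missingness mask of an abundance table
#'
#' @param x an \code{abundance_table}
#' @return logical matrix, \code{TRUE} where the measurement is missing
#' @export
missing_mask <- function(x) {
  stopifnot(inherits(x, "abundance_table"))
  is.na(x$values)
}

#' @export
print.abundance_table <- function(x, ...) {
  nm <- sum(is.na(x$values))
  cat(sprintf("abundance_table: %d samples x %d metabolites, %d missing (%.1f%%)\n",
              nrow(x$values), ncol(x$values), nm,
              100 * nm / length(x$values)))
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$values)

# internal: subset columns (metabolites), keeping class invariants
subset_metabolites <- function(x, keep) {
  abundance_table(x$values[, keep, drop = FALSE])
}
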