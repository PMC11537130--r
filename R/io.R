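#' Load and cross-validate all pipeline inputs
#'
#' Reads the five delimited text tables (CSV or TSV by file extension, header
#' row required, missing abundances as empty fields or "NA"), validates each
#' against its structural invariants, cross-references them, and logs a short
#' validation report.
#'
#' @param abundance_path samples x metabolites table; first column = sample id.
#' @param visits_path columns \code{patient_id}, \code{sample_id},
#'   \code{time_years} (years from each patient's own baseline visit).
#' @param cohort_path columns \code{patient_id}, \code{age_baseline},
#'   \code{sex} (female = 1), \code{dmt_history} (prior DMT = 1).
#' @param pathways_path columns \code{metabolite_id}, \code{sub_pathway},
#'   \code{super_pathway}.
#' @param clinical_path per-visit clinical outcomes: \code{patient_id},
#'   \code{time_years}, \code{edss}, \code{t25fw_s}, \code{hpt_dom_s},
#'   \code{hpt_nondom_s}, \code{pst}, and one \code{qol_<item>} column per
#'   neuro-QOL item.
#' @param config an \code{\link{analysis_config}}
#' @param quiet suppress the validation report
#' @return a list with elements \code{abundance} (an
#'   \code{\link{abundance_table}}), \code{visits}, \code{cohort},
#'   \code{pathways}, \code{clinical} (data frames)
#' @export
load_dataset <- function(abundance_path, visits_path, cohort_path,
                         pathways_path, clinical_path,
                         config = analysis_config(), quiet = FALSE) {
  for (p in c(abundance_path, visits_path, cohort_path, pathways_path,
              clinical_path))
    if (!file.exists(p)) stop("input file not found: ", p)

  ab_raw <- read_table_auto(abundance_path)
  if (ncol(ab_raw) < 2) stop("abundance table needs a sample-id column plus metabolites")
  vals <- as.matrix(ab_raw[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- as.character(ab_raw[[1]])
  abundance <- abundance_table(vals)

  visits <- read_table_auto(visits_path)
  visits <- validate_visits(visits)
  cohort <- read_table_auto(cohort_path)
  cohort <- validate_cohort(cohort, visits)
  pathways <- read_table_auto(pathways_path)
  pathways <- validate_pathways(pathways)
  clinical <- read_table_auto(clinical_path)
  clinical <- validate_clinical(clinical)

  orphan <- setdiff(abundance$sample_ids, visits$sample_id)
  if (length(orphan))
    stop("abundance samples without visit metadata: ",
         paste(utils::head(orphan, 5), collapse = ", "))

  if (!quiet) {
    message(sprintf(
      "loaded %d samples x %d metabolites (%.1f%% missing), %d visits, %d patients, %d pathway annotations",
      nrow(abundance$values), ncol(abundance$values),
      100 * mean(is.na(abundance$values)), nrow(visits),
      nrow(cohort), nrow(pathways)))
  }
  list(abundance = abundance, visits = visits, cohort = cohort,
       pathways = pathways, clinical = clinical)
}

read_table_auto <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, na.strings = c("", "NA"),
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "")
}

validate_visits <- function(visits) {
  need <- c("patient_id", "sample_id", "time_years")
  if (!all(need %in% names(visits)))
    stop("visits table must have columns: ", paste(need, collapse = ", "))
  visits$patient_id <- as.character(visits$patient_id)
  visits$sample_id <- as.character(visits$sample_id)
  if (anyDuplicated(visits$sample_id))
    stop("duplicated sample_id in visits table")
  if (any(visits$time_years < 0)) stop("negative time_years in visits table")
  for (p in unique(visits$patient_id)) {
    tt <- visits$time_years[visits$patient_id == p]
    if (sum(tt == 0) != 1)
      stop("patient ", p, " must have exactly one baseline visit (time_years = 0)")
    if (is.unsorted(tt, strictly = TRUE) && is.unsorted(rev(tt), strictly = TRUE))
      stop("visit times not strictly ordered for patient ", p)
    if (anyDuplicated(tt)) stop("duplicated visit time for patient ", p)
  }
  visits[order(visits$patient_id, visits$time_years), , drop = FALSE]
}

validate_cohort <- function(cohort, visits) {
  need <- c("patient_id", "age_baseline", "sex", "dmt_history")
  if (!all(need %in% names(cohort)))
    stop("cohort table must have columns: ", paste(need, collapse = ", "))
  cohort$patient_id <- as.character(cohort$patient_id)
  if (anyDuplicated(cohort$patient_id))
    stop("duplicated patient_id in cohort table")
  if (!all(cohort$sex %in% c(0, 1)) || !all(cohort$dmt_history %in% c(0, 1)))
    stop("sex and dmt_history must be coded 0/1 (female = 1, prior DMT = 1)")
  missing_pat <- setdiff(unique(visits$patient_id), cohort$patient_id)
  if (length(missing_pat))
    stop("patients with visits but no cohort record: ",
         paste(missing_pat, collapse = ", "))
  cohort
}

validate_pathways <- function(pathways) {
  need <- c("metabolite_id", "sub_pathway")
  if (!all(need %in% names(pathways)))
    stop("pathway table must have columns metabolite_id, sub_pathway")
  pathways$metabolite_id <- as.character(pathways$metabolite_id)
  if (anyDuplicated(pathways$metabolite_id))
    stop("a metabolite maps to more than one sub-pathway")
  if (!"super_pathway" %in% names(pathways)) pathways$super_pathway <- NA_character_
  pathways
}

validate_clinical <- function(clinical) {
  need <- c("patient_id", "time_years", "edss", "t25fw_s", "hpt_dom_s",
            "hpt_nondom_s")
  if (!all(need %in% names(clinical)))
    stop("clinical table must have columns: ", paste(need, collapse = ", "))
  clinical$patient_id <- as.character(clinical$patient_id)
  check_edss_grid(clinical$edss)
  timed <- c("t25fw_s", "hpt_dom_s", "hpt_nondom_s")
  for (cn in timed) {
    bad <- which(!is.na(clinical[[cn]]) & clinical[[cn]] <= 0)
    if (length(bad))
      stop(cn, " must be positive seconds; offending row(s): ",
           paste(utils::head(bad, 5), collapse = ", "))
  }
  clinical[order(clinical$patient_id, clinical$time_years), , drop = FALSE]
}

# EDSS is scored on a 0-10 grid in 0.5-point steps; anything else is a
# data-entry error and is rejected with its row number.
check_edss_grid <- function(edss) {
  ok <- is.na(edss) | (edss >= 0 & edss <= 10 &
                         abs(edss * 2 - round(edss * 2)) < 1e-9)
  if (!all(ok)) {
    bad <- which(!ok)
    stop("EDSS off the 0-10 half-point grid at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "),
         " (value ", edss[bad[1]], ")")
  }
  invisible(TRUE)
}

#' Write all stage outputs as TSV files plus a run manifest
#'
#' Each element of \code{stage_outputs} that is a data frame is written as
#' \code{<name>.tsv}; matrices are written with their row names in a leading
#' id column. Writing is deterministic: identical inputs, config and seed
#' yield byte-identical files. An empty data frame yields a header-only TSV.
#'
#' @param stage_outputs named list of data frames / matrices
#' @param out_dir output directory, created if needed
#' @param config optional \code{analysis_config} recorded in the manifest
#' @return invisible character vector of files written (the manifest last)
#' @export
write_results <- function(stage_outputs, out_dir, config = NULL) {
  stopifnot(is.list(stage_outputs), length(names(stage_outputs)) ==
              length(stage_outputs))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  if (file.access(out_dir, mode = 2) != 0)
    stop("output directory not writable: ", out_dir)

  files <- character(0)
  for (nm in names(stage_outputs)) {
    x <- stage_outputs[[nm]]
    if (is.matrix(x)) {
      x <- data.frame(id = rownames(x), x, check.names = FALSE,
                      stringsAsFactors = FALSE)
    }
    if (!is.data.frame(x)) next
    path <- file.path(out_dir, paste0(nm, ".tsv"))
    write_tsv_det(x, path)
    files <- c(files, path)
  }
  manifest <- data.frame(
    key = c("package_version",
            if (!is.null(config)) names(scalar_config(config)),
            paste0("rows_", names(stage_outputs))),
    value = c(as.character(utils::packageVersion("metamodtrend")),
              if (!is.null(config)) unname(scalar_config(config)),
              vapply(stage_outputs, function(x)
                as.character(if (is.null(dim(x))) length(x) else nrow(x)),
                character(1))),
    stringsAsFactors = FALSE)
  mpath <- file.path(out_dir, "run_manifest.tsv")
  write_tsv_det(manifest, mpath)
  invisible(c(files, mpath))
}

scalar_config <- function(config) {
  sc <- config[vapply(config, function(v)
    is.atomic(v) && length(v) == 1, logical(1))]
  vapply(sc, as.character, character(1))
}

# deterministic TSV writer: fixed eol, full-precision numbers via
# as.character (15 significant digits, locale-independent)
write_tsv_det <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "NA", eol = "\n")
}
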