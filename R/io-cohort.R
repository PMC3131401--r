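.cohortRequiredColumns <- c("subject_id", "sex", "group", "category",
                            "discipline", "best_distance_m",
                            "carnosine_left_mM", "carnosine_right_mM")

#' Read a cohort table
#'
#' CSV with the documented header
#' `subject_id,sex,group,category,discipline,best_distance_m,carnosine_left_mM,carnosine_right_mM`.
#' Parsing is order-preserving and total: n rows in give n records out or a
#' hard error. `carnosine_mean_mM` is filled by [bilateralMean()] — the
#' bilateral mean when both legs are present, otherwise the single
#' measurement.
#'
#' @param path CSV file.
#' @return a cohort data.frame with a `carnosine_mean_mM` column appended.
#' @export
readCohortTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.cohortRequiredColumns, names(d))
  if (length(miss))
    stop("cohort table is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(d$subject_id)) {
    dup <- unique(d$subject_id[duplicated(d$subject_id)])
    stop("duplicate subject_id: ", paste(dup, collapse = ", "))
  }
  badSex <- setdiff(unique(d$sex), .validSexes)
  if (length(badSex))
    stop(sprintf("unknown sex token(s) %s; valid tokens: %s",
                 paste(sQuote(badSex), collapse = ", "),
                 paste(.validSexes, collapse = ", ")))
  badGroup <- setdiff(unique(d$group), .validGroups)
  if (length(badGroup))
    stop(sprintf("unknown group token(s) %s; valid tokens: %s",
                 paste(sQuote(badGroup), collapse = ", "),
                 paste(.validGroups, collapse = ", ")))
  badCat <- setdiff(unique(d$category[!is.na(d$category)]), .validCategories)
  if (length(badCat))
    stop(sprintf("unknown category token(s) %s; valid tokens: %s",
                 paste(sQuote(badCat), collapse = ", "),
                 paste(.validCategories, collapse = ", ")))
  if (any(!is.na(d$best_distance_m) & d$best_distance_m <= 0))
    stop("'best_distance_m' must be > 0 when present")
  d$carnosine_mean_mM <- vapply(seq_len(nrow(d)), function(i)
    bilateralMean(d$carnosine_left_mM[i], d$carnosine_right_mM[i]),
    numeric(1))
  d
}

#' Write a cohort table
#'
#' @param cohort a cohort data.frame.
#' @param path output CSV.
#' @return the path, invisibly.
#' @export
writeCohortTable <- function(cohort, path) {
  miss <- setdiff(.cohortRequiredColumns, names(cohort))
  if (length(miss))
    stop("cohort is missing column(s): ", paste(miss, collapse = ", "))
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a biopsy calibration table
#'
#' CSV with columns `subject_id,ft_area_pct,carnosine_mM`.
#'
#' @param path CSV file.
#' @return a data.frame.
#' @export
readCalibrationTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("subject_id", "ft_area_pct", "carnosine_mM"), names(d))
  if (length(miss))
    stop("calibration table is missing column(s): ",
         paste(miss, collapse = ", "))
  if (any(is.na(d$ft_area_pct)) || any(is.na(d$carnosine_mM)))
    stop("calibration table contains missing values")
  d
}
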