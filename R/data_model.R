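#' Study-level multivariate meta-analysis dataset
#'
#' Container for study-level effect estimates and their standard errors across
#' one or more outcomes, with outcomes possibly missing in some studies. This
#' is the arm-agnostic input every fitting function in the package consumes:
#' per study \code{i} and outcome \code{j} an effect \eqn{Y_{ij}} on its
#' native scale and a positive standard error \eqn{s_{ij}}, either both
#' present or both absent.
#'
#' @param effects numeric matrix (studies x outcomes) of effect estimates;
#'   \code{NA} marks a missing outcome.
#' @param std_errors numeric matrix of the same shape with the standard
#'   errors; the \code{NA} pattern must match \code{effects} exactly and all
#'   present values must be strictly positive.
#' @param study_ids character vector of unique study labels; defaults to
#'   \code{"S1", "S2", ...}.
#' @param outcome_names character vector of outcome labels; defaults to
#'   \code{"Y1", "Y2", ...}. Outcome order is the column order and all
#'   matrices produced downstream are indexed in that order.
#'
#' @return An object of class \code{meta_dataset}: a list with elements
#'   \code{effects}, \code{std_errors} (named matrices), \code{study_ids},
#'   \code{outcome_names}.
#'
#' @examples
#' d <- meta_dataset(effects = cbind(c(0.2, -0.1, 0.4), c(0.1, NA, 0.3)),
#'                   std_errors = cbind(c(0.1, 0.2, 0.3), c(0.2, NA, 0.1)))
#' outcome_n(d)
#' overlap_ids(d, 1, 2)
#' @export
meta_dataset <- function(effects, std_errors, study_ids = NULL,
                         outcome_names = NULL) {
  effects <- as.matrix(effects)
  std_errors <- as.matrix(std_errors)
  if (!all(dim(effects) == dim(std_errors)))
    stop("'effects' and 'std_errors' must have identical dimensions")
  n <- nrow(effects)
  J <- ncol(effects)
  if (J < 1L) stop("at least one outcome is required")
  if (is.null(study_ids)) study_ids <- paste0("S", seq_len(n))
  study_ids <- as.character(study_ids)
  if (length(study_ids) != n) stop("'study_ids' length must match rows")
  if (anyDuplicated(study_ids))
    stop("study_ids must be unique; duplicated: ",
         paste(unique(study_ids[duplicated(study_ids)]), collapse = ", "))
  if (is.null(outcome_names)) {
    outcome_names <- colnames(effects)
    if (is.null(outcome_names)) outcome_names <- paste0("Y", seq_len(J))
  }
  if (length(outcome_names) != J) stop("'outcome_names' length must match columns")

  for (j in seq_len(J)) {
    ey <- is.na(effects[, j]); es <- is.na(std_errors[, j])
    bad <- which(ey != es)
    if (length(bad))
      stop(sprintf("study %s, outcome %s: effect and standard error must be present together",
                   study_ids[bad[1L]], outcome_names[j]))
    nonpos <- which(!es & std_errors[, j] <= 0)
    if (length(nonpos))
      stop(sprintf("study %s, outcome %s: standard error must be > 0 (got %g)",
                   study_ids[nonpos[1L]], outcome_names[j],
                   std_errors[nonpos[1L], j]))
  }

  dimnames(effects) <- dimnames(std_errors) <- list(study_ids, outcome_names)
  structure(list(effects = effects, std_errors = std_errors,
                 study_ids = study_ids, outcome_names = outcome_names),
            class = "meta_dataset")
}

#' @export
print.meta_dataset <- function(x, ...) {
  cat(sprintf("meta_dataset: %d studies, %d outcome(s) [%s]\n",
              length(x$study_ids), length(x$outcome_names),
              paste(x$outcome_names, collapse = ", ")))
  nj <- outcome_n(x)
  cat("studies per outcome:", paste(sprintf("%s=%d", names(nj), nj),
                                    collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.meta_dataset <- function(x, ...) {
  J <- length(x$outcome_names)
  out <- data.frame(study_id = x$study_ids, stringsAsFactors = FALSE)
  for (j in seq_len(J)) {
    out[[paste0("y_", x$outcome_names[j])]] <- x$effects[, j]
    out[[paste0("s_", x$outcome_names[j])]] <- x$std_errors[, j]
  }
  out
}

resolve_outcome <- function(dataset, outcome) {
  if (is.character(outcome)) {
    j <- match(outcome, dataset$outcome_names)
    if (is.na(j)) stop("unknown outcome: ", outcome)
    j
  } else {
    j <- as.integer(outcome)
    if (j < 1L || j > length(dataset$outcome_names))
      stop("outcome index out of range: ", outcome)
    j
  }
}

#' Number of studies reporting each outcome
#'
#' @param dataset a [meta_dataset()].
#' @return named integer vector \eqn{n_j} = number of studies with the
#'   outcome present.
#' @export
outcome_n <- function(dataset) {
  stopifnot(inherits(dataset, "meta_dataset"))
  nj <- colSums(!is.na(dataset$effects))
  stats::setNames(as.integer(nj), dataset$outcome_names)
}

#' Overlap set of a pair of outcomes
#'
#' The set \eqn{A} of studies reporting both outcomes of a pair: the only
#' studies that contribute to the cross-covariance "meat" of the sandwich
#' estimator.
#'
#' @param dataset a [meta_dataset()].
#' @param j,k outcome index or name.
#' @return character vector of study ids in \eqn{A} (possibly empty).
#' @export
overlap_ids <- function(dataset, j, k) {
  stopifnot(inherits(dataset, "meta_dataset"))
  j <- resolve_outcome(dataset, j); k <- resolve_outcome(dataset, k)
  keep <- !is.na(dataset$effects[, j]) & !is.na(dataset$effects[, k])
  dataset$study_ids[keep]
}

# Extract the complete cases of one outcome as vectors, erroring below a
# minimum study count (2 regression parameters + a residual variance need 3).
outcome_vectors <- function(dataset, j, min_n = 3L) {
  j <- resolve_outcome(dataset, j)
  keep <- !is.na(dataset$effects[, j])
  n <- sum(keep)
  if (n < min_n)
    stop(sprintf("outcome %s has %d studies; at least %d are required",
                 dataset$outcome_names[j], n, min_n))
  list(y = dataset$effects[keep, j], s = dataset$std_errors[keep, j],
       ids = dataset$study_ids[keep], name = dataset$outcome_names[j])
}

#' Read a study-level meta-analysis dataset from CSV
#'
#' Expected schema: one row per study, header
#' \code{study_id, y_<name1>, s_<name1>, y_<name2>, s_<name2>, ...};
#' empty cells encode missing outcomes; decimal point, comma separator.
#'
#' @param path path to a CSV file.
#' @return a [meta_dataset()].
#' @export
read_meta_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"study_id" %in% names(df))
    stop("header must contain a 'study_id' column")
  ycols <- grep("^y_", names(df), value = TRUE)
  if (!length(ycols)) stop("no outcome columns (y_<name>) found")
  nms <- sub("^y_", "", ycols)
  scols <- paste0("s_", nms)
  missing_s <- setdiff(scols, names(df))
  if (length(missing_s))
    stop("missing standard-error column(s): ", paste(missing_s, collapse = ", "))
  eff <- as.matrix(df[, ycols, drop = FALSE])
  se <- as.matrix(df[, scols, drop = FALSE])
  storage.mode(eff) <- "double"; storage.mode(se) <- "double"
  meta_dataset(eff, se, study_ids = as.character(df$study_id),
               outcome_names = nms)
}

#' Write a meta-analysis dataset to CSV
#'
#' Inverse of [read_meta_csv()]: values are written at full precision so a
#' write/read round trip reproduces the dataset exactly, including the
#' missingness pattern (missing outcomes become empty cells).
#'
#' @param dataset a [meta_dataset()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_meta_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "meta_dataset"))
  df <- as.data.frame(dataset)
  num <- vapply(df, is.numeric, logical(1))
  for (cl in names(df)[num])
    df[[cl]] <- ifelse(is.na(df[[cl]]), "",
                       formatC(df[[cl]], digits = 17, format = "g"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
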