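#' Metabolite abundance matrix
#'
#' Container for a samples x metabolites abundance table together with the
#' per-sample run-day labels needed for batch scaling. Missing measurements
#' are encoded as `NA`. All downstream stages of the package consume this
#' class.
#'
#' @param values Numeric matrix, samples in rows, metabolites in columns.
#'   Row names are sample ids, column names metabolite ids; defaults are
#'   generated when absent.
#' @param runday Character (or factor) vector of per-sample run-day labels,
#'   recycled from a single value. Defaults to a single run day.
#' @return An object of class `MetaboliteMatrix`: a list with elements
#'   `values` (the matrix) and `runday` (character vector aligned to rows).
#' @examples
#' m <- metabolite_matrix(matrix(rlnorm(20), 5, 4))
#' dim(m$values)
#' @export
metabolite_matrix <- function(values, runday = NULL) {
  if (is.data.frame(values)) values <- as.matrix(values)
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("S%04d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("M%04d", seq_len(ncol(values)))
  if (anyDuplicated(rownames(values))) stop("duplicated sample ids")
  if (anyDuplicated(colnames(values))) stop("duplicated metabolite ids")
  if (is.null(runday)) runday <- "D1"
  runday <- as.character(runday)
  if (length(runday) == 1L) runday <- rep(runday, nrow(values))
  if (length(runday) != nrow(values))
    stop("runday must have one label per sample")
  structure(list(values = values, runday = runday),
            class = "MetaboliteMatrix")
}

#' @export
print.MetaboliteMatrix <- function(x, ...) {
  cat(sprintf("MetaboliteMatrix: %d samples x %d metabolites, %d run day(s), %.1f%% missing\n",
              nrow(x$values), ncol(x$values), length(unique(x$runday)),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' @rdname metabolite_matrix
#' @param m A `MetaboliteMatrix`.
#' @export
sample_ids <- function(m) rownames(m$values)

#' @rdname metabolite_matrix
#' @export
metabolite_ids <- function(m) colnames(m$values)

# validate a covariate table against a MetaboliteMatrix; returns the table
# reordered to the matrix's samples
.check_covariates <- function(m, cov) {
  stopifnot(is.data.frame(cov))
  need <- c("gender", "age", "bmi")
  miss <- setdiff(need, colnames(cov))
  if (length(miss)) stop("covariate table lacks column(s): ",
                         paste(miss, collapse = ", "))
  ids <- sample_ids(m)
  if (!all(ids %in% rownames(cov)))
    stop("covariate table does not cover all samples of the matrix")
  cov <- cov[ids, , drop = FALSE]
  if (!all(cov$gender %in% c(0, 1)))
    stop("gender must be coded female = 1, male = 0")
  cov
}

#' Read and write the package's TSV formats
#'
#' Plain-text readers/writers for the cohort file set: abundance matrix
#' (columns `sample_id`, `runday`, then one column per metabolite; empty
#' fields are missing values), covariates (`sample_id`, `gender`, `age`,
#' `bmi`; gender coded female = 1, male = 0), annotations (`metabolite_id`,
#' `super_pathway`, `sub_pathway`) and SNP dosages (`sample_id`, then one
#' column per SNP, values in \[0, 2\]). Comma- or tab-delimited files are
#' both accepted.
#'
#' @param path File path.
#' @param delim Field delimiter; `NULL` sniffs tab vs comma from the header.
#' @return `read_metabolite_matrix()` a [metabolite_matrix()];
#'   `read_covariate_table()` / `read_annotation_table()` a data frame;
#'   `read_dosage_matrix()` a numeric matrix with sample row names.
#' @name cohort_io
NULL

.sniff_delim <- function(path) {
  hdr <- readLines(path, n = 1L)
  if (grepl("\t", hdr)) "\t" else ","
}

.read_table <- function(path, delim = NULL) {
  if (is.null(delim)) delim <- .sniff_delim(path)
  utils::read.delim(path, sep = delim, header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, na.strings = c("NA", ""))
}

#' @rdname cohort_io
#' @export
read_metabolite_matrix <- function(path, delim = NULL) {
  tab <- .read_table(path, delim)
  if (!"sample_id" %in% colnames(tab)) stop("first column must be sample_id")
  runday <- if ("runday" %in% colnames(tab)) as.character(tab$runday) else "D1"
  keep <- setdiff(colnames(tab), c("sample_id", "runday"))
  vals <- as.matrix(tab[, keep, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- as.character(tab$sample_id)
  metabolite_matrix(vals, runday)
}

#' @rdname cohort_io
#' @param m A `MetaboliteMatrix` to write.
#' @export
write_metabolite_matrix <- function(m, path) {
  out <- data.frame(sample_id = sample_ids(m), runday = m$runday,
                    m$values, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname cohort_io
#' @export
read_covariate_table <- function(path, delim = NULL) {
  tab <- .read_table(path, delim)
  if (!"sample_id" %in% colnames(tab)) stop("first column must be sample_id")
  rownames(tab) <- as.character(tab$sample_id)
  tab$sample_id <- NULL
  tab
}

#' @rdname cohort_io
#' @export
read_annotation_table <- function(path, delim = NULL) {
  tab <- .read_table(path, delim)
  need <- c("metabolite_id", "super_pathway", "sub_pathway")
  if (!all(need %in% colnames(tab)))
    stop("annotation table needs columns: ", paste(need, collapse = ", "))
  tab
}

#' @rdname cohort_io
#' @export
read_dosage_matrix <- function(path, delim = NULL) {
  tab <- .read_table(path, delim)
  if (!"sample_id" %in% colnames(tab)) stop("first column must be sample_id")
  ids <- as.character(tab$sample_id)
  tab$sample_id <- NULL
  vals <- as.matrix(tab)
  storage.mode(vals) <- "double"
  rownames(vals) <- ids
  if (any(vals < 0 | vals > 2, na.rm = TRUE))
    stop("dosages must lie in [0, 2]")
  vals
}
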