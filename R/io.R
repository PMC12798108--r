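# Tidy CSV readers/writers for the pipeline's external interfaces, plus
# JSON (de)serialisation of simulation ground truth.

#' Read a tidy trait table
#'
#' CSV with header `accession,trait,condition,replicate,value` (UTF-8, `.`
#' decimal), validated on read.
#'
#' @param path CSV file path.
#' @return Validated data.frame.
#' @export
read_trait_table <- function(path) {
  validate_trait_table(read.csv(path, stringsAsFactors = FALSE))
}

#' Read a per-feature statistics table
#'
#' CSV with header `feature,kind,group,log2fc,adj_p` and optional `vip`.
#'
#' @param path CSV file path.
#' @return Data.frame as read (validated at screening time per group).
#' @export
read_feature_stats <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("feature", "log2fc", "adj_p")
  if (!all(need %in% names(d)))
    stop("stats file must have columns: ", paste(need, collapse = ", "))
  d
}

#' Read an abundance matrix (features x samples)
#'
#' CSV whose first column holds feature ids and remaining columns samples.
#'
#' @param path CSV file path.
#' @return Numeric matrix with feature rownames.
#' @export
read_abundance_matrix <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("abundance values must be numeric")
  rownames(m) <- as.character(d[[1]])
  m
}

#' Write an abundance matrix as CSV
#' @param m Features x samples numeric matrix with rownames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_abundance_matrix <- function(m, path) {
  d <- data.frame(feature = rownames(m), m, check.names = FALSE,
                  stringsAsFactors = FALSE)
  write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialise simulation ground truth to JSON
#' @param truth A `ground_truth` object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  x <- unclass(truth)
  if (!is.null(x$tolerance_factor)) # keep accession names as JSON keys
    x$tolerance_factor <- as.list(x$tolerance_factor)
  jsonlite::write_json(x, path, auto_unbox = FALSE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Read simulation ground truth written by [write_ground_truth()]
#' @param path JSON path.
#' @return A `ground_truth` object.
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  gt <- new_ground_truth(
    tolerance_rank = x$tolerance_rank,
    tolerance_factor = if (!is.null(x$tolerance_factor))
      unlist(x$tolerance_factor),
    true_de_features = x$true_de_features,
    linked_pairs = if (!is.null(x$linked_pairs))
      as.data.frame(x$linked_pairs, stringsAsFactors = FALSE))
  gt
}
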