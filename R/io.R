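# Tab-separated I/O shared across modules. The summary-statistics format
# (one header line, 1-based positions) is common to the exposure side
# (consortium downloads) and the outcome side (association-scan output):
#   variant_id chr pos effect_allele other_allele eaf beta se pvalue n trait

SUMMARY_COLS <- c("variant_id", "chr", "pos", "effect_allele",
                  "other_allele", "eaf", "beta", "se", "pvalue", "n",
                  "trait")

#' Read a summary-statistics file
#'
#' @param path tab-separated file with the documented header.
#' @return Validated data.frame. Malformed rows (non-numeric fields,
#'   non-positive SEs, frequencies outside (0,1), duplicated variant ids
#'   within a trait) are rejected with the offending line numbers.
#' @export
read_summary_stats <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(SUMMARY_COLS, names(d))
  if (length(miss) > 0L)
    stop("missing required column(s) in ", path, ": ",
         paste(miss, collapse = ", "))
  lineno <- function(i) paste(i + 1L, collapse = ", ")  # header is line 1
  for (col in c("pos", "eaf", "beta", "se", "pvalue", "n")) {
    v <- suppressWarnings(as.numeric(d[[col]]))
    bad <- which(is.na(v) & !is.na(d[[col]]))
    if (length(bad) > 0L)
      stop("non-numeric ", col, " at line(s) ", lineno(bad), " of ", path)
    d[[col]] <- v
  }
  bad <- which(d$se <= 0)
  if (length(bad) > 0L)
    stop("non-positive se at line(s) ", lineno(bad), " of ", path)
  bad <- which(d$eaf <= 0 | d$eaf >= 1)
  if (length(bad) > 0L)
    stop("eaf outside (0,1) at line(s) ", lineno(bad), " of ", path)
  bad <- which(d$effect_allele == d$other_allele)
  if (length(bad) > 0L)
    stop("identical effect/other alleles at line(s) ", lineno(bad),
         " of ", path)
  dup <- which(duplicated(d[, c("variant_id", "trait")]))
  if (length(dup) > 0L)
    stop("duplicated variant id within trait at line(s) ", lineno(dup),
         " of ", path)
  d[, SUMMARY_COLS]
}

#' Write a summary-statistics file
#'
#' @param stats summary-statistics data.frame (extra columns are dropped).
#' @param path output path.
#' @export
write_summary_stats <- function(stats, path) {
  miss <- setdiff(SUMMARY_COLS, names(stats))
  if (length(miss) > 0L)
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  write.table(stats[, SUMMARY_COLS], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a signed LD correlation matrix
#'
#' Square tab-separated numeric file with a variant-id header row and
#' first column. Asymmetric entries, a non-unit diagonal or mismatched
#' row/column ids are rejected.
#'
#' @param path input path.
#' @return Numeric matrix with variant-id dimnames.
#' @export
read_ld_matrix <- function(path) {
  d <- read.delim(path, row.names = 1L, check.names = FALSE)
  m <- as.matrix(d)
  if (nrow(m) != ncol(m)) stop("LD matrix is not square: ", path)
  if (!identical(rownames(m), colnames(m)))
    stop("LD matrix row/column ids differ: ", path)
  if (!is.numeric(m)) stop("non-numeric entries in LD matrix: ", path)
  if (max(abs(m - t(m))) > 1e-8)
    stop("asymmetric LD matrix entry in ", path)
  if (max(abs(diag(m) - 1)) > 1e-8)
    stop("LD matrix diagonal must be 1 in ", path)
  m
}

#' Write a signed LD correlation matrix
#' @param mat square matrix with variant-id dimnames.
#' @param path output path.
#' @export
write_ld_matrix <- function(mat, path) {
  stopifnot(nrow(mat) == ncol(mat), !is.null(rownames(mat)))
  d <- data.frame(variant_id = rownames(mat), mat, check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write an estimates table
#'
#' Tab-separated table as produced by [estimates_table()].
#'
#' @param path file path.
#' @export
read_estimates <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("method", "exposure", "outcome", "n_variants", "beta", "se",
            "lcl", "ucl", "or", "or_lcl", "or_ucl", "p")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0L)
    stop("missing required column(s) in ", path, ": ",
         paste(miss, collapse = ", "))
  d
}

#' @rdname read_estimates
#' @param estimates data.frame from [estimates_table()].
#' @export
write_estimates <- function(estimates, path) {
  write.table(estimates, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a reproducibility manifest
#'
#' Plain hierarchical key/value text (`key<TAB>value`, nested names joined
#' with dots) recording seeds, thresholds and package version for a run.
#'
#' @param info named list (flat or one level of nesting).
#' @param path output path.
#' @export
write_manifest <- function(info, path) {
  flat <- list()
  for (nm in names(info)) {
    v <- info[[nm]]
    if (is.list(v)) {
      for (nm2 in names(v)) flat[[paste(nm, nm2, sep = ".")]] <- v[[nm2]]
    } else flat[[nm]] <- v
  }
  lines <- vapply(names(flat), function(k)
    paste(k, paste(format(flat[[k]], trim = TRUE), collapse = ","),
          sep = "\t"), character(1L))
  writeLines(lines, path)
  invisible(path)
}
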