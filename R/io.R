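#' Read a long-format abundance table
#'
#' Reads a TSV/CSV file with header columns \code{subject}, \code{time},
#' \code{feature}, \code{value} (case-insensitive, any order) into a
#' \code{\link{longitudinal_table}}.
#'
#' @param path file path.
#' @param dialect \code{"tsv"} (default) or \code{"csv"}.
#' @return a \code{longitudinal_table}.
#' @export
read_long_table <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (dialect == "tsv") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          comment.char = "#", quote = "",
                          colClasses = "character",
                          check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  required <- c("subject", "time", "feature", "value")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("input is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df$time <- suppressWarnings(as.numeric(df$time))
  df$value <- suppressWarnings(as.numeric(df$value))
  if (anyNA(df$time)) stop("non-numeric entry in 'time' column", call. = FALSE)
  if (anyNA(df$value)) stop("non-numeric entry in 'value' column", call. = FALSE)
  longitudinal_table(df[required])
}

#' Write a long-format abundance table
#'
#' @param table a \code{longitudinal_table}.
#' @param path output file path (TSV).
#' @export
write_long_table <- function(table, path) {
  stopifnot(inherits(table, "longitudinal_table"))
  out <- as.data.frame(table)
  out$time <- sprintf("%.12g", out$time)
  out$value <- sprintf("%.12g", out$value)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a wide sample-by-feature table plus sample metadata
#'
#' The wide matrix has sample IDs as rows and feature IDs as columns;
#' the metadata file maps each sample ID to a subject, a sampling time and
#' (optionally) a group label. Each matrix cell becomes one observation.
#'
#' @param matrix_path TSV with rows = sample IDs, columns = feature IDs.
#' @param metadata_path TSV with header \code{sample subject time group}
#'   (group optional).
#' @return a \code{longitudinal_table} with group labels attached when the
#'   metadata provides them.
#' @export
read_wide_table <- function(matrix_path, metadata_path) {
  if (!file.exists(matrix_path)) stop("file not found: ", matrix_path, call. = FALSE)
  if (!file.exists(metadata_path)) stop("file not found: ", metadata_path, call. = FALSE)
  mat <- utils::read.table(matrix_path, header = TRUE, sep = "\t",
                           row.names = 1L, check.names = FALSE,
                           comment.char = "#", quote = "")
  meta <- read_metadata(metadata_path)
  missing_samples <- setdiff(rownames(mat), meta$sample)
  if (length(missing_samples) > 0L) {
    stop("sample(s) in matrix absent from metadata: ",
         paste(missing_samples, collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(mat)
  if (!is.numeric(m)) stop("non-numeric cell in abundance matrix", call. = FALSE)
  idx <- match(rownames(m), meta$sample)
  obs <- data.frame(
    subject = rep(meta$subject[idx], times = ncol(m)),
    time    = rep(meta$time[idx], times = ncol(m)),
    feature = rep(colnames(m), each = nrow(m)),
    value   = as.vector(m),
    stringsAsFactors = FALSE
  )
  groups <- NULL
  if (!is.null(meta$group)) {
    groups <- meta$group[idx]
    names(groups) <- meta$subject[idx]
    groups <- groups[!duplicated(names(groups))]
  }
  longitudinal_table(obs, groups = groups)
}

#' Write a longitudinal table as a wide sample-by-feature matrix
#'
#' Inverse of \code{\link{read_wide_table}}: each (subject, time) pair
#' becomes one sample row named \code{subject.time}; missing
#' (sample, feature) combinations are written as 0.
#'
#' @param table a \code{longitudinal_table}.
#' @param matrix_path output TSV path for the matrix.
#' @param metadata_path output TSV path for the sample metadata.
#' @export
write_wide_table <- function(table, matrix_path, metadata_path) {
  stopifnot(inherits(table, "longitudinal_table"))
  sample_id <- paste(table$subject, sprintf("%.12g", table$time), sep = ".")
  samples <- unique(sample_id)
  features <- unique(table$feature)
  m <- matrix(0, nrow = length(samples), ncol = length(features),
              dimnames = list(samples, features))
  m[cbind(match(sample_id, samples), match(table$feature, features))] <-
    table$value
  out <- data.frame(sample = rownames(m),
                    apply(m, 2L, function(col) sprintf("%.12g", col)),
                    check.names = FALSE)
  utils::write.table(out, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  first <- !duplicated(sample_id)
  meta <- data.frame(sample = sample_id[first],
                     subject = table$subject[first],
                     time = sprintf("%.12g", table$time[first]),
                     stringsAsFactors = FALSE)
  groups <- subject_groups(table)
  if (!is.null(groups)) meta$group <- groups[meta$subject]
  utils::write.table(meta, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(matrix_path)
}

read_metadata <- function(path) {
  meta <- utils::read.table(path, header = TRUE, sep = "\t",
                            comment.char = "#", quote = "",
                            colClasses = "character",
                            check.names = FALSE, stringsAsFactors = FALSE)
  names(meta) <- tolower(names(meta))
  required <- c("sample", "subject", "time")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols) > 0L) {
    stop("metadata is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  meta$time <- suppressWarnings(as.numeric(meta$time))
  if (anyNA(meta$time)) stop("non-numeric entry in metadata 'time'", call. = FALSE)
  meta
}

#' Total sum scaling normalization
#'
#' Divides every value by the total of its (subject, time) sample, turning
#' counts into relative abundances that sum to 1 within each sample.
#'
#' @param table a \code{longitudinal_table} of counts.
#' @return a \code{longitudinal_table} of relative abundances.
#' @export
tss_normalize <- function(table) {
  stopifnot(inherits(table, "longitudinal_table"))
  sample_key <- paste(table$subject, table$time, sep = "\r")
  totals <- tapply(table$value, sample_key, sum)
  if (any(totals <= 0)) {
    bad <- names(totals)[which(totals <= 0)[1L]]
    parts <- strsplit(bad, "\r", fixed = TRUE)[[1L]]
    stop(sprintf("all-zero sample (subject %s, time %s): cannot normalize",
                 parts[1L], parts[2L]), call. = FALSE)
  }
  obs <- as.data.frame(table)
  obs$value <- obs$value / as.numeric(totals[sample_key])
  rebuild_table(table, obs)
}

#' Remove features with low total counts
#'
#' Drops every feature whose count summed over all observations is below
#' \code{min_total}.
#'
#' @param table a \code{longitudinal_table} of counts.
#' @param min_total minimum total count to keep a feature (default 5).
#' @export
filter_low_count_features <- function(table, min_total = 5) {
  stopifnot(inherits(table, "longitudinal_table"))
  totals <- tapply(table$value, table$feature, sum)
  keep <- names(totals)[totals >= min_total]
  obs <- as.data.frame(table)[table$feature %in% keep, , drop = FALSE]
  rebuild_table(table, obs)
}

#' Prevalence/abundance filter for relative-abundance tables
#'
#' Removes a feature when its relative abundance is below \code{min_rel}
#' in strictly more than \code{max_frac} of samples, where a sample is a
#' (subject, time) pair. A feature absent from a sample counts as abundance
#' 0 in that sample.
#'
#' @param table a \code{longitudinal_table} of relative abundances in [0, 1].
#' @param min_rel abundance threshold (default 1e-4, i.e. 0.01\%).
#' @param max_frac sample-fraction threshold (default 0.9).
#' @export
filter_low_abundance_features <- function(table, min_rel = 1e-4,
                                          max_frac = 0.9) {
  stopifnot(inherits(table, "longitudinal_table"))
  if (any(table$value > 1)) {
    stop("values exceed 1: this filter expects relative abundances; ",
         "apply tss_normalize() first", call. = FALSE)
  }
  sample_key <- paste(table$subject, table$time, sep = "\r")
  n_samples <- length(unique(sample_key))
  # per feature, number of samples with abundance >= min_rel; samples where
  # the feature is unrecorded have abundance 0 and so fall below min_rel
  above <- table$value >= min_rel
  n_above <- tapply(above, table$feature, sum)
  frac_below <- 1 - as.numeric(n_above) / n_samples
  keep <- names(n_above)[frac_below <= max_frac]
  obs <- as.data.frame(table)[table$feature %in% keep, , drop = FALSE]
  rebuild_table(table, obs)
}

#' Drop subjects with too few distinct time points
#'
#' Trajectory smoothing needs at least three observations per subject, so
#' subjects sampled at fewer than \code{min_k} distinct times are removed.
#' The IDs of dropped subjects are attached to the result as attribute
#' \code{dropped_subjects}.
#'
#' @param table a \code{longitudinal_table}.
#' @param min_k minimum number of distinct sampling times (default 3).
#' @export
require_min_timepoints <- function(table, min_k = 3) {
  stopifnot(inherits(table, "longitudinal_table"))
  n_times <- tapply(table$time, table$subject,
                    function(t) length(unique(t)))
  dropped <- names(n_times)[n_times < min_k]
  obs <- as.data.frame(table)[!(table$subject %in% dropped), , drop = FALSE]
  if (nrow(obs) == 0L) {
    stop("no subjects left after requiring ", min_k, " time points",
         call. = FALSE)
  }
  rebuild_table(table, obs, dropped_subjects = dropped)
}

#' Write / read a subject distance matrix
#'
#' The on-disk format is a square TSV with subject IDs as both the header
#' row and the first column. \code{read_distance_matrix} validates symmetry
#' (within 1e-9), a zero diagonal and nonnegative entries.
#'
#' @param D a symmetric numeric matrix with zero diagonal and subject IDs
#'   as dimnames.
#' @param path file path.
#' @export
write_distance_matrix <- function(D, path) {
  D <- as.matrix(D)
  stopifnot(nrow(D) == ncol(D))
  validate_distance_matrix(D)
  ids <- rownames(D)
  if (is.null(ids)) ids <- paste0("S", seq_len(nrow(D)))
  out <- data.frame(subject = ids,
                    apply(D, 2L, function(col) sprintf("%.17g", col)),
                    check.names = FALSE)
  names(out) <- c("subject", ids)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1L,
                          comment.char = "#", quote = "",
                          check.names = FALSE)
  D <- as.matrix(df)
  if (!is.numeric(D)) stop("non-numeric entry in distance matrix", call. = FALSE)
  if (nrow(D) != ncol(D)) stop("distance matrix is not square", call. = FALSE)
  colnames(D) <- rownames(D)
  validate_distance_matrix(D)
  D
}

validate_distance_matrix <- function(D, tol = 1e-9) {
  if (any(!is.finite(D))) stop("non-finite entry in distance matrix", call. = FALSE)
  if (any(D < 0)) {
    idx <- which(D < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative distance at (%d, %d)", idx[1L], idx[2L]),
         call. = FALSE)
  }
  asym <- abs(D - t(D))
  if (max(asym) > tol) {
    idx <- which(asym == max(asym), arr.ind = TRUE)[1L, ]
    stop(sprintf("asymmetric distance matrix: D[%d,%d] != D[%d,%d]",
                 idx[1L], idx[2L], idx[2L], idx[1L]), call. = FALSE)
  }
  if (any(abs(diag(D)) > tol)) {
    stop("distance matrix diagonal is not zero", call. = FALSE)
  }
  invisible(TRUE)
}
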