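#' Longitudinal abundance table
#'
#' The central data container: a long-format table of observations
#' (subject, feature, time, value) over a common time domain \code{[0, T]},
#' optionally carrying a group label per subject. Values are abundances
#' (counts or relative abundances); a recorded 0 is an observation, a
#' missing time point is simply absent.
#'
#' @param observations data.frame with columns \code{subject}, \code{time},
#'   \code{feature}, \code{value}.
#' @param domain_end upper end \code{T} of the time domain; defaults to the
#'   maximum observed time.
#' @param groups optional named character vector mapping subject IDs to
#'   group labels.
#' @return An object of class \code{longitudinal_table}: a data.frame with
#'   attributes \code{domain_end} and \code{groups}.
#' @examples
#' obs <- data.frame(subject = "S1", time = c(0, 1, 2),
#'                   feature = "F1", value = c(5, 6, 4))
#' lt <- longitudinal_table(obs)
#' domain_end(lt)
#' @export
longitudinal_table <- function(observations, domain_end = NULL, groups = NULL) {
  required <- c("subject", "time", "feature", "value")
  missing_cols <- setdiff(required, names(observations))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  obs <- data.frame(
    subject = as.character(observations$subject),
    time    = as.numeric(observations$time),
    feature = as.character(observations$feature),
    value   = as.numeric(observations$value),
    stringsAsFactors = FALSE
  )
  if (anyNA(obs$time) || any(!is.finite(obs$time))) {
    stop("non-finite time value in table", call. = FALSE)
  }
  if (anyNA(obs$value) || any(!is.finite(obs$value))) {
    stop("non-finite (NA/NaN/Inf) abundance value in table", call. = FALSE)
  }
  if (any(obs$value < 0)) {
    bad <- which(obs$value < 0)[1L]
    stop(sprintf("negative abundance value %g at (%s, %s, t=%g)",
                 obs$value[bad], obs$subject[bad], obs$feature[bad],
                 obs$time[bad]), call. = FALSE)
  }
  if (any(obs$time < 0)) {
    stop("times must be >= 0", call. = FALSE)
  }
  key <- paste(obs$subject, obs$feature, obs$time, sep = "\r")
  if (anyDuplicated(key)) {
    first <- obs[which(duplicated(key))[1L], ]
    stop(sprintf("duplicate (subject, feature, time) key: (%s, %s, t=%g)",
                 first$subject, first$feature, first$time), call. = FALSE)
  }
  if (is.null(domain_end)) {
    domain_end <- max(obs$time)
    if (domain_end <= 0) domain_end <- 1  # single-time tables need T > 0
  }
  if (!is.numeric(domain_end) || length(domain_end) != 1L || domain_end <= 0) {
    stop("domain_end must be a single positive number", call. = FALSE)
  }
  if (any(obs$time > domain_end)) {
    stop("observed time exceeds domain_end", call. = FALSE)
  }
  if (!is.null(groups)) {
    groups <- vapply(groups, as.character, character(1L))
    extra <- setdiff(unique(obs$subject), names(groups))
    if (length(extra) > 0L) {
      stop("groups missing label for subject(s): ",
           paste(extra, collapse = ", "), call. = FALSE)
    }
  }
  structure(obs,
            domain_end = domain_end,
            groups = groups,
            class = c("longitudinal_table", "data.frame"))
}

#' @rdname longitudinal_table
#' @param x a \code{longitudinal_table}.
#' @export
domain_end <- function(x) attr(x, "domain_end")

#' @rdname longitudinal_table
#' @export
subject_groups <- function(x) attr(x, "groups")

#' @export
print.longitudinal_table <- function(x, ...) {
  cat(sprintf("Longitudinal table: %d observations, %d subjects, %d features, domain [0, %g]\n",
              nrow(x), length(unique(x$subject)), length(unique(x$feature)),
              domain_end(x)))
  if (!is.null(subject_groups(x))) {
    tab <- table(subject_groups(x)[unique(x$subject)])
    cat("Groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  dropped <- attr(x, "dropped_subjects")
  if (!is.null(dropped) && length(dropped) > 0L) {
    cat("Dropped subjects (too few time points):",
        paste(dropped, collapse = ", "), "\n")
  }
  invisible(x)
}

# Rebuild a longitudinal_table from a filtered subset, preserving domain and
# restricting the group map to surviving subjects.
rebuild_table <- function(template, obs, dropped_subjects = NULL) {
  groups <- subject_groups(template)
  if (!is.null(groups)) {
    groups <- groups[names(groups) %in% unique(obs$subject)]
    if (length(groups) == 0L) groups <- NULL
  }
  out <- longitudinal_table(obs, domain_end = domain_end(template),
                            groups = groups)
  if (!is.null(dropped_subjects)) {
    attr(out, "dropped_subjects") <- dropped_subjects
  }
  out
}
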