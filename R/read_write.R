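#' Read study summary statistics from a delimited text file
#'
#' Reads a wide-format CSV in which each row is one study: `study_id`, `n`,
#' one column per moderator, the lower-triangle covariance columns
#' `cov_<i>_<j>` (with `i >= j`, in [vech()] order), and the mean columns
#' `mean_<i>`. Variable indices refer to positions `1..p`. Missing (`NA`)
#' covariance/mean cells mark variables the study did not report. An optional
#' JSON sidecar (same path with extension `.json`) may declare `variables`
#' and `moderators`; without it, `p` is inferred from the `mean_` columns and
#' every remaining column is treated as a moderator.
#'
#' @param path Path to the CSV file.
#' @param sidecar Optional path to the JSON sidecar; defaults to `path` with
#'   a `.json` extension when that file exists.
#' @param fail_fast Stop on the first flagged record.
#' @param quiet Suppress the read-count message.
#' @return A list of [study_record()] objects. Flagged records are kept (with
#'   `valid = FALSE`) so callers can decide how to handle them.
#' @export
read_studies <- function(path, sidecar = NULL, fail_fast = FALSE,
                         quiet = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (is.null(sidecar)) {
    cand <- sub("\\.[^.]+$", ".json", path)
    if (file.exists(cand)) sidecar <- cand
  }
  meta <- if (!is.null(sidecar)) jsonlite::fromJSON(sidecar) else NULL

  if (!all(c("study_id", "n") %in% names(df))) {
    stop("header must declare `study_id` and `n` columns", call. = FALSE)
  }
  mean_cols <- grep("^mean_[0-9]+$", names(df), value = TRUE)
  p <- length(mean_cols)
  if (!is.null(meta$variables)) p <- length(meta$variables)
  if (p < 1) stop("no `mean_<i>` columns found and no sidecar declares ",
                  "`variables`", call. = FALSE)
  lt <- which(lower.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  cov_cols <- paste0("cov_", lt[, 1], "_", lt[, 2])
  mean_cols <- paste0("mean_", seq_len(p))
  missing_cols <- setdiff(c(cov_cols, mean_cols), names(df))
  if (length(missing_cols)) {
    stop("missing columns for p = ", p, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  mod_cols <- setdiff(names(df), c("study_id", "n", cov_cols, mean_cols))
  if (!is.null(meta$moderators)) {
    unknown <- setdiff(meta$moderators, names(df))
    if (length(unknown)) {
      stop("sidecar declares unknown moderator columns: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    mod_cols <- meta$moderators
  }

  studies <- vector("list", nrow(df))
  for (r in seq_len(nrow(df))) {
    if (is.na(df$n[r])) stop("study ", df$study_id[r], " has missing `n`",
                             call. = FALSE)
    S <- unvech(as.numeric(df[r, cov_cols]))
    ybar <- as.numeric(df[r, mean_cols])
    mods <- as.numeric(df[r, mod_cols])
    names(mods) <- mod_cols
    studies[[r]] <- study_record(df$study_id[r], df$n[r], S, ybar, mods)
  }
  diag_df <- validate_studies(studies, fail_fast = fail_fast)
  if (!quiet) {
    message("read ", length(studies), " studies (", sum(!diag_df$valid),
            " flagged)")
  }
  studies
}

#' Write study records to a delimited text file
#'
#' Inverse of [read_studies()]: writes the wide-format CSV (and, optionally,
#' a JSON sidecar naming variables and moderators).
#'
#' @param studies List of [study_record()] objects.
#' @param path Output CSV path.
#' @param sidecar Write a JSON sidecar next to the CSV.
#' @return `path`, invisibly.
#' @export
write_studies <- function(studies, path, sidecar = FALSE) {
  validate_studies(studies)
  p <- nrow(studies[[1]]$S)
  lt <- which(lower.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  mod_names <- names(studies[[1]]$moderators)
  rows <- lapply(studies, function(s) {
    S <- s$S
    S[!s$observed_mask, ] <- NA
    S[, !s$observed_mask] <- NA
    ybar <- ifelse(s$observed_mask, s$ybar, NA_real_)
    out <- c(list(study_id = s$study_id, n = s$n),
             as.list(s$moderators[mod_names]),
             as.list(S[lower.tri(S, diag = TRUE)]),
             as.list(ybar))
    names(out) <- c("study_id", "n", mod_names,
                    paste0("cov_", lt[, 1], "_", lt[, 2]),
                    paste0("mean_", seq_len(p)))
    as.data.frame(out, check.names = FALSE)
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE)
  if (sidecar) {
    jsonlite::write_json(
      list(variables = paste0("y", seq_len(p)), moderators = mod_names),
      sub("\\.[^.]+$", ".json", path)
    )
  }
  invisible(path)
}

#' Summarize a validated dataset
#'
#' @param studies List of [study_record()] objects.
#' @return A data frame with one row per study: id, n, number of observed
#'   variables, moderator values, and the validity flag.
#' @export
summarize_studies <- function(studies) {
  diag_df <- validate_studies(studies)
  mods <- do.call(rbind, lapply(studies, function(s) {
    as.data.frame(as.list(s$moderators))
  }))
  out <- data.frame(
    study_id = diag_df$study_id,
    n = vapply(studies, `[[`, 0, "n"),
    p_observed = vapply(studies, function(s) sum(s$observed_mask), 0L),
    valid = diag_df$valid
  )
  if (!is.null(mods) && ncol(mods)) out <- cbind(out, mods)
  out
}
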