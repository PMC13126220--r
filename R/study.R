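#' Create a study record of summary statistics
#'
#' One record holds everything the meta-analysis needs from a primary study:
#' the within-study sample size, the sample covariance matrix (denominator
#' `n - 1`), the sample means, the study-level moderator values, and a mask of
#' which variables the study actually reports. No raw participant data are
#' required.
#'
#' The covariance matrix is checked for symmetry and for positive
#' semidefiniteness on the observed submatrix. A record that fails the PSD
#' check (or whose observed submatrix is numerically singular) is *flagged*
#' rather than repaired: fitting functions refuse flagged records, because a
#' singular sample covariance has no valid normal-theory sampling covariance.
#'
#' @param study_id Character label for the study.
#' @param n Within-study sample size (>= 2).
#' @param S `p` by `p` sample covariance matrix. Rows/columns of unobserved
#'   variables may be `NA`.
#' @param ybar Length-`p` vector of sample means (`NA` where unobserved).
#' @param moderators Named numeric vector of study-level moderator values
#'   (dummies coded 0/1, or continuous).
#' @param observed_mask Logical length-`p` vector marking reported variables.
#'   Defaults to non-`NA` entries of `ybar`.
#' @return An object of class `masem_study`. The logical attribute element
#'   `valid` is `FALSE` for flagged records, with the reason in `flag_reason`.
#' @export
study_record <- function(study_id, n, S, ybar, moderators = numeric(0),
                         observed_mask = NULL) {
  stopifnot(is.matrix(S), nrow(S) == ncol(S))
  p <- nrow(S)
  if (length(ybar) != p) {
    stop("`ybar` must have length ", p, " (the order of `S`)", call. = FALSE)
  }
  if (length(n) != 1 || is.na(n) || n < 2) {
    stop("`n` must be a single count >= 2", call. = FALSE)
  }
  if (is.null(observed_mask)) observed_mask <- !is.na(ybar)
  stopifnot(is.logical(observed_mask), length(observed_mask) == p)
  if (length(moderators) && is.null(names(moderators))) {
    stop("`moderators` must be a named vector", call. = FALSE)
  }
  moderators <- unlist(moderators)

  valid <- TRUE
  flag_reason <- NA_character_
  obs <- which(observed_mask)
  if (!length(obs)) {
    valid <- FALSE
    flag_reason <- "no observed variables"
  } else {
    So <- S[obs, obs, drop = FALSE]
    if (anyNA(So) || anyNA(ybar[obs])) {
      valid <- FALSE
      flag_reason <- "NA inside the observed submatrix"
    } else if (max(abs(So - t(So))) > 1e-6 * max(1, max(abs(So)))) {
      valid <- FALSE
      flag_reason <- "covariance matrix not symmetric"
    } else {
      So <- (So + t(So)) / 2
      ev <- eigen(So, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) < -1e-8 * max(abs(ev), 1)) {
        valid <- FALSE
        flag_reason <- "covariance matrix not positive semidefinite"
      } else if (min(ev) < 1e-10 * max(abs(ev), 1)) {
        valid <- FALSE
        flag_reason <- "covariance matrix numerically singular"
      }
      S[obs, obs] <- So
    }
  }

  structure(
    list(study_id = as.character(study_id), n = as.numeric(n), S = S,
         ybar = as.numeric(ybar), moderators = moderators,
         observed_mask = observed_mask, valid = valid,
         flag_reason = flag_reason),
    class = "masem_study"
  )
}

#' @export
print.masem_study <- function(x, ...) {
  cat("<masem_study> ", x$study_id, ": n = ", x$n, ", p = ", nrow(x$S),
      " (", sum(x$observed_mask), " observed)",
      if (!x$valid) paste0(" [FLAGGED: ", x$flag_reason, "]"), "\n", sep = "")
  invisible(x)
}

#' Stack a study's summary statistics into an effect-size vector
#'
#' Returns the study's observed effect sizes `y_i = c(vech(S), ybar)` together
#' with the index map and a `present` indicator derived from the observed
#' mask: a covariance element is present only when both of its variables are
#' reported.
#'
#' @param study A [study_record()].
#' @return A list with `values`, `present`, and `index_map`.
#' @export
study_effect_vector <- function(study) {
  stopifnot(inherits(study, "masem_study"))
  p <- nrow(study$S)
  map <- effect_index_map(p)
  S <- study$S
  S[is.na(S)] <- 0
  values <- c(S[lower.tri(S, diag = TRUE)],
              ifelse(is.na(study$ybar), 0, study$ybar))
  present <- ifelse(map$type == "cov",
                    study$observed_mask[map$i] & study$observed_mask[map$j],
                    study$observed_mask[map$i])
  list(values = values, present = present, index_map = map)
}

#' Normal-theory sampling covariance of a study's effect sizes
#'
#' Computes the within-study sampling covariance matrix `V_i` of the stacked
#' effect-size vector `c(vech(S), ybar)`, treated as known in the
#' meta-analysis. Under multivariate normality with population covariance
#' `Sigma` (plugged in by the study's own `S`):
#' `Cov(s_ij, s_kl) = (s_ik s_jl + s_il s_jk) / (n - 1)` for the unbiased
#' sample covariances, `Cov(ybar) = S / n` for the means, and the cross-block
#' is exactly zero because third central moments of the normal vanish.
#'
#' @param S Sample covariance matrix of the study (denominator `n - 1`).
#' @param n Within-study sample size (>= 2).
#' @param observed_mask Optional logical mask; rows/columns of effect sizes
#'   that involve an unobserved variable are returned as `NA`.
#' @return A square matrix of order `p*(p+1)/2 + p` with attribute `blocks`
#'   giving the index ranges of the covariance and mean blocks.
#' @export
sampling_covariance <- function(S, n, observed_mask = NULL) {
  stopifnot(is.matrix(S), nrow(S) == ncol(S))
  if (n < 2) stop("`n` must be >= 2", call. = FALSE)
  p <- nrow(S)
  ns <- p * (p + 1L) / 2L
  if (is.null(observed_mask)) observed_mask <- rep(TRUE, p)
  obs <- which(observed_mask)
  if (length(obs)) {
    So <- S[obs, obs, drop = FALSE]
    ev <- eigen((So + t(So)) / 2, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 1e-10 * max(abs(ev), 1)) {
      warning("covariance matrix is singular on the observed submatrix; ",
              "the study should be flagged for exclusion", call. = FALSE)
    }
  }
  lt <- which(lower.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  ii <- lt[, 1]
  jj <- lt[, 2]
  Sz <- S
  Sz[is.na(Sz)] <- 0
  cov_block <- (Sz[ii, ii, drop = FALSE] * Sz[jj, jj, drop = FALSE] +
                Sz[ii, jj, drop = FALSE] * Sz[jj, ii, drop = FALSE]) / (n - 1)
  V <- matrix(0, ns + p, ns + p)
  V[seq_len(ns), seq_len(ns)] <- cov_block
  V[ns + seq_len(p), ns + seq_len(p)] <- Sz / n
  if (!all(observed_mask)) {
    pres <- c(observed_mask[ii] & observed_mask[jj], observed_mask)
    V[!pres, ] <- NA_real_
    V[, !pres] <- NA_real_
  }
  attr(V, "blocks") <- list(cov = seq_len(ns), mean = ns + seq_len(p))
  V
}

#' Validate a list of study records
#'
#' Checks that all records share the same number of variables and the same
#' moderator names, and reports how many records are flagged.
#'
#' @param studies A list of [study_record()] objects.
#' @param fail_fast Stop at the first flagged record instead of collecting
#'   diagnostics.
#' @return Invisibly, a data frame of per-study diagnostics.
#' @export
validate_studies <- function(studies, fail_fast = FALSE) {
  stopifnot(length(studies) > 0,
            all(vapply(studies, inherits, TRUE, "masem_study")))
  p <- nrow(studies[[1]]$S)
  mods <- sort(names(studies[[1]]$moderators))
  diag_df <- data.frame(
    study_id = vapply(studies, `[[`, "", "study_id"),
    valid = vapply(studies, `[[`, TRUE, "valid"),
    reason = vapply(studies, `[[`, "", "flag_reason"),
    stringsAsFactors = FALSE
  )
  for (s in studies) {
    if (nrow(s$S) != p) {
      stop("study ", s$study_id, " has p = ", nrow(s$S),
           " but the first study has p = ", p, call. = FALSE)
    }
    if (!identical(sort(names(s$moderators)), mods)) {
      stop("study ", s$study_id, " has moderator names [",
           paste(names(s$moderators), collapse = ", "),
           "] that differ from the first study's [",
           paste(mods, collapse = ", "), "]", call. = FALSE)
    }
    if (fail_fast && !s$valid) {
      stop("study ", s$study_id, " is flagged: ", s$flag_reason, call. = FALSE)
    }
  }
  invisible(diag_df)
}
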