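#' Likelihood-ratio (chi-square difference) test of nested fits
#'
#' `delta_chi2 = (-2 log L restricted) - (-2 log L general)`, referred to a
#' chi-square with the difference in free-parameter counts. Both models must
#' be fitted to the same data (same studies, same heterogeneity structure),
#' so the heterogeneity parameters cancel from the difference in df when they
#' are shared; the df difference is computed from the free-parameter counts.
#' A negative difference beyond tolerance signals non-convergence of one of
#' the fits and is reported as an error.
#'
#' @param restricted,general Nested `masem_fit` objects (restricted has
#'   fewer free parameters).
#' @param tol Tolerance for a negative chi-square difference.
#' @return List with `delta_chi2`, `delta_df`, `p_value`.
#' @export
masem_lrt <- function(restricted, general, tol = 1e-6) {
  stopifnot(inherits(restricted, "masem_fit"), inherits(general, "masem_fit"))
  if (restricted$k != general$k || restricted$N_total != general$N_total) {
    stop("fits are not on identical data (k or N differ)", call. = FALSE)
  }
  delta <- restricted$m2ll - general$m2ll
  ddf <- general$n_free - restricted$n_free
  if (ddf < 0) stop("`restricted` has more free parameters than `general`",
                    call. = FALSE)
  if (delta < -tol * max(1, abs(general$m2ll))) {
    stop("negative chi-square difference (", format(delta),
         "); a fit likely did not reach its optimum", call. = FALSE)
  }
  delta <- max(delta, 0)
  p <- if (ddf == 0) {
    if (delta <= tol * max(1, abs(general$m2ll))) 1 else 0
  } else {
    stats::pchisq(delta, ddf, lower.tail = FALSE)
  }
  list(delta_chi2 = delta, delta_df = ddf, p_value = p)
}

#' @export
anova.masem_fit <- function(object, ...) {
  fits <- c(list(object), list(...))
  stopifnot(length(fits) >= 2)
  ord <- order(vapply(fits, `[[`, 0, "n_free"))
  fits <- fits[ord]
  out <- data.frame(n_free = vapply(fits, `[[`, 0, "n_free"),
                    m2ll = vapply(fits, `[[`, 0, "m2ll"),
                    delta_chi2 = NA_real_, delta_df = NA_real_,
                    p_value = NA_real_)
  for (i in seq_along(fits)[-length(fits)]) {
    lr <- masem_lrt(fits[[i]], fits[[i + 1]])
    out$delta_chi2[i] <- lr$delta_chi2
    out$delta_df[i] <- lr$delta_df
    out$p_value[i] <- lr$p_value
  }
  out
}

#' Information criteria of a fitted model
#'
#' `AIC = -2 log L + 2 * n_free` and `BIC = -2 log L + n_free * log(N)`,
#' where `n_free` counts every estimated parameter including the
#' heterogeneity parameters, and `N` is the summed within-study sample size.
#' The likelihood constant is included consistently, so differences between
#' fits on the same data are invariant to it.
#'
#' @param fit A converged `masem_fit`.
#' @return Named vector with `AIC` and `BIC`.
#' @export
information_criteria <- function(fit) {
  stopifnot(inherits(fit, "masem_fit"))
  c(AIC = fit$m2ll + 2 * fit$n_free,
    BIC = fit$m2ll + fit$n_free * log(fit$N_total))
}

#' Chi-square statistic and fit indices against a saturated baseline
#'
#' The overall chi-square of a CFA fit is the difference in `-2 log L`
#' between the factor model and the saturated means-and-covariances model
#' with the *matching* moderation status (unmoderated CFA vs unmoderated
#' saturated; moderated invariance models vs the moderated saturated model).
#'
#' @param fit A CFA `masem_fit`.
#' @param saturated The matching saturated `masem_fit`.
#' @return List with `chisq`, `df`, `p_value`, `rmsea`, `AIC`, `BIC`.
#' @export
model_fit <- function(fit, saturated) {
  stopifnot(inherits(fit, "masem_fit"), inherits(saturated, "masem_fit"))
  if (!inherits(saturated$spec, "saturated_spec")) {
    stop("`saturated` must be a saturated-model fit", call. = FALSE)
  }
  lr <- masem_lrt(fit, saturated)
  ic <- information_criteria(fit)
  list(chisq = lr$delta_chi2, df = fit$df,
       p_value = stats::pchisq(lr$delta_chi2, fit$df, lower.tail = FALSE),
       rmsea = rmsea(lr$delta_chi2, fit$df, fit$N_total),
       AIC = unname(ic["AIC"]), BIC = unname(ic["BIC"]))
}

#' Root mean square error of approximation
#'
#' `RMSEA = sqrt(max(chisq - df, 0) / (df * (N - 1)))` with `N` the summed
#' within-study sample size. Other conventions exist in the MASEM literature
#' (total N vs N - 1); this one is used throughout the package and flagged
#' here so results can be compared across software.
#'
#' @param chisq Chi-square statistic versus the saturated model.
#' @param df Residual degrees of freedom (> 0).
#' @param N_total Summed within-study sample size.
#' @return The RMSEA; `NA` with a warning when `df = 0` (undefined).
#' @export
rmsea <- function(chisq, df, N_total) {
  if (df == 0) {
    warning("RMSEA is undefined for df = 0", call. = FALSE)
    return(NA_real_)
  }
  sqrt(max(chisq - df, 0) / (df * (N_total - 1)))
}

#' Wald test of a single parameter
#'
#' @param fit A `masem_fit` with standard errors.
#' @param parameter Parameter name (see [theta_names()]).
#' @return List with `estimate`, `se`, `z`, `p_value` (two-sided).
#' @export
wald_test <- function(fit, parameter) {
  est <- c(fit$coefficients, fit$het_par)
  if (!parameter %in% names(est)) {
    stop("unknown parameter: ", parameter, call. = FALSE)
  }
  se <- fit$se[parameter]
  if (is.na(se)) stop("no standard error available for ", parameter,
                      call. = FALSE)
  z <- unname(est[parameter] / se)
  list(estimate = unname(est[parameter]), se = unname(se), z = z,
       p_value = 2 * stats::pnorm(-abs(z)))
}

#' Standardized latent mean difference
#'
#' Divides a raw latent mean difference by the pooled standard deviation of
#' the common factor across the two groups. The default pooling is
#' unweighted: `sqrt((phi_ref + phi_other) / 2)`.
#'
#' @param mean_diff Raw factor-mean difference.
#' @param phi_ref Factor variance in the reference group.
#' @param phi_other Factor variance in the other group.
#' @return The standardized mean difference.
#' @export
smd <- function(mean_diff, phi_ref, phi_other) {
  if (phi_ref <= 0 || phi_other <= 0) {
    stop("factor variances must be positive", call. = FALSE)
  }
  mean_diff / sqrt((phi_ref + phi_other) / 2)
}

#' Search for a partial-invariance model
#'
#' When full weak (or strong) invariance is rejected, practice is to free
#' the offending parameters one at a time: fit every candidate model with a
#' single loading (under `"weak"`) or intercept (under `"strong"`) exempted
#' from the equality constraint, compare each against the less restrictive
#' reference model by the chi-square difference test, and keep the candidate
#' with the best fit (lowest `-2 log L`; ties, which can only arise at equal
#' parameter counts, are broken by lower AIC). The function codifies that
#' search.
#'
#' @param spec The unmoderated reference [cfa_spec()].
#' @param studies List of [study_record()]s.
#' @param level `"weak"` (free one loading; reference: configural) or
#'   `"strong"` (free one intercept; reference: the partial-weak model).
#' @param group_dummy Moderator name.
#' @param keep_free Exemptions already granted (e.g. the loading freed by a
#'   previous weak-level search) that every candidate retains.
#' @param reference Optional fitted reference model; fitted if omitted
#'   (configural for `"weak"`; the partial-weak model implied by
#'   `keep_free` for `"strong"`).
#' @param het,v_plugin,control Passed to [masem()].
#' @return List with `best` (name of the freed parameter), `fit` (its
#'   fitted model), `reference` (the reference fit), and `table` (one row
#'   per candidate with `-2 log L`, the chi-square difference against the
#'   reference, its df and p-value, and AIC).
#' @export
partial_invariance_search <- function(spec, studies,
                                      level = c("weak", "strong"),
                                      group_dummy, keep_free = character(0),
                                      reference = NULL, het = het_spec(),
                                      v_plugin = "pooled", control = list()) {
  level <- match.arg(level)
  stopifnot(inherits(spec, "cfa_spec"))
  tab <- param_table(spec)
  candidates <- if (level == "weak") {
    setdiff(tab$name[grepl("^lambda", tab$name) & tab$free], keep_free)
  } else {
    setdiff(tab$name[grepl("^tau", tab$name) & tab$free], keep_free)
  }
  if (!length(candidates)) stop("no candidate parameters to free",
                                call. = FALSE)
  if (is.null(reference)) {
    ref_spec <- if (level == "weak") {
      build_invariance_model(spec, "configural", group_dummy)
    } else {
      build_invariance_model(spec, "weak", group_dummy,
                             partial_free = keep_free)
    }
    reference <- masem(ref_spec, studies, het = het, se = FALSE,
                       v_plugin = v_plugin, control = control)
  }
  rows <- lapply(candidates, function(cand) {
    cand_spec <- build_invariance_model(spec, level, group_dummy,
                                        partial_free = c(keep_free, cand))
    fit <- masem(cand_spec, studies, het = het, se = FALSE,
                 v_plugin = v_plugin, control = control,
                 start = c(reference$coefficients, reference$het_par))
    lr <- if (fit$converged && reference$converged) {
      masem_lrt(fit, reference)
    } else {
      list(delta_chi2 = NA_real_, delta_df = NA_integer_,
           p_value = NA_real_)
    }
    list(fit = fit,
         row = data.frame(freed = cand, converged = fit$converged,
                          m2ll = fit$m2ll, delta_chi2 = lr$delta_chi2,
                          delta_df = lr$delta_df, p_value = lr$p_value,
                          AIC = information_criteria(fit)[["AIC"]],
                          stringsAsFactors = FALSE))
  })
  table <- do.call(rbind, lapply(rows, `[[`, "row"))
  ok <- which(table$converged)
  if (!length(ok)) stop("no candidate model converged", call. = FALSE)
  best_i <- ok[order(table$m2ll[ok], table$AIC[ok])][1]
  list(best = table$freed[best_i], fit = rows[[best_i]]$fit,
       reference = reference, table = table)
}
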