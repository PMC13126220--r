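#' Between-study heterogeneity structure
#'
#' Describes the structure of the between-studies covariance matrix `T2` of
#' the random effects. Following standard MASEM practice, the block for the
#' covariance effect sizes is diagonal (between-study covariances fixed at
#' zero, variances estimated on a log-SD scale), while the block for the
#' means may be fully symmetric (parameterized by its Cholesky factor, which
#' guarantees positive semidefiniteness without explicit constraints). The
#' cross-block between covariance and mean effect sizes is fixed at zero.
#'
#' @param tau2_s Structure for the covariance-effect block: `"diagonal"` or
#'   `"zero"`.
#' @param tau2_m Structure for the mean-effect block: `"symmetric"` (full,
#'   Cholesky-parameterized), `"exchangeable"` (compound symmetry: one
#'   variance and one common correlation, mapped onto the interval that
#'   keeps the block positive definite), `"diagonal"`, or `"zero"`. The
#'   exchangeable structure is the workhorse for designs with few studies:
#'   it captures the correlation among mean effects with two parameters
#'   instead of `p(p+1)/2`, which keeps likelihood-ratio tests near their
#'   nominal level (see the package vignette).
#' @return An object of class `het_spec`.
#' @export
het_spec <- function(tau2_s = c("diagonal", "zero"),
                     tau2_m = c("symmetric", "exchangeable", "diagonal",
                                "zero")) {
  structure(list(tau2_s = match.arg(tau2_s), tau2_m = match.arg(tau2_m)),
            class = "het_spec")
}

het_codes <- function(het) {
  list(s = switch(het$tau2_s, zero = 0L, diagonal = 1L),
       m = switch(het$tau2_m, zero = 0L, diagonal = 1L, symmetric = 2L,
                  exchangeable = 3L))
}

het_par_names <- function(het, p) {
  ns <- p * (p + 1) / 2
  lt_p <- which(lower.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  nm <- character(0)
  if (het$tau2_s == "diagonal") {
    lt <- which(lower.tri(diag(p), diag = TRUE), arr.ind = TRUE)
    nm <- c(nm, paste0("lnsd_s[", lt[, 1], ",", lt[, 2], "]"))
  }
  if (het$tau2_m == "diagonal") {
    nm <- c(nm, paste0("lnsd_m[", seq_len(p), "]"))
  } else if (het$tau2_m == "symmetric") {
    nm <- c(nm, paste0("chol_m[", lt_p[, 1], ",", lt_p[, 2], "]"))
  } else if (het$tau2_m == "exchangeable") {
    nm <- c(nm, "lnsd_m", "rho_m")
  }
  nm
}

n_het_par <- function(het, p) length(het_par_names(het, p))

# rebuild the T2 matrix (and its blocks) from heterogeneity parameters
het_estimates <- function(het, p, hp) {
  ns <- p * (p + 1) / 2
  tau2_s <- rep(0, ns)
  T2_m <- matrix(0, p, p)
  pos <- 0
  if (het$tau2_s == "diagonal") {
    tau2_s <- exp(2 * hp[pos + seq_len(ns)])
    pos <- pos + ns
  }
  if (het$tau2_m == "diagonal") {
    diag(T2_m) <- exp(2 * hp[pos + seq_len(p)])
  } else if (het$tau2_m == "symmetric") {
    L <- matrix(0, p, p)
    L[lower.tri(L, diag = TRUE)] <- hp[pos + seq_len(p * (p + 1) / 2)]
    T2_m <- L %*% t(L)
  } else if (het$tau2_m == "exchangeable") {
    v <- exp(2 * hp[pos + 1])
    lo <- -1 / (p - 1)
    rho <- lo + (1 - lo) * stats::plogis(hp[pos + 2])
    T2_m <- matrix(v * rho, p, p)
    diag(T2_m) <- v
  }
  list(tau2_s = tau2_s, T2_m = T2_m)
}

# ---- data preparation -----------------------------------------------------

# Assemble the data object consumed by the C++ likelihood.
build_fit_data <- function(spec, studies, het, v_plugin = "pooled") {
  validate_studies(studies)
  ok <- vapply(studies, `[[`, TRUE, "valid")
  if (any(!ok)) {
    warning(sum(!ok), " flagged study record(s) excluded from the fit",
            call. = FALSE)
    studies <- studies[ok]
  }
  if (!length(studies)) stop("no valid studies", call. = FALSE)
  p <- if (inherits(spec, "cfa_spec")) spec$p else spec$p
  if (nrow(studies[[1]]$S) != p) {
    stop("studies have p = ", nrow(studies[[1]]$S),
         " variables but the spec declares p = ", p, call. = FALSE)
  }
  k <- length(studies)
  nm <- n_effects(p)
  is_cfa <- inherits(spec, "cfa_spec")

  y <- matrix(0, nm, k)
  V <- array(0, c(nm, nm, k))
  pres <- vector("list", k)
  layout <- if (is_cfa) theta_layout(spec) else NULL
  mods <- spec_moderators(spec)

  # pooled plug-in for the sampling covariances: elementwise
  # (n_i - 1)-weighted average of the observed sample covariances
  S_pool <- NULL
  if (v_plugin == "pooled") {
    num <- matrix(0, p, p)
    den <- matrix(0, p, p)
    for (s in studies) {
      ob <- s$observed_mask
      wt <- (s$n - 1) * tcrossprod(ob)
      Si <- s$S
      Si[!ob, ] <- 0
      Si[, !ob] <- 0
      num <- num + wt * Si
      den <- den + wt
    }
    S_pool <- num / pmax(den, 1)
  }

  # studies sharing a moderator profile share the same design matrix
  xmat <- matrix(0, k, length(mods))
  for (i in seq_len(k)) {
    s <- studies[[i]]
    ev <- study_effect_vector(s)
    y[, i] <- ev$values
    Vi <- sampling_covariance(if (v_plugin == "pooled") S_pool else s$S,
                              s$n, s$observed_mask)
    Vi[is.na(Vi)] <- 0
    V[, , i] <- Vi
    pres[[i]] <- as.integer(which(ev$present) - 1L)
    xi <- s$moderators[mods]
    if (length(mods) && anyNA(xi)) {
      stop("study ", s$study_id, " is missing moderator value(s): ",
           paste(mods[is.na(xi)], collapse = ", "), call. = FALSE)
    }
    if (length(mods)) xmat[i, ] <- xi
  }
  profile_key <- apply(xmat, 1, paste, collapse = "\r")
  profiles <- !duplicated(profile_key)
  grp <- match(profile_key, profile_key[profiles])
  A <- lapply(which(profiles), function(i) {
    xi <- xmat[i, ]
    names(xi) <- mods
    if (is_cfa) {
      design_for_study(layout, xi)
    } else {
      do.call(cbind, c(list(diag(nm)),
                       lapply(seq_along(mods),
                              function(j) xi[j] * diag(nm))))
    }
  })
  ntm <- if (is_cfa) layout$n_base + layout$n_slope else nm * (1 + length(mods))
  codes <- het_codes(het)
  dat <- list(y = y, V = V, pres = pres, A = A, grp = as.integer(grp - 1L),
              cvec = if (is_cfa) design_const(layout) else numeric(nm),
              type = if (is_cfa) 1L else 0L,
              p = as.integer(p),
              q = if (is_cfa) as.integer(spec$q) else 0L,
              ntm = as.integer(ntm),
              het_s = codes$s, het_m = codes$m)
  list(dat = dat, ptr = cpp_make_data(dat), studies = studies, k = k,
       N_total = sum(vapply(studies, `[[`, 0, "n")),
       par_names = c(theta_names(spec), het_par_names(het, p)))
}

# Moment-based starting values for the heterogeneity parameters: the
# between-study spread of each effect size in excess of the average sampling
# variance, floored at a small fraction of the spread.
het_start <- function(het, dat) {
  p <- dat$p
  ns <- p * (p + 1) / 2
  nm <- ns + p
  k <- ncol(dat$y)
  pres_mat <- matrix(FALSE, nm, k)
  for (i in seq_len(k)) pres_mat[dat$pres[[i]] + 1L, i] <- TRUE
  yv <- dat$y
  yv[!pres_mat] <- NA
  s2 <- apply(yv, 1, stats::var, na.rm = TRUE)
  s2[is.na(s2) | s2 <= 0] <- 0.1
  vbar <- sapply(seq_len(nm), function(j) {
    vals <- dat$V[j, j, pres_mat[j, ]]
    if (length(vals)) mean(vals) else 0
  })
  tau2 <- pmax(s2 - vbar, 0.05 * s2, 1e-5)
  hp <- numeric(0)
  if (het$tau2_s == "diagonal") hp <- c(hp, 0.5 * log(tau2[seq_len(ns)]))
  if (het$tau2_m == "diagonal") {
    hp <- c(hp, 0.5 * log(tau2[ns + seq_len(p)]))
  } else if (het$tau2_m == "exchangeable") {
    hp <- c(hp, 0.5 * log(mean(tau2[ns + seq_len(p)])), 0)
  } else if (het$tau2_m == "symmetric") {
    # moment estimate of the full mean-block matrix, floored to PD
    ybm <- t(yv[ns + seq_len(p), , drop = FALSE])
    Tm <- if (k > p + 1 && !anyNA(ybm)) {
      stats::cov(ybm) - apply(dat$V[ns + seq_len(p), ns + seq_len(p), ,
                                    drop = FALSE], c(1, 2), mean)
    } else {
      diag(tau2[ns + seq_len(p)], p)
    }
    ed <- eigen((Tm + t(Tm)) / 2, symmetric = TRUE)
    ev <- pmax(ed$values, 0.05 * max(abs(ed$values), 1e-4))
    Tm <- ed$vectors %*% (ev * t(ed$vectors))
    L <- t(chol(Tm))
    hp <- c(hp, L[lower.tri(L, diag = TRUE)])
  }
  hp
}

# ---- fitting --------------------------------------------------------------

#' Fit a one-stage meta-analytic CFA with means
#'
#' Maximizes the marginal likelihood of the study-level effect sizes
#' `y_i = c(vech(S_i), ybar_i)` under
#' `y_i ~ N(m(theta, x_i), T2 + V_i)`, where `m` stacks the model-implied
#' covariances and means of the CFA (with moderated parameters resolved at
#' the study's moderator values `x_i`), `T2` is the between-studies
#' covariance of the random effects, and `V_i` the study's known sampling
#' covariance. Estimation uses a quasi-Newton optimizer with analytic
#' gradients; standard errors come from the inverse observed information
#' (numerical differentiation of the analytic gradient) at the optimum.
#'
#' @param spec A [cfa_spec()] (possibly moderated / an invariance model).
#' @param studies List of [study_record()]s.
#' @param het A [het_spec()].
#' @param start Optional named vector of starting values; missing entries are
#'   filled with defaults (see [start_values()]), so estimates of a simpler
#'   model can warm-start a richer one.
#' @param se Compute standard errors (skipped in bulk simulation for speed).
#' @param v_plugin Covariance matrix plugged into the normal-theory formula
#'   for `V_i`: `"pooled"` (default) uses the precision-weighted pooled
#'   sample covariance for every study, `"study"` uses each study's own `S`.
#'   Using the study's own `S` makes the weights correlate with the observed
#'   effect sizes, which noticeably shrinks pooled covariances (and biases
#'   latent mean differences upward) at moderate within-study `n`; the
#'   pooled plug-in removes that artifact while keeping `V_i` "known".
#' @param fix_het Optional vector of heterogeneity-parameter values (in
#'   [het_spec()] order, e.g. a previous fit's `het_par`) at which the
#'   between-study covariance is held fixed while only the mean structure is
#'   optimized. Sharing the saturated baseline's heterogeneity across an
#'   invariance ladder keeps chi-square-difference tests close to their
#'   nominal level at realistic study counts, where re-estimating a rich
#'   `T2` in every model makes them anticonservative. The heterogeneity
#'   parameters still count as estimated in `n_free` (they are maximum
#'   likelihood estimates carried over from the baseline), so information
#'   criteria remain comparable across fits.
#' @param n_restarts Extra jittered restarts attempted on non-convergence.
#' @param control Passed to [stats::nlminb()] (defaults: `rel.tol 1e-10`,
#'   `iter.max 500`).
#' @return An object of class `masem_fit`: estimates, standard errors,
#'   `-2 log L`, free-parameter count, residual df, heterogeneity estimates,
#'   convergence status, `k`, and total N.
#' @export
masem <- function(spec, studies, het = het_spec(), start = NULL, se = TRUE,
                  v_plugin = c("pooled", "study"), fix_het = NULL,
                  n_restarts = 1, control = list()) {
  stopifnot(inherits(spec, "cfa_spec"))
  check_identified(spec)
  fd <- build_fit_data(spec, studies, het, match.arg(v_plugin))
  st0 <- c(start_values(spec, fd$studies), het_start(het, fd$dat))
  names(st0) <- fd$par_names
  if (!is.null(start)) {
    keep <- intersect(names(start), names(st0))
    st0[keep] <- start[keep]
  }
  ntm <- fd$dat$ntm
  n_par <- length(st0)
  if (!is.null(fix_het)) {
    nh <- n_par - ntm
    if (length(fix_het) != nh) {
      stop("`fix_het` must supply all ", nh, " heterogeneity parameters",
           call. = FALSE)
    }
    st0[ntm + seq_len(nh)] <- fix_het
  }
  lower <- rep(-Inf, n_par)
  upper <- rep(Inf, n_par)
  is_lnsd <- grepl("^lnsd", names(st0))
  lower[is_lnsd] <- -8
  upper[is_lnsd] <- 5
  is_rho <- names(st0) == "rho_m"
  lower[is_rho] <- -8
  upper[is_rho] <- 8
  if (!is.null(fix_het)) {
    # heterogeneity held at the supplied values (typically the saturated
    # baseline's estimates); only the mean structure is optimized
    lower[ntm + seq_len(n_par - ntm)] <- st0[ntm + seq_len(n_par - ntm)]
    upper[ntm + seq_len(n_par - ntm)] <- st0[ntm + seq_len(n_par - ntm)]
  }

  opt <- run_nlminb(st0, fd$ptr, lower, upper, control, n_restarts)
  par <- opt$par
  names(par) <- fd$par_names

  vcov_mat <- NULL
  se_vec <- rep(NA_real_, n_par)
  free_idx <- if (is.null(fix_het)) seq_len(n_par) else seq_len(ntm)
  if (se && opt$converged) {
    H <- numeric_hessian(function(x) {
      full <- par
      full[free_idx] <- x
      cpp_masem_eval(full, fd$ptr, TRUE)$grad[free_idx]
    }, par[free_idx])
    vcov_mat <- try(solve(H), silent = TRUE)
    if (!inherits(vcov_mat, "try-error") &&
        all(is.finite(diag(vcov_mat))) && all(diag(vcov_mat) > 0)) {
      dimnames(vcov_mat) <- list(fd$par_names[free_idx],
                                 fd$par_names[free_idx])
      se_vec[free_idx] <- sqrt(diag(vcov_mat))
    } else {
      vcov_mat <- NULL
      warning("observed information not positive definite; no standard errors",
              call. = FALSE)
    }
  }
  names(se_vec) <- fd$par_names

  hp <- par[seq_len(n_par - ntm) + ntm]
  new_masem_fit(
    spec = spec, het = het,
    coefficients = par[seq_len(ntm)], het_par = hp,
    het_estimates = het_estimates(het, fd$dat$p, hp),
    at_bound = names(hp)[is_lnsd[-seq_len(ntm)] & hp <= -8 + 1e-6],
    se = se_vec, vcov = vcov_mat,
    m2ll = 2 * opt$objective, n_free = n_par,
    df = count_df(spec), converged = opt$converged,
    k = fd$k, N_total = fd$N_total, optim = opt$info,
    het_fixed = !is.null(fix_het)
  )
}

#' Fit the saturated means-and-covariances model
#'
#' The baseline model in which every pooled effect size is free (optionally
#' regressed on the moderators). For fixed heterogeneity parameters the mean
#' structure is linear, so it is profiled out in closed form (GLS) and the
#' optimizer only searches the heterogeneity parameters. An unmoderated
#' saturated fit is exactly the multivariate random-effects meta-analysis of
#' the covariances and means: its pooled means equal the meta-analytic
#' pooled effect sizes.
#'
#' @param studies List of [study_record()]s.
#' @param moderators Character vector of moderator names (possibly empty).
#' @param het A [het_spec()].
#' @param se Compute standard errors for the mean-structure parameters.
#' @param v_plugin Plug-in for the sampling covariances, as in [masem()].
#' @param n_restarts Extra jittered restarts on non-convergence.
#' @param control Passed to [stats::nlminb()].
#' @return A `masem_fit` with `df = 0`.
#' @export
masem_saturated <- function(studies, moderators = character(0),
                            het = het_spec(), se = FALSE,
                            v_plugin = c("pooled", "study"), n_restarts = 1,
                            control = list()) {
  p <- nrow(studies[[1]]$S)
  spec <- saturated_spec(p, moderators,
                         var_names = paste0("y", seq_len(p)))
  fd <- build_fit_data(spec, studies, het, match.arg(v_plugin))
  hp0 <- het_start(het, fd$dat)
  ntm <- fd$dat$ntm
  nh <- length(hp0)
  ctrl <- utils::modifyList(list(rel.tol = 1e-10, iter.max = 500,
                                 eval.max = 1000), control)

  if (nh == 0) {
    prof <- cpp_sat_profile(numeric(0), fd$ptr, FALSE)
    opt <- list(par = numeric(0), objective = prof$nll,
                converged = isTRUE(prof$ok), info = list(fixed_het = TRUE))
  } else {
    lower <- rep(-Inf, nh)
    upper <- rep(Inf, nh)
    is_lnsd <- grepl("^lnsd", het_par_names(het, p))
    lower[is_lnsd] <- -8
    upper[is_lnsd] <- 5
    obj <- function(hp) cpp_sat_profile(hp, fd$ptr, FALSE)$nll
    gr <- function(hp) cpp_sat_profile(hp, fd$ptr, TRUE)$grad
    o <- stats::nlminb(hp0, obj, gr, lower = lower, upper = upper,
                       control = ctrl)
    conv <- o$convergence == 0 && is.finite(o$objective)
    if (!conv && n_restarts > 0) {
      for (r in seq_len(n_restarts)) {
        o2 <- stats::nlminb(hp0 + stats::rnorm(nh, 0, 0.1), obj, gr,
                            lower = lower, upper = upper, control = ctrl)
        if (o2$convergence == 0 && is.finite(o2$objective) &&
            o2$objective <= o$objective + 1e-6) {
          o <- o2
          conv <- TRUE
          break
        }
      }
    }
    opt <- list(par = o$par, objective = o$objective, converged = conv,
                info = list(convergence = o$convergence, message = o$message,
                            iterations = o$iterations))
  }
  prof <- cpp_sat_profile(opt$par, fd$ptr, FALSE)
  theta <- as.vector(prof$theta)
  names(theta) <- theta_names(spec)
  hp <- opt$par
  names(hp) <- het_par_names(het, p)

  se_vec <- rep(NA_real_, ntm + nh)
  names(se_vec) <- fd$par_names
  vcov_mat <- NULL
  if (se && opt$converged) {
    full <- c(theta, hp)
    H <- numeric_hessian(function(x) cpp_masem_eval(x, fd$ptr, TRUE)$grad,
                         full)
    vcov_mat <- try(solve(H), silent = TRUE)
    if (!inherits(vcov_mat, "try-error") && all(diag(vcov_mat) > 0)) {
      dimnames(vcov_mat) <- list(fd$par_names, fd$par_names)
      se_vec <- sqrt(diag(vcov_mat))
    } else {
      vcov_mat <- NULL
    }
  }

  new_masem_fit(
    spec = spec, het = het,
    coefficients = theta, het_par = hp,
    het_estimates = het_estimates(het, p, hp),
    at_bound = names(hp)[grepl("^lnsd", names(hp)) & hp <= -8 + 1e-6],
    se = se_vec, vcov = vcov_mat,
    m2ll = 2 * prof$nll, n_free = ntm + nh,
    df = 0L, converged = opt$converged,
    k = fd$k, N_total = fd$N_total, optim = opt$info
  )
}

run_nlminb <- function(st, dat, lower, upper, control, n_restarts) {
  ctrl <- utils::modifyList(list(rel.tol = 1e-10, iter.max = 500,
                                 eval.max = 1000), control)
  last <- new.env(parent = emptyenv())
  evaluate <- function(par) {
    if (!identical(last$par, par)) {
      last$res <- cpp_masem_eval(par, dat, TRUE)
      last$par <- par
    }
    last$res
  }
  obj <- function(par) evaluate(par)$nll
  gr <- function(par) evaluate(par)$grad
  o <- stats::nlminb(st, obj, gr, lower = lower, upper = upper, control = ctrl)
  conv <- o$convergence == 0 && is.finite(o$objective)
  tried <- 1
  while (!conv && n_restarts > 0) {
    n_restarts <- n_restarts - 1
    tried <- tried + 1
    jitter <- stats::rnorm(length(st), 0, 0.1)
    o2 <- stats::nlminb(st + jitter, obj, gr, lower = lower, upper = upper,
                        control = ctrl)
    if (o2$convergence == 0 && is.finite(o2$objective)) {
      o <- o2
      conv <- TRUE
    } else if (is.finite(o2$objective) && o2$objective < o$objective) {
      o <- o2
    }
  }
  list(par = o$par, objective = o$objective, converged = conv,
       info = list(convergence = o$convergence, message = o$message,
                   iterations = o$iterations, starts_tried = tried))
}

# central-difference Hessian of a gradient function (observed information
# when applied to the gradient of the negative log-likelihood)
numeric_hessian <- function(grad_fn, par, h = 1e-5) {
  n <- length(par)
  H <- matrix(0, n, n)
  for (j in seq_len(n)) {
    hj <- h * max(1, abs(par[j]))
    up <- par
    up[j] <- up[j] + hj
    dn <- par
    dn[j] <- dn[j] - hj
    H[, j] <- (grad_fn(up) - grad_fn(dn)) / (2 * hj)
  }
  (H + t(H)) / 2
}

#' Marginal log-likelihood at a given parameter vector
#'
#' Evaluates the one-stage MASEM-with-means log-likelihood (sum over studies
#' of the multivariate-normal log-density of the observed effect sizes) at an
#' arbitrary parameter vector, without optimizing. Exposed mainly for
#' verification and diagnostics.
#'
#' @param spec A [cfa_spec()] or [saturated_spec()].
#' @param studies List of [study_record()]s.
#' @param par Full parameter vector: mean-structure parameters in
#'   [theta_names()] order followed by heterogeneity parameters (log-SDs,
#'   then Cholesky entries; see [het_spec()]).
#' @param het A [het_spec()].
#' @param v_plugin Plug-in for the sampling covariances, as in [masem()].
#' @return The scalar log-likelihood.
#' @export
masem_loglik <- function(spec, studies, par, het = het_spec(),
                         v_plugin = c("pooled", "study")) {
  fd <- build_fit_data(spec, studies, het, match.arg(v_plugin))
  if (length(par) != length(fd$par_names)) {
    stop("`par` must have length ", length(fd$par_names), call. = FALSE)
  }
  -cpp_masem_eval(as.numeric(par), fd$ptr, FALSE)$nll
}

new_masem_fit <- function(...) {
  structure(list(...), class = "masem_fit")
}

#' @export
print.masem_fit <- function(x, ...) {
  cat("<masem_fit> ",
      if (inherits(x$spec, "saturated_spec")) "saturated model" else
        "CFA model", "\n", sep = "")
  inv <- attr(x$spec, "invariance")
  if (!is.null(inv)) cat("  invariance level:", inv$level, "\n")
  cat("  k =", x$k, "studies, total N =", x$N_total, "\n")
  cat("  -2 log L =", format(x$m2ll, digits = 10), " free parameters:",
      x$n_free, " df:", x$df, "\n")
  cat("  converged:", x$converged,
      if (length(x$at_bound)) {
        paste0("(heterogeneity at bound: ",
               paste(x$at_bound, collapse = ", "), ")")
      }, "\n")
  invisible(x)
}

#' @export
coef.masem_fit <- function(object, ...) object$coefficients

#' @export
vcov.masem_fit <- function(object, ...) object$vcov

#' @export
logLik.masem_fit <- function(object, ...) {
  structure(-object$m2ll / 2, df = object$n_free, nobs = object$N_total,
            class = "logLik")
}

#' Parameter table of a fitted model
#'
#' @param object A `masem_fit`.
#' @param ... Unused.
#' @return Data frame with estimate, SE, z, and two-sided p per parameter.
#' @export
summary.masem_fit <- function(object, ...) {
  est <- c(object$coefficients, object$het_par)
  se <- object$se
  z <- est / se
  data.frame(parameter = names(est), estimate = unname(est),
             se = unname(se), z = unname(z),
             p = unname(2 * stats::pnorm(-abs(z))),
             stringsAsFactors = FALSE)
}
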