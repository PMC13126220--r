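#' Specify a confirmatory factor model with a mean structure
#'
#' Defines the structure of a CFA for `p` observed variables and `q` common
#' factors: the factor-loading matrix Lambda, the factor (co)variance matrix
#' Phi, the diagonal residual-variance matrix Psi, the measurement intercepts
#' tau, and the factor means kappa. In every pattern argument `NA` marks a
#' *free* parameter and a number fixes the entry at that value.
#'
#' The default identification follows the convention of fixing factor
#' variances at 1 and factor means at 0, so the common factors are standard
#' normal in the reference configuration; a fixed-marker alternative can be
#' requested by fixing a loading (and an intercept) instead. Residual
#' variances may be fixed at 0 to accommodate single-indicator factors.
#'
#' @param loadings `p` by `q` pattern matrix for Lambda (`NA` = free).
#' @param phi `q` by `q` symmetric pattern for Phi. Default: variances fixed
#'   at 1, covariances free.
#' @param psi Length-`p` pattern for the residual variances (default: free).
#' @param tau Length-`p` pattern for the intercepts (default: free).
#' @param kappa Length-`q` pattern for the factor means (default: fixed 0).
#' @param var_names,factor_names Optional display names.
#' @return An object of class `cfa_spec`.
#' @seealso [moderate()], [build_invariance_model()], [implied_moments()],
#'   [count_df()]
#' @export
#' @examples
#' # one factor, five indicators, standard-normal factor
#' spec <- cfa_spec(loadings = matrix(NA, 5, 1))
cfa_spec <- function(loadings, phi = NULL, psi = NULL, tau = NULL,
                     kappa = NULL, var_names = NULL, factor_names = NULL) {
  loadings <- as.matrix(loadings)
  p <- nrow(loadings)
  q <- ncol(loadings)
  if (is.null(phi)) {
    phi <- matrix(NA_real_, q, q)
    diag(phi) <- 1
  }
  phi <- as.matrix(phi)
  stopifnot(nrow(phi) == q, ncol(phi) == q)
  # symmetric pattern required; values compared only where both fixed
  fixed_phi <- !is.na(phi)
  if (any(fixed_phi != t(fixed_phi)) ||
      any(phi[fixed_phi] != t(phi)[fixed_phi & t(fixed_phi)])) {
    stop("`phi` pattern must be symmetric", call. = FALSE)
  }
  if (is.null(psi)) psi <- rep(NA_real_, p)
  if (is.null(tau)) tau <- rep(NA_real_, p)
  if (is.null(kappa)) kappa <- rep(0, q)
  stopifnot(length(psi) == p, length(tau) == p, length(kappa) == q)
  if (is.null(var_names)) var_names <- paste0("y", seq_len(p))
  if (is.null(factor_names)) factor_names <- paste0("f", seq_len(q))

  block <- function(x) list(free = is.na(x), value = ifelse(is.na(x), 0, x))
  spec <- structure(
    list(p = p, q = q,
         lambda = block(loadings), phi = block(phi), psi = block(psi),
         tau = block(tau), kappa = block(kappa),
         moderation = data.frame(par = character(0), moderator = character(0),
                                 stringsAsFactors = FALSE),
         var_names = var_names, factor_names = factor_names),
    class = "cfa_spec"
  )
  spec
}

# ---- internal bookkeeping -------------------------------------------------

# Table of all model-matrix entries in the canonical packing order used by
# the likelihood code: vec(Lambda) column-major, vech(Phi), diag(Psi), tau,
# kappa. One row per entry with its canonical name and free/fixed status.
param_table <- function(spec) {
  p <- spec$p
  q <- spec$q
  lam <- expand.grid(i = seq_len(p), j = seq_len(q))
  lt <- which(lower.tri(diag(q), diag = TRUE), arr.ind = TRUE)
  phi_lower <- cbind(spec$phi$free[lt], spec$phi$value[lt])
  tab <- data.frame(
    name = c(paste0("lambda[", lam$i, ",", lam$j, "]"),
             paste0("phi[", lt[, 1], ",", lt[, 2], "]"),
             paste0("psi[", seq_len(p), "]"),
             paste0("tau[", seq_len(p), "]"),
             paste0("kappa[", seq_len(q), "]")),
    free = c(as.vector(spec$lambda$free), phi_lower[, 1] > 0,
             spec$psi$free, spec$tau$free, spec$kappa$free),
    value = c(as.vector(spec$lambda$value), phi_lower[, 2],
              spec$psi$value, spec$tau$value, spec$kappa$value),
    stringsAsFactors = FALSE
  )
  tab$vidx <- seq_len(nrow(tab))
  tab
}

# Free-parameter layout: baselines (free entries in packing order) followed
# by moderator slopes (in moderation-map order).
theta_layout <- function(spec) {
  tab <- param_table(spec)
  base <- tab[tab$free, , drop = FALSE]
  base_tidx <- integer(nrow(tab))
  base_tidx[base$vidx] <- seq_len(nrow(base))
  nmod <- nrow(spec$moderation)
  slope_vidx <- integer(nmod)
  slope_names <- character(nmod)
  if (nmod) {
    for (r in seq_len(nmod)) {
      vi <- match(spec$moderation$par[r], tab$name)
      if (is.na(vi)) {
        stop("unknown parameter in moderation map: ", spec$moderation$par[r],
             call. = FALSE)
      }
      slope_vidx[r] <- vi
      slope_names[r] <- paste0(spec$moderation$par[r], "@",
                               spec$moderation$moderator[r])
    }
  }
  list(tab = tab,
       names = c(base$name, slope_names),
       n_base = nrow(base), n_slope = nmod,
       base_vidx = base$vidx, base_tidx = base_tidx,
       slope_vidx = slope_vidx,
       slope_mod = spec$moderation$moderator)
}

#' Names of the free parameters of a model specification
#'
#' Baseline parameters are named `matrix[row,col]`; moderator slopes are
#' named `matrix[row,col]@moderator`.
#'
#' @param spec A [cfa_spec()] or [saturated_spec()].
#' @return Character vector in the internal parameter order.
#' @export
theta_names <- function(spec) UseMethod("theta_names")

#' @export
theta_names.cfa_spec <- function(spec) theta_layout(spec)$names

n_free_mean <- function(spec) length(theta_names(spec))

#' Moderators referenced by a model specification
#' @param spec A model specification.
#' @return Character vector of moderator names (may be empty).
#' @export
spec_moderators <- function(spec) UseMethod("spec_moderators")

#' @export
spec_moderators.cfa_spec <- function(spec) unique(spec$moderation$moderator)

# A_i and c of the affine map from theta to the packed matrix entries of
# study i: v_i = A_i %*% theta + c. A_i depends on the study only through its
# moderator values (each moderated entry is baseline + slope * x).
design_for_study <- function(layout, x) {
  tab <- layout$tab
  nt <- layout$n_base + layout$n_slope
  A <- matrix(0, nrow(tab), nt)
  if (layout$n_base) {
    A[cbind(layout$base_vidx, seq_len(layout$n_base))] <- 1
  }
  if (layout$n_slope) {
    xm <- x[layout$slope_mod]
    if (anyNA(xm)) {
      stop("missing moderator value for: ",
           paste(unique(layout$slope_mod[is.na(xm)]), collapse = ", "),
           call. = FALSE)
    }
    A[cbind(layout$slope_vidx, layout$n_base + seq_len(layout$n_slope))] <- xm
  }
  A
}

design_const <- function(layout) {
  ifelse(layout$tab$free, 0, layout$tab$value)
}

# Rebuild Lambda/Phi/Psi/tau/kappa matrices from a packed entry vector v.
unpack_matrices <- function(spec, v) {
  p <- spec$p
  q <- spec$q
  pq <- p * q
  qh <- q * (q + 1) / 2
  lambda <- matrix(v[seq_len(pq)], p, q)
  phi <- unvech(v[pq + seq_len(qh)])
  psi <- v[pq + qh + seq_len(p)]
  tau <- v[pq + qh + p + seq_len(p)]
  kappa <- v[pq + qh + 2 * p + seq_len(q)]
  list(lambda = lambda, phi = phi, psi = psi, tau = tau, kappa = kappa)
}

# ---- moderation -----------------------------------------------------------

#' Let model parameters depend on a study-level moderator
#'
#' Implements the regression approach: every moderated parameter becomes
#' `beta0 + beta1 * x`, where `beta0` is the (free or fixed) baseline and
#' `beta1` a free slope on the study-level variable `moderator`. With a 0/1
#' dummy the slope is the group difference in the parameter; with a
#' continuous moderator it is the change per unit. Multiple moderators on the
#' same parameter compose additively. Moderating a *fixed* baseline is
#' allowed and is exactly how invariance models free a parameter in the
#' non-reference group only (e.g. factor variance fixed at 1 plus a free
#' slope).
#'
#' @param spec A [cfa_spec()].
#' @param pars Character vector of parameter names (`"lambda[2,1]"`,
#'   `"psi[3]"`, ...) or whole-block shortcuts `"lambda"`, `"phi"`,
#'   `"phi_diag"`, `"phi_offdiag"`, `"psi"`, `"tau"`, `"kappa"`. Block
#'   shortcuts select the *free* cells of the block, except `"phi_diag"` and
#'   `"kappa"`, which select all cells (their baselines are typically fixed
#'   for identification).
#' @param moderator Name of the study-level moderator.
#' @return The modified `cfa_spec`.
#' @export
moderate <- function(spec, pars, moderator) {
  stopifnot(inherits(spec, "cfa_spec"), is.character(pars),
            length(moderator) == 1)
  tab <- param_table(spec)
  q <- spec$q
  expand_one <- function(par) {
    if (par %in% tab$name) return(par)
    block_names <- switch(
      par,
      lambda = tab$name[grepl("^lambda", tab$name) & tab$free],
      phi = tab$name[grepl("^phi", tab$name)],
      phi_diag = paste0("phi[", seq_len(q), ",", seq_len(q), "]"),
      phi_offdiag = {
        lt <- which(lower.tri(diag(q)), arr.ind = TRUE)
        nm <- paste0("phi[", lt[, 1], ",", lt[, 2], "]")
        nm[nm %in% tab$name[tab$free]]
      },
      psi = tab$name[grepl("^psi", tab$name) & tab$free],
      tau = tab$name[grepl("^tau", tab$name) & tab$free],
      kappa = tab$name[grepl("^kappa", tab$name)],
      stop("unknown parameter or block: ", par, call. = FALSE)
    )
    block_names
  }
  new_pars <- unique(unlist(lapply(pars, expand_one)))
  add <- data.frame(par = new_pars, moderator = moderator,
                    stringsAsFactors = FALSE)
  comb <- rbind(spec$moderation, add)
  dup <- duplicated(comb[c("par", "moderator")])
  spec$moderation <- comb[!dup, , drop = FALSE]
  rownames(spec$moderation) <- NULL
  spec
}

# ---- model-implied moments ------------------------------------------------

#' Model-implied covariance matrix and mean vector
#'
#' Computes `Sigma = Lambda Phi Lambda' + Psi` and `mu = tau + Lambda kappa`
#' at a given parameter vector, after resolving every moderated parameter to
#' `baseline + sum(slope * x)` at the supplied moderator values.
#'
#' @param spec A [cfa_spec()].
#' @param theta Named vector of free-parameter values in [theta_names()]
#'   order; defaults to the specification's start values.
#' @param x Named vector of moderator values (required when the spec has a
#'   moderation map).
#' @return A list with `Sigma` (`p` by `p`, symmetric) and `mu` (length `p`).
#' @export
implied_moments <- function(spec, theta = NULL, x = numeric(0)) {
  stopifnot(inherits(spec, "cfa_spec"))
  layout <- theta_layout(spec)
  if (is.null(theta)) theta <- start_values(spec)
  if (length(theta) != layout$n_base + layout$n_slope) {
    stop("`theta` must have length ", layout$n_base + layout$n_slope,
         call. = FALSE)
  }
  A <- design_for_study(layout, x)
  v <- as.vector(A %*% theta + design_const(layout))
  m <- unpack_matrices(spec, v)
  Sigma <- m$lambda %*% m$phi %*% t(m$lambda) + diag(m$psi, spec$p)
  Sigma <- (Sigma + t(Sigma)) / 2
  mu <- as.vector(m$tau + m$lambda %*% m$kappa)
  list(Sigma = Sigma, mu = mu)
}

#' Default starting values for the free parameters
#'
#' Free loadings start at .5, residual variances at half the pooled observed
#' variances (or .5 without data), intercepts at the pooled means (or 0),
#' free factor (co)variances at 1 (diagonal) / 0 (off-diagonal), factor means
#' at 0, and all moderator slopes at 0.
#'
#' @param spec A [cfa_spec()].
#' @param studies Optional list of [study_record()]s used to pool variances
#'   and means.
#' @return Named numeric vector in [theta_names()] order.
#' @export
start_values <- function(spec, studies = NULL) {
  layout <- theta_layout(spec)
  pooled_var <- rep(1, spec$p)
  pooled_mean <- rep(0, spec$p)
  if (!is.null(studies) && length(studies)) {
    ok <- vapply(studies, `[[`, TRUE, "valid")
    Ss <- lapply(studies[ok], `[[`, "S")
    pooled_var <- rowMeans(vapply(Ss, diag, numeric(spec$p)), na.rm = TRUE)
    pooled_mean <- rowMeans(vapply(studies[ok], `[[`, numeric(spec$p), "ybar"),
                            na.rm = TRUE)
    pooled_var[is.na(pooled_var)] <- 1
    pooled_mean[is.na(pooled_mean)] <- 0
  }
  st <- numeric(layout$n_base + layout$n_slope)
  names(st) <- layout$names
  for (b in seq_len(layout$n_base)) {
    nm <- layout$names[b]
    i <- as.integer(sub(".*\\[([0-9]+).*", "\\1", nm))
    j <- if (grepl(",", nm)) as.integer(sub(".*,([0-9]+)\\]", "\\1", nm)) else i
    st[b] <- if (grepl("^lambda", nm)) 0.5
    else if (grepl("^phi", nm)) as.numeric(i == j)
    else if (grepl("^psi", nm)) pooled_var[i] / 2
    else if (grepl("^tau", nm)) pooled_mean[i]
    else 0
  }
  st
}

# ---- invariance models ----------------------------------------------------

#' Build a measurement-invariance model across (groups of) studies
#'
#' Starting from a reference CFA specification (factor variances fixed at 1,
#' factor means fixed at 0), constructs the moderated model for one of three
#' increasingly restrictive levels of factorial invariance with respect to a
#' study-level grouping dummy (the same mechanics apply to a continuous
#' moderator):
#'
#' * `configural`: the factor structure is shared but every free CFA
#'   parameter (loadings, residual variances, intercepts, factor covariances)
#'   gets a moderator slope; factor variances stay fixed at 1 and factor
#'   means at 0 at every moderator value.
#' * `weak`: loading slopes are dropped (loadings equal across groups) except
#'   for `partial_free` loadings; factor variances keep their baseline fixed
#'   at 1 and gain a free slope, so the non-reference group's variance is
#'   estimated.
#' * `strong`: additionally intercept slopes are dropped except for
#'   `partial_free` entries; factor means keep their baseline fixed at 0 and
#'   gain a free slope, so each slope estimates the latent mean difference
#'   between groups.
#'
#' @param spec The reference [cfa_spec()] (unmoderated).
#' @param level `"configural"`, `"weak"`, or `"strong"`.
#' @param group_dummy Name of the moderator (0 = reference group).
#' @param partial_free Parameter names exempted from the equality constraint:
#'   loadings under `weak`; loadings and/or intercepts under `strong`.
#' @return A moderated `cfa_spec`.
#' @export
build_invariance_model <- function(spec, level = c("configural", "weak",
                                                   "strong"),
                                   group_dummy, partial_free = character(0)) {
  level <- match.arg(level)
  stopifnot(inherits(spec, "cfa_spec"), is.character(group_dummy))
  if (nrow(spec$moderation)) {
    stop("`spec` must be an unmoderated reference specification", call. = FALSE)
  }
  if (any(spec$phi$free[cbind(seq_len(spec$q), seq_len(spec$q))]) ||
      any(spec$kappa$free)) {
    stop("the reference configuration must fix the factor variances and ",
         "factor means (e.g. at 1 and 0)", call. = FALSE)
  }
  ok_partial <- switch(level,
                       configural = "^$",  # nothing is constrained yet
                       weak = "^lambda\\[",
                       strong = "^(lambda|tau)\\[")
  bad <- if (length(partial_free)) {
    partial_free[!grepl(ok_partial, partial_free)]
  } else character(0)
  if (length(bad)) {
    stop("`partial_free` entries not allowed at level `", level, "`: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }

  if (level == "configural") {
    spec <- moderate(spec, c("lambda", "phi_offdiag", "psi", "tau"),
                     group_dummy)
  } else if (level == "weak") {
    spec <- moderate(spec, c("phi_diag", "phi_offdiag", "psi", "tau"),
                     group_dummy)
    if (length(partial_free)) spec <- moderate(spec, partial_free, group_dummy)
  } else {
    spec <- moderate(spec, c("phi_diag", "phi_offdiag", "psi", "kappa"),
                     group_dummy)
    if (length(partial_free)) spec <- moderate(spec, partial_free, group_dummy)
  }
  attr(spec, "invariance") <- list(level = level, group_dummy = group_dummy,
                                   partial_free = partial_free)
  spec
}

# ---- degrees of freedom ---------------------------------------------------

#' Residual degrees of freedom against the saturated model
#'
#' Counts the residual degrees of freedom of a mean-structure model relative
#' to the saturated means-and-covariances model with the same moderation
#' status: `df = m * (p(p+1)/2 + p) - n_free`, where `m` is 1 plus the number
#' of distinct moderators (i.e. the number of groups for a single dummy) and
#' `n_free` counts the free baselines and slopes of the mean structure.
#' Between-study heterogeneity parameters are shared with the saturated
#' baseline and excluded from the count.
#'
#' @param spec A [cfa_spec()] or [saturated_spec()].
#' @param n_groups Optional override of `m` (e.g. `2` for a two-group dummy;
#'   the default infers it from the spec's moderation map).
#' @return Integer degrees of freedom.
#' @export
count_df <- function(spec, n_groups = NULL) UseMethod("count_df")

#' @export
count_df.cfa_spec <- function(spec, n_groups = NULL) {
  check_identified(spec)
  m <- if (!is.null(n_groups)) n_groups else 1 + length(spec_moderators(spec))
  as.integer(m * n_effects(spec$p) - n_free_mean(spec))
}

# every factor needs a scale (fixed variance or fixed nonzero loading) and an
# origin (fixed mean or a fixed intercept among its indicators)
check_identified <- function(spec) {
  for (f in seq_len(spec$q)) {
    fixed_var <- !spec$phi$free[f, f]
    marker <- any(!spec$lambda$free[, f] & spec$lambda$value[, f] != 0)
    if (!fixed_var && !marker) {
      stop("factor ", f, " has no scale: fix its variance or a loading",
           call. = FALSE)
    }
    fixed_mean <- !spec$kappa$free[f]
    ind <- spec$lambda$free[, f] | spec$lambda$value[, f] != 0
    fixed_int <- any(!spec$tau$free[ind])
    if (!fixed_mean && !fixed_int) {
      stop("factor ", f, " has no origin: fix its mean or an intercept",
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' @export
print.cfa_spec <- function(x, ...) {
  cat("<cfa_spec> p =", x$p, "variables, q =", x$q, "factors;",
      n_free_mean(x), "free parameters (",
      nrow(x$moderation), "moderator slopes )\n")
  inv <- attr(x, "invariance")
  if (!is.null(inv)) {
    cat("  invariance level:", inv$level, "across `", inv$group_dummy, "`",
        if (length(inv$partial_free)) {
          paste0("(partial: ", paste(inv$partial_free, collapse = ", "), ")")
        }, "\n")
  }
  invisible(x)
}

# ---- saturated specification ----------------------------------------------

#' Saturated means-and-covariances model
#'
#' The baseline model in which every average effect size (each pooled
#' covariance element and each pooled mean) is a free parameter, optionally
#' regressed on study-level moderators. Serves as the chi-square baseline for
#' CFA fits with the matching moderation status.
#'
#' @param p Number of observed variables.
#' @param moderators Character vector of moderator names (possibly empty).
#' @param var_names Optional variable names.
#' @return An object of class `saturated_spec`.
#' @export
saturated_spec <- function(p, moderators = character(0), var_names = NULL) {
  structure(list(p = p, moderators = as.character(moderators),
                 var_names = var_names),
            class = "saturated_spec")
}

#' @export
theta_names.saturated_spec <- function(spec) {
  labels <- effect_index_map(spec$p, spec$var_names)$label
  c(labels, unlist(lapply(spec$moderators, function(m) {
    paste0(labels, "@", m)
  })))
}

#' @export
spec_moderators.saturated_spec <- function(spec) spec$moderators

#' @export
count_df.saturated_spec <- function(spec, n_groups = NULL) 0L

#' @export
print.saturated_spec <- function(x, ...) {
  cat("<saturated_spec> p =", x$p, "variables;",
      length(theta_names(x)), "free mean-structure parameters")
  if (length(x$moderators)) {
    cat("; moderated by", paste(x$moderators, collapse = ", "))
  }
  cat("\n")
  invisible(x)
}
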