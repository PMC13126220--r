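one_factor <- function(p = 4) cfa_spec(loadings = matrix(NA, p, 1))

test_that("marginal log-likelihood matches an independent density oracle", {
  studies <- make_studies(k = 8, n = 50, p = 4, seed = 21)
  spec <- moderate(one_factor(4), "kappa", "group")
  het <- het_spec("diagonal", "symmetric")
  nt <- length(theta_names(spec))
  p <- 4
  ns <- p * (p + 1) / 2

  lambda <- matrix(c(0.6, 0.5, 0.7, 0.4), 4, 1)
  psi <- c(0.5, 0.6, 0.4, 0.7)
  tau <- c(0.2, 0.3, 0.1, 0.4)
  kap_slope <- 0.3
  lnsd_s <- rep(log(0.1), ns)
  Lm <- diag(sqrt(0.2), p)
  par <- numeric(nt + ns + p * (p + 1) / 2)
  names(par) <- c(theta_names(spec), metacfa:::het_par_names(het, p))
  par[paste0("lambda[", 1:4, ",1]")] <- lambda
  par[paste0("psi[", 1:4, "]")] <- psi
  par[paste0("tau[", 1:4, "]")] <- tau
  par["kappa[1]@group"] <- kap_slope
  par[grep("^lnsd_s", names(par))] <- lnsd_s
  par[paste0("chol_m[", 1:4, ",", 1:4, "]")] <- diag(Lm)

  got <- masem_loglik(spec, studies, par, het)
  want <- oracle_marginal_loglik(
    studies, lambda, matrix(1), psi, tau,
    kappa_fun = function(x) kap_slope * x,
    tau2_s = exp(2 * lnsd_s), T2_m = Lm %*% t(Lm), v_from = "pooled"
  )
  expect_equal(got, want, tolerance = 1e-10)

  # same check with each study's own covariance plugged into V_i
  got_own <- masem_loglik(spec, studies, par, het, v_plugin = "study")
  want_own <- oracle_marginal_loglik(
    studies, lambda, matrix(1), psi, tau,
    kappa_fun = function(x) kap_slope * x,
    tau2_s = exp(2 * lnsd_s), T2_m = Lm %*% t(Lm), v_from = "study"
  )
  expect_equal(got_own, want_own, tolerance = 1e-10)
})

test_that("analytic gradients match numerical differentiation", {
  studies <- make_studies(k = 6, n = 40, p = 3, seed = 22)
  spec <- build_invariance_model(one_factor(3), "strong", "group")
  for (het in list(het_spec("diagonal", "symmetric"),
                   het_spec("diagonal", "diagonal"),
                   het_spec("zero", "zero"))) {
    fd <- metacfa:::build_fit_data(spec, studies, het)
    st <- c(start_values(spec, studies), metacfa:::het_start(het, fd$dat))
    st <- st + stats::rnorm(length(st), 0, 0.02)
    got <- metacfa:::cpp_masem_eval(st, fd$ptr, TRUE)$grad
    num <- vapply(seq_along(st), function(j) {
      h <- 1e-6 * max(1, abs(st[j]))
      up <- st; up[j] <- up[j] + h
      dn <- st; dn[j] <- dn[j] - h
      (metacfa:::cpp_masem_eval(up, fd$ptr, FALSE)$nll -
         metacfa:::cpp_masem_eval(dn, fd$ptr, FALSE)$nll) / (2 * h)
    }, 0)
    expect_equal(got, num, tolerance = 1e-5)
  }
})

test_that("likelihood is invariant to study order and missing-data selection drops rows", {
  studies <- make_studies(k = 6, n = 40, p = 3, seed = 23)
  spec <- moderate(one_factor(3), "tau", "group")
  het <- het_spec()
  nt <- length(theta_names(spec)) + metacfa:::n_het_par(het, 3)
  set.seed(1)
  par <- c(start_values(spec, studies),
           metacfa:::het_start(het, metacfa:::build_fit_data(spec, studies,
                                                             het)$dat))
  perm <- c(4, 1, 6, 2, 5, 3)
  expect_equal(masem_loglik(spec, studies, par, het),
               masem_loglik(spec, studies[perm], par, het), tolerance = 1e-10)

  # masking a variable equals dropping its rows from the effect vector
  s_mask <- studies[[1]]
  s_mask$ybar[2] <- NA
  s_mask$observed_mask[2] <- FALSE
  masked <- c(list(s_mask), studies[-1])
  ll_masked <- masem_loglik(spec, masked, par, het)
  expect_true(is.finite(ll_masked))
  expect_false(isTRUE(all.equal(ll_masked,
                                masem_loglik(spec, studies, par, het))))
})

test_that("saturated fit with T2 = 0 and equal V pools by the arithmetic mean", {
  # identical n and identical S across studies -> equal weights
  p <- 2
  S <- matrix(c(1, 0.3, 0.3, 1), 2, 2)
  studies <- lapply(1:5, function(i) {
    study_record(paste0("s", i), 100, S, c(i / 10, -i / 10))
  })
  fit <- masem_saturated(studies, het = het_spec("zero", "zero"))
  ym <- rowMeans(vapply(studies, function(s) {
    c(vech(s$S), s$ybar)
  }, numeric(5)))
  expect_equal(unname(coef(fit)), ym, tolerance = 1e-8)
  expect_equal(fit$df, 0L)

  # single study: saturated mean equals the observed effect vector exactly
  fit1 <- masem_saturated(studies[1], het = het_spec("zero", "zero"))
  expect_equal(unname(coef(fit1)), c(vech(S), 0.1, -0.1), tolerance = 1e-8)
})

test_that("one study with T2 = 0 reproduces an independent GLS CFA fit", {
  set.seed(31)
  p <- 4
  lambda <- c(0.8, 0.7, 0.6, 0.5)
  X <- MASS::mvrnorm(400, rep(0.3, p), tcrossprod(lambda) + diag(0.4, p))
  one <- list(study_record("s1", 400, cov(X), colMeans(X)))
  zero_het <- het_spec("zero", "zero")
  fit <- masem(one_factor(4), one, het = zero_het, se = FALSE)
  sat <- masem_saturated(one, het = zero_het)
  chisq_pkg <- fit$m2ll - sat$m2ll

  # independent oracle: minimize the GLS quadratic form (y - m)' V^-1 (y - m)
  # over the same 12 parameters with plain optim on hand-written moments
  y <- c(cov(X)[lower.tri(cov(X), diag = TRUE)], colMeans(X))
  V <- sampling_covariance(cov(X), 400)
  Vinv <- solve(V)
  qform <- function(par) {
    l <- par[1:4]; ps <- par[5:8]; tu <- par[9:12]
    Sg <- tcrossprod(l) + diag(ps)
    m <- c(Sg[lower.tri(Sg, diag = TRUE)], tu)
    drop(t(y - m) %*% Vinv %*% (y - m))
  }
  o <- optim(c(lambda, rep(0.4, 4), rep(0.3, 4)), qform, method = "BFGS",
             control = list(reltol = 1e-15, maxit = 5000))
  o <- optim(o$par, qform, method = "BFGS",
             control = list(reltol = 1e-15, maxit = 5000))
  expect_equal(chisq_pkg, o$value, tolerance = 1e-6)
})

test_that("the -2logL nesting chain holds along the invariance ladder", {
  set.seed(32)
  base <- cfa_spec(matrix(NA, 5, 1))
  cond <- sim_condition("weak", k_per_group = 10, n_within = 80, seed = 5)
  data <- generate_dataset(cond)
  sat <- masem_saturated(data, moderators = "group")
  fits <- list(sat)
  for (level in c("configural", "weak", "strong")) {
    spec <- build_invariance_model(base, level, "group")
    fits[[level]] <- masem(spec, data, se = FALSE,
                           start = metacfa:::warm_start_from(fits))
  }
  expect_true(all(vapply(fits, `[[`, TRUE, "converged")))
  m2 <- vapply(fits, `[[`, 0, "m2ll")
  expect_true(all(diff(m2) >= -1e-6))

  lr <- masem_lrt(fits$strong, fits$weak)
  expect_equal(lr$delta_df, 4)
  expect_gte(lr$delta_chi2, 0)
  an <- anova(fits$strong, fits$weak, sat)
  expect_equal(an$delta_df, c(4, 14, NA))
})

test_that("parameter recovery without heterogeneity at large n", {
  set.seed(33)
  lambda <- rep(0.7, 4)
  Sigma <- tcrossprod(lambda) + diag(0.51, 4)
  studies <- lapply(1:6, function(i) {
    X <- MASS::mvrnorm(4000, rep(0.5, 4), Sigma)
    study_record(paste0("s", i), 4000, cov(X), colMeans(X))
  })
  fit <- masem(one_factor(4), studies, het = het_spec("zero", "zero"),
               se = TRUE)
  expect_true(fit$converged)
  for (j in 1:4) {
    nm <- paste0("lambda[", j, ",1]")
    expect_lt(abs(coef(fit)[nm] - 0.7), 2 * fit$se[nm] + 0.01)
  }
})

test_that("chi-square difference test handles identity and degenerate cases", {
  studies <- make_studies(k = 6, n = 50, p = 3, seed = 24, group = FALSE)
  fit <- masem(one_factor(3), studies, se = FALSE)
  self <- masem_lrt(fit, fit)
  expect_equal(self$delta_chi2, 0)
  expect_equal(self$delta_df, 0)
  expect_equal(self$p_value, 1)
})

test_that("information criteria follow their definitions", {
  studies <- make_studies(k = 6, n = 50, p = 3, seed = 25, group = FALSE)
  fit <- masem(one_factor(3), studies, se = FALSE)
  ic <- information_criteria(fit)
  expect_equal(ic[["AIC"]], fit$m2ll + 2 * fit$n_free)
  expect_equal(ic[["BIC"]], fit$m2ll + fit$n_free * log(fit$N_total))
  # stats generics agree via the logLik method
  expect_equal(AIC(fit), ic[["AIC"]])
  expect_equal(BIC(fit), ic[["BIC"]])
  # one extra free parameter at equal -2logL costs exactly 2 AIC points
  f2 <- fit
  f2$n_free <- fit$n_free + 1
  expect_equal(information_criteria(f2)[["AIC"]] - ic[["AIC"]], 2)
  # BIC penalizes harder than AIC whenever log(N) > 2
  expect_gt(log(fit$N_total), 2)
  expect_gt(ic[["BIC"]] - ic[["AIC"]], 0)
})

test_that("RMSEA follows its closed form and conventions", {
  expect_equal(rmsea(10, 10, 500), 0)
  expect_equal(rmsea(20, 10, 1001), sqrt(10 / (10 * 1000)))
  expect_equal(rmsea(5, 10, 500), 0)  # chisq below df floors at zero
  chis <- seq(5, 50, by = 5)
  expect_true(!is.unsorted(vapply(chis, rmsea, 0, df = 10, N_total = 300)))
  expect_warning(v <- rmsea(3, 0, 100), "df = 0")
  expect_true(is.na(v))
})

test_that("Wald test and standardized mean difference follow closed forms", {
  studies <- make_studies(k = 8, n = 60, p = 3, seed = 26)
  spec <- build_invariance_model(one_factor(3), "strong", "group")
  fit <- masem(spec, studies, se = TRUE)
  w <- wald_test(fit, "kappa[1]@group")
  expect_equal(w$z, w$estimate / w$se)
  expect_equal(w$p_value, 2 * pnorm(-abs(w$z)))
  expect_error(wald_test(fit, "nope"), "unknown parameter")

  expect_equal(smd(0.5, 1, 1), 0.5)
  expect_equal(smd(0, 2, 5), 0)
  expect_equal(smd(1, 1, 3), 1 / sqrt(2))
  expect_error(smd(1, 0, 1), "positive")
})

test_that("optimum is invariant to the study ordering", {
  studies <- make_studies(k = 8, n = 50, p = 3, seed = 27)
  spec <- build_invariance_model(one_factor(3), "weak", "group")
  f1 <- masem(spec, studies, se = FALSE)
  f2 <- masem(spec, studies[sample(8)], se = FALSE)
  expect_equal(f1$m2ll, f2$m2ll, tolerance = 1e-7)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-4)
})

test_that("partial-invariance search frees the genuinely non-invariant loading", {
  studies <- read_studies(system.file("extdata", "ttctf_synthetic.csv",
                                      package = "metacfa"), quiet = TRUE)
  load2 <- matrix(0, 5, 2)
  load2[1:2, 1] <- NA
  load2[3:5, 2] <- NA
  base <- cfa_spec(load2)
  # the synthetic dataset's group difference is built into loading [4,2]
  sw <- partial_invariance_search(base, studies, level = "weak",
                                  group_dummy = "west")
  expect_equal(sw$best, "lambda[4,2]")
  expect_equal(nrow(sw$table), 5)
  expect_true(all(c("delta_chi2", "p_value", "AIC") %in% names(sw$table)))
  # freeing the right loading is a clear win over the other candidates
  others <- sw$table$m2ll[sw$table$freed != sw$best]
  expect_true(all(sw$fit$m2ll < others - 2))

  ss <- partial_invariance_search(base, studies, level = "strong",
                                  group_dummy = "west",
                                  keep_free = sw$best)
  expect_true(ss$best %in% paste0("tau[", 1:5, "]"))
  expect_true(ss$fit$converged)
})
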