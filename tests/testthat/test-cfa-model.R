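one_factor <- function(p = 5) cfa_spec(loadings = matrix(NA, p, 1))

theta_with <- function(spec, lambda = 0.7, psi = 0.51, tau = 0.5) {
  th <- start_values(spec)
  th[grep("^lambda", names(th))] <- lambda
  th[grep("^psi\\[", names(th))] <- psi
  th[grep("^tau", names(th))] <- tau
  th
}

test_that("implied moments reproduce the one-factor closed forms", {
  spec <- one_factor()
  im <- implied_moments(spec, theta_with(spec))
  expect_equal(diag(im$Sigma), rep(1, 5))
  expect_equal(im$Sigma[lower.tri(im$Sigma)], rep(0.49, 10))
  expect_equal(im$mu, rep(0.5, 5))

  # free factor mean: mu = tau + lambda * kappa
  spec2 <- cfa_spec(matrix(NA, 5, 1), kappa = NA, tau = rep(0.5, 5),
                    phi = matrix(1, 1, 1))
  th2 <- theta_with(spec2)
  th2["kappa[1]"] <- 0.5
  expect_equal(implied_moments(spec2, th2)$mu, rep(0.85, 5))

  # null loadings: Sigma = Psi and mu = tau whatever Phi, kappa are
  th0 <- theta_with(spec, lambda = 0)
  im0 <- implied_moments(spec, th0)
  expect_equal(im0$Sigma, diag(0.51, 5))
  expect_equal(im0$mu, rep(0.5, 5))
})

test_that("implied Sigma is symmetric and PSD for admissible parameters", {
  set.seed(3)
  spec <- cfa_spec(matrix(NA, 4, 2))
  for (r in 1:20) {
    th <- start_values(spec)
    th[grep("^lambda", names(th))] <- rnorm(8)
    th[grep("^psi", names(th))] <- runif(4, 0.1, 2)
    th[grep("^phi\\[2,1\\]", names(th))] <- runif(1, -0.9, 0.9)
    im <- implied_moments(spec, th)
    expect_equal(im$Sigma, t(im$Sigma))
    expect_gte(min(eigen(im$Sigma, symmetric = TRUE)$values), 0)
  }
})

test_that("moderation with zero slopes reproduces the unmoderated moments", {
  spec <- one_factor()
  mod <- moderate(spec, c("lambda", "psi", "tau"), "group")
  th <- theta_with(spec)
  thm <- c(th, rep(0, length(theta_names(mod)) - length(th)))
  names(thm) <- theta_names(mod)
  for (x in c(0, 1, 2.5)) {
    imm <- implied_moments(mod, thm, x = c(group = x))
    im <- implied_moments(spec, th)
    expect_equal(imm$Sigma, im$Sigma)
    expect_equal(imm$mu, im$mu)
  }
  # nonzero slope shifts the moderated parameter linearly
  thm["lambda[1,1]@group"] <- 0.2
  im1 <- implied_moments(mod, thm, x = c(group = 1))
  expect_equal(im1$Sigma[1, 2], (0.7 + 0.2) * 0.7)
})

test_that("missing moderator values are rejected by name", {
  mod <- moderate(one_factor(), "lambda", "wave")
  expect_error(implied_moments(mod, x = c(group = 1)), "wave")
})

test_that("invariance ladder has the published degrees of freedom", {
  base <- one_factor()
  expect_equal(count_df(build_invariance_model(base, "configural", "group")),
               10L)
  expect_equal(count_df(build_invariance_model(base, "weak", "group")), 14L)
  expect_equal(count_df(build_invariance_model(base, "strong", "group")), 18L)
  expect_equal(count_df(saturated_spec(5, "group")), 0L)
})

test_that("df bookkeeping matches the free-parameter ladder", {
  base <- one_factor()
  conf <- build_invariance_model(base, "configural", "group")
  weak <- build_invariance_model(base, "weak", "group")
  strong <- build_invariance_model(base, "strong", "group")
  # weak removes 5 loading slopes, adds 1 factor-variance slope
  expect_equal(count_df(weak) - count_df(conf),
               length(theta_names(conf)) - length(theta_names(weak)))
  # strong removes 5 intercept slopes, adds 1 factor-mean slope
  expect_equal(count_df(strong) - count_df(weak), 4L)

  # two-factor structure (2 + 3 indicators): weak has 3 more dfs than
  # configural (5 loading slopes out, 2 factor-variance slopes in)
  load2 <- matrix(0, 5, 2)
  load2[1:2, 1] <- NA
  load2[3:5, 2] <- NA
  base2 <- cfa_spec(load2)
  conf2 <- build_invariance_model(base2, "configural", "west")
  weak2 <- build_invariance_model(base2, "weak", "west")
  expect_equal(count_df(weak2) - count_df(conf2), 3L)
})

test_that("partial invariance frees only the exempted parameters", {
  base <- one_factor()
  pw <- build_invariance_model(base, "weak", "group",
                               partial_free = "lambda[3,1]")
  expect_true("lambda[3,1]@group" %in% theta_names(pw))
  expect_equal(count_df(pw),
               count_df(build_invariance_model(base, "weak", "group")) - 1L)
  ps <- build_invariance_model(base, "strong", "group",
                               partial_free = c("lambda[3,1]", "tau[1]"))
  expect_true(all(c("lambda[3,1]@group", "tau[1]@group") %in%
                    theta_names(ps)))

  expect_error(build_invariance_model(base, "weak", "group",
                                      partial_free = "tau[1]"),
               "not allowed")
  expect_error(build_invariance_model(base, "configural", "group",
                                      partial_free = "lambda[1,1]"),
               "not allowed")
})

test_that("identification requires a scale and origin per factor", {
  free_var <- cfa_spec(matrix(NA, 3, 1), phi = matrix(NA, 1, 1))
  expect_error(count_df(free_var), "scale")
  free_mean <- cfa_spec(matrix(NA, 3, 1), kappa = NA)
  expect_error(count_df(free_mean), "origin")
  # fixed-marker alternative identifies the scale
  marker <- cfa_spec(matrix(c(1, NA, NA), 3, 1), phi = matrix(NA, 1, 1))
  expect_silent(count_df(marker))
})

test_that("single-indicator factors use a zero residual variance", {
  load <- matrix(0, 3, 2)
  load[1:2, 1] <- NA
  load[3, 2] <- NA
  spec <- cfa_spec(load, psi = c(NA, NA, 0))
  th <- start_values(spec)
  th[grep("lambda\\[3,2\\]", names(th))] <- 1
  im <- implied_moments(spec, th)
  expect_equal(im$Sigma[3, 3], 1)  # variance = loading^2 * phi only
})
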