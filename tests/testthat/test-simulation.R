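test_that("group populations carry the design's model-implied moments", {
  cond <- sim_condition("strong", 15)
  p1 <- metacfa:::sim_population(cond, 1)
  p2 <- metacfa:::sim_population(cond, 2)
  expect_equal(diag(p1$Sigma), rep(1, 5))
  expect_equal(p1$Sigma[lower.tri(p1$Sigma)], rep(0.49, 10))
  expect_equal(p1$mu, rep(0.5, 5))
  expect_equal(p2$mu, rep(0.85, 5))
  expect_equal(p2$Sigma, p1$Sigma)

  w2 <- metacfa:::sim_population(sim_condition("weak", 15), 2)
  expect_equal(w2$mu, c(1.35, rep(0.85, 4)))
})

test_that("generated studies carry the group dummy and valid moments", {
  cond <- sim_condition("strong", 15, n_within = 50)
  set.seed(1)
  s1 <- generate_study(cond, 1, "a")
  s2 <- generate_study(cond, 2, "b")
  expect_equal(unname(s1$moderators["group"]), 0)
  expect_equal(unname(s2$moderators["group"]), 1)
  expect_equal(s1$n, 50)
  expect_true(s1$valid && s2$valid)

  data <- generate_dataset(cond)
  expect_length(data, 30)
  expect_equal(sum(vapply(data, function(s) s$moderators[["group"]], 0)), 15)
})

test_that("between-study heterogeneity matches the design moments", {
  cond <- sim_condition("strong", 15, n_within = 8000)
  set.seed(99)
  R <- 4000
  mus <- t(vapply(seq_len(R), function(i) {
    generate_study(cond, 1, "s")$ybar
  }, numeric(5)))
  # with huge n the spread of study means is the between-study part:
  # variance .20 per mean, covariance .10 between means
  Cm <- cov(mus)
  expect_true(all(abs(diag(Cm) - 0.20) < 3 * 0.20 * sqrt(2 / R) + 0.003))
  off <- Cm[lower.tri(Cm)]
  expect_true(all(abs(off - 0.10) < 0.02))
  # covariance elements perturbed with variance .01
  ss <- vapply(seq_len(1000), function(i) {
    generate_study(cond, 1, "s")$S[2, 1]
  }, 0)
  expect_equal(mean(ss), 0.49, tolerance = 0.02)
  expect_equal(var(ss), 0.01, tolerance = 0.25)
})

test_that("without heterogeneity and large n the sample moments approach the implied moments", {
  cond <- sim_condition("strong", 15, n_within = 20000)
  set.seed(7)
  s <- generate_study(cond, 2, "big", het_scale = 0)
  expect_equal(diag(s$S), rep(1, 5), tolerance = 0.05)
  expect_equal(s$S[lower.tri(s$S)], rep(0.49, 10), tolerance = 0.05)
  expect_equal(s$ybar, rep(0.85, 5), tolerance = 0.05)
})

test_that("replication sub-streams make runs reproducible in isolation", {
  cond <- sim_condition("strong", k_per_group = 4, n_within = 40, reps = 3,
                        seed = 31)
  r1 <- run_condition(cond, fit_models = "strong")
  r2 <- run_condition(cond, fit_models = "strong")
  expect_identical(r1$log, r2$log)
  # a shorter run reproduces the head of a longer one (interrupt/resume)
  cond5 <- sim_condition("strong", k_per_group = 4, n_within = 40, reps = 5,
                         seed = 31)
  r5 <- run_condition(cond5, fit_models = "strong")
  expect_identical(r5$log[1:3, ], r1$log)
})

test_that("report_table renders one complete row per condition", {
  cond <- sim_condition("strong", k_per_group = 5, n_within = 40, reps = 2,
                        seed = 8)
  s1 <- run_condition(cond)
  tab <- report_table(list(s1, s1))
  expect_equal(nrow(tab), 2)
  needed <- c("truth", "k", "factor_mean", "reject_overall",
              "reject_strong_weak", "reject_weak_conf", "aic_strong",
              "bic_strong", "convergence")
  expect_true(all(needed %in% names(tab)))
  expect_false(anyNA(tab[needed]))
  # AIC selection proportions sum to one over the four models
  expect_equal(sum(tab[1, grep("^aic_", names(tab))]), 1)
})
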