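test_that("vech stacks the lower triangle column-major and unvech inverts it", {
  expect_equal(vech(matrix(c(1, 2, 2, 3), 2, 2)), c(1, 2, 3))
  expect_equal(vech(diag(3)), c(1, 0, 0, 1, 0, 1))
  expect_equal(unvech(c(1, 2, 3)), matrix(c(1, 2, 2, 3), 2, 2))
  expect_equal(unvech(rep(0, 6)), matrix(0, 3, 3))

  set.seed(11)
  for (p in 1:12) {
    M <- crossprod(matrix(rnorm(p * p), p))
    expect_equal(unvech(vech(M)), M)
    v <- rnorm(p * (p + 1) / 2)
    expect_equal(vech(unvech(v)), v)
  }
})

test_that("vech and unvech reject malformed input", {
  expect_error(vech(matrix(1:6, 2, 3)), "square")
  expect_error(vech(matrix(c(1, 2, 3, 4), 2, 2)), "symmetric")
  expect_error(unvech(1:4), "triangular number")
})

test_that("effect index map is a bijection onto covariances plus means", {
  for (p in c(1, 3, 5)) {
    map <- effect_index_map(p)
    expect_equal(nrow(map), p * (p + 1) / 2 + p)
    expect_equal(sum(map$type == "cov"), p * (p + 1) / 2)
    expect_equal(sum(map$type == "mean"), p)
    expect_true(all(map$i[map$type == "cov"] >= map$j[map$type == "cov"]))
    expect_false(any(duplicated(map[c("type", "i", "j")])))
  }
})

test_that("sampling covariance matches the normal-theory closed forms", {
  V <- sampling_covariance(diag(2), n = 100)
  b <- attr(V, "blocks")
  expect_equal(V[b$mean, b$mean], diag(0.01, 2))
  expect_equal(V[b$cov, b$mean], matrix(0, 3, 2))

  V2 <- sampling_covariance(diag(2), n = 101)
  # Var(s11) = 2/(n-1); Cov(s11, s22) = 0 when s12 = 0
  expect_equal(V2[1, 1], 0.02)
  expect_equal(V2[1, 3], 0)
  expect_equal(V2, t(V2))
})

test_that("sampling covariance matches a Monte-Carlo oracle", {
  set.seed(42)
  p <- 3
  n <- 40
  A <- matrix(rnorm(p * p), p)
  Sigma <- crossprod(A) + diag(p)
  mu <- c(-1, 0, 1)
  R <- 6000
  draws <- t(vapply(seq_len(R), function(r) {
    X <- MASS::mvrnorm(n, mu, Sigma)
    S <- cov(X)
    c(S[lower.tri(S, diag = TRUE)], colMeans(X))
  }, numeric(p * (p + 1) / 2 + p)))
  V_emp <- cov(draws)
  V_theory <- sampling_covariance(Sigma, n)
  # elementwise agreement within 3 Monte-Carlo standard errors
  mc_se <- sqrt((outer(diag(V_theory), diag(V_theory)) + V_theory^2) / R)
  expect_true(all(abs(V_emp - V_theory) < 3.5 * mc_se + 1e-12))
  # cross-block between covariances and means is exactly zero
  b <- attr(V_theory, "blocks")
  expect_true(all(V_theory[b$cov, b$mean] == 0))
})

test_that("singular covariance input is warned about, not repaired", {
  S <- matrix(1, 2, 2)
  expect_warning(sampling_covariance(S, 50), "singular")
  rec <- study_record("bad", 50, S, c(0, 0))
  expect_false(rec$valid)
  expect_match(rec$flag_reason, "singular|semidefinite")
})

test_that("study records validate dimensions, masks, and PSD", {
  S <- diag(3)
  expect_error(study_record("a", 50, S, c(0, 0)), "length 3")
  expect_error(study_record("a", 1, S, c(0, 0, 0)), ">= 2")
  rec <- study_record("a", 50, S, c(0, NA, 0))
  expect_equal(rec$observed_mask, c(TRUE, FALSE, TRUE))
  expect_true(rec$valid)
  bad <- study_record("b", 50, matrix(c(1, 2, 2, 1), 2, 2), c(0, 0))
  expect_false(bad$valid)

  ev <- study_effect_vector(rec)
  expect_length(ev$values, 9)
  expect_equal(sum(ev$present), 3 + 2)  # cov(1,1), cov(3,1), cov(3,3) + 2 means
})

test_that("moderator names must agree across studies", {
  a <- study_record("a", 20, diag(2), c(0, 0), moderators = c(g = 0))
  b <- study_record("b", 20, diag(2), c(0, 0), moderators = c(h = 1))
  expect_error(validate_studies(list(a, b)), "moderator names")
})

test_that("write_studies / read_studies round-trips a dataset", {
  studies <- make_studies(k = 4, n = 30, p = 3, seed = 5)
  path <- tempfile(fileext = ".csv")
  write_studies(studies, path, sidecar = TRUE)
  back <- read_studies(path, quiet = TRUE)
  expect_length(back, 4)
  for (i in seq_along(back)) {
    expect_equal(back[[i]]$S, studies[[i]]$S, tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(back[[i]]$ybar, studies[[i]]$ybar, tolerance = 1e-12)
    expect_equal(back[[i]]$moderators, studies[[i]]$moderators)
  }
  # a second write from the re-read records is byte-identical
  path2 <- tempfile(fileext = ".csv")
  write_studies(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("reading flags non-PSD records but keeps the rest", {
  studies <- make_studies(k = 3, n = 30, p = 2, seed = 6)
  path <- tempfile(fileext = ".csv")
  write_studies(studies, path)
  df <- read.csv(path)
  df$cov_2_1[2] <- 5  # breaks PSD for study 2
  write.csv(df, path, row.names = FALSE)
  expect_message(back <- read_studies(path), "1 flagged")
  expect_false(back[[2]]$valid)
  expect_true(back[[1]]$valid && back[[3]]$valid)
  expect_error(read_studies(path, fail_fast = TRUE, quiet = TRUE), "flagged")
})
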