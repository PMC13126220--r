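# Independent oracles used across the test files. These deliberately avoid
# the package's own likelihood path (C++), matrix packing, and moment code.

# log-density of y ~ N(m, M), written out with base R only
oracle_mvn_logdens <- function(y, m, M) {
  r <- y - m
  -0.5 * (length(y) * log(2 * pi) +
            as.numeric(determinant(M, logarithm = TRUE)$modulus) +
            drop(t(r) %*% solve(M, r)))
}

# independent per-study density summation for the marginal model, building
# each study's mean vector from first principles (no package moment code)
oracle_marginal_loglik <- function(studies, lambda, phi, psi, tau, kappa_fun,
                                   tau2_s, T2_m, v_from = c("pooled", "study")) {
  v_from <- match.arg(v_from)
  p <- length(tau)
  lt <- which(lower.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  S_pool <- NULL
  if (v_from == "pooled") {
    wts <- vapply(studies, function(s) s$n - 1, 0)
    S_pool <- Reduce(`+`, Map(function(s, w) w * s$S, studies, wts)) /
      sum(wts)
  }
  total <- 0
  for (s in studies) {
    x <- s$moderators[["group"]]
    kap <- kappa_fun(x)
    Sigma <- lambda %*% phi %*% t(lambda) + diag(psi)
    mu <- tau + lambda %*% kap
    m <- c(Sigma[lower.tri(Sigma, diag = TRUE)], mu)
    y <- c(s$S[lower.tri(s$S, diag = TRUE)], s$ybar)
    Sv <- if (v_from == "pooled") S_pool else s$S
    Vc <- matrix(0, nrow(lt), nrow(lt))
    for (a in seq_len(nrow(lt))) {
      for (b in seq_len(nrow(lt))) {
        i <- lt[a, 1]; j <- lt[a, 2]; k2 <- lt[b, 1]; l <- lt[b, 2]
        Vc[a, b] <- (Sv[i, k2] * Sv[j, l] + Sv[i, l] * Sv[j, k2]) / (s$n - 1)
      }
    }
    M <- rbind(cbind(Vc + diag(tau2_s), matrix(0, nrow(lt), p)),
               cbind(matrix(0, p, nrow(lt)), Sv / s$n + T2_m))
    total <- total + oracle_mvn_logdens(y, m, M)
  }
  total
}

# small meta-analytic dataset from an arbitrary one-factor population,
# independent of the package's simulation module
make_studies <- function(k = 6, n = 60, p = 4, seed = 1, group = TRUE,
                         het_mean_sd = 0.2) {
  set.seed(seed)
  lambda <- seq(0.5, 0.8, length.out = p)
  Sigma <- tcrossprod(lambda) + diag(0.5, p)
  lapply(seq_len(k), function(i) {
    mu <- 0.3 + stats::rnorm(p, 0, het_mean_sd)
    X <- MASS::mvrnorm(n, mu, Sigma)
    mods <- if (group) c(group = as.numeric(i > k / 2)) else numeric(0)
    study_record(paste0("s", i), n, stats::cov(X), colMeans(X),
                 moderators = mods)
  })
}
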