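#' Half-vectorization of a symmetric matrix
#'
#' Stacks the lower triangle (including the diagonal) of a symmetric matrix
#' column by column: the ordering is (1,1), (2,1), ..., (p,1), (2,2), ...,
#' (p,p). Every part of the package that maps between matrices and effect-size
#' vectors uses this ordering.
#'
#' @param M A symmetric numeric matrix.
#' @param tol Relative tolerance for the symmetry check.
#' @return A numeric vector of length `p*(p+1)/2`.
#' @seealso [unvech()] for the inverse operation.
#' @export
#' @examples
#' vech(matrix(c(1, 2, 2, 3), 2, 2))  # c(1, 2, 3)
vech <- function(M, tol = 1e-8) {
  if (!is.matrix(M) || nrow(M) != ncol(M) || !is.numeric(M)) {
    stop("`M` must be a square numeric matrix", call. = FALSE)
  }
  scale <- max(1, max(abs(M)))
  if (max(abs(M - t(M))) > tol * scale) {
    stop("`M` is not symmetric within tolerance", call. = FALSE)
  }
  M[lower.tri(M, diag = TRUE)]
}

#' Inverse half-vectorization
#'
#' Rebuilds the symmetric matrix whose [vech()] equals `v`.
#'
#' @param v Numeric vector whose length is a triangular number `p*(p+1)/2`.
#' @return A symmetric `p` by `p` matrix.
#' @export
#' @examples
#' unvech(c(1, 2, 3))  # matrix(c(1, 2, 2, 3), 2, 2)
unvech <- function(v) {
  if (!is.numeric(v)) stop("`v` must be numeric", call. = FALSE)
  nv <- length(v)
  p <- (sqrt(8 * nv + 1) - 1) / 2
  if (abs(p - round(p)) > 1e-8) {
    stop("length of `v` (", nv, ") is not a triangular number p*(p+1)/2",
         call. = FALSE)
  }
  p <- as.integer(round(p))
  M <- matrix(0, p, p)
  M[lower.tri(M, diag = TRUE)] <- v
  M <- M + t(M)
  diag(M) <- diag(M) / 2
  M
}

#' Index map for a stacked effect-size vector
#'
#' An effect-size vector for one study stacks `vech(S)` on top of the sample
#' means, so it has length `p*(p+1)/2 + p`. This returns, for each position,
#' whether it is a covariance element `cov(i, j)` (with `i >= j`) or a mean
#' `mean(i)`.
#'
#' @param p Number of observed variables.
#' @param var_names Optional variable names used in the labels.
#' @return A data frame with columns `pos`, `type` (`"cov"` or `"mean"`),
#'   `i`, `j`, and `label`.
#' @export
effect_index_map <- function(p, var_names = NULL) {
  if (is.null(var_names)) var_names <- paste0("y", seq_len(p))
  stopifnot(length(var_names) == p)
  lt <- which(lower.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  # which() on lower.tri walks columns first, matching the vech ordering
  cov_part <- data.frame(
    pos = seq_len(nrow(lt)), type = "cov", i = lt[, 1], j = lt[, 2],
    label = paste0("cov(", var_names[lt[, 1]], ",", var_names[lt[, 2]], ")"),
    stringsAsFactors = FALSE
  )
  mean_part <- data.frame(
    pos = nrow(lt) + seq_len(p), type = "mean", i = seq_len(p), j = NA_integer_,
    label = paste0("mean(", var_names, ")"), stringsAsFactors = FALSE
  )
  rbind(cov_part, mean_part)
}

n_effects <- function(p) p * (p + 1L) / 2L + p
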