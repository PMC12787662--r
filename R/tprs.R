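# Rank-reduced thin-plate regression spline basis for a single covariate.
#
# Construction: with unique covariate values u_1..u_m, the full thin-plate
# system uses the radial basis eta(r) = r^3 / 12 (second-order penalty in
# one dimension, so straight lines are unpenalized).  The m x m matrix
# E_ij = eta(|u_i - u_j|) is eigen-truncated to the k leading
# (largest-magnitude) eigenvectors; the side condition T' delta = 0 with
# T = [1, u] is absorbed by a null-space reparametrization, leaving k - 2
# penalized "range" functions plus the unpenalized constant and linear
# functions.  The constant is dropped (absorbed by the model intercept) and
# all columns are centred to sum to zero over the observed covariate
# values, so the smooth is identifiable against the intercept.

eta_tps <- function(r) r^3 / 12

#' Thin-plate regression spline basis and penalty
#'
#' Builds a rank-reduced thin-plate regression spline for the week
#' covariate: a design matrix with `k - 2` penalized range columns followed
#' by one linear column, and the matching penalty matrix (zero row/column
#' for the linear term, so constant and linear functions of week are
#' unpenalized). Columns are centred to sum to zero over the observed
#' weeks.
#'
#' @param weeks Covariate values (at least 3 distinct values).
#' @param k Basis dimension (default 10, >= 3); silently reduced to the
#'   number of distinct covariate values when fewer are available.
#' @return A list of class `tprs_basis` with elements `X` (n x (k-1)
#'   design), `S` ((k-1) x (k-1) penalty), `k` (basis dimension used) and
#'   internal fields needed to evaluate the basis at new covariate values
#'   via [tprs_eval()].
#' @export
tprs_basis <- function(weeks, k = 10) {
  if (!is.numeric(weeks) || length(weeks) == 0L) {
    tri_abort("weeks must be numeric", "invalid_parameter")
  }
  if (!is_scalar_num(k) || k < 3) {
    tri_abort("k must be >= 3", "invalid_parameter")
  }
  u <- sort(unique(weeks))
  m <- length(u)
  if (m < 3L) {
    tri_abort("need at least 3 distinct covariate values for a smooth",
              "insufficient_support")
  }
  k <- as.integer(min(k, m))
  E <- eta_tps(abs(outer(u, u, "-")))
  Tm <- cbind(1, u)
  eg <- eigen(E, symmetric = TRUE)
  ord <- order(abs(eg$values), decreasing = TRUE)[seq_len(k)]
  U <- eg$vectors[, ord, drop = FALSE]
  D <- eg$values[ord]
  # absorb the side condition T' delta = 0 within the truncated space
  C <- crossprod(Tm, U)                       # 2 x k
  qrC <- qr(t(C))
  Z <- qr.Q(qrC, complete = TRUE)[, -seq_len(2L), drop = FALSE]  # k x (k-2)
  M <- U %*% Z                                # m x (k-2): delta = M coefs
  S_r <- crossprod(Z, Z * D)                  # Z' diag(D) Z
  S_r <- (S_r + t(S_r)) / 2
  # numerical PSD cleanup: the constrained bending energy is >= 0
  es <- eigen(S_r, symmetric = TRUE)
  ev <- pmax(es$values, 0)
  S_r <- es$vectors %*% (ev * t(es$vectors))
  S_r <- (S_r + t(S_r)) / 2
  # scale the penalty to unit mean diagonal (pure reparametrization of
  # lambda; keeps the REML optimization well conditioned)
  scl <- mean(diag(S_r))
  if (scl > 0) S_r <- S_r / scl
  pos <- ev / max(ev) > 1e-10
  basis <- structure(
    list(knots = u, M = M, S_range = S_r,
         rank = sum(pos),
         ldS = sum(log(ev[pos] / scl)),
         x_mean = mean(weeks), k = k,
         col_means = NULL),
    class = "tprs_basis")
  X <- tprs_eval(basis, weeks, center = FALSE)
  cm <- colMeans(X)
  basis$col_means <- cm
  basis$X <- sweep(X, 2, cm)
  p <- k - 1L
  S <- matrix(0, p, p)
  S[seq_len(k - 2L), seq_len(k - 2L)] <- S_r
  basis$S <- S
  basis
}

#' Evaluate a thin-plate regression spline basis at new covariate values
#'
#' @param basis A [tprs_basis()].
#' @param weeks New covariate values.
#' @param center Subtract the training-column means (default TRUE).
#' @return Matrix with `k - 2` range columns and one linear column.
#' @export
tprs_eval <- function(basis, weeks, center = TRUE) {
  E0 <- eta_tps(abs(outer(weeks, basis$knots, "-")))
  X <- cbind(E0 %*% basis$M, weeks - basis$x_mean)
  colnames(X) <- c(sprintf("tprs%d", seq_len(basis$k - 2L)), "week_lin")
  if (center && !is.null(basis$col_means)) X <- sweep(X, 2, basis$col_means)
  X
}
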