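#' Standardize calving number to the Legendre domain
#'
#' Maps a calving number (parity) linearly onto \eqn{[-1, 1]}, the domain of
#' the Legendre polynomial basis used by the random-regression model.
#'
#' @param cn Numeric vector of calving numbers.
#' @param cn_min,cn_max Range of the calving-number scale (defaults 1 and 9).
#' @return Numeric vector in \eqn{[-1, 1]}.
#' @examples
#' standardize_cn(c(1, 5, 9))
#' @export
standardize_cn <- function(cn, cn_min = 1, cn_max = 9) {
  if (cn_min >= cn_max) stop("cn_min must be < cn_max")
  if (any(cn < cn_min | cn > cn_max)) {
    stop("calving numbers outside [", cn_min, ", ", cn_max,
         "]: no extrapolation beyond the fitted trajectory")
  }
  -1 + 2 * (cn - cn_min) / (cn_max - cn_min)
}

#' Normalized Legendre polynomial basis
#'
#' Evaluates the first \code{r + 1} normalized (orthonormal on \eqn{[-1,1]})
#' Legendre polynomials \eqn{\phi_k(x) = \sqrt{(2k+1)/2}\, P_k(x)} at the
#' given points, with \eqn{P_k} from the standard three-term recurrence.
#' This is the basis conventionally used for random-regression test-day and
#' parity models.
#'
#' @param x Numeric vector with \eqn{|x| \le 1}.
#' @param r Polynomial order (non-negative integer).
#' @return Matrix with \code{length(x)} rows and \code{r + 1} columns; row i
#'   holds \eqn{\phi_0(x_i), \ldots, \phi_r(x_i)}.
#' @examples
#' legendre_basis(c(-1, 0, 1), 2)
#' @export
legendre_basis <- function(x, r) {
  stopifnot(r >= 0, r == as.integer(r))
  if (any(abs(x) > 1 + 1e-12)) stop("basis points must lie in [-1, 1]")
  x <- pmin(pmax(x, -1), 1)
  n <- length(x)
  P <- matrix(0, n, r + 1)
  P[, 1] <- 1
  if (r >= 1) P[, 2] <- x
  if (r >= 2) {
    for (k in 2:r) {
      # (k) P_k = (2k-1) x P_{k-1} - (k-1) P_{k-2}
      P[, k + 1] <- ((2 * k - 1) * x * P[, k] - (k - 1) * P[, k - 1]) / k
    }
  }
  norm <- sqrt((2 * (0:r) + 1) / 2)
  Phi <- sweep(P, 2, norm, "*")
  colnames(Phi) <- paste0("phi", 0:r)
  Phi
}

#' Legendre basis over the calving-number classes
#'
#' Convenience wrapper: the basis matrix evaluated at the integer calving
#' classes \code{cn_min:cn_max} after standardization.
#'
#' @inheritParams standardize_cn
#' @param r Polynomial order.
#' @return \code{(cn_max - cn_min + 1) x (r + 1)} matrix, rows named by
#'   calving number.
#' @export
cn_basis <- function(r = 2, cn_min = 1, cn_max = 9) {
  cn <- cn_min:cn_max
  Phi <- legendre_basis(standardize_cn(cn, cn_min, cn_max), r)
  rownames(Phi) <- cn
  Phi
}

#' Genetic variance at a trajectory point from the coefficient covariance
#'
#' The covariance function evaluated at one point: \eqn{\sigma^2_{a,i} =
#' \Phi_i K_a \Phi_i'} where \eqn{K_a} is the covariance matrix of the
#' random-regression coefficients (intercept, slope, quadratic) and
#' \eqn{\Phi_i} the basis row at calving i.
#'
#' @param Ka Symmetric \code{(r+1) x (r+1)} coefficient covariance matrix.
#' @param Phi_i Numeric basis row (length \code{r + 1}).
#' @return Scalar variance (non-negative for positive-definite \code{Ka}).
#' @export
covfun_variance <- function(Ka, Phi_i) {
  Phi_i <- as.numeric(Phi_i)
  stopifnot(length(Phi_i) == nrow(Ka), nrow(Ka) == ncol(Ka))
  drop(Phi_i %*% Ka %*% Phi_i)
}

#' Heritability at a trajectory point
#'
#' \eqn{h^2_i = \Phi_i K_a \Phi_i' / (\Phi_i K_a \Phi_i' + \sigma^2_p +
#' \sigma^2_{HYS} + \sigma^2_{e,i})}: the parity-specific genetic variance
#' over the parity-specific total, with scalar permanent-environment and
#' herd-year-season components and the residual variance of the parity's
#' residual class.
#'
#' @inheritParams covfun_variance
#' @param sigma_p2 Permanent environmental variance.
#' @param sigma_hys2 Herd-year-season variance.
#' @param sigma_e2_i Residual variance applying at this trajectory point.
#' @return Heritability in \eqn{[0, 1]}.
#' @export
trajectory_h2 <- function(Ka, Phi_i, sigma_p2, sigma_hys2, sigma_e2_i) {
  stopifnot(sigma_p2 >= 0, sigma_hys2 >= 0, sigma_e2_i >= 0)
  vg <- covfun_variance(Ka, Phi_i)
  tot <- vg + sigma_p2 + sigma_hys2 + sigma_e2_i
  if (tot <= 0) stop("total variance must be positive")
  vg / tot
}

#' Genetic correlation between two trajectory points
#'
#' \eqn{r_{g,ij} = \Phi_i K_a \Phi_j' / \sqrt{(\Phi_i K_a \Phi_i')(\Phi_j
#' K_a \Phi_j')}}. Returns \code{NA} when either point has zero genetic
#' variance.
#'
#' @inheritParams covfun_variance
#' @param Phi_j Basis row of the second point.
#' @return Correlation in \eqn{[-1, 1]}, or \code{NA}.
#' @export
genetic_correlation <- function(Ka, Phi_i, Phi_j) {
  vi <- covfun_variance(Ka, Phi_i)
  vj <- covfun_variance(Ka, Phi_j)
  if (vi <= 0 || vj <= 0) return(NA_real_)
  cij <- drop(as.numeric(Phi_i) %*% Ka %*% as.numeric(Phi_j))
  r <- cij / sqrt(vi * vj)
  min(1, max(-1, r))
}

#' Per-calving expected genetic values from regression coefficients
#'
#' \eqn{EGV_{mi} = \Phi_i a_m'}: an animal's additive-genetic trajectory,
#' obtained by evaluating its fitted coefficient vector at each calving.
#'
#' @param a_m Numeric coefficient vector (length \code{r + 1}) or a matrix
#'   with one row per animal.
#' @param Phi Basis matrix (one row per calving), e.g. \code{cn_basis(2)}.
#' @return Vector (one animal) or matrix (animals x calvings) of EGVs.
#' @export
egv_trajectory <- function(a_m, Phi) {
  if (is.null(dim(a_m))) {
    stopifnot(length(a_m) == ncol(Phi))
    return(drop(Phi %*% a_m))
  }
  stopifnot(ncol(a_m) == ncol(Phi))
  out <- a_m %*% t(Phi)
  colnames(out) <- rownames(Phi)
  out
}

#' Implied genetic covariance matrix across calvings
#'
#' \eqn{\Phi K_a \Phi'}: the full genetic (co)variance matrix over the
#' evaluated calvings (rank at most \code{r + 1}).
#'
#' @inheritParams egv_trajectory
#' @param Ka Coefficient covariance matrix.
#' @return Symmetric matrix, calvings x calvings.
#' @export
covfun_matrix <- function(Ka, Phi) {
  G <- Phi %*% Ka %*% t(Phi)
  dimnames(G) <- list(rownames(Phi), rownames(Phi))
  (G + t(G)) / 2
}
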