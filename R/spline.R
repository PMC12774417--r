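#' Cubic smoothing spline with the csaps convention
#'
#' Fits a natural cubic smoothing spline minimizing
#' \deqn{p \sum_i w_i (y_i - f(x_i))^2 + (1 - p) \int f''(t)^2 dt,}
#' the convention used by MATLAB's \code{csaps}: \code{p = 1} gives the
#' natural cubic interpolant, \code{p = 0} the weighted least-squares line.
#' All speed-domain fits in this package use this spline on the natural-log
#' speed axis with \code{p = 0.93}, the value that tracks speed tuning
#' without overfitting.
#'
#' The fit is the Reinsch / Green--Silverman solution: fitted knot values
#' \eqn{a = (pW + (1-p) Q R^{-1} Q^T)^{-1} p W y} with the usual
#' second-difference matrix \eqn{Q} and roughness matrix \eqn{R}; second
#' derivatives at interior knots are \eqn{R^{-1} Q^T a} (zero at the ends,
#' natural boundary). Evaluation outside the knot range extrapolates the
#' cubic polynomial of the end piece, as \code{fnval} does for a pp-form.
#'
#' @param x numeric vector of strictly increasing knot sites (the fit sorts
#'   and errors on duplicates).
#' @param y numeric responses, same length as \code{x}.
#' @param p smoothing parameter in \[0, 1\]; fidelity weight.
#' @param w optional positive observation weights (default all 1).
#' @return An object of class \code{"csaps"} with elements \code{x},
#'   \code{values} (fitted knot values), \code{d2} (second derivatives at
#'   the knots) and \code{p}.
#' @examples
#' x <- log(c(1.25, 2.5, 5, 10, 20, 40, 80))
#' y <- 5 + 45 * exp(-(x - log(10))^2 / 2)
#' f <- csaps_fit(x, y, p = 0.93)
#' predict(f, log(10))
#' @export
csaps_fit <- function(x, y, p = 0.93, w = NULL) {
  if (length(x) != length(y)) stop("x and y must have the same length")
  if (anyNA(x) || anyNA(y) || any(!is.finite(x)) || any(!is.finite(y)))
    stop("x and y must be finite")
  if (length(p) != 1L || is.na(p) || p < 0 || p > 1)
    stop("p must be a single value in [0, 1]")
  ord <- order(x)
  x <- x[ord]; y <- y[ord]
  if (is.null(w)) w <- rep(1, length(x)) else {
    if (any(w <= 0)) stop("weights must be positive")
    w <- w[ord]
  }
  n <- length(x)
  if (n < 2L) stop("need at least 2 points")
  if (any(diff(x) <= 0)) stop("x values must be distinct")

  if (n == 2L || p == 0) {
    # least-squares line through the (weighted) points
    fit <- stats::lm.wfit(cbind(1, x), y, w)
    a <- fit$fitted.values
    # a line is its own natural "spline": zero curvature everywhere
    obj <- list(x = x, values = as.numeric(a), d2 = rep(0, n), p = p)
    class(obj) <- "csaps"
    return(obj)
  }

  h <- diff(x)
  # Q: n x (n-2), R: (n-2) x (n-2), Green & Silverman (1994) ch. 2
  m <- n - 2L
  Q <- matrix(0, n, m)
  R <- matrix(0, m, m)
  for (j in seq_len(m)) {
    Q[j, j]     <- 1 / h[j]
    Q[j + 1, j] <- -1 / h[j] - 1 / h[j + 1]
    Q[j + 2, j] <- 1 / h[j + 1]
    R[j, j] <- (h[j] + h[j + 1]) / 3
    if (j < m) {
      R[j, j + 1] <- h[j + 1] / 6
      R[j + 1, j] <- h[j + 1] / 6
    }
  }
  K <- Q %*% solve(R, t(Q))        # roughness: int f''^2 = a' K a
  A <- p * diag(w) + (1 - p) * K
  a <- solve(A, p * w * y)
  d2 <- c(0, solve(R, crossprod(Q, a)), 0)
  obj <- list(x = x, values = as.numeric(a), d2 = as.numeric(d2), p = p)
  class(obj) <- "csaps"
  obj
}

#' Evaluate a fitted smoothing spline
#'
#' @param object a \code{"csaps"} fit.
#' @param xout sites at which to evaluate.
#' @param ... unused.
#' @return numeric vector of spline values at \code{xout}.
#' @export
predict.csaps <- function(object, xout, ...) {
  x <- object$x; a <- object$values; M <- object$d2
  n <- length(x)
  # interval index; sites beyond the range use the end polynomial
  i <- findInterval(xout, x, all.inside = TRUE)
  h <- x[i + 1] - x[i]
  A <- (x[i + 1] - xout) / h
  B <- (xout - x[i]) / h
  A * a[i] + B * a[i + 1] +
    ((A^3 - A) * M[i] + (B^3 - B) * M[i + 1]) * h^2 / 6
}

#' Linear-operator form of the smoothing spline
#'
#' The smoothing spline is a linear smoother: for fixed sites \code{x},
#' smoothing parameter \code{p} and evaluation sites \code{xout}, the map
#' from observations \code{y} to spline values at \code{xout} is a matrix
#' \code{H} with \code{H \%*\% y == predict(csaps_fit(x, y, p), xout)}.
#' The decoder uses this to precompute population smoothing once and then
#' score hundreds of thousands of candidate speed distributions as cheap
#' matrix-vector products.
#'
#' @inheritParams csaps_fit
#' @param xout evaluation sites.
#' @return a \code{length(xout)} by \code{length(x)} matrix.
#' @export
csaps_operator <- function(x, p = 0.93, xout, w = NULL) {
  ord <- order(x)
  xs <- x[ord]
  n <- length(xs)
  if (n < 2L) stop("need at least 2 points")
  if (any(diff(xs) <= 0)) stop("x values must be distinct")
  if (is.null(w)) w <- rep(1, n) else w <- w[ord]

  if (n == 2L || p == 0) {
    X <- cbind(1, xs)
    Smat <- X %*% solve(crossprod(X, w * X), t(X * w))  # hat matrix of the line
    D2 <- matrix(0, n, n)
  } else {
    h <- diff(xs)
    m <- n - 2L
    Q <- matrix(0, n, m)
    R <- matrix(0, m, m)
    for (j in seq_len(m)) {
      Q[j, j]     <- 1 / h[j]
      Q[j + 1, j] <- -1 / h[j] - 1 / h[j + 1]
      Q[j + 2, j] <- 1 / h[j + 1]
      R[j, j] <- (h[j] + h[j + 1]) / 3
      if (j < m) {
        R[j, j + 1] <- h[j + 1] / 6
        R[j + 1, j] <- h[j + 1] / 6
      }
    }
    K <- Q %*% solve(R, t(Q))
    Smat <- solve(p * diag(w) + (1 - p) * K, p * diag(w, n))  # y -> fitted knot values
    D2 <- rbind(0, solve(R, crossprod(Q, Smat)), 0)           # y -> knot 2nd derivs
  }

  i <- findInterval(xout, xs, all.inside = TRUE)
  hh <- xs[i + 1] - xs[i]
  A <- (xs[i + 1] - xout) / hh
  B <- (xout - xs[i]) / hh
  # f(xout) = A*a_i + B*a_{i+1} + ((A^3-A) M_i + (B^3-B) M_{i+1}) h^2/6, linear in y
  H <- A * Smat[i, , drop = FALSE] + B * Smat[i + 1, , drop = FALSE] +
    ((A^3 - A) * hh^2 / 6) * D2[i, , drop = FALSE] +
    ((B^3 - B) * hh^2 / 6) * D2[i + 1, , drop = FALSE]
  H[, order(ord), drop = FALSE]  # columns back in input order
}
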