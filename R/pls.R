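# Univariate-response partial least squares (SIMPLS). This is the linear
# learner inside the spectral ensemble; it returns cumulative regression
# coefficients for every component count so nested cross-validation can
# score the whole component grid from a single fit.

#' Fit a PLS1 regression (SIMPLS)
#'
#' @param X numeric matrix, observations x variables.
#' @param y numeric response (class labels coded 0/1 for classification).
#' @param ncomp maximum number of latent components.
#' @return object of class `pls1` with per-component coefficient columns
#'   `B`, the centering constants, and `ncomp` (the number of components
#'   actually extracted; deflation can exhaust the signal earlier).
#' @export
pls1_fit <- function(X, y, ncomp) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), ncomp >= 1)
  ncomp <- min(ncomp, nrow(X) - 1L, ncol(X))
  xm <- colMeans(X)
  ym <- mean(y)
  Xc <- sweep(X, 2L, xm, "-")
  yc <- y - ym
  p <- ncol(X)
  s <- crossprod(Xc, yc)
  V <- matrix(0, p, ncomp)
  B <- matrix(0, p, ncomp)
  b <- numeric(p)
  a_used <- 0L
  for (a in seq_len(ncomp)) {
    r <- s
    t <- Xc %*% r
    nt <- sqrt(sum(t^2))
    if (!is.finite(nt) || nt < 1e-10) break
    t <- t / nt
    r <- r / nt
    pv <- crossprod(Xc, t)
    qa <- sum(yc * t)
    v <- pv
    if (a > 1L) {
      Vp <- V[, seq_len(a - 1L), drop = FALSE]
      v <- v - Vp %*% crossprod(Vp, pv)
    }
    nv <- sqrt(sum(v^2))
    if (nv < 1e-10) break
    v <- v / nv
    s <- s - v %*% crossprod(v, s)
    b <- b + r * qa
    V[, a] <- v
    B[, a] <- b
    a_used <- a
  }
  if (a_used == 0L) stop("PLS fit degenerate: no usable component", call. = FALSE)
  structure(list(xmeans = xm, ymean = ym,
                 B = B[, seq_len(a_used), drop = FALSE], ncomp = a_used),
            class = "pls1")
}

#' Predict from a PLS1 fit
#'
#' @param object a [pls1_fit()] result.
#' @param newdata matrix of new observations on the same variables.
#' @param ncomp component count to use (defaults to all extracted); may be a
#'   vector, in which case a matrix with one column per requested count is
#'   returned.
#' @param ... unused.
#' @return numeric predictions (vector, or matrix for vector `ncomp`).
#' @export
predict.pls1 <- function(object, newdata, ncomp = object$ncomp, ...) {
  stopifnot(all(ncomp >= 1), all(ncomp <= object$ncomp))
  Xc <- sweep(as.matrix(newdata), 2L, object$xmeans, "-")
  out <- object$ymean + Xc %*% object$B[, ncomp, drop = FALSE]
  if (length(ncomp) == 1L) drop(out) else out
}
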