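#' @keywords internal
"_PACKAGE"

#' @importFrom methods as is
#' @importFrom stats runif
#' @importFrom utils modifyList read.table write.table packageVersion
NULL

## 24-point Gauss-Legendre nodes/weights on [-1, 1], computed once at load
## time by Newton iteration on the Legendre polynomial.
.gl24 <- local({
  n <- 24L
  legendre <- function(x) {            # P_n(x), P_{n-1}(x)
    p0 <- rep(1, length(x)); p1 <- x
    for (j in 2:n) {
      p2 <- ((2 * j - 1) * x * p1 - (j - 1) * p0) / j
      p0 <- p1; p1 <- p2
    }
    list(p = p1, pm1 = p0)
  }
  x <- cos(pi * (seq_len(n) - 0.25) / (n + 0.5))
  for (it in 1:100) {
    lg <- legendre(x)
    dp <- n * (x * lg$p - lg$pm1) / (x^2 - 1)
    dx <- lg$p / dp
    x <- x - dx
    if (max(abs(dx)) < 1e-15) break
  }
  lg <- legendre(x)
  dp <- n * (x * lg$p - lg$pm1) / (x^2 - 1)
  list(nodes = x, weights = 2 / ((1 - x^2) * dp^2))
})

## Integrate f over [a, b] with composite 24-point Gauss-Legendre on
## `panels` equal panels. f must be vectorized.
gauss_quad <- function(f, a, b, panels = 1L) {
  edges <- seq(a, b, length.out = panels + 1L)
  total <- 0
  for (p in seq_len(panels)) {
    lo <- edges[p]; hi <- edges[p + 1L]
    xm <- 0.5 * (hi + lo); xr <- 0.5 * (hi - lo)
    total <- total + xr * sum(.gl24$weights * f(xm + xr * .gl24$nodes))
  }
  total
}

#' Sine integral Si(x)
#'
#' \eqn{Si(x) = \int_0^x \sin(t)/t \, dt}, evaluated by composite
#' Gauss-Legendre quadrature with one panel per half-period, which is
#' accurate to close to machine precision for the argument ranges used by
#' the sinc machinery (integer multiples of \eqn{\pi}).
#'
#' @param x numeric vector.
#' @return numeric vector of the same length.
#' @export
sine_integral <- function(x) {
  f <- function(t) ifelse(t == 0, 1, sin(t) / t)
  vapply(x, function(xi) {
    if (xi == 0) return(0)
    s <- sign(xi); ax <- abs(xi)
    s * gauss_quad(f, 0, ax, panels = max(1L, ceiling(ax / pi)))
  }, numeric(1))
}

## Run expr with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Restarted GMRES for a real linear operator
#'
#' Solves \code{Amul(x) = b} for a real-valued linear operator given as a
#' function, by restarted GMRES with Givens rotations.  Used for the
#' real-linear D-bar collocation system, where the operator is real-linear
#' (but not complex-linear) in the stacked real/imaginary representation.
#'
#' @param Amul function taking and returning a numeric vector.
#' @param b right-hand side vector.
#' @param x0 initial guess (default zero).
#' @param tol relative residual tolerance.
#' @param restart Krylov subspace dimension before restart.
#' @param maxit maximum total iterations.
#' @return list with \code{x}, \code{converged}, \code{iterations},
#'   \code{residual} (relative).
#' @export
gmres <- function(Amul, b, x0 = NULL, tol = 1e-5, restart = 30L,
                  maxit = 200L) {
  n <- length(b)
  x <- if (is.null(x0)) numeric(n) else x0
  bnorm <- sqrt(sum(b^2))
  if (bnorm == 0) {
    return(list(x = numeric(n), converged = TRUE, iterations = 0L,
                residual = 0))
  }
  total_it <- 0L
  repeat {
    r <- b - Amul(x)
    beta <- sqrt(sum(r^2))
    if (beta / bnorm <= tol) {
      return(list(x = x, converged = TRUE, iterations = total_it,
                  residual = beta / bnorm))
    }
    m <- min(restart, maxit - total_it)
    if (m <= 0L) {
      return(list(x = x, converged = FALSE, iterations = total_it,
                  residual = beta / bnorm))
    }
    V <- matrix(0, n, m + 1L)
    H <- matrix(0, m + 1L, m)
    cs <- numeric(m); sn <- numeric(m)
    g <- numeric(m + 1L); g[1L] <- beta
    V[, 1L] <- r / beta
    k_used <- 0L
    for (k in seq_len(m)) {
      w <- Amul(V[, k])
      for (i in seq_len(k)) {        # modified Gram-Schmidt
        H[i, k] <- sum(w * V[, i])
        w <- w - H[i, k] * V[, i]
      }
      H[k + 1L, k] <- sqrt(sum(w^2))
      if (H[k + 1L, k] > 1e-14 * beta) V[, k + 1L] <- w / H[k + 1L, k]
      for (i in seq_len(k - 1L)) {   # apply previous rotations
        t1 <- cs[i] * H[i, k] + sn[i] * H[i + 1L, k]
        H[i + 1L, k] <- -sn[i] * H[i, k] + cs[i] * H[i + 1L, k]
        H[i, k] <- t1
      }
      d <- sqrt(H[k, k]^2 + H[k + 1L, k]^2)
      cs[k] <- H[k, k] / d; sn[k] <- H[k + 1L, k] / d
      H[k, k] <- d; H[k + 1L, k] <- 0
      g[k + 1L] <- -sn[k] * g[k]
      g[k] <- cs[k] * g[k]
      total_it <- total_it + 1L
      k_used <- k
      if (abs(g[k + 1L]) / bnorm <= tol || total_it >= maxit) break
    }
    y <- backsolve(H[seq_len(k_used), seq_len(k_used), drop = FALSE],
                   g[seq_len(k_used)])
    x <- x + V[, seq_len(k_used), drop = FALSE] %*% y
    x <- drop(x)
    res <- abs(g[k_used + 1L]) / bnorm
    if (res <= tol) {
      ## confirm with a true residual (guards against loss of orthogonality)
      true_res <- sqrt(sum((b - Amul(x))^2)) / bnorm
      if (true_res <= 10 * tol) {
        return(list(x = x, converged = TRUE, iterations = total_it,
                    residual = true_res))
      }
    }
    if (total_it >= maxit) {
      return(list(x = x, converged = FALSE, iterations = total_it,
                  residual = sqrt(sum((b - Amul(x))^2)) / bnorm))
    }
  }
}

## small assertion helper used across the package
stopf <- function(...) stop(sprintf(...), call. = FALSE)
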