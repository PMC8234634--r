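#' Fleishman power-method coefficients
#'
#' The Fleishman method represents a standardized non-normal variable as a
#' cubic polynomial of a standard normal deviate,
#' \deqn{Y = a + bZ + cZ^2 + dZ^3, \quad Z \sim N(0,1),}
#' with coefficients chosen so that Y has mean 0, variance 1 and prescribed
#' skewness and excess kurtosis. Zero mean forces `a = -c`; the remaining
#' three moment equations in (b, c, d) are
#' \deqn{b^2 + 6bd + 2c^2 + 15d^2 = 1}
#' \deqn{2c(b^2 + 24bd + 105d^2 + 2) = \gamma_1}
#' \deqn{24[bd + c^2(1 + b^2 + 28bd) + d^2(12 + 48bd + 141c^2 + 225d^2)] = \gamma_2}
#'
#' The system is multi-modal, so it is solved by damped Newton iteration with
#' a numerical Jacobian from several starting points; sign-symmetric solutions
#' ((b,c,d) and (-b,c,-d) solve the same system) are resolved to `b > 0`.
#'
#' @name fleishman
NULL

# Residuals of the three Fleishman moment equations at (b, c, d)
fleishman_residual <- function(bcd, skewness, excess_kurtosis) {
  b <- bcd[1]; c <- bcd[2]; d <- bcd[3]
  c(b^2 + 6 * b * d + 2 * c^2 + 15 * d^2 - 1,
    2 * c * (b^2 + 24 * b * d + 105 * d^2 + 2) - skewness,
    24 * (b * d + c^2 * (1 + b^2 + 28 * b * d) +
            d^2 * (12 + 48 * b * d + 141 * c^2 + 225 * d^2)) - excess_kurtosis)
}

# Damped Newton with forward-difference Jacobian from one start point.
# Returns list(par, resid_norm, converged).
fleishman_newton <- function(start, skewness, excess_kurtosis,
                             tol = 1e-12, max_iter = 200) {
  x <- start
  f <- fleishman_residual(x, skewness, excess_kurtosis)
  for (it in seq_len(max_iter)) {
    nf <- sqrt(sum(f^2))
    if (nf < tol) break
    J <- matrix(0, 3, 3)
    h <- 1e-7
    for (j in 1:3) {
      xh <- x
      xh[j] <- xh[j] + h
      J[, j] <- (fleishman_residual(xh, skewness, excess_kurtosis) - f) / h
    }
    step <- tryCatch(solve(J, f), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    lambda <- 1
    improved <- FALSE
    for (k in 1:30) {
      xn <- x - lambda * step
      fn <- fleishman_residual(xn, skewness, excess_kurtosis)
      if (all(is.finite(fn)) && sqrt(sum(fn^2)) < nf) {
        x <- xn
        f <- fn
        improved <- TRUE
        break
      }
      lambda <- lambda / 2
    }
    if (!improved) break
  }
  nf <- sqrt(sum(f^2))
  list(par = x, resid_norm = nf, converged = nf < 1e-8)
}

# Stated multi-start grid: identity transform plus perturbations spanning the
# skewed/heavy-tailed branch of the solution surface.
fleishman_starts <- function(skewness, excess_kurtosis) {
  c0 <- skewness / 6
  d0 <- excess_kurtosis / 48
  starts <- list(
    c(1, 0, 0),
    c(1, c0, d0),
    c(0.9, c0, 0.05),
    c(0.8, c0 / 2, 0.15),
    c(0.5, c0, 0.25),
    c(1.1, c0, -0.05),
    c(0.95, 0.1 * sign(skewness + 1e-12), 0.01)
  )
  starts
}

#' Solve the Fleishman moment system
#'
#' @param skewness target skewness (gamma1, dimensionless).
#' @param excess_kurtosis target excess kurtosis (gamma2, dimensionless).
#' @return a `fleishman_coef` object: list with elements `a`, `b`, `c`, `d`.
#'   `a = -c` always; among the sign-symmetric pair the solution with `b > 0`
#'   is returned.
#' @seealso [fleishman_feasible()]
#' @export
solve_fleishman <- function(skewness, excess_kurtosis) {
  assert_scalar(skewness)
  assert_scalar(excess_kurtosis)
  if (skewness == 0 && excess_kurtosis == 0) {
    return(structure(list(a = 0, b = 1, c = 0, d = 0),
                     class = "fleishman_coef"))
  }
  best <- NULL
  for (s in fleishman_starts(skewness, excess_kurtosis)) {
    fit <- fleishman_newton(s, skewness, excess_kurtosis)
    if (is.null(best) || fit$resid_norm < best$resid_norm) best <- fit
    if (fit$converged) break
  }
  if (!best$converged) {
    stop(sprintf(
      "Fleishman system infeasible for (skewness = %g, excess kurtosis = %g)",
      skewness, excess_kurtosis), call. = FALSE)
  }
  b <- best$par[1]; c <- best$par[2]; d <- best$par[3]
  if (b < 0) { # sign-symmetric twin
    b <- -b
    d <- -d
  }
  structure(list(a = -c, b = b, c = c, d = d), class = "fleishman_coef")
}

#' Is a (skewness, excess kurtosis) pair attainable by the Fleishman cubic?
#'
#' Total function: `TRUE` iff the moment system admits a real solution with
#' residual norm below 1e-8 from at least one of the solver's starting points.
#'
#' @inheritParams solve_fleishman
#' @return logical scalar.
#' @export
fleishman_feasible <- function(skewness, excess_kurtosis) {
  ok <- tryCatch({
    solve_fleishman(skewness, excess_kurtosis)
    TRUE
  }, error = function(e) FALSE)
  ok
}

#' Apply a Fleishman polynomial to standard-normal draws
#'
#' @param coef a `fleishman_coef` object.
#' @param z numeric vector (or matrix) of standard-normal values.
#' @return transformed values, same shape as `z`.
#' @export
fleishman_transform <- function(coef, z) {
  stopifnot(inherits(coef, "fleishman_coef"))
  coef$a + coef$b * z + coef$c * z^2 + coef$d * z^3
}

#' @exportS3Method base::print
print.fleishman_coef <- function(x, ...) {
  cat(sprintf("Fleishman coefficients: a=%.6f b=%.6f c=%.6f d=%.6f\n",
              x$a, x$b, x$c, x$d))
  invisible(x)
}
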