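#' @importFrom stats fft rnorm runif sd
#' @importFrom withr with_seed
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_osteo <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "osteorient_error")))
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         integer = FALSE, strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_osteo(sprintf("'%s' must be a single finite number", name),
               "validation_error")
  if (x < lower || (strict_lower && x == lower) || x > upper)
    stop_osteo(sprintf("'%s' = %g is out of range [%g, %g]", name, x,
                       lower, upper), "validation_error")
  if (integer && x != round(x))
    stop_osteo(sprintf("'%s' must be an integer", name), "validation_error")
  invisible(x)
}

#' Sample from a von Mises distribution
#'
#' Best-Fisher rejection sampler. Used internally to draw fiber orientations
#' on the doubled-angle circle; exported because it is convenient when
#' constructing custom orientation scenarios.
#'
#' @param n number of draws.
#' @param mu mean direction in radians.
#' @param kappa concentration (>= 0); 0 gives the uniform circular
#'   distribution.
#' @return numeric vector of angles in \code{[0, 2*pi)}.
#' @export
rvonmises <- function(n, mu, kappa) {
  check_scalar(n, "n", lower = 0, integer = TRUE)
  check_scalar(kappa, "kappa", lower = 0)
  if (kappa == 0) return(runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      cc <- kappa * (r - f)
      if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
        out[i] <- (mu + sign(u[3] - 0.5) * acos(f)) %% (2 * pi)
        break
      }
    }
  }
  out
}
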