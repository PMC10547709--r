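#' Wrap angles to (-pi, pi]
#'
#' Angles are mapped to the half-open interval (-pi, pi]; values that land
#' exactly on -pi are mapped to +pi, so a full reversal always reads +pi.
#'
#' @param x Numeric vector of angles in radians.
#' @return Numeric vector of the same length in (-pi, pi].
#' @export
#' @examples
#' wrap_angle(c(3 * pi / 2, -pi, 4 * pi))
wrap_angle <- function(x) {
  a <- atan2(sin(x), cos(x))
  a[a <= -pi + 1e-12] <- pi
  a
}

#' Von Mises density
#'
#' Density of the von Mises distribution with mean direction `mu` and
#' concentration `kappa`, using the modified Bessel function of order 0.
#' `kappa = 0` gives the uniform circular density `1 / (2 * pi)`.
#'
#' @param x Angles in radians.
#' @param mu Mean direction (radians).
#' @param kappa Concentration, `>= 0`.
#' @param log Return the log density?
#' @return Numeric vector of (log) densities.
#' @export
dvonmises <- function(x, mu, kappa, log = FALSE) {
  stopifnot(all(kappa >= 0))
  ld <- kappa * cos(x - mu) - log(2 * pi) - log(besselI(kappa, 0, expon.scaled = TRUE)) - kappa
  if (log) ld else exp(ld)
}

#' Von Mises random deviates
#'
#' Best & Fisher (1979) rejection sampler; exact for any `kappa >= 0`.
#'
#' @param n Number of draws.
#' @param mu Mean direction (radians).
#' @param kappa Concentration, `>= 0`.
#' @return `n` angles in (-pi, pi].
#' @export
rvonmises <- function(n, mu, kappa) {
  stopifnot(length(mu) == 1, length(kappa) == 1, kappa >= 0)
  if (kappa < 1e-10) {
    return(wrap_angle(runif(n, -pi, pi)))
  }
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- runif(m); u2 <- runif(m); u3 <- runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    keep <- (c0 * (2 - c0) - u2 > 0) | (log(c0 / u2) + 1 - c0 >= 0)
    th <- sign(u3[keep] - 0.5) * acos(f[keep])
    take <- seq_len(min(length(th), m))
    out[got + take] <- th[take]
    got <- got + length(take)
  }
  wrap_angle(out + mu)
}

# gamma (mean, sd) <-> (shape, scale)
gamma_shape <- function(mean, sd) (mean / sd)^2
gamma_scale <- function(mean, sd) sd^2 / mean

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# row-wise softmax of a matrix of linear scores
softmax_rows <- function(m) {
  mm <- m - apply(m, 1, max)
  e <- exp(mm)
  e / rowSums(e)
}

assert_cols <- function(df, cols, what = deparse(substitute(df))) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0) {
    abort(sprintf("%s is missing required column(s): %s", what,
                  paste(miss, collapse = ", ")))
  }
  invisible(df)
}
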