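# Synthetic division-angle samples: uniform on [0, 90] degrees, or an
# axially folded von Mises ("concentrated") distribution for oriented
# division scenarios.

# Best & Fisher (1979) rejection sampler for the von Mises distribution,
# centred at 0, concentration kappa, values in (-pi, pi].
rvonmises0 <- function(n, kappa) {
  if (kappa < 1e-8) return(runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1
  while (i <= n) {
    u1 <- runif(1); u2 <- runif(1); u3 <- runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      out[i] <- sign(u3 - 0.5) * acos(pmin(1, pmax(-1, f)))
      i <- i + 1
    }
  }
  out
}

#' Generate synthetic division angles
#'
#' @param n number of angles (>= 1).
#' @param distribution `"uniform"` (uniform on `[0, 90]` degrees) or
#'   `"concentrated"` (von Mises around `mu`, folded axially into
#'   `[0, 90]`).
#' @param mu centre of the concentrated distribution, degrees.
#' @param kappa von Mises concentration (larger = tighter).
#' @param seed integer seed.
#' @return numeric vector of angles in degrees, all in `[0, 90]`, with the
#'   distribution parameters attached as attributes.
#' @export
generate_division_angles <- function(n, distribution = c("uniform", "concentrated"),
                                     mu = 0, kappa = 8, seed = 1) {
  distribution <- match.arg(distribution)
  assert_that(is_count(n) && n >= 1, "n must be a positive count")
  ang <- with_seed(seed, {
    if (distribution == "uniform") runif(n, 0, 90)
    else {
      assert_that(kappa >= 0, "kappa must be >= 0")
      raw <- rvonmises0(n, kappa) * 180 / pi + mu
      fold <- abs(raw) %% 180
      ifelse(fold > 90, 180 - fold, fold)
    }
  })
  attr(ang, "distribution") <- distribution
  if (distribution == "concentrated") {
    attr(ang, "mu") <- mu
    attr(ang, "kappa") <- kappa
  }
  attr(ang, "seed") <- seed
  ang
}
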