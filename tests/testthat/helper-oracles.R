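# Independent numerical oracles, kept deliberately naive: they integrate
# densities on grids rather than reusing any closed form from the package.

# 2.5th percentile of log2(lambda) where lambda*(E+0.5) ~ Gamma(a+0.5),
# by trapezoid integration of the gamma density.
ic025_quadrature <- function(a, E, p = 0.025) {
  shape <- a + 0.5
  rate <- E + 0.5
  hi <- qgamma(1 - 1e-10, shape = shape, rate = rate)
  lo <- qgamma(1e-12, shape = shape, rate = rate)
  x <- exp(seq(log(max(lo, 1e-12)), log(hi), length.out = 400000L))
  f <- dgamma(x, shape = shape, rate = rate)
  w <- diff(x)
  cum <- c(0, cumsum((f[-1] + f[-length(f)]) / 2 * w))
  cum <- cum / cum[length(cum)]
  log2(stats::approx(cum, x, xout = p, ties = "ordered")$y)
}

# 5th percentile of the posterior over lambda given a ~ Poisson(lambda*E)
# under a 2-component gamma mixture prior, via grid integration of
# prior(lambda) * likelihood(lambda) -- does not use conjugacy.
ebgm05_quadrature <- function(a, E, prior, p = 0.05) {
  center <- max((a + prior$alpha1) / (E + prior$beta1),
                (a + prior$alpha2) / (E + prior$beta2), 1e-8)
  lo <- center / 1e4
  hi <- center * 1e4
  x <- exp(seq(log(lo), log(hi), length.out = 400000L))
  logpri <- log(prior$P * dgamma(x, prior$alpha1, rate = prior$beta1) +
                  (1 - prior$P) * dgamma(x, prior$alpha2, rate = prior$beta2))
  loglik <- dpois(a, x * E, log = TRUE)
  lf <- logpri + loglik
  lf <- lf - max(lf[is.finite(lf)])
  f <- exp(lf)
  w <- diff(x)
  cum <- c(0, cumsum((f[-1] + f[-length(f)]) / 2 * w))
  cum <- cum / cum[length(cum)]
  stats::approx(cum, x, xout = p, ties = "ordered")$y
}

# Posterior geometric mean by the same grid route.
ebgm_quadrature <- function(a, E, prior) {
  center <- max((a + prior$alpha1) / (E + prior$beta1),
                (a + prior$alpha2) / (E + prior$beta2), 1e-8)
  x <- exp(seq(log(center / 1e4), log(center * 1e4), length.out = 400000L))
  logpri <- log(prior$P * dgamma(x, prior$alpha1, rate = prior$beta1) +
                  (1 - prior$P) * dgamma(x, prior$alpha2, rate = prior$beta2))
  lf <- logpri + dpois(a, x * E, log = TRUE)
  lf <- lf - max(lf[is.finite(lf)])
  f <- exp(lf)
  w <- diff(x)
  mids <- (f[-1] + f[-length(f)]) / 2
  z <- sum(mids * w)
  exp(sum(mids * w * (log(x[-1]) + log(x[-length(x)])) / 2) / z)
}
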