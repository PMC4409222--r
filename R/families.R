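#' Normal/independent error families
#'
#' An N/I random variable is a scale mixture of normals,
#' \eqn{Y = \mu + e/\sqrt{u}}, where \eqn{e \sim N(0, \sigma)} and the
#' mixing variable \eqn{u > 0} has density (or mass) \eqn{g(u; \nu)}.
#' Conditional on \eqn{u}, \eqn{Y \sim N(\mu, \sigma/u)}, so small mixing
#' values inflate the variance and produce heavy tails.  The five members
#' supported here and their mixing laws are
#' \describe{
#'   \item{normal}{\eqn{u \equiv 1} (no shape parameter).}
#'   \item{t}{\eqn{u \sim \Gamma(v/2, v/2)} (shape/rate), \eqn{v > 0} the
#'     degrees of freedom; marginally Student t.}
#'   \item{slash}{\eqn{u \sim \mathrm{Beta}(v, 1)}, \eqn{v > 0}; polynomial
#'     tails.}
#'   \item{contaminated normal}{\eqn{u = \gamma} with probability
#'     \eqn{\lambda} and \eqn{u = 1} otherwise, \eqn{\lambda, \gamma \in
#'     (0,1)}; a fraction \eqn{\lambda} of observations have variance
#'     \eqn{\sigma/\gamma}.}
#'   \item{laplace}{\eqn{1/u \sim \mathrm{Exp}(v)}, i.e.
#'     \eqn{g(u) = v u^{-2} e^{-v/u}}; marginally Laplace (double
#'     exponential).}
#' }
#'
#' @param family One of `"normal"`, `"t"`, `"slash"`, `"cn"`, `"laplace"`.
#' @param shape Numeric vector of shape parameters: `t` degrees of freedom
#'   (> 0), slash exponent (> 0), contaminated normal `c(lambda, gamma)`
#'   (each in (0,1)), Laplace rate (> 0).  Empty for `"normal"`.
#' @return An object of class `nid_family`.
#' @examples
#' nid_family("cn", c(0.1, 0.25))
#' nid_family("t", 4)
#' @export
nid_family <- function(family = c("normal", "t", "slash", "cn", "laplace"),
                       shape = numeric()) {
  family <- match.arg(family)
  shape <- as.numeric(shape)
  defaults <- list(normal = numeric(), t = 5, slash = 2,
                   cn = c(0.5, 0.5), laplace = 1)
  if (length(shape) == 0L) shape <- defaults[[family]]
  switch(family,
    normal = if (length(shape) != 0L)
      stop("the normal family carries no shape parameter"),
    t = if (length(shape) != 1L || shape <= 0)
      stop("t degrees of freedom must be a single value > 0"),
    slash = if (length(shape) != 1L || shape <= 0)
      stop("slash exponent must be a single value > 0"),
    cn = if (length(shape) != 2L || any(shape <= 0) || any(shape >= 1))
      stop("contaminated normal needs (lambda, gamma), each in (0,1)"),
    laplace = if (length(shape) != 1L || shape <= 0)
      stop("Laplace rate must be a single value > 0"))
  structure(list(family = family, shape = unname(shape)),
            class = "nid_family")
}

#' @export
print.nid_family <- function(x, ...) {
  lab <- c(normal = "normal", t = "Student t", slash = "slash",
           cn = "contaminated normal", laplace = "Laplace")[[x$family]]
  cat("<nid_family> ", lab, sep = "")
  if (length(x$shape))
    cat(" (", paste(signif(x$shape, 4), collapse = ", "), ")", sep = "")
  cat("\n")
  invisible(x)
}

# integer codes shared with src/gibbs.cpp
family_code <- function(spec) {
  match(spec$family, c("normal", "t", "slash", "cn", "laplace")) - 1L
}

stopifnot_family <- function(spec) {
  if (!inherits(spec, "nid_family")) stop("`spec` must be an nid_family")
  invisible(spec)
}

#' Mixing density of an N/I family
#'
#' Density (for t, slash, Laplace) or probability mass (for the contaminated
#' normal and the degenerate normal) of the latent scale \eqn{u} at `u`.
#'
#' @param u Positive mixing values.
#' @param spec An [nid_family()].
#' @return Nonnegative densities/masses, one per element of `u`.
#' @export
nid_mixing_density <- function(u, spec) {
  stopifnot_family(spec)
  if (any(u <= 0)) stop("mixing values must be positive")
  s <- spec$shape
  switch(spec$family,
    normal = as.numeric(u == 1),
    t = dgamma(u, shape = s / 2, rate = s / 2),
    slash = ifelse(u < 1, s * u^(s - 1), 0),
    cn = ifelse(u == s[2], s[1], ifelse(u == 1, 1 - s[1], 0)),
    laplace = s * u^(-2) * exp(-s / u))
}

#' Marginal N/I density
#'
#' Marginal density \eqn{f(y \mid \mu, \sigma, \nu) = \int_0^\infty
#' \phi(y; \mu, \sigma/u)\, dG(u; \nu)}.  Closed forms are used for the
#' normal, t, contaminated normal and Laplace members; the slash density is
#' evaluated by adaptive quadrature over \eqn{u \in (0, 1)}.
#'
#' @param y Numeric vector of evaluation points.
#' @param mu Location.
#' @param sigma Scale, the conditional variance at \eqn{u = 1} (> 0).
#' @param spec An [nid_family()].
#' @return Densities at `y`.
#' @details The slash integral \eqn{v\int_0^1 u^{v-1/2}\phi(y;\mu,\sigma/u)du}
#'   reduces to a lower incomplete gamma function, which is used directly
#'   (equivalent to, but far more stable than, adaptive quadrature in the
#'   far tails).
#' @export
dnid <- function(y, mu, sigma, spec) {
  stopifnot_family(spec)
  if (sigma <= 0) stop("sigma must be positive")
  s <- spec$shape
  sd0 <- sqrt(sigma)
  switch(spec$family,
    normal = dnorm(y, mu, sd0),
    t = dt((y - mu) / sd0, df = s) / sd0,
    cn = s[1] * dnorm(y, mu, sqrt(sigma / s[2])) +
         (1 - s[1]) * dnorm(y, mu, sd0),
    laplace = {
      b <- sqrt(sigma / (2 * s))
      exp(-abs(y - mu) / b) / (2 * b)
    },
    slash = {
      # v/sqrt(2 pi sigma) * gamma_lower(v + 1/2, z^2/2) / (z^2/2)^(v+1/2)
      z2h <- (y - mu)^2 / (2 * sigma)
      a <- s + 0.5
      out <- numeric(length(y))
      tiny <- z2h < 1e-30
      out[tiny] <- s / (a * sqrt(2 * pi * sigma))
      zz <- z2h[!tiny]
      out[!tiny] <- s / sqrt(2 * pi * sigma) * gamma(a) *
        pgamma(zz, a) * exp(-a * log(zz))
      out
    })
}

#' Sample from an N/I distribution
#'
#' Draws via the scale-mixture representation: \eqn{u \sim g(u;\nu)}, then
#' \eqn{y \sim N(\mu, \sigma/u)}.
#'
#' @inheritParams dnid
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
rnid <- function(n, mu, sigma, spec) {
  stopifnot_family(spec)
  if (sigma <= 0) stop("sigma must be positive")
  u <- rnid_mixing(n, spec)
  mu + rnorm(n, 0, sqrt(sigma / u))
}

# latent-scale draws from the prior mixing law
rnid_mixing <- function(n, spec) {
  s <- spec$shape
  switch(spec$family,
    normal = rep(1, n),
    t = rgamma(n, shape = s / 2, rate = s / 2),
    slash = rbeta(n, s, 1),
    cn = ifelse(runif(n) < s[1], s[2], 1),
    laplace = 1 / rgamma(n, shape = 1, rate = s))
}

#' Conditional latent-scale draws
#'
#' Samples from the full conditional of one latent scale factor,
#' \eqn{p(u \mid e, \tau, \nu) \propto u^{1/2} \exp(-u \tau e^2 / 2)\,
#' g(u; \nu)}, the update used for \eqn{u_{isr}} inside the Gibbs sampler.
#' Family kernels: t and slash are (truncated) gamma, the contaminated
#' normal is two-point, and the Laplace kernel is inverse-Gaussian, all
#' sampled exactly.
#'
#' @param n Number of draws.
#' @param residual Residual \eqn{e = y - \mu}.
#' @param tau Error precision \eqn{\tau = 1/\sigma} (> 0).
#' @param spec An [nid_family()].
#' @return `n` positive draws.
#' @export
r_scale_conditional <- function(n, residual, tau, spec) {
  stopifnot_family(spec)
  if (tau <= 0) stop("tau must be positive")
  .cpp_draw_scale(as.integer(n), residual, tau, family_code(spec),
                  as.numeric(spec$shape))
}

#' Contaminated-normal conditional scale weight
#'
#' Posterior probability that one observation is contaminated
#' (\eqn{u = \gamma}) given its residual: the normalized two-point weight
#' \eqn{\lambda\sqrt{\gamma} e^{-\gamma\tau e^2/2} / (\lambda\sqrt{\gamma}
#' e^{-\gamma\tau e^2/2} + (1-\lambda) e^{-\tau e^2/2})}.
#'
#' @inheritParams r_scale_conditional
#' @param lambda,gamma Contamination weight and variance-deflation factor.
#' @return Probability in (0, 1).
#' @export
cn_scale_weight <- function(residual, tau, lambda, gamma) {
  lw1 <- log(lambda) + 0.5 * log(gamma) - 0.5 * gamma * tau * residual^2
  lw2 <- log1p(-lambda) - 0.5 * tau * residual^2
  1 / (1 + exp(lw2 - lw1))
}
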