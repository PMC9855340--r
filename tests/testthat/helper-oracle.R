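# Independent factor-by-factor oracle: a direct scalar transcription of the
# TG-43 2D line-source equations, deliberately separate from the package's
# implementation (no shared helpers; beta via the law of cosines instead of
# atan2 differences). Used to cross-check the engine on fixtures.

oracle_coef <- function(r, q) q[1] * r^q[2] + q[3] * r + q[4]

oracle_g <- function(r, h, i, j, k) h * r^i / (1 + j * r^k)

oracle_F <- function(r, theta_deg, quads) {
  u <- theta_deg / 180
  kr <- oracle_coef(r, quads$k)
  ar <- oracle_coef(r, quads$a); br <- oracle_coef(r, quads$b)
  er <- oracle_coef(r, quads$e)
  apr <- oracle_coef(r, quads$a_prime); bpr <- oracle_coef(r, quads$b_prime)
  epr <- oracle_coef(r, quads$e_prime)
  kr + ar * u^er / (1 + br * u^er) + apr * (1 - u)^epr / (1 + bpr * (1 - u)^epr)
}

# Geometry function from explicit tip coordinates: the point sits at
# (r sin(theta), 0, r cos(theta)) with the source segment on the z axis.
oracle_G <- function(r, theta_deg, L) {
  th <- theta_deg * pi / 180
  if (abs(sin(th)) < 1e-12) return(1 / (r^2 - L^2 / 4))
  p <- c(r * sin(th), 0, r * cos(th))
  v1 <- c(0, 0, L / 2) - p
  v2 <- c(0, 0, -L / 2) - p
  beta <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)))
  beta / (L * r * sin(th))
}

# Full dose rate for an axial dwell at the origin, point given in polar form.
oracle_rate <- function(Sk, Lambda, L, radial, quads, r, theta_deg) {
  Sk * Lambda * (oracle_G(r, theta_deg, L) / oracle_G(1, 90, L)) *
    oracle_g(r, radial[["h"]], radial[["i"]], radial[["j"]], radial[["k"]]) *
    oracle_F(r, theta_deg, quads)
}

# Table rows of the built-in GammaMed Plus Ir-192 model, restated here so the
# oracle does not read the package's configuration file.
gmp_radial <- c(h = 1.001, i = 7.69e-3, j = 2.1e-4, k = 2.63)
gmp_quads <- list(
  k       = c(-2.30569, -1.98e-2, 2.847e-2, 2.27378),
  a       = c(0, 0, -3.25e-1, 11.5962),
  b       = c(4.97e-1, -1.46, 5.2e-1, 24.586),
  e       = c(-1.7e-3, -2.96, 0, 1.469),
  a_prime = c(0, 0, -6.3265e-1, 17.0192),
  b_prime = c(-14.54, -1.5588e-1, -4.47e-1, 39.889),
  e_prime = c(-1.14e-1, -1.057, -1.81e-2, 1.2924))
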