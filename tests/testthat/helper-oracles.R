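# Independent oracles and small fixture builders shared across tests.

# Brute-force line-source geometry function: numerical quadrature of the
# uniform-line inverse-square integrand. Independent of the closed form
# used by geometry_function().
gl_quadrature <- function(r, theta_deg, L, rel.tol = 1e-12) {
  th <- theta_deg * pi / 180
  y <- r * sin(th); z <- r * cos(th)
  stats::integrate(function(s) 1 / (L * ((z - s)^2 + y^2)),
                   -L / 2, L / 2, rel.tol = rel.tol)$value
}

# A grid that is pure geometry (no attenuation): D = C * G(r, theta).
pure_geometry_grid <- function(model, radii = c(0.5, 1, 2, 5),
                               angles = seq(0, 90, 15), C = 40) {
  v <- outer(seq_along(radii), seq_along(angles), function(i, j)
    C * geometry_function(radii[i], angles[j], model))
  dose_rate_grid(radii, angles, v)
}

# A random strictly positive grid containing r = 1 cm and theta = 90 deg.
random_positive_grid <- function(seed) {
  set.seed(seed)
  radii <- sort(c(1, runif(5, 0.3, 5)))
  angles <- sort(c(90, runif(4, 0, 89)))
  v <- matrix(rlnorm(length(radii) * length(angles), 0, 0.5),
              length(radii), length(angles))
  dose_rate_grid(radii, angles, v)
}

ir06_path <- function() system.file("extdata", "ir06.tg43",
                                    package = "tg43seed")
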