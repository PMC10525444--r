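## Shared fixtures and oracles, built in code at test time.

MMHG_PA <- 133.322

healthy_anterior_params <- list(Rx = 7.37, Ry = 7.62, Qx = -0.25, Qy = -0.10)
kc_anterior_params <- list(Rx = 6.15, Ry = 7.24, Qx = -1.55, Qy = 1.33)

healthy_surface <- function(zone = 9, h = 0.1)
  make_biconic_surface(healthy_anterior_params, zone, h,
                       label = "healthy pre-op")

sphere_surface <- function(R = 7.5, zone = 8.4, h = 0.1)
  make_biconic_surface(list(Rx = R, Ry = R, Qx = 0, Qy = 0), zone, h,
                       label = "sphere")

## Gauss-Legendre nodes/weights on [a, b] (Golub-Welsch), used as the
## independent quadrature oracle for Zernike orthonormality
gauss_legendre <- function(n, a = 0, b = 1) {
  k <- seq_len(n - 1)
  beta <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1)] <- beta
  J[cbind(k + 1, k)] <- beta
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1, ]^2
  list(x = (a + b) / 2 + (b - a) / 2 * x, w = (b - a) / 2 * w)
}

## dense unit-disk quadrature exact for polynomials up to high order:
## Gauss-Legendre in rho^2, uniform trapezoid in theta
disk_quadrature <- function(n_r = 24, n_t = 64) {
  gl <- gauss_legendre(n_r, 0, 1)
  th <- 2 * pi * (seq_len(n_t) - 1) / n_t
  g <- expand.grid(u = gl$x, t = th)
  list(rho = sqrt(g$u), theta = g$t,
       w = rep(gl$w, times = n_t) / n_t)   # area-averaged measure
}
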