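test_that("OSA indexing and basis values match closed forms", {
  nm <- osa_index(0:27)
  expect_equal(nm$n[1:6], c(0, 1, 1, 2, 2, 2))
  expect_equal(nm$m[c(4, 5, 6)], c(-2, 0, 2))   # j = 3, 4, 5
  expect_identical(icrsim:::osa_j(nm$n, nm$m), 0:27)
  ## piston is 1 everywhere; defocus at rho = 1 is sqrt(3)
  expect_equal(zernike_value(0, c(0, 0.5, 1), c(0, 1, 2)), rep(1, 3))
  expect_equal(zernike_value(4, 1, 0.3), sqrt(3) * (2 - 1), tolerance = 1e-12)
  expect_error(zernike_value(28, 0.5, 0), "0..27")
  expect_error(zernike_value(4, 1.5, 0), "rho")
})

test_that("the 28-function basis is orthonormal on the unit disk", {
  q <- disk_quadrature(24, 64)
  A <- icrsim:::zernike_design(q$rho, q$theta)
  G <- crossprod(A * q$w, A)   # area-averaged Gram matrix
  expect_lt(max(abs(G - diag(28))), 1e-6)
})

test_that("fit recovers single-mode and random spectra exactly", {
  s <- sphere_surface(R = 7.5, zone = 6, h = 0.1)
  rp <- 2.5
  r <- sqrt(s$points$x^2 + s$points$y^2)
  inside <- r <= rp + 1e-9
  rho <- pmin(r[inside] / rp, 1)
  th <- atan2(s$points$y[inside], s$points$x[inside])
  ## pure vertical coma, amplitude 3 um
  s1 <- s
  s1$points$z[] <- 0
  s1$points$z[inside] <- -3.0 * zernike_value(7, rho, th) / 1000
  sp1 <- fit_zernike(s1, 5)
  expect_equal(unname(sp1$coefficients["c7"]), 3.0, tolerance = 1e-8)
  expect_lt(max(abs(sp1$coefficients[-8])), 1e-8)
  ## random 28-coefficient spectrum round-trips
  set.seed(5)
  co <- stats::rnorm(28)
  s2 <- s
  s2$points$z[] <- 0
  s2$points$z[inside] <-
    -(icrsim:::zernike_design(rho, th) %*% co) / 1000
  sp2 <- fit_zernike(s2, 5)
  expect_lt(max(abs(sp2$coefficients - co)), 1e-8)
  expect_lt(sp2$rms_fit_residual, 1e-8)
})

test_that("a centred sphere has no odd-symmetry aberrations", {
  sp <- fit_zernike(sphere_surface(R = 7.5, zone = 6, h = 0.1), 5)
  nm <- osa_index(0:27)
  odd <- which(nm$m != 0)
  ## non-axisymmetric terms vanish up to the aliasing of the (out-of-span)
  ## r^8+ sphere remainder onto the square grid's 4-fold symmetry
  expect_lt(max(abs(sp$coefficients[odd])), 1e-4)
  ## dominant terms are piston and defocus
  big <- order(abs(sp$coefficients), decreasing = TRUE)[1:2]
  expect_setequal(big - 1, c(0, 4))
})

test_that("a 90-degree rotation permutes paired coefficients analytically", {
  s <- healthy_surface(zone = 6, h = 0.1)
  kc <- add_kc_cone(s, cone_spec(center = c(0.6, -0.8), amplitude = 40,
                                 width = 1))
  rot <- kc
  rot$points <- data.frame(x = -kc$points$y, y = kc$points$x,
                           z = kc$points$z)
  a <- fit_zernike(kc, 5)$coefficients
  b <- fit_zernike(rot, 5)$coefficients
  nm <- osa_index(0:27)
  ## rotation by phi maps (cos, sin) pairs by a 2x2 rotation of angle m*phi;
  ## for phi = 90 deg: c_cos' = cos(m*pi/2) c_cos - sin(m*pi/2) c_sin, etc.
  for (n in 1:6) for (m in seq_len(n)) {
    if ((n - m) %% 2 != 0) next
    jc <- icrsim:::osa_j(n, m); js <- icrsim:::osa_j(n, -m)
    ang <- m * pi / 2
    expect_equal(unname(b[jc + 1]),
                 cos(ang) * a[[jc + 1]] - sin(ang) * a[[js + 1]],
                 tolerance = 1e-7)
    expect_equal(unname(b[js + 1]),
                 sin(ang) * a[[jc + 1]] + cos(ang) * a[[js + 1]],
                 tolerance = 1e-7)
  }
})

test_that("fit residual decreases monotonically with max_order", {
  kc <- add_kc_cone(healthy_surface(zone = 6, h = 0.1), cone_spec())
  res <- vapply(2:6, function(mo)
    fit_zernike(kc, 5, max_order = mo)$rms_fit_residual, numeric(1))
  expect_true(all(diff(res) <= 1e-12))
})

test_that("index descriptions match the clinical naming", {
  dd <- zernike_descriptions()
  expect_equal(dd$description[dd$osa_index == 7], "vertical coma")
  expect_equal(dd$description[dd$osa_index == 12], "primary spherical")
  expect_equal(dd$description[dd$osa_index == 4], "defocus")
  expect_equal(nrow(dd), 14)
})

test_that("aberration tables difference against the stated baseline", {
  s <- sphere_surface(R = 7.7, zone = 6, h = 0.15)
  kc <- add_kc_cone(healthy_surface(zone = 6, h = 0.15), cone_spec())
  spectra <- list(pre = fit_zernike(s, 5), post = fit_zernike(kc, 5))
  tab <- aberration_table(spectra, baseline = "pre")
  expect_equal(tab$post[1:14],
               unname(spectra$post$coefficients[2:15] -
                      spectra$pre$coefficients[2:15]))
  self <- aberration_table(list(a = spectra$pre, b = spectra$pre),
                           baseline = "a")
  expect_true(all(abs(self$b) < 1e-12))
  ## mismatched pupils are not comparable
  spectra$post$pupil_radius <- 3
  expect_error(aberration_table(spectra, "pre"), "pupil")
})
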