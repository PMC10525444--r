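test_that("biconic fit is exact on noiseless surfaces", {
  s <- sphere_surface(R = 7.5, zone = 6, h = 0.2)
  f <- fit_biconic(s, 5)
  expect_equal(f$Rx, 7.5, tolerance = 1e-6)
  expect_equal(f$Ry, 7.5, tolerance = 1e-6)
  expect_lt(abs(f$Qx), 1e-6)
  expect_lt(abs(f$Qy), 1e-6)
  ## keratoconic pre-op parameters (strong asymmetric asphericity)
  s2 <- make_biconic_surface(kc_anterior_params, 6, 0.1)
  f2 <- fit_biconic(s2, 5)
  expect_equal(f2$Rx, 6.15, tolerance = 1e-4)
  expect_equal(f2$Ry, 7.24, tolerance = 1e-4)
  expect_equal(f2$Qx, -1.55, tolerance = 1e-4)
  expect_equal(f2$Qy, 1.33, tolerance = 1e-4)
})

test_that("biconic fit round-trips across the parameter space", {
  set.seed(42)
  for (i in 1:25) {
    p <- list(Rx = runif(1, 5.5, 9), Ry = runif(1, 5.5, 9),
              Qx = runif(1, -2, 2), Qy = runif(1, -2, 2))
    s <- make_biconic_surface(p, 5.6, 0.28)
    f <- fit_biconic(s, 5)
    expect_lt(abs(f$Rx - p$Rx) / p$Rx, 1e-6)
    expect_lt(abs(f$Ry - p$Ry) / p$Ry, 1e-6)
    expect_lt(abs(f$Qx - p$Qx) / max(1, abs(p$Qx)), 1e-6)
    expect_lt(abs(f$Qy - p$Qy) / max(1, abs(p$Qy)), 1e-6)
  }
})

test_that("noisy-sphere radius recovery stays within 0.02 mm", {
  set.seed(11)
  errs <- replicate(100, {
    s <- make_biconic_surface(list(Rx = 7.5, Ry = 7.5), 5.6, 0.1,
                              noise_sd_um = 1)
    fit_biconic(s, 5)$Rx - 7.5
  })
  expect_lt(max(abs(errs)), 0.02)
})

test_that("fit_biconic rejects degenerate inputs", {
  pts <- data.frame(x = seq(-1, 1, 0.1), y = 0, z = 0)
  s <- surface_sampling(pts, zone_diameter = 4)
  expect_error(fit_biconic(s, 4), "degenerate|rank")
  expect_error(fit_biconic(surface_sampling(
    data.frame(x = c(0, 1, -1), y = c(0, 1, -1), z = c(0, 0.1, 0.1)),
    zone_diameter = 4), 4), "at least 6")
})

test_that("sphere sagittal map is constant at the keratometric power", {
  m <- sagittal_map(sphere_surface(R = 7.5, zone = 8.4, h = 0.1),
                    zone_diameter = 7)
  vals <- m$K[!is.na(m$K)]
  expect_equal(mean(vals), 0.375 / 0.0075, tolerance = 1e-3)
  expect_lt(diff(range(vals)), 0.02)
  ## posterior surface carries the posterior index step (negative power)
  sp <- make_biconic_surface(list(Rx = 7.5, Ry = 7.5), 8.4, 0.1,
                             surface_side = "posterior")
  mp <- sagittal_map(sp, zone_diameter = 7)
  expect_equal(mean(mp$K, na.rm = TRUE), -42 / 7.5, tolerance = 1e-3)
})

test_that("biconic map approaches 375/Rx along the x-meridian at the apex", {
  s <- make_biconic_surface(list(Rx = 7.37, Ry = 7.62, Qx = -0.25,
                                 Qy = -0.10), 8.4, 0.1)
  m <- sagittal_map(s, zone_diameter = 7)
  ix <- which.min(abs(m$x - 0.2)); iy <- which.min(abs(m$y))
  expect_equal(m$K[ix, iy], 375 / 7.37, tolerance = 2e-3 * 375 / 7.37)
})

test_that("re-origin places the map origin at the most elevated point", {
  kc <- add_kc_cone(healthy_surface(), cone_spec())
  m <- sagittal_map(kc, zone_diameter = 8, re_origin = TRUE)
  ap <- apex_point(kc)
  expect_equal(m$origin, c(ap$x, ap$y))
  m0 <- sagittal_map(kc, zone_diameter = 8, re_origin = FALSE)
  expect_equal(m0$origin, c(0, 0))
})

test_that("difference maps subtract pointwise and are antisymmetric", {
  s <- healthy_surface()
  post <- apply_icrs_effect(s, icrs_design_set()$sym)
  a <- sagittal_map(s, 8); b <- sagittal_map(post, 8)
  d1 <- difference_map(b, a); d2 <- difference_map(a, b)
  expect_equal(d1$K, -d2$K)
  z <- difference_map(a, a)$K
  expect_true(all(z[!is.na(z)] == 0))
  ## grid mismatch is refused
  a2 <- sagittal_map(healthy_surface(zone = 9, h = 0.15), 8)
  expect_error(difference_map(a2, a), "not aligned")
})

test_that("sym ICRS difference map flattens the implanted half and steepens the other", {
  s <- healthy_surface()
  d <- icrs_design_set()$sym
  post <- apply_icrs_effect(s, d)
  dm <- difference_map(sagittal_map(post, 8), sagittal_map(s, 8))
  ## probe mid-radius points on the arc-center meridian and opposite it
  mid_ang <- (d$orientation + d$arc_length / 2) * pi / 180
  probe <- function(ang, r) {
    ix <- which.min(abs(dm$x - r * cos(ang)))
    iy <- which.min(abs(dm$y - r * sin(ang)))
    dm$K[ix, iy]
  }
  expect_lt(probe(mid_ang, 1.8), 0)          # flattening, implanted half
  expect_gt(probe(mid_ang + pi, 2.5), 0)     # steepening, opposite half
})

test_that("difference map is first-order linear in a small perturbation", {
  s <- sphere_surface(R = 7.7, zone = 8.4, h = 0.1)
  pert <- s
  eps <- 1e-4   # 0.1 um bump
  pert$points$z <- s$points$z +
    eps * exp(-((s$points$x - 1)^2 + s$points$y^2) / 2)
  d1 <- difference_map(sagittal_map(pert, 7), sagittal_map(s, 7))
  pert2 <- s
  pert2$points$z <- s$points$z + 2 * eps *
    exp(-((s$points$x - 1)^2 + s$points$y^2) / 2)
  d2 <- difference_map(sagittal_map(pert2, 7), sagittal_map(s, 7))
  expect_equal(d2$K, 2 * d1$K, tolerance = 1e-3)
})

test_that("extrema agree with an exhaustive scan and obey the tie rule", {
  set.seed(3)
  s <- sphere_surface(R = 7.5, zone = 8.4, h = 0.2)
  m <- sagittal_map(s, 7)
  m$K <- m$K + stats::rnorm(length(m$K)) * (!is.na(m$K))
  ex <- extract_extrema(m)
  expect_equal(ex$Kmax$value, max(m$K, na.rm = TRUE))
  expect_equal(ex$Kmin$value, min(m$K, na.rm = TRUE))
  i <- which(m$K == ex$Kmax$value, arr.ind = TRUE)
  expect_equal(c(m$x[i[1]], m$y[i[2]]), c(ex$Kmax$x, ex$Kmax$y))
  ## all-tied map: smallest radius, then smallest angle
  m$K[!is.na(m$K)] <- 0
  ex0 <- extract_extrema(m)
  expect_equal(sqrt(ex0$Kmax$x^2 + ex0$Kmax$y^2), 0, tolerance = 1e-9)
})

test_that("axial-length change is the signed extreme displacement", {
  s <- healthy_surface(zone = 6, h = 0.2)
  expect_equal(delta_axial_length(s, s), 0)
  shifted <- s
  shifted$points$z <- s$points$z + 0.036   # sag +36 um = recession
  expect_equal(delta_axial_length(shifted, s), -0.036)
  ## 40 um apex recession reported as -0.04 mm
  rec <- s
  rec$points$z <- s$points$z + 0.040 * exp(-(s$points$x^2 + s$points$y^2))
  expect_equal(round(delta_axial_length(rec, s), 2), -0.04)
  ## sampling mismatch is refused
  other <- healthy_surface(zone = 6, h = 0.3)
  expect_error(delta_axial_length(other, s), "sampling")
})
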