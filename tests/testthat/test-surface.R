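test_that("biconic sag matches closed forms", {
  ## spherical cap: R - sqrt(R^2 - r^2)
  expect_equal(biconic_sag(2.5, 0, 7.5, 7.5), 7.5 - sqrt(7.5^2 - 2.5^2),
               tolerance = 1e-12)
  expect_equal(biconic_sag(0, 0, 7.37, 7.62, -0.25, -0.1), 0)
  ## independent scalar evaluation at (1, 0), Q = 0
  Rx <- 7.37; Ry <- 7.62
  manual <- (1 / Rx) / (1 + sqrt(1 - 1 / Rx^2))
  expect_equal(biconic_sag(1, 0, Rx, Ry, 0, 0), manual, tolerance = 1e-14)
})

test_that("biconic sag rejects a non-positive radicand, naming the pair", {
  err <- expect_error(biconic_sag(4, 0, 4, 7.5, 0.5, 0), "radicand")
  expect_match(conditionMessage(err), "Qx=0.500")
})

test_that("generated surfaces respect zone and grid structure", {
  s <- healthy_surface(zone = 6, h = 0.2)
  r <- sqrt(s$points$x^2 + s$points$y^2)
  expect_lte(max(r), 3 + 1e-9)
  expect_true(all(c(0) %in% s$points$x))   # symmetric axes present
  expect_error(surface_sampling(data.frame(x = 1, y = 0, z = 0),
                                zone_diameter = 6),
               "at least 3 points")
  expect_error(surface_sampling(data.frame(x = c(0, 1, 4), y = 0, z = 0),
                                zone_diameter = 6),
               "outside")
})

test_that("zero-amplitude cone is the identity; bump peaks at the center", {
  s <- healthy_surface(zone = 8, h = 0.1)
  expect_equal(add_kc_cone(s, cone_spec(amplitude = 0))$points$z,
               s$points$z)
  kc <- add_kc_cone(s, cone_spec(amplitude = 50, center = c(0, -1)))
  d <- kc$points$z - s$points$z   # anterior protrusion: sag decreases
  i <- which.min(d)
  expect_lte(abs(kc$points$x[i] - 0), 0.1)
  expect_lte(abs(kc$points$y[i] - (-1)), 0.1)
  expect_equal(min(d), -0.050, tolerance = 1e-12)
})

test_that("the cone displaces the most elevated point toward its center", {
  s <- healthy_surface()
  expect_equal(unlist(apex_point(s)[c("x", "y")]), c(x = 0, y = 0))
  kc <- add_kc_cone(s, cone_spec())
  ap <- apex_point(kc)
  expect_lt(ap$y, 0)                       # moved inferiorly, toward the cone
  expect_gt(sqrt(ap$x^2 + ap$y^2), 0.1)    # off the axis
})

test_that("cone center outside the zone is rejected", {
  s <- healthy_surface(zone = 6)
  expect_error(add_kc_cone(s, cone_spec(center = c(0, -4))), "outside")
})

test_that("cone_spec and icrs_design enforce their invariants", {
  expect_error(cone_spec(amplitude = -1), "amplitude")
  expect_error(cone_spec(inner_weaken_fraction = 0.8,
                         outer_weaken_fraction = 0.5), "fraction")
  expect_error(cone_spec(core_radius = 3, outer_radius = 2), "core_radius")
  expect_error(icrs_design("x", arc_length = 400), "arc_length")
  expect_error(icrs_design("x", start_thickness = -5), "positive")
})

test_that("ICRS effect: zero gain is identity, negative gain is an error", {
  s <- healthy_surface()
  d <- icrs_design_set()$sym
  expect_equal(apply_icrs_effect(s, d, gain = 0)$points$z, s$points$z)
  expect_error(apply_icrs_effect(s, d, gain = -1), "gain")
  post <- make_biconic_surface(list(Rx = 7.91, Ry = 7.97),
                               surface_side = "posterior")
  expect_error(apply_icrs_effect(post, d), "anterior")
})

test_that("sym perturbation is constant along the arc; asym end ratio is t*w", {
  d <- icrs_design_set()
  phis <- d$sym$orientation + seq(10, 150, by = 10)  # arc interior
  a_sym <- icrsim:::icrs_angular_amplitude(phis, d$sym, gain = 400)
  expect_lt(diff(range(a_sym)) / mean(a_sym), 1e-10)
  ## thick end / thin end magnitude ratio = (300*800)/(150*600)
  ends <- icrsim:::icrs_angular_amplitude(
    d$asym$orientation + c(1e-9, d$asym$arc_length - 1e-9), d$asym,
    gain = 400)
  expect_equal(ends[2] / ends[1], (300 * 800) / (150 * 600),
               tolerance = 1e-9)
})

test_that("ICRS effect conserves elevation outside the perturbation support", {
  s <- healthy_surface(zone = 9, h = 0.1)
  d <- icrs_design_set()$asym
  post <- apply_icrs_effect(s, d)
  b <- d$optical_zone / 2 + max(d$start_width, d$end_width) / 1000
  outside <- sqrt(s$points$x^2 + s$points$y^2) >= b
  expect_true(any(outside))
  expect_identical(post$points$z[outside], s$points$z[outside])
})

test_that("fixture set enumerates the full scenario grid deterministically", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- write_fixture_set(d1, seed = 7, zone_diameter = 5, grid_spacing = 0.5,
                          noise_sd_um = 0.5)
  m2 <- write_fixture_set(d2, seed = 7, zone_diameter = 5, grid_spacing = 0.5,
                          noise_sd_um = 0.5)
  ## 2 surfaces x (2 pre-op + 2 x 6 post-op) = 28 files
  expect_equal(nrow(m1), 28)
  for (f in m1$file)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  ## a different seed changes at least one file when noise is on
  d3 <- withr::local_tempdir()
  write_fixture_set(d3, seed = 8, zone_diameter = 5, grid_spacing = 0.5,
                    noise_sd_um = 0.5)
  same <- vapply(m1$file, function(f)
    identical(readLines(file.path(d1, f)), readLines(file.path(d3, f))),
    logical(1))
  expect_false(all(same))
})
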