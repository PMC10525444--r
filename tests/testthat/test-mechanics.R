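test_that("material table and merged layer are consistent", {
  st <- material_table()$stroma
  h <- st[st$part == "healthy", ]
  expect_equal(h$C1, c(35.5e3, 32.0e3))
  merged <- merged_stroma_material()
  expect_equal(merged$thickness_um, 550)
  expect_equal(merged$material$C1, (385 * 35.5e3 + 165 * 32e3) / 550)
  expect_error(yeoh_material(-1), "C1")
})

test_that("Yeoh energy and stress behave at and away from the reference state", {
  mat <- yeoh_material(35.5e3, 3.2e3, 1.9e3)
  ref <- yeoh_energy_and_stress(3, 1, mat)
  expect_equal(ref$energy, 0)
  expect_equal(ref$cauchy_stress, 0)
  expect_equal(initial_shear_modulus(mat), 71e3)
  expect_error(yeoh_energy_and_stress(2.9, 1, mat), "I1")
  ## energy monotone non-decreasing over I1 in [3, 3.5]
  I1 <- seq(3, 3.5, length.out = 200)
  W <- vapply(I1, function(i) icrsim:::yeoh_W(i, mat), numeric(1))
  expect_true(all(diff(W) >= 0))
})

test_that("analytic stress derivative matches numerical energy differentiation", {
  mat <- yeoh_material(35.5e3, 3.2e3, 1.9e3)
  for (I1 in c(3.001, 3.05, 3.2, 3.5)) {
    h <- 1e-6
    num <- (icrsim:::yeoh_W(I1 + h, mat) - icrsim:::yeoh_W(I1 - h, mat)) /
      (2 * h)
    expect_equal(icrsim:::yeoh_dW(I1, mat), num,
                 tolerance = 1e-6 * icrsim:::yeoh_dW(I1, mat))
  }
  ## the small-strain equibiaxial stress slope equals 6 mu0 = 12 C1
  neo <- yeoh_material(35.5e3)
  eps <- 1e-5
  I1 <- 2 * (1 + eps)^2 + (1 + eps)^-4
  st <- yeoh_energy_and_stress(I1, (1 + eps)^2, neo)
  expect_equal(st$cauchy_stress / eps, 12 * neo$C1, tolerance = 1e-3)
})

test_that("zero pressure leaves the mesh unchanged in one iteration", {
  mesh <- cap_mesh_sphere(n_theta = 6, n_phi = 12)
  r <- inflate(mesh, 0)
  expect_true(r$converged)
  expect_equal(r$iterations, 1)
  expect_equal(r$deformed_nodes, mesh$nodes)
  expect_error(inflate(mesh, -5), "pressure")
})

test_that("small-pressure inflation approaches the Laplace membrane stress", {
  mesh <- cap_mesh_sphere(R = 7.5, theta_max = pi / 2, n_theta = 14,
                          n_phi = 28, thickness = 550,
                          boundary_type = "sliding")
  p <- 0.01 * 15 * MMHG_PA
  r <- inflate(mesh, p)
  expect_true(r$converged)
  sig <- membrane_stress(mesh, r)
  R_def <- sqrt(sum(r$deformed_nodes[1, ]^2))
  laplace <- p * R_def / (2 * 0.55)
  expect_lt(abs(mean(sig) / laplace - 1), 0.02)
})

test_that("doubling the stiffness halves the apex displacement to first order", {
  cap <- cap_mesh_sphere(theta_max = pi / 3, n_theta = 8, n_phi = 16)
  p <- 0.001 * 15 * MMHG_PA
  r1 <- inflate(cap, p)
  stiff <- cap
  stiff$material <- yeoh_material(2 * cap$material$C1, 2 * cap$material$C2,
                                  2 * cap$material$C3)
  r2 <- inflate(stiff, p)
  expect_equal(r2$apex_axial_displacement / r1$apex_axial_displacement, 0.5,
               tolerance = 0.05)
})

test_that("regional weakening maps the cone zones onto element stiffness", {
  mesh <- cap_mesh_sphere(theta_max = pi / 3, n_theta = 10, n_phi = 16)
  same <- apply_weakening(mesh, cone_spec(inner_weaken_fraction = 1,
                                          outer_weaken_fraction = 1))
  expect_equal(same$stiffness_scale, rep(1, nrow(mesh$triangles)))
  weak <- apply_weakening(mesh, cone_spec())
  expect_setequal(unique(weak$stiffness_scale), c(0.30, 0.70, 1))
  ## effective C1 of the weakened elements reproduces the KC material rows
  st <- material_table()$stroma
  expect_lt(abs(0.70 * 35.5e3 - st$C1[st$part == "KC region1" &
                                      st$layer == "anterior"]), 250)
  expect_lt(abs(0.30 * 35.5e3 - st$C1[st$part == "KC region2" &
                                      st$layer == "anterior"]), 250)
})

test_that("weakened inflation bulges more and steepens over the cone", {
  cap <- cap_mesh_sphere(R = 7.5, theta_max = pi / 3, n_theta = 10,
                         n_phi = 16)
  p <- 15 * MMHG_PA
  rh <- inflate(cap, p)
  weak <- apply_weakening(cap, cone_spec())
  rw <- inflate(weak, p)
  expect_gt(rw$apex_axial_displacement, rh$apex_axial_displacement)
  ## local curvature over the weakened zone exceeds the healthy inflation
  sh <- surface_from_inflation(cap, rh, zone_diameter = 7)
  sw <- surface_from_inflation(weak, rw, zone_diameter = 7)
  mh <- sagittal_map(sh, 6); mw <- sagittal_map(sw, 6)
  over_cone <- function(m) {
    X <- matrix(m$x, length(m$x), length(m$y))
    Y <- matrix(m$y, length(m$x), length(m$y), byrow = TRUE)
    mean(m$K[sqrt(X^2 + (Y + 1)^2) <= 1.25], na.rm = TRUE)
  }
  expect_gt(over_cone(mw), over_cone(mh))
})

test_that("stress-free search inverts inflation to within 0.1 um", {
  hemi <- cap_mesh_sphere(R = 7.5, theta_max = pi / 2, n_theta = 10,
                          n_phi = 16, boundary_type = "sliding")
  p <- 15 * MMHG_PA
  ## zero pressure: the stress-free geometry is the target itself
  sf0 <- find_stress_free(hemi$nodes, hemi, 0)
  expect_equal(sf0$nodes, hemi$nodes)
  expect_equal(attr(sf0, "iterations"), 1)
  ## attainable target: the inflated image of the spherical cap
  target <- inflate(hemi, p)$deformed_nodes
  sf <- find_stress_free(target, hemi, p)
  expect_true(attr(sf, "converged"))
  m <- hemi; m$nodes <- sf$nodes
  check <- inflate(m, p)
  expect_lt(max(sqrt(rowSums((check$deformed_nodes - target)^2))), 1e-4)
  ## recovered stress-free apex lies posterior to (below) the target apex
  expect_lte(sf$nodes[1, 3], target[1, 3])
})

test_that("mesh invariants are enforced", {
  mesh <- cap_mesh_sphere(n_theta = 4, n_phi = 8)
  expect_error(membrane_mesh(mesh$nodes, cbind(1, 2, 999), 0.5,
                             mesh$material, boundary_nodes = 1),
               "out of range")
  expect_error(membrane_mesh(mesh$nodes, mesh$triangles, -0.1,
                             mesh$material, boundary_nodes = 1),
               "thickness")
  expect_error(membrane_mesh(mesh$nodes, mesh$triangles, 0.5,
                             mesh$material, stiffness_scale = 1.5,
                             boundary_nodes = 1),
               "stiffness_scale")
})
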