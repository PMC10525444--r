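## Triangulated membrane meshes for the inflation solver.

#' Construct a membrane mesh
#'
#' @param nodes numeric matrix (n x 3) of node coordinates, mm.
#' @param triangles integer matrix (m x 3) of node indices, oriented so
#'   that the right-hand normal points outward (toward the pressurizing
#'   side's opposite, i.e. anteriorly).
#' @param thickness per-element thickness, um (scalar or length m).
#' @param material a [yeoh_material()].
#' @param stiffness_scale per-element stiffness multiplier in (0, 1]
#'   (scalar or length m).
#' @param boundary_nodes indices of constrained nodes.
#' @param boundary_type "pinned" (fixed) or "sliding" (radial motion in
#'   the boundary plane only; exact for a boundary plane through z = 0).
#' @param polar optional list describing a structured polar layout
#'   (`ring_radius`, `phi`, `node_ring`, `node_sector`) used for surface
#'   extraction.
#' @return object of class `membrane_mesh`.
#' @export
membrane_mesh <- function(nodes, triangles, thickness, material,
                          stiffness_scale = 1, boundary_nodes,
                          boundary_type = c("pinned", "sliding"),
                          polar = NULL) {
  boundary_type <- match.arg(boundary_type)
  nodes <- as.matrix(nodes); triangles <- as.matrix(triangles)
  m <- nrow(triangles)
  if (any(triangles < 1 | triangles > nrow(nodes)))
    stop("triangle indices out of range")
  thickness <- rep_len(thickness, m)
  stiffness_scale <- rep_len(stiffness_scale, m)
  if (any(thickness <= 0)) stop("thickness must be positive")
  if (any(stiffness_scale <= 0 | stiffness_scale > 1))
    stop("stiffness_scale must lie in (0, 1]")
  structure(list(nodes = nodes, triangles = triangles,
                 thickness = thickness, material = material,
                 stiffness_scale = stiffness_scale,
                 boundary_nodes = as.integer(boundary_nodes),
                 boundary_type = boundary_type, polar = polar),
            class = "membrane_mesh")
}

#' @export
print.membrane_mesh <- function(x, ...) {
  cat("Membrane mesh:", nrow(x$nodes), "nodes,", nrow(x$triangles),
      "triangles,", x$boundary_type, "boundary (",
      length(x$boundary_nodes), "nodes )\n")
  cat("  thickness [um]:", paste(format(range(x$thickness * 1000),
                                        digits = 4), collapse = " .. "),
      " stiffness scale:", paste(format(range(x$stiffness_scale),
                                        digits = 3), collapse = " .. "), "\n")
  invisible(x)
}

#' Spherical-cap membrane mesh
#'
#' Polar triangulation of a spherical cap of radius `R` centred at the
#' origin (apex on the +z axis): an apex node plus `n_theta` rings of
#' `n_phi` nodes at uniform polar angle up to `theta_max`. With
#' `theta_max = pi/2` and a sliding boundary this is the symmetric half
#' of a closed pressurized sphere (the boundary ring lies in the z = 0
#' plane through the centre, where the radial-sliding condition and the
#' fan-volume pressure potential are both exact).
#'
#' @param R sphere radius, mm.
#' @param theta_max cap half-angle, radians.
#' @param n_theta number of rings.
#' @param n_phi nodes per ring.
#' @param thickness membrane thickness, um.
#' @param material a [yeoh_material()] (default: merged healthy stroma).
#' @param boundary_type "pinned" or "sliding".
#' @return a [membrane_mesh()].
#' @export
cap_mesh_sphere <- function(R = 7.5, theta_max = pi / 2, n_theta = 10,
                            n_phi = 16, thickness = 550,
                            material = merged_stroma_material()$material,
                            boundary_type = "pinned") {
  th <- seq(0, theta_max, length.out = n_theta + 1)[-1]
  ph <- seq(0, 2 * pi, length.out = n_phi + 1)[-(n_phi + 1)]
  nodes <- rbind(c(0, 0, R),
                 do.call(rbind, lapply(th, function(t)
                   cbind(R * sin(t) * cos(ph), R * sin(t) * sin(ph),
                         R * cos(t)))))
  idx <- function(i, j) 1 + (i - 1) * n_phi + ((j - 1) %% n_phi) + 1
  tris <- list()
  for (j in seq_len(n_phi))   # apex fan (CCW seen from +z: outward normals)
    tris[[length(tris) + 1]] <- c(1, idx(1, j), idx(1, j + 1))
  for (i in seq_len(n_theta - 1)) for (j in seq_len(n_phi)) {
    tris[[length(tris) + 1]] <- c(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1))
    tris[[length(tris) + 1]] <- c(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1))
  }
  tri <- do.call(rbind, tris)
  boundary <- (1 + (n_theta - 1) * n_phi + 1):(1 + n_theta * n_phi)
  polar <- list(ring_radius = R * sin(th), phi = ph,
                node_ring = c(0, rep(seq_along(th), each = n_phi)),
                node_sector = c(0, rep(seq_len(n_phi), times = n_theta)))
  membrane_mesh(nodes, tri, thickness / 1000, material,
                boundary_nodes = boundary, boundary_type = boundary_type,
                polar = polar)
}

#' Apply keratoconic regional weakening to a mesh
#'
#' Sets the per-element stiffness multiplier from the cone's two
#' concentric weakening zones (evaluated at element planform centroids):
#' `inner_weaken_fraction` inside `core_radius` of the cone centre,
#' `outer_weaken_fraction` in the annulus to `outer_radius`, and 1
#' elsewhere. Thickness is untouched.
#'
#' @param mesh a [membrane_mesh()].
#' @param cone a [cone_spec()].
#' @return the mesh with updated `stiffness_scale`.
#' @export
apply_weakening <- function(mesh, cone) {
  stopifnot(inherits(mesh, "membrane_mesh"), inherits(cone, "cone_spec"))
  cx <- (mesh$nodes[mesh$triangles[, 1], 1] +
         mesh$nodes[mesh$triangles[, 2], 1] +
         mesh$nodes[mesh$triangles[, 3], 1]) / 3
  cy <- (mesh$nodes[mesh$triangles[, 1], 2] +
         mesh$nodes[mesh$triangles[, 2], 2] +
         mesh$nodes[mesh$triangles[, 3], 2]) / 3
  d <- sqrt((cx - cone$center[1])^2 + (cy - cone$center[2])^2)
  s <- rep(1, nrow(mesh$triangles))
  s[d <= cone$outer_radius] <- cone$outer_weaken_fraction
  s[d <= cone$core_radius] <- cone$inner_weaken_fraction
  mesh$stiffness_scale <- s
  mesh
}
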