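## Nonlinear membrane inflation: incompressible Yeoh triangles under
## follower (volume-conjugate) pressure, solved by Newton iteration with
## backtracking line search on the total potential energy.
##
## Kinematics per flat triangle: reference edge metric A_ab, current
## metric a_ab; in-plane right Cauchy-Green in the convected basis is
## A^{-1} a, the thickness stretch follows from incompressibility
## (lambda3^2 = det A / det a), and
## I1 = tr(A^{-1} a) + det A / det a. Element energy = scale * t0 *
## refArea * W(I1); pressure potential = -p * fan volume.

## precomputed reference quantities for all elements
mesh_reference <- function(mesh) {
  tri <- mesh$triangles
  X1 <- mesh$nodes[tri[, 1], , drop = FALSE]
  E1 <- mesh$nodes[tri[, 2], , drop = FALSE] - X1
  E2 <- mesh$nodes[tri[, 3], , drop = FALSE] - X1
  A11 <- rowSums(E1 * E1); A12 <- rowSums(E1 * E2); A22 <- rowSums(E2 * E2)
  detA <- A11 * A22 - A12^2
  if (any(detA <= 0)) stop("degenerate reference triangle")
  list(Ai11 = A22 / detA, Ai12 = -A12 / detA, Ai22 = A11 / detA,
       detA = detA, area = sqrt(detA) / 2,
       wgt = mesh$stiffness_scale * mesh$thickness * sqrt(detA) / 2)
}

## current edge metrics and invariants for node positions x (n x 3)
element_state <- function(x, tri, ref) {
  x1 <- x[tri[, 1], , drop = FALSE]
  e1 <- x[tri[, 2], , drop = FALSE] - x1
  e2 <- x[tri[, 3], , drop = FALSE] - x1
  a11 <- rowSums(e1 * e1); a12 <- rowSums(e1 * e2); a22 <- rowSums(e2 * e2)
  deta <- a11 * a22 - a12^2
  I1 <- ref$Ai11 * a11 + 2 * ref$Ai12 * a12 + ref$Ai22 * a22 +
    ref$detA / deta
  list(e1 = e1, e2 = e2, a11 = a11, a12 = a12, a22 = a22,
       deta = deta, I1 = I1)
}

## elastic energy (scalar) of all elements
elastic_energy <- function(x, mesh, ref) {
  st <- element_state(x, mesh$triangles, ref)
  sum(ref$wgt * yeoh_W(pmax(st$I1, 3), mesh$material))
}

## per-element elastic gradient wrt the 9 local dofs; returns m x 9
## matrix in order (x1, y1, z1, x2, y2, z2, x3, y3, z3)
elastic_element_gradient <- function(x, mesh, ref) {
  st <- element_state(x, mesh$triangles, ref)
  dW <- yeoh_dW(pmax(st$I1, 3), mesh$material)
  c0 <- ref$wgt * dW
  ## dI1/da_ab: metric part + det part (d(detA/deta)/da)
  f <- -ref$detA / st$deta^2
  dI_da11 <- ref$Ai11 + f * st$a22
  dI_da12 <- 2 * ref$Ai12 + f * (-2 * st$a12)
  dI_da22 <- ref$Ai22 + f * st$a11
  ## da/d(e): a11 -> 2 e1 ; a12 -> e2 (wrt e1), e1 (wrt e2); a22 -> 2 e2
  g_e1 <- c0 * (2 * dI_da11) * st$e1 + c0 * dI_da12 * st$e2
  g_e2 <- c0 * (2 * dI_da22) * st$e2 + c0 * dI_da12 * st$e1
  cbind(-(g_e1 + g_e2), g_e1, g_e2)
}

## fan volume (mm^3) and its per-element gradient
fan_volume <- function(x, tri) {
  x1 <- x[tri[, 1], , drop = FALSE]
  x2 <- x[tri[, 2], , drop = FALSE]
  x3 <- x[tri[, 3], , drop = FALSE]
  sum(x1[, 1] * (x2[, 2] * x3[, 3] - x2[, 3] * x3[, 2]) -
      x1[, 2] * (x2[, 1] * x3[, 3] - x2[, 3] * x3[, 1]) +
      x1[, 3] * (x2[, 1] * x3[, 2] - x2[, 2] * x3[, 1])) / 6
}

cross3 <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

volume_element_gradient <- function(x, tri) {
  x1 <- x[tri[, 1], , drop = FALSE]
  x2 <- x[tri[, 2], , drop = FALSE]
  x3 <- x[tri[, 3], , drop = FALSE]
  cbind(cross3(x2, x3), cross3(x3, x1), cross3(x1, x2)) / 6
}

## total element gradient (elastic - p * dV), m x 9
total_element_gradient <- function(x, mesh, ref, pressure) {
  g <- elastic_element_gradient(x, mesh, ref)
  if (pressure != 0)
    g <- g - pressure * volume_element_gradient(x, mesh$triangles)
  g
}

## scatter-add of element gradients into the global vector
scatter_gradient <- function(gel, tri, n) {
  g <- numeric(3 * n)
  for (k in 1:3) for (d in 1:3) {
    idx <- (tri[, k] - 1) * 3 + d
    add <- gel[, (k - 1) * 3 + d]
    s <- rowsum(add, idx)
    g[as.integer(rownames(s))] <- g[as.integer(rownames(s))] + s[, 1]
  }
  g
}

## element-level central-difference Hessian of the total element energy,
## assembled as a sparse symmetric matrix (3n x 3n)
assemble_hessian <- function(x, mesh, ref, pressure, eps = 1e-6) {
  tri <- mesh$triangles
  m <- nrow(tri); n <- nrow(mesh$nodes)
  cols <- vector("list", 9)
  for (col in 1:9) {
    k <- (col - 1) %/% 3 + 1; d <- (col - 1) %% 3 + 1
    ## perturb dof d of local node k independently per element (node-
    ## expanded copies, no scatter) and difference the element gradients
    gp <- element_gradient_perturbed(x, mesh, ref, pressure, k, d, +eps)
    gm <- element_gradient_perturbed(x, mesh, ref, pressure, k, d, -eps)
    cols[[col]] <- (gp - gm) / (2 * eps)
  }
  ii <- jj <- vv <- vector("list", 81)
  q <- 0
  for (col in 1:9) {
    kc <- (col - 1) %/% 3 + 1; dc <- (col - 1) %% 3 + 1
    jdx <- (tri[, kc] - 1) * 3 + dc
    for (row in 1:9) {
      kr <- (row - 1) %/% 3 + 1; dr <- (row - 1) %% 3 + 1
      idx <- (tri[, kr] - 1) * 3 + dr
      q <- q + 1
      ii[[q]] <- idx; jj[[q]] <- jdx; vv[[q]] <- cols[[col]][, row]
    }
  }
  H <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(vv),
                            dims = c(3 * n, 3 * n))
  (H + Matrix::t(H)) / 2
}

## element gradients with local node k's coordinate d perturbed by eps,
## evaluated independently per element (no scatter)
element_gradient_perturbed <- function(x, mesh, ref, pressure, k, d, eps) {
  tri <- mesh$triangles
  xl <- list(x[tri[, 1], , drop = FALSE],
             x[tri[, 2], , drop = FALSE],
             x[tri[, 3], , drop = FALSE])
  xl[[k]][, d] <- xl[[k]][, d] + eps
  element_gradient_local(xl[[1]], xl[[2]], xl[[3]], mesh, ref, pressure)
}

## gradient given explicit per-element vertex coordinates
element_gradient_local <- function(x1, x2, x3, mesh, ref, pressure) {
  e1 <- x2 - x1; e2 <- x3 - x1
  a11 <- rowSums(e1 * e1); a12 <- rowSums(e1 * e2); a22 <- rowSums(e2 * e2)
  deta <- a11 * a22 - a12^2
  I1 <- ref$Ai11 * a11 + 2 * ref$Ai12 * a12 + ref$Ai22 * a22 +
    ref$detA / deta
  dW <- yeoh_dW(pmax(I1, 3), mesh$material)
  c0 <- ref$wgt * dW
  f <- -ref$detA / deta^2
  dI_da11 <- ref$Ai11 + f * a22
  dI_da12 <- 2 * ref$Ai12 - 2 * f * a12
  dI_da22 <- ref$Ai22 + f * a11
  g_e1 <- c0 * (2 * dI_da11) * e1 + c0 * dI_da12 * e2
  g_e2 <- c0 * (2 * dI_da22) * e2 + c0 * dI_da12 * e1
  g <- cbind(-(g_e1 + g_e2), g_e1, g_e2)
  if (pressure != 0)
    g <- g - pressure * cbind(cross3(x2, x3), cross3(x3, x1),
                              cross3(x1, x2)) / 6
  g
}

## reduction basis for the boundary conditions: full dofs = T %*% reduced
constraint_basis <- function(mesh) {
  n <- nrow(mesh$nodes)
  bset <- mesh$boundary_nodes
  free <- setdiff(seq_len(n), bset)
  ii <- jj <- vv <- list()
  q <- 0
  col <- 0
  for (nd in free) for (d in 1:3) {
    col <- col + 1; q <- q + 1
    ii[[q]] <- (nd - 1) * 3 + d; jj[[q]] <- col; vv[[q]] <- 1
  }
  if (mesh$boundary_type == "sliding") {
    for (nd in bset) {
      r <- sqrt(sum(mesh$nodes[nd, 1:2]^2))
      if (r < 1e-12) next  # a boundary node on the axis cannot slide radially
      dir <- c(mesh$nodes[nd, 1:2] / r, 0)
      col <- col + 1
      for (d in 1:3) {
        q <- q + 1
        ii[[q]] <- (nd - 1) * 3 + d; jj[[q]] <- col; vv[[q]] <- dir[d]
      }
    }
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(vv),
                       dims = c(3 * n, col))
}

total_energy <- function(x, mesh, ref, pressure) {
  elastic_energy(x, mesh, ref) - pressure * fan_volume(x, mesh$triangles)
}

#' Inflate a membrane mesh under follower pressure
#'
#' Static equilibrium of the incompressible Yeoh membrane under an
#' internal (posterior) follower pressure, found by Newton iteration on
#' the total potential energy with incremental load stepping and a
#' backtracking line search. Convergence requires both the reduced
#' residual norm (below `1e-8 * pressure * mean element area`, with a
#' small absolute floor) and the step norm to be small.
#'
#' @param mesh a [membrane_mesh()].
#' @param pressure internal pressure, Pa (15 mmHg = 1999.8 Pa).
#' @param max_iter Newton iterations per load step.
#' @param n_steps number of load increments (default: automatic).
#' @param init optional initial nodal positions (warm start).
#' @param tol absolute residual tolerance override.
#' @return object of class `inflation_result`: `deformed_nodes`,
#'   `apex_axial_displacement` (um, signed along +z),
#'   `residual_norm`, `iterations`, `converged`, `residual_history`.
#' @export
inflate <- function(mesh, pressure, max_iter = 40, n_steps = NULL,
                    init = NULL, tol = NULL) {
  stopifnot(inherits(mesh, "membrane_mesh"))
  if (pressure < 0) stop("pressure must be >= 0")
  ref <- mesh_reference(mesh)
  tri <- mesh$triangles; n <- nrow(mesh$nodes)
  Tb <- constraint_basis(mesh)
  mean_area <- mean(ref$area)
  ## spec'd tolerance scaled by load, floored by the elastic force scale
  ## (the attainable accuracy of the finite-difference tangent)
  if (is.null(tol))
    tol <- max(1e-8 * pressure * mean_area,
               1e-10 * mesh$material$C1 * mean(mesh$thickness) *
                 sqrt(mean_area))
  x <- if (is.null(init)) mesh$nodes else as.matrix(init)
  if (is.null(n_steps))
    n_steps <- if (is.null(init)) max(1L, ceiling(pressure / 1500)) else 1L
  total_iter <- 0L
  hist <- numeric(0)
  converged <- TRUE
  for (step in seq_len(n_steps)) {
    p <- pressure * step / n_steps
    step_tol <- if (step == n_steps) tol else max(tol, 1e-6 * p * mean_area)
    mu <- 0   # Levenberg-style damping against indefinite (wrinkling) states
    for (it in seq_len(max_iter)) {
      total_iter <- total_iter + 1L
      g <- scatter_gradient(total_element_gradient(x, mesh, ref, p), tri, n)
      gr <- as.numeric(Matrix::crossprod(Tb, g))
      rn <- max(abs(gr))
      hist <- c(hist, rn)
      if (rn <= step_tol) break
      H <- assemble_hessian(x, mesh, ref, p)
      Hr <- Matrix::forceSymmetric(Matrix::crossprod(Tb, H %*% Tb))
      dscale <- mean(abs(Matrix::diag(Hr)))
      E0 <- total_energy(x, mesh, ref, p)
      accepted <- FALSE
      for (try in 1:12) {
        Hd <- if (mu > 0) Hr + Matrix::Diagonal(ncol(Tb), mu * dscale) else Hr
        dq <- tryCatch(as.numeric(Matrix::solve(Hd, -gr)),
                       error = function(e) NULL)
        slope <- if (is.null(dq)) 1 else sum(gr * dq)
        if (is.null(dq) || slope >= 0) {   # not a descent direction
          mu <- max(mu * 10, 1e-8)
          next
        }
        du <- matrix(as.numeric(Tb %*% dq), n, 3, byrow = TRUE)
        if (abs(slope) <= 1e-12 * (abs(E0) + 1)) {
          ## predicted decrease below energy roundoff: take the Newton step
          x <- x + du
          mu <- mu / 3; if (mu < 1e-10) mu <- 0
          accepted <- TRUE
          break
        }
        alpha <- 1
        ok <- FALSE
        while (alpha >= 2^-16) {
          xn <- x + alpha * du
          En <- tryCatch(total_energy(xn, mesh, ref, p),
                         error = function(e) Inf)
          if (is.finite(En) && En <= E0 + 1e-4 * alpha * slope) {
            ok <- TRUE; break
          }
          alpha <- alpha / 2
        }
        if (ok) {
          x <- xn
          mu <- mu / 3
          if (mu < 1e-10) mu <- 0
          accepted <- TRUE
          break
        }
        mu <- max(mu * 10, 1e-8)
      }
      if (!accepted) break   # stalled; reported through the residual check
    }
    g <- scatter_gradient(total_element_gradient(x, mesh, ref, p), tri, n)
    rn <- max(abs(as.numeric(Matrix::crossprod(Tb, g))))
    if (rn > step_tol * 1.0001) {
      converged <- FALSE
      break
    }
  }
  apex <- which.max(mesh$nodes[, 3])
  res <- structure(list(
    deformed_nodes = x,
    apex_axial_displacement = (x[apex, 3] - mesh$nodes[apex, 3]) * 1000,
    residual_norm = rn, iterations = total_iter,
    converged = converged && rn <= tol * 1.0001,
    residual_history = hist), class = "inflation_result")
  if (!res$converged)
    warning("inflation did not converge: residual ", format(rn, digits = 4),
            " after ", total_iter, " iterations")
  res
}

#' @export
print.inflation_result <- function(x, ...) {
  cat("Inflation result:", if (x$converged) "converged" else "NOT converged",
      "in", x$iterations, "iterations; residual",
      format(x$residual_norm, digits = 4), "\n")
  cat("  apex axial displacement:",
      format(x$apex_axial_displacement, digits = 5), "um\n")
  invisible(x)
}

#' Per-element membrane Cauchy stress of an inflation state
#'
#' Mean in-plane Cauchy stress per element,
#' `2 W'(I1) ((lambda1^2 + lambda2^2)/2 - lambda3^2)` with the
#' element's stiffness scaling applied, Pa.
#'
#' @param mesh a [membrane_mesh()].
#' @param result an [inflate()] result.
#' @return numeric vector, one value per element.
#' @export
membrane_stress <- function(mesh, result) {
  ref <- mesh_reference(mesh)
  st <- element_state(result$deformed_nodes, mesh$triangles, ref)
  lam3_sq <- ref$detA / st$deta
  tr2 <- st$I1 - lam3_sq      # lambda1^2 + lambda2^2
  dW <- yeoh_dW(pmax(st$I1, 3), mesh$material) * mesh$stiffness_scale
  2 * dW * (tr2 / 2 - lam3_sq)
}

#' Inversely determine the stress-free geometry
#'
#' Fixed-point (deflation) iteration for the unloaded configuration: the
#' stress-free guess is updated by the damped residual
#' `X <- X + damping * (target - inflate(X))`, with Anderson(1) (secant)
#' acceleration of the slowly contracting modes, until the inflated
#' geometry reproduces the target within `tol` (maximum nodal distance).
#' The target must be attainable by the membrane under the given
#' pressure; a persistent error rise over several consecutive iterations
#' raises a non-contraction failure with the error history.
#'
#' @param target_nodes the stressed (measured) geometry, n x 3 mm.
#' @param mesh a [membrane_mesh()] providing topology, thickness,
#'   material and boundary conditions.
#' @param pressure inflating pressure, Pa.
#' @param tol maximum nodal distance tolerance, mm (default 1e-4 =
#'   0.1 um).
#' @param max_iter maximum fixed-point iterations.
#' @param damping update damping factor in (0, 1].
#' @param accelerate apply Anderson(1) acceleration (default TRUE).
#' @return the mesh with stress-free `nodes`; attributes
#'   `iterations`, `error_history` (mm), `converged`.
#' @export
find_stress_free <- function(target_nodes, mesh, pressure, tol = 1e-4,
                             max_iter = 100, damping = 0.5,
                             accelerate = TRUE) {
  target <- as.matrix(target_nodes)
  X <- target
  errs <- numeric(0)
  init <- NULL
  converged <- FALSE
  best_err <- Inf
  best_X <- X
  g_prev <- f_prev <- NULL
  rises <- 0
  for (it in seq_len(max_iter)) {
    m <- mesh; m$nodes <- X
    res <- inflate(m, pressure, init = init)
    init <- res$deformed_nodes
    err <- max(sqrt(rowSums((res$deformed_nodes - target)^2)))
    errs <- c(errs, err)
    if (err <= tol) { converged <- TRUE; break }
    if (err < best_err) {
      best_err <- err; best_X <- X
      rises <- 0
    } else {
      rises <- rises + 1
      if (rises >= 8)
        stop("stress-free iteration is not contracting (error history: ",
             paste(format(errs, digits = 4), collapse = ", "), ")")
    }
    g <- X + damping * (target - res$deformed_nodes)
    f <- g - X
    if (accelerate && !is.null(f_prev) && err < 2 * best_err) {
      df <- f - f_prev
      gam <- sum(f * df) / sum(df * df)
      Xn <- g - gam * (g - g_prev)
    } else Xn <- g
    g_prev <- g; f_prev <- f
    X <- Xn
  }
  if (!converged)
    warning("stress-free search hit max_iter with error ",
            format(errs[length(errs)], digits = 4), " mm")
  out <- mesh; out$nodes <- X
  attr(out, "iterations") <- length(errs)
  attr(out, "error_history") <- errs
  attr(out, "converged") <- converged
  out
}

#' Extract a surface sampling from an inflated polar mesh
#'
#' Interpolates the deformed surface of a polar (ring/sector) mesh onto a
#' regular Cartesian grid and returns it as a [surface_sampling()] in the
#' package's sag convention (sag measured posteriorly from the reference
#' apex level). Interpolation is linear along meridians (in deformed
#' planform radius) and in angle across sectors.
#'
#' @param mesh a polar [membrane_mesh()] (as from [cap_mesh_sphere()]).
#' @param result an [inflate()] result (or NULL for the reference shape).
#' @param zone_diameter output zone diameter, mm.
#' @param grid_spacing output grid step, mm.
#' @param surface_side label for the output surface.
#' @param label output label.
#' @return a [surface_sampling()].
#' @export
surface_from_inflation <- function(mesh, result = NULL, zone_diameter = 8,
                                   grid_spacing = 0.1,
                                   surface_side = "anterior",
                                   label = "inflated membrane") {
  stopifnot(inherits(mesh, "membrane_mesh"), !is.null(mesh$polar))
  x <- if (is.null(result)) mesh$nodes else result$deformed_nodes
  pol <- mesh$polar
  n_phi <- length(pol$phi)
  apex_z <- x[1, 3]
  ## per-sector meridian: apex + one node per ring
  merid_r <- merid_z <- matrix(0, length(pol$ring_radius) + 1, n_phi)
  for (j in seq_len(n_phi)) {
    nd <- which(pol$node_sector == j)
    nd <- nd[order(pol$node_ring[nd])]
    merid_r[, j] <- c(0, sqrt(x[nd, 1]^2 + x[nd, 2]^2))
    merid_z[, j] <- c(apex_z, x[nd, 3])
  }
  g <- disk_grid(zone_diameter, grid_spacing)
  r <- sqrt(g$x^2 + g$y^2)
  phi <- atan2(g$y, g$x) %% (2 * pi)
  dphi <- 2 * pi / n_phi
  j0 <- floor(phi / dphi) + 1
  j1 <- j0 %% n_phi + 1
  w <- (phi - (j0 - 1) * dphi) / dphi
  z <- numeric(length(r))
  for (j in unique(j0)) {
    sel <- j0 == j
    z0 <- stats::approx(merid_r[, j], merid_z[, j], xout = r[sel],
                        rule = 2)$y
    z1 <- stats::approx(merid_r[, j %% n_phi + 1], merid_z[, j %% n_phi + 1],
                        xout = r[sel], rule = 2)$y
    z[sel] <- (1 - w[sel]) * z0 + w[sel] * z1
  }
  ## sag convention: posterior-positive, zero at the reference apex level
  sag <- apex_z - z
  surface_sampling(data.frame(x = g$x, y = g$y, z = sag),
                   surface_side = surface_side,
                   zone_diameter = zone_diameter, label = label,
                   grid_spacing = grid_spacing)
}
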