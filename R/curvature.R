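## Curvature analysis: biconic least-squares fitting, clinical sagittal
## (axial) curvature maps, difference maps, extrema, and axial-length
## change extraction.

#' Biconic fit parameters
#'
#' @param Rx,Ry apical radii (mm, > 0).
#' @param Qx,Qy asphericities.
#' @param rms_residual rms elevation residual of the fit, mm.
#' @return object of class `biconic_params`.
#' @export
biconic_params <- function(Rx, Ry, Qx = 0, Qy = 0, rms_residual = 0) {
  if (Rx <= 0 || Ry <= 0) stop("radii must be positive")
  if (rms_residual < 0) stop("rms_residual must be >= 0")
  structure(list(Rx = Rx, Ry = Ry, Qx = Qx, Qy = Qy,
                 rms_residual = rms_residual), class = "biconic_params")
}

#' @export
print.biconic_params <- function(x, ...) {
  cat(sprintf("Biconic: Rx = %.4f mm, Ry = %.4f mm, Qx = %+.4f, Qy = %+.4f (rms %.2e mm)\n",
              x$Rx, x$Ry, x$Qx, x$Qy, x$rms_residual))
  invisible(x)
}

#' Fit a biconic surface to a corneal sampling
#'
#' Nonlinear least squares of the biconic sag on the points inside the
#' fitting zone (Levenberg-Marquardt through \pkg{minpack.lm}).
#' Initialization: a paraxial sphere fit (linear in 1/R) with
#' `Qx = Qy = 0`. Deterministic given the data.
#'
#' @param surface a [surface_sampling()].
#' @param zone_diameter fitting zone diameter, mm (default 5).
#' @param fit_offset also estimate an apex sag offset `z0` (default TRUE),
#'   so that surfaces referenced to a different apex plane (e.g. deformed
#'   post-operative geometry) are fitted in their own apex frame.
#' @return a [biconic_params()] (with the fitted offset in field `z0`).
#' @export
fit_biconic <- function(surface, zone_diameter = 5, fit_offset = TRUE) {
  stopifnot(inherits(surface, "surface_sampling"))
  pts <- surface$points
  keep <- sqrt(pts$x^2 + pts$y^2) <= zone_diameter / 2 + 1e-9
  pts <- pts[keep, , drop = FALSE]
  if (nrow(pts) < 6) stop("need at least 6 points inside the fitting zone")
  if (qr(cbind(1, pts$x, pts$y, pts$x^2, pts$y^2))$rank < 4)
    stop("degenerate point set: rank-deficient design")
  ## paraxial sphere start: z - z0 ~ (x^2+y^2)/(2R)
  r2 <- pts$x^2 + pts$y^2
  co0 <- qr.coef(qr(cbind(1, r2 / 2)), pts$z)
  R0 <- if (is.finite(co0[2]) && co0[2] > 1e-6) 1 / co0[2] else 8
  z0_start <- if (fit_offset) unname(co0[1]) else 0
  resid_fn <- function(p) {
    Rx <- p[1]; Ry <- p[2]; Qx <- p[3]; Qy <- p[4]
    z0 <- if (fit_offset) p[5] else 0
    if (Rx <= 0.5 || Ry <= 0.5) return(rep(1e3, nrow(pts)))
    rad <- 1 - (1 + Qx) * pts$x^2 / Rx^2 - (1 + Qy) * pts$y^2 / Ry^2
    bad <- rad <= 1e-10
    rad[bad] <- 1e-10
    model <- (pts$x^2 / Rx + pts$y^2 / Ry) / (1 + sqrt(rad)) + z0
    out <- model - pts$z
    out[bad] <- out[bad] + 1e3   # push solver back into the domain
    out
  }
  start <- c(R0, R0, 0, 0)
  if (fit_offset) start <- c(start, z0_start)
  fit <- minpack.lm::nls.lm(
    par = start, fn = resid_fn,
    control = minpack.lm::nls.lm.control(
      maxiter = 500, ftol = 1e-15, ptol = 1e-15, gtol = 0))
  ## iteration-cap exits with a sub-nanometre residual are converged fits
  if (fit$info %in% c(0, 5, 9) && sqrt(mean(fit$fvec^2)) > 1e-9)
    stop("biconic fit did not converge: ", fit$message,
         " (residual trace: ",
         paste(format(utils::tail(fit$rsstrace, 8), digits = 4),
               collapse = ", "), ")")
  p <- fit$par
  out <- biconic_params(p[1], p[2], p[3], p[4],
                        rms_residual = sqrt(mean(fit$fvec^2)))
  out$z0 <- if (fit_offset) p[5] else 0
  out
}

## reshape a gridded sampling into matrices; errors if not a regular grid
surface_as_grid <- function(surface) {
  pts <- surface$points
  ux <- sort(unique(pts$x)); uy <- sort(unique(pts$y))
  Z <- matrix(NA_real_, length(ux), length(uy))
  Z[cbind(match(pts$x, ux), match(pts$y, uy))] <- pts$z
  h <- if (!is.na(surface$grid_spacing)) surface$grid_spacing
       else stats::median(diff(ux))
  list(x = ux, y = uy, z = Z, h = h)
}

## central (interior) / one-sided (disk edge) finite differences of a
## matrix with NA padding outside the sampled disk
grid_gradient <- function(Z, h) {
  n <- nrow(Z); m <- ncol(Z)
  pad <- function(M, di, dj) {
    out <- matrix(NA_real_, n, m)
    is <- seq_len(n) + di; js <- seq_len(m) + dj
    ok_i <- is >= 1 & is <= n; ok_j <- js >= 1 & js <= m
    out[ok_i, ok_j] <- M[is[ok_i], js[ok_j]]
    out
  }
  diff_axis <- function(zp, zm) {
    ## central where both neighbours exist, one-sided otherwise
    d <- (zp - zm) / (2 * h)
    fwd <- (zp - Z) / h
    bwd <- (Z - zm) / h
    d[is.na(d)] <- fwd[is.na(d)]
    d[is.na(d)] <- bwd[is.na(d)]
    d
  }
  list(zx = diff_axis(pad(Z, 1, 0), pad(Z, -1, 0)),
       zy = diff_axis(pad(Z, 0, 1), pad(Z, 0, -1)))
}

## local quadric (2nd-order) fit around one grid point; returns the
## paraxial mean curvature (zxx + zyy)/2 -> here d2 coefficients
quadric_mean_curvature <- function(g, i, j) {
  ii <- max(1, i - 1):min(length(g$x), i + 1)
  jj <- max(1, j - 1):min(length(g$y), j + 1)
  pts <- expand.grid(i = ii, j = jj)
  z <- g$z[cbind(pts$i, pts$j)]
  ok <- !is.na(z)
  x <- g$x[pts$i[ok]] - g$x[i]; y <- g$y[pts$j[ok]] - g$y[j]
  A <- cbind(1, x, y, x^2, y^2, x * y)
  co <- qr.coef(qr(A), z[ok])
  co[is.na(co)] <- 0
  unname(co[4] + co[5])   # (zxx + zyy)/2 paraxial mean curvature, 1/mm
}

#' Sagittal (axial) curvature map of a corneal surface
#'
#' Clinical axial curvature on the surface's native grid: at each point
#' the axial radius is the distance along the surface normal from the
#' point to the reference axis (the vertical line through the map
#' origin), i.e. `R_axial = r / sin(alpha)` with `r` the planform
#' distance from the origin and `alpha` the tilt of the surface normal.
#' Curvature is converted to diopters with the refractive-index step of
#' the surface side. The origin is the geometric apex (the axis) for
#' healthy corneas, or the most elevated surface point when
#' `re_origin = TRUE` (keratoconus convention). At the origin itself the
#' value is the meridional (paraxial) limit from a local quadric fit.
#'
#' @param surface a gridded [surface_sampling()].
#' @param zone_diameter map zone diameter, mm (default 8); points outside
#'   are masked.
#' @param re_origin use the most elevated point as origin (default FALSE).
#' @param mode "axial" (clinical sagittal/axial curvature, default) or
#'   "meridional" (tangential curvature along the meridian).
#' @return object of class `curvature_map`: list with `x`, `y` (grid
#'   axes, mm), `K` (matrix, diopters), `origin`, `zone_diameter`,
#'   `surface_side`.
#' @export
sagittal_map <- function(surface, zone_diameter = 8, re_origin = FALSE,
                         mode = c("axial", "meridional")) {
  mode <- match.arg(mode)
  stopifnot(inherits(surface, "surface_sampling"))
  g <- surface_as_grid(surface)
  dn <- if (surface$surface_side == "anterior") 0.375 else -0.042
  origin <- if (re_origin) {
    ap <- apex_point(surface); c(ap$x, ap$y)
  } else c(0, 0)
  gr <- grid_gradient(g$z, g$h)
  slope2 <- gr$zx^2 + gr$zy^2
  X <- matrix(g$x, length(g$x), length(g$y))
  Y <- matrix(g$y, length(g$x), length(g$y), byrow = TRUE)
  r <- sqrt((X - origin[1])^2 + (Y - origin[2])^2)
  if (mode == "axial") {
    sin_a <- sqrt(slope2 / (1 + slope2))
    K <- 1000 * dn * sin_a / r
  } else {
    ## tangential curvature along the meridian through the origin
    ex <- (X - origin[1]) / r; ey <- (Y - origin[2]) / r
    dzdr <- gr$zx * ex + gr$zy * ey
    ## second derivative along the meridian by differencing dz/dr
    ## via the axial first derivatives of the slope components
    gx2 <- grid_gradient(gr$zx, g$h); gy2 <- grid_gradient(gr$zy, g$h)
    d2 <- gx2$zx * ex^2 + (gx2$zy + gy2$zx) * ex * ey + gy2$zy * ey^2
    K <- 1000 * dn * d2 / (1 + dzdr^2)^1.5
  }
  ## origin-adjacent cells: meridional/paraxial limit from a quadric fit
  near <- which(r < 0.75 * g$h, arr.ind = TRUE)
  for (k in seq_len(nrow(near)))
    K[near[k, 1], near[k, 2]] <-
      1000 * dn * quadric_mean_curvature(g, near[k, 1], near[k, 2])
  ## mask to the display zone (centred on the instrument axis)
  K[sqrt(X^2 + Y^2) > zone_diameter / 2 + 1e-9] <- NA_real_
  structure(list(x = g$x, y = g$y, K = K, origin = origin,
                 zone_diameter = zone_diameter,
                 surface_side = surface$surface_side, mode = mode),
            class = "curvature_map")
}

#' @export
print.curvature_map <- function(x, ...) {
  cat("Sagittal curvature map (", x$mode, "), ", x$surface_side,
      " surface, zone ", x$zone_diameter, " mm\n", sep = "")
  cat("  origin: (", x$origin[1], ", ", x$origin[2], ") mm; K range [dpt]: ",
      paste(format(range(x$K, na.rm = TRUE), digits = 4), collapse = " .. "),
      "\n", sep = "")
  invisible(x)
}

#' @export
plot.curvature_map <- function(x, main = "sagittal curvature [dpt]", ...) {
  graphics::image(x$x, x$y, x$K, asp = 1, xlab = "x [mm]", ylab = "y [mm]",
                  main = main, col = grDevices::hcl.colors(64, "Spectral",
                                                          rev = TRUE), ...)
  invisible(x)
}

#' Pointwise difference of two curvature maps
#'
#' `post - pre` on the shared grid; origin metadata is carried from the
#' post-operative map.
#'
#' @param post,pre `curvature_map` objects on identical grids.
#' @return a `curvature_map` of the change in diopters.
#' @export
difference_map <- function(post, pre) {
  stopifnot(inherits(post, "curvature_map"), inherits(pre, "curvature_map"))
  if (!isTRUE(all.equal(post$x, pre$x)) || !isTRUE(all.equal(post$y, pre$y)) ||
      post$zone_diameter != pre$zone_diameter)
    stop("curvature maps are not aligned: grids or zones differ")
  out <- post
  out$K <- post$K - pre$K
  out
}

#' Extrema of a curvature map
#'
#' Maximum and minimum map values with their grid locations. Ties are
#' broken by smallest planform radius from the map origin, then smallest
#' polar angle in [0, 2*pi).
#'
#' @param map a `curvature_map`.
#' @return list with `Kmax` and `Kmin`, each `list(value, x, y)`.
#' @export
extract_extrema <- function(map) {
  stopifnot(inherits(map, "curvature_map"))
  ok <- which(!is.na(map$K), arr.ind = TRUE)
  if (!nrow(ok)) stop("empty curvature map")
  vals <- map$K[ok]
  xs <- map$x[ok[, 1]]; ys <- map$y[ok[, 2]]
  r <- sqrt((xs - map$origin[1])^2 + (ys - map$origin[2])^2)
  ang <- atan2(ys - map$origin[2], xs - map$origin[1]) %% (2 * pi)
  pick <- function(target) {
    cand <- which(abs(vals - target) <= 1e-12)
    cand <- cand[order(r[cand], ang[cand])]
    i <- cand[1]
    list(value = vals[i], x = xs[i], y = ys[i])
  }
  list(Kmax = pick(max(vals)), Kmin = pick(min(vals)))
}

#' Axial-length change between two surfaces
#'
#' Signed maximal-magnitude axial displacement between two samplings of
#' the same surface in a common frame, in anterior-positive elevation
#' terms: a receding anterior surface (sag increase) gives a negative
#' value, i.e. an axial-length reduction.
#'
#' @param post,pre [surface_sampling()] objects on the same (x, y)
#'   sampling.
#' @return signed axial-length change in mm.
#' @export
delta_axial_length <- function(post, pre) {
  stopifnot(inherits(post, "surface_sampling"),
            inherits(pre, "surface_sampling"))
  if (nrow(post$points) != nrow(pre$points) ||
      max(abs(post$points$x - pre$points$x),
          abs(post$points$y - pre$points$y)) > 1e-9)
    stop("surfaces do not share the same (x, y) sampling")
  d_elev <- -(post$points$z - pre$points$z)
  d_elev[which.max(abs(d_elev))]
}
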