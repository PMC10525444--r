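## Synthetic corneal surfaces: biconic base shapes, keratoconic cones,
## and the parametric ICRS-induced deformation used to emulate the
## post-operative geometry.
##
## Axis convention (used everywhere in the package): z is the axial sag in
## mm, zero at the pre-operative apex and increasing posteriorly. The
## anterior-positive "elevation" is -z, so the most elevated (most
## anterior) point of a surface is the sag minimum. A keratoconic cone
## protrudes anteriorly and therefore *subtracts* from the sag.

#' Construct a corneal surface sampling
#'
#' A labeled set of 3D surface points for one corneal surface. `z` is the
#' axial sag (mm, posterior-positive, zero at the pre-op apex).
#'
#' @param points data.frame with numeric columns `x`, `y`, `z` (mm).
#' @param surface_side "anterior" or "posterior".
#' @param zone_diameter diameter (mm) over which the points are valid.
#' @param label free-text description.
#' @param grid_spacing grid step in mm if the points form a regular grid
#'   (NA for scattered data).
#' @return object of class `surface_sampling`.
#' @export
surface_sampling <- function(points, surface_side = c("anterior", "posterior"),
                             zone_diameter, label = "",
                             grid_spacing = NA_real_) {
  surface_side <- match.arg(surface_side)
  stopifnot(is.data.frame(points), all(c("x", "y", "z") %in% names(points)))
  if (zone_diameter <= 0) stop("zone_diameter must be positive")
  r <- sqrt(points$x^2 + points$y^2)
  if (any(r > zone_diameter / 2 + 1e-9))
    stop("points lie outside the declared zone_diameter")
  if (nrow(points) < 3) stop("need at least 3 points")
  if (any(!is.finite(points$z))) stop("non-finite elevations in surface points")
  structure(list(points = points[, c("x", "y", "z")],
                 surface_side = surface_side,
                 zone_diameter = zone_diameter,
                 label = label,
                 grid_spacing = grid_spacing),
            class = "surface_sampling")
}

#' @export
print.surface_sampling <- function(x, ...) {
  cat("Corneal surface sampling:", x$label, "\n")
  cat("  side:", x$surface_side, " zone:", x$zone_diameter, "mm ",
      nrow(x$points), "points\n")
  cat("  sag range [mm]:", format(range(x$points$z), digits = 4), "\n")
  invisible(x)
}

#' Biconic sag function
#'
#' Axial sag of a biconic surface with apical radii `Rx`, `Ry` (mm) and
#' asphericities `Qx`, `Qy`:
#' \deqn{z = \frac{x^2/R_x + y^2/R_y}{1 + \sqrt{1 - (1+Q_x)x^2/R_x^2 -
#'   (1+Q_y)y^2/R_y^2}}}
#' For `Rx = Ry = R`, `Qx = Qy = 0` this reduces to the spherical sag
#' `R - sqrt(R^2 - r^2)`.
#'
#' @param x,y coordinates in mm (vectorized).
#' @param Rx,Ry apical radii of curvature, mm (> 0).
#' @param Qx,Qy asphericities (0 = circle, negative = prolate).
#' @return sag in mm.
#' @export
biconic_sag <- function(x, y, Rx, Ry, Qx = 0, Qy = 0) {
  if (Rx <= 0 || Ry <= 0) stop("radii must be positive")
  rad <- 1 - (1 + Qx) * x^2 / Rx^2 - (1 + Qy) * y^2 / Ry^2
  if (any(rad <= 0)) {
    i <- which.min(rad)
    stop(sprintf(paste0("biconic radicand non-positive at (x=%.3f, y=%.3f): ",
                        "radius/Q pairs (Rx=%.3f, Qx=%.3f), (Ry=%.3f, Qy=%.3f)"),
                 x[i], y[i], Rx, Qx, Ry, Qy))
  }
  (x^2 / Rx + y^2 / Ry) / (1 + sqrt(rad))
}

## regular square-grid coordinates clipped to a disk; always contains
## the symmetric axes (x = 0 and y = 0 lines)
disk_grid <- function(zone_diameter, grid_spacing) {
  half <- floor((zone_diameter / 2) / grid_spacing) * grid_spacing
  ax <- seq(-half, half, by = grid_spacing)
  g <- expand.grid(x = ax, y = ax)
  g[sqrt(g$x^2 + g$y^2) <= zone_diameter / 2 + 1e-9, ]
}

#' Generate a biconic surface sampling
#'
#' Evaluates the biconic sag on a regular grid clipped to the analysis
#' zone. Optional zero-mean Gaussian measurement noise (standard
#' deviation in micrometres) can be added; the caller controls the RNG
#' state (e.g. via [set.seed()]).
#'
#' @param params list or `biconic_params` with `Rx`, `Ry`, `Qx`, `Qy`.
#' @param zone_diameter sampling zone diameter, mm.
#' @param grid_spacing grid step, mm.
#' @param surface_side "anterior" or "posterior".
#' @param label surface label.
#' @param noise_sd_um Gaussian noise sd in micrometres (default 0).
#' @return a [surface_sampling()].
#' @export
make_biconic_surface <- function(params, zone_diameter = 9, grid_spacing = 0.1,
                                 surface_side = "anterior", label = "biconic",
                                 noise_sd_um = 0) {
  g <- disk_grid(zone_diameter, grid_spacing)
  Qx <- if (is.null(params$Qx)) 0 else params$Qx
  Qy <- if (is.null(params$Qy)) 0 else params$Qy
  z <- biconic_sag(g$x, g$y, params$Rx, params$Ry, Qx, Qy)
  if (noise_sd_um > 0)
    z <- z + stats::rnorm(length(z), sd = noise_sd_um / 1000)
  surface_sampling(data.frame(x = g$x, y = g$y, z = z),
                   surface_side = surface_side,
                   zone_diameter = zone_diameter, label = label,
                   grid_spacing = grid_spacing)
}

#' Keratoconic cone specification
#'
#' Parameters of the synthetic keratoconic cone: a smooth anterior
#' protrusion (Gaussian in planform radius) centred off-axis, plus the
#' two concentric stiffness-weakening zones used by the mechanics module.
#' The default multipliers follow the published keratoconic material
#' table: the cone core retains 30% and the surrounding annulus 70% of
#' the healthy stiffness (the zone-to-multiplier assignment is
#' configurable, as the zone wording in the source model is ambiguous).
#'
#' @param center (x, y) offset of the cone apex from the axis, mm.
#' @param amplitude added anterior elevation at the cone centre, um.
#' @param width Gaussian decay length (sigma) of the bump, mm.
#' @param inner_weaken_fraction stiffness multiplier of the core zone.
#' @param outer_weaken_fraction stiffness multiplier of the outer zone.
#' @param core_radius,outer_radius zone radii, mm.
#' @return object of class `cone_spec`.
#' @export
cone_spec <- function(center = c(0, -1), amplitude = 80, width = 1.5,
                      inner_weaken_fraction = 0.30,
                      outer_weaken_fraction = 0.70,
                      core_radius = 1.25, outer_radius = 2.5) {
  if (amplitude < 0) stop("amplitude must be >= 0")
  if (!(inner_weaken_fraction > 0 &&
        inner_weaken_fraction <= outer_weaken_fraction &&
        outer_weaken_fraction <= 1))
    stop("need 0 < inner_weaken_fraction <= outer_weaken_fraction <= 1")
  if (core_radius >= outer_radius) stop("core_radius must be < outer_radius")
  structure(list(center = as.numeric(center), amplitude = amplitude,
                 width = width,
                 inner_weaken_fraction = inner_weaken_fraction,
                 outer_weaken_fraction = outer_weaken_fraction,
                 core_radius = core_radius, outer_radius = outer_radius),
            class = "cone_spec")
}

#' Add a keratoconic cone to a surface
#'
#' Superimposes a smooth, radially decaying anterior protrusion centred
#' at `cone$center`: the sag decreases by
#' `amplitude * exp(-d^2 / (2 width^2))`, which locally steepens the
#' surface. The added anterior elevation is maximal (equal to
#' `amplitude`) at the cone centre and negligible beyond a few decay
#' lengths.
#'
#' @param surface a [surface_sampling()].
#' @param cone a [cone_spec()].
#' @return the modified surface (label suffixed with "+KC cone").
#' @export
add_kc_cone <- function(surface, cone) {
  stopifnot(inherits(surface, "surface_sampling"), inherits(cone, "cone_spec"))
  if (sqrt(sum(cone$center^2)) > surface$zone_diameter / 2)
    stop("cone center lies outside the surface zone")
  pts <- surface$points
  d2 <- (pts$x - cone$center[1])^2 + (pts$y - cone$center[2])^2
  bump_mm <- (cone$amplitude / 1000) * exp(-d2 / (2 * cone$width^2))
  pts$z <- pts$z - bump_mm
  out <- surface
  out$points <- pts
  out$label <- paste0(surface$label, " +KC cone")
  out
}

#' Most elevated (most anterior) point of a surface
#'
#' Grid argmin of the sag; ties are broken by smallest planform radius,
#' then smallest polar angle in [0, 2*pi).
#'
#' @param surface a [surface_sampling()].
#' @return list with `x`, `y`, `z` of the apex point.
#' @export
apex_point <- function(surface) {
  pts <- surface$points
  zmin <- min(pts$z)
  cand <- which(pts$z <= zmin + 1e-12)
  if (length(cand) > 1) {
    r <- sqrt(pts$x[cand]^2 + pts$y[cand]^2)
    ang <- atan2(pts$y[cand], pts$x[cand]) %% (2 * pi)
    cand <- cand[order(r, ang)]
  }
  i <- cand[1]
  list(x = pts$x[i], y = pts$y[i], z = pts$z[i])
}

#' Intracorneal ring segment design
#'
#' Geometry and material of one ICRS: an arc-shaped implant of
#' triangular cross-section with linearly varying thickness and base
#' width along the arc. The six named designs of the study are available
#' through [icrs_design_set()].
#'
#' @param name design name.
#' @param arc_length arc span, degrees (0 < arc <= 360).
#' @param start_thickness,end_thickness thickness at the two arc ends, um.
#' @param start_width,end_width base width at the two arc ends, um.
#' @param optical_zone optical zone diameter, mm.
#' @param orientation angular position (degrees, CCW from +x) of the arc
#'   start end; the arc sweeps counter-clockwise.
#' @param material_E Young's modulus of the implant, MPa (PMMA: 3300).
#' @param material_nu Poisson's ratio (PMMA: 0.4).
#' @param material_rho density, kg/m^3 (PMMA: 1062).
#' @return object of class `icrs_design`.
#' @export
icrs_design <- function(name, arc_length = 160,
                        start_thickness = 225, end_thickness = 225,
                        start_width = 700, end_width = 700,
                        optical_zone = 6, orientation = -170,
                        material_E = 3300, material_nu = 0.4,
                        material_rho = 1062) {
  if (!(arc_length > 0 && arc_length <= 360))
    stop("arc_length must be in (0, 360]")
  if (min(start_thickness, end_thickness, start_width, end_width) <= 0)
    stop("thickness and width profiles must be positive")
  if (optical_zone <= 0) stop("optical_zone must be positive")
  structure(list(name = name, arc_length = arc_length,
                 start_thickness = start_thickness,
                 end_thickness = end_thickness,
                 start_width = start_width, end_width = end_width,
                 optical_zone = optical_zone, orientation = orientation,
                 material_E = material_E, material_nu = material_nu,
                 material_rho = material_rho),
            class = "icrs_design")
}

#' The six ICRS designs of the comparison study
#'
#' asym: the progressive asymmetric segment (160 deg arc, thickness
#' 150 -> 300 um, base width 600 -> 800 um, 6 mm optical zone); sym: the
#' average symmetric segment (225 um x 700 um, the asym cross-section at
#' half arc); symMax / symMin: symmetric segments with the maximal
#' (300 x 800) and minimal (150 x 600) asym cross-sections; asymW /
#' asymTH: width-only and thickness-only progressive variants.
#'
#' @param orientation arc-start angular position in degrees applied to
#'   all designs (default places the arc on the inferior cornea).
#' @return named list of [icrs_design()] objects.
#' @export
icrs_design_set <- function(orientation = -170) {
  list(
    asym   = icrs_design("asym",   start_thickness = 150, end_thickness = 300,
                         start_width = 600, end_width = 800,
                         orientation = orientation),
    sym    = icrs_design("sym",    orientation = orientation),
    symMax = icrs_design("symMax", start_thickness = 300, end_thickness = 300,
                         start_width = 800, end_width = 800,
                         orientation = orientation),
    symMin = icrs_design("symMin", start_thickness = 150, end_thickness = 150,
                         start_width = 600, end_width = 600,
                         orientation = orientation),
    asymW  = icrs_design("asymW",  start_thickness = 225, end_thickness = 225,
                         start_width = 600, end_width = 800,
                         orientation = orientation),
    asymTH = icrs_design("asymTH", start_thickness = 150, end_thickness = 300,
                         start_width = 700, end_width = 700,
                         orientation = orientation))
}

## Angular amplitude profile of the ICRS effect, in micrometres of apex-
## level sag change, at planform angles `phi_deg`. Positive = flattening
## (sag increase / anterior recession) on the ring-track side; a smaller
## negative (steepening) lobe sits on the diametrically opposite half.
icrs_angular_amplitude <- function(phi_deg, design, gain,
                                   opposite_fraction = 0.15,
                                   taper_deg = 20) {
  arc <- design$arc_length
  ## arc coordinate s in [0,1] from the start end, sweeping CCW
  delta <- (phi_deg - design$orientation) %% 360
  s <- delta / arc
  cs <- function(s) {  # local cross-section, mm^2
    th <- design$start_thickness + s * (design$end_thickness - design$start_thickness)
    w  <- design$start_width + s * (design$end_width - design$start_width)
    (th / 1000) * (w / 1000)
  }
  amp <- numeric(length(phi_deg))
  inarc <- delta <= arc
  amp[inarc] <- gain * cs(s[inarc])
  ## raised-cosine taper beyond each arc end
  past_end <- delta > arc & delta <= arc + taper_deg
  amp[past_end] <- gain * cs(1) *
    cos((delta[past_end] - arc) / taper_deg * pi / 2)^2
  before_start <- delta >= 360 - taper_deg
  amp[before_start] <- gain * cs(0) *
    cos((360 - delta[before_start]) / taper_deg * pi / 2)^2
  ## opposite-half steepening lobe, centred opposite the arc midpoint
  mean_cs <- (cs(0) + cs(1)) / 2
  mid <- design$orientation + arc / 2
  dpsi <- ((phi_deg - mid - 180 + 180) %% 360) - 180
  opp <- abs(dpsi) < 90
  amp[opp] <- amp[opp] -
    opposite_fraction * gain * mean_cs * cos(dpsi[opp] / 90 * pi / 2)^2
  amp
}

#' Apply the geometric ICRS effect to a surface
#'
#' Emulates the first-order geometric consequence of ICRS implantation on
#' the analysed surface: a smooth, locally restricted flattening of the
#' zone enclosed by the ring track on the implanted half (sag increases,
#' the surface recedes), with magnitude proportional to
#' `gain x local thickness x local width` interpolated linearly along the
#' arc, and a smaller opposite-sign (steepening) perturbation on the
#' diametrically opposite half. The radial profile is
#' `(1 - (r/b)^2)^2` inside `b` = optical-zone radius + maximal base
#' width and exactly zero outside, so elevation beyond the perturbation
#' support is conserved to machine precision. This is an emulation knob
#' for exercising the downstream analyses, not a mechanical prediction.
#'
#' @param surface an anterior [surface_sampling()] (posterior surfaces
#'   are accepted with `allow_posterior = TRUE`, e.g. with a reduced gain).
#' @param design an [icrs_design()].
#' @param gain flattening gain in um of sag change per mm^2 of local ring
#'   cross-section (default 400, calibrated so the healthy `sym` scenario
#'   flattens by roughly 3-4 dpt in mean meridional power).
#' @param opposite_fraction relative magnitude of the opposite-half
#'   steepening lobe.
#' @param allow_posterior permit application to a posterior surface.
#' @return the perturbed surface.
#' @export
apply_icrs_effect <- function(surface, design, gain = 400,
                              opposite_fraction = 0.15,
                              allow_posterior = FALSE) {
  stopifnot(inherits(surface, "surface_sampling"),
            inherits(design, "icrs_design"))
  if (gain < 0) stop("gain must be >= 0")
  if (surface$surface_side != "anterior" && !allow_posterior)
    stop("ICRS effect applies to the anterior surface")
  pts <- surface$points
  r <- sqrt(pts$x^2 + pts$y^2)
  b <- design$optical_zone / 2 +
    max(design$start_width, design$end_width) / 1000
  phi <- atan2(pts$y, pts$x) * 180 / pi
  A_um <- icrs_angular_amplitude(phi, design, gain, opposite_fraction)
  Abar <- mean(icrs_angular_amplitude(seq(0, 359.5, by = 0.5), design, gain,
                                      opposite_fraction))
  p <- ifelse(r < b, (1 - (r / b)^2)^2, 0)
  q <- 1 - exp(-(r / 1.0)^2)       # angular variation vanishes at the axis
  dz_mm <- (Abar + (A_um - Abar) * q) * p / 1000
  pts$z <- pts$z + dz_mm
  out <- surface
  out$points <- pts
  out$label <- paste0(surface$label, " +ICRS ", design$name)
  out
}
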