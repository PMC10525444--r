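## Refraction arithmetic: radius -> power conversion, mean meridional power,
## axial-length myopic shift, effective refractive change, summary tables.

## Keratometric index steps across the two corneal surfaces.
## Anterior: air (1.000) -> stroma (1.375); posterior: stroma -> aqueous (1.333).
REFRACTIVE_INDICES <- list(
  anterior  = c(n0 = 1.000, n1 = 1.375),
  posterior = c(n0 = 1.375, n1 = 1.333))

#' Convert a radius of curvature to refractive power
#'
#' Surface power in diopters from a radius of curvature and the
#' refractive-index step across the surface: `(n1 - n0) / R` with `R` in
#' metres. A convex anterior surface (air to stroma) has positive power;
#' the posterior surface (stroma to aqueous) has negative power.
#'
#' @param R radius of curvature in mm (vectorized).
#' @param side "anterior" or "posterior".
#' @return power in diopters.
#' @examples
#' radius_to_power(7.37, "anterior")   # ~ 50.88 dpt
#' radius_to_power(7.91, "posterior")  # ~ -5.31 dpt
#' @export
radius_to_power <- function(R, side = c("anterior", "posterior")) {
  side <- match.arg(side)
  if (any(!is.finite(R)) || any(R <= 0)) stop("radius must be positive")
  idx <- REFRACTIVE_INDICES[[side]]
  unname((idx["n1"] - idx["n0"]) / (R / 1000))
}

#' Mean meridional power of a biconic surface
#'
#' The scalar power assigned to a biconic surface: the arithmetic mean of
#' the powers of its two principal meridians, `(P(Rx) + P(Ry)) / 2`.
#' Alternative averaging rules (power of the mean radius; geometric mean
#' of the meridional powers) are available behind `rule`.
#'
#' @param params a `biconic_params` object or list with `Rx`, `Ry` (mm).
#' @param side "anterior" or "posterior".
#' @param rule averaging rule; default "mean_power".
#' @return power in diopters.
#' @export
mean_meridional_power <- function(params, side = c("anterior", "posterior"),
                                  rule = c("mean_power", "mean_radius",
                                           "geometric")) {
  side <- match.arg(side)
  rule <- match.arg(rule)
  px <- radius_to_power(params$Rx, side)
  py <- radius_to_power(params$Ry, side)
  switch(rule,
    mean_power  = (px + py) / 2,
    mean_radius = radius_to_power((params$Rx + params$Ry) / 2, side),
    geometric   = sign(px) * sqrt(abs(px * py)))
}

#' Myopic shift induced by an axial-length change
#'
#' A shortening of the globe by `|dAL|` moves the retina relative to the
#' eye's focal plane; to first order the refraction changes by
#' `D_total^2 * |dAL|` (dAL in metres), a myopic (positive) shift for an
#' axial-length reduction. With D = 60 dpt and dAL = 36 um this gives
#' 60^2 * 36e-6 = 0.13 dpt.
#'
#' @param delta_AL axial-length change in mm (sign ignored; the shift is
#'   reported as a magnitude).
#' @param total_power total ocular power in diopters (cornea + lens;
#'   60 for the healthy eye).
#' @return myopic shift in diopters (>= 0).
#' @export
myopic_shift <- function(delta_AL, total_power = 60) {
  if (total_power <= 0) stop("total_power must be positive")
  total_power^2 * abs(delta_AL) / 1000
}

#' Effective refractive change of an ICRS scenario
#'
#' Aggregates the anterior and posterior surface-power changes and the
#' axial-length contribution of one scenario:
#' `anterior_delta + posterior_delta - myopic_shift(|dAL|, D_total)`.
#' Sign convention: flattening negative, steepening positive; an
#' axial-length reduction offsets part of the flattening (the eye becomes
#' more myopic, i.e. the shift subtracts).
#'
#' @param anterior_delta_dpt anterior surface power change, dpt.
#' @param posterior_delta_dpt posterior surface power change, dpt.
#' @param delta_AL axial-length change, mm.
#' @param total_power total ocular power, dpt (60 healthy; 60 + keratoconic
#'   steepening for the KC eye).
#' @param digits reporting rounding (default 1 decimal place);
#'   `digits = NULL` returns the unrounded value.
#' @return effective refractive change in diopters.
#' @export
effective_change <- function(anterior_delta_dpt, posterior_delta_dpt,
                             delta_AL, total_power = 60, digits = 1) {
  val <- anterior_delta_dpt + posterior_delta_dpt -
    myopic_shift(delta_AL, total_power)
  if (is.null(digits)) val else round(val, digits)
}

## Total ocular power of the keratoconic model eye: 60 dpt baseline plus
## the average keratoconic steepening of +4.7 dpt.
KC_TOTAL_POWER <- 60 + 4.7

#' Reference biconic curvature table (simulated ICRS scenarios)
#'
#' The published biconic assessment of the six ICRS designs in the
#' simulated generic healthy and keratoconic corneas: radii of curvature
#' Rx/Ry (mm), their changes, axial-length change dAL (mm), asphericities
#' Qx/Qy, and the per-surface dioptric change, for the anterior and
#' posterior surfaces. These printed values are inputs to the refraction
#' arithmetic (and the source of the generator's default shape
#' parameters); they are not recomputed by the membrane model.
#'
#' @return data.frame with columns `surface_side`, `scenario`, `Rx`, `Ry`,
#'   `dRx`, `dRy`, `dAL`, `Qx`, `Qy`, `ddpt`.
#' @export
reference_curvature_table <- function() {
  ant <- rbind(
    c("healthy pre-op", 7.37, 7.62,    NA,    NA,    NA, -0.25, -0.10,    NA),
    c("healthy asym",   8.05, 7.95,  0.68,  0.33, -0.04,  1.21, -2.07, -3.17),
    c("healthy sym",    7.96, 8.14,  0.59,  0.52, -0.04, -0.13, -0.22, -3.44),
    c("healthy symMax", 8.36, 8.35,  0.99,  0.73, -0.04,  0.98, -1.40, -5.14),
    c("healthy symMin", 7.77, 7.87,  0.40,  0.25, -0.03, -0.18, -0.17, -2.09),
    c("healthy asymW",  7.97, 8.14,  0.60,  0.52, -0.04, -0.15, -0.21, -3.47),
    c("healthy asymTH", 7.96, 8.13,  0.59,  0.50, -0.04,  0.65, -0.94, -3.40),
    c("KC pre-op",      6.15, 7.24,    NA,    NA,  0.11, -1.55,  1.33,    NA),
    c("KC asym",        5.88, 7.72, -0.26,  0.48, -0.04, -3.83,  2.19, -0.89),
    c("KC sym",         6.34, 7.61,  0.19,  0.36, -0.04, -2.17,  1.76, -2.23),
    c("KC symMax",      6.89, 7.61,  0.75,  0.36, -0.05, -0.19, -0.18, -4.29),
    c("KC symMin",      6.20, 6.61,  0.05, -0.63, -0.04, -1.76, -2.54,  2.52),
    c("KC asymW",       6.44, 7.57,  0.29,  0.33, -0.04, -1.63,  1.53, -2.49),
    c("KC asymTH",      6.44, 6.79,  0.30, -0.46, -0.04, -0.01, -3.77,  0.68))
  post <- rbind(
    c("healthy pre-op", 7.91, 7.97,    NA,    NA, NA,  0.63,  0.37,    NA),
    c("healthy asym",   8.35, 8.70,  0.99,  1.08, NA,  5.18,  7.85,  0.39),
    c("healthy sym",    7.17, 7.40, -0.20, -0.22, NA, -1.39,  1.03, -0.51),
    c("healthy symMax", 8.74, 8.69,  1.37,  1.07, NA,  8.16,  9.08,  0.50),
    c("healthy symMin", 7.51, 7.45,  0.14, -0.17, NA, -0.19, -0.20, -0.35),
    c("healthy asymW",  7.18, 7.37, -0.19, -0.25, NA, -1.48,  1.08, -0.52),
    c("healthy asymTH", 7.10, 7.46, -0.26, -0.17, NA, -1.53,  1.10, -0.52),
    c("KC pre-op",      6.18, 6.81,    NA,    NA, NA, -1.13, -1.02,    NA),
    c("KC asym",        6.23, 7.55,  0.08,  0.31, NA,  1.11,  7.05,  0.40),
    c("KC sym",         6.34, 7.71,  0.19,  0.47, NA,  0.66,  7.32,  0.52),
    c("KC symMax",      6.54, 7.58,  0.40,  0.33, NA,  2.88,  7.59,  0.56),
    c("KC symMin",      5.86, 7.18, -0.28, -0.07, NA, -2.37,  4.01,  0.03),
    c("KC asymW",       6.48, 7.71,  0.34,  0.47, NA,  1.42,  7.36,  0.59),
    c("KC asymTH",      5.29, 6.35, -0.86, -0.89, NA, -2.56,  2.42, -0.80))
  build <- function(m, side) {
    df <- data.frame(surface_side = side, scenario = m[, 1],
                     stringsAsFactors = FALSE)
    num <- apply(m[, -1], 2, as.numeric)
    colnames(num) <- c("Rx", "Ry", "dRx", "dRy", "dAL", "Qx", "Qy", "ddpt")
    cbind(df, as.data.frame(num))
  }
  rbind(build(ant, "anterior"), build(post, "posterior"))
}

#' Effective refractive changes for all reference scenarios
#'
#' Applies [effective_change()] to every post-op scenario of the reference
#' curvature table: anterior and posterior per-surface power changes plus
#' the axial-length myopic shift, at total ocular power 60 dpt (healthy)
#' or 64.7 dpt (keratoconic eye, including its +4.7 dpt steepening).
#'
#' @param table reference table as from [reference_curvature_table()].
#' @param digits reporting rounding, default 1.
#' @return data.frame with one row per scenario: `scenario`,
#'   `anterior_delta_dpt`, `posterior_delta_dpt`, `delta_AL`,
#'   `total_power`, `myopic_shift`, `effective_change`.
#' @export
reference_effective_changes <- function(table = reference_curvature_table(),
                                        digits = 1) {
  ant <- table[table$surface_side == "anterior" & !is.na(table$ddpt), ]
  post <- table[table$surface_side == "posterior", ]
  rows <- lapply(seq_len(nrow(ant)), function(i) {
    sc <- ant$scenario[i]
    pd <- post$ddpt[post$scenario == sc]
    D <- if (grepl("^KC", sc)) KC_TOTAL_POWER else 60
    data.frame(scenario = sc,
               anterior_delta_dpt = ant$ddpt[i],
               posterior_delta_dpt = pd,
               delta_AL = ant$dAL[i],
               total_power = D,
               myopic_shift = myopic_shift(ant$dAL[i], D),
               effective_change = effective_change(ant$ddpt[i], pd,
                                                   ant$dAL[i], D, digits))
  })
  do.call(rbind, rows)
}

#' Build a curvature summary table from fitted scenarios
#'
#' Assembles the standard reporting table (one row per scenario and
#' surface: Rx, Ry, dRx, dRy, dAL, Qx, Qy, ddpt) from biconic fits of
#' pre- and post-op surfaces, recomputing the radius changes and the
#' per-surface mean meridional power change from the fitted radii.
#'
#' @param fits named list: for each scenario, a list with elements
#'   `anterior` and/or `posterior`, each a `biconic_params`, plus
#'   optionally `delta_AL` (mm).
#' @param pre name of the pre-op baseline scenario in `fits`.
#' @return data.frame in the reference table's column layout.
#' @export
build_summary_table <- function(fits, pre = "pre-op") {
  if (!pre %in% names(fits)) stop("missing pre-op baseline scenario '", pre, "'")
  sides <- intersect(c("anterior", "posterior"), names(fits[[pre]]))
  if (!length(sides)) stop("pre-op scenario carries no surface fits")
  scen <- names(fits)
  missing <- unlist(lapply(setdiff(scen, pre), function(sc)
    paste0(sc, ":", setdiff(sides, names(fits[[sc]])))))
  missing <- missing[!grepl(":$", missing)]
  if (length(missing))
    stop("incomplete scenario data: ", paste(missing, collapse = ", "))
  rows <- list()
  for (side in sides) {
    p0 <- fits[[pre]][[side]]
    P0 <- mean_meridional_power(p0, side)
    for (sc in scen) {
      p <- fits[[sc]][[side]]
      is_pre <- identical(sc, pre)
      rows[[length(rows) + 1]] <- data.frame(
        surface_side = side, scenario = sc,
        Rx = p$Rx, Ry = p$Ry,
        dRx = if (is_pre) NA_real_ else p$Rx - p0$Rx,
        dRy = if (is_pre) NA_real_ else p$Ry - p0$Ry,
        dAL = if (side == "anterior" && !is.null(fits[[sc]]$delta_AL))
                fits[[sc]]$delta_AL else NA_real_,
        Qx = p$Qx, Qy = p$Qy,
        ddpt = if (is_pre) NA_real_
               else mean_meridional_power(p, side) - P0,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
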