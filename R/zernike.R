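## Zernike aberration analysis (OSA/ANSI single indexing, orders 0..6).

#' OSA single index to (n, m)
#'
#' Converts the OSA/ANSI single index `j` into radial order `n` and
#' azimuthal frequency `m` (`m < 0` selects the sine term).
#'
#' @param j integer OSA index (0-based).
#' @return data.frame with columns `j`, `n`, `m`.
#' @export
osa_index <- function(j) {
  j <- as.integer(j)
  if (any(j < 0)) stop("OSA index must be >= 0")
  n <- ceiling((-3 + sqrt(9 + 8 * j)) / 2 - 1e-9)
  m <- 2 * j - n * (n + 2)
  data.frame(j = j, n = as.integer(n), m = as.integer(m))
}

## inverse map: j = (n(n+2)+m)/2
osa_j <- function(n, m) as.integer((n * (n + 2) + m) / 2)

#' Orthonormal Zernike polynomial value
#'
#' Value of the orthonormal (OSA/ANSI normalized) Zernike polynomial with
#' OSA single index `j` at polar coordinates on the unit disk. The radial
#' part uses the standard factorial formula; normalization is
#' \eqn{\sqrt{2(n+1)/(1+\delta_{m0})}} so that the basis is orthonormal
#' under the area-averaged inner product over the unit disk.
#'
#' @param j OSA index in 0..27 (orders 0..6).
#' @param rho radial coordinate(s), 0 <= rho <= 1.
#' @param theta azimuthal angle(s) in radians.
#' @return numeric vector of polynomial values.
#' @export
zernike_value <- function(j, rho, theta) {
  if (length(j) != 1 || is.na(j) || j < 0 || j > 27)
    stop("OSA index j must be a single integer in 0..27")
  if (any(rho < -1e-12 | rho > 1 + 1e-9))
    stop("rho must lie in [0, 1]")
  nm <- osa_index(j)
  n <- nm$n; m <- nm$m; am <- abs(m)
  rad <- zernike_radial(n, am, rho)
  norm <- sqrt(2 * (n + 1) / (1 + (m == 0)))
  ang <- if (m < 0) sin(am * theta) else cos(am * theta)
  norm * rad * ang
}

## R_n^|m|(rho), standard factorial formula
zernike_radial <- function(n, am, rho) {
  kmax <- (n - am) / 2
  out <- 0
  for (k in 0:kmax) {
    coef <- (-1)^k * factorial(n - k) /
      (factorial(k) * factorial((n + am) / 2 - k) * factorial((n - am) / 2 - k))
    out <- out + coef * rho^(n - 2 * k)
  }
  out
}

## design matrix of the 28 orthonormal basis functions at (rho, theta)
zernike_design <- function(rho, theta, max_order = 6) {
  jmax <- osa_j(max_order, max_order)
  vapply(0:jmax, function(j) zernike_value(j, rho, theta), numeric(length(rho)))
}

#' Fit a sixth-order Zernike spectrum to surface elevation
#'
#' Linear least squares of anterior (or posterior) elevation, in
#' micrometres, on the 28 orthonormal Zernike polynomials of radial
#' orders 0..6, evaluated over a circular pupil centred on the axis.
#' Elevation is taken anterior-positive (the negative of the stored sag),
#' so a steeper region carries positive elevation.
#'
#' @param surface a [surface_sampling()] object.
#' @param pupil_diameter pupil diameter in mm (default 5).
#' @param max_order maximum radial order (default 6).
#' @param cond_threshold condition-number threshold above which a small
#'   ridge penalty is applied (with a warning).
#' @return object of class `zernike_spectrum`: list with `coefficients`
#'   (named c0..c27, micrometres), `pupil_radius` (mm), `normalization`,
#'   `rms_fit_residual` (micrometres), `n`, `m`.
#' @export
fit_zernike <- function(surface, pupil_diameter = 5, max_order = 6,
                        cond_threshold = 1e8) {
  stopifnot(inherits(surface, "surface_sampling"))
  if (pupil_diameter <= 0) stop("pupil_diameter must be positive")
  pts <- surface$points
  rp <- pupil_diameter / 2
  r <- sqrt(pts$x^2 + pts$y^2)
  keep <- r <= rp + 1e-9
  jmax <- osa_j(max_order, max_order)
  if (sum(keep) < jmax + 1)
    stop("need at least ", jmax + 1, " points inside the pupil")
  rho <- pmin(r[keep] / rp, 1)
  theta <- atan2(pts$y[keep], pts$x[keep])
  elev_um <- -pts$z[keep] * 1000   # anterior-positive elevation, micrometres
  A <- zernike_design(rho, theta, max_order)
  kap <- kappa(A, exact = FALSE)
  if (is.finite(kap) && kap > cond_threshold) {
    warning("ill-conditioned Zernike design matrix (condition ~ ",
            format(kap, digits = 3), "); applying ridge fallback")
    AtA <- crossprod(A) + diag(1e-8, ncol(A))
    coefs <- solve(AtA, crossprod(A, elev_um))[, 1]
  } else {
    coefs <- qr.coef(qr(A), elev_um)
  }
  fitted <- A %*% coefs
  nm <- osa_index(0:jmax)
  structure(list(
    coefficients = stats::setNames(as.numeric(coefs), paste0("c", 0:jmax)),
    pupil_radius = rp,
    normalization = "unit-normalized",
    rms_fit_residual = sqrt(mean((elev_um - fitted)^2)),
    n = nm$n, m = nm$m), class = "zernike_spectrum")
}

#' @export
print.zernike_spectrum <- function(x, ...) {
  cat("Zernike spectrum (OSA indices 0..", length(x$coefficients) - 1,
      "), pupil radius ", x$pupil_radius, " mm\n", sep = "")
  cat("  normalization:", x$normalization,
      " rms residual:", format(x$rms_fit_residual, digits = 4), "um\n")
  top <- sort(abs(x$coefficients), decreasing = TRUE)[1:5]
  cat("  largest |c_j|:", paste(names(top), collapse = ", "), "\n")
  invisible(x)
}

#' Clinical descriptions of OSA Zernike indices 1..14
#'
#' The index-to-aberration-name mapping used in the reporting tables
#' (tilt through quadrafoil terms of radial orders 1..4).
#'
#' @return data.frame with columns `osa_index`, `n`, `m`, `description`.
#' @export
zernike_descriptions <- function() {
  desc <- c("vertical tilt", "horizontal tilt",
            "oblique primary astigmatism", "defocus",
            "vertical/horizontal primary astigmatism",
            "vertical trefoil", "vertical coma", "horizontal coma",
            "oblique trefoil", "oblique quadrafoil",
            "oblique secondary astigmatism", "primary spherical",
            "vertical secondary astigmatism", "vertical quadrafoil")
  nm <- osa_index(1:14)
  data.frame(osa_index = 1:14, n = nm$n, m = nm$m, description = desc,
             stringsAsFactors = FALSE)
}

#' Tabulate Zernike coefficient changes against a baseline scenario
#'
#' Per-index coefficient differences of each scenario against the stated
#' baseline, with clinical descriptions for indices 1..14 and configurable
#' low-order/high-order summary rows (signed sums or RMS; low order =
#' radial orders <= 2, high order = radial orders >= 3).
#'
#' @param spectra named list of `zernike_spectrum` objects.
#' @param baseline name of the baseline scenario in `spectra`.
#' @param summary_kind "signed" (plain sums) or "rms".
#' @return data.frame: one row per OSA index 1..14 plus two summary rows;
#'   one column per non-baseline scenario, plus `osa_index`/`description`.
#' @export
aberration_table <- function(spectra, baseline, summary_kind = c("signed", "rms")) {
  summary_kind <- match.arg(summary_kind)
  stopifnot(is.list(spectra), baseline %in% names(spectra))
  rp <- vapply(spectra, function(s) s$pupil_radius, numeric(1))
  if (any(abs(rp - rp[1]) > 1e-9))
    stop("spectra are not comparable: pupil radii differ")
  norms <- vapply(spectra, function(s) s$normalization, character(1))
  if (length(unique(norms)) != 1)
    stop("spectra are not comparable: normalizations differ")
  base <- spectra[[baseline]]$coefficients
  others <- setdiff(names(spectra), baseline)
  dd <- zernike_descriptions()
  nm <- osa_index(seq_along(base) - 1)
  lo <- nm$n <= 2 & nm$j >= 1
  hi <- nm$n >= 3
  cols <- lapply(others, function(sc) {
    d <- spectra[[sc]]$coefficients - base
    summ <- if (summary_kind == "signed") c(sum(d[lo]), sum(d[hi]))
            else c(sqrt(sum(d[lo]^2)), sqrt(sum(d[hi]^2)))
    c(d[dd$osa_index + 1], summ)
  })
  out <- data.frame(
    osa_index = c(as.character(dd$osa_index), "sum low order", "sum high order"),
    description = c(dd$description, "orders 1-2 summary", "orders 3-6 summary"),
    stringsAsFactors = FALSE)
  for (i in seq_along(others)) out[[others[i]]] <- cols[[i]]
  attr(out, "baseline") <- baseline
  attr(out, "summary_kind") <- summary_kind
  out
}

#' Export a Zernike spectrum to CSV
#'
#' Writes columns (osa_index, n, m, description, coefficient_um); indices
#' outside 1..14 carry an empty description.
#'
#' @param spectrum a `zernike_spectrum`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_zernike_csv <- function(spectrum, path) {
  dd <- zernike_descriptions()
  j <- seq_along(spectrum$coefficients) - 1
  desc <- dd$description[match(j, dd$osa_index)]
  desc[is.na(desc)] <- ""
  df <- data.frame(osa_index = j, n = spectrum$n, m = spectrum$m,
                   description = desc,
                   coefficient_um = unname(spectrum$coefficients))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
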