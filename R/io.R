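## Readers and writers for the package's plain-text formats: surface
## samplings (CSV + key:value metadata sidecar), curvature maps, and the
## fixture manifest.

sidecar_path <- function(path) paste0(path, ".meta")

write_sidecar <- function(path, fields) {
  writeLines(paste0(names(fields), ": ", unlist(fields)), sidecar_path(path))
}

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp))
    stop("missing metadata sidecar: ", sp)
  lines <- readLines(sp)
  kv <- regmatches(lines, regexec("^([^:]+):[[:space:]]*(.*)$", lines))
  bad <- which(vapply(kv, length, integer(1)) != 3)
  if (length(bad))
    stop("malformed sidecar line ", bad[1], " in ", sp, ": '", lines[bad[1]], "'")
  stats::setNames(vapply(kv, `[`, character(1), 3),
                  trimws(vapply(kv, `[`, character(1), 2)))
}

#' Write a surface sampling to CSV
#'
#' One point per row with header `x_mm,y_mm,z_mm` (15 significant
#' digits), plus a `<path>.meta` sidecar holding `zone_diameter`,
#' `surface_side`, `label` and `grid_spacing` as `key: value` lines.
#'
#' @param surface a [surface_sampling()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_surface <- function(surface, path) {
  stopifnot(inherits(surface, "surface_sampling"))
  pts <- surface$points
  lines <- c("x_mm,y_mm,z_mm",
             sprintf("%.15g,%.15g,%.15g", pts$x, pts$y, pts$z))
  writeLines(lines, path)
  write_sidecar(path, list(zone_diameter = surface$zone_diameter,
                           surface_side = surface$surface_side,
                           label = surface$label,
                           grid_spacing = surface$grid_spacing))
  invisible(path)
}

#' Read a surface sampling from CSV
#'
#' Inverse of [write_surface()]; parse failures (bad header, non-numeric
#' or non-finite cells) are reported with the offending line number.
#'
#' @param path CSV path (sidecar expected at `<path>.meta`).
#' @return a [surface_sampling()].
#' @export
read_surface <- function(path) {
  if (!file.exists(path)) stop("no such surface file: ", path)
  lines <- readLines(path)
  if (!identical(trimws(lines[1]), "x_mm,y_mm,z_mm"))
    stop("malformed header at line 1 of ", path, ": '", lines[1], "'")
  body <- lines[-1]
  parts <- strsplit(body, ",", fixed = TRUE)
  nf <- vapply(parts, length, integer(1))
  if (any(nf != 3))
    stop("malformed row at line ", which(nf != 3)[1] + 1, " of ", path)
  vals <- suppressWarnings(
    matrix(as.numeric(unlist(parts)), ncol = 3, byrow = TRUE))
  bad <- which(!stats::complete.cases(vals) | !is.finite(rowSums(vals)))
  if (length(bad))
    stop("non-numeric or non-finite cell at line ", bad[1] + 1, " of ", path)
  meta <- read_sidecar(path)
  surface_sampling(data.frame(x = vals[, 1], y = vals[, 2], z = vals[, 3]),
                   surface_side = meta[["surface_side"]],
                   zone_diameter = as.numeric(meta[["zone_diameter"]]),
                   label = if ("label" %in% names(meta)) meta[["label"]] else "",
                   grid_spacing = suppressWarnings(
                     as.numeric(meta[["grid_spacing"]])))
}

#' Write a curvature map to CSV
#'
#' Matrix layout (rows = x, columns = y) with a metadata sidecar holding
#' the grid axes, origin, zone and diopter convention.
#'
#' @param map a `curvature_map`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_curvature_map <- function(map, path) {
  stopifnot(inherits(map, "curvature_map"))
  utils::write.table(map$K, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  write_sidecar(path, list(
    x_axis = paste(sprintf("%.10g", map$x), collapse = ";"),
    y_axis = paste(sprintf("%.10g", map$y), collapse = ";"),
    origin = paste(sprintf("%.10g", map$origin), collapse = ";"),
    zone_diameter = map$zone_diameter,
    surface_side = map$surface_side,
    mode = map$mode,
    units = "diopter"))
  invisible(path)
}

#' Read a curvature map written by [write_curvature_map()]
#' @param path map CSV path.
#' @return a `curvature_map`.
#' @export
read_curvature_map <- function(path) {
  meta <- read_sidecar(path)
  K <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(K) <- NULL
  structure(list(
    x = as.numeric(strsplit(meta[["x_axis"]], ";")[[1]]),
    y = as.numeric(strsplit(meta[["y_axis"]], ";")[[1]]),
    K = K,
    origin = as.numeric(strsplit(meta[["origin"]], ";")[[1]]),
    zone_diameter = as.numeric(meta[["zone_diameter"]]),
    surface_side = meta[["surface_side"]],
    mode = meta[["mode"]]), class = "curvature_map")
}

#' Generate the full fixture set of synthetic surfaces
#'
#' Writes the deterministic (seeded) set of surfaces covering the whole
#' scenario grid: healthy and keratoconic pre-op corneas plus all six
#' ICRS designs applied to each, anterior and posterior surfaces
#' (2 x (2 + 2 x 6) = 28 files), with a tab-separated manifest listing
#' scenario, side, file and generation parameters. The keratoconic
#' pre-op cornea is the healthy biconic plus the default cone; the ICRS
#' effect is applied geometrically with the given gain (posterior
#' surfaces receive `posterior_gain_fraction` of it).
#'
#' @param output_dir writable directory (created if needed).
#' @param seed integer RNG seed (used for the optional noise).
#' @param zone_diameter,grid_spacing sampling geometry, mm.
#' @param noise_sd_um Gaussian measurement noise, um (default 0).
#' @param gain ICRS flattening gain, um per mm^2.
#' @param posterior_gain_fraction fraction of `gain` applied to the
#'   posterior surface.
#' @param cone a [cone_spec()].
#' @param designs named list of [icrs_design()]s.
#' @return data.frame manifest (also written to `manifest.tsv`),
#'   invisibly.
#' @export
write_fixture_set <- function(output_dir, seed = 1, zone_diameter = 9,
                              grid_spacing = 0.1, noise_sd_um = 0,
                              gain = 400, posterior_gain_fraction = 0.15,
                              cone = cone_spec(),
                              designs = icrs_design_set()) {
  if (!dir.exists(output_dir))
    dir.create(output_dir, recursive = TRUE)
  set.seed(seed)
  base <- list(
    healthy_anterior  = list(Rx = 7.37, Ry = 7.62, Qx = -0.25, Qy = -0.10),
    healthy_posterior = list(Rx = 7.91, Ry = 7.97, Qx = 0.63, Qy = 0.37))
  mk <- function(params, side, label)
    make_biconic_surface(params, zone_diameter, grid_spacing,
                         surface_side = side, label = label,
                         noise_sd_um = noise_sd_um)
  surfaces <- list()
  surfaces[["healthy pre-op::anterior"]] <-
    mk(base$healthy_anterior, "anterior", "healthy pre-op")
  surfaces[["healthy pre-op::posterior"]] <-
    mk(base$healthy_posterior, "posterior", "healthy pre-op")
  surfaces[["KC pre-op::anterior"]] <-
    add_kc_cone(surfaces[["healthy pre-op::anterior"]], cone)
  surfaces[["KC pre-op::posterior"]] <-
    add_kc_cone(surfaces[["healthy pre-op::posterior"]], cone)
  for (cornea in c("healthy", "KC")) for (nm in names(designs)) {
    pre_a <- surfaces[[paste0(cornea, " pre-op::anterior")]]
    pre_p <- surfaces[[paste0(cornea, " pre-op::posterior")]]
    key <- paste0(cornea, " ", nm)
    surfaces[[paste0(key, "::anterior")]] <-
      apply_icrs_effect(pre_a, designs[[nm]], gain = gain)
    surfaces[[paste0(key, "::posterior")]] <-
      apply_icrs_effect(pre_p, designs[[nm]],
                        gain = gain * posterior_gain_fraction,
                        allow_posterior = TRUE)
  }
  rows <- lapply(names(surfaces), function(key) {
    parts <- strsplit(key, "::", fixed = TRUE)[[1]]
    fn <- paste0(gsub("[^A-Za-z0-9]+", "_", key), ".csv")
    write_surface(surfaces[[key]], file.path(output_dir, fn))
    data.frame(scenario = parts[1], surface_side = parts[2], file = fn,
               seed = seed, zone_diameter = zone_diameter,
               grid_spacing = grid_spacing, noise_sd_um = noise_sd_um,
               gain = gain, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(output_dir, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

#' Read a fixture manifest and its surfaces
#'
#' @param dir directory written by [write_fixture_set()].
#' @return list with `manifest` (data.frame) and `surfaces` (named list,
#'   keys `"<scenario>::<side>"`).
#' @export
read_fixture_set <- function(dir) {
  mf <- file.path(dir, "manifest.tsv")
  if (!file.exists(mf)) stop("no manifest.tsv in ", dir)
  manifest <- utils::read.table(mf, sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE)
  surfaces <- stats::setNames(
    lapply(seq_len(nrow(manifest)), function(i)
      read_surface(file.path(dir, manifest$file[i]))),
    paste0(manifest$scenario, "::", manifest$surface_side))
  list(manifest = manifest, surfaces = surfaces)
}
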