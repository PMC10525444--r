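## Pipeline orchestration: one call runs the full scenario comparison
## (generation, biconic fits, curvature/difference maps, Zernike change
## tables, refraction summaries) and writes the report bundle.

#' Pipeline configuration
#'
#' Validated configuration for [run_pipeline()]: the ICRS scenario list,
#' cone specification, IOP, analysis zones, seeds and output directory.
#'
#' @param designs named list of [icrs_design()]s (default: the six study
#'   designs).
#' @param scenarios character vector of design names to run (default:
#'   all in `designs`).
#' @param cone a [cone_spec()].
#' @param iop_mmHg intraocular pressure, mmHg.
#' @param fit_zone biconic fitting zone diameter, mm.
#' @param pupil_diameter Zernike pupil diameter, mm.
#' @param map_zone curvature map zone diameter, mm.
#' @param zone_diameter,grid_spacing surface sampling geometry, mm.
#' @param gain ICRS effect gain, um per mm^2 of cross-section.
#' @param noise_sd_um measurement noise, um.
#' @param seed RNG seed.
#' @param output_dir report output directory (NULL: no files written).
#' @param write_maps also export every curvature/difference map as CSV.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(designs = icrs_design_set(),
                            scenarios = names(designs),
                            cone = cone_spec(), iop_mmHg = 15,
                            fit_zone = 5, pupil_diameter = 5, map_zone = 8,
                            zone_diameter = 9, grid_spacing = 0.1,
                            gain = 400, noise_sd_um = 0, seed = 1,
                            output_dir = NULL, write_maps = FALSE) {
  unknown <- setdiff(scenarios, names(designs))
  if (length(unknown))
    stop("unknown scenario name(s): ", paste(unknown, collapse = ", "))
  if (iop_mmHg < 0) stop("IOP must be >= 0")
  if (map_zone + 2 * grid_spacing > zone_diameter)
    stop("map_zone must leave a margin of at least one grid cell inside ",
         "zone_diameter")
  structure(list(designs = designs, scenarios = scenarios, cone = cone,
                 iop_mmHg = iop_mmHg, fit_zone = fit_zone,
                 pupil_diameter = pupil_diameter, map_zone = map_zone,
                 zone_diameter = zone_diameter, grid_spacing = grid_spacing,
                 gain = gain, noise_sd_um = noise_sd_um, seed = seed,
                 output_dir = output_dir, write_maps = write_maps),
            class = "pipeline_config")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(utils::capture.output(utils::str(config)), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full scenario-comparison pipeline
#'
#' Generates the synthetic pre-operative corneas (healthy biconic;
#' keratoconic = healthy + cone) and the post-operative surfaces for
#' every configured ICRS scenario on both corneas, then computes per
#' scenario: anterior/posterior biconic fits, the axial-length change,
#' sagittal curvature and difference maps, anterior Zernike spectra, the
#' coefficient change table, and the refraction summary (per-surface
#' power changes, myopic shift, effective refractive change). When
#' `output_dir` is set, writes `curvature_summary.csv`,
#' `effective_changes.csv`, `zernike_changes_<cornea>.csv`, optional map
#' CSVs and a timestamped run log carrying the config hash and seed.
#'
#' @param config a [pipeline_config()].
#' @return list with `fits`, `summary_table`, `effective_changes`,
#'   `zernike_changes`, `maps`, `config_hash` (class `pipeline_report`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  hash <- config_hash(config)
  log_lines <- c(sprintf("[%s] pipeline start (seed %d, config %s)",
                         format(Sys.time()), config$seed, hash))
  stage <- function(name, scenario, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed for scenario '", scenario,
           "': ", conditionMessage(e)))
  }
  set.seed(config$seed)
  zd <- config$zone_diameter; gs <- config$grid_spacing
  surf <- list()
  surf[["healthy pre-op"]] <- list(
    anterior = make_biconic_surface(
      list(Rx = 7.37, Ry = 7.62, Qx = -0.25, Qy = -0.10), zd, gs,
      "anterior", "healthy pre-op", config$noise_sd_um),
    posterior = make_biconic_surface(
      list(Rx = 7.91, Ry = 7.97, Qx = 0.63, Qy = 0.37), zd, gs,
      "posterior", "healthy pre-op", config$noise_sd_um))
  surf[["KC pre-op"]] <- list(
    anterior = add_kc_cone(surf[["healthy pre-op"]]$anterior, config$cone),
    posterior = add_kc_cone(surf[["healthy pre-op"]]$posterior, config$cone))
  for (cornea in c("healthy", "KC")) for (nm in config$scenarios) {
    key <- paste(cornea, nm)
    pre <- surf[[paste(cornea, "pre-op")]]
    surf[[key]] <- list(
      anterior = apply_icrs_effect(pre$anterior, config$designs[[nm]],
                                   gain = config$gain),
      posterior = apply_icrs_effect(pre$posterior, config$designs[[nm]],
                                    gain = config$gain * 0.15,
                                    allow_posterior = TRUE))
  }
  log_lines <- c(log_lines, sprintf("  generated %d scenario surface pairs",
                                    length(surf)))

  ## biconic fits + axial-length changes
  fits <- list()
  for (key in names(surf)) {
    cornea <- if (startsWith(key, "KC")) "KC" else "healthy"
    pre <- surf[[paste(cornea, "pre-op")]]
    fits[[key]] <- stage("biconic fit", key, list(
      anterior = fit_biconic(surf[[key]]$anterior, config$fit_zone),
      posterior = fit_biconic(surf[[key]]$posterior, config$fit_zone),
      delta_AL = if (grepl("pre-op", key)) NA_real_
                 else delta_axial_length(surf[[key]]$anterior, pre$anterior)))
  }

  ## summary tables per cornea block
  blocks <- lapply(c("healthy", "KC"), function(cornea) {
    keys <- grep(paste0("^", cornea, " "), names(fits), value = TRUE)
    fb <- fits[keys]
    names(fb) <- sub(paste0("^", cornea, " "), "", names(fb))
    tab <- build_summary_table(fb, pre = "pre-op")
    tab$scenario <- paste(cornea, tab$scenario)
    tab
  })
  summary_table <- do.call(rbind, blocks)

  ## effective refractive changes (KC total power includes the measured
  ## pre-op steepening of the fitted anterior surface)
  kc_steepening <-
    mean_meridional_power(fits[["KC pre-op"]]$anterior, "anterior") -
    mean_meridional_power(fits[["healthy pre-op"]]$anterior, "anterior")
  eff <- do.call(rbind, lapply(names(fits), function(key) {
    if (grepl("pre-op", key)) return(NULL)
    cornea <- if (startsWith(key, "KC")) "KC" else "healthy"
    pre <- fits[[paste(cornea, "pre-op")]]
    D <- if (cornea == "KC") 60 + kc_steepening else 60
    ant <- mean_meridional_power(fits[[key]]$anterior, "anterior") -
      mean_meridional_power(pre$anterior, "anterior")
    post <- mean_meridional_power(fits[[key]]$posterior, "posterior") -
      mean_meridional_power(pre$posterior, "posterior")
    data.frame(scenario = key, anterior_delta_dpt = ant,
               posterior_delta_dpt = post, delta_AL = fits[[key]]$delta_AL,
               total_power = D,
               myopic_shift = myopic_shift(fits[[key]]$delta_AL, D),
               effective_change = effective_change(ant, post,
                                                   fits[[key]]$delta_AL, D),
               stringsAsFactors = FALSE)
  }))

  ## curvature and difference maps
  maps <- list()
  for (key in names(surf)) {
    re_o <- startsWith(key, "KC")
    maps[[key]] <- stage("sagittal map", key,
      sagittal_map(surf[[key]]$anterior, config$map_zone, re_origin = re_o))
  }
  diffs <- list()
  for (key in names(surf)) {
    if (grepl("pre-op", key)) next
    cornea <- if (startsWith(key, "KC")) "KC" else "healthy"
    diffs[[key]] <- stage("difference map", key,
      difference_map(maps[[key]], maps[[paste(cornea, "pre-op")]]))
  }
  diffs[["KC vs healthy"]] <- difference_map(
    sagittal_map(surf[["KC pre-op"]]$anterior, config$map_zone),
    maps[["healthy pre-op"]])

  ## Zernike spectra and change tables
  spectra <- lapply(surf, function(s)
    fit_zernike(s$anterior, config$pupil_diameter))
  zern <- list()
  for (cornea in c("healthy", "KC")) {
    keys <- grep(paste0("^", cornea, " "), names(spectra), value = TRUE)
    zern[[cornea]] <- aberration_table(spectra[keys],
                                       baseline = paste(cornea, "pre-op"))
  }
  zern[["KC pre-op vs healthy"]] <- aberration_table(
    spectra[c("healthy pre-op", "KC pre-op")], baseline = "healthy pre-op")

  report <- structure(list(fits = fits, summary_table = summary_table,
                           effective_changes = eff, zernike_changes = zern,
                           maps = c(maps, diffs), spectra = spectra,
                           config = config, config_hash = hash),
                      class = "pipeline_report")

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    od <- config$output_dir
    utils::write.csv(summary_table, file.path(od, "curvature_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(eff, file.path(od, "effective_changes.csv"),
                     row.names = FALSE)
    for (cornea in names(zern))
      utils::write.csv(zern[[cornea]],
                       file.path(od, paste0("zernike_changes_",
                                            gsub("[^A-Za-z0-9]+", "_", cornea),
                                            ".csv")), row.names = FALSE)
    if (config$write_maps)
      for (key in names(report$maps))
        write_curvature_map(report$maps[[key]],
                            file.path(od, paste0("map_",
                                                 gsub("[^A-Za-z0-9]+", "_", key),
                                                 ".csv")))
    log_lines <- c(log_lines,
                   sprintf("[%s] wrote report bundle to %s",
                           format(Sys.time()), od))
    writeLines(log_lines, file.path(od, "run_log.txt"))
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline report (config", x$config_hash, ")\n")
  cat("  scenarios:", paste(x$config$scenarios, collapse = ", "), "\n")
  cat("  effective refractive changes [dpt]:\n")
  print(x$effective_changes[, c("scenario", "anterior_delta_dpt",
                                "posterior_delta_dpt", "delta_AL",
                                "effective_change")], digits = 3)
  invisible(x)
}
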