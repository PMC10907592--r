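.default_config <- function() {
  list(
    geometry = list(R1_mm = 7.76, k1 = -0.10, R2_mm = 6.52, k2 = -0.30,
                    central_thickness_mm = 0.55, diameter_mm = 12,
                    bulk_index = 1.3777),
    indices = list(central = c(1.3764, 1.3776, 1.3775),
                   peripheral = c(1.3770, 1.3776, 1.3765),
                   mu = 0.45, sigma = 0.1, normalization_radius_mm = 6),
    # distance_mm NULL = the mode's own default (650 external, 3.5 iris plane)
    source = list(mode = "external", distance_mm = NULL),
    wavelength_nm = 660,
    grid = list(n = 301L, extent_mm = 6),
    frame_rotation_deg = 0,
    double_pass = FALSE,
    regime = "blended",
    output_dir = ".",
    seed = 1L
  )
}

# recursive override merge: values in y replace values in x
.merge_config <- function(x, y) {
  for (nm in names(y)) {
    x[[nm]] <- if (is.list(x[[nm]]) && is.list(y[[nm]]))
      .merge_config(x[[nm]], y[[nm]]) else y[[nm]]
  }
  x
}

.validate_config <- function(config) {
  if (isTRUE(attr(config, "validated"))) return(config)
  cfg <- .merge_config(.default_config(), config)
  g <- cfg$geometry
  if (g$R1_mm <= 0 || g$R2_mm <= 0)
    stop("radii of curvature must be positive", call. = FALSE)
  if (g$central_thickness_mm <= 0)
    stop("central thickness must be positive", call. = FALSE)
  if (g$diameter_mm <= 0) stop("diameter must be positive", call. = FALSE)
  if (cfg$indices$sigma <= 0) stop("sigma must be positive", call. = FALSE)
  if (length(cfg$indices$central) != 3L || length(cfg$indices$peripheral) != 3L)
    stop("index columns must have three components", call. = FALSE)
  if (!cfg$source$mode %in% c("external", "iris_plane"))
    stop("source mode must be 'external' or 'iris_plane'", call. = FALSE)
  if (!is.null(cfg$source$distance_mm) &&
      (!is.finite(cfg$source$distance_mm) || cfg$source$distance_mm <= 0))
    stop("source distance must be positive", call. = FALSE)
  if (!cfg$regime %in% c("blended", "central", "peripheral"))
    stop("regime must be blended, central or peripheral", call. = FALSE)
  cfg$grid$n <- as.integer(cfg$grid$n)
  if (is.na(cfg$grid$n) || cfg$grid$n < 3L)
    stop("grid n must be an integer >= 3", call. = FALSE)
  if (cfg$grid$n %% 2L == 0L)
    stop("grid n must be odd so the apex is sampled", call. = FALSE)
  if (cfg$grid$extent_mm <= 0) stop("grid extent must be positive",
                                    call. = FALSE)
  if (cfg$wavelength_nm <= 0) stop("wavelength must be positive",
                                   call. = FALSE)
  if (!is.logical(cfg$double_pass)) stop("double_pass must be logical",
                                         call. = FALSE)
  attr(cfg, "validated") <- TRUE
  cfg
}

# build the model objects a configuration describes
.config_parts <- function(config) {
  g <- config$geometry
  list(
    shell = corneal_shell(g$R1_mm, g$k1, g$R2_mm, g$k2,
                          g$central_thickness_mm, g$diameter_mm, g$bulk_index),
    profile = index_profile(
      central = principal_indices(config$indices$central[1L],
                                  config$indices$central[2L],
                                  config$indices$central[3L]),
      peripheral = principal_indices(config$indices$peripheral[1L],
                                     config$indices$peripheral[2L],
                                     config$indices$peripheral[3L]),
      mu = config$indices$mu, sigma = config$indices$sigma,
      normalization_radius = config$indices$normalization_radius_mm),
    source = light_source(config$source$mode, config$source$distance_mm))
}

#' Run configuration for the corneal birefringence model
#'
#' Assembles (and validates) the full configuration of a simulation run. The
#' defaults are the published corneal model: Goncharov-eye geometry
#' (R1 = 7.76 mm / k1 = -0.10, R2 = 6.52 mm / k2 = -0.30, 0.55 mm central
#' thickness, 12 mm diameter, bulk index 1.3777), the central/peripheral
#' index columns blended with mu = 0.45, sigma = 0.1 over 6 mm, an external
#' on-axis point source at 650 mm, and a 660 nm wavelength.
#'
#' @param ... Named overrides, e.g. `source = list(mode = "iris_plane")`,
#'   `grid = list(n = 41L)`, `regime = "central"`. Nested lists are merged
#'   recursively into the defaults.
#' @param file Optional path to a JSON run-configuration file; overrides in
#'   `...` are applied on top of it.
#' @return Validated configuration list (class `run_config`).
#' @export
run_config <- function(..., file = NULL) {
  cfg <- .default_config()
  if (!is.null(file)) {
    if (!file.exists(file)) stop("config file not found: ", file,
                                 call. = FALSE)
    cfg <- .merge_config(cfg, jsonlite::read_json(file, simplifyVector = TRUE))
  }
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == ""))
      stop("overrides must be named", call. = FALSE)
    cfg <- .merge_config(cfg, dots)
  }
  cfg <- .validate_config(cfg)
  class(cfg) <- c("run_config", class(cfg))
  cfg
}

#' @export
print.run_config <- function(x, ...) {
  cat("run configuration\n")
  d <- if (is.null(x$source$distance_mm)) {
    if (x$source$mode == "external") 650 else 3.5
  } else x$source$distance_mm
  cat(sprintf("  source: %s at %g mm; lambda = %g nm; regime = %s\n",
              x$source$mode, d, x$wavelength_nm, x$regime))
  cat(sprintf("  grid: %d x %d over +/- %g mm\n", x$grid$n, x$grid$n,
              x$grid$extent_mm))
  invisible(x)
}

#' Write a gridded map to a commented-header CSV
#'
#' Full-precision plain CSV: '#'-prefixed header lines record the grid
#' extent, step, size and the mask convention (NaN = outside aperture),
#' followed by one row per grid row. write/read round-trips exactly.
#'
#' @param path Output file path.
#' @param grid Numeric matrix (NA cells written as NaN).
#' @param coords Coordinate vector of the grid axes, mm.
#' @return `path`, invisibly.
#' @export
write_map <- function(path, grid, coords) {
  stopifnot(is.matrix(grid), nrow(grid) == length(coords))
  header <- c(
    "# corneal map grid",
    sprintf("# extent_mm: %.17g %.17g", min(coords), max(coords)),
    sprintf("# step_mm: %.17g", if (length(coords) > 1L)
      coords[2L] - coords[1L] else 0),
    sprintf("# n: %d", length(coords)),
    "# mask: NaN = outside aperture")
  vals <- apply(grid, 1L, function(row)
    paste(sprintf("%.17g", row), collapse = ","))
  writeLines(c(header, vals), path)
  invisible(path)
}

#' Read a gridded map written by [write_map()]
#'
#' @param path File path.
#' @return List with `values` (matrix, NaN cells as NA), `coords` (mm).
#' @export
read_map <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("parse error: empty file", call. = FALSE)
  hdr <- grepl("^#", lines)
  head_lines <- lines[hdr]
  n_line <- grep("^# n:", head_lines, value = TRUE)
  ext_line <- grep("^# extent_mm:", head_lines, value = TRUE)
  if (!length(n_line) || !length(ext_line))
    stop("parse error: missing header (line 1)", call. = FALSE)
  n <- as.integer(sub("^# n:\\s*", "", n_line[1L]))
  ext <- as.numeric(strsplit(sub("^# extent_mm:\\s*", "", ext_line[1L]),
                             "\\s+")[[1L]])
  body <- which(!hdr)
  if (length(body) != n)
    stop(sprintf("parse error: expected %d data rows, found %d (line %d)",
                 n, length(body), body[1L]), call. = FALSE)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ln <- body[i]
    v <- suppressWarnings(as.numeric(strsplit(lines[ln], ",",
                                              fixed = TRUE)[[1L]]))
    if (length(v) != n)
      stop(sprintf("parse error: ragged row at line %d (%d values, expected %d)",
                   ln, length(v), n), call. = FALSE)
    rows[[i]] <- v
  }
  values <- do.call(rbind, rows)
  list(values = values, coords = seq(ext[1L], ext[2L], length.out = n))
}

#' Run the full simulation and write the artifact bundle
#'
#' Computes the map set, meridional cross-sections and summary metrics for a
#' configuration and writes them to disk: `retardation.csv`,
#' `birefringence.csv`, `phase.csv`, `azimuth.csv` (commented-header CSV
#' matrices), `profile_horizontal.csv` / `profile_vertical.csv`,
#' `isochromes.png` (8-bit grayscale circular-polariscope image) and
#' `summary.json`.
#'
#' @param config A [run_config()] configuration.
#' @param out_dir Output directory (created if needed); defaults to the
#'   configuration's `output_dir`.
#' @param quiet Suppress progress messages.
#' @return The summary list, invisibly.
#' @export
run_simulation <- function(config = run_config(), out_dir = NULL,
                           quiet = FALSE) {
  config <- .validate_config(config)
  if (is.null(out_dir)) out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- proc.time()[["elapsed"]]
  say("tracing %d x %d grid (%s source, %s regime)...",
      config$grid$n, config$grid$n, config$source$mode, config$regime)
  maps <- compute_maps(config)
  for (nm in c("retardation", "birefringence", "phase", "azimuth")) {
    write_map(file.path(out_dir, paste0(nm, ".csv")), maps[[nm]], maps$y)
  }
  say("computing meridional cross-sections...")
  profs <- list()
  for (m in c("horizontal", "vertical")) {
    pr <- cross_section(config, m, step = 0.02)
    utils::write.csv(pr, file.path(out_dir, paste0("profile_", m, ".csv")),
                     row.names = FALSE)
    profs[[m]] <- pr
  }
  intensity <- polariscope_intensity(maps$phase)
  img <- intensity
  img[is.na(img)] <- 0
  png::writePNG(t(img)[rev(seq_len(ncol(img))), , drop = FALSE],
                file.path(out_dir, "isochromes.png"))
  ret_metrics <- profile_metrics(profs$horizontal)
  bir_metrics <- profile_metrics(profs$horizontal,
                                 profs$horizontal$birefringence)
  parts <- .config_parts(config)
  beta_c <- binormal_axes(principal_indices(config$indices$central[1L],
                                            config$indices$central[2L],
                                            config$indices$central[3L]))
  beta_p <- binormal_axes(principal_indices(config$indices$peripheral[1L],
                                            config$indices$peripheral[2L],
                                            config$indices$peripheral[3L]))
  summary <- list(
    beta_central_deg = beta_c$beta_deg,
    beta_peripheral_deg = beta_p$beta_deg,
    minima_separation_mm = ret_metrics$minima_separation,
    minima_positions_mm = ret_metrics$minima_positions,
    birefringence_max_position_mm = abs(bir_metrics$max_position),
    retardation_max_nm = max(maps$retardation, na.rm = TRUE),
    metrics_status = ret_metrics$status)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  say("done in %.1f s; artifacts in %s", proc.time()[["elapsed"]] - t0,
      normalizePath(out_dir))
  invisible(summary)
}
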