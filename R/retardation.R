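#' Point light source for the polariscope model
#'
#' Two source models are supported: an `external` point source on the optical
#' axis in front of the cornea (default 650 mm, effectively a plane wave),
#' and an `iris_plane` secondary source representing light scattered from the
#' iris, placed on axis 3.5 mm deep to the anterior corneal vertex.
#'
#' @param mode `"external"` or `"iris_plane"`.
#' @param distance_mm Axial distance of the source: in front of the anterior
#'   vertex for `external` (default 650), behind it for `iris_plane`
#'   (default 3.5).
#' @return Class `light_source`: list with `mode` and `position` (3-vector,
#'   mm, anterior vertex at the origin).
#' @export
light_source <- function(mode = c("external", "iris_plane"),
                         distance_mm = NULL) {
  mode <- match.arg(mode)
  if (is.null(distance_mm))
    distance_mm <- if (mode == "external") 650 else 3.5
  if (!is.finite(distance_mm) || distance_mm <= 0)
    stop("source distance must be positive", call. = FALSE)
  pos <- if (mode == "external") c(-distance_mm, 0, 0) else c(distance_mm, 0, 0)
  structure(list(mode = mode, position = pos), class = "light_source")
}

#' Vector form of Snell's law
#'
#' Refracts a unit direction at an interface with unit normal. The normal may
#' point to either side; it is oriented internally along the propagation.
#'
#' @param direction Incident unit 3-vector.
#' @param normal Unit 3-vector of the interface normal.
#' @param n_in,n_out Refractive indices on the incident and transmitted side.
#' @return Transmitted unit 3-vector, lying in the plane of incidence.
#'   Raises an error of class `cornea_tir` on total internal reflection.
#' @export
refract_direction <- function(direction, normal, n_in, n_out) {
  d <- as.numeric(direction); nn <- as.numeric(normal)
  d <- d / sqrt(sum(d^2)); nn <- nn / sqrt(sum(nn^2))
  ci <- sum(d * nn)
  if (abs(ci) < 1e-12)
    stop("grazing incidence: |direction . normal| must be positive",
         call. = FALSE)
  if (ci < 0) { nn <- -nn; ci <- -ci }
  eta <- n_in / n_out
  s2 <- eta^2 * (1 - ci^2)
  if (s2 > 1)
    stop(structure(class = c("cornea_tir", "error", "condition"),
                   list(message = "total internal reflection",
                        call = sys.call(-1))))
  ct <- sqrt(1 - s2)
  t <- eta * d + (ct - eta * ci) * nn
  t / sqrt(sum(t^2))
}

# vectorized refraction; D, N are n x 3 with N oriented along propagation
.refract_many <- function(D, N, eta) {
  ci <- rowSums(D * N)
  s2 <- eta^2 * (1 - ci^2)
  ct <- sqrt(pmax(1 - s2, 0))
  t <- eta * D + (ct - eta * ci) * N
  t / sqrt(rowSums(t^2))
}

#' Trace one ray through the corneal shell
#'
#' External mode: the ray runs from the source to a target point on the
#' anterior surface, refracts into the bulk (air -> bulk index), and
#' propagates in a straight line to the posterior surface; the small
#' cornea-to-aqueous refraction at exit is neglected. Iris-plane mode: the
#' ray runs from the secondary source to a target on the posterior surface,
#' enters without refraction (cornea and aqueous indices nearly match), and
#' traverses to the anterior surface. A single traversal is modeled in both
#' cases.
#'
#' @param source A [light_source].
#' @param target Point on the entry surface: either a 3-vector (mm) on that
#'   surface or a length-2 `(y, z)` pair which is lifted onto it.
#' @param shell A [corneal_shell].
#' @return Class `ray_path`: list with entry point `A`, exit point `B`
#'   (3-vectors, mm), `dir_outside`, `dir_inside` (unit vectors), geometric
#'   path length `d` (mm), and `entry`/`exit` surface labels.
#' @export
trace_ray <- function(source, target, shell) {
  aperture <- shell$diameter / 2
  entry <- if (source$mode == "external") shell$anterior else shell$posterior
  exit_s <- if (source$mode == "external") shell$posterior else shell$anterior
  target <- as.numeric(target)
  if (length(target) == 2L) {
    h <- sqrt(sum(target^2))
    if (h > aperture)
      stop(structure(class = c("cornea_miss", "error", "condition"),
                     list(message = "target outside the aperture",
                          call = sys.call(-1))))
    target <- c(entry$vertex_x + surface_sag(h, entry), target)
  }
  if (length(target) != 3L || !all(is.finite(target)))
    stop("target must be a (y,z) pair or 3-vector", call. = FALSE)
  if (sqrt(sum(target[2:3]^2)) > aperture)
    stop(structure(class = c("cornea_miss", "error", "condition"),
                   list(message = "target outside the aperture",
                        call = sys.call(-1))))
  A <- target
  dir_out <- A - source$position
  dir_out <- dir_out / sqrt(sum(dir_out^2))
  dir_in <- if (source$mode == "external") {
    refract_direction(dir_out, surface_normal(A, entry), 1, shell$bulk_index)
  } else {
    dir_out
  }
  B <- intersect_ray(A, dir_in, exit_s, aperture)
  structure(list(A = A, B = B, dir_outside = dir_out, dir_inside = dir_in,
                 d = sqrt(sum((B - A)^2)),
                 entry = if (source$mode == "external") "anterior"
                         else "posterior",
                 exit = if (source$mode == "external") "posterior"
                        else "anterior"),
            class = "ray_path")
}

#' @export
print.ray_path <- function(x, ...) {
  cat(sprintf("ray path (%s -> %s): d = %.4f mm\n", x$entry, x$exit, x$d))
  cat(sprintf("  A = (%.4f, %.4f, %.4f)  B = (%.4f, %.4f, %.4f)\n",
              x$A[1L], x$A[2L], x$A[3L], x$B[1L], x$B[2L], x$B[3L]))
  invisible(x)
}

#' Components of a propagation vector in a local frame
#'
#' @param P_vec Numeric 3-vector (any nonzero length) in global coordinates.
#' @param frame A [local_frame].
#' @return A [propagation_direction]: `(P . e_i)/|P|` for i = x, y, z.
#' @export
direction_components <- function(P_vec, frame) {
  P_vec <- as.numeric(P_vec)
  nrm <- sqrt(sum(P_vec^2))
  if (!is.finite(nrm) || nrm == 0)
    stop("P_vec must be a nonzero finite vector", call. = FALSE)
  propagation_direction(c(sum(P_vec * frame$e_x), sum(P_vec * frame$e_y),
                          sum(P_vec * frame$e_z)) / nrm)
}

## Core vectorized evaluation of rays addressed by registration-plane
## coordinates (y, z) of the entry-surface target. Returns per-ray vectors;
## NA where the ray misses or leaves the aperture.
.evaluate_rays <- function(y, z, shell, profile, source,
                           lambda_nm = 660, frame_rotation_deg = 0,
                           double_pass = FALSE,
                           regime = c("blended", "central", "peripheral")) {
  regime <- match.arg(regime)
  aperture <- shell$diameter / 2
  k <- max(length(y), length(z))
  y <- rep_len(y, k); z <- rep_len(z, k)
  h <- sqrt(y^2 + z^2)
  ok <- h <= aperture
  out <- list(dn_A = rep(NA_real_, k), dn_B = rep(NA_real_, k),
              dn = rep(NA_real_, k), R = rep(NA_real_, k),
              delta = rep(NA_real_, k), azimuth = rep(NA_real_, k),
              d = rep(NA_real_, k), hit = rep(FALSE, k))
  if (!any(ok)) return(out)
  yi <- y[ok]; zi <- z[ok]; hi <- h[ok]
  entry <- if (source$mode == "external") shell$anterior else shell$posterior
  exit_s <- if (source$mode == "external") shell$posterior else shell$anterior
  A <- cbind(entry$vertex_x + surface_sag(hi, entry), yi, zi)
  Dir <- A - matrix(source$position, nrow(A), 3L, byrow = TRUE)
  Dir <- Dir / sqrt(rowSums(Dir^2))
  if (source$mode == "external") {
    N <- .normal_many(A, entry)             # +X: along propagation
    DirI <- .refract_many(Dir, N, 1 / shell$bulk_index)
  } else {
    DirI <- Dir                             # enters without refraction
  }
  t <- .intersect_many(A, DirI, exit_s, aperture)
  hit <- !is.na(t)
  A <- A[hit, , drop = FALSE]; DirI <- DirI[hit, , drop = FALSE]
  t <- t[hit]
  if (!any(hit)) return(out)
  B <- A + t * DirI
  hA <- sqrt(A[, 2L]^2 + A[, 3L]^2)
  hB <- sqrt(B[, 2L]^2 + B[, 3L]^2)

  frame_A <- .frame_many(A, entry, frame_rotation_deg)
  frame_B <- .frame_many(B, exit_s, frame_rotation_deg)
  s_of <- function(fr) cbind(rowSums(DirI * fr$e_x), rowSums(DirI * fr$e_y),
                             rowSums(DirI * fr$e_z))
  sA <- s_of(frame_A); sB <- s_of(frame_B)
  n_of <- function(hh) switch(regime,
    blended = .indices_at_many(hh, profile),
    central = list(nx = rep_len(profile$central[1L], length(hh)),
                   ny = rep_len(profile$central[2L], length(hh)),
                   nz = rep_len(profile$central[3L], length(hh))),
    peripheral = list(nx = rep_len(profile$peripheral[1L], length(hh)),
                      ny = rep_len(profile$peripheral[2L], length(hh)),
                      nz = rep_len(profile$peripheral[3L], length(hh))))
  nA <- n_of(hA); nB <- n_of(hB)
  wA <- .wave_pair(sA[, 1L], sA[, 2L], sA[, 3L], nA$nx, nA$ny, nA$nz)
  wB <- .wave_pair(sB[, 1L], sB[, 2L], sB[, 3L], nB$nx, nB$ny, nB$nz)
  dn_A <- wA$n_slow - wA$n_fast
  dn_B <- wB$n_slow - wB$n_fast
  dn <- (dn_A + dn_B) / 2
  d <- t
  R <- dn * d * 1e6 * (if (double_pass) 2 else 1)   # mm -> nm
  delta <- 360 * R / lambda_nm

  # azimuth of the slow transverse eigen-axis at the entry surface,
  # projected on the Y-Z registration plane, degrees in [0, 180)
  Dax <- .slow_axis_local(sA[, 1L], sA[, 2L], sA[, 3L], nA$nx, nA$ny, nA$nz)
  g_y <- Dax[, 1L] * frame_A$e_x[, 2L] + Dax[, 2L] * frame_A$e_y[, 2L] +
    Dax[, 3L] * frame_A$e_z[, 2L]
  g_z <- Dax[, 1L] * frame_A$e_x[, 3L] + Dax[, 2L] * frame_A$e_y[, 3L] +
    Dax[, 3L] * frame_A$e_z[, 3L]
  azi <- (atan2(g_z, g_y) * 180 / pi) %% 180

  idx <- which(ok)[hit]
  out$dn_A[idx] <- dn_A; out$dn_B[idx] <- dn_B; out$dn[idx] <- dn
  out$R[idx] <- R; out$delta[idx] <- delta; out$azimuth[idx] <- azi
  out$d[idx] <- d; out$hit[idx] <- TRUE
  out
}

#' Retardation sample for a traced ray
#'
#' Evaluates the birefringence at the entry and exit surfaces (same inside
#' propagation direction, expressed in each surface's local frame, indices
#' taken at each point's radial height), averages them, and converts to
#' retardation and phase difference.
#'
#' @param path A [ray_path].
#' @param profile An [index_profile].
#' @param shell A [corneal_shell].
#' @param lambda_nm Wavelength, nm (default 660).
#' @param frame_rotation_deg Tangent-frame rotation, degrees (default 0).
#' @param double_pass If TRUE, report twice the single-traversal retardation.
#' @param regime `"blended"` (default), `"central"` or `"peripheral"`:
#'   which index regime to evaluate.
#' @return Class `retardation_sample`: list with local directions `s_A`,
#'   `s_B`, birefringences `dn_A`, `dn_B`, `dn_mean`, path `d` (mm),
#'   retardation `R` (nm), phase `delta` (degrees) and `azimuth` (degrees in
#'   [0, 180), 0 = horizontal).
#' @export
ray_retardation <- function(path, profile, shell, lambda_nm = 660,
                            frame_rotation_deg = 0, double_pass = FALSE,
                            regime = "blended") {
  entry <- if (path$entry == "anterior") shell$anterior else shell$posterior
  exit_s <- if (path$exit == "anterior") shell$anterior else shell$posterior
  fA <- local_frame(path$A, entry, frame_rotation_deg)
  fB <- local_frame(path$B, exit_s, frame_rotation_deg)
  s_A <- direction_components(path$dir_inside, fA)
  s_B <- direction_components(path$dir_inside, fB)
  n_at <- function(h) switch(regime,
    blended = indices_at(h, profile),
    central = principal_indices(profile$central[1L], profile$central[2L],
                                profile$central[3L]),
    peripheral = principal_indices(profile$peripheral[1L],
                                   profile$peripheral[2L],
                                   profile$peripheral[3L]),
    stop("unknown regime", call. = FALSE))
  iA <- n_at(sqrt(sum(path$A[2:3]^2)))
  iB <- n_at(sqrt(sum(path$B[2:3]^2)))
  dn_A <- birefringence(s_A, iA)
  dn_B <- birefringence(s_B, iB)
  dn_mean <- (dn_A + dn_B) / 2
  R <- dn_mean * path$d * 1e6 * (if (double_pass) 2 else 1)
  delta <- 360 * R / lambda_nm
  ax <- .slow_axis_local(s_A[1L], s_A[2L], s_A[3L], iA[1L], iA[2L], iA[3L])
  g <- ax[1L, 1L] * fA$e_x + ax[1L, 2L] * fA$e_y + ax[1L, 3L] * fA$e_z
  azimuth <- if (any(is.na(g))) NA_real_ else
    (atan2(g[3L], g[2L]) * 180 / pi) %% 180
  structure(list(s_A = s_A, s_B = s_B, dn_A = dn_A, dn_B = dn_B,
                 dn_mean = dn_mean, d = path$d, R = R, delta = delta,
                 azimuth = azimuth),
            class = "retardation_sample")
}

#' @export
print.retardation_sample <- function(x, ...) {
  cat(sprintf("retardation sample: R = %.3f nm, delta = %.3f deg, d = %.4f mm\n",
              x$R, x$delta, x$d))
  cat(sprintf("  dn_A = %.4g, dn_B = %.4g, mean = %.4g, azimuth = %.2f deg\n",
              x$dn_A, x$dn_B, x$dn_mean, x$azimuth))
  invisible(x)
}

#' Retardation, birefringence, phase and azimuth maps
#'
#' Traces one ray per grid cell of a regular Y-Z grid over the corneal disc
#' and evaluates the per-ray retardation quantities. Cells outside the
#' aperture (or whose ray leaves it) are masked with NA.
#'
#' @param config A run configuration from [run_config()].
#' @return Class `cornea_maps`: list with coordinate vectors `y`, `z` (mm),
#'   matrices `retardation` (nm), `birefringence`, `phase` (deg), `azimuth`
#'   (deg), `path` (mm), logical `mask` (TRUE = valid cell), and the
#'   generating `config` as an attribute.
#' @export
compute_maps <- function(config = run_config()) {
  config <- .validate_config(config)
  n <- config$grid$n
  e <- config$grid$extent_mm
  y <- seq(-e, e, length.out = n)
  g <- expand.grid(y = y, z = y)
  parts <- .config_parts(config)
  ev <- .evaluate_rays(g$y, g$z, parts$shell, parts$profile, parts$source,
                       lambda_nm = config$wavelength_nm,
                       frame_rotation_deg = config$frame_rotation_deg,
                       double_pass = config$double_pass,
                       regime = config$regime)
  shape <- function(v) matrix(v, n, n)
  structure(list(y = y, z = y,
                 retardation = shape(ev$R),
                 birefringence = shape(ev$dn),
                 phase = shape(ev$delta),
                 azimuth = shape(ev$azimuth),
                 path = shape(ev$d),
                 mask = shape(ev$hit)),
            class = "cornea_maps", config = config)
}

#' @export
print.cornea_maps <- function(x, ...) {
  cat(sprintf("cornea maps: %d x %d over [%.1f, %.1f] mm (%d valid cells)\n",
              length(x$y), length(x$z), min(x$y), max(x$y), sum(x$mask)))
  cat(sprintf("  retardation range [%.2f, %.2f] nm\n",
              min(x$retardation, na.rm = TRUE),
              max(x$retardation, na.rm = TRUE)))
  invisible(x)
}

#' Meridional cross-section of the model
#'
#' Evaluates dedicated rays along the horizontal (z = 0) or vertical (y = 0)
#' meridian at a fine step, independent of any map grid, for metric-precision
#' profiles.
#'
#' @param config A run configuration from [run_config()].
#' @param meridian `"horizontal"` or `"vertical"`.
#' @param step Sampling step along the meridian, mm (default 0.02).
#' @return data.frame with columns `position_mm` (signed), `retardation_nm`,
#'   `birefringence`, `phase_deg`, `azimuth_deg`, `path_mm`.
#' @export
cross_section <- function(config = run_config(),
                          meridian = c("horizontal", "vertical"),
                          step = 0.02) {
  config <- .validate_config(config)
  meridian <- match.arg(meridian)
  if (!is.finite(step) || step <= 0) stop("step must be positive",
                                          call. = FALSE)
  e <- config$grid$extent_mm
  pos <- seq(-e, e, by = step)
  if (pos[length(pos)] < e) pos <- c(pos, e)
  parts <- .config_parts(config)
  y <- if (meridian == "horizontal") pos else rep(0, length(pos))
  z <- if (meridian == "horizontal") rep(0, length(pos)) else pos
  ev <- .evaluate_rays(y, z, parts$shell, parts$profile, parts$source,
                       lambda_nm = config$wavelength_nm,
                       frame_rotation_deg = config$frame_rotation_deg,
                       double_pass = config$double_pass,
                       regime = config$regime)
  data.frame(position_mm = pos, retardation_nm = ev$R, birefringence = ev$dn,
             phase_deg = ev$delta, azimuth_deg = ev$azimuth, path_mm = ev$d)
}

# three-point parabolic refinement of an extremum at index i
.parabolic_refine <- function(x, v, i) {
  denom <- v[i - 1L] - 2 * v[i] + v[i + 1L]
  if (!is.finite(denom) || abs(denom) < .Machine$double.eps) return(x[i])
  x[i] + 0.5 * (x[i + 1L] - x[i - 1L]) / 2 * (v[i - 1L] - v[i + 1L]) / denom
}

#' Extract minima/maximum metrics from a meridional profile
#'
#' Locates interior local minima and the global maximum of a sampled 1-D
#' profile by discrete three-point comparison with parabolic sub-sample
#' refinement. The pair of interior minima most symmetric about the apex
#' gives the minima separation.
#'
#' @param profile A data.frame with a `position_mm` column (as returned by
#'   [cross_section()]) or a numeric position vector.
#' @param value Values at the positions; by default the `retardation_nm`
#'   column of `profile`. Pass e.g. `profile$birefringence` for the
#'   birefringence metrics.
#' @return List with `minima_positions` (mm, refined), `minima_separation`
#'   (mm, NA when fewer than two interior minima exist), `max_position`
#'   (signed mm), `max_value`, and `status` (`"ok"` or
#'   `"minima-not-found"`).
#' @export
profile_metrics <- function(profile, value = NULL) {
  if (is.data.frame(profile)) {
    x <- profile$position_mm
    v <- if (is.null(value)) profile$retardation_nm else value
  } else {
    x <- as.numeric(profile)
    v <- value
  }
  if (is.null(v) || length(v) != length(x))
    stop("positions and values must have equal length", call. = FALSE)
  keep <- is.finite(x) & is.finite(v)
  x <- x[keep]; v <- v[keep]
  k <- length(v)
  if (k < 5L) stop("profile too short for metric extraction", call. = FALSE)
  interior <- 2:(k - 1L)
  is_min <- v[interior] <= v[interior - 1L] & v[interior] <= v[interior + 1L] &
    (v[interior] < v[interior - 1L] | v[interior] < v[interior + 1L])
  mins <- interior[is_min]
  # collapse runs of adjacent flagged samples to one representative
  if (length(mins) > 1L) mins <- mins[c(TRUE, diff(mins) > 1L)]
  min_pos <- vapply(mins, function(i) .parabolic_refine(x, v, i), numeric(1L))
  imax <- interior[which.max(v[interior])]
  if (v[1L] >= v[imax] || v[k] >= v[imax]) {
    max_pos <- x[if (v[1L] >= v[k]) 1L else k]
    max_val <- max(v[1L], v[k])
  } else {
    max_pos <- .parabolic_refine(x, v, imax)
    max_val <- v[imax]
  }
  neg <- min_pos[min_pos < 0]; posv <- min_pos[min_pos > 0]
  if (length(neg) && length(posv)) {
    pairs <- expand.grid(a = neg, b = posv)
    best <- pairs[which.min(abs(pairs$a + pairs$b)), ]
    sep <- best$b - best$a
    status <- "ok"
  } else {
    sep <- NA_real_
    status <- "minima-not-found"
  }
  list(minima_positions = min_pos, minima_separation = sep,
       max_position = max_pos, max_value = max_val, status = status)
}
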