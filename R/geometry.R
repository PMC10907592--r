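#' Aspheric (conicoid) surface of revolution
#'
#' A rotationally symmetric conicoid about the X axis, described by the apical
#' radius of curvature R and conic constant k. Its sag (axial depth) at radial
#' height h is \eqn{x = h^2 / (R (1 + \sqrt{1 - (1+k) h^2/R^2}))}; k = 0 is a
#' sphere, -1 < k < 0 a prolate ellipsoid.
#'
#' @param R Apical radius of curvature, mm (> 0).
#' @param k Conic constant, dimensionless.
#' @param vertex_x Axial position of the vertex, mm.
#' @return Class `aspheric_surface`.
#' @export
aspheric_surface <- function(R, k, vertex_x = 0) {
  if (!is.finite(R) || R <= 0) stop("R must be positive", call. = FALSE)
  if (!is.finite(k) || !is.finite(vertex_x))
    stop("k and vertex_x must be finite", call. = FALSE)
  structure(list(R = R, k = k, vertex_x = vertex_x),
            class = "aspheric_surface")
}

#' Sag of an aspheric surface
#'
#' @param h Radial height(s), mm (>= 0).
#' @param surface An [aspheric_surface].
#' @return Axial depth x - vertex_x, mm (vectorized over `h`).
#' @export
surface_sag <- function(h, surface) {
  if (any(!is.finite(h)) || any(h < 0))
    stop("h must be finite and non-negative", call. = FALSE)
  u <- (1 + surface$k) * h^2 / surface$R^2
  if (any(u >= 1))
    stop("h beyond the surface's domain of definition", call. = FALSE)
  h^2 / (surface$R * (1 + sqrt(1 - u)))
}

# implicit conicoid form F(x,y,z) = y^2 + z^2 - 2 R dx + (1+k) dx^2, dx = x - vx
.implicit_value <- function(p, surface) {
  dx <- p[, 1L] - surface$vertex_x
  p[, 2L]^2 + p[, 3L]^2 - 2 * surface$R * dx + (1 + surface$k) * dx^2
}

# inward-oriented (positive X at the apex) unit normals; p is an n x 3 matrix
.normal_many <- function(p, surface) {
  dx <- p[, 1L] - surface$vertex_x
  g <- cbind(surface$R - (1 + surface$k) * dx, -p[, 2L], -p[, 3L])
  g / sqrt(rowSums(g^2))
}

#' Unit surface normal at a point of an aspheric surface
#'
#' The normal is the normalized gradient of the conicoid implicit form,
#' oriented to have a positive X component (pointing from the surface into
#' the eye at the apex).
#'
#' @param point Numeric 3-vector (mm) lying on the surface (within 1e-9 mm).
#' @param surface An [aspheric_surface].
#' @return Unit 3-vector.
#' @export
surface_normal <- function(point, surface) {
  point <- as.numeric(point)
  if (length(point) != 3L || !all(is.finite(point)))
    stop("point must be a finite 3-vector", call. = FALSE)
  p <- matrix(point, 1L, 3L)
  f <- .implicit_value(p, surface)
  # |F| / |grad F| approximates the distance to the surface
  dx <- point[1L] - surface$vertex_x
  gn <- 2 * sqrt((surface$R - (1 + surface$k) * dx)^2 + point[2L]^2 +
                   point[3L]^2)
  if (abs(f) / gn > 1e-9)
    stop("point does not lie on the surface", call. = FALSE)
  drop(.normal_many(p, surface))
}

## Forward ray-conicoid intersection, vectorized. O, D are n x 3 matrices
## (origins, unit directions). Returns the smallest ray parameter t > 1e-9
## whose point lies within the aperture radius, NA where the ray misses.
.intersect_many <- function(O, D, surface, aperture) {
  ox <- O[, 1L] - surface$vertex_x
  A <- D[, 2L]^2 + D[, 3L]^2 + (1 + surface$k) * D[, 1L]^2
  B <- 2 * (O[, 2L] * D[, 2L] + O[, 3L] * D[, 3L]) - 2 * surface$R * D[, 1L] +
    2 * (1 + surface$k) * ox * D[, 1L]
  C <- O[, 2L]^2 + O[, 3L]^2 - 2 * surface$R * ox + (1 + surface$k) * ox^2
  t <- rep(NA_real_, nrow(O))
  lin <- abs(A) < 1e-14
  disc <- B^2 - 4 * A * C
  ok <- !lin & disc >= 0
  sq <- sqrt(pmax(disc, 0))
  # numerically stable quadratic roots (no cancellation for distant origins)
  qq <- -(B + sign(B) * sq) / 2
  t1 <- qq / A
  t2 <- ifelse(abs(qq) > 0, C / qq, NA_real_)
  inside <- function(tt) {
    px <- O[, 2L] + tt * D[, 2L]
    pz <- O[, 3L] + tt * D[, 3L]
    ok & is.finite(tt) & tt > 1e-9 & sqrt(px^2 + pz^2) <= aperture
  }
  use2 <- inside(t2)
  t[use2] <- t2[use2]
  use1 <- inside(t1) & (is.na(t) | t1 < t)
  t[use1] <- t1[use1]
  tl <- -C / B
  if (any(lin)) {
    px <- O[, 2L] + tl * D[, 2L]
    pz <- O[, 3L] + tl * D[, 3L]
    sel <- lin & is.finite(tl) & tl > 1e-9 & sqrt(px^2 + pz^2) <= aperture
    t[sel] <- tl[sel]
  }
  t
}

#' Intersect a ray with an aspheric surface
#'
#' Substitutes the parametric ray into the conicoid implicit form, solves the
#' resulting quadratic in the ray parameter, and returns the nearest forward
#' intersection within the aperture.
#'
#' @param origin Numeric 3-vector, mm.
#' @param direction Unit 3-vector.
#' @param surface An [aspheric_surface].
#' @param aperture Aperture radius, mm; intersections at larger radial height
#'   are rejected. Default 6 (the 12 mm corneal disc).
#' @return The intersection point (3-vector, mm). Raises an error of class
#'   `cornea_miss` when no forward intersection lies within the aperture.
#' @export
intersect_ray <- function(origin, direction, surface, aperture = 6) {
  origin <- as.numeric(origin); direction <- as.numeric(direction)
  if (length(origin) != 3L || length(direction) != 3L ||
      !all(is.finite(c(origin, direction))))
    stop("origin and direction must be finite 3-vectors", call. = FALSE)
  direction <- direction / sqrt(sum(direction^2))
  t <- .intersect_many(matrix(origin, 1L, 3L), matrix(direction, 1L, 3L),
                       surface, aperture)
  if (is.na(t))
    stop(structure(class = c("cornea_miss", "error", "condition"),
                   list(message = "ray misses the surface within the aperture",
                        call = sys.call(-1))))
  origin + t * direction
}

#' Corneal shell: two aspheric surfaces plus bulk constants
#'
#' @param R1,k1 Anterior apical radius (mm) and conic constant.
#' @param R2,k2 Posterior apical radius (mm) and conic constant.
#' @param central_thickness Axial distance between the vertices, mm.
#' @param diameter Corneal diameter, mm (aperture = diameter/2).
#' @param bulk_index Mean bulk refractive index used for refraction.
#' @return Class `corneal_shell` with elements `anterior`, `posterior`
#'   ([aspheric_surface]s, anterior vertex at x = 0), `central_thickness`,
#'   `diameter`, `bulk_index`.
#' @export
corneal_shell <- function(R1 = 7.76, k1 = -0.10, R2 = 6.52, k2 = -0.30,
                          central_thickness = 0.55, diameter = 12,
                          bulk_index = 1.3777) {
  if (central_thickness <= 0) stop("central thickness must be positive",
                                   call. = FALSE)
  if (diameter <= 0) stop("diameter must be positive", call. = FALSE)
  if (bulk_index <= 1) stop("bulk index must exceed 1", call. = FALSE)
  shell <- structure(
    list(anterior = aspheric_surface(R1, k1, vertex_x = 0),
         posterior = aspheric_surface(R2, k2, vertex_x = central_thickness),
         central_thickness = central_thickness, diameter = diameter,
         bulk_index = bulk_index),
    class = "corneal_shell")
  h <- seq(0, diameter / 2, length.out = 61L)
  th <- axial_thickness(h, shell)
  if (any(th <= 0))
    stop("shell thickness must stay positive over the aperture", call. = FALSE)
  shell
}

#' Axial thickness of the shell at radial height h
#'
#' @param h Radial height(s), mm.
#' @param shell A [corneal_shell].
#' @return Thickness along X, mm (vectorized).
#' @export
axial_thickness <- function(h, shell) {
  shell$central_thickness + surface_sag(h, shell$posterior) -
    surface_sag(h, shell$anterior)
}

#' @export
print.corneal_shell <- function(x, ...) {
  cat(sprintf(paste0("corneal shell: R1 = %.3f mm (k1 = %.2f), ",
                     "R2 = %.3f mm (k2 = %.2f)\n"),
              x$anterior$R, x$anterior$k, x$posterior$R, x$posterior$k))
  cat(sprintf("  central thickness %.3f mm, diameter %.1f mm, n = %.4f\n",
              x$central_thickness, x$diameter, x$bulk_index))
  invisible(x)
}

## Local frames at surface points, vectorized. P is n x 3; returns a list of
## three n x 3 matrices (e_x = inward normal, e_y ~ global Y projected onto
## the tangent plane, e_z = e_x x e_y), optionally rotated about e_x.
.frame_many <- function(P, surface, frame_rotation_deg = 0) {
  ex <- .normal_many(P, surface)
  # project global Y onto the tangent plane
  ey <- cbind(-ex[, 2L] * ex[, 1L], 1 - ex[, 2L]^2, -ex[, 2L] * ex[, 3L])
  nrm <- sqrt(rowSums(ey^2))
  if (any(nrm < 1e-12))
    stop("degenerate frame: normal parallel to global Y", call. = FALSE)
  ey <- ey / nrm
  ez <- cbind(ex[, 2L] * ey[, 3L] - ex[, 3L] * ey[, 2L],
              ex[, 3L] * ey[, 1L] - ex[, 1L] * ey[, 3L],
              ex[, 1L] * ey[, 2L] - ex[, 2L] * ey[, 1L])
  if (frame_rotation_deg != 0) {
    a <- frame_rotation_deg * pi / 180
    ey2 <- cos(a) * ey + sin(a) * ez
    ez <- -sin(a) * ey + cos(a) * ez
    ey <- ey2
  }
  list(e_x = ex, e_y = ey, e_z = ez)
}

#' Local principal frame at a surface point
#'
#' The orthonormal triad carried by the birefringent medium: `e_x` is the
#' inward surface normal, `e_y` the normalized projection of the global Y
#' (horizontal) axis onto the tangent plane, and `e_z = e_x x e_y`, so that
#' the triad coincides with the global frame at the apex. The transverse
#' axes may additionally be rotated about the normal to represent a tilted
#' in-plane eigen-axis orientation.
#'
#' @param point Numeric 3-vector on the surface, mm.
#' @param surface An [aspheric_surface].
#' @param frame_rotation_deg Rotation of the tangent axes about the normal,
#'   degrees. Default 0 (horizontal-vertical transverse axes).
#' @return Class `local_frame`: list of unit 3-vectors `e_x`, `e_y`, `e_z`.
#' @export
local_frame <- function(point, surface, frame_rotation_deg = 0) {
  # validates the point via surface_normal's on-surface check
  surface_normal(point, surface)
  f <- .frame_many(matrix(as.numeric(point), 1L, 3L), surface,
                   frame_rotation_deg)
  structure(list(e_x = drop(f$e_x), e_y = drop(f$e_y), e_z = drop(f$e_z)),
            class = "local_frame")
}
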