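#' Principal refractive indices of a linear birefringent medium
#'
#' Bundles the three principal refractive indices (n_x, n_y, n_z) attached to
#' the local principal frame of a homogeneous linear birefringent medium.
#' The medium is biaxial when all three differ, uniaxial when exactly two are
#' equal, and isotropic when all three coincide.
#'
#' @param n_x,n_y,n_z Dimensionless refractive indices along the local x, y
#'   and z principal axes. Must be finite and in (1, 2) for physically
#'   meaningful tissue/crystal input.
#' @return An object of class `principal_indices`: a named numeric vector
#'   with elements `n_x`, `n_y`, `n_z`.
#' @examples
#' principal_indices(1.3764, 1.3776, 1.3775)  # central cornea
#' @export
principal_indices <- function(n_x, n_y, n_z) {
  n <- c(n_x = n_x, n_y = n_y, n_z = n_z)
  if (length(n) != 3L || !all(is.finite(n)))
    stop("principal indices must be three finite numbers", call. = FALSE)
  if (any(n <= 1) || any(n >= 2))
    stop("principal indices must lie strictly between 1 and 2", call. = FALSE)
  structure(n, class = "principal_indices")
}

.as_indices <- function(x) {
  if (inherits(x, "principal_indices")) return(unclass(x))
  x <- as.numeric(x)
  if (length(x) != 3L || !all(is.finite(x)) || any(x <= 0))
    stop("invalid principal indices", call. = FALSE)
  names(x) <- c("n_x", "n_y", "n_z")
  x
}

#' @export
print.principal_indices <- function(x, ...) {
  cat(sprintf("principal indices: n_x = %.6g, n_y = %.6g, n_z = %.6g\n",
              x[[1L]], x[[2L]], x[[3L]]))
  invisible(x)
}

#' Unit propagation direction in the principal frame
#'
#' @param s A numeric 3-vector; it is normalized to unit length.
#' @return Class `propagation_direction`: named unit 3-vector (s_x, s_y, s_z).
#' @export
propagation_direction <- function(s) {
  s <- as.numeric(s)
  if (length(s) != 3L || !all(is.finite(s)))
    stop("direction must be a finite 3-vector", call. = FALSE)
  nrm <- sqrt(sum(s^2))
  if (nrm == 0) stop("direction must be non-zero", call. = FALSE)
  structure(c(s_x = s[1L], s_y = s[2L], s_z = s[3L]) / nrm,
            class = "propagation_direction")
}

.as_direction <- function(s) {
  if (inherits(s, "propagation_direction")) return(unclass(s))
  s <- as.numeric(s)
  if (length(s) != 3L || !all(is.finite(s)))
    stop("direction must be a finite 3-vector", call. = FALSE)
  nrm <- sqrt(sum(s^2))
  if (abs(nrm - 1) > 1e-6)
    stop("direction must be unit length", call. = FALSE)
  s / nrm
}

#' Diagonal permittivity tensor of the medium
#'
#' The (relative, optical-frequency) permittivity tensor is diagonal in the
#' principal frame with entries equal to the squared principal indices.
#'
#' @param indices A [principal_indices] object (or numeric 3-vector).
#' @return Named numeric vector `(eps_x, eps_y, eps_z)` = the diagonal of the
#'   permittivity tensor; off-diagonal elements are zero by construction.
#' @export
permittivity <- function(indices) {
  n <- .as_indices(indices)
  c(eps_x = n[[1L]]^2, eps_y = n[[2L]]^2, eps_z = n[[3L]]^2)
}

## Vectorized wave-normal solver.
##
## The two wave refractive indices for propagation direction (sx,sy,sz) solve
## the biquadratic n^4 - p n^2 + q = 0 with
##   p = [sx^2 ex(ey+ez) + sy^2 ey(ex+ez) + sz^2 ez(ex+ey)] / (sx^2 ex + ...)
##   q = ex ey ez / (sx^2 ex + ...)
## The naive discriminant p^2 - 4q cancels catastrophically near the optic
## axes, so the root *splitting* is evaluated through the exact identity
##   1/n_fast^2 - 1/n_slow^2 = (1/e_min - 1/e_max) sin(th1) sin(th2),
## th1, th2 being the angles between s and the two optic axes, together with
##   1/n_fast^2 + 1/n_slow^2 = sum_i (1 - s_i^2)/e_i .
## Both expressions are cancellation-free; the discriminant is nonnegative by
## construction. All arguments are recycled vectors; directions are assumed
## unit length.
.wave_pair <- function(sx, sy, sz, nx, ny, nz) {
  k <- max(length(sx), length(sy), length(sz),
           length(nx), length(ny), length(nz))
  ex <- rep_len(nx^2, k); ey <- rep_len(ny^2, k); ez <- rep_len(nz^2, k)
  sx <- rep_len(sx, k); sy <- rep_len(sy, k); sz <- rep_len(sz, k)
  den <- sx^2 * ex + sy^2 * ey + sz^2 * ez
  p <- (sx^2 * ex * (ey + ez) + sy^2 * ey * (ex + ez) +
          sz^2 * ez * (ex + ey)) / den
  q <- ex * ey * ez / den

  E <- cbind(ex, ey, ez)
  S <- cbind(sx, sy, sz)
  o_min <- max.col(-E, ties.method = "first")
  o_max <- max.col(E, ties.method = "last")
  o_mid <- 6L - o_min - o_max
  i <- seq_len(k)
  a <- E[cbind(i, o_min)]; b <- E[cbind(i, o_mid)]; c_ <- E[cbind(i, o_max)]
  su <- S[cbind(i, o_min)]; sv <- S[cbind(i, o_mid)]; sw <- S[cbind(i, o_max)]

  # optic-axis angle from the max-index axis, within the min-max plane
  spread <- 1 / a - 1 / c_
  cos2V <- ifelse(spread > 0, (1 / b - 1 / c_) / spread, 1)
  cos2V <- pmin(pmax(cos2V, 0), 1)
  cV <- sqrt(cos2V); sV <- sqrt(1 - cos2V)
  sin2_th1 <- sv^2 + (sw * sV - su * cV)^2
  sin2_th2 <- sv^2 + (sw * sV + su * cV)^2
  dv <- spread * sqrt(sin2_th1 * sin2_th2)
  tr <- (1 - su^2) / a + (1 - sv^2) / b + (1 - sw^2) / c_
  n_slow <- 1 / sqrt((tr - dv) / 2)
  n_fast <- 1 / sqrt((tr + dv) / 2)
  list(n_slow = n_slow, n_fast = n_fast, p = rep_len(p, k), q = rep_len(q, k))
}

#' Refractive indices of the two waves along a propagation direction
#'
#' Solves the anisotropic wave-normal (biquadratic) equation
#' \eqn{n^4 - p n^2 + q = 0} for the two plane waves that can propagate along
#' a given direction in the medium. The coefficients p and q are formed from
#' the permittivity diagonal and the direction components; the root splitting
#' is evaluated through an exact factored form that stays accurate near the
#' optic axes, where the naive discriminant \eqn{p^2 - 4q} underflows to
#' rounding noise.
#'
#' @param direction Unit propagation direction (a [propagation_direction] or
#'   numeric unit 3-vector) expressed in the principal frame.
#' @param indices A [principal_indices] object.
#' @return Class `wave_solution`: list with `n_slow`, `n_fast`
#'   (`n_slow >= n_fast`), and the biquadratic coefficients `p`, `q`.
#' @examples
#' wave_indices(c(1, 0, 0), principal_indices(1.5, 1.55, 1.6))
#' @export
wave_indices <- function(direction, indices) {
  s <- .as_direction(direction)
  n <- .as_indices(indices)
  w <- .wave_pair(s[1L], s[2L], s[3L], n[1L], n[2L], n[3L])
  structure(list(n_slow = w$n_slow, n_fast = w$n_fast, p = w$p, q = w$q),
            class = "wave_solution")
}

#' @export
print.wave_solution <- function(x, ...) {
  cat(sprintf("wave solution: n_slow = %.10g, n_fast = %.10g (dn = %.4g)\n",
              x$n_slow, x$n_fast, x$n_slow - x$n_fast))
  invisible(x)
}

#' Birefringence along a propagation direction
#'
#' @inheritParams wave_indices
#' @return The birefringence `n_slow - n_fast` (dimensionless, >= 0).
#' @export
birefringence <- function(direction, indices) {
  w <- wave_indices(direction, indices)
  w$n_slow - w$n_fast
}

# angle (deg) from the max-index axis to each optic axis, closed form
.optic_axis_angle <- function(n_sorted) {
  a <- n_sorted[1L]^2; b <- n_sorted[2L]^2; c_ <- n_sorted[3L]^2
  cos2V <- (1 / b - 1 / c_) / (1 / a - 1 / c_)
  acos(sqrt(pmin(pmax(cos2V, 0), 1))) * 180 / pi
}

#' Binormal (optic) axes of a birefringent medium
#'
#' Locates the two propagation directions along which the birefringence
#' vanishes. For a biaxial medium the axes lie in the plane spanned by the
#' principal axes of the smallest and largest index; they are found by a
#' coarse 1-degree scan of that plane followed by golden-section refinement
#' of the birefringence minimum. A uniaxial medium has a single optic axis
#' along its distinct principal axis; an isotropic medium has none and is
#' rejected.
#'
#' @param indices A [principal_indices] object.
#' @param uniaxial_tol Two principal indices equal within this tolerance are
#'   treated as equal (uniaxial/isotropic branch). Default 1e-12.
#' @return Class `binormal_result`: list with unit vectors `axis_1`, `axis_2`
#'   (principal-frame components, sign-normalized into the hemisphere of the
#'   bisectrix), `beta_deg` (acute angle between the axes), `bisectrix`
#'   (label of the principal axis bisecting the acute angle) and `plane`
#'   (labels of the two principal axes spanning the optic-axis plane).
#' @examples
#' binormal_axes(principal_indices(1.3764, 1.3776, 1.3775))
#' @export
binormal_axes <- function(indices, uniaxial_tol = 1e-12) {
  n <- .as_indices(indices)
  lab <- c("x", "y", "z")
  o <- order(n)
  ns <- n[o]
  if (ns[3L] - ns[1L] <= uniaxial_tol)
    stop("isotropic medium: binormal axes are undefined", call. = FALSE)
  if (ns[2L] - ns[1L] <= uniaxial_tol || ns[3L] - ns[2L] <= uniaxial_tol) {
    # uniaxial: optic axis along the distinct principal axis
    distinct <- if (ns[2L] - ns[1L] <= uniaxial_tol) o[3L] else o[1L]
    ax <- numeric(3L); ax[distinct] <- 1
    return(structure(list(axis_1 = ax, axis_2 = ax, beta_deg = 0,
                          bisectrix = lab[distinct], plane = lab[distinct]),
                     class = "binormal_result"))
  }
  e_min <- numeric(3L); e_min[o[1L]] <- 1
  e_max <- numeric(3L); e_max[o[3L]] <- 1
  dn_of <- function(theta_deg) {   # theta measured from the max-index axis
    th <- theta_deg * pi / 180
    d <- cos(th) * e_max + sin(th) * e_min
    w <- .wave_pair(d[1L], d[2L], d[3L], n[1L], n[2L], n[3L])
    w$n_slow - w$n_fast
  }
  theta <- seq(0, 179, by = 1)
  dn <- vapply(theta, dn_of, numeric(1L))
  k <- length(dn)
  is_min <- c(FALSE, dn[2:(k - 1)] <= dn[1:(k - 2)] &
                     dn[2:(k - 1)] <= dn[3:k], FALSE)
  cand <- theta[is_min]
  refine <- function(t0) {
    stats::optimize(dn_of, interval = c(t0 - 1.5, t0 + 1.5),
                    tol = 1e-10)$minimum
  }
  V <- sort(vapply(cand[1:2], refine, numeric(1L)))
  ax1 <- cos(V[1L] * pi / 180) * e_max + sin(V[1L] * pi / 180) * e_min
  ax2 <- cos(V[2L] * pi / 180) * e_max + sin(V[2L] * pi / 180) * e_min
  # minima sit at V and 180 - V (measured from the max axis); their opening
  # straddles the min axis, so an opening <= 90 is bisected by the min axis
  opening <- V[2L] - V[1L]
  if (opening <= 90) {
    bis <- lab[o[1L]]
  } else {
    bis <- lab[o[3L]]      # max-index axis bisects; flip ax2 into that side
    ax2 <- -ax2
  }
  cosb <- abs(sum(ax1 * ax2))
  beta <- acos(min(1, cosb)) * 180 / pi
  structure(list(axis_1 = ax1, axis_2 = ax2, beta_deg = beta,
                 bisectrix = bis, plane = lab[sort(c(o[1L], o[3L]))]),
            class = "binormal_result")
}

#' @export
print.binormal_result <- function(x, ...) {
  cat(sprintf("binormal axes: beta = %.4f deg, bisectrix = %s, plane = %s\n",
              x$beta_deg, x$bisectrix, paste(x$plane, collapse = "-")))
  cat(sprintf("  axis 1: (%+.6f, %+.6f, %+.6f)\n", x$axis_1[1L], x$axis_1[2L],
              x$axis_1[3L]))
  cat(sprintf("  axis 2: (%+.6f, %+.6f, %+.6f)\n", x$axis_2[1L], x$axis_2[2L],
              x$axis_2[3L]))
  invisible(x)
}

#' Birefringence map over the unit sphere
#'
#' Evaluates the birefringence for radial propagation directions on a
#' hemisphere of the unit sphere and projects it onto one of the coordinate
#' planes, reproducing the classic conoscopic-style maps in which the optic
#' axes appear as zeros of the field.
#'
#' @param indices A [principal_indices] object.
#' @param grid_n Number of grid points per axis (>= 32).
#' @param plane One of `"XY"`, `"YZ"`, `"XZ"`: the projection plane; the
#'   hemisphere with positive third coordinate is shown.
#' @return Class `sphere_map`: list with plane coordinates `u`, `v`, the
#'   birefringence matrix `dn` (NA outside the unit disc) and `plane`.
#' @export
sphere_map <- function(indices, grid_n = 201L, plane = c("XY", "YZ", "XZ")) {
  n <- .as_indices(indices)
  plane <- toupper(plane[1L])
  if (!plane %in% c("XY", "YZ", "XZ"))
    stop("unknown plane label: must be one of XY, YZ, XZ", call. = FALSE)
  grid_n <- as.integer(grid_n)
  if (is.na(grid_n) || grid_n < 32L)
    stop("grid_n must be at least 32", call. = FALSE)
  u <- seq(-1, 1, length.out = grid_n)
  g <- expand.grid(u = u, v = u)
  r2 <- g$u^2 + g$v^2
  inside <- r2 <= 1
  w <- sqrt(pmax(1 - r2, 0))
  d <- switch(plane,
    XY = cbind(g$u, g$v, w),
    YZ = cbind(w, g$u, g$v),
    XZ = cbind(g$u, w, g$v))
  dn <- rep(NA_real_, nrow(g))
  if (any(inside)) {
    wp <- .wave_pair(d[inside, 1L], d[inside, 2L], d[inside, 3L],
                     n[1L], n[2L], n[3L])
    dn[inside] <- wp$n_slow - wp$n_fast
  }
  structure(list(u = u, v = u, dn = matrix(dn, grid_n, grid_n), plane = plane),
            class = "sphere_map")
}

#' @export
print.sphere_map <- function(x, ...) {
  cat(sprintf("sphere map (%s plane): %d x %d, dn range [%.3g, %.3g]\n",
              x$plane, length(x$u), length(x$v),
              min(x$dn, na.rm = TRUE), max(x$dn, na.rm = TRUE)))
  invisible(x)
}

#' Count the isolated zeros of a sphere map
#'
#' Interior local minima of the birefringence field whose value is below
#' `threshold` are counted as optic-axis zeros.
#'
#' @param map A [sphere_map].
#' @param threshold Birefringence below which a local minimum counts as a
#'   zero. Default 1e-3 (the field's scale is the index spread, ~0.1).
#' @return Integer count of zeros visible on the mapped hemisphere.
#' @export
sphere_map_zeros <- function(map, threshold = 1e-3) {
  m <- map$dn
  nr <- nrow(m); nc <- ncol(m)
  cnt <- 0L
  for (i in 2:(nr - 1)) for (j in 2:(nc - 1)) {
    v <- m[i, j]
    if (is.na(v) || v >= threshold) next
    nb <- c(m[i - 1, j], m[i + 1, j], m[i, j - 1], m[i, j + 1],
            m[i - 1, j - 1], m[i - 1, j + 1], m[i + 1, j - 1], m[i + 1, j + 1])
    if (all(is.na(nb) | v <= nb) && any(!is.na(nb))) cnt <- cnt + 1L
  }
  cnt
}

## Slow-axis transverse eigenvector, vectorized.
## The two eigen-polarizations (D fields) diagonalize the inverse permittivity
## restricted to the plane transverse to s. Returns the local-frame components
## of the slow wave's D direction (rows), NA rows where the splitting is
## below tol (azimuth indeterminate). Directions must not be parallel to the
## local y axis (never the case for corneal rays, which run near local x).
.slow_axis_local <- function(sx, sy, sz, nx, ny, nz, tol = 1e-14) {
  iex <- 1 / nx^2; iey <- 1 / ny^2; iez <- 1 / nz^2
  h <- sqrt(sx^2 + sz^2)
  t1x <- -sz / h; t1y <- 0 * h; t1z <- sx / h         # s x yhat, normalized
  t2x <- sy * t1z - sz * t1y
  t2y <- sz * t1x - sx * t1z
  t2z <- sx * t1y - sy * t1x
  m11 <- t1x^2 * iex + t1y^2 * iey + t1z^2 * iez
  m22 <- t2x^2 * iex + t2y^2 * iey + t2z^2 * iez
  m12 <- t1x * t2x * iex + t1y * t2y * iey + t1z * t2z * iez
  half_diff <- sqrt(((m11 - m22) / 2)^2 + m12^2)
  lam_slow <- (m11 + m22) / 2 - half_diff       # smaller eigenvalue = 1/n_slow^2
  # eigenvector (c1, c2) of the 2x2: pick the better-conditioned expression
  c1 <- m12
  c2 <- lam_slow - m11
  alt <- abs(lam_slow - m22) > abs(c2)
  c1 <- ifelse(alt, lam_slow - m22, c1)
  c2 <- ifelse(alt, m12, c2)
  nrm <- sqrt(c1^2 + c2^2)
  bad <- half_diff < tol | nrm < tol
  c1 <- c1 / nrm; c2 <- c2 / nrm
  dx <- c1 * t1x + c2 * t2x
  dy <- c1 * t1y + c2 * t2y
  dz <- c1 * t1z + c2 * t2z
  dx[bad] <- NA_real_; dy[bad] <- NA_real_; dz[bad] <- NA_real_
  cbind(dx, dy, dz)
}
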