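#' Radially blended principal-index profile
#'
#' The corneal principal indices change smoothly from a central to a
#' peripheral regime. The transition is modeled with the complementary
#' standard-normal CDF of the normalized radius: the central weight is
#' \eqn{P(r) = 1 - \Phi((r/r_0 - \mu)/\sigma)}, so P runs from ~1 at the apex
#' to ~0 at the limbus, centered at \eqn{\mu r_0}.
#'
#' @param central,peripheral [principal_indices] for the two regimes.
#'   Defaults: central (1.3764, 1.3776, 1.3775), peripheral
#'   (1.3770, 1.3776, 1.3765).
#' @param mu Transition center as a fraction of `normalization_radius`
#'   (default 0.45).
#' @param sigma Transition width, same normalized units (default 0.1, > 0).
#' @param normalization_radius Radius mapped to 1, mm (default 6, half the
#'   12 mm corneal diameter).
#' @return Class `index_profile`.
#' @export
index_profile <- function(central = principal_indices(1.3764, 1.3776, 1.3775),
                          peripheral = principal_indices(1.3770, 1.3776, 1.3765),
                          mu = 0.45, sigma = 0.1, normalization_radius = 6) {
  if (!is.finite(sigma) || sigma <= 0)
    stop("sigma must be positive", call. = FALSE)
  if (!is.finite(mu)) stop("mu must be finite", call. = FALSE)
  if (!is.finite(normalization_radius) || normalization_radius <= 0)
    stop("normalization_radius must be positive", call. = FALSE)
  structure(list(central = .as_indices(central),
                 peripheral = .as_indices(peripheral),
                 mu = mu, sigma = sigma,
                 normalization_radius = normalization_radius),
            class = "index_profile")
}

#' @export
print.index_profile <- function(x, ...) {
  cat("index profile (central -> peripheral blend)\n")
  cat(sprintf("  central:    (%.4f, %.4f, %.4f)\n", x$central[1L],
              x$central[2L], x$central[3L]))
  cat(sprintf("  peripheral: (%.4f, %.4f, %.4f)\n", x$peripheral[1L],
              x$peripheral[2L], x$peripheral[3L]))
  cat(sprintf("  mu = %.2f, sigma = %.2f of %.1f mm\n", x$mu, x$sigma,
              x$normalization_radius))
  invisible(x)
}

#' Central-regime blend weight at radius r
#'
#' @param r Radial height(s), mm (>= 0).
#' @param profile An [index_profile].
#' @return P in [0, 1], strictly decreasing in r (vectorized).
#' @export
blend_weight <- function(r, profile) {
  if (any(!is.finite(r)) || any(r < 0))
    stop("r must be finite and non-negative", call. = FALSE)
  stats::pnorm((r / profile$normalization_radius - profile$mu) / profile$sigma,
               lower.tail = FALSE)
}

# vectorized component-wise blend; radii beyond the normalization radius
# clamp to the peripheral column (the blend is a convex combination)
.indices_at_many <- function(r, profile) {
  r <- pmin(r, profile$normalization_radius)
  P <- blend_weight(r, profile)
  list(nx = P * profile$central[1L] + (1 - P) * profile$peripheral[1L],
       ny = P * profile$central[2L] + (1 - P) * profile$peripheral[2L],
       nz = P * profile$central[3L] + (1 - P) * profile$peripheral[3L])
}

#' Blended principal indices at radius r
#'
#' Component-wise convex combination of the central and peripheral columns
#' with weight [blend_weight]. Radii beyond the normalization radius clamp
#' to the peripheral regime.
#'
#' @param r Radial height, mm (scalar, >= 0).
#' @param profile An [index_profile].
#' @return A [principal_indices] object.
#' @export
indices_at <- function(r, profile) {
  if (length(r) != 1L) stop("r must be a scalar; see .indices_at_many",
                            call. = FALSE)
  v <- .indices_at_many(r, profile)
  principal_indices(v$nx, v$ny, v$nz)
}

#' Tabulate the radial index profile
#'
#' @param profile An [index_profile].
#' @param r_step Radial step, mm.
#' @return data.frame with columns `r_mm`, `P`, `n_x`, `n_y`, `n_z`.
#' @export
profile_table <- function(profile, r_step = 0.05) {
  r <- seq(0, profile$normalization_radius, by = r_step)
  v <- .indices_at_many(r, profile)
  data.frame(r_mm = r, P = blend_weight(r, profile),
             n_x = v$nx, n_y = v$ny, n_z = v$nz)
}
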