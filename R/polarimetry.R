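#' Crossed circular polariscope intensity
#'
#' Transmission of a linear retarder between matched circular polarizer and
#' crossed circular analyzer: I = sin^2(delta/2), independent of the retarder
#' azimuth. Level sets of the intensity are the isochromes, rendered
#' monochromatically at the working wavelength.
#'
#' @param phase_deg Phase-difference values in degrees (vector or matrix);
#'   NA cells (outside the aperture) propagate.
#' @return Intensities in [0, 1], same shape as the input.
#' @export
polariscope_intensity <- function(phase_deg) {
  sin(phase_deg * pi / 360)^2
}

#' Mueller matrix of a linear retarder
#'
#' @param theta_deg Azimuth of the fast axis, degrees.
#' @param delta_deg Retardance (phase difference), degrees.
#' @return 4x4 Mueller matrix (Stokes order S0, S1, S2, S3).
#' @export
retarder_mueller <- function(theta_deg, delta_deg) {
  c2 <- cos(2 * theta_deg * pi / 180); s2 <- sin(2 * theta_deg * pi / 180)
  cd <- cos(delta_deg * pi / 180); sd <- sin(delta_deg * pi / 180)
  matrix(c(
    1, 0, 0, 0,
    0, c2^2 + s2^2 * cd, c2 * s2 * (1 - cd), -s2 * sd,
    0, c2 * s2 * (1 - cd), s2^2 + c2^2 * cd, c2 * sd,
    0, s2 * sd, -c2 * sd, cd), 4L, 4L, byrow = TRUE)
}

# Poincare-sphere unit vectors of the six probing states:
# linear 0, 45, 90, 135 degrees; right and left circular
.six_states <- function() {
  rbind(c(1, 0, 0), c(0, 1, 0), c(-1, 0, 0), c(0, -1, 0),
        c(0, 0, 1), c(0, 0, -1))
}

#' Six-state intensities of a linear retarder
#'
#' Matched generator/analyzer single-pass intensities for the six probing
#' polarization states (four linear, two circular): each state is produced,
#' passed through the retarder, and analyzed with the same state.
#'
#' @inheritParams retarder_mueller
#' @return Numeric vector of six intensities in [0, 1], named
#'   `lin0`, `lin45`, `lin90`, `lin135`, `rcp`, `lcp`.
#' @export
six_state_intensities <- function(theta_deg, delta_deg) {
  M <- retarder_mueller(theta_deg, delta_deg)
  S <- .six_states()
  I <- vapply(seq_len(6L), function(k) {
    s_in <- c(1, S[k, ])
    s_out <- drop(M %*% s_in)
    0.5 * (s_out[1L] + sum(S[k, ] * s_out[2:4]))
  }, numeric(1L))
  names(I) <- c("lin0", "lin45", "lin90", "lin135", "rcp", "lcp")
  I
}

#' Wrapped retarder state recovered from the six-state measurement
#'
#' Simulates the six matched generator/analyzer intensities and inverts them
#' to an equivalent retarder state in the wrapped ranges accessible to the
#' measurement. The six intensities determine only cos(4 theta) and
#' cos(delta), so the returned pair is the representative with
#' `theta_wrapped` in [0, 45] and `delta_wrapped` in [0, 180] degrees; it
#' reproduces the six input intensities exactly (equivalence-class contract).
#' When delta = 0 the azimuth is indeterminate and is flagged.
#'
#' @inheritParams retarder_mueller
#' @return List with `theta_wrapped`, `delta_wrapped` (degrees),
#'   `azimuth_indeterminate` (logical) and the six simulated `intensities`.
#' @export
six_state_roundtrip <- function(theta_deg, delta_deg) {
  I <- six_state_intensities(theta_deg, delta_deg)
  m11 <- 2 * I[["lin0"]] - 1
  m22 <- 2 * I[["lin45"]] - 1
  m33 <- 2 * I[["rcp"]] - 1
  cd <- min(1, max(-1, m33))
  delta_w <- acos(cd) * 180 / pi
  if (1 - cd < 1e-12) {
    return(list(theta_wrapped = NA_real_, delta_wrapped = 0,
                azimuth_indeterminate = TRUE, intensities = I))
  }
  c4 <- min(1, max(-1, (m11 - m22) / (1 - cd)))
  theta_w <- acos(c4) * 180 / pi / 4
  list(theta_wrapped = theta_w, delta_wrapped = delta_w,
       azimuth_indeterminate = FALSE, intensities = I)
}
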