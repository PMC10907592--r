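# shared fixtures: the published corneal model constants
central_idx <- function() principal_indices(1.3764, 1.3776, 1.3775)
peripheral_idx <- function() principal_indices(1.3770, 1.3776, 1.3765)
default_shell <- function() corneal_shell()
default_profile <- function() index_profile()

# independent closed-form acute binormal angle from the optic-axis formula
closed_form_beta <- function(n) {
  n <- sort(as.numeric(unclass(n)))
  cos2V <- (1 / n[2]^2 - 1 / n[3]^2) / (1 / n[1]^2 - 1 / n[3]^2)
  two_v <- 2 * acos(sqrt(cos2V)) * 180 / pi
  if (two_v <= 90) two_v else 180 - two_v
}

# brute-force biquadratic roots by scanning |n^4 - p n^2 + q|
brute_force_roots <- function(s, n) {
  e <- unclass(n)^2
  den <- sum(s^2 * e)
  p <- (s[1]^2 * e[1] * (e[2] + e[3]) + s[2]^2 * e[2] * (e[1] + e[3]) +
          s[3]^2 * e[3] * (e[1] + e[2])) / den
  q <- prod(e) / den
  f <- function(x) x^4 - p * x^2 + q
  grid <- seq(min(n) - 1e-3, max(n) + 1e-3, length.out = 20001L)
  v <- abs(f(grid))
  k <- length(v)
  idx <- which(v[2:(k - 1)] < v[1:(k - 2)] & v[2:(k - 1)] < v[3:k]) + 1L
  roots <- vapply(grid[idx], function(x0)
    stats::optimize(function(x) abs(f(x)), c(x0 - 2e-4, x0 + 2e-4),
                    tol = 1e-14)$minimum, numeric(1))
  sort(unique(round(roots, 10)))
}
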