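test_that("vector Snell's law matches the scalar law and its limits", {
  n <- c(1, 0, 0)
  d <- c(1, 0, 0)
  expect_equal(refract_direction(d, n, 1, 1.3777), d)
  d45 <- c(1, 1, 0) / sqrt(2)
  t <- refract_direction(d45, n, 1, 1.3777)
  # independent oracle: asin(sin 45 / 1.3777) = 30.88066 degrees
  expect_equal(acos(sum(t * n)) * 180 / pi, 30.88066346, tolerance = 1e-6)
  expect_equal(sqrt(sum(t^2)), 1, tolerance = 1e-12)
  expect_equal(t[3], 0)   # stays in the plane of incidence
  expect_equal(refract_direction(d45, n, 1.5, 1.5), d45, tolerance = 1e-12)
  expect_error(refract_direction(c(0.2, sqrt(1 - 0.04), 0), n, 1.6, 1.0),
               class = "cornea_tir")
})

test_that("traced rays honor the axial case, symmetry and path bounds", {
  shell <- default_shell()
  src <- light_source("external")
  p <- trace_ray(src, c(0, 0), shell)
  expect_equal(p$A, c(0, 0, 0)); expect_equal(p$B, c(0.55, 0, 0))
  expect_equal(p$d, 0.55)
  p1 <- trace_ray(src, c(2.5, 0), shell)
  p2 <- trace_ray(src, c(-2.5, 0), shell)
  expect_equal(p1$d, p2$d, tolerance = 1e-12)
  expect_equal(p1$A * c(1, -1, 1), p2$A, tolerance = 1e-10)
  # independent re-integration of |B - A| and a lower bound from the
  # axial thickness and the maximum incidence angle
  seg <- sqrt(sum((p1$B - p1$A)^2))
  mid <- (p1$A + p1$B) / 2
  seg2 <- sqrt(sum((mid - p1$A)^2)) + sqrt(sum((p1$B - mid)^2))
  expect_equal(p1$d, seg2, tolerance = 1e-12)
  expect_gte(p1$d, 0.55 * cos(asin(sin(atan(6 / 7)) / shell$bulk_index)))
  expect_error(trace_ray(src, c(6.5, 0), shell), class = "cornea_miss")
})

test_that("direction components are an orthonormal change of basis", {
  shell <- default_shell()
  f <- local_frame(c(surface_sag(3, shell$anterior), 3, 0), shell$anterior)
  expect_equal(unname(unclass(direction_components(2.5 * f$e_x, f))),
               c(1, 0, 0), tolerance = 1e-12)
  expect_equal(unname(unclass(direction_components(f$e_x + f$e_y, f))),
               c(1, 1, 0) / sqrt(2), tolerance = 1e-12)
  set.seed(5)
  for (i in 1:10) {
    v <- rnorm(3)
    s <- direction_components(v, f)
    back <- s[1] * f$e_x + s[2] * f$e_y + s[3] * f$e_z
    expect_equal(back, v / sqrt(sum(v^2)), tolerance = 1e-12)
  }
  expect_error(direction_components(c(0, 0, 0), f), "nonzero")
})

test_that("the apex ray carries R = 55 nm and delta = 30 degrees", {
  shell <- default_shell()
  pr <- default_profile()
  p <- trace_ray(light_source("external"), c(0, 0), shell)
  # pure central regime: forced arithmetic from the printed constants
  s <- ray_retardation(p, pr, shell, regime = "central")
  expect_equal(s$dn_A, 1e-4, tolerance = 1e-12)
  expect_equal(s$dn_B, 1e-4, tolerance = 1e-12)
  expect_equal(s$dn_mean, (s$dn_A + s$dn_B) / 2)
  expect_equal(s$R, 55, tolerance = 1e-9)
  expect_equal(s$delta, 30, tolerance = 1e-9)
  expect_equal(s$azimuth, 0, tolerance = 1e-9)   # slow axis horizontal (n_y)
  # blended default: within the CDF tail of the same value
  sb <- ray_retardation(p, pr, shell)
  expect_equal(sb$R, 55, tolerance = 1e-4)
  # double pass doubles R
  expect_equal(ray_retardation(p, pr, shell, double_pass = TRUE,
                               regime = "central")$R, 110, tolerance = 1e-9)
})

test_that("an isotropic medium yields zero retardation for every ray", {
  shell <- default_shell()
  iso <- index_profile(central = principal_indices(1.3777, 1.3777, 1.3777),
                       peripheral = principal_indices(1.3777, 1.3777, 1.3777))
  for (y in c(0, 1.7, 4.4)) {
    s <- ray_retardation(trace_ray(light_source("external"), c(y, 0), shell),
                         iso, shell)
    expect_lt(abs(s$R), 1e-9)
  }
})

test_that("rays along the optic axis of the medium accumulate no retardation", {
  # concentric spherical shell + uniaxial medium with its distinct axis along
  # the local normal: every radial ray runs along the optic axis at both
  # surfaces, so R vanishes identically
  shell <- corneal_shell(R1 = 7.76, k1 = 0, R2 = 7.21, k2 = 0,
                         central_thickness = 0.55)
  uni <- index_profile(central = principal_indices(1.40, 1.3777, 1.3777),
                       peripheral = principal_indices(1.40, 1.3777, 1.3777))
  b <- binormal_axes(principal_indices(1.40, 1.3777, 1.3777))
  expect_equal(b$axis_1, c(1, 0, 0))   # optic axis along local x (the normal)
  center <- c(7.76, 0, 0)
  for (h in c(1, 2.5, 4)) {
    A <- c(surface_sag(h, shell$anterior), h, 0)
    dir <- (center - A) / sqrt(sum((center - A)^2))
    B <- intersect_ray(A, dir, shell$posterior)
    path <- structure(list(A = A, B = B, dir_outside = dir, dir_inside = dir,
                           d = sqrt(sum((B - A)^2)),
                           entry = "anterior", exit = "posterior"),
                      class = "ray_path")
    s <- ray_retardation(path, uni, shell, regime = "central")
    expect_lt(abs(s$R), 1e-3)
  }
})

test_that("maps are mirror symmetric and internally consistent", {
  cfg <- run_config(grid = list(n = 41L))
  maps <- compute_maps(cfg)
  rel_dev <- function(a, b) max(abs(a - b) / pmax(abs(a), 1e-12), na.rm = TRUE)
  expect_lt(rel_dev(maps$retardation,
                    maps$retardation[rev(seq_along(maps$y)), ]), 1e-9)
  expect_lt(rel_dev(maps$retardation,
                    maps$retardation[, rev(seq_along(maps$z))]), 1e-9)
  # R = dn * d * 1e6 cell-wise as stored
  expect_equal(maps$retardation, maps$birefringence * maps$path * 1e6)
  # delta = 360 R / lambda; doubling lambda halves delta, leaves R unchanged
  expect_equal(maps$phase, 360 * maps$retardation / 660)
  cfg2 <- run_config(grid = list(n = 41L), wavelength_nm = 1320)
  maps2 <- compute_maps(cfg2)
  expect_equal(maps2$retardation, maps$retardation)
  expect_equal(maps2$phase, maps$phase / 2)
  # all four grids share the mask
  expect_true(all(is.na(maps$azimuth[!maps$mask])))
  expect_true(all(!is.na(maps$retardation[maps$mask])))
})

test_that("central-regime minima sit where rays align with the tilted axes", {
  cfg <- run_config(regime = "central")
  cs <- cross_section(cfg, "horizontal", 0.02)
  m <- profile_metrics(cs)
  expect_equal(m$status, "ok")
  expect_equal(sum(m$minima_positions < 0), 1L)
  # oracle: the anterior-surface birefringence vanishes where the refracted
  # ray angle to the local normal equals the binormal half-angle; the
  # retardation minimum lies between that radius and the (inner) radius
  # where the exit-surface birefringence vanishes
  beta_half <- binormal_axes(central_idx())$beta_deg / 2 * pi / 180
  shell <- default_shell()
  h_ant <- stats::uniroot(function(h) {
    p <- c(surface_sag(h, shell$anterior), h, 0)
    alpha <- acos(surface_normal(p, shell$anterior)[1])
    asin(sin(alpha) / shell$bulk_index) - beta_half
  }, c(0.5, 5))$root
  parts <- corneabiref:::.config_parts(cfg)
  pos <- seq(0.5, 5, 0.01)
  ev <- corneabiref:::.evaluate_rays(pos, rep(0, length(pos)), parts$shell,
                                     parts$profile, parts$source,
                                     regime = "central")
  h_dnA <- pos[which.min(ev$dn_A)]
  h_dnB <- pos[which.min(ev$dn_B)]
  expect_equal(h_dnA, h_ant, tolerance = 0.03)
  expect_gt(max(m$minima_positions), min(h_dnA, h_dnB) - 0.02)
  expect_lt(max(m$minima_positions), max(h_dnA, h_dnB) + 0.02)
})

test_that("cross-sections are even, zero for isotropy, rising to the limbus", {
  cs <- cross_section(run_config(), "horizontal", 0.05)
  expect_equal(cs$retardation_nm, rev(cs$retardation_nm), tolerance = 1e-9)
  k <- nrow(cs)
  expect_gt(cs$retardation_nm[k], max(cs$retardation_nm[abs(cs$position_mm) < 3]))
  iso <- run_config(indices = list(central = c(1.3777, 1.3777, 1.3777),
                                   peripheral = c(1.3777, 1.3777, 1.3777)))
  csi <- cross_section(iso, "horizontal", 0.1)
  expect_lt(max(abs(csi$retardation_nm), na.rm = TRUE), 1e-9)
  expect_error(cross_section(run_config(), "diagonal"), "arg")
})

test_that("external and iris-plane sources agree on the minima separation", {
  m_ext <- profile_metrics(cross_section(run_config(), "horizontal", 0.02))
  m_iris <- profile_metrics(cross_section(
    run_config(source = list(mode = "iris_plane", distance_mm = 3.5)),
    "horizontal", 0.02))
  expect_equal(m_ext$status, "ok")
  expect_equal(m_iris$status, "ok")
  expect_lt(abs(m_ext$minima_separation - m_iris$minima_separation), 0.3)
})

test_that("profile metrics locate constructed minima and report failures", {
  x <- seq(-6, 6, 0.02)
  m <- profile_metrics(x, (abs(x) - 2)^2)
  expect_equal(sort(m$minima_positions), c(-2, 2), tolerance = 1e-6)
  expect_equal(m$minima_separation, 4, tolerance = 1e-6)
  mono <- profile_metrics(x, x + 10)
  expect_equal(mono$status, "minima-not-found")
  expect_true(is.na(mono$minima_separation))
  expect_equal(mono$max_position, 6)
  # parabolic refinement recovers an off-grid minimum
  m2 <- profile_metrics(x, (x - 1.013)^2 + 0.3 * (x + 2.99)^2)
  expect_equal(length(m2$minima_positions), 1L)
})

test_that("azimuth is radial when the in-plane indices are equal", {
  # transversely isotropic medium: the distinct (fast) axis is the surface
  # normal, whose projection is radial; the slow axis is tangential, so the
  # azimuth equals the polar angle mod 90
  cfg <- run_config(grid = list(n = 41L),
                    indices = list(central = c(1.3764, 1.3776, 1.3776),
                                   peripheral = c(1.3755, 1.3776, 1.3776)))
  maps <- compute_maps(cfg)
  n <- length(maps$y)
  yy <- matrix(maps$y, n, n); zz <- matrix(maps$z, n, n, byrow = TRUE)
  h <- sqrt(yy^2 + zz^2)
  polar <- (atan2(zz, yy) * 180 / pi) %% 180
  dev <- abs(((maps$azimuth - polar) + 45) %% 90 - 45)
  sel <- h > 1 & maps$mask
  expect_lt(max(dev[sel], na.rm = TRUE), 1e-6)
})
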