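test_that("pure geometry grids extract to g == 1 and F == 1", {
  lm <- geometry_model("line", 0.3)
  grid <- pure_geometry_grid(lm)
  g <- extract_radial_dose(grid, lm)
  expect_equal(g$g_values, rep(1, length(g$radii)), tolerance = 1e-12)
  Ft <- extract_anisotropy(grid, lm)
  expect_equal(unname(Ft$F_values),
               matrix(1, length(Ft$radii), length(Ft$angles)),
               tolerance = 1e-12)
})

test_that("a known exponential transverse falloff is recovered exactly", {
  lm <- geometry_model("line", 0.3)
  radii <- c(0.5, 1, 1.5, 2, 3, 4, 5)
  mu <- 0.1
  v <- sapply(seq(0, 90, 30), function(a)
    geometry_function(radii, a, lm) * exp(-mu * (radii - 1)))
  grid <- dose_rate_grid(radii, seq(0, 90, 30), v)
  g <- extract_radial_dose(grid, lm)
  expect_equal(g$g_values, exp(-mu * (radii - 1)), tolerance = 1e-12)
  expect_identical(g$g_values[radii == 1], 1)
})

test_that("synthetic noiseless grids reproduce the generator's analytic truth", {
  cfg <- simulator_config(noise_relative_sigma = 0)
  sim <- simulate_dose_grid(cfg)
  lm <- geometry_model("line", cfg$geometry$active_length)
  g <- extract_radial_dose(sim$grid, lm)
  expect_equal(g$g_values, sim$truth$g_true(g$radii), tolerance = 1e-12)
  Ft <- extract_anisotropy(sim$grid, lm)
  expect_equal(Ft$F_values,
               outer(Ft$radii, Ft$angles, sim$truth$F_true),
               tolerance = 1e-12)
  # capsule filtration makes F non-decreasing toward the transverse axis
  expect_true(all(apply(Ft$F_values, 1, function(x) all(diff(x) >= 0))))
})

test_that("extraction is invariant to overall grid scaling", {
  lm <- geometry_model("line", 0.3)
  for (seed in 1:5) {
    grid <- random_positive_grid(seed)
    c_scale <- exp(runif(1, -3, 3))
    scaled <- dose_rate_grid(grid$radii, grid$angles, grid$values * c_scale)
    expect_equal(extract_radial_dose(grid, lm)$g_values,
                 extract_radial_dose(scaled, lm)$g_values, tolerance = 1e-12)
    expect_equal(extract_anisotropy(grid, lm)$F_values,
                 extract_anisotropy(scaled, lm)$F_values, tolerance = 1e-12)
  }
})

test_that("normalisation holds for any valid grid", {
  lm <- geometry_model("line", 0.3)
  for (seed in 1:10) {
    grid <- random_positive_grid(seed)
    g <- extract_radial_dose(grid, lm)
    expect_identical(g$g_values[g$radii == 1], 1)
    Ft <- extract_anisotropy(grid, lm)
    expect_identical(unname(Ft$F_values[, Ft$angles == 90]),
                     rep(1, length(Ft$radii)))
  }
})

test_that("r0 off the radial lattice is handled by interpolation", {
  lm <- geometry_model("line", 0.3)
  radii <- c(0.5, 0.95, 1.05, 2, 5)  # no r = 1
  v <- sapply(c(45, 90), function(a) geometry_function(radii, a, lm))
  grid <- dose_rate_grid(radii, c(45, 90), v)
  g <- extract_radial_dose(grid, lm, r0 = 1)
  expect_s3_class(g, "radial_dose_table")
  expect_equal(g$reference_radius, 1)
  # pure-geometry grid: interpolation error only (dose is smooth), g near 1
  expect_equal(g$g_values, rep(1, 5), tolerance = 0.02)
})

test_that("extraction errors on missing transverse column and zero dose", {
  lm <- geometry_model("line", 0.3)
  grid <- dose_rate_grid(c(1, 2), c(0, 45), matrix(1, 2, 2))
  expect_error(extract_radial_dose(grid, lm), "90")
  expect_error(extract_anisotropy(grid, lm), "90")
  gz <- dose_rate_grid(c(1, 2), c(45, 90), matrix(c(1, 1, 0, 0), 2, 2))
  expect_error(extract_radial_dose(gz, lm), "degenerate")
  expect_error(extract_anisotropy(gz, lm), "degenerate")
  wide <- dose_rate_grid(c(1, 2), c(45, 90, 135), matrix(1, 2, 3))
  expect_error(extract_anisotropy(wide, lm), "fold_angles")
})

test_that("fold_angles maps full-circle grids onto the first quadrant", {
  # single angle 330 appears at 30
  g1 <- dose_rate_grid(c(1, 2), 330, matrix(c(3, 4), 2, 1))
  f1 <- fold_angles(g1)
  expect_equal(f1$angles, 30)
  expect_equal(f1$values, g1$values)

  # four quadrant images average with equal weights
  vals <- c(a = 1.0, b = 1.2, c = 0.9, d = 1.3)
  g4 <- dose_rate_grid(1, c(30, 150, 210, 330),
                       matrix(vals, 1, 4))
  f4 <- fold_angles(g4)
  expect_equal(f4$angles, 30)
  expect_equal(drop(f4$values), mean(vals))

  # a mirror-symmetric grid folds onto its own first quadrant
  cfg <- simulator_config(noise_relative_sigma = 0)
  full <- simulate_dose_grid(cfg, angles = seq(0, 330, 30))
  quad <- simulate_dose_grid(cfg, angles = c(0, 30, 60, 90))
  folded <- fold_angles(full$grid)
  expect_equal(folded$angles, c(0, 30, 60, 90))
  expect_equal(folded$values, quad$grid$values, tolerance = 1e-12)
})

test_that("extraction then reconstruction is the identity on lattice points", {
  cfg <- simulator_config(noise_relative_sigma = 0)
  sim <- simulate_dose_grid(cfg)
  lm <- geometry_model("line", cfg$geometry$active_length)
  sk <- air_kerma_strength(simulate_ring_kerma(cfg))$sk
  d_ref <- sim$grid$values[sim$grid$radii == 1, sim$grid$angles == 90]
  lam <- dose_rate_constant(d_ref, sk)
  ds <- consensus_dataset("synthetic", lam, lam, lam,
                          g_table = extract_radial_dose(sim$grid, lm),
                          F_table = extract_anisotropy(sim$grid, lm),
                          geometry = cfg$geometry, nuclide = pd103_nuclide())
  for (i in seq_along(sim$grid$radii)) {
    rec <- reconstruct_dose_rate(ds, sk, sim$grid$radii[i], sim$grid$angles)
    expect_equal(rec, unname(sim$grid$values[i, ]), tolerance = 1e-9)
  }
})
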