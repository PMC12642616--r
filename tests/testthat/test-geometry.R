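# slab picked from the middle of a groove profile
interior_slab <- function(model, index = 10, thickness = 5) {
  ax <- fit_channel_axis(model)
  partition_slabs(model, ax, thickness)$slabs[[index]]
}

test_that("lumen area agrees with a Monte-Carlo point-sampling oracle", {
  # wall with real disk radii, < 200 atoms in the slab
  g <- make_groove(groove_spec(length = 60, inner_radius = 10,
                               opening_angle = 180, lattice_spacing = 2,
                               atom_radius = 1.5, jitter_sd = 0.25, seed = 6))
  sl <- interior_slab(g$model, 6)
  expect_lt(length(sl$atom_idx), 200)
  cs <- lumen_cross_section(sl, g$model$atoms$vdw_radius[sl$atom_idx],
                            grid_resolution = 0.25)
  oracle <- mc_lumen_area(sl$proj, g$model$atoms$vdw_radius[sl$atom_idx],
                          n = 1e6, seed = 17)
  expect_equal(cs$area, oracle, tolerance = 0.02)
})

test_that("halving the grid resolution changes the semicircle area < 1%", {
  g <- make_groove(synth_preset("halfpipe10"))
  sl <- interior_slab(g$model)
  a1 <- lumen_cross_section(sl, 0, grid_resolution = 0.5)$area
  a2 <- lumen_cross_section(sl, 0, grid_resolution = 0.25)$area
  expect_lt(abs(a2 - a1) / a2, 0.01)
})

test_that("areas scale as k^2 and widths as k under coordinate scaling", {
  g <- make_groove(groove_spec(length = 40, inner_radius = 10,
                               opening_angle = 180, lattice_spacing = 1,
                               atom_radius = 0))
  m2 <- g$model
  m2$atoms$x <- 2 * m2$atoms$x
  m2$atoms$y <- 2 * m2$atoms$y
  m2$atoms$z <- 2 * m2$atoms$z
  cs1 <- lumen_cross_section(interior_slab(g$model, 4), 0,
                             grid_resolution = 0.25)
  cs2 <- lumen_cross_section(interior_slab(m2, 4, thickness = 10), 0,
                             grid_resolution = 0.25)
  expect_equal(cs2$area / cs1$area, 4, tolerance = 0.02)
  expect_equal(cs2$width_inscribed / cs1$width_inscribed, 2,
               tolerance = 0.02)
  expect_equal(cs2$width_maxchord / cs1$width_maxchord, 2, tolerance = 0.02)
})

test_that("empty and degenerate slabs give zero area and widths", {
  sl <- list(index = 0L, s_lo = 0, s_hi = 5, atom_idx = integer(0),
             proj = matrix(numeric(0), 0, 2))
  cs <- lumen_cross_section(sl, numeric(0))
  expect_true(cs$is_empty)
  expect_equal(cs$area, 0)
  expect_equal(cs$width_inscribed, 0)
  expect_equal(cs$width_maxchord, 0)
  # two atoms only
  sl2 <- list(index = 0L, s_lo = 0, s_hi = 5, atom_idx = 1:2,
              proj = rbind(c(0, 0), c(5, 0)))
  expect_true(lumen_cross_section(sl2, 1.7)$is_empty)
  expect_error(lumen_cross_section(sl2, 1.7, grid_resolution = -1),
               "grid_resolution")
})

test_that("width metrics obey inscribed <= maxchord on varied fixtures", {
  for (preset in c("halfpipe10", "tube10", "flare8to16")) {
    g <- make_groove(synth_preset(preset))
    p <- groove_profile(g$model)
    i <- !vapply(p$sections, `[[`, TRUE, "is_empty")
    expect_true(all(p$table$width_inscribed_A[i] <=
                      p$table$width_maxchord_A[i] + 1e-9))
  }
})

test_that("constant-radius grooves give a flat interior area profile", {
  g <- make_groove(groove_spec(length = 100, inner_radius = 10,
                               opening_angle = 180, lattice_spacing = 1.5,
                               atom_radius = 0.5, jitter_sd = 0.2, seed = 2))
  p <- groove_profile(g$model)
  interior <- p$table$slab_index %in% 2:17
  a <- p$table$area_A2[interior]
  expect_lt(stats::sd(a) / mean(a), 0.05)
})

test_that("a linearly flaring groove yields a strictly increasing area profile", {
  g <- make_groove(synth_preset("flare8to16"))
  p <- groove_profile(g$model)
  interior <- p$table$slab_index %in% 2:17
  expect_true(all(diff(p$table$area_A2[interior]) > 0))
})

test_that("lumen volume is exactly the area-thickness sum and feeds capacity", {
  g <- make_groove(groove_spec(length = 47, inner_radius = 10,
                               lattice_spacing = 2))
  p <- groove_profile(g$model, per_lipid_volume = 1300)
  expect_equal(p$lumen_volume,
               sum(p$table$area_A2 * (p$table$s_hi - p$table$s_lo)))
  expect_equal(p$capacity$capacity, p$lumen_volume / 1300)
})

test_that("lipid capacity arithmetic is exact and proportional", {
  expect_equal(estimate_lipid_capacity(156000, 1300)$n_lipids, 120L)
  expect_equal(estimate_lipid_capacity(0)$capacity, 0)
  c1 <- estimate_lipid_capacity(100000, 1000)$capacity
  c2 <- estimate_lipid_capacity(100000, 2000)$capacity
  expect_equal(c1, 2 * c2)
  expect_error(estimate_lipid_capacity(100, 0), "per_lipid_volume")
})

test_that("morphological mouth closure approximates the convex result on a tube", {
  g <- make_groove(groove_spec(length = 40, inner_radius = 10,
                               opening_angle = 0, lattice_spacing = 1.5,
                               atom_radius = 1))
  sl <- interior_slab(g$model, 4)
  r <- g$model$atoms$vdw_radius[sl$atom_idx]
  a_convex <- lumen_cross_section(sl, r, grid_resolution = 0.25)$area
  a_morph <- lumen_cross_section(sl, r, grid_resolution = 0.25,
                                 mouth_closure = "morphological")$area
  expect_equal(a_morph, a_convex, tolerance = 0.05)
})

test_that("end-slab trimming keeps cap slabs out of the summary widths", {
  g <- make_groove(groove_spec(length = 100, inner_radius = 10,
                               opening_angle = 180, lattice_spacing = 1.5,
                               atom_radius = 0.5))
  p <- groove_profile(g$model, trim_fraction = 0.25)
  expect_true(all(p$summary$slabs_used %in% p$table$slab_index))
  med <- stats::median(p$table$n_atoms[p$table$area_A2 > 0])
  expect_true(all(p$table$n_atoms[p$table$slab_index %in%
                                    p$summary$slabs_used] >= 0.25 * med))
})
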