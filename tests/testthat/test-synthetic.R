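test_that("half-pipe atoms lie on the stated cylinder", {
  g <- make_groove(groove_spec(length = 100, inner_radius = 10,
                               opening_angle = 180, lattice_spacing = 1,
                               atom_radius = 0, jitter_sd = 0))
  xyz <- coords(g$model)
  r <- sqrt(xyz[, 1]^2 + xyz[, 2]^2)
  expect_true(all(abs(r - 10) < 1e-9))
  expect_true(all(xyz[, 3] >= 0 & xyz[, 3] <= 100))
  # azimuths span exactly the closed half-circle (90..270 deg)
  phi <- g$truth$atoms$azimuth_deg
  expect_true(all(phi >= 90 - 1e-9 & phi <= 270 + 1e-9))
  expect_equal(range(phi), c(90, 270))
})

test_that("identical spec and seed give bitwise-identical coordinates", {
  sp <- groove_spec(length = 50, inner_radius = 10, jitter_sd = 0.4,
                    seed = 7)
  g1 <- make_groove(sp)
  g2 <- make_groove(sp)
  expect_identical(coords(g1$model), coords(g2$model))
  g3 <- make_groove(groove_spec(length = 50, inner_radius = 10,
                                jitter_sd = 0.4, seed = 8))
  expect_false(identical(coords(g1$model), coords(g3$model)))
})

test_that("jitter-free output is seed independent and jitter restores RNG state", {
  a <- make_groove(groove_spec(length = 30, inner_radius = 9, seed = 1))
  b <- make_groove(groove_spec(length = 30, inner_radius = 9, seed = 99))
  expect_identical(coords(a$model), coords(b$model))
  set.seed(123)
  before <- .Random.seed
  invisible(make_groove(groove_spec(length = 30, inner_radius = 9,
                                    jitter_sd = 0.5, seed = 5)))
  expect_identical(.Random.seed, before)
})

test_that("two-layer grooves stack radially with correct labels and residues", {
  g <- make_groove(groove_spec(length = 30, inner_radius = 10,
                               wall_layers = 2, layer_spacing = 3,
                               lattice_spacing = 2, jitter_sd = 0))
  xyz <- coords(g$model)
  r <- sqrt(xyz[, 1]^2 + xyz[, 2]^2)
  tr <- g$truth$atoms
  expect_true(all(abs(r[tr$layer == 1] - 10) < 1e-9))
  expect_true(all(abs(r[tr$layer == 2] - 13) < 1e-9))
  expect_identical(tr$label, ifelse(tr$layer == 1, "interior", "exterior"))
  expect_identical(g$model$atoms$resid,
                   ifelse(tr$layer == 1, "LEU", "ASP"))
})

test_that("generated grooves are self-consistent with their stated axis", {
  for (d in list(c(1, 0, 0), c(0, 1, 0), c(1, 1, 1) / sqrt(3))) {
    g <- make_groove(groove_spec(length = 80, inner_radius = 10,
                                 lattice_spacing = 2, axis_direction = d,
                                 jitter_sd = 0))
    ax <- fit_channel_axis(g$model)
    expect_lt(angle_deg(ax$direction, d), 0.5)
  }
})

test_that("analytic lumen area matches the closed forms", {
  half <- make_groove(groove_spec(length = 20, inner_radius = 10,
                                  opening_angle = 180))
  expect_equal(half$truth$lumen_area_fun(10), pi * 100 / 2, tolerance = 1e-12)
  tube <- make_groove(groove_spec(length = 20, inner_radius = 10,
                                  opening_angle = 0))
  expect_equal(tube$truth$lumen_area_fun(10), pi * 100, tolerance = 1e-12)
  # wall shorter than a half circle: circular segment of the wall arc
  wide <- make_groove(groove_spec(length = 20, inner_radius = 10,
                                  opening_angle = 270))
  a <- (100 / 2) * (pi / 2 - sin(pi / 2))
  expect_equal(wide$truth$lumen_area_fun(5), a, tolerance = 1e-12)
})

test_that("invalid groove specs are rejected", {
  expect_error(groove_spec(length = -1), "length")
  expect_error(groove_spec(opening_angle = 360), "opening_angle")
  expect_error(groove_spec(inner_radius = 1, atom_radius = 1.7),
               "must exceed atom_radius")
  expect_error(groove_spec(inner_radius = function(s) 10 - s / 5,
                           length = 100), "must exceed atom_radius")
})

test_that("sphere systems carry one single-atom residue per sphere", {
  m <- make_sphere_system(rbind(c(0, 0, 0), c(100, 0, 0)), c(1.7, 1.8),
                          c("A", "B"))
  expect_equal(nrow(m$atoms), 2L)
  expect_equal(m$atoms$chain, c("A", "B"))
  expect_equal(m$atoms$vdw_radius, c(1.7, 1.8))
  expect_error(make_sphere_system(rbind(c(0, 0, 0)), c(1, 2)), "disagree")
})

test_that("run_synth writes a readable fixture with spec header and sidecar", {
  pre <- withr::local_tempfile()
  run_synth("halfpipe10", pre)
  pdb <- paste0(pre, ".pdb")
  expect_true(file.exists(pdb))
  head_lines <- readLines(pdb, n = 3)
  expect_true(any(grepl("seed=1", head_lines)))
  truth <- read.csv(paste0(pre, "_truth.csv"))
  m <- read_structure(pdb)
  expect_equal(nrow(truth), nrow(m$atoms))
  expect_true(all(c("serial", "label", "s") %in% names(truth)))
})
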