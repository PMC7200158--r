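test_that("pitch is rise * 360 / twist", {
  expect_equal(pitch(helical_symmetry(48.0, 13.5)), 101.25)
  expect_equal(round(pitch(helical_symmetry(48.0, 13.5)), 1), 101.2,
               tolerance = 0.11)  # prints as 101.3 at the paper's precision
  expect_equal(pitch(helical_symmetry(360, 7)), 7)
  expect_equal(pitch(helical_symmetry(90, 10)), 40)
})

test_that("protomers per turn is 360 / twist", {
  expect_equal(protomers_per_turn(helical_symmetry(48.0, 13.5)), 7.5)
  expect_equal(protomers_per_turn(helical_symmetry(360, 1)), 1)
  expect_equal(protomers_per_turn(helical_symmetry(60, 1)), 6)
  expect_error(helical_symmetry(0, 13.5))
  expect_error(helical_symmetry(400, 13.5))
  expect_error(helical_symmetry(48, -1))
})

test_that("the screw operation maps protomer i to protomer i+1", {
  sym <- helical_symmetry(48.0, 13.5)
  model <- build_double_helix(sym, 8, radius = 20, dyad_phase = 30)
  a <- as.matrix(model[model$strand == "A", c("x", "y", "z")])
  th <- 48 * pi / 180
  screw <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  for (i in 1:7) {
    mapped <- screw %*% a[i, ] + c(0, 0, 13.5)
    expect_equal(as.numeric(mapped), as.numeric(a[i + 1, ]),
                 tolerance = 1e-9)
  }
})

test_that("strands are antiparallel, dyad-related and at radius", {
  sym <- helical_symmetry(48.0, 13.5)
  model <- build_double_helix(sym, 6, radius = 20, dyad_phase = 15)
  expect_equal(nrow(model), 12)
  a <- as.matrix(model[model$strand == "A", c("x", "y", "z")])
  b <- as.matrix(model[model$strand == "B", c("x", "y", "z")])
  # all centroids on the cylinder
  expect_equal(sqrt(model$x^2 + model$y^2), rep(20, 12), tolerance = 1e-9)
  # opposite polarity: strand B z decreases where strand A z increases
  pol_a <- sign(diff(a[, 3])[1]); pol_b <- sign(diff(b[, 3])[1])
  expect_equal(unname(pol_a * pol_b), -1)
  expect_setequal(model$polarity, c(1, -1))
  # dyad applied twice is the identity
  dd <- oligocount:::dyad_matrix(15)
  expect_equal(dd %*% dd, diag(3), tolerance = 1e-12)
  # n_per_strand = 1: the two centroids are exact dyad images
  m1 <- build_double_helix(sym, 1, radius = 20, dyad_phase = 15)
  expect_equal(as.numeric(dd %*% as.numeric(m1[1, c("x", "y", "z")])),
               as.numeric(m1[2, c("x", "y", "z")]), tolerance = 1e-12)
})

test_that("intra-strand neighbour distance matches the chord formula", {
  sym <- helical_symmetry(48.0, 13.5)
  r <- 20
  model <- build_double_helix(sym, 5, radius = r)
  a <- as.matrix(model[model$strand == "A", c("x", "y", "z")])
  d_direct <- sqrt(rowSums((a[-1, ] - a[-5, ])^2))
  d_formula <- sqrt((2 * r * sin(48 * pi / 360))^2 + 13.5^2)
  expect_equal(unname(d_direct), rep(d_formula, 4), tolerance = 1e-9)
})

test_that("handedness flips the sense of rotation", {
  sym <- helical_symmetry(90, 10)
  rh <- build_double_helix(sym, 2, radius = 10, handedness = "right")
  lh <- build_double_helix(sym, 2, radius = 10, handedness = "left")
  expect_equal(rh$y[2], 10, tolerance = 1e-9)
  expect_equal(lh$y[2], -10, tolerance = 1e-9)
})

test_that("centroid PDB export round-trips", {
  sym <- helical_symmetry(48.0, 13.5)
  model <- build_double_helix(sym, 6, radius = 20)
  path <- file.path(tempdir(), "filament.pdb")
  export_centroids(model, path)
  pdb <- bio3d::read.pdb(path)
  expect_equal(nrow(pdb$atom), 12)
  expect_setequal(unique(pdb$atom$chain), c("A", "B"))
  got <- as.numeric(pdb$xyz)
  want <- as.numeric(t(as.matrix(model[, c("x", "y", "z")])))
  expect_equal(got, want, tolerance = 1e-3)
  expect_error(export_centroids(model[0, ], path), "empty")
  expect_error(export_centroids(model, "/no/such/dir/f.pdb"), "directory")
  unlink(path)
})
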