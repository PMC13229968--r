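# helper: single-internode plant with configurable angles
single_internode_plant <- function(internode_pitch = 0, length = 0.1,
                                   base_rotation = c(0, 0, 0),
                                   leaf_pitch = 0, petiole_pitch = 0) {
  plant_architecture(
    shoots = list(shoot(
      shoot_id = 0L, shoot_type_label = 1, base_pitch = 0, base_yaw = 0,
      base_roll = 0,
      phytomers = list(phytomer(
        internode(length, 0.001, internode_pitch, 0),
        petiole(1e-6, 1e-6, petiole_pitch, 0),
        list(leaf(0.01, leaf_pitch, 0, 0)))))),
    plant_age = 0, base_rotation = base_rotation)
}

test_that("identity transforms place a vertical internode apex at (0, 0, L)", {
  g <- reconstruct_geometry(single_internode_plant(length = 0.1))
  apex <- g$segments[1, c("x1", "y1", "z1")]
  expect_equal(unname(apex), c(0, 0, 0.1), tolerance = 1e-12)
  # height exceeds the apex only by the micro petiole and flat leaf offsets
  expect_equal(plant_height(g), 0.1, tolerance = 1e-4)
})

test_that("a horizontal internode contributes nothing to height", {
  g <- reconstruct_geometry(single_internode_plant(internode_pitch = 90, length = 0.1))
  expect_lt(abs(g$segments[1, "z1"]), 1e-12)
})

test_that("an untransformed leaf has vertical normal and zero inclination", {
  g <- reconstruct_geometry(single_internode_plant())
  expect_equal(g$leaves[[1]]$normal, c(0, 0, 1), tolerance = 1e-12)
  h <- leaf_inclination_distribution(g, n_bins = 10)
  expect_equal(unname(h[1]), 1)
  expect_equal(sum(h), 1, tolerance = 1e-12)
  # pitch 90 puts the normal horizontal: all mass in the last bin
  g90 <- reconstruct_geometry(single_internode_plant(leaf_pitch = 90))
  expect_equal(unname(leaf_inclination_distribution(g90)[10]), 1)
})

test_that("successive phytomers with 180-degree phyllotaxis point petioles oppositely", {
  p <- plant_architecture(
    shoots = list(shoot(
      shoot_id = 0L, shoot_type_label = 1,
      phytomers = list(
        phytomer(internode(0.05, 0.001, 0, 180), petiole(0.02, 0.001, 90, 0),
                 list(leaf(0.01))),
        phytomer(internode(0.05, 0.001, 0, 180), petiole(0.02, 0.001, 90, 0),
                 list(leaf(0.01)))))),
    plant_age = 0)
  g <- reconstruct_geometry(p, arc_segments = 1L)
  # petiole direction = segment 2 (first petiole) vs segment 4 (second)
  d1 <- g$segments[2, 4:6] - g$segments[2, 1:3]
  d2 <- g$segments[4, 4:6] - g$segments[4, 1:3]
  expect_equal(unname(d1[1:2]), unname(-d2[1:2]), tolerance = 1e-9)
})

test_that("height, leaf area and inclination are invariant to rotation about z", {
  for (seed in c(1, 8, 30)) {
    plant <- generate_plant(seed, 20)
    g0 <- reconstruct_geometry(plant)
    g1 <- reconstruct_geometry(plant, azimuth_offset_deg = 137.5)
    expect_equal(plant_height(g1), plant_height(g0), tolerance = 1e-9)
    expect_equal(total_leaf_area(g1), total_leaf_area(g0), tolerance = 1e-9)
    expect_equal(leaf_inclination_distribution(g1),
                 leaf_inclination_distribution(g0), tolerance = 1e-9)
  }
})

test_that("scaling every leaf scale by c scales total area by c^2", {
  plant <- generate_plant(4, 15)
  scaled <- plant
  for (i in seq_along(scaled$shoots))
    for (k in seq_along(scaled$shoots[[i]]$phytomers))
      for (l in seq_along(scaled$shoots[[i]]$phytomers[[k]]$leaves))
        scaled$shoots[[i]]$phytomers[[k]]$leaves[[l]]$scale <-
          scaled$shoots[[i]]$phytomers[[k]]$leaves[[l]]$scale * 1.7
  expect_equal(total_leaf_area(reconstruct_geometry(scaled)),
               1.7^2 * total_leaf_area(reconstruct_geometry(plant)),
               tolerance = 1e-9)
})

test_that("token organ counts match the worked example and the architecture tally", {
  seq <- tokenize_architecture(make_two_shoot_plant(), plant_metadata(0.3, 0.2, 0.1))
  cnt <- count_organs(seq)
  expect_identical(cnt$n_shoots, 2L)
  expect_identical(cnt$n_phytomers, 2L)
  expect_identical(cnt$n_leaves, 5L)

  # single-shoot single-phytomer trifoliate
  tri <- plant_architecture(
    shoots = list(shoot(shoot_id = 0L, shoot_type_label = 3,
                        phytomers = list(phytomer(
                          internode(0.01, 0.001, 20, 170),
                          petiole(0.07, 0.0018, 50, -100, leaflet_scale = 0.9),
                          list(leaf(0.1), leaf(0.1), leaf(0.1)))))),
    plant_age = 0)
  cnt <- count_organs(tokenize_architecture(tri, plant_metadata(0, 0, 0)))
  expect_identical(unlist(cnt), c(n_shoots = 1L, n_phytomers = 1L, n_leaves = 3L))

  # generated plants: token tallies equal hierarchy tallies
  for (seed in c(2, 13)) {
    p <- generate_plant(seed, 22)
    cnt <- count_organs(tokenize_architecture(p, plant_metadata(0, 0, 0)))
    expect_identical(cnt$n_shoots, length(p$shoots))
    expect_identical(cnt$n_phytomers,
                     sum(vapply(p$shoots, function(s) length(s$phytomers), integer(1))))
    expect_identical(cnt$n_leaves,
                     sum(vapply(p$shoots, function(s)
                       sum(vapply(s$phytomers, function(ph) length(ph$leaves),
                                  integer(1))), integer(1))))
  }
})

test_that("vegetation fraction matches the analytic area ratio for a flat leaf", {
  sq <- rbind(c(-0.5, -0.5, 0.1), c(0.5, -0.5, 0.1),
              c(0.5, 0.5, 0.1), c(-0.5, 0.5, 0.1))
  g <- geometry3d(leaves = list(list(center = c(0, 0, 0.1),
                                     normal = c(0, 0, 1), area = 1,
                                     corners = sq)))
  m <- bounding_metadata(g, window_m = 2, resolution = 256L)
  expect_equal(m$vegetation_fraction, 0.25, tolerance = 2 * (2 / 256))
  expect_equal(m$width_m, 1)
  # doubling the window side divides the fraction by ~4
  m2 <- bounding_metadata(g, window_m = 4, resolution = 256L)
  expect_equal(m2$vegetation_fraction, 0.25 / 4, tolerance = 2 * (4 / 256))
  # no leaves -> fraction 0; zero window is a domain error
  expect_identical(bounding_metadata(geometry3d())$vegetation_fraction, 0)
  expect_error(bounding_metadata(g, window_m = 0), "window_m")
})

test_that("plant_traits bundles height, counts, area and a unit-mass histogram", {
  tr <- plant_traits(generate_plant(6, 18))
  expect_gt(tr$height_m, 0)
  expect_gt(tr$leaf_count, 0)
  expect_gt(tr$total_leaf_area_m2, 0)
  expect_equal(sum(tr$inclination_histogram), 1, tolerance = 1e-9)
  expect_gte(tr$n_phytomers, tr$n_shoots)
  expect_gte(tr$leaf_count, tr$n_phytomers)
})
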