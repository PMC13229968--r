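# Hand-built fixtures shared across tests.

# Smallest valid plant: one unifoliate shoot with one phytomer, one leaf.
make_minimal_plant <- function() {
  plant_architecture(
    shoots = list(shoot(
      shoot_id = 0L, shoot_type_label = 1, base_pitch = 40, base_yaw = 120,
      base_roll = 90,
      phytomers = list(phytomer(
        internode(0.002, 0.0015, 0, 180),
        petiole(0.0004, 0.0001, 70, 0),
        list(leaf(0.02, 5, 0, -15)))))),
    plant_age = 0, base_rotation = c(5, 100, 200))
}

# The two-shoot worked example: a unifoliate primary shoot (one phytomer,
# two opposite unifoliate leaves) with a trifoliate lateral attached at its
# first node.
make_two_shoot_plant <- function() {
  primary <- shoot(
    shoot_id = 0L, shoot_type_label = 1, base_pitch = 40, base_yaw = 30,
    base_roll = 90,
    phytomers = list(phytomer(
      internode(0.01, 0.0015, 0, 180),
      petiole(0.0004, 0.0001, 70, 0),
      list(leaf(0.02, 5, 0, -15), leaf(0.02, -5, 0, -15)))))
  lateral <- shoot(
    shoot_id = 1L, parent_shoot_id = 0L, parent_node_index = 0L,
    branching_order = 1L, shoot_type_label = 3, base_pitch = 50,
    base_yaw = 10, base_roll = 90,
    phytomers = list(phytomer(
      internode(0.02, 0.0015, 20, 170),
      petiole(0.07, 0.0018, 50, -100, leaflet_scale = 0.9),
      list(leaf(0.1, 40, 10, -15), leaf(0.1, 50, 10, -15),
           leaf(0.1, 45, 10, -15)))))
  plant_architecture(shoots = list(primary, lateral), plant_age = 10,
                     base_rotation = c(5, 100, 200))
}

# Field-for-field architecture comparison, ignoring base_position (tokens do
# not carry it) and comparing numerics with a tolerance.
expect_plants_equal <- function(a, b, tol = 1e-9, ignore_position = TRUE) {
  expect_equal(a$plant_age, b$plant_age, tolerance = tol)
  expect_equal(a$base_rotation, b$base_rotation, tolerance = tol)
  if (!ignore_position) expect_equal(a$base_position, b$base_position, tolerance = tol)
  expect_equal(length(a$shoots), length(b$shoots))
  for (i in seq_along(a$shoots)) {
    sa <- a$shoots[[i]]; sb <- b$shoots[[i]]
    expect_equal(sa$shoot_id, sb$shoot_id)
    expect_equal(sa$parent_shoot_id, sb$parent_shoot_id)
    expect_equal(sa$parent_node_index, sb$parent_node_index)
    expect_equal(sa$branching_order, sb$branching_order)
    expect_equal(sa$shoot_type_label, sb$shoot_type_label, tolerance = tol)
    expect_equal(c(sa$base_pitch, sa$base_yaw, sa$base_roll),
                 c(sb$base_pitch, sb$base_yaw, sb$base_roll), tolerance = tol)
    expect_equal(length(sa$phytomers), length(sb$phytomers))
    for (k in seq_along(sa$phytomers)) {
      pa <- sa$phytomers[[k]]; pb <- sb$phytomers[[k]]
      expect_equal(unlist(pa$internode), unlist(pb$internode), tolerance = tol)
      expect_equal(is.null(pa$petiole$leaflet_scale), is.null(pb$petiole$leaflet_scale))
      expect_equal(unlist(pa$petiole), unlist(pb$petiole), tolerance = tol)
      expect_equal(length(pa$leaves), length(pb$leaves))
      for (l in seq_along(pa$leaves))
        expect_equal(unlist(pa$leaves[[l]]), unlist(pb$leaves[[l]]), tolerance = tol)
    }
  }
  invisible(TRUE)
}

# Quantize every parameter of a plant in place (what one token round trip
# should reproduce exactly).
quantize_plant <- function(plant, vocab = build_vocabulary()) {
  q <- function(v, name) dequantize(quantize_parameter(v, name, vocab), name, vocab)
  plant$base_rotation <- c(q(plant$base_rotation[1], "base_rotation_pitch"),
                           q(plant$base_rotation[2], "base_rotation_yaw"),
                           q(plant$base_rotation[3], "base_rotation_roll"))
  plant$plant_age <- q(plant$plant_age, "plant_age")
  plant$base_position <- c(0, 0, 0)
  for (i in seq_along(plant$shoots)) {
    s <- plant$shoots[[i]]
    s$shoot_type_label <- q(s$shoot_type_label, "shoot_type_label")
    s$base_pitch <- q(s$base_pitch, "shoot_base_pitch")
    s$base_yaw <- q(s$base_yaw, "shoot_base_yaw")
    s$base_roll <- q(s$base_roll, "shoot_base_roll")
    for (k in seq_along(s$phytomers)) {
      ph <- s$phytomers[[k]]
      ph$internode$length <- q(ph$internode$length, "internode_length")
      ph$internode$radius <- q(ph$internode$radius, "internode_radius")
      ph$internode$pitch <- q(ph$internode$pitch, "internode_pitch")
      ph$internode$phyllotactic_angle <- q(ph$internode$phyllotactic_angle,
                                           "internode_phyllotactic_angle")
      ph$petiole$length <- q(ph$petiole$length, "petiole_length")
      ph$petiole$radius <- q(ph$petiole$radius, "petiole_radius")
      ph$petiole$pitch <- q(ph$petiole$pitch, "petiole_pitch")
      ph$petiole$curvature <- q(ph$petiole$curvature, "petiole_curvature")
      if (!is.null(ph$petiole$leaflet_scale))
        ph$petiole$leaflet_scale <- q(ph$petiole$leaflet_scale, "leaflet_scale")
      for (l in seq_along(ph$leaves)) {
        lf <- ph$leaves[[l]]
        ph$leaves[[l]] <- leaf(q(lf$scale, "leaf_scale"), q(lf$pitch, "leaf_pitch"),
                               q(lf$yaw, "leaf_yaw"), q(lf$roll, "leaf_roll"))
      }
      s$phytomers[[k]] <- ph
    }
    plant$shoots[[i]] <- s
  }
  plant
}

# Organ-token subsequence rendered as two-digit strings.
organ_subsequence <- function(seq) {
  ids <- as.integer(unclass(seq))
  ids <- ids[ids < 24L]
  sprintf("%d%d", ids %/% 6L, ids %% 6L)
}
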