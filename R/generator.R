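# Seeded procedural generator of vegetative cowpea architectures.
#
# Architectural parameters are sampled from the cowpea parameter table
# (constant / uniform / normal rows with unifoliate and trifoliate variants).
# Growth is simulated daily: each shoot apex initiates a new phytomer every
# phyllochron, each childless node may break a lateral bud (Bernoulli, per
# day), and internodes elongate linearly toward a saturating maximum.
# All draws are consumed in a fixed documented order so a plant is fully
# determined by (seed, config), and the day-d architecture is a prefix of the
# day-(d+1) architecture for the same seed.

#' Construct a parameter specification
#'
#' One row of the architectural parameter table: a named quantity with a
#' sampling distribution, its context (unifoliate, trifoliate or both) and
#' units.
#'
#' @param name Parameter identifier.
#' @param distribution One of `"constant"`, `"uniform"`, `"normal"`.
#' @param args Numeric arguments: the constant value, `c(low, high)` or
#'   `c(mean, sd)`.
#' @param context `"unifoliate"`, `"trifoliate"` or `"both"`.
#' @param units One of `"deg"`, `"m"`, `"days"`, `"index"`, `"dimensionless"`.
#' @return Object of class `pa_parameter_spec`.
#' @export
parameter_spec <- function(name, distribution, args, context = "both",
                           units = "dimensionless") {
  distribution <- match.arg(distribution, c("constant", "uniform", "normal"))
  context <- match.arg(context, c("unifoliate", "trifoliate", "both"))
  args <- as.numeric(args)
  if (distribution == "constant" && length(args) != 1)
    stop("constant spec takes exactly 1 argument", call. = FALSE)
  if (distribution == "uniform") {
    if (length(args) != 2 || args[1] >= args[2])
      stop("uniform spec requires low < high", call. = FALSE)
  }
  if (distribution == "normal") {
    if (length(args) != 2 || args[2] <= 0)
      stop("normal spec requires sd > 0", call. = FALSE)
  }
  structure(list(name = name, distribution = distribution, args = args,
                 context = context, units = units),
            class = "pa_parameter_spec")
}

#' Default cowpea architectural parameter table
#'
#' The sampling distributions of every architectural parameter of the cowpea
#' model, with separate unifoliate and trifoliate variants where the two
#' shoot types differ. Internode length and radius are *initial* dimensions
#' at organ creation; the growth model elongates them (see
#' [generator_config()]).
#'
#' @return A list of [parameter_spec()] rows.
#' @export
default_parameter_table <- function() {
  u <- "unifoliate"; t <- "trifoliate"; b <- "both"
  list(
    parameter_spec("base_rotation_pitch", "uniform", c(0, 10), b, "deg"),
    parameter_spec("base_rotation_yaw", "uniform", c(0, 360), b, "deg"),
    parameter_spec("base_rotation_roll", "uniform", c(0, 360), b, "deg"),
    parameter_spec("plant_age", "uniform", c(0, 39), b, "days"),
    parameter_spec("shoot_type_label", "constant", 1, u, "index"),
    parameter_spec("shoot_type_label", "constant", 3, t, "index"),
    parameter_spec("shoot_base_pitch", "constant", 40, u, "deg"),
    parameter_spec("shoot_base_pitch", "uniform", c(40, 60), t, "deg"),
    parameter_spec("shoot_base_yaw", "uniform", c(0, 360), u, "deg"),
    parameter_spec("shoot_base_yaw", "uniform", c(-20, 20), t, "deg"),
    parameter_spec("shoot_base_roll", "constant", 90, b, "deg"),
    parameter_spec("internode_length", "constant", 0.002, b, "m"),
    parameter_spec("internode_radius", "constant", 0.0015, b, "m"),
    parameter_spec("internode_pitch", "constant", 0, u, "deg"),
    parameter_spec("internode_pitch", "constant", 20, t, "deg"),
    parameter_spec("internode_phyllotactic_angle", "uniform", c(145, 215), b, "deg"),
    parameter_spec("petiole_length", "constant", 0.0004, u, "m"),
    parameter_spec("petiole_length", "uniform", c(0.06, 0.08), t, "m"),
    parameter_spec("petiole_radius", "constant", 0.0001, u, "m"),
    parameter_spec("petiole_radius", "constant", 0.0018, t, "m"),
    parameter_spec("petiole_pitch", "uniform", c(60, 80), u, "deg"),
    parameter_spec("petiole_pitch", "uniform", c(45, 60), t, "deg"),
    parameter_spec("petiole_curvature", "uniform", c(-200, -50), t, "deg"),
    parameter_spec("leaflet_scale", "constant", 0.9, t, "dimensionless"),
    parameter_spec("leaf_scale", "constant", 0.02, u, "dimensionless"),
    parameter_spec("leaf_scale", "uniform", c(0.09, 0.12), t, "dimensionless"),
    parameter_spec("leaf_pitch", "uniform", c(-10, 10), u, "deg"),
    parameter_spec("leaf_pitch", "normal", c(45, 20), t, "deg"),
    parameter_spec("leaf_yaw", "constant", 0, u, "deg"),
    parameter_spec("leaf_yaw", "constant", 10, t, "deg"),
    parameter_spec("leaf_roll", "constant", -15, b, "deg")
  )
}

#' Sample a value from a parameter specification
#'
#' Constant rows return the value without consuming randomness; uniform and
#' normal rows draw from the current R random number stream.
#'
#' @param spec A [parameter_spec()].
#' @return A single numeric value.
#' @export
sample_parameters <- function(spec) {
  switch(spec$distribution,
         constant = spec$args[1],
         uniform = stats::runif(1, spec$args[1], spec$args[2]),
         normal = stats::rnorm(1, spec$args[1], spec$args[2]),
         stop("unknown distribution kind", call. = FALSE))
}

#' Generator configuration
#'
#' Bundles the parameter table with the growth-rule constants. The growth
#' rules (phyllochron, lateral bud-break probability, internode elongation)
#' are internal to the growth simulator and exposed here so they can be
#' tuned; defaults are calibrated so day-39 plants carry tens of shoots and
#' hundreds of phytomers and leaves (population maxima around 400).
#'
#' @param parameter_table List of [parameter_spec()] rows.
#' @param phyllochron_days Days between successive phytomer initiations at a
#'   shoot apex (> 0).
#' @param lateral_bud_break_prob Per-node per-day probability that a
#'   childless node initiates a lateral shoot, in `[0, 1]`.
#' @param max_branching_order Deepest lateral order allowed (<= 3).
#' @param elongation List with `internode_length_rate` (m/day),
#'   `internode_length_max` (m), `internode_radius_rate` (m/day),
#'   `internode_radius_max` (m): linear growth with saturation.
#' @param seed_base Base random seed for dataset generation; plant `i` uses
#'   seed `seed_base + i`.
#' @return Object of class `pa_generator_config`.
#' @export
generator_config <- function(parameter_table = default_parameter_table(),
                             phyllochron_days = 3.0,
                             lateral_bud_break_prob = 0.02,
                             max_branching_order = 3L,
                             elongation = list(internode_length_rate = 0.005,
                                               internode_length_max = 0.05,
                                               internode_radius_rate = 1e-4,
                                               internode_radius_max = 0.003),
                             seed_base = 0L) {
  if (phyllochron_days <= 0) stop("phyllochron_days must be > 0", call. = FALSE)
  if (lateral_bud_break_prob < 0 || lateral_bud_break_prob > 1)
    stop("lateral_bud_break_prob must be in [0, 1]", call. = FALSE)
  if (max_branching_order > 3L)
    stop("max_branching_order must be <= 3", call. = FALSE)
  lookup <- new.env(parent = emptyenv())
  for (spec in parameter_table) {
    assign(paste(spec$name, spec$context, sep = "."), spec, envir = lookup)
  }
  structure(list(parameter_table = parameter_table,
                 phyllochron_days = phyllochron_days,
                 lateral_bud_break_prob = lateral_bud_break_prob,
                 max_branching_order = as.integer(max_branching_order),
                 elongation = elongation,
                 seed_base = as.integer(seed_base),
                 .lookup = lookup),
            class = "pa_generator_config")
}

.spec_for <- function(config, name, context) {
  key <- paste(name, context, sep = ".")
  if (exists(key, envir = config$.lookup, inherits = FALSE))
    return(get(key, envir = config$.lookup))
  key <- paste(name, "both", sep = ".")
  if (exists(key, envir = config$.lookup, inherits = FALSE))
    return(get(key, envir = config$.lookup))
  stop(sprintf("no parameter spec for %s (%s)", name, context), call. = FALSE)
}

.draw <- function(config, name, context) {
  sample_parameters(.spec_for(config, name, context))
}

# Internode dimension after `days` days of growth from the initial value.
.elongated <- function(initial, rate, maximum, days) {
  pmin(maximum, initial + rate * days)
}

# New phytomer; `context` is "unifoliate" or "trifoliate"; birth_day is kept
# for analytic elongation. Draw order: internode pitch, phyllotactic angle,
# petiole length/radius/pitch[/curvature], shared leaf scale, then per leaf
# pitch/yaw/roll.
.new_phytomer <- function(config, context, birth_day, n_uni_leaves = 2L) {
  tri <- context == "trifoliate"
  internode_obj <- internode(
    length = .draw(config, "internode_length", context),
    radius = .draw(config, "internode_radius", context),
    pitch = .draw(config, "internode_pitch", context),
    phyllotactic_angle = .draw(config, "internode_phyllotactic_angle", context))
  pet <- petiole(
    length = .draw(config, "petiole_length", context),
    radius = .draw(config, "petiole_radius", context),
    pitch = .draw(config, "petiole_pitch", context),
    curvature = if (tri) .draw(config, "petiole_curvature", context) else 0,
    leaflet_scale = if (tri) .draw(config, "leaflet_scale", context) else NULL)
  scale <- .draw(config, "leaf_scale", context)
  n_leaves <- if (tri) 3L else n_uni_leaves
  leaves <- vector("list", n_leaves)
  for (l in seq_len(n_leaves)) {
    leaves[[l]] <- leaf(scale = scale,
                        pitch = .draw(config, "leaf_pitch", context),
                        yaw = .draw(config, "leaf_yaw", context),
                        roll = .draw(config, "leaf_roll", context))
  }
  ph <- phytomer(internode_obj, pet, leaves)
  attr(ph, "birth_day") <- birth_day
  ph
}

.new_shoot <- function(config, sid, parent_id, parent_node, order, context,
                       birth_day) {
  s <- shoot(shoot_id = sid, parent_shoot_id = parent_id,
             parent_node_index = parent_node, branching_order = order,
             shoot_type_label = .draw(config, "shoot_type_label", context),
             base_pitch = .draw(config, "shoot_base_pitch", context),
             base_yaw = .draw(config, "shoot_base_yaw", context),
             base_roll = .draw(config, "shoot_base_roll", context),
             phytomers = list(.new_phytomer(config, context, birth_day)))
  s$phyllo_counter <- 0
  s$has_child <- FALSE  # grown to length(phytomers) lazily
  s
}

# One day of structural growth. Draw order per existing shoot (snapshot taken
# before the loop): apex phytomer draws first, then one vectorized uniform
# draw over the shoot's childless nodes for bud break; child shoot draws
# follow immediately, in node order. Shoots created today start growing
# tomorrow.
.grow_structure <- function(shoots, day, config) {
  n_existing <- length(shoots)
  next_id <- max(vapply(shoots, function(s) s$shoot_id, integer(1))) + 1L
  for (i in seq_len(n_existing)) {
    s <- shoots[[i]]
    s$phyllo_counter <- s$phyllo_counter + 1
    if (s$phyllo_counter >= config$phyllochron_days) {
      s$phyllo_counter <- s$phyllo_counter - config$phyllochron_days
      s$phytomers[[length(s$phytomers) + 1L]] <-
        .new_phytomer(config, "trifoliate", day)
    }
    nph <- length(s$phytomers)
    if (length(s$has_child) < nph)
      s$has_child <- c(s$has_child, rep(FALSE, nph - length(s$has_child)))
    if (s$branching_order < config$max_branching_order &&
        config$lateral_bud_break_prob > 0) {
      open <- which(!s$has_child)
      if (length(open) > 0) {
        fire <- open[stats::runif(length(open)) < config$lateral_bud_break_prob]
        for (k in fire) {
          s$has_child[k] <- TRUE
          shoots[[length(shoots) + 1L]] <-
            .new_shoot(config, next_id, s$shoot_id, k - 1L,
                       s$branching_order + 1L, "trifoliate", day)
          next_id <- next_id + 1L
        }
      }
    }
    shoots[[i]] <- s
  }
  shoots
}

# Set internode dimensions analytically from organ age, and drop the
# generator's bookkeeping fields.
.finalize_plant <- function(shoots, age_days, config) {
  el <- config$elongation
  for (i in seq_along(shoots)) {
    s <- shoots[[i]]
    for (k in seq_along(s$phytomers)) {
      ph <- s$phytomers[[k]]
      days <- age_days - attr(ph, "birth_day")
      ph$internode$length <- .elongated(ph$internode$length,
                                        el$internode_length_rate,
                                        el$internode_length_max, days)
      ph$internode$radius <- .elongated(ph$internode$radius,
                                        el$internode_radius_rate,
                                        el$internode_radius_max, days)
      attr(ph, "birth_day") <- NULL
      s$phytomers[[k]] <- ph
    }
    s$phyllo_counter <- NULL
    s$has_child <- NULL
    shoots[[i]] <- s
  }
  shoots
}

# Reorder shoots depth-first (children grouped under the phytomer they attach
# to, in creation order) and renumber ids 0..n-1.
.canonicalize <- function(plant) {
  shoots <- plant$shoots
  ids <- vapply(shoots, function(s) s$shoot_id, integer(1))
  parent <- vapply(shoots, function(s) s$parent_shoot_id, integer(1))
  pnode <- vapply(shoots, function(s) s$parent_node_index, integer(1))
  order_out <- integer(0)
  visit <- function(i) {
    order_out <<- c(order_out, i)
    for (k in seq_along(shoots[[i]]$phytomers)) {
      kids <- which(parent == ids[i] & pnode == (k - 1L))
      for (ci in kids) visit(ci)
    }
  }
  visit(which(parent == -1L))
  new_id <- integer(length(shoots))
  new_id[order_out] <- seq_along(order_out) - 1L
  out <- vector("list", length(order_out))
  for (j in seq_along(order_out)) {
    s <- shoots[[order_out[j]]]
    s$shoot_id <- new_id[order_out[j]]
    if (s$parent_shoot_id != -1L)
      s$parent_shoot_id <- new_id[match(s$parent_shoot_id, ids)]
    out[[j]] <- s
  }
  plant$shoots <- out
  plant
}

#' Generate a plant architecture
#'
#' Deterministically generates a cowpea architecture for a given seed and
#' age. The day-0 plant is a single branching-order-0 unifoliate shoot with
#' one phytomer bearing two opposite unifoliate leaves; daily growth then
#' adds trifoliate phytomers and lateral shoots. For a fixed seed, growth is
#' incremental: the day-`d` architecture is a structural prefix of the
#' day-`d+1` architecture.
#'
#' The caller's random number stream is left untouched.
#'
#' @param seed Integer random seed for this plant.
#' @param age_days Integer plant age in days, 0..39.
#' @param config A [generator_config()].
#' @return A valid [plant_architecture()] with shoots in depth-first order.
#' @export
generate_plant <- function(seed, age_days, config = generator_config()) {
  if (!is.numeric(age_days) || age_days < 0 || age_days > 39)
    stop("age_days must be in 0..39", call. = FALSE)
  age_days <- as.integer(age_days)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))

  base_rotation <- c(.draw(config, "base_rotation_pitch", "both"),
                     .draw(config, "base_rotation_yaw", "both"),
                     .draw(config, "base_rotation_roll", "both"))
  shoots <- list(.new_shoot(config, 0L, -1L, -1L, 0L, "unifoliate", 0L))
  if (age_days > 0) {
    for (day in seq_len(age_days))
      shoots <- .grow_structure(shoots, day, config)
  }
  shoots <- .finalize_plant(shoots, age_days, config)
  .canonicalize(plant_architecture(shoots = shoots, plant_age = age_days,
                                   base_rotation = base_rotation))
}

#' Advance a plant architecture by one day
#'
#' Standalone one-day growth step on a finalized architecture: each shoot
#' apex initiates a phytomer when its phyllochron counter elapses, childless
#' nodes may break lateral buds, internodes elongate. Because a finalized
#' architecture does not carry organ ages, elongation here applies one day of
#' growth to every internode below its saturating maximum. Uses the current R
#' random stream; seed it for reproducibility.
#'
#' @param plant A [plant_architecture()].
#' @param config A [generator_config()].
#' @return The grown [plant_architecture()], age incremented by one day.
#' @export
grow_day <- function(plant, config = generator_config()) {
  shoots <- plant$shoots
  for (i in seq_along(shoots)) {
    shoots[[i]]$phyllo_counter <- plant$plant_age %% config$phyllochron_days
    shoots[[i]]$has_child <- rep(FALSE, length(shoots[[i]]$phytomers))
  }
  # mark existing children so nodes do not double-branch
  for (s in shoots) {
    if (s$parent_shoot_id != -1L) {
      j <- which(vapply(shoots, function(x) x$shoot_id, integer(1)) == s$parent_shoot_id)
      shoots[[j]]$has_child[s$parent_node_index + 1L] <- TRUE
    }
  }
  day <- plant$plant_age + 1
  shoots <- .grow_structure(shoots, day, config)
  el <- config$elongation
  for (i in seq_along(shoots)) {
    s <- shoots[[i]]
    for (k in seq_along(s$phytomers)) {
      born_today <- !is.null(attr(s$phytomers[[k]], "birth_day"))
      if (!born_today) {
        s$phytomers[[k]]$internode$length <-
          .elongated(s$phytomers[[k]]$internode$length,
                     el$internode_length_rate, el$internode_length_max, 1)
        s$phytomers[[k]]$internode$radius <-
          .elongated(s$phytomers[[k]]$internode$radius,
                     el$internode_radius_rate, el$internode_radius_max, 1)
      }
      attr(s$phytomers[[k]], "birth_day") <- NULL
    }
    s$phyllo_counter <- NULL
    s$has_child <- NULL
    shoots[[i]] <- s
  }
  .canonicalize(plant_architecture(shoots = shoots, plant_age = day,
                                   base_rotation = plant$base_rotation,
                                   base_position = plant$base_position))
}

#' Generate a population of plants
#'
#' Convenience wrapper: plant `i` (1-based) uses seed `seed_base + i - 1`.
#' When `ages` is `NULL` each plant's age is drawn uniformly from 0..39 using
#' a dedicated stream seeded from `seed_base`, mirroring a population whose
#' age parameter follows the age row of the parameter table.
#'
#' @param n_plants Number of plants.
#' @param config A [generator_config()].
#' @param ages Optional integer vector of ages (recycled to `n_plants`).
#' @param seed_base Base seed; defaults to the config's.
#' @return List of [plant_architecture()] objects.
#' @export
generate_population <- function(n_plants, config = generator_config(),
                                ages = NULL, seed_base = config$seed_base) {
  if (is.null(ages)) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(as.integer(seed_base) + 1000003L)
    ages <- sample(0:39, n_plants, replace = TRUE)
    if (is.null(old_seed)) {
      rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  }
  ages <- rep_len(as.integer(ages), n_plants)
  lapply(seq_len(n_plants), function(i)
    generate_plant(seed_base + i - 1L, ages[i], config))
}

#' Generate a dataset of XML files, token files and a manifest
#'
#' Writes one XML document and one token line per (seed, day) pair, a JSON
#' Lines manifest with fields `seed`, `day`, `xml_path`, `token_path`, and a
#' `summary.json` with record counts and the maximum organ counts reached.
#' Reruns with the same config are byte-identical.
#'
#' @param n_seeds Number of plant seeds; plant `i` uses
#'   `seed_base + i - 1`.
#' @param days Integer vector of simulation days (default 0..39).
#' @param out_dir Output directory (created if missing).
#' @param config A [generator_config()].
#' @param window_m Image window side used for vegetation-fraction metadata.
#' @return Invisibly, the manifest as a data.frame.
#' @export
generate_dataset <- function(n_seeds, days = 0:39, out_dir,
                             config = generator_config(), window_m = 1.0) {
  dir.create(file.path(out_dir, "xml"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "tokens"), recursive = TRUE, showWarnings = FALSE)
  vocab <- build_vocabulary()
  records <- vector("list", n_seeds * length(days))
  r <- 0L
  max_counts <- c(shoots = 0L, phytomers = 0L, leaves = 0L)
  for (i in seq_len(n_seeds)) {
    seed <- config$seed_base + i - 1L
    for (day in days) {
      plant <- generate_plant(seed, day, config)
      geom <- reconstruct_geometry(plant)
      meta <- bounding_metadata(geom, window_m = window_m, resolution = 64L)
      tok <- tokenize_architecture(plant, meta, vocab)
      cnt <- count_organs(tok)
      max_counts <- pmax(max_counts, c(shoots = cnt$n_shoots,
                                       phytomers = cnt$n_phytomers,
                                       leaves = cnt$n_leaves))
      xml_path <- file.path("xml", sprintf("plant_%06d_day%02d.xml", seed, day))
      tok_path <- file.path("tokens", sprintf("plant_%06d_day%02d.txt", seed, day))
      write_architecture_xml(plant, file.path(out_dir, xml_path))
      write_token_file(tok, file.path(out_dir, tok_path))
      r <- r + 1L
      records[[r]] <- data.frame(seed = seed, day = day, xml_path = xml_path,
                                 token_path = tok_path)
    }
  }
  manifest <- do.call(rbind, records)
  man_lines <- vapply(seq_len(nrow(manifest)), function(j)
    as.character(jsonlite::toJSON(as.list(manifest[j, ]), auto_unbox = TRUE)),
    character(1))
  writeLines(man_lines, file.path(out_dir, "manifest.jsonl"), useBytes = TRUE)
  jsonlite::write_json(list(n_records = nrow(manifest),
                            max_shoots = unname(max_counts["shoots"]),
                            max_phytomers = unname(max_counts["phytomers"]),
                            max_leaves = unname(max_counts["leaves"])),
                       file.path(out_dir, "summary.json"), auto_unbox = TRUE)
  invisible(manifest)
}

# ---------------------------------------------------------------------------
# Distribution recovery

# Collect stored parameter values per (parameter, context) across plants.
# Internode length/radius are growth-modified and excluded; unifoliate
# petiole curvature is a structural 0, not a table row, and excluded too.
.collect_parameters <- function(plants) {
  n_plants <- length(plants)
  chunks <- new.env(parent = emptyenv())
  add <- function(key, i, values) {
    if (length(values) == 0) return(invisible(NULL))
    cur <- if (exists(key, envir = chunks, inherits = FALSE))
      get(key, envir = chunks) else vector("list", n_plants)
    cur[[i]] <- values
    assign(key, cur, envir = chunks)
  }
  for (i in seq_len(n_plants)) {
    plant <- plants[[i]]
    add("base_rotation_pitch.both", i, plant$base_rotation[1])
    add("base_rotation_yaw.both", i, plant$base_rotation[2])
    add("base_rotation_roll.both", i, plant$base_rotation[3])
    add("plant_age.both", i, plant$plant_age)

    types <- vapply(plant$shoots, function(s) s$shoot_type_label, numeric(1))
    uni <- types == 1
    add("shoot_type_label.unifoliate", i, types[uni])
    add("shoot_type_label.trifoliate", i, types[!uni])
    bp <- vapply(plant$shoots, function(s) s$base_pitch, numeric(1))
    by <- vapply(plant$shoots, function(s) s$base_yaw, numeric(1))
    add("shoot_base_pitch.unifoliate", i, bp[uni])
    add("shoot_base_pitch.trifoliate", i, bp[!uni])
    add("shoot_base_yaw.unifoliate", i, by[uni])
    add("shoot_base_yaw.trifoliate", i, by[!uni])
    add("shoot_base_roll.both", i,
        vapply(plant$shoots, function(s) s$base_roll, numeric(1)))

    phyts <- unlist(lapply(plant$shoots, function(s) s$phytomers),
                    recursive = FALSE)
    tri <- vapply(phyts, function(ph) !is.null(ph$petiole$leaflet_scale), logical(1))
    grab <- function(f) vapply(phyts, f, numeric(1))
    ipitch <- grab(function(ph) ph$internode$pitch)
    add("internode_pitch.unifoliate", i, ipitch[!tri])
    add("internode_pitch.trifoliate", i, ipitch[tri])
    add("internode_phyllotactic_angle.both", i,
        grab(function(ph) ph$internode$phyllotactic_angle))
    plen <- grab(function(ph) ph$petiole$length)
    prad <- grab(function(ph) ph$petiole$radius)
    ppit <- grab(function(ph) ph$petiole$pitch)
    add("petiole_length.unifoliate", i, plen[!tri])
    add("petiole_length.trifoliate", i, plen[tri])
    add("petiole_radius.unifoliate", i, prad[!tri])
    add("petiole_radius.trifoliate", i, prad[tri])
    add("petiole_pitch.unifoliate", i, ppit[!tri])
    add("petiole_pitch.trifoliate", i, ppit[tri])
    add("petiole_curvature.trifoliate", i,
        grab(function(ph) if (is.null(ph$petiole$leaflet_scale)) NA_real_
             else ph$petiole$curvature)[tri])
    add("leaflet_scale.trifoliate", i,
        grab(function(ph) if (is.null(ph$petiole$leaflet_scale)) NA_real_
             else ph$petiole$leaflet_scale)[tri])

    leaf_ctx <- rep(tri, vapply(phyts, function(ph) length(ph$leaves), integer(1)))
    leaves <- unlist(lapply(phyts, function(ph) ph$leaves), recursive = FALSE)
    lgrab <- function(field) vapply(leaves, `[[`, numeric(1), field)
    lsc <- lgrab("scale"); lpi <- lgrab("pitch"); lya <- lgrab("yaw")
    add("leaf_scale.unifoliate", i, lsc[!leaf_ctx])
    add("leaf_scale.trifoliate", i, lsc[leaf_ctx])
    add("leaf_pitch.unifoliate", i, lpi[!leaf_ctx])
    add("leaf_pitch.trifoliate", i, lpi[leaf_ctx])
    add("leaf_yaw.unifoliate", i, lya[!leaf_ctx])
    add("leaf_yaw.trifoliate", i, lya[leaf_ctx])
    add("leaf_roll.both", i, lgrab("roll"))
  }
  out <- list()
  for (key in ls(chunks))
    out[[key]] <- unlist(get(key, envir = chunks), use.names = FALSE)
  out
}

# Deterministic reference sample from a parameter spec: quantile function at
# mid-rank plotting positions.
.reference_sample <- function(spec, m = 4001L) {
  u <- (seq_len(m) - 0.5) / m
  switch(spec$distribution,
         constant = rep(spec$args[1], m),
         uniform = spec$args[1] + u * (spec$args[2] - spec$args[1]),
         normal = stats::qnorm(u, spec$args[1], spec$args[2]))
}

#' Check generated parameter distributions against their specifications
#'
#' For every sampled architectural parameter stored in the given plants,
#' computes the p = 1 Wasserstein distance between the empirical values and a
#' deterministic reference sample of the specified distribution, normalized
#' by the reference range. Internode length and radius are excluded because
#' the growth model elongates them away from their initial constants.
#'
#' @param plants List of [plant_architecture()] objects.
#' @param config The [generator_config()] the plants were generated with.
#' @param max_values Cap on empirical sample size per parameter
#'   (deterministically thinned above this).
#' @return data.frame with columns `parameter`, `context`, `n`, `wd`,
#'   `normalized_wd`.
#' @export
parameter_recovery <- function(plants, config = generator_config(),
                               max_values = 20000L) {
  collected <- .collect_parameters(plants)
  rows <- lapply(names(collected), function(key) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    name <- parts[1]; context <- parts[2]
    x <- collected[[key]]
    if (length(x) > max_values)
      x <- x[round(seq(1, length(x), length.out = max_values))]
    spec <- .spec_for(config, name, context)
    ref <- .reference_sample(spec)
    wd <- wasserstein_1d(x, ref)
    rng <- max(ref) - min(ref)
    nwd <- if (rng <= .Machine$double.eps) {
      if (wd <= .Machine$double.eps) 0 else Inf
    } else wd / rng
    data.frame(parameter = name, context = context, n = length(x),
               wd = wd, normalized_wd = nwd)
  })
  out <- do.call(rbind, rows)
  out[order(out$parameter, out$context), , drop = FALSE]
}
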