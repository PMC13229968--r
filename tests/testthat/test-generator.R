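test_that("sampling honours each distribution kind and context", {
  spec_c <- parameter_spec("leaf_roll", "constant", -15, "both", "deg")
  expect_identical(sample_parameters(spec_c), -15)

  spec_u <- parameter_spec("shoot_base_yaw", "uniform", c(-20, 20), "trifoliate", "deg")
  set.seed(1)
  draws <- replicate(10000, sample_parameters(spec_u))
  expect_gte(min(draws), -20)
  expect_lte(max(draws), 20)

  expect_error(parameter_spec("x", "uniform", c(5, 2)), "low < high")
  expect_error(parameter_spec("x", "normal", c(0, -1)), "sd > 0")
  expect_error(parameter_spec("x", "poisson", 1))
})

test_that("generation is deterministic and leaves the caller's RNG untouched", {
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  a <- generate_plant(7, 0)
  b <- generate_plant(7, 0)
  expect_identical(write_architecture_xml(a), write_architecture_xml(b))
  expect_identical(runif(1), before)
})

test_that("the day-0 plant is a single unifoliate shoot with one phytomer", {
  p <- generate_plant(3, 0)
  expect_length(p$shoots, 1)
  expect_identical(p$shoots[[1]]$branching_order, 0L)
  expect_identical(p$shoots[[1]]$shoot_type_label, 1)
  expect_length(p$shoots[[1]]$phytomers, 1)
  ph <- p$shoots[[1]]$phytomers[[1]]
  expect_null(ph$petiole$leaflet_scale)
  expect_identical(ph$internode$length, 0.002)
  expect_identical(ph$internode$radius, 0.0015)
  expect_error(generate_plant(3, 40), "age_days")
  expect_error(generate_plant(3, -1), "age_days")
})

test_that("growth is incremental and monotone in age for a fixed seed", {
  counts <- function(p)
    c(length(p$shoots),
      sum(vapply(p$shoots, function(s) length(s$phytomers), integer(1))))
  for (seed in c(7, 21)) {
    prev <- counts(generate_plant(seed, 0))
    for (age in c(1, 5, 11, 12, 25, 39)) {
      cur <- counts(generate_plant(seed, age))
      expect_true(all(cur >= prev))
      prev <- cur
    }
  }
  # one day below the phyllochron adds no phytomer
  p0 <- generate_plant(7, 0); p1 <- generate_plant(7, 1)
  expect_identical(length(p1$shoots[[1]]$phytomers),
                   length(p0$shoots[[1]]$phytomers))
})

test_that("bud-break probability 0 keeps a single shoot; probability 1 caps order at 3", {
  cfg0 <- generator_config(lateral_bud_break_prob = 0)
  expect_length(generate_plant(5, 39, cfg0)$shoots, 1)

  cfg1 <- generator_config(lateral_bud_break_prob = 1)
  p <- generate_plant(5, 39, cfg1)
  orders <- vapply(p$shoots, function(s) s$branching_order, integer(1))
  expect_identical(max(orders), 3L)
  expect_identical(validate_architecture(p), character(0))
})

test_that("sampled parameters stay inside their table bounds at day 39", {
  p <- generate_plant(17, 39)
  for (s in p$shoots) {
    tri <- s$shoot_type_label == 3
    if (tri) {
      expect_true(s$base_pitch >= 40 && s$base_pitch <= 60)
      expect_true(s$base_yaw >= -20 && s$base_yaw <= 20)
    } else {
      expect_identical(s$base_pitch, 40)
    }
    expect_identical(s$base_roll, 90)
    for (ph in s$phytomers) {
      expect_true(ph$internode$phyllotactic_angle >= 145 &&
                    ph$internode$phyllotactic_angle <= 215)
      if (!is.null(ph$petiole$leaflet_scale)) {
        expect_true(ph$petiole$length >= 0.06 && ph$petiole$length <= 0.08)
        expect_true(ph$petiole$curvature >= -200 && ph$petiole$curvature <= -50)
        expect_identical(ph$petiole$leaflet_scale, 0.9)
      }
      for (lf in ph$leaves) expect_identical(lf$roll, -15)
    }
  }
  # internode elongation saturates at the configured maximum
  lens <- unlist(lapply(p$shoots, function(s)
    vapply(s$phytomers, function(ph) ph$internode$length, numeric(1))))
  expect_lte(max(lens), 0.05)
  expect_gte(min(lens), 0.002)
})

test_that("every generated plant validates and tokenizes cleanly", {
  for (seed in 0:14) {
    p <- generate_plant(seed, (seed * 3) %% 40)
    expect_identical(validate_architecture(p), character(0))
    expect_no_error(tokenize_architecture(p, plant_metadata(0, 0, 0)))
  }
})

test_that("grow_day on a finalized plant adds structure and preserves validity", {
  p <- generate_plant(2, 6)
  set.seed(99)
  p2 <- grow_day(p)
  expect_identical(p2$plant_age, 7)
  expect_gte(sum(vapply(p2$shoots, function(s) length(s$phytomers), integer(1))),
             sum(vapply(p$shoots, function(s) length(s$phytomers), integer(1))))
  expect_identical(validate_architecture(p2), character(0))
})

test_that("generate_dataset writes XML, token lines and a consistent manifest", {
  out <- withr::local_tempdir()
  manifest <- generate_dataset(2, days = 0:1, out_dir = out)
  expect_identical(nrow(manifest), 4L)
  expect_true(all(file.exists(file.path(out, manifest$xml_path))))
  expect_true(all(file.exists(file.path(out, manifest$token_path))))
  expect_true(file.exists(file.path(out, "manifest.jsonl")))
  summary <- jsonlite::read_json(file.path(out, "summary.json"))
  expect_identical(summary$n_records, 4L)

  # rerun is byte-identical
  out2 <- withr::local_tempdir()
  generate_dataset(2, days = 0:1, out_dir = out2)
  for (rel in manifest$token_path)
    expect_identical(readLines(file.path(out, rel)), readLines(file.path(out2, rel)))

  # token line and XML agree
  tok <- read_token_file(file.path(out, manifest$token_path[2]))[[1]]
  xml_plant <- read_architecture_xml(file.path(out, manifest$xml_path[2]))
  dec <- detokenize(tok)$plant
  expect_identical(length(dec$shoots), length(xml_plant$shoots))
})

test_that("empirical parameter distributions recover their specifications", {
  pop <- generate_population(300, seed_base = 50L)
  rec <- parameter_recovery(pop)
  expect_true(all(is.finite(rec$normalized_wd)))
  # even at this modest population size every parameter is close
  expect_lt(max(rec$normalized_wd), 0.1)
  # constants are recovered exactly
  consts <- rec$parameter %in% c("leaf_roll", "shoot_base_roll", "leaflet_scale")
  expect_identical(max(rec$normalized_wd[consts]), 0)
})
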