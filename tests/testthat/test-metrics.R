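# Oracles (exhaustive LCS, brute-force transport, ECDF integral) live in
# helper-oracles.R.

test_that("token accuracy counts aligned matches", {
  expect_identical(token_accuracy(1:4, 1:4), 1)
  expect_identical(token_accuracy(1:4, 5:8), 0)
  expect_identical(token_accuracy(c(1, 2, 3, 9), 1:4), 0.75)
  expect_error(token_accuracy(1:3, 1:4), "alignment error")
})

test_that("weighted F1 matches hand computation and a brute-force confusion tally", {
  # two classes with supports (3, 1): class A fully correct, class B fully
  # wrong -> weighted F1 = 3/4 * F1_A. Here predictions turn the lone B into
  # an extra A, so F1_A = 2 * (3/4 * 1) / (3/4 + 1) = 6/7; weighted = 0.75 * 6/7 + 0.
  pred <- c(1, 1, 1, 1)
  ref <- c(1, 1, 1, 2)
  f1_a <- 2 * (3 / 4) * 1 / (3 / 4 + 1)
  expect_equal(weighted_f1(pred, ref), (3 * f1_a + 1 * 0) / 4)

  # clean (1.0, 0.0) case with supports (3, 1): distinct wrong class
  expect_equal(weighted_f1(c(1, 1, 1, 9), c(1, 1, 1, 2)), 0.75)
  expect_identical(weighted_f1(1:6, 1:6), 1)
  expect_identical(weighted_f1(rep(2, 5), rep(7, 5)), 0)

  # random sequences against an independent per-class tally
  set.seed(11)
  for (rep in 1:5) {
    pred <- sample(0:5, 40, replace = TRUE)
    ref <- sample(0:5, 40, replace = TRUE)
    manual <- 0
    for (k in unique(ref)) {
      tp <- sum(pred == k & ref == k); fp <- sum(pred == k & ref != k)
      fn <- sum(ref == k & pred != k)
      prec <- if (tp + fp) tp / (tp + fp) else 0
      rec <- if (tp + fn) tp / (tp + fn) else 0
      f1 <- if (prec + rec) 2 * prec * rec / (prec + rec) else 0
      manual <- manual + sum(ref == k) * f1
    }
    expect_equal(weighted_f1(pred, ref), manual / length(ref))
  }
})

test_that("sequence_eval supports sum to the reference length", {
  rep <- sequence_eval(c(1, 1, 2, 3), c(1, 2, 2, 3))
  expect_identical(sum(rep$per_token$n), 4L)
  expect_equal(rep$accuracy, 0.75)
})

test_that("BLEU-4 identity, brevity penalty and disjoint cases follow the formula", {
  seq <- tokenize_architecture(make_two_shoot_plant(), plant_metadata(0.3, 0.2, 0.1))
  expect_equal(bleu4(seq, seq), 100)

  # first half of the reference: all n-grams present, brevity penalty e^(1-2)
  ref <- rep(1:8, 4)
  gen <- ref[1:16]
  expect_equal(bleu4(gen, ref), 100 * exp(1 - 2), tolerance = 1e-9)

  expect_identical(bleu4(c(1, 2, 3, 4, 5), c(6, 7, 8, 9, 10)), 0)
  expect_error(bleu4(integer(0), 1:3), "non-empty")

  # corpus-level pooling differs from averaging per-sentence scores
  gen_l <- list(c(1, 2, 3, 4), c(5, 6, 7, 8, 5, 6, 7, 8))
  ref_l <- list(c(1, 2, 3, 4), c(5, 6, 7, 8))
  expect_gt(bleu4(gen_l, ref_l), 0)
})

test_that("ROUGE-L is 1 for identical and 0 for disjoint sequences", {
  seq <- tokenize_architecture(make_minimal_plant(), plant_metadata(0, 0, 0))
  expect_equal(rouge_l(seq, seq), 1)
  expect_equal(rouge_l(seq, seq, standard = TRUE), 1)
  expect_identical(rouge_l(c(1, 2, 3), c(4, 5, 6)), 0)
  expect_error(rouge_l(integer(0), 1:3), "non-empty")
  # averaged over pairs
  expect_equal(rouge_l(list(c(1, 2), c(3, 4)), list(c(1, 2), c(5, 6))), 0.5)
})

test_that("LCS dynamic programming matches exhaustive enumeration", {
  set.seed(7)
  for (rep in 1:60) {
    a <- sample(1:4, sample(1:8, 1), replace = TRUE)
    b <- sample(1:4, sample(1:8, 1), replace = TRUE)
    expect_identical(lcs_length(a, b), lcs_bruteforce(a, b))
  }
})

test_that("BLEU and ROUGE are non-increasing under growing corruption", {
  set.seed(5)
  ref <- as.integer(unclass(tokenize_architecture(generate_plant(1, 12),
                                                  plant_metadata(0.3, 0.2, 0.1))))
  rates <- c(0, 0.1, 0.3, 0.6, 1)
  scores <- sapply(rates, function(r) {
    gen <- ref
    flip <- which(runif(length(ref)) < r)
    gen[flip] <- (gen[flip] + 101L) %% 228L
    c(bleu = bleu4(gen, ref), rouge = rouge_l(gen, ref))
  })
  expect_true(all(diff(scores["bleu", ]) <= 1e-9))
  expect_true(all(diff(scores["rouge", ]) <= 1e-9))
})

test_that("1-D Wasserstein distance matches closed forms and transport oracles", {
  expect_identical(wasserstein_1d(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_identical(wasserstein_1d(2, 5), 3)

  set.seed(3)
  # equal sizes: brute-force assignment over permutations
  for (rep in 1:10) {
    a <- round(runif(5, 0, 10), 2)
    b <- round(runif(5, 0, 10), 2)
    expect_equal(wasserstein_1d(a, b), wd_assignment_bruteforce(a, b),
                 tolerance = 1e-9)
  }
  # unequal sizes up to 50 points: integrated ECDF difference
  for (rep in 1:10) {
    a <- runif(sample(5:50, 1), -3, 7)
    b <- runif(sample(5:50, 1), -1, 9)
    expect_equal(wasserstein_1d(a, b), wd_cdf_integral(a, b), tolerance = 1e-9)
  }
  expect_error(wasserstein_1d(numeric(0), 1), "non-empty")
})

test_that("normalized Wasserstein divides by the reference range with a degenerate guard", {
  a <- c(0, 5); b <- c(0, 10)
  expect_equal(wasserstein_1d(a, b, normalize = TRUE),
               wasserstein_1d(a, b) / 10)
  expect_identical(wasserstein_1d(c(2, 2), c(2, 2), normalize = TRUE), 0)
  expect_identical(wasserstein_1d(c(3, 3), c(2, 2), normalize = TRUE), Inf)
})

test_that("regression metrics match hand computation", {
  r <- regression_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$r2, 1); expect_equal(r$rmse, 0); expect_equal(r$mape_percent, 0)

  truth <- c(2, 4, 6, 8, 10)
  r <- regression_metrics(rep(mean(truth), 5), truth)
  expect_equal(r$r2, 0)

  pred <- c(1, 2, 3, 4, 5); truth2 <- c(2, 2, 4, 4, 5)
  r <- regression_metrics(pred, truth2)
  expect_equal(r$rmse, sqrt(mean((truth2 - pred)^2)))
  expect_equal(r$mape_percent, 100 * mean(abs((truth2 - pred) / truth2)))

  expect_warning(r <- regression_metrics(c(1, 2), c(0, 2)), "excluded from MAPE")
  expect_identical(r$n_mape_excluded, 1L)
})

test_that("distribution_eval of a population against itself is zero everywhere", {
  seqs <- lapply(0:4, function(s)
    tokenize_architecture(generate_plant(s, 10), plant_metadata(0.3, 0.2, 0.1)))
  ev <- distribution_eval(seqs, seqs)
  expect_true(all(ev$wd == 0))
  expect_true(all(ev$normalized_wd %in% c(0)))
})
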