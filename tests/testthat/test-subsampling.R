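test_that("Good's u follows the singleton formula in both modes", {
  # tallies A:3 B:2 C:1 -> N = 6, n1 = 1, u = 5/6
  occs <- occ_df(genus = c("A", "A", "A", "B", "B", "C"),
                 reference = c("r1", "r2", "r3", "r1", "r1", "r2"))
  cov <- estimate_coverage(occs)
  expect_equal(cov$N, 6L)
  expect_equal(cov$n1, 1L)
  expect_equal(cov$u, 5 / 6)

  # all genera singletons -> u = 0; none -> u = 1; empty -> NA
  expect_equal(estimate_coverage(occ_df(c("A", "B", "C")))$u, 0)
  expect_equal(estimate_coverage(occ_df(c("A", "A", "B", "B")))$u, 1)
  expect_true(is.na(estimate_coverage(occ_df(character(0)))$u))

  # by_reference: A known from 3 refs, B from 1, C from 1 -> n1 = 2
  covr <- estimate_coverage(occs, "by_reference")
  expect_equal(covr$n1, 2L)
  expect_equal(covr$u, 1 - 2 / 6)

  # u monotonically non-increasing in singleton fraction at fixed N
  u_vals <- vapply(0:4, function(k) {
    g <- c(rep("dom", 8 - k), paste0("s", seq_len(k)))
    estimate_coverage(occ_df(g))$u
  }, numeric(1))
  expect_true(all(diff(u_vals) <= 0))
})

test_that("single trials honour quorum reachability and tiny-bin cases", {
  cfg <- sqs_config(quorum = 0.1, deflate_by_u = FALSE, seed = 1)
  # one collection holding {A, B}: the first draw exhausts it -> richness 2
  one <- occ_df(c("A", "B"), collection = "c1", reference = "r1")
  expect_equal(sqs_single_trial(one, cfg), 2L)

  # all singletons -> u = 0 -> q/u unreachable -> failure, not richness 0
  sing <- occ_df(c("A", "B", "C"))
  expect_true(is.na(sqs_single_trial(sing, sqs_config(quorum = 0.4))))

  # subsampled richness never exceeds raw richness
  set.seed(9)
  for (s in 1:20) {
    occs <- occ_df(genus = sample(letters[1:8], 30, TRUE),
                   collection = sample(paste0("c", 1:6), 30, TRUE),
                   reference = sample(paste0("r", 1:3), 30, TRUE))
    r <- sqs_single_trial(occs, sqs_config(quorum = 0.7, seed = s))
    if (!is.na(r)) expect_lte(r, length(unique(occs$genus)))
  }
})

test_that("Monte-Carlo SQS matches the exhaustive enumeration oracle within 1%", {
  cases <- list(
    # 3 even genera in 3 single-publication collections, q = 0.4, deflation on
    list(occs = occ_df(c("A", "A", "B", "B", "C", "C"),
                       collection = c("c1", "c1", "c2", "c2", "c3", "c3"),
                       reference = c("r1", "r1", "r2", "r2", "r3", "r3")),
         q = 0.4, deflate = TRUE),
    # 5 collections, 2 publications, uneven tallies, q = 0.6
    list(occs = occ_df(c("A", "A", "A", "A", "B", "B", "C", "D", "D", "E",
                         "E", "E"),
                       collection = c("c1", "c1", "c2", "c3", "c2", "c4",
                                      "c4", "c5", "c3", "c5", "c1", "c2"),
                       reference = c("r1", "r1", "r1", "r2", "r1", "r2",
                                     "r2", "r2", "r2", "r2", "r1", "r1")),
         q = 0.6, deflate = TRUE),
    # deflation off, publication cap binding (4 collections share one pub)
    list(occs = occ_df(c("A", "B", "C", "D", "E", "F", "A", "B"),
                       collection = c("c1", "c1", "c2", "c2", "c3", "c3",
                                      "c4", "c4"),
                       reference = c("r1", "r1", "r1", "r1", "r1", "r1",
                                     "r2", "r2")),
         q = 0.5, deflate = FALSE)
  )
  for (case in cases) {
    expected <- oracle_sqs_expected(case$occs, case$q, deflate = case$deflate)
    cfg <- sqs_config(quorum = case$q, deflate_by_u = case$deflate, seed = 11)
    set.seed(11)
    draws <- replicate(10000, sqs_single_trial(case$occs, cfg))
    expect_false(anyNA(draws))
    expect_lt(abs(mean(draws) - expected) / expected, 0.01)
  }
})

test_that("expected SQS richness is non-decreasing in the quorum", {
  set.seed(21)
  occs <- occ_df(genus = sample(paste0("g", 1:12), 80, TRUE,
                                prob = 0.6^(1:12)),
                 collection = sample(paste0("c", 1:10), 80, TRUE),
                 reference = sample(paste0("r", 1:4), 80, TRUE))
  means <- vapply(c(0.2, 0.4, 0.6, 0.8), function(q) {
    cfg <- sqs_config(quorum = q, deflate_by_u = FALSE, seed = 5)
    set.seed(5)
    mean(replicate(2000, sqs_single_trial(occs, cfg)), na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(means) > -0.05))   # Monte-Carlo slack
})

test_that("per-bin estimates are seed-deterministic and flag unreachable bins NA", {
  b <- small_binned_record(seed = 3)
  cfg <- sqs_config(quorum = 0.4, trials = 150, seed = 17)
  a1 <- sqs_estimate(b, cfg)
  a2 <- sqs_estimate(b, cfg)
  expect_identical(a1, a2)
  ok <- !is.na(a1$mean)
  expect_true(any(ok))
  expect_true(all(a1$mean[ok] <= a1$raw_richness[ok]))

  # a bin whose coverage is below the quorum is reported NA, not 0
  sc <- make_uniform_bins(160, 150, 1)
  sparse <- occ_df(c("A", "B", "C"), max_ma = 158, min_ma = 155)
  est <- sqs_estimate(assign_to_bins(sparse, sc), sqs_config(quorum = 0.4))
  expect_equal(est$u, 0)
  expect_true(is.na(est$mean))
  expect_equal(est$n_trials_ok, 0L)
})

test_that("even abundances at quorum 1 without deflation return the true richness", {
  occs <- occ_df(rep(c("A", "B", "C", "D"), each = 3),
                 collection = rep(paste0("c", 1:4), times = 3),
                 reference = "r1")
  sc <- make_uniform_bins(160, 150, 1)
  occs$max_ma <- 158; occs$min_ma <- 155
  cfg <- sqs_config(quorum = 1, trials = 50, deflate_by_u = FALSE, seed = 2)
  est <- sqs_estimate(assign_to_bins(occs, sc), cfg)
  expect_equal(est$mean, 4)
  expect_equal(est$sd, 0)
})

test_that("bootstrap of a single-collection bin collapses to a zero-width interval", {
  occs <- occ_df(c("A", "A", "B", "C"), collection = "c1", reference = "r1",
                 max_ma = 158, min_ma = 155)
  sc <- make_uniform_bins(160, 150, 1)
  b <- assign_to_bins(occs, sc)
  bs <- bootstrap_sqs(b, sqs_config(quorum = 0.3, trials = 30, seed = 4),
                      reps = 20)
  expect_equal(bs$ci_lo, bs$ci_hi)
  expect_false(is.na(bs$ci_lo))
})

test_that("bootstrap intervals bracket the long-run SQS mean at near-nominal rates", {
  # fixed generative process; the long-run mean is estimated from many
  # independent datasets, then fresh datasets' percentile intervals are
  # checked for coverage
  gen <- function(seed) {
    world <- simulate_true_world(1, 15, seed = seed)
    rec <- simulate_fossil_record(
      world, sampling_regime(collections_per_bin = 15, occ_per_collection = 4),
      seed = seed)
    assign_to_bins(rec, attr(rec, "scheme"))
  }
  cfg <- sqs_config(quorum = 0.5, trials = 60, seed = 1)
  long_run <- mean(vapply(1:150, function(s) {
    sqs_estimate(gen(1000 + s), cfg)$mean
  }, numeric(1)), na.rm = TRUE)
  covered <- vapply(1:100, function(s) {
    bs <- bootstrap_sqs(gen(5000 + s),
                        sqs_config(quorum = 0.5, trials = 40, seed = s),
                        reps = 60)
    !is.na(bs$ci_lo) && bs$ci_lo <= long_run && long_run <= bs$ci_hi
  }, logical(1))
  expect_gte(mean(covered), 0.90)
})
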