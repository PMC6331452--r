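test_that("simulate_sample is deterministic under a fixed seed", {
  specs <- three_cluster_specs()
  d <- study_design(treatments = "Neg", replicates_per_treatment = 1,
                    sampling_days = c(0, 4), events_per_sample = 10000,
                    adaptation_shift = numeric(), seed = 42)
  a <- simulate_sample(d, specs, "Neg", 1, 4)
  b <- simulate_sample(d, specs, "Neg", 1, 4)
  expect_identical(a$events, b$events)
  expect_identical(a$labels, b$labels)
  # different day or replicate gives a different stream
  c <- simulate_sample(d, specs, "Neg", 1, 0)
  expect_false(identical(a$events[1:10, ], c$events[1:10, ]))
})

test_that("ground-truth label frequencies match mixture weights", {
  specs <- three_cluster_specs(c(50, 30, 20))
  d <- study_design(treatments = "Neg", replicates_per_treatment = 1,
                    sampling_days = 4, events_per_sample = 100000,
                    adaptation_shift = numeric(),
                    noise_concentration = Inf, seed = 11)
  cl <- simulate_sample(d, specs, "Neg", 1, 4)
  n <- 100000
  for (i in seq_along(specs)) {
    p <- c(0.5, 0.3, 0.2)[i]
    freq <- mean(cl$labels == names(specs)[i])
    expect_lt(abs(freq - p), 4 * sqrt(p * (1 - p) / n))
  }
})

test_that("zero covariance collapses a cluster onto its center", {
  specs <- three_cluster_specs()
  specs$A$covariance <- matrix(0, 2, 2)
  d <- study_design(treatments = "Neg", replicates_per_treatment = 1,
                    sampling_days = 4, events_per_sample = 5000,
                    adaptation_shift = numeric(), seed = 3)
  cl <- simulate_sample(d, specs, "Neg", 1, 4)
  ev <- cl$events[cl$labels == "A", , drop = FALSE]
  expect_gt(nrow(ev), 0)
  expect_true(all(ev[, 1] == 1 & ev[, 2] == 1))
})

test_that("realized abundances sum to 100 and respect the trajectory model", {
  specs <- six_cluster_specs(list(G1 = c(Tox = 0.9), G2 = c(Tox = -0.75)))
  d <- study_design(treatments = c("Neg", "Tox"),
                    replicates_per_treatment = 2,
                    sampling_days = c(0, 4, 7, 24), events_per_sample = 100,
                    adaptation_shift = c(G1 = -5, G3 = 5),
                    noise_concentration = Inf, seed = 5)
  for (day in d$sampling_days) {
    ab <- cytofp:::realized_abundances(d, specs, "Tox", 1, day)
    expect_equal(sum(ab), 100)
  }
  # all-zero slopes: constant expected abundances from day 4 on
  ab4 <- cytofp:::realized_abundances(d, specs, "Neg", 1, 4)
  ab24 <- cytofp:::realized_abundances(d, specs, "Neg", 1, 24)
  expect_equal(ab4, ab24)
  # day 0 shared across treatments (common inoculum)
  expect_equal(cytofp:::realized_abundances(d, specs, "Neg", 1, 0),
               cytofp:::realized_abundances(d, specs, "Tox", 1, 0))
  # linear rise with clipping and renormalization
  raw <- c(25 + 0.9 * 20, 20 - 0.75 * 20, 18, 15, 12, 10)
  expect_equal(unname(cytofp:::realized_abundances(d, specs, "Tox", 1, 24)),
               100 * raw / sum(raw))
})

test_that("simulate_study covers the full design grid", {
  specs <- three_cluster_specs()
  d <- study_design(replicates_per_treatment = 3,
                    sampling_days = c(0, 4, 7, 10, 14, 17, 21, 24),
                    events_per_sample = 50, adaptation_shift = numeric(),
                    seed = 2)
  st <- simulate_study(d, specs)
  expect_length(st, 5 * 3 * 8)
  expect_false(anyDuplicated(names(st)) > 0)
  expect_true(all(vapply(st, function(x) nrow(x$events), 0) == 50))
})

test_that("a positive generative slope raises day-24 frequency over day-4", {
  specs <- six_cluster_specs(list(G6 = c(Tox = 0.9)))
  wins <- 0L
  for (s in 1:100) {
    d <- study_design(treatments = "Tox", replicates_per_treatment = 1,
                      sampling_days = c(4, 24), events_per_sample = 2000,
                      adaptation_shift = numeric(), seed = s)
    f4 <- mean(simulate_sample(d, specs, "Tox", 1, 4)$labels == "G6")
    f24 <- mean(simulate_sample(d, specs, "Tox", 1, 24)$labels == "G6")
    if (f24 > f4) wins <- wins + 1L
  }
  expect_gte(wins, 95)
})

test_that("invalid simulation inputs are rejected", {
  specs <- three_cluster_specs()
  d <- study_design(treatments = "Neg", replicates_per_treatment = 1,
                    sampling_days = c(0, 4), events_per_sample = 100,
                    adaptation_shift = numeric())
  expect_error(simulate_sample(d, specs, "Nope", 1, 4), "unknown treatment")
  expect_error(simulate_sample(d, specs, "Neg", 1, 5), "not a sampling day")
  expect_error(subcommunity_spec("X", c(1, 1),
                                 matrix(c(1, 2, 2, 1), 2), 10),
               "positive-definite")
  expect_error(subcommunity_spec("X", c(1, 1),
                                 matrix(c(1, 0.2, 0.3, 1), 2), 10),
               "symmetric")
  expect_error(study_design(sampling_days = c(4, 4)), "strictly increasing")
  # total driven to zero: single subcommunity fully clipped
  one <- list(A = subcommunity_spec("A", c(1, 1), diag(2) * 0.01, 5,
                                    c(Tox = -1)))
  dd <- study_design(treatments = "Tox", replicates_per_treatment = 1,
                     sampling_days = c(4, 24), events_per_sample = 10,
                     adaptation_shift = numeric(),
                     noise_concentration = Inf)
  expect_error(simulate_sample(dd, one, "Tox", 1, 24), "sum to")
})

test_that("replicate noise perturbs composition but not dynamics shape", {
  specs <- six_cluster_specs()
  d <- study_design(treatments = "Neg", replicates_per_treatment = 3,
                    sampling_days = c(4, 24), events_per_sample = 100,
                    adaptation_shift = numeric(),
                    noise_concentration = 200, seed = 9)
  # same replicate, different days: identical perturbed composition
  expect_equal(cytofp:::realized_abundances(d, specs, "Neg", 1, 4),
               cytofp:::realized_abundances(d, specs, "Neg", 1, 24))
  # different replicates differ
  expect_false(isTRUE(all.equal(
    cytofp:::realized_abundances(d, specs, "Neg", 1, 4),
    cytofp:::realized_abundances(d, specs, "Neg", 2, 4))))
})
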