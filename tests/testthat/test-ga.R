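# Genetic-algorithm conductance fitting.

test_that("the AP score is the squared SE-normalized residual sum", {
  targets <- list(mean = c(a = 8, b = 26), se = c(a = 1, b = 2))
  expect_identical(ap_score(c(a = 8, b = 26), targets), 0)
  expect_identical(ap_score(c(a = 9, b = 26), targets), 1)
  expect_identical(ap_score(c(a = 10, b = 20), targets), 4 + 9)
  # missing / undefined features earn the penalty
  expect_identical(ap_score(c(a = 10), targets), 1e6)
  expect_identical(ap_score(c(a = NA_real_, b = 26), targets, penalty = 99), 99)
  nonbeat <- extract_ap_features(
    structure(data.frame(time_ms = 0:99, V_mV = rep(-70, 100)),
              class = c("cardiomag_ap_trace", "data.frame")), "ventricular")
  expect_identical(ap_score(nonbeat, list(mean = c(MDP = -60), se = c(MDP = 1))),
                   1e6)
})

sphere_bounds <- function(n) {
  b <- rbind(lower = rep(0, n), upper = rep(1, n))
  colnames(b) <- paste0("g", seq_len(n))
  b
}

test_that("the GA minimizes a sphere function to high precision", {
  ev <- function(g) sum((g - 0.5)^2)
  cfg <- ga_config(pop_size = 60, generations = 100,
                   bounds = sphere_bounds(8), seed = 3)
  res <- run_ga(ev, cfg)
  expect_lt(res$best_score, 1e-3)
  expect_equal(unname(res$best), rep(0.5, 8), tolerance = 0.05)
  # history is monotone non-increasing (elitism)
  expect_true(all(diff(res$history) <= 0))
})

test_that("GA runs are deterministic given the seed and respect bounds", {
  ev <- function(g) sum(g^2) # optimum at the lower bound
  cfg <- ga_config(pop_size = 20, generations = 15,
                   bounds = sphere_bounds(3), seed = 11)
  r1 <- run_ga(ev, cfg); r2 <- run_ga(ev, cfg)
  expect_identical(r1$best, r2$best)
  expect_identical(r1$history, r2$history)
  expect_true(all(r1$best >= 0 & r1$best <= 1))
})

test_that("zero mutation on an identical population leaves the best unchanged", {
  ev <- function(g) sum((g - 0.25)^2)
  cfg <- ga_config(pop_size = 10, generations = 8, bounds = sphere_bounds(2),
                   mutation_rate = 0, seed = 5)
  # identical initial population: collapse bounds to a point, then widen the
  # clamp so variation could only come from crossover/mutation
  cfg$bounds[1, ] <- 0.7; cfg$bounds[2, ] <- 0.7
  res <- run_ga(ev, cfg)
  expect_equal(unname(res$best), c(0.7, 0.7))
  expect_true(all(res$history == res$history[1]))
})

test_that("configuration errors are rejected", {
  expect_error(ga_config(pop_size = 0, generations = 5,
                         bounds = sphere_bounds(2)))
  expect_error(ga_config(pop_size = 5, generations = 0,
                         bounds = sphere_bounds(2)))
  b <- sphere_bounds(2); b[1, 1] <- 2 # lower > upper
  expect_error(ga_config(pop_size = 5, generations = 5, bounds = b))
})

test_that("the best of independent runs is selected, ties by lowest seed", {
  mk <- function(score, seed)
    structure(list(best = c(g1 = 0), best_score = score, history = score,
                   seed = seed), class = "cardiomag_ga_result")
  runs <- list(mk(3.2, 1), mk(1.1, 2), mk(5.0, 3))
  expect_identical(select_best_of_runs(runs)$seed, 2)
  expect_identical(select_best_of_runs(runs[1])$best_score, 3.2)
  ties <- list(mk(1.0, 7), mk(1.0, 3))
  expect_identical(select_best_of_runs(ties)$seed, 3)
  expect_error(select_best_of_runs(list()))
})

test_that("the GA recovers parameters of a synthetic surrogate model", {
  # surrogate: 'features' are a fixed linear map of the genes; targets are
  # generated from a known gene vector, so a perfect fit has score 0
  set.seed(42)
  A <- matrix(rnorm(5 * 4), 5, 4)
  truth <- c(0.3, 0.8, 0.1, 0.6)
  target_mean <- drop(A %*% truth)
  targets <- list(mean = setNames(target_mean, paste0("f", 1:5)),
                  se = setNames(rep(0.05, 5), paste0("f", 1:5)))
  ev <- function(g) ap_score(setNames(drop(A %*% g), paste0("f", 1:5)), targets)
  cfg <- ga_config(pop_size = 60, generations = 120,
                   bounds = sphere_bounds(4), seed = 9)
  res <- run_ga(ev, cfg)
  expect_lt(res$best_score, 0.5)  # within the target SEs
  pred <- drop(A %*% res$best)
  expect_equal(pred, target_mean, tolerance = 0.05)
})
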