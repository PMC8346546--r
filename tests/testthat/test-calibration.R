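# Calibration engine: fit metric, design construction, screening, ABC,
# narrowing and loop termination. Simulator-independent pieces use cheap
# surrogate fit functions so the mechanics are tested exactly.

surrogate_fit <- function(coef, noise = 0) {
  # deterministic (plus optional noise) linear response in the parameters
  function(theta, seed) {
    set.seed(seed)
    y <- sum(coef[names(theta)] * theta) + stats::rnorm(1, 0, noise)
    list(r2 = y, min_viability = 100)
  }
}

test_that("the fit metric is the normalized absolute difference", {
  obs <- observed_dataset(data.frame(
    condition = c(3, 3, 6), day = c(3, 6, 3),
    observable = "live_count", mean = c(100, 200, 150)))
  sim <- data.frame(condition = c(3, 3, 6), day = c(3, 6, 3),
                    observable = "live_count", value = c(100, 200, 150))
  expect_equal(as.numeric(r_squared(sim, obs)), 1)
  sim$value <- c(0, 0, 0)
  expect_equal(as.numeric(r_squared(sim, obs)), 0)
  sim$value <- 1.1 * obs$mean
  expect_equal(as.numeric(r_squared(sim, obs)), 0.9)
  # multiple observables average their per-observable values
  obs2 <- observed_dataset(data.frame(
    condition = 3, day = c(3, 3), observable = c("alp", "oc"),
    mean = c(10, 20)))
  sim2 <- data.frame(condition = 3, day = c(3, 3),
                     observable = c("alp", "oc"), value = c(10, 10))
  expect_equal(as.numeric(r_squared(sim2, obs2)), mean(c(1, 0.5)))
  # key mismatch is a data error
  sim3 <- sim2; sim3$day <- c(3, 7)
  expect_error(r_squared(sim3, obs2), "keys")
})

test_that("the folded two-level design has orthogonal, balanced main effects", {
  for (k in c(3, 5, 8, 20)) {
    X <- ffd_design(k)
    expect_true(all(X %in% c(-1, 1)))
    expect_equal(colSums(X), rep(0, k))           # balance
    G <- crossprod(X) / nrow(X)
    expect_equal(G, diag(k), tolerance = 1e-12)   # orthogonality
    # fold-over: second half is the mirror of the first
    n <- nrow(X)
    expect_equal(X[(n / 2 + 1):n, ], -X[1:(n / 2), ])
    # resolution IV: main effects clear of two-factor interactions
    if (k <= 8) {
      for (i in 1:(k - 1)) for (j in (i + 1):k)
        expect_equal(sum(X[, i] * X[, j] * X[, 1]), 0)
    }
  }
})

test_that("screening ranks a dominant surrogate parameter first", {
  priors <- data.frame(name = c("A", "B", "C"), lo = 0, hi = 1,
                       dist = "uniform")
  fit <- surrogate_fit(c(A = 3, B = 0.1, C = 0), noise = 0.01)
  eff <- ffd_screen(priors, fit, seed = 5)
  expect_equal(eff$name[which.max(eff$effect)], "A")
  expect_equal(max(eff$effect), 1)  # scaled to the maximum
  # a zero-influence parameter scores (essentially) nothing
  expect_lt(eff$effect[eff$name == "C"], 0.05)
  # main effects from the fractional design match a brute-force full
  # factorial on the same surrogate (no interactions present)
  full <- as.matrix(expand.grid(A = c(0, 1), B = c(0, 1), C = c(0, 1)))
  yfull <- full %*% c(3, 0.1, 0)
  me_full <- vapply(1:3, function(j)
    mean(yfull[full[, j] == 1]) - mean(yfull[full[, j] == 0]), numeric(1))
  X <- ffd_design(3)
  yfrac <- vapply(seq_len(nrow(X)), function(i)
    sum(((X[i, ] + 1) / 2) * c(3, 0.1, 0)), numeric(1))
  me_frac <- vapply(1:3, function(j)
    mean(yfrac[X[, j] == 1]) - mean(yfrac[X[, j] == -1]), numeric(1))
  expect_equal(me_frac, me_full, tolerance = 1e-12)
})

test_that("top-parameter selection is deterministic with lexicographic ties", {
  eff <- data.frame(name = c("b", "a", "c", "d", "e"),
                    effect = c(0.5, 0.5, 1, 0.2, 0.1))
  expect_equal(select_top(eff, 5), c("c", "a", "b", "d", "e"))
  expect_equal(select_top(eff, 3), c("c", "a", "b"))  # tie: a before b
  expect_error(select_top(eff, 6), "pool")
})

test_that("ABC keeps everything when n_keep = n_runs and matches the prior on flat distance", {
  priors <- data.frame(name = "A", lo = 2, hi = 4, dist = "uniform")
  obs <- observed_dataset(data.frame(condition = 1, day = 1,
                                     observable = "x", mean = 1))
  flat <- function(theta, seed) list(r2 = 0.5, min_viability = 100)
  out <- abc_reject(priors, flat, obs, n_runs = 400, n_keep = 400, seed = 9)
  expect_identical(out$samples, out$all_samples)
  # flat distance: posterior is a prior sample
  out2 <- abc_reject(priors, flat, obs, n_runs = 400, n_keep = 100, seed = 9)
  ks <- stats::ks.test(out2$samples$A, "punif", 2, 4)
  expect_gt(ks$p.value, 0.01)
})

test_that("the viability constraint sends violating runs to the worst distance", {
  priors <- data.frame(name = "A", lo = 0, hi = 1, dist = "uniform")
  obs <- observed_dataset(data.frame(condition = 1, day = 1,
                                     observable = "x", mean = 1),
                          min_viability = 50)
  # viability fails whenever A > 0.5, fit otherwise rewards large A
  fit <- function(theta, seed)
    list(r2 = theta[["A"]], min_viability = if (theta[["A"]] > 0.5) 10 else 90)
  out <- abc_reject(priors, fit, obs, n_runs = 200, n_keep = 20, seed = 3)
  expect_true(all(out$samples$A <= 0.5))
  expect_false(out$degenerate)
  # all runs violating: degenerate posterior flagged
  fit_bad <- function(theta, seed) list(r2 = 1, min_viability = 0)
  out2 <- abc_reject(priors, fit_bad, obs, n_runs = 50, n_keep = 5, seed = 3)
  expect_true(out2$degenerate)
})

test_that("narrowing requires a strictly smaller posterior IQR", {
  set.seed(4)
  prior_sample <- runif(500, 0, 1)
  expect_false(narrowing_test(prior_sample, 0, 1)$accept)
  nt <- narrowing_test(rep(0.3, 50), 0, 1)
  expect_true(nt$accept)
  expect_equal(nt$median, 0.3)
  # exactly at the threshold: rejected (strict inequality)
  x <- c(rep(0, 25), rep(0.25, 50), rep(1, 25))  # IQR exactly 0.25
  expect_equal(stats::IQR(x), 0.25)
  expect_false(narrowing_test(x, 0, 1, rho = 0.5)$accept)
})

test_that("the iteration loop fixes identifiable surrogate parameters and terminates", {
  priors <- data.frame(name = c("A", "B", "C"), lo = c(0, 0, 0),
                       hi = c(1, 1, 1), dist = "uniform")
  obs <- observed_dataset(data.frame(condition = 1, day = 1,
                                     observable = "x", mean = 1))
  # fit peaks sharply at A = 0.6; B, C irrelevant
  fit <- function(theta, seed)
    list(r2 = 1 - abs(theta[["A"]] - 0.6), min_viability = 100)
  cal <- calibrate(priors, fit, obs, k_top = 3, n_runs = 300, n_keep = 15,
                   max_iter = 4, seed = 13)
  expect_true("A" %in% names(cal$fixed))
  expect_lt(abs(cal$fixed[["A"]] - 0.6), 0.1)
  expect_true(cal$converged)
  # the loop stopped because some iteration accepted nothing new
  last <- cal$iterations[[length(cal$iterations)]]
  expect_equal(length(last$accepted), 0)
  # zero free parameters: immediate termination
  cal0 <- calibrate(priors[0, ], fit, obs, seed = 1)
  expect_equal(length(cal0$iterations), 0)
  expect_true(cal0$converged)
})

test_that("calibration records are reproducible under the master seed", {
  priors <- data.frame(name = c("A", "B"), lo = 0, hi = 1, dist = "uniform")
  obs <- observed_dataset(data.frame(condition = 1, day = 1,
                                     observable = "x", mean = 1))
  fit <- surrogate_fit(c(A = 1, B = 0.2), noise = 0.05)
  a <- calibrate(priors, fit, obs, k_top = 2, n_runs = 100, n_keep = 10,
                 max_iter = 2, seed = 77)
  b <- calibrate(priors, fit, obs, k_top = 2, n_runs = 100, n_keep = 10,
                 max_iter = 2, seed = 77)
  expect_identical(a$fixed, b$fixed)
  expect_identical(lapply(a$iterations, `[[`, "r2_mean"),
                   lapply(b$iterations, `[[`, "r2_mean"))
})
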