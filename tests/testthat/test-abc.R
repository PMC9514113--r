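test_that("rms score matches its definitional formula", {
  expect_equal(rms_score(c(3, 4, 5), c(3, 4, 5)), 0)
  expect_equal(rms_score(c(10, 0), c(0, 10)), 10)
  withr::with_seed(6, {
    for (i in 1:10) {
      a <- runif(4, 0, 30); b <- runif(4, 0, 30)
      expect_equal(rms_score(a, b), sqrt(mean((a - b)^2)), tolerance = 1e-12)
      expect_equal(rms_score(a, b), rms_score(b, a))
    }
  })
  expect_error(rms_score(1:3, 1:4), "different lengths")
})

test_that("abc configuration validates priors and acceptance rule", {
  expect_error(abc_config(priors = list(a = c(0, 1))), "priors must name")
  pr <- default_abc_priors()
  pr$phi_mean <- c(2, 1)
  expect_error(abc_config(priors = pr), "lo < hi")
  expect_error(abc_config(accept_fraction = 0), "> 0")
})

test_that("a short ABC run is deterministic, respects priors, and improves its score", {
  sc <- synthetic_scenario(n_patients = 8, n_peptides = 3,
                           visit_days = c(0, 7))
  obs <- make_observed_trial(sc)
  cfg <- abc_config(n_samples = 40, n_generations = 3, seed = 17)
  fit1 <- run_abc(obs$observed, obs$design, cfg)
  fit2 <- run_abc(obs$observed, obs$design, cfg)
  expect_identical(fit1$particles, fit2$particles)

  pr <- cfg$priors
  for (nm in names(pr)) {
    expect_true(all(fit1$particles[[nm]] >= pr[[nm]][1]))
    expect_true(all(fit1$particles[[nm]] <= pr[[nm]][2]))
  }
  d <- fit1$diagnostics
  expect_true(all(diff(d$median_score) <= 1e-9))
  # per-generation weights are normalised
  for (g in unique(fit1$particles$generation))
    expect_equal(sum(fit1$particles$weight[fit1$particles$generation == g]), 1)
  # the best particle beats the bulk of the first blind generation
  expect_lte(tail(d$best_score, 1), d$q10_score[1])
})

test_that("observed histogram must match the design size", {
  sc <- synthetic_scenario(n_patients = 8, n_peptides = 3)
  des <- make_trial_design(sc)
  expect_error(run_abc(c(`0` = 1, `1` = 1, `2` = 1, `3+` = 1), des),
               "n_patients")
})

test_that("posterior projections integrate to one and recover simple structure", {
  # uniform-weight Gaussian cloud: grid density integrates to 1 and its
  # covariance is close to the sample covariance
  withr::with_seed(23, {
    n <- 5000
    df <- data.frame(weight = rep(1 / n, n),
                     transit_mean = rnorm(n, 30, 4),
                     spread_mean = rnorm(n, 10, 2))
    proj <- posterior_projections(df, pairs = list(c("transit_mean",
                                                     "spread_mean")))
    den <- proj[["transit_mean:spread_mean"]]
    cell <- diff(den$x[1:2]) * diff(den$y[1:2])
    expect_equal(sum(den$z) * cell, 1, tolerance = 1e-3)
    mx <- rowSums(den$z) * cell / diff(den$x[1:2]) * diff(den$x[1:2])
    mean_x <- sum(den$x * rowSums(den$z)) / sum(den$z)
    var_x <- sum((den$x - mean_x)^2 * rowSums(den$z)) / sum(den$z)
    expect_lt(abs(var_x - var(df$transit_mean)) / var(df$transit_mean), 0.1)
  })
  # degenerate cloud: all mass in one place
  df1 <- data.frame(weight = rep(0.5, 2), transit_mean = c(30, 30),
                    spread_mean = c(10, 10))
  proj1 <- posterior_projections(df1, pairs = list(c("transit_mean",
                                                     "spread_mean")))
  z <- proj1[[1]]$z
  expect_equal(which(z == max(z), arr.ind = TRUE)[1, ],
               c(row = 25, col = 25), tolerance = 2)
  expect_warning(
    posterior_projections(df1[1, ], pairs = list(c("transit_mean",
                                                   "spread_mean"))),
    "single particle")
})
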