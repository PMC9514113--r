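make_design <- function(half_life = c(30, 20, 0.3), n_patients = 4,
                        visit_days = c(0, 7)) {
  trial_design("unit", n_patients, fix_panel(half_life), visit_days)
}

test_that("cohorts are reproducible and degenerate at zero spread", {
  hyper <- population_hyperparams(f_avail = c(0.5, 0), transit_time = c(30, 0),
                                  spread = c(10, 0), phi = c(2e-5, 0))
  design <- make_design()
  coh <- draw_cohort(hyper, design, seed = 5)
  expect_equal(unique(coh$patients$f_avail), 0.5)
  expect_equal(unique(coh$patients$transit_time), 30)
  expect_equal(unique(coh$patients$phi), 2e-5)
  expect_equal(dim(coh$D), c(4, 2))

  hyper2 <- population_hyperparams()
  a <- draw_cohort(hyper2, design, seed = 11)
  b <- draw_cohort(hyper2, design, seed = 11)
  expect_identical(a$patients, b$patients)
  expect_identical(a$D, b$D)
})

test_that("cohort draws respect ranges and converge to the population mean", {
  hyper <- population_hyperparams(f_avail = c(0.6, 0.15))
  design <- trial_design("big", 1e4, fix_panel(30), 0)
  coh <- draw_cohort(hyper, design, seed = 2)
  x <- coh$patients$f_avail
  expect_true(all(x > 0 & x <= 1))
  # truncation at 1 shifts the mean slightly low; stay within 3 SEs of the
  # truncated-normal mean
  z <- (1 - 0.6) / 0.15
  trunc_mean <- 0.6 - 0.15 * dnorm(z) / pnorm(z)
  expect_lt(abs(mean(x) - trunc_mean), 3 * 0.15 / sqrt(1e4))
  # infeasible hyperparameters are rejected with a clear error
  bad <- population_hyperparams(f_avail = c(1e-3, 1e-9))
  bad$f_avail <- c(mean = 8, sd = 1e-9)
  expect_error(draw_cohort(bad, design, seed = 1), "cohort construction")
})

test_that("single-visit response equals the dose probability and doses combine independently", {
  design <- make_design(half_life = 25, visit_days = 0)
  cfg <- model_config(mode = "wellmixed")
  hyper <- population_hyperparams()
  coh <- draw_cohort(hyper, design, seed = 3)
  prof <- simulate_patient(coh$patients[1, ], coh$D[1, ], design, cfg)
  expect_equal(unname(prof$p_response), unname(prof$p_dose[, 1]))
  expect_equal(prof$expected_responses, sum(prof$p_response))

  # independence formula on a synthetic two-dose profile
  p <- 1 - (1 - 0.5) * (1 - 0.5)
  expect_equal(p, 0.75)
  prof2 <- simulate_patient(coh$patients[1, ], c(coh$D[1, 1], coh$D[1, 1]),
                            make_design(half_life = 25), cfg)
  expect_equal(unname(prof2$p_response),
               unname(1 - (1 - prof2$p_dose[, 1]) * (1 - prof2$p_dose[, 2])))
})

test_that("a peptide with half-life far below transit time never evokes a response", {
  design <- make_design(half_life = c(30, 0.2))
  cfg <- model_config(mode = "wellmixed")
  hyper <- population_hyperparams(transit_time = c(30, 2))
  coh <- draw_cohort(hyper, design, seed = 8)
  prof <- simulate_patient(coh$patients[1, ], coh$D[1, ], design, cfg)
  expect_lt(prof$p_response[["P2"]], 1e-8)
})

test_that("Poisson-binomial responder histogram is exact", {
  # hand-checkable cases
  h1 <- responder_histogram(list(structure(list(p_response = c(1, 0, 0)),
                                           class = "response_profile")))
  expect_equal(unname(h1), c(0, 1, 0, 0))
  h2 <- responder_histogram(list(structure(list(p_response = c(0.5, 0.5)),
                                           class = "response_profile")))
  expect_equal(unname(h2), c(0.25, 0.5, 0.25, 0))
  # exhaustive oracle over 2^9 outcomes
  withr::with_seed(13, {
    p <- runif(9)
    expect_equal(poisson_binomial_pmf(p), poisbin_enumerate(p),
                 tolerance = 1e-12)
  })
  # conservation: expected-mode histogram totals the cohort size
  profs <- withr::with_seed(14, lapply(1:7, function(i)
    structure(list(p_response = runif(9)), class = "response_profile")))
  h <- responder_histogram(profs)
  expect_equal(sum(h), 7, tolerance = 1e-6)
  # sampled mode returns integer counts with the same total
  hs <- responder_histogram(profs, mode = "sampled", seed = 4)
  expect_equal(sum(hs), 7)
  expect_true(all(hs == round(hs)))
})

test_that("run_trial is deterministic given a seed and conserves patients", {
  design <- make_design(n_patients = 3)
  hyper <- population_hyperparams()
  cfg <- model_config(mode = "wellmixed")
  a <- run_trial(design, hyper, cfg, n_repeats = 2, seed = 31)
  b <- run_trial(design, hyper, cfg, n_repeats = 2, seed = 31)
  expect_identical(a$histogram, b$histogram)
  expect_identical(a$per_repeat, b$per_repeat)
  expect_equal(unname(rowSums(a$per_repeat)), rep(3, 2), tolerance = 1e-6)
})

test_that("design variants drop peptides and propagate overrides", {
  design <- make_design(half_life = c(30, 25, 20, 0.5, 0.2),
                        n_patients = 3)
  expect_identical(design_variant(design)$design$peptides, design$peptides)
  v <- design_variant(design, drop_peptides = c("P4", "P5"))
  expect_equal(nrow(v$design$peptides), 3)
  expect_error(design_variant(design, drop_peptides = paste0("P", 1:5)),
               "every peptide")
  expect_error(design_variant(design, drop_peptides = "XX"), "unknown")
  # transit override reaches the arrival schedule through the hyperparams
  v2 <- design_variant(design, transit_override = 10)
  hyper <- population_hyperparams()
  h2 <- pepvax:::apply_variant_overrides(hyper, v2)
  expect_equal(unname(h2$transit_time["mean"]), 10)
  sch <- build_arrival_schedule(10, transit_time = h2$transit_time[["mean"]],
                                t_first_departure = 6, p = 5)
  expect_equal(sch$P, 16)
})

test_that("removing competing peptides releases dermal MHC-I for the rest", {
  bp <- binding_params(f_avail = 0.5)
  full <- fix_panel(c(30, 25, 20, 0.5, 0.2))
  reduced <- full[1:3, ]
  class(reduced) <- class(full)
  A_full <- departure_bound_fractions(solve_binding(full, bp, 6), 6)
  A_red <- departure_bound_fractions(solve_binding(reduced, bp, 6), 6)
  expect_true(all(A_red >= A_full[1:3] - 1e-12))
  expect_gt(min(A_red - A_full[1:3]), 0)
})

test_that("trial-level interventions improve responses as expected", {
  # dropping the fastest peptides and shortening transit both increase the
  # mean expected number of responses
  design <- trial_design("intervention", 6,
                         fix_panel(c(30, 25, 20, 0.5, 0.2)), c(0, 7))
  hyper <- population_hyperparams(transit_time = c(30, 3))
  cfg <- model_config(mode = "wellmixed")
  base <- run_trial(design, hyper, cfg, n_repeats = 2, seed = 9)
  dropped <- run_trial(design_variant(design, drop_peptides = c("P4", "P5")),
                       hyper, cfg, n_repeats = 2, seed = 9)
  faster <- run_trial(design_variant(design, transit_override = 10),
                      hyper, cfg, n_repeats = 2, seed = 9)
  expect_gt(dropped$mean_expected_responses, base$mean_expected_responses)
  expect_gt(faster$mean_expected_responses, base$mean_expected_responses)
})
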