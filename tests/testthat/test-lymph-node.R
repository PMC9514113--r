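test_that("per-contact activation probability matches brute-force summation", {
  withr::with_seed(21, {
    for (i in 1:8) {
      N <- sample(5:30, 1)
      T_thresh <- sample(0:N, 1)
      A <- runif(1)
      bio <- biophysical_params(N = N, T_thresh = T_thresh)
      expect_equal(contact_activation_probability(A, bio),
                   binom_tail_bruteforce(N, T_thresh, A), tolerance = 1e-12)
    }
  })
  bio <- biophysical_params(N = 10, T_thresh = 3)
  expect_equal(contact_activation_probability(0.2, bio),
               binom_tail_bruteforce(10, 3, 0.2), tolerance = 1e-12)
  # edge cases
  expect_equal(contact_activation_probability(0, bio), 0)
  expect_equal(contact_activation_probability(1, bio), 1)
})

test_that("binomial sampling stays within 0.1 of the hypergeometric draw", {
  gap <- activation_sampling_gap(biophysical_params(), n_grid = 1001)
  expect_lte(gap$max_gap, 0.1)
  # independent spot checks of the hypergeometric curve
  bio <- biophysical_params()
  for (A in c(0.05, 0.1, 0.5)) {
    K <- round(A * bio$r_tot_count)
    ref <- phyper(bio$T_thresh - 1, K, bio$r_tot_count - K, bio$N,
                  lower.tail = FALSE)
    expect_equal(gap$p_hyper[which.min(abs(gap$A - A))], ref,
                 tolerance = 1e-9)
  }
})

test_that("no antigen or no DCs means no activation", {
  pool <- fix_pool()
  res0 <- simulate_lymph_node(fix_schedule(), 0, 0.03,
                              pool = pool, replicates = 2, seed = 1,
                              horizon = 50)
  expect_true(all(res0$p_any == 0))
  empty <- build_arrival_schedule(0)
  rese <- simulate_lymph_node(empty, 0.3, 0.03, pool = pool,
                              replicates = 2, seed = 1)
  expect_true(all(rese$p_any == 0))
  expect_warning(
    simulate_lymph_node(fix_schedule(), 0.3, 0.03,
                        pool = cognate_pool(1e-9), replicates = 1, seed = 1,
                        horizon = 50),
    "empty")
})

test_that("peptides dissociating far faster than transit cannot activate", {
  # half-life 0.2 h against a 30 h transit: essentially all antigen is gone
  res <- simulate_lymph_node(fix_schedule(D = 800, transit = 30), 0.3,
                             log(2) / 0.2, pool = fix_pool(5e-5),
                             replicates = 5, seed = 2, horizon = 50)
  expect_lt(tail(res$p_any, 1), 1e-6)
})

test_that("identical seeds give bit-identical results and probabilities are monotone in t", {
  sch <- fix_schedule(D = 150)
  a <- simulate_lymph_node(sch, 0.25, 0.02, pool = fix_pool(),
                           replicates = 3, seed = 77, horizon = 60)
  b <- simulate_lymph_node(sch, 0.25, 0.02, pool = fix_pool(),
                           replicates = 3, seed = 77, horizon = 60)
  expect_identical(a$p_any, b$p_any)
  expect_identical(a$p_per_cell, b$p_per_cell)
  expect_identical(a$n_contacts, b$n_contacts)
  c_ <- simulate_lymph_node(sch, 0.25, 0.02, pool = fix_pool(),
                            replicates = 3, seed = 78, horizon = 60)
  expect_false(identical(a$p_any, c_$p_any))
  # non-decreasing probabilities; p_any >= p_per_cell
  expect_true(all(diff(a$p_any) >= -1e-12))
  expect_true(all(diff(a$p_per_cell) >= -1e-12))
  expect_true(all(a$p_any >= a$p_per_cell - 1e-12))
})

test_that("sweeping k_off over four decades gives a monotone sigmoid with a low-off-rate plateau", {
  sch <- fix_schedule(D = 400, transit = 30)
  pool <- fix_pool(3e-5)
  koffs <- 10^seq(-3, 1, length.out = 6)
  p <- vapply(koffs, function(k)
    response_probability_for_dose(sch, 0.3, k, pool = pool,
                                  mode = "wellmixed"), numeric(1))
  expect_true(all(diff(p) <= 1e-9))          # non-increasing in k_off
  expect_lt(tail(p, 1), 1e-4)               # fast off-rates: no activation
  # plateau: a further 10x reduction below the smallest k_off changes little
  p_lower <- response_probability_for_dose(sch, 0.3, koffs[1] / 10,
                                           pool = pool, mode = "wellmixed")
  expect_lt(abs(p_lower - p[1]) / p[1], 0.05)
})

test_that("well-mixed surrogate tracks the ABM away from saturation", {
  # moderate antigen, short horizon: surrogate and ABM should agree closely
  sch <- build_arrival_schedule(200, transit_time = 0, t_first_departure = 0,
                                p = 0, dc_lifetime = 48)
  pool <- fix_pool(2e-5)
  bio <- biophysical_params()
  abm <- simulate_lymph_node(sch, 0.12, 0.05, bio, pool, horizon = 12,
                             replicates = 40, seed = 5)
  wm <- wellmixed_activation(sch, 0.12, 0.05, bio, pool, horizon = 12)
  i <- length(abm$times)
  expect_lt(abs(abm$p_per_cell[i] - wm$p_per_cell[i]) /
              max(wm$p_per_cell[i], 1e-12), 0.25)
})
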