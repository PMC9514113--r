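test_that("with no dissociation and no clearance all receptors end up bound", {
  pan <- peptide_panel("P1", "SVASTITGV", k_off = 0)
  bp <- binding_params(k_clear = 0, f_avail = 0.7)
  traj <- solve_binding(pan, bp, horizon = 2)
  r_avail <- bp$f_avail * bp$r_tot
  expect_equal(tail(traj$bound_complex[, 1], 1), r_avail, tolerance = 1e-6)
  expect_equal(tail(traj$A[, 1], 1), 1, tolerance = 1e-6)
})

test_that("identical peptides share identical bound-fraction curves", {
  pan <- fix_panel(rep(8, 4))
  traj <- solve_binding(pan, binding_params(), horizon = 12)
  for (i in 2:4)
    expect_equal(traj$A[, i], traj$A[, 1], tolerance = 1e-9)
})

test_that("with k_on = 0 and fast clearance the complex decays purely exponentially", {
  pan <- fix_panel(5)
  bp <- binding_params(k_on = 0, k_clear = 1e4)
  c0 <- 0.4 * bp$f_avail * bp$r_tot
  traj <- solve_binding(pan, bp, horizon = 10, l0 = 0, c0 = c0)
  expected <- c0 * exp(-pan$k_off * traj$times)
  expect_equal(traj$bound_complex[, 1], expected, tolerance = 1e-6)
})

test_that("adaptive solution matches a fixed-step RK4 reference", {
  # two peptides with off-rates differing 100-fold, default params
  pan <- fix_panel(c(20, 0.2))
  bp <- binding_params()
  traj <- solve_binding(pan, bp, horizon = 24)
  A24 <- departure_bound_fractions(traj, 24)
  ref <- rk4_binding(pan$k_off, bp$k_on, bp$k_clear,
                     bp$f_avail * bp$r_tot, bp$l0, t_end = 24, dt = 1e-3)
  expect_lt(max(abs(A24 - ref$A)), 1e-5)

  # oracle equivalence across random parameter draws
  withr::with_seed(11, {
    for (i in 1:5) {
      ko <- 10^runif(2, -2, 1)
      bp2 <- binding_params(k_on = runif(1, 0.5, 2),
                            k_clear = runif(1, 5, 40),
                            f_avail = runif(1, 0.2, 1))
      pan2 <- fix_panel(log(2) / ko)
      tr <- solve_binding(pan2, bp2, horizon = 6)
      Ai <- departure_bound_fractions(tr, 6)
      rf <- rk4_binding(ko, bp2$k_on, bp2$k_clear,
                        bp2$f_avail * bp2$r_tot, bp2$l0, 6, dt = 1e-3)
      expect_lt(max(abs(Ai - rf$A)), 1e-5)
    }
  })
})

test_that("receptors are conserved along every trajectory", {
  withr::with_seed(4, {
    for (i in 1:4) {
      n <- sample(1:9, 1)
      pan <- fix_panel(10^runif(n, -1, 2))
      bp <- binding_params(f_avail = runif(1, 0.1, 1))
      traj <- solve_binding(pan, bp, horizon = 48)
      r_avail <- bp$f_avail * bp$r_tot
      cons <- traj$free_receptor + rowSums(traj$bound_complex)
      expect_lt(max(abs(cons - r_avail)) / r_avail, 1e-6)
      expect_true(all(rowSums(traj$A) <= 1 + 1e-9))
    }
  })
})

test_that("under fast clearance bound fractions decay exponentially after 1 h", {
  pan <- fix_panel(c(15, 1.5))
  bp <- binding_params(k_clear = 1e3)
  traj <- solve_binding(pan, bp, horizon = 24)
  idx <- which(traj$times > 1)
  t1 <- traj$times[idx[1]]
  for (i in 1:2) {
    A1 <- traj$A[idx[1], i]
    pred <- A1 * exp(-pan$k_off[i] * (traj$times[idx] - t1))
    expect_lt(max(abs(traj$A[idx, i] - pred) / pred), 1e-3)
  }
})

test_that("adding a competitor never increases another peptide's bound fraction", {
  base <- fix_panel(c(25, 3))
  bigger <- fix_panel(c(25, 3, 40, 0.5))
  bp <- binding_params(f_avail = 0.6)
  tr_base <- solve_binding(base, bp, horizon = 24)
  tr_big <- solve_binding(bigger, bp, horizon = 24)
  for (tq in c(0.5, 2, 6, 12, 24)) {
    A_b <- departure_bound_fractions(tr_base, tq)
    A_g <- departure_bound_fractions(tr_big, tq)
    expect_true(all(A_g[1:2] <= A_b[1:2] + 1e-9))
  }
})

test_that("departure extraction interpolates the stored grid", {
  pan <- fix_panel(c(20, 0.1))
  traj <- solve_binding(pan, binding_params(), horizon = 12)
  # grid endpoint is exact
  expect_equal(unname(departure_bound_fractions(traj, traj$times[1])),
               unname(traj$A[1, ]))
  # midpoint of two grid times is the mean of the neighbouring values
  k <- 150
  tm <- (traj$times[k] + traj$times[k + 1]) / 2
  expect_equal(unname(departure_bound_fractions(traj, tm)),
               unname((traj$A[k, ] + traj$A[k + 1, ]) / 2), tolerance = 1e-12)
  # out-of-range departure
  expect_error(departure_bound_fractions(traj, 13), "outside")
  # a fast-off-rate peptide carries negligible antigen at departure
  expect_lt(departure_bound_fractions(traj, 6)[["P2"]], 1e-3)
})
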