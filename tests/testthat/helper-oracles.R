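# Independent reference implementations used as oracles.  These deliberately
# share no code with the package: fixed-step RK4 instead of lsoda, direct
# summation instead of pbinom, exhaustive enumeration instead of the DP
# convolution, and a plain-R random-walk collision counter instead of the
# compiled agent-based model.

# Fixed-step RK4 integration of the dermal competition ODEs.
rk4_binding <- function(k_off, k_on, k_clear, r_avail, l0, t_end, dt = 1e-3) {
  n <- length(k_off)
  y <- c(l = rep(l0, length.out = n), c = rep(0, n))
  deriv <- function(y) {
    l <- y[1:n]; cc <- y[n + 1:n]
    r <- r_avail - sum(cc)
    bind <- k_on * r * l
    unbind <- k_off * cc
    c(unbind - bind - k_clear * l, bind - unbind)
  }
  n_steps <- round(t_end / dt)
  for (s in seq_len(n_steps)) {
    k1 <- deriv(y)
    k2 <- deriv(y + dt / 2 * k1)
    k3 <- deriv(y + dt / 2 * k2)
    k4 <- deriv(y + dt * k3)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  list(l = y[1:n], c = y[n + 1:n], A = y[n + 1:n] / r_avail)
}

# P(X >= T), X ~ Binomial(N, p), by direct summation of the mass function.
binom_tail_bruteforce <- function(N, T_thresh, p) {
  if (T_thresh <= 0) return(1)
  sum(vapply(T_thresh:N, function(k) choose(N, k) * p^k * (1 - p)^(N - k),
             numeric(1)))
}

# Poisson-binomial pmf by exhaustive enumeration over all 2^n outcomes.
poisbin_enumerate <- function(p) {
  n <- length(p)
  pmf <- numeric(n + 1)
  for (mask in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(mask)[1:n])
    pr <- prod(ifelse(bits == 1, p, 1 - p))
    pmf[sum(bits) + 1] <- pmf[sum(bits) + 1] + pr
  }
  pmf
}

# Monte-Carlo estimate of the per-DC encounter rate (contacts initiated per
# T-cell per DC per hour) for run-and-tumble motion among stationary DCs in a
# reflective sphere, with the same can't-re-contact-until-separated rule as
# the model.  Plain R, vectorised over DCs.
mc_encounter_rate <- function(R = 500, v = 10, F_um = 25, b = 10,
                              n_dc = 1000, n_cells = 20, t_hours = 4,
                              reps = 10, dt_min = 0.25, seed = 1) {
  withr::with_seed(seed, {
    total_contacts <- 0
    for (rep in seq_len(reps)) {
      dc <- matrix(runif(n_dc * 3, -R, R), n_dc, 3)
      bad <- rowSums(dc^2) > R^2
      while (any(bad)) {
        dc[bad, ] <- matrix(runif(sum(bad) * 3, -R, R), sum(bad), 3)
        bad <- rowSums(dc^2) > R^2
      }
      for (cell in seq_len(n_cells)) {
        pos <- runif(3, -R, R)
        while (sum(pos^2) > R^2) pos <- runif(3, -R, R)
        u <- rnorm(3); dir <- u / sqrt(sum(u^2))
        run <- rexp(1, 1 / F_um)
        engaged <- rep(FALSE, n_dc)
        n_steps <- round(t_hours * 60 / dt_min)
        for (s in seq_len(n_steps)) {
          remain <- v * dt_min
          while (remain > 0) {
            seg <- min(remain, run)
            pos <- pos + seg * dir
            r <- sqrt(sum(pos^2))
            if (r > R) {
              pos <- pos * (2 * R - r) / r
              rad <- pos / sqrt(sum(pos^2))
              dir <- dir - 2 * sum(dir * rad) * rad
            }
            run <- run - seg
            remain <- remain - seg
            if (run <= 0) {
              u <- rnorm(3); dir <- u / sqrt(sum(u^2))
              run <- rexp(1, 1 / F_um)
            }
          }
          d2 <- colSums((t(dc) - pos)^2)
          inside <- d2 <= b^2
          total_contacts <- total_contacts + sum(inside & !engaged)
          engaged <- inside
        }
      }
    }
    total_contacts / (reps * n_cells * n_dc * t_hours)
  })
}
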