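#' Root-mean-square score between responder histograms
#'
#' `sqrt(mean((simulated - observed)^2))` over the shared response-count
#' bins; the distance that ABC minimises.
#'
#' @param simulated,observed numeric histograms over identical bins.
#' @return a non-negative, symmetric score.
#' @export
rms_score <- function(simulated, observed) {
  if (length(simulated) != length(observed))
    stopf("histograms have different lengths (%d vs %d)",
          length(simulated), length(observed))
  sqrt(mean((as.numeric(simulated) - as.numeric(observed))^2))
}

ABC_PARAM_NAMES <- c("f_avail_mean", "f_avail_sd",
                     "transit_mean", "transit_sd",
                     "spread_mean", "spread_sd",
                     "phi_mean", "phi_sd")

#' ABC configuration
#'
#' Population-Monte-Carlo-style ABC over the 8 population hyperparameters
#' (mean and sd of `f_avail`, `transit_time`, `spread`, `phi`).  Generation 1
#' samples uniformly from the prior box; later generations resample accepted
#' particles and perturb them with a component-wise Gaussian kernel of width
#' `kernel_factor` times the weighted particle standard deviation, reflected
#' at the prior bounds.  Each generation keeps the fraction of particles with
#' the lowest root-mean-square histogram distance.
#'
#' @param priors named list of `c(lo, hi)` prior ranges for each of
#'   `f_avail_mean`, `f_avail_sd`, `transit_mean`, `transit_sd`,
#'   `spread_mean`, `spread_sd`, `phi_mean`, `phi_sd`.
#' @param n_samples particles per generation (the full-scale fit uses 10000;
#'   scale down for quick runs).
#' @param n_generations maximum generations (full-scale: 25).
#' @param accept_fraction fraction of lowest-scoring particles kept per
#'   generation.
#' @param kernel_factor perturbation width in units of the weighted particle
#'   sd.
#' @param mode forward-model mode inside the loop: `"wellmixed"` (default,
#'   fast surrogate) or `"abm"`.
#' @param ln_replicates ABM replicates per dose when `mode = "abm"`.
#' @param n_trial_repeats simulated-trial repeats per particle (1 by default
#'   inside ABC; repeat noise is absorbed by the acceptance tolerance).
#' @param converge_tol early stop when the median accepted score improves by
#'   less than this relative amount over two consecutive generations.
#' @param seed integer seed for the whole run.
#' @return an `abc_config` list.
#' @export
abc_config <- function(priors = default_abc_priors(),
                       n_samples = 10000, n_generations = 25,
                       accept_fraction = 0.1, kernel_factor = 2,
                       mode = c("wellmixed", "abm"), ln_replicates = 10,
                       n_trial_repeats = 1, converge_tol = 0.01,
                       seed = NULL) {
  mode <- match.arg(mode)
  if (!all(ABC_PARAM_NAMES %in% names(priors)))
    stopf("priors must name all of: %s", paste(ABC_PARAM_NAMES, collapse = ", "))
  for (nm in ABC_PARAM_NAMES) {
    pr <- priors[[nm]]
    if (length(pr) != 2 || pr[1] >= pr[2])
      stopf("prior for %s must be c(lo, hi) with lo < hi", nm)
  }
  check_number(accept_fraction, "accept_fraction", 0, 1, strict_lower = TRUE)
  if (accept_fraction >= 1) stopf("accept_fraction must be < 1")
  check_number(n_generations, "n_generations", 1)
  structure(list(priors = priors[ABC_PARAM_NAMES],
                 n_samples = as.integer(n_samples),
                 n_generations = as.integer(n_generations),
                 accept_fraction = accept_fraction,
                 kernel_factor = kernel_factor, mode = mode,
                 ln_replicates = as.integer(ln_replicates),
                 n_trial_repeats = as.integer(n_trial_repeats),
                 converge_tol = converge_tol, seed = seed),
            class = "abc_config")
}

#' @rdname abc_config
#' @export
default_abc_priors <- function() {
  list(f_avail_mean = c(0.05, 1), f_avail_sd = c(0.01, 0.3),
       transit_mean = c(5, 60), transit_sd = c(0.5, 15),
       spread_mean = c(1, 30), spread_sd = c(0.5, 8),
       phi_mean = c(2e-6, 8e-5), phi_sd = c(2e-7, 2e-5))
}

particle_to_hyper <- function(theta, migration) {
  population_hyperparams(f_avail = c(theta[["f_avail_mean"]],
                                     theta[["f_avail_sd"]]),
                         transit_time = c(theta[["transit_mean"]],
                                          theta[["transit_sd"]]),
                         spread = c(theta[["spread_mean"]],
                                    theta[["spread_sd"]]),
                         phi = c(theta[["phi_mean"]], theta[["phi_sd"]]),
                         migration = migration)
}

reflect_into <- function(x, lo, hi) {
  width <- hi - lo
  for (i in seq_len(100)) {
    if (x >= lo && x <= hi) return(x)
    if (x < lo) x <- 2 * lo - x
    if (x > hi) x <- 2 * hi - x
  }
  min(max(x, lo), hi)  # pathological width; clamp
}

#' Fit population hyperparameters by Approximate Bayesian Computation
#'
#' Iteratively samples population hyperparameters, simulates one trial per
#' particle with the forward model, scores each simulated responder histogram
#' against the observed one by [rms_score()], keeps the best fraction, and
#' refines the proposal around the accepted particles until the score stops
#' improving or `n_generations` is reached.  Particles whose forward
#' simulation fails are discarded (with the reason logged in the
#' diagnostics); more than 50% failures in a generation aborts the run.
#'
#' @param observed named responder histogram (counts over 0, 1, ...,
#'   `max_bin`+ bins) whose total equals `design$n_patients`.
#' @param design a [trial_design()].
#' @param cfg an [abc_config()].
#' @param config a [model_config()] for the fixed submodel settings; its
#'   `mode`/`ln_replicates` are overridden by `cfg`.
#' @param migration fixed [migration_model()] used for every particle.
#' @param progress print a line per generation.
#' @return an `abc_fit`: list with `particles` (data frame: generation,
#'   weight, score and the 8 hyperparameters, accepted particles only),
#'   `final` (last generation), `diagnostics` (per-generation score
#'   quantiles, acceptance and failure counts, effective sample size),
#'   `converged`, and the `cfg` echo.
#' @export
run_abc <- function(observed, design, cfg = abc_config(),
                    config = model_config(), migration = migration_model(),
                    progress = FALSE) {
  stopifnot(inherits(design, "trial_design"), inherits(cfg, "abc_config"))
  if (abs(sum(observed) - design$n_patients) > 1e-6)
    stopf("observed histogram total (%g) != n_patients (%d)",
          sum(observed), design$n_patients)
  if (length(observed) != design$max_bin + 1)
    stopf("observed histogram must have %d bins", design$max_bin + 1)
  config$mode <- cfg$mode
  config$ln_replicates <- cfg$ln_replicates

  lo <- vapply(cfg$priors, `[`, numeric(1), 1)
  hi <- vapply(cfg$priors, `[`, numeric(1), 2)
  n_par <- length(ABC_PARAM_NAMES)
  n_keep <- max(1L, as.integer(ceiling(cfg$accept_fraction * cfg$n_samples)))

  gen_seeds <- derive_seeds(cfg$seed, cfg$n_generations)
  all_accepted <- list()
  diagnostics <- list()
  prev <- NULL        # accepted particle matrix of the previous generation
  prev_w <- NULL
  med_history <- numeric(0)
  converged <- FALSE

  for (g in seq_len(cfg$n_generations)) {
    seeds <- derive_seeds(gen_seeds[g], 2L * cfg$n_samples)
    theta <- matrix(NA_real_, cfg$n_samples, n_par,
                    dimnames = list(NULL, ABC_PARAM_NAMES))
    if (is.null(prev)) {
      theta[] <- with_seed(gen_seeds[g],
                           vapply(seq_len(n_par), function(j)
                             runif(cfg$n_samples, lo[j], hi[j]),
                             numeric(cfg$n_samples)))
    } else {
      wsd <- vapply(seq_len(n_par), function(j) {
        m <- weighted.mean(prev[, j], prev_w)
        sqrt(weighted.mean((prev[, j] - m)^2, prev_w))
      }, numeric(1))
      width <- pmax(cfg$kernel_factor * wsd, 1e-12 * (hi - lo))
      theta[] <- with_seed(gen_seeds[g], {
        idx <- sample.int(nrow(prev), cfg$n_samples, replace = TRUE,
                          prob = prev_w)
        base <- prev[idx, , drop = FALSE]
        pert <- base + matrix(rnorm(cfg$n_samples * n_par), ncol = n_par) *
          rep(width, each = cfg$n_samples)
        for (j in seq_len(n_par))
          pert[, j] <- vapply(pert[, j], reflect_into, numeric(1),
                              lo[j], hi[j])
        pert
      })
    }

    scores <- rep(NA_real_, cfg$n_samples)
    failures <- character(0)
    for (k in seq_len(cfg$n_samples)) {
      scores[k] <- tryCatch({
        hyper <- particle_to_hyper(as.list(theta[k, ]), migration)
        # Warnings (e.g. empty cognate pools at low phi) are expected over a
        # wide prior and are not per-particle diagnostics.
        tr <- suppressWarnings(
          run_trial(design, hyper, config,
                    n_repeats = cfg$n_trial_repeats, seed = seeds[k]))
        rms_score(tr$histogram, observed)
      }, error = function(e) {
        failures <<- c(failures, conditionMessage(e))
        NA_real_
      })
    }
    if (length(failures) > cfg$n_samples / 2)
      stopf("ABC generation %d: %d/%d particle simulations failed (first: %s)",
            g, length(failures), cfg$n_samples, failures[1])
    ok <- which(!is.na(scores))
    keep <- ok[order(scores[ok])][seq_len(min(n_keep, length(ok)))]
    prev <- theta[keep, , drop = FALSE]
    prev_w <- rep(1 / length(keep), length(keep))
    acc <- data.frame(generation = g, weight = prev_w, score = scores[keep])
    acc <- cbind(acc, as.data.frame(prev))
    all_accepted[[g]] <- acc
    med <- stats::median(scores[keep])
    diagnostics[[g]] <- data.frame(
      generation = g,
      median_score = med,
      q10_score = unname(quantile(scores[ok], 0.1)),
      best_score = min(scores[keep]),
      n_accepted = length(keep),
      n_failed = length(failures),
      ess = 1 / sum(prev_w^2))
    if (progress)
      message(sprintf("ABC generation %d: median accepted score %.4g", g, med))
    med_history <- c(med_history, med)
    ng <- length(med_history)
    if (ng >= 3) {
      impr <- (med_history[ng - 2] - med_history[ng]) /
        max(med_history[ng - 2], .Machine$double.eps)
      if (impr < cfg$converge_tol) { converged <- TRUE; break }
    }
  }

  particles <- do.call(rbind, all_accepted)
  structure(list(particles = particles,
                 final = all_accepted[[length(all_accepted)]],
                 diagnostics = do.call(rbind, diagnostics),
                 converged = converged,
                 cfg = cfg),
            class = "abc_fit")
}

#' Weighted 2D posterior density projections
#'
#' Weighted Gaussian kernel density of the particle cloud on a regular grid,
#' for each requested hyperparameter pair, normalised so the density
#' integrates to 1 over the grid.  Bandwidths follow the normal reference
#' rule per dimension (`sd * n_eff^(-1/6)`).
#'
#' @param samples an `abc_fit` or a data frame with `weight` and
#'   hyperparameter columns.
#' @param pairs list of character 2-vectors naming hyperparameter pairs;
#'   default all consecutive mean pairs.
#' @param n_grid grid resolution per axis.
#' @return named list of lists with `x`, `y`, `z` (density matrix) per pair.
#' @export
posterior_projections <- function(samples, pairs = NULL, n_grid = 50) {
  df <- if (inherits(samples, "abc_fit")) samples$final else samples
  if (is.null(df) || nrow(df) == 0) stopf("no posterior samples")
  if (nrow(df) == 1)
    warning("single particle: degenerate density")
  w <- if ("weight" %in% names(df)) df$weight else rep(1, nrow(df))
  w <- w / sum(w)
  if (is.null(pairs)) {
    means <- grep("_mean$", ABC_PARAM_NAMES, value = TRUE)
    pairs <- lapply(seq_len(length(means) - 1),
                    function(i) means[c(i, i + 1)])
  }
  out <- list()
  for (pr in pairs) {
    x <- df[[pr[1]]]; y <- df[[pr[2]]]
    if (is.null(x) || is.null(y))
      stopf("unknown hyperparameter pair: %s", paste(pr, collapse = ", "))
    out[[paste(pr, collapse = ":")]] <- weighted_kde2d(x, y, w, n_grid)
  }
  out
}

weighted_kde2d <- function(x, y, w, n_grid) {
  n_eff <- 1 / sum(w^2)
  bw <- function(v) {
    s <- sqrt(max(weighted.mean((v - weighted.mean(v, w))^2, w), 0))
    if (s == 0) s <- max(abs(v), 1) * 1e-6   # degenerate cloud
    s * n_eff^(-1 / 6)
  }
  hx <- bw(x); hy <- bw(y)
  gx <- seq(min(x) - 3 * hx, max(x) + 3 * hx, length.out = n_grid)
  gy <- seq(min(y) - 3 * hy, max(y) + 3 * hy, length.out = n_grid)
  z <- matrix(0, n_grid, n_grid)
  for (k in seq_along(x)) {
    z <- z + w[k] * outer(stats::dnorm(gx, x[k], hx),
                          stats::dnorm(gy, y[k], hy))
  }
  # Renormalise on the grid (guards quadrature truncation at the edges).
  cell <- (gx[2] - gx[1]) * (gy[2] - gy[1])
  z <- z / (sum(z) * cell)
  list(x = gx, y = gy, z = z)
}

#' @export
print.abc_fit <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf("<abc_fit> %d generation(s), %s\n", nrow(d),
              if (x$converged) "converged" else "max generations reached"))
  cat(sprintf("final median accepted score: %.4g (best %.4g, ESS %.0f)\n",
              tail(d$median_score, 1), tail(d$best_score, 1), tail(d$ess, 1)))
  invisible(x)
}
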