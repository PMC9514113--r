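#' Lymph-node biophysical parameters
#'
#' Geometry and kinetics of the T-cell / dendritic-cell encounter process in
#' the paracortex, modelled as a sphere of radius `R`.  Defaults follow the
#' two-photon literature conventions: T-cells run-and-tumble at `v` = 10
#' µm/min with mean free path `F` = 25 µm; DCs are stationary (`w` = 0);
#' contacts occur within `b` = 10 µm; a contact samples `N` = 100 MHC-I from
#' the DC's 1e5 and activates when at least `T` = 10 of them carry cognate
#' peptide.  Every value is configurable and none is treated as a measured
#' quantity.
#'
#' @param b contact radius, µm.
#' @param F_um T-cell mean free path, µm.
#' @param F_dc DC mean free path, µm (used only when `w > 0`).
#' @param N number of MHC-I in the T-cell–DC contact region.
#' @param R paracortex radius, µm.
#' @param T_thresh activation threshold: minimum cognate pMHC-I in a contact.
#' @param v T-cell speed, µm/min.
#' @param w DC speed, µm/min (0 = stationary).
#' @param r_tot_count MHC-I receptors per DC.
#' @return a `biophysical_params` list.
#' @export
biophysical_params <- function(b = 10, F_um = 25, F_dc = 25, N = 100,
                               R = 500, T_thresh = 10, v = 10, w = 0,
                               r_tot_count = 1e5) {
  check_number(b, "b", 0, strict_lower = TRUE)
  check_number(F_um, "F_um", 0, strict_lower = TRUE)
  check_number(F_dc, "F_dc", 0, strict_lower = TRUE)
  check_number(N, "N", 1)
  check_number(R, "R", b, strict_lower = TRUE)
  check_number(T_thresh, "T_thresh", 0)
  check_number(v, "v", 0, strict_lower = TRUE)
  check_number(w, "w", 0)
  check_number(r_tot_count, "r_tot_count", N)
  if (T_thresh > N) stopf("activation threshold T exceeds contact sample N")
  structure(list(b = b, F_um = F_um, F_dc = F_dc, N = as.integer(N), R = R,
                 T_thresh = as.integer(T_thresh), v = v, w = w,
                 r_tot_count = as.integer(r_tot_count)),
            class = "biophysical_params")
}

#' Cognate T-cell pool
#'
#' The number of simulated cognate T-cells is `phi * rho * V` with `V` the
#' paracortex volume: only the product of precursor frequency and T-cell
#' density matters, so `rho` is held fixed and `phi` is the patient-level
#' parameter.
#'
#' @param phi precursor frequency, in (0, 1).
#' @param rho T-cell density in the paracortex, cells/µm³ (default 1e-3,
#'   about one T-cell per 10 µm cube).
#' @param bio a [biophysical_params()] supplying the paracortex radius.
#' @return a `cognate_pool` list with `phi`, `rho`, `n_cells`.
#' @export
cognate_pool <- function(phi, rho = 1e-3, bio = biophysical_params()) {
  check_number(phi, "phi", 0, 1, strict_lower = TRUE)
  if (phi >= 1) stopf("phi must be < 1")
  check_number(rho, "rho", 0, strict_lower = TRUE)
  vol <- 4 / 3 * pi * bio$R^3
  structure(list(phi = phi, rho = rho,
                 n_cells = max(0L, as.integer(round(phi * rho * vol)))),
            class = "cognate_pool")
}

#' Per-contact T-cell activation probability
#'
#' A contact samples `N` MHC-I (with replacement) from the DC surface where a
#' fraction `A` is cognate, and activates when at least `T_thresh` are
#' cognate: `P(X >= T)` with `X ~ Binomial(N, A)`.  Sampling with replacement
#' stands in for the hypergeometric draw from the DC's full receptor
#' complement; see [activation_sampling_gap()] for the size of that
#' approximation.
#'
#' @param A cognate bound fraction on the DC surface, in \[0, 1\] (vectorised).
#' @param bio a [biophysical_params()].
#' @return activation probability (same length as `A`).
#' @export
contact_activation_probability <- function(A, bio = biophysical_params()) {
  stopifnot(all(A >= 0 & A <= 1))
  if (bio$T_thresh == 0) return(rep(1, length(A)))
  pbinom(bio$T_thresh - 1, bio$N, A, lower.tail = FALSE)
}

#' Binomial-vs-hypergeometric activation-probability gap
#'
#' Maximum absolute difference, over a dense grid of cognate antigen ratios,
#' between the binomial activation probability (sampling `N` contact-region
#' MHC-I with replacement) and the exact hypergeometric one (sampling `N`
#' without replacement from the DC's `r_tot_count` receptors of which
#' `round(A * r_tot_count)` are cognate).  Quantifies the sampling-with-
#' replacement assumption.
#'
#' @param bio a [biophysical_params()].
#' @param n_grid number of evenly spaced grid points on \[0, 1\].
#' @return list with `max_gap`, the grid `A`, and both probability curves.
#' @export
activation_sampling_gap <- function(bio = biophysical_params(), n_grid = 1001) {
  A <- seq(0, 1, length.out = n_grid)
  p_binom <- contact_activation_probability(A, bio)
  K <- round(A * bio$r_tot_count)
  p_hyper <- if (bio$T_thresh == 0) rep(1, length(A)) else
    phyper(bio$T_thresh - 1, m = K, n = bio$r_tot_count - K, k = bio$N,
           lower.tail = FALSE)
  list(max_gap = max(abs(p_binom - p_hyper)), A = A,
       p_binom = p_binom, p_hyper = p_hyper)
}

as_activation_result <- function(times, p_per_cell, p_any, n_contacts,
                                 replicates, mode) {
  structure(list(times = times, p_per_cell = p_per_cell, p_any = p_any,
                 n_contacts = n_contacts, replicates = replicates,
                 mode = mode),
            class = "activation_result")
}

#' Agent-based lymph-node activation simulation
#'
#' Simulates cognate T-cells performing a run-and-tumble (or Levy) walk at
#' speed `v` inside a reflective sphere of radius `R` while DCs arrive per
#' `schedule`, sit (by default) at uniform random positions, and stay active
#' for `dc_lifetime`.  A contact (centre separation <= `b`) at time t succeeds
#' with [contact_activation_probability()] evaluated at
#' [antigen_at_time()]`(A_depart, k_off, t - departure)`, where each DC's
#' departure is its arrival minus the lymphatic transit time.  Because surface
#' antigen is monotone decreasing, a T-cell that fails a contact keeps
#' searching and its activation probability accumulates as
#' `1 - prod(1 - q_i)` over its contacts — the model output is the maximum
#' probability of activation.  The simulation time step is
#' `min(F, b) / v / 4` minutes so cells cannot tunnel through contact shells.
#'
#' @param schedule an [build_arrival_schedule()] result.
#' @param A_depart cognate bound fraction on departing DCs, in \[0, 1\].
#' @param k_off peptide–MHC-I off-rate, 1/hour.
#' @param bio a [biophysical_params()].
#' @param pool a [cognate_pool()].
#' @param horizon simulation end time, hours; default last arrival +
#'   DC lifetime.
#' @param replicates number of independent ABM replicates averaged.
#' @param seed integer seed (bit-identical results for equal seeds).
#' @param out_times time grid (hours) at which probabilities are recorded;
#'   default hourly plus the horizon.
#' @param motility `"rt"` (run-and-tumble) or `"levy"` (Pareto run lengths,
#'   shape 2, same mean free path).
#' @return an `activation_result`: `times`, non-decreasing `p_per_cell(t)`
#'   (probability a given cognate T-cell has had an activating interaction)
#'   and `p_any(t)` (at least one cell activated), `n_contacts`, `replicates`.
#' @export
simulate_lymph_node <- function(schedule, A_depart, k_off,
                                bio = biophysical_params(),
                                pool, horizon = NULL, replicates = 10,
                                seed = NULL, out_times = NULL,
                                motility = c("rt", "levy")) {
  stopifnot(inherits(schedule, "arrival_schedule"),
            inherits(bio, "biophysical_params"),
            inherits(pool, "cognate_pool"))
  motility <- match.arg(motility)
  check_number(A_depart, "A_depart", 0, 1)
  check_number(k_off, "k_off", 0)
  if (replicates < 1) stopf("replicates must be >= 1")
  if (is.null(horizon)) {
    horizon <- if (schedule$D == 0) schedule$dc_lifetime else
      max(schedule$arrival_times) + schedule$dc_lifetime
  }
  if (schedule$D > 0 && horizon < max(schedule$arrival_times))
    stopf("horizon does not cover the arrival schedule")
  if (is.null(out_times))
    out_times <- unique(c(seq(0, horizon, by = 1), horizon))
  if (pool$n_cells == 0) {
    warning("cognate T-cell pool is empty; activation probability is 0")
    return(as_activation_result(out_times, rep(0, length(out_times)),
                                rep(0, length(out_times)), 0, replicates,
                                "abm"))
  }
  if (schedule$D == 0 || A_depart == 0) {
    return(as_activation_result(out_times, rep(0, length(out_times)),
                                rep(0, length(out_times)), 0, replicates,
                                "abm"))
  }
  dt_min <- min(bio$F_um, bio$b) / bio$v / 4
  if (is.null(seed)) seed <- with_seed(NULL, sample.int(1e9, 1))
  res <- .ln_abm_cpp(schedule$arrival_times, schedule$transit_time,
                     schedule$dc_lifetime, A_depart, k_off,
                     bio$R, bio$v, bio$F_um, bio$b, bio$N, bio$T_thresh,
                     bio$w, bio$F_dc, pool$n_cells, horizon,
                     as.integer(replicates), dt_min, out_times,
                     if (motility == "levy") 2 else -1, as.integer(seed))
  if (res$max_tcell_radius > bio$R * (1 + 1e-9))
    stopf("T-cell escaped the paracortex sphere (radius %.6g > R)",
          res$max_tcell_radius)
  as_activation_result(out_times, res$p_per_cell, res$p_any,
                       res$n_contacts, replicates, "abm")
}

#' Well-mixed surrogate for the lymph-node model
#'
#' Non-spatial approximation used in fast inference loops: a T-cell encounters
#' any one active DC at the kinetic-theory rate `gamma = pi b^2 v / V` (swept
#' contact volume per unit time over the paracortex volume), and each
#' encounter succeeds with the same per-contact probability as the ABM.  The
#' per-cell activation probability is `1 - exp(-Lambda(t))` with hazard
#' `Lambda(t) = gamma * sum_j int_0^t q(A_j(s)) ds` over active DCs, and
#' `p_any = 1 - exp(-n_cells * Lambda)`.  Deterministic.
#'
#' @inheritParams simulate_lymph_node
#' @param n_grid number of points of the internal integration grid.
#' @return an `activation_result` with `mode = "wellmixed"`.
#' @export
wellmixed_activation <- function(schedule, A_depart, k_off,
                                 bio = biophysical_params(), pool,
                                 horizon = NULL, out_times = NULL,
                                 n_grid = 241) {
  stopifnot(inherits(schedule, "arrival_schedule"),
            inherits(bio, "biophysical_params"),
            inherits(pool, "cognate_pool"))
  check_number(A_depart, "A_depart", 0, 1)
  check_number(k_off, "k_off", 0)
  if (is.null(horizon)) {
    horizon <- if (schedule$D == 0) schedule$dc_lifetime else
      max(schedule$arrival_times) + schedule$dc_lifetime
  }
  if (is.null(out_times))
    out_times <- unique(c(seq(0, horizon, by = 1), horizon))
  if (schedule$D == 0 || A_depart == 0 || pool$n_cells == 0) {
    if (pool$n_cells == 0)
      warning("cognate T-cell pool is empty; activation probability is 0")
    return(as_activation_result(out_times, rep(0, length(out_times)),
                                rep(0, length(out_times)), 0, 0, "wellmixed"))
  }
  gamma <- encounter_rate(bio)                       # per hour per DC
  life <- schedule$dc_lifetime
  transit <- schedule$transit_time
  # Hazard contribution of one DC as a function of time since its dermal
  # departure u: active for u in [transit, transit + lifetime].  All DCs share
  # this curve, shifted by their departure times, so we integrate it once.
  u <- seq(0, transit + life, length.out = n_grid)
  g <- ifelse(u >= transit,
              contact_activation_probability(antigen_at_time(A_depart, k_off, u),
                                             bio),
              0)
  G <- cumtrapz(u, g)                                # integral of g, hours
  G_at <- function(uu) {
    out <- approx(u, G, xout = pmin(pmax(uu, 0), max(u)), rule = 2)$y
    out[uu < 0] <- 0
    out
  }
  depart <- schedule$arrival_times - transit
  Lambda <- gamma * vapply(out_times,
                           function(t) sum(G_at(t - depart)), numeric(1))
  p_cell <- 1 - exp(-Lambda)
  p_any <- 1 - exp(-pool$n_cells * Lambda)
  as_activation_result(out_times, p_cell, p_any, NA_real_, 0, "wellmixed")
}

# Kinetic-theory encounter rate of one T-cell with one stationary DC, 1/hour.
encounter_rate <- function(bio) {
  V <- 4 / 3 * pi * bio$R^3
  pi * bio$b^2 * (bio$v * 60) / V
}

#' Response probability for one vaccine dose
#'
#' Probability that at least one cognate T-cell is activated by the end of the
#' simulation horizon for a single dose of a single peptide: `p_any(horizon)`
#' from [simulate_lymph_node()] (or [wellmixed_activation()] with
#' `mode = "wellmixed"`).
#'
#' @inheritParams simulate_lymph_node
#' @param mode `"abm"` or `"wellmixed"`.
#' @return a single probability.
#' @export
response_probability_for_dose <- function(schedule, A_depart, k_off,
                                          bio = biophysical_params(), pool,
                                          horizon = NULL, replicates = 10,
                                          seed = NULL,
                                          mode = c("abm", "wellmixed")) {
  mode <- match.arg(mode)
  res <- if (mode == "abm")
    simulate_lymph_node(schedule, A_depart, k_off, bio, pool, horizon,
                        replicates, seed)
  else {
    if (is.null(horizon)) {
      horizon <- if (schedule$D == 0) schedule$dc_lifetime else
        max(schedule$arrival_times) + schedule$dc_lifetime
    }
    wellmixed_activation(schedule, A_depart, k_off, bio, pool, horizon,
                         out_times = c(0, horizon))
  }
  tail(res$p_any, 1)
}

#' @export
print.activation_result <- function(x, ...) {
  cat(sprintf(
    "<activation_result> [%s] p_any(%.3g h) = %.4g, p_per_cell = %.4g, contacts = %s\n",
    x$mode, max(x$times), tail(x$p_any, 1), tail(x$p_per_cell, 1),
    format(x$n_contacts)))
  invisible(x)
}
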