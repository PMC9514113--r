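#' Dendritic-cell migration model
#'
#' The fraction of dermally activated DCs that reach the draining lymph node
#' (migration efficiency) is exponentially distributed; measured efficiencies
#' are of order 1%, with essentially all mass below ~3%.  Draws above
#' `efficiency_cap` are resampled (not clipped) so the cap carries no atom.
#' The migrated count is `round(efficiency * dc_density * area)`, with
#' `dc_density = 600` DCs/mm² and a vaccine dispersal area of 0.6 cm²
#' (i.e. 60 mm²): efficiencies of 1% and 4% give D = 360 and 1440.
#'
#' @param rate rate of the exponential efficiency distribution (mean
#'   efficiency = 1/rate before truncation); default 100 (mean 1%).
#' @param dc_density DCs per mm² of dermis.
#' @param area vaccine dispersal area, cm².
#' @param efficiency_cap maximum admissible efficiency, in (0, 1].
#' @return a `migration_model` list.
#' @export
migration_model <- function(rate = 100, dc_density = 600, area = 0.6,
                            efficiency_cap = 0.03) {
  check_number(rate, "rate", 0, strict_lower = TRUE)
  check_number(dc_density, "dc_density", 0, strict_lower = TRUE)
  check_number(area, "area", 0, strict_lower = TRUE)
  check_number(efficiency_cap, "efficiency_cap", 0, 1, strict_lower = TRUE)
  structure(list(rate = rate, dc_density = dc_density, area = area,
                 efficiency_cap = efficiency_cap),
            class = "migration_model")
}

#' Sample DC migration efficiencies
#'
#' Exponential draws truncated to `[0, efficiency_cap]` by inverse-CDF
#' sampling (equivalent to resampling, without rejection loops).
#'
#' @param model a [migration_model()].
#' @param n number of draws.
#' @param seed optional integer seed.
#' @return numeric vector of efficiencies.
#' @export
sample_migration_efficiency <- function(model, n = 1, seed = NULL) {
  stopifnot(inherits(model, "migration_model"))
  with_seed(seed, {
    u <- runif(n)
    qexp(u * pexp_cap(model), rate = model$rate)
  })
}

pexp_cap <- function(model) 1 - exp(-model$rate * model$efficiency_cap)

# Mean of the exponential truncated to [0, cap] — the analytic target of the
# law-of-large-numbers checks.
truncated_efficiency_mean <- function(model) {
  lam <- model$rate
  cap <- model$efficiency_cap
  1 / lam - cap * exp(-lam * cap) / (1 - exp(-lam * cap))
}

#' Sample the number of DCs migrating to the draining lymph node
#'
#' @param model a [migration_model()].
#' @param seed optional integer seed.
#' @param efficiency optional forced efficiency (bypasses sampling; used for
#'   deterministic checks and what-if calculations).
#' @return integer DC count `D`.
#' @examples
#' m <- migration_model()
#' sample_migrated_dc_count(m, efficiency = 0.01)  # 360
#' sample_migrated_dc_count(m, efficiency = 0.04)  # 1440
#' @export
sample_migrated_dc_count <- function(model, seed = NULL, efficiency = NULL) {
  stopifnot(inherits(model, "migration_model"))
  if (is.null(efficiency))
    efficiency <- sample_migration_efficiency(model, 1, seed = seed)
  check_number(efficiency, "efficiency", 0)
  as.integer(round(efficiency * model$dc_density * model$area * 100))
}

#' Build a lymph-node arrival schedule
#'
#' DCs leave the dermis from `t_first_departure` over a spread of `p` hours
#' and arrive after a lymphatic `transit_time`; the first arrival is at
#' `P = t_first_departure + transit_time` and DCs arrive at the constant rate
#' `(D - 1)/p`, i.e. evenly spaced on `[P, P + p]` (the default), or uniformly
#' at random on the same interval with `mode = "random"` (arrival-time
#' randomness was found to change results little).
#'
#' @param D integer number of migrated DCs.
#' @param transit_time lymphatic transit time, hours.
#' @param t_first_departure dermal departure time of the first DC, hours.
#' @param p spread of departures, hours.  With `D >= 2` and `p = 0` all
#'   arrivals coincide at `P`.
#' @param dc_lifetime lifetime of an activated DC in the lymph node, hours.
#' @param mode `"linear"` (constant rate) or `"random"`.
#' @param seed seed for `mode = "random"`.
#' @return an `arrival_schedule` list with fields `D`, `P`, `p`,
#'   `arrival_times` (sorted, hours), `transit_time`, `dc_lifetime`.
#' @examples
#' build_arrival_schedule(3, transit_time = 25, t_first_departure = 5, p = 10)
#' @export
build_arrival_schedule <- function(D, transit_time = 30, t_first_departure = 6,
                                   p = 10, dc_lifetime = 48,
                                   mode = c("linear", "random"), seed = NULL) {
  mode <- match.arg(mode)
  D <- as.integer(D)
  if (D < 0) stopf("D must be >= 0")
  check_number(transit_time, "transit_time", 0)
  check_number(t_first_departure, "t_first_departure", 0)
  check_number(p, "p", 0)
  check_number(dc_lifetime, "dc_lifetime", 0, strict_lower = TRUE)
  P <- t_first_departure + transit_time
  arrival_times <- if (D == 0) {
    numeric(0)
  } else if (D == 1) {
    P
  } else if (mode == "linear") {
    seq(P, P + p, length.out = D)
  } else {
    sort(c(P, P + p, with_seed(seed, runif(max(D - 2L, 0L), P, P + p))))[1:D]
  }
  structure(list(D = D, P = P, p = p, arrival_times = arrival_times,
                 transit_time = transit_time, dc_lifetime = dc_lifetime),
            class = "arrival_schedule")
}

#' Surface antigen remaining after dissociation
#'
#' Once free peptide has been cleared, the bound fraction on a DC decays as
#' pure first-order dissociation, `dA/dt = -k_off A`: rebinding is negligible
#' both in the dermis after the clearance transient and in the lymphatics,
#' where no free peptide is present.
#'
#' @param A_depart bound fraction at dermal departure, in \[0, 1\].
#' @param k_off dissociation rate, 1/hour.
#' @param t_since_departure hours since departure (>= 0).
#' @return `A_depart * exp(-k_off * t_since_departure)`.
#' @export
antigen_at_time <- function(A_depart, k_off, t_since_departure) {
  stopifnot(all(A_depart >= 0 & A_depart <= 1), all(k_off >= 0),
            all(t_since_departure >= 0))
  A_depart * exp(-k_off * t_since_departure)
}

#' @export
print.arrival_schedule <- function(x, ...) {
  cat(sprintf(
    "<arrival_schedule> D = %d, first arrival P = %.3g h, spread p = %.3g h, transit %.3g h\n",
    x$D, x$P, x$p, x$transit_time))
  invisible(x)
}
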