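#' Injection-site binding parameters
#'
#' Parameters of the mass-action competition of vaccine peptides for
#' dendritic-cell MHC-I in the dermis.  All peptides share one association
#' rate `k_on` (on-rates of equally sized short peptides are taken as equal);
#' free peptide is cleared by the vasculature at `k_clear`.  `f_avail` is the
#' patient-specific fraction of the total MHC-I pool available to vaccine
#' peptides (endogenous occupancy is absorbed into it, so self-peptides never
#' appear explicitly).
#'
#' Defaults: `l0 = 200` µM initial free concentration per peptide and
#' `r_tot = 2e-2` µM total receptor concentration (1e5 MHC-I per DC at dermal
#' DC density).  `k_on = 1` 1/(µM·h) makes binding saturate within minutes at
#' `l0 = 200` µM (pseudo-first-order rate `k_on * l0 = 200`/h); `k_clear = 20`/h
#' puts vascular clearance on the minutes timescale, with free peptide below
#' 1% of `l0` well inside two hours.
#'
#' @param k_on association rate, 1/(µM·hour), shared by all peptides.
#' @param k_clear vascular clearance rate of free peptide, 1/hour.
#' @param r_tot total MHC-I receptor concentration, µM.
#' @param l0 initial free concentration of each peptide, µM.
#' @param f_avail fraction of `r_tot` available to vaccine peptides, in (0, 1].
#' @param t_depart hours after injection at which DCs leave the dermis.
#' @return a `binding_params` list.
#' @export
binding_params <- function(k_on = 1, k_clear = 20, r_tot = 2e-2, l0 = 200,
                           f_avail = 1, t_depart = 6) {
  check_number(k_on, "k_on", 0)
  check_number(k_clear, "k_clear", 0)
  check_number(r_tot, "r_tot", 0, strict_lower = TRUE)
  check_number(l0, "l0", 0, strict_lower = TRUE)
  check_number(f_avail, "f_avail", 0, 1, strict_lower = TRUE)
  check_number(t_depart, "t_depart", 0, strict_lower = TRUE)
  structure(list(k_on = k_on, k_clear = k_clear, r_tot = r_tot, l0 = l0,
                 f_avail = f_avail, t_depart = t_depart),
            class = "binding_params")
}

#' Solve the dermal peptide/MHC-I competition ODEs
#'
#' For peptides i with free concentrations l_i, free available receptor r and
#' complexes c_i (all µM):
#' \deqn{dl_i/dt = k_{off,i} c_i - k_{on} r l_i - k_{clear} l_i}
#' \deqn{dr/dt   = \sum_i (k_{off,i} c_i - k_{on} r l_i)}
#' \deqn{dc_i/dt = k_{on} r l_i - k_{off,i} c_i}
#' The peptides are coupled through the shared receptor pool
#' `r + sum(c_i) = f_avail * r_tot`.  The system is stiff (l0 exceeds r_tot by
#' about four orders of magnitude, so receptor filling is much faster than
#' clearance or dissociation) and is integrated with the stiff-switching
#' `deSolve::lsoda` solver on a log-spaced output grid that resolves the fast
#' filling transient as well as the slow decay.
#'
#' @param peptides a [peptide_panel()] with finite off-rates.
#' @param params a [binding_params()].
#' @param horizon integration horizon, hours.
#' @param n_grid number of stored time points (log-spaced, plus t = 0).
#' @param l0 optional per-peptide initial free concentrations (µM), overriding
#'   the scalar `params$l0`.
#' @param c0 optional per-peptide initial bound concentrations (µM), default
#'   all zero.  Must leave `f_avail * r_tot - sum(c0) >= 0` free receptor.
#' @param rtol,atol solver tolerances.
#' @return a `binding_trajectory`: list with `times` (hours), matrices
#'   `free_ligand`, `bound_complex` (time x peptide, µM), vector
#'   `free_receptor` (µM), matrix `A` of bound fractions
#'   `bound_complex / (f_avail * r_tot)`, plus `peptides` and `params`.
#' @examples
#' pan <- peptide_panel(c("slow", "fast"), c("SVASTITGV", "STAPPVHNV"),
#'                      half_life = c(20, 0.2))
#' traj <- solve_binding(pan, binding_params(), horizon = 24)
#' departure_bound_fractions(traj, 6)
#' @export
solve_binding <- function(peptides, params, horizon, n_grid = 400,
                          l0 = NULL, c0 = NULL, rtol = 1e-8, atol = 1e-12) {
  validate_peptide_panel(peptides)
  require_rates(peptides)
  stopifnot(inherits(params, "binding_params"))
  check_number(horizon, "horizon", 0, strict_lower = TRUE)
  n <- nrow(peptides)
  k_off <- peptides$k_off
  r_avail <- params$f_avail * params$r_tot
  if (is.null(l0)) l0 <- rep(params$l0, n)
  if (length(l0) == 1) l0 <- rep(l0, n)
  if (is.null(c0)) c0 <- rep(0, n)
  if (length(c0) == 1) c0 <- rep(c0, n)
  if (any(c0 < 0) || sum(c0) > r_avail * (1 + 1e-12))
    stopf("initial bound concentrations exceed the available receptor pool")

  times <- c(0, exp(seq(log(min(1e-4, horizon / 10)), log(horizon),
                        length.out = n_grid)))
  y0 <- c(l0, c0)
  k_on <- params$k_on
  k_clear <- params$k_clear
  deriv <- function(t, y, parms) {
    l <- y[seq_len(n)]
    cc <- y[n + seq_len(n)]
    r <- r_avail - sum(cc)
    bind <- k_on * r * l
    unbind <- k_off * cc
    list(c(unbind - bind - k_clear * l, bind - unbind))
  }
  sol <- deSolve::lsoda(y0, times, deriv, parms = NULL,
                        rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0 || any(!is.finite(sol)))
    stopf("injection-site integration failed for peptide set: %s",
          paste(peptides$name, collapse = ", "))
  L <- sol[, 1 + seq_len(n), drop = FALSE]
  C <- sol[, 1 + n + seq_len(n), drop = FALSE]
  neg_tol <- 1e-9 * max(params$l0, r_avail)
  if (any(L < -neg_tol) || any(C < -neg_tol))
    stopf("negative concentrations beyond tolerance in injection-site solution")
  L[L < 0] <- 0
  C[C < 0] <- 0
  free_receptor <- r_avail - rowSums(C)
  traj <- structure(list(times = sol[, 1],
                         free_ligand = L,
                         bound_complex = C,
                         free_receptor = free_receptor,
                         A = C / r_avail,
                         peptides = peptides,
                         params = params),
                    class = "binding_trajectory")
  cons <- abs(traj$free_receptor + rowSums(traj$bound_complex) - r_avail) /
    r_avail
  if (any(cons > 1e-6))
    stopf("receptor conservation violated (max relative error %.3g)", max(cons))
  traj
}

#' Bound fractions carried by departing dendritic cells
#'
#' Linear interpolation of the per-peptide bound fraction A_i(t) on the stored
#' trajectory grid, evaluated at the DC departure time.
#'
#' @param traj a `binding_trajectory` from [solve_binding()].
#' @param t_depart departure time, hours; must lie within the stored grid.
#' @return named numeric vector of bound fractions (one per peptide, each in
#'   \[0, 1\], summing to at most 1).
#' @export
departure_bound_fractions <- function(traj, t_depart) {
  stopifnot(inherits(traj, "binding_trajectory"))
  tt <- traj$times
  if (t_depart < tt[1] || t_depart > tt[length(tt)])
    stopf("t_depart = %g h outside trajectory grid [%g, %g]",
          t_depart, tt[1], tt[length(tt)])
  A <- vapply(seq_len(ncol(traj$A)), function(i) {
    approx(tt, traj$A[, i], xout = t_depart, ties = "ordered")$y
  }, numeric(1))
  A <- pmin(pmax(A, 0), 1)
  setNames(A, traj$peptides$name)
}

#' @export
print.binding_trajectory <- function(x, ...) {
  cat(sprintf("<binding_trajectory> %d peptides, %d time points over %.3g h\n",
              ncol(x$A), length(x$times), max(x$times)))
  A_end <- x$A[nrow(x$A), ]
  cat("  final bound fractions:",
      paste(sprintf("%s=%.3g", x$peptides$name, A_end), collapse = ", "), "\n")
  invisible(x)
}
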