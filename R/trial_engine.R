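#' Population hyperparameters for virtual-patient cohorts
#'
#' Each patient-specific parameter — the fraction `f_avail` of dermal MHC-I
#' available to vaccine peptides, the lymphatic `transit_time`, the `spread`
#' of dermal departure times, and the T-cell precursor frequency `phi` — is
#' drawn per patient from a Gaussian with the given (mean, sd), truncated to
#' its admissible range by resampling.  The DC migration-efficiency
#' distribution is fixed (not fitted) and carried alongside.
#'
#' @param f_avail,transit_time,spread,phi length-2 numeric vectors
#'   `c(mean, sd)`; units: dimensionless, hours, hours, dimensionless.
#' @param migration a [migration_model()].
#' @return a `population_hyperparams` list.
#' @export
population_hyperparams <- function(f_avail = c(0.5, 0.1),
                                   transit_time = c(30, 5),
                                   spread = c(10, 2),
                                   phi = c(2e-5, 5e-6),
                                   migration = migration_model()) {
  as_pair <- function(x, name) {
    if (length(x) != 2 || any(!is.finite(x)))
      stopf("`%s` must be c(mean, sd)", name)
    if (x[2] < 0) stopf("`%s` sd must be >= 0", name)
    setNames(as.numeric(x), c("mean", "sd"))
  }
  hp <- structure(list(f_avail = as_pair(f_avail, "f_avail"),
                       transit_time = as_pair(transit_time, "transit_time"),
                       spread = as_pair(spread, "spread"),
                       phi = as_pair(phi, "phi"),
                       migration = migration),
                  class = "population_hyperparams")
  if (hp$f_avail["mean"] <= 0 || hp$f_avail["mean"] > 1)
    stopf("f_avail mean must be in (0, 1]")
  if (hp$transit_time["mean"] <= 0) stopf("transit_time mean must be > 0")
  if (hp$phi["mean"] <= 0 || hp$phi["mean"] >= 1)
    stopf("phi mean must be in (0, 1)")
  hp
}

# Admissible ranges used for truncation-by-resampling of patient draws.
PATIENT_RANGES <- list(f_avail = c(1e-6, 1),
                       transit_time = c(1e-3, Inf),
                       spread = c(0, Inf),
                       phi = c(1e-9, 1 - 1e-9))

#' Trial design
#'
#' @param label design name.
#' @param n_patients number of enrolled (virtual) patients.
#' @param peptides a [peptide_panel()] with finite off-rates.
#' @param visit_days vaccination days (sorted, non-negative); each visit is an
#'   independent dose of every peptide.
#' @param dose_mg per-peptide mass per visit (informational only).
#' @param max_bin responder histogram aggregation level: counts of
#'   `max_bin` or more responses are pooled into one `"k+"` bin (default 3,
#'   matching phase-style 0/1/2/3+ reporting).
#' @return a `trial_design` list.
#' @export
trial_design <- function(label, n_patients, peptides, visit_days,
                         dose_mg = 4, max_bin = 3) {
  validate_peptide_panel(peptides)
  require_rates(peptides)
  check_number(n_patients, "n_patients", 1)
  if (length(visit_days) < 1 || is.unsorted(visit_days) || any(visit_days < 0))
    stopf("visit_days must be sorted and non-negative")
  check_number(max_bin, "max_bin", 1)
  structure(list(label = as.character(label),
                 n_patients = as.integer(n_patients),
                 peptides = peptides,
                 visit_days = as.numeric(visit_days),
                 dose_mg = dose_mg,
                 max_bin = as.integer(max_bin)),
            class = "trial_design")
}

#' Model configuration for the per-patient pipeline
#'
#' Bundles the fixed (non-fitted) submodel settings: injection-site binding
#' constants, lymph-node biophysics, paracortex T-cell density, DC lifetime,
#' arrival mode, the number of lymph-node replicates per evaluation (10 by
#' default, to reduce Monte-Carlo uncertainty of the response probability)
#' and the forward-model mode (`"abm"` reference or `"wellmixed"` surrogate).
#'
#' @param binding a [binding_params()] (its `f_avail` is overridden per
#'   patient).
#' @param bio a [biophysical_params()].
#' @param rho paracortex T-cell density, cells/µm³.
#' @param dc_lifetime activated-DC lifetime in the lymph node, hours.
#' @param arrival_mode `"linear"` or `"random"` DC arrivals.
#' @param ln_replicates ABM replicates per dose evaluation.
#' @param mode `"abm"` or `"wellmixed"`.
#' @param horizon per-dose simulation horizon, hours (`NULL` = last arrival +
#'   DC lifetime).
#' @return a `model_config` list.
#' @export
model_config <- function(binding = binding_params(),
                         bio = biophysical_params(),
                         rho = 1e-3, dc_lifetime = 48,
                         arrival_mode = c("linear", "random"),
                         ln_replicates = 10,
                         mode = c("abm", "wellmixed"),
                         horizon = NULL) {
  structure(list(binding = binding, bio = bio, rho = rho,
                 dc_lifetime = dc_lifetime,
                 arrival_mode = match.arg(arrival_mode),
                 ln_replicates = as.integer(ln_replicates),
                 mode = match.arg(mode), horizon = horizon),
            class = "model_config")
}

draw_truncated <- function(n, mean, sd, range, what, max_tries = 1e4) {
  if (sd == 0) {
    if (mean < range[1] || mean > range[2])
      stopf("degenerate %s distribution (mean %g) outside admissible range",
            what, mean)
    return(rep(mean, n))
  }
  out <- numeric(n)
  todo <- seq_len(n)
  tries <- 0
  while (length(todo) > 0) {
    tries <- tries + 1
    if (tries > max_tries)
      stopf("cohort construction failed: %s draws rejected > %d times (mean %g, sd %g)",
            what, max_tries, mean, sd)
    cand <- rnorm(length(todo), mean, sd)
    ok <- cand >= range[1] & cand <= range[2]
    out[todo[ok]] <- cand[ok]
    todo <- todo[!ok]
  }
  out
}

#' Draw a virtual-patient cohort
#'
#' @param hyper a [population_hyperparams()].
#' @param design a [trial_design()] (supplies the cohort size and the number
#'   of visits for the per-dose DC draws).
#' @param seed integer seed; cohorts are reproducible from it.
#' @return a `virtual_cohort`: list with `patients` (data frame of id,
#'   f_avail, transit_time, spread, phi, seed) and `D` (n_patients x n_visits
#'   matrix of per-dose migrated-DC counts).
#' @export
draw_cohort <- function(hyper, design, seed = NULL) {
  stopifnot(inherits(hyper, "population_hyperparams"),
            inherits(design, "trial_design"))
  n <- design$n_patients
  n_visits <- length(design$visit_days)
  with_seed(seed, {
    pat <- data.frame(
      id = seq_len(n),
      f_avail = draw_truncated(n, hyper$f_avail["mean"], hyper$f_avail["sd"],
                               PATIENT_RANGES$f_avail, "f_avail"),
      transit_time = draw_truncated(n, hyper$transit_time["mean"],
                                    hyper$transit_time["sd"],
                                    PATIENT_RANGES$transit_time,
                                    "transit_time"),
      spread = draw_truncated(n, hyper$spread["mean"], hyper$spread["sd"],
                              PATIENT_RANGES$spread, "spread"),
      phi = draw_truncated(n, hyper$phi["mean"], hyper$phi["sd"],
                           PATIENT_RANGES$phi, "phi"))
    eff <- matrix(sample_migration_efficiency(hyper$migration, n * n_visits),
                  n, n_visits)
    D <- matrix(as.integer(round(eff * hyper$migration$dc_density *
                                   hyper$migration$area * 100)), n, n_visits)
    pat$seed <- derive_seeds(sample.int(1e9, 1), n)
    structure(list(patients = pat, D = D, n_visits = n_visits),
              class = "virtual_cohort")
  })
}

#' Simulate one virtual patient through the full pipeline
#'
#' For each peptide: solve the injection-site competition with the patient's
#' `f_avail`, take the bound fractions at DC departure, convert them to the
#' cognate fraction among all contact-region MHC-I (`f_avail * A_i`, since
#' only a fraction `f_avail` of the DC's receptors is available to vaccine
#' peptide), and run the lymph-node model once per visit with a fresh DC
#' count.  Doses combine independently:
#' `p_response[i] = 1 - prod_v (1 - p_dose[i, v])`.
#'
#' @param patient one row of `cohort$patients`.
#' @param D_draws integer vector of per-visit DC counts for this patient.
#' @param design a [trial_design()].
#' @param config a [model_config()].
#' @return a `response_profile`: list with `id`, `p_response` (named per
#'   peptide), `expected_responses = sum(p_response)`, and the `p_dose`
#'   matrix.
#' @export
simulate_patient <- function(patient, D_draws, design, config = model_config()) {
  stopifnot(inherits(design, "trial_design"), inherits(config, "model_config"))
  bp <- config$binding
  bp$f_avail <- patient$f_avail
  traj <- tryCatch(
    solve_binding(design$peptides, bp, horizon = bp$t_depart),
    error = function(e) stopf("patient %s: %s", patient$id, conditionMessage(e)))
  A_dep <- departure_bound_fractions(traj, bp$t_depart)
  cognate <- pmin(1, A_dep * patient$f_avail)
  pool <- cognate_pool(patient$phi, config$rho, config$bio)
  n_pep <- nrow(design$peptides)
  n_visits <- length(design$visit_days)
  dose_seeds <- matrix(derive_seeds(patient$seed, n_pep * n_visits),
                       n_pep, n_visits)
  p_dose <- matrix(0, n_pep, n_visits,
                   dimnames = list(design$peptides$name, NULL))
  for (v in seq_len(n_visits)) {
    sched <- build_arrival_schedule(D_draws[v],
                                    transit_time = patient$transit_time,
                                    t_first_departure = bp$t_depart,
                                    p = patient$spread,
                                    dc_lifetime = config$dc_lifetime,
                                    mode = config$arrival_mode,
                                    seed = dose_seeds[1, v])
    for (i in seq_len(n_pep)) {
      p_dose[i, v] <- tryCatch(
        response_probability_for_dose(sched, cognate[i],
                                      design$peptides$k_off[i],
                                      config$bio, pool,
                                      horizon = config$horizon,
                                      replicates = config$ln_replicates,
                                      seed = dose_seeds[i, v],
                                      mode = config$mode),
        error = function(e)
          stopf("patient %s, peptide %s: %s", patient$id,
                design$peptides$name[i], conditionMessage(e)))
    }
  }
  p_response <- 1 - apply(1 - p_dose, 1, prod)
  structure(list(id = patient$id, p_response = p_response,
                 expected_responses = sum(p_response), p_dose = p_dose),
            class = "response_profile")
}

#' Exact Poisson-binomial probability mass function
#'
#' Distribution of the number of successes among independent Bernoulli trials
#' with probabilities `p`, computed by the standard O(n^2) convolution.
#'
#' @param p vector of success probabilities.
#' @return numeric vector of length `length(p) + 1`: P(0), P(1), ...
#' @export
poisson_binomial_pmf <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  pmf <- 1
  for (pi in p) pmf <- c(pmf * (1 - pi), 0) + c(0, pmf * pi)
  pmf
}

#' Responder-count histogram over a cohort
#'
#' In `"expected"` mode (default, deterministic) each patient contributes its
#' exact Poisson-binomial mass over response counts, truncated at
#' `max_bin`+; the histogram entries are expected patient counts and sum to
#' the cohort size.  In `"sampled"` mode each patient-peptide response is a
#' Bernoulli draw.
#'
#' @param profiles list of `response_profile` objects.
#' @param mode `"expected"` or `"sampled"`.
#' @param seed seed for `"sampled"` mode.
#' @param max_bin aggregation level (counts >= `max_bin` pooled).
#' @return named numeric histogram over bins `0 ... (max_bin-1), "max_bin+"`.
#' @export
responder_histogram <- function(profiles, mode = c("expected", "sampled"),
                                seed = NULL, max_bin = 3) {
  mode <- match.arg(mode)
  if (length(profiles) == 0) stopf("no response profiles")
  bins <- c(as.character(seq(0, max_bin - 1)), paste0(max_bin, "+"))
  hist <- setNames(numeric(max_bin + 1), bins)
  for (pr in profiles) {
    if (mode == "expected") {
      pmf <- poisson_binomial_pmf(pr$p_response)
      agg <- c(pmf[seq_len(min(max_bin, length(pmf) - 1))],
               sum(pmf[-seq_len(min(max_bin, length(pmf) - 1))]))
      length(agg) <- max_bin + 1
      agg[is.na(agg)] <- 0
      hist <- hist + agg
    } else {
      k <- with_seed(seed, sum(rbinom(length(pr$p_response), 1,
                                      pr$p_response)))
      seed <- if (!is.null(seed)) seed + 1L else NULL
      hist[min(k, max_bin) + 1] <- hist[min(k, max_bin) + 1] + 1
    }
  }
  hist
}

#' Run a simulated clinical trial
#'
#' Draws a fresh cohort per repeat (3 repeats by default, to estimate the
#' variability induced by patient randomness), simulates every patient and
#' peptide over the whole vaccination schedule, and aggregates responder
#' histograms.
#'
#' @param design a [trial_design()] or a [design_variant()] result.
#' @param hyper a [population_hyperparams()]; a variant's transit/spread
#'   overrides are applied to it.
#' @param config a [model_config()].
#' @param n_repeats number of independent trial repeats.
#' @param seed integer seed.
#' @param mode histogram mode, `"expected"` or `"sampled"`.
#' @return a `trial_result`: list with `histogram` (mean over repeats),
#'   `sd`, `per_repeat` (repeats x bins matrix), `profiles` (list of lists of
#'   `response_profile`), `mean_expected_responses`, `design_label`.
#' @export
run_trial <- function(design, hyper, config = model_config(), n_repeats = 3,
                      seed = NULL, mode = c("expected", "sampled")) {
  mode <- match.arg(mode)
  if (inherits(design, "trial_variant")) {
    hyper <- apply_variant_overrides(hyper, design)
    design <- design$design
  }
  stopifnot(inherits(design, "trial_design"),
            inherits(hyper, "population_hyperparams"))
  seeds <- derive_seeds(seed, n_repeats * 2)
  per_repeat <- matrix(0, n_repeats, design$max_bin + 1)
  profiles <- vector("list", n_repeats)
  mean_exp <- numeric(n_repeats)
  for (r in seq_len(n_repeats)) {
    cohort <- draw_cohort(hyper, design, seed = seeds[r])
    profs <- lapply(seq_len(design$n_patients), function(i)
      simulate_patient(cohort$patients[i, ], cohort$D[i, ], design, config))
    h <- responder_histogram(profs, mode = mode,
                             seed = seeds[n_repeats + r],
                             max_bin = design$max_bin)
    per_repeat[r, ] <- h
    colnames(per_repeat) <- names(h)
    profiles[[r]] <- profs
    mean_exp[r] <- mean(vapply(profs, `[[`, numeric(1), "expected_responses"))
  }
  structure(list(histogram = colMeans(per_repeat),
                 sd = apply(per_repeat, 2, sd),
                 per_repeat = per_repeat,
                 profiles = profiles,
                 mean_expected_responses = mean(mean_exp),
                 design_label = design$label,
                 n_repeats = n_repeats, seed = seed, mode = mode),
            class = "trial_result")
}

#' Intervention-design variants
#'
#' Pure transformation of a trial design: remove named peptides (reducing
#' competition for dermal MHC-I) and/or override the population mean of the
#' lymphatic transit time or departure spread (e.g. transit 30 h to 10 h,
#' emulating faster-draining delivery routes).  The original design is
#' untouched.
#'
#' @param design a [trial_design()].
#' @param drop_peptides character vector of peptide names to remove.
#' @param transit_override new population mean transit time, hours, or `NULL`.
#' @param spread_override new population mean departure spread, hours, or
#'   `NULL`.
#' @return a `trial_variant` list accepted by [run_trial()].
#' @export
design_variant <- function(design, drop_peptides = character(),
                           transit_override = NULL, spread_override = NULL) {
  stopifnot(inherits(design, "trial_design"))
  new_design <- design
  if (length(drop_peptides) > 0) {
    missing <- setdiff(drop_peptides, design$peptides$name)
    if (length(missing) > 0)
      stopf("unknown peptide(s): %s", paste(missing, collapse = ", "))
    keep <- !(design$peptides$name %in% drop_peptides)
    if (!any(keep)) stopf("cannot drop every peptide from the design")
    new_design$peptides <- design$peptides[keep, , drop = FALSE]
    class(new_design$peptides) <- class(design$peptides)
    new_design$label <- paste0(design$label, " [-",
                               paste(drop_peptides, collapse = ","), "]")
  }
  structure(list(design = new_design,
                 transit_override = transit_override,
                 spread_override = spread_override),
            class = "trial_variant")
}

apply_variant_overrides <- function(hyper, variant) {
  if (!is.null(variant$transit_override))
    hyper$transit_time["mean"] <- variant$transit_override
  if (!is.null(variant$spread_override))
    hyper$spread["mean"] <- variant$spread_override
  hyper
}

#' @export
print.trial_result <- function(x, ...) {
  cat(sprintf("<trial_result> '%s': %d repeat(s), %s mode\n",
              x$design_label, x$n_repeats, x$mode))
  h <- rbind(mean = round(x$histogram, 2), sd = round(x$sd, 2))
  print(h)
  cat(sprintf("mean expected responses per patient: %.3g\n",
              x$mean_expected_responses))
  invisible(x)
}
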