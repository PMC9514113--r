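#' Synthetic study scenario
#'
#' Defines everything needed to exercise the full pipeline without external
#' data: a peptide panel with a cluster of slow off-rates plus fast-off-rate
#' outliers (the structure seen in measured short-peptide panels, where a few
#' poor binders have much shorter half-lives than the rest), a ground-truth
#' Gaussian patient population, and a trial-design template.  Defaults are
#' sized for routine runs: 12 patients, 5 peptides, 3 visits, 200 ABC
#' particles.
#'
#' @param seed scenario seed.
#' @param n_peptides total peptides.
#' @param n_fast_outliers how many have fast (short half-life) off-rates.
#' @param slow_range half-life range of the slow cluster, hours.
#' @param fast_range half-life range of the outliers, hours; must lie
#'   strictly below `slow_range`.
#' @param n_patients cohort size of the design template.
#' @param visit_days vaccination days.
#' @param truth ground-truth [population_hyperparams()].
#' @param n_particles,n_generations ABC sizes for recovery experiments.
#' @return a `synthetic_scenario` list.
#' @export
synthetic_scenario <- function(seed = 20260101, n_peptides = 5,
                               n_fast_outliers = 1,
                               slow_range = c(15, 40), fast_range = c(0.1, 1),
                               n_patients = 12, visit_days = c(0, 7, 14),
                               truth = population_hyperparams(),
                               n_particles = 200, n_generations = 6) {
  if (n_fast_outliers >= n_peptides)
    stopf("need at least one slow-cluster peptide")
  stopifnot(length(slow_range) == 2, length(fast_range) == 2,
            all(slow_range > 0), all(fast_range > 0))
  if (n_fast_outliers > 0 && max(fast_range) >= min(slow_range))
    stopf("fast-outlier half-lives must lie strictly below the slow cluster")
  structure(list(seed = as.integer(seed), n_peptides = as.integer(n_peptides),
                 n_fast_outliers = as.integer(n_fast_outliers),
                 slow_range = slow_range, fast_range = fast_range,
                 n_patients = as.integer(n_patients),
                 visit_days = visit_days, truth = truth,
                 n_particles = as.integer(n_particles),
                 n_generations = as.integer(n_generations)),
            class = "synthetic_scenario")
}

random_9mers <- function(n) {
  vapply(seq_len(n), function(i)
    paste(sample(AA_ALPHABET, 9, replace = TRUE), collapse = ""), character(1))
}

#' Generate a synthetic peptide panel
#'
#' Random 9-mer sequences (cosmetic: only the off-rate enters any
#' computation) with half-lives drawn uniformly from the slow-cluster range,
#' and the last `n_fast_outliers` from the fast range.
#'
#' @param scenario a [synthetic_scenario()].
#' @return a [peptide_panel()], deterministic given `scenario$seed`.
#' @export
make_peptide_panel <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  with_seed(scenario$seed, {
    n <- scenario$n_peptides
    nf <- scenario$n_fast_outliers
    hl <- c(runif(n - nf, scenario$slow_range[1], scenario$slow_range[2]),
            if (nf > 0) runif(nf, scenario$fast_range[1],
                              scenario$fast_range[2]))
    peptide_panel(name = sprintf("SYN-%d", seq_len(n)),
                  sequence = random_9mers(n),
                  half_life = hl)
  })
}

#' Trial design of a synthetic scenario
#'
#' @param scenario a [synthetic_scenario()].
#' @return a [trial_design()] built from the scenario's panel and template.
#' @export
make_trial_design <- function(scenario) {
  trial_design(label = sprintf("synthetic-%d", scenario$seed),
               n_patients = scenario$n_patients,
               peptides = make_peptide_panel(scenario),
               visit_days = scenario$visit_days)
}

#' Generate an observed responder histogram from known ground truth
#'
#' Runs the forward model at the scenario's ground-truth hyperparameters and
#' returns a sampled-mode responder histogram (integer patient counts)
#' together with the generating truth, for ABC parameter-recovery
#' experiments.
#'
#' @param scenario a [synthetic_scenario()].
#' @param config a [model_config()]; the well-mixed surrogate is the default
#'   forward mode here to match its use inside ABC.
#' @return list with `observed` (named histogram), `truth`
#'   (`population_hyperparams`), `design`, and the underlying `trial_result`.
#' @export
make_observed_trial <- function(scenario,
                                config = model_config(mode = "wellmixed")) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  design <- make_trial_design(scenario)
  tr <- run_trial(design, scenario$truth, config, n_repeats = 1,
                  seed = scenario$seed + 1L, mode = "sampled")
  list(observed = tr$per_repeat[1, ], truth = scenario$truth,
       design = design, trial = tr)
}

# ---- design / histogram / config serialisation --------------------------

#' Read and write trial designs and responder histograms
#'
#' Trial designs serialise as YAML or JSON with fields `label`, `n_patients`,
#' `visit_days`, `dose_mg`, `max_bin` and a `peptides` file reference or
#' inline table; histograms as JSON objects keyed by bin label.
#'
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @param design a [trial_design()].
#' @param peptides_path optional path the peptide table is written to (CSV);
#'   defaults to inline peptides in the design file.
#' @return `read_trial_design()` returns a `trial_design`;
#'   writers return `path` invisibly.
#' @export
read_trial_design <- function(path) {
  obj <- read_structured(path)
  pep <- if (!is.null(obj$peptides_file)) {
    read_peptide_table(file.path(dirname(path), obj$peptides_file))
  } else {
    tab <- as.data.frame(do.call(rbind, lapply(obj$peptides, as.data.frame)))
    peptide_panel(tab$name, tab$sequence,
                  half_life = as.numeric(tab$half_life_h))
  }
  trial_design(label = obj$label, n_patients = obj$n_patients,
               peptides = pep, visit_days = unlist(obj$visit_days),
               dose_mg = obj$dose_mg %||% 4, max_bin = obj$max_bin %||% 3)
}

#' @rdname read_trial_design
#' @export
write_trial_design <- function(design, path, peptides_path = NULL) {
  stopifnot(inherits(design, "trial_design"))
  obj <- list(label = design$label, n_patients = design$n_patients,
              visit_days = design$visit_days, dose_mg = design$dose_mg,
              max_bin = design$max_bin)
  if (!is.null(peptides_path)) {
    write_peptide_table(design$peptides,
                        file.path(dirname(path), peptides_path))
    obj$peptides_file <- peptides_path
  } else {
    obj$peptides <- lapply(seq_len(nrow(design$peptides)), function(i)
      list(name = design$peptides$name[i],
           sequence = design$peptides$sequence[i],
           half_life_h = design$peptides$half_life[i]))
  }
  write_structured(obj, path)
}

#' @rdname read_trial_design
#' @param histogram named numeric responder histogram.
#' @export
write_histogram <- function(histogram, path) {
  jsonlite::write_json(as.list(histogram), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname read_trial_design
#' @export
read_histogram <- function(path) {
  unlist(jsonlite::read_json(path, simplifyVector = TRUE))
}

read_structured <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = FALSE)
  else yaml::read_yaml(path)
}

write_structured <- function(obj, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  else yaml::write_yaml(obj, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write every synthetic input for a scenario to a directory
#'
#' Produces `peptides.csv`, `design.yaml`, `observed.json` and `truth.json`
#' (ground-truth hyperparameter means/sds), mirroring the file interfaces of
#' the trial and ABC entry points.
#'
#' @param scenario a [synthetic_scenario()].
#' @param out_dir output directory (created if missing).
#' @param config forward-model [model_config()].
#' @return invisibly, the list of written paths.
#' @export
write_synthetic_inputs <- function(scenario, out_dir,
                                   config = model_config(mode = "wellmixed")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  obs <- make_observed_trial(scenario, config)
  paths <- list(
    peptides = file.path(out_dir, "peptides.csv"),
    design = file.path(out_dir, "design.yaml"),
    observed = file.path(out_dir, "observed.json"),
    truth = file.path(out_dir, "truth.json"))
  write_trial_design(obs$design, paths$design, peptides_path = "peptides.csv")
  write_histogram(obs$observed, paths$observed)
  tr <- obs$truth
  jsonlite::write_json(
    list(f_avail = as.list(tr$f_avail), transit_time = as.list(tr$transit_time),
         spread = as.list(tr$spread), phi = as.list(tr$phi)),
    paths$truth, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
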