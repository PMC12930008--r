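#' Default run configuration
#'
#' The configuration is a nested list with blocks `compound`, `regimen`,
#' `population` (sampling bounds and cohort size), `milk` (pH anchors,
#' creamatocrit, optional `fu_milk` and fat-partition coefficients),
#' `study` (synthetic-study design) plus `seed` and `out_dir`. Defaults
#' are the calibrated doravirine single-dose configuration.
#'
#' @return A named list (see [load_config()]).
#' @export
default_config <- function() {
  dor <- doravirine()
  list(
    compound = unclass(dor)[c("name", "mol_weight", "logP", "pKa",
                              "ionization_class", "fu_plasma", "cl_f",
                              "v_f", "ka", "f_abs", "iiv_cv")],
    regimen = list(dose = 100, interval = 24, n_doses = 1),
    population = list(
      n_subjects = 10, n_trials = 10,
      age = list(kind = "truncated_normal", location = 32, scale = 3.5,
                 min = 28, max = 39),
      weight = list(kind = "lognormal", location = 80.8, scale = 0.20,
                    min = 60.6, max = 140),
      postpartum = list(kind = "lognormal", location = 6.5, scale = 0.45,
                        min = 2, max = 12)),
    milk = list(
      ph_anchors = list(months = c(0.5, 12), ph = c(7.0, 7.4)),
      ph_plasma = 7.4, creamatocrit = 4, fu_milk = NA,
      k_fat = list(a = 0.253671, b = 0)),
    study = list(
      n_subjects = 8, dose = 100,
      plasma_times = c(0, 1, 2, 3, 4, 5, 6, 8, 10, 12, 24),
      milk_times = c(0, 2, 4, 6, 12, 24),
      lloq = 0.01, residual_cv = 0.15, volume_range = c(20, 150)),
    seed = 1,
    out_dir = "milkpk-output"
  )
}

.check_keys <- function(supplied, defaults, path = "") {
  unknown <- setdiff(names(supplied), names(defaults))
  if (length(unknown) > 0) {
    abort(sprintf("Unknown configuration key%s: %s",
                  if (length(unknown) > 1) "s" else "",
                  paste0(path, unknown, collapse = ", ")))
  }
  for (nm in names(supplied)) {
    # recurse only into named blocks that are nested in the defaults too
    if (is.list(supplied[[nm]]) && is.list(defaults[[nm]]) &&
        !is.null(names(defaults[[nm]])) &&
        !nm %in% c("ph_anchors", "iiv_cv")) {
      .check_keys(supplied[[nm]], defaults[[nm]], paste0(path, nm, "$"))
    }
  }
  invisible(TRUE)
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration, rejects unknown keys (naming the
#' offender), and fills every omitted key from [default_config()].
#'
#' @param path Path to a YAML file.
#' @return The validated configuration list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file '%s' not found.", path))
  user <- yaml::read_yaml(path) %||% list()
  defaults <- default_config()
  .check_keys(user, defaults)
  modifyList(defaults, user)
}

#' Write a run configuration to YAML
#'
#' @param config Configuration list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

# build package objects out of a config list
.config_compound <- function(config) {
  cc <- config$compound
  compound_profile(cc$name, cc$mol_weight, cc$logP, cc$pKa,
                   cc$ionization_class, cc$fu_plasma, cc$cl_f, cc$v_f,
                   cc$ka, cc$f_abs, cc$iiv_cv)
}

.config_demographics <- function(config) {
  mk <- function(d) dist_spec(d$kind, d$location, d$scale,
                              d$min %||% -Inf, d$max %||% Inf)
  p <- config$population
  demographic_spec(age = mk(p$age), weight = mk(p$weight),
                   postpartum = mk(p$postpartum))
}

.config_design <- function(config) {
  s <- config$study
  study_design(s$n_subjects, s$dose, s$plasma_times, s$milk_times,
               s$lloq, s$residual_cv, s$volume_range)
}

#' Write a profile table to CSV
#'
#' Columns `subject_id`, `matrix`, `time_h`, `conc_mg_L` (the token `BLQ`
#' for below-LLOQ samples), `lloq`, and `volume_mL` when present.
#'
#' @param data Profile tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_study_csv <- function(data, path) {
  out <- data |>
    dplyr::mutate(conc_mg_L = ifelse(.data$blq, "BLQ",
                                     format(.data$conc_mg_L, digits = 15))) |>
    dplyr::select(-"blq")
  readr::write_csv(out, path)
  invisible(path)
}

#' Read a study profile CSV
#'
#' Expects columns `subject_id`, `matrix`, `time_h`, `conc_mg_L` (numeric
#' or the token `BLQ`), optionally `lloq`. Validates that times are
#' strictly increasing within each subject and matrix, reporting the
#' offending row on failure.
#'
#' @param path CSV path.
#' @return A profile tibble with `blq` flags.
#' @export
read_study_csv <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           conc_mg_L = readr::col_character()))
  need <- c("subject_id", "matrix", "time_h", "conc_mg_L")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0) {
    abort(sprintf("Missing column%s: %s",
                  if (length(missing) > 1) "s" else "",
                  paste(missing, collapse = ", ")))
  }
  bad_matrix <- !raw$matrix %in% c("plasma", "milk")
  if (any(bad_matrix)) {
    abort(sprintf("Row %d: matrix must be 'plasma' or 'milk'.",
                  which(bad_matrix)[1] + 1L))
  }
  out <- raw |>
    dplyr::mutate(
      blq = .data$conc_mg_L == "BLQ",
      conc_mg_L = suppressWarnings(
        ifelse(.data$blq, NA_real_, as.numeric(.data$conc_mg_L))))
  if (any(!out$blq & is.na(out$conc_mg_L))) {
    abort(sprintf("Row %d: concentration is neither numeric nor 'BLQ'.",
                  which(!out$blq & is.na(out$conc_mg_L))[1] + 1L))
  }
  if (!"lloq" %in% names(out)) out$lloq <- NA_real_
  bad <- out |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::group_by(.data$subject_id, .data$matrix) |>
    dplyr::filter(c(FALSE, diff(.data$time_h) <= 0)) |>
    dplyr::ungroup()
  if (nrow(bad) > 0) {
    abort(sprintf("Row %d: times must be strictly increasing within %s/%s.",
                  bad$.row[1] + 1L, bad$subject_id[1], bad$matrix[1]))
  }
  out
}

#' Run an analysis pipeline stage
#'
#' Thin driver over the package's functions. `"synth"` generates a
#' synthetic study and writes its profile, collection and truth CSVs;
#' `"simulate"` runs the population simulation and writes the ensemble
#' profiles and VPC bands; `"nca"` analyses a study CSV (defaulting to
#' the synthetic study written previously); `"exposure"` computes the
#' per-subject infant-exposure metrics and their population summary;
#' `"validate"` writes the predicted:observed report tables. All outputs
#' are new CSV files under `out_dir`; inputs are never modified. A
#' `run_log.yaml` records command, seed and configuration for
#' reproducibility.
#'
#' @param config Configuration list (see [load_config()]).
#' @param command One of `"synth"`, `"simulate"`, `"nca"`, `"exposure"`,
#'   `"validate"`.
#' @param out_dir Output directory (default from config).
#' @param seed Seed override (default from config).
#' @return Invisibly, a character vector of the files written.
#' @export
run_pipeline <- function(config = default_config(),
                         command = c("synth", "simulate", "nca",
                                     "exposure", "validate"),
                         out_dir = config$out_dir, seed = config$seed) {
  command <- match.arg(command)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  compound <- .config_compound(config)
  demo <- .config_demographics(config)
  design <- .config_design(config)
  regimen <- dosing_regimen(config$regimen$dose, config$regimen$interval,
                            config$regimen$n_doses)
  paths <- character(0)
  emit <- function(x, name) {
    p <- file.path(out_dir, name)
    if (all(c("blq", "conc_mg_L") %in% names(x))) {
      write_study_csv(x, p)
    } else {
      readr::write_csv(x, p)
    }
    paths <<- c(paths, p)
  }

  make_study <- function() {
    fu_milk <- config$milk$fu_milk
    if (is.null(fu_milk) || is.na(fu_milk)) fu_milk <- NULL
    generate_study(design, compound, seed = seed, demographics = demo,
                   creamatocrit = config$milk$creamatocrit,
                   milk_anchors = tibble::as_tibble(config$milk$ph_anchors),
                   fu_milk = fu_milk, k_fat = config$milk$k_fat)
  }
  make_ensemble <- function(subjects) {
    simulate_population(compound, regimen, subjects,
                        n_trials = config$population$n_trials, seed = seed)
  }

  if (command == "synth") {
    study <- make_study()
    emit(study$profiles, "study_profiles.csv")
    emit(study$collections, "study_collections.csv")
    emit(study$truth, "study_truth.csv")
    emit(study$subjects, "study_subjects.csv")
  } else if (command == "simulate") {
    subjects <- sample_subjects(demo, config$population$n_subjects,
                                seed = seed)
    ens <- make_ensemble(subjects)
    emit(ens$profiles, "ensemble_profiles.csv")
    emit(summarize_vpc(ens), "vpc_bands.csv")
  } else if (command == "nca") {
    profiles <- .pipeline_profiles(config, out_dir, make_study)
    emit(run_nca(profiles), "nca_results.csv")
  } else if (command == "exposure") {
    study <- make_study()
    metrics <- exposure_metrics(run_nca(study$profiles), study$subjects,
                                study$collections, dose = design$dose)
    emit(metrics, "exposure_metrics.csv")
    emit(summarize_exposure(metrics), "exposure_summary.csv")
  } else if (command == "validate") {
    study <- make_study()
    ens <- make_ensemble(study$subjects)
    rep <- study_report(study, ens)
    emit(rep$ratio_checks, "ratio_checks.csv")
    emit(rep$observed_nca, "observed_nca.csv")
    emit(rep$predicted_nca, "predicted_nca.csv")
    emit(rep$exposure_summary, "exposure_summary.csv")
    emit(rep$vpc, "vpc_bands.csv")
  }

  log <- list(command = command, seed = seed,
              written = basename(paths), config = config)
  yaml::write_yaml(log, file.path(out_dir, "run_log.yaml"))
  invisible(paths)
}

# nca stage input: an existing study CSV if present, else a fresh synthesis
.pipeline_profiles <- function(config, out_dir, make_study) {
  p <- file.path(out_dir, "study_profiles.csv")
  if (file.exists(p)) read_study_csv(p) else make_study()$profiles
}
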