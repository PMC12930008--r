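#' Predicted:observed ratio check
#'
#' Model performance is considered adequate when the predicted:observed
#' ratio of a PK parameter falls within \[0.7, 1.43\] (a strict two-fold
#' style window; both boundaries inclusive).
#'
#' @param predicted,observed Positive values (vectorized).
#' @param parameter Optional parameter label(s).
#' @param lower,upper Acceptance window bounds.
#' @return A tibble: `parameter`, `predicted`, `observed`, `ratio`, `pass`.
#' @export
#' @examples
#' pred_obs_ratio(19.4, 19.2, "auc_inf")
pred_obs_ratio <- function(predicted, observed, parameter = "",
                           lower = 0.7, upper = 1.43) {
  if (any(predicted <= 0) || any(observed <= 0)) {
    abort("`predicted` and `observed` must be > 0.")
  }
  ratio <- predicted / observed
  tibble::tibble(parameter = parameter, predicted = predicted,
                 observed = observed, ratio = ratio,
                 pass = ratio >= lower & ratio <= upper)
}

#' Sensitivity grid over milk pH and creamatocrit
#'
#' Evaluates the phase-distribution model over the Cartesian grid of milk
#' pH and creamatocrit values at fixed plasma exposure, propagating each
#' M/P into the daily and relative infant dose.
#'
#' @param compound A [compound_profile()].
#' @param milk_ph_values Milk pH grid.
#' @param creamatocrit_values Creamatocrit (%) grid.
#' @param auc_plasma Plasma AUC over 0-24 h held fixed (mg·h/L).
#' @param maternal_weight,infant_weight Weights (kg) for the dose metrics.
#' @param dose Maternal daily dose (mg).
#' @param ... Further arguments to [milk_composition()] (e.g. `fu_milk`).
#' @return A tibble: `ph_milk`, `creamatocrit`, `mp_ratio`, `did`, `rid`.
#' @export
#' @examples
#' sensitivity_grid(doravirine(), c(6.8, 7.0, 7.2), c(2, 4, 6))
sensitivity_grid <- function(compound,
                             milk_ph_values, creamatocrit_values,
                             auc_plasma = 13.73, maternal_weight = 80.8,
                             infant_weight = 6.6, dose = 100, ...) {
  if (length(milk_ph_values) == 0 || length(creamatocrit_values) == 0) {
    abort("Grids must be nonempty.")
  }
  tidyr::expand_grid(ph_milk = milk_ph_values,
                     creamatocrit = creamatocrit_values) |>
    dplyr::mutate(
      mp_ratio = purrr::map2_dbl(.data$ph_milk, .data$creamatocrit,
        function(ph, cr) {
          milk_plasma_ratio(
            compound,
            milk_composition(ph_milk = ph, creamatocrit = cr, ...))$mp_ratio
        }),
      did = did_estimated(.data$mp_ratio * auc_plasma, infant_weight),
      rid = rid(.data$did / infant_weight, dose, maternal_weight))
}

#' Predicted-versus-observed study report
#'
#' Compares a (synthetic or clinical) study dataset against a population
#' simulation: per-matrix NCA summary tables (geometric mean and CV%),
#' per-subject exposure metrics with median (IQR) summaries,
#' predicted:observed ratio checks for AUC_inf, Cmax and half-life, and
#' the simulated VPC bands with observed overlay points.
#'
#' @param study A `lactation_study` (or a compatible list with `profiles`,
#'   `subjects`, `collections`, `design`).
#' @param ensemble A `simulation_ensemble` simulated under the same
#'   regimen, plasma matrix.
#' @param mp_predicted Predicted milk:plasma ratio used to scale the
#'   simulated plasma ensemble into milk for the milk-side comparison;
#'   default from the phase-distribution model for the study compound at
#'   the roster's median postpartum age.
#' @return An object of class `study_report`: list of tibbles
#'   `observed_nca`, `predicted_nca`, `ratio_checks`, `exposure`,
#'   `exposure_summary`, `vpc`, `observed_points`.
#' @export
#' @examples
#' study <- generate_study(seed = 7)
#' ens <- simulate_population(doravirine(), dosing_regimen(100),
#'                            study$subjects, n_trials = 10, seed = 7)
#' rep <- study_report(study, ens)
#' rep$ratio_checks
study_report <- function(study, ensemble, mp_predicted = NULL) {
  if (abs(ensemble$regimen$dose - study$design$dose) > 1e-9) {
    abort("Ensemble and study must use the same dose.")
  }
  if (is.null(mp_predicted)) {
    mp_predicted <- milk_plasma_ratio(
      study$compound,
      milk_composition(median(study$subjects$postpartum_age)))$mp_ratio
  }
  obs_nca <- run_nca(study$profiles)
  sim_nca <- run_nca(dplyr::mutate(
    ensemble$profiles,
    subject_id = paste(.data$trial, .data$subject_id, sep = ":")))
  sim_milk_nca <- dplyr::mutate(
    sim_nca,
    matrix = "milk",
    dplyr::across(c("cmax", "auc_0_24", "auc_last", "auc_inf"),
                  ~ .x * mp_predicted))

  gm_table <- function(nca) {
    nca |>
      tidyr::pivot_longer(c("auc_inf", "cmax", "t_half"),
                          names_to = "parameter") |>
      dplyr::filter(is.finite(.data$value)) |>
      dplyr::group_by(.data$matrix, .data$parameter) |>
      dplyr::reframe(geomean_cv(.data$value))
  }
  observed_nca <- gm_table(obs_nca)
  predicted_nca <- gm_table(dplyr::bind_rows(sim_nca, sim_milk_nca))

  both <- dplyr::inner_join(predicted_nca, observed_nca,
                            by = c("matrix", "parameter"),
                            suffix = c("_pred", "_obs"))
  ratio_checks <- pred_obs_ratio(
    both$geo_mean_pred, both$geo_mean_obs,
    parameter = paste(both$matrix, both$parameter, sep = "_"))

  metrics <- exposure_metrics(obs_nca, study$subjects, study$collections,
                              dose = study$design$dose)
  vpc <- summarize_vpc(ensemble)
  observed_points <- dplyr::filter(study$profiles, !.data$blq)

  structure(list(observed_nca = observed_nca,
                 predicted_nca = predicted_nca,
                 ratio_checks = ratio_checks,
                 exposure = metrics,
                 exposure_summary = summarize_exposure(metrics),
                 vpc = vpc,
                 observed_points = observed_points,
                 mp_predicted = mp_predicted),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n\nPredicted:observed ratio checks (window 0.7-1.43):\n")
  print(as.data.frame(x$ratio_checks), digits = 3, row.names = FALSE)
  cat("\nExposure metrics summary:\n")
  print(as.data.frame(x$exposure_summary), digits = 3, row.names = FALSE)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.study_report <- function(x, ...) {
  x$ratio_checks
}
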