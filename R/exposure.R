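#' Milk-to-plasma exposure ratio
#'
#' \eqn{M/P = AUC_{milk}/AUC_{plasma}}, reported to two decimals in study
#' summaries.
#'
#' @param auc_milk,auc_plasma AUCs (mg·h/L) over matching intervals.
#' @return Dimensionless ratio (vectorized).
#' @export
#' @examples
#' mp_ratio(5.31, 20.75)  # 0.26 after rounding
mp_ratio <- function(auc_milk, auc_plasma) {
  if (any(auc_plasma <= 0, na.rm = TRUE)) abort("`auc_plasma` must be > 0.")
  if (any(auc_milk < 0, na.rm = TRUE)) abort("`auc_milk` must be >= 0.")
  auc_milk / auc_plasma
}

#' Daily infant dose from expressed milk collections
#'
#' Sum over the day's milk collections of concentration times expressed
#' volume: \eqn{DID = \sum_i C_i V_i} (mg/day), volumes supplied in mL.
#'
#' @param conc_mg_L Concentration in each collection (mg/L).
#' @param volume_mL Expressed volume of each collection (mL).
#' @return Daily infant dose (mg/day).
#' @export
#' @examples
#' did_actual(c(0.31, 0.25, 0.15), c(120, 80, 150))
did_actual <- function(conc_mg_L, volume_mL) {
  if (length(conc_mg_L) == 0) return(0)
  stopifnot(length(conc_mg_L) == length(volume_mL))
  if (any(conc_mg_L < 0) || any(volume_mL < 0)) {
    abort("Concentrations and volumes must be >= 0.")
  }
  sum(conc_mg_L * volume_mL / 1000)
}

#' Daily infant dose at a standardized milk intake
#'
#' \eqn{DID = (AUC_{milk}/24)\times(150\times w_{infant}/1000)} mg/day:
#' the average milk concentration over the day times a standardized intake
#' of 150 mL/kg/day. Over a single-dose day the average concentration is
#' AUC over 0-24 h divided by 24; at once-daily steady state it is
#' AUC over the dosing interval divided by 24 (equal to single-dose
#' AUC_inf/24 under linear PK).
#'
#' @param auc_milk Milk AUC over the 24 h day (mg·h/L).
#' @param infant_weight Infant weight (kg).
#' @param intake_ml_kg Daily milk intake per kg (mL/kg/day), default 150.
#' @return Estimated daily infant dose (mg/day), vectorized.
#' @export
#' @examples
#' did_estimated(5.31, infant_weight = 5.4)
did_estimated <- function(auc_milk, infant_weight, intake_ml_kg = 150) {
  if (any(auc_milk < 0, na.rm = TRUE)) abort("`auc_milk` must be >= 0.")
  if (any(infant_weight <= 0, na.rm = TRUE)) abort("`infant_weight` must be > 0.")
  (auc_milk / 24) * (intake_ml_kg * infant_weight / 1000)
}

#' Relative infant dose
#'
#' Weight-normalized infant dose as a percentage of the weight-normalized
#' maternal dose:
#' \eqn{RID = 100 \times (dose_{infant}/kg) / (dose_{maternal}/kg)}.
#' An RID below 5-10% is the conventional screening threshold for drugs in
#' breastmilk.
#'
#' @param infant_dose_per_kg Infant dose (mg/kg/day).
#' @param maternal_dose Maternal daily dose (mg/day).
#' @param maternal_weight Maternal weight (kg).
#' @return RID (%), vectorized.
#' @export
#' @examples
#' rid(5.31 / 24 * 0.150, maternal_dose = 100, maternal_weight = 80.8)
rid <- function(infant_dose_per_kg, maternal_dose, maternal_weight) {
  if (any(maternal_dose <= 0, na.rm = TRUE) ||
      any(maternal_weight <= 0, na.rm = TRUE)) {
    abort("Maternal dose and weight must be > 0.")
  }
  if (any(infant_dose_per_kg < 0, na.rm = TRUE)) {
    abort("Infant dose must be >= 0.")
  }
  100 * infant_dose_per_kg / (maternal_dose / maternal_weight)
}

#' Fraction of drug remaining after a washout period
#'
#' \eqn{2^{-duration/t_{1/2}}}; with a 15 h half-life, a 4-day (96 h)
#' washout leaves about 1.2% of the dose in the body, the rationale for a
#' 4-day pump-and-discard period after single-dose studies.
#'
#' @param t_half Half-life (h).
#' @param duration Washout duration (h).
#' @return Fraction remaining, vectorized.
#' @export
#' @examples
#' washout_fraction(15, 96)
washout_fraction <- function(t_half, duration) {
  if (any(t_half <= 0)) abort("`t_half` must be > 0.")
  2^(-duration / t_half)
}

#' Per-subject infant-exposure metrics from NCA results
#'
#' Joins plasma and milk NCA rows per subject and computes the exposure
#' metrics: M/P from AUC_inf (matching the reporting convention of
#' clinical lactation studies), the estimated daily infant dose from the
#' milk AUC over 0-24 h at 150 mL/kg/day, the relative infant dose, and
#' (when collections are given) the actual daily infant dose from
#' expressed volumes.
#'
#' @param nca A [run_nca()] result containing plasma and milk rows.
#' @param subjects Subject roster with `id`, `weight` (maternal, kg) and
#'   `infant_weight` (kg).
#' @param collections Optional milk collections tibble with `subject_id`,
#'   `conc_mg_L`, `volume_mL`.
#' @param dose Maternal daily dose (mg/day).
#' @param intake_ml_kg Standardized intake (mL/kg/day).
#' @return A tibble with one row per subject: `subject_id`, `mp_ratio`,
#'   `did_actual` (NA without collections), `did_estimated`, `rid`.
#' @export
#' @examples
#' study <- generate_study(seed = 1)
#' nca <- run_nca(study$profiles)
#' exposure_metrics(nca, study$subjects, study$collections)
exposure_metrics <- function(nca, subjects, collections = NULL, dose = 100,
                             intake_ml_kg = 150) {
  wide <- nca |>
    dplyr::select("subject_id", "matrix", "auc_0_24", "auc_inf") |>
    tidyr::pivot_wider(names_from = "matrix",
                       values_from = c("auc_0_24", "auc_inf"))
  out <- wide |>
    dplyr::left_join(
      dplyr::select(subjects, subject_id = "id", "weight", "infant_weight"),
      by = "subject_id") |>
    dplyr::mutate(
      mp_ratio = mp_ratio(.data$auc_inf_milk, .data$auc_inf_plasma),
      did_estimated = did_estimated(.data$auc_0_24_milk,
                                    .data$infant_weight, intake_ml_kg),
      rid = rid(.data$did_estimated / .data$infant_weight, dose,
                .data$weight))
  out$did_actual <- if (!is.null(collections)) {
    purrr::map_dbl(out$subject_id, function(id) {
      cc <- collections[collections$subject_id == id, ]
      did_actual(cc$conc_mg_L, cc$volume_mL)
    })
  } else {
    NA_real_
  }
  dplyr::select(out, "subject_id", "mp_ratio", "did_actual",
                "did_estimated", "rid")
}

#' Population summary of exposure metrics
#'
#' Geometric mean (CV%) for the M/P ratio and median (IQR) for the dose
#' metrics, the conventions used when reporting lactation studies.
#'
#' @param metrics Output of [exposure_metrics()].
#' @return A tibble with one row per metric: `metric`, `geo_mean`,
#'   `cv_pct`, `median`, `iqr_low`, `iqr_high`, `n`.
#' @export
summarize_exposure <- function(metrics) {
  one <- function(name, x) {
    x <- x[is.finite(x)]
    if (length(x) == 0) {
      return(tibble::tibble(metric = name, geo_mean = NA_real_,
                            cv_pct = NA_real_, median = NA_real_,
                            iqr_low = NA_real_, iqr_high = NA_real_, n = 0L))
    }
    gm <- if (all(x > 0)) geomean_cv(x) else
      tibble::tibble(geo_mean = NA_real_, cv_pct = NA_real_)
    mi <- median_iqr(x)
    tibble::tibble(metric = name, geo_mean = gm$geo_mean, cv_pct = gm$cv_pct,
                   median = mi$median, iqr_low = mi$iqr_low,
                   iqr_high = mi$iqr_high, n = length(x))
  }
  dplyr::bind_rows(
    one("mp_ratio", metrics$mp_ratio),
    one("did_actual", metrics$did_actual),
    one("did_estimated", metrics$did_estimated),
    one("rid", metrics$rid)
  )
}
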