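#' Population prediction of milk transfer and infant exposure
#'
#' The in-silico arm of a lactation risk assessment: simulates a virtual
#' lactating population under the given regimen, predicts each subject's
#' milk:plasma ratio from the phase-distribution model at her postpartum
#' milk pH, runs NCA on each simulated plasma profile, scales exposure
#' into milk, and computes the infant-dose metrics (estimated daily
#' infant dose at 150 mL/kg/day from the milk AUC over the dosing day,
#' and the relative infant dose).
#'
#' @param compound A [compound_profile()].
#' @param dose Oral dose (mg), once daily.
#' @param n_subjects Virtual population size.
#' @param seed Integer seed.
#' @param demographics A [demographic_spec()].
#' @param creamatocrit Creamatocrit (%) of the population's milk.
#' @param milk_anchors Milk pH anchors, see [milk_ph()].
#' @param times Simulation grid (h) for the single-dose profiles.
#' @param intake_ml_kg Standardized infant intake (mL/kg/day).
#' @return A list of class `exposure_prediction`: `per_subject` (tibble
#'   with demographics, individual parameters, `mp_ratio`,
#'   `auc_inf_plasma`, `auc_0_24_milk`, `did_estimated`, `rid`) and
#'   `summary` (tibble of GM/CV and median/IQR rows for the key
#'   quantities).
#' @export
#' @examples
#' pred <- predict_infant_exposure(doravirine(), n_subjects = 25, seed = 1)
#' pred$summary
predict_infant_exposure <- function(compound, dose = 100, n_subjects = 100,
                                    seed = 1,
                                    demographics = demographic_spec(),
                                    creamatocrit = 4,
                                    milk_anchors = milk_ph_anchors(),
                                    times = seq(0, 24, by = 0.1),
                                    intake_ml_kg = 150) {
  subjects <- sample_subjects(demographics, n_subjects, seed = seed)
  regimen <- dosing_regimen(dose = dose, n_doses = 1)
  iiv <- apply_iiv(compound, n = n_subjects)  # continues the seeded stream

  per_subject <- purrr::map_dfr(seq_len(n_subjects), function(i) {
    indiv <- compound
    indiv$cl_f <- iiv$cl_f[i]; indiv$v_f <- iiv$v_f[i]; indiv$ka <- iiv$ka[i]
    mp <- milk_plasma_ratio(
      indiv,
      milk_composition(postpartum_age = subjects$postpartum_age[i],
                       creamatocrit = creamatocrit,
                       anchors = milk_anchors))$mp_ratio
    prof <- simulate_profile(indiv, regimen, times,
                             subject_id = subjects$id[i])
    nca <- nca_summary(prof$time_h, prof$conc_mg_L)
    tibble::tibble(
      subject_id = subjects$id[i],
      weight = subjects$weight[i],
      postpartum_age = subjects$postpartum_age[i],
      infant_weight = subjects$infant_weight[i],
      cl_f = indiv$cl_f, v_f = indiv$v_f, ka = indiv$ka,
      mp_ratio = mp,
      auc_inf_plasma = nca$auc_inf,
      auc_0_24_plasma = nca$auc_0_24,
      cmax_plasma = nca$cmax,
      t_half = nca$t_half,
      auc_0_24_milk = mp * nca$auc_0_24)
  })

  per_subject <- per_subject |>
    dplyr::mutate(
      did_estimated = did_estimated(.data$auc_0_24_milk,
                                    .data$infant_weight, intake_ml_kg),
      rid = rid(.data$did_estimated / .data$infant_weight, dose,
                .data$weight))

  sum_row <- function(name, x) {
    dplyr::bind_cols(tibble::tibble(quantity = name),
                     geomean_cv(x)[, c("geo_mean", "cv_pct")],
                     median_iqr(x)[, c("median", "iqr_low", "iqr_high")])
  }
  summary <- dplyr::bind_rows(
    sum_row("mp_ratio", per_subject$mp_ratio),
    sum_row("auc_inf_plasma", per_subject$auc_inf_plasma),
    sum_row("cmax_plasma", per_subject$cmax_plasma),
    sum_row("t_half", per_subject$t_half),
    sum_row("did_estimated", per_subject$did_estimated),
    sum_row("rid", per_subject$rid))

  structure(list(per_subject = per_subject, summary = summary,
                 seed = as.integer(seed), dose = dose),
            class = "exposure_prediction")
}

#' @export
print.exposure_prediction <- function(x, ...) {
  cat(sprintf("<exposure_prediction> n = %d virtual subjects, %g mg, seed %d\n\n",
              nrow(x$per_subject), x$dose, x$seed))
  print(as.data.frame(x$summary), digits = 3, row.names = FALSE)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.exposure_prediction <- function(x, ...) {
  x$per_subject
}

#' @exportS3Method generics::glance
glance.exposure_prediction <- function(x, ...) {
  s <- x$summary
  g <- function(q, col) s[[col]][s$quantity == q]
  tibble::tibble(
    n = nrow(x$per_subject),
    gm_mp_ratio = g("mp_ratio", "geo_mean"),
    gm_auc_inf_plasma = g("auc_inf_plasma", "geo_mean"),
    median_did = g("did_estimated", "median"),
    median_rid = g("rid", "median"),
    seed = x$seed)
}
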