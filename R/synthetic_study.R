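#' Design of a synthetic clinical lactation study
#'
#' Defaults emulate a single-dose clinical lactation study: 8 lactating
#' subjects, one 100 mg oral dose, rich plasma sampling
#' (0,1,2,3,4,5,6,8,10,12,24 h), sparser milk sampling (0,2,4,6,12,24 h),
#' an assay LLOQ of 0.01 mg/L, 15% proportional residual error and
#' uniform 20-150 mL expressed milk volumes per collection.
#'
#' @param n_subjects Number of subjects.
#' @param dose Oral dose (mg).
#' @param plasma_times,milk_times Sampling times (h), strictly increasing.
#' @param lloq Lower limit of quantification (mg/L).
#' @param residual_cv Proportional (log-normal) residual error CV.
#' @param volume_range Range (mL) of expressed volume per milk collection.
#' @return A `study_design` list.
#' @export
study_design <- function(n_subjects = 8, dose = 100,
                         plasma_times = c(0, 1, 2, 3, 4, 5, 6, 8, 10, 12, 24),
                         milk_times = c(0, 2, 4, 6, 12, 24),
                         lloq = 0.01, residual_cv = 0.15,
                         volume_range = c(20, 150)) {
  if (any(diff(plasma_times) <= 0) || any(diff(milk_times) <= 0)) {
    abort("Sampling times must be strictly increasing.")
  }
  if (lloq <= 0) abort("`lloq` must be > 0.")
  if (residual_cv < 0) abort("`residual_cv` must be >= 0.")
  structure(list(n_subjects = as.integer(n_subjects), dose = dose,
                 plasma_times = plasma_times, milk_times = milk_times,
                 lloq = lloq, residual_cv = residual_cv,
                 volume_range = volume_range),
            class = "study_design")
}

#' Censor a profile at the assay LLOQ
#'
#' Quantifiable values are kept; values below `lloq` (including true
#' zeros) are flagged `blq` with `conc_mg_L` set to `NA`. Idempotent.
#'
#' @param profile Profile tibble.
#' @param lloq LLOQ (mg/L), > 0.
#' @return The censored profile.
#' @export
censor_lloq <- function(profile, lloq) {
  if (lloq <= 0) abort("`lloq` must be > 0.")
  limit <- lloq  # avoid data-masking collision with the `lloq` column
  profile |>
    dplyr::mutate(
      blq = .data$blq | (!is.na(.data$conc_mg_L) & .data$conc_mg_L < limit),
      conc_mg_L = ifelse(.data$blq, NA_real_, .data$conc_mg_L),
      lloq = limit)
}

#' Generate a complete synthetic clinical lactation study
#'
#' End-to-end data generator: samples a subject roster, draws individual
#' PK parameters (log-normal IIV), simulates each subject's plasma
#' profile, derives that subject's milk:plasma ratio from the
#' phase-distribution model at her postpartum milk pH, scales the plasma
#' profile into milk, adds multiplicative log-normal residual error
#' (pre-dose samples are true zeros and stay exact), censors at the LLOQ
#' and draws expressed milk volumes per collection. The generating truth
#' (individual parameters, true M/P, true AUCs) is retained for recovery
#' tests.
#'
#' @param design A [study_design()].
#' @param compound A [compound_profile()].
#' @param seed Integer seed; the whole dataset is reproducible under it.
#' @param demographics A [demographic_spec()].
#' @param creamatocrit Creamatocrit (%) used for every subject's milk.
#' @param milk_anchors Milk pH anchors, see [milk_ph()].
#' @param fu_milk Optional unbound-fraction-in-milk override.
#' @param k_fat Optional list with elements `a`, `b` overriding the
#'   [k_fat_aqueous()] coefficients.
#' @return An object of class `lactation_study`: list with `design`,
#'   `subjects`, `profiles` (observed, censored), `collections`, `truth`
#'   and `seed`.
#' @export
#' @examples
#' study <- generate_study(seed = 42)
#' dplyr::count(study$profiles, matrix)
generate_study <- function(design = study_design(),
                           compound = doravirine(), seed = 1,
                           demographics = demographic_spec(),
                           creamatocrit = 4,
                           milk_anchors = milk_ph_anchors(),
                           fu_milk = NULL, k_fat = NULL) {
  stopifnot(inherits(design, "study_design"))
  subjects <- sample_subjects(demographics, design$n_subjects, seed = seed)
  # subject sampling reseeds; continue the stream for all study-level draws
  regimen <- dosing_regimen(dose = design$dose, n_doses = 1)
  iiv <- apply_iiv(compound, n = design$n_subjects)
  sdlog <- sqrt(log(1 + design$residual_cv^2))

  per_subject <- purrr::map(seq_len(design$n_subjects), function(i) {
    indiv <- compound
    indiv$cl_f <- iiv$cl_f[i]; indiv$v_f <- iiv$v_f[i]; indiv$ka <- iiv$ka[i]
    milk_state <- milk_composition(
      postpartum_age = subjects$postpartum_age[i],
      creamatocrit = creamatocrit, anchors = milk_anchors,
      fu_milk = fu_milk)
    k_fat_aq <- if (!is.null(k_fat)) {
      k_fat_aqueous(compound$logP, k_fat$a, k_fat$b)
    }
    mp <- milk_plasma_ratio(indiv, milk_state, k_fat_aq = k_fat_aq)
    plasma <- simulate_profile(indiv, regimen, design$plasma_times,
                               subject_id = subjects$id[i])
    milk <- milk_profile(
      simulate_profile(indiv, regimen, design$milk_times,
                       subject_id = subjects$id[i]), mp)
    true_prof <- dplyr::bind_rows(plasma, milk)
    noisy <- dplyr::mutate(
      true_prof,
      conc_mg_L = .data$conc_mg_L *
        ifelse(.data$time_h > 0,
               exp(rnorm(dplyr::n(), 0, sdlog)), 1))
    observed <- censor_lloq(noisy, design$lloq)
    obs_milk <- observed[observed$matrix == "milk" & observed$time_h > 0, ]
    collections <- tibble::tibble(
      subject_id = subjects$id[i],
      time_h = obs_milk$time_h,
      conc_mg_L = ifelse(obs_milk$blq, 0, obs_milk$conc_mg_L),
      volume_mL = runif(nrow(obs_milk), design$volume_range[1],
                        design$volume_range[2]))
    truth <- tibble::tibble(
      subject_id = subjects$id[i],
      cl_f = indiv$cl_f, v_f = indiv$v_f, ka = indiv$ka,
      mp_ratio = mp$mp_ratio,
      ph_milk = milk_state$ph_milk,
      auc_inf_plasma = indiv$f_abs * design$dose / indiv$cl_f,
      t_half = log(2) * indiv$v_f / indiv$cl_f)
    list(observed = observed, collections = collections, truth = truth)
  })

  structure(
    list(design = design,
         subjects = subjects,
         profiles = purrr::list_rbind(purrr::map(per_subject, "observed")),
         collections = purrr::list_rbind(purrr::map(per_subject,
                                                    "collections")),
         truth = purrr::list_rbind(purrr::map(per_subject, "truth")),
         compound = compound,
         seed = as.integer(seed)),
    class = "lactation_study")
}

#' @export
print.lactation_study <- function(x, ...) {
  cat(sprintf("<lactation_study> %d subjects, %g mg single dose, seed %d\n",
              x$design$n_subjects, x$design$dose, x$seed))
  cat(sprintf("  %d plasma + %d milk samples/subject, LLOQ %g mg/L, residual CV %.0f%%\n",
              length(x$design$plasma_times), length(x$design$milk_times),
              x$design$lloq, 100 * x$design$residual_cv))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.lactation_study <- function(x, ...) {
  tibble::tibble(
    n_subjects = x$design$n_subjects,
    dose_mg = x$design$dose,
    n_samples = nrow(x$profiles),
    n_blq = sum(x$profiles$blq & x$profiles$time_h > 0),
    lloq = x$design$lloq,
    residual_cv = x$design$residual_cv,
    true_gm_mp = exp(mean(log(x$truth$mp_ratio))),
    seed = x$seed)
}
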