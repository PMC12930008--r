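#' Fraction of drug un-ionized at a given pH
#'
#' Henderson-Hasselbalch ionization. For a monoprotic base the neutral
#' (permeating) fraction is \eqn{1/(1+10^{pKa-pH})}; for a monoprotic acid
#' \eqn{1/(1+10^{pH-pKa})}; a neutral compound is fully un-ionized.
#'
#' @param pKa Acid dissociation constant.
#' @param pH pH of the phase, in \[0, 14\].
#' @param ionization_class `"monoprotic_base"`, `"monoprotic_acid"` or
#'   `"neutral"`.
#' @return Un-ionized fraction in (0, 1].
#' @export
#' @examples
#' fraction_unionized(8, 7.4, "monoprotic_base")
fraction_unionized <- function(pKa, pH, ionization_class) {
  if (any(pH < 0 | pH > 14)) abort("`pH` must be in [0, 14].")
  switch(ionization_class,
    monoprotic_base = 1 / (1 + 10^(pKa - pH)),
    monoprotic_acid = 1 / (1 + 10^(pH - pKa)),
    neutral = rep(1, length.out = max(length(pKa), length(pH))),
    abort(sprintf("Unknown ionization class '%s'.", ionization_class))
  )
}

#' Default dynamic milk pH anchors
#'
#' Milk pH rises from about 7.0 in early mature milk towards plasma-like
#' values late in lactation. The default trajectory is linear from pH 7.0
#' at 0.5 months to pH 7.4 at 12 months postpartum.
#'
#' @return A tibble with columns `months` and `ph`.
#' @export
milk_ph_anchors <- function() {
  tibble::tibble(months = c(0.5, 12), ph = c(7.0, 7.4))
}

#' Breastmilk pH at a given postpartum age
#'
#' Monotone piecewise-linear interpolation over pH anchors, constant
#' beyond the first/last anchor. Ages above 12 months are outside the
#' supported lactation range and are clamped with a warning.
#'
#' @param postpartum_age Months postpartum (vectorized).
#' @param anchors Data frame with `months` and `ph` columns, `ph`
#'   non-decreasing in `months`.
#' @return Milk pH at each age.
#' @export
#' @examples
#' milk_ph(c(0.5, 6.5, 12))
milk_ph <- function(postpartum_age, anchors = milk_ph_anchors()) {
  if (any(postpartum_age < 0)) abort("`postpartum_age` must be >= 0.")
  if (any(diff(anchors$ph) < 0) || any(diff(anchors$months) <= 0)) {
    abort("pH anchors must be increasing in months and non-decreasing in pH.")
  }
  if (any(postpartum_age > 12)) {
    warn("Postpartum age > 12 months is outside the supported lactation range; clamped to 12.")
    postpartum_age <- pmin(postpartum_age, 12)
  }
  stats::approx(anchors$months, anchors$ph, xout = postpartum_age,
                rule = 2)$y
}

#' Convert creamatocrit to milk fat volume fraction
#'
#' Creamatocrit is the packed-fat percentage of a centrifuged milk sample;
#' the default conversion takes it directly as the fat volume fraction
#' (fraction = creamatocrit/100).
#'
#' @param creamatocrit Creamatocrit (%), in \[0, 15\].
#' @return Fat volume fraction.
#' @export
fat_fraction_from_creamatocrit <- function(creamatocrit) {
  if (any(creamatocrit < 0 | creamatocrit > 15)) {
    abort("`creamatocrit` must be in [0, 15] %.")
  }
  creamatocrit / 100
}

#' Default unbound fraction in milk from the plasma unbound fraction
#'
#' Milk has roughly one seventh of the binding protein of plasma; assuming
#' the bound:unbound equilibrium scales with protein content,
#' \eqn{fu_{milk} = fu_p / (fu_p + (1-fu_p)/7)}.
#'
#' @param fu_plasma Plasma unbound fraction in (0, 1].
#' @param protein_ratio Milk:plasma binding-protein ratio (default 1/7).
#' @return Unbound fraction in milk.
#' @export
default_fu_milk <- function(fu_plasma, protein_ratio = 1 / 7) {
  fu_plasma / (fu_plasma + (1 - fu_plasma) * protein_ratio)
}

#' Milk composition state for one subject
#'
#' Bundles the phase-distribution inputs: milk and plasma pH, fat content
#' (via creamatocrit) and unbound fraction in milk. By default milk pH
#' follows the dynamic postpartum trajectory ([milk_ph()]) and `fu_milk`
#' is derived from the compound's plasma binding when the ratio is
#' computed.
#'
#' @param postpartum_age Months postpartum.
#' @param ph_milk Milk pH; default interpolated from `anchors`.
#' @param ph_plasma Plasma pH (default 7.4).
#' @param creamatocrit Creamatocrit (%), default 4 (mature milk).
#' @param fu_milk Optional unbound fraction in milk override.
#' @param anchors pH anchors passed to [milk_ph()].
#' @return An object of class `milk_composition`.
#' @export
#' @examples
#' milk_composition(postpartum_age = 6.5)
milk_composition <- function(postpartum_age = 6.5, ph_milk = NULL,
                             ph_plasma = 7.4, creamatocrit = 4,
                             fu_milk = NULL, anchors = milk_ph_anchors()) {
  if (is.null(ph_milk)) ph_milk <- milk_ph(postpartum_age, anchors)
  if (ph_milk < 6 || ph_milk > 8) abort("`ph_milk` must be in [6, 8].")
  fat_fraction <- fat_fraction_from_creamatocrit(creamatocrit)
  if (!is.null(fu_milk) && (fu_milk <= 0 || fu_milk > 1)) {
    abort("`fu_milk` must be in (0, 1].")
  }
  structure(
    list(postpartum_age = postpartum_age, ph_milk = ph_milk,
         ph_plasma = ph_plasma, creamatocrit = creamatocrit,
         fat_fraction = fat_fraction, fu_milk = fu_milk),
    class = "milk_composition"
  )
}

#' Milk-fat to milk-aqueous partition coefficient from logP
#'
#' Partitioning of the un-ionized species into milk fat is correlated with
#' lipophilicity: \eqn{\log_{10} k = a\,\log P + b}. The default slope is
#' calibrated once so the shipped doravirine configuration (logP 3.0)
#' reproduces a population milk:plasma ratio of 0.39; see the methods
#' vignette.
#'
#' @param logP Compound logP.
#' @param a,b Regression coefficients.
#' @return Dimensionless fat:aqueous partition coefficient.
#' @export
k_fat_aqueous <- function(logP, a = 0.253671, b = 0) {
  10^(a * logP + b)
}

#' Milk-to-plasma ratio by the phase-distribution model
#'
#' Predicts the milk:plasma concentration ratio of a passively
#' distributing drug from pH partitioning (ion trapping), protein binding
#' in both phases and partitioning into milk fat:
#' \deqn{M/P = \phi_p\, fu_p \left[\frac{1-f_{fat}}{\phi_m\, fu_m} +
#'       f_{fat}\, k_{fat:aq}\right]}
#' where \eqn{\phi_p,\phi_m} are the un-ionized fractions at plasma and
#' milk pH, \eqn{fu_p, fu_m} the unbound fractions, and \eqn{f_{fat}} the
#' milk fat volume fraction. The skim (aqueous + protein) and fat
#' contributions are returned separately.
#'
#' @param compound A [compound_profile()].
#' @param milk A [milk_composition()].
#' @param k_fat_aq Fat:aqueous partition coefficient of the un-ionized
#'   species; default from [k_fat_aqueous()] at the compound's logP.
#' @return An object of class `milk_partition` with elements `mp_ratio`,
#'   `skim_term`, `fat_term`, `phi_plasma`, `phi_milk`, `fu_milk`.
#' @export
#' @examples
#' milk_plasma_ratio(doravirine(), milk_composition(6.5))
milk_plasma_ratio <- function(compound, milk, k_fat_aq = NULL) {
  stopifnot(inherits(compound, "compound_profile"),
            inherits(milk, "milk_composition"))
  fu_m <- milk$fu_milk %||% default_fu_milk(compound$fu_plasma)
  if (fu_m <= 0) abort("`fu_milk` must be > 0.")
  if (is.null(k_fat_aq)) k_fat_aq <- k_fat_aqueous(compound$logP)
  phi_p <- fraction_unionized(compound$pKa, milk$ph_plasma,
                              compound$ionization_class)
  phi_m <- fraction_unionized(compound$pKa, milk$ph_milk,
                              compound$ionization_class)
  skim <- (1 - milk$fat_fraction) / (phi_m * fu_m)
  fat <- milk$fat_fraction * k_fat_aq
  structure(
    list(mp_ratio = phi_p * compound$fu_plasma * (skim + fat),
         skim_term = skim, fat_term = fat,
         phi_plasma = phi_p, phi_milk = phi_m, fu_milk = fu_m),
    class = "milk_partition"
  )
}

#' @export
print.milk_partition <- function(x, ...) {
  cat(sprintf("<milk_partition> M/P = %.3f (skim %.3f + fat %.3f, phi_p %.4f, phi_m %.4f)\n",
              x$mp_ratio, x$skim_term, x$fat_term, x$phi_plasma, x$phi_milk))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.milk_partition <- function(x, ...) {
  tibble::tibble(mp_ratio = x$mp_ratio, skim_term = x$skim_term,
                 fat_term = x$fat_term, phi_plasma = x$phi_plasma,
                 phi_milk = x$phi_milk, fu_milk = x$fu_milk)
}

#' Derive a milk profile from a plasma profile
#'
#' The lactation model assumes instantaneous equilibration: milk
#' concentration is the plasma concentration scaled by a fixed M/P ratio,
#' so milk and plasma share Tmax and half-life.
#'
#' @param plasma A plasma profile tibble (as from [simulate_profile()]).
#' @param mp Milk:plasma ratio (> 0); a scalar or a `milk_partition`.
#' @return The profile with `matrix = "milk"` and scaled concentrations.
#' @export
milk_profile <- function(plasma, mp) {
  if (inherits(mp, "milk_partition")) mp <- mp$mp_ratio
  if (!is.numeric(mp) || mp <= 0) abort("`mp` must be > 0.")
  dplyr::mutate(plasma, matrix = "milk",
                conc_mg_L = .data$conc_mg_L * mp)
}
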