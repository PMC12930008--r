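#' Distribution specification for one demographic variable
#'
#' @param kind `"lognormal"`, `"uniform"` or `"truncated_normal"`.
#' @param location Median (lognormal, truncated normal) or lower bound
#'   (uniform).
#' @param scale Log-scale SD (lognormal), SD (truncated normal) or upper
#'   bound (uniform).
#' @param min,max Optional truncation bounds.
#' @return A `dist_spec` list.
#' @export
dist_spec <- function(kind = c("lognormal", "uniform", "truncated_normal"),
                      location, scale, min = -Inf, max = Inf) {
  kind <- match.arg(kind)
  if (min >= max) abort("`min` must be < `max`.")
  structure(list(kind = kind, location = location, scale = scale,
                 min = min, max = max), class = "dist_spec")
}

# inverse-CDF sampling under truncation: exact, no rejection loops
.sample_dist <- function(spec, n) {
  u <- runif(n)
  switch(spec$kind,
    uniform = {
      lo <- max(spec$location, spec$min); hi <- min(spec$scale, spec$max)
      lo + u * (hi - lo)
    },
    truncated_normal = {
      plo <- stats::pnorm(spec$min, spec$location, spec$scale)
      phi <- stats::pnorm(spec$max, spec$location, spec$scale)
      stats::qnorm(plo + u * (phi - plo), spec$location, spec$scale)
    },
    lognormal = {
      mu <- log(spec$location)
      plo <- stats::plnorm(max(spec$min, 0), mu, spec$scale)
      phi <- stats::plnorm(spec$max, mu, spec$scale)
      stats::qlnorm(plo + u * (phi - plo), mu, spec$scale)
    })
}

#' Demographic specification for a virtual lactating population
#'
#' Defaults mirror the clinical cohort the model is matched to: median
#' (range) age 32 (28-39) years, weight 80.8 (60.6-140) kg, postpartum
#' age 6.5 months (range 2-38, clamped to the supported 2-12 month
#' simulation window).
#'
#' @param age,weight,postpartum [dist_spec()] objects.
#' @return A `demographic_spec` list.
#' @export
demographic_spec <- function(
    age = dist_spec("truncated_normal", location = 32, scale = 3.5,
                    min = 28, max = 39),
    weight = dist_spec("lognormal", location = 80.8, scale = 0.20,
                       min = 60.6, max = 140),
    postpartum = dist_spec("lognormal", location = 6.5, scale = 0.45,
                           min = 2, max = 12)) {
  structure(list(age = age, weight = weight, postpartum = postpartum),
            class = "demographic_spec")
}

#' Sample a virtual subject roster
#'
#' Draws demographics from a [demographic_spec()] (all samples respect the
#' declared bounds) and pairs each subject with an infant weight from the
#' postpartum-age growth curve ([sample_infant_weight()]).
#'
#' @param spec A [demographic_spec()].
#' @param n Number of subjects.
#' @param seed Integer seed; the roster is reproducible under it.
#' @param infant_cv CV of infant weight around the growth curve.
#' @return A tibble: `id`, `age`, `weight`, `postpartum_age`,
#'   `infant_weight`.
#' @export
#' @examples
#' sample_subjects(demographic_spec(), n = 8, seed = 1)
sample_subjects <- function(spec, n, seed = 1, infant_cv = 0.15) {
  if (n < 1) abort("`n` must be >= 1.")
  set.seed(as.integer(seed))
  pp <- .sample_dist(spec$postpartum, n)
  tibble::tibble(
    id = sprintf("S%03d", seq_len(n)),
    age = .sample_dist(spec$age, n),
    weight = .sample_dist(spec$weight, n),
    postpartum_age = pp,
    infant_weight = sample_infant_weight(pp, cv = infant_cv)
  )
}

#' Default infant growth-curve anchors
#'
#' Linear reference curve from 4.5 kg at 2 months to 9.5 kg at 12 months,
#' constant outside the anchors.
#'
#' @return A tibble with `months` and `weight` columns.
#' @export
infant_weight_anchors <- function() {
  tibble::tibble(months = c(2, 12), weight = c(4.5, 9.5))
}

#' Sample infant weight at a postpartum age
#'
#' Log-normal draw whose median follows a piecewise-linear age-to-weight
#' reference curve; `cv = 0` returns the curve value exactly.
#'
#' @param postpartum_age Months postpartum (vectorized).
#' @param cv Coefficient of variation of the log-normal draw.
#' @param anchors Growth-curve anchors (see [infant_weight_anchors()]).
#' @param seed Optional integer seed; by default draws consume the current
#'   RNG stream so callers control reproducibility with one outer seed.
#' @return Infant weights (kg).
#' @export
sample_infant_weight <- function(postpartum_age, cv = 0.15,
                                 anchors = infant_weight_anchors(),
                                 seed = NULL) {
  if (any(postpartum_age < 0)) abort("`postpartum_age` must be >= 0.")
  if (!is.null(seed)) set.seed(as.integer(seed))
  mu <- stats::approx(anchors$months, anchors$weight,
                      xout = postpartum_age, rule = 2)$y
  if (cv == 0) return(mu)
  sdlog <- sqrt(log(1 + cv^2))
  mu * exp(rnorm(length(mu), 0, sdlog))
}

#' Apply log-normal inter-individual variability to compound parameters
#'
#' Draws individual CL/F, V/F and ka as
#' \eqn{\theta_i = \theta\,e^{\eta_i}}, \eqn{\eta_i \sim N(0, \ln(1+CV^2))},
#' which preserves the population geometric mean of every parameter.
#'
#' @param compound A [compound_profile()] whose `iiv_cv` supplies the CVs.
#' @param n Number of parameter sets to draw.
#' @param seed Optional integer seed; by default draws consume the current
#'   RNG stream.
#' @return A tibble with `n` rows and columns `cl_f`, `v_f`, `ka`.
#' @export
#' @examples
#' apply_iiv(doravirine(), n = 3, seed = 7)
apply_iiv <- function(compound, n = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  draw <- function(theta, cv) {
    if (cv == 0) return(rep(theta, n))
    theta * exp(rnorm(n, 0, sqrt(log(1 + cv^2))))
  }
  tibble::tibble(
    cl_f = draw(compound$cl_f, compound$iiv_cv$cl_f),
    v_f = draw(compound$v_f, compound$iiv_cv$v_f),
    ka = draw(compound$ka, compound$iiv_cv$ka)
  )
}
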