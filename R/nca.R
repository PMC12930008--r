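#' Area under the concentration-time curve by the trapezoidal rule
#'
#' `"lin_up_log_down"` (the default, standard NCA practice) uses the linear
#' trapezoid on rising or equal segments and the logarithmic trapezoid
#' \eqn{(C_1-C_2)\Delta t/\ln(C_1/C_2)} on strictly decreasing positive
#' segments; `"linear"` uses the linear trapezoid throughout. If `t_end`
#' falls between samples the profile is interpolated at `t_end` under the
#' same rule.
#'
#' @param time Sampling times (h), strictly increasing.
#' @param conc Concentrations (mg/L), same length, non-negative.
#' @param t_end Upper integration limit (default: last sample).
#' @param method `"lin_up_log_down"` or `"linear"`.
#' @return AUC (mg·h/L) from the first sample to `min(t_end, max(time))`.
#' @export
#' @examples
#' compute_auc(0:24, rep(1, 25))                 # rectangle: 24
#' t <- seq(0, 24, 0.1); compute_auc(t, exp(-0.1 * t))
compute_auc <- function(time, conc, t_end = max(time),
                        method = c("lin_up_log_down", "linear")) {
  method <- match.arg(method)
  stopifnot(length(time) == length(conc))
  if (any(diff(time) <= 0)) abort("`time` must be strictly increasing.")
  if (any(conc < 0)) abort("Concentrations must be non-negative.")
  if (sum(time <= t_end) < 2) {
    abort("Need at least two observations at or before `t_end`.")
  }
  if (t_end < max(time) && !t_end %in% time) {
    i <- max(which(time < t_end))
    c_end <- if (method == "lin_up_log_down" && conc[i + 1] < conc[i] &&
                 conc[i + 1] > 0) {
      exp(stats::approx(time[i + (0:1)], log(conc[i + (0:1)]), t_end)$y)
    } else {
      stats::approx(time[i + (0:1)], conc[i + (0:1)], t_end)$y
    }
    keep <- time < t_end
    time <- c(time[keep], t_end)
    conc <- c(conc[keep], c_end)
  } else {
    keep <- time <= t_end
    time <- time[keep]
    conc <- conc[keep]
  }
  c1 <- conc[-length(conc)]; c2 <- conc[-1]; dt <- diff(time)
  seg <- (c1 + c2) / 2 * dt
  if (method == "lin_up_log_down") {
    logseg <- c2 < c1 & c2 > 0
    seg[logseg] <- (c1[logseg] - c2[logseg]) * dt[logseg] /
      log(c1[logseg] / c2[logseg])
  }
  sum(seg)
}

#' Terminal elimination rate constant by log-linear regression
#'
#' Fits log concentration against time by least squares over candidate
#' terminal point sets (the last 3, 4, ... points after Tmax, excluding
#' Cmax itself) and keeps the fit with the highest adjusted R-squared
#' (ties broken towards more points). Requires a negative slope.
#'
#' @param time,conc Profile vectors as in [compute_auc()].
#' @return A list with `lambda_z` (1/h), `intercept` (log scale),
#'   `n_points`, `adj_r2`; all `NA` (with `ok = FALSE`) when no valid
#'   terminal slope exists.
#' @export
#' @examples
#' t <- c(1, 2, 4, 8, 12, 24)
#' fit_lambda_z(t, 2 * exp(-0.05 * t))$lambda_z
fit_lambda_z <- function(time, conc) {
  failed <- list(lambda_z = NA_real_, intercept = NA_real_,
                 n_points = NA_integer_, adj_r2 = NA_real_, ok = FALSE)
  pos <- conc > 0
  if (!any(pos)) return(failed)
  i_max <- which.max(conc)
  idx <- which(seq_along(conc) > i_max & pos)
  m <- length(idx)
  if (m < 3) return(failed)
  x <- time[idx]
  y <- log(conc[idx])
  # closed-form least squares for every "last k points" candidate at once,
  # via suffix sums (equivalent to refitting lm() per candidate set)
  sfx <- function(v) rev(cumsum(rev(v)))
  k <- m:1
  sx <- sfx(x); sy <- sfx(y); sxx <- sfx(x^2); sxy <- sfx(x * y)
  syy <- sfx(y^2)
  ssxx <- k * sxx - sx^2
  ssyy <- k * syy - sy^2
  ssxy <- k * sxy - sx * sy
  slope <- ssxy / ssxx
  r2 <- ifelse(ssyy > 0, ssxy^2 / (ssxx * ssyy), 0)
  adj_r2 <- 1 - (1 - r2) * (k - 1) / (k - 2)
  valid <- k >= 3 & is.finite(slope) & slope < 0
  if (!any(valid)) return(failed)
  # highest adjusted R^2; ties (within 1e-12) broken towards more points
  cand <- which(valid)
  best <- cand[order(-round(adj_r2[cand], 12), -k[cand])][1]
  list(lambda_z = -slope[best],
       intercept = (sy[best] - slope[best] * sx[best]) / k[best],
       n_points = as.integer(k[best]), adj_r2 = adj_r2[best], ok = TRUE)
}

# BLQ convention: flagged values before the first quantifiable sample are
# zero; flagged values after Cmax are excluded from AUC and lambda_z.
.prepare_conc <- function(time, conc, blq) {
  if (is.null(blq)) blq <- rep(FALSE, length(conc))
  blq <- blq | is.na(conc)
  conc[blq] <- NA_real_
  first_q <- which(!blq)[1]
  if (is.na(first_q)) return(NULL)
  pre <- blq & seq_along(conc) < first_q
  conc[pre] <- 0
  blq[pre] <- FALSE
  keep <- !blq
  list(time = time[keep], conc = conc[keep])
}

#' Noncompartmental analysis of one profile
#'
#' Computes observed Cmax/Tmax, AUC to 24 h and to the last sample,
#' extrapolates to infinity with the terminal slope
#' (\eqn{AUC_\infty = AUC_{0-tlast} + C_{last}/\lambda_z}) and reports the
#' extrapolated percentage, terminal half-life and regression diagnostics.
#' When no terminal slope can be estimated, `auc_inf`, `t_half` and
#' related fields are `NA` while the observed quantities are still
#' reported.
#'
#' @param time,conc Profile vectors.
#' @param blq Optional logical below-LLOQ flags (see Details in
#'   [run_nca()] for the convention).
#' @param method AUC method, see [compute_auc()].
#' @return A one-row tibble: `cmax`, `tmax`, `auc_0_24`, `auc_last`,
#'   `auc_inf`, `lambda_z`, `t_half`, `pct_extrapolated`,
#'   `n_lambda_points`, `adj_r2`.
#' @export
nca_summary <- function(time, conc, blq = NULL,
                        method = c("lin_up_log_down", "linear")) {
  method <- match.arg(method)
  prep <- .prepare_conc(time, conc, blq)
  if (is.null(prep) || length(prep$time) < 2) {
    abort("Need at least two quantifiable observations for NCA.")
  }
  time <- prep$time; conc <- prep$conc
  cmax <- max(conc)
  tmax <- time[which.max(conc)]
  auc_last <- compute_auc(time, conc, method = method)
  auc_0_24 <- if (max(time) >= 24) {
    compute_auc(time, conc, t_end = 24, method = method)
  } else {
    NA_real_
  }
  lz <- fit_lambda_z(time, conc)
  clast <- conc[max(which(conc > 0))]
  auc_inf <- if (lz$ok) auc_last + clast / lz$lambda_z else NA_real_
  tibble::tibble(
    cmax = cmax, tmax = tmax, auc_0_24 = auc_0_24, auc_last = auc_last,
    auc_inf = auc_inf,
    lambda_z = lz$lambda_z,
    t_half = if (lz$ok) log(2) / lz$lambda_z else NA_real_,
    pct_extrapolated = if (lz$ok) 100 * (auc_inf - auc_last) / auc_inf
                       else NA_real_,
    n_lambda_points = lz$n_points, adj_r2 = lz$adj_r2
  )
}

#' Noncompartmental analysis of a profile table
#'
#' Applies [nca_summary()] to every `subject_id` x `matrix` group of a
#' tidy profile table.
#'
#' @param data Profile tibble with `subject_id`, `matrix`, `time_h`,
#'   `conc_mg_L` and optionally `blq`.
#' @param method AUC method, see [compute_auc()].
#' @return A tibble with one row per subject and matrix plus all
#'   [nca_summary()] columns.
#' @export
#' @examples
#' prof <- simulate_profile(doravirine(), dosing_regimen(100),
#'                          times = c(0, 1, 2, 3, 4, 5, 6, 8, 10, 12, 24))
#' run_nca(prof)
run_nca <- function(data, method = c("lin_up_log_down", "linear")) {
  method <- match.arg(method)
  need <- c("subject_id", "matrix", "time_h", "conc_mg_L")
  if (!all(need %in% names(data))) {
    abort(sprintf("Profile data must have columns %s.",
                  paste(need, collapse = ", ")))
  }
  if (!"blq" %in% names(data)) data$blq <- FALSE
  data |>
    dplyr::group_by(.data$subject_id, .data$matrix) |>
    dplyr::group_modify(~ nca_summary(.x$time_h, .x$conc_mg_L, .x$blq,
                                      method = method)) |>
    dplyr::ungroup()
}

#' Geometric mean and geometric CV%
#'
#' \eqn{GM = \exp(\overline{\ln x})}; \eqn{CV\% = 100\sqrt{e^{s^2_{\ln x}}-1}}
#' with the sample variance of log values, the convention used for
#' log-normally distributed PK parameters.
#'
#' @param x Positive values.
#' @return A one-row tibble: `geo_mean`, `cv_pct`, `n`.
#' @export
#' @examples
#' geomean_cv(c(2, 8))  # GM 4, CV about 127%
geomean_cv <- function(x) {
  if (length(x) < 1) abort("Need at least one value.")
  if (any(x <= 0)) abort("Geometric statistics need strictly positive values.")
  lx <- log(x)
  cv <- if (length(x) > 1) 100 * sqrt(exp(var(lx)) - 1) else 0
  tibble::tibble(geo_mean = exp(mean(lx)), cv_pct = cv, n = length(x))
}

#' Median and interquartile range
#'
#' Quantiles use linear interpolation between order statistics
#' (`stats::quantile` type 7).
#'
#' @param x Numeric values.
#' @return A one-row tibble: `median`, `iqr_low`, `iqr_high`, `n`.
#' @export
median_iqr <- function(x) {
  if (length(x) < 1) abort("Need at least one value.")
  q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  tibble::tibble(median = q[2], iqr_low = q[1], iqr_high = q[3],
                 n = length(x))
}
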