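#' Coincidence time window from scanner geometry
#'
#' The window must cover the maximum photon travel time along the scanner
#' diagonal plus twice the coincidence time resolution:
#' `tau = sqrt(diameter^2 + length^2) / c + 2 * CTR`,
#' with c the vacuum speed of light.
#'
#' @param diameter_m scanner bore diameter in metres.
#' @param length_m axial length in metres.
#' @param ctr_ps coincidence time resolution (FWHM) in picoseconds.
#' @return tau in picoseconds.
#' @examples
#' compute_tau(0.40, 0.25, 500) / 1e3  # ns; rounds to 2.6
#' @export
compute_tau <- function(diameter_m, length_m, ctr_ps) {
  if (diameter_m < 0 || length_m < 0 || ctr_ps < 0)
    stop("all inputs must be >= 0")
  c_m_per_s <- 299792458
  sqrt(diameter_m^2 + length_m^2) / c_m_per_s * 1e12 + 2 * ctr_ps
}

#' Analytic rate-curve parameters
#'
#' Closed-form `(a, b)` of the activity-dependence models
#' `rate = a * A^order * exp(-b * A)` for the random and delayed
#' coincidence rates of each veto scheme, expressed through the detection
#' efficiencies, the coincidence window and the expected in-window time
#' differences:
#'
#' * outer doubles: `a = tau * eps1^2`, `b = eps_ge1 * (2*tau + dt)`
#' * inner doubles: same `a`, `b = eps_ge1 * (2*tau - dt)`
#' * no-veto doubles: `a = (eps1 + 2*eps2)^2 * tau`, `b = 0`
#' * between doubles: `a = (eps1 + eps2)^2 * tau`, `b = eps_ge1 * dt`
#' * outer/inner delayed schemes d1-d3: same prefactors with the partner
#'   factor `(eps1 + 2*eps2)` for d2/d3 and the exponent doubled for
#'   d1/d3
#' * outer two-decay triples: `a = eps2 * eps1 * (2*tau - dt_true)`,
#'   `b = eps_ge1 * (2*tau + dt13)` (quadratic model)
#' * outer three-decay triples: `a = eps1^3 * tau^2 / 2`, same `b`
#'   (cubic model)
#'
#' `dt` defaults to `0.5 * tau` (uniform in-window offsets), `dt_true` to
#' the folded-Gaussian mean `sqrt(2/pi) * ctr_fwhm_ps / 2.3548` of the
#' true-pair time difference, and `dt13` (first-to-last span of a triple)
#' to `0.5 * tau`.
#'
#' @param isotope an [isotope_model].
#' @param tau_ps coincidence window (ps).
#' @param target one of `"vouter_doubles"`, `"vinner_doubles"`,
#'   `"vno_doubles"`, `"vbetween_doubles"`, `"vouter_d1"`, `"vouter_d2"`,
#'   `"vouter_d3"`, `"vinner_d1"`, `"vinner_d2"`, `"vinner_d3"`,
#'   `"vouter_triples_2decay"`, `"vouter_triples_3decay"`.
#' @param mean_dt_ps expected time difference of accepted random doubles.
#' @param mean_dt_true_ps expected true-pair time difference.
#' @param mean_span13_ps expected first-to-last span of accepted triples.
#' @param ctr_fwhm_ps used for the `mean_dt_true_ps` default.
#' @return List with `a` (seconds, or seconds^2 for the cubic model), `b`
#'   (seconds), `model_order` (2 or 3) and `target`. With activity in Bq,
#'   `a * A^order * exp(-b * A)` is a rate in 1/s.
#' @export
analytic_params <- function(isotope, tau_ps, target,
                            mean_dt_ps = 0.5 * tau_ps,
                            mean_dt_true_ps = NULL,
                            mean_span13_ps = 0.5 * tau_ps,
                            ctr_fwhm_ps = 500) {
  stopifnot(inherits(isotope, "isotope_model"))
  tau <- tau_ps * 1e-12
  dt <- mean_dt_ps * 1e-12
  if (is.null(mean_dt_true_ps))
    mean_dt_true_ps <- sqrt(2 / pi) * ctr_fwhm_ps / (2 * sqrt(2 * log(2)))
  dtt <- mean_dt_true_ps * 1e-12
  dt13 <- mean_span13_ps * 1e-12
  e1 <- isotope$eps1; e2 <- isotope$eps2; ege1 <- isotope$eps_ge1
  par <- switch(target,
    vouter_doubles = list(a = tau * e1^2, b = ege1 * (2 * tau + dt), order = 2),
    vinner_doubles = list(a = tau * e1^2, b = ege1 * (2 * tau - dt), order = 2),
    vno_doubles = list(a = (e1 + 2 * e2)^2 * tau, b = 0, order = 2),
    vbetween_doubles = list(a = (e1 + e2)^2 * tau, b = ege1 * dt, order = 2),
    vouter_d1 = list(a = tau * e1^2, b = 2 * ege1 * (2 * tau + dt), order = 2),
    vouter_d2 = list(a = tau * e1 * (e1 + 2 * e2), b = ege1 * (2 * tau + dt),
                     order = 2),
    vouter_d3 = list(a = tau * e1 * (e1 + 2 * e2),
                     b = 2 * ege1 * (2 * tau + dt), order = 2),
    vinner_d1 = list(a = tau * e1^2, b = 2 * ege1 * (2 * tau - dt), order = 2),
    vinner_d2 = list(a = tau * e1 * (e1 + 2 * e2), b = ege1 * (2 * tau - dt),
                     order = 2),
    vinner_d3 = list(a = tau * e1 * (e1 + 2 * e2),
                     b = 2 * ege1 * (2 * tau - dt), order = 2),
    vouter_triples_2decay = list(a = e2 * e1 * (2 * tau - dtt),
                                 b = ege1 * (2 * tau + dt13), order = 2),
    vouter_triples_3decay = list(a = 0.5 * e1^3 * tau^2,
                                 b = ege1 * (2 * tau + dt13), order = 3),
    stop("unknown analytic target: ", target)
  )
  list(a = par$a, b = par$b, model_order = par$order, target = target)
}

#' Fit an activity-dependence rate curve
#'
#' Weighted least squares of `rate = a * A^order * exp(-b * A)` with
#' weights `1/std_err^2` (unweighted when `std_errs` is `NULL`).
#' Initialization comes from a log-linear regression of
#' `log(rate / A^order)` on A; `b` is constrained to be non-negative.
#' Fitting is performed with activities scaled to MBq for conditioning and
#' results are returned on the Bq scale.
#'
#' @param activities_bq strictly increasing activity grid (Bq).
#' @param rates mean rates (1/s) at each activity.
#' @param std_errs optional standard errors of the rates.
#' @param model_order 2 (quadratic) or 3 (cubic).
#' @return A `rate_fit`: list with `a`, `b`, `se_a`, `se_b`, `cov`,
#'   `chi2_red`, `model_order`.
#' @export
fit_rate_curve <- function(activities_bq, rates, std_errs = NULL,
                           model_order = 2) {
  n <- length(activities_bq)
  stopifnot(length(rates) == n, model_order %in% c(2, 3))
  if (n < 3) stop("need at least 3 points to fit")
  if (is.unsorted(activities_bq, strictly = TRUE))
    stop("activities must be strictly increasing")
  if (!is.null(std_errs)) {
    stopifnot(length(std_errs) == n)
    if (any(std_errs <= 0)) stop("std_errs must be positive")
  }
  am <- activities_bq / 1e6
  w <- if (is.null(std_errs)) rep(1, n) else 1 / std_errs^2

  pos <- rates > 0
  if (sum(pos) < 3) stop("degenerate fit: fewer than 3 positive rates")
  lf <- stats::lm(log(rates[pos] / am[pos]^model_order) ~ am[pos])
  a0 <- exp(stats::coef(lf)[[1L]])
  b0 <- max(0, -stats::coef(lf)[[2L]])

  df <- data.frame(am = am, rate = rates, w = w)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      rate ~ a_m * am^model_order * exp(-b_m * am),
      data = df, weights = w,
      start = list(a_m = a0, b_m = b0),
      lower = c(0, 0),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("rate-curve fit failed: ", conditionMessage(e)))

  cf <- stats::coef(fit)
  vc <- stats::vcov(fit)
  resid <- rates - cf[["a_m"]] * am^model_order * exp(-cf[["b_m"]] * am)
  chi2_red <- sum(w * resid^2) / max(1L, n - 2L)

  scale <- c(a_m = 1e6^model_order, b_m = 1e6)  # back to Bq units
  structure(list(
    a = cf[["a_m"]] / scale[["a_m"]],
    b = cf[["b_m"]] / scale[["b_m"]],
    se_a = sqrt(vc["a_m", "a_m"]) / scale[["a_m"]],
    se_b = sqrt(vc["b_m", "b_m"]) / scale[["b_m"]],
    cov = vc / outer(scale, scale),
    chi2_red = chi2_red,
    model_order = model_order
  ), class = "rate_fit")
}

#' @export
print.rate_fit <- function(x, ...) {
  cat(sprintf(
    "<rate_fit> order %d: a = %.4g s%s (+/- %.2g), b = %.4g ns (+/- %.2g), chi2_red = %.3g\n",
    x$model_order, x$a, if (x$model_order == 3) "^2" else "",
    x$se_a, x$b * 1e9, x$se_b * 1e9, x$chi2_red))
  invisible(x)
}

#' Mean in-window time differences of accepted coincidences
#'
#' Summarizes the time-difference structure that enters the analytic rate
#' models: the mean gap of accepted random doubles (expected near
#' `0.5 * tau`), the mean gap of true doubles (set by the timing jitter),
#' and the mean first-to-last span of triples.
#'
#' @param doubles data.frame from [find_prompt_doubles()].
#' @param stream the originating `singles_stream` (for ground truth).
#' @param triples optional `prompt_multiples` of order 3.
#' @param unpaired_only restrict the random-doubles mean to randoms whose
#'   members are both unpaired singles — the population the closed-form
#'   rate models describe; randoms containing a paired single have a
#'   systematically different gap distribution.
#' @return List with `mean_dt_ps` (random doubles), `mean_dt_true_ps`
#'   (true doubles), `mean_span13_ps` (triples, `NA` if not supplied),
#'   and the underlying counts.
#' @export
mean_gap_stats <- function(doubles, stream, triples = NULL,
                           unpaired_only = FALSE) {
  if (nrow(doubles) == 0L) stop("no accepted doubles: mean gap undefined")
  lab <- classify_coincidences(doubles, stream)
  rnd <- !lab$is_true
  if (unpaired_only) {
    unp <- flag_paired_singles(stream) == "unpaired"
    rnd <- rnd & unp[doubles$i] & unp[doubles$j]
  }
  out <- list(
    mean_dt_ps = if (any(rnd)) mean(doubles$dt_ps[rnd]) else NA_real_,
    mean_dt_true_ps = if (any(lab$is_true)) mean(doubles$dt_ps[lab$is_true])
                      else NA_real_,
    mean_span13_ps = NA_real_,
    n_randoms = sum(rnd), n_trues = sum(lab$is_true)
  )
  if (!is.null(triples) && length(triples$span_ps))
    out$mean_span13_ps <- mean(triples$span_ps)
  out
}

#' Summarize estimator deviations over a sweep
#'
#' @param estimates data.frame with columns `target`, `activity_bq` (or
#'   `activity_mbq`), `estimate_rate`, `truth_rate`, and optionally
#'   `se_estimate`, `se_truth`.
#' @return data.frame with one row per target: `max_abs_dev_pct`,
#'   `mean_abs_dev_pct`, `n_points`, and (when standard errors are
#'   supplied) `se_dev_at_max_pct` propagated at the maximizing point.
#' @export
deviation_report <- function(estimates) {
  stopifnot(all(c("target", "estimate_rate", "truth_rate") %in% names(estimates)))
  split_df <- split(estimates, estimates$target)
  rows <- lapply(split_df, function(d) {
    dev <- d$estimate_rate / d$truth_rate - 1
    i <- which.max(abs(dev))
    se <- NA_real_
    if (all(c("se_estimate", "se_truth") %in% names(d))) {
      se <- sqrt(d$se_estimate[i]^2 +
                   (d$estimate_rate[i] / d$truth_rate[i])^2 * d$se_truth[i]^2) /
        d$truth_rate[i]
    }
    data.frame(target = d$target[1L],
               max_abs_dev_pct = 100 * abs(dev[i]),
               mean_abs_dev_pct = 100 * mean(abs(dev)),
               se_dev_at_max_pct = 100 * se,
               n_points = nrow(d))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
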