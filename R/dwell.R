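#' Bound-lifetime records with right-censoring
#'
#' One row per particle: the observed dwell time and whether dissociation
#' was actually seen (`observed = TRUE`) or the particle persisted to the
#' end of the observation window (right-censored). When `observed` is
#' omitted and a `window` is given, records within one frame of the window
#' are auto-flagged as censored.
#'
#' @param duration dwell durations, s (> 0).
#' @param observed logical; `TRUE` = dissociation seen. May be omitted if
#'   `window` is supplied.
#' @param particle_id optional identifiers.
#' @param window observation-window length, s (used for auto-flagging).
#' @param frame_duration one frame, s; the auto-flag tolerance
#'   (default 0.08, i.e. 12.5 fps).
#' @return data frame of class `dwell_records` (`particle_id`, `duration`,
#'   `observed`).
#' @export
dwell_records <- function(duration, observed = NULL, particle_id = NULL,
                          window = NULL, frame_duration = 0.08) {
  check_numeric_vec(duration, "duration", lower = 1e-300)
  if (is.null(observed)) {
    if (is.null(window))
      stop_bad_arg("observed", "must be given unless `window` is supplied")
    observed <- duration < window - frame_duration
  }
  if (!is.logical(observed) || length(observed) != length(duration))
    stop_bad_arg("observed", "must be a logical vector matching duration")
  if (is.null(particle_id)) particle_id <- sprintf("p%04d", seq_along(duration))
  out <- data.frame(particle_id = as.character(particle_id),
                    duration = as.numeric(duration),
                    observed = observed, stringsAsFactors = FALSE)
  class(out) <- c("dwell_records", "data.frame")
  out
}

#' Survival curve of bound lifetimes
#'
#' Product-limit (Kaplan-Meier) estimate of the survival fraction, honoring
#' right-censoring; with no censoring it reduces to the empirical
#' complementary CDF. Estimation is delegated to [survival::survfit()].
#'
#' @param records a [dwell_records()] data frame.
#' @return data frame of class `survival_curve` with `time` (s, starting at
#'   0), `survival` (in \[0, 1\], non-increasing) and `n_at_risk`. If every
#'   record is censored the curve is flat at 1 and carries attribute
#'   `all_censored = TRUE` (with a warning).
#' @export
build_survival_curve <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) >= 1L)
  if (!any(records$observed)) {
    warning("all dwell times are right-censored; survival curve is flat at 1")
    out <- data.frame(time = c(0, max(records$duration)),
                      survival = c(1, 1),
                      n_at_risk = c(nrow(records), nrow(records)))
    attr(out, "all_censored") <- TRUE
    class(out) <- c("survival_curve", "data.frame")
    return(out)
  }
  fit <- survival::survfit(
    survival::Surv(records$duration, records$observed) ~ 1)
  out <- data.frame(time = c(0, fit$time),
                    survival = c(1, fit$surv),
                    n_at_risk = c(nrow(records), fit$n.risk))
  attr(out, "all_censored") <- FALSE
  class(out) <- c("survival_curve", "data.frame")
  out
}

#' Single-exponential half-life of bound lifetimes
#'
#' Two estimators of the half-life `t1/2` of an exponential dwell-time
#' distribution:
#' \describe{
#'   \item{`"least_squares"`}{unweighted nonlinear least squares of
#'     `S(t) = exp(-t log(2) / t1/2)` to the Kaplan-Meier survival curve --
#'     the conventional fit to a plotted survival-fraction decay. The
#'     standard error comes from the fit covariance.}
#'   \item{`"mle_censored"`}{the censored-exponential maximum-likelihood
#'     estimator `t1/2 = log(2) * sum(duration) / n_observed`, which is
#'     unbiased under arbitrary right-censoring; its standard error is
#'     `t1/2 / sqrt(n_observed)`. This is the recommended mode when most
#'     records are censored.}
#' }
#'
#' @param x a [dwell_records()] data frame, or (for `"least_squares"`) a
#'   [build_survival_curve()] result.
#' @param method `"least_squares"` (default, matching common practice) or
#'   `"mle_censored"`.
#' @return object of class `halflife_fit`: `half_life` (s), `rate`
#'   (`log(2)/half_life`, 1/s), `fit_error` (s), `method`, `n_observed`,
#'   `n_censored`, `r_squared` (LS only).
#' @examples
#' rec <- simulate_dwell_times(200, half_life = 590, seed = 1)
#' fit_half_life(rec, method = "mle_censored")
#' @export
fit_half_life <- function(x, method = c("least_squares", "mle_censored")) {
  method <- match.arg(method)
  if (method == "mle_censored") {
    if (!is.data.frame(x) || is.null(x$duration))
      stop("mle_censored needs dwell records, not a survival curve")
    n_obs <- sum(x$observed)
    if (n_obs < 1L)
      stop("cannot estimate a half-life: no dissociation events were ",
           "observed (every record is right-censored)")
    thalf <- log(2) * sum(x$duration) / n_obs
    return(new_halflife_fit(thalf, thalf / sqrt(n_obs), method,
                            n_obs, sum(!x$observed), NA_real_))
  }
  if (inherits(x, "survival_curve")) {
    curve <- x
    n_obs <- NA_integer_; n_cen <- NA_integer_
  } else {
    curve <- build_survival_curve(x)
    n_obs <- sum(x$observed); n_cen <- sum(!x$observed)
  }
  pts <- curve[curve$time > 0, , drop = FALSE]
  if (length(unique(pts$time)) < 3L)
    stop("least-squares survival fit needs >= 3 distinct event times")
  # crude initial value: time scale of the empirical decay
  s_end <- max(min(pts$survival), 1e-6)
  t0 <- if (s_end < 1) log(2) * max(pts$time) / -log(s_end) else max(pts$time)
  fit <- stats::nls(survival ~ exp(-time * log(2) / thalf),
                    data = pts, start = list(thalf = t0),
                    control = stats::nls.control(maxiter = 200,
                                                 scaleOffset = 1,
                                                 warnOnly = TRUE))
  est <- summary(fit)$coefficients
  resid <- stats::resid(fit)
  ss_tot <- sum((pts$survival - mean(pts$survival))^2)
  r2 <- if (ss_tot > 0) 1 - sum(resid^2) / ss_tot else NA_real_
  new_halflife_fit(unname(est[1L, 1L]), unname(est[1L, 2L]), method,
                   n_obs, n_cen, r2)
}

new_halflife_fit <- function(half_life, fit_error, method,
                             n_observed, n_censored, r_squared) {
  structure(
    list(half_life = half_life, rate = log(2) / half_life,
         fit_error = fit_error, method = method,
         n_observed = n_observed, n_censored = n_censored,
         r_squared = r_squared),
    class = "halflife_fit")
}

#' @export
print.halflife_fit <- function(x, ...) {
  cat(sprintf("Exponential half-life (%s): %.4g +/- %.3g s (k = %.3g /s)\n",
              x$method, x$half_life, x$fit_error, x$rate))
  if (!is.na(x$n_observed))
    cat(sprintf("  %d observed, %d censored\n", x$n_observed, x$n_censored))
  invisible(x)
}

#' @export
coef.halflife_fit <- function(object, ...) {
  c(half_life = object$half_life, rate = object$rate)
}

#' Fraction of particles dissociating within the observation window
#'
#' @param records a [dwell_records()] data frame.
#' @return list with `frequency` (= n_observed / n_total), binomial `se`,
#'   a 95% normal-approximation `ci`, and the counts.
#' @export
dissociation_frequency <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) >= 1L)
  n <- nrow(records)
  p <- mean(records$observed)
  se <- sqrt(p * (1 - p) / n)
  list(frequency = p, se = se,
       ci = c(max(0, p - 1.96 * se), min(1, p + 1.96 * se)),
       n_observed = sum(records$observed), n_total = n)
}
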