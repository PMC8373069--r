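#' Excision time course container
#'
#' @param times sampling times, s (ascending).
#' @param product_percent cleaved product as % of substrate (may carry
#'   measurement noise, so small excursions outside \[0, 100\] are clipped).
#' @param substrate_total total substrate, nM.
#' @param enzyme_total total (active) enzyme, nM; optional.
#' @return data frame of class `excision_timecourse` with `time_s`,
#'   `product_nM`, `product_percent`; attributes `substrate_total`,
#'   `enzyme_total`.
#' @export
excision_timecourse <- function(times, product_percent, substrate_total,
                                enzyme_total = NA_real_) {
  check_numeric_vec(times, "times", lower = 0)
  if (is.unsorted(times)) stop_bad_arg("times", "must be ascending")
  check_numeric_vec(product_percent, "product_percent")
  if (length(product_percent) != length(times))
    stop_bad_arg("product_percent", "must match times in length")
  check_number(substrate_total, "substrate_total", lower = 1e-12)
  pct <- pmin(pmax(product_percent, 0), 100)
  out <- data.frame(time_s = times,
                    product_nM = pct / 100 * substrate_total,
                    product_percent = pct)
  attr(out, "substrate_total") <- substrate_total
  attr(out, "enzyme_total") <- enzyme_total
  class(out) <- c("excision_timecourse", "data.frame")
  out
}

#' Quantify an EMSA lane from band intensities
#'
#' Per-band background is subtracted, and each band group's percent of
#' total lane signal is `100 * sum(corrected group) / sum(corrected lane)`,
#' clipped at 0. Groups (e.g. all bound states vs free DNA, or
#' monomer/dimer/co-complex species) are a user-supplied mapping of band
#' names; ungrouped quantification treats each band as its own group.
#'
#' @param intensities named numeric vector of band intensities.
#' @param background background intensity per band (scalar, recycled, or a
#'   vector matching `intensities`).
#' @param groups named list mapping group names to band names.
#' @return object of class `lane_quantification`: data frame `percents`
#'   (`group`, `percent`), plus `total_corrected`.
#' @examples
#' quantify_lane(c(free = 300, bound = 500, supershift = 200),
#'               background = 100,
#'               groups = list(bound = c("bound", "supershift"),
#'                             free = "free"))
#' @export
quantify_lane <- function(intensities, background = 0, groups = NULL) {
  check_numeric_vec(intensities, "intensities", lower = 0)
  if (is.null(names(intensities)))
    names(intensities) <- paste0("band", seq_along(intensities))
  background <- rep_len(background, length(intensities))
  corrected <- intensities - background
  total <- sum(corrected)
  if (total <= 0)
    stop("background-corrected lane total is not positive; ",
         "cannot quantify this lane")
  if (is.null(groups))
    groups <- stats::setNames(as.list(names(intensities)), names(intensities))
  bad <- setdiff(unlist(groups), names(intensities))
  if (length(bad) > 0L)
    stop("unknown band name(s) in groups: ", paste(bad, collapse = ", "))
  pct <- vapply(groups, function(bands) {
    max(0, 100 * sum(corrected[bands]) / total)
  }, numeric(1))
  structure(list(percents = data.frame(group = names(groups),
                                       percent = unname(pct),
                                       stringsAsFactors = FALSE),
                 total_corrected = total),
            class = "lane_quantification")
}

#' @export
print.lane_quantification <- function(x, ...) {
  cat("EMSA lane quantification (% of corrected lane signal):\n")
  print(transform(x$percents, percent = round(percent, 2)), row.names = FALSE)
  invisible(x)
}

#' Fraction of DNA bound under the single-site quadratic binding model
#'
#' The exact ligand-depletion solution of `P + D <-> PD` with total protein
#' `E`, total DNA `S` and dissociation constant `Kd`:
#' \deqn{f = \frac{(E+S+K_d) - \sqrt{(E+S+K_d)^2 - 4ES}}{2S}}
#' valid (unlike the hyperbolic approximation) when the reactant
#' concentrations are comparable to `Kd`.
#'
#' @param titrant total protein concentration(s) `E`, nM.
#' @param dna_total total DNA `S`, nM (> 0).
#' @param kd dissociation constant, nM (> 0).
#' @return fraction of DNA bound, in \[0, 1\].
#' @examples
#' 100 * fraction_bound_quadratic(20, 8, 0.05)  # percent bound
#' @export
fraction_bound_quadratic <- function(titrant, dna_total, kd) {
  check_numeric_vec(titrant, "titrant", lower = 0)
  check_number(dna_total, "dna_total", lower = 1e-300)
  check_number(kd, "kd", lower = 1e-300)
  b <- titrant + dna_total + kd
  disc <- pmax(b * b - 4 * titrant * dna_total, 0)
  (b - sqrt(disc)) / (2 * dna_total)
}

#' Fit a dissociation constant by the quadratic (ligand-depletion) model
#'
#' Nonlinear least squares of [fraction_bound_quadratic()] against the
#' titration, via bounded Levenberg-Marquardt. Requires a visible binding
#' transition; a flat isotherm is rejected as unidentifiable.
#'
#' @param isotherm a `binding_isotherm` data frame (`titrant_nM`,
#'   `fraction_bound`) as produced by [simulate_binding_isotherm()], or any
#'   data frame with those columns.
#' @param dna_total total DNA, nM; defaults to the isotherm's `dna_total`
#'   attribute.
#' @return object of class `kd_fit`: `kd` (nM), `standard_error` (nM),
#'   `model = "quadratic_depletion"`, `r_squared`, `fit` (the underlying
#'   nls object).
#' @export
fit_quadratic_kd <- function(isotherm, dna_total = NULL) {
  stopifnot(is.data.frame(isotherm),
            all(c("titrant_nM", "fraction_bound") %in% names(isotherm)))
  dna_total <- dna_total %||% attr(isotherm, "dna_total")
  check_number(dna_total, "dna_total", lower = 1e-300)
  if (nrow(isotherm) < 4L)
    stop("need >= 4 titration points spanning the transition")
  span <- diff(range(isotherm$fraction_bound))
  if (span < 0.1)
    stop("flat isotherm (fraction-bound span ", signif(span, 2),
         "): Kd is not identifiable from these data")
  # start at the titrant giving half-maximal binding
  half <- min(isotherm$fraction_bound) + span / 2
  kd0 <- max(stats::approx(isotherm$fraction_bound, isotherm$titrant_nM,
                           xout = half, ties = mean)$y, 1e-3)
  fit <- minpack.lm::nlsLM(
    fraction_bound ~ fraction_bound_quadratic(titrant_nM, dna_total, kd),
    data = isotherm, start = list(kd = kd0),
    lower = c(kd = 1e-9),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- summary(fit)$coefficients
  ss_tot <- sum((isotherm$fraction_bound -
                   mean(isotherm$fraction_bound))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::resid(fit)^2) / ss_tot else NA_real_
  structure(list(kd = unname(est[1L, 1L]),
                 standard_error = unname(est[1L, 2L]),
                 model = "quadratic_depletion", r_squared = r2,
                 dna_total = dna_total, fit = fit),
            class = "kd_fit")
}

#' @export
print.kd_fit <- function(x, ...) {
  cat(sprintf("Quadratic-depletion binding fit: Kd = %.4g +/- %.3g nM (R^2 = %.4f)\n",
              x$kd, x$standard_error, x$r_squared))
  invisible(x)
}

#' @export
coef.kd_fit <- function(object, ...) c(kd = object$kd)

#' Fit pre-steady-state burst kinetics to an excision time course
#'
#' Nonlinear least squares of the standard glycosylase burst equation
#' `product(t) = A0 (1 - exp(-k_burst t)) + A0 k_ss t`, where the burst
#' amplitude `A0` estimates the active-enzyme concentration, `k_burst` the
#' first-turnover (chemistry) rate and `k_ss` the slow steady-state
#' turnover limited by product release. All parameters are bounded at 0 and
#' `A0` is bounded above by the total enzyme when known.
#'
#' @param tc an [excision_timecourse()].
#' @param enzyme_total total active enzyme, nM; defaults to the course's
#'   attribute (upper bound for `A0`).
#' @return object of class `burst_fit`: `amplitude` (nM), `k_burst` (1/s),
#'   `k_ss` (1/s), `r_squared`, `fit`.
#' @export
fit_burst_kinetics <- function(tc, enzyme_total = NULL) {
  stopifnot(inherits(tc, "excision_timecourse") ||
              all(c("time_s", "product_nM") %in% names(tc)))
  enzyme_total <- enzyme_total %||% attr(tc, "enzyme_total")
  if (is.null(enzyme_total) || is.na(enzyme_total)) enzyme_total <- Inf
  if (nrow(tc) < 5L)
    stop("burst fit needs >= 5 time points including the early burst region")
  a0 <- max(tc$product_nM) * 0.8 + 1e-6
  early <- tc$time_s[tc$time_s > 0][1L]
  fit <- tryCatch(
    minpack.lm::nlsLM(
      product_nM ~ A0 * (1 - exp(-kb * time_s)) + A0 * kss * time_s,
      data = as.data.frame(tc),
      start = list(A0 = min(a0, enzyme_total),
                   kb = log(2) / max(early, 1), kss = 1e-5),
      lower = c(A0 = 0, kb = 0, kss = 0),
      upper = c(A0 = enzyme_total, kb = Inf, kss = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) {
      stop("burst-kinetics fit did not converge: ", conditionMessage(e),
           call. = FALSE)
    })
  cf <- stats::coef(fit)
  ss_tot <- sum((tc$product_nM - mean(tc$product_nM))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::resid(fit)^2) / ss_tot else NA_real_
  structure(list(amplitude = unname(cf["A0"]),
                 k_burst = unname(cf["kb"]),
                 k_ss = unname(cf["kss"]),
                 r_squared = r2, enzyme_total = enzyme_total, fit = fit),
            class = "burst_fit")
}

#' @export
print.burst_fit <- function(x, ...) {
  cat(sprintf(paste0("Burst kinetics: A0 = %.3g nM, k_burst = %.3g /s, ",
                     "k_ss = %.3g /s (R^2 = %.4f)\n"),
              x$amplitude, x$k_burst, x$k_ss, x$r_squared))
  invisible(x)
}

#' @export
coef.burst_fit <- function(object, ...) {
  c(amplitude = object$amplitude, k_burst = object$k_burst,
    k_ss = object$k_ss)
}

#' @export
predict.burst_fit <- function(object, times, ...) {
  object$amplitude * (1 - exp(-object$k_burst * times)) +
    object$amplitude * object$k_ss * times
}

#' Fold-stimulation between two excision time courses
#'
#' Compares a condition pair (e.g. glycosylase alone vs plus a stimulating
#' factor) two ways: the ratio of interpolated product at `t_eval`, and the
#' ratio of fitted steady-state turnover rates `k_ss`. The two need not
#' coincide when the substrate is near exhaustion at `t_eval`.
#'
#' @param tc_minus,tc_plus [excision_timecourse()] objects for the
#'   unstimulated / stimulated condition; both must cover `t_eval`.
#' @param t_eval evaluation time, s (default: last common time point).
#' @return object of class `stimulation_fold`: `fold_product`, `fold_kss`
#'   (NA when either burst fit fails), `t_eval`, products at `t_eval`.
#' @export
stimulation_fold <- function(tc_minus, tc_plus, t_eval = NULL) {
  t_eval <- t_eval %||% min(max(tc_minus$time_s), max(tc_plus$time_s))
  if (t_eval > max(tc_minus$time_s) || t_eval > max(tc_plus$time_s))
    stop("both time courses must cover t_eval = ", t_eval, " s")
  p_minus <- stats::approx(tc_minus$time_s, tc_minus$product_nM,
                           xout = t_eval, ties = mean)$y
  p_plus <- stats::approx(tc_plus$time_s, tc_plus$product_nM,
                          xout = t_eval, ties = mean)$y
  if (p_minus <= 0)
    stop("unstimulated product at t_eval is not positive; fold undefined")
  fold_kss <- tryCatch({
    kss_m <- fit_burst_kinetics(tc_minus)$k_ss
    kss_p <- fit_burst_kinetics(tc_plus)$k_ss
    if (kss_m > 0) kss_p / kss_m else NA_real_
  }, error = function(e) NA_real_)
  structure(list(fold_product = p_plus / p_minus, fold_kss = fold_kss,
                 t_eval = t_eval, product_minus = p_minus,
                 product_plus = p_plus),
            class = "stimulation_fold")
}

#' @export
print.stimulation_fold <- function(x, ...) {
  cat(sprintf("Stimulation at t = %g s: product fold = %.3g; k_ss fold = %s\n",
              x$t_eval, x$fold_product,
              if (is.na(x$fold_kss)) "NA" else sprintf("%.3g", x$fold_kss)))
  invisible(x)
}
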