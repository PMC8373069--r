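#' AFM particle volume from height, background and area
#'
#' `Volume = (<H> - B) * A`, where `<H>` is the mean particle height, `B`
#' the image background and `A` the thresholded particle area. Negative
#' volumes (sub-background particles) are permitted but flagged via the
#' `"sub_background"` attribute.
#'
#' @param mean_height mean particle height `<H>`, nm.
#' @param background image background `B`, nm.
#' @param area particle area `A`, nm^2 (> 0).
#' @return numeric vector of volumes, nm^3, with logical attribute
#'   `sub_background` marking negative entries.
#' @examples
#' particle_volume(2, 0.5, 100)  # 150 nm^3
#' @export
particle_volume <- function(mean_height, background, area) {
  check_numeric_vec(mean_height, "mean_height")
  check_numeric_vec(background, "background")
  check_numeric_vec(area, "area")
  if (any(area <= 0)) stop_bad_arg("area", "must be > 0")
  v <- (mean_height - background) * area
  attr(v, "sub_background") <- v < 0
  v
}

#' Protein volume of a protein-DNA complex by flanking-DNA subtraction
#'
#' `V_protein = V_complex - (V_DNA1 + V_DNA2) / 2`, where the two DNA
#' volumes are measured on unbound DNA regions flanking the complex, each of
#' the same contour length as the complex footprint.
#'
#' @param v_complex total complex volume, nm^3.
#' @param v_dna1,v_dna2 flanking DNA volumes, nm^3.
#' @return protein volume(s), nm^3.
#' @examples
#' protein_volume_from_complex(300, 40, 60)  # 250 nm^3
#' @export
protein_volume_from_complex <- function(v_complex, v_dna1, v_dna2) {
  check_numeric_vec(v_complex, "v_complex")
  check_numeric_vec(v_dna1, "v_dna1")
  check_numeric_vec(v_dna2, "v_dna2")
  v_complex - (v_dna1 + v_dna2) / 2
}

#' Volume-to-molecular-weight standard curve
#'
#' Ordinary least-squares regression of AFM volume on known molecular
#' weight across calibration proteins. The inverse map
#' `mw = (volume - intercept) / slope` converts measured volumes to
#' molecular weights.
#'
#' @param points data frame with columns `mw_kda` and `volume_nm3` (and
#'   optionally `label`); at least 2 points with distinct molecular weights.
#' @return object of class `afm_standard_curve`: `slope` (nm^3/kDa),
#'   `intercept` (nm^3), `r_squared`, `points`.
#' @examples
#' sc <- fit_standard_curve(data.frame(mw_kda = c(100, 200),
#'                                     volume_nm3 = c(200, 400)))
#' mw_from_volume(sc, 300)  # 150 kDa
#' @export
fit_standard_curve <- function(points) {
  stopifnot(is.data.frame(points),
            all(c("mw_kda", "volume_nm3") %in% names(points)))
  if (nrow(points) < 2L || length(unique(points$mw_kda)) < 2L)
    stop("standard curve needs >= 2 calibration points with distinct ",
         "molecular weights")
  fit <- stats::lm(volume_nm3 ~ mw_kda, data = points)
  slope <- unname(stats::coef(fit)[2L])
  if (slope <= 0)
    warning("standard-curve slope is not positive; calibration is unphysical")
  r2 <- if (nrow(points) > 2L)
    suppressWarnings(summary(fit)$r.squared) else 1
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = r2, points = points),
            class = "afm_standard_curve")
}

#' @export
print.afm_standard_curve <- function(x, ...) {
  cat(sprintf("AFM standard curve: volume = %.4g * MW %+.4g nm^3 (R^2 = %.4f, %d points)\n",
              x$slope, x$intercept, x$r_squared, nrow(x$points)))
  invisible(x)
}

#' @export
predict.afm_standard_curve <- function(object, mw_kda, ...) {
  object$intercept + object$slope * mw_kda
}

#' @rdname fit_standard_curve
#' @param curve an `afm_standard_curve`.
#' @param volume_nm3 measured volume(s), nm^3.
#' @export
mw_from_volume <- function(curve, volume_nm3) {
  stopifnot(inherits(curve, "afm_standard_curve"))
  (volume_nm3 - curve$intercept) / curve$slope
}

#' Gaussian-mixture deconvolution of molecular-weight populations
#'
#' Fits a `k`-component univariate Gaussian mixture to calibrated molecular
#' weights by expectation-maximization, with k-means initialization and
#' multiple restarts (the best log-likelihood is kept). Components are
#' reported in ascending order of mean; each particle is assigned its
#' maximum-posterior component. The per-iteration log-likelihood trace is
#' retained so monotone convergence can be verified.
#'
#' @param mws molecular weights, kDa (length >= 5 * k).
#' @param k number of components.
#' @param seed optional integer seed (initialization is stochastic).
#' @param n_restarts number of EM restarts (default 10).
#' @param max_iter maximum EM iterations per restart (default 500).
#' @param tol relative log-likelihood change declaring convergence.
#' @return object of class `gaussian_mixture`: `components` (data frame of
#'   `mean`, `sd`, `weight`), `assignments`, `loglik`, `loglik_trace`,
#'   `bic`, `converged`. Non-convergence returns the best state so far with
#'   `converged = FALSE`.
#' @export
fit_species_gaussians <- function(mws, k, seed = NULL, n_restarts = 10,
                                  max_iter = 500, tol = 1e-8) {
  check_numeric_vec(mws, "mws")
  check_number(k, "k", lower = 1)
  n <- length(mws)
  if (n < 5 * k)
    stop("need at least 5*k = ", 5 * k, " observations, got ", n)
  if (!is.null(seed)) set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    km <- suppressWarnings(
      stats::kmeans(mws, centers = min(k, length(unique(mws))),
                    nstart = 1, iter.max = 50))
    init_mu <- as.numeric(km$centers)
    if (length(init_mu) < k)
      init_mu <- c(init_mu, sample(mws, k - length(init_mu)))
    fit <- em_gmm_1d(mws, init_mu, max_iter, tol)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  ord <- order(best$mu)
  post <- best$post[, ord, drop = FALSE]
  comps <- data.frame(mean = best$mu[ord], sd = best$sigma[ord],
                      weight = best$w[ord])
  n_par <- 3 * k - 1
  structure(list(components = comps,
                 assignments = max.col(post),
                 posterior = post,
                 loglik = best$loglik,
                 loglik_trace = best$trace,
                 bic = -2 * best$loglik + n_par * log(n),
                 converged = best$converged),
            class = "gaussian_mixture")
}

# plain 1-D EM; sigma floored to avoid component collapse
em_gmm_1d <- function(x, mu, max_iter, tol) {
  k <- length(mu)
  n <- length(x)
  sigma <- rep(max(stats::sd(x) / k, 1e-8), k)
  w <- rep(1 / k, k)
  floor_sd <- max(diff(range(x)), 1e-6) * 1e-4
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  post <- matrix(1 / k, n, k)
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(k),
                   function(j) w[j] * stats::dnorm(x, mu[j], sigma[j]),
                   numeric(n))
    rowsum_d <- rowSums(dens)
    rowsum_d[rowsum_d < 1e-300] <- 1e-300
    ll <- sum(log(rowsum_d))
    trace <- c(trace, ll)
    post <- dens / rowsum_d
    if (is.finite(ll_old) && ll - ll_old < tol * abs(ll)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    nk <- colSums(post)
    nk[nk < 1e-12] <- 1e-12
    w <- nk / n
    mu <- colSums(post * x) / nk
    sigma <- sqrt(colSums(post * outer(x, mu, "-")^2) / nk)
    sigma <- pmax(sigma, floor_sd)
  }
  if (!converged)
    warning("EM did not converge within ", max_iter,
            " iterations; returning best state so far")
  list(mu = mu, sigma = sigma, w = w, post = post,
       loglik = trace[length(trace)], trace = trace, converged = converged)
}

#' @export
print.gaussian_mixture <- function(x, ...) {
  cat(sprintf("Gaussian mixture (%d components, logLik %.2f, BIC %.2f%s)\n",
              nrow(x$components), x$loglik, x$bic,
              if (x$converged) "" else ", NOT converged"))
  print(round(x$components, 3))
  invisible(x)
}
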