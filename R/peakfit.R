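#' Eligibility of a profile for Gaussian deconvolution
#'
#' A profile qualifies for peak fitting when the protein was quantified in at
#' least three fractions, two of which are adjacent.  Profiles failing this
#' rule carry too little shape information for a Gaussian model.
#'
#' @param intensities Nonnegative intensity vector over fractions.
#' @return `TRUE` or `FALSE`.
#' @export
eligible_for_fitting <- function(intensities) {
  nz <- which(intensities > 0)
  length(nz) >= 3L && any(diff(nz) == 1L)
}

#' BIC for a Gaussian mixture fit to an elution profile
#'
#' `n * ln(rss / n) + 3 * K * ln(n)`, with three free parameters (center,
#' width, amplitude) per peak.  Lower is better.  A perfect fit (`rss == 0`)
#' is scored with a small floor substituted for the residual sum of squares
#' so the criterion stays finite.
#'
#' @param n_points Number of fitted data points (fractions).
#' @param rss Residual sum of squares.
#' @param n_peaks Number of Gaussian components.
#' @param rss_floor Positive floor substituted when `rss` is zero.
#' @return The criterion value.
#' @export
bic_score <- function(n_points, rss, n_peaks, rss_floor = 1e-10) {
  if (rss < 0) stop("rss must be nonnegative")
  if (n_points <= 3 * n_peaks)
    stop("need more data points than parameters (3 per peak)")
  rss <- max(rss, rss_floor)
  n_points * log(rss / n_points) + 3 * n_peaks * log(n_points)
}

#' Impute single-fraction dropouts
#'
#' XIC quantification drops individual fractions to zero when a peptide is
#' not picked in that run even though the protein clearly elutes there.  A
#' zero flanked by two nonzero fractions is such a dropout, not a true
#' absence, and is replaced by the mean of its neighbors.  Runs of two or
#' more zeros, and zeros at the profile edges, are kept as genuine
#' below-detection values.
#'
#' @param intensities Nonnegative intensity vector over fractions.
#' @return The intensity vector with isolated interior zeros filled in.
#' @export
impute_dropouts <- function(intensities) {
  n <- length(intensities)
  if (n < 3L) return(intensities)
  i <- 2:(n - 1)
  fix <- i[intensities[i] == 0 & intensities[i - 1] > 0 &
             intensities[i + 1] > 0]
  intensities[fix] <- (intensities[fix - 1] + intensities[fix + 1]) / 2
  intensities
}

gauss_mix <- function(par, f) {
  # par = c(A1, mu1, s1, A2, mu2, s2, ...)
  K <- length(par) / 3L
  y <- numeric(length(f))
  for (k in seq_len(K)) {
    A <- par[3 * k - 2]; mu <- par[3 * k - 1]; s <- par[3 * k]
    y <- y + A * exp(-(f - mu)^2 / (2 * s^2))
  }
  y
}

# local maxima of the 3-point moving-average smoothed profile, tallest first
seed_centers <- function(intensities, fractions) {
  n <- length(intensities)
  sm <- stats::filter(intensities, rep(1 / 3, 3), sides = 2)
  sm[1] <- mean(intensities[1:2]); sm[n] <- mean(intensities[(n - 1):n])
  sm <- as.numeric(sm)
  is_max <- vapply(seq_len(n), function(i) {
    left <- if (i == 1L) -Inf else sm[i - 1]
    right <- if (i == n) -Inf else sm[i + 1]
    sm[i] > 0 && sm[i] >= left && sm[i] > right
  }, logical(1))
  idx <- which(is_max)
  idx[order(sm[idx], decreasing = TRUE)]
}

fit_k_gaussians <- function(y, f, init, sigma_bounds, maxiter = 300) {
  K <- nrow(init)
  par <- as.numeric(t(init))  # A, mu, s per peak
  lower <- rep(c(1e-12, min(f) - 1, sigma_bounds[1]), K)
  upper <- rep(c(2 * max(y), max(f) + 1, sigma_bounds[2]), K)
  par <- pmin(pmax(par, lower), upper)
  res <- try(suppressWarnings(minpack.lm::nls.lm(
    par = par,
    lower = lower, upper = upper,
    fn = function(p) y - gauss_mix(p, f),
    control = minpack.lm::nls.lm.control(maxiter = maxiter))), silent = TRUE)
  if (inherits(res, "try-error")) return(NULL)
  p <- res$par
  peaks <- data.frame(
    amplitude = p[seq(1, 3 * K, by = 3)],
    center = p[seq(2, 3 * K, by = 3)],
    sigma = p[seq(3, 3 * K, by = 3)])
  list(peaks = peaks, rss = sum((y - gauss_mix(p, f))^2))
}

#' Deconvolve an elution profile into Gaussian peaks
#'
#' Fits sums of `K = 1..max_peaks` Gaussian components
#' `I(f) = sum_k A_k exp(-(f - mu_k)^2 / (2 sigma_k^2))` to the profile by
#' bounded nonlinear least squares, then selects the number of peaks by the
#' lowest BIC.  Candidate models must satisfy two acceptance rules: retained
#' peaks are pairwise separated by at least `min_separation` fractions, and
#' every non-maximal peak must reach at least `min_rel_height` of the most
#' intense peak (weaker components are pruned and the model refit with fewer
#' components).  Component centers are seeded at local maxima of the 3-point
#' moving-average smoothed profile, so at most as many components are tried
#' as the profile has local maxima.
#'
#' Profiles that cannot be fit (optimizer failure at every `K`, or profiles
#' failing [eligible_for_fitting()]) fall back to the global-maximum method:
#' a single peak at the arg-max fraction (ties broken toward the earlier
#' fraction).  All-zero profiles are marked ineligible.
#'
#' @param intensities Nonnegative intensity vector over fractions.
#' @param fractions Fraction coordinates (defaults to `1:length`).
#' @param max_peaks Maximum number of Gaussian components (default 4).
#' @param min_separation Minimum pairwise center separation, in fractions.
#' @param min_rel_height Minimum relative height of non-maximal peaks.
#' @param void_fraction Void fraction index or `NULL`; peaks not at least
#'   one fraction past the void are flagged unresolved (see
#'   [is_resolved()]).
#' @param sigma_bounds Allowed Gaussian width range, in fractions.
#' @param rss_floor Floor for the BIC residual term, see [bic_score()].
#' @param impute Fill isolated interior zeros before fitting (see
#'   [impute_dropouts()]); eligibility is always judged on the raw profile.
#' @return Object of class `peakfit` with components `peaks` (data frame
#'   `center`, `sigma`, `amplitude`, `relative_height`, `resolved`, sorted
#'   by decreasing amplitude), `n_peaks`, `method` (`"gaussian"`,
#'   `"global_max"` or `"ineligible"`), `bic` (defined only for the Gaussian
#'   method), `rss`, plus the input profile.
#' @examples
#' f <- 1:24
#' y <- 100 * exp(-(f - 10)^2 / (2 * 1.5^2))
#' fit <- fit_elution_peaks(y)
#' coef(fit)
#' @export
fit_elution_peaks <- function(intensities, fractions = seq_along(intensities),
                              max_peaks = 4, min_separation = 4,
                              min_rel_height = 0.2, void_fraction = NULL,
                              sigma_bounds = c(0.5, 5), rss_floor = 1e-10,
                              impute = TRUE) {
  stopifnot(length(intensities) == length(fractions))
  if (any(intensities < 0)) stop("intensities must be nonnegative")
  cl <- match.call()

  if (all(intensities == 0))
    return(new_peakfit(NULL, "ineligible", NA_real_, NA_real_,
                       intensities, fractions, void_fraction, cl))
  if (!eligible_for_fitting(intensities))
    return(global_max_peak(intensities, fractions, void_fraction,
                           impute = impute, call = cl))

  if (impute) intensities <- impute_dropouts(intensities)
  y <- as.numeric(intensities)
  f <- as.numeric(fractions)
  n <- length(y)
  seeds <- seed_centers(y, f)
  kmax <- min(max_peaks, length(seeds), floor((n - 1) / 3))

  candidates <- list()
  for (K in seq_len(kmax)) {
    init <- data.frame(A = pmax(y[seeds[1:K]], max(y) * 0.05),
                       mu = f[seeds[1:K]],
                       s = rep(1.5, K))
    fit <- fit_k_gaussians(y, f, init, sigma_bounds)
    if (is.null(fit)) next
    # prune components below the relative-height rule, refit at reduced K
    for (iter in 1:4) {
      rel <- fit$peaks$amplitude / max(fit$peaks$amplitude)
      keep <- rel >= min_rel_height | rel == max(rel)
      if (all(keep)) break
      init2 <- fit$peaks[keep, c("amplitude", "center", "sigma")]
      names(init2) <- c("A", "mu", "s")
      fit2 <- fit_k_gaussians(y, f, init2, sigma_bounds)
      if (is.null(fit2)) break
      fit <- fit2
    }
    rel <- fit$peaks$amplitude / max(fit$peaks$amplitude)
    if (any(rel < min_rel_height & rel < 1)) next     # pruning did not settle
    ctr <- fit$peaks$center
    if (nrow(fit$peaks) > 1L &&
        min(stats::dist(ctr)) < min_separation) next  # separation rule
    kf <- nrow(fit$peaks)
    if (n <= 3 * kf) next
    fit$bic <- bic_score(n, fit$rss, kf, rss_floor)
    candidates[[length(candidates) + 1L]] <- fit
  }

  if (length(candidates) == 0L)
    return(global_max_peak(intensities, fractions, void_fraction,
                           impute = FALSE, call = cl))

  best <- candidates[[which.min(vapply(candidates, `[[`, 1, "bic"))]]
  pk <- best$peaks[order(best$peaks$amplitude, decreasing = TRUE), , drop = FALSE]
  pk <- data.frame(center = pk$center, sigma = pk$sigma,
                   amplitude = pk$amplitude,
                   relative_height = pk$amplitude / max(pk$amplitude),
                   resolved = is_resolved(pk$center, void_fraction))
  new_peakfit(pk, "gaussian", best$bic, best$rss,
              intensities, fractions, void_fraction, cl)
}

#' Global-maximum fallback peak
#'
#' Places a single peak at the arg-max fraction of the profile (integer
#' center; ties broken toward the earlier fraction and recorded in the
#' `tie` attribute of the peaks table).
#'
#' @inheritParams fit_elution_peaks
#' @param call Calling expression recorded in the result (internal).
#' @return A `peakfit` object with `method = "global_max"`, or
#'   `method = "ineligible"` for an all-zero profile.
#' @export
global_max_peak <- function(intensities, fractions = seq_along(intensities),
                            void_fraction = NULL, impute = TRUE,
                            call = sys.call()) {
  if (all(intensities == 0))
    return(new_peakfit(NULL, "ineligible", NA_real_, NA_real_,
                       intensities, fractions, void_fraction, call))
  if (impute) intensities <- impute_dropouts(intensities)
  i <- which.max(intensities)  # earliest fraction on ties
  tie <- sum(intensities == intensities[i]) > 1L
  pk <- data.frame(center = as.numeric(fractions[i]), sigma = NA_real_,
                   amplitude = intensities[i], relative_height = 1,
                   resolved = is_resolved(fractions[i], void_fraction))
  attr(pk, "tie") <- tie
  new_peakfit(pk, "global_max", NA_real_,
              sum((intensities - ifelse(seq_along(intensities) == i,
                                        intensities[i], 0))^2),
              intensities, fractions, void_fraction, call)
}

new_peakfit <- function(peaks, method, bic, rss, intensities, fractions,
                        void_fraction, call) {
  structure(
    list(peaks = peaks, n_peaks = if (is.null(peaks)) 0L else nrow(peaks),
         method = method, bic = bic, rss = rss,
         intensities = as.numeric(intensities),
         fractions = as.numeric(fractions),
         void_fraction = void_fraction, call = call),
    class = "peakfit")
}

#' @export
print.peakfit <- function(x, ...) {
  cat("Elution profile deconvolution (method: ", x$method, ")\n", sep = "")
  if (x$n_peaks > 0) {
    cat(x$n_peaks, "peak(s):\n")
    print(format(x$peaks, digits = 4), ...)
  } else cat("no peaks\n")
  if (!is.na(x$bic)) cat("BIC:", format(x$bic, digits = 6), "\n")
  invisible(x)
}

#' @export
summary.peakfit <- function(object, ...) {
  cat("Profile of", length(object$intensities), "fractions,",
      sum(object$intensities > 0), "nonzero; method:", object$method, "\n")
  print(object)
  invisible(object)
}

#' @export
coef.peakfit <- function(object, ...) {
  if (object$n_peaks == 0L)
    return(matrix(numeric(0), 0, 3,
                  dimnames = list(NULL, c("center", "sigma", "amplitude"))))
  as.matrix(object$peaks[, c("center", "sigma", "amplitude")])
}

#' Evaluate the fitted mixture on a fraction grid
#'
#' For Gaussian fits, the sum of the retained components; for global-max
#' fits the raw profile is returned unchanged (there is no parametric
#' model); for ineligible profiles, zeros.
#'
#' @param object A `peakfit` object.
#' @param fractions Evaluation grid (defaults to the fitted fractions).
#' @param ... Unused.
#' @export
predict.peakfit <- function(object, fractions = object$fractions, ...) {
  if (object$method == "gaussian") {
    par <- as.numeric(t(object$peaks[, c("amplitude", "center", "sigma")]))
    gauss_mix(par, fractions)
  } else if (object$method == "global_max") {
    if (identical(fractions, object$fractions)) object$intensities
    else stats::approx(object$fractions, object$intensities, xout = fractions,
                       yleft = 0, yright = 0)$y
  } else rep(0, length(fractions))
}

#' @export
fitted.peakfit <- function(object, ...) predict(object)

#' @export
residuals.peakfit <- function(object, ...) object$intensities - fitted(object)

#' @export
plot.peakfit <- function(x, ...) {
  graphics::plot(x$fractions, x$intensities, type = "h", lwd = 2,
                 col = "grey60", xlab = "fraction", ylab = "intensity", ...)
  if (x$method == "gaussian") {
    g <- seq(min(x$fractions), max(x$fractions), length.out = 200)
    graphics::lines(g, predict(x, g), col = "firebrick")
    graphics::abline(v = x$peaks$center, lty = 3, col = "firebrick")
  } else if (x$n_peaks > 0) {
    graphics::abline(v = x$peaks$center, lty = 3, col = "firebrick")
  }
  invisible(x)
}
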