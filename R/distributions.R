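#' Lognormal degree law for a social network
#'
#' Parametric model for the degree distribution of the substrate network: a
#' lognormal law on the log scale, discretised onto the integers
#' `k_min, k_min + 1, ...` and renormalised. The default discretisation puts
#' probability mass at integer `k` proportional to the continuous lognormal
#' density evaluated at `k`; an interval-mass convention (mass of
#' `[k - 1/2, k + 1/2)`) is available as a pluggable alternative.
#'
#' When `k_max` is left unbounded, functions that need a finite support (the
#' pmf, sampling, the mean) apply a structural cutoff at the
#' `1 - 1/n` quantile of the continuous law for a population of size `n`,
#' which is the largest degree one expects to observe once in a sample of
#' that size.
#'
#' @param mu Location of `log(k)`.
#' @param sigma Width of `log(k)`; must be positive.
#' @param k_min Smallest admissible degree (integer, at least 1).
#' @param k_max Largest admissible degree, or `NULL` for the structural
#'   cutoff tied to the population size.
#' @param convention Discretisation convention, `"density"` (default) or
#'   `"interval"`.
#' @return An object of class `degree_model`.
#' @examples
#' dm <- degree_model(1.09, 1.39)
#' degree_mean(dm, n = 1e4)
#' @export
degree_model <- function(mu, sigma, k_min = 1L, k_max = NULL,
                         convention = c("density", "interval")) {
  stopifnot(is.numeric(mu), length(mu) == 1, is.finite(mu))
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma <= 0)
    stop("`sigma` must be a positive number", call. = FALSE)
  k_min <- as.integer(k_min)
  if (k_min < 1L) stop("`k_min` must be >= 1", call. = FALSE)
  if (!is.null(k_max)) {
    k_max <- as.integer(k_max)
    if (k_max < k_min) stop("`k_max` must be >= `k_min`", call. = FALSE)
  }
  structure(
    list(mu = mu, sigma = sigma, k_min = k_min, k_max = k_max,
         convention = match.arg(convention)),
    class = "degree_model"
  )
}

#' @export
print.degree_model <- function(x, ...) {
  cat(sprintf(
    "<degree_model> lognormal(mu = %g, sigma = %g), k in [%d, %s], %s convention\n",
    x$mu, x$sigma, x$k_min,
    if (is.null(x$k_max)) "structural cutoff" else format(x$k_max),
    x$convention))
  invisible(x)
}

resolve_k_max <- function(model, n = NULL) {
  if (!is.null(model$k_max)) return(model$k_max)
  if (is.null(n)) n <- 1e4
  kq <- floor(stats::qlnorm(1 - 1 / n, model$mu, model$sigma))
  max(model$k_min, as.integer(kq))
}

#' Probability mass function of a discretised degree law
#'
#' @param model A [degree_model()].
#' @param n Population size used to resolve the structural cutoff when the
#'   model's `k_max` is unbounded.
#' @return A tibble with columns `k` and `p` (summing to 1).
#' @export
degree_pmf <- function(model, n = NULL) {
  stopifnot(inherits(model, "degree_model"))
  k_max <- resolve_k_max(model, n)
  k <- seq.int(model$k_min, k_max)
  p <- switch(model$convention,
    density = stats::dlnorm(k, model$mu, model$sigma),
    interval = stats::plnorm(k + 0.5, model$mu, model$sigma) -
      stats::plnorm(pmax(k - 0.5, 0), model$mu, model$sigma)
  )
  s <- sum(p)
  if (!is.finite(s) || s <= 0)
    stop("degree law has no mass on [k_min, k_max]; truncation failed",
         call. = FALSE)
  tibble::tibble(k = k, p = p / s)
}

#' Mean degree z of a discretised degree law
#'
#' @inheritParams degree_pmf
#' @return The average degree under the model's discretisation convention.
#' @export
degree_mean <- function(model, n = NULL) {
  pmf <- degree_pmf(model, n)
  sum(pmf$k * pmf$p)
}

#' Sample integer degrees
#'
#' Draws `size` i.i.d. degrees from the discretised law. Reproducible under
#' a fixed RNG state (`set.seed()`).
#'
#' @inheritParams degree_pmf
#' @param size Number of draws.
#' @return An integer vector of length `size`, all `>= k_min`.
#' @export
sample_degrees <- function(model, size, n = size) {
  stopifnot(size >= 1)
  pmf <- degree_pmf(model, n)
  sample(pmf$k, size, replace = TRUE, prob = pmf$p)
}

#' Lognormal behavioural-threshold law on (0, 1]
#'
#' Individual adoption thresholds phi are fractions of adopting neighbours,
#' so the lognormal law is truncated (not censored) to the unit interval:
#' draws condition on phi <= 1. With `mu = -2`, `sigma = 1` the truncated
#' mean is w = 0.19, the empirical average threshold.
#'
#' @param mu Location of `log(phi)`.
#' @param sigma Width of `log(phi)`; must be positive.
#' @return An object of class `threshold_model`.
#' @export
threshold_model <- function(mu, sigma) {
  stopifnot(is.numeric(mu), length(mu) == 1, is.finite(mu))
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma <= 0)
    stop("`sigma` must be a positive number", call. = FALSE)
  structure(list(mu = mu, sigma = sigma), class = "threshold_model")
}

#' @export
print.threshold_model <- function(x, ...) {
  m <- threshold_moments(x)
  cat(sprintf(
    "<threshold_model> lognormal(mu = %g, sigma = %g) truncated to (0,1]: w = %.4f, sd = %.4f\n",
    x$mu, x$sigma, m$mean, m$sd))
  invisible(x)
}

#' CDF, quantile function and sampler of the truncated threshold law
#'
#' @param model A [threshold_model()].
#' @param q,p Vectors of quantiles / probabilities.
#' @param size Number of draws.
#' @return `threshold_cdf()` and `threshold_quantile()` return numeric
#'   vectors; `sample_thresholds()` returns `size` i.i.d. draws in (0, 1].
#' @export
threshold_cdf <- function(model, q) {
  stopifnot(inherits(model, "threshold_model"))
  z <- stats::plnorm(1, model$mu, model$sigma)
  out <- stats::plnorm(pmin(q, 1), model$mu, model$sigma) / z
  out[q <= 0] <- 0
  out
}

#' @rdname threshold_cdf
#' @export
threshold_quantile <- function(model, p) {
  stopifnot(inherits(model, "threshold_model"), all(p >= 0), all(p <= 1))
  z <- stats::plnorm(1, model$mu, model$sigma)
  stats::qlnorm(p * z, model$mu, model$sigma)
}

#' @rdname threshold_cdf
#' @export
sample_thresholds <- function(model, size) {
  stopifnot(size >= 1)
  threshold_quantile(model, stats::runif(size))
}

#' Mean and standard deviation of the truncated threshold law
#'
#' Closed form via normal CDF factors: for a lognormal(mu, sigma) truncated
#' to (0, 1], the j-th moment is
#' `exp(j mu + j^2 sigma^2 / 2) * pnorm(-mu/sigma - j sigma) / pnorm(-mu/sigma)`.
#'
#' @param model A [threshold_model()].
#' @return A tibble with columns `mean` (the average threshold w) and `sd`.
#' @export
threshold_moments <- function(model) {
  stopifnot(inherits(model, "threshold_model"))
  a <- -model$mu / model$sigma # standardised truncation point, log(1) = 0
  z <- stats::pnorm(a)
  m1 <- exp(model$mu + model$sigma^2 / 2) * stats::pnorm(a - model$sigma) / z
  m2 <- exp(2 * model$mu + 2 * model$sigma^2) *
    stats::pnorm(a - 2 * model$sigma) / z
  tibble::tibble(mean = m1, sd = sqrt(pmax(m2 - m1^2, 0)))
}

#' Method-of-moments fit of an (untruncated) lognormal law
#'
#' Inverts the lognormal moment map: `sigma^2 = log(1 + (sd/mean)^2)`,
#' `mu = log(mean) - sigma^2 / 2`. Applied to the empirical threshold
#' moments (mean 0.19, sd 0.233) this returns mu ~ -2.12, sigma ~ 0.96,
#' i.e. the integer-rounded reference parameterisation (-2, 1).
#'
#' @param mean,sd Target mean and standard deviation; both positive.
#' @return A tibble with columns `mu` and `sigma`.
#' @export
fit_lognormal_moments <- function(mean, sd) {
  if (!is.numeric(mean) || mean <= 0 || !is.numeric(sd) || sd <= 0)
    stop("`mean` and `sd` must be positive", call. = FALSE)
  sigma2 <- log(1 + (sd / mean)^2)
  tibble::tibble(mu = log(mean) - sigma2 / 2, sigma = sqrt(sigma2))
}

#' Mean and sd of an untruncated lognormal law (inverse of the fit)
#'
#' @param mu,sigma Lognormal parameters.
#' @return A tibble with columns `mean` and `sd`.
#' @export
lognormal_moments <- function(mu, sigma) {
  m <- exp(mu + sigma^2 / 2)
  tibble::tibble(mean = m, sd = m * sqrt(exp(sigma^2) - 1))
}

#' Tabulate integer thresholds per degree group
#'
#' Builds the `(k, phi_int, count)` table of integer thresholds
#' (number of adopting neighbours at the time of adoption) from a
#' classification table as returned by [classify_adopters()]. Degree groups
#' are exact degrees by default; `log_bins` switches to logarithmic degree
#' grouping (group label = geometric mid-degree) for sparse data.
#'
#' @param classified A data frame with columns `degree` and `phi_k`.
#' @param log_bins Number of logarithmic degree bins, or `NULL` for exact
#'   degrees.
#' @return A tibble with columns `k`, `phi_int`, `count`.
#' @export
integer_threshold_table <- function(classified, log_bins = NULL) {
  stopifnot(all(c("degree", "phi_k") %in% names(classified)))
  df <- tibble::tibble(k = classified$degree, phi_int = classified$phi_k)
  if (any(df$phi_int > df$k))
    stop("integer threshold exceeds degree", call. = FALSE)
  if (!is.null(log_bins)) {
    rng <- range(df$k[df$k >= 1])
    brk <- exp(seq(log(rng[1]), log(rng[2] + 1), length.out = log_bins + 1))
    brk[1] <- brk[1] * (1 - 1e-9) # guard float round-up at the lower edge
    idx <- findInterval(df$k, brk, rightmost.closed = TRUE)
    mid <- sqrt(brk[-length(brk)] * brk[-1])
    df$k <- round(mid[idx])
  }
  dplyr::count(df, .data$k, .data$phi_int, name = "count") |>
    dplyr::arrange(.data$k, .data$phi_int)
}

#' Scaling collapse of integer-threshold distributions
#'
#' Rescales the per-degree-group distributions P(Phi_k, k) onto the master
#' curve k P(Phi_k / k): for each group the normalised frequency is
#' multiplied by k and plotted against x = Phi_k / k. Groups are returned
#' separately so collapse quality can be assessed across degrees.
#'
#' @param table A tibble with columns `k`, `phi_int`, `count` as produced by
#'   [integer_threshold_table()].
#' @return A tibble with columns `k`, `x` (= phi_int / k), `y` (= k * freq).
#' @export
collapse_integer_thresholds <- function(table) {
  stopifnot(all(c("k", "phi_int", "count") %in% names(table)))
  empty <- table |>
    dplyr::group_by(.data$k) |>
    dplyr::summarise(tot = sum(.data$count)) |>
    dplyr::filter(.data$tot == 0)
  if (nrow(empty) > 0)
    warning("skipping empty degree group(s): ",
            paste(empty$k, collapse = ", "), call. = FALSE)
  table |>
    dplyr::group_by(.data$k) |>
    dplyr::filter(sum(.data$count) > 0) |>
    dplyr::mutate(
      x = .data$phi_int / .data$k,
      y = .data$k * .data$count / sum(.data$count)
    ) |>
    dplyr::ungroup() |>
    dplyr::select("k", "x", "y")
}
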