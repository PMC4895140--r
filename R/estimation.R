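#' Estimate the spontaneous adoption rate from the innovator-rate plateau
#'
#' After an initial transient the innovator adoption rate R_i(t) is
#' approximately constant and equal to p_n. The estimator is the
#' least-squares constant fit (the mean) of R_i beyond the burn-in, with
#' its standard error.
#'
#' @param rates A tibble with columns `t` and `R_i` (see [class_rates()]).
#' @param burn_in Discard windows with `t <= burn_in` (the conventional
#'   choice is twice an arbitrary transient scale tau).
#' @return An object of class `pn_fit`: list with `estimate`, `std_error`,
#'   `n_windows`, `burn_in`.
#' @export
estimate_pn <- function(rates, burn_in = 0) {
  stopifnot(all(c("t", "R_i") %in% names(rates)))
  keep <- rates$R_i[rates$t > burn_in]
  if (length(keep) == 0)
    stop("no rate windows beyond `burn_in`", call. = FALSE)
  if (all(keep == 0))
    stop("innovator rate is identically zero beyond `burn_in`",
         call. = FALSE)
  se <- if (length(keep) > 1) stats::sd(keep) / sqrt(length(keep)) else NA_real_
  structure(
    list(estimate = mean(keep), std_error = se,
         n_windows = length(keep), burn_in = burn_in),
    class = "pn_fit"
  )
}

#' @export
print.pn_fit <- function(x, ...) {
  cat(sprintf("<pn_fit> p_n = %.3g +/- %.2g (%d windows, burn-in %g)\n",
              x$estimate, x$std_error, x$n_windows, x$burn_in))
  invisible(x)
}

lc_fraction_at <- function(degree, threshold, n, r, p_n, steps, runs) {
  mean(vapply(seq_len(runs), function(i) {
    pop <- build_population(degree, threshold, n, r)
    sim <- simulate_adoption(pop, p_n, steps)
    if (nrow(sim$events) == 0) return(0)
    an <- build_adoption_network(pop, sim$events)
    component_stats(an, n_total = n)$lc_frac
  }, 1.0))
}

#' Estimate the immune fraction by largest-component matching
#'
#' The only free parameter of the model, the immune fraction r, is
#' recovered by matching the relative size of the largest connected
#' component of the adoption network at time T between an observed process
#' and model simulations: for every r on a grid the mean LC fraction
#' (relative to substrate size) over `runs` realisations is measured, and
#' r_hat is the grid point whose LC fraction is closest to the target,
#' refined by linear interpolation on the locally monotone section.
#'
#' @param target_lc_frac Observed LC of the adoption network divided by
#'   substrate size, in (0, 1].
#' @param degree,threshold Generating models for the substrate.
#' @param n Substrate size for the matching simulations.
#' @param p_n Spontaneous rate (fixed, estimated separately).
#' @param steps Observation length T in iterations.
#' @param r_grid Grid of candidate immune fractions in `[0, 1)`.
#' @param runs Simulated realisations per grid point.
#' @return An object of class `r_match`: list with `r_hat`, `curve`
#'   (tibble: `r`, `lc_frac`), `target`.
#' @export
estimate_r <- function(target_lc_frac, degree, threshold, n, p_n, steps,
                       r_grid = seq(0.5, 0.95, by = 0.05), runs = 10) {
  stopifnot(target_lc_frac > 0, target_lc_frac <= 1,
            all(r_grid >= 0), all(r_grid < 1))
  r_grid <- sort(r_grid)
  lc <- vapply(r_grid, function(r)
    lc_fraction_at(degree, threshold, n, r, p_n, steps, runs), 1.0)
  if (target_lc_frac > max(lc) || target_lc_frac < min(lc)) {
    if (target_lc_frac > max(lc))
      stop(sprintf(
        "target LC fraction %.4f outside achievable range [%.4f, %.4f]",
        target_lc_frac, min(lc), max(lc)), call. = FALSE)
    warning(sprintf(
      "target LC fraction %.4f below the achievable range [%.4f, %.4f]; %s",
      target_lc_frac, min(lc), max(lc),
      "returning the grid edge"), call. = FALSE)
  }
  i <- which.min(abs(lc - target_lc_frac))
  r_hat <- r_grid[i]
  # refine on the locally monotone segment around the best grid point
  j <- if (i < length(r_grid) &&
             (lc[i] - target_lc_frac) * (lc[i + 1] - target_lc_frac) < 0) {
    i + 1L
  } else if (i > 1 &&
               (lc[i] - target_lc_frac) * (lc[i - 1] - target_lc_frac) < 0) {
    i - 1L
  } else NA_integer_
  if (!is.na(j) && lc[j] != lc[i]) {
    r_hat <- r_grid[i] + (target_lc_frac - lc[i]) /
      (lc[j] - lc[i]) * (r_grid[j] - r_grid[i])
  }
  structure(
    list(r_hat = r_hat, curve = tibble::tibble(r = r_grid, lc_frac = lc),
         target = target_lc_frac),
    class = "r_match"
  )
}

#' @export
print.r_match <- function(x, ...) {
  cat(sprintf("<r_match> r_hat = %.3f (target LC fraction %.4f, %d grid points)\n",
              x$r_hat, x$target, nrow(x$curve)))
  invisible(x)
}

#' Component-size curves of the four networks as a function of r
#'
#' For every immune fraction on the grid, simulates the model and measures
#' the mean largest (LC) and second-largest (LC2) component sizes, relative
#' to substrate size, of: the non-immune substrate ("net"), the adoption
#' network ("casc"), the stable subnetwork ("stab"), and the
#' innovator-induced vulnerable trees ("vuln", tree sizes standing in for
#' component sizes). LC2 peaks mark the fragmentation of the respective
#' percolating cluster and delimit the cascading, crossover and fragmented
#' regimes.
#'
#' @inheritParams estimate_r
#' @return An object of class `regime_report`: tibble with columns `r`,
#'   `network`, `lc`, `lc2`, `lc_sd` (dispersion of LC over runs).
#' @export
regime_report <- function(degree, threshold, n, p_n, steps,
                          r_grid = seq(0, 0.95, by = 0.05), runs = 5) {
  rows <- purrr::map(r_grid, function(r) {
    per_run <- purrr::map(seq_len(runs), function(i) {
      pop <- build_population(degree, threshold, n, r)
      sim <- simulate_adoption(pop, p_n, steps)
      sub <- igraph::induced_subgraph(pop$graph,
                                      which(!pop$nodes$immune))
      net <- component_stats(sub, n_total = n)
      if (nrow(sim$events) == 0) {
        empty <- component_stats(igraph::make_empty_graph(0, FALSE), n)
        casc <- stab <- empty
        vuln <- c(lc = 0, lc2 = 0)
      } else {
        casc <- component_stats(build_adoption_network(pop, sim$events), n)
        stab <- component_stats(stable_subnetwork(pop, sim$events), n)
        fo <- vulnerable_forest(pop, sim$events)
        sz <- sort(fo$trees$size, decreasing = TRUE)
        vuln <- c(lc = if (length(sz)) sz[1] else 0,
                  lc2 = if (length(sz) > 1) sz[2] else 0)
      }
      tibble::tibble(
        network = c("net", "casc", "stab", "vuln"),
        lc = c(net$lc, casc$lc, stab$lc, vuln["lc"]) / n,
        lc2 = c(net$lc2, casc$lc2, stab$lc2, vuln["lc2"]) / n
      )
    })
    dplyr::bind_rows(per_run) |>
      dplyr::group_by(.data$network) |>
      dplyr::summarise(lc_sd = stats::sd(.data$lc),
                       lc = mean(.data$lc), lc2 = mean(.data$lc2),
                       .groups = "drop") |>
      dplyr::mutate(r = r)
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::select("r", "network", "lc", "lc2", "lc_sd")
  class(out) <- c("regime_report", class(out))
  out
}
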