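#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy methods for fitted and scanned objects
#'
#' `tidy()` returns the per-term or per-grid-point table of an object;
#' `glance()` returns its one-row summary.
#'
#' @param x A `pn_fit`, `r_match`, `crossover_scan`, `component_stats`,
#'   `vulnerable_forest` or `adoption_sim` object.
#' @param ... Unused.
#' @return A tibble.
#' @name adoptnet-tidiers
NULL

#' @rdname adoptnet-tidiers
#' @export
tidy.pn_fit <- function(x, ...) {
  tibble::tibble(term = "p_n", estimate = x$estimate,
                 std.error = x$std_error)
}

#' @rdname adoptnet-tidiers
#' @export
glance.pn_fit <- function(x, ...) {
  tibble::tibble(estimate = x$estimate, std.error = x$std_error,
                 n.windows = x$n_windows, burn.in = x$burn_in)
}

#' @rdname adoptnet-tidiers
#' @export
tidy.r_match <- function(x, ...) x$curve

#' @rdname adoptnet-tidiers
#' @export
glance.r_match <- function(x, ...) {
  tibble::tibble(r.hat = x$r_hat, target.lc.frac = x$target,
                 n.grid = nrow(x$curve))
}

#' @rdname adoptnet-tidiers
#' @export
tidy.crossover_scan <- function(x, ...) x$curve

#' @rdname adoptnet-tidiers
#' @export
glance.crossover_scan <- function(x, ...) {
  tibble::tibble(r.c = x$r_c, criterion = x$criterion,
                 n.grid = nrow(x$curve))
}

#' @rdname adoptnet-tidiers
#' @export
tidy.component_stats <- function(x, ...) x$sizes

#' @rdname adoptnet-tidiers
#' @export
glance.component_stats <- function(x, ...) {
  tibble::tibble(lc = x$lc, lc2 = x$lc2, n.nodes = x$n_nodes,
                 lc.frac = x$lc_frac)
}

#' @rdname adoptnet-tidiers
#' @export
tidy.vulnerable_forest <- function(x, ...) x$trees

#' @rdname adoptnet-tidiers
#' @export
glance.vulnerable_forest <- function(x, ...) {
  tibble::tibble(
    n.trees = nrow(x$trees),
    n.members = nrow(x$members),
    max.depth = if (nrow(x$trees)) max(x$trees$depth) else NA_integer_,
    mean.size = if (nrow(x$trees)) mean(x$trees$size) else NA_real_,
    n.orphans = x$n_orphans
  )
}

#' @rdname adoptnet-tidiers
#' @export
tidy.adoption_sim <- function(x, ...) x$series

#' @rdname adoptnet-tidiers
#' @export
glance.adoption_sim <- function(x, ...) {
  tibble::tibble(
    n = x$pop$n, r = x$pop$r, p.n = x$p_n, steps = x$steps,
    n.adopters = nrow(x$events),
    rho.final = nrow(x$events) / x$pop$n,
    rho0.final = utils::tail(x$series$rho0, 1)
  )
}
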