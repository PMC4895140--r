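# Compressed adjacency built once per simulation; neighbour lookups during
# the sweep are O(sum degree of new adopters) per iteration.
build_csr <- function(graph, n) {
  el <- igraph::as_edgelist(graph, names = FALSE)
  from <- c(el[, 1], el[, 2])
  to <- c(el[, 2], el[, 1])
  ord <- order(from)
  list(to = as.integer(to[ord]),
       ptr = c(0L, cumsum(tabulate(from, n))))
}

csr_neighbours <- function(csr, nodes) {
  idx <- unlist(lapply(nodes, function(v) {
    if (csr$ptr[v] == csr$ptr[v + 1L]) return(integer(0))
    (csr$ptr[v] + 1L):csr$ptr[v + 1L]
  }))
  csr$to[idx]
}

#' Simulate threshold-driven adoption with spontaneous adopters
#'
#' Discrete-time Monte Carlo of the contagion: per iteration, (1) every
#' susceptible non-immune node adopts spontaneously with probability
#' `p_r = p_n / (1 - r)` (so the early innovator flux per network node is
#' `p_n`); (2) one synchronous threshold sweep over the states frozen at the
#' start of the iteration: a susceptible non-immune node with `m` adopting
#' neighbours adopts iff `m / k >= phi`. All nodes adopting in the same
#' iteration share one integer timestamp and are mutually invisible to the
#' threshold rule, consistent with the analysis-side exclusion of same-time
#' links. Adoption is absorbing; the frozen state has rho(inf) = 1 - r.
#'
#' `update = "exhaustive"` instead iterates the threshold sweep to
#' exhaustion within each timestamp (cascades become instantaneous on the
#' iteration clock); the default single sweep gives cascades a finite speed
#' so that one iteration corresponds to one month under the empirical
#' calibration of `p_n`.
#'
#' @param pop A [build_population()] result.
#' @param p_n Spontaneous adoption rate per network node per iteration.
#' @param steps Number of iterations T.
#' @param update Threshold sweep mode, `"sweep"` (default) or `"exhaustive"`.
#' @return An object of class `adoption_sim`: list with `events` (tibble:
#'   `node`, `t`, `channel` ("spontaneous"/"social"), `m_at_adoption`),
#'   `series` (tibble: `t`, `rho`, `rho0` — cumulative adopter and
#'   spontaneous-adopter fractions), `pop`, `p_n`, `steps`.
#' @examples
#' set.seed(1)
#' pop <- build_population(degree_model(1.09, 1.39), threshold_model(-2, 1),
#'                         n = 300, r = 0.5)
#' sim <- simulate_adoption(pop, p_n = 0.01, steps = 30)
#' @export
simulate_adoption <- function(pop, p_n, steps,
                              update = c("sweep", "exhaustive")) {
  stopifnot(inherits(pop, "population"))
  if (p_n < 0 || p_n > 1) stop("`p_n` must lie in [0, 1]", call. = FALSE)
  if (steps < 1) stop("`steps` must be >= 1", call. = FALSE)
  update <- match.arg(update)
  n <- pop$n
  immune <- pop$nodes$immune
  if (all(immune)) {
    if (p_n > 0)
      warning("r = 1: every node is immune, event log is empty",
              call. = FALSE)
    p_r <- 0
  } else {
    p_r <- min(p_n / (1 - pop$r), 1)
  }
  deg <- pop$nodes$degree
  need <- ceiling(deg * pop$nodes$threshold)
  need[is.na(need)] <- .Machine$integer.max # immune: unreachable
  need[deg == 0L] <- 1L                     # isolated: spontaneous only
  csr <- build_csr(pop$graph, n)

  state <- logical(n)
  m <- integer(n)
  t_adopt <- rep(NA_integer_, n)
  spont <- logical(n)
  m_at <- rep(NA_integer_, n)
  for (t in seq_len(steps)) {
    susc <- which(!state & !immune)
    if (length(susc) == 0) break
    sp <- susc[stats::runif(length(susc)) < p_r]
    th <- susc[m[susc] >= need[susc]]
    new <- union(sp, th)
    if (length(new) > 0) {
      spont[setdiff(sp, th)] <- TRUE
      state[new] <- TRUE
      t_adopt[new] <- t
      m_at[new] <- m[new]
      m <- m + tabulate(csr_neighbours(csr, new), n)
      if (update == "exhaustive") {
        repeat {
          susc2 <- which(!state & !immune)
          nxt <- susc2[m[susc2] >= need[susc2]]
          if (length(nxt) == 0) break
          state[nxt] <- TRUE
          t_adopt[nxt] <- t
          m_at[nxt] <- m[nxt]
          m <- m + tabulate(csr_neighbours(csr, nxt), n)
        }
      }
    }
  }
  adopters <- which(state)
  events <- tibble::tibble(
    node = adopters,
    t = t_adopt[adopters],
    channel = ifelse(spont[adopters], "spontaneous", "social"),
    m_at_adoption = m_at[adopters]
  ) |> dplyr::arrange(.data$t, .data$node)
  counts <- tabulate(events$t, steps)
  sp_counts <- tabulate(events$t[events$channel == "spontaneous"], steps)
  series <- tibble::tibble(
    t = seq_len(steps),
    rho = cumsum(counts) / n,
    rho0 = cumsum(sp_counts) / n
  )
  structure(
    list(events = events, series = series, pop = pop, p_n = p_n,
         steps = steps, update = update),
    class = "adoption_sim"
  )
}

#' @export
print.adoption_sim <- function(x, ...) {
  cat(sprintf(
    "<adoption_sim> %d iterations, %d/%d adopters (rho = %.3f, 1 - r = %.3f)\n",
    x$steps, nrow(x$events), x$pop$n,
    nrow(x$events) / x$pop$n, 1 - x$pop$r))
  invisible(x)
}

#' Windowed adoption rates per node class
#'
#' Assigns each adopter its integer threshold Phi_k (neighbours with
#' strictly earlier adoption time) and class — innovator (Phi_k = 0),
#' vulnerable (Phi_k = 1), stable (Phi_k > 1) — then counts adoptions of
#' each class per time window, normalised per network node per window
#' (so the innovator rate plateaus at ~ p_n).
#'
#' @param pop A `population` (or igraph substrate).
#' @param events An event log tibble with columns `node`, `t`.
#' @param window Window length in iterations (1 window = 1 month under the
#'   default calibration).
#' @return A tibble with columns `t` (window end), `R_i`, `R_v`, `R_s`, `R`;
#'   `R = R_i + R_v + R_s`.
#' @export
class_rates <- function(pop, events, window = 1) {
  cls <- classify_adopters(pop, events)
  n <- if (inherits(pop, "population")) pop$n else igraph::vcount(pop)
  t_max <- max(events$t)
  win <- ceiling(cls$t / window)
  n_win <- ceiling(t_max / window)
  count_by <- function(sel) tabulate(win[sel], n_win)
  tibble::tibble(
    t = seq_len(n_win) * window,
    R_i = count_by(cls$class == "innovator") / (n * window),
    R_v = count_by(cls$class == "vulnerable") / (n * window),
    R_s = count_by(cls$class == "stable") / (n * window)
  ) |>
    dplyr::mutate(R = .data$R_i + .data$R_v + .data$R_s)
}
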