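#' Parameters of the approximate master equations
#'
#' Bundles the degree law (full integer support by default, or the
#' geometric degree-class reduction), the discrete threshold types, the
#' immune fraction `r` and the spontaneous rate `p_n` into the parameter
#' object consumed by the AME integrators. The per-non-immune-node
#' spontaneous rate is `p_r = p_n / (1 - r)`.
#'
#' The supra-threshold adoption rate (`rate_supra`, default 1 per unit
#' time) matches one threshold sweep per Monte Carlo iteration; it is
#' exposed for sensitivity checks. `rate_supra = 0` switches the social
#' channel off entirely (pure spontaneous adoption).
#'
#' @param degree A [degree_model()] or a tibble with columns `k`, `p`.
#' @param threshold A [threshold_model()] (discretised into `M` types) or a
#'   type tibble with columns `phi`, `prob`.
#' @param r Immune fraction in `[0, 1)`.
#' @param p_n Spontaneous adoption rate per network node per unit time.
#' @param M Number of threshold types when `threshold` is a continuous law.
#' @param degree_support `"full"` (all integers `k_min..k_max`) or
#'   `"classes"` (geometric classes, the setting used for the full AME).
#' @param k_lo,k_hi,n_classes Degree-class grid when
#'   `degree_support = "classes"`.
#' @param n Population size used for the structural degree cutoff.
#' @param rate_supra Adoption rate once the threshold is reached.
#' @return An object of class `ame_params`.
#' @export
ame_params <- function(degree, threshold, r, p_n, M = 25,
                       degree_support = c("full", "classes"),
                       k_lo = 3, k_hi = 150, n_classes = 25, n = 1e4,
                       rate_supra = 1) {
  if (r < 0 || r >= 1) stop("`r` must lie in [0, 1)", call. = FALSE)
  if (p_n < 0) stop("`p_n` must be >= 0", call. = FALSE)
  degree_support <- match.arg(degree_support)
  pk <- if (inherits(degree, "degree_model")) {
    if (degree_support == "classes")
      degree_classes(degree, k_lo, k_hi, n_classes, n)
    else degree_pmf(degree, n)
  } else {
    stopifnot(all(c("k", "p") %in% names(degree)))
    tibble::as_tibble(degree)
  }
  if (abs(sum(pk$p) - 1) > 1e-8) stop("degree masses must sum to 1",
                                      call. = FALSE)
  types <- if (inherits(threshold, "threshold_model")) {
    discretise_types(threshold, M)
  } else {
    stopifnot(all(c("phi", "prob") %in% names(threshold)))
    tibble::as_tibble(threshold)
  }
  if (abs(sum(types$prob) - 1) > 1e-8) stop("type masses must sum to 1",
                                            call. = FALSE)
  if (is.unsorted(types$phi, strictly = FALSE))
    stop("type thresholds must be non-decreasing", call. = FALSE)
  structure(
    list(pk = pk, types = types, r = r, p_n = p_n,
         p_r = if (r < 1) p_n / (1 - r) else 0,
         rate_supra = rate_supra,
         z = sum(pk$k * pk$p)),
    class = "ame_params"
  )
}

#' @export
print.ame_params <- function(x, ...) {
  cat(sprintf(
    "<ame_params> %d degree classes (z = %.2f), %d types, r = %g, p_n = %g (p_r = %g)\n",
    nrow(x$pk), x$z, nrow(x$types), x$r, x$p_n, x$p_r))
  invisible(x)
}

# integer exposure needed for social adoption: smallest m with m/k >= phi
m_needed <- function(k, phi) {
  mk <- ceiling(outer(k, phi))
  mk[k == 0, ] <- 1L # isolated nodes never reach the social branch
  mk
}

#' Adoption response function F_{(k,c),m}
#'
#' Rate at which a susceptible node of degree `k`, type `c` and `m`
#' adopting neighbours adopts: 0 for immune nodes (c = 0); `p_r` below
#' threshold (m < k phi_c) and for isolated non-immune nodes; the
#' supra-threshold rate (default 1) once `m >= k phi_c`.
#'
#' @param params An [ame_params()] object.
#' @param k,c,m Degree, type index (0 = immune, 1..M otherwise) and number
#'   of adopting neighbours; vectors are recycled.
#' @return A numeric vector of rates.
#' @export
response_rate <- function(params, k, c, m) {
  stopifnot(inherits(params, "ame_params"))
  len <- max(length(k), length(c), length(m))
  k <- rep_len(k, len); c <- rep_len(c, len); m <- rep_len(m, len)
  if (any(m > k)) stop("`m` cannot exceed `k`", call. = FALSE)
  if (any(c < 0) || any(c > nrow(params$types)))
    stop("type index out of range", call. = FALSE)
  out <- numeric(len)
  non_imm <- c > 0
  phi <- ifelse(non_imm, params$types$phi[pmax(c, 1)], Inf)
  supra <- non_imm & k > 0 & m >= ceiling(k * phi)
  out[non_imm] <- params$p_r
  out[supra] <- params$rate_supra
  out
}

reduced_rhs_factory <- function(params) {
  k <- params$pk$k
  pk <- params$pk$p
  z <- params$z
  phi <- params$types$phi
  pc <- params$types$prob
  mk <- m_needed(k, phi)                       # n_k x M
  Kh <- matrix(k, length(k), length(phi))
  Kg <- pmax(Kh - 1, 0)
  p_r <- params$p_r
  lam <- params$rate_supra
  r <- params$r
  if (lam > 0) {
    fac <- (1 - p_r / lam)
    function(t, y, parms) {
      rho <- y[1]; nu <- y[2]
      decay <- exp(-p_r * t)
      s_h <- sum(pk * as.numeric(stats::pbinom(mk - 1, Kh, nu) %*% pc))
      s_g <- sum((k * pk / z) *
                   as.numeric(stats::pbinom(mk - 1, Kg, nu) %*% pc))
      h <- (1 - r) * (1 - fac * decay * s_h)
      g <- (1 - r) * (1 - fac * decay * s_g)
      f0 <- decay * sum(pk * (1 - nu)^k)
      list(c(lam * (h - rho),
             lam * (g - nu),
             p_r * (1 - r) * f0,       # innovators by exposure (Phi_k = 0)
             p_r * (1 - r - rho)))     # all spontaneous adopters
    }
  } else {
    # social channel off: every non-immune susceptible adopts at p_r
    function(t, y, parms) {
      rho <- y[1]; nu <- y[2]
      decay <- exp(-p_r * t)
      f0 <- decay * sum(pk * (1 - nu)^k)
      list(c(p_r * (1 - r - rho),
             p_r * (1 - r - nu),       # neighbours adopt at the same rate
             p_r * (1 - r) * f0,
             p_r * (1 - r - rho)))
    }
  }
}

#' Integrate the reduced AME pair
#'
#' Solves the two coupled ODEs for the adopter fraction rho(t) and the
#' probability nu(t) that a random neighbour of a susceptible node is an
#' adopter, with initial conditions rho(0) = nu(0) = 0. The right-hand
#' sides mix the response function over binomial weights B_{k,m}(nu) and
#' the degree/type masses; sub-threshold susceptible occupation carries the
#' exp(-p_r t) depletion factor of spontaneous adoption. Two innovator
#' bookkeeping ODEs are integrated alongside: `rho0` (spontaneous adopters
#' with no adopting neighbour at adoption, i.e. the Phi_k = 0 innovators
#' of the empirical categorisation) and `rho0_spont` (all spontaneous
#' adopters,
#' d rho0/dt = p_r (1 - r - rho)).
#'
#' Without an explicit grid the system is integrated until the frozen
#' state, detected as `t > 20 / p_r` (by then the susceptible mass is down
#' to e^-20).
#'
#' @param params An [ame_params()] object.
#' @param t_grid Output time grid (first element must be 0), or `NULL` to
#'   integrate to the frozen state.
#' @param atol,rtol Solver tolerances (deSolve::lsoda).
#' @return A tibble of class `ame_reduced` with columns `t`, `rho`, `nu`,
#'   `rho0`, `rho0_spont`, and attributes `r`, `p_n`.
#' @export
integrate_reduced <- function(params, t_grid = NULL, atol = 1e-10,
                              rtol = 1e-8) {
  stopifnot(inherits(params, "ame_params"))
  if (is.null(t_grid)) {
    t_end <- if (params$p_r > 0) min(20 / params$p_r, 5e4) else 100
    t_grid <- unique(sort(c(seq(0, min(t_end, 200), by = 1),
                            seq(0, t_end, length.out = 400))))
  }
  stopifnot(t_grid[1] == 0, !is.unsorted(t_grid))
  if (params$p_n == 0) {
    out <- tibble::tibble(t = t_grid, rho = 0, nu = 0, rho0 = 0,
                          rho0_spont = 0)
  } else {
    rhs <- reduced_rhs_factory(params)
    sol <- deSolve::ode(c(rho = 0, nu = 0, rho0 = 0, rho0_spont = 0),
                        t_grid, rhs, NULL, method = "lsoda",
                        atol = atol, rtol = rtol)
    out <- tibble::tibble(
      t = sol[, "time"], rho = sol[, "rho"], nu = sol[, "nu"],
      rho0 = sol[, "rho0"], rho0_spont = sol[, "rho0_spont"]
    )
  }
  attr(out, "r") <- params$r
  attr(out, "p_n") <- params$p_n
  class(out) <- c("ame_reduced", class(out))
  out
}

#' Innovator fraction rho0(t)
#'
#' Extracts (or recomputes) the innovator fraction from a reduced-AME
#' solution. `"exposure"` counts spontaneous adopters that had no adopting
#' neighbour at their adoption time (the Phi_k = 0 innovators of the
#' empirical categorisation, the default); `"spontaneous"` counts every
#' spontaneous adopter, i.e. integrates p_r (1 - r - rho) dt.
#'
#' @param solution An `ame_reduced` tibble, or any data frame with columns
#'   `t` and `rho` (then only `"spontaneous"` is available and the flux is
#'   integrated by the trapezoidal rule, using `params` for `p_r`).
#' @param definition `"exposure"` or `"spontaneous"`.
#' @param params Required only for plain `t`/`rho` inputs.
#' @return A numeric vector rho0(t) aligned with `solution$t`.
#' @export
innovator_fraction <- function(solution,
                               definition = c("exposure", "spontaneous"),
                               params = NULL) {
  definition <- match.arg(definition)
  if (inherits(solution, "ame_reduced")) {
    return(if (definition == "exposure") solution$rho0
           else solution$rho0_spont)
  }
  if (definition == "exposure")
    stop("exposure-based innovators need an `ame_reduced` solution",
         call. = FALSE)
  stopifnot(!is.null(params), all(c("t", "rho") %in% names(solution)))
  flux <- params$p_r * (1 - params$r - solution$rho)
  dt <- diff(solution$t)
  c(0, cumsum(dt * (utils::head(flux, -1) + utils::tail(flux, -1)) / 2))
}

#' Critical (half-adoption) time t_c
#'
#' First time at which rho(t) crosses (1 - r) / 2, linearly interpolated
#' on the solution grid; `NA` (with a warning) if the level is not reached.
#'
#' @param solution A data frame with columns `t`, `rho` (e.g. an
#'   `ame_reduced` tibble or a Monte Carlo `series`).
#' @param r Immune fraction; taken from the solution's attribute when
#'   omitted.
#' @return The crossing time (scalar), or `NA_real_`.
#' @export
critical_time <- function(solution, r = NULL) {
  if (is.null(r)) r <- attr(solution, "r")
  stopifnot(!is.null(r), all(c("t", "rho") %in% names(solution)))
  half <- (1 - r) / 2
  i <- which(solution$rho >= half)[1]
  if (is.na(i)) {
    warning("rho never reaches (1 - r)/2 on the grid", call. = FALSE)
    return(NA_real_)
  }
  if (i == 1) return(solution$t[1])
  t0 <- solution$t[i - 1]; t1 <- solution$t[i]
  r0 <- solution$rho[i - 1]; r1 <- solution$rho[i]
  t0 + (half - r0) / (r1 - r0) * (t1 - t0)
}

#' Locate the crossover immune fraction r_c
#'
#' Scans a grid of immune fractions, integrating the reduced AME to the
#' frozen state at each point, and returns the grid r maximising the final
#' innovator fraction rho0(inf) (default) or the half-adoption time t_c.
#' At the crossover, rapid cascades give way to quenched slow adoption and
#' both measures peak.
#'
#' @param degree A [degree_model()] or degree-mass tibble.
#' @param threshold A [threshold_model()] or type tibble.
#' @param p_n Spontaneous rate per network node.
#' @param r_grid Grid of immune fractions in `[0, 1)`.
#' @param criterion `"innovator"` (max rho0(inf)) or `"critical_time"`.
#' @param definition Innovator definition passed to [innovator_fraction()].
#' @inheritParams ame_params
#' @return An object of class `crossover_scan`: list with `r_c`,
#'   `criterion`, and `curve` (tibble: `r`, `rho0_inf`, `rho0_spont_inf`,
#'   `t_c`, `rho_inf`).
#' @export
crossover_point <- function(degree, threshold, p_n, r_grid,
                            criterion = c("innovator", "critical_time"),
                            definition = "exposure", M = 25,
                            degree_support = "full",
                            k_lo = 3, k_hi = 150, n_classes = 25, n = 1e4,
                            rate_supra = 1) {
  criterion <- match.arg(criterion)
  stopifnot(all(r_grid >= 0), all(r_grid < 1))
  rows <- purrr::map(r_grid, function(r) {
    pars <- ame_params(degree, threshold, r = r, p_n = p_n, M = M,
                       degree_support = degree_support, k_lo = k_lo,
                       k_hi = k_hi, n_classes = n_classes, n = n,
                       rate_supra = rate_supra)
    sol <- integrate_reduced(pars)
    tc <- suppressWarnings(critical_time(sol, r))
    tibble::tibble(
      r = r,
      rho0_inf = utils::tail(innovator_fraction(sol, definition), 1),
      rho0_spont_inf = utils::tail(sol$rho0_spont, 1),
      t_c = tc,
      rho_inf = utils::tail(sol$rho, 1)
    )
  })
  curve <- dplyr::bind_rows(rows)
  score <- if (criterion == "innovator") curve$rho0_inf else curve$t_c
  i <- which.max(score)
  if (i == 1 || i == length(r_grid))
    warning("maximum at the boundary of `r_grid`; grid may be too narrow",
            call. = FALSE)
  structure(list(r_c = r_grid[i], criterion = criterion, curve = curve),
            class = "crossover_scan")
}

#' @export
print.crossover_scan <- function(x, ...) {
  cat(sprintf("<crossover_scan> r_c = %g (criterion: %s, %d grid points)\n",
              x$r_c, x$criterion, nrow(x$curve)))
  invisible(x)
}

#' Normalised adoption surface in (w, z)-space
#'
#' For every grid point, the degree-law location is re-derived so the mean
#' degree equals `z` and the threshold-law location so the truncated mean
#' equals `w` (widths `sigma_D`, `sigma_T` held fixed), the reduced AME is
#' integrated to time `t`, and the normalised adoption rho/(1 - r) is
#' reported. Cells where no lognormal location attains the requested `w`
#' or `z` are masked (`NA`). A contour at `level` (default 0.2, i.e. 20%
#' of non-immune nodes adopted) is extracted from the surface.
#'
#' @param w_grid,z_grid Grids of average thresholds / degrees.
#' @param t Evaluation time (iterations).
#' @param r Immune fraction.
#' @param p_n Spontaneous rate.
#' @param sigma_D,sigma_T Fixed widths of the degree / threshold laws.
#' @param k_min Minimum degree.
#' @param level Contour level for the normalised adoption.
#' @param M,n Type count and structural-cutoff size for the AME.
#' @return An object of class `phase_surface`: list with `surface` (tibble:
#'   `w`, `z`, `rho_norm`), `contour` (tibble: `piece`, `w`, `z`), `t`,
#'   `r`, `level`.
#' @export
phase_surface <- function(w_grid, z_grid, t, r, p_n,
                          sigma_D = 1.39, sigma_T = 1, k_min = 1,
                          level = 0.2, M = 10, n = 1e4) {
  stopifnot(all(w_grid > 0), all(z_grid > 0), t >= 0)
  mu_for_w <- function(w) {
    f <- function(mu) threshold_moments(threshold_model(mu, sigma_T))$mean - w
    if (f(-30) > 0 || f(10) < 0) return(NA_real_)
    stats::uniroot(f, c(-30, 10), tol = 1e-9)$root
  }
  mu_for_z <- function(z) {
    f <- function(mu) degree_mean(degree_model(mu, sigma_D, k_min), n) - z
    if (f(-10) > 0 || f(8) < 0) return(NA_real_)
    stats::uniroot(f, c(-10, 8), tol = 1e-9)$root
  }
  mu_t <- vapply(w_grid, mu_for_w, 1.0)
  mu_d <- vapply(z_grid, mu_for_z, 1.0)
  cells <- tidyr::expand_grid(iw = seq_along(w_grid), iz = seq_along(z_grid))
  rho_norm <- purrr::pmap_dbl(cells, function(iw, iz) {
    if (is.na(mu_t[iw]) || is.na(mu_d[iz])) return(NA_real_)
    if (t == 0) return(0)
    pars <- ame_params(degree_model(mu_d[iz], sigma_D, k_min),
                       threshold_model(mu_t[iw], sigma_T),
                       r = r, p_n = p_n, M = M, n = n)
    sol <- integrate_reduced(pars, t_grid = c(0, t))
    utils::tail(sol$rho, 1) / (1 - r)
  })
  surface <- tibble::tibble(
    w = w_grid[cells$iw], z = z_grid[cells$iz], rho_norm = rho_norm
  )
  contour <- tibble::tibble(piece = integer(0), w = numeric(0),
                            z = numeric(0))
  if (length(w_grid) >= 2 && length(z_grid) >= 2) {
    m <- matrix(rho_norm, nrow = length(w_grid), byrow = TRUE)
    if (any(is.finite(m))) {
      m2 <- m
      m2[!is.finite(m2)] <- -1
      cl <- grDevices::contourLines(w_grid, z_grid, m2, levels = level)
      if (length(cl) > 0)
        contour <- dplyr::bind_rows(purrr::imap(cl, function(p, i) {
          tibble::tibble(piece = i, w = p$x, z = p$y)
        }))
    }
  }
  structure(list(surface = surface, contour = contour, t = t, r = r,
                 level = level),
            class = "phase_surface")
}

#' Integrate the full approximate master equations
#'
#' Tracks the fraction s_{(k,c),m}(t) of nodes of degree k and type c that
#' are susceptible with m adopting neighbours, for every m in 0..k. The
#' coupling rate beta_s(t) (rate at which a susceptible neighbour of a
#' susceptible node adopts) is computed from the response function over
#' the degree-biased class masses. This is the high-dimensional system the
#' reduced pair approximates; on single-type regular substrates the
#' reduction is exact and the two solutions agree to solver tolerance.
#'
#' @param params An [ame_params()] object (use `degree_support = "classes"`
#'   or a small custom degree table; the state dimension is
#'   `sum(k + 1) * (M + 1)` and is capped at `max_dim`).
#' @param t_grid Output time grid starting at 0.
#' @param max_dim Guard on the state dimension.
#' @param keep_states Return the full occupation table over time.
#' @return A list with `series` (tibble `t`, `rho`, `nu`), `index` (tibble
#'   `k`, `c`, `m`), and optionally `states` (matrix, rows = times).
#' @export
integrate_full_ame <- function(params, t_grid, max_dim = 2e4,
                               keep_states = FALSE) {
  stopifnot(inherits(params, "ame_params"), t_grid[1] == 0)
  kk <- params$pk$k
  pkv <- params$pk$p
  phi <- params$types$phi
  pc <- params$types$prob
  M <- length(phi)
  r <- params$r
  idx <- tidyr::expand_grid(ki = seq_along(kk), c = 0:M) |>
    dplyr::mutate(k = kk[.data$ki]) |>
    tidyr::uncount(.data$k + 1, .id = "mi") |>
    dplyr::mutate(m = .data$mi - 1L) |>
    dplyr::select("k", "c", "m")
  dim_total <- nrow(idx)
  if (dim_total > max_dim)
    stop("full AME dimension ", dim_total,
         " exceeds `max_dim`; coarsen the degree classes", call. = FALSE)
  # per-entry constants
  kv <- idx$k; cv <- idx$c; mv <- idx$m
  class_mass <- ifelse(cv == 0, r * pkv[match(kv, kk)],
                       (1 - r) * pkv[match(kv, kk)] * pc[pmax(cv, 1)])
  need <- ifelse(cv == 0, Inf,
                 ifelse(kv == 0, Inf, ceiling(kv * phi[pmax(cv, 1)])))
  fv <- ifelse(cv == 0, 0,
               ifelse(mv >= need, params$rate_supra, params$p_r))
  wdeg <- kv * class_mass / params$z # degree-biased weight per entry
  shift_from <- match(paste(kv, cv, mv - 1), paste(kv, cv, mv))
  y0 <- as.numeric(mv == 0)

  rhs <- function(t, y, parms) {
    num <- sum(wdeg * (kv - mv) * fv * y)
    den <- sum(wdeg * (kv - mv) * y)
    beta <- if (den > 1e-300) num / den else 0
    inflow <- ifelse(is.na(shift_from), 0, y[shift_from] *
                       (kv - mv + 1))
    list(-fv * y - beta * (kv - mv) * y + beta * inflow)
  }
  sol <- deSolve::ode(y0, t_grid, rhs, NULL, method = "lsoda",
                      atol = 1e-10, rtol = 1e-8)
  states <- sol[, -1, drop = FALSE]
  rho <- 1 - as.numeric(states %*% class_mass)
  # nu estimated from the degree-biased susceptible-edge occupancy
  nu <- as.numeric(states %*% (wdeg * mv)) /
    pmax(as.numeric(states %*% (wdeg * kv)), 1e-300)
  out <- list(series = tibble::tibble(t = sol[, 1], rho = rho, nu = nu),
              index = idx)
  if (keep_states) out$states <- states
  out
}
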