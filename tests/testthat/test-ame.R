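toy_params <- function(k = 5, phi = 0.3, r = 0, p_n = 1e-3, ...) {
  ame_params(tibble::tibble(k = k, p = rep(1 / length(k), length(k))),
             tibble::tibble(phi = phi, prob = rep(1 / length(phi),
                                                  length(phi))),
    r = r, p_n = p_n, ...)
}

test_that("response function implements the threshold rule and boundaries", {
  pars <- toy_params(k = 10, phi = 0.19, r = 0.2, p_n = 0.001)
  # immune nodes never adopt
  expect_equal(response_rate(pars, k = c(0, 3, 10), c = 0, m = c(0, 2, 9)),
               rep(0, 3))
  # isolated non-immune nodes only adopt spontaneously
  expect_equal(response_rate(pars, k = 0, c = 1, m = 0), pars$p_r)
  # k = 10, phi = 0.19: m = 2 >= 1.9 reaches the supra-threshold branch
  expect_equal(response_rate(pars, k = 10, c = 1, m = 2), 1)
  expect_equal(response_rate(pars, k = 10, c = 1, m = 1), pars$p_r)
  expect_error(response_rate(pars, k = 3, c = 1, m = 4), "exceed")
})

test_that("reduced AME has the trivial fixed point and the frozen limit", {
  pars <- toy_params(p_n = 0)
  sol <- integrate_reduced(pars, t_grid = 0:10)
  expect_true(all(sol$rho == 0) && all(sol$nu == 0))

  pars2 <- ame_params(ref_degree(), ref_threshold(), r = 0.4,
                      p_n = 0.01, M = 10, n = 1e3)
  sol2 <- integrate_reduced(pars2)
  expect_equal(utils::tail(sol2$rho, 1), 0.6, tolerance = 1e-3)
  expect_true(all(diff(sol2$rho) >= -1e-9))
  expect_true(all(sol2$rho0 <= sol2$rho + 1e-9))
})

test_that("reduced pair matches the full AME on a single-type regular toy", {
  tg <- seq(0, 80, by = 2)
  pars <- toy_params(k = 5, phi = 0.3, r = 0, p_n = 1e-3)
  red <- integrate_reduced(pars, t_grid = tg)
  full <- integrate_full_ame(pars, t_grid = tg)
  expect_lt(max(abs(red$rho - full$series$rho)), 1e-3)

  # with immune nodes present
  pars2 <- toy_params(k = 6, phi = 0.25, r = 0.3, p_n = 2e-3)
  red2 <- integrate_reduced(pars2, t_grid = tg)
  full2 <- integrate_full_ame(pars2, t_grid = tg)
  expect_lt(max(abs(red2$rho - full2$series$rho)), 1e-3)
})

test_that("full AME occupation fractions are monotone and frozen at p_n = 0", {
  tg <- seq(0, 30, by = 1)
  pars <- toy_params(k = 4, phi = 0.4, r = 0.2, p_n = 5e-3)
  full <- integrate_full_ame(pars, tg, keep_states = TRUE)
  expect_true(all(diff(full$series$rho) >= -1e-9))
  expect_true(all(full$states >= -1e-9 & full$states <= 1 + 1e-9))
  # each susceptible class can only lose mass to larger m or adoption:
  # the total susceptible fraction decreases
  total_s <- rowSums(full$states)
  expect_true(all(diff(total_s) <= 1e-9))

  frozen <- integrate_full_ame(toy_params(k = 4, phi = 0.4, p_n = 0), tg,
                               keep_states = TRUE)
  expect_true(all(abs(frozen$states - rep(frozen$states[1, ],
                                          each = length(tg))) < 1e-9))
})

test_that("innovator fraction obeys its closed forms", {
  # social channel unreachable (phi > 1): pure spontaneous adoption
  pars <- ame_params(tibble::tibble(k = 4, p = 1),
                     tibble::tibble(phi = 1.5, prob = 1),
                     r = 0, p_n = 0.02)
  tg <- seq(0, 100, by = 1)
  sol <- integrate_reduced(pars, t_grid = tg)
  expect_equal(sol$rho0_spont, 1 - exp(-0.02 * tg), tolerance = 1e-6)
  expect_equal(sol$rho, 1 - exp(-0.02 * tg), tolerance = 1e-6)

  # p_n = 0: no innovators at all
  sol0 <- integrate_reduced(toy_params(p_n = 0), t_grid = 0:10)
  expect_true(all(innovator_fraction(sol0) == 0))

  # trapezoidal reconstruction agrees with the integrated ODE
  pars2 <- ame_params(ref_degree(), ref_threshold(), r = 0.5,
                      p_n = 0.001, M = 10, n = 1e3)
  sol2 <- integrate_reduced(pars2, t_grid = seq(0, 200, by = 0.5))
  recon <- innovator_fraction(tibble::as_tibble(sol2)[, c("t", "rho")],
                              definition = "spontaneous", params = pars2)
  expect_lt(max(abs(recon - sol2$rho0_spont)), 5e-4)

  expect_error(innovator_fraction(data.frame(t = 0:2, rho = c(0, 0, 0))),
               "ame_reduced")
})

test_that("critical time interpolates the half-adoption crossing", {
  r <- 0.4
  tt <- seq(0, 12, by = 0.01)
  series <- tibble::tibble(t = tt, rho = (1 - r) * (1 - exp(-tt)))
  expect_equal(critical_time(series, r), log(2), tolerance = 1e-4)

  # monotone series: the crossing found is the unique one
  expect_equal(sum(series$rho >= (1 - r) / 2 &
                     dplyr::lag(series$rho, default = 0) < (1 - r) / 2), 1)

  flat <- tibble::tibble(t = 0:5, rho = rep(0.01, 6))
  expect_warning(tc <- critical_time(flat, 0.5), "never")
  expect_true(is.na(tc))
})

test_that("crossover scan finds interior maxima consistently", {
  rg <- seq(0.65, 0.9, by = 0.05)
  sc_i <- crossover_point(ref_degree(), ref_threshold(),
                          p_n = 0.00019, r_grid = rg, M = 25,
                          degree_support = "classes")
  sc_t <- crossover_point(ref_degree(), ref_threshold(),
                          p_n = 0.00019, r_grid = rg, M = 25,
                          degree_support = "classes",
                          criterion = "critical_time")
  # dual-criterion consistency within one grid step
  expect_lte(abs(sc_i$r_c - sc_t$r_c), 0.0501)
  expect_equal(nrow(sc_i$curve), length(rg))
  expect_true(all(diff(sc_i$curve$rho_inf) < 0)) # rho(inf) = 1 - r

  # no social channel: rho0(inf) = 1 - r is monotone, boundary warning
  expect_warning(
    sc0 <- crossover_point(tibble::tibble(k = 4, p = 1),
                           tibble::tibble(phi = 1.5, prob = 1),
                           p_n = 0.001, r_grid = c(0.2, 0.4, 0.6)),
    "boundary")
  expect_equal(sc0$r_c, 0.2)
  expect_equal(sc0$curve$rho0_spont_inf, 1 - c(0.2, 0.4, 0.6),
               tolerance = 1e-3)
})

test_that("phase surface behaves like the adoption phase diagram", {
  wg <- c(0.1, 0.2, 0.35)
  zg <- c(3, 5, 8)
  ps <- phase_surface(wg, zg, t = 40, r = 0.2, p_n = 0.00019, M = 6,
                      n = 1e3)
  s <- tidyr::pivot_wider(ps$surface, names_from = "z",
                          values_from = "rho_norm")
  m <- as.matrix(s[, -1]) # rows = w, cols = z
  # larger thresholds always impede adoption
  expect_true(all(apply(m, 2, diff) <= 1e-6))
  # inside the cascading region more contacts help; outside it adoption is
  # spontaneous-dominated and the ordering is not guaranteed
  casc_rows <- apply(m, 1, function(x) all(x >= ps$level))
  expect_true(all(apply(m[casc_rows, , drop = FALSE], 1, diff) >= -1e-6))
  expect_gt(sum(casc_rows), 0)

  # t = 0: empty surface
  ps0 <- phase_surface(wg, zg, t = 0, r = 0.2, p_n = 0.00019, M = 6,
                       n = 1e3)
  expect_true(all(ps0$surface$rho_norm == 0))

  # adoption is pointwise monotone in time, and the high-adoption region
  # (cells above the contour level) shrinks as r grows
  ps_late <- phase_surface(wg, zg, t = 89, r = 0.2, p_n = 0.00019, M = 6,
                           n = 1e3)
  ps_imm <- phase_surface(wg, zg, t = 40, r = 0.7, p_n = 0.00019, M = 6,
                          n = 1e3)
  expect_true(all(ps_late$surface$rho_norm >= ps$surface$rho_norm - 1e-6))
  region <- function(p) mean(p$surface$rho_norm >= p$level, na.rm = TRUE)
  expect_gte(region(ps_late), region(ps))
  expect_lte(region(ps_imm), region(ps))

  # infeasible w (no lognormal location reaches w ~ 1) is masked
  ps_bad <- phase_surface(c(0.2, 0.999), c(6), t = 5, r = 0, p_n = 1e-4,
                          M = 4, n = 500)
  expect_true(is.na(ps_bad$surface$rho_norm[ps_bad$surface$w == 0.999][1]))
})

test_that("ame_params validates its inputs", {
  expect_error(ame_params(ref_degree(), ref_threshold(), r = 1,
                          p_n = 0.1), "r")
  expect_error(toy_params(phi = c(0.5, 0.2)), "non-decreasing")
  expect_error(ame_params(tibble::tibble(k = 3, p = 0.5),
                          tibble::tibble(phi = 0.2, prob = 1),
                          r = 0, p_n = 0.1), "sum to 1")
  full_dim <- ame_params(ref_degree(), ref_threshold(), r = 0.1,
                         p_n = 1e-4, M = 25, degree_support = "classes")
  expect_error(integrate_full_ame(full_dim, 0:5, max_dim = 100),
               "coarsen")
})
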