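test_that("mode coefficients obey their algebraic structure", {
  p <- baseline_params(lam = 0)
  mc <- mode_coefficients(p, 1:5)
  r2 <- mc$r2[1]
  # lambda = 0, n = 1: r7 = r6 + pi^2, r8 = r2 pi^2 / (r6 + pi^2)
  expect_equal(mc$r7[1], mc$r6[1] + pi^2, tolerance = 1e-14)
  expect_equal(mc$r8[1], r2 * pi^2 / (mc$r6[1] + pi^2), tolerance = 1e-14)
  # symbolic substitution oracle for the temperature coefficients
  expect_equal(mc$r4, r2 * mc$sigma_n^2 / (mc$r1 + mc$sigma_n^2), tolerance = 1e-14)
  expect_equal(mc$r5, mc$sigma_n / mc$r3, tolerance = 1e-14)
  # algebraic bounds: the relaxation rates never exceed r2
  expect_true(all(mc$r4 < r2))
  expect_true(all(mc$r8 < r2))
  expect_true(all(mc$r1 > 0 & mc$r3 > 0 & mc$r6 > 0 & mc$r7 > 0))
  # shared prefactor: A3/A4 = (r2 - r4)^2 / (r2 - r8)^2
  p3 <- baseline_params(lam = 3)
  mc3 <- mode_coefficients(p3, 1:6)
  expect_equal(mc3$A3 / mc3$A4, (mc3$r2 - mc3$r4)^2 / (mc3$r2 - mc3$r8)^2,
               tolerance = 1e-12)
  expect_error(mode_coefficients(baseline_params(alpha = 1), 1),
               class = "thnflow_classical_limit")
  expect_error(mode_coefficients(p, 0), class = "thnflow_domain_error")
})

test_that("steady velocity satisfies the momentum balance and its boundary conditions", {
  for (lam in c(0, 1, 3, 5)) {
    for (G in c(0, 1.2, 2)) {
      expect_equal(steady_velocity(0, G, lam), 1, tolerance = 1e-12)
      expect_equal(steady_velocity(1, G, lam), 0, tolerance = 1e-12)
      if (lam > 0) {
        # finite-difference residual of 0 = G + w'' - lam w''''
        xi <- seq(0.2, 0.8, by = 0.1)
        h <- 1e-2
        sten <- function(k) steady_velocity(xi + k * h, G, lam)
        d2 <- (sten(1) - 2 * sten(0) + sten(-1)) / h^2
        d4 <- (sten(2) - 4 * sten(1) + 6 * sten(0) - 4 * sten(-1) + sten(-2)) / h^4
        expect_true(max(abs(G + d2 - lam * d4)) < 1e-3)
        # hinged ends: w'' = 0 at the wall
        expect_lt(abs((steady_velocity(2 * h, G, lam) -
                         2 * steady_velocity(h, G, lam) +
                         steady_velocity(0, G, lam)) / h^2), 1e-2)
      }
    }
  }
  # reduces to the printed lambda = 1 closed form
  xi <- seq(0, 1, by = 0.05)
  G <- 2
  printed <- 1 - G - (1 - G / 2) * xi - G / 2 * xi^2 +
    G * cosh(0.5 - xi) / cosh(0.5)
  expect_equal(steady_velocity(xi, G, 1), printed, tolerance = 1e-12)
})

test_that("temperature and velocity satisfy the wall conditions at all times", {
  xi <- c(0, interior_grid(), 1)
  for (tau in c(0.5, 1, 2)) {
    for (p in list(baseline_params(), baseline_params(alpha = 0.3),
                   baseline_params(alpha = 0.9), baseline_params(lam = 0, G = 0),
                   baseline_params(phi_total = 0))) {
      th <- temperature_profile(p, tau, xi)
      w <- velocity_profile(p, tau, xi)
      expect_lt(abs(th$value[1] - 1), 1e-6)
      expect_lt(abs(th$value[length(xi)]), 1e-6)
      expect_lt(abs(w$value[1] - 1), 1e-6)
      expect_lt(abs(w$value[length(xi)]), 1e-6)
      expect_true(all(is.finite(th$value)) && all(is.finite(w$value)))
    }
  }
})

test_that("interior fields converge under truncation refinement", {
  p <- baseline_params()
  xi <- interior_grid()
  th_a <- temperature_profile(p, 1, xi, n_modes = 500, series_tol = 1e-7)
  th_b <- temperature_profile(p, 1, xi, n_modes = 2000, series_tol = 1e-9)
  expect_lt(max(abs(th_a$value - th_b$value)), 1e-7)
  w_a <- velocity_profile(p, 1, xi, n_modes = 500, series_tol = 1e-7)
  w_b <- velocity_profile(p, 1, xi, n_modes = 2000, series_tol = 1e-9)
  expect_lt(max(abs(w_a$value - w_b$value)), 1e-7)
  # an unreachable tolerance is reported, carrying the tail estimate
  err <- tryCatch(temperature_profile(p, 1, xi, n_modes = 30, series_tol = 1e-12),
                  error = identity)
  expect_s3_class(err, "thnflow_convergence_error")
  expect_true(is.finite(err$tail_estimate))
})

test_that("fields relax toward their initial state as tau -> 0+", {
  p <- baseline_params()
  xi <- interior_grid()
  l1_th <- vapply(c(0.05, 0.5, 2), function(tt) {
    mean(abs(temperature_profile(p, tt, xi)$value))
  }, numeric(1))
  expect_true(all(diff(l1_th) > 0))
  l1_w <- vapply(c(0.05, 0.5, 2), function(tt) {
    mean(abs(velocity_profile(p, tt, xi)$value))
  }, numeric(1))
  expect_true(all(diff(l1_w) > 0))
})

# independent series evaluation of the buoyancy steady correction
# (sine coefficients B2 / (sigma_n s)); used to check late-time limits
buoyancy_steady_ref <- function(params, xi, N = 4000) {
  n <- seq_len(N)
  sg <- n * pi
  s <- sg^2 + params$lam * sg^4
  coef <- params$B2 / (sg * s)
  2 * colSums(coef * sin(outer(sg, xi)))
}

test_that("classical limit is continuous in alpha and has exponential transients", {
  xi <- seq(0, 1, by = 0.05)
  p999 <- baseline_params(alpha = 0.999)
  p1 <- baseline_params(alpha = 1)
  th999 <- temperature_profile(p999, 1, xi)
  th1 <- classical_limit_profile(p1, 1, xi, "temperature")
  expect_lt(max(abs(th999$value - th1$value)), 1e-3)
  w999 <- velocity_profile(p999, 1, xi)
  w1 <- classical_limit_profile(p1, 1, xi, "velocity")
  expect_lt(max(abs(w999$value - w1$value)), 1e-3)

  # per-mode decay rate equals the analytic alpha -> 1 limit of r4:
  # sigma_n^2 / B3 for temperature (mode-1 dominated at late times)
  tgrid <- c(2, 2.5)
  dev1 <- vapply(tgrid, function(tt) {
    pr <- classical_limit_profile(p1, tt, 0.5, "temperature")
    pr$value - steady_temperature(0.5)
  }, numeric(1))
  rate <- -diff(log(abs(dev1))) / diff(tgrid)
  expect_equal(rate, pi^2 / p1$B3, tolerance = 1e-2)

  # profile routing: alpha = 1 inputs go through the classical path
  th_route <- temperature_profile(p1, 1, xi)
  expect_equal(th_route$value, th1$value, tolerance = 1e-14)
  # steady parts are identical to the closed forms
  big <- classical_limit_profile(p1, 400, xi, "velocity")
  expect_lt(max(abs(big$value -
                      (steady_velocity(xi, p1$G, p1$lam) +
                         buoyancy_steady_ref(p1, xi)))), 1e-6)
})

test_that("velocity trends follow the model's monotone responses", {
  xi <- 0.5
  at <- function(p, tau = 1) velocity_profile(p, tau, xi)$value
  # pressure and buoyancy accelerate the flow
  g_vals <- vapply(c(0, 1, 2, 3), function(G) at(baseline_params(G = G)), numeric(1))
  expect_true(all(diff(g_vals) > 0))
  gr_vals <- vapply(c(0, 2, 4, 6), function(Gr) at(baseline_params(Gr = Gr)), numeric(1))
  expect_true(all(diff(gr_vals) > 0))
  # couple stress, Reynolds and Prandtl retard it
  lam_vals <- vapply(c(1, 3, 5), function(l) at(baseline_params(lam = l)), numeric(1))
  expect_true(all(diff(lam_vals) < 0))
  re_vals <- vapply(c(1.2, 1.5, 2), function(r) at(baseline_params(Re = r)), numeric(1))
  expect_true(all(diff(re_vals) < 0))
  pr_vals <- vapply(c(21, 22, 25), function(q) at(baseline_params(Pr = q)), numeric(1))
  expect_true(all(diff(pr_vals) < 0))
  # early-time memory effect: larger alpha slows the initial rise
  a_vals <- vapply(c(0.3, 0.5, 0.7, 0.9), function(a) {
    at(baseline_params(alpha = a), tau = 0.1)
  }, numeric(1))
  expect_true(all(diff(a_vals) < 0))
})

test_that("temperature trends follow the model's monotone responses", {
  xi <- 0.5
  at <- function(p, tau = 1) temperature_profile(p, tau, xi)$value
  phi_vals <- vapply(c(0, 0.01, 0.02, 0.04), function(ph) {
    at(baseline_params(phi_total = ph))
  }, numeric(1))
  expect_true(all(diff(phi_vals) > 0))
  re_vals <- vapply(c(1.2, 1.5, 2), function(r) at(baseline_params(Re = r)), numeric(1))
  expect_true(all(diff(re_vals) < 0))
  pr_vals <- vapply(c(21, 22, 25), function(q) at(baseline_params(Pr = q)), numeric(1))
  expect_true(all(diff(pr_vals) < 0))
})

test_that("profiles persist as deterministic CSV", {
  p <- baseline_params()
  prof <- temperature_profile(p, 1, seq(0, 1, by = 0.25))
  path1 <- withr::local_tempfile(fileext = ".csv")
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_profile(prof, path1)
  write_profile(temperature_profile(p, 1, seq(0, 1, by = 0.25)), path2)
  expect_identical(readLines(path1), readLines(path2))
  back <- readr::read_csv(path1, show_col_types = FALSE)
  expect_equal(back$value, prof$value, tolerance = 1e-12)
  expect_s3_class(ggplot2::autoplot(prof), "ggplot")
})
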