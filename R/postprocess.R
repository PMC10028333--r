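# Wall heat-transfer quantities. The wall gradient is computed by term-wise
# analytic differentiation of the temperature series (cosines at xi = 0),
# never by finite-differencing samples. The raw derivative series decays
# only like 1/n^2, so the tail is resummed exactly: with
# E_inf = E_alpha(-r2 tau^alpha) the constant part of the mode factors,
#   -dtheta/dxi(0) = 1 + E_inf (sqrt(r1) coth sqrt(r1) - 1)
#                      + 2 sum_n r1 (E_n - E_inf) / r3,
# using sum_n r1/(r1 + n^2 pi^2) = (sqrt(r1) coth(sqrt(r1)) - 1)/2; the
# remaining summand decays like 1/n^4.

wall_temperature_gradient <- function(params, tau, n_modes = 400) {
  if (length(tau) != 1 || tau <= 0) abort_domain("tau must be a single value > 0")
  if (params$alpha == 1) {
    n <- seq_len(max(n_modes, 50))
    terms <- 2 * exp(-(n * pi)^2 * tau / params$B3)
    return(1 + sum(terms[terms > 1e-18]))
  }
  mc <- mode_coefficients(params, seq_len(n_modes))
  alpha <- params$alpha
  Einf <- mittag_leffler(-mc$r2[1] * tau^alpha, alpha)
  En <- mittag_leffler(-mc$r4 * tau^alpha, alpha)
  r1 <- mc$r1[1]
  sq <- sqrt(r1)
  1 + Einf * (sq / tanh(sq) - 1) + sum(2 * r1 * (En - Einf) / mc$r3)
}

# Printed-table anchors used (only) to select between the two candidate
# Nusselt definitions: the particle-free baseline and the phi = 0.02
# tri-hybrid row at alpha = 0.5, tau = 1, Pr = 21, Re = 1.2.
.nu_anchor_baseline <- 4.708
.nu_anchor_phi02 <- 4.898

.thnf_cache <- new.env(parent = emptyenv())

#' Calibrate the Nusselt-number definition
#'
#' The source tables print Nusselt values but never the defining formula.
#' Two physically standard candidates are considered: the bare dimensionless
#' wall gradient `-dtheta/dxi` at the hot wall, and the conductivity-scaled
#' gradient `chi11 * (-dtheta/dxi)` (i.e. `Nu = k_hnf/k_bf * gradient`, the
#' usual nanofluid convention). Both coincide in the particle-free baseline
#' (`chi11 = 1`), which therefore only validates the temperature solution;
#' the tri-hybrid `phi = 0.02` table row separates them. The candidate
#' matching the printed values within 0.5% is selected; if neither matches,
#' both are reported with a warning and downstream Nusselt calls fall back
#' to the conductivity-scaled form.
#'
#' @param n_modes Fourier truncation for the wall-gradient series.
#' @return A list with elements `definition` (the selected definition
#'   string), `matched` (logical), and `reference` (a tibble of candidate
#'   values against the printed anchors).
#' @export
calibrate_nusselt_definition <- function(n_modes = 400) {
  if (!is.null(.thnf_cache$nu_calibration)) return(.thnf_cache$nu_calibration)
  base_par <- function(phi_total) {
    f <- phi_total / 3
    model_parameters(mixture_state(f, f, f), alpha = 0.5, beta_casson = 1.2,
                     lam = 3, G = 2, Gr = 4, Pr = 21, Re = 1.2)
  }
  p0 <- base_par(0)
  p02 <- base_par(0.02)
  g0 <- wall_temperature_gradient(p0, tau = 1, n_modes = n_modes)
  g02 <- wall_temperature_gradient(p02, tau = 1, n_modes = n_modes)
  chi11 <- p02$mixture$chi[["chi11"]]
  reference <- tibble::tibble(
    candidate = c("gradient", "gradient", "gradient_times_kratio"),
    case = c("phi = 0 baseline", "phi = 0.02", "phi = 0.02"),
    value = c(g0, g02, chi11 * g02),
    printed = c(.nu_anchor_baseline, .nu_anchor_phi02, .nu_anchor_phi02)
  )
  reference$rel_dev <- abs(reference$value - reference$printed) / reference$printed
  baseline_ok <- abs(g0 - .nu_anchor_baseline) / .nu_anchor_baseline < 0.005
  hit <- reference$case == "phi = 0.02" & reference$rel_dev < 0.005
  if (baseline_ok && any(hit)) {
    definition <- reference$candidate[which(hit)[1]]
    matched <- TRUE
  } else {
    rlang::warn(paste0(
      "no candidate Nusselt definition matches the printed anchors within 0.5%; ",
      "falling back to the conductivity-scaled wall gradient"
    ))
    definition <- "gradient_times_kratio"
    matched <- FALSE
  }
  out <- list(definition = definition, matched = matched, reference = reference)
  .thnf_cache$nu_calibration <- out
  out
}

#' Nusselt number at the hot wall
#'
#' Wall heat-transfer rate of the temperature solution, by term-wise
#' analytic differentiation of the sine series with exact tail resummation
#' (see the methods vignette). With `definition = "calibrated"` the
#' definition selected by [calibrate_nusselt_definition()] is used
#' (the conductivity-scaled gradient, `chi11 * (-dtheta/dxi)|_0`).
#'
#' @inheritParams temperature_profile
#' @param definition `"calibrated"`, `"gradient"` or
#'   `"gradient_times_kratio"`.
#' @return The Nusselt number (scalar), with the definition used and the
#'   calibration outcome attached as attributes.
#' @export
#' @examples
#' p <- model_parameters(mixture_state(0, 0, 0), alpha = 0.5,
#'                       beta_casson = 1.2, lam = 3, G = 2, Gr = 4,
#'                       Pr = 21, Re = 1.2)
#' nusselt(p, tau = 1)
nusselt <- function(params, tau = 1,
                    definition = c("calibrated", "gradient", "gradient_times_kratio"),
                    n_modes = 400) {
  definition <- match.arg(definition)
  calib <- NULL
  if (definition == "calibrated") {
    calib <- calibrate_nusselt_definition(n_modes = n_modes)
    definition <- calib$definition
  }
  grad <- wall_temperature_gradient(params, tau, n_modes = n_modes)
  value <- if (definition == "gradient_times_kratio") {
    params$mixture$chi[["chi11"]] * grad
  } else {
    grad
  }
  structure(value, definition = definition,
            calibrated = if (is.null(calib)) NA else calib$matched)
}

#' Skin friction at the moving wall
#'
#' Candidate wall shear definition
#' \deqn{C_f = (1 + 1/\beta)\,\partial_\xi w|_{\xi=0}
#'       - \lambda\,\partial_\xi^3 w|_{\xi=0},}
#' evaluated by term-wise analytic differentiation of the velocity series
#' plus the exact derivatives of the closed-form steady part. The source
#' never prints a skin-friction formula, so this is an explicit candidate
#' and is flagged as such in the result's attributes.
#'
#' @inheritParams temperature_profile
#' @return The skin-friction value with attribute `candidate_definition`.
#' @export
skin_friction <- function(params, tau = 1, n_modes = 2000) {
  if (length(tau) != 1 || tau <= 0) abort_domain("tau must be a single value > 0")
  G <- params$G
  lam <- params$lam
  if (lam > 0) {
    rl <- sqrt(lam)
    th <- tanh(0.5 / rl)
    d1_steady <- -1 + G * (0.5 - rl * th)
    d3_steady <- -(G / rl) * th
  } else {
    d1_steady <- -1 + G / 2
    d3_steady <- 0
  }
  n <- seq_len(n_modes)
  sg <- n * pi / params$h
  if (params$alpha == 1) {
    Tn <- classical_velocity_transient(params, n, tau)
  } else {
    mc <- mode_coefficients(params, n)
    Tn <- velocity_mode_transient(params, mc, tau)
  }
  d1 <- d1_steady + 2 * sum(Tn * sg)
  d3 <- d3_steady - 2 * sum(Tn * sg^3)
  value <- (1 + 1 / params$beta_casson) * d1 - lam * d3
  structure(value,
            candidate_definition = "(1 + 1/beta) dw/dxi|0 - lambda d3w/dxi3|0",
            wall_gradient = d1, wall_third_derivative = d3)
}

#' Heat-transfer enhancement table
#'
#' Nusselt numbers and percentage enhancement over the particle-free
#' baseline for a sweep of total volume fractions, for the tri-hybrid
#' suspension or a single species. The canonical fixed parameter set of the
#' printed tables is used by default: `alpha = 0.5`, `tau = 1`, `Pr = 21`,
#' `Re = 1.2`. Enhancement is `100 (Nu(phi) - Nu(0)) / Nu(0)`; the zero
#' fraction must be part of `phis` to provide the baseline.
#'
#' @param particle_config `"trihybrid"`, `"Fe3O4"`, `"Zn"` or `"Au"`.
#' @param phis Total volume fractions, including 0.
#' @param alpha,tau,Pr,Re,beta_casson,lam,G,Gr Fixed flow parameters.
#' @param split Length-3 weights dividing the total fraction among the
#'   species in the tri-hybrid configuration (normalised internally;
#'   default equal thirds).
#' @param materials Material table.
#' @param definition Nusselt definition, see [nusselt()].
#' @param n_modes Fourier truncation for the wall-gradient series.
#' @return A tibble with columns `particle_config`, `phi`, `nu`, `percent`.
#' @export
#' @examples
#' enhancement_table("trihybrid", phis = c(0, 0.02, 0.04))
enhancement_table <- function(particle_config = c("trihybrid", "Fe3O4", "Zn", "Au"),
                              phis = c(0, 0.01, 0.02, 0.03, 0.04),
                              alpha = 0.5, tau = 1, Pr = 21, Re = 1.2,
                              beta_casson = 1.2, lam = 3, G = 2, Gr = 4,
                              split = c(1, 1, 1) / 3,
                              materials = thnf_materials(),
                              definition = "calibrated", n_modes = 400) {
  particle_config <- match.arg(particle_config)
  if (!any(phis == 0)) {
    abort_domain("phis must include 0 (the baseline for the enhancement percentage)")
  }
  split <- split / sum(split)
  phi_vec <- function(phi) {
    switch(particle_config,
      trihybrid = phi * split,
      Fe3O4 = c(phi, 0, 0),
      Zn = c(0, phi, 0),
      Au = c(0, 0, phi)
    )
  }
  nu <- vapply(phis, function(phi) {
    pv <- phi_vec(phi)
    mx <- mixture_state(pv[1], pv[2], pv[3], materials = materials)
    p <- model_parameters(mx, alpha = alpha, beta_casson = beta_casson,
                          lam = lam, G = G, Gr = Gr, Pr = Pr, Re = Re)
    as.numeric(nusselt(p, tau = tau, definition = definition, n_modes = n_modes))
  }, numeric(1))
  nu0 <- nu[which(phis == 0)[1]]
  tibble::tibble(
    particle_config = particle_config,
    phi = phis,
    nu = nu,
    percent = 100 * (nu - nu0) / nu0
  )
}

#' Regenerate the printed Nusselt and enhancement tables
#'
#' Recomputes, with the calibrated Nusselt definition, the Nusselt-number
#' parameter-variation table (baseline `alpha = 0.5`, `tau = 1`,
#' `phi_hnf = 0.02`, `Pr = 21`, `Re = 1.2`, one parameter varied per row)
#' and the four enhancement tables (tri-hybrid, Fe3O4-only, Zn-only,
#' Au-only, fractions 0 to 0.04).
#'
#' @inheritParams enhancement_table
#' @return A named list of tibbles: `nusselt_variation`, `trihybrid`,
#'   `Fe3O4`, `Zn`, `Au`.
#' @export
heat_transfer_tables <- function(materials = thnf_materials(), n_modes = 400) {
  rows <- tibble::tribble(
    ~alpha, ~tau, ~phi_hnf, ~Pr, ~Re,
    0.5, 1.0, 0.02, 21, 1.2,
    0.7, 1.0, 0.02, 21, 1.2,
    0.5, 1.5, 0.02, 21, 1.2,
    0.5, 1.0, 0.03, 21, 1.2,
    0.5, 1.0, 0.02, 22, 1.2,
    0.5, 1.0, 0.02, 21, 1.5
  )
  rows$nu <- vapply(seq_len(nrow(rows)), function(i) {
    f <- rows$phi_hnf[i] / 3
    mx <- mixture_state(f, f, f, materials = materials)
    p <- model_parameters(mx, alpha = rows$alpha[i], beta_casson = 1.2,
                          lam = 3, G = 2, Gr = 4, Pr = rows$Pr[i], Re = rows$Re[i])
    as.numeric(nusselt(p, tau = rows$tau[i], n_modes = n_modes))
  }, numeric(1))
  configs <- c("trihybrid", "Fe3O4", "Zn", "Au")
  tables <- lapply(configs, function(cfg) {
    enhancement_table(cfg, materials = materials, n_modes = n_modes)
  })
  names(tables) <- configs
  c(list(nusselt_variation = rows), tables)
}

#' Limiting-case consistency checks
#'
#' Evaluates the solution under the two published parameter reductions and
#' cross-validates it against the Laplace-inversion oracle:
#' `"no_pressure_no_particles"` (`G = 0`, `phi = 0`: plain fractional
#' couple-stress Casson Couette flow) and `"no_casson_no_buoyancy"`
#' (`1/beta -> 0`, `Gr = 0`, `phi = 0`: pressure-driven couple-stress flow,
#' realised with a very large Casson parameter).
#'
#' @param case_id One of the two case names above.
#' @param tau Evaluation time.
#' @param xi Spatial grid.
#' @param n_modes Series truncation (analytic) and inversion mode count
#'   (oracle).
#' @return A tibble with the case, the boundary values, and the maximum
#'   absolute analytic-vs-oracle deviation for both fields.
#' @export
limiting_case_check <- function(case_id = c("no_pressure_no_particles",
                                            "no_casson_no_buoyancy"),
                                tau = 1, xi = seq(0, 1, length.out = 41),
                                n_modes = 200) {
  case_id <- match.arg(case_id)
  mx <- mixture_state(0, 0, 0)
  params <- switch(case_id,
    no_pressure_no_particles = model_parameters(
      mx, alpha = 0.5, beta_casson = 1.2, lam = 3, G = 0, Gr = 4,
      Pr = 21, Re = 1.2
    ),
    no_casson_no_buoyancy = model_parameters(
      mx, alpha = 0.5, beta_casson = 1e8, lam = 3, G = 1.2, Gr = 0,
      Pr = 21, Re = 1.2
    )
  )
  th <- temperature_profile(params, tau, xi, n_modes = max(n_modes, 400))
  w <- velocity_profile(params, tau, xi, n_modes = max(n_modes, 400))
  th_o <- oracle_profile(params, tau, xi, "temperature", n_modes = n_modes)
  w_o <- oracle_profile(params, tau, xi, "velocity", n_modes = n_modes)
  tibble::tibble(
    case = case_id,
    tau = tau,
    theta_wall0 = th$value[which.min(xi)], theta_wall1 = th$value[which.max(xi)],
    w_wall0 = w$value[which.min(xi)], w_wall1 = w$value[which.max(xi)],
    max_dev_temperature = max(abs(th$value - th_o$value)),
    max_dev_velocity = max(abs(w$value - w_o$value))
  )
}

#' Plot an enhancement table
#'
#' Bar chart of the percentage Nusselt enhancement against volume fraction.
#'
#' @param table A tibble from [enhancement_table()].
#' @return A ggplot object.
#' @export
plot_enhancement <- function(table) {
  ggplot2::ggplot(table, ggplot2::aes(x = factor(.data$phi), y = .data$percent)) +
    ggplot2::geom_col(fill = "#1f6fb2") +
    ggplot2::labs(x = "total volume fraction", y = "Nu enhancement (%)",
                  title = unique(table$particle_config)) +
    ggplot2::theme_minimal()
}
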