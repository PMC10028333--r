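#' Steady parts of the temperature and velocity fields
#'
#' `steady_temperature()` is the conduction profile `1 - xi`.
#' `steady_velocity()` is the wall- and pressure-driven steady solution of
#' the couple-stress momentum balance with hinged ends
#' (`w'' = 0` at both walls),
#' \deqn{w_s(\xi) = (1-\xi) + G\left[\tfrac{\xi(1-\xi)}{2}
#'   - \lambda\left(1 - \frac{\cosh((\xi - 1/2)/\sqrt{\lambda})}
#'                        {\cosh(1/(2\sqrt{\lambda}))}\right)\right],}
#' which satisfies `0 = G + w'' - lambda w''''` exactly for every
#' `lambda >= 0` and reduces to the familiar
#' `1 - G - (1 - G/2) xi - (G/2) xi^2 + G cosh(1/2 - xi)/cosh(1/2)` form at
#' `lambda = 1`. At `lambda = 0` the boundary-layer term vanishes and the
#' profile is `(1 - xi) + G xi (1 - xi) / 2`.
#'
#' @param xi Dimensionless wall-normal coordinate in `[0, 1]`.
#' @param G Dimensionless pressure gradient.
#' @param lam Couple-stress parameter (>= 0).
#' @return Numeric vector of steady field values.
#' @export
steady_temperature <- function(xi) 1 - xi

#' @rdname steady_temperature
#' @export
steady_velocity <- function(xi, G, lam) {
  base <- (1 - xi) + G * xi * (1 - xi) / 2
  if (lam == 0) return(base)
  rl <- sqrt(lam)
  base - G * lam * (1 - cosh((xi - 0.5) / rl) / cosh(0.5 / rl))
}

new_profile <- function(xi, values, tau, field_kind, params, n_modes, series_tol) {
  out <- tibble::tibble(
    xi = xi, value = values, tau = tau, field_kind = field_kind
  )
  structure(out,
    class = c("thnf_profile", class(out)),
    params = params, n_modes = n_modes, series_tol = series_tol
  )
}

check_profile_inputs <- function(params, tau, xi) {
  if (!inherits(params, "thnf_params")) {
    abort_domain("`params` must be a thnf_params object")
  }
  if (length(tau) != 1 || tau <= 0) abort_domain("tau must be a single value > 0")
  if (any(xi < 0) || any(xi > 1)) abort_domain("xi must lie in [0, 1]")
  invisible(NULL)
}

# truncation bookkeeping shared by both fields: the series is accepted when
# the last mode's largest possible contribution is below tol and n >= 20
check_truncation <- function(last_contrib, series_tol, n_modes) {
  if (!is.finite(last_contrib) || last_contrib > series_tol) {
    rlang::abort(
      sprintf(
        "sine series not converged with %d modes (last-mode contribution %.3g > %.3g)",
        n_modes, last_contrib, series_tol
      ),
      class = "thnflow_convergence_error",
      tail_estimate = last_contrib
    )
  }
  invisible(NULL)
}

#' Temperature field of the fractional channel-flow problem
#'
#' Evaluates the closed-form Atangana-Baleanu fractional temperature
#' \deqn{\theta(\xi, \tau) = (1 - \xi) - 2\sum_{n\ge 1}
#'   \frac{r_1\,E_\alpha(-r_4 \tau^\alpha)}{\sigma_n r_3}
#'   \sin(\sigma_n \xi),}
#' i.e. the conduction profile plus a fractional-relaxation sine series
#' (the series coefficient is `r5 (r4 - r2)/r4 * (h * F)(tau)` written in a
#' cancellation-free form). Boundary values `theta(0) = 1`, `theta(1) = 0`
#' hold exactly at every truncation. At `alpha = 1` the call is routed to
#' [classical_limit_profile()].
#'
#' @param params A [model_parameters()] object.
#' @param tau Dimensionless time (> 0).
#' @param xi Evaluation grid in `[0, 1]`.
#' @param n_modes Fourier truncation cap (the series is cut earlier once the
#'   mode-amplitude bound drops below `series_tol`, but never below 20
#'   modes).
#' @param series_tol Absolute series-tail tolerance.
#' @return A `thnf_profile` tibble with columns `xi`, `value`, `tau`,
#'   `field_kind`, carrying the truncation used as attributes.
#' @export
#' @examples
#' mx <- mixture_state(0.02 / 3, 0.02 / 3, 0.02 / 3)
#' p <- model_parameters(mx, alpha = 0.5, beta_casson = 1.2, lam = 3,
#'                       G = 2, Gr = 4, Pr = 21, Re = 1.2)
#' temperature_profile(p, tau = 1, xi = c(0, 0.5, 1))
temperature_profile <- function(params, tau, xi = seq(0, 1, length.out = 101),
                                n_modes = 1000, series_tol = 1e-7) {
  check_profile_inputs(params, tau, xi)
  if (params$alpha == 1) {
    return(classical_limit_profile(params, tau, xi, "temperature",
                                   n_modes = n_modes, series_tol = series_tol))
  }
  mc <- mode_coefficients(params, seq_len(n_modes))
  # amplitude bound 2 r1 / (sigma_n r3) is tau-independent; truncate where
  # it falls below a tenth of the tolerance (tail-sum safety margin)
  bound <- 2 * mc$r1 / (mc$sigma_n * mc$r3)
  N <- max(20L, min(c(which(bound < series_tol / 10), n_modes)))
  mc <- mc[seq_len(N), ]
  En <- mittag_leffler(-mc$r4 * tau^params$alpha, params$alpha)
  b <- -mc$r1 * En / (mc$sigma_n * mc$r3)
  check_truncation(abs(2 * b[N]), series_tol, N)
  sines <- sin(outer(mc$sigma_n, xi))
  values <- steady_temperature(xi) + 2 * colSums(b * sines)
  new_profile(xi, values, tau, "temperature", params, N, series_tol)
}

# classical (alpha = 1) velocity transient relative to the pressure/wall
# steady part g_n/(sigma_n s): exponential decay of the wall forcing plus the
# buoyancy particular solution driven by the temperature transient
classical_velocity_transient <- function(params, n, tau) {
  sg <- n * pi / params$h
  sg2 <- sg^2
  s <- sg2 + params$lam * sg2^2
  a_th <- sg2 / params$B3
  a_w <- s / params$B0
  g <- params$G * (1 - (-1)^n) + s
  denom <- a_w - a_th
  cross <- ifelse(abs(denom) < 1e-10 * (a_w + a_th),
                  tau * exp(-a_th * tau),
                  (exp(-a_th * tau) - exp(-a_w * tau)) / denom)
  buoy <- params$B2 / (params$B0 * sg) *
    ((1 - exp(-a_w * tau)) / a_w - cross)
  -(g / (sg * s)) * exp(-a_w * tau) + buoy
}

# time-dependent transient coefficient of velocity mode n (everything except
# the pressure/wall steady part g_n / (sigma_n s), which is resummed in
# closed form by steady_velocity())
velocity_mode_transient <- function(params, mc, tau) {
  alpha <- params$alpha
  ta <- tau^alpha
  E4 <- mittag_leffler(-mc$r4 * ta, alpha)
  E8 <- mittag_leffler(-mc$r8 * ta, alpha)
  mc$A1 * E8 + mc$A2 - mc$A3 * (1 - E4) / mc$r4 + mc$A4 * (1 - E8) / mc$r8
}

#' Velocity field of the fractional channel-flow problem
#'
#' Evaluates the closed-form velocity as the steady part
#' [steady_velocity()] plus the unsteady sine series
#' \deqn{w(\xi,\tau) = w_s(\xi) + 2 \sum_{n\ge 1}\Big[
#'   A_1 (h * F_\beta(-r_8, \cdot))(\tau) + A_2
#'   - A_3 (1 * F_\beta(-r_4, \cdot))(\tau)
#'   + A_4 (1 * F_\beta(-r_8, \cdot))(\tau) \Big]\sin(\sigma_n\xi),}
#' with the convolutions evaluated through their Mittag-Leffler closed
#' forms. The `A2 - A3/r4 + A4/r8` residue of the series is the
#' buoyancy-driven steady correction (it equals `B2/(sigma_n s)` per mode),
#' so the series converges like `n^-5` for `lambda > 0`. Wall values
#' `w(0) = 1`, `w(1) = 0` hold exactly at every truncation. At `alpha = 1`
#' the call is routed to [classical_limit_profile()].
#'
#' @inheritParams temperature_profile
#' @return A `thnf_profile` tibble, as for [temperature_profile()].
#' @export
velocity_profile <- function(params, tau, xi = seq(0, 1, length.out = 101),
                             n_modes = 1000, series_tol = 1e-7) {
  check_profile_inputs(params, tau, xi)
  if (params$alpha == 1) {
    return(classical_limit_profile(params, tau, xi, "velocity",
                                   n_modes = n_modes, series_tol = series_tol))
  }
  mc <- mode_coefficients(params, seq_len(n_modes))
  Tn <- velocity_mode_transient(params, mc, tau)
  # adaptive cut at the first mode (>= 20) whose contribution is below a
  # tenth of the tolerance (tail-sum safety margin)
  N <- max(20L, min(c(which(abs(2 * Tn) < series_tol / 10), n_modes)))
  check_truncation(abs(2 * Tn[N]), series_tol, N)
  mc <- mc[seq_len(N), ]
  Tn <- Tn[seq_len(N)]
  sines <- sin(outer(mc$sigma_n, xi))
  values <- steady_velocity(xi, params$G, params$lam) + 2 * colSums(Tn * sines)
  new_profile(xi, values, tau, "velocity", params, N, series_tol)
}

#' Classical (alpha = 1) limit of the temperature and velocity fields
#'
#' At `alpha = 1` the fractional kernel degenerates
#' (`F_1(-r, tau) = exp(-r tau)`) and the per-mode relaxation becomes
#' exponential with rates `sigma_n^2 / B3` (temperature) and
#' `(sigma_n^2 + lambda sigma_n^4) / B0` (velocity). This routine evaluates
#' those classical solutions directly, bypassing the `1/(1 - alpha)`
#' coefficients:
#' \deqn{\theta = (1-\xi) - 2\sum \frac{e^{-\sigma_n^2 \tau / B_3}}{\sigma_n}
#'   \sin(\sigma_n\xi),}
#' and for velocity the exact solution of the per-mode linear ODE forced by
#' the wall, the pressure and the buoyancy term `B2 theta_F(tau)`.
#'
#' @inheritParams temperature_profile
#' @param field_kind `"temperature"` or `"velocity"`.
#' @return A `thnf_profile` tibble.
#' @export
classical_limit_profile <- function(params, tau, xi = seq(0, 1, length.out = 101),
                                    field_kind = c("temperature", "velocity"),
                                    n_modes = 1000, series_tol = 1e-7) {
  field_kind <- match.arg(field_kind)
  check_profile_inputs(params, tau, xi)
  n <- seq_len(n_modes)
  sg <- n * pi / params$h
  sg2 <- sg^2
  a_th <- sg2 / params$B3
  if (field_kind == "temperature") {
    b <- -exp(-a_th * tau) / sg
    N <- max(20L, min(c(which(abs(2 * b) < series_tol / 10), n_modes)))
    b <- b[seq_len(N)]
    values <- steady_temperature(xi) + 2 * colSums(b * sin(outer(sg[seq_len(N)], xi)))
    return(new_profile(xi, values, tau, "temperature", params, N, series_tol))
  }
  Tn <- classical_velocity_transient(params, n, tau)
  N <- max(20L, min(c(which(abs(2 * Tn) < series_tol / 10 &
                              seq_along(Tn) >= 20), n_modes)))
  Tn <- Tn[seq_len(N)]
  values <- steady_velocity(xi, params$G, params$lam) +
    2 * colSums(Tn * sin(outer(sg[seq_len(N)], xi)))
  new_profile(xi, values, tau, "velocity", params, N, series_tol)
}

#' Write a field profile as CSV
#'
#' Persists a `thnf_profile` with columns `xi, value, tau, field_kind`.
#' Doubles are written in shortest round-trip representation, so the output
#' is byte-identical across runs with identical inputs.
#'
#' @param profile A `thnf_profile` tibble.
#' @param path Output CSV path.
#' @return `profile`, invisibly.
#' @export
write_profile <- function(profile, path) {
  readr::write_csv(tibble::as_tibble(profile), path)
  invisible(profile)
}

#' @export
#' @method autoplot thnf_profile
autoplot.thnf_profile <- function(object, ...) {
  kind <- object$field_kind[1]
  ggplot2::ggplot(object, ggplot2::aes(x = .data$xi, y = .data$value)) +
    ggplot2::geom_line(colour = if (kind == "temperature") "#c23b22" else "#1f6fb2") +
    ggplot2::labs(
      x = expression(xi),
      y = if (kind == "temperature") expression(theta(xi, tau)) else expression(w(xi, tau)),
      title = sprintf("%s profile at tau = %g", kind, object$tau[1])
    ) +
    ggplot2::theme_minimal()
}

#' Plot a field profile
#'
#' Convenience wrapper around [ggplot2::autoplot()] for `thnf_profile`
#' objects.
#'
#' @param profile A `thnf_profile`.
#' @param ... Passed to `autoplot()`.
#' @return A ggplot object.
#' @export
plot_profile <- function(profile, ...) ggplot2::autoplot(profile, ...)
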