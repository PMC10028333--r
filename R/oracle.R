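# Independent numerical validation layer: the per-mode Laplace-domain images
# of temperature and velocity are evaluated exactly as printed rational
# functions of (q, q^alpha) and inverted by contour quadrature. Nothing here
# reuses the Mittag-Leffler closed forms of the analytic solution -- the two
# code paths share only the elementary steady profiles.

#' Numerical inverse Laplace transform
#'
#' Inverts a Laplace image at a single time by contour summation, with two
#' independent method families:
#' `"talbot"` -- the fixed (modified) Talbot contour, nodes
#' `delta_0 = 2M/5`, `delta_k = (2 k pi / 5)(cot(k pi/M) + i)`;
#' `"euler"` -- the Euler-accelerated Bromwich series on a vertical line
#' with binomial averaging of the alternating partial sums.
#' Both handle images containing `q^alpha` on the principal branch (no
#' Talbot node ever falls on the negative real axis).
#'
#' @param image_fun Function of a complex `q` returning the image value
#'   (vectorised over `q`).
#' @param tau Time at which to invert (> 0). Vectorised.
#' @param method `"talbot"` or `"euler"`.
#' @param M Number of contour nodes (Talbot) or Euler terms; the defaults
#'   give ~1e-10 relative accuracy on smooth rational images.
#' @return The inverse transform evaluated at `tau`.
#' @export
#' @examples
#' laplace_invert(function(q) 1 / q, 1)            # Heaviside -> 1
#' laplace_invert(function(q) 1 / (q + 2), 0.5)    # exp(-2 * 0.5)
laplace_invert <- function(image_fun, tau, method = c("talbot", "euler"), M = NULL) {
  method <- match.arg(method)
  if (any(tau <= 0)) abort_domain("tau must be > 0")
  if (method == "talbot") {
    M <- if (is.null(M)) 32L else as.integer(M)
    k <- seq_len(M - 1)
    theta <- k * pi / M
    cotk <- cos(theta) / sin(theta)
    delta <- c(2 * M / 5, 2 * k * pi / 5 * (cotk + 1i))
    gam <- c(
      0.5 * exp(delta[1]),
      (1 + 1i * theta * (1 + cotk^2) - 1i * cotk) * exp(delta[-1])
    )
    vapply(tau, function(tt) {
      vals <- image_fun(delta / tt)
      out <- 2 / (5 * tt) * sum(Re(gam * vals))
      if (!is.finite(out)) {
        rlang::abort("Talbot contour evaluation overflowed",
                     class = "thnflow_convergence_error")
      }
      out
    }, numeric(1))
  } else {
    M <- if (is.null(M)) 18L else as.integer(M)
    # Abate-Whitt Euler framework: nodes (M log 10)/3 + i pi k, alternating
    # weights with binomial tail averaging
    kk <- 0:(2 * M)
    xi_w <- c(0.5, rep(1, M), numeric(M))
    xi_w[2 * M + 1] <- 2^(-M)
    for (j in seq_len(M - 1)) {
      xi_w[2 * M + 1 - j] <- xi_w[2 * M + 2 - j] + 2^(-M) * choose(M, j)
    }
    a0 <- M * log(10) / 3
    beta_k <- a0 + 1i * pi * kk
    eta <- (-1)^kk * xi_w
    vapply(tau, function(tt) {
      vals <- image_fun(beta_k / tt)
      out <- 10^(M / 3) / tt * sum(eta * Re(vals))
      if (!is.finite(out)) {
        rlang::abort("Euler inversion overflowed",
                     class = "thnflow_convergence_error")
      }
      out
    }, numeric(1))
  }
}

new_image <- function(fun, steady, n, field_kind, coefs) {
  structure(
    list(fun = fun, steady = steady, n = n, field_kind = field_kind, coefs = coefs),
    class = "thnf_image"
  )
}

#' Per-mode Laplace-domain images of the transformed fields
#'
#' Constructs the printed Laplace/finite-sine-domain images: for temperature
#' \deqn{\bar\theta_F(n, q) = \frac{r_5 (q^\alpha + r_2)}{q (q^\alpha + r_4)}}
#' and for velocity
#' \deqn{\bar w_F(n, q) = \frac{g_n}{r_7 \sigma_n}
#'   \frac{q^\alpha + r_2}{q (q^\alpha + r_8)}
#'   + \frac{B_2 r_5}{r_7}
#'   \frac{(q^\alpha + r_2)^2}{q (q^\alpha + r_4)(q^\alpha + r_8)}.}
#' The returned object carries the exact steady (final-value) coefficient
#' `lim q -> 0 of q * image(q)`, read off the rational structure.
#'
#' @inheritParams mode_coefficients
#' @param n Single mode index.
#' @return A `thnf_image` object with elements `fun` (complex evaluator),
#'   `steady`, `n`, `field_kind` and the mode coefficients.
#' @export
temperature_image <- function(params, n) {
  mc <- mode_coefficients(params, n)
  alpha <- params$alpha
  fun <- function(q) {
    qa <- q^alpha
    mc$r5 * (qa + mc$r2) / (q * (qa + mc$r4))
  }
  new_image(fun, mc$r5 * mc$r2 / mc$r4, n, "temperature", mc)
}

#' @rdname temperature_image
#' @export
velocity_image <- function(params, n) {
  mc <- mode_coefficients(params, n)
  alpha <- params$alpha
  s <- mc$sigma_n^2 + params$lam * mc$sigma_n^4
  g <- params$G * (1 - (-1)^n) + s
  B2 <- params$B2
  fun <- function(q) {
    qa <- q^alpha
    (g / (mc$r7 * mc$sigma_n)) * (qa + mc$r2) / (q * (qa + mc$r8)) +
      (B2 * mc$r5 / mc$r7) * (qa + mc$r2)^2 / (q * (qa + mc$r4) * (qa + mc$r8))
  }
  steady <- (g / (mc$r7 * mc$sigma_n)) * mc$r2 / mc$r8 +
    (B2 * mc$r5 / mc$r7) * mc$r2^2 / (mc$r4 * mc$r8)
  new_image(fun, steady, n, "velocity", mc)
}

#' Evaluate a Laplace-domain image
#'
#' Exact rational evaluation of a `thnf_image` at complex `q` on the
#' principal branch of `q^alpha`. Points on the branch cut (the closed
#' negative real axis) are rejected.
#'
#' @param image A `thnf_image`.
#' @param q Complex (or positive real) Laplace variable, vectorised.
#' @return Complex image values.
#' @export
evaluate_image <- function(image, q) {
  if (!inherits(image, "thnf_image")) abort_domain("`image` must be a thnf_image")
  q <- as.complex(q)
  if (any(Re(q) <= 0 & Im(q) == 0)) {
    abort_domain("q on the branch cut (negative real axis) is not allowed")
  }
  image$fun(q)
}

#' Reconstruct a field profile from per-mode Laplace images
#'
#' Inverts each mode image numerically at time `tau` and assembles the field
#' as closed-form steady part plus sine series. The non-decaying (steady)
#' component of each image is split off exactly before inversion -- the
#' contour quadrature then acts on a decaying transient, and the slowly
#' converging steady sine series is replaced by its elementary closed form.
#'
#' @param images List of `thnf_image` objects for modes `1..N` (all of one
#'   `field_kind`, built from the same parameter set).
#' @param tau Evaluation time (> 0).
#' @param xi_grid Spatial grid in `[0, 1]`.
#' @param params The [model_parameters()] object the images were built from
#'   (supplies the closed-form steady profile).
#' @param method Inversion method, see [laplace_invert()].
#' @return A `thnf_profile` tibble.
#' @export
reconstruct_field <- function(images, tau, xi_grid, params,
                              method = c("talbot", "euler")) {
  method <- match.arg(method)
  if (length(images) == 0) abort_domain("need at least one mode image")
  kind <- images[[1]]$field_kind
  sg <- vapply(images, function(im) im$coefs$sigma_n, numeric(1))
  cn <- vapply(images, function(im) im$steady, numeric(1))
  trans <- vapply(images, function(im) {
    laplace_invert(function(q) im$fun(q) - im$steady / q, tau, method = method)
  }, numeric(1))
  if (kind == "temperature") {
    steady_field <- steady_temperature(xi_grid)
    pn <- 1 / sg  # sine coefficients of 1 - xi
  } else {
    steady_field <- steady_velocity(xi_grid, params$G, params$lam)
    s <- sg^2 + params$lam * sg^4
    pn <- (params$G * (1 - (-1)^seq_along(sg)) + s) / (sg * s)
  }
  coef <- (cn - pn) + trans
  values <- steady_field + 2 * colSums(coef * sin(outer(sg, xi_grid)))
  new_profile(xi_grid, values, tau, kind, params, length(images), NA_real_)
}

#' Independent numerical solution by Laplace-domain inversion
#'
#' End-to-end oracle: builds the per-mode images ([temperature_image()],
#' [velocity_image()]), inverts them numerically and reconstructs the field.
#' This path never touches the Mittag-Leffler/Robotnov-Hartley closed forms
#' used by [temperature_profile()] / [velocity_profile()], so agreement
#' between the two is a genuine cross-validation of the analytic solution.
#'
#' @inheritParams temperature_profile
#' @param field_kind `"temperature"` or `"velocity"`.
#' @param n_modes Number of modes to invert.
#' @param method Inversion method, see [laplace_invert()].
#' @return A `thnf_profile` tibble.
#' @export
#' @examples
#' mx <- mixture_state(0, 0, 0)
#' p <- model_parameters(mx, alpha = 0.5, beta_casson = 1.2, lam = 3,
#'                       G = 2, Gr = 4, Pr = 21, Re = 1.2)
#' oracle_profile(p, tau = 1, xi = c(0.25, 0.5), n_modes = 50)
oracle_profile <- function(params, tau, xi = seq(0, 1, length.out = 101),
                           field_kind = c("temperature", "velocity"),
                           n_modes = 200, method = c("talbot", "euler")) {
  field_kind <- match.arg(field_kind)
  method <- match.arg(method)
  check_profile_inputs(params, tau, xi)
  maker <- if (field_kind == "temperature") temperature_image else velocity_image
  images <- lapply(seq_len(n_modes), function(n) maker(params, n))
  reconstruct_field(images, tau, xi, params, method = method)
}
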