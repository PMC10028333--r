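#' Per-mode coefficients of the closed-form solutions
#'
#' For Fourier mode `n` of the finite sine transform (`sigma_n = n pi / h`)
#' the fractional solutions are governed by the rational coefficients
#' \deqn{r_1 = B_3/(1-\alpha),\quad r_2 = \alpha/(1-\alpha),\quad
#'       r_3 = r_1 + \sigma_n^2,\quad r_4 = r_2 \sigma_n^2 / r_3,\quad
#'       r_5 = \sigma_n / r_3,}
#' \deqn{r_6 = B_0/(1-\alpha),\quad
#'       r_7 = r_6 + \sigma_n^2 + \lambda \sigma_n^4,\quad
#'       r_8 = (r_2 \sigma_n^2 + \lambda r_2 \sigma_n^4)/r_7,}
#' and the velocity amplitudes
#' `A1 = (g_n / sigma_n) (r8 - r2) / (r7 r8)`, `A2 = B2 r5 / r7`,
#' `A3 = A2 (r2 - r4)^2 / (r4 - r8)`, `A4 = A2 (r2 - r8)^2 / (r4 - r8)`,
#' with `g_n = G (1 - (-1)^n) + sigma_n^2 + lambda sigma_n^4`.
#'
#' `r4` and `r8` are the per-mode fractional relaxation rates of temperature
#' and velocity; both lie in `[0, r2)`.
#'
#' @param params A [model_parameters()] object with `alpha < 1` (the
#'   `1 - alpha` denominators degenerate at `alpha = 1`; use
#'   [classical_limit_profile()] there).
#' @param n Integer vector of mode indices (>= 1).
#' @return A tibble with one row per mode and columns `n`, `sigma_n`,
#'   `r1`..`r8`, `A1`..`A4`.
#' @export
#' @examples
#' p <- model_parameters(mixture_state(0, 0, 0), alpha = 0.5,
#'                       beta_casson = 1.2, lam = 3, G = 2, Gr = 4,
#'                       Pr = 21, Re = 1.2)
#' mode_coefficients(p, 1:3)
mode_coefficients <- function(params, n) {
  if (!inherits(params, "thnf_params")) {
    abort_domain("`params` must be a thnf_params object")
  }
  if (params$alpha >= 1) {
    rlang::abort(
      "alpha = 1 degenerates the r1/r6 coefficients; use classical_limit_profile()",
      class = "thnflow_classical_limit"
    )
  }
  if (any(n < 1) || any(n != round(n))) abort_domain("mode index n must be >= 1")
  alpha <- params$alpha
  sg <- n * pi / params$h
  sg2 <- sg^2
  r1 <- params$B3 / (1 - alpha)
  r2 <- alpha / (1 - alpha)
  r3 <- r1 + sg2
  r4 <- r2 * sg2 / r3
  r5 <- sg / r3
  r6 <- params$B0 / (1 - alpha)
  s <- sg2 + params$lam * sg2^2
  r7 <- r6 + s
  r8 <- r2 * s / r7
  # near-coincident relaxation rates would blow up the A3/A4 partial
  # fractions; nudge r8 (the combined A-terms have a finite limit there)
  close <- abs(r4 - r8) < 1e-10 * (r4 + r8)
  if (any(close)) {
    r8[close] <- r8[close] * (1 + 1e-7)
    rlang::warn("r4 and r8 nearly coincide; r8 perturbed to stabilise partial fractions")
  }
  g <- params$G * (1 - (-1)^n) + s
  A1 <- (g / sg) * (r8 - r2) / (r7 * r8)
  A2 <- params$B2 * r5 / r7
  A3 <- A2 * (r2 - r4)^2 / (r4 - r8)
  A4 <- A2 * (r2 - r8)^2 / (r4 - r8)
  tibble::tibble(
    n = as.integer(n), sigma_n = sg,
    r1 = r1, r2 = r2, r3 = r3, r4 = r4, r5 = r5,
    r6 = r6, r7 = r7, r8 = r8,
    A1 = A1, A2 = A2, A3 = A3, A4 = A4
  )
}
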