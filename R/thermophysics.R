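# Shape-specific correlation coefficients for dilute suspensions:
# viscosity mu/mu_bf = 1 + a1*phi + a2*phi^2, and the Hamilton-Crosser style
# conductivity ratio with coefficient c = n - 1 (n = 3/psi the shape factor).
.visc_coefs <- list(
  spherical   = c(2.5, 6.2),
  cylindrical = c(13.5, 904.4),
  platelet    = c(37.1, 612.6)
)
.cond_coefs <- c(spherical = 2, cylindrical = 3.9, platelet = 4.7)

abort_domain <- function(msg) rlang::abort(msg, class = "thnflow_domain_error")

check_fractions <- function(phi) {
  if (any(!is.finite(phi)) || any(phi < 0)) {
    abort_domain("volume fractions must be finite and >= 0")
  }
  if (sum(phi) >= 1) {
    abort_domain("total volume fraction phi1 + phi2 + phi3 must be < 1")
  }
  invisible(phi)
}

#' Shape-dependent viscosity ratio of a dilute suspension
#'
#' Ratio of suspension to base-fluid dynamic viscosity for a given particle
#' shape at total volume fraction `phi`:
#' spherical `1 + 2.5 phi + 6.2 phi^2`, cylindrical
#' `1 + 13.5 phi + 904.4 phi^2`, platelet `1 + 37.1 phi + 612.6 phi^2`.
#'
#' @param shape One of `"spherical"`, `"cylindrical"`, `"platelet"`.
#' @param phi Total particle volume fraction in `[0, 1)`.
#' @return The dimensionless viscosity ratio (vectorised over `phi`).
#' @export
#' @examples
#' shape_viscosity_ratio("spherical", 0.02)
shape_viscosity_ratio <- function(shape, phi) {
  shape <- match.arg(shape, .thnf_shapes)
  if (any(!is.finite(phi)) || any(phi < 0) || any(phi >= 1)) {
    abort_domain("phi must lie in [0, 1)")
  }
  a <- .visc_coefs[[shape]]
  1 + a[1] * phi + a[2] * phi^2
}

#' Shape-dependent thermal conductivity ratio (Maxwell / Hamilton-Crosser)
#'
#' Conductivity ratio `k_nf / k_bf` of a dilute suspension with
#' shape-dependent coefficient `c` (2 spherical, 3.9 cylindrical, 4.7
#' platelet, i.e. `n - 1` for shape factors 3, 4.9 and 5.7):
#' \deqn{\frac{k_p + c\,k_{bf} + c\,\phi (k_p - k_{bf})}
#'            {k_p + c\,k_{bf} - \phi (k_p - k_{bf})}.}
#'
#' @inheritParams shape_viscosity_ratio
#' @param k_particle,k_bf Particle and base-fluid conductivities (W/m K), > 0.
#' @return The dimensionless conductivity ratio; exactly 1 when
#'   `k_particle == k_bf`.
#' @export
shape_conductivity_ratio <- function(shape, phi, k_particle, k_bf) {
  shape <- match.arg(shape, .thnf_shapes)
  if (any(k_particle <= 0) || any(k_bf <= 0)) {
    abort_domain("conductivities must be > 0")
  }
  if (any(!is.finite(phi)) || any(phi < 0) || any(phi >= 1)) {
    abort_domain("phi must lie in [0, 1)")
  }
  cc <- .cond_coefs[[shape]]
  den <- k_particle + cc * k_bf - phi * (k_particle - k_bf)
  if (any(den <= 0)) {
    abort_domain("conductivity-ratio denominator is non-positive")
  }
  (k_particle + cc * k_bf + cc * phi * (k_particle - k_bf)) / den
}

#' Maxwell conductivity ratio with an explicit shape factor
#'
#' General Maxwell form with shape factor `n = 3 / psi` (`psi` the
#' sphericity). The shape-specific coefficients in
#' [shape_conductivity_ratio()] correspond to `c = n - 1` with `n` = 3, 4.9,
#' 5.7; that shape-specific form is what the flow pipeline uses -- this
#' helper is provided for exploring other shape factors.
#'
#' @inheritParams shape_conductivity_ratio
#' @param n Shape factor (> 1).
#' @return The dimensionless conductivity ratio.
#' @export
maxwell_conductivity_ratio <- function(n, phi, k_particle, k_bf) {
  if (any(n <= 1)) abort_domain("shape factor n must be > 1")
  shape_ratio <- function(cc) {
    den <- k_particle + cc * k_bf - phi * (k_particle - k_bf)
    if (any(den <= 0)) abort_domain("conductivity-ratio denominator is non-positive")
    (k_particle + cc * k_bf + cc * phi * (k_particle - k_bf)) / den
  }
  shape_ratio(n - 1)
}

split_materials <- function(materials) {
  materials <- tibble::as_tibble(validate_materials(materials))
  list(
    bf = materials[materials$shape == "base_fluid", , drop = FALSE],
    sp = materials[materials$shape != "base_fluid", , drop = FALSE]
  )
}

linear_mixture_ratio <- function(phi, ratios) {
  (1 - sum(phi)) + sum(phi * ratios)
}

#' Linear mixture ratios of the tri-hybrid suspension
#'
#' Volume-fraction weighted mixture rules for density (`chi1`), heat
#' capacitance `rho cp` (`chi7`) and thermal expansion `rho beta_T` (`chi6`),
#' each expressed relative to the base fluid, e.g.
#' `chi1 = (1 - phi1 - phi2 - phi3) + sum(phi_i rho_i / rho_bf)`.
#'
#' @param phi1,phi2,phi3 Volume fractions of the three particle species, in
#'   the row order of `materials` (Fe3O4, Zn, Au for the built-in table).
#' @param materials Material table, see [thnf_materials()].
#' @return The dimensionless mixture ratio.
#' @export
#' @examples
#' mixture_ratio_density(0.01, 0, 0)  # 0.99 + 0.01 * 5200 / 1053
mixture_ratio_density <- function(phi1, phi2, phi3, materials = thnf_materials()) {
  phi <- check_fractions(c(phi1, phi2, phi3))
  m <- split_materials(materials)
  linear_mixture_ratio(phi, m$sp$rho / m$bf$rho)
}

#' @rdname mixture_ratio_density
#' @export
mixture_ratio_heat_capacity <- function(phi1, phi2, phi3, materials = thnf_materials()) {
  phi <- check_fractions(c(phi1, phi2, phi3))
  m <- split_materials(materials)
  linear_mixture_ratio(phi, (m$sp$rho * m$sp$cp) / (m$bf$rho * m$bf$cp))
}

#' @rdname mixture_ratio_density
#' @export
mixture_ratio_expansion <- function(phi1, phi2, phi3, materials = thnf_materials()) {
  phi <- check_fractions(c(phi1, phi2, phi3))
  m <- split_materials(materials)
  linear_mixture_ratio(phi, (m$sp$rho * m$sp$beta_T) / (m$bf$rho * m$bf$beta_T))
}

#' Assemble the full mixture state of the tri-hybrid suspension
#'
#' Computes all eleven dimensionless mixture ratios from the volume fractions
#' and the material table:
#' `chi1` (density), `chi2`-`chi4` (per-species viscosity ratios at the
#' *total* fraction), `chi5` (fraction-weighted viscosity interpolation),
#' `chi6` (thermal expansion), `chi7` (heat capacitance), `chi8`-`chi10`
#' (per-species conductivity ratios at the total fraction) and `chi11`
#' (fraction-weighted conductivity interpolation, i.e. `k_hnf / k_bf`).
#'
#' The interpolations `chi5` and `chi11` are 0/0 at zero total fraction and
#' are defined there by their continuous limit 1, so a pure-base-fluid run is
#' a regular special case.
#'
#' @inheritParams mixture_ratio_density
#' @return An object of class `thnf_mixture`: a list with elements `phi`
#'   (named fractions), `phi_hnf`, `chi` (named vector `chi1`..`chi11`) and
#'   `materials`.
#' @export
#' @examples
#' mixture_state(0.01, 0.01, 0.02)
mixture_state <- function(phi1, phi2, phi3, materials = thnf_materials()) {
  phi <- check_fractions(c(phi1, phi2, phi3))
  m <- split_materials(materials)
  if (nrow(m$sp) != 3) {
    abort_domain("mixture_state needs exactly three particle species")
  }
  phih <- sum(phi)

  visc <- vapply(m$sp$shape, shape_viscosity_ratio, numeric(1), phi = phih)
  cond <- vapply(seq_len(3), function(i) {
    shape_conductivity_ratio(m$sp$shape[i], phih, m$sp$k[i], m$bf$k)
  }, numeric(1))

  interp <- function(ratios) {
    if (phih == 0) 1 else sum(phi * ratios) / phih
  }

  chi <- c(
    chi1  = linear_mixture_ratio(phi, m$sp$rho / m$bf$rho),
    chi2  = unname(visc[1]), chi3 = unname(visc[2]), chi4 = unname(visc[3]),
    chi5  = interp(visc),
    chi6  = linear_mixture_ratio(phi, (m$sp$rho * m$sp$beta_T) / (m$bf$rho * m$bf$beta_T)),
    chi7  = linear_mixture_ratio(phi, (m$sp$rho * m$sp$cp) / (m$bf$rho * m$bf$cp)),
    chi8  = unname(cond[1]), chi9 = unname(cond[2]), chi10 = unname(cond[3]),
    chi11 = interp(cond)
  )

  structure(
    list(
      phi = stats::setNames(phi, m$sp$name),
      phi_hnf = phih,
      chi = chi,
      materials = tibble::as_tibble(materials)
    ),
    class = "thnf_mixture"
  )
}

#' @export
print.thnf_mixture <- function(x, ...) {
  cat("Tri-hybrid mixture state\n")
  cat("  phi:", paste(sprintf("%s = %g", names(x$phi), x$phi), collapse = ", "),
      sprintf(" (total %g)\n", x$phi_hnf))
  cat("  chi:", paste(sprintf("%s = %.5g", names(x$chi), x$chi), collapse = ", "), "\n")
  invisible(x)
}

#' @export
#' @method tidy thnf_mixture
tidy.thnf_mixture <- function(x, ...) {
  tibble::tibble(term = names(x$chi), value = unname(x$chi))
}

#' Dimensionless model parameters of the fractional channel-flow problem
#'
#' Bundles the physical control parameters with the derived coefficient
#' groups of the dimensionless momentum and energy balances:
#' `B0 = Re chi1 / (beta chi5)`, `B1 = chi6 / chi5`, `B2 = B1 Gr / beta`,
#' `B3 = Pr chi7 Re / chi11`.
#'
#' @param mixture A [mixture_state()] object.
#' @param alpha Fractional order of the Atangana-Baleanu time derivative,
#'   in `(0, 1]` (`alpha = 1` is the classical limit).
#' @param beta_casson Casson parameter (> 0); the momentum diffusivity is
#'   scaled by `(1 + 1/beta)` before non-dimensionalisation.
#' @param lam Dimensionless couple-stress parameter (>= 0); coefficient of
#'   the fourth-order velocity derivative.
#' @param G Dimensionless axial pressure gradient.
#' @param Gr,Pr,Re Grashof, Prandtl and Reynolds numbers. `Gr` is always
#'   taken as a direct input (its defining velocity/viscosity scales are
#'   never fixed numerically by the model).
#' @param h Dimensionless channel height. Only `h = 1` is supported (the
#'   wall coordinate `xi = y/h` then runs over `[0, 1]`).
#' @return An object of class `thnf_params`.
#' @export
#' @examples
#' mx <- mixture_state(0.02 / 3, 0.02 / 3, 0.02 / 3)
#' model_parameters(mx, alpha = 0.5, beta_casson = 1.2, lam = 3,
#'                  G = 2, Gr = 4, Pr = 21, Re = 1.2)
model_parameters <- function(mixture, alpha, beta_casson, lam, G, Gr, Pr, Re, h = 1) {
  if (!inherits(mixture, "thnf_mixture")) {
    abort_domain("`mixture` must be a thnf_mixture object")
  }
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha > 1) {
    abort_domain("alpha must lie in (0, 1]")
  }
  if (beta_casson <= 0) abort_domain("beta_casson must be > 0")
  if (lam < 0) abort_domain("lam must be >= 0")
  if (Pr <= 0 || Re <= 0) abort_domain("Pr and Re must be > 0")
  if (h != 1) abort_domain("only h = 1 is supported")
  chi <- mixture$chi
  if (chi[["chi5"]] <= 0 || chi[["chi11"]] <= 0) {
    abort_domain("chi5 and chi11 must be > 0")
  }
  B0 <- Re * chi[["chi1"]] / (beta_casson * chi[["chi5"]])
  B1 <- chi[["chi6"]] / chi[["chi5"]]
  B2 <- B1 * Gr / beta_casson
  B3 <- Pr * chi[["chi7"]] * Re / chi[["chi11"]]
  structure(
    list(
      mixture = mixture,
      alpha = alpha, beta_casson = beta_casson, lam = lam,
      G = G, Gr = Gr, Pr = Pr, Re = Re, h = h,
      B0 = B0, B1 = B1, B2 = B2, B3 = B3
    ),
    class = "thnf_params"
  )
}

#' @export
print.thnf_params <- function(x, ...) {
  cat("Fractional couple-stress Casson channel-flow parameters\n")
  cat(sprintf("  alpha = %g, beta = %g, lambda = %g, G = %g\n",
              x$alpha, x$beta_casson, x$lam, x$G))
  cat(sprintf("  Gr = %g, Pr = %g, Re = %g, phi_hnf = %g\n",
              x$Gr, x$Pr, x$Re, x$mixture$phi_hnf))
  cat(sprintf("  B0 = %.6g, B1 = %.6g, B2 = %.6g, B3 = %.6g\n",
              x$B0, x$B1, x$B2, x$B3))
  invisible(x)
}

#' @export
#' @method tidy thnf_params
tidy.thnf_params <- function(x, ...) {
  tibble::tibble(
    term = c("alpha", "beta_casson", "lam", "G", "Gr", "Pr", "Re", "h",
             "B0", "B1", "B2", "B3"),
    value = c(x$alpha, x$beta_casson, x$lam, x$G, x$Gr, x$Pr, x$Re, x$h,
              x$B0, x$B1, x$B2, x$B3)
  )
}

#' @export
#' @method glance thnf_params
glance.thnf_params <- function(x, ...) {
  tibble::tibble(
    phi_hnf = x$mixture$phi_hnf, alpha = x$alpha,
    B0 = x$B0, B1 = x$B1, B2 = x$B2, B3 = x$B3
  )
}
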