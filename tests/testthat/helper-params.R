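# Shared parameter constructors: the figure-baseline conditions of the study.

baseline_mixture <- function(phi_total = 0.02) {
  f <- phi_total / 3
  mixture_state(f, f, f)
}

# temperature figure baseline: alpha = 0.5, tau = 1, phi = 0.02, Pr = 21,
# Re = 1.2; velocity figures additionally fix Gr = 4, G = 2, lam = 3,
# beta = 1.2
baseline_params <- function(alpha = 0.5, phi_total = 0.02, Pr = 21, Re = 1.2,
                            Gr = 4, G = 2, lam = 3, beta_casson = 1.2,
                            mixture = baseline_mixture(phi_total)) {
  model_parameters(mixture, alpha = alpha, beta_casson = beta_casson,
                   lam = lam, G = G, Gr = Gr, Pr = Pr, Re = Re)
}

interior_grid <- function(n = 19) seq(0.05, 0.95, length.out = n)

value_at <- function(profile, xi) profile$value[match(xi, profile$xi)]
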