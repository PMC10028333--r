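test_that("linear mixture ratios reproduce hand-computed values", {
  # pure base fluid
  expect_identical(mixture_ratio_density(0, 0, 0), 1)
  # single species: 0.99 + 0.01 * 5200 / 1053
  expect_equal(mixture_ratio_density(0.01, 0, 0), 0.99 + 0.01 * 5200 / 1053,
               tolerance = 1e-15)
  expect_equal(mixture_ratio_density(0.01, 0, 0), 1.03938271604938, tolerance = 1e-12)

  # brute-force spreadsheet-style summation over the material table rows,
  # written out independently of the package's mixture code
  mat <- thnf_materials()
  phi <- c(0.01, 0.01, 0.02)
  rho <- mat$rho[match(c("Fe3O4", "Zn", "Au"), mat$name)]
  rho_bf <- mat$rho[mat$name == "blood"]
  brute <- (1 - 0.04) +
    phi[1] * rho[1] / rho_bf + phi[2] * rho[2] / rho_bf + phi[3] * rho[3] / rho_bf
  expect_equal(mixture_ratio_density(0.01, 0.01, 0.02), brute, tolerance = 1e-15)

  cp_prod <- mat$rho * mat$cp
  brute7 <- (1 - 0.04) + sum(phi * cp_prod[2:4] / cp_prod[1])
  expect_equal(mixture_ratio_heat_capacity(0.01, 0.01, 0.02), brute7, tolerance = 1e-15)

  bt_prod <- mat$rho * mat$beta_T
  brute6 <- (1 - 0.04) + sum(phi * bt_prod[2:4] / bt_prod[1])
  expect_equal(mixture_ratio_expansion(0.01, 0.01, 0.02), brute6, tolerance = 1e-15)
})

test_that("shape correlations evaluate as printed", {
  expect_identical(shape_viscosity_ratio("spherical", 0), 1)
  expect_equal(shape_viscosity_ratio("spherical", 0.02), 1.05248, tolerance = 1e-12)
  expect_equal(shape_viscosity_ratio("platelet", 0.02), 1.98704, tolerance = 1e-12)
  expect_equal(shape_viscosity_ratio("cylindrical", 0.02),
               1 + 13.5 * 0.02 + 904.4 * 4e-4, tolerance = 1e-15)

  # equal conductivities give exactly 1 for every shape and fraction
  for (shape in c("spherical", "cylindrical", "platelet")) {
    expect_identical(shape_conductivity_ratio(shape, 0.3, 0.492, 0.492), 1)
  }
  # independent evaluation of the printed rational forms
  sph <- (6 + 2 * 0.492 + 2 * 0.02 * (6 - 0.492)) /
    (6 + 2 * 0.492 - 0.02 * (6 - 0.492))
  expect_equal(shape_conductivity_ratio("spherical", 0.02, 6, 0.492), sph,
               tolerance = 1e-15)
  cyl <- (318 + 3.9 * 0.492 + 3.9 * 0.02 * (318 - 0.492)) /
    (318 + 3.9 * 0.492 - 0.02 * (318 - 0.492))
  expect_equal(shape_conductivity_ratio("cylindrical", 0.02, 318, 0.492), cyl,
               tolerance = 1e-15)
  expect_error(shape_conductivity_ratio("cube", 0.02, 6, 0.492))
  # Maxwell helper agrees with the shape-specific coefficient at n = 4.9
  expect_equal(maxwell_conductivity_ratio(4.9, 0.02, 318, 0.492),
               shape_conductivity_ratio("cylindrical", 0.02, 318, 0.492),
               tolerance = 1e-15)
})

test_that("fraction validation rejects out-of-domain inputs", {
  expect_error(mixture_ratio_density(-0.01, 0, 0), class = "thnflow_domain_error")
  expect_error(mixture_state(0.5, 0.3, 0.2), class = "thnflow_domain_error")
  expect_error(shape_viscosity_ratio("spherical", 1), class = "thnflow_domain_error")
})

test_that("mixture interpolations collapse and weight correctly", {
  # phi = 0: all chi equal 1 by the continuous limit
  mx0 <- mixture_state(0, 0, 0)
  expect_true(all(abs(mx0$chi - 1) < 1e-15))

  # single-species recovery: chi5 -> chi2 as the other fractions vanish
  eps <- 1e-6
  mx <- mixture_state(eps, 0, 0)
  expect_equal(mx$chi[["chi5"]], mx$chi[["chi2"]], tolerance = 1e-12)
  expect_equal(mx$chi[["chi11"]], mx$chi[["chi8"]], tolerance = 1e-12)

  # phi-weighted mean recomputed by an independent weighted-average oracle
  mx <- mixture_state(0.01, 0.01, 0.02)
  w <- c(0.01, 0.01, 0.02) / 0.04
  expect_equal(mx$chi[["chi5"]],
               sum(w * mx$chi[c("chi2", "chi3", "chi4")]), tolerance = 1e-14)
  expect_equal(mx$chi[["chi11"]],
               sum(w * mx$chi[c("chi8", "chi9", "chi10")]), tolerance = 1e-14)
})

test_that("chi ratios are continuous, monotone and symmetric where they should be", {
  # continuity at the origin along a ray
  phis <- c(1e-9, 1e-6, 1e-4, 1e-3)
  chis <- vapply(phis, function(p) mixture_state(p / 3, p / 3, p / 3)$chi[["chi5"]],
                 numeric(1))
  expect_true(all(abs(chis - 1) < 0.05))
  expect_true(all(diff(chis) > 0))

  # chi2-chi4 strictly increasing in phi (positive polynomial coefficients)
  grid <- seq(0, 0.2, by = 0.02)
  for (shape in c("spherical", "cylindrical", "platelet")) {
    expect_true(all(diff(shape_viscosity_ratio(shape, grid)) > 0))
  }

  # permuting fractions together with material rows leaves the linear
  # ratios invariant (shapes travel with their rows)
  mat <- thnf_materials()
  perm <- mat[c(1, 4, 2, 3), ]
  a <- mixture_state(0.01, 0.02, 0.005, materials = mat)
  b <- mixture_state(0.005, 0.01, 0.02, materials = perm)
  for (key in c("chi1", "chi5", "chi6", "chi7", "chi11")) {
    expect_equal(a$chi[[key]], b$chi[[key]], tolerance = 1e-14)
  }

  # equal-conductivity degeneracy: all k equal to the base fluid's k
  flat <- mat
  flat$k <- rep(mat$k[mat$name == "blood"], 4)
  mxf <- mixture_state(0.01, 0.02, 0.01, materials = flat)
  expect_equal(mxf$chi[["chi11"]], 1, tolerance = 1e-15)
})

test_that("dimensionless groups combine the mixture ratios as specified", {
  mx0 <- mixture_state(0, 0, 0)
  p <- model_parameters(mx0, alpha = 0.5, beta_casson = 1.2, lam = 3,
                        G = 2, Gr = 4, Pr = 21, Re = 1.2)
  expect_equal(p$B3, 21 * 1 * 1.2 / 1, tolerance = 1e-15)  # 25.2
  expect_equal(p$B0, 1.2 / 1.2, tolerance = 1e-15)

  # B0 scales as 1/beta
  p2 <- model_parameters(mx0, alpha = 0.5, beta_casson = 2.4, lam = 3,
                         G = 2, Gr = 4, Pr = 21, Re = 1.2)
  expect_equal(p2$B0, p$B0 / 2, tolerance = 1e-14)

  # two-step oracle: chi ratios first, then the ratio combination
  mx <- baseline_mixture(0.02)
  pm <- model_parameters(mx, alpha = 0.5, beta_casson = 1.2, lam = 3,
                         G = 2, Gr = 4, Pr = 21, Re = 1.2)
  expect_equal(pm$B0, 1.2 * mx$chi[["chi1"]] / (1.2 * mx$chi[["chi5"]]),
               tolerance = 1e-14)
  expect_equal(pm$B2, (mx$chi[["chi6"]] / mx$chi[["chi5"]]) * 4 / 1.2,
               tolerance = 1e-14)
  expect_equal(pm$B3, 21 * mx$chi[["chi7"]] * 1.2 / mx$chi[["chi11"]],
               tolerance = 1e-14)

  expect_error(model_parameters(mx, alpha = 1.5, beta_casson = 1.2, lam = 3,
                                G = 2, Gr = 4, Pr = 21, Re = 1.2),
               class = "thnflow_domain_error")
  expect_error(model_parameters(mx, alpha = 0.5, beta_casson = 0, lam = 3,
                                G = 2, Gr = 4, Pr = 21, Re = 1.2),
               class = "thnflow_domain_error")
  expect_error(model_parameters(mx, alpha = 0.5, beta_casson = 1.2, lam = 3,
                                G = 2, Gr = 4, Pr = 21, Re = 1.2, h = 2),
               class = "thnflow_domain_error")

  td <- tidy(pm)
  expect_true(all(c("B0", "B1", "B2", "B3") %in% td$term))
})

test_that("material tables round-trip through CSV bit-exactly", {
  path <- withr::local_tempfile(fileext = ".csv")
  mat <- thnf_materials()
  mat$rho[2] <- 5200.123456789012  # exercise full double precision
  write_materials(mat, path)
  back <- read_materials(path)
  for (col in names(mat)) expect_identical(back[[col]], mat[[col]])
  expect_error(validate_materials(mat[, -2]), class = "thnflow_materials_error")
  bad <- mat; bad$rho[1] <- -1
  expect_error(validate_materials(bad), class = "thnflow_materials_error")
})
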