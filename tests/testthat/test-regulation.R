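test_that("spatial masks follow the printed region rules", {
  # QC: both boundaries inclusive
  expect_equal(qc_indicator(c(0, 7.5, -7.5, 15, -8), L_QC = 15),
               c(1, 1, 1, 0, 0))
  # activation: Heaviside at -L_QC/2, shootward side always active
  expect_equal(activation_mask(c(-7.5, -7.5 - 1e-9, 100, -100), L_QC = 15),
               c(1, 0, 1, 0))
  # VI region: (L_QC/2, 3 L_QC/2], same length as the QC
  expect_equal(vi_indicator(c(7.5, 7.6, 22.5, 22.6), L_QC = 15),
               c(0, 1, 1, 0))
})

test_that("BRAVO production: linear, half-saturation and columella masking", {
  p <- model_params(alpha_L = 0.5, alpha = 2, k_B = 0.3, n = 2)
  lin <- model_spec("sequestration", "linear")
  hil <- model_spec("sequestration", "hill")
  expect_equal(prod_bravo(2, 0, p, lin), 1.0)
  expect_equal(prod_bravo(p$k_B, 0, p, hil), p$alpha / 2)
  # columella side masked for any positive activator
  expect_equal(prod_bravo(3, -p$L_QC, p, lin), 0)
  expect_equal(prod_bravo(3, -p$L_QC, p, hil), 0)
  expect_error(prod_bravo(-1, 0, p, lin), "negative")
  # basal VI production adds alpha_0 on VI nodes only
  bas <- model_spec("sequestration", "linear", basal_vi_production = TRUE)
  expect_equal(prod_bravo(0, 10, p, bas), p$alpha_0)
  expect_equal(prod_bravo(0, 30, p, bas), 0)
})

test_that("WOX5 production is gamma in the QC, gamma/2 at k_W for any h", {
  sp <- model_spec("sequestration", "linear")
  sr <- model_spec("sequestration", "linear", wox5_self_repression = TRUE)
  for (h in c(1, 2, 3.5)) {
    p <- model_params(gamma = 1.7, k_W = 0.8, h = h)
    expect_equal(prod_wox5(0.3, 0, p, sp), p$gamma)
    expect_equal(prod_wox5(p$k_W, 0, p, sr), p$gamma / 2)
    expect_equal(prod_wox5(p$k_W, 2 * p$L_QC, p, sr), 0)
  }
})

test_that("Z production: half-saturation, exact c = 0 switch, monotone limit", {
  hil <- model_spec("repression", "hill")
  p <- model_params(beta = 2, k_Z = 0.4, n = 2, c = 0)
  expect_equal(prod_z(p$k_Z, 5, p, hil), p$beta / 2) # c = 0: B irrelevant
  expect_equal(prod_z(p$k_Z, 5, p, hil), prod_z(p$k_Z, 0, p, hil))
  p$c <- 1e9
  expect_lt(prod_z(p$k_Z, 1, p, hil), 1e-8)
  # repression factor absent in the plain intermediary variant
  noz <- model_spec("sequestration_z", "hill")
  p$c <- 7
  expect_equal(prod_z(p$k_Z, 3, p, noz), p$beta / 2)
})

test_that("model_rhs reproduces the printed reaction terms", {
  p <- model_params(alpha_L = 0.3, d_B = 0.07, d_W = 0.11, lambda = 0.9,
                    gamma = 1.3)
  sp <- model_spec("sequestration", "linear")
  r <- model_rhs(list(B = 1, W = 1), 0, p, sp)
  expect_equal(r$dB, p$alpha_L - p$d_B - p$lambda)
  expect_equal(r$dW, p$gamma - p$d_W - p$lambda)
  # all-zero state outside the QC is a fixed point of the reaction part
  z <- model_rhs(list(B = 0, W = 0), 40, p, sp)
  expect_equal(unlist(z), c(dB = 0, dW = 0))
  # bravo mutant: B == 0, no lambda term, no dB component
  mut <- model_spec("sequestration", "linear", genotype = "bravo")
  rm_ <- model_rhs(list(W = 1), 0, p, mut)
  expect_named(rm_, "dW")
  expect_equal(rm_$dW, p$gamma - p$d_W)
})

test_that("reaction terms never drive a zero concentration negative", {
  set.seed(42)
  for (variant in c("sequestration", "sequestration_z", "repression",
                    "mixed", "sequestration_S")) {
    spec <- default_spec(variant)
    p <- default_params(variant)
    species <- intersect(c("B", "W", "Z", "S"),
                         c("B", "W",
                           if (scniche:::spec_has_z(spec)) "Z",
                           if (variant == "sequestration_S") "S"))
    for (rep in 1:20) {
      st <- random_state(5, species)
      zs <- sample(species, 1)
      st[[zs]] <- rep(0, 5)
      x <- runif(5, -30, 30)
      r <- model_rhs(st, x, p, spec)
      dz <- r[[paste0("d", zs)]]
      if (!is.null(dz)) expect_true(all(dz >= 0))
    }
  }
})

test_that("mixed model reduces to its parent variants", {
  p <- default_params("mixed")
  x <- seq(-30, 30, by = 5)
  set.seed(7)
  st <- random_state(length(x), c("B", "W", "Z"))
  # c = 0 removes repression: identical to the intermediary-Z variant
  p0 <- p; p0$c <- 0
  mix <- model_spec("mixed", "hill", wox5_self_repression = TRUE)
  sz <- model_spec("sequestration_z", "hill", wox5_self_repression = TRUE)
  expect_equal(model_rhs(st, x, p0, mix), model_rhs(st, x, p0, sz))
  # lambda = 0 removes sequestration: identical to the repression variant
  pl <- p; pl$lambda <- 0
  rep_ <- model_spec("repression", "hill", wox5_self_repression = TRUE)
  expect_equal(model_rhs(st, x, pl, mix), model_rhs(st, x, pl, rep_))
})

test_that("explicit-complex model: lambda_eff limits and exchange terms", {
  expect_equal(lambda_eff(full_model_params(k_on = 2, k_off = 0, d_C = 1)), 2)
  expect_equal(lambda_eff(full_model_params(k_on = 2, k_off = 1, d_C = 0)), 0)
  fp <- full_model_params(k_on = 1.5, k_off = 0.4, d_C = 0.2)
  expect_equal(lambda_eff(fp), 1.5 * 0.2 / 0.6)
  p <- model_params()
  sp <- model_spec("full_complex", "linear")
  r <- full_complex_rhs(list(B = 1, W = 2, C = 3), 0, p, fp, sp)
  expect_equal(r$dC, fp$k_on * 2 - (fp$k_off + fp$d_C) * 3)
  # B and W carry matching -k_on*B*W + k_off*C exchange terms
  expect_equal(r$dB - (prod_bravo(2, 0, p, sp) - p$d_B * 1),
               -fp$k_on * 2 + fp$k_off * 3)
  expect_equal(r$dW - (prod_wox5(2, 0, p, sp) - p$d_W * 2),
               -fp$k_on * 2 + fp$k_off * 3)
})

test_that("parameter and spec validation reject invalid input", {
  expect_error(model_params(lambda = -1), "negative")
  expect_error(model_params(n = 0.5), "n must be")
  expect_error(model_spec("nonsense"), "arg")
  expect_error(grid1d(-600, 600, 0.07), "integer")
  expect_error(grid1d(-5, 5, 0.05, L_QC = 15), "QC")
})
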